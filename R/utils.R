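# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a sub-seed for an internal stage so that independent generator
# calls sharing one user seed do not replay the same stream.
derive_seed <- function(seed, salt) {
  (as.integer(seed) + as.integer(salt) * 7919L) %% 2147483647L
}

stop_if_not_granges <- function(x, arg = deparse(substitute(x))) {
  if (!methods::is(x, "GRanges"))
    stop(sprintf("`%s` must be a GRanges object", arg), call. = FALSE)
  invisible(x)
}

# Coerce a list of GRanges, checking names and classes.
as_granges_list <- function(sets, arg = "sets") {
  if (methods::is(sets, "GRanges")) sets <- list(sets)
  if (!is.list(sets) || length(sets) == 0L)
    stop(sprintf("`%s` must be a non-empty list of GRanges", arg), call. = FALSE)
  lapply(sets, stop_if_not_granges)
  sets
}

feature_scores <- function(fs) {
  if (!"score" %in% names(mcols(fs))) return(NULL)
  mcols(fs)$score
}

# 0-based midpoint floor((start0 + end0) / 2) of each interval, returned in
# 0-based coordinates (the convention used for bin arithmetic).
feature_center0 <- function(fs) {
  floor((BiocGenerics::start(fs) - 1 + BiocGenerics::end(fs)) / 2)
}

sort_features <- function(fs) {
  BiocGenerics::sort(fs, ignore.strand = TRUE)
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else as.character(v)
  }, character(1))
}
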