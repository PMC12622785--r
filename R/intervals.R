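# Internal: decompose a GRanges into per-chromosome IRanges (plus the
# original element indices), in seqlevels order. The heavy lifting of the
# interval algebra happens on IRanges, which avoids the per-call overhead
# of whole-GRanges set operations; results are reassembled once.
per_chrom <- function(fs) {
  ch <- as.character(seqnames(fs))
  lvls <- intersect(seqlevels(fs), unique(ch))
  lapply(setNames(lvls, lvls), function(l) {
    i <- which(ch == l)
    list(idx = i, ir = IRanges(start = BiocGenerics::start(fs)[i],
                               end = BiocGenerics::end(fs)[i]))
  })
}

# Internal: assemble per-chromosome start/end vectors into a GRanges that
# inherits the seqinfo of `template`. `parts` is a named list of
# list(start=, end=, idx=) where idx (optional) maps rows to elements of
# `template` whose metadata the rows inherit.
assemble_granges <- function(parts, template, keep_mcols = FALSE) {
  ch <- rep(names(parts), vapply(parts, function(p) length(p$start),
                                 integer(1)))
  s <- unlist(lapply(parts, `[[`, "start"), use.names = FALSE)
  e <- unlist(lapply(parts, `[[`, "end"), use.names = FALSE)
  if (is.null(s)) { s <- integer(0); e <- integer(0); ch <- character(0) }
  gr <- GRanges(factor(ch, levels = seqlevels(template)), IRanges(s, e),
                seqinfo = seqinfo(template))
  if (keep_mcols) {
    idx <- unlist(lapply(parts, `[[`, "idx"), use.names = FALSE)
    mcols(gr) <- mcols(template)[idx, , drop = FALSE]
  }
  gr
}

#' Merge intervals separated by less than a gap
#'
#' Closes gaps strictly smaller than `max_gap` and unions overlapping or
#' book-ended intervals (the "regions closer than x bp are merged" rule of
#' ChIP peak post-processing). Scores are dropped: a merged region has no
#' single parent.
#'
#' @param fs a [GenomicRanges::GRanges].
#' @param max_gap non-negative gap in bp; two intervals whose separation is
#'   `< max_gap` are merged. `max_gap = 0` still unions overlapping and
#'   directly adjacent (half-open book-ended) intervals.
#' @return A sorted, score-free [GenomicRanges::GRanges].
#' @examples
#' merge_intervals(features("chrI", c(0, 120), c(100, 200)), max_gap = 350)
#' @export
merge_intervals <- function(fs, max_gap = 0) {
  stop_if_not_granges(fs)
  if (max_gap < 0) stop("`max_gap` must be >= 0")
  gw <- max(as.integer(max_gap), 1L)
  parts <- lapply(per_chrom(fs), function(p) {
    r <- IRanges::reduce(p$ir, min.gapwidth = gw)
    list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
  })
  assemble_granges(parts, fs)
}

#' Select intervals of `a` overlapping `b`
#'
#' Selection-mode intersection: returns the intervals of `a` (with their
#' coordinates and scores untouched) that share at least `min_overlap` bp
#' with a single interval of `b`.
#'
#' @param a,b [GenomicRanges::GRanges].
#' @param min_overlap minimum pairwise overlap in bp (>= 1).
#' @return Subset of `a`.
#' @export
intersect_features <- function(a, b, min_overlap = 1) {
  stop_if_not_granges(a); stop_if_not_granges(b)
  if (min_overlap < 1) stop("`min_overlap` must be >= 1")
  a[overlap_indicator(a, per_chrom(b), as.integer(min_overlap))]
}

# Internal: logical vector marking elements of `x` that overlap the
# pre-split reference `ref_parts` (from per_chrom) by >= min_overlap bp.
overlap_indicator <- function(x, ref_parts, min_overlap = 1L) {
  hit <- logical(length(x))
  xp <- per_chrom(x)
  for (ch in names(xp)) {
    rp <- ref_parts[[ch]]
    if (!is.null(rp))
      hit[xp[[ch]]$idx] <- countOverlaps(xp[[ch]]$ir, rp$ir,
                                         minoverlap = min_overlap) > 0
  }
  hit
}

#' Per-base subtraction of one feature set from another
#'
#' Removes from each interval of `a` every base covered by `b`, splitting
#' intervals where necessary. Fragments inherit the metadata (scores) of
#' their parent interval.
#'
#' @param a,b [GenomicRanges::GRanges].
#' @return A sorted [GenomicRanges::GRanges]; may contain more or fewer
#'   intervals than `a`.
#' @export
subtract_features <- function(a, b) {
  stop_if_not_granges(a); stop_if_not_granges(b)
  if (length(b) == 0 || length(a) == 0) return(a)
  bp <- per_chrom(b)
  parts <- lapply(per_chrom(a), function(p) p)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    rp <- bp[[ch]]
    if (is.null(rp))
      return(list(start = BiocGenerics::start(p$ir),
                  end = BiocGenerics::end(p$ir), idx = p$idx))
    # keep = union(a) \ union(b); each parent's fragments are its
    # intersections with keep (every parent is a subset of union(a))
    keep <- IRanges::setdiff(IRanges::reduce(p$ir), IRanges::reduce(rp$ir))
    h <- findOverlaps(p$ir, keep)
    qs <- queryHits(h); ss <- subjectHits(h)
    fs <- pmax(BiocGenerics::start(p$ir)[qs], BiocGenerics::start(keep)[ss])
    fe <- pmin(BiocGenerics::end(p$ir)[qs], BiocGenerics::end(keep)[ss])
    o <- order(fs, fe)
    list(start = fs[o], end = fe[o], idx = p$idx[qs][o])
  })
  names(out) <- names(parts)
  assemble_granges(out, a, keep_mcols = TRUE)
}

#' k-of-n consensus of several feature sets
#'
#' Canonical (`mode = "base"`) consensus returns the maximal regions where
#' at least `k` of the `n` input sets cover a base -- the rule used to
#' define chromosome-axis sites from Red1/Hop1/Rec8 binding maps with
#' `k = 2`. `mode = "site"` instead retains whole intervals (from any set)
#' that overlap intervals of at least `k - 1` other sets, then unions them.
#'
#' @param sets list of [GenomicRanges::GRanges].
#' @param k integer, `1 <= k <= length(sets)`.
#' @param mode `"base"` (per-base coverage vote) or `"site"` (whole-site
#'   retention).
#' @return A sorted [GenomicRanges::GRanges].
#' @examples
#' A <- features("chrI", 0, 100); B <- features("chrI", 50, 150)
#' C <- features("chrI", 200, 300)
#' consensus_features(list(A, B, C), k = 2)
#' @export
consensus_features <- function(sets, k, mode = c("base", "site")) {
  mode <- match.arg(mode)
  sets <- as_granges_list(sets)
  n <- length(sets)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= length(sets)")
  if (mode == "base") {
    # after a per-set reduce, pooled coverage counts covering sets per base
    split_sets <- lapply(sets, per_chrom)
    lvls <- unique(unlist(lapply(sets, function(s)
      intersect(seqlevels(s), as.character(unique(seqnames(s)))))))
    parts <- lapply(setNames(lvls, lvls), function(ch) {
      irs <- lapply(split_sets, function(ss)
        if (is.null(ss[[ch]])) IRanges() else IRanges::reduce(ss[[ch]]$ir))
      cov <- IRanges::coverage(do.call(c, irs))
      r <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
      list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
    })
    template <- GRanges(factor(character(0), levels = lvls), IRanges())
    return(assemble_granges(parts, template))
  }
  keep <- lapply(seq_len(n), function(i) {
    others <- sets[-i]
    votes <- Reduce(`+`, lapply(others, function(o)
      as.integer(countOverlaps(sets[[i]], o, ignore.strand = TRUE) > 0)))
    if (is.null(votes)) votes <- rep(0L, length(sets[[i]]))
    sets[[i]][votes >= k - 1]
  })
  sort_features(GenomicRanges::reduce(
    do.call(c, lapply(keep, function(g) { mcols(g) <- NULL; g }))))
}

#' Pairwise overlap table between feature sets
#'
#' For every ordered pair of sets, the count and percentage of intervals of
#' the column set overlapping the row set by at least `min_overlap` bp,
#' plus an "alone" row (intervals overlapping none of the other sets) and
#' Venn-style exclusive combination counts per set.
#'
#' @param sets named list of [GenomicRanges::GRanges] (>= 2 sets).
#' @param min_overlap minimum overlap in bp.
#' @return An object of class `overlap_table`: list with `counts` and
#'   `percent` matrices (rows = reference set, columns = query set,
#'   diagonal `NA`), `alone` counts/percentages, `n` set sizes, and
#'   `exclusive` (per-set table of which other-set combinations each
#'   interval overlaps).
#' @export
overlap_table <- function(sets, min_overlap = 1) {
  sets <- as_granges_list(sets)
  if (length(sets) < 2) stop("need at least two feature sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  nm <- names(sets)
  nsz <- vapply(sets, length, integer(1))
  if (any(nsz == 0)) stop("feature sets must be non-empty")
  cnt <- matrix(NA_real_, length(sets), length(sets), dimnames = list(nm, nm))
  for (r in seq_along(sets)) for (q in seq_along(sets)) {
    if (r == q) next
    cnt[r, q] <- sum(countOverlaps(sets[[q]], sets[[r]],
                                   minoverlap = as.integer(min_overlap),
                                   ignore.strand = TRUE) > 0)
  }
  pct <- sweep(cnt, 2, nsz, function(x, n) 100 * x / n)
  memb <- lapply(seq_along(sets), function(q) {
    hits <- vapply(seq_along(sets)[-q], function(r)
      countOverlaps(sets[[q]], sets[[r]], minoverlap = as.integer(min_overlap),
                    ignore.strand = TRUE) > 0,
      logical(length(sets[[q]])))
    hits <- matrix(hits, nrow = length(sets[[q]]),
                   dimnames = list(NULL, nm[-q]))
    hits
  })
  names(memb) <- nm
  alone_cnt <- vapply(memb, function(m) sum(rowSums(m) == 0), numeric(1))
  exclusive <- lapply(memb, function(m) {
    key <- apply(m, 1, function(r)
      if (!any(r)) "alone" else paste(colnames(m)[r], collapse = "+"))
    table(key)
  })
  structure(list(counts = cnt, percent = pct,
                 alone = alone_cnt, alone_percent = 100 * alone_cnt / nsz,
                 n = nsz, exclusive = exclusive,
                 min_overlap = min_overlap),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("Overlap table (min overlap", x$min_overlap, "bp)\n")
  cat("Percent of column-set intervals overlapping the row set:\n")
  print(round(rbind(x$percent, alone = x$alone_percent), 1))
  invisible(x)
}
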