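narrowpeak_extra_cols <- c(signalValue = "numeric", pValue = "numeric",
                           qValue = "numeric", peak = "integer")

#' Read genomic features from BED or ENCODE narrowPeak
#'
#' Files use BED conventions (0-based half-open, tab-separated). For BED6
#' the analysis score is column 5; for narrowPeak it is column 7
#' (`signalValue`) by default, while the BED score (column 5) is retained
#' as `bed_score` so that writing round-trips losslessly.
#'
#' @param path input file.
#' @param format `"bed"` or `"narrowPeak"`; `"auto"` guesses from the file
#'   extension (`.narrowPeak` vs anything else).
#' @param genome optional [GenomeInfoDb::Seqinfo]; when supplied, intervals
#'   on unknown chromosomes or exceeding a chromosome length are rejected.
#' @param score_col for narrowPeak, which column feeds the `score` used by
#'   downstream analyses (`"signalValue"`, `"pValue"` or `"qValue"`).
#' @return A sorted [GenomicRanges::GRanges]; `score` metadata when present.
#' @export
read_features <- function(path, format = c("auto", "bed", "narrowPeak"),
                          genome = NULL, score_col = "signalValue") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  check_feature_lines(path, min_fields = if (format == "narrowPeak") 10L else 3L)
  gr <- if (format == "narrowPeak") {
    g <- rtracklayer::import(path, format = "BED",
                             extraCols = narrowpeak_extra_cols)
    names(mcols(g))[names(mcols(g)) == "score"] <- "bed_score"
    mcols(g)$score <- mcols(g)[[score_col]]
    g
  } else {
    rtracklayer::import(path, format = "BED")
  }
  BiocGenerics::strand(gr) <- "*"
  gr <- apply_genome(gr, genome)
  sort_features(gr)
}

# Cheap structural scan so malformed lines are reported by number, which
# rtracklayer does not do reliably.
check_feature_lines <- function(path, min_fields) {
  n <- utils::count.fields(path, sep = "\t", comment.char = "#",
                           quote = "", blank.lines.skip = FALSE)
  bad <- which(n < min_fields & n > 0L)
  blank <- which(n == 0L)
  bad <- setdiff(bad, blank)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, got %d",
                 bad[1], path, min_fields, n[bad[1]]))
  invisible(TRUE)
}

#' Write genomic features as BED or narrowPeak
#'
#' BED output is BED3 when no metadata is present and BED6 (`name`,
#' `score`, `strand`) otherwise. narrowPeak output emits the standard 10
#' columns, reconstructing `bed_score` and using `-1` sentinels for absent
#' summit offsets.
#'
#' @param fs a [GenomicRanges::GRanges].
#' @param path output file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  stop_if_not_granges(fs)
  chrom <- as.character(seqnames(fs))
  s0 <- BiocGenerics::start(fs) - 1L
  e0 <- BiocGenerics::end(fs)
  mc <- mcols(fs)
  get_col <- function(nm, default) {
    if (nm %in% names(mc) && !all(is.na(mc[[nm]]))) mc[[nm]] else
      rep(default, length(fs))
  }
  if (format == "bed") {
    if (ncol(mc) == 0) {
      lines <- paste(chrom, s0, e0, sep = "\t")
    } else {
      nm <- get_col("name", ".")
      nm[is.na(nm)] <- "."
      sc <- fmt_num(get_col("score", 0))
      lines <- paste(chrom, s0, e0, nm, sc, ".", sep = "\t")
    }
  } else {
    nm <- get_col("name", ".")
    nm[is.na(nm)] <- "."
    bs <- fmt_num(get_col("bed_score", 0))
    sv <- fmt_num(get_col("signalValue", get_col("score", 0)))
    pv <- fmt_num(get_col("pValue", -1))
    qv <- fmt_num(get_col("qValue", -1))
    pk <- fmt_num(get_col("peak", -1))
    lines <- paste(chrom, s0, e0, nm, bs, ".", sv, pv, qv, pk, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a feature set from 0-based half-open coordinates
#'
#' Convenience constructor mirroring the on-disk BED convention, mostly
#' used in examples, tests and the simulator.
#'
#' @param chrom chromosome name(s), recycled.
#' @param start0,end0 0-based half-open coordinates (`start0 < end0`).
#' @param score optional numeric score per interval.
#' @param genome optional [GenomeInfoDb::Seqinfo] to validate/attach.
#' @return A sorted [GenomicRanges::GRanges].
#' @examples
#' features("chrI", c(0, 120), c(100, 200))
#' @export
features <- function(chrom, start0, end0, score = NULL, genome = NULL) {
  if (any(start0 < 0) || any(end0 <= start0))
    stop("require 0 <= start0 < end0")
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0))
  if (!is.null(score)) mcols(gr)$score <- score
  gr <- apply_genome(gr, genome)
  sort_features(gr)
}
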