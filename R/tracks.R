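#' Fixed-bin numeric signal over a genome
#'
#' A `binned_track` stores one numeric vector per chromosome, each of
#' length `ceiling(chrom_length / bin_size)`. Values are raw counts,
#' RPKM, or any derived signal; `NA` marks missing data (distinct from 0).
#'
#' @param values named list of numeric vectors, one per chromosome of
#'   `genome`, or a single number recycled.
#' @param genome [GenomeInfoDb::Seqinfo].
#' @param bin_size bin width in bp.
#' @param units free-text unit label (e.g. `"counts"`, `"RPKM"`).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, genome, bin_size, units = "counts") {
  if (!methods::is(genome, "Seqinfo")) stop("`genome` must be a Seqinfo")
  bin_size <- as.integer(bin_size)
  if (bin_size < 1) stop("`bin_size` must be >= 1")
  nb <- ceiling(seqlengths(genome) / bin_size)
  chroms <- seqnames(genome)
  if (is.numeric(values) && length(values) == 1)
    values <- lapply(nb, function(n) rep(as.numeric(values), n))
  if (!is.list(values) || !all(chroms %in% names(values)))
    stop("`values` must be a named list covering every chromosome")
  values <- values[chroms]
  for (ch in chroms) {
    if (length(values[[ch]]) != nb[[ch]])
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, nb[[ch]], length(values[[ch]])))
    values[[ch]] <- as.numeric(values[[ch]])
  }
  structure(list(values = values, genome = genome,
                 bin_size = bin_size, units = units),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  tot <- sum(vapply(x$values, function(v) sum(v, na.rm = TRUE), numeric(1)))
  cat(sprintf("binned_track: %d chromosomes, %d-bp bins, units '%s', total %.4g\n",
              length(x$values), x$bin_size, x$units, tot))
  invisible(x)
}

stop_if_not_track <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "binned_track"))
    stop(sprintf("`%s` must be a binned_track", arg), call. = FALSE)
  invisible(x)
}

check_same_binning <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(seqnames(a$genome), seqnames(b$genome)) ||
      !identical(seqlengths(a$genome), seqlengths(b$genome)))
    stop("tracks must share genome layout and bin size")
  invisible(TRUE)
}

#' Read a bedGraph coverage file onto fixed bins
#'
#' Rasterizes a 4-column UCSC bedGraph onto `bin_size` bins using
#' length-weighted means; bases not covered by any record read as 0
#' (coverage semantics). Overlapping records or unknown chromosomes are
#' errors.
#'
#' @param path bedGraph file.
#' @param genome [GenomeInfoDb::Seqinfo].
#' @param bin_size bin width in bp.
#' @param units unit label stored on the track.
#' @return A [binned_track()].
#' @export
read_track <- function(path, genome, bin_size, units = "counts") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  BiocGenerics::strand(gr) <- "*"
  check_features_in_genome(gr, genome)
  if (length(gr) > 1) {
    self <- findOverlaps(gr, ignore.strand = TRUE, drop.self = TRUE)
    if (length(self) > 0) {
      i <- queryHits(self)[1]
      stop(sprintf("overlapping bedGraph records near %s:%d",
                   as.character(seqnames(gr))[i],
                   BiocGenerics::start(gr)[i] - 1L))
    }
  }
  GenomeInfoDb::seqlevels(gr) <- seqnames(genome)
  suppressWarnings(seqinfo(gr) <- genome)
  cov <- GenomicRanges::coverage(gr, weight = mcols(gr)$score)
  vals <- lapply(seqnames(genome), function(ch) {
    L <- seqlengths(genome)[[ch]]
    starts <- seq(1L, L, by = bin_size)
    ends <- pmin(starts + bin_size - 1L, L)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov[[ch]],
                                                 start = starts, end = ends)))
  })
  names(vals) <- seqnames(genome)
  binned_track(vals, genome, bin_size, units = units)
}

#' Write a binned track as run-length-compressed bedGraph
#'
#' Consecutive bins with identical values are collapsed into one record;
#' `NA` bins are omitted.
#'
#' @param track a [binned_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stop_if_not_track(track)
  bs <- track$bin_size
  lines <- unlist(lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    L <- seqlengths(track$genome)[[ch]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    keep <- !is.na(r$values)
    if (!any(keep)) return(character(0))
    s0 <- (starts_bin[keep] - 1L) * bs
    e0 <- pmin(ends_bin[keep] * bs, L)
    paste(ch, s0, e0, fmt_num(r$values[keep]), sep = "\t")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' RPKM normalization of a counts track
#'
#' `value * 1e9 / (library_size * bin_size)` -- reads per kilobase of bin
#' per million mapped reads.
#'
#' @param track a [binned_track()] of raw counts.
#' @param library_size total mapped reads (> 0).
#' @return A [binned_track()] with units `"RPKM"`.
#' @export
normalize_rpkm <- function(track, library_size) {
  stop_if_not_track(track)
  if (!is.numeric(library_size) || library_size <= 0)
    stop("`library_size` must be > 0")
  f <- 1e9 / (library_size * track$bin_size)
  track$values <- lapply(track$values, function(v) v * f)
  track$units <- "RPKM"
  track
}

#' Background correction and replicate averaging
#'
#' Subtracts each control track (untagged / input, then t = 0 h signal)
#' from every replicate, then averages the corrected replicates
#' element-wise.
#'
#' @param replicates a [binned_track()] or list of replicate tracks.
#' @param controls list of control tracks subtracted from each replicate
#'   (may be empty).
#' @param floor_at_zero clip negative corrected values to 0 (default off).
#' @return A [binned_track()].
#' @export
background_correct <- function(replicates, controls = list(),
                               floor_at_zero = FALSE) {
  if (inherits(replicates, "binned_track")) replicates <- list(replicates)
  if (inherits(controls, "binned_track")) controls <- list(controls)
  if (length(replicates) == 0) stop("need at least one replicate track")
  lapply(replicates, stop_if_not_track)
  lapply(controls, stop_if_not_track)
  ref <- replicates[[1]]
  for (t in c(replicates[-1], controls)) check_same_binning(ref, t)
  corrected <- lapply(replicates, function(rep) {
    out <- rep$values
    for (ctl in controls)
      out <- Map(`-`, out, ctl$values)
    if (floor_at_zero) out <- lapply(out, pmax, 0)
    out
  })
  avg <- corrected[[1]]
  if (length(corrected) > 1) {
    for (i in 2:length(corrected)) avg <- Map(`+`, avg, corrected[[i]])
    avg <- lapply(avg, `/`, length(corrected))
  }
  out <- ref
  out$values <- avg
  out$units <- paste0(ref$units, " (background-corrected)")
  out
}

#' Normalized Hann smoothing kernel
#'
#' `w_j = 0.5 * (1 - cos(2 * pi * j / (M - 1)))`, `j = 0..M-1`, scaled to
#' sum to 1. `M = 1` returns the identity kernel.
#'
#' @param m odd kernel length in bins.
#' @return Numeric vector of length `m` summing to 1.
#' @export
hann_kernel <- function(m) {
  m <- as.integer(m)
  if (m < 1 || m %% 2 == 0) stop("`m` must be a positive odd integer")
  if (m == 1) return(1)
  j <- 0:(m - 1)
  w <- 0.5 * (1 - cos(2 * pi * j / (m - 1)))
  w / sum(w)
}

#' Hann-window smoothing of a binned track
#'
#' Convolution with the normalized Hann kernel of width `window` bp
#' (rounded to the nearest odd number of bins). At chromosome edges the
#' kernel is truncated and renormalized; `NA` bins are excluded from the
#' local weighting and remain `NA` in the output.
#'
#' @param track a [binned_track()].
#' @param window smoothing window in bp (>= `bin_size`).
#' @return A smoothed [binned_track()].
#' @export
hann_smooth <- function(track, window) {
  stop_if_not_track(track)
  if (window < track$bin_size) stop("`window` must be >= bin_size")
  m_raw <- window / track$bin_size
  m <- 2L * as.integer(round((m_raw - 1) / 2)) + 1L
  w <- hann_kernel(m)
  h <- (m - 1L) %/% 2L
  smooth_one <- function(v) {
    if (m == 1) return(v)
    n <- length(v)
    ok <- !is.na(v)
    x0 <- ifelse(ok, v, 0)
    pad <- rep(0, h)
    num <- stats::filter(c(pad, x0, pad), w, sides = 2)[(h + 1):(h + n)]
    den <- stats::filter(c(pad, as.numeric(ok), pad), w, sides = 2)[(h + 1):(h + n)]
    out <- as.numeric(num) / as.numeric(den)
    out[!ok | den == 0] <- NA_real_
    out
  }
  track$values <- lapply(track$values, smooth_one)
  track
}
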