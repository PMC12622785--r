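# Window/profile numerics. All use the same primitive: the integral
# C(x) = \int_0^x v(u) du of the step function of bin values, which gives
# exact length-weighted means over arbitrary [s, e) windows in O(1).

# Per-chromosome evaluator. Returns a function(s, e) -> list(mean, sum,
# has_na) vectorized over 0-based half-open windows clipped by the caller.
make_window_eval <- function(v, bin_size, chrom_len) {
  nb <- length(v)
  v0 <- ifelse(is.na(v), 0, v)
  cumVb <- c(0, cumsum(v0)) * bin_size        # value*bp up to bin boundary
  cumNA <- c(0L, cumsum(is.na(v)))
  Cfun <- function(x) {                        # x in [0, chrom_len]
    f <- pmin(floor(x / bin_size), nb - 1)
    part <- x - f * bin_size
    cumVb[f + 1] + part * v0[f + 1]
  }
  function(s, e) {
    integ <- Cfun(e) - Cfun(s)
    first_bin <- floor(s / bin_size)
    last_bin <- pmin(floor((e - 1) / bin_size), nb - 1)
    has_na <- (cumNA[last_bin + 2] - cumNA[first_bin + 1]) > 0
    list(mean = ifelse(has_na, NA_real_, integ / (e - s)),
         sum = ifelse(has_na, NA_real_, integ / bin_size),
         has_na = has_na)
  }
}

# Shared row extractor: matrix with one row per feature and one column per
# offset bin; out-of-chromosome bins are NA.
profile_rows <- function(track, centers, flank, bin) {
  stop_if_not_track(track)
  stop_if_not_granges(centers)
  if (length(centers) == 0) stop("`centers` must be non-empty")
  if (flank %% bin != 0) stop("`flank` must be a multiple of `bin`")
  if (bin %% track$bin_size != 0)
    stop("profile `bin` must be a multiple of the track bin size")
  nbin <- as.integer(2 * flank / bin)
  mat <- matrix(NA_real_, nrow = length(centers), ncol = nbin)
  cen <- feature_center0(centers)
  chroms <- as.character(seqnames(centers))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    L <- seqlengths(track$genome)[[ch]]
    ev <- make_window_eval(track$values[[ch]], track$bin_size, L)
    s <- outer(cen[idx] - flank, (0:(nbin - 1)) * bin, `+`)
    e <- s + bin
    valid <- s >= 0 & e <= L
    res <- rep(NA_real_, length(s))
    if (any(valid))
      res[valid] <- ev(s[valid], e[valid])$mean
    mat[idx, ] <- matrix(res, nrow = length(idx))
  }
  offsets <- -flank + (0:(nbin - 1) + 0.5) * bin
  list(mat = mat, offsets = offsets)
}

#' Average signal profile around feature midpoints (pile-up)
#'
#' Samples the track in fixed offset bins around each feature midpoint
#' (`floor((start + end) / 2)`) and averages across features. Offset bins
#' falling outside a chromosome are excluded from that offset's mean
#' rather than zero-filled.
#'
#' @param track a [binned_track()].
#' @param centers features whose midpoints anchor the profile.
#' @param flank half-width of the profile in bp (multiple of `bin`).
#' @param bin profile bin width in bp (multiple of the track bin size).
#' @return A data.frame of class `pileup_profile` with columns `offset`
#'   (bp, bin centers, symmetric about 0), `mean`, and `n_features`
#'   contributing to each offset.
#' @export
pileup_profile <- function(track, centers, flank = 5000, bin = 20) {
  pr <- profile_rows(track, centers, flank, bin)
  n <- colSums(!is.na(pr$mat))
  m <- ifelse(n > 0, colMeans(pr$mat, na.rm = TRUE), NA_real_)
  out <- data.frame(offset = pr$offsets, mean = m, n_features = n)
  class(out) <- c("pileup_profile", "data.frame")
  out
}

#' Per-feature signal matrix around feature midpoints (heatmap rows)
#'
#' Same bins as [pileup_profile()] but one row per feature, rows ordered
#' by a per-feature score (e.g. DSB strength), ties broken by genomic
#' order. Column means reproduce the pile-up wherever the same features
#' contribute.
#'
#' @param track a [binned_track()].
#' @param centers features carrying the ordering score.
#' @param order_by name of the metadata column to order rows by.
#' @param descending strongest feature first (default `TRUE`).
#' @param flank,bin as in [pileup_profile()].
#' @return A numeric matrix with `length(centers)` rows; column names are
#'   bp offsets, row names the feature order index; attribute `"centers"`
#'   holds the reordered features.
#' @export
profile_matrix <- function(track, centers, order_by = "score",
                           descending = TRUE, flank = 5000, bin = 20) {
  stop_if_not_granges(centers)
  if (!order_by %in% names(mcols(centers)))
    stop("`centers` lacks the ordering score column '", order_by, "'")
  sc <- mcols(centers)[[order_by]]
  if (anyNA(sc)) stop("ordering score contains NA")
  key <- if (descending) -rank(sc, ties.method = "first") else
    rank(sc, ties.method = "first")
  ord <- order(key)
  centers <- centers[ord]
  pr <- profile_rows(track, centers, flank, bin)
  mat <- pr$mat
  dimnames(mat) <- list(seq_len(nrow(mat)), pr$offsets)
  attr(mat, "centers") <- centers
  mat
}

#' Fixed-width window signal per feature
#'
#' Centers a window of `width` bp on each feature midpoint and returns the
#' chosen statistic; optionally drops windows overlapping an exclusion set
#' (e.g. axis regions) by at least a fraction of the window width.
#'
#' @param track a [binned_track()].
#' @param fs features ([GenomicRanges::GRanges]).
#' @param width window width in bp.
#' @param stat `"mean_bin_value"` (length-weighted mean of bin values) or
#'   `"summed_count"` (sum of bin values pro-rated by covered fraction).
#' @param exclude optional [GenomicRanges::GRanges]; windows whose overlap
#'   with it is `>= max_fraction * width` are flagged excluded (value NA).
#' @param max_fraction exclusion threshold as a fraction of `width`
#'   (default 0.10; windows overlapping less are kept).
#' @return A data.frame with columns `chrom`, `center` (0-based bp),
#'   `value`, `excluded`.
#' @export
window_signal <- function(track, fs, width,
                          stat = c("mean_bin_value", "summed_count"),
                          exclude = NULL, max_fraction = 0.10) {
  stat <- match.arg(stat)
  stop_if_not_track(track)
  stop_if_not_granges(fs)
  if (width <= 0) stop("`width` must be > 0")
  cen <- feature_center0(fs)
  chroms <- as.character(seqnames(fs))
  s <- cen - floor(width / 2)
  e <- s + width
  value <- rep(NA_real_, length(fs))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    L <- seqlengths(track$genome)[[ch]]
    ev <- make_window_eval(track$values[[ch]], track$bin_size, L)
    sc <- pmax(s[idx], 0)
    ec <- pmin(e[idx], L)
    ok <- ec > sc
    r <- ev(sc[ok], ec[ok])
    v <- if (stat == "mean_bin_value") r$mean else r$sum
    value[idx[ok]] <- v
  }
  excluded <- rep(FALSE, length(fs))
  if (!is.null(exclude) && length(exclude) > 0) {
    win <- GRanges(chroms, IRanges(start = pmax(s, 0) + 1, end = pmax(e, 1)))
    hit <- findOverlaps(win, GenomicRanges::reduce(exclude),
                        ignore.strand = TRUE)
    if (length(hit) > 0) {
      ov <- BiocGenerics::width(pintersect(win[queryHits(hit)],
                                           GenomicRanges::reduce(exclude)[subjectHits(hit)]))
      tot <- tapply(ov, queryHits(hit), sum)
      ids <- as.integer(names(tot))
      excluded[ids] <- as.numeric(tot) >= max_fraction * width
    }
    value[excluded] <- NA_real_
  }
  data.frame(chrom = chroms, center = cen, value = value, excluded = excluded)
}

#' Rank-based equal-count percentile partition
#'
#' Assigns each score a percentile-bin index `0 .. n_bins - 1`; index
#' `n_bins - 1` holds the strongest scores, ties resolved by stable rank
#' (first occurrence wins the lower bin), and bin populations differ by at
#' most one. With `n_bins = 10`, the "top 20% strongest" are indices 8-9.
#'
#' @param scores numeric vector (no NA).
#' @param n_bins number of equal-count bins (>= 2, <= `length(scores)`).
#' @return Integer vector of bin indices in `0:(n_bins - 1)`.
#' @export
partition_by_percentile <- function(scores, n_bins = 10) {
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (anyNA(scores)) stop("`scores` must not contain NA")
  n <- length(scores)
  if (n < n_bins) stop("fewer scores than bins")
  r <- rank(scores, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n))
}

#' Genome-wide window correlation between two tracks
#'
#' Averages both tracks in non-overlapping windows of `window` bp and
#' reports Pearson r, Spearman rho, and the coefficient of determination
#' of the simple least-squares fit (`R^2 = r^2`). Windows missing (NA) in
#' either track are excluded.
#'
#' @param a,b [binned_track()]s on the same genome.
#' @param window window width in bp (multiple of both bin sizes).
#' @return List with `pearson`, `spearman`, `r_squared`, `n_windows`.
#' @export
window_correlation <- function(a, b, window = 100) {
  stop_if_not_track(a); stop_if_not_track(b)
  if (!identical(seqlengths(a$genome), seqlengths(b$genome)))
    stop("tracks must share a genome layout")
  if (window %% a$bin_size != 0 || window %% b$bin_size != 0)
    stop("`window` must be a multiple of both track bin sizes")
  wmeans <- function(tr) {
    unlist(lapply(seqnames(tr$genome), function(ch) {
      L <- seqlengths(tr$genome)[[ch]]
      ev <- make_window_eval(tr$values[[ch]], tr$bin_size, L)
      s <- seq(0, L - 1, by = window)
      e <- pmin(s + window, L)
      ev(s, e)$mean
    }), use.names = FALSE)
  }
  va <- wmeans(a); vb <- wmeans(b)
  ok <- complete.cases(va, vb)
  if (sum(ok) < 3) stop("fewer than 3 windows shared by both tracks")
  r <- stats::cor(va[ok], vb[ok], method = "pearson")
  rho <- stats::cor(va[ok], vb[ok], method = "spearman")
  list(pearson = r, spearman = rho, r_squared = r^2, n_windows = sum(ok))
}
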