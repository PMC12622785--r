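#' Build a hyper-ChIPable blacklist from negative-control peak sets
#'
#' Unions the peak calls of untagged / pre-meiotic negative controls into a
#' merged set of regions excluded from all downstream peak lists.
#'
#' @param controls list of [GenomicRanges::GRanges] control peak sets
#'   (at least one, possibly empty elements).
#' @return A merged, sorted [GenomicRanges::GRanges].
#' @export
build_blacklist <- function(controls) {
  controls <- as_granges_list(controls, "controls")
  pooled <- do.call(c, lapply(controls, function(g) { mcols(g) <- NULL; g }))
  merge_intervals(pooled, max_gap = 0)
}

#' Reduce overlapping peaks to the smallest member per overlap component
#'
#' Pools peaks from several call sets (replicates and/or p-value cutoffs),
#' groups them into overlap-connected components (>= 1 bp shared), and
#' keeps only the shortest interval of each component; ties break to the
#' leftmost interval, then to input order. Non-overlapping peaks pass
#' through untouched, with their metadata.
#'
#' @param peaksets list of [GenomicRanges::GRanges].
#' @return A sorted [GenomicRanges::GRanges] with one interval per
#'   component.
#' @export
minimal_region_reduce <- function(peaksets) {
  peaksets <- as_granges_list(peaksets, "peaksets")
  common <- Reduce(intersect, lapply(peaksets, function(g) names(mcols(g))))
  pooled <- do.call(c, lapply(seq_along(peaksets), function(i) {
    g <- peaksets[[i]]
    mcols(g) <- mcols(g)[, common, drop = FALSE]
    mcols(g)$.set <- rep(i, length(g))
    mcols(g)$.idx <- seq_along(g)
    g
  }))
  if (length(pooled) == 0) return(pooled)
  # components: merge only truly overlapping peaks (book-ended stay apart)
  comp <- GenomicRanges::reduce(pooled, min.gapwidth = 0L, ignore.strand = TRUE)
  hit <- findOverlaps(pooled, comp, ignore.strand = TRUE)
  comp_id <- subjectHits(hit)[order(queryHits(hit))]
  ord <- order(comp_id, BiocGenerics::width(pooled),
               BiocGenerics::start(pooled),
               mcols(pooled)$.set, mcols(pooled)$.idx)
  keep <- ord[!duplicated(comp_id[ord])]
  out <- pooled[sort(keep)]
  mcols(out)$.set <- NULL
  mcols(out)$.idx <- NULL
  sort_features(out)
}

#' Consolidate multi-cutoff ChIP-seq peak calls into a final peak set
#'
#' The peak post-processing cascade for noisy meiotic ChIP-seq: peaks
#' called per replicate at several p-value cutoffs are reduced to the
#' smallest region of each overlap component, nearby regions are merged,
#' peaks overlapping the pre-meiotic (t = 0 h) peak list are removed
#' wholesale, hyper-ChIPable blacklist bases are trimmed away, and only
#' fragments strictly longer than `min_len` survive.
#'
#' @param peaksets list of [GenomicRanges::GRanges], one per
#'   replicate-by-cutoff peak call (order free).
#' @param t0_peaks peaks called at t = 0 h ("hyper-ChIPable" at the peak
#'   level); any consolidated peak overlapping one is dropped entirely.
#' @param blacklist merged hyper-ChIPable regions (see
#'   [build_blacklist()]); overlapping bases are trimmed from peak
#'   coordinates.
#' @param merge_gap regions closer than this are merged (bp).
#' @param min_len only fragments with length `> min_len` bp are retained
#'   (strict inequality).
#' @param merge_before_t0 apply the gap merge before the t0 removal
#'   (default, following the order the processing is described in);
#'   `FALSE` swaps the two stages.
#' @return A sorted [GenomicRanges::GRanges]; attribute `"stages"` holds a
#'   data.frame of interval counts surviving each stage.
#' @export
consolidate_peaks <- function(peaksets, t0_peaks = NULL, blacklist = NULL,
                              merge_gap = 350, min_len = 200,
                              merge_before_t0 = TRUE) {
  peaksets <- as_granges_list(peaksets, "peaksets")
  stages <- list()
  note <- function(x, nm) { stages[[nm]] <<- length(x); x }

  x <- note(minimal_region_reduce(peaksets), "minimal_region")
  do_merge <- function(x) note(merge_intervals(x, max_gap = merge_gap), "gap_merge")
  do_t0 <- function(x) {
    if (is.null(t0_peaks) || length(t0_peaks) == 0) return(note(x, "t0_removal"))
    note(x[countOverlaps(x, t0_peaks, ignore.strand = TRUE) == 0], "t0_removal")
  }
  if (merge_before_t0) { x <- do_merge(x); x <- do_t0(x) }
  else { x <- do_t0(x); x <- do_merge(x) }
  if (!is.null(blacklist) && length(blacklist) > 0)
    x <- subtract_features(x, blacklist)
  x <- note(x, "blacklist_trim")
  x <- note(x[BiocGenerics::width(x) > min_len], "length_filter")
  out <- sort_features(x)
  attr(out, "stages") <- data.frame(stage = names(stages),
                                    n = unlist(stages, use.names = FALSE))
  out
}
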