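#' Randomly relocate features, conserving their length distribution
#'
#' Places every interval at a uniformly random position, by rejection
#' sampling, with the constraints used for permutation nulls of peak
#' overlap: placed intervals may not overlap a `forbidden` set nor each
#' other, and with `per_chromosome = TRUE` each interval stays on its
#' chromosome (the `shuffleBed -chrom -noOverlapping` behaviour).
#'
#' @param fs intervals to relocate ([GenomicRanges::GRanges]).
#' @param genome [GenomeInfoDb::Seqinfo] giving chromosome lengths.
#' @param forbidden optional [GenomicRanges::GRanges] the output must avoid.
#' @param per_chromosome keep each interval on its original chromosome
#'   (default `TRUE`); otherwise chromosomes are drawn with probability
#'   proportional to the feasible placement space.
#' @param seed optional integer; identical seeds give identical output.
#'   The caller's RNG stream is left untouched when a seed is given.
#' @param max_attempts rejection-sampling attempts per interval before
#'   aborting with an error naming the chromosome.
#' @return A sorted [GenomicRanges::GRanges] with the same number of
#'   intervals and the same multiset of lengths as `fs` (scores dropped).
#' @export
shuffle_features <- function(fs, genome, forbidden = NULL,
                             per_chromosome = TRUE, seed = NULL,
                             max_attempts = 10000) {
  stop_if_not_granges(fs)
  if (!methods::is(genome, "Seqinfo")) stop("`genome` must be a Seqinfo")
  check_features_in_genome(fs, genome)
  if (!is.null(forbidden)) {
    stop_if_not_granges(forbidden)
    forbidden <- GenomicRanges::reduce(forbidden)
  }
  lens <- seqlengths(genome)
  # forbidden intervals as per-chromosome start/end vectors (1-based closed)
  fb <- lapply(seqnames(genome), function(ch) {
    if (is.null(forbidden)) return(list(s = numeric(0), e = numeric(0)))
    f <- forbidden[as.character(seqnames(forbidden)) == ch]
    list(s = BiocGenerics::start(f), e = BiocGenerics::end(f))
  })
  names(fb) <- seqnames(genome)

  with_seed(seed, {
    widths <- BiocGenerics::width(fs)
    chrom_of <- as.character(seqnames(fs))
    ord <- order(-widths)                 # place long intervals first
    placed <- fb                           # grows with accepted placements
    out_s <- numeric(length(fs)); out_ch <- character(length(fs))
    for (i in ord) {
      w <- widths[i]
      done <- FALSE
      attempts <- 0L
      while (!done && attempts < max_attempts) {
        k <- min(100L, max_attempts - attempts)
        if (per_chromosome) {
          ch <- rep(chrom_of[i], k)
        } else {
          space <- pmax(lens - w + 1, 0)
          if (sum(space) == 0)
            stop("no chromosome can host an interval of length ", w)
          ch <- sample(names(lens), k, replace = TRUE, prob = space / sum(space))
        }
        hi <- lens[ch] - w + 1
        if (any(hi < 1)) {
          bad <- ch[hi < 1][1]
          stop(sprintf("interval of length %d does not fit on chromosome %s", w, bad))
        }
        s <- floor(runif(k, min = 1, max = hi + 1))    # 1-based start
        e <- s + w - 1
        for (j in seq_len(k)) {
          attempts <- attempts + 1L
          pl <- placed[[ch[j]]]
          if (!any(pl$s <= e[j] & pl$e >= s[j])) {
            placed[[ch[j]]]$s <- c(pl$s, s[j])
            placed[[ch[j]]]$e <- c(pl$e, e[j])
            out_s[i] <- s[j]; out_ch[i] <- ch[j]
            done <- TRUE
            break
          }
        }
      }
      if (!done)
        stop(sprintf("could not place an interval of length %d on chromosome %s after %d attempts",
                     w, chrom_of[i], max_attempts))
    }
    gr <- GRanges(out_ch, IRanges(start = out_s, width = widths))
    suppressWarnings(seqinfo(gr) <- genome)
    sort_features(gr)
  })
}

#' Permutation test of overlap between two feature sets
#'
#' Compares the observed number of `real` intervals overlapping `ref`
#' against `n_shuffles` constrained random relocations of `real` (see
#' [shuffle_features()]). Reports an empirical permutation p-value with the
#' +1 correction, `p = (1 + #\{shuffled count >= real\}) / (n_shuffles + 1)`
#' for enrichment (mirrored for depletion), and a two-sided rank-sum
#' (Wilcoxon/Mann-Whitney) p comparing the per-interval overlap indicators
#' of the real set against the pooled shuffled sets (mid-ranks, normal
#' approximation with continuity correction).
#'
#' @param real,ref [GenomicRanges::GRanges].
#' @param genome [GenomeInfoDb::Seqinfo].
#' @param forbidden regions the shuffled sets must avoid (commonly the
#'   union of the real peak sets under study); `NULL` for unconstrained.
#' @param n_shuffles number of random sets (>= 1; the study design uses 10).
#' @param min_overlap minimum overlap in bp counting as a hit.
#' @param seed optional integer seed; shuffle `i` uses a sub-seed derived
#'   from it, so results are reproducible end to end.
#' @return An object of class `shuffle_result`: list with `real_count`,
#'   `shuffle_counts`, `n_real`, `p_enrichment`, `p_depletion`,
#'   `p_ranksum`, `n_shuffles`.
#' @export
overlap_significance <- function(real, ref, genome, forbidden = NULL,
                                 n_shuffles = 10, min_overlap = 1,
                                 seed = NULL) {
  stop_if_not_granges(real); stop_if_not_granges(ref)
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1")
  ref_parts <- per_chrom(ref)
  hit_ind <- function(x)
    as.integer(overlap_indicator(x, ref_parts, as.integer(min_overlap)))
  real_ind <- hit_ind(real)
  real_count <- sum(real_ind)
  sh_counts <- numeric(n_shuffles)
  sh_ind <- vector("list", n_shuffles)
  for (i in seq_len(n_shuffles)) {
    si <- if (is.null(seed)) NULL else derive_seed(seed, i)
    sh <- shuffle_features(real, genome, forbidden = forbidden, seed = si)
    sh_ind[[i]] <- hit_ind(sh)
    sh_counts[i] <- sum(sh_ind[[i]])
  }
  p_enr <- (1 + sum(sh_counts >= real_count)) / (n_shuffles + 1)
  p_dep <- (1 + sum(sh_counts <= real_count)) / (n_shuffles + 1)
  pooled <- unlist(sh_ind)
  p_rs <- if (length(unique(c(real_ind, pooled))) < 2) 1 else
    suppressWarnings(wilcox.test(real_ind, pooled, exact = FALSE,
                                 correct = TRUE)$p.value)
  structure(list(real_count = real_count, shuffle_counts = sh_counts,
                 n_real = length(real), n_shuffles = n_shuffles,
                 p_enrichment = p_enr, p_depletion = p_dep,
                 p_ranksum = p_rs, min_overlap = min_overlap),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf("Overlap permutation test: %d/%d real intervals overlap the reference\n",
              x$real_count, x$n_real))
  cat(sprintf("  shuffled counts (n = %d): %s\n", x$n_shuffles,
              paste(x$shuffle_counts, collapse = ", ")))
  cat(sprintf("  empirical p: enrichment %.4g, depletion %.4g; rank-sum p %.4g\n",
              x$p_enrichment, x$p_depletion, x$p_ranksum))
  invisible(x)
}
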