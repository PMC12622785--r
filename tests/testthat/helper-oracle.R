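# Independent per-base oracles for interval algebra on a single small
# chromosome. Intervals are data.frames with 0-based half-open columns
# start0/end0; masks are logical vectors over positions 0..L-1.

ORACLE_CHR <- "chrZ"
ORACLE_LEN <- 10000L

df2gr <- function(df, score = NULL)
  features(ORACLE_CHR, df$start0, df$end0, score = score)

gr2df <- function(gr) {
  df <- data.frame(start0 = BiocGenerics::start(gr) - 1L,
                   end0 = BiocGenerics::end(gr))
  df[order(df$start0, df$end0), , drop = FALSE]
}

mask_of <- function(df, L = ORACLE_LEN) {
  m <- logical(L)
  for (i in seq_len(nrow(df))) m[(df$start0[i] + 1):df$end0[i]] <- TRUE
  m
}

mask2df <- function(m) {
  r <- rle(m)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  data.frame(start0 = s[r$values], end0 = e[r$values])
}

oracle_merge <- function(df, max_gap) {
  df <- df[order(df$start0, df$end0), , drop = FALSE]
  thr <- max(max_gap, 1)
  out_s <- df$start0[1]; out_e <- df$end0[1]
  res <- NULL
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start0[i] - out_e < thr) {
      out_e <- max(out_e, df$end0[i])
    } else {
      res <- rbind(res, data.frame(start0 = out_s, end0 = out_e))
      out_s <- df$start0[i]; out_e <- df$end0[i]
    }
  }
  rbind(res, data.frame(start0 = out_s, end0 = out_e))
}

oracle_intersect_select <- function(a, b, min_overlap = 1) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    ov <- pmin(a$end0[i], b$end0) - pmax(a$start0[i], b$start0)
    any(ov >= min_overlap)
  }, logical(1))
  a[keep, , drop = FALSE]
}

oracle_subtract <- function(a, b) {
  bm <- mask_of(b)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    frag <- mask2df(!bm[(a$start0[i] + 1):a$end0[i]])
    if (nrow(frag)) out <- rbind(out, frag + a$start0[i])
  }
  if (is.null(out)) out <- data.frame(start0 = integer(0), end0 = integer(0))
  out[order(out$start0, out$end0), , drop = FALSE]
}

oracle_consensus <- function(dfs, k) {
  votes <- Reduce(`+`, lapply(dfs, function(d) as.integer(mask_of(d))))
  mask2df(votes >= k)
}

# random non-degenerate interval set on the oracle chromosome
random_df <- function(n, max_len = 400) {
  s <- sort(sample.int(ORACLE_LEN - max_len, n))
  w <- sample.int(max_len, n)
  data.frame(start0 = s, end0 = pmin(s + w, ORACLE_LEN))
}

expect_same_intervals <- function(gr, df) {
  expect_equal(gr2df(gr), df, ignore_attr = TRUE)
}
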