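test_that("BED and narrowPeak round-trip through the readers", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t100", "chrI\t150\t300", "chrII\t10\t20"), bed)
  fs <- read_features(bed)
  expect_length(fs, 3)
  expect_equal(BiocGenerics::start(fs)[1] - 1L, 0L)
  out <- tempfile(fileext = ".bed")
  write_features(fs, out)
  expect_identical(readLines(out), readLines(bed))

  np <- tempfile(fileext = ".narrowPeak")
  rec <- paste(paste0("chr", c("I", "I", "I", "II", "II")),
               c(0, 500, 900, 10, 400), c(200, 800, 1200, 300, 900),
               paste0("pk", 1:5), c(10, 20, 30, 40, 50), ".",
               c(7.5, 3.25, 9, 1.5, 2), c(5.3, 4.1, 8, 2, 3),
               c(4.2, 3, 6, 1, 2), c(100, 150, 140, 120, 250),
               sep = "\t")
  writeLines(rec, np)
  peaks <- read_features(np, format = "narrowPeak")
  expect_length(peaks, 5)
  expect_setequal(mcols(peaks)$score, c(7.5, 3.25, 9, 1.5, 2))
  out2 <- tempfile(fileext = ".narrowPeak")
  write_features(peaks, out2, format = "narrowPeak")
  expect_setequal(readLines(out2), rec)
})

test_that("malformed and out-of-genome inputs error informatively", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t100", "chrI\t200"), bad)
  expect_error(read_features(bad), "line 2")
  g <- genome_layout("chrI", 500)
  oob <- tempfile(fileext = ".bed")
  writeLines("chrI\t0\t600", oob)
  expect_error(read_features(oob, genome = g), "exceeds")
  wrongchr <- tempfile(fileext = ".bed")
  writeLines("chrX\t0\t100", wrongchr)
  expect_error(read_features(wrongchr, genome = g), "chrX")
})

test_that("genome layouts read the two-column and faidx dialects", {
  p <- tempfile()
  writeLines(c("chrI\t1000", "chrII\t2000"), p)
  g <- read_genome_layout(p)
  expect_equal(unname(GenomeInfoDb::seqlengths(g)), c(1000, 2000))
  fai <- tempfile()
  writeLines(c("chrI\t1000\t6\t60\t61", "chrII\t2000\t1100\t60\t61"), fai)
  expect_equal(GenomeInfoDb::seqlengths(read_genome_layout(fai)),
               GenomeInfoDb::seqlengths(g))
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_layout("a", 0), "positive")
})

test_that("merge_intervals applies the strict distance rule", {
  fs <- features("chrI", c(0, 120), c(100, 200))
  expect_same_intervals(merge_intervals(fs, 350),
                        data.frame(start0 = 0, end0 = 200))
  expect_same_intervals(merge_intervals(fs, 5),
                        data.frame(start0 = c(0, 120), end0 = c(100, 200)))
  # adjacent half-open intervals are one contiguous base run
  adj <- features("chrI", c(0, 100), c(100, 200))
  expect_same_intervals(merge_intervals(adj, 0),
                        data.frame(start0 = 0, end0 = 200))
})

test_that("intersect_features selects by pairwise overlap", {
  a <- features("chrI", 0, 100)
  expect_length(intersect_features(a, features("chrI", 99, 200)), 1)
  expect_length(intersect_features(a, features("chrI", 100, 200)), 0)
  expect_length(intersect_features(a, features("chrI", 50, 200),
                                   min_overlap = 51), 0)
})

test_that("subtract_features splits intervals and keeps parent scores", {
  a <- features("chrI", 0, 100, score = 7)
  res <- subtract_features(a, features("chrI", 40, 60))
  expect_same_intervals(res, data.frame(start0 = c(0, 60), end0 = c(40, 100)))
  expect_equal(mcols(res)$score, c(7, 7))
  expect_identical(subtract_features(a, GRanges()), a)
  expect_length(subtract_features(a, a), 0)
  expect_identical(intersect_features(a, a), a)
})

test_that("k-of-n consensus votes per base", {
  A <- features("chrI", 0, 100); B <- features("chrI", 50, 150)
  C <- features("chrI", 200, 300)
  expect_same_intervals(consensus_features(list(A, B, C), 2),
                        data.frame(start0 = 50, end0 = 100))
  expect_same_intervals(consensus_features(list(A, B, C), 1),
                        data.frame(start0 = c(0, 200), end0 = c(150, 300)))
  expect_length(consensus_features(list(A, B, C), 3), 0)
  expect_error(consensus_features(list(A, B), 3), "k")
})

test_that("site-level consensus retains whole intervals", {
  A <- features("chrI", 0, 100); B <- features("chrI", 50, 150)
  C <- features("chrI", 200, 300)
  res <- consensus_features(list(A, B, C), 2, mode = "site")
  expect_same_intervals(res, data.frame(start0 = 0, end0 = 150))
})

test_that("interval operations agree with the per-base oracle", {
  set.seed(401)
  for (rep in 1:40) {
    a <- random_df(sample(3:25, 1))
    b <- random_df(sample(3:25, 1))
    gap <- sample(c(0, 5, 50, 350), 1)
    expect_same_intervals(merge_intervals(df2gr(a), gap),
                          oracle_merge(a, gap))
    mo <- sample(c(1, 10, 100), 1)
    expect_same_intervals(intersect_features(df2gr(a), df2gr(b), mo),
                          oracle_intersect_select(a, b, mo))
    expect_same_intervals(subtract_features(df2gr(a), df2gr(b)),
                          oracle_subtract(a, b))
    cc <- random_df(sample(3:25, 1))
    k <- sample(1:3, 1)
    expect_same_intervals(consensus_features(lapply(list(a, b, cc), df2gr), k),
                          oracle_consensus(list(a, b, cc), k))
  }
})

test_that("overlap_table reports counts, percentages and alone fractions", {
  nested <- list(q = features("chrI", 10, 20),
                 r = features("chrI", 0, 100))
  ot <- overlap_table(nested)
  expect_equal(ot$percent["r", "q"], 100)
  expect_equal(unname(ot$alone_percent["q"]), 0)
  disj <- list(q = features("chrI", 10, 20),
               r = features("chrI", 500, 600))
  ot2 <- overlap_table(disj)
  expect_equal(ot2$percent["r", "q"], 0)
  expect_equal(unname(ot2$alone_percent["q"]), 100)

  # brute-force pair enumeration on a random toy
  set.seed(77)
  x <- random_df(20); y <- random_df(15); z <- random_df(10)
  ot3 <- overlap_table(list(x = df2gr(x), y = df2gr(y), z = df2gr(z)))
  brute <- function(q, r) sum(vapply(seq_len(nrow(q)), function(i)
    any(pmin(q$end0[i], r$end0) - pmax(q$start0[i], r$start0) >= 1),
    logical(1)))
  expect_equal(ot3$counts["y", "x"], brute(x, y))
  expect_equal(ot3$counts["z", "x"], brute(x, z))
  expect_equal(ot3$counts["x", "y"], brute(y, x))
  alone_x <- sum(vapply(seq_len(nrow(x)), function(i) {
    !any(pmin(x$end0[i], y$end0) - pmax(x$start0[i], y$start0) >= 1) &&
      !any(pmin(x$end0[i], z$end0) - pmax(x$start0[i], z$start0) >= 1)
  }, logical(1)))
  expect_equal(unname(ot3$alone["x"]), alone_x)
  expect_equal(sum(ot3$exclusive$x), nrow(x))
})

test_that("shuffle_features conserves lengths and respects constraints", {
  g <- genome_layout("chrI", 1000)
  fs <- features("chrI", 0, 100)
  sh <- shuffle_features(fs, g, forbidden = features("chrI", 0, 900), seed = 5)
  expect_equal(BiocGenerics::start(sh) - 1L, 900L)  # only feasible slot
  g2 <- genome_layout(c("chrI", "chrII"), c(10000, 8000))
  fs2 <- features(rep(c("chrI", "chrII"), c(4, 3)),
                  c(0, 500, 2000, 9000, 0, 100, 7000),
                  c(300, 900, 2600, 9500, 50, 1100, 8000))
  sh2 <- shuffle_features(fs2, g2, seed = 11)
  expect_equal(sort(BiocGenerics::width(sh2)), sort(BiocGenerics::width(fs2)))
  expect_equal(table(as.character(seqnames(sh2))),
               table(as.character(seqnames(fs2))))
  expect_true(all(countOverlaps(sh2, sh2) == 1))  # mutually disjoint
  expect_identical(shuffle_features(fs2, g2, seed = 11), sh2)
  expect_error(
    shuffle_features(features("chrI", 0, 500), genome_layout("chrI", 1000),
                     forbidden = features("chrI", 100, 1000),
                     max_attempts = 50),
    "chrI")
})

test_that("unconstrained shuffle starts are uniform", {
  g <- genome_layout("chrI", 10000)
  fs <- features("chrI", 0, 10)
  starts <- vapply(1:300, function(i)
    BiocGenerics::start(shuffle_features(fs, g, seed = 9000 + i)), numeric(1))
  cs <- suppressWarnings(
    stats::chisq.test(table(cut(starts, breaks = seq(0, 10000, by = 1000)))))
  expect_gt(cs$p.value, 0.01)
})

test_that("overlap_significance handles the boundary cases", {
  g <- genome_layout("chrI", 100000)
  real <- features("chrI", c(0, 40000, 80000), c(200, 40200, 80200))
  res <- overlap_significance(real, real, g, forbidden = real,
                              n_shuffles = 10, seed = 3)
  expect_equal(res$real_count, 3)
  expect_equal(res$p_enrichment, 1 / 11)
  empty_res <- overlap_significance(real, GRanges(), g, n_shuffles = 10,
                                    seed = 4)
  expect_equal(empty_res$real_count, 0)
  expect_equal(empty_res$p_depletion, 1)
})
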