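one_chrom <- function(len) genome_layout("chrT", len)

test_that("bedGraph rasterization uses length-weighted means", {
  g <- one_chrom(1000)
  f <- tempfile(fileext = ".bedGraph")
  writeLines("chrT\t0\t1000\t5", f)
  tr <- read_track(f, g, 100)
  expect_equal(tr$values$chrT, rep(5, 10))
  writeLines("chrT\t0\t50\t10", f)
  tr2 <- read_track(f, g, 100)
  expect_equal(tr2$values$chrT[1:2], c(5, 0))  # half-covered bin, rest 0
  writeLines(c("chrT\t0\t100\t1", "chrT\t50\t200\t2"), f)
  expect_error(read_track(f, g, 100), "overlapping")
  writeLines("chrQ\t0\t100\t1", f)
  expect_error(read_track(f, g, 100), "chrQ")
})

test_that("track writing round-trips values", {
  g <- one_chrom(5000)
  set.seed(8)
  vals <- round(stats::runif(50, 0, 20), 3)
  f <- tempfile(fileext = ".bedGraph")
  writeLines(paste("chrT", seq(0, 4900, 100), seq(100, 5000, 100), vals,
                   sep = "\t"), f)
  tr <- read_track(f, g, 100)
  f2 <- tempfile(fileext = ".bedGraph")
  write_track(tr, f2)
  tr2 <- read_track(f2, g, 100)
  expect_equal(tr2$values, tr$values)
})

test_that("RPKM normalization follows the formula and is homogeneous", {
  g <- one_chrom(10000)
  tr <- binned_track(list(chrT = c(100, rep(0, 9))), g, 1000)
  rp <- normalize_rpkm(tr, 1e6)
  expect_equal(rp$values$chrT[1], 100)
  expect_equal(rp$values$chrT[2], 0)
  half <- normalize_rpkm(tr, 2e6)
  expect_equal(half$values$chrT, rp$values$chrT / 2)
  expect_error(normalize_rpkm(tr, 0), "library_size")
})

test_that("background correction subtracts controls then averages replicates", {
  g <- one_chrom(300)
  mk <- function(x) binned_track(list(chrT = rep(x, 3)), g, 100)
  out <- background_correct(mk(10), controls = list(mk(3), mk(2)))
  expect_equal(out$values$chrT, rep(5, 3))
  reps <- background_correct(list(mk(5), mk(7)))
  expect_equal(reps$values$chrT, rep(6, 3))   # controls absent: plain mean
  fl <- background_correct(mk(1), controls = list(mk(4)), floor_at_zero = TRUE)
  expect_equal(fl$values$chrT, rep(0, 3))
  expect_error(background_correct(mk(1), controls = list(
    binned_track(list(chrT = rep(0, 6)), g, 50))), "bin size")
})

test_that("Hann smoothing matches the closed-form kernel", {
  g <- one_chrom(20000)
  v <- rep(0, 1000); v[500] <- 1
  tr <- binned_track(list(chrT = v), g, 20)
  m3 <- hann_smooth(tr, 60)   # M = 3: endpoints of the kernel are zero
  expect_equal(m3$values$chrT, v, tolerance = 1e-12)
  m5 <- hann_smooth(tr, 100)  # M = 5
  expect_equal(m5$values$chrT[498:502], hann_kernel(5), tolerance = 1e-12)
  expect_equal(sum(m5$values$chrT), 1, tolerance = 1e-12)
  expect_equal(which.max(m5$values$chrT), 500)
  const <- binned_track(list(chrT = rep(3.25, 1000)), g, 20)
  expect_equal(hann_smooth(const, 500)$values$chrT, rep(3.25, 1000),
               tolerance = 1e-12)
  expect_error(hann_smooth(tr, 10), "window")
  expect_equal(hann_kernel(5), c(0, 0.25, 0.5, 0.25, 0))
})

test_that("pile-up profiles average the track around feature midpoints", {
  g <- one_chrom(100000)
  bin <- 20
  centers0 <- c(20000, 50000, 80000)
  bc <- (seq_len(100000 / bin) - 0.5) * bin
  v <- rowSums(vapply(centers0, function(cc) dnorm(bc, cc, 200), bc))
  tr <- binned_track(list(chrT = v), g, bin)
  ctr <- features("chrT", centers0 - 95, centers0 + 95)
  pp <- pileup_profile(tr, ctr, flank = 2000, bin = 20)
  expect_equal(nrow(pp), 200)
  expect_equal(pp$offset, -2000 + (0:199 + 0.5) * 20)
  expect_lte(abs(pp$offset[which.max(pp$mean)]), 10)  # bump peaks at 0
  expect_true(all(pp$n_features == 3))
  # flat track gives a flat profile
  flat <- binned_track(list(chrT = rep(2.5, 5000)), g, 20)
  pf <- pileup_profile(flat, ctr, flank = 1000, bin = 20)
  expect_equal(pf$mean, rep(2.5, 100))
  # feature at the chromosome start: out-of-range offsets are missing
  edge <- pileup_profile(flat, features("chrT", 0, 190), flank = 1000,
                         bin = 20)
  expect_true(all(edge$n_features[edge$offset < -95] == 0))
  expect_true(all(is.na(edge$mean[edge$offset < -95])))
  expect_true(all(edge$n_features[edge$offset > 0] == 1))
})

test_that("profile_matrix orders rows by score and averages to the pile-up", {
  g <- one_chrom(50000)
  set.seed(31)
  v <- stats::rpois(2500, 5)
  tr <- binned_track(list(chrT = v), g, 20)
  cen <- seq(5000, 45000, by = 2000)
  fs <- features("chrT", cen - 100, cen + 100,
                 score = seq_along(cen) * 1.0)
  pm <- profile_matrix(tr, fs, flank = 1000, bin = 20)
  expect_equal(dim(pm), c(length(cen), 100))
  ord_scores <- mcols(attr(pm, "centers"))$score
  expect_equal(ord_scores, sort(ord_scores, decreasing = TRUE))
  pp <- pileup_profile(tr, fs, flank = 1000, bin = 20)
  expect_equal(unname(colMeans(pm)), pp$mean)
  # independent per-feature slicing oracle
  for (i in sample(length(cen), 3)) {
    c0 <- cen[i]
    want <- vapply(0:99, function(j) {
      s <- c0 - 1000 + j * 20
      mean(v[(s / 20 + 1):(s / 20 + 1)])
    }, numeric(1))
    row_i <- which(abs(ord_scores - i) < 1e-9)
    expect_equal(unname(pm[row_i, ]), want)
  }
  expect_error(profile_matrix(tr, features("chrT", 100, 300)), "score")
})

test_that("window_signal drops windows overlapping the exclusion set", {
  g <- one_chrom(100000)
  tr <- binned_track(list(chrT = rep(4, 5000)), g, 20)
  fs <- features("chrT", c(10000, 20000), c(10100, 20100))
  axis <- features("chrT", c(10600, 20690), c(11000, 21000))
  # window 1: [9300,10800) overlaps axis by 200 bp (13.3%) -> excluded
  # window 2: [19300,20800) overlaps axis by 110 bp (7.3%) -> kept
  ws <- window_signal(tr, fs, width = 1500, exclude = axis,
                      max_fraction = 0.10)
  expect_true(ws$excluded[1]); expect_true(is.na(ws$value[1]))
  expect_false(ws$excluded[2]); expect_equal(ws$value[2], 4)
  sm <- window_signal(tr, fs, width = 600, stat = "summed_count")
  expect_equal(sm$value, rep(4 * 600 / 20, 2))
})

test_that("percentile partition gives equal-count bins with stable ties", {
  idx <- partition_by_percentile(1:100, 10)
  expect_equal(as.integer(table(idx)), rep(10L, 10))
  expect_true(all(idx[81:100] %in% c(8, 9)))
  ties <- partition_by_percentile(rep(1, 50), 10)
  expect_equal(as.integer(table(ties)), rep(5L, 10))
  expect_equal(ties, as.integer(floor((0:49) * 10 / 50)))
  set.seed(6)
  rnd <- partition_by_percentile(stats::rnorm(103), 10)
  expect_lte(diff(range(table(rnd))), 1)
  expect_error(partition_by_percentile(1:5, 10), "fewer")
})

test_that("window_correlation recovers exact and null relationships", {
  g <- one_chrom(100000)
  set.seed(12)
  a <- binned_track(list(chrT = stats::rnorm(5000)), g, 20)
  self <- window_correlation(a, a, 100)
  expect_equal(self$pearson, 1)
  expect_equal(self$spearman, 1)
  expect_equal(self$r_squared, 1)
  neg <- a; neg$values$chrT <- -a$values$chrT
  expect_equal(window_correlation(a, neg, 100)$pearson, -1)
  lin <- a; lin$values$chrT <- 3 * a$values$chrT + 2
  expect_equal(window_correlation(a, lin, 100)$pearson, 1)
  b <- binned_track(list(chrT = stats::rnorm(5000)), g, 20)
  expect_lt(abs(window_correlation(a, b, 100)$pearson), 0.1)
  expect_error(window_correlation(a, b, 150), "multiple")
})
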