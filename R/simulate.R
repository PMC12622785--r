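#' Configuration of the synthetic meiotic ChIP landscape
#'
#' Defaults emulate the study system: ~3,000 DSB hotspots of ~190 bp on a
#' 16-chromosome ~12 Mb genome, per-cell cleavage strengths spanning
#' orders of magnitude with a 0.15 ceiling (the strongest hotspots are cut
#' in ~15% of cells), quasi-periodic axis sites disjoint from hotspots,
#' DSB-end-resection-style bimodal protein coverage around hotspot
#' midpoints for the DSB sensor versus a single narrow peak for the DSB
#' catalyst (which additionally loads on axis sites), and background-only
#' untagged / pre-meiotic control tracks with Poisson counting noise.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param genome [GenomeInfoDb::Seqinfo] (default [yeast_genome_layout()]).
#' @param n_hotspots number of hotspots (default 3000).
#' @param hotspot_width hotspot width in bp (default 190).
#' @param hotspot_min_spacing minimum distance between hotspot midpoints
#'   in bp (default 1200; hotspots occupy distinct nucleosome-depleted
#'   promoter regions).
#' @param strength_meanlog,strength_sdlog log-normal parameters of per-cell
#'   cleavage strength (defaults `log(0.005)`, 1.2: median 0.5% of cells,
#'   dynamic range far beyond 100x).
#' @param strength_max per-cell cleavage ceiling (default 0.15).
#' @param axis_spacing mean inter-axis distance in bp (default 15000).
#' @param axis_width axis-site width in bp (default 500).
#' @param axis_jitter uniform jitter of axis placement in bp (default 2000).
#' @param tel1_mode `"bimodal"` (two kernels flanking hotspot midpoints)
#'   or `"none"` (no DSB-dependent signal; background only).
#' @param bimodal_offset distance of each flanking kernel from the hotspot
#'   midpoint in bp (default 300).
#' @param tel1_sigma,spo11_sigma Gaussian kernel widths in bp (defaults
#'   150 and 100).
#' @param tel1_gain,spo11_gain expected reads per unit hotspot strength
#'   (defaults 6000 and 4000).
#' @param tel1_axis_gain,spo11_axis_gain expected reads per axis site
#'   (defaults 80 and 250; the catalyst loads on the axis more strongly,
#'   its sensor only via tethered DSBs).
#' @param axis_sigma axis kernel width in bp (default 400).
#' @param background_rate background coverage in reads/bp (default 0.5).
#' @param bin_size track bin width in bp (default 20).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = yeast_genome_layout(),
                       n_hotspots = 3000,
                       hotspot_width = 190,
                       hotspot_min_spacing = 1200,
                       strength_meanlog = log(0.005),
                       strength_sdlog = 1.2,
                       strength_max = 0.15,
                       axis_spacing = 15000,
                       axis_width = 500,
                       axis_jitter = 2000,
                       tel1_mode = c("bimodal", "none"),
                       bimodal_offset = 300,
                       tel1_sigma = 150,
                       spo11_sigma = 100,
                       tel1_gain = 12000,
                       spo11_gain = 8000,
                       tel1_axis_gain = 80,
                       spo11_axis_gain = 250,
                       axis_sigma = 400,
                       background_rate = 0.5,
                       bin_size = 20) {
  tel1_mode <- match.arg(tel1_mode)
  if (!methods::is(genome, "Seqinfo")) stop("`genome` must be a Seqinfo")
  cfg <- list(seed = as.integer(seed), genome = genome,
              n_hotspots = as.integer(n_hotspots),
              hotspot_width = hotspot_width,
              hotspot_min_spacing = hotspot_min_spacing,
              strength_meanlog = strength_meanlog,
              strength_sdlog = strength_sdlog,
              strength_max = strength_max,
              axis_spacing = axis_spacing, axis_width = axis_width,
              axis_jitter = axis_jitter,
              tel1_mode = tel1_mode, bimodal_offset = bimodal_offset,
              tel1_sigma = tel1_sigma, spo11_sigma = spo11_sigma,
              tel1_gain = tel1_gain, spo11_gain = spo11_gain,
              tel1_axis_gain = tel1_axis_gain,
              spo11_axis_gain = spo11_axis_gain,
              axis_sigma = axis_sigma,
              background_rate = background_rate,
              bin_size = as.integer(bin_size))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a hotspot / axis landscape
#'
#' Axis sites are placed quasi-periodically (spacing plus uniform jitter);
#' hotspots of fixed width are dropped uniformly into the inter-axis space
#' with rejection of any overlap with axis sites or other hotspots, and
#' receive log-normal per-cell cleavage strengths clipped at the ceiling.
#' Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `hotspots` (GRanges, `score` = strength) and `axis`
#'   (GRanges), mutually disjoint.
#' @export
simulate_features <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- seqlengths(cfg$genome)
  with_seed(derive_seed(cfg$seed, 1L), {
    ax_ch <- character(0); ax_s <- numeric(0)
    for (ch in seqnames(cfg$genome)) {
      L <- lens[[ch]]
      k <- max(1L, floor(L / cfg$axis_spacing))
      centers <- (seq_len(k) - 0.5) * (L / k) +
        runif(k, -cfg$axis_jitter, cfg$axis_jitter)
      s <- round(centers - cfg$axis_width / 2)
      s <- pmin(pmax(s, 0), L - cfg$axis_width)
      # drop rare jitter-induced overlaps
      o <- order(s)
      s <- s[o]
      keep <- c(TRUE, diff(s) >= cfg$axis_width)
      s <- s[keep]
      ax_ch <- c(ax_ch, rep(ch, length(s)))
      ax_s <- c(ax_s, s)
    }
    axis <- features(ax_ch, ax_s, ax_s + cfg$axis_width)
    suppressWarnings(seqinfo(axis) <- cfg$genome)

    # hotspot counts per chromosome proportional to length (largest
    # remainder so the total is exact)
    frac <- lens / sum(as.numeric(lens)) * cfg$n_hotspots
    nh <- floor(frac)
    rem <- cfg$n_hotspots - sum(nh)
    if (rem > 0) {
      o <- order(frac - nh, decreasing = TRUE)
      nh[o[seq_len(rem)]] <- nh[o[seq_len(rem)]] + 1
    }
    hs_ch <- character(0); hs_s <- numeric(0)
    w <- cfg$hotspot_width
    for (ch in seqnames(cfg$genome)) {
      L <- lens[[ch]]
      ax <- axis[as.character(seqnames(axis)) == ch]
      a_s <- BiocGenerics::start(ax); a_e <- BiocGenerics::end(ax)
      placed_s <- numeric(0); placed_e <- numeric(0)
      need <- nh[[ch]]
      attempts <- 0L
      while (length(placed_s) < need) {
        attempts <- attempts + 1L
        if (attempts > 200L * need)
          stop("infeasible hotspot density on chromosome ", ch)
        s <- floor(runif(1, 1, L - w + 2))
        e <- s + w - 1
        if (any(a_s <= e & a_e >= s)) next
        if (length(placed_s) &&
            any(abs(placed_s - s) < cfg$hotspot_min_spacing)) next
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
      }
      hs_ch <- c(hs_ch, rep(ch, need)); hs_s <- c(hs_s, placed_s - 1)
    }
    strength <- pmin(rlnorm(cfg$n_hotspots, cfg$strength_meanlog,
                            cfg$strength_sdlog), cfg$strength_max)
    hotspots <- features(hs_ch, hs_s, hs_s + w, score = strength)
    suppressWarnings(seqinfo(hotspots) <- cfg$genome)
    list(hotspots = sort_features(hotspots), axis = sort_features(axis))
  })
}

# Accumulate `reads[f] * Normal(center0[f], sigma)` kernels onto per-bin
# expected counts. Kernel mass beyond 5 sigma is dropped.
add_gaussian_kernels <- function(expect, bin, L, centers0, reads, sigma) {
  if (length(centers0) == 0 || sigma <= 0) return(expect)
  nb <- length(expect)
  half <- ceiling(5 * sigma / bin)
  rel <- (-half):half
  cen_bin <- floor(centers0 / bin)
  idx <- outer(cen_bin, rel, `+`)
  bin_centers <- (idx + 0.5) * bin
  dens <- dnorm(bin_centers - centers0, mean = 0, sd = sigma) * bin
  vals <- dens * reads
  ok <- idx >= 0 & idx < nb
  if (any(ok)) {
    acc <- rowsum(as.numeric(vals[ok]), as.integer(idx[ok]))
    at <- as.integer(rownames(acc)) + 1L
    expect[at] <- expect[at] + acc[, 1]
  }
  expect
}

#' Simulate ChIP coverage tracks for the synthetic landscape
#'
#' Expected coverage is background plus per-hotspot kernels (for the DSB
#' sensor, `tel1`: two Gaussians at +/- `bimodal_offset` scaled by hotspot
#' strength; for the catalyst, `spo11`: one narrow Gaussian) plus axis
#' kernels (catalyst-weighted > sensor-weighted); counts are Poisson per
#' bin. `untagged` and `t0` controls carry background only. Deterministic
#' under the config seed.
#'
#' @param cfg a [sim_config()].
#' @param hotspots,axis feature sets from [simulate_features()].
#' @return List of class `sim_tracks`: `tel1`, `spo11`, `untagged`, `t0`
#'   ([binned_track()]s of counts), `expected` (noise-free expected-count
#'   tracks), and `library_sizes` (named total read counts).
#' @export
simulate_chip_tracks <- function(cfg, hotspots, axis) {
  stopifnot(inherits(cfg, "sim_config"))
  bin <- cfg$bin_size
  lens <- seqlengths(cfg$genome)
  chroms <- seqnames(cfg$genome)
  hs_cen <- feature_center0(hotspots)
  hs_ch <- as.character(seqnames(hotspots))
  hs_str <- feature_scores(hotspots)
  ax_cen <- feature_center0(axis)
  ax_ch <- as.character(seqnames(axis))

  build_expected <- function(hot_gain, hot_sigma, offsets, axis_gain) {
    v <- lapply(chroms, function(ch) {
      L <- lens[[ch]]
      nb <- ceiling(L / bin)
      ex <- rep(cfg$background_rate * bin, nb)
      i <- hs_ch == ch
      if (any(i) && hot_gain > 0) {
        per_kernel <- hot_gain * hs_str[i] / length(offsets)
        for (off in offsets)
          ex <- add_gaussian_kernels(ex, bin, L, hs_cen[i] + off,
                                     per_kernel, hot_sigma)
      }
      j <- ax_ch == ch
      if (any(j) && axis_gain > 0)
        ex <- add_gaussian_kernels(ex, bin, L, ax_cen[j],
                                   rep(axis_gain, sum(j)), cfg$axis_sigma)
      ex
    })
    names(v) <- chroms
    v
  }

  tel1_exp <- if (cfg$tel1_mode == "bimodal")
    build_expected(cfg$tel1_gain, cfg$tel1_sigma,
                   c(-cfg$bimodal_offset, cfg$bimodal_offset),
                   cfg$tel1_axis_gain)
  else build_expected(0, cfg$tel1_sigma, numeric(0), 0)
  spo11_exp <- build_expected(cfg$spo11_gain, cfg$spo11_sigma, 0,
                              cfg$spo11_axis_gain)
  bg_exp <- build_expected(0, 1, numeric(0), 0)

  with_seed(derive_seed(cfg$seed, 2L), {
    draw <- function(exp_vals) lapply(exp_vals, function(e) rpois(length(e), e))
    obs <- list(tel1 = draw(tel1_exp), spo11 = draw(spo11_exp),
                untagged = draw(bg_exp), t0 = draw(bg_exp))
    tracks <- lapply(obs, binned_track, genome = cfg$genome,
                     bin_size = bin, units = "counts")
    lib <- vapply(obs, function(v) sum(unlist(v)), numeric(1))
    structure(c(tracks,
                list(expected = lapply(list(tel1 = tel1_exp,
                                            spo11 = spo11_exp,
                                            background = bg_exp),
                                       binned_track, genome = cfg$genome,
                                       bin_size = bin, units = "expected"),
                     library_sizes = lib)),
              class = "sim_tracks")
  })
}

#' Simulate a per-chromatid double-cut cohort
#'
#' Each cell's chromatid is cut at site I with probability `p1`, at site
#' II with `p2`, and at both with `P(DC) = (1 - I_true) * p1 * p2` (the
#' minimal joint model in which interference acts as a multiplicative
#' factor on the independence product; marginals are preserved). The
#' measurement model mirrors the Southern-blot readout: the site-I band
#' reports every chromatid cut at I, double-cut molecules are absent from
#' the site-II band when `dc_loss_on_f2` (they run as the short double-cut
#' fragment instead), and the central double-cut probe hybridizes to
#' `probe_loci` parental locations so its fractional signal is diluted
#' `probe_loci`-fold.
#'
#' @param n_cells number of cells (chromatids) to draw.
#' @param p1,p2 per-chromatid cut probabilities at sites I and II.
#' @param I_true true interference parameter (`<= 1`).
#' @param seed optional integer seed.
#' @param dc_loss_on_f2 double cuts vanish from the site-II band (default
#'   `TRUE`).
#' @param probe_loci central-probe multiplicity `m` (default 3).
#' @return A list of class `dsb_cohort`: `outcomes` (named counts `none`,
#'   `i_only`, `ii_only`, `dc`), `measured` (`f1`, `f2_raw`,
#'   `dc_central_raw`), the parameters, and `n_cells`.
#' @export
simulate_dsb_cohort <- function(n_cells, p1, p2, I_true, seed = NULL,
                                dc_loss_on_f2 = TRUE, probe_loci = 3) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("p1, p2 must be in [0, 1]")
  if (I_true > 1) stop("`I_true` must be <= 1")
  p_dc <- max(0, (1 - I_true) * p1 * p2)
  if (p_dc > min(p1, p2) + 1e-12)
    stop("infeasible joint distribution: (1 - I_true) * p1 * p2 > min(p1, p2)")
  p_dc <- max(p_dc, p1 + p2 - 1)   # clip to the feasible joint region
  probs <- c(none = 1 - p1 - p2 + p_dc, i_only = p1 - p_dc,
             ii_only = p2 - p_dc, dc = p_dc)
  counts <- with_seed(seed, drop(rmultinom(1, n_cells, probs)))
  f1 <- (counts[["i_only"]] + counts[["dc"]]) / n_cells
  f2_raw <- if (dc_loss_on_f2) counts[["ii_only"]] / n_cells else
    (counts[["ii_only"]] + counts[["dc"]]) / n_cells
  dc_central_raw <- counts[["dc"]] / (probe_loci * n_cells)
  structure(list(outcomes = counts,
                 measured = list(f1 = f1, f2_raw = f2_raw,
                                 dc_central_raw = dc_central_raw),
                 n_cells = n_cells, p1 = p1, p2 = p2, I_true = I_true,
                 dc_loss_on_f2 = dc_loss_on_f2, probe_loci = probe_loci),
            class = "dsb_cohort")
}

#' Simulate a ChIP-qPCR plate
#'
#' Generates IP/input quantity pairs whose [percent_ip()] recovers
#' `100 * true_enrichment` in expectation; technical noise is log-normal
#' with the given coefficient of variation (mean 1).
#'
#' @param true_enrichment immunoprecipitated fraction of input at the
#'   locus (e.g. 6e-4 for a 0.06% IP).
#' @param n_wells number of replicate wells (default 3).
#' @param dilution,volume_ratio correction factors (defaults 20 and 10).
#' @param noise_cv technical coefficient of variation (default 0).
#' @param q_input_true latent input quantity (default 1).
#' @param seed optional integer seed.
#' @return data.frame with columns `q_ip`, `q_input`, `dilution`,
#'   `volume_ratio`.
#' @export
simulate_qpcr_plate <- function(true_enrichment, n_wells = 3,
                                dilution = 20, volume_ratio = 10,
                                noise_cv = 0, q_input_true = 1,
                                seed = NULL) {
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (true_enrichment < 0) stop("`true_enrichment` must be >= 0")
  with_seed(seed, {
    lnoise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    q_input <- q_input_true * lnoise(n_wells)
    q_ip <- true_enrichment * q_input_true * dilution * volume_ratio *
      lnoise(n_wells)
    data.frame(q_ip = q_ip, q_input = q_input,
               dilution = dilution, volume_ratio = volume_ratio)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Runs [simulate_features()], [simulate_chip_tracks()],
#' [simulate_dsb_cohort()] and [simulate_qpcr_plate()] under the config
#' seed and writes plain-text outputs: `genome.tsv`, `hotspots.bed`
#' (score = strength), `axis.bed`, four bedGraph tracks, `bands.tsv`,
#' `plate.tsv`, and `truth.json` with the generating parameters and
#' ground truth. Identical seeds give byte-identical directories.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param cohort_pars named list of [simulate_dsb_cohort()] arguments
#'   (defaults: `n_cells = 1e5`, `p1 = p2 = 0.1`, `I_true = 0.5`).
#' @param plate_pars named list of [simulate_qpcr_plate()] arguments
#'   (default `true_enrichment = 6e-4`, `noise_cv = 0.1`).
#' @return `outdir`, invisibly.
#' @export
simulate_all <- function(cfg, outdir,
                         cohort_pars = list(n_cells = 1e5, p1 = 0.1,
                                            p2 = 0.1, I_true = 0.5),
                         plate_pars = list(true_enrichment = 6e-4,
                                           noise_cv = 0.1)) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fx <- simulate_features(cfg)
  tr <- simulate_chip_tracks(cfg, fx$hotspots, fx$axis)
  write_genome_layout(cfg$genome, file.path(outdir, "genome.tsv"))
  hs <- fx$hotspots
  mcols(hs)$name <- sprintf("hotspot_%04d", seq_along(hs))
  write_features(hs, file.path(outdir, "hotspots.bed"))
  ax <- fx$axis
  mcols(ax)$name <- sprintf("axis_%04d", seq_along(ax))
  mcols(ax)$score <- 0
  write_features(ax, file.path(outdir, "axis.bed"))
  for (nm in c("tel1", "spo11", "untagged", "t0"))
    write_track(tr[[nm]], file.path(outdir, paste0(nm, ".bedGraph")))
  cohort <- do.call(simulate_dsb_cohort,
                    c(cohort_pars, list(seed = derive_seed(cfg$seed, 3L))))
  bands <- data.frame(quantity = c("f1", "f2_raw", "dc_central_raw"),
                      frequency = unlist(cohort$measured, use.names = FALSE))
  write.table(bands, file.path(outdir, "bands.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  plate <- do.call(simulate_qpcr_plate,
                   c(plate_pars, list(seed = derive_seed(cfg$seed, 4L))))
  write.table(format(plate, digits = 15, trim = TRUE, scientific = FALSE),
              file.path(outdir, "plate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- list(
    seed = cfg$seed,
    n_hotspots = length(fx$hotspots),
    n_axis = length(fx$axis),
    strength_max = max(feature_scores(fx$hotspots)),
    bimodal_offset = cfg$bimodal_offset,
    tel1_mode = cfg$tel1_mode,
    library_sizes = as.list(tr$library_sizes),
    cohort = list(I_true = cohort$I_true, p1 = cohort$p1, p2 = cohort$p2,
                  n_cells = cohort$n_cells,
                  outcomes = as.list(cohort$outcomes)),
    plate = plate_pars)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outdir, "truth.json"))
  invisible(outdir)
}
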