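#' ChIP-qPCR percent-input enrichment
#'
#' `%IP = 100 * q_ip / (q_input * dilution * volume_ratio)`: the
#' immunoprecipitated fraction of input material at a locus, corrected for
#' the dilution of the input before qPCR (20-fold by default) and for the
#' volume difference between the input aliquot and the material used for
#' IP (10-fold by default).
#'
#' @param q_ip quantity at the target locus in the IP sample
#'   (standard-curve units); vectorized.
#' @param q_input same quantity in the (diluted) input sample (> 0).
#' @param dilution input dilution factor (default 20).
#' @param volume_ratio input-to-IP volume factor (default 10).
#' @return Percent IP value(s).
#' @examples
#' percent_ip(0.5, 1.0)  # 0.25 %
#' @export
percent_ip <- function(q_ip, q_input, dilution = 20, volume_ratio = 10) {
  if (any(!is.finite(q_input)) || any(q_input <= 0))
    stop("`q_input` must be > 0")
  if (dilution <= 0 || volume_ratio <= 0)
    stop("`dilution` and `volume_ratio` must be > 0")
  100 * q_ip / (q_input * dilution * volume_ratio)
}

#' Observed double-cut frequency with probe-multiplicity correction
#'
#' The double-cut band is quantified with a central probe that hybridizes
#' to `m` parental genomic locations (three for the LEU2 probe), so the
#' measured fraction of lane signal underestimates the double-cut
#' frequency `m`-fold: `dc_obs = m * dc_central_raw`.
#'
#' @param dc_central_raw double-cut signal as a fraction of total lane
#'   signal, in `[0, 1/m]`.
#' @param m number of genomic loci the probe hybridizes to (default 3).
#' @return Corrected observed double-cut frequency.
#' @export
observed_dc <- function(dc_central_raw, m = 3) {
  if (m < 1) stop("`m` must be >= 1")
  if (any(dc_central_raw < 0) || any(dc_central_raw > 1 / m + 1e-12))
    stop("`dc_central_raw` must lie in [0, 1/m]")
  out <- m * dc_central_raw
  if (any(out > 1 + 1e-12))
    stop("corrected double-cut frequency exceeds 1: inconsistent quantification")
  pmin(out, 1)
}

#' Expected double-cut frequency under independence
#'
#' Product of the single-cut frequencies at the two DSB sites. With the
#' double-cut loss correction (`correct_loss = TRUE`, the short-range
#' assay), the distal-site frequency measured from band II is first
#' restored by adding back the observed double cuts, which are physically
#' absent from that band: `dc_exp = f1 * (f2_raw + dc_obs)`. Without the
#' correction (mid-range assay, where the expected product uses directly
#' measured single-cut frequencies) `dc_exp = f1 * f2_raw`.
#'
#' @param f1 DSB frequency at site I (fraction of lane signal).
#' @param f2_raw DSB frequency at site II as measured.
#' @param dc_obs observed double-cut frequency (see [observed_dc()]).
#' @param correct_loss apply the double-cut loss correction (default
#'   `TRUE`).
#' @return Expected double-cut frequency.
#' @examples
#' expected_dc(0.20, 0.15, dc_obs = 0.03)  # 0.2 * 0.18 = 0.036
#' @export
expected_dc <- function(f1, f2_raw, dc_obs = 0, correct_loss = TRUE) {
  f2 <- if (correct_loss) f2_raw + dc_obs else f2_raw
  vals <- c(f1, f2_raw, dc_obs, f2)
  if (any(vals < -1e-12) || any(c(f1, f2) > 1 + 1e-12))
    stop("frequencies must lie in [0, 1]")
  f1 * f2
}

#' DSB interference value
#'
#' `I = 1 - dc_obs / dc_exp`. Positive values indicate DSB interference
#' (coincident cuts rarer than under independence), values near zero
#' indicate independence, and negative values manifest concerted cutting.
#'
#' @param dc_obs observed double-cut frequency.
#' @param dc_exp expected double-cut frequency under independence.
#' @return List of class `interference_result` with `dc_obs`, `dc_exp`,
#'   and `I` (NA when both frequencies are 0).
#' @export
interference_value <- function(dc_obs, dc_exp) {
  if (dc_obs < 0 || dc_exp < 0) stop("frequencies must be >= 0")
  if (dc_exp == 0) {
    if (dc_obs > 0)
      stop("interference undefined: expected double-cut frequency is 0 with observed > 0")
    I <- NA_real_
  } else {
    I <- 1 - dc_obs / dc_exp
  }
  structure(list(dc_obs = dc_obs, dc_exp = dc_exp, I = I),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf("DSB interference: observed DC %.4g, expected DC %.4g, I = %.4g\n",
              x$dc_obs, x$dc_exp, x$I))
  invisible(x)
}

#' Interference estimate (with standard error) from band quantifications
#'
#' Full short-range pipeline on one set of lane fractions: probe
#' multiplicity correction, double-cut loss correction, and the
#' interference value.
#'
#' @param f1 single-cut fraction at site I.
#' @param f2_raw single-cut fraction at site II as measured.
#' @param dc_central_raw double-cut fraction from the central probe.
#' @param m probe multiplicity (default 3).
#' @param correct_loss apply the loss correction to site II (default
#'   `TRUE`).
#' @return An `interference_result`.
#' @export
interference_from_bands <- function(f1, f2_raw, dc_central_raw, m = 3,
                                    correct_loss = TRUE) {
  dc_obs <- observed_dc(dc_central_raw, m = m)
  dc_exp <- expected_dc(f1, f2_raw, dc_obs = dc_obs,
                        correct_loss = correct_loss)
  interference_value(dc_obs, dc_exp)
}

#' Interference estimate from a simulated double-cut cohort
#'
#' Applies the measurement pipeline ([observed_dc()], [expected_dc()],
#' [interference_value()]) to the band fractions derived from a
#' [simulate_dsb_cohort()] draw, and attaches a delta-method standard
#' error propagated through the multinomial outcome covariance.
#'
#' @param cohort a `dsb_cohort` object.
#' @param correct_loss apply the double-cut loss correction (defaults to
#'   the cohort's measurement model flag).
#' @return An `interference_result` with additional elements `se`
#'   (standard error of `I`) and `n_cells`.
#' @export
interference_from_cohort <- function(cohort, correct_loss = NULL) {
  if (!inherits(cohort, "dsb_cohort")) stop("`cohort` must be a dsb_cohort")
  if (is.null(correct_loss)) correct_loss <- cohort$dc_loss_on_f2
  m <- cohort$probe_loci
  n <- cohort$n_cells
  counts <- cohort$outcomes   # none, i_only, ii_only, dc
  stat <- function(p) {
    f1 <- p[["i_only"]] + p[["dc"]]
    f2_raw <- if (cohort$dc_loss_on_f2) p[["ii_only"]] else
      p[["ii_only"]] + p[["dc"]]
    dc_obs <- m * (p[["dc"]] / m)       # probe dilution then correction
    f2 <- if (correct_loss) f2_raw + dc_obs else f2_raw
    1 - dc_obs / (f1 * f2)
  }
  phat <- counts / n
  I_hat <- stat(phat)
  eps <- 1e-6
  grad <- vapply(seq_along(phat), function(k) {
    up <- phat; up[k] <- up[k] + eps
    dn <- phat; dn[k] <- dn[k] - eps
    (stat(up) - stat(dn)) / (2 * eps)
  }, numeric(1))
  Sigma <- (diag(phat) - outer(phat, phat)) / n
  se <- sqrt(drop(t(grad) %*% Sigma %*% grad))
  res <- interference_value(m * (phat[["dc"]] / m),
                            expected_dc(phat[["i_only"]] + phat[["dc"]],
                                        if (cohort$dc_loss_on_f2) phat[["ii_only"]] else
                                          phat[["ii_only"]] + phat[["dc"]],
                                        dc_obs = phat[["dc"]],
                                        correct_loss = correct_loss))
  res$I <- I_hat
  res$se <- se
  res$n_cells <- n
  res
}
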