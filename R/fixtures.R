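# Synthetic peak-table generator: emulates the reduced output of an
# HPLC-CAD oligomer analysis of a sample with known scission extent, so the
# estimator can be validated by parameter recovery without any instrument
# data.

#' Generate a synthetic oligomer peak table with known scission extent
#'
#' Simulates one ensemble to the requested true extent, converts the
#' per-oligomer weight fractions inside the resolved window to detector
#' integrals (the CAD response is mass proportional), perturbs every
#' integral by multiplicative lognormal noise, and collapses the mass
#' outside the censoring bounds into `lump_low` / `lump_high` rows exactly
#' as a real censored chromatogram would. When writing to a file, the true
#' extent goes to a JSON sidecar (`<path>.meta.json`), never into the table
#' itself, so fitting tests stay blind.
#'
#' @param true_sic True scission extent (`>= 0`; 0 yields the unreacted
#'   initial ensemble).
#' @param noise_rel Lognormal sigma of the multiplicative integral noise
#'   (`0 <= noise_rel < 0.5`).
#' @param censor_bounds Resolved window `(low, high)` in Da (default
#'   `c(2000, 6400)`).
#' @param seed Integer seed (drives both the simulation and the noise).
#' @param spec An [ensemble_spec()] for the sample (default the reference
#'   5000-chain, 6380 +/- 400 Da ensemble).
#' @param model A [rate_model()].
#' @param path Optional CSV output path; a `<path>.meta.json` sidecar
#'   records `true_sic`, the seed and the generator parameters.
#' @return The `peak_table`, invisibly when `path` is given.
#' @export
generate_fixture_peak_table <- function(true_sic, noise_rel = 0,
                                        censor_bounds = c(2000, 6400),
                                        seed = 1L,
                                        spec = ensemble_spec(5000, 145, 400 / 44),
                                        model = rate_model(), path = NULL) {
  check_nonnegative(true_sic, "true_sic")
  if (noise_rel < 0 || noise_rel >= 0.5) {
    stop_domain("'noise_rel' must be in [0, 0.5)")
  }
  if (length(censor_bounds) != 2L || censor_bounds[1] >= censor_bounds[2]) {
    stop_domain("'censor_bounds' must be (low, high) with low < high")
  }
  if (true_sic > 0) {
    sim <- run_simulation(spec, model, true_sic, seed = seed)
    ens <- sim$final
  } else {
    set.seed(seed)
    ens <- build_initial_ensemble(spec, seed = seed)
  }
  counts <- ens$counts
  n <- seq_along(counts)
  mw <- n * ens$mw_monomer
  mass <- n * counts
  wt <- 100 * mass / sum(mass)
  resolved <- which(mw >= censor_bounds[1] & mw <= censor_bounds[2] & counts > 0)
  low <- sum(wt[mw < censor_bounds[1]])
  high <- sum(wt[mw > censor_bounds[2]])
  kind <- c(if (low > 0) "lump_low", rep("resolved", length(resolved)),
            if (high > 0) "lump_high")
  integral <- c(if (low > 0) low, wt[resolved], if (high > 0) high)
  if (noise_rel > 0) {
    integral <- integral * stats::rlnorm(length(integral), 0, noise_rel)
  }
  tab <- peak_table(kind = kind, integral = integral,
                    mw_da = c(if (low > 0) NA_real_, mw[resolved],
                              if (high > 0) NA_real_))
  if (!is.null(path)) {
    write_peak_table(tab, path)
    meta <- list(true_sic = true_sic, noise_rel = noise_rel,
                 censor_bounds = censor_bounds, seed = seed,
                 m = spec$m, lambda_len = spec$lambda_len,
                 sigma_len = spec$sigma_len, mw_monomer = spec$mw_monomer,
                 package_version = as.character(utils::packageVersion("scission")))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(tab))
  }
  tab
}
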