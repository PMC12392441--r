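# Replicate simulations and checkpointed trajectories.
#
# A run terminated at the largest scission extent of interest passes
# through every smaller extent on the way (events are cumulative and the
# process is Markovian in the ensemble), so one simulation per replicate
# with snapshots at each grid value gives the whole extent-grid at the cost
# of the largest run. Replicate r uses seed base_seed + r, so any replicate
# is reproducible in isolation.

replicate_seed <- function(base_seed, r) {
  s <- as.integer(base_seed) + r
  if (s >= 2^31 - 1) stop_domain("base_seed too large: replicate seed overflows")
  s
}

#' Simulate replicate ensembles checkpointed along a scission-extent grid
#'
#' Runs `n_replicates` independent simulations, each snapshotting the
#' length histogram after `round(sic * m)` events for every `sic` in
#' `sic_grid`. This is the workhorse behind [run_replicates()],
#' [sic_trajectory()] and [simulate_sic_curves()].
#'
#' @param spec An [ensemble_spec()].
#' @param model A [rate_model()].
#' @param sic_grid Nondecreasing vector of scission extents (`>= 0`; 0
#'   snapshots the initial ensemble).
#' @param n_replicates Number of replicate runs.
#' @param base_seed Integer seed; replicate `r` uses `base_seed + r`.
#' @return An object of class `scission_checkpoints`: a list with
#'   `sic_grid`, `achieved_sic` (the grid as actually realized,
#'   `round(sic * m) / m`), `snapshots` (`[[replicate]][[grid point]]`
#'   numeric count vectors), plus `spec` and `model`.
#' @export
simulate_checkpoints <- function(spec, model = rate_model(), sic_grid,
                                 n_replicates, base_seed = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(model, "rate_model"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (length(sic_grid) == 0L || any(sic_grid < 0) || is.unsorted(sic_grid)) {
    stop_domain("'sic_grid' must be nonempty, nonnegative and nondecreasing")
  }
  ev_grid <- as.integer(round_half_up(sic_grid * spec$m))
  snapshots <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed <- replicate_seed(base_seed, r)
    set.seed(seed)
    initial <- build_initial_ensemble(spec, seed = seed)
    kvec <- eligible_rate_vector(length(initial$counts), model)
    res <- mc_event_loop(initial$counts, kvec, max(ev_grid),
                         checkpoint_after = ev_grid, m_initial = spec$m)
    snapshots[[r]] <- res$snapshots
  }
  structure(list(sic_grid = sic_grid, achieved_sic = ev_grid / spec$m,
                 snapshots = snapshots, spec = spec, model = model,
                 n_replicates = n_replicates, base_seed = base_seed),
            class = "scission_checkpoints")
}

#' @export
print.scission_checkpoints <- function(x, ...) {
  cat(sprintf(
    "Checkpointed scission simulations: %d replicates of m = %d chains,\n  %d extent grid points over SiC %g..%g\n",
    x$n_replicates, x$spec$m, length(x$sic_grid), min(x$sic_grid),
    max(x$sic_grid)))
  invisible(x)
}

checkpoint_ensemble <- function(cp, replicate, grid_index) {
  new_chain_ensemble(cp$snapshots[[replicate]][[grid_index]],
                     cp$spec$mw_monomer)
}

# common bin grid wide enough for every replicate snapshot
common_bins <- function(cp, bin_width) {
  nmax <- max(vapply(cp$snapshots, function(s) length(s[[1]]), numeric(1)))
  ceiling(nmax * cp$spec$mw_monomer / bin_width - 1e-12)
}

#' Replicate-averaged weight-percent MW distribution
#'
#' Runs `n_replicates` independent simulations to the requested scission
#' extent and averages their wt\% histograms, with a 95\% envelope taken as
#' the 2.5 and 97.5 percentiles across replicates per bin.
#'
#' @param spec An [ensemble_spec()].
#' @param model A [rate_model()].
#' @param sic_target Scission extent at which to summarize.
#' @param n_replicates Number of replicates (`>= 2`).
#' @param base_seed Integer seed; replicate `r` uses `base_seed + r`.
#' @param bin_width Histogram bin width in Da (default 44).
#' @return A data frame with columns `bin_lo_da`, `bin_hi_da`,
#'   `mean_wt_pct`, `lo95`, `hi95` (empty trailing bins trimmed).
#' @examples
#' \donttest{
#' spec <- ensemble_spec(5000, 145, 9.09)
#' d <- run_replicates(spec, sic_target = 8, n_replicates = 10, base_seed = 1)
#' sum(d$mean_wt_pct[d$bin_hi_da < 4000])  # most mass below 4000 Da
#' }
#' @export
run_replicates <- function(spec, model = rate_model(), sic_target,
                           n_replicates, base_seed = 1L, bin_width = 44) {
  if (n_replicates < 2L) stop_domain("'n_replicates' must be >= 2")
  cp <- simulate_checkpoints(spec, model, sic_grid = sic_target,
                             n_replicates = n_replicates,
                             base_seed = base_seed)
  nbins <- common_bins(cp, bin_width)
  wt <- matrix(0, nrow = n_replicates, ncol = nbins)
  for (r in seq_len(n_replicates)) {
    h <- mw_histogram(checkpoint_ensemble(cp, r, 1L), bin_width)
    wt[r, seq_len(nrow(h))] <- h$wt_pct
  }
  q <- apply(wt, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(
    bin_lo_da = (seq_len(nbins) - 1) * bin_width,
    bin_hi_da = seq_len(nbins) * bin_width,
    mean_wt_pct = colMeans(wt),
    lo95 = q[1, ],
    hi95 = q[2, ]
  )
  keep <- seq_len(max(which(out$mean_wt_pct > 0)))
  out[keep, , drop = FALSE]
}

#' Weight-percent trajectories of selected MW classes versus scission extent
#'
#' Tracks how the wt\% abundance of chains of selected molecular weights
#' changes as the scission extent grows: high-MW chains are depleted
#' monotonically, low-MW chains accumulate monotonically, and
#' intermediate-MW chains rise (formation from longer chains dominates)
#' and then fall (their own scission takes over).
#'
#' Each requested MW is snapped to the nearest whole number of monomer
#' units, with a warning when the correction is nonzero.
#'
#' @param spec An [ensemble_spec()].
#' @param model A [rate_model()].
#' @param sic_grid Increasing grid of scission extents.
#' @param target_mws MW values to track, in Da.
#' @param n_replicates Replicates per grid point (checkpointed runs).
#' @param base_seed Integer seed.
#' @return A data frame with columns `sic`, `mw_da`, `mean_wt_pct`,
#'   `lo95`, `hi95`.
#' @export
sic_trajectory <- function(spec, model = rate_model(), sic_grid, target_mws,
                           n_replicates, base_seed = 1L) {
  if (is.unsorted(sic_grid, strictly = TRUE)) {
    stop_domain("'sic_grid' must be strictly increasing")
  }
  n_target <- round(target_mws / spec$mw_monomer)
  snapped <- n_target * spec$mw_monomer
  if (any(abs(snapped - target_mws) > 1e-9)) {
    warning(sprintf("target MW(s) %s snapped to monomer multiples %s",
                    paste(target_mws[abs(snapped - target_mws) > 1e-9], collapse = ", "),
                    paste(snapped[abs(snapped - target_mws) > 1e-9], collapse = ", ")))
  }
  if (any(n_target < 1)) stop_domain("target MW below one monomer unit")
  cp <- simulate_checkpoints(spec, model, sic_grid, n_replicates, base_seed)
  trajectory_from_checkpoints(cp, n_target, snapped)
}

trajectory_from_checkpoints <- function(cp, n_target, mw_target) {
  G <- length(cp$sic_grid)
  R <- cp$n_replicates
  out <- vector("list", G * length(n_target))
  k <- 1L
  for (g in seq_len(G)) {
    wt <- matrix(0, nrow = R, ncol = length(n_target))
    for (r in seq_len(R)) {
      counts <- cp$snapshots[[r]][[g]]
      mass <- counts * seq_along(counts)
      m_t <- ifelse(n_target <= length(mass), mass[n_target], 0)
      wt[r, ] <- 100 * m_t / sum(mass)
    }
    q <- apply(wt, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    for (j in seq_along(n_target)) {
      out[[k]] <- data.frame(sic = cp$sic_grid[g], mw_da = mw_target[j],
                             mean_wt_pct = mean(wt[, j]),
                             lo95 = q[1, j], hi95 = q[2, j])
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
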