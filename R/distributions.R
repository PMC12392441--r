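# Molecular-weight distribution summaries. A chain of n monomers has
# MW = n * mw_monomer exactly; histograms use right-closed bins
# ((i-1)*w, i*w] so that a chain's MW falls on its own bin's upper edge,
# and cumulative curves follow the right-continuous step convention: a
# chain of MW x counts at every query point >= x.

#' Number- and weight-percent MW histogram of an ensemble
#'
#' Bins chain masses into right-closed intervals of width `bin_width`.
#' nr\% weights every chain equally, wt\% weights each chain by its monomer
#' count; both columns sum to 100.
#'
#' @param ensemble A `chain_ensemble`.
#' @param bin_width Bin width in Da (default 44, one repeat unit — each
#'   chain length then occupies its own bin).
#' @return An object of class `mw_distribution`: a data frame with columns
#'   `bin_lo_da`, `bin_hi_da`, `nr_pct`, `wt_pct` covering
#'   `(0, max MW]` contiguously.
#' @examples
#' mw_histogram(chain_ensemble(c(1, 3), c(3, 1)))
#' @export
mw_histogram <- function(ensemble, bin_width = 44) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  check_positive(bin_width, "bin_width")
  counts <- ensemble$counts
  if (sum(counts) <= 0) stop_domain("empty ensemble")
  n <- seq_along(counts)
  mw <- n * ensemble$mw_monomer
  bin <- ceiling(mw / bin_width - 1e-12)  # chain MW on an edge goes below it
  nbins <- max(bin)
  nr <- vapply(seq_len(nbins), function(b) sum(counts[bin == b]), numeric(1))
  wt <- vapply(seq_len(nbins), function(b) sum((n * counts)[bin == b]), numeric(1))
  out <- data.frame(
    bin_lo_da = (seq_len(nbins) - 1) * bin_width,
    bin_hi_da = seq_len(nbins) * bin_width,
    nr_pct = 100 * nr / sum(nr),
    wt_pct = 100 * wt / sum(wt)
  )
  structure(out, class = c("mw_distribution", "data.frame"),
            bin_width = bin_width)
}

#' Cumulative weight-percent curve of a MW distribution
#'
#' Running sum of wt\% over bins in increasing MW, tabulated at the upper
#' bin edges (right-continuous step curve). Optional censoring lumps carry
#' the mass outside a resolved window; the final tabulated value plus
#' `lump_high` is 100.
#'
#' @param x An `mw_distribution` (from [mw_histogram()]).
#' @return An object of class `cumulative_mw_curve`: a list with
#'   `mw_da` (increasing), `cum_wt_pct` (nondecreasing, in `[0, 100]`),
#'   `lump_low` and `lump_high` (both 0 for a fully resolved simulated
#'   distribution).
#' @examples
#' cumulative_curve(mw_histogram(chain_ensemble(c(1, 3), c(3, 1))))
#' @export
cumulative_curve <- function(x) {
  stopifnot(inherits(x, "mw_distribution"))
  occ <- x$wt_pct > 0
  new_cumulative_curve(
    mw_da = x$bin_hi_da[occ],
    cum_wt_pct = cumsum(x$wt_pct)[occ],
    lump_low = 0, lump_high = 0
  )
}

new_cumulative_curve <- function(mw_da, cum_wt_pct, lump_low = 0,
                                 lump_high = 0) {
  if (is.unsorted(mw_da, strictly = TRUE)) {
    stop_domain("curve MW points must be strictly increasing")
  }
  if (is.unsorted(cum_wt_pct)) stop_domain("cumulative wt%% must be nondecreasing")
  if (length(cum_wt_pct) &&
      abs(cum_wt_pct[length(cum_wt_pct)] + lump_high - 100) > 1e-6) {
    stop_domain("last cumulative value (%g) + lump_high (%g) must equal 100",
                cum_wt_pct[length(cum_wt_pct)], lump_high)
  }
  structure(list(mw_da = mw_da, cum_wt_pct = cum_wt_pct,
                 lump_low = lump_low, lump_high = lump_high),
            class = "cumulative_mw_curve")
}

#' @export
print.cumulative_mw_curve <- function(x, ...) {
  cat(sprintf(
    "Cumulative MW curve: %d points over %g..%g Da; lumps %.3g wt%% low, %.3g wt%% high\n",
    length(x$mw_da), min(x$mw_da), max(x$mw_da), x$lump_low, x$lump_high))
  invisible(x)
}

#' Evaluate a cumulative curve at arbitrary MW points
#'
#' Step interpolation: the value at the greatest tabulated MW at or below
#' the query. Below the first tabulated point the value is `lump_low`
#' (mass censored below the resolved window; 0 for simulated curves).
#'
#' @param curve A `cumulative_mw_curve`.
#' @param mw Query MW values in Da.
#' @return Cumulative wt\% at each query point.
#' @export
eval_curve <- function(curve, mw) {
  stopifnot(inherits(curve, "cumulative_mw_curve"))
  idx <- findInterval(mw + 1e-9, curve$mw_da)
  out <- ifelse(idx == 0, curve$lump_low, curve$cum_wt_pct[pmax(idx, 1L)])
  as.numeric(out)
}

#' Weight fraction of an ensemble below a MW threshold
#'
#' Mass percentage carried by chains with MW strictly below `threshold`.
#'
#' @param ensemble A `chain_ensemble`.
#' @param threshold MW threshold in Da (> 0; strict `<`).
#' @return wt\% in `[0, 100]`.
#' @examples
#' ens <- build_initial_ensemble(ensemble_spec(5000, 145, 9.09))
#' fraction_below(ens, 6380)  # ~47.6 wt% of mass in chains below the mean MW
#' @export
fraction_below <- function(ensemble, threshold) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  check_positive(threshold, "threshold")
  counts <- ensemble$counts
  n <- seq_along(counts)
  mass <- n * counts
  100 * sum(mass[n * ensemble$mw_monomer < threshold]) / sum(mass)
}

#' Write a distribution or cumulative curve as TSV
#'
#' Distributions are written with columns `bin_lo_da`, `bin_hi_da`,
#' `nr_pct`, `wt_pct`; curves with columns `mw_da`, `cum_wt_pct` preceded
#' by `# lump_low:` and `# lump_high:` metadata lines.
#'
#' @param x An `mw_distribution` or `cumulative_mw_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "cumulative_mw_curve")) {
    writeLines(c(sprintf("# lump_low: %.10g", x$lump_low),
                 sprintf("# lump_high: %.10g", x$lump_high)), con)
    utils::write.table(data.frame(mw_da = x$mw_da, cum_wt_pct = x$cum_wt_pct),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "mw_distribution")) {
    utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    stop_domain("unsupported object of class '%s'", class(x)[1])
  }
  invisible(path)
}
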