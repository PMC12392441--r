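# Chromatographic oligomer peak tables (HPLC with charged-aerosol detection
# and parallel high-resolution MS). The CAD response is proportional to
# analyte mass and independent of MW, so peak integrals convert directly to
# weight percent. Oligomers outside the resolved window are only known as
# two lumped integrals (below ~2000 Da and above ~6400 Da).

#' Assign a repeat-unit count from an m/z value and charge
#'
#' Inverts the oligomer ion mass relation
#' `z * mz = n * repeat_mass + end_group_mass + z * adduct_mass_per_charge`
#' for the repeat-unit count `n`, rounding to the nearest integer. The
#' residual between the observed and back-computed m/z is reported; an
#' assignment whose absolute mass residual exceeds half a repeat unit is
#' flagged, which surfaces a wrong adduct or end-group convention
#' immediately.
#'
#' @param mz Observed mass-to-charge ratio.
#' @param z Integer charge (`>= 1`).
#' @param repeat_mass Repeat-unit mass in Da (default 46.05, the
#'   carbon-13-labeled ethylene-oxide unit; use 44.03 for unlabeled
#'   material).
#' @param end_group_mass Combined end-group mass in Da (default 18.01,
#'   H and OH).
#' @param adduct_mass_per_charge Adduct mass per charge in Da (default
#'   1.007, protonation).
#' @return A list with `n` (integer repeat units), `mw` (the neutral mass
#'   `n * repeat_mass + end_group_mass`), `residual_da` (observed minus
#'   computed neutral mass) and `flagged` (residual beyond half a repeat
#'   unit).
#' @examples
#' assign_repeat_units(1758, 2)  # n = 76
#' assign_repeat_units(1873, 2)  # n = 81
#' @export
assign_repeat_units <- function(mz, z, repeat_mass = 46.05,
                                end_group_mass = 18.01,
                                adduct_mass_per_charge = 1.007) {
  check_positive(mz, "mz")
  z <- check_count(z, "z")
  check_positive(repeat_mass, "repeat_mass")
  neutral <- z * mz - end_group_mass - z * adduct_mass_per_charge
  n <- as.integer(round(neutral / repeat_mass))
  if (n < 1L) {
    stop_domain("m/z %g at charge %d implies a nonpositive repeat count", mz, z)
  }
  residual <- neutral - n * repeat_mass
  list(n = n, mw = n * repeat_mass + end_group_mass,
       residual_da = residual,
       flagged = abs(residual) > 0.5 * repeat_mass)
}

#' Construct a peak table
#'
#' A peak table holds one row per chromatographic feature: resolved
#' oligomer peaks carry a MW (directly, or via m/z and charge which are
#' converted through [assign_repeat_units()]), and up to one `lump_low` and
#' one `lump_high` row carry the unresolved integrals outside the resolved
#' window without a MW.
#'
#' @param kind Character vector: `"resolved"`, `"lump_low"` or
#'   `"lump_high"` per row.
#' @param integral Nonnegative detector integrals (CAD response, arbitrary
#'   units, proportional to mass).
#' @param mw_da MW per row in Da (`NA` for lumps and for rows assigned from
#'   m/z).
#' @param mz,z Optional m/z and charge per row; used when `mw_da` is `NA`.
#'   When both a MW and an m/z are present the MW takes precedence (a
#'   message is emitted).
#' @param rt_min Optional retention times, carried through untouched.
#' @param repeat_mass,end_group_mass,adduct_mass_per_charge Assignment
#'   constants, see [assign_repeat_units()].
#' @return An object of class `peak_table`: a data frame with columns
#'   `kind`, `mw_da`, `mz`, `z`, `integral`, `rt_min`, resolved rows sorted
#'   by increasing MW.
#' @export
peak_table <- function(kind, integral, mw_da = NA_real_, mz = NA_real_,
                       z = NA_integer_, rt_min = NA_real_,
                       repeat_mass = 46.05, end_group_mass = 18.01,
                       adduct_mass_per_charge = 1.007) {
  nr <- length(kind)
  df <- data.frame(kind = as.character(kind),
                   mw_da = rep_len(as.numeric(mw_da), nr),
                   mz = rep_len(as.numeric(mz), nr),
                   z = rep_len(as.integer(z), nr),
                   integral = rep_len(as.numeric(integral), nr),
                   rt_min = rep_len(as.numeric(rt_min), nr))
  bad_kind <- !df$kind %in% c("resolved", "lump_low", "lump_high")
  if (any(bad_kind)) {
    stop_domain("invalid kind in row(s) %s",
                paste(which(bad_kind), collapse = ", "))
  }
  if (any(!is.finite(df$integral) | df$integral < 0)) {
    stop_domain("negative or missing integral in row(s) %s",
                paste(which(!is.finite(df$integral) | df$integral < 0),
                      collapse = ", "))
  }
  for (lk in c("lump_low", "lump_high")) {
    if (sum(df$kind == lk) > 1L) stop_domain("duplicate %s row", lk)
  }
  res <- df$kind == "resolved"
  need_assign <- res & is.na(df$mw_da)
  if (any(res & !is.na(df$mw_da) & !is.na(df$mz))) {
    message("rows with both mw_da and mz: mw_da takes precedence")
  }
  if (any(need_assign)) {
    if (any(need_assign & (is.na(df$mz) | is.na(df$z)))) {
      stop_domain("resolved row(s) %s have neither mw_da nor (mz, z)",
                  paste(which(need_assign & (is.na(df$mz) | is.na(df$z))),
                        collapse = ", "))
    }
    for (i in which(need_assign)) {
      a <- assign_repeat_units(df$mz[i], df$z[i], repeat_mass,
                               end_group_mass, adduct_mass_per_charge)
      df$mw_da[i] <- a$mw
      if (a$flagged) {
        warning(sprintf(
          "row %d: m/z assignment residual %.2f Da exceeds half a repeat unit",
          i, a$residual_da))
      }
    }
  }
  ord <- c(which(df$kind == "lump_low"),
           which(res)[order(df$mw_da[res])],
           which(df$kind == "lump_high"))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (any(duplicated(df$mw_da[df$kind == "resolved"]))) {
    stop_domain("duplicate resolved MW values")
  }
  structure(df, class = c("peak_table", "data.frame"))
}

#' Read a peak table from CSV
#'
#' The schema is one row per peak with columns `kind` (`resolved`,
#' `lump_low`, `lump_high`), `integral`, and either `mw_da` or the pair
#' `mz`, `z`; `rt_min` is optional and passed through. Unknown columns are
#' ignored with a warning. Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @param ... Assignment constants forwarded to [peak_table()].
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path, ...) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  known <- c("kind", "mw_da", "mz", "z", "integral", "rt_min")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  if (!"kind" %in% names(df)) stop_domain("missing 'kind' column")
  if (!"integral" %in% names(df)) stop_domain("missing 'integral' column")
  get <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  peak_table(kind = df$kind, integral = df$integral,
             mw_da = get("mw_da", NA_real_), mz = get("mz", NA_real_),
             z = get("z", NA_integer_), rt_min = get("rt_min", NA_real_),
             ...)
}

#' Write a peak table to CSV
#'
#' @param table A `peak_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Normalize a peak table into an experimental cumulative MW curve
#'
#' Divides each integral by the grand total (the CAD response is mass
#' proportional, so this is wt\%), accumulates the resolved rows in
#' increasing MW on top of the low-MW lump, and attaches the lumps at the
#' censoring boundaries: the curve starts at `lump_low` wt\% at the low
#' boundary and its final resolved value plus `lump_high` is 100.
#'
#' @param table A `peak_table` with positive total integral.
#' @param low_bound_da,high_bound_da Censoring boundaries of the resolved
#'   window in Da (defaults 2000 and 6400).
#' @return An object of class `fit_input`: a `cumulative_mw_curve` plus
#'   `low_bound_da`, `high_bound_da` and provenance attributes.
#' @export
to_fit_input <- function(table, low_bound_da = 2000, high_bound_da = 6400) {
  stopifnot(inherits(table, "peak_table"))
  if (low_bound_da >= high_bound_da) {
    stop_domain("censoring bounds inverted: low %g >= high %g",
                low_bound_da, high_bound_da)
  }
  tot <- sum(table$integral)
  if (tot <= 0) stop_domain("total integral must be positive")
  wt <- 100 * table$integral / tot
  lump_low <- sum(wt[table$kind == "lump_low"])
  lump_high <- sum(wt[table$kind == "lump_high"])
  res <- table$kind == "resolved"
  if (!any(res)) stop_domain("peak table has no resolved rows")
  mw <- table$mw_da[res]
  cum <- lump_low + cumsum(wt[res])
  curve <- new_cumulative_curve(mw, cum, lump_low = lump_low,
                                lump_high = lump_high)
  structure(c(curve, list(low_bound_da = low_bound_da,
                          high_bound_da = high_bound_da,
                          normalization_total = tot)),
            class = c("fit_input", "cumulative_mw_curve"))
}

#' @export
print.fit_input <- function(x, ...) {
  cat(sprintf(
    "Experimental cumulative MW curve: %d resolved points in [%g, %g] Da\n",
    length(x$mw_da), x$low_bound_da, x$high_bound_da))
  cat(sprintf("  lump below %g Da: %.3g wt%%; lump above %g Da: %.3g wt%%\n",
              x$low_bound_da, x$lump_low, x$high_bound_da, x$lump_high))
  invisible(x)
}
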