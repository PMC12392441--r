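# Closed-form pseudo-first-order kinetics of chain scission.
#
# A monomer unit reacts with hydroxyl radical at second-order rate constant
# kM under a steady-state radical concentration [OH]ss, giving a
# pseudo-first-order rate k1 = kM * [OH]ss. The average number of scissions
# per initial chain after time t is the reacted monomer fraction times the
# initial degree of polymerization, and the number-average MW follows the
# classical 1/(S+1) decay.

#' Kinetics parameters for pseudo-first-order chain scission
#'
#' Bundles the constants of the closed-form scission model: the second-order
#' rate constant of a monomer unit with hydroxyl radical, the steady-state
#' radical concentration, the initial number-average molecular weight and the
#' monomer mass.
#'
#' @param kM Second-order rate constant of a monomer unit with the hydroxyl
#'   radical, in 1/(M s). Default `2.1e9`, the experimental value for
#'   polyethylene glycol.
#' @param oh_ss Steady-state hydroxyl-radical concentration in mol/L. Sunlit
#'   surface waters span roughly `1e-17` to `1e-15` M.
#' @param mn0 Initial number-average molecular weight in Da.
#' @param mw_monomer Monomer molecular weight in Da (default 44, the
#'   unlabeled ethylene-oxide repeat unit).
#' @return An object of class `kinetics_params`.
#' @examples
#' kp <- kinetics_params(oh_ss = 1e-16, mn0 = 6380)
#' scissions_per_chain(kp, 86400)
#' @export
kinetics_params <- function(kM = 2.1e9, oh_ss, mn0, mw_monomer = 44) {
  check_positive(kM, "kM")
  check_positive(oh_ss, "oh_ss")
  check_positive(mn0, "mn0")
  check_positive(mw_monomer, "mw_monomer")
  if (mn0 < mw_monomer) {
    stop_domain("'mn0' (%g Da) must be at least one monomer mass (%g Da)",
                mn0, mw_monomer)
  }
  structure(list(kM = kM, oh_ss = oh_ss, mn0 = mn0, mw_monomer = mw_monomer),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Pseudo-first-order scission kinetics parameters\n")
  cat(sprintf("  kM          : %g /M/s\n", x$kM))
  cat(sprintf("  [OH]ss      : %g M   (k1 = %g /s)\n",
              x$oh_ss, pseudo_first_order_rate(x$kM, x$oh_ss)))
  cat(sprintf("  Mn(t0)      : %g Da\n", x$mn0))
  cat(sprintf("  monomer MW  : %g Da  (DP0 = %.4g)\n",
              x$mw_monomer, x$mn0 / x$mw_monomer))
  invisible(x)
}

#' Pseudo-first-order rate constant
#'
#' `k1 = kM * [OH]ss`: the product of the second-order monomer rate constant
#' and the steady-state hydroxyl-radical concentration.
#'
#' @param kM Second-order rate constant, 1/(M s).
#' @param oh_ss Steady-state radical concentration, M.
#' @return The pseudo-first-order rate constant in 1/s.
#' @examples
#' pseudo_first_order_rate(2.1e9, 1e-16)  # 2.1e-7 /s
#' @export
pseudo_first_order_rate <- function(kM, oh_ss) {
  check_positive(kM, "kM")
  check_positive(oh_ss, "oh_ss")
  kM * oh_ss
}

#' Average number of scissions per initial chain at time t
#'
#' The fraction of monomer units that have reacted by time `t`,
#' `1 - exp(-k1 t)`, multiplied by the initial average degree of
#' polymerization `mn0 / mw_monomer`. Every monomer unit of a chain is
#' assumed equally likely to react.
#'
#' @param params A [kinetics_params()] object.
#' @param t Reaction time in seconds (vectorized, each `>= 0`).
#' @return The dimensionless average scissions per initial chain.
#' @examples
#' kp <- kinetics_params(oh_ss = 1e-16, mn0 = 6380)
#' scissions_per_chain(kp, c(0, 86400))
#' @export
scissions_per_chain <- function(params, t) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_domain("'t' must be nonnegative and finite")
  }
  k1 <- params$kM * params$oh_ss
  dp0 <- params$mn0 / params$mw_monomer
  x <- k1 * t
  # guard against exp() underflow at extreme exposures: the reacted fraction
  # is exactly 1 to double precision for k1*t > 700
  frac <- ifelse(x > 700, 1, -expm1(-x))
  frac * dp0
}

#' Number-average molecular weight after a given scission extent
#'
#' Each scission adds one chain while conserving monomer mass, so the
#' number-average MW decays as `mn0 / (sic + 1)`.
#'
#' @param mn0 Initial number-average MW in Da.
#' @param sic Average scissions per initial chain (vectorized, each `>= 0`).
#' @return Number-average MW in Da.
#' @examples
#' mn_from_scissions(6380, 1)  # halved
#' @export
mn_from_scissions <- function(mn0, sic) {
  check_positive(mn0, "mn0")
  if (any(!is.finite(sic)) || any(sic < 0)) {
    stop_domain("'sic' must be nonnegative and finite")
  }
  mn0 / (sic + 1)
}

#' Time required to reach a target scission extent
#'
#' Inverts the closed-form scission model:
#' `t = -log(1 - sic * mw_monomer / mn0) / k1`. The target must be strictly
#' below the saturation value `mn0 / mw_monomer` (the reacted monomer
#' fraction cannot exceed 1).
#'
#' @param params A [kinetics_params()] object.
#' @param sic_target Target average scissions per initial chain.
#' @return Reaction time in seconds.
#' @examples
#' kp <- kinetics_params(oh_ss = 1e-16, mn0 = 6380)
#' time_for_scissions(kp, scissions_per_chain(kp, 86400))  # 86400 s
#' @export
time_for_scissions <- function(params, sic_target) {
  stopifnot(inherits(params, "kinetics_params"))
  check_nonnegative(sic_target, "sic_target")
  dp0 <- params$mn0 / params$mw_monomer
  if (sic_target >= dp0) {
    stop_domain(paste0(
      "scission extent %g is unreachable: the reacted monomer fraction ",
      "cannot exceed 1 (saturation at %g scissions per chain)"),
      sic_target, dp0,
      class = "scission_unreachable_error")
  }
  k1 <- params$kM * params$oh_ss
  -log1p(-sic_target / dp0) / k1
}

#' Tabulate the closed-form kinetics over a time grid
#'
#' @param params A [kinetics_params()] object.
#' @param t_grid Nonempty, nondecreasing vector of nonnegative times in
#'   seconds.
#' @return A data frame with columns `t_s`, `k1_per_s`, `sic` and `mn_da`;
#'   `sic` is nondecreasing and `mn_da` nonincreasing down the rows.
#' @examples
#' kp <- kinetics_params(oh_ss = 1e-16, mn0 = 6380)
#' kinetics_profile(kp, c(0, 3600, 86400, 864000))
#' @export
kinetics_profile <- function(params, t_grid) {
  stopifnot(inherits(params, "kinetics_params"))
  if (length(t_grid) == 0L) stop_domain("'t_grid' must be nonempty")
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) {
    stop_domain("'t_grid' must be nonnegative and finite")
  }
  if (is.unsorted(t_grid)) {
    stop_domain("'t_grid' must be nondecreasing")
  }
  sic <- scissions_per_chain(params, t_grid)
  data.frame(
    t_s = t_grid,
    k1_per_s = params$kM * params$oh_ss,
    sic = sic,
    mn_da = mn_from_scissions(params$mn0, sic)
  )
}
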