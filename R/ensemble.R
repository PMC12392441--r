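# Chain ensembles: the simulator's state is a histogram of chain lengths
# (monomer units -> chain count), plus the monomer mass. The chain MW
# convention is MW = n * mw_monomer exactly, with no end-group mass, matching
# the closed-form kinetics.

#' Specification of an initial chain ensemble
#'
#' Describes an ensemble of `m` chains whose lengths follow a discretized
#' normal distribution: the normal density is evaluated at integer lengths
#' `n >= 1`, truncated and renormalized. Counts are assigned either by
#' deterministic largest-remainder apportionment of `p(n) * m` (the default,
#' bit-reproducible) or by multinomial sampling.
#'
#' @param m Total initial chain count (positive integer).
#' @param lambda_len Mean chain length in monomer units (may be fractional);
#'   use [da_to_length()] to convert a mean MW in Da.
#' @param sigma_len Standard deviation of chain length in monomer units
#'   (`>= 0`; 0 gives a monodisperse ensemble at `round(lambda_len)`).
#' @param mw_monomer Monomer molecular weight in Da (default 44).
#' @param rounding_policy `"deterministic"` (largest-remainder apportionment)
#'   or `"multinomial"` (sampled counts, needs a seed at build time).
#' @return An object of class `ensemble_spec`.
#' @examples
#' # the reference distribution: 6380 +/- 400 Da
#' ensemble_spec(5000, da_to_length(6380), da_to_length(400))
#' @export
ensemble_spec <- function(m, lambda_len, sigma_len, mw_monomer = 44,
                          rounding_policy = c("deterministic", "multinomial")) {
  m <- check_count(m, "m")
  check_positive(lambda_len, "lambda_len")
  if (lambda_len < 1) stop_domain("'lambda_len' must be >= 1 monomer unit")
  check_nonnegative(sigma_len, "sigma_len")
  check_positive(mw_monomer, "mw_monomer")
  rounding_policy <- match.arg(rounding_policy)
  structure(list(m = m, lambda_len = lambda_len, sigma_len = sigma_len,
                 mw_monomer = mw_monomer, rounding_policy = rounding_policy),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "Ensemble spec: m = %d chains, length ~ N(%.4g, %.4g) (monomer units),\n",
    x$m, x$lambda_len, x$sigma_len))
  cat(sprintf("  monomer %g Da (mean MW %.4g Da), %s rounding\n",
              x$mw_monomer, x$lambda_len * x$mw_monomer, x$rounding_policy))
  invisible(x)
}

#' Chain-length-dependent rate model
#'
#' The scission rate constant of a whole chain of `n` monomer units is
#' piecewise in `n`: proportional to `n` for short chains (every monomer
#' fully exposed) and sublinear beyond a breakpoint where coiling shields
#' part of the backbone,
#' \deqn{k(n) = 0.8\, k_M\, n \quad (n \le 30), \qquad
#'       k(n) = 0.8\, k_M\, 30\, (n/30)^{0.57} \quad (n > 30),}
#' continuous at the breakpoint by construction.
#'
#' @param kM Second-order monomer rate constant, 1/(M s) (default 2.1e9).
#' @param prefactor Dimensionless prefactor (default 0.8).
#' @param breakpoint Chain length at which the scaling changes (default 30).
#' @param exponent Sublinear exponent above the breakpoint (default 0.57).
#' @return An object of class `rate_model`.
#' @examples
#' rm <- rate_model()
#' chain_rate_constant(c(10, 30, 300), rm)
#' @export
rate_model <- function(kM = 2.1e9, prefactor = 0.8, breakpoint = 30,
                       exponent = 0.57) {
  check_positive(kM, "kM")
  check_positive(prefactor, "prefactor")
  breakpoint <- check_count(breakpoint, "breakpoint")
  check_positive(exponent, "exponent")
  structure(list(kM = kM, prefactor = prefactor, breakpoint = breakpoint,
                 exponent = exponent),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "Chain scission rate model: k(n) = %g * %g * min(n, %d) * (max(n/%d, 1))^%g\n",
    x$prefactor, x$kM, x$breakpoint, x$breakpoint, x$exponent))
  invisible(x)
}

#' Scission rate constant of a chain of given length
#'
#' @param n Integer chain length(s) in monomer units, each `>= 1`.
#' @param model A [rate_model()].
#' @return Rate constant(s) in 1/(M s); strictly increasing in `n` and
#'   continuous at the breakpoint.
#' @export
chain_rate_constant <- function(n, model = rate_model()) {
  stopifnot(inherits(model, "rate_model"))
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop_domain("chain length 'n' must be integer >= 1")
  }
  b <- model$breakpoint
  base <- model$prefactor * model$kM
  ifelse(n <= b, base * n, base * b * (n / b)^model$exponent)
}

# --- chain_ensemble -------------------------------------------------------

new_chain_ensemble <- function(counts, mw_monomer) {
  # counts: integer vector, counts[n] = number of chains of length n.
  # Trailing empty classes are trimmed so the representation is canonical
  # (serialization round-trips identically).
  counts <- as.numeric(counts)  # numeric: counts can exceed .Machine max int sums
  last <- max(which(counts > 0))
  counts <- counts[seq_len(last)]
  structure(list(counts = counts, mw_monomer = mw_monomer),
            class = "chain_ensemble")
}

#' Construct a chain ensemble from explicit length counts
#'
#' @param lengths Integer chain lengths in monomer units.
#' @param counts Chain count per length (same length as `lengths`).
#' @param mw_monomer Monomer molecular weight in Da.
#' @return A `chain_ensemble` object.
#' @examples
#' chain_ensemble(c(10, 100), c(1, 1))
#' @export
chain_ensemble <- function(lengths, counts, mw_monomer = 44) {
  if (length(lengths) != length(counts)) {
    stop_domain("'lengths' and 'counts' must have equal length")
  }
  if (any(lengths < 1) || any(lengths != round(lengths))) {
    stop_domain("chain lengths must be integers >= 1")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("chain counts must be nonnegative integers")
  }
  check_positive(mw_monomer, "mw_monomer")
  v <- numeric(max(lengths))
  for (i in seq_along(lengths)) {
    v[lengths[i]] <- v[lengths[i]] + counts[i]
  }
  if (sum(v) < 1) stop_domain("ensemble must contain at least one chain")
  new_chain_ensemble(v, mw_monomer)
}

#' @export
print.chain_ensemble <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf(
    "Chain ensemble: %g chains, %g monomer units, lengths %d..%d (%d classes)\n",
    sum(x$counts), sum(x$counts * seq_along(x$counts)),
    min(occ), max(occ), length(occ)))
  cat(sprintf("  monomer %g Da; Mn = %.4g Da, Mw = %.4g Da, dispersity %.4f\n",
              x$mw_monomer, number_average_mw(x), weight_average_mw(x),
              dispersity(x)))
  invisible(x)
}

# density of the discretized, truncated normal on integers n >= 1
discrete_length_pmf <- function(lambda_len, sigma_len) {
  nmax <- max(ceiling(lambda_len + 8 * max(sigma_len, 1)), ceiling(lambda_len) + 1)
  n <- seq_len(nmax)
  p <- stats::dnorm(n, mean = lambda_len, sd = sigma_len)
  s <- sum(p)
  if (s <= 0) stop_domain("degenerate length distribution: density underflows")
  p / s
}

#' Build the initial chain ensemble from a spec
#'
#' Evaluates the normal length density at integer lengths `n >= 1`,
#' renormalizes, and converts the probabilities to whole-chain counts. The
#' deterministic policy uses largest-remainder apportionment (floor every
#' quota `p(n) * m`, then hand out the remaining chains to the largest
#' fractional remainders, ties to the shorter chain), so the result is
#' identical across runs and platforms. The multinomial policy draws counts
#' with the given seed.
#'
#' @param spec An [ensemble_spec()].
#' @param seed Integer seed, used only under the multinomial policy.
#' @return A `chain_ensemble` with total count exactly `spec$m`.
#' @examples
#' spec <- ensemble_spec(5000, 145, 9.09)
#' ens <- build_initial_ensemble(spec)
#' number_average_mw(ens)
#' @export
build_initial_ensemble <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$sigma_len == 0) {
    n0 <- max(1L, as.integer(round(spec$lambda_len)))
    v <- numeric(n0)
    v[n0] <- spec$m
    return(new_chain_ensemble(v, spec$mw_monomer))
  }
  p <- discrete_length_pmf(spec$lambda_len, spec$sigma_len)
  if (spec$rounding_policy == "deterministic") {
    quota <- p * spec$m
    cnt <- floor(quota)
    rem <- spec$m - sum(cnt)
    if (rem > 0) {
      ord <- order(quota - cnt, -seq_along(quota), decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
  } else {
    set.seed(seed)
    cnt <- as.numeric(stats::rmultinom(1, spec$m, p))
  }
  new_chain_ensemble(cnt, spec$mw_monomer)
}

#' Selection probabilities per chain-length class
#'
#' In each simulation step a chain is selected for scission with probability
#' proportional to its length-specific rate constant; the per-class weight
#' is therefore `m(n) * k(n)`, normalized over eligible classes. Chains
#' shorter than `eligible_min_length` (default 2: monomers, the terminal
#' product, cannot be cleaved) receive weight zero.
#'
#' @param ensemble A `chain_ensemble`.
#' @param model A [rate_model()].
#' @param eligible_min_length Minimum cleavable chain length (default 2).
#' @return Numeric vector `w` with `w[n]` the probability that the next
#'   scission hits a chain of length `n`; sums to 1.
#' @export
selection_weights <- function(ensemble, model = rate_model(),
                              eligible_min_length = 2L) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  counts <- ensemble$counts
  n <- seq_along(counts)
  w <- counts * chain_rate_constant(n, model)
  if (eligible_min_length > 1) w[seq_len(eligible_min_length - 1L)] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    stop_domain("no eligible chain left to cleave (all chains below length %d)",
                eligible_min_length, class = "scission_exhausted_error")
  }
  w / tot
}

#' Ensemble molecular-weight averages and dispersity
#'
#' Number-average MW weights every chain equally; weight-average MW weights
#' each chain by its mass. The dispersity is their ratio and is `>= 1` for
#' any ensemble.
#'
#' @param ensemble A `chain_ensemble`.
#' @return A scalar in Da (`number_average_mw`, `weight_average_mw`) or
#'   dimensionless (`dispersity`).
#' @examples
#' e <- chain_ensemble(c(1, 3), c(1, 1))
#' number_average_mw(e)  # 88
#' weight_average_mw(e)  # 110
#' dispersity(e)         # 1.25
#' @export
number_average_mw <- function(ensemble) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  counts <- ensemble$counts
  tot <- sum(counts)
  if (tot <= 0) stop_domain("empty ensemble")
  n <- seq_along(counts)
  ensemble$mw_monomer * sum(n * counts) / tot
}

#' @rdname number_average_mw
#' @export
weight_average_mw <- function(ensemble) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  counts <- ensemble$counts
  if (sum(counts) <= 0) stop_domain("empty ensemble")
  n <- seq_along(counts)
  ensemble$mw_monomer * sum(n^2 * counts) / sum(n * counts)
}

#' @rdname number_average_mw
#' @export
dispersity <- function(ensemble) {
  weight_average_mw(ensemble) / number_average_mw(ensemble)
}

#' Read or write a chain ensemble as two-column CSV
#'
#' The on-disk form is a plain CSV with columns `length_n` and `count`
#' (occupied length classes only); a `# mw_monomer:` comment line carries
#' the monomer mass. Write-then-read round-trips exactly.
#'
#' @param ensemble A `chain_ensemble`.
#' @param path File path.
#' @return `read_ensemble_csv` returns a `chain_ensemble`;
#'   `write_ensemble_csv` returns `path` invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  occ <- which(ensemble$counts > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mw_monomer: %.10g", ensemble$mw_monomer), con)
  utils::write.csv(
    data.frame(length_n = occ, count = ensemble$counts[occ]),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @param mw_monomer Monomer mass override; defaults to the value stored in
#'   the file header (44 if absent).
#' @export
read_ensemble_csv <- function(path, mw_monomer = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(mw_monomer)) {
    m <- grep("mw_monomer:", hdr, value = TRUE)
    mw_monomer <- if (length(m)) as.numeric(sub(".*mw_monomer:\\s*", "", m[1])) else 44
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (!all(c("length_n", "count") %in% names(df))) {
    stop_domain("ensemble CSV must have columns 'length_n' and 'count'")
  }
  chain_ensemble(df$length_n, df$count, mw_monomer)
}
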