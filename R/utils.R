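# Internal validation helpers shared across the package.

stop_domain <- function(msg, ..., class = "scission_domain_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_domain("'%s' must be a single strictly positive number (got %s)",
                name, deparse(substitute(x)))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_domain("'%s' must be a single nonnegative number", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_domain("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

#' Convert a molecular weight to a chain length in monomer units
#'
#' Mean and spread of a chain-length distribution are often quoted in Daltons
#' (e.g. "6380 +/- 400 Da"). Chain lengths in this package are monomer counts;
#' the conversion is a plain division by the monomer mass and is kept explicit
#' rather than implicit in constructors.
#'
#' @param mw_da Molecular weight (or a standard deviation of MW) in Daltons.
#' @param mw_monomer Monomer molecular weight in Daltons (default 44).
#' @return Chain length in monomer units (possibly fractional).
#' @examples
#' da_to_length(6380)      # 145 monomer units
#' da_to_length(400)       # ~9.09, the spread of the reference distribution
#' @export
da_to_length <- function(mw_da, mw_monomer = 44) {
  check_positive(mw_monomer, "mw_monomer")
  if (any(mw_da < 0)) stop_domain("'mw_da' must be nonnegative")
  mw_da / mw_monomer
}
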