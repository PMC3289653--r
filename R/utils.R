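# Shared numerical helpers.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain -Inf).
#' @return log(sum(exp(x))) computed without overflow/underflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
logsumexp_rows <- function(X) {
  m <- apply(X, 1L, max)
  out <- m + log(rowSums(exp(X - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# kT in kcal/mol at temperature T (Kelvin); R in kcal/(mol K).
BOLTZ_KCAL <- 0.0019872041

#' Thermal energy in kcal/mol
#'
#' @param temperature temperature in Kelvin.
#' @return kT in kcal/mol (0.596 kcal/mol at 300 K).
#' @export
kT_kcal <- function(temperature = 300) BOLTZ_KCAL * temperature

# Coulomb constant in kcal * Angstrom / (mol * e^2).
COULOMB_KCAL <- 332.06
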