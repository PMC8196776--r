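# Internal helpers shared across modules: polynomial arithmetic in ascending
# coefficient order, classed error conditions, and small numeric utilities.

xcp_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "xcp_error")))
}

xcp_assert <- function(cond, class, msg) {
  if (!isTRUE(cond)) xcp_error(class, msg)
  invisible(TRUE)
}

#' Evaluate a polynomial with ascending coefficients
#'
#' @param coefs numeric vector, `coefs[i]` multiplies `x^(i-1)`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
#' @noRd
poly_eval <- function(coefs, x) {
  # Horner's scheme, vectorised over x
  out <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1L) {
    for (i in seq(length(coefs) - 1L, 1L)) out <- out * x + coefs[i]
  }
  out
}

poly_deriv <- function(coefs) {
  n <- length(coefs)
  if (n <= 1L) return(0)
  coefs[-1L] * seq_len(n - 1L)
}

# Real roots of a polynomial (ascending coefficients), via polyroot with an
# imaginary-part tolerance scaled to the root magnitude.
poly_real_roots <- function(coefs, tol = 1e-7) {
  # strip trailing (near-)zero leading coefficients
  nz <- which(abs(coefs) > 0)
  if (length(nz) == 0L) return(numeric(0))
  coefs <- coefs[seq_len(max(nz))]
  if (length(coefs) <= 1L) return(numeric(0))
  r <- polyroot(coefs)
  keep <- abs(Im(r)) <= tol * pmax(1, abs(r))
  sort(Re(r[keep]))
}

# Round to 0.01 W resolution, ties toward lower power.
round_resolution <- function(x, resolution = 0.01) {
  q <- x / resolution
  f <- floor(q)
  up <- (q - f) > 0.5 + 1e-12   # strict: exact .5 goes down
  (f + as.numeric(up)) * resolution
}

# Seed derivation for per-athlete substreams; keeps results < 2^31.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1000003 * as.double(index) +
    7919 * as.double(salt)
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
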