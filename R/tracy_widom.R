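# Tracy-Widom (GOE, beta = 1) distribution for tests on the leading
# eigenvalues of a genotype covariance matrix. The CDF is computed from the
# Painleve II representation: with q the Hastings-McLeod solution of
# q'' = s q + 2 q^3 (q(s) ~ Ai(s) as s -> +Inf),
#   F2(s) = exp(-int_s^Inf (x - s) q(x)^2 dx),
#   F1(s) = sqrt(F2(s)) * exp(-1/2 int_s^Inf q(x) dx).
# The ODE (augmented with the needed integrals) is solved once per session
# from s = 8 downward, initialized with the asymptotic Airy expansion, and
# the CDF cached on a fine grid.

tw_cache <- new.env(parent = emptyenv())

airy_asym <- function(s) {
  z <- 2 / 3 * s^1.5
  exp(-z) / (2 * sqrt(pi) * s^0.25) * (1 - 5 / (72 * z) + 385 / (10368 * z^2))
}
airy_prime_asym <- function(s) {
  z <- 2 / 3 * s^1.5
  -s^0.25 * exp(-z) / (2 * sqrt(pi)) * (1 + 7 / (72 * z) - 455 / (10368 * z^2))
}

tw1_table <- function() {
  if (!is.null(tw_cache$tab)) return(tw_cache$tab)
  s0 <- 8
  deriv <- function(s, y, p) {
    q <- y[1]
    list(c(y[2], s * q + 2 * q^3, -q, -q^2, -s * q^2))
  }
  a0 <- airy_asym(s0)
  y0 <- c(q = a0, qp = airy_prime_asym(s0),
          I1 = a0 / sqrt(s0), I2 = a0^2 / (2 * sqrt(s0)),
          R = a0^2 * sqrt(s0) / 2)
  ss <- seq(s0, -10, by = -0.005)
  sol <- deSolve::ode(y0, ss, deriv, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  f2 <- exp(-(sol[, "R"] - sol[, 1] * sol[, "I2"]))
  f1 <- sqrt(f2) * exp(-sol[, "I1"] / 2)
  tab <- list(s = rev(sol[, 1]), F1 = rev(pmin(pmax(f1, 0), 1)))
  tw_cache$tab <- tab
  tab
}

#' Tracy-Widom (GOE) upper-tail probability
#'
#' `P(TW1 > x)`, the significance of a standardized largest eigenvalue.
#'
#' @param x Numeric vector of standardized eigenvalue statistics.
#' @return Upper-tail probabilities (interpolated on a precomputed
#'   Painleve II solution; values beyond the grid are clamped to the grid
#'   ends, i.e. `1` below `-10` and `~3e-11` above `8`).
#' @export
tw1_pvalue <- function(x) {
  tab <- tw1_table()
  logp <- log(pmax(1 - tab$F1, 1e-300))
  out <- exp(stats::approx(tab$s, logp, xout = pmin(pmax(x, -10), 8),
                           rule = 2)$y)
  out[is.na(x)] <- NA_real_
  pmin(out, 1)
}
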