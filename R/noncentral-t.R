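#' Noncentral t density, vectorized over the noncentrality parameter
#'
#' Evaluates the density of the noncentral t distribution at a fixed
#' observation `t` with `nu` degrees of freedom, for a vector of
#' noncentrality parameters. This is the likelihood of the standardized
#' effect size in the JZS two-sample model, where the noncentrality is
#' `delta * sqrt(n_eff)`, so it must be fast over a dense grid of `ncp`
#' values.
#'
#' The density is computed from the scale-mixture representation
#' `T = (Z + ncp) / W`, `Z ~ N(0, 1)`, `W = sqrt(V / nu)`, `V ~ chisq(nu)`:
#' `f(t; nu, ncp) = E_W[ W * phi(t * W - ncp) ]`, with the expectation over
#' `W` evaluated by fixed Gauss-Legendre quadrature on the central
#' `1 - 2e-12` quantile range of `W`. The integrand is smooth, so 48 nodes
#' give absolute error near 1e-11 across `nu` from 3 to several hundred
#' (checked against [stats::dt()] in the test suite). Unlike
#' `stats::dt(ncp = )`, the evaluation is vectorized over `ncp` at
#' ~100 floating-point operations per grid point and never warns about
#' precision.
#'
#' @param t scalar observed t statistic.
#' @param nu degrees of freedom (positive scalar).
#' @param ncp numeric vector of noncentrality parameters.
#' @param nodes number of Gauss-Legendre nodes.
#' @return numeric vector of densities, one per element of `ncp`.
#' @examples
#' dt_noncentral(2.1, 18, c(-1, 0, 1, 2))
#' @export
dt_noncentral <- function(t, nu, ncp, nodes = 48L) {
  stopifnot(length(t) == 1L, is.finite(t), length(nu) == 1L, nu > 0)
  mix <- chi_mixture_nodes(nu, nodes)
  z <- outer(mix$w * t, ncp, "-")
  as.vector(crossprod(mix$coef, exp(-0.5 * z * z))) / sqrt(2 * pi)
}

# Quadrature nodes w over the distribution of W = sqrt(chisq(nu)/nu) and the
# combined weights omega * w * f_W(w); memoized per (nu, nodes) because the
# Bayes factor integrator re-evaluates the same-nu kernel many times.
.mix_cache <- new.env(parent = emptyenv())

chi_mixture_nodes <- function(nu, nodes) {
  key <- paste(format(nu, digits = 15), nodes, sep = "|")
  if (!is.null(.mix_cache[[key]])) return(.mix_cache[[key]])
  g <- gauss_legendre(nodes)
  qr <- sqrt(stats::qchisq(c(1e-12, 1 - 1e-12), df = nu) / nu)
  w <- (qr[2] - qr[1]) / 2 * g$x + (qr[1] + qr[2]) / 2
  omega <- (qr[2] - qr[1]) / 2 * g$w
  lfw <- log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
    (nu - 1) * log(w) - nu * w^2 / 2
  out <- list(w = w, coef = omega * w * exp(lfw))
  if (length(ls(.mix_cache)) > 200) rm(list = ls(.mix_cache), envir = .mix_cache)
  .mix_cache[[key]] <- out
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# construction; cached per node count since the kernel is called once per
# Monte-Carlo replicate.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- out
  out
}
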