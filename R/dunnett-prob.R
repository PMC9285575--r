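# Equicoordinate probability of the balanced Dunnett statistic:
# P(max_j |T_j| <= t) for m comparisons against a shared control with equal
# group sizes, i.e. a multivariate t with product correlation rho = 1/2 and
# `df` error degrees of freedom. Conditioning on the control-group variate z
# and the pooled scale s makes the coordinates independent:
#   P = E_{s} E_{z} [ Phi(z + sqrt(2) t s) - Phi(z - sqrt(2) t s) ]^m
# Both expectations are evaluated by Gauss-Legendre quadrature (the scale
# integral through its probability transform), giving ~1e-5 absolute
# accuracy deterministically.

gauss_legendre <- function(n, a, b) {
  j <- seq_len(n - 1)
  bb <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- bb
  J[cbind(j + 1, j)] <- bb
  e <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * e$values + (a + b) / 2,
       w = (b - a) * e$vectors[1, ]^2)
}

.dunnett_quad <- new.env(parent = emptyenv())

dunnett_prob <- function(t, m, df) {
  if (!is.finite(t)) return(as.numeric(t > 0))
  if (t <= 0) return(0)
  if (is.null(.dunnett_quad$u)) {
    .dunnett_quad$u <- gauss_legendre(64, 1e-7, 1 - 1e-7)
    .dunnett_quad$z <- gauss_legendre(96, -8, 8)
  }
  qu <- .dunnett_quad$u
  qz <- .dunnett_quad$z
  s <- sqrt(stats::qchisq(qu$x, df) / df)
  phi_w <- qz$w * stats::dnorm(qz$x)
  inner <- vapply(s, function(si) {
    a <- sqrt(2) * t * si
    sum(phi_w * (stats::pnorm(qz$x + a) - stats::pnorm(qz$x - a))^m)
  }, numeric(1))
  min(1, max(0, sum(qu$w * inner)))
}
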