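# Shared fixtures: the reference anchor (h^2 = 1.0%) and small oracles.

anchor_beta <- c(0.5744, 0.7183, 0.4564)
anchor_model <- chain_model(beta = anchor_beta)

# Brute-force tail moments by numerical integration of the standard normal
# density over [z, Inf); independent of the closed forms in the package.
integrate_tail_moments <- function(alpha) {
  z <- qnorm(1 - alpha)
  m0 <- integrate(dnorm, z, Inf, rel.tol = 1e-12)$value
  m1 <- integrate(function(y) y * dnorm(y), z, Inf, rel.tol = 1e-12)$value
  m2 <- integrate(function(y) y^2 * dnorm(y), z, Inf, rel.tol = 1e-12)$value
  lam <- m1 / m0
  list(
    z = z, lambda = lam,
    tail_var = m2 / m0 - lam^2,
    sel_m2 = m2 / m0 # symmetric tails: E[Y^2 | |Y| >= z] = E[Y^2 | Y >= z]
  )
}

# Strictly increasing until the power saturates at 1 in double precision,
# non-decreasing throughout.
increasing_to_saturation <- function(p) {
  d <- diff(p)
  below <- p[-length(p)] < 1 - 1e-12 & p[-1] < 1 - 1e-12
  all(d >= 0) && all(d[below] > 0)
}

# Random valid chain parameterisations for property-style loops.
random_params <- function() {
  list(
    maf = runif(1, 0.05, 0.5),
    beta = runif(3, 0.1, 1.5),
    error_var = runif(3, 0.5, 2)
  )
}
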