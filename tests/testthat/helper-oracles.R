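# Shared fixtures and independent oracles. Everything here deliberately
# avoids the package's own code paths where it serves as a cross-check.

R_ORACLE <- 8.314462618   # J/(mol K), restated independently of the package

# Default test scheme: two hydration steps with table-like thermochemistry.
test_scheme <- function(dH = c(-61.1, -50.2), dS = c(-66.1, -77.8),
                        forward_rates = 0.01) {
  kinetic_scheme(data.frame(dH = dH, dS = dS), forward_rates = forward_rates)
}

# Conditions chosen so the step ratios are O(0.1-1) and equilibration
# completes within a fraction of the drift time.
test_conditions <- function(temperature = 440, water_pressure = 0.1, ...) {
  cell_conditions(temperature = temperature, water_pressure = water_pressure,
                  ...)
}

# Closed-form equilibrium intensity ratio (independent restatement).
oracle_ratio <- function(dH, dS, temperature, water_pressure) {
  exp(-(dH * 1000 - temperature * dS) / (R_ORACLE * temperature)) *
    water_pressure / 1000
}

# Stationary distribution of a birth-death ladder from the product formula.
oracle_stationary <- function(ratios) {
  p <- c(1, cumprod(ratios))
  p / sum(p)
}

# Brute-force master-equation integration, fixed-step RK4 on dp/dt = Q p.
oracle_integrate_master <- function(Q, p0, t_end, dt = 0.1) {
  p <- p0
  steps <- ceiling(t_end / dt)
  dt <- t_end / steps
  f <- function(p) as.vector(Q %*% p)
  for (i in seq_len(steps)) {
    k1 <- f(p); k2 <- f(p + dt / 2 * k1)
    k3 <- f(p + dt / 2 * k2); k4 <- f(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p
}

# Plain normal-equations OLS oracle for y ~ 1 + x.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.vector(X %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       residuals = y - fitted, r_squared = 1 - ss_res / ss_tot)
}

# Weighted straight-line fit via explicit normal equations (no centring) —
# oracle for the package's centred implementation.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  beta <- solve(A, t(X) %*% (w * y))
  cov <- solve(A)
  list(intercept = beta[1], slope = beta[2],
       intercept_sigma = sqrt(cov[1, 1]), slope_sigma = sqrt(cov[2, 2]),
       cov_ab = cov[1, 2])
}

# Flat-top ATD pair with an exactly constant product/reactant ratio.
constant_ratio_pair <- function(ratio = 0.5, level = 1000, n_channels = 200) {
  times <- seq_len(n_channels) - 0.5
  reac <- atd_record("reactant", 1, 400, 0.1, times, rep(level, n_channels))
  prod <- atd_record("product", 2, 400, 0.1, times,
                     rep(round(level * ratio), n_channels))
  list(product = prod, reactant = reac)
}
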