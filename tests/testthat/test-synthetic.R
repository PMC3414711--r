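# synthetic_data: equilibrium ratios, rate matrices, ATD and K-series sims

test_that("equilibrium_ratio_from_thermo matches the closed form", {
  cond_std <- cell_conditions(temperature = 298, water_pressure = 999,
                              carrier_pressure = 1e4)
  # identity case: K = 1 at P = P_o
  cond_po <- cell_conditions(temperature = 298, water_pressure = 1000,
                             carrier_pressure = 1e4)
  expect_equal(equilibrium_ratio_from_thermo(0, 0, cond_po), 1)

  # table-derived case: dG = dH - T dS = -41.4022 kJ/mol at 298 K
  expected <- exp(41.4022 * 1000 / (8.314462618 * 298))
  expect_equal(equilibrium_ratio_from_thermo(-61.1, -66.1, cond_po),
               expected, tolerance = 1e-12)

  # linearity in P: halving the pressure halves the ratio
  cond_half <- cell_conditions(temperature = 440, water_pressure = 0.05)
  cond_full <- cell_conditions(temperature = 440, water_pressure = 0.10)
  expect_equal(equilibrium_ratio_from_thermo(-61.1, -66.1, cond_half),
               equilibrium_ratio_from_thermo(-61.1, -66.1, cond_full) / 2)

  expect_error(cell_conditions(temperature = -1), "positive")
  expect_error(equilibrium_constant_from_thermo(-61.1, -66.1, 0), "positive")
})

test_that("build_rate_matrix conserves probability and obeys detailed balance", {
  cond <- test_conditions()
  for (dH in list(c(-61.1, -50.2), c(-52.7, -47.7, -40))) {
    scheme <- test_scheme(dH = dH, dS = rep(-70, length(dH)))
    Q <- build_rate_matrix(scheme, cond)
    expect_equal(colSums(Q), rep(0, length(dH) + 1), tolerance = 1e-14)
    p <- stationary_distribution(Q)
    r <- attr(Q, "ratios")
    expect_equal(p[-1] / p[-length(p)], r, tolerance = 1e-10)
  }
  # two-state detailed balance with a hand-built ratio
  cond2 <- cell_conditions(temperature = 298, water_pressure = 1000,
                           carrier_pressure = 1e4)
  dS2 <- 8.314462618 * log(2)   # makes K = 2 at any T when dH = 0
  sch2 <- kinetic_scheme(data.frame(dH = 0, dS = dS2))
  p2 <- stationary_distribution(build_rate_matrix(sch2, cond2))
  expect_equal(p2[2] / p2[1], 2, tolerance = 1e-10)
})

test_that("stationary state agrees with product formula and brute-force ODE", {
  scheme <- test_scheme()
  cond <- test_conditions()
  Q <- build_rate_matrix(scheme, cond)
  p_svd <- stationary_distribution(Q)
  expect_equal(p_svd, oracle_stationary(attr(Q, "ratios")), tolerance = 1e-12)

  # long-time RK4 integration: 100x the slowest relaxation time
  tau <- 1 / min(abs(Re(eigen(Q)$values[abs(eigen(Q)$values) > 1e-12])))
  p_ode <- oracle_integrate_master(Q, c(1, 0, 0), 100 * tau, dt = tau / 200)
  expect_equal(p_ode, p_svd, tolerance = 1e-8)

  # package propagator reaches the same stationary state
  p_prop <- hydratherm:::propagate_populations(Q, c(1, 0, 0), 100 * tau)
  expect_equal(p_prop, p_svd, tolerance = 1e-10)
  # and agrees with RK4 at finite (pre-equilibrium) time
  p_mid_ode <- oracle_integrate_master(Q, c(1, 0, 0), 30, dt = 0.02)
  p_mid <- hydratherm:::propagate_populations(Q, c(1, 0, 0), 30)
  expect_equal(p_mid, p_mid_ode, tolerance = 1e-7)
})

test_that("simulate_atds is deterministic, linear in pulses, and equilibrates", {
  scheme <- test_scheme()
  cond <- test_conditions()
  ds1 <- simulate_atds(scheme, cond, seed = 42)
  ds2 <- simulate_atds(scheme, cond, seed = 42)
  expect_identical(lapply(ds1$atds, `[[`, "counts"),
                   lapply(ds2$atds, `[[`, "counts"))
  ds3 <- simulate_atds(scheme, cond, seed = 43)
  expect_false(identical(ds1$atds[[1]]$counts, ds3$atds[[1]]$counts))

  # expected counts scale linearly with n_pulses
  cond2 <- test_conditions(n_pulses = 2 * cond$n_pulses)
  ds_2x <- simulate_atds(scheme, cond2, seed = 42)
  expect_equal(ds_2x$atds[[1]]$expected, 2 * ds1$atds[[1]]$expected)

  # channel-summed ratio vs closed-form equilibrium ratio, 3 Poisson SE
  r1 <- oracle_ratio(-61.1, -66.1, cond$temperature, cond$water_pressure)
  I0 <- sum(ds1$atds[[1]]$counts)
  I1 <- sum(ds1$atds[[2]]$counts)
  se <- (I1 / I0) * sqrt(1 / I1 + 1 / I0)
  expect_lt(abs(I1 / I0 - r1), 3 * se)

  # every record carries its generating conditions and the seed is recorded
  expect_identical(ds1$seed, 42L)
  expect_equal(ds1$atds[[2]]$temperature, cond$temperature)
  expect_equal(ds1$atds[[2]]$water_pressure, cond$water_pressure)
})

test_that("Poisson counting noise has unit variance-to-mean ratio", {
  scheme <- test_scheme()
  cond <- test_conditions(n_pulses = 500)
  peak_ch <- round(cond$drift_time_mean)
  counts <- vapply(1:200, function(s) {
    simulate_atds(scheme, cond, seed = s)$atds[[1]]$counts[peak_ch]
  }, numeric(1))
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("simulate_k_series: noiseless line, frozen value, determinism", {
  temps <- seq(350, 550, length.out = 8)
  s0 <- simulate_k_series(-61.1, -66.1, temps, relative_noise = 0, seed = 1)
  # ln K exactly linear in 1/T
  fit <- lm(log(K) ~ I(1 / temperature_K), data = s0$points)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(s0$points$sigma_K, rep(0, 8))

  # frozen closed-form value at 298 K (Na+ hydration validation step)
  s298 <- simulate_k_series(-52.7, -100.4, 298, 0, 1)
  expect_equal(s298$points$K, exp(22.7808 * 1000 / (8.314462618 * 298)),
               tolerance = 1e-12)

  sa <- simulate_k_series(-61.1, -66.1, temps, 0.05, seed = 11)
  sb <- simulate_k_series(-61.1, -66.1, temps, 0.05, seed = 11)
  sc <- simulate_k_series(-61.1, -66.1, temps, 0.05, seed = 12)
  expect_identical(sa$points, sb$points)
  expect_false(identical(sa$points$K, sc$points$K))
  expect_equal(sa$points$sigma_K, 0.05 * sa$points$K)
})

test_that("ATD and series CSV round-trip bit-compatibly", {
  scheme <- test_scheme()
  ds <- simulate_atds(scheme, test_conditions(), seed = 5,
                      species_prefix = "UraNa+")
  f <- withr::local_tempfile(fileext = ".csv")
  write_atd_csv(ds$atds[[2]], f)
  header <- readLines(f, n = 1)
  expect_identical(header,
                   "species,temperature_K,water_pressure_mbar,time_us,counts")
  back <- read_atd_csv(f)
  expect_identical(back$counts, ds$atds[[2]]$counts)
  expect_identical(back$hydration_n, 1L)   # parsed from the label
  expect_equal(back$times, ds$atds[[2]]$times)

  s <- simulate_k_series(-61.1, -66.1, c(350, 400, 450), 0.05, seed = 2)
  g <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, g)
  expect_identical(readLines(g, n = 1), "temperature_K,K,sigma_K")
  expect_equal(read_series_csv(g)$points, s$points, tolerance = 1e-12)
})

test_that("end-to-end recovery: zero-noise series returns generating thermo", {
  for (th in list(c(-61.1, -66.1), c(-52.7, -100.4), c(-47.7, -83.7))) {
    s <- simulate_k_series(th[1], th[2], seq(330, 570, length.out = 5), 0, 1)
    f <- vant_hoff_fit(s)
    expect_equal(f$dH, th[1], tolerance = 1e-9)
    expect_equal(f$dS, th[2], tolerance = 1e-9)
  }
})
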