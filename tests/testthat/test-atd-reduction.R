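# atd_reduction: peak integration and the residence-time equilibrium test

test_that("atd_record validates its invariants", {
  t <- 1:10 - 0.5
  expect_error(atd_record("x", 0, 400, 0.1, t, rep(1, 9)), "equal length")
  expect_error(atd_record("x", 0, 400, 0.1, c(1, 3, 4), c(1, 1, 1)),
               "1 us spacing")
  expect_error(atd_record("x", 0, 400, 0.1, t, c(rep(1, 9), -1)),
               "non-negative")
  expect_error(atd_record("x", 0, 400, 0.1, t, c(rep(1, 9), 0.5)),
               "integers")
  expect_silent(atd_record("x", 0, 400, 0.1, t, c(rep(1, 9), 0.5),
                           integer_counts = FALSE))
})

test_that("integrate_atd: Poisson sums, baselines, degenerate input", {
  times <- 1:200 - 0.5
  zero <- atd_record("z", 0, 400, 0.1, times, rep(0, 200))
  pz <- integrate_atd(zero)
  expect_equal(pz$area, 0)
  expect_equal(pz$sigma, 0)

  # 100 counts in each of 10 window channels, zero baseline
  counts <- rep(0, 200); counts[101:110] <- 100
  flat <- atd_record("f", 0, 400, 0.1, times, counts)
  pa <- integrate_atd(flat, window = c(100.5, 109.5), baseline_channels = 50)
  expect_equal(pa$area, 1000)
  expect_equal(pa$sigma, sqrt(1000))
  expect_equal(pa$baseline_rate, 0)

  # constant baseline of 7 is removed exactly
  shifted <- atd_record("s", 0, 400, 0.1, times, counts + 7)
  pb <- integrate_atd(shifted, window = c(100.5, 109.5),
                      baseline_channels = 50)
  expect_equal(pb$area, 1000)
  expect_equal(pb$baseline_rate, 7)
  # variance picks up the baseline-estimate term: raw + (W/B)^2 * base_sum
  expect_equal(pb$sigma, sqrt(1070 + (10 / 50)^2 * 350))

  # area floored at zero when baseline exceeds the window
  dip <- atd_record("d", 0, 400, 0.1, times,
                    c(rep(10, 100), rep(0, 100)))
  expect_equal(integrate_atd(dip, window = c(150.5, 159.5),
                             baseline_channels = 50)$area, 0)

  expect_error(integrate_atd(flat, window = c(500, 600)), "outside")
})

test_that("integrate_atd is additive over adjacent windows at zero baseline", {
  ds <- simulate_atds(test_scheme(), test_conditions(), seed = 3)
  atd <- ds$atds[[1]]
  mid <- atd$times[round(length(atd$times) * 0.7)]
  a_all <- integrate_atd(atd, window = c(0, 1000), baseline_channels = 0)
  a_lo <- integrate_atd(atd, window = c(0, mid), baseline_channels = 0)
  a_hi <- integrate_atd(atd, window = c(mid + 1, 1000), baseline_channels = 0)
  expect_equal(a_lo$area + a_hi$area, a_all$area)
})

test_that("integrated area recovers the simulator expectation within 3 sigma", {
  scheme <- test_scheme()
  cond <- test_conditions()
  hits <- vapply(1:50, function(s) {
    ds <- simulate_atds(scheme, cond, seed = s)
    atd <- ds$atds[[1]]
    pa <- integrate_atd(atd, baseline_channels = 0)
    expected <- sum(atd$expected[atd$times >= pa$window[1] &
                                   atd$times <= pa$window[2]])
    abs(pa$area - expected) <= 3 * sqrt(expected)
  }, logical(1))
  expect_gte(sum(hits), 48)
})

test_that("ratio_vs_residence_time: constant ratio passes with zero slope", {
  pair <- constant_ratio_pair(ratio = 0.5, level = 1000)
  chk <- ratio_vs_residence_time(pair$product, pair$reactant, n_bins = 8)
  expect_equal(chk$slope, 0, tolerance = 1e-12)
  expect_equal(chk$ratio_mean, 0.5, tolerance = 1e-12)
  expect_true(chk$passed)
})

test_that("ratio test is symmetric under numerator/denominator swap", {
  pair <- constant_ratio_pair(ratio = 0.4, level = 2000)
  fwd <- ratio_vs_residence_time(pair$product, pair$reactant)
  rev <- ratio_vs_residence_time(pair$reactant, pair$product)
  expect_equal(fwd$ratio_mean, 1 / rev$ratio_mean, tolerance = 1e-9)
})

test_that("an injected 0.4 -> 0.6 ratio ramp at high counts is flagged", {
  n_ch <- 100
  times <- seq_len(n_ch) - 0.5
  reac_counts <- rep(10000L, n_ch)
  ramp <- seq(0.4, 0.6, length.out = n_ch)
  prod_counts <- as.integer(round(reac_counts * ramp))
  reac <- atd_record("r", 1, 400, 0.1, times, reac_counts)
  prod <- atd_record("p", 2, 400, 0.1, times, prod_counts)
  for (nb in c(5, 8, 10)) {
    chk <- ratio_vs_residence_time(prod, reac, n_bins = nb)
    expect_false(chk$passed)
    expect_gt(abs(chk$slope) / chk$slope_sigma, 2)
  }
})

test_that("equilibrated synthetic data rarely fails the 2-sigma test", {
  scheme <- test_scheme()
  cond <- test_conditions()
  fails <- vapply(1:100, function(s) {
    ds <- simulate_atds(scheme, cond, seed = 1000 + s)
    !ratio_vs_residence_time(ds$atds[[2]], ds$atds[[1]])$passed
  }, logical(1))
  # false-positive rate <= 10% at the 2-sigma rule (expected ~5%)
  expect_lte(sum(fails), 10)
})

test_that("count floor and bin minimum guard degenerate inputs", {
  times <- 1:30 - 0.5
  reac <- atd_record("r", 1, 400, 0.1, times, rep(3L, 30))
  prod <- atd_record("p", 2, 400, 0.1, times, rep(1L, 30))
  expect_error(ratio_vs_residence_time(prod, reac, n_bins = 25),
               "insufficient data")
  other <- atd_record("p", 2, 400, 0.1, 1:40 - 0.5, rep(1L, 40))
  expect_error(ratio_vs_residence_time(other, reac), "time axis")
  expect_error(ratio_vs_residence_time(prod, reac, n_bins = 2), "at least 3")
})
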