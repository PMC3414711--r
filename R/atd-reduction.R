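#' Arrival-time distribution record
#'
#' One multichannel-scaler histogram for one ion species at stated cell
#' temperature and water partial pressure: ion counts per 1 us channel
#' versus arrival time after the injection pulse.
#'
#' @param species_label Ion label, e.g. `"UraNa+(H2O)1"`.
#' @param hydration_n Number of attached waters, n >= 0.
#' @param temperature Cell temperature, K.
#' @param water_pressure Water partial pressure, mbar.
#' @param times Channel centres, us; strictly increasing with uniform 1 us
#'   spacing.
#' @param counts Non-negative integer counts, same length as `times`.
#' @param expected Optional noise-free expected counts (simulator
#'   bookkeeping for tests).
#' @param integer_counts Enforce integer counts (TRUE for measured data;
#'   the simulator's no-Poisson mode stores real-valued expectations).
#' @return An `atd_record` list.
#' @export
atd_record <- function(species_label, hydration_n, temperature,
                       water_pressure, times, counts, expected = NULL,
                       integer_counts = TRUE) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts)) {
    stop("times and counts must have equal length", call. = FALSE)
  }
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || any(abs(dt - 1) > 1e-9))) {
    stop("times must be strictly increasing with uniform 1 us spacing",
         call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (integer_counts && any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(species_label = as.character(species_label),
                 hydration_n = as.integer(hydration_n),
                 temperature = temperature,
                 water_pressure = water_pressure,
                 times = times,
                 counts = counts,
                 expected = expected),
            class = "atd_record")
}

#' @export
print.atd_record <- function(x, ...) {
  cat(sprintf("<atd_record> %s  n=%d  T=%.1f K  P(H2O)=%.3f mbar  %d channels, %d counts\n",
              x$species_label, x$hydration_n, x$temperature,
              x$water_pressure, length(x$times), sum(x$counts)))
  invisible(x)
}

#' Default integration window from peak moments
#'
#' Locates the modal channel and takes mode +/- 3 sigma-hat, with sigma-hat
#' a count-weighted moment estimate of the peak width. Used when no window
#' is supplied explicitly.
#'
#' @param atd An [atd_record()].
#' @param half_width_sigmas Half-width in units of sigma-hat (default 3).
#' @return Numeric `c(lo, hi)` in us, clipped to the time range.
#' @export
find_peak_window <- function(atd, half_width_sigmas = 3) {
  stopifnot(inherits(atd, "atd_record"))
  if (sum(atd$counts) == 0) {
    return(range(atd$times))
  }
  w <- atd$counts / sum(atd$counts)
  mode_t <- atd$times[which.max(atd$counts)]
  mu <- sum(w * atd$times)
  sigma_hat <- sqrt(max(sum(w * (atd$times - mu)^2), 1))
  lo <- max(min(atd$times), mode_t - half_width_sigmas * sigma_hat)
  hi <- min(max(atd$times), mode_t + half_width_sigmas * sigma_hat)
  c(lo, hi)
}

#' Integrate an ATD peak with Poisson uncertainty
#'
#' Peak area = sum of counts inside the window minus a constant baseline
#' estimated from channels immediately preceding the window, floored at
#' zero. The variance combines the Poisson variance of the window sum with
#' the variance of the subtracted baseline estimate:
#' var = sum(window counts) + (W / B)^2 * sum(baseline counts), with W
#' window channels and B baseline channels.
#'
#' @param atd An [atd_record()].
#' @param window Numeric `c(lo, hi)` in us; default [find_peak_window()].
#' @param baseline_channels Number of pre-window channels used for the
#'   constant-baseline estimate (default 50; 0 disables subtraction).
#' @return A `peak_area` list: `area`, `sigma`, `window`, `baseline_rate`.
#' @export
integrate_atd <- function(atd, window = NULL, baseline_channels = 50) {
  stopifnot(inherits(atd, "atd_record"))
  if (is.null(window)) window <- find_peak_window(atd)
  if (window[1] > window[2] ||
      window[2] < min(atd$times) || window[1] > max(atd$times)) {
    stop("integration window outside the ATD time range", call. = FALSE)
  }
  in_win <- atd$times >= window[1] & atd$times <= window[2]
  if (!any(in_win)) {
    stop("integration window contains no channels", call. = FALSE)
  }
  n_win <- sum(in_win)
  raw <- sum(atd$counts[in_win])
  pre <- which(atd$times < window[1])
  pre <- utils::tail(pre, baseline_channels)
  if (baseline_channels > 0 && length(pre) > 0) {
    base_sum <- sum(atd$counts[pre])
    base_rate <- base_sum / length(pre)
    base_var <- (n_win / length(pre))^2 * base_sum
  } else {
    base_rate <- 0
    base_var <- 0
  }
  area <- max(raw - base_rate * n_win, 0)
  structure(list(area = area,
                 sigma = sqrt(raw + base_var),
                 window = window,
                 baseline_rate = base_rate),
            class = "peak_area")
}

#' Equilibrium-attainment test: intensity ratio versus residence time
#'
#' At equilibrium the product/reactant intensity ratio is independent of
#' how long the ions have resided in the cell. The overlapping peak region
#' is split into `n_bins` contiguous time bins; per-bin count ratios carry
#' Poisson errors sigma_r = r * sqrt(1/Np + 1/Nr); a weighted straight line
#' of ratio versus bin-centre time is fitted. The system passes when the
#' slope is compatible with zero at two standard errors.
#'
#' @param product,reactant [atd_record()]s on the same time axis (product
#'   is hydration step n, reactant n-1).
#' @param n_bins Number of residence-time bins (>= 3).
#' @param count_floor Bins whose reactant count falls below this are
#'   excluded (default 10; Poisson ratio errors degenerate below that).
#' @return An `equilibrium_check` list: `slope`, `slope_sigma`,
#'   `ratio_mean`, `passed`, `bins` (data frame of the usable bins).
#' @export
ratio_vs_residence_time <- function(product, reactant, n_bins = 8,
                                    count_floor = 10) {
  stopifnot(inherits(product, "atd_record"), inherits(reactant, "atd_record"))
  if (length(product$times) != length(reactant$times) ||
      any(abs(product$times - reactant$times) > 1e-9)) {
    stop("product and reactant must share the time axis", call. = FALSE)
  }
  if (n_bins < 3) stop("n_bins must be at least 3", call. = FALSE)
  active <- which(reactant$counts > 0 | product$counts > 0)
  if (length(active) < n_bins) {
    stop("insufficient data: fewer active channels than bins", call. = FALSE)
  }
  idx <- seq(min(active), max(active))
  edges <- round(seq(idx[1], idx[length(idx)] + 1, length.out = n_bins + 1))
  bin_of <- cut(idx, breaks = edges, right = FALSE, labels = FALSE)
  centre <- tapply(reactant$times[idx], bin_of, mean)
  nr <- tapply(reactant$counts[idx], bin_of, sum)
  np <- tapply(product$counts[idx], bin_of, sum)
  keep <- nr >= count_floor
  if (sum(keep) < 3) {
    stop("insufficient data: fewer than 3 bins above the count floor",
         call. = FALSE)
  }
  centre <- centre[keep]; nr <- nr[keep]; np <- np[keep]
  ratio <- np / nr
  sigma_r <- sqrt(pmax(np, 1)) / nr * sqrt(1 + pmax(np, 1) / nr)
  w <- 1 / sigma_r^2
  fit <- wls_line(centre, ratio, w)
  passed <- abs(fit$slope) <= 2 * fit$slope_sigma
  structure(list(slope = fit$slope,
                 slope_sigma = fit$slope_sigma,
                 ratio_mean = sum(w * ratio) / sum(w),
                 passed = passed,
                 bins = data.frame(time_us = as.numeric(centre),
                                   reactant = as.numeric(nr),
                                   product = as.numeric(np),
                                   ratio = as.numeric(ratio),
                                   sigma = as.numeric(sigma_r))),
            class = "equilibrium_check")
}

#' @export
print.equilibrium_check <- function(x, ...) {
  cat(sprintf("<equilibrium_check> slope = %.3g +/- %.3g /us, ratio = %.4g, %s\n",
              x$slope, x$slope_sigma, x$ratio_mean,
              if (x$passed) "PASSED (|slope| <= 2 sigma)" else "FAILED"))
  invisible(x)
}

# Weighted straight-line fit y = a + b x with weights w; x centred about
# its weighted mean for conditioning, intercept un-centred on return.
# Parameter sigmas from the unscaled weighted normal-equations covariance.
wls_line <- function(x, y, w) {
  if (length(unique(x)) < 2) {
    stop("singular design: all x identical", call. = FALSE)
  }
  xm <- sum(w * x) / sum(w)
  xc <- x - xm
  sw <- sum(w)
  sxx <- sum(w * xc^2)
  b <- sum(w * xc * y) / sxx
  a_c <- sum(w * y) / sw
  resid <- y - (a_c + b * xc)
  dof <- length(x) - 2
  red_chi2 <- if (dof > 0) sum(w * resid^2) / dof else NA_real_
  # cov of (a_c, b) is diag(1/sw, 1/sxx); un-centring a = a_c - b*xm couples
  var_b <- 1 / sxx
  var_a <- 1 / sw + xm^2 / sxx
  cov_ab <- -xm / sxx
  list(intercept = a_c - b * xm, slope = b,
       intercept_sigma = sqrt(var_a), slope_sigma = sqrt(var_b),
       cov_ab = cov_ab, reduced_chi2 = red_chi2, residuals = resid)
}
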