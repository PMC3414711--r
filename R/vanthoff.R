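#' Weighted van't Hoff fit of an equilibrium series
#'
#' Fits ln K = dS/R - dH/(R T), i.e. a straight line y = a + b x with
#' y = ln K and x = 1/T, by weighted least squares with weights
#' w_i = 1 / sigma^2(ln K_i) and sigma(ln K) = sigma_K / K (first-order).
#' Then dH = -R b (slope) and dS = R a (intercept). Parameter sigmas and
#' their covariance come from the unscaled weighted normal-equations
#' covariance matrix — the supplied sigma_K are taken at face value — with
#' the reduced chi-square reported so callers can inflate if the scatter
#' demands it. Under uniform weights (requested, or forced by absent
#' sigmas) no absolute error scale exists and the covariance is instead
#' scaled by the reduced chi-square, i.e. ordinary least-squares errors. Internally x is centred about its weighted mean and the
#' intercept un-centred afterwards, which keeps the intercept (entropy)
#' well conditioned even though 1/T spans a narrow range.
#'
#' @param series An [equilibrium_series()] with at least 3 points (all
#'   K > 0, temperatures not all equal).
#' @param weights `"sigma"` (default) for statistical weights from
#'   `sigma_K`, `"uniform"` for an unweighted fit. Zero/absent sigmas fall
#'   back to uniform weights.
#' @return A `thermo_result`: `species`, `n`, `dH` (kJ/mol), `sd_dH`,
#'   `dS` (J/(mol K)), `sd_dS`, `cov_dH_dS`, `dG298`, `sd_dG298`,
#'   `n_points`, `reduced_chi2`. Association sign convention: favourable
#'   hydration gives negative dH, dS, dG.
#' @export
vant_hoff_fit <- function(series, weights = c("sigma", "uniform")) {
  stopifnot(inherits(series, "equilibrium_series"))
  weights <- match.arg(weights)
  pts <- series$points
  if (nrow(pts) < 3) {
    stop("van't Hoff fit needs at least 3 points", call. = FALSE)
  }
  if (any(pts$K <= 0)) stop("all K must be positive", call. = FALSE)
  x <- 1 / pts$temperature_K
  y <- log(pts$K)
  sigma_y <- pts$sigma_K / pts$K
  uniform <- weights == "uniform" || any(sigma_y <= 0) ||
    any(!is.finite(sigma_y))
  w <- if (uniform) rep(1, length(x)) else 1 / sigma_y^2
  fit <- wls_line(x, y, w)
  # With statistical weights the covariance is unscaled (sigma_K taken at
  # face value). Uniform weights carry no absolute error scale, so the
  # covariance is scaled by the reduced chi-square (plain OLS errors) —
  # zero for a perfect line.
  scale <- if (uniform) sqrt(fit$reduced_chi2) else 1
  dH <- -R_GAS * fit$slope / 1000
  dS <- R_GAS * fit$intercept
  sd_dH <- R_GAS * fit$slope_sigma * scale / 1000
  sd_dS <- R_GAS * fit$intercept_sigma * scale
  # cov(dH, dS) = -R^2 cov(a, b) / 1000 in (kJ/mol)(J/(mol K))
  cov_dH_dS <- -R_GAS^2 * fit$cov_ab * scale^2 / 1000
  g <- gibbs_energy(dH, dS, T_REPORT, sd_dH, sd_dS, cov_dH_dS)
  structure(list(species = series$species, n = series$n,
                 dH = dH, sd_dH = sd_dH,
                 dS = dS, sd_dS = sd_dS,
                 cov_dH_dS = cov_dH_dS,
                 dG298 = g$value, sd_dG298 = g$sd,
                 n_points = nrow(pts),
                 reduced_chi2 = fit$reduced_chi2),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> %s step (%d,%d), %d points\n",
              x$species, x$n - 1L, x$n, x$n_points))
  cat(sprintf("  -dH  = %s kJ/mol\n", format_value_sigma(-x$dH, x$sd_dH)))
  cat(sprintf("  -dS  = %s J/(mol K)\n", format_value_sigma(-x$dS, x$sd_dS)))
  cat(sprintf("  -dG(298) = %s kJ/mol   red.chi2 = %.2f\n",
              format_value_sigma(-x$dG298, x$sd_dG298), x$reduced_chi2))
  invisible(x)
}

#' Standard Gibbs energy at a chosen temperature
#'
#' `gibbs()` evaluates dG = dH - T dS from a fitted [vant_hoff_fit()]
#' result (propagating the fit covariance) or, in the default method, from
#' plain printed table values such as the -dH/-dS columns of a
#' thermochemistry report.
#'
#' @param x A `thermo_result`, or a numeric dH in kJ/mol.
#' @param ... Passed on to methods.
#' @return List with `value` and `sd`, kJ/mol.
#' @export
gibbs <- function(x, ...) UseMethod("gibbs")

#' @rdname gibbs
#' @param temperature Temperature, K (default 298.15).
#' @export
gibbs.thermo_result <- function(x, temperature = T_REPORT, ...) {
  gibbs_energy(x$dH, x$dS, temperature, x$sd_dH, x$sd_dS, x$cov_dH_dS)
}

#' @rdname gibbs
#' @param dS Entropy, J/(mol K).
#' @param sd_dH,sd_dS,cov_dH_dS Optional uncertainties, defaults 0.
#' @export
gibbs.default <- function(x, dS, temperature = T_REPORT,
                          sd_dH = 0, sd_dS = 0, cov_dH_dS = 0, ...) {
  gibbs_energy(x, dS, temperature, sd_dH, sd_dS, cov_dH_dS)
}

#' Paper-style thermochemistry table
#'
#' Formats fitted results the way clustering-thermochemistry tables print
#' them: -dH (kJ/mol), -dS (J/(mol K)) and -dG at 298 K (kJ/mol) to one
#' decimal, with the 1-sigma uncertainty's last digit in parentheses,
#' e.g. `62.3(2)`. Rounding is half-even on the displayed decimal.
#'
#' @param results A `thermo_result` or list of them.
#' @return Data frame with columns `species`, `n`, `neg_dH`, `neg_dS`,
#'   `neg_dG298`, `n_points`, `reduced_chi2` (the three value columns are
#'   formatted strings).
#' @export
format_thermo_table <- function(results) {
  if (inherits(results, "thermo_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "thermo_result")))
  do.call(rbind, lapply(results, function(r) {
    data.frame(species = r$species, n = r$n,
               neg_dH = format_value_sigma(-r$dH, r$sd_dH),
               neg_dS = format_value_sigma(-r$dS, r$sd_dS),
               neg_dG298 = format_value_sigma(-r$dG298, r$sd_dG298),
               n_points = r$n_points,
               reduced_chi2 = round(r$reduced_chi2, 3))
  }))
}
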