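#' One hydration-step measurement
#'
#' Pairs the product and reactant ATD peak areas for hydration step
#' (n-1, n) with the water partial pressure and cell temperature under
#' which they were recorded — the inputs of one equilibrium constant.
#'
#' @param species Ion label without the water count, e.g. `"UraNa+"`.
#' @param n Product hydration number (the step attaches the n-th water).
#' @param I_n,sigma_In Product peak area and its 1-sigma (counts).
#' @param I_nm1,sigma_Inm1 Reactant peak area and its 1-sigma (counts);
#'   `I_nm1` must be positive.
#' @param water_pressure Water partial pressure, mbar (0 < P).
#' @param temperature Cell temperature, K.
#' @param eq_passed Optional result of the residence-time equilibrium test.
#' @return A `hydration_measurement` list.
#' @export
hydration_measurement <- function(species, n, I_n, sigma_In,
                                  I_nm1, sigma_Inm1,
                                  water_pressure, temperature,
                                  eq_passed = NA) {
  if (I_nm1 <= 0) stop("reactant intensity I_nm1 must be positive",
                       call. = FALSE)
  if (water_pressure <= 0) stop("water_pressure must be positive",
                                call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(species = as.character(species), n = as.integer(n),
                 I_n = I_n, sigma_In = sigma_In,
                 I_nm1 = I_nm1, sigma_Inm1 = sigma_Inm1,
                 water_pressure = water_pressure,
                 temperature = temperature,
                 eq_passed = eq_passed),
            class = "hydration_measurement")
}

#' Equilibrium constant from one hydration-step measurement
#'
#' K_{n-1,n} = I_n * P_o / (I_{n-1} * P) with P_o = 1000 mbar. The
#' uncertainty propagates the two intensity sigmas and a relative pressure
#' uncertainty in quadrature:
#' (sigma_K/K)^2 = (sigma_In/I_n)^2 + (sigma_Inm1/I_nm1)^2 + rel_P^2.
#'
#' @param m A [hydration_measurement()].
#' @param pressure_rel_sigma Relative 1-sigma of the water partial pressure
#'   (default 0.02, capacitance-manometer class).
#' @return List with `K` and `sigma_K` (dimensionless).
#' @export
equilibrium_constant <- function(m, pressure_rel_sigma = 0.02) {
  stopifnot(inherits(m, "hydration_measurement"))
  K <- m$I_n * P_STANDARD / (m$I_nm1 * m$water_pressure)
  rel_In <- if (m$I_n > 0) m$sigma_In / m$I_n else 0
  rel2 <- rel_In^2 + (m$sigma_Inm1 / m$I_nm1)^2 + pressure_rel_sigma^2
  list(K = K, sigma_K = K * sqrt(rel2))
}

#' Temperature series of equilibrium constants for one hydration step
#'
#' @param species Ion label.
#' @param n Product hydration number.
#' @param points Data frame with columns `temperature_K`, `K`, `sigma_K`;
#'   all K positive, replicate temperatures allowed.
#' @return An `equilibrium_series` list.
#' @export
equilibrium_series <- function(species, n, points) {
  points <- as.data.frame(points)
  need <- c("temperature_K", "K", "sigma_K")
  if (!all(need %in% names(points))) {
    stop("points needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(points$K <= 0)) stop("all K must be positive", call. = FALSE)
  if (any(points$sigma_K < 0)) stop("sigma_K must be >= 0", call. = FALSE)
  structure(list(species = as.character(species), n = as.integer(n),
                 points = points[need]),
            class = "equilibrium_series")
}

#' @export
print.equilibrium_series <- function(x, ...) {
  cat(sprintf("<equilibrium_series> %s step (%d,%d): %d points, T in [%.0f, %.0f] K\n",
              x$species, x$n - 1L, x$n, nrow(x$points),
              min(x$points$temperature_K), max(x$points$temperature_K)))
  invisible(x)
}

#' Aggregate hydration-step measurements into an equilibrium series
#'
#' Converts each measurement to a (T, K, sigma_K) point via
#' [equilibrium_constant()]. All measurements must share species and step.
#' Replicates (same temperature, e.g. different water pressures) are kept
#' as separate points — the van't Hoff fit, not this stage, weights them.
#'
#' @param measurements List of [hydration_measurement()]s.
#' @param require_eq_pass When TRUE, measurements whose residence-time
#'   equilibrium check failed are excluded (each exclusion is messaged).
#' @param pressure_rel_sigma Passed to [equilibrium_constant()].
#' @return An [equilibrium_series()], points ordered by temperature
#'   (stable: input order preserved within ties).
#' @export
build_series <- function(measurements, require_eq_pass = FALSE,
                         pressure_rel_sigma = 0.02) {
  stopifnot(length(measurements) >= 1,
            all(vapply(measurements, inherits, TRUE, "hydration_measurement")))
  species <- unique(vapply(measurements, `[[`, "", "species"))
  ns <- unique(vapply(measurements, `[[`, 1L, "n"))
  if (length(species) != 1 || length(ns) != 1) {
    stop("all measurements must share species and hydration step",
         call. = FALSE)
  }
  if (require_eq_pass) {
    ok <- vapply(measurements, function(m) isTRUE(m$eq_passed), TRUE)
    for (m in measurements[!ok]) {
      message(sprintf("build_series: excluding %s n=%d at T=%.1f K (equilibrium check failed)",
                      m$species, m$n, m$temperature))
    }
    measurements <- measurements[ok]
    if (length(measurements) == 0) {
      stop("insufficient data: no measurements left after equilibrium filter",
           call. = FALSE)
    }
  }
  pts <- do.call(rbind, lapply(measurements, function(m) {
    k <- equilibrium_constant(m, pressure_rel_sigma)
    data.frame(temperature_K = m$temperature, K = k$K, sigma_K = k$sigma_K)
  }))
  pts <- pts[order(pts$temperature_K), , drop = FALSE]
  rownames(pts) <- NULL
  equilibrium_series(species = species, n = ns, points = pts)
}
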