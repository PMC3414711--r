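# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All simulator entry points route randomness through this, so every
# stochastic operation is a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from the top-level seed by a stable string hash
# of the stage name (31-adic, mod 2^31 - 1). Keeps stages decorrelated while
# the whole pipeline remains a function of one integer.
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Shared arrival-time peak profile: the injection boxcar (width w, centred
# on the mean drift time) convolved with a Gaussian spread, evaluated at
# the 1 us channel centres and normalised to unit sum.
arrival_profile <- function(times, conditions) {
  w <- conditions$injection_pulse_width
  s <- conditions$drift_time_sd
  t0 <- conditions$drift_time_mean
  prof <- stats::pnorm((times - t0 + w / 2) / s) -
    stats::pnorm((times - t0 - w / 2) / s)
  prof / sum(prof)
}

#' Simulate arrival-time distributions for a hydration ladder
#'
#' Propagates the hydration master equation from the bare complex (n = 0)
#' to the mean cell-exit time, then lays each species' population on a
#' common arrival-time peak (injection boxcar convolved with a Gaussian
#' spread), scales by the number of accumulated pulses, and draws Poisson
#' counts per 1 us channel. When the kinetic relaxation time is much
#' shorter than the drift time, channel-summed intensity ratios
#' I_n / I_{n-1} converge to the equilibrium ratios r_n.
#'
#' @param scheme A [kinetic_scheme()].
#' @param conditions A [cell_conditions()].
#' @param seed Integer seed; the dataset records it.
#' @param species_prefix Label stem for the simulated ion, e.g. "UraNa+";
#'   species n is labelled `<prefix>(H2O)<n>`.
#' @param poisson Draw Poisson counts (default). With FALSE the records
#'   carry the noise-free expected counts — the zero-noise limit used by
#'   end-to-end consistency checks.
#' @return A `simulated_dataset`: list of [atd_record()]s (one per
#'   hydration state), the generating scheme, conditions, and seed.
#' @export
simulate_atds <- function(scheme, conditions, seed,
                          species_prefix = "NAB-M+", poisson = TRUE) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(conditions, "cell_conditions"),
            conditions$n_pulses >= 1)
  Q <- build_rate_matrix(scheme, conditions)
  p0 <- c(1, rep(0, scheme$max_n))
  pops <- propagate_populations(Q, p0, conditions$drift_time_mean)
  times <- seq_len(conditions$repetition_period) - 0.5
  prof <- arrival_profile(times, conditions)
  atds <- with_seed(seed, {
    lapply(seq_along(pops), function(i) {
      lambda <- conditions$n_pulses * pops[i] * prof
      atd_record(species_label = sprintf("%s(H2O)%d", species_prefix, i - 1L),
                 hydration_n = i - 1L,
                 temperature = conditions$temperature,
                 water_pressure = conditions$water_pressure,
                 times = times,
                 counts = if (poisson) {
                   stats::rpois(length(lambda), lambda)
                 } else lambda,
                 expected = lambda,
                 integer_counts = poisson)
    })
  })
  structure(list(atds = atds, ground_truth = scheme,
                 conditions = conditions, seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' Simulate a temperature series of equilibrium constants
#'
#' Evaluates the exact van't Hoff line K(T) = exp(-dH/(R T) + dS/R) at the
#' requested temperatures and perturbs it with multiplicative log-normal
#' noise of the stated relative magnitude; the sigma column is set
#' consistently to `relative_noise * K`.
#'
#' @param dH Association enthalpy, kJ/mol.
#' @param dS Association entropy, J/(mol K).
#' @param temperatures Temperatures, K (all positive).
#' @param relative_noise Relative 1-sigma noise on K (>= 0; 0 gives the
#'   exact line with zero sigmas).
#' @param seed Integer seed.
#' @param species,n Metadata carried on the resulting series.
#' @return An [equilibrium_series()].
#' @export
simulate_k_series <- function(dH, dS, temperatures, relative_noise = 0,
                              seed = 1L, species = "synthetic", n = 1L) {
  stopifnot(all(temperatures > 0), relative_noise >= 0)
  K <- equilibrium_constant_from_thermo(dH, dS, temperatures)
  if (relative_noise > 0) {
    K <- with_seed(seed, {
      K * exp(stats::rnorm(length(K), 0, relative_noise))
    })
  }
  equilibrium_series(species = species, n = n,
                     points = data.frame(temperature_K = temperatures,
                                         K = K,
                                         sigma_K = relative_noise * K))
}

#' Write / read the ATD CSV interchange format
#'
#' One row per 1 us channel with header
#' `species,temperature_K,water_pressure_mbar,time_us,counts`.
#'
#' @param atd An [atd_record()] (`write_atd_csv`) .
#' @param path File path.
#' @return `read_atd_csv` returns an [atd_record()]; `write_atd_csv`
#'   invisibly returns `path`.
#' @export
write_atd_csv <- function(atd, path) {
  stopifnot(inherits(atd, "atd_record"))
  df <- data.frame(species = atd$species_label,
                   temperature_K = atd$temperature,
                   water_pressure_mbar = atd$water_pressure,
                   time_us = atd$times,
                   counts = atd$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atd_csv
#' @param hydration_n Hydration number metadata for the record (not stored
#'   in the CSV; parsed from a trailing `(H2O)<n>` in the species label when
#'   omitted).
#' @export
read_atd_csv <- function(path, hydration_n = NULL) {
  df <- utils::read.csv(path)
  need <- c("species", "temperature_K", "water_pressure_mbar",
            "time_us", "counts")
  if (!all(need %in% names(df))) {
    stop("ATD CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  label <- as.character(df$species[1])
  if (is.null(hydration_n)) {
    m <- regmatches(label, regexpr("\\(H2O\\)([0-9]+)$", label))
    hydration_n <- if (length(m)) {
      as.integer(sub("\\(H2O\\)", "", m))
    } else NA_integer_
  }
  atd_record(species_label = label,
             hydration_n = hydration_n,
             temperature = df$temperature_K[1],
             water_pressure = df$water_pressure_mbar[1],
             times = df$time_us,
             counts = df$counts)
}

#' Write / read the equilibrium-series CSV interchange format
#'
#' Header `temperature_K,K,sigma_K`, one row per (T, K) point.
#'
#' @param series An [equilibrium_series()].
#' @param path File path.
#' @param species,n Metadata attached on read.
#' @return `read_series_csv` returns an [equilibrium_series()].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "equilibrium_series"))
  utils::write.csv(series$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, species = "unknown", n = 1L) {
  df <- utils::read.csv(path)
  need <- c("temperature_K", "K", "sigma_K")
  if (!all(need %in% names(df))) {
    stop("series CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  equilibrium_series(species = species, n = n, points = df[need])
}
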