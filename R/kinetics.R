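#' Reaction-cell conditions for a simulated measurement
#'
#' Describes the drift-cell state under which one set of arrival-time
#' distributions is accumulated: temperature, carrier and water partial
#' pressures, the mean ion drift (residence) time, and the pulsed-injection
#' timing. Defaults mirror a typical pulsed ion-beam HPMS configuration:
#' a 90 us, +50 V injection pulse repeated every 1 ms into ~10 mbar N2
#' carrying 0.02-0.20 mbar of water vapour, with counts accumulated over
#' several thousand pulses at 1 us dwell per channel.
#'
#' @param temperature Cell temperature, K.
#' @param carrier_pressure Total carrier (N2) pressure, mbar.
#' @param water_pressure Water partial pressure, mbar; must be below
#'   `carrier_pressure`.
#' @param drift_time_mean Mean ion drift time across the cell, us.
#' @param drift_time_sd Gaussian arrival-time spread, us.
#' @param injection_pulse_width Injection pulse width, us; must be below
#'   `repetition_period`.
#' @param repetition_period Pulse repetition period, us (also the length of
#'   the recorded time axis).
#' @param n_pulses Number of accumulated injection pulses.
#' @return A `cell_conditions` list.
#' @export
cell_conditions <- function(temperature = 400,
                            carrier_pressure = 10,
                            water_pressure = 0.1,
                            drift_time_mean = 700,
                            drift_time_sd = 30,
                            injection_pulse_width = 90,
                            repetition_period = 1000,
                            n_pulses = 2000) {
  vals <- c(temperature, carrier_pressure, water_pressure, drift_time_mean,
            drift_time_sd, injection_pulse_width, repetition_period, n_pulses)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all cell_conditions fields must be positive and finite",
         call. = FALSE)
  }
  if (water_pressure >= carrier_pressure) {
    stop("water_pressure must be below carrier_pressure", call. = FALSE)
  }
  if (injection_pulse_width >= repetition_period) {
    stop("injection_pulse_width must be below repetition_period",
         call. = FALSE)
  }
  structure(list(temperature = temperature,
                 carrier_pressure = carrier_pressure,
                 water_pressure = water_pressure,
                 drift_time_mean = drift_time_mean,
                 drift_time_sd = drift_time_sd,
                 injection_pulse_width = injection_pulse_width,
                 repetition_period = repetition_period,
                 n_pulses = as.integer(n_pulses)),
            class = "cell_conditions")
}

#' Kinetic scheme for sequential hydration in the drift cell
#'
#' A birth-death ladder over hydration states n = 0..max_n for the
#' clustering steps NAB-M+.(H2O)_{n-1} + H2O <-> NAB-M+.(H2O)_n. The
#' forward direction carries pseudo-first-order rates (water concentration
#' absorbed); reverse rates are fixed by detailed balance against the
#' thermodynamic equilibrium ratio of each step, so the scheme's stationary
#' state is exactly the equilibrium the analysis assumes. The true
#' per-step (dH, dS) are retained as ground truth for recovery tests.
#'
#' @param true_thermo Data frame (or matrix) with columns `dH` (kJ/mol) and
#'   `dS` (J/(mol K)), one row per hydration step n = 1..max_n. Association
#'   sign convention: both negative for favourable attachment.
#' @param forward_rates Forward pseudo-first-order rates, per us; recycled
#'   to `max_n`. Default 0.01/us, fast enough that equilibration completes
#'   well inside a ~1 ms residence window.
#' @return A `kinetic_scheme` list with `max_n`, `forward_rates`,
#'   `true_thermo`.
#' @export
kinetic_scheme <- function(true_thermo, forward_rates = 0.01) {
  true_thermo <- as.data.frame(true_thermo)
  if (!all(c("dH", "dS") %in% names(true_thermo)) || nrow(true_thermo) < 1) {
    stop("true_thermo needs columns dH, dS and at least one row",
         call. = FALSE)
  }
  max_n <- nrow(true_thermo)
  forward_rates <- rep_len(forward_rates, max_n)
  if (any(!is.finite(forward_rates)) || any(forward_rates <= 0)) {
    stop("forward_rates must be positive and finite", call. = FALSE)
  }
  structure(list(max_n = max_n,
                 forward_rates = forward_rates,
                 true_thermo = true_thermo[c("dH", "dS")]),
            class = "kinetic_scheme")
}

#' Master-equation rate matrix for a hydration ladder
#'
#' Builds the (max_n+1)-state generator Q with dp/dt = Q p: forward rates on
#' the first subdiagonal, reverse rates nu_rev = nu_fwd / r_n (detailed
#' balance) on the first superdiagonal, diagonal set so every column sums to
#' zero. The stationary distribution therefore satisfies
#' p_n / p_{n-1} = r_n exactly, with r_n the equilibrium intensity ratio of
#' step n under `conditions`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param conditions A [cell_conditions()].
#' @return Square matrix, per-us rates, with attribute `ratios` (the r_n).
#' @export
build_rate_matrix <- function(scheme, conditions) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(conditions, "cell_conditions"))
  r <- equilibrium_ratio_from_thermo(scheme$true_thermo$dH,
                                     scheme$true_thermo$dS,
                                     conditions)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("equilibrium ratios must be positive and finite; check thermo/conditions",
         call. = FALSE)
  }
  m <- scheme$max_n
  Q <- matrix(0, m + 1, m + 1)
  for (n in seq_len(m)) {
    fwd <- scheme$forward_rates[n]
    Q[n + 1, n] <- fwd            # (n-1) -> n
    Q[n, n + 1] <- fwd / r[n]     # n -> (n-1)
  }
  diag(Q) <- -colSums(Q)
  attr(Q, "ratios") <- r
  Q
}

#' Stationary distribution of a master-equation generator
#'
#' Solves Q p = 0 with sum(p) = 1 by singular value decomposition (the
#' right-singular vector of the smallest singular value). For the
#' birth-death generators built here this equals the detailed-balance
#' product formula to machine precision.
#'
#' @param Q Generator matrix with zero column sums.
#' @return Probability vector over states 0..max_n.
#' @export
stationary_distribution <- function(Q) {
  sv <- svd(Q)
  p <- sv$v[, ncol(Q)]
  p <- p / sum(p)
  if (any(p < -1e-9)) {
    stop("generator has no non-negative null vector", call. = FALSE)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

# exp(Q t) p0 via the detailed-balance symmetrization: with pi the
# stationary state, S = D^{-1/2} Q D^{1/2} (D = diag(pi)) is symmetric, so
# eigen(S) is exact and stable. Valid for the birth-death generators this
# package builds.
propagate_populations <- function(Q, p0, t) {
  pi_s <- stationary_distribution(Q)
  d <- sqrt(pi_s)
  S <- Q * outer(1 / d, d)        # S_ij = Q_ij * d_j / d_i
  S <- (S + t(S)) / 2             # symmetrize residual fp asymmetry
  es <- eigen(S, symmetric = TRUE)
  y <- crossprod(es$vectors, p0 / d)
  p <- d * as.vector(es$vectors %*% (exp(es$values * t) * y))
  pmax(p, 0) / sum(pmax(p, 0))
}
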