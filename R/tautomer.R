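#' A population of tautomeric metal-ion complexes
#'
#' Labels, metal-ion affinities (MIAs), and mole fractions on the unit
#' simplex for the tautomers of a cationized nucleobase. For cytosine the
#' canonical amino-oxo complex coexists with enol and imino forms whose
#' MIAs differ by tens of kJ/mol, so the effective affinity of an
#' electrosprayed population is a fraction-weighted mixture.
#'
#' @param labels Character tautomer labels.
#' @param mias Metal-ion affinities, kJ/mol.
#' @param fractions Mole fractions; non-negative, summing to 1 within 1e-9.
#' @return A `tautomer_set` list.
#' @export
tautomer_set <- function(labels, mias, fractions) {
  if (length(labels) != length(mias) || length(mias) != length(fractions)) {
    stop("labels, mias, fractions must have equal length", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  structure(list(labels = as.character(labels),
                 mias = as.numeric(mias),
                 fractions = as.numeric(fractions)),
            class = "tautomer_set")
}

#' Population-weighted metal-ion affinity of a tautomer mixture
#'
#' The effective MIA of a mixture is the sum of the individual tautomer
#' MIAs weighted by their mole fractions: sum(x_i * MIA_i). By convexity
#' the result always lies between the smallest and largest individual MIA.
#'
#' @param t A [tautomer_set()].
#' @return Weighted MIA, kJ/mol.
#' @export
weighted_mia <- function(t) {
  stopifnot(inherits(t, "tautomer_set"))
  sum(t$fractions * t$mias)
}

#' Linear correlation of water binding energy with metal-ion affinity
#'
#' Cation-nucleobase binding is largely electrostatic: the more charge the
#' base withdraws from the metal ion (the larger its MIA), the weaker the
#' residual ion-water attraction. Ordinary least squares of the water
#' binding energy (-dH of the hydration step, kJ/mol) on the MIA (kJ/mol)
#' quantifies that trend; the fitted slope is expected negative.
#'
#' @param points Data frame with columns `label`, `mia`, `binding`
#'   (binding = -dH in kJ/mol); at least 3 rows.
#' @param weights Optional per-point weights (e.g. 1/sigma^2 of the
#'   binding energies); default unweighted.
#' @return A `correlation_model`: `slope`, `intercept`, `point_labels`,
#'   `fitted`, `residuals`, `r_squared`.
#' @export
fit_correlation <- function(points, weights = NULL) {
  points <- as.data.frame(points)
  if (!all(c("label", "mia", "binding") %in% names(points))) {
    stop("points needs columns label, mia, binding", call. = FALSE)
  }
  if (nrow(points) < 3) {
    stop("insufficient data: correlation fit needs at least 3 points",
         call. = FALSE)
  }
  fit <- if (is.null(weights)) {
    stats::lm(binding ~ mia, data = points)
  } else {
    stats::lm(binding ~ mia, data = points, weights = weights)
  }
  resid <- unname(stats::residuals(fit))
  ss_tot <- sum((points$binding - mean(points$binding))^2)
  structure(list(slope = unname(stats::coef(fit)["mia"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 point_labels = as.character(points$label),
                 fitted = unname(stats::fitted(fit)),
                 residuals = resid,
                 r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> binding = %.3f %+.4f * MIA, R^2 = %.3f, %d points\n",
              x$intercept, x$slope, x$r_squared, length(x$point_labels)))
  invisible(x)
}

#' Predicted binding energy at a given MIA
#'
#' @param object A `correlation_model`.
#' @param newdata Optional data frame with column `mia` (or a numeric
#'   vector of MIAs); defaults to the fitted values.
#' @param ... Unused.
#' @return Predicted binding energies, kJ/mol.
#' @export
predict.correlation_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  mia <- if (is.data.frame(newdata)) newdata$mia else as.numeric(newdata)
  object$intercept + object$slope * mia
}

#' Effective MIA implied by an observed water binding energy
#'
#' Inverts the linear binding-versus-MIA correlation: given an observed
#' binding energy, returns the MIA a pure (or mixed) population would need
#' to sit on the correlation line. Comparing this effective MIA with the
#' canonical-tautomer MIA and with a population-weighted mixture MIA is
#' the test for whether a species hydrates as a tautomer mixture.
#'
#' @param binding Observed binding energy (-dH), kJ/mol.
#' @param model A `correlation_model` with non-negligible slope.
#' @return Effective MIA, kJ/mol.
#' @export
infer_effective_mia <- function(binding, model) {
  stopifnot(inherits(model, "correlation_model"))
  if (abs(model$slope) < 1e-6) {
    stop("ill-conditioned inversion: |slope| below 1e-6", call. = FALSE)
  }
  (binding - model$intercept) / model$slope
}

#' Enumerate mixture fractions compatible with a target weighted MIA
#'
#' One observable (the effective MIA) cannot pin down >= 2 mole fractions,
#' so the inversion is reported as a feasible set: all simplex grid points
#' x (step `grid_step`) whose weighted MIA lies within `tol` of the
#' target. Vectors are returned in lexicographic order of their fractions,
#' so the enumeration is deterministic. An empty set is a valid outcome.
#'
#' @param target_mia Target effective MIA, kJ/mol.
#' @param mias Individual tautomer MIAs, kJ/mol (>= 2 values).
#' @param tol Half-width of the acceptance band, kJ/mol.
#' @param grid_step Simplex grid step; 1/grid_step must be an integer.
#' @return Matrix, one row per feasible fraction vector (columns named by
#'   `names(mias)` when present), with attribute `weighted_mia`.
#' @export
mixture_feasible_set <- function(target_mia, mias, tol = 1, grid_step = 0.02) {
  if (length(mias) < 2) stop("need at least 2 tautomers", call. = FALSE)
  m <- 1 / grid_step
  if (abs(m - round(m)) > 1e-9) {
    stop("grid_step must divide 1 evenly", call. = FALSE)
  }
  m <- as.integer(round(m))
  grid <- simplex_grid(length(mias), m) / m
  wm <- as.vector(grid %*% mias)
  keep <- abs(wm - target_mia) <= tol + 1e-12
  out <- grid[keep, , drop = FALSE]
  if (!is.null(names(mias))) colnames(out) <- names(mias)
  attr(out, "weighted_mia") <- wm[keep]
  out
}

# All compositions of m into k non-negative parts, lexicographic rows.
simplex_grid <- function(k, m) {
  if (k == 1) return(matrix(m, 1, 1))
  do.call(rbind, lapply(0:m, function(first) {
    rest <- simplex_grid(k - 1, m - first)
    cbind(first, rest, deparse.level = 0)
  }))
}
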