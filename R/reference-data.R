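#' Reference hydration thermochemistry of cationized nucleobases
#'
#' The published experimental hydration thermochemistry for sodiated and
#' potassiated uracil, thymine, cytosine and adenine, plus the
#' Na+(H2O)3->4 validation step, as printed: -dH (kJ/mol), -dS
#' (J/(mol K)), -dG at 298 K (kJ/mol), each with the parenthetical
#' 1-sigma last-digit uncertainty expanded into a numeric sigma column,
#' and the metal-ion affinity (MIA, kJ/mol) of each base. Cytosine's MIA
#' is the tautomer-population-weighted value (see
#' [cytosine_tautomers()]); the others are single-tautomer computed
#' values.
#'
#' @param cation `"Na"`, `"K"`, or `"all"` (default).
#' @return Data frame with columns `species`, `base`, `cation`, `n`,
#'   `neg_dH`, `sd_dH`, `neg_dS`, `sd_dS`, `neg_dG298`, `sd_dG298`, `mia`.
#' @export
nucleobase_hydration_thermo <- function(cation = c("all", "Na", "K")) {
  cation <- match.arg(cation)
  df <- rbind(
    data.frame(base = "Ura", cation = "Na", n = 1L, neg_dH = 62.3, sd_dH = 0.2,
               neg_dS = 66.5, sd_dS = 0.4, neg_dG298 = 42.6, sd_dG298 = 0.3,
               mia = 145.2),
    data.frame(base = "Ura", cation = "Na", n = 2L, neg_dH = 50.6, sd_dH = 0.2,
               neg_dS = 70.3, sd_dS = 0.5, neg_dG298 = 29.7, sd_dG298 = 0.3,
               mia = 145.2),
    data.frame(base = "Thy", cation = "Na", n = 1L, neg_dH = 61.1, sd_dH = 0.2,
               neg_dS = 66.1, sd_dS = 0.7, neg_dG298 = 41.4, sd_dG298 = 0.4,
               mia = 145.6),
    data.frame(base = "Thy", cation = "Na", n = 2L, neg_dH = 51.0, sd_dH = 0.2,
               neg_dS = 73.2, sd_dS = 0.6, neg_dG298 = 29.0, sd_dG298 = 0.4,
               mia = 145.6),
    data.frame(base = "Cyt", cation = "Na", n = 1L, neg_dH = 57.7, sd_dH = 0.2,
               neg_dS = 69.0, sd_dS = 0.5, neg_dG298 = 37.0, sd_dG298 = 0.5,
               mia = 177),
    data.frame(base = "Cyt", cation = "Na", n = 2L, neg_dH = 50.2, sd_dH = 0.3,
               neg_dS = 77.8, sd_dS = 0.7, neg_dG298 = 27.0, sd_dG298 = 0.5,
               mia = 177),
    data.frame(base = "Ade", cation = "Na", n = 1L, neg_dH = 53.6, sd_dH = 0.3,
               neg_dS = 62.0, sd_dS = 0.6, neg_dG298 = 35.1, sd_dG298 = 0.5,
               mia = 203.8),
    data.frame(base = "Ade", cation = "Na", n = 2L, neg_dH = 47.7, sd_dH = 0.1,
               neg_dS = 83.7, sd_dS = 0.3, neg_dG298 = 22.8, sd_dG298 = 0.2,
               mia = 203.8),
    data.frame(base = "H2O", cation = "Na", n = 4L, neg_dH = 52.7, sd_dH = 0.2,
               neg_dS = 100.4, sd_dS = 0.8, neg_dG298 = 22.8, sd_dG298 = 0.4,
               mia = NA_real_),
    data.frame(base = "Ura", cation = "K", n = 1L, neg_dH = 57.3, sd_dH = 0.2,
               neg_dS = 93.3, sd_dS = 0.3, neg_dG298 = 29.5, sd_dG298 = 0.3,
               mia = 108.4),
    data.frame(base = "Thy", cation = "K", n = 1L, neg_dH = 56.9, sd_dH = 0.1,
               neg_dS = 94.6, sd_dS = 0.4, neg_dG298 = 28.8, sd_dG298 = 0.2,
               mia = 107.1),
    data.frame(base = "Cyt", cation = "K", n = 1L, neg_dH = 55.6, sd_dH = 0.1,
               neg_dS = 103.8, sd_dS = 0.3, neg_dG298 = 24.7, sd_dG298 = 0.2,
               mia = 126),
    data.frame(base = "Ade", cation = "K", n = 1L, neg_dH = 52.7, sd_dH = 0.3,
               neg_dS = 97.9, sd_dS = 0.4, neg_dG298 = 23.5, sd_dG298 = 0.4,
               mia = 154.4))
  df$species <- ifelse(df$base == "H2O", sprintf("%s+(H2O)", df$cation),
                       sprintf("%s-%s+", df$base, df$cation))
  if (cation != "all") df <- df[df$cation == cation, , drop = FALSE]
  rownames(df) <- NULL
  df[c("species", "base", "cation", "n", "neg_dH", "sd_dH", "neg_dS",
       "sd_dS", "neg_dG298", "sd_dG298", "mia")]
}

#' Cytosine tautomer mixture bundled with the reference data
#'
#' The four lowest-energy cytosine tautomer complexes (canonical amino-oxo
#' 2d, enol 2e/2f, imino 2g) with their computed metal-ion affinities and
#' the mole fractions of their neutral precursors measured by
#' matrix-isolation spectroscopy of thermally evaporated cytosine
#' (0.22, 0.44, 0.26, 0.08). Weighting the MIAs by these fractions gives
#' the effective mixture affinities 177 kJ/mol (Na+) and 126 kJ/mol (K+).
#'
#' @param cation `"Na"` or `"K"`.
#' @return A [tautomer_set()].
#' @export
cytosine_tautomers <- function(cation = c("Na", "K")) {
  cation <- match.arg(cation)
  mias <- switch(cation,
                 Na = c(212.5, 165.7, 179.0, 137.7),
                 K  = c(159.0, 111.3, 132.6, 94.6))
  tautomer_set(labels = c("2d", "2e", "2f", "2g"),
               mias = mias,
               fractions = c(0.22, 0.44, 0.26, 0.08))
}

#' Binding-energy versus MIA point sets for the correlation analysis
#'
#' The water binding energies (-dH of hydration step `n`) of the four
#' cationized nucleobases paired with their MIAs, as used in the linear
#' correlation. Cytosine carries its mixture-weighted MIA; pass
#' `canonical_cytosine = TRUE` to substitute the canonical single-tautomer
#' value (212.5 kJ/mol for Na+, 159.0 for K+) instead.
#'
#' @param cation `"Na"` or `"K"`.
#' @param n Hydration step (1 or 2; step 2 exists only for Na+).
#' @param canonical_cytosine Use the canonical 2d MIA for cytosine.
#' @return Data frame with columns `label`, `mia`, `binding`.
#' @export
correlation_points <- function(cation = c("Na", "K"), n = 1L,
                               canonical_cytosine = FALSE) {
  cation <- match.arg(cation)
  tab <- nucleobase_hydration_thermo(cation)
  tab <- tab[tab$base %in% c("Ura", "Thy", "Cyt", "Ade") & tab$n == n, ]
  if (nrow(tab) == 0) {
    stop("no hydration step n = ", n, " for cation ", cation, call. = FALSE)
  }
  if (canonical_cytosine) {
    tab$mia[tab$base == "Cyt"] <- if (cation == "Na") 212.5 else 159.0
  }
  data.frame(label = tab$base, mia = tab$mia, binding = tab$neg_dH)
}
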