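#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()] with every option
#' defaulted to the package's documented defaults. Unknown keys anywhere in
#' the structure are rejected rather than ignored. The configuration
#' round-trips through JSON via [serialize_config()] / [parse_config()].
#'
#' @param mode `"simulate"` (synthetic data, the default) or `"fixture"`
#'   (run the correlation/mixture analysis on the bundled reference
#'   tables).
#' @param seed Top-level integer seed; each stochastic stage derives its
#'   own seed from it by a stable hash of the stage name.
#' @param simulator List: `kind` ("kseries" for direct equilibrium-constant
#'   series, "atd" for the full arrival-time-distribution route), `dH`/`dS`
#'   per hydration step (association sign, kJ/mol and J/(mol K)),
#'   `forward_rates` (/us), `temperatures` (K), `relative_noise`,
#'   `species`, and `conditions` (overrides for [cell_conditions()]).
#' @param reduction List: `baseline_channels`, `count_floor`, `n_bins`,
#'   `require_eq_pass`.
#' @param fit List: `weights` ("sigma" or "uniform"), `report_temperature`
#'   (K).
#' @param tautomer List: `cation` ("Na" or "K"), `grid_step`, `tol`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "fixture"),
                            seed = 1L,
                            simulator = list(),
                            reduction = list(),
                            fit = list(),
                            tautomer = list()) {
  mode <- match.arg(mode)
  # integers coming back from JSON are normalised to double so that a
  # config survives serialize/parse round-trips identically
  merge_opts <- function(defaults, given, where) {
    given <- as.list(given)
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) {
      stop("unknown ", where, " option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out <- utils::modifyList(as.list(defaults), given)
    lapply(out, function(v) if (is.integer(v)) as.numeric(v) else v)
  }
  simulator <- merge_opts(list(kind = "kseries",
                               species = "Thy-Na+",
                               dH = -61.1, dS = -66.1,
                               forward_rates = 0.01,
                               temperatures = seq(350, 550, length.out = 8),
                               relative_noise = 0.05,
                               conditions = list()),
                          simulator, "simulator")
  stopifnot(simulator$kind %in% c("kseries", "atd"))
  simulator$conditions <- merge_opts(formals(cell_conditions),
                                     simulator$conditions,
                                     "simulator$conditions")
  reduction <- merge_opts(list(baseline_channels = 50, count_floor = 10,
                               n_bins = 8, require_eq_pass = FALSE),
                          reduction, "reduction")
  fit <- merge_opts(list(weights = "sigma", report_temperature = T_REPORT),
                    fit, "fit")
  tautomer <- merge_opts(list(cation = "Na", grid_step = 0.02, tol = 1),
                         tautomer, "tautomer")
  structure(list(mode = mode, seed = as.integer(seed),
                 simulator = simulator, reduction = reduction,
                 fit = fit, tautomer = tautomer),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline_config
#' @param json JSON text or a path to a JSON file.
#' @export
parse_config <- function(json) {
  if (length(json) == 1 && !grepl("[{]", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  top <- setdiff(names(raw), c("mode", "seed", "simulator", "reduction",
                               "fit", "tautomer"))
  if (length(top)) {
    stop("unknown top-level config key(s): ", paste(top, collapse = ", "),
         call. = FALSE)
  }
  pipeline_config(mode = raw$mode %||% "simulate",
                  seed = raw$seed %||% 1L,
                  simulator = raw$simulator %||% list(),
                  reduction = raw$reduction %||% list(),
                  fit = raw$fit %||% list(),
                  tautomer = raw$tautomer %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Composes the stages simulate (optional) -> reduce -> equilibrium
#' constants -> van't Hoff fit -> tautomer correlation, logging exclusions
#' and seeds, and optionally writes a machine-readable JSON report plus a
#' paper-style formatted CSV table. With `mode = "fixture"` the
#' thermochemistry stages are replaced by the bundled reference tables and
#' only the Gibbs/correlation/mixture analysis runs.
#'
#' @param config A [pipeline_config()] (or a path/JSON parsed through
#'   [parse_config()]).
#' @param out_dir Optional output directory for `report.json` and
#'   `thermo_table.csv`.
#' @return A `pipeline_report` list: `config`, `thermo` (list of
#'   `thermo_result` or the fixture table), `table` (formatted rows),
#'   `correlation` (per-cation fit + effective-MIA inversion + weighted
#'   MIA), `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- parse_config(config)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (config$mode == "simulate") {
    sim <- config$simulator
    steps <- seq_along(sim$dH)
    results <- vector("list", length(steps))
    if (sim$kind == "kseries") {
      for (i in steps) {
        sd_i <- derive_seed(config$seed, paste0("kseries:", i))
        note("simulate: K series step %d, seed %d", i, sd_i)
        series <- simulate_k_series(sim$dH[i], sim$dS[i], sim$temperatures,
                                    sim$relative_noise, seed = sd_i,
                                    species = sim$species, n = i)
        results[[i]] <- vant_hoff_fit(series, weights = config$fit$weights)
      }
    } else {
      scheme <- kinetic_scheme(data.frame(dH = sim$dH, dS = sim$dS),
                               forward_rates = sim$forward_rates)
      meas <- rep(list(list()), length(steps))
      for (Tk in sim$temperatures) {
        cond_args <- utils::modifyList(sim$conditions,
                                       list(temperature = Tk))
        cond <- do.call(cell_conditions, cond_args)
        sd_T <- derive_seed(config$seed, sprintf("atd:%.6g", Tk))
        note("simulate: ATDs at T = %g K, seed %d", Tk, sd_T)
        ds <- simulate_atds(scheme, cond, seed = sd_T,
                            species_prefix = sim$species)
        areas <- lapply(ds$atds, integrate_atd,
                        baseline_channels = config$reduction$baseline_channels)
        for (i in steps) {
          chk <- tryCatch(
            ratio_vs_residence_time(ds$atds[[i + 1]], ds$atds[[i]],
                                    n_bins = config$reduction$n_bins,
                                    count_floor = config$reduction$count_floor),
            error = function(e) NULL)
          if (is.null(chk)) {
            note("reduce: step %d at T = %g K: ratio test not evaluable", i, Tk)
          }
          meas[[i]] <- c(meas[[i]], list(hydration_measurement(
            species = sim$species, n = i,
            I_n = areas[[i + 1]]$area, sigma_In = areas[[i + 1]]$sigma,
            I_nm1 = areas[[i]]$area, sigma_Inm1 = areas[[i]]$sigma,
            water_pressure = cond$water_pressure, temperature = Tk,
            eq_passed = if (is.null(chk)) NA else chk$passed)))
        }
      }
      for (i in steps) {
        series <- build_series(meas[[i]],
                               require_eq_pass = config$reduction$require_eq_pass)
        results[[i]] <- vant_hoff_fit(series, weights = config$fit$weights)
      }
    }
    thermo <- results
    table <- format_thermo_table(results)
  } else {
    thermo <- nucleobase_hydration_thermo()
    table <- thermo
    note("fixture: using bundled reference thermochemistry table")
  }

  correlation <- lapply(c(Na = "Na", K = "K"), function(cat) {
    taut <- cytosine_tautomers(cat)
    wm <- weighted_mia(taut)
    pts <- correlation_points(cat, n = 1L)
    model <- fit_correlation(pts)
    loo <- fit_correlation(pts[pts$label != "Cyt", ])
    cyt_binding <- pts$binding[pts$label == "Cyt"]
    list(weighted_mia = wm,
         model = model,
         model_without_cytosine = loo,
         cytosine_effective_mia = infer_effective_mia(cyt_binding, loo))
  })
  note("tautomer: weighted MIA Na = %g, K = %g kJ/mol",
       correlation$Na$weighted_mia, correlation$K$weighted_mia)

  report <- structure(list(config = config, thermo = thermo, table = table,
                           correlation = correlation, log = log),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "thermo_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Full-precision serializable view of a pipeline report.
report_to_list <- function(report) {
  thermo <- if (is.data.frame(report$thermo)) {
    report$thermo
  } else {
    lapply(report$thermo, function(r) r[c("species", "n", "dH", "sd_dH",
                                          "dS", "sd_dS", "cov_dH_dS",
                                          "dG298", "sd_dG298", "n_points",
                                          "reduced_chi2")])
  }
  corr <- lapply(report$correlation, function(cc) {
    list(weighted_mia = cc$weighted_mia,
         slope = cc$model$slope, intercept = cc$model$intercept,
         r_squared = cc$model$r_squared,
         loo_slope = cc$model_without_cytosine$slope,
         loo_intercept = cc$model_without_cytosine$intercept,
         cytosine_effective_mia = cc$cytosine_effective_mia)
  })
  list(seed = report$config$seed, mode = report$config$mode,
       thermo = thermo, table = report$table, correlation = corr,
       log = report$log)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> mode = %s, seed = %d\n",
              x$config$mode, x$config$seed))
  print(x$table)
  for (cat_ in names(x$correlation)) {
    cc <- x$correlation[[cat_]]
    cat(sprintf("%s+: weighted MIA = %.4g kJ/mol, slope = %.4f, Cyt effective MIA = %.4g kJ/mol\n",
                cat_, cc$weighted_mia, cc$model$slope,
                cc$cytosine_effective_mia))
  }
  invisible(x)
}
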