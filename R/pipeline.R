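# End-to-end workflow: total effects, direct effects, sensitivity suite,
# evidence labelling and reporting, driven by a run configuration.

#' Build a run configuration
#'
#' Houses every analysis constant: instrument threshold, clumping r2,
#' palindrome window, proxy r2, phenotypic correlation, estimator settings
#' and the two evidence alpha levels (0.05 nominal; 0.0125 strong =
#' 0.05 / (2 blood-pressure traits x 2 outcome groups)).
#'
#' @param p_threshold instrument p threshold (default 5e-8)
#' @param clump_r2 LD-independence threshold (default 0.001)
#' @param palindrome_window exclusive ambiguity window (default c(0.42, 0.58))
#' @param proxy_r2_min minimum proxy r2 (default 0.8)
#' @param rho phenotypic correlation between exposures (default 0.69)
#' @param ldsc_intercept SE-inflation intercept for composite endpoints
#'   (config input, e.g. 1.337)
#' @param n_bootstrap,n_presso_sim estimator settings
#' @param nominal_alpha,strong_alpha evidence thresholds
#' @param unit_increments named per-exposure native-unit increments for the
#'   interpretability scaling (e.g. c(sbp = 10, dbp = 5) mmHg)
#' @param seed run seed (recorded in the manifest)
#' @return object of class `mr_config`
#' @export
mr_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                      palindrome_window = c(0.42, 0.58), proxy_r2_min = 0.8,
                      rho = 0.69, ldsc_intercept = 1.337,
                      n_bootstrap = 1000, n_presso_sim = 1000,
                      nominal_alpha = 0.05, strong_alpha = 0.0125,
                      unit_increments = c(sbp = 10, dbp = 5), seed = 1) {
  stopifnot(p_threshold > 0, p_threshold <= 1, clump_r2 >= 0, clump_r2 <= 1,
            proxy_r2_min >= 0, proxy_r2_min <= 1,
            strong_alpha < nominal_alpha)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 palindrome_window = palindrome_window,
                 proxy_r2_min = proxy_r2_min, rho = rho,
                 ldsc_intercept = ldsc_intercept,
                 n_bootstrap = n_bootstrap, n_presso_sim = n_presso_sim,
                 nominal_alpha = nominal_alpha, strong_alpha = strong_alpha,
                 unit_increments = unit_increments, seed = seed),
            class = "mr_config")
}

#' Read a run configuration from YAML or JSON
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return an [mr_config]
#' @export
read_mr_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$unit_increments)) vals$unit_increments <- unlist(vals$unit_increments)
  if (!is.null(vals$palindrome_window)) vals$palindrome_window <- unlist(vals$palindrome_window)
  do.call(mr_config, vals)
}

#' Label MR results by strength of evidence
#'
#' `strong` for p < `strong_alpha` (Bonferroni-corrected), `suggestive` for
#' `strong_alpha <= p < nominal_alpha`, else `none`. The boundary
#' p = `strong_alpha` is labelled suggestive.
#'
#' @param results data.frame with a `pvalue` column
#' @param strong_alpha default 0.0125
#' @param nominal_alpha default 0.05
#' @return the data.frame with an `evidence` column appended
#' @export
label_evidence <- function(results, strong_alpha = 0.0125, nominal_alpha = 0.05) {
  results$evidence <- ifelse(results$pvalue < strong_alpha, "strong",
                             ifelse(results$pvalue < nominal_alpha, "suggestive", "none"))
  results
}

#' Rescale per-SD results to native-unit increments
#'
#' Estimates per SD of the exposure are converted to estimates per
#' `increment` native units by the factor `increment / trait_sd` on the
#' linear (or log-odds) scale.
#'
#' @param results data.frame from the run functions (per-SD scale)
#' @param exposure_sds named vector of phenotypic SDs in native units
#' @param increments named vector of native-unit increments (e.g.
#'   c(sbp = 10, dbp = 5))
#' @return rescaled data.frame
#' @export
rescale_results <- function(results, exposure_sds, increments) {
  fac <- increments[results$exposure] / exposure_sds[results$exposure]
  fac[is.na(fac)] <- 1
  for (col in c("estimate", "se", "ci_low", "ci_high", "egger_intercept")) {
    results[[col]] <- results[[col]] * fac
  }
  binary <- !is.na(results$or)
  results$or[binary] <- exp(results$estimate[binary])
  results$or_ci_low[binary] <- exp(results$ci_low[binary])
  results$or_ci_high[binary] <- exp(results$ci_high[binary])
  results
}

#' Run the full MR workflow
#'
#' Executes instrument selection, clumping, harmonisation, diagnostics, the
#' univariable suite per exposure-outcome pair, the annotation-screened
#' sensitivity repeat, the multivariable suite (optionally with
#' covariate-exposure adjustment), and evidence labelling; results are
#' produced per SD and per native-unit increment. A machine-readable
#' manifest records thresholds, seeds, exclusions and the package version.
#' Any stage failure aborts with the stage name; completed stages are kept
#' in the partial output.
#'
#' @param exposures named list of [sumstats] exposure tables
#' @param outcomes named list of [sumstats] outcome tables
#' @param ld an [ld_reference] or NULL
#' @param annotations annotation data.frame for the pleiotropy screen, or
#'   NULL to skip
#' @param covariates optional named list of covariate [sumstats] tables for
#'   the adjusted multivariable sensitivity model
#' @param config an [mr_config]
#' @return list of class `mr_report`: `univariable`, `univariable_screened`,
#'   `multivariable`, `diagnostics`, `per_unit` tables, `manifest`
#' @export
run_mr_workflow <- function(exposures, outcomes, ld = NULL, annotations = NULL,
                            covariates = NULL, config = mr_config()) {
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_usage(sprintf("workflow stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  uni <- stage("univariable", {
    run_total_effects(exposures, outcomes, ld = ld,
                      p_threshold = config$p_threshold, clump_r2 = config$clump_r2,
                      n_bootstrap = config$n_bootstrap,
                      n_presso_sim = config$n_presso_sim, seed = config$seed)
  })
  hsets <- attr(uni, "hsets")
  report$univariable <- label_evidence(uni, config$strong_alpha, config$nominal_alpha)

  report$diagnostics <- stage("diagnostics", {
    lapply(hsets, function(hs) instrument_diagnostics(hs, rho = config$rho))
  })

  if (!is.null(annotations)) {
    report$univariable_screened <- stage("annotation-screen", {
      rows <- list()
      for (key in names(hsets)) {
        hs <- screen_annotations(hsets[[key]], annotations)
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        binary <- hs$outcome_type == "binary"
        rows[[length(rows) + 1L]] <- mr_result_row(mr_ivw(hs), parts[1], parts[2], binary)
      }
      label_evidence(do.call(rbind, rows), config$strong_alpha, config$nominal_alpha)
    })
  }

  report$multivariable <- stage("multivariable", {
    mv <- run_direct_effects(exposures, outcomes, ld = ld, covariates = NULL,
                             p_threshold = config$p_threshold,
                             clump_r2 = config$clump_r2, rho = config$rho,
                             n_bootstrap = config$n_bootstrap,
                             n_presso_sim = config$n_presso_sim, seed = config$seed)
    out <- label_evidence(mv, config$strong_alpha, config$nominal_alpha)
    attr(out, "diagnostics") <- attr(mv, "diagnostics")
    out
  })
  report$multivariable_diagnostics <- attr(report$multivariable, "diagnostics")

  if (!is.null(covariates)) {
    report$multivariable_adjusted <- stage("multivariable-adjusted", {
      mv <- run_direct_effects(exposures, outcomes, ld = ld, covariates = covariates,
                               p_threshold = config$p_threshold,
                               clump_r2 = config$clump_r2, rho = config$rho,
                               n_bootstrap = config$n_bootstrap,
                               n_presso_sim = config$n_presso_sim, seed = config$seed,
                               methods = "ivw")
      label_evidence(mv, config$strong_alpha, config$nominal_alpha)
    })
  }

  exposure_sds <- vapply(exposures, function(e) e$trait_sd, numeric(1))
  report$per_unit <- stage("per-unit scaling", {
    list(univariable = rescale_results(report$univariable, exposure_sds,
                                       config$unit_increments),
         multivariable = rescale_results(report$multivariable, exposure_sds,
                                         config$unit_increments))
  })

  exclusions <- do.call(rbind, c(
    lapply(names(hsets), function(key) {
      log <- hsets[[key]]$exclusion_log
      if (nrow(log)) cbind(analysis = key, log) else NULL
    }),
    lapply(names(report$multivariable_diagnostics), function(yn) {
      log <- report$multivariable_diagnostics[[yn]]$exclusions
      if (nrow(log)) cbind(analysis = paste0("multivariable.", yn), log) else NULL
    })))
  report$manifest <- list(
    package_version = as.character(utils::packageVersion("gwasmr")),
    config = unclass(config),
    exposures = names(exposures), outcomes = names(outcomes),
    n_instruments = lapply(hsets, n_snps),
    exclusions = exclusions %||% data.frame(analysis = character(0),
                                            variant_id = character(0),
                                            reason = character(0)))
  class(report) <- "mr_report"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d univariable rows, %d multivariable rows, %d exclusions logged\n",
              nrow(x$univariable), nrow(x$multivariable),
              nrow(x$manifest$exclusions)))
  invisible(x)
}

#' Write an `mr_report` to disk
#'
#' results.tsv (univariable + multivariable, per SD), results_per_unit.tsv,
#' diagnostics.json and manifest.json.
#'
#' @param report an `mr_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_mr_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  combined <- rbind(cbind(analysis = "univariable", report$univariable),
                    cbind(analysis = "multivariable", report$multivariable))
  data.table::fwrite(combined, file.path(dir, "results.tsv"), sep = "\t")
  per_unit <- rbind(cbind(analysis = "univariable", report$per_unit$univariable),
                    cbind(analysis = "multivariable", report$per_unit$multivariable))
  data.table::fwrite(per_unit, file.path(dir, "results_per_unit.tsv"), sep = "\t")
  jsonlite::write_json(report$diagnostics, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
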