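#' Pipeline configuration
#'
#' One serializable object drives the whole analysis: simulate (or load) a
#' cohort, threshold weak regions, fit and apply the injection-volume
#' power law, scale regions to unit mean, fit the per-region GLM, run the
#' bootstrap test of the mean condition coefficient, build the
#' region-correlation graph and its multiscale partitions, and classify
#' animals by leave-one-out. One master seed fans out deterministically
#' into per-stage seeds (generate, bootstrap, cluster, classify), so a
#' config plus its seed reproduces every output.
#'
#' @param input optional list of paths (\code{values}, \code{metadata},
#'   \code{ontology}) to load a cohort from disk; \code{NULL} simulates
#'   one.
#' @param generator a \code{\link{synth_config}} used when simulating.
#' @param subset_sex optionally restrict to \code{"M"} or \code{"F"}
#'   animals before analysis (the sex-stratified reanalysis).
#' @param min_mean_pf region retention threshold.
#' @param bootstrap_R,bootstrap_tail bootstrap resamples per group and
#'   tested tail.
#' @param cluster_times,cluster_restarts Markov-time grid and optimizer
#'   restarts; \code{do_cluster = FALSE} skips clustering (and
#'   classification then runs on raw residualized regions).
#' @param classifier_rounds,classifier_depth,scale_policy classifier
#'   settings; \code{do_classify = FALSE} skips classification.
#' @param seed master seed.
#' @param out_dir optional directory for stage artifacts and the report.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = NULL,
                            generator = synth_config(),
                            subset_sex = NULL,
                            min_mean_pf = 0.001,
                            bootstrap_R = 50L,
                            bootstrap_tail = "positive",
                            do_cluster = TRUE,
                            cluster_times = 10 ^ seq(-2, 2, length.out = 20),
                            cluster_restarts = 20L,
                            do_classify = TRUE,
                            classifier_rounds = 100L,
                            classifier_depth = 1L,
                            scale_policy = "inner",
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(input = input, generator = generator, subset_sex = subset_sex,
              min_mean_pf = min_mean_pf,
              bootstrap_R = bootstrap_R, bootstrap_tail = bootstrap_tail,
              do_cluster = do_cluster, cluster_times = cluster_times,
              cluster_restarts = cluster_restarts,
              do_classify = do_classify,
              classifier_rounds = classifier_rounds,
              classifier_depth = classifier_depth,
              scale_policy = scale_policy,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns findings rather than erroring so
#' callers can report all problems at once.
#'
#' @param config a \code{pipeline_config}.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!inherits(config, "pipeline_config"))
    return("not a pipeline_config object")
  if (!is.null(config$input)) {
    need <- c("values", "metadata", "ontology")
    miss <- setdiff(need, names(config$input))
    if (length(miss) > 0L)
      note(paste0("input lacks path(s): ", paste(miss, collapse = ", ")))
  } else if (!inherits(config$generator, "synth_config")) {
    note("generator must be a synth_config when no input paths are given")
  }
  if (!is.null(config$subset_sex) && !config$subset_sex %in% c("M", "F"))
    note("subset_sex must be NULL, 'M' or 'F'")
  if (!is.numeric(config$min_mean_pf) || config$min_mean_pf < 0)
    note("min_mean_pf must be a non-negative number")
  if (!is.numeric(config$bootstrap_R) || config$bootstrap_R < 1)
    note("bootstrap_R must be at least 1")
  if (!config$bootstrap_tail %in% c("positive", "negative"))
    note("bootstrap_tail must be 'positive' or 'negative'")
  if (any(config$cluster_times <= 0))
    note("cluster_times must be positive")
  if (is.unsorted(config$cluster_times))
    note("cluster_times must be sorted ascending")
  if (!is.numeric(config$cluster_restarts) || config$cluster_restarts < 1)
    note("cluster_restarts must be at least 1")
  if (!is.numeric(config$classifier_rounds) || config$classifier_rounds < 1)
    note("classifier_rounds must be at least 1")
  if (!is.numeric(config$classifier_depth) || config$classifier_depth < 1)
    note("classifier_depth must be at least 1")
  if (!config$scale_policy %in% c("inner", "fixed", "per-scale"))
    note(paste0("unknown scale_policy '", config$scale_policy, "'"))
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    note("seed must be an integer")
  problems
}

#' Run the full analysis pipeline
#'
#' Executes the canonical stage chain on a loaded or simulated cohort and
#' returns (and optionally writes) a combined report: power-law fit, mean
#' condition coefficient, bootstrap p value, partition hierarchy summary,
#' and classification accuracy with its exact binomial significance.
#'
#' @param config a \code{pipeline_config} (validated first; any problem
#'   aborts).
#' @return a \code{pipeline_report} list with elements \code{cohort_summary},
#'   \code{removed_regions}, \code{power_law}, \code{glm}, \code{mu_kc},
#'   \code{bootstrap}, \code{hierarchy}, \code{classification},
#'   \code{seeds}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  problems <- validate_config(config)
  if (length(problems) > 0L)
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))

  seeds <- stats::setNames(derive_seeds(config$seed, length(PIPELINE_STAGES_SEEDED)),
                           PIPELINE_STAGES_SEEDED)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  cohort <- run_stage("input", {
    if (!is.null(config$input)) {
      load_cohort(config$input$values, config$input$metadata,
                  config$input$ontology)
    } else {
      g <- generate_cohort(config$generator, seed = seeds[["generate"]])
      truth <- g$truth
      g$cohort
    }
  })
  if (!is.null(config$subset_sex)) {
    sx <- config$subset_sex
    cohort <- run_stage("subset",
                        subset_cohort(cohort, function(a) a$sex == sx))
  }

  thr <- run_stage("threshold", threshold_regions(cohort, config$min_mean_pf))
  pl <- run_stage("fit_volume", fit_volume_exponent(thr$cohort))
  voln <- run_stage("normalize", normalize_by_volume(thr$cohort, pl$exponent))
  um <- run_stage("unit_mean", unit_mean_normalize(voln))

  glm_fit <- run_stage("glm", fit_region_glm(um, include_condition = TRUE))
  mu <- mean_condition_effect(glm_fit)
  boot <- run_stage("bootstrap",
                    bootstrap_condition_test(um, R = config$bootstrap_R,
                                             tail = config$bootstrap_tail,
                                             seed = seeds[["bootstrap"]]))

  hierarchy <- NULL
  if (isTRUE(config$do_cluster)) {
    hierarchy <- run_stage("cluster", {
      feats <- residualize_covariates(um)
      graph <- region_correlation_graph(feats)
      markov_stability_scan(graph, times = config$cluster_times,
                            n_restarts = config$cluster_restarts,
                            seed = seeds[["cluster"]])
    })
  }
  classification <- NULL
  if (isTRUE(config$do_classify)) {
    classification <- run_stage("classify",
      loocv_classify(um, hierarchy = hierarchy,
                     rounds = config$classifier_rounds,
                     depth = config$classifier_depth,
                     scale_policy = config$scale_policy,
                     fixed_scale = if (config$scale_policy == "fixed") 1L else NULL))
  }

  report <- structure(
    list(cohort_summary = list(
           n_animals = nrow(um$values),
           n_regions_raw = ncol(cohort$values),
           n_regions_retained = ncol(um$values),
           hemisphere = um$hemisphere),
         removed_regions = thr$removed,
         power_law = pl,
         glm = glm_fit,
         mu_kc = mu,
         bootstrap = boot,
         hierarchy = hierarchy,
         classification = classification,
         truth = truth,
         seeds = as.list(seeds),
         config = config),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$glm), file.path(out_dir, "glm_fit.csv"),
                   row.names = FALSE)
  summary <- list(
    cohort = report$cohort_summary,
    removed_regions = report$removed_regions,
    power_law = report$power_law[c("exponent", "prefactor", "r_squared")],
    mu_kc = report$mu_kc,
    bootstrap = report$bootstrap[c("observed_mu_kc", "tail", "R", "comparisons",
                                   "tail_fraction", "p_floor", "p_value")],
    hierarchy = if (!is.null(report$hierarchy))
      lapply(report$hierarchy, function(s)
        list(time = s$time, n_clusters = s$n_clusters,
             stability = s$stability, labels = as.list(s$labels))),
    classification = if (!is.null(report$classification))
      report$classification[c("errors", "n_animals", "accuracy",
                              "accuracy_pct", "binomial_p", "scale_policy")],
    seeds = report$seeds)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # bootstrap draws kept separately for audit
  jsonlite::write_json(report$bootstrap$mu_kc_samples,
                       file.path(out_dir, "bootstrap_mu_kc_samples.json"),
                       digits = NA)
  invisible(file.path(out_dir, "report.json"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cohort: %d animals, %d/%d regions retained (%s)\n",
              x$cohort_summary$n_animals, x$cohort_summary$n_regions_retained,
              x$cohort_summary$n_regions_raw, x$cohort_summary$hemisphere))
  cat(sprintf("  power law: n = %.4g (R^2 = %.3f)\n",
              x$power_law$exponent, x$power_law$r_squared))
  cat(sprintf("  mean condition coefficient = %.4g, bootstrap p = %.4g (%s tail)\n",
              x$mu_kc, x$bootstrap$p_value, x$bootstrap$tail))
  if (!is.null(x$hierarchy))
    cat(sprintf("  hierarchy: %d scales, %d..%d clusters\n",
                length(x$hierarchy),
                min(vapply(x$hierarchy, `[[`, 1, "n_clusters")),
                max(vapply(x$hierarchy, `[[`, 1, "n_clusters"))))
  if (!is.null(x$classification))
    cat(sprintf("  classification: %d%% accuracy (%d errors), binomial p = %.4g\n",
                x$classification$accuracy_pct, x$classification$errors,
                x$classification$binomial_p))
  invisible(x)
}
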