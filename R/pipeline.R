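#' Run the full community-change analysis pipeline
#'
#' Orchestrates every stage on one configuration: ingest (or simulate)
#' occurrences, apply the phenological filter, pool records into time
#' layers, build the incidence matrix, partition species statuses, score
#' the specialization register, compute Gower/PCoA/FDis, assemble the
#' community time series, fit the trend and status models, and run the
#' Sorensen NMDS with permutation vector fitting. All outputs are written
#' as CSV/JSON to the output directory together with a manifest recording
#' options, seeds and warnings.
#'
#' @param config Named list (or path to a JSON/YAML file) with either
#'   real-data inputs (`occurrences`, `traits`, `layers` file paths) or a
#'   `scenario` block of [scenario_config()] arguments - exactly one of the
#'   two; plus optional `cut_year` (default 1997), `correction` (default
#'   "sqrt"), `basis_dim` (default 4), `n_restarts` (default 50),
#'   `n_permutations` (default 999), `seed` (default 1), `out_dir`.
#' @return Invisibly, a list with all stage results (`incidence`,
#'   `statuses`, `scores`, `series`, `trends`, `status_models`,
#'   `ordination`, `vector_fits`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(cut_year = 1997L, correction = "sqrt", basis_dim = 4,
                   n_restarts = 50L, n_permutations = 999L, seed = 1L,
                   out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  has_files <- !is.null(config$occurrences)
  has_scenario <- !is.null(config$scenario)
  if (has_files == has_scenario) {
    stop("config must provide exactly one of real-data paths or a scenario")
  }
  warnings_log <- character()
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = note),
             error = function(e) {
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }

  if (has_scenario) {
    sc <- config$scenario
    if (is.character(sc)) sc <- list(scenario = sc)
    if (is.null(sc$seed)) sc$seed <- config$seed
    cfg <- do.call(scenario_config, sc)
    pool <- stage("simulate",
                  generate_species_pool(cfg$n_species, seed = cfg$seed))
    sim <- stage("simulate", simulate_occurrence_history(pool, cfg))
    records <- sim$occurrences
    traits <- sim$trait_table
    scheme <- sim$scheme
    config$cut_year <- sim$cut_year
  } else {
    records <- stage("ingest", load_occurrences(config$occurrences))
    traits <- stage("ingest", utils::read.csv(config$traits,
                                              stringsAsFactors = FALSE))
    scheme <- stage("ingest", time_layer_scheme(
      utils::read.csv(config$layers, stringsAsFactors = FALSE)))
  }

  records <- stage("filter", apply_phenological_filter(records, traits))
  labelled <- stage("layers", assign_time_layers(records, scheme))
  incidence <- stage("layers", build_incidence(labelled, scheme))
  statuses <- stage("status",
                    assign_status(incidence, cut_year = config$cut_year,
                                  scheme = scheme))
  scores <- stage("scores", score_specialization(
    traits[traits$species_id %in% rownames(incidence), , drop = FALSE]))

  tm <- stage("funcdiv",
              build_functional_matrix(traits, rownames(incidence)))
  emb <- stage("funcdiv", pcoa_embed(gower_matrix(tm),
                                     correction = config$correction))
  fdis_values <- stage("funcdiv", fdis_per_layer(emb, incidence))

  series <- stage("trends",
                  layer_metrics(incidence, traits, scores = scores,
                                fdis_values = fdis_values, scheme = scheme))
  trend_responses <- c("log_mean_wingspan", "mean_total_specialization",
                       "logit_prop_open", "fdis")
  trends <- lapply(trend_responses, function(r) {
    stage("trends", fit_trend_gam(series, r, basis_dim = config$basis_dim))
  })
  names(trends) <- trend_responses
  status_models <- list(
    wingspan = stage("trends", fit_wingspan_status_model(traits, statuses)))
  for (r in c("food_score", "range_score", "habitat_score",
              "total_specialization")) {
    status_models[[r]] <- stage("trends", fit_specialization_status_model(
      scores, statuses, traits, response = r))
  }

  keep <- colSums(incidence) > 0
  D <- stage("ordination",
             sorensen_dissimilarity(incidence[, keep, drop = FALSE]))
  ord <- stage("ordination", nmds(D, n_restarts = config$n_restarts,
                                  seed = config$seed))
  descr <- series[match(ord$layer_labels, series$layer_label),
                  c("log_mean_wingspan", "mean_total_specialization",
                    "logit_prop_open")]
  vfits <- stage("ordination",
                 permutation_vector_fit(ord, descr,
                                        n_permutations =
                                          config$n_permutations,
                                        seed = config$seed))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mothdrift")),
    stages = c("records", "traits", "funcdiv", "community_trends",
               "ordination"),
    n_species = nrow(incidence), n_layers = ncol(incidence),
    status_counts = as.list(attr(statuses, "counts")),
    cut_year = config$cut_year,
    correction = emb$correction_applied,
    seed = config$seed,
    nmds_stress = ord$stress,
    options = config[c("basis_dim", "n_restarts", "n_permutations")],
    warnings = warnings_log)

  result <- list(incidence = incidence, statuses = statuses,
                 scores = scores, series = series, trends = trends,
                 status_models = status_models, ordination = ord,
                 vector_fits = vfits, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(species_id = rownames(result$incidence),
                              result$incidence, check.names = FALSE),
                   file.path(out_dir, "incidence.csv"), row.names = FALSE)
  utils::write.csv(result$statuses, file.path(out_dir, "status.csv"),
                   row.names = FALSE)
  utils::write.csv(result$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$series, file.path(out_dir, "time_series.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(layer = result$ordination$layer_labels,
                              result$ordination$coordinates),
                   file.path(out_dir, "ordination.csv"), row.names = FALSE)
  utils::write.csv(result$vector_fits,
                   file.path(out_dir, "vector_fits.csv"), row.names = FALSE)
  fits <- list(
    trends = lapply(result$trends, function(t)
      t[c("response_name", "smooth_edf", "coefficient", "test_statistic",
          "p_value", "adjusted_r2")]),
    status_models = lapply(result$status_models, function(m)
      m[c("response_name", "test_statistic", "p_value", "marginal_r2",
          "conditional_r2", "random_intercept_variance")]))
  jsonlite::write_json(fits, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
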