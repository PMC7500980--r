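#' Scenario configuration for synthetic communities
#'
#' Bundles and validates the parameters of the occupancy simulator. The four
#' scenarios mirror qualitatively distinct community dynamics: `neutral` is
#' pure ecological drift (trait-independent extinction and colonization),
#' `size_filter` raises local-extinction odds with body size,
#' `succession` progressively removes open-habitat species while forest
#' species colonize more readily (land-use abandonment), and
#' `generalization` draws late colonists with traits shrunk toward the pool
#' centroid (community-wide loss of specialization). The latter two both
#' depress functional dispersion in late layers; neutral drift does not.
#'
#' @param scenario One of `"neutral"`, `"size_filter"`, `"succession"`,
#'   `"generalization"`.
#' @param n_species Species pool size (default 300, >= 10).
#' @param n_layers Number of time layers (default 12, >= 4).
#' @param seed Integer seed.
#' @param baseline_extinction_prob Per-layer local extinction probability.
#' @param baseline_colonization_prob Per-layer colonization probability.
#' @param initial_occupancy Probability a species is present in layer 1.
#'   Defaults to the stationary occupancy of the baseline chain,
#'   `colonization / (colonization + extinction)`, so that drift alone
#'   produces no systematic richness trend.
#' @param size_effect_slope Log-odds of local extinction added per unit of
#'   centred log-wingspan (active in `size_filter`).
#' @param open_habitat_decline_rate Per-layer multiplicative survival factor
#'   for open-habitat species (active in `succession`); forest colonization
#'   ramps up symmetrically.
#' @param trait_shrink_factor Shrinkage of late colonists' traits toward the
#'   pool centroid, in (0, 1\]; 1 means no shrinkage (active in
#'   `generalization`).
#' @param detection_prob Probability a latent presence yields a record.
#' @param size_biased_detection Optional log-odds of detection per unit of
#'   centred log-wingspan (default 0: detection is trait-independent).
#' @return Validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("neutral", "size_filter",
                                         "succession", "generalization"),
                            n_species = 300L, n_layers = 12L, seed = 1L,
                            baseline_extinction_prob = 0.15,
                            baseline_colonization_prob = 0.08,
                            initial_occupancy = NULL,
                            size_effect_slope = 2,
                            open_habitat_decline_rate = 0.7,
                            trait_shrink_factor = 0.4,
                            detection_prob = 0.9,
                            size_biased_detection = 0) {
  scenario <- match.arg(scenario)
  if (is.null(initial_occupancy)) {
    initial_occupancy <- baseline_colonization_prob /
      max(baseline_colonization_prob + baseline_extinction_prob, 1e-12)
  }
  stopifnot(n_species >= 10L, n_layers >= 4L,
            baseline_extinction_prob >= 0, baseline_extinction_prob <= 1,
            baseline_colonization_prob >= 0, baseline_colonization_prob <= 1,
            initial_occupancy >= 0, initial_occupancy <= 1,
            detection_prob > 0, detection_prob <= 1,
            trait_shrink_factor > 0, trait_shrink_factor <= 1,
            open_habitat_decline_rate > 0, open_habitat_decline_rate <= 1)
  structure(list(scenario = scenario, n_species = as.integer(n_species),
                 n_layers = as.integer(n_layers), seed = as.integer(seed),
                 baseline_extinction_prob = baseline_extinction_prob,
                 baseline_colonization_prob = baseline_colonization_prob,
                 initial_occupancy = initial_occupancy,
                 size_effect_slope = size_effect_slope,
                 open_habitat_decline_rate = open_habitat_decline_rate,
                 trait_shrink_factor = trait_shrink_factor,
                 detection_prob = detection_prob,
                 size_biased_detection = size_biased_detection),
            class = "scenario_config")
}

#' Generate a synthetic species trait pool
#'
#' Draws a species pool with the statistical structure of a Mediterranean
#' macro-moth assemblage: log-normal wingspans (right-skewed, median about
#' 33 mm) with a family-level size component, families from a
#' Dirichlet-multinomial, habitat guilds (forest/open/shrub/reed) with
#' fixed proportions, guild-correlated functional traits, and specialization
#' register inputs drawn so totals span 3..12 with the mode near 10 (such
#' faunas are dominated by fairly generalist species). A small fraction of
#' species carries phenological cleaning flags.
#'
#' @param n_species Number of species (>= 10).
#' @param seed Integer seed.
#' @param median_wingspan_mm Median of the wingspan distribution.
#' @param sdlog_wingspan Log-scale standard deviation (within family).
#' @param family_sdlog Log-scale standard deviation of family size effects.
#' @param n_families Number of taxonomic families in the pool.
#' @param guild_prop Named proportions of the four habitat guilds.
#' @param flag_prob Probability a species carries each cleaning flag.
#' @return Species trait data.frame (one row per species) with identifiers,
#'   register inputs, cleaning flags and the 12 functional trait columns.
#' @export
generate_species_pool <- function(n_species = 300L, seed = 1L,
                                  median_wingspan_mm = 33,
                                  sdlog_wingspan = 0.28,
                                  family_sdlog = 0.15,
                                  n_families = 12L,
                                  guild_prop = c(forest = 0.45, open = 0.30,
                                                 shrub = 0.15, reed = 0.10),
                                  flag_prob = 0.02) {
  stopifnot(n_species >= 10L, median_wingspan_mm > 0)
  set.seed(seed)
  n <- as.integer(n_species)
  fam_names <- sprintf("Family%02d", seq_len(n_families))
  fam_w <- as.numeric(stats::rgamma(n_families, shape = 2))
  family <- sample(fam_names, n, replace = TRUE, prob = fam_w / sum(fam_w))
  fam_eff <- stats::setNames(stats::rnorm(n_families, 0, family_sdlog),
                             fam_names)
  # centre realized family effects so the pool median stays anchored
  fam_eff <- fam_eff - mean(fam_eff[family])
  wingspan <- exp(log(median_wingspan_mm) + fam_eff[family] +
                    stats::rnorm(n, 0, sdlog_wingspan))
  guild <- sample(names(guild_prop), n, replace = TRUE, prob = guild_prop)

  # register inputs, skewed toward generalists (total mode near 10)
  breadth_levels <- c("monophagous_genus", "oligophagous_family",
                      "polyphagous_gt1_family",
                      "highly_polyphagous_gt5_families")
  host_breadth <- sample(breadth_levels, n, replace = TRUE,
                         prob = c(0.06, 0.16, 0.38, 0.40))
  lat_by_bin <- list(43:46, 47:50, 51:54, 55:71)
  range_bin <- sample(1:4, n, replace = TRUE,
                      prob = c(0.05, 0.13, 0.30, 0.52))
  northern_limit <- vapply(range_bin,
                           function(b) sample(lat_by_bin[[b]], 1L),
                           integer(1))
  habitat_pool <- c("xeric_grassland", "coppice_forest", "pine_forest",
                    "downy_oak_forest", "riparian_forest", "reed_bed",
                    "dune", "hedgerow", "meadow", "forest_edge")
  n_hab <- sample(1:6, n, replace = TRUE,
                  prob = c(0.05, 0.07, 0.14, 0.18, 0.28, 0.28))
  habitat_types <- vapply(n_hab, function(k) {
    paste(sample(habitat_pool, k), collapse = ";")
  }, character(1))
  habitat_common <- stats::runif(n) < 0.20
  habitat_anthropogenic <- stats::runif(n) < 0.18

  # 12 functional traits with guild-correlated structure
  food_labels <- larval_food_labels()
  woody_fams <- c("Fagaceae", "Salicaceae", "Betulaceae", "Rosaceae",
                  "Pinaceae", "Oleaceae", "Ulmaceae")
  herb_fams <- setdiff(food_labels, c(woody_fams, "detritivore", "lichen"))
  n_food <- pmax(1L, stats::rpois(n, lambda = c(monophagous_genus = 1,
                                                oligophagous_family = 1,
                                                polyphagous_gt1_family = 2.5,
                                                highly_polyphagous_gt5_families = 6
                                                )[host_breadth]))
  larval_food <- vapply(seq_len(n), function(i) {
    pool <- if (guild[i] == "forest") c(woody_fams, herb_fams[1:3]) else
      if (guild[i] == "reed") c("Poaceae", herb_fams) else
        c(herb_fams, "detritivore", "lichen", woody_fams[1:2])
    paste(sample(pool, min(n_food[i], length(pool))), collapse = ";")
  }, character(1))
  host_growth_form <- ifelse(guild == "forest",
                             sample(c("woody", "herbaceous"), n, TRUE,
                                    prob = c(0.8, 0.2)),
                             sample(c("woody", "herbaceous", "graminoid"),
                                    n, TRUE, prob = c(0.2, 0.6, 0.2)))
  pool <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    family = family,
    wingspan_mm = round(wingspan, 1),
    host_breadth = host_breadth,
    northern_limit_deg = northern_limit,
    habitat_types = habitat_types,
    habitat_common = habitat_common,
    habitat_anthropogenic = habitat_anthropogenic,
    open_habitat = guild == "open",
    guild = guild,
    early_late_flyer = stats::runif(n) < flag_prob,
    long_distance_migrant = stats::runif(n) < flag_prob,
    strictly_diurnal = stats::runif(n) < flag_prob,
    proboscis = stats::runif(n) < 0.9,
    larval_food_source = larval_food,
    salt_tolerant_hosts = stats::runif(n) < 0.1,
    ruderal_hosts = stats::runif(n) < 0.25,
    host_growth_form = host_growth_form,
    food_specialization = score_food_specialization(host_breadth),
    habitat_type = guild,
    phenology = sample(c("spring", "early_summer", "summer"), n, TRUE,
                       prob = c(0.2, 0.35, 0.45)),
    voltinism = sample(1:3, n, TRUE, prob = c(0.5, 0.38, 0.12)),
    hibernating_stage = sample(c("egg", "larva", "pupa", "adult"), n, TRUE,
                               prob = c(0.25, 0.4, 0.3, 0.05)),
    range_extent = range_bin,
    stringsAsFactors = FALSE)
  pool
}

#' Simulate a multi-decade occurrence history
#'
#' Evolves per-species presence through the time layers as a two-state
#' Markov chain (local extinction / colonization), modified by the scenario
#' (see [scenario_config()]), then thins latent presences by the detection
#' probability to produce occurrence records. The first third of the layers
#' are "historic" spans pooling several years (museum-style aggregation);
#' the remaining layers are single survey years. The cut year separating
#' pre- and post-cut layers is placed at the first survey layer.
#'
#' @param pool Species trait table from [generate_species_pool()].
#' @param config A [scenario_config()].
#' @return List of class `"synthetic_community"` with elements
#'   `trait_table`, `occurrences` (an occurrence table), `scheme`
#'   ([time_layer_scheme()]), `cut_year`, `incidence_observed` (binary
#'   species x layer matrix of detected presences), `truth` (list with the
#'   latent occupancy matrix and the scenario config).
#' @export
simulate_occurrence_history <- function(pool, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  n <- nrow(pool)
  L <- config$n_layers
  lws <- log(pool$wingspan_mm) - mean(log(pool$wingspan_mm))
  open <- pool$guild == "open"
  forest <- pool$guild == "forest"

  # per-species, per-layer extinction and colonization probabilities
  e0 <- config$baseline_extinction_prob
  c0 <- config$baseline_colonization_prob
  ext <- matrix(e0, n, L)
  col <- matrix(c0, n, L)
  if (config$scenario == "size_filter") {
    ext[] <- stats::plogis(stats::qlogis(pmin(pmax(e0, 1e-6), 1 - 1e-6)) +
                             config$size_effect_slope * lws)
  }
  if (config$scenario == "succession") {
    r <- config$open_habitat_decline_rate
    for (l in seq_len(L)) {
      # open-habitat occupancy shrinks geometrically; forest colonization
      # ramps up as succession closes the canopy
      ext[open, l] <- 1 - (1 - e0) * r
      col[open, l] <- c0 * r^l
      col[forest, l] <- c0 * (1 + (l - 1) / (L - 1))
    }
  }
  occ <- matrix(0L, n, L)
  occ[, 1L] <- stats::rbinom(n, 1L, config$initial_occupancy)
  if (config$scenario == "succession") {
    # succession acts from the very first transition; layer 1 is the
    # extensively managed baseline with open habitats fully available
  }
  for (l in 2:L) {
    stay <- stats::rbinom(n, 1L, 1 - ext[, l]) * occ[, l - 1L]
    arrive <- stats::rbinom(n, 1L, col[, l]) * (1L - occ[, l - 1L])
    occ[, l] <- stay + arrive
  }

  trait_table <- pool
  if (config$scenario == "generalization") {
    # species first appearing in the second half of the series carry traits
    # shrunk toward the pool centroid: community-wide loss of specialization
    first_seen <- apply(occ, 1L, function(z) {
      w <- which(z > 0); if (length(w) == 0L) NA_integer_ else w[1L]
    })
    late <- !is.na(first_seen) & first_seen > ceiling(L / 2)
    s <- config$trait_shrink_factor
    for (qcol in c("wingspan_mm", "food_specialization", "voltinism",
                   "range_extent", "northern_limit_deg")) {
      centre <- mean(trait_table[[qcol]])
      v <- centre + s * (trait_table[[qcol]][late] - centre)
      trait_table[[qcol]][late] <- if (is.integer(trait_table[[qcol]]))
        as.integer(round(v)) else round(v, 1)
    }
    for (ccol in c("host_growth_form", "habitat_type", "phenology",
                   "hibernating_stage")) {
      mode_lvl <- names(which.max(table(trait_table[[ccol]])))
      switch_to_mode <- late & stats::runif(n) < (1 - s)
      trait_table[[ccol]][switch_to_mode] <- mode_lvl
    }
    trait_table$northern_limit_deg <- pmin(pmax(
      trait_table$northern_limit_deg, 43), 71)
  }

  # detection thinning (optionally size-biased, to probe museum bias)
  p_det <- if (config$size_biased_detection != 0) {
    stats::plogis(stats::qlogis(config$detection_prob) +
                    config$size_biased_detection * lws)
  } else rep(config$detection_prob, n)
  det <- matrix(stats::rbinom(n * L, 1L, rep(p_det, L)), n, L)
  obs <- occ * det

  # layer scheme: historic pooled spans, then single survey years
  n_historic <- max(1L, floor(L / 3))
  span <- 8L
  base_year <- 1997L - n_historic * span
  labels <- c(sprintf("H%02d", seq_len(n_historic)),
              as.character(1997L + seq_len(L - n_historic) - 1L))
  scheme <- time_layer_scheme(data.frame(
    label = labels,
    year_min = c(base_year + (seq_len(n_historic) - 1L) * span,
                 1997L + seq_len(L - n_historic) - 1L),
    year_max = c(base_year + seq_len(n_historic) * span - 1L,
                 1997L + seq_len(L - n_historic) - 1L)))
  rec_idx <- which(obs > 0, arr.ind = TRUE)
  years <- vapply(rec_idx[, 2L], function(l) {
    if (scheme$year_min[l] == scheme$year_max[l]) scheme$year_min[l] else
      sample(scheme$year_min[l]:scheme$year_max[l], 1L)
  }, integer(1))
  occurrences <- occurrence_table(
    species_id = pool$species_id[rec_idx[, 1L]],
    year = years,
    source = ifelse(rec_idx[, 2L] <= n_historic, "museum", "survey"))
  dimnames(obs) <- list(pool$species_id, labels)
  dimnames(occ) <- list(pool$species_id, labels)
  attr(obs, "scheme") <- scheme
  structure(list(trait_table = trait_table,
                 occurrences = occurrences,
                 scheme = scheme,
                 cut_year = 1997L,
                 incidence_observed = obs,
                 truth = list(latent = occ, config = config)),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic community:", nrow(x$trait_table), "species,",
      ncol(x$incidence_observed), "layers, scenario",
      x$truth$config$scenario, "\n")
  invisible(x)
}

#' Replicate-level expectations of the scenario generators
#'
#' Runs the analysis pipeline over many simulated replicates of a scenario
#' and summarizes the statistics the scenarios are designed to move: the
#' lost-versus-previously-unrecorded wingspan contrast and its p-value, the
#' ordering of group mean wingspans, and (optionally) the sign and
#' significance of the FDis trend over layers. This is the calibration and
#' power harness for the whole pipeline.
#'
#' @param config A [scenario_config()]; its seed anchors the replicate
#'   seed stream.
#' @param n_replicates Number of independent replicates (>= 2).
#' @param metrics Character subset of `c("wingspan", "fdis")` selecting
#'   which statistics to compute per replicate (FDis is the expensive one).
#' @return List with `per_replicate` (data.frame of per-replicate
#'   statistics) and `summary` (rejection and ordering rates).
#' @export
scenario_expectation_suite <- function(config, n_replicates = 200L,
                                       metrics = c("wingspan", "fdis")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + i * 1000L
    pool <- generate_species_pool(cfg$n_species, seed = cfg$seed)
    sim <- simulate_occurrence_history(pool, cfg)
    inc <- sim$incidence_observed
    inc <- inc[rowSums(inc) > 0, , drop = FALSE]
    st <- assign_status(inc, cut_year = sim$cut_year, scheme = sim$scheme)
    res <- list(replicate = i)
    if ("wingspan" %in% metrics && nlevels(droplevels(st$status)) >= 2L &&
        "lost" %in% st$status && "previously_unrecorded" %in% st$status) {
      fit <- suppressWarnings(
        fit_wingspan_status_model(sim$trait_table, st))
      mw <- tapply(sim$trait_table$wingspan_mm[
        match(st$species_id, sim$trait_table$species_id)], st$status, mean)
      res$wingspan_contrast <- fit$fixed_effects$estimate[
        fit$fixed_effects$contrast == "lost"]
      res$wingspan_p <- fit$p_value
      res$lost_gt_new <- unname(mw["lost"] > mw["previously_unrecorded"])
    }
    if ("fdis" %in% metrics) {
      keep_layers <- colSums(inc) > 1
      inc_f <- inc[, keep_layers, drop = FALSE]
      series <- suppressWarnings(
        layer_metrics(inc_f, sim$trait_table, scheme = sim$scheme))
      tf <- fit_trend_gam(series, "fdis")
      res$fdis_slope <- tf$coefficient
      res$fdis_p <- tf$p_value
    }
    rows[[i]] <- as.data.frame(res)
  }
  per_rep <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- c("replicate", "wingspan_contrast", "wingspan_p",
                  "lost_gt_new", "fdis_slope", "fdis_p")
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  summary <- list(
    n_replicates = n_replicates,
    wingspan_rejection_rate = mean(per_rep$wingspan_p < 0.05, na.rm = TRUE),
    lost_gt_new_rate = mean(per_rep$lost_gt_new, na.rm = TRUE),
    fdis_negative_significant_rate =
      mean(per_rep$fdis_slope < 0 & per_rep$fdis_p < 0.05, na.rm = TRUE),
    mean_fdis_slope = mean(per_rep$fdis_slope, na.rm = TRUE))
  list(per_replicate = per_rep, summary = summary)
}
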