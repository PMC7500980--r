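# Small in-code fixtures shared across test files.

# A hand-built five-species trait table with all register inputs, cleaning
# flags and the 12 functional trait columns.
tiny_traits <- function() {
  data.frame(
    species_id = paste0("sp", 1:5),
    family = c("Noctuidae", "Noctuidae", "Geometridae", "Erebidae",
               "Geometridae"),
    wingspan_mm = c(30, 40, 25, 52, 33),
    host_breadth = c("monophagous_genus", "oligophagous_family",
                     "polyphagous_gt1_family",
                     "highly_polyphagous_gt5_families",
                     "polyphagous_gt1_family"),
    northern_limit_deg = c(44, 49, 53, 60, 47),
    habitat_types = c("xeric_grassland", "meadow;dune;reed_bed",
                      "forest_edge;meadow;hedgerow;dune;pine_forest",
                      "meadow", "downy_oak_forest;pine_forest"),
    habitat_common = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    habitat_anthropogenic = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    open_habitat = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    early_late_flyer = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    long_distance_migrant = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    strictly_diurnal = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    proboscis = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    larval_food_source = c("Poaceae", "Poaceae;Asteraceae",
                           "Fagaceae;Rosaceae", "Asteraceae;Lamiaceae",
                           "Pinaceae"),
    salt_tolerant_hosts = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    ruderal_hosts = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    host_growth_form = c("graminoid", "herbaceous", "woody", "herbaceous",
                         "woody"),
    food_specialization = c(1, 2, 3, 4, 3),
    habitat_type = c("open", "open", "forest", "open", "forest"),
    phenology = c("summer", "spring", "summer", "early_summer", "summer"),
    voltinism = c(1, 2, 1, 2, 1),
    hibernating_stage = c("egg", "larva", "pupa", "larva", "pupa"),
    range_extent = c(1, 2, 3, 4, 2),
    stringsAsFactors = FALSE)
}

# Random mixed-type trait matrix for oracle/property tests.
random_trait_matrix <- function(n, seed, with_missing = FALSE) {
  set.seed(seed)
  tt <- data.frame(
    species_id = sprintf("s%02d", seq_len(n)),
    wingspan_mm = round(rlnorm(n, log(33), 0.3), 1),
    proboscis = runif(n) < 0.8,
    larval_food_source = vapply(seq_len(n), function(i)
      paste(sample(larval_food_labels(), sample(1:5, 1)), collapse = ";"),
      character(1)),
    salt_tolerant_hosts = runif(n) < 0.2,
    ruderal_hosts = runif(n) < 0.3,
    host_growth_form = sample(c("woody", "herbaceous", "graminoid"), n,
                              TRUE),
    food_specialization = sample(1:4, n, TRUE),
    habitat_type = sample(c("forest", "open", "shrub", "reed"), n, TRUE),
    phenology = sample(c("spring", "early_summer", "summer"), n, TRUE),
    voltinism = sample(1:3, n, TRUE),
    hibernating_stage = sample(c("egg", "larva", "pupa", "adult"), n, TRUE),
    range_extent = sample(1:4, n, TRUE),
    stringsAsFactors = FALSE)
  tm <- build_functional_matrix(tt)
  if (with_missing) {
    tm$data$voltinism[1] <- NA
    tm$missing <- is.na(as.matrix(tm$data))
  }
  tm
}

# Minimal labelled record set across two historic and two survey layers.
tiny_records <- function() {
  occurrence_table(
    species_id = c("sp1", "sp1", "sp2", "sp3", "sp3", "sp4", "sp5"),
    year = c(1940, 1995, 1960, 1998, 2011, 1941, 2012),
    source = c("museumA", "museumB", "museumA", "survey", "survey",
               "museumA", "survey"))
}
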