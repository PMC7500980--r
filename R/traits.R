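#' Specialization register: larval food breadth score
#'
#' Scores larval host-plant breadth on the 1 (most specialized) to 4 (least
#' specialized) rank scale: monophagous within one plant genus = 1,
#' oligophagous within one plant family = 2, polyphagous across more than
#' one family = 3, highly polyphagous across more than five families = 4.
#'
#' @param host_breadth Character vector with values among
#'   `"monophagous_genus"`, `"oligophagous_family"`,
#'   `"polyphagous_gt1_family"`, `"highly_polyphagous_gt5_families"`.
#' @return Integer vector of scores in 1..4.
#' @export
score_food_specialization <- function(host_breadth) {
  map <- c(monophagous_genus = 1L,
           oligophagous_family = 2L,
           polyphagous_gt1_family = 3L,
           highly_polyphagous_gt5_families = 4L)
  out <- map[as.character(host_breadth)]
  if (anyNA(out)) {
    stop("unknown host breadth category: ",
         paste(unique(host_breadth[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Specialization register: northern distribution limit score
#'
#' Bins the northern limit of a species' European range (degrees latitude N)
#' into the four register classes: 43-46 (south of the Alps) = 1, 47-50
#' (German highlands) = 2, 51-54 (North/Baltic sea coast) = 3, 55-71
#' (further north) = 4. The register is defined on whole-degree bands, so
#' fractional latitudes are rounded to the nearest degree before binning.
#'
#' @param northern_limit_deg Numeric vector of latitudes (degrees N).
#' @return Integer vector of scores in 1..4.
#' @export
score_northern_limit <- function(northern_limit_deg) {
  deg <- round(as.numeric(northern_limit_deg))
  if (any(is.na(deg) | deg < 43 | deg > 71)) {
    stop("northern limit outside the register (43-71 deg N): ",
         paste(unique(northern_limit_deg[is.na(deg) | deg < 43 | deg > 71]),
               collapse = ", "))
  }
  unname(c(rep(1L, 4), rep(2L, 4), rep(3L, 4), rep(4L, 17))[deg - 42L])
}

#' Specialization register: habitat breadth score
#'
#' Scores habitat use breadth 1..4: 1-2 habitat types = 1, 3-4 types = 2,
#' five or more types or common/nonspecial habitat types = 3, numerous
#' and/or anthropogenically influenced habitats (gardens, parks, urban
#' areas) = 4. The anthropogenic qualifier overrides the count, and the
#' common/nonspecial qualifier promotes to at least 3.
#'
#' @param habitat_types Character vector of habitat labels for one species,
#'   or an integer count of distinct habitat types.
#' @param common Logical; habitat list consists of common/nonspecial types.
#' @param anthropogenic Logical; species uses numerous and/or anthropogenic
#'   habitats.
#' @return Integer score in 1..4.
#' @export
score_habitat <- function(habitat_types, common = FALSE,
                          anthropogenic = FALSE) {
  n <- if (is.numeric(habitat_types)) as.integer(habitat_types[1]) else
    length(unique(habitat_types))
  if (is.na(n) || n < 1L) stop("habitat type list must be non-empty")
  if (isTRUE(anthropogenic)) return(4L)
  if (isTRUE(common)) return(3L)
  if (n <= 2L) 1L else if (n <= 4L) 2L else 3L
}

#' Total specialization score
#'
#' The degree of total specialization is the sum of the food, northern-limit
#' and habitat scores; highly specialized species attain the minimum of 3
#' (three times score 1), extreme generalists the maximum of 12 (three times
#' score 4).
#'
#' @param food_score,range_score,habitat_score Integer component scores, each
#'   in 1..4 (vectors recycled to common length).
#' @return Integer vector of totals in 3..12.
#' @export
total_specialization <- function(food_score, range_score, habitat_score) {
  comp <- cbind(food_score, range_score, habitat_score)
  if (any(is.na(comp)) || any(comp < 1L) || any(comp > 4L) ||
      any(comp != floor(comp))) {
    stop("component scores must be integers in 1..4")
  }
  as.integer(rowSums(comp))
}

#' Score a species trait table on the specialization register
#'
#' Applies the three register dimensions to every species and appends the
#' total. Expects columns `host_breadth`, `northern_limit_deg`, and either a
#' `habitat_types` column (a `;`-separated label list) or a precomputed
#' `n_habitat_types` count, plus optional logical `habitat_common` and
#' `habitat_anthropogenic` qualifiers.
#'
#' @param trait_table Species trait data.frame with a `species_id` column.
#' @return data.frame with `species_id`, `food_score`, `range_score`,
#'   `habitat_score`, `total_specialization`.
#' @export
score_specialization <- function(trait_table) {
  tt <- trait_table
  food <- score_food_specialization(tt$host_breadth)
  range_s <- score_northern_limit(tt$northern_limit_deg)
  n <- nrow(tt)
  common <- if (is.null(tt$habitat_common)) rep(FALSE, n) else
    isTRUE_vec(tt$habitat_common)
  anthro <- if (is.null(tt$habitat_anthropogenic)) rep(FALSE, n) else
    isTRUE_vec(tt$habitat_anthropogenic)
  habitat <- vapply(seq_len(n), function(i) {
    types <- if (!is.null(tt$n_habitat_types)) tt$n_habitat_types[i] else
      strsplit(as.character(tt$habitat_types[i]), ";", fixed = TRUE)[[1]]
    score_habitat(types, common = common[i], anthropogenic = anthro[i])
  }, integer(1))
  data.frame(species_id = tt$species_id,
             food_score = food,
             range_score = range_s,
             habitat_score = habitat,
             total_specialization = total_specialization(food, range_s,
                                                         habitat),
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' The twelve functional trait slots
#'
#' Named character vector giving the type of each functional trait used for
#' the Gower dissimilarity: `quantitative`, `ordinal`, `binary`,
#' `categorical`, or `multilabel` (a set-valued slot such as the larval food
#' source list, contributing the mean mismatch over its label set).
#'
#' @return Named character vector of length 12.
#' @export
functional_trait_types <- function() {
  c(wingspan_mm = "quantitative",
    proboscis = "binary",
    larval_food_source = "multilabel",
    salt_tolerant_hosts = "binary",
    ruderal_hosts = "binary",
    host_growth_form = "categorical",
    food_specialization = "ordinal",
    habitat_type = "categorical",
    phenology = "categorical",
    voltinism = "ordinal",
    hibernating_stage = "categorical",
    range_extent = "ordinal")
}

#' Default larval food source label set
#'
#' Detritivory, lichen feeding, and fifteen widespread host plant families;
#' the schema accepts arbitrary label sets, this list only anchors the
#' bundled synthetic data.
#'
#' @return Character vector of 17 labels.
#' @export
larval_food_labels <- function() {
  c("detritivore", "lichen",
    "Fagaceae", "Salicaceae", "Betulaceae", "Rosaceae", "Pinaceae",
    "Poaceae", "Fabaceae", "Asteraceae", "Lamiaceae", "Ranunculaceae",
    "Brassicaceae", "Chenopodiaceae", "Ericaceae", "Oleaceae", "Ulmaceae")
}

#' Assemble the mixed-type functional trait matrix
#'
#' Collects the 12 functional trait columns from a species trait table into a
#' typed matrix aligned with a reference species order (typically the row
#' order of the incidence matrix). Missing values are allowed and flagged;
#' they are excluded pairwise inside the Gower computation, never imputed.
#'
#' @param trait_table Species trait data.frame containing `species_id` and
#'   the 12 columns named in [functional_trait_types()].
#' @param species_order Optional character vector; output rows follow this
#'   order. Species listed here but absent from `trait_table` are an error.
#' @return An object of class `"trait_matrix"`: a list with `data` (a
#'   data.frame, rows = species), `types` (named character vector) and
#'   `missing` (logical matrix marking unobserved cells).
#' @export
build_functional_matrix <- function(trait_table, species_order = NULL) {
  types <- functional_trait_types()
  miss_cols <- setdiff(names(types), names(trait_table))
  if (length(miss_cols) > 0L) {
    stop("trait table lacks functional trait column(s): ",
         paste(miss_cols, collapse = ", "))
  }
  if (is.null(species_order)) species_order <- trait_table$species_id
  idx <- match(species_order, trait_table$species_id)
  if (anyNA(idx)) {
    stop("species present in incidence but absent from trait table: ",
         paste(species_order[is.na(idx)], collapse = ", "))
  }
  dat <- trait_table[idx, names(types), drop = FALSE]
  rownames(dat) <- species_order
  for (j in names(types)) {
    dat[[j]] <- switch(types[[j]],
                       quantitative = as.numeric(dat[[j]]),
                       ordinal = as.numeric(dat[[j]]),
                       binary = as.integer(isTRUE_vec(dat[[j]])),
                       as.character(dat[[j]]))
    if (types[[j]] == "binary" && anyNA(trait_table[[j]][idx])) {
      dat[[j]][is.na(trait_table[[j]][idx])] <- NA_integer_
    }
  }
  missing <- is.na(as.matrix(dat))
  structure(list(data = dat, types = types, missing = missing),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Functional trait matrix:", nrow(x$data), "species x",
      length(x$types), "traits\n")
  cat("types:", paste(unique(x$types), collapse = ", "), "\n")
  if (any(x$missing)) cat(sum(x$missing), "missing cells\n")
  invisible(x)
}
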