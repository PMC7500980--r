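#' Load occurrence records from a delimited text file
#'
#' Reads species-by-year detection records (one row per record) from a CSV or
#' TSV file and validates them against the expected schema. Museum and survey
#' data typically carry one row per voucher or per species-year detection;
#' duplicates are tolerated here and collapsed later by [build_incidence()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping the required fields `species`, `year` and
#'   `source` to column names in the file. Defaults to columns of the same
#'   names.
#' @param strict Logical. If `TRUE`, any malformed row (e.g. a non-integer
#'   year) aborts with an error naming the offending row; if `FALSE`
#'   (default) malformed rows are dropped and reported via the `"problems"`
#'   attribute and a warning.
#' @param year_range Integer vector of length 2; records outside this study
#'   window are treated as malformed.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` => tab, otherwise comma).
#'
#' @return A data.frame with columns `species_id`, `year` (integer) and
#'   `source`, one row per record, with a `"problems"` attribute listing
#'   rejected rows (row number and reason).
#' @seealso [build_incidence()], [assign_time_layers()]
#' @export
load_occurrences <- function(path, schema = list(species = "species",
                                                 year = "year",
                                                 source = "source"),
                             strict = FALSE,
                             year_range = c(1900L, 2100L),
                             sep = NULL) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  needed <- unlist(schema[c("species", "year", "source")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("occurrence file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  occurrence_table(species_id = raw[[schema$species]],
                   year = raw[[schema$year]],
                   source = raw[[schema$source]],
                   strict = strict, year_range = year_range)
}

#' Construct a validated occurrence table
#'
#' In-memory counterpart of [load_occurrences()]; useful for synthetic data
#' and tests.
#'
#' @param species_id Character vector of species identifiers.
#' @param year Vector of calendar years (coerced to integer).
#' @param source Character vector naming the collection or survey.
#' @inheritParams load_occurrences
#' @return A validated occurrence data.frame (see [load_occurrences()]).
#' @export
occurrence_table <- function(species_id, year, source = "unknown",
                             strict = FALSE, year_range = c(1900L, 2100L)) {
  n <- length(species_id)
  source <- rep_len(as.character(source), n)
  year_num <- suppressWarnings(as.numeric(year))
  bad_year <- is.na(year_num) | year_num != floor(year_num) |
    year_num < year_range[1] | year_num > year_range[2]
  bad_species <- is.na(species_id) | !nzchar(species_id)
  bad <- bad_year | bad_species
  if (any(bad)) {
    reasons <- ifelse(bad_species[bad], "empty species_id",
                      paste0("invalid year '", year[bad], "'"))
    problems <- data.frame(row = which(bad), reason = reasons,
                           stringsAsFactors = FALSE)
    if (strict) {
      stop("malformed occurrence row(s): ",
           paste0("row ", problems$row, " (", problems$reason, ")",
                  collapse = "; "))
    }
    warning(nrow(problems), " malformed occurrence row(s) dropped")
  } else {
    problems <- data.frame(row = integer(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  out <- data.frame(species_id = as.character(species_id[!bad]),
                    year = as.integer(year_num[!bad]),
                    source = source[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "problems") <- problems
  out
}

#' Remove species not comparably sampled across data sources
#'
#' Drops all records of species carrying at least one phenological cleaning
#' flag in the trait table: early- or late-season flyers, long-distance
#' migrants, and strictly diurnal species. Such species are absent from, or
#' under-represented in, standard summer light-trap samples and would bias a
#' comparison of museum and survey layers. Flags are expert-assigned in the
#' trait table; no algorithmic phenology inference is attempted.
#'
#' @param records Occurrence table (see [occurrence_table()]).
#' @param trait_table Species trait data.frame with a `species_id` column and
#'   logical columns `early_late_flyer`, `long_distance_migrant`,
#'   `strictly_diurnal` (missing flag columns are treated as all-`FALSE`).
#' @param unknown_species How to treat record species absent from the trait
#'   table: `"drop"` removes them with a warning, `"error"` aborts.
#' @return The filtered occurrence table, with a `"removed"` attribute: a
#'   data.frame of removed species and the reason (flag or `"unknown"`).
#' @export
apply_phenological_filter <- function(records, trait_table,
                                      unknown_species = c("drop", "error")) {
  unknown_species <- match.arg(unknown_species)
  flags <- c("early_late_flyer", "long_distance_migrant", "strictly_diurnal")
  tt <- trait_table
  for (f in flags) if (is.null(tt[[f]])) tt[[f]] <- FALSE
  idx <- match(records$species_id, tt$species_id)
  unknown <- unique(records$species_id[is.na(idx)])
  if (length(unknown) > 0L && unknown_species == "error") {
    stop("species in records but absent from trait table: ",
         paste(unknown, collapse = ", "))
  }
  flag_mat <- sapply(flags, function(f) {
    v <- tt[[f]][idx]
    !is.na(v) & as.logical(v)
  })
  if (is.null(dim(flag_mat))) flag_mat <- matrix(flag_mat, nrow = 1)
  flagged <- rowSums(flag_mat) > 0
  drop <- flagged | is.na(idx)
  removed_species <- unique(records$species_id[drop])
  removed <- do.call(rbind, lapply(removed_species, function(s) {
    i <- which(records$species_id == s)[1]
    reason <- if (is.na(idx[i])) "unknown" else
      paste(flags[flag_mat[i, ]], collapse = "+")
    data.frame(species_id = s, reason = reason, stringsAsFactors = FALSE)
  }))
  if (is.null(removed)) {
    removed <- data.frame(species_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  if (length(unknown) > 0L) {
    warning("dropped ", length(unknown),
            " species absent from the trait table")
  }
  out <- records[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("all species removed by phenological filter")
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Define a time-layer scheme
#'
#' A time layer is a pooled span of sampling years treated as one community
#' snapshot: museum decades pool multiple collection years (vouchers per
#' single year are too sparse), while systematic survey years stand alone.
#'
#' @param layers data.frame with columns `label`, `year_min`, `year_max`
#'   (inclusive bounds).
#' @return The validated scheme (class `"time_layer_scheme"`), rows ordered
#'   chronologically by `year_min`.
#' @export
time_layer_scheme <- function(layers) {
  stopifnot(is.data.frame(layers),
            all(c("label", "year_min", "year_max") %in% names(layers)))
  layers$label <- as.character(layers$label)
  layers$year_min <- as.integer(layers$year_min)
  layers$year_max <- as.integer(layers$year_max)
  if (anyDuplicated(layers$label)) stop("duplicate layer labels")
  if (any(layers$year_min > layers$year_max)) {
    stop("layer with year_min > year_max")
  }
  layers <- layers[order(layers$year_min), , drop = FALSE]
  if (nrow(layers) > 1L) {
    overlap <- layers$year_min[-1L] <= layers$year_max[-nrow(layers)]
    if (any(overlap)) {
      stop("overlapping layers: ",
           paste(layers$label[which(overlap) + 1L], collapse = ", "))
    }
  }
  rownames(layers) <- NULL
  class(layers) <- c("time_layer_scheme", "data.frame")
  layers
}

#' Default historic-plus-survey layer scheme
#'
#' Four pooled museum partitions ("1940s" 1933-1949, "1960s" 1950-1976,
#' "1970s" 1977-1984, "1980s" 1985-1996) followed by one single-year layer
#' per survey year. With the eight survey years actually sampled
#' (1997-2002, 2011, 2012) this yields 12 layers, the variant used for
#' ordination; passing all years of a continuous survey period yields the
#' finer variant. Both are exposed because pooled-museum analyses and
#' per-year survey analyses legitimately use different layer counts.
#'
#' @param survey_years Integer vector of survey years to expand into
#'   single-year layers.
#' @return A [time_layer_scheme()].
#' @export
default_layer_scheme <- function(survey_years = c(1997:2002, 2011, 2012)) {
  historic <- data.frame(
    label = c("1940s", "1960s", "1970s", "1980s"),
    year_min = c(1933L, 1950L, 1977L, 1985L),
    year_max = c(1949L, 1976L, 1984L, 1996L))
  survey_years <- sort(unique(as.integer(survey_years)))
  survey <- data.frame(label = as.character(survey_years),
                       year_min = survey_years, year_max = survey_years)
  time_layer_scheme(rbind(historic, survey))
}

#' Assign each occurrence record to a time layer
#'
#' @param records Occurrence table.
#' @param scheme A [time_layer_scheme()].
#' @return The records with an added `layer` column; records whose year falls
#'   outside all layers are removed and reported via the `"rejected"`
#'   attribute and a warning.
#' @export
assign_time_layers <- function(records, scheme) {
  stopifnot(inherits(scheme, "time_layer_scheme"))
  hit <- outer(records$year, scheme$year_min, ">=") &
    outer(records$year, scheme$year_max, "<=")
  which_layer <- apply(hit, 1L, function(z) {
    w <- which(z)
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  rejected <- records[is.na(which_layer), , drop = FALSE]
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " record(s) outside all layers rejected (years ",
            paste(sort(unique(rejected$year)), collapse = ", "), ")")
  }
  out <- records[!is.na(which_layer), , drop = FALSE]
  out$layer <- scheme$label[which_layer[!is.na(which_layer)]]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "scheme") <- scheme
  out
}

#' Build a binary species-by-layer incidence matrix
#'
#' Pools all records into one species list per layer: a cell is 1 if the
#' species has at least one record in the layer, regardless of how many
#' vouchers exist. Abundances are never used; historic collections do not
#' support them.
#'
#' @param labelled_records Occurrence table with a `layer` column, as
#'   returned by [assign_time_layers()].
#' @param scheme Optional [time_layer_scheme()]; defaults to the scheme
#'   attached by [assign_time_layers()]. Determines chronological column
#'   order; layers with no records are dropped.
#' @return Integer 0/1 matrix, species rows (alphabetical) by layer columns
#'   (chronological), with the scheme stored in the `"scheme"` attribute.
#' @export
build_incidence <- function(labelled_records, scheme = NULL) {
  if (is.null(scheme)) scheme <- attr(labelled_records, "scheme")
  if (is.null(labelled_records$layer)) {
    stop("records carry no layer labels; run assign_time_layers() first")
  }
  if (nrow(labelled_records) == 0L) stop("no records to pool")
  species <- sort(unique(labelled_records$species_id))
  if (is.null(scheme)) {
    layers <- unique(labelled_records$layer)
  } else {
    layers <- scheme$label[scheme$label %in% labelled_records$layer]
  }
  mat <- matrix(0L, nrow = length(species), ncol = length(layers),
                dimnames = list(species, layers))
  mat[cbind(match(labelled_records$species_id, species),
            match(labelled_records$layer, layers))] <- 1L
  attr(mat, "scheme") <- scheme
  mat
}

#' Partition species into lost / persistent / previously unrecorded
#'
#' Species recorded only before the cut year are "lost", species recorded
#' only from the cut year onward are "previously unrecorded", and species
#' recorded on both sides are "persistent". The cut year marks the start of
#' the systematic survey period; records in the cut year itself count as
#' post-cut. Every layer must lie entirely on one side of the cut.
#'
#' @param incidence Incidence matrix from [build_incidence()].
#' @param cut_year Integer year separating historic from recent data
#'   (default 1997).
#' @param scheme [time_layer_scheme()] mapping layer columns to year spans;
#'   defaults to the scheme attached to `incidence`.
#' @return data.frame with columns `species_id` and `status` (factor with
#'   levels `lost`, `persistent`, `previously_unrecorded`), plus attributes
#'   `cut_year` and `counts` (a named table of statuses).
#' @export
assign_status <- function(incidence, cut_year = 1997L, scheme = NULL) {
  if (is.null(scheme)) scheme <- attr(incidence, "scheme")
  if (is.null(scheme)) stop("a time_layer_scheme is required")
  idx <- match(colnames(incidence), scheme$label)
  if (anyNA(idx)) {
    stop("incidence layers missing from scheme: ",
         paste(colnames(incidence)[is.na(idx)], collapse = ", "))
  }
  pre <- scheme$year_max[idx] < cut_year
  post <- scheme$year_min[idx] >= cut_year
  straddle <- !pre & !post
  if (any(straddle)) {
    stop("layer(s) straddle the cut year ", cut_year, ": ",
         paste(colnames(incidence)[straddle], collapse = ", "))
  }
  seen_pre <- rowSums(incidence[, pre, drop = FALSE]) > 0
  seen_post <- rowSums(incidence[, post, drop = FALSE]) > 0
  if (any(!seen_pre & !seen_post)) {
    stop("species with no records in any layer: ",
         paste(rownames(incidence)[!seen_pre & !seen_post], collapse = ", "))
  }
  status <- ifelse(seen_pre & seen_post, "persistent",
                   ifelse(seen_pre, "lost", "previously_unrecorded"))
  out <- data.frame(
    species_id = rownames(incidence),
    status = factor(status,
                    levels = c("lost", "persistent", "previously_unrecorded")),
    stringsAsFactors = FALSE)
  attr(out, "cut_year") <- as.integer(cut_year)
  attr(out, "counts") <- table(out$status)
  out
}
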