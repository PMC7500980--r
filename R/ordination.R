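#' Sorensen dissimilarity between time layers
#'
#' For two layers sharing `a` species, with `b` and `c` species unique to
#' each, the Sorensen similarity is `2a / (2a + b + c)`; the returned
#' dissimilarity is its complement. Computed on the binary incidence matrix
#' (layers as observations) via [vegan::vegdist()] with the binary
#' Bray-Curtis option, which is exactly this coefficient.
#'
#' @param incidence Incidence matrix from [build_incidence()] (species rows,
#'   layer columns).
#' @return Symmetric layer x layer dissimilarity matrix in \[0, 1\].
#' @export
sorensen_dissimilarity <- function(incidence) {
  if (ncol(incidence) < 2L) stop("at least two layers are required")
  empty <- colSums(incidence) == 0
  if (any(empty)) {
    stop("layer(s) with zero species must be dropped upstream: ",
         paste(colnames(incidence)[empty], collapse = ", "))
  }
  d <- vegan::vegdist(t(incidence), method = "bray", binary = TRUE)
  as.matrix(d)
}

#' Non-metric multidimensional scaling with seeded restarts
#'
#' Runs monotone-regression NMDS (Kruskal stress-1, via
#' [vegan::monoMDS()]) from one metric start and `n_restarts - 1` random
#' starts, keeping the lowest-stress solution. Coordinates are centred at
#' the origin; the whole procedure is deterministic given the seed.
#'
#' @param D Square dissimilarity matrix or `dist` over layers.
#' @param n_axes Number of ordination axes (default 2).
#' @param n_restarts Number of starts (default 50, the first one metric).
#' @param seed Integer seed controlling the random starts.
#' @return Object of class `"ordination_result"`: list with `layer_labels`,
#'   `coordinates` (layers x axes, centred), `stress` (Kruskal stress-1 in
#'   \[0, 1\]), `n_restarts`, `converged`, `seed`.
#' @export
nmds <- function(D, n_axes = 2L, n_restarts = 50L, seed = 1L) {
  d <- stats::as.dist(D)
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(attr(d, "Size")))
  n <- attr(d, "Size")
  stopifnot(n_restarts >= 1L)
  best <- NULL
  set.seed(seed)
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch({
      if (i == 1L) {
        vegan::monoMDS(d, k = n_axes, model = "global")
      } else {
        init <- matrix(stats::rnorm(n * n_axes), n, n_axes)
        vegan::monoMDS(d, y = init, k = n_axes, model = "global")
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("all NMDS starts failed")
  # icause 1 = iteration limit; 2-4 are the convergence criteria
  converged <- isTRUE(best$icause != 1L) || best$stress < 1e-6
  if (!converged) warning("NMDS did not converge in any restart")
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(labels, paste0("NMDS", seq_len(n_axes)))
  structure(list(layer_labels = labels,
                 coordinates = coords,
                 stress = best$stress,
                 n_restarts = n_restarts,
                 converged = converged,
                 seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("NMDS over %d layers: stress %.4f (%d restarts%s)\n",
              nrow(x$coordinates), x$stress, x$n_restarts,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Permutation test for descriptor-ordination association
#'
#' Fits each community descriptor (e.g. log mean wingspan, mean total
#' specialization, logit proportion of open-habitat species) as a vector in
#' the ordination by least squares and tests its squared multiple
#' correlation against a null built by permuting descriptor values across
#' layers: `p = (#{permuted R2 >= observed} + 1) / (n_permutations + 1)`.
#' Delegates to [vegan::envfit()].
#'
#' @param ordination An `"ordination_result"` from [nmds()] (or a
#'   coordinate matrix).
#' @param variables data.frame of per-layer descriptor values, rows aligned
#'   with the ordinated layers.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame of class `"vector_fit"` with one row per descriptor:
#'   `variable`, direction cosines `axis1`, `axis2`, ..., `r_squared`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_vector_fit <- function(ordination, variables,
                                   n_permutations = 999L, seed = 1L) {
  coords <- if (inherits(ordination, "ordination_result"))
    ordination$coordinates else as.matrix(ordination)
  variables <- as.data.frame(variables)
  if (nrow(variables) != nrow(coords)) {
    stop("descriptor rows must match the number of ordinated layers")
  }
  constant <- vapply(variables, function(v) stats::var(as.numeric(v)) == 0,
                     logical(1))
  if (any(constant)) {
    stop("constant descriptor(s): ",
         paste(names(variables)[constant], collapse = ", "))
  }
  set.seed(seed)
  ef <- vegan::envfit(coords, variables, permutations = n_permutations)
  arrows <- ef$vectors$arrows
  out <- data.frame(variable = rownames(arrows),
                    arrows,
                    r_squared = unname(ef$vectors$r),
                    p_value = unname(ef$vectors$pvals),
                    n_permutations = n_permutations,
                    stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[2:(1 + ncol(arrows))] <- paste0("axis", seq_len(ncol(arrows)))
  rownames(out) <- NULL
  class(out) <- c("vector_fit", "data.frame")
  out
}
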