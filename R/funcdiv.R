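#' Gower dissimilarity for mixed-type trait matrices
#'
#' Computes the classic Gower coefficient: for species i and j the
#' dissimilarity is the mean, over traits observed in both, of per-trait
#' contributions in \[0, 1\]: quantitative and ordinal traits contribute
#' `|x_i - x_j| / range`, binary and categorical traits contribute 0 on a
#' match and 1 otherwise, and a multilabel (set-valued) trait contributes
#' the mean mismatch over its label block. Missing values are excluded
#' pairwise: the denominator for a pair counts only traits observed in both
#' species (no imputation).
#'
#' @param x A `"trait_matrix"` from [build_functional_matrix()], or a
#'   data.frame accompanied by `types`.
#' @param types Named character vector of column types (`quantitative`,
#'   `ordinal`, `binary`, `categorical`, `multilabel`); ignored when `x` is
#'   a `"trait_matrix"`.
#' @param ranges Optional named numeric vector fixing the range used to
#'   scale quantitative columns (defaults to the observed range). Ordinal
#'   columns always use the observed range of their codes.
#' @param ordinal How ordinal traits enter: `"classic"` uses the numeric
#'   level codes range-scaled like a quantitative trait; `"rank"` replaces
#'   codes by mid-ranks first.
#' @return Symmetric dissimilarity matrix in \[0, 1\] with zero diagonal and
#'   species labels as dimnames.
#' @export
gower_matrix <- function(x, types = NULL, ranges = NULL,
                         ordinal = c("classic", "rank")) {
  ordinal <- match.arg(ordinal)
  if (inherits(x, "trait_matrix")) {
    dat <- x$data
    types <- x$types
  } else {
    dat <- as.data.frame(x)
    if (is.null(types)) stop("column types must be supplied")
  }
  n <- nrow(dat)
  if (n < 2L) stop("at least two species are required")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in names(types)) {
    v <- dat[[j]]
    ty <- types[[j]]
    if (ty %in% c("quantitative", "ordinal")) {
      v <- as.numeric(v)
      if (ty == "ordinal" && ordinal == "rank") v <- rank(v, na.last = "keep")
      r <- if (ty == "quantitative" && !is.null(ranges) && j %in% names(ranges))
        ranges[[j]] else diff(range(v, na.rm = TRUE))
      if (!is.finite(r) || r <= 0) {
        warning("zero-range column '", j, "' dropped from Gower")
        next
      }
      contrib <- abs(outer(v, v, "-")) / r
      obs <- outer(!is.na(v), !is.na(v), "&")
    } else if (ty %in% c("binary", "categorical")) {
      v <- as.character(v)
      contrib <- 1 - outer(v, v, "==")
      obs <- outer(!is.na(v), !is.na(v), "&")
      contrib[!obs] <- 0
    } else if (ty == "multilabel") {
      sets <- lapply(as.character(v), function(s) {
        if (is.na(s)) NA_character_ else strsplit(s, ";", fixed = TRUE)[[1]]
      })
      labels <- sort(unique(unlist(sets[!is.na(v)])))
      if (length(labels) == 0L) next
      block <- vapply(sets, function(s) {
        if (length(s) == 1L && is.na(s[1])) rep(NA, length(labels)) else
          as.numeric(labels %in% s)
      }, numeric(length(labels)))
      block <- t(block)  # species x labels
      # mean mismatch over the block: Hamming distance / block width
      ok <- !is.na(block[, 1L])
      contrib <- matrix(0, n, n)
      if (sum(ok) >= 2L) {
        b <- block[ok, , drop = FALSE]
        ham <- outer(rowSums(b), rep(1, sum(ok))) +
          outer(rep(1, sum(ok)), rowSums(b)) - 2 * tcrossprod(b)
        contrib[ok, ok] <- ham / length(labels)
      }
      obs <- outer(ok, ok, "&")
    } else {
      stop("unknown trait type '", ty, "' for column '", j, "'")
    }
    contrib[!obs] <- 0
    num <- num + contrib
    den <- den + obs
  }
  dd <- diag(den)
  dd[dd == 0] <- 1  # self-dissimilarity is 0 by definition
  diag(den) <- dd
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1L, ]
    stop("species pair with no commonly observed trait: ",
         rownames(dat)[bad[1]], " / ", rownames(dat)[bad[2]])
  }
  d <- num / den
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(dat), rownames(dat))
  d
}

#' Principal-coordinate embedding of a dissimilarity matrix
#'
#' Classical scaling: the squared dissimilarities are double-centred and
#' eigen-decomposed; coordinates are eigenvectors scaled by the square root
#' of their eigenvalues. Gower dissimilarities are generally not Euclidean,
#' producing negative eigenvalues; if these exceed tolerance the configured
#' correction is applied and the matrix re-embedded. The default correction
#' takes the element-wise square root of the dissimilarities (which renders
#' any Gower matrix without missing values Euclidean); the additive Cailliez
#' and Lingoes corrections are available as alternatives.
#'
#' @param D Symmetric non-negative dissimilarity matrix (or `dist`).
#' @param correction One of `"sqrt"` (default), `"cailliez"`, `"lingoes"`,
#'   `"none"`.
#' @param tol Relative eigenvalue tolerance: axes with eigenvalue below
#'   `tol * max(eigenvalue)` are dropped, and negative eigenvalues smaller
#'   in magnitude than that threshold are ignored.
#' @return Object of class `"pcoa_embedding"`: list with `coordinates`
#'   (species x axes), `eigenvalues` (retained, decreasing),
#'   `correction_applied`, and `negative_eigenvalue` (most negative
#'   eigenvalue of the uncorrected matrix).
#' @export
pcoa_embed <- function(D, correction = c("sqrt", "cailliez", "lingoes",
                                         "none"),
                       tol = 1e-9) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  labels <- rownames(D)
  decomp <- function(M) {
    B <- double_centre(-0.5 * M^2)
    eigen(B, symmetric = TRUE)
  }
  e <- decomp(D)
  scale_max <- max(abs(e$values))
  neg <- min(e$values)
  applied <- "none"
  if (neg < -tol * scale_max && correction != "none") {
    D2 <- switch(correction,
                 sqrt = sqrt(D),
                 cailliez = cailliez_correct(D),
                 lingoes = lingoes_correct(D))
    e2 <- decomp(D2)
    if (min(e2$values) < -tol * max(abs(e2$values))) {
      stop("correction '", correction, "' failed to remove negative ",
           "eigenvalues; most negative after correction: ",
           format(min(e2$values)))
    }
    applied <- correction
    e <- e2
  }
  keep <- e$values > tol * max(e$values)
  if (!any(keep)) stop("no positive eigenvalues: degenerate dissimilarities")
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- labels
  colnames(coords) <- paste0("A", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values[keep],
                 correction_applied = applied,
                 negative_eigenvalue = neg),
            class = "pcoa_embedding")
}

double_centre <- function(A) {
  rm <- rowMeans(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
}

# Additive constant corrections (Cailliez 1983; Lingoes 1971).
cailliez_correct <- function(D) {
  n <- nrow(D)
  d1 <- double_centre(-0.5 * D^2)
  d2 <- double_centre(-0.5 * D)
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  cstar <- max(Re(eigen(M, only.values = TRUE)$values))
  Dc <- D + cstar
  diag(Dc) <- 0
  Dc
}

lingoes_correct <- function(D) {
  B <- double_centre(-0.5 * D^2)
  cstar <- -min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  Dc <- sqrt(D^2 + 2 * cstar)
  diag(Dc) <- 0
  Dc
}

#' Functional dispersion (FDis)
#'
#' The weighted mean distance of species to the weighted centroid of the
#' community in trait space: with weights `a_j` (incidence data use
#' `a_j = 1` for present species), centroid `c = sum(a_j x_j) / sum(a_j)`
#' and `z_j` the Euclidean distance of species j to `c`,
#' `FDis = sum(a_j z_j) / sum(a_j)`. Since functional specialization is the
#' distance of a species from the community centroid, FDis is the mean
#' functional specialization of the community.
#'
#' @param x A `"pcoa_embedding"`, a coordinate matrix (species x axes), or a
#'   symmetric dissimilarity matrix / `dist` (which is embedded first with
#'   [pcoa_embed()]).
#' @param weights Non-negative per-species weights `a_j`; species with zero
#'   weight are absent from the community. Defaults to all present.
#' @param correction Passed to [pcoa_embed()] when `x` is a dissimilarity.
#' @return Object of class `"fdis"`: list with `value`, `n_species_present`,
#'   `weights_used`, `centroid`, and `note` (set when fewer than two species
#'   are present, in which case the value is 0).
#' @export
fdis <- function(x, weights = NULL, correction = "sqrt") {
  if (inherits(x, "pcoa_embedding")) {
    coords <- x$coordinates
  } else if (inherits(x, "dist")) {
    coords <- pcoa_embed(x, correction = correction)$coordinates
  } else {
    x <- as.matrix(x)
    is_dissim <- nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8) &&
      all(abs(diag(x)) < 1e-12)
    coords <- if (is_dissim)
      pcoa_embed(x, correction = correction)$coordinates else x
  }
  n <- nrow(coords)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must match species count")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  present <- weights > 0
  if (sum(present) < 2L) {
    return(structure(list(value = 0, n_species_present = sum(present),
                          weights_used = weights,
                          centroid = colSums(coords[present, , drop = FALSE]),
                          note = "fewer than two species present"),
                     class = "fdis"))
  }
  a <- weights[present]
  xs <- coords[present, , drop = FALSE]
  centroid <- colSums(xs * a) / sum(a)
  z <- sqrt(rowSums(sweep(xs, 2L, centroid)^2))
  structure(list(value = sum(a * z) / sum(a),
                 n_species_present = sum(present),
                 weights_used = weights,
                 centroid = centroid,
                 note = NULL),
            class = "fdis")
}

#' @export
print.fdis <- function(x, ...) {
  cat("FDis =", format(x$value, digits = 6), "over",
      x$n_species_present, "species\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' FDis per incidence layer
#'
#' Embeds the full species pool once and evaluates FDis for every layer of a
#' binary incidence matrix, each species present in a layer receiving unit
#' weight. Embedding the pooled species set once keeps all layers in a
#' common trait space, so values are comparable across layers.
#'
#' @param trait_matrix A `"trait_matrix"` covering all incidence species, or
#'   a precomputed `"pcoa_embedding"`.
#' @param incidence Binary species x layer matrix; row names must match the
#'   trait matrix species.
#' @inheritParams fdis
#' @return Named numeric vector of FDis values, one per layer.
#' @export
fdis_per_layer <- function(trait_matrix, incidence, correction = "sqrt") {
  emb <- if (inherits(trait_matrix, "pcoa_embedding")) trait_matrix else
    pcoa_embed(gower_matrix(trait_matrix), correction = correction)
  if (!all(rownames(incidence) %in% rownames(emb$coordinates))) {
    stop("incidence species missing from trait matrix: ",
         paste(setdiff(rownames(incidence), rownames(emb$coordinates)),
               collapse = ", "))
  }
  coords <- emb$coordinates[rownames(incidence), , drop = FALSE]
  vapply(seq_len(ncol(incidence)), function(l) {
    fdis(coords, weights = as.numeric(incidence[, l]))$value
  }, numeric(1)) |> stats::setNames(colnames(incidence))
}

#' Definitional brute-force FDis oracle
#'
#' Recomputes FDis by an independent path for validation: the trait
#' dissimilarities are square-root corrected whenever the uncorrected matrix
#' is non-Euclidean, embedded at full rank with classical scaling
#' ([stats::cmdscale()]), and the weighted centroid distance evaluated
#' directly. Intended for small problems (n <= 50) in tests; it shares no
#' code with [pcoa_embed()]/[fdis()] beyond the Gower input preparation.
#'
#' @param trait_matrix A `"trait_matrix"` (see [build_functional_matrix()]).
#' @param weights Non-negative species weights.
#' @return The FDis value (numeric scalar).
#' @export
fdis_brute_oracle <- function(trait_matrix, weights = NULL) {
  D <- gower_matrix(trait_matrix)
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1, n)
  B <- double_centre(-0.5 * D^2)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev))) D <- sqrt(D)
  coords <- suppressWarnings(stats::cmdscale(D, k = n - 1L))
  present <- weights > 0
  if (sum(present) < 2L) return(0)
  a <- weights[present]
  xs <- coords[present, , drop = FALSE]
  centroid <- colSums(xs * a) / sum(a)
  sum(a * sqrt(rowSums(sweep(xs, 2L, centroid)^2))) / sum(a)
}
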