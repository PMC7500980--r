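#' Logit transform with boundary clamping
#'
#' `log(p / (1 - p))` after clamping `p` into `[epsilon, 1 - epsilon]`, so
#' proportions of exactly 0 or 1 (common with small per-layer species lists)
#' stay finite. The empirical-logit convention `epsilon = 0.5 / n` is used
#' by [layer_metrics()].
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @param epsilon Clamping constant in (0, 0.5).
#' @return Numeric vector of logits.
#' @export
logit <- function(p, epsilon = 0.005) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must be in [0, 1]")
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  log(p / (1 - p))
}

#' Per-layer community metrics
#'
#' Summarizes each time layer of an incidence matrix: species count, mean
#' wingspan over present species (and its log), mean total specialization,
#' proportion of open-habitat species (and its empirical logit), and FDis in
#' the pooled trait space. The layer midpoint year (mean of the layer's year
#' span) serves as the time covariate for trend models, e.g. the pooled
#' "1940s" museum partition (1933-1949) is placed at 1941.
#'
#' @param incidence Incidence matrix from [build_incidence()].
#' @param trait_table Species trait data.frame with `species_id`,
#'   `wingspan_mm` and logical `open_habitat` columns.
#' @param scores Specialization scores from [score_specialization()]
#'   (optional; computed from `trait_table` when `NULL`).
#' @param fdis_values Optional named per-layer FDis vector; computed via
#'   [fdis_per_layer()] when `NULL` and the trait table carries the 12
#'   functional trait columns.
#' @param scheme [time_layer_scheme()]; defaults to the one attached to
#'   `incidence`.
#' @param log_of_mean If `TRUE` (default) `log_mean_wingspan` is the log of
#'   the per-layer mean wingspan; if `FALSE` it is the mean of per-species
#'   log wingspans.
#' @return data.frame of class `"community_time_series"`, one row per
#'   retained layer (layers with zero species are dropped with a warning).
#' @export
layer_metrics <- function(incidence, trait_table, scores = NULL,
                          fdis_values = NULL, scheme = NULL,
                          log_of_mean = TRUE) {
  if (is.null(scheme)) scheme <- attr(incidence, "scheme")
  if (is.null(scheme)) stop("a time_layer_scheme is required")
  if (is.null(scores)) scores <- score_specialization(trait_table)
  empty <- colSums(incidence) == 0
  if (any(empty)) {
    warning("dropping empty layer(s): ",
            paste(colnames(incidence)[empty], collapse = ", "))
    incidence <- incidence[, !empty, drop = FALSE]
  }
  idx <- match(rownames(incidence), trait_table$species_id)
  if (anyNA(idx)) {
    stop("incidence species missing from trait table: ",
         paste(rownames(incidence)[is.na(idx)], collapse = ", "))
  }
  ws <- as.numeric(trait_table$wingspan_mm[idx])
  open <- isTRUE_vec(trait_table$open_habitat[idx])
  tot <- scores$total_specialization[match(rownames(incidence),
                                           scores$species_id)]
  if (is.null(fdis_values) &&
      all(names(functional_trait_types()) %in% names(trait_table))) {
    tm <- build_functional_matrix(trait_table[idx, , drop = FALSE],
                                  rownames(incidence))
    fdis_values <- fdis_per_layer(tm, incidence)
  }
  sidx <- match(colnames(incidence), scheme$label)
  out <- do.call(rbind, lapply(seq_len(ncol(incidence)), function(l) {
    present <- incidence[, l] > 0
    n <- sum(present)
    mw <- mean(ws[present])
    p_open <- mean(open[present])
    data.frame(
      layer_label = colnames(incidence)[l],
      layer_midpoint_year = mean(c(scheme$year_min[sidx[l]],
                                   scheme$year_max[sidx[l]])),
      n_species = n,
      mean_wingspan_mm = mw,
      log_mean_wingspan = if (log_of_mean) log(mw) else
        mean(log(ws[present])),
      mean_total_specialization = mean(tot[present]),
      prop_open_habitat = p_open,
      logit_prop_open = logit(p_open, epsilon = 0.5 / n),
      fdis = if (is.null(fdis_values)) NA_real_ else
        unname(fdis_values[colnames(incidence)[l]]),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("community_time_series", "data.frame")
  out
}

#' Penalized-spline trend over time layers
#'
#' Fits a generalized additive model `response ~ s(year, k = basis_dim)`
#' (thin-plate spline, GCV smoothing) to a community time series and
#' summarizes the smooth: effective degrees of freedom, the approximate
#' significance of the smooth term, adjusted R-squared, and a trend
#' coefficient. With a dozen or so time layers a smooth cannot be defined by
#' a single slope, so the reported coefficient is the standardized slope of
#' the linear projection of the fitted smooth onto year - its sign and
#' magnitude summarize the overall direction of change.
#'
#' @param series `"community_time_series"` (or any data.frame).
#' @param response Name of the response column.
#' @param basis_dim Spline basis dimension `k`; reduced with a warning when
#'   there are too few time points to support it.
#' @param year_col Name of the time covariate column.
#' @return Object of class `"trend_fit"`: list with `response_name`,
#'   `smooth_edf`, `coefficient` (standardized projection slope),
#'   `raw_slope` (response units per year), `test_statistic` (signed square
#'   root of the smooth's F statistic), `p_value`, `adjusted_r2`, and the
#'   fitted `model`.
#' @export
fit_trend_gam <- function(series, response, basis_dim = 4,
                          year_col = "layer_midpoint_year") {
  y <- series[[response]]
  year <- series[[year_col]]
  keep <- is.finite(y) & is.finite(year)
  y <- y[keep]; year <- year[keep]
  if (length(y) < 6L) stop("at least 6 time points are required")
  k <- basis_dim
  if (length(y) < k + 1L) {
    k <- length(y) - 1L
    warning("basis dimension reduced to ", k, " for ", length(y),
            " time points")
  }
  dat <- data.frame(y = y, year = year)
  g <- mgcv::gam(y ~ s(year, k = k), data = dat, method = "GCV.Cp")
  st <- summary(g)$s.table
  fitted_y <- stats::fitted(g)
  raw_slope <- stats::cov(fitted_y, year) / stats::var(year)
  coef_std <- if (stats::sd(y) > 0) raw_slope * stats::sd(year) / stats::sd(y)
    else 0
  structure(list(response_name = response,
                 smooth_edf = unname(st[1L, "edf"]),
                 coefficient = coef_std,
                 raw_slope = raw_slope,
                 test_statistic = sign(raw_slope) * sqrt(max(st[1L, "F"], 0)),
                 p_value = unname(st[1L, "p-value"]),
                 adjusted_r2 = summary(g)$r.sq,
                 model = g),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend in %s: edf %.2f, beta %.3f, t %.2f, p %.4g, adj R2 %.2f\n",
              x$response_name, x$smooth_edf, x$coefficient,
              x$test_statistic, x$p_value, x$adjusted_r2))
  invisible(x)
}

# Nakagawa-Schielzeth variance components for a fitted mixed model.
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  tot <- var_fixed + var_random + var_resid
  list(marginal = var_fixed / tot,
       conditional = (var_fixed + var_random) / tot)
}

#' Body size versus occurrence status (linear mixed model)
#'
#' Fits `log(wingspan) ~ status` with a taxonomic-family random intercept.
#' Body size is strongly conserved within moth families, so family must be
#' absorbed before status contrasts are interpretable. The primary contrast
#' is lost versus previously unrecorded species (the reference level), the
#' comparison that captures directional turnover in body size.
#'
#' @param trait_table Species trait data.frame with `species_id`,
#'   `wingspan_mm`, `family`.
#' @param statuses Status table from [assign_status()].
#' @param reference Reference status level for contrasts.
#' @return Object of class `"status_model_fit"`: list with `response_name`,
#'   `fixed_effects` (data.frame of contrasts with estimate, statistic, df,
#'   p), `test_statistic` and `p_value` for the primary (lost) contrast,
#'   `marginal_r2`, `conditional_r2` (Nakagawa-Schielzeth),
#'   `random_intercept_variance`, `singular_fallback` flag and the fitted
#'   `model`.
#' @export
fit_wingspan_status_model <- function(trait_table, statuses,
                                      reference = "previously_unrecorded") {
  dat <- merge(trait_table[, c("species_id", "wingspan_mm", "family")],
               statuses, by = "species_id")
  dat$log_ws <- log(as.numeric(dat$wingspan_mm))
  dat$status <- stats::relevel(factor(as.character(dat$status)),
                               ref = reference)
  dat$family <- factor(dat$family)
  if (nlevels(dat$status) < 2L) stop("at least two statuses are required")
  if (nlevels(dat$family) < 2L) stop("at least two families are required")
  fit <- tryCatch(
    nlme::lme(log_ws ~ status, random = ~ 1 | family, data = dat,
              method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to fixed-effects model")
    return(status_fit_from_lm(stats::lm(log_ws ~ status, data = dat),
                              "log_wingspan"))
  }
  tt <- summary(fit)$tTable
  rows <- grep("^status", rownames(tt))
  fixed <- data.frame(contrast = sub("^status", "", rownames(tt)[rows]),
                      estimate = tt[rows, "Value"],
                      statistic = tt[rows, "t-value"],
                      df = tt[rows, "DF"],
                      p_value = tt[rows, "p-value"],
                      stringsAsFactors = FALSE)
  vr <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  var_random <- vr[1L]
  var_resid <- vr[2L]
  var_fixed <- stats::var(as.numeric(stats::predict(fit, level = 0)))
  r2 <- nakagawa_r2(var_fixed, var_random, var_resid)
  primary <- which(fixed$contrast == "lost")
  if (length(primary) == 0L) primary <- 1L
  structure(list(response_name = "log_wingspan",
                 fixed_effects = fixed,
                 test_statistic = fixed$statistic[primary],
                 p_value = fixed$p_value[primary],
                 marginal_r2 = r2$marginal,
                 conditional_r2 = r2$conditional,
                 random_intercept_variance = var_random,
                 singular_fallback = FALSE,
                 model = fit),
            class = "status_model_fit")
}

status_fit_from_lm <- function(fit, response_name) {
  ct <- summary(fit)$coefficients
  rows <- grep("^status", rownames(ct))
  fixed <- data.frame(contrast = sub("^status", "", rownames(ct)[rows]),
                      estimate = ct[rows, 1L],
                      statistic = ct[rows, 3L],
                      df = stats::df.residual(fit),
                      p_value = ct[rows, 4L],
                      stringsAsFactors = FALSE)
  primary <- which(fixed$contrast == "lost")
  if (length(primary) == 0L) primary <- 1L
  r2 <- summary(fit)$r.squared
  structure(list(response_name = response_name,
                 fixed_effects = fixed,
                 test_statistic = fixed$statistic[primary],
                 p_value = fixed$p_value[primary],
                 marginal_r2 = r2,
                 conditional_r2 = r2,
                 random_intercept_variance = 0,
                 singular_fallback = TRUE,
                 model = fit),
            class = "status_model_fit")
}

#' Specialization scores versus occurrence status (Poisson mixed model)
#'
#' Fits a generalized linear mixed model with Poisson error and log link,
#' `score ~ status + (1 | family)`, for a specialization score response
#' (food, habitat, range, or total). The scores are bounded ranks rather
#' than open counts, so the Poisson family is a pragmatic convention and
#' dispersion should be checked; marginal and conditional R-squared use the
#' Nakagawa-Schielzeth decomposition with the lognormal approximation for
#' the observation-level variance.
#'
#' @param scores Score table from [score_specialization()] (or any
#'   data.frame with `species_id` and the response column).
#' @param statuses Status table from [assign_status()].
#' @param trait_table Trait table providing the `family` column.
#' @param response Name of the integer score column (default
#'   `"total_specialization"`).
#' @inheritParams fit_wingspan_status_model
#' @return A `"status_model_fit"` (see [fit_wingspan_status_model()]);
#'   statistics are Wald z values.
#' @export
fit_specialization_status_model <- function(scores, statuses, trait_table,
                                            response = "total_specialization",
                                            reference =
                                              "previously_unrecorded") {
  dat <- merge(merge(scores, statuses, by = "species_id"),
               trait_table[, c("species_id", "family")], by = "species_id")
  dat$y <- as.integer(dat[[response]])
  if (any(dat$y < 0)) stop("score response must be a non-negative integer")
  dat$status <- stats::relevel(factor(as.character(dat$status)),
                               ref = reference)
  dat$family <- factor(dat$family)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(y ~ status + (1 | family), data = dat,
                  family = "poisson"))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("GLMM fit failed; falling back to fixed-effects Poisson GLM")
    g <- stats::glm(y ~ status, data = dat, family = "poisson")
    out <- status_fit_from_lm(g, response)
    out$fixed_effects$df <- NA_real_
    # marginal R2 on the latent log scale, lognormal residual approximation
    vf <- stats::var(stats::predict(g, type = "link"))
    ve <- log1p(1 / mean(dat$y))
    out$marginal_r2 <- out$conditional_r2 <- vf / (vf + ve)
    return(out)
  }
  ct <- summary(fit)$coefficients
  rows <- grep("^status", rownames(ct))
  fixed <- data.frame(contrast = sub("^status", "", rownames(ct)[rows]),
                      estimate = ct[rows, 1L],
                      statistic = ct[rows, 3L],
                      df = NA_real_,
                      p_value = ct[rows, 4L],
                      stringsAsFactors = FALSE)
  var_random <- as.numeric(lme4::VarCorr(fit)$family[1L])
  var_fixed <- stats::var(as.numeric(lme4::getME(fit, "X") %*%
                                       lme4::fixef(fit)))
  lambda_bar <- exp(lme4::fixef(fit)[["(Intercept)"]] + 0.5 * var_random)
  var_resid <- log1p(1 / lambda_bar)
  r2 <- nakagawa_r2(var_fixed, var_random, var_resid)
  primary <- which(fixed$contrast == "lost")
  if (length(primary) == 0L) primary <- 1L
  structure(list(response_name = response,
                 fixed_effects = fixed,
                 test_statistic = fixed$statistic[primary],
                 p_value = fixed$p_value[primary],
                 marginal_r2 = r2$marginal,
                 conditional_r2 = r2$conditional,
                 random_intercept_variance = var_random,
                 singular_fallback = FALSE,
                 model = fit),
            class = "status_model_fit")
}

#' @export
print.status_model_fit <- function(x, ...) {
  cat(sprintf("Status model for %s: primary contrast t/z %.2f, p %.4g\n",
              x$response_name, x$test_statistic, x$p_value))
  cat(sprintf("  marginal R2 %.3f, conditional R2 %.3f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}
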