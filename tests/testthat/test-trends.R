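test_that("logit is antisymmetric and clamps boundaries", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0, epsilon = 0.005), log(0.005 / 0.995),
               tolerance = 1e-12)
  p <- c(0.1, 0.25, 0.6, 0.9)
  expect_equal(logit(p), -logit(1 - p), tolerance = 1e-12)
  expect_error(logit(1.2), "\\[0, 1\\]")
})

test_that("layer metrics compute the documented per-layer summaries", {
  tt <- tiny_traits()
  scheme <- time_layer_scheme(data.frame(
    label = c("old", "recent"), year_min = c(1933, 1997),
    year_max = c(1949, 1997)))
  inc <- matrix(c(1, 0,
                  1, 1,
                  1, 1,
                  1, 0,
                  0, 1), ncol = 2, byrow = TRUE,
                dimnames = list(tt$species_id, c("old", "recent")))
  ser <- layer_metrics(inc, tt, scheme = scheme)
  expect_s3_class(ser, "community_time_series")
  expect_equal(ser$layer_midpoint_year, c(1941, 1997))
  expect_equal(ser$n_species, c(4L, 3L))
  expect_equal(ser$mean_wingspan_mm[1], mean(c(30, 40, 25, 52)))
  expect_equal(ser$log_mean_wingspan[1], log(mean(c(30, 40, 25, 52))))
  # layer "old": sp1, sp2, sp4 are open-habitat among 4 present
  expect_equal(ser$prop_open_habitat, c(3 / 4, 1 / 3))
  sc <- score_specialization(tt)
  expect_equal(ser$mean_total_specialization[1],
               mean(sc$total_specialization[1:4]))
  expect_true(all(ser$fdis >= 0))

  # a species never present changes nothing
  inc0 <- rbind(inc, sp9 = c(0, 0))
  tt9 <- rbind(tt, within(tt[1, ], species_id <- "sp9"))
  ser0 <- layer_metrics(inc0[rowSums(inc0) > 0, ], tt9, scheme = scheme)
  expect_equal(ser0, ser)

  # half open-habitat at the symmetry point of the logit
  inc2 <- inc; inc2[, 2] <- c(1, 1, 1, 0, 1)
  ser2 <- layer_metrics(inc2, tt, scheme = scheme)
  expect_equal(ser2$prop_open_habitat[2], 0.5)
  expect_equal(ser2$logit_prop_open[2], 0)
})

test_that("spline trends recover exact linear and null signals", {
  years <- seq(1940, 2010, length.out = 12)
  lin <- data.frame(layer_midpoint_year = years, y = 100 - 1 * years)
  f <- fit_trend_gam(lin, "y")
  expect_lt(f$coefficient, 0)
  expect_equal(f$raw_slope, -1, tolerance = 1e-6)
  expect_gt(f$adjusted_r2, 0.99)

  set.seed(14)
  noisy <- data.frame(layer_midpoint_year = years,
                      y = 100 - 1 * years + rnorm(12, sd = 2))
  fn <- fit_trend_gam(noisy, "y")
  expect_lt(fn$coefficient, 0)
  expect_lt(fn$p_value, 0.01)

  const <- data.frame(layer_midpoint_year = years, y = rep(5, 12))
  f0 <- fit_trend_gam(const, "y")
  expect_equal(f0$coefficient, 0, tolerance = 1e-8)
  expect_lte(f0$adjusted_r2, 0)

  # monotone series yields a matching trend sign
  mono <- data.frame(layer_midpoint_year = years, y = exp(years / 50))
  expect_gt(fit_trend_gam(mono, "y")$coefficient, 0)

  expect_error(fit_trend_gam(lin[1:4, ], "y"), "6 time points")
  expect_warning(fit_trend_gam(cbind(lin[1:7, ]), "y", basis_dim = 10),
                 "reduced")
})

test_that("wingspan status model recovers simulated effects", {
  sim_status_data <- function(seed, effect, fam_sd = 0.15) {
    set.seed(seed)
    n <- 300
    fam <- sample(sprintf("F%02d", 1:20), n, TRUE)
    fam_eff <- setNames(rnorm(20, 0, fam_sd), sprintf("F%02d", 1:20))
    status <- sample(c("lost", "persistent", "previously_unrecorded"),
                     n, TRUE)
    lws <- log(33) + fam_eff[fam] + effect * (status == "lost") +
      rnorm(n, 0, 0.25)
    list(traits = data.frame(species_id = sprintf("s%03d", 1:n),
                             wingspan_mm = exp(lws), family = fam,
                             stringsAsFactors = FALSE),
         statuses = data.frame(species_id = sprintf("s%03d", 1:n),
                               status = factor(status),
                               stringsAsFactors = FALSE))
  }

  # effect recovery: mean estimate over replicates near the truth
  est <- vapply(1:30, function(s) {
    d <- sim_status_data(s, effect = 0.2)
    fit <- fit_wingspan_status_model(d$traits, d$statuses)
    fit$fixed_effects$estimate[fit$fixed_effects$contrast == "lost"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.05)

  # with no family variance the conditional R2 collapses onto the marginal
  # (mean gap over replicates, since REML variance estimates stay >= 0)
  gap <- vapply(101:110, function(s) {
    d0 <- sim_status_data(s, effect = 0.3, fam_sd = 0)
    fit0 <- fit_wingspan_status_model(d0$traits, d0$statuses)
    expect_lte(fit0$marginal_r2, fit0$conditional_r2)
    expect_gte(fit0$marginal_r2, 0)
    expect_lte(fit0$conditional_r2, 1)
    fit0$conditional_r2 - fit0$marginal_r2
  }, numeric(1))
  expect_lt(mean(gap), 0.02)
})

test_that("Poisson status model is null-calibrated and recovers rates", {
  sim_pois <- function(seed, log_rr) {
    set.seed(seed)
    n <- 300
    fam <- sample(sprintf("F%02d", 1:15), n, TRUE)
    status <- sample(c("lost", "persistent", "previously_unrecorded"),
                     n, TRUE)
    mu <- exp(log(8) + log_rr * (status == "lost"))
    data.frame(species_id = sprintf("s%03d", 1:n),
               total_specialization = rpois(n, mu),
               status = factor(status), family = fam,
               stringsAsFactors = FALSE)
  }
  est <- vapply(1:30, function(s) {
    d <- sim_pois(s, log_rr = log(1.3))
    fit <- fit_specialization_status_model(
      d[, c("species_id", "total_specialization")],
      d[, c("species_id", "status")],
      d[, c("species_id", "family")])
    fit$fixed_effects$estimate[fit$fixed_effects$contrast == "lost"]
  }, numeric(1))
  expect_lt(abs(mean(est) - log(1.3)), 0.1)

  # constant response: contrasts near zero
  dc <- sim_pois(7, 0)
  dc$total_specialization <- 8L
  fitc <- suppressWarnings(fit_specialization_status_model(
    dc[, c("species_id", "total_specialization")],
    dc[, c("species_id", "status")],
    dc[, c("species_id", "family")]))
  expect_lt(max(abs(fitc$fixed_effects$estimate)), 1e-6)

  # fitted means stay inside the score range on real-looking scores
  tt <- tiny_traits()
  sc <- score_specialization(tt)
  st <- data.frame(species_id = tt$species_id,
                   status = factor(c("lost", "persistent", "persistent",
                                     "previously_unrecorded", "lost")))
  fit <- suppressWarnings(
    fit_specialization_status_model(sc, st, tt))
  nd <- data.frame(status = levels(st$status), family = tt$family[1])
  mu <- if (inherits(fit$model, "merMod")) {
    predict(fit$model, newdata = nd, type = "response", re.form = NA)
  } else {
    predict(fit$model, newdata = nd, type = "response")
  }
  expect_true(all(mu >= 3 - 1e-6 & mu <= 12 + 1e-6))
})

test_that("R2 decomposition is ordered and bounded", {
  d <- data.frame(
    species_id = sprintf("s%02d", 1:60),
    wingspan_mm = exp(rnorm(60, log(30), 0.3)),
    family = rep(sprintf("F%d", 1:6), each = 10),
    stringsAsFactors = FALSE)
  st <- data.frame(species_id = d$species_id,
                   status = factor(rep(c("lost", "persistent",
                                         "previously_unrecorded"), 20)))
  fit <- fit_wingspan_status_model(d, st)
  expect_gte(fit$marginal_r2, 0)
  expect_lte(fit$marginal_r2, fit$conditional_r2)
  expect_lte(fit$conditional_r2, 1)
})
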