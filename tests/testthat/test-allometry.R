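# simulation helper: volumes from a known log-log law with nested
# random intercepts
sim_loglog <- function(seed, n = 300, beta = c(2.80, 1.97), beta2 = 0,
                       residual_sd = 0.3, sd_plot = 0.1, n_plots = 12) {
  set.seed(seed)
  plot_num <- sample(seq_len(n_plots), n, replace = TRUE)
  plot <- paste0("P", plot_num)
  site <- ifelse(plot_num <= n_plots / 2, "S1", "S2")
  fragment <- paste0("F", (plot_num - 1) %/% 3 + 1)
  u_plot <- stats::setNames(rnorm(n_plots, 0, sd_plot),
                            paste0("P", seq_len(n_plots)))
  dbh <- exp(runif(n, log(0.05), log(0.9)))
  height <- exp(0.9 + 0.62 * log(dbh * 100))
  x <- log(dbh)
  lnv <- beta[1] + beta[2] * x + beta2 * x^2 + u_plot[plot] +
    rnorm(n, 0, residual_sd)
  data.frame(volume = exp(lnv), dbh = dbh, height = height,
             site = site, fragment = fragment, plot = plot)
}

test_that("published equations reproduce the printed worked examples", {
  expect_equal(predict_volume_published("eq1", 0.70, 33), 7.7,
               tolerance = 0.01)
  expect_equal(predict_volume_published("eq2", 0.70, 33), 7.4,
               tolerance = 0.01)
  expect_equal(predict_volume_published("eq1", 0.10, 10), 0.12,
               tolerance = 0.05)
  expect_equal(predict_volume_published("eq2", 0.10, 10), 0.18,
               tolerance = 0.02)
  expect_equal(predict_volume_published("eq3", 0.70), 8.14,
               tolerance = 0.001)
  expect_equal(predict_volume_published("eq4", 0.70), 6.27,
               tolerance = 0.001)
})

test_that("published-equation argument contracts hold", {
  expect_error(predict_volume_published("eq1", 0.5), "height")
  expect_error(predict_volume_published("eq2", -0.1, 10), "positive")
  expect_warning(predict_volume_published("eq3", 0.5, height = 20),
                 "ignored")
})

test_that("predictions are monotone in dbh and height on a grid", {
  d <- seq(0.02, 1.0, length.out = 25)
  h <- seq(2, 40, length.out = 20)
  for (eq in c("eq3", "eq4"))
    expect_true(all(diff(predict_volume_published(eq, d)) > 0))
  for (eq in c("eq1", "eq2")) {
    for (hh in h)
      expect_true(all(diff(predict_volume_published(eq, d, hh)) > 0))
    for (dd in d)
      expect_true(all(diff(predict_volume_published(eq, dd, h)) > 0))
  }
})

test_that("edge and interior height-based equations cross", {
  expect_gt(predict_volume_published("eq2", 0.10, 10),
            predict_volume_published("eq1", 0.10, 10))
  expect_lte(predict_volume_published("eq2", 0.70, 33),
             predict_volume_published("eq1", 0.70, 33))
})

test_that("log-log fitting recovers a noise-free law exactly", {
  d <- sim_loglog(1, n = 60, residual_sd = 0, sd_plot = 0)
  fit <- suppressWarnings(fit_loglog_allometry(d, "loglog_dbh"))
  expect_equal(fit$beta0, 2.80, tolerance = 1e-6)
  expect_equal(fit$beta1, 1.97, tolerance = 1e-6)
  expect_equal(unname(predict(fit, dbh = 0.7)),
               predict_volume_published("eq3", 0.7), tolerance = 1e-5)

  # dbh2h form, noise-free
  d2 <- d
  d2$volume <- exp(-0.21 + 0.81 * log(d2$dbh^2 * d2$height))
  fit2 <- suppressWarnings(fit_loglog_allometry(d2, "loglog_dbh2h"))
  expect_equal(fit2$beta0, -0.21, tolerance = 1e-6)
  expect_equal(fit2$beta1, 0.81, tolerance = 1e-6)
})

test_that("single-plot data fall back to plain least squares", {
  d <- sim_loglog(2, n = 40, sd_plot = 0)
  d$plot <- "P1"; d$site <- "S1"; d$fragment <- "F1"
  expect_warning(fit <- fit_loglog_allometry(d, "loglog_dbh"),
                 "least squares")
  expect_equal(unname(fit$random_sd), c(0, 0, 0))
  ols <- lm(log(volume) ~ log(dbh), data = d)
  expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-9)
  expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-9)
})

test_that("mixed fit recovers coefficients and variance components", {
  d <- sim_loglog(3, n = 500, sd_plot = 0.3, residual_sd = 0.3,
                  n_plots = 40)
  fit <- fit_loglog_allometry(d, "loglog_dbh")
  expect_equal(fit$beta1, 1.97, tolerance = 0.05)
  # plot sd = residual sd: proportions each near 0.5
  vc <- variance_components(fit)
  expect_equal(sum(vc), 1, tolerance = 1e-9)
  expect_equal(unname(vc["plot"] + vc["site"] + vc["fragment"]), 0.5,
               tolerance = 0.2)
  expect_equal(unname(vc["residual"]), 0.5, tolerance = 0.2)
})

test_that("AIC selects quadratic only when curvature is present", {
  pick <- function(seed, beta2) {
    d <- sim_loglog(seed, n = 300, beta2 = beta2, residual_sd = 0.2,
                    sd_plot = 0.05)
    suppressWarnings(select_quadratic_by_aic(d, "loglog_dbh"))$quadratic
  }
  linear_picks <- vapply(1:20, pick, logical(1), beta2 = 0)
  expect_gte(mean(!linear_picks), 0.9)
  quad_picks <- vapply(1:20, pick, logical(1), beta2 = 0.15)
  expect_gte(mean(quad_picks), 0.9)

  # exact tie on degenerate (noise-free linear) data -> linear
  d0 <- sim_loglog(5, n = 60, residual_sd = 0, sd_plot = 0)
  expect_false(suppressWarnings(
    select_quadratic_by_aic(d0, "loglog_dbh"))$quadratic)
})

test_that("power-law trait-height model recovers known parameters", {
  set.seed(10)
  n <- 200
  d <- data.frame(height = runif(n, 5, 35),
                  site = "S1", fragment = "F1",
                  plot = sample(c("P1", "P2", "P3"), n, replace = TRUE))
  d$trait <- 100 * d$height^(-0.5)
  fit <- suppressWarnings(fit_trait_height_model(d, "trait"))
  expect_equal(fit$beta0, 100, tolerance = 1e-4)
  expect_equal(fit$beta1, -0.5, tolerance = 1e-4)

  # flat trait: CI for the exponent covers 0
  d$trait <- 50 + rnorm(n, 0, 2)
  fit0 <- suppressWarnings(fit_trait_height_model(d, "trait"))
  ci <- fit0$beta1 + c(-1, 1) * 1.96 * fit0$se[2]
  expect_lt(ci[1], 0); expect_gt(ci[2], 0)

  # decreasing generator law -> fitted curve monotone decreasing
  d$trait <- 300 * d$height^(-0.4) * exp(rnorm(n, 0, 0.1))
  fit2 <- suppressWarnings(fit_trait_height_model(d, "trait"))
  hh <- seq(5, 35, 1)
  expect_true(all(diff(fit2$beta0 * hh^fit2$beta1) < 0))
})

test_that("permutation validation is reproducible and noise-sensitive", {
  d <- sim_loglog(7, n = 120, residual_sd = 0.25, sd_plot = 0.1)
  e1 <- suppressWarnings(
    permutation_validation(d, "loglog_dbh", n_reps = 25, seed = 99))
  e2 <- suppressWarnings(
    permutation_validation(d, "loglog_dbh", n_reps = 25, seed = 99))
  expect_identical(e1$coefficients, e2$coefficients)

  # zero noise: every replicate recovers identical coefficients
  d0 <- sim_loglog(8, n = 80, residual_sd = 0, sd_plot = 0)
  e0 <- suppressWarnings(
    permutation_validation(d0, "loglog_dbh", n_reps = 20, seed = 1))
  expect_equal(diff(range(e0$coefficients$beta1)), 0, tolerance = 1e-8)
  expect_equal(max(e0$coefficients$rmse), 0, tolerance = 1e-8)

  # heteroscedastic residuals widen the coefficient spread
  set.seed(11)
  base <- sim_loglog(11, n = 150, residual_sd = 0.001, sd_plot = 0)
  hom <- het <- base
  x <- log(base$dbh)
  hom$volume <- exp(log(base$volume) + rnorm(150, 0, 0.3))
  sd_het <- 0.3 * sqrt(2) * (x - min(x)) / (max(x) - min(x))
  het$volume <- exp(log(base$volume) + rnorm(150, 0, sd_het))
  sp <- function(d) {
    e <- suppressWarnings(
      permutation_validation(d, "loglog_dbh", n_reps = 60, seed = 5))
    sd(e$coefficients$beta1, na.rm = TRUE)
  }
  expect_gte(sp(het), sp(hom) * 0.9)
})
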