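#' Published allometric equations for woody volume
#'
#' Evaluates the four published woody-volume equations for Central
#' Amazonian fragmented forests. Equations 1 (interior) and 2 (edge)
#' predict volume from stem size and height, ln(DBH^2 H); equations 3
#' (interior) and 4 (edge) use DBH only:
#' \deqn{eq1:\ \ln V = -0.21 + 0.81 \ln(d^2 h)}
#' \deqn{eq2:\ \ln V = -0.13 + 0.72 \ln(d^2 h) + 0.016 \ln(d^2 h)^2}
#' \deqn{eq3:\ \ln V = 2.80 + 1.97 \ln d}
#' \deqn{eq4:\ \ln V = 2.45 + 1.72 \ln d}
#' Predictions exponentiate the ln-scale value directly, with no
#' back-transformation bias correction: the published worked examples
#' (7.7, 7.4, 0.12, 0.18, 8.14 and 6.27 m^3) are reproduced by plain
#' exponentiation.
#'
#' @param equation one of `"eq1"`, `"eq2"`, `"eq3"`, `"eq4"`.
#' @param dbh stem diameter at breast height in METRES (> 0). Note the
#'   unit: the printed coefficients reproduce the published worked examples
#'   only with diameter in metres, so census diameters in cm must be
#'   divided by 100 (as [stem_agb()] does).
#' @param height tree height in metres; required for `eq1`/`eq2`, ignored
#'   with a warning for `eq3`/`eq4`.
#' @return Predicted woody volume in m^3 (vectorised over `dbh`/`height`).
#' @export
#' @examples
#' predict_volume_published("eq1", dbh = 0.70, height = 33)  # ~7.7 m^3
#' predict_volume_published("eq3", dbh = 0.70)               # ~8.14 m^3
predict_volume_published <- function(equation = c("eq1", "eq2", "eq3", "eq4"),
                                     dbh, height = NULL) {
  equation <- match.arg(equation)
  if (any(!is.finite(dbh) | dbh <= 0)) stop("dbh must be positive (metres)")
  if (equation %in% c("eq1", "eq2")) {
    if (is.null(height)) stop("height is required for ", equation)
    if (any(!is.finite(height) | height <= 0))
      stop("height must be positive (metres)")
    x <- log(dbh^2 * height)
    lnv <- switch(equation,
                  eq1 = -0.21 + 0.81 * x,
                  eq2 = -0.13 + 0.72 * x + 0.016 * x^2)
  } else {
    if (!is.null(height))
      warning("height is ignored for ", equation, " (DBH-only model)")
    lnv <- switch(equation,
                  eq3 = 2.80 + 1.97 * log(dbh),
                  eq4 = 2.45 + 1.72 * log(dbh))
  }
  exp(lnv)
}

# published fixed-effect coefficients, used as generator defaults elsewhere
published_coefficients <- function(equation) {
  switch(equation,
         eq1 = c(beta0 = -0.21, beta1 = 0.81),
         eq2 = c(beta0 = -0.13, beta1 = 0.72, beta2 = 0.016),
         eq3 = c(beta0 = 2.80, beta1 = 1.97),
         eq4 = c(beta0 = 2.45, beta1 = 1.72),
         stop("unknown equation"))
}

# Fit lnv ~ x (+ x^2) with nested random intercepts, degrading gracefully:
# full nesting -> site/fragment -> site -> plain least squares. Returns
# list(fit, levels_used). Grouping columns must be named site, fragment,
# plot.
fit_nested_lme <- function(df, formula_fixed) {
  structures <- list(
    list(random = ~ 1 | site / fragment / plot,
         levels = c("site", "fragment", "plot")),
    list(random = ~ 1 | site / fragment, levels = c("site", "fragment")),
    list(random = ~ 1 | site, levels = "site"))
  grp_counts <- c(
    site = length(unique(df$site)),
    fragment = length(unique(paste(df$site, df$fragment))),
    plot = length(unique(paste(df$site, df$fragment, df$plot))))
  for (s in structures) {
    # nesting levels with a single group carry no information; skip ahead
    if (any(grp_counts[s$levels] < 2L)) next
    fit <- tryCatch(
      nlme::lme(fixed = formula_fixed, random = s$random, data = df,
                method = "REML"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (length(s$levels) < 3L)
        warning("random-effect structure reduced to ",
                paste(s$levels, collapse = "/"), call. = FALSE)
      return(list(fit = fit, levels = s$levels))
    }
  }
  warning("mixed model unfittable; falling back to plain least squares",
          call. = FALSE)
  list(fit = stats::lm(formula_fixed, data = df), levels = character(0))
}

# standard deviations of the nested random intercepts, named
# site/fragment/plot with 0 for levels not in the fit
extract_random_sd <- function(fitted) {
  out <- c(site = 0, fragment = 0, plot = 0)
  if (inherits(fitted$fit, "lme")) {
    vc <- nlme::VarCorr(fitted$fit)
    sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    ints <- which(rownames(vc) == "(Intercept)")
    out[fitted$levels] <- sds[ints][seq_along(fitted$levels)]
  }
  out
}

residual_sd_of <- function(fit) {
  if (inherits(fit, "lme")) fit$sigma else summary(fit)$sigma
}

#' Fit a log-log volume allometry with nested random intercepts
#'
#' Fits `ln(volume) ~ ln(X) (+ ln(X)^2)` by restricted maximum likelihood
#' with random intercepts for plot nested within fragment nested within
#' site, where X is `DBH^2 * H` (`form = "loglog_dbh2h"`) or `DBH`
#' (`form = "loglog_dbh"`). If the nested fit fails (too few groups or
#' non-convergence) the deepest random level is dropped with a warning;
#' the terminal fallback is plain least squares with zero random-effect
#' standard deviations.
#'
#' @param data data frame with columns `volume` (m^3), `dbh` (m), `height`
#'   (m, required for the dbh2h form) and grouping columns `site`,
#'   `fragment`, `plot`.
#' @param form `"loglog_dbh2h"` or `"loglog_dbh"`.
#' @param quadratic include a quadratic term in ln(X)?
#' @return An object of class `allometric_fit`: list with `form`,
#'   `quadratic`, `beta0`, `beta1`, `beta2` (NA unless quadratic),
#'   `se` (named vector), `random_sd` (site/fragment/plot), `residual_sd`,
#'   `aic`, `n`, and the underlying `model`.
#' @export
fit_loglog_allometry <- function(data,
                                 form = c("loglog_dbh2h", "loglog_dbh"),
                                 quadratic = FALSE) {
  form <- match.arg(form)
  df <- prepare_loglog_data(data, form)
  if (nrow(df) < 10L) stop("need at least 10 complete rows, got ", nrow(df))
  fixed <- if (quadratic) lnv ~ x + I(x^2) else lnv ~ x
  fitted <- fit_nested_lme(df, fixed)
  fe <- if (inherits(fitted$fit, "lme")) nlme::fixef(fitted$fit)
        else stats::coef(fitted$fit)
  se <- sqrt(diag(stats::vcov(fitted$fit)))
  structure(list(
    form = form, quadratic = quadratic,
    beta0 = unname(fe[1L]), beta1 = unname(fe[2L]),
    beta2 = if (quadratic) unname(fe[3L]) else NA_real_,
    se = stats::setNames(unname(se),
                         c("beta0", "beta1", if (quadratic) "beta2")),
    random_sd = extract_random_sd(fitted),
    residual_sd = residual_sd_of(fitted$fit),
    aic = stats::AIC(fitted$fit),
    n = nrow(df),
    model = fitted$fit), class = "allometric_fit")
}

prepare_loglog_data <- function(data, form) {
  need <- c("volume", "dbh", "site", "fragment", "plot",
            if (form == "loglog_dbh2h") "height")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- data
  df$x <- if (form == "loglog_dbh2h") log(df$dbh^2 * df$height)
          else log(df$dbh)
  df$lnv <- log(df$volume)
  df <- df[stats::complete.cases(df[c("lnv", "x", "site", "fragment",
                                      "plot")]), , drop = FALSE]
  df$site <- factor(df$site)
  df$fragment <- factor(df$fragment)
  df$plot <- factor(df$plot)
  df
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("<allometric_fit> ", x$form,
      if (x$quadratic) " (quadratic)" else " (linear)",
      ": beta0 = ", signif(x$beta0, 4), ", beta1 = ", signif(x$beta1, 4),
      if (x$quadratic) paste0(", beta2 = ", signif(x$beta2, 4)),
      ", residual sd = ", signif(x$residual_sd, 3),
      ", AIC = ", round(x$aic, 1), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Predict woody volume from a fitted allometry
#'
#' @param object an `allometric_fit`.
#' @param dbh diameter in metres.
#' @param height height in metres (required for the dbh2h form).
#' @param ... unused.
#' @return Predicted volume in m^3 (population level, plain
#'   exponentiation).
#' @export
predict.allometric_fit <- function(object, dbh, height = NULL, ...) {
  x <- if (object$form == "loglog_dbh2h") {
    if (is.null(height)) stop("height required for dbh2h form")
    log(dbh^2 * height)
  } else log(dbh)
  lnv <- object$beta0 + object$beta1 * x +
    if (object$quadratic) object$beta2 * x^2 else 0
  exp(lnv)
}

#' Select linear vs. quadratic allometry by AIC
#'
#' Fits the linear and quadratic variants of the log-log allometry and
#' returns the one with the lower AIC. Because REML likelihoods are not
#' comparable across different fixed-effect structures, the comparison
#' fits use maximum likelihood; the selected form is then refitted by
#' REML. Ties (|delta AIC| < 1e-9) resolve to the simpler linear model.
#'
#' @inheritParams fit_loglog_allometry
#' @return The selected `allometric_fit` (REML), with attribute
#'   `aic_comparison` holding the ML AICs of both candidates.
#' @export
select_quadratic_by_aic <- function(data,
                                    form = c("loglog_dbh2h", "loglog_dbh")) {
  form <- match.arg(form)
  df <- prepare_loglog_data(data, form)
  if (nrow(df) < 10L) stop("need at least 10 complete rows, got ", nrow(df))
  aic_ml <- vapply(c(linear = FALSE, quadratic = TRUE), function(q) {
    fixed <- if (q) lnv ~ x + I(x^2) else lnv ~ x
    f <- fit_nested_lme_ml(df, fixed)
    stats::AIC(f)
  }, numeric(1))
  quad <- (aic_ml["quadratic"] < aic_ml["linear"] - 1e-9)
  out <- fit_loglog_allometry(data, form, quadratic = unname(quad))
  attr(out, "aic_comparison") <- aic_ml
  out
}

fit_nested_lme_ml <- function(df, fixed) {
  f <- tryCatch(
    nlme::lme(fixed = fixed, random = ~ 1 | site / fragment / plot,
              data = df, method = "ML"),
    error = function(e) NULL)
  if (is.null(f)) f <- stats::lm(fixed, data = df)
  f
}

#' Fit a power-law trait-height model with nested random intercepts
#'
#' Fits `trait = beta0 * height^beta1 + u + e` by nonlinear mixed-effects
#' estimation with a random intercept on `beta0` for the nested grouping,
#' initialised from an ordinary log-log least-squares fit. On
#' non-convergence the random structure is simplified level by level and
#' the starting values are perturbed over a small restart grid; the final
#' fallback is plain nonlinear least squares. If no candidate converges an
#' error is raised carrying the best log-log starting values.
#'
#' @param data data frame with the trait column, `height` and grouping
#'   columns `site`, `fragment`, `plot`; trait and height must be positive.
#' @param trait name of the trait column.
#' @return An object of class `power_law_fit`: list with `trait`, `beta0`,
#'   `beta1`, `se`, `random_sd`, `residual_sd`, `n`, `converged`, `model`.
#' @export
fit_trait_height_model <- function(data, trait) {
  if (!trait %in% names(data)) stop("no column '", trait, "'")
  df <- data[stats::complete.cases(data[c(trait, "height")]), , drop = FALSE]
  df$.y <- df[[trait]]
  if (any(df$.y <= 0) || any(df$height <= 0))
    stop("trait and height must be positive for the power-law model")
  df$site <- factor(df$site); df$fragment <- factor(df$fragment)
  df$plot <- factor(df$plot)
  ols <- stats::lm(log(.y) ~ log(height), data = df)
  start0 <- c(beta0 = unname(exp(stats::coef(ols)[1L])),
              beta1 = unname(stats::coef(ols)[2L]))
  randoms <- list(nlme::pdIdent(beta0 ~ 1))
  grouping <- list(~ 1 | site / fragment / plot, ~ 1 | plot, NULL)
  fit <- NULL; levels_used <- character(0)
  for (scale in c(1, 0.5, 2)) {
    start <- start0 * c(scale, 1)
    for (g in seq_along(grouping)) {
      fit <- tryCatch({
        if (is.null(grouping[[g]])) {
          # Levenberg-Marquardt: stable on near-zero-residual data
          minpack.lm::nlsLM(.y ~ beta0 * height^beta1, data = df,
                            start = as.list(start))
        } else {
          nlme::nlme(.y ~ beta0 * height^beta1, data = df,
                     fixed = beta0 + beta1 ~ 1,
                     random = beta0 ~ 1,
                     groups = grouping[[g]],
                     start = start,
                     control = nlme::nlmeControl(returnObject = FALSE,
                                                 maxIter = 100))
        }
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        levels_used <- switch(g, c("site", "fragment", "plot"), "plot",
                              character(0))
        break
      }
    }
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    err <- simpleError(
      paste0("power-law fit did not converge for '", trait, "'"))
    err$best_candidate <- start0
    stop(err)
  }
  fe <- if (inherits(fit, "nlme")) nlme::fixef(fit) else stats::coef(fit)
  rsd <- c(site = 0, fragment = 0, plot = 0)
  if (inherits(fit, "nlme")) {
    vc <- nlme::VarCorr(fit)
    sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    ints <- grep("beta0", rownames(vc))
    rsd[levels_used] <- sds[ints][seq_along(levels_used)]
  }
  structure(list(
    trait = trait,
    beta0 = unname(fe["beta0"]), beta1 = unname(fe["beta1"]),
    se = sqrt(diag(stats::vcov(fit)))[1:2],
    random_sd = rsd,
    residual_sd = if (inherits(fit, "nlme")) fit$sigma
                  else summary(fit)$sigma,
    n = nrow(df),
    converged = TRUE,
    model = fit), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> ", x$trait, " = ", signif(x$beta0, 4),
      " * height^", signif(x$beta1, 4), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Permutation validation of an allometric model
#'
#' Assesses model stability by refitting on random calibration subsets:
#' for each of `n_reps` permutations the data are split into a calibration
#' fraction (`split`, stratified by plot so every plot contributes to
#' calibration) and a validation remainder; the model is refitted on the
#' calibration set and the root-mean-square error of ln(volume) on the
#' held-out set is recorded together with the coefficient draws.
#'
#' @inheritParams fit_loglog_allometry
#' @param n_reps number of random permutations (default 200).
#' @param split calibration fraction in (0, 1) (default 0.8).
#' @param seed integer seed; the ensemble is fully reproducible given the
#'   seed.
#' @param stratify stratify the split by plot (default TRUE); FALSE draws
#'   a plain uniform split.
#' @return An object of class `permutation_ensemble`: list with
#'   `coefficients` (data frame rep/beta0/beta1/beta2/rmse/ok), `n_reps`,
#'   `split`, `seed`, `n_failed`. Fails only if more than 10% of the
#'   replicate fits fail.
#' @export
permutation_validation <- function(data,
                                   form = c("loglog_dbh2h", "loglog_dbh"),
                                   quadratic = FALSE, n_reps = 200,
                                   split = 0.8, seed = 20191980,
                                   stratify = TRUE) {
  form <- match.arg(form)
  stopifnot(split > 0, split < 1, n_reps >= 1)
  df <- prepare_loglog_data(data, form)
  if (nrow(df) < 10L) stop("need at least 10 complete rows, got ", nrow(df))
  rng <- local({ set.seed(seed); lapply(seq_len(n_reps), function(i)
    sample.int(.Machine$integer.max, 1L)) })
  reps <- lapply(seq_len(n_reps), function(i) {
    set.seed(rng[[i]])
    cal_idx <- if (stratify) {
      unlist(lapply(split(seq_len(nrow(df)), df$plot, drop = TRUE),
                    function(ix) {
                      k <- max(1L, round(split * length(ix)))
                      if (length(ix) == 1L) ix else sample(ix, k)
                    }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(df)), max(2L, round(split * nrow(df))))
    }
    val_idx <- setdiff(seq_len(nrow(df)), cal_idx)
    res <- tryCatch({
      f <- fit_loglog_allometry(df[cal_idx, , drop = FALSE], form,
                                quadratic)
      pred <- f$beta0 + f$beta1 * df$x[val_idx] +
        (if (quadratic) f$beta2 * df$x[val_idx]^2 else 0)
      rmse <- if (length(val_idx)) {
        sqrt(mean((df$lnv[val_idx] - pred)^2))
      } else NA_real_
      data.frame(rep = i, beta0 = f$beta0, beta1 = f$beta1,
                 beta2 = f$beta2, rmse = rmse, ok = TRUE)
    }, error = function(e)
      data.frame(rep = i, beta0 = NA_real_, beta1 = NA_real_,
                 beta2 = NA_real_, rmse = NA_real_, ok = FALSE))
    res
  })
  tab <- do.call(rbind, reps)
  n_failed <- sum(!tab$ok)
  if (n_failed > 0.1 * n_reps)
    stop("permutation validation failed: ", n_failed, "/", n_reps,
         " replicate fits failed")
  structure(list(coefficients = tab, n_reps = n_reps, split = split,
                 seed = seed, n_failed = n_failed),
            class = "permutation_ensemble")
}

#' @export
print.permutation_ensemble <- function(x, ...) {
  ok <- x$coefficients[x$coefficients$ok, ]
  cat("<permutation_ensemble> ", x$n_reps, " reps (", x$n_failed,
      " failed), split ", x$split, "\n", sep = "")
  cat("  beta1: mean ", signif(mean(ok$beta1), 4), ", sd ",
      signif(stats::sd(ok$beta1), 4), "; held-out RMSE(lnV): mean ",
      signif(mean(ok$rmse, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}
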