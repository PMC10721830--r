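#' Fit an edge-effect model for an architectural trait
#'
#' Fits the additive-plus-interaction mixed model
#' `trait = b0 + b1*edge + b2*H + b3*edge*H + u + e`
#' by REML with random intercepts for plot nested within fragment nested
#' within site. `edge` is coded 1 when `distance_to_edge < threshold_d`
#' (strict) and 0 otherwise; the interaction allows the edge effect to
#' differ between short colonising and tall surviving trees.
#'
#' @param data data frame with the trait column and `distance_to_edge`,
#'   `height`, `site`, `fragment`, `plot`.
#' @param trait name of the response column.
#' @param threshold_d edge/interior threshold distance in metres.
#' @param min_stratum minimum number of trees required in each stratum
#'   (default 5); below the floor the threshold is treated as degenerate.
#' @return An object of class `edge_model_fit`: list with `response`,
#'   `threshold_d`, `coefficients` (data frame term/estimate/se/t/df/p),
#'   `random_sd`, `residual_sd`, `n_edge`, `n_interior`, `model`.
#' @export
fit_edge_trait_model <- function(data, trait, threshold_d,
                                 min_stratum = 5L) {
  df <- prepare_edge_data(data, trait, threshold_d)
  check_strata(df, threshold_d, min_stratum)
  fitted <- fit_nested_lme(df, .y ~ edge * height)
  build_edge_fit(fitted, df, response = trait, threshold_d = threshold_d)
}

prepare_edge_data <- function(data, response, threshold_d,
                              needs_height = TRUE) {
  need <- c(response, "distance_to_edge",
            if (needs_height) "height", "site", "fragment", "plot")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- data[stats::complete.cases(data[need]), , drop = FALSE]
  df$.y <- df[[response]]
  df$edge <- as.numeric(df$distance_to_edge < threshold_d)
  df$site <- factor(df$site); df$fragment <- factor(df$fragment)
  df$plot <- factor(df$plot)
  df
}

check_strata <- function(df, threshold_d, min_stratum) {
  n_edge <- sum(df$edge == 1); n_int <- sum(df$edge == 0)
  if (n_edge < min_stratum || n_int < min_stratum)
    stop("degenerate threshold at ", threshold_d, " m: ", n_edge,
         " edge / ", n_int, " interior trees (floor ", min_stratum, ")")
  invisible(TRUE)
}

build_edge_fit <- function(fitted, df, response, threshold_d) {
  fit <- fitted$fit
  if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], df = tt[, "DF"],
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        row.names = NULL)
  } else {
    tt <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(tt), estimate = tt[, 1L],
                        se = tt[, 2L], df = fit$df.residual,
                        t = tt[, 3L], p = tt[, 4L], row.names = NULL)
  }
  structure(list(
    response = response, threshold_d = threshold_d,
    coefficients = coefs,
    random_sd = extract_random_sd(fitted),
    residual_sd = residual_sd_of(fit),
    n_edge = sum(df$edge == 1), n_interior = sum(df$edge == 0),
    model = fit), class = "edge_model_fit")
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat("<edge_model_fit> ", x$response, " at threshold ", x$threshold_d,
      " m (", x$n_edge, " edge / ", x$n_interior, " interior)\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# t-value of a fitted term, NA if absent
edge_term_t <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$t[i]
}

#' Scan candidate edge-extent thresholds
#'
#' Determines the spatial extent of an edge effect: refits the edge model
#' at every candidate threshold distance and selects the threshold with
#' the maximum absolute t-value of the designated edge term. Thresholds
#' where either stratum holds fewer than `min_stratum` trees are recorded
#' as missing and excluded from the argmax; exact ties resolve to the
#' smallest distance. Note that maximising |t| over thresholds inflates
#' the apparent significance of the selected term (a selection effect);
#' the chosen extent is an estimate of where the effect is strongest, not
#' a hypothesis test.
#'
#' @param data trait table as in [fit_edge_trait_model()] (or allometry
#'   data when `model = "allometry"`).
#' @param response trait column to model (trait mode), or ignored in
#'   allometry mode.
#' @param grid candidate thresholds in metres (default 1:100).
#' @param edge_term name of the scanned coefficient: `"edge"` for the
#'   trait model; for the allometry model the edge x ln(X) interaction is
#'   scanned automatically.
#' @param model `"trait"` (default) fits [fit_edge_trait_model()];
#'   `"allometry"` fits [fit_edge_allometry_interaction()].
#' @param predictor passed to [fit_edge_allometry_interaction()] in
#'   allometry mode.
#' @param min_stratum per-stratum tree floor (default 5).
#' @param literal passed through in allometry mode.
#' @return An object of class `edge_extent_result`: list with `response`,
#'   `grid`, `t_values` (NA where unfittable), `chosen_extent`,
#'   `edge_term`.
#' @export
scan_edge_extent <- function(data, response, grid = 1:100,
                             edge_term = "edge",
                             model = c("trait", "allometry"),
                             predictor = c("dbh", "dbh2h"),
                             min_stratum = 5L, literal = FALSE) {
  model <- match.arg(model); predictor <- match.arg(predictor)
  dist_col <- data$distance_to_edge
  if (length(unique(dist_col[!is.na(dist_col)])) < 2L)
    stop("need at least 2 distinct distance_to_edge values")
  if (model == "allometry") edge_term <- "edge:lnx"
  t_values <- vapply(grid, function(d) {
    f <- tryCatch({
      if (model == "trait")
        fit_edge_trait_model(data, response, d, min_stratum)
      else
        fit_edge_allometry_interaction(data, predictor, d, min_stratum,
                                       literal = literal)
    }, error = function(e) NULL)
    if (is.null(f)) NA_real_ else edge_term_t(f, edge_term)
  }, numeric(1))
  if (all(is.na(t_values)))
    stop("no fittable threshold in the scan grid")
  # argmax of |t|; ties go to the smallest distance (grid is ordered)
  best <- which.max(abs(t_values))
  structure(list(response = if (model == "trait") response
                            else paste0("ln_volume~", predictor),
                 grid = grid, t_values = t_values,
                 chosen_extent = grid[best], edge_term = edge_term),
            class = "edge_extent_result")
}

#' @export
print.edge_extent_result <- function(x, ...) {
  cat("<edge_extent_result> ", x$response, ": chosen extent ",
      x$chosen_extent, " m (|t| = ",
      signif(abs(x$t_values[match(x$chosen_extent, x$grid)]), 4),
      ", term '", x$edge_term, "')\n", sep = "")
  invisible(x)
}

#' Fit an edge x allometry interaction model
#'
#' Tests whether the log-log volume allometry differs between edge and
#' interior trees:
#' `ln(V) = b0 + g*ln(X) + b1*(edge x ln(X)) + u + e`
#' with X = DBH (m) or DBH^2*H and nested random intercepts. The scanned
#' edge term is the interaction coefficient `b1`. With `literal = TRUE`
#' the main `ln(X)` slope is omitted so that the model contains only the
#' intercept and the interaction; this variant cannot represent a non-zero
#' interior slope and exists for comparison only.
#'
#' @param data data frame with `volume` (m^3), `dbh` (m), `height` (m,
#'   dbh2h only), `distance_to_edge`, `site`, `fragment`, `plot`.
#' @param predictor `"dbh"` or `"dbh2h"`.
#' @param threshold_d edge threshold in metres (strict `<`).
#' @param min_stratum per-stratum floor (default 5).
#' @param literal omit the main ln(X) slope (default FALSE).
#' @return An `edge_model_fit`; the interaction row is named `edge:lnx`.
#' @export
fit_edge_allometry_interaction <- function(data,
                                           predictor = c("dbh", "dbh2h"),
                                           threshold_d, min_stratum = 5L,
                                           literal = FALSE) {
  predictor <- match.arg(predictor)
  need <- c("volume", "dbh", if (predictor == "dbh2h") "height")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(data$volume <= 0, na.rm = TRUE) ||
      any(data$dbh <= 0, na.rm = TRUE))
    stop("volume and dbh must be positive")
  df <- data
  df$lnx <- if (predictor == "dbh2h") log(df$dbh^2 * df$height)
            else log(df$dbh)
  df$lnv <- log(df$volume)
  df <- prepare_edge_data(df, "lnv", threshold_d, needs_height = FALSE)
  df <- df[stats::complete.cases(df[c("lnv", "lnx")]), , drop = FALSE]
  check_strata(df, threshold_d, min_stratum)
  fixed <- if (literal) .y ~ edge:lnx else .y ~ lnx + edge:lnx
  fitted <- fit_nested_lme(df, fixed)
  out <- build_edge_fit(fitted, df,
                        response = paste0("ln_volume~", predictor),
                        threshold_d = threshold_d)
  out$coefficients$term <- sub("^edge:lnx$|^lnx:edge$", "edge:lnx",
                               out$coefficients$term)
  out
}

#' Variance components of a mixed-model fit
#'
#' Normalises the random-intercept variances (site, fragment, plot) and
#' the residual variance of a fitted model to proportions of the total,
#' summing to 1. The within-plot (residual) share measures how much trait
#' variability is local rather than structured by the spatial nesting.
#'
#' @param fit an `edge_model_fit`, `allometric_fit` or `power_law_fit`.
#' @return Named numeric vector (site, fragment, plot, residual) of
#'   non-negative proportions summing to 1.
#' @export
variance_components <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$random_sd),
            !is.null(fit$residual_sd))
  v <- c(fit$random_sd[c("site", "fragment", "plot")]^2,
         residual = fit$residual_sd^2)
  names(v) <- c("site", "fragment", "plot", "residual")
  v / sum(v)
}
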