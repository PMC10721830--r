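#' Build a wood-density lookup table
#'
#' Wraps a taxon-to-density table (g cm^-3) and precomputes genus means,
#' family means and the overall mean once, so that lookups are
#' deterministic and order-independent.
#'
#' @param records data frame with columns `family`, `genus`, `species` and
#'   `wd_g_cm3`; densities must lie in (0.05, 1.5) g cm^-3.
#' @return An object of class `wood_density_table`.
#' @export
wood_density_table <- function(records) {
  need <- c("family", "genus", "species", "wd_g_cm3")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(records)) stop("wood-density table is empty")
  wd <- records$wd_g_cm3
  if (any(!is.finite(wd) | wd <= 0.05 | wd >= 1.5))
    stop("wood densities must lie in (0.05, 1.5) g cm^-3")
  species_key <- paste(records$genus, records$species)
  structure(list(
    records = records,
    species_mean = tapply(wd, species_key, mean),
    genus_mean = tapply(wd, records$genus, mean),
    family_mean = tapply(wd, records$family, mean),
    overall_mean = mean(wd)), class = "wood_density_table")
}

#' @export
print.wood_density_table <- function(x, ...) {
  cat("<wood_density_table> ", nrow(x$records), " records, ",
      length(x$genus_mean), " genera, ", length(x$family_mean),
      " families; overall mean ", round(x$overall_mean, 3),
      " g cm^-3\n", sep = "")
  invisible(x)
}

#' Look up wood density with taxonomic fallback
#'
#' Resolves wood density for a stem at the finest taxonomic level
#' available: exact genus+species match, then genus mean, then family
#' mean, then the overall table mean as the terminal fallback. Vectorised
#' over stems.
#'
#' @param family,genus,species character vectors (recycled to a common
#'   length; blanks and NAs allowed).
#' @param table a [wood_density_table()].
#' @return data frame with columns `wd` (g cm^-3) and `resolution`
#'   (`"species"`, `"genus"`, `"family"` or `"overall"`).
#' @export
lookup_wood_density <- function(family, genus, species, table) {
  stopifnot(inherits(table, "wood_density_table"))
  n <- max(length(family), length(genus), length(species))
  family <- rep_len(as.character(family), n)
  genus <- rep_len(as.character(genus), n)
  species <- rep_len(as.character(species), n)
  wd <- rep(NA_real_, n)
  res <- rep(NA_character_, n)
  sp <- table$species_mean[paste(genus, species)]
  hit <- !is.na(sp) & !is.na(species) & nzchar(species)
  wd[hit] <- sp[hit]; res[hit] <- "species"
  ge <- table$genus_mean[genus]
  hit2 <- is.na(wd) & !is.na(ge)
  wd[hit2] <- ge[hit2]; res[hit2] <- "genus"
  fa <- table$family_mean[family]
  hit3 <- is.na(wd) & !is.na(fa)
  wd[hit3] <- fa[hit3]; res[hit3] <- "family"
  left <- is.na(wd)
  if (any(left)) {
    wd[left] <- table$overall_mean; res[left] <- "overall"
    warning(sum(left), " stem(s) resolved only to the overall mean ",
            "wood density", call. = FALSE)
  }
  data.frame(wd = unname(wd), resolution = res, stringsAsFactors = FALSE)
}

#' Aboveground biomass of a single stem
#'
#' Converts a census diameter to woody volume with the published DBH-only
#' allometry (interior equation eq3, or edge equation eq4 when the stem
#' experiences edge conditions) and multiplies by wood density. The unit
#' identity 1 g cm^-3 = 1 Mg m^-3 makes the product biomass in Mg.
#'
#' @param dbh_cm stem diameter in centimetres (>= 10, the census
#'   inclusion rule).
#' @param stem_edge logical: does the stem fall under edge allometry?
#' @param wd wood density in g cm^-3.
#' @return Aboveground biomass in Mg (vectorised).
#' @export
stem_agb <- function(dbh_cm, stem_edge, wd) {
  if (any(dbh_cm < 10))
    stop("census stems must have DBH >= 10 cm")
  n <- max(length(dbh_cm), length(stem_edge), length(wd))
  dbh_cm <- rep_len(dbh_cm, n); stem_edge <- rep_len(stem_edge, n)
  wd <- rep_len(wd, n)
  v <- numeric(n)
  if (any(stem_edge))
    v[stem_edge] <- predict_volume_published("eq4",
                                             dbh_cm[stem_edge] / 100)
  if (any(!stem_edge))
    v[!stem_edge] <- predict_volume_published("eq3",
                                              dbh_cm[!stem_edge] / 100)
  v * wd
}

#' Plot-level aboveground biomass
#'
#' Sums stem-level AGB per plot and divides by plot area (Mg ha^-1). A
#' stem uses the edge allometry (eq4) when its plot lies closer to the
#' forest margin than `allometry_extent`; stem-level distances are not
#' available in 1-ha census plots, so the plot distance is the proxy for
#' every stem it contains. Set `allometry_extent = 0` to apply the
#' interior allometry everywhere.
#'
#' @param census data frame with columns `stem_id`, `plot_id`, `dbh_cm`,
#'   `family`, `genus`, `species`.
#' @param plots data frame with columns `plot_id`, `site`, `area_ha`,
#'   `distance_to_edge_m`.
#' @param wd_table a [wood_density_table()].
#' @param allometry_extent distance in metres within which the edge
#'   allometry applies (default 55).
#' @return data frame with one row per plot: `plot_id`, `site`,
#'   `area_ha`, `distance_to_edge_m`, `n_stems`, `agb` (Mg ha^-1).
#'   Stems with DBH < 10 cm are dropped with a warning; empty plots get
#'   0 with a warning.
#' @export
plot_agb <- function(census, plots, wd_table, allometry_extent = 55) {
  need_c <- c("stem_id", "plot_id", "dbh_cm", "family", "genus", "species")
  need_p <- c("plot_id", "site", "area_ha", "distance_to_edge_m")
  missing_cols <- c(setdiff(need_c, names(census)),
                    setdiff(need_p, names(plots)))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(plots$area_ha <= 0)) stop("plot areas must be positive")
  unknown <- setdiff(census$plot_id, plots$plot_id)
  if (length(unknown))
    stop("census references unknown plot_id: ",
         paste(unique(unknown), collapse = ", "))
  small <- census$dbh_cm < 10
  if (any(small)) {
    warning(sum(small), " stem(s) with DBH < 10 cm rejected",
            call. = FALSE)
    census <- census[!small, , drop = FALSE]
  }
  pidx <- match(census$plot_id, plots$plot_id)
  stem_edge <- plots$distance_to_edge_m[pidx] < allometry_extent
  wd <- lookup_wood_density(census$family, census$genus, census$species,
                            wd_table)$wd
  agb_stem <- stem_agb(census$dbh_cm, stem_edge, wd)
  tot <- tapply(agb_stem, factor(census$plot_id,
                                 levels = plots$plot_id), sum)
  tot[is.na(tot)] <- 0
  nst <- tapply(rep(1, nrow(census)),
                factor(census$plot_id, levels = plots$plot_id), sum)
  nst[is.na(nst)] <- 0
  if (any(nst == 0))
    warning(sum(nst == 0), " plot(s) contain no stems; AGB set to 0",
            call. = FALSE)
  data.frame(plot_id = plots$plot_id, site = plots$site,
             area_ha = plots$area_ha,
             distance_to_edge_m = plots$distance_to_edge_m,
             n_stems = as.integer(nst),
             agb = unname(tot / plots$area_ha),
             stringsAsFactors = FALSE)
}

#' Mixed-model comparison of edge and interior plot AGB
#'
#' Fits `AGB ~ edge` with a random intercept per forest site, where
#' `edge` indicates plots closer to the margin than `edge_threshold`
#' (default 100 m). With a single site the model falls back to ordinary
#' least squares with a warning. Confidence intervals on the class means
#' come from the model-based standard errors.
#'
#' @param agb_table output of [plot_agb()].
#' @param edge_threshold edge/interior classification distance in metres.
#' @return list with `estimate` (edge minus interior, Mg ha^-1), `se`,
#'   `t`, `p`, `mean_interior`, `mean_edge`, `ci_interior`, `ci_edge`,
#'   `ci_effect` (95%), `n_edge`, `n_interior`, `model`.
#' @export
fit_agb_edge_model <- function(agb_table, edge_threshold = 100) {
  df <- agb_table
  df$edge <- as.numeric(df$distance_to_edge_m < edge_threshold)
  if (sum(df$edge == 1) < 2L || sum(df$edge == 0) < 2L)
    stop("need at least 2 plots per class")
  df$site <- factor(df$site)
  fit <- NULL
  if (nlevels(df$site) >= 2L) {
    fit <- tryCatch(
      nlme::lme(agb ~ edge, random = ~ 1 | site, data = df,
                method = "REML"),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    warning("single site or unfittable mixed model; using plain least ",
            "squares", call. = FALSE)
    fit <- stats::lm(agb ~ edge, data = df)
    tt <- summary(fit)$coefficients
    est <- tt["edge", 1L]; se <- tt["edge", 2L]
    tv <- tt["edge", 3L]; pv <- tt["edge", 4L]
    vc <- stats::vcov(fit)
  } else {
    tt <- summary(fit)$tTable
    est <- tt["edge", "Value"]; se <- tt["edge", "Std.Error"]
    tv <- tt["edge", "t-value"]; pv <- tt["edge", "p-value"]
    vc <- stats::vcov(fit)
  }
  b <- if (inherits(fit, "lme")) nlme::fixef(fit) else stats::coef(fit)
  mean_int <- unname(b[1L]); mean_edge <- unname(b[1L] + b[2L])
  se_int <- sqrt(vc[1L, 1L])
  se_edge <- sqrt(vc[1L, 1L] + vc[2L, 2L] + 2 * vc[1L, 2L])
  z <- stats::qnorm(0.975)
  list(estimate = unname(est), se = unname(se), t = unname(tv),
       p = unname(pv),
       mean_interior = mean_int, mean_edge = mean_edge,
       ci_interior = mean_int + c(-1, 1) * z * se_int,
       ci_edge = mean_edge + c(-1, 1) * z * se_edge,
       ci_effect = unname(est) + c(-1, 1) * z * unname(se),
       n_edge = sum(df$edge == 1), n_interior = sum(df$edge == 0),
       model = fit)
}

#' Decompose the edge AGB deficit into structure and allometry components
#'
#' Separates the aboveground-biomass difference between edge and interior
#' plots into two additive parts. Edge-plot AGB is computed twice: once
#' with the interior allometry applied everywhere (differences from the
#' interior plots then reflect forest structure only: stem sizes, stem
#' density, composition), and once with the edge allometry applied within
#' `allometry_extent` of the margin (adding the allometric change). With
#' means \eqn{I} (interior plots, interior allometry), \eqn{E_{int}}
#' (edge plots, interior allometry) and \eqn{E_{edge}} (edge plots, edge
#' allometry rule):
#' structure = \eqn{I - E_{int}}, allometry = \eqn{E_{int} - E_{edge}},
#' and total = structure + allometry = \eqn{I - E_{edge}} exactly.
#'
#' @inheritParams plot_agb
#' @param structure_extent distance in metres classifying plots as edge
#'   (default 100).
#' @param allometry_extent distance in metres within which the edge
#'   allometry applies (default 55); 0 disables the rule, forcing the
#'   allometry component to exactly 0.
#' @return An object of class `agb_decomposition`: list with
#'   `mean_agb_interior`, `mean_agb_edge_interior_eq`,
#'   `mean_agb_edge_edge_eq`, `structure_component`,
#'   `allometry_component`, `total_effect` (all Mg ha^-1), `ci95` (list
#'   per quantity), `n_edge`, `n_interior`, and the two mixed-model fits.
#'   Component signs follow the definition above: positive components are
#'   AGB losses at the edge.
#' @export
decompose_edge_effect <- function(census, plots, wd_table,
                                  structure_extent = 100,
                                  allometry_extent = 55) {
  plots$edge_class <- ifelse(plots$distance_to_edge_m < structure_extent,
                             "edge", "interior")
  if (!any(plots$edge_class == "edge") ||
      !any(plots$edge_class == "interior"))
    stop("both edge and interior plot classes must be populated")
  agb_int_eq <- plot_agb(census, plots, wd_table, allometry_extent = 0)
  agb_edge_eq <- plot_agb(census, plots, wd_table,
                          allometry_extent = allometry_extent)
  is_edge <- plots$edge_class == "edge"
  m_interior <- mean(agb_int_eq$agb[!is_edge])
  m_edge_int <- mean(agb_int_eq$agb[is_edge])
  m_edge_edge <- mean(agb_edge_eq$agb[is_edge])
  structure_component <- m_interior - m_edge_int
  allometry_component <- m_edge_int - m_edge_edge
  # mixed-model CIs: structure comparison (all-interior allometry) and
  # total comparison (edge allometry rule active)
  fit_structure <- fit_agb_edge_model(agb_int_eq, structure_extent)
  fit_total <- fit_agb_edge_model(agb_edge_eq, structure_extent)
  # allometry component: paired per-plot differences on edge plots
  d_allo <- agb_int_eq$agb[is_edge] - agb_edge_eq$agb[is_edge]
  se_allo <- stats::sd(d_allo) / sqrt(length(d_allo))
  z <- stats::qnorm(0.975)
  structure(list(
    mean_agb_interior = m_interior,
    mean_agb_edge_interior_eq = m_edge_int,
    mean_agb_edge_edge_eq = m_edge_edge,
    structure_component = structure_component,
    allometry_component = allometry_component,
    total_effect = structure_component + allometry_component,
    ci95 = list(
      interior = fit_structure$ci_interior,
      edge_interior_eq = fit_structure$ci_edge,
      edge_edge_eq = fit_total$ci_edge,
      structure_component = -rev(fit_structure$ci_effect),
      allometry_component = mean(d_allo) + c(-1, 1) * z * se_allo,
      total_effect = -rev(fit_total$ci_effect)),
    se = list(structure_component = fit_structure$se,
              allometry_component = se_allo,
              total_effect = fit_total$se),
    n_edge = sum(is_edge), n_interior = sum(!is_edge),
    fit_structure = fit_structure, fit_total = fit_total),
    class = "agb_decomposition")
}

#' @export
print.agb_decomposition <- function(x, ...) {
  cat("<agb_decomposition> (Mg ha^-1; positive = loss at the edge)\n")
  cat("  interior AGB:            ", round(x$mean_agb_interior, 1), "\n")
  cat("  edge AGB (interior eq):  ", round(x$mean_agb_edge_interior_eq, 1),
      "\n")
  cat("  edge AGB (edge eq rule): ", round(x$mean_agb_edge_edge_eq, 1),
      "\n")
  cat("  structure component:     ", round(x$structure_component, 1), "\n")
  cat("  allometry component:     ", round(x$allometry_component, 1), "\n")
  cat("  total edge effect:       ", round(x$total_effect, 1), "\n")
  invisible(x)
}
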