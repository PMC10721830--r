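#' Parameters for the synthetic stand generator
#'
#' Bundles every knob of the stand generator with defaults emulating the
#' statistical structure of a fragmented-forest TLS campaign: two sites,
#' fragments of 1/10/100 ha whose maximum interior distance is 50/100/500
#' m, trees nested in plots within fragments within sites, a tree-height
#' mixture of tall pre-fragmentation survivors and short colonising trees,
#' log-normal residuals around per-stratum power-law volume allometries
#' (defaults = the published interior/edge DBH-only coefficients), and
#' additive edge shifts on the architectural traits inside
#' `edge_extent_true`.
#'
#' @param n_trees number of trees (default 300).
#' @param edge_extent_true true edge-effect extent in metres (default 40).
#' @param shift_scale multiplier on all trait shifts: 0 = null stand
#'   (no edge effect), 1 = contrasts of the magnitude reported for
#'   fragmented Central Amazonian stands, 3 = strong shift for
#'   recovery simulations.
#' @param trait_params data frame of per-trait generating parameters
#'   (baseline, height slope, residual sd, edge shift); defaults via
#'   `default_trait_params()`.
#' @param p_survivor mixture weight of tall survivor trees (default 0.3).
#' @param allometry list with `interior` and `edge` coefficient vectors
#'   c(beta0, beta1) for ln V = beta0 + beta1 ln(DBH_m); defaults are the
#'   published interior (2.80, 1.97) and edge (2.45, 1.72) values.
#' @param residual_sd residual standard deviation of ln V (default 0.3).
#' @param re_sd named vector of random-intercept standard deviations on
#'   the ln V scale, c(site, fragment, plot) (default 0.05/0.05/0.10).
#' @param re_frac random-intercept sd for each trait, as a fraction of
#'   that trait's residual sd, c(site, fragment, plot) (default
#'   0.3/0.3/0.5).
#' @param n_sites,n_fragments,n_plots nesting sizes (defaults 2 sites, 4
#'   fragments, 12 plots; fragments cycle through sizes 1/10/100 ha).
#' @param seed integer seed.
#' @return A list of class `stand_params`.
#' @export
stand_params <- function(n_trees = 300, edge_extent_true = 40,
                         shift_scale = 1,
                         trait_params = default_trait_params(),
                         p_survivor = 0.3,
                         allometry = list(
                           interior = published_coefficients("eq3")[1:2],
                           edge = published_coefficients("eq4")[1:2]),
                         residual_sd = 0.3,
                         re_sd = c(site = 0.05, fragment = 0.05,
                                   plot = 0.10),
                         re_frac = c(site = 0.3, fragment = 0.3,
                                     plot = 0.5),
                         n_sites = 2, n_fragments = 4, n_plots = 12,
                         seed = 20191980) {
  stopifnot(n_trees >= 0, edge_extent_true >= 1, edge_extent_true <= 100,
            all(re_sd >= 0), all(re_frac >= 0), residual_sd >= 0,
            shift_scale >= 0, n_sites >= 1, n_fragments >= n_sites,
            n_plots >= n_fragments)
  structure(list(n_trees = n_trees, edge_extent_true = edge_extent_true,
                 shift_scale = shift_scale, trait_params = trait_params,
                 p_survivor = p_survivor, allometry = allometry,
                 residual_sd = residual_sd, re_sd = re_sd,
                 re_frac = re_frac, n_sites = n_sites,
                 n_fragments = n_fragments, n_plots = n_plots,
                 seed = as.integer(seed)), class = "stand_params")
}

#' Per-trait generating parameters of the synthetic stand
#'
#' Baselines, height slopes, residual standard deviations and edge shifts
#' for the six architectural traits. Shift directions mirror the reported
#' short-tree edge contrasts: thicker branches and trunks (lower surface
#' area per unit volume), higher asymmetry and path fraction, deeper but
#' relatively narrower crowns near the margin.
#'
#' @return data frame with columns `trait`, `baseline`, `slope_height`,
#'   `sd`, `shift`, `lower`, `upper`.
#' @export
default_trait_params <- function() {
  data.frame(
    trait = c("sa_per_vol_branch", "sa_per_vol_trunk", "path_fraction",
              "asymmetry", "relative_crown_depth", "relative_crown_width"),
    baseline = c(300, 85, 0.55, 2.2, 0.52, 0.53),
    slope_height = c(-6, -2.2, 0.004, 0.25, 0, 0),
    sd = c(40, 10, 0.06, 0.8, 0.10, 0.10),
    shift = c(-80, -8, 0.05, 0.8, 0.12, -0.08),
    lower = c(1, 1, 0.01, 0, 0.01, 0.01),
    upper = c(Inf, Inf, 0.999, Inf, 0.999, Inf),
    stringsAsFactors = FALSE)
}

# fragment sizes cycle 1/10/100 ha; the maximum distance from the margin
# is tied to the size as in the field layout
fragment_layout <- function(n_sites, n_fragments, n_plots) {
  sizes <- rep_len(c(1, 10, 100), n_fragments)
  max_dist <- c(`1` = 50, `10` = 100, `100` = 500)[as.character(sizes)]
  frag_site <- rep_len(seq_len(n_sites), n_fragments)
  plot_frag <- rep_len(seq_len(n_fragments), n_plots)
  data.frame(plot = paste0("P", seq_len(n_plots)),
             fragment = paste0("F", plot_frag),
             site = paste0("S", frag_site[plot_frag]),
             fragment_size = sizes[plot_frag],
             max_dist = unname(max_dist[plot_frag]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic stand of trees with known ground truth
#'
#' Draws a stand of trees with nested site/fragment/plot labels,
#' continuous distances to the forest margin, tree heights from a
#' survivor/colonising mixture, DBH from a height-diameter relation, woody
#' volume from the per-stratum power law (edge stratum = trees closer
#' than `edge_extent_true`) with log-normal residuals and nested random
#' intercepts, and all six architectural traits with additive edge shifts
#' inside the true extent. Every draw is reproducible from
#' `params$seed`.
#'
#' @param params a [stand_params()] object.
#' @return list with `trees` (data frame: tree_id, site, fragment, plot,
#'   fragment_size, distance_to_edge, height, dbh (cm), volume (m^3), the
#'   six trait columns, establishment) and `ground_truth` (list: the
#'   generating parameters plus the random intercepts drawn per level).
#' @export
generate_stand <- function(params) {
  stopifnot(inherits(params, "stand_params"))
  set.seed(params$seed)
  layout <- fragment_layout(params$n_sites, params$n_fragments,
                            params$n_plots)
  tp <- params$trait_params
  # random intercepts: ln-volume scale and per-trait scale
  sites <- unique(layout$site); frags <- unique(layout$fragment)
  u <- list(
    lnv = list(site = stats::setNames(stats::rnorm(length(sites), 0,
                                                   params$re_sd["site"]),
                                      sites),
               fragment = stats::setNames(
                 stats::rnorm(length(frags), 0,
                              params$re_sd["fragment"]), frags),
               plot = stats::setNames(
                 stats::rnorm(nrow(layout), 0, params$re_sd["plot"]),
                 layout$plot)))
  for (k in seq_len(nrow(tp))) {
    tr <- tp$trait[k]
    u[[tr]] <- list(
      site = stats::setNames(
        stats::rnorm(length(sites), 0,
                     params$re_frac["site"] * tp$sd[k]), sites),
      fragment = stats::setNames(
        stats::rnorm(length(frags), 0,
                     params$re_frac["fragment"] * tp$sd[k]), frags),
      plot = stats::setNames(
        stats::rnorm(nrow(layout), 0,
                     params$re_frac["plot"] * tp$sd[k]), layout$plot))
  }
  n <- params$n_trees
  if (n == 0L) {
    return(list(trees = empty_stand_table(tp$trait),
                ground_truth = list(params = params, intercepts = u,
                                    layout = layout)))
  }
  pidx <- sample.int(nrow(layout), n, replace = TRUE)
  dist <- stats::runif(n, 0, layout$max_dist[pidx])
  survivor <- stats::runif(n) < params$p_survivor
  height <- ifelse(
    survivor,
    pmin(pmax(stats::rlnorm(n, log(26), 0.15), 20.5), 35.8),
    pmin(pmax(stats::rlnorm(n, log(11), 0.35), 5), 19.5))
  dbh_cm <- exp((log(height) - 0.9) / 0.62 + stats::rnorm(n, 0, 0.15))
  dbh_m <- dbh_cm / 100
  edge <- dist < params$edge_extent_true
  co <- params$allometry
  lnv <- ifelse(edge,
                co$edge[1] + co$edge[2] * log(dbh_m),
                co$interior[1] + co$interior[2] * log(dbh_m)) +
    u$lnv$site[layout$site[pidx]] +
    u$lnv$fragment[layout$fragment[pidx]] +
    u$lnv$plot[layout$plot[pidx]] +
    stats::rnorm(n, 0, params$residual_sd)
  out <- data.frame(
    tree_id = sprintf("T%04d", seq_len(n)),
    site = layout$site[pidx], fragment = layout$fragment[pidx],
    plot = layout$plot[pidx], fragment_size = layout$fragment_size[pidx],
    distance_to_edge = dist, height = height, dbh = dbh_cm,
    volume = exp(lnv), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tp))) {
    tr <- tp$trait[k]
    val <- tp$baseline[k] + tp$slope_height[k] * (height - 15) +
      u[[tr]]$site[out$site] + u[[tr]]$fragment[out$fragment] +
      u[[tr]]$plot[out$plot] +
      params$shift_scale * tp$shift[k] * edge +
      stats::rnorm(n, 0, tp$sd[k])
    out[[tr]] <- pmin(pmax(val, tp$lower[k]), tp$upper[k])
  }
  out$establishment <- classify_establishment(out$height)
  rownames(out) <- NULL
  list(trees = out,
       ground_truth = list(params = params, intercepts = u,
                           layout = layout))
}

empty_stand_table <- function(trait_names) {
  base <- data.frame(tree_id = character(0), site = character(0),
                     fragment = character(0), plot = character(0),
                     fragment_size = numeric(0),
                     distance_to_edge = numeric(0), height = numeric(0),
                     dbh = numeric(0), volume = numeric(0),
                     stringsAsFactors = FALSE)
  for (tr in trait_names) base[[tr]] <- numeric(0)
  base$establishment <- character(0)
  base
}

#' Generate a synthetic QSM tree of a given architectural archetype
#'
#' Builds a single tree as a stochastic recursive branching process over
#' cylinders. The four archetypes contrast edge and interior conditions
#' for short colonising and tall surviving trees: `edge_short` trees get
#' thicker branches (lower branch surface area per unit volume), a
#' one-sided azimuth bias (higher asymmetry) and a co-dominant basal split
#' (crown base near the ground, deep crown); `edge_tall` trees are
#' shorter for their diameter with shorter branch chains (reduced maximum
#' path). The construction aims at controllable trait contrasts, not
#' botanical realism.
#'
#' @param archetype one of `"edge_short"`, `"interior_short"`,
#'   `"edge_tall"`, `"interior_tall"`.
#' @param params optional overrides: list with any of `height` (m),
#'   `p_branch` (branching probability per trunk node, default 0.9; 0
#'   gives an unbranched stem), `branch_thickness` (radius multiplier),
#'   `azimuth_bias` (0 = uniform azimuths, 1 = all branches on one side),
#'   `n_trunk_segments` (default 10), `max_order` (default 3).
#' @param seed integer seed; the cylinder table is bit-identical for a
#'   given archetype, params and seed.
#' @param tree_id,plot_id,site,fragment_size,distance_to_edge metadata
#'   passed to [qsm_tree()].
#' @return A valid [qsm_tree()].
#' @export
generate_qsm_tree <- function(archetype = c("edge_short", "interior_short",
                                            "edge_tall", "interior_tall"),
                              params = list(), seed = 1L,
                              tree_id = paste0(archetype, "_", seed),
                              plot_id = NA_character_,
                              site = NA_character_,
                              fragment_size = NA_real_,
                              distance_to_edge = NA_real_) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  short <- grepl("short", archetype)
  edge <- grepl("edge", archetype)
  p <- list(
    height = if (short) stats::runif(1, 8, 14) else
      stats::runif(1, 24, 32) * (if (edge) 0.85 else 1),
    p_branch = 0.9,
    branch_thickness = if (edge && short) 1.6 else 1.0,
    azimuth_bias = if (edge) 0.85 else 0,
    n_trunk_segments = 10L,
    max_order = 3L,
    basal_split = edge && short,
    branch_len_factor = if (edge && !short) 0.55 else 1.0,
    crown_base_frac = if (edge && short) 0.05 else 0.45)
  p[names(params)] <- params
  H <- p$height
  r0 <- 0.004 * H^1.25          # basal radius from height (m)
  main_azimuth <- stats::runif(1, 0, 2 * pi)

  rows <- list()
  next_id <- 0L
  add_cyl <- function(parent_id, start, axis, length, radius,
                      branch_order, branch_id) {
    next_id <<- next_id + 1L
    rows[[next_id]] <<- data.frame(
      cyl_id = next_id, parent_id = parent_id,
      start_x = start[1], start_y = start[2], start_z = start[3],
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
      length = length, radius = radius,
      branch_order = branch_order, branch_id = branch_id)
    next_id
  }
  unit <- function(v) v / sqrt(sum(v^2))
  branch_counter <- 0L

  # a branch: a chain of shrinking cylinders with optional sub-branches
  grow_branch <- function(parent_id, start, radius, order, length0) {
    branch_counter <<- branch_counter + 1L
    bid <- branch_counter
    azim <- if (stats::runif(1) < p$azimuth_bias) {
      main_azimuth + stats::rnorm(1, 0, 0.3)
    } else stats::runif(1, 0, 2 * pi)
    zen <- stats::runif(1, 0.6, 1.2)  # zenith angle from vertical (rad)
    axis <- unit(c(sin(zen) * cos(azim), sin(zen) * sin(azim), cos(zen)))
    n_seg <- 3L
    pos <- start; pid <- parent_id; r <- radius; len <- length0
    for (s in seq_len(n_seg)) {
      pid <- add_cyl(pid, pos, axis, len, r, order, bid)
      pos <- pos + axis * len
      if (order < p$max_order && stats::runif(1) < 0.5)
        grow_branch(pid, pos, r * 0.6, order + 1L, len * 0.7)
      axis <- unit(axis + stats::rnorm(3, 0, 0.15))
      r <- r * 0.7
      len <- len * 0.8
    }
    invisible(NULL)
  }

  # trunk: near-vertical chain with linear taper
  nseg <- p$n_trunk_segments
  seg_len <- H / nseg
  radii <- r0 * seq(1, 0.15, length.out = nseg)
  pos <- c(0, 0, 0); pid <- NA_integer_
  crown_start <- max(1L, ceiling(p$crown_base_frac * nseg))
  for (s in seq_len(nseg)) {
    axis <- unit(c(stats::rnorm(2, 0, 0.02), 1))
    pid <- add_cyl(pid, pos, axis, seg_len, radii[s], 0L, 0L)
    pos <- pos + axis * seg_len
    if (p$basal_split && s == 1L && p$p_branch > 0) {
      # co-dominant second stem from near the ground
      branch_counter <- branch_counter + 1L
      azim <- main_azimuth
      axis2 <- unit(c(0.35 * cos(azim), 0.35 * sin(azim), 1))
      pos2 <- pos; pid2 <- pid; r2 <- radii[s] * 0.8
      len2 <- seg_len * 0.9
      for (ss in seq_len(nseg - 1L)) {
        pid2 <- add_cyl(pid2, pos2, axis2, len2, r2, 1L, branch_counter)
        pos2 <- pos2 + axis2 * len2
        if (ss >= crown_start && stats::runif(1) < p$p_branch)
          grow_branch(pid2, pos2,
                      r2 * 0.4 * p$branch_thickness, 2L,
                      seg_len * 0.8 * p$branch_len_factor)
        axis2 <- unit(axis2 + c(stats::rnorm(2, 0, 0.05), 0.02))
        r2 <- r2 * 0.82
      }
    }
    if (s >= crown_start && s < nseg && stats::runif(1) < p$p_branch)
      grow_branch(pid, pos, radii[s] * 0.4 * p$branch_thickness, 1L,
                  seg_len * 0.9 * p$branch_len_factor)
  }
  cyl <- do.call(rbind, rows)
  qsm_tree(cyl, tree_id = tree_id, plot_id = plot_id, site = site,
           fragment_size = fragment_size,
           distance_to_edge = distance_to_edge)
}

#' Parameters for the synthetic census generator
#'
#' @param n_plots total number of 1-ha plots (default 44).
#' @param n_edge_plots plots within 100 m of the margin (default 28).
#' @param n_sites number of forest sites (default 4).
#' @param stems_per_ha expected stem density of interior plots
#'   (default 275, giving about 12,000 stems over 44 ha).
#' @param dbh_rate rate of the exponential DBH excess above the 10 cm
#'   census threshold (default 1/16.3, i.e. mean DBH about 26 cm),
#'   producing the reverse-J size distribution of natural uneven-aged
#'   stands; at the default stem density this sizes interior plots near
#'   the 282 Mg ha^-1 biomass typical of intact Central Amazonian
#'   forest.
#' @param edge_density_factor multiplier on expected stem density in edge
#'   plots (default 0.93: edge structure loss of about 7% of stems,
#'   matching the relative AGB deficit attributed to structure in
#'   fragmented Central Amazonian stands; 1 disables the structure
#'   effect).
#' @param seed integer seed.
#' @return list of class `census_params`.
#' @export
census_params <- function(n_plots = 44, n_edge_plots = 28, n_sites = 4,
                          stems_per_ha = 275, dbh_rate = 1 / 16.3,
                          edge_density_factor = 0.93, seed = 20191980) {
  stopifnot(n_plots >= 4, n_edge_plots >= 2, n_edge_plots <= n_plots - 2,
            stems_per_ha > 0, dbh_rate > 0, edge_density_factor > 0)
  structure(list(n_plots = n_plots, n_edge_plots = n_edge_plots,
                 n_sites = n_sites, stems_per_ha = stems_per_ha,
                 dbh_rate = dbh_rate,
                 edge_density_factor = edge_density_factor,
                 seed = as.integer(seed)), class = "census_params")
}

#' Generate a synthetic plot census with a reverse-J size distribution
#'
#' Draws 1-ha plots split between edge (margin distance < 100 m) and
#' interior, Poisson stem counts per plot (edge density scaled by
#' `edge_density_factor`), DBH as 10 cm plus an exponential excess
#' (monotonically decreasing size density, truncated at the 10 cm census
#' threshold), and taxa sampled from the bundled synthetic wood-density
#' fixture, with a fraction of stems identified only to genus or family
#' to exercise the density fallback. Deterministic given the seed.
#'
#' @param params a [census_params()] object.
#' @return list with `census` (stem_id, plot_id, dbh_cm, family, genus,
#'   species), `plots` (plot_id, site, area_ha, distance_to_edge_m),
#'   `wd_table` (a [wood_density_table()]) and `ground_truth` (the
#'   parameters).
#' @export
generate_census <- function(params = census_params()) {
  stopifnot(inherits(params, "census_params"))
  set.seed(params$seed)
  taxa <- synthetic_wood_density_records()
  n_int <- params$n_plots - params$n_edge_plots
  plots <- data.frame(
    plot_id = sprintf("PL%02d", seq_len(params$n_plots)),
    site = paste0("Site", rep_len(seq_len(params$n_sites),
                                  params$n_plots)),
    area_ha = 1,
    distance_to_edge_m = c(stats::runif(params$n_edge_plots, 5, 95),
                           stats::runif(n_int, 150, 500)),
    stringsAsFactors = FALSE)
  dens <- ifelse(plots$distance_to_edge_m < 100,
                 params$stems_per_ha * params$edge_density_factor,
                 params$stems_per_ha)
  n_stems <- stats::rpois(params$n_plots, dens * plots$area_ha)
  total <- sum(n_stems)
  tax_idx <- sample.int(nrow(taxa), total, replace = TRUE)
  census <- data.frame(
    stem_id = sprintf("ST%05d", seq_len(total)),
    plot_id = rep(plots$plot_id, n_stems),
    dbh_cm = 10 + stats::rexp(total, params$dbh_rate),
    family = taxa$family[tax_idx],
    genus = taxa$genus[tax_idx],
    species = taxa$species[tax_idx],
    stringsAsFactors = FALSE)
  # some stems only identified to genus (blank species) or family
  to_genus <- stats::runif(total) < 0.10
  census$species[to_genus] <- ""
  to_family <- stats::runif(total) < 0.02
  census$genus[to_family] <- "Indet"
  census$species[to_family] <- ""
  list(census = census, plots = plots,
       wd_table = wood_density_table(taxa),
       ground_truth = list(params = params))
}

#' Bundled synthetic wood-density records
#'
#' Reads the synthetic taxon-to-density fixture shipped with the package
#' (30 common Amazonian taxa with plausible but invented densities; not a
#' published database).
#'
#' @return data frame with columns `family`, `genus`, `species`,
#'   `wd_g_cm3`.
#' @export
synthetic_wood_density_records <- function() {
  path <- system.file("extdata", "wood_density_synthetic.csv",
                      package = "fragarch", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
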