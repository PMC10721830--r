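#' Surface area per unit woody volume
#'
#' Ratio of lateral surface area to woody volume of a compartment
#' (m^2 m^-3). High values indicate thin trunks or branches: for cylinders
#' of common radius r the ratio is exactly 2/r regardless of topology.
#'
#' @param tree a [qsm_tree()].
#' @param compartment `"trunk"` or `"branch"`.
#' @return Ratio in m^2 m^-3.
#' @export
surface_area_per_volume <- function(tree, compartment = c("trunk", "branch")) {
  compartment <- match.arg(compartment)
  if (nrow(compartment_rows(tree, compartment)) == 0L)
    stop("no branches: tree '", tree$tree_id, "' has an empty ",
         compartment, " compartment")
  surface_area(tree, compartment) / woody_volume(tree, compartment)
}

#' Path fraction
#'
#' Mean root-to-tip path length divided by the maximum root-to-tip path
#' length. Equals 1 when all tips lie at the same path distance from the
#' base (an unbranched stem or perfectly symmetric crown); values near 1
#' indicate umbrella-shaped crowns with many tips at near-maximal path
#' length.
#'
#' @param tree a [qsm_tree()].
#' @return Dimensionless value in (0, 1].
#' @export
path_fraction <- function(tree) {
  p <- root_to_tip_paths(tree)
  mean(p) / max(p)
}

#' Crown asymmetry
#'
#' Displacement of wood allocation relative to the vertical axis through
#' the stem base. The default (and currently only) method returns the
#' horizontal (xy) distance between the woody-volume-weighted centroid of
#' cylinder midpoints and the base start point, in metres. A perfectly
#' vertical unbranched stem scores 0; the value is invariant under rotation
#' about the vertical axis through the base and scales linearly with
#' uniform spatial scaling.
#'
#' @param tree a [qsm_tree()].
#' @param method asymmetry definition; only `"centroid_offset"` is
#'   implemented. The argument exists so alternative published definitions
#'   can be added without changing call sites.
#' @return Asymmetry in metres (>= 0).
#' @export
asymmetry <- function(tree, method = c("centroid_offset")) {
  method <- match.arg(method)
  cyl <- tree$cylinders
  w <- pi * cyl$radius^2 * cyl$length
  mx <- cyl$start_x + cyl$axis_x * cyl$length / 2
  my <- cyl$start_y + cyl$axis_y * cyl$length / 2
  base <- which(is.na(cyl$parent_id))
  cx <- sum(w * mx) / sum(w) - cyl$start_x[base]
  cy <- sum(w * my) / sum(w) - cyl$start_y[base]
  sqrt(cx^2 + cy^2)
}

#' Crown base height
#'
#' Vertical height above the base of the lowest point at which the tree
#' crown starts. The crown is taken to begin at the lowest multi-stemming
#' point: an attachment where a parent supports two or more children whose
#' radii are each at least `codominance_ratio` times the parent radius.
#' If no such co-dominant split exists, the lowest attachment of any
#' branch (`branch_order >= 1` cylinder whose parent has a lower order)
#' is used instead.
#'
#' @param tree a [qsm_tree()].
#' @param codominance_ratio minimum child/parent radius ratio for a split
#'   to count as multi-stemming (default 0.5).
#' @return Height of the crown base above the tree base, in metres.
#' @export
crown_base_height <- function(tree, codominance_ratio = 0.5) {
  cyl <- tree$cylinders
  idx <- match(cyl$parent_id, cyl$cyl_id)
  base_z <- cyl$start_z[is.na(idx)]
  kids <- cyl_children(cyl)
  split_z <- numeric(0)
  for (p in names(kids)) {
    ch <- kids[[p]]
    pr <- cyl$radius[as.integer(p)]
    big <- ch[cyl$radius[ch] >= codominance_ratio * pr]
    if (length(big) >= 2L)
      split_z <- c(split_z, min(cyl$start_z[big]))
  }
  if (length(split_z)) return(min(split_z) - base_z)
  first_branch <- which(!is.na(idx) & cyl$branch_order > 0L &
                          cyl$branch_order > cyl$branch_order[idx])
  if (!length(first_branch))
    stop("no crown: tree '", tree$tree_id, "' is unbranched")
  min(cyl$start_z[first_branch]) - base_z
}

#' Relative crown depth
#'
#' Vertical crown size relative to tree height:
#' `(tree_height - crown_base_height) / tree_height`, in m m^-1, bounded
#' in \[0, 1\]. Multi-stemming from the ground gives the deepest possible
#' crown (1).
#'
#' @inheritParams crown_base_height
#' @return Relative crown depth in \[0, 1\].
#' @export
relative_crown_depth <- function(tree, codominance_ratio = 0.5) {
  h <- tree_height(tree)
  (h - crown_base_height(tree, codominance_ratio)) / h
}

#' Relative crown width
#'
#' Horizontal crown size relative to stem diameter: crown width in metres
#' divided by DBH in centimetres (m cm^-1). Crown width is the maximum
#' horizontal (xy) distance between any two endpoints (start or end) of
#' crown cylinders, where crown cylinders are those starting at or above
#' the crown base height.
#'
#' @inheritParams crown_base_height
#' @return Relative crown width in m cm^-1.
#' @export
relative_crown_width <- function(tree, codominance_ratio = 0.5) {
  cbh <- crown_base_height(tree, codominance_ratio)
  d <- dbh(tree)
  cyl <- tree$cylinders
  base_z <- cyl$start_z[is.na(cyl$parent_id)]
  in_crown <- cyl$start_z - base_z >= cbh - 1e-9
  cc <- cyl[in_crown, , drop = FALSE]
  pts <- rbind(cbind(cc$start_x, cc$start_y),
               cyl_endpoints(cc)[, c("x", "y"), drop = FALSE])
  crown_width(pts) / d
}

# maximum pairwise horizontal distance; O(n) via convex hull diameter
crown_width <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  hull <- unique(grDevices::chull(pts[, 1], pts[, 2]))
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) < 2L) return(0)
  max(stats::dist(hp))
}

#' Classify tree establishment epoch by height
#'
#' In a forest fragmented several decades ago, trees taller than a height
#' threshold must have established before fragmentation and thus survived
#' the edge effects; most shorter trees are post-fragmentation recruits.
#' The default threshold is 20 m. The comparison is strict: a tree exactly
#' at the threshold is classified `short_tree`.
#'
#' @param height tree height(s) in metres, all > 0.
#' @param threshold height threshold in metres (default 20).
#' @return Character vector: `"survivor"` or `"short_tree"`.
#' @export
classify_establishment <- function(height, threshold = 20) {
  if (any(!is.finite(height) | height <= 0))
    stop("height must be positive and finite")
  ifelse(height > threshold, "survivor", "short_tree")
}

#' Compute the architectural trait table for a collection of trees
#'
#' Applies branch trimming and then computes all architectural traits for
#' each tree: height, DBH, woody volume, trunk and branch surface area per
#' unit volume, path fraction, asymmetry, relative crown depth and width,
#' and the establishment class. Trees without a crown or without branches
#' get `NA` in the affected columns with a warning rather than aborting
#' the pipeline; downstream models drop incomplete cases per trait.
#'
#' @param trees list of [qsm_tree()] objects with unique `tree_id`s.
#' @param trim diameter threshold in metres passed to
#'   [trim_small_branches()] (default 0.02; use 0 to disable).
#' @param establishment_threshold height threshold in metres for
#'   [classify_establishment()].
#' @param codominance_ratio passed to the crown operations.
#' @return A data frame with one row per tree: `tree_id`, `plot_id`,
#'   `site`, `fragment_size`, `distance_to_edge`, `height`, `dbh`,
#'   `woody_volume`, `sa_per_vol_trunk`, `sa_per_vol_branch`,
#'   `path_fraction`, `asymmetry`, `relative_crown_depth`,
#'   `relative_crown_width`, `establishment`.
#' @export
compute_trait_table <- function(trees, trim = 0.02,
                                establishment_threshold = 20,
                                codominance_ratio = 0.5) {
  ids <- vapply(trees, function(t) t$tree_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate tree_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(trees, function(tr) {
    if (trim > 0) tr <- trim_small_branches(tr, trim)
    na_or <- function(expr) tryCatch(expr, error = function(e) {
      warning("tree '", tr$tree_id, "': ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    h <- tree_height(tr)
    data.frame(
      tree_id = tr$tree_id, plot_id = tr$plot_id, site = tr$site,
      fragment_size = tr$fragment_size,
      distance_to_edge = tr$distance_to_edge,
      height = h,
      dbh = na_or(dbh(tr)),
      woody_volume = woody_volume(tr),
      sa_per_vol_trunk = na_or(surface_area_per_volume(tr, "trunk")),
      sa_per_vol_branch = na_or(surface_area_per_volume(tr, "branch")),
      path_fraction = path_fraction(tr),
      asymmetry = asymmetry(tr),
      relative_crown_depth = na_or(
        relative_crown_depth(tr, codominance_ratio)),
      relative_crown_width = na_or(
        relative_crown_width(tr, codominance_ratio)),
      establishment = classify_establishment(h, establishment_threshold),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(empty_trait_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_trait_table <- function() {
  data.frame(tree_id = character(0), plot_id = character(0),
             site = character(0), fragment_size = numeric(0),
             distance_to_edge = numeric(0), height = numeric(0),
             dbh = numeric(0), woody_volume = numeric(0),
             sa_per_vol_trunk = numeric(0), sa_per_vol_branch = numeric(0),
             path_fraction = numeric(0), asymmetry = numeric(0),
             relative_crown_depth = numeric(0),
             relative_crown_width = numeric(0),
             establishment = character(0), stringsAsFactors = FALSE)
}
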