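#' Construct a quantitative structure model (QSM) of a single tree
#'
#' A QSM represents the woody structure of one tree as a rooted hierarchy of
#' geometric cylinders. Each cylinder has a start point, a unit axis
#' direction, a length and a radius; parent references encode the branching
#' topology. Exactly one cylinder (the base) has no parent.
#'
#' @param cylinders data frame with columns `cyl_id`, `parent_id` (NA for the
#'   base cylinder), `start_x`, `start_y`, `start_z`, `axis_x`, `axis_y`,
#'   `axis_z`, `length`, `radius` (all metres), `branch_order` (0 = trunk)
#'   and `branch_id`.
#' @param tree_id character scalar identifying the tree.
#' @param plot_id,site character metadata labels.
#' @param fragment_size fragment size in hectares (optional, `NA` allowed).
#' @param distance_to_edge distance from the tree to the nearest forest
#'   margin in metres (>= 0, `NA` allowed).
#'
#' @return An object of class `qsm_tree`: a list with elements `tree_id`,
#'   `plot_id`, `site`, `fragment_size`, `distance_to_edge` and `cylinders`.
#' @export
#' @examples
#' cyl <- data.frame(cyl_id = 1L, parent_id = NA_integer_,
#'                   start_x = 0, start_y = 0, start_z = 0,
#'                   axis_x = 0, axis_y = 0, axis_z = 1,
#'                   length = 10, radius = 0.15,
#'                   branch_order = 0L, branch_id = 1L)
#' tr <- qsm_tree(cyl, tree_id = "t1")
#' tree_height(tr)
qsm_tree <- function(cylinders, tree_id, plot_id = NA_character_,
                     site = NA_character_, fragment_size = NA_real_,
                     distance_to_edge = NA_real_) {
  stopifnot(is.data.frame(cylinders), length(tree_id) == 1L)
  cylinders <- as.data.frame(cylinders)
  validate_cylinders(cylinders)
  out <- structure(
    list(tree_id = as.character(tree_id),
         plot_id = as.character(plot_id),
         site = as.character(site),
         fragment_size = as.numeric(fragment_size),
         distance_to_edge = as.numeric(distance_to_edge),
         cylinders = cylinders[order(cylinders$cyl_id), , drop = FALSE]),
    class = "qsm_tree")
  rownames(out$cylinders) <- NULL
  out
}

QSM_COLS <- c("cyl_id", "parent_id", "start_x", "start_y", "start_z",
              "axis_x", "axis_y", "axis_z", "length", "radius",
              "branch_order", "branch_id")

# Structural validation of a cylinder table. Stops with an informative error
# listing the offending cyl_ids on the first violated invariant.
validate_cylinders <- function(cyl) {
  missing_cols <- setdiff(QSM_COLS, names(cyl))
  if (length(missing_cols))
    stop("cylinder table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cyl) < 1L) stop("a QSM must contain at least one cylinder")
  if (anyDuplicated(cyl$cyl_id))
    stop("duplicate cyl_id: ",
         paste(unique(cyl$cyl_id[duplicated(cyl$cyl_id)]), collapse = ", "))
  bad <- cyl$cyl_id[!(cyl$length > 0) | !(cyl$radius > 0)]
  if (length(bad))
    stop("non-positive length or radius for cyl_id: ",
         paste(bad, collapse = ", "))
  nrm <- sqrt(cyl$axis_x^2 + cyl$axis_y^2 + cyl$axis_z^2)
  bad <- cyl$cyl_id[abs(nrm - 1) > 1e-6]
  if (length(bad))
    stop("axis not unit length for cyl_id: ", paste(bad, collapse = ", "))
  if (any(cyl$branch_order < 0))
    stop("negative branch_order")
  base <- which(is.na(cyl$parent_id))
  if (length(base) != 1L)
    stop("exactly one base cylinder (parent_id = NA) required, found ",
         length(base))
  idx <- match(cyl$parent_id, cyl$cyl_id)
  orphan <- cyl$cyl_id[!is.na(cyl$parent_id) & is.na(idx)]
  if (length(orphan))
    stop("parent_id not found for cyl_id: ", paste(orphan, collapse = ", "))
  # rooted-tree check: every cylinder must reach the base by parent hops
  n <- nrow(cyl)
  depth <- rep(NA_integer_, n)
  depth[base] <- 0L
  for (pass in seq_len(n)) {
    newly <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(newly)) break
    depth[newly] <- depth[idx[newly]] + 1L
  }
  if (anyNA(depth))
    stop("cycle or disconnected cylinders: cyl_id ",
         paste(cyl$cyl_id[is.na(depth)], collapse = ", "))
  bad <- cyl$cyl_id[!is.na(cyl$parent_id) &
                      cyl$branch_order < cyl$branch_order[idx]]
  if (length(bad))
    stop("branch_order lower than parent for cyl_id: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.qsm_tree <- function(x, ...) {
  cat("<qsm_tree> ", x$tree_id, ": ", nrow(x$cylinders), " cylinders, ",
      "height ", round(tree_height(x), 2), " m, volume ",
      signif(woody_volume(x), 4), " m^3\n", sep = "")
  invisible(x)
}

#' Read a QSM cylinder table from CSV
#'
#' Reads the documented cylinder CSV dialect: columns
#' `cyl_id,parent_id,start_x,start_y,start_z,axis_x,axis_y,axis_z,length_m,
#' radius_m,branch_order,branch_id`, UTF-8, "." decimal separator, empty
#' `parent_id` for the base cylinder. One file holds one tree.
#'
#' @param path path to the CSV file.
#' @param metadata list or one-row data frame with optional fields
#'   `tree_id`, `plot_id`, `site`, `fragment_size`, `distance_to_edge`.
#'   Missing `tree_id` defaults to the file name without extension.
#' @return A validated [qsm_tree()].
#' @seealso [write_qsm_table()]
#' @export
read_qsm_table <- function(path, metadata = list()) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ""),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  file_cols <- c("cyl_id", "parent_id", "start_x", "start_y", "start_z",
                 "axis_x", "axis_y", "axis_z", "length_m", "radius_m",
                 "branch_order", "branch_id")
  missing_cols <- setdiff(file_cols, names(raw))
  if (length(missing_cols))
    stop("'", path, "' lacks columns: ", paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(file_cols, c("cyl_id", "parent_id", "branch_order",
                                   "branch_id"))
  for (cc in c(file_cols)) {
    v <- raw[[cc]]
    if (cc %in% num_cols) v <- suppressWarnings(as.numeric(v))
    else v <- suppressWarnings(as.integer(v))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad))
      stop("malformed value in column '", cc, "' of '", path,
           "' at data line ", bad[1L])
    raw[[cc]] <- v
  }
  names(raw)[names(raw) == "length_m"] <- "length"
  names(raw)[names(raw) == "radius_m"] <- "radius"
  md <- as.list(metadata)
  tree_id <- md$tree_id %||% sub("\\.[^.]*$", "", basename(path))
  qsm_tree(raw[QSM_COLS], tree_id = tree_id,
           plot_id = md$plot_id %||% NA_character_,
           site = md$site %||% NA_character_,
           fragment_size = md$fragment_size %||% NA_real_,
           distance_to_edge = md$distance_to_edge %||% NA_real_)
}

#' Write a QSM cylinder table to CSV
#'
#' Inverse of [read_qsm_table()]; writes the documented dialect so that a
#' read/write round trip preserves all fields.
#'
#' @param tree a [qsm_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qsm_table <- function(tree, path) {
  stopifnot(inherits(tree, "qsm_tree"))
  out <- tree$cylinders
  names(out)[names(out) == "length"] <- "length_m"
  names(out)[names(out) == "radius"] <- "radius_m"
  # full double precision so a read/write round trip is exact
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# children index: list mapping row -> integer vector of child rows
cyl_children <- function(cyl) {
  idx <- match(cyl$parent_id, cyl$cyl_id)
  split(seq_len(nrow(cyl))[!is.na(idx)], idx[!is.na(idx)])
}

# rows of the main stem: start at the base, follow the largest-radius
# branch_order-0 child at each step (handles co-dominant basal splits)
trunk_chain_rows <- function(cyl) {
  kids <- cyl_children(cyl)
  row <- which(is.na(cyl$parent_id))
  chain <- row
  repeat {
    ch <- kids[[as.character(row)]]
    ch <- ch[cyl$branch_order[ch] == 0L]
    if (!length(ch)) break
    row <- ch[which.max(cyl$radius[ch])]
    chain <- c(chain, row)
  }
  chain
}

#' Trim small branches from a QSM
#'
#' Removes every non-trunk cylinder thinner than a diameter threshold,
#' together with its whole subtree (branches are detached whole, so a thick
#' descendant under a thin parent is removed too). Trunk cylinders
#' (`branch_order == 0`) are never removed. QSMs fitted to laser point
#' clouds overestimate the size of the finest branches, so trimming below
#' 2 cm diameter is the conventional preprocessing step before computing
#' architectural traits.
#'
#' @param tree a [qsm_tree()].
#' @param min_diameter diameter threshold in metres (default 0.02, i.e. 2 cm).
#' @return The trimmed [qsm_tree()] (still a valid rooted tree).
#' @export
trim_small_branches <- function(tree, min_diameter = 0.02) {
  stopifnot(inherits(tree, "qsm_tree"))
  cyl <- tree$cylinders
  idx <- match(cyl$parent_id, cyl$cyl_id)
  drop <- cyl$branch_order > 0L & 2 * cyl$radius < min_diameter
  # propagate removal to descendants (parents come before children after
  # enough passes; iterate until fixed point)
  repeat {
    newly <- !drop & !is.na(idx) & drop[ifelse(is.na(idx), 1L, idx)]
    newly[is.na(idx)] <- FALSE
    if (!any(newly)) break
    drop <- drop | newly
  }
  tree$cylinders <- cyl[!drop, , drop = FALSE]
  rownames(tree$cylinders) <- NULL
  validate_cylinders(tree$cylinders)
  tree
}

# end points of every cylinder (start + axis * length)
cyl_endpoints <- function(cyl) {
  cbind(x = cyl$start_x + cyl$axis_x * cyl$length,
        y = cyl$start_y + cyl$axis_y * cyl$length,
        z = cyl$start_z + cyl$axis_z * cyl$length)
}

#' Tree height from a QSM
#'
#' Vertical extent of the tree: the maximum z over all cylinder start and
#' end points minus the z of the base cylinder's start point.
#'
#' @param tree a [qsm_tree()].
#' @return Height in metres (>= 0).
#' @export
tree_height <- function(tree) {
  stopifnot(inherits(tree, "qsm_tree"))
  cyl <- tree$cylinders
  base_z <- cyl$start_z[is.na(cyl$parent_id)]
  max(c(cyl$start_z, cyl_endpoints(cyl)[, "z"])) - base_z
}

#' Diameter at breast height (DBH) from a QSM
#'
#' Diameter of the main stem at 1.3 m from the base, measured along the
#' stem path (cumulative axial length, robust for leaning stems): returns
#' twice the radius of the trunk cylinder whose along-stem interval contains
#' 1.3 m. The trunk is the branch-order-0 chain from the base, following the
#' largest-radius child at co-dominant splits.
#'
#' @param tree a [qsm_tree()].
#' @param breast_height measurement position along the stem in metres
#'   (default 1.3).
#' @return DBH in centimetres.
#' @export
dbh <- function(tree, breast_height = 1.3) {
  stopifnot(inherits(tree, "qsm_tree"))
  cyl <- tree$cylinders
  chain <- trunk_chain_rows(cyl)
  cum <- cumsum(cyl$length[chain])
  if (cum[length(cum)] <= breast_height)
    stop("tree too short for DBH: stem length ",
         round(cum[length(cum)], 3), " m <= ", breast_height, " m")
  seg <- chain[which(cum > breast_height)[1L]]
  200 * cyl$radius[seg]
}

#' Woody volume of a QSM
#'
#' Sum of cylinder volumes pi * r^2 * L over the selected compartment.
#' The trunk compartment is `branch_order == 0`; branches are everything
#' else; `whole` equals `trunk + branch` exactly.
#'
#' @param tree a [qsm_tree()].
#' @param compartment one of `"whole"`, `"trunk"`, `"branch"`.
#' @return Volume in cubic metres.
#' @export
woody_volume <- function(tree, compartment = c("whole", "trunk", "branch")) {
  compartment <- match.arg(compartment)
  cyl <- compartment_rows(tree, compartment)
  sum(pi * cyl$radius^2 * cyl$length)
}

#' Woody surface area of a QSM
#'
#' Sum of lateral cylinder areas 2 * pi * r * L over the selected
#' compartment. End caps are excluded by convention; the definition only
#' matters as a consistent numerator for the area-per-volume traits.
#'
#' @inheritParams woody_volume
#' @return Surface area in square metres.
#' @export
surface_area <- function(tree, compartment = c("whole", "trunk", "branch")) {
  compartment <- match.arg(compartment)
  cyl <- compartment_rows(tree, compartment)
  sum(2 * pi * cyl$radius * cyl$length)
}

compartment_rows <- function(tree, compartment) {
  stopifnot(inherits(tree, "qsm_tree"))
  cyl <- tree$cylinders
  switch(compartment,
         whole = cyl,
         trunk = cyl[cyl$branch_order == 0L, , drop = FALSE],
         branch = cyl[cyl$branch_order > 0L, , drop = FALSE])
}

#' Root-to-tip path lengths
#'
#' Cumulative axial length from the base start point to the end of every
#' tip cylinder (a cylinder with no children), one entry per tip. Path
#' length is measured along the cylinder axes, not as Euclidean distance.
#'
#' @param tree a [qsm_tree()].
#' @return Numeric vector of path lengths in metres, one per tip.
#' @export
root_to_tip_paths <- function(tree) {
  stopifnot(inherits(tree, "qsm_tree"))
  cyl <- tree$cylinders
  idx <- match(cyl$parent_id, cyl$cyl_id)
  n <- nrow(cyl)
  # cumulative length to each cylinder's end, resolved in topological order
  cum <- rep(NA_real_, n)
  base <- which(is.na(idx))
  cum[base] <- cyl$length[base]
  repeat {
    ready <- which(is.na(cum) & !is.na(cum[idx]))
    if (!length(ready)) break
    cum[ready] <- cum[idx[ready]] + cyl$length[ready]
  }
  tips <- setdiff(seq_len(n), idx)
  cum[tips]
}
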