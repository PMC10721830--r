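# Fixture builders: small QSM trees constructed in code.

cyl_row <- function(cyl_id, parent_id, start, axis, length, radius,
                    branch_order, branch_id = branch_order) {
  axis <- axis / sqrt(sum(axis^2))
  data.frame(cyl_id = cyl_id, parent_id = parent_id,
             start_x = start[1], start_y = start[2], start_z = start[3],
             axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
             length = length, radius = radius,
             branch_order = branch_order, branch_id = branch_id)
}

# single vertical cylinder
single_cyl_tree <- function(length = 10, radius = 0.15,
                            axis = c(0, 0, 1), id = "single") {
  qsm_tree(cyl_row(1L, NA_integer_, c(0, 0, 0), axis, length, radius, 0L),
           tree_id = id)
}

# unbranched vertical stem of stacked cylinders
stacked_stem <- function(lengths, radii, id = "stem") {
  n <- length(lengths)
  z0 <- c(0, cumsum(lengths))[seq_len(n)]
  rows <- lapply(seq_len(n), function(i)
    cyl_row(i, if (i == 1L) NA_integer_ else i - 1L, c(0, 0, z0[i]),
            c(0, 0, 1), lengths[i], radii[i], 0L))
  qsm_tree(do.call(rbind, rows), tree_id = id)
}

# trunk with a Y split: two branches from the trunk top with given
# chain lengths (each branch is one cylinder here)
y_tree <- function(trunk_len = 2, branch_lens = c(1, 3),
                   branch_radii = c(0.05, 0.05), trunk_radius = 0.1,
                   id = "y") {
  rows <- list(cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1),
                       trunk_len, trunk_radius, 0L))
  for (i in seq_along(branch_lens)) {
    ax <- c(if (i == 1) 0.3 else -0.3, 0, 1)
    rows[[i + 1L]] <- cyl_row(i + 1L, 1L, c(0, 0, trunk_len), ax,
                              branch_lens[i], branch_radii[i], 1L, i)
  }
  qsm_tree(do.call(rbind, rows), tree_id = id)
}

# random valid tree for property tests: random topology, geometry, radii
random_tree <- function(seed, n = 40, id = paste0("rand", seed)) {
  set.seed(seed)
  rows <- list(cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1),
                       runif(1, 1, 3), runif(1, 0.1, 0.3), 0L))
  order_of <- c(0L)
  for (i in 2:n) {
    parent <- sample(i - 1L, 1L)
    po <- order_of[parent]
    o <- po + sample(0:1, 1L)
    ax <- rnorm(3); ax[3] <- abs(ax[3]) + 0.5
    prow <- rows[[parent]]
    start <- c(prow$start_x + prow$axis_x * prow$length,
               prow$start_y + prow$axis_y * prow$length,
               prow$start_z + prow$axis_z * prow$length)
    rows[[i]] <- cyl_row(i, parent, start, ax, runif(1, 0.2, 2),
                         runif(1, 0.005, 0.15), o, o)
    order_of[i] <- o
  }
  qsm_tree(do.call(rbind, rows), tree_id = id)
}

# brute-force descendant set of given cylinders (for trim oracle)
descendants_of <- function(cyl, ids) {
  out <- ids
  repeat {
    more <- cyl$cyl_id[!is.na(cyl$parent_id) & cyl$parent_id %in% out &
                         !(cyl$cyl_id %in% out)]
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

# rigid transform helpers for invariance tests
rotate_tree_z <- function(tree, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
              2, 2, byrow = TRUE)
  cyl <- tree$cylinders
  base <- c(cyl$start_x[is.na(cyl$parent_id)],
            cyl$start_y[is.na(cyl$parent_id)])
  s <- t(R %*% rbind(cyl$start_x - base[1], cyl$start_y - base[2]))
  a <- t(R %*% rbind(cyl$axis_x, cyl$axis_y))
  cyl$start_x <- s[, 1] + base[1]; cyl$start_y <- s[, 2] + base[2]
  cyl$axis_x <- a[, 1]; cyl$axis_y <- a[, 2]
  tree$cylinders <- cyl
  tree
}

scale_tree <- function(tree, k) {
  cyl <- tree$cylinders
  for (cc in c("start_x", "start_y", "start_z", "length", "radius"))
    cyl[[cc]] <- cyl[[cc]] * k
  tree$cylinders <- cyl
  tree
}

# statistical stand for model tests, bypassing the QSM layer
stand_traits <- function(seed, n = 300, shift_scale = 1,
                         edge_extent_true = 40, ...) {
  generate_stand(stand_params(n_trees = n, shift_scale = shift_scale,
                              edge_extent_true = edge_extent_true,
                              seed = seed, ...))$trees
}

# t-value of a term from an edge_model_fit's coefficient table
edge_term_t_for_test <- function(fit, term) {
  fit$coefficients$t[match(term, fit$coefficients$term)]
}
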