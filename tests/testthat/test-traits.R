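test_that("surface area per volume is 2/r for uniform radius, any topology", {
  for (r in c(0.1, 0.01)) {
    tr <- random_tree(2)
    tr$cylinders$radius <- r
    expect_equal(surface_area_per_volume(tr, "trunk"), 2 / r,
                 tolerance = 1e-12)
    expect_equal(surface_area_per_volume(tr, "branch"), 2 / r,
                 tolerance = 1e-12)
  }
  # mixed radii: brute-force ratio of sums
  tr <- random_tree(9)
  cyl <- tr$cylinders[tr$cylinders$branch_order > 0L, ]
  expect_equal(surface_area_per_volume(tr, "branch"),
               sum(2 * pi * cyl$radius * cyl$length) /
                 sum(pi * cyl$radius^2 * cyl$length))
  # empty branch compartment is an error, not zero
  expect_error(surface_area_per_volume(stacked_stem(2, 0.1), "branch"),
               "no branches")
})

test_that("path fraction is mean/max of tip paths", {
  expect_equal(path_fraction(stacked_stem(c(2, 3), c(0.2, 0.1))), 1.0)
  expect_equal(path_fraction(y_tree(trunk_len = 2, branch_lens = c(1, 3))),
               0.8)  # tips at 3 and 5: mean 4 / max 5
  symmetric <- y_tree(trunk_len = 2, branch_lens = c(3, 3))
  expect_equal(path_fraction(symmetric), 1.0)
})

test_that("asymmetry is the volume-weighted horizontal centroid offset", {
  expect_equal(asymmetry(single_cyl_tree()), 0)

  # vertical trunk volume 1 centred on axis + horizontal branch volume 1
  # with midpoint 4 m off-axis -> centroid offset 2
  r_t <- sqrt(1 / (pi * 10))        # trunk: L = 10, volume 1
  r_b <- sqrt(1 / (pi * 8))         # branch: L = 8, volume 1
  rows <- rbind(
    cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), 10, r_t, 0L),
    cyl_row(2L, 1L, c(0, 0, 10), c(1, 0, 0), 8, r_b, 1L))
  tr <- qsm_tree(rows, "asym")
  expect_equal(asymmetry(tr), 2.0, tolerance = 1e-12)

  # invariant under rotation about the vertical axis through the base
  for (seed in 1:3) {
    tr <- random_tree(seed)
    expect_equal(asymmetry(rotate_tree_z(tr, 1.234)), asymmetry(tr),
                 tolerance = 1e-9)
  }
})

test_that("crown base follows the multi-stem rule with branch fallback", {
  split2 <- y_tree(trunk_len = 2, branch_lens = c(3, 3),
                   branch_radii = c(0.08, 0.08), trunk_radius = 0.1)
  expect_equal(crown_base_height(split2), 2.0)

  # thin branch at 5 m, co-dominant split at 12 m -> crown base 12
  rows <- rbind(
    cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), 5, 0.30, 0L),
    cyl_row(2L, 1L, c(0, 0, 5), c(1, 0, 2), 2, 0.06, 1L),   # 0.2 x parent
    cyl_row(3L, 1L, c(0, 0, 5), c(0, 0, 1), 7, 0.25, 0L),
    cyl_row(4L, 3L, c(0, 0, 12), c(1, 0, 3), 5, 0.15, 0L),
    cyl_row(5L, 3L, c(0, 0, 12), c(-1, 0, 3), 5, 0.15, 1L))
  tr <- qsm_tree(rows, "codom")
  expect_equal(crown_base_height(tr), 12.0)

  # no co-dominant split anywhere: lowest branch attachment wins
  only_thin <- qsm_tree(rows[1:3, ], "thin")
  expect_equal(crown_base_height(only_thin), 5.0)

  expect_error(crown_base_height(stacked_stem(c(2, 3), c(0.2, 0.1))),
               "no crown")
})

test_that("relative crown depth is (H - crown base)/H", {
  # crown base at half height
  half <- y_tree(trunk_len = 5, branch_lens = c(5 / sqrt(1.09), 5 / sqrt(1.09)),
                 branch_radii = c(0.08, 0.08))
  expect_equal(relative_crown_depth(half),
               (tree_height(half) - 5) / tree_height(half))

  # multi-stem from the base: deepest possible crown
  rows <- rbind(
    cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), 0.5, 0.2, 0L),
    cyl_row(2L, 1L, c(0, 0, 0.5), c(1, 0, 4), 8, 0.15, 0L),
    cyl_row(3L, 1L, c(0, 0, 0.5), c(-1, 0, 4), 8, 0.15, 1L))
  basal <- qsm_tree(rows, "basal")
  expect_equal(relative_crown_depth(basal),
               (tree_height(basal) - 0.5) / tree_height(basal))
  expect_gt(relative_crown_depth(basal), 0.9)

  # constructed 20 m tree with crown base at 8 m -> 0.6
  rows <- rbind(
    cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), 8, 0.3, 0L),
    cyl_row(2L, 1L, c(0, 0, 8), c(1, 0, 2), 6, 0.2, 0L),
    cyl_row(3L, 1L, c(0, 0, 8), c(0, 0, 1), 12, 0.2, 1L))
  tr20 <- qsm_tree(rows, "t20")
  expect_equal(tree_height(tr20), 20)
  expect_equal(relative_crown_depth(tr20), 0.6)
})

test_that("relative crown width is crown span over DBH", {
  # crown spanning 10 m horizontally on a 20 cm DBH tree -> 0.5
  rows <- rbind(
    cyl_row(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), 6, 0.10, 0L),
    cyl_row(2L, 1L, c(0, 0, 6), c(1, 0, 0), 5, 0.06, 0L),
    cyl_row(3L, 1L, c(0, 0, 6), c(-1, 0, 0), 5, 0.06, 1L))
  tr <- qsm_tree(rows, "wide")
  expect_equal(relative_crown_width(tr), 10 / 20, tolerance = 1e-12)

  # crown cylinders all on the vertical axis -> width 0
  axial <- stacked_stem(c(3, 3, 3), c(0.2, 0.15, 0.10))
  axial$cylinders$branch_order[3] <- 1L
  axial$cylinders$branch_id[3] <- 1L
  axial <- qsm_tree(axial$cylinders, "axial")
  expect_equal(relative_crown_width(axial), 0)

  # O(n^2) pairwise-distance oracle on a random crown
  tr <- generate_qsm_tree("interior_short", seed = 21)
  cbh <- crown_base_height(tr)
  cyl <- tr$cylinders
  base_z <- cyl$start_z[is.na(cyl$parent_id)]
  cc <- cyl[cyl$start_z - base_z >= cbh - 1e-9, ]
  pts <- rbind(cbind(cc$start_x, cc$start_y),
               cbind(cc$start_x + cc$axis_x * cc$length,
                     cc$start_y + cc$axis_y * cc$length))
  brute <- max(as.matrix(dist(pts)))
  expect_equal(relative_crown_width(tr), brute / dbh(tr),
               tolerance = 1e-9)
})

test_that("establishment classification is strict at the threshold", {
  expect_equal(classify_establishment(25), "survivor")
  expect_equal(classify_establishment(10), "short_tree")
  expect_equal(classify_establishment(20), "short_tree")
  expect_equal(classify_establishment(c(25, 10)),
               c("survivor", "short_tree"))
  expect_error(classify_establishment(-1), "positive")
})

test_that("traits are invariant/equivariant under scaling and rotation", {
  for (seed in c(2, 5)) {
    tr <- generate_qsm_tree("interior_short", seed = seed)
    k <- 1.7
    sc <- scale_tree(tr, k)
    expect_equal(path_fraction(sc), path_fraction(tr), tolerance = 1e-9)
    expect_equal(relative_crown_depth(sc), relative_crown_depth(tr),
                 tolerance = 1e-9)
    expect_equal(asymmetry(sc), k * asymmetry(tr), tolerance = 1e-9)
    expect_equal(surface_area_per_volume(sc, "branch"),
                 surface_area_per_volume(tr, "branch") / k,
                 tolerance = 1e-9)
    rot <- rotate_tree_z(tr, 0.77)
    expect_equal(path_fraction(rot), path_fraction(tr), tolerance = 1e-9)
    expect_equal(relative_crown_width(rot), relative_crown_width(tr),
                 tolerance = 1e-9)
    expect_equal(surface_area_per_volume(rot, "trunk"),
                 surface_area_per_volume(tr, "trunk"), tolerance = 1e-9)
  }
})

test_that("trait table handles missing crowns and duplicate ids", {
  trees <- lapply(1:3, function(s)
    generate_qsm_tree("interior_short", seed = s))
  tab <- compute_trait_table(trees)
  expect_equal(nrow(tab), 3L)
  expect_true(all(!is.na(tab$path_fraction)))
  expect_true(all(!is.na(tab$relative_crown_width)))

  stem_only <- stacked_stem(c(2, 3), c(0.2, 0.1), id = "plain")
  w <- capture_warnings(
    tab2 <- compute_trait_table(c(trees, list(stem_only))))
  expect_match(w, "no crown|no branches", all = FALSE)
  expect_true(is.na(tab2$relative_crown_depth[4]))
  expect_false(anyNA(tab2$height))

  expect_error(compute_trait_table(list(trees[[1]], trees[[1]])),
               "duplicate tree_id")
  expect_equal(nrow(compute_trait_table(list())), 0L)
})
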