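test_that("grid construction centres on the target centre of mass", {
  s <- random_toy_structure(4)
  s$atoms$x <- c(0, 2, 10, -5); s$atoms$y <- 0; s$atoms$z <- 0
  g <- build_grid(s, c("A:1", "A:2"), grid_params(edge_length = 6, spacing = 1))
  expect_equal(g$dims, rep(7L, 3))
  expect_equal(g$center, c(1, 0, 0), ignore_attr = TRUE)
  g2 <- build_grid(s, "A:1", grid_params(edge_length = 24, spacing = 0.5))
  expect_equal(g2$dims, rep(49L, 3))
  expect_error(build_grid(s, "A:99", grid_params()), "A:99")
})

test_that("classification matches lattice enumeration for one atom", {
  s <- random_toy_structure(1)
  s$atoms$x <- 0; s$atoms$y <- 0; s$atoms$z <- 0
  s$atoms$radius <- 1.8
  g <- build_grid(s, "A:1", grid_params(edge_length = 6, spacing = 1))
  g <- classify_grid(g, s)
  # offsets with squared norm <= 3.24 -> 0 (1), 1 (6), 2 (12), 3 (8)
  expect_equal(sum(g$labels == 1L), 27)
})

test_that("bounded-segment marking handles the P S S S P line", {
  s <- random_toy_structure(2)
  s$atoms$x <- c(-2, 2); s$atoms$y <- 0; s$atoms$z <- 0
  s$atoms$radius <- 0.4  # covers exactly one grid point each at spacing 1
  g <- build_grid(s, c("A:1", "A:2"), grid_params(edge_length = 8, spacing = 1))
  g <- classify_grid(g, s)
  g <- mark_pockets(g)
  pk <- which(g$labels == 2L)
  expect_equal(length(pk), 3)
  expect_equal(grid_point_coords(g, pk)[, 1], c(-1, 0, 1))
  expect_true(all(grid_point_coords(g, pk)[, 2:3] == 0))
})

test_that("a convex block of protein yields no pocket points", {
  lab <- integer(5^3)
  pts <- grid_coords_all(c(5, 5, 5))
  lab[pts[, 1] >= 1 & pts[, 1] <= 3 & pts[, 2] >= 1 & pts[, 2] <= 3 &
      pts[, 3] >= 1 & pts[, 3] <= 3] <- 1L
  out <- pocketeer:::grid_mark_cpp(lab, c(5L, 5L, 5L), ligsite_directions(), 1L)
  expect_equal(sum(out == 2L), 0)
})

test_that("deep relabelling is strict at the burial boundary", {
  # 1-D tube at spacing 0.5: solvent at x = 1 and x = 13 (grid units),
  # pocket in between. x = 7 is 3.0 A from the nearest solvent point
  # (deep); x = 6 and 8 are exactly 2.5 A away ('more than' is strict).
  dims <- c(15L, 3L, 3L)
  lab <- rep(1L, prod(dims))
  pts <- grid_coords_all(dims)
  core <- pts[, 2] == 1 & pts[, 3] == 1 & pts[, 1] >= 1 & pts[, 1] <= 13
  lab[core] <- 2L
  lab[core & pts[, 1] %in% c(1, 13)] <- 0L
  g <- list(labels = lab, dims = dims, spacing = 0.5,
            params = grid_params(spacing = 0.5), origin = c(0, 0, 0))
  class(g) <- "pocket_grid"
  g2 <- compute_deep(g, g$params)
  deep_x <- pts[, 1][g2$labels == 3L]
  expect_equal(deep_x, 7)
})

test_that("classify/mark/deep/cluster match brute-force oracles on random grids", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      s <- random_toy_structure(n = 8, box = 7)
      dims <- c(15L, 15L, 15L)
      origin <- c(-0.5, -0.5, -0.5)
      lab <- pocketeer:::grid_classify_cpp(coords(s), s$atoms$radius,
                                           origin, 0.5, dims)
      expect_identical(lab,
                       oracle_classify(coords(s), s$atoms$radius, origin, 0.5, dims))
      dirs <- ligsite_directions()
      mk <- pocketeer:::grid_mark_cpp(lab, dims, dirs, 1L)
      expect_identical(mk, oracle_mark(lab, dims, dirs, 1L))
      sd <- pocketeer:::grid_solvent_dist_cpp(mk, dims, 0.5)
      deep <- mk
      deep[mk == 2L & sd > 1.2] <- 3L
      expect_identical(deep, oracle_deep(mk, dims, 0.5, 1.2))
      comp <- pocketeer:::grid_components_cpp(deep, dims)
      oc <- oracle_components(deep, dims)
      # same partition (component ids may differ)
      sel <- deep >= 2L
      expect_equal(length(unique(comp[sel])), length(unique(oc[sel])))
      expect_true(all(tapply(oc[sel], comp[sel],
                             function(v) length(unique(v))) == 1))
    }
  })
})

test_that("deep volume bookkeeping and cluster filtering", {
  cup <- cup_fixture()
  det <- detect_pockets(cup$structure, cup$targets)
  expect_gt(det$total_deep_volume, 0)
  for (cl in det$clusters) {
    expect_true(all(cl$deep_points %in% cl$points))
    expect_equal(cl$deep_volume, length(cl$deep_points) * 0.5^3)
    expect_lte(cl$deep_volume, cl$pocket_volume)
    expect_true(cl$contacts_target)
  }
  # a cavity on the far side is not retained at the near-side target
  far_op <- carve_cylinder(c(0, 0, -1), radius = 3, depth = 5.5)
  s2 <- assign_radii(carve_pocket(carve_pocket(make_shell_protein(), cup$op), far_op))
  det2 <- detect_pockets(s2, rim_targets(s2, cup$op))
  ctr <- vapply(det2$clusters, function(cl)
    mean(grid_point_coords(det2$grid, cl$points)[, 3]), 0)
  expect_true(all(ctr > 0))  # only the +z cavity is retained
})

test_that("detection is deterministic and label partition is consistent", {
  cup <- cup_fixture()
  d1 <- detect_pockets(cup$structure, cup$targets)
  d2 <- detect_pockets(cup$structure, cup$targets)
  expect_identical(d1$grid$labels, d2$grid$labels)
  expect_true(all(d1$grid$labels %in% 0:3))
})

test_that("deep volume is invariant under rigid rotation within 10%", {
  cup <- cup_fixture(radius = 3, depth = 8)  # large pocket: quantization
                                             # noise well below 10%
  det <- detect_pockets(cup$structure, cup$targets)
  withr::with_seed(7, {
    R <- pocketeer:::random_rotation()
    t <- runif(3, -5, 5)
  })
  s2 <- set_coords(cup$structure, sweep(coords(cup$structure) %*% t(R), 2, t, `+`))
  det2 <- detect_pockets(s2, cup$targets)
  expect_lt(abs(det2$total_deep_volume - det$total_deep_volume),
            0.1 * det$total_deep_volume)
})
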