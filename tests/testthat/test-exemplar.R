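test_that("polar probes land along the donor/acceptor direction and filter", {
  # donor N at the cavity mouth pointing +x into an artificial pocket grid
  dims <- c(13L, 13L, 13L)
  g <- list(origin = c(0, 0, 0), spacing = 0.5, dims = dims,
            labels = rep(2L, prod(dims)), target = data.frame(chain = "A", resno = 1L),
            center = c(3, 3, 3), params = grid_params(), solvent_dist = NULL,
            retained = NULL)
  class(g) <- "pocket_grid"
  s <- read_structure(
    "ATOM      1  N   GLY A   1       0.000   3.000   3.000  1.00  0.00           N")
  pg <- data.frame(chain = "A", resno = 1L, resname = "GLY", atom = "N",
                   kind = "donor", dx = 1, dy = 0, dz = 0)
  probes <- place_polar_probes(s, g, pg)
  expect_equal(nrow(probes), 1)
  expect_equal(unname(unlist(probes[1, c("x", "y", "z")])), c(2.9, 3, 3))
  expect_equal(probes$feature, "acceptor")  # complement of the donor

  # probe location labelled protein -> dropped
  g2 <- g
  g2$labels <- rep(1L, prod(dims))
  expect_equal(nrow(place_polar_probes(s, g2, pg)), 0)
})

test_that("probe retention matches exhaustive nearest-pocket-point search", {
  withr::with_seed(19, {
    cup <- cup_fixture()
    cup$structure <- assign_radii(decorate_pocket(cup$structure, cup$op,
                                                  kind = "ser", n = 3))
    det <- detect_pockets(cup$structure, cup$targets)
    pgs <- find_polar_groups(cup$structure, warn = FALSE)
    probes <- place_polar_probes(cup$structure, det$grid, pgs)
    expect_gt(nrow(probes), 0)
    if (nrow(probes) > 0) {
      pk <- grid_point_coords(det$grid,
                              pocketeer:::pocket_point_idx(det$grid))
      for (q in seq_len(nrow(probes))) {
        d <- sqrt((pk[, 1] - probes$x[q])^2 + (pk[, 2] - probes$y[q])^2 +
                  (pk[, 3] - probes$z[q])^2)
        expect_lte(min(d), det$grid$spacing)
      }
    }
  })
})

test_that("greedy hydrophobic fill packs a line at the spacing bound", {
  # deep points along a 3.4 A line at 0.1 A pitch
  npt <- 35
  dims <- c(as.integer(npt), 1L, 1L)
  g <- list(origin = c(0, 0, 0), spacing = 0.1, dims = dims,
            labels = rep(3L, npt), target = data.frame(chain = "A", resno = 1L),
            center = c(0, 0, 0), params = grid_params(spacing = 0.1),
            solvent_dist = rep(10, npt) - abs(seq(0, 3.4, by = 0.1) - 1.7),
            retained = NULL)
  class(g) <- "pocket_grid"
  empty <- typed_atoms(matrix(0, 0, 3), character(0), 1.5)
  out <- fill_hydrophobic(g, empty)
  expect_equal(nrow(out), 3)
  d <- dist(as.matrix(out[, c("x", "y", "z")]))
  expect_true(all(d >= 1.7 - 1e-9))
  # zero deep points: identity
  g$labels <- rep(2L, npt)
  expect_equal(nrow(fill_hydrophobic(g, empty)), 0)
})

test_that("greedy fill is feasible and maximal on a real pocket", {
  cup <- cup_fixture()
  ex <- build_exemplar(cup$structure, cup$targets, label = "cup")
  xyz <- as.matrix(ex$atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1) expect_gte(min(dist(xyz)), 1.7)
  # maximality: every remaining deep point is within 1.7 A of a placed atom
  det <- detect_pockets(cup$structure, cup$targets)
  deep <- grid_point_coords(det$grid,
                            pocketeer:::pocket_point_idx(det$grid, deep_only = TRUE))
  full <- fill_hydrophobic(det$grid,
                           place_polar_probes(cup$structure, det$grid,
                                              find_polar_groups(cup$structure, warn = FALSE)))
  fxyz <- as.matrix(full[, c("x", "y", "z")])
  for (q in seq_len(nrow(deep))) {
    d <- sqrt((fxyz[, 1] - deep[q, 1])^2 + (fxyz[, 2] - deep[q, 2])^2 +
              (fxyz[, 3] - deep[q, 3])^2)
    expect_lt(min(d), 1.7)
  }
  # hydrophobe centres coincide with deep grid points
  hyd <- full[full$feature == "hydrophobe", ]
  for (q in seq_len(nrow(hyd))) {
    d <- sqrt((deep[, 1] - hyd$x[q])^2 + (deep[, 2] - hyd$y[q])^2 +
              (deep[, 3] - hyd$z[q])^2)
    expect_lt(min(d), 1e-9)
  }
})

test_that("shrinking min_spacing never decreases the hydrophobe count", {
  cup <- cup_fixture()
  det <- detect_pockets(cup$structure, cup$targets)
  empty <- typed_atoms(matrix(0, 0, 3), character(0), 1.5)
  counts <- vapply(c(2.2, 1.7, 1.2), function(ms)
    nrow(fill_hydrophobic(det$grid, empty, exemplar_params(min_spacing = ms))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("proximity clustering follows single linkage at 5 A", {
  g <- list(center = c(0, 0, 0))
  class(g) <- "pocket_grid"
  two <- typed_atoms(rbind(c(0, 0, 0), c(4.9, 0, 0)), rep("hydrophobe", 2), 1.7)
  ex <- cluster_exemplar(two, g)
  expect_equal(nrow(ex$atoms), 2)
  apart <- typed_atoms(rbind(c(0, 0, 0), c(5.1, 0, 0)), rep("hydrophobe", 2), 1.7)
  ex2 <- cluster_exemplar(apart, g)
  expect_equal(nrow(ex2$atoms), 1)
  expect_equal(ex2$atoms$x, 0)  # the component nearer the target centre
  expect_error(cluster_exemplar(two[0, ], g), "empty")
})

test_that("single-linkage components equal the union-find oracle", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(5:15, 1)
      xyz <- matrix(runif(3 * n, 0, 12), ncol = 3)
      memb <- cutree(hclust(dist(xyz), method = "single"), h = 5)
      oc <- oracle_single_linkage(xyz, 5)
      expect_true(all(tapply(oc, memb, function(v) length(unique(v))) == 1))
      expect_equal(length(unique(memb)), length(unique(oc)))
    }
  })
})

test_that("build_exemplar errors without a pocket and is deterministic", {
  s <- assign_radii(make_shell_protein())
  tg <- sprintf("A:%d", which.max(coords(s)[, 3]))
  expect_error(build_exemplar(s, tg), "no pocket")
  cup <- cup_fixture()
  e1 <- build_exemplar(cup$structure, cup$targets)
  e2 <- build_exemplar(cup$structure, cup$targets)
  expect_identical(write_exemplar(e1), write_exemplar(e2))
  expect_equal(e1$deep_volume,
               detect_pockets(cup$structure, cup$targets)$total_deep_volume)
})

test_that("decorated cavity yields polar probes in the exemplar", {
  op <- carve_cylinder(c(0, 0, 1), radius = 3, depth = 5.5)
  s <- decorate_pocket(carve_pocket(make_shell_protein(), op), op,
                       kind = "lys", n = 2)
  s <- assign_radii(s)
  ex <- build_exemplar(s, rim_targets(s, op))
  expect_gte(sum(ex$atoms$feature == "acceptor"), 1)  # complement of donors
  expect_gte(sum(ex$atoms$feature == "hydrophobe"), 1)
})

test_that("exemplar files round-trip losslessly", {
  cup <- cup_fixture()
  ex <- build_exemplar(cup$structure, cup$targets, label = "cup")
  tf <- tempfile(fileext = ".pdb")
  write_exemplar(ex, tf)
  back <- read_exemplar(tf)
  expect_equal(nrow(back$atoms), nrow(ex$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(ex$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
  expect_identical(back$atoms$feature, ex$atoms$feature)
  expect_equal(back$deep_volume, ex$deep_volume, tolerance = 1e-3)
  # line count = atoms + 2 header + END
  expect_length(readLines(tf), nrow(ex$atoms) + 3)
  empty <- ex
  empty$atoms <- ex$atoms[0, ]
  expect_error(write_exemplar(empty), "empty")
})
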