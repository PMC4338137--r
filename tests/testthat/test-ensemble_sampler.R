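two_atom_system <- function(d0 = 3, r = 0.1) {
  atoms <- data.frame(serial = 1:2, name = c("A1", "A2"), element = "C",
                      resname = "UNK", chain = "A", resno = 1:2,
                      x = c(0, d0), y = 0, z = 0, radius = r,
                      stringsAsFactors = FALSE)
  pocketeer:::new_structure(atoms)
}

test_that("stand-in energy is zero at the reference and positive on clashes", {
  cup <- cup_fixture()
  expect_equal(stand_in_energy(cup$structure, cup$structure), 0)
  # two distant atoms (non-contacts) pushed into a clash
  s <- random_toy_structure(2)
  s$atoms$x <- c(0, 20); s$atoms$y <- 0; s$atoms$z <- 0
  s$atoms$radius <- 1.7
  s2 <- s
  s2$atoms$x <- c(0, 1.0)
  expect_equal(stand_in_energy(s, s), 0)
  expect_gt(stand_in_energy(s2, s), 0)
})

test_that("stand-in energy matches a naive double-loop evaluation", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      ref <- random_toy_structure(12, box = 10)
      cfg <- sampler_config()
      s <- set_coords(ref, coords(ref) + matrix(rnorm(36, 0, 0.4), ncol = 3))
      e <- stand_in_energy(s, ref, cfg)
      # naive oracle
      xyz <- coords(s); rxyz <- coords(ref); rad <- ref$atoms$radius
      eo <- 0
      for (i in 1:11) for (j in (i + 1):12) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        dr <- sqrt(sum((rxyz[i, ] - rxyz[j, ])^2))
        c <- rad[i] + rad[j]
        if (dr <= cfg$contact_cutoff) {
          eo <- eo + cfg$k_elastic * (d - dr)^2
        } else if (d < c) {
          eo <- eo + cfg$k_repulsion * (1 - d / c)^4
        }
      }
      expect_equal(e, eo, tolerance = 1e-9)
    }
  })
})

test_that("delta energy agrees with full recomputation", {
  withr::with_seed(13, {
    ref <- random_toy_structure(30, box = 12)
    cfg <- sampler_config()
    model <- pocketeer:::make_energy_model(ref, cfg)
    xyz <- coords(ref) + matrix(rnorm(90, 0, 0.3), ncol = 3)
    e0 <- pocketeer:::standin_energy_cpp(xyz, model$contact_radius, model$ci,
                                         model$cj, model$dref, cfg$k_elastic,
                                         cfg$k_repulsion)
    for (rep in 1:10) {
      moved <- sample.int(30, sample(1:5, 1))
      prop <- xyz
      prop[moved, ] <- prop[moved, , drop = FALSE] +
        matrix(rnorm(3 * length(moved), 0, 0.5), ncol = 3)
      de <- pocketeer:::standin_delta_cpp(xyz, prop, moved - 1L,
                                          model$contact_radius,
                                          model$csr$ptr, model$csr$idx,
                                          model$csr$dref, cfg$k_elastic,
                                          cfg$k_repulsion)
      e1 <- pocketeer:::standin_energy_cpp(prop, model$contact_radius,
                                           model$ci, model$cj, model$dref,
                                           cfg$k_elastic, cfg$k_repulsion)
      expect_equal(e0 + de, e1, tolerance = 1e-8)
      xyz <- prop
      e0 <- e1
    }
  })
})

test_that("biased energy adds bias_constant times the deep volume", {
  cup <- cup_fixture()
  cfg <- sampler_config()
  be <- biased_energy(cup$structure, cup$structure, cup$targets, cfg)
  expect_gt(be$deep_volume, 0)
  expect_equal(be$e_biased - be$e_unbiased, -0.25 * be$deep_volume,
               tolerance = 1e-9)
  cfg0 <- sampler_config(bias_constant = 0)
  be0 <- biased_energy(cup$structure, cup$structure, cup$targets, cfg0)
  expect_equal(be0$e_biased, be0$e_unbiased)
})

test_that("sampler-grid deep volume is consistent with full detection", {
  cup <- cup_fixture()
  cfg <- sampler_config()
  be <- biased_energy(cup$structure, cup$structure, cup$targets, cfg)
  det <- detect_pockets(cup$structure, cup$targets,
                        grid_params(edge_length = 24, spacing = 1.0))
  expect_equal(be$deep_volume, det$total_deep_volume)
})

test_that("trajectories are reproducible and 0 steps returns the start", {
  cup <- cup_fixture()
  cfg <- sampler_config(steps = 50)
  c1 <- run_trajectory(cup$structure, cup$targets, cfg, seed = 4)
  c2 <- run_trajectory(cup$structure, cup$targets, cfg, seed = 4)
  expect_identical(coords(c1$structure), coords(c2$structure))
  expect_identical(c1$unbiased_energy, c2$unbiased_energy)
  c0 <- run_trajectory(cup$structure, cup$targets,
                       sampler_config(steps = 0), seed = 4)
  expect_identical(coords(c0$structure), coords(cup$structure))
  expect_equal(c0$unbiased_energy, 0)
  # energy bookkeeping
  expect_lt(abs(c1$biased_energy - c1$unbiased_energy -
                cfg$bias_constant * c1$deep_volume), 1e-9)
})

test_that("ensembles have the requested size, seeds, and merge cleanly", {
  cup <- cup_fixture()
  cfg <- sampler_config(steps = 10, n_conformations = 5, seed = 42)
  ens <- generate_ensemble(cup$structure, cup$targets, cfg, label = "cup")
  expect_length(ens$conformations, 5)
  expect_equal(ens$provenance$seeds, 42:46)
  expect_equal(vapply(ens$conformations, `[[`, 0, "seed"), 42:46,
               ignore_attr = TRUE)
  cfg2 <- sampler_config(steps = 10, n_conformations = 5, seed = 77)
  ens2 <- generate_ensemble(cup$structure, cup$targets, cfg2, label = "cup2")
  m <- merge_ensembles(ens, ens2, label = "both")
  expect_length(m$conformations, 10)
  expect_length(m$provenance$parents, 2)
})

test_that("the energy filter keeps conformations within the window", {
  fake_ens <- function(energies) {
    confs <- lapply(energies, function(e)
      base::structure(list(unbiased_energy = e), class = "conformation"))
    base::structure(list(conformations = confs, provenance = list()),
                    class = "pocket_ensemble")
  }
  unb <- fake_ens(c(90, 100, 110))  # median 100
  bia <- fake_ens(c(80, 110, 115, 115.0001, 120))
  out <- filter_by_energy(bia, unb, window = 15)
  expect_equal(ensemble_energies(out), c(80, 110, 115))
  # brute-force comparison oracle on random vectors
  withr::with_seed(9, {
    for (rep in 1:5) {
      eu <- rnorm(20, 100, 10)
      eb <- rnorm(30, 105, 10)
      kept <- ensemble_energies(filter_by_energy(fake_ens(eb), fake_ens(eu)))
      expect_equal(kept, eb[eb <= median(eu) + 15])
    }
  })
  expect_error(filter_by_energy(fake_ens(1), fake_ens(numeric(0))), "empty")
})

test_that("unbiased sampling of a harmonic dimer matches Boltzmann", {
  # stationary density of the inter-atom distance r is proportional to
  # r^2 exp(-k (r - d0)^2 / T); compare the sampled CDF by KS
  d0 <- 3; k <- 2
  sys <- two_atom_system(d0 = d0)
  cfg <- sampler_config(bias_constant = 0, steps = 42000, jitter_sd = 0.45,
                        rot_prob = 0, k_elastic = k, temperature = 1)
  cf <- run_trajectory(sys, c("A:1", "A:2"), cfg, seed = 8,
                       monitor = function(xyz)
                         sqrt(sum((xyz[1, ] - xyz[2, ]) ^ 2)))
  r <- attr(cf, "trace")
  r <- r[seq(2004, length(r), by = 4)]  # burn-in dropped, thinned to 10^4
  dens <- function(x) x^2 * exp(-k * (x - d0)^2)
  zz <- integrate(dens, 0, 10)$value
  cdf <- Vectorize(function(x) integrate(dens, 0, x)$value / zz)
  ks <- suppressWarnings(ks.test(r, cdf))
  expect_lt(unname(ks$statistic), 0.05)
})
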