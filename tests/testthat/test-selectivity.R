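test_that("distance matrices are symmetric with near-zero duplicate entries", {
  withr::with_seed(3, {
    exs <- lapply(1:4, function(i) random_typed_set(6))
    exs[[4]] <- exs[[1]]  # duplicate
    D <- distance_matrix(exs, labels = letters[1:4])
    expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
    expect_true(all(diag(D) == 0))
    expect_lt(D[1, 4], 1e-3)
    expect_true(all(D >= 0 & D <= 2))
  })
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  # 3-4-5 right triangle
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pts <- classical_mds(D, dim = 2)
  expect_equal(as.matrix(dist(pts)), unclass(D), tolerance = 1e-9,
               ignore_attr = TRUE)
  # collinear equidistant points: second axis collapses
  D2 <- as.matrix(dist(cbind(c(0, 1, 2, 3), 0)))
  pts2 <- classical_mds(D2, dim = 2)
  expect_lt(max(abs(pts2[, 2])), 1e-6)
  # sign convention is deterministic
  expect_identical(classical_mds(D), classical_mds(D))
  expect_gt(classical_mds(D)[which(abs(classical_mds(D)[, 1]) > 1e-10)[1], 1], 0)
})

test_that("distinctness equals a brute-force double loop", {
  withr::with_seed(21, {
    n <- 15
    groups <- rep(c("p1", "p2", "p3"), each = 5)
    xyz <- matrix(rnorm(3 * n, 0, 2), ncol = 3)
    D <- as.matrix(dist(xyz))  # any symmetric distance works here
    rownames(D) <- colnames(D) <- sprintf("c%02d", 1:n)
    dv <- distinctness(D, groups)
    for (q in seq_len(nrow(dv))) {
      i <- match(dv$id[q], rownames(D))
      others <- which(groups != groups[i])
      own <- setdiff(which(groups == groups[i]), i)
      expect_equal(dv$d_other[q], min(D[i, others]))
      expect_equal(dv$d_self[q], min(D[i, own]))
      expect_equal(dv$distinctness[q], dv$d_other[q] - dv$d_self[q])
    }
    expect_error(distinctness(D, rep(c("a", "b"), c(1, 14))), "single")
  })
})

test_that("identical ensembles give non-positive distinctness", {
  withr::with_seed(2, {
    xyz <- matrix(rnorm(12, 0, 2), 4, 3)
    D <- as.matrix(dist(rbind(xyz, xyz)))
    dv <- distinctness(D, rep(c("p1", "p2"), each = 4))
    expect_true(all(dv$distinctness <= 1e-12))
  })
})

test_that("selectivity rows are z-scored with population SD", {
  withr::with_seed(12, {
    ref <- random_typed_set(6)
    far1 <- apply_transform(random_typed_set(6), rigid_transform(diag(3), c(30, 0, 0)))
    ens <- list(p1 = list(ref), p2 = list(random_typed_set(5)),
                p3 = list(far1, random_typed_set(4)))
    row <- selectivity_row(ref, ens, reference_id = "r")
    expect_equal(mean(row$z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(row$z^2)), 1, tolerance = 1e-9)
    expect_equal(row$protein[which.min(row$z)], "p1")
    expect_lt(row$min_distance[row$protein == "p1"], 1e-3)
  })
  # closed-form check: distances (1,2,3) -> z = (-1.2247, 0, 1.2247)
  fake_row <- function(d) (d - mean(d)) / sqrt(mean((d - mean(d))^2))
  expect_equal(fake_row(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-4)
})

test_that("degenerate rows with no variation flag and zero out", {
  ref <- typed_atoms(matrix(0, 1, 3), "donor", 1.5)
  same <- typed_atoms(matrix(c(5, 5, 5), 1, 3), "donor", 1.5)
  ens <- list(p1 = list(same), p2 = list(same))
  row <- suppressMessages(selectivity_row(ref, ens))
  expect_equal(row$z, c(0, 0))
  expect_true(attr(row, "no_variation"))
})

test_that("ROC evaluation matches the pair-counting oracle", {
  mk_rows <- function(zmat) {
    lapply(seq_len(nrow(zmat)), function(i) {
      r <- data.frame(protein = colnames(zmat), min_distance = NA,
                      z = zmat[i, ], stringsAsFactors = FALSE)
      attr(r, "reference_id") <- rownames(zmat)[i]
      class(r) <- c("selectivity_row", "data.frame")
      r
    })
  }
  zm <- matrix(c(-1.2, 0.3, 0.9, 1.1, -0.8, -0.3), 2, 3, byrow = TRUE,
               dimnames = list(c("rA", "rB"), c("p1", "p2", "p3")))
  labels <- data.frame(reference = c("rA", "rA", "rA", "rB", "rB", "rB"),
                       protein = rep(c("p1", "p2", "p3"), 2),
                       class = c("strong", "none", "none",
                                 "none", "strong", "strong"))
  roc <- roc_evaluate(mk_rows(zm), labels)
  pos <- c(-1.2, -0.8, -0.3); neg <- c(0.3, 0.9, 1.1)
  expect_equal(roc$auc, oracle_auc_paircount(-pos, -neg))
  expect_equal(roc$auc, 1.0)
  # inverted labels
  labels2 <- labels
  labels2$class <- ifelse(labels$class == "strong", "none", "strong")
  expect_equal(roc_evaluate(mk_rows(zm), labels2)$auc, 0.0)
  # one inversion
  withr::with_seed(6, {
    for (rep in 1:5) {
      z <- rnorm(6)
      lab <- data.frame(reference = "rA", protein = sprintf("p%d", 1:6),
                        class = sample(rep(c("strong", "none"), 3)))
      zm1 <- matrix(z, 1, dimnames = list("rA", sprintf("p%d", 1:6)))
      roc1 <- roc_evaluate(mk_rows(zm1), lab)
      expect_equal(roc1$auc,
                   oracle_auc_paircount(-z[lab$class == "strong"],
                                        -z[lab$class == "none"]))
      # complement property on tie-free data
      expect_equal(roc1$auc +
                     roc_evaluate(mk_rows(-zm1), lab)$auc, 1)
    }
  })
  expect_error(roc_evaluate(mk_rows(zm),
                            transform(labels, class = "strong")), "negative")
})

test_that("Mann-Whitney p agrees with the reference implementation", {
  withr::with_seed(44, {
    z <- rnorm(10)
    lab <- data.frame(reference = "rA", protein = sprintf("p%d", 1:10),
                      class = rep(c("strong", "none"), 5))
    zm <- matrix(z, 1, dimnames = list("rA", sprintf("p%d", 1:10)))
    r <- data.frame(protein = colnames(zm), min_distance = NA, z = z)
    attr(r, "reference_id") <- "rA"
    class(r) <- c("selectivity_row", "data.frame")
    roc <- roc_evaluate(list(r), lab)
    ref <- wilcox.test(-z[lab$class == "strong"], -z[lab$class == "none"],
                       alternative = "greater", exact = FALSE,
                       correct = FALSE)$p.value
    expect_equal(roc$p_value, ref)
  })
})

test_that("Spearman matrix correlation equals rank-then-Pearson", {
  withr::with_seed(33, {
    M1 <- as.matrix(dist(matrix(rnorm(18), 6, 3)))
    M2 <- as.matrix(dist(matrix(rnorm(18), 6, 3)))
    out <- spearman_matrix_corr(M1, M2)
    ut <- upper.tri(M1)
    expect_equal(out$rho, oracle_spearman(M1[ut], M2[ut]), tolerance = 1e-12)
    expect_equal(spearman_matrix_corr(M1, M1)$rho, 1)
    expect_equal(spearman_matrix_corr(M1, exp(-M1))$rho, -1)
    expect_error(spearman_matrix_corr(M1, M2[1:5, 1:5]), "shape")
  })
})
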