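# Independent brute-force oracles and small generators used across the
# suite. These deliberately re-derive results from first principles (double
# loops, union-find, quadrature) and share no code with the package
# internals they check.

# ---- grid label oracles (codes: 0 solvent, 1 protein, 2 pocket, 3 deep) ----

oracle_classify <- function(xyz, radii, origin, spacing, dims) {
  lab <- integer(prod(dims))
  q <- 0L
  for (k in 0:(dims[3] - 1)) for (j in 0:(dims[2] - 1)) for (i in 0:(dims[1] - 1)) {
    q <- q + 1L
    p <- origin + c(i, j, k) * spacing
    d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
    if (any(d2 <= radii^2)) lab[q] <- 1L
  }
  lab
}

# per-line scan: runs of non-protein bounded by protein at both ends
oracle_mark <- function(lab, dims, dirs, min_bounded) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lin <- function(i, j, k) i + nx * (j + ny * k) + 1L
  cnt <- integer(length(lab))
  inb <- function(i, j, k) i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz
  for (d in seq_len(nrow(dirs))) {
    dd <- dirs[d, ]
    for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
      if (inb(i - dd[1], j - dd[2], k - dd[3])) next  # not a line start
      p <- c(i, j, k)
      line <- integer(0)
      while (inb(p[1], p[2], p[3])) {
        line <- c(line, lin(p[1], p[2], p[3]))
        p <- p + dd
      }
      lv <- lab[line]
      prot <- which(lv == 1L)
      if (length(prot) >= 2) {
        for (q in seq_len(length(prot) - 1)) {
          a <- prot[q]; b <- prot[q + 1]
          if (b - a > 1) cnt[line[(a + 1):(b - 1)]] <- cnt[line[(a + 1):(b - 1)]] + 1L
        }
      }
    }
  }
  out <- lab
  out[lab == 0L & cnt >= min_bounded] <- 2L
  out
}

oracle_deep <- function(lab, dims, spacing, burial) {
  pts <- grid_coords_all(dims)
  sol <- pts[lab == 0L, , drop = FALSE]
  out <- lab
  if (nrow(sol) == 0) {
    out[lab == 2L] <- 3L
    return(out)
  }
  for (q in which(lab == 2L)) {
    d2 <- (sol[, 1] - pts[q, 1])^2 + (sol[, 2] - pts[q, 2])^2 +
      (sol[, 3] - pts[q, 3])^2
    if (sqrt(min(d2)) * spacing > burial) out[q] <- 3L
  }
  out
}

grid_coords_all <- function(dims) {
  idx <- 0:(prod(dims) - 1)
  cbind(idx %% dims[1], (idx %/% dims[1]) %% dims[2], idx %/% (dims[1] * dims[2]))
}

# ---- union-find ----

uf_new <- function(n) seq_len(n)
uf_find <- function(par, i) {
  while (par[i] != i) i <- par[i]
  i
}
uf_components <- function(n, edges) {
  par <- uf_new(n)
  if (nrow(edges) > 0) {
    for (q in seq_len(nrow(edges))) {
      a <- uf_find(par, edges[q, 1]); b <- uf_find(par, edges[q, 2])
      if (a != b) par[b] <- a
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(par, i), 0L)
  match(roots, unique(roots))
}

# connected components of label>=2 points under 26-adjacency, via union-find
oracle_components <- function(lab, dims) {
  pts <- grid_coords_all(dims)
  sel <- which(lab >= 2L)
  comp <- integer(length(lab))
  if (length(sel) == 0) return(comp)
  sub <- pts[sel, , drop = FALSE]
  edges <- matrix(0L, 0, 2)
  for (a in seq_along(sel)) for (b in seq_len(a - 1L)) {
    if (all(abs(sub[a, ] - sub[b, ]) <= 1L)) edges <- rbind(edges, c(a, b))
  }
  comp[sel] <- uf_components(length(sel), edges)
  comp
}

# single-linkage components at threshold via union-find on the distance matrix
oracle_single_linkage <- function(xyz, threshold) {
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  edges <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  uf_components(n, edges)
}

# ---- random fixtures ----

random_label_grid <- function(dims = c(15, 15, 15), p_protein = 0.35) {
  lab <- as.integer(runif(prod(dims)) < p_protein)
  lab
}

random_toy_structure <- function(n = 10, box = 8) {
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      resname = "UNK", chain = "A", resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = runif(n, 1.2, 2.0), stringsAsFactors = FALSE)
  s <- pocketeer:::new_structure(atoms)
  s
}

random_typed_set <- function(n = 8, spread = 4, polar_frac = 0.4) {
  xyz <- matrix(rnorm(3 * n, 0, spread), ncol = 3)
  feats <- sample(c("hydrophobe", "donor", "acceptor"), n, replace = TRUE,
                  prob = c(1 - polar_frac, polar_frac / 2, polar_frac / 2))
  typed_atoms(xyz, feats, runif(n, 1.2, 1.9))
}

random_rigid <- function() {
  rot <- pocketeer:::random_rotation()
  rigid_transform(rot, runif(3, -8, 8))
}

# ---- gaussian overlap quadrature oracle ----

# midpoint-rule integration of the product of the two summed Gaussian
# densities on a regular grid
oracle_overlap_quadrature <- function(A, B, h = 0.1, pad = 4.5) {
  amp <- pocketeer:::GAUSS_AMP
  allxyz <- rbind(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]))
  lo <- apply(allxyz, 2, min) - pad
  hi <- apply(allxyz, 2, max) + pad
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  dens <- function(set) {
    g <- pocketeer:::gauss_exponent(set$radius)
    out <- 0
    for (q in seq_len(nrow(set))) {
      d2 <- outer(outer((gx - set$x[q])^2, (gy - set$y[q])^2, `+`),
                  (gz - set$z[q])^2, `+`)
      out <- out + amp * exp(-g[q] * d2)
    }
    out
  }
  sum(dens(A) * dens(B)) * h^3
}

# ---- statistics oracles ----

oracle_auc_paircount <- function(scores_pos, scores_neg) {
  wins <- 0
  for (p in scores_pos) for (n in scores_neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(scores_pos) * length(scores_neg))
}

oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# carved-cup structure used in several tests
cup_fixture <- function(radius = 3, depth = 5.5) {
  op <- carve_cylinder(c(0, 0, 1), radius = radius, depth = depth)
  s <- assign_radii(carve_pocket(make_shell_protein(), op))
  list(structure = s, op = op, targets = rim_targets(s, op))
}
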