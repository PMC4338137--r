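# shape_align: Gaussian volume/chemistry overlap, rigid alignment,
# Tanimoto scoring and the exemplar distance.
#
# Each atom carries a spherical Gaussian p*exp(-g r^2) in the Grant-Pickup
# parameterisation: fixed amplitude p = 2.828 and exponent g chosen so that
# an isolated atom's Gaussian volume equals its hard-sphere volume
# (4/3) pi r^3. Overlap is first-order (pairwise products only). "Color"
# chemistry overlap is restricted to matching polar features
# (donor-donor, acceptor-acceptor) with a fixed color radius.

GAUSS_AMP <- 2.828

gauss_exponent <- function(radius, amp = GAUSS_AMP) {
  pi * (3 * amp / (4 * pi * radius^3))^(2 / 3)
}

feature_code <- function(feature) {
  match(feature, FEATURE_LEVELS) - 1L  # 0 hydrophobe, 1 donor, 2 acceptor
}

#' Alignment configuration
#'
#' @param color_weight weight of the color term in the alignment objective
#'   (final scores are always computed at the final pose)
#' @param color_radius Gaussian radius of color features (Angstrom)
#' @param extra_starts seeded random rotation starts added to the four
#'   principal-axes starts
#' @param seed RNG seed for random starts
#' @param maxeval maximum objective evaluations per start
#' @param ftol relative convergence tolerance of the simplex refinement
#' @param rot_step,trans_step initial simplex steps (radians / Angstrom)
#' @return list of class `align_config`
#' @export
align_config <- function(color_weight = 0.5, color_radius = 1.0,
                         extra_starts = 4L, seed = 17L, maxeval = 300L,
                         ftol = 1e-4, rot_step = 0.35, trans_step = 1.0) {
  base::structure(list(color_weight = color_weight,
                       color_radius = color_radius,
                       extra_starts = as.integer(extra_starts),
                       seed = as.integer(seed), maxeval = as.integer(maxeval),
                       ftol = ftol, rot_step = rot_step,
                       trans_step = trans_step),
                  class = "align_config")
}

#' Identity rigid transform
#' @export
identity_transform <- function() {
  base::structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                  class = "rigid_transform")
}

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @export
rigid_transform <- function(rotation, translation) {
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6)
  base::structure(list(rotation = rotation, translation = translation),
                  class = "rigid_transform")
}

#' Apply a rigid transform to a typed atom set (or matrix)
#' @param x `typed_atoms` or n x 3 matrix
#' @param transform a `rigid_transform`
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "typed_atoms")) {
    xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(transform$rotation)
    x$x <- xyz[, 1] + transform$translation[1]
    x$y <- xyz[, 2] + transform$translation[2]
    x$z <- xyz[, 3] + transform$translation[3]
    return(x)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' First-order Gaussian volume overlap of two typed atom sets
#'
#' @param A,B `typed_atoms` sets (or objects coercible via
#'   [as_typed_atoms()])
#' @param transform optional `rigid_transform` applied to `B`
#' @return overlap volume (Angstrom^3)
#' @export
gaussian_overlap <- function(A, B, transform = NULL) {
  A <- as_typed_atoms(A); B <- as_typed_atoms(B)
  if (!is.null(transform)) B <- apply_transform(B, transform)
  gauss_overlap_pairs_cpp(as.matrix(A[, c("x", "y", "z")]),
                          gauss_exponent(A$radius),
                          as.matrix(B[, c("x", "y", "z")]),
                          gauss_exponent(B$radius), GAUSS_AMP)
}

#' Color (chemistry) overlap of two typed atom sets
#'
#' Gaussian overlap restricted to matching polar features; hydrophobes
#' contribute to shape only. Color Gaussians use `config$color_radius`.
#'
#' @inheritParams gaussian_overlap
#' @param config an [align_config()]
#' @return list with `per_feature` overlaps, `color_overlap`, and
#'   `color_tanimoto`
#' @export
color_overlap <- function(A, B, transform = NULL, config = align_config()) {
  A <- as_typed_atoms(A); B <- as_typed_atoms(B)
  if (!is.null(transform)) B <- apply_transform(B, transform)
  gcol <- gauss_exponent(config$color_radius)
  per <- c(donor = 0, acceptor = 0)
  ov <- function(X, Y) {
    if (nrow(X) == 0 || nrow(Y) == 0) return(0)
    gauss_overlap_pairs_cpp(as.matrix(X[, c("x", "y", "z")]),
                            rep(gcol, nrow(X)),
                            as.matrix(Y[, c("x", "y", "z")]),
                            rep(gcol, nrow(Y)), GAUSS_AMP)
  }
  for (f in c("donor", "acceptor"))
    per[f] <- ov(A[A$feature == f, , drop = FALSE],
                 B[B$feature == f, , drop = FALSE])
  self_a <- sum(vapply(c("donor", "acceptor"), function(f)
    ov(A[A$feature == f, , drop = FALSE], A[A$feature == f, , drop = FALSE]), 0))
  self_b <- sum(vapply(c("donor", "acceptor"), function(f)
    ov(B[B$feature == f, , drop = FALSE], B[B$feature == f, , drop = FALSE]), 0))
  cab <- sum(per)
  ct <- if (self_a + self_b - cab > 1e-12) cab / (self_a + self_b - cab) else 0
  list(per_feature = per, color_overlap = cab,
       color_tanimoto = min(max(ct, 0), 1))
}

# principal-axes rotation candidates mapping B's axes onto A's
principal_starts <- function(xyzA, xyzB) {
  eig_frame <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
    E <- ev$vectors
    if (det(E) < 0) E[, 3] <- -E[, 3]
    list(E = E, values = ev$values)
  }
  fa <- eig_frame(xyzA); fb <- eig_frame(xyzB)
  degenerate <- min(fa$values, fb$values) < 1e-8 ||
    nrow(xyzA) < 3 || nrow(xyzB) < 3
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  starts <- lapply(signs, function(s) fa$E %*% diag(s) %*% t(fb$E))
  list(starts = starts, degenerate = degenerate)
}

score_from_overlaps <- function(oab, oaa, obb, cab_tan) {
  st <- oab / (oaa + obb - oab)
  st <- min(max(st, 0), 1)
  combo <- st + cab_tan
  base::structure(list(shape_overlap = oab, self_overlap_A = oaa,
                       self_overlap_B = obb, shape_tanimoto = st,
                       color_tanimoto = cab_tan, tanimoto_combo = combo,
                       distance = 2 - combo),
                  class = "overlap_score")
}

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("<overlap_score> shape %.4f, color %.4f, combo %.4f, distance %.4f\n",
              x$shape_tanimoto, x$color_tanimoto, x$tanimoto_combo, x$distance))
  invisible(x)
}

#' Align two typed atom sets by Gaussian overlap maximisation
#'
#' Starting poses superpose centroids and enumerate the four proper
#' principal-axes sign combinations (plus optional seeded random starts;
#' degenerate/collinear inertia falls back to random starts). Each start is
#' refined by derivative-free simplex maximisation of
#' shape_overlap + color_weight * color_overlap over the 6 rigid DOF.
#'
#' @param A,B typed atom sets (or exemplars)
#' @param config an [align_config()]
#' @return list with `transform` (`rigid_transform` for B onto A) and
#'   `score` (an `overlap_score`)
#' @export
align <- function(A, B, config = align_config()) {
  A <- as_typed_atoms(A); B <- as_typed_atoms(B)
  if (nrow(A) < 1 || nrow(B) < 1) stop("cannot align an empty atom set")
  xyzA <- as.matrix(A[, c("x", "y", "z")])
  xyzB <- as.matrix(B[, c("x", "y", "z")])
  cA <- colMeans(xyzA); cB <- colMeans(xyzB)
  gsA <- gauss_exponent(A$radius); gsB <- gauss_exponent(B$radius)
  gcol <- gauss_exponent(config$color_radius)
  fA <- feature_code(A$feature); fB <- feature_code(B$feature)

  ps <- principal_starts(xyzA, xyzB)
  starts <- ps$starts
  n_rand <- config$extra_starts + if (ps$degenerate) 8L else 0L
  if (ps$degenerate) message("degenerate principal axes; adding random starts")
  if (n_rand > 0) {
    rand <- withr::with_seed(config$seed,
                             lapply(seq_len(n_rand), function(i) random_rotation()))
    starts <- c(starts, rand)
  }
  best <- NULL
  for (R0 in starts) {
    B0 <- sweep(xyzB, 2, cB) %*% t(R0)
    fit <- align_refine_cpp(xyzA, fA, gsA, rep(gcol, nrow(A)),
                            B0, fB, gsB, rep(gcol, nrow(B)), GAUSS_AMP,
                            cA, config$color_weight, config$rot_step,
                            config$trans_step, config$maxeval, config$ftol)
    if (is.null(best) || fit$objective > best$fit$objective)
      best <- list(fit = fit, R0 = R0)
  }
  par <- best$fit$par
  Rfin <- rotation_from_vector(par[1:3]) %*% best$R0
  tfin <- cA + par[4:6] - as.vector(Rfin %*% cB)
  transform <- rigid_transform(Rfin, tfin)
  oaa <- gauss_overlap_pairs_cpp(xyzA, gsA, xyzA, gsA, GAUSS_AMP)
  obb <- gauss_overlap_pairs_cpp(xyzB, gsB, xyzB, gsB, GAUSS_AMP)
  col <- color_overlap(A, B, transform, config)
  score <- score_from_overlaps(best$fit$shape_overlap, oaa, obb,
                               col$color_tanimoto)
  stopifnot(score$shape_tanimoto >= 0, score$shape_tanimoto <= 1,
            score$color_tanimoto >= 0, score$color_tanimoto <= 1,
            score$distance >= 0, score$distance <= 2)
  list(transform = transform, score = score)
}

#' Exemplar distance between two pockets
#'
#' `2 - TanimotoCombo` of the best alignment. Both alignment directions are
#' evaluated and the smaller distance returned, making the measure
#' symmetric up to optimiser tolerance.
#'
#' @inheritParams align
#' @return numeric distance in `[0, 2]`, with the winning alignment's
#'   `overlap_score` attached as attribute `"score"`
#' @export
exemplar_distance <- function(A, B, config = align_config()) {
  f1 <- align(A, B, config)
  f2 <- align(B, A, config)
  pick <- if (f1$score$distance <= f2$score$distance) f1 else f2
  out <- pick$score$distance
  attr(out, "score") <- pick$score
  out
}
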