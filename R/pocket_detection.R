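# pocket_detection: Ligsite-style grid scanning around target residues,
# deep-volume computation, clustering and target-contact filtering.
#
# Grid label codes: 0 solvent, 1 protein, 2 pocket, 3 deep pocket.

LBL_SOLVENT <- 0L
LBL_PROTEIN <- 1L
LBL_POCKET <- 2L
LBL_DEEP <- 3L

#' The classic Ligsite scan-direction set
#'
#' Three lattice axes plus the four body diagonals.
#' @return 7 x 3 integer matrix of lattice step vectors
#' @export
ligsite_directions <- function() {
  matrix(as.integer(c(1, 0, 0,
                      0, 1, 0,
                      0, 0, 1,
                      1, 1, 1,
                      1, 1, -1,
                      1, -1, 1,
                      1, -1, -1)), ncol = 3, byrow = TRUE)
}

#' Pocket-grid parameters
#'
#' @param edge_length cube edge of the candidate grid (Angstrom)
#' @param spacing lattice spacing (Angstrom)
#' @param scan_directions integer matrix of lattice scan directions
#' @param min_bounded_directions how many scan directions must bound a
#'   solvent point for it to become a pocket point
#' @param burial_distance a pocket point strictly farther than this from any
#'   solvent point becomes deep pocket (Angstrom)
#' @param contact_tolerance clusters must have a point within
#'   (atom vdW radius + this) of a target-residue atom to be retained
#' @return list of class `grid_params`
#' @export
grid_params <- function(edge_length = 24, spacing = 0.5,
                        scan_directions = ligsite_directions(),
                        min_bounded_directions = 1L,
                        burial_distance = 2.5,
                        contact_tolerance = 1.0) {
  stopifnot(spacing > 0, edge_length >= 4 * spacing, burial_distance > 0,
            min_bounded_directions >= 1, is.matrix(scan_directions),
            ncol(scan_directions) == 3)
  base::structure(list(edge_length = edge_length, spacing = spacing,
                 scan_directions = scan_directions,
                 min_bounded_directions = as.integer(min_bounded_directions),
                 burial_distance = burial_distance,
                 contact_tolerance = contact_tolerance),
            class = "grid_params")
}

#' Build an empty pocket grid around target residues
#'
#' A cubic grid of edge `edge_length` centred at the (unit-mass) centre of
#' mass of the target residues' atoms, all points initialised solvent.
#'
#' @param structure a `pocket_structure`
#' @param target_residues one or two residue ids ("A:93" style or a
#'   data.frame with chain/resno)
#' @param params a [grid_params()] object
#' @return list of class `pocket_grid`
#' @export
build_grid <- function(structure, target_residues, params = grid_params()) {
  tgt <- parse_residue_ids(target_residues)
  stopifnot(nrow(tgt) %in% 1:2)
  rows <- residue_rows(structure, tgt)
  center <- colMeans(coords(structure)[rows, , drop = FALSE])
  nside <- as.integer(round(params$edge_length / params$spacing)) + 1L
  dims <- rep(nside, 3L)
  origin <- center - (nside - 1L) * params$spacing / 2
  base::structure(list(origin = origin, spacing = params$spacing, dims = dims,
                 labels = integer(prod(dims)), target = tgt,
                 center = center, params = params, solvent_dist = NULL,
                 retained = NULL),
            class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<pocket_grid> %dx%dx%d @ %.2f A (solvent %d, protein %d, pocket %d, deep %d)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Cartesian coordinates of grid points
#' @param grid a `pocket_grid`
#' @param idx 1-based linear point indices (default: all)
#' @return length(idx) x 3 matrix
#' @export
grid_point_coords <- function(grid, idx = seq_along(grid$labels)) {
  i0 <- idx - 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]
  cbind(grid$origin[1] + (i0 %% nx) * grid$spacing,
        grid$origin[2] + ((i0 %/% nx) %% ny) * grid$spacing,
        grid$origin[3] + (i0 %/% (nx * ny)) * grid$spacing)
}

#' Map the protein van der Waals surface onto the grid
#'
#' Every grid point within the vdW radius of any atom centre is labelled
#' protein; all remaining points are solvent.
#'
#' @param grid a `pocket_grid`
#' @param structure a `pocket_structure` with radii assigned
#' @return the grid with protein/solvent labels
#' @export
classify_grid <- function(grid, structure) {
  if (!has_radii(structure))
    stop("assign_radii() must be called before classify_grid()")
  grid$labels <- grid_classify_cpp(coords(structure),
                                   structure$atoms$radius,
                                   grid$origin, grid$spacing, grid$dims)
  grid
}

#' Mark pocket points by bounded-segment scanning
#'
#' For each scan direction, maximal runs of solvent points bounded by
#' protein points at both ends are found; solvent points bounded in at
#' least `min_bounded_directions` directions are relabelled pocket.
#'
#' @param grid a classified `pocket_grid`
#' @param params a [grid_params()]; defaults to the grid's own
#' @return the grid with pocket labels
#' @export
mark_pockets <- function(grid, params = grid$params) {
  grid$labels <- grid_mark_cpp(grid$labels, grid$dims,
                               params$scan_directions,
                               params$min_bounded_directions)
  grid
}

#' Relabel well-sequestered pocket points as deep pocket
#'
#' Pocket points strictly farther than `burial_distance` from every
#' remaining solvent point become deep pocket. Distances are Euclidean
#' between grid-point centres (exact distance transform).
#'
#' @param grid a `pocket_grid` with pockets marked
#' @param params a [grid_params()]
#' @return the grid with deep labels and a `solvent_dist` field
#' @export
compute_deep <- function(grid, params = grid$params) {
  sd <- grid_solvent_dist_cpp(grid$labels, grid$dims, grid$spacing)
  grid$labels <- ifelse(grid$labels == LBL_POCKET & sd > params$burial_distance,
                        LBL_DEEP, grid$labels)
  grid$solvent_dist <- sd
  grid
}

#' Cluster pocket points and keep target-contacting clusters
#'
#' Connected components of pocket+deep points under 26-neighbour adjacency.
#' Clusters with no point within (vdW radius + contact tolerance) of any
#' target-residue atom are discarded. Retained clusters are sorted by deep
#' volume (descending), ties by smallest member index.
#'
#' @param grid a `pocket_grid` after [compute_deep()]
#' @param structure the `pocket_structure` (radii assigned)
#' @return list of `pocket_cluster` objects (possibly empty)
#' @export
cluster_pockets <- function(grid, structure) {
  comp <- grid_components_cpp(grid$labels, grid$dims)
  ncomp <- max(comp)
  if (ncomp == 0) return(list())
  trows <- residue_rows(structure, grid$target)
  txyz <- coords(structure)[trows, , drop = FALSE]
  trad <- structure$atoms$radius[trows]
  cell <- grid$spacing^3
  out <- list()
  for (cid in seq_len(ncomp)) {
    members <- which(comp == cid)
    deep <- members[grid$labels[members] == LBL_DEEP]
    pxyz <- grid_point_coords(grid, members)
    contact <- FALSE
    for (t in seq_len(nrow(txyz))) {
      thr <- trad[t] + grid$params$contact_tolerance
      d2 <- (pxyz[, 1] - txyz[t, 1])^2 + (pxyz[, 2] - txyz[t, 2])^2 +
        (pxyz[, 3] - txyz[t, 3])^2
      if (any(d2 <= thr^2)) { contact <- TRUE; break }
    }
    if (!contact) next
    out[[length(out) + 1L]] <- base::structure(
      list(points = members, deep_points = deep,
           pocket_volume = length(members) * cell,
           deep_volume = length(deep) * cell,
           contacts_target = TRUE),
      class = "pocket_cluster")
  }
  if (length(out) > 1) {
    ord <- order(-vapply(out, function(cl) cl$deep_volume, 0),
                 vapply(out, function(cl) min(cl$points), 0L))
    out <- out[ord]
  }
  out
}

#' Detect pockets near target residues
#'
#' Full pipeline: build grid, map vdW surface, mark bounded solvent
#' segments, compute deep volume, cluster and filter by target contact.
#'
#' @inheritParams build_grid
#' @return list of class `pocket_detection` with fields `grid`, `clusters`,
#'   `total_deep_volume` (Angstrom^3)
#' @export
detect_pockets <- function(structure, target_residues, params = grid_params()) {
  grid <- build_grid(structure, target_residues, params)
  grid <- classify_grid(grid, structure)
  grid <- mark_pockets(grid, params)
  grid <- compute_deep(grid, params)
  clusters <- cluster_pockets(grid, structure)
  grid$retained <- if (length(clusters) > 0)
    sort(unique(unlist(lapply(clusters, `[[`, "points")))) else integer(0)
  base::structure(list(grid = grid, clusters = clusters,
                 total_deep_volume = sum(vapply(clusters, function(cl)
                   cl$deep_volume, 0))),
            class = "pocket_detection")
}

#' @export
print.pocket_detection <- function(x, ...) {
  cat(sprintf("<pocket_detection> %d retained cluster(s), total deep volume %.2f A^3\n",
              length(x$clusters), x$total_deep_volume))
  invisible(x)
}

# fast one-shot deep volume used by the biased sampler
fast_deep_volume <- function(xyz, radii, target_rows, center, params) {
  nside <- as.integer(round(params$edge_length / params$spacing)) + 1L
  dims <- rep(nside, 3L)
  origin <- center - (nside - 1L) * params$spacing / 2
  deep_volume_cpp(xyz, radii, xyz[target_rows, , drop = FALSE],
                  radii[target_rows], origin, params$spacing, dims,
                  params$scan_directions, params$min_bounded_directions,
                  params$burial_distance, params$contact_tolerance)
}
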