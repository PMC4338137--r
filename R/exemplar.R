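# exemplar: build the "perfect ligand" map of a pocket — complementary
# polar probes plus greedy hydrophobic fill, then proximity clustering.

#' Exemplar construction parameters
#' @param hbond_distance heavy-atom-to-probe hydrogen-bond length (Angstrom)
#' @param min_spacing minimum centre-centre distance between exemplar atoms
#' @param cluster_threshold single-linkage proximity threshold (Angstrom)
#' @param hydrophobe_radius Gaussian radius for hydrophobe pseudo-atoms
#' @param polar_radius Gaussian radius for donor/acceptor probes
#' @param keep `"nearest"` keeps the linkage component closest to the
#'   target-pair centre of mass; `"all"` keeps every component
#' @return list of class `exemplar_params`
#' @export
exemplar_params <- function(hbond_distance = 2.9, min_spacing = 1.7,
                            cluster_threshold = 5.0,
                            hydrophobe_radius = 1.70, polar_radius = 1.50,
                            keep = c("nearest", "all")) {
  keep <- match.arg(keep)
  stopifnot(hbond_distance > 0, min_spacing > 0, cluster_threshold > 0)
  base::structure(list(hbond_distance = hbond_distance,
                       min_spacing = min_spacing,
                       cluster_threshold = cluster_threshold,
                       hydrophobe_radius = hydrophobe_radius,
                       polar_radius = polar_radius, keep = keep),
                  class = "exemplar_params")
}

# pocket/deep point indices restricted to retained clusters when available
pocket_point_idx <- function(grid, deep_only = FALSE) {
  lab <- if (deep_only) LBL_DEEP else c(LBL_POCKET, LBL_DEEP)
  idx <- which(grid$labels %in% lab)
  if (!is.null(grid$retained)) idx <- intersect(idx, grid$retained)
  idx
}

#' Place complementary polar probes in a pocket
#'
#' For every protein donor direction a candidate acceptor probe is placed
#' `hbond_distance` along the direction from the heavy atom (and a donor
#' probe for every protein acceptor). Probes are retained iff their nearest
#' grid point is not protein and a pocket or deep-pocket point lies within
#' one grid spacing; probes closer than `min_spacing` to an already
#' accepted probe are dropped so the exemplar spacing constraint holds.
#'
#' @param structure a `pocket_structure`
#' @param grid a `pocket_grid` with pocket/deep labels
#' @param polar_groups a [find_polar_groups()] table
#' @param params an [exemplar_params()]
#' @return a `typed_atoms` set (possibly empty)
#' @export
place_polar_probes <- function(structure, grid, polar_groups,
                               params = exemplar_params()) {
  pk_idx <- pocket_point_idx(grid)
  if (length(pk_idx) == 0 || nrow(polar_groups) == 0)
    return(typed_atoms(matrix(0, 0, 3), character(0), 1.5))
  pk_xyz <- grid_point_coords(grid, pk_idx)
  a <- structure$atoms
  acc_xyz <- matrix(0, 0, 3)
  feats <- character(0)
  for (q in seq_len(nrow(polar_groups))) {
    g <- polar_groups[q, ]
    hit <- which(a$chain == g$chain & a$resno == g$resno & a$name == g$atom)
    if (length(hit) == 0) next
    heavy <- c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
    probe <- heavy + params$hbond_distance * c(g$dx, g$dy, g$dz)
    # nearest grid point must not be protein
    ijk <- pmin(pmax(round((probe - grid$origin) / grid$spacing), 0),
                grid$dims - 1L)
    nearest <- as.integer(ijk[1] + grid$dims[1] * (ijk[2] + grid$dims[2] * ijk[3])) + 1L
    if (grid$labels[nearest] == LBL_PROTEIN) next
    d2 <- (pk_xyz[, 1] - probe[1])^2 + (pk_xyz[, 2] - probe[2])^2 +
      (pk_xyz[, 3] - probe[3])^2
    if (min(d2) > grid$spacing^2) next
    if (nrow(acc_xyz) > 0) {
      dd <- (acc_xyz[, 1] - probe[1])^2 + (acc_xyz[, 2] - probe[2])^2 +
        (acc_xyz[, 3] - probe[3])^2
      if (min(dd) < params$min_spacing^2) next
    }
    acc_xyz <- rbind(acc_xyz, probe)
    feats <- c(feats, if (g$kind == "donor") "acceptor" else "donor")
  }
  typed_atoms(acc_xyz, feats, params$polar_radius)
}

#' Greedy hydrophobic fill of the deep pocket volume
#'
#' Candidate sites are the deep-pocket grid points ordered by burial depth
#' (distance to the nearest solvent point, descending; ties by grid index).
#' A site is accepted if it is at least `min_spacing` from every exemplar
#' atom placed so far (polar probes included) and becomes a hydrophobe.
#'
#' @param grid a `pocket_grid` after [compute_deep()]
#' @param placed `typed_atoms` already in the exemplar (the polar probes)
#' @param params an [exemplar_params()]
#' @return `placed` plus the accepted hydrophobes
#' @export
fill_hydrophobic <- function(grid, placed, params = exemplar_params()) {
  deep_idx <- pocket_point_idx(grid, deep_only = TRUE)
  if (length(deep_idx) == 0) return(placed)
  if (is.null(grid$solvent_dist))
    stop("compute_deep() must run before fill_hydrophobic()")
  ord <- order(-grid$solvent_dist[deep_idx], deep_idx)
  cand <- grid_point_coords(grid, deep_idx[ord])
  acc <- as.matrix(placed[, c("x", "y", "z")])
  keep <- integer(0)
  min2 <- params$min_spacing^2
  for (q in seq_len(nrow(cand))) {
    p <- cand[q, ]
    if (nrow(acc) > 0) {
      d2 <- (acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 + (acc[, 3] - p[3])^2
      if (min(d2) < min2) next
    }
    acc <- rbind(acc, p)
    keep <- c(keep, q)
  }
  if (length(keep) == 0) return(placed)
  hydro <- typed_atoms(cand[keep, , drop = FALSE],
                       rep("hydrophobe", length(keep)),
                       params$hydrophobe_radius)
  out <- rbind(placed, hydro)
  attr(out, "label") <- attr(placed, "label")
  class(out) <- class(placed)
  out
}

#' Proximity-cluster exemplar atoms and keep the target-proximal component
#'
#' Single-linkage components at `cluster_threshold`; by default the
#' component whose centroid is nearest the target-pair centre of mass is
#' retained (ties go to the larger component), so two small pockets
#' flanking the target residues are represented by a single exemplar.
#'
#' @param atoms a non-empty `typed_atoms` set
#' @param grid the `pocket_grid` (supplies the target centre)
#' @param params an [exemplar_params()]
#' @return an `exemplar` object
#' @export
cluster_exemplar <- function(atoms, grid, params = exemplar_params()) {
  if (nrow(atoms) == 0) stop("cannot cluster an empty exemplar atom set")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  memb <- if (nrow(atoms) == 1) 1L else
    cutree(hclust(dist(xyz), method = "single"),
           h = params$cluster_threshold)
  if (params$keep == "nearest" && max(memb) > 1) {
    cls <- sort(unique(memb))
    cdist <- vapply(cls, function(k)
      vnorm(colMeans(xyz[memb == k, , drop = FALSE]) - grid$center), 0)
    csize <- vapply(cls, function(k) sum(memb == k), 0L)
    pick <- cls[order(cdist, -csize)][1]
    atoms <- atoms[memb == pick, , drop = FALSE]
    class(atoms) <- c("typed_atoms", "data.frame")
  }
  base::structure(list(atoms = atoms,
                       source = list(target = grid$target),
                       deep_volume = NA_real_),
                  class = "exemplar")
}

#' @export
print.exemplar <- function(x, ...) {
  tab <- table(factor(x$atoms$feature, levels = FEATURE_LEVELS))
  cat(sprintf("<exemplar> %d atoms (%s), deep volume %.2f A^3\n",
              nrow(x$atoms),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$deep_volume))
  invisible(x)
}

#' Build the exemplar of the pocket at a target site
#'
#' Composition of [detect_pockets()], [place_polar_probes()],
#' [fill_hydrophobic()] and [cluster_exemplar()].
#'
#' @param structure a `pocket_structure` with radii assigned
#' @param target_residues one or two residue ids
#' @param grid_params a [grid_params()]
#' @param params an [exemplar_params()]
#' @param polar_groups optional precomputed [find_polar_groups()] table
#' @param label label recorded on the exemplar
#' @return an `exemplar`; errors with "no pocket at target site" when no
#'   retained cluster exists
#' @export
build_exemplar <- function(structure, target_residues,
                           grid_params = pocketeer::grid_params(),
                           params = exemplar_params(),
                           polar_groups = NULL, label = "") {
  det <- detect_pockets(structure, target_residues, grid_params)
  if (length(det$clusters) == 0) stop("no pocket at target site")
  if (is.null(polar_groups))
    polar_groups <- find_polar_groups(structure, warn = FALSE)
  placed <- place_polar_probes(structure, det$grid, polar_groups, params)
  filled <- fill_hydrophobic(det$grid, placed, params)
  if (nrow(filled) == 0) stop("no pocket at target site: empty exemplar")
  ex <- cluster_exemplar(filled, det$grid, params)
  ex$deep_volume <- det$total_deep_volume
  ex$source$label <- label
  attr(ex$atoms, "label") <- label
  ex
}

# ---- exemplar file round-trip (PDB-like; feature coded in residue name) ----

FEATURE_RESNAME <- c(hydrophobe = "HPH", donor = "DON", acceptor = "ACC")
FEATURE_ELEMENT <- c(hydrophobe = "C", donor = "N", acceptor = "O")

#' Write an exemplar to a PDB-like file
#'
#' HETATM records with the feature encoded in the residue name (HPH/DON/ACC)
#' and the Gaussian radius in the occupancy column; provenance and deep
#' volume go in REMARK lines. Positions round-trip at 3 decimals.
#'
#' @param exemplar an `exemplar`
#' @param path output path; if `NULL` the lines are returned
#' @export
write_exemplar <- function(exemplar, path = NULL) {
  at <- exemplar$atoms
  if (nrow(at) == 0) stop("refusing to write an empty exemplar")
  hdr <- c(sprintf("REMARK EXEMPLAR label=%s", exemplar$source$label %||% ""),
           sprintf("REMARK EXEMPLAR deep_volume=%.3f", exemplar$deep_volume))
  rn <- FEATURE_RESNAME[at$feature]
  el <- FEATURE_ELEMENT[at$feature]
  recs <- sprintf("HETATM%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  seq_len(nrow(at)), sprintf(" %-3s", el), rn, "X",
                  seq_len(nrow(at)), at$x, at$y, at$z, at$radius, 0.0, el)
  lines <- c(hdr, recs, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read an exemplar written by [write_exemplar()]
#' @param x path or character lines
#' @return an `exemplar`
#' @export
read_exemplar <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else unlist(strsplit(x, "\n", fixed = TRUE))
  recs <- lines[grepl("^HETATM", lines)]
  if (length(recs) == 0) stop("no exemplar records found")
  rn <- trimws(substr(recs, 18, 20))
  feat_map <- setNames(names(FEATURE_RESNAME), FEATURE_RESNAME)
  feature <- unname(feat_map[rn])
  if (anyNA(feature))
    stop("malformed exemplar record: unknown feature residue name '",
         rn[which(is.na(feature))[1]], "'")
  xyz <- cbind(as.numeric(substr(recs, 31, 38)),
               as.numeric(substr(recs, 39, 46)),
               as.numeric(substr(recs, 47, 54)))
  radius <- as.numeric(substr(recs, 55, 60))
  if (anyNA(xyz) || anyNA(radius)) stop("malformed exemplar record: bad numeric field")
  lab <- sub("^REMARK EXEMPLAR label=", "",
             grep("^REMARK EXEMPLAR label=", lines, value = TRUE)[1])
  dv <- suppressWarnings(as.numeric(sub("^REMARK EXEMPLAR deep_volume=", "",
             grep("^REMARK EXEMPLAR deep_volume=", lines, value = TRUE)[1])))
  base::structure(list(atoms = typed_atoms(xyz, feature, radius,
                                           label = lab %||% ""),
                       source = list(label = lab %||% ""),
                       deep_volume = dv),
                  class = "exemplar")
}
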