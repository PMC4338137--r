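# synthetic_fixtures: deterministic pseudo-proteins with carved pockets,
# matched families with known ground truth, and toy ddG tables. These are
# geometric stand-ins (atoms, radii, residue ids, polar-group geometry),
# not folded polypeptides — sufficient for every algorithm in the package.

#' Generate a cup-capable pseudo-protein shell
#'
#' Atoms on a face-centred-cubic lattice restricted to a thick spherical
#' shell. FCC at nearest-neighbour distance `packing` guarantees both the
#' minimum pairwise spacing and a sealed wall: the largest lattice hole
#' (the octahedral interstice, 0.707 * packing from the nearest atom) is
#' well inside the 1.80 A sulfur vdW radius, so no solvent scan line can
#' tunnel through the wall. Every atom is its own residue (resname SHL) so
#' any atom can serve as a target residue. Fully deterministic.
#'
#' @param radius outer shell radius (Angstrom)
#' @param packing lattice nearest-neighbour distance (Angstrom); must stay
#'   below 2 * sqrt(2) * 1.8 / 2 = 2.55 to keep the wall sealed
#' @param thickness radial wall thickness (Angstrom); the default is a
#'   solid ball, so carved cavities can never tunnel into an inner void
#' @param element shell atom element
#' @param chain chain id
#' @return a `pocket_structure` with attributes `shell_radius`, `packing`
#' @export
make_shell_protein <- function(radius = 12, packing = 2.2, thickness = radius,
                               element = "S", chain = "A") {
  stopifnot(thickness <= radius, thickness > packing)
  h <- packing / sqrt(2)  # FCC half-cell
  m <- ceiling(radius / h)
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]
  xyz <- as.matrix(g) * h
  # fixed generic rotation: decouples the lattice from the carve axes and
  # the grid scan directions
  xyz <- xyz %*% t(rotation_from_vector(c(0.41, 0.79, 0.23)))
  r <- sqrt(rowSums(xyz^2))
  xyz <- xyz[r <= radius & r >= radius - thickness, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 20) stop("shell fixture needs at least 20 atoms")
  # deterministic order: by radius descending then lexicographic
  ord <- order(-round(sqrt(rowSums(xyz^2)), 6), xyz[, 1], xyz[, 2], xyz[, 3])
  xyz <- xyz[ord, , drop = FALSE]
  atoms <- data.frame(serial = seq_len(n), name = element, element = element,
                      resname = "SHL", chain = chain, resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = NA_real_, stringsAsFactors = FALSE)
  s <- new_structure(atoms)
  attr(s, "shell_radius") <- radius
  attr(s, "packing") <- packing
  s
}

#' Carve operations for pseudo-protein pockets
#'
#' A cylinder is bored inward from the shell surface along `direction`
#' (channel of given radius and depth); a sphere is embedded with its top
#' at depth 0.
#'
#' @param direction outward axis (need not be unit)
#' @param radius carve radius (Angstrom)
#' @param depth carve depth below the outer surface (Angstrom)
#' @return list of class `carve_op`
#' @export
carve_cylinder <- function(direction = c(0, 0, 1), radius = 3, depth = 8) {
  base::structure(list(type = "cylinder", direction = unit(direction),
                       radius = radius, depth = depth),
                  class = "carve_op")
}

#' @rdname carve_cylinder
#' @export
carve_sphere <- function(direction = c(0, 0, 1), radius = 4, depth = 8) {
  base::structure(list(type = "sphere", direction = unit(direction),
                       radius = radius, depth = depth),
                  class = "carve_op")
}

# orthonormal basis perpendicular to u
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Carve a pocket out of a shell pseudo-protein
#'
#' Atoms inside the carve region are removed; the remaining rim bounds the
#' cavity along grid scan lines.
#'
#' @param structure a [make_shell_protein()] structure
#' @param op a `carve_op`
#' @return the carved `pocket_structure`
#' @export
carve_pocket <- function(structure, op) {
  stopifnot(inherits(op, "carve_op"))
  rout <- attr(structure, "shell_radius")
  if (is.null(rout)) stop("carve_pocket() expects a shell fixture")
  xyz <- coords(structure)
  u <- op$direction
  axial <- xyz %*% u
  radial2 <- rowSums(xyz^2) - axial^2
  inside <- if (op$type == "cylinder") {
    axial > (rout - op$depth) & radial2 < op$radius^2
  } else {
    ctr <- (rout - op$depth + op$radius) * u
    rowSums(sweep(xyz, 2, ctr)^2) < op$radius^2
  }
  if (!any(inside)) stop("carve region does not intersect the structure")
  if (mean(inside) > 0.5) stop("carve would remove more than half the atoms")
  out <- structure
  out$atoms <- structure$atoms[!inside, , drop = FALSE]
  rownames(out$atoms) <- NULL
  attr(out, "shell_radius") <- rout
  attr(out, "packing") <- attr(structure, "packing")
  out
}

DECORATION_ATOMS <- list(
  lys = list(resname = "LYS", ante = c("CE", "C"), head = c("NZ", "N")),
  asp = list(resname = "ASP", ante = c("CG", "C"), head = c("OD1", "O")),
  ser = list(resname = "SER", ante = c("CB", "C"), head = c("OG", "O"))
)

#' Add polar side-chain decorations pointing into a carved cavity
#'
#' Places `n` two-atom pseudo-side-chains (antecedent carbon + polar head)
#' on the cavity wall so their idealised hydrogen-bond directions point
#' into the pocket volume: `lys` contributes a donor, `asp` an acceptor,
#' `ser` both.
#'
#' @param structure a carved shell structure
#' @param op the `carve_op` that made the cavity
#' @param kind decoration chemistry: "lys", "asp" or "ser"
#' @param n number of decorations, spread around the cavity wall
#' @param depth_frac fractional depth of the decoration ring
#' @return the decorated structure
#' @export
decorate_pocket <- function(structure, op, kind = c("lys", "asp", "ser"),
                            n = 2, depth_frac = 0.5) {
  kind <- match.arg(kind)
  spec <- DECORATION_ATOMS[[kind]]
  rout <- attr(structure, "shell_radius")
  u <- op$direction
  pb <- perp_basis(u)
  a <- structure$atoms
  next_resno <- max(a$resno) + 1L
  next_serial <- max(a$serial) + 1L
  wall_r <- op$radius + 0.9  # polar head sits just behind the cavity wall
  axial <- rout - op$depth * depth_frac
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n + 0.3
    rdir <- cos(th) * pb$e1 + sin(th) * pb$e2
    head <- axial * u + wall_r * rdir
    ante <- axial * u + (wall_r + 1.4) * rdir
    a <- rbind(a,
      data.frame(serial = next_serial, name = spec$ante[1],
                 element = spec$ante[2], resname = spec$resname,
                 chain = a$chain[1], resno = next_resno,
                 x = ante[1], y = ante[2], z = ante[3], radius = NA_real_,
                 stringsAsFactors = FALSE),
      data.frame(serial = next_serial + 1L, name = spec$head[1],
                 element = spec$head[2], resname = spec$resname,
                 chain = a$chain[1], resno = next_resno,
                 x = head[1], y = head[2], z = head[3], radius = NA_real_,
                 stringsAsFactors = FALSE))
    next_resno <- next_resno + 1L
    next_serial <- next_serial + 2L
  }
  out <- structure
  out$atoms <- a
  rownames(out$atoms) <- NULL
  attr(out, "shell_radius") <- rout
  attr(out, "packing") <- attr(structure, "packing")
  out
}

#' Target residues at a carved cavity rim
#'
#' The two shell residues nearest to opposite points of the cavity mouth,
#' mirroring the role of energetically dominant interfacial residue pairs.
#'
#' @param structure a carved shell structure
#' @param op the `carve_op`
#' @return character vector of two residue ids ("chain:resno")
#' @export
rim_targets <- function(structure, op) {
  rout <- attr(structure, "shell_radius")
  u <- op$direction
  pb <- perp_basis(u)
  xyz <- coords(structure)
  pick <- function(p) {
    d2 <- rowSums(sweep(xyz, 2, p)^2)
    i <- which.min(d2)
    sprintf("%s:%d", structure$atoms$chain[i], structure$atoms$resno[i])
  }
  p1 <- (rout - 0.5) * u + op$radius * pb$e1
  p2 <- (rout - 0.5) * u - op$radius * pb$e1
  unique(c(pick(p1), pick(p2)))
}

#' Build a synthetic protein family with known pocket ground truth
#'
#' Shell pseudo-proteins sharing pocket shape "A" or carrying the distinct
#' shape "B" according to `assignment`; reference ("inhibitor-bound")
#' structures carry one pocket each. The truth table lists which reference
#' pocket each family member can present. Per-protein coordinate jitter
#' makes family members non-identical.
#'
#' @param assignment named list: protein id -> character vector of pocket
#'   ids the protein carries
#' @param carves named list of `carve_op`s (one per pocket id)
#' @param decorations named list: pocket id -> list(kind=, n=)
#' @param radius,packing,thickness shell geometry, see
#'   [make_shell_protein()]
#' @param jitter_sd per-coordinate SD of the seeded per-protein jitter
#' @param seed RNG seed (jitter only; everything else is deterministic)
#' @return list with `structures`, `targets` (per protein, per pocket),
#'   `references`, `ref_targets`, `truth` (reference/protein/binder),
#'   `assignment`
#' @export
make_family <- function(assignment = list(P1 = "A", P2 = "A", P3 = "B"),
                        carves = list(
                          A = carve_cylinder(c(0, 0, 1), radius = 3, depth = 5.5),
                          B = carve_cylinder(c(0, 0, -1), radius = 4.5, depth = 3.5)),
                        decorations = list(A = list(kind = "lys", n = 2),
                                           B = list(kind = "asp", n = 3)),
                        radius = 12, packing = 2.2, thickness = radius,
                        jitter_sd = 0.1, seed = 1) {
  pockets <- sort(unique(unlist(assignment)))
  if (!all(pockets %in% names(carves)))
    stop("assignment names pockets without carve specs: ",
         paste(setdiff(pockets, names(carves)), collapse = ", "))
  shell <- make_shell_protein(radius, packing, thickness)
  apply_pocket <- function(s, pid) {
    s <- carve_pocket(s, carves[[pid]])
    dec <- decorations[[pid]]
    if (!is.null(dec))
      s <- decorate_pocket(s, carves[[pid]], dec$kind, dec$n)
    s
  }
  references <- ref_targets <- list()
  for (pid in names(carves)) {
    references[[pid]] <- assign_radii(apply_pocket(shell, pid))
    ref_targets[[pid]] <- rim_targets(references[[pid]], carves[[pid]])
  }
  structures <- targets <- list()
  for (q in seq_along(assignment)) {
    prot <- names(assignment)[q]
    s <- shell
    for (pid in assignment[[q]]) s <- apply_pocket(s, pid)
    s <- withr::with_seed(seed + q, {
      xyz <- coords(s) + matrix(rnorm(3 * nrow(s$atoms), 0, jitter_sd),
                                ncol = 3)
      set_coords(s, xyz)
    })
    structures[[prot]] <- assign_radii(s)
    targets[[prot]] <- lapply(setNames(nm = assignment[[q]]), function(pid)
      rim_targets(structures[[prot]], carves[[pid]]))
  }
  truth <- expand.grid(reference = names(carves),
                       protein = names(assignment),
                       stringsAsFactors = FALSE)
  truth$binder <- mapply(function(r, p) r %in% assignment[[p]],
                         truth$reference, truth$protein)
  list(structures = structures, targets = targets, references = references,
       ref_targets = ref_targets, truth = truth, assignment = assignment)
}

#' Synthetic per-residue ddG table
#'
#' Exact values at hotspot residues, small seeded half-normal noise for the
#' remaining listed interfacial residues — a stand-in for computational
#' alanine-scanning output.
#'
#' @param structure a `pocket_structure`
#' @param hotspots named numeric vector, e.g. `c("A:5" = 3.0)`
#' @param residues interfacial residue ids to include (default: hotspots)
#' @param noise_sd half-normal noise SD for non-hotspot residues
#' @param seed RNG seed
#' @return a `ddg_table`
#' @export
make_ddg_table <- function(structure, hotspots, residues = names(hotspots),
                           noise_sd = 0.1, seed = 1) {
  residues <- unique(c(names(hotspots), residues))
  ids <- parse_residue_ids(residues)
  for (q in seq_len(nrow(ids)))  # errors for unknown residues
    residue_rows(structure, ids[q, , drop = FALSE])
  vals <- withr::with_seed(seed, abs(rnorm(nrow(ids), 0, noise_sd)))
  hot <- match(residues, names(hotspots))
  vals[!is.na(hot)] <- hotspots[hot[!is.na(hot)]]
  read_ddg_table(data.frame(chain = ids$chain, resno = ids$resno,
                            ddg = vals, stringsAsFactors = FALSE))
}
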