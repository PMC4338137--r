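# structure_io: protein/ligand reading and writing, vdW radii, and
# hydrogen-bond donor/acceptor typing.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Default van der Waals radius table
#'
#' Conventional element radii used to map the protein van der Waals surface
#' onto the pocket grid. Elements absent from the table fall back to
#' `default` with a warning in [assign_radii()].
#'
#' @return named numeric vector of radii in Angstrom
#' @export
default_radius_table <- function() {
  c(H = 1.09, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resno")]))
  cat(sprintf("<pocket_structure> %d atoms, %d residues, %d chain(s)\n",
              nrow(a), nres, length(unique(a$chain))))
  invisible(x)
}

#' Atom coordinates of a structure
#' @param structure a `pocket_structure`
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param structure a `pocket_structure`
#' @param xyz n x 3 matrix matching the atom order
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Residue index of a structure
#' @param structure a `pocket_structure`
#' @return named list mapping "chain:resno" to atom row indices
#' @export
residue_index <- function(structure) {
  key <- paste(structure$atoms$chain, structure$atoms$resno, sep = ":")
  split(seq_len(nrow(structure$atoms)), factor(key, levels = unique(key)))
}

# parse residue ids given as "A:93" strings or a data.frame(chain, resno)
parse_residue_ids <- function(ids) {
  if (is.data.frame(ids)) {
    stopifnot(all(c("chain", "resno") %in% names(ids)))
    return(data.frame(chain = as.character(ids$chain),
                      resno = as.integer(ids$resno),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(as.character(ids), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("residue ids must look like 'A:93', got: ",
                     paste(ids[bad], collapse = ", "))
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

residue_rows <- function(structure, ids) {
  ids <- parse_residue_ids(ids)
  out <- integer(0)
  for (q in seq_len(nrow(ids))) {
    hit <- which(structure$atoms$chain == ids$chain[q] &
                 structure$atoms$resno == ids$resno[q])
    if (length(hit) == 0)
      stop(sprintf("target residue %s:%d not found in structure",
                   ids$chain[q], ids$resno[q]))
    out <- c(out, hit)
  }
  out
}

# ---- PDB reading/writing ----

#' Read a protein structure from PDB text
#'
#' Parses ATOM/HETATM records from PDB-format text. Water residues are
#' dropped; for alternate locations only blank or 'A' records are kept.
#'
#' @param x path to a PDB file, or a character vector of PDB lines
#' @return a `pocket_structure`
#' @export
read_structure <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else unlist(strsplit(x, "\n", fixed = TRUE))
  sel <- grepl("^(ATOM  |HETATM)", lines)
  recs <- lines[sel]
  recno <- which(sel)
  if (length(recs) == 0) stop("empty structure: no ATOM/HETATM records")
  f <- function(from, to) substr(recs, from, to)
  serial <- suppressWarnings(as.integer(f(7, 11)))
  name <- trimws(f(13, 16))
  altloc <- f(17, 17)
  resname <- trimws(f(18, 20))
  chain <- f(22, 22)
  resno <- suppressWarnings(as.integer(f(23, 26)))
  x_ <- suppressWarnings(as.numeric(f(31, 38)))
  y_ <- suppressWarnings(as.numeric(f(39, 46)))
  z_ <- suppressWarnings(as.numeric(f(47, 54)))
  element <- toupper(trimws(f(77, 78)))
  bad <- which(is.na(x_) | is.na(y_) | is.na(z_) | is.na(resno) | is.na(serial))
  if (length(bad) > 0)
    stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                 recno[bad[1]], recs[bad[1]]))
  # element fallback from the atom name (first letter that is not a digit)
  noel <- element == ""
  if (any(noel))
    element[noel] <- toupper(substr(gsub("^[0-9' ]+", "", name[noel]), 1, 1))
  keep <- !(resname %in% WATER_RESNAMES) & altloc %in% c(" ", "", "A")
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, chain = chain, resno = resno,
                      x = x_, y = y_, z = z_, radius = NA_real_,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty structure: all records filtered out")
  new_structure(atoms)
}

#' Write a structure as PDB text
#' @param structure a `pocket_structure`
#' @param path optional output file; if `NULL` the lines are returned
#' @return character vector of PDB lines, invisibly when `path` is given
#' @export
write_structure <- function(structure, path = NULL) {
  a <- structure$atoms
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial %% 100000, nm, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, 1.0, 0.0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Assign van der Waals radii to every atom
#'
#' @param structure a `pocket_structure`
#' @param radius_table named numeric vector, element -> radius (Angstrom)
#' @param default radius for elements not in the table (a warning lists them)
#' @return the structure with its `radius` column filled
#' @export
assign_radii <- function(structure, radius_table = default_radius_table(),
                         default = 1.80) {
  el <- toupper(structure$atoms$element)
  r <- unname(radius_table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no vdW radius for element(s) ",
            paste(sort(unique(el[unknown])), collapse = ", "),
            "; using default ", default, " A")
    r[unknown] <- default
  }
  structure$atoms$radius <- r
  structure
}

has_radii <- function(structure) !anyNA(structure$atoms$radius)

# ---- polar group typing ----

# side-chain donor/acceptor table: for each residue, polar heavy atoms with
# the rule used to build an idealised direction. "bond" extends the
# antecedent->atom bond; "bisector" points away from the two antecedents.
SIDECHAIN_POLAR <- list(
  SER = list(list(atom = "OG",  kind = c("donor", "acceptor"), rule = "bond", ante = "CB")),
  THR = list(list(atom = "OG1", kind = c("donor", "acceptor"), rule = "bond", ante = "CB")),
  TYR = list(list(atom = "OH",  kind = c("donor", "acceptor"), rule = "bond", ante = "CZ")),
  LYS = list(list(atom = "NZ",  kind = "donor", rule = "bond", ante = "CE")),
  ARG = list(list(atom = "NH1", kind = "donor", rule = "bond", ante = "CZ"),
             list(atom = "NH2", kind = "donor", rule = "bond", ante = "CZ"),
             list(atom = "NE",  kind = "donor", rule = "bisector", ante = c("CD", "CZ"))),
  ASP = list(list(atom = "OD1", kind = "acceptor", rule = "bond", ante = "CG"),
             list(atom = "OD2", kind = "acceptor", rule = "bond", ante = "CG")),
  GLU = list(list(atom = "OE1", kind = "acceptor", rule = "bond", ante = "CD"),
             list(atom = "OE2", kind = "acceptor", rule = "bond", ante = "CD")),
  ASN = list(list(atom = "OD1", kind = "acceptor", rule = "bond", ante = "CG"),
             list(atom = "ND2", kind = "donor", rule = "bond", ante = "CG")),
  GLN = list(list(atom = "OE1", kind = "acceptor", rule = "bond", ante = "CD"),
             list(atom = "NE2", kind = "donor", rule = "bond", ante = "CD")),
  HIS = list(list(atom = "ND1", kind = c("donor", "acceptor"), rule = "bisector", ante = c("CG", "CE1")),
             list(atom = "NE2", kind = c("donor", "acceptor"), rule = "bisector", ante = c("CD2", "CE1"))),
  TRP = list(list(atom = "NE1", kind = "donor", rule = "bisector", ante = c("CD1", "CE2")))
)

polar_group_row <- function(chain, resno, resname, atom, kind, dir) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             kind = kind, dx = dir[1], dy = dir[2], dz = dir[3],
             stringsAsFactors = FALSE)
}

#' Find hydrogen-bond donor and acceptor groups of a protein
#'
#' Types backbone amide N (donor, except proline), backbone carbonyl O
#' (acceptor, two sp2 lone-pair directions) and side-chain polar atoms from
#' a documented residue table. Directions are idealised unit vectors built
#' from bonded-neighbour geometry (explicit amide H is used when present).
#'
#' @param structure a `pocket_structure`
#' @param warn emit warnings for skipped residues/groups
#' @return data.frame of class `polar_groups`: one row per (atom, kind,
#'   direction) with unit direction columns `dx, dy, dz`
#' @export
find_polar_groups <- function(structure, warn = TRUE) {
  a <- structure$atoms
  ridx <- residue_index(structure)
  rows <- list()
  skipped_res <- character(0)
  skipped_groups <- 0L
  pos <- function(rws, nm) {
    i <- rws[a$name[rws] == nm]
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  keys <- names(ridx)
  for (q in seq_along(ridx)) {
    rws <- ridx[[q]]
    resname <- a$resname[rws[1]]
    chain <- a$chain[rws[1]]
    resno <- a$resno[rws[1]]
    if (!(resname %in% STANDARD_AA)) {
      skipped_res <- c(skipped_res, resname)
      next
    }
    N <- pos(rws, "N"); CA <- pos(rws, "CA"); C <- pos(rws, "C")
    O <- pos(rws, "O"); H <- pos(rws, "H") %||% pos(rws, "HN")
    # backbone donor
    if (resname != "PRO" && !is.null(N)) {
      dir <- NULL
      if (!is.null(H)) {
        dir <- unit(H - N)
      } else {
        # idealised: opposite the bisector of N-CA and N-C(prev)
        prev <- which(a$chain == chain & a$resno == resno - 1L & a$name == "C")
        if (!is.null(CA) && length(prev) > 0) {
          Cp <- c(a$x[prev[1]], a$y[prev[1]], a$z[prev[1]])
          dir <- unit(-(unit(CA - N) + unit(Cp - N)))
        }
      }
      if (is.null(dir)) skipped_groups <- skipped_groups + 1L
      else rows[[length(rows) + 1L]] <-
          polar_group_row(chain, resno, resname, "N", "donor", dir)
    }
    # backbone acceptor: two lone pairs in the sp2 plane, +-60 deg off C=O
    if (!is.null(O)) {
      if (!is.null(C) && !is.null(CA)) {
        u <- unit(O - C)
        w <- unit(CA - C)
        p <- w - sum(w * u) * u
        if (vnorm(p) > 1e-8) {
          p <- unit(p)
          for (s in c(-1, 1)) {
            dir <- unit(cos(pi / 3) * u + s * sin(pi / 3) * (-p))
            rows[[length(rows) + 1L]] <-
              polar_group_row(chain, resno, resname, "O", "acceptor", dir)
          }
        } else skipped_groups <- skipped_groups + 1L
      } else skipped_groups <- skipped_groups + 1L
    }
    # side chains
    for (g in SIDECHAIN_POLAR[[resname]] %||% list()) {
      X <- pos(rws, g$atom)
      if (is.null(X)) next
      dir <- NULL
      if (g$rule == "bond") {
        A1 <- pos(rws, g$ante)
        if (!is.null(A1)) dir <- unit(X - A1)
      } else {
        A1 <- pos(rws, g$ante[1]); A2 <- pos(rws, g$ante[2])
        if (!is.null(A1) && !is.null(A2)) dir <- unit(-(unit(A1 - X) + unit(A2 - X)))
      }
      if (is.null(dir)) { skipped_groups <- skipped_groups + 1L; next }
      for (k in g$kind)
        rows[[length(rows) + 1L]] <-
          polar_group_row(chain, resno, resname, g$atom, k, dir)
    }
  }
  if (warn && length(skipped_res) > 0)
    warning("skipped ", length(skipped_res), " non-standard residue(s): ",
            paste(sort(unique(skipped_res)), collapse = ", "))
  if (warn && skipped_groups > 0)
    warning(skipped_groups,
            " polar group(s) skipped: missing heavy atoms for direction construction")
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    polar_group_row("", 0L, "", "", "", c(0, 0, 1))[0, ]
  class(out) <- c("polar_groups", "data.frame")
  out
}

# ---- typed atom sets ----

FEATURE_LEVELS <- c("hydrophobe", "donor", "acceptor")

#' Construct a typed pseudo-atom set
#'
#' The shared representation for exemplars and ligand conformers: positions
#' plus a pharmacophore feature (hydrophobe/donor/acceptor) and a Gaussian
#' radius per atom.
#'
#' @param xyz n x 3 matrix of positions (Angstrom)
#' @param feature character vector in `c("hydrophobe","donor","acceptor")`
#' @param radius positive radii (Angstrom), recycled
#' @param label free-text label
#' @return data.frame of class `typed_atoms`
#' @export
typed_atoms <- function(xyz, feature, radius, label = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(feature) == nrow(xyz), all(feature %in% FEATURE_LEVELS))
  radius <- rep_len(radius, nrow(xyz))
  stopifnot(all(radius > 0), all(is.finite(xyz)))
  out <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    feature = as.character(feature), radius = radius,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("typed_atoms", "data.frame")
  out
}

#' Coerce to a typed atom set
#' @param x a `typed_atoms`, `exemplar`, or data.frame with the right columns
#' @export
as_typed_atoms <- function(x) {
  if (inherits(x, "typed_atoms")) return(x)
  if (inherits(x, "exemplar")) return(x$atoms)
  if (is.data.frame(x) && all(c("x", "y", "z", "feature", "radius") %in% names(x)))
    return(typed_atoms(as.matrix(x[, c("x", "y", "z")]), x$feature, x$radius))
  stop("cannot coerce to typed_atoms")
}

#' @export
print.typed_atoms <- function(x, ...) {
  tab <- table(factor(x$feature, levels = FEATURE_LEVELS))
  cat(sprintf("<typed_atoms> %d atoms (%s)%s\n", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if (nzchar(attr(x, "label") %||% "")) paste0(" '", attr(x, "label"), "'") else ""))
  invisible(x)
}

# ---- ligand reading ----

#' Read and type a small-molecule ligand
#'
#' Heavy atoms are typed by simple element/hydrogen rules: N/O with an
#' attached hydrogen become donors; oxygens, and nitrogens with a free
#' valence, become acceptors (an atom may be both); C, S, P and halogens
#' become hydrophobes. Hydrogens are dropped after typing.
#'
#' @param x path to the ligand file or character vector of lines
#' @param format `"sdf"` (V2000, read via ChemmineR) or `"pdb"`
#' @param radius_table element radius table for the Gaussian model
#' @return a `typed_atoms` set
#' @export
read_ligand <- function(x, format = c("sdf", "pdb"),
                        radius_table = default_radius_table()) {
  format <- match.arg(format)
  if (format == "sdf") read_ligand_sdf(x, radius_table)
  else read_ligand_pdb(x, radius_table)
}

ligand_typed_set <- function(xyz, element, has_h, n_neighbors, radius_table, label) {
  element <- toupper(element)
  heavy <- element != "H"
  xyz <- xyz[heavy, , drop = FALSE]
  element <- element[heavy]
  has_h <- has_h[heavy]
  n_neighbors <- n_neighbors[heavy]
  is_no <- element %in% c("N", "O")
  donor <- is_no & has_h
  acceptor <- element == "O" | (element == "N" & n_neighbors < 4L)
  feats <- character(0)
  keep <- integer(0)
  for (i in seq_along(element)) {
    if (is_no[i]) {
      if (donor[i]) { feats <- c(feats, "donor"); keep <- c(keep, i) }
      if (acceptor[i]) { feats <- c(feats, "acceptor"); keep <- c(keep, i) }
      if (!donor[i] && !acceptor[i]) { feats <- c(feats, "hydrophobe"); keep <- c(keep, i) }
    } else {
      feats <- c(feats, "hydrophobe"); keep <- c(keep, i)
    }
  }
  rad <- unname(radius_table[element[keep]])
  rad[is.na(rad)] <- 1.80
  typed_atoms(xyz[keep, , drop = FALSE], feats, rad, label = label)
}

read_ligand_sdf <- function(x, radius_table) {
  path <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x else {
    tf <- tempfile(fileext = ".sdf")
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), tf)
    tf
  }
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  xyz <- unname(ab[, 1:3, drop = FALSE])
  if (all(abs(xyz[, 3]) < 1e-9))
    stop("ligand has 2D-only coordinates (all z = 0); 3D coordinates required")
  element <- toupper(gsub("_[0-9]+$", "", rownames(ab)))
  n <- nrow(xyz)
  has_h <- logical(n)
  n_neighbors <- integer(n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (q in seq_len(nrow(bb))) {
      i <- bb[q, 1]; j <- bb[q, 2]
      n_neighbors[i] <- n_neighbors[i] + 1L
      n_neighbors[j] <- n_neighbors[j] + 1L
      if (element[j] == "H") has_h[i] <- TRUE
      if (element[i] == "H") has_h[j] <- TRUE
    }
  }
  ligand_typed_set(xyz, element, has_h, n_neighbors, radius_table,
                   label = basename(path))
}

read_ligand_pdb <- function(x, radius_table) {
  s <- read_structure(x)
  a <- s$atoms
  xyz <- coords(s)
  if (all(abs(xyz[, 3]) < 1e-9))
    stop("ligand has 2D-only coordinates (all z = 0); 3D coordinates required")
  n <- nrow(a)
  d <- as.matrix(dist(xyz))
  has_h <- logical(n)
  n_neighbors <- integer(n)
  for (i in seq_len(n)) {
    bond_cut <- ifelse(a$element == "H" | a$element[i] == "H", 1.25, 1.85)
    nb <- which(d[i, ] > 0 & d[i, ] < bond_cut)
    n_neighbors[i] <- length(nb)
    has_h[i] <- any(a$element[nb] == "H")
  }
  ligand_typed_set(xyz, a$element, has_h, n_neighbors, radius_table,
                   label = "ligand")
}
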