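# ensemble_sampler: Metropolis Monte Carlo generation of pocket-containing
# conformations with a deep-volume biasing term, an unbiased baseline, and
# the energy-window filter against the unbiased ensemble.

#' Sampler configuration
#'
#' The biasing term adds `bias_constant * deep_volume` to the stand-in
#' conformational energy during sampling; output conformations are always
#' re-evaluated without the bias.
#'
#' @param bias_constant energy units per Angstrom^3 (the pocket-opening bias)
#' @param temperature Metropolis temperature (stand-in energy units)
#' @param steps Monte Carlo steps per trajectory
#' @param jitter_sd per-coordinate SD of single-atom jitter moves (Angstrom)
#' @param rot_prob probability of a rigid group-rotation move
#' @param rot_sd_deg SD of the group-rotation angle (degrees)
#' @param rot_radius atoms within this radius of the picked atom rotate
#'   together (Angstrom)
#' @param seed base RNG seed; trajectory i uses `seed + i - 1`
#' @param n_conformations trajectories per ensemble
#' @param energy_window energy filter width against the unbiased ensemble
#' @param k_elastic elastic-network force constant (units/A^2)
#' @param k_repulsion soft-sphere repulsion scale
#' @param contact_cutoff elastic-network reference contact cutoff (Angstrom)
#' @param grid [grid_params()] used for deep-volume evaluation during
#'   sampling (coarser than the detection default for speed)
#' @return list of class `sampler_config`
#' @export
sampler_config <- function(bias_constant = -0.25, temperature = 1.0,
                           steps = 2000L, jitter_sd = 0.3, rot_prob = 0.25,
                           rot_sd_deg = 4, rot_radius = 4.0, seed = 1L,
                           n_conformations = 1000L, energy_window = 15,
                           k_elastic = 0.02, k_repulsion = 100,
                           contact_cutoff = 10,
                           grid = grid_params(edge_length = 24, spacing = 1.0)) {
  stopifnot(steps >= 0, jitter_sd > 0, energy_window >= 0, temperature > 0)
  base::structure(list(bias_constant = bias_constant,
                       temperature = temperature, steps = as.integer(steps),
                       jitter_sd = jitter_sd, rot_prob = rot_prob,
                       rot_sd_deg = rot_sd_deg, rot_radius = rot_radius,
                       seed = as.integer(seed),
                       n_conformations = as.integer(n_conformations),
                       energy_window = energy_window,
                       k_elastic = k_elastic, k_repulsion = k_repulsion,
                       contact_cutoff = contact_cutoff, grid = grid),
                  class = "sampler_config")
}

# elastic-network model precomputed from the reference structure
make_energy_model <- function(reference, config) {
  if (!has_radii(reference)) stop("reference needs radii assigned")
  xyz <- coords(reference)
  d <- as.matrix(dist(xyz))
  sel <- which(upper.tri(d) & d <= config$contact_cutoff, arr.ind = TRUE)
  model <- list(ci = sel[, 1] - 1L, cj = sel[, 2] - 1L,
                dref = d[sel], contact_radius = reference$atoms$radius)
  model$csr <- contacts_csr_cpp(nrow(xyz), model$ci, model$cj, model$dref)
  model
}

#' Stand-in conformational energy
#'
#' Soft-sphere quartic repulsion over non-bonded pairs (pairs outside the
#' elastic-network contact list) plus an elastic-network restraint
#' `k_elastic * (d - d_ref)^2` over reference contacts within
#' `contact_cutoff`. Zero at the reference structure by construction.
#'
#' @param structure conformation to score (same atoms as `reference`)
#' @param reference the reference `pocket_structure`
#' @param config a [sampler_config()]
#' @param model optional precomputed contact model (internal reuse)
#' @return energy (stand-in units)
#' @export
stand_in_energy <- function(structure, reference, config = sampler_config(),
                            model = NULL) {
  if (nrow(structure$atoms) != nrow(reference$atoms) ||
      !identical(structure$atoms$name, reference$atoms$name))
    stop("structure and reference must share atoms")
  if (is.null(model)) model <- make_energy_model(reference, config)
  standin_energy_cpp(coords(structure), model$contact_radius,
                     model$ci, model$cj, model$dref,
                     config$k_elastic, config$k_repulsion)
}

#' Biased energy: stand-in energy plus the deep-volume term
#'
#' `E_biased = E_unbiased + bias_constant * deep_volume`, with the deep
#' volume measured on a grid re-anchored at the current target-residue
#' centre of mass.
#'
#' @inheritParams stand_in_energy
#' @param target_residues one or two residue ids anchoring the pocket grid
#' @return list with `e_biased`, `e_unbiased`, `deep_volume`
#' @export
biased_energy <- function(structure, reference, target_residues,
                          config = sampler_config(), model = NULL) {
  e_unb <- stand_in_energy(structure, reference, config, model)
  xyz <- coords(structure)
  trows <- residue_rows(structure, target_residues)
  v <- fast_deep_volume(xyz, structure$atoms$radius, trows,
                        colMeans(xyz[trows, , drop = FALSE]), config$grid)
  list(e_biased = e_unb + config$bias_constant * v, e_unbiased = e_unb,
       deep_volume = v)
}

#' Run one biased Monte Carlo trajectory
#'
#' Metropolis sampling on the biased energy with single-atom jitter and
#' rigid group-rotation moves; returns the final accepted conformation with
#' its energy re-evaluated without the bias term. Fully reproducible from
#' `seed`.
#'
#' @param start starting `pocket_structure` (radii assigned)
#' @param target_residues grid anchor residues
#' @param config a [sampler_config()]
#' @param seed trajectory RNG seed
#' @param reference reference structure for the stand-in energy
#' @param monitor optional `function(xyz)` recorded at every step (returned
#'   as attribute `"trace"` on the conformation; used for sampler
#'   diagnostics)
#' @return list of class `conformation`
#' @export
run_trajectory <- function(start, target_residues, config = sampler_config(),
                           seed = config$seed, reference = start,
                           monitor = NULL) {
  model <- make_energy_model(reference, config)
  trows <- residue_rows(start, target_residues)
  radii <- start$atoms$radius
  bias_on <- config$bias_constant != 0
  deep_vol <- function(xyz) {
    if (!bias_on) return(0)
    fast_deep_volume(xyz, radii, trows,
                     colMeans(xyz[trows, , drop = FALSE]), config$grid)
  }
  trace <- if (!is.null(monitor)) numeric(config$steps) else NULL
  res <- withr::with_seed(seed, {
    xyz <- coords(start)
    n <- nrow(xyz)
    e_cur <- standin_energy_cpp(xyz, model$contact_radius, model$ci,
                                model$cj, model$dref, config$k_elastic,
                                config$k_repulsion)
    v_cur <- deep_vol(xyz)
    accepted <- 0L
    for (s in seq_len(config$steps)) {
      prop <- xyz
      if (runif(1) < config$rot_prob) {
        a <- sample.int(n, 1)
        d2 <- (xyz[, 1] - xyz[a, 1])^2 + (xyz[, 2] - xyz[a, 2])^2 +
          (xyz[, 3] - xyz[a, 3])^2
        moved <- which(d2 <= config$rot_radius^2)
        ang <- rnorm(1, 0, config$rot_sd_deg * pi / 180)
        axis <- unit(rnorm(3))
        R <- rotation_from_vector(axis * ang)
        ctr <- colMeans(xyz[moved, , drop = FALSE])
        prop[moved, ] <- sweep(sweep(xyz[moved, , drop = FALSE], 2, ctr) %*% t(R),
                               2, ctr, `+`)
      } else {
        moved <- sample.int(n, 1)
        prop[moved, ] <- xyz[moved, ] + rnorm(3, 0, config$jitter_sd)
      }
      de <- standin_delta_cpp(xyz, prop, moved - 1L, model$contact_radius,
                              model$csr$ptr, model$csr$idx, model$csr$dref,
                              config$k_elastic, config$k_repulsion)
      v_new <- deep_vol(prop)
      d_total <- de + config$bias_constant * (v_new - v_cur)
      if (runif(1) < exp(-d_total / config$temperature)) {
        xyz <- prop
        e_cur <- e_cur + de
        v_cur <- v_new
        accepted <- accepted + 1L
      }
      if (!is.null(monitor)) trace[s] <- monitor(xyz)
    }
    list(xyz = xyz, accepted = accepted, trace = trace)
  })
  if (config$steps > 0 && res$accepted == 0L)
    warning("trajectory with seed ", seed, " accepted no moves")
  final <- set_coords(start, res$xyz)
  e_unb <- standin_energy_cpp(res$xyz, model$contact_radius, model$ci,
                              model$cj, model$dref, config$k_elastic,
                              config$k_repulsion)
  v <- fast_deep_volume(res$xyz, radii, trows,
                        colMeans(res$xyz[trows, , drop = FALSE]), config$grid)
  out <- base::structure(
    list(structure = final, unbiased_energy = e_unb,
         biased_energy = e_unb + config$bias_constant * v,
         deep_volume = v, seed = seed, accepted = res$accepted,
         steps = config$steps, exemplar = NULL),
    class = "conformation")
  if (!is.null(monitor)) attr(out, "trace") <- res$trace
  out
}

#' Generate an ensemble of pocket-containing conformations
#'
#' `n_conformations` independent trajectories with seeds
#' `config$seed + 0:(n-1)`. Optionally builds the exemplar of each final
#' conformation on the full-resolution detection grid.
#'
#' @inheritParams run_trajectory
#' @param build_exemplars build an exemplar per conformation
#' @param detect_params [grid_params()] used for exemplar construction
#' @param exemplar_config an [exemplar_params()]
#' @param label ensemble label (protein id)
#' @return list of class `pocket_ensemble`
#' @export
generate_ensemble <- function(start, target_residues,
                              config = sampler_config(),
                              build_exemplars = FALSE,
                              detect_params = grid_params(),
                              exemplar_config = exemplar_params(),
                              reference = start, label = "") {
  seeds <- config$seed + seq_len(config$n_conformations) - 1L
  pg <- if (build_exemplars) find_polar_groups(start, warn = FALSE) else NULL
  confs <- lapply(seeds, function(s) {
    cf <- run_trajectory(start, target_residues, config, seed = s,
                         reference = reference)
    if (build_exemplars) {
      cf$exemplar <- tryCatch(
        build_exemplar(cf$structure, target_residues, detect_params,
                       exemplar_config,
                       polar_groups = find_polar_groups(cf$structure,
                                                        warn = FALSE),
                       label = sprintf("%s/%d", label, s)),
        error = function(e) NULL)
    }
    cf
  })
  base::structure(list(conformations = confs,
                       provenance = list(label = label,
                                         target = parse_residue_ids(target_residues),
                                         config_hash = rlang::hash(config),
                                         seeds = seeds)),
                  class = "pocket_ensemble")
}

#' @export
print.pocket_ensemble <- function(x, ...) {
  e <- ensemble_energies(x)
  cat(sprintf("<pocket_ensemble> %d conformations '%s'; unbiased energy median %.3f\n",
              length(x$conformations), x$provenance$label %||% "",
              stats::median(e)))
  invisible(x)
}

#' Unbiased energies of an ensemble
#' @param ensemble a `pocket_ensemble`
#' @return numeric vector
#' @export
ensemble_energies <- function(ensemble) {
  vapply(ensemble$conformations, function(cf) cf$unbiased_energy, 0)
}

#' Deep volumes of an ensemble
#' @param ensemble a `pocket_ensemble`
#' @return numeric vector (Angstrom^3)
#' @export
ensemble_deep_volumes <- function(ensemble) {
  vapply(ensemble$conformations, function(cf) cf$deep_volume, 0)
}

#' Merge ensembles (e.g. from different target pairs) into one
#' @param ... `pocket_ensemble` objects
#' @param label label of the merged ensemble
#' @export
merge_ensembles <- function(..., label = "") {
  parts <- list(...)
  stopifnot(length(parts) > 0,
            all(vapply(parts, inherits, TRUE, "pocket_ensemble")))
  base::structure(list(conformations = do.call(c, lapply(parts, `[[`, "conformations")),
                       provenance = list(label = label,
                                         parents = lapply(parts, `[[`, "provenance"))),
                  class = "pocket_ensemble")
}

#' Filter biased conformations by the unbiased energy window
#'
#' Keeps biased conformations whose unbiased-evaluated energy is at most
#' `reference statistic of the unbiased ensemble + window`, i.e. pockets
#' that are in principle available within the unbiased ensemble.
#'
#' @param biased a biased `pocket_ensemble` (unbiased-evaluated energies)
#' @param unbiased the matching unbiased `pocket_ensemble`
#' @param window energy window (stand-in units)
#' @param reference reference statistic of the unbiased energy distribution
#' @return the filtered biased ensemble
#' @export
filter_by_energy <- function(biased, unbiased, window = 15,
                             reference = c("median", "min", "max")) {
  reference <- match.arg(reference)
  eu <- ensemble_energies(unbiased)
  if (length(eu) == 0) stop("empty unbiased ensemble")
  ref <- switch(reference, median = stats::median(eu), min = min(eu),
                max = max(eu))
  thr <- ref + window
  keep <- ensemble_energies(biased) <= thr
  biased$conformations <- biased$conformations[keep]
  biased$provenance$energy_filter <- list(window = window,
                                          reference = reference,
                                          threshold = thr)
  biased
}
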