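# cli_app: end-to-end pipeline (structures -> ensembles -> exemplars ->
# selectivity report) with a resolved-config snapshot. A thin command-line
# wrapper over these functions ships in inst/scripts/pocketeer.

PIPELINE_KEYS <- c("seed", "n_conformations", "steps", "bias_constant",
                   "jitter_sd", "temperature", "family", "align", "detect",
                   "exemplar", "positive_class", "negative_class")

#' Pipeline run configuration
#'
#' Nested configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param seed global seed: fixture jitter, trajectory seeds and alignment
#'   starts all derive from it
#' @param n_conformations ensemble size per protein
#' @param steps Monte Carlo steps per trajectory
#' @param bias_constant pocket-opening bias (energy units per Angstrom^3)
#' @param jitter_sd sampler move size (Angstrom)
#' @param temperature Metropolis temperature
#' @param family arguments forwarded to [make_family()]
#' @param align an [align_config()]
#' @param detect a [grid_params()] for exemplar-resolution detection
#' @param exemplar an [exemplar_params()]
#' @param positive_class,negative_class truth labels mapped to the ROC
#'   positive/negative classes
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, n_conformations = 20, steps = 300,
                            bias_constant = -0.25, jitter_sd = 0.3,
                            temperature = 1.0, family = list(),
                            align = align_config(),
                            detect = grid_params(),
                            exemplar = exemplar_params(),
                            positive_class = "strong",
                            negative_class = "none") {
  cfg <- list(seed = as.integer(seed),
              n_conformations = as.integer(n_conformations),
              steps = as.integer(steps), bias_constant = bias_constant,
              jitter_sd = jitter_sd, temperature = temperature,
              family = family, align = align, detect = detect,
              exemplar = exemplar, positive_class = positive_class,
              negative_class = negative_class)
  base::structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys must be [pipeline_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in c("align", "detect", "exemplar"))
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- do.call(switch(nm, align = align_config,
                                  detect = grid_params,
                                  exemplar = exemplar_params), raw[[nm]])
  do.call(pipeline_config, raw)
}

#' Run the end-to-end selectivity pipeline on the synthetic family
#'
#' Generates the ground-truth family, samples a biased ensemble per
#' protein, builds per-conformation exemplars and reference ("bound
#' pocket") exemplars, computes selectivity Z-score rows, ROC performance
#' against the generative truth, the all-conformer distance matrix, its MDS
#' embedding and distinctness values. All numeric outputs are written as
#' TSV/JSON under `out_dir` together with a resolved-config snapshot.
#'
#' @param out_dir report directory (created); `NULL` skips file output
#' @param config a [pipeline_config()]
#' @param verbose log per-stage progress
#' @return summary list (class `pipeline_report`): auc, roc p-value, truth
#'   table with z-scores, distinctness table, config hash
#' @export
run_pipeline <- function(out_dir = NULL, config = pipeline_config(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cfg_hash <- rlang::hash(unclass(config))
  say("pipeline start (seed %d, config %s)", config$seed, cfg_hash)

  fam_args <- utils::modifyList(list(seed = config$seed), config$family)
  fam <- do.call(make_family, fam_args)
  say("family: %d proteins, %d reference pockets",
      length(fam$structures), length(fam$references))

  refs <- lapply(setNames(nm = names(fam$references)), function(pid)
    build_exemplar(fam$references[[pid]], fam$ref_targets[[pid]],
                   grid_params = config$detect, params = config$exemplar,
                   label = paste0("ref", pid)))

  ensembles <- list()
  for (q in seq_along(fam$structures)) {
    prot <- names(fam$structures)[q]
    scfg <- sampler_config(bias_constant = config$bias_constant,
                           temperature = config$temperature,
                           steps = config$steps,
                           jitter_sd = config$jitter_sd,
                           seed = config$seed + 1000L * q,
                           n_conformations = config$n_conformations)
    tgt <- fam$targets[[prot]][[1]]
    ensembles[[prot]] <- generate_ensemble(
      fam$structures[[prot]], tgt, scfg, build_exemplars = TRUE,
      detect_params = config$detect, exemplar_config = config$exemplar,
      label = prot)
    say("ensemble %s: %d conformations, %d exemplars", prot,
        length(ensembles[[prot]]$conformations),
        sum(!vapply(ensembles[[prot]]$conformations,
                    function(cf) is.null(cf$exemplar), TRUE)))
  }

  rows <- lapply(setNames(nm = names(refs)), function(pid)
    selectivity_row(refs[[pid]], ensembles, config$align,
                    reference_id = pid))
  ztab <- selectivity_table(rows)
  labels <- fam$truth
  labels$class <- ifelse(labels$binder, config$positive_class,
                         config$negative_class)
  roc <- roc_evaluate(rows, labels, positive = config$positive_class,
                      negative = config$negative_class)
  say("selectivity ROC: AUC %.3f (p = %.3g)", roc$auc, roc$p_value)

  ex_all <- list()
  groups <- character(0)
  for (prot in names(ensembles)) {
    exs <- Filter(Negate(is.null),
                  lapply(ensembles[[prot]]$conformations, `[[`, "exemplar"))
    names(exs) <- sprintf("%s_%02d", prot, seq_along(exs))
    ex_all <- c(ex_all, exs)
    groups <- c(groups, rep(prot, length(exs)))
  }
  D <- distance_matrix(ex_all, config$align)
  mds <- classical_mds(D, dim = 2)
  dstn <- distinctness(D, groups)
  say("pocket space: %d exemplars, top distinctness %.3f (%s)",
      nrow(D), dstn$distinctness[1], dstn$id[1])

  truth_z <- fam$truth
  truth_z$z <- mapply(function(r, p) ztab[r, p], truth_z$reference,
                      truth_z$protein)
  report <- base::structure(
    list(auc = roc$auc, roc_p = roc$p_value, z_table = ztab,
         truth = truth_z, distinctness = dstn, mds = mds,
         distance_matrix = D, rows = rows,
         deep_volumes = lapply(ensembles, ensemble_deep_volumes),
         config_hash = cfg_hash, seed = config$seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(format(as.data.frame(unclass(D)), digits = 6),
                       file.path(out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(mds, file.path(out_dir, "mds.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(dstn, file.path(out_dir, "distinctness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_z, file.path(out_dir, "selectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roc$curve, file.path(out_dir, "roc_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = roc$auc, roc_p = roc$p_value, seed = config$seed,
           config_hash = cfg_hash, elapsed_s = report$elapsed_s),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(yaml::as.yaml(resolve_config_snapshot(config)),
               file.path(out_dir, "config.yaml"))
  }
  say("pipeline done in %.1f s", report$elapsed_s)
  report
}

resolve_config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$align <- unclass(snap$align)
  snap$exemplar <- unclass(snap$exemplar)
  snap$detect <- unclass(snap$detect)
  snap$detect$scan_directions <- apply(snap$detect$scan_directions, 1,
                                       paste, collapse = ",")
  snap
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> AUC %.3f (p = %.3g), %d exemplars, seed %d\n",
              x$auc, x$roc_p, nrow(x$distance_matrix), x$seed))
  invisible(x)
}
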