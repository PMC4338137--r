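# selectivity_analysis: distance matrices, MDS pocket-space maps,
# distinctness, selectivity Z-score rows, ROC evaluation and rank-matrix
# correlation.

#' All-vs-all exemplar distance matrix
#'
#' Pairwise [exemplar_distance()] over a list of exemplars (already the
#' minimum over both alignment directions, hence symmetric). Pairs whose
#' alignment fails are flagged `NA` with a warning summary.
#'
#' @param exemplars list of `exemplar`/`typed_atoms` objects
#' @param config an [align_config()]
#' @param labels optional ids (default: list names or indices)
#' @return square symmetric matrix of class `exemplar_dist`
#' @export
distance_matrix <- function(exemplars, config = align_config(),
                            labels = NULL) {
  n <- length(exemplars)
  if (n < 2) stop("need at least 2 exemplars")
  labels <- labels %||% names(exemplars) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  failed <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(as.numeric(exemplar_distance(exemplars[[i]],
                                                 exemplars[[j]], config)),
                    error = function(e) NA_real_)
      if (is.na(d)) failed <- c(failed, sprintf("%s-%s", labels[i], labels[j]))
      D[i, j] <- D[j, i] <- d
    }
  }
  if (length(failed) > 0)
    warning("alignment failed for ", length(failed), " pair(s): ",
            paste(head(failed, 5), collapse = ", "))
  class(D) <- c("exemplar_dist", class(D))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centred squared-distance embedding via [stats::cmdscale()], with
#' a deterministic sign convention: the first coordinate of magnitude above
#' 1e-10 on each axis is made positive.
#'
#' @param D distance matrix
#' @param dim embedding dimension
#' @return n x dim coordinate matrix (rownames from D)
#' @export
classical_mds <- function(D, dim = 2) {
  D <- as.matrix(unclass(D))
  if (all(D == 0)) {
    out <- matrix(0, nrow(D), dim, dimnames = list(rownames(D), NULL))
    return(out)
  }
  fit <- cmdscale(D, k = dim, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dim)  # degenerate geometry: pad collapsed axes with zeros
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  for (ax in seq_len(ncol(pts))) {
    lead <- which(abs(pts[, ax]) > 1e-10)
    if (length(lead) > 0 && pts[lead[1], ax] < 0) pts[, ax] <- -pts[, ax]
  }
  rownames(pts) <- rownames(D)
  pts
}

#' Pocket distinctness within a protein family
#'
#' For every conformation: `d_other` is the exemplar distance to the
#' closest pocket sampled by a different family member, `d_self` the
#' distance to the closest other pocket from its own ensemble, and
#' distinctness = d_other - d_self. Large values mark pockets unique to one
#' protein — candidate handles for selective inhibitors.
#'
#' @param D pairwise exemplar distance matrix over all conformations
#' @param groups protein id per row of `D` (character or factor)
#' @return data.frame with id, group, d_other, d_self, distinctness,
#'   sorted by distinctness descending
#' @export
distinctness <- function(D, groups) {
  D <- as.matrix(unclass(D))
  n <- nrow(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2) stop("need at least 2 proteins")
  cnt <- table(groups)
  if (any(cnt < 2))
    stop("protein(s) with a single conformation: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  ids <- rownames(D) %||% as.character(seq_len(n))
  d_other <- d_self <- numeric(n)
  for (i in seq_len(n)) {
    same <- groups == groups[i]
    d_other[i] <- min(D[i, !same])
    d_self[i] <- min(D[i, same & seq_len(n) != i])
  }
  out <- data.frame(id = ids, group = groups, d_other = d_other,
                    d_self = d_self, distinctness = d_other - d_self,
                    stringsAsFactors = FALSE)
  out[order(-out$distinctness), , drop = FALSE]
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Selectivity row: one reference pocket/ligand against all ensembles
#'
#' Per protein, the minimum exemplar distance from the reference to any
#' pocket in that protein's ensemble, normalised to a Z-score across the
#' row (population mean/SD). Low Z predicts that the reference's ligand
#' can inhibit that family member. A reference may be an exemplar or a
#' typed ligand conformer (ligand-vs-ensemble mode).
#'
#' @param reference `exemplar` or `typed_atoms`
#' @param ensembles named list: protein id -> list of exemplars (or a
#'   `pocket_ensemble` whose conformations carry exemplars)
#' @param config an [align_config()]
#' @param reference_id id recorded on the row
#' @return data.frame of class `selectivity_row`: protein, min_distance, z
#' @export
selectivity_row <- function(reference, ensembles, config = align_config(),
                            reference_id = "ref") {
  stopifnot(length(ensembles) > 0, !is.null(names(ensembles)))
  ex_list <- lapply(ensembles, function(e) {
    if (inherits(e, "pocket_ensemble"))
      e <- Filter(Negate(is.null), lapply(e$conformations, `[[`, "exemplar"))
    if (length(e) == 0) stop("empty ensemble")
    e
  })
  mind <- vapply(ex_list, function(exs)
    min(vapply(exs, function(ex)
      as.numeric(exemplar_distance(reference, ex, config)), 0)), 0)
  sdv <- population_sd(mind)
  if (sdv < 1e-12) {
    z <- rep(0, length(mind))
    no_var <- TRUE
  } else {
    z <- (mind - mean(mind)) / sdv
    no_var <- FALSE
  }
  out <- data.frame(protein = names(ensembles), min_distance = unname(mind),
                    z = unname(z), stringsAsFactors = FALSE)
  attr(out, "reference_id") <- reference_id
  attr(out, "no_variation") <- no_var
  class(out) <- c("selectivity_row", "data.frame")
  out
}

#' Stack selectivity rows into a reference x protein Z-score matrix
#' @param rows list of `selectivity_row` objects
#' @param value `"z"` or `"min_distance"`
#' @export
selectivity_table <- function(rows, value = c("z", "min_distance")) {
  value <- match.arg(value)
  prot <- rows[[1]]$protein
  m <- t(vapply(rows, function(r) {
    stopifnot(identical(r$protein, prot))
    r[[value]]
  }, numeric(length(prot))))
  rownames(m) <- vapply(rows, function(r) attr(r, "reference_id"), "")
  colnames(m) <- prot
  m
}

# AUC by the rank-sum (Mann-Whitney U) identity; higher score = positive
auc_rank_sum <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' ROC evaluation of selectivity predictions
#'
#' Cells (reference, protein) labelled with the positive class (true
#' binders) should get low Z-scores; prediction score is therefore `-z`.
#' AUC comes from the rank-sum identity and the p-value from the
#' normal-approximated one-sided Mann-Whitney test (tie-corrected).
#' Cells with other labels are excluded.
#'
#' @param rows list of `selectivity_row` objects
#' @param labels data.frame with columns reference, protein, class
#' @param positive,negative class labels defining the binary problem
#' @return list with `auc`, `p_value`, `curve` (FPR/TPR points), `n_pos`,
#'   `n_neg`
#' @export
roc_evaluate <- function(rows, labels, positive = "strong",
                         negative = "none") {
  z <- selectivity_table(rows, "z")
  key <- paste(labels$reference, labels$protein)
  cls <- setNames(as.character(labels$class), key)
  cells <- expand.grid(reference = rownames(z), protein = colnames(z),
                       stringsAsFactors = FALSE)
  cells$z <- as.vector(z)
  cells$class <- unname(cls[paste(cells$reference, cells$protein)])
  pos <- cells$z[cells$class %in% positive]
  neg <- cells$z[cells$class %in% negative]
  if (length(pos) == 0 || length(neg) == 0)
    stop("need at least one positive and one negative labelled cell")
  auc <- auc_rank_sum(-pos, -neg)
  p <- wilcox.test(-pos, -neg, alternative = "greater", exact = FALSE,
                   correct = FALSE)$p.value
  # ROC curve points over score thresholds
  sc <- -c(pos, neg)
  truth <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  th <- c(Inf, sort(unique(sc), decreasing = TRUE))
  curve <- t(vapply(th, function(t) {
    pred <- sc >= t
    c(fpr = sum(pred & !truth) / sum(!truth),
      tpr = sum(pred & truth) / sum(truth))
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc, p_value = p, curve = as.data.frame(curve),
       n_pos = length(pos), n_neg = length(neg))
}

#' Spearman correlation between two similarity/distance matrices
#'
#' Tie-aware Spearman rho over the vectorised upper triangles (diagonal
#' excluded); p-value by the t-approximation.
#'
#' @param M1,M2 square matrices with identical labels
#' @return list with `rho` and `p_value`
#' @export
spearman_matrix_corr <- function(M1, M2) {
  M1 <- as.matrix(unclass(M1)); M2 <- as.matrix(unclass(M2))
  if (!identical(dim(M1), dim(M2)))
    stop("matrices must have the same shape")
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2)))
    stop("matrices must share labels")
  ut <- upper.tri(M1)
  ct <- suppressWarnings(cor.test(M1[ut], M2[ut], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
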