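# target_selection: choose the interfacial residue pair whose candidate
# grid captures the largest cumulative per-residue binding energy.

#' Read a per-residue binding-energy (ddG) table
#'
#' Tab-separated columns: chain, residue number, ddG (energy units), as
#' produced by computational alanine scanning of the protein-protein
#' interface. The listed residues define the interfacial set.
#'
#' @param x path to a TSV file, or a data.frame with columns
#'   chain/resno/ddg
#' @return data.frame of class `ddg_table`
#' @export
read_ddg_table <- function(x) {
  tab <- if (is.data.frame(x)) x else
    read.table(x, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("chain", "resno", "ddg"))
  if (!all(c("chain", "resno", "ddg") %in% names(tab)))
    stop("ddG table needs columns chain, resno, ddg")
  tab <- data.frame(chain = as.character(tab$chain),
                    resno = as.integer(tab$resno),
                    ddg = as.numeric(tab$ddg), stringsAsFactors = FALSE)
  key <- paste(tab$chain, tab$resno)
  if (anyDuplicated(key)) stop("duplicate residue ids in ddG table")
  if (!all(is.finite(tab$ddg))) stop("non-finite ddG values")
  class(tab) <- c("ddg_table", "data.frame")
  tab
}

#' Score one candidate target-residue pair
#'
#' Builds a cube of edge `edge_length` centred at the pair's (unit-mass)
#' atom centre of mass and sums ddG over every table residue with at least
#' one atom inside the cube.
#'
#' @param structure a `pocket_structure`
#' @param ddg a [read_ddg_table()] table
#' @param pair two residue ids
#' @param edge_length candidate-cube edge (Angstrom)
#' @param clip_negative if `TRUE`, negative ddG entries contribute 0
#' @return list of class `target_pair_score` with `pair`, `grid_center`,
#'   `captured_ddg`, `captured_residues`
#' @export
score_pair <- function(structure, ddg, pair, edge_length = 24,
                       clip_negative = FALSE) {
  pr <- parse_residue_ids(pair)
  stopifnot(nrow(pr) == 2)
  rows <- residue_rows(structure, pr)
  xyz <- coords(structure)
  if (anyNA(xyz[rows, ])) stop("target pair residue has missing coordinates")
  center <- colMeans(xyz[rows, , drop = FALSE])
  half <- edge_length / 2
  captured <- logical(nrow(ddg))
  for (q in seq_len(nrow(ddg))) {
    rr <- which(structure$atoms$chain == ddg$chain[q] &
                structure$atoms$resno == ddg$resno[q])
    if (length(rr) == 0) next
    inside <- abs(xyz[rr, 1] - center[1]) <= half &
      abs(xyz[rr, 2] - center[2]) <= half &
      abs(xyz[rr, 3] - center[3]) <= half
    captured[q] <- any(inside)
  }
  vals <- ddg$ddg
  if (clip_negative) vals <- pmax(vals, 0)
  base::structure(list(pair = pr, grid_center = center,
                       captured_ddg = sum(vals[captured]),
                       captured_residues = paste(ddg$chain, ddg$resno,
                                                 sep = ":")[captured]),
                  class = "target_pair_score")
}

#' Rank all interfacial residue pairs by captured ddG
#'
#' Exhaustively scores every unordered pair of residues in the ddG table
#' and returns the full ranking (descending captured ddG; ties broken
#' lexicographically by chain then residue number). The top-ranked pair is
#' the recommended grid anchor; downstream analyses sometimes also use the
#' runner-up.
#'
#' @inheritParams score_pair
#' @return data.frame of class `target_ranking`: chain1, resno1, chain2,
#'   resno2, captured_ddg, rank
#' @export
select_target_pair <- function(structure, ddg, edge_length = 24,
                               clip_negative = FALSE) {
  n <- nrow(ddg)
  if (n < 2) stop("need at least 2 interfacial residues in the ddG table")
  # canonical residue order for deterministic ties
  ord <- order(ddg$chain, ddg$resno)
  ddg_o <- ddg[ord, , drop = FALSE]
  combs <- utils::combn(n, 2)
  res <- data.frame(chain1 = character(0), resno1 = integer(0),
                    chain2 = character(0), resno2 = integer(0),
                    captured_ddg = numeric(0), stringsAsFactors = FALSE)
  for (q in seq_len(ncol(combs))) {
    i <- combs[1, q]; j <- combs[2, q]
    pr <- data.frame(chain = c(ddg_o$chain[i], ddg_o$chain[j]),
                     resno = c(ddg_o$resno[i], ddg_o$resno[j]))
    sc <- score_pair(structure, ddg, pr, edge_length, clip_negative)
    res[nrow(res) + 1L, ] <- list(pr$chain[1], pr$resno[1], pr$chain[2],
                                  pr$resno[2], sc$captured_ddg)
  }
  res <- res[order(-res$captured_ddg, res$chain1, res$resno1,
                   res$chain2, res$resno2), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("target_ranking", "data.frame")
  res
}
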