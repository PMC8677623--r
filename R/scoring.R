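#' Module-score parameters
#'
#' @param n_bins Number of equal-size expression bins (>= 2).
#' @param n_ctrl Control genes sampled per signature gene (>= 1).
#' @param seed Seed for control-gene sampling; part of the parameters so
#'   scores are reproducible across sessions.
#' @return Object of class `module_score_params`.
#' @export
module_score_params <- function(n_bins = 24, n_ctrl = 100, seed = 0) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  if (n_ctrl < 1) stopf("n_ctrl must be >= 1")
  structure(list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "module_score_params")
}

#' Expression-bin-matched module score
#'
#' Genes are assigned to `n_bins` equal-size bins by their average
#' expression across cells. For each signature gene, `n_ctrl` control genes
#' are sampled from its bin (excluding signature genes; with replacement
#' when the bin holds fewer candidates). The score of a cell is the mean
#' expression of the signature genes minus the mean expression of the
#' pooled control genes (with multiplicity). Deterministic given the seed.
#'
#' @param norm Normalized genes x cells matrix.
#' @param sig A [gene_signature]; genes absent from `norm` are dropped with
#'   a warning, and an error is raised if none remain.
#' @param params A [module_score_params()] object.
#' @return Numeric per-cell score named by cell barcode.
#' @export
module_score <- function(norm, sig, params = module_score_params()) {
  genes <- rownames(norm)
  present <- sig$genes[sig$genes %in% genes]
  missing <- setdiff(sig$genes, present)
  if (length(missing) > 0)
    warnf("signature '%s': %d gene(s) absent and dropped", sig$name,
          length(missing))
  if (length(present) == 0)
    stopf("signature '%s': no genes present in the matrix", sig$name)

  avg <- Matrix::rowMeans(norm)
  # equal-size bins by rank of average expression
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / length(avg) * params$n_bins)
  names(bin) <- genes

  ctrl <- with_seed(params$seed, {
    unlist(lapply(present, function(g) {
      pool <- genes[bin == bin[g]]
      pool <- setdiff(pool, present)
      if (length(pool) == 0) return(character(0))
      sample(pool, params$n_ctrl, replace = length(pool) < params$n_ctrl)
    }))
  })
  sig_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl) > 0)
    Matrix::colMeans(norm[ctrl, , drop = FALSE]) else 0
  out <- sig_mean - ctrl_mean
  names(out) <- colnames(norm)
  out
}

#' Pathway-activity scores from a gene x pathway weight matrix
#'
#' Expression is z-scored per gene across cells (sd floored at 1e-8), the
#' weighted sum over the genes shared with the weight matrix is taken per
#' pathway, and the resulting per-pathway scores are z-scored across cells.
#'
#' @param norm Normalized genes x cells matrix.
#' @param weights List with `genes`, `pathways` and `W` (gene x pathway
#'   matrix), e.g. from [load_pathway_weights()].
#' @return Cells x pathways score matrix; pathways with no matching genes
#'   or all-zero weights are dropped with a warning.
#' @export
pathway_activity <- function(norm, weights) {
  shared <- intersect(weights$genes, rownames(norm))
  if (length(shared) == 0) stopf("no weighted genes present in the matrix")
  W <- weights$W[match(shared, weights$genes), , drop = FALSE]
  ok <- colSums(W != 0) > 0
  if (!all(ok)) {
    warnf("pathway(s) dropped (no matching nonzero weights): %s",
          paste(colnames(W)[!ok], collapse = ", "))
    W <- W[, ok, drop = FALSE]
  }
  if (ncol(W) == 0) stopf("no pathway has matching genes")

  x <- as.matrix(norm[shared, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- pmax(apply(x, 1, sd), 1e-8)
  z <- (x - mu) / sdv
  scores <- t(z) %*% W
  mu2 <- colMeans(scores)
  sd2 <- pmax(apply(scores, 2, sd), 1e-8)
  out <- sweep(sweep(scores, 2, mu2), 2, sd2, "/")
  rownames(out) <- colnames(norm)
  out
}

#' Load a gene x pathway weight table from TSV
#'
#' First column gene symbol, remaining columns one per pathway.
#'
#' @param path TSV path.
#' @return List with `genes`, `pathways`, `W`.
#' @export
load_pathway_weights <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- tab[[1]]
  W <- as.matrix(tab[, -1, drop = FALSE])
  rownames(W) <- genes
  if (any(!is.finite(W))) stopf("non-finite pathway weights in '%s'", path)
  list(genes = genes, pathways = colnames(W), W = W)
}

#' Mean scores by group
#'
#' @param scores Per-cell numeric vector or cells x k matrix, named/rownamed
#'   by cell.
#' @param groups Group label per scored cell (cluster id, patient, ...).
#' @return Data frame with one row per non-empty group: group, n, and one
#'   column per score.
#' @export
group_mean_scores <- function(scores, groups) {
  if (is.null(dim(scores)))
    scores <- matrix(scores, ncol = 1,
                     dimnames = list(names(scores), "score"))
  groups <- as.character(groups)
  if (length(groups) != nrow(scores))
    stopf("group labels must cover all %d scored cells", nrow(scores))
  keep <- !is.na(groups)
  agg <- rowsum(scores[keep, , drop = FALSE], groups[keep]) /
    as.vector(table(groups[keep]))
  data.frame(group = rownames(agg),
             n = as.integer(table(groups[keep])[rownames(agg)]),
             agg, row.names = NULL, check.names = FALSE)
}
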