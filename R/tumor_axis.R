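#' Derive the tumor-cell differentiation axis
#'
#' PCA is run on the z-scored highly variable genes of tumor epithelial
#' cells. The sign of PC1 is anchored so that it correlates positively with
#' the mean of the supplied normal-epithelial reference module scores
#' (alveolar type 1/2 and club-like programs): high scores mean
#' alveolar/club-like, low scores undifferentiated. Each gene's Pearson
#' correlation with the anchored PC1 is computed over genes detected in at
#' least `min_detect_frac` of the tumor cells (constant genes get
#' correlation 0); the top `n_sig` positively and negatively correlated
#' genes form the alveolar/club-like and undifferentiated signatures.
#'
#' @param norm_tumor Normalized genes x cells matrix restricted to tumor
#'   epithelial cells (>= 50 cells).
#' @param ref_scores Per-cell reference module scores: a numeric vector or
#'   a cells x k matrix (mean over columns is used), aligned with the cells.
#' @param n_sig Genes per signature (30 by default; fewer only when the
#'   eligible gene universe is smaller than `2 * n_sig`, with a warning).
#' @param n_hvg Highly variable genes used for the PCA.
#' @param min_detect_frac Minimum detection fraction for a gene to enter the
#'   correlation ranking.
#' @return Object of class `differentiation_axis` with `pc1_scores`,
#'   `gene_corr`, `sig_alveolar`, `sig_undiff` and `orientation`.
#' @export
derive_axis <- function(norm_tumor, ref_scores, n_sig = 30, n_hvg = 2000,
                        min_detect_frac = 0.01) {
  if (ncol(norm_tumor) < 50) stopf("need >= 50 tumor cells")
  anchor <- if (is.null(dim(ref_scores))) as.numeric(ref_scores)
            else rowMeans(ref_scores)
  if (length(anchor) != ncol(norm_tumor))
    stopf("ref_scores must align with the tumor cells")

  hvg <- select_hvg(norm_tumor, min(n_hvg, nrow(norm_tumor)))
  emb <- pca_embed(norm_tumor, hvg, n_pcs = 2)
  pc1 <- emb$scores[, 1]

  a_cor <- suppressWarnings(cor(pc1, anchor))
  if (!is.finite(a_cor) || abs(a_cor) < 1e-6)
    stopf(paste("PC1 is uncorrelated with the reference scores;",
                "supply an explicit orientation"))
  if (a_cor < 0) pc1 <- -pc1

  detect <- Matrix::rowSums(norm_tumor > 0) / ncol(norm_tumor)
  eligible <- which(detect >= min_detect_frac)
  x <- as.matrix(norm_tumor[eligible, , drop = FALSE])
  sdv <- apply(x, 1, sd)
  gene_corr <- rep(0, length(eligible))
  nz <- sdv > 0
  gene_corr[nz] <- as.numeric(cor(t(x[nz, , drop = FALSE]), pc1))
  names(gene_corr) <- rownames(norm_tumor)[eligible]

  n_take <- n_sig
  n_nonconst <- sum(nz)
  if (n_nonconst < 2 * n_sig) {
    warnf("only %d non-constant genes; signatures truncated", n_nonconst)
    n_take <- floor(n_nonconst / 2)
  }
  cand <- gene_corr[nz]  # constant genes never enter a signature
  ord <- order(-cand, names(cand))
  pos <- names(cand)[head(ord, n_take)]
  neg <- names(cand)[head(rev(ord), n_take)]
  structure(
    list(pc1_scores = pc1, gene_corr = gene_corr,
         orientation = "alveolar-positive",
         sig_alveolar = gene_signature("alveolar_club_like", pos,
                                       direction = "bidirectional-positive"),
         sig_undiff = gene_signature("undifferentiated", neg,
                                     direction = "bidirectional-negative")),
    class = "differentiation_axis"
  )
}

#' @export
print.differentiation_axis <- function(x, ...) {
  cat(sprintf(
    "<differentiation_axis> %d cells; %d/%d signature genes (%s)\n",
    length(x$pc1_scores), length(x$sig_alveolar$genes),
    length(x$sig_undiff$genes), x$orientation))
  invisible(x)
}

#' Score the differentiation signatures per cell
#'
#' Module scores ([module_score()]) of the alveolar/club-like and
#' undifferentiated signatures, with optional per-patient means.
#'
#' @param norm Normalized genes x cells matrix.
#' @param axis A [derive_axis()] result.
#' @param params Module-score parameters.
#' @param patients Optional patient label per cell; when given, per-patient
#'   mean scores are attached as the `"patient_means"` attribute.
#' @return Cells x 2 matrix with columns `alveolar_club_like` and
#'   `undifferentiated`.
#' @export
score_axis_signatures <- function(norm, axis,
                                  params = module_score_params(),
                                  patients = NULL) {
  out <- cbind(
    alveolar_club_like = module_score(norm, axis$sig_alveolar, params),
    undifferentiated = module_score(norm, axis$sig_undiff, params)
  )
  if (!is.null(patients))
    attr(out, "patient_means") <- group_mean_scores(out, patients)
  out
}
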