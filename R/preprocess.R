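#' Quality-control thresholds
#'
#' Defaults follow the filtering used throughout the pipeline: 500-10,000
#' genes detected and 1,000-100,000 UMIs (both ranges inclusive), fraction
#' of mitochondrial reads strictly below 30% and fraction of hemoglobin
#' reads strictly below 5%.
#'
#' @param min_genes,max_genes Inclusive bounds on genes detected per cell.
#' @param min_umi,max_umi Inclusive bounds on total UMI count per cell.
#' @param max_mito_frac Strict upper bound on mitochondrial read fraction.
#' @param max_hb_frac Strict upper bound on hemoglobin read fraction.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 10000,
                          min_umi = 1000, max_umi = 100000,
                          max_mito_frac = 0.30, max_hb_frac = 0.05) {
  if (min_genes >= max_genes || min_umi >= max_umi)
    stopf("lower QC bounds must be below upper bounds")
  if (max_mito_frac < 0 || max_mito_frac > 1 || max_hb_frac < 0 ||
      max_hb_frac > 1)
    stopf("fraction thresholds must be in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac, max_hb_frac = max_hb_frac),
            class = "qc_thresholds")
}

# Mitochondrial genes by symbol prefix; hemoglobin genes by explicit list.
mito_genes <- function(genes) genes[grepl("^MT-", genes)]
hb_genes <- function(genes) intersect(genes, c("HBA1", "HBA2", "HBB", "HBD"))

#' Per-cell quality-control filtering
#'
#' Retains cells satisfying all of: genes detected within
#' `[min_genes, max_genes]`, UMIs within `[min_umi, max_umi]`,
#' mitochondrial fraction `< max_mito_frac`, hemoglobin fraction
#' `< max_hb_frac`. Count bounds are inclusive, fraction bounds strict.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param meta Cell metadata data frame with a `barcode` column matching the
#'   columns of `counts`.
#' @param thresholds A [qc_thresholds] object.
#' @return List of class `qc_result` with filtered `counts`, matching
#'   `meta`, and `report` (data frame of per-rule removal counts; cells
#'   violating several rules are counted under each).
#' @export
qc_filter <- function(counts, meta, thresholds = qc_thresholds()) {
  t <- thresholds
  genes <- rownames(counts)
  mt <- mito_genes(genes)
  hb <- hb_genes(genes)
  if (length(mt) == 0) warnf("no mitochondrial (MT-) genes found")
  if (length(hb) == 0) warnf("no hemoglobin genes found")

  umi <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito_frac <- if (length(mt))
    Matrix::colSums(counts[mt, , drop = FALSE]) / umi else rep(0, ncol(counts))
  hb_frac <- if (length(hb))
    Matrix::colSums(counts[hb, , drop = FALSE]) / umi else rep(0, ncol(counts))

  fails <- cbind(
    genes_low = ngene < t$min_genes,
    genes_high = ngene > t$max_genes,
    umi_low = umi < t$min_umi,
    umi_high = umi > t$max_umi,
    mito = mito_frac >= t$max_mito_frac,
    hemoglobin = hb_frac >= t$max_hb_frac
  )
  keep <- rowSums(fails) == 0
  if (!any(keep)) {
    dominant <- names(which.max(colSums(fails)))
    stopf("all %d cells removed by QC; dominant failing rule: %s",
          ncol(counts), dominant)
  }
  report <- data.frame(rule = colnames(fails), cells_removed = colSums(fails))
  rownames(report) <- NULL
  meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  structure(
    list(counts = counts[, keep, drop = FALSE],
         meta = meta[keep, , drop = FALSE],
         report = report,
         n_removed = sum(!keep)),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d cells retained, %d removed\n",
              ncol(x$counts), x$n_removed))
  print(x$report)
  invisible(x)
}

#' Log-normalize a count matrix
#'
#' `value = log(1 + count / cell_total * scale)`; sparsity is preserved.
#'
#' @param counts Sparse genes x cells count matrix with no all-zero cells.
#' @param scale Library-size scale factor.
#' @return Sparse normalized matrix of the same shape.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stopf("all-zero cells present; run qc_filter first")
  m <- as(counts, "CsparseMatrix")
  per_entry <- rep.int(totals, diff(m@p))
  out <- m
  out@x <- log1p(m@x / per_entry * scale)
  out
}

#' Select highly variable genes by standardized variance
#'
#' Fits the mean-variance trend by local (loess) regression of log10
#' variance on log10 mean over genes with positive variance, standardizes
#' each gene by its trend-expected standard deviation with z-values clipped
#' at `sqrt(n_cells)`, and ranks genes by the variance of the clipped
#' z-scores. Deterministic given the input.
#'
#' @param norm Normalized genes x cells matrix.
#' @param n Number of genes to select (clamped with a warning if it exceeds
#'   the gene count).
#' @return Integer vector of row indices of the selected genes (named by
#'   gene symbol), ordered by decreasing standardized variance.
#' @export
select_hvg <- function(norm, n = 3000) {
  ngenes <- nrow(norm)
  if (n > ngenes) {
    warnf("n = %d exceeds gene count %d; clamped", n, ngenes)
    n <- ngenes
  }
  nc <- ncol(norm)
  mu <- Matrix::rowSums(norm) / nc
  ex2 <- Matrix::rowSums(norm^2) / nc
  v <- (ex2 - mu^2) * nc / (nc - 1)
  v[v < 0] <- 0

  std_var <- numeric(ngenes)
  pos <- which(v > 0 & mu > 0)
  if (length(pos) >= 10) {
    fit <- loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.3, degree = 2)
    esd <- sqrt(10^predict(fit))
    esd[!is.finite(esd) | esd <= 0] <- sqrt(v[pos])[!is.finite(esd) | esd <= 0]
  } else {
    esd <- sqrt(v[pos])
  }
  clip <- sqrt(nc)
  m <- as(norm, "CsparseMatrix")
  # variance of clipped z-scores, computed sparsely: zeros contribute the
  # clipped z of 0 for each gene
  ridx <- m@i + 1L
  x <- m@x
  esd_full <- rep(NA_real_, ngenes)
  esd_full[pos] <- esd
  z_nz <- (x - mu[ridx]) / esd_full[ridx]
  z_nz <- pmin(pmax(z_nz, -clip), clip)
  z0 <- pmin(pmax((0 - mu) / esd_full, -clip), clip)
  nnz <- tabulate(ridx, nbins = ngenes)
  sum_z <- rowsum_vec(z_nz, ridx, ngenes) + z0 * (nc - nnz)
  sum_z2 <- rowsum_vec(z_nz^2, ridx, ngenes) + z0^2 * (nc - nnz)
  std_var <- (sum_z2 - sum_z^2 / nc) / (nc - 1)
  std_var[is.na(std_var)] <- 0
  std_var[v == 0] <- 0

  ord <- order(-std_var, rownames(norm) %||% seq_len(ngenes))
  idx <- ord[seq_len(n)]
  names(idx) <- rownames(norm)[idx]
  idx
}

# Sum values by integer group over a fixed number of groups.
rowsum_vec <- function(x, g, ngroups) {
  out <- numeric(ngroups)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
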