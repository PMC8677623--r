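#' Cluster marker-gene detection
#'
#' For each cluster versus all other cells, genes are retained only if they
#' pass all of: natural-log fold change >= `logfc_min` (positive markers
#' only), expressing-cell fraction inside the cluster >= `pct_min`, and
#' difference between inside and outside expressing fractions >=
#' `diff_min`. P-values come from a two-sided Wilcoxon rank-sum test on the
#' normalized expression (normal approximation with tie correction; exact
#' enumeration over all group assignments when both groups have at most 10
#' cells). Fold change follows the convention
#' `log(mean(expm1(in)) + 1) - log(mean(expm1(out)) + 1)`.
#'
#' @param norm Normalized genes x cells matrix.
#' @param ca A `cluster_assignment` (only `clusters` is used) or a named
#'   vector of cluster labels.
#' @param logfc_min,pct_min,diff_min Filter thresholds.
#' @param min_cells Minimum cluster size; smaller clusters are skipped with
#'   a warning.
#' @return Data frame of class `marker_result` with columns gene, cluster,
#'   log_fc, pct_in, pct_out, p_value, p_adj (Bonferroni over the genes
#'   tested for the cluster; reported, not used as a filter), sorted within
#'   cluster by p, then decreasing log_fc, then gene name.
#' @export
find_markers <- function(norm, ca, logfc_min = 0.25, pct_min = 0.25,
                         diff_min = 0.25, min_cells = 3) {
  clusters <- if (inherits(ca, "cluster_assignment")) ca$clusters else ca
  cells <- names(clusters)
  norm <- norm[, cells, drop = FALSE]
  ids <- sort(unique(clusters))
  if (length(ids) < 2) stopf("need at least two clusters")

  out <- list()
  for (cl in ids) {
    in_cells <- cells[clusters == cl]
    out_cells <- cells[clusters != cl]
    if (length(in_cells) < min_cells) {
      warnf("cluster %s has fewer than %d cells; skipped", cl, min_cells)
      next
    }
    stat_in <- sparse_row_stats(norm, in_cells)
    stat_out <- sparse_row_stats(norm, out_cells)
    log_fc <- log(stat_in$mean_expm1 + 1) - log(stat_out$mean_expm1 + 1)
    pass <- which(log_fc >= logfc_min &
                    stat_in$frac >= pct_min &
                    stat_in$frac - stat_out$frac >= diff_min)
    if (length(pass) == 0) next
    sub <- as.matrix(norm[pass, c(in_cells, out_cells), drop = FALSE])
    n1 <- length(in_cells)
    p <- apply(sub, 1, function(v)
      wilcox_rank_sum_p(v[seq_len(n1)], v[-seq_len(n1)]))
    df <- data.frame(
      gene = rownames(norm)[pass], cluster = cl,
      log_fc = log_fc[pass], pct_in = stat_in$frac[pass],
      pct_out = stat_out$frac[pass], p_value = p,
      p_adj = pmin(1, p * length(pass)), stringsAsFactors = FALSE
    )
    df <- df[order(df$p_value, -df$log_fc, df$gene), ]
    out[[as.character(cl)]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), cluster = integer(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      p_adj = numeric())
  rownames(res) <- NULL
  class(res) <- c("marker_result", "data.frame")
  res
}

# Two-sided Wilcoxon rank-sum p-value. Exact permutation enumeration when
# both groups are small; otherwise normal approximation with tie
# correction and no continuity correction.
wilcox_rank_sum_p <- function(x, y, exact_max = 10) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  e <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- combn(n1 + n2, n1)
    s_all <- colSums(matrix(r[sets], nrow = n1))
    return(mean(abs(s_all - e) >= abs(s_obs - e) - 1e-9))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (s_obs - e) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

#' Top retained markers per cluster as gene signatures
#'
#' @param mr A [find_markers()] result (already sorted).
#' @param n Markers per cluster; if fewer survive the filters, all are
#'   returned with a message.
#' @param labels Optional named vector mapping cluster id to a label used as
#'   the signature name.
#' @return Named list of [gene_signature] objects, one per cluster.
#' @export
top_markers <- function(mr, n = 10, labels = NULL) {
  sigs <- list()
  for (cl in unique(mr$cluster)) {
    rows <- mr[mr$cluster == cl, ]
    if (nrow(rows) < n)
      message(sprintf("cluster %s: only %d marker(s) survive the filters",
                      cl, nrow(rows)))
    genes <- head(rows$gene, n)
    nm <- if (!is.null(labels) && as.character(cl) %in% names(labels))
      labels[[as.character(cl)]] else as.character(cl)
    sigs[[nm]] <- gene_signature(nm, genes, direction = "up")
  }
  sigs
}
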