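#' Load a ligand-receptor pair table
#'
#' TSV with columns ligand, receptor, family. Heteromeric complexes are
#' written as `+`-separated member genes (e.g. `TGFBR1+TGFBR2`); complex
#' expression is aggregated by the minimum over members.
#'
#' @param path TSV path; defaults to the small curated table shipped with
#'   the package.
#' @return Data frame with columns ligand, receptor, family.
#' @export
load_lr_pairs <- function(path = system.file("extdata", "lr_pairs.tsv",
                                             package = "tmepatterns")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "family")
  if (!all(need %in% names(tab)))
    stopf("ligand-receptor table must have columns: %s",
          paste(need, collapse = ", "))
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
    stopf("empty ligand or receptor entries")
  tab
}

# Per-cluster mean expression and expressing fraction for a set of genes,
# for a given label assignment. Complexes take the member minimum.
cluster_gene_stats <- function(norm, labels, genes) {
  ids <- sort(unique(labels))
  mean_mat <- matrix(0, length(genes), length(ids),
                     dimnames = list(genes, as.character(ids)))
  frac_mat <- mean_mat
  for (k in seq_along(ids)) {
    cols <- which(labels == ids[k])
    mean_mat[, k] <- Matrix::rowSums(norm[genes, cols, drop = FALSE]) /
      length(cols)
    frac_mat[, k] <- Matrix::rowSums(norm[genes, cols, drop = FALSE] > 0) /
      length(cols)
  }
  list(mean = mean_mat, frac = frac_mat)
}

complex_members <- function(s) strsplit(s, "+", fixed = TRUE)[[1]]

#' Ligand-receptor interaction test with a cluster-label permutation null
#'
#' A partner is considered expressed in a cluster only if its
#' expressing-cell fraction is at least `expr_frac` (complexes: every
#' member). For each expressed (pair, sender, receiver) combination the
#' statistic is the mean of the ligand's mean expression in the sender and
#' the receptor's mean expression in the receiver (complexes aggregated by
#' member minimum). The null distribution shuffles cluster labels across
#' all cells; the one-sided p-value is the fraction of permuted statistics
#' at least as large as the observed one.
#'
#' @param norm Normalized genes x cells matrix.
#' @param ca A `cluster_assignment` or named label vector (>= 2 clusters).
#' @param pairs Ligand-receptor table from [load_lr_pairs()]; pairs with
#'   unresolvable genes are dropped with a message.
#' @param n_perm Number of label permutations (warning below 100).
#' @param expr_frac Minimum expressing-cell fraction.
#' @param seed Permutation seed.
#' @param method `"sample"` for random shuffles, `"exact"` to enumerate all
#'   distinct two-cluster label assignments (only with exactly 2 clusters).
#' @return Data frame of class `interaction_result`: ligand, receptor,
#'   family, sender, receiver, mean_score, p, significant (p < 0.05).
#' @export
lr_test <- function(norm, ca, pairs = load_lr_pairs(), n_perm = 1000,
                    expr_frac = 0.1, seed = 0,
                    method = c("sample", "exact")) {
  method <- match.arg(method)
  labels <- if (inherits(ca, "cluster_assignment")) ca$clusters else ca
  cells <- names(labels)
  norm <- norm[, cells, drop = FALSE]
  ids <- sort(unique(labels))
  if (length(ids) < 2) stopf("need >= 2 clusters")
  if (method == "sample" && n_perm < 100)
    warnf("n_perm = %d gives coarse p-value granularity", n_perm)
  if (method == "exact" && length(ids) != 2)
    stopf("exact enumeration supports exactly 2 clusters")

  all_genes <- rownames(norm)
  resolvable <- vapply(seq_len(nrow(pairs)), function(i)
    all(complex_members(pairs$ligand[i]) %in% all_genes) &&
      all(complex_members(pairs$receptor[i]) %in% all_genes), logical(1))
  if (any(!resolvable))
    message(sum(!resolvable), " pair(s) with unresolvable genes dropped")
  pairs <- pairs[resolvable, , drop = FALSE]
  if (nrow(pairs) == 0) stopf("no resolvable ligand-receptor pairs")

  used_genes <- unique(unlist(lapply(
    c(pairs$ligand, pairs$receptor), complex_members)))
  obs <- cluster_gene_stats(norm, labels, used_genes)

  agg <- function(mat, entity) {
    mem <- complex_members(entity)
    if (length(mem) == 1) mat[mem, ] else apply(mat[mem, , drop = FALSE], 2, min)
  }

  # enumerate tested combinations on the observed labels
  tested <- list()
  for (i in seq_len(nrow(pairs))) {
    lig_frac <- agg(obs$frac, pairs$ligand[i])
    rec_frac <- agg(obs$frac, pairs$receptor[i])
    lig_mean <- agg(obs$mean, pairs$ligand[i])
    rec_mean <- agg(obs$mean, pairs$receptor[i])
    for (s in as.character(ids)) {
      for (r in as.character(ids)) {
        if (s == r) next
        if (lig_frac[s] < expr_frac || rec_frac[r] < expr_frac) next
        tested[[length(tested) + 1]] <- data.frame(
          ligand = pairs$ligand[i], receptor = pairs$receptor[i],
          family = pairs$family[i], sender = s, receiver = r,
          mean_score = (lig_mean[s] + rec_mean[r]) / 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(tested) == 0) {
    res <- data.frame(ligand = character(), receptor = character(),
                      family = character(), sender = character(),
                      receiver = character(), mean_score = numeric(),
                      p = numeric(), significant = logical())
    class(res) <- c("interaction_result", "data.frame")
    return(res)
  }
  res <- do.call(rbind, tested)

  perm_labels <- if (method == "exact") {
    n1 <- sum(labels == ids[1])
    sets <- combn(length(labels), n1)
    lapply(seq_len(ncol(sets)), function(j) {
      lab <- rep(ids[2], length(labels))
      lab[sets[, j]] <- ids[1]
      names(lab) <- cells
      lab
    })
  } else {
    with_seed(seed, lapply(seq_len(n_perm), function(j)
      setNames(sample(labels), cells)))
  }

  exceed <- numeric(nrow(res))
  for (pl in perm_labels) {
    stat <- cluster_gene_stats(norm, pl, used_genes)
    for (q in seq_len(nrow(res))) {
      sc <- (agg(stat$mean, res$ligand[q])[res$sender[q]] +
               agg(stat$mean, res$receptor[q])[res$receiver[q]]) / 2
      exceed[q] <- exceed[q] + (sc >= res$mean_score[q] - 1e-12)
    }
  }
  res$p <- exceed / length(perm_labels)
  res$significant <- res$p < 0.05
  rownames(res) <- NULL
  class(res) <- c("interaction_result", "data.frame")
  res
}

#' Count significant interactions
#'
#' @param results An [lr_test()] result.
#' @param senders,receivers Optional cluster filters.
#' @param by Grouping column (default `"family"`).
#' @return Data frame of counts per (sender, receiver, group); all-zero
#'   when nothing is significant.
#' @export
count_interactions <- function(results, senders = NULL, receivers = NULL,
                               by = "family") {
  sub <- results[results$significant, , drop = FALSE]
  if (!is.null(senders)) sub <- sub[sub$sender %in% senders, , drop = FALSE]
  if (!is.null(receivers))
    sub <- sub[sub$receiver %in% receivers, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(sender = character(), receiver = character(),
                      group = character(), n = integer()))
  tab <- aggregate(list(n = rep(1L, nrow(sub))),
                   by = list(sender = sub$sender, receiver = sub$receiver,
                             group = sub[[by]]), FUN = sum)
  tab[order(tab$sender, tab$receiver, tab$group), ]
}
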