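#' PCA embedding of cells
#'
#' Genes are z-scored across cells (mean 0, sd 1, z clipped at +/-10) before
#' the decomposition. Principal components are ordered by decreasing
#' explained variance; the sign of each component is fixed so that its
#' loading of largest absolute value is positive.
#'
#' @param norm Normalized genes x cells matrix.
#' @param hvg Gene indices or names to use (typically from [select_hvg()]).
#' @param n_pcs Number of components (clamped with a warning if it exceeds
#'   the matrix rank bound).
#' @return List of class `pca_embedding` with `scores` (cells x PC),
#'   `rotation` (genes x PC) and `sdev`.
#' @export
pca_embed <- function(norm, hvg = seq_len(nrow(norm)), n_pcs = 15) {
  sub <- as.matrix(norm[hvg, , drop = FALSE])
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  keep <- sdv > 0
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  z[z > 10] <- 10
  z[z < -10] <- -10
  maxk <- min(dim(z)) - 1L
  if (n_pcs > maxk) {
    warnf("n_pcs = %d exceeds available dimensions; clamped to %d", n_pcs, maxk)
    n_pcs <- maxk
  }
  X <- t(z)                      # cells x genes
  X <- sweep(X, 2, colMeans(X))  # center genes (clipping can shift means)
  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rotation <- sv$v
  # sign convention: largest-|loading| entry of each PC is positive
  for (k in seq_len(n_pcs)) {
    top <- which.max(abs(rotation[, k]))
    if (rotation[top, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(colnames(norm), paste0("PC", seq_len(n_pcs)))
  dimnames(rotation) <- list(rownames(z), paste0("PC", seq_len(n_pcs)))
  structure(list(scores = scores, rotation = rotation,
                 sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(X) - 1))),
            class = "pca_embedding")
}

# Blockwise k-nearest neighbors (Euclidean), self included.
knn_indices <- function(scores, k, block = 1000L) {
  n <- nrow(scores)
  if (n < k + 1) stopf("need at least k + 1 = %d cells", k + 1)
  sq <- rowSums(scores^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    d2 <- outer(sq[start:end], sq, "+") -
      2 * scores[start:end, , drop = FALSE] %*% t(scores)
    for (r in seq_len(end - start + 1L)) {
      idx[start + r - 1L, ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  idx
}

#' Shared-nearest-neighbor graph
#'
#' Builds the k-nearest-neighbor sets of each cell in PC space (self
#' included, Euclidean metric) and connects cells by the Jaccard overlap of
#' their neighbor sets; edges with weight below `prune` are removed.
#'
#' @param pcs A [pca_embed()] result or a cells x PC score matrix.
#' @param k Neighbors per cell.
#' @param prune Minimum Jaccard weight retained.
#' @return An undirected weighted `igraph` graph whose vertices are cells.
#' @export
build_snn <- function(pcs, k = 20, prune = 1 / 15) {
  scores <- if (inherits(pcs, "pca_embedding")) pcs$scores else as.matrix(pcs)
  n <- nrow(scores)
  nn <- knn_indices(scores, k)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(nn)), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  shared <- as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * k - shared@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  igraph::V(g)$name <- rownames(scores)
  g
}

#' Louvain community detection on the SNN graph
#'
#' @param g Weighted graph from [build_snn()].
#' @param resolution Modularity resolution.
#' @param seed Random seed (the refinement order is stochastic).
#' @return Object of class `cluster_assignment`: `clusters` (named integer
#'   vector, cell -> cluster id) and `info` (one row per cluster with
#'   `cell_type`, `compartment`, `tumor_call` to be filled by
#'   [annotate_clusters()] and [call_tumor_clusters()]).
#' @export
cluster_graph <- function(g, resolution = 0.8, seed = 0) {
  if (igraph::vcount(g) == 0) stopf("empty graph")
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- igraph::membership(comm)
  clusters <- setNames(as.integer(labels), igraph::V(g)$name)
  info <- data.frame(
    cluster = sort(unique(clusters)),
    n_cells = as.integer(table(clusters)[as.character(sort(unique(clusters)))]),
    cell_type = NA_character_, compartment = NA_character_,
    tumor_call = "n/a", stringsAsFactors = FALSE
  )
  structure(list(clusters = clusters, info = info),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d clusters\n",
              length(x$clusters), nrow(x$info)))
  print(x$info)
  invisible(x)
}

#' Annotate clusters by reference module scores
#'
#' Each cluster receives the label of the reference signature with the
#' highest mean module score over its cells; the compartment is inherited
#' from the winning signature. Ties are broken by the larger margin over the
#' runner-up, then lexicographically. A cluster whose best score is not
#' positive is labeled `"unassigned"` with a warning.
#'
#' @param ca A [cluster_graph()] result.
#' @param norm Normalized genes x cells matrix covering the clustered cells.
#' @param references List of [gene_signature] objects with `compartment`
#'   tags.
#' @param params Module-score parameters ([module_score_params()]).
#' @return The updated `cluster_assignment`.
#' @export
annotate_clusters <- function(ca, norm, references,
                              params = module_score_params()) {
  if (length(references) == 0) stopf("empty reference signature list")
  cells <- names(ca$clusters)
  norm <- norm[, cells, drop = FALSE]
  score_mat <- sapply(references, function(sig)
    module_score(norm, sig, params))
  colnames(score_mat) <- vapply(references, `[[`, "", "name")

  for (r in seq_len(nrow(ca$info))) {
    cl <- ca$info$cluster[r]
    in_cl <- ca$clusters == cl
    means <- colMeans(score_mat[in_cl, , drop = FALSE])
    ord <- order(-means, names(means))
    best <- ord[1]
    if (means[best] <= 0) {
      warnf("cluster %s has no positive reference score; unassigned", cl)
      ca$info$cell_type[r] <- "unassigned"
      next
    }
    ca$info$cell_type[r] <- names(means)[best]
    ref <- references[[which(colnames(score_mat) == names(means)[best])[1]]]
    ca$info$compartment[r] <- ref$compartment %||% NA_character_
  }
  ca
}

#' Call tumor clusters from tissue composition
#'
#' Epithelial clusters whose fraction of tumor-tissue cells is at least
#' `min_tumor_frac` are called tumor; other epithelial clusters are normal;
#' non-epithelial clusters are `"n/a"`.
#'
#' @param ca Annotated `cluster_assignment`.
#' @param meta Cell metadata with `barcode` and `tissue` columns.
#' @param min_tumor_frac Tumor-tissue fraction threshold.
#' @return The updated `cluster_assignment`.
#' @export
call_tumor_clusters <- function(ca, meta, min_tumor_frac = 0.9) {
  tissue <- setNames(meta$tissue, meta$barcode)[names(ca$clusters)]
  for (r in seq_len(nrow(ca$info))) {
    if (identical(ca$info$compartment[r], "epithelial")) {
      in_cl <- ca$clusters == ca$info$cluster[r]
      frac <- mean(tissue[in_cl] == "tumor")
      ca$info$tumor_call[r] <- if (frac >= min_tumor_frac) "tumor" else "normal"
    } else {
      ca$info$tumor_call[r] <- "n/a"
    }
  }
  ca
}

#' Reference signatures from simulated cell-type programs
#'
#' @param programs List of [cell_type_program] objects.
#' @return List of [gene_signature] objects carrying compartment tags,
#'   suitable for [annotate_clusters()].
#' @export
program_signatures <- function(programs) {
  lapply(programs, function(p)
    gene_signature(p$name, p$marker_genes, compartment = p$compartment))
}
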