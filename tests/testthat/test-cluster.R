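test_that("PCA recovers a planted direction of variance", {
  set.seed(8)
  n <- 100
  latent <- rnorm(n, sd = 4)
  dense <- rbind(
    outer(rep(1, 10), latent) + matrix(rnorm(10 * n, sd = 0.2), 10),
    matrix(rnorm(30 * n, sd = 0.2), 30)
  )
  rownames(dense) <- paste0("G", 1:40)
  colnames(dense) <- paste0("C", 1:n)
  nm <- as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  emb <- pca_embed(nm, 1:40, n_pcs = 5)
  # eigen oracle on the standardized data
  z <- t(scale(t(dense)))
  z[z > 10] <- 10; z[z < -10] <- -10
  X <- scale(t(z), scale = FALSE)
  ev <- eigen(stats::cov(X))$values
  expect_equal(emb$sdev[1]^2, ev[1], tolerance = 1e-8)
  expect_gte(emb$sdev[1]^2 / sum(ev), ev[1] / sum(ev) - 1e-12)
  expect_gt(abs(cor(emb$scores[, 1], latent)), 0.99)
})

test_that("duplicate cells get identical PC scores and the sign rule holds", {
  set.seed(9)
  dense <- matrix(rnorm(30 * 40), 30, 40,
                  dimnames = list(paste0("G", 1:30), paste0("C", 1:40)))
  dense[, 40] <- dense[, 39]  # duplicate cell
  nm <- as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  emb <- pca_embed(nm, 1:30, n_pcs = 5)
  expect_equal(emb$scores[39, ], emb$scores[40, ])
  for (k in 1:5) {
    top <- which.max(abs(emb$rotation[, k]))
    expect_gt(emb$rotation[top, k], 0)
  }
  # the sign convention re-normalizes a globally flipped input
  emb2 <- pca_embed(as(Matrix::Matrix(-dense, sparse = TRUE),
                       "CsparseMatrix"), 1:30, n_pcs = 5)
  for (k in 1:5) {
    top <- which.max(abs(emb2$rotation[, k]))
    expect_gt(emb2$rotation[top, k], 0)
  }
})

test_that("SNN edges follow Jaccard overlap of neighbor sets", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(15 * 2, mean = 0, sd = 0.3), ncol = 2),
               matrix(rnorm(15 * 2, mean = 10, sd = 0.3), ncol = 2))
  rownames(pts) <- paste0("C", 1:30)
  # identical cells share their entire kNN set: edge weight 1
  pts2 <- rbind(pts, C31 = pts[1, ])
  g <- build_snn(pts2, k = 5)
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("C1", "C31"))]
  expect_equal(w, 1)
  # no edge survives between two well-separated blobs
  g2 <- build_snn(pts, k = 5)
  ends <- igraph::ends(g2, igraph::E(g2))
  blob <- function(nm) as.integer(sub("C", "", nm)) > 15
  expect_true(all(blob(ends[, 1]) == blob(ends[, 2])))
  # brute-force kNN oracle: each cell's neighbors stay within its blob
  d <- as.matrix(dist(pts))
  for (i in 1:30) {
    nn <- order(d[i, ])[1:5]
    expect_true(all(blob(rownames(pts)[nn]) == blob(rownames(pts)[i])))
  }
})

test_that("Louvain clustering separates disconnected cliques deterministically", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- paste0("C", 1:10)
  ca <- cluster_graph(g, resolution = 0.8, seed = 1)
  expect_equal(nrow(ca$info), 2)
  expect_equal(length(unique(ca$clusters[1:5])), 1)
  expect_equal(length(unique(ca$clusters[6:10])), 1)
  ca2 <- cluster_graph(g, resolution = 0.8, seed = 1)
  expect_identical(ca$clusters, ca2$clusters)
  expect_error(cluster_graph(igraph::make_empty_graph(0), 0.8, 1), "empty")
})

test_that("clusters recover planted cell types on synthetic cohorts", {
  for (s in 1:3) {
    sim <- simulate_sc_cohort(n_patients = 3, cells_per_patient = 250,
                              seed = 40 + s)
    pipe <- run_sc_pipeline(sim)
    truth <- sim$truth$cells[match(names(pipe$ca$clusters),
                                   sim$truth$cells$barcode), ]
    expect_gte(adjusted_rand_index(pipe$ca$clusters, truth$true_type), 0.8)
    # >= 95% of clusters labeled with their dominant true type
    info <- pipe$ca$info
    hits <- vapply(seq_len(nrow(info)), function(r) {
      dom <- names(which.max(table(
        truth$true_type[pipe$ca$clusters == info$cluster[r]])))
      identical(info$cell_type[r], dom)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("cluster annotation responds to expressed markers and errors on empty references", {
  set.seed(12)
  genes <- c(paste0("A", 1:5), paste0("B", 1:5), paste0("F", 1:40))
  dense <- matrix(rexp(50 * 30, 1), 50, 30,
                  dimnames = list(genes, paste0("C", 1:30)))
  dense[1:5, 1:15] <- dense[1:5, 1:15] + 5    # cluster 1 expresses A
  dense[6:10, 16:30] <- dense[6:10, 16:30] + 5 # cluster 2 expresses B
  nm <- as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  ca <- structure(list(
    clusters = setNames(rep(1:2, each = 15), colnames(dense)),
    info = data.frame(cluster = 1:2, n_cells = 15L,
                      cell_type = NA_character_,
                      compartment = NA_character_, tumor_call = "n/a")),
    class = "cluster_assignment")
  refs <- list(gene_signature("typeA", paste0("A", 1:5),
                              compartment = "epithelial"),
               gene_signature("typeB", paste0("B", 1:5),
                              compartment = "myeloid"))
  ca <- annotate_clusters(ca, nm, refs, module_score_params(n_bins = 5))
  expect_equal(ca$info$cell_type, c("typeA", "typeB"))
  expect_equal(ca$info$compartment, c("epithelial", "myeloid"))
  expect_error(annotate_clusters(ca, nm, list()), "empty")
})

test_that("tumor calling follows the tumor-tissue fraction threshold", {
  ca <- structure(list(
    clusters = setNames(rep(1:3, each = 20), paste0("C", 1:60)),
    info = data.frame(cluster = 1:3, n_cells = 20L,
                      cell_type = c("epiA", "epiB", "mac"),
                      compartment = c("epithelial", "epithelial", "myeloid"),
                      tumor_call = "n/a")),
    class = "cluster_assignment")
  tissue <- c(rep("tumor", 19), "normal",            # cluster 1: 95% tumor
              rep(c("tumor", "normal"), 10),         # cluster 2: 50%
              rep("tumor", 20))                      # cluster 3: myeloid
  meta <- data.frame(barcode = paste0("C", 1:60), patient = "P1",
                     tissue = tissue)
  out <- call_tumor_clusters(ca, meta)
  expect_equal(out$info$tumor_call, c("tumor", "normal", "n/a"))
  out0 <- call_tumor_clusters(ca, meta, min_tumor_frac = 0)
  expect_equal(out0$info$tumor_call, c("tumor", "tumor", "n/a"))
})
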