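# A hand-buildable cluster assignment over two compartments.
toy_assignment <- function(counts_per) {
  # counts_per: named list patient -> named vector cluster -> cells
  rows <- list()
  for (p in names(counts_per)) {
    for (cl in names(counts_per[[p]])) {
      n <- counts_per[[p]][[cl]]
      if (n > 0)
        rows[[length(rows) + 1]] <- data.frame(
          patient = p, cluster = as.integer(cl), n = n)
    }
  }
  tab <- do.call(rbind, rows)
  barcodes <- unlist(lapply(seq_len(nrow(tab)), function(i)
    sprintf("%s_cl%s_%03d", tab$patient[i], tab$cluster[i],
            seq_len(tab$n[i]))))
  clusters <- setNames(rep(tab$cluster, tab$n), barcodes)
  meta <- data.frame(barcode = barcodes,
                     patient = rep(tab$patient, tab$n), tissue = "tumor")
  info <- data.frame(cluster = sort(unique(tab$cluster)))
  info$n_cells <- as.integer(table(clusters)[as.character(info$cluster)])
  info$cell_type <- paste0("type", info$cluster)
  info$compartment <- ifelse(info$cluster <= 2, "myeloid", "fibroblastic")
  info$tumor_call <- "n/a"
  ca <- structure(list(clusters = clusters, info = info),
                  class = "cluster_assignment")
  list(ca = ca, meta = meta)
}

test_that("proportions are computed within compartments and sum to one", {
  fx <- toy_assignment(list(
    P1 = c("1" = 30, "2" = 70, "3" = 10, "4" = 40),
    P2 = c("1" = 50, "2" = 50, "3" = 25, "4" = 25)
  ))
  ct <- compute_proportions(fx$ca, fx$meta)
  expect_equal(ct$P["P1", "1"], 0.3)
  expect_equal(ct$P["P1", "2"], 0.7)
  expect_equal(ct$P["P1", "3"], 0.2)
  expect_equal(ct$P["P2", "3"], 0.5)
  # per-compartment conservation
  for (comp in unique(ct$clusters$compartment)) {
    cols <- which(ct$clusters$compartment == comp)
    expect_equal(unname(rowSums(ct$P[, cols, drop = FALSE])), c(1, 1),
                 tolerance = 1e-9)
  }
  # tally oracle on the 100-cell myeloid compartment of P1
  expect_equal(ct$P["P1", "1"],
               sum(fx$meta$patient == "P1" & fx$ca$clusters == 1) /
                 sum(fx$meta$patient == "P1" & fx$ca$clusters %in% 1:2))
})

test_that("normal-tissue cells are excluded from composition", {
  fx <- toy_assignment(list(P1 = c("1" = 10, "2" = 10),
                            P2 = c("1" = 10, "2" = 10)))
  fx$meta$tissue[fx$meta$barcode %in%
                   names(fx$ca$clusters)[fx$ca$clusters == 2][1:5]] <- "normal"
  ct <- suppressWarnings(compute_proportions(fx$ca, fx$meta))
  expect_equal(ct$P["P1", "2"] + ct$P["P1", "1"], 1)
  expect_lt(ct$P["P1", "2"], 10 / 20)
})

test_that("rare clusters are excluded at the patient-count boundary", {
  P <- rbind(
    p1 = c(a = 0.5, b = 0.5, c = 0.0),
    p2 = c(a = 0.5, b = 0.5, c = 0.0),
    p3 = c(a = 0.4, b = 0.6, c = 0.0),
    p4 = c(a = 0.3, b = 0.4, c = 0.3),
    p5 = c(a = 0.3, b = 0.4, c = 0.3),
    p6 = c(a = 0.2, b = 0.5, c = 0.3)
  )
  ct <- structure(list(
    patients = rownames(P),
    clusters = data.frame(cluster = 1:3, label = colnames(P),
                          compartment = "myeloid"),
    P = P, Z = tmepatterns:::zscore_cols(P)), class = "composition_table")
  kept3 <- filter_rare_clusters(ct, min_patients = 3)
  expect_true("c" %in% kept3$clusters$label)    # occurs in exactly 3
  P2 <- P; P2[4, "c"] <- 0
  ct$P <- P2
  kept2 <- filter_rare_clusters(ct, min_patients = 3)
  expect_false("c" %in% kept2$clusters$label)   # occurs in only 2
  # proportions are not renormalized after exclusion
  expect_equal(kept2$P[, "a"], P2[, "a"])
  ident <- filter_rare_clusters(ct, min_patients = 0)
  expect_equal(ident$P, ct$P)
})

test_that("pattern PCA groups patients by planted archetype", {
  sim <- simulate_sc_cohort(n_patients = 6, cells_per_patient = 250,
                            seed = 71)
  pipe <- run_sc_pipeline(sim)
  ct <- filter_rare_clusters(
    suppressWarnings(compute_proportions(pipe$ca, pipe$qc$meta)))
  pa <- pattern_pca(ct)
  truth <- sim$truth$patients
  expect_equal(unname(pa$group[truth$patient]), truth$archetype)
})

test_that("pattern PCA is invariant to duplication and equal compositions", {
  set.seed(23)
  P <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(paste0("p", 1:6), NULL))
  P <- P / rowSums(P)
  P[5, ] <- P[6, ]  # two identical patients
  labels <- c("momac_proinflammatory", "myofib_cancer_assoc",
              "momac_noninflammatory", "nk_cell")
  ct <- structure(list(
    patients = rownames(P),
    clusters = data.frame(cluster = 1:4, label = labels,
                          compartment = "myeloid"),
    P = P, Z = tmepatterns:::zscore_cols(P)), class = "composition_table")
  pa <- pattern_pca(ct)
  expect_equal(pa$pattern_pc1["p5"], pa$pattern_pc1["p6"],
               ignore_attr = TRUE)
  # patient order must not matter
  ord <- c(3, 1, 6, 2, 5, 4)
  ct2 <- ct
  ct2$patients <- ct$patients[ord]
  ct2$P <- P[ord, ]
  ct2$Z <- tmepatterns:::zscore_cols(ct2$P)
  pa2 <- pattern_pca(ct2)
  expect_equal(pa2$group[names(pa$group)], pa$group)
  # missing anchors are an error
  ct3 <- ct
  ct3$clusters$label <- paste0("x", 1:4)
  expect_error(pattern_pca(ct3), "anchor")
})

test_that("correlation network retains only strong positive edges", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  P <- cbind(a = x, b = x + 0.01, c = rev(x), d = runif(10))
  rownames(P) <- paste0("p", 1:10)
  ct <- structure(list(
    patients = rownames(P),
    clusters = data.frame(cluster = 1:4, label = colnames(P),
                          compartment = "myeloid"),
    P = P, Z = tmepatterns:::zscore_cols(P)), class = "composition_table")
  net <- correlation_network(ct)
  ab <- net[net$cluster_a == "a" & net$cluster_b == "b", ]
  expect_equal(ab$rho, 1)
  # perfect anti-correlation is excluded: the rule is positive rho only
  expect_false(any(net$cluster_b == "c" & net$cluster_a == "a"))
})

test_that("exact Spearman p at n = 7 matches exhaustive enumeration", {
  set.seed(24)
  x <- c(2, 9, 4, 7, 1, 8, 3)
  y <- c(1, 8, 5, 6, 2, 9, 4)
  got <- tmepatterns:::spearman_test(x, y, tmepatterns:::all_permutations(7))
  want <- spearman_exact_oracle(x, y)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("pattern signatures union member markers and stay disjoint", {
  markers <- list(
    m1 = gene_signature("m1", c("A", "B")),
    m2 = gene_signature("m2", c("B", "C")),
    f1 = gene_signature("f1", c("D")),
    f2 = gene_signature("f2", c("E", "A"))
  )
  membership <- list(N3MC = c("m1", "m2"), CP2E = c("f1", "f2"))
  sp <- assemble_pattern_signatures(markers, membership)
  expect_setequal(sp$N3MC$genes, c("B", "C"))  # A shared, removed from both
  expect_setequal(sp$CP2E$genes, c("D", "E"))
  expect_error(assemble_pattern_signatures(markers,
                                           list(N3MC = "zz", CP2E = "f1")),
               "zz")
})

test_that("compact signatures fill a round-robin budget deterministically", {
  markers <- list(
    m1 = gene_signature("m1", paste0("A", 1:8)),
    m2 = gene_signature("m2", paste0("B", 1:8)),
    f1 = gene_signature("f1", paste0("C", 1:8)),
    f2 = gene_signature("f2", paste0("D", 1:8))
  )
  membership <- list(N3MC = c("m1", "m2"), CP2E = c("f1", "f2"))
  sp <- assemble_pattern_signatures(markers, membership)
  red <- reduce_signature(sp, markers, membership, k_total = 20)
  expect_equal(length(red$N3MC$genes), 10)
  expect_equal(length(red$CP2E$genes), 10)
  expect_equal(red$N3MC$genes[1:4], c("A1", "B1", "A2", "B2"))
  red2 <- reduce_signature(sp, markers, membership, k_total = 2)
  expect_equal(red2$N3MC$genes, "A1")
  expect_equal(red2$CP2E$genes, "C1")
  expect_identical(reduce_signature(sp, markers, membership, 20), red)
})
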