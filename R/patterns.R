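#' Per-patient cell-cluster composition
#'
#' Proportions are computed within compartments over tumor-tissue cells
#' only: `P[patient, cluster]` is the patient's cell count in the cluster
#' divided by the patient's total cell count in that cluster's compartment.
#' A z-scored copy (`Z`, per cluster across patients) is attached for the
#' pattern PCA; patients lacking a compartment entirely get missing
#' proportions with a warning.
#'
#' @param ca Annotated `cluster_assignment` (cell types and compartments
#'   filled in).
#' @param meta Cell metadata with `barcode`, `patient` and `tissue`.
#' @param compartments Compartments included (the microenvironment by
#'   default; epithelial tumor cells are not part of composition).
#' @return Object of class `composition_table` with `patients`, `clusters`
#'   (cluster id, label, compartment), `P` and `Z`.
#' @export
compute_proportions <- function(ca, meta,
                                compartments = c("myeloid", "lymphoid",
                                                 "endothelial",
                                                 "fibroblastic")) {
  meta <- meta[match(names(ca$clusters), meta$barcode), ]
  tumor_cells <- meta$tissue == "tumor"
  info <- ca$info[ca$info$compartment %in% compartments, , drop = FALSE]
  if (nrow(info) == 0) stopf("no clusters in the requested compartments")
  patients <- sort(unique(meta$patient[tumor_cells]))

  P <- matrix(0, length(patients), nrow(info),
              dimnames = list(patients, as.character(info$cluster)))
  for (pi in seq_along(patients)) {
    sel <- tumor_cells & meta$patient == patients[pi]
    cl <- ca$clusters[sel]
    cl_comp <- info$compartment[match(cl, info$cluster)]
    for (r in seq_len(nrow(info))) {
      comp_total <- sum(cl_comp == info$compartment[r], na.rm = TRUE)
      if (comp_total == 0) {
        P[pi, r] <- NA
      } else {
        P[pi, r] <- sum(cl == info$cluster[r]) / comp_total
      }
    }
  }
  if (anyNA(P))
    warnf("patient(s) with an empty compartment; proportions set missing")
  structure(
    list(patients = patients,
         clusters = data.frame(cluster = info$cluster,
                               label = info$cell_type,
                               compartment = info$compartment,
                               stringsAsFactors = FALSE),
         P = P, Z = zscore_cols(P)),
    class = "composition_table"
  )
}

zscore_cols <- function(P) {
  mu <- colMeans(P, na.rm = TRUE)
  sdv <- apply(P, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(P, 2, mu), 2, sdv, "/")
}

#' Exclude clusters occurring in few patients
#'
#' Drops cluster columns with nonzero proportion in fewer than
#' `min_patients` patients. Remaining proportions keep their original
#' compartment denominators (no renormalization).
#'
#' @param ct A [compute_proportions()] result.
#' @param min_patients Minimum number of patients a cluster must occur in.
#' @return The filtered `composition_table`.
#' @export
filter_rare_clusters <- function(ct, min_patients = 3) {
  occ <- colSums(ct$P > 0, na.rm = TRUE)
  keep <- occ >= min_patients
  if (!any(keep)) stopf("all clusters occur in fewer than %d patients",
                        min_patients)
  ct$P <- ct$P[, keep, drop = FALSE]
  ct$Z <- zscore_cols(ct$P)
  ct$clusters <- ct$clusters[keep, , drop = FALSE]
  ct
}

#' Pattern PCA and archetype grouping of patients
#'
#' PCA on the z-scored composition matrix; the sign of PC1 is fixed so that
#' the mean loading of the CP2E anchor clusters is positive, and patients
#' are grouped CP2E if their PC1 score is positive, N3MC otherwise.
#'
#' @param ct A `composition_table` (>= 4 patients).
#' @param anchors Named list with `CP2E` and `N3MC` cluster-label vectors;
#'   labels are matched against `ct$clusters$label`.
#' @return Object of class `pattern_assignment` with `pattern_pc1`,
#'   `group`, `anchor_clusters` and `loadings`.
#' @export
pattern_pca <- function(ct, anchors = archetype_anchors()) {
  if (length(ct$patients) < 4) stopf("need >= 4 patients")
  Z <- ct$Z
  Z[is.na(Z)] <- 0
  hit_cp2e <- which(ct$clusters$label %in% anchors$CP2E)
  if (length(hit_cp2e) == 0)
    stopf("no CP2E anchor clusters present; missing: %s",
          paste(anchors$CP2E, collapse = ", "))
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  pc1 <- pc$x[, 1]
  if (mean(load1[hit_cp2e]) < 0) {
    pc1 <- -pc1
    load1 <- -load1
  }
  group <- ifelse(pc1 > 0, "CP2E", "N3MC")
  structure(
    list(pattern_pc1 = setNames(pc1, ct$patients),
         group = setNames(group, ct$patients),
         anchor_clusters = anchors,
         loadings = setNames(load1, colnames(Z))),
    class = "pattern_assignment"
  )
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat(sprintf("<pattern_assignment> %d patients: %d CP2E, %d N3MC\n",
              length(x$group), sum(x$group == "CP2E"),
              sum(x$group == "N3MC")))
  invisible(x)
}

#' Cluster-proportion correlation network
#'
#' Spearman correlation (average ranks for ties) between all cluster pairs
#' across patients. Two-sided p-values are computed by exact enumeration
#' over all rank permutations when there are at most 9 patients and by the
#' t approximation otherwise. Only edges with `rho > rho_min` and
#' `p < p_max` are retained.
#'
#' @param ct A `composition_table` (>= 5 patients).
#' @param rho_min,p_max Retention thresholds.
#' @return Data frame of retained edges: cluster_a, cluster_b (labels),
#'   rho, p. Pairs involving a constant column are skipped with a message.
#' @export
correlation_network <- function(ct, rho_min = 0.7, p_max = 0.05) {
  n <- length(ct$patients)
  if (n < 5) stopf("need >= 5 patients for meaningful Spearman p-values")
  P <- ct$P
  labels <- ct$clusters$label
  k <- ncol(P)
  edges <- list()
  perms <- if (n <= 9) all_permutations(n) else NULL
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      x <- P[, a]
      y <- P[, b]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 5) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        message(sprintf("constant proportions (%s vs %s); pair skipped",
                        labels[a], labels[b]))
        next
      }
      sp <- spearman_test(x[ok], y[ok], perms)
      if (sp$rho > rho_min && sp$p < p_max)
        edges[[length(edges) + 1]] <- data.frame(
          cluster_a = labels[a], cluster_b = labels[b],
          rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0)
    return(data.frame(cluster_a = character(), cluster_b = character(),
                      rho = numeric(), p = numeric()))
  do.call(rbind, edges)
}

# Spearman rho with average ranks; exact two-sided permutation p when a
# permutation matrix is supplied (n <= 9), else t approximation.
spearman_test <- function(x, y, perms = NULL) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- suppressWarnings(cor(rx, ry))
  n <- length(x)
  if (!is.null(perms) && nrow(perms) >= factorial(n) && ncol(perms) == n) {
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    rho_all <- suppressWarnings(as.numeric(cor(t(ry_perm), rx)))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else if (!is.null(perms)) {
    stopf("internal: permutation matrix does not match n = %d", n)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Assemble pattern signatures from member-cluster markers
#'
#' The signature of a pattern is the union of its member clusters' marker
#' genes, deduplicated; genes occurring in both patterns' unions are
#' removed from both so the signatures are disjoint.
#'
#' @param markers Named list of [gene_signature] objects (one per cluster
#'   label, e.g. from [top_markers()]).
#' @param membership Named list with `N3MC` and `CP2E` member cluster
#'   labels.
#' @return Named list of two disjoint [gene_signature] objects.
#' @export
assemble_pattern_signatures <- function(markers,
                                        membership = archetype_anchors()) {
  take <- function(cls) {
    miss <- setdiff(cls, names(markers))
    if (length(miss) > 0)
      stopf("no marker signature for cluster(s): %s",
            paste(miss, collapse = ", "))
    genes <- unlist(lapply(markers[cls], `[[`, "genes"), use.names = FALSE)
    genes[!duplicated(genes)]
  }
  g_n3mc <- take(membership$N3MC)
  g_cp2e <- take(membership$CP2E)
  shared <- intersect(g_n3mc, g_cp2e)
  g_n3mc <- setdiff(g_n3mc, shared)
  g_cp2e <- setdiff(g_cp2e, shared)
  if (length(g_n3mc) == 0 || length(g_cp2e) == 0)
    stopf("a pattern signature is empty after removing shared genes")
  list(N3MC = gene_signature("N3MC", g_n3mc, direction = "up"),
       CP2E = gene_signature("CP2E", g_cp2e, direction = "up"))
}

#' Compact prognostic signature pair
#'
#' Selects `k_total / 2` genes per pattern by round-robin over the
#' pattern's member clusters, taking each cluster's top-ranked marker not
#' yet used and not shared between patterns, until the budget fills.
#' Deterministic.
#'
#' @param sig_pair Output of [assemble_pattern_signatures()] (defines the
#'   admissible, disjoint gene pools).
#' @param markers Per-cluster marker signatures (rank order preserved).
#' @param membership Pattern membership as in
#'   [assemble_pattern_signatures()].
#' @param k_total Total genes across both patterns.
#' @return Named list of two [gene_signature] objects; if a pattern's pool
#'   is smaller than its budget all its genes are returned with a message.
#' @export
reduce_signature <- function(sig_pair, markers,
                             membership = archetype_anchors(),
                             k_total = 20) {
  budget <- floor(k_total / 2)
  pick <- function(pattern) {
    pool <- sig_pair[[pattern]]$genes
    cls <- membership[[pattern]]
    queues <- lapply(markers[cls], function(s) intersect(s$genes, pool))
    chosen <- character(0)
    repeat {
      advanced <- FALSE
      for (q in seq_along(queues)) {
        if (length(chosen) >= budget) break
        avail <- setdiff(queues[[q]], chosen)
        if (length(avail) > 0) {
          chosen <- c(chosen, avail[1])
          advanced <- TRUE
        }
      }
      if (length(chosen) >= budget || !advanced) break
    }
    if (length(chosen) < budget)
      message(sprintf("pattern %s: only %d gene(s) available for budget %d",
                      pattern, length(chosen), budget))
    chosen
  }
  list(N3MC = gene_signature("N3MC_compact", pick("N3MC"), direction = "up"),
       CP2E = gene_signature("CP2E_compact", pick("CP2E"), direction = "up"))
}
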