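# Independent oracles used by the unit and acceptance tests. These are
# written as plain, slow loops against dense matrices, deliberately apart
# from the package's vectorized implementations.

# Brute-force expression-bin-matched module score on a dense matrix.
module_score_oracle <- function(dense, sig_genes, n_bins = 24, n_ctrl = 100,
                                seed = 0) {
  genes <- rownames(dense)
  avg <- apply(dense, 1, mean)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / length(avg) * n_bins)
  names(bin) <- genes
  present <- sig_genes[sig_genes %in% genes]
  ctrl <- tmepatterns:::with_seed(seed, {
    out <- character(0)
    for (g in present) {
      pool <- genes[bin == bin[g]]
      pool <- setdiff(pool, present)
      if (length(pool) == 0) next
      out <- c(out, sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
    }
    out
  })
  scores <- numeric(ncol(dense))
  for (c in seq_len(ncol(dense))) {
    s <- mean(dense[present, c])
    k <- if (length(ctrl) > 0) mean(dense[ctrl, c]) else 0
    scores[c] <- s - k
  }
  setNames(scores, colnames(dense))
}

# Step-by-step single-sample running-sum enrichment score for one sample.
ssgsea_oracle_one <- function(expr, set_genes, alpha = 0.25) {
  genes <- names(expr)
  r <- rank(expr)
  ord <- order(expr, decreasing = TRUE)
  in_set <- genes[ord] %in% set_genes
  n <- length(genes)
  n_in <- sum(in_set)
  denom_in <- 0
  for (j in seq_len(n)) if (in_set[j]) denom_in <- denom_in + abs(r[ord][j])^alpha
  cdf_in <- 0
  cdf_out <- 0
  es <- 0
  for (j in seq_len(n)) {
    if (in_set[j]) cdf_in <- cdf_in + abs(r[ord][j])^alpha / denom_in
    else cdf_out <- cdf_out + 1 / (n - n_in)
    es <- es + (cdf_in - cdf_out)
  }
  unname(es)
}

# Hand-computed two-group log-rank chi-squared (hypergeometric variance).
logrank_chi2_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# All permutations of 1..n via Heap's algorithm (iterative), independent of
# the recursive generator inside the package.
perms_heap <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  c_vec <- rep(1L, n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_vec[i] < i) {
      if (i %% 2L == 1L) {
        tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_vec[i]]; a[c_vec[i]] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_vec[i] <- c_vec[i] + 1L
      i <- 1L
    } else {
      c_vec[i] <- 1L
      i <- i + 1L
    }
  }
  out
}

# Exhaustive two-sided Spearman permutation p-value.
spearman_exact_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_of <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  obs <- rho_of(rx, ry)
  pm <- perms_heap(length(x))
  cnt <- 0L
  for (r in seq_len(nrow(pm))) {
    if (abs(rho_of(rx, ry[pm[r, ]])) >= abs(obs) - 1e-12) cnt <- cnt + 1L
  }
  list(rho = obs, p = cnt / nrow(pm))
}

# Adjusted Rand index.
adjusted_rand_index <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  ai <- sum(choose(rowSums(t), 2))
  bj <- sum(choose(colSums(t), 2))
  e <- ai * bj / choose(n, 2)
  (sij - e) / ((ai + bj) / 2 - e)
}

# Standard pipeline through clustering and annotation on a simulated cohort.
run_sc_pipeline <- function(sim, n_hvg = 500, n_pcs = 15, resolution = 0.8,
                            seed = 0) {
  qc <- qc_filter(sim$counts, sim$meta)
  nm <- normalize_log(qc$counts)
  hvg <- select_hvg(nm, min(n_hvg, nrow(nm)))
  emb <- pca_embed(nm, hvg, n_pcs)
  ca <- cluster_graph(build_snn(emb), resolution, seed = seed)
  refs <- program_signatures(default_cell_programs())
  ca <- suppressWarnings(annotate_clusters(ca, nm, refs))
  ca <- call_tumor_clusters(ca, qc$meta)
  list(qc = qc, norm = nm, hvg = hvg, emb = emb, ca = ca)
}
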