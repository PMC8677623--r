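toy_bulk <- function(X, time = NULL, event = NULL) {
  n <- nrow(X)
  if (is.null(time)) time <- seq_len(n)
  if (is.null(event)) event <- rep(1, n)
  bulk_cohort(X, time, event)
}

test_that("ssGSEA matches the independent running-sum oracle", {
  set.seed(25)
  X <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(paste0("S", 1:3), paste0("G", 1:20)))
  sigs <- list(gene_signature("setA", paste0("G", c(1, 4, 7, 12))),
               gene_signature("setB", paste0("G", 15:20)))
  es <- ssgsea(X, sigs, alpha = 0.25, normalize = FALSE)
  for (i in 1:3) {
    for (s in seq_along(sigs)) {
      want <- ssgsea_oracle_one(setNames(X[i, ], colnames(X)),
                                sigs[[s]]$genes, alpha = 0.25)
      expect_equal(unname(es[i, s]), want, tolerance = 1e-9)
    }
  }
  # normalization rescales by the global range
  esn <- ssgsea(X, sigs, normalize = TRUE)
  expect_equal(as.numeric(esn), as.numeric(es / (max(es) - min(es))),
               tolerance = 1e-12)
})

test_that("ssGSEA is rank-based and consistent across identical samples", {
  set.seed(26)
  X <- matrix(rnorm(2 * 30), 2, 30,
              dimnames = list(c("S1", "S2"), paste0("G", 1:30)))
  X[2, ] <- X[1, ]
  sig <- gene_signature("s", paste0("G", 1:5))
  es <- ssgsea(X, list(sig), normalize = FALSE)
  expect_equal(es[1, 1], es[2, 1])
  # a rank-preserving monotone transform leaves the score unchanged
  X2 <- X
  X2[1, ] <- exp(X2[1, ]) * 3 + 1
  es2 <- ssgsea(X2, list(sig), normalize = FALSE)
  expect_equal(es2[1, 1], es[1, 1], tolerance = 1e-12)
  expect_error(ssgsea(X, list(gene_signature("bad", "ZZZ"))), "bad")
})

test_that("appending universally low out-of-set genes shifts ES predictably", {
  set.seed(27)
  X <- matrix(rnorm(2 * 25), 2, 25,
              dimnames = list(c("S1", "S2"), paste0("G", 1:25)))
  sig <- gene_signature("s", paste0("G", 1:6))
  es <- ssgsea(X, list(sig), normalize = FALSE)
  Xa <- cbind(X, matrix(min(X) - 5 + 0, 2, 3,
                        dimnames = list(NULL, paste0("PAD", 1:3))))
  esa <- ssgsea(Xa, list(sig), normalize = FALSE)
  # the padded genes rank at the bottom, tied: the in-set running sum is
  # unchanged over the original genes; scores move together across samples
  expect_equal(order(es[, 1]), order(esa[, 1]))
})

test_that("pattern scores and median dichotomization follow their rules", {
  es <- matrix(c(0.4, 0.1, 0.3, 0.3), 2, 2,
               dimnames = list(c("S1", "S2"), c("CP2E", "N3MC")))
  d <- pattern_score(es, "CP2E", "N3MC")
  expect_equal(unname(d), c(0.1, -0.2))
  expect_equal(unname(pattern_score(es, "CP2E", "N3MC", mode = "ratio")),
               c(0.4 / 0.3, 0.1 / 0.3))
  es2 <- es; es2["S1", "N3MC"] <- 0
  expect_error(pattern_score(es2, "CP2E", "N3MC", mode = "ratio"),
               "non-positive")

  expect_equal(as.character(stratify_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # odd n: the median sample itself goes low
  expect_equal(as.character(stratify_median(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_warning(g <- stratify_median(c(2, 2, 2)), "identical")
  expect_true(all(g == "low"))
})

test_that("log-rank matches the hand-computed hypergeometric sum", {
  X <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("S", 1:6), paste0("G", 1:4)))
  bc <- toy_bulk(X, time = 1:6, event = rep(1, 6))
  groups <- factor(rep(c("A", "B"), 3))
  res <- km_logrank(bc, groups)
  want <- logrank_chi2_oracle(bc$survival$time, bc$survival$event, groups)
  expect_equal(res$logrank_chi2, want, tolerance = 1e-10)
  expect_equal(res$logrank_p, pchisq(want, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("log-rank degenerate cases behave as expected", {
  X <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(paste0("S", 1:8), paste0("G", 1:3)))
  # identical survival experience in both groups: chi2 = 0, p = 1
  bc <- toy_bulk(X, time = rep(c(1, 2, 3, 4), 2), event = rep(1, 8))
  res <- km_logrank(bc, factor(rep(c("A", "B"), each = 4)))
  expect_equal(res$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(res$logrank_p, 1, tolerance = 1e-12)
  # symmetry in group labels
  res2 <- km_logrank(toy_bulk(X, time = 1:8, event = rep(1, 8)),
                     factor(rep(c("A", "B"), 4)))
  res3 <- km_logrank(toy_bulk(X, time = 1:8, event = rep(1, 8)),
                     factor(rep(c("B", "A"), 4)))
  expect_equal(res2$logrank_chi2, res3$logrank_chi2, tolerance = 1e-12)
  # all-censored data: KM curves stay at 1, log-rank errors
  bc0 <- toy_bulk(X, time = 1:8, event = rep(0, 8))
  expect_error(km_logrank(bc0, factor(rep(c("A", "B"), 4))), "no events")
  fit <- survival::survfit(survival::Surv(bc0$survival$time,
                                          bc0$survival$event) ~ 1)
  expect_true(all(fit$surv == 1))
})

test_that("Cox fit recovers a known log hazard ratio", {
  betas <- vapply(1:20, function(r) {
    n <- 500
    x <- tmepatterns:::with_seed(100 + r, {
      grp <- rbinom(n, 1, 0.5)
      tt <- rexp(n, rate = 0.2 * exp(log(2) * grp))
      list(grp = grp, tt = tt)
    })
    X <- matrix(0, n, 2, dimnames = list(paste0("S", 1:n), c("G1", "G2")))
    bc <- toy_bulk(X, time = x$tt, event = rep(1, n))
    cox_fit(bc, x$grp)$cox_beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - log(2)), 0.1)
})

test_that("Cox beta matches an independent partial-likelihood maximizer", {
  set.seed(28)
  n <- 40
  grp <- rep(0:1, each = 20)
  tt <- rexp(n, rate = 0.5 * exp(0.7 * grp))  # continuous: no ties
  X <- matrix(0, n, 2, dimnames = list(paste0("S", 1:n), c("G1", "G2")))
  bc <- toy_bulk(X, time = tt, event = rep(1, n))
  got <- cox_fit(bc, grp)$cox_beta
  # independent one-dimensional maximization of the log partial likelihood
  pll <- function(beta) {
    ll <- 0
    for (i in seq_len(n)) {
      risk <- tt >= tt[i]
      ll <- ll + beta * grp[i] - log(sum(exp(beta * grp[risk])))
    }
    ll
  }
  want <- optimize(pll, c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(got, want, tolerance = 1e-6)
  expect_error(cox_fit(bc, rep(1, n)), "constant")
})
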