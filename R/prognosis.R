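#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (descending; ties get
#' average ranks) and the enrichment score of a set is the sum over the
#' ranked list of the difference between the rank-weighted in-set empirical
#' CDF (weights `|rank|^alpha`) and the uniform out-of-set ECDF — the
#' classical single-sample running-sum statistic. With `normalize = TRUE`
#' all scores are divided by the global range (max - min) over the whole
#' score matrix.
#'
#' @param bc A [bulk_cohort] or a sample x gene expression matrix.
#' @param sigs List of [gene_signature] objects; a signature with no gene in
#'   the cohort is an error naming it.
#' @param alpha Rank weighting exponent.
#' @param normalize Divide by the global score range.
#' @return Sample x signature score matrix of class `enrichment_scores`,
#'   with the per-signature gene overlap in attribute `"overlap"`.
#' @export
ssgsea <- function(bc, sigs, alpha = 0.25, normalize = TRUE) {
  X <- if (inherits(bc, "bulk_cohort")) bc$X else as.matrix(bc)
  if (!is.list(sigs) || inherits(sigs, "gene_signature")) sigs <- list(sigs)
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  genes <- colnames(X)
  overlap <- vapply(sigs, function(s) sum(s$genes %in% genes), integer(1))
  if (any(overlap == 0))
    stopf("signature(s) with no genes in the cohort: %s",
          paste(names(sigs)[overlap == 0], collapse = ", "))

  ng <- length(genes)
  ES <- matrix(0, nrow(X), length(sigs),
               dimnames = list(rownames(X), names(sigs)))
  in_set <- sapply(sigs, function(s) genes %in% s$genes)
  for (i in seq_len(nrow(X))) {
    expr <- X[i, ]
    r <- rank(expr)                 # low expr -> low rank; ties averaged
    ord <- order(expr, decreasing = TRUE)
    w <- abs(r)^alpha
    for (j in seq_along(sigs)) {
      m <- in_set[ord, j]
      wo <- w[ord]
      cdf_in <- cumsum(wo * m) / sum(wo * m)
      cdf_out <- cumsum(!m) / (ng - sum(m))
      ES[i, j] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  structure(ES, overlap = overlap, alpha = alpha, normalized = normalize,
            class = c("enrichment_scores", class(ES)))
}

#' Combine two signature scores into one pattern score
#'
#' Default is the difference `ES[pos] - ES[neg]`, which is defined for
#' normalized scores of any sign; the ratio is available and errors when
#' any denominator score is non-positive.
#'
#' @param es An [ssgsea()] score matrix.
#' @param pos,neg Signature column names.
#' @param mode `"difference"` or `"ratio"`.
#' @return Named per-sample numeric score.
#' @export
pattern_score <- function(es, pos, neg, mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (!all(c(pos, neg) %in% colnames(es)))
    stopf("signatures '%s' and '%s' must both be scored", pos, neg)
  if (mode == "difference") return(es[, pos] - es[, neg])
  if (any(es[, neg] <= 0))
    stopf("ratio undefined: ES['%s'] has non-positive values", neg)
  es[, pos] / es[, neg]
}

#' Median dichotomization of a per-sample score
#'
#' High if the score exceeds the median, low if at or below it (ties go to
#' the low group).
#'
#' @param score Named per-sample numeric vector (>= 2 samples).
#' @return Factor with levels `low`, `high`.
#' @export
stratify_median <- function(score) {
  if (length(score) < 2) stopf("need >= 2 samples")
  med <- median(score)
  if (all(score == score[1])) warnf("all scores identical; all samples low")
  factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard log-rank
#' statistic (observed minus expected events with hypergeometric variance,
#' chi-squared with 1 degree of freedom).
#'
#' @param bc A [bulk_cohort].
#' @param groups Two-level grouping aligned with the cohort samples.
#' @return Object of class `survival_result` with `km` (a
#'   `survival::survfit` object), `logrank_chi2` and `logrank_p`.
#' @export
km_logrank <- function(bc, groups) {
  sv <- bc$survival
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stopf("need exactly two non-empty groups")
  if (sum(sv$event) == 0)
    stopf("no events in the cohort; log-rank p undefined")
  s <- survival::Surv(sv$time, sv$event)
  fit <- survival::survfit(s ~ groups)
  sdf <- survival::survdiff(s ~ groups)
  chi2 <- as.numeric(sdf$chisq)
  structure(list(km = fit, logrank_chi2 = chi2,
                 logrank_p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 groups = groups),
            class = "survival_result")
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow handling of ties
#' (via the survival package), Wald confidence interval
#' `exp(beta +/- 1.96 se)`.
#'
#' @param bc A [bulk_cohort] with at least one event.
#' @param covariate Per-sample numeric covariate or group factor
#'   (non-constant).
#' @return Object of class `survival_result` with `cox_beta`, `HR`,
#'   `ci_low`, `ci_high`, `cox_p` and the underlying `coxph` fit.
#' @export
cox_fit <- function(bc, covariate) {
  sv <- bc$survival
  if (sum(sv$event) < 1) stopf("need at least one event")
  xv <- if (is.factor(covariate) || is.character(covariate))
    as.numeric(as.factor(covariate)) - 1 else as.numeric(covariate)
  if (length(unique(xv)) < 2) stopf("covariate is constant")
  fit <- survival::coxph(
    survival::Surv(sv$time, sv$event) ~ xv, ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15)
    stopf(paste("monotone partial likelihood (perfect separation);",
                "penalized fitting is out of scope"))
  structure(
    list(cox_beta = beta, HR = exp(beta),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         cox_p = 2 * pnorm(-abs(beta / se)), fit = fit),
    class = "survival_result"
  )
}

#' @export
print.survival_result <- function(x, ...) {
  if (!is.null(x$logrank_chi2))
    cat(sprintf("log-rank chi2 = %.4f, p = %.4g\n", x$logrank_chi2,
                x$logrank_p))
  if (!is.null(x$cox_beta))
    cat(sprintf("Cox HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n", x$HR,
                x$ci_low, x$ci_high, x$cox_p))
  invisible(x)
}
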