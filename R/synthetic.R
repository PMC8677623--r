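#' Cell-type expression program
#'
#' Defines one simulated cell type: its compartment, a disjoint set of
#' marker genes boosted by `exp(marker_logfc)` in cells of the type, and a
#' baseline expression level for all other genes.
#'
#' @param name Cell-type label.
#' @param compartment One of epithelial, myeloid, lymphoid, endothelial,
#'   fibroblastic.
#' @param marker_genes Marker gene symbols (disjoint across programs).
#' @param marker_logfc Natural-log fold boost of markers in own cells.
#' @param baseline_mean Relative baseline expression of non-marker genes.
#' @return Object of class `cell_type_program`.
#' @export
cell_type_program <- function(name, compartment, marker_genes,
                              marker_logfc = 2.0, baseline_mean = 1.0) {
  compartment <- match.arg(compartment, c("epithelial", "myeloid", "lymphoid",
                                          "endothelial", "fibroblastic"))
  if (marker_logfc <= 0) stopf("marker_logfc must be positive")
  structure(list(name = name, compartment = compartment,
                 marker_genes = as.character(marker_genes),
                 marker_logfc = marker_logfc, baseline_mean = baseline_mean),
            class = "cell_type_program")
}

#' Default simulated cell-type programs
#'
#' Eleven programs emulating the annotated clusters of a lung
#' adenocarcinoma atlas: tumor and alveolar epithelial cells, normal-like
#' and cancer-associated myofibroblasts, non- and pro-inflammatory
#' monocyte-derived macrophages, myeloid and plasmacytoid dendritic cells,
#' NK cells, conventional T cells, exhausted CD8 T cells, and endothelium.
#'
#' @param n_markers Marker genes per program.
#' @return Named list of [cell_type_program] objects.
#' @export
default_cell_programs <- function(n_markers = 20) {
  specs <- list(
    tumor_cell            = "epithelial",
    alveolar_epithelial   = "epithelial",
    myofib_normal_like    = "fibroblastic",
    myofib_cancer_assoc   = "fibroblastic",
    momac_noninflammatory = "myeloid",
    momac_proinflammatory = "myeloid",
    dc_myeloid            = "myeloid",
    dc_plasmacytoid       = "myeloid",
    nk_cell               = "lymphoid",
    t_conventional        = "lymphoid",
    cd8_exhausted         = "lymphoid",
    endothelial           = "endothelial"
  )
  tags <- toupper(abbreviate(names(specs), 6))
  out <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    out[[nm]] <- cell_type_program(
      name = nm, compartment = specs[[i]],
      marker_genes = sprintf("%s.M%02d", tags[i], seq_len(n_markers))
    )
  }
  out
}

#' Microenvironmental archetype
#'
#' An archetype is a prior over per-patient cell-type composition (Dirichlet
#' concentrations) plus the center of the tumor-cell differentiation latent.
#' The N3MC archetype elevates normal-like myofibroblasts, non-inflammatory
#' monocyte-derived macrophages, NK cells, myeloid DCs and conventional
#' T cells and centers differentiation high (alveolar/club-like); CP2E
#' elevates cancer-associated myofibroblasts, proinflammatory macrophages,
#' plasmacytoid DCs and exhausted CD8 T cells and centers it low
#' (undifferentiated).
#'
#' @param name `"N3MC"` or `"CP2E"`.
#' @param proportion_alpha Named vector of Dirichlet concentrations, one per
#'   cell-type program.
#' @param differentiation_mean Center of the tumor-cell latent in \[0, 1\].
#' @return Object of class `archetype_spec`.
#' @export
archetype_spec <- function(name = c("N3MC", "CP2E"), proportion_alpha,
                           differentiation_mean) {
  name <- match.arg(name)
  if (any(proportion_alpha <= 0)) stopf("Dirichlet concentrations must be > 0")
  if (differentiation_mean < 0 || differentiation_mean > 1)
    stopf("differentiation_mean must be in [0, 1]")
  structure(list(name = name, proportion_alpha = proportion_alpha,
                 differentiation_mean = differentiation_mean),
            class = "archetype_spec")
}

#' Anchor cell types of the two archetypes
#' @return Named list with elements `N3MC` and `CP2E`.
#' @export
archetype_anchors <- function() {
  list(
    N3MC = c("myofib_normal_like", "momac_noninflammatory", "nk_cell",
             "dc_myeloid", "t_conventional"),
    CP2E = c("myofib_cancer_assoc", "momac_proinflammatory",
             "dc_plasmacytoid", "cd8_exhausted")
  )
}

#' Default archetype specifications
#'
#' Anchor cell types of an archetype receive `anchor_fold` times the
#' concentration they have under the opposite archetype, a two-fold
#' composition shift by default.
#'
#' @param programs Output of [default_cell_programs()].
#' @param anchor_fold Concentration fold between own- and opposite-pattern
#'   anchors.
#' @param base_alpha Concentration of non-anchor types.
#' @return List of two [archetype_spec] objects.
#' @export
default_archetypes <- function(programs = default_cell_programs(),
                               anchor_fold = 2, base_alpha = 24) {
  anchors <- archetype_anchors()
  types <- names(programs)
  mk <- function(own, other, dmean) {
    a <- setNames(rep(base_alpha, length(types)), types)
    a[anchors[[own]]] <- base_alpha * sqrt(anchor_fold)
    a[anchors[[other]]] <- base_alpha / sqrt(anchor_fold)
    a["tumor_cell"] <- base_alpha * 1.5
    archetype_spec(own, a, dmean)
  }
  list(
    N3MC = mk("N3MC", "CP2E", 0.75),
    CP2E = mk("CP2E", "N3MC", 0.25)
  )
}

# Gene universe for a scenario: program markers, planted differentiation
# programs, mitochondrial and hemoglobin genes, background filler.
build_gene_universe <- function(programs, n_genes, n_axis_genes = 30) {
  markers <- unlist(lapply(programs, `[[`, "marker_genes"), use.names = FALSE)
  if (anyDuplicated(markers)) stopf("program marker genes must be disjoint")
  alv <- sprintf("ALVSIG.G%02d", seq_len(n_axis_genes))
  und <- sprintf("UNDSIG.G%02d", seq_len(n_axis_genes))
  mito <- paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND5", "CO1", "CO2",
                          "CO3", "ATP6", "ATP8", "CYB", "ND4L", "ND6"))
  hb <- c("HBA1", "HBA2", "HBB", "HBD")
  fixed <- c(markers, alv, und, mito, hb)
  n_bg <- n_genes - length(fixed)
  if (n_bg < 0)
    stopf("n_genes = %d too small for %d program/planted genes",
          n_genes, length(fixed))
  bg <- sprintf("BG.G%05d", seq_len(n_bg))
  list(genes = c(fixed, bg), markers_by_type = lapply(programs, `[[`,
                                                      "marker_genes"),
       sig_alveolar = alv, sig_undiff = und, mito = mito, hb = hb)
}

#' Simulate a multi-patient single-cell cohort with planted structure
#'
#' Each patient is assigned an archetype (alternating, so both are always
#' represented). Per patient, tumor-sample cell-type counts are drawn from a
#' Dirichlet-multinomial with the archetype's concentrations, and a smaller
#' matched normal sample is drawn from a fixed normal-tissue prior without
#' tumor cells. Per cell, counts are negative binomial (dispersion 0.3) with
#' lognormal library sizes (meanlog 9, sdlog 0.3); a program's marker genes
#' are boosted by `exp(marker_logfc)` in its own cells. Tumor cells carry a
#' differentiation latent `u ~ N(center, 0.15)` truncated to \[0, 1\]; a
#' planted alveolar/club-like gene program scales as `exp(axis_logfc * u)`
#' and an undifferentiated program as `exp(axis_logfc * (1 - u))`.
#'
#' A fraction `qc_artifact_frac` of each patient's tumor cells is corrupted
#' to violate exactly one quality-control rule each (cycling through low
#' gene count, mitochondrial fraction > 0.30, hemoglobin fraction > 0.05),
#' so filter attribution is testable. Dedicated `MT-` prefixed and
#' hemoglobin genes exist in every scenario.
#'
#' @param n_patients Number of patients (>= 2; archetypes alternate).
#' @param cells_per_patient Tumor-sample cells per patient.
#' @param programs,archetypes Scenario definition; see
#'   [default_cell_programs()], [default_archetypes()].
#' @param qc_artifact_frac Fraction of tumor cells corrupted to fail QC.
#' @param n_genes Total gene universe size.
#' @param normal_cells_frac Normal-sample size as a fraction of
#'   `cells_per_patient`.
#' @param axis_logfc Strength of the differentiation programs.
#' @param dispersion Negative binomial dispersion (1/size).
#' @param seed Random seed; fully determines the output.
#' @return List with `counts` (sparse genes x cells), `meta` (data frame:
#'   barcode, patient, tissue) and `truth` (per-cell and per-patient ground
#'   truth plus planted signature gene lists). `counts` and `meta` carry no
#'   truth fields.
#' @export
simulate_sc_cohort <- function(n_patients = 10, cells_per_patient = 500,
                               programs = default_cell_programs(),
                               archetypes = default_archetypes(programs),
                               qc_artifact_frac = 0, n_genes = 1000,
                               normal_cells_frac = 0.25, axis_logfc = 2,
                               dispersion = 0.3, seed = 1) {
  if (n_patients < 2) stopf("need n_patients >= 2 (one per archetype)")
  if (length(archetypes) < 2)
    stopf("both archetypes are required for pattern recovery")
  uni <- build_gene_universe(programs, n_genes)
  genes <- uni$genes
  ng <- length(genes)
  types <- names(programs)
  comp <- vapply(programs, `[[`, "", "compartment")

  with_seed(seed, {
    # per-gene baseline relative rates, shared across cell types
    baseline <- rlnorm(ng, meanlog = 0, sdlog = 0.5)
    names(baseline) <- genes
    baseline[uni$mito] <- baseline[uni$mito] * 0.8
    baseline[uni$hb] <- baseline[uni$hb] * 0.5

    # per-type rate vectors
    rate_by_type <- sapply(types, function(tp) {
      r <- baseline * programs[[tp]]$baseline_mean
      r[programs[[tp]]$marker_genes] <-
        r[programs[[tp]]$marker_genes] * exp(programs[[tp]]$marker_logfc)
      r
    })

    normal_alpha <- setNames(rep(3, length(types)), types)
    normal_alpha["alveolar_epithelial"] <- 12
    normal_alpha["tumor_cell"] <- 1e-6  # effectively absent from normal tissue

    arch_names <- rep(names(archetypes), length.out = n_patients)
    patients <- sprintf("P%02d", seq_len(n_patients))

    cell_rows <- list()
    count_cols <- list()
    size <- 1 / dispersion
    n_fail <- round(qc_artifact_frac * cells_per_patient)

    for (pi in seq_len(n_patients)) {
      arch <- archetypes[[arch_names[pi]]]
      # tumor sample
      p_tum <- rdirichlet1(arch$proportion_alpha[types])
      tum_types <- sample(types, cells_per_patient, replace = TRUE,
                          prob = p_tum)
      # normal sample
      n_norm <- round(normal_cells_frac * cells_per_patient)
      p_nrm <- rdirichlet1(normal_alpha)
      nrm_types <- if (n_norm > 0)
        sample(types, n_norm, replace = TRUE, prob = p_nrm) else character(0)

      all_types <- c(tum_types, nrm_types)
      tissue <- rep(c("tumor", "normal"), c(cells_per_patient, n_norm))
      n_cells <- length(all_types)
      barcodes <- sprintf("%s_%s_%04d", patients[pi],
                          ifelse(tissue == "tumor", "T", "N"), seq_len(n_cells))

      u <- rep(NA_real_, n_cells)
      qc_rule <- rep(NA_character_, n_cells)
      if (n_fail > 0) {
        fail_idx <- sample(seq_len(cells_per_patient), n_fail)
        qc_rule[fail_idx] <- rep(c("low_genes", "mito", "hemoglobin"),
                                 length.out = n_fail)
      }

      lib <- rlnorm(n_cells, meanlog = 9, sdlog = 0.3)
      cols <- vector("list", n_cells)
      for (ci in seq_len(n_cells)) {
        tp <- all_types[ci]
        r <- rate_by_type[, tp]
        if (tp == "tumor_cell") {
          uc <- min(1, max(0, rnorm(1, arch$differentiation_mean, 0.15)))
          u[ci] <- uc
          r[uni$sig_alveolar] <- r[uni$sig_alveolar] * exp(axis_logfc * uc)
          r[uni$sig_undiff] <- r[uni$sig_undiff] * exp(axis_logfc * (1 - uc))
          # differentiated tumor cells partially re-express the normal
          # alveolar program (at half strength, so cluster annotation by
          # own markers is unaffected); this is what anchors the axis sign
          if ("alveolar_epithelial" %in% names(programs)) {
            amk <- programs[["alveolar_epithelial"]]$marker_genes
            r[amk] <- r[amk] * exp(0.5 * axis_logfc * uc)
          }
        }
        mu <- lib[ci] * r / sum(r)
        x <- rnbinom(ng, size = size, mu = mu)
        x <- corrupt_cell(x, qc_rule[ci], genes, uni)
        cols[[ci]] <- x
      }
      count_cols[[pi]] <- cols
      cell_rows[[pi]] <- data.frame(
        barcode = barcodes, patient = patients[pi], tissue = tissue,
        true_type = all_types, compartment = comp[all_types],
        u = u, qc_rule = qc_rule, stringsAsFactors = FALSE
      )
    }

    cells <- do.call(rbind, cell_rows)
    rownames(cells) <- NULL
    dense <- do.call(cbind, unlist(count_cols, recursive = FALSE))
    dimnames(dense) <- list(genes, cells$barcode)
    counts <- as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")

    meta <- cells[, c("barcode", "patient", "tissue")]
    truth <- list(
      cells = cells,
      patients = data.frame(patient = patients, archetype = arch_names,
                            stringsAsFactors = FALSE),
      signatures = list(
        alveolar = uni$sig_alveolar, undiff = uni$sig_undiff,
        markers_by_type = uni$markers_by_type
      )
    )
    list(counts = counts, meta = meta, truth = truth)
  })
}

# Overwrite a simulated cell's counts so it violates exactly one QC rule.
corrupt_cell <- function(x, rule, genes, uni) {
  if (is.na(rule)) return(x)
  special <- genes %in% c(uni$mito, uni$hb)
  if (rule == "low_genes") {
    # concentrate the library in 100 ordinary genes: < 500 genes detected,
    # UMI total, mito and hemoglobin fractions untouched in aggregate
    total <- sum(x)
    keep <- which(!special)[1:100]
    x[] <- 0L
    x[keep] <- as.integer(rmultinom(1, total, rep(1, 100)))
  } else if (rule == "mito") {
    # mitochondrial counts equal to everything else: fraction = 0.5 > 0.30
    x[genes %in% uni$hb] <- 0L
    other <- sum(x[!genes %in% uni$mito])
    add <- as.integer(rmultinom(1, other, rep(1, length(uni$mito))))
    x[match(uni$mito, genes)] <- add
  } else if (rule == "hemoglobin") {
    # hemoglobin at ~7.4% of the library: > 0.05, mito fraction untouched
    x[genes %in% uni$mito] <- 0L
    other <- sum(x[!genes %in% uni$hb])
    add <- as.integer(rmultinom(1, ceiling(0.08 * other), rep(1, length(uni$hb))))
    x[match(uni$hb, genes)] <- add
  }
  x
}

#' Simulate a bulk cohort with planted archetypes and survival structure
#'
#' Each sample is a pseudobulk mixture: archetype-specific Dirichlet
#' proportions times per-program mean-expression vectors, log1p-transformed
#' with Gaussian noise on the log scale. Survival time is exponential with
#' rate `baseline_hazard * exp(survival_beta)` for CP2E samples and
#' `baseline_hazard` for N3MC; an independent exponential censoring time is
#' tuned so that approximately `censor_rate` of samples are censored.
#'
#' @param n_samples Number of samples (>= 20).
#' @param programs,archetypes Scenario definition as in
#'   [simulate_sc_cohort()].
#' @param survival_beta Log hazard ratio of CP2E vs N3MC (finite).
#' @param censor_rate Target censoring fraction in \[0, 1).
#' @param baseline_hazard N3MC event rate.
#' @param noise_sd SD of log-scale expression noise.
#' @param n_genes Gene universe size.
#' @param axis_logfc Differentiation-program strength, as in the
#'   single-cell generator.
#' @param seed Random seed.
#' @return List with `cohort` (a [bulk_cohort]) and `truth` (per-sample
#'   archetype and hazard multiplier). The cohort carries no truth fields.
#' @export
simulate_bulk_cohort <- function(n_samples = 100,
                                 programs = default_cell_programs(),
                                 archetypes = default_archetypes(programs),
                                 survival_beta = log(2), censor_rate = 0.3,
                                 baseline_hazard = 0.1, noise_sd = 0.3,
                                 n_genes = 500, axis_logfc = 2, seed = 1) {
  if (n_samples < 20) stopf("need n_samples >= 20")
  if (!is.finite(survival_beta)) stopf("survival_beta must be finite")
  uni <- build_gene_universe(programs, n_genes)
  genes <- uni$genes
  types <- names(programs)

  with_seed(seed, {
    baseline <- rlnorm(length(genes), meanlog = 0, sdlog = 0.5)
    names(baseline) <- genes
    rate_by_type <- sapply(types, function(tp) {
      r <- baseline * programs[[tp]]$baseline_mean
      r[programs[[tp]]$marker_genes] <-
        r[programs[[tp]]$marker_genes] * exp(programs[[tp]]$marker_logfc)
      r / sum(r)
    })

    arch_names <- rep(names(archetypes), length.out = n_samples)
    samples <- sprintf("B%03d", seq_len(n_samples))
    X <- matrix(0, n_samples, length(genes),
                dimnames = list(samples, genes))
    for (si in seq_len(n_samples)) {
      arch <- archetypes[[arch_names[si]]]
      props <- rdirichlet1(arch$proportion_alpha[types])
      rt <- rate_by_type
      dm <- arch$differentiation_mean
      rt[uni$sig_alveolar, "tumor_cell"] <-
        rt[uni$sig_alveolar, "tumor_cell"] * exp(axis_logfc * dm)
      rt[uni$sig_undiff, "tumor_cell"] <-
        rt[uni$sig_undiff, "tumor_cell"] * exp(axis_logfc * (1 - dm))
      mix <- as.numeric(rt %*% props)
      X[si, ] <- log1p(1e4 * mix / sum(mix)) + rnorm(length(genes), 0, noise_sd)
    }

    is_cp2e <- arch_names == "CP2E"
    haz <- baseline_hazard * exp(survival_beta * is_cp2e)
    t_event <- rexp(n_samples, rate = haz)
    if (censor_rate > 0) {
      c_rate <- mean(haz) * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n_samples, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    cohort <- bulk_cohort(X, time, event)
    truth <- data.frame(sample = samples, archetype = arch_names,
                        hazard_mult = exp(survival_beta * is_cp2e),
                        stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth,
         signatures = list(alveolar = uni$sig_alveolar,
                           undiff = uni$sig_undiff,
                           markers_by_type = uni$markers_by_type))
  })
}
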