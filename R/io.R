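#' Read a 10x Genomics triplet-format count matrix
#'
#' Loads a sparse UMI count matrix from a directory containing
#' `matrix.mtx(.gz)`, `features.tsv(.gz)` (or `genes.tsv(.gz)`) and
#' `barcodes.tsv(.gz)`. Gene identity is taken from the symbol column
#' (second column of the features file when present); duplicate symbols are
#' made unique with a numeric suffix (`A`, `A` becomes `A`, `A.1`). Matrix
#' Market 1-based coordinates are handled by the reader; the returned object
#' indexes from 1 as usual in R.
#'
#' @param dir_path Directory with the three triplet files.
#' @return A sparse `dgCMatrix` (genes x cells) with gene symbols as row
#'   names and barcodes as column names. When the features file has an ID
#'   column it is retained in the `"feature_ids"` attribute.
#' @export
read_10x_mtx <- function(dir_path) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir_path, f)
      if (file.exists(p)) return(p)
    }
    stopf("10x directory '%s' is missing one of: %s", dir_path,
          paste(cands, collapse = ", "))
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv",
                  "genes.tsv.gz"))
  bcs <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(bcs, header = FALSE, stringsAsFactors = FALSE)[[1]]

  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stopf("matrix is %d x %d but features/barcodes have %d/%d entries",
          nrow(m), ncol(m), nrow(features), length(barcodes))
  if (anyDuplicated(barcodes))
    stopf("duplicate cell barcodes in '%s'", bcs)
  if (any(m@x < 0)) stopf("negative counts in '%s'", mtx)

  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  genes <- make.unique(as.character(symbols))
  dimnames(m) <- list(genes, barcodes)
  if (ncol(features) >= 2) attr(m, "feature_ids") <- as.character(features[[1]])
  m
}

#' Write a count matrix in 10x triplet format
#'
#' Inverse of [read_10x_mtx()]; writes `matrix.mtx`, `features.tsv`
#' (ID and symbol columns) and `barcodes.tsv` uncompressed.
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param dir_path Output directory (created if absent).
#' @export
write_10x_mtx <- function(counts, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir_path, "matrix.mtx"))
  ids <- attr(counts, "feature_ids") %||% rownames(counts)
  write.table(data.frame(ids, rownames(counts)),
              file.path(dir_path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Load gene sets from GMT or two-column TSV
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gmt"` (name, description, genes)
#'   or `"tsv"` (columns: set name, gene).
#' @return Named list of [gene_signature] objects. Duplicate genes within a
#'   set are dropped (order preserved); empty sets are skipped with a
#'   warning.
#' @export
load_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  lines <- readLines(path)
  sigs <- list()
  if (format == "gmt") {
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2)
        stopf("unparseable GMT line %d in '%s'", i, path)
      genes <- f[-(1:2)]
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) {
        warnf("gene set '%s' (line %d) is empty; skipped", f[1], i)
        next
      }
      sigs[[f[1]]] <- gene_signature(f[1], genes)
    }
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stopf("TSV gene-set file '%s' needs two columns", path)
    for (nm in unique(tab[[1]])) {
      genes <- tab[[2]][tab[[1]] == nm]
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) {
        warnf("gene set '%s' is empty; skipped", nm)
        next
      }
      sigs[[nm]] <- gene_signature(nm, genes)
    }
  }
  sigs
}

#' Write gene signatures as a GMT file
#'
#' @param sigs List of [gene_signature] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bulk expression cohort with survival annotation
#'
#' @param X Numeric sample x gene matrix of log-scale expression. Genes with
#'   any missing value are dropped with a message.
#' @param time Positive follow-up times, one per sample.
#' @param event Event indicators in \{0, 1\}.
#' @return An object of class `bulk_cohort` with elements `samples`,
#'   `genes`, `X`, and `survival` (data frame: sample, time, event).
#' @export
bulk_cohort <- function(X, time, event) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (nrow(X) != length(time) || nrow(X) != length(event))
    stopf("survival vectors must match the number of samples (%d)", nrow(X))
  bad <- apply(X, 2, anyNA)
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing values dropped")
    X <- X[, !bad, drop = FALSE]
  }
  if (any(time <= 0)) stopf("all survival times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  structure(
    list(samples = rownames(X), genes = colnames(X), X = X,
         survival = data.frame(sample = rownames(X), time = as.numeric(time),
                               event = as.integer(event))),
    class = "bulk_cohort"
  )
}

#' Read a bulk cohort from expression and survival TSV files
#'
#' The expression table has genes in rows (first column: gene symbol) and
#' samples in columns; values are assumed to be on log scale already. The
#' survival table has columns sample, time, event.
#'
#' @param expr_path,survival_path File paths.
#' @return A [bulk_cohort] restricted to samples present in both tables.
#' @export
read_bulk_cohort <- function(expr_path, survival_path) {
  expr <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- expr[[1]]
  mat <- t(as.matrix(expr[, -1, drop = FALSE]))
  colnames(mat) <- genes
  surv <- read.delim(survival_path, stringsAsFactors = FALSE)
  common <- intersect(rownames(mat), surv[[1]])
  if (length(common) == 0L) stopf("no samples shared between the two tables")
  surv <- surv[match(common, surv[[1]]), ]
  bulk_cohort(mat[common, , drop = FALSE], surv[[2]], surv[[3]])
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d samples x %d genes, %d events\n",
              length(x$samples), length(x$genes), sum(x$survival$event)))
  invisible(x)
}
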