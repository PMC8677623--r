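#' Gene signature
#'
#' A named, ordered list of gene symbols with an optional direction tag.
#' Signatures unify cluster marker sets, module-score gene sets and the
#' derived tumor-cell and microenvironmental pattern signatures.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols (duplicates are removed,
#'   order preserved).
#' @param direction One of `"none"`, `"up"`, `"bidirectional-positive"`,
#'   `"bidirectional-negative"`.
#' @param compartment Optional compartment tag (used by reference
#'   signatures during cluster annotation).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes,
                           direction = c("none", "up",
                                         "bidirectional-positive",
                                         "bidirectional-negative"),
                           compartment = NULL) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("gene signature '%s' is empty", name)
  genes <- genes[!duplicated(genes)]
  structure(
    list(name = as.character(name), genes = genes, direction = direction,
         compartment = compartment),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%s)%s\n", x$name,
              length(x$genes), x$direction,
              if (!is.null(x$compartment)) paste0(" [", x$compartment, "]")
              else ""))
  shown <- head(x$genes, 8L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)
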