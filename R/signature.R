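#' Construct a gene signature
#'
#' A signature is a named, ordered set of up-regulated genes: high expression
#' of every member is assumed to be associated with poor survival, which is
#' what lets the score be a plain sum of median-dichotomized calls.
#'
#' @param name Signature name.
#' @param genes Character vector of gene identifiers. Duplicates are removed
#'   (first occurrence kept) with a warning.
#' @param description Optional free-text description (carried through GMT
#'   round trips).
#' @return An object of class `gene_signature`.
#' @examples
#' gene_signature("hypoxia_demo", c("VEGFA", "CA9", "SLC2A1"))
#' @export
gene_signature <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_input("`name` must be a non-empty string.")
  }
  genes <- as.character(genes)
  if (length(genes) == 0L || any(!nzchar(genes)) || anyNA(genes)) {
    abort_input(sprintf("signature '%s' must contain at least one non-empty gene id.", name))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    rlang::warn(sprintf("signature '%s': removed %d duplicated gene id(s): %s",
                        name, length(dup),
                        paste(utils::head(dup, 5), collapse = ", ")),
                class = "sigensemble_duplicate_genes")
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes, description = description),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up-regulated genes\n", x$name,
              length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)
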