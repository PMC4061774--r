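#' Median-dichotomize a vector of expression values
#'
#' Returns +1 for patients whose value is strictly greater than the median
#' over all patients and -1 otherwise; values tied with the median go to the
#' lower class. Because the rule only consults ranks relative to the median,
#' any strictly increasing transform of the input (log2, scaling, shifting)
#' yields the same calls.
#'
#' @param values Named numeric vector (one value per patient), all finite.
#' @return An integer vector of +1/-1 with the input names. If the input is
#'   constant every call is -1 and the result carries attribute
#'   `constant = TRUE` as a diagnostic.
#' @examples
#' median_dichotomize(c(a = 1, b = 2, c = 3, d = 4))
#' median_dichotomize(c(a = 1, b = 2, c = 2, d = 3)) # ties at median go low
#' @export
median_dichotomize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort_input("`values` must be a numeric vector with at least 2 patients.")
  }
  if (any(!is.finite(values))) {
    abort_input("`values` must be finite (no NA/NaN/Inf).")
  }
  out <- ifelse(values > stats::median(values), 1L, -1L)
  names(out) <- names(values)
  if (length(unique(values)) == 1L) attr(out, "constant") <- TRUE
  out
}

resolve_signature_rows <- function(matrix, signature) {
  rn <- rownames(matrix)
  present <- intersect(signature$genes, rn)
  if (length(present) == 0L) {
    abort_input(sprintf(
      "signature '%s' shares no genes with the expression matrix.",
      signature$name), class = "sigensemble_coverage_error")
  }
  dropped <- setdiff(signature$genes, rn)
  if (length(dropped) > 0L) {
    rlang::warn(sprintf(
      "signature '%s': %d of %d genes absent from the matrix and dropped (e.g. %s).",
      signature$name, length(dropped), length(signature$genes),
      paste(utils::head(dropped, 3), collapse = ", ")),
      class = "sigensemble_coverage_warning")
  }
  # Duplicate rows for one gene: keep the row with the highest variance
  # across patients.
  rows <- vapply(present, function(g) {
    idx <- which(rn == g)
    if (length(idx) == 1L) return(idx)
    idx[which.max(apply(matrix[idx, , drop = FALSE], 1L, stats::var))]
  }, integer(1))
  list(rows = rows, genes = present, dropped = dropped)
}

#' Score patients against a gene signature
#'
#' The multi-gene score of a patient is the sum, over the N signature genes
#' present in the matrix, of the median-dichotomized (+1/-1) expression
#' calls. Scores are integers in {-N, -N+2, ..., N} (same parity as N).
#'
#' @param matrix Genes x patients numeric matrix with gene row names and
#'   patient column names.
#' @param signature A [gene_signature()].
#' @return A tibble with columns `patient_id` and `score`, carrying
#'   attributes `n_genes_used` (N), `genes_used` and `genes_dropped`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), paste0("P", 1:4)))
#' signature_score(m, gene_signature("demo", c("gA", "gB")))
#' @export
signature_score <- function(matrix, signature) {
  if (!is.matrix(matrix) || !is.numeric(matrix) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix))) {
    abort_input("`matrix` must be a numeric matrix with gene rownames and patient colnames.")
  }
  if (!inherits(signature, "gene_signature")) {
    abort_input("`signature` must be a gene_signature object.")
  }
  sel <- resolve_signature_rows(matrix, signature)
  calls <- t(apply(matrix[sel$rows, , drop = FALSE], 1L, median_dichotomize))
  scores <- as.integer(colSums(calls))
  out <- tibble::tibble(patient_id = colnames(matrix), score = scores)
  attr(out, "n_genes_used") <- length(sel$rows)
  attr(out, "genes_used") <- sel$genes
  attr(out, "genes_dropped") <- sel$dropped
  attr(out, "signature") <- signature$name
  out
}

#' Classify patients into risk groups by a median split of their scores
#'
#' Patients whose signature score is strictly greater than the median score
#' are labelled high risk, all others low risk; ties at the median go to the
#' low-risk group, mirroring the gene-level rule. Every patient receives a
#' label at this stage.
#'
#' @param scores A tibble with `patient_id` and `score` columns (as returned
#'   by [signature_score()]) or a named numeric vector.
#' @param source Provenance string recorded in the output (e.g. the pipeline
#'   variant id).
#' @return A risk-classification tibble (`patient_id`, `label`, `source`,
#'   plus the input `score`). When all scores are equal, every patient is
#'   low risk and the attribute `degenerate = TRUE` is set.
#' @examples
#' classify_by_median_score(c(P1 = 3, P2 = 1, P3 = -1, P4 = -3))
#' @export
classify_by_median_score <- function(scores, source = "pipeline") {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      patient_id = names(scores) %||% sprintf("P%04d", seq_along(scores)),
      score = as.numeric(scores))
  }
  if (!is.data.frame(scores) || !all(c("patient_id", "score") %in% names(scores))) {
    abort_input("`scores` must have columns `patient_id` and `score`.")
  }
  if (nrow(scores) < 2L) {
    abort_input("at least 2 patients are required for a median split.")
  }
  m <- stats::median(scores$score)
  out <- new_classification(scores$patient_id,
                            ifelse(scores$score > m, "high", "low"), source)
  out$score <- scores$score
  if (length(unique(scores$score)) == 1L) attr(out, "degenerate") <- TRUE
  out
}

#' Score and classify one pipeline variant in a single step
#'
#' @inheritParams signature_score
#' @param source Provenance string for the classification.
#' @return A risk-classification tibble as from [classify_by_median_score()].
#' @export
classify_pipeline <- function(matrix, signature, source = "pipeline") {
  classify_by_median_score(signature_score(matrix, signature), source = source)
}

#' Classify every pipeline view, producing the vote table
#'
#' Applies signature scoring and median-score classification to every view,
#' yielding one high/low vote per patient per pipeline variant (the input of
#' the ensemble stage).
#'
#' @param views A [render_pipeline_views()] object or a named list of
#'   genes x patients matrices.
#' @param signature A [gene_signature()].
#' @return A long tibble of votes (`patient_id`, `variant`, `label`) with
#'   the design (if available) stored in attribute `design`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 20, n_genes = 30,
#'                                      signature_size = 5, seed = 2))
#' votes <- classify_views(render_pipeline_views(cohort), cohort$signature)
#' @export
classify_views <- function(views, signature) {
  if (!is.list(views) || length(views) == 0L || is.null(names(views))) {
    abort_input("`views` must be a non-empty named list of matrices.")
  }
  votes <- purrr::imap(unclass(views), function(m, v) {
    cls <- classify_pipeline(m, signature, source = v)
    tibble::tibble(patient_id = cls$patient_id, variant = v,
                   label = as.character(cls$label))
  })
  out <- dplyr::bind_rows(votes)
  attr(out, "design") <- attr(views, "design")
  out
}
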