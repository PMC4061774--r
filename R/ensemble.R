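check_votes <- function(votes) {
  need <- c("patient_id", "variant", "label")
  if (!is.data.frame(votes) || !all(need %in% names(votes))) {
    abort_input("`votes` must be a data frame with columns patient_id, variant, label.")
  }
  bad <- setdiff(unique(as.character(votes$label)), c("high", "low"))
  if (length(bad) > 0) {
    abort_input(sprintf("votes must be 'high' or 'low'; found: %s",
                        paste(bad, collapse = ", ")))
  }
  patients <- unique(as.character(votes$patient_id))
  variants <- unique(as.character(votes$variant))
  if (nrow(votes) != length(patients) * length(variants) ||
      anyDuplicated(votes[c("patient_id", "variant")])) {
    grid <- tidyr::expand_grid(patient_id = patients, variant = variants)
    miss <- dplyr::anti_join(grid, votes, by = c("patient_id", "variant"))
    if (nrow(miss) > 0) {
      abort_input(sprintf(
        "vote matrix is incomplete: no vote for patient '%s' from variant '%s' (and %d more).",
        miss$patient_id[1], miss$variant[1], nrow(miss) - 1L))
    }
    abort_input("vote matrix contains duplicated (patient, variant) cells.")
  }
  list(patients = patients, variants = variants)
}

# patients x variants logical matrix, TRUE = high-risk vote
votes_to_matrix <- function(votes, dims = NULL) {
  dims <- dims %||% check_votes(votes)
  m <- matrix(NA, nrow = length(dims$patients), ncol = length(dims$variants),
              dimnames = list(dims$patients, dims$variants))
  m[cbind(match(as.character(votes$patient_id), dims$patients),
          match(as.character(votes$variant), dims$variants))] <-
    as.character(votes$label) == "high"
  m
}

#' Sum per-pipeline votes into ensemble scores
#'
#' Each pipeline variant's classification is one vote per patient; the
#' ensemble score counts the high-risk votes and therefore ranges from 0 to
#' the number of variants M (0 to 24 for the full factorial design).
#'
#' @param votes Long vote tibble (`patient_id`, `variant`, `label` in
#'   high/low), e.g. from [classify_views()]. Every (patient, variant) cell
#'   must be present.
#' @return A tibble with `patient_id`, `score` (number of high votes) and
#'   `n_variants` (M).
#' @examples
#' votes <- tidyr::expand_grid(patient_id = c("P1", "P2"), variant = c("a", "b"))
#' votes$label <- c("high", "high", "high", "low")
#' ensemble_score(votes)
#' @export
ensemble_score <- function(votes) {
  dims <- check_votes(votes)
  m <- votes_to_matrix(votes, dims)
  tibble::tibble(patient_id = dims$patients,
                 score = as.integer(rowSums(m)),
                 n_variants = length(dims$variants))
}

#' Unanimity classification from ensemble scores
#'
#' A patient is assigned high risk only when every variant voted high
#' (score = M) and low risk only when every variant voted low (score = 0);
#' patients with conflicting votes are deemed unreliable and left
#' unclassified. With M = 1 this reduces exactly to the single pipeline's
#' classification.
#'
#' @param scores Tibble from [ensemble_score()] (`patient_id`, `score`,
#'   `n_variants`).
#' @return A risk-classification tibble (`patient_id`, `label` in
#'   high/low/unclassified, `source = "ensemble"`, plus `score`).
#' @examples
#' unanimous_classify(tibble::tibble(patient_id = c("P1", "P2", "P3"),
#'                                   score = c(24, 0, 13), n_variants = 24))
#' @export
unanimous_classify <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("patient_id", "score", "n_variants") %in% names(scores))) {
    abort_input("`scores` must have columns patient_id, score, n_variants.")
  }
  if (any(scores$score < 0 | scores$score > scores$n_variants)) {
    abort_input("ensemble scores must lie in [0, n_variants].")
  }
  lab <- ifelse(scores$score == scores$n_variants, "high",
                ifelse(scores$score == 0, "low", "unclassified"))
  out <- new_classification(scores$patient_id, lab, "ensemble")
  out$score <- scores$score
  out
}

#' Build the unanimity ensemble classification straight from votes
#'
#' Convenience composition of [ensemble_score()] and [unanimous_classify()].
#'
#' @inheritParams ensemble_score
#' @return A risk-classification tibble.
#' @export
ensemble_classify <- function(votes) {
  unanimous_classify(ensemble_score(votes))
}

#' Individual classification matched to the ensemble's group sizes
#'
#' To compare a single pipeline with the ensemble at equal patient numbers,
#' patients are ordered by their signature score (descending; ties broken by
#' patient id for determinism) and exactly `k_high` are taken from the top
#' as high risk and `k_low` from the bottom as low risk, leaving the middle
#' unclassified.
#'
#' @param scores Tibble with `patient_id` and `score` (from
#'   [signature_score()]) or a named numeric vector.
#' @param k_high,k_low Numbers of patients to label (non-negative,
#'   `k_high + k_low <= n`). Typically the ensemble's group sizes.
#' @param source Provenance string.
#' @return A risk-classification tibble.
#' @examples
#' matched_individual_classify(c(P1 = 5, P2 = 3, P3 = 1, P4 = -1, P5 = -3, P6 = -5),
#'                             k_high = 2, k_low = 1)
#' @export
matched_individual_classify <- function(scores, k_high, k_low,
                                        source = "matched_individual") {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      patient_id = names(scores) %||% sprintf("P%04d", seq_along(scores)),
      score = as.numeric(scores))
  }
  if (!is.data.frame(scores) || !all(c("patient_id", "score") %in% names(scores))) {
    abort_input("`scores` must have columns `patient_id` and `score`.")
  }
  k_high <- assert_count(k_high, "k_high", min = 0L)
  k_low <- assert_count(k_low, "k_low", min = 0L)
  n <- nrow(scores)
  if (k_high + k_low > n) {
    abort_input(sprintf("k_high + k_low (%d) exceeds the number of patients (%d).",
                        k_high + k_low, n),
                class = "sigensemble_argument_error")
  }
  ord <- order(-scores$score, as.character(scores$patient_id))
  lab <- rep("unclassified", n)
  if (k_high > 0) lab[ord[seq_len(k_high)]] <- "high"
  if (k_low > 0) lab[ord[seq.int(n - k_low + 1L, n)]] <- "low"
  out <- new_classification(scores$patient_id, lab, source)
  out$score <- scores$score
  out
}

#' Combine the classifications of two signatures
#'
#' Two ensemble (or other) classifications over the same patients can be
#' pooled to further filter noise or to classify more patients. Under
#' `intersect`, a patient is labelled only when both inputs assign the same
#' high/low label. Under `union`, a patient is labelled when at least one
#' input assigns a label and the other assigns the same label or none.
#' Patients with contrasting labels are unclassified in both modes.
#'
#' @param a,b Risk-classification tibbles over the same patient universe.
#' @param mode "intersect" or "union".
#' @return A risk-classification tibble with `source` recording the mode and
#'   input sources.
#' @examples
#' a <- tibble::tibble(patient_id = c("P1", "P2"), label = c("high", "high"))
#' b <- tibble::tibble(patient_id = c("P1", "P2"), label = c("high", "unclassified"))
#' combine_signatures(a, b, "union")
#' @export
combine_signatures <- function(a, b, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  check_classification(a, "a")
  check_classification(b, "b")
  check_same_patients(a, b, "a", "b")
  la <- as.character(a$label)
  lb <- as.character(b$label)[match(as.character(a$patient_id),
                                    as.character(b$patient_id))]
  out_label <- if (mode == "intersect") {
    ifelse(la == lb & la != "unclassified", la, "unclassified")
  } else {
    ifelse(la == lb, la,
           ifelse(la == "unclassified", lb,
                  ifelse(lb == "unclassified", la, "unclassified")))
  }
  src_a <- if ("source" %in% names(a)) unique(as.character(a$source))[1] else "a"
  src_b <- if ("source" %in% names(b)) unique(as.character(b$source))[1] else "b"
  new_classification(a$patient_id, out_label,
                     sprintf("%s(%s,%s)", mode, src_a, src_b))
}
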