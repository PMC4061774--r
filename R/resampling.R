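# Evaluate the unanimity ensemble of one variant subset against survival.
# vmat: patients x variants logical vote matrix; cols: column indices.
evaluate_vote_subset <- function(vmat, time, event, cols) {
  k <- length(cols)
  rs <- rowSums(vmat[, cols, drop = FALSE])
  hi <- rs == k
  lo <- rs == 0
  cls <- hi | lo
  n_cls <- sum(cls)
  res <- list(hr = NA_real_, p = NA_real_,
              pct_classified = 100 * n_cls / nrow(vmat),
              n_high = sum(hi), n_low = sum(lo))
  if (res$n_high > 0 && res$n_low > 0 && sum(event[cls]) > 0) {
    fit <- cox_fit_fast(time[cls], event[cls], hi[cls])
    if (fit$ok) {
      res$hr <- exp(fit$coef)
      res$p <- 2 * stats::pnorm(-abs(fit$coef / fit$se))
    }
  }
  res
}

align_survival_to_votes <- function(survival, patients) {
  check_survival(survival)
  idx <- match(patients, survival$patient_id)
  if (anyNA(idx)) {
    abort_input(sprintf("patients missing from `survival`: %s",
                        paste(utils::head(patients[is.na(idx)], 5),
                              collapse = ", ")))
  }
  list(time = survival$time[idx], event = survival$event[idx])
}

#' Permutation sweep of ensemble size
#'
#' For each requested ensemble size n, repeatedly draws n pipeline variants
#' uniformly at random (each draw without internal replacement; subsets may
#' recur across replicates), builds the unanimity ensemble and evaluates its
#' hazard ratio and the percentage of patients classified. Replicates whose
#' Cox fit is non-estimable are retained with `NA` and excluded from means.
#'
#' @param votes Long vote tibble (`patient_id`, `variant`, `label`).
#' @param survival Data frame with `patient_id`, `time`, `event`.
#' @param n_values Ensemble sizes to sweep (default `1:M`).
#' @param reps Number of random subsets per size (default 2000).
#' @param seed Integer seed; the sweep is bit-identical for a fixed seed.
#' @return An `ensemble_sweep` object: tibble with one row per (n,
#'   replicate): `n`, `replicate`, `hr`, `p`, `pct_classified`, `n_high`,
#'   `n_low`. Summarise per size with [summarise_sweep()] or
#'   [generics::tidy()].
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 40, n_genes = 30,
#'                                      signature_size = 10, seed = 4))
#' votes <- classify_views(render_pipeline_views(cohort), cohort$signature)
#' sweep <- sweep_ensemble_size(votes, cohort$patients,
#'                              n_values = c(1, 12, 24), reps = 20, seed = 1)
#' summarise_sweep(sweep)
#' @export
sweep_ensemble_size <- function(votes, survival, n_values = NULL, reps = 2000,
                                seed = 1) {
  dims <- check_votes(votes)
  vmat <- votes_to_matrix(votes, dims)
  sv <- align_survival_to_votes(survival, dims$patients)
  M <- ncol(vmat)
  n_values <- as.integer(n_values %||% seq_len(M))
  if (any(n_values < 1L | n_values > M)) {
    abort_input(sprintf("`n_values` must lie in [1, %d].", M),
                class = "sigensemble_argument_error")
  }
  reps <- assert_count(reps, "reps", min = 1L)
  rows <- vector("list", length(n_values))
  withr::with_seed(derive_seed(seed, "sweep_ensemble_size"), {
    for (i in seq_along(n_values)) {
      n <- n_values[i]
      hr <- p <- pct <- numeric(reps)
      nh <- nl <- integer(reps)
      for (r in seq_len(reps)) {
        res <- evaluate_vote_subset(vmat, sv$time, sv$event,
                                    sample.int(M, n))
        hr[r] <- res$hr; p[r] <- res$p; pct[r] <- res$pct_classified
        nh[r] <- res$n_high; nl[r] <- res$n_low
      }
      rows[[i]] <- tibble::tibble(n = n, replicate = seq_len(reps), hr = hr,
                                  p = p, pct_classified = pct,
                                  n_high = nh, n_low = nl)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ensemble_sweep", class(out))
  attr(out, "M") <- M
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' Summarise an ensemble-size sweep per size
#'
#' @param sweep An [sweep_ensemble_size()] result (or any tibble with `n`,
#'   `hr`, `pct_classified`).
#' @return Per-size tibble: `n`, `mean_hr`, `log2_mean_hr` (the scale used
#'   when plotting size sweeps), `mean_pct_classified`, `hr_min`, `hr_max`,
#'   `n_inestimable`, `n_reps`.
#' @export
summarise_sweep <- function(sweep) {
  if (!is.data.frame(sweep) ||
      !all(c("n", "hr", "pct_classified") %in% names(sweep))) {
    abort_input("`sweep` must have columns n, hr, pct_classified.")
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sweep), .data$n),
    mean_hr = mean(.data$hr, na.rm = TRUE),
    log2_mean_hr = log2(mean(.data$hr, na.rm = TRUE)),
    mean_pct_classified = mean(.data$pct_classified),
    hr_min = suppressWarnings(min(.data$hr, na.rm = TRUE)),
    hr_max = suppressWarnings(max(.data$hr, na.rm = TRUE)),
    n_inestimable = sum(is.na(.data$hr)),
    n_reps = dplyr::n(),
    .groups = "drop")
}

#' Exhaustive ensemble enumeration within a pipeline-aspect subgroup
#'
#' Restricts the design to the variants sharing one level of one aspect
#' (e.g. algorithm = "RMA", or annotation = "default") and enumerates every
#' n-subset of that subgroup for each feasible n (1 to 4 when subgrouping by
#' algorithm, 1 to 12 by annotation or handling in the full design),
#' evaluating the unanimity ensemble of each subset.
#'
#' @inheritParams sweep_ensemble_size
#' @param aspect One of "algorithm", "annotation", "handling".
#' @param level The level of that aspect defining the subgroup.
#' @param design Design tibble mapping variants to factors (defaults to the
#'   votes' `design` attribute, falling back to the full factorial design).
#' @param n_values Subset sizes to enumerate (default: all feasible sizes).
#' @return Tibble with one row per enumerated ensemble: `n`,
#'   `combination_id`, `variants` (slash-separated), `hr`, `p`,
#'   `pct_classified`, `n_high`, `n_low`.
#' @export
exhaustive_subgroup_sweep <- function(votes, survival, aspect, level,
                                      design = NULL, n_values = NULL) {
  if (!is.character(aspect) || length(aspect) != 1L ||
      !aspect %in% c("algorithm", "annotation", "handling")) {
    abort_input("`aspect` must be one of 'algorithm', 'annotation', 'handling'.",
                class = "sigensemble_argument_error")
  }
  dims <- check_votes(votes)
  design <- check_design(design %||% attr(votes, "design") %||% pipeline_design())
  design <- design[design$variant %in% dims$variants, , drop = FALSE]
  subgroup <- design$variant[as.character(design[[aspect]]) == level]
  if (length(subgroup) == 0L) {
    abort_input(sprintf("no variant in the votes has %s = '%s'.", aspect, level),
                class = "sigensemble_argument_error")
  }
  vmat <- votes_to_matrix(votes, dims)
  sv <- align_survival_to_votes(survival, dims$patients)
  cols_all <- match(subgroup, colnames(vmat))
  sz <- length(cols_all)
  n_values <- as.integer(n_values %||% seq_len(sz))
  if (any(n_values < 1L | n_values > sz)) {
    abort_input(sprintf("`n_values` must lie in [1, %d] for this subgroup.", sz),
                class = "sigensemble_argument_error")
  }
  rows <- list()
  for (n in n_values) {
    combos <- utils::combn(cols_all, n, simplify = FALSE)
    for (ci in seq_along(combos)) {
      res <- evaluate_vote_subset(vmat, sv$time, sv$event, combos[[ci]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = n, combination_id = ci,
        variants = paste(colnames(vmat)[combos[[ci]]], collapse = "/"),
        hr = res$hr, p = res$p, pct_classified = res$pct_classified,
        n_high = res$n_high, n_low = res$n_low)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "aspect") <- aspect
  attr(out, "level") <- level
  out
}

#' Paired comparison of pipeline aspects by hazard ratio
#'
#' Splits the pool of per-variant hazard ratios by one aspect of the
#' pipeline and compares each pair of levels with a paired t-test, pairing
#' variants that are identical in every other factor (and signature, when a
#' `signature` column is present).
#'
#' @param hr_table Tibble with one row per (variant, signature): the factor
#'   columns (`algorithm`, `annotation`, `handling`, optionally `platform`,
#'   `signature`) and an `hr` column.
#' @param aspect One of "algorithm", "annotation", "handling".
#' @return Tibble with one row per level pair: `aspect`, `level_a`,
#'   `level_b`, `n_pairs`, `estimate` (mean HR difference a - b),
#'   `statistic`, `df`, `p_value`, `direction` (the level with the higher
#'   mean HR).
#' @export
aspect_paired_comparison <- function(hr_table, aspect) {
  if (!is.character(aspect) || length(aspect) != 1L ||
      !aspect %in% c("algorithm", "annotation", "handling")) {
    abort_input("`aspect` must be one of 'algorithm', 'annotation', 'handling'.",
                class = "sigensemble_argument_error")
  }
  if (!is.data.frame(hr_table) || !all(c(aspect, "hr") %in% names(hr_table))) {
    abort_input(sprintf("`hr_table` must contain columns `%s` and `hr`.", aspect))
  }
  keys <- intersect(c("algorithm", "annotation", "handling", "platform",
                      "signature"), names(hr_table))
  keys <- setdiff(keys, aspect)
  levels <- sort(unique(as.character(hr_table[[aspect]])))
  if (length(levels) < 2L) {
    abort_input(sprintf("aspect `%s` has fewer than 2 levels in `hr_table`.", aspect),
                class = "sigensemble_argument_error")
  }
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(lv) {
    a <- hr_table[as.character(hr_table[[aspect]]) == lv[1], , drop = FALSE]
    b <- hr_table[as.character(hr_table[[aspect]]) == lv[2], , drop = FALSE]
    key_a <- do.call(paste, c(lapply(keys, function(k) as.character(a[[k]])),
                              sep = "\r"))
    key_b <- do.call(paste, c(lapply(keys, function(k) as.character(b[[k]])),
                              sep = "\r"))
    if (anyDuplicated(key_a) || anyDuplicated(key_b) ||
        !setequal(key_a, key_b) || length(key_a) != length(key_b)) {
      offenders <- c(setdiff(key_a, key_b), setdiff(key_b, key_a),
                     key_a[duplicated(key_a)], key_b[duplicated(key_b)])
      abort_input(sprintf(
        "variants do not pair off bijectively for %s levels %s vs %s (offending keys: %s).",
        aspect, lv[1], lv[2],
        paste(gsub("\r", "/", utils::head(unique(offenders), 4)), collapse = "; ")),
        class = "sigensemble_pairing_error")
    }
    hr_a <- a$hr
    hr_b <- b$hr[match(key_a, key_b)]
    tt <- paired_t_test(hr_a, hr_b)
    tibble::tibble(aspect = aspect, level_a = lv[1], level_b = lv[2],
                   n_pairs = length(hr_a), estimate = tt$estimate,
                   statistic = tt$statistic, df = tt$df,
                   p_value = tt$p_value,
                   direction = ifelse(tt$estimate > 0, lv[1],
                                      ifelse(tt$estimate < 0, lv[2], "tie")))
  })
  dplyr::bind_rows(rows)
}
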