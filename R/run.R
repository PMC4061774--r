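#' Configure a full ensemble-classification run
#'
#' @param input_dir Directory holding the cohort bundle: `design.yaml`, one
#'   `<variant>.tsv` expression matrix per design row, `clinical.tsv` and a
#'   GMT file of signatures.
#' @param out_dir Output directory for result tables, the JSON summary and
#'   the run log.
#' @param gmt Path to the GMT file (default `signature.gmt` inside
#'   `input_dir`).
#' @param signature Name of the signature to evaluate; default: the first in
#'   the GMT file.
#' @param alpha Significance threshold on q-values.
#' @param reps Replicates per ensemble size in the permutation sweep.
#' @param sweep_sizes Ensemble sizes for the sweep (default 1..M).
#' @param seed Master seed for every random draw of the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_dir, out_dir, gmt = NULL, signature = NULL,
                       alpha = 0.05, reps = 2000, sweep_sizes = NULL,
                       seed = 1) {
  if (!dir.exists(input_dir)) {
    abort_input(sprintf("input directory not found: %s", input_dir),
                class = "sigensemble_config_error")
  }
  gmt <- gmt %||% file.path(input_dir, "signature.gmt")
  if (!file.exists(gmt)) {
    abort_input(sprintf("GMT file not found: %s", gmt),
                class = "sigensemble_config_error")
  }
  assert_number(alpha, "alpha", min = 0, strict_min = TRUE)
  if (alpha >= 1) abort_input("`alpha` must lie in (0, 1).",
                              class = "sigensemble_config_error")
  structure(list(input_dir = input_dir, out_dir = out_dir, gmt = gmt,
                 signature = signature, alpha = alpha,
                 reps = assert_count(reps, "reps"),
                 sweep_sizes = sweep_sizes,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = c("sigensemble_stage_error", "sigensemble_error"),
                 parent = e)
  })
}

#' Run the complete ensemble-classification analysis
#'
#' Executes every stage of the framework on a cohort bundle: per-pipeline
#' signature classification (votes), ensemble scoring and unanimity
#' classification, Cox/Kaplan-Meier evaluation of the ensemble and of every
#' individual pipeline, matched-count individual classifications at the
#' ensemble's group sizes, the permutation sweep of ensemble size, and
#' paired comparisons of pipeline aspects. All tables are written as TSV
#' plus a machine-readable JSON summary and a run log (seed, versions,
#' config echo); a failing stage aborts with the stage name. Outputs are
#' deterministic functions of (inputs, seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`votes`,
#'   `ensemble_scores`, `ensemble_classification`, `evaluation`,
#'   `matched_evaluation`, `sweep_summary`, `aspect_comparisons`, `km`).
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "run_config")) {
    abort_input("`config` must come from run_config().",
                class = "sigensemble_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- run_stage("load_inputs", {
    b <- read_cohort_bundle_with_gmt(config)
    expr_pat <- colnames(b$views[[1]])
    missing <- setdiff(expr_pat, b$survival$patient_id)
    if (length(missing) > 0) {
      abort_input(sprintf(
        "clinical table is missing %d patient id(s) present in the expression data: %s",
        length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    }
    b
  })
  sig <- run_stage("select_signature", {
    if (is.null(config$signature)) bundle$signatures[[1]]
    else if (config$signature %in% names(bundle$signatures)) {
      bundle$signatures[[config$signature]]
    } else {
      abort_input(sprintf("signature '%s' not present in %s.",
                          config$signature, config$gmt))
    }
  })

  votes <- run_stage("classify", classify_views(bundle$views, sig))
  scores <- run_stage("ensemble", ensemble_score(votes))
  ens <- run_stage("ensemble", unanimous_classify(scores))

  evaluation <- run_stage("evaluate", {
    rows <- list(evaluate_classification(bundle$survival, ens,
                                         signature = sig$name))
    for (v in names(bundle$views)) {
      cls <- classify_pipeline(bundle$views[[v]], sig, source = v)
      rows[[length(rows) + 1L]] <-
        evaluate_classification(bundle$survival, cls, signature = sig$name)
    }
    dplyr::bind_rows(rows)
  })

  matched <- run_stage("matched_individual", {
    k_high <- sum(as.character(ens$label) == "high")
    k_low <- sum(as.character(ens$label) == "low")
    rows <- purrr::imap(unclass(bundle$views), function(m, v) {
      sc <- signature_score(m, sig)
      cls <- matched_individual_classify(sc, k_high, k_low,
                                         source = paste0("matched:", v))
      evaluate_classification(bundle$survival, cls, signature = sig$name)
    })
    dplyr::bind_rows(rows)
  })

  sweep <- run_stage("sweep", {
    sweep_ensemble_size(votes, bundle$survival,
                        n_values = config$sweep_sizes, reps = config$reps,
                        seed = derive_seed(config$seed, "run/sweep"))
  })
  sweep_summary <- summarise_sweep(sweep)

  aspects <- run_stage("compare_aspects", {
    hr_tab <- dplyr::inner_join(
      evaluation[evaluation$source != "ensemble", , drop = FALSE],
      bundle$design, by = c(source = "variant"))
    out <- list()
    for (a in c("algorithm", "annotation", "handling")) {
      res <- tryCatch(aspect_paired_comparison(hr_tab, a),
                      error = function(e) NULL)
      if (!is.null(res)) out[[a]] <- res
    }
    dplyr::bind_rows(out)
  })

  km <- run_stage("evaluate", kaplan_meier(bundle$survival, ens))

  run_stage("write_outputs", {
    w <- function(x, f) readr::write_tsv(x, file.path(config$out_dir, f))
    w(votes, "votes.tsv")
    w(scores, "ensemble_scores.tsv")
    w(classification_to_tsv(ens, scores), "ensemble_classification.tsv")
    w(evaluation, "classifier_evaluation.tsv")
    w(matched, "matched_evaluation.tsv")
    w(tibble::as_tibble(sweep), "sweep.tsv")
    w(sweep_summary, "sweep_summary.tsv")
    if (nrow(aspects) > 0) w(aspects, "aspect_comparisons.tsv")
    w(km, "kaplan_meier.tsv")
    summary <- list(
      signature = sig$name,
      n_patients = length(unique(votes$patient_id)),
      n_variants = length(unique(votes$variant)),
      ensemble = as.list(evaluation[1, ]),
      pct_classified = evaluation$pct_classified[1],
      alpha = config$alpha, reps = config$reps, seed = config$seed)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log <- c(
      sprintf("sigensemble %s", as.character(utils::packageVersion("sigensemble"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", config$seed),
      "config:",
      yaml::as.yaml(unclass(config)))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  })

  invisible(list(votes = votes, ensemble_scores = scores,
                 ensemble_classification = ens, evaluation = evaluation,
                 matched_evaluation = matched, sweep = sweep,
                 sweep_summary = sweep_summary,
                 aspect_comparisons = aspects, km = km))
}

read_cohort_bundle_with_gmt <- function(config) {
  design <- read_design_manifest(file.path(config$input_dir, "design.yaml"))
  views <- lapply(design$variant, function(v) {
    read_expression_tsv(file.path(config$input_dir, paste0(v, ".tsv")))
  })
  names(views) <- design$variant
  list(views = structure(views, design = design, class = "pipeline_views"),
       design = design,
       survival = read_clinical_tsv(file.path(config$input_dir, "clinical.tsv")),
       signatures = read_gmt(config$gmt))
}

classification_to_tsv <- function(cls, scores) {
  out <- dplyr::left_join(
    dplyr::select(scores, "patient_id", ensemble_score = "score"),
    dplyr::mutate(dplyr::select(cls, "patient_id", "label", "source"),
                  label = as.character(.data$label)),
    by = "patient_id")
  out
}
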