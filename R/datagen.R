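#' Configure a synthetic cohort simulation
#'
#' The generator emulates the statistical skeleton of a survival-annotated
#' expression cohort: a standard-normal latent risk per patient drives both
#' the expression of the signature genes and the hazard of an event. Defaults
#' describe a moderately sized breast-cancer-like cohort with a clear but
#' noisy hypoxia-type signal; see the methods vignette for the rationale
#' behind each value.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_genes Number of genes on the synthetic platform.
#' @param signature_size Number of genes driven by the latent risk
#'   (<= `n_genes`); these form the cohort's built-in signature.
#' @param effect_size Loading of the latent risk on each signature gene.
#' @param noise_sd_gene SD of the independent per-gene measurement noise.
#' @param noise_sd_pipeline SD of the additional per-pipeline noise applied
#'   when rendering pipeline views (see [render_pipeline_views()]).
#' @param log_hazard_beta Effect of latent risk on the log hazard.
#' @param baseline_hazard Baseline exponential event rate (> 0).
#' @param censor_horizon Upper bound of the uniform administrative censoring
#'   time (> 0); set very large for effectively uncensored cohorts.
#' @param seed Master integer seed; identical configs give bit-identical
#'   cohorts.
#' @return A validated `sim_config` object.
#' @examples
#' cfg <- sim_config(n_patients = 50, n_genes = 40, signature_size = 10, seed = 7)
#' @export
sim_config <- function(n_patients = 250, n_genes = 500, signature_size = 25,
                       effect_size = 1, noise_sd_gene = 1,
                       noise_sd_pipeline = 1, log_hazard_beta = 1,
                       baseline_hazard = 0.1, censor_horizon = 30, seed = 1) {
  n_patients <- assert_count(n_patients, "n_patients", min = 2L)
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  signature_size <- assert_count(signature_size, "signature_size", min = 1L)
  if (signature_size > n_genes) {
    abort_input("`signature_size` must not exceed `n_genes`.",
                class = "sigensemble_config_error")
  }
  effect_size <- assert_number(effect_size, "effect_size")
  noise_sd_gene <- assert_number(noise_sd_gene, "noise_sd_gene", min = 0)
  noise_sd_pipeline <- assert_number(noise_sd_pipeline, "noise_sd_pipeline", min = 0)
  log_hazard_beta <- assert_number(log_hazard_beta, "log_hazard_beta")
  baseline_hazard <- assert_number(baseline_hazard, "baseline_hazard",
                                   min = 0, strict_min = TRUE)
  censor_horizon <- assert_number(censor_horizon, "censor_horizon",
                                  min = 0, strict_min = TRUE)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_patients = n_patients, n_genes = n_genes,
         signature_size = signature_size, effect_size = effect_size,
         noise_sd_gene = noise_sd_gene, noise_sd_pipeline = noise_sd_pipeline,
         log_hazard_beta = log_hazard_beta, baseline_hazard = baseline_hazard,
         censor_horizon = censor_horizon, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Simulate a synthetic survival-annotated expression cohort
#'
#' Draws a standard-normal latent risk per patient. Each of the
#' `signature_size` signature genes is `effect_size * latent_risk` plus
#' independent Gaussian noise; the remaining genes are pure noise. Event
#' times are exponential with rate `baseline_hazard * exp(log_hazard_beta *
#' latent_risk)`; censoring times are uniform on (0, `censor_horizon`]; the
#' observed time is the minimum, and the event indicator records whether the
#' event preceded censoring. Truth labels split patients at the median latent
#' risk.
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_cohort`: a list with `patients` (tibble of
#'   `patient_id`, `latent_risk`, `time`, `event`, `truth_label`),
#'   `expression` (genes x patients matrix), `signature` (the built-in
#'   [gene_signature()] of driven genes) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 20, n_genes = 30,
#'                                      signature_size = 5, seed = 2))
#' cohort$patients
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_input("`config` must be created with sim_config().",
                class = "sigensemble_config_error")
  }
  n <- config$n_patients
  g <- config$n_genes
  patient_id <- sprintf("P%04d", seq_len(n))
  gene_id <- sprintf("g%04d", seq_len(g))
  sig_genes <- gene_id[seq_len(config$signature_size)]

  withr::with_seed(derive_seed(config$seed, "cohort"), {
    z <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(g * n, sd = config$noise_sd_gene), nrow = g)
    signal <- matrix(0, nrow = g, ncol = n)
    signal[seq_len(config$signature_size), ] <-
      matrix(rep(config$effect_size * z, each = config$signature_size),
             nrow = config$signature_size)
    expr <- signal + noise
    t_event <- stats::rexp(n, rate = config$baseline_hazard *
                             exp(config$log_hazard_beta * z))
    t_cens <- stats::runif(n, min = 0, max = config$censor_horizon)
  })
  dimnames(expr) <- list(gene_id, patient_id)

  truth <- factor(ifelse(z > stats::median(z), "high", "low"),
                  levels = c("high", "low"))
  patients <- tibble::tibble(
    patient_id = patient_id,
    latent_risk = z,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    truth_label = truth
  )
  structure(
    list(patients = patients, expression = expr,
         signature = gene_signature("simulated_signature", sig_genes,
                                    "genes driven by the latent risk"),
         config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d genes (%d signature genes)\n",
              nrow(x$patients), nrow(x$expression), length(x$signature)))
  cat(sprintf("  events: %d/%d  seed: %d\n", sum(x$patients$event),
              nrow(x$patients), x$config$seed))
  invisible(x)
}

shift_positive <- function(m) {
  mn <- min(m)
  if (mn <= 0) m + (1 - mn) else m
}

#' Render per-pipeline views of a cohort's expression matrix
#'
#' Emulates pre-processing the same underlying data in many different ways.
#' Each non-log variant is the base expression plus independent Gaussian
#' pipeline noise, shifted to be strictly positive (adding `1 - min` when any
#' value is <= 0) so the log2 pair is well defined; the shift preserves rank
#' order, which is all the downstream classifier consumes. Each log variant
#' is the exact elementwise log2 of its declared partner's matrix, with no
#' additional noise, so a log pair can never yield a different
#' classification.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param design A [pipeline_design()] tibble (defaults to the full
#'   24-variant design).
#' @param noise_sd_pipeline SD of the per-pipeline noise; defaults to the
#'   cohort config.
#' @param seed Master seed for the per-variant noise streams; defaults to
#'   the cohort seed. Each variant draws from its own derived sub-stream, so
#'   adding a variant does not perturb the others.
#' @return A `pipeline_views` object: a named list of genes x patients
#'   matrices (one per design row) with the design stored as an attribute.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 20, n_genes = 30,
#'                                      signature_size = 5, seed = 2))
#' views <- render_pipeline_views(cohort)
#' length(views)
#' @export
render_pipeline_views <- function(cohort, design = pipeline_design(),
                                  noise_sd_pipeline = NULL, seed = NULL) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort_input("`cohort` must be a synthetic_cohort from simulate_cohort().")
  }
  design <- check_design(design)
  if (nrow(design) == 0) {
    abort_input("`design` must contain at least one variant.",
                class = "sigensemble_design_error")
  }
  noise_sd_pipeline <- assert_number(
    noise_sd_pipeline %||% cohort$config$noise_sd_pipeline,
    "noise_sd_pipeline", min = 0)
  seed <- seed %||% cohort$config$seed

  base <- shift_positive(cohort$expression)
  views <- vector("list", nrow(design))
  names(views) <- design$variant

  nonlog <- which(!design$is_log)
  for (i in nonlog) {
    v <- design$variant[i]
    withr::with_seed(derive_seed(seed, paste0("view/", v)), {
      noise <- matrix(stats::rnorm(length(base), sd = noise_sd_pipeline),
                      nrow = nrow(base))
    })
    views[[v]] <- shift_positive(base + noise)
  }
  for (i in which(design$is_log)) {
    src_alg <- design$log_source[i]
    j <- which(design$algorithm == src_alg &
                 design$annotation == design$annotation[i] &
                 design$handling == design$handling[i])
    if (length(j) != 1L) {
      abort_input(sprintf(
        "log variant '%s' has no monotone pair (%s with annotation=%s, handling=%s) in the design.",
        design$variant[i], src_alg, design$annotation[i], design$handling[i]),
        class = "sigensemble_design_error")
    }
    views[[design$variant[i]]] <- log2(views[[design$variant[j]]])
  }
  structure(views, design = design, class = "pipeline_views")
}

#' @export
print.pipeline_views <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<pipeline_views> %d variants, %d genes x %d patients\n",
              length(x), nrow(x[[1]]), ncol(x[[1]])))
  cat("  variants:", paste(utils::head(d$variant, 4), collapse = ", "),
      if (nrow(d) > 4) "..." else "", "\n")
  invisible(x)
}
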