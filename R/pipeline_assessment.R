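#' Univariate prognostic screen of every gene in one pipeline view
#'
#' For each gene, patients are median-dichotomized on that gene's abundance
#' (strictly-above-median = high risk) and a univariate Cox model with Wald
#' test is fitted. Wald p-values are then Benjamini-Hochberg adjusted across
#' the estimable genes of this view; genes whose fit is non-estimable (e.g.
#' constant expression, empty group, no events, monotone likelihood) are
#' kept as flagged `NA` rows and excluded from the FDR input.
#'
#' @param matrix Genes x patients numeric matrix.
#' @param survival Data frame with `patient_id`, `time`, `event`; must cover
#'   the matrix columns.
#' @return A tibble with one row per gene: `gene`, `hr`, `p`, `q`,
#'   `estimable`. Attribute `n_inestimable` counts the flagged genes.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 40, n_genes = 10,
#'                                      signature_size = 3, seed = 3))
#' per_gene_prognosis(cohort$expression, cohort$patients)
#' @export
per_gene_prognosis <- function(matrix, survival) {
  check_survival(survival)
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix))) {
    abort_input("`matrix` must have gene rownames and patient colnames.")
  }
  idx <- match(colnames(matrix), survival$patient_id)
  if (anyNA(idx)) {
    abort_input(sprintf("patients missing from `survival`: %s",
                        paste(utils::head(colnames(matrix)[is.na(idx)], 5),
                              collapse = ", ")))
  }
  time <- survival$time[idx]
  event <- survival$event[idx]
  if (ncol(matrix) < 2L || sum(event) < 1L) {
    abort_input("need >= 2 patients and >= 1 event for the per-gene screen.")
  }
  g <- nrow(matrix)
  coef <- se <- rep(NA_real_, g)
  ok <- logical(g)
  for (i in seq_len(g)) {
    x <- median_dichotomize(matrix[i, ]) == 1L
    if (!any(x) || all(x)) next
    fit <- cox_fit_fast(time, event, x)
    if (fit$ok) {
      coef[i] <- fit$coef
      se[i] <- fit$se
      ok[i] <- TRUE
    }
  }
  p <- ifelse(ok, 2 * stats::pnorm(-abs(coef / se)), NA_real_)
  q <- rep(NA_real_, g)
  if (any(ok)) q[ok] <- bh_fdr(p[ok])
  out <- tibble::tibble(gene = rownames(matrix), hr = exp(coef), p = p,
                        q = q, estimable = ok)
  attr(out, "n_inestimable") <- sum(!ok)
  out
}

#' Per-gene prognostic screen across all pipeline views
#'
#' Runs [per_gene_prognosis()] on every view; the FDR adjustment stays
#' within each pipeline variant. Since log2 variants are exact monotone
#' transforms of their partners and the screen only consumes ranks, a log
#' pair always yields identical rows.
#'
#' @param views A [render_pipeline_views()] object or named list of
#'   matrices.
#' @inheritParams per_gene_prognosis
#' @return Long tibble: `gene`, `variant`, `hr`, `p`, `q`, `estimable`,
#'   with the views' design (if any) in attribute `design`.
#' @export
gene_prognosis_table <- function(views, survival) {
  if (!is.list(views) || length(views) == 0L || is.null(names(views))) {
    abort_input("`views` must be a non-empty named list of matrices.")
  }
  out <- dplyr::bind_rows(purrr::imap(unclass(views), function(m, v) {
    tbl <- per_gene_prognosis(m, survival)
    tbl$variant <- v
    tbl
  }))
  out <- dplyr::select(out, "gene", "variant", "hr", "p", "q", "estimable")
  attr(out, "design") <- attr(views, "design")
  out
}

#' Marginal significance counts of a gene-prognosis table
#'
#' @param table Long tibble from [gene_prognosis_table()] (columns `gene`,
#'   `variant`, `q`).
#' @param alpha Significance threshold on the q-value.
#' @return A list with `per_variant` (tibble `variant`, `n_significant`) and
#'   `per_gene` (tibble `gene`, `n_variants_significant`): the two marginals
#'   of the significance indicator matrix. Non-estimable (`NA`) q-values
#'   never count as significant.
#' @export
significance_summary <- function(table, alpha = 0.05) {
  if (!is.data.frame(table) || !all(c("gene", "variant", "q") %in% names(table))) {
    abort_input("`table` must have columns gene, variant, q.")
  }
  assert_number(alpha, "alpha", min = 0)
  sig <- dplyr::mutate(table,
                       significant = !is.na(.data$q) & .data$q <= alpha)
  list(
    per_variant = dplyr::summarise(dplyr::group_by(sig, .data$variant),
                                   n_significant = sum(.data$significant),
                                   .groups = "drop"),
    per_gene = dplyr::summarise(dplyr::group_by(sig, .data$gene),
                                n_variants_significant = sum(.data$significant),
                                .groups = "drop")
  )
}

#' Inter-pipeline concordance of per-gene q-values
#'
#' Pairwise Spearman correlation of the q-value profiles of every pair of
#' pipeline variants, computed over the genes estimable in both.
#'
#' @inheritParams significance_summary
#' @return Symmetric variant x variant matrix with unit diagonal; a cell is
#'   `NA` when fewer than 3 shared estimable genes exist.
#' @export
pipeline_concordance <- function(table) {
  if (!is.data.frame(table) || !all(c("gene", "variant", "q") %in% names(table))) {
    abort_input("`table` must have columns gene, variant, q.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(table, "gene", "variant", "q"),
    names_from = "variant", values_from = "q")
  variants <- setdiff(names(wide), "gene")
  k <- length(variants)
  m <- matrix(NA_real_, k, k, dimnames = list(variants, variants))
  diag(m) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)[-seq_len(i)]) {
      qi <- wide[[variants[i]]]
      qj <- wide[[variants[j]]]
      shared <- !is.na(qi) & !is.na(qj)
      if (sum(shared) >= 3L) {
        m[i, j] <- m[j, i] <- spearman_cor(qi[shared], qj[shared])
      }
    }
  }
  m
}

#' Per-variant significant-gene counts with design factors
#'
#' Joins the per-variant marginal of [significance_summary()] with the
#' factorial design labels, producing the response table for
#' [fit_count_model()].
#'
#' @inheritParams significance_summary
#' @param design Design tibble with `variant` plus the factor columns
#'   (defaults to the table's `design` attribute).
#' @return Tibble: `variant`, `algorithm`, `annotation`, `handling`,
#'   `platform`, `n_significant`.
#' @export
significant_gene_counts <- function(table, design = NULL, alpha = 0.05) {
  design <- design %||% attr(table, "design")
  if (is.null(design)) {
    abort_input("`design` must be supplied (or present as an attribute of `table`).")
  }
  design <- check_design(design)
  counts <- significance_summary(table, alpha)$per_variant
  out <- dplyr::left_join(
    dplyr::select(design, "variant", "algorithm", "annotation", "handling",
                  dplyr::any_of("platform")),
    counts, by = "variant")
  out$n_significant[is.na(out$n_significant)] <- 0L
  out
}

count_model_baselines <- list(annotation = "alternative",
                              platform = "HG-U133A",
                              handling = "merged",
                              algorithm = "GCRMA")

# Gaussian AIC on the n*log(RSS/n) + 2*(npar + 1) scale (npar = rank of the
# fit, +1 for the variance). Only differences between nested models matter.
aic_gaussian <- function(fit) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  n * log(rss / n) + 2 * (fit$rank + 1)
}

#' Linear model of significant-gene counts on the pipeline factors
#'
#' Ordinary least-squares fit of the per-variant significant-gene count on
#' the factorial design: main effects of annotation, platform, handling and
#' algorithm (5 dummy codes against the GCRMA baseline), optionally with all
#' pairwise interactions. Baselines follow the factorial convention:
#' alternative annotation, HG-U133A platform, merged handling, GCRMA
#' algorithm (missing baseline levels fall back to the first level present).
#' Factors constant in the data (e.g. a single platform) are dropped from
#' the formula with a message.
#'
#' @param counts Tibble from [significant_gene_counts()] (or any tibble with
#'   a numeric response plus the factor columns).
#' @param interactions "none" for main effects only, "pairwise" for all
#'   main effects plus pairwise interactions.
#' @param response Name of the response column.
#' @param baselines Named list of baseline levels per factor.
#' @return A `count_model` object wrapping the `lm` fit with the coefficient
#'   table (estimate, SE, t, p), `adj_r_squared` and `aic` (Gaussian,
#'   `n log(RSS/n) + 2(k+1)` scale). [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @export
fit_count_model <- function(counts, interactions = c("none", "pairwise"),
                            response = "n_significant",
                            baselines = count_model_baselines) {
  interactions <- match.arg(interactions)
  factors <- intersect(c("annotation", "platform", "handling", "algorithm"),
                       names(counts))
  if (!is.data.frame(counts) || !response %in% names(counts) ||
      length(factors) == 0L) {
    abort_input(sprintf(
      "`counts` must contain `%s` and at least one of annotation, platform, handling, algorithm.",
      response))
  }
  d <- as.data.frame(counts)
  keep <- character(0)
  for (f in factors) {
    lv <- unique(as.character(d[[f]]))
    if (length(lv) < 2L) {
      rlang::inform(sprintf("factor `%s` is constant and was dropped from the model.", f))
      next
    }
    base <- baselines[[f]]
    if (is.null(base) || !base %in% lv) base <- sort(lv)[1]
    d[[f]] <- stats::relevel(factor(d[[f]]), ref = base)
    keep <- c(keep, f)
  }
  if (length(keep) == 0L) {
    abort_input("no non-constant design factor available.",
                class = "sigensemble_model_error")
  }
  rhs <- paste(keep, collapse = " + ")
  if (interactions == "pairwise" && length(keep) > 1L) {
    rhs <- sprintf("(%s)^2", rhs)
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_input(sprintf("design matrix is rank deficient; aliased terms: %s",
                        paste(aliased, collapse = ", ")),
                class = "sigensemble_model_error")
  }
  smry <- summary(fit)
  coefs <- tibble::as_tibble(smry$coefficients, rownames = "term")
  names(coefs) <- c("term", "estimate", "std_error", "statistic", "p_value")
  structure(list(
    lm = fit, formula = fml, data = d, response = response,
    interactions = interactions, coefficients = coefs,
    adj_r_squared = smry$adj.r.squared,
    r_squared = smry$r.squared,
    aic = aic_gaussian(fit)
  ), class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count_model> %s  (interactions: %s)\n",
              deparse(x$formula), x$interactions))
  cat(sprintf("  adj R^2 = %.4g, AIC = %.2f, %d terms\n",
              x$adj_r_squared, x$aic, nrow(x$coefficients)))
  invisible(x)
}

#' Backwards stepwise refinement of a count model by AIC
#'
#' Starting from a fitted [fit_count_model()] (typically the full pairwise
#' model), iteratively removes the single term whose removal lowers the AIC
#' most, stopping when no removal lowers it. Marginality is respected: a
#' main effect is only a removal candidate when no retained interaction
#' contains it. Ties are broken alphabetically by term name for
#' determinism.
#'
#' @param model A `count_model`.
#' @return The reduced `count_model` with a `trace` attribute (tibble of
#'   removed terms and the AIC after each removal). The final AIC is always
#'   <= the starting AIC.
#' @export
stepwise_aic_backward <- function(model) {
  if (!inherits(model, "count_model")) {
    abort_input("`model` must come from fit_count_model().",
                class = "sigensemble_model_error")
  }
  current <- model$lm
  trace <- list(tibble::tibble(removed = "<start>", aic = aic_gaussian(current)))
  repeat {
    cand <- tryCatch(stats::drop1(current, k = 2), error = function(e) NULL)
    if (is.null(cand) || nrow(cand) < 2L) break
    terms <- rownames(cand)[-1]        # drop1 respects marginality
    # drop1's AIC is n log(RSS/n) + 2*edf; differences match aic_gaussian.
    delta <- cand$AIC[-1] - cand$AIC[1]
    ord <- order(delta, terms)
    if (delta[ord[1]] >= 0) break
    best <- terms[ord[1]]
    # refit explicitly against the stored data: update() would re-evaluate
    # the original lm call in a frame where its data object no longer exists
    fml <- stats::update(stats::formula(current),
                         stats::as.formula(paste(". ~ . -", best)))
    current <- stats::lm(fml, data = model$data)
    trace <- c(trace, list(tibble::tibble(removed = best,
                                          aic = aic_gaussian(current))))
  }
  smry <- summary(current)
  coefs <- tibble::as_tibble(smry$coefficients, rownames = "term")
  names(coefs) <- c("term", "estimate", "std_error", "statistic", "p_value")
  out <- structure(list(
    lm = current, formula = stats::formula(current), data = model$data,
    response = model$response, interactions = "stepwise",
    coefficients = coefs,
    adj_r_squared = smry$adj.r.squared,
    r_squared = smry$r.squared,
    aic = aic_gaussian(current)
  ), class = "count_model")
  attr(out, "trace") <- dplyr::bind_rows(trace)
  out
}
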