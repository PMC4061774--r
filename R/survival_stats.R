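check_survival <- function(survival, arg = "survival") {
  need <- c("patient_id", "time", "event")
  if (!is.data.frame(survival) || !all(need %in% names(survival))) {
    abort_input(sprintf(
      "`%s` must be a data frame with columns patient_id, time, event.", arg))
  }
  if (anyDuplicated(survival$patient_id)) {
    abort_input(sprintf("`%s` contains duplicated patient ids.", arg))
  }
  if (!is.numeric(survival$time) || any(!is.finite(survival$time)) ||
      any(survival$time <= 0)) {
    abort_input(sprintf("`%s$time` must be finite and > 0.", arg))
  }
  if (!all(survival$event %in% c(0, 1))) {
    abort_input(sprintf("`%s$event` must be 0 (censored) or 1 (event).", arg))
  }
  invisible(survival)
}

# Lean fitting core shared by fit_cox_binary, the per-gene screen and the
# resampling sweeps: binary covariate x (TRUE/1 = high), Efron ties.
# Returns list(coef, se, ok) where ok = FALSE flags non-estimable or
# non-convergent (monotone likelihood) fits.
cox_fit_fast <- function(time, event, x) {
  x <- as.numeric(x)
  if (sum(event) == 0 || length(unique(x)) < 2L) {
    return(list(coef = NA_real_, se = NA_real_, ok = FALSE))
  }
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(matrix(x, ncol = 1), survival::Surv(time, event),
                          strata = NULL, offset = NULL, init = 0,
                          control = survival::coxph.control(),
                          weights = NULL, method = "efron", rownames = NULL),
      warning = function(w) {
        if (grepl("converge|infinite|iterations", conditionMessage(w))) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(list(coef = NA_real_, se = NA_real_, ok = FALSE))
  coef <- as.numeric(fit$coefficients)
  se <- sqrt(as.numeric(fit$var))
  ok <- converged && is.finite(coef) && is.finite(se) && abs(coef) <= 15 &&
    se <= 100
  list(coef = coef, se = se, ok = ok)
}

new_cox_binary <- function(estimable, reason = NULL, coef = NA_real_,
                           se = NA_real_, n_high = NA_integer_,
                           n_low = NA_integer_, n_events = NA_integer_) {
  hr <- exp(coef)
  z <- coef / se
  structure(list(
    hr = hr,
    log_hr = coef,
    log_hr_se = se,
    wald_p = if (estimable) 2 * stats::pnorm(-abs(z)) else NA_real_,
    ci95 = if (estimable) exp(coef + c(-1, 1) * stats::qnorm(0.975) * se)
           else c(NA_real_, NA_real_),
    n_high = n_high, n_low = n_low, n_events = n_events,
    ties = "efron",
    estimable = estimable,
    reason = reason
  ), class = "cox_binary")
}

#' Univariate Cox model of a binary risk classification
#'
#' Fits a Cox proportional-hazards model with a single binary covariate
#' (high risk = 1), maximizing the partial likelihood with the Efron
#' correction for tied event times. The hazard ratio is reported high over
#' low, never sign-flipped. Patients labelled `unclassified` are excluded
#' before fitting (the unanimity ensemble's evaluation semantics).
#'
#' @param survival Data frame with `patient_id`, `time` (> 0) and `event`
#'   (0/1).
#' @param classification Risk-classification tibble (`patient_id`, `label`)
#'   or a vector of labels named by patient id.
#' @return A `cox_binary` object with fields `hr`, `log_hr`, `log_hr_se`,
#'   `wald_p`, `ci95`, `n_high`, `n_low`, `n_events`, `estimable` and
#'   `reason`. When one group is empty, no events occurred, or the partial
#'   likelihood is monotone (complete separation), the result is an explicit
#'   non-estimable object with `NA` fields, never a silent failure. Methods
#'   for [generics::tidy()] and [generics::glance()] are provided.
#' @examples
#' surv <- tibble::tibble(patient_id = paste0("P", 1:6),
#'                        time = c(1, 2, 3, 4, 5, 6), event = 1)
#' cls <- tibble::tibble(patient_id = paste0("P", 1:6),
#'                       label = rep(c("high", "low"), each = 3))
#' fit_cox_binary(surv, cls)
#' @export
fit_cox_binary <- function(survival, classification) {
  check_survival(survival)
  if (!is.data.frame(classification)) {
    classification <- tibble::tibble(
      patient_id = names(classification) %||% survival$patient_id,
      label = as.character(classification))
  }
  check_classification(classification)
  d <- dplyr::inner_join(
    survival,
    dplyr::select(classification, "patient_id", "label"),
    by = "patient_id")
  d <- d[as.character(d$label) %in% c("high", "low"), , drop = FALSE]
  n_high <- sum(d$label == "high")
  n_low <- sum(d$label == "low")
  n_events <- as.integer(sum(d$event))
  if (n_high == 0L || n_low == 0L) {
    return(new_cox_binary(FALSE, "one risk group is empty",
                          n_high = n_high, n_low = n_low, n_events = n_events))
  }
  if (n_events == 0L) {
    return(new_cox_binary(FALSE, "no events",
                          n_high = n_high, n_low = n_low, n_events = n_events))
  }
  fit <- cox_fit_fast(d$time, d$event, d$label == "high")
  if (!fit$ok) {
    return(new_cox_binary(FALSE, "non-convergent fit (monotone partial likelihood)",
                          n_high = n_high, n_low = n_low, n_events = n_events))
  }
  new_cox_binary(TRUE, NULL, coef = fit$coef, se = fit$se,
                 n_high = as.integer(n_high), n_low = as.integer(n_low),
                 n_events = n_events)
}

#' Univariate Cox model of a continuous score
#'
#' Companion to [fit_cox_binary()] for a single continuous covariate (e.g.
#' the latent risk of a synthetic cohort, used to validate parameter
#' recovery). Efron tie correction.
#'
#' @inheritParams fit_cox_binary
#' @param values Numeric covariate, either named by patient id or aligned
#'   with `survival` rows.
#' @return A list with `coef`, `se`, `wald_p`, `n`, `n_events`, `estimable`.
#' @export
fit_cox_score <- function(survival, values) {
  check_survival(survival)
  if (!is.null(names(values))) {
    values <- values[match(survival$patient_id, names(values))]
  }
  if (length(values) != nrow(survival) || any(!is.finite(values))) {
    abort_input("`values` must be finite and cover every patient in `survival`.")
  }
  if (sum(survival$event) == 0 || stats::sd(values) == 0) {
    return(list(coef = NA_real_, se = NA_real_, wald_p = NA_real_,
                n = nrow(survival), n_events = as.integer(sum(survival$event)),
                estimable = FALSE))
  }
  fit <- survival::coxph.fit(matrix(as.numeric(values), ncol = 1),
                             survival::Surv(survival$time, survival$event),
                             strata = NULL, offset = NULL, init = 0,
                             control = survival::coxph.control(),
                             weights = NULL, method = "efron", rownames = NULL)
  coef <- as.numeric(fit$coefficients)
  se <- sqrt(as.numeric(fit$var))
  list(coef = coef, se = se, wald_p = 2 * stats::pnorm(-abs(coef / se)),
       n = nrow(survival), n_events = as.integer(sum(survival$event)),
       estimable = is.finite(coef) && is.finite(se) && abs(coef) <= 15)
}

#' @export
print.cox_binary <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<cox_binary> non-estimable (%s); n_high=%s n_low=%s events=%s\n",
                x$reason, x$n_high, x$n_low, x$n_events))
  } else {
    cat(sprintf("<cox_binary> HR (high vs low) = %.3f [%.3f, %.3f], Wald p = %.3g\n",
                x$hr, x$ci95[1], x$ci95[2], x$wald_p))
    cat(sprintf("  n_high=%d n_low=%d events=%d ties=%s\n",
                x$n_high, x$n_low, x$n_events, x$ties))
  }
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param survival Data frame with `patient_id`, `time`, `event`.
#' @param classification Optional risk-classification tibble; when given,
#'   one curve per high/low group is computed (unclassified patients are
#'   excluded).
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (and `group` when stratified): the right-continuous step
#'   function starting at 1, evaluated at each observed time.
#' @examples
#' kaplan_meier(tibble::tibble(patient_id = paste0("P", 1:4),
#'                             time = 1:4, event = 1))
#' @export
kaplan_meier <- function(survival, classification = NULL) {
  check_survival(survival)
  if (is.null(classification)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = survival)
    return(tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          surv = fit$surv))
  }
  check_classification(classification)
  d <- dplyr::inner_join(survival,
                         dplyr::select(classification, "patient_id", "label"),
                         by = "patient_id")
  d <- d[as.character(d$label) %in% c("high", "low"), , drop = FALSE]
  d$label <- droplevels(factor(d$label, levels = c("high", "low")))
  fit <- survival::survfit(survival::Surv(time, event) ~ label, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(levels(d$label)[1], length(fit$time))
  } else {
    rep(sub("^label=", "", names(fit$strata)), fit$strata)
  }
  tibble::tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone-enforced and order-preserving with
#' the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, elementwise >= the input p-values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort_input("`pvalues` must be numeric in [0, 1] with no NA.")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided paired t-test
#'
#' @param x,y Equal-length numeric vectors (n >= 2) of paired measurements.
#' @return One-row tibble: `estimate` (mean difference x - y), `statistic`
#'   (t), `df` (n - 1) and `p_value`.
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t_test <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 2L || anyNA(x) || anyNA(y)) {
    abort_input("`x` and `y` must be equal-length numeric vectors (n >= 2) without NA.")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    abort_input("pairwise differences have zero variance; the paired t-test is degenerate.",
                class = "sigensemble_degenerate_error")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return Correlation in \[-1, 1\]; `NA` when either vector is constant
#'   (rank correlation undefined).
#' @examples
#' spearman_cor(1:5, c(2, 4, 6, 8, 10))
#' @export
spearman_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y)) {
    abort_input("`x` and `y` must be equal-length numeric vectors (n >= 3) without NA.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Percentage agreement between two classifications
#'
#' The fraction of patients carrying the same label in both classifications,
#' counting `unclassified` as a label in its own right, times 100.
#'
#' @param a,b Risk-classification tibbles over the same patient universe.
#' @return A percentage in \[0, 100\].
#' @examples
#' a <- tibble::tibble(patient_id = c("P1", "P2"), label = c("high", "low"))
#' b <- tibble::tibble(patient_id = c("P1", "P2"), label = c("high", "high"))
#' percent_agreement(a, b)
#' @export
percent_agreement <- function(a, b) {
  check_classification(a, "a")
  check_classification(b, "b")
  check_same_patients(a, b, "a", "b")
  lb <- as.character(b$label)[match(as.character(a$patient_id),
                                    as.character(b$patient_id))]
  100 * mean(as.character(a$label) == lb)
}

#' Compare two classifications by hazard-ratio point estimate
#'
#' The superior classification is the one with the higher Cox hazard-ratio
#' point estimate.
#'
#' @param a,b `cox_binary` fits.
#' @return "a", "b" or "tie"; `NA` if either fit is non-estimable.
#' @export
superior_classification <- function(a, b) {
  if (!inherits(a, "cox_binary") || !inherits(b, "cox_binary")) {
    abort_input("`a` and `b` must be cox_binary fits.")
  }
  if (!a$estimable || !b$estimable) return(NA_character_)
  if (a$hr > b$hr) "a" else if (b$hr > a$hr) "b" else "tie"
}

#' Evaluate a classification against survival as a summary row
#'
#' Fits [fit_cox_binary()] and returns the standard one-row evaluation
#' record used in result tables.
#'
#' @inheritParams fit_cox_binary
#' @param signature Optional signature name recorded in the row.
#' @return One-row tibble: `signature`, `source`, `n_high`, `n_low`,
#'   `n_unclassified`, `pct_classified`, `hr`, `ci_low`, `ci_high`,
#'   `wald_p`, `n_events`, `estimable`.
#' @export
evaluate_classification <- function(survival, classification,
                                    signature = NA_character_) {
  check_classification(classification)
  fit <- fit_cox_binary(survival, classification)
  n_unc <- sum(as.character(classification$label) == "unclassified")
  n_tot <- nrow(classification)
  src <- if ("source" %in% names(classification)) {
    unique(as.character(classification$source))[1]
  } else NA_character_
  tibble::tibble(
    signature = signature, source = src,
    n_high = fit$n_high, n_low = fit$n_low, n_unclassified = n_unc,
    pct_classified = 100 * (n_tot - n_unc) / n_tot,
    hr = fit$hr, ci_low = fit$ci95[1], ci_high = fit$ci95[2],
    wald_p = fit$wald_p, n_events = fit$n_events, estimable = fit$estimable)
}
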