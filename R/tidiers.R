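#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binary Cox fit
#'
#' @param x A `cox_binary` object from [fit_cox_binary()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate` (log HR), `std_error`,
#'   `statistic`, `p_value`, `hr`, `ci_low`, `ci_high`.
#' @method tidy cox_binary
#' @export
tidy.cox_binary <- function(x, ...) {
  tibble::tibble(term = "high_vs_low",
                 estimate = x$log_hr,
                 std_error = x$log_hr_se,
                 statistic = x$log_hr / x$log_hr_se,
                 p_value = x$wald_p,
                 hr = x$hr, ci_low = x$ci95[1], ci_high = x$ci95[2])
}

#' Glance at a binary Cox fit
#'
#' @inheritParams tidy.cox_binary
#' @return One-row tibble: `hr`, `ci_low`, `ci_high`, `wald_p`, `n_high`,
#'   `n_low`, `n_events`, `estimable`, `ties`.
#' @method glance cox_binary
#' @export
glance.cox_binary <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_low = x$ci95[1], ci_high = x$ci95[2],
                 wald_p = x$wald_p, n_high = x$n_high, n_low = x$n_low,
                 n_events = x$n_events, estimable = x$estimable,
                 ties = x$ties)
}

#' Tidy a count model
#'
#' @param x A `count_model` from [fit_count_model()] or
#'   [stepwise_aic_backward()].
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy count_model
#' @export
tidy.count_model <- function(x, ...) x$coefficients

#' Glance at a count model
#'
#' @inheritParams tidy.count_model
#' @return One-row tibble: `r_squared`, `adj_r_squared`, `aic`, `n_terms`,
#'   `interactions`.
#' @method glance count_model
#' @export
glance.count_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 aic = x$aic, n_terms = nrow(x$coefficients),
                 interactions = x$interactions)
}

#' Tidy an ensemble-size sweep
#'
#' @param x An `ensemble_sweep` from [sweep_ensemble_size()].
#' @param ... Unused.
#' @return The per-size summary of [summarise_sweep()].
#' @method tidy ensemble_sweep
#' @export
tidy.ensemble_sweep <- function(x, ...) summarise_sweep(x)

#' Glance at an ensemble-size sweep
#'
#' @inheritParams tidy.ensemble_sweep
#' @return One-row tibble: `n_sizes`, `reps`, `M`, `seed`.
#' @method glance ensemble_sweep
#' @export
glance.ensemble_sweep <- function(x, ...) {
  tibble::tibble(n_sizes = length(unique(x$n)),
                 reps = attr(x, "reps") %||% NA_integer_,
                 M = attr(x, "M") %||% NA_integer_,
                 seed = attr(x, "seed") %||% NA_integer_)
}
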