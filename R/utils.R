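# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg, class = "sigensemble_input_error", ...) {
  rlang::abort(msg, class = c(class, "sigensemble_error"), ...)
}

#' Derive a reproducible sub-seed from a master seed and a purpose label
#'
#' All randomness in the package funnels through one integer master seed.
#' Sub-streams are derived per purpose (e.g. per pipeline variant) so that
#' adding a variant or a stage does not perturb the draws of any other.
#' The derivation is a fixed polynomial hash of the label folded into a
#' Lehmer step of the master seed; results stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param key Character label identifying the consuming stream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1L, "views/RMA.default.separate")
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_input(sprintf("`%s` must be a single integer >= %d.", name, min),
                class = "sigensemble_config_error")
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min)
  if (!ok) {
    what <- if (strict_min) sprintf("> %g", min) else sprintf(">= %g", min)
    abort_input(sprintf("`%s` must be a single finite number %s.", name, what),
                class = "sigensemble_config_error")
  }
  invisible(as.numeric(x))
}

# Standard per-patient risk classification tibble used throughout.
risk_levels <- c("high", "low", "unclassified")

new_classification <- function(patient_id, label, source) {
  tibble::tibble(
    patient_id = as.character(patient_id),
    label = factor(as.character(label), levels = risk_levels),
    source = source
  )
}

check_classification <- function(x, arg = "classification") {
  if (!is.data.frame(x) || !all(c("patient_id", "label") %in% names(x))) {
    abort_input(sprintf(
      "`%s` must be a data frame with columns `patient_id` and `label`.", arg))
  }
  bad <- setdiff(unique(as.character(x$label)), risk_levels)
  if (length(bad) > 0) {
    abort_input(sprintf("`%s` contains unknown labels: %s.", arg,
                        paste(bad, collapse = ", ")))
  }
  invisible(x)
}

check_same_patients <- function(a, b, arg_a = "a", arg_b = "b") {
  ia <- as.character(a$patient_id)
  ib <- as.character(b$patient_id)
  if (length(ia) != length(ib) || !setequal(ia, ib) ||
      anyDuplicated(ia) || anyDuplicated(ib)) {
    missing_a <- setdiff(ib, ia)
    missing_b <- setdiff(ia, ib)
    abort_input(sprintf(
      "`%s` and `%s` must cover the same patients (missing in %s: %s; missing in %s: %s).",
      arg_a, arg_b,
      arg_a, paste(utils::head(missing_a, 5), collapse = ", ") %||% "",
      arg_b, paste(utils::head(missing_b, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
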