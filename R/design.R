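pipeline_algorithms <- c("RMA", "GCRMA", "MAS5", "log2MAS5", "MBEI", "log2MBEI")
log_pair_map <- c(log2MAS5 = "MAS5", log2MBEI = "MBEI")

#' Enumerate the factorial design of pre-processing pipeline variants
#'
#' A pipeline variant is one combination of normalization algorithm, probe
#' annotation and dataset-handling mode. The full design crosses 6 algorithms
#' (RMA, GCRMA, MAS5, log2MAS5, MBEI, log2MBEI) with 2 annotations (default,
#' alternative) and 2 handling modes (separate, merged), giving 24 variants.
#' `log2MAS5` and `log2MBEI` are declared exact log2-monotone pairs of MAS5
#' and MBEI: they are rendered as elementwise log2 of their partner's matrix
#' and therefore can never produce a different rank-based classification.
#'
#' @param algorithms,annotations,handlings Factor levels to cross; defaults
#'   give the full 24-variant design.
#' @param platform_tag Free-text platform label attached to every variant.
#' @return A tibble with one row per variant: `variant` (unique id),
#'   `algorithm`, `annotation`, `handling`, `platform`, `log_source` (the
#'   algorithm whose matrix a log2 variant transforms, `NA` otherwise) and
#'   `is_log`.
#' @examples
#' pipeline_design()
#' @export
pipeline_design <- function(algorithms = pipeline_algorithms,
                            annotations = c("default", "alternative"),
                            handlings = c("separate", "merged"),
                            platform_tag = "synthetic") {
  bad <- setdiff(algorithms, pipeline_algorithms)
  if (length(bad) > 0) {
    abort_input(sprintf("unknown algorithm(s): %s", paste(bad, collapse = ", ")),
                class = "sigensemble_design_error")
  }
  d <- tidyr::expand_grid(
    algorithm = algorithms,
    annotation = annotations,
    handling = handlings
  )
  d <- dplyr::mutate(
    d,
    platform = platform_tag,
    is_log = .data$algorithm %in% names(log_pair_map),
    log_source = unname(log_pair_map[as.character(.data$algorithm)]),
    variant = paste(.data$algorithm, .data$annotation, .data$handling, sep = ".")
  )
  dplyr::select(d, "variant", "algorithm", "annotation", "handling",
                "platform", "log_source", "is_log")
}

check_design <- function(design) {
  need <- c("variant", "algorithm", "annotation", "handling")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    abort_input("`design` must be a data frame with columns variant, algorithm, annotation, handling.",
                class = "sigensemble_design_error")
  }
  if (anyDuplicated(design$variant)) {
    abort_input("`design` contains duplicated variant labels.",
                class = "sigensemble_design_error")
  }
  if (!"is_log" %in% names(design)) {
    design$is_log <- design$algorithm %in% names(log_pair_map)
  }
  if (!"log_source" %in% names(design)) {
    design$log_source <- unname(log_pair_map[as.character(design$algorithm)])
  }
  invisible(design)
}
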