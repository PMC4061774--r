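# Readers and writers for the package's on-disk contracts: expression
# matrices and clinical tables as tab-delimited text, signatures as GMT,
# the pipeline design as a YAML manifest.

#' Read a genes-by-patients expression matrix from TSV
#'
#' Expects a header row of patient ids, a first column of gene ids and
#' numeric cells; the dialect written by [write_expression_tsv()].
#'
#' @param path Path to the file.
#' @return Numeric matrix with gene rownames and patient colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path),
                                      class = "sigensemble_parse_error")
  lines <- readLines(path)
  if (length(lines) < 2L) {
    abort_input(sprintf("%s: expected a header row and at least one gene row.", path),
                class = "sigensemble_parse_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    abort_input(sprintf("%s: header defines 0 patients.", path),
                class = "sigensemble_parse_error")
  }
  patients <- header[-1]
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0) {
    abort_input(sprintf("%s: line %d has %d fields, expected %d (ragged row).",
                        path, bad[1] + 1L, n_fields[bad[1]], length(header)),
                class = "sigensemble_parse_error")
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    abort_input(sprintf("%s: duplicated gene id '%s'.", path,
                        genes[duplicated(genes)][1]),
                class = "sigensemble_parse_error")
  }
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(patients),
                 dimnames = list(genes, patients))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort_input(sprintf("%s: line %d, column %d: non-numeric cell '%s'.",
                          path, i + 1L, j + 1L, fields[[i]][j + 1L]),
                  class = "sigensemble_parse_error")
    }
    vals[i, ] <- v
  }
  vals
}

#' Write a genes-by-patients expression matrix to TSV
#'
#' @param matrix Numeric matrix with gene rownames and patient colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix))) {
    abort_input("`matrix` must have gene rownames and patient colnames.")
  }
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Columns `patient_id`, `time` (> 0) and `event` (0/1).
#'
#' @param path Path to the file.
#' @return A validated tibble.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path),
                                      class = "sigensemble_parse_error")
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(d))) {
    abort_input(sprintf("%s: missing column(s): %s", path,
                        paste(setdiff(need, names(d)), collapse = ", ")),
                class = "sigensemble_parse_error")
  }
  d$patient_id <- as.character(d$patient_id)
  check_survival(d, arg = path)
  tibble::as_tibble(d[need])
}

#' Write a clinical survival table to TSV
#'
#' @param survival Data frame with `patient_id`, `time`, `event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(survival, path) {
  check_survival(survival)
  readr::write_tsv(survival[c("patient_id", "time", "event")], path)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then one gene id per field,
#' tab-delimited. Duplicate genes within a set are deduplicated with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path),
                                      class = "sigensemble_parse_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_input(sprintf("%s: no signatures found.", path),
                class = "sigensemble_parse_error")
  }
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      abort_input(sprintf(
        "%s: line %d has %d tab-separated fields; need name, description and at least one gene.",
        path, i, length(f)), class = "sigensemble_parse_error")
    }
    sigs[[i]] <- gene_signature(f[1], f[-(1:2)], description = f[2])
  }
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(names(sigs))) {
    abort_input(sprintf("%s: duplicated signature name '%s'.", path,
                        names(sigs)[duplicated(names(sigs))][1]),
                class = "sigensemble_parse_error")
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A [gene_signature()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    desc <- if (nzchar(s$description %||% "")) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pipeline design manifest
#'
#' Serializes the factor levels of each variant as YAML so a directory of
#' per-variant expression matrices is self-describing.
#'
#' @param design A [pipeline_design()] tibble.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_design_manifest <- function(design, path) {
  design <- check_design(design)
  rows <- purrr::transpose(as.list(design))
  yaml::write_yaml(list(variants = rows), path)
  invisible(path)
}

#' Read a pipeline design manifest
#'
#' @param path Path to a YAML manifest written by [write_design_manifest()].
#' @return A design tibble.
#' @export
read_design_manifest <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path),
                                      class = "sigensemble_parse_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variants)) {
    abort_input(sprintf("%s: no `variants` entry.", path),
                class = "sigensemble_parse_error")
  }
  check_design(dplyr::bind_rows(lapply(raw$variants, tibble::as_tibble)))
}

#' Write a cohort and its pipeline views to a directory
#'
#' Produces the on-disk layout read by [run_full_analysis()]: one expression
#' TSV per pipeline variant, `clinical.tsv`, `design.yaml` and
#' `signature.gmt` (the cohort's built-in signature).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param views A [render_pipeline_views()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, views, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- attr(views, "design")
  write_design_manifest(design, file.path(dir, "design.yaml"))
  for (v in names(views)) {
    write_expression_tsv(views[[v]], file.path(dir, paste0(v, ".tsv")))
  }
  write_clinical_tsv(cohort$patients, file.path(dir, "clinical.tsv"))
  write_gmt(cohort$signature, file.path(dir, "signature.gmt"))
  invisible(dir)
}

#' Load a cohort bundle directory
#'
#' @param dir Directory written by [write_cohort_bundle()] (or assembled by
#'   hand with the same layout).
#' @return List with `views` (named list of matrices, design attached),
#'   `design`, `survival` and `signatures`.
#' @export
read_cohort_bundle <- function(dir) {
  design <- read_design_manifest(file.path(dir, "design.yaml"))
  views <- lapply(design$variant, function(v) {
    read_expression_tsv(file.path(dir, paste0(v, ".tsv")))
  })
  names(views) <- design$variant
  views <- structure(views, design = design, class = "pipeline_views")
  list(views = views,
       design = design,
       survival = read_clinical_tsv(file.path(dir, "clinical.tsv")),
       signatures = read_gmt(file.path(dir, "signature.gmt")))
}
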