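# Small in-code fixtures shared across test files.

small_cohort <- function(seed = 1, n_patients = 60, n_genes = 40,
                         signature_size = 10, ...) {
  simulate_cohort(sim_config(n_patients = n_patients, n_genes = n_genes,
                             signature_size = signature_size, seed = seed,
                             ...))
}

# A tiny named expression matrix with distinct values.
tiny_matrix <- function(n_genes = 4, n_patients = 6, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_patients), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("P%02d", seq_len(n_patients))))
  })
  m
}

# Long vote tibble from a patients x variants label matrix.
votes_from_matrix <- function(labels) {
  tibble::tibble(
    patient_id = rep(rownames(labels), times = ncol(labels)),
    variant = rep(colnames(labels), each = nrow(labels)),
    label = as.vector(labels))
}

simple_survival <- function(n, seed = 1, event_p = 0.8) {
  withr::with_seed(seed, {
    tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)),
                   time = stats::rexp(n, 0.2),
                   event = stats::rbinom(n, 1, event_p))
  })
}
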