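resampling_fixture <- function(seed = 7, ...) {
  cohort <- small_cohort(seed = seed, n_patients = 40, n_genes = 20,
                         signature_size = 8, ...)
  views <- render_pipeline_views(cohort)
  list(cohort = cohort,
       votes = classify_views(views, cohort$signature))
}

test_that("a sweep at n = M has zero variance and matches the full ensemble", {
  fx <- resampling_fixture()
  sw <- sweep_ensemble_size(fx$votes, fx$cohort$patients, n_values = 24,
                            reps = 10, seed = 3)
  expect_equal(length(unique(sw$hr)), 1)
  expect_equal(length(unique(sw$pct_classified)), 1)
  ens <- ensemble_classify(fx$votes)
  fit <- fit_cox_binary(fx$cohort$patients, ens)
  expect_equal(sw$hr[1], fit$hr, tolerance = 1e-8)
  expect_equal(sw$pct_classified[1],
               100 * mean(ens$label != "unclassified"))
  s <- summarise_sweep(sw)
  expect_equal(s$hr_min, s$hr_max)
})

test_that("single-pipeline ensembles classify every patient", {
  fx <- resampling_fixture()
  sw <- sweep_ensemble_size(fx$votes, fx$cohort$patients, n_values = 1,
                            reps = 30, seed = 4)
  expect_true(all(sw$pct_classified == 100))
  expect_equal(nrow(sw), 30)
})

test_that("sweeps are bit-identical for a fixed seed and move with it", {
  fx <- resampling_fixture()
  a <- sweep_ensemble_size(fx$votes, fx$cohort$patients, n_values = c(2, 5),
                           reps = 15, seed = 11)
  b <- sweep_ensemble_size(fx$votes, fx$cohort$patients, n_values = c(2, 5),
                           reps = 15, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- sweep_ensemble_size(fx$votes, fx$cohort$patients, n_values = c(2, 5),
                            reps = 15, seed = 12)
  expect_false(identical(a$hr, c2$hr))
})

test_that("out-of-range sweep sizes are rejected", {
  fx <- resampling_fixture()
  expect_error(sweep_ensemble_size(fx$votes, fx$cohort$patients,
                                   n_values = 25, reps = 2),
               class = "sigensemble_argument_error")
  expect_error(sweep_ensemble_size(fx$votes, fx$cohort$patients,
                                   n_values = 0, reps = 2),
               class = "sigensemble_argument_error")
})

test_that("sweep summaries aggregate exactly, excluding NA fits from means", {
  sw <- tibble::tibble(n = rep(c(2L, 3L), each = 4),
                       replicate = rep(1:4, 2),
                       hr = c(2, 4, NA, 6, 1, 1, 1, NA),
                       p = 0.5,
                       pct_classified = c(50, 60, 70, 80, 10, 20, 30, 40),
                       n_high = 1L, n_low = 1L)
  s <- summarise_sweep(sw)
  expect_equal(s$mean_hr, c(4, 1))
  expect_equal(s$log2_mean_hr, log2(c(4, 1)))
  expect_equal(s$mean_pct_classified, c(65, 25))
  expect_equal(s$hr_min, c(2, 1))
  expect_equal(s$hr_max, c(6, 1))
  expect_equal(s$n_inestimable, c(1L, 1L))
  expect_equal(s$n_reps, c(4L, 4L))
})

test_that("the classified percentage shrinks from single pipelines to the full ensemble", {
  fx <- resampling_fixture()
  sw <- sweep_ensemble_size(fx$votes, fx$cohort$patients,
                            n_values = c(1, 24), reps = 40, seed = 6)
  s <- summarise_sweep(sw)
  expect_equal(s$mean_pct_classified[s$n == 1], 100)
  expect_lte(s$mean_pct_classified[s$n == 24],
             s$mean_pct_classified[s$n == 1])
})

test_that("exhaustive subgroup enumeration has binomial-coefficient row counts", {
  fx <- resampling_fixture()
  # algorithm subgroup: 2 annotations x 2 handlings = 4 variants
  sub_alg <- exhaustive_subgroup_sweep(fx$votes, fx$cohort$patients,
                                       aspect = "algorithm", level = "RMA")
  expect_equal(as.integer(table(sub_alg$n)), choose(4, 1:4))
  expect_equal(nrow(sub_alg), 2^4 - 1)
  expect_equal(anyDuplicated(sub_alg$variants), 0)
  # annotation subgroup: 6 algorithms x 2 handlings = 12 variants; size 12
  # has exactly one combination
  sub_ann <- exhaustive_subgroup_sweep(fx$votes, fx$cohort$patients,
                                       aspect = "annotation",
                                       level = "default", n_values = 12)
  expect_equal(nrow(sub_ann), 1)
  expect_equal(length(strsplit(sub_ann$variants, "/")[[1]]), 12)
})

test_that("the full-subgroup enumeration row equals the direct unanimity ensemble", {
  fx <- resampling_fixture()
  d <- attr(fx$votes, "design")
  sep <- d$variant[d$handling == "separate"]
  row <- exhaustive_subgroup_sweep(fx$votes, fx$cohort$patients,
                                   aspect = "handling", level = "separate",
                                   n_values = 12)
  ens <- ensemble_classify(fx$votes[fx$votes$variant %in% sep, ])
  fit <- fit_cox_binary(fx$cohort$patients, ens)
  expect_equal(row$hr, fit$hr, tolerance = 1e-8)
  expect_equal(row$n_high, sum(ens$label == "high"))
  expect_equal(row$n_low, sum(ens$label == "low"))
  expect_equal(row$pct_classified, 100 * mean(ens$label != "unclassified"))
})

test_that("degenerate subsets are kept as NA rows in the enumeration", {
  labels <- matrix(rep(c("high", "low"), each = 4), nrow = 8, ncol = 2,
                   dimnames = list(paste0("P", 1:8), c("v1", "v2")))
  labels[, "v2"] <- "high"  # v2 alone has an empty low group
  votes <- votes_from_matrix(labels)
  design <- tibble::tibble(variant = c("v1", "v2"),
                           algorithm = c("RMA", "MAS5"),
                           annotation = "default", handling = "separate")
  surv <- tibble::tibble(patient_id = paste0("P", 1:8), time = 1:8,
                         event = rep(c(1, 0), 4))
  out <- exhaustive_subgroup_sweep(votes, surv, aspect = "annotation",
                                   level = "default", design = design)
  v2_row <- out[out$variants == "v2", ]
  expect_true(is.na(v2_row$hr))
  expect_equal(v2_row$n_low, 0L)
  expect_equal(v2_row$pct_classified, 100)
  expect_error(exhaustive_subgroup_sweep(votes, surv, aspect = "annotation",
                                         level = "missing", design = design),
               class = "sigensemble_argument_error")
})

test_that("aspect comparisons pair variants bijectively with the expected counts", {
  d <- pipeline_design()
  d$hr <- withr::with_seed(8, stats::runif(24, 1, 3))
  ann <- aspect_paired_comparison(d, "annotation")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$n_pairs, 12)
  expect_equal(ann$df, 11)
  alg <- aspect_paired_comparison(d, "algorithm")
  expect_equal(nrow(alg), choose(6, 2))
  expect_true(all(alg$n_pairs == 4))
})

test_that("a constant shift between levels reproduces the paired t-test by hand", {
  d <- pipeline_design(algorithms = c("RMA", "MAS5")) # 8 rows, 4 per handling
  key <- paste(d$algorithm, d$annotation)
  base <- stats::setNames(withr::with_seed(9, stats::runif(4, 1, 2)),
                          unique(key))
  delta <- stats::setNames(c(0.5, 0.7, 0.6, 0.8), unique(key))
  d$hr <- unname(base[key] +
                   ifelse(d$handling == "separate", delta[key], 0))
  out <- aspect_paired_comparison(d, "handling")
  tt <- stats::t.test(if (out$level_a == "separate") unname(delta)
                      else -unname(delta))
  expect_equal(out$estimate, unname(tt$estimate), tolerance = 1e-12)
  expect_equal(out$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(out$direction, "separate")
})

test_that("non-bijective pairings raise a pairing error naming offenders", {
  d <- pipeline_design(algorithms = c("RMA", "MAS5"))
  d$hr <- 1:8
  broken <- d[-1, ]
  expect_error(aspect_paired_comparison(broken, "handling"),
               class = "sigensemble_pairing_error")
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(aspect_paired_comparison(dup, "handling"),
               class = "sigensemble_pairing_error")
  expect_error(aspect_paired_comparison(d, "platform"),
               class = "sigensemble_argument_error")
})

test_that("a zero paired difference surfaces the degenerate t-test error", {
  d <- pipeline_design(algorithms = c("RMA", "MAS5"), annotations = "default")
  d$hr <- 2  # identical HRs everywhere: all paired differences are zero
  expect_error(aspect_paired_comparison(d, "handling"),
               class = "sigensemble_degenerate_error")
})
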