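test_that("a strongly prognostic planted gene attains the smallest q-value", {
  cohort <- simulate_cohort(sim_config(n_patients = 500, n_genes = 50,
                                       signature_size = 1, effect_size = 4,
                                       noise_sd_gene = 1, log_hazard_beta = 1.5,
                                       censor_horizon = 100, seed = 14))
  tbl <- per_gene_prognosis(cohort$expression, cohort$patients)
  planted <- cohort$signature$genes[1]
  expect_equal(tbl$gene[which.min(tbl$q)], planted)
  expect_lte(min(tbl$q, na.rm = TRUE), 0.05)
})

test_that("a null cohort yields no significant genes", {
  cohort <- simulate_cohort(sim_config(n_patients = 120, n_genes = 200,
                                       signature_size = 1, effect_size = 0,
                                       log_hazard_beta = 0, seed = 15))
  tbl <- per_gene_prognosis(cohort$expression, cohort$patients)
  expect_equal(sum(tbl$q <= 0.05, na.rm = TRUE), 0)
})

test_that("constant-expression genes are flagged NA and excluded from the FDR input", {
  cohort <- small_cohort(seed = 16)
  m <- cohort$expression
  m["g0003", ] <- 5
  tbl <- per_gene_prognosis(m, cohort$patients)
  row <- tbl[tbl$gene == "g0003", ]
  expect_false(row$estimable)
  expect_true(is.na(row$q))
  expect_equal(attr(tbl, "n_inestimable"), 1)
  # q-values recomputed over estimable genes only
  expect_equal(tbl$q[tbl$estimable], bh_fdr(tbl$p[tbl$estimable]))
})

test_that("a variant and its log2 pair produce identical per-gene results", {
  cohort <- small_cohort(seed = 17, n_patients = 50, n_genes = 20,
                         signature_size = 5)
  views <- render_pipeline_views(cohort)
  tbl <- gene_prognosis_table(
    views[c("MAS5.default.separate", "log2MAS5.default.separate")],
    cohort$patients)
  a <- tbl[tbl$variant == "MAS5.default.separate",
           c("gene", "hr", "p", "q", "estimable")]
  b <- tbl[tbl$variant == "log2MAS5.default.separate",
           c("gene", "hr", "p", "q", "estimable")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("significance summaries are the marginals of the indicator matrix", {
  withr::with_seed(20, {
    tbl <- tidyr::expand_grid(gene = sprintf("g%02d", 1:15),
                              variant = sprintf("v%02d", 1:6))
    tbl$q <- stats::runif(nrow(tbl))
  })
  s <- significance_summary(tbl, alpha = 0.3)
  ind <- matrix(tbl$q <= 0.3, nrow = 15, byrow = TRUE) # gene-major grid
  per_gene <- rowSums(ind)
  per_variant <- colSums(ind)
  expect_equal(s$per_gene$n_variants_significant[order(s$per_gene$gene)],
               unname(per_gene))
  expect_equal(s$per_variant$n_significant[order(s$per_variant$variant)],
               unname(per_variant))
  # all q = 1 gives all-zero counts
  tbl$q <- 1
  s0 <- significance_summary(tbl)
  expect_true(all(s0$per_variant$n_significant == 0))
  expect_true(all(s0$per_gene$n_variants_significant == 0))
})

test_that("pipeline concordance is a symmetric unit-diagonal Spearman matrix", {
  withr::with_seed(21, {
    q1 <- stats::runif(40)
    q2 <- q1^1.5              # monotone of q1: rho exactly 1
    q3 <- stats::runif(40)
  })
  tbl <- tibble::tibble(gene = rep(sprintf("g%02d", 1:40), 3),
                        variant = rep(c("a", "b", "c"), each = 40),
                        q = c(q1, q2, q3), estimable = TRUE)
  m <- pipeline_concordance(tbl)
  expect_equal(dim(m), c(3, 3))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], spearman_cor(q1, q3))
  # fewer than 3 shared estimable genes gives NA
  tbl$q[tbl$variant == "c"][3:40] <- NA
  m2 <- pipeline_concordance(tbl)
  expect_true(is.na(m2["a", "c"]))
})

test_that("uncorrelated q-value columns show near-zero concordance", {
  withr::with_seed(22, {
    tbl <- tibble::tibble(gene = rep(sprintf("g%03d", 1:500), 2),
                          variant = rep(c("a", "b"), each = 500),
                          q = stats::runif(1000))
  })
  m <- pipeline_concordance(tbl)
  expect_lt(abs(m["a", "b"]), 0.3)
})

test_that("the count model reproduces a noiseless linear truth exactly", {
  d <- pipeline_design(platform_tag = "HG-U133A")
  d$n_significant <- 100 + 50 * (d$handling == "separate")
  fit <- suppressMessages(suppressWarnings(fit_count_model(d)))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 100, tolerance = 1e-9)
  expect_equal(co$estimate[co$term == "handlingseparate"], 50, tolerance = 1e-9)
  expect_equal(fit$adj_r_squared, 1)
})

test_that("count-model coefficients match a normal-equations oracle", {
  for (seed in 1:5) {
    d <- dplyr::bind_rows(pipeline_design(platform_tag = "HG-U133A"),
                          pipeline_design(platform_tag = "HG-U133 Plus 2.0"))
    d$n_significant <- withr::with_seed(seed, stats::rnorm(nrow(d), 500, 100))
    fit <- fit_count_model(d, interactions = "none")
    X <- stats::model.matrix(fit$lm)
    beta <- solve(t(X) %*% X, t(X) %*% d$n_significant)
    expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("baselines follow the factorial convention", {
  d <- dplyr::bind_rows(pipeline_design(platform_tag = "HG-U133A"),
                        pipeline_design(platform_tag = "HG-U133 Plus 2.0"))
  d$n_significant <- seq_len(nrow(d))
  fit <- suppressWarnings(fit_count_model(d, interactions = "none"))
  terms <- fit$coefficients$term
  # baseline levels never appear as dummy coefficients
  expect_false(any(grepl("GCRMA|alternative$|merged|HG-U133A$", terms)))
  expect_equal(sum(grepl("^algorithm", terms)), 5)
})

test_that("a constant response is fitted by its intercept with zero residuals", {
  d <- pipeline_design(platform_tag = "HG-U133A")
  d$n_significant <- 7
  fit <- suppressMessages(suppressWarnings(fit_count_model(d, interactions = "none")))
  expect_equal(unname(stats::residuals(fit$lm)), rep(0, 24), tolerance = 1e-10)
  expect_equal(unname(stats::fitted(fit$lm)), rep(7, 24), tolerance = 1e-10)
})

test_that("backward AIC stepwise keeps true main effects and prunes most interactions", {
  # With a main-effects-only truth, AIC (k = 2) is expected to retain a
  # spurious interaction term with probability roughly P(chisq_d > 2d)
  # (~0.16 for 1 df, ~0.08 for 5 df), so full pruning is NOT guaranteed.
  # The principled checks: the strong true main effects always survive,
  # the AIC never increases, and spurious interactions are rare on average
  # (expectation ~0.7 of the 6 candidate interaction terms).
  n_runs <- 60
  n_kept_interactions <- integer(n_runs)
  for (seed in seq_len(n_runs)) {
    d <- dplyr::bind_rows(pipeline_design(platform_tag = "HG-U133A"),
                          pipeline_design(platform_tag = "HG-U133 Plus 2.0"))
    withr::with_seed(seed + 300, {
      d$n_significant <- 200 +
        80 * (d$handling == "separate") +
        120 * (d$platform == "HG-U133 Plus 2.0") +
        40 * (d$annotation == "default") +
        stats::rnorm(nrow(d), sd = 30)
    })
    full <- fit_count_model(d, interactions = "pairwise")
    red <- stepwise_aic_backward(full)
    expect_lte(red$aic, full$aic)
    kept <- attr(stats::terms(red$lm), "term.labels")
    expect_true(all(c("handling", "platform", "annotation") %in% kept))
    n_kept_interactions[seed] <- sum(grepl(":", kept))
  }
  expect_lte(mean(n_kept_interactions), 2)
  expect_gte(mean(n_kept_interactions == 0), 0.1)
})

test_that("the first stepwise removal is the single-term drop with lowest AIC", {
  d <- dplyr::bind_rows(pipeline_design(platform_tag = "HG-U133A"),
                        pipeline_design(platform_tag = "HG-U133 Plus 2.0"))
  withr::with_seed(31, {
    d$n_significant <- 100 + 60 * (d$handling == "separate") +
      stats::rnorm(nrow(d), sd = 20)
  })
  full <- fit_count_model(d, interactions = "pairwise")
  red <- stepwise_aic_backward(full)
  trace <- attr(red, "trace")
  # oracle: enumerate every single-term removal respecting marginality
  cand <- stats::drop1(full$lm, k = 2)
  deltas <- cand$AIC[-1] - cand$AIC[1]
  best <- rownames(cand)[-1][order(deltas, rownames(cand)[-1])][1]
  expect_equal(trace$removed[2], best)
  expect_lt(deltas[rownames(cand)[-1] == best], 0)
})

test_that("stepwise removal never violates marginality", {
  for (seed in 1:10) {
    d <- dplyr::bind_rows(pipeline_design(platform_tag = "HG-U133A"),
                          pipeline_design(platform_tag = "HG-U133 Plus 2.0"))
    d$n_significant <- withr::with_seed(seed + 500,
                                        stats::rnorm(nrow(d), 100, 50))
    red <- stepwise_aic_backward(fit_count_model(d, interactions = "pairwise"))
    kept <- attr(stats::terms(red$lm), "term.labels")
    expect_type(kept, "character")
    mains <- kept[!grepl(":", kept)]
    inters <- strsplit(kept[grepl(":", kept)], ":")
    for (int in inters) expect_true(all(int %in% mains))
  }
})

test_that("significant gene counts join design factors and fill zeros", {
  cohort <- small_cohort(seed = 23, n_patients = 40, n_genes = 12,
                         signature_size = 4)
  design <- pipeline_design(algorithms = c("RMA", "MAS5"),
                            annotations = "default")
  views <- render_pipeline_views(cohort, design = design)
  tbl <- gene_prognosis_table(views, cohort$patients)
  counts <- significant_gene_counts(tbl, alpha = 0.9)
  expect_equal(nrow(counts), nrow(design))
  expect_true(all(c("algorithm", "annotation", "handling",
                    "n_significant") %in% names(counts)))
  s <- significance_summary(tbl, alpha = 0.9)$per_variant
  expect_equal(counts$n_significant[match(s$variant, counts$variant)],
               s$n_significant)
})
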