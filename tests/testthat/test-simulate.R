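test_that("cohort simulation is deterministic given its seed", {
  sp <- cohort_spec("human", n_female = 30, n_male = 30,
                    betas = c(a = 0.3, b = -0.2), seed = 77)
  expect_identical(simulate_cohort(sp), simulate_cohort(sp))
  sp2 <- cohort_spec("human", n_female = 30, n_male = 30,
                     betas = c(a = 0.3, b = -0.2), seed = 78)
  expect_false(identical(simulate_cohort(sp)$vol_a,
                         simulate_cohort(sp2)$vol_a))
})

test_that("with no effects and no noise, volumes track TTV only", {
  sp <- cohort_spec("mouse", n_female = 10, n_male = 10,
                    betas = c(a = 0, b = 0), noise_sd = 1e-9,
                    age_slope = 0, qc_slope = 0, strain_offset = 0,
                    n_batches = 1, seed = 5)
  tab <- simulate_cohort(sp)
  ratio <- tab$vol_a / tab$ttv
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-5)
  expect_equal(cor(tab$vol_b, tab$ttv), 1, tolerance = 1e-6)
})

test_that("the generator's default structure mirrors the two study cohorts", {
  hu <- simulate_cohort(cohort_spec("human", seed = 1))
  mo <- simulate_cohort(cohort_spec("mouse", seed = 1))
  expect_equal(nrow(hu), 597 + 496)
  expect_equal(nrow(mo), 213 + 216)
  expect_true(all(c("euler", "family_id") %in% names(hu)))
  expect_true(all(c("strain", "batch") %in% names(mo)))
  expect_equal(length(grep("^vol_", names(hu))), 60)
  # human TTV sex shift ~1.3 standardized units; mouse none
  fh <- fit_sex_effect(hu, "ttv", qc_col = "euler")
  fm <- fit_sex_effect(mo, "ttv", qc_col = "strain")
  expect_lt(abs(fh$beta_sex - 1.3), 0.15)
  expect_lt(abs(fm$beta_sex), 0.2)
})

test_that("planted standardized sex effects are recovered by the estimator", {
  ests <- sapply(1:40, function(i) {
    tab <- simulate_cohort(cohort_spec("human", n_female = 200,
                                       n_male = 200,
                                       betas = c(a = 0.5, b = -0.5, c = 0),
                                       seed = 1000 + i))
    coef(fit_sex_effects(tab, qc_col = "euler"))
  })
  bias <- rowMeans(ests) - c(0.5, -0.5, 0)
  expect_lt(max(abs(bias)), 0.06)
})

test_that("male variance inflation is detectable by the variance test", {
  tab <- simulate_cohort(cohort_spec("human", n_female = 500, n_male = 500,
                                     betas = c(a = 0), variance_ratio = 1.5,
                                     seed = 55))
  res <- residualize(tab, c("ttv", "age", "euler"))
  vt <- levene_variance_test(res[, "a"], tab$sex)
  expect_lt(vt$p, 0.05)
  expect_gt(vt$group_variances[["M"]], vt$group_variances[["F"]])
})

test_that("infeasible variance budgets are rejected", {
  expect_error(simulate_cohort(cohort_spec("human", n_female = 10,
                                           n_male = 10, betas = c(a = 1.9),
                                           noise_sd = 0.9)),
               "infeasible")
  expect_error(cohort_spec("human", n_female = 1, n_male = 10,
                           betas = c(a = 0)), "at least 2")
  expect_error(cohort_spec("human", variance_ratio = -1), "positive")
  expect_error(cohort_spec("human", ttv_sex_shift = 2.5), "infeasible")
})

test_that("expression pair generation honors the planted congruence", {
  # perfect congruence, no noise
  sim1 <- simulate_expression_pair(
    expression_pair_spec(rho = c(r1 = 1, r2 = 1, r3 = 1), n_genes = 50,
                         noise_sd = 0, seed = 4))
  paired <- intersect_homologous_genes(sim1$human, sim1$mouse, sim1$map)
  hz <- zscore_genes_across_regions(paired$human)
  mz <- zscore_genes_across_regions(paired$mouse)
  ts <- transcriptional_similarity(hz, mz)
  expect_equal(ts$transcriptional, rep(1, 3), tolerance = 1e-10)
  # zero congruence with many genes: similarity within sampling error
  sim0 <- simulate_expression_pair(
    expression_pair_spec(rho = c(r1 = 0, r2 = 0, r3 = 0), n_genes = 5000,
                         seed = 6))
  ts0 <- transcriptional_similarity(
    zscore_genes_across_regions(sim0$human),
    zscore_genes_across_regions(sim0$mouse))
  expect_lt(max(abs(ts0$transcriptional)), 0.05)
  # seeded determinism and symbol casing conventions
  sim_a <- simulate_expression_pair(expression_pair_spec(n_genes = 15,
                                                         seed = 9))
  sim_b <- simulate_expression_pair(expression_pair_spec(n_genes = 15,
                                                         seed = 9))
  expect_identical(unclass(sim_a$human), unclass(sim_b$human))
  expect_true(all(grepl("^GENE", colnames(sim_a$human))))
  expect_true(all(grepl("^Gene", colnames(sim_a$mouse))))
  expect_error(expression_pair_spec(rho = c(a = 1.2)), "\\[-1, 1\\]")
  expect_error(expression_pair_spec(n_genes = 5), "at least 10")
})

test_that("negative congruence flips the sign of the similarity", {
  rho <- c(r1 = -0.8, r2 = 0.8, r3 = 0.1,
           setNames(rep(0.3, 12), paste0("f", 4:15)))
  sim <- simulate_expression_pair(
    expression_pair_spec(rho = rho, n_genes = 3000, noise_sd = 0,
                         seed = 13))
  ts <- transcriptional_similarity(
    zscore_genes_across_regions(sim$human),
    zscore_genes_across_regions(sim$mouse))
  est <- setNames(ts$transcriptional, ts$key)
  expect_lt(est[["r1"]], -0.7)
  expect_gt(est[["r2"]], 0.7)
  expect_lt(abs(est[["r3"]] - 0.1), 0.08)
})

test_that("recovery reports compute per-parameter bias and RMSE", {
  truth <- c(a = 0.5, b = -0.2)
  perfect <- data.frame(parameter = c("a", "a", "b"),
                        estimate = c(0.5, 0.5, -0.2))
  rep1 <- recovery_report(truth, perfect)
  expect_equal(rep1$bias, c(0, 0))
  expect_equal(rep1$rmse, c(0, 0))
  shifted <- data.frame(parameter = rep("a", 4),
                        estimate = rep(0.6, 4))
  rep2 <- recovery_report(c(a = 0.5), shifted)
  expect_equal(rep2$bias, 0.1, tolerance = 1e-12)
  expect_equal(rep2$rmse, 0.1, tolerance = 1e-12)
  expect_error(recovery_report(truth,
                               data.frame(parameter = "zz", estimate = 1)),
               "no matching truth")
  path <- tempfile(fileext = ".tsv")
  recovery_report(truth, perfect, path = path)
  expect_equal(read.delim(path)$parameter, c("a", "b"))
})

test_that("estimation error shrinks with sample size", {
  rmse_at <- function(n) {
    ests <- vapply(1:30, function(i) {
      tab <- simulate_cohort(cohort_spec("human", n_female = n,
                                         n_male = n, betas = c(a = 0.5),
                                         seed = 400 + i))
      fit_sex_effect(tab, "vol_a", qc_col = "euler")$beta_sex
    }, numeric(1))
    sqrt(mean((ests - 0.5)^2))
  }
  expect_gt(rmse_at(50), rmse_at(200))
})

test_that("heavy-tailed noise hurts Pearson more than the bend correlation", {
  # percentage-bend stays closer to the planted association under t(3)
  set.seed(66)
  diffs <- replicate(60, {
    x <- rnorm(60)
    y <- 0.6 * x + 0.8 * (rt(60, 3) / sqrt(3))
    y[1:2] <- y[1:2] + c(25, -25)  # occasional gross outliers
    pb <- percentage_bend_correlation(x, y)$r
    pe <- pearson_correlation(x, y)$r
    abs(pb - 0.6) - abs(pe - 0.6)
  })
  expect_lt(mean(diffs), 0)
})
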