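test_that("region aggregation computes (weighted) means per region", {
  samples <- matrix(c(3, 9, 5, 1, 2, 4), 3, 2,
                    dimnames = list(paste0("s", 1:3), c("g1", "g2")))
  # two samples for region A with weights (2, 1): (2*3 + 1*9) / 3 = 5
  agg <- aggregate_expression_by_region(samples, c("A", "A", "B"),
                                        weights = c(2, 1, 1))
  expect_equal(agg["A", "g1"], 5)
  expect_equal(agg["A", "g2"], (2 * 1 + 1 * 2) / 3)
  expect_equal(agg["B", ], samples["s3", ])  # one sample -> its values
  # uniform weights are a plain mean
  agg_u <- aggregate_expression_by_region(samples, c("A", "A", "B"))
  expect_equal(agg_u["A", "g1"], 6)
  expect_error(aggregate_expression_by_region(samples, c("A", "A", "B"),
                                              regions = c("A", "B", "C")),
               "no samples: C")
  expect_error(aggregate_expression_by_region(samples, c("A", "A", "B"),
                                              weights = c(0, 0, 1)),
               "all weights zero")
})

test_that("hemisphere reflection fills missing right rows from the left", {
  map <- load_homologous_regions()
  sim <- simulate_expression_pair(expression_pair_spec(n_genes = 20,
                                                       seed = 3))
  h <- sim$human
  drop_keys <- c("Bed nucleus of stria terminalis (right)",
                 "Hypothalamus (right)")
  h_missing <- sexcongr:::new_region_gene_matrix(
    unclass(h)[setdiff(rownames(h), drop_keys), , drop = FALSE], "human")
  filled <- reflect_hemisphere(h_missing, map)
  for (k in drop_keys) {
    donor <- sub("\\(right\\)", "(left)", k)
    expect_equal(unclass(filled)[k, ], unclass(h_missing)[donor, ])
  }
  expect_setequal(attr(filled, "reflected"), drop_keys)
  # nothing missing -> identity
  expect_identical(reflect_hemisphere(h, map), h)
  # both sides missing -> error naming the region
  h_both <- sexcongr:::new_region_gene_matrix(
    unclass(h)[!grepl("^Hypothalamus", rownames(h)), , drop = FALSE],
    "human")
  expect_error(reflect_hemisphere(h_both, map), "Hypothalamus")
})

test_that("homologous-gene intersection aligns gene order across species", {
  h <- sexcongr:::new_region_gene_matrix(
    matrix(1:12, 3, 4, dimnames = list(paste0("r", 1:3),
                                       c("A", "B", "C", "D"))), "human")
  m <- sexcongr:::new_region_gene_matrix(
    matrix(13:24, 3, 4, dimnames = list(paste0("r", 1:3),
                                        c("b", "c", "d", "e"))), "mouse")
  map <- data.frame(human = c("B", "C", "Z"), mouse = c("b", "c", "z"))
  out <- intersect_homologous_genes(h, m, map)
  expect_equal(colnames(out$human), c("B", "C"))
  expect_equal(colnames(out$mouse), c("b", "c"))
  expect_equal(nrow(out$map), 2)
  # identical sets with an identity map retain everything
  idmap <- data.frame(human = c("A", "B", "C", "D"),
                      mouse = c("A", "B", "C", "D"))
  m2 <- sexcongr:::new_region_gene_matrix(
    `colnames<-`(unclass(m), c("A", "B", "C", "D")), "mouse")
  expect_equal(ncol(intersect_homologous_genes(h, m2, idmap)$human), 4)
  disjoint <- data.frame(human = "X", mouse = "x")
  expect_error(intersect_homologous_genes(h, m, disjoint), "empty")
  dup <- data.frame(human = c("B", "B"), mouse = c("b", "c"))
  expect_error(intersect_homologous_genes(h, m, dup), "one-to-one")
})

test_that("z-scoring across regions standardizes each gene and drops constants", {
  vals <- matrix(c(1, 2, 3, 5, 5, 5, 2, 4, 9), 3, 3,
                 dimnames = list(paste0("r", 1:3), c("g1", "gconst", "g3")))
  mat <- sexcongr:::new_region_gene_matrix(vals, "human")
  z <- suppressMessages(zscore_genes_across_regions(mat))
  expect_equal(colnames(z), c("g1", "g3"))
  expect_equal(unclass(z)[, "g1"], c(r1 = -1, r2 = 0, r3 = 1))
  expect_equal(attr(z, "n_dropped"), 1L)
  expect_true(attr(z, "zscored"))
  expect_true(all(abs(colMeans(unclass(z))) < 1e-12))
  expect_true(all(abs(apply(unclass(z), 2, sd) - 1) < 1e-12))
  allconst <- sexcongr:::new_region_gene_matrix(
    matrix(1, 3, 2, dimnames = list(paste0("r", 1:3), c("a", "b"))),
    "human")
  expect_error(zscore_genes_across_regions(allconst), "constant")
})

test_that("transcriptional similarity is the per-region Pearson correlation", {
  pair <- toy_zscored_pair()
  ts <- transcriptional_similarity(pair$human, pair$mouse)
  expect_equal(ts$transcriptional, rep(1, nrow(ts)), tolerance = 1e-12)
  neg <- sexcongr:::new_region_gene_matrix(-unclass(pair$mouse), "mouse",
                                           zscored = TRUE)
  expect_equal(transcriptional_similarity(pair$human, neg)$transcriptional,
               rep(-1, 6), tolerance = 1e-12)
  # agrees with cor() per region and is permutation-invariant
  set.seed(8)
  noisy <- sexcongr:::new_region_gene_matrix(
    unclass(pair$mouse) + matrix(rnorm(48), 6, 8), "mouse", zscored = TRUE)
  ts2 <- transcriptional_similarity(pair$human, noisy)
  for (i in 1:6)
    expect_equal(ts2$transcriptional[i],
                 cor(unclass(pair$human)[i, ], unclass(noisy)[i, ]),
                 tolerance = 1e-12)
  perm <- sample(8)
  hp <- sexcongr:::new_region_gene_matrix(unclass(pair$human)[, perm],
                                          "human", zscored = TRUE)
  mp <- sexcongr:::new_region_gene_matrix(unclass(noisy)[, perm], "mouse",
                                          zscored = TRUE)
  expect_equal(transcriptional_similarity(hp, mp)$transcriptional,
               ts2$transcriptional, tolerance = 1e-12)
  expect_error(transcriptional_similarity(pair$human, noisy,
                                          genes = c("G01", "G02")),
               "at least 3")
})

test_that("planted per-region congruence is recovered in rank order", {
  rho <- seq(0.1, 0.9, by = 0.1)
  names(rho) <- paste0("reg", seq_along(rho))
  sim <- simulate_expression_pair(expression_pair_spec(rho = rho,
                                                       n_genes = 2000,
                                                       noise_sd = 0,
                                                       seed = 17))
  paired <- intersect_homologous_genes(sim$human, sim$mouse, sim$map)
  hz <- zscore_genes_across_regions(paired$human)
  mz <- zscore_genes_across_regions(paired$mouse)
  ts <- transcriptional_similarity(hz, mz)
  est <- ts$transcriptional[match(names(rho), ts$key)]
  expect_equal(order(est), order(rho))
  expect_lt(max(abs(est - rho)), 0.1)
})

test_that("similarity-vs-expression correlation recovers a planted association", {
  # self-pairing gives r = 1
  sc <- data.frame(region = paste0("r", 1:20), hemisphere = "left",
                   compartment = rep(c("cortical", "non_cortical"), 10),
                   key = paste0("r", 1:20),
                   anatomical = seq(-0.5, 0.5, length.out = 20))
  sc$transcriptional <- sc$anatomical
  expect_equal(similarity_vs_expression_correlation(sc)$r, 1,
               tolerance = 1e-12)
  # planted correlation 0.6, n = 56 regions
  set.seed(23)
  rs <- replicate(150, {
    a <- rnorm(56)
    b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(56)
    df <- data.frame(region = paste0("r", 1:56), hemisphere = "left",
                     compartment = "cortical", key = paste0("r", 1:56),
                     anatomical = a, transcriptional = b)
    similarity_vs_expression_correlation(df)$r
  })
  expect_lt(abs(mean(rs) - 0.6), 0.06)
  # compartment filtering delegates to filter_compartment
  sub <- filter_compartment(sc, "cortical")
  expect_equal(similarity_vs_expression_correlation(sc, "cortical")$r,
               percentage_bend_correlation(sub$anatomical,
                                           sub$transcriptional)$r)
})

test_that("gene-subset null is seeded, never returns p = 0, and handles the degenerate draw", {
  pair <- toy_zscored_pair(n_regions = 10, n_genes = 6, seed = 2)
  set.seed(99)
  noisy <- sexcongr:::new_region_gene_matrix(
    scale(unclass(pair$mouse) + matrix(rnorm(60), 10, 6)), "mouse",
    zscored = TRUE)
  attr(noisy, "scaled:center") <- NULL; attr(noisy, "scaled:scale") <- NULL
  sc <- data.frame(region = rownames(pair$human), hemisphere = "left",
                   compartment = "cortical", key = rownames(pair$human),
                   anatomical = rnorm(10))
  genes <- colnames(pair$human)[1:3]
  n1 <- gene_subset_null(pair$human, noisy, sc, genes, n_resamples = 200,
                         seed = 42)
  n2 <- gene_subset_null(pair$human, noisy, sc, genes, n_resamples = 200,
                         seed = 42)
  expect_identical(n1$values, n2$values)
  expect_gt(n1$p, 0)
  expect_lte(n1$p, 1)
  # subset = whole universe -> all resamples equal the observed statistic
  all_genes <- colnames(pair$human)
  nd <- gene_subset_null(pair$human, noisy, sc, all_genes,
                         n_resamples = 50, seed = 1)
  expect_true(all(abs(nd$values - nd$observed) < 1e-12))
  expect_equal(nd$p, 1)
  expect_error(gene_subset_null(pair$human, noisy, sc,
                                c(all_genes, "EXTRA"), 10, 1),
               "exceeds")
})

test_that("the resampled null converges to the exact subset enumeration", {
  pair <- toy_zscored_pair(n_regions = 12, n_genes = 6, seed = 5)
  set.seed(100)
  noisy <- sexcongr:::new_region_gene_matrix(
    scale(unclass(pair$mouse) + matrix(rnorm(72), 12, 6)), "mouse",
    zscored = TRUE)
  attr(noisy, "scaled:center") <- NULL; attr(noisy, "scaled:scale") <- NULL
  sc <- data.frame(region = rownames(pair$human), hemisphere = "left",
                   compartment = "cortical", key = rownames(pair$human),
                   anatomical = rnorm(12))
  h <- unclass(pair$human); m <- unclass(noisy)
  exact <- vapply(oracle_subsets(6, 3), function(s) {
    ts <- sapply(seq_len(12), function(i) cor(h[i, s], m[i, s]))
    percentage_bend_correlation(sc$anatomical, ts)$r
  }, numeric(1))
  nd <- gene_subset_null(pair$human, noisy, sc,
                         colnames(pair$human)[c(2, 4, 6)],
                         n_resamples = 4000, seed = 7)
  # total-variation distance between the empirical draw frequencies and
  # the uniform weight over the 20 enumerable subsets
  freq <- table(factor(round(nd$values, 10),
                       levels = sort(unique(round(exact, 10)))))
  expect_equal(sum(freq), 4000)  # every draw maps onto an enumerated subset
  tv <- 0.5 * sum(abs(freq / sum(freq) - 1 / 20))
  expect_lt(tv, 0.05)
  # two seeds give p-values within Monte-Carlo error of each other
  p1 <- gene_subset_null(pair$human, noisy, sc,
                         colnames(pair$human)[1:3], 500, seed = 1)$p
  p2 <- gene_subset_null(pair$human, noisy, sc,
                         colnames(pair$human)[1:3], 500, seed = 2)$p
  expect_lt(abs(p1 - p2), 3 * sqrt(0.5 * 0.5 / 500) + 0.02)
})
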