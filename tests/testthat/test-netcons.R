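test_that("adjacency equals entry-wise pairwise PCC and flags zero variance", {
  set.seed(2)
  x <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("g", 1:3), NULL))
  a <- coexpression_adjacency(x)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(a[i, j], pearson_correlation(x[i, ], x[j, ]), tolerance = 1e-12)
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 3))

  # identical profiles correlate at 1
  x2 <- rbind(g1 = 1:5, g2 = 1:5 * 2 + 3)
  expect_equal(coexpression_adjacency(x2)["g1", "g2"], 1)

  # constant row: undefined off-diagonal entries
  x3 <- rbind(g1 = rep(1, 5), g2 = rnorm(5), g3 = rnorm(5))
  a3 <- coexpression_adjacency(x3)
  expect_true(all(is.na(a3["g1", -1])) && all(is.na(a3[-1, "g1"])))
  expect_equal(a3["g1", "g1"], 1)
  expect_error(coexpression_adjacency(x[1, , drop = FALSE]), ">= 2 genes")
  expect_error(coexpression_adjacency(x[, 1:2]), ">= 3")
})

test_that("EC identities: self-comparison gives 1 everywhere", {
  set.seed(3)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(sprintf("g%02d", 1:50), NULL))
  a <- coexpression_adjacency(x)
  expect_true(all(abs(ec_scores(a, a) - 1) < 1e-12))
  expect_equal(full_matrix_correlation(a, a), 1, tolerance = 1e-12)
  # negated off-diagonal rows give -1
  b <- -a; diag(b) <- 1
  expect_true(all(abs(ec_scores(a, b) + 1) < 1e-12))
  expect_equal(full_matrix_correlation(a, b), -1, tolerance = 1e-12)
})

test_that("worked 4-gene EC value matches the direct PCC oracle", {
  mk <- function(r12, r13, r14, r23 = 0.3, r24 = -0.4, r34 = 0.5) {
    a <- diag(4)
    a[1, 2] <- a[2, 1] <- r12; a[1, 3] <- a[3, 1] <- r13
    a[1, 4] <- a[4, 1] <- r14; a[2, 3] <- a[3, 2] <- r23
    a[2, 4] <- a[4, 2] <- r24; a[3, 4] <- a[4, 3] <- r34
    dimnames(a) <- list(paste0("g", 1:4), paste0("g", 1:4))
    a
  }
  a_tr <- mk(0.9, 0.1, -0.2)
  a_tl <- mk(0.8, 0.2, -0.1)
  oracle <- cor(c(0.9, 0.1, -0.2), c(0.8, 0.2, -0.1))
  expect_equal(ec_score(a_tr, a_tl, "g1"), oracle, tolerance = 1e-12)
  expect_equal(ec_score(a_tr, a_tl, 1), oracle, tolerance = 1e-12)
  expect_error(ec_score(a_tr, a_tl, "g9"), "not found")
})

test_that("full-matrix correlation equals the upper-triangle vector oracle", {
  set.seed(4)
  x <- matrix(rnorm(9), 3, 3); a1 <- (x + t(x)) / 2; diag(a1) <- 1
  y <- matrix(rnorm(9), 3, 3); a2 <- (y + t(y)) / 2; diag(a2) <- 1
  oracle <- cor(a1[upper.tri(a1)], a2[upper.tri(a2)])
  expect_equal(full_matrix_correlation(a1, a2), oracle, tolerance = 1e-12)
  expect_equal(full_matrix_correlation(a1, a2), full_matrix_correlation(a2, a1))
})

test_that("EC rows exclude the diagonal and NA entries pairwise", {
  a <- diag(4); a[upper.tri(a)] <- c(0.5, 0.2, NA, 0.1, 0.6, -0.3)
  a <- a + t(a) - diag(diag(a)); diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:4), paste0("g", 1:4))
  b <- a * 0.9; diag(b) <- 1
  # row g1 of a: (0.5, 0.2, 0.1) vs proportional row in b -> exactly 1
  expect_equal(unname(ec_scores(a, b)["g1"]), 1, tolerance = 1e-12)
  # g2 row has an NA at g3: only 2 usable entries -> undefined
  expect_true(is.na(ec_scores(a, b)["g2"]))
})

test_that("EC bootstrap is deterministic and collapses when pool == k with fixed pairing", {
  syn <- small_synth(30, seed = 31)
  cfg <- pipeline_config(n_boot = 15, seed = 33)
  n1 <- bootstrap_ec_null(syn$x_tr, syn$x_tl, syn$map, k = 5, cfg)
  n2 <- bootstrap_ec_null(syn$x_tr, syn$x_tl, syn$map, k = 5, cfg)
  expect_identical(n1, n2)
  expect_length(n1$fmc_null, 15L)
  expect_identical(nrow(n1$per_gene), 30L)
})

test_that("ec_analysis classifies with its own invariants intact", {
  syn <- small_synth(60, seed = 41)
  cfg <- pipeline_config(n_boot = 40, seed = 43)
  ec <- ec_analysis(syn$x_tr, syn$x_tl, syn$map, "common", cfg)
  ok <- !is.na(ec$zscore)
  expect_true(all(ec$ec[ok & ec$ec_class == "conserved"] > 0))
  expect_true(all(ec$zscore[ok & ec$ec_class == "conserved"] >= cfg$z_crit))
  expect_true(all(ec$zscore[ok & ec$ec_class == "rewired"] <= -cfg$z_crit))
  p <- attr(ec, "fmc_p_lower")
  expect_true(p > 0 && p <= 1)
})

test_that("coupled genes keep conserved network rows as noise vanishes", {
  # all profiles conserved across levels: every row correlates near 1
  syn <- generate_paired_dataset(synthetic_config(
    n_genes = 40, frac_coupled = 1, frac_uncoupled = 0, frac_null = 0,
    frac_motif_genes = 0, noise_sd_tr = 0.01, noise_sd_tl = 0.01, seed = 8))
  p <- aggregate_to_cell_types(syn$x_tr, syn$x_tl, syn$map, "common")
  ec <- ec_scores(coexpression_adjacency(p$x_tr),
                  coexpression_adjacency(p$x_tl))
  expect_gt(min(ec), 0.95)
  # in a mixture, coupled genes keep higher EC than noise-only genes
  syn2 <- generate_paired_dataset(synthetic_config(
    n_genes = 60, frac_coupled = 0.5, frac_uncoupled = 0, frac_null = 0.5,
    frac_motif_genes = 0, noise_sd_tr = 0.05, noise_sd_tl = 0.05, seed = 9))
  p2 <- aggregate_to_cell_types(syn2$x_tr, syn2$x_tl, syn2$map, "common")
  ec2 <- ec_scores(coexpression_adjacency(p2$x_tr),
                   coexpression_adjacency(p2$x_tl))
  cl <- syn2$truth$classes$coupling_class
  expect_gt(mean(ec2[cl == "coupled"]), mean(ec2[cl == "null"]) + 0.2)
})

test_that("threshold graph places edges exactly at the cutoff", {
  a <- diag(3); a[1, 2] <- a[2, 1] <- 0.95; a[1, 3] <- a[3, 1] <- 0.85
  a[2, 3] <- a[3, 2] <- NA
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  g <- threshold_graph(a, 0.9)
  expect_equal(igraph::ecount(g), 1L)       # only the 0.95 edge
  g2 <- threshold_graph(a, 0.96)
  expect_equal(igraph::ecount(g2), 0L)      # t above every entry
  a2 <- a; a2[is.na(a2)] <- 0.5
  g3 <- threshold_graph(a2, 0.1)
  expect_equal(igraph::ecount(g3), 3L)      # complete graph
  expect_error(threshold_graph(a, 0), "\\(0, 1\\]")
})

test_that("node properties on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  np <- node_properties(tri)
  expect_equal(np$degree, rep(2, 3))
  expect_equal(attr(np, "graph_transitivity"), 1)
  expect_equal(np$transitivity, rep(1, 3))
  expect_equal(np$eigenvector, rep(1, 3))

  path3 <- igraph::make_graph(~ a - b - c)
  np2 <- node_properties(path3)
  expect_equal(attr(np2, "graph_transitivity"), 0)
  expect_equal(np2$degree[np2$node == "b"], 2)
  expect_gt(np2$betweenness[np2$node == "b"], 0)
  eb <- attr(np2, "edge_betweenness")
  expect_identical(nrow(eb), 2L)

  iso <- igraph::make_empty_graph(1, directed = FALSE)
  np3 <- node_properties(iso)
  expect_equal(unlist(np3[1, c("degree", "betweenness", "closeness",
                               "eigenvector", "alpha", "transitivity")]),
               rep(0, 6), ignore_attr = TRUE)
})

test_that("network-level empirical p is approximately uniform on all-null data", {
  # repeated all-null experiments: the one-sided full-matrix-correlation
  # p-value should be close to Uniform(0,1)
  ps <- sapply(1:24, function(i) {
    syn <- generate_paired_dataset(synthetic_config(
      n_genes = 60, frac_coupled = 0, frac_uncoupled = 0, frac_null = 1,
      frac_motif_genes = 0, seed = 1000 + i))
    ec <- ec_analysis(syn$x_tr, syn$x_tl, syn$map, "common",
                      pipeline_config(n_boot = 80, seed = 2000 + i))
    attr(ec, "fmc_p_lower")
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("per-gene EC Z-scores on all-null data are centred", {
  # the promoter-subset bootstrap varies subsets conditional on the realized
  # data, so a gene's own noise realization is shared across its null draws:
  # per-gene EC Z-scores are centred but can be over-dispersed relative to
  # standard normal (the same effect that yields very large rewired-gene
  # counts on real data), so no nominal tail rate is asserted here
  syn <- generate_paired_dataset(synthetic_config(
    n_genes = 600, frac_coupled = 0, frac_uncoupled = 0, frac_null = 1,
    frac_motif_genes = 0, seed = 51))
  cfg <- pipeline_config(n_boot = 150, seed = 52)
  ec <- ec_analysis(syn$x_tr, syn$x_tl, syn$map, "common", cfg)
  expect_lt(abs(mean(ec$zscore, na.rm = TRUE)), 0.3)
  rate <- mean(ec$ec_class %in% c("rewired", "conserved"))
  expect_lte(rate, 0.5)    # far from wholesale misclassification
})
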