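test_that("one-way ANOVA matches hand sums of squares and the stats oracle", {
  # identical groups: no between-group variance
  r0 <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # SSB = 13.5, MSW = 1, df = (1, 4)
  r1 <- oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r1$F, 13.5, tolerance = 1e-12)
  expect_equal(r1$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # all values identical: degenerate
  expect_true(is.na(oneway_anova(list(c(2, 2), c(2, 2)))$F))

  # independent oracle: stats::oneway.test with pooled variance
  set.seed(5)
  for (i in 1:25) {
    g <- random_groups(sample(2:5, 1), sample(2:4, 1))
    y <- unlist(g); f <- factor(rep(seq_along(g), lengths(g)))
    ours <- oneway_anova(g)
    ref <- oneway.test(y ~ f, var.equal = TRUE)
    expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("ANOVA F is shift-invariant and scale-stable", {
  set.seed(6)
  g <- random_groups(4, 3)
  f0 <- oneway_anova(g)$F
  expect_equal(oneway_anova(lapply(g, `+`, 100))$F, f0, tolerance = 1e-9)
  expect_equal(oneway_anova(lapply(g, `*`, 7))$F, f0, tolerance = 1e-9)
})

test_that("vectorized per-gene ANOVA equals the scalar version", {
  set.seed(7)
  x <- matrix(rnorm(20 * 9), 20, 9)
  f <- rep(c("a", "b", "c"), each = 3)
  v <- coupletrans:::anova_by_group(x, f)
  for (i in c(1, 7, 20)) {
    s <- oneway_anova(split(x[i, ], f))
    expect_equal(v$F[i], s$F, tolerance = 1e-9)
    expect_equal(v$p[i], s$p, tolerance = 1e-9)
  }
})

test_that("BH adjustment: worked examples and Bonferroni superset property", {
  r1 <- bh_fdr(0.04, 0.05)
  expect_equal(r1$p_adj, 0.04)
  expect_true(r1$reject)
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(r2$p_adj, rep(0.04, 4))
  expect_true(all(r2$reject))
  r3 <- bh_fdr(numeric(0), 0.05)
  expect_length(r3$p_adj, 0)
  expect_error(bh_fdr(c(0.1, 1.4)), "\\[0, 1\\]")
  # BH rejections contain Bonferroni rejections at the same level
  set.seed(8)
  for (i in 1:10) {
    p <- runif(30)^2
    bh <- bh_fdr(p, 0.05)$reject
    bonf <- p.adjust(p, "bonferroni") < 0.05
    expect_true(all(!bonf | bh))
    expect_true(all(bh_fdr(p, 0.05)$p_adj >= p))
  }
})

test_that("Tukey HSD agrees with the reference implementation on random balanced designs", {
  set.seed(9)
  for (i in 1:100) {
    g <- random_groups(sample(3:5, 1), sample(3:5, 1))
    ours <- tukey_hsd(g, 0.05)
    y <- unlist(g); f <- factor(rep(seq_along(g), lengths(g)))
    ref <- TukeyHSD(aov(y ~ f))$f
    lab <- paste(ours$j, ours$i, sep = "-")
    expect_equal(ours$p, unname(ref[lab, "p adj"]), tolerance = 1e-8)
    expect_equal(ours$difference, unname(ref[lab, "diff"]), tolerance = 1e-10)
  }
})

test_that("Tukey HSD toy cases and the two-group studentized-range identity", {
  # identical groups: nothing significant
  t0 <- tukey_hsd(list(c(1, 2, 3), c(1, 2, 3)), 0.05)
  expect_false(any(t0$significant))
  # far-apart group 1, close groups 2 and 3
  t1 <- tukey_hsd(list(c(0, 0.1, -0.1), c(10, 10.1, 9.9),
                       c(10.05, 9.95, 10)), 0.05)
  sig <- t1$significant
  names(sig) <- paste(t1$i, t1$j)
  expect_true(sig[["1 2"]] && sig[["1 3"]])
  expect_false(sig[["2 3"]])
  # k = 2: q = t * sqrt(2), so Tukey p equals the pooled two-sample t-test p
  set.seed(10)
  g <- random_groups(2, 5)
  t2 <- tukey_hsd(g, 0.05)
  tt <- t.test(g[[2]], g[[1]], var.equal = TRUE)
  expect_equal(t2$p, tt$p.value, tolerance = 1e-8)
  # degenerate variance: flagged, equal means never significant
  t3 <- tukey_hsd(list(c(1, 1), c(1, 1)), 0.05)
  expect_true(attr(t3, "degenerate"))
  expect_false(any(t3$significant))
})

test_that("Tukey significant pairs are a subset of unadjusted pairwise t-tests", {
  set.seed(11)
  for (i in 1:15) {
    g <- random_groups(4, 3, mu_sd = 1.5)
    tk <- tukey_hsd(g, 0.05)
    for (r in seq_len(nrow(tk))) {
      if (tk$significant[r]) {
        tt <- t.test(g[[tk$i[r]]], g[[tk$j[r]]], var.equal = TRUE)
        expect_lt(tt$p.value, 0.05)
      }
    }
  }
})

test_that("celltype_de flags DE genes per level and builds consistent bit vectors", {
  syn <- small_synth(150, seed = 23)
  cfg <- pipeline_config(seed = 24)
  de <- celltype_de(syn$x_tr, syn$x_tl, syn$map, "identical", cfg)
  a <- de$anova$transcriptome
  expect_identical(a$de_flag, !is.na(a$p_adj) & a$p_adj < cfg$fdr_q)
  expect_true(all(a$p_adj >= a$p, na.rm = TRUE))
  expect_setequal(de$de_both,
                  intersect(a$gene_id[a$de_flag],
                            de$anova$translatome$gene_id[de$anova$translatome$de_flag]))
  b <- de$diff_bits$transcriptome
  expect_identical(rownames(b), de$de_both)
  expect_identical(ncol(b), nrow(de$pair_order))
  expect_true(all(b %in% c(0L, 1L)))
  sv <- similarity_vectors(de)
  expect_identical(nrow(sv), 2L * length(de$de_both))
  expect_true(all(nchar(sv$diff_bits) == nrow(de$pair_order)))
})

test_that("planted one-deviant-cell-type genes recover their exact bit pattern", {
  # strong shift, low noise; identical scenario (4 cell types, 6 pairs)
  syn <- generate_paired_dataset(synthetic_config(
    n_genes = 300, frac_coupled = 0, frac_uncoupled = 0, frac_null = 1,
    frac_motif_genes = 0.5, motif_shift = 2, noise_sd_tr = 0.1,
    noise_sd_tl = 0.1, seed = 25))
  cfg <- pipeline_config(seed = 26)
  de <- celltype_de(syn$x_tr, syn$x_tl, syn$map, "identical", cfg)
  cl <- syn$truth$classes
  cts <- de$cell_types
  motif_genes <- cl$gene_id[!is.na(cl$deviant_cell_type) &
                              cl$deviant_cell_type %in% cts]
  expect_gt(length(motif_genes), 50)
  recovered <- de$de_both
  expect_gt(mean(motif_genes %in% recovered), 0.95)
  hits <- 0L; tot <- 0L
  for (gn in intersect(motif_genes, recovered)) {
    dev <- cl$deviant_cell_type[cl$gene_id == gn]
    planted <- as.integer(cts[de$pair_order[, 1]] == dev |
                            cts[de$pair_order[, 2]] == dev)
    for (lv in c("transcriptome", "translatome")) {
      tot <- tot + 1L
      if (all(de$diff_bits[[lv]][gn, ] == planted)) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.95)
})
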