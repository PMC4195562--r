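test_that("pair ordering is canonical lexicographic", {
  p4 <- pair_ordering(4)
  expect_identical(nrow(p4), 6L)
  expect_equal(unname(p4),
               cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4)),
               ignore_attr = TRUE)
  expect_identical(nrow(pair_ordering(2)), 1L)
  expect_identical(nrow(pair_ordering(5)), 10L)
  expect_error(pair_ordering(1), ">= 2")
})

test_that("motif space size is 2^(n(n-1)/2)", {
  expect_equal(motif_count_space(4), 64)
  expect_equal(motif_count_space(2), 2)
  expect_equal(motif_count_space(5), 1024)
})

test_that("positional encoding of similarity bits", {
  # all differences -> no edges -> id 0
  expect_equal(encode_motif(rep(1, 6)), 0)
  # no differences -> complete similarity graph -> 2^6 - 1
  expect_equal(encode_motif(rep(0, 6)), 63)
  # node 1 isolated, nodes 2-4 a clique: s = (0,0,0,1,1,1) -> 2^3+2^4+2^5
  expect_equal(encode_motif(c(1, 1, 1, 0, 0, 0)), 56)
  expect_error(encode_motif(c(0, 2, 1)), "0/1")
})

test_that("encode and decode are mutually inverse over the full n=4 space", {
  for (id in 0:63) {
    s <- decode_motif(id, 4)
    expect_equal(encode_motif(1 - s), id)
  }
  expect_error(decode_motif(64, 4), "out of range")
  expect_error(decode_motif(-1, 4), "out of range")
})

test_that("motif structure decodes components and the isolate-plus-clique shape", {
  s0 <- motif_structure(0, 4)
  expect_length(s0$isolated, 4L)
  expect_false(s0$is_clique_plus_isolate)
  s63 <- motif_structure(63, 4)
  expect_length(s63$components, 1L)
  expect_false(s63$is_clique_plus_isolate)
  s56 <- motif_structure(56, 4)
  expect_identical(s56$isolated, 1L)
  expect_true(s56$is_clique_plus_isolate)
  expect_length(s56$components, 2L)
  # exhaustive: flag true exactly for the n motifs with one isolate + clique
  flags <- vapply(0:63, function(i) motif_structure(i, 4)$is_clique_plus_isolate, TRUE)
  expect_equal(sum(flags), 4)
})

test_that("pipeline counts equal a brute-force tally on random vectors", {
  set.seed(12)
  bits <- matrix(rbinom(500 * 6, 1, 0.5), 500, 6)
  counts <- coupletrans:::count_motifs(bits, 6)
  brute <- sapply(0:63, function(id) {
    s <- decode_motif(id, 4)
    sum(apply(bits, 1, function(b) all((1 - b) == s)))
  })
  expect_equal(unname(counts), brute)
  expect_equal(sum(counts), 500)
})

test_that("permutation test: forced identity case and conservation laws", {
  cfg <- pipeline_config(n_perm = 50, seed = 13)
  # all-zero vectors: shuffling is the identity, so p = 1 for the occupied motif
  bits <- matrix(0L, 5, 6)
  mt <- permutation_motif_test(bits, 4, cfg)
  expect_equal(mt$empirical_p[mt$motif_id == 63], 1)
  expect_equal(mt$observed_count[mt$motif_id == 63], 5L)
  expect_equal(sum(mt$observed_count), 5L)
  expect_equal(mt$null_sd[mt$motif_id == 63], 0)
  # occurrence counts always sum to the gene count
  set.seed(14)
  bits2 <- matrix(rbinom(40 * 6, 1, 0.4), 40, 6)
  mt2 <- permutation_motif_test(bits2, 4, cfg)
  expect_equal(sum(mt2$observed_count), 40L)
  expect_true(all(mt2$empirical_p > 0 & mt2$empirical_p <= 1))
  # determinism
  mt3 <- permutation_motif_test(bits2, 4, cfg)
  expect_identical(as.data.frame(mt2), as.data.frame(mt3))
})

test_that("within-gene shuffling preserves each gene's number of significant pairs", {
  set.seed(15)
  bits <- matrix(rbinom(10 * 6, 1, 0.5), 10, 6)
  ones <- rowSums(bits)
  # a permuted dataset reachable by the test's shuffle keeps row sums:
  # verify via the null count of the motif determined by each gene's bits --
  # any permutation of a row with c ones encodes a motif with m - c edges
  mt <- permutation_motif_test(bits, 4, pipeline_config(n_perm = 30, seed = 16))
  edges_per_motif <- vapply(mt$motif_id, function(i) sum(decode_motif(i, 4)), 0)
  occupied <- mt$observed_count > 0
  # observed motifs' edge counts match 6 - (row one-counts) as a multiset
  expect_equal(sort(rep(edges_per_motif[occupied], mt$observed_count[occupied])),
               sort(6 - ones))
})

test_that("empirical p matches exhaustive enumeration on a tiny case", {
  # 3 genes, n = 3 cell types, m = 3 bits; enumerate all 6^3 shuffle triples
  bits <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0))
  allperm <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  combos <- expand.grid(p1 = 1:6, p2 = 1:6, p3 = 1:6)
  exact_counts <- matrix(0, nrow(combos), 8)  # motif ids 0..7
  for (r in seq_len(nrow(combos))) {
    ids <- vapply(1:3, function(g)
      encode_motif(bits[g, allperm[[combos[r, g]]]]), 0)
    exact_counts[r, ] <- tabulate(ids + 1, nbins = 8)
  }
  cfg <- pipeline_config(n_perm = 2000, seed = 17)
  mt <- permutation_motif_test(bits, 3, cfg)
  for (row in seq_len(nrow(mt))) {
    id <- mt$motif_id[row]
    obs <- mt$observed_count[row]
    p_exact <- mean(exact_counts[, id + 1] >= obs)
    se <- sqrt(p_exact * (1 - p_exact) / cfg$n_perm)
    expect_lt(abs(mt$empirical_p[row] - p_exact), 2 * se + 2 / cfg$n_perm)
  }
})
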