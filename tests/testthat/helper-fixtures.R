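# Shared fixtures, built in code at test time.

# Minimal two-level design: 2 promoters per level, one cell type each,
# explicit values so aggregation results can be hand-checked.
tiny_map <- function() {
  data.frame(
    sample_id = c("tr.P1.r1", "tr.P1.r2", "tr.P2.r1", "tr.P2.r2",
                  "tl.P1.r1", "tl.P1.r2", "tl.P2.r1", "tl.P2.r2"),
    level = rep(c("transcriptome", "translatome"), each = 4),
    promoter = rep(c("P1", "P1", "P2", "P2"), 2),
    cell_type = rep(c("CTa", "CTa", "CTb", "CTb"), 2),
    replicate = rep(c(1L, 2L), 4),
    stringsAsFactors = FALSE)
}

tiny_matrix <- function(genes, samples, values) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# A small paired synthetic dataset reused by several files.
small_synth <- function(n_genes = 120, seed = 7, ...) {
  generate_paired_dataset(synthetic_config(n_genes = n_genes, seed = seed, ...))
}

# Random balanced groups for post-hoc comparisons.
random_groups <- function(g, n_per, mu_sd = 1, noise_sd = 1) {
  mu <- rnorm(g, 0, mu_sd)
  lapply(seq_len(g), function(i) mu[i] + rnorm(n_per, 0, noise_sd))
}
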