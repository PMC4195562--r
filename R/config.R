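#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the analysis stages. Defaults follow
#' the published protocol: 1000 bootstrap datasets, 1000 permutations,
#' two-sided 5% normal critical value 1.96, relevance-network edge
#' threshold t = 0.9, and 5% significance for ANOVA, Tukey HSD and FDR.
#'
#' @param n_boot bootstrap iterations for the PCC/EC null distributions.
#' @param n_perm permutations for the motif occurrence test.
#' @param z_crit Z-score threshold for coupled/uncoupled and
#'   conserved/rewired calls.
#' @param t_edge PCC threshold for unweighted relevance networks, in (0, 1].
#' @param alpha pairwise significance level (Tukey HSD, motif test).
#' @param fdr_q Benjamini-Hochberg FDR level for the per-gene ANOVA.
#' @param seed integer seed for all stochastic stages.
#' @param classify_scale scale on which coupling Z-scores are formed:
#'   `"fisher"` (atanh-transformed PCC, the default) or `"raw"`.
#' @param boot_unit bootstrap sampling unit: `"cell_type"` draws as many
#'   promoters as there are cell types (4 identical / 5 common);
#'   `"promoter"` draws as many promoters as the scenario uses (8 for
#'   common), mirroring the alternative reading of the protocol.
#' @param alpha_centrality_factor alpha-centrality damping as a fraction of
#'   the convergence bound 1/lambda_max.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_boot = 1000L, n_perm = 1000L, z_crit = 1.96,
                            t_edge = 0.9, alpha = 0.05, fdr_q = 0.05,
                            seed = 1L,
                            classify_scale = c("fisher", "raw"),
                            boot_unit = c("cell_type", "promoter"),
                            alpha_centrality_factor = 0.5) {
  classify_scale <- match.arg(classify_scale)
  boot_unit <- match.arg(boot_unit)
  stopifnot(n_boot >= 2, n_perm >= 2, z_crit > 0,
            t_edge > 0, t_edge <= 1,
            alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1,
            alpha_centrality_factor > 0, alpha_centrality_factor < 1)
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 z_crit = z_crit, t_edge = t_edge, alpha = alpha,
                 fdr_q = fdr_q, seed = as.integer(seed),
                 classify_scale = classify_scale, boot_unit = boot_unit,
                 alpha_centrality_factor = alpha_centrality_factor),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
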