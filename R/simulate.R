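## Synthetic paired transcriptome/translatome generator with planted ground
## truth: coupling classes, one-deviant-cell-type (motif) genes, and
## annotation terms enriched in the coupled set.

#' Synthetic dataset configuration
#'
#' Describes a paired cell-type expression study to simulate. The defaults
#' emulate the real study design: 5 cell types shared by both system
#' levels, of which 4 are covered by promoter sets with identical labels in
#' both levels (the fifth is targeted by level-specific promoters, so the
#' `"identical"` scenario has 4 cell types and `"common"` has 5); two
#' promoters per cell type per level (pools of 10 promoters per level);
#' 2-3 replicates per promoter; log2-scale intensities with a gene baseline
#' ~ Uniform(4, 12); and a translatome replicate noise below the
#' transcriptome one, reproducing the direction of the lower translatome
#' variability seen in the real data.
#'
#' Gene classes: `coupled` genes carry one cell-type effect vector (entries
#' ~ Normal(0, `effect_sd`^2)) applied to both levels; `uncoupled` genes
#' get the sign-flipped vector on the translatome (an anti-correlated mode;
#' `uncoupled_mode = "independent"` plants an independent vector instead);
#' `null` genes have zero effects. Motif genes are drawn from the null
#' class and receive a `motif_shift` on exactly one (deviant) cell type on
#' both levels, so their planted cell-type similarity pattern is one
#' isolated node plus a clique.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_cell_types number of cell types shared by the levels (>= 3).
#' @param promoters_per_cell_type promoters targeting each cell type in
#'   each level (>= 1).
#' @param replicates integer range (min, max) of replicates per promoter.
#' @param frac_coupled,frac_uncoupled,frac_null class proportions; must sum
#'   to 1 (largest-remainder rounding fixes the integer counts).
#' @param effect_sd standard deviation of cell-type effects (log2 units).
#' @param noise_sd_tr,noise_sd_tl replicate noise sd per level (log2 units).
#' @param frac_motif_genes proportion of genes (taken from the null class)
#'   with exactly one deviant cell type.
#' @param motif_shift log2 shift applied to the deviant cell type.
#' @param baseline_range range of the uniform per-gene baseline (log2).
#' @param uncoupled_mode `"sign_flip"` (default) or `"independent"`.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L, n_cell_types = 5L,
                             promoters_per_cell_type = 2L,
                             replicates = c(2L, 3L),
                             frac_coupled = 0.15, frac_uncoupled = 0.10,
                             frac_null = 0.75,
                             effect_sd = 1.0,
                             noise_sd_tr = 0.25, noise_sd_tl = 0.15,
                             frac_motif_genes = 0.10, motif_shift = 2.0,
                             baseline_range = c(4, 12),
                             uncoupled_mode = c("sign_flip", "independent"),
                             seed = 1L) {
  uncoupled_mode <- match.arg(uncoupled_mode)
  fr <- c(frac_coupled, frac_uncoupled, frac_null)
  if (any(fr < 0) || any(fr > 1))
    stopf("class proportions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    stopf("class proportions must sum to 1 (got %.12f)", sum(fr))
  stopifnot(n_genes >= 10, n_cell_types >= 3, promoters_per_cell_type >= 1,
            length(replicates) == 2, replicates[1] >= 1,
            replicates[2] >= replicates[1],
            effect_sd >= 0, noise_sd_tr >= 0, noise_sd_tl >= 0,
            frac_motif_genes >= 0, frac_motif_genes <= 1,
            baseline_range[2] >= baseline_range[1])
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 promoters_per_cell_type = as.integer(promoters_per_cell_type),
                 replicates = as.integer(replicates),
                 frac_coupled = frac_coupled, frac_uncoupled = frac_uncoupled,
                 frac_null = frac_null, effect_sd = effect_sd,
                 noise_sd_tr = noise_sd_tr, noise_sd_tl = noise_sd_tl,
                 frac_motif_genes = frac_motif_genes,
                 motif_shift = motif_shift,
                 baseline_range = as.numeric(baseline_range),
                 uncoupled_mode = uncoupled_mode,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Largest-remainder apportionment of n into integer counts with the given
## proportions; ties broken by position order. Deterministic.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    rem <- exact - base
    ord <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a paired synthetic dataset with planted truth
#'
#' Simulates transcriptome and translatome expression matrices plus the
#' sample map and the planted ground truth, per the design described in
#' [synthetic_config()]. Each replicate sample equals
#' `baseline + cell-type effect + Normal(0, noise_sd^2)`.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `x_tr`, `x_tl`
#'   (expression matrices), `map` (sample map), and `truth` — a list with
#'   the per-gene `classes` data.frame (`gene_id`, `coupling_class`,
#'   `deviant_cell_type`), the per-level true effect matrices
#'   `effects_tr` / `effects_tl`, `cell_types`, and `config`.
#' @export
generate_paired_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    n_ct <- cfg$n_cell_types
    cts <- sprintf("CT%d", seq_len(n_ct))
    genes <- sprintf("G%05d", seq_len(G))

    counts <- largest_remainder(G, c(cfg$frac_coupled, cfg$frac_uncoupled,
                                     cfg$frac_null))
    classes <- rep(c("coupled", "uncoupled", "null"), counts)
    n_motif <- largest_remainder(G, c(cfg$frac_motif_genes,
                                      1 - cfg$frac_motif_genes))[1]
    if (n_motif > counts[3])
      stopf("frac_motif_genes (%d genes) exceeds the null class (%d genes)",
            n_motif, counts[3])
    # motif genes: last n_motif genes of the (contiguous) null block
    motif_idx <- if (n_motif > 0) seq.int(G - n_motif + 1L, G) else integer(0)
    deviant <- rep(NA_character_, G)
    if (n_motif > 0)
      deviant[motif_idx] <- cts[1 + (seq_len(n_motif) - 1L) %% n_ct]

    baseline <- stats::runif(G, cfg$baseline_range[1], cfg$baseline_range[2])
    eff_tr <- matrix(0, G, n_ct, dimnames = list(genes, cts))
    eff_tl <- eff_tr
    is_cp <- classes == "coupled"
    is_uc <- classes == "uncoupled"
    if (any(is_cp)) {
      e <- matrix(stats::rnorm(sum(is_cp) * n_ct, 0, cfg$effect_sd),
                  sum(is_cp), n_ct)
      eff_tr[is_cp, ] <- e
      eff_tl[is_cp, ] <- e
    }
    if (any(is_uc)) {
      e <- matrix(stats::rnorm(sum(is_uc) * n_ct, 0, cfg$effect_sd),
                  sum(is_uc), n_ct)
      eff_tr[is_uc, ] <- e
      eff_tl[is_uc, ] <- if (cfg$uncoupled_mode == "sign_flip") -e else
        matrix(stats::rnorm(sum(is_uc) * n_ct, 0, cfg$effect_sd), sum(is_uc), n_ct)
    }
    for (i in motif_idx) {
      eff_tr[i, deviant[i]] <- eff_tr[i, deviant[i]] + cfg$motif_shift
      eff_tl[i, deviant[i]] <- eff_tl[i, deviant[i]] + cfg$motif_shift
    }

    ## promoter design: promoter j of cell type c; the first promoter of
    ## every cell type but the last is shared ("identical") across levels
    prom_tab <- function(level) {
      pre <- if (level == "transcriptome") "tr" else "tl"
      rows <- list()
      for (c in seq_len(n_ct)) for (j in seq_len(cfg$promoters_per_cell_type)) {
        shared <- (j == 1L && c < n_ct)
        prom <- if (shared) sprintf("P%d", c) else sprintf("%sP.%s.%d", pre, cts[c], j)
        rows[[length(rows) + 1L]] <- data.frame(promoter = prom,
                                                cell_type = cts[c],
                                                stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }

    sim_level <- function(level, eff, noise_sd) {
      pre <- if (level == "transcriptome") "tr" else "tl"
      pt <- prom_tab(level)
      nrep <- if (cfg$replicates[1] == cfg$replicates[2])
        rep(cfg$replicates[1], nrow(pt)) else
        sample(seq.int(cfg$replicates[1], cfg$replicates[2]), nrow(pt), replace = TRUE)
      maps <- list(); cols <- list()
      for (p in seq_len(nrow(pt))) {
        for (r in seq_len(nrep[p])) {
          sid <- sprintf("%s.%s.r%d", pre, pt$promoter[p], r)
          maps[[length(maps) + 1L]] <- data.frame(
            sample_id = sid, level = level, promoter = pt$promoter[p],
            cell_type = pt$cell_type[p], replicate = r,
            stringsAsFactors = FALSE)
          cols[[length(cols) + 1L]] <-
            baseline + eff[, pt$cell_type[p]] + stats::rnorm(G, 0, noise_sd)
        }
      }
      x <- do.call(cbind, cols)
      dimnames(x) <- list(genes, vapply(maps, `[[`, "", "sample_id"))
      list(x = x, map = do.call(rbind, maps))
    }

    tr <- sim_level("transcriptome", eff_tr, cfg$noise_sd_tr)
    tl <- sim_level("translatome", eff_tl, cfg$noise_sd_tl)

    truth <- list(classes = data.frame(gene_id = genes,
                                       coupling_class = classes,
                                       deviant_cell_type = deviant,
                                       stringsAsFactors = FALSE),
                  effects_tr = eff_tr, effects_tl = eff_tl,
                  cell_types = cts, config = cfg)
    structure(list(x_tr = tr$x, x_tl = tl$x,
                   map = rbind(tr$map, tl$map), truth = truth),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic paired dataset\n")
  cat("  genes:", nrow(x$x_tr),
      "| transcriptome samples:", ncol(x$x_tr),
      "| translatome samples:", ncol(x$x_tl), "\n")
  print(table(x$truth$classes$coupling_class))
  invisible(x)
}

#' Generate a gene-to-term annotation table with one planted term
#'
#' Annotates every gene with each of `n_terms` background terms
#' independently with probability `background_prob`, and adds one planted
#' term (`T_planted`) that annotates genes of the coupled class with
#' probability `planted_prob`. Used as the fixture for the hypergeometric
#' overrepresentation test.
#'
#' @param truth `truth` element of a [generate_paired_dataset()] result.
#' @param n_terms number of background terms.
#' @param background_prob,planted_prob annotation probabilities with
#'   `0 <= background_prob < planted_prob <= 1`.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `term_id`; attribute
#'   `planted_term` names the planted term.
#' @export
generate_annotation <- function(truth, n_terms = 50L, background_prob = 0.05,
                                planted_prob = 0.9, seed = 1L) {
  if (background_prob < 0 || background_prob > 1 ||
      planted_prob < 0 || planted_prob > 1)
    stopf("annotation probabilities must lie in [0, 1]")
  if (background_prob >= planted_prob)
    stopf("background_prob must be below planted_prob")
  genes <- truth$classes$gene_id
  coupled <- genes[truth$classes$coupling_class == "coupled"]
  with_seed(seed, {
    rows <- list()
    if (n_terms > 0) {
      terms <- sprintf("T%03d", seq_len(n_terms))
      for (t in terms) {
        hit <- genes[stats::runif(length(genes)) < background_prob]
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(gene_id = hit, term_id = t,
                                                  stringsAsFactors = FALSE)
      }
    }
    if (length(coupled)) {
      hit <- coupled[stats::runif(length(coupled)) < planted_prob]
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(gene_id = hit,
                                                term_id = "T_planted",
                                                stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(0), term_id = character(0),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "planted_term") <- "T_planted"
    out
  })
}
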