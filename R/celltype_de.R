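## Per-gene one-way ANOVA across cell types (per system level), BH-FDR
## selection, Tukey HSD pairwise calls, and binary similarity vectors.

#' One-way fixed-effects ANOVA
#'
#' Classic one-way ANOVA of a list of replicate-value groups:
#' `F = (SSB/(g-1)) / (SSW/(N-g))` with an upper-tail p-value from the F
#' distribution. When both between- and within-group variance are zero
#' the gene is degenerate: `F` and `p` are `NA`.
#'
#' @param groups list of >= 2 numeric vectors (replicate values per cell
#'   type); single-value groups are allowed while total df permit.
#' @return list with `F`, `p`, `df1`, `df2`, `ms_within`, `group_means`,
#'   `group_n`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 1)) stopf("empty group")
  N <- sum(n); g <- length(groups)
  if (N - g < 1) stopf("no residual degrees of freedom (N = %d, groups = %d)", N, g)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i) sum((groups[[i]] - means[i])^2), 0))
  if (ssb == 0 && ssw == 0)
    return(list(F = NA_real_, p = NA_real_, df1 = g - 1L, df2 = N - g,
                ms_within = 0, group_means = means, group_n = n))
  msb <- ssb / (g - 1); msw <- ssw / (N - g)
  f <- if (msw == 0) Inf else msb / msw
  p <- if (is.infinite(f)) 0 else stats::pf(f, g - 1, N - g, lower.tail = FALSE)
  list(F = f, p = p, df1 = g - 1L, df2 = N - g, ms_within = msw,
       group_means = means, group_n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (via `stats::p.adjust`) with rejection at
#' adjusted p < `q`. P-values outside `[0, 1]` are a hard error.
#'
#' @param pvalues numeric vector of p-values (NA allowed, passed through).
#' @param q FDR level.
#' @return list with `p_adj` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adj = p_adj, reject = !is.na(p_adj) & p_adj < q)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise p-values with pooled within-group variance;
#' unequal group sizes are handled by the Tukey-Kramer correction
#' `SE = sqrt(MSW/2 * (1/n_i + 1/n_j))`. Pairs are emitted in canonical
#' lexicographic order (see [pair_ordering()]); `difference` is
#' `mean_j - mean_i`. Degenerate pooled variance (MSW = 0 with equal
#' means, or no residual df) marks all pairs non-significant with a
#' `degenerate` flag.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param alpha pairwise significance level.
#' @return data.frame: `i`, `j`, `difference`, `p`, `significant`;
#'   attribute `degenerate`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 2) stopf("need >= 2 groups")
  an <- oneway_anova(groups)
  pairs <- pair_ordering(g)
  msw <- an$ms_within; df2 <- an$df2
  degenerate <- (msw == 0)
  res <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    difference = an$group_means[pairs[, 2]] -
                      an$group_means[pairs[, 1]],
                    p = NA_real_, significant = FALSE)
  if (!degenerate) {
    se <- sqrt(msw / 2 * (1 / an$group_n[res$i] + 1 / an$group_n[res$j]))
    q <- abs(res$difference) / se
    res$p <- stats::ptukey(q, nmeans = g, df = df2, lower.tail = FALSE)
    res$significant <- res$p < alpha
  } else {
    # zero pooled variance: differences are exact; any nonzero difference
    # is infinitely significant, equal means are not
    res$p <- ifelse(res$difference != 0, 0, 1)
    res$significant <- res$difference != 0
    degenerate <- all(res$difference == 0)
  }
  attr(res, "degenerate") <- degenerate
  res
}

## Vectorized per-gene one-way ANOVA: x is genes x samples, f the grouping
## factor over columns. Equivalent to oneway_anova row by row (tested).
anova_by_group <- function(x, f) {
  f <- factor(f)
  g <- nlevels(f); N <- ncol(x)
  ind <- stats::model.matrix(~ 0 + f)
  n <- colSums(ind)
  gm <- (x %*% ind) %*% diag(1 / n, g)
  grand <- rowMeans(x)
  ssb <- as.vector(((gm - grand)^2) %*% n)
  tot <- rowSums((x - grand)^2)
  ssw <- pmax(tot - ssb, 0)
  msb <- ssb / (g - 1); msw <- ssw / (N - g)
  fstat <- ifelse(msw == 0 & msb == 0, NA_real_,
                  ifelse(msw == 0, Inf, msb / msw))
  p <- ifelse(is.na(fstat), NA_real_,
              ifelse(is.infinite(fstat), 0,
                     stats::pf(fstat, g - 1, N - g, lower.tail = FALSE)))
  list(F = fstat, p = p, df1 = g - 1L, df2 = N - g, msw = msw,
       group_means = gm, group_n = n, levels = levels(f))
}

#' Per-gene differential expression across cell types
#'
#' For each system level: one-way ANOVA of every gene's replicate values
#' grouped by cell type (all promoters of a cell type pooled), BH-FDR
#' across genes at `cfg$fdr_q`, then Tukey HSD (at `cfg$alpha`) for the
#' ANOVA-significant genes. Genes differentially expressed on *both*
#' levels get binary similarity vectors: bit = 1 for a significant
#' pairwise cell-type difference, in canonical pair order.
#'
#' @inheritParams coupling_analysis
#' @param group_by grouping factor for the ANOVA: `"cell_type"` (default)
#'   or `"promoter"`.
#' @return object of class `de_result`: list with per-level `anova`
#'   data.frames (`gene_id`, `F`, `p`, `p_adj`, `de_flag`), `de_both`
#'   (gene ids DE on both levels), per-level `diff_bits` binary matrices
#'   (genes x pairs) for those genes, `cell_types`, `pair_order`, `config`.
#' @export
celltype_de <- function(x_tr, x_tl, map, scenario = c("common", "identical"),
                        cfg = pipeline_config(),
                        group_by = c("cell_type", "promoter")) {
  scenario <- match.arg(scenario)
  group_by <- match.arg(group_by)
  validate_sample_map(map)
  genes <- intersect(rownames(x_tr), rownames(x_tl))
  if (!length(genes)) stopf("no genes shared between the two matrices")

  level_data <- function(x, level) {
    m <- map_for_level(map, level)
    m <- m[m$sample_id %in% colnames(x), , drop = FALSE]
    if (identical(scenario, "identical")) {
      mtr <- map_for_level(map, "transcriptome")
      mtl <- map_for_level(map, "translatome")
      shared <- intersect(unique(mtr$promoter), unique(mtl$promoter))
      m <- m[m$promoter %in% shared, , drop = FALSE]
    }
    list(x = x[genes, m$sample_id, drop = FALSE],
         f = m[[if (group_by == "cell_type") "cell_type" else "promoter"]])
  }
  dtr <- level_data(x_tr, "transcriptome")
  dtl <- level_data(x_tl, "translatome")
  cts <- sort(intersect(unique(dtr$f), unique(dtl$f)))
  dtr$keep <- dtr$f %in% cts; dtl$keep <- dtl$f %in% cts
  dtr$x <- dtr$x[, dtr$keep, drop = FALSE]; dtr$f <- dtr$f[dtr$keep]
  dtl$x <- dtl$x[, dtl$keep, drop = FALSE]; dtl$f <- dtl$f[dtl$keep]
  if (length(cts) < 2) stopf("need >= 2 shared cell types")

  run_level <- function(d) {
    a <- anova_by_group(d$x, factor(d$f, levels = cts))
    adj <- bh_fdr(a$p, cfg$fdr_q)
    data.frame(gene_id = genes, F = a$F, p = a$p, p_adj = adj$p_adj,
               de_flag = adj$reject, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  an_tr <- run_level(dtr)
  an_tl <- run_level(dtl)
  de_both <- genes[an_tr$de_flag & an_tl$de_flag]

  pairs <- pair_ordering(length(cts))
  bits_level <- function(d, de_genes) {
    out <- matrix(0L, length(de_genes), nrow(pairs),
                  dimnames = list(de_genes,
                                  paste(cts[pairs[, 1]], cts[pairs[, 2]], sep = "|")))
    fl <- factor(d$f, levels = cts)
    for (gn in de_genes) {
      tk <- tukey_hsd(split(d$x[gn, ], fl), cfg$alpha)
      out[gn, ] <- as.integer(tk$significant)
    }
    out
  }
  structure(list(anova = list(transcriptome = an_tr, translatome = an_tl),
                 de_both = de_both,
                 diff_bits = list(transcriptome = bits_level(dtr, de_both),
                                  translatome = bits_level(dtl, de_both)),
                 cell_types = cts, pair_order = pairs,
                 scenario = scenario, config = cfg),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  n_tr <- sum(x$anova$transcriptome$de_flag, na.rm = TRUE)
  n_tl <- sum(x$anova$translatome$de_flag, na.rm = TRUE)
  cat("Cell-type differential expression (", x$scenario, " scenario, ",
      length(x$cell_types), " cell types)\n", sep = "")
  cat("  DE genes: transcriptome ", n_tr, ", translatome ", n_tl,
      ", intersection ", length(x$de_both), "\n", sep = "")
  invisible(x)
}

#' Extract similarity vectors from a DE result
#'
#' Per-gene, per-level binary pairwise-difference patterns for the genes
#' differentially expressed on both levels, as a compact data.frame with
#' the 0/1 string in canonical pair order.
#'
#' @param de a [celltype_de()] result.
#' @return data.frame: `gene_id`, `level`, `diff_bits` (string).
#' @export
similarity_vectors <- function(de) {
  stopifnot(inherits(de, "de_result"))
  do.call(rbind, lapply(names(de$diff_bits), function(lv) {
    b <- de$diff_bits[[lv]]
    if (nrow(b) == 0)
      return(data.frame(gene_id = character(0), level = character(0),
                        diff_bits = character(0), stringsAsFactors = FALSE))
    data.frame(gene_id = rownames(b), level = lv,
               diff_bits = apply(b, 1, paste, collapse = ""),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
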