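## Per-gene transcriptome-translatome coupling: CV, PCC across cell types,
## Fisher transformation, promoter-subset bootstrap null, Z classification.

#' Coefficient of variation of an expression profile
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Profiles with non-positive mean are degenerate and return `NA` (such
#' genes are excluded from CV summaries).
#'
#' @param profile numeric vector, length >= 2.
#' @return non-negative scalar, or `NA` if the mean is <= 0.
#' @export
coefficient_of_variation <- function(profile) {
  if (length(profile) < 2) stopf("profile needs >= 2 values")
  m <- mean(profile)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(profile) / m
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Standard product-moment correlation. Returns `NA` (undefined) when
#' either vector has zero variance instead of warning like `stats::cor()`.
#' Lengths below 3 are tolerated with a warning; a length mismatch is a
#' hard error.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stopf("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2) stopf("need >= 2 paired values")
  if (length(x) < 3) warning("correlation on only 2 points is +/-1 by construction")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  min(max(stats::cor(x, y), -1), 1)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `atanh(r)` after clipping `|r|` to `1 - 1e-15`, so that boundary values
#' +/-1 map to large finite values rather than +/-Inf. Values outside
#' `[-1, 1]` are a hard error.
#'
#' @param r correlation value(s) in `[-1, 1]` (NA passed through).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stopf("|r| > 1: %s", paste(r[bad], collapse = ", "))
  atanh(pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15))
}

#' Bootstrap null distribution of per-gene cross-level PCC
#'
#' For each of `cfg$n_boot` iterations, `k` promoters are drawn without
#' replacement, independently for each system level, from that level's
#' full promoter pool; replicates are averaged per promoter; the two
#' k-vectors are paired in sampled order; and the per-gene PCC is
#' computed. Because each bootstrapped group mixes cell types at random,
#' variation in these PCCs reflects cell-type-specific expression rather
#' than level differences — the empirical null. Iterations where a gene's
#' PCC is undefined are dropped from that gene's null (count reported).
#'
#' @param x_tr,x_tl full expression matrices (all promoters of each level).
#' @param map sample map.
#' @param k promoters drawn per level per iteration; both pools must hold
#'   at least `k` promoters.
#' @param cfg a [pipeline_config()]; `n_boot`, `seed` and
#'   `classify_scale` are used ("fisher" takes the null moments of
#'   `atanh(PCC)`, "raw" of the PCC itself).
#' @return data.frame: `gene_id`, `null_mean`, `null_sd`, `n_null_used`.
#' @export
bootstrap_pcc_null <- function(x_tr, x_tl, map, k, cfg = pipeline_config()) {
  genes <- intersect(rownames(x_tr), rownames(x_tl))
  if (!length(genes)) stopf("no genes shared between the two matrices")
  pm_tr <- promoter_means(x_tr[genes, , drop = FALSE], map, "transcriptome")
  pm_tl <- promoter_means(x_tl[genes, , drop = FALSE], map, "translatome")
  if (ncol(pm_tr) < k || ncol(pm_tl) < k)
    stopf("promoter pool smaller than k = %d (transcriptome %d, translatome %d)",
          k, ncol(pm_tr), ncol(pm_tl))
  draws <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_boot), function(b) {
      i_tr <- sample.int(ncol(pm_tr), k)
      i_tl <- sample.int(ncol(pm_tl), k)
      rowwise_pcc(pm_tr[, i_tr, drop = FALSE], pm_tl[, i_tl, drop = FALSE])
    }, numeric(length(genes)))
  })
  if (length(genes) == 1L) draws <- matrix(draws, nrow = 1L)
  if (identical(cfg$classify_scale, "fisher")) draws <- fisher_z(draws)
  n_used <- rowSums(!is.na(draws))
  data.frame(gene_id = genes,
             null_mean = rowMeans(draws, na.rm = TRUE),
             null_sd = apply(draws, 1, stats::sd, na.rm = TRUE),
             n_null_used = n_used,
             stringsAsFactors = FALSE)
}

#' Z-score classification of an observed statistic against its null
#'
#' `zscore = (stat - null_mean) / null_sd`; class `coupled` if
#' `zscore >= z_crit`, `uncoupled` if `zscore <= -z_crit`, otherwise
#' `neutral`; `degenerate` (Z undefined) when the statistic is `NA` or the
#' null sd is zero/NA. Degenerate is a value, not an error. Vectorized.
#'
#' @param stat observed statistic (raw PCC or its Fisher transform,
#'   matching the scale of the null moments).
#' @param null_mean,null_sd bootstrap null moments on the same scale.
#' @param z_crit classification threshold (default 1.96, the two-sided 5%
#'   standard-normal critical value).
#' @return data.frame with `zscore` and `coupling_class`.
#' @export
classify_coupling <- function(stat, null_mean, null_sd, z_crit = 1.96) {
  if (any(null_sd < 0, na.rm = TRUE)) stopf("null_sd must be >= 0")
  z <- ifelse(is.na(stat) | is.na(null_sd) | null_sd == 0,
              NA_real_, (stat - null_mean) / null_sd)
  cls <- ifelse(is.na(z), "degenerate",
         ifelse(z >= z_crit, "coupled",
         ifelse(z <= -z_crit, "uncoupled", "neutral")))
  data.frame(zscore = z, coupling_class = cls, stringsAsFactors = FALSE)
}

#' Per-gene transcriptome-translatome coupling analysis
#'
#' End-to-end coupling stage: aggregates samples to paired cell-type
#' profiles, computes per-gene CV on each level, the cross-level PCC and
#' its Fisher transform, the promoter-subset bootstrap null, and the
#' Z-score classification into coupled / uncoupled / neutral / degenerate.
#'
#' By default the Z-score is formed on the Fisher-z scale
#' (`cfg$classify_scale`): the bootstrap null of the raw PCC over k
#' randomly paired promoters has variance close to 1/(k-1) for every gene,
#' which with 4-5 cell types caps raw-scale Z-scores near sqrt(k-1); the
#' variance-stabilizing transform restores a usable normal scale.
#'
#' @param x_tr,x_tl expression matrices.
#' @param map sample map.
#' @param scenario `"identical"` (4 cell types, shared promoters) or
#'   `"common"` (5 cell types, all promoters).
#' @param cfg a [pipeline_config()]. `boot_unit` sets k: `"cell_type"`
#'   draws as many promoters as cell types; `"promoter"` draws as many as
#'   the scenario's promoter count.
#' @param k override for the bootstrap subset size (default per
#'   `cfg$boot_unit`).
#' @return object of class `coupling_result`: data.frame with columns
#'   `gene_id`, `cv_tr`, `cv_tl`, `pcc`, `fisher_z`, `null_mean`,
#'   `null_sd`, `zscore`, `coupling_class`, `n_null_used`; attributes
#'   `scenario`, `k`, `cell_types`, `config`.
#' @export
coupling_analysis <- function(x_tr, x_tl, map,
                              scenario = c("common", "identical"),
                              cfg = pipeline_config(), k = NULL) {
  scenario <- match.arg(scenario)
  paired <- aggregate_to_cell_types(x_tr, x_tl, map, scenario)
  if (length(paired$cell_types) < 3)
    stopf("correlation stages need >= 3 cell types (got %d)",
          length(paired$cell_types))
  if (is.null(k)) {
    k <- if (identical(cfg$boot_unit, "cell_type")) length(paired$cell_types)
    else {
      m2 <- map[map$sample_id %in% c(colnames(x_tr), colnames(x_tl)), ]
      if (identical(scenario, "identical"))
        m2 <- m2[m2$promoter %in% intersect(
          unique(m2$promoter[m2$level == "transcriptome"]),
          unique(m2$promoter[m2$level == "translatome"])), ]
      length(unique(m2$promoter))
    }
  }
  cv_tr <- apply(paired$x_tr, 1, coefficient_of_variation)
  cv_tl <- apply(paired$x_tl, 1, coefficient_of_variation)
  pcc <- rowwise_pcc(paired$x_tr, paired$x_tl)
  fz <- fisher_z(pcc)
  nul <- bootstrap_pcc_null(x_tr[paired$gene_ids, , drop = FALSE],
                            x_tl[paired$gene_ids, , drop = FALSE],
                            map, k, cfg)
  stat <- if (identical(cfg$classify_scale, "fisher")) fz else pcc
  cl <- classify_coupling(stat, nul$null_mean, nul$null_sd, cfg$z_crit)
  out <- data.frame(gene_id = paired$gene_ids,
                    cv_tr = cv_tr, cv_tl = cv_tl,
                    pcc = pcc, fisher_z = fz,
                    null_mean = nul$null_mean, null_sd = nul$null_sd,
                    zscore = cl$zscore, coupling_class = cl$coupling_class,
                    n_null_used = nul$n_null_used,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("coupling_result", "data.frame"),
            scenario = scenario, k = k, cell_types = paired$cell_types,
            config = cfg)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Gene coupling analysis (", attr(x, "scenario"), " scenario, ",
      length(attr(x, "cell_types")), " cell types, k = ", attr(x, "k"),
      ", n_boot = ", attr(x, "config")$n_boot, ")\n", sep = "")
  print(table(x$coupling_class))
  cat("mean CV  transcriptome:", signif(mean(x$cv_tr, na.rm = TRUE), 3),
      " translatome:", signif(mean(x$cv_tl, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @export
summary.coupling_result <- function(object, ...) {
  tab <- table(object$coupling_class)
  out <- list(n_genes = nrow(object), classes = tab,
              mean_cv_tr = mean(object$cv_tr, na.rm = TRUE),
              mean_cv_tl = mean(object$cv_tl, na.rm = TRUE),
              scenario = attr(object, "scenario"))
  class(out) <- "summary.coupling_result"
  out
}

#' @export
print.summary.coupling_result <- function(x, ...) {
  cat("Coupling analysis (", x$scenario, "): ", x$n_genes, " genes\n", sep = "")
  print(x$classes)
  cat(sprintf("mean CV: transcriptome %.4f, translatome %.4f\n",
              x$mean_cv_tr, x$mean_cv_tl))
  invisible(x)
}

#' @export
plot.coupling_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::hist(x$pcc, breaks = 40, main = "Observed cross-level PCC",
                 xlab = "PCC", col = "grey80", ...)
  graphics::hist(x$zscore, breaks = 40, main = "Coupling Z-scores",
                 xlab = "Z", col = "grey80", ...)
  graphics::abline(v = c(-1, 1) * attr(x, "config")$z_crit, lty = 2)
  invisible(x)
}

#' Write a coupling result table to TSV
#' @param x a `coupling_result`.
#' @param path output path.
#' @export
write_coupling_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
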