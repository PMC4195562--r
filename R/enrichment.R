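## Hypergeometric overrepresentation of annotation terms in a study gene
## set against a population background.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' population of `N` of which `K` carry the term, the probability of
#' seeing `k` or more carriers. Computed through the log-gamma-stable
#' `stats::phyper`. Constraint violations are hard errors.
#'
#' @param k observed carriers in the study set.
#' @param K population carriers.
#' @param n study-set size.
#' @param N population size.
#' @return probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n))
    stopf("invalid hypergeometric instance: k=%s K=%s n=%s N=%s", k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term overrepresentation analysis
#'
#' One upper-tail hypergeometric test per annotation term with at least
#' one study gene, BH adjustment across the tested terms, sorted by raw
#' p-value. Study genes outside the population are a hard error naming
#' the offenders; annotation rows outside the population are dropped.
#'
#' @param study character vector of study gene ids (subset of population).
#' @param annotation data.frame with columns `gene_id`, `term_id`.
#' @param population character vector of background gene ids (default:
#'   the annotated genes' universe must be supplied explicitly by the
#'   caller — typically all genes on the input matrices).
#' @param q BH-FDR level used for the `significant` flag.
#' @return object of class `enrichment_result`: data.frame with `term_id`,
#'   `k` (study carriers), `K` (population carriers), `n` (study size),
#'   `N` (population size), `p`, `p_adj`, `significant`.
#' @export
enrich <- function(study, annotation, population, q = 0.05) {
  if (!all(c("gene_id", "term_id") %in% names(annotation)))
    stopf("annotation needs columns gene_id, term_id")
  study <- unique(study)
  population <- unique(population)
  out_of_pop <- setdiff(study, population)
  if (length(out_of_pop))
    stopf("study gene(s) outside the population: %s",
          paste(utils::head(out_of_pop, 5), collapse = ", "))
  annotation <- annotation[annotation$gene_id %in% population, , drop = FALSE]
  N <- length(population); n <- length(study)
  terms <- unique(annotation$term_id[annotation$gene_id %in% study])
  rows <- lapply(terms, function(t) {
    carriers <- unique(annotation$gene_id[annotation$term_id == t])
    K <- length(carriers)
    k <- length(intersect(carriers, study))
    data.frame(term_id = t, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), k = integer(0), K = integer(0),
               n = integer(0), N = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  adj <- bh_fdr(res$p, q)
  res$p_adj <- adj$p_adj
  res$significant <- adj$reject
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"), q = q)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Term enrichment: ", nrow(x), " terms tested (study n = ",
      if (nrow(x)) x$n[1] else 0, ", population N = ",
      if (nrow(x)) x$N[1] else 0, ")\n", sep = "")
  print(as.data.frame(utils::head(x, 10)), row.names = FALSE)
  invisible(x)
}

#' Read a gene-to-term annotation TSV
#'
#' Columns `gene_id`, `term_id`, one row per (gene, term).
#' @param path TSV path.
#' @return data.frame.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stopf("annotation TSV needs columns gene_id, term_id")
  df
}
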