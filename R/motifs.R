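## Cell-type similarity network motifs: labeled encoding of per-gene
## binary pairwise-difference patterns, occurrence counts, and permutation
## significance.

#' Canonical ordering of cell-type pairs
#'
#' Lexicographic pairs `(i, j)`, `i < j`, over cell-type indices
#' `1..n`; length `n(n-1)/2`. All pairwise stages (Tukey bits, motif
#' encoding) share this order.
#'
#' @param n number of cell types (>= 2).
#' @return integer matrix with columns `i`, `j`.
#' @export
pair_ordering <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stopf("need n >= 2 cell types")
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  rownames(m) <- NULL
  m
}

#' Size of the motif space
#'
#' `2^(n(n-1)/2)` labeled similarity-network topologies on `n` cell types
#' (64 for n = 4).
#'
#' @param n number of cell types (>= 2).
#' @return integer count (numeric for large n).
#' @export
motif_count_space <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stopf("need n >= 2 cell types")
  2^(n * (n - 1) / 2)
}

#' Encode a binary difference vector as a motif id
#'
#' The similarity bits are `s = 1 - diff_bits` (an edge means *no*
#' significant difference); the id is `sum(s[p] * 2^p)` with position 0
#' the first pair in canonical order. Labeled encoding — no isomorphism
#' collapsing, so the same shape on different cell types gets different
#' ids. All-different patterns encode to 0; all-similar to `2^m - 1`.
#'
#' @param diff_bits 0/1 vector of length `n(n-1)/2`.
#' @return non-negative motif id.
#' @export
encode_motif <- function(diff_bits) {
  if (!all(diff_bits %in% c(0, 1))) stopf("diff_bits must be 0/1")
  s <- 1 - as.numeric(diff_bits)
  sum(s * 2^(seq_along(s) - 1))
}

#' Decode a motif id into its similarity bits
#'
#' Inverse of [encode_motif()] (up to the difference/similarity flip):
#' returns the similarity bit vector of length `m`.
#'
#' @param id motif id in `[0, 2^m)`.
#' @param n number of cell types.
#' @return 0/1 similarity vector (1 = edge = no significant difference).
#' @export
decode_motif <- function(id, n) {
  m <- n * (n - 1) / 2
  if (id < 0 || id >= 2^m) stopf("id %s out of range [0, %s)", id, 2^m)
  (id %/% 2^(seq_len(m) - 1)) %% 2
}

#' Structure of a motif: components, isolated nodes, isolate-plus-clique
#'
#' Decodes the similarity graph of a motif id and reports its isolated
#' nodes and connected components. The flag is true iff the graph has
#' exactly one isolated node and the remaining nodes form a complete
#' subgraph — the shape of the two dominant motifs (one cell type
#' dissimilar to all others, which behave alike).
#'
#' @param id motif id.
#' @param n number of cell types.
#' @return list: `similarity_bits`, `edges` (matrix), `isolated`
#'   (node indices), `components` (list of node-index vectors),
#'   `is_clique_plus_isolate`.
#' @export
motif_structure <- function(id, n) {
  s <- decode_motif(id, n)
  pairs <- pair_ordering(n)
  edges <- pairs[s == 1, , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  # connected components by label propagation over the small graph
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (v in seq_len(n)) {
      nb <- which(adj[v, ])
      if (length(nb)) new[v] <- min(new[v], min(new[nb]))
    }
    if (identical(new, comp)) break
    comp <- new
  }
  comps <- unname(split(seq_len(n), comp))
  iso <- which(rowSums(adj) == 0)
  rest <- setdiff(seq_len(n), iso)
  flag <- length(iso) == 1 && length(rest) >= 2 &&
    all(adj[rest, rest][upper.tri(diag(length(rest)))])
  list(similarity_bits = s, edges = edges, isolated = iso,
       components = comps, is_clique_plus_isolate = flag)
}

## Count motif occurrences of a genes x m bit matrix over the full motif
## space (ids 0..2^m-1) when small, else over observed ids only.
count_motifs <- function(bits, m, full_space = (2^m <= 4096)) {
  ids <- if (nrow(bits)) apply(bits, 1, encode_motif) else numeric(0)
  if (full_space) {
    tab <- tabulate(ids + 1, nbins = 2^m)
    stats::setNames(tab, as.character(0:(2^m - 1)))
  } else {
    t2 <- table(ids)
    stats::setNames(as.integer(t2), names(t2))
  }
}

#' Permutation test of motif occurrence counts
#'
#' Counts how many genes realize each labeled motif, then permutes each
#' gene's bits independently and uniformly at random (`cfg$n_perm` times,
#' preserving each gene's number of significant pairs), re-encodes and
#' re-counts. The one-sided upper-tail empirical p-value per motif is
#' `(1 + #{permutations with count >= observed}) / (n_perm + 1)`;
#' significant iff below `cfg$alpha`.
#'
#' @param bits genes x m binary matrix of difference bits (one level).
#' @param n number of cell types (so `m = n(n-1)/2` columns).
#' @param cfg a [pipeline_config()] (`n_perm`, `alpha`, `seed`).
#' @return object of class `motif_table`: data.frame with `motif_id`,
#'   `similarity_bits`, `observed_count`, `null_mean`, `null_sd`,
#'   `empirical_p`, `significant`, `is_clique_plus_isolate`; attribute
#'   `n_genes`.
#' @export
permutation_motif_test <- function(bits, n, cfg = pipeline_config()) {
  m <- n * (n - 1) / 2
  if (ncol(bits) != m)
    stopf("bit matrix has %d columns; expected m = %d for n = %d",
          ncol(bits), m, n)
  obs <- count_motifs(bits, m)
  ids <- names(obs)
  nperm <- cfg$n_perm
  null_counts <- matrix(0L, length(ids), nperm, dimnames = list(ids, NULL))
  with_seed(cfg$seed, {
    for (p in seq_len(nperm)) {
      perm <- t(apply(bits, 1, function(b) b[sample.int(m)]))
      if (nrow(bits) == 1L) perm <- matrix(perm, nrow = 1L)
      pc <- count_motifs(perm, m, full_space = FALSE)
      hit <- intersect(names(pc), ids)
      null_counts[hit, p] <- pc[hit]
    }
  })
  ge <- rowSums(null_counts >= obs[ids])
  emp_p <- (1 + ge) / (nperm + 1)
  structure(data.frame(
    motif_id = as.numeric(ids),
    similarity_bits = vapply(as.numeric(ids),
                             function(i) paste(decode_motif(i, n), collapse = ""), ""),
    observed_count = as.integer(obs[ids]),
    null_mean = rowMeans(null_counts),
    null_sd = apply(null_counts, 1, stats::sd),
    empirical_p = emp_p,
    significant = emp_p < cfg$alpha,
    is_clique_plus_isolate = vapply(as.numeric(ids), function(i)
      motif_structure(i, n)$is_clique_plus_isolate, TRUE),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("motif_table", "data.frame"),
    n_genes = nrow(bits), n_cell_types = n, n_perm = nperm)
}

#' Motif analysis of a DE result
#'
#' Runs [permutation_motif_test()] on each system level's difference-bit
#' matrix (genes DE on both levels) and merges the per-level tables.
#'
#' @param de a [celltype_de()] result.
#' @param cfg a [pipeline_config()].
#' @return named list of `motif_table`s (`transcriptome`, `translatome`).
#' @export
motif_analysis <- function(de, cfg = pipeline_config()) {
  stopifnot(inherits(de, "de_result"))
  n <- length(de$cell_types)
  lapply(de$diff_bits, permutation_motif_test, n = n, cfg = cfg)
}

#' @export
print.motif_table <- function(x, ...) {
  cat("Motif occurrence table: ", attr(x, "n_genes"), " genes, ",
      nrow(x), " labeled motifs (n = ", attr(x, "n_cell_types"),
      " cell types), ", attr(x, "n_perm"), " permutations\n", sep = "")
  top <- x[order(-x$observed_count), ][seq_len(min(5, nrow(x))), ]
  print(as.data.frame(top), row.names = FALSE)
  cat("significant motifs:", sum(x$significant), "\n")
  invisible(x)
}
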