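## Co-expression / co-translation networks: weighted adjacency, per-gene
## expression conservation (EC) scores, full-matrix network correlation,
## bootstrap significance, and thresholded relevance-network properties.

#' Co-expression adjacency matrix
#'
#' Fully connected weighted network over genes: the weight of edge (i, j)
#' is the PCC between the two genes' cell-type profiles. Zero-variance
#' rows yield undefined (`NA`) off-diagonal entries, which downstream
#' operations exclude pairwise. Diagonal is 1 by convention.
#'
#' @param x genes x cell-types numeric matrix (>= 2 genes, >= 3 columns).
#' @return symmetric genes x genes matrix with unit diagonal.
#' @export
coexpression_adjacency <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) stopf("need a matrix with >= 2 genes")
  if (ncol(x) < 3) stopf("need >= 3 cell-type columns")
  w <- suppressWarnings(stats::cor(t(x)))
  sdz <- apply(x, 1, stats::sd) == 0
  w[sdz, ] <- NA_real_
  w[, sdz] <- NA_real_
  diag(w) <- 1
  w[!is.na(w)] <- pmin(pmax(w[!is.na(w)], -1), 1)
  w
}

#' Expression conservation (EC) score of one gene
#'
#' PCC between the gene's row in the co-expression adjacency and the same
#' row in the co-translation adjacency, excluding the diagonal entry and
#' (pairwise) any undefined entries; undefined if fewer than 3 usable
#' entries remain.
#'
#' @param a_tr,a_tl adjacency matrices with identical gene lists/order.
#' @param gene gene id (rowname) or row index.
#' @return EC score in `[-1, 1]`, or `NA`.
#' @export
ec_score <- function(a_tr, a_tl, gene) {
  if (!identical(dim(a_tr), dim(a_tl)) ||
      !identical(rownames(a_tr), rownames(a_tl)))
    stopf("adjacency matrices must share shape and gene order")
  i <- if (is.character(gene)) match(gene, rownames(a_tr)) else as.integer(gene)
  if (is.na(i) || i < 1 || i > nrow(a_tr)) stopf("gene '%s' not found", gene)
  unname(ec_scores(a_tr, a_tl)[i])
}

#' Expression conservation scores for all genes
#'
#' Vectorized [ec_score()] over every row.
#'
#' @inheritParams ec_score
#' @return named numeric vector of EC scores.
#' @export
ec_scores <- function(a_tr, a_tl) {
  if (!identical(dim(a_tr), dim(a_tl)))
    stopf("adjacency matrices must share shape and gene order")
  x <- a_tr; y <- a_tl
  diag(x) <- NA_real_; diag(y) <- NA_real_  # diagonal excluded
  r <- rowwise_pcc_na(x, y, min_n = 3L)
  names(r) <- rownames(a_tr)
  r
}

#' Full-matrix correlation of two networks
#'
#' PCC over the vectorized strict upper triangles of the two adjacency
#' matrices (diagonal excluded, undefined entries pairwise-excluded) — the
#' global similarity of the co-expression and co-translation networks,
#' in `[-1, 1]`.
#'
#' @inheritParams ec_score
#' @return scalar correlation, or `NA` if fewer than 3 usable pairs.
#' @export
full_matrix_correlation <- function(a_tr, a_tl) {
  if (!identical(dim(a_tr), dim(a_tl)))
    stopf("adjacency matrices must share shape and gene order")
  ut <- upper.tri(a_tr)
  x <- a_tr[ut]; y <- a_tl[ut]
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  min(max(stats::cor(x[ok], y[ok]), -1), 1)
}

#' Bootstrap null for EC scores and the full-matrix correlation
#'
#' For each of `cfg$n_boot` iterations, draws `k` promoters without
#' replacement per level (as in [bootstrap_pcc_null()]), builds both
#' adjacency matrices from the resulting random cell-type mixtures, and
#' records every gene's EC score plus the full-matrix correlation. Gene
#' count may be subsampled upstream for tractability.
#'
#' @inheritParams bootstrap_pcc_null
#' @return list: `per_gene` data.frame (`gene_id`, `null_mean`, `null_sd`,
#'   `n_null_used`) and `fmc_null` (numeric vector, length `n_boot`).
#' @export
bootstrap_ec_null <- function(x_tr, x_tl, map, k, cfg = pipeline_config()) {
  genes <- intersect(rownames(x_tr), rownames(x_tl))
  if (length(genes) < 2) stopf("need >= 2 shared genes")
  pm_tr <- promoter_means(x_tr[genes, , drop = FALSE], map, "transcriptome")
  pm_tl <- promoter_means(x_tl[genes, , drop = FALSE], map, "translatome")
  if (ncol(pm_tr) < k || ncol(pm_tl) < k)
    stopf("promoter pool smaller than k = %d (transcriptome %d, translatome %d)",
          k, ncol(pm_tr), ncol(pm_tl))
  G <- length(genes)
  ec_draws <- matrix(NA_real_, G, cfg$n_boot)
  fmc_null <- numeric(cfg$n_boot)
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_boot)) {
      a_tr <- coexpression_adjacency(pm_tr[, sample.int(ncol(pm_tr), k), drop = FALSE])
      a_tl <- coexpression_adjacency(pm_tl[, sample.int(ncol(pm_tl), k), drop = FALSE])
      ec_draws[, b] <- ec_scores(a_tr, a_tl)
      fmc_null[b] <- full_matrix_correlation(a_tr, a_tl)
    }
  })
  list(per_gene = data.frame(gene_id = genes,
                             null_mean = rowMeans(ec_draws, na.rm = TRUE),
                             null_sd = apply(ec_draws, 1, stats::sd, na.rm = TRUE),
                             n_null_used = rowSums(!is.na(ec_draws)),
                             stringsAsFactors = FALSE),
       fmc_null = fmc_null)
}

#' Network conservation analysis
#'
#' Builds the co-expression (transcriptome) and co-translation
#' (translatome) networks over cell-type profiles, computes every gene's
#' EC score and the observed full-matrix correlation, derives bootstrap
#' nulls, and classifies genes: `conserved` (EC > 0 and Z >= z_crit),
#' `rewired` (Z <= -z_crit), `neutral`, or `degenerate`. The full-matrix
#' correlation gets a one-sided empirical p-value for being lower than
#' chance, `(1 + #{null <= observed}) / (n_boot + 1)`.
#'
#' @inheritParams coupling_analysis
#' @param genes optional subset of gene ids to analyze (subsampling keeps
#'   the 1000-network bootstrap tractable at large G).
#' @return object of class `ec_result`: data.frame (`gene_id`, `ec`,
#'   `null_mean`, `null_sd`, `zscore`, `ec_class`) with attributes
#'   `fmc` (observed full-matrix correlation), `fmc_null`, `fmc_p_lower`,
#'   `scenario`, `k`, `cell_types`, `config`, and the adjacency matrices
#'   `a_tr`, `a_tl`.
#' @export
ec_analysis <- function(x_tr, x_tl, map, scenario = c("common", "identical"),
                        cfg = pipeline_config(), k = NULL, genes = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(genes)) {
    x_tr <- x_tr[intersect(genes, rownames(x_tr)), , drop = FALSE]
    x_tl <- x_tl[intersect(genes, rownames(x_tl)), , drop = FALSE]
  }
  paired <- aggregate_to_cell_types(x_tr, x_tl, map, scenario)
  if (is.null(k)) k <- length(paired$cell_types)
  a_tr <- coexpression_adjacency(paired$x_tr)
  a_tl <- coexpression_adjacency(paired$x_tl)
  ec <- ec_scores(a_tr, a_tl)
  fmc <- full_matrix_correlation(a_tr, a_tl)
  nul <- bootstrap_ec_null(x_tr[paired$gene_ids, , drop = FALSE],
                           x_tl[paired$gene_ids, , drop = FALSE],
                           map, k, cfg)
  z <- ifelse(is.na(ec) | is.na(nul$per_gene$null_sd) | nul$per_gene$null_sd == 0,
              NA_real_, (ec - nul$per_gene$null_mean) / nul$per_gene$null_sd)
  cls <- ifelse(is.na(z), "degenerate",
         ifelse(z >= cfg$z_crit & ec > 0, "conserved",
         ifelse(z <= -cfg$z_crit, "rewired", "neutral")))
  fmc_ok <- nul$fmc_null[!is.na(nul$fmc_null)]
  p_lower <- (1 + sum(fmc_ok <= fmc)) / (length(fmc_ok) + 1)
  out <- data.frame(gene_id = paired$gene_ids, ec = ec,
                    null_mean = nul$per_gene$null_mean,
                    null_sd = nul$per_gene$null_sd,
                    zscore = z, ec_class = cls,
                    n_null_used = nul$per_gene$n_null_used,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ec_result", "data.frame"),
            fmc = fmc, fmc_null = nul$fmc_null, fmc_p_lower = p_lower,
            scenario = scenario, k = k, cell_types = paired$cell_types,
            config = cfg, a_tr = a_tr, a_tl = a_tl)
}

#' @export
print.ec_result <- function(x, ...) {
  cat("Network conservation analysis (", attr(x, "scenario"), " scenario, ",
      nrow(x), " genes)\n", sep = "")
  print(table(x$ec_class))
  cat(sprintf("full-matrix correlation: %.4f (one-sided empirical p, lower tail: %.4g)\n",
              attr(x, "fmc"), attr(x, "fmc_p_lower")))
  invisible(x)
}

#' @export
plot.ec_result <- function(x, ...) {
  graphics::hist(x$ec, breaks = 40, col = "grey80",
                 main = "Expression conservation scores", xlab = "EC", ...)
  graphics::abline(v = attr(x, "fmc"), lty = 2)
  invisible(x)
}

#' Threshold a weighted network into a relevance graph
#'
#' Unweighted undirected graph with an edge wherever the PCC weight is at
#' least `t` (undefined entries give no edge).
#'
#' @param a adjacency matrix of PCC weights.
#' @param t threshold in (0, 1].
#' @return an `igraph` graph.
#' @export
threshold_graph <- function(a, t = 0.9) {
  if (t <= 0 || t > 1) stopf("t must lie in (0, 1]")
  b <- !is.na(a) & a >= t
  diag(b) <- FALSE
  igraph::graph_from_adjacency_matrix(b, mode = "undirected", diag = FALSE)
}

#' Node properties of a relevance network
#'
#' Per node: degree, betweenness, harmonic closeness, eigenvector
#' centrality (max-normalized), alpha centrality (alpha =
#' `factor`/lambda_max with a unit exogenous vector) and local
#' transitivity. Isolated nodes get 0 for closeness and the centralities
#' by convention; local transitivity of degree<2 nodes is 0. Graph-level
#' transitivity and the per-edge betweenness table are attached as
#' attributes.
#'
#' @param g an `igraph` graph (>= 1 node).
#' @param factor alpha-centrality damping as a fraction of the 1/lambda_max
#'   convergence bound.
#' @return data.frame, one row per node; attributes `graph_transitivity`
#'   and `edge_betweenness`.
#' @export
node_properties <- function(g, factor = 0.5) {
  n <- igraph::vcount(g)
  if (n < 1) stopf("graph needs >= 1 node")
  deg <- igraph::degree(g)
  iso <- deg == 0
  btw <- igraph::betweenness(g, directed = FALSE)
  clo <- igraph::harmonic_centrality(g, normalized = TRUE)
  clo[iso] <- 0
  if (igraph::ecount(g) > 0) {
    # principal eigenvector via dense symmetric eigen: deterministic,
    # unlike ARPACK iteration; max-normalized, sign fixed to the Perron
    # (non-negative) orientation
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    ed <- eigen(adj, symmetric = TRUE)
    lmax <- ed$values[1]
    v <- ed$vectors[, 1]
    v <- v * sign(v[which.max(abs(v))])
    v <- pmax(v, 0)
    eig <- if (max(v) > 0) v / max(v) else v
    alp <- if (lmax > 0)
      igraph::alpha_centrality(g, alpha = factor / lmax, exo = 1)
    else rep(1, n)
  } else {
    eig <- rep(0, n)
    alp <- rep(1, n)
  }
  eig[iso] <- 0
  alp[iso] <- 0
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  glob <- igraph::transitivity(g, type = "global")
  if (is.nan(glob)) glob <- 0
  eb <- if (igraph::ecount(g) > 0)
    data.frame(igraph::as_edgelist(g),
               edge_betweenness = igraph::edge_betweenness(g, directed = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(X1 = character(0), X2 = character(0),
                  edge_betweenness = numeric(0), stringsAsFactors = FALSE)
  names(eb)[1:2] <- c("node_a", "node_b")
  out <- data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
                    degree = as.numeric(deg), betweenness = btw,
                    closeness = clo, eigenvector = eig, alpha = as.numeric(alp),
                    transitivity = loc,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "graph_transitivity") <- glob
  attr(out, "edge_betweenness") <- eb
  out
}

#' Write a weighted network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `weight`; upper triangle only; undefined
#' weights are omitted.
#' @param a adjacency matrix.
#' @param path output path.
#' @export
write_edge_list <- function(a, path) {
  ut <- which(upper.tri(a), arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(a)[ut[, 1]],
                   gene_b = colnames(a)[ut[, 2]],
                   weight = a[ut], stringsAsFactors = FALSE)
  df <- df[!is.na(df$weight), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
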