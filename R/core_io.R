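## Data model and I/O: expression matrices, sample metadata, aggregation of
## replicate/promoter samples into paired cell-type matrices.

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of normalized log2
#' intensities with unique gene ids as rownames and unique sample ids as
#' colnames; all values must be finite.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  dg <- rownames(x)[duplicated(rownames(x))]
  if (length(dg)) stopf("duplicated gene id(s): %s", paste(unique(dg), collapse = ", "))
  ds <- colnames(x)[duplicated(colnames(x))]
  if (length(ds)) stopf("duplicated sample id(s): %s", paste(unique(ds), collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stopf("non-finite value at gene '%s', sample '%s'",
          rownames(x)[bad[1]], colnames(x)[bad[2]])
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row is
#' `gene_id<TAB><sample ids...>` and whose first column holds gene ids.
#' Row order is preserved. Duplicate ids and non-numeric cells are hard
#' errors naming the offenders.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples) with id dimnames.
#' @export
load_expression_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stopf("expression TSV needs a gene_id column plus >=1 sample column: %s", path)
  gene_ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(gene_ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stopf("non-numeric cell '%s' at row %d (gene '%s'), column '%s'",
            vals[[j]][bad[1]], bad[1], gene_ids[bad[1]], colnames(vals)[j])
    if (anyNA(v))
      stopf("missing value at row %d, column '%s' (missing values are not permitted)",
            which(is.na(v))[1], colnames(vals)[j])
    m[, j] <- v
  }
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Emits the same dialect [load_expression_matrix()] reads, so that a
#' write/load round trip is the identity.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `level` (one of `transcriptome`, `translatome`),
#' `promoter`, `cell_type`, `replicate` (positive integer).
#'
#' @param path TSV path.
#' @return data.frame with the five columns above.
#' @export
load_sample_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_map(df)
  df
}

#' @rdname load_sample_map
#' @param map sample map data.frame.
#' @export
write_sample_map <- function(map, path) {
  validate_sample_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname load_sample_map
#' @export
validate_sample_map <- function(map) {
  need <- c("sample_id", "level", "promoter", "cell_type", "replicate")
  miss <- setdiff(need, names(map))
  if (length(miss)) stopf("sample map lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(map$sample_id))
    stopf("duplicated sample_id(s): %s",
          paste(unique(map$sample_id[duplicated(map$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(map$level), c("transcriptome", "translatome"))
  if (length(bad)) stopf("unknown level(s): %s", paste(bad, collapse = ", "))
  if (any(map$replicate < 1 | map$replicate != round(map$replicate)))
    stopf("replicate must be a positive integer")
  invisible(map)
}

map_for_level <- function(map, level) {
  map[map$level == level, , drop = FALSE]
}

#' Per-promoter mean expression
#'
#' Averages replicate samples of each promoter of one system level,
#' returning a genes x promoters matrix. Used both for cell-type
#' aggregation (promoter-level pooling) and as the bootstrap pool.
#'
#' @param x expression matrix of that level.
#' @param map sample map.
#' @param level `"transcriptome"` or `"translatome"`.
#' @return genes x promoters matrix; attribute `cell_type` gives each
#'   promoter's target cell type.
#' @export
promoter_means <- function(x, map, level) {
  m <- map_for_level(map, level)
  m <- m[m$sample_id %in% colnames(x), , drop = FALSE]
  if (!nrow(m)) stopf("no %s samples of the matrix appear in the map", level)
  proms <- unique(m$promoter)
  out <- matrix(NA_real_, nrow(x), length(proms),
                dimnames = list(rownames(x), proms))
  ct <- character(length(proms))
  for (i in seq_along(proms)) {
    mi <- m[m$promoter == proms[i], , drop = FALSE]
    cts <- unique(mi$cell_type)
    if (length(cts) != 1)
      stopf("promoter '%s' maps to multiple cell types at level %s", proms[i], level)
    ct[i] <- cts
    out[, i] <- rowMeans(x[, mi$sample_id, drop = FALSE])
  }
  attr(out, "cell_type") <- stats::setNames(ct, proms)
  out
}

#' Aggregate paired samples into cell-type profile matrices
#'
#' Restricts genes to the intersection of the two matrices' gene lists and
#' collapses replicate/promoter samples into one column per cell type, in
#' an identical cell-type order for both system levels.
#'
#' Two scenarios are supported. `"identical"` uses only promoters whose
#' label occurs in both levels (the shared promoter sets); `"common"` uses
#' all samples of every cell type present in both levels. With the default
#' synthetic design these yield 4 and 5 cell types respectively.
#'
#' Multiple promoters targeting one cell type are pooled at the replicate
#' level (grand mean over all replicate samples) by default;
#' `pooling = "promoter"` averages promoter means instead.
#'
#' @param x_tr,x_tl transcriptome and translatome expression matrices.
#' @param map sample map covering both levels.
#' @param scenario `"identical"` or `"common"`.
#' @param pooling `"replicate"` (grand mean) or `"promoter"`
#'   (mean of promoter means).
#' @return object of class `paired_celltype_data`: list with `gene_ids`,
#'   `cell_types`, `x_tr`, `x_tl` (genes x cell types), `scenario`.
#' @export
aggregate_to_cell_types <- function(x_tr, x_tl, map,
                                    scenario = c("common", "identical"),
                                    pooling = c("replicate", "promoter")) {
  scenario <- match.arg(scenario)
  pooling <- match.arg(pooling)
  validate_expression_matrix(x_tr)
  validate_expression_matrix(x_tl)
  validate_sample_map(map)
  genes <- intersect(rownames(x_tr), rownames(x_tl))
  if (!length(genes)) stopf("no genes shared between the two matrices")
  x_tr <- x_tr[genes, , drop = FALSE]
  x_tl <- x_tl[genes, , drop = FALSE]

  mtr <- map_for_level(map, "transcriptome")
  mtl <- map_for_level(map, "translatome")
  mtr <- mtr[mtr$sample_id %in% colnames(x_tr), , drop = FALSE]
  mtl <- mtl[mtl$sample_id %in% colnames(x_tl), , drop = FALSE]
  if (identical(scenario, "identical")) {
    shared <- intersect(unique(mtr$promoter), unique(mtl$promoter))
    if (!length(shared)) stopf("no promoter labels shared between levels")
    mtr <- mtr[mtr$promoter %in% shared, , drop = FALSE]
    mtl <- mtl[mtl$promoter %in% shared, , drop = FALSE]
  }
  cts <- intersect(sort(unique(mtr$cell_type)), sort(unique(mtl$cell_type)))
  only_tr <- setdiff(unique(mtr$cell_type), cts)
  only_tl <- setdiff(unique(mtl$cell_type), cts)
  if (!length(cts)) stopf("no cell types shared between levels")
  if (identical(scenario, "identical") && (length(only_tr) || length(only_tl)))
    stopf("cell type(s) absent from one level under the identical scenario: %s",
          paste(c(only_tr, only_tl), collapse = ", "))

  agg <- function(x, m) {
    out <- matrix(NA_real_, nrow(x), length(cts), dimnames = list(rownames(x), cts))
    for (ct in cts) {
      mi <- m[m$cell_type == ct, , drop = FALSE]
      if (!nrow(mi)) stopf("cell type '%s' has no samples in one level", ct)
      if (pooling == "replicate") {
        out[, ct] <- rowMeans(x[, mi$sample_id, drop = FALSE])
      } else {
        pm <- vapply(split(mi$sample_id, mi$promoter),
                     function(s) rowMeans(x[, s, drop = FALSE]),
                     numeric(nrow(x)))
        out[, ct] <- rowMeans(matrix(pm, nrow = nrow(x)))
      }
    }
    out
  }
  structure(list(gene_ids = genes, cell_types = cts,
                 x_tr = agg(x_tr, mtr), x_tl = agg(x_tl, mtl),
                 scenario = scenario),
            class = "paired_celltype_data")
}

#' @export
print.paired_celltype_data <- function(x, ...) {
  cat("Paired cell-type data (", x$scenario, " scenario)\n", sep = "")
  cat("  genes:     ", length(x$gene_ids), "\n", sep = "")
  cat("  cell types:", paste(x$cell_types, collapse = ", "), "\n")
  invisible(x)
}
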