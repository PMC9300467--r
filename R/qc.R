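#' Quality-control thresholds for cells and genes
#'
#' Defaults follow common human single-cell practice: drop genes detected in
#' fewer than 3 cells, then drop cells detecting fewer than 500 genes, cells
#' above 20% mitochondrial content, and cells with both more than 10%
#' mitochondrial content and fewer than 1,500 counts.
#'
#' @param min_cells_per_gene Genes must be detected in at least this many
#'   cells (default 3).
#' @param min_genes_per_cell Cells must detect at least this many genes
#'   (default 500).
#' @param max_mito_fraction Cells above this mitochondrial fraction are
#'   removed (strict >, default 0.20).
#' @param joint_mito_fraction,joint_min_counts Cells with mitochondrial
#'   fraction strictly above `joint_mito_fraction` AND total counts strictly
#'   below `joint_min_counts` are removed (defaults 0.10 and 1500).
#' @param mito_gene_prefix Prefix identifying mitochondrial genes
#'   (default "MT-").
#' @return List of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3, min_genes_per_cell = 500,
                          max_mito_fraction = 0.20, joint_mito_fraction = 0.10,
                          joint_min_counts = 1500, mito_gene_prefix = "MT-") {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            joint_mito_fraction >= 0,
            joint_mito_fraction <= max_mito_fraction)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 joint_mito_fraction = joint_mito_fraction,
                 joint_min_counts = joint_min_counts,
                 mito_gene_prefix = mito_gene_prefix),
            class = "QCThresholds")
}

#' Filter cells and genes on quality rules
#'
#' Genes detected in too few cells are removed first; the three cell rules
#' (minimum detected genes, mitochondrial ceiling, joint mitochondrial/count
#' rule) are then evaluated on the gene-filtered matrix. A per-rule removal
#' report is attached as the `"qc_report"` attribute.
#'
#' @param counts A [count_matrix()].
#' @param thr A [qc_thresholds()].
#' @return The filtered [count_matrix()].
#' @export
qc_filter <- function(counts, thr = qc_thresholds()) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$counts
  detected_cells <- Matrix::colSums(m > 0)
  keep_gene <- detected_cells >= thr$min_cells_per_gene
  m <- m[, keep_gene, drop = FALSE]

  genes_per_cell <- Matrix::rowSums(m > 0)
  total <- Matrix::rowSums(m)
  mito <- startsWith(colnames(m), thr$mito_gene_prefix)
  mito_frac <- if (any(mito))
    Matrix::rowSums(m[, mito, drop = FALSE]) / pmax(total, 1) else
    rep(0, nrow(m))
  fail_genes <- genes_per_cell < thr$min_genes_per_cell
  fail_mito <- mito_frac > thr$max_mito_fraction
  fail_joint <- mito_frac > thr$joint_mito_fraction &
    total < thr$joint_min_counts
  keep_cell <- !(fail_genes | fail_mito | fail_joint)
  report <- list(genes_removed = sum(!keep_gene),
                 cells_low_genes = sum(fail_genes),
                 cells_high_mito = sum(fail_mito),
                 cells_joint_rule = sum(fail_joint),
                 cells_removed = sum(!keep_cell),
                 cells_kept = sum(keep_cell), genes_kept = ncol(m))
  if (!any(keep_cell))
    stop("QC removed every cell (low genes: ", report$cells_low_genes,
         ", high mito: ", report$cells_high_mito,
         ", joint rule: ", report$cells_joint_rule, ")")
  out <- count_matrix(m[keep_cell, , drop = FALSE],
                      counts$cell_meta[keep_cell, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Normalize counts to the natural-log CPM/100 scale
#'
#' value(c, g) = ln(count(c, g) / total(c) * 1e4 + 1), i.e. log(CPM/100 + 1).
#' Invariant to per-cell scaling of counts; a zero count maps to 0.
#'
#' @param counts A QC-filtered [count_matrix()]; every cell total must be
#'   positive.
#' @return A [normalized_matrix()] (dense, cells x genes).
#' @export
normalize_log_cpm100 <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  total <- Matrix::rowSums(counts$counts)
  if (any(total <= 0))
    stop("cell with zero total counts: ",
         rownames(counts$counts)[total <= 0][1], " (run qc_filter first)")
  v <- log1p(as.matrix(counts$counts) / total * 1e4)
  normalized_matrix(v, provenance = list(method = "log1p_cpm100",
                                         log_base = "e", scale = 1e4))
}

#' Summarize expression per cell type
#'
#' Means are computed on normalized values; expression fractions count cells
#' with raw count > 0 (detection, not normalized magnitude).
#'
#' @param norm A [normalized_matrix()] (cells x genes).
#' @param counts The matching [count_matrix()].
#' @param labels Optional per-cell labels; defaults to `cell_type` from the
#'   count metadata.
#' @return List of class `CellTypeProfile` with matrices `mean_norm` and
#'   `fraction` (cell types x genes) and vector `n_cells`.
#' @export
profile_cell_types <- function(norm, counts, labels = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"),
            inherits(counts, "CountMatrix"))
  labels <- labels %||% counts$cell_meta$cell_type
  stopifnot(length(labels) == nrow(norm$values))
  types <- sort(unique(labels))
  ind <- outer(labels, types, "==") * 1          # cells x types indicator
  n_cells <- colSums(ind)
  mean_norm <- t(ind) %*% norm$values / n_cells
  fraction <- as.matrix(t(ind) %*% (counts$counts > 0)) / n_cells
  dimnames(mean_norm) <- dimnames(fraction) <-
    list(types, colnames(norm$values))
  structure(list(mean_norm = as.matrix(mean_norm), fraction = fraction,
                 n_cells = stats::setNames(n_cells, types)),
            class = "CellTypeProfile")
}

#' TF-IDF cluster markers
#'
#' score(gene, cluster) = tf x idf with tf the fraction of cluster cells
#' detecting the gene and idf = ln(total cells / cells detecting the gene
#' overall). Genes detected in every cell score 0; genes detected nowhere
#' score 0 by convention. Ties are broken by gene id.
#'
#' @param counts A [count_matrix()].
#' @param labels Optional cluster labels (default: cell types).
#' @param top_n Markers reported per cluster (default 10).
#' @return data.frame with columns cluster, gene, score, rank.
#' @export
tfidf_markers <- function(counts, labels = NULL, top_n = 10) {
  stopifnot(inherits(counts, "CountMatrix"))
  labels <- labels %||% counts$cell_meta$cell_type
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("tfidf_markers needs at least 2 clusters")
  det <- counts$counts > 0
  n_total <- nrow(det)
  n_overall <- Matrix::colSums(det)
  idf <- ifelse(n_overall > 0, log(n_total / pmax(n_overall, 1)), 0)
  out <- list()
  for (cl in clusters) {
    rows <- labels == cl
    if (sum(rows) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    tf <- Matrix::colSums(det[rows, , drop = FALSE]) / sum(rows)
    score <- tf * idf
    ord <- order(-score, colnames(det))
    top <- head(ord, top_n)
    out[[cl]] <- data.frame(cluster = cl, gene = colnames(det)[top],
                            score = score[top], rank = seq_along(top))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
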