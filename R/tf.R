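#' Regulon-based TF activity scores
#'
#' Each gene's normalized expression is z-scored across cells (its
#' "signature"); a TF's activity in a cell is the weighted, mode-signed mean
#' of its targets' signatures, scaled to a z-like score:
#' activity(TF, c) = sum(mode * weight * signature) / sqrt(sum(weight^2)).
#' Targets absent from the matrix are dropped with a warning; regulons that
#' fall below the size floor are excluded.
#'
#' @param norm A [normalized_matrix()] (cells x genes) or plain matrix.
#' @param regulons A [regulon_set()] table.
#' @param min_targets Minimum usable targets per regulon (default 5).
#' @return `ActivityMatrix`: real matrix, TFs x cells, with attribute
#'   `source = "regulon"`.
#' @export
regulon_activity <- function(norm, regulons, min_targets = 5) {
  values <- if (inherits(norm, "NormalizedMatrix")) norm$values else
    as.matrix(norm)
  missing_tg <- setdiff(unique(regulons$target), colnames(values))
  if (length(missing_tg)) {
    warning(length(missing_tg), " regulon target(s) absent from the matrix; ",
            "dropped: ", paste(head(missing_tg, 5), collapse = ", "))
    regulons <- regulons[!regulons$target %in% missing_tg, , drop = FALSE]
  }
  n <- table(regulons$tf)
  small <- names(n)[n < min_targets]
  if (length(small)) {
    warning("regulon(s) below the ", min_targets, "-target floor excluded: ",
            paste(small, collapse = ", "))
    regulons <- regulons[!regulons$tf %in% small, , drop = FALSE]
  }
  if (!nrow(regulons)) stop("no usable regulon left")
  sig <- scale(values)                      # per-gene z across cells
  sig[, attr(sig, "scaled:scale") == 0] <- 0
  sig[is.na(sig)] <- 0
  tfs <- sort(unique(regulons$tf))
  W <- Matrix::sparseMatrix(
    i = match(regulons$target, colnames(values)),
    j = match(regulons$tf, tfs),
    x = regulons$mode * regulons$weight /
      sqrt(vapply(regulons$tf, function(f)
        sum(regulons$weight[regulons$tf == f]^2), 1)),
    dims = c(ncol(values), length(tfs)),
    dimnames = list(colnames(values), tfs))
  act <- t(as.matrix(sig %*% W))
  colnames(act) <- rownames(values)
  attr(act, "source") <- "regulon"
  act
}

#' Quality-filter accessibility peaks
#'
#' Drops peaks that overlap a blacklist interval by at least 1 bp, peaks
#' whose width lies outside the allowed range (bounds inclusive), and peaks
#' accessible in less than the minimum fraction of cells of every cluster
#' (a peak is kept when it reaches the fraction in at least one cluster).
#'
#' @param pa A [peak_accessibility()] object.
#' @param blacklist BED-style data.frame (chrom/start/end, 0-based
#'   half-open) or NULL to skip.
#' @param cluster_labels Per-cell cluster labels (defaults to one cluster).
#' @param width_range Inclusive width bounds (default c(210, 1500)).
#' @param min_cluster_fraction Minimum accessible-cell fraction in at least
#'   one cluster (default 0.04, inclusive).
#' @return The filtered [peak_accessibility()] object.
#' @export
filter_peaks <- function(pa, blacklist = NULL, cluster_labels = NULL,
                         width_range = c(210, 1500),
                         min_cluster_fraction = 0.04) {
  stopifnot(inherits(pa, "PeakAccessibility"))
  keep <- rep(TRUE, nrow(pa$peaks))
  if (!is.null(blacklist) && nrow(blacklist)) {
    gr_peaks <- GenomicRanges::GRanges(
      pa$peaks$chrom,
      IRanges::IRanges(pa$peaks$start + 1L, pa$peaks$end))
    gr_bl <- GenomicRanges::GRanges(
      blacklist$chrom, IRanges::IRanges(blacklist$start + 1L, blacklist$end))
    hits <- GenomicRanges::findOverlaps(gr_peaks, gr_bl, minoverlap = 1L)
    keep[unique(S4Vectors_queryHits(hits))] <- FALSE
  }
  w <- peak_width(pa$peaks)
  keep <- keep & w >= width_range[1] & w <= width_range[2]
  labels <- cluster_labels %||% rep("all", ncol(pa$access))
  clusters <- unique(labels)
  det <- pa$access > 0
  frac_ok <- rep(FALSE, nrow(pa$peaks))
  for (cl in clusters) {
    cols <- labels == cl
    frac_ok <- frac_ok |
      (Matrix::rowSums(det[, cols, drop = FALSE]) / sum(cols) >=
         min_cluster_fraction)
  }
  keep <- keep & frac_ok
  if (!any(keep)) stop("no peak survives filtering")
  peak_accessibility(pa$peaks[keep, , drop = FALSE],
                     pa$access[keep, , drop = FALSE],
                     pa$motif_annot[keep, , drop = FALSE],
                     pa$motif_tf)
}

# thin indirection so the import is explicit and mockable
S4Vectors_queryHits <- function(hits) S4Vectors::queryHits(hits)

#' Motif accessibility deviation z-scores
#'
#' For a peak set S and cell c, the expected accessibility is the set's total
#' accessibility across all cells times the cell's share of all fragments;
#' the raw deviation is (observed - expected) / expected. Each motif's raw
#' deviation is compared against `n_background` background peak sets built by
#' matching every motif peak to a nearest neighbour in the standardized
#' (GC content, mean accessibility) plane, sampled without replacement within
#' a set; the deviation z-score is
#' (y_obs - mean(y_background)) / sd(y_background), per cell.
#'
#' @param pa A filtered [peak_accessibility()] object.
#' @param n_background Number of background peak sets (default 50).
#' @param seed RNG seed for background sampling.
#' @param k_neighbours Candidate pool per motif peak (default
#'   max(2 * n_background, 50)).
#' @return `ActivityMatrix`: TFs x cells matrix of deviation z-scores, with
#'   attribute `source = "motif"`. Motifs whose background deviations are
#'   degenerate (zero variance) are dropped with a warning.
#' @export
motif_deviations <- function(pa, n_background = 50, seed = 1,
                             k_neighbours = max(2 * n_background, 50)) {
  stopifnot(inherits(pa, "PeakAccessibility"))
  set.seed(seed)
  acc <- pa$access
  n_peaks <- nrow(acc); n_cells <- ncol(acc)
  ftot <- Matrix::colSums(acc)
  rtot <- Matrix::rowSums(acc)
  grand <- sum(ftot)
  dev_for <- function(idx) {
    obs <- Matrix::colSums(acc[idx, , drop = FALSE])
    expd <- sum(rtot[idx]) * ftot / grand
    ifelse(expd > 0, (obs - expd) / expd, 0)
  }
  # nearest neighbours in standardized (GC, mean accessibility) space
  feat <- scale(cbind(pa$peaks$gc, rtot / n_cells))
  feat[is.na(feat)] <- 0
  k <- min(k_neighbours, n_peaks - 1L)
  nn <- matrix(0L, n_peaks, k)
  d2 <- as.matrix(stats::dist(feat))^2
  for (i in seq_len(n_peaks)) {
    o <- order(d2[i, -i])[seq_len(k)]
    nn[i, ] <- o + (o >= i)   # shift back past the removed self entry
  }

  motifs <- colnames(pa$motif_annot)
  out <- matrix(NA_real_, length(motifs), n_cells,
                dimnames = list(unname(pa$motif_tf[motifs]), colnames(acc)))
  dropped <- character()
  for (mi in seq_along(motifs)) {
    idx <- which(pa$motif_annot[, mi] != 0)
    if (!length(idx)) { dropped <- c(dropped, motifs[mi]); next }
    y_obs <- dev_for(idx)
    y_bg <- matrix(0, n_background, n_cells)
    for (b in seq_len(n_background)) {
      used <- logical(n_peaks)
      sel <- integer(length(idx))
      for (j in sample(seq_along(idx))) {
        cand <- nn[idx[j], ]
        cand <- cand[!used[cand]]
        pick <- if (length(cand)) cand[sample.int(length(cand), 1L)] else
          sample(which(!used), 1L)
        sel[j] <- pick
        used[pick] <- TRUE
      }
      y_bg[b, ] <- dev_for(sel)
    }
    mu <- colMeans(y_bg)
    sdev <- apply(y_bg, 2, sd)
    if (all(sdev == 0)) { dropped <- c(dropped, motifs[mi]); next }
    sdev[sdev == 0] <- NA
    out[mi, ] <- (y_obs - mu) / sdev
  }
  if (length(dropped)) {
    warning("motif(s) dropped (degenerate background): ",
            paste(dropped, collapse = ", "))
    out <- out[!motifs %in% dropped, , drop = FALSE]
  }
  out[is.na(out)] <- 0
  attr(out, "source") <- "motif"
  out
}

#' One-vs-all differential activity
#'
#' The activity matrix is z-transformed per TF across cells, then each TF is
#' tested per group with the one-sided rank-sum one-vs-all machinery. Fold
#' change is undefined for signed z-scores, so the effect column is the
#' difference of group means on the z scale (switchable).
#'
#' @param activity TF x cells activity matrix (regulon or motif source).
#' @param labels Per-cell group labels.
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @param lfc_method Effect-size convention (default `"meandiff"`).
#' @return DE table as from [de_one_vs_all()].
#' @export
activity_de <- function(activity, labels,
                        adjust_method = c("bonferroni", "bh"),
                        lfc_method = "meandiff") {
  z <- t(scale(t(activity)))
  z[is.na(z)] <- 0
  de_one_vs_all(z, labels, adjust_method = match.arg(adjust_method),
                lfc_method = lfc_method)
}

#' Thresholds for TF prioritization
#'
#' A TF is prioritized in a cell type when it is differentially expressed
#' (log2 fold change above `expr_log2fc_min`, adjusted p below
#' `expr_padj_max`) AND differentially active in at least one activity
#' measurement (effect above `act_log2fc_min`, adjusted p below
#' `act_padj_max`).
#'
#' @param expr_log2fc_min Expression effect floor (default 0.5, strict >).
#' @param expr_padj_max Expression adjusted-p ceiling (default 0.01,
#'   strict <).
#' @param act_log2fc_min Activity effect floor (default 0.75, strict >).
#' @param act_padj_max Activity adjusted-p ceiling (default 0.01, strict <).
#' @return List of class `TFPriorityThresholds`.
#' @export
tf_priority_thresholds <- function(expr_log2fc_min = 0.5,
                                   expr_padj_max = 0.01,
                                   act_log2fc_min = 0.75,
                                   act_padj_max = 0.01) {
  structure(list(expr_log2fc_min = expr_log2fc_min,
                 expr_padj_max = expr_padj_max,
                 act_log2fc_min = act_log2fc_min,
                 act_padj_max = act_padj_max),
            class = "TFPriorityThresholds")
}

de_flag <- function(de, tfs, types, lfc_min, padj_max) {
  flag <- matrix(FALSE, length(tfs), length(types),
                 dimnames = list(tfs, types))
  if (is.null(de) || !nrow(de)) return(flag)
  hit <- de$feature %in% tfs & de$group %in% types &
    de$log2fc > lfc_min & de$p_adj < padj_max
  if (any(hit)) flag[cbind(de$feature[hit], de$group[hit])] <- TRUE
  flag
}

#' Prioritize transcription factors from three evidence layers
#'
#' Combines per-(TF, cell type) differential expression with differential
#' activity from regulon scores and/or motif-accessibility deviations:
#' prioritized = expression passes AND (regulon passes OR motif passes). A
#' missing motif modality yields `motif_pass = FALSE`, never NA.
#'
#' @param expr_de Gene-level DE table ([de_one_vs_all()] on normalized
#'   expression).
#' @param regulon_de Activity DE table for regulon scores
#'   ([activity_de()]), or NULL.
#' @param motif_de Activity DE table for motif deviations, or NULL.
#' @param thr A [tf_priority_thresholds()].
#' @param tfs TF universe; defaults to the union of features in the two
#'   activity tables.
#' @return data.frame with one row per (tf, cell_type): `expr_pass`,
#'   `regulon_pass`, `motif_pass`, `prioritized`.
#' @export
prioritize_tfs <- function(expr_de, regulon_de = NULL, motif_de = NULL,
                           thr = tf_priority_thresholds(), tfs = NULL) {
  tfs <- sort(tfs %||% unique(c(regulon_de$feature, motif_de$feature)))
  if (!length(tfs)) stop("empty TF universe")
  types <- sort(unique(expr_de$group))
  expr <- de_flag(expr_de, tfs, types, thr$expr_log2fc_min, thr$expr_padj_max)
  reg <- de_flag(regulon_de, tfs, types, thr$act_log2fc_min, thr$act_padj_max)
  mot <- de_flag(motif_de, tfs, types, thr$act_log2fc_min, thr$act_padj_max)
  out <- data.frame(
    tf = rep(tfs, times = length(types)),
    cell_type = rep(types, each = length(tfs)),
    expr_pass = as.vector(expr), regulon_pass = as.vector(reg),
    motif_pass = as.vector(mot))
  out$prioritized <- out$expr_pass & (out$regulon_pass | out$motif_pass)
  out <- out[order(out$tf, out$cell_type), ]
  rownames(out) <- NULL
  out
}
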