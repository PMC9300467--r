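#' One-sided Wilcoxon rank-sum test (x stochastically greater than y)
#'
#' Midranks are used for ties. The p-value is exact (from the null
#' distribution of the Mann-Whitney U statistic) when the combined sample is
#' small and tie-free, and a normal approximation with tie and continuity
#' correction otherwise. When every observation is tied the statistic carries
#' no information and p = 0.5 by symmetry.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact_limit Use the exact null distribution when
#'   `length(x) + length(y) <= exact_limit` and there are no ties
#'   (default 10).
#' @param correct Apply the continuity correction on the approximate path
#'   (default TRUE).
#' @return List with `U` (Mann-Whitney statistic for x) and `p`.
#' @export
wilcoxon_one_sided <- function(x, y, exact_limit = 10, correct = TRUE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && N <= exact_limit) {
    p <- pwilcox(U - 1, n, m, lower.tail = FALSE)
  } else {
    t <- rle(sort.int(c(x, y), method = "quick"))$lengths
    sigma2 <- (n * m / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 0.5))
    z <- U - n * m / 2
    if (correct) z <- z - 0.5
    p <- pnorm(z / sqrt(sigma2), lower.tail = FALSE)
  }
  list(U = U, p = min(max(p, .Machine$double.xmin), 1))
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of raw p-values.
#' @param method `"bonferroni"` (min(1, p*m)) or `"bh"`
#'   (Benjamini-Hochberg step-up).
#' @return Adjusted p-values, input order preserved.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' log2 fold change between two groups of normalized values
#'
#' The default convention back-transforms the natural-log values with
#' `expm1`, averages within each group, adds a pseudocount and takes log2 of
#' the ratio. The alternative `"logmean"` convention is the difference of
#' group means of the log values, divided by ln(2).
#'
#' @param norm_in,norm_out Normalized (natural-log) values for the in- and
#'   out-group.
#' @param pseudocount Pseudocount added to both back-transformed means
#'   (default 1).
#' @param method `"expm1"` (default) or `"logmean"`.
#' @return Scalar log2 fold change.
#' @export
log2_fold_change <- function(norm_in, norm_out, pseudocount = 1,
                             method = c("expm1", "logmean")) {
  method <- match.arg(method)
  if (method == "expm1")
    log2((mean(expm1(norm_in)) + pseudocount) /
           (mean(expm1(norm_out)) + pseudocount))
  else (mean(norm_in) - mean(norm_out)) / log(2)
}

#' One-versus-all differential expression / activity
#'
#' Every feature is tested in each group against the pooled remaining cells
#' with the one-sided ("greater in the in-group") Wilcoxon rank-sum test
#' (normal approximation with tie and continuity correction, vectorized over
#' features). P-values are adjusted across features within each group.
#'
#' @param mat Real matrix, features x cells, with feature ids as rownames.
#' @param labels Per-cell group labels.
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @param lfc_method How the effect-size column is computed: `"expm1"`
#'   (back-transformed ratio of group means with pseudocount, the expression
#'   convention), `"logmean"` (difference of log means / ln 2) or
#'   `"meandiff"` (plain difference of group means, the convention for
#'   z-scored activity matrices).
#' @param pseudocount Pseudocount for the `"expm1"` convention (default 1).
#' @param min_cells Groups smaller than this are skipped with a warning
#'   (default 3).
#' @return data.frame with one row per (feature, group): `log2fc`, `p_raw`,
#'   `p_adj`, `frac_in`, `frac_out` (fraction of cells with value > 0),
#'   `n_in`, `n_out`.
#' @export
de_one_vs_all <- function(mat, labels,
                          adjust_method = c("bonferroni", "bh"),
                          lfc_method = c("expm1", "logmean", "meandiff"),
                          pseudocount = 1, min_cells = 3) {
  adjust_method <- match.arg(adjust_method)
  lfc_method <- match.arg(lfc_method)
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(labels))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%d", seq_len(nrow(mat)))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("skipping group(s) below ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  N <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  tie_term <- apply(mat, 1, function(x)
    sum(rle(sort.int(x, method = "quick"))$lengths^3) - N)
  ind <- outer(labels, groups, "==") * 1              # cells x groups
  n_in <- colSums(ind)
  R_in <- ranks %*% ind                               # features x groups
  det_in <- (mat > 0) %*% ind
  det_all <- rowSums(mat > 0)
  sum_in <- mat %*% ind
  sum_all <- rowSums(mat)
  if (lfc_method == "expm1") {
    e <- expm1(mat)
    esum_in <- e %*% ind
    esum_all <- rowSums(e)
  }
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    n1 <- n_in[gi]; n2 <- N - n1
    U <- R_in[, gi] - n1 * (n1 + 1) / 2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U - n1 * n2 / 2 - 0.5) / sqrt(pmax(sigma2, 0))
    p <- ifelse(sigma2 <= 0, 0.5, pnorm(z, lower.tail = FALSE))
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    lfc <- switch(lfc_method,
      expm1 = log2((esum_in[, gi] / n1 + pseudocount) /
                     ((esum_all - esum_in[, gi]) / n2 + pseudocount)),
      logmean = (sum_in[, gi] / n1 -
                   (sum_all - sum_in[, gi]) / n2) / log(2),
      meandiff = sum_in[, gi] / n1 - (sum_all - sum_in[, gi]) / n2)
    out[[gi]] <- data.frame(
      feature = rownames(mat), group = groups[gi], log2fc = as.vector(lfc),
      p_raw = as.vector(p),
      p_adj = adjust_pvalues(as.vector(p), adjust_method),
      frac_in = as.vector(det_in[, gi]) / n1,
      frac_out = (det_all - as.vector(det_in[, gi])) / n2,
      n_in = n1, n_out = n2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
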