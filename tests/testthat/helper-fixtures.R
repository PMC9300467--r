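# Small simulation used across test files (cheap but large enough for the
# planted effects to clear every gate).
small_config <- function(seed = 1, cells_per_type = 80, n_genes = 400, ...) {
  sim_config(n_cell_types = 4, cells_per_type = cells_per_type,
             n_genes = n_genes, n_regulons = 4, n_motifs = 4,
             targets_per_regulon = 8, n_peaks = 300,
             n_planted_interactions = 4, n_decoy_interactions = 4,
             seed = seed, ...)
}

# medium simulation (enough cells for stable planted recovery), memoised
.fixture_cache <- new.env(parent = emptyenv())
midi_sim <- function() {
  if (is.null(.fixture_cache$midi)) {
    cfg <- sim_config(n_cell_types = 4, cells_per_type = 150, n_genes = 500,
                      n_regulons = 4, n_motifs = 4, targets_per_regulon = 8,
                      n_peaks = 300, n_planted_interactions = 4,
                      n_decoy_interactions = 4, seed = 101)
    sim <- simulate_counts(cfg)
    norm <- normalize_log_cpm100(sim$counts)
    labels <- sim$counts$cell_meta$cell_type
    .fixture_cache$midi <- list(
      cfg = cfg, sim = sim, norm = norm, labels = labels,
      profile = profile_cell_types(norm, sim$counts),
      de = de_one_vs_all(t(norm$values), labels))
  }
  .fixture_cache$midi
}

# hand-built count matrix from a dense matrix
toy_counts <- function(m, types, samples = "s1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  count_matrix(Matrix::Matrix(m, sparse = TRUE),
               data.frame(cell_id = rownames(m),
                          cell_type = rep(types, length.out = nrow(m)),
                          sample = samples))
}

# hand-built cell type expression profile
toy_profile <- function(fraction, mean_norm = fraction) {
  structure(list(fraction = fraction, mean_norm = mean_norm,
                 n_cells = stats::setNames(rep(10, nrow(fraction)),
                                           rownames(fraction))),
            class = "CellTypeProfile")
}

toy_db <- function(partners, interactions) {
  interaction_db(partners, interactions)
}

# Exact one-sided rank-sum p by full enumeration over rank splits (no ties):
# the ranks are 1..N, and every size-n subset is equally likely under H0.
wilcox_enum_oracle <- function(x, y) {
  n <- length(x); N <- n + length(y)
  obs <- sum(rank(c(x, y))[seq_len(n)])
  splits <- utils::combn(N, n)
  mean(colSums(splits) >= obs)
}

# Hand step-up (BH) and step-down (Bonferroni) references
bh_oracle <- function(p) {
  m <- length(p)
  i <- order(p)
  sorted <- p[i] * m / seq_len(m)
  sorted <- rev(cummin(rev(sorted)))
  out <- numeric(m)
  out[i] <- pmin(sorted, 1)
  out
}
bonferroni_oracle <- function(p) pmin(p * length(p), 1)
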