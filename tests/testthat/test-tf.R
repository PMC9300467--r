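test_that("regulon activity equals the signed weighted-mean z formula", {
  set.seed(8)
  values <- matrix(rnorm(30 * 12), 30, 12,
                   dimnames = list(sprintf("c%02d", 1:30),
                                   sprintf("g%02d", 1:12)))
  values <- values - min(values)          # normalized values are >= 0
  reg <- data.frame(tf = rep(c("TFa", "TFb"), each = 5),
                    target = sprintf("g%02d", 1:10),
                    mode = c(1, 1, 1, -1, -1, rep(1, 5)),
                    weight = c(rep(1, 5), seq(0.2, 1, 0.2)))
  act <- regulon_activity(values, reg)
  z <- scale(values)
  for (tfg in c("TFa", "TFb")) {
    rr <- reg[reg$tf == tfg, ]
    manual <- as.vector(z[, rr$target] %*% (rr$mode * rr$weight)) /
      sqrt(sum(rr$weight^2))
    expect_equal(unname(act[tfg, ]), manual, tolerance = 1e-12)
  }
  # linear in the signature: adding a constant shift to one gene's values
  # scales through the z-score, and an all-constant gene contributes 0
  values2 <- cbind(values, gflat = 1)
  reg2 <- data.frame(tf = "TFc", target = c(sprintf("g%02d", 1:4), "gflat"),
                     mode = 1, weight = 1)
  act2 <- regulon_activity(values2, reg2)
  manual <- rowSums(z[, sprintf("g%02d", 1:4)]) / sqrt(5)
  expect_equal(unname(act2["TFc", ]), unname(manual), tolerance = 1e-12)
})

test_that("regulons with missing targets are pruned or dropped", {
  values <- matrix(abs(rnorm(20 * 6)), 20, 6,
                   dimnames = list(NULL, sprintf("g%d", 1:6)))
  reg <- data.frame(tf = "TFa",
                    target = c(sprintf("g%d", 1:5), "ghost1"),
                    mode = 1, weight = 1)
  expect_warning(act <- regulon_activity(values, reg), "absent")
  expect_equal(nrow(act), 1)
  reg2 <- data.frame(tf = "TFa", target = c("g1", "g2", "ghost1", "ghost2",
                                            "ghost3"), mode = 1, weight = 1)
  suppressWarnings(expect_error(regulon_activity(values, reg2), "no usable"))
})

test_that("peak filters apply inclusive width bounds, blacklist and cluster fraction", {
  n_cells <- 100
  peaks <- data.frame(
    peak_id = sprintf("p%d", 1:6), chrom = "chr1",
    start = c(1000, 3000, 5000, 8000, 11000, 13000),
    end = c(1000 + 209, 3000 + 210, 5000 + 1500, 8000 + 1501,
             11000 + 400, 13000 + 400),
    gc = 0.5)
  acc <- matrix(0, 6, n_cells,
                dimnames = list(peaks$peak_id, sprintf("c%03d", 1:n_cells)))
  acc[1:5, 1:50] <- 1                   # widely accessible
  acc[6, 1:4] <- 1                      # exactly 4% of 100 cells
  annot <- matrix(0, 6, 1, dimnames = list(peaks$peak_id, "M1"))
  pa <- peak_accessibility(peaks, Matrix::Matrix(acc, sparse = TRUE),
                           Matrix::Matrix(annot, sparse = TRUE),
                           c(M1 = "TF1"))
  out <- filter_peaks(pa, blacklist = NULL)
  expect_setequal(out$peaks$peak_id, c("p2", "p3", "p5", "p6"))  # 209/1501 out
  # 3% accessibility fails, 4% passes (inclusive)
  acc3 <- acc; acc3[6, ] <- 0; acc3[6, 1:3] <- 1
  pa3 <- peak_accessibility(peaks, Matrix::Matrix(acc3, sparse = TRUE),
                            Matrix::Matrix(annot, sparse = TRUE),
                            c(M1 = "TF1"))
  expect_false("p6" %in% filter_peaks(pa3)$peaks$peak_id)
  # a single-bp blacklist overlap drops the peak (0-based half-open)
  bl <- data.frame(chrom = "chr1", start = 11000, end = 11001)
  expect_false("p5" %in% filter_peaks(pa, bl)$peaks$peak_id)
  # an interval that only abuts (end == start of peak) does not overlap
  bl2 <- data.frame(chrom = "chr1", start = 10999, end = 11000)
  expect_true("p5" %in% filter_peaks(pa, bl2)$peaks$peak_id)
  expect_error(filter_peaks(pa, min_cluster_fraction = 1.01), "no peak")
})

test_that("motif deviations are centred under a null and permutation-equivariant", {
  cfg <- small_config(seed = 12, motif_effect = 0)
  sim <- simulate_counts(cfg)
  acc <- simulate_accessibility(cfg, sim$truth, sim$counts$cell_meta)
  pa <- filter_peaks(acc$access, acc$blacklist, acc$cluster_labels)
  dev <- motif_deviations(pa, n_background = 25, seed = 1)
  expect_true(all(abs(rowMeans(dev)) < 0.3))
  # identical seeds reproduce exactly
  dev2 <- motif_deviations(pa, n_background = 25, seed = 1)
  expect_identical(dev, dev2)
  # permuting cells permutes the scores: background sets depend on peaks only
  perm <- sample(ncol(pa$access))
  pa_perm <- peak_accessibility(pa$peaks, pa$access[, perm],
                                pa$motif_annot, pa$motif_tf)
  dev_perm <- motif_deviations(pa_perm, n_background = 25, seed = 1)
  expect_equal(dev_perm, dev[, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a planted motif has positive mean deviation in its cell type", {
  for (seed in c(21, 22, 23)) {
    cfg <- small_config(seed = seed)
    sim <- simulate_counts(cfg)
    acc <- simulate_accessibility(cfg, sim$truth, sim$counts$cell_meta)
    pa <- filter_peaks(acc$access, acc$blacklist, acc$cluster_labels)
    dev <- motif_deviations(pa, n_background = 25, seed = seed)
    labels <- acc$cluster_labels[colnames(pa$access)]
    for (i in seq_len(nrow(sim$truth$planted_motif_tfs))) {
      row <- sim$truth$planted_motif_tfs[i, ]
      expect_gt(mean(dev[row$tf, labels == row$cell_type]), 0)
    }
  }
})

test_that("activity DE finds nothing between identical groups", {
  set.seed(5)
  act <- matrix(rnorm(4 * 60), 4, 60,
                dimnames = list(sprintf("TF%d", 1:4), NULL))
  de <- activity_de(act, rep(c("A", "B"), 30))
  expect_equal(sum(de$p_adj < 0.01 & de$log2fc > 0.75), 0)
})

test_that("prioritization combines the three evidence layers with strict gates", {
  mk_de <- function(lfc, padj) data.frame(
    feature = "TFX", group = "T1", log2fc = lfc, p_raw = padj, p_adj = padj,
    frac_in = 1, frac_out = 1, n_in = 10, n_out = 10)
  thr <- tf_priority_thresholds()
  # expression + regulon pass, motif fails -> prioritized
  out <- prioritize_tfs(mk_de(0.6, 1e-3), mk_de(0.8, 5e-3), mk_de(0.1, 0.9),
                        thr, tfs = "TFX")
  expect_true(out$prioritized)
  expect_true(out$expr_pass && out$regulon_pass && !out$motif_pass)
  # expression below the 0.5 gate -> not prioritized despite both activities
  out2 <- prioritize_tfs(mk_de(0.4, 1e-3), mk_de(2, 1e-3), mk_de(2, 1e-3),
                         thr, tfs = "TFX")
  expect_false(out2$prioritized)
  # expression passes, both activities fail -> not prioritized
  out3 <- prioritize_tfs(mk_de(2, 1e-3), mk_de(0.7, 1e-3), NULL, thr,
                         tfs = "TFX")
  expect_false(out3$prioritized)
  # boundary: activity effect exactly 0.75 fails, just above passes
  expect_false(prioritize_tfs(mk_de(2, 1e-3), mk_de(0.75, 1e-3), NULL, thr,
                              tfs = "TFX")$prioritized)
  expect_true(prioritize_tfs(mk_de(2, 1e-3), mk_de(0.7501, 1e-3), NULL, thr,
                             tfs = "TFX")$prioritized)
  # missing motif modality yields FALSE, never NA
  expect_false(is.na(out3$motif_pass))
})

test_that("prioritization is monotone in the thresholds", {
  set.seed(31)
  rnd_de <- function() data.frame(
    feature = rep(sprintf("TF%d", 1:5), 2),
    group = rep(c("A", "B"), each = 5),
    log2fc = runif(10, -1, 2), p_raw = runif(10), p_adj = runif(10),
    frac_in = 1, frac_out = 1, n_in = 10, n_out = 10)
  for (i in 1:10) {
    e <- rnd_de(); r <- rnd_de(); m <- rnd_de()
    strictv <- prioritize_tfs(e, r, m)
    relaxed <- prioritize_tfs(e, r, m, tf_priority_thresholds(
      expr_log2fc_min = 0.2, expr_padj_max = 0.05,
      act_log2fc_min = 0.3, act_padj_max = 0.05))
    key <- function(d) paste(d$tf, d$cell_type)[d$prioritized]
    expect_true(all(key(strictv) %in% key(relaxed)))
  }
})

test_that("planted TFs are the exactly prioritized set on synthetic data", {
  fx <- midi_sim()
  reg_act <- regulon_activity(fx$norm, fx$sim$regulons)
  reg_de <- activity_de(reg_act, fx$labels)
  acc <- simulate_accessibility(fx$cfg, fx$sim$truth, fx$sim$counts$cell_meta)
  pa <- filter_peaks(acc$access, acc$blacklist, acc$cluster_labels)
  dev <- motif_deviations(pa, n_background = 25, seed = 1)
  mot_de <- activity_de(dev, acc$cluster_labels)
  pri <- prioritize_tfs(fx$de, reg_de, mot_de)
  got <- with(pri[pri$prioritized, ], paste(tf, cell_type))
  want <- with(fx$sim$truth$planted_active_tfs, paste(tf, cell_type))
  expect_setequal(got, want)
})
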