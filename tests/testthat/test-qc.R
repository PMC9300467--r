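# Build a matrix where each cell's detected-gene count, total counts and
# mitochondrial fraction are controlled exactly.
qc_fixture <- function() {
  n_norm <- 690
  genes <- c(sprintf("g%03d", seq_len(n_norm)), sprintf("MT-%d", 1:10))
  mk_cell <- function(n_detected, per_gene, mito) {
    v <- numeric(length(genes))
    v[seq_len(n_detected)] <- per_gene
    v[n_norm + 1] <- mito
    v
  }
  cells <- rbind(
    base1 = mk_cell(600, 3, 30),     # kept: 601 genes, mito 30/1830 = 1.6%
    base2 = mk_cell(600, 3, 30),
    base3 = mk_cell(600, 3, 30),
    lowgenes = mk_cell(450, 4, 30),  # dropped: 451 genes detected
    joint = mk_cell(610, 2, 168),    # mito 168/1388 = 12.1% AND total < 1500
    mitook = mk_cell(586, 3, 240),   # mito 240/1998 = 12% but total >= 1500
    himito = mk_cell(520, 3, 525)    # mito 525/2085 = 25.2% -> dropped
  )
  colnames(cells) <- genes
  cells
}

test_that("cell filters follow the detected-gene, mito and joint rules", {
  m <- qc_fixture()
  cm <- toy_counts(m, "T1")
  out <- qc_filter(cm, qc_thresholds(min_cells_per_gene = 1))
  kept <- rownames(out$counts)
  expect_true(all(c("base1", "base2", "base3", "mitook") %in% kept))
  expect_false("lowgenes" %in% kept)   # fewer than 500 genes
  expect_false("joint" %in% kept)      # >10% mito AND <1500 counts
  expect_false("himito" %in% kept)     # >20% mito regardless of counts
  rep <- attr(out, "qc_report")
  expect_equal(rep$cells_low_genes, 1)
  expect_equal(rep$cells_high_mito, 1)
})

test_that("genes detected in too few cells are removed before cell rules", {
  m <- matrix(3, 6, 600)
  colnames(m) <- sprintf("g%03d", 1:600)
  m <- cbind(m, gRare = c(1, 1, 0, 0, 0, 0))   # detected in 2 cells
  cm <- toy_counts(m, "T1")
  out <- qc_filter(cm, qc_thresholds(min_genes_per_cell = 10))
  expect_false("gRare" %in% colnames(out$counts))
  expect_equal(ncol(out$counts), 600)
})

test_that("qc_filter is idempotent and can fail loudly", {
  cfg <- small_config(seed = 6)
  sim <- simulate_counts(cfg)
  thr <- qc_thresholds(min_genes_per_cell = 50)  # scaled to the 400-gene sim
  once <- qc_filter(sim$counts, thr)
  twice <- qc_filter(once, thr)
  expect_identical(dim(once), dim(twice))
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
  expect_error(qc_filter(sim$counts,
                         qc_thresholds(min_genes_per_cell = 1e6)),
               "every cell")
})

test_that("normalization matches the log(CPM/100 + 1) closed form", {
  m <- matrix(c(1, 3, 0, 8), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  cm <- toy_counts(m, "T1")
  norm <- normalize_log_cpm100(cm)
  expect_equal(norm$values["c1", "g1"], log(1 / 4 * 1e4 + 1))  # ln(2501)
  expect_equal(norm$values["c1", "g1"], 7.8245, tolerance = 1e-4)
  expect_equal(norm$values["c2", "g1"], 0)                     # zero count
  # scale invariance: doubling a cell's counts changes nothing
  cm2 <- toy_counts(m * 2, "T1")
  expect_equal(normalize_log_cpm100(cm2)$values, norm$values)
  # monotone within a cell
  expect_gt(norm$values["c1", "g2"], norm$values["c1", "g1"])
  expect_error(normalize_log_cpm100(toy_counts(matrix(0, 1, 2), "T1")),
               "zero total")
})

test_that("cell type profiles match a brute-force recount", {
  set.seed(42)
  m <- matrix(rpois(20 * 15, 0.8), 20, 15)
  cm <- toy_counts(m, c("A", "B"))
  norm <- normalize_log_cpm100(toy_counts(m + 1, c("A", "B"))) # avoid 0 rows
  cm <- toy_counts(m + 1, c("A", "B"))
  norm <- normalize_log_cpm100(cm)
  prof <- profile_cell_types(norm, cm)
  for (ty in c("A", "B")) {
    rows <- cm$cell_meta$cell_type == ty
    for (g in seq_len(15)) {
      expect_equal(prof$fraction[ty, g],
                   mean(as.matrix(cm$counts)[rows, g] > 0))
      expect_equal(prof$mean_norm[ty, g], mean(norm$values[rows, g]))
    }
  }
  expect_true(all(prof$fraction >= 0 & prof$fraction <= 1))
  expect_equal(sum(prof$n_cells), 20)
})

test_that("profile handles the 1-in-10 and all-zero edge cases", {
  m <- matrix(0, 10, 2, dimnames = list(sprintf("c%02d", 1:10), c("g1", "g2")))
  m[1, 1] <- 5
  m[, 2] <- 0
  m2 <- cbind(m, filler = 1)  # keep totals positive
  cm <- toy_counts(m2, "T1")
  prof <- profile_cell_types(normalize_log_cpm100(cm), cm)
  expect_equal(unname(prof$fraction["T1", "g1"]), 0.10)
  expect_equal(unname(prof$fraction["T1", "g2"]), 0)
  expect_equal(unname(prof$mean_norm["T1", "g2"]), 0)
})

test_that("TF-IDF markers follow the closed form and recover planted markers", {
  # 100 cells, cluster A = first 10; gene gA detected only in all of A
  m <- matrix(0, 100, 3,
              dimnames = list(sprintf("c%03d", 1:100), c("gA", "gEvery", "gFill")))
  m[1:10, "gA"] <- 1
  m[, "gEvery"] <- 1
  m[, "gFill"] <- 1
  cm <- toy_counts(m, rep(c("A", "B"), c(10, 90)))
  mk <- tfidf_markers(cm, top_n = 2)
  a <- mk[mk$cluster == "A" & mk$gene == "gA", ]
  expect_equal(a$score, log(10), tolerance = 1e-12)         # 1 x ln(100/10)
  expect_equal(mk$score[mk$gene == "gEvery"], rep(0, 2))    # idf = 0
  expect_error(tfidf_markers(toy_counts(m, "onlyone")), "2 clusters")

  sim <- midi_sim()
  mk <- tfidf_markers(sim$sim$counts, top_n = 10)
  for (i in seq_len(sim$cfg$n_cell_types)) {
    ty <- sprintf("CT%d", i)
    planted <- sprintf("MK%d_%d", i, 1:5)
    expect_true(all(planted %in% mk$gene[mk$cluster == ty]))
  }
})
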