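ccc_fixture_db <- function() {
  toy_db(
    data.frame(partner_id = c("L1", "R1", "CPLX", "EZ"),
               kind = c("gene", "gene", "complex", "enzyme_proxy"),
               members = c("L1", "R1", "CA,CB", "CYP19A1")),
    data.frame(interaction_id = c("i1", "i2", "i3"),
               partner_a = c("L1", "L1", "EZ"),
               partner_b = c("R1", "CPLX", "R1"),
               directionality = c("ligand_receptor", "ligand_receptor",
                                  "ligand_receptor"),
               annotation = ""))
}

ccc_fixture_profile <- function(frac) {
  genes <- colnames(frac)
  toy_profile(frac, matrix(1, nrow(frac), ncol(frac),
                           dimnames = dimnames(frac)))
}

test_that("partner expression requires every member at or above the fraction gate", {
  frac <- matrix(c(0.12, 0.09, 0.10, 0.55, 0, 0.5), 1, 6,
                 dimnames = list("T1", c("CA", "CB", "CA2", "CB2", "L1",
                                         "CYP19A1")))
  db <- toy_db(
    data.frame(partner_id = c("CPLX", "CPLX2", "L1", "EZ"),
               kind = c("complex", "complex", "gene", "enzyme_proxy"),
               members = c("CA,CB", "CA2,CB2", "L1", "CYP19A1")),
    data.frame(interaction_id = "i", partner_a = "L1", partner_b = "CPLX",
               directionality = "ligand_receptor", annotation = ""))
  prof <- ccc_fixture_profile(frac)
  expect_false(partner_expressed(prof, db, "CPLX", "T1"))  # 0.09 member fails
  expect_true(partner_expressed(prof, db, "CPLX2", "T1")) # 0.10 is inclusive
  expect_false(partner_expressed(prof, db, "L1", "T1"))   # fraction 0
  expect_true(partner_expressed(prof, db, "EZ", "T1"))    # enzyme gene gate
  db2 <- toy_db(data.frame(partner_id = "GH", kind = "gene", members = "ghost"),
                data.frame(interaction_id = "i", partner_a = "GH",
                           partner_b = "GH", directionality = "undirected",
                           annotation = ""))
  expect_warning(ok <- partner_expressed(prof, db2, "GH", "T1"), "absent")
  expect_false(ok)
})

test_that("retrieval requires expression on both sides plus a DE member", {
  db <- ccc_fixture_db()
  genes <- c("L1", "R1", "CA", "CB", "CYP19A1")
  frac <- rbind(S = c(0.5, 0.5, 0.5, 0.5, 0.5),
                R = c(0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(frac) <- genes
  prof <- ccc_fixture_profile(frac)
  de_none <- data.frame(feature = genes, group = "S", log2fc = 0,
                        p_raw = 1, p_adj = 1, frac_in = 0.5, frac_out = 0.5,
                        n_in = 10, n_out = 10)
  expect_equal(nrow(retrieve_relevant(prof, de_none, db)), 0)

  de_l1 <- de_none
  de_l1$log2fc[de_l1$feature == "L1"] <- 1.5
  de_l1$p_adj[de_l1$feature == "L1"] <- 1e-5
  rel <- retrieve_relevant(prof, de_l1, db)
  # L1 is DE in S only: all interactions with ligand L1, sender S, any receiver
  expect_true(all(rel$sender_type == "S"))
  expect_setequal(unique(rel$interaction_id), c("i1", "i2"))
  expect_true(all(rel$de_partner == "a"))
  expect_true(all(rel$de_genes == "L1"))

  # receptor-side DE is enough too, and is attributed to partner b
  de_r1 <- de_none
  de_r1$group <- "R"
  de_r1$log2fc[de_r1$feature == "R1"] <- 1
  de_r1$p_adj[de_r1$feature == "R1"] <- 1e-4
  rel_b <- retrieve_relevant(prof, de_r1, db)
  expect_true(all(rel_b$receiver_type == "R"))
  expect_true(all(rel_b$de_partner == "b"))
})

test_that("DE gates are strict and the fraction gate monotone", {
  db <- toy_db(data.frame(partner_id = c("L1", "R1"), kind = "gene",
                          members = c("L1", "R1")),
               data.frame(interaction_id = "i1", partner_a = "L1",
                          partner_b = "R1",
                          directionality = "ligand_receptor", annotation = ""))
  frac <- rbind(S = c(L1 = 0.11, R1 = 0.5), R = c(L1 = 0.11, R1 = 0.5))
  prof <- ccc_fixture_profile(frac)
  de_at <- function(lfc, padj) data.frame(
    feature = "L1", group = "S", log2fc = lfc, p_raw = padj, p_adj = padj,
    frac_in = 0.5, frac_out = 0.5, n_in = 10, n_out = 10)
  # boundary: log2fc must be ABOVE 0.2, padj BELOW 0.01
  expect_equal(nrow(retrieve_relevant(prof, de_at(0.2, 1e-5), db)), 0)
  expect_gt(nrow(retrieve_relevant(prof, de_at(0.2001, 1e-5), db)), 0)
  expect_equal(nrow(retrieve_relevant(prof, de_at(1, 0.01), db)), 0)
  expect_gt(nrow(retrieve_relevant(prof, de_at(1, 0.0099), db)), 0)
  # raising the fraction gate can only shrink the result
  lo <- retrieve_relevant(prof, de_at(1, 1e-5), db, ccc_thresholds())
  hi <- retrieve_relevant(prof, de_at(1, 1e-5), db,
                          ccc_thresholds(min_fraction = 0.60))
  key <- function(d) paste(d$interaction_id, d$sender_type, d$receiver_type)
  expect_true(all(key(hi) %in% key(lo)))
  expect_equal(nrow(hi), 0)
})

test_that("microenvironment filtering is shared-zone set intersection", {
  rel <- data.frame(interaction_id = c("i1", "i2"),
                    sender_type = c("A", "B"), receiver_type = c("C", "C"),
                    ligand_partner = "L", receptor_partner = "R",
                    de_partner = "a", de_genes = "L", shared_zones = "",
                    cellsign_tfs = "", cellsign_active = "",
                    supported = FALSE)
  env <- data.frame(
    cell_type = c("A", "B", "B", "C"),
    zone = c("medulla", "inner_cortex", "medulla", "outer_cortex"))
  out <- filter_by_microenvironment(rel, env)  # nobody shares with C
  expect_equal(nrow(out), 0)
  env2 <- rbind(env, data.frame(cell_type = "C", zone = "medulla"))
  out2 <- filter_by_microenvironment(rel, env2)
  expect_equal(out2$interaction_id, c("i1", "i2"))
  expect_equal(out2$shared_zones, c("medulla", "medulla"))
  expect_error(
    filter_by_microenvironment(transform(rel, sender_type = "ghost"), env),
    "ghost")
})

test_that("CellSign support requires an active downstream TF in the receiver", {
  rel <- data.frame(interaction_id = "i1", sender_type = "S",
                    receiver_type = "R", ligand_partner = "L1",
                    receptor_partner = "R1", de_partner = "a", de_genes = "L1",
                    shared_zones = "z", cellsign_tfs = "",
                    cellsign_active = "", supported = FALSE)
  cs <- data.frame(receptor_partner_id = "R1", tf_gene = "TFX",
                   evidence_ref = "PMID:1")
  out <- annotate_cellsign(rel, cs, list(R = "TFX"))
  expect_true(out$supported)
  expect_equal(out$cellsign_active, "TFX")
  out2 <- annotate_cellsign(rel, cs, list(R = "OTHER"))
  expect_false(out2$supported)
  expect_equal(out2$cellsign_tfs, "TFX")
  # receptor absent from the table: empty list, unsupported, no error
  rel3 <- transform(rel, receptor_partner = "R9")
  out3 <- annotate_cellsign(rel3, cs, list(R = "TFX"))
  expect_false(out3$supported)
  expect_equal(out3$cellsign_tfs, "")
})

test_that("planted interactions are recovered and decoys excluded on synthetic data", {
  fx <- midi_sim()
  rel <- retrieve_relevant(fx$profile, fx$de, fx$sim$db)
  rel <- filter_by_microenvironment(rel, fx$sim$microenv)
  truth <- fx$sim$truth
  key <- paste(rel$interaction_id, rel$sender_type, rel$receiver_type)
  truth_key <- with(truth$planted_interactions,
                    paste(interaction_id, sender_type, receiver_type))
  expect_true(all(truth_key %in% key))                       # recall 1
  expect_equal(intersect(rel$interaction_id,
                         truth$decoys$interaction_id), character(0))
  # output sorted deterministically
  expect_identical(key, sort(key))
})
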