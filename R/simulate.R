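#' Default cell type to zone assignment for simulations
#'
#' Cycles cell types through single- and double-zone patterns over the
#' three-zone vocabulary so that both overlapping and disjoint sender/receiver
#' zone pairs exist.
#'
#' @param n_cell_types Number of cell types.
#' @param zones Zone vocabulary (three zones expected).
#' @return Named list mapping cell type -> character vector of zones.
#' @export
default_zone_assignment <- function(n_cell_types, zones = default_zones()) {
  patterns <- list(zones[1], zones[1:2], zones[2], zones[2:3], zones[3], zones[3])
  out <- lapply(seq_len(n_cell_types),
                function(i) patterns[[(i - 1L) %% length(patterns) + 1L]])
  names(out) <- sprintf("CT%d", seq_len(n_cell_types))
  out
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: an overdispersed negative-binomial
#' count model with planted cell-type markers, planted zone-restricted
#' ligand-receptor interactions (plus decoys that must not be recovered),
#' planted TF regulons whose targets shift in the TF's active cell type, and
#' motif-enriched binary accessibility.
#'
#' @param n_cell_types Number of cell types (default 6).
#' @param cells_per_type Cells per type (default 300).
#' @param n_genes Total genes (default 1500).
#' @param nb_dispersion Negative-binomial dispersion; variance =
#'   mu + dispersion * mu^2 (default 0.5).
#' @param baseline_mean Scale of per-gene baseline means (counts/cell,
#'   default 1); background baselines are drawn log-normally around it.
#' @param marker_log2fc log2 fold change planted for cell-type marker genes
#'   and for planted-active TF genes in their type (default 2).
#' @param n_planted_interactions Planted ligand-receptor interactions
#'   (default 6).
#' @param n_decoy_interactions Decoy interactions, split between
#'   zone-mismatch and below-detection-fraction constructions (default 4).
#' @param planted_interaction_log2fc log2 fold change of ligand genes in
#'   sender types and receptor genes in receiver types (default 2).
#' @param zone_assignment Named list cell type -> zone set; default
#'   [default_zone_assignment()].
#' @param n_regulons Number of planted TF regulons (default 6).
#' @param targets_per_regulon Targets per regulon (default 10).
#' @param regulon_effect Natural-log shift of target means in the TF's
#'   planted-active cell type, signed by the regulation mode (default 1).
#' @param n_peaks Accessibility peaks (default 1000).
#' @param n_motifs Motifs, mapped 1:1 to regulon TFs (default = n_regulons).
#' @param motif_effect Additive accessibility-probability increase for motif
#'   peaks in the motif TF's planted cell type (default 0.3).
#' @param seed Integer RNG seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_cell_types = 6, cells_per_type = 300, n_genes = 1500,
                       nb_dispersion = 0.5, baseline_mean = 1,
                       marker_log2fc = 2, n_planted_interactions = 6,
                       n_decoy_interactions = 4,
                       planted_interaction_log2fc = 2,
                       zone_assignment = default_zone_assignment(n_cell_types),
                       n_regulons = 6, targets_per_regulon = 10,
                       regulon_effect = 1, n_peaks = 1000,
                       n_motifs = n_regulons, motif_effect = 0.3, seed = 1) {
  cfg <- list(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
              n_genes = n_genes, nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean, marker_log2fc = marker_log2fc,
              n_planted_interactions = n_planted_interactions,
              n_decoy_interactions = n_decoy_interactions,
              planted_interaction_log2fc = planted_interaction_log2fc,
              zone_assignment = zone_assignment, n_regulons = n_regulons,
              targets_per_regulon = targets_per_regulon,
              regulon_effect = regulon_effect, n_peaks = n_peaks,
              n_motifs = n_motifs, motif_effect = motif_effect,
              seed = as.integer(seed))
  stopifnot(n_cell_types >= 2, cells_per_type >= 10, n_genes >= 50,
            nb_dispersion > 0, baseline_mean > 0)
  if (length(zone_assignment) != n_cell_types)
    stop("zone_assignment must name every cell type")
  class(cfg) <- "SimConfig"
  cfg
}

sim_cell_types <- function(config) sprintf("CT%d", seq_len(config$n_cell_types))

n_markers_per_type <- 5L   # fixed marker budget per cell type

# Lay out which gene ids play which role; deterministic given the config.
sim_gene_design <- function(config) {
  n_pl <- config$n_planted_interactions
  n_dc <- config$n_decoy_interactions
  k <- config$n_regulons
  types <- sim_cell_types(config)

  lig <- sprintf("LIG%d", seq_len(n_pl + n_dc))
  rec <- sprintf("REC%d", seq_len(n_pl + n_dc))
  cplx_members <- if (n_pl >= 1) c("REC1A", "REC1B") else character()
  if (n_pl >= 1) rec[1] <- NA  # interaction 1 uses the complex instead
  enz <- if (n_pl >= 2) "ENZ2" else character()
  if (n_pl >= 2) lig[2] <- NA  # interaction 2 uses the enzyme proxy
  tf <- sprintf("TF%d", seq_len(k))
  targets <- as.vector(t(outer(seq_len(k), seq_len(config$targets_per_regulon),
                               function(i, j) sprintf("TF%d_T%02d", i, j))))
  markers <- as.vector(t(outer(seq_along(types), seq_len(n_markers_per_type),
                               function(i, j) sprintf("MK%d_%d", i, j))))
  role <- c(stats::na.omit(lig), stats::na.omit(rec), cplx_members, enz, tf,
            targets, markers)
  if (length(role) >= config$n_genes)
    stop("n_genes too small for the requested planted structure (needs > ",
         length(role), ")")
  bg <- sprintf("gB%04d", seq_len(config$n_genes - length(role)))
  list(ligand = lig, receptor = rec, complex_members = cplx_members,
       enzyme = enz, tf = tf, targets = targets, markers = markers,
       genes = c(role, bg))
}

zone_sharing_pairs <- function(zone_assignment, share = TRUE) {
  types <- names(zone_assignment)
  out <- list()
  for (s in types) for (r in types) {
    if (s == r) next
    ok <- length(intersect(zone_assignment[[s]], zone_assignment[[r]])) > 0
    if (ok == share) out[[length(out) + 1L]] <- c(s, r)
  }
  out
}

#' Simulate a single-cell count dataset with planted ground truth
#'
#' Draws negative-binomial counts per gene and cell type with log-normal
#' per-cell library-size factors. Ligand genes are upregulated in their
#' sender type and receptor genes in their receiver type; decoy interactions
#' are constructed either with sender/receiver in disjoint zones or with the
#' receptor kept below the detection-fraction gate. Regulon target means are
#' shifted (in natural-log units, signed by mode) in the type where the TF is
#' planted active, and marker/TF genes are upregulated in their own type.
#' Effects of exactly zero plant nothing: the corresponding truth entries are
#' empty, which is how null datasets are built.
#'
#' @param config A [sim_config()].
#' @return A list of class `ccc_simulation` with elements `counts`
#'   ([count_matrix()]), `truth` (planted interactions/TFs and decoys), `db`
#'   ([interaction_db()]), `cellsign`, `microenv`, `regulons`, and `design`
#'   (role gene ids, per-type mean matrix, size factors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_planted_interactions > 0 &&
      config$planted_interaction_log2fc > 0 &&
      config$planted_interaction_log2fc <= 0.2)
    stop("planted interaction effect overlaps the sub-threshold decoy regime ",
         "(log2fc must exceed 0.2 or be exactly 0)")
  set.seed(config$seed)
  types <- sim_cell_types(config)
  des <- sim_gene_design(config)
  genes <- des$genes
  n_genes <- config$n_genes
  n_pl <- config$n_planted_interactions
  n_dc <- config$n_decoy_interactions

  # baselines: role ligand/receptor genes sit below the 10% detection gate
  base <- stats::setNames(rlnorm(n_genes, meanlog = log(config$baseline_mean),
                                 sdlog = 1), genes)
  lr_genes <- c(stats::na.omit(des$ligand), stats::na.omit(des$receptor),
                des$complex_members, des$enzyme)
  base[lr_genes] <- config$baseline_mean * 0.05
  base[des$tf] <- config$baseline_mean
  base[des$targets] <- config$baseline_mean
  # markers are near-absent outside their type, strongly expressed within it
  base[des$markers] <- config$baseline_mean * 0.05

  mean_mat <- matrix(rep(base, each = length(types)), nrow = length(types),
                     dimnames = list(types, genes))

  # interaction partners and database ------------------------------------
  partner_rows <- list()
  inter_rows <- list()
  add_partner <- function(id, kind, members) {
    partner_rows[[length(partner_rows) + 1L]] <<-
      data.frame(partner_id = id, kind = kind,
                 members = paste(members, collapse = ","))
  }
  partner_for <- function(i, side) {
    if (side == "a") {
      if (!is.na(des$ligand[i])) {
        add_partner(des$ligand[i], "gene", des$ligand[i])
        list(id = des$ligand[i], genes = des$ligand[i])
      } else {
        id <- paste0("steroid_via_", des$enzyme)
        add_partner(id, "enzyme_proxy", des$enzyme)
        list(id = id, genes = des$enzyme)
      }
    } else {
      if (!is.na(des$receptor[i])) {
        add_partner(des$receptor[i], "gene", des$receptor[i])
        list(id = des$receptor[i], genes = des$receptor[i])
      } else {
        add_partner("RCPX1", "complex", des$complex_members)
        list(id = "RCPX1", genes = des$complex_members)
      }
    }
  }

  share_pairs <- zone_sharing_pairs(config$zone_assignment, TRUE)
  disj_pairs <- zone_sharing_pairs(config$zone_assignment, FALSE)
  if (n_pl > 0 && !length(share_pairs))
    stop("no zone-sharing cell type pair available for planted interactions")
  n_zm <- if (n_dc > 0) ceiling(n_dc / 2) else 0L  # zone-mismatch decoys
  if (n_zm > 0 && !length(disj_pairs))
    stop("zone-mismatch decoys require at least one disjoint-zone type pair")

  lfc <- config$planted_interaction_log2fc
  planted <- list()
  decoys <- list()
  pick <- function(pairs) pairs[[sample.int(length(pairs), 1L)]]

  for (i in seq_len(n_pl + n_dc)) {
    a <- partner_for(i, "a"); b <- partner_for(i, "b")
    iid <- sprintf("INT%02d", i)
    if (i <= n_pl) {
      sr <- pick(share_pairs)
      if (lfc > 0) {
        mean_mat[sr[1], a$genes] <- mean_mat[sr[1], a$genes] * 2^lfc
        mean_mat[sr[2], b$genes] <- mean_mat[sr[2], b$genes] * 2^lfc
        planted[[length(planted) + 1L]] <- data.frame(
          interaction_id = iid, sender_type = sr[1], receiver_type = sr[2],
          shared_zone = intersect(config$zone_assignment[[sr[1]]],
                                  config$zone_assignment[[sr[2]]])[1],
          ligand_partner = a$id, receptor_partner = b$id)
      }
    } else if (i <= n_pl + n_zm) {          # zone-mismatch decoy
      sr <- pick(disj_pairs)
      if (lfc > 0) {
        mean_mat[sr[1], a$genes] <- mean_mat[sr[1], a$genes] * 2^lfc
        mean_mat[sr[2], b$genes] <- mean_mat[sr[2], b$genes] * 2^lfc
      }
      decoys[[length(decoys) + 1L]] <- data.frame(
        interaction_id = iid, kind = "zone_mismatch",
        sender_type = sr[1], receiver_type = sr[2])
    } else {                                 # receptor stays sub-fraction
      sr <- pick(share_pairs)
      if (lfc > 0)
        mean_mat[sr[1], a$genes] <- mean_mat[sr[1], a$genes] * 2^lfc
      decoys[[length(decoys) + 1L]] <- data.frame(
        interaction_id = iid, kind = "sub_fraction",
        sender_type = sr[1], receiver_type = sr[2])
    }
    inter_rows[[length(inter_rows) + 1L]] <- data.frame(
      interaction_id = iid, partner_a = a$id, partner_b = b$id,
      directionality = "ligand_receptor",
      annotation = if (i <= n_pl) "planted" else "decoy")
  }

  # regulons, markers, TF expression --------------------------------------
  k <- config$n_regulons
  tpr <- config$targets_per_regulon
  reg_rows <- list()
  tf_type <- stats::setNames(types[(seq_len(k) - 1L) %% length(types) + 1L],
                             des$tf)
  tf_planted <- config$marker_log2fc > 0 &&
    (config$regulon_effect > 0 || config$motif_effect > 0)
  for (i in seq_len(k)) {
    tg <- des$targets[((i - 1L) * tpr + 1L):(i * tpr)]
    mode <- rep(1, tpr)
    if (tpr >= 5) mode[(tpr - 1L):tpr] <- -1   # a couple of repressed targets
    reg_rows[[i]] <- data.frame(tf = des$tf[i], target = tg, mode = mode,
                                weight = 1)
    ty <- tf_type[des$tf[i]]
    if (config$marker_log2fc > 0)
      mean_mat[ty, des$tf[i]] <- mean_mat[ty, des$tf[i]] * 2^config$marker_log2fc
    if (config$regulon_effect > 0)
      mean_mat[ty, tg] <- mean_mat[ty, tg] * exp(config$regulon_effect * mode)
  }
  if (config$marker_log2fc > 0) {
    for (i in seq_along(types)) {
      mk <- des$markers[((i - 1L) * n_markers_per_type + 1L):
                          (i * n_markers_per_type)]
      mean_mat[types[i], mk] <- config$baseline_mean * 2^config$marker_log2fc
    }
  }

  # draw counts ------------------------------------------------------------
  n_cells <- config$cells_per_type * length(types)
  cell_type <- rep(types, each = config$cells_per_type)
  cell_id <- sprintf("cell_%04d", seq_len(n_cells))
  sf <- rlnorm(n_cells, 0, 0.3)              # library-size variation
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, n_cells, n_genes, dimnames = list(cell_id, genes))
  for (ti in seq_along(types)) {
    rows <- which(cell_type == types[ti])
    mu <- outer(sf[rows], mean_mat[ti, ])
    counts[rows, ] <- rnbinom(length(mu), mu = mu, size = size)
  }
  meta <- data.frame(cell_id = cell_id, cell_type = cell_type,
                     sample = "sim1", zone = NA_character_)
  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), meta)

  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(interaction_id = character(), sender_type = character(),
               receiver_type = character(), shared_zone = character(),
               ligand_partner = character(), receptor_partner = character())
  decoy_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(interaction_id = character(), kind = character(),
               sender_type = character(), receiver_type = character())
  tf_df <- if (tf_planted)
    data.frame(cell_type = unname(tf_type), tf = names(tf_type)) else
    data.frame(cell_type = character(), tf = character())
  motif_df <- if (config$motif_effect > 0 && config$n_motifs > 0) {
    mt <- des$tf[seq_len(min(config$n_motifs, k))]
    data.frame(cell_type = unname(tf_type[mt]), tf = mt,
               motif_id = sprintf("MOTIF_%s", mt))
  } else data.frame(cell_type = character(), tf = character(),
                    motif_id = character())
  truth <- structure(list(planted_interactions = planted_df,
                          planted_active_tfs = tf_df,
                          planted_motif_tfs = motif_df,
                          decoys = decoy_df),
                     class = "SyntheticTruth")

  microenv <- do.call(rbind, lapply(names(config$zone_assignment), function(ct)
    data.frame(cell_type = ct, zone = config$zone_assignment[[ct]])))

  db <- interaction_db(unique(do.call(rbind, partner_rows)),
                       do.call(rbind, inter_rows))
  cs_rows <- list()
  if (nrow(planted_df) && nrow(tf_df)) {
    for (j in seq_len(nrow(planted_df))) {
      tfs <- tf_df$tf[tf_df$cell_type == planted_df$receiver_type[j]]
      for (tfg in tfs)
        cs_rows[[length(cs_rows) + 1L]] <- data.frame(
          receptor_partner_id = planted_df$receptor_partner[j],
          tf_gene = tfg, evidence_ref = "synthetic")
    }
  }
  cellsign <- if (length(cs_rows))
    cellsign_table(unique(do.call(rbind, cs_rows)), db) else
    data.frame(receptor_partner_id = character(), tf_gene = character(),
               evidence_ref = character())

  structure(list(counts = cm, truth = truth, db = db, cellsign = cellsign,
                 microenv = microenvironment_table(microenv),
                 regulons = regulon_set(do.call(rbind, reg_rows)),
                 config = config,
                 design = list(genes = des, base_means = base,
                               mean_matrix = mean_mat, size_factors = sf,
                               tf_type = tf_type)),
            class = "ccc_simulation")
}

#' Simulate a binary peak x cell accessibility matrix
#'
#' Peaks carrying a planted motif have their accessibility probability
#' increased by `motif_effect` in cells of the motif TF's planted type. A
#' small set of "junk" peaks (out-of-range widths, blacklist overlaps, peaks
#' rarer than the 4% cluster gate) is included so that peak QC is exercised;
#' none of them carries a motif.
#'
#' @param config A [sim_config()].
#' @param truth A `SyntheticTruth` (from [simulate_counts()]); its
#'   `planted_motif_tfs` drive the enrichment.
#' @param cell_meta Optional per-cell metadata; defaults to the layout
#'   [simulate_counts()] uses (cells grouped by type, same barcodes).
#' @return List of class `accessibility_sim` with `access`
#'   ([peak_accessibility()]) and `blacklist` (BED-style data.frame).
#' @export
simulate_accessibility <- function(config, truth, cell_meta = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_motifs > 0 && config$n_peaks < config$n_motifs * 10)
    stop("n_peaks must be at least 10x n_motifs")
  set.seed(config$seed + 1000003L)
  types <- sim_cell_types(config)
  if (is.null(cell_meta)) {
    n_cells <- config$cells_per_type * length(types)
    cell_meta <- data.frame(
      cell_id = sprintf("cell_%04d", seq_len(n_cells)),
      cell_type = rep(types, each = config$cells_per_type))
  }
  n_cells <- nrow(cell_meta)
  n_peaks <- config$n_peaks

  width <- sample(300:800, n_peaks, replace = TRUE)
  n_junk_w <- max(2L, round(0.02 * n_peaks))
  n_rare <- max(2L, round(0.02 * n_peaks))
  junk_w <- seq_len(n_junk_w)                      # widths out of range
  junk_bl <- (n_junk_w + 1L):(n_junk_w + 2L)       # blacklist overlap
  junk_rare <- (n_junk_w + 3L):(n_junk_w + 2L + n_rare)
  width[junk_w] <- rep(c(100L, 2000L), length.out = n_junk_w)
  start <- 1000L + cumsum(c(0L, width[-n_peaks] + 200L))
  peaks <- data.frame(peak_id = sprintf("peak_%05d", seq_len(n_peaks)),
                      chrom = "chr1", start = start, end = start + width,
                      gc = runif(n_peaks, 0.3, 0.7))
  blacklist <- data.frame(chrom = "chr1",
                          start = peaks$start[junk_bl] + 10L,
                          end = peaks$start[junk_bl] + 11L)

  prob <- runif(n_peaks, 0.05, 0.30)
  prob[junk_rare] <- 0.005                         # < 4% in every cluster

  motif_tbl <- truth$planted_motif_tfs
  motifs <- if (config$n_motifs > 0)
    sprintf("MOTIF_TF%d", seq_len(config$n_motifs)) else character()
  usable <- setdiff(seq_len(n_peaks), c(junk_w, junk_bl, junk_rare))
  ppm <- max(10L, min(40L, floor(length(usable) / max(1L, length(motifs)))))
  annot <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_peaks, length(motifs)),
                                dimnames = list(peaks$peak_id, motifs))
  motif_tf <- stats::setNames(sub("^MOTIF_", "", motifs), motifs)
  pool <- sample(usable)
  prob_mat <- matrix(rep(prob, n_cells), n_peaks, n_cells)
  type_of <- cell_meta$cell_type
  tf_type <- stats::setNames(types[(seq_len(config$n_regulons) - 1L) %%
                                     length(types) + 1L],
                             sprintf("TF%d", seq_len(config$n_regulons)))
  for (mi in seq_along(motifs)) {
    sel <- pool[((mi - 1L) * ppm + 1L):(mi * ppm)]
    prob[sel] <- pmax(prob[sel], 0.10)  # keep planted peaks above the 4% gate
    prob_mat[sel, ] <- matrix(rep(prob[sel], n_cells), length(sel), n_cells)
    annot[sel, mi] <- 1
    tfg <- motif_tf[motifs[mi]]
    if (config$motif_effect > 0 && tfg %in% names(tf_type)) {
      cols <- which(type_of == tf_type[tfg])
      prob_mat[sel, cols] <- pmin(prob_mat[sel, cols] + config$motif_effect,
                                  0.95)
    }
  }
  acc <- matrix(rbinom(n_peaks * n_cells, 1L, prob_mat), n_peaks, n_cells,
                dimnames = list(peaks$peak_id, cell_meta$cell_id))
  pa <- peak_accessibility(peaks, Matrix::Matrix(acc, sparse = TRUE),
                           annot, motif_tf)
  structure(list(access = pa, blacklist = blacklist,
                 cluster_labels = stats::setNames(type_of, cell_meta$cell_id)),
            class = "accessibility_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the readers consume: the Matrix Market count
#' trio plus cell metadata, the interaction database, CellSign, zone and
#' regulon tables, the accessibility matrix with peak BED, motif annotation
#' and blacklist, and the ground-truth manifest.
#'
#' @param sim A `ccc_simulation` from [simulate_counts()].
#' @param out_dir Output directory (created if needed).
#' @param access_sim Optional `accessibility_sim` from
#'   [simulate_accessibility()].
#' @return Invisibly, `out_dir`.
#' @export
write_dataset <- function(sim, out_dir, access_sim = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  Matrix::writeMM(Matrix::t(sim$counts$counts), p("matrix.mtx"))
  writeLines(colnames(sim$counts$counts), p("features.tsv"))
  writeLines(rownames(sim$counts$counts), p("barcodes.tsv"))
  write_table(sim$counts$cell_meta, p("cell_metadata.tsv"), sort = FALSE)
  partners <- data.frame(partner_id = sim$db$partners$partner_id,
                         kind = sim$db$partners$kind,
                         members = vapply(sim$db$members, paste,
                                          character(1), collapse = ","))
  write_table(partners, p("partners.tsv"))
  write_table(sim$db$interactions, p("interactions.tsv"))
  write_table(sim$cellsign, p("cellsign.tsv"))
  write_table(sim$microenv, p("microenvironments.tsv"))
  write_table(sim$regulons, p("regulons.tsv"))
  write_table(sim$truth$planted_interactions, p("truth_interactions.tsv"))
  write_table(sim$truth$planted_active_tfs, p("truth_tfs.tsv"))
  write_table(sim$truth$decoys, p("truth_decoys.tsv"))
  if (!is.null(access_sim)) {
    pa <- access_sim$access
    write_bed(pa$peaks[, c("chrom", "start", "end", "peak_id", "gc")],
              p("peaks.bed"))
    Matrix::writeMM(pa$access, p("access.mtx"))
    writeLines(colnames(pa$access), p("access_barcodes.tsv"))
    idx <- Matrix::which(pa$motif_annot != 0, arr.ind = TRUE)
    write_table(data.frame(peak_id = rownames(pa$motif_annot)[idx[, 1]],
                           motif_id = colnames(pa$motif_annot)[idx[, 2]],
                           tf_gene = unname(pa$motif_tf[colnames(
                             pa$motif_annot)[idx[, 2]]])),
                p("peak_motifs.tsv"))
    write_bed(access_sim$blacklist, p("blacklist.bed"))
  }
  invisible(out_dir)
}
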