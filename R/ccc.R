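#' Thresholds for relevant-interaction retrieval
#'
#' The detection-fraction gate is inclusive ("at least 10%"); the DE gates
#' are strict ("below 0.01", "above 0.2").
#'
#' @param min_fraction Minimum expression fraction for every member gene of
#'   a partner in its cell type (default 0.10, inclusive).
#' @param de_padj_max Adjusted p-value ceiling for the DE gate (default
#'   0.01, strict <).
#' @param de_log2fc_min log2 fold-change floor for the DE gate (default 0.2,
#'   strict >).
#' @return List of class `CCCThresholds`.
#' @export
ccc_thresholds <- function(min_fraction = 0.10, de_padj_max = 0.01,
                           de_log2fc_min = 0.2) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  structure(list(min_fraction = min_fraction, de_padj_max = de_padj_max,
                 de_log2fc_min = de_log2fc_min), class = "CCCThresholds")
}

partner_members <- function(db, partner_id) {
  m <- db$members[[partner_id]]
  if (is.null(m)) stop("unknown partner: ", partner_id)
  m
}

#' Is a partner expressed in a cell type?
#'
#' TRUE iff every member gene of the partner (all complex subunits; the
#' enzyme gene(s) for enzyme proxies) is detected in at least `min_fraction`
#' of the type's cells. Member genes absent from the profile count as
#' fraction 0, with a warning.
#'
#' @param profile A `CellTypeProfile` from [profile_cell_types()].
#' @param db An [interaction_db()].
#' @param partner_id Partner to evaluate.
#' @param cell_type Cell type to evaluate in.
#' @param min_fraction Inclusive detection-fraction gate (default 0.10).
#' @return Logical scalar.
#' @export
partner_expressed <- function(profile, db, partner_id, cell_type,
                              min_fraction = 0.10) {
  genes <- partner_members(db, partner_id)
  known <- genes %in% colnames(profile$fraction)
  if (!all(known))
    warning("member gene(s) absent from profile (treated as fraction 0): ",
            paste(genes[!known], collapse = ", "))
  fr <- rep(0, length(genes))
  fr[known] <- profile$fraction[cell_type, genes[known]]
  all(fr >= min_fraction)
}

de_pass_lookup <- function(de, thr) {
  pass <- de$p_adj < thr$de_padj_max & de$log2fc > thr$de_log2fc_min
  split(de$feature[pass], de$group[pass])
}

#' Retrieve relevant ligand-receptor interactions between cell types
#'
#' For every ordered (sender, receiver) cell-type pair and every interaction,
#' the interaction is kept iff (1) the ligand-side partner is expressed in
#' the sender and the receptor-side partner in the receiver (all member
#' genes at or above the detection-fraction gate) and (2) at least one
#' member gene of either partner is differentially expressed in its
#' respective cell type (adjusted p below and log2 fold change above the DE
#' gates). Directed interactions evaluate partner_a as ligand in the sender;
#' undirected interactions are tested in both orientations.
#'
#' @param profile A `CellTypeProfile`.
#' @param de A DE table from [de_one_vs_all()] on genes (feature = gene,
#'   group = cell type).
#' @param db An [interaction_db()].
#' @param thr A [ccc_thresholds()].
#' @param de_any_type If TRUE, the DE gene may be differentially expressed in
#'   any cell type rather than specifically in the type where its partner is
#'   evaluated (default FALSE).
#' @return data.frame of relevant interactions, sorted by
#'   (interaction_id, sender_type, receiver_type), with the gate evidence
#'   recorded (`de_partner`, `de_genes`) and empty zone/CellSign columns to
#'   be filled by [filter_by_microenvironment()] and [annotate_cellsign()].
#' @export
retrieve_relevant <- function(profile, de, db, thr = ccc_thresholds(),
                              de_any_type = FALSE) {
  types <- rownames(profile$fraction)
  pids <- db$partners$partner_id
  expressed <- matrix(FALSE, length(pids), length(types),
                      dimnames = list(pids, types))
  for (pid in pids) for (ty in types)
    expressed[pid, ty] <- partner_expressed(profile, db, pid, ty,
                                            thr$min_fraction)
  de_pass <- de_pass_lookup(de, thr)
  de_genes_in <- function(genes, ty) {
    if (de_any_type) intersect(genes, unlist(de_pass, use.names = FALSE))
    else intersect(genes, de_pass[[ty]])
  }
  rows <- list()
  for (ii in seq_len(nrow(db$interactions))) {
    rec <- db$interactions[ii, ]
    orientations <- list(c(rec$partner_a, rec$partner_b, "ab"))
    if (rec$directionality == "undirected")
      orientations <- c(orientations, list(c(rec$partner_b, rec$partner_a, "ba")))
    for (ori in orientations) {
      lig <- ori[1]; rcp <- ori[2]
      lig_genes <- partner_members(db, lig)
      rcp_genes <- partner_members(db, rcp)
      for (s in types) {
        if (!expressed[lig, s]) next
        de_lig <- de_genes_in(lig_genes, s)
        for (r in types) {
          if (!expressed[rcp, r]) next
          de_rcp <- de_genes_in(rcp_genes, r)
          if (!length(de_lig) && !length(de_rcp)) next
          side <- c(if (length(de_lig)) if (ori[3] == "ab") "a" else "b",
                    if (length(de_rcp)) if (ori[3] == "ab") "b" else "a")
          rows[[length(rows) + 1L]] <- data.frame(
            interaction_id = rec$interaction_id, sender_type = s,
            receiver_type = r, ligand_partner = lig, receptor_partner = rcp,
            de_partner = if (length(side) == 2) "both" else side,
            de_genes = paste(sort(unique(c(de_lig, de_rcp))), collapse = ","),
            shared_zones = "", cellsign_tfs = "", cellsign_active = "",
            supported = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    interaction_id = character(), sender_type = character(),
    receiver_type = character(), ligand_partner = character(),
    receptor_partner = character(), de_partner = character(),
    de_genes = character(), shared_zones = character(),
    cellsign_tfs = character(), cellsign_active = character(),
    supported = logical())
  out <- out[order(out$interaction_id, out$sender_type, out$receiver_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter interactions to co-located cell type pairs
#'
#' Keeps an interaction iff the sender's and receiver's zone sets intersect,
#' recording the shared zones. Every sender/receiver type must appear in the
#' microenvironment table; a missing type is an error (no silent
#' pass-through).
#'
#' @param interactions Output of [retrieve_relevant()].
#' @param env A [microenvironment_table()].
#' @return The filtered interaction table with `shared_zones` filled in.
#' @export
filter_by_microenvironment <- function(interactions, env) {
  zones <- split(env$zone, env$cell_type)
  used <- unique(c(interactions$sender_type, interactions$receiver_type))
  missing_ty <- setdiff(used, names(zones))
  if (length(missing_ty))
    stop("cell type missing from microenvironment table: ", missing_ty[1])
  if (!nrow(interactions)) return(interactions)
  shared <- mapply(function(s, r)
    paste(sort(intersect(zones[[s]], zones[[r]])), collapse = ","),
    interactions$sender_type, interactions$receiver_type)
  interactions$shared_zones <- unname(shared)
  out <- interactions[nzchar(interactions$shared_zones), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate interactions with downstream-TF (CellSign) support
#'
#' For each interaction, the receptor-side partner is looked up in the
#' receptor-to-TF table; each linked TF is marked active iff it belongs to
#' the receiver type's active-TF set, and the interaction is `supported` iff
#' at least one linked TF is active. Receptors without an entry get an empty
#' TF list and `supported = FALSE`.
#'
#' @param interactions Output of [retrieve_relevant()] (optionally
#'   zone-filtered).
#' @param cellsign A [cellsign_table()].
#' @param active_tfs Named list (or data.frame with columns `cell_type`,
#'   `tf`) of active/prioritized TFs per cell type.
#' @return The interaction table with `cellsign_tfs`, `cellsign_active` and
#'   `supported` filled in.
#' @export
annotate_cellsign <- function(interactions, cellsign, active_tfs) {
  if (is.data.frame(active_tfs))
    active_tfs <- split(active_tfs$tf, active_tfs$cell_type)
  if (!nrow(interactions)) return(interactions)
  for (i in seq_len(nrow(interactions))) {
    tfs <- sort(cellsign$tf_gene[
      cellsign$receptor_partner_id == interactions$receptor_partner[i]])
    act <- tfs[tfs %in% (active_tfs[[interactions$receiver_type[i]]] %||%
                           character())]
    interactions$cellsign_tfs[i] <- paste(tfs, collapse = ",")
    interactions$cellsign_active[i] <- paste(act, collapse = ",")
    interactions$supported[i] <- length(act) > 0
  }
  interactions
}
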