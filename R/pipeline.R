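fnv1a <- function(s) {
  # 32-bit FNV-1a over the UTF-8 bytes of s; used to fingerprint configs
  h <- 0x811c9dc5
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Assemble a pipeline configuration
#'
#' A run is a pure function of (inputs, config, seed). Inputs are either
#' simulated in-process from `sim` or read from `input_dir` (a directory laid
#' out by [write_dataset()]).
#'
#' @param sim A [sim_config()] used when `input_dir` is NULL.
#' @param input_dir Optional directory with an on-disk dataset.
#' @param out_dir Optional output directory; when given, every intermediate
#'   table is written there as sorted TSV.
#' @param qc [qc_thresholds()].
#' @param ccc [ccc_thresholds()].
#' @param tf [tf_priority_thresholds()].
#' @param adjust_method Multiple-testing correction, `"bonferroni"`
#'   (default) or `"bh"`.
#' @param use_zones Apply the shared-zone microenvironment filter
#'   (default TRUE).
#' @param use_motif Compute the motif-accessibility evidence (default TRUE).
#' @param n_background Background sets for motif deviations (default 50).
#' @param zones Zone vocabulary.
#' @param seed Seed for every stochastic stage (defaults to the simulation
#'   seed).
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL, qc = qc_thresholds(),
                            ccc = ccc_thresholds(),
                            tf = tf_priority_thresholds(),
                            adjust_method = c("bonferroni", "bh"),
                            use_zones = TRUE, use_motif = TRUE,
                            n_background = 50, zones = default_zones(),
                            seed = sim$seed) {
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 qc = qc, ccc = ccc, tf = tf,
                 adjust_method = match.arg(adjust_method),
                 use_zones = use_zones, use_motif = use_motif,
                 n_background = n_background, zones = zones,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

read_dataset_dir <- function(dir, zones) {
  counts <- read_counts_mtx(dir)
  db <- read_interaction_db(file.path(dir, "partners.tsv"),
                            file.path(dir, "interactions.tsv"))
  cellsign <- read_cellsign(file.path(dir, "cellsign.tsv"), db)
  microenv <- read_microenvironments(file.path(dir, "microenvironments.tsv"),
                                     zones)
  regulons <- read_regulons(file.path(dir, "regulons.tsv"))
  acc <- NULL
  if (file.exists(file.path(dir, "access.mtx"))) {
    pa <- read_peaks(file.path(dir, "peaks.bed"), file.path(dir, "access.mtx"),
                     file.path(dir, "peak_motifs.tsv"))
    bl <- if (file.exists(file.path(dir, "blacklist.bed")))
      read_bed(file.path(dir, "blacklist.bed")) else NULL
    lab <- stats::setNames(counts$cell_meta$cell_type,
                           counts$cell_meta$cell_id)[colnames(pa$access)]
    acc <- structure(list(access = pa, blacklist = bl, cluster_labels = lab),
                     class = "accessibility_sim")
  }
  list(counts = counts, db = db, cellsign = cellsign, microenv = microenv,
       regulons = regulons, access = acc, truth = NULL)
}

#' Run the full communication + TF-prioritization pipeline
#'
#' Stages, in order: simulate or load inputs; gene/cell QC; log(CPM/100 + 1)
#' normalization; per-type expression profiles; one-vs-all gene DE;
#' relevant-interaction retrieval; microenvironment (shared-zone) filtering;
#' regulon activity and motif-deviation evidence; TF prioritization;
#' receptor-to-downstream-TF (CellSign) support annotation. Every
#' intermediate table is written to `config$out_dir` when set, and the
#' returned report summarizes the counts at each gate.
#'
#' @param config A [pipeline_config()].
#' @return List of class `RunReport` with the final tables (`relevant`,
#'   `tf_priority`, DE tables), the per-gate counts (`gates`), the seed and a
#'   config fingerprint.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- "input"
  res <- tryCatch({
    if (is.null(config$input_dir)) {
      sim <- simulate_counts(config$sim)
      acc <- if (config$use_motif)
        simulate_accessibility(config$sim, sim$truth, sim$counts$cell_meta)
      data <- list(counts = sim$counts, db = sim$db, cellsign = sim$cellsign,
                   microenv = sim$microenv, regulons = sim$regulons,
                   access = acc, truth = sim$truth)
    } else {
      data <- read_dataset_dir(config$input_dir, config$zones)
    }

    stage <- "qc"
    counts_f <- qc_filter(data$counts, config$qc)
    qc_report <- attr(counts_f, "qc_report")
    labels <- counts_f$cell_meta$cell_type

    stage <- "normalize"
    norm <- normalize_log_cpm100(counts_f)
    profile <- profile_cell_types(norm, counts_f)

    stage <- "differential expression"
    expr_de <- de_one_vs_all(t(norm$values), labels,
                             adjust_method = config$adjust_method)

    stage <- "interaction retrieval"
    relevant <- retrieve_relevant(profile, expr_de, data$db, config$ccc)
    n_retrieved <- nrow(relevant)
    if (config$use_zones) {
      stage <- "microenvironment filter"
      relevant <- filter_by_microenvironment(relevant, data$microenv)
    }
    n_zone <- nrow(relevant)

    stage <- "regulon activity"
    reg_act <- regulon_activity(norm, data$regulons)
    regulon_de <- activity_de(reg_act, labels,
                              adjust_method = config$adjust_method)

    motif_de <- NULL
    if (config$use_motif && !is.null(data$access)) {
      stage <- "motif deviations"
      pa <- filter_peaks(data$access$access, data$access$blacklist,
                         data$access$cluster_labels)
      dev <- motif_deviations(pa, n_background = config$n_background,
                              seed = config$seed)
      motif_de <- activity_de(dev, data$access$cluster_labels,
                              adjust_method = config$adjust_method)
    }

    stage <- "TF prioritization"
    tf_priority <- prioritize_tfs(expr_de, regulon_de, motif_de, config$tf)
    active <- tf_priority[tf_priority$prioritized, c("tf", "cell_type")]

    stage <- "cellsign annotation"
    relevant <- annotate_cellsign(relevant, data$cellsign,
                                  split(active$tf, active$cell_type))

    list(data = data, qc_report = qc_report, expr_de = expr_de,
         regulon_de = regulon_de, motif_de = motif_de, relevant = relevant,
         tf_priority = tf_priority,
         gates = list(cells_in = nrow(data$counts$counts),
                      cells_kept = qc_report$cells_kept,
                      genes_kept = qc_report$genes_kept,
                      interactions_retrieved = n_retrieved,
                      interactions_zone_filtered = n_zone,
                      interactions_supported = sum(relevant$supported),
                      tfs_prioritized = nrow(active)))
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  report <- structure(
    list(seed = config$seed,
         config_hash = fnv1a(as.character(jsonlite::serializeJSON(config))),
         gates = res$gates, relevant = res$relevant,
         tf_priority = res$tf_priority, expr_de = res$expr_de,
         regulon_de = res$regulon_de, motif_de = res$motif_de,
         qc_report = res$qc_report, truth = res$data$truth),
    class = "RunReport")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_table(res$relevant, p("relevant_interactions.tsv"))
    write_table(res$tf_priority, p("tf_priority.tsv"))
    write_table(res$expr_de, p("expression_de.tsv"))
    write_table(res$regulon_de, p("regulon_activity_de.tsv"))
    if (!is.null(res$motif_de)) write_table(res$motif_de, p("motif_activity_de.tsv"))
    write_table(data.frame(metric = names(unlist(res$gates)),
                           value = unlist(res$gates)), p("gate_counts.tsv"))
    if (!is.null(res$data$truth)) {
      write_table(res$data$truth$planted_interactions, p("truth_interactions.tsv"))
      write_table(res$data$truth$planted_active_tfs, p("truth_tfs.tsv"))
      write_table(res$data$truth$decoys, p("truth_decoys.tsv"))
    }
    cfg <- rapply(unclass(config), unclass, how = "replace")
    yaml::write_yaml(cfg, p("resolved_config.yaml"))
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  g <- x$gates
  cat("Pipeline run (seed ", x$seed, ", config ", x$config_hash, ")\n",
      "  cells: ", g$cells_in, " -> ", g$cells_kept,
      " | genes kept: ", g$genes_kept, "\n",
      "  interactions: retrieved ", g$interactions_retrieved,
      " -> zone-filtered ", g$interactions_zone_filtered,
      " (supported: ", g$interactions_supported, ")\n",
      "  prioritized TFs: ", g$tfs_prioritized, "\n", sep = "")
  invisible(x)
}

set_metrics <- function(found, truth) {
  tp <- length(intersect(found, truth))
  data.frame(
    n_truth = length(truth), n_found = length(found), true_positive = tp,
    precision = if (length(found)) tp / length(found) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

#' Compare pipeline results with a planted truth
#'
#' Exact set arithmetic on (interaction, sender, receiver) triples and
#' (TF, cell type) pairs. Precision is NA when nothing was recovered and
#' recall is NA when nothing was planted (the null-simulation edge case).
#'
#' @param relevant Relevant-interaction table (zone-filtered).
#' @param tf_priority TF prioritization table.
#' @param truth A `SyntheticTruth`.
#' @return data.frame with one row per stage (`interactions`, `tfs`):
#'   precision, recall, counts, and `decoys_retained` for interactions.
#' @export
evaluate_recovery <- function(relevant, tf_priority, truth) {
  found_i <- unique(paste(relevant$interaction_id, relevant$sender_type,
                          relevant$receiver_type))
  truth_i <- with(truth$planted_interactions,
                  paste(interaction_id, sender_type, receiver_type))
  mi <- set_metrics(found_i, truth_i)
  mi$decoys_retained <- length(intersect(unique(relevant$interaction_id),
                                         truth$decoys$interaction_id))
  pri <- tf_priority[tf_priority$prioritized, , drop = FALSE]
  mt <- set_metrics(unique(paste(pri$tf, pri$cell_type)),
                    with(truth$planted_active_tfs, paste(tf, cell_type)))
  mt$decoys_retained <- NA_integer_
  cbind(stage = c("interactions", "tfs"), rbind(mi, mt))
}

#' Compare written results with a written truth
#'
#' Directory wrapper around [evaluate_recovery()] for runs and datasets that
#' live on disk.
#'
#' @param results_dir Directory written by [run_pipeline()]
#'   (relevant_interactions.tsv, tf_priority.tsv).
#' @param truth_dir Directory holding truth_interactions.tsv, truth_tfs.tsv,
#'   truth_decoys.tsv (as written by [write_dataset()] or [run_pipeline()]).
#' @return Metrics table from [evaluate_recovery()].
#' @export
evaluate_against_truth <- function(results_dir, truth_dir = results_dir) {
  relevant <- read_tsv_checked(
    file.path(results_dir, "relevant_interactions.tsv"),
    c("interaction_id", "sender_type", "receiver_type"), "relevant")
  tfp <- read_tsv_checked(file.path(results_dir, "tf_priority.tsv"),
                          c("tf", "cell_type", "prioritized"), "tf priority")
  tfp$prioritized <- as.logical(tfp$prioritized)
  truth <- structure(list(
    planted_interactions = read_tsv_checked(
      file.path(truth_dir, "truth_interactions.tsv"),
      c("interaction_id", "sender_type", "receiver_type"), "truth"),
    planted_active_tfs = read_tsv_checked(
      file.path(truth_dir, "truth_tfs.tsv"), c("cell_type", "tf"), "truth"),
    decoys = read_tsv_checked(file.path(truth_dir, "truth_decoys.tsv"),
                              c("interaction_id", "kind"), "truth")),
    class = "SyntheticTruth")
  evaluate_recovery(relevant, tfp, truth)
}
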