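read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing file: none of ", paste(candidates, collapse = "/"),
       " found in ", dir)
}

#' Read a sparse count matrix directory into a CountMatrix
#'
#' Expects the 10x-style trio `matrix.mtx(.gz)`, `features.tsv(.gz)` (or
#' `genes.tsv`), `barcodes.tsv(.gz)`, plus a `cell_metadata.tsv` with columns
#' cell_id / cell_type / sample (/ zone). On-disk orientation may be either
#' genes x cells (the dominant convention, transposed on read) or
#' cells x genes; the result is always cells x genes.
#'
#' @param directory_path Directory holding the four files.
#' @return A validated [count_matrix()].
#' @export
read_counts_mtx <- function(directory_path) {
  mtx <- first_existing(directory_path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(directory_path,
                         c("features.tsv", "features.tsv.gz",
                           "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(directory_path, c("barcodes.tsv", "barcodes.tsv.gz"))
  meta_path <- file.path(directory_path, "cell_metadata.tsv")
  if (!file.exists(meta_path)) stop("missing file: ", meta_path)

  m <- Matrix::readMM(mtx)
  genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)          # genes-as-rows convention on disk
    orientation <- "genes_x_cells"
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    orientation <- "cells_x_genes"
  } else {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") match neither features (", length(genes),
         ") nor barcodes (", length(barcodes), ")")
  }
  dimnames(m) <- list(barcodes, genes)
  meta <- read_tsv_checked(meta_path, c("cell_id", "cell_type", "sample"),
                           "cell metadata")
  extra <- setdiff(meta$cell_id, barcodes)
  if (length(extra)) stop("metadata barcode not in matrix: ", extra[1])
  cm <- count_matrix(m, meta)
  attr(cm, "provenance") <- list(source = directory_path,
                                 on_disk_orientation = orientation)
  cm
}

#' Read the interaction database tables
#'
#' @param partners_path TSV with columns partner_id, kind, members
#'   (comma-separated gene list; single gene for kind = gene, the pathway's
#'   terminal enzyme(s) for kind = enzyme_proxy).
#' @param interactions_path TSV with columns interaction_id, partner_a,
#'   partner_b, directionality, annotation.
#' @return An [interaction_db()].
#' @export
read_interaction_db <- function(partners_path, interactions_path) {
  partners <- read_tsv_checked(partners_path,
                               c("partner_id", "kind", "members"), "partners")
  interactions <- read_tsv_checked(
    interactions_path,
    c("interaction_id", "partner_a", "partner_b", "directionality",
      "annotation"), "interactions")
  interaction_db(partners, interactions)
}

#' Read a receptor-to-downstream-TF table
#' @param path TSV with columns receptor_partner_id, tf_gene, evidence_ref.
#' @param db Optional [interaction_db()] for receptor validation.
#' @return Validated data.frame (see [cellsign_table()]).
#' @export
read_cellsign <- function(path, db = NULL) {
  cellsign_table(read_tsv_checked(
    path, c("receptor_partner_id", "tf_gene", "evidence_ref"), "cellsign"), db)
}

#' Read a cell type to zone assignment table
#' @param path TSV with columns cell_type, zone.
#' @param zones Zone vocabulary; defaults to [default_zones()].
#' @return Validated data.frame (see [microenvironment_table()]).
#' @export
read_microenvironments <- function(path, zones = default_zones()) {
  microenvironment_table(read_tsv_checked(path, c("cell_type", "zone"),
                                          "microenvironment"), zones)
}

#' Read a regulon table
#' @param path TSV with columns tf, target, mode (and optional weight).
#' @param min_targets Minimum targets per regulon.
#' @return Validated data.frame (see [regulon_set()]).
#' @export
read_regulons <- function(path, min_targets = 5) {
  regulon_set(read_tsv_checked(path, c("tf", "target", "mode"), "regulon"),
              min_targets)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path; first three columns chrom/start/end, optional
#'   name and score columns.
#' @return data.frame with chrom, start, end (+ name, score when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path)
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4) names(raw)[4] <- "name"
  if (ncol(raw) >= 5) names(raw)[5] <- "score"
  bad <- which(raw$end <= raw$start)
  if (length(bad))
    stop("malformed BED interval (end <= start) at line ", bad[1],
         " of ", path)
  raw
}

#' Read a peak accessibility dataset
#'
#' @param bed_path Peak BED: chrom, start, end, peak_id, gc fraction.
#' @param mtx_path Matrix Market file, peaks x cells.
#' @param motif_path TSV with columns peak_id, motif_id, tf_gene (one row
#'   per peak-motif annotation).
#' @param barcodes_path TSV of cell barcodes (one per line); defaults to
#'   `access_barcodes.tsv` next to the matrix.
#' @return A [peak_accessibility()] object.
#' @export
read_peaks <- function(bed_path, mtx_path, motif_path,
                       barcodes_path = file.path(dirname(mtx_path),
                                                 "access_barcodes.tsv")) {
  bed <- read_bed(bed_path)
  if (ncol(bed) < 5) stop("peak BED needs name and gc columns: ", bed_path)
  peaks <- data.frame(peak_id = as.character(bed$name), chrom = bed$chrom,
                      start = bed$start, end = bed$end,
                      gc = as.numeric(bed$score), stringsAsFactors = FALSE)
  if (!file.exists(mtx_path)) stop("missing file: ", mtx_path)
  access <- Matrix::readMM(mtx_path)
  if (!file.exists(barcodes_path)) stop("missing file: ", barcodes_path)
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(access) != nrow(peaks) || ncol(access) != length(barcodes))
    stop("accessibility matrix dimensions do not match peaks/barcodes")
  dimnames(access) <- list(peaks$peak_id, barcodes)
  mot <- read_tsv_checked(motif_path, c("peak_id", "motif_id", "tf_gene"),
                          "peak-motif")
  unknown <- setdiff(mot$peak_id, peaks$peak_id)
  if (length(unknown)) stop("motif annotation for unknown peak: ", unknown[1])
  motifs <- sort(unique(mot$motif_id))
  annot <- Matrix::sparseMatrix(
    i = match(mot$peak_id, peaks$peak_id),
    j = match(mot$motif_id, motifs),
    x = 1, dims = c(nrow(peaks), length(motifs)),
    dimnames = list(peaks$peak_id, motifs))
  tf_map <- vapply(motifs, function(m) unique(mot$tf_gene[mot$motif_id == m])[1],
                   character(1))
  peak_accessibility(peaks, access, annot, tf_map)
}

format_cell <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g")
  else as.character(x)
}

#' Write a table deterministically
#'
#' Rows are sorted over all columns and written tab-separated with a header;
#' doubles are printed with full round-trip precision so that identical
#' inputs yield byte-identical files.
#'
#' @param records data.frame to write.
#' @param path Output file.
#' @param sort Sort rows before writing (default TRUE).
#' @return Invisibly, the path.
#' @export
write_table <- function(records, path, sort = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- as.data.frame(lapply(records, format_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(records)
  if (sort && nrow(out) > 1) {
    out <- out[do.call(order, c(unname(as.list(out)), list(method = "radix"))), ,
               drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), list(sep = "\t"))), con)
  invisible(path)
}

#' Write a BED file (0-based half-open)
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_bed <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(
      as.data.frame(lapply(df, format_cell)))), list(sep = "\t"))), con)
  invisible(path)
}
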