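#' @importFrom methods as is new
#' @importFrom stats pnorm pwilcox p.adjust rnbinom rlnorm rnorm runif rbinom sd
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default spatial zone vocabulary
#'
#' Zones used to constrain cell-cell communication to co-located cell types.
#' The defaults are the three anatomical zones of a developing ovary.
#'
#' @return Character vector of zone names.
#' @export
default_zones <- function() c("outer_cortex", "inner_cortex", "medulla")

#' Construct a validated cell x gene count matrix
#'
#' Container for raw single-cell counts plus per-cell metadata. Counts are
#' stored cells x genes as a sparse matrix; metadata must carry one row per
#' cell with its type, sample of origin, and (optionally) spatial zone.
#'
#' @param counts Matrix-like of non-negative integer counts, cells x genes,
#'   with cell identifiers as rownames and gene identifiers as colnames.
#' @param cell_meta data.frame with columns `cell_id`, `cell_type`, `sample`
#'   and optionally `zone` (NA allowed; zones are usually assigned per cell
#'   type, not per cell).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, cell_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell ids (rownames) and gene ids (colnames)")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicated cell id: ", dup[1])
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicated gene id: ", dup[1])
  x <- counts@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)))
    stop("counts must be finite non-negative integers")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "sample")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stop("cell_meta missing column(s): ", paste(miss, collapse = ", "))
  if (!"zone" %in% names(cell_meta)) cell_meta$zone <- NA_character_
  if (anyDuplicated(cell_meta$cell_id))
    stop("duplicated cell id in metadata: ",
         cell_meta$cell_id[duplicated(cell_meta$cell_id)][1])
  idx <- match(rownames(counts), cell_meta$cell_id)
  if (anyNA(idx)) {
    missing_bc <- rownames(counts)[which(is.na(idx))[1]]
    stop("metadata does not cover barcode: ", missing_bc)
  }
  cell_meta <- cell_meta[idx, c("cell_id", "cell_type", "sample", "zone"), drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Construct a normalized expression matrix
#'
#' @param values Dense or sparse real matrix, cells x genes, natural-log scale.
#' @param provenance List describing the normalization applied.
#' @return Object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, provenance = list()) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("normalized values must be non-negative")
  structure(list(values = values, provenance = provenance),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              x$provenance$method %||% "unspecified"))
  invisible(x)
}

#' Construct a ligand-receptor interaction database
#'
#' Partners are simple genes, heteromeric complexes (several member genes,
#' all of which must pass the expression gate) or enzyme proxies standing in
#' for non-peptide ligands via the last bona fide enzyme of their
#' biosynthesis pathway.
#'
#' @param partners data.frame with columns `partner_id`, `kind`
#'   (gene/complex/enzyme_proxy) and `members` (comma-separated gene ids).
#' @param interactions data.frame with columns `interaction_id`, `partner_a`,
#'   `partner_b`, `directionality` (`ligand_receptor` with a = ligand,
#'   b = receptor, or `undirected`) and `annotation`.
#' @return Object of class `InteractionDB`.
#' @export
interaction_db <- function(partners, interactions) {
  partners <- as.data.frame(partners, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  kinds <- c("gene", "complex", "enzyme_proxy")
  if (!all(partners$kind %in% kinds))
    stop("partner kind must be one of: ", paste(kinds, collapse = ", "))
  if (anyDuplicated(partners$partner_id))
    stop("duplicated partner_id: ",
         partners$partner_id[duplicated(partners$partner_id)][1])
  members <- strsplit(as.character(partners$members), ",", fixed = TRUE)
  members <- lapply(members, function(m) trimws(m[nzchar(trimws(m))]))
  names(members) <- partners$partner_id
  bad <- vapply(members, length, 1L) == 0L
  if (any(bad)) stop("partner with empty member list: ",
                     partners$partner_id[bad][1])
  if (anyDuplicated(interactions$interaction_id))
    stop("duplicated interaction_id: ",
         interactions$interaction_id[duplicated(interactions$interaction_id)][1])
  ref <- c(interactions$partner_a, interactions$partner_b)
  unknown <- setdiff(ref, partners$partner_id)
  if (length(unknown)) stop("interaction references unknown partner: ", unknown[1])
  if (!all(interactions$directionality %in% c("ligand_receptor", "undirected")))
    stop("directionality must be 'ligand_receptor' or 'undirected'")
  structure(list(partners = partners[, c("partner_id", "kind")],
                 members = members,
                 interactions = interactions),
            class = "InteractionDB")
}

#' @export
print.InteractionDB <- function(x, ...) {
  cat(sprintf("InteractionDB: %d partners (%d complexes, %d enzyme proxies), %d interactions\n",
              nrow(x$partners), sum(x$partners$kind == "complex"),
              sum(x$partners$kind == "enzyme_proxy"), nrow(x$interactions)))
  invisible(x)
}

#' Validate a receptor-to-downstream-TF (CellSign-style) table
#'
#' @param df data.frame with columns `receptor_partner_id`, `tf_gene`,
#'   `evidence_ref` (free-text citation key).
#' @param db Optional `InteractionDB`; when given, receptor partner ids are
#'   checked against it.
#' @return The validated data.frame.
#' @export
cellsign_table <- function(df, db = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("receptor_partner_id", "tf_gene", "evidence_ref")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cellsign table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(df$receptor_partner_id, df$tf_gene)
  if (anyDuplicated(key)) stop("duplicated (receptor, TF) pair: ",
                               key[duplicated(key)][1])
  if (!is.null(db)) {
    unknown <- setdiff(df$receptor_partner_id, db$partners$partner_id)
    if (length(unknown))
      stop("cellsign receptor not in interaction database: ", unknown[1])
  }
  df[, need]
}

#' Validate a cell type to spatial zone assignment table
#'
#' A cell type may map to several zones; interactions later require the
#' sender's and receiver's zone sets to intersect.
#'
#' @param df data.frame with columns `cell_type`, `zone`.
#' @param zones Controlled zone vocabulary.
#' @return The validated data.frame.
#' @export
microenvironment_table <- function(df, zones = default_zones()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_type", "zone"), names(df))
  if (length(miss)) stop("microenvironment table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(df$zone, zones)
  if (length(bad)) stop("zone not in vocabulary: ", bad[1])
  unique(df[, c("cell_type", "zone")])
}

#' Validate a regulon table (TF -> target gene sets)
#'
#' @param df data.frame with columns `tf`, `target`, `mode` (+1 activation /
#'   -1 repression) and optional `weight` in (0, 1] (default 1).
#' @param min_targets Minimum usable targets per regulon; smaller regulons
#'   are rejected.
#' @return Validated data.frame with columns tf, target, mode, weight.
#' @export
regulon_set <- function(df, min_targets = 5) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(c("tf", "target", "mode"), names(df))
  if (length(miss)) stop("regulon table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"weight" %in% names(df)) df$weight <- 1
  if (any(df$tf == df$target)) stop("self-target in regulon: ",
                                    df$tf[df$tf == df$target][1])
  key <- paste(df$tf, df$target)
  if (anyDuplicated(key)) stop("duplicated (TF, target) pair: ",
                               key[duplicated(key)][1])
  if (!all(df$mode %in% c(-1, 1))) stop("mode must be +1 or -1")
  if (any(df$weight <= 0 | df$weight > 1)) stop("weights must lie in (0, 1]")
  n <- table(df$tf)
  small <- names(n)[n < min_targets]
  if (length(small))
    stop("regulon below the ", min_targets, "-target floor: ", small[1])
  df[, c("tf", "target", "mode", "weight")]
}

#' Construct a peak x cell accessibility container
#'
#' Peaks use 0-based half-open coordinates, so width = end - start.
#'
#' @param peaks data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `gc` (GC fraction in \[0, 1\]).
#' @param access Sparse binary/count matrix, peaks x cells, with peak ids as
#'   rownames and cell barcodes as colnames.
#' @param motif_annot Binary matrix, peaks x motifs (motif ids as colnames).
#' @param motif_tf Named character vector mapping motif id -> TF gene.
#' @return Object of class `PeakAccessibility`.
#' @export
peak_accessibility <- function(peaks, access, motif_annot, motif_tf) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  need <- c("peak_id", "chrom", "start", "end", "gc")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peaks missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(peaks$peak_id))
    stop("duplicated peak_id: ", peaks$peak_id[duplicated(peaks$peak_id)][1])
  if (any(peaks$end <= peaks$start))
    stop("peak with end <= start: ", peaks$peak_id[peaks$end <= peaks$start][1])
  if (any(peaks$gc < 0 | peaks$gc > 1)) stop("gc content must lie in [0, 1]")
  access <- as(as(access * 1, "CsparseMatrix"), "generalMatrix")
  motif_annot <- as(as(motif_annot * 1, "CsparseMatrix"), "generalMatrix")
  if (nrow(access) != nrow(peaks) || nrow(motif_annot) != nrow(peaks))
    stop("matrix rows must match the peak table")
  if (!identical(rownames(access), peaks$peak_id))
    stop("access rownames must equal peak ids, in order")
  if (is.null(colnames(motif_annot))) stop("motif matrix needs motif ids as colnames")
  unknown <- setdiff(colnames(motif_annot), names(motif_tf))
  if (length(unknown)) stop("motif without TF mapping: ", unknown[1])
  structure(list(peaks = peaks, access = access,
                 motif_annot = motif_annot,
                 motif_tf = motif_tf[colnames(motif_annot)]),
            class = "PeakAccessibility")
}

#' @export
print.PeakAccessibility <- function(x, ...) {
  cat(sprintf("PeakAccessibility: %d peaks x %d cells, %d motifs\n",
              nrow(x$access), ncol(x$access), ncol(x$motif_annot)))
  invisible(x)
}

#' Peak widths (0-based half-open: end - start)
#'
#' @param peaks data.frame with `start` and `end` columns.
#' @return Integer vector of widths.
#' @export
peak_width <- function(peaks) peaks$end - peaks$start
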