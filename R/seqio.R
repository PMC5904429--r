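#' Read an aligned FASTA plus specimen metadata
#'
#' Assembles a [barcode_alignment()] from an aligned FASTA file and a
#' tab-separated metadata table. The FASTA record id (the header up to the
#' first whitespace) is the join key against the metadata `specimen_id`
#' column. Record order follows the FASTA file. Residues are upper-cased and
#' `U` is mapped to `T` on ingest.
#'
#' @param fasta_path path to an aligned FASTA file (all records equal length).
#' @param metadata_path path to a TSV with header columns `specimen_id`,
#'   `species` and optionally `sex`, `accession`, `locality`.
#' @return a `barcode_alignment`
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  recs <- seqinr::read.fasta(fasta_path, seqtype = "DNA",
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", fasta_path)
  ids <- names(recs)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has %d residues, expected %d",
                 ids[bad], lens[bad], lens[1L]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate specimen_id in FASTA: ",
                        paste(unique(dup), collapse = ", "))
  meta <- utils::read.delim(metadata_path, colClasses = "character",
                            na.strings = c("NA", ""), check.names = FALSE)
  if (is.null(meta$specimen_id)) stop("metadata lacks a specimen_id column")
  dupm <- meta$specimen_id[duplicated(meta$specimen_id)]
  if (length(dupm)) stop("duplicate specimen_id in metadata: ",
                         paste(unique(dupm), collapse = ", "))
  unknown <- setdiff(ids, meta$specimen_id)
  if (length(unknown)) {
    stop("FASTA record(s) absent from metadata: ", paste(unknown, collapse = ", "))
  }
  seqs <- do.call(rbind, recs)
  barcode_alignment(seqs, meta[match(ids, meta$specimen_id), , drop = FALSE])
}

#' Write an alignment back to FASTA (and optionally its metadata TSV)
#'
#' The FASTA written here round-trips byte-identically through
#' [read_alignment()] (one sequence line per record, ids as written).
#'
#' @param aln a `barcode_alignment`
#' @param fasta_path output FASTA path
#' @param metadata_path optional output TSV path
#' @return invisibly, `fasta_path`
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  seq_lines <- apply(aln$seqs, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", rownames(aln$seqs)), seq_lines)),
             fasta_path)
  if (!is.null(metadata_path)) {
    utils::write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(fasta_path)
}

#' Write a p-distance matrix to disk
#'
#' Writes a lower-triangular PHYLIP-style text file and a full square TSV.
#' Distances are printed with 4 decimal places.
#'
#' @param dm a `pdist_matrix` from [distance_matrix()]
#' @param path output path for the PHYLIP-style file
#' @param tsv_path output path for the square TSV; defaults to `path` with a
#'   `.tsv` extension
#' @return invisibly, a character vector of the two paths written
#' @export
write_distance_matrix <- function(dm, path,
                                  tsv_path = paste0(tools::file_path_sans_ext(path), ".tsv")) {
  n <- length(dm$ids)
  if (n == 0L) stop("empty distance matrix")
  tri <- vapply(seq_len(n), function(i) {
    paste(c(format(dm$ids[i], width = 10),
            sprintf("%.4f", dm$d[i, seq_len(i - 1L)])), collapse = "  ")
  }, character(1))
  writeLines(c(sprintf("%5d", n), tri), path)
  sq <- as.data.frame(matrix(sprintf("%.4f", dm$d), n, n), stringsAsFactors = FALSE)
  names(sq) <- dm$ids
  sq <- cbind(specimen_id = dm$ids, sq)
  utils::write.table(sq, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, tsv_path))
}

#' Write a tree as Newick with bootstrap labels filtered for display
#'
#' Internal-node bootstrap supports are rendered as internal node labels.
#' Supports below `support_min_display` are omitted from the rendered file —
#' the convention used in published barcode NJ trees — but are never removed
#' from the in-memory tree.
#'
#' @param tree an `ape::phylo`, typically from [bootstrap_support()]
#' @param path output path
#' @param support_min_display integer percent; node labels that parse as
#'   numbers below this are blanked in the file (default 50). Use 0 to render
#'   every support.
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path, support_min_display = 50) {
  phy <- tree
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    hide <- !is.na(sup) & sup < support_min_display
    phy$node.label[hide] <- ""
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
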