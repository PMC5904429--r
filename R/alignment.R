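# Residue model: A, C, G, T are the only informative states. Everything else
# seen in barcode data (alignment gaps '-', N, '?', IUPAC ambiguity codes) is
# collapsed into a single "missing" class, coded 0, for every downstream
# computation (pairwise deletion, site classification, diagnostics).

.BASES <- c("A", "C", "G", "T")

# integer codes: A=1, C=2, G=3, T=4, missing=0
encode_residues <- function(seqs) {
  codes <- match(seqs, .BASES, nomatch = 0L)
  dim(codes) <- dim(seqs)
  dimnames(codes) <- dimnames(seqs)
  codes
}

normalize_residues <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  x
}

normalize_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[!nzchar(sex) | is.na(sex)] <- NA_character_
  known <- is.na(sex) | sex %in% c("male", "female", "unknown")
  if (!all(known)) {
    stop("invalid sex value(s): ", paste(unique(sex[!known]), collapse = ", "),
         " (expected male/female/unknown or NA)")
  }
  sex
}

#' Construct a labelled barcode alignment
#'
#' Bundles an aligned set of barcode sequences (one row per specimen) with a
#' specimen metadata table. Residues are upper-cased and RNA `U` is mapped to
#' `T`. Any character outside `A/C/G/T` — alignment gaps (`-`), `N`, `?` and
#' IUPAC ambiguity codes — is treated as a single *missing* class by all
#' downstream computations (pairwise deletion in distances, site
#' classification, diagnostic-site detection).
#'
#' Sequences must be pre-aligned and of equal length; protein-coding COI
#' barcodes are normally gap-free, so no aligner is embedded. Trim records to
#' the common covered region before input if coverage differs.
#'
#' @param seqs character matrix of aligned residues (rows = specimens), or a
#'   character vector of equal-length sequence strings, one per specimen.
#' @param meta data.frame with columns `specimen_id` and `species` (optional:
#'   `sex`, `accession`, `locality`), one row per specimen, in the same order
#'   as `seqs`.
#' @return An object of class `barcode_alignment`: a list with elements
#'   `seqs` (character matrix, rownames = specimen ids), `meta` (data.frame),
#'   `length` (number of alignment columns) and `codes` (integer matrix,
#'   A=1, C=2, G=3, T=4, missing=0).
#' @examples
#' aln <- barcode_alignment(
#'   c(x1 = "ACGTACGT", x2 = "ACGTACGA"),
#'   data.frame(specimen_id = c("x1", "x2"), species = c("sp1", "sp1"))
#' )
#' aln$length
#' @export
barcode_alignment <- function(seqs, meta) {
  if (!is.matrix(seqs)) {
    if (!is.character(seqs)) {
      stop("`seqs` must be a character matrix or a character vector of sequence strings")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1L])[1L]
      nm <- if (!is.null(names(seqs))) names(seqs)[bad] else as.character(bad)
      stop(sprintf("ragged alignment: record '%s' has %d residues, expected %d",
                   nm, lens[bad], lens[1L]))
    }
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("specimen_id", "species")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("sex", "accession", "locality")) {
    if (is.null(meta[[opt]])) meta[[opt]] <- NA_character_
  }
  meta <- meta[, c(required, "sex", "accession", "locality")]
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$species <- as.character(meta$species)
  meta$sex <- normalize_sex(meta$sex)
  if (nrow(meta) != nrow(seqs)) {
    stop(sprintf("metadata has %d rows but alignment has %d records",
                 nrow(meta), nrow(seqs)))
  }
  if (nrow(seqs) < 2L) stop("an alignment needs at least 2 records")
  dup <- meta$specimen_id[duplicated(meta$specimen_id)]
  if (length(dup)) stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  if (any(is.na(meta$species) | !nzchar(meta$species))) {
    stop("every specimen needs a non-empty species label")
  }
  seqs <- normalize_residues(seqs)
  rownames(seqs) <- meta$specimen_id
  colnames(seqs) <- NULL
  rownames(meta) <- NULL
  structure(
    list(seqs = seqs, meta = meta, length = ncol(seqs), codes = encode_residues(seqs)),
    class = "barcode_alignment"
  )
}

#' Number of specimens in an alignment
#' @param aln a `barcode_alignment`
#' @return integer
#' @export
n_specimens <- function(aln) nrow(aln$seqs)

#' Species label of every specimen
#' @param aln a `barcode_alignment`
#' @return named character vector (names = specimen ids)
#' @export
species_labels <- function(aln) {
  stats::setNames(aln$meta$species, aln$meta$specimen_id)
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d specimens x %d sites, %d species\n",
              nrow(x$seqs), x$length, length(unique(x$meta$species))))
  miss <- mean(x$codes == 0L)
  cat(sprintf("  missing/ambiguous residues: %.1f%%\n", 100 * miss))
  invisible(x)
}

# restrict an alignment to a subset of specimens (internal)
subset_alignment <- function(aln, keep) {
  idx <- if (is.logical(keep)) which(keep) else match(keep, aln$meta$specimen_id)
  structure(
    list(seqs = aln$seqs[idx, , drop = FALSE],
         meta = aln$meta[idx, , drop = FALSE],
         length = aln$length,
         codes = aln$codes[idx, , drop = FALSE]),
    class = "barcode_alignment"
  )
}
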