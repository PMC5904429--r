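# Character-based delimitation: alignment site classification and "pure"
# diagnostic sites (fixed within one species, absent from all others) in the
# style of CAOS pure-simple characters.

#' Classify alignment sites
#'
#' Each column is classified over its non-missing states: no state at all is
#' `all_missing`; exactly one distinct state is `constant`; two or more are
#' variable, and a variable column is `parsimony_informative` when at least
#' two states are each carried by at least two specimens (otherwise
#' `variable_uninformative`). Missing/ambiguous residues never count as
#' states.
#'
#' @param aln a `barcode_alignment`
#' @return object of class `site_classification`: list with counts `n_sites`,
#'   `n_constant`, `n_variable`, `n_parsimony_informative`, `n_all_missing`
#'   and the per-column factor `per_site`
#' @export
classify_sites <- function(aln) {
  codes <- aln$codes
  counts <- vapply(1:4, function(b) colSums(codes == b), numeric(ncol(codes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)  # single-column alignment
  n_states <- rowSums(counts > 0L)
  informative <- rowSums(counts >= 2L) >= 2L & n_states >= 2L
  per_site <- ifelse(n_states == 0L, "all_missing",
              ifelse(n_states == 1L, "constant",
              ifelse(informative, "parsimony_informative", "variable_uninformative")))
  per_site <- factor(per_site, levels = c("constant", "variable_uninformative",
                                          "parsimony_informative", "all_missing"))
  tab <- table(per_site)
  structure(list(
    n_sites = ncol(codes),
    n_constant = unname(tab[["constant"]]),
    n_variable = unname(tab[["variable_uninformative"]] + tab[["parsimony_informative"]]),
    n_parsimony_informative = unname(tab[["parsimony_informative"]]),
    n_all_missing = unname(tab[["all_missing"]]),
    per_site = per_site
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf("site_classification: %d sites — %d constant, %d variable (%d parsimony-informative), %d all-missing\n",
              x$n_sites, x$n_constant, x$n_variable, x$n_parsimony_informative,
              x$n_all_missing))
  invisible(x)
}

#' Pure diagnostic nucleotide sites per species
#'
#' A site `p` with state `x` is a *pure* diagnostic for species `S` when
#' every non-missing specimen of `S` carries `x` at `p` (with at least one
#' such specimen), no non-missing specimen of any other species carries `x`
#' at `p`, and the column is variable overall. Missing states neither support
#' nor contradict a diagnosis, so a species entirely missing at a column
#' cannot be diagnosed there. Positions are 1-based alignment coordinates.
#'
#' @param aln a `barcode_alignment`
#' @param outgroup species labels treated as outgroup
#' @param ingroup_only if `TRUE` (default) outgroup specimens are removed
#'   before the scan — diagnostics are fixed-in/absent-out with respect to
#'   the ingroup only; if `FALSE` all specimens take part
#' @param include_private also report *private-but-not-fixed* characters
#'   (state found in only one species but not carried by all its specimens) —
#'   a weaker, clearly separated category
#' @return object of class `diagnostic_table`: list with `sites` (data.frame
#'   `species`, `position`, `state`), the `species` scanned, `positions`
#'   (sorted union of diagnostic positions) and, when requested, `private`
#' @export
pure_diagnostic_sites <- function(aln, outgroup = character(),
                                  ingroup_only = TRUE, include_private = FALSE) {
  if (ingroup_only && length(outgroup)) {
    aln <- subset_alignment(aln, !(aln$meta$species %in% outgroup))
  }
  codes <- aln$codes
  sp <- aln$meta$species
  species <- unique(sp)
  if (length(species) < 2L) stop("diagnostic scan needs at least 2 species")
  L <- ncol(codes)
  # pres[s, b, p]: does species s carry base b at column p?
  pres <- array(FALSE, dim = c(length(species), 4L, L))
  for (si in seq_along(species)) {
    block <- codes[sp == species[si], , drop = FALSE]
    for (b in 1:4) pres[si, b, ] <- colSums(block == b) > 0L
  }
  n_species_with_state <- apply(pres, c(2L, 3L), sum)   # 4 x L
  states_per_species <- apply(pres, c(1L, 3L), sum)     # nsp x L
  n_states_col <- colSums(n_species_with_state > 0L)    # distinct states per column
  sites <- list()
  private <- list()
  for (si in seq_along(species)) {
    for (b in 1:4) {
      here <- pres[si, b, ] & n_species_with_state[b, ] == 1L & n_states_col >= 2L
      fixed <- here & states_per_species[si, ] == 1L
      if (any(fixed)) {
        sites[[length(sites) + 1L]] <- data.frame(
          species = species[si], position = which(fixed),
          state = .BASES[b], stringsAsFactors = FALSE)
      }
      if (include_private) {
        priv <- here & states_per_species[si, ] > 1L
        if (any(priv)) {
          private[[length(private) + 1L]] <- data.frame(
            species = species[si], position = which(priv),
            state = .BASES[b], stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(species = character(0), position = integer(0),
                      state = character(0), stringsAsFactors = FALSE)
  sites <- if (length(sites)) do.call(rbind, sites) else empty
  sites <- sites[order(match(sites$species, species), sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  out <- list(sites = sites, species = species,
              positions = sort(unique(sites$position)))
  if (include_private) {
    private <- if (length(private)) do.call(rbind, private) else empty
    private <- private[order(match(private$species, species), private$position), ,
                       drop = FALSE]
    rownames(private) <- NULL
    out$private <- private
  }
  structure(out, class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  per <- table(factor(x$sites$species, levels = x$species))
  cat(sprintf("diagnostic_table: %d pure diagnostic (species, site) pairs over %d species\n",
              nrow(x$sites), length(x$species)))
  for (S in x$species) cat(sprintf("  %s: %d\n", S, per[[S]]))
  invisible(x)
}

#' Specimen-by-position grid of diagnostic sites
#'
#' Renders the alignment restricted to the union of diagnostic positions:
#' rows are specimens grouped by species, columns the sorted positions, cells
#' the residue (or `-` for any missing/ambiguous state). A parallel logical
#' mask marks the cells belonging to a (species, position) diagnostic — the
#' machine-readable analogue of shading in published diagnostic-site figures.
#'
#' @param table a `diagnostic_table` from [pure_diagnostic_sites()]
#' @param aln the `barcode_alignment` the table was computed from
#' @return list with `grid` (data.frame: `specimen_id`, `species`, one column
#'   per position) and `mask` (logical matrix, specimens x positions)
#' @export
diagnostic_report <- function(table, aln) {
  pos <- table$positions
  ord <- order(match(aln$meta$species, table$species))
  ord <- ord[!is.na(match(aln$meta$species[ord], table$species))]
  ids <- aln$meta$specimen_id[ord]
  sp <- aln$meta$species[ord]
  cells <- aln$seqs[ord, pos, drop = FALSE]
  cells[aln$codes[ord, pos, drop = FALSE] == 0L] <- "-"
  mask <- matrix(FALSE, length(ord), length(pos),
                 dimnames = list(ids, as.character(pos)))
  if (nrow(table$sites)) {
    for (k in seq_len(nrow(table$sites))) {
      j <- match(table$sites$position[k], pos)
      mask[sp == table$sites$species[k], j] <- TRUE
    }
  }
  grid <- data.frame(specimen_id = ids, species = sp, stringsAsFactors = FALSE)
  for (j in seq_along(pos)) grid[[as.character(pos[j])]] <- unname(cells[, j])
  list(grid = grid, mask = mask)
}
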