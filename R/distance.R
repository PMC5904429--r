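# Uncorrected p-distances under pairwise deletion. The whole matrix is
# computed with cross-products of per-base indicator matrices, so bootstrap
# replicates stay cheap; correctness against a per-pair double loop is
# enforced in the test suite.

# core: codes is an integer matrix (specimens x sites, 0 = missing).
# Returns list(n = comparable-site counts, mism = mismatch counts), or NULL
# when `strict = FALSE` and some pair has zero comparable sites.
pdist_core <- function(codes, strict = TRUE) {
  pres <- (codes > 0L) * 1
  n_cmp <- tcrossprod(pres)
  eq <- matrix(0, nrow(codes), nrow(codes))
  for (b in 1:4) eq <- eq + tcrossprod((codes == b) * 1)
  off <- n_cmp
  diag(off) <- 1
  if (any(off == 0)) {
    if (!strict) return(NULL)
    bad <- which(off == 0, arr.ind = TRUE)[1L, ]
    ids <- rownames(codes)
    stop(sprintf("no comparable sites between '%s' and '%s' (disjoint coverage)",
                 ids[bad[1L]], ids[bad[2L]]))
  }
  list(n = n_cmp, mism = n_cmp - eq)
}

new_pdist_matrix <- function(ids, d, n_sites) {
  dimnames(d) <- list(ids, ids)
  storage.mode(n_sites) <- "integer"
  dimnames(n_sites) <- list(ids, ids)
  structure(list(ids = ids, d = d, n_sites = n_sites), class = "pdist_matrix")
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of differing sites among sites where both sequences carry
#' an unambiguous base (pairwise deletion: a column is excluded from this
#' pair's comparison when either member is missing or ambiguous there).
#'
#' @param seq_a,seq_b aligned residues: character vectors, or single strings
#'   of equal length. Case and `U`/`T` are normalized.
#' @return list with `distance` (proportion in \[0, 1\]) and `sites_compared`
#'   (positive integer count of comparable columns).
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' p_distance("ACNT", "ACGT")  # 0 over 3 sites: the N column is deleted
#' @export
p_distance <- function(seq_a, seq_b) {
  as_residues <- function(s) {
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "", fixed = TRUE)[[1L]]
    match(normalize_residues(s), .BASES, nomatch = 0L)
  }
  a <- as_residues(seq_a)
  b <- as_residues(seq_b)
  if (length(a) != length(b)) {
    stop(sprintf("sequences differ in length (%d vs %d)", length(a), length(b)))
  }
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites (disjoint coverage)")
  list(distance = sum(a[ok] != b[ok]) / n, sites_compared = n)
}

#' Pairwise p-distance matrix for an alignment
#'
#' Applies [p_distance()] to every specimen pair (computed jointly for
#' speed), keeping per-pair counts of compared sites.
#'
#' @param aln a `barcode_alignment`
#' @return object of class `pdist_matrix`: list with `ids`, symmetric
#'   matrix `d` of proportions (zero diagonal) and symmetric integer matrix
#'   `n_sites` of compared-site counts.
#' @export
distance_matrix <- function(aln) {
  codes <- aln$codes
  if (nrow(codes) < 2L) stop("need at least 2 records to compute distances")
  pc <- pdist_core(codes, strict = TRUE)
  d <- pc$mism / pmax(pc$n, 1L)
  diag(d) <- 0
  new_pdist_matrix(rownames(codes), d, pc$n)
}

#' @export
print.pdist_matrix <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("pdist_matrix: %d specimens, p-distance range %.4f-%.4f\n",
              n, min(off), max(off)))
  invisible(x)
}

#' Per-species intra- and interspecific distance summaries
#'
#' For every (ingroup) species: the minimum, maximum, arithmetic mean and
#' sample standard deviation (denominator n-1) of (a) all unordered
#' conspecific pairwise distances and (b) all distances from its specimens to
#' every other ingroup specimen. Each heterospecific pair therefore
#' contributes to both species' interspecific rows, giving the usual
#' one-row-per-species barcode summary table. Intraspecific fields are `NA`
#' for singleton species, and the intraspecific SD is `NA` when only one
#' conspecific pair exists.
#'
#' @param dm a `pdist_matrix`
#' @param labels species label per specimen: a named character vector
#'   (names = specimen ids) or a vector aligned with `dm$ids`
#' @param outgroup character vector of species labels to exclude entirely
#'   (no summary row, and not counted in other species' interspecific pools)
#' @return data.frame with columns `species`, `n_seqs`, `intra_min`,
#'   `intra_max`, `intra_mean`, `intra_sd`, `inter_min`, `inter_max`,
#'   `inter_mean`, `inter_sd`
#' @export
summarize_species <- function(dm, labels, outgroup = character()) {
  if (is.factor(labels)) {
    empty <- setdiff(levels(labels), as.character(unique(labels)))
    if (length(empty)) {
      warning("skipping species with no specimens: ", paste(empty, collapse = ", "))
    }
    labels <- as.character(labels)
  }
  if (!is.null(names(labels)) && all(dm$ids %in% names(labels))) {
    labels <- unname(labels[dm$ids])
  }
  if (length(labels) != length(dm$ids) || anyNA(labels)) {
    stop("every specimen in the distance matrix must carry a species label")
  }
  ingroup <- !(labels %in% outgroup)
  species <- unique(labels[ingroup])
  stat_row <- function(v, sd_min_pairs = 2L) {
    if (length(v) == 0L) {
      c(min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_)
    } else {
      c(min = min(v), max = max(v), mean = mean(v),
        sd = if (length(v) >= sd_min_pairs) stats::sd(v) else NA_real_)
    }
  }
  rows <- lapply(species, function(S) {
    idx <- which(ingroup & labels == S)
    others <- which(ingroup & labels != S)
    n <- length(idx)
    intra <- if (n >= 2L) dm$d[idx, idx, drop = FALSE][upper.tri(diag(n))] else numeric(0)
    inter <- as.vector(dm$d[idx, others, drop = FALSE])
    a <- stat_row(intra)
    e <- stat_row(inter)
    data.frame(species = S, n_seqs = n,
               intra_min = a["min"], intra_max = a["max"],
               intra_mean = a["mean"], intra_sd = a["sd"],
               inter_min = e["min"], inter_max = e["max"],
               inter_mean = e["mean"], inter_sd = e["sd"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a species distance summary as TSV
#'
#' Proportions are printed with 4 decimals; undefined cells as literal `NA`.
#'
#' @param summaries data.frame from [summarize_species()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_species_summary <- function(summaries, path) {
  out <- summaries
  num <- setdiff(names(out), c("species", "n_seqs"))
  for (cl in num) out[[cl]] <- ifelse(is.na(out[[cl]]), "NA", sprintf("%.4f", out[[cl]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Barcode-gap report
#'
#' Per species, the gap between its smallest interspecific and largest
#' intraspecific distance (`inter_min - intra_max`, `NA`-propagating), plus
#' the global extremes: the largest intraspecific maximum with the species
#' attaining it, and the smallest interspecific minimum with the species pair
#' attaining it. A positive gap for every species is the classic barcode-gap
#' condition for distance-based delimitation.
#'
#' @param summaries data.frame from [summarize_species()]
#' @return object of class `barcode_gap`: list with `per_species` (data.frame
#'   `species`, `intra_max`, `inter_min`, `gap`) and `global` (list
#'   `largest_intra_max`, `largest_intra_species`, `smallest_inter_min`,
#'   `smallest_inter_species`)
#' @export
barcode_gap <- function(summaries) {
  per <- data.frame(species = summaries$species,
                    intra_max = summaries$intra_max,
                    inter_min = summaries$inter_min,
                    gap = summaries$inter_min - summaries$intra_max,
                    stringsAsFactors = FALSE)
  all_na <- function(x) all(is.na(x))
  global <- list(
    largest_intra_max = if (all_na(per$intra_max)) NA_real_ else max(per$intra_max, na.rm = TRUE),
    largest_intra_species = character(0),
    smallest_inter_min = if (all_na(per$inter_min)) NA_real_ else min(per$inter_min, na.rm = TRUE),
    smallest_inter_species = character(0)
  )
  if (!is.na(global$largest_intra_max)) {
    global$largest_intra_species <-
      per$species[!is.na(per$intra_max) & per$intra_max == global$largest_intra_max]
  }
  if (!is.na(global$smallest_inter_min)) {
    global$smallest_inter_species <-
      per$species[!is.na(per$inter_min) & per$inter_min == global$smallest_inter_min]
  }
  structure(list(per_species = per, global = global), class = "barcode_gap")
}

#' @export
print.barcode_gap <- function(x, ...) {
  g <- x$global
  cat("barcode_gap report\n")
  if (!is.na(g$largest_intra_max)) {
    cat(sprintf("  largest intraspecific max: %.4f (%s)\n",
                g$largest_intra_max, paste(g$largest_intra_species, collapse = ", ")))
  }
  if (!is.na(g$smallest_inter_min)) {
    cat(sprintf("  smallest interspecific min: %.4f (%s)\n",
                g$smallest_inter_min, paste(g$smallest_inter_species, collapse = " / ")))
  }
  neg <- x$per_species$species[!is.na(x$per_species$gap) & x$per_species$gap <= 0]
  cat(if (length(neg)) paste("  gap violated for:", paste(neg, collapse = ", "), "\n")
      else "  gap positive for every species with a defined gap\n")
  invisible(x)
}

#' Bootstrap standard errors of per-species mean distances
#'
#' Site-resampling alternative to the analytic SD column of
#' [summarize_species()]: alignment columns are resampled with replacement,
#' the per-species mean intra- and interspecific distances recomputed, and
#' the standard deviation across replicates reported as a standard error.
#' Barcode papers vary in whether their "±" column is the SD of the pairwise
#' values or a bootstrap SE of the mean; this function provides the latter
#' for comparison.
#'
#' @param aln a `barcode_alignment`
#' @param outgroup species labels excluded from the summaries
#' @param replicates number of site resamples (default 1000)
#' @param seed integer seed
#' @return data.frame with columns `species`, `intra_mean_se`, `inter_mean_se`
#' @export
bootstrap_distance_se <- function(aln, outgroup = character(),
                                  replicates = 1000, seed = 1) {
  labels <- aln$meta$species
  ingroup <- !(labels %in% outgroup)
  species <- unique(labels[ingroup])
  set.seed(seed)
  L <- aln$length
  acc <- array(NA_real_, dim = c(replicates, length(species), 2L))
  b <- 0L
  attempts <- 0L
  while (b < replicates) {
    attempts <- attempts + 1L
    if (attempts > 10L * replicates) {
      stop("too many bootstrap replicates with non-comparable pairs")
    }
    pc <- pdist_core(aln$codes[, sample.int(L, L, replace = TRUE), drop = FALSE],
                     strict = FALSE)
    if (is.null(pc)) next
    b <- b + 1L
    d <- pc$mism / pmax(pc$n, 1L)
    diag(d) <- 0
    for (si in seq_along(species)) {
      idx <- which(ingroup & labels == species[si])
      others <- which(ingroup & labels != species[si])
      n <- length(idx)
      if (n >= 2L) {
        acc[b, si, 1L] <- mean(d[idx, idx, drop = FALSE][upper.tri(diag(n))])
      }
      if (length(others)) acc[b, si, 2L] <- mean(d[idx, others])
    }
  }
  data.frame(species = species,
             intra_mean_se = apply(acc[, , 1L, drop = FALSE], 2L, stats::sd),
             inter_mean_se = apply(acc[, , 2L, drop = FALSE], 2L, stats::sd),
             stringsAsFactors = FALSE)
}
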