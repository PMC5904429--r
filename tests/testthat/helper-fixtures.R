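# Fixtures and independent brute-force oracles. The oracles deliberately use
# naive per-column loops so they share no code path with the vectorized
# implementations they check.

make_aln <- function(seqs, species, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else sprintf("s%02d", seq_along(species))
  }
  barcode_alignment(unname(seqs),
                    data.frame(specimen_id = ids, species = species,
                               stringsAsFactors = FALSE))
}

# 4 x 8 two-species toy: site 3 is diagnostic (G for X, C for Y), site 8 is
# variable within X so not diagnostic
toy_aln <- function() {
  make_aln(c("ACGTACGT", "ACGTACGA", "ACCTACGT", "ACCTACGT"),
           species = c("X", "X", "Y", "Y"),
           ids = c("X1", "X2", "Y1", "Y2"))
}

MISSING_CHARS <- c("-", "N", "?", "R", "Y", "W", "S", "K", "M")

random_alignment <- function(n, L, miss_prob = 0.1, n_species = 2,
                             ids = sprintf("r%02d", seq_len(n))) {
  chars <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (miss_prob > 0) {
    hit <- matrix(runif(n * L) < miss_prob, n, L)
    chars[hit] <- sample(MISSING_CHARS, sum(hit), replace = TRUE)
  }
  species <- sprintf("sp%d", rep_len(seq_len(n_species), n))
  make_aln(apply(chars, 1, paste, collapse = ""), species, ids = ids)
}

# oracle: p-distances by an explicit double loop over pairs and columns
brute_pdist <- function(aln) {
  seqs <- aln$seqs
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  ns <- matrix(0L, n, n, dimnames = dimnames(d))
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    ns[i, i] <- sum(is_base(seqs[i, ]))
    if (i == n) break
    for (j in (i + 1L):n) {
      cmp <- 0L
      mism <- 0L
      for (p in seq_len(ncol(seqs))) {
        a <- seqs[i, p]
        b <- seqs[j, p]
        if (is_base(a) && is_base(b)) {
          cmp <- cmp + 1L
          if (a != b) mism <- mism + 1L
        }
      }
      stopifnot(cmp > 0L)
      d[i, j] <- d[j, i] <- mism / cmp
      ns[i, j] <- ns[j, i] <- cmp
    }
  }
  list(d = d, n_sites = ns)
}

# oracle: pure diagnostics by an explicit species x column x specimen loop
brute_diagnostics <- function(aln) {
  seqs <- aln$seqs
  sp <- aln$meta$species
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  rows <- list()
  for (S in unique(sp)) {
    for (p in seq_len(ncol(seqs))) {
      col <- seqs[, p]
      states_col <- unique(col[is_base(col)])
      if (length(states_col) < 2L) next
      mine <- col[sp == S]
      mine <- mine[is_base(mine)]
      if (length(mine) == 0L || length(unique(mine)) != 1L) next
      x <- mine[1L]
      other <- col[sp != S]
      if (x %in% other[is_base(other)]) next
      rows[[length(rows) + 1L]] <- data.frame(species = S, position = p,
                                              state = x, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), position = integer(0),
               state = character(0), stringsAsFactors = FALSE)
}

# random additive distance matrix: path lengths of a random tree with known
# positive branch lengths (closed-form oracle for NJ recovery)
random_additive <- function(n_taxa) {
  phy <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 0.5))
  phy <- ape::unroot(phy)
  list(tree = phy, d = ape::cophenetic.phylo(phy))
}

write_aln_files <- function(aln, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "aln.fasta")
  tsv <- file.path(dir, "meta.tsv")
  write_alignment(aln, fa, tsv)
  list(fasta = fa, metadata = tsv)
}
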