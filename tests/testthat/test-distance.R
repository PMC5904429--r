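test_that("p_distance handles identity, mismatch and pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), list(distance = 0, sites_compared = 4L))
  expect_equal(p_distance("ACGT", "ACGA"), list(distance = 0.25, sites_compared = 4L))
  expect_equal(p_distance("ACNT", "ACGT"), list(distance = 0, sites_compared = 3L))
  expect_equal(p_distance("AC-T", "ACGA"), list(distance = 1 / 3, sites_compared = 3L))
  expect_error(p_distance("NN--", "AC--"), "no comparable sites")
  expect_error(p_distance("ACGT", "ACG"), "length")
})

test_that("distance_matrix covers degenerate alignments", {
  ident <- distance_matrix(make_aln(c("ACGT", "ACGT", "ACGT"), c("a", "b", "c")))
  expect_true(all(ident$d == 0))
  expect_true(all(ident$n_sites == 4L))

  opposite <- distance_matrix(make_aln(c("ACGT", "TGCA"), c("a", "b")))
  expect_equal(opposite$d[1, 2], 1)

  disjoint <- make_aln(c("AC--", "--GT", "ACGT"), c("a", "b", "c"))
  expect_error(distance_matrix(disjoint), "no comparable sites.*s0[12].*s0[12]")
})

test_that("distance_matrix equals the brute-force double-loop oracle", {
  toy <- toy_aln()
  dm <- distance_matrix(toy)
  oracle <- brute_pdist(toy)
  expect_equal(dm$d, oracle$d)
  expect_equal(dm$n_sites[upper.tri(dm$n_sites)],
               oracle$n_sites[upper.tri(oracle$n_sites)])

  for (seed in 1:10) {
    set.seed(seed)
    aln <- random_alignment(sample(3:6, 1), sample(10:20, 1), miss_prob = 0.15)
    dm <- distance_matrix(aln)
    oracle <- brute_pdist(aln)
    expect_equal(dm$d, oracle$d)
    expect_equal(dm$n_sites[upper.tri(dm$n_sites)],
                 oracle$n_sites[upper.tri(oracle$n_sites)])
    # symmetric, zero diagonal, bounded, pairwise n_sites <= alignment length
    expect_identical(dm$d, t(dm$d))
    expect_true(all(diag(dm$d) == 0))
    expect_true(all(dm$d >= 0 & dm$d <= 1))
    expect_true(all(dm$n_sites[upper.tri(dm$n_sites)] <= aln$length))
  }
})

test_that("with no missing data every pair compares the full alignment", {
  set.seed(3)
  aln <- random_alignment(5, 30, miss_prob = 0)
  dm <- distance_matrix(aln)
  expect_true(all(dm$n_sites == 30L))
})

test_that("specimen order does not affect distances or summaries", {
  set.seed(11)
  aln <- random_alignment(8, 25, miss_prob = 0.1, n_species = 3)
  dm <- distance_matrix(aln)
  perm <- sample(n_specimens(aln))
  aln2 <- barcode_alignment(aln$seqs[perm, ], aln$meta[perm, ])
  dm2 <- distance_matrix(aln2)
  expect_equal(dm2$d[dm$ids, dm$ids], dm$d)

  s1 <- summarize_species(dm, species_labels(aln))
  s2 <- summarize_species(dm2, species_labels(aln2))
  expect_equal(s1[order(s1$species), ], s2[order(s2$species), ],
               ignore_attr = TRUE)
})

test_that("species summaries follow the intra/inter pooling contract", {
  # two identical conspecifics: single pair, zero distances, SD undefined
  aln <- make_aln(c("ACGTACGT", "ACGTACGT", "TTTTACGT", "TTTAACGT"),
                  c("A", "A", "B", "B"))
  s <- summarize_species(distance_matrix(aln), species_labels(aln))
  rowA <- s[s$species == "A", ]
  expect_equal(rowA$n_seqs, 2L)
  expect_equal(c(rowA$intra_min, rowA$intra_max, rowA$intra_mean), c(0, 0, 0))
  expect_true(is.na(rowA$intra_sd))

  # single species: no heterospecific pairs, inter fields NA
  solo <- summarize_species(distance_matrix(make_aln(c("ACGT", "ACGA"),
                                                     c("A", "A"))),
                            c("A", "A"))
  expect_true(all(is.na(solo[, c("inter_min", "inter_max", "inter_mean", "inter_sd")])))

  # three conspecifics with pairwise distances {0.002, 0.002, 0.003}
  base <- strrep("A", 1000)
  v <- function(pos, to) {
    x <- strsplit(base, "")[[1]]
    x[pos] <- to
    paste(x, collapse = "")
  }
  trio <- make_aln(c(base, v(1:2, c("C", "C")), v(c(1, 3), c("G", "C")), strrep("T", 1000)),
                   c("A", "A", "A", "B"))
  st <- summarize_species(distance_matrix(trio), species_labels(trio))
  rowA <- st[st$species == "A", ]
  expect_equal(rowA$intra_min, 0.002)
  expect_equal(rowA$intra_max, 0.003)
  expect_equal(rowA$intra_mean, mean(c(0.002, 0.002, 0.003)))
  expect_equal(rowA$intra_sd, sd(c(0.002, 0.002, 0.003)))
})

test_that("intra/inter pair counts pool correctly and outgroups are excluded", {
  set.seed(21)
  aln <- random_alignment(9, 40, miss_prob = 0, n_species = 3)
  labels <- species_labels(aln)
  dm <- distance_matrix(aln)
  s <- summarize_species(dm, labels)
  n_s <- table(labels)
  expect_equal(s$n_seqs[match(names(n_s), s$species)], as.integer(n_s),
               ignore_attr = TRUE)
  # each heterospecific pair contributes to both species' inter rows
  n_intra_pairs <- sum(choose(as.integer(n_s), 2))
  n_hetero_pairs <- choose(9, 2) - n_intra_pairs
  inter_counts <- vapply(s$species, function(S) {
    sum(labels == S) * sum(labels != S)
  }, numeric(1))
  expect_equal(sum(inter_counts), 2 * n_hetero_pairs)

  withog <- summarize_species(dm, labels, outgroup = "sp3")
  expect_false("sp3" %in% withog$species)
  # outgroup removal shrinks the inter pool: inter stats must not use sp3
  manual <- dm$d[labels == "sp1", labels == "sp2"]
  expect_equal(withog$inter_min[withog$species == "sp1"], min(manual))
  expect_equal(withog$inter_max[withog$species == "sp1"], max(manual))
})

test_that("barcode_gap arithmetic, NA propagation and global extremes", {
  s <- data.frame(
    species = c("A", "B", "C"),
    n_seqs = c(3L, 2L, 1L),
    intra_min = c(0, 0, NA), intra_max = c(0.01, 0.02, NA),
    intra_mean = c(0.005, 0.01, NA), intra_sd = c(0.001, NA, NA),
    inter_min = c(0.05, 0.04, 0.04), inter_max = c(0.1, 0.1, 0.09),
    inter_mean = c(0.07, 0.06, 0.06), inter_sd = c(0.01, 0.01, 0.01))
  g <- barcode_gap(s)
  expect_equal(g$per_species$gap, c(0.04, 0.02, NA))
  expect_equal(g$global$largest_intra_max, 0.02)
  expect_equal(g$global$largest_intra_species, "B")
  expect_equal(g$global$smallest_inter_min, 0.04)
  expect_setequal(g$global$smallest_inter_species, c("B", "C"))
})

test_that("bootstrap SE of mean distances is reproducible and plausible", {
  set.seed(5)
  sim <- simulate_dataset(simulation_config(n_species = 3,
                                            specimens_per_species = 3,
                                            seq_length = 200, seed = 5))
  se1 <- bootstrap_distance_se(sim$alignment, replicates = 50, seed = 9)
  se2 <- bootstrap_distance_se(sim$alignment, replicates = 50, seed = 9)
  expect_equal(se1, se2)
  expect_true(all(se1$inter_mean_se > 0))
  expect_true(all(se1$inter_mean_se < 0.05))
})
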