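test_that("site classification follows the column definitions", {
  aln <- make_aln(c("AAAA", "AACA", "A-GC", "ANTC"), c("w", "x", "y", "z"))
  # columns: (A,A,A,A) constant; (A,A,-,N) constant (missing ignored);
  # (A,C,G,T) variable singleton; (A,A,C,C) parsimony informative
  cls <- classify_sites(aln)
  expect_equal(as.character(cls$per_site),
               c("constant", "constant", "variable_uninformative",
                 "parsimony_informative"))
  expect_equal(cls$n_constant, 2L)
  expect_equal(cls$n_variable, 2L)
  expect_equal(cls$n_parsimony_informative, 1L)

  gone <- classify_sites(make_aln(c("A-N?", "AN-R"), c("x", "y")))
  expect_equal(cls_counts <- gone$n_all_missing, 3L)
})

test_that("classification counts are conserved and row-order invariant", {
  for (seed in 1:8) {
    set.seed(seed)
    aln <- random_alignment(sample(4:10, 1), sample(20:50, 1), miss_prob = 0.2)
    cls <- classify_sites(aln)
    expect_equal(cls$n_constant + cls$n_variable + cls$n_all_missing, cls$n_sites)
    expect_lte(cls$n_parsimony_informative, cls$n_variable)

    perm <- sample(n_specimens(aln))
    cls2 <- classify_sites(barcode_alignment(aln$seqs[perm, ], aln$meta[perm, ]))
    expect_equal(cls2$per_site, cls$per_site)
  }
})

test_that("pure diagnostics on the two-species toy alignment", {
  dt <- pure_diagnostic_sites(toy_aln())
  # site 3: G fixed in X, C fixed in Y; site 8 polymorphic within X
  expect_true(any(dt$sites$species == "X" & dt$sites$position == 3 & dt$sites$state == "G"))
  expect_true(any(dt$sites$species == "Y" & dt$sites$position == 3 & dt$sites$state == "C"))
  expect_false(any(dt$sites$position == 8))
  expect_equal(dt$positions, 3L)
})

test_that("missing data and shared states block a diagnosis", {
  # species B entirely missing at site 1; A and C share T at site 2
  aln <- make_aln(c("GT", "GT", "-A", "-A", "CT", "CT"),
                  c("A", "A", "B", "B", "C", "C"))
  dt <- pure_diagnostic_sites(aln)
  expect_false(any(dt$sites$species == "B" & dt$sites$position == 1))
  # T at site 2 is shared by A and C: diagnostic for neither
  expect_false(any(dt$sites$position == 2 & dt$sites$state == "T"))
  # site 1 still diagnoses A (G) and C (C) against each other
  expect_true(any(dt$sites$species == "A" & dt$sites$position == 1 & dt$sites$state == "G"))

  # a column constant across the alignment is never diagnostic, even when
  # only one species is non-missing there
  cst <- make_aln(c("AT", "AT", "-T", "-T"), c("A", "A", "B", "B"))
  expect_false(any(pure_diagnostic_sites(cst)$sites$position == 1))
})

test_that("pure diagnostics equal the brute-force triple-loop oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    aln <- random_alignment(sample(6:20, 1), sample(20:50, 1),
                            miss_prob = 0.15, n_species = sample(2:4, 1))
    got <- pure_diagnostic_sites(aln)$sites
    want <- brute_diagnostics(aln)
    key <- function(d) sort(paste(d$species, d$position, d$state))
    expect_equal(key(got), key(want))
  }
})

test_that("adding a conflicting specimen removes a diagnostic (monotonicity)", {
  aln <- toy_aln()
  dt <- pure_diagnostic_sites(aln)
  expect_true(any(dt$sites$species == "X" & dt$sites$position == 3))
  # a new X specimen carrying Y's state at site 3
  bigger <- make_aln(c(apply(aln$seqs, 1, paste, collapse = ""), "ACCTACGT"),
                     c(aln$meta$species, "X"),
                     ids = c(aln$meta$specimen_id, "X3"))
  dt2 <- pure_diagnostic_sites(bigger)
  expect_false(any(dt2$sites$species == "X" & dt2$sites$position == 3))
  expect_false(any(dt2$sites$species == "Y" & dt2$sites$position == 3))
})

test_that("outgroup specimens are excluded when ingroup_only is set", {
  # outgroup shares X's diagnostic state; must not veto it under ingroup_only
  aln <- make_aln(c("ACGTACGT", "ACGTACGT", "ACCTACGT", "ACCTACGT", "ACGTACGT"),
                  c("X", "X", "Y", "Y", "OG"))
  with_og <- pure_diagnostic_sites(aln, outgroup = "OG", ingroup_only = FALSE)
  expect_false(any(with_og$sites$species == "X" & with_og$sites$position == 3))
  ingroup <- pure_diagnostic_sites(aln, outgroup = "OG", ingroup_only = TRUE)
  expect_true(any(ingroup$sites$species == "X" & ingroup$sites$position == 3))
  expect_false("OG" %in% ingroup$species)
})

test_that("private-but-not-fixed characters are reported separately on request", {
  # X carries T and A at site 8; T is private to X but not fixed
  dt <- pure_diagnostic_sites(toy_aln(), include_private = TRUE)
  expect_false(any(dt$sites$position == 8))
  expect_true(any(dt$private$species == "X" & dt$private$position == 8 &
                    dt$private$state == "A"))
})

test_that("diagnostic grid mirrors the alignment at diagnostic positions", {
  aln <- toy_aln()
  dt <- pure_diagnostic_sites(aln)
  rep <- diagnostic_report(dt, aln)
  expect_equal(nrow(rep$grid), 4L)
  expect_equal(ncol(rep$mask), length(dt$positions))
  expect_equal(rep$grid[["3"]], c("G", "G", "C", "C"))
  expect_true(all(rep$mask[, "3"]))

  # masked residues render as '-'
  masked <- make_aln(c("ACGTACGT", "ACGTACGT", "ACCTACG-", "ACCTACNT"),
                     c("X", "X", "Y", "Y"))
  dtm <- pure_diagnostic_sites(masked)
  repm <- diagnostic_report(dtm, masked)
  expect_true(all(unlist(repm$grid[, -(1:2)]) %in% c("A", "C", "G", "T", "-")))

  # empty table gives a header-only grid
  none <- make_aln(c("AAAA", "AAAA"), c("X", "Y"))
  dt0 <- pure_diagnostic_sites(none)
  rep0 <- diagnostic_report(dt0, none)
  expect_equal(ncol(rep0$grid), 2L)
  expect_equal(ncol(rep0$mask), 0L)
})
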