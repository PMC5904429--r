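#' End-to-end run configuration
#'
#' Exactly one input mode must be chosen: either an alignment/metadata file
#' pair, or simulation from a [simulation_config()].
#'
#' @param alignment path to an aligned FASTA (with `metadata`), or `NULL`
#' @param metadata path to the specimen TSV, or `NULL`
#' @param simulate logical; simulate the dataset instead of reading files
#' @param sim_config `sim_config` used when `simulate = TRUE`; its seed is
#'   overridden by `seed` so one seed drives the whole run
#' @param outgroup character vector of outgroup *species* labels; excluded
#'   from distance summaries and diagnostics, used to root the tree
#' @param bootstrap_replicates bootstrap replicate count (default 1000)
#' @param seed integer seed for every source of randomness in the run
#' @param support_min_display bootstrap percentages below this are hidden in
#'   the rendered Newick (default 50)
#' @param out_dir output directory (created if absent)
#' @return a `run_config` list
#' @export
run_config <- function(alignment = NULL, metadata = NULL,
                       simulate = FALSE, sim_config = paperlike_config(),
                       outgroup = character(),
                       bootstrap_replicates = 1000, seed = 1,
                       support_min_display = 50, out_dir = "barcode_run") {
  has_files <- !is.null(alignment) || !is.null(metadata)
  if (simulate == has_files) {
    stop("choose exactly one input mode: alignment+metadata files, or simulate")
  }
  if (has_files && (is.null(alignment) || is.null(metadata))) {
    stop("file mode needs both `alignment` and `metadata`")
  }
  structure(list(alignment = alignment, metadata = metadata,
                 simulate = simulate, sim_config = sim_config,
                 outgroup = outgroup,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed),
                 support_min_display = support_min_display,
                 out_dir = out_dir),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  writeLines(msg, con)
}

#' Run the full delimitation pipeline
#'
#' Distances, per-species summaries, barcode-gap report, bootstrapped NJ tree
#' (rooted on the outgroup when given), per-species clade supports, site
#' classification and pure diagnostic sites, all written under
#' `config$out_dir`, plus a run log and a per-species verdict table
#' (monophyletic? at least one pure diagnostic? positive barcode gap?).
#' With fewer than 3 specimens the tree stage is skipped with a warning;
#' distances and diagnostics are still produced.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with every computed object: `alignment`,
#'   `distances`, `summaries`, `gap`, `tree` (or NULL), `clade_support`,
#'   `sites`, `diagnostics`, `report`, `verdicts`, `files`
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  logcon <- file(out("run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  log_line(logcon, "barcodedelim ", as.character(utils::packageVersion("barcodedelim")),
           " | ", R.version.string)
  log_line(logcon, "seed: ", config$seed,
           " | bootstrap replicates: ", config$bootstrap_replicates)
  files <- character(0)

  stage <- "input"
  result <- tryCatch({
    if (config$simulate) {
      cfg <- config$sim_config
      cfg$seed <- config$seed
      sim <- simulate_dataset(cfg)
      aln <- sim$alignment
      write_alignment(aln, out("alignment.fasta"), out("metadata.tsv"))
      utils::write.table(sim$truth$diagnostics, out("truth_diagnostics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, out("alignment.fasta"), out("metadata.tsv"),
                 out("truth_diagnostics.tsv"))
      log_line(logcon, "simulated dataset: ", n_specimens(aln), " specimens x ",
               aln$length, " sites")
    } else {
      aln <- read_alignment(config$alignment, config$metadata)
      log_line(logcon, "read ", n_specimens(aln), " specimens x ",
               aln$length, " sites from ", config$alignment)
    }
    labels <- species_labels(aln)
    ingroup_species <- setdiff(unique(aln$meta$species), config$outgroup)

    stage <- "distances"
    dm <- distance_matrix(aln)
    write_distance_matrix(dm, out("distances.phy"), out("distances.tsv"))
    files <- c(files, out("distances.phy"), out("distances.tsv"))
    summaries <- summarize_species(dm, labels, outgroup = config$outgroup)
    write_species_summary(summaries, out("species_summary.tsv"))
    files <- c(files, out("species_summary.tsv"))
    gap <- barcode_gap(summaries)
    gap_out <- gap$per_species
    for (cl in c("intra_max", "inter_min", "gap")) {
      gap_out[[cl]] <- ifelse(is.na(gap_out[[cl]]), "NA", sprintf("%.4f", gap_out[[cl]]))
    }
    utils::write.table(gap_out, out("barcode_gap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("barcode_gap.tsv"))
    log_line(logcon, "distances: ", length(dm$ids), " specimens, largest intra max ",
             format(gap$global$largest_intra_max, digits = 3),
             ", smallest inter min ",
             format(gap$global$smallest_inter_min, digits = 3))

    stage <- "tree"
    tree <- NULL
    clade_support <- NULL
    if (n_specimens(aln) >= 3L) {
      tree <- bootstrap_support(aln, replicates = config$bootstrap_replicates,
                                seed = config$seed)
      og_ids <- aln$meta$specimen_id[aln$meta$species %in% config$outgroup]
      if (length(og_ids) && length(og_ids) < n_specimens(aln)) {
        tree <- root_with_outgroup(tree, og_ids)
      }
      write_newick(tree, out("tree.nwk"),
                   support_min_display = config$support_min_display)
      clade_support <- clade_support_by_species(tree, labels)
      utils::write.table(clade_support, out("clade_support.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
      files <- c(files, out("tree.nwk"), out("clade_support.tsv"))
      log_line(logcon, "tree: NJ with ", config$bootstrap_replicates,
               " bootstrap replicates")
    } else {
      warning("fewer than 3 specimens: tree stage skipped")
      log_line(logcon, "tree stage skipped: fewer than 3 specimens")
    }

    stage <- "diagnostics"
    sites <- classify_sites(aln)
    site_df <- data.frame(
      metric = c("n_sites", "n_constant", "n_variable",
                 "n_parsimony_informative", "n_all_missing"),
      value = c(sites$n_sites, sites$n_constant, sites$n_variable,
                sites$n_parsimony_informative, sites$n_all_missing))
    utils::write.table(site_df, out("site_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("site_classification.tsv"))
    diagnostics <- pure_diagnostic_sites(aln, outgroup = config$outgroup,
                                         ingroup_only = TRUE)
    utils::write.table(diagnostics$sites, out("diagnostic_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ingroup_aln <- if (length(config$outgroup)) {
      subset_alignment(aln, !(aln$meta$species %in% config$outgroup))
    } else aln
    report <- diagnostic_report(diagnostics, ingroup_aln)
    utils::write.table(report$grid, out("diagnostic_grid.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mask_df <- cbind(specimen_id = rownames(report$mask),
                     as.data.frame(report$mask))
    utils::write.table(mask_df, out("diagnostic_mask.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("diagnostic_sites.tsv"), out("diagnostic_grid.tsv"),
               out("diagnostic_mask.tsv"))
    log_line(logcon, "sites: ", sites$n_variable, " variable / ",
             sites$n_parsimony_informative, " parsimony-informative of ",
             sites$n_sites)

    stage <- "verdicts"
    n_diag <- table(factor(diagnostics$sites$species, levels = ingroup_species))
    verdicts <- data.frame(species = ingroup_species, stringsAsFactors = FALSE)
    verdicts$monophyletic <- if (is.null(clade_support)) NA else
      clade_support$status[match(ingroup_species, clade_support$species)] %in%
        c("monophyletic", "trivially monophyletic")
    verdicts$clade_support <- if (is.null(clade_support)) NA_integer_ else
      clade_support$support[match(ingroup_species, clade_support$species)]
    verdicts$n_diagnostics <- as.integer(n_diag[ingroup_species])
    gp <- gap$per_species$gap[match(ingroup_species, gap$per_species$species)]
    verdicts$gap_positive <- !is.na(gp) & gp > 0
    utils::write.table(verdicts, out("verdicts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files <- c(files, out("verdicts.tsv"))
    log_line(logcon, "verdicts: ", sum(verdicts$monophyletic, na.rm = TRUE),
             "/", nrow(verdicts), " species monophyletic, ",
             sum(verdicts$n_diagnostics >= 1L), "/", nrow(verdicts),
             " with >= 1 pure diagnostic")

    list(alignment = aln, distances = dm, summaries = summaries, gap = gap,
         tree = tree, clade_support = clade_support, sites = sites,
         diagnostics = diagnostics, report = report, verdicts = verdicts,
         files = files)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}
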