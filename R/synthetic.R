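# Synthetic barcode datasets with planted species structure: a random
# ultrametric species tree, Jukes-Cantor-like substitution (uniform over the
# three alternative bases), reserved planted diagnostic columns, Poisson
# within-species polymorphism and terminal missing-data runs — the
# statistical shape of a multi-species COI barcode study, so every pipeline
# stage can be validated against known truth without downloads.

#' Simulation configuration
#'
#' @param n_species number of species
#' @param specimens_per_species integer vector (recycled if scalar) of
#'   specimens per species
#' @param seq_length alignment length in sites (default 662, the classic COI
#'   barcode window)
#' @param interspecific_divergence target *maximum* pairwise proportion of
#'   differing sites between species; the species tree is ultrametric with
#'   root depth `interspecific_divergence/2` and internal joins drawn
#'   uniformly between 40% and 90% of that depth, so pairwise interspecific
#'   divergence spans roughly 40–100% of the target
#' @param intraspecific_rate expected number of private mutations per
#'   specimen (Poisson mean); implies a mean pairwise intraspecific
#'   p-distance of about `2 * intraspecific_rate / seq_length`
#' @param n_planted_diagnostics reserved diagnostic columns per species
#'   (scalar or per-species vector); within-species mutation avoids reserved
#'   columns so planted diagnostics survive
#' @param missing_block list with `prob` (per-specimen probability of a
#'   terminal missing run) and `max_run` (maximum run length in sites);
#'   `prob = 0` disables masking
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   dataset
#' @param species_names optional character vector of species labels
#' @return a `sim_config` list
#' @export
simulation_config <- function(n_species = 5,
                              specimens_per_species = 4,
                              seq_length = 662,
                              interspecific_divergence = 0.13,
                              intraspecific_rate = 2,
                              n_planted_diagnostics = 3,
                              missing_block = list(prob = 0, max_run = 0),
                              seed = 1,
                              species_names = NULL) {
  if (length(specimens_per_species) == 1L) {
    specimens_per_species <- rep(specimens_per_species, n_species)
  }
  if (length(n_planted_diagnostics) == 1L) {
    n_planted_diagnostics <- rep(n_planted_diagnostics, n_species)
  }
  if (is.null(species_names)) species_names <- sprintf("sp%02d", seq_len(n_species))
  cfg <- structure(list(
    n_species = as.integer(n_species),
    specimens_per_species = as.integer(specimens_per_species),
    seq_length = as.integer(seq_length),
    interspecific_divergence = interspecific_divergence,
    intraspecific_rate = intraspecific_rate,
    n_planted_diagnostics = as.integer(n_planted_diagnostics),
    missing_block = missing_block,
    seed = as.integer(seed),
    species_names = species_names
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_species < 2L) stop("need at least 2 species")
  if (length(cfg$specimens_per_species) != cfg$n_species) {
    stop("specimens_per_species must have one entry per species")
  }
  if (any(cfg$specimens_per_species < 1L)) stop("every species needs >= 1 specimen")
  if (length(cfg$n_planted_diagnostics) != cfg$n_species) {
    stop("n_planted_diagnostics must be scalar or one entry per species")
  }
  if (any(cfg$n_planted_diagnostics < 0L)) stop("n_planted_diagnostics must be >= 0")
  if (cfg$seq_length < cfg$n_species * max(cfg$n_planted_diagnostics, 0L)) {
    stop("seq_length too short to reserve non-colliding diagnostic columns")
  }
  if (sum(cfg$n_planted_diagnostics) > cfg$seq_length) {
    stop("more planted diagnostics than alignment columns")
  }
  if (cfg$interspecific_divergence <= 0 || cfg$interspecific_divergence > 1) {
    stop("interspecific_divergence must be in (0, 1]")
  }
  if (cfg$intraspecific_rate < 0) stop("intraspecific_rate must be >= 0")
  mb <- cfg$missing_block
  if (is.null(mb$prob) || is.null(mb$max_run)) {
    stop("missing_block needs elements prob and max_run")
  }
  if (mb$prob < 0 || mb$prob > 1) stop("missing_block$prob must be in [0, 1]")
  if (mb$prob > 0 && mb$max_run < 1) stop("missing_block$max_run must be >= 1 when prob > 0")
  if (mb$max_run >= cfg$seq_length) stop("missing_block$max_run must be < seq_length")
  invisible(cfg)
}

#' Configuration mirroring a 9-species, 35-specimen COI barcode study
#'
#' Nine species with specimen counts (7, 3, 2, 6, 3, 2, 2, 5, 5) — 35
#' sequences — over a 662-site alignment, divergence targets tuned so
#' intraspecific p-distances land around 0–3% and interspecific ones around
#' 5–13%, three planted diagnostics per species, and terminal missing runs on
#' a quarter of specimens.
#'
#' @param seed integer seed
#' @return a `sim_config`
#' @export
paperlike_config <- function(seed = 1) {
  simulation_config(
    n_species = 9,
    specimens_per_species = c(7, 3, 2, 6, 3, 2, 2, 5, 5),
    seq_length = 662,
    interspecific_divergence = 0.13,
    intraspecific_rate = 2,
    n_planted_diagnostics = 3,
    missing_block = list(prob = 0.25, max_run = 40),
    seed = seed
  )
}

# random ultrametric species "tree" as a join table; returns per-species
# ancestor code matrix evolved from a uniform random root sequence.
evolve_species_ancestors <- function(cfg) {
  nsp <- cfg$n_species
  L <- cfg$seq_length
  D <- cfg$interspecific_divergence / 2
  root_seq <- sample.int(4L, L, replace = TRUE)
  if (nsp == 2L) {
    depths <- D
  } else {
    depths <- c(sort(stats::runif(nsp - 2L, 0.4 * D, 0.9 * D)), D)
  }
  # mutate a code sequence along a branch of length t (per-site substitution
  # probability t, new base uniform over the 3 alternatives)
  mutate_branch <- function(seq, t) {
    hit <- which(stats::runif(length(seq)) < t)
    if (length(hit)) {
      seq[hit] <- ((seq[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
    }
    seq
  }
  # build the join order bottom-up (sequential random pairs, deepest join
  # last), then evolve root-down over the implied tree
  active <- seq_len(nsp)
  node_depth <- rep(0, 2L * nsp - 1L)
  children <- vector("list", 2L * nsp - 1L)
  nxt <- nsp
  for (k in seq_len(nsp - 1L)) {
    pick <- sample(seq_along(active), 2L)
    nxt <- nxt + 1L
    children[[nxt]] <- active[pick]
    node_depth[nxt] <- depths[k]
    active <- c(active[-pick], nxt)
  }
  root <- nxt
  seqs <- matrix(0L, nsp, L)
  assign_down <- function(node, seq_here) {
    if (node <= nsp) {
      seqs[node, ] <<- seq_here
      return(invisible())
    }
    for (ch in children[[node]]) {
      t <- node_depth[node] - node_depth[ch]
      assign_down(ch, mutate_branch(seq_here, t))
    }
  }
  assign_down(root, root_seq)
  list(ancestors = seqs, root_seq = root_seq)
}

#' Simulate a labelled barcode dataset with known truth
#'
#' Procedure: (1) draw a root sequence uniformly over A/C/G/T; (2) evolve one
#' ancestral sequence per species along a random ultrametric binary species
#' tree (substitutions uniform over the three alternative bases) so pairwise
#' interspecific divergence approaches the configured target; (3) overwrite
#' the reserved diagnostic columns of each species with a state unique to it
#' (all other species carry the root state there); (4) give each specimen a
#' Poisson number of private mutations at non-reserved columns; (5) mask
#' terminal runs with `-` according to `missing_block`. Deterministic given
#' the seed.
#'
#' @param config a `sim_config` from [simulation_config()] or
#'   [paperlike_config()]
#' @return list with `alignment` (a `barcode_alignment`) and `truth` (list:
#'   `diagnostics` data.frame of planted (species, position, state) triples,
#'   `ancestors` character vector of per-species ancestral sequences,
#'   `reserved` integer positions, `expected_intra` implied mean pairwise
#'   intraspecific p-distance, `config`)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nsp <- config$n_species
  L <- config$seq_length
  ev <- evolve_species_ancestors(config)
  anc <- ev$ancestors
  # plant diagnostics at reserved, non-colliding columns
  total_k <- sum(config$n_planted_diagnostics)
  reserved <- if (total_k > 0L) sort(sample.int(L, total_k)) else integer(0)
  owner <- rep(seq_len(nsp), config$n_planted_diagnostics)
  owner <- owner[sample.int(length(owner))]  # shuffle column ownership
  truth_rows <- vector("list", total_k)
  for (k in seq_along(reserved)) {
    p <- reserved[k]
    s <- owner[k]
    r <- ev$root_seq[p]
    anc[, p] <- r
    x <- ((r - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    anc[s, p] <- x
    truth_rows[[k]] <- data.frame(species = config$species_names[s],
                                  position = p, state = .BASES[x],
                                  stringsAsFactors = FALSE)
  }
  truth <- if (total_k) do.call(rbind, truth_rows) else
    data.frame(species = character(0), position = integer(0),
               state = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$species, config$species_names), truth$position), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  # specimens: ancestor + Poisson private mutations at non-reserved columns
  free_cols <- setdiff(seq_len(L), reserved)
  n_total <- sum(config$specimens_per_species)
  seq_codes <- matrix(0L, n_total, L)
  sp_of <- rep(config$species_names, config$specimens_per_species)
  row <- 0L
  for (s in seq_len(nsp)) {
    for (j in seq_len(config$specimens_per_species[s])) {
      row <- row + 1L
      x <- anc[s, ]
      m <- stats::rpois(1L, config$intraspecific_rate)
      m <- min(m, length(free_cols))
      if (m > 0L) {
        pos <- sample(free_cols, m)
        x[pos] <- ((x[pos] - 1L + sample.int(3L, m, replace = TRUE)) %% 4L) + 1L
      }
      seq_codes[row, ] <- x
    }
  }
  chars <- matrix(.BASES[seq_codes], n_total, L)
  # terminal missing-data runs
  mb <- config$missing_block
  if (mb$prob > 0) {
    for (i in seq_len(n_total)) {
      if (stats::runif(1L) < mb$prob) {
        run <- sample.int(mb$max_run, 1L)
        if (stats::runif(1L) < 0.5) chars[i, seq_len(run)] <- "-"
        else chars[i, (L - run + 1L):L] <- "-"
      }
    }
  }
  ids <- unlist(lapply(seq_len(nsp), function(s) {
    sprintf("%s_%02d", config$species_names[s],
            seq_len(config$specimens_per_species[s]))
  }))
  meta <- data.frame(specimen_id = ids, species = sp_of,
                     stringsAsFactors = FALSE)
  aln <- barcode_alignment(chars, meta)
  list(
    alignment = aln,
    truth = list(
      diagnostics = truth,
      ancestors = stats::setNames(
        apply(matrix(.BASES[anc], nsp, L), 1L, paste, collapse = ""),
        config$species_names),
      reserved = reserved,
      expected_intra = 2 * config$intraspecific_rate / L,
      config = config
    )
  )
}
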