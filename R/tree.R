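# Neighbor-joining tree with nonparametric bootstrap supports. Supports are
# attached to bipartitions (unrooted splits identified by their tip-label
# sets), so they survive rerooting and are independent of leaf input order.

# canonical key of the split separating `side` from the rest: the side NOT
# containing the lexicographically smallest tip label, sorted and pasted.
split_key <- function(side, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\r")
}

# keys of the splits induced by the internal nodes of `phy`, named by node
# number; trivial splits (fewer than 2 tips on either side) are NA.
tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- rep(NA_character_, length(pp))
  for (i in seq_along(pp)) {
    sz <- length(pp[[i]])
    if (sz >= 2L && sz <= ntip - 2L) keys[i] <- split_key(labs[pp[[i]]], labs)
  }
  names(keys) <- as.character(seq_along(pp) + ntip)
  keys
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`), deterministic given the
#' matrix. Negative branch lengths — an artifact NJ can produce on
#' non-additive matrices — are clamped to zero with the deficit transferred
#' to the sister branch, so leaf-to-leaf path lengths are approximately
#' preserved and the tree stays printable.
#'
#' @param dm a `pdist_matrix` (or a plain symmetric numeric matrix with
#'   dimnames) on at least 3 taxa
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "pdist_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (!all(is.finite(d))) stop("non-finite distances")
  phy <- ape::nj(d)
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    sib <- which(phy$edge[, 1L] == phy$edge[e, 1L] & seq_len(nrow(phy$edge)) != e)
    if (length(sib)) {
      phy$edge.length[sib[1L]] <- phy$edge.length[sib[1L]] + deficit
    }
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times, recomputing the
#' p-distance matrix and NJ tree each time. The support of each internal
#' bipartition of the reference tree is the percentage of replicate trees
#' containing that bipartition, rounded to the nearest integer, stored in
#' `node.label` (empty where no support applies, e.g. the basal node).
#'
#' Randomness draws only column indices, so supports are reproducible given
#' the seed and invariant to specimen input order. A replicate that leaves
#' some specimen pair with no comparable sites is redrawn (up to 10 times the
#' replicate count in total attempts).
#'
#' @param aln a `barcode_alignment`
#' @param replicates number of bootstrap replicates (>= 1); default 1000
#' @param seed integer seed
#' @return the reference `ape::phylo` tree with integer-percent supports in
#'   `node.label`
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1) {
  if (replicates < 1L) stop("replicates must be >= 1")
  ref <- nj_tree(distance_matrix(aln))
  keys <- tree_splits(ref)
  counts <- stats::setNames(integer(length(keys)), names(keys))
  L <- aln$length
  set.seed(seed)
  done <- 0L
  attempts <- 0L
  while (done < replicates) {
    attempts <- attempts + 1L
    if (attempts > 10L * replicates) {
      stop("too many bootstrap replicates with undefined pairwise distances")
    }
    pc <- pdist_core(aln$codes[, sample.int(L, L, replace = TRUE), drop = FALSE],
                     strict = FALSE)
    if (is.null(pc)) {
      message("bootstrap replicate redrawn: a specimen pair had no comparable sites")
      next
    }
    done <- done + 1L
    d <- pc$mism / pmax(pc$n, 1L)
    diag(d) <- 0
    dimnames(d) <- list(rownames(aln$codes), rownames(aln$codes))
    rep_keys <- tree_splits(nj_tree(d))
    counts <- counts + (keys %in% rep_keys)
  }
  support <- round(100 * counts / replicates)
  ref$node.label <- ifelse(is.na(keys), "", as.character(support))
  ref
}

# named support map (split key -> label) of a tree carrying node labels
support_map <- function(phy) {
  keys <- tree_splits(phy)
  labs <- phy$node.label
  if (is.null(labs)) labs <- rep("", length(keys))
  stats::setNames(labs[!is.na(keys)], keys[!is.na(keys)])
}

#' Root a tree on the branch separating the outgroup from the ingroup
#'
#' If the outgroup specimens form one side of a bipartition of the tree, the
#' root is placed on that branch. Otherwise the tree is rooted on the first
#' outgroup tip's pendant edge with a warning that the outgroup is not
#' monophyletic. Bootstrap supports held in `node.label` are remapped to the
#' rerooted nodes by bipartition identity.
#'
#' @param tree an `ape::phylo`
#' @param outgroup_ids tip labels of the outgroup specimens (a proper,
#'   non-empty subset of the leaves)
#' @return a rooted `ape::phylo`
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  tips <- tree$tip.label
  missing_ids <- setdiff(outgroup_ids, tips)
  if (length(missing_ids)) {
    stop("outgroup id(s) not in tree: ", paste(missing_ids, collapse = ", "))
  }
  if (length(outgroup_ids) == 0L) stop("empty outgroup")
  if (setequal(outgroup_ids, tips)) stop("outgroup cannot contain every leaf")
  smap <- support_map(tree)
  og_key <- split_key(outgroup_ids, tips)
  monophyletic <- length(outgroup_ids) == 1L ||
    length(outgroup_ids) == length(tips) - 1L ||
    og_key %in% tree_splits(tree)
  if (monophyletic) {
    rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  } else {
    warning("outgroup is not monophyletic in the unrooted tree; ",
            "rooting on the pendant edge of '", outgroup_ids[1L], "'")
    rooted <- ape::root(tree, outgroup = outgroup_ids[1L], resolve.root = TRUE)
  }
  if (length(smap)) {
    keys <- tree_splits(rooted)
    lab <- smap[keys]
    lab[is.na(lab)] <- ""
    rooted$node.label <- unname(lab)
  }
  rooted
}

#' Bootstrap support of each species' clade
#'
#' For every species with two or more specimens in the tree: if the split
#' (its specimens | everything else) is present, the species is monophyletic
#' and the bootstrap support of that bipartition is reported; otherwise it is
#' flagged non-monophyletic. Singleton species are trivially monophyletic and
#' carry no support value. Judging monophyly by bipartition keeps the answer
#' independent of where the (possibly arbitrary) basal node sits.
#'
#' @param tree an `ape::phylo`, typically with supports from
#'   [bootstrap_support()]
#' @param labels species per specimen: named character vector
#'   (names = tip labels) or a data.frame-free vector aligned with
#'   `tree$tip.label`
#' @return data.frame with columns `species`, `n_tips`, `status`
#'   (`"monophyletic"`, `"non-monophyletic"` or `"trivially monophyletic"`)
#'   and `support` (integer percent or NA)
#' @export
clade_support_by_species <- function(tree, labels) {
  tips <- tree$tip.label
  if (!is.null(names(labels))) {
    if (!all(tips %in% names(labels))) stop("every tip needs a species label")
    labels <- unname(labels[tips])
  }
  if (length(labels) != length(tips)) stop("labels must cover every tip")
  keys <- tree_splits(tree)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", length(keys))
  species <- unique(labels)
  rows <- lapply(species, function(S) {
    sp_tips <- tips[labels == S]
    n <- length(sp_tips)
    if (n == 1L || n == length(tips) - 1L) {
      return(data.frame(species = S, n_tips = n,
                        status = if (n == 1L) "trivially monophyletic" else "monophyletic",
                        support = NA_integer_, stringsAsFactors = FALSE))
    }
    hit <- which(!is.na(keys) & keys == split_key(sp_tips, tips))
    if (length(hit)) {
      sup <- suppressWarnings(as.integer(labs[hit[1L]]))
      data.frame(species = S, n_tips = n, status = "monophyletic",
                 support = sup, stringsAsFactors = FALSE)
    } else {
      data.frame(species = S, n_tips = n, status = "non-monophyletic",
                 support = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
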