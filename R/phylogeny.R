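# Core-gene supertree: p-distances, neighbor-joining per family, strict
# majority-rule consensus with clade supports and mean branch lengths,
# outgroup rooting.

#' p-distance matrix from an alignment
#'
#' Proportion of differing sites between every pair of equal-length
#' sequences, ignoring columns where either sequence carries an ambiguity
#' character (`X`, `-`, `.`, `?`, `*`).
#'
#' @param alignment named character vector (taxon -> aligned sequence) or a
#'   character matrix with one row per taxon.
#' @return symmetric numeric matrix of p-distances with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    chars <- alignment
  } else {
    if (is.null(names(alignment))) stop_input("alignment must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1)
      stop_input("unequal sequence lengths for taxa: %s",
                 paste(names(alignment)[lens != lens[1]], collapse = ", "))
    if (any(lens == 0)) stop_input("empty sequences in alignment")
    chars <- do.call(rbind, strsplit(alignment, ""))
    rownames(chars) <- names(alignment)
  }
  n <- nrow(chars)
  if (n < 3) stop_input("need at least 3 taxa")
  amb <- chars %in% c("X", "-", ".", "?", "*")
  dim(amb) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !amb[i, ] & !amb[j, ]
      d[i, j] <- d[j, i] <-
        if (any(use)) mean(chars[i, use] != chars[j, use]) else 0
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj()]), with
#' negative branch lengths clamped to zero and the deficit moved onto the
#' sister edge at the same node so path lengths are preserved.
#'
#' @param dist symmetric distance matrix (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop_input("need at least 3 taxa")
  tre <- ape::nj(dist)
  neg <- which(tre$edge.length < 0)
  for (e in neg) {
    node <- tre$edge[e, 1]
    sisters <- setdiff(which(tre$edge[, 1] == node), e)
    deficit <- -tre$edge.length[e]
    tre$edge.length[e] <- 0
    # subtract the deficit from a sister edge so paths through the node
    # keep their length
    if (length(sisters))
      tre$edge.length[sisters[1]] <- tre$edge.length[sisters[1]] - deficit
  }
  tre$edge.length[tre$edge.length < 0] <- 0
  tre
}

# Clade table of one tree: for every internal edge, the sorted tip set below
# it (as a collapsed key) and its branch length; plus pendant-edge lengths.
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"),
                 character(1))
  len <- rep(NA_real_, length(keys))
  if (!is.null(tree$edge.length)) {
    node_of <- ntip + seq_along(keys)
    for (k in seq_along(keys)) {
      e <- which(tree$edge[, 2] == node_of[k])
      if (length(e) == 1) len[k] <- tree$edge.length[e]
    }
  }
  tips <- rep(NA_real_, ntip)
  names(tips) <- tree$tip.label
  if (!is.null(tree$edge.length)) {
    pe <- match(seq_len(ntip), tree$edge[, 2])
    tips[] <- tree$edge.length[pe]
  }
  list(keys = keys, lengths = len, tip_lengths = tips)
}

#' Majority-rule consensus tree
#'
#' Retains exactly the clades occurring in strictly more than `threshold` of
#' the input trees (rooted sense, as counted by [ape::prop.part()]); node
#' labels carry the support as percent of input trees. Branch lengths are
#' averaged across the trees containing each clade; pendant edges average
#' across all trees. For `threshold >= 0.5` the retained clades are mutually
#' compatible, so the consensus always exists.
#'
#' @param trees list (or `multiPhylo`) of trees sharing one leaf set.
#' @param threshold clade-retention fraction, default 0.5 (strict majority).
#' @return `phylo` tree with `node.label` supports in [0, 100].
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  trees <- unclass(trees)
  if (length(trees) < 1) stop_input("need at least one tree")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(leafsets)) != 1) {
    diffs <- setdiff(union(leafsets[[1]], leafsets[[2]]),
                     intersect(leafsets[[1]], leafsets[[2]]))
    stop_input("trees do not share one leaf set (symmetric difference: %s)",
               paste(unique(c(diffs, "...")), collapse = ", "))
  }
  leaves <- leafsets[[1]]
  ntree <- length(trees)
  # anchor every tree at one reference leaf so rooted clades correspond
  # one-to-one to unrooted bipartitions across trees
  trees <- lapply(trees, function(tr)
    ape::root(tr, outgroup = leaves[1], resolve.root = FALSE))
  counts <- new.env(parent = emptyenv())
  lensum <- new.env(parent = emptyenv())
  tipsum <- stats::setNames(numeric(length(leaves)), leaves)
  tipn <- stats::setNames(numeric(length(leaves)), leaves)
  for (tr in trees) {
    tc <- tree_clades(tr)
    for (k in seq_along(tc$keys)) {
      key <- tc$keys[k]
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      if (!is.na(tc$lengths[k]))
        lensum[[key]] <- (lensum[[key]] %||% 0) + tc$lengths[k]
    }
    ok <- !is.na(tc$tip_lengths)
    tipsum[names(tc$tip_lengths)[ok]] <-
      tipsum[names(tc$tip_lengths)[ok]] + tc$tip_lengths[ok]
    tipn[names(tc$tip_lengths)[ok]] <- tipn[names(tc$tip_lengths)[ok]] + 1
  }
  keys <- ls(counts)
  # non-trivial clades only (more than one leaf, not the full set)
  sizes <- lengths(strsplit(keys, "\r", fixed = TRUE))
  keys <- keys[sizes > 1 & sizes < length(leaves)]
  freq <- vapply(keys, function(k) counts[[k]], numeric(1))
  keep <- keys[freq / ntree > threshold]
  clades <- lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  support <- 100 * freq[match(keep, keys)] / ntree
  brlen <- vapply(keep, function(k)
    (lensum[[k]] %||% NA_real_) / counts[[k]], numeric(1))
  tiplen <- ifelse(tipn > 0, tipsum / tipn, 0)
  nwk <- consensus_newick(leaves, clades, support, brlen, tiplen)
  tre <- ape::read.tree(text = nwk)
  attr(tre, "bipartitions") <- data.frame(
    clade = vapply(clades, paste, character(1), collapse = ","),
    support = support, row.names = NULL)
  tre
}

# Build a Newick string from a set of nested, mutually compatible clades.
consensus_newick <- function(leaves, clades, support, brlen, tiplen) {
  sizes <- lengths(clades)
  full <- which(sizes == length(leaves))
  build <- function(set, idx) {
    idx <- idx[vapply(idx, function(i) all(clades[[i]] %in% set) &&
                        length(clades[[i]]) < length(set), logical(1))]
    maximal <- idx[vapply(idx, function(i)
      !any(vapply(idx, function(j)
        i != j && all(clades[[i]] %in% clades[[j]]), logical(1))),
      logical(1))]
    used <- unique(unlist(clades[maximal]))
    parts <- character(0)
    for (i in maximal) {
      sub <- build(clades[[i]], idx)
      lab <- format(support[i], trim = TRUE)
      bl <- if (is.na(brlen[i])) "" else sprintf(":%.10g", brlen[i])
      parts <- c(parts, sprintf("(%s)%s%s", sub, lab, bl))
    }
    singles <- sort(setdiff(set, used))
    for (s in singles)
      parts <- c(parts, sprintf("%s:%.10g", s, tiplen[[s]]))
    paste(parts, collapse = ",")
  }
  sprintf("(%s);", build(leaves, setdiff(seq_along(clades), full)))
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the branch leading to the outgroup
#' taxon.
#'
#' @param tree a `phylo` tree.
#' @param outgroup tip label to root on.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop_input("outgroup '%s' is not a leaf of the tree", outgroup)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!is.null(rooted$edge.length)) {
    og_tip <- match(outgroup, rooted$tip.label)
    root_node <- length(rooted$tip.label) + 1
    og_edge <- which(rooted$edge[, 2] == og_tip &
                       rooted$edge[, 1] == root_node)
    if (length(og_edge) == 1) {
      sis <- which(rooted$edge[, 1] == root_node &
                     rooted$edge[, 2] != og_tip)
      half <- rooted$edge.length[og_edge] / 2
      rooted$edge.length[og_edge] <- half
      if (length(sis) == 1)
        rooted$edge.length[sis] <- rooted$edge.length[sis] + half
    }
  }
  rooted
}

#' Gather per-family alignments from simulator output
#'
#' Collects, for each requested single-copy family, the member sequences of
#' every strain (plus the outgroup reference sequence where available) into
#' a named vector; sequences are already aligned since the simulator emits
#' equal-length families.
#'
#' @param sim a [simulate_pangenome()] result.
#' @param family_ids families to gather (default: all core families).
#' @return named list family -> named character vector (taxon -> sequence).
#' @export
family_alignments <- function(sim, family_ids = NULL) {
  family_ids <- family_ids %||% sim$truth$core_families
  gene_tab <- do.call(rbind, lapply(names(sim$genomes), function(s) {
    ids <- names(sim$genomes[[s]])
    data.frame(strain = s, gene_id = ids,
               family = vapply(strsplit(ids, "|", fixed = TRUE),
                               `[`, character(1), 2),
               stringsAsFactors = FALSE)
  }))
  lapply(stats::setNames(family_ids, family_ids), function(f) {
    rows <- gene_tab[gene_tab$family == f, ]
    seqs <- stats::setNames(
      mapply(function(s, g) sim$genomes[[s]][[g]], rows$strain, rows$gene_id),
      rows$strain)
    if (f %in% names(sim$outgroup_proteins))
      seqs[sim$truth$outgroup] <- sim$outgroup_proteins[[f]]
    seqs
  })
}

#' Build a core-gene consensus supertree
#'
#' Per family: p-distance matrix, then neighbor joining; the family trees are
#' combined by strict majority-rule consensus and rooted on the outgroup.
#' Families missing the outgroup are skipped with a warning.
#'
#' @param alignments named list family -> named character vector of aligned
#'   sequences, each covering the same taxon set including the outgroup.
#' @param outgroup taxon id used for rooting.
#' @param threshold consensus clade-retention fraction (default 0.5).
#' @return list of class `supertree`: `tree` (rooted consensus `phylo` with
#'   support node labels), `family_trees`, `bipartitions` (clade support
#'   table), `n_families_used`, `skipped`.
#' @export
build_supertree <- function(alignments, outgroup, threshold = 0.5) {
  skipped <- character(0)
  trees <- list()
  for (f in names(alignments)) {
    aln <- alignments[[f]]
    if (!outgroup %in% names(aln)) {
      skipped <- c(skipped, f)
      next
    }
    trees[[f]] <- neighbor_joining(p_distance_matrix(aln))
  }
  if (length(skipped))
    warning(sprintf("%d famil%s missing the outgroup were skipped",
                    length(skipped), if (length(skipped) == 1) "y" else "ies"))
  if (length(trees) == 0) stop_input("no usable families for the supertree")
  cons <- majority_consensus(trees, threshold = threshold)
  rooted <- root_with_outgroup(cons, outgroup)
  structure(list(tree = rooted, family_trees = trees,
                 bipartitions = attr(cons, "bipartitions"),
                 n_families_used = length(trees), skipped = skipped),
            class = "supertree")
}

#' @export
print.supertree <- function(x, ...) {
  cat(sprintf("Consensus supertree from %d family trees (%d skipped)\n",
              x$n_families_used, length(x$skipped)))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}
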