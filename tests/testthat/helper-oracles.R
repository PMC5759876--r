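# Independent oracles and shared fixtures for the test suite.

# Minimal dense MCL, written independently of the package implementation:
# no pruning, convergence to machine fixed point, clusters read as connected
# components of the limit matrix's nonzero pattern (same self-loop
# convention: max incident weight, 1 for isolated nodes).
oracle_mcl <- function(W, inflation) {
  n <- nrow(W)
  d <- apply(W, 1, max)
  d[d == 0] <- 1
  diag(W) <- d
  M <- sweep(W, 2, colSums(W), "/")
  for (k in 1:500) {
    I <- (M %*% M)^inflation
    I <- sweep(I, 2, colSums(I), "/")
    if (max(abs(I - M)) < 1e-9) { M <- I; break }
    M <- I
  }
  A <- (M > 1e-6) | t(M > 1e-6)
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0) {
      cid <- cid + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        if (comp[v] == 0) {
          comp[v] <- cid
          stack <- c(stack, which(A[v, ] & comp == 0))
        }
      }
    }
  }
  unname(split(seq_len(n), comp))
}

# Random weighted undirected graph as (adjacency, similarity records).
random_weighted_graph <- function(seed, n_max = 30, p = 0.25) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- stats::runif(1, 0.5, 2)
  nodes <- sprintf("n%02d", 1:n)
  dimnames(A) <- list(nodes, nodes)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  recs <- if (nrow(idx)) {
    data.frame(query = nodes[idx[, 1]], subject = nodes[idx[, 2]],
               pct_identity = 100, evalue = 0, bitscore = A[idx],
               stringsAsFactors = FALSE)
  } else {
    data.frame(query = character(0), subject = character(0),
               pct_identity = numeric(0), evalue = numeric(0),
               bitscore = numeric(0))
  }
  list(adj = A, records = recs, nodes = nodes)
}

# Canonical form of a node partition for label-free comparison.
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, groups[[1]][1], 1))])
}

mcl_partition <- function(famset, nodes) {
  canon_partition(lapply(split(famset$gene_id, famset$family_id),
                         function(x) match(x, nodes)))
}

# Brute-force bipartition counter: for every internal edge of every tree,
# the side of the split not containing the reference leaf, counted over
# trees. Implemented by direct recursion over the edge table, independent
# of ape::prop.part.
oracle_bipartition_counts <- function(trees) {
  ref <- sort(trees[[1]]$tip.label)[1]
  tab <- new.env(parent = emptyenv())
  for (tr in trees) {
    tr <- ape::root(tr, outgroup = ref, resolve.root = FALSE)
    ntip <- length(tr$tip.label)
    below <- function(node) {
      if (node <= ntip) return(tr$tip.label[node])
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      unlist(lapply(kids, below))
    }
    internal <- unique(tr$edge[, 1])
    for (node in setdiff(internal, ntip + 1)) {
      tips <- sort(below(node))
      if (length(tips) > 1 && length(tips) < ntip) {
        key <- paste(tips, collapse = ",")
        tab[[key]] <- (tab[[key]] %||% 0) + 1
      }
    }
  }
  counts <- vapply(ls(tab), function(k) tab[[k]], numeric(1))
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fam_of <- function(gene_ids) {
  vapply(strsplit(gene_ids, "|", fixed = TRUE), `[`, character(1), 2)
}

# Default-scale simulation (20 strains, 400 core, 600 dispensable, 4 planted
# clusters, zero phenotype noise), shared across acceptance checks
# (memoised per session).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20)
      sim <- simulate_pangenome(cfg)
      cache <<- list(config = cfg, sim = sim,
                     curves = simulate_growth_curves(sim$truth, cfg))
    }
    cache
  }
})

# Small simulation shared by several files (memoised per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_strains = 8, core_size = 40, n_dispensable = 60,
                        n_trait_clusters = 2, cluster_size_range = c(3, 5),
                        unique_per_strain_range = c(0, 4),
                        protein_length = 120, od_noise_sd = 0, seed = 7)
      cache <<- list(config = cfg, sim = simulate_pangenome(cfg))
    }
    cache
  }
})
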