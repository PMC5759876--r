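# Markov Cluster Algorithm, implemented from scratch on a dense column-
# stochastic matrix. Alternates expansion (matrix squaring) with inflation
# (elementwise powering followed by column renormalization), pruning small
# entries, until the matrix reaches its fixed point; attractor systems of the
# limit matrix are read out as clusters.

#' Cluster a similarity graph with the Markov Cluster Algorithm
#'
#' @param graph a `similarity_graph` from [build_graph()].
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters. Default 2.5.
#' @param max_iter iteration cap; non-convergence raises an error naming the
#'   cap and the residual.
#' @param tol convergence tolerance: maximum absolute matrix change.
#' @param prune entries below this value are zeroed (with column
#'   renormalization) after each inflation.
#' @param gene_to_genome optional function mapping a gene id to its genome id
#'   (defaults to the `"<strain>|<family>|<serial>"` convention of the
#'   simulator); used to organise families by genome.
#' @return a `family_set`; isolated nodes become singleton families.
#' @export
mcl_cluster <- function(graph, inflation = 2.5, max_iter = 200, tol = 1e-6,
                        prune = 1e-5, gene_to_genome = NULL) {
  if (!inherits(graph, "similarity_graph"))
    stop_input("graph must be a similarity_graph")
  if (inflation <= 1) stop_input("inflation must be > 1")
  nodes <- graph$nodes
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    M[cbind(i, j)] <- graph$edges$weight
    M[cbind(j, i)] <- graph$edges$weight
  }
  # self-loop per node = maximum incident edge weight (1 for isolated nodes),
  # the canonical stabilizer
  loop <- apply(M, 1, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")

  converged <- FALSE
  resid <- NA_real_
  for (it in seq_len(max_iter)) {
    M_new <- M %*% M                 # expansion
    M_new <- M_new^inflation         # inflation
    M_new <- sweep(M_new, 2, colSums(M_new), "/")
    M_new[M_new < prune] <- 0
    cs <- colSums(M_new)
    if (any(cs == 0)) stop_input("MCL column vanished after pruning")
    M_new <- sweep(M_new, 2, cs, "/")
    resid <- max(abs(M_new - M))
    M <- M_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_input("MCL did not converge within %d iterations (residual %.3g)",
               max_iter, resid)

  members <- mcl_interpret(M, nodes)
  families_from_members(members, gene_to_genome,
                        provenance = list(method = "mcl",
                                          inflation = inflation,
                                          iterations = it,
                                          residual = resid))
}

# Read clusters off the MCL limit matrix. Attractors are nodes with positive
# diagonal mass; attractors sharing a column form one attractor system; every
# other node joins the system holding the largest share of its column mass
# (ties broken toward the system whose smallest attractor label sorts first).
mcl_interpret <- function(M, nodes, eps = 1e-9) {
  n <- length(nodes)
  attract <- which(diag(M) > eps)
  if (length(attract) == 0) attract <- seq_len(n)  # degenerate, tiny graphs
  # union attractors that appear together in any column
  sys_id <- seq_along(attract)
  names(sys_id) <- attract
  for (j in seq_len(n)) {
    rows <- intersect(which(M[, j] > eps), attract)
    if (length(rows) > 1) {
      ids <- sys_id[as.character(rows)]
      sys_id[sys_id %in% ids] <- min(ids)
    }
  }
  systems <- split(attract, sys_id)
  # deterministic system order: by smallest member label
  first_label <- vapply(systems, function(r) min(nodes[r]), character(1))
  systems <- systems[order(first_label)]
  assign <- integer(n)
  for (j in seq_len(n)) {
    mass <- vapply(systems, function(r) sum(M[r, j]), numeric(1))
    if (all(mass <= eps)) {
      # no attractor mass (numerically isolated): own singleton
      assign[j] <- NA_integer_
    } else {
      assign[j] <- which(mass == max(mass))[1]
    }
  }
  out <- split(nodes[!is.na(assign)], assign[!is.na(assign)])
  orphans <- nodes[is.na(assign)]
  c(unname(out), as.list(orphans))
}

# Build a family_set from a list of member-gene character vectors.
families_from_members <- function(members, gene_to_genome = NULL,
                                  provenance = list()) {
  if (is.null(gene_to_genome))
    gene_to_genome <- function(g)
      vapply(strsplit(g, "|", fixed = TRUE), `[`, character(1), 1)
  members <- members[order(vapply(members, min, character(1)))]
  fam_ids <- sprintf("MCL%05d", seq_along(members))
  df <- data.frame(
    family_id = rep(fam_ids, lengths(members)),
    gene_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  df$genome_id <- gene_to_genome(df$gene_id)
  family_set(df[, c("family_id", "genome_id", "gene_id")],
             provenance = provenance)
}
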