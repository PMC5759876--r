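# Pan-genome structure: presence/absence matrix, core/dispensable/unique
# partition, accumulation curves with fitted models, pan-genome comparison,
# genome summary statistics and the clustered heatmap export.

#' Presence/absence matrix of families across genomes
#'
#' Rows are families, columns genomes, entries the member-gene count (the
#' binary view is `count > 0`). Rows and columns are sorted by id so the
#' matrix is deterministic.
#'
#' @param families a `family_set`.
#' @param genome_ids the analysed genome set (defaults to the genomes present
#'   in `families`).
#' @return integer matrix families x genomes.
#' @export
presence_absence <- function(families, genome_ids = NULL) {
  genome_ids <- sort(genome_ids %||% unique(families$genome_id))
  tab <- table(factor(families$family_id),
               factor(families$genome_id, levels = genome_ids))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), genome_ids))
  m <- m[sort(rownames(m)), , drop = FALSE]
  if (any(rowSums(m) == 0))
    stop_input("family with no members among the listed genomes")
  m
}

#' Partition families into core, shared-dispensable and unique
#'
#' Core families occur (at least once) in every genome; unique families occur
#' in exactly one; the shared dispensable set is the remainder. The variable
#' genome reported alongside aggregates everything that is not core (shared
#' dispensable plus unique), the convention used in printed pan-genome
#' totals.
#'
#' @param matrix presence/absence matrix from [presence_absence()].
#' @return list of class `pan_partition`: family id vectors `core`,
#'   `dispensable`, `unique`; `unique_owner` (named genome per unique
#'   family); `counts` (core, dispensable, unique, variable, total) and
#'   `core_fraction_pct`.
#' @export
partition_families <- function(matrix) {
  bin <- matrix > 0
  npres <- rowSums(bin)
  core <- rownames(matrix)[npres == ncol(matrix)]
  uniq <- rownames(matrix)[npres == 1]
  disp <- setdiff(rownames(matrix), c(core, uniq))
  owner <- apply(bin[uniq, , drop = FALSE], 1,
                 function(r) colnames(matrix)[which(r)])
  counts <- c(core = length(core), dispensable = length(disp),
              unique = length(uniq),
              variable = length(disp) + length(uniq),
              total = nrow(matrix))
  structure(list(core = core, dispensable = disp, unique = uniq,
                 unique_owner = owner, counts = counts,
                 core_fraction_pct =
                   100 * length(core) / nrow(matrix)),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf(
    "Pan-genome partition: %d families; core %d (%.1f%%), variable %d (shared %d + unique %d)\n",
    x$counts[["total"]], x$counts[["core"]], x$core_fraction_pct,
    x$counts[["variable"]], x$counts[["dispensable"]], x$counts[["unique"]]))
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Pan- and core-genome accumulation curves
#'
#' For random orderings of the genomes, pan(N) is the number of families seen
#' in the first N genomes and core(N) the number present in all of the first
#' N. Means and standard deviations are taken across orderings; when G! <=
#' 5040 every ordering is enumerated exactly instead of sampled. A Heaps-type
#' power law `P(N) = kappa * N^gamma` is fitted to the pan means and an
#' exponential decay `C(N) = omega + A * exp(-N / tau)` to the core means, by
#' least squares.
#'
#' @param matrix presence/absence matrix.
#' @param n_permutations orderings sampled when exhaustive enumeration is out
#'   of reach.
#' @param seed seed for the sampled orderings.
#' @return list of class `accumulation_curve`: data.frame `curve` (N,
#'   pan_mean, pan_sd, core_mean, core_sd), `fitted_pan` (kappa, gamma),
#'   `fitted_core` (omega, A, tau), `n_permutations`, `exhaustive`, `seed`.
#' @export
accumulation_curves <- function(matrix, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop_input("n_permutations must be >= 1")
  bin <- matrix > 0
  G <- ncol(bin)
  if (factorial(G) <= 5040) {
    perms <- all_permutations(seq_len(G))
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    perms <- replicate(n_permutations, sample(G), simplify = FALSE)
    exhaustive <- FALSE
  }
  pan <- core <- matrix(0L, length(perms), G)
  for (k in seq_along(perms)) {
    seen <- rep(FALSE, nrow(bin)); inall <- rep(TRUE, nrow(bin))
    for (N in seq_len(G)) {
      col <- bin[, perms[[k]][N]]
      seen <- seen | col
      inall <- inall & col
      pan[k, N] <- sum(seen)
      core[k, N] <- sum(inall)
    }
  }
  sd0 <- function(m) apply(m, 2, pop_sd)
  curve <- data.frame(N = seq_len(G),
                      pan_mean = colMeans(pan), pan_sd = sd0(pan),
                      core_mean = colMeans(core), core_sd = sd0(core))
  fitted_pan <- fitted_core <- NULL
  if (G < 3) {
    warning("fewer than 3 genomes: accumulation-curve fits skipped")
  } else {
    fitted_pan <- fit_heaps(curve$N, curve$pan_mean)
    fitted_core <- fit_core_decay(curve$N, curve$core_mean)
  }
  structure(list(curve = curve, fitted_pan = fitted_pan,
                 fitted_core = fitted_core,
                 n_permutations = length(perms), exhaustive = exhaustive,
                 seed = seed),
            class = "accumulation_curve")
}

fit_heaps <- function(N, pan) {
  tryCatch({
    start <- stats::lm(log(pan) ~ log(N))
    fit <- minpack.lm::nlsLM(
      pan ~ kappa * N^gamma,
      start = list(kappa = exp(stats::coef(start)[1]),
                   gamma = stats::coef(start)[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(stats::coef(fit))
  }, error = function(e) {
    warning("pan-curve fit failed (", conditionMessage(e),
            "); curve is likely degenerate", call. = FALSE)
    NULL
  })
}

fit_core_decay <- function(N, core) {
  tryCatch({
    omega0 <- min(core)
    a0 <- max(core[1] - omega0, 1)
    fit <- minpack.lm::nlsLM(
      core ~ omega + A * exp(-N / tau),
      start = list(omega = omega0, A = a0, tau = max(length(N) / 4, 1)),
      lower = c(0, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(stats::coef(fit))
  }, error = function(e) {
    warning("core-curve fit failed (", conditionMessage(e),
            "); curve is likely degenerate", call. = FALSE)
    NULL
  })
}

#' @export
print.accumulation_curve <- function(x, ...) {
  G <- nrow(x$curve)
  cat(sprintf("Accumulation curves over %d genomes (%s, %d orderings)\n",
              G, if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  cat(sprintf("  pan: %d -> %.1f families", round(x$curve$pan_mean[1]),
              x$curve$pan_mean[G]))
  if (!is.null(x$fitted_pan))
    cat(sprintf("; fit P(N) = %.1f * N^%.3f",
                x$fitted_pan$kappa, x$fitted_pan$gamma))
  cat("\n")
  cat(sprintf("  core: %d -> %.1f families", round(x$curve$core_mean[1]),
              x$curve$core_mean[G]))
  if (!is.null(x$fitted_core))
    cat(sprintf("; fit C(N) = %.1f + %.1f * exp(-N/%.2f)",
                x$fitted_core$omega, x$fitted_core$A, x$fitted_core$tau))
  cat("\n")
  invisible(x)
}

#' Mean new-family rate over a genome-addition window
#'
#' Average of pan(N) - pan(N-1) over N in `[from_N, to_N]`, using the
#' permutation-mean pan sizes: the "new gene families per added genome" rate
#' quoted for accumulation curves.
#'
#' @param curve an `accumulation_curve`.
#' @param from_N,to_N window bounds, `1 < from_N <= to_N <= G`.
#' @return mean new families per added genome.
#' @export
new_gene_rate <- function(curve, from_N, to_N) {
  G <- nrow(curve$curve)
  if (from_N <= 1 || from_N > to_N || to_N > G)
    stop_input("window must satisfy 1 < from_N <= to_N <= %d", G)
  pan <- curve$curve$pan_mean
  mean(pan[from_N:to_N] - pan[(from_N - 1):(to_N - 1)])
}

#' Compare a pan-genome against a genome subset
#'
#' Reports how much of the full family repertoire is retained when only a
#' subset of genomes is kept: `n_absent` families have no member in the
#' subset, and `pct_present` is 100 * (total - n_absent) / total, rounded
#' half-up to the nearest integer for reporting (the raw value is returned
#' alongside).
#'
#' @param full presence/absence matrix of the full genome set.
#' @param subset_genomes column subset to compare against.
#' @return list(pct_present, pct_present_raw, n_absent, n_total).
#' @export
compare_pangenomes <- function(full, subset_genomes) {
  if (length(subset_genomes) == 0) stop_input("empty genome subset")
  if (!all(subset_genomes %in% colnames(full)))
    stop_input("subset genome(s) not in matrix: %s",
               paste(setdiff(subset_genomes, colnames(full)), collapse = ", "))
  pres <- rowSums(full[, subset_genomes, drop = FALSE] > 0) > 0
  n_absent <- sum(!pres)
  raw <- 100 * (nrow(full) - n_absent) / nrow(full)
  list(pct_present = round_half_up(raw), pct_present_raw = raw,
       n_absent = n_absent, n_total = nrow(full))
}

#' Summarise a genome statistics table
#'
#' Mean, population standard deviation (divisor n), minimum and maximum with
#' genome labels for each numeric column of a per-genome statistics table
#' (ORF counts, genome size, GC content, unique genes). Report rounding is
#' half-up: ORFs to integers, GC to 2 decimals, genome size to 2 decimals in
#' Mbp.
#'
#' @param stats data.frame with a `genome` column plus numeric columns; the
#'   conventional columns are `orfs`, `genome_size_bp`, `gc_pct`,
#'   `unique_genes`.
#' @return list of class `genome_summary`: `raw` (per-column mean, sd, min,
#'   max, which_min, which_max), `report` (rounded means and sds, genome size
#'   in Mbp, total unique genes), `n_genomes`.
#' @export
genome_summary <- function(stats) {
  if (nrow(stats) < 1) stop_input("empty genome statistics table")
  if (!"genome" %in% names(stats)) stop_input("need a 'genome' column")
  numcols <- names(stats)[vapply(stats, is.numeric, logical(1))]
  raw <- lapply(stats::setNames(numcols, numcols), function(cl) {
    x <- stats[[cl]]
    list(mean = mean(x), sd = pop_sd(x), min = min(x), max = max(x),
         which_min = stats$genome[which.min(x)],
         which_max = stats$genome[which.max(x)])
  })
  report <- list()
  if ("orfs" %in% numcols) {
    report$orf_mean <- round_half_up(raw$orfs$mean)
    report$orf_sd <- round_half_up(raw$orfs$sd)
  }
  if ("gc_pct" %in% numcols) {
    report$gc_mean <- round_half_up(raw$gc_pct$mean, 2)
    report$gc_sd <- round_half_up(raw$gc_pct$sd, 2)
    report$gc_min <- raw$gc_pct$min
    report$gc_min_genome <- raw$gc_pct$which_min
    report$gc_max <- raw$gc_pct$max
    report$gc_max_genome <- raw$gc_pct$which_max
  }
  if ("genome_size_bp" %in% numcols) {
    report$size_mean_mbp <- round_half_up(raw$genome_size_bp$mean / 1e6, 2)
    report$size_max_mbp <- round_half_up(raw$genome_size_bp$max / 1e6, 2)
    report$size_min_mbp <- round_half_up(raw$genome_size_bp$min / 1e6, 2)
    report$size_max_genome <- raw$genome_size_bp$which_max
    report$size_min_genome <- raw$genome_size_bp$which_min
  }
  if ("unique_genes" %in% numcols)
    report$unique_total <- sum(stats$unique_genes)
  structure(list(raw = raw, report = report, n_genomes = nrow(stats)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  r <- x$report
  cat(sprintf("Genome summary over %d genomes\n", x$n_genomes))
  if (!is.null(r$orf_mean))
    cat(sprintf("  ORFs: %d +/- %d\n", r$orf_mean, r$orf_sd))
  if (!is.null(r$gc_mean))
    cat(sprintf("  GC%%: %.2f +/- %.2f (range %.1f [%s] - %.1f [%s])\n",
                r$gc_mean, r$gc_sd, r$gc_min, r$gc_min_genome,
                r$gc_max, r$gc_max_genome))
  if (!is.null(r$size_mean_mbp))
    cat(sprintf("  size: %.2f Mbp (max %.2f [%s], min %.2f [%s])\n",
                r$size_mean_mbp, r$size_max_mbp, r$size_max_genome,
                r$size_min_mbp, r$size_min_genome))
  if (!is.null(r$unique_total))
    cat(sprintf("  unique genes total: %d\n", r$unique_total))
  invisible(x)
}

#' Clustered presence/absence export for heatmap plotting
#'
#' Average-linkage hierarchical clustering of genomes on the Jaccard distance
#' between their binary family profiles, with a deterministic leaf order
#' (columns are pre-sorted by genome id, so equal-distance ties resolve by
#' id). Returns the genome-reordered matrix, the dendrogram as both hclust
#' and Newick, and the distance matrix, ready for external plotting.
#'
#' @param matrix presence/absence matrix (>= 2 genomes).
#' @return list: `ordered_matrix`, `genome_order`, `hclust`, `newick`,
#'   `distance`.
#' @export
hierarchical_heatmap_export <- function(matrix) {
  if (ncol(matrix) < 2) stop_input("need at least 2 genomes")
  bin <- (matrix > 0)[, order(colnames(matrix)), drop = FALSE]
  d <- vegan::vegdist(t(bin), method = "jaccard", binary = TRUE)
  hc <- stats::hclust(d, method = "average")
  ord <- hc$labels[hc$order]
  phy <- ape::as.phylo(hc)
  list(ordered_matrix = matrix[, ord, drop = FALSE],
       genome_order = ord, hclust = hc,
       newick = ape::write.tree(phy), distance = as.matrix(d))
}
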