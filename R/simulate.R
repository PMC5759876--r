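# Synthetic pan-genome simulator.
#
# Emulates the statistical structure the downstream analysis assumes: a fixed
# core shared by all strains, dispensable families carried with per-family
# probabilities, strain-unique singletons, and K planted carbohydrate-
# utilization gene clusters whose carriage determines growth phenotypes.
# Protein sequences within a family are generated pre-aligned (equal length,
# substitutions only) by evolving one ancestral sequence along the species
# tree, so p-distances and percent identities are exact without an aligner.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

CARB_LABELS <- c("xylooligosaccharides", "arabinan", "arabinoxylan",
                 "galactan", "fucosyllactose", "melibiose", "raffinose",
                 "maltotriose")

CARB_KEY_ENZYMES <- c(
  xylooligosaccharides = "beta-1,4-xylosidase (GH43)",
  arabinan             = "endo-1,4-beta-xylanase (GH5)",
  arabinoxylan         = "exo-alpha-L-arabinofuranosidase II (GH51)",
  galactan             = "endogalactanase (GH53)",
  fucosyllactose       = "alpha-1,3/4-fucosidase (GH95)",
  melibiose            = "alpha-galactosidase (GH36)",
  raffinose            = "beta-fructofuranosidase (GH32)",
  maltotriose          = "alpha-glucosidase (GH13)")

CLUSTER_ACCESSORY_FUNCS <- c(
  "ABC transporter permease",
  "ABC transporter substrate-binding protein",
  "LacI family transcriptional regulator",
  "MFS sugar transporter",
  "carbohydrate kinase",
  "sugar isomerase",
  "alpha-L-arabinofuranosidase",
  "beta-galactosidase",
  "galactoside O-acetyltransferase")

MOBILE_ELEMENT_FUNCS <- c(
  "IS3-family transposase",
  "prophage protein",
  "phage integrase",
  "type II restriction endonuclease",
  "DNA methyltransferase",
  "CRISPR-associated protein Cas1",
  "mobile element protein")

HOUSEKEEPING_FUNCS <- c(
  "DNA polymerase III subunit alpha", "ribosomal protein L2",
  "elongation factor Tu", "ATP synthase subunit beta",
  "DNA gyrase subunit A", "chaperone protein DnaK",
  "phosphoglycerate kinase", "glyceraldehyde-3-phosphate dehydrogenase",
  "aminopeptidase N", "cell division protein FtsZ",
  "RNA polymerase beta subunit", "tRNA ligase",
  "UDP-glucose pyrophosphorylase", "enolase", "pyruvate kinase")

BACKGROUND_FUNCS <- c(
  "hypothetical protein", "membrane protein", "secreted protein",
  "sortase-dependent pilus subunit", "exopolysaccharide biosynthesis protein",
  "two-component system response regulator", "oxidoreductase",
  "acetyltransferase", "amino acid permease")

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic pan-genome
#' generator. Defaults describe a set of 20 closely related bacterial strains
#' with a 400-family core, 600 probabilistically carried dispensable families,
#' a handful of strain-unique genes each, and 4 planted carbohydrate-
#' utilization clusters.
#'
#' @param n_strains number of strains in the set.
#' @param core_size number of core gene families (present in every strain).
#' @param n_dispensable number of dispensable families; their per-family
#'   carriage probability is drawn uniformly from `occurrence_prob_range`.
#' @param occurrence_prob_range pair of probabilities in (0,1), exclusive.
#' @param unique_per_strain_range integer pair; per-strain count of
#'   strain-unique singleton genes is drawn uniformly from this range.
#' @param n_trait_clusters number K of planted trait clusters, each tied to
#'   one carbohydrate.
#' @param cluster_size_range integer pair: families per planted cluster.
#' @param carrier_fraction probability that a strain carries a given planted
#'   cluster (strictly between 0 and 1).
#' @param phenotype_noise probability in [0,1) of flipping a true growth call
#'   when generating OD600 curves (the positive-control carbohydrate is never
#'   flipped).
#' @param protein_length protein length in residues (one global length; all
#'   sequences are emitted pre-aligned).
#' @param divergence_within_family per-site substitution probability along
#'   each branch of the species tree.
#' @param divergence_between_families minimum fraction of differing sites
#'   required between ancestral sequences of different families.
#' @param od_noise_sd Gaussian measurement noise (OD600 units) added to
#'   growth curves, truncated at 0.
#' @param growth_od12_range OD600 range at 12 h for growers (minimum must
#'   exceed 0.4 so noiseless binarization is unambiguous).
#' @param nogrowth_od12_range OD600 range at 12 h for non-growers (maximum
#'   must stay below 0.3).
#' @param mobile_annotation_fraction fraction of non-planted dispensable
#'   families annotated from the mobile-element vocabulary, to exercise the
#'   gene-trait-matching exclusion filter.
#' @param outgroup_id taxon label of the outgroup used for rooting the
#'   species tree.
#' @param seed master random seed; all per-output sub-streams derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 20,
                       core_size = 400,
                       n_dispensable = 600,
                       occurrence_prob_range = c(0.15, 0.85),
                       unique_per_strain_range = c(0L, 24L),
                       n_trait_clusters = 4,
                       cluster_size_range = c(4L, 10L),
                       carrier_fraction = 0.5,
                       phenotype_noise = 0,
                       protein_length = 250,
                       divergence_within_family = 0.01,
                       divergence_between_families = 0.6,
                       od_noise_sd = 0.02,
                       growth_od12_range = c(0.55, 0.9),
                       nogrowth_od12_range = c(0.05, 0.25),
                       mobile_annotation_fraction = 0.2,
                       outgroup_id = "OUTG",
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              core_size = as.integer(core_size),
              n_dispensable = as.integer(n_dispensable),
              occurrence_prob_range = as.numeric(occurrence_prob_range),
              unique_per_strain_range = as.integer(unique_per_strain_range),
              n_trait_clusters = as.integer(n_trait_clusters),
              cluster_size_range = as.integer(cluster_size_range),
              carrier_fraction = carrier_fraction,
              phenotype_noise = phenotype_noise,
              protein_length = as.integer(protein_length),
              divergence_within_family = divergence_within_family,
              divergence_between_families = divergence_between_families,
              od_noise_sd = od_noise_sd,
              growth_od12_range = as.numeric(growth_od12_range),
              nogrowth_od12_range = as.numeric(nogrowth_od12_range),
              mobile_annotation_fraction = mobile_annotation_fraction,
              outgroup_id = outgroup_id,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_strains < 3) stop_input("n_strains must be >= 3")
    if (core_size < 1) stop_input("core_size must be >= 1")
    check_range_pair(occurrence_prob_range, "occurrence_prob_range")
    if (occurrence_prob_range[1] <= 0 || occurrence_prob_range[2] >= 1)
      stop_input("occurrence_prob_range must lie strictly within (0, 1)")
    if (carrier_fraction <= 0 || carrier_fraction >= 1)
      stop_input("carrier_fraction must be strictly between 0 and 1")
    if (phenotype_noise < 0 || phenotype_noise >= 1)
      stop_input("phenotype_noise must be in [0, 1)")
    check_range_pair(unique_per_strain_range, "unique_per_strain_range")
    check_range_pair(cluster_size_range, "cluster_size_range")
    if (n_trait_clusters > 0 &&
        n_trait_clusters * cluster_size_range[2] > n_dispensable)
      stop_input(paste("cluster_size_range exceeds n_dispensable:",
                       "%d clusters of up to %d families cannot be planted",
                       "among %d dispensable families"),
                 n_trait_clusters, cluster_size_range[2], n_dispensable)
    check_range_pair(growth_od12_range, "growth_od12_range")
    check_range_pair(nogrowth_od12_range, "nogrowth_od12_range")
    if (growth_od12_range[1] <= 0.4)
      stop_input("growth_od12_range minimum must exceed 0.4 OD600")
    if (nogrowth_od12_range[2] >= 0.3)
      stop_input("nogrowth_od12_range maximum must stay below 0.3 OD600")
    if (od_noise_sd < 0) stop_input("od_noise_sd must be >= 0")
    # Within-family identity must stay clear of the 50% clustering threshold
    # (margin: threshold + 5 points) even along the longest root-to-tip-to-tip
    # path of a maximally unbalanced tree plus the stretched outgroup branch.
    worst_edges <- 2 * n_strains + 5
    worst_pdist <- 1 - (1 - divergence_within_family)^worst_edges
    if (worst_pdist > 0.45)
      stop_input(paste("divergence_within_family = %.4g could push",
                       "within-family identity to %.1f%%, below the 55%%",
                       "margin over the 50%% clustering threshold;",
                       "reduce it below %.4g"),
                 divergence_within_family, 100 * (1 - worst_pdist),
                 1 - 0.55^(1 / worst_edges))
    if (divergence_between_families <= 0.5)
      stop_input("divergence_between_families must exceed 0.5 so ancestral
  sequences sit at least 10 identity points below the 50% threshold")
  })
  invisible(cfg)
}

# Random rooted bifurcating species tree over the strains, with the outgroup
# attached below the ingroup root on a stretched branch. Branch "lengths"
# are per-site substitution probabilities consumed by evolve_sequence().
simulate_species_tree <- function(strains, outgroup, divergence) {
  n <- length(strains)
  tre <- ape::rtree(n, rooted = TRUE, tip.label = sample(strains), br = NULL)
  nwk <- sub(";$", "", ape::write.tree(tre))
  full <- ape::read.tree(text = sprintf("(%s,%s);", nwk, outgroup))
  full$edge.length <- rep(divergence, nrow(full$edge))
  og_edge <- which(full$edge[, 2] == match(outgroup, full$tip.label))
  full$edge.length[og_edge] <- 3 * divergence
  full
}

random_protein <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

# Mutate each site independently with probability p, always to a different
# residue.
mutate_sites <- function(chars, p) {
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  chars
}

# Evolve an ancestral sequence down the tree; returns named character vector
# of tip sequences. Children are visited in edge-table order, which is fixed
# for a given tree, so the draw order is reproducible.
evolve_along_tree <- function(tree, ancestral) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(ancestral, "")[[1]]
  ord <- ape::reorder.phylo(tree, "cladewise")
  tips <- character(0)
  res <- character(ntip)
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    seqs[[child]] <- mutate_sites(seqs[[par]], ord$edge.length[k])
    if (child <= ntip) res[child] <- paste(seqs[[child]], collapse = "")
  }
  names(res) <- tree$tip.label
  res
}

draw_carriage <- function(n, p) {
  repeat {
    v <- stats::runif(n) < p
    if (any(v) && !all(v)) return(v)
  }
}

#' Simulate a synthetic pan-genome
#'
#' Generates per-strain protein sequences, per-gene functional annotations and
#' a ground-truth record. Every strain carries every core family; dispensable
#' carriage is drawn per family with a probability uniform in
#' `occurrence_prob_range` (redrawn until the family is neither universal nor
#' absent); planted-cluster families co-occur exactly in their cluster's
#' carrier strains, and carrier sets are redrawn until distinct from each
#' other and from every background dispensable carriage vector, so planted
#' occurrence patterns are unambiguous; each strain receives its own unique
#' singleton genes. Gene ids follow `"<strain>|<family>|<serial>"` so truth
#' can be recovered from the FASTA headers alone.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `pan_sim` with elements `genomes` (named list of
#'   named character vectors, gene id -> protein sequence), `annotations`
#'   (data.frame gene_id, func), `truth` (family membership, planted
#'   clusters, species tree, true phenotypes), `outgroup_proteins` (core
#'   family -> outgroup sequence) and `config`.
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  strains <- sprintf("S%02d", seq_len(config$n_strains))

  ## stream 1: species tree
  set.seed(derive_seed(config$seed, 1))
  tree <- simulate_species_tree(strains, config$outgroup_id,
                                config$divergence_within_family)

  ## stream 2: family structure
  set.seed(derive_seed(config$seed, 2))
  n_fam_cd <- config$core_size + config$n_dispensable
  fam_ids <- sprintf("F%05d", seq_len(n_fam_cd))
  core_ids <- fam_ids[seq_len(config$core_size)]
  disp_ids <- setdiff(fam_ids, core_ids)

  carriage <- matrix(FALSE, n_fam_cd, config$n_strains,
                     dimnames = list(fam_ids, strains))
  carriage[core_ids, ] <- TRUE
  for (f in disp_ids) {
    p <- stats::runif(1, config$occurrence_prob_range[1],
                      config$occurrence_prob_range[2])
    carriage[f, ] <- draw_carriage(config$n_strains, p)
  }

  ## planted clusters: disjoint dispensable families, shared carrier set
  planted <- list()
  planted_fams <- character(0)
  carrier_sets <- list()
  if (config$n_trait_clusters > 0) {
    carbs <- rep_len(CARB_LABELS, config$n_trait_clusters)
    pool <- sample(disp_ids)
    for (k in seq_len(config$n_trait_clusters)) {
      sz <- sample(seq(config$cluster_size_range[1],
                       config$cluster_size_range[2]), 1)
      fams <- sort(pool[seq_len(sz)])
      pool <- pool[-seq_len(sz)]
      repeat {
        carriers <- draw_carriage(config$n_strains, config$carrier_fraction)
        if (!any(vapply(carrier_sets, identical, logical(1), carriers))) break
      }
      carrier_sets[[k]] <- carriers
      carriage[fams, ] <- matrix(carriers, length(fams), config$n_strains,
                                 byrow = TRUE)
      planted[[sprintf("CL%d", k)]] <-
        list(families = fams, carriers = strains[carriers],
             carbohydrate = carbs[k])
      planted_fams <- c(planted_fams, fams)
    }
    ## background families must not mimic a planted occurrence pattern
    for (f in setdiff(disp_ids, planted_fams)) {
      while (any(vapply(carrier_sets, identical, logical(1), carriage[f, ]))) {
        p <- stats::runif(1, config$occurrence_prob_range[1],
                          config$occurrence_prob_range[2])
        carriage[f, ] <- draw_carriage(config$n_strains, p)
      }
    }
  }

  ## strain-unique singleton families
  uniq_counts <- sample(seq(config$unique_per_strain_range[1],
                            config$unique_per_strain_range[2]),
                        config$n_strains, replace = TRUE)
  uniq_ids <- list()
  serial <- n_fam_cd
  for (i in seq_along(strains)) {
    ids <- if (uniq_counts[i] > 0)
      sprintf("F%05d", serial + seq_len(uniq_counts[i])) else character(0)
    serial <- serial + uniq_counts[i]
    uniq_ids[[strains[i]]] <- ids
  }
  all_uniq <- unlist(uniq_ids, use.names = FALSE)

  ## stream 3: annotations (one function label per family)
  set.seed(derive_seed(config$seed, 3))
  fam_func <- character(0)
  fam_func[core_ids] <- sample(HOUSEKEEPING_FUNCS, length(core_ids),
                               replace = TRUE)
  bg_disp <- setdiff(disp_ids, planted_fams)
  n_mobile <- round(config$mobile_annotation_fraction * length(bg_disp))
  mobile_fams <- sample(bg_disp, n_mobile)
  fam_func[mobile_fams] <- sample(MOBILE_ELEMENT_FUNCS, n_mobile,
                                  replace = TRUE)
  rest <- setdiff(bg_disp, mobile_fams)
  fam_func[rest] <- sample(BACKGROUND_FUNCS, length(rest), replace = TRUE)
  for (cl in planted) {
    fams <- cl$families
    fam_func[fams[1]] <- CARB_KEY_ENZYMES[[cl$carbohydrate]]
    if (length(fams) > 1)
      fam_func[fams[-1]] <- sample(CLUSTER_ACCESSORY_FUNCS,
                                   length(fams) - 1, replace = TRUE)
  }
  if (length(all_uniq))
    fam_func[all_uniq] <- sample(BACKGROUND_FUNCS, length(all_uniq),
                                 replace = TRUE)

  ## stream 4: sequences
  set.seed(derive_seed(config$seed, 4))
  ingroup_tree <- ape::drop.tip(tree, config$outgroup_id)
  genomes <- stats::setNames(
    replicate(config$n_strains, character(0), simplify = FALSE), strains)
  outgroup_proteins <- character(0)
  for (f in fam_ids) {
    anc <- random_protein(config$protein_length)
    is_core <- f %in% core_ids
    tips <- evolve_along_tree(if (is_core) tree else ingroup_tree, anc)
    carriers <- strains[carriage[f, ]]
    for (s in carriers) {
      gid <- paste(s, f, "1", sep = "|")
      genomes[[s]][gid] <- tips[[s]]
    }
    if (is_core) outgroup_proteins[f] <- tips[[config$outgroup_id]]
  }
  for (s in strains) {
    for (f in uniq_ids[[s]]) {
      gid <- paste(s, f, "1", sep = "|")
      genomes[[s]][gid] <- random_protein(config$protein_length)
    }
  }

  ## ground truth
  membership <- lapply(stats::setNames(fam_ids, fam_ids),
                       function(f) strains[carriage[f, ]])
  for (s in strains)
    for (f in uniq_ids[[s]]) membership[[f]] <- s

  carbs_all <- c("lactose",
                 vapply(planted, function(cl) cl$carbohydrate, character(1)))
  phen <- matrix(0L, length(carbs_all), config$n_strains,
                 dimnames = list(carbs_all, strains))
  phen["lactose", ] <- 1L
  for (cl in planted) phen[cl$carbohydrate, cl$carriers] <- 1L

  ann <- data.frame(
    gene_id = unlist(lapply(genomes, names), use.names = FALSE),
    func = NA_character_, stringsAsFactors = FALSE)
  ann$func <- fam_func[vapply(strsplit(ann$gene_id, "|", fixed = TRUE),
                              `[`, character(1), 2)]
  ann <- ann[order(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL

  truth <- list(family_membership = membership,
                planted_clusters = planted,
                species_tree = tree,
                true_phenotypes = phen,
                strains = strains,
                outgroup = config$outgroup_id,
                core_families = core_ids,
                dispensable_families = disp_ids,
                unique_families = stats::setNames(
                  rep(strains, lengths(uniq_ids[strains])), all_uniq))
  structure(list(genomes = genomes, annotations = ann, truth = truth,
                 outgroup_proteins = outgroup_proteins, config = config),
            class = "pan_sim")
}

#' @export
print.pan_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic pan-genome: %d strains, %d families (%d core), %d genes\n",
    length(x$genomes), length(x$truth$family_membership),
    length(x$truth$core_families),
    sum(lengths(x$genomes))))
  cat(sprintf("Planted trait clusters: %d (%s)\n",
              length(x$truth$planted_clusters),
              paste(vapply(x$truth$planted_clusters,
                           function(cl) cl$carbohydrate, character(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate OD600 growth curves
#'
#' Emits a long-format growth-curve table (strain x carbohydrate x time) from
#' the simulated ground truth. Growers follow a monotone logistic-like rise
#' hitting an OD600 at 12 h drawn from `growth_od12_range`; non-growers stay
#' within `nogrowth_od12_range`. Gaussian measurement noise of sd
#' `od_noise_sd` is added and truncated at 0. A lactose row with all-grower
#' calls is always emitted as positive control and is never flipped by
#' `phenotype_noise`.
#'
#' Draw order (one seeded stream): carbohydrates in the row order of
#' `truth$true_phenotypes`, strains in column order; per non-control pair one
#' uniform flip draw, then one uniform OD-at-12h draw, then five normal noise
#' draws; control pairs skip the flip draw.
#'
#' @param truth the `truth` element of a [simulate_pangenome()] result.
#' @param config the matching [sim_config()].
#' @return data.frame (strain, carbohydrate, time_h, od600) with attribute
#'   `"flips"`, a data.frame of the (carbohydrate, strain) calls inverted by
#'   phenotype noise.
#' @export
simulate_growth_curves <- function(truth, config) {
  validate_sim_config(config)
  times <- c(0, 6, 9, 12, 24)
  s_curve <- function(t) 1 / (1 + exp(-(t - 8) / 2.2))
  g_shape <- (s_curve(times) - s_curve(0)) / (s_curve(12) - s_curve(0))
  ng_shape <- c(0.5, 0.8, 0.9, 1, 1.02)
  od0_grow <- 0.05

  set.seed(derive_seed(config$seed, 5))
  phen <- truth$true_phenotypes
  rows <- list()
  flips <- list()
  for (carb in rownames(phen)) {
    for (s in colnames(phen)) {
      call <- phen[carb, s]
      if (carb != "lactose") {
        if (stats::runif(1) < config$phenotype_noise) {
          call <- 1L - call
          flips[[length(flips) + 1]] <- data.frame(
            carbohydrate = carb, strain = s, stringsAsFactors = FALSE)
        }
      }
      if (call == 1L) {
        od12 <- stats::runif(1, config$growth_od12_range[1],
                             config$growth_od12_range[2])
        od <- od0_grow + (od12 - od0_grow) * g_shape
      } else {
        od12 <- stats::runif(1, config$nogrowth_od12_range[1],
                             config$nogrowth_od12_range[2])
        od <- od12 * ng_shape
      }
      od <- pmax(0, od + stats::rnorm(length(times), 0, config$od_noise_sd))
      rows[[length(rows) + 1]] <- data.frame(
        strain = s, carbohydrate = carb, time_h = times, od600 = od,
        stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, rows)
  rownames(curves) <- NULL
  attr(curves, "flips") <- if (length(flips)) do.call(rbind, flips) else
    data.frame(carbohydrate = character(0), strain = character(0))
  curves
}

#' Reconstruct a family set from simulator gene ids
#'
#' Gene ids follow `"<strain>|<family>|<serial>"`, so family membership can be
#' recovered from the emitted sequences without a lookup table.
#'
#' @param genomes named list of named sequence vectors (as emitted by
#'   [simulate_pangenome()]) or a named character vector of gene ids grouped
#'   arbitrarily.
#' @return a `family_set` (see [family_set()]).
#' @export
families_from_gene_ids <- function(genomes) {
  gids <- unlist(lapply(genomes, names), use.names = FALSE)
  parts <- strsplit(gids, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad))
    stop_input("gene id(s) not in '<strain>|<family>|<serial>' form: %s",
               paste(utils::head(gids[bad], 3), collapse = ", "))
  family_set(data.frame(
    family_id = vapply(parts, `[`, character(1), 2),
    genome_id = vapply(parts, `[`, character(1), 1),
    gene_id = gids, stringsAsFactors = FALSE),
    provenance = list(method = "simulator gene ids"))
}

#' Write simulator outputs to disk
#'
#' One protein FASTA per strain, annotations as a two-column TSV, growth
#' curves as long-format CSV and ground truth as JSON. Outputs are
#' byte-stable for a fixed configuration.
#'
#' @param sim a [simulate_pangenome()] result.
#' @param curves a [simulate_growth_curves()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, curves, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "genomes"), showWarnings = FALSE)
  paths <- character(0)
  for (s in names(sim$genomes)) {
    p <- file.path(outdir, "genomes", paste0(s, ".faa"))
    write_fasta(sim$genomes[[s]], p)
    paths <- c(paths, p)
  }
  if (length(sim$outgroup_proteins)) {
    p <- file.path(outdir, "genomes", paste0(sim$config$outgroup_id, ".faa"))
    og <- sim$outgroup_proteins
    names(og) <- paste(sim$config$outgroup_id, names(og), "1", sep = "|")
    write_fasta(og, p)
    paths <- c(paths, p)
  }
  ap <- file.path(outdir, "annotations.tsv")
  utils::write.table(sim$annotations, ap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cp <- file.path(outdir, "growth_curves.csv")
  utils::write.csv(curves, cp, row.names = FALSE, quote = FALSE)
  tp <- file.path(outdir, "truth.json")
  truth_json <- list(
    family_membership = sim$truth$family_membership,
    planted_clusters = sim$truth$planted_clusters,
    species_tree_newick = ape::write.tree(sim$truth$species_tree),
    true_phenotypes = as.data.frame(sim$truth$true_phenotypes),
    strains = sim$truth$strains,
    outgroup = sim$truth$outgroup)
  jsonlite::write_json(truth_json, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, ap, cp, tp))
}
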