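# Pipeline driver: one configuration object holding every stage parameter,
# and run_all() executing simulate -> cluster -> pangenome -> phylogeny ->
# phenotype -> gene-trait matching with a checksummed manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the analysis
#' constants: 50% identity / 1e-4 e-value similarity filter, MCL inflation
#' 2.5, 100 accumulation permutations, OD600 binarization at 0.3/0.4 with
#' the 0.4/0.5 category cut-offs, and the strictly-greater 95% gene-trait
#' match rule. Unknown parameter names are rejected.
#'
#' @param ... overrides for any of the defaults; `sim` takes a list of
#'   [sim_config()] arguments.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sim = list(),
    min_identity = 50,
    max_evalue = 1e-4,
    inflation = 2.5,
    n_permutations = 100,
    phenotype_time_h = 12,
    control_carbohydrate = "lactose",
    exclusion_keywords = DEFAULT_EXCLUSION_KEYWORDS,
    indeterminate = "as_zero",
    match_threshold = 95,
    consensus_threshold = 0.5,
    supertree_families = 30,
    cluster_from = "gene_ids")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_input("unknown pipeline parameter(s): %s",
               paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$cluster_from %in% c("gene_ids", "identity"))
    stop_input("cluster_from must be 'gene_ids' or 'identity'")
  if (cfg$match_threshold < 0 || cfg$match_threshold > 100)
    stop_input("match_threshold must be in [0, 100]")
  if (cfg$consensus_threshold < 0.5 || cfg$consensus_threshold >= 1)
    stop_input("consensus_threshold must be in [0.5, 1)")
  cfg$sim$seed <- cfg$sim$seed %||% cfg$seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a simulated pan-genome
#'
#' Executes every stage in order, writing stage outputs plus a manifest JSON
#' (parameters, seeds, per-file checksums) under `workdir`. Two runs with
#' the same configuration produce byte-identical outputs and manifests.
#'
#' Family recovery uses the simulator's self-describing gene ids by default
#' (`cluster_from = "gene_ids"`); `cluster_from = "identity"` instead runs
#' the all-vs-all identity path, the similarity filter and Markov
#' clustering, which is quadratic in gene count and meant for small
#' configurations.
#'
#' @param config a [pipeline_config()].
#' @param workdir output directory.
#' @return invisibly, a list with the main stage objects and the manifest.
#' @export
run_all <- function(config, workdir) {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must be a pipeline_config")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(workdir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  file.create(log_path)
  stage <- "simulate"
  result <- tryCatch({
    logf("[simulate] seed=%d", config$seed)
    scfg <- do.call(sim_config, config$sim)
    sim <- simulate_pangenome(scfg)
    curves <- simulate_growth_curves(sim$truth, scfg)
    write_simulation(sim, curves, file.path(workdir, "simulate"))

    stage <- "cluster"
    logf("[cluster] source=%s", config$cluster_from)
    fams <- if (config$cluster_from == "gene_ids") {
      families_from_gene_ids(sim$genomes)
    } else {
      seqs <- unlist(unname(sim$genomes))
      recs <- all_vs_all_identity(seqs)
      recs <- filter_similarities(recs, config$min_identity,
                                  config$max_evalue)
      g <- build_graph(recs, names(seqs))
      mcl_cluster(g, inflation = config$inflation)
    }
    write_families(fams, file.path(workdir, "families.tsv"))

    stage <- "pangenome"
    logf("[pangenome] permutations=%d", config$n_permutations)
    pa <- presence_absence(fams, sim$truth$strains)
    write_matrix_tsv(pa, file.path(workdir, "presence_absence.tsv"))
    part <- partition_families(pa)
    curve <- accumulation_curves(pa, config$n_permutations,
                                 seed = derive_seed(config$seed, 11))
    utils::write.csv(curve$curve, file.path(workdir, "accumulation.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(partition = as.list(part$counts),
           core_fraction_pct = part$core_fraction_pct,
           fitted_pan = curve$fitted_pan, fitted_core = curve$fitted_core),
      file.path(workdir, "pangenome_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    heat <- hierarchical_heatmap_export(pa)
    write_matrix_tsv(heat$ordered_matrix,
                     file.path(workdir, "presence_absence_clustered.tsv"))
    writeLines(heat$newick, file.path(workdir, "genome_dendrogram.nwk"))

    stage <- "phylogeny"
    sc <- extract_single_copy(fams, sim$truth$strains)
    # map recovered family labels back to simulator family ids via the
    # self-describing gene ids (unanimous families only)
    sc_truth <- vapply(split(sc$gene_id, sc$family_id), function(g) {
      ids <- unique(vapply(strsplit(g, "|", fixed = TRUE), `[`,
                           character(1), 2))
      if (length(ids) == 1) ids else NA_character_
    }, character(1))
    sc_core <- intersect(sort(stats::na.omit(sc_truth)),
                         names(sim$outgroup_proteins))
    use <- utils::head(sort(sc_core), config$supertree_families)
    logf("[phylogeny] families=%d outgroup=%s", length(use),
         sim$truth$outgroup)
    alns <- family_alignments(sim, use)
    st <- build_supertree(alns, sim$truth$outgroup,
                          threshold = config$consensus_threshold)
    ape::write.tree(st$tree, file.path(workdir, "supertree.nwk"))
    utils::write.table(st$bipartitions,
                       file.path(workdir, "bipartitions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "phenotype"
    pheno <- build_phenotype_matrix(curves, config$phenotype_time_h,
                                    config$control_carbohydrate)
    write_matrix_tsv(unclass(pheno), file.path(workdir, "phenotypes.tsv"))
    utils::write.csv(attr(pheno, "call_log"),
                     file.path(workdir, "growth_calls.csv"),
                     row.names = FALSE, quote = FALSE)
    diff_carbs <- select_differential(pheno)
    logf("[phenotype] %d differential carbohydrate(s)", length(diff_carbs))

    stage <- "gtm"
    geno <- build_genotype_matrix(pa, fams, sim$annotations,
                                  config$exclusion_keywords)
    pats <- collapse_patterns(geno)
    res <- match_all(pats, pheno[diff_carbs, , drop = FALSE],
                     indeterminate = config$indeterminate)
    write_matrix_tsv(res$percent, file.path(workdir, "match_heatmap.tsv"))
    rep <- report_hits(res, threshold = config$match_threshold)
    utils::write.table(rep$hits, file.path(workdir, "gtm_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep$hits, file.path(workdir, "gtm_hits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("[gtm] %d hit(s) above %g%%", nrow(rep$hits),
         config$match_threshold)

    list(sim = sim, curves = curves, families = fams, matrix = pa,
         partition = part, curve = curve, supertree = st,
         phenotypes = pheno, patterns = pats, match = res, report = rep)
  }, error = function(e) {
    logf("[%s] FAILED: %s", stage, conditionMessage(e))
    stop_input("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  files <- sort(setdiff(list.files(workdir, recursive = TRUE),
                        c("manifest.json", "pipeline.log")))
  manifest <- list(
    parameters = unclass(config),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(workdir, f))),
           bytes = file.size(file.path(workdir, f)))))
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
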