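# Genotype-matrix filtering, pattern collapsing and gene-trait matching.

toy_genotype_inputs <- function() {
  strains <- paste0("s", 1:4)
  fams <- c("core1", "mob1", "xyl1", "xyl2", "other1", "uniq1")
  m <- matrix(0L, length(fams), length(strains),
              dimnames = list(fams, strains))
  m["core1", ] <- 1L
  m["mob1", c("s1", "s3")] <- 1L
  m["xyl1", c("s1", "s2")] <- 1L
  m["xyl2", c("s1", "s2")] <- 1L
  m["other1", c("s2", "s3", "s4")] <- 1L
  m["uniq1", "s4"] <- 1L
  rows <- do.call(rbind, lapply(fams, function(f)
    data.frame(family_id = f, genome_id = strains[m[f, ] > 0],
               gene_id = paste0(strains[m[f, ] > 0], "|", f, "|1"))))
  families <- family_set(rows)
  ann <- data.frame(
    gene_id = families$gene_id,
    func = c(core1 = "elongation factor Tu",
             mob1 = "IS3-family transposase",
             xyl1 = "beta-xylosidase",
             xyl2 = "ABC transporter permease",
             other1 = "hypothetical protein",
             uniq1 = "secreted protein")[families$family_id],
    stringsAsFactors = FALSE)
  list(matrix = m, families = families, annotations = ann,
       strains = strains)
}

test_that("genotype matrix drops core families and excluded annotations", {
  inp <- toy_genotype_inputs()
  g <- build_genotype_matrix(inp$matrix, inp$families, inp$annotations)
  expect_setequal(rownames(g), c("xyl1", "xyl2", "other1", "uniq1"))
  expect_equal(attr(g, "n_dropped_core"), 1)
  expect_equal(attr(g, "n_dropped_excluded"), 1)
  expect_identical(unname(attr(g, "annotation")["xyl1"]), "beta-xylosidase")
  # families with no annotated member are kept and flagged
  ann2 <- inp$annotations[inp$families$family_id != "uniq1", ]
  g2 <- build_genotype_matrix(inp$matrix, inp$families, ann2)
  expect_true("uniq1" %in% rownames(g2))
  expect_identical(attr(g2, "unannotated"), "uniq1")
})

test_that("pattern collapsing groups identical occurrence vectors and round-trips", {
  inp <- toy_genotype_inputs()
  g <- build_genotype_matrix(inp$matrix, inp$families, inp$annotations)
  pats <- collapse_patterns(g)
  expect_equal(nrow(pats$patterns), 3)  # xyl1+xyl2 share a vector
  joint <- pats$members[[which(vapply(pats$members, length, 1L) == 2)]]
  expect_setequal(joint, c("xyl1", "xyl2"))
  # expanding members reproduces the filtered family set exactly
  expect_setequal(unlist(pats$members), rownames(g))
  for (p in rownames(pats$patterns))
    for (f in pats$members[[p]])
      expect_equal(unname(pats$patterns[p, ]), unname(g[f, ]))
  # all-distinct input keeps one pattern per family
  sub <- g[c("xyl1", "other1", "uniq1"), ]
  expect_equal(nrow(collapse_patterns(sub)$patterns), 3)
})

test_that("matching percentage counts positional agreement with both policies", {
  expect_equal(match_percentage(c(1, 1, 0, 0), c(1, 1, 0, 0))$percent, 100)
  expect_equal(match_percentage(c(1, 0), c(0, 1))$percent, 0)
  expect_equal(match_percentage(c(1, 0, 1, 0, 1), c(1, 1, 1, 0, 0))$percent,
               60)
  # symmetry and permutation invariance
  set.seed(4)
  for (k in 1:10) {
    a <- stats::rbinom(12, 1, 0.5); b <- stats::rbinom(12, 1, 0.5)
    expect_equal(match_percentage(a, b)$percent,
                 match_percentage(b, a)$percent)
    perm <- sample(12)
    expect_equal(match_percentage(a[perm], b[perm])$percent,
                 match_percentage(a, b)$percent)
  }
  expect_error(match_percentage(c(1, 0), c(1, 0, 1)), "length")
  # indeterminate handling
  ph <- c(1, NA, 0, NA)
  gt <- c(1, 0, 0, 1)
  az <- match_percentage(gt, ph, "as_zero")
  expect_equal(az$percent, 75)       # NA -> 0: agree at 1,2,3
  expect_equal(az$n_compared, 4)
  expect_equal(az$n_indeterminate, 2)
  st <- match_percentage(gt, ph, "strict")
  expect_equal(st$percent, 100)      # positions 1 and 3 only
  expect_equal(st$n_compared, 2)
})

test_that("pattern-phenotype matching scores exact rows at 100 and checks strain sets", {
  inp <- toy_genotype_inputs()
  g <- build_genotype_matrix(inp$matrix, inp$families, inp$annotations)
  pats <- collapse_patterns(g)
  pheno <- rbind(xylose = c(1L, 1L, 0L, 0L),
                 arabinan = c(0L, 1L, 1L, 1L))
  colnames(pheno) <- inp$strains
  res <- match_all(pats, pheno)
  xyl_pat <- names(which(vapply(pats$members, function(m)
    "xyl1" %in% m, logical(1))))
  expect_equal(res$percent[xyl_pat, "xylose"], 100)
  expect_true(all(res$n_compared == 4))
  bad <- pheno[, c(1, 2, 3), drop = FALSE]
  expect_error(match_all(pats, bad), "strain sets differ")
})

test_that("mean random match agrees with the independence closed form", {
  set.seed(21)
  p <- 0.6; q <- 0.3; n <- 40
  expected <- p * q + (1 - p) * (1 - q)
  draws <- replicate(4000, {
    match_percentage(stats::rbinom(n, 1, p),
                     stats::rbinom(n, 1, q))$percent / 100
  })
  se <- sqrt(expected * (1 - expected) / (n * 4000))
  expect_lt(abs(mean(draws) - expected), 5 * se)
})

test_that("the hit rule is strictly greater than the threshold", {
  pats <- structure(list(
    patterns = matrix(c(rep(1L, 10), rep(0L, 10)), 1, 20,
                      dimnames = list("P0001", sprintf("s%02d", 1:20))),
    members = list(P0001 = "famA"),
    annotations = list(P0001 = c(famA = "beta-xylosidase"))),
    class = "genotype_patterns")
  pheno_exact <- pats$patterns
  rownames(pheno_exact) <- "xos"
  res <- match_all(pats, pheno_exact)
  expect_equal(nrow(report_hits(res)$hits), 1)
  # flip one strain: 19/20 = 95 is not > 95
  pheno_flip <- pheno_exact
  pheno_flip[1, 1] <- 0L
  res95 <- match_all(pats, pheno_flip)
  expect_equal(unname(res95$percent[1, 1]), 95)
  expect_equal(nrow(report_hits(res95)$hits), 0)
  expect_equal(nrow(report_hits(res95)$partial), 1)
  # empty result set gives an empty report
  empty <- res
  empty$percent <- empty$percent[0, , drop = FALSE]
  empty$n_compared <- empty$n_compared[0, , drop = FALSE]
  expect_equal(nrow(report_hits(empty)$hits), 0)
})

test_that("noiseless simulation yields exactly the planted clusters as hits", {
  s <- small_sim()
  sim <- s$sim
  curves <- simulate_growth_curves(sim$truth, s$config)
  fams <- families_from_gene_ids(sim$genomes)
  pa <- presence_absence(fams, sim$truth$strains)
  pheno <- build_phenotype_matrix(curves)
  diff_carbs <- select_differential(pheno)
  geno <- build_genotype_matrix(pa, fams, sim$annotations)
  pats <- collapse_patterns(geno)
  rep <- report_hits(match_all(pats, pheno[diff_carbs, , drop = FALSE]))
  planted <- sim$truth$planted_clusters
  expect_equal(nrow(rep$hits), length(planted))
  for (cl in planted) {
    hit <- rep$hits[rep$hits$carbohydrate == cl$carbohydrate, ]
    expect_equal(nrow(hit), 1)
    expect_setequal(strsplit(hit$families, ";")[[1]], cl$families)
    expect_equal(hit$percent, 100)
  }
})
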