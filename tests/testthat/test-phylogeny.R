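# p-distances, neighbor joining, majority-rule consensus and outgroup
# rooting.

test_that("p-distance counts differing sites and skips ambiguity columns", {
  aln <- c(a = "AAAA", b = "AATT", c = "TTTT")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 1)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  amb <- c(a = "AAXA", b = "AATA", c = "TTTT")
  expect_equal(p_distance_matrix(amb)["a", "b"], 0)  # X column ignored
  expect_error(p_distance_matrix(c(a = "AA", b = "AAA", c = "AA")),
               "unequal")
  expect_error(p_distance_matrix(c(a = "AA", b = "AA")), "3 taxa")
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tre <- neighbor_joining(d)
  expect_setequal(tre$tip.label, c("a", "b", "c"))
  # closed form: la = (dab + dac - dbc)/2 etc.
  pend <- tre$edge.length[match(seq_len(3), tre$edge[, 2])]
  names(pend) <- tre$tip.label
  expect_equal(unname(pend[c("a", "b", "c")]), c(0.1, 0.2, 0.4))
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  # tree ((a:1, b:2):1, c:3, d:1) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5
  d["a", "d"] <- d["d", "a"] <- 3
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 4
  d["c", "d"] <- d["d", "c"] <- 4
  tre <- neighbor_joining(d)
  # four-point condition: ab|cd split, so path a-b avoids the internal edge
  expect_equal(unname(cophenetic(tre)[letters[1:4], letters[1:4]]),
               unname(d))
  bip <- ape::prop.part(ape::root(tre, outgroup = "a",
                                  resolve.root = FALSE))
  labs <- attr(bip, "labels")
  clades <- lapply(bip, function(i) sort(labs[i]))
  expect_true(list(c("c", "d")) %in% clades ||
                any(vapply(clades, identical, logical(1), c("c", "d"))))
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister", {
  # distances violating additivity can yield negative NJ branches
  set.seed(42)
  for (k in 1:5) {
    n <- 6
    d <- as.matrix(stats::dist(matrix(stats::runif(n * 2), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    d <- d + matrix(stats::runif(n * n, 0, 0.05), n) * (1 - diag(n))
    d <- (d + t(d)) / 2
    tre <- neighbor_joining(d)
    expect_true(all(tre$edge.length >= 0))
    raw <- ape::nj(d)
    if (all(raw$edge.length >= 0)) {
      expect_equal(tre$edge.length, raw$edge.length)
    } else {
      # deficit transfer preserves total length unless a sister edge is
      # itself driven negative and clamped
      expect_lte(sum(tre$edge.length), sum(raw$edge.length) +
                   sum(-raw$edge.length[raw$edge.length < 0]) + 1e-12)
    }
  }
})

test_that("majority consensus keeps clades in > threshold of trees with correct supports", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  t3 <- ape::read.tree(text = "((a,b),(c,d),e);")

  same <- majority_consensus(list(t1, t1, t1))
  expect_equal(phangorn::RF.dist(ape::unroot(same), ape::unroot(t1)), 0)
  expect_true(all(as.numeric(same$node.label[same$node.label != ""]) == 100))

  cons <- majority_consensus(list(t1, t2, t3))
  labs <- cons$node.label[nzchar(cons$node.label)]
  # (a,b) in 3/3 -> 100; (c,d) in 2/3 -> 66.7 retained
  expect_setequal(round(as.numeric(labs), 1), c(100, 66.7))

  # clade in exactly half of the trees is dropped under strict majority
  half <- majority_consensus(list(t1, t2))
  bip <- attr(half, "bipartitions")
  expect_false(any(grepl("c", bip$clade) & bip$support <= 50))
  expect_equal(phangorn::RF.dist(ape::unroot(half),
                                 ape::unroot(ape::read.tree(
                                   text = "((a,b),c,d,e);"))), 0)
})

test_that("consensus equals brute-force bipartition counting on random tree sets", {
  set.seed(9)
  for (rep in 1:5) {
    trees <- replicate(10, ape::rtree(6, tip.label = letters[1:6]),
                       simplify = FALSE)
    cons <- majority_consensus(trees)
    counts <- oracle_bipartition_counts(trees)
    majority <- sort(names(counts)[counts / 10 > 0.5])
    got <- sort(attr(cons, "bipartitions")$clade)
    expect_identical(got, majority)
    # supports are multiples of 100 / n_trees
    sup <- attr(cons, "bipartitions")$support
    expect_true(all(abs(sup * 10 / 100 - round(sup * 10 / 100)) < 1e-9))
    # topology agrees with the reference consensus implementation
    ref <- ape::consensus(trees, p = 0.5)
    expect_equal(phangorn::RF.dist(ape::unroot(cons), ape::unroot(ref)), 0)
  }
})

test_that("consensus rejects trees with different leaf sets", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,f),e);")
  expect_error(majority_consensus(list(t1, t2)), "leaf set")
})

test_that("outgroup rooting is leaf-preserving, idempotent and isolates the ingroup", {
  tre <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,o:2):0.5);")
  r1 <- root_with_outgroup(tre, "o")
  expect_setequal(r1$tip.label, tre$tip.label)
  r2 <- root_with_outgroup(r1, "o")
  expect_equal(phangorn::RF.dist(r1, r2), 0)
  # ingroup forms one clade of the rooted tree
  pp <- ape::prop.part(r1)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(i) sort(labs[i]))
  expect_true(any(vapply(clades, identical, logical(1), c("a", "b", "c"))))
  expect_error(root_with_outgroup(tre, "zz"), "not a leaf")
})

test_that("supertree of one family reproduces that family's tree with full support", {
  sim <- small_sim()$sim
  aln <- family_alignments(sim, sim$truth$core_families[1])
  st <- build_supertree(aln, sim$truth$outgroup)
  expect_equal(st$n_families_used, 1)
  fam_tree <- st$family_trees[[1]]
  expect_equal(phangorn::RF.dist(ape::unroot(st$tree),
                                 ape::unroot(fam_tree)), 0)
  expect_true(all(st$bipartitions$support == 100))
})

test_that("families missing the outgroup are skipped with a warning", {
  sim <- small_sim()$sim
  alns <- family_alignments(sim, sim$truth$core_families[1:3])
  alns[[2]] <- alns[[2]][setdiff(names(alns[[2]]), sim$truth$outgroup)]
  expect_warning(st <- build_supertree(alns, sim$truth$outgroup), "skipped")
  expect_equal(st$n_families_used, 2)
  expect_error(suppressWarnings(
    build_supertree(list(f = alns[[2]]), sim$truth$outgroup)), "no usable")
})

test_that("consensus of simulated core-family trees recovers the species tree", {
  cfg <- sim_config(n_strains = 12, core_size = 30, n_dispensable = 30,
                    n_trait_clusters = 2, unique_per_strain_range = c(0, 2),
                    seed = 11)
  sim <- simulate_pangenome(cfg)
  alns <- family_alignments(sim, sim$truth$core_families[1:25])
  st <- build_supertree(alns, sim$truth$outgroup)
  expect_equal(phangorn::RF.dist(ape::unroot(st$tree),
                                 ape::unroot(sim$truth$species_tree)), 0)
})
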