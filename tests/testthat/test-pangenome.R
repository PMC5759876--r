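# Core/dispensable/unique partitioning, accumulation curves, pan-genome
# comparison, genome summaries and the clustered heatmap export.

toy_family_set <- function() {
  # 6 families over 3 genomes: carriage {all},{all},{g1,g2},{g2,g3},{g1},{g3}
  rows <- list(
    c("f1", "g1"), c("f1", "g2"), c("f1", "g3"),
    c("f2", "g1"), c("f2", "g2"), c("f2", "g3"),
    c("f3", "g1"), c("f3", "g2"),
    c("f4", "g2"), c("f4", "g3"),
    c("f5", "g1"),
    c("f6", "g3"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("family_id", "genome_id")
  df$gene_id <- paste0(df$genome_id, "|", df$family_id, "|1")
  family_set(df)
}

test_that("presence/absence matrix counts members and orders deterministically", {
  df <- data.frame(family_id = c("fam1", "fam1", "fam2", "fam2"),
                   genome_id = c("g1", "g2", "g1", "g1"),
                   gene_id = c("a", "b", "c", "d"))
  m <- presence_absence(family_set(df))
  expect_identical(rownames(m), c("fam1", "fam2"))
  expect_identical(colnames(m), c("g1", "g2"))
  expect_equal(unname(m), rbind(c(1L, 1L), c(2L, 0L)))  # paralogue count 2
  expect_equal(unname(m["fam2", "g1"] > 0), TRUE)       # binary view
})

test_that("partition splits core, shared-dispensable and unique with the variable aggregate", {
  pa <- presence_absence(toy_family_set())
  part <- partition_families(pa)
  expect_setequal(part$core, c("f1", "f2"))
  expect_setequal(part$dispensable, c("f3", "f4"))
  expect_setequal(part$unique, c("f5", "f6"))
  expect_equal(unname(part$counts["variable"]), 4)
  expect_equal(sum(part$counts[c("core", "dispensable", "unique")]),
               unname(part$counts["total"]))
  expect_equal(part$unique_owner[["f5"]], "g1")
})

test_that("exhaustive 3-genome accumulation equals the hand-computed 6-permutation average", {
  pa <- presence_absence(toy_family_set())
  acc <- accumulation_curves(pa)
  expect_true(acc$exhaustive)
  expect_equal(acc$n_permutations, 6)
  # hand enumeration over orders of (g1, g2, g3):
  # sizes: g1 {f1,f2,f3,f5}=4, g2 {f1,f2,f3,f4}=4, g3 {f1,f2,f4,f6}=4
  # pan at N=2: g1g2=5, g1g3=6, g2g3=5 (each order twice) -> mean 16/3
  # core at N=2: g1g2=3, g1g3=2, g2g3=3 -> mean 8/3
  expect_equal(acc$curve$pan_mean, c(4, 16 / 3, 6))
  expect_equal(acc$curve$core_mean, c(4, 8 / 3, 2))
  expect_equal(acc$curve$pan_sd[1], 0)
})

test_that("pan curves are nondecreasing and core curves nonincreasing on seeded runs", {
  sim <- small_sim()$sim
  pa <- presence_absence(families_from_gene_ids(sim$genomes),
                         sim$truth$strains)
  acc <- accumulation_curves(pa, n_permutations = 20, seed = 5)
  expect_true(all(diff(acc$curve$pan_mean) >= 0))
  expect_true(all(diff(acc$curve$core_mean) <= 0))
  # N = 1 sanity: pan and core coincide at the first genome
  expect_equal(acc$curve$pan_mean[1], acc$curve$core_mean[1])
})

test_that("identical genomes give flat accumulation curves", {
  m <- matrix(1L, 5, 4, dimnames = list(paste0("f", 1:5), paste0("g", 1:4)))
  # degenerate constant curves cannot support the model fits
  acc <- suppressWarnings(accumulation_curves(m))
  expect_equal(acc$curve$pan_mean, rep(5, 4))
  expect_equal(acc$curve$core_mean, rep(5, 4))
})

test_that("new-gene rate averages pan increments over the requested window", {
  fake <- structure(list(curve = data.frame(
    N = 1:4, pan_mean = c(10, 13, 15, 16), pan_sd = 0,
    core_mean = 10, core_sd = 0)), class = "accumulation_curve")
  expect_equal(new_gene_rate(fake, 2, 4), 2)
  flat <- structure(list(curve = data.frame(
    N = 1:4, pan_mean = rep(7, 4), pan_sd = 0, core_mean = 7, core_sd = 0)),
    class = "accumulation_curve")
  expect_equal(new_gene_rate(flat, 2, 4), 0)
  expect_error(new_gene_rate(fake, 1, 4), "window")
  expect_error(new_gene_rate(fake, 2, 5), "window")
})

test_that("late additions contribute fewer new families than early ones in a finite pool", {
  sim <- small_sim()$sim
  pa <- presence_absence(families_from_gene_ids(sim$genomes),
                         sim$truth$strains)
  acc <- accumulation_curves(pa, n_permutations = 30, seed = 2)
  G <- nrow(acc$curve)
  expect_lt(new_gene_rate(acc, G - 1, G), new_gene_rate(acc, 2, 3))
})

test_that("pan-genome comparison counts absent families and rounds the shared percentage", {
  m <- matrix(0L, 10, 3,
              dimnames = list(paste0("f", 1:10), c("g1", "g2", "g3")))
  m[1:7, "g1"] <- 1L
  m[8:10, "g2"] <- 1L
  m[, "g3"] <- 1L
  cmp <- compare_pangenomes(m, "g1")
  expect_equal(cmp$pct_present, 70)
  expect_equal(cmp$n_absent, 3)
  all_in <- compare_pangenomes(m, colnames(m))
  expect_equal(all_in$pct_present, 100)
  expect_equal(all_in$n_absent, 0)
  expect_error(compare_pangenomes(m, character(0)), "empty")
})

test_that("genome summary uses population sd and half-up report rounding", {
  one <- data.frame(genome = "g1", orfs = 2000, genome_size_bp = 2.4e6,
                    gc_pct = 60.1, unique_genes = 3)
  s1 <- genome_summary(one)
  expect_equal(s1$raw$orfs$mean, 2000)
  expect_equal(s1$raw$orfs$sd, 0)
  two <- data.frame(genome = c("a", "b"), orfs = c(10, 20),
                    genome_size_bp = c(1e6, 2e6), gc_pct = c(59.985, 59.985),
                    unique_genes = c(1, 2))
  s2 <- genome_summary(two)
  expect_equal(s2$raw$orfs$sd, 5)         # population sd; sample sd = 7.07
  expect_equal(s2$report$gc_mean, 59.99)  # half-up at 2 decimals
  expect_equal(s2$report$unique_total, 3)
  expect_identical(s2$raw$orfs$which_max, "b")
})

test_that("heatmap export clusters identical genomes first with deterministic leaf order", {
  m <- matrix(0L, 6, 4,
              dimnames = list(paste0("f", 1:6), c("g1", "g2", "g3", "g4")))
  m[, "g1"] <- m[, "g2"] <- c(1L, 1L, 1L, 0L, 0L, 0L)   # identical pair
  m[, "g3"] <- c(1L, 1L, 0L, 1L, 0L, 0L)
  m[, "g4"] <- c(0L, 0L, 0L, 0L, 1L, 1L)                # disjoint profile
  out <- hierarchical_heatmap_export(m)
  expect_equal(out$distance["g1", "g2"], 0)
  # identical genomes merge first
  first <- out$hclust$merge[1, ]
  expect_setequal(out$hclust$labels[-first], c("g1", "g2"))
  # disjoint genome is maximally distant from every other
  expect_true(all(out$distance["g4", c("g1", "g2", "g3")] == 1))
  expect_setequal(colnames(out$ordered_matrix), colnames(m))
  # average-linkage oracle on this toy: d(g3, {g1,g2}) = 0.5,
  # then {g1,g2,g3} vs g4 at height 1
  expect_equal(sort(out$hclust$height),
               c(0, 0.5, 1))
})
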