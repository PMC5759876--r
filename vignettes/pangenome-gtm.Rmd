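---
title: "Methods: pan-genome structure, core-gene supertrees and gene-trait matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome structure, core-gene supertrees and gene-trait matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pangtm` implements a comparative-genomics chain for tens of closely
related bacterial genomes: gene-family clustering, pan-genome structure,
a core-gene consensus supertree, growth-phenotype binarization and
gene-trait matching (GTM). This vignette is the package's account of the
underlying models, the parameters that matter, the numerical choices, and
what the synthetic-data validation does and does not establish.

## Gene families by Markov clustering

The unit of all downstream analysis is the *gene family*: a cluster of
protein-coding genes grouped by sequence similarity. The input is an
all-vs-all protein comparison (BLAST tabular files, or the package's
internal global-identity path for pre-aligned sequence sets). Records are
filtered at **50% identity** and **e-value 1e-4** — the standard stringency
for within-species orthologue clustering — with self-hits removed.
Reciprocal hits collapse into one undirected edge weighted by the larger
bit score (percent identity when bit scores are absent), and genes without
passing hits remain isolated nodes, so the family set always partitions
the full gene complement.

Clustering uses the Markov Cluster Algorithm, implemented in the package
on a dense column-stochastic matrix:

* self-loops set to each node's maximum incident edge weight (1 for
  isolated nodes), the canonical stabilizer;
* iterate expansion (matrix squaring) and inflation (elementwise power
  **2.5**, then column renormalization);
* prune entries below 1e-5 with renormalization;
* converge when the maximum absolute matrix change falls below 1e-6, with
  a 200-iteration cap that raises an explicit error rather than returning
  a half-converged clustering.

Clusters are read off the limit matrix as attractor systems; a node
attracted to more than one system is assigned to the one holding the
larger share of its column mass, ties resolved toward the
lexicographically smallest cluster label, so the output is deterministic.
The inflation exponent controls granularity: 2.5 separates families that a
weak bridge edge would otherwise merge (the barbell test), while never
splitting a clean clique. The test suite checks equality with an
independently written dense reference implementation on dozens of seeded
random graphs.

No alignment-coverage threshold is applied by default: the similarity
filter is exactly identity + e-value. Callers who want a coverage filter
can pre-filter the record table; we chose not to add one silently because
it changes family boundaries in ways the stated thresholds do not imply.

## Pan-genome structure

From the family-by-genome presence/absence matrix:

* **core** families occur at least once in every genome;
* **unique** families (truly unique genes, TUGs) occur in exactly one;
* the **shared dispensable** set is the remainder.

Reports also quote the *variable genome* — everything non-core, unique
genes included — because that aggregate is what pan-genome studies
conventionally print next to the core count. Accumulation curves add
genomes in random order: `pan(N)` is the union size after `N` genomes and
`core(N)` the intersection size. When `G! ≤ 5040` every ordering is
enumerated, making toy expectations exact; otherwise 100 seeded orderings
are sampled (means are reported with population standard deviations).
The fitted forms are the field's standard choices for asymptotic trends —
a Heaps-type power law `P(N) = κ·N^γ` for the pan curve and an exponential
decay `C(N) = Ω + A·exp(−N/τ)` for the core curve — fitted by
Levenberg–Marquardt least squares on the permutation means, started from a
log–log linear fit and from the observed range respectively. Degenerate
curves (e.g. identical genomes) make these models unidentifiable; the fit
is then skipped with a warning rather than forced. On simulated matrices
with 20 genomes and a 400-family core, the fitted `Ω` lands within about
1% of the true core size; the acceptance checks require 5%.

`genome_summary()` follows report-table conventions: population (divisor
*n*) standard deviation, and half-up rounding (ORFs to integers, GC% and
Mbp to two decimals). These conventions are what reproduce printed values
such as a GC mean of 59.99% from a raw mean of 59.985 and an ORF standard
deviation of 107 where the sample estimator would give 110. The genome
dendrogram uses Jaccard distance between binary family profiles with
average linkage; columns are pre-sorted by genome id so equal-distance
ties resolve deterministically.

## Core-gene consensus supertree

Families passing the single-copy filter (exactly one member in every
genome) provide per-family alignments. Each family yields a
neighbor-joining tree on p-distances (proportion of differing sites,
ambiguity columns excluded). Negative NJ branch lengths are clamped to
zero with the deficit subtracted from the sister edge, preserving path
lengths through the node.

The supertree is the **strict majority-rule consensus**: exactly the
bipartitions present in more than half of the family trees, with support
equal to the percentage of trees containing the clade and branch lengths
averaged over those trees. We implement the consensus directly from clade
counts (every tree is first anchored at a common reference leaf so rooted
clades correspond one-to-one to unrooted bipartitions); the plain rule is
the default because the extended variant adds minority clades whose
interpretation under topological conflict is murkier, and the threshold is
exposed for callers who want a stricter consensus. The tree is finally
rooted at the midpoint of the branch leading to the designated outgroup.

Distance-based NJ replaces likelihood tree inference deliberately: at the
within-species divergences this package targets, the signal carried into
the consensus is topological, and p-distances on the package's alignments
are exact. The package makes no claim of likelihood-equivalence; users
with deep divergences should build family trees externally and feed them
to `majority_consensus()`.

## Growth phenotyping

Growth on a carbon source is read from the 12-h OD600 (the time point is
configurable): *good* above 0.5, *moderate* in [0.4, 0.5], *none* below
0.4. Binarization for matching assigns 0 below 0.3 and 1 above 0.4.
These two conventions leave a gap: readings in [0.3, 0.4] are neither
clear growth nor clear absence. The package refuses to guess — such calls
are **indeterminate** (`NA` in the matrix), counted and reported. For
matching they are treated as 0 by default (`indeterminate = "as_zero"`);
the `"strict"` policy instead removes those strains from both numerator
and denominator of the affected cell. No negative-control subtraction is
applied: the raw 12-h OD is used. The control carbohydrate (lactose, on
which all strains grow) is retained in the matrix as a positive control
but excluded from matching.

Only carbohydrates with a *differential* profile — at least one 0 and one
1 across strains — enter GTM; all-grow and all-no-grow rows carry no
genotype signal.

## Gene-trait matching

The genotype matrix starts from the presence/absence matrix, drops core
families, and drops families whose representative annotation (most
frequent member annotation, ties lexicographic) contains any exclusion
keyword — by default `transposase, integrase, phage, prophage,
restriction, methyltransferase, CRISPR, mobile element`, a configurable
list covering mobile elements and defence systems that co-vary with
strains without explaining carbon-source phenotypes. Unannotated families
are retained and flagged rather than silently dropped. Families with
identical occurrence vectors collapse into one *pattern* row.

The match between a pattern row and a phenotype row is the percentage of
strains at which the two binary vectors agree; 0–0 agreements count as
matches, since shared absence is as informative as shared presence under
this scoring. Hits use **strictly greater than 95%**: with 20 strains a
single disagreeing strain gives exactly 19/20 = 95% and is excluded — the
suite asserts this boundary. Partial matches down to 75% are reported
separately, ranked, since near-misses (one incongruent strain) are often
biologically interesting. An inverse association (gene absence with
growth) is not mixed into the hit list; only direct matches are scored.

## The synthetic pan-genome

The simulator generates the statistical structure the analysis assumes,
with ground truth for recovery testing:

* **Defaults** (chosen once as a realistic within-species study): 20
  strains; 400 core families; 600 dispensable families carried with
  per-family probability uniform in (0.15, 0.85), redrawn until neither
  universal nor absent; 0–24 unique genes per strain; 4 planted trait
  clusters of 4–10 families, carrier fraction 0.5; proteins of 250
  residues; per-branch per-site substitution probability 0.01 on a random
  bifurcating species tree, outgroup branch stretched threefold.
* With 0.01 per-site substitution over 250 sites, every branch expects
  ~2.5 substitutions, so each internal branch leaves signal in most gene
  trees (the probability of a signal-free branch in one family is
  `0.99^250 ≈ 0.08`), which is what makes the 20-family consensus recover
  the generating topology exactly; within-family identity stays above
  ~90%, far above the 55% margin over the clustering threshold, while
  random ancestral sequences keep between-family identity near 5%.
* Sequences are emitted **pre-aligned**: equal length within (indeed
  across) families, substitutions only. This removes aligner behaviour
  from every test — identities and p-distances are exact — at the cost of
  realism (no indels, no domain shuffling, no length variation).
* Planted clusters take over disjoint sets of dispensable families and
  receive exactly the cluster's carrier set as carriage. Carrier sets are
  redrawn until distinct from each other and from every background
  carriage vector, so pattern recovery is structural, not probabilistic:
  precision and recall 1.0 are the forced outcome when the chain is
  correct, and any failure indicates a real defect.
* Phenotype noise flips the binary growth call (never the lactose
  control); OD measurement noise is separate Gaussian noise (sd 0.02,
  truncated at 0) on the curve values. Keeping the two apart lets tests
  attribute disagreements: flipped calls are recorded and the suite
  replays the documented seeded stream to confirm them. Grower and
  non-grower 12-h ODs are drawn from (0.55, 0.9) and (0.05, 0.25), so
  noiseless binarization is unambiguous by construction.
* Gene ids are `"<strain>|<family>|<serial>"`, making truth recovery
  lookup-free; each output stream derives its own sub-seed from the
  master seed, so outputs are byte-identical across runs and individual
  files can be regenerated stably.

What passing recovery tests shows: the chain of clustering, partitioning,
binarization, collapsing and matching is internally correct and
deterministic. What it does not show: robustness to annotation errors,
fragmented assemblies, paralogue inflation, indel-rich alignments, or
phenotype structure that violates the one-cluster-per-carbohydrate
assumption — real data have all of these, and results there depend on the
quality of the inputs in ways the simulator does not emulate.

## Problem sizes and costs

The test suite runs at desk scale by design: MCL oracle comparisons on
graphs of at most 30 nodes, clustering-from-sequences on a few hundred
genes, recovery checks on the 20-strain default simulation, supertrees
from 25 families, pipeline determinism on 8–10 strains. The all-vs-all
identity path is quadratic in gene count and intended for validation-scale
inputs; production-scale family construction should ingest precomputed
BLAST tabular files. Full-suite runtime is well under a minute on one
CPU; the acceptance script takes a few seconds.

## Known limitations

* E-values are not computed on the internal identity path (reported as 0);
  filtering there rests on the identity threshold alone.
* The consensus carries mean branch lengths, which are descriptive, not
  model-based estimates.
* `compare_pangenomes()` assumes the subset's families were called on the
  same clustering as the full set; comparing independently clustered
  pan-genomes requires mapping families first.
* GTM is exact pattern matching, not association testing: no p-values, no
  phylogenetic correction, and a single discordant strain removes a hit
  (by design, per the strict threshold).
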