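# All-vs-all protein similarity: filtering BLAST-style records and building
# the undirected weighted graph that feeds the Markov clustering step.

#' Percent identity between two proteins
#'
#' Global (Needleman-Wunsch) alignment with identity scoring and a linear gap
#' penalty; percent identity is 100 * matches / alignment length (gap columns
#' included). This is the in-repo stand-in for a BLASTP hit when no tabular
#' similarity file is supplied; the e-value of the returned record is 0, so
#' filtering on this path relies on the identity threshold.
#'
#' @param seq_a,seq_b protein sequences (single strings, standard amino-acid
#'   alphabet).
#' @param query,subject ids recorded in the result.
#' @return one-row data.frame with columns query, subject, pct_identity,
#'   evalue, bitscore, aln_len.
#' @export
pairwise_identity <- function(seq_a, seq_b, query = "a", subject = "b") {
  check_protein(seq_a); check_protein(seq_b)
  if (nchar(seq_a) == nchar(seq_b)) {
    # equal lengths: the identity-scored global alignment never pays for a
    # gap, so positional comparison is exact
    a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
    nmatch <- sum(a == b); alen <- length(a)
  } else {
    alpha <- Biostrings::AA_ALPHABET
    mat <- diag(1, length(alpha))
    dimnames(mat) <- list(alpha, alpha)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 0.5)
    nmatch <- Biostrings::nmatch(aln)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  }
  data.frame(query = query, subject = subject,
             pct_identity = 100 * nmatch / alen,
             evalue = 0, bitscore = nmatch, aln_len = alen,
             stringsAsFactors = FALSE)
}

check_protein <- function(s) {
  if (!is.character(s) || length(s) != 1 || nchar(s) == 0)
    stop_input("sequences must be non-empty single strings")
  if (grepl(sprintf("[^%s]", paste(Biostrings::AA_ALPHABET[1:26],
                                   collapse = "")), s))
    stop_input("non-amino-acid characters in sequence")
  invisible(s)
}

#' All-vs-all percent identity for equal-length protein sets
#'
#' Vectorized identity computation for sequence sets in which all sequences
#' share one length (e.g. simulator output, which is emitted pre-aligned).
#' Returns records for ordered pairs with identity above `report_min`
#' (self-hits excluded), mirroring a thresholded all-vs-all search.
#'
#' @param seqs named character vector of equal-length protein sequences.
#' @param report_min report only pairs with percent identity >= this value
#'   (keeps the record list near-linear in the number of genes).
#' @return data.frame of similarity records (see [pairwise_identity()]).
#' @export
all_vs_all_identity <- function(seqs, report_min = 30) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_input("seqs must be uniquely named")
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop_input("all_vs_all_identity requires equal-length sequences")
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  counts <- matrix(0, n, n)
  for (a in unique(as.vector(chars))) {
    ind <- chars == a
    counts <- counts + tcrossprod(ind)
  }
  pid <- 100 * counts / L
  keep <- which(upper.tri(pid) & pid >= report_min, arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(query = character(0), subject = character(0),
                      pct_identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), aln_len = numeric(0)))
  data.frame(query = names(seqs)[keep[, 1]],
             subject = names(seqs)[keep[, 2]],
             pct_identity = pid[keep],
             evalue = 0, bitscore = counts[keep], aln_len = L,
             stringsAsFactors = FALSE)
}

#' Filter similarity records
#'
#' Retains records with percent identity at or above `min_identity` and
#' e-value at or below `max_evalue`; self-hits (query == subject) are always
#' removed. Input order is preserved.
#'
#' @param records data.frame of similarity records with columns query,
#'   subject, pct_identity, evalue.
#' @param min_identity minimum percent identity (default 50).
#' @param max_evalue maximum e-value (default 1e-4).
#' @return the retained records.
#' @export
filter_similarities <- function(records, min_identity = 50,
                                max_evalue = 1e-4) {
  if (min_identity < 0 || min_identity > 100)
    stop_input("min_identity must be in [0, 100]")
  if (max_evalue < 0) stop_input("max_evalue must be >= 0")
  keep <- records$pct_identity >= min_identity &
    records$evalue <= max_evalue &
    records$query != records$subject
  records[keep, , drop = FALSE]
}

#' Build the similarity graph
#'
#' Undirected weighted graph over all genes. Reciprocal hits collapse into a
#' single edge whose weight is the larger of the two bit scores (falling back
#' to percent identity where bit scores are absent); genes with no passing
#' hits remain as isolated nodes.
#'
#' @param records filtered similarity records.
#' @param all_genes character vector of every gene id under analysis.
#' @return list of class `similarity_graph` with elements `nodes` (character)
#'   and `edges` (data.frame from, to, weight).
#' @export
build_graph <- function(records, all_genes) {
  if (anyDuplicated(all_genes)) stop_input("duplicate gene ids in all_genes")
  unknown <- setdiff(unique(c(records$query, records$subject)), all_genes)
  if (length(unknown))
    stop_input("similarity records reference gene(s) not in all_genes: %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  if (nrow(records)) {
    w <- if (!is.null(records$bitscore) && !all(is.na(records$bitscore)))
      records$bitscore else records$pct_identity
    a <- pmin(records$query, records$subject)
    b <- pmax(records$query, records$subject)
    key <- paste(a, b, sep = "\r")
    wmax <- tapply(w, key, max)
    ab <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        weight = as.numeric(wmax), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  if (any(edges$weight <= 0)) stop_input("edge weights must be positive")
  structure(list(nodes = sort(all_genes), edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
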