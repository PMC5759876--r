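# Gene-trait matching: filter the genotype matrix, collapse identical
# occurrence patterns, score genotype rows against phenotype rows by
# position-wise agreement, and report candidate gene clusters.

#' Default annotation-exclusion keywords
#'
#' Case-insensitive substrings flagging gene functions not involved in
#' carbon-source utilization (mobile elements, restriction/modification,
#' CRISPR, prophages), removed from the genotype matrix before matching.
#' @export
DEFAULT_EXCLUSION_KEYWORDS <- c(
  "transposase", "integrase", "phage", "prophage", "restriction",
  "methyltransferase", "crispr", "mobile element")

#' Build the filtered genotype matrix
#'
#' Starting from the family presence/absence matrix: drops core families
#' (present in all strains, hence uninformative for trait matching) and
#' families whose representative annotation matches any exclusion keyword
#' (case-insensitive substring). The representative annotation of a family
#' is its most frequent member annotation, ties broken lexicographically;
#' families with no annotated member are retained and flagged.
#'
#' @param matrix presence/absence matrix from [presence_absence()].
#' @param families the `family_set` behind `matrix` (links gene ids to
#'   families).
#' @param annotations data.frame (gene_id, func).
#' @param exclusion_keywords character vector of keywords (default
#'   [DEFAULT_EXCLUSION_KEYWORDS]).
#' @return binary integer matrix (families x strains) with attributes
#'   `annotation` (named representative annotation per retained family),
#'   `unannotated` (flagged family ids), `n_dropped_core`,
#'   `n_dropped_excluded`.
#' @export
build_genotype_matrix <- function(matrix, families, annotations,
                                  exclusion_keywords =
                                    DEFAULT_EXCLUSION_KEYWORDS) {
  bin <- (matrix > 0) * 1L
  core <- rownames(bin)[rowSums(bin) == ncol(bin)]
  keep <- setdiff(rownames(bin), core)

  ann <- annotations$func[match(families$gene_id, annotations$gene_id)]
  rep_ann <- vapply(split(ann, families$family_id), function(a) {
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_character_)
    tab <- sort(table(a), decreasing = TRUE)
    best <- names(tab)[tab == tab[1]]
    sort(best)[1]
  }, character(1))

  excl <- vapply(keep, function(f) {
    a <- rep_ann[[f]] %||% NA_character_
    !is.na(a) && any(vapply(exclusion_keywords, grepl, logical(1),
                            x = a, ignore.case = TRUE, fixed = FALSE))
  }, logical(1))
  retained <- keep[!excl]
  out <- bin[retained, , drop = FALSE]
  attr(out, "annotation") <- rep_ann[retained]
  attr(out, "unannotated") <- retained[is.na(rep_ann[retained])]
  attr(out, "n_dropped_core") <- length(core)
  attr(out, "n_dropped_excluded") <- sum(excl)
  out
}

#' Collapse families with identical occurrence patterns
#'
#' Families sharing one presence/absence vector across strains are grouped
#' into a single genotype pattern row; the genotype matrix rows are the
#' distinct occurrence patterns. Pattern ids are assigned in order of
#' decreasing carrier count, then lexicographic pattern, for determinism.
#'
#' @param filtered binary matrix from [build_genotype_matrix()].
#' @return list of class `genotype_patterns`: `patterns` (binary matrix
#'   pattern x strain), `members` (pattern -> family ids), `annotations`
#'   (pattern -> member annotations, when present on the input).
#' @export
collapse_patterns <- function(filtered) {
  if (nrow(filtered) == 0)
    stop_input("no families left to collapse")
  key <- apply(filtered, 1, paste, collapse = "")
  groups <- split(rownames(filtered), key)
  ord <- order(-vapply(names(groups), function(k)
    sum(as.integer(strsplit(k, "")[[1]])), numeric(1)),
    names(groups), method = "radix", decreasing = FALSE)
  groups <- groups[ord]
  pat_ids <- sprintf("P%04d", seq_along(groups))
  pat <- do.call(rbind, lapply(names(groups), function(k)
    as.integer(strsplit(k, "")[[1]])))
  dimnames(pat) <- list(pat_ids, colnames(filtered))
  members <- stats::setNames(lapply(groups, sort), pat_ids)
  fam_ann <- attr(filtered, "annotation")
  anns <- if (!is.null(fam_ann))
    stats::setNames(lapply(members, function(f) fam_ann[f]), pat_ids)
  structure(list(patterns = pat, members = members, annotations = anns),
            class = "genotype_patterns")
}

#' @export
print.genotype_patterns <- function(x, ...) {
  cat(sprintf("Genotype patterns: %d distinct occurrence patterns over %d strains (%d families)\n",
              nrow(x$patterns), ncol(x$patterns),
              sum(lengths(x$members))))
  invisible(x)
}

#' Matching percentage between a genotype row and a phenotype row
#'
#' 100 times the fraction of strains at which the binary genotype equals the
#' binary phenotype (both 1-1 and 0-0 agreements count). Indeterminate
#' phenotype calls (`NA`) are handled per policy: `"as_zero"` (default)
#' scores them as phenotype 0; `"strict"` drops those strains from numerator
#' and denominator.
#'
#' @param genotype_row binary vector.
#' @param phenotype_row vector of 0/1/`NA`, same length and strain order.
#' @param indeterminate policy, `"as_zero"` or `"strict"`.
#' @return list(percent, n_compared, n_indeterminate).
#' @export
match_percentage <- function(genotype_row, phenotype_row,
                             indeterminate = c("as_zero", "strict")) {
  indeterminate <- match.arg(indeterminate)
  if (length(genotype_row) != length(phenotype_row))
    stop_input("genotype and phenotype rows differ in length (%d vs %d)",
               length(genotype_row), length(phenotype_row))
  ind <- is.na(phenotype_row)
  if (indeterminate == "as_zero") {
    ph <- ifelse(ind, 0L, phenotype_row)
    n <- length(ph)
    pct <- 100 * sum(genotype_row == ph) / n
  } else {
    ph <- phenotype_row[!ind]
    gt <- genotype_row[!ind]
    n <- length(ph)
    pct <- if (n == 0) NA_real_ else 100 * sum(gt == ph) / n
  }
  list(percent = pct, n_compared = n, n_indeterminate = sum(ind))
}

#' Match every genotype pattern against every phenotype row
#'
#' @param genotype a `genotype_patterns` object.
#' @param phenotype a phenotype matrix (carbohydrates x strains), usually
#'   restricted to [select_differential()] carbohydrates.
#' @param indeterminate policy passed to [match_percentage()].
#' @return list of class `match_result`: `percent` (pattern x carbohydrate),
#'   `n_compared`, `n_indeterminate`, `genotype`, `indeterminate` (policy).
#' @export
match_all <- function(genotype, phenotype,
                      indeterminate = c("as_zero", "strict")) {
  indeterminate <- match.arg(indeterminate)
  gstr <- colnames(genotype$patterns)
  pstr <- colnames(phenotype)
  if (!setequal(gstr, pstr))
    stop_input("strain sets differ (only in genotype: %s; only in phenotype: %s)",
               paste(setdiff(gstr, pstr), collapse = ",") ,
               paste(setdiff(pstr, gstr), collapse = ","))
  ph <- phenotype[, gstr, drop = FALSE]
  pct <- nc <- ni <- matrix(
    NA_real_, nrow(genotype$patterns), nrow(ph),
    dimnames = list(rownames(genotype$patterns), rownames(ph)))
  for (p in rownames(genotype$patterns)) {
    for (cb in rownames(ph)) {
      m <- match_percentage(genotype$patterns[p, ], ph[cb, ], indeterminate)
      pct[p, cb] <- m$percent
      nc[p, cb] <- m$n_compared
      ni[p, cb] <- m$n_indeterminate
    }
  }
  structure(list(percent = pct, n_compared = nc, n_indeterminate = ni,
                 genotype = genotype, indeterminate = indeterminate),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Gene-trait match: %d patterns x %d carbohydrates (policy: %s)\n",
              nrow(x$percent), ncol(x$percent), x$indeterminate))
  cat(sprintf("  best match %.1f%%, %d cells above 95%%\n",
              max(x$percent, na.rm = TRUE),
              sum(x$percent > 95, na.rm = TRUE)))
  invisible(x)
}

#' Report gene-trait matching hits
#'
#' Hits are (pattern, carbohydrate) cells with matching percentage strictly
#' greater than `threshold` (so with 20 strains only perfect 20/20 agreement
#' exceeds 95). Each hit lists the member families with their annotations --
#' the candidate carbohydrate-utilization gene cluster. Partial matches (the
#' remaining cells) are returned ranked by percentage.
#'
#' @param result a [match_all()] result.
#' @param threshold percent threshold, default 95; strictly-greater
#'   semantics.
#' @param partial_min lowest matching percentage retained in the ranked
#'   partial-match list (default 75).
#' @return list of class `gtm_report`: `hits` and `partial` data.frames
#'   (carbohydrate, pattern, percent, n_compared, families, annotations),
#'   `threshold`.
#' @export
report_hits <- function(result, threshold = 95, partial_min = 75) {
  cells <- expand.grid(pattern = rownames(result$percent),
                       carbohydrate = colnames(result$percent),
                       stringsAsFactors = FALSE)
  if (nrow(cells) == 0) {
    empty <- data.frame(carbohydrate = character(0), pattern = character(0),
                        percent = numeric(0), n_compared = numeric(0),
                        families = character(0), annotations = character(0))
    return(structure(list(hits = empty, partial = empty,
                          threshold = threshold), class = "gtm_report"))
  }
  cells$percent <- result$percent[as.matrix(cells[, c("pattern",
                                                      "carbohydrate")])]
  cells$n_compared <- result$n_compared[as.matrix(cells[, c("pattern",
                                                            "carbohydrate")])]
  mem <- result$genotype$members
  ann <- result$genotype$annotations
  cells$families <- vapply(cells$pattern, function(p)
    paste(mem[[p]], collapse = ";"), character(1))
  cells$annotations <- vapply(cells$pattern, function(p) {
    if (is.null(ann)) return(NA_character_)
    paste(ann[[p]], collapse = ";")
  }, character(1))
  cells <- cells[, c("carbohydrate", "pattern", "percent", "n_compared",
                     "families", "annotations")]
  hits <- cells[!is.na(cells$percent) & cells$percent > threshold, ,
                drop = FALSE]
  hits <- hits[order(hits$carbohydrate, -hits$percent, hits$pattern), ,
               drop = FALSE]
  partial <- cells[!is.na(cells$percent) & cells$percent <= threshold &
                     cells$percent >= partial_min, , drop = FALSE]
  partial <- partial[order(-partial$percent, partial$carbohydrate,
                           partial$pattern), , drop = FALSE]
  rownames(hits) <- rownames(partial) <- NULL
  structure(list(hits = hits, partial = partial, threshold = threshold),
            class = "gtm_report")
}

#' @export
print.gtm_report <- function(x, ...) {
  cat(sprintf("Gene-trait matching report (> %g%% rule): %d hit(s)\n",
              x$threshold, nrow(x$hits)))
  for (i in seq_len(nrow(x$hits))) {
    h <- x$hits[i, ]
    cat(sprintf("  %s <- pattern %s (%.1f%% of %d strains)\n",
                h$carbohydrate, h$pattern, h$percent, h$n_compared))
    fams <- strsplit(h$families, ";")[[1]]
    anns <- strsplit(h$annotations, ";")[[1]]
    for (k in seq_along(fams))
      cat(sprintf("      %s  %s\n", fams[k],
                  if (k <= length(anns)) anns[k] else ""))
  }
  if (nrow(x$partial))
    cat(sprintf("  plus %d partial match(es), best %.1f%%\n",
                nrow(x$partial), max(x$partial$percent)))
  invisible(x)
}
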