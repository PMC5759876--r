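# Gene family sets: the partition of all genes into families, each family
# mapping genome -> member gene ids.

#' Construct a family set
#'
#' A family set is a long-format data.frame (family_id, genome_id, gene_id)
#' carrying the partition of genes into families, plus a provenance list of
#' the parameters that produced it. Every gene belongs to exactly one family.
#'
#' @param df data.frame with columns family_id, genome_id, gene_id.
#' @param provenance named list of parameters recorded with the set.
#' @return data.frame of class `family_set`.
#' @export
family_set <- function(df, provenance = list()) {
  need <- c("family_id", "genome_id", "gene_id")
  if (!all(need %in% names(df)))
    stop_input("family set needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop_input("gene(s) assigned to more than one family: %s",
               paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 3),
                     collapse = ", "))
  if (nrow(df) == 0) stop_input("family set has no genes")
  df <- df[order(df$family_id, df$genome_id, df$gene_id), need]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("family_set", "data.frame"))
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("Family set: %d families, %d genes, %d genomes\n",
              length(unique(x$family_id)), nrow(x),
              length(unique(x$genome_id))))
  prov <- attr(x, "provenance")
  if (length(prov))
    cat("Provenance:", paste(names(prov),
                             vapply(prov, function(p)
                               paste(format(p), collapse = ","),
                               character(1)),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Extract single-copy families
#'
#' Keeps families represented by exactly one gene in every listed genome:
#' present everywhere and never duplicated, the usual paralogue filter before
#' building per-family trees.
#'
#' @param families a `family_set`.
#' @param genome_ids genomes that must each contribute exactly one member.
#' @return the filtered `family_set`.
#' @export
extract_single_copy <- function(families, genome_ids) {
  tab <- table(families$family_id, families$genome_id)
  if (!all(genome_ids %in% colnames(tab)))
    tab <- cbind(tab, matrix(0, nrow(tab),
                             length(setdiff(genome_ids, colnames(tab))),
                             dimnames = list(NULL,
                                             setdiff(genome_ids,
                                                     colnames(tab)))))
  ok <- rownames(tab)[apply(tab[, genome_ids, drop = FALSE] == 1, 1, all)]
  keep <- families[families$family_id %in% ok &
                     families$genome_id %in% genome_ids, , drop = FALSE]
  if (nrow(keep) == 0)
    stop_input("no single-copy families across the %d genomes",
               length(genome_ids))
  family_set(keep, provenance = c(attr(families, "provenance"),
                                  list(single_copy = TRUE)))
}

#' Write / read a family set as TSV
#'
#' Tab-separated columns family_id, genome_id, gene_id; provenance is written
#' alongside as JSON.
#'
#' @param families a `family_set`.
#' @param path TSV path; provenance goes to `<path>.provenance.json`.
#' @return invisibly, `path`.
#' @export
write_families <- function(families, path) {
  utils::write.table(as.data.frame(families), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prov <- attr(families, "provenance")
  if (length(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_families
#' @export
read_families <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  provp <- paste0(path, ".provenance.json")
  prov <- if (file.exists(provp)) jsonlite::read_json(provp) else list()
  family_set(df, provenance = prov)
}
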