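# Readers and writers for the external formats: protein FASTA, BLAST
# tabular (outfmt 6), TSV matrices and long-format growth-curve CSV.

#' Read a protein FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences (possibly empty). Duplicate
#'   ids or malformed records raise an error with the offending line number.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  hdr <- grepl("^>", lines)
  if (!hdr[1] && any(nzchar(trimws(lines))))
    stop_input("%s: line %d: sequence before first header", path,
               which(nzchar(trimws(lines)))[1])
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop_input("%s: line %d: empty FASTA header", path,
               which(hdr)[!nzchar(ids)][1])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_input("%s: line %d: duplicate FASTA id '%s'", path,
               which(hdr)[which(ids == dup)[2]], dup)
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  out <- stats::setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- gsub("\\s", "", seqs)
  names(out) <- ids
  out
}

#' Write a protein FASTA file
#'
#' Canonical formatting: 60 residues per line, Unix newlines; a write/read
#' round trip is byte-stable.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop_input("sequences must have unique names")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con, sep = "\n")
    s <- seqs[[id]]
    starts <- seq(1, max(nchar(s), 1), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con,
               sep = "\n")
  }
  invisible(path)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Twelve tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore); lines starting
#' with `#` are skipped. Any other column count raises an error with the
#' line number.
#'
#' @param path TSV path.
#' @return data.frame of similarity records with columns query, subject,
#'   pct_identity, aln_len, evalue, bitscore (plus the remaining outfmt-6
#'   coordinates).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- lengths(parts) != 12
  if (any(bad))
    stop_input("%s: line %d: expected 12 tab-separated columns, found %d",
               path, idx[bad][1], lengths(parts)[bad][1])
  if (!length(parts))
    return(data.frame(query = character(0), subject = character(0),
                      pct_identity = numeric(0), aln_len = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  m <- do.call(rbind, parts)
  data.frame(query = m[, 1], subject = m[, 2],
             pct_identity = as.numeric(m[, 3]),
             aln_len = as.numeric(m[, 4]),
             mismatch = as.numeric(m[, 5]), gapopen = as.numeric(m[, 6]),
             qstart = as.numeric(m[, 7]), qend = as.numeric(m[, 8]),
             sstart = as.numeric(m[, 9]), send = as.numeric(m[, 10]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             stringsAsFactors = FALSE)
}

#' Read a long-format growth-curve CSV
#'
#' Expects columns strain, carbohydrate, time_h, od600.
#'
#' @param path CSV path.
#' @return data.frame of growth curves.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "carbohydrate", "time_h", "od600")
  if (!all(need %in% names(df)))
    stop_input("%s: growth CSV needs columns %s", path,
               paste(need, collapse = ", "))
  if (any(df$od600 < 0)) stop_input("%s: negative OD600 values", path)
  df
}

#' Write / read a named matrix as TSV
#'
#' Tab-separated, row names in the first column (`id`), UTF-8, Unix
#' newlines.
#'
#' @param m matrix with dimnames.
#' @param path TSV path.
#' @return invisibly `path` (write); the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
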