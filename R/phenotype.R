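# OD600 growth phenotyping: categorical growth calls at 12 h and the binary
# phenotype matrix consumed by gene-trait matching.

#' Categorize growth from the 12 h OD600
#'
#' Good growth above 0.5 OD600, moderate between 0.4 and 0.5 (inclusive),
#' none below 0.4 -- the cut-off separating strains unable to grow on a
#' carbon source.
#'
#' @param od12 OD600 value(s) at 12 h, non-negative.
#' @return character vector in {"good", "moderate", "none"}.
#' @export
categorize_growth <- function(od12) {
  if (any(od12 < 0)) stop_input("OD600 cannot be negative")
  ifelse(od12 > 0.5, "good", ifelse(od12 >= 0.4, "moderate", "none"))
}

#' Binarize a 12 h OD600 into a growth call
#'
#' 0 below 0.3 OD600, 1 above 0.4; readings in the gap [0.3, 0.4] fall
#' between the no-growth and growth bounds and are returned as `NA`
#' (indeterminate). Downstream matching treats indeterminate calls as 0 by
#' default and reports their count; a strict policy can exclude them
#' entirely (see [match_percentage()]).
#'
#' @param od12 OD600 value(s) at 12 h, non-negative.
#' @return integer vector of 0, 1 or `NA` (indeterminate).
#' @export
binarize_phenotype <- function(od12) {
  if (any(od12 < 0)) stop_input("OD600 cannot be negative")
  ifelse(od12 < 0.3, 0L, ifelse(od12 > 0.4, 1L, NA_integer_))
}

#' Build the binary phenotype matrix
#'
#' Applies [binarize_phenotype()] to the 12 h reading of every (strain,
#' carbohydrate) growth curve. Rows (carbohydrates) and columns (strains)
#' are sorted; the control carbohydrate, when present, is flagged via the
#' `"control"` attribute and excluded from matching by default.
#'
#' @param curves long-format data.frame (strain, carbohydrate, time_h,
#'   od600).
#' @param time_h evaluation time point (default 12).
#' @param control control carbohydrate name (default "lactose").
#' @return integer matrix carbohydrates x strains with entries 0/1/`NA` and
#'   attributes `control` and `call_log` (per-pair category and raw OD).
#' @export
build_phenotype_matrix <- function(curves, time_h = 12, control = "lactose") {
  at <- curves[curves$time_h == time_h, , drop = FALSE]
  strains <- sort(unique(curves$strain))
  carbs <- sort(unique(curves$carbohydrate))
  key <- paste(at$carbohydrate, at$strain, sep = "\r")
  want <- expand.grid(strain = strains, carbohydrate = carbs,
                      stringsAsFactors = FALSE)
  wkey <- paste(want$carbohydrate, want$strain, sep = "\r")
  miss <- !wkey %in% key
  if (any(miss))
    stop_input("missing %g h reading for: %s", time_h,
               paste(utils::head(gsub("\r", " / ", wkey[miss]), 5),
                     collapse = "; "))
  od <- at$od600[match(wkey, key)]
  # expand.grid varies strain fastest: columns of the reshape are carbs
  m <- t(matrix(binarize_phenotype(od), nrow = length(strains),
                ncol = length(carbs)))
  dimnames(m) <- list(carbs, strains)
  attr(m, "control") <- if (control %in% carbs) control else NULL
  attr(m, "call_log") <- data.frame(
    carbohydrate = want$carbohydrate, strain = want$strain, od600 = od,
    category = categorize_growth(od),
    call = binarize_phenotype(od), stringsAsFactors = FALSE)
  class(m) <- c("phenotype_matrix", class(m))
  m
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("Phenotype matrix: %d carbohydrates x %d strains (%d indeterminate calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  if (!is.null(attr(x, "control")))
    cat("Control carbohydrate:", attr(x, "control"), "\n")
  print(unclass(x)[, seq_len(min(ncol(x), 10)), drop = FALSE])
  invisible(x)
}

#' Select carbohydrates with a differential utilization profile
#'
#' Keeps carbohydrates whose growth-call row contains at least one 0 and at
#' least one 1 (indeterminate calls are ignored for the criterion); all-grow
#' and all-no-grow rows carry no genotype-matching signal and are excluded,
#' as is the control carbohydrate.
#'
#' @param matrix a [build_phenotype_matrix()] result.
#' @param drop_control drop the flagged control row (default TRUE).
#' @return character vector of carbohydrate names.
#' @export
select_differential <- function(matrix, drop_control = TRUE) {
  carbs <- rownames(matrix)[apply(matrix, 1, function(r)
    any(r == 0, na.rm = TRUE) && any(r == 1, na.rm = TRUE))]
  if (drop_control && !is.null(attr(matrix, "control")))
    carbs <- setdiff(carbs, attr(matrix, "control"))
  carbs
}
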