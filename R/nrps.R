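# NRPS adenylation-domain records: per-module binding-pocket signature
# codes, the amino acids predicted by two substrate predictors, and the
# amino acids actually detected in the products.

#' Read an NRPS module table
#'
#' TSV columns: `species`, `position` (1-20), `signature` (8-letter
#' binding-pocket code over the amino-acid alphabet plus `-`),
#' `predicted_a`, `predicted_b`, `detected` (semicolon-separated token
#' sets; `predicted_b` may be empty).  Lowercase predictor tokens are
#' parsed case-insensitively but flagged as low confidence.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return A data.frame with list-columns `predicted_a`, `predicted_b`,
#'   `detected` (character vectors) and `low_confidence_b` (logical).
#' @export
read_nrps_table <- function(path = peptaibol_fixture("nrps")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("species", "position", "signature", "predicted_a",
                  "predicted_b", "detected") %in% names(tab)))
  tab$position <- as.integer(tab$position)
  bad <- nchar(tab$signature) != 8L
  if (any(bad)) {
    stop(sprintf("signature of %s position %d is not 8 characters",
                 tab$species[bad][1L], tab$position[bad][1L]), call. = FALSE)
  }
  split_set <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, ";", fixed = TRUE)[[1L]]
  }
  cap <- function(tok) paste0(toupper(substr(tok, 1, 1)), substring(tok, 2))
  tab$low_confidence_b <- vapply(tab$predicted_b, function(x) {
    any(grepl("^[a-z]", split_set(x)))
  }, TRUE)
  tab$predicted_a <- lapply(tab$predicted_a, function(x) cap(split_set(x)))
  tab$predicted_b <- lapply(tab$predicted_b, function(x) cap(split_set(x)))
  tab$detected <- lapply(tab$detected, function(x) cap(split_set(x)))
  tab
}

collapse_set <- function(tokens) {
  map <- c(Val = "Vxx", Iva = "Vxx", Leu = "Lxx", Ile = "Lxx")
  unique(ifelse(tokens %in% names(map), map[tokens], tokens))
}

#' Prediction/observation agreement for an NRPS module
#'
#' Compares the detected amino acids of a module with the predicted sets
#' under an explicit rule.  No single natural rule reproduces published
#' headline agreement counts, so the rule is always a named argument and
#' per-rule counts can be tabulated with [nrps_agreement_counts()].
#'
#' @param record One row of [read_nrps_table()] (data.frame of one row).
#' @param rule `"subset_of_union"` (detected contained in the union of both
#'   predictors), `"subset_of_first"` (contained in the first predictor's
#'   set), or `"nonempty_intersection"`.
#' @param collapse Apply the Vxx/Lxx collapse to all sets before comparing
#'   (so a predicted Iva counts as matching a detected Ile's mass class)?
#'   Default `FALSE`.
#' @return Logical scalar.
#' @export
nrps_agreement <- function(record, rule = c("subset_of_union",
                           "subset_of_first", "nonempty_intersection"),
                           collapse = FALSE) {
  rule <- match.arg(rule)
  det <- record$detected[[1L]]
  a <- record$predicted_a[[1L]]
  b <- record$predicted_b[[1L]]
  if (collapse) {
    det <- collapse_set(det); a <- collapse_set(a); b <- collapse_set(b)
  }
  u <- union(a, b)
  if (length(det) == 0L) return(FALSE)
  switch(rule,
    subset_of_union = length(u) > 0L && all(det %in% u),
    subset_of_first = length(a) > 0L && all(det %in% a),
    nonempty_intersection = length(intersect(det, u)) > 0L
  )
}

#' @rdname nrps_agreement
#' @param tab Full table from [read_nrps_table()].
#' @return For `nrps_agreement_counts`: a data.frame of per-species,
#'   per-rule counts of agreeing positions.
#' @export
nrps_agreement_counts <- function(tab, collapse = FALSE) {
  rules <- c("subset_of_union", "subset_of_first", "nonempty_intersection")
  out <- expand.grid(species = unique(tab$species), rule = rules,
                     stringsAsFactors = FALSE)
  out$agreeing <- mapply(function(sp, rl) {
    rows <- which(tab$species == sp)
    sum(vapply(rows, function(i)
      nrps_agreement(tab[i, ], rule = rl, collapse = collapse), TRUE))
  }, out$species, out$rule)
  out
}

#' Partition species by signature identity at a module position
#'
#' @param tab Table from [read_nrps_table()].
#' @param position Module position 1-20.
#' @return A list of character vectors (species sharing one signature),
#'   named by the shared signature, in alphabetical species order.
#' @export
signature_identity <- function(tab, position) {
  rows <- tab[tab$position == position, ]
  if (nrow(rows) == 0L) stop("no records at position ", position,
                             call. = FALSE)
  rows <- rows[order(rows$species), ]
  split(rows$species, rows$signature)
}

#' @rdname signature_identity
#' @return For `most_variable_position`: the position with the largest
#'   number of distinct signatures across species.
#' @export
most_variable_position <- function(tab) {
  groups <- vapply(sort(unique(tab$position)), function(p)
    length(signature_identity(tab, p)), 0L)
  sort(unique(tab$position))[which.max(groups)]
}
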