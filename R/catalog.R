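# Comparison of candidate sequences against a reference catalogue:
# identity, positional isomery, substitution lists and the new-vs-known
# verdict.  All matching is done on the collapsed Vxx/Lxx alphabet, since
# the MS data cannot distinguish Val/Iva or Leu/Ile; catalogues containing
# exact isomers are normalised on load.

#' Read a reference catalogue
#'
#' @param path CSV with columns `name`, `chain` (hyphen-separated token
#'   string) and `citation`.  Chains are collapsed onto the Vxx/Lxx
#'   alphabet on load.
#' @return A data.frame with a list-column `seq` of collapsed
#'   [peptaibol_sequence()] objects.
#' @export
read_reference_catalog <- function(path = peptaibol_fixture("catalog")) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chain", "citation") %in% names(cat)))
  if (anyDuplicated(cat$name)) {
    stop("catalogue names must be unique", call. = FALSE)
  }
  cat$seq <- lapply(seq_len(nrow(cat)), function(i) {
    collapse_sequence(peptaibol_sequence(cat$chain[i], name = cat$name[i]))
  })
  cat
}

# label (20-frame position) of internal residue index i after deleting
# reference position d: indices < d keep their position, later ones shift
frame_label <- function(i, d) ifelse(i < d, i, i + 1L)

#' Compare a candidate sequence to a reference
#'
#' Both chains are collapsed first.  Equal-length chains are compared
#' position by position (Hamming).  A 19-unit candidate against a 20-unit
#' reference is aligned by a single internal deletion placed where it
#' minimises the substitution count; when several positions tie, the
#' rightmost is taken, which reproduces the published alignment of the
#' 19-residue brevicelsins at R6.  Substitutions are reported in the
#' 20-residue label frame as `"[from]^i -> [to]^i"` (with a Unicode arrow).
#'
#' @param candidate,reference [peptaibol_sequence()] objects sharing cap
#'   and alcohol unit classes.
#' @return An object of class `match_report`: list with `status`
#'   (`"identical"` or `"variant"`), `substitutions` (data.frame `label`,
#'   `from`, `to`), `gap_label` (`"R6"` equivalent position or `NA`),
#'   `distance` (substitution count, +1 per gap) and `rendered` (the
#'   paper-style notation).
#' @export
compare_chains <- function(candidate, reference) {
  cand <- collapse_sequence(candidate)
  ref <- collapse_sequence(reference)
  ci <- internal_tokens(cand); ri <- internal_tokens(ref)
  # termini must be comparable
  if (!identical(collapse_tokens(cand$chain[1L]), collapse_tokens(ref$chain[1L])) ||
      !identical(collapse_tokens(cand$chain[length(cand$chain)]),
                 collapse_tokens(ref$chain[length(ref$chain)]))) {
    stop("candidate and reference differ in cap or C-terminal alcohol class",
         call. = FALSE)
  }
  nl <- length(ci); rl <- length(ri)
  if (abs(nl - rl) > 1L) {
    stop("chains differing by more than one residue are not supported",
         call. = FALSE)
  }
  swap <- FALSE
  if (nl > rl) {  # allow 20-unit candidate vs 19-unit reference symmetrically
    tmp <- ci; ci <- ri; ri <- tmp
    swap <- TRUE
  }
  if (length(ci) == length(ri)) {
    diff <- which(ci != ri)
    subs <- data.frame(label = paste0("R", diff, recycle0 = TRUE),
                       from = ri[diff], to = ci[diff],
                       stringsAsFactors = FALSE)
    gap <- NA_character_
  } else {
    # one internal deletion in the longer chain
    n <- length(ri)
    counts <- vapply(seq_len(n), function(d)
      sum(ri[-d] != ci), 0L)
    d <- max(which(counts == min(counts)))  # rightmost minimiser
    short <- ri[-d]
    diff <- which(short != ci)
    subs <- data.frame(label = paste0("R", frame_label(diff, d), recycle0 = TRUE),
                       from = short[diff], to = ci[diff],
                       stringsAsFactors = FALSE)
    gap <- paste0("R", d)
  }
  if (swap && nrow(subs) > 0L) {
    tmp <- subs$from; subs$from <- subs$to; subs$to <- tmp
  }
  distance <- nrow(subs) + !is.na(gap)
  status <- if (distance == 0L) "identical" else "variant"
  structure(list(
    candidate = if (is.null(candidate$name)) NA_character_ else candidate$name,
    reference = if (is.null(reference$name)) NA_character_ else reference$name,
    status = status, substitutions = subs, gap_label = gap,
    distance = distance,
    rendered = render_substitutions(subs, gap)
  ), class = "match_report")
}

#' Render and parse the paper-style substitution notation
#'
#' A substitution is written `"[from]^i -> [to]^i"` (with a Unicode arrow); multiple
#' substitutions are joined with `", "`; a gap is prefixed as
#' `"gap at R6"`. `parse_substitutions()` round-trips the rendering back to
#' the structured form.
#'
#' @param subs data.frame with columns `label`, `from`, `to`.
#' @param gap_label Gap label or `NA`.
#' @return A character scalar.
#' @export
render_substitutions <- function(subs, gap_label = NA_character_) {
  parts <- character(0)
  if (!is.na(gap_label)) parts <- paste("gap at", gap_label)
  if (nrow(subs) > 0L) {
    i <- sub("^R", "", subs$label)
    parts <- c(parts,
               sprintf("[%s]^%s \u2192 [%s]^%s", subs$from, i, subs$to, i))
  }
  if (length(parts) == 0L) "identical" else paste(parts, collapse = ", ")
}

#' @rdname render_substitutions
#' @param x Rendered notation string.
#' @export
parse_substitutions <- function(x) {
  if (identical(x, "identical")) {
    return(list(substitutions = data.frame(label = character(0),
                                           from = character(0),
                                           to = character(0),
                                           stringsAsFactors = FALSE),
                gap_label = NA_character_))
  }
  parts <- strsplit(x, ", ", fixed = TRUE)[[1L]]
  gap <- NA_character_
  g <- grepl("^gap at ", parts)
  if (any(g)) gap <- sub("^gap at ", "", parts[g][1L])
  parts <- parts[!g]
  m <- regmatches(parts,
                  regexec("^\\[(\\w+)\\]\\^(\\d+) \u2192 \\[(\\w+)\\]\\^(\\d+)$",
                          parts))
  subs <- do.call(rbind, lapply(m, function(p) {
    stopifnot(length(p) == 5L, p[3L] == p[5L])
    data.frame(label = paste0("R", p[3L]), from = p[2L], to = p[4L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(subs)) subs <- data.frame(label = character(0),
                                        from = character(0),
                                        to = character(0),
                                        stringsAsFactors = FALSE)
  list(substitutions = subs, gap_label = gap)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: %s vs %s -> %s (distance %d)\n",
              x$candidate, x$reference, x$status, x$distance))
  cat(" ", x$rendered, "\n")
  invisible(x)
}

#' Classify a candidate as known or new against a catalogue
#'
#' A candidate is *known* when some catalogue entry matches at distance 0
#' on the collapsed alphabet, and *new* otherwise; in either case all
#' entries within `max_subs` differences are listed, ordered by distance
#' and then name, mirroring the reporting of new compounds as differing by
#' one to three residues from their nearest described relatives.
#'
#' @param candidate A [peptaibol_sequence()].
#' @param catalog A data.frame from [read_reference_catalog()].
#' @param max_subs Neighbourhood radius in substitution distance
#'   (default 3).
#' @return A list with `verdict` (`"known"`/`"new"`) and `neighbors`
#'   (data.frame `name`, `distance`, `notation`).
#' @export
classify_novelty <- function(candidate, catalog, max_subs = 3L) {
  stopifnot(nrow(catalog) > 0L)
  reports <- list()
  for (i in seq_len(nrow(catalog))) {
    rep_i <- tryCatch(compare_chains(candidate, catalog$seq[[i]]),
                      error = function(e) NULL)  # incomparable entries skipped
    if (!is.null(rep_i)) reports[[catalog$name[i]]] <- rep_i
  }
  dists <- vapply(reports, function(r) r$distance, 0L)
  keep <- names(dists)[dists <= max_subs]
  nb <- data.frame(
    name = keep,
    distance = unname(dists[keep]),
    notation = vapply(reports[keep], function(r) r$rendered, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  nb <- nb[order(nb$distance, nb$name), , drop = FALSE]
  rownames(nb) <- NULL
  list(verdict = if (any(dists == 0L)) "known" else "new", neighbors = nb)
}
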