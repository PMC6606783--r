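# The peptaibol sequence container: an acetylated chain of 18 or 19 internal
# residues ending in a C-terminal amino alcohol, with position labels in the
# 20-residue frame (19-unit chains carry a vacancy at label R6).

#' Construct a peptaibol sequence
#'
#' A peptaibol chain starts with an N-terminal cap (acetyl), carries 18 or 19
#' internal residues and ends in a C-terminal 1,2-amino alcohol.  Positions
#' are labelled R1..R20; 19-unit chains (18 internal residues + alcohol) are
#' aligned in the 20-residue frame with a vacancy at label R6, the position
#' lost by internal module skipping in the shorter brevicelsin-type
#' compounds.
#'
#' @param chain Either a hyphen-separated token string
#'   (`"Ac-Aib-Ala-...-Pheol"`) or a character vector of registry codes.
#'   The first token must be an N-cap, the last a C-terminal alcohol.
#' @param name Optional compound identifier.
#' @param r6_vacant Logical; for 19-unit chains the vacancy is always placed
#'   at R6 (the only supported gap position); ignored for 20-unit chains.
#' @return An object of class `peptaibol_sequence`: a list with elements
#'   `chain` (tokens), `labels` (R-position label per token, `"R0"` for the
#'   cap), and `name`.
#' @examples
#' ps <- peptaibol_sequence("Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Ala-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol")
#' neutral_mass(ps)
#' @export
peptaibol_sequence <- function(chain, name = NULL, r6_vacant = NULL) {
  if (is.character(chain) && length(chain) == 1L && grepl("-", chain)) {
    chain <- strsplit(chain, "-", fixed = TRUE)[[1L]]
  }
  chain <- as.character(chain)
  cls <- unit_class(chain)
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1L]
    stop(sprintf("unknown residue code '%s' at chain position %d",
                 chain[bad], bad), call. = FALSE)
  }
  n <- length(chain)
  if (cls[1L] != "n_cap") {
    stop("chain must begin with an N-cap (e.g. 'Ac')", call. = FALSE)
  }
  if (cls[n] != "c_terminal_alcohol") {
    stop("chain must end with a C-terminal amino alcohol (e.g. 'Pheol')",
         call. = FALSE)
  }
  if (any(cls[-c(1L, n)] != "internal_residue")) {
    stop("caps and alcohols may only occur at the chain termini",
         call. = FALSE)
  }
  n_internal <- n - 2L
  if (!n_internal %in% c(18L, 19L)) {
    stop(sprintf(
      "chain must contain 18 or 19 internal residues, found %d", n_internal),
      call. = FALSE)
  }
  labels <- if (n_internal == 19L) {
    c("R0", paste0("R", 1:20))
  } else {
    c("R0", paste0("R", c(1:5, 7:20)))  # vacancy at R6
  }
  structure(
    list(chain = chain, labels = labels, name = name),
    class = "peptaibol_sequence"
  )
}

#' @export
print.peptaibol_sequence <- function(x, ...) {
  nm <- if (is.null(x$name)) "<unnamed>" else x$name
  cat(sprintf("peptaibol_sequence %s (%d units%s)\n", nm,
              length(x$chain) - 2L,
              if (has_r6_vacancy(x)) ", R6 vacant" else ""))
  cat(" ", paste(x$chain, collapse = "-"), "\n")
  invisible(x)
}

#' @export
as.character.peptaibol_sequence <- function(x, ...) {
  paste(x$chain, collapse = "-")
}

#' Does a sequence carry the R6 vacancy?
#' @param seq A `peptaibol_sequence`.
#' @return Logical.
#' @export
has_r6_vacancy <- function(seq) {
  !"R6" %in% seq$labels
}

#' Collapse a sequence onto the Vxx/Lxx alphabet
#'
#' Applies [collapse_tokens()] to the whole chain and returns a new sequence.
#' Idempotent: sequences already in the collapsed alphabet are unchanged.
#'
#' @param seq A `peptaibol_sequence`.
#' @return A `peptaibol_sequence` in the collapsed alphabet.
#' @export
collapse_sequence <- function(seq) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  out <- seq
  out$chain <- collapse_tokens(seq$chain)
  out
}

# internal residue tokens (between cap and alcohol)
internal_tokens <- function(seq) {
  seq$chain[-c(1L, length(seq$chain))]
}

# token at a 20-frame label, or NA if vacant/absent
token_at_label <- function(seq, label) {
  i <- match(label, seq$labels)
  if (is.na(i)) NA_character_ else seq$chain[i]
}
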