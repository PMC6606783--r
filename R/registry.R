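# Residue registry and mass constants.
#
# All masses are monoisotopic and fixed in a versioned TSV shipped with the
# package, so results do not depend on external element tables.

.registry_env <- new.env(parent = emptyenv())

#' Mass constants used throughout the package
#'
#' Monoisotopic masses (Da) of the hydrogen atom, the proton, sodium and the
#' acetyl cap, pinned to five decimals.
#'
#' @format A named numeric vector with elements `hydrogen`, `proton`,
#'   `sodium`, `acetyl`.
#' @export
mass_constants <- c(
  hydrogen = 1.00783,
  proton   = 1.00728,
  sodium   = 22.98977,
  acetyl   = 42.01057
)

#' Residue registry
#'
#' Returns the table of residue, N-cap and C-terminal amino-alcohol units the
#' package knows about.  Each unit has a token code, a monoisotopic mass in
#' Da, a unit class (`internal_residue`, `n_cap` or `c_terminal_alcohol`) and
#' a collapse class.  The collapse class implements the Vxx/Lxx convention:
#' Val and Iva are isobaric and indistinguishable by MS, as are Leu and Ile,
#' so each maps onto a shared token (`Vxx`, `Lxx`).  C-terminal amino
#' alcohols carry the full unit mass of the condensed 1,2-amino alcohol
#' (e.g. phenylalaninol, `Pheol`, 151.09971 Da).
#'
#' @return A data.frame with columns `code`, `mono_mass`, `unit_class`,
#'   `collapse_class`.
#' @examples
#' reg <- residue_registry()
#' reg[reg$code == "Aib", ]
#' @export
residue_registry <- function() {
  if (is.null(.registry_env$registry)) {
    path <- system.file("extdata", "residue_masses.tsv", package = "peptaibols",
                        mustWork = TRUE)
    reg <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(
      !anyDuplicated(reg$code),
      all(reg$mono_mass > 0),
      all(reg$unit_class %in% c("internal_residue", "n_cap",
                                "c_terminal_alcohol"))
    )
    .registry_env$registry <- reg
  }
  .registry_env$registry
}

# mass of a single unit token; fatal on unknown tokens
unit_mass <- function(code, position = NULL) {
  reg <- residue_registry()
  i <- match(code, reg$code)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1L]
    where <- if (is.null(position)) "" else sprintf(" at position %s",
                                                    position[bad])
    stop(sprintf("unknown residue code '%s'%s", code[bad], where),
         call. = FALSE)
  }
  reg$mono_mass[i]
}

unit_class <- function(code) {
  reg <- residue_registry()
  reg$unit_class[match(code, reg$code)]
}

#' Collapse residue tokens onto the Vxx/Lxx alphabet
#'
#' Maps Val and Iva to `Vxx`, Leu and Ile to `Lxx` (and leucinol/isoleucinol
#' to `Lxxol`); every other token is returned unchanged.  Idempotent.
#'
#' @param tokens Character vector of registry codes.
#' @return Character vector of collapsed codes.
#' @export
collapse_tokens <- function(tokens) {
  reg <- residue_registry()
  i <- match(tokens, reg$code)
  if (anyNA(i)) {
    stop(sprintf("unknown residue code '%s'", tokens[which(is.na(i))[1L]]),
         call. = FALSE)
  }
  reg$collapse_class[i]
}

# internal residues in the collapsed alphabet, one row per distinct mass class
collapsed_internal_classes <- function() {
  reg <- residue_registry()
  reg <- reg[reg$unit_class == "internal_residue", ]
  reg <- reg[!duplicated(reg$collapse_class), c("collapse_class", "mono_mass")]
  names(reg) <- c("code", "mono_mass")
  reg
}

# composite step across the fragmentation-stable Gln-Aib bond (missing b7)
gln_aib_step <- function() {
  sum(unit_mass(c("Gln", "Aib")))
}
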