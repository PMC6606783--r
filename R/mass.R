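# Mass and fragment-ion arithmetic.
#
# Printed table values are floored monoisotopic masses: flooring (not
# rounding) is the only convention that reproduces the published tables
# (774 from 774.447, 1922 from 1922.099).  Doubly sodiated values are
# floored to the nearest 0.5 Da, and the y-ion convention adds a single
# hydrogen (+1.00783), again pinned by the printed values.

#' Floor to the nearest half / tenth
#'
#' Printed doubly-charged sodium adducts use 0.5 Da resolution and the MS2
#' selection values for y7 use 0.1 Da resolution; both are truncations, not
#' roundings.
#'
#' @param x Numeric vector.
#' @return Numeric vector truncated to the stated resolution.
#' @export
floor_to_half <- function(x) floor(x * 2) / 2

#' @rdname floor_to_half
#' @export
floor_to_tenth <- function(x) floor(x * 10) / 10

#' Neutral monoisotopic mass of a peptaibol
#'
#' The neutral mass is the sum of the cap mass, the internal residue masses
#' and the full unit mass of the C-terminal amino alcohol.
#'
#' @param seq A [peptaibol_sequence()].
#' @param printed If `TRUE` return the floored integer value as printed in
#'   compound tables; otherwise the exact value in Da.
#' @return Numeric scalar.
#' @examples
#' ps <- peptaibol_sequence("Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Ala-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol")
#' neutral_mass(ps)                  # 1922.099
#' neutral_mass(ps, printed = TRUE)  # 1922
#' @export
neutral_mass <- function(seq, printed = FALSE) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  m <- sum(unit_mass(seq$chain, position = seq$labels))
  if (printed) floor(m) else m
}

#' Adduct m/z values
#'
#' Computes the m/z of the sodiated and protonated forms observed in full
#' scans.  `[M+Na]+` is printed floored to integer, `[M+2Na]2+` floored to
#' the nearest 0.5, and `[M+H]+` is reported exactly (high-resolution mode).
#'
#' @param M_exact Exact neutral mass in Da.
#' @param adduct One of `"H"`, `"Na"`, `"2Na"`.
#' @param charge Positive integer; must be 2 for `"2Na"` and 1 otherwise.
#' @param printed If `TRUE`, apply the table printing convention.
#' @return Numeric scalar m/z.
#' @export
adduct_mz <- function(M_exact, adduct = c("Na", "2Na", "H"), charge = NULL,
                      printed = FALSE) {
  adduct <- match.arg(adduct)
  expected_charge <- if (adduct == "2Na") 2L else 1L
  if (is.null(charge)) charge <- expected_charge
  if (charge != expected_charge) {
    stop(sprintf("adduct '%s' implies charge %d, got %d", adduct,
                 expected_charge, charge), call. = FALSE)
  }
  na <- mass_constants[["sodium"]]
  mz <- switch(adduct,
    H   = M_exact + mass_constants[["proton"]],
    Na  = M_exact + na,
    `2Na` = (M_exact + 2 * na) / 2
  )
  if (!printed) return(mz)
  switch(adduct,
    H   = mz,                  # high-resolution mode, printed exactly
    Na  = floor(mz),
    `2Na` = floor_to_half(mz)
  )
}

#' N-terminal b ions
#'
#' The b_n ion covers the cap and the first `n` internal residues plus one
#' hydrogen.  Full-scan spectra show b1-b6 and b8-b13; b7 is absent because
#' of the fragmentation-stable Gln-Aib bond at R7-R8.
#'
#' @param seq A [peptaibol_sequence()].
#' @param n Chain position (1-based, counting internal residues).
#' @param printed If `TRUE` return the floored integer value.
#' @return Numeric scalar.
#' @export
b_ion <- function(seq, n, printed = FALSE) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  res <- internal_tokens(seq)
  if (!(n >= 1L && n < length(res) + 1L)) {
    stop(sprintf("b-ion index %d out of range 1..%d", n, length(res)),
         call. = FALSE)
  }
  m <- unit_mass(seq$chain[1L]) + sum(unit_mass(res[seq_len(n)])) +
    mass_constants[["hydrogen"]]
  if (printed) floor(m) else m
}

#' C-terminal y ions
#'
#' The y_k ion covers the last `k` chain units (the C-terminal alcohol counts
#' as the last unit) plus a single hydrogen.  This one-hydrogen convention is
#' pinned because it reproduces every printed y7 value (774 from 774.447) and
#' the MS2 selection masses (774.4, 775.4, 788.4, 789.4).
#'
#' @param seq A [peptaibol_sequence()].
#' @param k Number of C-terminal units, `1 <= k <=` number of internal
#'   residues + 1.
#' @param printed One of `"exact"`, `"integer"`, `"tenth"`.
#' @return Numeric scalar.
#' @export
y_ion <- function(seq, k, printed = c("exact", "integer", "tenth")) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  printed <- match.arg(printed)
  units <- seq$chain[-1L]  # internal residues + alcohol
  if (!(k >= 1L && k <= length(units))) {
    stop(sprintf("y-ion count %d out of range 1..%d", k, length(units)),
         call. = FALSE)
  }
  m <- sum(unit_mass(rev(units)[seq_len(k)])) + mass_constants[["hydrogen"]]
  switch(printed, exact = m, integer = floor(m), tenth = floor_to_tenth(m))
}

#' Chain index of the diagnostic b ion (one unit before Pro)
#'
#' The tables print a diagnostic N-terminal fragment ending at the residue
#' immediately preceding the single Pro of the chain: b13 for 20-unit
#' compounds (Pro at R14) and b12 for the 19-unit brevicelsins.
#'
#' @param seq A [peptaibol_sequence()].
#' @return Integer chain position.
#' @export
pre_pro_b_index <- function(seq) {
  stopifnot(inherits(seq, "peptaibol_sequence"))
  res <- internal_tokens(seq)
  pro <- which(res == "Pro")
  if (length(pro) == 0L) stop("chain contains no Pro", call. = FALSE)
  if (length(pro) > 1L) {
    stop("chain contains multiple Pro residues; diagnostic b ion is ambiguous",
         call. = FALSE)
  }
  pro - 1L
}

#' Summarise the printed mass columns of a compound
#'
#' Recomputes the five printed quantities of the compound tables (M,
#' \[M+Na\]+, \[M+2Na\]2+, diagnostic b ion, y7) together with their exact
#' counterparts.
#'
#' @param seq A [peptaibol_sequence()].
#' @return A one-row data.frame with columns `M_exact`, `M_printed`,
#'   `mNa_printed`, `m2Na_printed`, `mH_exact`, `b_diag_printed`,
#'   `y7_printed`, `y7_1dp`.
#' @export
mass_summary <- function(seq) {
  M <- neutral_mass(seq)
  data.frame(
    M_exact      = M,
    M_printed    = floor(M),
    mNa_printed  = adduct_mz(M, "Na", printed = TRUE),
    m2Na_printed = adduct_mz(M, "2Na", printed = TRUE),
    mH_exact     = adduct_mz(M, "H"),
    b_diag_printed = b_ion(seq, pre_pro_b_index(seq), printed = TRUE),
    y7_printed   = y_ion(seq, 7, printed = "integer"),
    y7_1dp       = y_ion(seq, 7, printed = "tenth")
  )
}

#' Assign a residue class to an observed mass difference
#'
#' Looks up the collapsed residue class whose monoisotopic mass lies within
#' `tolerance` of an observed ladder step.  The composite step of 213.111 Da
#' (Gln + Aib across the fragmentation-stable bond, where no intermediate b
#' ion is observed) is returned as the ordered pair `c("Gln", "Aib")`.
#'
#' @param delta Observed mass difference in Da.
#' @param tolerance Matching tolerance in Da (> 0).
#' @return A list with elements `tokens` (character vector: one token, the
#'   composite pair, or the full ambiguous candidate set), `status` (one of
#'   `"assigned"`, `"composite"`, `"ambiguous"`, `"unassigned"`).
#' @examples
#' residue_from_delta(85.05, 0.3)    # Aib
#' residue_from_delta(213.11, 0.3)   # Gln, Aib composite
#' @export
residue_from_delta <- function(delta, tolerance) {
  stopifnot(tolerance > 0)
  classes <- collapsed_internal_classes()
  hit <- which(abs(classes$mono_mass - delta) <= tolerance)
  if (length(hit) == 1L) {
    return(list(tokens = classes$code[hit], status = "assigned"))
  }
  if (length(hit) > 1L) {
    ord <- hit[order(abs(classes$mono_mass[hit] - delta))]
    return(list(tokens = classes$code[ord], status = "ambiguous"))
  }
  if (abs(gln_aib_step() - delta) <= tolerance) {
    return(list(tokens = c("Gln", "Aib"), status = "composite"))
  }
  list(tokens = character(0), status = "unassigned")
}
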