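# De novo sequence reading from peak lists, following the two-stage
# strategy used for these compounds: the N-terminal half (R1-R13) is read
# as a b-ion ladder from the full scan (b1-b6, b8-b13; b7 is never observed
# because of the stable Gln-Aib bond, which is bridged by a composite
# Gln+Aib step of 213.111 Da), and the C-terminal half (R14-R20) from the
# MS2 spectrum of the y7 fragment.  The two partial calls are merged and
# checked for mass closure against the precursor.

new_sequence_call <- function() {
  structure(list(
    assignments = character(0),   # named by label; "(vacant)" marks the gap
    provenance  = character(0),
    closure_residual = NA_real_,
    M_computed = NA_real_,
    M_observed = NA_real_,
    precursor_interpretation = NA_character_,
    complete = FALSE,
    branches = NULL,
    diagnostics = character(0)
  ), class = "sequence_call")
}

#' @export
print.sequence_call <- function(x, ...) {
  cat(sprintf("sequence_call: %d assigned position(s)%s\n",
              sum(!is.na(x$assignments)),
              if (isTRUE(x$complete)) ", complete" else ""))
  if (length(x$assignments) > 0L) {
    cat(" ", paste(sprintf("%s=%s", names(x$assignments), x$assignments),
                   collapse = " "), "\n")
  }
  if (!is.na(x$closure_residual)) {
    cat(sprintf("  closure residual %.4f Da (%s)\n", x$closure_residual,
                x$precursor_interpretation))
  }
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

# Depth-first extension of a b-ion ladder.  Each branch records the tokens
# read so far, the m/z of the last matched peak and the cumulative absolute
# mass error; at every step all single-residue extensions within tolerance
# are followed, and where none exists the composite Gln-Aib step is tried.
#
# A single-residue Gln step is never taken: the Gln residue mass (128.059)
# coincides with a Gly+Ala pair (57.021 + 71.037) whose intermediate b ion
# may simply be missing, and in the b-ion region of these compounds the
# only Gln sits at R7, whose own b ion is systematically absent (stable
# Gln-Aib bond) and which is therefore only ever reached through the
# composite step.  Treating direct Gln steps as unassignable trades a
# conservative ladder break for immunity against hallucinated calls.
#
# The composite step itself is anchored at chain positions 6-7 (the R7-R8
# bond, allowing for the R6 vacancy of 19-unit chains): 213.111 Da also
# equals Ala+Ala+Ala and Ala+Gly+Aib, so an unanchored composite could
# bridge two dropped peaks elsewhere and hallucinate a Gln.  `offset` is
# the number of chain positions already consumed before this extension.
extend_b_ladder <- function(pl, tolerance, start_mz, max_tokens,
                            offset = 1L) {
  classes <- collapsed_internal_classes()
  classes <- classes[classes$code != "Gln", ]
  branches <- list(list(tokens = character(0), prov = character(0),
                        mz = start_mz, err = 0))
  done <- list()
  while (length(branches) > 0L) {
    nxt <- list()
    for (br in branches) {
      if (length(br$tokens) >= max_tokens) { done <- c(done, list(br)); next }
      grown <- FALSE
      for (j in seq_len(nrow(classes))) {
        target <- br$mz + classes$mono_mass[j]
        for (p in peaks_near(pl, target, tolerance)) {
          nb <- br
          nb$tokens <- c(br$tokens, classes$code[j])
          nb$prov <- c(br$prov, sprintf("b%d-b%d (step %.3f)",
                                        length(br$tokens),
                                        length(br$tokens) + 1L,
                                        pl$mz[p] - br$mz))
          nb$mz <- pl$mz[p]
          nb$err <- br$err + abs(pl$mz[p] - target)
          nxt <- c(nxt, list(nb))
          grown <- TRUE
        }
      }
      gln_pos <- offset + length(br$tokens) + 1L
      if (!grown && length(br$tokens) + 2L <= max_tokens &&
          gln_pos %in% c(6L, 7L)) {
        # bridge the missing b ion across the stable Gln-Aib bond
        target <- br$mz + gln_aib_step()
        for (p in peaks_near(pl, target, tolerance)) {
          nb <- br
          nb$tokens <- c(br$tokens, "Gln", "Aib")
          nb$prov <- c(br$prov, sprintf("composite b%d-b%d (Gln)",
                                        length(br$tokens),
                                        length(br$tokens) + 2L),
                       sprintf("composite b%d-b%d (Aib)",
                               length(br$tokens), length(br$tokens) + 2L))
          nb$mz <- pl$mz[p]
          nb$err <- br$err + abs(pl$mz[p] - target)
          nxt <- c(nxt, list(nb))
          grown <- TRUE
        }
      }
      if (!grown) done <- c(done, list(br))
    }
    branches <- nxt
  }
  # rank: longest ladder first, then smallest cumulative error
  done[order(-vapply(done, function(b) length(b$tokens), 0L),
             vapply(done, function(b) b$err, 0))]
}

#' Read the N-terminal half of a peptaibol from a full scan
#'
#' Starts a b1 candidate (cap + residue + H) for every registered residue
#' class and greedily extends the ladder by single-residue mass steps within
#' tolerance.  Where no single step matches at chain positions 6-7, a
#' composite 213.111 Da step is accepted and assigned as Gln followed by
#' Aib (the pair flanking the fragmentation-stable bond whose intermediate
#' b ion is never observed); the composite is anchored there because the
#' same total mass also arises from triples such as Ala+Ala+Ala.  A direct
#' single-residue Gln step is treated as unassignable, its mass being
#' indistinguishable from a Gly+Ala pair with a missing intermediate ion.
#' Branching ladders are all followed and ranked by cumulative mass error;
#' the best branch forms the returned call.
#'
#' @param peaks A [peak_list()] with level `"full_scan"`.
#' @param cap N-cap token, default `"Ac"`.
#' @param tolerance Override of the peak list tolerance (Da).
#' @param max_positions Maximum number of chain positions to read (default
#'   13, the span covered by the printed b series).
#' @return A `sequence_call` with chain positions 1..n assigned (named
#'   `"P1"`.., label mapping is deferred to [assemble_call()]), plus all
#'   ranked branches in `$branches`.
#' @export
read_n_terminus <- function(peaks, cap = "Ac", tolerance = NULL,
                            max_positions = 13L) {
  stopifnot(inherits(peaks, "peak_list"))
  if (attr(peaks, "level") != "full_scan") {
    stop("read_n_terminus expects a full-scan peak list", call. = FALSE)
  }
  if (is.null(tolerance)) tolerance <- attr(peaks, "tolerance")
  call <- new_sequence_call()
  classes <- collapsed_internal_classes()
  classes <- classes[classes$code != "Gln", ]  # see extend_b_ladder
  b1 <- unit_mass(cap) + classes$mono_mass + mass_constants[["hydrogen"]]
  seeds <- list()
  for (j in seq_along(b1)) {
    for (p in peaks_near(peaks, b1[j], tolerance)) {
      seeds <- c(seeds, list(list(token = classes$code[j], mz = peaks$mz[p],
                                  err = abs(peaks$mz[p] - b1[j]))))
    }
  }
  if (length(seeds) == 0L) {
    call$diagnostics <- "no b1 candidate found"
    return(call)
  }
  branches <- list()
  for (s in seeds) {
    for (br in extend_b_ladder(peaks, tolerance, s$mz,
                               max_tokens = max_positions - 1L)) {
      br$tokens <- c(s$token, br$tokens)
      br$prov <- c(sprintf("b1 (%.3f)", s$mz), br$prov)
      br$err <- br$err + s$err
      branches <- c(branches, list(br))
    }
  }
  branches <- branches[order(-vapply(branches, function(b) length(b$tokens), 0L),
                             vapply(branches, function(b) b$err, 0))]
  best <- branches[[1L]]
  call$assignments <- stats::setNames(best$tokens,
                                      paste0("P", seq_along(best$tokens)))
  call$provenance <- stats::setNames(best$prov,
                                     paste0("P", seq_along(best$tokens)))
  call$branches <- branches
  call
}

#' Read the C-terminal half from the MS2 spectrum of the y7 fragment
#'
#' The terminal amino alcohol (R20) is identified from the y1 ion (alcohol
#' unit + H); R19 down to R15 follow from successive y-series differences;
#' R14 is fixed to Pro when the residual step from the highest matched y ion
#' to the y7 precursor matches 97.053 Da.
#'
#' @param y7_ms2 A [peak_list()] with level `"ms2_of_y7"` and `precursor_mz`
#'   set to the selected y7 value.
#' @param alcohol_hint Optional alcohol token to try first for R20.
#' @param tolerance Override of the peak list tolerance (Da).
#' @return A `sequence_call` with labels R14..R20 (partially) assigned.
#' @export
read_c_terminus <- function(y7_ms2, alcohol_hint = NULL, tolerance = NULL) {
  stopifnot(inherits(y7_ms2, "peak_list"))
  if (attr(y7_ms2, "level") != "ms2_of_y7") {
    stop("read_c_terminus expects an MS2-of-y7 peak list", call. = FALSE)
  }
  if (is.null(tolerance)) tolerance <- attr(y7_ms2, "tolerance")
  precursor <- attr(y7_ms2, "precursor_mz")
  if (is.null(precursor)) {
    stop("y7 MS2 peak list must carry precursor_mz", call. = FALSE)
  }
  call <- new_sequence_call()
  if (nrow(y7_ms2) == 0L) {
    call$diagnostics <- "empty MS2 peak list"
    return(call)
  }
  reg <- residue_registry()
  alcohols <- reg[reg$unit_class == "c_terminal_alcohol", ]
  alcohols <- alcohols[!duplicated(alcohols$collapse_class), ]
  if (!is.null(alcohol_hint)) {
    alcohols <- alcohols[order(alcohols$collapse_class != alcohol_hint), ]
  }
  h <- mass_constants[["hydrogen"]]
  asn <- character(0); prov <- character(0)
  # y1: terminal alcohol unit
  y_mz <- NA_real_; best <- Inf
  for (j in seq_len(nrow(alcohols))) {
    for (p in peaks_near(y7_ms2, alcohols$mono_mass[j] + h, tolerance)) {
      err <- abs(y7_ms2$mz[p] - (alcohols$mono_mass[j] + h))
      if (err < best) {
        best <- err
        asn["R20"] <- alcohols$collapse_class[j]
        prov["R20"] <- sprintf("y1 (%.3f)", y7_ms2$mz[p])
        y_mz <- y7_ms2$mz[p]
      }
    }
  }
  if (is.na(y_mz)) {
    call$diagnostics <- "terminal unit matches no registered amino alcohol"
    return(call)
  }
  # y2..y6 ladder: residues R19 down to R15
  classes <- collapsed_internal_classes()
  for (k in 2:6) {
    label <- paste0("R", 21L - k)
    stepped <- FALSE
    for (j in seq_len(nrow(classes))) {
      target <- y_mz + classes$mono_mass[j]
      hits <- peaks_near(y7_ms2, target, tolerance)
      if (length(hits) > 0L) {
        p <- hits[which.min(abs(y7_ms2$mz[hits] - target))]
        asn[label] <- classes$code[j]
        prov[label] <- sprintf("y%d-y%d (step %.3f)", k - 1L, k,
                               y7_ms2$mz[p] - y_mz)
        y_mz <- y7_ms2$mz[p]
        stepped <- TRUE
        break
      }
    }
    if (!stepped) {
      call$diagnostics <- c(call$diagnostics,
                            sprintf("y ladder broken before %s", label))
      break
    }
  }
  # residual step y6 -> y7 precursor: Pro closes the fragment at R14
  if (all(paste0("R", 15:20) %in% names(asn))) {
    resid <- precursor - y_mz
    if (abs(resid - unit_mass("Pro")) <= 2 * tolerance) {
      asn["R14"] <- "Pro"
      prov["R14"] <- sprintf("y7-y6 residual (%.3f)", resid)
    } else {
      call$diagnostics <- c(call$diagnostics, sprintf(
        "residual %.3f Da from y6 to the y7 precursor does not match Pro",
        resid))
    }
  }
  ord <- paste0("R", 14:20)
  ord <- ord[ord %in% names(asn)]
  call$assignments <- asn[ord]
  call$provenance <- prov[ord]
  call
}

#' Assemble partial calls and check mass closure
#'
#' Merges the N-terminal chain-position call and the C-terminal label call
#' into one sequence call in the R1..R20 frame.  When the combined chain has
#' 18 internal residues the compound is a 19-unit chain and the vacancy is
#' recorded at R6 (the N-terminal ladder then spans R5 to R7 with a
#' single-residue step).  If a precursor is supplied, its `[M+H]+`,
#' `[M+Na]+` and `[M+2Na]2+` interpretations are tried and the one
#' minimising the closure residual |M_computed - M_observed| is kept; the
#' call is complete only when all labels are assigned and the residual is at
#' most `2 * tolerance`.
#'
#' @param n_call `sequence_call` from [read_n_terminus()].
#' @param c_call `sequence_call` from [read_c_terminus()].
#' @param precursor_mz Observed precursor m/z (any of the three adduct
#'   forms), or an exact neutral mass via `M_observed`.
#' @param M_observed Optional neutral mass in Da (overrides `precursor_mz`).
#' @param cap N-cap token used for mass closure.
#' @param tolerance Tolerance in Da for the completeness check.
#' @return A merged `sequence_call`.
#' @export
assemble_call <- function(n_call, c_call, precursor_mz = NULL,
                          M_observed = NULL, cap = "Ac", tolerance = 0.3) {
  stopifnot(inherits(n_call, "sequence_call"),
            inherits(c_call, "sequence_call"))
  out <- new_sequence_call()
  out$diagnostics <- c(n_call$diagnostics, c_call$diagnostics)
  n_tok <- n_call$assignments
  c_tok <- c_call$assignments
  n_len <- length(n_tok)
  n_internal <- n_len + sum(names(c_tok) %in% paste0("R", 14:19))
  c_complete <- all(paste0("R", 14:20) %in% names(c_tok))

  if (c_complete && n_internal == 19L) {         # 20-unit chain
    labels <- paste0("R", seq_len(n_len))
  } else if (c_complete && n_internal == 18L) {  # 19-unit chain, R6 vacant
    labels <- paste0("R", c(1:5, 7:13))[seq_len(n_len)]
    out$assignments["R6"] <- "(vacant)"
    out$provenance["R6"] <- "inferred from 18-residue closure"
  } else {
    labels <- paste0("R", seq_len(n_len))        # provisional frame
    out$diagnostics <- c(out$diagnostics,
                         "partial call: chain length could not be closed")
  }
  for (i in seq_len(n_len)) {
    out$assignments[labels[i]] <- n_tok[[i]]
    out$provenance[labels[i]] <- n_call$provenance[[i]]
  }
  for (lab in names(c_tok)) {
    if (lab %in% names(out$assignments) &&
        !identical(out$assignments[[lab]], c_tok[[lab]])) {
      stop(sprintf(
        "conflicting assignments for %s: '%s' (%s) vs '%s' (%s)",
        lab, out$assignments[[lab]], out$provenance[[lab]],
        c_tok[[lab]], c_call$provenance[[lab]]), call. = FALSE)
    }
    out$assignments[lab] <- c_tok[[lab]]
    out$provenance[lab] <- c_call$provenance[[lab]]
  }
  ord <- c(paste0("R", 1:20))
  keep <- ord[ord %in% names(out$assignments)]
  out$assignments <- out$assignments[keep]
  out$provenance <- out$provenance[keep]

  all_assigned <- c_complete && n_internal %in% c(18L, 19L) &&
    n_len == (if (n_internal == 18L) 12L else 13L)
  if (all_assigned) {
    tokens <- out$assignments[out$assignments != "(vacant)"]
    chain <- c(cap, unname(tokens))
    out$M_computed <- neutral_mass(peptaibol_sequence(chain))
  }
  if (!is.null(M_observed)) {
    out$M_observed <- M_observed
    out$precursor_interpretation <- "neutral mass"
  } else if (!is.null(precursor_mz) && !is.na(out$M_computed)) {
    interp <- c(
      "[M+H]+"    = precursor_mz - mass_constants[["proton"]],
      "[M+Na]+"   = precursor_mz - mass_constants[["sodium"]],
      "[M+2Na]2+" = 2 * precursor_mz - 2 * mass_constants[["sodium"]]
    )
    i <- which.min(abs(out$M_computed - interp))
    out$M_observed <- interp[[i]]
    out$precursor_interpretation <- names(interp)[i]
  }
  if (!is.na(out$M_computed) && !is.na(out$M_observed)) {
    out$closure_residual <- abs(out$M_computed - out$M_observed)
  }
  out$complete <- all_assigned &&
    (is.na(out$closure_residual) || out$closure_residual <= 2 * tolerance)
  if (all_assigned && !is.na(out$closure_residual) &&
      out$closure_residual > 2 * tolerance) {
    out$diagnostics <- c(out$diagnostics, sprintf(
      "mass closure failed: residual %.3f Da", out$closure_residual))
  }
  out
}

#' Chain tokens of an assembled call
#'
#' @param call A complete `sequence_call`.
#' @param cap N-cap token to prepend.
#' @return A [peptaibol_sequence()] built from the call.
#' @export
call_to_sequence <- function(call, cap = "Ac") {
  stopifnot(inherits(call, "sequence_call"))
  tokens <- call$assignments[call$assignments != "(vacant)"]
  if (anyNA(tokens)) stop("call has unassigned positions", call. = FALSE)
  peptaibol_sequence(c(cap, unname(tokens)))
}
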