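# Group assignment (A / B / C) and compound nomenclature: group plus a
# Roman numeral following elution order, with lowercase variant letters in
# decreasing order of abundance.

#' Roman numerals
#'
#' @param n Integer in 1..99.
#' @return Standard subtractive Roman numeral string.
#' @export
roman <- function(n) {
  stopifnot(n >= 1, n <= 99)
  as.character(utils::as.roman(n))
}

#' @rdname roman
#' @param x Roman numeral string.
#' @export
parse_roman <- function(x) {
  v <- as.integer(utils::as.roman(x))
  if (anyNA(v)) stop("not a Roman numeral: ", x[is.na(v)][1L], call. = FALSE)
  v
}

#' Assign a peptaibol to group A, B or C
#'
#' 19-unit chains (R6 vacancy) form group C, the brevicelsins.  Among the
#' 20-unit chains the discriminating position is R12: Lxx marks group A,
#' Aib or Ala group B.  An R12 of Vxx occurs in both groups in the
#' published tables, so it is resolved by a nearest-neighbour vote: the
#' group whose labelled prototype chains have the smaller mean Hamming
#' distance to the candidate wins, with ties going to A.
#'
#' @param seq A [peptaibol_sequence()] (collapsed or not).
#' @param prototypes Optional list with elements `A` and `B`, each a list
#'   of labelled prototype sequences; defaults to the packaged group A and
#'   B tables.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
assign_group <- function(seq, prototypes = NULL) {
  s <- collapse_sequence(seq)
  if (has_r6_vacancy(s)) return("C")
  r12 <- token_at_label(s, "R12")
  if (r12 == "Lxx") return("A")
  if (r12 %in% c("Aib", "Ala")) return("B")
  if (is.null(prototypes)) prototypes <- default_group_prototypes()
  cand <- internal_tokens(s)
  mean_dist <- function(protos) {
    mean(vapply(protos, function(p)
      sum(internal_tokens(p) != cand), 0))
  }
  if (mean_dist(prototypes$A) <= mean_dist(prototypes$B)) "A" else "B"
}

.prototype_env <- new.env(parent = emptyenv())

default_group_prototypes <- function() {
  if (is.null(.prototype_env$protos)) {
    a <- parse_sequence_table(peptaibol_fixture("groupA"))
    b <- parse_sequence_table(peptaibol_fixture("groupB"))
    # prototypes are the unambiguous fixtures (R12 not Vxx)
    keep <- function(tbl) {
      r12 <- collapse_tokens(tbl$R12)
      tbl$seq[r12 != "Vxx"]
    }
    .prototype_env$protos <- list(A = lapply(keep(a), collapse_sequence),
                                  B = lapply(keep(b), collapse_sequence))
  }
  .prototype_env$protos
}

#' Name observed compounds by group, elution order and abundance
#'
#' Within each group, compounds sharing the printed mass triple (M,
#' diagnostic b, y7) are clustered into families by retention-time
#' proximity (single linkage, threshold `rt_tolerance`); families are
#' numbered with Roman numerals by ascending minimum retention time, and
#' members of a family receive lowercase letters in decreasing order of
#' abundance.  Groups A and B are named `Pept-<group>-<numeral><letter>`;
#' group C compounds are named `Brevicelsin-<numeral>`, with letters only
#' when a family holds several variants.
#'
#' The published family numbering of the large group A/B tables cannot be
#' regenerated without the raw chromatograms, so the threshold is an
#' explicit reconstruction knob; the default of 0.5 min reflects the
#' spacing of published same-numeral variants.
#'
#' @param compounds A data.frame with columns `group`, `rt`, `abundance`,
#'   and the printed columns `M`, `b_diag`, `y7`.
#' @param rt_tolerance Retention-time threshold in minutes (default 0.5).
#' @return The input data.frame with a `name` column added, in the input
#'   row order.
#' @export
assign_names <- function(compounds, rt_tolerance = 0.5) {
  stopifnot(rt_tolerance > 0)
  if (nrow(compounds) == 0L) {
    compounds$name <- character(0)
    return(compounds)
  }
  needed <- c("group", "rt", "abundance", "M", "b_diag", "y7")
  stopifnot(all(needed %in% names(compounds)))
  compounds$name <- NA_character_
  for (g in unique(compounds$group)) {
    gi <- which(compounds$group == g)
    sub <- compounds[gi, ]
    key <- paste(sub$M, sub$b_diag, sub$y7)
    # single-linkage rt families within each shared mass triple
    fam <- integer(nrow(sub))
    next_fam <- 1L
    for (k in unique(key)) {
      ki <- which(key == k)
      o <- ki[order(sub$rt[ki], ki)]
      fam[o[1L]] <- next_fam
      if (length(o) > 1L) {
        for (j in 2:length(o)) {
          if (sub$rt[o[j]] - sub$rt[o[j - 1L]] <= rt_tolerance) {
            fam[o[j]] <- fam[o[j - 1L]]
          } else {
            next_fam <- next_fam + 1L
            fam[o[j]] <- next_fam
          }
        }
      }
      next_fam <- next_fam + 1L
    }
    # numerals by ascending minimum rt of the family
    fam_min_rt <- tapply(sub$rt, fam, min)
    numeral_of <- stats::setNames(
      rank(fam_min_rt, ties.method = "first"),
      names(fam_min_rt))
    for (f in unique(fam)) {
      members <- which(fam == f)
      numeral <- roman(numeral_of[[as.character(f)]])
      stem <- if (g == "C") paste0("Brevicelsin-", numeral)
              else sprintf("Pept-%s-%s", g, numeral)
      if (length(members) == 1L) {
        sub$name[members] <- stem
      } else {
        o <- members[order(-sub$abundance[members], members)]
        sub$name[o] <- paste0(stem, letters[seq_along(o)])
      }
    }
    compounds$name[gi] <- sub$name
  }
  if (anyDuplicated(compounds$name)) {
    stop("internal error: duplicate compound names generated", call. = FALSE)
  }
  compounds
}

#' Flag positional isomers among observed compounds
#'
#' Two observed compounds are positional isomers when their collapsed
#' chains are identical but they elute at distinct retention times (the
#' difference lying in Val/Iva or Leu/Ile isomery the MS cannot resolve).
#'
#' @param compounds Data.frame with list-column `seq` and column `rt`.
#' @param rt_tolerance Retention times differing by more than this are
#'   considered distinct (default 0.5 min).
#' @return Data.frame of index pairs `i`, `j` with `chain` string.
#' @export
positional_isomers <- function(compounds, rt_tolerance = 0.5) {
  chains <- vapply(compounds$seq, function(s)
    as.character(collapse_sequence(s)), "")
  out <- list()
  for (ch in unique(chains[duplicated(chains)])) {
    idx <- which(chains == ch)
    prs <- utils::combn(idx, 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; j <- prs[2L, k]
      if (abs(compounds$rt[i] - compounds$rt[j]) > rt_tolerance) {
        out[[length(out) + 1L]] <- data.frame(i = i, j = j, chain = ch,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), chain = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
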