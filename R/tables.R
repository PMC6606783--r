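# Reading and writing compound tables in the published layout
# (name, printed masses, retention time, cap, residues R1-R20).

#' Packaged data fixtures
#'
#' Convenience accessor for the plain-text fixtures shipped with the
#' package: the three compound tables (groups A, B and the 19-residue
#' brevicelsins of group C), the NRPS signature table, the reference
#' catalogue and the residue registry.
#'
#' @param which One of `"groupA"`, `"groupB"`, `"groupC"`, `"nrps"`,
#'   `"catalog"`, `"registry"`.
#' @return File path to the fixture.
#' @export
peptaibol_fixture <- function(which = c("groupA", "groupB", "groupC",
                                        "nrps", "catalog", "registry")) {
  which <- match.arg(which)
  fn <- switch(which,
    groupA   = "table_groupA.tsv",
    groupB   = "table_groupB.tsv",
    groupC   = "table_groupC.tsv",
    nrps     = "table_nrps.tsv",
    catalog  = "reference_catalog.csv",
    registry = "residue_masses.tsv"
  )
  system.file("extdata", fn, package = "peptaibols", mustWork = TRUE)
}

#' Parse a compound table
#'
#' Reads a TSV in the published table layout: `name`, printed `M`, `MNa`
#' (\[M+Na\]+), `M2Na` (\[M+2Na\]2+), `b_diag`, `y7`, `rt`, `cap` and the
#' twenty residue columns `R1`..`R20`, where a `-` cell at R6 marks the
#' vacancy of the 19-residue compounds.  Every row is validated: residue
#' tokens must be registered and a vacancy is only accepted at R6.
#'
#' @param path TSV file path.
#' @return A data.frame with the table columns plus a list-column `seq` of
#'   [peptaibol_sequence()] objects.
#' @export
parse_sequence_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  rescols <- paste0("R", 1:20)
  needed <- c("name", "M", "MNa", "M2Na", "b_diag", "y7", "rt", "cap", rescols)
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0L) {
    stop(sprintf("table is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("M", "MNa", "M2Na", "b_diag", "y7", "rt")) {
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  seqs <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    res <- unlist(tbl[i, rescols], use.names = FALSE)
    gap <- which(res == "-")
    if (length(gap) > 1L || (length(gap) == 1L && gap != 6L)) {
      stop(sprintf("row %d (%s): a residue vacancy is only supported at R6",
                   i, tbl$name[i]), call. = FALSE)
    }
    chain <- c(tbl$cap[i], res[res != "-"])
    seqs[[i]] <- tryCatch(
      peptaibol_sequence(chain, name = tbl$name[i]),
      error = function(e) {
        stop(sprintf("row %d (%s): %s", i, tbl$name[i], conditionMessage(e)),
             call. = FALSE)
      })
  }
  tbl$seq <- seqs
  tbl
}

#' Write a compound table
#'
#' Inverse of [parse_sequence_table()]; round-trips the table layout.
#'
#' @param tbl A data.frame as returned by [parse_sequence_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sequence_table <- function(tbl, path) {
  out <- tbl[setdiff(names(tbl), "seq")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load all packaged compound tables
#'
#' @return A single data.frame concatenating the group A, B and C fixtures.
#' @export
load_compound_tables <- function() {
  tabs <- lapply(c("groupA", "groupB", "groupC"),
                 function(w) parse_sequence_table(peptaibol_fixture(w)))
  do.call(rbind, tabs)
}

#' Recompute the printed mass columns of a compound table
#'
#' For every row, recomputes the quintuple (M, \[M+Na\]+, \[M+2Na\]2+,
#' diagnostic b, y7) from the residue chain and compares it cell by cell to
#' the printed values.  Rows that disagree form the discrepancy report;
#' sporadic disagreements are expected from typographical errors in
#' published tables.
#'
#' @param tbl A data.frame from [parse_sequence_table()].
#' @return A data.frame with the recomputed columns, per-cell logical
#'   `ok_*` flags and an `ok_row` flag; the overall cell-level pass rate is
#'   attached as attribute `pass_rate` and the failing rows as attribute
#'   `discrepancies`.
#' @export
mass_table_check <- function(tbl) {
  stopifnot(is.list(tbl$seq))
  rec <- do.call(rbind, lapply(tbl$seq, mass_summary))
  out <- data.frame(
    name = tbl$name,
    M_printed = tbl$M,        M_recomputed = rec$M_printed,
    mNa_printed = tbl$MNa,    mNa_recomputed = rec$mNa_printed,
    m2Na_printed = tbl$M2Na,  m2Na_recomputed = rec$m2Na_printed,
    b_printed = tbl$b_diag,   b_recomputed = rec$b_diag_printed,
    y7_printed = tbl$y7,      y7_recomputed = rec$y7_printed,
    stringsAsFactors = FALSE
  )
  out$ok_M    <- out$M_printed == out$M_recomputed
  out$ok_mNa  <- out$mNa_printed == out$mNa_recomputed
  out$ok_m2Na <- out$m2Na_printed == out$m2Na_recomputed
  out$ok_b    <- out$b_printed == out$b_recomputed
  out$ok_y7   <- out$y7_printed == out$y7_recomputed
  okcols <- c("ok_M", "ok_mNa", "ok_m2Na", "ok_b", "ok_y7")
  out$ok_row <- Reduce(`&`, out[okcols])
  attr(out, "pass_rate") <- mean(as.matrix(out[okcols]))
  attr(out, "discrepancies") <- out[!out$ok_row, , drop = FALSE]
  out
}
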