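# Peak lists and their file formats (MGF, two-column text).

#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values (Da), strictly positive.
#' @param intensity Numeric vector of intensities (arbitrary units);
#'   defaults to 1.
#' @param level Spectrum level: `"full_scan"` or `"ms2_of_y7"`.
#' @param precursor_mz Optional precursor m/z (for MS2, the selected y7).
#' @param tolerance Matching tolerance in Da used when reading ladders from
#'   this list.  The default 0.3 Da suits ion-trap full scans; use
#'   `tolerance = 0.01` for Orbitrap-style data.
#' @return An object of class `peak_list` (data.frame with `mz`,
#'   `intensity`, sorted ascending by m/z, plus attributes).
#' @export
peak_list <- function(mz, intensity = NULL, level = c("full_scan",
                      "ms2_of_y7"), precursor_mz = NULL, tolerance = 0.3) {
  level <- match.arg(level)
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  stopifnot(length(mz) == length(intensity), all(mz > 0), tolerance > 0)
  o <- order(mz)
  x <- data.frame(mz = mz[o], intensity = intensity[o])
  structure(x, class = c("peak_list", "data.frame"),
            level = level, precursor_mz = precursor_mz,
            tolerance = tolerance)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list: %d peaks, level %s, tolerance %g Da%s\n",
              nrow(x), attr(x, "level"), attr(x, "tolerance"),
              if (!is.null(attr(x, "precursor_mz")))
                sprintf(", precursor %.4f", attr(x, "precursor_mz")) else ""))
  NextMethod()
}

peaks_near <- function(pl, target, tolerance) {
  which(abs(pl$mz - target) <= tolerance)
}

#' Read and write MGF peak lists
#'
#' Minimal Mascot Generic Format support: one `BEGIN IONS` block per
#' spectrum with optional `TITLE`, `PEPMASS` and `LEVEL` headers followed by
#' `m/z intensity` lines.
#'
#' @param path File path.
#' @param tolerance Tolerance attached to the returned peak lists.
#' @return `read_mgf`: a list of `peak_list` objects; `write_mgf`: `path`,
#'   invisibly.
#' @export
read_mgf <- function(path, tolerance = 0.3) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grep("=", block, value = TRUE, fixed = TRUE)
    pk <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, `[`, "", 2L)
    prec <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1L]][1L])
    } else NULL
    lvl <- if ("LEVEL" %in% keys) vals[match("LEVEL", keys)] else "full_scan"
    mat <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(p)
      as.numeric(p[1:2])))
    out[[i]] <- peak_list(mat[, 1L], mat[, 2L], level = lvl,
                          precursor_mz = prec, tolerance = tolerance)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NULL
    attr(out[[i]], "title") <- title
  }
  out
}

#' @rdname read_mgf
#' @param spectra A `peak_list` or list of them.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "peak_list")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (pl in spectra) {
    writeLines("BEGIN IONS", con)
    title <- attr(pl, "title")
    if (!is.null(title)) writeLines(paste0("TITLE=", title), con)
    prec <- attr(pl, "precursor_mz")
    if (!is.null(prec)) writeLines(sprintf("PEPMASS=%.5f", prec), con)
    writeLines(paste0("LEVEL=", attr(pl, "level")), con)
    writeLines(sprintf("%.5f %.3f", pl$mz, pl$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a two-column whitespace-delimited peak list
#'
#' @inheritParams peak_list
#' @param path File path; lines of `m/z intensity` (intensity optional).
#' @return A `peak_list`.
#' @export
read_peaks_txt <- function(path, level = "full_scan", precursor_mz = NULL,
                           tolerance = 0.3) {
  tab <- utils::read.table(path)
  intensity <- if (ncol(tab) >= 2L) tab[[2L]] else rep(1, nrow(tab))
  peak_list(tab[[1L]], intensity, level = level,
            precursor_mz = precursor_mz, tolerance = tolerance)
}
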