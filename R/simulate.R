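# Synthetic spectra and strain-profile matrices with the statistical
# structure the analysis assumes, so every stage can be exercised without
# instrument data.

# run code under a local RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for simulation", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spectrum simulation configuration
#'
#' @param noise_sigma Gaussian m/z jitter in Da (default 0.02, a typical
#'   ion-trap mass accuracy).
#' @param dropout_p Per-peak omission probability in \[0, 1\].
#' @param n_decoys Number of uniform random decoy peaks added to each list.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model
#'   (intensities are cosmetic; the reader is intensity-agnostic).
#' @param seed Integer seed; mandatory, so simulations are reproducible.
#' @return A list of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(noise_sigma = 0.02, dropout_p = 0,
                                n_decoys = 0, intensity_meanlog = 10,
                                intensity_sdlog = 1, seed) {
  stopifnot(noise_sigma >= 0, dropout_p >= 0, dropout_p <= 1, n_decoys >= 0)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(list(noise_sigma = noise_sigma, dropout_p = dropout_p,
                 n_decoys = as.integer(n_decoys),
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 seed = as.integer(seed)),
            class = "spectrum_sim_config")
}

#' Simulate the full-scan and y7 MS2 peak lists of a peptaibol
#'
#' Emits the ion inventory observed for these compounds: the sodiated
#' precursors \[M+Na\]+ and \[M+2Na\]2+, the N-terminal b series b1 up to
#' the diagnostic pre-Pro b ion (skipping the b ion ending at the R7 Gln,
#' which is never observed because of the stable Gln-Aib bond), the y7
#' fragment, and, in the MS2 list, the y1-y6 ladder of the y7 fragment.
#' b ions are emitted in the protonated convention matching the printed
#' series.  Gaussian m/z jitter, dropout and uniform decoy peaks are applied
#' under the config seed.
#'
#' @param seq A [peptaibol_sequence()].
#' @param config A [spectrum_sim_config()].
#' @param tolerance Tolerance attached to the returned peak lists.
#' @return A list with elements `full_scan` and `ms2` ([peak_list()]s); the
#'   MS2 list carries the theoretical y7 as `precursor_mz` (jittered under
#'   the same noise model).
#' @export
simulate_spectrum <- function(seq, config, tolerance = 0.3) {
  stopifnot(inherits(seq, "peptaibol_sequence"),
            inherits(config, "spectrum_sim_config"))
  M <- neutral_mass(seq)
  res <- internal_tokens(seq)
  pre_pro <- pre_pro_b_index(seq)
  # position of the Gln of the stable Gln-Aib bond (label R7)
  gln_pos <- match("R7", seq$labels) - 1L
  b_idx <- setdiff(seq_len(pre_pro), gln_pos)
  full_theory <- c(
    adduct_mz(M, "Na"),
    adduct_mz(M, "2Na"),
    vapply(b_idx, function(n) b_ion(seq, n), 0),
    y_ion(seq, 7)
  )
  y7 <- y_ion(seq, 7)
  ms2_theory <- vapply(1:6, function(k) y_ion(seq, k), 0)

  with_seed(config$seed, {
    jitter <- function(mz) mz + stats::rnorm(length(mz), 0, config$noise_sigma)
    keep <- function(n) stats::runif(n) >= config$dropout_p
    build <- function(theory, level, precursor = NULL) {
      mz <- jitter(theory)
      mz <- mz[keep(length(mz))]
      if (config$n_decoys > 0L && length(theory) > 0L) {
        mz <- c(mz, stats::runif(config$n_decoys, 100,
                                 max(theory) * 1.05))
      }
      if (length(mz) == 0L) {
        return(structure(data.frame(mz = numeric(0), intensity = numeric(0)),
                         class = c("peak_list", "data.frame"), level = level,
                         precursor_mz = precursor, tolerance = tolerance))
      }
      inten <- stats::rlnorm(length(mz), config$intensity_meanlog,
                             config$intensity_sdlog)
      peak_list(mz, inten, level = level, precursor_mz = precursor,
                tolerance = tolerance)
    }
    full <- build(full_theory, "full_scan")
    ms2 <- build(ms2_theory, "ms2_of_y7",
                 precursor = y7 + stats::rnorm(1, 0, config$noise_sigma))
    list(full_scan = full, ms2 = ms2)
  })
}

#' Simulate a block-structured strain production matrix
#'
#' Generates a compounds-by-strains matrix of semi-quantitative production
#' levels in which strains fall into blocks sharing a production template
#' (a random on/off pattern scaled by `separation`), jittered per strain.
#' This emulates the structure of producer-profile matrices in which groups
#' of related species share which compounds they produce; it does not model
#' chromatographic quantification noise beyond the level jitter.
#'
#' @param n_strains Number of strains (columns).
#' @param n_compounds Number of compounds (rows).
#' @param n_blocks Number of planted strain blocks (default 2).
#' @param separation Production level of an "on" compound (default 5).
#' @param jitter_sigma Within-block level jitter (default 0.1).
#' @param seed Integer seed (mandatory).
#' @return A list with `matrix` (rows named compound_i, columns strain_j)
#'   and `partition` (named integer vector: planted block per strain).
#' @export
simulate_profiles <- function(n_strains, n_compounds, n_blocks = 2,
                              separation = 5, jitter_sigma = 0.1, seed) {
  stopifnot(n_blocks <= n_strains, n_blocks >= 1)
  with_seed(seed, {
    repeat {
      templates <- matrix(stats::rbinom(n_blocks * n_compounds, 1, 0.5),
                          nrow = n_compounds) * separation
      if (n_blocks == 1L || !anyDuplicated(t(templates))) break
    }
    block <- sort(rep_len(seq_len(n_blocks), n_strains))
    m <- sapply(seq_len(n_strains), function(j) {
      pmax(0, templates[, block[j]] +
             stats::rnorm(n_compounds, 0, jitter_sigma))
    })
    dimnames(m) <- list(paste0("compound_", seq_len(n_compounds)),
                        paste0("strain_", seq_len(n_strains)))
    list(matrix = m,
         partition = stats::setNames(block, colnames(m)))
  })
}
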