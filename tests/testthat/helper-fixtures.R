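# Shared fixtures and independent oracles used across the test files.

# compound tables are parsed once per test run
fixture_tables <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- load_compound_tables()
    tbl
  }
})

fixture_catalog <- local({
  cat <- NULL
  function() {
    if (is.null(cat)) cat <<- read_reference_catalog()
    cat
  }
})

fixture_seq <- function(name) {
  tbl <- fixture_tables()
  i <- match(name, tbl$name)
  stopifnot(!is.na(i))
  tbl$seq[[i]]
}

catalog_seq <- function(name) {
  cat <- fixture_catalog()
  i <- match(name, cat$name)
  stopifnot(!is.na(i))
  cat$seq[[i]]
}

# random valid collapsed 20-unit chain (for property tests)
random_chain <- function(alphabet = c("Aib", "Ala", "Gly", "Vxx", "Lxx",
                                      "Gln", "Glu", "Pro", "Ser")) {
  res <- sample(setdiff(alphabet, "Pro"), 19, replace = TRUE)
  res[14] <- "Pro"  # single Pro, as in the compound families studied
  peptaibol_sequence(c("Ac", res, "Pheol"))
}

# independent brute-force complete-linkage oracle: at each step merge the
# pair of clusters with the smallest maximum pairwise member distance
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in 1:(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    heights <- c(heights, best$h)
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
    partitions[[length(partitions) + 1L]] <- lapply(clusters, identity)
  }
  list(heights = heights, partitions = partitions)
}

# canonical string form of a partition (list of index vectors or a
# membership vector), for order-insensitive comparison
canonical_partition <- function(x) {
  if (!is.list(x)) x <- split(seq_along(x), x)
  groups <- vapply(lapply(x, sort), paste, "", collapse = ",")
  paste(sort(groups), collapse = "|")
}

# simulate + read + assemble one fixture sequence, returning the call
round_trip_call <- function(seq, seed, noise_sigma = 0.02, dropout_p = 0,
                            n_decoys = 0) {
  cfg <- spectrum_sim_config(noise_sigma = noise_sigma,
                             dropout_p = dropout_p, n_decoys = n_decoys,
                             seed = seed)
  sim <- simulate_spectrum(seq, cfg)
  n_call <- read_n_terminus(sim$full_scan)
  c_call <- read_c_terminus(sim$ms2)
  assemble_call(n_call, c_call,
                precursor_mz = adduct_mz(neutral_mass(seq), "2Na"))
}
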