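# De novo ladder reading from simulated peak lists.

test_that("noise-free round trips recover the collapsed chains, bridging
           the missing b ion at the Gln-Aib bond", {
  for (nm in c("Pept-A-Ia", "Pept-B-VI", "Pept-B-LIX", "Brevicelsin-I",
               "Brevicelsin-IV")) {
    s <- fixture_seq(nm)
    call <- round_trip_call(s, seed = 7)
    expect_true(call$complete, info = nm)
    expect_identical(call_to_sequence(call)$chain,
                     collapse_sequence(s)$chain, info = nm)
    expect_match(call$provenance[["R7"]], "composite", info = nm)
    expect_match(call$provenance[["R8"]], "composite", info = nm)
    if (has_r6_vacancy(s)) {
      expect_identical(call$assignments[["R6"]], "(vacant)", info = nm)
    }
  }
})

test_that("the simulator never emits the b ion ending at the R7 Gln", {
  s <- fixture_seq("Pept-A-Ia")
  sim <- simulate_spectrum(s, spectrum_sim_config(noise_sigma = 0, seed = 1))
  b7 <- b_ion(s, 7)
  expect_false(any(abs(sim$full_scan$mz - b7) < 0.5))
  # but b6 and b8 are present
  expect_true(any(abs(sim$full_scan$mz - b_ion(s, 6)) < 1e-6))
  expect_true(any(abs(sim$full_scan$mz - b_ion(s, 8)) < 1e-6))
})

test_that("peak lists lacking ladder ions give empty calls with
           diagnostics", {
  empty_full <- peak_list(c(400.123, 900.456), level = "full_scan")
  n_call <- read_n_terminus(empty_full)
  expect_length(n_call$assignments, 0)
  expect_match(n_call$diagnostics, "no b1 candidate")
  empty_ms2 <- peak_list(numeric(0), level = "ms2_of_y7",
                         precursor_mz = 774.45)
  c_call <- read_c_terminus(empty_ms2)
  expect_length(c_call$assignments, 0)
  expect_match(c_call$diagnostics, "empty")
})

test_that("the y7 MS2 read identifies the alcohol, the y ladder and the
           Pro residual", {
  s <- fixture_seq("Pept-A-Ia")
  sim <- simulate_spectrum(s, spectrum_sim_config(noise_sigma = 0, seed = 3))
  call <- read_c_terminus(sim$ms2)
  expect_identical(unname(call$assignments[paste0("R", 14:20)]),
                   c("Pro", "Vxx", "Aib", "Aib", "Gln", "Gln", "Pheol"))
  # the simulated precursor agrees with the printed y7 selection value
  expect_identical(floor_to_tenth(attr(sim$ms2, "precursor_mz")), 774.4)
})

test_that("under peak dropout, recovered positions are a subset of the
           correct positions (no hallucinated assignments)", {
  tbl <- fixture_tables()
  n_wrong <- 0L
  for (i in 1:100) {
    s <- tbl$seq[[(i - 1L) %% nrow(tbl) + 1L]]
    truth <- collapse_sequence(s)
    call <- round_trip_call(s, seed = 5000 + i, dropout_p = 0.1)
    asn <- call$assignments
    asn <- asn[!is.na(asn) & asn != "(vacant)"]
    if (isTRUE(call$complete)) {
      rec <- call_to_sequence(call)$chain
      n_wrong <- n_wrong +
        (length(rec) != length(truth$chain) || any(rec != truth$chain))
    } else {
      # partial N-terminal ladders are reported in the provisional frame:
      # compare the ladder prefix to the true chain prefix
      n_lab <- grep("^R(1[0-3]|[1-9])$", names(asn), value = TRUE)
      ladder <- asn[n_lab[order(as.integer(sub("R", "", n_lab)))]]
      truth_res <- truth$chain[-c(1L, length(truth$chain))]
      n_wrong <- n_wrong + sum(ladder != truth_res[seq_along(ladder)])
      # C-terminal labels are anchored at the terminus and must agree
      for (lab in intersect(names(asn), paste0("R", 14:20))) {
        i <- match(lab, truth$labels)
        n_wrong <- n_wrong + (is.na(i) || asn[[lab]] != truth$chain[i])
      }
    }
  }
  expect_equal(n_wrong, 0)
})

test_that("enlarging the tolerance never removes a correct ladder step", {
  for (nm in c("Pept-A-Va", "Brevicelsin-III")) {
    s <- fixture_seq(nm)
    sim <- simulate_spectrum(s, spectrum_sim_config(seed = 11))
    narrow <- read_n_terminus(sim$full_scan, tolerance = 0.1)
    wide <- read_n_terminus(sim$full_scan, tolerance = 0.3)
    expect_true(length(wide$assignments) >= length(narrow$assignments))
    common <- seq_along(narrow$assignments)
    expect_identical(unname(wide$assignments[common]),
                     unname(narrow$assignments[common]))
  }
})

test_that("a wrong residue breaks mass closure with the expected residual", {
  s <- fixture_seq("Pept-A-Ia")
  mutant <- s
  mutant$chain[which(mutant$chain == "Ala")[1]] <- "Aib"  # +14.016 Da
  sim <- simulate_spectrum(mutant, spectrum_sim_config(noise_sigma = 0,
                                                       seed = 2))
  call <- assemble_call(read_n_terminus(sim$full_scan),
                        read_c_terminus(sim$ms2),
                        precursor_mz = adduct_mz(neutral_mass(s), "2Na"))
  expect_false(call$complete)
  expect_equal(call$closure_residual, 14.01565, tolerance = 1e-3)
})

test_that("all three precursor interpretations close to the same mass", {
  s <- fixture_seq("Pept-B-VI")
  M <- neutral_mass(s)
  sim <- simulate_spectrum(s, spectrum_sim_config(noise_sigma = 0, seed = 4))
  for (ad in c("H", "Na", "2Na")) {
    call <- assemble_call(read_n_terminus(sim$full_scan),
                          read_c_terminus(sim$ms2),
                          precursor_mz = adduct_mz(M, ad))
    expect_true(call$complete)
    expect_lt(call$closure_residual, 1e-6)
  }
})

test_that("MGF output round-trips peak lists", {
  s <- fixture_seq("Pept-A-Ia")
  sim <- simulate_spectrum(s, spectrum_sim_config(seed = 9))
  tmp <- tempfile(fileext = ".mgf")
  write_mgf(list(sim$full_scan, sim$ms2), tmp)
  back <- read_mgf(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$mz, sim$full_scan$mz, tolerance = 1e-5)
  expect_identical(attr(back[[2]], "level"), "ms2_of_y7")
  expect_equal(attr(back[[2]], "precursor_mz"),
               attr(sim$ms2, "precursor_mz"), tolerance = 1e-5)
})
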