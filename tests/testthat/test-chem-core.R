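# Residue registry and mass/ion arithmetic.

test_that("registry is well-formed and collapse classes are shared", {
  reg <- residue_registry()
  expect_false(anyDuplicated(reg$code) > 0)
  expect_true(all(reg$mono_mass > 0))
  expect_identical(unique(collapse_tokens(c("Val", "Iva", "Vxx"))), "Vxx")
  expect_identical(unique(collapse_tokens(c("Leu", "Ile", "Lxx"))), "Lxx")
  # collapsing is idempotent
  toks <- reg$code
  expect_identical(collapse_tokens(collapse_tokens(toks)),
                   collapse_tokens(toks))
})

test_that("neutral mass reproduces printed table values and trivial sums", {
  expect_identical(neutral_mass(fixture_seq("Pept-A-Ia"), printed = TRUE),
                   1922)
  expect_identical(neutral_mass(fixture_seq("Pept-B-IXa"), printed = TRUE),
                   1908)
  # a bare cap + alcohol pair is the sum of two registry constants
  m <- sum(c(42.01057, 151.09971))
  reg <- residue_registry()
  expect_equal(unname(sum(reg$mono_mass[match(c("Ac", "Pheol"), reg$code)])),
               m, tolerance = 1e-9)
})

test_that("unknown residue codes are fatal with the offending token", {
  expect_error(peptaibol_sequence(c("Ac", rep("Aib", 18), "Bogus", "Pheol")),
               "Bogus")
})

test_that("adduct m/z printing conventions match the tables", {
  M_Ia <- neutral_mass(fixture_seq("Pept-A-Ia"))
  expect_identical(adduct_mz(M_Ia, "Na", printed = TRUE), 1945)
  M_IIa <- neutral_mass(fixture_seq("Pept-A-IIa"))
  expect_identical(adduct_mz(M_IIa, "2Na", printed = TRUE), 984.5)
  expect_equal(adduct_mz(1000, "H"), 1001.00728, tolerance = 1e-9)
  expect_error(adduct_mz(1000, "2Na", charge = 1), "charge")
})

test_that("b ions follow the protonated convention and floor printing", {
  expect_identical(b_ion(fixture_seq("Pept-A-IVa"), 13, printed = TRUE), 1163)
  # hand oracle: Ac + Aib + H = 42.01057 + 85.05276 + 1.00783 = 128.068
  expect_identical(b_ion(fixture_seq("Pept-A-Ia"), 1, printed = TRUE), 128)
  expect_equal(b_ion(fixture_seq("Pept-A-Ia"), 1), 128.07116,
               tolerance = 1e-5)
  expect_error(b_ion(fixture_seq("Pept-A-Ia"), 25), "out of range")
})

test_that("the diagnostic b ion ends one unit before the single Pro", {
  expect_identical(pre_pro_b_index(fixture_seq("Pept-A-Ia")), 13L)
  brev <- fixture_seq("Brevicelsin-I")
  expect_identical(pre_pro_b_index(brev), 12L)
  expect_identical(b_ion(brev, pre_pro_b_index(brev), printed = TRUE), 1078)
  no_pro <- peptaibol_sequence(c("Ac", rep(c("Aib", "Ala"), 9), "Aib",
                                 "Pheol"))
  expect_error(pre_pro_b_index(no_pro), "no Pro")
})

test_that("y ions use the single-hydrogen convention", {
  ia <- fixture_seq("Pept-A-Ia")
  expect_identical(y_ion(ia, 7, printed = "integer"), 774)
  expect_identical(y_ion(ia, 7, printed = "tenth"), 774.4)
  expect_identical(y_ion(fixture_seq("Pept-A-IIIa"), 7, printed = "integer"),
                   788)
  # y1 of any Pheol-terminated chain: 151.09971 + 1.00783
  expect_equal(y_ion(ia, 1), 152.10754, tolerance = 1e-5)
  expect_error(y_ion(ia, 0), "out of range")
})

test_that("residue class lookup from mass deltas", {
  expect_identical(residue_from_delta(85.05, 0.3),
                   list(tokens = "Aib", status = "assigned"))
  expect_identical(residue_from_delta(99.07, 0.3)$tokens, "Vxx")
  comp <- residue_from_delta(213.11, 0.3)
  expect_identical(comp$tokens, c("Gln", "Aib"))
  expect_identical(comp$status, "composite")
  expect_identical(residue_from_delta(500, 0.3)$status, "unassigned")
  amb <- residue_from_delta(86, 1.2)  # Aib (85.05) and Ser (87.03) both fit
  expect_identical(amb$status, "ambiguous")
  expect_setequal(amb$tokens, c("Aib", "Ser"))
})

test_that("substitution arithmetic shifts the exact mass by the residue
           mass difference", {
  set.seed(42)
  shifts <- c(Gln_Glu = 0.98402, Ala_Aib = 14.01565,
              Aib_Vxx = 14.01565, Vxx_Lxx = 14.01565)
  pairs <- list(c("Gln", "Glu"), c("Ala", "Aib"), c("Aib", "Vxx"),
                c("Vxx", "Lxx"))
  for (rep in 1:20) {
    s <- random_chain()
    for (k in seq_along(pairs)) {
      from <- pairs[[k]][1]; to <- pairs[[k]][2]
      pos <- which(s$chain == from)
      if (length(pos) == 0) next
      mutant <- s
      mutant$chain[pos[1]] <- to
      expect_equal(neutral_mass(mutant) - neutral_mass(s),
                   unname(shifts[k]), tolerance = 1e-4)
    }
  }
})

test_that("b and y series are strictly increasing", {
  s <- fixture_seq("Pept-B-VI")
  b <- vapply(1:19, function(n) b_ion(s, n), 0)
  y <- vapply(1:20, function(k) y_ion(s, k), 0)
  expect_true(all(diff(b) > 0))
  expect_true(all(diff(y) > 0))
})

test_that("recomputed mass quintuples match the printed tables and the
           diagnostic fragments partition the chain", {
  chk <- mass_table_check(fixture_tables())
  expect_gte(attr(chk, "pass_rate"), 0.95)
  ok <- chk[chk$ok_row, ]
  # b_diag and y7 together cover the chain plus two extra hydrogens
  excess <- ok$b_printed + ok$y7_printed - ok$M_printed
  expect_true(all(excess %in% 1:3))
})
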