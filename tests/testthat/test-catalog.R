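# Catalogue comparison: collapse, substitution lists, gap alignment,
# novelty verdicts and the text notation.

test_that("collapse maps isomer pairs onto one canonical chain", {
  a <- peptaibol_sequence(paste(c("Ac", "Aib", "Val", rep("Ala", 11), "Pro",
                                  rep("Ala", 4), "Leu", "Pheol"),
                                collapse = "-"))
  b <- peptaibol_sequence(paste(c("Ac", "Aib", "Iva", rep("Ala", 11), "Pro",
                                  rep("Ala", 4), "Ile", "Pheol"),
                                collapse = "-"))
  expect_identical(collapse_sequence(a)$chain, collapse_sequence(b)$chain)
  expect_identical(collapse_sequence(collapse_sequence(a))$chain,
                   collapse_sequence(a)$chain)
})

test_that("a chain compared with itself is identical at distance zero", {
  s <- fixture_seq("Pept-B-VI")
  r <- compare_chains(s, s)
  expect_identical(r$status, "identical")
  expect_identical(r$distance, 0L)
  expect_identical(nrow(r$substitutions), 0L)
  expect_true(is.na(r$gap_label))
})

test_that("substitution distance is a metric on equal-length collapsed
           chains", {
  set.seed(99)
  dist_of <- function(a, b) compare_chains(a, b)$distance
  for (rep in 1:15) {
    a <- random_chain(); b <- random_chain(); c <- random_chain()
    expect_identical(dist_of(a, a), 0L)
    expect_identical(dist_of(a, b), dist_of(b, a))
    expect_lte(dist_of(a, c), dist_of(a, b) + dist_of(b, c))
  }
})

test_that("golden novelty annotations reproduce the published notation", {
  cases <- list(
    list("Pept-A-Ia",   "Trichoaureocin 1d",    "identical"),
    list("Pept-A-IIa",  "Longibrachin B II",    "[Lxx]^12 → [Vxx]^12"),
    list("Pept-A-VIIb", "Trichoaureocin 1d",    "[Aib]^3 → [Vxx]^3"),
    list("Pept-A-VIIIb", "Longibrachin A I",    "[Aib]^3 → [Vxx]^3"),
    list("Pept-A-XVIII", "Longibrachin A IV",   "[Aib]^3 → [Vxx]^3"),
    list("Pept-A-XX",   "Longibrachin A III",   "[Aib]^3 → [Vxx]^3"),
    list("Pept-A-XIa",  "Longibrachin B II",    "[Aib]^3 → [Vxx]^3"),
    list("Pept-A-XVIb", "Trichosporin TS-B-VIa", "[Aib]^10 → [Ala]^10"),
    list("Pept-A-XIXb", "Trichosporin TS-B-VIa",
         "[Aib]^10 → [Ala]^10, [Gln]^18 → [Glu]^18"),
    list("Pept-B-I",    "Paracelsin B",         "[Aib]^3 → [Ala]^3"),
    list("Pept-B-IV",   "Paracelsin H",         "[Aib]^3 → [Ala]^3"),
    list("Pept-B-XXV",  "Paracelsin D",         "[Gln]^18 → [Glu]^18"),
    list("Pept-B-XXVI", "Paracelsin D",         "[Aib]^3 → [Vxx]^3"),
    list("Pept-B-XXVIII", "Paracelsin D",       "[Aib]^5 → [Vxx]^5"),
    list("Pept-B-XXXIIb", "Paracelsin H",       "[Ala]^6 → [Vxx]^6"),
    list("Pept-B-XLIII", "Paracelsin B",
         "[Aib]^5 → [Vxx]^5, [Ala]^6 → [Vxx]^6"),
    list("Pept-B-LIV",  "Paracelsin H",
         "[Aib]^5 → [Vxx]^5, [Ala]^6 → [Vxx]^6"),
    list("Pept-B-LIX",  "Paracelsin H",
         "[Aib]^3 → [Vxx]^3, [Aib]^5 → [Vxx]^5, [Ala]^6 → [Vxx]^6"),
    list("Brevicelsin-I",  "Paracelsin B", "gap at R6"),
    list("Brevicelsin-II", "Paracelsin B",
         "gap at R6, [Aib]^3 → [Vxx]^3"),
    list("Brevicelsin-IV", "Paracelsin H", "gap at R6"),
    list("Brevicelsin-V",  "Paracelsin H",
         "gap at R6, [Aib]^5 → [Vxx]^5"),
    list("Brevicelsin-VI", "Paracelsin B",
         "gap at R6, [Aib]^5 → [Vxx]^5")
  )
  for (cs in cases) {
    r <- compare_chains(fixture_seq(cs[[1]]), catalog_seq(cs[[2]]))
    expect_identical(r$rendered, cs[[3]],
                     info = paste(cs[[1]], "vs", cs[[2]]))
  }
})

test_that("the minimizing single deletion sits at R6 for every 19-residue
           compound against its nearest 20-residue reference", {
  c_tab <- parse_sequence_table(peptaibol_fixture("groupC"))
  catl <- fixture_catalog()
  for (i in seq_len(nrow(c_tab))) {
    reports <- lapply(catl$seq, function(ref)
      tryCatch(compare_chains(c_tab$seq[[i]], ref), error = function(e) NULL))
    reports <- Filter(Negate(is.null), reports)
    gaps <- vapply(reports, function(r)
      if (is.na(r$gap_label)) "" else r$gap_label, "")
    dists <- vapply(reports, function(r) r$distance, 0L)
    best <- which(dists == min(dists))
    expect_true(all(gaps[best] == "R6"), info = c_tab$name[i])
  }
})

test_that("novelty verdicts: known at distance zero, new otherwise, with
           ranked neighbours", {
  catl <- fixture_catalog()
  known <- classify_novelty(fixture_seq("Pept-A-IVa"), catl)
  expect_identical(known$verdict, "known")
  expect_identical(known$neighbors$name[1], "Longibrachin A I")
  expect_identical(known$neighbors$distance[1], 0L)

  near <- classify_novelty(fixture_seq("Pept-A-IIa"), catl)
  expect_identical(near$verdict, "new")
  expect_identical(near$neighbors$distance[1], 1L)
  expect_identical(near$neighbors$notation[1], "[Lxx]^12 → [Vxx]^12")

  # mutate four positions of a catalogue entry: no neighbour remains
  far <- catalog_seq("Paracelsin B")
  idx <- c(2, 4, 11, 19) + 1L  # internal positions, avoiding Pro
  far$chain[idx] <- c("Ser", "Ser", "Ser", "Ser")
  out <- classify_novelty(far, catl, max_subs = 3)
  expect_identical(out$verdict, "new")
  expect_identical(nrow(out$neighbors), 0L)
})

test_that("the rendered notation round-trips to the structured form", {
  r <- compare_chains(fixture_seq("Brevicelsin-II"),
                      catalog_seq("Paracelsin B"))
  back <- parse_substitutions(r$rendered)
  expect_identical(back$gap_label, r$gap_label)
  expect_identical(back$substitutions, r$substitutions)
  expect_identical(parse_substitutions("identical")$gap_label, NA_character_)
})

test_that("chains differing in length by more than one are rejected", {
  s20 <- fixture_seq("Pept-A-Ia")
  short <- s20
  short$chain <- short$chain[-c(3, 5)]  # 17 internal residues
  expect_error(compare_chains(short, s20), "more than one")
})
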