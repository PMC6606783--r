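# peptaibols

Identification and classification of 19- and 20-residue peptaibols from
electrospray mass spectra.

Peptaibols are linear fungal peptides built by non-ribosomal peptide
synthetases: acetylated at the N-terminus, ending in a 1,2-amino alcohol
(here phenylalaninol), and rich in the non-proteinogenic residues
α-aminoisobutyric acid (Aib) and isovaline. A single producer secretes
whole families of variants, and their sequences are read directly from
LC–MS data: full scans carry the sodiated precursors and an N-terminal
b-ion series (b1–b6 and b8–b13 — b7 is missing because the Gln–Aib bond
at R7–R8 is fragmentation stable), and an MS² spectrum of the conserved
C-terminal y7 fragment covers the rest of the chain. This package is for
natural-product and proteomics researchers who need that workflow as
tested, scriptable code.

It provides:

* **Mass calculus** on a pinned monoisotopic registry, with the printing
  conventions of the published compound tables: floored masses
  (`M = floor(Σ residues + cap + alcohol)`), `[M+Na]+` floored, `[M+2Na]2+`
  floored to 0.5 Da, y ions under a single-hydrogen convention
  (`y_k = Σ last k units + 1.00783`).
* **De novo reading** of b/y ion ladders with the composite 213.111 Da
  step across the missing b7, precursor closure under all three adduct
  interpretations, and detection of the R6 vacancy that marks the
  19-residue brevicelsins.
* **Catalogue comparison** on the collapsed Vxx/Lxx alphabet with
  substitution notation (`[Lxx]^12 → [Vxx]^12`), single-gap alignment and
  new-vs-known verdicts.
* **Nomenclature**: group A/B/C assignment and naming by elution order and
  abundance (Pept-A-IVa, Brevicelsin-I, ...).
* **Profile clustering** of strain × compound production matrices
  (Euclidean, complete linkage) with Newick export.
* **NRPS signature records**: binding-pocket codes vs detected residues,
  with explicit agreement rules.
* **Simulators** for spectra and producer profiles, so every stage is
  testable without instrument data.

## Worked example

```r
library(peptaibols)

ps <- peptaibol_sequence(
  "Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Ala-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol",
  name = "Pept-A-Ia")
mass_summary(ps)
#>    M_exact M_printed mNa_printed m2Na_printed mH_exact b_diag_printed
#> 1 1922.099      1922        1945          984 1923.106           1149
#>   y7_printed y7_1dp
#> 1        774  774.4
```

The exact neutral mass is 1922.099 Da, printed as 1922; its sodiated
adduct appears at m/z 1945, the doubly sodiated ion at 984, the
diagnostic b13 (everything before the Pro at R14) at 1149, and the y7
fragment at 774 (MS² selection value 774.4).

Simulate its spectra and read the sequence back:

```r
sim  <- simulate_spectrum(ps, spectrum_sim_config(seed = 1))
call <- assemble_call(read_n_terminus(sim$full_scan),
                      read_c_terminus(sim$ms2),
                      precursor_mz = adduct_mz(neutral_mass(ps), "2Na"))
call
#> sequence_call: 20 assigned position(s), complete
#>   R1=Aib R2=Ala R3=Aib R4=Ala R5=Aib R6=Ala R7=Gln R8=Aib R9=Vxx R10=Ala
#>   R11=Gly R12=Lxx R13=Aib R14=Pro R15=Vxx R16=Aib R17=Aib R18=Gln R19=Gln
#>   R20=Pheol
#>   closure residual 0.0000 Da ([M+2Na]2+)
```

All twenty positions are recovered (R7/R8 via the composite step) and the
assembled chain closes on the doubly sodiated precursor. Compare against
the packaged reference catalogue:

```r
catl <- read_reference_catalog()
classify_novelty(ps, catl)$neighbors[1:2, ]
#>                name distance            notation
#> 1 Trichoaureocin 1d        0           identical
#> 2  Longibrachin A I        1 [Aib]^10 → [Ala]^10

brev2 <- load_compound_tables()
brev2 <- brev2$seq[[match("Brevicelsin-II", brev2$name)]]
compare_chains(brev2, catl$seq[[match("Paracelsin B", catl$name)]])
#> match_report: Brevicelsin-II vs Paracelsin B -> variant (distance 2)
#>   gap at R6, [Aib]^3 → [Vxx]^3
```

The compound is identical to trichoaureocin 1d; the 19-residue
Brevicelsin-II differs from paracelsin B by the R6 deletion plus one
substitution.

See `vignettes/peptaibol-identification.Rmd` for the conventions, the
reader's design and its limitations.

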