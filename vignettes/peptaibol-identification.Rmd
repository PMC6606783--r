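---
title: "Identifying and classifying peptaibols from mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying peptaibols from mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptaibols)
```

## The problem

Peptaibols are linear, membrane-active fungal peptides assembled by
non-ribosomal peptide synthetases (NRPS). The 19- and 20-residue compounds
handled by this package carry an N-terminal acetyl cap, a C-terminal
1,2-amino alcohol (phenylalaninol in all packaged compounds), and are rich
in the non-proteinogenic residue α-aminoisobutyric acid (Aib) and its
isomer isovaline (Iva). Because a single NRPS accepts closely related
residues, one producer strain secretes large families of sequence variants
that must be read directly from LC–MS data: electrospray full scans show
sodiated precursors and an N-terminal b-ion series, and an MS² spectrum of
the conserved C-terminal y7 fragment covers the rest of the chain.

The package implements that identification workflow end to end: exact mass
and fragment-ion arithmetic, ladder-based sequence reading, comparison
against a catalogue of described compounds, group assignment and
elution-order nomenclature, clustering of strain production profiles, and
book-keeping of NRPS binding-pocket signatures against the residues
actually incorporated.

## Mass conventions

All arithmetic is monoisotopic, from a versioned registry
(`residue_registry()`) pinned to five decimals; nothing is looked up in
external element tables at run time. Three conventions are fixed because
they are the only ones that reproduce the printed values of the packaged
compound tables cell for cell:

* **Printed masses are floored**, not rounded: a neutral mass of
  1922.099 Da prints as 1922, a y7 of 774.447 prints as 774 (rounding
  would give 1922 but 774 → 774, and fails elsewhere, e.g. 1945.089 →
  1945 vs 1945.09 → 1945; flooring is verified across all 680 printed
  cells by `mass_table_check()`).
* **Doubly sodiated values use 0.5 Da resolution**: `[M+2Na]2+` is
  floored to the nearest half (984.531 → 984.5).
* **y ions add a single hydrogen** (+1.00783 Da), not two protons; this
  reproduces every printed y7 and the published MS² selection values
  (774.4, 775.4, 788.4, 789.4) via `floor_to_tenth()`.

Because MS cannot distinguish the isobaric pairs Val/Iva and Leu/Ile, all
sequence comparison operates on the collapsed alphabet (`Vxx`, `Lxx`);
stereochemistry is ignored throughout.

```{r}
ps <- peptaibol_sequence(
  "Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Ala-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol",
  name = "Pept-A-Ia")
mass_summary(ps)
```

## Reading a sequence from spectra

The reader follows the two-stage strategy the ion inventory dictates:

1. **N-terminus (R1–R13)** from the full scan: a b-ion ladder is grown
   from b1 by matching successive mass differences against the collapsed
   residue classes within a tolerance (default 0.3 Da, an ion-trap
   regime; 0.01 Da suits Orbitrap-style data). The b ion at R7 is never
   observed — the Gln–Aib bond at R7–R8 is fragmentation stable — so a
   composite step of 213.111 Da is accepted there and assigned as
   (Gln, Aib).
2. **C-terminus (R14–R20)** from the MS² spectrum of y7: the terminal
   amino alcohol is read from y1, residues R19…R15 from successive
   y-series differences, and R14 is fixed to Pro when the residual step
   to the y7 precursor matches 97.053 Da.

`assemble_call()` merges both partial calls, computes the neutral mass of
the assembled chain and closes it against the precursor, trying the
`[M+H]+`, `[M+Na]+` and `[M+2Na]2+` interpretations and keeping the one
with the smallest residual. A chain that closes with 18 internal residues
is a 19-unit compound and the vacancy is recorded at R6, the position
lost by internal module skipping in the brevicelsin-type compounds.
Partial calls are first class: unassignable positions stay unassigned,
ambiguous ladders are returned as ranked branches (by cumulative |Δm|)
rather than silently resolved, and co-eluting variants are left to the
caller as ranked alternatives.

Two exact mass degeneracies of this residue alphabet deserve note, because
they shaped the reader:

* Gln (128.0586) equals Gly + Ala to the fifth decimal. A single-residue
  Gln step in a b ladder is therefore indistinguishable from a Gly–Ala
  pair whose intermediate ion happens to be missing. Since the only Gln
  in the b-ion region of these compounds (R7) is never reachable by a
  single step anyway, the reader treats direct Gln steps as unassignable
  — a conservative ladder break instead of a possible hallucination.
* The composite 213.111 Da equals Ala+Ala+Ala and Ala+Gly+Aib. The
  composite step is therefore only accepted at chain positions 6–7,
  where the Gln–Aib bond sits in both 19- and 20-unit chains.

With these two rules, position recovery under simulated peak dropout is
strictly conservative: dropped peaks shorten calls but never corrupt
them, which the test suite asserts over 100 simulated spectra.

## Catalogue comparison and nomenclature

`compare_chains()` reports identity or a substitution list in the
20-residue label frame, rendered in the field's notation
(`[Lxx]^12 → [Vxx]^12`). A 19-unit chain against a 20-unit reference is
aligned by the single internal deletion minimising substitutions; ties
are broken to the **rightmost** minimiser, which places the gap at R6 for
every packaged 19-residue compound — deletions at R5 and R6 can tie when
the flanking residues repeat, and R6 is where the skipped NRPS module
sits. `classify_novelty()` declares a compound known only at distance
zero and otherwise lists neighbours within three differences, ascending.

Naming follows the published scheme: within a group, compounds sharing
the printed (M, diagnostic b, y7) triple are clustered into families by
retention-time proximity (single linkage, default threshold 0.5 min — a
reconstruction knob, since the generative rule behind the published
numbering is not recoverable); families receive Roman numerals by
elution order and members lowercase letters by decreasing abundance.
Group assignment: 19-unit chains are group C (brevicelsins); otherwise
R12 = Lxx gives group A, R12 ∈ {Aib, Ala} group B, and the ambiguous
R12 = Vxx is settled by a nearest-neighbour vote against labelled
prototype chains (ties to A). Only the group C ordering is asserted
against the published table; regenerating the full A/B numbering would
require the raw chromatograms.

## Profile clustering

Strain production matrices are clustered with Euclidean distances on the
strain columns and complete linkage, the settings used for the published
heat map. The implementation delegates to `stats::hclust` behind the
module surface and is verified in the test suite against an independent
brute-force oracle (200 seeded 6×6 matrices, merge heights and all
cut-level partitions). Columns are sorted by name before clustering so
results are input-order invariant; row scaling is off by default (raw
semi-quantitative levels) with an explicit option. The ordered matrix and
a Newick serialisation of the tree are the exported artefacts; image
rendering is out of scope.

## Synthetic data

`simulate_spectrum()` emits the exact theoretical ion inventory
(sodiated precursors, b1 up to the pre-Pro diagnostic ion minus the
missing b at R7, y7, and the y1–y6 MS² ladder) with Gaussian m/z jitter
(default σ = 0.02 Da), optional per-peak dropout and uniform decoys, all
under a mandatory seed. Intensities are cosmetic (log-normal): the
reader is intensity-agnostic apart from recording y7. What the simulator
does **not** model — isotope envelopes, chromatographic peak shapes,
chimeric co-elution, sodiated fragment series — bounds what the passing
round-trip tests can say about real data: they validate the reading
logic and mass arithmetic, not deconvolution of crowded spectra.

`simulate_profiles()` plants block-structured producer profiles (on/off
templates scaled by a separation of 5, jittered at σ = 0.1 by default —
the recovery-test conditions) and returns the ground-truth partition, so
cluster recovery can be scored. Real producer matrices are less cleanly
block structured; the planted model tests the machinery, not ecology.

Problem sizes used by the shipped tests: all 136 packaged compounds for
the mass-table and round-trip checks, 200 six-strain matrices for the
clustering oracle, and 100 seeded replicates for dropout and recovery
properties — sizes at which every property is exercised in seconds.

## Known limitations

* The reader is specialised to acetyl-capped 19/20-residue chains with a
  single Pro and the Gln–Aib bond anchored at R7–R8; other peptaibol
  families (shorter lipopeptaibols, multiple Pro) need a generalised
  ladder model.
* Catalogue comparison supports at most one internal deletion.
* Prediction/observation agreement for NRPS modules is reported per
  explicit rule (`subset_of_union`, `subset_of_first`,
  `nonempty_intersection`, with an optional Vxx/Lxx collapse) because no
  single natural rule is canonical; headline counts from the literature
  are deliberately not reproduced as a fixed target.
* mzML ingestion is an extension point; MGF and two-column text are the
  supported peak-list formats.
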