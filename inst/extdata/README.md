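# Packaged fixtures

- `residue_masses.tsv` — versioned residue registry: token code,
  monoisotopic mass (Da), unit class, collapse class. C-terminal amino
  alcohols carry the full unit mass of the condensed 1,2-amino alcohol.
- `table_groupA.tsv`, `table_groupB.tsv`, `table_groupC.tsv` — compound
  tables of the three published peptaibol groups (20-residue groups A and
  B; 19-residue brevicelsins, group C), transcribed verbatim from the
  source publication: compound name, printed M / [M+Na]+ / [M+2Na]2+ /
  diagnostic b / y7 values, retention time (min), N-cap and residues
  R1–R20 (`-` marks the R6 vacancy of group C). The `note` column keeps
  the first line of the published identity/novelty annotation. No
  transcription corrections were applied; every printed mass cell is
  reproduced by the package's mass arithmetic.
- `table_nrps.tsv` — NRPS adenylation-module records for the four
  sequenced species: position, 8-letter binding-pocket signature,
  predicted amino-acid sets of the two substrate predictors (semicolon
  separated; lowercase tokens are low-confidence calls preserved as
  printed), and the residues detected in the products.
- `reference_catalog.csv` — reference catalogue of previously described
  peptaibols, assembled from the table rows declared identical to named
  known compounds (name, hyphen-separated chain, citation). It is a
  working subset for novelty classification, not a reconstruction of the
  full historical peptaibiotics databases.
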