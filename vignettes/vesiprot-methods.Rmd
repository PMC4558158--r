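---
title: "Proteogenomic EV cargo analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic EV cargo analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiprot)
```

`vesiprot` turns a coding-variant table and per-sample peptide-spectrum
match (PSM) tables into per-compartment protein identifications, mutant
protein calls, spectral-count fold changes and gene-set enrichment results
for extracellular-vesicle (EV) studies. This vignette explains the models
behind each stage, the tunable parameters, what the synthetic-data module
does and does not emulate, and the choices we made where the design was
genuinely open.

## The analysis model

### Customized mutant database

The search database is the union of the wild-type proteome (one protein per
transcript model) and mutant entries derived from coding variants:

* **Substitutions.** A coding SNV is mapped through the transcript's CDS
  segments (strand-aware; minus-strand alleles are reverse-complemented)
  and its codon retranslated with the standard genetic code. Missense
  changes yield the full-length protein with the single substitution;
  stop gains yield the protein truncated before the new stop. Stop losses
  append the alternate residue at the former stop position — transcript
  models carry no 3'UTR sequence, so read-through beyond the first novel
  residue is not representable; such entries are rare and conservative.
  Synonymous and noncoding variants yield nothing. A variant overlapping
  several transcript isoforms produces one entry per isoform.
* **INDELs.** Up to `flank_nt` (default 150) reference bases on each side
  of the variant are fetched, the alternate allele is spliced in (the
  database must contain the *mutant* peptide sequence, so windows are built
  on the alternate allele, not the reference), and the window is translated
  in all six reading frames. Each frame is split at stop codons and
  fragments shorter than `min_fragment_aa` (default 7, the shortest
  confidently identifiable tryptic peptide) are dropped. Keeping *all*
  inter-stop fragments, rather than truncating at the first stop, matters
  because a frameshift's novel peptide may lie between two stops. Windows
  are built once per variant on the genomic sequence; for spliced models
  this means intron sequence can enter a window, which mirrors a
  genome-space window construction and is recorded in the run manifest.
* **Decoys.** Full sequence reversal with a `rev_` accession prefix,
  generated for the combined wild-type + mutant database. A PSM is a decoy
  only if *every* accession it maps to is a decoy; mixed hits count as
  target.

### Identification

PSMs are collapsed to their best-scoring match per peptide before FDR
estimation (filtering is at the peptide level). The decoy-based FDR,
`n_decoy / max(n_target, 1)`, is computed at every observed score, and the
operating point is the most permissive threshold with FDR strictly below
`peptide_fdr_max` (default 0.005). All spectra of retained peptides — not
just the collapsed best hits — feed spectral counting.

A peptide is *unique* if it maps to exactly one accession in the combined
database; isoleucine and leucine are treated as distinct residues (the
simplest rule; uniqueness under I/L equivalence would only shrink the
unique set). Proteins need `min_unique_peptides` (default 2) unique
peptides; their significant spectral count `s` includes shared spectra,
so column sums of a count matrix may exceed the sample total `T` — `T`
counts each retained spectrum once.

A mutant entry is *called* only when at least one retained peptide (a) is
absent from every wild-type protein and (b) for substitution entries,
covers the substituted residue. Without this evidence rule a combined
search would "identify" mutants from peptides shared with the wild type,
which is vacuous.

### Quantification

Relative abundance between samples X and Y uses the ratio of normalized
spectral counts with correction factor `c` (default 1.25):

$$\mathrm{RSc} = \frac{(s_Y + c)\,(T_X - s_X + c)}{(s_X + c)\,(T_Y - s_Y + c)}$$

Ratios below 1 are reported as the negative inverse, so \|signed\| ≥ 1
always and the value stays finite even at zero counts. Note the direction
of the formula as printed: the numerator carries sample *Y*'s count, so a
*negative* signed ratio means higher abundance in sample *X*. The default
`ratio_orientation = "as_printed"` maps signed ≥ `fold_change_min` to
"up in y" and ≤ −`fold_change_min` to "up in x"; a `"flipped"` switch swaps
the labels for readers who prefer the opposite convention, without touching
the numbers. Whether the 2-fold rule is applied to the raw or the signed
magnitude is immaterial: the two are reciprocal below 1, so
\|signed\| ≥ 2 ⇔ raw ≥ 2 or raw ≤ 0.5.

Exclusivity is decided by identification presence/absence after all
filters, not by raw zero counts, and takes precedence over the fold-change
classes; the remaining proteins are classified against `fold_change_min`
(default 2).

### Enrichment

For a query gene set against a categorized background, each category gives
a 2×2 table (query∩category, query∖category, background∩category minus the
overlap, remainder) over the background universe — all genes of the
background file, not all genes in existence. The test is uncorrected
Pearson chi-square with 1 df; no Yates correction, matching the default
reading of "chi-square test" and the large-table regime of real mutation
catalogues. Decisions use the raw p-value at `enrichment_alpha` (default
0.05) *and* require over-representation, since a depleted category is not
"enriched"; Benjamini–Hochberg q-values are appended for modern use but do
not drive the flag.

Expression backgrounds are built from library count tables by TPM
normalization (each library scaled to one million) and dense per-library
ranking, highest TPM first. The membership rule for an expression-derived
category is the top quantile of genes per library (default 25 %). The
original ranking procedure this emulates is not reconstructible in detail,
so the quantile rule is a documented stand-in and the quantile a visible
parameter.

## The synthetic study

`simulate_bundle()` generates the complete toy study used by the tests and
the acceptance script:

* **Reference.** One transcript per chromosome (default 50), CDS length
  300–900 nt with valid start, no internal stop, terminal stop; about half
  the models are split by a single 50–150 nt intron; strands alternate.
* **Variants.** Missense SNVs (codon-search for an amino-acid-changing
  base), synonymous SNVs (third-position codon-table search), and INDELs
  split between frameshift (1–2 nt) and in-frame (3 nt), all converted to
  genomic coordinates and alleles honoring strand.
* **Abundance.** Log-normal base abundance (sdlog 0.6 — a modest dynamic
  range so that every protein remains quantifiable at the simulated depth);
  per-protein spectral rates proportional to length × abundance.
* **Planted truth.** About 15 differential proteins with log2 folds of
  ±{1.5, 2, 2.5}, two exclusive proteins per compartment, and six secreted
  mutants (exosome-only / ectosome-only / both) chosen among mutant entries
  with at least two distinct variant-spanning tryptic peptides. A fold *f*
  is realized symmetrically (exosome ×2^(f/2), ectosome ×2^(−f/2)) and
  both differential and exclusive planting use abundance-matched
  opposite-sign pairs. This matters: at fixed sequencing depth only the
  *composition* of a sample is observable, so unbalanced planting shifts
  the per-sample rate sums and attenuates every observed ratio through the
  total-count normalizer. Balanced pairing keeps the planted fold equal to
  the expected observed fold without biasing the null proteins.
* **Spectra.** Per-sample counts are one multinomial draw of the sample
  depth (default 20,000) over protein rates; each spectrum samples a
  tryptic peptide (up to one missed cleavage, 7–35 residues) from its
  protein's digest. Correct matches score N(40, 6). A `decoy_fraction`
  (default 5 %) of spectra are incorrect matches scoring N(25, 6), split
  evenly between decoy hits and false target hits — the half that hits
  targets is what makes the decoy count an *estimator* of something real,
  so empirical FDR can be measured against the truth labels. Mutant
  entries emit only variant-spanning peptides, only in their planted
  compartments; exclusive proteins get zero spectra in the excluded
  compartment.

What the generator does *not* emulate: fragment-level spectra and search
engine scoring physics, retention time, intensity-based quantification,
peptide detectability differences (flyability), protein inference ambiguity
beyond shared tryptic peptides, and biological replicate variance. Passing
the recovery tests therefore demonstrates that the pipeline's logic is
correct under its own statistical assumptions, not that real EV data of
this size would behave as cleanly.

## Numerical and degenerate-case choices

* Variant normalization left-trims the shared allele prefix, then
  right-trims the shared suffix, making VCF-style anchored INDELs and
  minimal representations identical; the operation is idempotent.
* The FDR sweep with zero decoys warns and treats FDR as 0; zero targets
  is an error; if no threshold qualifies, the retained set is empty.
* `rsc` rejects counts outside 0 ≤ s ≤ T; a raw ratio of exactly 1 maps to
  signed +1 (not −1).
* Top-N ranking breaks ties lexicographically by accession so output is
  deterministic; requesting more proteins than exist returns all with a
  warning.
* A 2×2 table with a zero row or column marginal leaves chi-square
  undefined: `chi_square_2x2` errors, and `enrich_sets` reports such
  categories with `NA` statistics rather than failing the whole run.
* Six-frame translation of codons containing `N` yields `X`; fragments are
  compared against `min_fragment_aa` after stop-splitting.
* The pipeline writes every artifact through a temporary `.incomplete`
  file renamed on success, records MD5 checksums of all inputs plus the
  full configuration in `manifest.txt`, and is byte-for-byte reproducible
  for identical inputs and seed.

## Problem sizes used by the test suite

Unit tests run on references of 6–20 transcripts at depths of 500–2,000
spectra. The study-level checks use 50 transcripts at 20,000 spectra per
sample for parameter recovery, 10^5 random cases for the ratio
antisymmetry property, 1,000 random sequences against the brute-force
six-frame oracle, and 500 Monte-Carlo replicates for enrichment
calibration (null type-I error within two Monte-Carlo standard errors of
0.05; a five-fold over-represented category must be detected in ≥ 95 % of
replicates).

## Known limitations

* Splice-site, UTR and intergenic variant effects are out of scope; only
  coding variants produce database entries.
* Stop-gain mutants are usually uncallable by construction: every tryptic
  peptide of a truncated protein is a substring of the wild type, so no
  variant-spanning evidence can exist. This is a property of the evidence
  rule, not a defect — calling truncations from spectral absence would not
  be reliable.
* Protein-level FDR and parsimony grouping beyond the unique-peptide rule
  are not implemented; the identification contract is peptide-level FDR
  plus the 2-unique-peptide filter.
* The annotation format is the package's own minimal transcript-model TSV
  (`transcript_id`, `gene_symbol`, `chrom`, `strand`, semicolon-joined
  `start-end` CDS segments, 1-based inclusive); users coming from GTF need
  a one-off conversion of their CDS records.
* Enrichment treats gene-level membership only; it does not weight by
  per-gene mutation counts within a category.
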