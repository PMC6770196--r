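---
title: "Mining SNVs that create or destroy peroxisomal targeting signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SNVs that create or destroy peroxisomal targeting signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pts1var)
```

## The biological problem

Soluble proteins reach the peroxisomal lumen via the receptor PEX5, whose
TPR domain recognizes a C-terminal peroxisomal targeting signal 1 (PTS1).
The core of the signal is the last tripeptide of the protein — canonically
Ser-Lys-Leu (SKL) or conserved variants matched by the consensus
[S/A/C]-[K/R/H]-L — with the preceding residues modulating binding
strength. Because the signal occupies exactly the last three codons of the
coding sequence, a single nucleotide variant (SNV) landing there can have
two mirror-image effects:

* **Loss of function (LoF):** an SNV in a peroxisomal enzyme's tripeptide
  inactivates the signal, stranding the enzyme in the cytosol.
* **Gain of function (GoF):** an SNV in a normally cytosolic protein
  completes a functional tripeptide, depleting the protein from its place
  of action by importing it into peroxisomes.

`pts1var` implements the desk half of a screen for such variants: it maps
population-catalogue SNVs onto the last three codons of validated
protein-coding transcripts, classifies each tripeptide change, scores
C-termini with a position-specific scoring matrix (PSSM), pushes candidate
changes through two prioritization cascades, and quantifies how well two
kinds of predictions (binding-energy changes and PSSM category changes)
agree with experimental receptor-affinity measurements.

## Coordinate and sequence model

All genomic intervals are held 0-based half-open; 1-based VCF positions are
converted on read, and 1-based positions are restored in all written
tables. Chromosome names are compared after stripping an optional `chr`
prefix, because transcript catalogues and variant files disagree on the
dialect.

A transcript record carries its CDS as ordered genomic segments *including
the stop codon*. This inclusion is not guaranteed by upstream formats, so
it is validated rather than assumed: every record is spliced from the
genome, oriented by strand and translated; records whose translation does
not end in a stop are rejected with a distinct `missing_stop_codon` reason,
and records whose stored protein disagrees with the translation are
rejected as `translation_mismatch`. This makes the stop-codon assumption
self-checking — a record that violates it cannot silently flow downstream.
Transcripts encoding proteins shorter than three residues have no
C-terminal tripeptide in the sense used here; they are excluded and logged,
not treated as errors.

The C-terminal window of a transcript with protein length $P$ is the
spliced-CDS interval $[3(P-3),\,3P)$ — nine coding bases, never including
the stop codon, split into multiple genomic intervals wherever an exon
boundary falls inside it. Codons are indexed from the C-terminal end
(`codon_index` 1 = last residue, 3 = antepenultimate), so the tripeptide
string position is `4 - codon_index`. Each variant is applied on the
coding strand (complemented for minus-strand transcripts), the affected
codon is rebuilt in frame, and the change is classified as `synonymous`,
`stop_gained` or `missense`; only missense changes continue. Two SNVs in
the same codon are treated independently — no multi-nucleotide phasing is
attempted.

A variant allele is one `(chromosome, position, ref, alt)` key;
multi-allelic sites are decomposed into per-allele records, non-SNV
alleles are dropped and counted, and alleles present in both an exome and
a genome call set are merged into one record carrying both quality flags.
"Quality-passing" means a literal `PASS` in *either* call set. A REF base
that disagrees with the genome aborts the scan rather than skipping the
record; silent skips would corrupt every downstream count.

## The scoring model

A `pts1_matrix` holds additive score contributions for 12 window positions
by the 20 standard residues, plus two ordered thresholds. The score of a
12-residue C-terminus is the plain sum of its per-position entries, and
the category is

* **Targeted** if score ≥ `t_targeted`,
* **Twilight zone** if `t_twilight` ≤ score < `t_targeted`,
* **Not targeted** otherwise,

with a score exactly at a threshold joining the higher category — a
deterministic, documented tie-break. The matrix of the original published
predictor is not redistributable, so matrices are configuration, not
constants: the package defines a strict file format (header of 20
residues, 12 data rows, two threshold footer lines) and ships two
fixtures. `zero_pts1_matrix()` is a neutral placeholder;
`example_pts1_matrix()` rewards consensus membership at the three
tripeptide positions (5 / 4.5 / 4 within [S,A,C] and [K,R,H], 5 for the
terminal L) with thresholds (12, 7), chosen so that a fully canonical
tripeptide is always Targeted, exactly two matches land in the Twilight
zone, and at most one match is Not targeted. Published score differences
consumed by the concordance statistics are treated as externally supplied
inputs and never claimed to be reproduced by the bundled example matrix.

Proteins shorter than 12 residues are rejected rather than padded: the
screened proteome contains no such proteins, and any padding scheme would
be unverifiable. Only the 20 standard residues are supported;
selenocysteine and ambiguity codes are rejected.

## The two filter cascades

Both cascades are pure conjunctions of per-record predicates, so the
retained set is independent of input order; the *sequence* of stages only
affects where an excluded record is logged. The source procedure describes
its filters as applied concurrently without fixing an order, so the stage
orders here are a package decision, and per-stage in/out counts plus a
first-failing-stage exclusion log are always emitted to keep any
order-sensitive accounting visible.

**LoF cascade** (for inactivated signals): (1) gene on the curated list of
PTS1-carrying peroxisomal genes; (2) gene disease-linked (OMIM-style
flag); (3) localization contains the token `Peroxisome` and none of
`Secreted`, `Nucleus`, `Mitochondrion`, `Endosome`, `Cytoplasm`; (4)
variant quality-passing; (5) wild-type tripeptide canonical, mutant not.
Stage 3 honours a per-gene `manual_include` whitelist, generalizing the
known case of a peroxisomal enzyme whose *mutant* form carries a
mitochondrial annotation: rather than hard-coding one gene, any gene can
be whitelisted.

**GoF cascade** (for de novo signals): (1) quality-passing; (2)
localization contains `Cytoplasm` and none of `Secreted`, `Nucleus`,
`Mitochondrion`, `Endosome`, `Peroxisome`; (3) predicted category rises to
Targeted from Twilight zone or Not targeted; (4) per gene, only the
longest transcript carrying the variant (ties broken by lexicographically
smallest transcript id — deterministic); (5) protein shorter than 1000
residues and no annotated transmembrane domain. Transmembrane status is
consumed as an annotation flag, not predicted.

Keyword matching is exact-token and case-insensitive after trimming, so
`Cytoplasmic vesicle` does not match `Cytoplasm`. Free-text annotation
matching granularity is genuinely open; token matching is the stricter
choice and is flagged as such. Annotations propagate across isoforms:
isoform-specific annotations stay put, all other isoforms inherit the
canonical (longest) transcript's annotation, and genes with no canonical
annotation are excluded later with reason `unannotated` rather than
guessed at.

## Concordance statistics

For each experimentally measured pair, the relative affinity change is

$$\log K_a^{app}\ ratio = \log_{10}\!\left(\frac{K_a^{app}\,WT}{K_a^{app}\,MT}\right)$$

positive when the mutant binds PEX5 more weakly. Ratios are
scale-invariant, so affinities are used on whatever common scale they are
printed. Non-analyzable fits are flagged `NA` and excluded — never
zero-filled, since a zero would silently produce an infinite ratio.

`pearson_with_ci()` reports the product-moment correlation with a
two-sided p-value from the t-transform on $n-2$ degrees of freedom and a
95% confidence interval from the Fisher z-transform (the implementation is
`stats::cor.test`; the test-suite re-derives r, p and the interval by hand
as an independent check). P-values are reported to three significant
figures and no multiple-testing correction is applied — only two planned
correlations exist.

Binding-energy predictions are turned into three-way labels with a
significance band: a predicted change in binding free energy above
+0.5 kcal/mol predicts *loss*, below −0.5 kcal/mol predicts *gain*,
anything inside the band predicts *no change*. A verdict is correct when
the label equals the experimental outcome. On the packaged 11-row affinity
fixture this rule yields exactly 8 of 11 correct, and the per-record
verdict table is always emitted for audit because prose accountings of
such counts tend to narrate subsets differently. One fixture entry with
weak native punctate staining is labelled `no_change`, following the
source's own accounting of localization outcomes. The categorical
predictor concordance works the same way on the ordered category scale.

The printed log ratio of one fixture row (0.738 for the YKV→CKV pair)
cannot be recovered from its rounded affinity columns (they give 0.732),
implying unrounded inputs upstream; that row is therefore excluded from
exact-reproduction checks, though it participates in the correlations.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds a complete offline study: two toy chromosomes
(≥10 kb, random background), multi-exon transcripts on both strands with
introns of 30–200 nt, a variant file with PASS/fail flags and per-allele
frequencies, localization and gene-context tables, a curated gene list and
a truth table. Planted LoF variants sit in peroxisome-exclusive,
disease-flagged, curated genes with canonical tripeptides mutated to
non-canonical ones; planted GoF variants sit in cytoplasm-exclusive genes
where one substitution completes a canonical tripeptide (Twilight zone →
Targeted under the example matrix). Each decoy violates exactly one rule:
synonymous in-window changes, variants upstream of the window, and
quality-failing but otherwise perfect LoF candidates. Codons at planted
positions are chosen among synonymous codons one substitution away from
the designed mutant codon, so every planted event is a genuine
single-nucleotide substitution; byte-identical output for identical
config + seed is part of the contract, with separate sub-seeded streams
for sequence design, genome background, allele frequencies and
annotations.

Default condition sizes are deliberately small — 2 LoF + 2 GoF planted
events, one decoy per class, 12 genes of 25–60 residues, 1–4 exons, half
on the minus strand — enough to exercise every stage and both strands
while keeping a full pipeline run sub-second. What the generator does
*not* emulate: realistic allele-frequency spectra or mutational
signatures (frequencies are placeholders), isoform families sharing
exons, indels/MNVs, selenocysteine recoding, or annotation noise. Passing
tests on this material demonstrate coordinate arithmetic, strand handling
and filter logic; they say nothing about annotation quality or variant
calling in real catalogues, which the real pipeline inherits from its
inputs.

## Numerical and testing choices

* Degenerate inputs fail loudly: empty variant sources, zero-variance
  correlations, non-positive affinities, unknown chromosomes and REF
  mismatches are all errors, not warnings.
* The test-suite checks the variant mapper against an independent oracle —
  full splice, mutate, re-translate of the whole CDS — on 500 random
  transcripts per strand, and sweeps 20 generator seeds for exact
  planted-candidate recovery; interval coverage of the Fisher-z CI is
  verified at ρ = 0.7, n = 11 over 1000 replicates (accepting 93–97%).
  These problem sizes keep the whole suite under a minute while leaving
  the property space (strand × exon count × codon position) densely
  sampled.
* Genome-scale catalogue counts (tens of thousands of variants across the
  full proteome) require the original external downloads and are out of
  scope at desk scale; the property suites above are the stand-in.

## Known limitations

* The bundled matrices are fixtures; reproducing published predictor
  scores requires the original matrix, which is configuration the user
  must supply.
* Stop-loss variants (in the stop codon itself) are outside the window by
  construction and not analyzed.
* Variant effect annotations from external tools (pathogenicity
  predictions, clinical significance) are pass-through strings, never
  recomputed.
* The final manual choice of which retained candidates to test at the
  bench is human judgment; the cascades reproduce candidate pools, not
  that choice.
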