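---
title: "Methods: comparing venom-gland transcriptomes and proteomes"
author: "venomeCorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing venom-gland transcriptomes and proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomeCorr)
```

## The problem

A venom gland transcribes toxin genes and secretes the corresponding
proteins, and the two can be measured independently: transcript abundance by
RNA-seq, protein abundance by LC/MS peptide identification against a
database built from the transcripts themselves. Whether venom composition
can be read off the transcriptome is a quantitative question, and answering
it requires abundance measures on both levels that are comparable despite
very different sampling processes. This vignette describes the statistical
choices behind each stage of the pipeline and the synthetic data model used
to validate it.

## Transcript abundance: FPKM and the retention filter

Fragment counts grow with both molar abundance and transcript length, so
counts are normalized to fragments per kilobase per million:
$\mathrm{FPKM}_i = c_i \cdot 10^9 / (L_i N)$. Two choices deserve note:

* **Full transcript length** is used, not an effective length corrected for
  fragment size. The correction matters for short transcripts at small
  fragment sizes; at the coding lengths typical of venom transcripts
  (hundreds of nt and up) it is a second-order effect, and omitting it keeps
  the measure self-inverting (the conservation identity
  $\sum_i \mathrm{FPKM}_i L_i N / 10^9 = \sum_i c_i$ holds exactly, and is
  tested).
* **Boundary semantics**: transcripts with FPKM *strictly below* 1 are
  removed; a transcript at exactly 1.0 is retained. The filter is idempotent
  and monotone in the threshold.

## Protein abundance: fractionally attributed counts per residue

Spectral counting treats the number of peptide identification events as a
proxy for protein amount. Two biases need correction:

1. **Shared peptides.** Venom gene families are full of recent duplicates,
   so a peptide frequently occurs in several database entries. Each
   observation's count is divided by its multiplicity $m$ (the number of
   proteins containing the peptide as a substring) and credited equally to
   all of them. This conserves the total count exactly — a property the test
   suite asserts to $10^{-9}$ over randomized inputs — and has the
   documented consequence that duplicating a protein halves each copy's
   score.
2. **Length.** Longer proteins yield more candidate peptides, so the
   adjusted count is divided by the protein's *effective length* in residues
   (mature protein; an annotated signal peptide is excluded, since it is
   removed before secretion and its residues can never be observed in
   venom). The result is *peptides per residue*.

The score is **not** divided by the total number of identification events in
the experiment. Unlike sequencing reads, which compete for flow-cell
positions, chromatographically separated peptides are detected largely
independently of one another, so one protein's signal does not dilute
another's. Operationally this makes the score degree-1 homogeneous: doubling
every count doubles every score, which the suite verifies exactly (a
total-normalized score would fail it).

"Count" means identification events summed over runs and enzymes; counting
distinct peptide species instead is available via
`adjustedCounts(countMode = "species")`.

## Search space: six frames, three proteases

Assembled transcripts carry no frame annotation, so the search database is
built from all six reading frames, split at stop codons into stop-free
segments (`sixFrameTranslate`, `splitOrfs`). Digestion follows the stated
specificities — trypsin after R and K, chymotrypsin after F, L, W and Y,
Glu-C after D and E — with up to two missed cleavages by default, plus an
intact "no enzyme" route for naturally occurring peptides in undigested
venom. Defaults the data do not determine, stated here as this package's
choices:

* **Peptide length bounds 6–50 residues**, the range typically observable by
  LC/MS. Both bounds are configurable.
* **No proline suppression.** The common "no cleavage before P" refinement
  is off by default because the specificities above are bare residue sets;
  `prolineRule = TRUE` enables it.
* **Glu-C cleaves after both D and E** by default; the E-only dialect seen
  in some buffers is available (`glucEOnly = TRUE`).
* **I/L equivalence off** by default: database matching operates on sequence
  text, where I and L are distinct. Because mass spectrometry cannot
  distinguish the isobaric pair, `ilEquivalent = TRUE` merges them during
  matching.

Matching itself is exact substring containment, implemented with a prefix
k-mer index plus verification; the tests assert equality with a naive
all-substrings scan.

## The contaminant noise floor

Keratins and other cRAP-style contaminants enter every preparation and
should be present at much lower levels than genuine venom proteins, so their
abundance scores estimate the noise floor of the experiment. The threshold
is derived by bootstrap: resample the contaminant scores with replacement
(10,000 times by default), take the chosen statistic of each resample (mean
by default; median available), and use the upper bound of the percentile
interval at 99.9% confidence as the cutoff. Proteins scoring below it are
filtered; contaminants themselves never enter the retained biological set.

Numerical choices: percentiles use the inverse empirical CDF (quantile
type 1), so on small contaminant sets the interval coincides exactly with
the quantiles of the complete enumeration of all $n^n$ resamples — the test
suite checks this equivalence exhaustively for sets of up to four scores.
The phrase "confidence interval around the scores" is ambiguous between a
CI of the mean and a tolerance interval on the score distribution; the CI of
the mean is the default reading here (the conservative end is the *upper*
bound either way), and the median statistic covers the heavier-tailed
alternative.

## Correlation

Proteins passing *both* filters (source transcript FPKM ≥ 1 and score at or
above the contaminant threshold) are paired with their transcripts, both
axes are log10-transformed, and Pearson's r is computed with a two-sided
p-value from the t distribution on $n-2$ degrees of freedom. Log scale is
the default because both abundance measures span several decades and a
raw-scale r would be dominated by the top decade; identity and rank
(Spearman) transforms are options. Zeros cannot be logged and are excluded
and tallied rather than shifted by a pseudocount — an excluded-zero count is
part of the result object, and a pseudocount is available when retention of
zeros matters more than interpretability of the statistic.

## The synthetic venome generator

The generator exists so every stage above can be tested against known
ground truth. It emulates the statistical structure of a venom-gland study:

* **Abundances** are drawn log-uniform over six decades (the span venom
  transcriptomes exhibit) and normalized. The log-uniform prior is the
  simplest distribution matching that span; it is not the empirical mixture
  of toxin-class abundances, which is lumpier.
* **Transcripts** are random open reading frames (ATG start, stop-free body
  of sense codons, terminal stop), 300–1500 nt; each translates to one
  protein. No alternative splicing; shared-peptide ambiguity is induced
  instead by optional paralog pairs (duplicated proteins mutated to a
  configurable identity, default 90%).
* **Fragment counts** are one multinomial draw of $10^6$ fragments with
  probabilities proportional to abundance × length, so counts sum exactly to
  the configured total.
* **Contaminants** (20 by default) are random sequences with the amino-acid
  composition of coding sequence — contaminants are ordinary proteins, and
  giving them a uniform residue distribution would bias their cleavage-site
  density and hence their scores relative to the targets. They are placed at
  the 0.05 quantile of the biological abundance distribution ("much lower
  concentrations than target proteins", quantified as a choice here).
* **Peptide detection**: for each candidate peptide of each protein, the
  expected identification count is
  $\kappa\, a^{\gamma} e^{\mathcal{N}(0,\sigma)}$ and the realized count is
  Poisson. Defaults $\kappa = 500$ (about $5\times10^4$ identification
  events per run, the scale of a multi-run LC/MS experiment),
  $\gamma = 1$ (detection proportional to abundance) and $\sigma = 0.5$.
  $\gamma = 0$ is the built-in null in which detection carries no abundance
  information.

Everything is reproducible from a single seed; derived seeds separate the
generator, the fragment draw, the detection draw and the bootstrap so the
stages can be rerun independently.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: assembly fragmentation and chimerism,
per-peptide ionization and digestion efficiency differences (noise here is
i.i.d. per peptide, so it averages out over a protein's many peptides,
which is why recovered correlations on synthetic data run far higher than
real transcriptome-proteome correlations), post-translational modification,
protein turnover and the time lag between transcription and secretion, and
search-engine identification error. The recovery experiment validates the
*pipeline*, not the biology.

## Parameter recovery as the acceptance surface

`recoveryExperiment()` composes the whole chain (generate → fragment counts
→ FPKM → filter → detect → match → score → threshold → correlate) and
reports the log-log r alongside the correlations of each estimated axis
with the true abundances. At the documented scale — 300 transcripts, six
decades, $10^6$ fragments, noiseless proportional detection — the log-log r
is expected above 0.95; with abundance-independent detection it collapses
toward 0. `scripts/acceptance.R` runs exactly this, 20 seeds per arm, plus
one run under the noisy defaults. In the null arm the contaminant threshold
removes most proteins (contaminants are indistinguishable from targets by
construction there), so the surviving pair count is small and the null |r|
fluctuates accordingly; the script reports per-seed tallies rather than a
single pooled value.

## Reciprocal best hits

The robustness check aligns a de-novo protein set against a reference set
with Smith–Waterman local alignment (BLOSUM62, gap open 11, extend 1; a gap
of length $L$ costs $11 + L$) and keeps pairs that are unique best hits in
both directions with score ≥ 50. Ties are excluded rather than broken:
when a reference contains one representative for several close isoforms,
arbitrary tie-breaking would fabricate homology. The raw-score floor stands
in for a database-search E-value cutoff — E-value calibration depends on
database size and composition and adds nothing at the scale this module
addresses; the floor is documented so users know the criterion is not
BLAST-equivalent. Alignment scoring is delegated to Biostrings; the test
suite pins it to an independent dynamic program and, on very short
sequences, to exhaustive enumeration of all local alignments.

## Problem sizes and determinism

The shipped tests exercise the pipeline at 40–300 transcripts and the
acceptance script at 300 transcripts / $10^6$ fragments / 20 seeds per arm,
sizes chosen so the full suite and script each complete in minutes on one
core while the multinomial and Poisson layers still operate at realistic
depths. All randomness flows from explicit seeds through a local RNG scope
that never perturbs the caller's random state, and pipeline outputs are
byte-identical across reruns of the same configuration — file headers
record the package version, seed and a configuration hash, never a
timestamp.

## Known limitations

* Fractional attribution is the only protein-inference step; no parsimony
  or grouping logic merges indistinguishable proteins, so families of
  near-identical paralogs dilute each member's score.
* FPKM uses full transcript length; comparisons against effective-length
  FPKM from other tools will differ slightly for short transcripts.
* The score floor in the RBH module is not an E-value; scores are not
  comparable across substitution matrices or gap settings.
* The detection model's parameters ($\kappa$, $\gamma$, $\sigma$) are
  plausible, not calibrated to any instrument; conclusions about absolute
  detection rates should not be drawn from the generator.
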