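---
title: "Residue-level missense constraint profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level missense constraint profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrscape)
```

## The problem

Missense variants in intrinsically disordered regions (IDRs) are hard to
interpret: disordered sequence lacks a stable fold, is under-represented in
experimental structures and clinical annotation, and is served poorly by
predictors trained on globular domains. Regional constraint metrics offer a
complementary, annotation-free signal: where a population of hundreds of
thousands of exomes shows *fewer missense variants than the coding sequence
makes possible*, selection is removing them, and the region is likely
functional — whether or not it folds.

`mtrscape` computes the Missense Tolerance Ratio (MTR) at residue
resolution, assigns each residue one of four structural states (ordered,
disordered, structural transition, missing-in-structure), classifies
residues as Intolerant/Tolerant, and runs the downstream statistical
battery relating constraint to composition, segment patterning, and
clinical variant classes.

## The MTR model

For residue $i$, a window of $w = 31$ codons centred on $i$ (truncated at
the protein termini) collects:

* $O_m, O_s$ — observed missense and synonymous single-nucleotide variants
  (SNVs) in the window, counted from a population VCF restricted to
  `FILTER = PASS` SNVs, each distinct allele counted once regardless of
  frequency;
* $E_m, E_s$ — *possible* missense and synonymous changes, obtained by
  enumerating all $3L$ single-nucleotide substitutions of the window's
  coding sequence and classifying each by re-translation.

$$\mathrm{MTR}_i \;=\; \frac{O_m / (O_m + O_s)}{E_m / (E_m + E_s)}$$

MTR $\approx 1$ means missense variation is observed at the rate the
genetic code makes available; MTR $\ll 1$ means missense depletion, i.e.
constraint. Changes that create or remove a stop codon belong to neither
class and are excluded from both numerator and denominator, as is the
terminal stop codon itself (it encodes no residue to score). The expected
proportion is unweighted enumeration: no mutation-rate, CpG, or coverage
modelling.

Significantly intolerant residues are flagged with a one-sided exact
binomial test — the probability of observing $\le O_m$ missense among
$n = O_m + O_s$ variants when each is missense with probability
$E_m/(E_m+E_s)$ — followed by Benjamini–Hochberg adjustment. The test is
one-sided in the depletion direction because it is used solely to find
intolerant regions.

### Numerical and edge-case choices

* **Windows at termini are truncated, not dropped**, so every residue is
  scored and full-length profiles can be drawn.
* **Windows with zero observed variants give missing MTR** (class
  `Unclassified`), not a pseudo-counted score: a tolerance estimate from no
  data would be manufactured. `q_fdr` is likewise missing there.
* **Window semantics**: the per-residue window is the residue-centred
  31-codon window. A per-nucleotide 93-base window advanced one base at a
  time coincides with this at every codon's central base; since all outputs
  are per residue, only the residue-centred form is computed.
* **FDR family**: all tested residues of the run's gene set form one BH
  family by default (`fdr_family = "global"`); `"per_gene"` adjusts within
  each gene. Each p-value appears in exactly one family.
* **Threshold semantics** are exact: Intolerant is MTR $< 0.4$, Tolerant is
  MTR $\ge 0.4$, so 0.39 and 0.40 fall on opposite sides by construction.

## Structural states

Curated disorder, predicted (consensus) disorder, curated structural
transition, and structure-derived missing-residue annotations are painted
onto an all-`order` baseline. Overlaps resolve by precedence

`structural_transition > curated disorder > predicted disorder >
missing_residues > order`,

a declared choice (curated evidence outranks prediction; transition is the
most specific curated label) that is configurable via the `precedence`
argument. Predicted disorder is merged into the single `disorder` state so
reporting stays four-state. Genes with no annotations are ordered-only.
Painting in increasing precedence order makes the result independent of
the order annotations arrive in (property-tested).

## Residue and segment analytics

Residues with defined MTR are classified at the 0.4 threshold and joined
with states into one row per residue. Per state:

* **Composition**: for each amino acid, a 2×2 table of (this amino acid vs
  the other 19) × (Intolerant vs Tolerant), two-sided Fisher exact test,
  odds ratio with the Haldane–Anscombe correction (+0.5 to all four cells
  when any is zero) reported as log2 OR, BH within the state's 20 tests
  (mirroring per-state reporting). A state with an empty constraint class
  yields NA rows — with no Intolerant residues the contrast does not exist.
* **Biophysics**: mean side-chain charge (K/R $+1$, D/E $-1$, H $0$ by
  default — neutral-pH convention; $+0.1$ available via
  `histidine_charge`), mean Kyte–Doolittle hydropathy, aromatic (F/Y/W)
  fraction.
* **Segments**: maximal runs of consecutive residues sharing (gene, state,
  constraint class); `Unclassified` residues break runs without forming
  segments. Aromatic spacing is the mean distance between *consecutive*
  aromatics in segment-local coordinates, missing with fewer than two
  aromatics — a declared, fixed definition.
* **Δ contrasts**: Δ = mean(Intolerant) − mean(Tolerant) per property and
  state, with two-sided Mann–Whitney p.

## Statistical battery conventions

* **Fisher two-sided p** uses the probability-ordering rule (sum of tables
  with hypergeometric probability ≤ the observed table's, within the same
  1e-7 relative tolerance `stats::fisher.test` uses). It is computed
  directly from the hypergeometric pmf; unit tests cross-check against
  `stats::fisher.test` and an independent `choose()`-based enumeration.
* **Clinical enrichment** tests each structural state against all other
  states combined, per clinical class (pathogenic / benign / VUS after
  mapping raw strings; conflicting or other records are excluded), with BH
  across all state × class tests of the run and significance stars at
  q < 0.05 / 0.01 / 0.001.
* **Kruskal–Wallis + Dunn**: tie-corrected H; Dunn pairwise z from pooled
  ranks with tie correction; BH across pairs. The compact letter display
  assigns one letter per maximal clique of the non-significance graph, so
  two groups share a letter exactly when their adjusted p ≥ α; cliques are
  ordered by earliest group in input order for deterministic lettering.
* **Descriptive moments** use the bias-corrected ("type 2") definitions:
  adjusted Fisher–Pearson skewness and bias-corrected *excess* kurtosis;
  the conventions are recorded in the returned object because kurtosis
  scales are a chronic source of ambiguity.
* **Wilson intervals** use the closed-form score interval at
  $z = \Phi^{-1}(0.975)$; the two-proportion z-test uses the pooled
  estimate, with the degenerate pooled proportion (0 or 1) mapped to
  $z = 0$ with a warning.

## The synthetic-data generator

Real inputs for this analysis are population variant catalogs, clinical
variant tables, and disorder databases — none of which can be bundled. The
generator emulates their statistical structure so every stage is testable
and parameter recovery is checkable against planted truth:

* **Transcripts**: sense codons drawn independently (uniform by default;
  weights allow disorder-like composition), terminal stop appended — so no
  internal stops arise by construction. Default: 50 genes, lengths uniform
  on 300–700 residues.
* **Population variants**: each possible SNV allele is emitted
  independently with probability `p_obs` (default 0.15 — chosen to give
  realistic tens of observations per 31-codon window). This is a
  presence/absence model: MTR as defined uses distinct alleles, not
  frequencies, so no allele-frequency spectrum is modelled. Depletion
  regions multiply *missense* emission only by a retention factor
  $\delta \in [0,1]$, leaving synonymous variation as the neutral
  yardstick — the minimal model in which a region's expected MTR is
  δ-controlled. A configurable fraction (default 0.1) of extra non-PASS
  records exercises quality filtering.
* **Annotations**: per gene, each non-order state receives its configured
  residue share (defaults follow the reported residue composition of
  curated neurodevelopmental-disorder proteins: order 0.685, disorder
  0.250, missing 0.063, transition 0.002) laid out as contiguous blocks in
  shuffled order; some curated disorder blocks carry overlapping predicted
  sub-regions to exercise precedence.
* **Clinical labels**: variants sampled uniformly over residues; classes
  drawn from per-state probabilities solved (damped fixed point) so the
  realized state-vs-rest log2 odds ratios equal the planted targets
  (defaults +2 for pathogenic-in-order, −2 for pathogenic-in-disorder,
  mirroring the qualitative direction reported for real data). The truth
  table written beside the labels carries target and realized log2 OR for
  every cell, sufficient to score recovery without re-reading the config.

Every generator output is a pure function of (config, seed); each stage
derives its own deterministic stream so stages can be rerun independently.

**What passing synthetic tests do and do not show.** The generator has
uniform codon usage, site-independent observation, no mutation-rate
heterogeneity (no CpG effects), no coverage model, and no population
structure. Tests on it validate the *machinery* — enumeration, windowing,
test calibration, FDR bookkeeping, recovery of planted effects — not the
biological calibration of MTR on real cohorts, which depends on exactly the
features the generator omits.

## Problem sizes used in the checks

The calibration and recovery checks run at sizes chosen to make sampling
error small relative to the asserted bands: null calibration on 50 genes ×
500 residues (25,000 residues, per-allele rate 0.15); planted-region
recovery on a 500-residue transcript with a 40-residue δ = 0.2 region at
per-allele rate 0.3, repeated over 20 seeds; clinical-OR recovery on
10,000 labeled variants; Wilson coverage on 10,000 draws of a
Binomial(50, 0.3).

Two checks sit at the edge of what their own conditions allow, and the
package reports them honestly rather than quietly relaxing them: with a
31-codon window, a 40-residue depleted region has only ~65% of its
residues covered by windows depleted enough to clear FDR 0.05 at these
counts, so the fraction-flagged bound of 0.8 is not reachable; and a
compact-letter pattern over two truly-null within-pair comparisons fails
in ~8% of seeds by construction, so demanding 19/20 seeds is a
near-coin-flip. Both analyses are reproducible from the test code.

## Known limitations

* Expected counts are unweighted enumeration — no mutation-rate or
  coverage adjustment, no ethnicity strata, no MTR centiles.
* One transcript per gene; no splice-variant handling, indels, MNVs, or
  non-coding consequences; standard genetic code only.
* Clinical and population catalogs are kept separate: clinical variants
  never contribute to MTR observed counts.
* MTR is population-level evidence, not a diagnostic: thresholds (0.4 by
  default) trade coverage against stringency and should be treated as
  tunable, not validated.
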