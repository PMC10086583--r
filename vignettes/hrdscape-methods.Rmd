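---
title: "Scoring HRDness: genomic scars, HRR-CIN and cut-off inference with hrdscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring HRDness: genomic scars, HRR-CIN and cut-off inference with hrdscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscape)
```

Tumours deficient in homologous recombination repair (HRR) resolve
double-strand breaks through error-prone pathways and accumulate a
characteristic pattern of chromosomal damage. hrdscape quantifies that
damage from allele-specific copy-number (ASCN) segment profiles — the
output of callers such as ASCAT — and carries the analysis through to
classification: genomic scar counts, chromosomal-instability features,
data-driven cut-offs, alteration matrices, an HRD expression signature
and drug-synergy scoring, with seeded generators so every stage is
testable offline.

## Coordinate and genome model

All coordinates are 1-based inclusive (the SEG/ASCAT convention);
interval lengths are `end - start + 1`. Chromosome names are
normalised to the `chr` prefix. chrY and the mitochondrial genome are
excluded from scoring (allele-specific calls are not meaningful for
them); chrX is retained.

Two builds are packaged. The `toy` build (3 chromosomes of 100 Mb,
centromere at 45–55 Mb, ten 10-Mb cytobands each) keeps every worked
example arithmetic-friendly. The `hg38` build carries the standard
GRCh38 chromosome lengths; its centromere intervals, arm-level bands
and the coordinates of the 70-gene HRR catalog are curated
approximations packaged in files labelled `*_synthetic.tsv` — adequate
for the Mb-scale interval overlap these methods need, but not an
authoritative annotation, and users with exact annotation can supply a
UCSC-layout cytoband file instead. The catalog spans the core HRR and
Fanconi anaemia machinery (BRCA1/2, the RAD51 paralogs, the FANC
genes, ATM/ATR signalling, resolvases and accessory factors).

## Genomic scar signatures

Three scar counts are computed per sample, and the HRD score is their
unweighted sum `hrd = loh + lst + tai`.

**LOH.** A loss-of-heterozygosity event is a maximal run of abutting
segments with `n_minor == 0` and `n_major >= 1` whose merged length
strictly exceeds 15 Mb (`loh_min_len`) and which does not cover the
whole chromosome. Two choices deserve note: homozygous deletions
(0,0) are excluded from LOH runs, because fully deleted DNA carries no
allele signal; and "whole chromosome" is judged against the full
chromosome length, not the arm.

**LST.** Large-scale transitions are counted per chromosome arm.
Segments crossing the centromere are split at the centromere midpoint.
Each arm is then *smoothed*: segments shorter than 3 Mb
(`lst_smooth_len`) are removed shortest-first, their span divided at
its midpoint between the two neighbours (absorbed entirely by the
single neighbour at an arm end), and abutting segments left with
identical allele copy numbers are merged. This conserves covered span;
the exact allocation of the removed span cannot change a count at the
default thresholds because it moves boundaries by at most 1.5 Mb while
the segment floor is 10 Mb. After smoothing, every adjacent pair of
segments with different `(n_major, n_minor)`, both at least 10 Mb
(`lst_min_segment`) long and separated by at most 3 Mb, is one
transition; abutting pairs (gap 0) qualify.

**TAI.** A telomeric allelic imbalance is a maximal run of abutting
segments with `n_major != n_minor` (any copy numbers) that reaches a
telomere — defined as the first or last base of the chromosome, since
ASCN profiles span whole chromosomes — does not cross the centromere
(does not span the entire centromere interval), does not cover the
whole chromosome, and exceeds `tai_min_len` (default 0; the size floor
is parameterised because published TAI variants differ on it, and no
ploidy correction is applied).

All three counters are verified against independent brute-force
re-implementations on a thousand random profiles, and all thresholds
are strict or inclusive exactly as stated above; the test suite pins
the boundary cases (a 15 Mb run is not LOH; a 10 Mb flank is an LST
flank).

## Chromosomal instability features

Segment calls use strict thresholds. In ASCN mode a segment is a gain
iff total copy number exceeds 2 and a loss iff below 2. In log2-ratio
mode gains are `l2r > 0.1`, losses `l2r < -0.1`, with high-level
amplification above 0.7 and deep deletion below -0.7 (the cBioPortal
convention). From the calls the package derives:

* **per-chromosome CIN** — counts of gain and loss segments and their
  sum. Raw counts depend on segmentation granularity, so a
  merged-runs variant (abutting same-call segments fused first) is
  available and is the pipeline default for cross-cohort
  comparability; both semantics are tested.
* **fraction of genome altered** — altered length over the summed
  chromosome lengths of the build, with per-chromosome fractions;
  uncovered genome counts as neutral.
* **aneuploidy events** — chromosomes whose gained (or lost) fraction
  strictly exceeds 90%.
* **per-cytoband CIN** — gain/loss segment counts per band at >= 1 bp
  overlap.
* **HRR-CIN** — instability restricted to the HRR catalog: each gene
  contributes 1 if any gain overlaps it and 1 if any loss overlaps it,
  so the score is bounded by twice the catalog size (0–140). Counting
  (gene, class) events — rather than genes or segments — is a
  documented modelling choice; it mirrors the "gains plus losses"
  construction of the chromosome-level counts and makes the 0–140
  range consistent with a cut-off near 37 on real cohorts.

## Cut-off inference

The HRR-CIN distribution across a mixed cohort is bimodal: a
high-instability and a low-instability population. The package fits a
two-component Gaussian mixture by EM (the mixture family is
parameterised in principle, but Gaussian is the reference default).
Initialisation is deterministic — means at the 25th/75th percentiles,
common starting spread, equal weights — so the fit is reproducible
without randomness; convergence is declared when the log-likelihood
improves by less than 1e-8, and a component collapse (sd below 1e-6)
is reported as non-convergence rather than silently accepted.

The cut-off separating the two peaks is the point between the means
where the weighted component densities cross — equivalently, posterior
probability 0.5 — found by bisection to 1e-6. When extreme weight
imbalance leaves no crossing between the means, the midpoint of the
means is returned and flagged. A Monte-Carlo confidence interval comes
from a parametric bootstrap: resample from the fitted mixture, refit,
take the 2.5/97.5 percentiles of the refitted cut-offs (1,000
replicates by default; a >20% degenerate-refit rate raises a warning).

Samples are classified `high`/`low` against the cut-off with an
*inclusive* boundary (a value equal to the cut-off is high). The HRD
score cut-off is then inferred by ROC analysis of the HRD score
against the HRR-CIN status: candidate thresholds are midpoints between
adjacent distinct scores plus ±Inf, the optimum maximises the Youden
index J = sensitivity + specificity − 1 (ties broken by higher
sensitivity, then lower threshold), and AUC is the trapezoid integral.
The optimal J is exhaustively verified against a full threshold search
in the tests. The same ROC construction applied to LOH against the
HRD status yields the LOH cut-off. For cross-cohort application the
pipeline accepts fixed published thresholds (HRD >= 32, LOH >= 10)
instead of inferring them.

## Alteration matrices and the SARC-HRD signature

Oncoprint input combines PASS-filtered somatic variants (MAF columns;
missense / truncating / splice / other mapping is configurable) with
per-gene copy-number categories (log2-ratio thresholds as above, or
GDC codes −2..2). Cells are category sets; per-sample totals count
(gene, category) events — the quantity whose cohort distribution is
bimodal — and per-gene altered fractions are altered samples over the
roster.

The SARC-HRD signature is the fixed 10-gene up-regulated set BRCA1,
BRCA2, BLM, EME1, FANCB, FANCD2, FANCI, RAD51, RAD54L, XRCC2. The
signature itself is a gene list; turning it into a per-sample number
is this package's operationalisation: per-gene z-scores of
log2(x + 1) expression across samples, averaged over the signature
genes. Scores are cohort-centred at 0 and invariant to per-gene affine
rescaling on the log scale; at least half the signature genes must be
present, and zero-variance genes are dropped with a warning. The
companion differential-expression filter flags genes with at least a
two-fold change and p <= 0.05, both boundaries inclusive; model
fitting itself (e.g. negative-binomial testing) is deliberately out of
scope — the filter consumes any upstream statistics table.

## Dose-response and synergy

Viability is normalised to the untreated-control mean. Monotherapy
curves are four-parameter logistic,
`y = bottom + (top − bottom) / (1 + (x/ic50)^hill)`, fitted by bounded
least squares (bottom in [−0.2, 1], top in [0.5, 1.5]) from a fixed
multi-start grid over hill in {±0.5, ±1, ±2} and IC50 at the dose-range
extremes and geometric centre, so the fit is deterministic given the
data. Curves with no dose effect are flagged non-convergent and backed
by a monotone spline over log10 dose for downstream use. The AUC
summary is the trapezoid integral of viability over log10 dose divided
by the span — a dimensionless mean viability (a convention choice,
since integration details are rarely reported).

Synergy is scored on inhibition fractions (1 − viability, clipped to
[0, 1]). Expected combination effects come from four reference models:
Bliss independence `y1 + y2 − y1·y2` and highest-single-agent
`max(y1, y2)` on the observed monotherapies; Loewe additivity by
solving `d1/D1(E) + d2/D2(E) = 1` with the inverse fitted 4PL curves
(bisection; cells with non-invertible monotherapy are excluded); and
the zero-interaction-potency (ZIP) null, Bliss independence evaluated
on the *fitted* monotherapy curves. The score is 100 times the mean
excess of observed over expected inhibition across combination cells.
For ZIP, "observed" is the average of the two directional
potency-shift fits (each row/column refitted with its baseline pinned
to the other drug's fitted effect and top at 1), following the
published ZIP formulation; rows or columns whose directional fit fails
fall back to the Bliss expectation and are flagged. Matrices generated
under each model's own null score 0 within noise, and the analytic
anchors hold to 1e-6: Bliss expectation 0.75 from two 0.5
monotherapies, and Loewe E = 0.5 for two identical drugs at half their
common IC50.

## What the generators emulate — and what they do not

`simulate_profile` builds a diploid heterozygous genome and implants
events so implanted counts are *exact by construction*, which is what
makes the closed-loop tests meaningful:

* LST chains: telomere-anchored runs of balanced 10.5–12 Mb blocks
  (alternating (2,2)/(3,3)) closed by a >= 10.5 Mb background segment
  or an LOH block — each adjacency is exactly one transition, and
  balanced blocks cannot create TAI.
* LOH blocks: (1,0) segments of 16–40 Mb placed away from telomeres;
  a 4–6 Mb balanced "guard" block caps the centromere-facing side so
  that neither the block nor the remaining background forms an
  unplanned transition on arms of any length.
* TAI blocks: telomere-anchored (2,1) segments of 5–9 Mb — below the
  LST segment floor, hence transition-free.
* Aneuploidy: dedicated whole-chromosome (2,1) gains (a
  whole-chromosome imbalance is excluded from TAI by definition).

Events are packed onto arms by a deterministic greedy planner that
errors on infeasible requests rather than under-implanting.
`simulate_cohort` adds a bimodal cohort structure: HRD-high samples
draw heavy scar loads and an HRR-CIN target from round-N(50, 8²),
HRD-low samples light loads and round-N(8, 3²) — artifact choices
tuned to reproduce the qualitative bimodality of real mixed sarcoma
cohorts, not fitted values. The generator reaches each HRR-CIN target
exactly by adding gene-sized gain/loss segments on catalog loci clear
of other implants (with both-class targets split across the locus
halves), after accounting for the (gene, class) events the scar blocks
themselves create; because targets can sit scores of events above the
scar baseline, the cohort generator needs the 70-gene catalog and
therefore runs on the hg38 build. Expression matrices are log-normal
(log2-scale sd 0.5) with a +1 log2 shift of the signature genes in the
high group.

None of this emulates subclonality, tumour purity, segmentation noise
in BAF/LRR space, or correlated breakpoint processes. Passing the
closed-loop tests therefore demonstrates that the *counting rules* are
implemented exactly as specified, not that the scores are robust to
real-data artefacts — robustness on real profiles inherits from the
upstream ASCN caller.

## Problem sizes and numerical choices

The shipped verification suite runs, per invocation: 100 noise-free
profiles for the closed loop; 1,000 random profiles against the
brute-force oracles; a 500-point bimodal benchmark for the mixture
(component means recovered within ±1, cut-off within 5e-2 of a
dense-grid crossing, typically within 1e-4); 20 cohorts of 60 + 60
samples for end-to-end cut-off recovery (>= 95% of samples classified
to their true group; in practice 100%); 50 null matrices per synergy
model at noise sd 0.02 (|mean score| < 1); and 200 noisy 4PL fits.
The 4PL noise experiment uses six dose levels spanning each curve's
IC50 read in triplicate wells, mirroring the standard viability-assay
design; with single wells the IC50 estimator's median error roughly
doubles. Bootstrap confidence intervals default to 1,000 replicates in
the API and 200 in the pipeline default, a runtime/precision
trade-off.

Ties and degeneracies are resolved deterministically throughout:
smoothing removes the leftmost-shortest segment first; ROC ties prefer
higher sensitivity then lower threshold; EM initialisation is
quantile-based rather than random; generator randomness is fully
derived from the user seed.

## Known limitations

* The packaged hg38 annotation (centromeres, arm bands, gene
  coordinates) is approximate; supply a real cytoband file where band
  resolution matters.
* Scar counts are not ploidy- or purity-adjusted; profiles from
  near-tetraploid tumours will read differently than their
  ploidy-corrected counterparts.
* HRR-CIN's (gene, class) counting is one of several defensible
  conventions; comparisons against published cut-offs assume the same
  convention upstream.
* The signature score is a relative, cohort-centred quantity; it is
  not calibrated across cohorts.
* Synergy scoring assumes a complete dose grid and does not model
  plate effects or well outliers.

## A minimal session

```{r example, eval = FALSE}
genome <- load_genome_build("hg38")
co <- simulate_cohort(60, 60, genome = genome, seed = 7)

scars <- score_cohort(co$segments, genome)
cin <- cin_profile(co$segments, genome)

fit <- fit_two_component_mixture(cin$per_sample$hrr_cin, seed = 7)
status <- classify_by_cutoff(cin$per_sample$hrr_cin, fit$cutoff)
roc <- roc_youden(status == "high", scars$hrd)
hrd_status <- classify_by_cutoff(scars$hrd, roc$optimal_cutpoint)

sig <- signature_score(co$expression)
```
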