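---
title: "Genomic scar scores for HRD from SNP-array signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar scores for HRD from SNP-array signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumors with homologous recombination deficiency (HRD) accumulate
characteristic chromosomal "scars" that are visible in allele-specific
copy-number profiles: large regions of loss of heterozygosity (LOH),
allelic imbalance extending into the subtelomeres (TAI), and abundant
large-scale copy-number state transitions (LST). The unweighted sum of the
three counts is the HRD score; clinically it is dichotomized at 42, with
scores of 42 or more labeled HRD positive.

SNP genotyping arrays measure, for a few hundred thousand autosomal
markers, the log R ratio (LRR; total intensity relative to a diploid
expectation) and B-allele frequency (BAF; fraction of signal from the B
allele). `hrdscar` implements the complete analysis path from these
marker-level signals to the scar scores: GC-wave correction, joint
two-channel segmentation, purity/ploidy estimation, integer allele-specific
copy-number (ASCN) calling, the three scorers, a concordance battery
(AUROC, AUPRC, correlations), and a marker-downsampling experiment. Because
patient-level array data of this kind are access-controlled, the package
also ships a first-class synthetic-data generator so every stage is
testable end to end against known truth.

All coordinates are 0-based and half-open, so `end - start` is always a
length.

## The forward signal model

The simulator uses the standard allele-specific array model. For a marker
inside a segment with parental copies $(n_A, n_B)$, total $n_T = n_A + n_B$,
at tumor purity $\rho$:

$$\mathrm{LRR} = \gamma \log_2 \frac{\rho n_T + 2(1-\rho)}{2}, \qquad
  \mathrm{BAF} = \frac{\rho n_B + (1-\rho)}{\rho n_T + 2(1-\rho)},$$

with the B allele assigned to the major or minor haplotype uniformly at
random per heterozygous marker. A fraction of markers (default 0.6, typical
of genotyping arrays) are germline homozygous with BAF near 0 or 1. The
platform compression factor $\gamma$ (default 0.55) reflects the damped
intensity response of array chemistry. A GC wave is injected as
`amplitude * (gc - mean(gc)) / sd(gc)` added to LRR — the amplitude is
therefore in LRR units per standard deviation of GC — and Gaussian noise is
added to both channels (defaults: 0.15 LRR, 0.03 BAF), with BAF clipped to
$[0, 1]$.

## What the generator emulates, and what it does not

Truth profiles start from a uniform diploid background and inject four
event classes, each dosing one rule of the scorers:

* interstitial one-copy deletions (1+0), log-uniform 16–40 Mb: LOH regions
  that also create two large-segment breakpoints;
* telomeric single-copy gains (2+1), 11–30 Mb anchored at a chromosome end:
  TAI regions plus one breakpoint;
* focal deletions 0.5–2.5 Mb: qualify under nothing and exercise the LST
  small-segment filter;
* whole-chromosome LOH: qualifies under nothing (LOH requires "shorter
  than the whole chromosome"; a whole-chromosome imbalance necessarily
  crosses the centromere).

Events are placed inside single chromosome arms, at least 10.5 Mb from arm
boundaries and from each other. The margin guarantees that every event's
qualifying contribution under each scar rule can be derived exactly at
injection time (the event ledger), and keeps event lengths safely away from
the 15/10/3 Mb rule thresholds so that segment boundaries recovered at
marker midpoints (boundary jitter of half a marker spacing) cannot flip a
count on the tested marker densities. Scar-rich ("hrd") samples multiply
all event rates by 10 (default base rates 1/1/2/0.5 per genome), yielding
HRD sums around the clinical cut-off of 42 for the scar-rich class and
single digits for the scar-poor class.

The generator deliberately omits: subclonal copy number, copy-number-neutral
LOH (invisible in LRR and only partially visible in BAF without a matched
normal), replication-timing waves, probe-specific bias, and FFPE artifacts.
Passing tests therefore demonstrate correctness of the scoring and
segmentation machinery under the stated model, not robustness to every
artifact of clinical arrays.

The bundled coordinate frame (`default_build()`) is a 22-autosome table
with hg19 lengths and the conventional 3 Mb centromere gaps. It is a
realistic stand-in: the scar definitions only need chromosome lengths and
centromere intervals, and no reference sequence is consulted (marker GC
content is itself simulated as a smooth two-sinusoid landscape per
chromosome).

## GC correction

GC-content bias produces smooth artifactual LRR variation. `gc_correct()`
residualizes LRR on GC with a robust local-linear smoother
(`stats::lowess`, span 0.3 by default) and re-centers so the genome-wide
median LRR is preserved. Residualization is idempotent and removes an
injected linear wave essentially completely (post-correction
$|\mathrm{cor}(\mathrm{LRR}, \mathrm{GC})| < 0.01$ at wave amplitude 0.3,
noise 0.15).

One known limitation: on a *single-chromosome* genome whose copy-number
events happen to align with the GC landscape's phase, the smoother cannot
distinguish wave from copy number and redistributes some CN signal as
position-structured residual, which over-segments (harmlessly — the extra
segments receive identical integer states and are merged at calling). On
the 22-autosome frame the phases are random per chromosome and this
confounding averages out.

## Segmentation

`segment_joint()` minimizes, per chromosome,

$$\sum_{\text{segments}} \mathrm{SSE}_{\mathrm{LRR}} +
  \mathrm{SSE}_{\mathrm{mBAF}} \; + \; \beta \times \#\text{changepoints}$$

exactly, by O($n^2$) optimal-partitioning dynamic programming (implemented
in C++). The second channel is the mirrored BAF, `0.5 + |BAF - 0.5|`, of
heterozygous markers only; without a matched normal, markers with raw BAF
in $[0.15, 0.85]$ are treated as heterozygous (configurable). Segment
boundaries are placed at inter-marker midpoints and the chromosome ends, so
segments tile the genome.

The default penalty is BIC-like and self-tuning:
$\beta = 2(\hat\sigma_1^2 + \hat\sigma_2^2)\log n$, with per-channel noise
scales estimated robustly from median absolute first differences within
chromosomes, floored at 0.05 so that near-noiseless input is not shattered
into marker-level segments by numerically tiny gains. Both the exact
optimum (against an independently coded brute-force implementation) and
breakpoint recovery on noisy simulations are covered by tests.

## Purity and ploidy

`fit_purity_ploidy()` inverts the signal model on segment means over a grid
of purity (0.10–1.00, step 0.01) and ploidy (1.0–5.0, step 0.05)
candidates. Segment LRR means are first centered at their marker-weighted
median, since array LRR is defined only up to a normalization constant; the
candidate ploidy enters through the denominator term
$\rho\psi + 2(1-\rho)$. For each candidate, the continuous allele-specific
copies of every heterozygous-informative segment (≥ 10 het markers by
default) are computed and the distance is the marker-weighted mean squared
deviation from the nearest non-negative integers.

Two numerical choices matter:

* **Folding bias.** The mirrored-BAF mean of a balanced segment is biased
  upward by $E|\varepsilon|$ when noise is folded at 0.5. The fit instead
  uses a moment-corrected estimate
  $\hat b = 0.5 + \sqrt{\max(0, \overline{(b-0.5)^2} - \hat\sigma_b^2)}$,
  which is exact on noise-free data and unbiased to first order otherwise.
* **Degenerate optima.** A genome-doubled interpretation of the data (twice
  the copies at lower purity) can fit almost exactly as well as the true
  one. Candidates within 1% of the minimum distance are treated as tied and
  resolved toward the smallest ploidy, then the largest purity — the
  conventional preference against whole-genome-duplication solutions. On
  noise-free rearranged samples this recovers grid purity exactly; samples
  with no allelic imbalance at all (an unrearranged genome) are inherently
  purity-unidentifiable and resolve to purity 1 with a diploid fit, which
  leaves their (zero) scar scores unaffected.

The reported `ploidy` is the length-weighted mean total copy number of the
called profile; `ploidy_grid` retains the grid value of the optimum, and
the full evaluated grid is kept for diagnostics. Samples with no
heterozygous-informative segment raise an "uninformative sample" error and
are counted against evaluability downstream — the analogue of samples that
fail CNV segmentation on real cohorts.

## Scar scoring rules

Following the published definitions, applied to the integer ASCN profile:

* **LOH**: maximal runs of segments with `cn_minor == 0` and
  `cn_major >= 1` (copy-neutral and amplified LOH count; homozygous
  deletions do not), strictly longer than 15 Mb and strictly shorter than
  the whole chromosome.
* **TAI**: maximal runs with `cn_major != cn_minor` that include a
  chromosome terminus, do not overlap the centromere interval, and do not
  span the whole chromosome. No minimum length is applied by default (the
  original region-count definition states none); `tai_min_mb` accommodates
  variants that use a floor.
* **LST**: computed per chromosome arm (segments split at the centromere,
  the centromere interval discarded — the arm-based convention of the
  original algorithm). Segments shorter than 3 Mb are iteratively smoothed
  away (shortest first, leftmost on ties; the vacated interval merges
  equal-state flanks or is split evenly between unequal ones — the even
  split is a symmetric, deterministic choice the published definitions
  leave open), then breakpoints whose two flanking segments are each at
  least 10 Mb are counted.

Strictness follows the wording of the definitions literally: "longer
than 15 Mb" is strict, "at least 10 Mb" is inclusive, "shorter than 3 Mb"
is strict. All three scorers are verified exactly against independent
brute-force implementations (per-megabase state-vector counting for LOH and
TAI; an independently coded recursive smoother for LST) on 1000 random
profiles, and against the simulator's event ledger on whole cohorts.

## Concordance statistics

AUROC uses the Mann–Whitney estimator (ties one half) with a DeLong 95% CI
(seeded bootstrap optional), computed via pROC with a fixed direction so
that `auroc(s) + auroc(-s) = 1` exactly; the result records whether the CI
overlaps 0.5, the interpretation convention for this descriptive statistic.
AUPRC is the step-wise average precision, whose chance baseline is the
class prevalence rather than 0.5 — the appropriate comparison when
biomarker-positive samples are scarce. Spearman and Pearson correlations
carry Fisher-z intervals with standard error $1/\sqrt{n-3}$. Sample
matching across platforms is pairwise-complete by sample id; nothing is
imputed, and evaluable counts are logged.

## Downsampling experiment

`run_downsampling_experiment()` reruns the entire pipeline after uniform
random marker subsetting, for the prespecified grid of 14 proportions
(0.25%–90%) × 10 seeded replicates, and summarizes each proportion by the
median Spearman correlation of HRD sums against a fixed reference score.
The optimal proportion is the smallest one maximizing median rho subject to
a median evaluability floor (default 0.95). A replicate with fewer than 3
evaluable samples has an undefined correlation (recorded as NA): at the
test scale of 10,000 markers, proportions at or below 1% leave so few
markers that no sample retains a heterozygous-informative segment, which is
how low-density degradation manifests at this scale. The experiment is
fully reproducible from its base seed, with replicate seeds derived from
the (proportion, replicate, sample) triple.

## Problem sizes used by the tests

The packaged verification uses cohorts the method's properties are stable
at: 1000 random profiles for the scorer oracles; 50 noise-free samples for
ledger agreement; 20 noise-free samples × 10,000 markers for exact
end-to-end recovery; 40 default-noise samples (purity uniform on 0.4–0.9)
for pipeline-vs-truth concordance; 20 samples for purity/ploidy recovery
and for the full 14 × 10 downsampling design. These sizes are the package's
own choices for stable, reproducible checks; all are configurable.

## Known limitations

* The ASCN stage is a transparent simplification, not a re-implementation
  of any specific production tool: exact penalized segmentation plus a grid
  fit replaces heuristic multi-stage pipelines. It is deliberately fully
  testable; it does not model subclonality.
* Heterozygosity is inferred from tumor BAF alone; at purity above ~0.85,
  heterozygous markers inside LOH regions leave the het window and such
  segments fall back to LRR-only calling (their total copy number is still
  correct, and an even allele split preserves the LOH state for single-copy
  segments).
* The clinical reference test's trained, weighted score is proprietary;
  correlations on synthetic cohorts are computed against simulation truth
  (or any user-supplied reference column), so only qualitative agreement
  with published cohort-level values should be expected.
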