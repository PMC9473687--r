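---
title: "Linking titin splicing to titin protein and sarcomere geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking titin splicing to titin protein and sarcomere geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinsplice)
```

## The problem

Titin is the third filament of the sarcomere: a single molecule spans from
the Z-line to the M-line, and its I-band segment — tandem immunoglobulin
(Ig) repeats plus the PEVK segment — acts as the sarcomere's spring.
Alternative splicing of the exons encoding this spring region (driven
largely by the splicing repressor RBM20) sets titin's length, and with it
sarcomere length and passive stiffness. `titinsplice` implements the
computational chain needed to study such a splicing change at three levels:

1. **mRNA**: percent spliced in (PSI) of each titin exon from
   inclusion/skipping junction read counts, with event-level aggregation.
2. **Protein**: exon-resolved quantification of tryptic titin peptides from
   label-free LC-MS peak areas, so an exon-inclusion change at the mRNA
   level can be confirmed in the protein.
3. **Sarcomere**: lengths and proximal-Ig epitope distances measured from
   1-D fluorescence line profiles, with a variance F-test for length
   homogeneity.

Everything is tied together by one coordinate system: the *genomic* exon
numbering of mouse *Ttn* (exons 1–363). All coordinates in the package are
1-based and inclusive.

## The exon model

`build_exon_model()` takes a transcript sequence plus an exon boundary
table that tiles it, translates the CDS, and annotates every residue with
the set of exons its codon nucleotides touch — a codon spanning an exon
junction is annotated with **all** exons it overlaps, which is the
maximally inclusive choice for peptides that straddle junctions.
Translation stops at the first in-frame stop codon; trailing sequence is
ignored.

Transcript databases number exons by their position in the transcript,
but the titin literature numbers them by the genomic gene structure (the
mouse transcript used for peptide identification carries 347 of the 363
genomic exons). `renumber_exons()` converts between the two, either with an
explicit mapping table (the primary, auditable path) or by exact sequence
matching against a genomic exon list. No alignment heuristics are used: an
exon that matches nothing (or more than one genomic exon) is an explicit
error, because a silent mis-assignment would corrupt every downstream
region definition.

`digest_tryptic()` applies the standard trypsin rule (cleave after K/R,
except before P) with configurable missed cleavages, and
`map_peptide_to_exons()` locates an observed peptide in the protein.
Titin's Ig and PEVK repeats guarantee that some tryptic peptides occur at
several loci; these are flagged with `n_loci > 1` and, by default, excluded
from exon-specific quantification (the exclusion is a policy flag,
`exclude_multi_locus`, because there is no uniquely correct attribution for
such peptides).

## Peptide quantification

The LC-MS layer reproduces a specific, documented convention:

* **Filter**: a peptide is kept if its *median* peak area over the
  control-group samples is at least 1.5e7 units; values exactly at the
  threshold are kept ("less than … excluded"). Missing values are dropped
  before the median; an all-missing peptide is below any threshold.
* **Normalization**: each sample's abundances are divided by that sample's
  mean peak area over peptides mapping entirely within exons 256–363. This
  region shows no evidence of alternative splicing, so it serves as a
  per-sample loading control; after normalization its mean abundance is 1
  in every sample by construction, and any per-sample rescaling of the raw
  data cancels exactly.
* **Summary**: per peptide, the median normalized abundance across each
  group's samples; per region, the mean and SD over peptides of those
  medians. The percent difference `100 (mean_ko − mean_ctrl)/mean_ctrl` is
  reported on the linear scale, matching how such effects are plotted and
  quoted.
* **Test**: Student t on the ln-transformed per-peptide medians, with a
  Bonferroni-adjusted threshold `alpha / n_regions_tested` (0.05/2 = 0.025
  for the two proximal-Ig regions tested).

One design point deserves emphasis. The same peptides are quantified in
both groups, and each peptide carries a large intrinsic ionization
efficiency that is irrelevant to the biology. `compare_region()` therefore
defaults to a **paired** t-test on each peptide's ln ratio, which cancels
the per-peptide baseline exactly and keeps the test calibrated (empirical
type-I error ≈ the nominal α in the package's null simulations). The
unpaired two-sample form is available via `paired = FALSE`; with realistic
baseline spread it is severely conservative, because the baseline variance
inflates the pooled variance. One residual imperfection of the paired form
is inherited from the normalization: the constitutive-region factor is
shared by every peptide in a sample, which induces a weak positive
correlation among the per-peptide ratios and makes the test slightly
anti-conservative (the null simulations run by the acceptance script
measure the empirical rejection rate, which sits just above the nominal
α = 0.05). Either way, peptides — not animals — are the
replication unit, so the p-values quantify measurement reproducibility
across peptides rather than biological replication; this caveat is
inherited from the underlying convention and documented rather than hidden.

A region can be empty in one group (titin exons 52–69 yield no detectable
peptides in wild-type muscle); `summarize_region()` returns an explicit
`undefined_reference` flag instead of a number in that case.

`gel_isoform_fractions()` covers the complementary gel-level arithmetic:
long T1, short T1 and T2 band intensities become per-lane fractions of
total titin plus a long:short ratio.

## PSI and splicing events

An included exon contributes reads to two junctions (upstream and
downstream) while the skipping event contributes to one, so the default
estimator halves the inclusion evidence:

PSI = (I/2) / (I/2 + S).

The raw ratio I/(I+S) is available by flag; length-normalization details of
junction counting pipelines vary, so the convention is stated rather than
guessed, and the generator is built to match the default estimator (making
it unbiased in simulations). PSI with zero evidence is missing, never zero
— a zero would assert confident exclusion where there is no information.

ΔPSI is the difference of group means (knockout − control). Contiguous
exon ranges are aggregated into splicing events by averaging member exons
per sample; events are compared across samples (n = 3 per group in the
motivating design) with a Student t-test and no correction across the three
events, matching per-event reporting. `segment_event_by_similarity()`
formalizes how a large event is split into sub-events: an exact dynamic
program partitions the range into k contiguous segments minimizing
within-segment variance of mean PSI, with ties broken toward the earliest
boundaries. For the default data this recovers the 52–69 / 70–79 / 80–88
split of the proximal-Ig block from the PSI profile itself.

## Sarcomere morphometry

Sarcomere lengths are spacings between successive Z-line (α-actinin)
fluorescence peaks along a 1-D profile. `detect_peaks()` keeps local maxima
passing a prominence filter (default 0.2 of the dynamic range) and a
minimum separation (default 1000 nm for Z-line channels, ~250 nm for
epitope doublets), then refines each peak with a three-point parabolic
fit. Sub-pixel refinement matters: the proximal-Ig epitope distance is
~200 nm, only a few pixels at typical confocal sampling, and the parabolic
fit recovers an off-grid Gaussian center to better than 0.1 px. Spacings
outside 1–5 µm (missed or spurious peaks) are excluded from summaries and
counted.

Length variability is compared with a two-sided variance F-test. F is
reported as var(a)/var(b) so direction is preserved, alongside the
larger/smaller convention; swapping groups inverts F and leaves the
two-sided p unchanged.

Proximal-Ig length is measured as the distance from each Z-line peak to the
nearest N2A-epitope peak on each side (the Z1Z2 and N2A epitopes flank the
proximal Ig segment, and Z1Z2 sits at the Z-line). Pairs are assigned
greedily by increasing distance so no epitope peak serves two Z-lines, and
sides with no epitope within `max_half_sarcomere` (default 1500 nm) are
missing rather than forced.

## What the generators simulate — and what they do not

The synthetic module exists so every stage is testable without downloads,
with ground truth carried alongside the data (`simulation_truth`). Defaults
are the study conditions of the motivating knockout experiment:

| parameter | default | source/rationale |
|---|---|---|
| region effects | ×1.18 (exons 70–79), ×1.16 (80–88) | printed +18 %/+16 % |
| ln-abundance noise SD | 0.25 | plausible label-free repeatability |
| baseline peak areas | log-normal, median 5e7, sdlog 0.5 | spans the 1.5e7 filter |
| LC-MS samples | 5 control / 6 knockout | animal counts used |
| PSI | 0.5 → 0.8 across exons 52–88; 0.95 elsewhere | +0.3 inclusion shift |
| junction depth | 500 reads/exon | deep-coverage RNAseq |
| RNAseq samples | 3/group | study group size |
| sarcomere mean | 2.12 / 2.28 µm | printed group means |
| sarcomere SD | 0.10 µm control; ×√3.62 for knockout | printed variance ratio; the control SD itself is not printed, 0.10 µm is a realistic healthy-muscle value |
| epitope offset | 182.4 / 229.5 nm | printed proximal-Ig lengths |
| localization noise | 10 nm | immunofluorescence localization error |
| PSF σ / pixel | 100 nm / 20 nm | diffraction-limited confocal imaging |

Peptide noise is log-normal (multiplicative), matching the rationale for
ln-transforming peak areas; junction counts are binomial at the true PSI
(the simplest model consistent with PSI semantics — overdispersion between
animals is *not* simulated); profiles are sums of Gaussians with additive
background. The generators are deterministic given `seed` and restore the
caller's RNG state.

These simulations deliberately omit several features of real data: missing
peptides (detection is complete apart from the planted low-abundance ones),
retention-time or batch structure, non-uniform read coverage and mappability
along the gene, biological overdispersion of PSI between animals, and the
2-D imaging steps (line-profile extraction, deconvolution) upstream of the
1-D contract. Passing recovery tests therefore demonstrates correctness of
the estimators under their own assumptions, not robustness to every
pathology of real instruments.

The synthetic transcript used in tests (`synthetic_titin_model()`) encodes
a fixed number of unique 4-residue tryptic peptides per exon. It reproduces
the exon-to-peptide bookkeeping of titin, not titin's sequence, and is
labelled synthetic throughout.

## Numerical choices and degenerate inputs

* Degenerate t-tests: zero-variance groups with equal means give t = 0,
  p = 1; with different means t = ±Inf, p = 0 (the limits of the statistic).
* Zero or missing normalized values are excluded from ln-scale tests with a
  warning that counts them.
* The segmentation DP uses a 1e-12 strict-improvement margin so exact ties
  resolve to the earliest boundaries deterministically.
* Peak refinement falls back to the grid position when the local curvature
  is non-negative or the parabolic shift exceeds half a pixel (both occur
  only on degenerate plateaus).
* The F-test returns F = 1, p = 1 for two zero-variance samples — the
  noiseless-simulation fixture — rather than NaN.

## Problem sizes

The test-suite simulations use 200 replicates for effect-recovery coverage,
500 (tests) / 200 (acceptance script) replicates for the null
type-I rate, 200 replicate pairs at 250 sarcomeres/group for F-test power,
and 300 sarcomeres for epitope-offset recovery; these sizes give Monte
Carlo standard errors comfortably below the assertion margins while keeping
a full run to a few minutes.

## Known limitations

* Peptides are the replication unit in region tests (see above).
* The PSI estimator's two-junction convention is one of several in use;
  results from pipelines with different length normalization are comparable
  only after re-estimating PSI from their counts.
* Multi-locus peptides are excluded rather than apportioned; a
  probabilistic attribution would require isoform-level quantification that
  is out of scope.
* Profile morphometry assumes the 1-D profiles are already extracted along
  the myofibril axis; oblique sampling would bias lengths upward.
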