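# titinsplice

Exon-resolved analysis of titin (*Ttn*) alternative splicing and its
consequences, from mRNA to protein to sarcomere. The package is written for
muscle biologists who have (a) junction read counts from an RNAseq splicing
pipeline, (b) a label-free LC-MS peptide peak-area table, and/or (c) 1-D
fluorescence line profiles of stained myofibrils, and who want to ask one
question three ways: *did the titin spring region change?*

Titin's I-band spring — tandem Ig repeats and the PEVK segment — is set by
alternative splicing under control of the repressor RBM20. The package
covers the full chain used to characterize such a change:

* **Exon model** — translate a titin transcript, annotate every residue
  with the genomic exon(s) its codon touches (exons 1–363, 1-based
  inclusive), renumber transcript exons to the genomic scheme, digest in
  silico with trypsin, and map observed peptides back to exons
  (multi-locus peptides are flagged and excluded from exon-specific
  quantification by default).
* **Peptide quantification** — filter peptides by control-group median
  peak area (≥ 1.5×10⁷ units), normalize each sample to the mean of the
  constitutive region (exons 256–363), summarize exon regions as
  mean-over-peptides of per-peptide group medians, report the linear-scale
  percent difference, and test regions with a Student t on per-peptide ln
  ratios at the Bonferroni-adjusted threshold α/n (0.05/2 = 0.025).
* **Splicing** — percent spliced in per exon and sample,
  PSI = (I/2)/(I/2 + S) with inclusion evidence halved for its two
  junctions; ΔPSI (knockout − control); event aggregation over exon ranges
  (defaults 52–69, 70–79, 80–88, the proximal-Ig events) with per-event
  t-tests; exact dynamic-programming segmentation of a range into events
  by PSI similarity.
* **Morphometry** — sub-pixel (parabolic) peak detection on line profiles,
  sarcomere lengths as Z-line peak spacings, two-sided variance F-tests,
  and proximal-Ig length as the Z1Z2↔N2A epitope distance per
  half-sarcomere.
* **Synthetic data** — seeded generators for all three input types with
  ground truth attached, defaulting to the study conditions the package
  models (+18 %/+16 % region effects, +0.3 PSI shift, 2.12/2.28 µm
  sarcomere means at variance ratio 3.62, 182.4/229.5 nm epitope offsets).

See `vignettes/titin-splicing-pipeline.Rmd` for the methods account.

## Worked example

Simulate a knockout-vs-control peptide table under the default study
conditions, run the proteomics stage, and read the region report:

```r
library(titinsplice)

model <- synthetic_titin_model(seed = 101)       # 363 exons, 3 peptides/exon
truth <- simulation_truth(seed = 1)              # +18 % on 70-79, +16 % on 80-88
sim   <- simulate_peptide_table(model, truth, n_control = 5, n_ko = 6)

report <- run_proteomics(list(), table = sim$table)
report$regions[["70-79"]][c("percent_difference", "t_statistic",
                            "p_value", "alpha_adjusted", "significant")]
#> $percent_difference
#> [1] 19.07755
#> $t_statistic
#> [1] 4.24967
#> $p_value
#> [1] 0.0002144291
#> $alpha_adjusted
#> [1] 0.025
#> $significant
#> [1] TRUE
```

The recovered percent difference (19.1 %) estimates the simulated +18 %
effect; the paired t on per-peptide ln ratios is tested against the
Bonferroni-adjusted threshold 0.025 (two regions in the family). The
splicing and morphometry stages run the same way:

```r
cnt <- simulate_exon_counts(truth, n_control = 3, n_ko = 3)
run_splicing(list(), counts = cnt$counts)$events[, c("event", "delta_psi", "p_value")]
#>   event delta_psi      p_value
#> 1 52-69 0.2942963 7.426339e-08
#> 2 70-79 0.3090667 3.767292e-07
#> 3 80-88 0.2991111 9.093394e-07
```

Each event's ΔPSI recovers the simulated +0.3 inclusion shift across exons
52–88.

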