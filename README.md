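# gbsmix

Relative abundance quantification of closely related strains from
multispecies genotyping-by-sequencing (msGBS).

## The problem

Mixtures of near-identical taxa — e.g. the strains of a diatom species
complex counted for freshwater quality indices — defeat both light
microscopy (morphologically indistinguishable) and marker-based molecular
methods (insufficient resolution, uncalibrated read counts). msGBS
sequences a restriction-digest reduced representation of every *monoclonal*
culture, clusters those reads into a strain-labelled **meta-reference**, and
maps mixture reads against it. Read counts are converted to cell-proportion
estimates with a **calibration key**: with read share `r_sj` of strain *s*
in sample *j* and calibration factor `f_s` (the strain's mean read share
across samples containing all strains in *equal* cell proportions),

```
a_sj = (r_sj / f_s) / Σ_t (r_tj / f_t)
```

which cancels strain-specific reads-per-cell biases (up to 32-fold between
strains). Homologous reference clusters that attract reads across strains
are removed beforehand using three rules computed from monoclonal
mappings: drop a cluster when non-target > target reads, when target
reads < 8, or when non-target/target > 1/15.

gbsmix implements the full workflow — demultiplexing, pair merging/joining
(≥ 20 bp overlap, ≤ 10% mismatches), UMI deduplication, dereplication
(minimum unique size 5), greedy 95%-identity clustering, semi-global
multi-mapping with a 0.8 score filter and fractional allocation of tied
hits, homologous-cluster filtering, < 3000-read sample exclusion,
calibration, and an evaluation layer (FP/FN detection, false-signal rate,
Pearson/OLS comparison against known compositions and light-microscopy
counts) — plus a restriction-digest read simulator that emulates the
mock-community benchmark design, so everything is testable from a seed.

## Worked example

```r
library(gbsmix)

study <- simulate_msgbs_study(seed = 42, reads_monoclonal = 4000,
                              reads_calibration = 2500, reads_mock = 2500)
run <- run_msgbs_pipeline(study$reads, study$barcode_map, study$designs,
                          min_sample_reads = 800)
run
#> msGBS run
#>   reads processed:   49444 (duplicate fraction 0.501)
#>   meta-reference:    198 clusters
#>   homology filter:   196 clusters retained, 2 removed
#>   samples excluded:  0
#>   target map rates:  1.000 1.000 1.000 1.000 1.000 1.000
#>   mock samples quantified: 25
```

Half the reads were PCR duplicates (the simulated rate is 0.5), the six
monoclonal libraries clustered into 198 strain-labelled clusters of which 2
were removed as cross-strain homologs, and after filtering each monoclonal
sample maps essentially only to its own strain's clusters.

```r
run$key
#>   strain_id     factor         s2
#> 1  strain01 0.01760843 0.03268654
#> ...
#> 6  strain06 0.48707980 1.62997595
```

The calibration key recovers the simulated 32-fold yield spread
(0.487 / 0.0176 ≈ 28): strain06 yields far more reads per cell than
strain01, so raw read shares would misstate both severely. `s2` is the
between-calibration-sample variance of the shares (percent scale) — small
values mean the key is stable, the property that makes calibration
transferable.

```r
expected <- expected_abundances(study$designs,
                                excluded_strains = run$excluded_strains)
al <- intersect_tables(run$abundance_gbs, expected)
head(correlate_abundances(al$observed, al$expected, unit = "sample"), 3)
#>     unit n         r     slope  class
#> 1 mock01 6 0.9917433 1.0220892 strong
#> 2 mock02 6 0.9930658 0.9944522 strong
#> 3 mock03 6 0.9977193 1.0329960 strong

round(head(unclass(al$observed), 3), 3)   # estimated
#>        strain01 strain02 strain03 strain04 strain05 strain06
#> mock01    0.000    0.125    0.297    0.164    0.056    0.359
round(head(unclass(al$expected), 3), 3)   # designed cell shares
#>        strain01 strain02 strain03 strain04 strain05 strain06
#> mock01    0.000    0.147    0.294    0.183    0.039    0.337
```

At this reduced depth the mean per-sample Pearson r is 0.993 and the mean
absolute abundance error 0.0105 — calibrated read counts track designed
cell proportions to about one percentage point per strain.

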