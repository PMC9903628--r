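---
title: "Quantifying strain mixtures with msGBS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying strain mixtures with msGBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Closely related strains — for instance the members of a diatom species
complex used as bioindicators in freshwater quality assessment — are often
impossible to tell apart under light microscopy, and single-marker molecular
methods (metabarcoding, qPCR) lack either the resolution or the quantitative
calibration to estimate their relative abundances in a mixed sample.
Multispecies genotyping-by-sequencing (msGBS) addresses both problems at
once: a reduced representation of each genome (restriction fragments from a
double digest) is sequenced for every *monoclonal* culture, clustered into a
strain-labelled *meta-reference*, and mixture reads are mapped against it.
Because different strains yield very different numbers of reads per cell
(DNA content, copy number, extraction efficiency — up to 32-fold in the
motivating benchmark), raw read shares are not abundances; a *calibration
key* learned from samples containing all strains in equal cell proportions
converts read counts into cell-proportion estimates.

gbsmix implements this workflow end to end, together with a synthetic-data
generator that emulates the benchmark's statistical structure, so that the
whole pipeline is testable without any external sequencing data.

## The pipeline model

1. **Demultiplexing** by 6-nt inline barcode (Hamming distance ≥ 3 between
   any two barcodes, one mismatch tolerated), stripping the barcode and the
   two 3-nt UMIs (one per adapter; see "UMIs" below).
2. **Merging / joining**: mate 2 is reverse-complemented and the longest
   suffix–prefix overlap of ≥ 20 bp with ≤ 10% mismatches produces a merged
   consensus; otherwise the pair is *joined* with a fixed spacer of ten `N`s
   (the connector is not specified by the protocol; `N` keeps joined and
   merged reads in one alphabet and is treated as a mismatch everywhere).
   Ties on mismatch count go to the longer overlap; consensus bases come
   from mate 1 (qualities are not modelled).
3. **UMI deduplication** on the exact key (sample, UMI pair, sequence),
   *before* mapping. Real implementations often deduplicate on mapping
   positions instead; pre-mapping dedup is this package's documented choice
   and is exact for the simulator's duplicates, which are verbatim copies.
4. **Meta-reference**: per monoclonal sample, reads are dereplicated
   (sequences seen fewer than `min_unique_size = 5` times are dropped) and
   clustered greedily at 95% identity, visiting sequences in decreasing
   abundance (ties broken lexicographically); a sequence joins the first
   centroid at ≥ 95% identity, else founds a cluster. Identity is
   `1 - d / max(length)` with `d` the unit-cost global alignment distance —
   on the near-uniform-length, substitution-dominated sequences of this
   protocol this equals matches over alignment columns, and it is uniquely
   defined (the test suite uses `utils::adist` as an independent oracle).
   Both orientations are compared, because fragments are sequenced from
   either end. A pluggable classifier hook stands in for BLAST-based
   contaminant removal (the default keeps everything; synthetic data has no
   contaminants).
5. **Mapping** is semi-global (read end-to-end, reference with free flanks)
   with score `matches / read length`; events with score < 0.8 are dropped
   and every cluster tying the read's best score is reported (tie tolerance
   zero, decided on integer match counts; at most `max_hits = 50` ties,
   beyond which the read is discarded as an unmappable repeat). Joined reads
   are scored as two pooled half-alignments across the spacer. A read with
   `k` tied clusters contributes `1/k` to each: column masses equal retained
   read counts exactly.
6. **Homologous-cluster filter** from the monoclonal mappings. For each
   cluster, `target` is its weight in its own strain's monoclonal sample and
   the non-target weights come from the other monoclonal samples
   (aggregated as the per-strain maximum; summing is exposed as an option
   but over-removes). A cluster is removed iff non-target > target, or
   target < 8, or non-target/target > 1/15 — strictly greater in rule 3, as
   the protocol's parenthetical inequality states; a ratio of exactly 1/15
   is retained.
7. **Sample exclusion**: mock/calibration samples with fewer than 3000
   retained reads after cluster filtering are dropped and reported.
8. **Calibration and abundances**: per calibration sample the strain read
   shares are computed; a strain's calibration factor is the arithmetic mean
   of its shares (factors sum to 1; the between-sample variance of the
   shares, reported on the percent scale, is a stability diagnostic).
   Abundances divide each strain's reads by its factor and renormalise:
   `a_sj = (r_sj / f_s) / Σ_t (r_tj / f_t)`. The benchmark does not print
   this formula; the share-mean / ratio-normalisation form is this package's
   explicit reconstruction, isolated in `estimate_abundances()` so that
   alternatives can be swapped. Strains with zero reads get abundance 0 (no
   pseudocount); equal weight per calibration replicate (rather than pooled
   counts) matches the per-sample variance QC.
9. **Evaluation**: FP/FN detection against the design (threshold 0 by
   default — any signal counts), abundance mass on absent strains ("false
   positive signal"), Pearson correlation and OLS regression of observed on
   expected per sample and per strain (95% t-based confidence intervals),
   strength classes at the conventional cutpoints (strong r > 0.7, moderate
   0.5–0.7, weak < 0.5), and a per-unit winner table between GBS and light
   microscopy. Per-sample correlations use all strains including
   zero-expected ones by default (`nonzero_only` restricts).

## What the simulator emulates — and what it does not

`simulate_msgbs_study()` generates, under one seed:

* **Six genomes (100 kb)** in three lineages: one distinct lineage
  (strain01, 5% from the ancestor), a close clade (strain02 with strain03
  and strain04 at 1.5% from it), a distant lineage (strain05, 8%), and a
  hybrid (strain06) built as a four-segment mosaic of strain01 and strain02
  plus 2% of its own substitutions. The hybrid's own divergence reflects
  that the motivating hybrid is an allopolyploid with high intra-genome
  polymorphism; a verbatim mosaic would have every cluster removed by the
  homology filter, which does not match the benchmark where the hybrid was
  quantifiable.
* **Digestion**: PacI (`TTAAT|TAA`) / NsiI (`ATGCA|T`) double digest, only
  fragments flanked by one cut of each enzyme and strictly longer than
  150 bp are retained (enzyme-specific adapters; > 150 bp size selection).
  Because an 8-bp cutter occurs only ~1.5 times per 100 kb of random
  sequence, PacI sites are planted in the ancestor every 1.5 kb, yielding
  ~25–35 fragments per strain; site-destroying mutations then create
  realistic presence/absence variation between strains.
* **Libraries**: read yield per strain proportional to cells × yield factor
  (defaults span exactly 32-fold, `2^(0:5)`), uniform fragment sampling
  within a strain, 2 × 150 bp reads from either fragment end with equal
  probability, one random 3-nt UMI per adapter, ~50% PCR duplicates
  (verbatim copies of finished molecules), and per-base substitution errors
  (default 0.1%, a typical Illumina-class rate; errors are applied to
  genomic bases only, not to barcode/UMI read-outs).
* **Design**: 6 monoclonal, 5 calibration (990,000 cells in equal
  proportions, 165,000 per strain) and 25 mock samples of ~10^6 cells
  (18 five-strain, 3 three-strain, 3 two-strain, 1 single-strain).
  Five-strain mixes rotate the left-out strain so absences — and hence
  false-positive opportunities — are balanced; mock proportions are
  Dirichlet(2), keeping compositions varied but rarely degenerate.
  Raw depth is 12,000 pairs per monoclonal and 7,000 per mixed sample
  (~2.8 × 10^5 pairs in total): at a 50% duplicate rate this leaves mixed
  samples ~3.5 × 10^3 retained reads, just clearing the pipeline's own
  3000-read exclusion threshold the way the benchmark's retained samples
  did. A strictly 2 × 10^5-pair run would push every mixed sample below its
  own exclusion floor.
* **Light microscopy**: 200 valves per mock drawn from the true composition
  pushed through a confusion matrix in which the clade members are mutually
  confused (8% each way) and every strain leaks 8% of identifications into
  the hybrid analogue, whose teratological valves resemble several strains.

Not emulated: indel sequencing errors, quality scores, chimeric PCR
artifacts, adapter read-through, contaminant taxa, PhiX. A green end-to-end
test therefore establishes that the *statistical machinery* (clustering,
filtering, calibration, evaluation) recovers known compositions under
realistic yield bias, duplication and substitution noise — not that any
particular wet-lab protocol performs to specification.

## Numerical choices

* **Alignment engine** (C++): banded unit-cost global distance for identity;
  bounded semi-global distance (Ukkonen cutoff) for mapping scores. Mapping
  candidates are shortlisted by shared 11-mers, but the shortlist is made
  *provably* equivalent to exhaustive all-pairs alignment via the q-gram
  bound (an alignment with `d` edits preserves at least `V − 11·d` of the
  read's `V` 11-mers): references failing the bound cannot reach the current
  best score, and whenever the bound cannot exclude the remaining
  references, they are aligned too. `exhaustive = TRUE` disables the
  shortlist outright; the test suite asserts byte-identical results.
* **Tie handling**: multi-mapping ties are decided on integer match counts
  (tie tolerance zero); greedy clustering ties on abundance break
  lexicographically by sequence; merge overlap ties on mismatch count go to
  the longer overlap.
* **Degenerate inputs**: empty dereplication input warns and returns an
  empty set; a strain whose monoclonal library yields no clusters is
  excluded from the meta-reference and reported (mirroring the benchmark's
  removal of a failed library), and expected abundances are renormalised
  after subtracting its cells; indistinguishable twin strains lose all
  clusters to the homology rules and the target-mapping-rate QC gate raises
  a structured error rather than returning NaNs; zero-variance units in the
  correlation layer are reported as not computable instead of propagating
  `NaN`.
* **Deterministic simulator mode** (`deterministic = TRUE`) realises the
  exact world `reads = cells × yield × rate`: counts are deterministic,
  reads are dealt round-robin over fragments, UMI pairs are handed out
  collision-free within each (fragment, orientation) group, and no errors or
  duplicates are produced. In this world the calibration identity is exact:
  estimated abundances equal designed cell shares to numerical precision,
  which the acceptance suite asserts at 1e-9.

## Known limitations

* The homologous-cluster filter is near-inert on the default synthetic
  world: with zero-tolerance score ties, cross-strain mapping requires
  exactly tied alignments, which at ≥ 1.5% divergence essentially demands
  identical fragments. The filter's three rules are therefore validated
  against a brute-force oracle on randomised statistics tables rather than
  through the simulator.
* Cluster counts per strain (dozens) are three orders of magnitude below the
  real benchmark's (thousands); all comparisons against printed values are
  structural (additivity, boundaries, classifications), never reanalyses.
* The multi-mapped read weighting (fractional `1/k` allocation) is this
  package's decision — the protocol does not state how multi-mappers were
  counted; sensitivity to this choice is untested beyond mass conservation.
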