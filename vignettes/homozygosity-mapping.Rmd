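---
title: "Homozygosity mapping and recessive-variant prioritization with autozygr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping and recessive-variant prioritization with autozygr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygr)
```

## The analysis this package implements

In a consanguineous family, a recessive disease allele is expected to sit
inside a long *autozygous* segment: a stretch of genome where the two
parental haplotypes descend from the same recent ancestor, so every
variant in it is homozygous. For children of first cousins the expected
autozygous fraction of the genome — the inbreeding coefficient $F$ — is
$1/16$. Homozygosity mapping exploits this: detect runs of homozygosity
(ROH) in each affected child from exome or genome calls, intersect them
across the affected sibs, and then prioritize the shared homozygous
variants inside those intervals with a cascade of filters until (ideally)
one candidate survives.

`autozygr` implements that pipeline end to end, together with a
gene-dropping simulator of the first-cousin study design so that every
stage can be verified against known truth without any external data.

## The run-of-homozygosity rule

A genotype call is classed, per sample and site, as one of `HQ_HOM`,
`HET`, `LOW_QUALITY` or `MISSING`. `HQ_HOM` requires a homozygous
genotype with

* genotype quality (GQ) $\ge$ 20,
* total read depth (sum of the AD field) $\ge$ 10, and
* called-allele fraction (called-allele depth / total depth) $\ge$ 0.9.

A run of homozygosity is a maximal stretch of **at least four**
consecutive `HQ_HOM` SNVs uninterrupted by any heterozygous SNV. These
defaults live in `roh_params()` and are the thresholds a practitioner
would use for exome-depth data; raising any of them can only shrink the
detected ROH (a property the test suite checks).

Interpretation choices the rule statement leaves open, and how this
package resolves them:

* "allele counts" is read as **total** read depth, and "allele
  percentage" as the called allele's share of it — the only reading that
  is well defined for homozygous calls.
* *Any* called heterozygote interrupts a run, whatever its quality;
  `het_min_gq` can be raised to demand confident interrupting hets.
* `LOW_QUALITY` and `MISSING` sites are transparent: they neither
  support nor break runs.
* Indels never support or interrupt runs (the rule speaks of SNVs); they
  are retained for prioritization.
* A run spans its first to last supporting SNV — no extrapolation toward
  flanking heterozygotes. This is conservative and reproducible.
* No maximum inter-marker gap is imposed by default (`max_gap = Inf`);
  exome data has capture-target deserts, and splitting on physical gaps
  is left as an explicit opt-in.

Per-sample runs are **not** length-filtered. The intersection across all
affected samples (`intersect_roh()`) keeps only pieces of at least 1 Mb
(`min_shared_length`), mirroring the way shared autozygous regions are
reported in practice.

Coordinates are 1-based closed intervals throughout the package, the
native convention of the R/Bioconductor interval stack (IRanges) used
for the interval algebra; conversion to BED's 0-based half-open
convention happens exactly once, in `write_roh_bed()` /
`read_roh_bed()`.

## The exclusion cascade

`exclusion_rank()` applies five independent filters to each candidate
and retains a candidate iff none fires. Because the filters do not
interact, the retained set is invariant under any ordering (also
tested). The reasons are machine-readable:

* `fails_segregation` / `missing_data` — autosomal-recessive
  segregation: every affected member homozygous for the alternate
  allele, every genotyped unaffected parent heterozygous, no unaffected
  member homozygous. A missing parental genotype is, by default,
  recorded as `missing_data` rather than a segregation failure.
* `frequency_exceeds_cutoff` — allele frequency above 0.5% in **any**
  population database (applied per database, not pooled; the
  conservative reading).
* `control_homozygote` — any homozygote in a control database excludes
  outright under a recessive model. Control *heterozygote* counts never
  exclude on their own — carriers are expected for a recessive allele —
  and are reported as context only.
* `outside_shared_roh` — the position is not inside any shared interval.
* `phenotype_mismatch` — the annotation flag `phenotype_match = "no"`.
  This is clinical judgment supplied as input; the pipeline records it
  but cannot derive it.
* `benign_prediction_low_conservation` — fires iff **no** prediction
  label is damaging-class **and** the conservation score is known and
  below 2.0. The rule is deliberately a combination: an intermediate
  label such as "possibly damaging" does not rescue a variant whose
  conservation is low, but either a damaging call or missing
  conservation prevents the exclusion.

The built-in worked example, `index_family_example()`, encodes four
shared homozygous variants with their reported annotations and
reproduces the reported outcome — the frameshift candidate retained,
the other three excluded for a control homozygote, a phenotype mismatch
and the benign/low-conservation combination respectively. The genotype
depths, the deletion's VCF anchor base, the retained variant's own
conservation value and the shared-ROH interval coordinates are synthetic
placeholders (documented on the help page); they only exist so that all
filters run.

`x_hemizygous_scan()` covers the all-male-sibship X chromosome check:
rare variants hemizygous in every affected male, absent from unaffected
males, outside the pseudoautosomal regions (hg19 PAR bounds by default).

## The splice-boundary frameshift chain

`transcript_model()` holds a strand-aware exon structure over a genomic
sequence. For a deletion touching an exon's terminal base the package
models the *empirically observed* splice outcome: splicing is preserved
and the donor shifts to recruit the adjacent base, so the spliced cDNA
loses exactly the deleted exonic bases. Splice-site strength is not
modeled — the deterministic rule encodes an outcome that is validated by
cDNA sequencing in the motivating study design, and predicting splicing
energetics is out of scope.

`translate_consequence()` compares the reference and edited
translations, reading the edited frame through to the end of the
transcript. Classification:

* identical (stop-trimmed) proteins → `synonymous_or_identity`;
* first divergent residue is a stop → `stop_gained` (whatever the
  deletion phase — this keeps the invariant that a reported frameshift
  always has `stop_offset` $\ge$ 2 or none found);
* deleted length not a multiple of 3 → `frameshift`, with `stop_offset`
  counting the divergent residue as 1;
* otherwise → `inframe_deletion`.

HGVS protein strings use one-letter codes with `fs*N` (e.g.
`p.K2Sfs*2`), matching clinical-report style rather than three-letter
HGVS-strict; no 3'-most normalization of deletion positions is applied.
Only the standard nuclear code is supported.

## What the simulator emulates

`simulate_family()` gene-drops a ten-member pedigree — a shared
grandparental couple, their two children married to unrelated spouses,
and the resulting first cousins whose two sons are affected — and emits
the sequenced quartet's calls. Model choices:

* **Map**: linear 1 cM/Mb, Poisson crossovers without interference —
  the simplest model with the right segment-length distribution.
* **Scale**: 2 autosomes × 50 Mb at 5 markers/Mb. Large enough for
  multi-Mb shared segments, small enough for seconds-per-replicate.
* **Markers**: founder allele frequencies i.i.d. Uniform(0.1, 0.5), so
  markers are informative for descent.
* **Planted variant**: a 1-bp deletion riding one grandparental
  haplotype at 25 Mb of chromosome 1. By default the drop is resampled
  until both children are homozygous for it (`require_segregating`),
  because that *is* the ascertained study design: an unconditional drop
  produces that configuration only ~1/256 of the time. The flag is
  turned off for the unconditional Monte-Carlo checks.
* **Decoys**: shared homozygous by construction, with annotation
  profiles that the cascade must reject — a control-homozygote profile,
  a phenotype-mismatch profile, a benign-prediction/low-conservation
  profile, and (for extra decoys) a 2%-frequency profile.
* **Noise**: depth is negative binomial (size `depth_dispersion`, mean
  30; size 0 means constant depth), allele depths are binomial given the
  *called* genotype with a 0.5% per-read error, GQ is normal (60 ± 15,
  clamped to [0, 99]), and genotypes are flipped with probability 0.001.
  Drawing AD conditional on the called genotype means an erroneous call
  carries internally consistent read support — the realistic failure
  mode for a variant caller — and such errors are then mostly screened
  by the HQ thresholds rather than spuriously breaking runs. Setting all
  noise parameters to zero (`sim_config_noise_free()`) makes call
  classification exact, which several tests rely on.

What the simulator does **not** emulate: linkage disequilibrium,
demography, mutation-rate heterogeneity, exome capture bias, multiallelic
sites and caller artifacts beyond the simple flip model. Passing tests
therefore demonstrate the pipeline's logic and its Monte-Carlo
statistics, not robustness to real exome artifacts.

A visible consequence of the common-marker design: per-sample ROH tracks
contain substantial chance runs (with Uniform(0.1, 0.5) frequencies a
marker is homozygous ~60% of the time, so runs of four appear
everywhere). The >1 Mb shared filter, and ultimately the annotations,
are what cut the candidate space down — just as in real exome data.

## Problem sizes and verification

The package verifies itself at these sizes (chosen as comfortable
Monte-Carlo sizes for a desk machine):

* ROH detection against a brute-force window-enumeration oracle on
  1,000 random chromosomes of up to 200 sites.
* Mean realized autozygous fraction over 2,000 unconditional
  first-cousin offspring within 3 Monte-Carlo standard errors of
  $1/16$. (The $1/16$ is a per-child quantity; the expected
  *intersection* of two sibs' autozygomes is strictly smaller, which is
  why the check is per child.)
* Detected shared ROH covering $\ge$ 95% of truth shared autozygous
  segments longer than 2 Mb across 50 noise-free replicates.
* The planted variant uniquely retained in $\ge$ 90% of 100 segregating
  replicates under the default noise model. The dominant failure mode
  is a realized autozygous segment around the planted site too short or
  too marker-poor to survive the 1 Mb shared filter, which is the
  honest behaviour of the method, not a bug.
* 500 random 1-bp CDS deletions against an independent
  full-translation diff oracle (built on a second, unrelated
  translation implementation), plus an exhaustive frameshift-iff-phase
  check on toy transcripts.

## Known limitations

* The ROH caller is the deterministic counting rule, not a
  likelihood/HMM caller; there is no genetic-map-aware length or LD
  pruning.
* Multi-allelic sites are kept as single records and classified via the
  called allele's depth; they are never decomposed.
* The consequence module handles deletions within or at the boundary of
  a single exon; whole-exon deletions and multi-exon events are
  explicit errors, and nonsense-mediated decay is not predicted.
* `phenotype_match` and the prediction/conservation scores are inputs;
  the package neither computes nor second-guesses them.
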