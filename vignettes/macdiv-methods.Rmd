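---
title: "Comparative SNV characterization with macdiv: models and methods"
author: "macdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative SNV characterization with macdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macdiv)
```

# The setting

`macdiv` analyzes single-nucleotide variants called for several related
individuals or species against one shared reference genome. All comparisons
therefore share a coordinate system, and a site's *carrier set* — the subset
of samples whose genotype contains the alternate allele — is directly
comparable across the panel. The package's stages follow the canonical
comparative workflow: merge, filter, carrier-set analysis, per-sample
diversity summaries, codon-level effect annotation, windowed divergence
scans, and gene-set enrichment.

Internally, coordinates are handled by the Bioconductor ranges stack and all
disk formats keep their native conventions (VCF and GFF3 are 1-based, BED is
0-based half-open); conversions happen only at the I/O boundary, which keeps
window binning and codon arithmetic free of off-by-one ambiguity.

# Merging and genotype semantics

`mergeSamples()` takes the union of per-sample sites. Genotypes are unphased
(0/1 and 1/0 are the same heterozygous state). A sample with no record at a
site is scored homozygous reference when the site is callable for it;
per-sample callable tracks are an *optional* input, and in their absence
everything is treated as callable. The merged callable-site intersection of a
real resequencing study depends on per-sample usable-site tracks that a user
may not have, so the package exposes callability explicitly rather than
guessing it; the default (callable everywhere) is the fallback a user can
always reproduce.

Sites whose ref/alt alleles conflict between inputs, and records that were
multi-allelic in any input, are kept but flagged *triallelic*. This is
deliberate: the filtering stage removes and counts them, so the attrition
report reflects them instead of losing them silently at merge time.

# Conservative site filters

`applyFilters()` runs, in a fixed order: missing genotypes → triallelic →
duplication mask → CpG context → proximity. Each removed site is attributed
to the first filter that rejects it, so `input = output + sum(removed)`
always reconciles. Each filter sees the survivors of its predecessors; the
proximity filter in particular measures distances within the surviving set
and removes *both* members of a close pair, which makes the whole procedure
idempotent (a property the test suite asserts).

Tunable parameters:

* `proximityBp` (default 5 bp): the source studies name a proximity filter
  without fixing the distance, so it is configuration, not a constant; 5 bp
  is a conventional conservative choice. Setting 0 disables it. Indel
  proximity cannot be evaluated without indel calls — the filter operates on
  the supplied variant set, and indels can be provided as extra masked
  points.
* CpG context is defined on the reference strand only (C followed by G, or G
  preceded by C), which is deterministic without ancestral-state inference.
* The mask is any merged interval set, typically known segmental
  duplications.

# Carrier sets, sharing and specificity

`sharingCounts()` tabulates each variant under its *exact* carrier subset
(UpSet "distinct" mode); counts always sum to the matrix size. A carrier is
a het or hom-alt genotype — heterozygous carriage counts, because diversity
tables account specific heterozygous variants separately.

`specificSnvs()` defines a variant specific to a unit (one sample, or a
conspecific pair that must both carry) as: carrier set = unit, exactly.
Sites the outgroup carries are then excluded, since such alleles predate the
split from the outgroup. Two exclusion modes exist because the narrow
reading ("only sites shared by the whole panel *and* the outgroup") makes
the exclusion vacuous for unit-specific sites; the package defaults to
excluding *any* outgroup-carried site and leaves the narrow mode selectable
(`outgroupMode = "sharedAll"`). The outgroup is consumed as a precomputed
carrier site set — read mapping thresholds and variant calling for the
outgroup are upstream concerns.

`sharedWithinSpecies()` restricts to sites both conspecific individuals
carry and appends a merged pseudo-sample (hom-alt only when both are
hom-alt), so a two-individual species can be summarized as one sample.

# Diversity summaries

`sampleSummary()` reports, over a sample's carried variants: totals, het/hom
split, %Het, SNVs/kb, Ti/Tv, and specific-SNV counts. Percentages are
reported to 2 decimals, matching how such tables are printed. The per-kb
density denominator defaults to the summed reference chromosome lengths but
is a parameter: published per-kb rates depend on an unstated usable-genome
denominator, so the package makes the knob explicit instead of hard-coding a
reconstruction. `sharedFraction()` quotes a conspecific pair's shared SNVs
against the pair's *mean* total, the scale on which within-species sharing
is conventionally cited. Amino-acid spectra are reported both ordered
(`P>L`) and unordered (`A<->T`) because both notations are in common use;
all spectrum tables break count ties lexicographically so output is
deterministic.

# Effect annotation

Every variant receives exactly one region category with precedence
`exonic > splicing > utr > intronic > ncRNA > upstream_downstream >
intergenic`. Defaults follow the conventions of the widespread annotators:
flank 1000 bp for up/downstream, splice region = 2 intronic bases at each
exon–intron boundary. 5' and 3' UTR are collapsed into one UTR category, and
ncRNA transcripts contribute a single collapsed ncRNA category (their
intronic and splice-adjacent bases included) rather than the finer
ncRNA_exonic/intronic split.

For exonic variants (i.e. within the CDS of a coding transcript) the ref and
alt codons are built strand-aware and translated with the standard genetic
code: stop-gain when the alt codon is a stop and the ref is not, stop-loss
for the converse, otherwise synonymous iff the residues agree (stop→stop is
synonymous). A variant hitting several transcripts reports the most severe
effect (stop changes > nonsynonymous > synonymous) while retaining every
per-transcript notation string. Transcripts whose CDS length is not a
multiple of 3 are kept but flagged incomplete, and their exonic variants
annotate as effect `unknown` rather than risking a frame guess.

The annotator is validated two ways: against an exhaustive oracle over all
64 × 3 × 3 = 576 single-base codon changes, and by 100%-recovery tests of
variants *planted* by an independent code path that searches CDS space by
brute-force codon lookup.

# Window scans and the Cook's-distance outlier rule

Counts are binned on a fixed non-overlapping grid anchored at each
chromosome start (default 50 kb; 10 kb and 100 kb are the usual
alternatives). A terminal partial window is counted and reported but
excluded from influence fitting — its smaller exposure would mimic
influence. Density scans (`densityOutliers()`) use the effective window
length for per-kb rates.

The outlier detector asks: *in which windows does one sample depart from the
cross-sample consensus?* For each chromosome and each sample *j*, the
sample's complete-window counts are regressed (OLS, intercept + slope) on
the leave-one-out mean of the other samples' counts, and each window's
Cook's distance is computed from the hat-matrix form with p = 2. A window is
flagged when its distance exceeds `multiplier` (default 30) times the mean
distance of its own fit; the mean — hence the threshold — is per fit per
chromosome, matching the one-threshold-per-panel form such scans are plotted
with. This regression design is a declared interpretation: the rule "Cook's
distance greater than 30 times the mean" fixes the statistic and threshold
but not the design matrix, and the leave-one-out-consensus design makes a
window influential exactly when a single sample departs from the rest, which
is the phenomenon of interest. The design is isolated in `cooksOutliers()`
and could be swapped without touching binning or gene extraction.

Numerical conventions: a perfect fit (zero residual variance) defines all
distances as 0 with no flags; a degenerate predictor (zero spread) falls
back to intercept-only hat values; chromosomes with fewer than 4 complete
windows are skipped with a warning. The central oracle — the hat-matrix
formula against an explicit leave-one-out refit — holds to better than 1e-9
relative error over a thousand random fits, and a planted 5× single-sample
hotspot is detected in ≥95% of seeded replicates at the 30× rule.

# Enrichment

`enrich()` is a minimal over-representation engine: upper-tail
hypergeometric p-value P(X ≥ k) for k study hits in a term of size K, study
size n, background N; terms outside the size bounds (default 5–500) are
removed before testing and terms with fewer than `minK` (default 3) study
hits after; Benjamini–Hochberg adjustment runs across the surviving terms.
Both raw p and q are emitted — significance is conventionally called at raw
p < 0.05 in this literature even when an FDR correction is computed, so the
output keeps both columns visible rather than taking a side. Term maps and
backgrounds are user inputs (two-column TSV); the package bundles no
pathway/ontology content and does no ortholog mapping.

# The synthetic-data generator

`simulateDataset()` emits a complete toy study: reference FASTA, GFF3 gene
models, duplication-mask BED, per-sample VCFs, an outgroup carrier set, and
a per-variant truth table. Its model:

* **Tree.** A branch table (leaf sets + expected mutation counts μ); the
  default eight-sample panel mirrors a macaque-like phylogeny — a
  rhesus+cynomolgus clade, a sinica-group clade containing a conspecific
  pair, a divergent pig-tailed-like terminal with the largest private load
  (terminal μ = 700 of ~4100 total, so roughly 40% of its variants are
  specific), and an outgroup branch. Branch mutation counts are
  Poisson(μ).
* **Infinite sites.** All positions are drawn without replacement from one
  global pool, so no two mutations collide and every observed carrier set
  is exactly a clade — the property the sharing-concordance tests exploit.
* **Substitution model.** A mutation is a transition with probability
  κ/(κ+1) (default κ = 2.2, inside the 2.17–2.25 band observed in primate
  panels), otherwise one of the two transversions uniformly.
* **Genotypes.** Carriers are homozygous alternate, downgraded to
  heterozygous independently with probability `hetProb` (default 0.45, the
  middle of the observed 17–63% heterozygosity spread). This is the
  simplest mechanism that lets per-sample %Het be dialed.
* **Gene models.** Two-exon transcripts with UTR stubs, alternating
  strands, ATG start, single terminal stop, no internal stops; CDS length
  is rounded to codons. For every mutation landing in a complete CDS the
  truth table records the effect class computed at generation time by
  direct codon lookup — a code path independent of the annotator.
* **Hotspots.** Optional rows add private terminal-branch mutations for one
  sample inside a window range at a chosen fold over that sample's genome-
  wide expectation, for detector power studies.

Default problem sizes (2 chromosomes × 500 kb, ~4,000 mutations, 40 genes)
were chosen so a full end-to-end run takes seconds while every stage still
sees hundreds of events; the Ti/Tv calibration check uses a dedicated
100,000-mutation configuration, and the detector power study uses 100
replicate count matrices of 40 windows × 8 samples.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: linked variation and recombination (sites are
independent), recurrent/back mutation (off by default; a collision-
permitting mode exists for triallelic-filter testing), sequencing and
mapping error models, CpG hypermutability (CpG status arises only from
random context), callability gaps, and realistic gene structure beyond
two-exon models. Branch intensities are user-set expectations, not derived
from effective population sizes or mutation rates; the generator is a
structural emulator, not a coalescent simulator.

# Known limitations

* The full-scale quantities of genome-wide surveys (tens of millions of
  SNVs, hundreds of outlier bins) require the original resequencing data;
  the package validates its methods by oracle and simulation instead, and
  its published-arithmetic checks recompute printed table percentages from
  printed counts.
* The outlier detector's regression design is one defensible reading of the
  30×-mean Cook's-distance rule (see above); alternative designs would
  change which windows are influential.
* Effect annotation assumes the supplied gene models' frames are anchored
  at the annotated CDS start; transcripts failing the mod-3 check are
  flagged rather than rescued.
* The merged-VCF writer emits a minimal GT-only VCFv4.2; FORMAT fields
  beyond GT are not round-tripped.

# Reproducibility

Every stochastic component is seed-driven: `SimConfig` carries its seed,
`runPipeline()` seeds from its config, and `scripts/acceptance.R` derives
all of its seeds from `--seed`. Identical configurations regenerate
byte-identical datasets, and the pipeline writes a manifest (per-stage
counts, echoed config, hash) from which a run can be reproduced.
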