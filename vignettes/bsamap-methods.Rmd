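---
title: "Methods: pooled-scan statistics, recombinant narrowing and the crossing simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-scan statistics, recombinant narrowing and the crossing simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## Scope and model

`bsamap` localizes a single recessive causal mutation in a diploid species
from two data sources: allele depths of two pooled sequencing libraries (a
phenotype-selected mutant pool and a mapping-parent control pool), and
individual-plant genotypes at ordered PCR markers. Two mapping designs are
supported, declared with `mapping_design()`:

* `hom_f2`: homozygous mutants selected from an F2. Selection fixes the
  causal locus; the expected mutant-background allele frequency is 1 at the
  causal site, decaying with recombination distance toward the unselected
  0.5.
* `het_bc`: heterozygous carriers selected from a BC~n~F~1~ backcross
  (used when homozygotes are inviable). The causal site sits at frequency
  exactly 0.5; an unlinked site sits at $(1/2)^{n+1}$, i.e. 0.0625 after
  three backcrosses.

Throughout, the mutant-background parent is called A and the mapping parent
B; all coordinates are 1-based inclusive (VCF/GFF3 convention), converted
to 0-based half-open only inside the BED writer.

## Per-site statistics

The marker index of a site is `alt / (alt + ref)` over reads of one pool;
`marker_index()` returns `NA` on a zero total rather than dividing by zero,
and such sites are later removed by the depth filter. The delta index is
the mutant-pool index minus the control-pool index (`delta_index()`), so a
causal region is positive: ≈ 1 under `hom_f2`, ≈ 0.5 under `het_bc`.

**Allele orientation.** Variant callers count alleles relative to the
reference genome, which may match either parent at a given site.
`orient_to_mutant_background()` swaps the ref/alt slots (alleles and
counts, both pools) so that "alt" always holds the A allele. When no
per-site truth is supplied, the control pool serves as a proxy for the
mapping parent: control index ≤ 0.1 calls the mapping parent fixed for the
reference (no swap), ≥ 0.9 fixed for the alternate (swap), anything in
between is flagged `ambiguous` and excluded from scans. The 0.1/0.9 cut
tolerates sequencing error and modest contamination at 20–40× while
rejecting genuinely segregating or unreliable sites; sites swapped this way
are, by construction, polymorphisms between the two parents, which is what
`subtract_parental()` later consumes as parental evidence.

**Read-support filter.** `depth_filter()` keeps sites with *more than* 8
supporting reads (i.e. ≥ 9) in **each** pool. Applying the rule per pool is
the stricter of the readings and protects both indexes entering the delta;
the boundary is intentional — support of exactly 8 fails.

**G statistic.** `g_statistic()` computes the log-likelihood-ratio
statistic $G = 2\sum_i n_i \ln(n_i/\hat n_i)$ over the 2×2 allele-by-pool
read-count table, with expected counts from the independence margins (row
total × column total / grand total). Numerical conventions: $0\ln 0 := 0$;
a table with a zero row or column margin is degenerate and returns 0, so
scans never emit non-finite values. `top_quantile_sites()` keeps the
`ceiling(q N)` largest G values (default q = 0.001, the "top 0.1 %" rule)
and always includes ties at the cutoff rather than dropping an arbitrary
subset.

## Genome scan

`sliding_window_profile()` averages the per-site delta index in windows
anchored at position 1 of each chromosome and advanced by `step` while the
start does not exceed the chromosome length. Anchoring is fixed (not
data-dependent) so outputs are bit-reproducible. Window means are
unweighted site means — averaging site indexes, not pooling reads — so a
deep site cannot dominate a window. Windows with fewer than
`min_sites = 3` sites are masked (`NA`): pooled scans of real crosses have
marker deserts, and masking is more honest than imputing across them.
Masked windows also break runs in `call_candidate_regions()`, which merges
maximal runs of windows at or above the threshold into intervals spanning
first window start to last window end.

Defaults follow common practice for this statistic: 100 kb windows with
20 kb steps, and 500 kb / 100 kb for sparser marker sets; calling
thresholds of 0.45–0.6 depending on design and noise. These are exposed,
not hard-coded.

A population of $n$ selected plants contributes $2n$ (F2) or $n$
(backcross) informative gametes, so the realized frequency profile is a
step function: around the causal locus there is a plateau at the maximal
frequency whose width is set by the nearest crossovers in the whole pool
(hundreds of kb for 100–200 gametes at ~4 cM/Mb). Within the plateau,
window ranking is decided by read noise alone. The window-scan property
test therefore uses a 1 Mb window matched to that plateau for pools of
100–136 plants; with small pools (~32 plants) the best window can land
several hundred kb off even at 40×, which is precisely why the workflow
continues with recombinant narrowing instead of trusting the scan peak.

## Recombinant narrowing

`genotype_marker_index()` scores PCR genotypes as the fraction of A alleles
among non-missing diploid calls, $(2\,\#\mathrm{HOM_A} +
\#\mathrm{HET})/(2\,\#\mathrm{calls})$; at a fully linked marker it is
exactly 1 (`hom_f2`) or 0.5 (`het_bc`) on error-free selected mutants.
`find_recombinants()` flags plants whose call is inconsistent with full
linkage (≠ `HOM_A`, resp. ≠ `HET`); in a backcross a `HOM_A` call is
genetically impossible and is treated as a scoring error — warned about and
ignored — rather than as a recombinant. Missing calls are ignored per
plant-marker, never imputed.

`narrow_interval()` evaluates every gap between adjacent markers (plus the
two chromosome-end gaps) under the assumption of **no double crossover
within a plant between the causal locus and any single marker**. Under that
assumption each gamete carries the A allele from the causal locus outward
to at most one crossover point per side, so a plant is consistent with a
gap exactly when its A-dosage sequence, read outward from the gap on each
side (missing calls skipped), is non-increasing. The gap(s) with zero
inconsistent plants are returned as the interval bounded by the flanking
marker positions; several contiguous consistent gaps are returned as their
union. Conventions chosen where the field is loose: internal gaps are
bounded by the marker positions themselves (inclusive), chromosome-end gaps
stop one bp short of the outermost marker; markers tied at one position
keep the first and drop the rest with a warning; if *no* gap is consistent
the function stops and names the minimal-conflict gap and plants, since
that pattern indicates genotyping error or a second causal locus. The test
suite checks the non-increasing-dosage rule against an independent oracle
that exhaustively enumerates per-gamete crossover configurations.

Nested recombinant patterns (every recombinant set on one side) leave
several contiguous gaps consistent, including a chromosome-end gap; the
returned union then reaches the chromosome end. Discriminating among those
gaps requires the pooled delta-index evidence, not recombinant counts — the
reason the workflow applies `candidates_in_interval()` afterwards.

`interval_size_mbp()` reports spans as $|b-a|/10^6$ rounded half-up to two
decimals, the convention used when quoting mapping intervals. Rounding
half-up (also in `abortion_rate()` and the segregation ratio text) avoids
the round-half-even surprises of `base::round()` in printed tables.

## Candidate extraction

Within the narrowed interval, `candidates_in_interval()` keeps sites with
delta index at or above `delta_min` (closed interval, closed threshold);
0.5 is the natural floor for the heterozygous design and a conservative one
for the homozygous design. `subtract_parental()` removes variants whose
exact (chrom, pos, ref, alt) matches parental-polymorphism evidence —
matching on the full allele pair, not position, so a causal mutation that
happens to coincide with a parental SNP position survives. The two filters
commute; order is immaterial. `annotate_location()` classifies candidates
by overlap of the affected reference span (`[pos, pos + nchar(ref) - 1]`)
with exons and gene spans, and flags exonic InDels whose length difference
is not a multiple of 3 as frameshifts. Full consequence prediction
(codon-level effects) is deliberately out of scope.

Large deletions evade site-level scans, so `coverage_gap_scan()` searches
binned depth tracks for runs where the mutant pool is at or below
`gap_max_depth = 2` while **every** control stays at or above
`ctrl_min_depth = 10`, of total length ≥ 5 kb. The control condition is
what separates a real deletion from an unsequenceable repeat, which drops
out in all samples. These thresholds are not dictated by the method — the
historical alternative is eyeballing a browser track — and were chosen to
flag multi-kb homozygous deletions at 20–40× coverage while ignoring
single-bin Poisson dropouts; all three are arguments.

## Marker screening

`screen_gel_markers()` retains InDels whose parental allele lengths differ
by strictly more than 5 bp — the resolution limit of 4 % agarose
electrophoresis for PCR product-size polymorphisms, so "more than 5" is a
hard boundary (a 5 bp difference fails). With `require_fixed = TRUE` a
marker must also look like a genuine parental polymorphism: control pool
fixed (index ≤ 0.1 or ≥ 0.9) plus at least one mutant-pool read of the
opposite allele. No floor is put on the mutant-pool *index*: in a BC3F1
population an unlinked marker legitimately sits near 0.0625, yet is fully
informative plant-by-plant. Externally supplied repeat-based markers
(SSR/SSLP lists from community databases) are not re-derived from repeat
motifs; `verify_external_markers()` validates them against the
resequencing variants with the same length-difference rule.
`extract_flanks()` cuts ±250 bp of reference sequence around each marker
(truncated at contig edges) for primer design, which itself is out of
scope.

## The crossing simulator

The simulator generates the data structures the method assumes, nothing
more:

* `simulate_parents()` draws biallelic parental polymorphisms (SNPs and
  InDels, positions on a 50 bp grid so alleles never overlap when the
  reference is materialized) plus one causal SNP unique to the mutant line.
  `background` controls which parent matches the reference genome; the
  default `"ref"` (reference = mutant line's progenitor) makes every
  parental polymorphism visible in the control pool, the cleanest setting
  for exercising parental subtraction from data alone.
* `simulate_population()` performs Haldane-model meiosis: crossover counts
  Poisson in the map length (default 4 cM/Mb, a typical plant genome-wide
  average), positions uniform, no interference. Selection is implemented
  by *exact conditional sampling*: the selection event "this gamete
  transmits the A haplotype at the causal locus" is precisely a condition
  on the crossover phase at that position, so the phase is anchored there
  instead of rejection-sampling gametes. The conditional law is identical,
  every draw is accepted, and the causal-site frequency is exactly 1
  (`hom_f2`) or 0.5 (`het_bc`) in every replicate, as selection dictates.
  `select = FALSE` gives unselected populations (used to verify 1:2:1 F2
  ratios and Haldane's map function against theory).
* `sample_pool_reads()` draws per-site total depth Poisson(depth) and
  focal-allele counts Binomial with the symmetric per-read error rate
  (default 0.002) folded into the frequency. `simulate_pooled_variants()`
  assembles the two-pool count table with the control pool fixed for the
  mapping-parent allele.
* `make_fixture()` writes a complete dataset — two-sample VCF with AD
  fields, genotype TSV with marker side-car, toy GFF3 in which the causal
  site is exonic, reference FASTA with the simulated alleles embedded,
  binned depth track with an optional planted deletion, and a `truth.json`
  — all byte-reproducible from one master seed via named per-stage
  sub-streams.

Default study conditions mirror the designs the package targets: pools of
30–200 plants, 40× mutant / 20× control coverage, three backcrosses in the
heterozygous design, a 23.5 kb planted deletion for the gap scan. What the
simulator deliberately does **not** model: read-level artefacts (mapping
bias, duplicated regions, reference errors), crossover interference,
segregation distortion, and polyploid genetics. Passing tests therefore
demonstrate the statistical machinery under idealized sequencing, not
robustness to alignment pathology — on real data the multi-region,
low-signal behaviour of the scans is expected to be worse, which is exactly
the gap the recombinant-narrowing stage closes.

## Problem sizes used by the test suite

Simulation-backed tests state their conditions explicitly and keep desk
scale: the window-overlap property uses a 20 Mb chromosome with one variant
per 4 kb, pools of 100 (F2) and 136 (BC3F1) plants at 40×, 50 seeded
replicates per design; the narrowing oracle runs 200 independent 8-plant ×
6-marker panels; end-to-end recovery runs 50 fixtures of 32 plants and 300
sites; the G-statistic identity is checked exhaustively on all 2×2 tables
with grand total ≤ 30. The acceptance script averages 1,000 simulated
populations (unlinked-frequency expectation) and 200 pool pairs
(causal-site delta index).

## Known limitations

* Single causal locus per run. Two-gene phenotypes (duplicate recessives)
  must be mapped as two independent single-locus analyses; the narrowing
  step reports the conflicting plants if one panel mixes two loci.
* No confidence bands on the delta index; the workflow uses fixed
  thresholds, trading formal coverage for simplicity and reproducibility.
* Polyploids are unsupported: allele dosage makes both the marker index and
  the recombinant logic ambiguous there.
* Mutations with no sequence change (epigenetic alleles) can be localized
  by the marker/recombinant machinery, but candidate extraction then
  requires expression data outside this package's scope.
* `narrow_interval()`'s single-crossover assumption can be violated over
  long marker spans in large populations; the error message (minimal
  conflict set) is designed to make that visible rather than silently
  returning a wrong gap.
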