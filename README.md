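# bsamap

Bulked segregant analysis and recombinant mapping of plant mutations.

## The problem

Forward genetics starts from a phenotype — an albino ovule, a yellow-green
seedling — and has to find the mutation behind it. Classical map-based
cloning does this with PCR markers and hundreds of plants; pooled
whole-genome sequencing (BSA-seq / MutMap-style scans) does it with two
sequencing libraries, but often produces dozens of candidate regions and
fails outright for heterozygous mutants, whose linked-allele signal is half
as strong. In practice the two approaches are complementary: pooled
sequencing supplies an essentially unlimited marker catalogue, and a small
genotyped population of recombinants turns a noisy genome-wide scan into a
marker-bounded interval containing a handful of candidate variants.

`bsamap` implements that combined workflow end to end for diploid species
with a reference genome, for both mapping designs:

* **homozygous F2 design** — phenotyped F2 mutants from a cross to a mapping
  parent; the mutant pool is fixed for the causal allele;
* **heterozygous backcross design** — BC<sub>n</sub>F<sub>1</sub>
  heterozygote carriers (for mutations whose homozygotes are inviable);
  after three backcrosses an unlinked marker carries the mutant-background
  allele at frequency 1/16 = 0.0625 while fully linked markers sit at 0.5.

## The statistics

For a biallelic site with pooled read counts, the **marker index** is the
fraction of reads carrying the mutant-background parent's allele,

```
marker index = alt / (alt + ref)
```

(after orienting counts so "alt" is the background parent's allele), and the
**Δ marker index** is the mutant-pool index minus the control-pool index:
≈ 1 at a causal site in the homozygous design, ≈ 0.5 in the heterozygous
design, ≈ 0 elsewhere. Sites need more than 8 supporting reads per pool to
enter a scan; window means over 100 kb–1 Mb sliding windows are compared to
a threshold (0.45–0.6) to call candidate regions. Per site, the **G
statistic**

```
G = 2 * sum_i n_i * ln(n_i / n̂_i)
```

over the 2×2 allele-by-pool count table (expectations `n̂` from the table
margins) flags phenotype-linked sites; the top 0.1 % of G values are kept.

**Recombinant narrowing** then places the causal locus between PCR markers:
a selected mutant plant is a recombinant at a marker when its genotype is
inconsistent with full linkage (not homozygous-background in the F2 design,
not heterozygous in the backcross design). Assuming at most one crossover
per gamete between the causal locus and any marker, a candidate gap between
adjacent markers is consistent with a plant exactly when the plant's
background-allele dosage, read outward from the gap, never increases; the
gap(s) consistent with every plant form the mapping interval. Inside it,
candidate variants are filtered by Δ index, stripped of parental
polymorphisms (exact chrom/pos/ref/alt matches against the mapping-parent
evidence), annotated against gene models, and large deletions are picked up
as mutant-specific coverage gaps in binned depth tracks.

A forward simulator (`simulate_parents()`, `simulate_population()`,
`make_fixture()`) generates complete synthetic datasets — parental
polymorphisms, Haldane-model meiosis with phenotype selection, pooled read
sampling, VCF/TSV/GFF3/FASTA fixture files — so the whole pipeline can be
exercised and power-checked without any external data.

## Worked example

Simulate a 32-plant homozygous-F2 fixture (40× mutant pool, 20× control
pool), then run the full scan → narrow → candidates pipeline:

```r
library(bsamap)

fixture  <- make_fixture("demo", design = mapping_design("hom_f2"),
                         n_plants = 32, seed = 42)
raw      <- read_pooled_variants("demo/pools.vcf",
                                 mutant_sample = "mutant_pool",
                                 control_sample = "control_pool")
oriented <- orient_to_mutant_background(raw)
stats    <- depth_filter(pool_site_stats(oriented))

profile  <- sliding_window_profile(stats, c(chrA = 2e6, chrB = 1e6),
                                   window = 1e5, step = 2e4)
call_candidate_regions(profile, threshold = 0.9)
#> # A tibble: 1 × 7
#>   chrom start     end label          source      n_windows peak_delta
#>   <chr> <dbl>   <dbl> <chr>          <chr>           <int>      <dbl>
#> 1 chrA      1 2060000 chrA:1-2060000 window_scan        99          1

geno   <- read_genotype_table("demo/genotypes.tsv")
narrow <- narrow_interval(geno, mapping_design("hom_f2"), chrom_length = 2e6)
glance(narrow)
#> # A tibble: 1 × 6
#>   chrom start     end label              source      span_mbp
#>   <chr> <dbl>   <dbl> <chr>              <chr>          <dbl>
#> 1 chrA  37000 1517500 chrA:37000-1517500 marker_pair     1.48

candidates_in_interval(stats, narrow$interval, delta_min = 0.5) |>
  subtract_parental(dplyr::filter(oriented, swapped)) |>
  annotate_location(read_gene_models("demo/genes.gff3")) |>
  dplyr::filter(location_class == "exonic")
#> # A tibble: 1 × ...
#>   chrom     pos ref   alt   delta_index gene_id
#> 1 chrA  1000025 C     G               1 GENE_CAUSAL
```

The whole-chromosome scan region shows why pooled sequencing alone is not
enough at this population size; six PCR markers narrow it to 1.48 Mbp, and
after removing parental polymorphisms a single exonic candidate remains —
the planted causal variant (`fixture$parents$causal`, chrA:1000025).

Phenotype-ratio utilities cover the segregation bookkeeping around such a
screen:

```r
chi_square_segregation(c(62, 24), c(3, 1))
#> Segregation test: observed 62:24 (2.58:1) vs expected 3:1
#>   chi-square = 0.3876, df = 1, p = 0.534
abortion_rate(209, 789)
#> [1] 26.49
```

A command-line interface wrapping these functions is installed at
`system.file("exec/bsamap", package = "bsamap")` with subcommands
`import-vcf`, `index`, `scan`, `markers`, `narrow`, `candidates`, `gaps`,
`simulate` and `segregation`.

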