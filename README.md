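# mutmapr

Bulked-segregant mapping of recessive EMS-induced mutations from two
pooled sequencing libraries — the "modified MutMap" design in which *both*
the mutant-phenotype pool and the wild-phenotype pool are sequenced and
aligned to a public reference genome, so no parental genome assembly is
needed.

The package is for geneticists mapping a causal point mutation from a
mutant × progenitor cross: it takes variant calls with per-pool allelic
depths (a two-sample VCF or a plain counts table) and carries them through
the whole downstream analysis — SNP indices, the windowed genome scan,
candidate-region calling, SNP effect annotation and screening, and CAPS
marker design — and it ships a forward-genetic simulator of the entire
cross-and-pool design so every statistic can be validated against its
theoretical expectation without any sequencing data.

## The statistic

For each biallelic SNP, the **SNP index** of a pool is the fraction of
reads carrying the non-reference allele; the mapping statistic is

```
Δ(SNP index) = index(pool A, mutant phenotype) − index(pool B, wild phenotype)
```

Under a single recessive causal gene, pooling 50 plants per phenotype
class from the mapping population gives, in expectation:

| locus | index A | index B | Δ |
|---|---|---|---|
| causal SNP | 1 | 1/3 | **2/3** |
| unlinked locus | 1/2 | 1/2 | 0 |
| fixed parental-vs-reference difference | ≈1 | ≈1 | ≈0 |

The last row is the design's key trick: aligning both pools to the public
reference makes the (numerous) fixed parental differences cancel in Δ,
while the EMS-induced causal SNP stands out as a genome-wide peak. A
pooled-frequency Fst (Nei's G<sub>ST</sub>, `pooled_fst()`) carries the
same signal: 0.5 at the causal expectation (1, 1/3), 1 at a fixed
difference between pools.

## Worked example

Simulate the full design (12 × 30 Mb genome, 500 EMS SNPs, 2,000 fixed
background differences, 50 + 50 plants pooled, 30× per pool), then scan
for the candidate region:

```r
library(mutmapr)

sim <- simulate_cross(sim_config(seed = 2018))
tb  <- sim$table                      # variant table with indices computed
causal <- sim$truth$causal            # hidden truth: chr04:13,894,442

tb[tb$chrom == causal$chrom & tb$pos == causal$pos,
   c("chrom", "pos", "ref", "alt", "snp_index_a", "snp_index_b", "delta")]
#>  chrom      pos ref alt snp_index_a snp_index_b   delta
#>  chr04 13894442   G   A           1     0.28125 0.71875

lengths <- setNames(rep(3e7, 12), sprintf("chr%02d", 1:12))
informative <- drop_fixed_differences(tb)
windows <- sliding_windows(informative, lengths)     # 50 kb / 10 kb step
regions <- call_candidate_regions(windows, table = informative)
regions[1, c("chrom", "start", "end", "peak_delta", "n_snps")]
#>  chrom    start      end peak_delta n_snps
#>  chr04 11910001 16510001  0.7692308      8
```

The top-ranked candidate region (4.6 Mb, 8 SNPs) contains the causal SNP,
whose observed indices sit at their expectations (A = 1, B ≈ 1/3,
Δ ≈ 2/3).

Mendelian sanity check of field phenotype counts against 3:1:

```r
segregation_test(820, 267)
#> Segregation test: 820:267 observed vs 3:1 expected
#>   chi-square = 0.1107 (df = 1), p = 0.7393 -> consistent at alpha = 0.05
```

Screening candidate SNPs — here the package's bundled example data, the
19 published candidate SNPs from the rice *wb1* white-belly endosperm
mapping experiment (delta values and effect labels as printed):

```r
snps <- wb1_candidate_snps()
screen_pipeline(snps, annotations = snps)
#> Candidate-SNP screen: 19 SNP(s) in 12 gene(s) survive
#> # A tibble: 2 × 3
#>   step         removed remaining
#>   <chr>          <int>     <int>
#> 1 delta_range        0        19
#> 2 effect_class       0        19
```

All 19 SNPs fall inside the Δ ∈ [0.6, 0.8] retention band and none is
intergenic or synonymous, so all survive, in 12 distinct genes. With gene
models (GFF3) and a genome (FASTA), `screen_pipeline()` computes the
effects itself via `classify_effects()` — e.g. a G→A transition at the
first base of codon GCG is reported as `missense`, `GCG>ACG`,
alanine→threonine, and flagged as a canonical EMS change.

Finally, a CAPS assay to genotype the candidate by restriction digestion
(HaeII site RGCGCY):

```r
caps_check("TTAGCGCCTT", snp_offset = 5, ref_base = "C", alt_base = "T", "HaeII")
#> [1] "site_lost"
```

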