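---
title: "Two-pool delta SNP-index mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pool delta SNP-index mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping design

mutmapr implements bulked-segregant mapping for a recessive EMS-induced
mutation, in the MutMap family of designs, with the two-pool variant that
sequences **both** phenotype classes and aligns them to a **public
reference genome** rather than to a parental assembly.

The cross is: EMS mutant x its pre-mutagenesis progenitor line; the F1 is
selfed; the segregating F2 (optionally confirmed through selfed F2:3
pedigrees) is phenotyped, and DNA from 50 mutant-phenotype plants (pool A)
and 50 wild-phenotype plants (pool B) is pooled in equal amounts and
sequenced at about 30x coverage per pool.

For each biallelic SNP the **SNP index** of a pool is the fraction of
reads carrying the non-reference allele, and

$$\Delta(\text{SNP index}) = \text{index}_A - \text{index}_B.$$

Under a single recessive causal gene:

* at the causal SNP, every pool-A plant is homozygous mutant, so
  $\text{index}_A = 1$; pool-B plants are the dominant class
  (wild-type : heterozygous = 1 : 2), so $\text{index}_B = 1/3$ and
  $\Delta = 2/3$;
* at loci unlinked to the causal gene both pools sit at $1/2$ and
  $\Delta = 0$;
* at **fixed parental-line-versus-reference differences** both pools sit
  near 1 and $\Delta \approx 0$.

The last point is the reason for aligning both pools to the public
reference: fixed differences -- by far the most numerous variant class --
identify themselves (high index in both pools) and cancel in $\Delta$, so
no parental genome assembly is needed. A pooled-frequency $F_{ST}$
(Nei's $G_{ST}$ computed from the two pool frequencies, `pooled_fst()`)
carries the same information in practice: 0 for identical pools, 0.5 at
the causal expectation $(1, 1/3)$, 1 for a fixed difference between
pools.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_depth` | 10 | reads/pool | below this a pool's index is *undefined* (`NA`), never 0; at 30x Poisson depth fewer than 0.001% of SNPs are lost |
| `delta_low`, `delta_high` | 0.6, 0.8 | -- | retention band around the causal expectation 2/3; bounds inclusive |
| `window_size` | 50,000 | bp | sliding-window width for the genome scan |
| `step_size` | 10,000 | bp | window step ("walking") |
| `region_threshold` | 0.5 | -- | windowed-$\Delta$ level entering a candidate region; halfway between the unlinked (0) and causal (2/3) expectations |
| `max_gap_windows` | `window/step` (5) | windows | below-threshold *defined* windows tolerated inside one region (see below) |
| `alpha` | 0.05 | -- | significance for the 3:1 segregation chi-square (df = 1, critical value 3.841) |

## The synthetic-data generator

`simulate_cross()` emulates the full design with known truth so that every
statistic can be checked against its expectation without sequencing data:

* **Genome and variants.** 12 chromosomes of 30 Mb; 500 EMS SNPs
  (70% canonical G:C>A:T transitions) homozygous in the mutant parent;
  2,000 background SNPs homozygous alternate in *both* parents (fixed
  differences from the reference).
* **Meiosis.** Crossovers are a Poisson process along the chromosome at
  `recomb_rate` = 4 cM/Mb with no interference (Haldane model). At the
  marker loci this is realised exactly as a Markov chain whose switch
  probability between adjacent loci is the Haldane recombination fraction
  $r = (1 - e^{-2d})/2$ at map distance $d$ Morgans -- the two
  formulations are equivalent in distribution at the loci, and the chain
  vectorises cleanly.
* **Phenotype and pools.** A plant is mutant iff it carries dosage 2 at
  the causal SNP. The initial F2 of `n_f2_individuals` (default 100)
  is grown in additional batches until both phenotype classes reach
  `pool_size` (default 50) -- exactly as a field experiment screens more
  plants than it finally pools; an F2 of 100 contains only ~25 recessive
  plants, so a 50-plant recessive pool always requires this. Extra
  individuals are unselected, so segregation ratios stay unbiased.
* **Pooled reads.** Per SNP and pool, depth ~ Poisson(30) and alternate
  reads ~ Binomial(depth, $f'$) with $f' = f(1-e) + (1-f)e$, where $f$ is
  the pool's true allele frequency and $e$ = 0.002 the per-read error.
  With $e > 0$ the pool-A index at the causal SNP is centred at $1 - e$,
  not exactly 1.
* **Pedigree confirmation.** `advance_generation()` selfs every F2 plant
  into an F2:3 pedigree and re-classifies the parent by the majority of
  its progeny phenotypes; because homozygotes breed true this removes
  essentially all phenotype misclassification (`pheno_error_rate`,
  default 0). Pooled DNA is modelled by the *parent's* genotype: pooling
  many pedigree plants in equal ratio recovers the parent's expected
  allele content, and this keeps the pool-B expectation at the design
  value 1/3. Sampling a single plant per pedigree instead would shift the
  dominant-pool frequency to 1/5 ($\Delta = 0.8$), which is not the
  design being emulated.

**What the simulator does not model:** read alignment and mapping bias,
base-quality variation, depth heterogeneity beyond Poisson, crossover
interference, segregation distortion, polygenic or environmentally leaky
phenotypes. Passing tests therefore demonstrate the *statistical* machinery
under the stated genetic model, not robustness to alignment artefacts in
real data.

## Genome scan and candidate regions

Windows are anchored at position 1 and use half-open membership
`start <= pos < start + window_size`; the windowed statistic is the
**unweighted** mean $\Delta$ over member SNPs (matching the plain
"average SNP indices" reading of the method; depth weighting would let a
single deep SNP dominate). SNPs with undefined $\Delta$ count neither in
the mean nor in `n_snps`, and windows with fewer than
`min_snps_per_window` SNPs are *undefined* rather than 0, so SNP-free
stretches can never suppress or dilute a region.

Candidate regions are maximal runs of defined windows at or above
`region_threshold`; undefined windows are transparent. Two design choices
here were genuinely open:

* **Gap tolerance.** A single SNP's $\Delta$ estimate at 30x has a
  standard deviation near 0.1, so inside a genuinely linked region an
  isolated SNP will dip below the threshold regularly. A region therefore
  tolerates up to one full window width (`window_size/step_size` = 5
  windows, i.e. one sub-threshold SNP cluster up to 50 kb) of defined
  below-threshold windows before it splits. Strict behaviour
  (`max_gap_windows = 0`) remains available.
* **Fixed-difference filter.** Background fixed differences are
  recognisable (index $\ge$ 0.9 in both pools, `drop_fixed_differences()`)
  and carry no linkage information -- a recessive causal SNP cannot
  exceed 1/3 in the wild pool -- yet at realistic densities they would
  fragment or dilute windowed means inside the causal region. The scan
  pipeline (`cmd_scan()`) removes them by default before windowing.

Regions are ranked by their peak windowed $\Delta$, and the peak window
is reported alongside the span. Ties and boundaries: `which.max` takes
the first peak; spans run from the first to the last qualifying window
(`end` exclusive).

## Effect classification

Coding effects substitute the alternate base into the strand-corrected
codon and translate with the standard genetic code. The vocabulary is
`intergenic`, `intron`, `splice_region`, `five_prime_utr`,
`three_prime_utr`, `synonymous`, `missense`, `nonsense`. Conventions:

* splice regions follow the SnpEff-style definition -- intronic positions
  within 8 bp of an exon boundary, exonic positions within 3 bp; the
  splice label outranks `intron` and `synonymous` but never
  `missense`/`nonsense`;
* a substitution destroying a stop codon is reported as `missense` (the
  vocabulary has no stop-loss class);
* models must carry a complete CDS (length divisible by 3, phase 0 at the
  first coding segment); violations are errors, not silent reframes;
* when several gene models overlap a SNP, each model yields one
  annotation, and the screen keeps the SNP if *any* annotation is neither
  intergenic nor synonymous.

The three-step screen retains SNPs with $\Delta$ in the 0.6--0.8 band
(inclusive -- the published candidate set spans 0.61--0.758, so either
convention fits; inclusivity is the predictable choice), drops
intergenic/synonymous SNPs, and emits a validation worklist with flanking
coordinates standing in for the wet-lab Sanger confirmation step.

## CAPS markers

Recognition sites are IUPAC-degenerate strings matched case-insensitively
on both strands (palindromic sites, like HaeII's RGCGCY, need only the
forward scan); `N` in the amplicon never satisfies a degenerate code.
Fragment lengths use the top-strand cut position (HaeII = RGCGC^Y, five
bases 5' of the cut); the cut offset is caller-overridable since cut
geometry varies by enzyme.

## Problem sizes and numerical checks

The test-suite and the acceptance script use the study's design values
(50 + 50 plants, 30x per pool, 500 EMS + 2,000 background SNPs over 12 x
30 Mb) with 100 seeded replicates for the expectation checks, an F2 of
10,000 for the segregation ratio, and smaller genomes (2-3 chromosomes of
5-10 Mb) where only mechanics are exercised. Property checks compare
windowed means against a brute-force rescan, translation against an
independent codon table over all 576 single-base codon substitutions, and
restriction fragments against length conservation; all simulation is
bit-reproducible under a fixed seed.

## Known limitations

* With 500 EMS SNPs genome-wide, single-SNP windows dominate the scan and
  the peak-ranked top region misses the causal SNP in roughly 5% of
  simulated replicates (a moderately linked SNP a few Mb away can
  out-peak the causal fragment); real mutant-pool data with dense SNP
  calls inside the candidate region is considerably easier. Published
  data of this design reported ~275 SNPs within a 2.5 Mb region --
  two orders of magnitude denser than the simulator's genome-wide
  default.
* The screen's effect step depends entirely on the supplied gene models;
  isoform selection is deliberately out of scope (every overlapping model
  is annotated).
* `pooled_fst()` is a descriptive pooled-frequency $G_{ST}$, not a
  variance-corrected estimator; it is reported for comparability, not
  inference.
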