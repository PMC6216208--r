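# gwasrx

Case-control association statistics and network-based drug repurposing for
GWAS follow-up studies, as a tidyverse-native R package.

## What it is for

After a genome-wide association study identifies risk loci, two analysis
tracks typically follow:

1. **Single-SNP association review.** From per-SNP genotype-count triples
   (hom-minor / het / hom-major in cases and controls), compute the minor
   allele frequency, the Cochran–Armitage trend test, the genotypic 2×3
   chi-squared test, the exact Hardy–Weinberg equilibrium (HWE) test in each
   cohort, genotyping call rates, and the allelic odds ratio with a Wald
   confidence interval — the standard summary table of a candidate-locus
   association study. Supporting statistics include two-locus LD r² from
   phased haplotype counts and inverse-variance fixed-effects meta-analysis
   of per-study log odds ratios.

2. **In silico drug repurposing.** Expand the GWAS risk genes by their direct
   protein–protein-interaction (PPI) neighbors, combine seeds and neighbors
   into a disease gene set, intersect with the target genes of approved
   drugs, and report candidate drug families with per-gene provenance and the
   full count cascade.

A synthetic-data module simulates genotype counts under an additive
allelic-odds disease model and builds planted screen instances with known
truth, so both tracks are testable end to end without external databases.

## The statistics at the core

For genotype counts $(n_2, n_1, n_0)$ (minor-allele dose 2, 1, 0) in cases
and controls:

* **MAF** $= (2 n_2 + n_1) / 2n$.
* **Trend test** (additive scores $w = (0,1,2)$ over hom-major → hom-minor,
  1 df, no continuity correction):
  $X^2 = U^2/V$ with $U = \sum_i w_i (r_i - \bar p\, t_i)$,
  $V = \bar p(1-\bar p)\left(\sum_i w_i^2 t_i - (\sum_i w_i t_i)^2/N\right)$,
  where $r_i$ are case counts, $t_i$ pooled counts, $\bar p$ the case
  fraction.
* **Exact HWE test**: sum of the conditional (hypergeometric) null
  probabilities of all heterozygote counts no more probable than the
  observed one (standard, not mid-p).
* **Allelic OR**: from the 2×2 allele table, with a Wald interval on the log
  scale ($\mathrm{SE} = \sqrt{\sum 1/\text{cell}}$) and the 0.5
  Haldane–Anscombe correction when a cell is empty.
* **LD**: $r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))$, $D = p_{AB} - p_A p_B$.
* **Meta-analysis**: $\hat\beta = \sum w_i \beta_i / \sum w_i$,
  $w_i = 1/\mathrm{se}_i^2$, $\mathrm{se} = (\sum w_i)^{-1/2}$.

The screen is set algebra on uppercase-normalised gene symbols: the disease
set is the disjoint union of seeds and first neighbors (so
`n_disease = n_seed + n_neighbor` always holds), hit genes are its
intersection with targets of drugs passing the approval filter, and the
family count follows an explicit grouping rule (one drug = one family unless
a family mapping is supplied).

## Worked example

The package bundles the genotype counts of five representative SNPs at the
*RIT2* Parkinson's disease locus (988 cases, 2521 controls):

```r
library(gwasrx)
counts <- read_genotype_counts(system.file("extdata", "rit2_snp_counts.tsv",
                                           package = "gwasrx"))
assoc <- assoc_table(counts)
dplyr::select(assoc, snp_id, maf_case, maf_control, p_trend,
              p_hwe_control, or_allelic, ci_low, ci_high)
#> # A tibble: 5 × 8
#>   snp_id    maf_case maf_control   p_trend p_hwe_control or_allelic ci_low ci_high
#>   <chr>        <dbl>       <dbl>     <dbl>         <dbl>      <dbl>  <dbl>   <dbl>
#> 1 rs879215     0.124       0.163 0.0000459         0.215      0.729  0.625   0.849
#> 2 rs4243267    0.316       0.370 0.0000253         0.732      0.789  0.706   0.881
#> 3 rs4441358    0.315       0.369 0.0000169         0.765      0.785  0.702   0.877
#> 4 rs4536548    0.317       0.370 0.0000301         0.732      0.791  0.708   0.883
#> 5 rs4130047    0.420       0.363 0.0000137         0.830      1.27   1.14    1.41
```

The index SNP rs4130047 shows the strongest trend association
(P = 1.37×10⁻⁵): cases carry the C allele more often than controls
(MAF 0.420 vs 0.363), with an allelic odds ratio of 1.27 (95% CI 1.14–1.41);
control genotypes are consistent with HWE (exact P = 0.830), as expected for
a well-genotyped SNP.

```r
allelic_or(c(176, 477, 335), c(330, 1172, 1018))
#> # A tibble: 1 × 6
#>      or ci_low ci_high log_or     se corrected
#>   <dbl>  <dbl>   <dbl>  <dbl>  <dbl> <lgl>
#> 1  1.27   1.14    1.41  0.236 0.0542 FALSE
```

A toy repurposing screen — seed gene `A`, a four-edge network, two approved
drugs of which one targets a disease gene:

```r
net <- ppi_network(data.frame(a = c("A", "A", "C"), b = c("B", "C", "D")))
drugs <- drug_targets(data.frame(drug_id = c("d1", "d2"),
                                 drug_name = c("one", "two"),
                                 target_gene = c("B", "Q"),
                                 approval_status = "approved"))
screen_report("A", net, drugs)
#> Drug-repurposing screen report
#>   seeds 1 + PPI neighbors 2 = disease genes 3
#>   drug target genes (filtered) 2; hit genes 1; candidate drug families 1
```

`glance()` returns the count cascade as a tibble, `tidy()` the candidate
drug–gene rows; `plot_regional()`, `autoplot()` (forest plot) and
`plot_power_curve()` render the result types with ggplot2. A thin CLI
(`inst/cli/gwasrx`, subcommands `assoc`, `screen`, `simulate`, `meta`)
wraps the same functions for shell pipelines.

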