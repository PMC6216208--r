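---
title: "Methods: case-control association statistics and the PPI drug-repurposing screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association statistics and the PPI drug-repurposing screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasrx)
```

This vignette is the package's account of its methods: the statistical
models, the conventions and defaults, the choices made where several
defensible options existed, and what the synthetic-data checks do and do not
establish about real data.

## The genotype-count data model

Everything in the association track starts from per-SNP genotype-count
triples in cases and controls. The triple ordering is fixed throughout as
**(hom-minor, het, hom-major)** — the minor-allele dose runs 2, 1, 0 across
the triple. Readers and the constructor (`genotype_counts()`,
`read_genotype_counts()`) validate this shape: non-negative integer counts,
each triple summing to at least one genotyped sample, distinct allele
labels, unique SNP ids. Positions are 1-based with the genome build carried
as a free-text label (default `"hg19"`); no strand flipping or allele
harmonisation is attempted — supplying consistently oriented counts is the
caller's responsibility. Per-cohort `*_missing` counts (samples attempted
but not called) exist only to produce call rates.

## Association statistics

**Trend test.** `catt_test()` is the Cochran–Armitage score test with
genotype weights `(0, 1, 2)` by default — the additive model that is the
GWAS standard — with no continuity correction, referred to the upper tail of
chi-square(1). The statistic is invariant to simultaneously reversing the
genotype ordering in both cohorts (equivalently, relabelling which allele is
"minor"), which the test suite asserts as a property. When the pooled sample
is monomorphic the score variance is zero; the function returns statistic 0
and p = 1 with a warning and a `degenerate` flag rather than `NaN`, so that
batch runs over many SNPs degrade gracefully.

**Genotypic test.** `genotypic_chi2_test()` is the Pearson chi-square on the
2×3 cohort-by-genotype table (again uncorrected), delegating to
`stats::chisq.test()`. Genotype classes with zero pooled count are dropped
and the degrees of freedom reduced; fewer than two occupied classes is an
error because no contingency test exists.

**Exact HWE test.** `hwe_exact_test()` enumerates every heterozygote count
consistent with the observed allele counts, evaluates the conditional
(hypergeometric) null probability of each configuration via a log-factorial
closed form, and sums the probabilities of all configurations no more
probable than the observed one. This is the standard exact test, **not** the
mid-p variant; the probability comparison uses a relative tolerance of 1e-9
so that floating-point ties count as ties. The asymptotic 1-df chi-square
(`hwe_chisq_test()`) is also exported, but the exact test is the default
everywhere: the two disagree noticeably whenever the expected
minor-homozygote count is modest, and published summary tables of the kind
this package reproduces are consistent with the exact form. A monomorphic
sample returns p = 1 by convention.

**Allelic odds ratio.** `allelic_or()` collapses genotypes to allele counts,
forms the 2×2 table, and reports the Wald interval on the log scale at a
configurable level (default 0.95). Any empty allele cell triggers the 0.5
Haldane–Anscombe correction on all four cells, flagged in the output; the
uncorrected estimator is used otherwise. Wald was chosen over exact or
score intervals because it is the convention for GWAS summary tables and is
what downstream inverse-variance meta-analysis consumes (`log_or` and `se`
are returned alongside).

**LD and meta-analysis.** `ld_r2()` takes *phased* haplotype counts — the
package deliberately does not implement EM phasing; r² is undefined at a
monomorphic locus and errors rather than returning 0. `fixed_effects_meta()`
is the closed-form inverse-variance pool; the test suite cross-checks it
against an independent meta-analysis implementation. Pooling one study
returns that study unchanged; pooling k identical studies divides the
standard error by sqrt(k) — both asserted as properties.

**Output precision.** Machine-readable writers print association p-values in
scientific notation with three significant digits (lower-case `e`) and
fractions (MAF, call rates, HWE p) to four decimals, matching the precision
at which such tables are conventionally published; full-precision values are
always available from `assoc_table()` itself.

## The repurposing screen

The screen is deterministic set algebra over uppercase-normalised gene
symbols. Design choices that were genuinely open:

* **Neighbors exclude seeds.** `first_neighbors()` subtracts the seed set
  from the neighbor union, so the disease set size is exactly
  `n_seed + n_neighbor` and interactions among seed genes never create
  "neighbor" entries. This is the arithmetic implied by reporting the
  combined set as seeds + neighbors.
* **Symbol identity.** Genes are compared as uppercase symbol strings; no
  Entrez/UniProt mapping layer exists. PPI and drug databases differ in
  their identifier discipline, and any mapping is better done explicitly by
  the caller than implicitly by this package.
* **Approval filter position.** The drug table is filtered to the approval
  whitelist (default `"approved"`) *before* intersection with the disease
  set, and `n_drug_target_genes` counts targets of filtered drugs. The
  filter is a parameter, so the opposite convention is one argument away.
* **Family rule.** "Drug family" has no universal definition; the default is
  one drug = one family, overridable by a record-level `family_id` or an
  external `family_map`. Conflicting assignments are an error, not a silent
  preference.
* **Normalisation is silent but counted.** Self-loops and duplicate or
  reversed PPI edges are removed with a message stating how many records
  were dropped; the same for duplicate (drug, target) records.

`screen_report()` orders candidates lexicographically by drug id and target,
making reports byte-identical across runs on identical inputs — asserted in
the tests by writing the report twice.

## The synthetic-data generator

`disease_model()` + `simulate_genotype_counts()` emulate a case-control
genotyping study: controls are multinomial from Hardy–Weinberg proportions
(p², 2pq, q²) at the population MAF, and case genotype probabilities are
those proportions tilted multiplicatively by `or_per_allele^dose` and
renormalised. This is the generative model under which a single allelic
odds ratio is the natural effect summary: the case allele frequency has the
closed form `p·OR / (1 − p + p·OR)`, and the population allelic odds ratio
equals `or_per_allele` exactly — the test suite verifies the closed form
against large-n simulation. Defaults used in the calibration and recovery
checks mirror a realistic candidate-locus design: MAF 0.3–0.36, per-allele
OR 1.27, and cohort sizes of 988 cases / 2521 controls (the bundled study
design) or 500/500 for null calibration.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, covariates, population stratification, genotyping error, or
differential missingness. Calibration of the trend test under this
generator therefore shows correctness of the statistic, not robustness to
confounding — stratification correction is explicitly out of scope.

`make_planted_screen()` builds screen instances whose truth is known by
construction: a random background graph (uniform Erdős–Rényi-style edges —
degree realism is unnecessary because the screen is purely set-based),
exactly the requested number of non-seed genes wired to seeds, approved
drugs laid out to hit exactly the requested number of disease genes, plus
decoy records (unapproved drugs on disease genes, approved drugs on
background genes) so the filter path is exercised. Background edges are
sampled only among pairs that cannot create unplanned seed neighbors. The
`truth` counts are filled from the construction, never by running the
screen, which makes `screen_report()` falsifiable against them.

## Numerical and testing choices

* **Problem sizes.** The exhaustive HWE oracle covers all genotype triples
  with total ≤ 50 (≈23,000 cases); trend-test calibration uses 10,000 null
  replicates at 500/500; odds-ratio recovery uses 2,000 replicates at
  988/2521; the planted-screen property runs 100 random instances including
  one shaped like a full study cascade (32 seeds, 834 neighbors, 48 hit
  genes, 57 families) on a 5,000-gene universe. These sizes give
  Monte-Carlo standard errors well inside the asserted bands while keeping
  the suite comfortably fast.
* **Stochastic bands.** All stochastic assertions use bands of about ±5
  binomial/empirical standard deviations so false alarms are rare; seeds
  are fixed in the tests.
* **The permutation oracle and discreteness.** The conditional null of the
  trend statistic (margins fixed) is discrete, so its exact tail
  probability at the observed statistic is ambiguous up to the tie atom.
  The oracle therefore computes both the strict (`>`) and inclusive (`>=`)
  permutation p-values and asserts that the asymptotic chi-square p lies
  inside that band widened by 5 Monte-Carlo standard errors. Collapsing the
  band to a single number would either fail spuriously (inclusive p exceeds
  the asymptotic p by roughly the tie mass) or require an arbitrary
  tolerance.
* **Degenerate inputs.** Monomorphic samples: trend test warns and returns
  p = 1; exact HWE returns 1; LD errors. Empty tables, duplicate SNP ids,
  overlapping seed/neighbor sets, and conflicting family assignments are
  errors with row-level messages, because silently "fixing" them would mask
  upstream data problems.

## Known limitations

* The screen's headline counts depend entirely on the supplied PPI and
  drug-target tables; with different database versions the cascade numbers
  will differ. The package guarantees the algebra, not the databases.
* The trend and genotypic tests are asymptotic; for very sparse tables the
  permutation machinery in the test helpers illustrates how to obtain
  conditional p-values, but no exact trend test is exported.
* The simulator's multiplicative-odds genotype model cannot represent
  dominance or recessive architectures; genotypic-risk alternatives were
  considered out of scope.
* Literature annotation (`annotate_literature()`) is arithmetic over a
  caller-supplied list; the package does not curate which drug families
  have reported neuroprotective effects.
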