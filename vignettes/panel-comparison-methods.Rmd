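---
title: "Methods: panel-comparison GWAS and founder-variant statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-comparison GWAS and founder-variant statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelgwas)
```

# Scope and model

`panelgwas` implements the statistical machinery needed to (i) run
quantitative-trait GWAS on imputed dosages from several reference panels,
(ii) reduce the results to independent genome-wide significant loci, (iii)
compare locus discovery across panels, and (iv) characterize variants
enriched in a founder population, including genealogical carrier inference.
All of it is exercised on synthetic cohorts with known ground truth, because
the individual-level data this kind of analysis is designed for is
access-controlled.

## Association model

The trait model is ordinary least squares of the rank-inverse-normal
transformed (RINT) phenotype on a single dosage plus covariates:

$$\mathrm{RINT}(y) = \beta_0 + \beta_g g + X\gamma + \varepsilon$$

- `rint()` maps values to $\Phi^{-1}((r - c)/(n - 2c + 1))$ with average
  ranks for ties. The default offset $c = 0.5$ gives $(r - 0.5)/n$; the Blom
  offset $3/8$ is available. The transform is invariant to strictly monotone
  transforms of the input, which the tests assert.
- P-values come from the t distribution with $n - k$ residual degrees of
  freedom, not a normal approximation.
- Mixed-model/polygenic corrections (regenie-style step 1) are deliberately
  out of scope: the synthetic cohorts have no relatedness, so plain OLS
  exercises the same contracts. This is an intentional simplification and
  results on real, related cohorts would need a mixed model.
- Missing dosages are mean-imputed per variant, the usual dosage convention.

`stepwise_conditional()` performs forward selection inside a locus: starting
from the lead variant, each round tests every unselected variant with all
selected dosages added as covariates and admits the minimum-P variant while
its conditional P is below the locus-wide threshold (default $10^{-5}$).
Minimum-P ties are broken by position, then alternate allele, so results are
deterministic. Singular additions are skipped with a warning.

## Locus calling

`filter_for_loci()` applies the conventional screening: MAC > 20 (strict),
INFO > 0.3 (strict), with an absolute MAC ≥ 5 floor. `call_loci()` seeds a
±500 kb window around every variant with $P < 5\times10^{-8}$, merges
windows on the same chromosome whose gap is at most 1 bp (touching windows
merge; this is the most literal reading of "overlapping or immediately
adjacent", and it is configurable via `max_gap`), and takes the lowest-P
member as lead. Loci are stored 1-based inclusive and emitted as 0-based
half-open BED. Window clipping at the right chromosome edge happens only
when `chrom_lengths` is supplied.

The implementation is checked against a brute-force interval-union oracle on
1,000 random variant sets, including the two boundary cases: variants
999,999 bp apart merge, variants 1,000,002 bp apart split.

## Cross-panel comparison

`match_loci()` connects same-trait loci from different approaches when their
intervals overlap by ≥ 1 bp and takes connected components (transitive
closure, union-find). The publication this design follows does not state its
matching rule, so the overlap threshold is a configurable free parameter.
Each cluster's membership pattern over {local, global, meta} is one of the
seven regions of a three-set Venn diagram; all seven are labelled by their
pattern string rather than guessing a letter mapping.

Per-cluster summaries (`subset_summary()`) need one lead per cluster even
when several approaches contribute loci; the package uses the lead of the
member locus with the smallest lead P. "Absent in the alternate panel" is
defined only when the pattern contains exactly one of the two real panels.
Both choices are documented here because the source material leaves them
open.

`recovery_stats()` counts, per individual, variants carried in truth,
well-imputed by panel A (INFO > 0.3, reusing the locus filter threshold) and
absent or poorly imputed in panel B, and computes hard-call concordance over
those variants (dosage rounded to the nearest of {0,1,2}; a no-call margin
is available but defaults to always calling). `relative_recovery_ratio()`
is the ratio of the recovery-event probability in the enriched-and-rare
stratum (fold ≥ 8, reference AF < 5%) to the probability over all rare
variants.

## Permutation inference

Two permutation tests mirror the panel-benchmarking figures this machinery
is built for:

- `perm_test_median_diff()`: observed statistic is the median of paired
  INFO differences (local − global) over a lead set; null replicates draw
  the same number of variants per minor-AF stratum from a genome-wide pool,
  without replacement. Default stratum edges are
  {0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5}; the source material does
  not state its bins, so these are configurable. The two-tailed p-value is
  centered on the null median and add-one corrected,
  $p = (1 + r)/(n_{perm} + 1)$, so $p$ never reaches 0. The 95% interval is
  a stratified percentile bootstrap of the observed median; whether the
  published intervals were bootstrap or null-band intervals is not stated,
  so the bootstrap is the default and the null summary is also returned.
- `perm_test_fold_change()`: observed statistic is the lead-set proportion
  satisfying a predicate divided by the pool proportion; the one-tailed
  p-value counts null fold changes at or above the observed. The null is
  unstratified by default, with a flag to stratify.

Sampling is always without replacement because a lead set is a subset of
real variants, not an i.i.d. draw. Desk-scale default is
`n_perm = 10000`; publication-scale $10^6$ is a parameter, not a code
change. Fixed seeds fully determine p and CI.

## Founder enrichment and carrier inference

- `enrichment_fold()`: enriched ⇔ cohort MAF ≥ 0.1% and
  AF_cohort/AF_ref ≥ 4. A zero reference AF with positive cohort AF yields
  an `Inf` fold sentinel.
- `fisher_or()`: central two-sided Fisher exact p (sum of hypergeometric
  table probabilities not exceeding the observed one, with the conventional
  $1 + 10^{-7}$ tolerance for floating ties), computed directly from
  `dhyper`; `stats::fisher.test` is used only as an independent oracle in
  the tests. The OR estimate is the sample odds ratio with the
  Haldane–Anscombe +0.5 correction when any cell is zero — the estimator is
  not stated in the source material, so the simplest auditable one is used.
- `prioritize_variants()`: an ordered, configurable rule chain — ClinVar
  P/LP/conflicting or pLoF; reference AF ≤ 1%; CADD ≥ 15 with SpliceAI
  ≥ 0.8 admitting splice candidates that fail CADD. Missing values fail
  their rule (conservative) unless the rule is removed from the chain. The
  exact conjunction order is ambiguous in the source material, hence the
  configurable chain.
- `mrca_carriers()`: the MRCA of the known carriers is found by lifting
  lineages in time order; "all individuals below this MRCA carry the
  mutation" is read as *leaf* descendants — internal nodes are ancestors,
  not sampled individuals. TMRCA is the MRCA's node time in generations.
- `carrier_frequency_ci()`: per-region carrier frequency with a percentile
  bootstrap CI (default 100,000 iterations). Resampling $n$ exchangeable
  binary indicators with replacement is exactly a
  $\mathrm{Binomial}(n, \hat p)/n$ draw, so replicates are generated with
  `rbinom` for speed; this is an identity, not an approximation.

## QC procedures

- `batch_lrt()` / `batch_lrt_scan()`: Gaussian LRT
  $n\,\ln(\mathrm{RSS}_{reduced}/\mathrm{RSS}_{full})$ comparing
  `G ~ 1 + PC1..PC4 + array` to `G ~ 1 + PC1..PC4`, $\chi^2$ with
  $n_{arrays}-1$ df, Bonferroni rejection at $0.05/n_{SNPs}$. The scan
  version exploits the fact that the design matrix is fixed across SNPs
  (the genotype is the response), computing all residual sums of squares
  from two QR decompositions; it is asserted equal to the per-SNP version.
  The statistic is invariant to affine rescaling of the PCs.
- `dedup_svs()`: candidate pairs share chromosome and type with both
  breakpoints within 100 bp. Equal allele counts → remove the shorter
  member (length ties: the later record in sort order); otherwise remove the
  lower-AC member when both AC and AF percent differences are below 1%. The
  percent-difference denominator is not stated in the source material; the
  default is the pair mean, with `max` as an alternative. Mutually-close
  groups larger than two are processed greedily in ascending
  $|\Delta start| + |\Delta end|$ order, skipping pairs with an
  already-removed member, which makes the operation idempotent and
  guarantees both members of a pair are never removed.

# The synthetic world

`sim_config()` fixes the cohort: size, variant count, AF law
(Beta(0.5, 0.5) truncated to $[1/(2N), 1 - 1/(2N)]$), planted causal
effects on the standardized-dosage scale, Gaussian residual noise
(sd = 1), covariates (sex, age, age², a five-level array indicator, ten
standard-normal PC surrogates independent of genotype), panel behaviour and
the enriched-variant fraction. One root seed drives derived per-operation
streams, so each module can be re-run independently and bit-identically.

Default stated-world parameters, chosen once:

| Parameter | Default | Why |
|---|---|---|
| AF law | Beta(0.5, 0.5), truncated | U-shaped site-frequency spectrum away from fixation |
| noise_sd | 1 | phenotype on the standardized scale |
| enrichment | 5% of variants at fold 8 | matches the enriched-and-rare stratum the recovery ratio conditions on (fold ≥ 8) |
| local panel INFO | 0.97 common / 0.80 rare (MAF 1% split) | local panels do best on common variants |
| global panel INFO | 0.95 common / 0.88 rare | global panels impute rare variants slightly better |
| global dropout | fold ≥ 4 and MAF < 5% | cohort-enriched rare variants are missing from global panels |
| genealogy scale | pop_size = 20 generations | root times of tens of generations, the founder-event scale |
| SV callset | 93% DEL, median length ~1.3 kb, 80% MAF < 5% | typical short-read SV callset shape |

The INFO-vs-AF curves are free parameters of the synthetic world — the
joint INFO distribution of the real panels is not published — so green
tests establish that the *machinery* behaves correctly under a plausible
world, not that any real panel pair behaves this way.

## Imputation noise model (a deliberate deviation)

The obvious noise model — attenuate the centered genotype by
$\sqrt{\mathrm{INFO}}$ and add Gaussian noise scaled to preserve variance —
produces dosages outside $[0, 2]$, and clipping them back truncates the
noise and inflates the realized $r^2$ (measured ≈ 0.66 for a 0.6 target at
n = 2000), violating the ±0.05 fidelity requirement the analysis relies on.
The package instead draws an independent Hardy–Weinberg genotype $g'$ at
the same AF and blends: $\hat g = a\,g + (1-a)\,g'$ with
$a^2/(a^2 + (1-a)^2) = \mathrm{INFO}$. This gives
$\mathrm{corr}(\hat g, g)^2 = \mathrm{INFO}$ exactly in population *and*
keeps dosages in $[0, 2]$ with no clipping. INFO = 1 returns the truth,
INFO = 0 an independent genotype.

## Meta-imputation rule

The meta panel copies, per variant, the dosages and INFO of the member
panel with the higher INFO (ties go to the local panel). Real
meta-imputation performs weighted dosage averaging; the copy rule is a
documented simplification sufficient for partition logic, which only needs
presence and relative quality.

## Genealogies

Trees are built by successive pairwise coalescence with exponential waiting
times (rate $\binom{k}{2}/\mathrm{pop\_size}$), leaves at time 0, times in
generations. The mutation is placed on an edge drawn uniformly over *all*
parent edges: the stated world wants single-leaf trees to carry the
mutation on their pendant edge, and a uniform choice over every edge covers
that case and the internal-edge case with one rule. No recombination, no
demography: the genealogy module exists to exercise the MRCA carrier rule,
not to model Quebec.

## What the generator does not emulate

No linkage disequilibrium (variants are independent), no relatedness or
population structure (PCs are pure noise), no phasing, no X chromosome, no
real AF spectra per consequence class. Consequently: green end-to-end tests
demonstrate correctness of the statistical contracts, not realism of any
particular biological claim; power numbers measured here do not transfer to
real cohorts.

# Numerical choices and degenerate inputs

- `rint` errors on constant input (the transform is undefined).
- Degenerate association designs (constant or collinear dosage) return a
  flagged row with NA effect rather than erroring a whole scan.
- Permutation p-values are bounded below by $1/(n_{perm}+1)$; reported
  confidence intervals always bracket the observed statistic.
- A permutation stratum whose pool holds fewer variants than the lead set
  requires raises an error naming the stratum.
- `fisher_or` requires positive margins; `relative_recovery_ratio` errors
  on an empty enriched stratum or a zero background proportion.
- The batch LRT returns 0 when either RSS is numerically zero (constant
  genotype), avoiding 0/0.

# Known limitations

- OLS only: no relatedness correction, binary traits, or X dosage.
- Locus matching by interval overlap cannot distinguish distinct signals
  that happen to share a window; with LD absent from the generator this
  cannot be exercised synthetically.
- The Fig-style subset letter assignment of the source material is not
  reproduced; patterns are labelled canonically.
- Carrier-frequency estimation operates on known or MRCA-expanded carrier
  labels; genealogical climbing estimation is out of scope.
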