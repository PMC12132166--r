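# panelgwas

Tools for comparing genome-wide association study (GWAS) results obtained
with different genotype-imputation reference panels, and for characterizing
variants enriched in founder populations.

## The problem

Populations with strong founder effects (for example French-Canadian
ancestry groups in Quebec) carry rare variants at frequencies far above
those seen in large multi-ancestry reference databases. A cohort-matched
("local") imputation reference panel can recover these variants where a much
larger multi-ancestry ("global") panel cannot, which changes which GWAS loci
are discoverable. Quantifying that advantage requires a chain of bespoke
statistics that general GWAS toolkits do not provide in one place:

- **Locus calling**: every genome-wide significant variant
  (P < 5×10⁻⁸, MAC > 20, INFO > 0.3) seeds a ±500 kb window; overlapping or
  immediately adjacent windows are merged into independent loci; the lowest-P
  member is the *lead variant*, and forward stepwise conditional analysis at
  a locus-wide threshold of 10⁻⁵ yields the *index variants*.
- **Cross-panel Venn partition**: loci from the local, global and
  meta-imputation runs of the same trait are matched by interval overlap;
  clusters are labelled by the set of approaches that discovered them.
- **AF-stratified permutation tests**: whether lead variants' paired
  imputation-quality differences (INFO_local − INFO_global), or the fraction
  of leads satisfying an enrichment predicate, are unusual relative to
  frequency-matched variants sampled from the genome-wide pool
  (without replacement, add-one-corrected p-values).
- **Founder enrichment**: a variant is *enriched* when cohort MAF ≥ 0.1% and
  AF_cohort / AF_reference ≥ 4; 2×2 allele-count tables are tested with a
  central two-sided Fisher exact test, odds ratios use the Haldane–Anscombe
  correction for zero cells.
- **Genealogical carrier inference**: given a genealogy and known carriers
  of a single-origin mutation, all leaves below the carriers' most recent
  common ancestor (MRCA) are inferred carriers; per-region carrier
  frequencies get percentile-bootstrap confidence intervals.
- **QC**: genotyping-array batch effects are screened with a Gaussian
  likelihood-ratio test of `G ~ 1 + PC1..PC4 + array` against
  `G ~ 1 + PC1..PC4` (χ², n_arrays − 1 df, Bonferroni threshold), and
  structural-variant callsets are deduplicated by a breakpoint-window /
  allele-count rule.

Because individual-level cohort data of this kind is access-controlled, the
package ships a first-class synthetic-data module (`simulate_*`) that
generates cohorts, imputed panels, reference AFs, genealogies, array batches
and SV callsets with known ground truth, so the entire pipeline is testable.

## Worked example

```r
library(panelgwas)

## founder enrichment from printed frequency pairs (TSHR p.Pro162Thr)
enrichment_fold(0.0015, 0.00029)
#>       fold enriched
#> 1 5.172414     TRUE

## a synthetic cohort with two planted causal variants
cfg   <- sim_config(2000, 200, n_causal = 2,
                    effect_sizes = c(0.25, 0.25), seed = 7)
world <- simulate_world(cfg)
p     <- world$panels$local
st    <- assoc_scan(p$dosage, world$cohort$phenotype,
                    world$cohort$covariates,
                    variants = world$cohort$variants,
                    info = p$info, approach = "local")
call_loci(filter_for_loci(st))
#>   chrom     start       end               lead       lead_p n_members
#> 1  chr1 120215671 121215671 chr1:120715671:C:T 7.796981e-30         1
#> 2  chr2 229984790 230984790 chr2:230484790:A:T 1.674421e-17         1
```

Both loci are exactly the planted causal variants
(`world$cohort$variants$id[world$cohort$variants$causal]`): the pipeline
recovers `chr1:120715671:C:T` and `chr2:230484790:A:T` with genome-wide
significant lead P-values, each in its own merged ±500 kb window.

A 2×2 enrichment table (3 carriers in 4,346 cohort alleles vs 1 in 100,000
reference alleles):

```r
fisher_or(3, 4343, 1, 99999)
#> $or_estimate
#> [1] 69.07598
#> $p
#> [1] 0.0002797957
```

## Command line

A multi-tool CLI is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","panelgwas.R",package="panelgwas"))') \
    simulate --config config.json --out-dir out/
# also: assoc, call-loci, compare, permute, enrich, carriers,
#       qc-svdedup, qc-batch
```

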