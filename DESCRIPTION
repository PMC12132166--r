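Package: panelgwas
Title: GWAS Comparison Across Genotype-Imputation Reference Panels and
    Founder-Variant Enrichment
Version: 0.1.0
Authors@R:
    person("Panelgwas", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking genotype-imputation reference panels
    through genome-wide association studies and for characterizing variants
    enriched in founder populations. Provides quantitative-trait association
    testing with rank-inverse-normal transformation and stepwise conditional
    analysis, window-based calling of independent genome-wide significant
    loci, cross-panel locus matching with Venn partitioning, allele-frequency
    stratified permutation tests for paired imputation-quality differences
    and lead-variant fold changes, founder allele-frequency enrichment and
    Fisher exact statistics, variant prioritization filters, MRCA-based
    carrier inference on genealogies with bootstrap carrier-frequency
    confidence intervals, genotyping-array batch-effect likelihood-ratio
    filtering, and structural-variant near-duplicate deduplication. A
    synthetic-data module generates cohorts, imputed panels, genealogies,
    array batches and SV callsets with known ground truth so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
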