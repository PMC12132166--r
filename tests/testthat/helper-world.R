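# Shared builders for synthetic scenarios used by several test files.

# A small cohort with no planted effects.
null_cohort <- function(n = 500, m = 50, seed = 1) {
  simulate_cohort(sim_config(n, m, seed = seed))
}

# End-to-end scenario for the cross-panel comparison: two strong causal
# variants with cohort MAF in (0.02, 0.05); one is planted absent from the
# global panel, the other is present in both panels but imputed below the
# INFO filter by the global panel (and well by the local panel).
planted_world <- function(seed, n = 2000, m = 300, beta = 0.3) {
  cfg <- sim_config(n, m, seed = seed)
  cohort <- simulate_cohort(cfg)
  v <- cohort$variants
  # pick the two planted variants on different chromosomes so their loci
  # never merge into one cluster
  mid1 <- which(v$af > 0.02 & v$af < 0.05 & v$chrom == "chr1")
  mid2 <- which(v$af > 0.02 & v$af < 0.05 & v$chrom == "chr2")
  stopifnot(length(mid1) >= 1, length(mid2) >= 1)
  dropped_id <- v$id[mid1[1]]
  lowinfo_id <- v$id[mid2[1]]
  for (id in c(dropped_id, lowinfo_id)) {
    g <- cohort$dosage[, id]
    cohort$phenotype <- cohort$phenotype + beta * (g - mean(g)) / sd(g)
  }
  specs <- list(
    local = panel_spec("local", info_fun = function(vv) {
      ifelse(vv$id == lowinfo_id, 0.95, 0.90)
    }),
    global = panel_spec(
      "global",
      info_fun = function(vv) ifelse(vv$id == lowinfo_id, 0.25, 0.90),
      drop_fun = function(vv) vv$id == dropped_id
    )
  )
  panels <- simulate_imputed_panels(cohort, specs, seed = seed)
  list(cohort = cohort, panels = panels,
       dropped_id = dropped_id, lowinfo_id = lowinfo_id)
}

# GWAS on every panel of a world, filtered and clumped into loci.
world_loci <- function(world, p_threshold = 5e-8) {
  all_loci <- list()
  stats_by <- list()
  for (pid in names(world$panels)) {
    panel <- world$panels[[pid]]
    st <- assoc_scan(panel$dosage, world$cohort$phenotype,
                     world$cohort$covariates,
                     variants = world$cohort$variants,
                     info = panel$info, approach = pid)
    st <- filter_for_loci(st)
    stats_by[[pid]] <- st
    all_loci[[pid]] <- call_loci(st, p_threshold = p_threshold)
  }
  list(loci = all_loci, stats = stats_by)
}
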