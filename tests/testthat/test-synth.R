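test_that("simulate_cohort is deterministic and respects its config", {
  cfg <- sim_config(300, 40, n_causal = 2, effect_sizes = c(0.3, -0.2),
                    seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$dosage), c(300, 40))
  expect_true(all(a$dosage %in% 0:2))
  expect_equal(sum(a$variants$causal), 2)
  expect_equal(a$variants$beta[a$variants$causal], c(0.3, -0.2))
  # positions sorted within chromosome and inside chromosome bounds
  for (cc in unique(a$variants$chrom)) {
    p <- a$variants$pos[a$variants$chrom == cc]
    expect_true(!is.unsorted(p))
    expect_true(all(p >= 1 & p <= cfg$chrom_lengths[[cc]]))
  }
  expect_error(sim_config(100, 10, n_causal = 11), "exceeds")
})

test_that("empirical AF tracks the generating AF within binomial tolerance", {
  cohort <- simulate_cohort(sim_config(2000, 400, seed = 11))
  v <- cohort$variants
  sd_af <- sqrt(v$af_gen * (1 - v$af_gen) / (2 * 2000))
  within3 <- abs(v$af - v$af_gen) <= 3 * sd_af
  expect_gte(mean(within3), 0.99)
  # Hardy-Weinberg chi-square screen at the generating AF
  pvals <- vapply(seq_len(nrow(v)), function(j) {
    g <- cohort$dosage[, j]
    af <- v$af_gen[j]
    expc <- 2000 * c((1 - af)^2, 2 * af * (1 - af), af^2)
    obs <- tabulate(g + 1L, 3L)
    keep <- expc > 1e-9
    stats::pchisq(sum((obs[keep] - expc[keep])^2 / expc[keep]),
                  df = 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(pvals > 1e-4), 0.98)
})

test_that("imputation noise model hits its target INFO", {
  cohort <- simulate_cohort(sim_config(2000, 60, seed = 3))
  common <- cohort$variants$af > 0.05 & cohort$variants$af < 0.95
  specs <- list(p6 = panel_spec("p6", function(v) rep(0.6, nrow(v))),
                p0 = panel_spec("p0", function(v) rep(0, nrow(v))),
                p1 = panel_spec("p1", function(v) rep(1, nrow(v))))
  panels <- simulate_imputed_panels(cohort, specs, seed = 3)
  r2 <- function(panel, j) cor(panel$dosage[, j], cohort$dosage[, j])^2
  # INFO = 1: dosage equals truth exactly
  expect_equal(panels$p1$dosage, cohort$dosage + 0, ignore_attr = TRUE)
  # INFO = 0.6: r^2 within +/- 0.05 for common variants
  r2s <- vapply(which(common), function(j) r2(panels$p6, j), numeric(1))
  expect_true(all(abs(r2s - 0.6) <= 0.05))
  # INFO = 0: independence limit
  r0 <- vapply(which(common), function(j) r2(panels$p0, j), numeric(1))
  expect_lt(max(r0), 0.01)
  # bad targets error
  bad <- list(p = panel_spec("p", function(v) rep(1.2, nrow(v))))
  expect_error(simulate_imputed_panels(cohort, bad, seed = 1), "INFO")
})

test_that("meta panel takes the member with higher INFO, union presence", {
  cohort <- simulate_cohort(sim_config(200, 30, seed = 5))
  specs <- list(
    local = panel_spec("local", function(v) rep(0.9, nrow(v))),
    global = panel_spec("global", function(v) rep(0.95, nrow(v)),
                        drop_fun = function(v) seq_len(nrow(v)) <= 10)
  )
  panels <- simulate_imputed_panels(cohort, specs, seed = 5)
  expect_true(all(panels$meta$present ==
                    (panels$local$present | panels$global$present)))
  # where global present its INFO is higher -> meta copies global
  expect_equal(panels$meta$info[11:30], panels$global$info[11:30])
  expect_equal(panels$meta$dosage[, 11:30], panels$global$dosage[, 11:30])
  # where global absent -> meta falls back to local
  expect_equal(panels$meta$info[1:10], panels$local$info[1:10])
})

test_that("simulate_reference_af plants enrichment and clips", {
  af <- c(0.5, 0.2, 0.001)
  spec <- list(fraction = 0, fold = 8)
  ref <- simulate_reference_af(af, spec, seed = 1)
  expect_true(all(!ref$enriched))
  cls <- enrichment_fold(af, ref$af_ref)
  expect_true(all(!cls$enriched))
  # clipping arithmetic: cohort 0.5 at fold 8 -> 0.0625
  one <- simulate_reference_af(0.5, list(fraction = 1, fold = 8), seed = 1)
  expect_equal(one$af_ref, 0.0625)
  expect_true(one$af_ref > 0 && one$af_ref < 1)
  expect_error(simulate_reference_af(0.5, list(fraction = 1, fold = -1), 1),
               "fold")
})

test_that("planted enriched fraction is recovered by classification", {
  set.seed(42)
  cohort_af <- runif(2000, 0.01, 0.4)
  ref <- simulate_reference_af(cohort_af, list(fraction = 0.05, fold = 8),
                               seed = 9)
  cls <- enrichment_fold(cohort_af, ref$af_ref)
  # planted enriched variants all classified (MAF >= 0.1% by construction)
  expect_true(all(cls$enriched[ref$enriched]))
  # recovered fraction ~ 5%, allowing for drift-induced false positives
  expect_equal(mean(cls$enriched), 0.05, tolerance = 0.25)
})

test_that("genealogies have coherent times, carriers and serialization", {
  g <- simulate_genealogy(16, seed = 2)
  expect_identical(g, simulate_genealogy(16, seed = 2))
  # child time < parent time everywhere
  child <- which(g$parent != 0L)
  expect_true(all(g$time[child] < g$time[g$parent[child]]))
  # exactly one root
  expect_equal(sum(g$parent == 0L), 1)
  expect_setequal(g$carriers, oracle_carriers(g, g$mutated_node))
  # single-leaf degenerate case
  g1 <- simulate_genealogy(1, seed = 4)
  expect_equal(g1$mutated_node, 1L)
  expect_equal(g1$carriers, "I1")
  expect_error(simulate_genealogy(0, seed = 1), "n_leaves")
  # Newick round-trip through ape preserves topology-implied leaf depths
  tf <- tempfile(fileext = ".nwk")
  write_genealogy(g, tf)
  tr <- ape::read.tree(tf)
  expect_setequal(tr$tip.label, g$labels)
  depth <- max(g$time)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1]), depth,
               tolerance = 1e-8)
})

test_that("carrier sets match the descendant oracle on many random trees", {
  for (s in 1:100) {
    n <- sample(2:64, 1)
    g <- simulate_genealogy(n, seed = s)
    expect_identical(sort(g$carriers),
                     sort(oracle_carriers(g, g$mutated_node)))
  }
})

test_that("array batches honour the null and the planted shift", {
  b <- simulate_array_batches(50, 10, 0, seed = 6)
  expect_identical(b, simulate_array_batches(50, 10, 0, seed = 6))
  expect_true(all(!b$shifted))
  expect_equal(dim(b$genotypes), c(250, 10))
  b2 <- simulate_array_batches(400, 10, 0.08, seed = 6,
                               shifted_fraction = 0.5)
  expect_equal(sum(b2$shifted), 5)
  last <- b2$arrays == "A5"
  af_last <- colMeans(b2$genotypes[last, b2$shifted, drop = FALSE]) / 2
  af_rest <- colMeans(b2$genotypes[!last, b2$shifted, drop = FALSE]) / 2
  expect_gt(mean(af_last - af_rest), 0.03)
  expect_error(simulate_array_batches(50, 10, 0.95, seed = 1), "outside")
  expect_error(simulate_array_batches(50, 10, 0, seed = 1, n_arrays = 1),
               "n_arrays")
})

test_that("sv callsets plant recoverable near-duplicates", {
  sv0 <- simulate_sv_callset(40, 0, seed = 8)
  expect_equal(nrow(attr(sv0, "truth")), 0)
  expect_equal(nrow(dedup_svs(sv0)$removed), 0)
  sv <- simulate_sv_callset(50, 0.2, seed = 8)
  truth <- attr(sv, "truth")
  expect_equal(nrow(truth), 5)
  # planted pairs satisfy the breakpoint-window rule
  for (r in seq_len(nrow(truth))) {
    a <- sv[sv$sv_id == truth$keep_id[r], ]
    b <- sv[sv$sv_id == truth$dup_id[r], ]
    expect_lte(abs(a$start - b$start), 100)
    expect_lte(abs(a$end - b$end), 100)
    expect_identical(a$type, b$type)
    expect_lt(b$length, a$length)
  }
  expect_true(all(sv$end > sv$start))
  expect_equal(sv$length, sv$end - sv$start)
})
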