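#' Simulation configuration for a synthetic GWAS cohort
#'
#' Bundles every knob of the synthetic world: cohort size, variant count and
#' allele-frequency law, planted causal effects, residual noise, imputation
#' panel behaviour and the fraction of founder-enriched variants. A single
#' root seed fully determines all downstream output.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_variants number of bi-allelic variants.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   variants are spread across these chromosomes.
#' @param af_law cohort allele-frequency law; a list with `dist = "beta"`,
#'   `shape1`, `shape2`. Draws are truncated to `[1/(2N), 1 - 1/(2N)]`.
#' @param n_causal number of causal variants planted into the phenotype.
#' @param effect_sizes standardized effect per causal variant (length
#'   `n_causal`, recycled if length 1).
#' @param noise_sd residual standard deviation of the phenotype.
#' @param panel_specs list of [panel_spec()] objects keyed by panel id; see
#'   [default_panel_specs()].
#' @param enrichment_spec list with `fraction` (share of variants planted as
#'   founder-enriched) and `fold` (cohort/reference AF ratio for those).
#' @param seed root seed (integer); per-operation streams are derived from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       n_variants,
                       chrom_lengths = c(chr1 = 248e6, chr2 = 242e6),
                       af_law = list(dist = "beta", shape1 = 0.5, shape2 = 0.5),
                       n_causal = 0,
                       effect_sizes = numeric(0),
                       noise_sd = 1,
                       panel_specs = default_panel_specs(),
                       enrichment_spec = list(fraction = 0.05, fold = 8),
                       seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_variants <- check_count(n_variants, "n_variants")
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_variants) {
    stop("n_causal (", n_causal, ") exceeds n_variants (", n_variants, ")")
  }
  if (n_causal > 0L) {
    if (length(effect_sizes) == 1L) effect_sizes <- rep(effect_sizes, n_causal)
    if (length(effect_sizes) != n_causal) {
      stop("effect_sizes must have length n_causal")
    }
  }
  if (!is.numeric(chrom_lengths) || is.null(names(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    stop("chrom_lengths must be a named positive numeric vector")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  check_prob(enrichment_spec$fraction, "enrichment_spec$fraction", open = FALSE)
  if (enrichment_spec$fold <= 0) stop("enrichment fold must be > 0")
  structure(
    list(
      n_individuals = n_individuals, n_variants = n_variants,
      chrom_lengths = chrom_lengths, af_law = af_law, n_causal = n_causal,
      effect_sizes = effect_sizes, noise_sd = noise_sd,
      panel_specs = panel_specs, enrichment_spec = enrichment_spec,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Imputation panel behaviour specification
#'
#' @param id panel label (`"local"`, `"global"`, ...).
#' @param info_fun function taking the variant metadata table and returning
#'   per-variant target imputation quality (INFO) in `[0, 1]`.
#' @param drop_fun function taking the variant metadata table and returning a
#'   logical vector marking variants absent from this panel.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(id, info_fun, drop_fun = function(variants) {
  rep(FALSE, nrow(variants))
}) {
  stopifnot(is.character(id), length(id) == 1L, is.function(info_fun),
            is.function(drop_fun))
  structure(list(id = id, info_fun = info_fun, drop_fun = drop_fun),
            class = "panel_spec")
}

#' Default local/global panel pair
#'
#' Emulates the contrast between a cohort-matched ("local") reference panel
#' and a large multi-ancestry ("global") panel: the global panel imputes rare
#' variants slightly better but drops variants that are rare-and-enriched in
#' the cohort (it has few matching haplotypes); the local panel retains them
#' and is slightly better for common variants. The INFO-vs-AF curves are free
#' parameters of the synthetic world, not estimates of any real panel.
#'
#' @param enriched_fold_min,enriched_maf_max dropout rule for the global
#'   panel: variants with cohort/reference AF fold at or above
#'   `enriched_fold_min` and cohort MAF below `enriched_maf_max` are absent.
#' @return named list of two [panel_spec()] objects.
#' @export
default_panel_specs <- function(enriched_fold_min = 4, enriched_maf_max = 0.05) {
  list(
    local = panel_spec(
      "local",
      info_fun = function(variants) {
        ifelse(pmin(variants$af, 1 - variants$af) >= 0.01, 0.97, 0.80)
      }
    ),
    global = panel_spec(
      "global",
      info_fun = function(variants) {
        ifelse(pmin(variants$af, 1 - variants$af) >= 0.01, 0.95, 0.88)
      },
      drop_fun = function(variants) {
        if (!all(c("fold", "af") %in% names(variants))) {
          return(rep(FALSE, nrow(variants)))
        }
        !is.na(variants$fold) & variants$fold >= enriched_fold_min &
          pmin(variants$af, 1 - variants$af) < enriched_maf_max
      }
    )
  )
}

draw_afs <- function(config) {
  law <- config$af_law
  if (!identical(law$dist, "beta")) stop("unsupported af_law: ", law$dist)
  lo <- 1 / (2 * config$n_individuals)
  af <- stats::rbeta(config$n_variants, law$shape1, law$shape2)
  pmin(pmax(af, lo), 1 - lo)
}

#' Simulate a diploid cohort with planted causal effects
#'
#' Genotypes are drawn under Hardy-Weinberg at each variant's generating AF.
#' The phenotype is a sum of standardized causal dosage effects, fixed
#' covariate effects (sex, standardized age, first two PC surrogates) and
#' Gaussian noise. Covariates mimic a typical GWAS model: sex, age, age^2,
#' genotyping-array indicator and ten PC surrogates (standard normals,
#' independent of genotype).
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_data`: list with `dosage` (n x m integer
#'   matrix, values 0/1/2), `phenotype`, `covariates` (data.frame),
#'   `variants` (metadata incl. generating and empirical AF, causal flag and
#'   true beta), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "cohort", {
    n <- config$n_individuals
    m <- config$n_variants

    af <- draw_afs(config)
    chroms <- names(config$chrom_lengths)
    chrom <- sample(chroms, m, replace = TRUE,
                    prob = config$chrom_lengths / sum(config$chrom_lengths))
    pos <- integer(m)
    for (cc in chroms) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(config$chrom_lengths[[cc]], length(idx)))
    }
    ord <- order(match(chrom, chroms), pos)
    chrom <- chrom[ord]; pos <- pos[ord]; af <- af[ord]
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1))
    id <- variant_key(chrom, pos, ref, alt)

    dosage <- matrix(stats::rbinom(n * m, 2L, rep(af, each = n)), nrow = n,
                     dimnames = list(NULL, id))

    causal_idx <- if (config$n_causal > 0L) {
      sort(sample.int(m, config$n_causal))
    } else {
      integer(0)
    }
    beta <- numeric(m)
    beta[causal_idx] <- config$effect_sizes

    age <- stats::runif(n, 40, 69)
    covariates <- data.frame(
      sex = stats::rbinom(n, 1L, 0.5),
      age = age,
      age2 = age^2,
      array = factor(sample.int(5L, n, replace = TRUE),
                     labels = paste0("A", 1:5))
    )
    for (k in 1:10) covariates[[paste0("PC", k)]] <- stats::rnorm(n)

    genetic <- 0
    for (j in causal_idx) {
      g <- dosage[, j]
      s <- stats::sd(g)
      if (s > 0) genetic <- genetic + beta[j] * (g - mean(g)) / s
    }
    phenotype <- genetic +
      0.2 * covariates$sex +
      0.1 * scale(covariates$age)[, 1] +
      0.1 * covariates$PC1 + 0.1 * covariates$PC2 +
      stats::rnorm(n, 0, config$noise_sd)

    variants <- data.frame(
      id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
      af_gen = af, af = colMeans(dosage) / 2,
      causal = seq_len(m) %in% causal_idx, beta = beta,
      stringsAsFactors = FALSE
    )
    structure(
      list(dosage = dosage, phenotype = as.numeric(phenotype),
           covariates = covariates, variants = variants, config = config),
      class = "cohort_data"
    )
  })
}

#' Plant a reference-population AF with founder-enriched variants
#'
#' A designated fraction of variants is marked enriched: their reference AF is
#' the cohort AF divided by the enrichment fold (clipped into the open unit
#' interval). All other variants drift by a small log-normal factor around the
#' cohort AF, emulating ordinary sampling differences between a cohort and a
#' reference database.
#'
#' @param cohort_afs cohort allele frequencies in (0, 1).
#' @param enrichment_spec list with `fraction` and `fold` (> 0).
#' @param seed integer seed.
#' @param drift_sd standard deviation of the log-normal drift for
#'   non-enriched variants.
#' @return data.frame with columns `af_ref`, `enriched` (planted flag) and
#'   `fold_true` (planted fold; 1 for non-enriched variants).
#' @export
simulate_reference_af <- function(cohort_afs, enrichment_spec, seed,
                                  drift_sd = 0.05) {
  check_prob(cohort_afs, "cohort_afs")
  fold <- enrichment_spec$fold
  if (fold <= 0) stop("enrichment fold must be > 0")
  fraction <- check_prob(enrichment_spec$fraction, "fraction", open = FALSE)
  m <- length(cohort_afs)
  with_stream(seed, "reference_af", {
    enriched <- rep(FALSE, m)
    n_enr <- round(fraction * m)
    if (n_enr > 0) enriched[sample.int(m, n_enr)] <- TRUE
    eps <- 1e-9
    af_ref <- ifelse(
      enriched,
      cohort_afs / fold,
      cohort_afs * exp(stats::rnorm(m, 0, drift_sd))
    )
    af_ref <- pmin(pmax(af_ref, eps), 1 - eps)
    data.frame(af_ref = af_ref, enriched = enriched,
               fold_true = ifelse(enriched, fold, 1))
  })
}

#' Simulate imputed dosage panels from true genotypes
#'
#' For each panel, present variants receive an imputed dosage built as a
#' convex blend of the true genotype with an independent Hardy-Weinberg draw
#' at the same AF, the blend weight chosen so the squared correlation between
#' imputed and true dosage equals the target INFO in population (and dosages
#' lie in `[0, 2]` without clipping). A `meta` panel is always
#' appended: per variant it copies dosages and INFO from the member panel
#' with the higher INFO (ties go to the first panel listed, i.e. local).
#'
#' @param cohort a `cohort_data` object; if its `variants` table carries
#'   `fold` and `af_ref` columns (see [simulate_reference_af()]), dropout
#'   rules may use them.
#' @param panel_specs named list of [panel_spec()]; default taken from the
#'   cohort's config.
#' @param seed integer seed; default the cohort's root seed.
#' @return named list of `imputed_panel` objects (the input panels plus
#'   `meta`), each with `panel_id`, `present` (logical per variant), `dosage`
#'   (numeric matrix, NA columns where absent) and `info` (NA where absent).
#' @export
simulate_imputed_panels <- function(cohort, panel_specs = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(panel_specs)) panel_specs <- cohort$config$panel_specs
  if (is.null(seed)) seed <- cohort$config$seed
  g <- cohort$dosage
  m <- ncol(g)
  with_stream(seed, "panels", {
    panels <- list()
    for (spec in panel_specs) {
      info <- spec$info_fun(cohort$variants)
      stopifnot(length(info) == m)
      if (any(info < 0 | info > 1, na.rm = TRUE)) {
        stop("target INFO outside [0,1] in panel ", spec$id)
      }
      drop <- spec$drop_fun(cohort$variants)
      stopifnot(length(drop) == m)
      dosage <- matrix(NA_real_, nrow(g), m, dimnames = dimnames(g))
      for (j in which(!drop)) {
        dosage[, j] <- impute_noise(g[, j], info[j])
      }
      info[drop] <- NA_real_
      panels[[spec$id]] <- structure(
        list(panel_id = spec$id, present = !drop, dosage = dosage, info = info),
        class = "imputed_panel"
      )
    }
    panels$meta <- meta_panel(panels)
    panels
  })
}

# Imputed dosage as a convex blend of the true genotype with an independent
# Hardy-Weinberg draw at the same AF: imp = a*g + (1-a)*g', with the weight
# solving a^2 / (a^2 + (1-a)^2) = info so that corr(imp, g)^2 = info exactly
# in population, while dosages stay inside [0, 2] with no clipping (clipping
# an additive-Gaussian model truncates the noise and inflates the realized
# r^2 well above the target).
impute_noise <- function(g, info) {
  if (info >= 1) return(g + 0)
  af <- mean(g) / 2
  g2 <- stats::rbinom(length(g), 2L, af)
  if (info <= 0) return(as.numeric(g2))
  w <- sqrt(info / (1 - info))
  a <- w / (1 + w)
  a * g + (1 - a) * g2
}

# Per variant, take the member panel with higher INFO; tie -> first panel.
meta_panel <- function(panels) {
  stopifnot(length(panels) >= 1L)
  m <- length(panels[[1]]$info)
  dosage <- panels[[1]]$dosage
  info <- panels[[1]]$info
  present <- panels[[1]]$present
  for (p in panels[-1]) {
    use_p <- p$present & (!present | (!is.na(p$info) &
                                        (is.na(info) | p$info > info)))
    dosage[, use_p] <- p$dosage[, use_p]
    info[use_p] <- p$info[use_p]
    present <- present | p$present
  }
  structure(list(panel_id = "meta", present = present, dosage = dosage,
                 info = info), class = "imputed_panel")
}

#' Simulate a coalescent-style genealogy carrying one mutation
#'
#' Builds a random binary tree by successive pairwise coalescence with
#' exponential waiting times (rate `choose(k, 2) / pop_size` while `k`
#' lineages remain), so node times are in generations with leaves at time 0.
#' One edge, chosen uniformly among all parent edges, carries a single-origin
#' mutation; the leaves below it are the true carriers.
#'
#' @param n_leaves number of sampled lineages (>= 1).
#' @param seed integer seed.
#' @param pop_size coalescent time scale in generations; the expected root
#'   time is about `2 * pop_size * (1 - 1/n)`.
#' @return object of class `genealogy`: `parent` (0 for the root), `time`
#'   (generations), `labels` (leaf labels, nodes `1..n_leaves`),
#'   `n_leaves`, `mutated_node` (child node of the mutated edge) and
#'   `carriers` (leaf labels below the mutated edge).
#' @export
simulate_genealogy <- function(n_leaves, seed, pop_size = 20) {
  n_leaves <- check_count(n_leaves, "n_leaves")
  with_stream(seed, "genealogy", {
    n_nodes <- 2L * n_leaves - 1L
    parent <- integer(n_nodes)
    time <- numeric(n_nodes)
    active <- seq_len(n_leaves)
    t <- 0
    nxt <- n_leaves + 1L
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / pop_size)
      pair <- sample(active, 2L)
      parent[pair] <- nxt
      time[nxt] <- t
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
    }
    labels <- paste0("I", seq_len(n_leaves))
    mutated_node <- if (n_nodes == 1L) 1L else sample.int(n_nodes - 1L, 1L)
    gen <- structure(
      list(parent = parent, time = time, labels = labels,
           n_leaves = n_leaves, mutated_node = mutated_node),
      class = "genealogy"
    )
    gen$carriers <- labels[leaves_below(gen, mutated_node)]
    gen
  })
}

# Leaf indices descending from `node` (inclusive when node is a leaf).
leaves_below <- function(gen, node) {
  children <- split(seq_along(gen$parent), gen$parent)
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= gen$n_leaves) {
      leaves <- c(leaves, v)
    } else {
      stack <- c(stack, children[[as.character(v)]])
    }
  }
  sort(leaves)
}

#' Convert a genealogy to an ape phylo object
#'
#' Branch lengths are in generations. Single-leaf genealogies cannot be
#' represented as `phylo` and raise an error.
#'
#' @param gen a `genealogy`.
#' @return an [ape::as.phylo] tree.
#' @export
genealogy_to_phylo <- function(gen) {
  stopifnot(inherits(gen, "genealogy"))
  if (gen$n_leaves < 2L) stop("phylo requires >= 2 leaves")
  n <- gen$n_leaves
  # ape numbering: tips 1..n, root n+1, internals n+2..; ours: root is the
  # last internal node. Map our internal ids to ape ids by reverse time order.
  internal <- order(gen$time[(n + 1L):(2L * n - 1L)], decreasing = TRUE) + n
  ape_id <- integer(2L * n - 1L)
  ape_id[seq_len(n)] <- seq_len(n)
  ape_id[internal] <- n + seq_along(internal)
  child <- which(gen$parent != 0L)
  edge <- cbind(ape_id[gen$parent[child]], ape_id[child])
  edge_length <- gen$time[gen$parent[child]] - gen$time[child]
  structure(
    list(edge = edge, edge.length = edge_length, tip.label = gen$labels,
         Nnode = n - 1L),
    class = "phylo", order = "cladewise"
  )
}

#' Write a genealogy as Newick (branch lengths in generations)
#' @param gen a `genealogy`.
#' @param path output file.
#' @export
write_genealogy <- function(gen, path) {
  ape::write.tree(genealogy_to_phylo(gen), file = path)
  invisible(path)
}

#' Convert an ape phylo tree into a genealogy
#'
#' Branch lengths are read as generations; the tree must be ultrametric (all
#' leaves contemporaneous) within `tol`, since node times are measured back
#' from the leaves.
#'
#' @param tree a rooted [ape::as.phylo] tree with edge lengths.
#' @param tol tolerance on leaf-depth differences.
#' @return a `genealogy` (without a mutated edge).
#' @export
phylo_to_genealogy <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  if (max(depth[seq_len(n)]) - min(depth[seq_len(n)]) > tol) {
    stop("tree is not ultrametric; node times are undefined")
  }
  time <- max(depth[seq_len(n)]) - depth
  time[seq_len(n)] <- 0
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  structure(
    list(parent = parent, time = time, labels = tree$tip.label,
         n_leaves = n, mutated_node = NA_integer_),
    class = "genealogy"
  )
}

#' Simulate multi-array genotype batches with optional planted batch effects
#'
#' Under the null (`delta = 0`) genotypes are drawn at a common AF per SNP in
#' every array, and PC surrogates are independent of array membership. With
#' `delta != 0`, a designated SNP subset has its AF shifted by `delta` in the
#' last array only, planting a batch effect that the LRT filter should catch.
#'
#' @param n_per_array individuals per array.
#' @param n_snps number of SNPs.
#' @param delta additive AF shift planted in the last array.
#' @param seed integer seed.
#' @param n_arrays number of arrays (>= 2; default 5).
#' @param shifted_fraction fraction of SNPs receiving the shift.
#' @return list with `genotypes` (individuals x SNPs), `arrays` (factor),
#'   `pcs` (4 columns), `af` (base AF per SNP) and `shifted` (logical ground
#'   truth per SNP).
#' @export
simulate_array_batches <- function(n_per_array, n_snps, delta, seed,
                                   n_arrays = 5L, shifted_fraction = 0.1) {
  n_per_array <- check_count(n_per_array, "n_per_array", min = 2L)
  n_snps <- check_count(n_snps, "n_snps")
  n_arrays <- check_count(n_arrays, "n_arrays", min = 2L)
  with_stream(seed, "batches", {
    af <- stats::runif(n_snps, 0.1, 0.9)
    if (any(af + delta <= 0 | af + delta >= 1)) {
      stop("delta pushes AF outside (0,1)")
    }
    shifted <- rep(FALSE, n_snps)
    if (delta != 0) {
      n_shift <- max(1L, round(shifted_fraction * n_snps))
      shifted[sample.int(n_snps, n_shift)] <- TRUE
    }
    n <- n_per_array * n_arrays
    arrays <- factor(rep(paste0("A", seq_len(n_arrays)), each = n_per_array))
    af_mat <- matrix(rep(af, each = n), nrow = n)
    last <- arrays == paste0("A", n_arrays)
    af_mat[last, shifted] <- af_mat[last, shifted] + delta
    genotypes <- matrix(stats::rbinom(n * n_snps, 2L, af_mat), nrow = n,
                        dimnames = list(NULL, paste0("snp", seq_len(n_snps))))
    pcs <- matrix(stats::rnorm(n * 4L), nrow = n,
                  dimnames = list(NULL, paste0("PC", 1:4)))
    list(genotypes = genotypes, arrays = arrays, pcs = pcs, af = af,
         shifted = shifted)
  })
}

#' Simulate a structural-variant callset with planted near-duplicates
#'
#' Records carry type (DEL/DUP), 1-based coordinates, length, allele count
#' and frequency. A fraction of records form planted near-duplicate pairs:
#' both start and end offsets are at most 100 bp, and pair allele counts
#' differ by `dup_ac_pct` percent (0 = identical AC, in which case the
#' deduplication rule removes the shorter member). Unrelated records are
#' placed on a 1-kb start grid so no accidental near-duplicates arise.
#'
#' @param n_svs total number of records (pairs count as two).
#' @param dup_fraction fraction of records that are members of a planted
#'   near-duplicate pair.
#' @param seed integer seed.
#' @param dup_ac_pct percent AC difference within planted pairs (percent of
#'   the pair mean).
#' @param n_alleles diploid allele total used to convert AC to AF.
#' @return data.frame of class `sv_callset` with columns `chrom`, `start`,
#'   `end`, `type`, `length`, `ac`, `af`, `sv_id`; the planted pairing is in
#'   `attr(, "truth")` (data.frame `keep_id`, `dup_id`).
#' @export
simulate_sv_callset <- function(n_svs, dup_fraction, seed, dup_ac_pct = 0,
                                n_alleles = 4346L) {
  n_svs <- check_count(n_svs, "n_svs")
  check_prob(dup_fraction, "dup_fraction", open = FALSE)
  with_stream(seed, "svs", {
    n_pairs <- floor(n_svs * dup_fraction / 2)
    n_orig <- n_svs - n_pairs
    chrom <- paste0("chr", sample.int(22L, n_orig, replace = TRUE))
    start <- integer(n_orig)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      start[idx] <- sample(seq(10000L, 200000000L, by = 1000L), length(idx))
    }
    len <- pmax(50L, round(stats::rlnorm(n_orig, log(1300), 1.2)))
    type <- sample(c("DEL", "DUP"), n_orig, replace = TRUE,
                   prob = c(0.93, 0.07))
    af <- pmin(pmax(stats::rbeta(n_orig, 0.3, 3), 1 / n_alleles), 0.99)
    ac <- pmax(1L, round(af * n_alleles))
    rec <- data.frame(
      chrom = chrom, start = start, end = start + len, type = type,
      length = len, ac = ac, af = ac / n_alleles,
      sv_id = paste0("sv", seq_len(n_orig)), stringsAsFactors = FALSE
    )
    truth <- data.frame(keep_id = character(0), dup_id = character(0))
    if (n_pairs > 0) {
      src <- sample.int(n_orig, n_pairs)
      if (dup_ac_pct > 0) {
        # keep planted AC percent differences meaningful after rounding
        rec$ac[src] <- pmax(rec$ac[src], 200L)
        rec$af[src] <- rec$ac[src] / n_alleles
      }
      dup <- rec[src, ]
      # offsets keep both breakpoints within the 100-bp window, and the
      # duplicate strictly shorter (by 1-50 bp) so "remove shorter" is
      # decisive
      ds <- sample(-50:50, n_pairs, replace = TRUE)
      de <- ds - sample(1:50, n_pairs, replace = TRUE)
      dup$start <- dup$start + ds
      dup$end <- dup$end + de
      dup$length <- dup$end - dup$start
      if (dup_ac_pct > 0) {
        dup$ac <- pmax(1L, round(dup$ac * (1 - dup_ac_pct / 100)))
        dup$af <- dup$ac / n_alleles
      }
      dup$sv_id <- paste0("sv", n_orig + seq_len(n_pairs))
      rec <- rbind(rec, dup)
      truth <- data.frame(keep_id = rec$sv_id[src], dup_id = dup$sv_id,
                          stringsAsFactors = FALSE)
    }
    rec <- rec[order(rec$chrom, rec$start), ]
    rownames(rec) <- NULL
    structure(rec, truth = truth, class = c("sv_callset", "data.frame"))
  })
}

#' Simulate the full synthetic world for one seed
#'
#' Convenience wrapper chaining [simulate_cohort()],
#' [simulate_reference_af()] (merged into the variant table) and
#' [simulate_imputed_panels()].
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (variant table augmented with `af_ref`,
#'   `enriched`, `fold`) and `panels`.
#' @export
simulate_world <- function(config) {
  cohort <- simulate_cohort(config)
  ref <- simulate_reference_af(
    pmin(pmax(cohort$variants$af, 1e-9), 1 - 1e-9),
    config$enrichment_spec, config$seed
  )
  cohort$variants$af_ref <- ref$af_ref
  cohort$variants$enriched <- ref$enriched
  cohort$variants$fold <- cohort$variants$af / ref$af_ref
  panels <- simulate_imputed_panels(cohort)
  list(cohort = cohort, panels = panels)
}
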