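#' Match loci across imputation approaches into a Venn partition
#'
#' Loci of the same trait coming from different approaches are connected
#' whenever their intervals overlap by at least `min_overlap` bp; connected
#' components (transitive closure) define locus clusters. Each cluster's
#' membership pattern is the set of approaches contributing at least one
#' locus; the seven possible patterns over \{local, global, meta\} partition
#' the clusters (the three-set Venn diagram).
#'
#' @param loci a `locus_set` (rows from all approaches together) or a list of
#'   `locus_set` objects which will be row-bound.
#' @param min_overlap minimum interval overlap in bp to connect two loci.
#' @return list of class `venn_partition`: `loci` (input with `cluster`
#'   column), `clusters` (per cluster: `cluster`, `trait`, `pattern`
#'   (approaches sorted, "+"-joined), `chrom`, `start`, `end` of the union
#'   interval, `lead` and `lead_p` of the representative lead — the member
#'   locus with the smallest lead P).
#' @export
match_loci <- function(loci, min_overlap = 1) {
  if (is.list(loci) && !is.data.frame(loci)) {
    loci <- do.call(rbind, loci)
  }
  stopifnot(is.data.frame(loci))
  n <- nrow(loci)
  if (n == 0L) {
    return(structure(list(loci = loci,
                          clusters = data.frame()), class = "venn_partition"))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (grp in split(seq_len(n), list(loci$trait, loci$chrom), drop = TRUE)) {
    if (length(grp) < 2L) next
    idx <- grp[order(loci$start[grp])]
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ov <- min(loci$end[i], loci$end[j]) -
          max(loci$start[i], loci$start[j]) + 1
        if (ov >= min_overlap) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  loci$cluster <- match(roots, unique(roots))
  clusters <- do.call(rbind, lapply(split(seq_len(n), loci$cluster),
    function(idx) {
      rep_i <- idx[order(loci$lead_p[idx])][1]
      data.frame(
        cluster = loci$cluster[idx[1]],
        trait = loci$trait[idx[1]],
        pattern = paste(sort(unique(loci$approach[idx])), collapse = "+"),
        chrom = loci$chrom[idx[1]],
        start = min(loci$start[idx]), end = max(loci$end[idx]),
        lead = loci$lead[rep_i], lead_p = loci$lead_p[rep_i],
        n_loci = length(idx), stringsAsFactors = FALSE
      )
    }))
  rownames(clusters) <- NULL
  structure(list(loci = loci, clusters = clusters), class = "venn_partition")
}

#' Per-subset summaries of a Venn partition
#'
#' For every membership pattern: cluster count, number of representative
#' leads absent from the alternate panel (defined when the pattern contains
#' exactly one of the two real panels; the alternate is the other one),
#' median paired INFO difference (local - global) over leads present in both
#' panels, and median lead AF (local-panel estimate).
#'
#' @param partition a `venn_partition` from [match_loci()].
#' @param variant_meta data.frame keyed by `id` with per-variant columns
#'   `present_local`, `present_global`, `info_local`, `info_global`, `af`.
#' @param local,global names of the two real panels in approach labels.
#' @return data.frame, one row per pattern: `pattern`, `n_loci`,
#'   `n_lead_absent`, `median_info_diff`, `median_lead_af`,
#'   `n_lead_in_both`.
#' @export
subset_summary <- function(partition, variant_meta, local = "local",
                           global = "global") {
  stopifnot(inherits(partition, "venn_partition"))
  cl <- partition$clusters
  if (nrow(cl) == 0L) return(data.frame())
  meta <- variant_meta[match(cl$lead, variant_meta$id), , drop = FALSE]
  out <- lapply(split(seq_len(nrow(cl)), cl$pattern), function(idx) {
    pat <- cl$pattern[idx[1]]
    apprs <- strsplit(pat, "+", fixed = TRUE)[[1]]
    has_local <- local %in% apprs
    has_global <- global %in% apprs
    alt_panel <- if (has_local && !has_global) {
      "present_global"
    } else if (has_global && !has_local) {
      "present_local"
    } else {
      NA_character_
    }
    n_absent <- if (is.na(alt_panel)) 0L else sum(!meta[[alt_panel]][idx],
                                                  na.rm = TRUE)
    in_both <- meta$present_local[idx] & meta$present_global[idx]
    in_both[is.na(in_both)] <- FALSE
    diffs <- (meta$info_local[idx] - meta$info_global[idx])[in_both]
    data.frame(
      pattern = pat, n_loci = length(idx), n_lead_absent = n_absent,
      median_info_diff = if (length(diffs)) stats::median(diffs) else NA_real_,
      median_lead_af = stats::median(meta$af[idx], na.rm = TRUE),
      n_lead_in_both = sum(in_both), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-individual panel recovery counts and concordance
#'
#' For each individual, counts variants that are carried in truth (at least
#' one alternate allele), well-imputed by panel A (present with INFO above
#' `well_imputed_info`) and absent or poorly imputed in panel B; genotype
#' concordance is the fraction of hard-called panel-A dosages equal to the
#' true genotype over those variants.
#'
#' @param truth integer matrix of true genotypes (individuals x variants).
#' @param panelA,panelB `imputed_panel` objects sharing `truth`'s variants.
#' @param well_imputed_info INFO threshold for "well-imputed" (exclusive).
#' @param hard_call_margin maximum distance from the nearest hard call; a
#'   dosage farther than this is a no-call (default `Inf`: always call).
#' @return data.frame with one row per individual (`recovered`,
#'   `concordance`); cohort `mean`/`se` of both in `attr(, "summary")`.
#' @export
recovery_stats <- function(truth, panelA, panelB, well_imputed_info = 0.3,
                           hard_call_margin = Inf) {
  stopifnot(inherits(panelA, "imputed_panel"), inherits(panelB, "imputed_panel"))
  m <- ncol(truth)
  if (length(panelA$info) != m || length(panelB$info) != m) {
    stop("panels and truth must share variant columns")
  }
  wellA <- panelA$present & !is.na(panelA$info) &
    panelA$info > well_imputed_info
  poorB <- !panelB$present | is.na(panelB$info) |
    panelB$info <= well_imputed_info
  target <- wellA & poorB
  if (!any(target)) stop("no variants well-imputed in A and missing/poor in B")
  carried <- truth[, target, drop = FALSE] >= 1
  recovered <- rowSums(carried)
  dosA <- panelA$dosage[, target, drop = FALSE]
  hard <- round(pmin(pmax(dosA, 0), 2))
  called <- abs(dosA - hard) <= hard_call_margin
  conc <- numeric(nrow(truth))
  truth_t <- truth[, target, drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    use <- carried[i, ] & called[i, ]
    conc[i] <- if (any(use)) mean(hard[i, use] == truth_t[i, use]) else NA_real_
  }
  out <- data.frame(recovered = recovered, concordance = conc)
  attr(out, "summary") <- c(
    mean_recovered = mean(recovered),
    se_recovered = stats::sd(recovered) / sqrt(nrow(out)),
    mean_concordance = mean(conc, na.rm = TRUE),
    se_concordance = stats::sd(conc, na.rm = TRUE) /
      sqrt(sum(!is.na(conc)))
  )
  out
}

#' Relative recovery ratio for enriched rare variants
#'
#' Ratio of the probability that a variant is present in truth, recovered by
#' panel A and missing in panel B, given that it is enriched
#' (`fold >= fold_min`) and rare in the reference (`af_ref < ref_af_max`),
#' to the same probability given only `af_ref < ref_af_max`.
#'
#' @param variant_table data.frame with logical columns `in_truth`,
#'   `recovered_by_A`, `missing_in_B` and numeric `fold`, `af_ref`.
#' @param fold_min enrichment fold defining the numerator stratum.
#' @param ref_af_max reference-AF cap defining the background stratum.
#' @return single numeric ratio; the stratum proportions are in
#'   `attr(, "detail")`.
#' @export
relative_recovery_ratio <- function(variant_table, fold_min = 8,
                                    ref_af_max = 0.05) {
  need <- c("in_truth", "recovered_by_A", "missing_in_B", "fold", "af_ref")
  if (!all(need %in% names(variant_table))) {
    stop("variant_table must have columns ", paste(need, collapse = ", "))
  }
  event <- variant_table$in_truth & variant_table$recovered_by_A &
    variant_table$missing_in_B
  background <- variant_table$af_ref < ref_af_max
  enriched <- background & variant_table$fold >= fold_min
  if (!any(enriched)) stop("empty enriched stratum (fold >= ", fold_min, ")")
  if (!any(background)) stop("empty background stratum")
  p_enr <- mean(event[enriched])
  p_bg <- mean(event[background])
  if (p_bg == 0) stop("background event proportion is zero; ratio undefined")
  structure(p_enr / p_bg,
            detail = c(p_enriched = p_enr, p_background = p_bg,
                       n_enriched = sum(enriched),
                       n_background = sum(background)))
}
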