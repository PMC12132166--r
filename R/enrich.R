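#' Founder-population allele-frequency enrichment
#'
#' A variant is classified enriched when its cohort minor allele frequency is
#' at least `maf_min` (default 0.1%) and the cohort/reference AF ratio is at
#' least `fold_min` (default 4). When the reference AF is exactly zero and
#' the cohort AF is positive the fold is the `Inf` sentinel (and the variant
#' is enriched whenever the MAF criterion holds).
#'
#' @param af_cohort,af_ref allele frequencies in `[0, 1]` (vectorized).
#' @param maf_min cohort minor-AF threshold (inclusive).
#' @param fold_min enrichment fold threshold (inclusive).
#' @return data.frame with columns `fold` and `enriched`.
#' @export
enrichment_fold <- function(af_cohort, af_ref, maf_min = 0.001,
                            fold_min = 4) {
  check_prob(af_cohort, "af_cohort", open = FALSE)
  check_prob(af_ref, "af_ref", open = FALSE)
  stopifnot(length(af_cohort) == length(af_ref))
  fold <- ifelse(af_ref == 0,
                 ifelse(af_cohort > 0, Inf, NA_real_),
                 af_cohort / af_ref)
  maf <- pmin(af_cohort, 1 - af_cohort)
  enriched <- !is.na(fold) & maf >= maf_min & fold >= fold_min
  data.frame(fold = fold, enriched = enriched)
}

#' Odds ratio and central two-sided Fisher exact test for a 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))`. The odds ratio is the sample
#' estimate `(a*d)/(b*c)`, with the Haldane-Anscombe correction (+0.5 to all
#' four cells) applied when any cell is zero. The p-value is the central
#' two-sided Fisher exact probability: the sum over the hypergeometric
#' support of all table probabilities not exceeding the observed table's
#' (with the conventional `1 + 1e-7` relative tolerance for floating-point
#' ties).
#'
#' @param a,b,c,d nonnegative integer cell counts; all four margins must be
#'   positive.
#' @return list with `or_estimate` and `p`.
#' @export
fisher_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("all margins of the 2x2 table must be positive")
  }
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  m <- a + b          # row-1 total
  n2 <- c + d         # row-2 total
  k <- a + c          # column-1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(or_estimate = or, p = p)
}

#' Prioritize variants of clinical interest
#'
#' Applies an ordered, configurable rule chain to an annotation table. The
#' default chain mirrors a typical rare-disease prioritization: (1)
#' `candidate` — ClinVar Pathogenic / Likely Pathogenic / conflicting
#' interpretations, or putative loss-of-function; (2) `maf` — reference
#' (e.g. gnomAD) AF at most `maf_max`; (3) `impact` — CADD at least
#' `cadd_min`, with splice candidates admitted by SpliceAI at least
#' `spliceai_min` even when CADD fails. Missing annotation values fail their
#' rule. Per-rule removal counts are attached as `attr(, "removed")`.
#'
#' @param annots data.frame with columns `id`, `clinvar` (factor/character:
#'   `P`, `LP`, `conflicting`, `other`, `none`), `plof` (logical), `af_ref`,
#'   `cadd`, `spliceai`.
#' @param rules character vector naming the rules to apply, in order; any
#'   subset of `c("candidate", "maf", "impact")`. Unknown names error.
#' @param maf_max,cadd_min,spliceai_min rule thresholds.
#' @return the surviving rows of `annots`.
#' @export
prioritize_variants <- function(annots,
                                rules = c("candidate", "maf", "impact"),
                                maf_max = 0.01, cadd_min = 15,
                                spliceai_min = 0.8) {
  known <- c("candidate", "maf", "impact")
  if (!all(rules %in% known)) {
    stop("unknown rule name(s): ",
         paste(setdiff(rules, known), collapse = ", "))
  }
  removed <- integer(0)
  keep <- annots
  for (rule in rules) {
    before <- nrow(keep)
    keep <- switch(rule,
      candidate = {
        cv <- as.character(keep$clinvar)
        cv_ok <- !is.na(cv) & cv %in% c("P", "LP", "conflicting")
        plof_ok <- !is.na(keep$plof) & keep$plof
        keep[cv_ok | plof_ok, , drop = FALSE]
      },
      maf = keep[!is.na(keep$af_ref) & keep$af_ref <= maf_max, ,
                 drop = FALSE],
      impact = {
        cadd_ok <- !is.na(keep$cadd) & keep$cadd >= cadd_min
        splice_ok <- !is.na(keep$spliceai) & keep$spliceai >= spliceai_min
        keep[cadd_ok | splice_ok, , drop = FALSE]
      }
    )
    removed[rule] <- before - nrow(keep)
  }
  rownames(keep) <- NULL
  attr(keep, "removed") <- removed
  keep
}

#' Carrier inference from the MRCA of known carriers
#'
#' Finds the most recent common ancestor of the known carrier leaves, reports
#' its age (TMRCA, in generations), and expands the carrier set to every leaf
#' descending from that MRCA — the assumption being that a single-origin
#' mutation above the MRCA is carried by the whole clade.
#'
#' @param tree a `genealogy` (see [simulate_genealogy()]).
#' @param known_carriers character vector of leaf labels (nonempty, all
#'   present in the tree).
#' @return list with `mrca` (node id), `tmrca` (generations) and `carriers`
#'   (expanded leaf label set, a superset of `known_carriers`).
#' @export
mrca_carriers <- function(tree, known_carriers) {
  stopifnot(inherits(tree, "genealogy"), length(known_carriers) >= 1L)
  leaf_idx <- match(known_carriers, tree$labels)
  if (anyNA(leaf_idx)) {
    stop("unknown leaf label(s): ",
         paste(known_carriers[is.na(leaf_idx)], collapse = ", "))
  }
  # walk each leaf's ancestor path; the MRCA is the first common node when
  # lifting the deepest lineage step by step
  mrca <- leaf_idx[1]
  for (v in leaf_idx[-1]) {
    a <- mrca
    b <- v
    while (a != b) {
      # lift whichever lineage sits lower; with equal times (two leaves at
      # time 0) lift both
      if (tree$time[a] < tree$time[b]) {
        a <- tree$parent[a]
      } else if (tree$time[b] < tree$time[a]) {
        b <- tree$parent[b]
      } else {
        a <- tree$parent[a]
        b <- tree$parent[b]
      }
      if (a == 0L || b == 0L) stop("disconnected tree")
    }
    mrca <- a
  }
  carriers <- tree$labels[leaves_below(tree, mrca)]
  list(mrca = mrca, tmrca = tree$time[mrca], carriers = carriers)
}

#' Per-region carrier frequency with bootstrap confidence intervals
#'
#' Carrier frequency per region is the carrier count over the region's
#' individual count. The 95% CI is a percentile bootstrap resampling
#' individuals with replacement within the region. Resampling n exchangeable
#' binary indicators is distributionally identical to a Binomial(n, p-hat)
#' draw, which is how the replicates are generated (seeded, so reproducible).
#'
#' @param carrier logical vector, one entry per individual.
#' @param region character/factor vector of region labels, same length.
#' @param n_boot bootstrap iterations (default 100000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame per region: `region`, `n`, `carriers`, `frequency`,
#'   `ci_low`, `ci_high`.
#' @export
carrier_frequency_ci <- function(carrier, region, n_boot = 100000, seed = 1L,
                                 conf = 0.95) {
  stopifnot(length(carrier) == length(region), is.logical(carrier))
  alpha <- (1 - conf) / 2
  with_stream(seed, "bootstrap", {
    out <- lapply(split(carrier, region), function(x) {
      n <- length(x)
      if (n == 0L) {
        warning("empty region skipped")
        return(NULL)
      }
      phat <- mean(x)
      boot <- stats::rbinom(n_boot, n, phat) / n
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      data.frame(n = n, carriers = sum(x), frequency = phat,
                 ci_low = ci[1], ci_high = ci[2])
    })
    out <- out[!vapply(out, is.null, logical(1))]
    res <- do.call(rbind, out)
    res <- cbind(region = names(out), res)
    rownames(res) <- NULL
    res
  })
}
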