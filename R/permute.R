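#' Default minor-allele-frequency strata
#'
#' Bin edges on the minor-allele scale used for AF-stratified permutation
#' sampling.
#' @export
default_af_bins <- function() c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5)

af_stratum <- function(af, bins) {
  maf <- pmin(af, 1 - af)
  cut(maf, breaks = bins, include.lowest = TRUE, right = TRUE)
}

new_perm_result <- function(observed, n_perm, p, tail, ci, strata, seed,
                            null_summary) {
  structure(
    list(observed = observed, n_perm = n_perm, p_value = p, tail = tail,
         ci_low = ci[1], ci_high = ci[2], strata = strata, seed = seed,
         null_summary = null_summary),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s-tailed, %d permutations)\n observed = %.6g\n p = %.3g\n 95%% CI of observed: [%.6g, %.6g]\n",
    x$tail, x$n_perm, x$observed, x$p_value, x$ci_low, x$ci_high
  ))
  invisible(x)
}

# Draw one without-replacement sample from `pool_idx` matching the per-stratum
# counts in `lead_strata`; strata are factor levels shared by pool and leads.
stratified_sample_idx <- function(pool_strata, counts) {
  idx <- integer(0)
  for (s in names(counts)) {
    k <- counts[[s]]
    if (k == 0L) next
    cand <- which(pool_strata == s)
    idx <- c(idx, cand[sample.int(length(cand), k)])
  }
  idx
}

#' AF-stratified permutation test for a median paired INFO difference
#'
#' Tests whether the median of per-variant paired imputation-quality
#' differences (local - global) over a lead-variant set is unusual relative
#' to frequency-matched variants drawn from a genome-wide pool. Each null
#' replicate draws, without replacement and within AF strata, the same number
#' of pool variants per stratum as the lead set holds, and recomputes the
#' median. The two-tailed p-value is centered on the null median with the
#' add-one correction `(1 + r) / (n_perm + 1)`. The confidence interval is a
#' stratified percentile bootstrap of the observed statistic.
#'
#' @param lead_set data.frame with columns `af` and `diff` for lead variants.
#' @param pool data.frame with columns `af` and `diff` for the comparison
#'   pool (typically all genome-wide variants present in both panels).
#' @param n_perm number of permutations (default 10000; use 1e6 to mirror
#'   publication-scale runs).
#' @param af_bins stratum edges on the minor-allele scale.
#' @param seed integer seed (fully determines p and CI).
#' @param n_boot bootstrap replicates for the CI of the observed median.
#' @return a `perm_result`.
#' @export
perm_test_median_diff <- function(lead_set, pool, n_perm = 10000,
                                  af_bins = default_af_bins(), seed = 1L,
                                  n_boot = 1000) {
  stopifnot(all(c("af", "diff") %in% names(lead_set)),
            all(c("af", "diff") %in% names(pool)))
  lead_strata <- af_stratum(lead_set$af, af_bins)
  pool_strata <- af_stratum(pool$af, af_bins)
  counts <- table(lead_strata)
  pool_counts <- table(pool_strata)
  short <- names(counts)[counts > pool_counts[names(counts)]]
  if (length(short)) {
    stop("pool stratum ", paste(short, collapse = ", "),
         " holds fewer variants than the lead set requires")
  }
  observed <- stats::median(lead_set$diff)
  with_stream(seed, "permute", {
    nulls <- numeric(n_perm)
    active <- names(counts)[counts > 0]
    stratum_members <- lapply(active, function(s) which(pool_strata == s))
    names(stratum_members) <- active
    for (b in seq_len(n_perm)) {
      idx <- unlist(lapply(active, function(s) {
        mem <- stratum_members[[s]]
        mem[sample.int(length(mem), counts[[s]])]
      }), use.names = FALSE)
      nulls[b] <- stats::median(pool$diff[idx])
    }
    null_center <- stats::median(nulls)
    r <- sum(abs(nulls - null_center) >= abs(observed - null_center))
    p <- (1 + r) / (n_perm + 1)
    # stratified bootstrap CI of the observed median
    boot <- numeric(n_boot)
    lead_by_stratum <- split(lead_set$diff, lead_strata, drop = TRUE)
    for (b in seq_len(n_boot)) {
      samp <- unlist(lapply(lead_by_stratum, function(v) {
        v[sample.int(length(v), length(v), replace = TRUE)]
      }), use.names = FALSE)
      boot[b] <- stats::median(samp)
    }
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    new_perm_result(observed, n_perm, p, "two", ci, af_bins, seed,
                    c(median = null_center, sd = stats::sd(nulls)))
  })
}

#' Permutation test for a fold change in a lead-variant property
#'
#' The observed statistic is the proportion of lead variants satisfying a
#' predicate divided by the pool proportion. Null replicates draw
#' `|lead_set|` pool variants without replacement (uniformly by default,
#' AF-stratified if `stratified = TRUE`) and recompute the fold change. The
#' one-tailed p-value is the add-one-corrected proportion of null fold
#' changes at or above the observed one.
#'
#' @param lead_set,pool data.frames; must contain the columns the predicate
#'   uses (and `af` if `stratified`).
#' @param predicate function mapping a data.frame to a logical vector, or
#'   the name of a logical column.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param stratified sample the null within AF strata (default FALSE).
#' @param af_bins stratum edges used when `stratified`.
#' @param n_boot bootstrap replicates for the CI of the observed fold.
#' @return a `perm_result`.
#' @export
perm_test_fold_change <- function(lead_set, pool, predicate, n_perm = 10000,
                                  seed = 1L, stratified = FALSE,
                                  af_bins = default_af_bins(),
                                  n_boot = 1000) {
  pred_fun <- if (is.character(predicate)) {
    function(df) as.logical(df[[predicate]])
  } else {
    predicate
  }
  pool_flag <- pred_fun(pool)
  lead_flag <- pred_fun(lead_set)
  stopifnot(!anyNA(pool_flag), !anyNA(lead_flag))
  pool_prop <- mean(pool_flag)
  if (pool_prop == 0) stop("pool proportion is zero; fold change undefined")
  n_lead <- nrow(lead_set)
  observed <- mean(lead_flag) / pool_prop
  with_stream(seed, "permute", {
    if (stratified) {
      lead_strata <- af_stratum(lead_set$af, af_bins)
      pool_strata <- af_stratum(pool$af, af_bins)
      counts <- table(lead_strata)
      active <- names(counts)[counts > 0]
      stratum_members <- lapply(active, function(s) which(pool_strata == s))
      names(stratum_members) <- active
      draw <- function() {
        unlist(lapply(active, function(s) {
          mem <- stratum_members[[s]]
          mem[sample.int(length(mem), counts[[s]])]
        }), use.names = FALSE)
      }
    } else {
      n_pool <- nrow(pool)
      draw <- function() sample.int(n_pool, n_lead)
    }
    nulls <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      nulls[b] <- mean(pool_flag[draw()]) / pool_prop
    }
    p <- (1 + sum(nulls >= observed)) / (n_perm + 1)
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      boot[b] <- mean(lead_flag[sample.int(n_lead, n_lead, replace = TRUE)]) /
        pool_prop
    }
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    new_perm_result(observed, n_perm, p, "one", ci,
                    if (stratified) af_bins else NULL, seed,
                    c(median = stats::median(nulls), sd = stats::sd(nulls)))
  })
}
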