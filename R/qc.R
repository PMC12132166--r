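#' Genotyping-array batch-effect likelihood-ratio test (one SNP)
#'
#' Compares the linear models `G ~ 1 + PC1..PC4 + array` (full) and
#' `G ~ 1 + PC1..PC4` (reduced), where G is the 0/1/2 genotype. The Gaussian
#' LRT statistic is `n * log(RSS_reduced / RSS_full)` and the p-value comes
#' from a chi-square distribution with `n_arrays - 1` degrees of freedom
#' (four for the usual five arrays). Under random sampling with no batch
#' effect, array membership should not predict individual genotype beyond
#' the PCs.
#'
#' @param genotypes integer vector of 0/1/2 genotypes for one SNP.
#' @param pcs matrix/data.frame with at least one PC column (typically 4).
#' @param arrays factor of array membership (>= 2 levels, each with >= 2
#'   individuals).
#' @param alpha rejection threshold; for genome-wide screening pass the
#'   Bonferroni level `0.05 / n_snps`.
#' @return one-row data.frame: `lrt`, `df`, `p`, `reject`.
#' @export
batch_lrt <- function(genotypes, pcs, arrays, alpha = 0.05) {
  arrays <- droplevels(as.factor(arrays))
  if (nlevels(arrays) < 2L) stop("need >= 2 arrays")
  if (any(table(arrays) < 2L)) stop("every array needs >= 2 individuals")
  pcs <- as.matrix(pcs)
  n <- length(genotypes)
  stopifnot(nrow(pcs) == n, length(arrays) == n)
  X_red <- cbind(1, pcs)
  if (qr(X_red)$rank < ncol(X_red)) stop("collinear PCs")
  X_full <- cbind(X_red, stats::model.matrix(~ arrays)[, -1, drop = FALSE])
  rss_red <- sum(stats::lm.fit(X_red, genotypes)$residuals^2)
  rss_full <- sum(stats::lm.fit(X_full, genotypes)$residuals^2)
  lrt <- if (rss_full <= n * 1e-12 || rss_red <= n * 1e-12) 0 else
    max(0, n * log(rss_red / rss_full))
  df <- nlevels(arrays) - 1L
  p <- stats::pchisq(lrt, df, lower.tail = FALSE)
  data.frame(lrt = lrt, df = df, p = p, reject = p < alpha)
}

#' Vectorized batch-effect LRT over a genotype matrix
#'
#' Identical statistic to [batch_lrt()] applied per SNP, computed via the
#' shared hat matrix (the design is fixed across SNPs; only the genotype
#' response changes). The default rejection threshold is the Bonferroni level
#' 0.05 / n_snps.
#'
#' @param genotypes integer matrix (individuals x SNPs).
#' @param pcs PC matrix (typically 4 columns).
#' @param arrays factor of array membership.
#' @param alpha per-SNP rejection threshold; default `0.05 / ncol(genotypes)`.
#' @return data.frame per SNP: `snp`, `lrt`, `df`, `p`, `reject`.
#' @export
batch_lrt_scan <- function(genotypes, pcs, arrays,
                           alpha = 0.05 / ncol(genotypes)) {
  arrays <- droplevels(as.factor(arrays))
  if (nlevels(arrays) < 2L) stop("need >= 2 arrays")
  if (any(table(arrays) < 2L)) stop("every array needs >= 2 individuals")
  pcs <- as.matrix(pcs)
  n <- nrow(genotypes)
  X_red <- cbind(1, pcs)
  if (qr(X_red)$rank < ncol(X_red)) stop("collinear PCs")
  X_full <- cbind(X_red, stats::model.matrix(~ arrays)[, -1, drop = FALSE])
  rss <- function(X) {
    q <- qr(X)
    res <- qr.resid(q, genotypes)
    colSums(res^2)
  }
  rss_red <- rss(X_red)
  rss_full <- rss(X_full)
  lrt <- ifelse(rss_full <= n * 1e-12 | rss_red <= n * 1e-12, 0,
                pmax(0, n * log(rss_red / rss_full)))
  df <- nlevels(arrays) - 1L
  p <- stats::pchisq(lrt, df, lower.tail = FALSE)
  snp <- colnames(genotypes)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(genotypes)))
  data.frame(snp = snp, lrt = lrt, df = df, p = p, reject = p < alpha,
             stringsAsFactors = FALSE)
}

#' Deduplicate near-identical structural variants
#'
#' Two records are a candidate pair when they share chromosome and type and
#' both their start and end positions lie within `window` bp of each other.
#' For a pair with identical allele counts the shorter member is removed
#' (length ties: the later record in (chrom, start) sort order). Otherwise,
#' when both the allele-count and the allele-frequency percent differences
#' are below `pct_max`, the lower-AC member is removed. Any other pair is
#' left untouched. When more than two records are mutually within the
#' window, pairs are processed greedily in ascending `|dstart| + |dend|`
#' order, skipping pairs whose member was already removed — so both members
#' of a pair are never removed and the operation is idempotent.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `type`,
#'   `length`, `ac`, `af` (an `sv_callset` works as-is).
#' @param window breakpoint window in bp (default 100).
#' @param pct_max percent-difference threshold (exclusive, default 1).
#' @param pct_denom denominator of the percent difference: `"mean"`
#'   (default) or `"max"` of the two values.
#' @return list with `kept` (data.frame) and `removed` (data.frame with a
#'   `reason` column: `"equal_ac_shorter"` or `"close_ac_lower"`).
#' @export
dedup_svs <- function(records, window = 100, pct_max = 1,
                      pct_denom = c("mean", "max")) {
  if (window < 0) stop("window must be nonnegative")
  pct_denom <- match.arg(pct_denom)
  need <- c("chrom", "start", "end", "type", "length", "ac", "af")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  rec <- as.data.frame(records)[order(records$chrom, records$start), ,
                                drop = FALSE]
  n <- nrow(rec)
  pct_diff <- function(x, y) {
    denom <- if (pct_denom == "mean") (x + y) / 2 else pmax(x, y)
    ifelse(denom == 0, 0, abs(x - y) / denom * 100)
  }
  # candidate pairs: same chrom+type, |dstart|<=window and |dend|<=window
  pairs <- NULL
  for (grp in split(seq_len(n), list(rec$chrom, rec$type), drop = TRUE)) {
    if (length(grp) < 2L) next
    idx <- grp[order(rec$start[grp])]
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        dstart <- abs(rec$start[j] - rec$start[i])
        if (dstart > window) break  # sorted by start
        dend <- abs(rec$end[j] - rec$end[i])
        if (dend > window) next
        pairs <- rbind(pairs, c(i, j, dstart + dend))
      }
    }
  }
  removed_idx <- integer(0)
  reason <- character(0)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    gone <- rep(FALSE, n)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (gone[i] || gone[j]) next
      if (rec$ac[i] == rec$ac[j]) {
        drop <- if (rec$length[i] < rec$length[j]) {
          i
        } else if (rec$length[j] < rec$length[i]) {
          j
        } else {
          j  # equal lengths: drop the later record in sort order
        }
        gone[drop] <- TRUE
        removed_idx <- c(removed_idx, drop)
        reason <- c(reason, "equal_ac_shorter")
      } else if (pct_diff(rec$ac[i], rec$ac[j]) < pct_max &&
                 pct_diff(rec$af[i], rec$af[j]) < pct_max) {
        drop <- if (rec$ac[i] < rec$ac[j]) i else j
        gone[drop] <- TRUE
        removed_idx <- c(removed_idx, drop)
        reason <- c(reason, "close_ac_lower")
      }
    }
  }
  kept <- rec[setdiff(seq_len(n), removed_idx), , drop = FALSE]
  removed <- rec[removed_idx, , drop = FALSE]
  removed$reason <- reason
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}
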