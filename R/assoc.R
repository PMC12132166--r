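#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (average-tie) ranks:
#' `qnorm((rank - offset) / (n - 2*offset + 1))`. The default
#' `offset = 0.5` gives `(rank - 0.5)/n`; `offset = 3/8` is the Blom variant.
#' The transform is order-preserving and invariant to any strictly monotone
#' transform of the input.
#'
#' @param values numeric vector, at least two finite values.
#' @param offset rank offset; 0.5 (default) or 3/8 (Blom).
#' @return numeric vector of normal scores.
#' @export
rint <- function(values, offset = 0.5) {
  if (length(values) < 2L || !all(is.finite(values))) {
    stop("rint requires >= 2 finite values")
  }
  if (length(unique(values)) == 1L) {
    stop("rint undefined for constant input")
  }
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Single-variant linear association test
#'
#' Ordinary least squares of the (optionally rank-inverse-normal transformed)
#' phenotype on one dosage plus intercept and covariates. The two-sided
#' P-value comes from the t distribution with `n - k` residual degrees of
#' freedom. Missing dosages are mean-imputed per variant before regression.
#'
#' @param dosage numeric dosage vector (0..2 scale; imputed dosages allowed).
#' @param phenotype numeric phenotype vector.
#' @param covariates data.frame or matrix of covariates (factors expanded),
#'   or NULL.
#' @param transform apply [rint()] to the phenotype first (default TRUE).
#' @param info imputation quality carried through to the result (optional).
#' @return one-row data.frame (an `AssocStat` row): `beta`, `se`, `p`, `n`,
#'   `af`, `mac`, `info`, `flag` (`"ok"` or `"degenerate"` when the dosage is
#'   constant or collinear with the covariates; then `beta`/`se`/`p` are NA).
#' @export
linear_assoc <- function(dosage, phenotype, covariates = NULL,
                         transform = TRUE, info = NA_real_) {
  n <- length(phenotype)
  stopifnot(length(dosage) == n)
  if (anyNA(dosage)) dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
  y <- if (transform) rint(phenotype) else phenotype
  X <- design_matrix(covariates, n)
  af <- mean(dosage) / 2
  mac <- round(min(sum(dosage), 2 * n - sum(dosage)))
  fit <- ols_last(cbind(X, dosage), y)
  if (is.null(fit)) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                      af = af, mac = mac, info = info, flag = "degenerate",
                      stringsAsFactors = FALSE))
  }
  data.frame(beta = fit$beta, se = fit$se, p = fit$p, n = n, af = af,
             mac = mac, info = info, flag = "ok", stringsAsFactors = FALSE)
}

# Intercept + expanded covariates.
design_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (is.matrix(covariates)) {
    return(cbind(`(Intercept)` = 1, covariates))
  }
  stats::model.matrix(~ ., data = as.data.frame(covariates))
}

# OLS; returns beta/se/p of the LAST column, or NULL if it adds no rank.
ols_last <- function(X, y) {
  X <- as.matrix(X)
  qr_x <- qr(X)
  p_all <- ncol(X)
  if (qr_x$rank < p_all || stats::var(X[, p_all]) == 0) {
    # last column collinear with the rest (or constant)
    qr_red <- qr(X[, -p_all, drop = FALSE])
    if (qr_x$rank == qr_red$rank) return(NULL)
  }
  fit <- stats::lm.fit(X, y)
  keep <- !is.na(fit$coefficients)
  if (!keep[p_all]) return(NULL)
  df <- length(y) - fit$rank
  if (df <= 0) return(NULL)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  XtX_inv <- chol2inv(R)
  # (X'X)^-1 is in pivoted column order; locate the dosage column there
  idx <- which(fit$qr$pivot[seq_len(fit$rank)] == p_all)
  if (length(idx) != 1L) return(NULL)
  se <- sqrt(sigma2 * XtX_inv[idx, idx])
  beta <- fit$coefficients[p_all]
  tval <- beta / se
  list(beta = unname(beta), se = se, p = 2 * stats::pt(-abs(tval), df))
}

#' Genome-wide scan over a dosage matrix
#'
#' Applies [linear_assoc()] to each column of a dosage matrix, with the
#' phenotype transformed once. Returns a regenie-like summary-statistics
#' table.
#'
#' @param dosage numeric matrix (individuals x variants) with column names.
#' @param phenotype numeric vector.
#' @param covariates data.frame of covariates or NULL.
#' @param variants optional variant metadata (`id`, `chrom`, `pos`, `ref`,
#'   `alt`) merged into the output by `id` = column name.
#' @param info optional per-variant INFO vector (NA allowed).
#' @param trait,approach labels stored on every row.
#' @param transform apply RINT to the phenotype (once, default TRUE).
#' @return data.frame with columns `id`, `beta`, `se`, `p`, `n`, `af`, `mac`,
#'   `info`, `trait`, `approach` (plus any metadata columns).
#' @export
assoc_scan <- function(dosage, phenotype, covariates = NULL, variants = NULL,
                       info = NULL, trait = "trait", approach = "panel",
                       transform = TRUE) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  y <- if (transform) rint(phenotype) else phenotype
  if (is.null(info)) info <- rep(NA_real_, ncol(dosage))
  rows <- vector("list", ncol(dosage))
  for (j in seq_len(ncol(dosage))) {
    d <- dosage[, j]
    if (all(is.na(d))) next
    rows[[j]] <- cbind(id = colnames(dosage)[j],
                       linear_assoc(d, y, covariates, transform = FALSE,
                                    info = info[j]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), n = integer(0), af = numeric(0),
                      mac = numeric(0), info = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE)
  }
  out$trait <- trait
  out$approach <- approach
  if (!is.null(variants)) {
    meta_cols <- setdiff(names(variants), names(out))
    out <- cbind(out, variants[match(out$id, variants$id), meta_cols,
                               drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Stepwise conditional analysis within a locus
#'
#' Forward selection of independent index variants. Selection starts from the
#' lead variant. At each round every unselected variant is tested with all
#' selected variants' dosages added as covariates; the minimum-P variant is
#' added if its conditional P is below `alpha`. Minimum-P ties are broken by
#' position, then lexicographic alternate allele. Variants whose addition
#' makes the design singular are skipped with a warning.
#'
#' @param locus_variants data.frame with columns `id`, `pos` and optionally
#'   `alt` for the locus members (lead included).
#' @param dosages numeric matrix (individuals x variants) whose column names
#'   cover `locus_variants$id`.
#' @param phenotype numeric phenotype vector.
#' @param covariates data.frame of covariates or NULL.
#' @param alpha locus-wide significance threshold (default 1e-5).
#' @param lead id of the lead variant; defaults to the marginally
#'   most-significant member.
#' @param transform apply RINT to the phenotype (default TRUE).
#' @return character vector of index variant ids in selection order (lead
#'   first).
#' @export
stepwise_conditional <- function(locus_variants, dosages, phenotype,
                                 covariates = NULL, alpha = 1e-5,
                                 lead = NULL, transform = TRUE) {
  stopifnot(nrow(locus_variants) >= 1L,
            all(locus_variants$id %in% colnames(dosages)))
  ids <- locus_variants$id
  y <- if (transform) rint(phenotype) else phenotype
  if (is.null(lead)) {
    marg <- vapply(ids, function(v) {
      linear_assoc(dosages[, v], y, covariates, transform = FALSE)$p
    }, numeric(1))
    lead <- pick_min_p(ids, marg, locus_variants)
  }
  stopifnot(lead %in% ids)
  selected <- lead
  remaining <- setdiff(ids, lead)
  base_X <- design_matrix(covariates, length(y))
  while (length(remaining) > 0L) {
    cond_X <- cbind(base_X, dosages[, selected, drop = FALSE])
    pvals <- rep(NA_real_, length(remaining))
    for (k in seq_along(remaining)) {
      d <- dosages[, remaining[k]]
      if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
      fit <- ols_last(cbind(cond_X, d), y)
      if (is.null(fit)) {
        warning("singular design; skipping variant ", remaining[k])
        next
      }
      pvals[k] <- fit$p
    }
    ok <- which(!is.na(pvals))
    if (length(ok) == 0L) break
    best <- pick_min_p(remaining[ok], pvals[ok], locus_variants)
    if (pvals[match(best, remaining)] < alpha) {
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    } else {
      break
    }
  }
  selected
}

# Deterministic min-P choice: lowest p, then position, then alternate allele.
pick_min_p <- function(ids, pvals, meta) {
  cand <- ids[pvals == min(pvals)]
  if (length(cand) == 1L) return(cand)
  rows <- meta[match(cand, meta$id), , drop = FALSE]
  alt <- if ("alt" %in% names(rows)) rows$alt else rep("", length(cand))
  cand[order(rows$pos, alt)][1L]
}
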