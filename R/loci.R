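#' Filter summary statistics before locus calling
#'
#' Keeps variants with minor allele count strictly greater than `mac_min`,
#' at least `mac_floor`, and imputation quality strictly greater than
#' `info_min` (both inequalities strict, matching the conventional
#' MAC > 20 / INFO > 0.3 locus filter). Removal counts per criterion are
#' attached as `attr(, "removed")`.
#'
#' @param stats summary-statistics data.frame with `mac` and `info` columns.
#' @param mac_min minor-allele-count threshold (exclusive).
#' @param info_min INFO threshold (exclusive).
#' @param mac_floor absolute MAC floor (inclusive) applied upstream of any
#'   analysis (variants below it are never considered).
#' @return filtered data.frame.
#' @export
filter_for_loci <- function(stats, mac_min = 20, info_min = 0.3,
                            mac_floor = 5) {
  if (!all(c("mac", "info") %in% names(stats))) {
    stop("stats must have 'mac' and 'info' columns")
  }
  fail_floor <- !is.na(stats$mac) & stats$mac < mac_floor
  fail_mac <- !is.na(stats$mac) & stats$mac <= mac_min & !fail_floor
  fail_info <- is.na(stats$info) | stats$info <= info_min
  keep <- !(fail_floor | fail_mac | fail_info)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(
    mac_floor = sum(fail_floor), mac = sum(fail_mac),
    info = sum(fail_info & !(fail_floor | fail_mac))
  )
  out
}

#' Call independent genome-wide significant loci
#'
#' Per trait and approach: every variant with `p < p_threshold` seeds a
#' window `[pos - flank, pos + flank]` (clipped at 1 and, when
#' `chrom_lengths` is given, at the chromosome end). Windows on the same
#' chromosome that overlap or are immediately adjacent (gap of at most
#' `max_gap` bp between them) are merged transitively into one locus. Each
#' locus's lead variant is its lowest-P member (ties: lowest position, then
#' lexicographic alternate allele).
#'
#' @param stats summary statistics with columns `id`, `chrom`, `pos`, `p`
#'   and optionally `alt`, `trait`, `approach`.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param flank window half-width in bp (default 500000).
#' @param chrom_lengths optional named vector for right-clipping windows.
#' @param max_gap windows with a gap of at most this many bp merge
#'   (default 1, i.e. touching or 1-bp-separated windows merge).
#' @return data.frame of class `locus_set`, one row per locus: `trait`,
#'   `approach`, `chrom`, `start`, `end` (1-based inclusive), `lead`,
#'   `lead_p`, `n_members`; member ids in the list column `members`.
#' @export
call_loci <- function(stats, p_threshold = 5e-8, flank = 500000,
                      chrom_lengths = NULL, max_gap = 1) {
  need <- c("id", "chrom", "pos", "p")
  if (!all(need %in% names(stats))) {
    stop("stats must have columns ", paste(need, collapse = ", "))
  }
  if (!"trait" %in% names(stats)) stats$trait <- "trait"
  if (!"approach" %in% names(stats)) stats$approach <- "panel"
  sig <- stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty_locus_set())
  groups <- split(sig, list(sig$trait, sig$approach, sig$chrom), drop = TRUE)
  loci <- lapply(groups, function(g) {
    g <- g[order(g$pos), , drop = FALSE]
    start <- pmax(1, g$pos - flank)
    end <- g$pos + flank
    if (!is.null(chrom_lengths) && g$chrom[1] %in% names(chrom_lengths)) {
      end <- pmin(end, chrom_lengths[[g$chrom[1]]])
    }
    # merge sorted windows whose gap (start2 - end1) <= max_gap
    cluster <- cumsum(c(1, (start[-1] - cummax(end[-length(end)])) > max_gap))
    out <- lapply(split(seq_len(nrow(g)), cluster), function(idx) {
      mem <- g[idx, , drop = FALSE]
      lead_row <- order(mem$p, mem$pos,
                        if ("alt" %in% names(mem)) mem$alt else mem$id)[1]
      data.frame(
        trait = mem$trait[1], approach = mem$approach[1],
        chrom = mem$chrom[1],
        start = min(start[idx]), end = max(end[idx]),
        lead = mem$id[lead_row], lead_p = mem$p[lead_row],
        n_members = nrow(mem),
        members = I(list(mem$id)), stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$trait, out$approach, out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("locus_set", "data.frame")
  out
}

empty_locus_set <- function() {
  out <- data.frame(
    trait = character(0), approach = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), lead = character(0),
    lead_p = numeric(0), n_members = integer(0), stringsAsFactors = FALSE
  )
  out$members <- I(list())
  class(out) <- c("locus_set", "data.frame")
  out
}

#' Write loci as BED (0-based half-open) plus a JSON report
#'
#' @param loci a `locus_set`.
#' @param bed_path,json_path output paths (either may be NULL to skip).
#' @export
write_loci <- function(loci, bed_path = NULL, json_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = loci$chrom, start = loci$start - 1,
                      end = loci$end,
                      name = paste(loci$trait, loci$approach, loci$lead,
                                   sep = "|"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path)) {
    rep <- lapply(seq_len(nrow(loci)), function(i) {
      list(trait = loci$trait[i], approach = loci$approach[i],
           chrom = loci$chrom[i], start = loci$start[i], end = loci$end[i],
           lead = loci$lead[i], lead_p = loci$lead_p[i],
           n_members = loci$n_members[i], members = loci$members[[i]])
    })
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(loci)
}
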