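# Population DMR scan: per-CpG variability, 500-bp sliding window with
# subset elimination, the mean-Spearman consistency score, combined ranking,
# top-quantile selection and zero-bp merging.

#' Per-CpG methylation SD across the population
#'
#' Drops sites detected in fewer than `min_individuals` samples and returns
#' the standard deviation of methylation levels over the detecting samples.
#'
#' @param pm A `PopulationMatrix`.
#' @param min_individuals Minimum detected individuals (default 3).
#' @return data.table: `chrom`, `start`, `n_detected`, `sd` plus the row
#'   index `site_idx` into `pm`.
#' @export
per_cpg_sd <- function(pm, min_individuals = 3L) {
  det <- detection_mask(pm)
  nd <- rowSums(det)
  keep <- which(nd >= min_individuals)
  sds <- vapply(keep, function(i) stats::sd(pm$level[i, det[i, ]]),
                numeric(1))
  out <- data.table::data.table(pm$sites[keep], n_detected = nd[keep],
                                sd = sds, site_idx = keep)
  out[]
}

#' Sliding-window scan over retained CpGs
#'
#' One candidate window is anchored at every retained CpG, spanning all
#' retained CpGs within `[anchor, anchor + window)`. Windows with a single
#' CpG are discarded, as are windows whose CpG set is a subset of another
#' candidate's set. Because windows are contiguous runs over the sorted site
#' list, a window is a subset exactly when the previous anchor reaches the
#' same right edge.
#'
#' @param site_sd Result of [per_cpg_sd] (sorted by chrom, start).
#' @param window Window length in bp (default 500).
#' @return data.table of candidate windows: `chrom`, `start`, `end`
#'   (trimmed to the first/last CpG dinucleotide), `n_cpg`, and the
#'   half-open index range `first`/`last` into `site_sd`.
#' @export
scan_windows <- function(site_sd, window = 500L) {
  x <- site_sd[order(chrom, start)]
  res <- x[, {
    pos <- start
    n <- length(pos)
    # right edge: last site with pos < anchor + window
    j <- findInterval(pos + as.integer(window) - 1L, pos)
    keep <- (j - seq_len(n) + 1L) >= 2L          # >= 2 CpGs
    keep <- keep & c(TRUE, j[-1] > j[-n])        # subset elimination
    anchors <- which(keep)
    .(start = pos[anchors], end = pos[j[anchors]] + 2L,
      n_cpg = j[anchors] - anchors + 1L,
      first = anchors, last = j[anchors])
  }, by = chrom]
  # convert per-chrom indices to global row indices of the sorted table
  offs <- cumsum(c(0L, x[, .N, by = chrom]$N))
  grp <- match(res$chrom, x[, unique(chrom)])
  res[, `:=`(first = first + offs[grp], last = last + offs[grp])]
  res[]
}

#' Consistency score of a window
#'
#' For each individual covering at least two CpGs of the window, the
#' Spearman correlation between that individual's per-CpG methylation
#' levels and the average methylation profile across all individuals
#' (per-CpG mean over the individuals detected there) is computed; the
#' consistency is the mean of these correlations. Individuals whose
#' profile is constant (undefined rank correlation) are excluded; fewer
#' than two scorable individuals leave the window unscored (`NA`).
#'
#' Degenerate cases: an individual with a constant profile has no rank
#' correlation and is excluded; a constant consensus profile carries no
#' shape information and contributes a neutral correlation of zero.
#' Because each individual contributes to the consensus, the score of an
#' exchangeable (signal-free) window centers near `1/sqrt(m)` rather than
#' zero; `exclude_self = TRUE` compares each individual to the average of
#' the others instead, which is centered at zero under the null.
#'
#' @param levels Sites-by-individuals matrix of methylation levels for the
#'   window (`NA` where undetected).
#' @param exclude_self Leave the scored individual out of the consensus
#'   profile (default `FALSE`, matching the stated formula).
#' @return List with `consistency` (mean Spearman r, in \[-1, 1\]) and `m`
#'   (number of individuals covering the window).
#' @export
consistency_score <- function(levels, exclude_self = FALSE) {
  covering <- colSums(!is.na(levels)) >= 1L
  mean_profile <- rowMeans(levels, na.rm = TRUE)
  qualifying <- which(colSums(!is.na(levels)) >= 2L)
  rs <- vapply(qualifying, function(j) {
    prof <- if (exclude_self) {
      rowMeans(levels[, -j, drop = FALSE], na.rm = TRUE)
    } else mean_profile
    x <- levels[, j]
    ok <- is.finite(x) & is.finite(prof)
    if (sum(ok) < 2L) return(NA_real_)
    if (stats::sd(x[ok]) == 0) return(NA_real_)
    if (stats::sd(prof[ok]) == 0) return(0)
    stats::cor(rank(x[ok]), rank(prof[ok]))
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  list(
    consistency = if (length(rs) >= 2L) mean(rs) else NA_real_,
    m = sum(covering)
  )
}

#' Score candidate windows
#'
#' Attaches the mean per-CpG SD and the consistency score to every
#' candidate window; unscorable windows (fewer than two individuals with
#' two or more covered CpGs) are dropped.
#'
#' @param windows Result of [scan_windows].
#' @param site_sd Result of [per_cpg_sd] (same ordering).
#' @param pm The `PopulationMatrix` the sites came from.
#' @param exclude_self Passed to [consistency_score].
#' @return `windows` with `mean_sd`, `consistency` and `m` columns.
#' @export
score_windows <- function(windows, site_sd, pm, exclude_self = FALSE) {
  x <- site_sd[order(chrom, start)]
  ms <- numeric(nrow(windows))
  cons <- numeric(nrow(windows))
  m <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    rows <- windows$first[w]:windows$last[w]
    ms[w] <- mean(x$sd[rows])
    lv <- pm$level[x$site_idx[rows], , drop = FALSE]
    cs <- consistency_score(lv, exclude_self)
    cons[w] <- cs$consistency
    m[w] <- cs$m
  }
  out <- data.table::copy(windows)
  out[, `:=`(mean_sd = ms, consistency = cons, m = m)]
  out[!is.na(consistency)]
}

#' Rank scored windows and select final pDMRs
#'
#' The default combination rule scores each window as
#' `mean_sd * max(consistency, 0)` (anti-consistent windows are excluded
#' from ranking by truncation at zero). Windows are ranked by score
#' descending (ties broken by genomic coordinate), the top `quantile`
#' fraction is kept, windows with fewer than three CpGs are removed, and
#' the surviving intervals are merged into non-overlapping regions with a
#' zero-base-pair merge (overlapping or bookended intervals coalesce).
#'
#' @param scored Result of [score_windows].
#' @param quantile Fraction of windows to keep (typically 0.10, 0.20 or
#'   0.25).
#' @param score_rule `"product"` (default) or `"sd_rank"` (rank by mean SD
#'   alone among windows with consistency above `consistency_min`).
#' @param consistency_min Consistency threshold for `"sd_rank"`.
#' @param min_cpg Minimum CpGs per selected window (default 3).
#' @return List with `calls` (merged pDMR intervals with `n_windows`) and
#'   `selected` (the selected windows before merging, with `score`).
#' @export
rank_and_select <- function(scored, quantile = 0.10,
                            score_rule = c("product", "sd_rank"),
                            consistency_min = 0, min_cpg = 3L) {
  if (nrow(scored) == 0L) stop("no scored windows to select from")
  score_rule <- match.arg(score_rule)
  x <- data.table::copy(scored)
  if (score_rule == "product") {
    x[, score := mean_sd * pmax(consistency, 0)]
  } else {
    x[, score := ifelse(consistency > consistency_min, mean_sd, -Inf)]
  }
  data.table::setorder(x, -score, chrom, start)
  n_keep <- ceiling(quantile * nrow(x))
  sel <- x[seq_len(n_keep)]
  sel <- sel[n_cpg >= min_cpg]
  calls <- merge_zero_bp(sel[, .(chrom, start, end)])
  if (nrow(calls) > 0L && nrow(sel) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(calls), as_granges(sel[, .(chrom, start, end)])
    )
    nw <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(calls))
    calls[, n_windows := nw]
  }
  list(calls = calls, selected = sel)
}

#' Full pDMR scan pipeline
#'
#' Runs [per_cpg_sd], [scan_windows], [score_windows] and
#' [rank_and_select] on a population matrix.
#'
#' @param pm A `PopulationMatrix`.
#' @param min_individuals Minimum detected individuals per CpG (default 3).
#' @param window Window length in bp (default 500).
#' @param quantile Selection quantile (default 0.10).
#' @param ... Passed to [rank_and_select].
#' @return As [rank_and_select], plus `scored` (all scored windows).
#' @export
pdmr_scan <- function(pm, min_individuals = 3L, window = 500L,
                      quantile = 0.10, ...) {
  sds <- per_cpg_sd(pm, min_individuals)
  w <- scan_windows(sds, window)
  scored <- score_windows(w, sds, pm)
  out <- rank_and_select(scored, quantile, ...)
  out$scored <- scored
  out
}

#' Stratify pDMR calls by regional methylation level
#'
#' Partitions calls into lowly methylated (< `cut`) and highly methylated
#' (>= `cut`) by the coverage-weighted mean methylation over all detected
#' (site, individual) observations inside each call.
#'
#' @param calls pDMR interval table (`chrom`, `start`, `end`).
#' @param pm The `PopulationMatrix`.
#' @param cut Level cut point (default 0.5; the boundary value is "high").
#' @return `calls` with `mean_level` and `stratum` (`"low"`/`"high"`).
#' @export
stratify_by_level <- function(calls, pm, cut = 0.5) {
  out <- data.table::as.data.table(calls)
  meth <- round(pm$level * pm$cov)
  ml <- rep(NA_real_, nrow(out))
  site_dt <- pm$sites
  for (i in seq_len(nrow(out))) {
    rows <- which(site_dt$chrom == out$chrom[i] &
                    site_dt$start >= out$start[i] &
                    site_dt$start < out$end[i])
    if (length(rows) == 0L) next
    cv <- pm$cov[rows, , drop = FALSE]
    lv <- pm$level[rows, , drop = FALSE]
    ml[i] <- sum(meth[rows, , drop = FALSE], na.rm = TRUE) /
      sum(cv[!is.na(lv)])
  }
  out[, mean_level := ml]
  out[, stratum := ifelse(mean_level < cut, "low", "high")]
  out[]
}
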