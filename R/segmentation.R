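# Merged-tissue methylomes and UMR/LMR segmentation by the cutoff method.

#' Merge filtered samples of one tissue
#'
#' Pools read counts across samples per CpG unit, keeping only sites
#' detected in at least `min_individuals` samples (with the default of 3
#' and the two-reads-per-strand filter this guarantees at least 12-fold
#' pooled coverage per site).
#'
#' @param samples Named list of filtered CpG unit tables of one tissue.
#' @param min_individuals Minimum number of contributing samples per site.
#' @return data.table with pooled `meth`, `cov`, `level` and `n_samples`
#'   per site, sorted.
#' @export
merge_tissue <- function(samples, min_individuals = 3L) {
  pooled <- data.table::rbindlist(
    lapply(samples, function(u) u[cov > 0, .(chrom, start, meth, cov)])
  )
  out <- pooled[, .(meth = sum(meth), cov = sum(cov), n_samples = .N),
                by = .(chrom, start)]
  out <- out[n_samples >= min_individuals]
  out[, level := meth / cov]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Segment a merged methylome into UMRs and LMRs
#'
#' Maximal runs of consecutive retained CpGs whose pooled level is below
#' `meth_threshold` form candidate segments; runs with at least
#' `umr_min_cpg` CpGs are called unmethylated regions (UMR), runs with
#' `min_cpg` to `umr_min_cpg - 1` CpGs are low-methylated regions (LMR),
#' and smaller runs are discarded. Intervals span the first to last CpG
#' dinucleotide of the run.
#'
#' @param merged Result of [merge_tissue].
#' @param meth_threshold Methylation threshold (fraction, default 0.5).
#' @param min_cpg Minimum CpGs for an LMR (default 4).
#' @param umr_min_cpg Minimum CpGs for a UMR (default 30).
#' @return data.table of segments: `chrom`, `start`, `end`, `class`
#'   (`"UMR"`/`"LMR"`), `n_cpg`, `mean_meth`.
#' @export
segment_low_methylation <- function(merged, meth_threshold = 0.5,
                                    min_cpg = 4L, umr_min_cpg = 30L) {
  x <- merged[order(chrom, start)]
  low <- x$level < meth_threshold
  # run ids advance at chromosome changes and at non-low sites
  newrun <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)]) | !low
  run <- cumsum(newrun)
  x[, `:=`(low = low, run = run)]
  seg <- x[low == TRUE,
           .(chrom = chrom[1], start = start[1],
             end = start[.N] + 2L, n_cpg = .N,
             mean_meth = sum(meth) / sum(cov)),
           by = run][, run := NULL]
  x[, c("low", "run") := NULL]
  seg <- seg[n_cpg >= min_cpg]
  seg[, class := ifelse(n_cpg >= umr_min_cpg, "UMR", "LMR")]
  data.table::setcolorder(seg, c("chrom", "start", "end", "class",
                                 "n_cpg", "mean_meth"))
  seg[order(chrom, start)]
}

#' Fraction of regions in one set overlapping another
#'
#' @param set_a,set_b Interval tables (`chrom`, `start`, `end`).
#' @return List with `a_in_b` and `b_in_a`: the fraction of regions in each
#'   set overlapping at least 1 bp of the other (`NA` for an empty set).
#' @export
region_overlap_fraction <- function(set_a, set_b) {
  a <- data.table::as.data.table(set_a)
  b <- data.table::as.data.table(set_b)
  frac <- function(q, s) {
    if (nrow(q) == 0L) return(NA_real_)
    mean(overlaps_any(q, s))
  }
  list(a_in_b = frac(a, b), b_in_a = frac(b, a))
}
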