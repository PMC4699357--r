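# Site-level QC: strand concordance, blacklist removal, study-specific
# high-coverage blacklisting, SNP removal, autosome restriction.

#' Filter configuration
#'
#' @param min_reads_per_strand Minimum reads required on each strand
#'   (default 2).
#' @param max_strand_diff Maximum absolute forward/reverse methylation
#'   difference, in percentage points (default 20, inclusive boundary).
#' @param coverage_sd_multiplier Multiplier of the per-sample coverage SD in
#'   the study-specific high-coverage blacklist (default 1.5).
#' @param min_samples_flagged Number of samples in which a locus must exceed
#'   its sample's threshold to be blacklisted (default 2).
#' @param autosomes_only Drop non-autosomal chromosomes.
#' @param blacklist,snp_positions Interval tables (`chrom`, `start`, `end`,
#'   0-based half-open) of externally blacklisted regions and SNP positions;
#'   `NULL` to skip.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_reads_per_strand = 2L, max_strand_diff = 20,
                          coverage_sd_multiplier = 1.5,
                          min_samples_flagged = 2L, autosomes_only = TRUE,
                          blacklist = NULL, snp_positions = NULL) {
  if (min_reads_per_strand < 0 || coverage_sd_multiplier <= 0) {
    stop("thresholds must be positive")
  }
  if (max_strand_diff < 0 || max_strand_diff > 100) {
    stop("max_strand_diff must lie in [0, 100]")
  }
  structure(as.list(environment()), class = "filter_config")
}

#' Strand-concordance filter
#'
#' Keeps CpG units covered by at least `min_reads_per_strand` reads on each
#' strand with an absolute between-strand methylation difference of at most
#' `max_strand_diff` percentage points. Single-stranded units are removed.
#'
#' @param units CpG unit table from [pair_strands].
#' @param config A [filter_config].
#' @return The kept units.
#' @export
strand_concordance_filter <- function(units, config = filter_config()) {
  min_r <- config$min_reads_per_strand
  keep <- units$cov_fwd >= min_r & units$cov_rev >= min_r &
    !units$single_stranded &
    abs(units$level_fwd - units$level_rev) * 100 <=
      config$max_strand_diff + 1e-9
  units[keep & !is.na(keep)]
}

#' Study-specific high-coverage blacklist
#'
#' Flags loci covered more than the sample-specific mean coverage plus
#' `coverage_sd_multiplier` times the coverage SD in at least
#' `min_samples_flagged` samples. Statistics are computed on pooled
#' (both-strand) CpG-unit coverage of the unfiltered samples, so artifact
#' loci are assessed before any other filter can remove them.
#'
#' @param samples Named list of (unfiltered) CpG unit tables.
#' @param config A [filter_config].
#' @return data.table of flagged loci as dinucleotide intervals
#'   (`chrom`, `start`, `end`) plus the number of samples flagging each.
#' @export
study_blacklist <- function(samples, config = filter_config()) {
  if (length(samples) < 2L) stop("study blacklist requires >= 2 samples")
  flagged <- data.table::rbindlist(lapply(samples, function(u) {
    covd <- u[cov > 0]
    if (nrow(covd) < 2L) {
      stop("sample with fewer than 2 covered sites: coverage SD undefined")
    }
    thr <- mean(covd$cov) + config$coverage_sd_multiplier * stats::sd(covd$cov)
    covd[cov > thr, .(chrom, start)]
  }))
  if (nrow(flagged) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_samples = integer()))
  }
  out <- flagged[, .(n_samples = .N), by = .(chrom, start)]
  out <- out[n_samples >= config$min_samples_flagged]
  out[, end := start + 2L]
  data.table::setcolorder(out, c("chrom", "start", "end", "n_samples"))
  data.table::setkey(out, chrom, start)
  out[]
}

#' Remove CpG units overlapping intervals
#'
#' A unit is removed when either of its two cytosine positions (the
#' dinucleotide interval `[start, start + 2)`) overlaps any interval.
#'
#' @param units CpG unit table.
#' @param intervals Interval table (`chrom`, `start`, `end`), or `NULL`
#'   for identity.
#' @return The kept units.
#' @export
remove_intervals <- function(units, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L || nrow(units) == 0L) {
    return(units)
  }
  hit <- overlaps_any(units[, .(chrom, start, end = start + 2L)],
                      data.table::as.data.table(intervals))
  units[!hit]
}

autosome_chroms <- paste0("chr", 1:22)

#' Apply the full filter chain to one sample
#'
#' Rules are applied in order: strand concordance, external blacklist,
#' study-specific high-coverage blacklist, SNP removal, autosome
#' restriction. The report counts sites removed by each rule (in that
#' order), so the counts sum to input minus output.
#'
#' @param units CpG unit table for one sample.
#' @param config A [filter_config]; supply the cohort-level
#'   [study_blacklist] result via `study_blacklist_intervals`.
#' @param study_blacklist_intervals Interval table of study-flagged loci.
#' @return List with `units` (filtered) and `report` (named removal counts).
#' @export
apply_all_filters <- function(units, config = filter_config(),
                              study_blacklist_intervals = NULL) {
  n0 <- nrow(units)
  u <- strand_concordance_filter(units, config)
  n1 <- nrow(u)
  u <- remove_intervals(u, config$blacklist)
  n2 <- nrow(u)
  u <- remove_intervals(u, study_blacklist_intervals)
  n3 <- nrow(u)
  u <- remove_intervals(u, config$snp_positions)
  n4 <- nrow(u)
  if (isTRUE(config$autosomes_only)) u <- u[chrom %in% autosome_chroms]
  n5 <- nrow(u)
  report <- c(input = n0, strand = n0 - n1, blacklist = n1 - n2,
              study_blacklist = n2 - n3, snp = n3 - n4,
              non_autosome = n4 - n5, kept = n5)
  list(units = u, report = report)
}
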