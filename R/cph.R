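# CpH methylation: stringent calling, context breakdown, conversion
# efficiency, CpG proximity, highCpH-lowCpG classification and clustering.

#' Call methylated CpH sites across individuals
#'
#' A strand-specific CpH site is called methylated when its level is
#' strictly above `level_cutoff` at coverage of at least `min_coverage`
#' reads in at least `min_individuals` individuals — a stringent cutoff
#' that excludes random bisulfite-conversion artifacts.
#'
#' @param records_list Named list (per sample) of CHG/CHH cytosine-record
#'   tables (post SNP/blacklist filtering).
#' @param min_coverage Minimum reads per site per individual (default 4).
#' @param level_cutoff Methylation level that must be exceeded
#'   (default 0.5, strict).
#' @param min_individuals Minimum individuals meeting the cutoff
#'   (default 2).
#' @return data.table of called sites (`chrom`, `start`, `strand`,
#'   `context`, `tri`, `dinuc`, `tri_class`, `n_meth_ind`). `tri_class`
#'   is `CpHpG`/`CpHpH` (`unknown` without a trinucleotide); `dinuc` is
#'   `CpA`/`CpT`/`CpC`.
#' @export
call_methylated_cph <- function(records_list, min_coverage = 4L,
                                level_cutoff = 0.5, min_individuals = 2L) {
  per <- data.table::rbindlist(lapply(records_list, function(r) {
    x <- r[context %in% c("CHG", "CHH") & cov >= min_coverage &
             level > level_cutoff]
    x[, .(chrom, start, strand, context, tri)]
  }))
  if (nrow(per) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  strand = character(), context = character(),
                                  tri = character(), dinuc = character(),
                                  tri_class = character(),
                                  n_meth_ind = integer()))
  }
  out <- per[, .(context = context[1], tri = tri[1], n_meth_ind = .N),
             by = .(chrom, start, strand)]
  out <- out[n_meth_ind >= min_individuals]
  out[, dinuc := ifelse(is.na(tri) | nchar(tri) < 2, "unknown",
                        paste0("Cp", substr(tri, 2, 2)))]
  out[, tri_class := ifelse(is.na(tri) | nchar(tri) < 3, "unknown",
                            ifelse(substr(tri, 3, 3) == "G", "CpHpG",
                                   "CpHpH"))]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Bisulfite conversion efficiency from CpH reads
#'
#' Per sample: `100 * (1 - methylated CpH reads / total CpH reads)`.
#' Because genuine CpH methylation is rare in somatic tissue, this is
#' dominated by conversion failure.
#'
#' @param records_list Named list (per sample) of CHG/CHH record tables.
#' @return List with `per_sample` (named percentages) and `median`.
#' @export
conversion_efficiency <- function(records_list) {
  per <- vapply(records_list, function(r) {
    x <- r[context %in% c("CHG", "CHH")]
    tot <- sum(x$cov)
    if (tot == 0) stop("sample with zero CpH reads")
    100 * (1 - sum(x$meth) / tot)
  }, numeric(1))
  list(per_sample = per, median = stats::median(per))
}

#' Nearest detected CpG for each methylated CpH
#'
#' Finds the closest detected CpG by absolute distance (ties broken
#' downstream, i.e. toward the larger coordinate) and its methylation
#' level; chromosomes without CpGs yield missing distances.
#'
#' @param cph_calls Result of [call_methylated_cph].
#' @param cpg_sites data.table of detected CpGs with `chrom`, `start`,
#'   `level` (e.g. pooled levels of a merged methylome).
#' @return `cph_calls` with `nearest_dist`, `nearest_level`, plus a
#'   `summary` attribute: fraction of calls whose nearest CpG is >= 50 %
#'   methylated (overall, and restricted to distance <= 10 bp), and the
#'   mean distance.
#' @export
cph_cpg_proximity <- function(cph_calls, cpg_sites) {
  calls <- data.table::copy(cph_calls)
  calls[, `:=`(nearest_dist = NA_integer_, nearest_level = NA_real_)]
  cpg <- data.table::as.data.table(cpg_sites)[order(chrom, start)]
  for (ch in unique(calls$chrom)) {
    g <- cpg[chrom == ch]
    if (nrow(g) == 0L) next
    q <- calls[chrom == ch, start]
    i <- findInterval(q, g$start)            # last CpG with start <= q
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, nrow(g))
    d_lo <- abs(q - g$start[lo])
    d_hi <- abs(g$start[hi] - q)
    # ties go downstream (the larger coordinate)
    use_hi <- (i == 0L) | (d_hi <= d_lo)
    pick <- ifelse(use_hi, hi, lo)
    calls[chrom == ch, `:=`(
      nearest_dist = as.integer(ifelse(use_hi, d_hi, d_lo)),
      nearest_level = g$level[pick]
    )]
  }
  ok <- !is.na(calls$nearest_dist)
  near10 <- ok & calls$nearest_dist <= 10L
  data.table::setattr(calls, "summary", list(
    frac_nearest_meth = mean(calls$nearest_level[ok] >= 0.5),
    frac_nearest_meth_within10 = if (any(near10))
      mean(calls$nearest_level[near10] >= 0.5) else NA_real_,
    mean_dist = mean(calls$nearest_dist[ok])
  ))
  calls[]
}

#' Flag highCpH-lowCpG methylation
#'
#' A methylated CpH is `highCpH-lowCpG` when its nearest detected CpG
#' displays less than 50 % methylation (the boundary value 50 % is not
#' flagged).
#'
#' @param calls Result of [cph_cpg_proximity].
#' @return `calls` with a logical `flag_highcph` column.
#' @export
classify_high_cph_low_cpg <- function(calls) {
  out <- data.table::copy(calls)
  out[, flag_highcph := !is.na(nearest_level) & nearest_level < 0.5]
  out[]
}

#' Cluster flagged CpH sites within individuals
#'
#' A flagged site is clustered when at least `min_sites` flagged sites
#' (including itself) lie within `window` bp on either side in the same
#' individual.
#'
#' @param flagged data.table of per-individual flagged sites (`sample_id`,
#'   `chrom`, `start`).
#' @param window Half-window in bp (default 500).
#' @param min_sites Cluster size threshold (default 3).
#' @return `flagged` with a logical `clustered` column.
#' @export
cluster_cph <- function(flagged, window = 500L, min_sites = 3L) {
  x <- data.table::as.data.table(flagged)[order(sample_id, chrom, start)]
  x[, clustered := {
    pos <- start
    lo <- findInterval(pos - window - 1L, pos) + 1L
    hi <- findInterval(pos + window, pos)
    (hi - lo + 1L) >= min_sites
  }, by = .(sample_id, chrom)]
  x[]
}

#' Share of CpH in total cytosine methylation per individual
#'
#' `methylated CpHs / (methylated CpHs + CpGs with level > cutoff)`
#' computed per sample on its own records.
#'
#' @param records_list Named list of full cytosine-record tables.
#' @param min_coverage Coverage floor for CpH sites (default 4).
#' @param cutoff Methylation cutoff for both contexts (default 0.5,
#'   strict).
#' @return Named numeric vector of per-sample fractions.
#' @export
cph_methylation_share <- function(records_list, min_coverage = 4L,
                                  cutoff = 0.5) {
  vapply(records_list, function(r) {
    n_cph <- nrow(r[context %in% c("CHG", "CHH") & cov >= min_coverage &
                      level > cutoff])
    cg <- pair_strands(r)
    n_cpg <- nrow(cg[!is.na(level) & level > cutoff])
    if (n_cph + n_cpg == 0) return(NA_real_)
    n_cph / (n_cph + n_cpg)
  }, numeric(1))
}
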