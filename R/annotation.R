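# Genomic-feature annotation (CGI, genic, histone-mark bins) and
# fold-enrichment against a stated background.

#' Classify positions relative to CpG islands
#'
#' Precedence: island (overlapping a CGI) > shore (within 2 kb) > shelf
#' (within 2-4 kb) > open sea. North/south is assigned by the side of the
#' nearest CGI: north for positions upstream (lower coordinate), south for
#' downstream.
#'
#' @param sites data.table of positions (`chrom`, `start`; optionally
#'   `end` for regions, classified by their closest point to a CGI).
#' @param cgi Interval table of CpG islands (`chrom`, `start`, `end`).
#' @param shore_bp,shelf_bp Shore and shelf extents in bp (2000 each).
#' @return Character vector of classes: `"island"`, `"N_shore"`,
#'   `"S_shore"`, `"N_shelf"`, `"S_shelf"`, `"open_sea"`.
#' @export
classify_cgi <- function(sites, cgi, shore_bp = 2000L, shelf_bp = 2000L) {
  s <- data.table::as.data.table(sites)
  if (!"end" %in% names(s)) s <- s[, .(chrom, start, end = start + 1L)]
  out <- rep("open_sea", nrow(s))
  cg <- data.table::as.data.table(cgi)
  if (nrow(cg) == 0L) return(out)
  cg <- merge_zero_bp(cg)  # overlapping islands act as one
  for (ch in unique(s$chrom)) {
    g <- cg[chrom == ch]
    rows <- which(s$chrom == ch)
    if (nrow(g) == 0L) next
    # classify regions by their closest point; ties between flanking
    # islands resolve to the upstream island (site on its south side)
    qs <- s$start[rows]; qe <- s$end[rows]
    i <- findInterval(qs, g$start)
    left_end <- ifelse(i >= 1L, g$end[pmax(i, 1L)], -Inf)
    right_start <- ifelse(i < nrow(g), g$start[pmin(i + 1L, nrow(g))], Inf)
    island <- (i >= 1L & qs < left_end) | (qe > right_start)
    d_left <- qs - left_end + 1L       # bp separation from upstream island
    d_right <- right_start - qe + 1L   # bp separation from downstream one
    use_left <- d_left <= d_right
    d <- ifelse(use_left, d_left, d_right)
    side <- ifelse(use_left, "S", "N")
    cls <- rep("open_sea", length(rows))
    cls[d <= shore_bp] <- paste0(side, "_shore")[d <= shore_bp]
    shelf <- d > shore_bp & d <= shore_bp + shelf_bp
    cls[shelf] <- paste0(side, "_shelf")[shelf]
    cls[island] <- "island"
    out[rows] <- cls
  }
  out
}

genic_classes <- c("TSS1500", "TSS200", "UTR5", "exon1", "exon", "intron",
                   "UTR3", "intergenic")

#' Build genic feature intervals from a gene-model table
#'
#' @param genes data.table with `gene`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`, `exon_starts`, `exon_ends`
#'   (comma-separated, 0-based half-open).
#' @return Named list of interval tables, one per genic class (excluding
#'   intergenic).
#' @export
genic_feature_intervals <- function(genes) {
  g <- data.table::as.data.table(genes)
  feats <- stats::setNames(
    lapply(setdiff(genic_classes, "intergenic"), function(x) list()),
    setdiff(genic_classes, "intergenic"))
  for (i in seq_len(nrow(g))) {
    st <- as.integer(strsplit(g$exon_starts[i], ",")[[1]])
    en <- as.integer(strsplit(g$exon_ends[i], ",")[[1]])
    if (length(st) != length(en) || any(st >= en)) {
      stop("malformed exon bounds for gene ", g$gene[i])
    }
    fwd <- g$strand[i] == "+"
    tss <- if (fwd) g$tx_start[i] else g$tx_end[i]
    add <- function(cls, s, e) {
      s <- pmax(s, 0L)
      keep <- s < e
      if (any(keep)) {
        feats[[cls]][[length(feats[[cls]]) + 1L]] <<-
          data.table::data.table(chrom = g$chrom[i], start = s[keep],
                                 end = e[keep])
      }
    }
    if (fwd) {
      add("TSS200", tss - 200L, tss)
      add("TSS1500", tss - 1500L, tss - 200L)
    } else {
      add("TSS200", tss, tss + 200L)
      add("TSS1500", tss + 200L, tss + 1500L)
    }
    # UTRs: exonic sequence outside the CDS
    utr_left <- cbind(pmax(st, g$tx_start[i]), pmin(en, g$cds_start[i]))
    utr_right <- cbind(pmax(st, g$cds_end[i]), pmin(en, g$tx_end[i]))
    if (fwd) {
      add("UTR5", utr_left[, 1], utr_left[, 2])
      add("UTR3", utr_right[, 1], utr_right[, 2])
    } else {
      add("UTR5", utr_right[, 1], utr_right[, 2])
      add("UTR3", utr_left[, 1], utr_left[, 2])
    }
    # exon classes cover the coding portions; exonic sequence outside the
    # CDS belongs to the UTR classes, which precede or follow them
    first_exon <- if (fwd) 1L else length(st)
    add("exon1", pmax(st[first_exon], g$cds_start[i]),
        pmin(en[first_exon], g$cds_end[i]))
    rest <- setdiff(seq_along(st), first_exon)
    if (length(rest)) {
      add("exon", pmax(st[rest], g$cds_start[i]),
          pmin(en[rest], g$cds_end[i]))
    }
    if (length(st) > 1L) {
      add("intron", en[-length(en)], st[-1])
    }
  }
  lapply(feats, function(l) {
    if (length(l) == 0L) {
      data.table::data.table(chrom = character(), start = integer(),
                             end = integer())
    } else data.table::rbindlist(l)
  })
}

#' Classify positions relative to a gene model
#'
#' Assigns the first matching class in precedence order TSS1500, TSS200,
#' 5'UTR, exon 1, other exons, introns, 3'UTR, intergenic (TSS windows are
#' strand-aware upstream; multi-transcript overlaps resolve by the same
#' precedence across transcripts).
#'
#' @param sites data.table of positions (`chrom`, `start`, optional `end`).
#' @param genes Gene-model table (see [genic_feature_intervals]).
#' @return Character vector of genic classes.
#' @export
classify_genic <- function(sites, genes) {
  s <- data.table::as.data.table(sites)
  if (!"end" %in% names(s)) s[, end := start + 1L]
  feats <- genic_feature_intervals(genes)
  out <- rep("intergenic", nrow(s))
  unassigned <- rep(TRUE, nrow(s))
  for (cls in setdiff(genic_classes, "intergenic")) {
    hit <- overlaps_any(s, feats[[cls]])
    out[unassigned & hit] <- cls
    unassigned <- unassigned & !hit
  }
  out
}

#' Rank 100-bp ChIP bins per donor and take the reproducible top set
#'
#' Per donor, reads (as intervals; each read assigned to the bin holding
#' its midpoint) are counted in fixed genome bins, normalized to the
#' donor's total read count, and the same-donor normalized input signal is
#' subtracted. Bins are ranked by the subtracted signal (ties broken by
#' genomic coordinate); the top `top` fraction with strictly positive
#' signal is flagged per donor, and the final set keeps bins flagged in at
#' least `min_donors` donors.
#'
#' @param chip_reads,input_reads Named lists (per donor) of read interval
#'   tables (`chrom`, `start`, `end`).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin_width Bin size in bp (default 100).
#' @param top Top quantile per donor (default 0.01).
#' @param min_donors Reproducibility threshold (default 3).
#' @return List with `bins` (per-donor signal and top flags) and
#'   `top_bins` (interval table of the reproducible set with
#'   `n_donors`).
#' @export
rank_chip_bins <- function(chip_reads, input_reads, chrom_sizes,
                           bin_width = 100L, top = 0.01, min_donors = 3L) {
  stopifnot(length(chip_reads) == length(input_reads),
            length(chip_reads) >= min_donors)
  bins <- data.table::rbindlist(lapply(names(chrom_sizes), function(ch) {
    n <- ceiling(chrom_sizes[[ch]] / bin_width)
    data.table::data.table(chrom = ch,
                           start = (seq_len(n) - 1L) * bin_width,
                           end = pmin(seq_len(n) * bin_width,
                                      as.integer(chrom_sizes[[ch]])))
  }))
  bin_counts <- function(reads) {
    r <- data.table::as.data.table(reads)
    if (nrow(r) == 0L) stop("donor with zero reads")
    mid <- (r$start + r$end) %/% 2L
    bdt <- data.table::data.table(chrom = r$chrom,
                                  start = (mid %/% bin_width) * bin_width)
    cnt <- bdt[, .(n = .N), by = .(chrom, start)]
    v <- rep(0, nrow(bins))
    i <- bins[cnt, on = c("chrom", "start"), which = TRUE]
    v[i] <- cnt$n
    v / sum(v)  # normalize to the donor's total reads
  }
  donors <- names(chip_reads)
  if (is.null(donors)) donors <- paste0("D", seq_along(chip_reads))
  sig <- matrix(0, nrow(bins), length(donors),
                dimnames = list(NULL, donors))
  top_flag <- matrix(FALSE, nrow(bins), length(donors))
  n_top <- ceiling(top * nrow(bins))
  for (d in seq_along(donors)) {
    sig[, d] <- bin_counts(chip_reads[[d]]) - bin_counts(input_reads[[d]])
    ord <- order(-sig[, d], bins$chrom, bins$start)
    cand <- ord[seq_len(n_top)]
    top_flag[cand[sig[cand, d] > 0], d] <- TRUE
  }
  n_donors_top <- rowSums(top_flag)
  out_bins <- data.table::copy(bins)
  out_bins[, n_donors := n_donors_top]
  list(
    bins = cbind(out_bins, data.table::as.data.table(sig)),
    top_bins = out_bins[n_donors >= min_donors]
  )
}

#' Define promoter and enhancer bins from ranked histone-mark bins
#'
#' Promoters: H3K4me3 top bins within `tss_window` bp of any TSS.
#' Enhancers: H3K4me1 top bins, discarding any bin overlapping an H3K4me3
#' top bin.
#'
#' @param h3k4me3_bins,h3k4me1_bins Interval tables of top bins.
#' @param tss data.table of TSS positions (`chrom`, `start`).
#' @param tss_window Distance threshold in bp (default 1000).
#' @return List with `promoters` and `enhancers` interval tables.
#' @export
define_promoters_enhancers <- function(h3k4me3_bins, h3k4me1_bins, tss,
                                       tss_window = 1000L) {
  me3 <- data.table::as.data.table(h3k4me3_bins)
  me1 <- data.table::as.data.table(h3k4me1_bins)
  tssd <- data.table::as.data.table(tss)
  if (nrow(me3) > 0L && nrow(tssd) > 0L) {
    gr_b <- as_granges(me3)
    gr_t <- as_granges(tssd[, .(chrom, start, end = start + 1L)])
    dtn <- GenomicRanges::distanceToNearest(gr_b, gr_t)
    near <- rep(FALSE, nrow(me3))
    near[S4Vectors::queryHits(dtn)] <-
      S4Vectors::mcols(dtn)$distance <= tss_window
    promoters <- me3[near]
  } else {
    promoters <- me3[0]
  }
  enhancers <- me1[!overlaps_any(me1, me3)]
  list(promoters = promoters, enhancers = enhancers)
}

#' Fold enrichment of a query set in a feature versus background
#'
#' Fold change = (fraction of query items in the feature) / (fraction of
#' background items in the feature); the p-value is a two-sided Fisher
#' exact test on the in/out-of-feature by query/background 2x2 table.
#'
#' @param query_in_feature Logical vector over query items.
#' @param background_in_feature Logical vector over background items.
#' @return List with `fold`, `p`, and the underlying fractions.
#' @export
enrichment <- function(query_in_feature, background_in_feature) {
  qf <- mean(query_in_feature)
  bf <- mean(background_in_feature)
  tab <- matrix(c(sum(query_in_feature), sum(!query_in_feature),
                  sum(background_in_feature), sum(!background_in_feature)),
                nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  list(fold = if (bf > 0) qf / bf else NA_real_, p = p,
       query_fraction = qf, background_fraction = bf)
}
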