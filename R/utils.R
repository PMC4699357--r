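# Shared internal helpers: interval conversion and exact-test kernels.

#' Convert a BED-style table to GRanges
#'
#' Intervals are 0-based half-open on input and converted to the 1-based
#' closed convention of [GenomicRanges::GRanges].
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @return A `GRanges` object.
#' @keywords internal
#' @noRd
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Convert GRanges back to a BED-style data.table (0-based half-open)
#' @keywords internal
#' @noRd
as_bed_dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

#' Two-sided Fisher exact probability for 2x2 tables, vectorized
#'
#' Computes the two-sided Fisher exact probability for tables
#' \code{[meth, unmeth] x [A, B]} by the standard rule: the sum of
#' probabilities of all tables (with the observed margins) whose
#' hypergeometric probability does not exceed that of the observed table.
#' Agrees with [stats::fisher.test] on 2x2 tables.
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth integer vectors of cell counts.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_p_2x2(10, 0, 0, 10)   # strongly discordant counts
#' fisher_p_2x2(3, 1, 1, 3)
#' @export
fisher_p_2x2 <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  n <- length(a_meth)
  stopifnot(length(a_unmeth) == n, length(b_meth) == n, length(b_unmeth) == n)
  if (any(c(a_meth, a_unmeth, b_meth, b_unmeth) < 0)) {
    stop("counts must be non-negative")
  }
  out <- numeric(n)
  nA <- a_meth + a_unmeth
  nB <- b_meth + b_unmeth
  k <- a_meth + b_meth
  for (i in seq_len(n)) {
    lo <- max(0L, k[i] - nB[i])
    hi <- min(k[i], nA[i])
    x <- lo:hi
    pr <- stats::dhyper(x, nA[i], nB[i], k[i])
    p_obs <- pr[match(a_meth[i], x)]
    # relative tolerance mirrors fisher.test's handling of ties
    out[i] <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  pmin(out, 1)
}

#' Spearman rank correlation with average-rank ties
#'
#' Pearson correlation of average-tied ranks; returns NA when either vector
#' is constant.
#' @keywords internal
#' @noRd
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Merge intervals at zero base-pair distance
#'
#' Overlapping and bookended (end == next start) intervals are merged;
#' intervals separated by one or more bases are kept apart. Input and output
#' are 0-based half-open.
#'
#' @param x data.frame with `chrom`, `start`, `end`.
#' @return data.table of merged intervals, sorted.
#' @export
merge_zero_bp <- function(x) {
  x <- data.table::as.data.table(x)
  if (nrow(x) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = 1L)
  out <- as_bed_dt(gr)
  data.table::setkey(out, chrom, start)
  out[]
}

#' Does each query interval overlap any subject interval?
#' 0-based half-open on both sides.
#' @keywords internal
#' @noRd
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L) {
    return(rep(FALSE, nrow(query)))
  }
  # disjoint chromosome sets are a legitimate no-overlap case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  )
  out <- rep(FALSE, nrow(query))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Deterministic seed streams derived from one master seed
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483647L
}
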