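# Reading and writing the file formats the pipeline touches, and assembly of
# per-sample and population data structures.

#' Read a Bismark-style cytosine report
#'
#' The report is tab-separated with columns: chromosome, 1-based position of
#' the cytosine, strand (`+`/`-`), methylated read count, unmethylated read
#' count, context (`CG`/`CHG`/`CHH`) and trinucleotide. Positions are
#' converted to the package's internal 0-based convention. Gzipped files are
#' read transparently.
#'
#' @param path File path.
#' @return data.table with columns `chrom`, `start` (0-based), `strand`,
#'   `meth`, `unmeth`, `context`, `tri`, plus `cov` and `level`
#'   (`NA` where coverage is zero).
#' @export
read_cytosine_report <- function(path) {
  cols <- c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")
  if (file.exists(path) && file.size(path) == 0) return(empty_records())
  x <- tryCatch(
    data.table::fread(path, header = FALSE, col.names = cols,
                      colClasses = "character"),
    error = function(e) stop("malformed cytosine report '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(x) == 0L) return(empty_records())
  for (col in c("pos", "meth", "unmeth")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    if (anyNA(v)) {
      stop("malformed cytosine report '", path, "' at line ",
           which(is.na(v))[1], ": non-integer ", col)
    }
    data.table::set(x, j = col, value = v)
  }
  if (any(x$meth < 0 | x$unmeth < 0)) stop("negative counts in ", path)
  if (!all(x$strand %in% c("+", "-"))) stop("invalid strand field in ", path)
  out <- data.table::data.table(
    chrom = normalize_chrom(x$chrom),
    start = x$pos - 1L,
    strand = x$strand, context = x$context, tri = x$tri,
    meth = x$meth, unmeth = x$unmeth
  )
  # positions must be sorted within chromosome as emitted by callers
  if (any(out[, diff(start) < 0, by = chrom]$V1)) {
    stop("positions not monotone within chromosome in ", path)
  }
  finalize_records(out)
}

empty_records <- function() {
  finalize_records(data.table::data.table(
    chrom = character(), start = integer(), strand = character(),
    context = character(), tri = character(),
    meth = integer(), unmeth = integer()
  ))
}

finalize_records <- function(x) {
  x[, cov := meth + unmeth]
  x[, level := ifelse(cov > 0, meth / cov, NA_real_)]
  x[]
}

#' Write records as a cytosine report (1-based positions)
#'
#' @param records data.table as returned by [read_cytosine_report] (columns
#'   `chrom`, `start`, `strand`, `meth`, `unmeth`, `context`, `tri`).
#' @param path Output path; `.gz` suffix writes gzipped.
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.table::data.table(
    chrom = records$chrom, pos = records$start + 1L,
    strand = records$strand, meth = records$meth, unmeth = records$unmeth,
    context = records$context, tri = records$tri
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Normalize chromosome names to the "chr"-prefixed dialect
#' @keywords internal
#' @noRd
normalize_chrom <- function(x) {
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Pair forward- and reverse-strand CpG records into CpG units
#'
#' CG-context records at forward position `p` and reverse position `p + 1`
#' are combined into one unit anchored at `p`. Units missing one strand are
#' kept and flagged `single_stranded`; they fail the strand filter
#' downstream but are never silently dropped.
#'
#' @param records data.table of cytosine records (only `context == "CG"`
#'   rows are used).
#' @return data.table keyed by (`chrom`, `start`) with per-strand counts,
#'   pooled `meth`, `cov`, `level` and `single_stranded` flag.
#' @export
pair_strands <- function(records) {
  cg <- records[context == "CG"]
  fwd <- cg[strand == "+", .(chrom, start, meth_fwd = meth, unmeth_fwd = unmeth)]
  rev <- cg[strand == "-", .(chrom, start = start - 1L,
                             meth_rev = meth, unmeth_rev = unmeth)]
  if (anyDuplicated(fwd, by = c("chrom", "start")) ||
      anyDuplicated(rev, by = c("chrom", "start"))) {
    stop("duplicate CpG position in strand records")
  }
  units <- merge(fwd, rev, by = c("chrom", "start"), all = TRUE)
  for (col in c("meth_fwd", "unmeth_fwd", "meth_rev", "unmeth_rev")) {
    data.table::set(units, which(is.na(units[[col]])), col, 0L)
  }
  units[, `:=`(
    cov_fwd = meth_fwd + unmeth_fwd,
    cov_rev = meth_rev + unmeth_rev
  )]
  units[, single_stranded := cov_fwd == 0L | cov_rev == 0L]
  units[, `:=`(
    meth = meth_fwd + meth_rev,
    cov = cov_fwd + cov_rev
  )]
  units[, level := ifelse(cov > 0, meth / cov, NA_real_)]
  units[, `:=`(
    level_fwd = ifelse(cov_fwd > 0, meth_fwd / cov_fwd, NA_real_),
    level_rev = ifelse(cov_rev > 0, meth_rev / cov_rev, NA_real_)
  )]
  data.table::setkey(units, chrom, start)
  units[]
}

#' Read a BED file (BED3+)
#'
#' BED is 0-based half-open; intervals are returned as given (no merging).
#'
#' @param path File path.
#' @return data.table with `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  x <- data.table::fread(path, header = FALSE)
  if (nrow(x) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(x, nm[seq_len(min(ncol(x), 6L))])
  x[, chrom := normalize_chrom(chrom)]
  if (any(x$start >= x$end)) stop("BED interval with start >= end in ", path)
  x[]
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @param sort Sort by (chrom, start) before writing.
#' @export
write_bed <- function(intervals, path, sort = FALSE) {
  x <- data.table::as.data.table(intervals)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  x <- x[, ..keep]
  if (sort && nrow(x)) x <- x[order(chrom, start)]
  data.table::fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export CpG units as bedGraph (chrom, start, end, level)
#'
#' @param units CpG unit table from [pair_strands].
#' @param path Output path.
#' @export
export_bedgraph <- function(units, path) {
  x <- units[!is.na(level),
             .(chrom, start, end = start + 2L, level = round(level, 6))]
  data.table::fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assemble a population matrix from filtered samples
#'
#' Builds site-by-sample methylation-level and coverage matrices over the
#' union of sites, keeping sites detected (covered) in at least
#' `min_detected` samples.
#'
#' @param samples Named list of CpG unit tables (one per sample, already
#'   filtered).
#' @param min_detected Minimum number of samples a site must be detected in.
#' @return An object of class `PopulationMatrix`: a list with `sites`
#'   (data.table `chrom`, `start`), `level` and `cov` matrices
#'   (sites x samples, `NA`/0 where undetected) and `samples`.
#' @export
build_population_matrix <- function(samples, min_detected = 2L) {
  if (min_detected < 1L) stop("min_detected must be >= 1")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("S", seq_along(samples))
  }
  all_sites <- unique(data.table::rbindlist(
    lapply(samples, function(u) u[, .(chrom, start)])
  ))
  data.table::setkey(all_sites, chrom, start)
  n <- nrow(all_sites)
  m <- length(samples)
  lev <- matrix(NA_real_, n, m, dimnames = list(NULL, names(samples)))
  cv <- matrix(0L, n, m, dimnames = list(NULL, names(samples)))
  for (j in seq_len(m)) {
    u <- samples[[j]]
    i <- all_sites[u[, .(chrom, start)], on = c("chrom", "start"), which = TRUE]
    lev[i, j] <- u$level
    cv[i, j] <- u$cov
  }
  detected <- !is.na(lev) & cv > 0L
  keep_rows <- rowSums(detected) >= min_detected
  out <- list(
    sites = all_sites[keep_rows],
    level = lev[keep_rows, , drop = FALSE],
    cov = cv[keep_rows, , drop = FALSE],
    samples = names(samples)
  )
  class(out) <- "PopulationMatrix"
  out
}

#' @export
print.PopulationMatrix <- function(x, ...) {
  cat("PopulationMatrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Detection mask of a population matrix
#'
#' @param pm A `PopulationMatrix`.
#' @return Logical sites-by-samples matrix; `TRUE` where the site was
#'   detected (covered post-filtering) in that sample.
#' @export
detection_mask <- function(pm) {
  !is.na(pm$level) & pm$cov > 0L
}

#' Subset a population matrix by site index or sample names
#' @param pm A `PopulationMatrix`.
#' @param sites Integer/logical row index (default: all).
#' @param samples Character or integer column selector (default: all).
#' @export
subset_population_matrix <- function(pm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(pm$sites))
  if (is.null(samples)) samples <- pm$samples
  out <- list(
    sites = pm$sites[sites],
    level = pm$level[sites, samples, drop = FALSE],
    cov = pm$cov[sites, samples, drop = FALSE],
    samples = colnames(pm$level[, samples, drop = FALSE])
  )
  class(out) <- "PopulationMatrix"
  out
}
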