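library(data.table)

# Build a CpG unit table from per-strand counts, the way pair_strands would.
make_units <- function(start, meth_fwd, unmeth_fwd, meth_rev, unmeth_rev,
                       chrom = "chr1") {
  rec <- rbindlist(list(
    data.table(chrom = chrom, start = start, strand = "+", context = "CG",
               tri = "CGA", meth = as.integer(meth_fwd),
               unmeth = as.integer(unmeth_fwd)),
    data.table(chrom = chrom, start = start + 1L, strand = "-",
               context = "CG", tri = "CGA", meth = as.integer(meth_rev),
               unmeth = as.integer(unmeth_rev))
  ))
  rec[, `:=`(cov = meth + unmeth,
             level = ifelse(meth + unmeth > 0, meth / (meth + unmeth),
                            NA_real_))]
  pair_strands(rec)
}

# Build a PopulationMatrix directly from level and coverage matrices.
make_pm <- function(level, cov, start = NULL, chrom = "chr1") {
  if (is.null(start)) start <- seq_len(nrow(level)) * 100L
  if (is.null(colnames(level))) {
    colnames(level) <- paste0("S", seq_len(ncol(level)))
  }
  colnames(cov) <- colnames(level)
  out <- list(sites = data.table(chrom = chrom, start = as.integer(start)),
              level = level, cov = cov, samples = colnames(level))
  class(out) <- "PopulationMatrix"
  out
}

# PopulationMatrix from integer methylated counts and coverages.
make_pm_counts <- function(meth, cov, ...) {
  level <- ifelse(cov > 0, meth / cov, NA_real_)
  make_pm(level, cov, ...)
}

# Independent two-sided Fisher probability via explicit choose() enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; n <- n1 + n2
  x <- max(0, k - n2):min(k, n1)
  pr <- choose(n1, x) * choose(n2, k - x) / choose(n, k)
  p_obs <- pr[match(a, x)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Independent Spearman via explicit average ranks + Pearson moment formula.
# Mirrors the scoring conventions: a constant individual profile is
# undefined (NA, excluded); a constant consensus profile is neutral (0).
oracle_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (length(unique(rx)) == 1) return(NA_real_)
  if (length(unique(ry)) == 1) return(0)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force pDMR pipeline used as the oracle for the window scan.
oracle_pdmr <- function(pm, min_individuals = 3L, window = 500L,
                        quantile = 0.10, min_cpg = 3L) {
  det <- !is.na(pm$level) & pm$cov > 0
  nd <- rowSums(det)
  keep <- which(nd >= min_individuals)
  pos <- pm$sites$start[keep]
  sds <- sapply(keep, function(i) sd(pm$level[i, det[i, ]]))
  n <- length(pos)
  # candidate windows anchored at every retained CpG
  sets <- lapply(seq_len(n), function(i) {
    which(pos >= pos[i] & pos < pos[i] + window)
  })
  ok <- vapply(sets, length, 1L) >= 2L
  # subset elimination, O(n^2) on index sets
  for (i in which(ok)) {
    for (j in seq_len(n)) {
      if (i != j && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[j]]) > length(sets[[i]])) {
        ok[i] <- FALSE
        break
      }
    }
  }
  rows <- list()
  for (i in which(ok)) {
    s <- sets[[i]]
    lv <- pm$level[keep[s], , drop = FALSE]
    prof <- rowMeans(lv, na.rm = TRUE)
    rs <- c()
    for (j in seq_len(ncol(lv))) {
      if (sum(!is.na(lv[, j])) >= 2) {
        r <- oracle_spearman(lv[, j], prof)
        if (!is.na(r)) rs <- c(rs, r)
      }
    }
    if (length(rs) < 2) next
    rows[[length(rows) + 1]] <- data.table(
      start = pos[s[1]], end = pos[s[length(s)]] + 2L,
      n_cpg = length(s), mean_sd = mean(sds[s]), consistency = mean(rs)
    )
  }
  scored <- rbindlist(rows)
  scored[, score := mean_sd * pmax(consistency, 0)]
  setorder(scored, -score, start)
  sel <- scored[seq_len(ceiling(quantile * nrow(scored)))]
  sel <- sel[n_cpg >= min_cpg]
  list(scored = scored[order(start)], selected = sel)
}

# One-way ICC(1,1) through aov mean squares (independent of popmeth::icc).
oracle_icc <- function(x1, x2) {
  g <- factor(rep(seq_along(x1), 2))
  fit <- summary(aov(c(x1, x2) ~ g))[[1]]
  msb <- fit["g", "Mean Sq"]
  msw <- fit["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# Small deterministic gene model for annotation tests: one + strand gene and
# one - strand gene with two exons each.
toy_genes <- function() {
  data.table(
    gene = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 50000L),
    tx_end = c(16000L, 56000L),
    cds_start = c(10500L, 50500L),
    cds_end = c(15500L, 55500L),
    exon_starts = c("10000,12000", "50000,54000"),
    exon_ends = c("11000,16000", "51000,56000")
  )
}
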