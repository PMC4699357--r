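# Twin-based variance decomposition, within-MZ-pair environmental DMC/DMR
# detection with permutation FDR, and inter-tissue drift concordance.

#' One-way random-effects intra-class correlation, ICC(1,1)
#'
#' Mean-squares form for paired data (k = 2 members per group):
#' `(MSB - MSW) / (MSB + MSW)`.
#'
#' @param x1,x2 Values of member 1 and member 2 across pairs (equal
#'   length; incomplete pairs are dropped).
#' @return The ICC, or `NA` when fewer than two complete pairs remain or
#'   total variance is zero.
#' @export
icc <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2L) return(NA_real_)
  grand <- mean(c(x1, x2))
  pm <- (x1 + x2) / 2
  msb <- 2 * sum((pm - grand)^2) / (n - 1)
  msw <- sum((x1 - pm)^2 + (x2 - pm)^2) / n
  if (msb + msw == 0) return(NA_real_)
  (msb - msw) / (msb + msw)
}

#' Twin ACE variance decomposition from MZ and DZ ICCs
#'
#' Falconer-style estimates per site: heritability
#' `h2 = 2 * (ICC_MZ - ICC_DZ)`, shared environment `c2 = ICC_MZ - h2`,
#' non-shared environment `e2 = 1 - ICC_MZ`. Raw (unclamped) estimates are
#' returned together with a clamped convenience view (components truncated
#' to \[0, 1\] and renormalized to sum 1).
#'
#' @param levels Sites-by-individuals matrix of methylation levels
#'   (`NA` where undetected). Columns must align with `metadata` rows.
#' @param metadata data.frame with `pair_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   `member` (1/2) per column of `levels`.
#' @param min_pairs Minimum complete MZ and DZ pairs per site (default 5).
#' @param sites Optional site table (one row per matrix row) carried
#'   through to the output.
#' @return List with `decomposition` (per-site ICCs, raw and clamped
#'   h2/c2/e2, pair counts) and `summary` (fractions with h2 > 0.3,
#'   c2 > 0.3, e2 > 0.9, on the clamped view).
#' @export
ace_decompose <- function(levels, metadata, min_pairs = 5L, sites = NULL) {
  md <- data.table::as.data.table(metadata)
  stopifnot(nrow(md) == ncol(levels))
  pair_cols <- function(zyg) {
    p <- md[zygosity %in% zyg & !is.na(pair_id)]
    ids <- unique(p$pair_id)
    m1 <- vapply(ids, function(id) which(md$pair_id == id & md$member == 1L)[1],
                 integer(1))
    m2 <- vapply(ids, function(id) which(md$pair_id == id & md$member == 2L)[1],
                 integer(1))
    ok <- !is.na(m1) & !is.na(m2)
    list(m1 = m1[ok], m2 = m2[ok])
  }
  mz <- pair_cols("MZ")
  dz <- pair_cols("DZ")
  n <- nrow(levels)
  icc_mz <- rep(NA_real_, n); icc_dz <- rep(NA_real_, n)
  n_mz <- integer(n); n_dz <- integer(n)
  for (i in seq_len(n)) {
    a1 <- levels[i, mz$m1]; a2 <- levels[i, mz$m2]
    b1 <- levels[i, dz$m1]; b2 <- levels[i, dz$m2]
    n_mz[i] <- sum(is.finite(a1) & is.finite(a2))
    n_dz[i] <- sum(is.finite(b1) & is.finite(b2))
    if (n_mz[i] >= min_pairs && n_dz[i] >= min_pairs) {
      icc_mz[i] <- icc(a1, a2)
      icc_dz[i] <- icc(b1, b2)
    }
  }
  h2 <- 2 * (icc_mz - icc_dz)
  c2 <- icc_mz - h2
  e2 <- 1 - icc_mz
  cl <- clamp_ace(h2, c2, e2)
  dec <- data.table::data.table(
    icc_mz = icc_mz, icc_dz = icc_dz,
    h2 = h2, c2 = c2, e2 = e2,
    h2_clamped = cl$h2, c2_clamped = cl$c2, e2_clamped = cl$e2,
    n_mz_pairs = n_mz, n_dz_pairs = n_dz
  )
  if (!is.null(sites)) dec <- cbind(data.table::as.data.table(sites), dec)
  ok <- !is.na(dec$h2)
  list(
    decomposition = dec,
    summary = list(
      n_sites = sum(ok),
      frac_h2_gt_0.3 = mean(dec$h2_clamped[ok] > 0.3),
      frac_c2_gt_0.3 = mean(dec$c2_clamped[ok] > 0.3),
      frac_e2_gt_0.9 = mean(dec$e2_clamped[ok] > 0.9)
    )
  )
}

clamp_ace <- function(h2, c2, e2) {
  m <- cbind(pmin(pmax(h2, 0), 1), pmin(pmax(c2, 0), 1), pmin(pmax(e2, 0), 1))
  s <- rowSums(m)
  s[s == 0] <- NA_real_
  list(h2 = m[, 1] / s, c2 = m[, 2] / s, e2 = m[, 3] / s)
}

#' Within-pair differential CpGs (eDMCs) for one MZ pair
#'
#' Fisher's exact test per shared covered site between the two co-twins;
#' sites with `p < alpha` are eDMCs, with the direction of the difference
#' recorded (+1 when co-twin 1 is higher).
#'
#' @param units_a,units_b Filtered CpG unit tables of co-twin 1 and
#'   co-twin 2.
#' @param alpha Significance level (default 0.05).
#' @return data.table of shared sites with `p`, `delta`, `direction` and
#'   `edmc` flag.
#' @export
call_edmc <- function(units_a, units_b, alpha = 0.05) {
  key <- c("chrom", "start")
  a <- units_a[cov > 0, .(chrom, start, meth_a = meth, cov_a = cov)]
  b <- units_b[cov > 0, .(chrom, start, meth_b = meth, cov_b = cov)]
  x <- merge(a, b, by = key)
  res <- fisher_dmc(x$meth_a, x$cov_a - x$meth_a,
                    x$meth_b, x$cov_b - x$meth_b)
  out <- cbind(x[, ..key], res)
  out[, edmc := !is.na(p) & p < alpha & direction != 0]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Call environmental DMRs (eDMRs) from directional eDMCs
#'
#' Screens a `flank`-bp window up- and downstream of every eDMC; a window
#' containing three or more eDMCs, all sharing one direction, is an eDMR
#' candidate spanning its first to last eDMC. Overlapping candidates with
#' matching direction are merged.
#'
#' @param edmcs data.table with `chrom`, `start`, `direction` of
#'   significant eDMCs (one pair, one tissue).
#' @param flank Flank size in bp (default 500).
#' @param min_edmc Minimum unidirectional eDMCs per region (default 3).
#' @return data.table of merged eDMRs: `chrom`, `start`, `end`,
#'   `direction`, `n_edmc` (eDMCs inside the merged region).
#' @export
call_edmr <- function(edmcs, flank = 500L, min_edmc = 3L) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), direction = integer(),
                                  n_edmc = integer())
  x <- data.table::as.data.table(edmcs)[order(chrom, start)]
  if (nrow(x) == 0L) return(empty)
  cand <- x[, {
    pos <- start
    dir <- direction
    n <- length(pos)
    lo <- findInterval(pos - flank - 1L, pos) + 1L   # first eDMC >= pos-flank
    hi <- findInterval(pos + flank, pos)             # last eDMC <= pos+flank
    ok <- logical(n)
    s <- integer(n); e <- integer(n)
    for (i in seq_len(n)) {
      d <- dir[lo[i]:hi[i]]
      if (length(d) >= min_edmc && length(unique(d)) == 1L) {
        ok[i] <- TRUE
        s[i] <- pos[lo[i]]
        e[i] <- pos[hi[i]] + 2L
      }
    }
    .(start = s[ok], end = e[ok], direction = dir[ok])
  }, by = chrom]
  if (nrow(cand) == 0L) return(empty)
  out <- cand[, {
    merged <- merge_zero_bp(.SD[, .(chrom = "x", start, end)])
    .(start = merged$start, end = merged$end)
  }, by = .(chrom, direction)]
  x_pos <- x[, .(chrom, start, direction)]
  out[, n_edmc := {
    mapply(function(ch, s, e, d) {
      x_pos[chrom == ch & start >= s & start < e & direction == d, .N]
    }, chrom, start, end, direction)
  }]
  data.table::setcolorder(out, c("chrom", "start", "end", "direction",
                                 "n_edmc"))
  out[order(chrom, start)]
}

#' Permutation FDR for eDMR calls
#'
#' The observed eDMCs (count and direction mix preserved, per chromosome
#' by default) are reassigned uniformly at random among all tested site
#' positions; eDMRs are re-called on each permutation. The FDR estimate is
#' the mean permuted fraction of eDMCs falling inside eDMRs divided by the
#' observed fraction (capped at 1). This null preserves the tested-site
#' density, the key driver of spurious clusters.
#'
#' @param edmcs Significant eDMC table (`chrom`, `start`, `direction`).
#' @param tested_sites All tested site positions (`chrom`, `start`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @param flank,min_edmc Passed to [call_edmr].
#' @param within_chrom Permute within chromosome (default) or genome-wide.
#' @return List with `fdr` (capped), `fdr_raw`, `observed_fraction`,
#'   `null_fractions`.
#' @export
edmr_permutation_fdr <- function(edmcs, tested_sites, n_perm = 1000L,
                                 seed = 1L, flank = 500L, min_edmc = 3L,
                                 within_chrom = TRUE) {
  x <- data.table::as.data.table(edmcs)
  sites <- data.table::as.data.table(tested_sites)
  obs <- call_edmr(x, flank, min_edmc)
  f_obs <- fraction_in_regions(x, obs)
  if (is.na(f_obs) || f_obs == 0) {
    stop("observed eDMC-in-eDMR fraction is zero; FDR undefined")
  }
  set.seed(derive_seed(seed, 97L))
  nulls <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (within_chrom) {
      perm <- x[, {
        pool <- sites[chrom == .BY$chrom, start]
        .(start = pool[sample.int(length(pool), .N)],
          direction = direction)
      }, by = chrom]
    } else {
      idx <- sample.int(nrow(sites), nrow(x))
      perm <- data.table::data.table(chrom = sites$chrom[idx],
                                     start = sites$start[idx],
                                     direction = x$direction)
    }
    null_regions <- call_edmr(perm, flank, min_edmc)
    f <- fraction_in_regions(perm, null_regions)
    nulls[b] <- if (is.na(f)) 0 else f
  }
  raw <- mean(nulls) / f_obs
  list(fdr = min(raw, 1), fdr_raw = raw, observed_fraction = f_obs,
       null_fractions = nulls)
}

fraction_in_regions <- function(edmcs, regions) {
  if (nrow(edmcs) == 0L) return(NA_real_)
  if (nrow(regions) == 0L) return(0)
  mean(overlaps_any(edmcs[, .(chrom, start, end = start + 1L)],
                    regions[, .(chrom, start, end)]))
}

#' Two-sided exact binomial test probability
#'
#' Sum of binomial outcome probabilities not exceeding that of the
#' observed count (the rule used by [stats::binom.test]); at `p0 = 0.5`
#' this is the symmetric two-tailed probability.
#'
#' @param k Successes. @param n Trials. @param p0 Null probability.
#' @return The two-sided p-value.
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n < 1L || k < 0L || k > n) stop("require 0 <= k <= n, n >= 1")
  stats::binom.test(k, n, p0)$p.value
}

#' Inter-tissue epigenetic drift concordance analysis
#'
#' For two MZ pairs measured in two tissues: (1) restrict to sites covered
#' in all four samples of both tissues; (2) keep the top 50 % of sites by
#' the between-pair/within-pair variance ratio of methylation levels in
#' the reference tissue (enriching for genetically driven sites);
#' (3) exclude eDMCs of either tissue; (4) pool read counts within
#' pair-by-tissue; (5) Fisher-test pair 1 versus pair 2 per tissue;
#' (6) among sites significant in both tissues, count those with the same
#' direction of effect and test the count against 0.5 with a two-sided
#' exact binomial test.
#'
#' @param tissue_units Named list (per tissue) of named lists (4 samples:
#'   `p1m1`, `p1m2`, `p2m1`, `p2m2`) of filtered CpG unit tables.
#' @param ref_tissue Name of the reference tissue for the variance-ratio
#'   selection (default: first).
#' @param exclude_edmc Optional table (`chrom`, `start`) of eDMC positions
#'   (either tissue) to exclude.
#' @param top_fraction Fraction of sites kept by variance ratio
#'   (default 0.5).
#' @param alpha Fisher significance level (default 0.05).
#' @return List with `n_candidate`, `n_significant_both`, `n_concordant`,
#'   `concordant_fraction`, `binomial_p` and the per-site table.
#' @export
drift_analysis <- function(tissue_units, ref_tissue = names(tissue_units)[1],
                           exclude_edmc = NULL, top_fraction = 0.5,
                           alpha = 0.05) {
  key <- c("chrom", "start")
  stopifnot(length(tissue_units) == 2L)
  roles <- c("p1m1", "p1m2", "p2m1", "p2m2")
  # shared covered sites across all eight samples
  tabs <- list()
  shared <- NULL
  for (t in names(tissue_units)) {
    stopifnot(all(roles %in% names(tissue_units[[t]])))
    for (r in roles) {
      u <- tissue_units[[t]][[r]][cov > 0, .(chrom, start, meth, cov, level)]
      data.table::setnames(u, c("meth", "cov", "level"),
                           paste0(c("meth_", "cov_", "level_"), t, "_", r))
      tabs[[paste(t, r)]] <- u
      shared <- if (is.null(shared)) u[, ..key] else
        merge(shared, u[, ..key], by = key)
    }
  }
  x <- shared
  for (u in tabs) x <- merge(x, u, by = key)
  if (!is.null(exclude_edmc) && nrow(exclude_edmc) > 0L) {
    x <- x[!data.table::as.data.table(exclude_edmc)[, ..key], on = key]
  }
  empty <- list(n_candidate = nrow(x), n_significant_both = 0L,
                n_concordant = 0L, concordant_fraction = NA_real_,
                binomial_p = NA_real_, sites = x)
  if (nrow(x) < 2L) return(empty)

  # variance-ratio selection in the reference tissue
  lv <- as.matrix(x[, paste0("level_", ref_tissue, "_", roles), with = FALSE])
  pair_means <- cbind((lv[, 1] + lv[, 2]) / 2, (lv[, 3] + lv[, 4]) / 2)
  between <- (pair_means[, 1] - pair_means[, 2])^2 / 2
  within <- ((lv[, 1] - lv[, 2])^2 + (lv[, 3] - lv[, 4])^2) / 4
  ratio <- between / pmax(within, 1e-12)
  keep <- ratio >= stats::quantile(ratio, 1 - top_fraction)
  x <- x[keep]
  if (nrow(x) < 2L) return(empty)

  # pool within pair x tissue, Fisher pair 1 vs pair 2 per tissue
  res <- list()
  for (t in names(tissue_units)) {
    m1 <- x[[paste0("meth_", t, "_p1m1")]] + x[[paste0("meth_", t, "_p1m2")]]
    c1 <- x[[paste0("cov_", t, "_p1m1")]] + x[[paste0("cov_", t, "_p1m2")]]
    m2 <- x[[paste0("meth_", t, "_p2m1")]] + x[[paste0("meth_", t, "_p2m2")]]
    c2 <- x[[paste0("cov_", t, "_p2m1")]] + x[[paste0("cov_", t, "_p2m2")]]
    r <- fisher_dmc(m1, c1 - m1, m2, c2 - m2)
    res[[t]] <- r
    x[, paste0("p_", t) := r$p]
    x[, paste0("dir_", t) := r$direction]
  }
  t1 <- names(tissue_units)[1]; t2 <- names(tissue_units)[2]
  sig <- !is.na(x[[paste0("p_", t1)]]) & x[[paste0("p_", t1)]] < alpha &
    !is.na(x[[paste0("p_", t2)]]) & x[[paste0("p_", t2)]] < alpha &
    x[[paste0("dir_", t1)]] != 0 & x[[paste0("dir_", t2)]] != 0
  n_sig <- sum(sig)
  conc <- sum(x[[paste0("dir_", t1)]][sig] == x[[paste0("dir_", t2)]][sig])
  list(
    n_candidate = nrow(x),
    n_significant_both = n_sig,
    n_concordant = conc,
    concordant_fraction = if (n_sig > 0) conc / n_sig else NA_real_,
    binomial_p = if (n_sig > 0) exact_binomial_two_sided(conc, n_sig)
                 else NA_real_,
    sites = x
  )
}
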