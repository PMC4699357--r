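# Invariable CpGs, pairwise differential CpGs (pDMCs) and confounder checks.

#' Call invariable CpGs
#'
#' A site is invariable when it is detected in at least `min_detected`
#' samples and every detected pooled methylation level is identical.
#' Equality is tested exactly on the count fractions (cross-multiplied
#' integer counts), not on floating-point levels. The constant level
#' classifies the site: `unmethylated` (0 %), `fully_methylated` (100 %)
#' or `other_constant`.
#'
#' @param pm A `PopulationMatrix` (one tissue).
#' @param min_detected Minimum detected samples (typically 2, 5 or 10).
#' @return data.table of invariable sites with `n_detected`, `level`,
#'   `class`.
#' @export
call_invariable <- function(pm, min_detected = 2L) {
  det <- detection_mask(pm)
  nd <- rowSums(det)
  cand <- which(nd >= min_detected)
  if (length(cand) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  n_detected = integer(), level = numeric(),
                                  class = character()))
  }
  meth <- round(pm$level * pm$cov)  # pooled methylated counts
  inv <- vapply(cand, function(i) {
    j <- which(det[i, ])
    m <- meth[i, j]; cv <- pm$cov[i, j]
    # exact rational equality: m1/c1 == mk/ck  <=>  m1*ck == mk*c1
    all(m[1] * cv == m * cv[1])
  }, logical(1))
  idx <- cand[inv]
  lev <- vapply(idx, function(i) {
    j <- which(det[i, ])[1]
    pm$level[i, j]
  }, numeric(1))
  cls <- ifelse(lev == 0, "unmethylated",
                ifelse(lev == 1, "fully_methylated", "other_constant"))
  out <- data.table::data.table(pm$sites[idx], n_detected = nd[idx],
                                level = lev, class = cls)
  out[]
}

#' Tissue status of invariable sites
#'
#' Compares invariability across two tissues: a site invariable in one
#' tissue is `shared` when its methylation SD is zero in both tissues (and
#' it is sufficiently detected in both), otherwise tissue-specific.
#'
#' @param inv_a,inv_b Results of [call_invariable] for tissues A and B.
#' @param name_a,name_b Tissue labels.
#' @return data.table of all invariable sites with a `status` column
#'   (`"shared"`, `"<name_a>-specific"`, `"<name_b>-specific"`).
#' @export
invariable_tissue_status <- function(inv_a, inv_b,
                                     name_a = "A", name_b = "B") {
  key <- c("chrom", "start")
  a <- inv_a[, key, with = FALSE][, status := paste0(name_a, "-specific")]
  b <- inv_b[, key, with = FALSE][, status := paste0(name_b, "-specific")]
  both <- merge(a[, ..key], b[, ..key], by = key)
  out <- unique(rbind(a, b), by = key)
  out[both, on = key, status := "shared"]
  out[]
}

#' Pairwise Fisher test for differential methylation at one CpG
#'
#' Two-sided Fisher exact probability on the 2x2 table
#' \code{[meth, unmeth] x [sample A, sample B]}, with the absolute level
#' difference in percentage points.
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth Pooled counts (vectorized).
#' @return data.table with `p`, `delta` (percentage points) and
#'   `direction` (+1 when A is higher). Zero-coverage entries yield `NA`.
#' @export
fisher_dmc <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  covA <- a_meth + a_unmeth
  covB <- b_meth + b_unmeth
  ok <- covA > 0 & covB > 0
  p <- rep(NA_real_, length(a_meth))
  p[ok] <- fisher_p_2x2(a_meth[ok], a_unmeth[ok], b_meth[ok], b_unmeth[ok])
  lA <- ifelse(covA > 0, a_meth / covA, NA_real_)
  lB <- ifelse(covB > 0, b_meth / covB, NA_real_)
  data.table::data.table(p = p, delta = abs(lA - lB) * 100,
                         direction = sign(lA - lB))
}

#' Call population differentially methylated CpGs (pDMCs)
#'
#' A site is a pDMC when Fisher's exact test is significant at `alpha` in
#' at least one pairwise comparison among the samples detecting it.
#'
#' @param pm A `PopulationMatrix`.
#' @param alpha Nominal significance level (default 0.05; no
#'   multiple-testing correction, by design).
#' @return List with `sites` (data.table: site, `pdmc` flag, `max_delta`,
#'   `min_p`, `n_significant`) and `summary` (median max-delta among pDMCs
#'   and the fraction with extreme differential methylation > 60 points).
#' @export
call_pdmc <- function(pm, alpha = 0.05) {
  det <- detection_mask(pm)
  meth <- round(pm$level * pm$cov)
  n <- nrow(pm$sites)
  pdmc <- logical(n)
  max_delta <- rep(NA_real_, n)
  min_p <- rep(NA_real_, n)
  n_sig <- integer(n)
  for (i in seq_len(n)) {
    j <- which(det[i, ])
    if (length(j) < 2L) next
    cmb <- utils::combn(j, 2L)
    res <- fisher_dmc(meth[i, cmb[1, ]], pm$cov[i, cmb[1, ]] - meth[i, cmb[1, ]],
                      meth[i, cmb[2, ]], pm$cov[i, cmb[2, ]] - meth[i, cmb[2, ]])
    n_sig[i] <- sum(res$p < alpha, na.rm = TRUE)
    pdmc[i] <- n_sig[i] >= 1L
    max_delta[i] <- max(res$delta, na.rm = TRUE)
    min_p[i] <- min(res$p, na.rm = TRUE)
  }
  sites <- data.table::data.table(pm$sites, pdmc = pdmc,
                                  max_delta = max_delta, min_p = min_p,
                                  n_significant = n_sig)
  dm <- max_delta[pdmc]
  list(
    sites = sites,
    summary = list(
      n_pdmc = sum(pdmc),
      fraction_pdmc = mean(pdmc),
      median_max_delta = if (length(dm)) stats::median(dm) else NA_real_,
      fraction_extreme = if (length(dm)) mean(dm > 60) else NA_real_
    )
  )
}

#' SNP-confounding profile over differential-methylation increments
#'
#' Bins pDMCs by their maximum pairwise differential methylation in
#' 10-point increments and reports the fraction of sites in each bin that
#' overlap an annotated SNP.
#'
#' @param pdmc_sites `sites` table from [call_pdmc], restricted to pDMCs.
#' @param snp_overlap Logical vector: does each site overlap a SNP?
#' @param bin_width Increment width in percentage points (default 10).
#' @return data.table with `bin` (label), `n`, `snp_fraction`
#'   (`NA` for empty bins).
#' @export
snp_confound_profile <- function(pdmc_sites, snp_overlap, bin_width = 10) {
  breaks <- seq(0, 100, by = bin_width)
  bins <- cut(pdmc_sites$max_delta, breaks = breaks, include.lowest = TRUE,
              right = FALSE)
  lab <- levels(bins)
  out <- data.table::data.table(bin = lab)
  tab <- data.table::data.table(bin = as.character(bins), snp = snp_overlap)
  agg <- tab[, .(n = .N, snp_fraction = mean(snp)), by = bin]
  out <- merge(out, agg, by = "bin", all.x = TRUE, sort = FALSE)
  out[is.na(n), n := 0L]
  out[]
}

#' Cell-composition confounding of pDMC methylation
#'
#' Correlates per-site methylation with measured blood cell-type fractions
#' across individuals detecting the site (Pearson, two-sided t-test). A
#' site is flagged when any cell type reaches `|R| > r_threshold` and
#' `p < alpha` with at least `min_individuals` informative samples.
#'
#' @param pm A `PopulationMatrix` (blood).
#' @param fractions data.frame of cell fractions, rows matching
#'   `pm$samples`, columns = cell types.
#' @param min_individuals Minimum samples with both measurements
#'   (default 10).
#' @param r_threshold Absolute correlation threshold (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @return data.table: one row per site with per-cell-type `r_` and `p_`
#'   columns and a `flagged` column. Zero-variance sites are unflagged.
#' @export
cell_composition_correlation <- function(pm, fractions,
                                         min_individuals = 10L,
                                         r_threshold = 0.5, alpha = 0.05) {
  fr <- as.matrix(fractions)
  stopifnot(nrow(fr) == length(pm$samples))
  det <- detection_mask(pm)
  out <- data.table::data.table(pm$sites)
  flagged <- rep(FALSE, nrow(out))
  for (ct in colnames(fr)) {
    f <- fr[, ct]
    r <- rep(NA_real_, nrow(out))
    pv <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      j <- which(det[i, ] & !is.na(f))
      if (length(j) < min_individuals) next
      x <- pm$level[i, j]; y <- f[j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ri <- stats::cor(x, y)
      df <- length(j) - 2L
      tt <- ri * sqrt(df / (1 - ri^2))
      r[i] <- ri
      pv[i] <- 2 * stats::pt(-abs(tt), df)
    }
    out[, paste0("r_", ct) := r]
    out[, paste0("p_", ct) := pv]
    flagged <- flagged | (!is.na(r) & abs(r) > r_threshold & pv < alpha)
  }
  out[, flagged := flagged]
  out[]
}
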