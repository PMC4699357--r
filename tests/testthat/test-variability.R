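test_that("invariable calling requires exact level identity", {
  meth <- rbind(c(0L, 0L, 0L),      # all unmethylated
                c(10L, 5L, NA),     # 100 % in two samples (3rd undetected)
                c(5L, 5L, 51L),     # 50, 50, 51 %: variable
                c(3L, 6L, 9L))      # 0.75 at different coverages: invariable
  cov <- rbind(c(10L, 8L, 12L),
               c(10L, 5L, 0L),
               c(10L, 10L, 100L),
               c(4L, 8L, 12L))
  pm <- make_pm_counts(meth, cov)
  inv <- call_invariable(pm, 2L)
  expect_equal(inv$start, c(100L, 200L, 400L))
  expect_equal(inv$class,
               c("unmethylated", "fully_methylated", "other_constant"))
  # not enough detections
  expect_equal(nrow(call_invariable(pm, 4L)), 0L)
})

test_that("tissue status separates shared and tissue-specific invariability", {
  inv_a <- data.table(chrom = "chr1", start = c(100L, 200L))
  inv_b <- data.table(chrom = "chr1", start = c(200L, 300L))
  st <- invariable_tissue_status(inv_a, inv_b, "adipose", "blood")
  expect_equal(st[start == 100L, status], "adipose-specific")
  expect_equal(st[start == 200L, status], "shared")
  expect_equal(st[start == 300L, status], "blood-specific")
})

test_that("fisher_dmc matches enumeration oracles on canonical tables", {
  r <- fisher_dmc(10L, 0L, 0L, 10L)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$delta, 100)
  expect_equal(fisher_dmc(5L, 5L, 5L, 5L)$p, 1)
  expect_equal(fisher_dmc(5L, 5L, 5L, 5L)$delta, 0)
  r2 <- fisher_dmc(3L, 1L, 1L, 3L)
  expect_equal(r2$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  # zero coverage is undefined
  expect_true(is.na(fisher_dmc(0L, 0L, 3L, 3L)$p))
})

test_that("fisher_dmc agrees with fisher.test across random tables", {
  set.seed(41)
  for (i in 1:150) {
    a <- rbinom(1, 15, 0.5); b <- rbinom(1, 15, 0.5)
    c <- rbinom(1, 15, 0.5); d <- rbinom(1, 15, 0.5)
    if ((a + b) == 0 || (c + d) == 0) next
    expect_equal(
      fisher_dmc(a, b, c, d)$p,
      fisher.test(matrix(c(a, b, c, d), 2))$p.value,
      tolerance = 1e-9, label = paste(a, b, c, d)
    )
  }
})

test_that("pDMC calls equal an all-pairs brute-force recount", {
  set.seed(42)
  n <- 60L; m <- 6L
  cov <- matrix(rpois(n * m, 12), n)
  meth <- matrix(rbinom(n * m, as.vector(cov), rep(runif(n), m)), n)
  cov[sample(length(cov), 40)] <- 0L
  pm <- make_pm_counts(meth, cov)
  res <- call_pdmc(pm, 0.05)
  brute <- sapply(seq_len(n), function(i) {
    j <- which(cov[i, ] > 0)
    if (length(j) < 2) return(FALSE)
    any(apply(combn(j, 2), 2, function(pr) {
      fisher.test(matrix(c(meth[i, pr[1]], cov[i, pr[1]] - meth[i, pr[1]],
                           meth[i, pr[2]], cov[i, pr[2]] - meth[i, pr[2]]),
                         2))$p.value < 0.05
    }))
  })
  expect_equal(res$sites$pdmc, unname(brute))
  # a constant site can never be a pDMC
  pm_const <- make_pm_counts(matrix(5L, 3, 4), matrix(10L, 3, 4))
  expect_false(any(call_pdmc(pm_const)$sites$pdmc))
})

test_that("invariable sites and pDMCs are disjoint", {
  set.seed(43)
  n <- 80L; m <- 5L
  cov <- matrix(rpois(n * m, 10) + 1L, n)
  meth <- matrix(rbinom(n * m, as.vector(cov), 0.5), n)
  meth[1:20, ] <- cov[1:20, ]  # invariable fully methylated block
  pm <- make_pm_counts(meth, cov)
  inv <- call_invariable(pm, 2L)
  pd <- call_pdmc(pm)$sites[pdmc == TRUE]
  expect_equal(nrow(merge(inv, pd, by = c("chrom", "start"))), 0L)
})

test_that("Fisher is conservative under a null with no differential signal", {
  set.seed(44)
  n <- 2000L
  covA <- rpois(n, 12) + 2L; covB <- rpois(n, 12) + 2L
  mA <- rbinom(n, covA, 0.5); mB <- rbinom(n, covB, 0.5)
  p <- fisher_dmc(mA, covA - mA, mB, covB - mB)$p
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("SNP confounding fractions are binned by delta increments", {
  # four pDMCs fall in the [0,10) increment, one of them SNP-overlapping
  sites <- data.table(chrom = "chr1", start = 1:6 * 100L,
                      max_delta = c(2, 5, 8, 9, 35, 95))
  prof <- snp_confound_profile(sites,
                               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(prof[bin == "[0,10)", snp_fraction], 0.25)
  expect_equal(prof[bin == "[30,40)", snp_fraction], 0)
  expect_equal(prof[bin == "[90,100]", snp_fraction], 1)
  expect_equal(prof[bin == "[50,60)", n], 0L)
  expect_true(is.na(prof[bin == "[50,60)", snp_fraction]))
  # no SNP annotation: all occupied bins at zero
  prof0 <- snp_confound_profile(sites, rep(FALSE, 6))
  expect_true(all(prof0[n > 0, snp_fraction] == 0))
})

test_that("SNP confounding rises with differential methylation on simulation", {
  sim <- simulate_twin_cohort(sim_config(n_cpg = 1200L, n_cph = 50L,
                                         genome_length = 2.5e5,
                                         snp_fraction = 0.15, seed = 45))
  blood <- names(sim$samples)[grepl("_blood$", names(sim$samples))]
  units <- lapply(sim$samples[blood], function(s) {
    strand_concordance_filter(pair_strands(s), filter_config())
  })
  pm <- build_population_matrix(units, 3L)
  pd <- call_pdmc(pm)$sites[pdmc == TRUE]
  snp_pos <- sim$truth$sites[sim$truth$snp_idx, start]
  prof <- snp_confound_profile(pd, pd$start %in% snp_pos)
  occ <- prof[n >= 10]
  # monotone trend: highest-delta occupied bin above the lowest
  expect_gt(occ$snp_fraction[nrow(occ)], occ$snp_fraction[1])
})

test_that("cell-composition correlation flags only real associations", {
  set.seed(46)
  m <- 12L
  fr <- matrix(runif(m * 2, 0.2, 0.8), m,
               dimnames = list(NULL, c("neutrophils", "lymphocytes")))
  lev <- rbind(fr[, "neutrophils"],          # perfectly correlated
               rep(0.5, m),                  # constant: undefined, unflagged
               runif(m))                     # noise
  pm <- make_pm(lev, matrix(10L, 3, m))
  res <- cell_composition_correlation(pm, fr, min_individuals = 10L)
  expect_true(res$flagged[1])
  expect_equal(res$r_neutrophils[1], 1)
  expect_false(res$flagged[2])
  # below the individual floor nothing is testable
  res2 <- cell_composition_correlation(pm, fr, min_individuals = 13L)
  expect_false(any(res2$flagged))
})

test_that("cell-type-driven sites are recalled from simulated blood", {
  sim <- simulate_twin_cohort(sim_config(n_cpg = 800L, n_cph = 50L,
                                         genome_length = 2e5,
                                         cell_site_fraction = 0.05,
                                         mean_coverage = 15, seed = 47))
  blood <- sim$metadata[tissue == "blood", sample_id]
  units <- lapply(sim$samples[blood], function(s) {
    strand_concordance_filter(pair_strands(s), filter_config())
  })
  pm <- build_population_matrix(units, 2L)
  fr <- as.matrix(sim$metadata[tissue == "blood",
                               .(neutrophils, lymphocytes, monocytes,
                                 eosinophils)])
  res <- cell_composition_correlation(pm, fr, min_individuals = 10L)
  truth_pos <- sim$truth$sites[sim$truth$cell_idx, start]
  flagged_truth <- res[start %in% truth_pos, mean(flagged)]
  expect_gte(flagged_truth, 0.8)
})
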