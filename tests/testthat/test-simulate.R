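test_that("config validation rejects impossible fractions and ACE sums", {
  expect_error(sim_config(snp_fraction = 1.2), "fractions")
  expect_error(sim_config(ace_a2_choices = 0.9, ace_c2 = 0.2), "exceed 1")
  expect_error(sim_config(baseline_weights = c(0.5, 0.2)), "sum to 1")
})

test_that("zero-variance sites share the baseline exactly", {
  cfg <- sim_config(n_mz_pairs = 2L, n_dz_pairs = 2L, n_singletons = 1L,
                    n_cpg = 200L, n_cph = 50L, genome_length = 5e4,
                    fraction_variable = 0, tissue_effect_fraction = 0,
                    snp_fraction = 0, cell_site_fraction = 0,
                    edmr_per_mz_pair = 0L, seed = 5)
  lat <- simulate_latent_methylation(cfg)
  spread <- apply(lat$level$adipose, 1, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_equal(lat$level$adipose[, 1],
               lat$truth$sites$baseline, tolerance = 1e-12)
})

test_that("perfect heritability makes MZ co-twins identical", {
  cfg <- sim_config(n_mz_pairs = 5L, n_dz_pairs = 2L, n_singletons = 0L,
                    n_cpg = 300L, n_cph = 50L, genome_length = 6e4,
                    fraction_variable = 1, ace_a2_choices = 1, ace_c2 = 0,
                    snp_fraction = 0, cell_site_fraction = 0,
                    edmr_per_mz_pair = 0L, tissue_effect_fraction = 0,
                    seed = 6)
  lat <- simulate_latent_methylation(cfg)
  ind <- lat$individuals
  for (p in unique(ind[zygosity == "MZ", pair_id])) {
    j <- which(ind$pair_id == p)
    expect_equal(lat$level$adipose[, j[1]], lat$level$adipose[, j[2]])
  }
})

test_that("twin correlations track a2 = 0.6 (MZ ~ 0.6, DZ ~ 0.3)", {
  cfg <- sim_config(n_mz_pairs = 50L, n_dz_pairs = 50L, n_singletons = 0L,
                    n_cpg = 4000L, n_cph = 50L, genome_length = 5e5,
                    fraction_variable = 1, ace_a2_choices = 0.6, ace_c2 = 0,
                    snp_fraction = 0, cell_site_fraction = 0,
                    edmr_per_mz_pair = 0L, tissue_effect_fraction = 0,
                    seed = 7)
  lat <- simulate_latent_methylation(cfg)
  ind <- lat$individuals
  cors <- function(zyg) {
    pid <- unique(ind[zygosity == zyg, pair_id])
    m1 <- sapply(pid, function(p) which(ind$pair_id == p & ind$member == 1))
    m2 <- sapply(pid, function(p) which(ind$pair_id == p & ind$member == 2))
    lv <- lat$level$adipose
    mean(sapply(seq_len(nrow(lv)), function(i) cor(lv[i, m1], lv[i, m2])))
  }
  expect_equal(cors("MZ"), 0.6, tolerance = 0.1)
  expect_equal(cors("DZ"), 0.3, tolerance = 0.1)
})

test_that("latent-value ICCs recover a2 + c2 (MZ) and a2/2 + c2 (DZ)", {
  cfg <- sim_config(n_mz_pairs = 200L, n_dz_pairs = 200L, n_singletons = 0L,
                    n_cpg = 800L, n_cph = 50L, genome_length = 2e5,
                    fraction_variable = 1, ace_a2_choices = 0.5, ace_c2 = 0.2,
                    liability_sd = 0.25, snp_fraction = 0,
                    cell_site_fraction = 0, edmr_per_mz_pair = 0L,
                    tissue_effect_fraction = 0, seed = 8)
  lat <- simulate_latent_methylation(cfg)
  ind <- lat$individuals
  mean_icc <- function(zyg) {
    pid <- unique(ind[zygosity == zyg, pair_id])
    m1 <- sapply(pid, function(p) which(ind$pair_id == p & ind$member == 1))
    m2 <- sapply(pid, function(p) which(ind$pair_id == p & ind$member == 2))
    lv <- lat$level$adipose
    mean(sapply(seq_len(nrow(lv)), function(i) icc(lv[i, m1], lv[i, m2])))
  }
  expect_equal(mean_icc("MZ"), 0.7, tolerance = 0.05)
  expect_equal(mean_icc("DZ"), 0.45, tolerance = 0.05)
})

test_that("count emission respects the level and conversion-noise model", {
  # level 1, no conversion failure: methylated count equals coverage
  cfg1 <- sim_config(n_mz_pairs = 1L, n_dz_pairs = 0L, n_singletons = 0L,
                     n_cpg = 300L, n_cph = 50L, genome_length = 6e4,
                     fraction_variable = 0, baseline_weights = 1,
                     baseline_means = 1, conversion_failure_rate = 0,
                     snp_fraction = 0, cell_site_fraction = 0,
                     edmr_per_mz_pair = 0L, tissue_effect_fraction = 0,
                     seed = 9)
  sim1 <- simulate_twin_cohort(cfg1)
  cg <- sim1$samples[[1]][context == "CG"]
  expect_equal(cg$meth, cg$cov)
  # level 0 with 1 % conversion failure: ~1 % apparent methylation
  cfg2 <- sim_config(n_mz_pairs = 3L, n_dz_pairs = 0L, n_singletons = 0L,
                     n_cpg = 4000L, n_cph = 50L, genome_length = 5e5,
                     fraction_variable = 0, baseline_weights = 1,
                     baseline_means = 0, conversion_failure_rate = 0.01,
                     snp_fraction = 0, cell_site_fraction = 0,
                     edmr_per_mz_pair = 0L, tissue_effect_fraction = 0,
                     seed = 10)
  sim2 <- simulate_twin_cohort(cfg2)
  cg2 <- rbindlist(sim2$samples)[context == "CG"]
  expect_equal(sum(cg2$meth) / sum(cg2$cov), 0.01, tolerance = 0.15)
})

test_that("SNP sites emit genotype-coded apparent methylation", {
  cfg <- sim_config(n_mz_pairs = 2L, n_dz_pairs = 2L, n_singletons = 1L,
                    n_cpg = 400L, n_cph = 50L, genome_length = 8e4,
                    snp_fraction = 0.2, mean_coverage = 30,
                    conversion_failure_rate = 0, cell_site_fraction = 0,
                    edmr_per_mz_pair = 0L, seed = 12)
  sim <- simulate_twin_cohort(cfg)
  ind <- sim$individuals
  for (j in c(1L, 3L)) {
    sid <- paste0(ind$ind_id[j], "_adipose")
    u <- pair_strands(sim$samples[[sid]])
    obs <- u[sim$truth$sites[sim$truth$snp_idx, .(chrom, start)],
             on = c("chrom", "start")]
    expected <- (2 - sim$truth$dosage[, j]) / 2
    # binomial noise around the coded level at 60x pooled coverage
    expect_true(mean(abs(obs$level - expected) < 0.2, na.rm = TRUE) > 0.95)
    # MZ co-twins share genotypes
  }
  mz <- which(ind$pair_id == "MZ1")
  expect_equal(sim$truth$dosage[, mz[1]], sim$truth$dosage[, mz[2]])
})

test_that("truth categories partition all simulated CpGs", {
  sim <- simulate_twin_cohort(sim_config(n_cpg = 1000L, n_cph = 100L,
                                         genome_length = 2e5, seed = 13))
  st <- sim$truth$sites
  expect_equal(nrow(st), 1000L)
  expect_true(all(st$category %in%
                    c("background", "variable", "snp", "artifact",
                      "cell_type")))
  expect_equal(sum(st$category == "snp"), length(sim$truth$snp_idx))
  expect_equal(sum(st$category == "artifact"),
               length(sim$truth$artifact_idx))
  # configured fractions are honoured within rounding
  expect_equal(length(sim$truth$snp_idx), round(0.05 * 1000))
  expect_equal(length(sim$truth$artifact_idx), round(0.002 * 1000))
})

test_that("identical seed and config reproduce output files byte-identically", {
  cfg <- sim_config(n_mz_pairs = 1L, n_dz_pairs = 1L, n_singletons = 0L,
                    n_cpg = 200L, n_cph = 100L, genome_length = 5e4,
                    seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_twin_cohort(cfg), d1)
  write_cohort(simulate_twin_cohort(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("truth tables round-trip and keep headers when empty", {
  sim <- simulate_twin_cohort(sim_config(n_cpg = 300L, n_cph = 50L,
                                         genome_length = 6e4, seed = 15))
  d <- withr::local_tempdir()
  write_truth(sim$truth, d)
  snp <- read_bed(file.path(d, "truth_snp.bed"))
  expect_equal(nrow(snp), length(sim$truth$snp_idx))
  st <- fread(file.path(d, "truth_sites.tsv"))
  expect_equal(st$a2, sim$truth$sites$a2)
  # empty truth still writes parseable tables
  empty <- sim$truth
  empty$snp_idx <- integer()
  empty$edmr <- empty$edmr[0]
  write_truth(empty, d)
  expect_equal(nrow(fread(file.path(d, "truth_edmr.tsv"))), 0L)
})
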