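test_that("per-CpG SD drops thin sites and matches the textbook formula", {
  lev <- rbind(c(0.5, 0.5, 0.5),
               c(0, 1, NA),
               c(0.2, 0.6, 0.7))
  cov <- matrix(10L, 3, 3); cov[2, 3] <- 0L
  pm <- make_pm(lev, cov)
  out <- per_cpg_sd(pm, 3L)
  expect_equal(out$start, c(100L, 300L))
  expect_equal(out$sd[1], 0)
  expect_equal(out$sd[2], sqrt(sum((c(0.2, 0.6, 0.7) - 0.5)^2) / 2))
  set.seed(51)
  lv <- matrix(runif(50), 10)
  pmr <- make_pm(lv, matrix(5L, 10, 5))
  expect_equal(per_cpg_sd(pmr, 3L)$sd, apply(lv, 1, sd))
})

test_that("window scan anchors at CpGs, drops singletons and subsets", {
  mk_sd <- function(start) data.table(chrom = "chr1", start = start,
                                      n_detected = 5L, sd = 0.1,
                                      site_idx = seq_along(start))
  # two isolated CpGs: every window would be a singleton
  expect_equal(nrow(scan_windows(mk_sd(c(100L, 5000L)))), 0L)
  # {100, 200, 300}: anchors at 200 and 300 give subsets of the first window
  w <- scan_windows(mk_sd(c(100L, 200L, 300L)))
  expect_equal(nrow(w), 1L)
  expect_equal(w$n_cpg, 3L)
  expect_equal(w$start, 100L)
  expect_equal(w$end, 302L)
  # a CpG exactly at anchor + 500 is outside the half-open window
  w2 <- scan_windows(mk_sd(c(100L, 400L, 600L)))
  expect_equal(w2$n_cpg, c(2L, 2L))  # {100,400} and {400,600}
})

test_that("window scan equals brute-force enumeration on random chromosomes", {
  for (seed in 52:54) {
    set.seed(seed)
    n <- 120L
    pos <- sort(sample.int(2e4, n))
    lv <- matrix(runif(n * 8), n)
    cv <- matrix(rpois(n * 8, 10) + 1L, n)
    cv[sample(length(cv), 120)] <- 0L
    lv[cv == 0] <- NA
    pm <- make_pm(lv, cv, start = pos)
    sds <- per_cpg_sd(pm, 3L)
    w <- scan_windows(sds, 500L)
    oracle <- oracle_pdmr(pm, 3L, 500L)
    expect_equal(w$start, oracle$scored$start)
    expect_equal(w$end, oracle$scored$end)
    expect_equal(w$n_cpg, oracle$scored$n_cpg)
  }
})

test_that("consistency score behaves at the symmetric limits", {
  # identical strictly increasing profiles: every correlation is 1
  lv <- matrix(rep(c(0.1, 0.3, 0.5, 0.7), 4), ncol = 4)
  expect_equal(consistency_score(lv)$consistency, 1)
  # two exactly mirrored profiles around the mean: +1 and -1 average to 0
  lv2 <- cbind(c(0.2, 0.4, 0.6), c(0.8, 0.6, 0.4))
  expect_equal(consistency_score(lv2)$consistency, 0)
  # fewer than two scorable individuals: unscored
  lv3 <- cbind(c(0.2, 0.4, 0.6), c(0.5, NA, NA))
  expect_true(is.na(consistency_score(lv3)$consistency))
})

test_that("consistency equals a rank-transform Pearson oracle", {
  set.seed(55)
  for (i in 1:10) {
    lv <- matrix(runif(40), 8)
    lv[sample(40, 6)] <- NA
    got <- consistency_score(lv)$consistency
    prof <- rowMeans(lv, na.rm = TRUE)
    rs <- c()
    for (j in 1:5) {
      if (sum(!is.na(lv[, j])) >= 2) {
        r <- oracle_spearman(lv[, j], prof)
        if (!is.na(r)) rs <- c(rs, r)
      }
    }
    expect_equal(got, if (length(rs) >= 2) mean(rs) else NA_real_)
  }
})

test_that("selection keeps the top quantile and merges at zero bp", {
  w <- data.table(chrom = "chr1",
                  start = seq(1000L, 10000L, 1000L),
                  end = seq(1000L, 10000L, 1000L) + 400L,
                  n_cpg = 5L, first = 1L, last = 5L,
                  mean_sd = seq(0.1, 1, 0.1), consistency = 1, m = 5L)
  sel <- rank_and_select(w, 0.10)
  expect_equal(nrow(sel$selected), 1L)
  expect_equal(sel$selected$start, 10000L)  # highest mean_sd wins
  # adjacent windows sharing a boundary base merge into one call
  w2 <- copy(w)[9:10, `:=`(start = c(20000L, 20400L),
                           end = c(20400L, 20800L))]
  sel2 <- rank_and_select(w2, 0.20)
  expect_equal(nrow(sel2$selected), 2L)
  expect_equal(nrow(sel2$calls), 1L)
  expect_equal(sel2$calls$start, 20000L)
  expect_equal(sel2$calls$end, 20800L)
  # windows below three CpGs never reach the calls
  w3 <- copy(w)[, n_cpg := 2L]
  expect_equal(nrow(rank_and_select(w3, 0.5)$calls), 0L)
  # anti-consistent windows score zero under the product rule
  w4 <- copy(w)[, consistency := -0.5]
  expect_true(all(rank_and_select(w4, 0.5)$selected$score == 0))
  expect_error(rank_and_select(w[0], 0.1), "no scored windows")
})

test_that("full scan matches the brute-force pipeline on small chromosomes", {
  for (seed in 56:57) {
    set.seed(seed)
    n <- 150L
    pos <- sort(sample.int(15000L, n))
    truep <- runif(n)
    cv <- matrix(rpois(n * 10, 15) + 2L, n)
    lv <- matrix(rbinom(length(cv), as.vector(cv), rep(truep, 10)), n) / cv
    pm <- make_pm(lv, cv, start = pos)
    res <- pdmr_scan(pm, quantile = 0.20)
    oracle <- oracle_pdmr(pm, quantile = 0.20)
    expect_equal(res$scored[order(start), .(start, end, n_cpg)],
                 oracle$scored[, .(start, end, n_cpg)],
                 ignore_attr = TRUE)
    expect_equal(res$scored[order(start), consistency],
                 oracle$scored$consistency, tolerance = 1e-12)
    expect_equal(sort(res$selected$start), sort(oracle$selected$start))
  }
})

test_that("label shuffling destroys offset-driven consistency", {
  set.seed(58)
  n_win <- 300L
  m <- 8L
  # windows where inter-individual offsets dominate the shared shape --
  # the configuration a population DMR represents
  res <- replicate(n_win, {
    prof <- runif(5, 0.45, 0.55)
    offs <- rnorm(m, 0, 0.2)
    lv <- sapply(seq_len(m), function(j) prof + offs[j] + rnorm(5, 0, 0.01))
    shuf <- t(apply(lv, 1, sample))   # break the offsets per CpG
    iid <- matrix(runif(5 * m), 5)    # signal-free reference window
    c(consistency_score(lv)$consistency,
      consistency_score(shuf)$consistency,
      consistency_score(iid, exclude_self = TRUE)$consistency)
  })
  expect_gt(mean(res[1, ]), 0.8)                  # consistent: near 1
  expect_lt(mean(res[2, ]), mean(res[1, ]) - 0.3) # shuffled: collapses
  # self-excluded consensus: the exchangeable null is centered at zero
  se <- sd(res[3, ]) / sqrt(n_win)
  expect_lt(abs(mean(res[3, ])), 3 * se)
})

test_that("pure noise added to one individual cannot raise consistency", {
  set.seed(59)
  diffs <- replicate(300, {
    prof <- sort(runif(5))
    lv <- sapply(1:6, function(j) prof + rnorm(5, 0, 0.02))
    base <- consistency_score(lv)$consistency
    noisy <- lv
    noisy[, 1] <- noisy[, 1] + rnorm(5, 0, 0.3)
    consistency_score(noisy)$consistency - base
  })
  expect_lt(mean(diffs), 0)
})

test_that("regional methylation stratification uses the 50 % boundary", {
  lv <- rbind(c(0.49, 0.49), c(0.50, 0.50), c(0.9, 0.9))
  pm <- make_pm(lv, matrix(100L, 3, 2), start = c(100L, 5000L, 9000L))
  calls <- data.table(chrom = "chr1",
                      start = c(90L, 4990L, 8990L),
                      end = c(110L, 5010L, 9010L))
  st <- stratify_by_level(calls, pm)
  expect_equal(st$stratum, c("low", "high", "high"))
  expect_equal(nrow(st[stratum == "low"]) + nrow(st[stratum == "high"]),
               nrow(calls))
})
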