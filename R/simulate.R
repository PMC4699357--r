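# Twin-structured two-tissue WGBS simulator with known ground truth.
#
# Latent per-site methylation follows a liability-scale ACE model: each site
# has a baseline (bimodal across sites: a low mode near 0 and a high mode
# near 1, giving ~80 % mean methylation), and individual liabilities add an
# additive-genetic component A (correlation 1 within MZ pairs, 0.5 within DZ
# pairs), a pair-shared environment C and an individual tissue-specific
# environment E, with variances proportional to the per-site (a2, c2, e2).
# The logistic link keeps levels in [0, 1]; the correlation structure is
# preserved approximately (attenuation is small at the default liability SD).

#' Simulation configuration for a twin methylome cohort
#'
#' Defaults emulate a two-tissue (adipose, blood) twin study: 7 MZ pairs,
#' 6 DZ pairs, a couple of singletons, bimodal baseline methylation,
#' Poisson stranded coverage, SNP-ablated CpGs, coverage-artifact loci,
#' blood cell-type mixtures, incomplete bisulfite conversion producing
#' background CpH signal, and planted within-MZ-pair environmental DMRs.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Cohort structure.
#' @param tissues Tissue names; cell-type mixing applies to `"blood"` only.
#' @param genome_length Simulated chromosome length (bp, single "chr1").
#' @param n_cpg,n_cph Numbers of CpG units and CpH sites.
#' @param mean_coverage Mean reads per site per strand (Poisson).
#' @param coverage_model `"poisson"` or `"nb"` (negative binomial with
#'   `nb_dispersion` as the size parameter), for robustness checks.
#' @param nb_dispersion Size parameter of the negative-binomial option.
#' @param baseline_weights,baseline_means Mixture weights and mean levels of
#'   the bimodal baseline methylation distribution.
#' @param fraction_variable Fraction of CpG sites with non-zero liability
#'   variance; the rest are strictly invariable (shared baseline).
#' @param liability_sd Total liability-scale SD at variable sites.
#' @param ace_a2_choices,ace_a2_probs Distribution of per-site a2 among
#'   variable sites (sampled once per site).
#' @param ace_c2 Per-site shared-environment fraction (e2 = 1 - a2 - c2).
#' @param snp_fraction Fraction of CpGs carrying a C-ablating variant;
#'   apparent methylation is genotype-coded (100/50/0 % for variant dosage
#'   0/1/2). Genotypes are shared within MZ pairs and shared per allele with
#'   probability 0.5 within DZ pairs.
#' @param blacklist_fraction Fraction of CpG loci with artifactually
#'   inflated coverage in every sample.
#' @param artifact_factor Coverage multiplier at artifact loci (default
#'   places them far above the global mean + 5 SD).
#' @param conversion_failure_rate Probability an unmethylated cytosine reads
#'   as methylated (incomplete bisulfite conversion).
#' @param cell_type_means Mean blood cell fractions
#'   (neutrophils/lymphocytes/monocytes/eosinophils simplex).
#' @param cell_concentration Dirichlet concentration of per-sample fractions.
#' @param cell_site_fraction Fraction of CpGs with cell-type-specific
#'   methylation in blood.
#' @param cell_effect Logit-scale polarization of cell-type-driven sites:
#'   neutrophil and lymphocyte levels sit at `plogis(+/-cell_effect)`
#'   (methylated in one cell type, unmethylated in the other).
#' @param tissue_effect_fraction,tissue_effect Fraction of sites with a
#'   between-tissue liability shift, and its size.
#' @param cph_meth_fraction,cph_meth_level Fraction of CpH sites with
#'   genuine methylation, and their level; kept rare so the background CpH
#'   signal is dominated by conversion failure, as in somatic tissues.
#' @param edmr_per_mz_pair,edmr_n_cpg,edmr_effect Number of planted
#'   environmental DMRs per MZ pair (each in one tissue, one co-twin
#'   shifted by `edmr_effect` on the liability scale over `edmr_n_cpg`
#'   consecutive CpGs).
#' @param seed Integer seed; identical config + seed reproduces output
#'   byte-identically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 7L, n_dz_pairs = 6L, n_singletons = 2L,
                       tissues = c("adipose", "blood"),
                       genome_length = 3e5, n_cpg = 3000L, n_cph = 3000L,
                       mean_coverage = 4, coverage_model = c("poisson", "nb"),
                       nb_dispersion = 5,
                       baseline_weights = c(0.2, 0.8),
                       baseline_means = c(0.01, 0.95),
                       fraction_variable = 0.2, liability_sd = 0.4,
                       ace_a2_choices = c(0, 0.3, 0.6),
                       ace_a2_probs = c(0.5, 0.3, 0.2),
                       ace_c2 = 0.05,
                       snp_fraction = 0.05,
                       blacklist_fraction = 0.002, artifact_factor = 30,
                       conversion_failure_rate = 0.006,
                       cell_type_means = c(neutrophils = 0.55,
                                           lymphocytes = 0.35,
                                           monocytes = 0.07,
                                           eosinophils = 0.03),
                       cell_concentration = 35,
                       cell_site_fraction = 0.01, cell_effect = 4,
                       tissue_effect_fraction = 0.05, tissue_effect = 1.5,
                       cph_meth_fraction = 5e-4, cph_meth_level = 0.8,
                       edmr_per_mz_pair = 2L, edmr_n_cpg = 8L,
                       edmr_effect = 2.5,
                       seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  if (length(ace_a2_probs) != length(ace_a2_choices)) {
    ace_a2_probs <- rep(1 / length(ace_a2_choices), length(ace_a2_choices))
  }
  cfg <- as.list(environment())
  fr <- c(fraction_variable, snp_fraction, blacklist_fraction,
          conversion_failure_rate, cell_site_fraction,
          tissue_effect_fraction, cph_meth_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(ace_a2_choices + ace_c2 > 1 + 1e-12)) {
    stop("a2 + c2 + e2 must not exceed 1 at any site")
  }
  if (abs(sum(baseline_weights) - 1) > 1e-8) {
    stop("baseline_weights must sum to 1")
  }
  if (abs(sum(cell_type_means) - 1) > 1e-8) {
    stop("cell_type_means must sum to 1")
  }
  if (n_cpg + n_cph > genome_length / 3) stop("genome_length too small")
  structure(cfg, class = "sim_config")
}

#' Individual table for a configured cohort
#' @keywords internal
#' @noRd
sim_individuals <- function(config) {
  mz <- if (config$n_mz_pairs > 0) data.table::data.table(
    pair_id = rep(paste0("MZ", seq_len(config$n_mz_pairs)), each = 2L),
    zygosity = "MZ", member = rep(1:2, config$n_mz_pairs)
  ) else NULL
  dz <- if (config$n_dz_pairs > 0) data.table::data.table(
    pair_id = rep(paste0("DZ", seq_len(config$n_dz_pairs)), each = 2L),
    zygosity = "DZ", member = rep(1:2, config$n_dz_pairs)
  ) else NULL
  sg <- if (config$n_singletons > 0) data.table::data.table(
    pair_id = NA_character_, zygosity = NA_character_,
    member = rep(1L, config$n_singletons)
  ) else NULL
  ind <- data.table::rbindlist(list(mz, dz, sg))
  ind[, ind_id := ifelse(is.na(pair_id),
                         paste0("SG", cumsum(is.na(pair_id))),
                         paste0(pair_id, "_", member))]
  ind[]
}

#' Simulate latent methylation levels under the twin ACE model
#'
#' Draws per-site, per-individual latent methylation levels in \[0, 1\] for
#' every tissue: `level = plogis(baseline + A + C + E)` with A pair-correlated
#' (1 for MZ, 0.5 for DZ), C pair-shared, E individual- and tissue-specific,
#' and component variances proportional to the per-site (a2, c2, e2).
#'
#' @param config A [sim_config].
#' @return List with `config`, `individuals`, `sites` (CpG forward-C
#'   positions, 0-based), `cph_sites`, per-tissue `liability` and `level`
#'   matrices (sites x individuals), and a `truth` list (per-site ACE
#'   fractions and category, SNP/artifact/cell-site assignments, genotype
#'   dosages, planted eDMR intervals, methylated-CpH truth).
#' @export
simulate_latent_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  ind <- sim_individuals(config)
  n_ind <- nrow(ind)
  n_cpg <- as.integer(config$n_cpg)
  pairs <- unique(ind$pair_id[!is.na(ind$pair_id)])
  n_pairs <- length(pairs)
  pair_idx <- match(ind$pair_id, pairs)

  # distinct even CpG positions (spacing >= 2 so dinucleotides never overlap)
  half <- floor(config$genome_length / 2) - 2L
  cpg_pos <- sort(sample.int(half, n_cpg)) * 2L
  sites <- data.table::data.table(chrom = "chr1", start = cpg_pos)

  # per-site baseline from the bimodal mixture, on the liability (logit) scale
  comp <- sample.int(length(config$baseline_weights), n_cpg, replace = TRUE,
                     prob = config$baseline_weights)
  base_logit <- stats::qlogis(config$baseline_means[comp])

  variable <- stats::runif(n_cpg) < config$fraction_variable
  a2_draw <- if (length(config$ace_a2_choices) == 1L) {
    rep(config$ace_a2_choices, n_cpg)
  } else {
    sample(config$ace_a2_choices, n_cpg, replace = TRUE,
           prob = config$ace_a2_probs)
  }
  a2 <- ifelse(variable, a2_draw, 0)
  c2 <- ifelse(variable, config$ace_c2, 0)
  e2 <- ifelse(variable, 1 - a2 - c2, 0)
  sigma <- ifelse(variable, config$liability_sd, 0)

  # tissue-specific baseline shifts for a minority of sites
  ts_site <- stats::runif(n_cpg) < config$tissue_effect_fraction
  ts_shift <- ifelse(ts_site,
                     sample(c(-1, 1), n_cpg, replace = TRUE) *
                       config$tissue_effect, 0)

  zA_pair <- matrix(stats::rnorm(n_cpg * max(n_pairs, 1L)), n_cpg)
  zA_ind <- matrix(stats::rnorm(n_cpg * n_ind), n_cpg)
  zC_pair <- matrix(stats::rnorm(n_cpg * max(n_pairs, 1L)), n_cpg)
  zC_ind <- matrix(stats::rnorm(n_cpg * n_ind), n_cpg)

  A <- matrix(0, n_cpg, n_ind)
  C <- matrix(0, n_cpg, n_ind)
  for (j in seq_len(n_ind)) {
    if (is.na(ind$zygosity[j])) {
      A[, j] <- zA_ind[, j]
      C[, j] <- zC_ind[, j]
    } else if (ind$zygosity[j] == "MZ") {
      A[, j] <- zA_pair[, pair_idx[j]]
      C[, j] <- zC_pair[, pair_idx[j]]
    } else {
      A[, j] <- sqrt(0.5) * zA_pair[, pair_idx[j]] + sqrt(0.5) * zA_ind[, j]
      C[, j] <- zC_pair[, pair_idx[j]]
    }
  }
  gshare <- sigma * sqrt(a2) * A + sigma * sqrt(c2) * C

  # planted within-MZ-pair environmental DMRs: runs of consecutive CpGs where
  # co-twin 1 is shifted in one tissue
  edmr <- data.table::data.table(pair_id = character(), tissue = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), first_idx = integer(),
                                 last_idx = integer(), direction = integer())
  mz_pairs <- unique(ind$pair_id[ind$zygosity %in% "MZ"])
  if (length(mz_pairs) > 0 && config$edmr_per_mz_pair > 0) {
    taken <- rep(FALSE, n_cpg)
    for (p in mz_pairs) {
      for (k in seq_len(config$edmr_per_mz_pair)) {
        pool <- which(!taken[seq_len(n_cpg - config$edmr_n_cpg)])
        anchor <- pool[sample.int(length(pool), 1L)]
        run <- anchor:(anchor + config$edmr_n_cpg - 1L)
        taken[run] <- TRUE
        edmr <- rbind(edmr, data.table::data.table(
          pair_id = p, tissue = sample(config$tissues, 1L),
          chrom = "chr1", start = cpg_pos[run[1]],
          end = cpg_pos[run[length(run)]] + 2L,
          first_idx = run[1], last_idx = run[length(run)],
          direction = sample(c(-1L, 1L), 1L)
        ))
      }
    }
  }

  liability <- list()
  level <- list()
  for (t in config$tissues) {
    E_t <- matrix(stats::rnorm(n_cpg * n_ind), n_cpg)
    shift_t <- if (t == config$tissues[1]) 0 else ts_shift
    liab <- base_logit + shift_t + gshare + sigma * sqrt(e2) * E_t
    if (nrow(edmr) > 0) {
      for (r in which(edmr$tissue == t)) {
        j <- which(ind$pair_id == edmr$pair_id[r] & ind$member == 1L)
        run <- edmr$first_idx[r]:edmr$last_idx[r]
        liab[run, j] <- liab[run, j] + edmr$direction[r] * config$edmr_effect
      }
    }
    liability[[t]] <- liab
    level[[t]] <- stats::plogis(liab)
  }

  # confounder assignments (disjoint categories for unambiguous truth)
  n_snp <- round(config$snp_fraction * n_cpg)
  n_art <- round(config$blacklist_fraction * n_cpg)
  n_cell <- round(config$cell_site_fraction * n_cpg)
  picks <- sample.int(n_cpg, n_snp + n_art + n_cell)
  snp_idx <- sort(picks[seq_len(n_snp)])
  art_idx <- sort(picks[n_snp + seq_len(n_art)])
  cell_idx <- sort(picks[n_snp + n_art + seq_len(n_cell)])

  # genotypes at SNP sites: variant-allele dosage per individual
  dosage <- matrix(0L, length(snp_idx), n_ind)
  if (length(snp_idx) > 0) {
    maf <- stats::runif(length(snp_idx), 0.1, 0.5)
    a1p <- matrix(0L, length(snp_idx), max(n_pairs, 1L))
    a2p <- matrix(0L, length(snp_idx), max(n_pairs, 1L))
    for (s in seq_along(snp_idx)) {
      a1p[s, ] <- stats::rbinom(max(n_pairs, 1L), 1L, maf[s])
      a2p[s, ] <- stats::rbinom(max(n_pairs, 1L), 1L, maf[s])
    }
    for (j in seq_len(n_ind)) {
      if (is.na(ind$zygosity[j])) {
        dosage[, j] <- stats::rbinom(length(snp_idx), 2L, maf)
      } else if (ind$zygosity[j] == "MZ") {
        dosage[, j] <- a1p[, pair_idx[j]] + a2p[, pair_idx[j]]
      } else {
        # DZ: each parental allele transmitted independently
        keep1 <- stats::runif(length(snp_idx)) < 0.5
        keep2 <- stats::runif(length(snp_idx)) < 0.5
        al1 <- ifelse(keep1, a1p[, pair_idx[j]],
                      stats::rbinom(length(snp_idx), 1L, maf))
        al2 <- ifelse(keep2, a2p[, pair_idx[j]],
                      stats::rbinom(length(snp_idx), 1L, maf))
        dosage[, j] <- al1 + al2
      }
    }
  }

  # cell-type liability offsets at cell-driven sites (blood only)
  cell_delta <- NULL
  if (n_cell > 0) {
    sgn <- sample(c(-1, 1), n_cell, replace = TRUE)
    cell_delta <- cbind(neutrophils = sgn * config$cell_effect,
                        lymphocytes = -sgn * config$cell_effect,
                        monocytes = 0, eosinophils = 0)
  }

  # CpH sites on odd positions (never colliding with CpG dinucleotides)
  n_cph <- as.integer(config$n_cph)
  cph_pos <- sort(sample.int(half - 1L, n_cph)) * 2L + 1L
  dinuc <- sample(c("CA", "CT", "CC"), n_cph, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  ctx3 <- ifelse(stats::runif(n_cph) < 1 / 3, "G",
                 sample(c("A", "C", "T"), n_cph, replace = TRUE))
  cph_sites <- data.table::data.table(
    chrom = "chr1", start = cph_pos,
    strand = sample(c("+", "-"), n_cph, replace = TRUE),
    tri = paste0(dinuc, ctx3),
    context = ifelse(ctx3 == "G", "CHG", "CHH")
  )
  cph_meth <- stats::runif(n_cph) < config$cph_meth_fraction

  category <- rep("background", n_cpg)
  category[variable] <- "variable"
  category[cell_idx] <- "cell_type"
  category[art_idx] <- "artifact"
  category[snp_idx] <- "snp"
  truth <- list(
    sites = data.table::data.table(
      chrom = "chr1", start = cpg_pos, a2 = a2, c2 = c2, e2 = e2,
      sigma = sigma, baseline = stats::plogis(base_logit),
      category = category
    ),
    snp_idx = snp_idx, artifact_idx = art_idx, cell_idx = cell_idx,
    dosage = dosage, cell_delta = cell_delta,
    edmr = edmr[, .(pair_id, tissue, chrom, start, end, direction)],
    edmr_idx = edmr,
    cph_methylated = cph_sites[cph_meth, .(chrom, start, strand)]
  )

  list(config = config, individuals = ind, sites = sites,
       cph_sites = cph_sites, cph_methylated = cph_meth,
       liability = liability, level = level, truth = truth)
}

rcov <- function(n, lambda, config) {
  if (config$coverage_model == "poisson") {
    stats::rpois(n, lambda)
  } else {
    stats::rnbinom(n, size = config$nb_dispersion, mu = lambda)
  }
}

#' Emit stranded read counts for every sample
#'
#' Converts latent levels into per-sample cytosine-report tables. Per strand,
#' coverage is Poisson (or negative binomial) around `mean_coverage`;
#' methylated counts are binomial at the apparent level
#' `p + (1 - p) * conversion_failure_rate`. SNP-carrying CpGs emit
#' genotype-coded apparent methylation (100/50/0 % for variant dosage
#' 0/1/2); artifact loci emit inflated coverage in every sample; blood
#' samples mix cell-type-specific levels by their cell fractions before
#' count emission.
#'
#' @param latent Result of [simulate_latent_methylation].
#' @return List with `samples` (named list of cytosine-record tables, CpG
#'   both strands plus CpH), `metadata` (sample table with tissue, pair,
#'   zygosity and blood cell fractions) and `cell_fractions`.
#' @export
emit_read_counts <- function(latent) {
  config <- latent$config
  set.seed(derive_seed(config$seed, 2L))
  ind <- latent$individuals
  n_ind <- nrow(ind)
  n_cpg <- nrow(latent$sites)
  n_cph <- nrow(latent$cph_sites)
  f <- config$conversion_failure_rate

  # per-individual blood cell fractions (Dirichlet via gamma draws)
  cm <- config$cell_type_means
  g <- matrix(stats::rgamma(n_ind * length(cm),
                            shape = config$cell_concentration * rep(cm, each = n_ind)),
              n_ind)
  fracs <- g / rowSums(g)
  colnames(fracs) <- names(cm)
  rownames(fracs) <- ind$ind_id

  lambda_cpg <- rep(config$mean_coverage, n_cpg)
  lambda_cpg[latent$truth$artifact_idx] <-
    config$mean_coverage * config$artifact_factor

  cph_level <- ifelse(latent$cph_methylated, config$cph_meth_level, 0)
  tri_fwd <- paste0("CG", sample(c("A", "C", "G", "T"), n_cpg, replace = TRUE))
  tri_rev <- paste0("CG", sample(c("A", "C", "G", "T"), n_cpg, replace = TRUE))

  samples <- list()
  meta <- list()
  for (t in config$tissues) {
    lev_t <- latent$level[[t]]
    for (j in seq_len(n_ind)) {
      p <- lev_t[, j]
      if (t == "blood" && length(latent$truth$cell_idx) > 0) {
        # cell-type-polarized loci: per-cell-type levels are fixed at
        # plogis(delta_c); the bulk level mixes them by the sample's
        # cell fractions
        ci <- latent$truth$cell_idx
        mix <- rep(0, length(ci))
        for (c in seq_along(cm)) {
          mix <- mix + fracs[j, c] *
            stats::plogis(latent$truth$cell_delta[, c])
        }
        p[ci] <- mix
      }
      if (length(latent$truth$snp_idx) > 0) {
        p[latent$truth$snp_idx] <- (2 - latent$truth$dosage[, j]) / 2
      }
      p_app <- p + (1 - p) * f
      cov_f <- rcov(n_cpg, lambda_cpg, config)
      cov_r <- rcov(n_cpg, lambda_cpg, config)
      meth_f <- stats::rbinom(n_cpg, cov_f, p_app)
      meth_r <- stats::rbinom(n_cpg, cov_r, p_app)
      cph_app <- cph_level + (1 - cph_level) * f
      cph_cov <- rcov(n_cph, config$mean_coverage, config)
      cph_meth <- stats::rbinom(n_cph, cph_cov, cph_app)

      rec <- data.table::rbindlist(list(
        data.table::data.table(chrom = "chr1", start = latent$sites$start,
                               strand = "+", context = "CG", tri = tri_fwd,
                               meth = meth_f, unmeth = cov_f - meth_f),
        data.table::data.table(chrom = "chr1", start = latent$sites$start + 1L,
                               strand = "-", context = "CG", tri = tri_rev,
                               meth = meth_r, unmeth = cov_r - meth_r),
        data.table::data.table(chrom = "chr1", start = latent$cph_sites$start,
                               strand = latent$cph_sites$strand,
                               context = latent$cph_sites$context,
                               tri = latent$cph_sites$tri,
                               meth = cph_meth, unmeth = cph_cov - cph_meth)
      ))
      data.table::setorder(rec, chrom, start, strand)
      sid <- paste0(ind$ind_id[j], "_", t)
      samples[[sid]] <- finalize_records(rec)
      meta[[sid]] <- data.table::data.table(
        sample_id = sid, ind_id = ind$ind_id[j], tissue = t,
        pair_id = ind$pair_id[j], zygosity = ind$zygosity[j],
        member = ind$member[j],
        neutrophils = if (t == "blood") fracs[j, "neutrophils"] else NA_real_,
        lymphocytes = if (t == "blood") fracs[j, "lymphocytes"] else NA_real_,
        monocytes = if (t == "blood") fracs[j, "monocytes"] else NA_real_,
        eosinophils = if (t == "blood") fracs[j, "eosinophils"] else NA_real_
      )
    }
  }
  list(samples = samples, metadata = data.table::rbindlist(meta),
       cell_fractions = fracs)
}

#' Simulate a full twin methylome cohort
#'
#' Convenience wrapper running [simulate_latent_methylation] then
#' [emit_read_counts].
#'
#' @param config A [sim_config].
#' @return List combining the latent simulation (`sites`, `level`,
#'   `truth`, ...) with `samples` (cytosine-record tables) and `metadata`.
#' @export
simulate_twin_cohort <- function(config = sim_config()) {
  latent <- simulate_latent_methylation(config)
  counts <- emit_read_counts(latent)
  c(latent, counts)
}

#' Write ground-truth tables to disk
#'
#' Writes `truth_sites.tsv` (per-site ACE fractions and category),
#' `truth_snp.bed`, `truth_blacklist.bed` (artifact loci),
#' `truth_cell_sites.tsv`, `truth_edmr.tsv` and `truth_cph.tsv`. Tables are
#' written with headers even when empty, and round-trip losslessly.
#'
#' @param truth The `truth` element of a simulated cohort.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- truth$sites
  data.table::fwrite(st, file.path(dir, "truth_sites.tsv"), sep = "\t")
  snp <- st[truth$snp_idx, .(chrom, start, end = start + 2L)]
  write_bed(snp, file.path(dir, "truth_snp.bed"))
  art <- st[truth$artifact_idx, .(chrom, start, end = start + 2L)]
  write_bed(art, file.path(dir, "truth_blacklist.bed"))
  data.table::fwrite(st[truth$cell_idx, .(chrom, start)],
                     file.path(dir, "truth_cell_sites.tsv"), sep = "\t")
  data.table::fwrite(truth$edmr, file.path(dir, "truth_edmr.tsv"), sep = "\t")
  data.table::fwrite(truth$cph_methylated,
                     file.path(dir, "truth_cph.tsv"), sep = "\t")
  invisible(file.path(dir, c("truth_sites.tsv", "truth_snp.bed",
                             "truth_blacklist.bed", "truth_cell_sites.tsv",
                             "truth_edmr.tsv", "truth_cph.tsv")))
}

#' Write a simulated cohort to disk
#'
#' Writes one cytosine report per sample, the sample metadata table, the
#' truth tables and the simulated SNP/blacklist BED files. Given the same
#' config and seed the files are byte-identical across runs.
#'
#' @param sim Result of [simulate_twin_cohort].
#' @param outdir Output directory.
#' @param gzip Write gzipped cytosine reports.
#' @return Invisibly, `outdir`.
#' @export
write_cohort <- function(sim, outdir, gzip = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".cytosine_report.tsv.gz" else ".cytosine_report.tsv"
  for (sid in names(sim$samples)) {
    write_cytosine_report(sim$samples[[sid]], file.path(outdir,
                                                        paste0(sid, ext)))
  }
  data.table::fwrite(sim$metadata, file.path(outdir, "metadata.tsv"),
                     sep = "\t")
  write_truth(sim$truth, outdir)
  invisible(outdir)
}
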