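test_that("parents differ at every SNP and density tracks the target", {
  cfg <- sim_config(n_rils = 10, chrom_lengths = c(chrA = 1e6),
                    snp_density = 1.2, seed = 11)
  p <- simulate_parents(cfg)
  expect_true(all(p$snps$allele_p1 != p$snps$allele_p2))
  expect_true(all(diff(p$snps$pos) > 0))
  ## Poisson(1200) count: within 4 sd of the mean
  expect_lt(abs(nrow(p$snps) - 1200), 4 * sqrt(1200))
})

test_that("embedded parental sequences carry the alleles at SNP positions", {
  cfg <- sim_config(n_rils = 5, chrom_lengths = c(chrA = 5e4), seed = 3)
  p <- simulate_parents(cfg, with_sequences = TRUE)
  at <- function(s, i) substr(s, i, i)
  expect_equal(vapply(p$snps$pos, function(i) at(p$p1_seq[["chrA"]], i),
                      character(1)), p$snps$allele_p1)
  expect_equal(vapply(p$snps$pos, function(i) at(p$p2_seq[["chrA"]], i),
                      character(1)), p$snps$allele_p2)
})

test_that("zero-length chromosomes and bad configs are rejected", {
  expect_error(sim_config(chrom_lengths = c(chrA = 0)), "positive")
  expect_error(sim_config(seq_error = 0.5), "seq_error")
  expect_error(sim_config(n_rils = 0), "n_rils")
})

test_that("RIL segments tile each chromosome exactly once", {
  s <- small_sim(seed = 5, n_rils = 30)
  for (ril in s$truth$rils) {
    seg <- s$truth$segments[[ril]][["chrA"]]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], unname(s$cfg$chrom_lengths[["chrA"]]))
    if (nrow(seg) > 1) {
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
      expect_true(all(seg$org[-1] != seg$org[-nrow(seg)]))
    }
  }
})

test_that("with no crossovers each chromosome is one parental segment", {
  cfg <- sim_config(n_rils = 40, chrom_lengths = c(chrA = 1e5),
                    cm_per_mb = 1e-9, seed = 8)
  truth <- simulate_ril_population(config = cfg)
  orgs <- vapply(truth$rils, function(r) {
    seg <- truth$segments[[r]][["chrA"]]
    expect_equal(nrow(seg), 1L)
    seg$org
  }, numeric(1))
  expect_setequal(unique(orgs), c(1, 2))
  ## P1/P2 with roughly equal probability
  expect_gt(min(table(orgs)), 5)
})

test_that("residual heterozygosity matches 0.5^generations and declines", {
  het_rate <- function(g, seed) {
    cfg <- sim_config(n_rils = 400, chrom_lengths = c(chrA = 1e5),
                      cm_per_mb = 1, selfing_generations = g, seed = seed)
    truth <- simulate_ril_population(config = cfg)
    mean(truth_at(truth, "chrA", 5e4) == 3L)
  }
  h3 <- het_rate(3, 21)
  p <- 0.5^3
  expect_lt(abs(h3 - p), 3 * sqrt(p * (1 - p) / 400))
  expect_gt(h3, het_rate(6, 22))  # declines with more selfing

  ## F10 genome-wide residual het near 0.5^9, over >= 100 lines
  s <- small_sim(seed = 19, n_rils = 150, len = 6e5, cm_per_mb = 5)
  frac <- vapply(s$truth$rils, function(r) {
    seg <- s$truth$segments[[r]][["chrA"]]
    sum((seg$end - seg$start)[seg$org == 3]) / 6e5
  }, numeric(1))
  expect_lt(mean(frac), 5 * 0.5^9)  # order-of-magnitude Monte-Carlo bound
})

test_that("recombination fraction across 10 cM matches the inbred-line expectation", {
  ## Haldane r for d = 0.1 Morgan; terminal RIL R = 2r/(1+2r)
  cfg <- sim_config(n_rils = 1000, chrom_lengths = c(chrA = 1e6),
                    cm_per_mb = 10, selfing_generations = 20, seed = 33)
  truth <- simulate_ril_population(config = cfg)
  g <- truth_at(truth, c("chrA", "chrA"), c(1, 1e6))
  r_meiosis <- (1 - exp(-2 * 0.1)) / 2
  R_expect <- 2 * r_meiosis / (1 + 2 * r_meiosis)
  ok <- g[, 1] %in% 1:2 & g[, 2] %in% 1:2
  R_obs <- mean(g[ok, 1] != g[ok, 2])
  se <- sqrt(R_expect * (1 - R_expect) / sum(ok))
  expect_lt(abs(R_obs - R_expect), 3 * se)
})

test_that("markers on different chromosomes are unlinked (R near 0.5)", {
  cfg <- sim_config(n_rils = 600, chrom_lengths = c(chrA = 2e5, chrB = 2e5),
                    cm_per_mb = 5, seed = 12)
  truth <- simulate_ril_population(config = cfg)
  g <- truth_at(truth, c("chrA", "chrB"), c(1e5, 1e5))
  ok <- g[, 1] %in% 1:2 & g[, 2] %in% 1:2
  R <- mean(g[ok, 1] != g[ok, 2])
  expect_lt(abs(R - 0.5), 3 * sqrt(0.25 / sum(ok)))
})

test_that("observation missingness matches the Poisson zero mass", {
  s <- small_sim(seed = 13, n_rils = 50, len = 8e5, mean_depth = 2)
  obs <- simulate_observations(s$truth, s$parents$snps, s$cfg)
  p0 <- exp(-2)
  n <- length(obs)
  expect_lt(abs(mean(obs == 0L) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("heterozygous sites are observed HET at the enumerated rate", {
  ## truth: one RIL, fully heterozygous chromosome
  truth <- structure(list(
    segments = list(RIL001 = list(chrA = data.frame(start = 0, end = 2e4,
                                                    org = 3))),
    breakpoints = data.frame(ril = character(0), chrom = character(0),
                             pos = numeric(0)),
    rils = "RIL001", chrom_lengths = c(chrA = 2e4)), class = "ril_truth")
  snps <- data.frame(chrom = "chrA", pos = seq_len(2e4))
  cfg <- sim_config(n_rils = 1, chrom_lengths = c(chrA = 2e4),
                    mean_depth = 2, seed = 99)
  set.seed(99)
  obs <- simulate_observations(truth, snps, cfg)
  ## P(HET observed) = sum_d Pois(d; 2) * (1 - 2 (1/2)^d), d >= 1
  d <- 1:60
  p_het <- sum(stats::dpois(d, 2) * (1 - 2 * 0.5^d))
  expect_lt(abs(mean(obs == 3L) - p_het),
            3 * sqrt(p_het * (1 - p_het) / 2e4))
})

test_that("in the high-depth, error-free limit observations equal truth", {
  s <- small_sim(seed = 17, n_rils = 20, len = 2e5)
  cfg <- s$cfg
  cfg$mean_depth <- 60  # Poisson(60): zero or single-allele draws negligible
  obs <- simulate_observations(s$truth, s$parents$snps, cfg)
  g <- truth_at(s$truth, s$parents$snps$chrom, s$parents$snps$pos)
  expect_gt(mean(obs == g), 0.9999)
})

test_that("qualitative phenotypes split exactly along the causal genotype", {
  s <- small_sim(seed = 23, n_rils = 80, len = 4e5)
  tr <- trait_config("leaf_color", "qualitative",
                     loci = data.frame(chrom = "chrA", pos = 2e5),
                     classes = c(p1 = "green", p2 = "yellow"),
                     dominant = "p1")
  ph <- simulate_phenotypes(s$truth, tr, seed = 1)
  g <- truth_at(s$truth, "chrA", 2e5)[, 1]
  expected <- ifelse(g == 2L, "yellow", "green")  # het -> dominant p1
  expect_equal(ph$leaf_color, unname(expected))
})

test_that("noise-free quantitative traits have zero within-class variance", {
  s <- small_sim(seed = 29, n_rils = 60, len = 4e5)
  tr <- trait_config("height", "quantitative",
                     loci = data.frame(chrom = "chrA", pos = 2e5,
                                       effect = 2), resid_sd = 0)
  ph <- simulate_phenotypes(s$truth, tr, seed = 2)
  g <- truth_at(s$truth, "chrA", 2e5)[, 1]
  for (cls in unique(g)) {
    if (sum(g == cls) < 2) next
    expect_equal(stats::var(ph$height[g == cls]), 0, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a planted PVE is realized within sampling error", {
  s <- small_sim(seed = 31, n_rils = 184, len = 6e5)
  pve_target <- 0.30
  tr <- trait_config("ph", "quantitative",
                     loci = data.frame(chrom = "chrA", pos = 3e5,
                                       effect = effect_for_pve(pve_target)),
                     resid_sd = 1)
  ## average realized PVE over replicates
  pves <- vapply(1:20, function(i) {
    ph <- simulate_phenotypes(s$truth, tr, seed = 100 + i)
    g <- truth_at(s$truth, "chrA", 3e5)[, 1]
    ok <- g %in% 1:2
    summary(stats::lm(ph$ph[ok] ~ factor(g[ok])))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(pves) - pve_target), 0.06)
})

test_that("causal loci outside the genome are rejected", {
  s <- small_sim(seed = 37, n_rils = 20, len = 1e5)
  tr <- trait_config("bad", "qualitative",
                     loci = data.frame(chrom = "chrA", pos = 2e5))
  expect_error(simulate_phenotypes(s$truth, tr), "outside genome")
})

test_that("simulation is reproducible: same config and seed, same output", {
  run <- function() {
    cfg <- sim_config(n_rils = 15, chrom_lengths = c(chrA = 1e5), seed = 77)
    p <- simulate_parents(cfg)
    t <- simulate_ril_population(p, cfg)
    o <- simulate_observations(t, p$snps, cfg)
    list(p = p, t = t$segments, o = o)
  }
  expect_identical(run(), run())
})

test_that("fragmented assemblies preserve length and record deleted truth", {
  set.seed(41)
  donor <- c(chrA = random_dna(20000))
  gaps <- data.frame(chrom = "chrA", start = 5000, end = 5100)
  fr <- simulate_fragmented_assembly(donor, gaps)
  expect_equal(nchar(fr$target[["chrA"]]), 20000)
  hits <- gregexpr("N{10,}", fr$target[["chrA"]])[[1]]
  expect_length(hits, 1)
  expect_equal(attr(hits, "match.length"), 100)
  expect_equal(fr$truth$deleted_seq,
               substr(donor[["chrA"]], 5001, 5100))

  ## zero gaps -> identity
  fr0 <- simulate_fragmented_assembly(donor,
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  expect_null(fr0$truth)
  expect_identical(fr0$target, donor)

  ## overlapping gaps rejected
  expect_error(simulate_fragmented_assembly(donor,
    data.frame(chrom = "chrA", start = c(100, 150), end = c(200, 260))),
    "overlapping")
})

test_that("gaps whose flank repeats in the donor are marked non-unique", {
  set.seed(43)
  block <- random_dna(3000)
  donor <- c(chrA = paste0(block, random_dna(8000), block, random_dna(3000)))
  ## gap right after the second copy of the repeat: left flank is repeated
  start <- 3000 + 8000 + 3000
  fr <- simulate_fragmented_assembly(donor,
    data.frame(chrom = "chrA", start = start, end = start + 200),
    flank_len = 500)
  expect_false(fr$truth$left_unique)
  expect_true(fr$truth$right_unique)
})
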