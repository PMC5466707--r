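## Shared fixtures. The default-scale simulation (184 RILs, 1/100-scale
## nine-chromosome genome, 2x depth) is computed once per test run and
## cached, since several suites measure recovery against its truth.

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(seed = seed)
  parents <- simulate_parents(cfg)
  truth <- simulate_ril_population(parents, cfg)
  obs <- simulate_observations(truth, parents$snps, cfg)
  track <- call_windows(obs, parents$snps)
  bp <- detect_breakpoints(track, parents$snps)
  bm <- build_bins(bp, track, parents$snps, cfg$chrom_lengths)
  lm_ <- construct_linkage_map(bm)
  out <- list(cfg = cfg, parents = parents, truth = truth, obs = obs,
              track = track, bp = bp, bm = bm, lmap = lm_)
  .fixture_cache[[key]] <- out
  out
}

## small single-chromosome simulation for cheap unit tests
small_sim <- function(seed = 7, n_rils = 60, len = 6e5, cm_per_mb = 10,
                      mean_depth = 2, selfing = 9) {
  cfg <- sim_config(n_rils = n_rils, chrom_lengths = c(chrA = len),
                    snp_density = 1.2, selfing_generations = selfing,
                    cm_per_mb = cm_per_mb, mean_depth = mean_depth,
                    seed = seed)
  parents <- simulate_parents(cfg)
  truth <- simulate_ril_population(parents, cfg)
  list(cfg = cfg, parents = parents, truth = truth)
}

## Markov-chain bin genotype fixture: n_bins ordered bins, columns evolve
## along the chromosome with per-step recombination probability r_step
## (r_step may be a vector of length n_bins - 1)
markov_bins <- function(n_bins = 10, n_rils = 100, r_step = 0.1,
                        chrom = "chr1", bin_len = 40000, seed = 1) {
  set.seed(seed)
  r_step <- rep_len(r_step, n_bins - 1L)
  geno <- matrix("", nrow = n_bins, ncol = n_rils)
  geno[1L, ] <- sample(c("a", "b"), n_rils, replace = TRUE)
  for (k in 2:n_bins) {
    flip <- stats::runif(n_rils) < r_step[k - 1L]
    geno[k, ] <- ifelse(flip, chartr("ab", "ba", geno[k - 1L, ]),
                        geno[k - 1L, ])
  }
  bins <- data.frame(bin_id = sprintf("bin%04d", seq_len(n_bins)),
                     chrom = chrom,
                     start = (seq_len(n_bins) - 1L) * bin_len,
                     end = seq_len(n_bins) * bin_len,
                     stringsAsFactors = FALSE)
  rownames(geno) <- bins$bin_id
  colnames(geno) <- sprintf("RIL%03d", seq_len(n_rils))
  structure(list(bins = bins, geno = geno), class = "bin_map")
}

## brute-force LOD oracle via independent least squares (lm deviances)
lod_oracle <- function(g, y) {
  ok <- g %in% c("a", "b") & !is.na(y)
  gg <- factor(g[ok]); yy <- y[ok]
  n <- sum(ok)
  ss0 <- stats::deviance(stats::lm(yy ~ 1))
  ss1 <- stats::deviance(stats::lm(yy ~ gg))
  (n / 2) * log10(ss0 / ss1)
}
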