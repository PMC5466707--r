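#' Default pipeline configuration
#'
#' Every stage parameter with its documented default; unknown keys in a
#' user configuration are rejected by [run_pipeline()].
#'
#' @return named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "binmapper_out",
    seed = 1L,
    simulate = TRUE,            # simulate inputs; else vcf/phenotypes paths
    vcf = NULL,
    p1_name = "Zhanggu",
    p2_name = "A2",
    phenotypes = NULL,          # TSV path (ril_id + trait columns)
    traits = NULL,              # list of trait_config when simulating
    n_rils = 184L,
    genome_scale = 0.01,
    snp_density = 1.2,
    selfing_generations = 9L,
    cm_per_mb = 4.63,
    mean_depth = 2.0,
    seq_error = 0,
    max_missing = 0.60,
    window = 15L,
    hi = 11,
    lo = 4,
    min_informative_window = 8L,
    min_run = 5L,
    min_interval = 20000,
    r_max = 0.25,
    ril_correct = FALSE,
    lod_threshold = 3.0,
    lod_drop = 1.5,
    min_informative_bin = 10L
  )
}

#' Run the full bin-map pipeline
#'
#' Executes the stages in dependency order: simulate (optional) -> write /
#' read VCF -> SNP filtering -> sliding-window genotyping -> breakpoints ->
#' bin map -> linkage map -> trait scans. Stage outputs are written under
#' `config$out_dir` and a JSON run manifest (version, config snapshot,
#' input checksums, per-stage row counts and timings) is emitted on every
#' run. Deterministic given the same config and seed.
#'
#' @param config named list; see [default_pipeline_config()] for keys and
#'   defaults. May also be a path to a YAML file.
#' @return invisibly, a list of in-memory stage results (`snps`, `obs`,
#'   `track`, `breakpoints`, `bin_map`, `linkage_map`, `scans`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) abort("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_snapshot <- cfg[order(names(cfg))]
  if (!is.null(cfg_snapshot$traits)) {
    cfg_snapshot$traits <- lapply(cfg_snapshot$traits, function(tr)
      list(name = tr$name, type = tr$type, loci = tr$loci,
           resid_sd = tr$resid_sd))
  }
  manifest <- list(tool = "binmapper",
                   version = as.character(utils::packageVersion("binmapper")),
                   config = cfg_snapshot, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  out <- list()

  if (isTRUE(cfg$simulate)) {
    sim <- t_stage("simulate", {
      sc <- sim_config(n_rils = cfg$n_rils,
                       chrom_lengths = default_chrom_lengths(cfg$genome_scale),
                       snp_density = cfg$snp_density,
                       selfing_generations = cfg$selfing_generations,
                       cm_per_mb = cfg$cm_per_mb,
                       mean_depth = cfg$mean_depth,
                       seq_error = cfg$seq_error, seed = cfg$seed)
      parents <- simulate_parents(sc)
      truth <- simulate_ril_population(parents, sc)
      obs <- simulate_observations(truth, parents$snps, sc)
      vcf_path <- file.path(cfg$out_dir, "population.vcf")
      write_vcf(parents$snps, obs, vcf_path, cfg$p1_name, cfg$p2_name,
                sc$chrom_lengths)
      truth_path <- file.path(cfg$out_dir, "truth.json")
      jsonlite::write_json(list(
        breakpoints = truth$breakpoints,
        chrom_lengths = as.list(truth$chrom_lengths)),
        truth_path, auto_unbox = TRUE, digits = NA)
      pheno <- NULL
      if (!is.null(cfg$traits)) {
        pheno <- simulate_phenotypes(truth, cfg$traits, seed = cfg$seed + 1L)
        write_tsv(pheno, file.path(cfg$out_dir, "phenotypes.tsv"))
      }
      list(vcf = vcf_path, truth = truth, pheno = pheno,
           chrom_lengths = sc$chrom_lengths)
    })
    cfg$vcf <- sim$vcf
    out$truth <- sim$truth
    pheno <- sim$pheno
    chrom_lengths <- sim$chrom_lengths
  } else {
    if (is.null(cfg$vcf)) abort("config$vcf required when simulate = FALSE")
    pheno <- if (!is.null(cfg$phenotypes)) read_tsv(cfg$phenotypes) else NULL
    chrom_lengths <- NULL
  }
  manifest$inputs <- list(vcf = unname(tools::md5sum(cfg$vcf)))

  vc <- t_stage("read_vcf", read_vcf(cfg$vcf, cfg$p1_name, cfg$p2_name))
  snps <- t_stage("filter_snps", filter_snps(vc$snps, cfg$max_missing))
  keep <- match(paste(snps$chrom, snps$pos),
                paste(vc$snps$chrom, vc$snps$pos))
  obs <- vc$obs[, keep, drop = FALSE]
  manifest$stages$filter_snps$n_snps <- nrow(snps)

  track <- t_stage("call_windows",
                   call_windows(obs, snps, cfg$window, cfg$hi, cfg$lo,
                                cfg$min_informative_window))
  write_geno_tsv(track, file.path(cfg$out_dir, "tracks.tsv"))

  bp <- t_stage("detect_breakpoints",
                detect_breakpoints(track, snps, cfg$min_run))
  write_tsv(bp, file.path(cfg$out_dir, "breakpoints.tsv"))
  manifest$stages$detect_breakpoints$n <- nrow(bp)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(snps$pos, snps$chrom, max)
  }
  bm <- t_stage("build_bins",
                build_bins(bp, track, snps, chrom_lengths, cfg$min_interval))
  write_bins(bm, file.path(cfg$out_dir, "bins.bed"),
             file.path(cfg$out_dir, "bin_genotypes.tsv"))
  manifest$stages$build_bins$n_bins <- nrow(bm$bins)

  lm_ <- t_stage("linkage_map",
                 construct_linkage_map(bm, cfg$r_max,
                                       cfg$min_informative_bin,
                                       cfg$ril_correct))
  write_tsv(lm_$map, file.path(cfg$out_dir, "linkage_map.tsv"))
  manifest$stages$linkage_map$total_cM <- lm_$total_cM
  manifest$stages$linkage_map$n_groups <- lm_$n_groups

  scans <- list()
  if (!is.null(pheno)) {
    scans <- t_stage("qtl", {
      res <- list()
      for (tr in setdiff(names(pheno), "ril_id")) {
        y <- pheno[[tr]]
        names(y) <- pheno$ril_id
        if (is.numeric(y)) {
          sc <- lod_scan(bm$geno, y, cfg$min_informative_bin)
          write_tsv(sc, file.path(cfg$out_dir, paste0("scan_", tr, ".tsv")))
          res[[tr]] <- list(scan = sc,
                            qtls = call_qtls(sc, bm$bins, cfg$lod_threshold,
                                             cfg$lod_drop))
        } else {
          res[[tr]] <- map_qualitative(bm$geno, y, bm$bins)
        }
      }
      res
    })
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(snps = snps, obs = obs, track = track, breakpoints = bp,
                 bin_map = bm, linkage_map = lm_, scans = scans,
                 truth = out$truth, manifest = manifest))
}
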