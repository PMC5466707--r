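#' Default chromosome lengths for simulations
#'
#' Nine chromosomes totalling ~416 Mb at full scale, the karyotype of a
#' foxtail millet reference genome. The default `scale = 0.01` yields a
#' ~4.16 Mb toy genome on which the whole pipeline runs in seconds; pass
#' `scale = 1` for full-scale lengths.
#'
#' @param scale multiplicative factor applied to the full-scale lengths.
#' @return named integer vector of chromosome lengths in bp.
#' @export
default_chrom_lengths <- function(scale = 0.01) {
  full <- c(chr1 = 44603498, chr2 = 51761675, chr3 = 54090027,
            chr4 = 43349090, chr5 = 49560508, chr6 = 36928436,
            chr7 = 37743793, chr8 = 38066565, chr9 = 59875680)
  round(full * scale)
}

#' Simulation configuration for a two-parent RIL population
#'
#' Captures the study design the simulator emulates: a biparental cross
#' carried to F10 by single-seed descent (9 selfing generations), ~1.2
#' segregating SNPs per kb, and ~2x sequencing depth per line, on a
#' 1/100-scale nine-chromosome genome by default.
#'
#' @param n_rils number of recombinant inbred lines (default 184).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param snp_density expected segregating SNPs per kb (default 1.2).
#' @param selfing_generations selfing rounds after F1 (default 9, i.e. F10).
#' @param crossover_rate expected crossovers per meiosis per Morgan of
#'   simulated map (default 1; the standard Poisson/no-interference model).
#' @param cm_per_mb genetic-to-physical ratio in cM/Mb used to set each
#'   chromosome's genetic length (default 4.63, the genome-wide ratio of a
#'   ~1928 cM map over ~416 Mb).
#' @param mean_depth expected reads per SNP per RIL (default 2.0).
#' @param seq_error per-read allele error probability (default 0).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rils = 184,
                       chrom_lengths = default_chrom_lengths(),
                       snp_density = 1.2,
                       selfing_generations = 9,
                       crossover_rate = 1,
                       cm_per_mb = 4.63,
                       mean_depth = 2.0,
                       seq_error = 0,
                       seed = NULL) {
  if (n_rils < 1) abort("n_rils must be >= 1 (got %s)", n_rils)
  if (length(chrom_lengths) < 1 || any(chrom_lengths < 1)) {
    abort("chrom_lengths must be positive (zero-length chromosome rejected)")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (snp_density <= 0) abort("snp_density must be > 0")
  if (selfing_generations < 1) abort("selfing_generations must be >= 1")
  if (crossover_rate <= 0) abort("crossover_rate must be > 0")
  if (cm_per_mb <= 0) abort("cm_per_mb must be > 0")
  if (mean_depth <= 0) abort("mean_depth must be > 0")
  if (seq_error < 0 || seq_error >= 0.5) abort("seq_error must be in [0, 0.5)")
  structure(list(n_rils = as.integer(n_rils),
                 chrom_lengths = chrom_lengths,
                 snp_density = snp_density,
                 selfing_generations = as.integer(selfing_generations),
                 crossover_rate = crossover_rate,
                 cm_per_mb = cm_per_mb,
                 mean_depth = mean_depth,
                 seq_error = seq_error,
                 seed = seed),
            class = "sim_config")
}

## genetic length of each chromosome in Morgans under a config
chrom_morgans <- function(config) {
  config$chrom_lengths / 1e6 * config$cm_per_mb / 100
}

#' Trait configuration for phenotype simulation
#'
#' @param name trait name.
#' @param type `"qualitative"` (binary classes) or `"quantitative"`.
#' @param loci data.frame with columns `chrom`, `pos` and (for quantitative
#'   traits) `effect`, the additive effect per allele-dose unit.
#' @param classes for qualitative traits, named character vector
#'   `c(p1 = ..., p2 = ...)` giving the phenotype class conferred by each
#'   parental genotype.
#' @param dominant which parental allele is dominant in heterozygotes of a
#'   qualitative trait: `"p1"` or `"p2"`.
#' @param resid_sd residual standard deviation for quantitative traits.
#' @return an object of class `trait_config`.
#' @export
trait_config <- function(name, type = c("quantitative", "qualitative"),
                         loci,
                         classes = c(p1 = "P1-like", p2 = "P2-like"),
                         dominant = "p1",
                         resid_sd = 1) {
  type <- match.arg(type)
  stopifnot(is.data.frame(loci), all(c("chrom", "pos") %in% names(loci)))
  if (type == "qualitative" && nrow(loci) != 1L) {
    abort("qualitative traits are monogenic: exactly one causal locus")
  }
  if (type == "quantitative" && !"effect" %in% names(loci)) {
    abort("quantitative trait loci need an 'effect' column")
  }
  if (resid_sd < 0) abort("resid_sd must be >= 0")
  if (!dominant %in% c("p1", "p2")) abort("dominant must be 'p1' or 'p2'")
  structure(list(name = name, type = type, loci = loci, classes = classes,
                 dominant = dominant, resid_sd = resid_sd),
            class = "trait_config")
}

#' Additive effect needed for a target proportion of variance explained
#'
#' For a RIL population (genotype score x = +1/-1 with equal frequency, so
#' var(x) = 1), an additive effect `a` on top of residual sd `s` explains
#' a^2 / (a^2 + s^2) of the phenotypic variance; invert for `a`.
#'
#' @param pve target proportion of variance explained, in (0, 1).
#' @param resid_sd residual standard deviation.
#' @return the additive effect size.
#' @export
effect_for_pve <- function(pve, resid_sd = 1) {
  if (pve <= 0 || pve >= 1) abort("pve must be in (0, 1)")
  resid_sd * sqrt(pve / (1 - pve))
}
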