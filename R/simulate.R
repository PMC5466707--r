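#' Simulate the two parental genomes and their segregating SNPs
#'
#' SNP positions are drawn along each chromosome at the configured density
#' (Poisson number of sites, uniform positions); the parents carry different
#' alleles at every site. Optionally emits toy parental sequences with the
#' alleles embedded at the SNP positions.
#'
#' @param config a [sim_config()].
#' @param with_sequences also generate the two parental FASTA-ready
#'   sequences (random background, alleles embedded).
#' @return list with `snps` (data.frame: `chrom`, `pos` 1-based,
#'   `allele_p1`, `allele_p2`) and, if requested, `p1_seq`/`p2_seq`
#'   (named character vectors of chromosome sequences).
#' @export
simulate_parents <- function(config, with_sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  snps <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    n <- stats::rpois(1L, len / 1000 * config$snp_density)
    n <- min(n, len)
    pos <- sort(sample.int(len, n))
    a1 <- sample(bases, n, replace = TRUE)
    shift <- sample.int(3L, n, replace = TRUE)  # a2 != a1 by construction
    a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
    data.frame(chrom = rep(chrom, n), pos = pos,
               allele_p1 = a1, allele_p2 = a2, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snps)
  rownames(snps) <- NULL
  out <- list(snps = snps)
  if (with_sequences) {
    p1 <- p2 <- character(0)
    for (chrom in names(config$chrom_lengths)) {
      len <- config$chrom_lengths[[chrom]]
      chars <- sample(bases, len, replace = TRUE)
      idx <- snps$pos[snps$chrom == chrom]
      c1 <- chars; c1[idx] <- snps$allele_p1[snps$chrom == chrom]
      c2 <- chars; c2[idx] <- snps$allele_p2[snps$chrom == chrom]
      p1[chrom] <- paste(c1, collapse = "")
      p2[chrom] <- paste(c2, collapse = "")
    }
    out$p1_seq <- p1
    out$p2_seq <- p2
  }
  out
}

## a haplotype is a data.frame(start, end, org) of 0-based half-open
## segments tiling [0, L), org in {1 = P1, 2 = P2}
new_hap <- function(org, L) data.frame(start = 0, end = L, org = org)

## clip a haplotype to [s, e)
hap_clip <- function(h, s, e) {
  keep <- h$end > s & h$start < e
  h <- h[keep, , drop = FALSE]
  h$start <- pmax(h$start, s)
  h$end <- pmin(h$end, e)
  h
}

## merge adjacent segments with equal origin
hap_merge <- function(h) {
  if (nrow(h) <= 1L) return(h)
  keep <- c(TRUE, h$org[-1L] != h$org[-nrow(h)])
  first <- which(keep)
  last <- c(first[-1L] - 1L, nrow(h))
  data.frame(start = h$start[first], end = h$end[last], org = h$org[first],
             row.names = NULL)
}

## one meiosis: recombine haplotypes h1/h2 of one plant into a gamete.
## Crossover count ~ Poisson(morgans * rate), positions uniform on [0, L).
make_gamete <- function(h1, h2, L, morgans, rate) {
  nx <- stats::rpois(1L, morgans * rate)
  cuts <- sort(stats::runif(nx, 0, L))
  bounds <- c(0, cuts, L)
  src <- sample(1:2, 1L)  # which haplotype starts
  parts <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    h <- if ((src + k) %% 2L == 0L) h1 else h2
    parts[[k]] <- hap_clip(h, bounds[k], bounds[k + 1L])
  }
  hap_merge(do.call(rbind, parts))
}

## diploid genotype segments from two haplotypes: code 1/2/3 (P1/P2/HET)
diploid_genotype <- function(h1, h2) {
  cuts <- sort(unique(c(h1$start, h1$end, h2$start, h2$end)))
  s <- cuts[-length(cuts)]
  e <- cuts[-1L]
  mid <- (s + e) / 2
  o1 <- h1$org[findInterval(mid, h1$start)]
  o2 <- h2$org[findInterval(mid, h2$start)]
  g <- ifelse(o1 == o2, o1, GT_HET)
  seg <- data.frame(start = s, end = e, org = g)
  hap_merge(seg)
}

#' Simulate a RIL population by single-seed descent
#'
#' Starting from the F1 (one haplotype from each parent), each line is
#' carried through `selfing_generations` rounds of selfing; every selfing
#' draws two independent gametes from the same plant, each gamete formed by
#' a meiosis with a Poisson number of crossovers (no interference) at
#' uniform positions. The result per line and chromosome is a mosaic of
#' P1/P2/HET segments with residual heterozygosity ~ 0.5^generations.
#'
#' @param parents output of [simulate_parents()] (unused beyond dimensions;
#'   accepted so call sites read naturally) or `NULL`.
#' @param config a [sim_config()].
#' @return object of class `ril_truth`: list with `segments` (a list, one
#'   per RIL, of per-chromosome data.frames `start`,`end`,`org` in 0-based
#'   half-open bp, org 1/2/3) and `breakpoints` (data.frame `ril`, `chrom`,
#'   `pos` of every true genotype-segment boundary, bp).
#' @export
simulate_ril_population <- function(parents = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  morg <- chrom_morgans(config)
  chroms <- names(config$chrom_lengths)
  rils <- sprintf("RIL%03d", seq_len(config$n_rils))
  segments <- vector("list", config$n_rils)
  names(segments) <- rils
  bp_acc <- list()
  for (i in seq_len(config$n_rils)) {
    per_chrom <- vector("list", length(chroms))
    names(per_chrom) <- chroms
    for (ch in chroms) {
      L <- config$chrom_lengths[[ch]]
      m <- morg[[ch]]
      h1 <- new_hap(GT_P1, L)
      h2 <- new_hap(GT_P2, L)
      for (g in seq_len(config$selfing_generations)) {
        g1 <- make_gamete(h1, h2, L, m, config$crossover_rate)
        g2 <- make_gamete(h1, h2, L, m, config$crossover_rate)
        h1 <- g1
        h2 <- g2
      }
      seg <- diploid_genotype(h1, h2)
      per_chrom[[ch]] <- seg
      if (nrow(seg) > 1L) {
        bp_acc[[length(bp_acc) + 1L]] <-
          data.frame(ril = rils[i], chrom = ch, pos = seg$start[-1L],
                     stringsAsFactors = FALSE)
      }
    }
    segments[[i]] <- per_chrom
  }
  breakpoints <- if (length(bp_acc)) do.call(rbind, bp_acc) else
    data.frame(ril = character(0), chrom = character(0), pos = numeric(0))
  structure(list(segments = segments, breakpoints = breakpoints,
                 rils = rils, chrom_lengths = config$chrom_lengths),
            class = "ril_truth")
}

#' True genotype codes of every RIL at given positions
#'
#' @param truth a `ril_truth` from [simulate_ril_population()].
#' @param chrom,pos vectors of positions to query (pos 1-based bp).
#' @return integer matrix (RILs x positions) of codes 1/2/3.
#' @export
truth_at <- function(truth, chrom, pos) {
  stopifnot(inherits(truth, "ril_truth"), length(chrom) == length(pos))
  n <- length(pos)
  out <- matrix(NA_integer_, nrow = length(truth$rils), ncol = n,
                dimnames = list(truth$rils, NULL))
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    p <- pos[j] - 0.5  # 1-based bp -> interior of 0-based half-open segs
    for (i in seq_along(truth$rils)) {
      seg <- truth$segments[[i]][[ch]]
      out[i, j] <- seg$org[findInterval(p, seg$start)]
    }
  }
  out
}

#' Simulate low-coverage parental-origin observations
#'
#' Per SNP and line, read depth is Poisson(`mean_depth`); each read reports
#' the parent-1 allele with probability 1-e (P1 homozygote), e (P2
#' homozygote) or 0.5 (heterozygote), where e is the per-read error rate.
#' Depth 0 gives MISSING; both alleles seen gives HET; otherwise the single
#' observed allele's parent.
#'
#' @param truth a `ril_truth`.
#' @param snps SNP table (`chrom`, `pos`) from [simulate_parents()].
#' @param config a [sim_config()].
#' @return integer observation matrix (RILs x SNPs; codes 0/1/2/3) with
#'   RIL and marker dimnames.
#' @export
simulate_observations <- function(truth, snps, config) {
  stopifnot(inherits(truth, "ril_truth"))
  g <- truth_at(truth, snps$chrom, snps$pos)
  n <- length(g)
  depth <- stats::rpois(n, config$mean_depth)
  p1prob <- c(1 - config$seq_error, config$seq_error, 0.5)[g]
  k <- stats::rbinom(n, depth, p1prob)  # reads showing the P1 allele
  obs <- ifelse(depth == 0L, GT_MISSING,
                ifelse(k == depth, GT_P1,
                       ifelse(k == 0L, GT_P2, GT_HET)))
  matrix(as.integer(obs), nrow = nrow(g),
         dimnames = list(rownames(g), sprintf("m%05d", seq_len(ncol(g)))))
}

#' Simulate phenotypes from true genotypes
#'
#' Qualitative traits are a deterministic function of the genotype at the
#' single causal locus (heterozygotes resolved by the dominance setting);
#' quantitative traits are the sum of additive locus effects (genotype
#' scored +1/0/-1 for P1/HET/P2) plus Gaussian noise.
#'
#' @param truth a `ril_truth`.
#' @param traits list of [trait_config()] objects.
#' @param seed optional RNG seed for the residual noise.
#' @return data.frame with `ril_id` and one column per trait.
#' @export
simulate_phenotypes <- function(truth, traits, seed = NULL) {
  stopifnot(inherits(truth, "ril_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(traits, "trait_config")) traits <- list(traits)
  out <- data.frame(ril_id = truth$rils, stringsAsFactors = FALSE)
  for (tr in traits) {
    loci <- tr$loci
    bad <- !loci$chrom %in% names(truth$chrom_lengths) |
      loci$pos < 1 | loci$pos > truth$chrom_lengths[loci$chrom]
    if (any(bad)) abort("trait '%s': causal locus outside genome", tr$name)
    g <- truth_at(truth, loci$chrom, loci$pos)  # RILs x loci
    if (tr$type == "qualitative") {
      gi <- g[, 1L]
      dom_code <- if (tr$dominant == "p1") GT_P1 else GT_P2
      gi[gi == GT_HET] <- dom_code
      out[[tr$name]] <- unname(tr$classes[c("p1", "p2")[gi]])
    } else {
      x <- matrix(c(0, 1, -1, 0)[g + 1L], nrow = nrow(g))  # 1->+1, 2->-1, 3->0
      y <- as.vector(x %*% loci$effect) +
        stats::rnorm(nrow(g), 0, tr$resid_sd)
      out[[tr$name]] <- y
    }
  }
  out
}

#' Fragment a donor sequence with N-gaps, keeping the deleted truth
#'
#' Replaces the requested spans of each donor sequence with runs of `N`
#' (sequence length unchanged) and records the deleted sequence per gap,
#' plus whether each flank occurs uniquely in the donor — non-unique flanks
#' mark gaps that a conservative filler must refuse.
#'
#' @param donor named character vector of donor sequences.
#' @param gaps data.frame with `chrom`, `start`, `end` (0-based half-open
#'   spans to erase).
#' @param flank_len flank length used for the uniqueness annotation.
#' @return list with `target` (gapped sequences) and `truth` (data.frame:
#'   `chrom`, `gap_start`, `gap_end`, `deleted_seq`, `left_unique`,
#'   `right_unique`, `at_edge`).
#' @export
simulate_fragmented_assembly <- function(donor, gaps, flank_len = 500) {
  stopifnot(is.character(donor), !is.null(names(donor)),
            all(c("chrom", "start", "end") %in% names(gaps)))
  if (any(!gaps$chrom %in% names(donor))) abort("gap chrom not in donor")
  if (any(gaps$start < 0) || any(gaps$end <= gaps$start)) {
    abort("gap spans must be non-empty with start >= 0")
  }
  lens <- nchar(donor)
  if (any(gaps$end > lens[gaps$chrom])) abort("gap extends past donor end")
  gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
  for (ch in unique(gaps$chrom)) {
    gg <- gaps[gaps$chrom == ch, ]
    if (nrow(gg) > 1L && any(gg$start[-1L] < gg$end[-nrow(gg)])) {
      abort("overlapping gaps on %s rejected", ch)
    }
  }
  donor_up <- toupper(donor)
  count_hits <- function(pat, ch) {
    if (nchar(pat) == 0L) return(0L)
    hits <- gregexpr(pat, donor_up[[ch]], fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }
  target <- donor
  rows <- vector("list", nrow(gaps))
  for (k in seq_len(nrow(gaps))) {
    ch <- gaps$chrom[k]; s <- gaps$start[k]; e <- gaps$end[k]
    deleted <- substr(donor[[ch]], s + 1L, e)
    lf <- if (s >= flank_len) toupper(substr(donor[[ch]], s - flank_len + 1L, s)) else ""
    rf <- if (e + flank_len <= lens[[ch]]) toupper(substr(donor[[ch]], e + 1L, e + flank_len)) else ""
    at_edge <- nchar(lf) < flank_len || nchar(rf) < flank_len
    substr(target[[ch]], s + 1L, e) <- strrep("N", e - s)
    rows[[k]] <- data.frame(chrom = ch, gap_start = s, gap_end = e,
                            deleted_seq = deleted,
                            left_unique = count_hits(lf, ch) == 1L,
                            right_unique = count_hits(rf, ch) == 1L,
                            at_edge = at_edge, stringsAsFactors = FALSE)
  }
  list(target = target, truth = do.call(rbind, rows))
}
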