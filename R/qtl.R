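#' Per-bin likelihood-ratio (LOD) scan of a quantitative trait
#'
#' Single-marker normal-model scan over the bin genotype matrix: for each
#' bin, RILs with homozygous calls (a/b) and finite phenotypes are split
#' into the two genotype classes; with SS0 the total sum of squares about
#' the grand mean and SS1 the residual about the class means,
#' LOD = (n/2) log10(SS0/SS1) and PVE = 100 (1 - SS1/SS0). Heterozygous
#' and missing genotypes are excluded. Bins with fewer than
#' `min_informative` informative lines, or with only one genotype class,
#' get `NA`. A zero-variance phenotype yields LOD = 0 everywhere by
#' convention.
#'
#' @param geno character bin genotype matrix (bins x RILs).
#' @param phenotype numeric vector named by RIL (or ordered as the columns
#'   of `geno`).
#' @param min_informative minimum informative RILs per bin (default 10).
#' @param cofactors optional character vector of bin ids; the phenotype is
#'   residualized on their genotype scores (+1/-1/0) before scanning, a
#'   light-weight approximation to composite interval mapping.
#' @return data.frame: `bin_id`, `n`, `LOD`, `PVE`, `mean_a`, `mean_b`,
#'   `effect` (half the class-mean difference, a - b).
#' @export
lod_scan <- function(geno, phenotype, min_informative = 10,
                     cofactors = NULL) {
  stopifnot(is.matrix(geno))
  y <- align_phenotype(phenotype, colnames(geno))
  if (!is.null(cofactors)) {
    miss <- setdiff(cofactors, rownames(geno))
    if (length(miss)) abort("unknown cofactor bin(s): %s",
                            paste(miss, collapse = ", "))
    X <- t((geno[cofactors, , drop = FALSE] == "a") -
             (geno[cofactors, , drop = FALSE] == "b"))
    fit <- stats::lm(y ~ X, na.action = stats::na.exclude)
    y <- stats::residuals(fit) + mean(y, na.rm = TRUE)
  }
  n_bins <- nrow(geno)
  out <- data.frame(bin_id = rownames(geno), n = NA_integer_,
                    LOD = NA_real_, PVE = NA_real_, mean_a = NA_real_,
                    mean_b = NA_real_, effect = NA_real_,
                    stringsAsFactors = FALSE)
  zero_var <- stats::var(y[!is.na(y)]) == 0
  for (k in seq_len(n_bins)) {
    g <- geno[k, ]
    ok <- g %in% c("a", "b") & !is.na(y)
    n <- sum(ok)
    out$n[k] <- n
    if (n < min_informative) next
    gg <- g[ok]; yy <- y[ok]
    if (isTRUE(zero_var)) {
      out$LOD[k] <- 0; out$PVE[k] <- 0
      out$effect[k] <- 0
      next
    }
    if (length(unique(gg)) < 2L) next
    ma <- mean(yy[gg == "a"]); mb <- mean(yy[gg == "b"])
    ss0 <- sum((yy - mean(yy))^2)
    ss1 <- sum((yy - ifelse(gg == "a", ma, mb))^2)
    out$LOD[k] <- if (ss1 <= 0) Inf else (n / 2) * log10(ss0 / ss1)
    out$PVE[k] <- 100 * (1 - ss1 / ss0)
    out$mean_a[k] <- ma; out$mean_b[k] <- mb
    out$effect[k] <- (ma - mb) / 2
  }
  out
}

align_phenotype <- function(phenotype, rils) {
  if (!is.null(names(phenotype)) && !is.null(rils)) {
    y <- phenotype[rils]
  } else {
    if (!is.null(rils)) stopifnot(length(phenotype) == length(rils))
    y <- phenotype
  }
  as.numeric(y)
}

#' Call QTLs from a LOD scan
#'
#' Contiguous runs of bins with LOD above `threshold` (default 3.0,
#' i.e. QTL are called for LOD values > 3.0) are collapsed to their peak
#' bin; independent peaks separated by a sub-threshold valley become
#' separate calls. The support interval is the contiguous set of bins
#' around the peak with LOD >= peak - `drop` (default 1.5).
#'
#' @param scan data.frame from [lod_scan()].
#' @param bins bin coordinate table (`bin_id`, `chrom`, `start`, `end`).
#' @param threshold LOD call threshold (default 3.0, strict >).
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return data.frame: `peak_bin`, `chrom`, `peak_LOD`, `PVE`,
#'   `support_start_bin`, `support_end_bin`, `support_start`, `support_end`
#'   (physical bp of the support interval).
#' @export
call_qtls <- function(scan, bins, threshold = 3.0, drop = 1.5) {
  m <- merge(scan, bins, by = "bin_id", sort = FALSE)
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  calls <- list()
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, , drop = FALSE]
    above <- !is.na(sub$LOD) & sub$LOD > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values)) {
      i <- starts[seg]:ends[seg]
      peak <- i[which.max(sub$LOD[i])]
      lim <- sub$LOD[peak] - drop
      lo <- peak; while (lo > 1L && !is.na(sub$LOD[lo - 1L]) &&
                         sub$LOD[lo - 1L] >= lim) lo <- lo - 1L
      hi <- peak; while (hi < nrow(sub) && !is.na(sub$LOD[hi + 1L]) &&
                         sub$LOD[hi + 1L] >= lim) hi <- hi + 1L
      calls[[length(calls) + 1L]] <- data.frame(
        peak_bin = sub$bin_id[peak], chrom = ch,
        peak_LOD = sub$LOD[peak], PVE = sub$PVE[peak],
        support_start_bin = sub$bin_id[lo],
        support_end_bin = sub$bin_id[hi],
        support_start = sub$start[lo], support_end = sub$end[hi],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(peak_bin = character(0), chrom = character(0),
                      peak_LOD = numeric(0), PVE = numeric(0),
                      support_start_bin = character(0),
                      support_end_bin = character(0),
                      support_start = numeric(0), support_end = numeric(0)))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Map a qualitative (monogenic) trait by co-segregation
#'
#' For every bin, counts the RILs whose homozygous genotype disagrees with
#' the class-to-parent assignment, evaluated under both polarities with the
#' better one kept. The best bin minimizes the mismatch count (ties broken
#' by smaller physical span, then lower coordinate). Also reports the 1:1
#' segregation chi-square over informative lines at the best bin and the
#' candidate region: the contiguous run of bins around the best bin whose
#' mismatch count stays minimal, i.e. bounded by the nearest bins where a
#' recombinant line's phenotype flips the co-segregation.
#'
#' @param geno character bin genotype matrix (bins x RILs).
#' @param classes character/factor vector of two phenotype classes, named
#'   by RIL or ordered as the columns of `geno`.
#' @param bins bin coordinate table (`bin_id`, `chrom`, `start`, `end`).
#' @param min_class minimum RILs per class (default 5).
#' @return list: `best_bin`, `chrom`, `mismatches`, `polarity`
#'   (class assigned to the `a` genotype), `chisq_1to1`,
#'   `region` (`chrom`, `start`, `end`), `per_bin` (mismatch count per bin).
#' @export
map_qualitative <- function(geno, classes, bins, min_class = 5) {
  if (!is.null(names(classes))) classes <- classes[colnames(geno)]
  stopifnot(length(classes) == ncol(geno))
  lev <- unique(stats::na.omit(as.character(classes)))
  if (length(lev) != 2L) abort("need exactly two phenotype classes")
  if (any(table(classes) < min_class)) {
    abort("each phenotype class needs >= %d RILs", min_class)
  }
  cl <- as.character(classes)
  n_bins <- nrow(geno)
  mm <- integer(n_bins)
  pol <- character(n_bins)
  for (k in seq_len(n_bins)) {
    g <- geno[k, ]
    ok <- g %in% c("a", "b") & !is.na(cl)
    m1 <- sum(ok & ((g == "a" & cl != lev[1L]) | (g == "b" & cl != lev[2L])))
    m2 <- sum(ok & ((g == "a" & cl != lev[2L]) | (g == "b" & cl != lev[1L])))
    mm[k] <- min(m1, m2)
    pol[k] <- if (m1 <= m2) lev[1L] else lev[2L]
  }
  ord <- match(rownames(geno), bins$bin_id)
  span <- bins$end[ord] - bins$start[ord]
  best <- order(mm, span, bins$chrom[ord], bins$start[ord])[1L]
  ## candidate region: contiguous minimal-mismatch run around the best bin
  bch <- bins$chrom[ord][best]
  on_ch <- which(bins$chrom[ord] == bch)
  on_ch <- on_ch[order(bins$start[ord][on_ch])]
  at <- match(best, on_ch)
  lo <- at; while (lo > 1L && mm[on_ch[lo - 1L]] == mm[best]) lo <- lo - 1L
  hi <- at; while (hi < length(on_ch) && mm[on_ch[hi + 1L]] == mm[best]) hi <- hi + 1L
  g <- geno[best, ]
  inf <- g %in% c("a", "b")
  na_ <- sum(g[inf] == "a"); nb_ <- sum(g[inf] == "b")
  chisq <- (na_ - nb_)^2 / (na_ + nb_)
  list(best_bin = rownames(geno)[best], chrom = bch,
       mismatches = mm[best], polarity = pol[best],
       chisq_1to1 = chisq,
       region = data.frame(chrom = bch,
                           start = bins$start[ord][on_ch[lo]],
                           end = bins$end[ord][on_ch[hi]]),
       per_bin = data.frame(bin_id = rownames(geno), mismatches = mm,
                            stringsAsFactors = FALSE))
}

#' Per-batch PVE at QTL peaks with cross-batch concordance
#'
#' Evaluates the percent variance explained at given peak bins in each
#' phenotype batch (e.g. year of phenotyping) and flags whether the batches
#' agree: peaks on the same chromosome within `radius_cM` on the linkage
#' map.
#'
#' @param geno bin genotype matrix (bins x RILs).
#' @param phenotypes named list of phenotype vectors, one per batch.
#' @param linkage_map a `linkage_map` (for peak-to-peak cM distances).
#' @param min_informative minimum informative RILs per bin.
#' @param radius_cM concordance radius in cM (default 10).
#' @return list: `pve` (data.frame `batch`, `peak_bin`, `LOD`, `PVE`),
#'   `concordant` (logical).
#' @export
pve_report <- function(geno, phenotypes, linkage_map,
                       min_informative = 10, radius_cM = 10) {
  stopifnot(is.list(phenotypes), !is.null(names(phenotypes)))
  map <- linkage_map$map
  rows <- list()
  for (b in names(phenotypes)) {
    scan <- lod_scan(geno, phenotypes[[b]], min_informative)
    if (all(is.na(scan$LOD))) next
    peak <- which.max(scan$LOD)
    rows[[b]] <- data.frame(batch = b, peak_bin = scan$bin_id[peak],
                            LOD = scan$LOD[peak], PVE = scan$PVE[peak],
                            stringsAsFactors = FALSE)
  }
  pve <- do.call(rbind, rows)
  rownames(pve) <- NULL
  concordant <- NA
  if (nrow(pve) >= 2L) {
    at <- match(pve$peak_bin, map$bin_id)
    same_group <- length(unique(map$group[at])) == 1L
    concordant <- same_group &&
      diff(range(map$cM_cumulative[at])) <= radius_cM
  }
  list(pve = pve, concordant = concordant)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Churchill-Doerge style: the phenotype is permuted against the genotype
#' matrix `n_perm` times, the genome-wide maximum LOD recorded each time,
#' and the `1 - alpha` quantile returned. Off by default in the pipeline,
#' which uses the conventional fixed threshold of 3.0.
#'
#' @param geno bin genotype matrix (bins x RILs).
#' @param phenotype numeric phenotype vector.
#' @param n_perm number of permutations (default 200).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param min_informative minimum informative RILs per bin.
#' @return list: `threshold`, `max_lods` (the permutation distribution).
#' @export
permutation_threshold <- function(geno, phenotype, n_perm = 200,
                                  alpha = 0.05, min_informative = 10) {
  y <- align_phenotype(phenotype, colnames(geno))
  mx <- vapply(seq_len(n_perm), function(i) {
    sc <- lod_scan(geno, sample(y), min_informative)
    if (all(is.na(sc$LOD))) 0 else max(sc$LOD, na.rm = TRUE)
  }, numeric(1L))
  list(threshold = stats::quantile(mx, 1 - alpha, names = FALSE),
       max_lods = mx)
}
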