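#' Filter SNPs to segregating, well-observed sites
#'
#' Retains sites where the two parents carry different alleles and the
#' per-population missing fraction is strictly below `max_missing` (default
#' 0.60, so a site missing in exactly 60% of lines is dropped). Sites where
#' either parental allele is unknown cannot be oriented and are dropped.
#'
#' @param raw data.frame with at least `chrom`, `pos`, `allele_p1`,
#'   `allele_p2`, `missing_frac`.
#' @param max_missing strict upper bound on the missing fraction.
#' @return the retained rows, sorted by (`chrom`, `pos`), with an attribute
#'   `"dropped"` giving counts per reason.
#' @export
filter_snps <- function(raw, max_missing = 0.60) {
  stopifnot(all(c("chrom", "pos", "allele_p1", "allele_p2", "missing_frac")
                %in% names(raw)))
  parent_na <- is.na(raw$allele_p1) | is.na(raw$allele_p2)
  same <- !parent_na & raw$allele_p1 == raw$allele_p2
  toomiss <- !parent_na & !same & raw$missing_frac >= max_missing
  keep <- !(parent_na | same | toomiss)
  out <- raw[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(parent_missing = sum(parent_na),
                            monomorphic_parents = sum(same),
                            too_missing = sum(toomiss))
  out
}

#' Impute the unobserved parent's allele from population SNPs
#'
#' When only one parent (P2) was genotyped, the other parental allele at a
#' biallelic site is taken as the population allele that differs from the
#' P2 allele. Monomorphic sites (nothing to orient) and sites with more
#' than two observed alleles are dropped.
#'
#' @param sites data.frame with `chrom`, `pos`, `alleles` (comma-separated
#'   distinct alleles observed in the population) and `allele_p2`.
#' @return data.frame with `allele_p1` filled in; attribute `"dropped"`
#'   holds counts per reason.
#' @export
infer_parent_alleles <- function(sites) {
  stopifnot(all(c("chrom", "pos", "alleles", "allele_p2") %in% names(sites)))
  al <- strsplit(sites$alleles, ",", fixed = TRUE)
  nal <- lengths(al)
  multi <- nal > 2L
  mono <- nal < 2L
  keep <- !multi & !mono
  p1 <- rep(NA_character_, nrow(sites))
  for (i in which(keep)) {
    other <- setdiff(al[[i]], sites$allele_p2[i])
    if (length(other) != 1L) { keep[i] <- FALSE; next }  # p2 not among alleles
    p1[i] <- other
  }
  out <- sites[keep, , drop = FALSE]
  out$allele_p1 <- p1[keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(multiallelic = sum(multi),
                            monomorphic = sum(mono),
                            p2_absent = sum(!multi & !mono) - nrow(out))
  out
}

#' Label one sliding window from its parental SNP counts
#'
#' The calling rule for a window of consecutive SNPs: a P1:P2 ratio of
#' `hi`:`lo` or higher is the parent-1 genotype (`"a"`), `lo`:`hi` or lower
#' the parent-2 genotype (`"b"`), anything between is heterozygous (`"h"`).
#' With the default 15-SNP window this is the 11:4 rule. Counts may be
#' fractional (heterozygous observations contribute 0.5 to each side).
#'
#' @param n_p1,n_p2 numeric vectors of per-window counts.
#' @param hi,lo the ratio thresholds (defaults 11 and 4).
#' @return character vector over `"a"`, `"b"`, `"h"`.
#' @export
window_label <- function(n_p1, n_p2, hi = 11, lo = 4) {
  ifelse(n_p1 * lo >= n_p2 * hi, "a",
         ifelse(n_p2 * lo >= n_p1 * hi, "b", "h"))
}

## window-call one chromosome row of observation codes; returns symbols
call_windows_row <- function(obs, window, hi, lo, min_informative) {
  n <- length(obs)
  calls <- rep(NA_character_, n)
  idx <- which(obs != GT_MISSING)
  m <- length(idx)
  v <- obs[idx]
  n_inf <- sum(v == GT_P1 | v == GT_P2)
  if (n_inf == 0L) return(rep("-", n))
  if (m < window) {
    ## too few observations for any window: whole-chromosome majority,
    ## flagged low-confidence by the caller
    s1 <- sum(v == GT_P1); s2 <- sum(v == GT_P2)
    lab <- if (s1 > s2) "a" else if (s2 > s1) "b" else "h"
    return(rep(lab, n))
  }
  is1 <- (v == GT_P1) + 0.5 * (v == GT_HET)
  is2 <- (v == GT_P2) + 0.5 * (v == GT_HET)
  inf <- as.numeric(v == GT_P1 | v == GT_P2)
  w1 <- roll_sum(is1, window)
  w2 <- roll_sum(is2, window)
  winf <- roll_sum(inf, window)
  wlab <- window_label(w1, w2, hi, lo)
  wlab[winf < min_informative] <- NA  # too few informative SNPs: no label
  ## per-SNP projection: majority label over covering windows
  ca <- roll_count(wlab == "a", m, window)
  cb <- roll_count(wlab == "b", m, window)
  ch <- roll_count(wlab == "h", m, window)
  compact <- rep(NA_character_, m)
  prev <- NA_character_
  counts <- cbind(a = ca, b = cb, h = ch)
  labs <- c("a", "b", "h")
  for (i in seq_len(m)) {
    ci <- counts[i, ]
    if (sum(ci) == 0) { compact[i] <- NA; next }
    mx <- max(ci)
    tied <- labs[ci == mx]
    lab <- if (length(tied) == 1L) tied
      else if (!is.na(prev) && prev %in% tied) prev   # tie -> previous call
      else if ("h" %in% tied) "h"
      else first_window_label(wlab, i, m, window, tied)
    compact[i] <- lab
    prev <- lab
  }
  calls[idx] <- compact
  fill_nearest(calls)
}

## number of non-NA TRUE window labels covering compact position i
roll_count <- function(flag, m, window) {
  flag[is.na(flag)] <- FALSE
  nw <- length(flag)
  cs <- cumsum(c(0, flag))
  lo_w <- pmax(1L, seq_len(m) - window + 1L)
  hi_w <- pmin(seq_len(m), nw)
  ok <- hi_w >= lo_w
  out <- numeric(m)
  out[ok] <- cs[hi_w[ok] + 1L] - cs[lo_w[ok]]
  out
}

## leftmost covering labelled window's label among the tied set
first_window_label <- function(wlab, i, m, window, tied) {
  lo_w <- max(1L, i - window + 1L)
  hi_w <- min(i, length(wlab))
  for (w in lo_w:hi_w) {
    if (!is.na(wlab[w]) && wlab[w] %in% tied) return(wlab[w])
  }
  tied[1L]
}

#' Smooth observations into genotype calls by sliding window
#'
#' For every RIL and chromosome, windows of `window` consecutive non-missing
#' observations are labelled by [window_label()] (heterozygous observations
#' count 0.5 to each side; windows with fewer than `min_informative`
#' homozygous observations emit no label), window labels are projected back
#' to per-SNP calls by majority vote over the covering windows (ties broken
#' toward the previous SNP's call), and SNPs without any labelled window —
#' including missing observations — take the nearest called SNP's label.
#' Chromosomes with fewer non-missing observations than one window get a
#' whole-chromosome majority call, flagged low-confidence.
#'
#' @param obs integer observation matrix (RILs x SNPs, codes 0/1/2/3).
#' @param snps SNP table matching the columns of `obs`.
#' @param window window size in SNPs (default 15).
#' @param hi,lo ratio thresholds (defaults 11:4).
#' @param min_informative minimum homozygous observations per labelled
#'   window (default 8).
#' @return character matrix of calls (`"a"`,`"b"`,`"h"`,`"-"`), same shape
#'   as `obs`, with attribute `"low_confidence"` (data.frame ril, chrom).
#' @export
call_windows <- function(obs, snps, window = 15, hi = 11, lo = 4,
                         min_informative = 8) {
  stopifnot(is.matrix(obs), ncol(obs) == nrow(snps))
  track <- matrix("-", nrow = nrow(obs), ncol = ncol(obs),
                  dimnames = dimnames(obs))
  lowconf <- list()
  for (ch in unique(snps$chrom)) {
    j <- which(snps$chrom == ch)
    for (i in seq_len(nrow(obs))) {
      row <- obs[i, j]
      n_obs <- sum(row != GT_MISSING)
      track[i, j] <- call_windows_row(row, window, hi, lo, min_informative)
      if (n_obs > 0L && n_obs < window) {
        lowconf[[length(lowconf) + 1L]] <-
          data.frame(ril = rownames(obs)[i], chrom = ch,
                     stringsAsFactors = FALSE)
      }
    }
  }
  attr(track, "low_confidence") <- if (length(lowconf))
    do.call(rbind, lowconf) else
    data.frame(ril = character(0), chrom = character(0))
  track
}

#' Detect recombination breakpoints from smoothed genotype tracks
#'
#' A breakpoint is the boundary between two maximal runs of different calls
#' along a chromosome. Runs shorter than `min_run` SNPs are first absorbed
#' into their longer neighbour (suppressing spurious double-recombinants
#' from low-coverage noise). The breakpoint coordinate is the floor of the
#' mean of the two flanking SNP positions.
#'
#' @param track character call matrix from [call_windows()] (or a single
#'   row as a vector together with a single-chromosome `snps`).
#' @param snps SNP table matching the columns of `track`.
#' @param min_run minimum run length in SNPs kept as a real segment
#'   (default 5).
#' @return data.frame: `ril`, `chrom`, `left_pos`, `right_pos`, `midpoint`,
#'   `from`, `to`.
#' @export
detect_breakpoints <- function(track, snps, min_run = 5) {
  if (!is.matrix(track)) track <- matrix(track, nrow = 1L,
                                         dimnames = list("RIL001", NULL))
  stopifnot(ncol(track) == nrow(snps))
  rows <- list()
  for (ch in unique(snps$chrom)) {
    j <- which(snps$chrom == ch)
    pos <- snps$pos[j]
    for (i in seq_len(nrow(track))) {
      calls <- track[i, j]
      if (all(calls == "-")) next
      r <- rle(calls)
      r <- absorb_short_runs(r, min_run)
      if (length(r$lengths) < 2L) next
      ends <- cumsum(r$lengths)
      for (k in seq_len(length(r$lengths) - 1L)) {
        lp <- pos[ends[k]]
        rp <- pos[ends[k] + 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          ril = rownames(track)[i], chrom = ch,
          left_pos = lp, right_pos = rp,
          midpoint = floor((lp + rp) / 2),
          from = r$values[k], to = r$values[k + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ril = character(0), chrom = character(0),
                      left_pos = numeric(0), right_pos = numeric(0),
                      midpoint = numeric(0), from = character(0),
                      to = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## iteratively absorb runs shorter than min_run into the longer neighbour
## (ties -> left); adjacent equal-valued runs are re-merged after each pass
absorb_short_runs <- function(r, min_run) {
  repeat {
    n <- length(r$lengths)
    if (n <= 1L) return(r)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(r)
    k <- short[which.min(r$lengths[short])][1L]
    left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
    right_len <- if (k < n) r$lengths[k + 1L] else -1L
    into <- if (left_len >= right_len) k - 1L else k + 1L
    r$values[k] <- r$values[into]
    merged <- rle(rep(r$values, r$lengths))
    if (identical(merged, r)) return(r)
    r <- merged
  }
}
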