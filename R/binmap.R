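#' Build recombination bins from population breakpoints
#'
#' All breakpoint midpoints in the population are snapped down to a
#' `min_interval` grid (default 20 kb) along each chromosome (a midpoint in
#' the first, unrepresentable cell is assigned to the first grid point, so
#' the transition is kept at the end of one minimal interval). The snapped
#' cut points partition the chromosome into intervals; each RIL's genotype
#' per interval is read from its own breakpoint-delimited runs on the
#' track, with the transition placed at the snapped cut (segments that
#' vanish under snapping are dropped). Adjacent intervals with identical
#' genotype columns across all RILs are merged into a single recombination
#' bin.
#'
#' @param breakpoints population breakpoint data.frame from
#'   [detect_breakpoints()].
#' @param track call matrix from [call_windows()].
#' @param snps SNP table matching `track` columns.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param min_interval grid size in bp (default 20000).
#' @return object of class `bin_map`: list with `bins` (data.frame
#'   `bin_id`, `chrom`, `start`, `end`; 0-based half-open) and `geno`
#'   (character matrix bins x RILs of `"a"/"b"/"h"/"-"`).
#' @export
build_bins <- function(breakpoints, track, snps, chrom_lengths,
                       min_interval = 20000) {
  stopifnot(is.matrix(track), ncol(track) == nrow(snps))
  if (nrow(breakpoints) > 0) {
    bad <- !breakpoints$chrom %in% names(chrom_lengths) |
      breakpoints$midpoint < 0 |
      breakpoints$midpoint > chrom_lengths[breakpoints$chrom]
    if (any(bad)) abort("breakpoint outside chromosome")
  }
  rils <- rownames(track)
  snap <- function(mid, L) {
    s <- floor(mid / min_interval) * min_interval
    s[s == 0] <- min_interval  # first-cell transition kept at first grid point
    s[s >= L] <- NA            # unrepresentable at the far edge
    s
  }
  bins <- list(); cols <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    bch <- breakpoints[breakpoints$chrom == ch, , drop = FALSE]
    bch$cut <- snap(bch$midpoint, L)
    bch <- bch[!is.na(bch$cut), , drop = FALSE]
    cuts <- sort(unique(bch$cut))
    starts <- c(0, cuts)
    ends <- c(cuts, L)
    j <- which(snps$chrom == ch)
    colmat <- matrix("-", nrow = length(starts), ncol = length(rils))
    for (i in seq_along(rils)) {
      base <- majority_call(track[i, j])
      rb <- bch[bch$ril == rils[i], , drop = FALSE]
      if (nrow(rb) == 0L) { colmat[, i] <- base; next }
      rb <- rb[order(rb$midpoint), , drop = FALSE]
      ## state sequence: from[1], to[1], to[2], ... at snapped cuts; a
      ## segment whose two cuts collide under snapping vanishes
      states <- c(rb$from[1L], rb$to)
      at <- c(0, rb$cut)
      keep <- !duplicated(at, fromLast = TRUE)
      states <- states[keep]; at <- at[keep]
      chg <- c(TRUE, states[-1L] != states[-length(states)])
      states <- states[chg]; at <- at[chg]
      colmat[, i] <- states[findInterval(starts, at)]
    }
    ## merge adjacent intervals with identical genotype columns
    if (length(starts) > 1L) {
      same <- vapply(2:length(starts), function(k)
        all(colmat[k, ] == colmat[k - 1L, ]), logical(1L))
      keep <- c(TRUE, !same)
      first <- which(keep)
      last <- c(first[-1L] - 1L, length(starts))
      starts <- starts[first]; ends <- ends[last]
      colmat <- colmat[first, , drop = FALSE]
    }
    bins[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                             stringsAsFactors = FALSE)
    cols[[ch]] <- colmat
  }
  bins <- do.call(rbind, bins)
  bins$bin_id <- sprintf("bin%04d", seq_len(nrow(bins)))
  bins <- bins[, c("bin_id", "chrom", "start", "end")]
  rownames(bins) <- NULL
  geno <- do.call(rbind, cols)
  dimnames(geno) <- list(bins$bin_id, rils)
  structure(list(bins = bins, geno = geno), class = "bin_map")
}

## majority of a/b/h calls in a vector ("-" excluded); ties -> first seen
majority_call <- function(x) {
  x <- x[x != "-"]
  if (!length(x)) return("-")
  tab <- table(factor(x, levels = unique(x)))
  names(tab)[which.max(tab)]
}

#' Recombination fraction between two bin genotype columns
#'
#' r is the fraction of discordant homozygous (a/b) calls among RILs
#' informative in both bins; heterozygous and missing calls are excluded.
#' Capped at 0.4999 so the Kosambi transform stays finite. With fewer than
#' `min_informative` jointly informative lines, r is undefined (`NA`).
#'
#' @param col1,col2 character genotype columns of equal length.
#' @param min_informative minimum jointly informative RILs (default 10).
#' @return recombination fraction in \[0, 0.4999\], or `NA`.
#' @export
pairwise_r <- function(col1, col2, min_informative = 10) {
  stopifnot(length(col1) == length(col2))
  ok <- col1 %in% c("a", "b") & col2 %in% c("a", "b")
  n <- sum(ok)
  if (n < min_informative) return(NA_real_)
  disc <- sum(col1[ok] != col2[ok])
  min(disc / n, 0.4999)
}

## all pairwise r between rows of a genotype matrix, via +1/-1/0 coding
pairwise_r_matrix <- function(geno, min_informative = 10) {
  M <- matrix(0, nrow = nrow(geno), ncol = ncol(geno))
  M[geno == "a"] <- 1
  M[geno == "b"] <- -1
  S <- M %*% t(M)               # concordant - discordant
  N <- abs(M) %*% t(abs(M))     # jointly informative
  R <- (N - S) / (2 * pmax(N, 1))
  R[N < min_informative] <- NA
  R <- pmin(R, 0.4999)
  dimnames(R) <- list(rownames(geno), rownames(geno))
  R
}

#' Kosambi map function
#'
#' Converts a recombination fraction r to genetic distance
#' d = 25 ln((1 + 2r) / (1 - 2r)) cM. For small r, d is approximately 100 r.
#'
#' @param r recombination fraction(s), 0 <= r < 0.5.
#' @return distance(s) in centimorgans.
#' @export
kosambi_cM <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    abort("kosambi_cM requires 0 <= r < 0.5")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d genetic distance(s) in cM.
#' @return recombination fraction(s): r = tanh(d / 50) / 2.
#' @export
kosambi_r <- function(d) {
  if (any(is.na(d)) || any(d < 0)) abort("kosambi_r requires d >= 0")
  tanh(d / 50) / 2
}

#' Construct a genetic linkage map from recombination bins
#'
#' Bins are grouped by connected components of the graph whose edges join
#' bin pairs with r below `r_max` (single-linkage clustering); within each
#' group, order follows the path through the minimum-spanning tree of the
#' r-graph (the tree's diameter path), seeded and oriented by physical
#' order, with a fall-back to physical order when the MST branches.
#' Adjacent distances are Kosambi-transformed r; optionally the RIL
#' map-expansion correction r = R / (2 - 2R) is applied first.
#'
#' @param bin_map a `bin_map` from [build_bins()].
#' @param r_max linkage threshold (default 0.25).
#' @param min_informative minimum jointly informative RILs per pair.
#' @param ril_correct apply the RIL correction R -> r before Kosambi.
#' @return object of class `linkage_map`: data.frame `map` with `group`,
#'   `bin_id`, `chrom`, `start`, `end`, `order`, `r_adjacent`,
#'   `cM_adjacent`, `cM_cumulative`; plus `total_cM` and `n_groups`.
#' @export
construct_linkage_map <- function(bin_map, r_max = 0.25,
                                  min_informative = 10,
                                  ril_correct = FALSE) {
  bins <- bin_map$bins
  geno <- bin_map$geno
  if (nrow(bins) < 2L) abort("need >= 2 bins to build a map")
  R <- pairwise_r_matrix(geno, min_informative)
  adj <- !is.na(R) & R < r_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  singletons <- sum(comp$csize == 1L)
  if (singletons > 0L) {
    warning(sprintf("%d bin(s) unlinked to every other bin; emitted as singleton group(s)",
                    singletons))
  }
  phys_rank <- order(order(bins$chrom, bins$start))
  rows <- list()
  group_id <- 0L
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    group_id <- group_id + 1L
    ord <- order_group(members, R, phys_rank)
    sub <- bins[ord, , drop = FALSE]
    r_adj <- c(NA, vapply(seq_len(length(ord) - 1L), function(k)
      R[ord[k], ord[k + 1L]], numeric(1L)))
    r_eff <- r_adj
    if (ril_correct) r_eff <- r_adj / (2 - 2 * r_adj)
    cm_adj <- ifelse(is.na(r_eff), NA,
                     kosambi_cM(pmin(ifelse(is.na(r_eff), 0, r_eff), 0.4999)))
    cm_adj[1L] <- 0
    ## unestimable adjacencies (too few informative lines) contribute 0 cM
    cm_cum <- cumsum(ifelse(is.na(cm_adj), 0, cm_adj))
    rows[[group_id]] <- data.frame(
      group = group_id, bin_id = sub$bin_id, chrom = sub$chrom,
      start = sub$start, end = sub$end, order = seq_along(ord),
      r_adjacent = r_adj, cM_adjacent = cm_adj, cM_cumulative = cm_cum,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  structure(list(map = map,
                 total_cM = sum(map$cM_adjacent, na.rm = TRUE),
                 n_groups = group_id),
            class = "linkage_map")
}

## order the member bins of one linkage group: MST diameter path when the
## MST is a path, else physical order; orientation follows physical order
order_group <- function(members, R, phys_rank) {
  if (length(members) <= 2L) {
    return(members[order(phys_rank[members])])
  }
  Rsub <- R[members, members, drop = FALSE]
  w <- Rsub
  w[is.na(w)] <- 0.4999
  g <- igraph::graph_from_adjacency_matrix(w + 1e-9, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  path <- as.integer(igraph::get_diameter(mst))
  ord <- if (length(path) == length(members)) members[path]
    else members[order(phys_rank[members])]  # branching MST: physical seed
  if (stats::cor(seq_along(ord), phys_rank[ord], method = "spearman") < 0) {
    ord <- rev(ord)
  }
  ord
}

#' Flag bins whose linkage disagrees with their physical position
#'
#' A bin is flagged when its recombination fraction to both physical
#' neighbours exceeds `r_flag` while some non-neighbour bin shows
#' r below `r_link`; the proposed new position is adjacent to the
#' minimum-r partner. This is the decision rule behind moving bins with
#' abnormal linkage to their proper map position.
#'
#' @param bin_map a `bin_map`.
#' @param r_flag neighbour-discordance threshold (default 0.15).
#' @param r_link tight-linkage threshold for the rescue partner
#'   (default 0.05).
#' @param min_informative minimum jointly informative RILs per pair.
#' @return data.frame: `bin_id`, `chrom`, `start`, `r_left`, `r_right`,
#'   `partner_bin`, `partner_r`, `proposed_after` (partner bin id).
#' @export
flag_misplaced_bins <- function(bin_map, r_flag = 0.15, r_link = 0.05,
                                min_informative = 10) {
  bins <- bin_map$bins
  R <- pairwise_r_matrix(bin_map$geno, min_informative)
  n <- nrow(bins)
  phys <- order(bins$chrom, bins$start)
  rows <- list()
  for (k in seq_len(n)) {
    at <- which(phys == k)  # position of bin k in physical order
    nb <- integer(0)
    if (at > 1L && bins$chrom[phys[at - 1L]] == bins$chrom[k]) {
      nb <- c(nb, phys[at - 1L])
    }
    if (at < n && bins$chrom[phys[at + 1L]] == bins$chrom[k]) {
      nb <- c(nb, phys[at + 1L])
    }
    if (!length(nb)) next
    r_nb <- R[k, nb]
    if (any(is.na(r_nb)) || !all(r_nb > r_flag)) next
    others <- setdiff(seq_len(n), c(k, nb))
    r_oth <- R[k, others]
    if (!any(!is.na(r_oth) & r_oth < r_link)) next
    best <- others[which.min(r_oth)]
    rows[[length(rows) + 1L]] <- data.frame(
      bin_id = bins$bin_id[k], chrom = bins$chrom[k], start = bins$start[k],
      r_left = if (length(nb) >= 1L) r_nb[1L] else NA,
      r_right = if (length(nb) >= 2L) r_nb[2L] else NA,
      partner_bin = bins$bin_id[best], partner_r = R[k, best],
      proposed_after = bins$bin_id[best], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(bin_id = character(0), chrom = character(0),
                      start = numeric(0), r_left = numeric(0),
                      r_right = numeric(0), partner_bin = character(0),
                      partner_r = numeric(0), proposed_after = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of a bin map by chromosome
#'
#' Given per-chromosome length, bin count, linkage length and SNP count,
#' computes SNP density per kb, a totals row, the mean physical bin length
#' and the mean inter-bin genetic interval — the standard summary table of
#' a bin-map study.
#'
#' @param per_chrom data.frame with `chrom`, `length_bp`, `n_bins`,
#'   `linkage_cM`, `n_snps`.
#' @return list with `table` (input plus `snp_density_kb` and a `Total`
#'   row), `mean_bin_length_kb`, `mean_interval_cM`.
#' @export
bin_map_summary <- function(per_chrom) {
  stopifnot(all(c("chrom", "length_bp", "n_bins", "linkage_cM", "n_snps")
                %in% names(per_chrom)))
  tab <- per_chrom
  tab$snp_density_kb <- tab$n_snps / (tab$length_bp / 1000)
  total <- data.frame(chrom = "Total",
                      length_bp = sum(tab$length_bp),
                      n_bins = sum(tab$n_bins),
                      linkage_cM = sum(tab$linkage_cM),
                      n_snps = sum(tab$n_snps))
  total$snp_density_kb <- total$n_snps / (total$length_bp / 1000)
  list(table = rbind(tab, total),
       mean_bin_length_kb = total$length_bp / total$n_bins / 1000,
       mean_interval_cM = total$linkage_cM / total$n_bins)
}

#' Gap statistics of assemblies before/after correction and filling
#'
#' @param assemblies data.frame with `strain`, `chrom_length_bp`,
#'   `gap_length_bp`, `gap_number`.
#' @param filled_pairs optional data.frame `before`, `after` naming strain
#'   rows; the number of gaps filled is `gap_number[before] -
#'   gap_number[after]`.
#' @return the input with `gap_ratio` added, and `filled_gaps` per pair.
#' @export
gap_fill_summary <- function(assemblies, filled_pairs = NULL) {
  stopifnot(all(c("strain", "chrom_length_bp", "gap_length_bp", "gap_number")
                %in% names(assemblies)))
  assemblies$gap_ratio <- assemblies$gap_length_bp / assemblies$chrom_length_bp
  out <- list(table = assemblies)
  if (!is.null(filled_pairs)) {
    gn <- stats::setNames(assemblies$gap_number, assemblies$strain)
    out$filled_gaps <- data.frame(
      before = filled_pairs$before, after = filled_pairs$after,
      filled = unname(gn[filled_pairs$before] - gn[filled_pairs$after]))
  }
  out
}
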