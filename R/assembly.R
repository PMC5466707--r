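#' Anchor unplaced scaffolds with the bin map as a guide
#'
#' Each scaffold carries one or more bins with genotype columns; the
#' scaffold is placed next to the anchored map bin with the smallest
#' recombination fraction to any of its bins. Orientation is resolved only
#' when at least two scaffold bins map: it follows whether the partners'
#' map positions increase or decrease along the scaffold.
#'
#' @param scaffold_bins list: per scaffold, a character genotype matrix
#'   (its bins in scaffold order x RILs) — scaffolds without bins may be
#'   entries with 0 rows.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param linkage_map a `linkage_map` over the anchored bins.
#' @param bin_map the anchored `bin_map` (for the partner genotype columns).
#' @param r_max scaffolds whose best r is >= this are left unanchored.
#' @param min_informative minimum jointly informative RILs per pair.
#' @return list with `anchors` (data.frame `scaffold`, `chrom`, `after_bin`,
#'   `order_index`, `orientation`, `best_r`, `n_bins`) and `unanchored`
#'   (character vector with reasons as names).
#' @export
anchor_scaffolds <- function(scaffold_bins, scaffold_lengths, linkage_map,
                             bin_map, r_max = 0.25, min_informative = 10) {
  map <- linkage_map$map
  geno <- bin_map$geno
  anchors <- list()
  unanchored <- character(0)
  for (sc in names(scaffold_bins)) {
    sb <- scaffold_bins[[sc]]
    if (is.null(sb) || nrow(sb) == 0L) {
      unanchored[sc] <- "no bins (no linkage signal)"
      next
    }
    ## best map partner per scaffold bin
    partner <- rep(NA_integer_, nrow(sb))
    partner_r <- rep(NA_real_, nrow(sb))
    for (k in seq_len(nrow(sb))) {
      rs <- vapply(seq_len(nrow(geno)), function(j)
        pairwise_r(sb[k, ], geno[j, ], min_informative), numeric(1L))
      if (all(is.na(rs))) next
      partner[k] <- which.min(rs)
      partner_r[k] <- min(rs, na.rm = TRUE)
    }
    if (all(is.na(partner_r)) || min(partner_r, na.rm = TRUE) >= r_max) {
      unanchored[sc] <- "best linkage too weak"
      next
    }
    best_k <- which.min(partner_r)
    best_bin <- rownames(geno)[partner[best_k]]
    mrow <- map[map$bin_id == best_bin, ][1L, ]
    orientation <- "unknown"
    ok <- which(!is.na(partner))
    if (length(ok) >= 2L) {
      pos <- map$order[match(rownames(geno)[partner[ok]], map$bin_id)]
      tr <- stats::cor(seq_along(ok), pos, method = "spearman")
      if (!is.na(tr) && tr > 0) orientation <- "+"
      if (!is.na(tr) && tr < 0) orientation <- "-"
    }
    anchors[[sc]] <- data.frame(
      scaffold = sc, chrom = mrow$chrom, after_bin = best_bin,
      order_index = mrow$order, orientation = orientation,
      best_r = partner_r[best_k], n_bins = nrow(sb),
      stringsAsFactors = FALSE)
  }
  anchors <- if (length(anchors)) do.call(rbind, anchors) else
    data.frame(scaffold = character(0), chrom = character(0),
               after_bin = character(0), order_index = integer(0),
               orientation = character(0), best_r = numeric(0),
               n_bins = integer(0))
  rownames(anchors) <- NULL
  list(anchors = anchors, unanchored = unanchored)
}

#' Build an AGP-style placement table from anchors
#'
#' Components are laid out per chromosome in anchor order with a fixed
#' 100-N spacer gap between consecutive components (AGP 2.1 convention for
#' map-derived joins).
#'
#' @param anchors data.frame as returned by [anchor_scaffolds()]
#'   (`scaffold`, `chrom`, `order_index`, `orientation`).
#' @param scaffold_lengths named vector of component lengths (bp).
#' @param spacer gap length between components (default 100).
#' @return AGP data.frame (`object`, `object_beg`, `object_end`,
#'   `part_number`, `component_type`, `component_id`, `component_beg`,
#'   `component_end`, `orientation`); gap rows have `component_type = "U"`.
#' @export
agp_from_anchors <- function(anchors, scaffold_lengths, spacer = 100) {
  rows <- list()
  for (ch in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$order_index), , drop = FALSE]
    at <- 0L; part <- 0L
    for (k in seq_len(nrow(sub))) {
      if (k > 1L) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = ch, object_beg = at + 1L, object_end = at + spacer,
          part_number = part, component_type = "U", component_id = "gap",
          component_beg = spacer, component_end = "scaffold",
          orientation = "na", stringsAsFactors = FALSE)
        at <- at + spacer
      }
      len <- scaffold_lengths[[sub$scaffold[k]]]
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = ch, object_beg = at + 1L, object_end = at + len,
        part_number = part, component_type = "W",
        component_id = sub$scaffold[k], component_beg = 1L,
        component_end = len,
        orientation = if (sub$orientation[k] == "unknown") "?"
          else sub$orientation[k],
        stringsAsFactors = FALSE)
      at <- at + len
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Move misplaced components and emit a liftover table
#'
#' Applies block moves to a component placement (the correction step after
#' [flag_misplaced_bins()]): each listed component is removed and
#' re-inserted after a target component (or at the start of an object).
#' Applying an empty move set is the identity. Object coordinates are
#' recomputed and every component's old-to-new interval is returned.
#'
#' @param placements data.frame with `object`, `component_id`, `length`
#'   (component length in bp), in current order.
#' @param moves data.frame with `component_id`, `new_object`,
#'   `after_component` (`NA` = insert at the start of `new_object`).
#' @return list with `placements` (corrected, coordinates in
#'   `object_beg`/`object_end`, gapless layout) and `liftover`
#'   (data.frame `component_id`, `old_object`, `old_beg`, `old_end`,
#'   `new_object`, `new_beg`, `new_end`).
#' @export
apply_corrections <- function(placements, moves = NULL) {
  stopifnot(all(c("object", "component_id", "length") %in% names(placements)))
  if (anyDuplicated(placements$component_id)) {
    abort("duplicate component ids in placements")
  }
  coords <- function(p) {
    p$object_beg <- NA_real_; p$object_end <- NA_real_
    for (ob in unique(p$object)) {
      i <- which(p$object == ob)
      ends <- cumsum(p$length[i])
      p$object_beg[i] <- ends - p$length[i] + 1
      p$object_end[i] <- ends
    }
    p
  }
  old <- coords(placements)
  new <- placements
  if (!is.null(moves) && nrow(moves) > 0L) {
    if (anyDuplicated(moves$component_id)) {
      abort("overlapping proposed moves: component moved twice")
    }
    for (k in seq_len(nrow(moves))) {
      cid <- moves$component_id[k]
      at <- which(new$component_id == cid)
      if (!length(at)) abort("move references unknown component '%s'", cid)
      row <- new[at, , drop = FALSE]
      row$object <- moves$new_object[k]
      new <- new[-at, , drop = FALSE]
      if (is.na(moves$after_component[k])) {
        ins <- match(TRUE, new$object == moves$new_object[k]) - 1L
        if (is.na(ins)) ins <- nrow(new)
      } else {
        ins <- which(new$component_id == moves$after_component[k])
        if (!length(ins)) abort("move target '%s' not found",
                                moves$after_component[k])
      }
      new <- rbind(new[seq_len(ins), , drop = FALSE], row,
                   new[seq_len(nrow(new)) > ins, , drop = FALSE])
    }
  }
  new <- coords(new)
  m <- match(old$component_id, new$component_id)
  liftover <- data.frame(component_id = old$component_id,
                         old_object = old$object,
                         old_beg = old$object_beg, old_end = old$object_end,
                         new_object = new$object[m],
                         new_beg = new$object_beg[m],
                         new_end = new$object_end[m],
                         stringsAsFactors = FALSE)
  rownames(new) <- NULL
  list(placements = new, liftover = liftover)
}

#' Fill assembly gaps from a donor assembly by dual-flank matching
#'
#' Every maximal N-run of at least `min_gap` bases is a gap. Its two
#' `flank_len`-bp flanks are located in the donor by exact 31-mer seeding
#' and ungapped extension; a gap is filled only when each flank has exactly
#' one donor match at identity >= `min_identity`, both matches lie on the
#' same donor sequence and strand in concordant order, and the enclosed
#' donor span is between 0 and `max_span_factor` times the gap length.
#' Filled bases are written in lowercase; all other bases keep their case.
#'
#' @param target named character vector of gapped sequences.
#' @param donor named character vector of donor sequences.
#' @param flank_len flank length in bp (default 500).
#' @param seed_len exact seed length (default 31).
#' @param max_span_factor maximum donor span as a multiple of gap length.
#' @param min_identity minimum ungapped flank identity (default 0.95).
#' @param min_gap minimum N-run length treated as a gap (default 10).
#' @return list with `filled` (sequences after filling) and `gaps`
#'   (data.frame: `chrom`, `gap_start`, `gap_end` 0-based half-open on the
#'   input target, `status`, `donor_chrom`, `donor_start`, `donor_end`,
#'   `strand`, `fill_length`).
#' @export
fill_gaps <- function(target, donor, flank_len = 500, seed_len = 31,
                      max_span_factor = 5, min_identity = 0.95,
                      min_gap = 10) {
  stopifnot(is.character(target), !is.null(names(target)),
            is.character(donor), !is.null(names(donor)))
  donor_up <- toupper(donor)
  records <- list()
  filled <- target
  for (ch in names(target)) {
    seq_up <- toupper(target[[ch]])
    runs <- gregexpr(sprintf("N{%d,}", min_gap), seq_up)[[1L]]
    if (runs[1L] == -1L) next
    starts <- as.integer(runs)
    lens <- attr(runs, "match.length")
    ## process right-to-left so replacements don't shift pending coordinates
    for (k in rev(seq_along(starts))) {
      gs <- starts[k] - 1L           # 0-based half-open
      ge <- gs + lens[k]
      gap_len <- lens[k]
      rec <- data.frame(chrom = ch, gap_start = gs, gap_end = ge,
                        status = NA_character_,
                        donor_chrom = NA_character_,
                        donor_start = NA_real_, donor_end = NA_real_,
                        strand = NA_character_, fill_length = NA_real_,
                        stringsAsFactors = FALSE)
      if (gs < flank_len || ge + flank_len > nchar(seq_up)) {
        rec$status <- "unfilled_no_match"   # gap at sequence edge
        records[[length(records) + 1L]] <- rec
        next
      }
      lf <- substr(seq_up, gs - flank_len + 1L, gs)
      rf <- substr(seq_up, ge + 1L, ge + flank_len)
      lm <- find_flank(lf, donor_up, seed_len, min_identity)
      rm_ <- find_flank(rf, donor_up, seed_len, min_identity)
      if (nrow(lm) == 0L || nrow(rm_) == 0L) {
        rec$status <- "unfilled_no_match"
      } else if (nrow(lm) > 1L || nrow(rm_) > 1L) {
        rec$status <- "unfilled_ambiguous"
      } else if (lm$chrom != rm_$chrom || lm$strand != rm_$strand) {
        rec$status <- "unfilled_discordant"
      } else {
        fl <- flank_len
        if (lm$strand == "+") {
          span_start <- lm$start + fl       # 0-based just after left flank
          span_end <- rm_$start             # 0-based start of right flank
        } else {
          span_start <- rm_$start + fl
          span_end <- lm$start
        }
        span <- span_end - span_start
        if (span < 0 || span > max_span_factor * gap_len) {
          rec$status <- "unfilled_discordant"
        } else {
          fill <- substr(donor[[lm$chrom]], span_start + 1L, span_end)
          if (lm$strand == "-") fill <- revcomp(fill)
          fill <- tolower(fill)
          filled[[ch]] <- paste0(substr(filled[[ch]], 1L, gs), fill,
                                 substr(filled[[ch]], ge + 1L,
                                        nchar(filled[[ch]])))
          rec$status <- "filled"
          rec$donor_chrom <- lm$chrom
          rec$donor_start <- span_start
          rec$donor_end <- span_end
          rec$strand <- lm$strand
          rec$fill_length <- span
        }
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  gaps <- if (length(records)) do.call(rbind, records) else
    data.frame(chrom = character(0), gap_start = numeric(0),
               gap_end = numeric(0), status = character(0),
               donor_chrom = character(0), donor_start = numeric(0),
               donor_end = numeric(0), strand = character(0),
               fill_length = numeric(0))
  gaps <- gaps[order(gaps$chrom, gaps$gap_start), , drop = FALSE]
  rownames(gaps) <- NULL
  list(filled = filled, gaps = gaps)
}

## locate a flank in the donor: exact seed k-mers at three offsets, ungapped
## extension to the full flank, identity filter, deduplicated matches.
## Returns data.frame(chrom, start [0-based], strand, identity).
find_flank <- function(flank, donor_up, seed_len, min_identity) {
  fl <- nchar(flank)
  offsets <- unique(pmax(1L, c(1L, (fl - seed_len) %/% 2L + 1L,
                               fl - seed_len + 1L)))
  hits <- list()
  for (orient in c("+", "-")) {
    query <- if (orient == "+") flank else revcomp(flank)
    qchars <- strsplit(query, "", fixed = TRUE)[[1L]]
    for (ch in names(donor_up)) {
      dseq <- donor_up[[ch]]
      dlen <- nchar(dseq)
      cand <- integer(0)
      for (off in offsets) {
        seed <- substr(query, off, off + seed_len - 1L)
        if (nchar(seed) < seed_len) next
        g <- gregexpr(seed, dseq, fixed = TRUE)[[1L]]
        if (g[1L] == -1L) next
        cand <- c(cand, as.integer(g) - off + 1L)  # implied flank start
      }
      cand <- unique(cand[cand >= 1L & cand + fl - 1L <= dlen])
      for (s in cand) {
        dchars <- strsplit(substr(dseq, s, s + fl - 1L), "",
                           fixed = TRUE)[[1L]]
        ident <- mean(dchars == qchars)
        if (ident >= min_identity) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = ch, start = s - 1L, strand = orient,
            identity = ident, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), identity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[!duplicated(out[, c("chrom", "start", "strand")]), , drop = FALSE]
}
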