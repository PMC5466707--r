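test_that("a scaffold cut from a chromosome anchors back at its position", {
  fx <- markov_bins(n_bins = 12, n_rils = 150, r_step = 0.08, seed = 41)
  bm <- fx
  lm_ <- construct_linkage_map(bm)
  ## scaffold carrying noisy copies of bins 6-8, in order
  noisy <- function(col, k, seed) {
    set.seed(seed)
    flip <- sample(length(col), k)
    col[flip] <- chartr("ab", "ba", col[flip])
    col
  }
  sb <- rbind(noisy(fx$geno[6, ], 3, 1), noisy(fx$geno[7, ], 3, 2),
              noisy(fx$geno[8, ], 3, 3))
  res <- anchor_scaffolds(list(sc1 = sb), c(sc1 = 50000), lm_, bm)
  expect_equal(nrow(res$anchors), 1)
  expect_true(res$anchors$after_bin %in% c("bin0006", "bin0007", "bin0008"))
  expect_equal(res$anchors$orientation, "+")

  ## reversed internal bin order anchors with minus orientation
  res_rev <- anchor_scaffolds(list(sc1 = sb[3:1, ]), c(sc1 = 50000), lm_, bm)
  expect_equal(res_rev$anchors$orientation, "-")

  ## one bin cannot orient
  res1 <- anchor_scaffolds(list(sc1 = sb[1, , drop = FALSE]),
                           c(sc1 = 50000), lm_, bm)
  expect_equal(res1$anchors$orientation, "unknown")
})

test_that("scaffolds without linkage signal stay unanchored", {
  fx <- markov_bins(n_bins = 8, n_rils = 150, r_step = 0.08, seed = 43)
  lm_ <- construct_linkage_map(fx)
  set.seed(44)
  random_col <- matrix(sample(c("a", "b"), 150, replace = TRUE), nrow = 1)
  none <- matrix(character(0), nrow = 0, ncol = 150)
  res <- anchor_scaffolds(list(noise = random_col, empty = none),
                          c(noise = 1000, empty = 1000), lm_, fx)
  expect_equal(nrow(res$anchors), 0)
  expect_setequal(names(res$unanchored), c("noise", "empty"))
})

test_that("AGP rows reconstruct object lengths with 100-N spacers", {
  anchors <- data.frame(scaffold = c("s1", "s2", "s3"),
                        chrom = c("chr1", "chr1", "chr2"),
                        order_index = c(1, 2, 1),
                        orientation = c("+", "-", "unknown"))
  lens <- c(s1 = 1000, s2 = 2000, s3 = 500)
  agp <- agp_from_anchors(anchors, lens)
  chr1 <- agp[agp$object == "chr1", ]
  expect_equal(nrow(chr1), 3)  # two components + one spacer
  expect_equal(chr1$object_end[nrow(chr1)], 1000 + 100 + 2000)
  expect_equal(chr1$component_type, c("W", "U", "W"))
  ## component coordinates are contiguous
  expect_equal(chr1$object_beg, c(1, 1001, 1101))
  expect_equal(agp$object_end[agp$object == "chr2"], 500)
  ## round trip through the writer
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(agp, path)
  lines <- readLines(path)
  expect_match(lines[1], "agp-version")
  expect_equal(length(lines), nrow(agp) + 1)
})

test_that("an empty correction set is the identity", {
  pl <- data.frame(object = c("chr1", "chr1", "chr2"),
                   component_id = c("c1", "c2", "c3"),
                   length = c(100, 200, 300))
  res <- apply_corrections(pl)
  expect_equal(res$placements$component_id, pl$component_id)
  expect_equal(res$liftover$old_beg, res$liftover$new_beg)
  expect_equal(res$liftover$old_object, res$liftover$new_object)
})

test_that("a shuffled block is restored and the liftover is a bijection", {
  truth <- data.frame(object = "chr1",
                      component_id = paste0("c", 1:5),
                      length = c(100, 150, 200, 250, 300))
  ## shuffle: move c4 to the front
  shuffled <- truth[c(4, 1, 2, 3, 5), ]
  res <- apply_corrections(shuffled,
                           data.frame(component_id = "c4",
                                      new_object = "chr1",
                                      after_component = "c3"))
  expect_equal(res$placements$component_id, truth$component_id)
  expect_equal(res$placements$object_beg,
               cumsum(truth$length) - truth$length + 1)
  ## bijection: every base maps exactly once
  cover <- unlist(mapply(seq, res$liftover$new_beg, res$liftover$new_end))
  expect_equal(sort(cover), seq_len(sum(truth$length)))
})

test_that("two independent moves compose and double moves are rejected", {
  pl <- data.frame(object = "chr1", component_id = paste0("c", 1:6),
                   length = rep(100, 6))
  moves <- data.frame(component_id = c("c2", "c5"),
                      new_object = "chr1",
                      after_component = c("c6", NA))
  res <- apply_corrections(pl, moves)
  expect_equal(res$placements$component_id,
               c("c5", "c1", "c3", "c4", "c6", "c2"))
  cover <- unlist(mapply(seq, res$liftover$new_beg, res$liftover$new_end))
  expect_equal(sort(cover), 1:600)
  expect_error(apply_corrections(pl,
    data.frame(component_id = c("c2", "c2"), new_object = "chr1",
               after_component = c("c3", "c4"))), "moved twice")
})

test_that("gap filling restores the deleted sequence in lowercase", {
  set.seed(61)
  donor <- c(chrA = random_dna(60000))
  gaps <- data.frame(chrom = "chrA",
                     start = c(10000, 30000), end = c(10200, 30500))
  fr <- simulate_fragmented_assembly(donor, gaps)
  res <- fill_gaps(fr$target, donor)
  expect_equal(res$gaps$status, c("filled", "filled"))
  expect_identical(toupper(res$filled[["chrA"]]), donor[["chrA"]])
  ## the filled bases are exactly the deleted sequence, lowercased
  expect_equal(substr(res$filled[["chrA"]], 10001, 10200),
               tolower(fr$truth$deleted_seq[1]))
  ## bases outside the fills keep their original (upper) case
  before <- substr(res$filled[["chrA"]], 1, 10000)
  expect_identical(before, substr(donor[["chrA"]], 1, 10000))
})

test_that("a repeated flank makes the gap ambiguous, not filled", {
  set.seed(63)
  block <- random_dna(2000)
  donor <- c(chrA = paste0(random_dna(5000), block, random_dna(8000),
                           block, random_dna(5000)))
  ## gap immediately right of the second repeat copy: left flank repeats
  s <- 5000 + 2000 + 8000 + 2000
  fr <- simulate_fragmented_assembly(donor,
    data.frame(chrom = "chrA", start = s, end = s + 100))
  res <- fill_gaps(fr$target, donor)
  expect_equal(res$gaps$status, "unfilled_ambiguous")
  expect_identical(res$filled, fr$target)
})

test_that("flanks on different donor sequences are discordant", {
  set.seed(65)
  donor <- c(chrA = random_dna(5000), chrB = random_dna(5000))
  target <- c(t1 = paste0(substr(donor[["chrA"]], 1000, 1999),
                          strrep("N", 100),
                          substr(donor[["chrB"]], 2000, 2999)))
  res <- fill_gaps(target, donor)
  expect_equal(res$gaps$status, "unfilled_discordant")
})

test_that("gaps at sequence edges cannot be filled", {
  set.seed(67)
  donor <- c(chrA = random_dna(3000))
  target <- c(t1 = paste0(strrep("N", 50), substr(donor[["chrA"]], 51, 3000)))
  res <- fill_gaps(target, donor)
  expect_equal(res$gaps$status, "unfilled_no_match")
})

test_that("an unrelated donor fills nothing", {
  set.seed(69)
  donor <- c(chrA = random_dna(50000))
  gaps <- data.frame(chrom = "chrA", start = c(9000, 20000),
                     end = c(9150, 20400))
  fr <- simulate_fragmented_assembly(donor, gaps)
  set.seed(70)
  unrelated <- c(chrX = random_dna(50000))
  res <- fill_gaps(fr$target, unrelated)
  expect_equal(sum(res$gaps$status == "filled"), 0)
  expect_identical(res$filled, fr$target)
})

test_that("a reverse-complemented donor fills on the minus strand", {
  set.seed(71)
  fwd <- random_dna(20000)
  donor_rc <- c(chrR = revcomp(fwd))
  target <- c(t1 = fwd)
  fr <- simulate_fragmented_assembly(target,
    data.frame(chrom = "t1", start = 8000, end = 8300))
  res <- fill_gaps(fr$target, donor_rc)
  expect_equal(res$gaps$status, "filled")
  expect_equal(res$gaps$strand, "-")
  expect_identical(toupper(res$filled[["t1"]]), fwd)
  expect_equal(substr(res$filled[["t1"]], 8001, 8300),
               tolower(fr$truth$deleted_seq))
})

test_that("flanks abutting in the donor close the gap to zero length", {
  set.seed(73)
  donor <- c(chrA = random_dna(10000))
  ## target inserts 50 spurious N between two adjacent donor regions
  target <- c(t1 = paste0(substr(donor[["chrA"]], 1, 5000), strrep("N", 50),
                          substr(donor[["chrA"]], 5001, 10000)))
  res <- fill_gaps(target, donor)
  expect_equal(res$gaps$status, "filled")
  expect_equal(res$gaps$fill_length, 0)
  expect_identical(res$filled[["t1"]], donor[["chrA"]])
})

test_that("a donor span far larger than the gap is refused", {
  set.seed(75)
  left <- random_dna(1000)
  right <- random_dna(1000)
  donor <- c(chrA = paste0(left, random_dna(5000), right))
  target <- c(t1 = paste0(left, strrep("N", 20), right))
  res <- fill_gaps(target, donor)  # span 5000 > 5 * 20
  expect_equal(res$gaps$status, "unfilled_discordant")
})
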