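# Virtual gene order construction and rearrangement detection.

test_that("window density counts genes by midpoint and matches brute force", {
  # 10 genes at one position: every covering window counts 10
  d <- window_density(rep(123456, 10), chrom_len = 1e6)
  covering <- d$count[d$start <= 123456 & d$end > 123456]
  expect_true(all(covering == 10))
  expect_true(all(d$count[d$start > 123456] == 0))
  # empty chromosome: all-zero track
  d0 <- window_density(numeric(0), chrom_len = 2e6)
  expect_true(all(d0$count == 0))
  expect_gt(nrow(d0), 0)
  # brute-force oracle on random positions
  set.seed(71)
  pos <- sort(runif(1000, 0, 5e6))
  d1 <- window_density(pos, chrom_len = 5e6)
  brute <- vapply(seq_len(nrow(d1)), function(i)
    sum(pos >= d1$start[i] & pos < d1$end[i]), numeric(1))
  expect_equal(d1$count, brute)
  expect_error(window_density(pos, window = 1e4, step = 2e4), "step")
})

test_that("block calling needs the density threshold in enough species", {
  grid_track <- function(count_vec)
    data.frame(start = (seq_along(count_vec) - 1) * 50000,
               end = (seq_along(count_vec) - 1) * 50000 + 500000,
               count = count_vec)
  # 60 genes/Mb everywhere in 2 species over ~2 Mb: one block
  dense <- rep(30, 31)      # 30 genes per 500 kb window = 60/Mb
  tr <- list(A = list(chr1 = grid_track(dense)),
             B = list(chr1 = grid_track(dense)),
             C = list(chr1 = grid_track(rep(0, 31))))
  b <- call_syntenic_blocks(tr)
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 0)
  expect_equal(b$end, 2000000)
  # 40 genes/Mb everywhere: below threshold, no blocks
  sparse <- rep(20, 31)
  tr2 <- list(A = list(chr1 = grid_track(sparse)),
              B = list(chr1 = grid_track(sparse)))
  expect_equal(nrow(call_syntenic_blocks(tr2)), 0)
  # only one species dense: no blocks at min_species = 2
  tr3 <- list(A = list(chr1 = grid_track(dense)),
              B = list(chr1 = grid_track(rep(0, 31))))
  expect_equal(nrow(call_syntenic_blocks(tr3)), 0)
  # a single sub-max_gap dip does not split the block
  dip <- dense; dip[15] <- 0
  tr4 <- list(A = list(chr1 = grid_track(dip)),
              B = list(chr1 = grid_track(dip)))
  expect_equal(nrow(call_syntenic_blocks(tr4)), 1)
})

# build a toy catalogue/anchor pair for zipper construction: genes on one
# reference chromosome at 10 kb spacing, arm order given by `perm`, bins
# cut from the arm order
toy_zipper_input <- function(n = 40, perm = seq_len(n), n_bins = 4,
                             anchor_every = 2) {
  ids <- sprintf("g%03d", seq_len(n))
  genes <- data.frame(
    gene_id = ids, db_tag = "genomeA", genome = "A",
    n_reads = 2L, group = seq_len(n), profile = "ABC",
    unig_uniprot_support = TRUE, chrom = "chr1",
    position = (seq_len(n) - 1L) * 10000L + 500L,
    stringsAsFactors = FALSE)
  genes$supporting_reads <- replicate(n, character(0), simplify = FALSE)
  catalogue <- structure(list(genes = genes), class = "gene_catalogue")
  bins <- sprintf("B%d", seq_len(n_bins))
  arm_bin <- bins[even_groups_(n, n_bins)]
  anchored <- seq(1, n, by = anchor_every)
  anchors <- data.frame(
    gene_id = ids[perm][anchored],
    bin = arm_bin[anchored],
    map_position = NA_real_, n_markers = 1L, stringsAsFactors = FALSE)
  blocks <- data.frame(ref_chrom = "chr1", start = 0,
                       end = n * 10000, n_windows = 1L, max_count = n)
  list(catalogue = catalogue, anchors = anchors, bins = bins,
       blocks = blocks, ids = ids)
}

even_groups_ <- function(n, k)
  rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))

test_that("an unrearranged arm reproduces the reference order exactly", {
  ti <- toy_zipper_input()
  ref_pos <- data.frame(gene_id = ti$ids, chrom = "chr1",
                        start = (seq_along(ti$ids) - 1L) * 10000L,
                        end = (seq_along(ti$ids) - 1L) * 10000L + 1000L)
  z <- build_zipper(ti$catalogue, ref_pos, ti$anchors, ti$bins,
                    blocks = ti$blocks)
  expect_equal(z$ref_gene[z$syntenic], ti$ids)
  r <- detect_rearrangements(z)
  expect_equal(nrow(r$segments), 1)
  expect_equal(r$segments$orientation, "+")
  expect_equal(nrow(r$events), 0)
})

test_that("a fully reversed arm is recovered as one reversed segment", {
  n <- 40
  ti <- toy_zipper_input(n, perm = rev(seq_len(n)))
  ref_pos <- data.frame(gene_id = ti$ids, chrom = "chr1",
                        start = (seq_len(n) - 1L) * 10000L,
                        end = (seq_len(n) - 1L) * 10000L + 1000L)
  z <- build_zipper(ti$catalogue, ref_pos, ti$anchors, ti$bins,
                    blocks = ti$blocks)
  expect_equal(z$ref_gene[z$syntenic], rev(ti$ids))
  r <- detect_rearrangements(z)
  expect_equal(nrow(r$segments), 1)
  expect_equal(r$segments$orientation, "-")
  expect_equal(r$events$type, "inversion")
})

test_that("a three-segment reversal is reported as 3 segments in reverse", {
  n <- 60
  seg <- even_groups_(n, 3)
  perm <- c(which(seg == 3), which(seg == 2), which(seg == 1))
  ti <- toy_zipper_input(n, perm = perm, n_bins = 6)
  ref_pos <- data.frame(gene_id = ti$ids, chrom = "chr1",
                        start = (seq_len(n) - 1L) * 10000L,
                        end = (seq_len(n) - 1L) * 10000L + 1000L)
  z <- build_zipper(ti$catalogue, ref_pos, ti$anchors, ti$bins,
                    blocks = ti$blocks)
  r <- detect_rearrangements(z)
  expect_equal(nrow(r$segments), 3)
  expect_equal(r$segments$orientation, rep("+", 3))
  # zipper-order segments descend through the reference
  expect_true(all(diff(r$segments$rank_from) < 0))
  expect_equal(r$events$n_segments, 3L)
  # involution consistency: applying the segment model to reference order
  # reproduces the zipper order of syntenic genes
  recon <- unlist(lapply(seq_len(nrow(r$all_runs)), function(i) {
    rk <- r$all_runs$rank_from[i]:r$all_runs$rank_to[i]
    ti$ids[rk]
  }))
  expect_equal(recon, z$ref_gene[z$syntenic])
})

test_that("a planted inversion inside a colinear arm is flagged", {
  n <- 40
  perm <- seq_len(n); perm[11:20] <- rev(perm[11:20])
  ti <- toy_zipper_input(n, perm = perm, n_bins = 8, anchor_every = 1)
  ref_pos <- data.frame(gene_id = ti$ids, chrom = "chr1",
                        start = (seq_len(n) - 1L) * 10000L,
                        end = (seq_len(n) - 1L) * 10000L + 1000L)
  z <- build_zipper(ti$catalogue, ref_pos, ti$anchors, ti$bins,
                    blocks = ti$blocks)
  r <- detect_rearrangements(z, min_segment = 3)
  ev <- r$events
  expect_gte(nrow(ev), 1)
  expect_true(any(ev$rank_min <= 11 & ev$rank_max >= 20))
})

test_that("bin synteny statistics flag a biased bin against the rest", {
  gb <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   bin = rep(c("B1", "B2"), each = 100),
                   syntenic = c(rep(TRUE, 90), rep(FALSE, 10),
                                rep(TRUE, 40), rep(FALSE, 60)))
  st <- bin_synteny_stats(gb, c("B1", "B2"))
  expect_lt(st$p_value[st$bin == "B2"], 0.01)
  # identical composition: p = 1 for a bin equal to the rest
  gb2 <- data.frame(gene_id = sprintf("h%03d", 1:40),
                    bin = rep(c("B1", "B2"), each = 20),
                    syntenic = rep(c(TRUE, FALSE), 20))
  st2 <- bin_synteny_stats(gb2, c("B1", "B2"))
  expect_equal(st2$p_value, c(1, 1))
  # p-values equal exhaustive hypergeometric enumeration
  expect_equal(st$p_value[1], fisher_two_tailed(90, 10, 40, 60))
  # low-power flag
  gb3 <- rbind(gb2, data.frame(gene_id = "x", bin = "B3", syntenic = TRUE))
  st3 <- bin_synteny_stats(gb3, c("B1", "B2", "B3"))
  expect_true(st3$low_power[st3$bin == "B3"])
  expect_error(bin_synteny_stats(data.frame(bin = NA, syntenic = TRUE),
                                 "B1"), "bin")
})

test_that("three-way zipper comparison counts shared and unique genes", {
  mk_zip <- function(ids) {
    z <- data.frame(index = seq_along(ids), ref_gene = ids,
                    ref_chrom = "chr1", ref_pos = seq_along(ids) * 100L,
                    bin = "B1", map_position = NA_real_, syntenic = TRUE)
    z$reads <- replicate(length(ids), character(0), simplify = FALSE)
    z
  }
  ids <- sprintf("g%02d", 1:10)
  z <- mk_zip(ids)
  cmp <- compare_zippers(z, z, z)
  expect_equal(unname(cmp$venn["all3"]), 10L)
  expect_equal(sum(cmp$venn), 10L)
  cmp2 <- compare_zippers(mk_zip(ids[1:4]), mk_zip(ids[5:7]),
                          mk_zip(ids[8:10]))
  expect_equal(unname(cmp2$venn["all3"]), 0L)
  expect_equal(unname(cmp2$venn["z1"]), 4L)
  # planted sharing structure recovered exactly
  cmp3 <- compare_zippers(mk_zip(ids[1:6]), mk_zip(ids[4:8]),
                          mk_zip(ids[c(4:6, 9:10)]))
  expect_equal(unname(cmp3$venn["all3"]), 3L)     # g04-g06
  expect_equal(unname(cmp3$venn["z1"]), 3L)       # g01-g03
  expect_equal(unname(cmp3$venn["z2"]), 2L)       # g07-g08
  expect_equal(unname(cmp3$venn["z3"]), 2L)       # g09-g10
  expect_equal(unname(cmp3$venn["z1&z2"]), 0L)
  links <- cmp3$links
  expect_true(all(c("pos_z1", "pos_z2", "pos_z3") %in% names(links)))
})

test_that("marker anchoring resolves conflicting bins by majority", {
  s <- medium_sim()
  pl <- medium_pipeline()
  an <- pl$anchors
  expect_true(all(an$bin %in% s$truth$bins$bin))
  # anchors point at genes whose truth bin matches in the large majority
  tg <- s$truth$genes
  truth_bin <- tg$bin[match(an$gene_id, tg$gene_id)]
  ok <- !is.na(truth_bin)
  expect_gt(mean(an$bin[ok] == truth_bin[ok]), 0.9)
  expect_error(anchor_markers(s$markers, s$reads, pl$cascade$assignments,
                              bin_order = c("Bx")), "absent")
})

test_that("zipper order on the simulated arm tracks the planted arm order", {
  s <- medium_sim()
  pl <- medium_pipeline()
  z <- pl$zipper
  zs <- z[z$syntenic, ]
  tg <- s$truth$genes
  to <- tg$arm_order[match(zs$ref_gene, tg$gene_id)]
  tau <- cor(seq_along(to), to, method = "kendall", use = "complete.obs")
  # at this scale each planted segment spans barely more than one
  # deletion bin, so boundary genes smear between units; the survey-scale
  # bound (0.95) is enforced in the acceptance tests
  expect_gt(tau, 0.75)
  # the planted three-segment reversal appears as a reversal event
  ev <- pl$rearrangements$events
  expect_true(any(ev$type == "reversal" & ev$n_segments >= 2))
})
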