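# The synthetic survey generator and its truth set.

test_that("config validation rejects invalid fractions and ranges", {
  expect_error(sim_config(repeat_fraction = 1.2), "fractions")
  expect_error(sim_config(purity = 0), "purity")
  expect_error(sim_config(n_genes = 10), "n_genes")
  expect_error(sim_config(coverage_fold = 0), "coverage_fold")
  expect_error(sim_config(rearrangement_spec = list(
    list(type = "inversion", genes = c(10, 5000)))), "out of bounds")
  expect_error(sim_config(rearrangement_spec = list(
    list(type = "shuffle", genes = c(1, 5)))), "unknown rearrangement")
})

test_that("YAML configuration maps one-to-one onto sim_config", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_genes: 40", "repeat_fraction: 0.6",
               "n_bins: 4", "purity: 0.9"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 40)
  expect_equal(cfg$repeat_fraction, 0.6)
  writeLines(c("seed: 5", "no_such_option: 1"), f)
  expect_error(read_sim_config(f), "unknown configuration")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- small_config()
  s1 <- small_sim()
  s2 <- simulate_survey(cfg)
  expect_identical(s1$arm$sequence, s2$arm$sequence)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth$genes, s2$truth$genes)
  # FASTA outputs byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "reads.fasta")),
                   readLines(file.path(d2, "reads.fasta")))
  s3 <- simulate_survey(sim_config(seed = 12, n_genes = 60, n_bins = 4))
  expect_false(identical(s1$arm$sequence, s3$arm$sequence))
})

test_that("repeat interval mass matches the configured fraction within 2%", {
  s <- small_sim()
  frac <- sum(s$truth$repeats$end - s$truth$repeats$start) / s$truth$arm_size
  expect_lt(abs(frac - small_config()$repeat_fraction), 0.02)
  # intervals in bounds, half-open
  expect_true(all(s$truth$repeats$start >= 0))
  expect_true(all(s$truth$repeats$end <= s$truth$arm_size))
  expect_true(all(s$truth$repeats$end > s$truth$repeats$start))
})

test_that("read count follows round(coverage * S / L) and labels are complete", {
  s <- small_sim()
  cfg <- small_config()
  expect_equal(nrow(s$reads),
               round(cfg$coverage_fold * s$truth$arm_size / cfg$mean_read_len))
  # every read id appears exactly once in the truth with one source label
  expect_setequal(s$reads$read_id, s$read_truth$read_id)
  expect_false(anyDuplicated(s$read_truth$read_id) > 0)
  expect_true(all(s$read_truth$source %in%
                    c("target", "contaminant", "organelle")))
  # the stated arithmetic example: S = 1.61e6 bp arm at L = 347
  cfg2 <- sim_config(seed = 3, n_genes = 60, arm_size = 1610000L,
                     mean_read_len = 347, coverage_fold = 1, purity = 1,
                     repeat_fraction = 0.2, n_bins = 4)
  s2 <- simulate_reads(simulate_wheat_arm(
    cfg2, simulate_reference_genomes(cfg2)), NULL, cfg2)
  expect_equal(nrow(s2$reads), round(1610000 / 347))
})

test_that("purity 1 and artifact rate 0 give clean truth sets", {
  cfg <- sim_config(seed = 7, n_genes = 40, purity = 1, artifact_rate = 0,
                    n_bins = 4)
  s <- simulate_survey(cfg)
  expect_length(s$truth$contaminant_read_ids, 0)
  expect_length(s$truth$organelle_read_ids, 0)
  expect_equal(nrow(s$artifact_pairs), 0)
})

test_that("artifact duplicates are byte-identical with recorded pairs", {
  s <- small_sim()
  ap <- s$artifact_pairs
  expect_gt(nrow(ap), 0)
  seqs <- setNames(s$reads$sequence, s$reads$read_id)
  expect_true(all(seqs[ap$duplicate] == seqs[ap$kept_candidate]))
  rt <- s$read_truth
  dup <- rt[match(ap$duplicate, rt$read_id), ]
  src <- rt[match(ap$kept_candidate, rt$read_id), ]
  expect_equal(dup$start, src$start)
  expect_equal(dup$end, src$end)
})

test_that("telomeric bias places insertions distally at the configured rate", {
  # the distal 10% of the final gene order must be able to hold the
  # biased draws, so the arm is large relative to the insertion count
  cfg <- sim_config(seed = 31, n_genes = 1000, n_nonsyntenic = 50,
                    n_wheat_specific = 10, n_fragment_genes = 0,
                    n_duplicated = 0, nonsyntenic_telomere_bias = 0.8,
                    n_bins = 8)
  s <- simulate_wheat_arm(cfg, simulate_reference_genomes(cfg))
  g <- s$truth$genes
  ins <- g[g$kind %in% c("nonsyntenic", "wheat_specific"), ]
  expect_equal(nrow(ins), 50)
  distal <- mean(ins$arm_order >= 0.9 * nrow(g))
  # binomial 95% lower bound for 50 draws at p = 0.8 (~0.69)
  expect_gte(distal, qbinom(0.025, 50, 0.8) / 50)
})

test_that("segment structure records the planted rearrangements", {
  s <- small_sim()
  seg <- s$truth$segments
  expect_true(any(seg$type == "inversion"))
  expect_equal(sum(seg$type == "segment_reversal"), 3)
  spec <- small_config()$rearrangement_spec
  inv <- seg[seg$type == "inversion", ]
  expect_equal(c(inv$first_gene, inv$last_gene), spec[[1]]$genes)
  # translocation_out removes its genes from the arm
  cfg <- sim_config(seed = 9, n_genes = 50, n_bins = 4,
                    rearrangement_spec = list(
                      list(type = "translocation_out", genes = c(10, 14))))
  arm <- simulate_wheat_arm(cfg, simulate_reference_genomes(cfg))
  out_ids <- sprintf("G%05d", 10:14)
  expect_false(any(out_ids %in% arm$truth$genes$gene_id))
})

test_that("markers carry the bin containing their gene", {
  s <- small_sim()
  g <- s$truth$genes
  mk <- s$markers
  gm <- g[match(mk$gene_id, g$gene_id), ]
  mid <- (gm$start + gm$end) %/% 2
  bins <- s$truth$bins
  expected <- bins$bin[findInterval(mid, bins$start)]
  expect_equal(mk$bin, expected)
  # marker sequences come from the wheat copies of their genes
  expect_true(all(mapply(grepl, mk$sequence,
                         s$arm$gene_seqs[gm$source_gene], fixed = TRUE)))
})

test_that("transcript classes and coverages respect the configured bands", {
  s <- small_sim()
  tt <- s$transcript_truth
  expect_true(all(tt$coverage[tt$class == "high"] >= 0.60))
  expect_true(all(tt$coverage[tt$class == "low"] >= 0.20 &
                    tt$coverage[tt$class == "low"] < 0.60))
  expect_true(all(tt$coverage[tt$class == "none"] == 0))
  expect_setequal(names(s$transcripts),
                  paste0("TX_", tt$gene_id[tt$class != "none"]))
})

test_that("tRNA token scan shows the planted repeat-capture bias", {
  s <- small_sim()
  pred_all <- scan_trna_tokens(s$reads, s$truth$token_table)
  lys_all <- sum(pred_all$isotype == "Lys")
  expect_gt(lys_all, 0)
  # split reads into repeat-flagged and retained sets: the TE-captured
  # isotype should be concentrated (per Mb) in the repeat fraction
  asm <- overlap_assemble(s$reads)
  deep <- flag_deep_contig_reads(asm)
  lm <- library_mask(s$reads, s$repeat_library)
  ns <- nonrepetitive_summary(lm$reads, deep$read_ids)
  kept <- data.frame(read_id = ns$reads$read_id,
                     sequence = ns$reads$sequence_masked)
  removed <- s$reads[s$reads$read_id %in% ns$removed, ]
  pred_kept <- scan_trna_tokens(kept, s$truth$token_table)
  pred_removed <- scan_trna_tokens(removed, s$truth$token_table)
  # the TE-captured isotype concentrates in the repeat fraction and
  # dominates it; the retained set keeps the genic isotypes
  expect_gte(sum(pred_removed$isotype == "Lys") / lys_all, 0.7)
  expect_equal(names(which.max(table(pred_removed$isotype))), "Lys")
  expect_true(all(setdiff(unique(pred_all$isotype), "Lys") %in%
                    pred_kept$isotype))
})
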