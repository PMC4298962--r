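# Reference-guided gene models and transcript-coverage confidence.

toy_assign <- function(query_id, subject_id, q_start, q_end, s_start, s_end,
                       db_tag = "genomeA", strand = "+", evalue = 1e-40) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100, pct_similarity = NA_real_,
             aln_len = q_end - q_start, evalue = evalue, bit_score = 100,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             strand = strand, db_tag = db_tag, stringsAsFactors = FALSE)
}

test_that("reads tiling a CDS assemble into one full-length contig", {
  set.seed(91)
  cds <- random_dna_str(600)
  st <- c(1, 150, 300, 401)
  reads <- data.frame(read_id = sprintf("r%d", 1:4),
                      sequence = substring(cds, st, st + 199))
  asg <- do.call(rbind, lapply(1:4, function(i)
    toy_assign(reads$read_id[i], "gene1", 0L, 200L,
               st[i] - 1L, st[i] + 199L)))
  ctg <- map_reads_to_reference(reads, asg)
  expect_length(ctg, 1)
  expect_equal(nrow(ctg[["genomeA:gene1"]]), 1)
  expect_equal(ctg[["genomeA:gene1"]]$consensus, cds)
  mdl <- merge_contigs(ctg[["genomeA:gene1"]])
  expect_equal(mdl$sequence, cds)
  expect_equal(mdl$n_gap_bases, 0L)
})

test_that("reads covering only the ends give two contigs joined by n-runs", {
  set.seed(92)
  cds <- random_dna_str(500)
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c(substr(cds, 1, 200),
                                   substr(cds, 301, 500)))
  asg <- rbind(toy_assign("a", "g", 0L, 200L, 0L, 200L),
               toy_assign("b", "g", 0L, 200L, 300L, 500L))
  ctg <- map_reads_to_reference(reads, asg)
  expect_equal(nrow(ctg[["genomeA:g"]]), 2)
  mdl <- merge_contigs(ctg[["genomeA:g"]])
  expect_equal(mdl$sequence,
               paste0(substr(cds, 1, 200), strrep("n", 100),
                      substr(cds, 301, 500)))
  expect_equal(mdl$n_gap_bases, 100L)
  # single contig: model equals the contig
  one <- merge_contigs(ctg[["genomeA:g"]][1, ])
  expect_equal(one$sequence, substr(cds, 1, 200))
})

test_that("minus-strand reads contribute their reverse complement", {
  set.seed(93)
  cds <- random_dna_str(300)
  reads <- data.frame(read_id = "m",
                      sequence = revcomp_str(substr(cds, 51, 250)))
  asg <- toy_assign("m", "g", 0L, 200L, 50L, 250L, strand = "-")
  ctg <- map_reads_to_reference(reads, asg, min_contig = 40L)
  expect_equal(ctg[["genomeA:g"]]$consensus, substr(cds, 51, 250))
})

test_that("database precedence assigns multi-database reads once", {
  set.seed(94)
  reads <- data.frame(read_id = "r", sequence = random_dna_str(200))
  asg <- rbind(toy_assign("r", "gB", 0L, 200L, 0L, 200L,
                          db_tag = "genomeB", evalue = 1e-60),
               toy_assign("r", "gA", 0L, 200L, 0L, 200L,
                          db_tag = "genomeA", evalue = 1e-40))
  ctg <- map_reads_to_reference(reads, asg)
  expect_equal(names(ctg), "genomeA:gA")       # A precedes B despite e-value
})

test_that("confidence classes follow the coverage boundaries", {
  models <- data.frame(model_id = c("m1", "m2", "m3"),
                       reference_id = c("g1", "g2", "g3"),
                       db_tag = "genomeA", source_class = "conserved",
                       sequence = c(strrep("A", 100), strrep("C", 1000),
                                    strrep("G", 1000)),
                       n_contigs = 1L, n_gap_bases = 0L, ambiguous = FALSE,
                       stringsAsFactors = FALSE)
  mk_hit <- function(model, s_start, s_end)
    data.frame(query_id = "tx", subject_id = model, pct_identity = 100,
               pct_similarity = NA_real_, aln_len = s_end - s_start,
               evalue = 1e-30, bit_score = 50, q_start = 0L,
               q_end = s_end - s_start, s_start = s_start, s_end = s_end,
               strand = "+", db_tag = "transcript",
               stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("m1", 0L, 100L),     # 100% -> high
                mk_hit("m2", 0L, 599L),     # 59.9% -> low
                mk_hit("m3", 0L, 600L))     # 60.0% -> high (boundary up)
  out <- classify_confidence(models, hits = hits)
  expect_equal(out$confidence, c("high", "low", "high"))
  expect_equal(out$transcript_coverage, c(100, 59.9, 60))
  # 19.9% -> eliminated; 20% -> low
  hits2 <- rbind(mk_hit("m2", 0L, 199L), mk_hit("m3", 0L, 200L))
  out2 <- classify_confidence(models, hits = hits2)
  expect_equal(out2$confidence, c("eliminated", "eliminated", "low"))
  # coverage counts non-n bases only
  mn <- data.frame(model_id = "mn", reference_id = "g", db_tag = "genomeA",
                   source_class = "conserved",
                   sequence = paste0(strrep("A", 100), strrep("n", 100),
                                     strrep("T", 100)),
                   n_contigs = 2L, n_gap_bases = 100L, ambiguous = FALSE,
                   stringsAsFactors = FALSE)
  outn <- classify_confidence(mn, hits = mk_hit("mn", 0L, 100L))
  expect_equal(outn$transcript_coverage, 50)
  # partition property: every model has exactly one class
  expect_true(all(out$confidence %in% c("high", "low", "eliminated")))
})

test_that("cross-dataset matching maps a model set onto itself at 100%", {
  set.seed(95)
  models <- data.frame(model_id = sprintf("m%d", 1:6),
                       sequence = replicate(6, random_dna_str(400)),
                       location = "armL", stringsAsFactors = FALSE)
  cm <- cross_dataset_match(models, models)
  expect_equal(nrow(cm$matches), 6)
  expect_equal(cm$matches$query, cm$matches$subject)
  expect_true(all(cm$matches$identity_bin == 100))
  expect_true(all(cm$matches$location_concordant))
})

test_that("equal-e-value ties resolve to the subject on the query's arm", {
  set.seed(96)
  sq <- random_dna_str(400)
  q <- data.frame(model_id = "q1", sequence = sq, location = "5D",
                  stringsAsFactors = FALSE)
  s <- data.frame(model_id = c("sA", "sB"), sequence = c(sq, sq),
                  location = c("5B", "5D"), stringsAsFactors = FALSE)
  cm <- cross_dataset_match(q, s)
  expect_equal(cm$matches$subject, "sB")
})

test_that("diverged homoeolog pairs land in the expected identity bin", {
  set.seed(97)
  base <- replicate(5, random_dna_str(500))
  q <- data.frame(model_id = sprintf("q%d", 1:5), sequence = base,
                  stringsAsFactors = FALSE)
  s <- data.frame(model_id = sprintf("s%d", 1:5),
                  sequence = vapply(base, mutate_str, character(1),
                                    rate = 0.03),
                  stringsAsFactors = FALSE)
  cm <- cross_dataset_match(q, s, min_identity = 90)
  expect_equal(nrow(cm$matches), 5)
  expect_true(all(cm$matches$identity_bin %in% 95:98))
  expect_equal(sum(cm$identity_histogram), 5)
})

test_that("models built from one gene's reads contain no invented bases", {
  s <- small_sim()
  asm <- overlap_assemble(s$reads)
  deep <- flag_deep_contig_reads(asm)
  lm <- library_mask(s$reads, s$repeat_library)
  ns <- nonrepetitive_summary(lm$reads, deep$read_ids)
  hc <- homology_cascade(ns$reads, s$references, mode = "nt",
                         organelle = s$organelle)
  models <- build_gene_models(ns$reads, hc$assignments)
  expect_gt(nrow(models), 0)
  seqs <- setNames(ns$reads$sequence, ns$reads$read_id)
  a <- hc$assignments
  for (i in seq_len(min(10, nrow(models)))) {
    parts <- strsplit(models$sequence[i], "n+", fixed = FALSE)[[1]]
    reads_i <- a$query_id[a$subject_id == models$reference_id[i]]
    pool <- paste(c(seqs[reads_i],
                    vapply(seqs[reads_i], revcomp_str, character(1))),
                  collapse = " ")
    for (p in parts[nchar(parts) >= 20]) {
      # every model chunk is covered by read-derived sequence: check that
      # its first 20-mer occurs in some supporting read (either strand)
      expect_true(grepl(substr(p, 1, 20), pool, fixed = TRUE),
                  label = paste("model chunk from", models$model_id[i]))
    }
  }
})
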