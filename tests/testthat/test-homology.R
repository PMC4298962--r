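# The conserved-gene filter cascade and catalogue.

toy_hits <- function(query_id, subject_id, pct_identity = 100,
                     pct_similarity = NA_real_, aln_len = 100L,
                     evalue = 1e-40, s_start = 0L, s_end = 100L,
                     db_tag = "genomeA", strand = "+") {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, pct_similarity = pct_similarity,
             aln_len = as.integer(aln_len), evalue = evalue,
             bit_score = 100, q_start = 0L, q_end = as.integer(aln_len),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             strand = strand, db_tag = db_tag, stringsAsFactors = FALSE)
}

test_that("organellar filter applies both thresholds jointly", {
  reads <- data.frame(read_id = c("a", "b", "c"),
                      sequence = strrep("A", 100))
  h <- rbind(toy_hits("a", "org", pct_identity = 96, aln_len = 80),
             toy_hits("b", "org", pct_identity = 96, aln_len = 50),
             toy_hits("c", "org", pct_identity = 90, aln_len = 90))
  out <- filter_organellar(reads, h)
  expect_equal(out$removed, "a")            # 96% over 80% of 100 bp
  expect_setequal(out$reads$read_id, c("b", "c"))
})

test_that("protein-hit filter enforces e-value, similarity and length", {
  h <- rbind(toy_hits("r1", "p", pct_similarity = 80, aln_len = 35,
                      evalue = 1e-7),
             toy_hits("r2", "p", pct_similarity = 80, aln_len = 29,
                      evalue = 1e-7),
             toy_hits("r3", "p", pct_similarity = 74.9, aln_len = 35,
                      evalue = 1e-7),
             toy_hits("r4", "p", pct_similarity = 80, aln_len = 35,
                      evalue = 1e-5))
  out <- filter_protein_hits(h)
  expect_equal(out$query_id, "r1")
  expect_equal(filter_protein_hits(out), out)   # idempotent
  h_na <- toy_hits("r", "p")
  expect_error(filter_protein_hits(h_na), "similarity")
})

test_that("nucleotide-hit filter raises identity for same-species sets", {
  h <- toy_hits("r", "u", pct_identity = 80, aln_len = 100, evalue = 1e-31)
  expect_equal(nrow(filter_nucleotide_hits(h)), 1)
  expect_equal(nrow(filter_nucleotide_hits(h, same_species = TRUE)), 0)
  expect_equal(nrow(filter_nucleotide_hits(
    toy_hits("r", "u", aln_len = 89, evalue = 1e-31))), 0)
  expect_equal(nrow(filter_nucleotide_hits(
    toy_hits("r", "u", evalue = 1e-29))), 0)
})

test_that("best-hit selection equals an exhaustive min-evalue scan", {
  set.seed(51)
  h <- do.call(rbind, lapply(1:200, function(i)
    toy_hits(sprintf("r%02d", sample(15, 1)), sprintf("g%02d", sample(8, 1)),
             evalue = 10^-runif(1, 31, 60), aln_len = sample(90:200, 1))))
  best <- filter_nucleotide_hits(h)
  for (q in unique(h$query_id)) {
    hq <- h[h$query_id == q, ]
    hq <- hq[order(hq$evalue, -hq$aln_len, hq$subject_id), ]
    expect_equal(best$subject_id[best$query_id == q], hq$subject_id[1])
  }
})

test_that("reciprocal best keeps mutual per-read best pairs only", {
  fwd <- rbind(toy_hits("r1", "g1", evalue = 1e-50),
               toy_hits("r1", "g2", evalue = 1e-40),
               toy_hits("r2", "g1", evalue = 1e-45))
  # reverse direction: gene is the query
  rev1 <- rbind(toy_hits("g1", "r1", evalue = 1e-50),
                toy_hits("g2", "r1", evalue = 1e-60),
                toy_hits("g1", "r2", evalue = 1e-45))
  out <- reciprocal_best(fwd, rev1)
  # r1's forward best is g1 but its reverse best is g2 -> dropped
  expect_equal(out$query_id, "r2")
  # symmetric toy: mutual best survives
  out2 <- reciprocal_best(toy_hits("r", "g"), toy_hits("g", "r"))
  expect_equal(nrow(out2), 1)
})

test_that("RBH equals brute-force double argmax on a random matrix", {
  set.seed(52)
  n_r <- 20; n_g <- 20
  score <- matrix(runif(n_r * n_g), n_r, n_g,
                  dimnames = list(sprintf("r%02d", 1:n_r),
                                  sprintf("g%02d", 1:n_g)))
  ev <- 10^(-30 - 30 * score)             # lower e-value = better
  fwd <- do.call(rbind, lapply(1:n_r, function(i)
    do.call(rbind, lapply(1:n_g, function(j)
      toy_hits(rownames(score)[i], colnames(score)[j], evalue = ev[i, j])))))
  rev1 <- swap_hits(fwd)
  got <- reciprocal_best(fwd, rev1)
  # oracle: for each read, the argmax gene must be the same in both
  # directions of the score matrix
  exp_pairs <- character(0)
  for (i in 1:n_r) {
    jf <- which.min(ev[i, ])
    jr <- which.min(ev[i, ])              # symmetric scores
    if (jf == jr) exp_pairs <- c(exp_pairs,
                                 paste(rownames(score)[i],
                                       colnames(score)[jf]))
  }
  expect_setequal(paste(got$query_id, got$subject_id), exp_pairs)
})

test_that("artifact dedup collapses identical reads at identical coordinates", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "TTTTAAAA")
  asg <- rbind(toy_hits("b", "g1", s_start = 10, s_end = 18),
               toy_hits("a", "g1", s_start = 10, s_end = 18),
               toy_hits("c", "g1", s_start = 12, s_end = 20),
               toy_hits("d", "g1", s_start = 10, s_end = 18))
  out <- dedup_artifacts(asg, seqs)
  # a and b identical at the same coordinates: lexicographically smallest
  # survives; c differs in coordinates, d in sequence
  expect_equal(out$removed, "b")
  expect_setequal(out$assignments$query_id, c("a", "c", "d"))
  expect_equal(out$groups$kept, "a")
})

test_that("catalogue applies single-read and over-support rules", {
  asg <- rbind(
    toy_hits(c("r1", "r2"), "gA", db_tag = "genomeA"),
    toy_hits("r9", "gLone", db_tag = "genomeA"),          # 1 read: dropped
    do.call(rbind, lapply(sprintf("u%02d", 1:51), function(r)
      toy_hits(r, "uniDeep", db_tag = "unigene"))),        # 51 reads: dropped
    toy_hits(c("r1", "r2"), "gB", db_tag = "genomeB"),
    toy_hits("r1", "uniOK", db_tag = "unigene"),
    toy_hits("r2", "uniOK", db_tag = "unigene"))
  cat1 <- build_gene_catalogue(asg)
  expect_false("gLone" %in% cat1$genes$gene_id)
  expect_false("uniDeep" %in% cat1$genes$gene_id)
  expect_true("uniOK" %in% cat1$genes$gene_id)
  # gA and gB share reads r1, r2 -> one ortholog group with profile AB
  gA <- cat1$genes[cat1$genes$gene_id == "gA", ]
  gB <- cat1$genes[cat1$genes$gene_id == "gB", ]
  expect_equal(gA$group, gB$group)
  expect_equal(gA$profile, "AB")
  expect_true(gA$unig_uniprot_support)
  expect_equal(unname(cat1$venn["AB"]), 1L)
  expect_equal(sum(cat1$venn), 1L)
})

test_that("arm contrast runs a Fisher test per conservation class", {
  v1 <- setNames(c(50L, 10L, 5L, 5L, 10L, 10L, 10L),
                 c("ABC", "AB", "AC", "BC", "A", "B", "C"))
  v2 <- setNames(c(20L, 10L, 25L, 5L, 10L, 10L, 10L),
                 c("ABC", "AB", "AC", "BC", "A", "B", "C"))
  ct <- venn_arm_contrast(v1, v2)
  expect_equal(nrow(ct), 7)
  expect_lt(ct$p_value[ct$class == "AC"], 0.01)
  expect_equal(ct$p_value[ct$class == "BC"], 1)
  # agreement with stats::fisher.test on one class
  ft <- fisher.test(matrix(c(50, sum(v1) - 50, 20, sum(v2) - 20), 2,
                           byrow = TRUE))$p.value
  expect_equal(ct$p_value[ct$class == "ABC"], ft, tolerance = 1e-7)
})

test_that("cascade removes planted contaminant single-read genes and artifacts", {
  s <- small_sim()
  asm <- overlap_assemble(s$reads)
  deep <- flag_deep_contig_reads(asm)
  lm <- library_mask(s$reads, s$repeat_library)
  ns <- nonrepetitive_summary(lm$reads, deep$read_ids)
  hc <- homology_cascade(ns$reads, s$references, mode = "nt",
                         organelle = s$organelle)
  # planted organellar reads that reached the cascade are all removed,
  # with no false organellar removals
  org <- intersect(s$truth$organelle_read_ids, ns$reads$read_id)
  expect_setequal(intersect(hc$removed_organellar, org), org)
  expect_length(setdiff(hc$removed_organellar, org), 0)
  # artifact dedup removes only planted duplicates
  ap <- s$artifact_pairs
  expect_true(all(hc$removed_artifacts %in%
                    c(ap$duplicate, ap$kept_candidate)))
  cat1 <- build_gene_catalogue(hc$assignments)
  # single-read contaminant genes never survive
  cont_genes <- s$truth$contaminant_genes$gene_id
  cont_support <- table(hc$assignments$subject_id[
    hc$assignments$subject_id %in% cont_genes])
  expect_false(any(names(cont_support)[cont_support < 2] %in%
                     cat1$genes$gene_id))
})

test_that("catalogue recovers planted conservation classes on a clean run", {
  # deep coverage and no artifacts: the Venn over ortholog groups must
  # reproduce the planted class proportions exactly
  cfg <- sim_config(seed = 61, n_genes = 80, coverage_fold = 8,
                    purity = 1, artifact_rate = 0, n_nonsyntenic = 0,
                    n_wheat_specific = 0, n_fragment_genes = 0,
                    n_duplicated = 0, n_bins = 4, lineage_move_rate = 0,
                    repeat_fraction = 0.4, gene_gap_min = 400,
                    rearrangement_spec = list())
  s <- simulate_survey(cfg)
  lm <- library_mask(s$reads, s$repeat_library)
  ns <- nonrepetitive_summary(lm$reads, character(0))
  hc <- homology_cascade(ns$reads, s$references, mode = "nt")
  cat1 <- build_gene_catalogue(hc$assignments)
  truth_classes <- table(s$references$genes$class[
    s$references$genes$role == "syntenic"])
  for (cl in names(truth_classes))
    expect_equal(unname(cat1$venn[cl]), unname(truth_classes[cl]),
                 label = paste("class", cl))
})
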