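# The conserved-gene discovery filter cascade:
#   organellar screen -> protein / nucleotide hit filters -> reciprocal
#   best hits -> amplification-artifact dedup -> gene catalogue with
#   cross-genome conservation classes.
# Thresholds follow the published cascade: organellar >=95% identity over
# >=75% of the read; protein hits e <= 1e-6, >=75% similarity, >=30 aa;
# nucleotide hits e <= 1e-30, >=75% identity (95% for same-species
# collections) over >=90 nt, best hit per read.

#' Remove putative organellar reads
#'
#' A read is organellar if any hit against the organellar genomes reaches
#' `min_identity` percent identity over at least `min_frac` of the read
#' length.
#'
#' @param reads read data.frame (`read_id`, `sequence`)
#' @param organelle_hits hit table from [internal_search()] or
#'   [read_hits_tabular()] against the organellar sequences
#' @param min_identity,min_frac removal thresholds
#' @return list: `reads` (retained), `removed` (read ids, logged)
#' @export
filter_organellar <- function(reads, organelle_hits, min_identity = 95,
                              min_frac = 0.75) {
  reads <- as_read_frame(reads)
  if (nrow(organelle_hits) == 0)
    return(list(reads = reads, removed = character(0)))
  rlen <- stats::setNames(nchar(reads$sequence), reads$read_id)
  h <- organelle_hits
  h <- h[h$pct_identity >= min_identity &
           h$aln_len >= min_frac * rlen[h$query_id], , drop = FALSE]
  removed <- unique(h$query_id)
  list(reads = reads[!(reads$read_id %in% removed), , drop = FALSE],
       removed = removed)
}

#' Filter protein-mode (translated) hits
#'
#' Keeps hits with e-value at most `max_evalue`, percent amino-acid
#' similarity (BLOSUM62 positives) at least `min_similarity`, and aligned
#' length at least `min_len_aa` residues.  Idempotent.
#'
#' @param hits hit table with `pct_similarity` populated
#' @param max_evalue,min_similarity,min_len_aa thresholds
#' @return filtered hit table
#' @export
filter_protein_hits <- function(hits, max_evalue = 1e-6,
                                min_similarity = 75, min_len_aa = 30) {
  if (nrow(hits) == 0) return(hits)
  if (all(is.na(hits$pct_similarity)))
    stop("hits carry no similarity column; recompute with internal_search ",
         "(mode = 'translated') or supply a 13-column hit table")
  keep <- !is.na(hits$pct_similarity) &
    hits$evalue <= max_evalue &
    hits$pct_similarity >= min_similarity &
    hits$aln_len >= min_len_aa
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter nucleotide-mode hits
#'
#' Keeps hits with e-value at most `max_evalue` and at least `min_identity`
#' percent identity (raised to `same_species_identity` for same-species
#' collections, where paralogy and homoeology demand near-identity) over at
#' least `min_len` nt; optionally retains only the best hit per read
#' (lowest e-value, then longest alignment, then lexicographic subject id).
#'
#' @param hits nucleotide hit table
#' @param same_species apply the stricter same-species identity threshold
#' @param max_evalue,min_len,min_identity,same_species_identity thresholds
#' @param best_only keep only the best hit per query
#' @return filtered hit table
#' @export
filter_nucleotide_hits <- function(hits, same_species = FALSE,
                                   max_evalue = 1e-30, min_len = 90,
                                   min_identity = 75,
                                   same_species_identity = 95,
                                   best_only = TRUE) {
  if (nrow(hits) == 0) return(hits)
  idmin <- if (same_species) same_species_identity else min_identity
  keep <- hits$evalue <= max_evalue & hits$aln_len >= min_len &
    hits$pct_identity >= idmin
  out <- hits[keep, , drop = FALSE]
  if (best_only && nrow(out)) {
    out <- out[order(out$query_id, out$evalue, -out$aln_len,
                     out$subject_id), , drop = FALSE]
    out <- out[!duplicated(out$query_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# best hit per query: lowest e-value, then longest alignment, then
# lexicographic subject id
best_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  out <- hits[order(hits$query_id, hits$evalue, -hits$aln_len,
                    hits$subject_id), , drop = FALSE]
  out[!duplicated(out$query_id), , drop = FALSE]
}

#' Reciprocal best hits between reads and genes
#'
#' A (read, gene) assignment is retained iff the gene is the read's best
#' forward hit and, in the reverse-direction search, the gene is again the
#' best-scoring query hitting that read.  Ties break by lowest e-value,
#' then longest alignment, then lexicographic id.
#'
#' @param hits_fwd forward hits (query = read, subject = gene), already
#'   filtered by the cascade
#' @param hits_rev reverse hits (query = gene, subject = read), same
#'   filtering; for a symmetric scorer this may be [swap_hits()] of an
#'   exhaustive forward table
#' @return the forward hit rows of the retained pairs
#' @export
reciprocal_best <- function(hits_fwd, hits_rev) {
  if (nrow(hits_fwd) == 0 || nrow(hits_rev) == 0)
    return(hits_fwd[0, , drop = FALSE])
  fb <- best_per_query(hits_fwd)                      # read -> best gene
  rev_by_read <- hits_rev[order(hits_rev$subject_id, hits_rev$evalue,
                                -hits_rev$aln_len, hits_rev$query_id), ,
                          drop = FALSE]
  rb <- rev_by_read[!duplicated(rev_by_read$subject_id), , drop = FALSE]
  rev_best <- stats::setNames(rb$query_id, rb$subject_id)  # read -> gene
  keep <- fb$subject_id == rev_best[fb$query_id]
  keep[is.na(keep)] <- FALSE
  out <- fb[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transpose a hit table (swap query and subject roles)
#'
#' @param hits hit table
#' @return hit table with query/subject ids and coordinates exchanged
#' @export
swap_hits <- function(hits) {
  out <- hits
  out$query_id <- hits$subject_id; out$subject_id <- hits$query_id
  out$q_start <- hits$s_start; out$q_end <- hits$s_end
  out$s_start <- hits$q_start; out$s_end <- hits$q_end
  out
}

#' Collapse MDA amplification artifacts
#'
#' Two or more byte-identical reads aligned to the same subject with the
#' same start and end points are amplification duplicates; all but the
#' lexicographically smallest read id are eliminated.
#'
#' @param assignments hit/assignment table carrying subject coordinates
#' @param read_sequences named character vector of read sequences
#' @return list: `assignments` (deduplicated), `removed` (read ids),
#'   `groups` (data.frame of collapsed duplicate sets)
#' @export
dedup_artifacts <- function(assignments, read_sequences) {
  if (nrow(assignments) == 0)
    return(list(assignments = assignments, removed = character(0),
                groups = data.frame()))
  key <- paste(assignments$db_tag, assignments$subject_id,
               assignments$s_start, assignments$s_end,
               read_sequences[assignments$query_id], sep = "\r")
  ord <- order(key, assignments$query_id)
  a <- assignments[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  removed <- unique(a$query_id[dup])
  kept_first <- a$query_id[!dup][match(key[dup], key[!dup])]
  groups <- if (any(dup))
    unique(data.frame(kept = kept_first, removed = a$query_id[dup],
                      stringsAsFactors = FALSE))
  else data.frame()
  out <- assignments[!(assignments$query_id %in% removed), , drop = FALSE]
  rownames(out) <- NULL
  list(assignments = out, removed = removed, groups = groups)
}

VENN_CLASSES <- c("ABC", "AB", "AC", "BC", "A", "B", "C")

profile_to_class <- function(genomes) {
  paste(sort(unique(genomes)), collapse = "")
}

#' Build the conserved-gene catalogue
#'
#' Applies the read-support quality criteria (single-read genes eliminated
#' as probable contaminants; UniGene/UniProt subjects with more than
#' `max_reads_extdb` reads excluded as probable repeats), links orthologous
#' subjects across the three genomes through their shared supporting reads,
#' and tallies the seven-region conservation Venn over ortholog groups.
#'
#' @param assignments deduplicated assignment table (one row per retained
#'   read-subject pair; `db_tag` in `genomeA/genomeB/genomeC/unigene/
#'   uniprot`)
#' @param gene_positions optional named list (by db_tag) of position tables
#'   (`gene_id, chrom, start, end`) used to annotate catalogue rows
#' @param min_reads minimum supporting reads per retained gene
#' @param max_reads_extdb exclusion threshold for UniGene/UniProt subjects
#' @return list of class `gene_catalogue`: `genes` (one row per retained
#'   (db, subject) with chromosome, position, read support, ortholog group
#'   and conservation profile), `venn` (named counts over ortholog groups),
#'   `venn_support` (fraction of each class with UniGene/UniProt support),
#'   `dropped` (subjects removed by each rule)
#' @export
build_gene_catalogue <- function(assignments, gene_positions = NULL,
                                 min_reads = 2L, max_reads_extdb = 50L) {
  if (nrow(assignments) == 0)
    stop("no assignments; run the filter cascade first")
  a <- assignments
  a$subj_key <- paste(a$db_tag, a$subject_id, sep = "\r")
  support <- table(a$subj_key)
  singletons <- names(support)[support < min_reads]
  ext <- grepl("^(unigene|uniprot)\r", names(support)) |
    grepl("^(unigene|uniprot)$", sub("\r.*", "", names(support)))
  too_deep <- names(support)[ext & support > max_reads_extdb]
  a <- a[!(a$subj_key %in% c(singletons, too_deep)), , drop = FALSE]
  if (nrow(a) == 0)
    stop("no subjects satisfy the read-support criteria")

  genome_tags <- c(genomeA = "A", genomeB = "B", genomeC = "C")
  ag <- a[a$db_tag %in% names(genome_tags), , drop = FALSE]
  # ortholog groups: connected components of the subject-read graph
  subj_ids <- unique(ag$subj_key)
  read_ids <- unique(ag$query_id)
  n_s <- length(subj_ids); n_r <- length(read_ids)
  parent <- seq_len(n_s + n_r)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  si <- match(ag$subj_key, subj_ids)
  ri <- n_s + match(ag$query_id, read_ids)
  for (k in seq_len(nrow(ag))) {
    rs <- find(si[k]); rr <- find(ri[k])
    if (rs != rr) parent[rs] <- rr
  }
  group_of_subj <- vapply(seq_len(n_s), find, integer(1))
  group_ids <- match(group_of_subj, sort(unique(group_of_subj)))

  # per-subject table
  subj_db <- sub("\r.*", "", subj_ids)
  subj_gene <- sub("^[^\r]*\r", "", subj_ids)
  reads_per_subj <- split(ag$query_id, si)
  subj_reads <- rep(list(character(0)), n_s)
  subj_reads[as.integer(names(reads_per_subj))] <-
    lapply(reads_per_subj, unique)

  # conservation profile per group
  grp_genomes <- split(genome_tags[subj_db], group_ids)
  grp_class <- vapply(grp_genomes, profile_to_class, character(1))

  # UniGene/UniProt support: any group read also assigned to an external db
  ext_reads <- unique(a$query_id[a$db_tag %in% c("unigene", "uniprot")])
  grp_reads <- split(unlist(subj_reads, use.names = FALSE),
                     rep(group_ids, lengths(subj_reads)))
  grp_ext <- vapply(grp_reads, function(r) any(r %in% ext_reads), logical(1))

  genes <- data.frame(
    gene_id = subj_gene, db_tag = subj_db,
    genome = unname(genome_tags[subj_db]),
    n_reads = lengths(subj_reads),
    group = group_ids,
    profile = unname(grp_class[as.character(group_ids)]),
    unig_uniprot_support = unname(grp_ext[as.character(group_ids)]),
    stringsAsFactors = FALSE)
  genes$supporting_reads <- subj_reads
  genes$chrom <- NA_character_; genes$position <- NA_integer_
  if (!is.null(gene_positions)) {
    for (db in names(gene_positions)) {
      p <- gene_positions[[db]]
      idx <- which(genes$db_tag == db)
      mm <- match(genes$gene_id[idx], p$gene_id)
      genes$chrom[idx] <- p$chrom[mm]
      genes$position[idx] <- (p$start[mm] + p$end[mm]) %/% 2L
    }
  }
  # external-db rows (kept per database; the catalogue keys on (db, subject))
  aext <- a[a$db_tag %in% c("unigene", "uniprot"), , drop = FALSE]
  if (nrow(aext)) {
    er <- split(aext$query_id, paste(aext$db_tag, aext$subject_id,
                                     sep = "\r"))
    ext_tab <- data.frame(
      gene_id = sub("^[^\r]*\r", "", names(er)),
      db_tag = sub("\r.*", "", names(er)),
      genome = NA_character_, n_reads = lengths(lapply(er, unique)),
      group = NA_integer_, profile = NA_character_,
      unig_uniprot_support = TRUE, stringsAsFactors = FALSE)
    ext_tab$supporting_reads <- lapply(er, unique)
    ext_tab$chrom <- NA_character_; ext_tab$position <- NA_integer_
    genes <- rbind(genes, ext_tab[, names(genes)])
  }
  venn <- stats::setNames(integer(length(VENN_CLASSES)), VENN_CLASSES)
  tv <- table(grp_class)
  venn[names(tv)] <- as.integer(tv)
  support_by_class <- vapply(VENN_CLASSES, function(cl) {
    in_cl <- grp_class == cl
    if (!any(in_cl)) return(NA_real_)
    mean(grp_ext[in_cl])
  }, numeric(1))
  structure(list(genes = genes, venn = venn,
                 venn_support = support_by_class,
                 dropped = list(single_read = sub("\r", ":", singletons),
                                too_many_reads = sub("\r", ":", too_deep))),
            class = "gene_catalogue")
}

#' @export
print.gene_catalogue <- function(x, ...) {
  cat("Gene catalogue:", nrow(x$genes), "retained (db, subject) entries\n")
  cat("  ortholog-group Venn:",
      paste(names(x$venn), x$venn, sep = "=", collapse = " "), "\n")
  cat("  dropped:", length(x$dropped$single_read), "single-read,",
      length(x$dropped$too_many_reads), "over-supported external subjects\n")
  invisible(x)
}

#' Contrast conservation-class composition between two arms
#'
#' For each Venn class, a two-tailed Fisher test of (class count vs rest)
#' between the two catalogues.
#'
#' @param venn_a,venn_b named Venn count vectors from
#'   [build_gene_catalogue()]
#' @return data.frame `class, count_a, count_b, p_value`
#' @export
venn_arm_contrast <- function(venn_a, venn_b) {
  stopifnot(setequal(names(venn_a), VENN_CLASSES),
            setequal(names(venn_b), VENN_CLASSES))
  tot_a <- sum(venn_a); tot_b <- sum(venn_b)
  out <- data.frame(class = VENN_CLASSES,
                    count_a = as.integer(venn_a[VENN_CLASSES]),
                    count_b = as.integer(venn_b[VENN_CLASSES]))
  out$p_value <- vapply(seq_len(nrow(out)), function(i)
    fisher_two_tailed(out$count_a[i], tot_a - out$count_a[i],
                      out$count_b[i], tot_b - out$count_b[i]), numeric(1))
  out
}

#' Run the full homology cascade against the three reference genomes
#'
#' Convenience driver: (optional) organellar screen, per-genome similarity
#' search, threshold filtering, reciprocal best hits, artifact dedup.
#' Nucleotide mode searches CDS sets directly (desk-scale); translated mode
#' mirrors the protein-database search of the published cascade.
#'
#' @param reads retained non-repetitive reads (data.frame with
#'   `sequence_masked` or `sequence`)
#' @param references output of [simulate_reference_genomes()], or any list
#'   with `genomes$A/B/C` each holding `cds` and `pos`
#' @param mode `"nt"` or `"translated"` (see [internal_search()])
#' @param organelle optional organellar genome sequence(s) for the screen
#' @param ... passed to [internal_search()]
#' @return list: `assignments` (deduplicated read-gene table over all
#'   genomes), `removed_organellar`, `removed_artifacts`, per-genome hit
#'   counts
#' @export
homology_cascade <- function(reads, references, mode = c("nt", "translated"),
                             organelle = NULL, ...) {
  mode <- match.arg(mode)
  reads <- as_read_frame(reads)
  qseq <- stats::setNames(
    if ("sequence_masked" %in% names(reads)) reads$sequence_masked
    else reads$sequence, reads$read_id)
  removed_org <- character(0)
  if (!is.null(organelle)) {
    og <- if (is.character(organelle) && is.null(names(organelle)))
      c(organelle = organelle) else organelle
    oh <- internal_search(qseq, og, mode = "nt", db_tag = "organelle", ...)
    fo <- filter_organellar(reads, oh)
    removed_org <- fo$removed
    reads <- fo$reads
    qseq <- qseq[reads$read_id]
  }
  # one combined scan over all genomes (subjects name-prefixed), split
  # back per genome so best-hit and RBH selection stay within-database
  gnames <- names(references$genomes)
  subj_all <- unlist(lapply(gnames, function(g) {
    cds <- references$genomes[[g]]$cds
    if (mode == "translated")
      cds <- vapply(cds, function(s) translate_frame(s, 0L), character(1))
    stats::setNames(cds, paste0(g, "|", names(cds)))
  }))
  split_db <- function(h, col) {
    g <- sub("\\|.*", "", h[[col]])
    h[[col]] <- sub("^[^|]*\\|", "", h[[col]])
    h$db_tag <- paste0("genome", g)
    split(h, h$db_tag)
  }
  if (mode == "nt") {
    fwd_all <- internal_search(qseq, subj_all, mode = "nt", ...)
    fwd_all <- split_db(fwd_all, "subject_id")
    rev_all <- internal_search(subj_all, qseq, mode = "nt", ...)
    rev_all <- split_db(rev_all, "query_id")
  } else {
    fwd_all <- internal_search(qseq, subj_all, mode = "translated", ...)
    fwd_all <- split_db(fwd_all, "subject_id")
    rev_all <- lapply(fwd_all, swap_hits)
  }
  per_db <- list()
  for (g in gnames) {
    tag <- paste0("genome", g)
    fwd <- fwd_all[[tag]] %||% empty_hits()
    rev <- rev_all[[tag]] %||% empty_hits()
    if (mode == "nt") {
      fwd <- filter_nucleotide_hits(fwd, best_only = FALSE)
      rev <- filter_nucleotide_hits(rev, best_only = FALSE)
    } else {
      fwd <- filter_protein_hits(fwd)
      rev <- filter_protein_hits(rev)
    }
    per_db[[tag]] <- reciprocal_best(fwd, rev)
  }
  assignments <- do.call(rbind, per_db)
  rownames(assignments) <- NULL
  dd <- dedup_artifacts(assignments, qseq)
  list(assignments = dd$assignments,
       removed_organellar = removed_org,
       removed_artifacts = dd$removed,
       hit_counts = vapply(per_db, nrow, integer(1)))
}
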