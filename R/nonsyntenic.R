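# Validation of non-syntenic conserved genes and calling of putative
# lineage-specific (wheat-specific) rearrangements.
#
# Pseudogenes and amplified fragments attract reads unevenly; the evenness
# test generalizes the published 2/3-read rule: a gene covered by n reads
# is split into k = min(n, 4) equal segments and is genuine only if every
# segment is overlapped by at least one read.

#' Read-coverage evenness test
#'
#' @param gene_len gene length (bp)
#' @param read_intervals data.frame of half-open read-alignment intervals
#'   on the gene (`start`, `end`), one row per read
#' @param n_segments_cap maximum number of equal segments (default 4; the
#'   2- and 3-read cases reduce to the published rule)
#' @return `"genuine"` if every segment is overlapped by at least one read
#'   interval, else `"artefactual"`
#' @export
evenness_test <- function(gene_len, read_intervals, n_segments_cap = 4L) {
  n <- nrow(read_intervals)
  if (n < 2) stop("evenness test requires >= 2 reads ",
                  "(single-read genes are eliminated upstream)")
  check_intervals(read_intervals, len = gene_len, what = "read interval")
  k <- min(n, n_segments_cap)
  bounds <- gene_len * (0:k) / k
  for (s in seq_len(k)) {
    covered <- any(read_intervals$start < bounds[s + 1] &
                     read_intervals$end > bounds[s])
    if (!covered) return("artefactual")
  }
  "genuine"
}

#' Find non-syntenic conserved candidate genes
#'
#' Genes conserved with all three reference genomes (profile `ABC`),
#' supported by at least `min_reads` reads, whose ordering-reference
#' position lies outside every syntenic block of the arm.
#'
#' @param catalogue a [build_gene_catalogue()] result with positions
#' @param blocks syntenic block table ([call_syntenic_blocks()])
#' @param min_reads minimum read support
#' @return data.frame of candidate genome A gene rows
#' @export
find_nonsyntenic_conserved <- function(catalogue, blocks, min_reads = 2L) {
  g <- catalogue$genes
  g <- g[g$db_tag == "genomeA" & g$profile == "ABC" &
           g$n_reads >= min_reads & !is.na(g$position), , drop = FALSE]
  if (nrow(blocks)) {
    inside <- rep(FALSE, nrow(g))
    for (b in seq_len(nrow(blocks)))
      inside <- inside | (g$chrom == blocks$ref_chrom[b] &
                            g$position >= blocks$start[b] &
                            g$position < blocks$end[b])
    g <- g[!inside, , drop = FALSE]
  }
  rownames(g) <- NULL
  g
}

#' Coverage profiles of candidate genes from their read alignments
#'
#' @param candidates candidate rows from [find_nonsyntenic_conserved()]
#' @param assignments assignment table carrying subject coordinates
#' @param gene_lengths named vector of reference CDS lengths
#' @return named list of `CoverageProfile`-style lists (`gene_id`,
#'   `gene_len`, `read_intervals`, `n_reads`)
#' @export
coverage_profiles <- function(candidates, assignments, gene_lengths) {
  a <- assignments[assignments$db_tag == "genomeA", , drop = FALSE]
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    gid <- candidates$gene_id[i]
    h <- a[a$subject_id == gid, , drop = FALSE]
    list(gene_id = gid, gene_len = unname(gene_lengths[gid]),
         read_intervals = data.frame(start = h$s_start, end = h$s_end,
                                     read_id = h$query_id),
         n_reads = nrow(h))
  })
  stats::setNames(out, candidates$gene_id)
}

#' Mutual synteny of reference orthologs between the three genomes
#'
#' Applies the same block-calling machinery pairwise between the reference
#' genomes: for each ordered genome pair, the density of shared orthologs
#' along the first genome's chromosomes is thresholded and merged into
#' blocks; a gene is pair-syntenic when it lies inside a shared-ortholog
#' block on both sides, and mutually syntenic when all three pairs agree.
#'
#' @param references reference bundle ([simulate_reference_genomes()])
#' @param window,step,min_genes_per_mb block parameters (as for the arm)
#' @return data.frame `gene_id, mutually_syntenic, pair_AB, pair_AC,
#'   pair_BC` for genes present in all three genomes
#' @export
cross_genome_synteny <- function(references, window = 500000, step = 50000,
                                 min_genes_per_mb = 50) {
  gn <- references$genomes
  ids <- Reduce(intersect, lapply(gn, function(g) g$pos$gene_id))
  pair_flag <- list()
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    flag <- rep(TRUE, length(ids))
    for (side in pr) {
      pos <- gn[[side]]$pos
      pos <- pos[match(ids, pos$gene_id), , drop = FALSE]
      mid <- (pos$start + pos$end) %/% 2L
      chrom_len <- tapply(gn[[side]]$pos$end, gn[[side]]$pos$chrom, max)
      inside <- rep(FALSE, length(ids))
      for (ch in unique(pos$chrom)) {
        sel <- pos$chrom == ch
        dens <- window_density(mid[sel], chrom_len = chrom_len[[ch]],
                               window = window, step = step)
        thr <- min_genes_per_mb * window / 1e6
        ok <- dens[dens$count >= thr, , drop = FALSE]
        if (!nrow(ok)) next
        iv <- merge_intervals(ok[, c("start", "end")])
        for (r in seq_len(nrow(iv)))
          inside[sel] <- inside[sel] | (mid[sel] >= iv$start[r] &
                                          mid[sel] < iv$end[r])
      }
      flag <- flag & inside
    }
    pair_flag[[paste(pr, collapse = "")]] <- flag
  }
  data.frame(gene_id = ids,
             mutually_syntenic = pair_flag$AB & pair_flag$AC & pair_flag$BC,
             pair_AB = pair_flag$AB, pair_AC = pair_flag$AC,
             pair_BC = pair_flag$BC, stringsAsFactors = FALSE)
}

#' Call putative wheat-specific rearrangements
#'
#' Among non-syntenic conserved candidates that pass the evenness test, a
#' gene whose three reference orthologs occupy mutually syntenic positions
#' points to a rearrangement specific to the wheat lineage (the gene moved
#' after wheat diverged from the common ancestor of the references).
#'
#' @param candidates candidate rows from [find_nonsyntenic_conserved()]
#' @param profiles coverage profiles ([coverage_profiles()])
#' @param synteny_table [cross_genome_synteny()] output (or any table with
#'   `gene_id` and `mutually_syntenic`)
#' @param n_segments_cap passed to [evenness_test()]
#' @return data.frame `gene_id, n_reads, evenness, mutually_syntenic,
#'   wheat_specific`; genes absent from the synteny table are skipped with
#'   a warning
#' @export
classify_wheat_specific <- function(candidates, profiles, synteny_table,
                                    n_segments_cap = 4L) {
  missing <- setdiff(candidates$gene_id, synteny_table$gene_id)
  if (length(missing)) {
    warning(length(missing), " candidate gene(s) missing from the synteny",
            " table; skipped")
    candidates <- candidates[!(candidates$gene_id %in% missing), ,
                             drop = FALSE]
  }
  if (nrow(candidates) == 0)
    return(data.frame(gene_id = character(0), n_reads = integer(0),
                      evenness = character(0),
                      mutually_syntenic = logical(0),
                      wheat_specific = logical(0)))
  ev <- vapply(candidates$gene_id, function(gid) {
    p <- profiles[[gid]]
    evenness_test(p$gene_len, p$read_intervals, n_segments_cap)
  }, character(1))
  ms <- synteny_table$mutually_syntenic[
    match(candidates$gene_id, synteny_table$gene_id)]
  data.frame(gene_id = candidates$gene_id,
             n_reads = candidates$n_reads,
             evenness = unname(ev),
             mutually_syntenic = ms,
             wheat_specific = ev == "genuine" & ms,
             stringsAsFactors = FALSE)
}
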