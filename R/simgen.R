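# Synthetic chromosome-arm survey generator.
#
# Emulates the inputs of a flow-sorted chromosome-arm shotgun survey: three
# model reference genomes sharing an ancestral gene order with per-lineage
# losses and moves; a wheat-like arm carrying syntenic gene runs (with a
# planted inversion and a three-segment order reversal), non-syntenic
# insertions biased toward one telomere, near-identical transposable-element
# copies tiled to a target repeat fraction (some carrying a captured
# tRNA-like token); shotgun reads with configurable purity and exact MDA
# duplicate artifacts; deletion-bin markers; and transcripts with planted
# coverage classes.  Everything is recorded in a truth set so each pipeline
# stage can be scored.

#' Simulation configuration
#'
#' All fractions are in \[0,1\]; coordinates are 0-based half-open.  Defaults
#' are the survey conditions of the long-arm dataset the pipeline targets
#' (1.61-fold coverage, 347.25 bp mean reads, 85.5% sorting purity, ~75%
#' repeat content) with generator-specific structure documented in the
#' methods vignette.
#'
#' @param seed integer RNG seed; the same config is byte-reproducible
#' @param n_genes syntenic arm genes (>= 20)
#' @param arm_size arm length in bp, or `NULL` to derive it from the genic
#'   length and `repeat_fraction`
#' @param mean_cds_len mean CDS length (bp, rounded to codons)
#' @param gene_gap_min minimum non-genic separation between genes (bp)
#' @param repeat_fraction fraction of the arm covered by TE copies
#' @param n_repeat_families TE families; `library_fraction` of them are
#'   present in the emitted repeat library, the rest are "novel" and only
#'   detectable by assembly depth
#' @param library_fraction see above
#' @param te_len_range min/max TE consensus length (bp)
#' @param te_divergence per-base substitution rate of TE copies relative to
#'   their family consensus (0 = recently amplified, identical copies)
#' @param trna_capture_rate fraction of TE copies carrying a 75 bp
#'   tRNA-like token insertion
#' @param n_trna_genic standalone (non-TE) tRNA-like tokens planted in
#'   non-repetitive sequence
#' @param mean_read_len,read_len_sd truncated-normal read length (min 50 bp)
#' @param coverage_fold target fold coverage; the read count is
#'   `round(coverage_fold * arm_size / mean_read_len)`
#' @param purity fraction of reads from the target arm, in (0,1]
#' @param organelle_fraction fraction of all reads drawn from a simulated
#'   organellar genome (a subset of the impurity; forced to 0 when
#'   `purity = 1`)
#' @param artifact_rate fraction of reads emitted as byte-identical
#'   duplicates of another read (MDA amplification artifacts)
#' @param read_strands `"both"` or `"forward"`
#' @param rearrangement_spec list of rearrangements applied to the syntenic
#'   gene order; each element is `list(type, genes = c(first, last), ...)`
#'   with `type` one of `"inversion"`, `"segment_reversal"` (extra field
#'   `segments`), `"translocation_out"`.  `NULL` plants the default
#'   structure: one inversion in the first reference region and a 3-segment
#'   order reversal of the second.
#' @param region_split fraction of syntenic genes in the first reference
#'   region (reference chromosome `"chr4"`); the rest sit on `"chr1"`
#' @param n_nonsyntenic non-syntenic gene insertions (reference location on
#'   other chromosomes); `n_wheat_specific` of them are mutually syntenic
#'   between the three references (planted lineage-specific translocations)
#' @param n_wheat_specific see above
#' @param n_fragment_genes non-syntenic insertions present only as a 5'
#'   fragment (planted pseudogene-like artefacts for the evenness test)
#' @param n_duplicated syntenic genes receiving a second, non-syntenic copy
#' @param nonsyntenic_telomere_bias fraction of non-syntenic insertions
#'   placed in the distal 10% of the arm
#' @param conservation_props named length-7 vector of gene conservation
#'   class proportions, names `ABC, AB, AC, BC, A, B, C`
#' @param lineage_move_rate per-genome fraction of ordinary genes relocated
#'   to a random other chromosome (breaking synteny in that lineage)
#' @param genome_divergence per-base substitution rate of each reference
#'   genome relative to the ancestor
#' @param wheat_divergence per-base substitution rate of the wheat arm copy
#'   relative to the ancestor
#' @param n_bins deletion bins (equal arm intervals, labels `B1..Bk`)
#' @param marker_fraction fraction of (non-fragment) arm genes with a
#'   deletion-bin-mapped marker
#' @param transcript_fraction_high,transcript_fraction_low fractions of arm
#'   genes given high (>= 60%) / low (20-60%) transcript coverage; the rest
#'   get none
#' @param cont_n_genes,cont_repeat_fraction gene count and repeat fraction
#'   of the contaminant source
#' @param cont_size_factor contaminant source size as a multiple of the
#'   target arm: impurities originate from the whole rest of the genome,
#'   so their per-gene coverage must be far below the target arm's (the
#'   single-read contaminant filter relies on exactly this dilution)
#' @param backdrop_factor ordinary reference genes (never on the arm)
#'   interleaved per non-syntenic pool gene on the pool chromosomes, so
#'   the references are gene-dense there while arm evidence stays sparse
#' @param arm_label label attached to reads and outputs
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       arm_size = NULL,
                       mean_cds_len = 450L,
                       gene_gap_min = 150L,
                       repeat_fraction = 0.75,
                       n_repeat_families = 10L,
                       library_fraction = 0.8,
                       te_len_range = c(2000L, 4000L),
                       te_divergence = 0,
                       trna_capture_rate = 0.10,
                       n_trna_genic = 12L,
                       mean_read_len = 347.25,
                       read_len_sd = 60,
                       coverage_fold = 1.61,
                       purity = 0.855,
                       organelle_fraction = 0.01,
                       artifact_rate = 0.02,
                       read_strands = c("both", "forward"),
                       rearrangement_spec = NULL,
                       region_split = 0.35,
                       n_nonsyntenic = 80L,
                       n_wheat_specific = 30L,
                       n_fragment_genes = 15L,
                       n_duplicated = 30L,
                       nonsyntenic_telomere_bias = 0.6,
                       conservation_props = c(ABC = 0.60, AB = 0.10,
                                              AC = 0.10, BC = 0.05,
                                              A = 0.07, B = 0.04, C = 0.04),
                       lineage_move_rate = 0.05,
                       genome_divergence = 0.03,
                       wheat_divergence = 0.02,
                       n_bins = 8L,
                       marker_fraction = 0.25,
                       transcript_fraction_high = 0.60,
                       transcript_fraction_low = 0.25,
                       cont_n_genes = NULL,
                       cont_repeat_fraction = 0.75,
                       cont_size_factor = 4,
                       backdrop_factor = 9L,
                       arm_label = "armL") {
  read_strands <- match.arg(read_strands)
  cfg <- as.list(environment())
  fr <- c(repeat_fraction, purity, artifact_rate, library_fraction,
          trna_capture_rate, nonsyntenic_telomere_bias, region_split,
          lineage_move_rate, genome_divergence, wheat_divergence,
          te_divergence, marker_fraction, transcript_fraction_high,
          transcript_fraction_low, organelle_fraction, cont_repeat_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (n_genes < 20) stop("n_genes must be >= 20")
  if (coverage_fold <= 0) stop("coverage_fold must be > 0")
  if (purity <= 0) stop("purity must be in (0, 1]")
  if (transcript_fraction_high + transcript_fraction_low > 1)
    stop("transcript class fractions exceed 1")
  if (sum(conservation_props) <= 0 || length(conservation_props) != 7 ||
      !setequal(names(conservation_props),
                c("ABC", "AB", "AC", "BC", "A", "B", "C")))
    stop("conservation_props must be a named length-7 vector")
  cfg$conservation_props <- conservation_props / sum(conservation_props)
  if (n_wheat_specific > n_nonsyntenic)
    stop("n_wheat_specific cannot exceed n_nonsyntenic")
  if (purity >= 1) cfg$organelle_fraction <- 0
  if (cfg$organelle_fraction > 1 - purity + 1e-12)
    stop("organelle_fraction must not exceed the impurity 1 - purity")
  if (is.null(cont_n_genes)) cfg$cont_n_genes <- max(20L, round(n_genes * 0.1))
  if (is.null(rearrangement_spec)) {
    # inversion span mirrors the published case: ~12% of the first
    # reference region's genes, well inside the region
    n1 <- round(region_split * n_genes)
    cfg$rearrangement_spec <- list(
      list(type = "inversion",
           genes = c(max(2L, round(0.12 * n_genes)),
                     round(0.165 * n_genes))),
      list(type = "segment_reversal", genes = c(n1 + 1L, n_genes),
           segments = 3L))
  }
  for (rs in cfg$rearrangement_spec) {
    if (!rs$type %in% c("inversion", "segment_reversal", "translocation_out"))
      stop("unknown rearrangement type: ", rs$type)
    if (rs$genes[1] < 1 || rs$genes[2] > n_genes || rs$genes[1] > rs$genes[2])
      stop("rearrangement gene range out of bounds")
  }
  if (!is.null(arm_size) && mean_read_len >= arm_size)
    stop("mean_read_len must be smaller than arm_size")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The file maps 1:1 onto [sim_config()] arguments; unknown keys are an
#' error so typos never silently fall back to defaults.
#'
#' @param path YAML file
#' @return validated `sim_config`
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$conservation_props))
    vals$conservation_props <- unlist(vals$conservation_props)
  if (!is.null(vals$rearrangement_spec))
    vals$rearrangement_spec <- lapply(vals$rearrangement_spec, function(rs) {
      rs$genes <- as.integer(unlist(rs$genes)); rs
    })
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes, repeat fraction %.2f, coverage %.2fx, purity %.3f, seed %d\n",
    x$n_genes, x$repeat_fraction, x$coverage_fold, x$purity, x$seed))
  invisible(x)
}

GENOMES <- c("A", "B", "C")
# gene spacing on reference chromosomes: syntenic gene-dense regions of
# compact model grass genomes run well above 100 genes/Mb
REF_SPACING <- 6000L

# conservation class name -> genome presence
class_genomes <- function(class) {
  list(ABC = c("A", "B", "C"), AB = c("A", "B"), AC = c("A", "C"),
       BC = c("B", "C"), A = "A", B = "B", C = "C")[[class]]
}

#' Simulate three annotated model reference genomes
#'
#' Generates an ancestral gene complement (arm-syntenic genes on reference
#' chromosomes `chr4`/`chr1`, a non-syntenic pool on `chr2`/`chr3`,
#' contaminant-arm genes on `chr5`), assigns each gene a conservation class,
#' derives each genome's CDS by independent point mutation of the ancestor,
#' and lays genes out in ancestral order with per-lineage random relocations.
#'
#' @param config a [sim_config()]
#' @return list with `genomes` (per genome: `cds` named character vector and
#'   `pos` data.frame `gene_id, chrom, start, end, strand`), `genes`
#'   (per-gene metadata: id, role, class, region, ancestral CDS, order) and
#'   `config`
#' @export
simulate_reference_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    n_syn <- config$n_genes
    n_pool <- config$n_nonsyntenic + config$n_fragment_genes
    n_back <- config$backdrop_factor * n_pool
    n_cont <- config$cont_n_genes
    n_tot <- n_syn + n_pool + n_back + n_cont
    gene_id <- sprintf("G%05d", seq_len(n_tot))

    # roles: arm-syntenic genes first; then the pool chromosomes carry
    # ordinary backdrop genes with the non-syntenic pool interleaved
    # sparsely among them (so pool regions are gene-dense in the
    # references but arm evidence there stays sparse); contaminant-arm
    # genes last
    role <- rep("backdrop", n_tot)
    role[seq_len(n_syn)] <- "syntenic"
    role[n_syn + n_pool + n_back + seq_len(n_cont)] <- "contaminant"
    sec <- n_syn + seq_len(n_pool + n_back)            # pool section indices
    if (n_pool > 0) {
      pool_slots <- round(seq(1, length(sec), length.out = n_pool))
      pool_roles <- sample(c(rep("wheat_specific", config$n_wheat_specific),
                             rep("nonsyntenic",
                                 config$n_nonsyntenic - config$n_wheat_specific),
                             rep("fragment", config$n_fragment_genes)))
      role[sec[pool_slots]] <- pool_roles
    }

    # CDS lengths in whole codons around the configured mean
    len <- 3L * pmax(60L, round(stats::runif(n_tot, 0.7, 1.3) *
                                  config$mean_cds_len / 3))
    ancestral <- vapply(len, random_dna, character(1))
    class <- sample(names(config$conservation_props), n_tot, replace = TRUE,
                    prob = config$conservation_props)
    # pool insertions, fragments and the backdrop model genes conserved
    # with all three references; contaminant genes keep sampled classes
    class[role %in% c("wheat_specific", "nonsyntenic", "fragment",
                      "backdrop")] <- "ABC"

    # reference chromosome layout (ancestral order)
    n1 <- round(config$region_split * n_syn)
    chrom <- character(n_tot)
    chrom[seq_len(n_syn)] <- ifelse(seq_len(n_syn) <= n1, "chr4", "chr1")
    chrom[sec] <- rep_len(c("chr2", "chr3"), length(sec))
    chrom[n_syn + n_pool + n_back + seq_len(n_cont)] <- "chr5"

    # each plain non-syntenic pool gene is relocated in one reference
    # lineage (breaking mutual synteny there); wheat-specific pool genes
    # stay put in all three (the move happened on the wheat lineage)
    move_genome <- rep(NA_character_, n_tot)
    ns_idx <- which(role == "nonsyntenic")
    move_genome[ns_idx] <- sample(GENOMES, length(ns_idx), replace = TRUE)

    genes <- data.frame(gene_id = gene_id, role = role, class = class,
                        chrom = chrom, len = len,
                        move_genome = move_genome, stringsAsFactors = FALSE)
    genes$seq <- ancestral

    genomes <- list()
    for (g in GENOMES) {
      present <- vapply(class, function(cl) g %in% class_genomes(cl),
                        logical(1))
      idx <- which(present)
      seqs <- vapply(ancestral[idx],
                     function(s) mutate_seq(s, config$genome_divergence),
                     character(1), USE.NAMES = FALSE)
      names(seqs) <- gene_id[idx]
      pos <- data.frame(gene_id = gene_id[idx], chrom = chrom[idx],
                        stringsAsFactors = FALSE)
      # lineage-specific relocations: a random fraction of ordinary genes,
      # plus the planted per-lineage moves of plain non-syntenic genes
      movable <- which(role[idx] %in% c("syntenic", "contaminant"))
      n_move <- round(config$lineage_move_rate * length(movable))
      moved <- if (n_move > 0) sample(movable, n_move) else integer(0)
      moved <- union(moved, which(!is.na(move_genome[idx]) &
                                    move_genome[idx] == g))
      pos$moved <- FALSE
      if (length(moved)) {
        pos$chrom[moved] <- sample(c("chr9", "chr10"), length(moved),
                                   replace = TRUE)
        pos$moved[moved] <- TRUE
      }
      # ancestral order within each chromosome; moved genes land at sparse
      # random positions on their new chromosome
      pos$start <- NA_integer_
      for (ch in unique(pos$chrom)) {
        on_ch <- which(pos$chrom == ch)
        if (ch %in% c("chr9", "chr10")) {
          pos$start[on_ch] <- sort(sample.int(5e7, length(on_ch))) * 10L
        } else {
          pos$start[on_ch] <- (seq_along(on_ch) - 1L) * REF_SPACING
        }
      }
      pos$end <- pos$start + len[idx]
      pos$strand <- "+"
      genomes[[g]] <- list(cds = seqs, pos = pos)
    }
    list(genomes = genomes, genes = genes, config = config)
  })
}

# apply the configured rearrangements to the syntenic order (vector of gene
# indices); returns list(order, segments) where segments records the planted
# structure
apply_rearrangements <- function(order, spec) {
  segments <- list()
  for (rs in spec) {
    a <- rs$genes[1]; b <- rs$genes[2]
    pos <- which(order %in% a:b)        # positions of the range in the order
    if (!length(pos)) next
    pos <- seq(min(pos), max(pos))
    if (rs$type == "inversion") {
      order[pos] <- rev(order[pos])
      segments[[length(segments) + 1L]] <-
        data.frame(type = "inversion", segment = NA_integer_,
                   orientation = "-", first_gene = a, last_gene = b)
    } else if (rs$type == "segment_reversal") {
      k <- rs$segments
      grp <- even_groups(length(pos), k)
      reordered <- unlist(lapply(rev(seq_len(k)),
                                 function(s) order[pos[grp == s]]))
      for (s in seq_len(k)) {
        rng <- range(order[pos[grp == s]])
        segments[[length(segments) + 1L]] <-
          data.frame(type = "segment_reversal", segment = s,
                     orientation = "+", first_gene = rng[1],
                     last_gene = rng[2])
      }
      order[pos] <- reordered
    } else if (rs$type == "translocation_out") {
      segments[[length(segments) + 1L]] <-
        data.frame(type = "translocation_out", segment = NA_integer_,
                   orientation = NA_character_, first_gene = a,
                   last_gene = b)
      order <- order[!(order %in% a:b)]
    }
  }
  list(order = order,
       segments = if (length(segments)) do.call(rbind, segments)
                  else data.frame())
}

# generate TE copies summing exactly to the budget (the final copy is
# trimmed); returns list of pieces (sequence + family + token flag)
make_repeat_copies <- function(families, budget, config, token) {
  pieces <- list()
  total <- 0L
  fam_names <- names(families)
  while (total < budget) {
    f <- sample(fam_names, 1)
    full <- families[[f]]
    frac <- stats::runif(1, 0.4, 1)
    lenc <- max(100L, round(frac * nchar(full)))
    from_start <- stats::runif(1) < 0.5
    s <- if (from_start) substr(full, 1, lenc)
         else substr(full, nchar(full) - lenc + 1L, nchar(full))
    if (config$te_divergence > 0) s <- mutate_seq(s, config$te_divergence)
    has_token <- nchar(token) > 0 &&
      stats::runif(1) < config$trna_capture_rate
    if (has_token && nchar(s) > 200) {
      at <- sample.int(nchar(s) - 100L, 1) + 50L
      s <- paste0(substr(s, 1, at), token, substr(s, at + 1L, nchar(s)))
    }
    if (stats::runif(1) < 0.5) s <- revcomp(s)
    remaining <- budget - total
    if (nchar(s) > remaining) {
      if (remaining < 60L) break        # < 60 bp short of budget: close enough
      s <- substr(s, 1, remaining)
    }
    pieces[[length(pieces) + 1L]] <- list(seq = s, family = f,
                                          token = has_token)
    total <- total + nchar(s)
  }
  pieces
}

# assemble an arm sequence from ordered gene pieces plus repeat/filler pieces
# distributed into the gaps; returns sequence + coordinate tables
assemble_arm <- function(gene_pieces, repeat_pieces, filler_total,
                         extra_pieces, gene_gap_min) {
  n_gaps <- length(gene_pieces) + 1L
  base_fill <- rep(gene_gap_min, n_gaps)
  spare <- max(0L, filler_total - sum(base_fill))
  # distribute the spare filler randomly over the gaps
  add <- if (spare > 0) tabulate(sample.int(n_gaps, spare, replace = TRUE),
                                 n_gaps) else rep(0L, n_gaps)
  gap_assign <- if (length(repeat_pieces))
    sample.int(n_gaps, length(repeat_pieces), replace = TRUE) else integer(0)
  extra_assign <- if (length(extra_pieces))
    sample.int(n_gaps, length(extra_pieces), replace = TRUE) else integer(0)

  seq_parts <- character(0)
  gene_coord <- data.frame(start = integer(length(gene_pieces)),
                           end = integer(length(gene_pieces)))
  rep_coord <- list(); extra_coord <- list()
  cursor <- 0L
  emit <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    start <- cursor
    cursor <<- cursor + nchar(s)
    c(start, cursor)
  }
  for (gap in seq_len(n_gaps)) {
    # filler halves flank the repeat pieces so genes never abut repeats
    fill_len <- base_fill[gap] + add[gap]
    lead <- fill_len %/% 2L
    if (lead > 0) emit(random_dna(lead))
    for (ri in which(gap_assign == gap)) {
      rc <- emit(repeat_pieces[[ri]]$seq)
      rep_coord[[length(rep_coord) + 1L]] <-
        data.frame(start = rc[1], end = rc[2],
                   family = repeat_pieces[[ri]]$family,
                   token = repeat_pieces[[ri]]$token)
    }
    for (ei in which(extra_assign == gap)) {
      ec <- emit(extra_pieces[[ei]]$seq)
      extra_coord[[length(extra_coord) + 1L]] <-
        data.frame(start = ec[1], end = ec[2],
                   isotype = extra_pieces[[ei]]$isotype)
    }
    if (fill_len - lead > 0) emit(random_dna(fill_len - lead))
    if (gap <= length(gene_pieces)) {
      gc <- emit(gene_pieces[[gap]])
      gene_coord$start[gap] <- gc[1]
      gene_coord$end[gap] <- gc[2]
    }
  }
  list(sequence = paste(seq_parts, collapse = ""),
       gene_coord = gene_coord,
       repeat_coord = if (length(rep_coord)) do.call(rbind, rep_coord)
                      else data.frame(start = integer(0), end = integer(0),
                                      family = character(0),
                                      token = logical(0)),
       extra_coord = if (length(extra_coord)) do.call(rbind, extra_coord)
                     else data.frame(start = integer(0), end = integer(0),
                                     isotype = character(0)))
}

#' Simulate the wheat-like chromosome arm
#'
#' Copies the syntenic genes of the reference framework onto the arm (in
#' ancestral order with the configured rearrangements applied), inserts
#' non-syntenic genes with the configured telomeric bias, plants duplicated
#' genes and 5'-fragment pseudogenes, tiles TE copies to the target repeat
#' fraction, and records all coordinates, segment structure and deletion-bin
#' boundaries in a truth set.
#'
#' @param config a [sim_config()]
#' @param references output of [simulate_reference_genomes()] for the same
#'   config
#' @return list with `sequence` (character), `truth` (list: `arm_size`,
#'   `genes`, `repeats`, `segments`, `bins`, `trna_sites`, `token_table`),
#'   `gene_seqs` (wheat copies), `repeat_library` (library families only),
#'   `families` (all family consensi)
#' @export
simulate_wheat_arm <- function(config, references) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 2L), {
    genes <- references$genes
    n_syn <- config$n_genes

    rr <- apply_rearrangements(seq_len(n_syn), config$rearrangement_spec)
    syn_order <- rr$order

    # wheat copies of every gene that will appear on the arm
    pool_ids <- genes$gene_id[genes$role %in%
                                c("wheat_specific", "nonsyntenic", "fragment")]
    dup_src <- sample(genes$gene_id[seq_len(n_syn)][
      seq_len(n_syn) %in% syn_order], config$n_duplicated)
    arm_gene_ids <- c(genes$gene_id[syn_order], pool_ids)
    wheat_seq <- vapply(
      genes$seq[match(unique(c(arm_gene_ids, dup_src)), genes$gene_id)],
      function(s) mutate_seq(s, config$wheat_divergence),
      character(1), USE.NAMES = FALSE)
    names(wheat_seq) <- unique(c(arm_gene_ids, dup_src))

    # ordered slot list: syntenic genes first, then insertions at biased slots
    slots <- data.frame(gene_id = genes$gene_id[syn_order],
                        kind = "syntenic", stringsAsFactors = FALSE)
    dup_ids <- if (length(dup_src)) paste0(dup_src, ".dup") else character(0)
    ins <- data.frame(gene_id = c(pool_ids, dup_ids),
                      kind = c(genes$role[match(pool_ids, genes$gene_id)],
                               rep("duplicate", length(dup_src))),
                      stringsAsFactors = FALSE)
    if (nrow(ins)) {
      ins <- ins[sample.int(nrow(ins)), , drop = FALSE]
      # each insertion draws a slot of the FINAL gene order: with
      # probability `nonsyntenic_telomere_bias` from the distal 10% of
      # slots, otherwise uniformly; syntenic genes fill the rest in order
      m <- nrow(ins)
      n_fin <- nrow(slots) + m
      distal_lo <- floor(0.9 * n_fin) + 1L
      avail <- rep(TRUE, n_fin)
      ranks <- integer(m)
      distal <- stats::runif(m) < config$nonsyntenic_telomere_bias
      for (i in seq_len(m)) {
        pool <- if (distal[i]) which(avail & seq_len(n_fin) >= distal_lo)
                else which(avail)
        if (!length(pool)) pool <- which(avail)
        ranks[i] <- pool[sample.int(length(pool), 1)]
        avail[ranks[i]] <- FALSE
      }
      combined <- rbind(slots, ins)
      idx <- integer(n_fin)
      idx[which(avail)] <- seq_len(nrow(slots))
      idx[ranks] <- nrow(slots) + seq_len(m)
      slots <- combined[idx, , drop = FALSE]
    }
    src_id <- sub("\\.dup$", "", slots$gene_id)
    piece_seq <- unname(wheat_seq[src_id])
    # fragments appear only as their 5' portion
    frag <- slots$kind == "fragment"
    if (any(frag)) {
      keep_frac <- stats::runif(sum(frag), 0.35, 0.45)
      piece_seq[frag] <- substr(piece_seq[frag], 1,
                                pmax(120, round(keep_frac * nchar(piece_seq[frag]))))
    }
    gene_strand <- sample(c("+", "-"), nrow(slots), replace = TRUE)
    piece_oriented <- ifelse(gene_strand == "-",
                             vapply(piece_seq, revcomp, character(1),
                                    USE.NAMES = FALSE),
                             piece_seq)

    genic_total <- sum(nchar(piece_oriented))
    token_total <- 75L * config$n_trna_genic
    min_fill <- (nrow(slots) + 1L) * config$gene_gap_min
    arm_size <- config$arm_size %||%
      ceiling((genic_total + token_total + min_fill) /
                max(0.05, 1 - config$repeat_fraction - 0.02))
    if (genic_total + token_total + min_fill +
          config$repeat_fraction * arm_size > arm_size)
      stop("repeat_fraction plus genic fraction exceeds 1 for this arm size")

    # TE families and the captured tRNA-like token
    n_fam <- config$n_repeat_families
    fam_len <- round(stats::runif(n_fam, config$te_len_range[1],
                                  config$te_len_range[2]))
    families <- vapply(fam_len, random_dna, character(1))
    names(families) <- sprintf("TE%02d", seq_len(n_fam))
    n_lib <- round(config$library_fraction * n_fam)
    library_fams <- names(families)[seq_len(n_lib)]

    isotypes <- c("Lys", "Met", "Ser", "Ala", "Gly")
    token_table <- data.frame(isotype = isotypes,
                              sequence = vapply(rep(75L, length(isotypes)),
                                                random_dna, character(1)),
                              stringsAsFactors = FALSE)
    te_token <- token_table$sequence[token_table$isotype == "Lys"]

    budget <- round(config$repeat_fraction * arm_size)
    repeat_pieces <- make_repeat_copies(families, budget, config, te_token)
    # standalone genic tRNA tokens (mixed isotypes, Lys rare outside TEs)
    extra_pieces <- lapply(seq_len(config$n_trna_genic), function(i) {
      iso <- sample(isotypes[-1], 1)
      list(seq = token_table$sequence[token_table$isotype == iso],
           isotype = iso)
    })
    filler_total <- max(0L, arm_size - genic_total -
                          sum(vapply(repeat_pieces, function(p) nchar(p$seq),
                                     integer(1))) -
                          75L * length(extra_pieces))

    asm <- assemble_arm(piece_oriented, repeat_pieces, filler_total,
                        extra_pieces, config$gene_gap_min)
    arm_size <- nchar(asm$sequence)

    # deletion bins: equal arm intervals
    bb <- round(seq(0, arm_size, length.out = config$n_bins + 1L))
    bins <- data.frame(bin = sprintf("B%d", seq_len(config$n_bins)),
                       start = bb[-length(bb)], end = bb[-1])

    gmid <- (asm$gene_coord$start + asm$gene_coord$end) %/% 2L
    gene_tab <- data.frame(
      gene_id = slots$gene_id,
      source_gene = src_id,
      kind = slots$kind,
      class = genes$class[match(src_id, genes$gene_id)],
      start = asm$gene_coord$start,
      end = asm$gene_coord$end,
      strand = gene_strand,
      arm_order = seq_len(nrow(slots)),
      syntenic = slots$kind == "syntenic",
      bin = bins$bin[findInterval(gmid, bins$start)],
      stringsAsFactors = FALSE)

    truth <- list(arm_label = config$arm_label,
                  arm_size = arm_size,
                  genes = gene_tab,
                  repeats = asm$repeat_coord,
                  segments = rr$segments,
                  bins = bins,
                  trna_sites = asm$extra_coord,
                  token_table = token_table)
    list(sequence = asm$sequence, truth = truth,
         gene_seqs = wheat_seq,
         repeat_library = families[library_fams],
         families = families)
  })
}

# a filler-heavy second arm providing contaminant reads ("fragments from
# other chromosomes"); shares the TE families of the target arm
build_contaminant_arm <- function(config, references, families) {
  with_seed(sub_seed(config$seed, 5L), {
    genes <- references$genes
    idx <- which(genes$role == "contaminant")
    cseq <- vapply(genes$seq[idx],
                   function(s) mutate_seq(s, config$wheat_divergence),
                   character(1), USE.NAMES = FALSE)
    genic_total <- sum(nchar(cseq))
    # several arm-equivalents of sequence, so impurity coverage per
    # contaminant gene stays far below 1x
    base_size <- config$arm_size %||%
      ceiling(config$n_genes * config$mean_cds_len /
                max(0.05, 1 - config$repeat_fraction - 0.03))
    arm_size <- round(config$cont_size_factor * base_size)
    budget <- round(config$cont_repeat_fraction * arm_size)
    pieces <- make_repeat_copies(families, budget, config, token = "")
    filler_total <- max(0L, arm_size - genic_total -
                          sum(vapply(pieces, function(p) nchar(p$seq),
                                     integer(1))))
    asm <- assemble_arm(as.list(cseq), pieces, filler_total, list(),
                        config$gene_gap_min)
    list(sequence = asm$sequence,
         genes = data.frame(gene_id = genes$gene_id[idx],
                            start = asm$gene_coord$start,
                            end = asm$gene_coord$end,
                            stringsAsFactors = FALSE),
         repeats = asm$repeat_coord)
  })
}

#' Simulate shotgun survey reads
#'
#' Draws `N = round(coverage_fold * arm_size / mean_read_len)` reads with
#' truncated-normal lengths (minimum 50 bp) at uniform positions; replaces a
#' `1 - purity` fraction with reads from the contaminant source (of which
#' `organelle_fraction` of all reads come from a simulated organellar
#' genome) and re-emits an `artifact_rate` fraction as byte-identical
#' duplicates of another read.  Every read is labelled in the truth table.
#'
#' @param arm output of [simulate_wheat_arm()]
#' @param contaminant_source list with a `sequence` field (see
#'   [simulate_survey()]), or `NULL` when `purity = 1`
#' @param config the [sim_config()]
#' @param organelle_seq organellar genome sequence (generated when `NULL`
#'   and `organelle_fraction > 0`)
#' @return list with `reads` (data.frame `read_id, arm, sequence`),
#'   `read_truth` (source labels, coordinates, repeat overlap, gene overlap,
#'   artifact flags), `artifact_pairs`, and `organelle` (sequence)
#' @export
simulate_reads <- function(arm, contaminant_source, config,
                           organelle_seq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  S <- nchar(arm$sequence)
  if (S == 0) stop("empty arm sequence")
  with_seed(sub_seed(config$seed, 3L), {
    N <- round(config$coverage_fold * S / config$mean_read_len)
    lens <- pmax(50L, pmin(S, round(stats::rnorm(N, config$mean_read_len,
                                                 config$read_len_sd))))
    n_org <- round(config$organelle_fraction * N)
    n_cont <- round((1 - config$purity) * N) - n_org
    if ((n_cont > 0 || n_org > 0) && is.null(contaminant_source) &&
        is.null(organelle_seq) && n_cont > 0)
      stop("purity < 1 requires a contaminant source")
    source <- rep("target", N)
    if (n_cont + n_org > 0) {
      imp <- sample.int(N, n_cont + n_org)
      source[imp[seq_len(n_cont)]] <- "contaminant"
      if (n_org > 0) source[imp[n_cont + seq_len(n_org)]] <- "organelle"
    }
    if (is.null(organelle_seq) && n_org > 0)
      organelle_seq <- random_dna(30000L)

    src_seq <- c(target = arm$sequence,
                 contaminant = contaminant_source$sequence %||% "",
                 organelle = organelle_seq %||% "")
    src_len <- nchar(src_seq)
    lens <- pmin(lens, src_len[source])
    starts <- floor(stats::runif(N) * (src_len[source] - lens + 1))
    strand <- if (config$read_strands == "both")
      sample(c("+", "-"), N, replace = TRUE) else rep("+", N)
    seqs <- substring(src_seq[source], starts + 1, starts + lens)
    minus <- which(strand == "-")
    if (length(minus))
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))

    # MDA duplicate artifacts: re-emit existing reads byte-identically
    n_art <- round(config$artifact_rate * N)
    art_of <- rep(NA_integer_, N)
    if (n_art > 0) {
      dup_pos <- sample.int(N, n_art)          # reads overwritten as dups
      src_pool <- setdiff(seq_len(N), dup_pos)
      dup_src <- sample(src_pool, n_art, replace = TRUE)
      seqs[dup_pos] <- seqs[dup_src]
      starts[dup_pos] <- starts[dup_src]
      lens[dup_pos] <- lens[dup_src]
      strand[dup_pos] <- strand[dup_src]
      source[dup_pos] <- source[dup_src]
      art_of[dup_pos] <- dup_src
    }
    read_id <- sprintf("%s_r%06d", config$arm_label, seq_len(N))

    # truth annotation: repeat overlap and best gene overlap (target reads)
    rt <- data.frame(read_id = read_id, source = source, start = starts,
                     end = starts + lens, len = lens, strand = strand,
                     artifact_of = ifelse(is.na(art_of), NA_character_,
                                          read_id[art_of]),
                     stringsAsFactors = FALSE)
    rt$repeat_frac <- 0
    rt$gene_id <- NA_character_
    rt$gene_overlap <- 0L
    # contaminant reads carry the repeat content of their source arm
    cnt <- which(rt$source == "contaminant")
    if (length(cnt) && !is.null(contaminant_source$repeats) &&
        nrow(contaminant_source$repeats)) {
      cd_ir <- IRanges::IRanges(start = rt$start[cnt] + 1L, end = rt$end[cnt])
      crep <- IRanges::reduce(IRanges::IRanges(
        start = contaminant_source$repeats$start + 1L,
        end = contaminant_source$repeats$end))
      ovc <- IRanges::findOverlaps(cd_ir, crep)
      if (length(ovc)) {
        interc <- IRanges::pintersect(cd_ir[S4Vectors::queryHits(ovc)],
                                      crep[S4Vectors::subjectHits(ovc)])
        covc <- tapply(IRanges::width(interc), S4Vectors::queryHits(ovc),
                       sum)
        rt$repeat_frac[cnt[as.integer(names(covc))]] <-
          as.numeric(covc) / rt$len[cnt[as.integer(names(covc))]]
      }
    }
    tgt <- which(rt$source == "target")
    if (length(tgt)) {
      rd_ir <- IRanges::IRanges(start = rt$start[tgt] + 1L, end = rt$end[tgt])
      if (nrow(arm$truth$repeats)) {
        rep_ir <- IRanges::reduce(IRanges::IRanges(
          start = arm$truth$repeats$start + 1L, end = arm$truth$repeats$end))
        ov <- IRanges::findOverlaps(rd_ir, rep_ir)
        if (length(ov)) {
          inter <- IRanges::pintersect(rd_ir[S4Vectors::queryHits(ov)],
                                       rep_ir[S4Vectors::subjectHits(ov)])
          covered <- tapply(IRanges::width(inter),
                            S4Vectors::queryHits(ov), sum)
          rt$repeat_frac[tgt[as.integer(names(covered))]] <-
            as.numeric(covered) / rt$len[tgt[as.integer(names(covered))]]
        }
      }
      gtab <- arm$truth$genes
      g_ir <- IRanges::IRanges(start = gtab$start + 1L, end = gtab$end)
      ovg <- IRanges::findOverlaps(rd_ir, g_ir)
      if (length(ovg)) {
        w <- IRanges::width(IRanges::pintersect(
          rd_ir[S4Vectors::queryHits(ovg)], g_ir[S4Vectors::subjectHits(ovg)]))
        od <- order(S4Vectors::queryHits(ovg), -w)
        qh <- S4Vectors::queryHits(ovg)[od]
        first <- !duplicated(qh)
        rt$gene_id[tgt[qh[first]]] <-
          gtab$gene_id[S4Vectors::subjectHits(ovg)[od][first]]
        rt$gene_overlap[tgt[qh[first]]] <- w[od][first]
      }
    }
    pairs <- rt[!is.na(rt$artifact_of), c("artifact_of", "read_id")]
    names(pairs) <- c("kept_candidate", "duplicate")
    list(reads = data.frame(read_id = read_id, arm = config$arm_label,
                            sequence = seqs, stringsAsFactors = FALSE),
         read_truth = rt, artifact_pairs = pairs,
         organelle = organelle_seq)
  })
}

#' Simulate deletion-bin markers and transcripts
#'
#' Markers are subsequences of the wheat gene copies tagged with the
#' deletion bin containing the gene; transcripts cover each gene to its
#' planted coverage class (high: 65-95%, low: 30-52%, contiguous interval).
#'
#' @param arm output of [simulate_wheat_arm()]
#' @param config the [sim_config()]
#' @return list with `markers` (data.frame), `transcripts` (named character
#'   vector) and `transcript_truth` (gene, planted class, planted coverage)
#' @export
simulate_markers_and_transcripts <- function(arm, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 4L), {
    gt <- arm$truth$genes
    eligible <- which(gt$kind != "fragment")
    n_mark <- round(config$marker_fraction * length(eligible))
    mk_idx <- sort(sample(eligible, n_mark))
    bin_rank <- match(gt$bin, arm$truth$bins$bin)
    markers <- data.frame(
      marker_id = sprintf("MK%04d", seq_len(n_mark)),
      kind = sample(c("EST", "SSR"), n_mark, replace = TRUE,
                    prob = c(0.8, 0.2)),
      bin = gt$bin[mk_idx],
      map_position = ifelse(stats::runif(n_mark) < 0.6,
                            round(bin_rank[mk_idx] * 10 +
                                    stats::runif(n_mark, 0, 8), 1),
                            NA_real_),
      gene_id = gt$gene_id[mk_idx],       # truth column, dropped on export
      stringsAsFactors = FALSE)
    seqs <- arm$gene_seqs[gt$source_gene[mk_idx]]
    mlen <- pmin(nchar(seqs), round(stats::runif(n_mark, 120, 200)))
    moff <- floor(stats::runif(n_mark) * (nchar(seqs) - mlen + 1))
    markers$sequence <- substring(seqs, moff + 1, moff + mlen)

    # transcript coverage classes
    cls <- sample(c("high", "low", "none"), length(eligible), replace = TRUE,
                  prob = c(config$transcript_fraction_high,
                           config$transcript_fraction_low,
                           max(0, 1 - config$transcript_fraction_high -
                                 config$transcript_fraction_low)))
    frac <- ifelse(cls == "high", stats::runif(length(eligible), 0.65, 0.95),
                   ifelse(cls == "low",
                          stats::runif(length(eligible), 0.30, 0.52), 0))
    tx <- character(0)
    keep <- which(frac > 0)
    if (length(keep)) {
      gsrc <- gt$source_gene[eligible[keep]]
      gseq <- arm$gene_seqs[gsrc]
      tlen <- pmax(60L, round(frac[keep] * nchar(gseq)))
      toff <- floor(stats::runif(length(keep)) * (nchar(gseq) - tlen + 1))
      tx <- substring(gseq, toff + 1, toff + tlen)
      names(tx) <- sprintf("TX_%s", gt$gene_id[eligible[keep]])
    }
    list(markers = markers,
         transcripts = tx,
         transcript_truth = data.frame(
           gene_id = gt$gene_id[eligible],
           class = cls, coverage = frac, stringsAsFactors = FALSE))
  })
}

#' Run the full survey simulation
#'
#' Convenience orchestrator: reference genomes, wheat arm, contaminant arm,
#' reads, markers and transcripts, with one merged truth set.
#'
#' @param config a [sim_config()]
#' @return list of class `arm_simulation` with components `config`,
#'   `references`, `arm`, `reads` (data.frame), `read_truth`,
#'   `artifact_pairs`, `markers`, `transcripts`, `transcript_truth`,
#'   `repeat_library`, `organelle`, `truth`
#' @export
simulate_survey <- function(config) {
  refs <- simulate_reference_genomes(config)
  arm <- simulate_wheat_arm(config, refs)
  cont <- if (config$purity < 1)
    build_contaminant_arm(config, refs, arm$families) else NULL
  rd <- simulate_reads(arm, cont, config)
  mt <- simulate_markers_and_transcripts(arm, config)
  truth <- arm$truth
  truth$reads <- rd$read_truth
  truth$artifact_pairs <- rd$artifact_pairs
  truth$contaminant_read_ids <-
    rd$read_truth$read_id[rd$read_truth$source == "contaminant"]
  truth$organelle_read_ids <-
    rd$read_truth$read_id[rd$read_truth$source == "organelle"]
  truth$contaminant_genes <- cont$genes %||% data.frame()
  structure(list(config = config, references = refs, arm = arm,
                 reads = rd$reads, read_truth = rd$read_truth,
                 artifact_pairs = rd$artifact_pairs,
                 markers = mt$markers, transcripts = mt$transcripts,
                 transcript_truth = mt$transcript_truth,
                 repeat_library = arm$repeat_library,
                 organelle = rd$organelle, truth = truth),
            class = "arm_simulation")
}

#' @export
print.arm_simulation <- function(x, ...) {
  cat(sprintf(
    "arm_simulation '%s': %d bp arm, %d genes on arm, %d reads, %d markers\n",
    x$config$arm_label, x$truth$arm_size, nrow(x$truth$genes),
    nrow(x$reads), nrow(x$markers)))
  invisible(x)
}

#' Write a simulation to disk in exchange formats
#'
#' Emits `reads.fasta`, `references/<G>.cds.fasta` and `.pos.tsv`,
#' `repeats.fasta`, `markers.tsv`, `transcripts.fasta`, `organelle.fasta`
#' and `truth.json` under `dir`.
#'
#' @param sim an `arm_simulation`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "references"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(stats::setNames(sim$reads$sequence, sim$reads$read_id),
              file.path(dir, "reads.fasta"))
  for (g in names(sim$references$genomes)) {
    gg <- sim$references$genomes[[g]]
    write_fasta(gg$cds, file.path(dir, "references",
                                  paste0(g, ".cds.fasta")))
    pos <- gg$pos
    pos$start <- pos$start + 1L   # external tables are 1-based inclusive
    utils::write.table(pos[, c("gene_id", "chrom", "start", "end", "strand")],
                       file.path(dir, "references", paste0(g, ".pos.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_fasta(sim$repeat_library, file.path(dir, "repeats.fasta"))
  write_markers(sim$markers[, c("marker_id", "kind", "bin", "map_position",
                                "sequence")],
                file.path(dir, "markers.tsv"))
  if (length(sim$transcripts))
    write_fasta(sim$transcripts, file.path(dir, "transcripts.fasta"))
  if (!is.null(sim$organelle))
    write_fasta(c(organelle = sim$organelle),
                file.path(dir, "organelle.fasta"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Scan reads for planted tRNA-like tokens
#'
#' A synthetic stand-in for an external tRNA prediction step, used to
#' exercise the density comparison: finds exact occurrences of the planted
#' isotype tokens (either strand) in a read set and returns a prediction
#' table consumable by [trna_density()].
#'
#' @param reads data.frame with `read_id` and `sequence`
#' @param token_table data.frame `isotype, sequence` (from the truth set)
#' @return data.frame `read_id, isotype, anticodon, score`
#' @export
scan_trna_tokens <- function(reads, token_table) {
  out <- list()
  subj <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                   reads$read_id))
  for (i in seq_len(nrow(token_table))) {
    for (pat in c(token_table$sequence[i],
                  revcomp(token_table$sequence[i]))) {
      n <- Biostrings::vcountPattern(pat, subj)
      hit <- which(n > 0)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          read_id = rep(reads$read_id[hit], n[hit]),
          isotype = token_table$isotype[i],
          anticodon = "NNN", score = 60, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(0), isotype = character(0),
                      anticodon = character(0), score = numeric(0)))
  do.call(rbind, out)
}
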