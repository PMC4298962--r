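# Repeat identification by (a) greedy exact-overlap assembly depth and
# (b) similarity masking against a repeat library.
#
# Low-coverage 454-style surveys cannot assemble kilobase-scale LTR
# retrotransposons, but reads from near-identical element copies collapse
# into contigs of high read depth; contigs at depth >= 5 flag their member
# reads as repetitive.  Library masking catches the known families
# independently of copy number.

as_read_frame <- function(reads) {
  if (methods::is(reads, "XStringSet"))
    reads <- data.frame(read_id = names(reads),
                        sequence = as.character(reads),
                        stringsAsFactors = FALSE)
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id)) stop("duplicate read ids")
  reads
}

#' Greedy exact suffix/prefix overlap assembly
#'
#' Lays reads out into contigs by exact suffix-to-prefix overlaps of at
#' least `min_overlap` nt (reads wholly contained in another read are
#' absorbed into its contig).  Merging is greedy: longest overlap first,
#' ties broken by lexicographic read id, so the layout is deterministic.
#' Reads on opposite strands are not co-assembled (orientation-naive
#' layout; both strands of a template simply yield two contigs).
#'
#' @param reads data.frame (`read_id`, `sequence`), named character vector
#'   or `DNAStringSet`
#' @param min_overlap minimum exact overlap (nt)
#' @param min_contig minimum reported contig length (nt)
#' @param max_candidates overlap candidates examined per read prefix
#'   (longest first); bounds worst-case work in collapsed repeat stacks
#' @return list of class `overlap_assembly`: `contigs` (data.frame
#'   `contig_id, length, depth, n_reads`), `members` (`contig_id, read_id,
#'   aligned_len`), `sequences` (named character), `singletons` (read ids),
#'   `n_reads` (input read count)
#' @export
overlap_assemble <- function(reads, min_overlap = 40L, min_contig = 40L,
                             max_candidates = 8L) {
  reads <- as_read_frame(reads)
  if (nrow(reads) == 0) stop("reads must be non-empty")
  ids <- reads$read_id
  seqs <- reads$sequence
  lens <- nchar(seqs)
  n <- length(ids)
  usable <- which(lens >= min_overlap)
  edges <- NULL
  contained_by <- rep(NA_integer_, n)
  if (length(usable) >= 2) {
    prefixes <- substr(seqs[usable], 1L, min_overlap)
    m <- seed_match(prefixes, seqs, min_overlap)
    if (nrow(m)) {
      m$pat <- usable[m$pat]
      m <- m[!(m$pat == m$subj & m$pos == 1L), , drop = FALSE]
    }
    if (nrow(m)) {
      avail <- lens[m$subj] - m$pos + 1L
      contain <- lens[m$pat] <= avail
      # cap overlap candidates per pattern read: longest available first
      ord <- order(m$pat, -avail, ids[m$subj])
      m <- m[ord, , drop = FALSE]; avail <- avail[ord]
      contain <- contain[ord]
      rank <- stats::ave(seq_len(nrow(m)), m$pat, FUN = seq_along)
      keep <- rank <= max_candidates
      m <- m[keep, , drop = FALSE]; avail <- avail[keep]
      contain <- contain[keep]
      # verify candidate overlaps / containments by exact string equality
      cmp_len <- pmin(avail, lens[m$pat])
      ok <- substr(seqs[m$subj], m$pos, m$pos + cmp_len - 1L) ==
        substr(seqs[m$pat], 1L, cmp_len)
      m <- m[ok, , drop = FALSE]; avail <- avail[ok]; contain <- contain[ok]
      if (nrow(m)) {
        # containment: strictly shorter, or equal length with smaller id
        cont_ok <- contain &
          (lens[m$pat] < lens[m$subj] |
             (lens[m$pat] == lens[m$subj] & ids[m$subj] < ids[m$pat]))
        cm <- m[cont_ok, , drop = FALSE]
        if (nrow(cm)) {
          # deterministic container choice: longest, then smallest id
          od <- order(cm$pat, -lens[cm$subj], ids[cm$subj])
          cm <- cm[od, , drop = FALSE]
          first <- !duplicated(cm$pat)
          contained_by[cm$pat[first]] <- cm$subj[first]
        }
        em <- m[!contain, , drop = FALSE]
        if (nrow(em))
          edges <- data.frame(from = em$subj, to = em$pat,
                              ov = avail[!contain])
      }
    }
  }
  contained <- which(!is.na(contained_by))
  # greedy chaining (longest overlap first, then lexicographic ids)
  nxt <- rep(NA_integer_, n); has_in <- rep(FALSE, n)
  ov_next <- rep(NA_integer_, n)              # overlap used by edge i -> nxt[i]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[!(edges$from %in% contained | edges$to %in% contained), ,
                   drop = FALSE]
    edges <- edges[order(-edges$ov, ids[edges$from], ids[edges$to]), ,
                   drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      fr <- edges$from[e]; to <- edges$to[e]
      if (!is.na(nxt[fr]) || has_in[to]) next
      rf <- find(fr); rt <- find(to)
      if (rf == rt) next                      # would close a cycle
      nxt[fr] <- to; has_in[to] <- TRUE
      ov_next[fr] <- edges$ov[e]
      parent[rf] <- rt
    }
  }

  # resolve containment chains to their final (non-contained) container
  resolve <- contained_by
  for (i in contained) {
    j <- resolve[i]; hops <- 0L
    while (!is.na(contained_by[j]) && hops < n) {
      j <- contained_by[j]; hops <- hops + 1L
    }
    resolve[i] <- j
  }

  # walk chains
  starts <- setdiff(which(!has_in), contained)
  contig_of <- rep(NA_integer_, n)
  contig_seq <- character(0); contig_members <- list()
  cid <- 0L
  for (s in starts) {
    chain <- s; i <- s
    while (!is.na(nxt[i])) { i <- nxt[i]; chain <- c(chain, i) }
    members <- c(chain, which(!is.na(resolve) & resolve %in% chain))
    if (length(members) < 2) next             # singleton
    cid <- cid + 1L
    sq <- seqs[chain[1]]
    if (length(chain) > 1)
      for (k in 2:length(chain)) {
        ov <- ov_next[chain[k - 1]]
        sq <- paste0(sq, substr(seqs[chain[k]], ov + 1L, lens[chain[k]]))
      }
    contig_seq[cid] <- sq
    contig_members[[cid]] <- members
    contig_of[members] <- cid
  }
  if (cid > 0) {
    clen <- nchar(contig_seq)
    keep <- which(clen >= min_contig)
    contigs <- data.frame(
      contig_id = sprintf("ctg%05d", seq_along(keep)),
      length = clen[keep],
      n_reads = vapply(contig_members[keep], length, integer(1)))
    members <- do.call(rbind, lapply(seq_along(keep), function(k) {
      mi <- contig_members[[keep[k]]]
      data.frame(contig_id = sprintf("ctg%05d", k), read_id = ids[mi],
                 aligned_len = lens[mi], stringsAsFactors = FALSE)
    }))
    agg <- tapply(members$aligned_len, members$contig_id, sum)
    contigs$depth <- as.numeric(agg[contigs$contig_id]) / contigs$length
    names(contig_seq) <- NULL
    sequences <- stats::setNames(contig_seq[keep], contigs$contig_id)
  } else {
    contigs <- data.frame(contig_id = character(0), length = integer(0),
                          n_reads = integer(0), depth = numeric(0))
    members <- data.frame(contig_id = character(0), read_id = character(0),
                          aligned_len = integer(0))
    sequences <- character(0)
  }
  singletons <- setdiff(ids, members$read_id)
  structure(list(contigs = contigs, members = members,
                 sequences = sequences, singletons = singletons,
                 n_reads = n,
                 read_lengths = stats::setNames(lens, ids)),
            class = "overlap_assembly")
}

#' Flag reads in deep assembly contigs as repetitive
#'
#' Member reads of contigs whose depth (total aligned member bases divided
#' by contig length) reaches `depth_threshold` are repeat-derived: at
#' survey coverage well below the threshold, only collapsed copies of
#' near-identical repeats can stack that deep.
#'
#' @param assembly an [overlap_assemble()] result
#' @param depth_threshold minimum contig depth (> 0)
#' @return list: `read_ids` (flagged reads), `n_deep_reads`,
#'   `pct_deep_reads` (of all assembled+singleton reads, 2 dp),
#'   `deep_contigs` (ids)
#' @export
flag_deep_contig_reads <- function(assembly, depth_threshold = 5) {
  stopifnot(inherits(assembly, "overlap_assembly"))
  if (depth_threshold <= 0) stop("depth_threshold must be > 0")
  deep <- assembly$contigs$contig_id[assembly$contigs$depth >= depth_threshold]
  rid <- unique(assembly$members$read_id[assembly$members$contig_id %in% deep])
  list(read_ids = rid,
       n_deep_reads = length(rid),
       pct_deep_reads = round(100 * length(rid) / assembly$n_reads, 2),
       deep_contigs = deep)
}

#' Mask reads against a repeat library
#'
#' k-mer seeded, ungapped masking: seeds from both strands of every library
#' consensus are located in the reads and extended along their diagonal;
#' the best run with at least `min_identity` percent identity and
#' `min_len` nt is masked.  Masking never alters read length; it only adds
#' half-open masked intervals.
#'
#' @param reads read set (see [overlap_assemble()] for accepted forms)
#' @param repeat_library named character vector / `DNAStringSet` of family
#'   consensus sequences
#' @param min_identity minimum percent identity of a masked interval
#' @param min_len minimum masked interval length (nt)
#' @param seed_k,seed_step seeding parameters along each consensus
#' @param max_diags diagonals extended per read/family/strand (insertions
#'   inside a copy split its match across adjacent diagonals)
#' @return list: `reads` (input data.frame plus list-column `masked` of
#'   merged intervals and `masked_bp`), `family_table` (per-family masked
#'   length and percent of total read length)
#' @export
library_mask <- function(reads, repeat_library, min_identity = 80,
                         min_len = 50L, seed_k = 24L, seed_step = 8L,
                         max_diags = 4L) {
  reads <- as_read_frame(reads)
  if (methods::is(repeat_library, "XStringSet"))
    repeat_library <- stats::setNames(as.character(repeat_library),
                                      names(repeat_library))
  if (length(repeat_library) == 0) stop("repeat library must be non-empty")
  lens <- nchar(reads$sequence)
  # seed table over both strands of every consensus
  pats <- list()
  cons <- list()
  for (f in names(repeat_library)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") repeat_library[[f]]
           else revcomp(repeat_library[[f]])
      key <- paste0(f, strand)
      cons[[key]] <- s
      pos <- seed_positions(nchar(s), seed_k, seed_step)
      if (!length(pos)) next
      pats[[key]] <- data.frame(key = key,
                                cpos = pos,
                                pat = substring(s, pos, pos + seed_k - 1L),
                                stringsAsFactors = FALSE)
    }
  }
  pats <- do.call(rbind, pats)
  masked <- rep(list(data.frame(start = integer(0), end = integer(0))),
                nrow(reads))
  fam_bp <- stats::setNames(numeric(length(repeat_library)),
                            names(repeat_library))
  if (!is.null(pats) && nrow(pats)) {
    m <- seed_match(pats$pat, reads$sequence, seed_k)
    if (nrow(m)) {
      key <- pats$key[m$pat]
      diag <- m$pos - pats$cpos[m$pat]
      gk <- paste(m$subj, key, diag)
      uniq <- !duplicated(gk)
      supp <- table(gk)
      cand <- data.frame(read = m$subj[uniq], key = key[uniq],
                         diag = diag[uniq],
                         supp = as.integer(supp[gk[uniq]]),
                         stringsAsFactors = FALSE)
      grp <- paste(cand$read, cand$key)
      cand <- cand[order(grp, -cand$supp, cand$diag), , drop = FALSE]
      rank <- stats::ave(seq_len(nrow(cand)), paste(cand$read, cand$key),
                         FUN = seq_along)
      cand <- cand[rank <= max_diags, , drop = FALSE]
      # mismatch penalty making score > 0 iff identity > min_identity
      pen <- min_identity / 100
      per_read <- split(seq_len(nrow(cand)), cand$read)
      for (ri_chr in names(per_read)) {
        ri <- as.integer(ri_chr)
        ivs <- list()
        for (r in per_read[[ri_chr]]) {
          cs <- cons[[cand$key[r]]]
          d <- cand$diag[r]
          lo <- max(1L, 1L + d); hi <- min(lens[ri], nchar(cs) + d)
          if (hi - lo + 1L < min_len) next
          rsub <- substr(reads$sequence[ri], lo, hi)
          csub <- substr(cs, lo - d, hi - d)
          mt <- charToRaw(rsub) == charToRaw(csub)
          run <- best_run(ifelse(mt, 1 - pen, -pen))
          if (is.null(run)) next
          alen <- run[2] - run[1] + 1L
          if (alen < min_len) next
          if (100 * sum(mt[run[1]:run[2]]) / alen < min_identity) next
          fam <- sub("[+-]$", "", cand$key[r])
          fam_bp[fam] <- fam_bp[fam] + alen
          ivs[[length(ivs) + 1L]] <-
            data.frame(start = lo + run[1] - 2L, end = lo + run[2] - 1L)
        }
        if (length(ivs))
          masked[[ri]] <- merge_intervals(do.call(rbind, ivs))
      }
    }
  }
  reads$masked <- masked
  reads$masked_bp <- vapply(masked, function(iv)
    if (nrow(iv)) sum(iv$end - iv$start) else 0L, numeric(1))
  total_len <- sum(lens)
  family_table <- data.frame(family = names(fam_bp),
                             masked_bp = as.numeric(fam_bp),
                             pct_of_read_length =
                               round(100 * as.numeric(fam_bp) / total_len, 2),
                             stringsAsFactors = FALSE)
  family_table <- family_table[order(-family_table$masked_bp), ]
  rownames(family_table) <- NULL
  list(reads = reads, family_table = family_table)
}

#' Remove repetitive reads and summarize the filtering stage
#'
#' Deep-contig reads and majority-masked reads (masked fraction above
#' `max_masked_fraction`) are removed; surviving reads keep their masked
#' intervals hard-masked to `N` in `sequence_masked` so downstream
#' similarity searches skip them (interval exclusion rather than whole-read
#' removal).
#'
#' @param masked_reads `reads` element of a [library_mask()] result
#' @param flagged read ids from [flag_deep_contig_reads()]
#' @param assembly optional [overlap_assemble()] result; when given, a full
#'   [survey_report()] is attached
#' @param max_masked_fraction removal threshold on the masked fraction
#' @return list: `reads` (retained, with `sequence_masked`), `removed`
#'   (ids), `filter_counts`, and `report` (when `assembly` supplied)
#' @export
nonrepetitive_summary <- function(masked_reads, flagged, assembly = NULL,
                                  max_masked_fraction = 0.5) {
  stopifnot(is.data.frame(masked_reads), "masked" %in% names(masked_reads))
  lens <- nchar(masked_reads$sequence)
  mfrac <- masked_reads$masked_bp / lens
  deep <- masked_reads$read_id %in% flagged
  drop <- deep | mfrac > max_masked_fraction
  kept <- masked_reads[!drop, , drop = FALSE]
  # hard-mask retained intervals
  seqm <- kept$sequence
  for (i in which(vapply(kept$masked, nrow, integer(1)) > 0)) {
    iv <- kept$masked[[i]]
    for (r in seq_len(nrow(iv)))
      substr(seqm[i], iv$start[r] + 1L, iv$end[r]) <-
        strrep("N", iv$end[r] - iv$start[r])
  }
  kept$sequence_masked <- seqm
  counts <- list(
    total_reads = nrow(masked_reads),
    total_bases = sum(lens),
    removed_deep = sum(deep),
    removed_masked = sum(!deep & drop),
    retained_reads = nrow(kept),
    retained_bases = sum(nchar(kept$sequence)) - sum(kept$masked_bp),
    masked_bp_total = sum(masked_reads$masked_bp),
    repeat_flagged_reads = sum(drop),
    repeat_flagged_fraction = mean(drop))
  report <- NULL
  if (!is.null(assembly)) {
    aligned <- assembly$members$read_id
    aligned_bases <- sum(assembly$read_lengths[unique(aligned)])
    non_aligned <- sum(assembly$read_lengths[assembly$singletons])
    report <- survey_report(
      total_reads = assembly$n_reads,
      total_bases = sum(assembly$read_lengths),
      aligned_reads = length(unique(aligned)),
      aligned_bases = aligned_bases,
      singleton_reads = length(assembly$singletons),
      n_contigs = sum(assembly$contigs$length > 100),
      bases_in_contigs = sum(assembly$contigs$length),
      non_aligned_bases = non_aligned,
      deep_reads = sum(deep))
  }
  list(reads = kept, removed = masked_reads$read_id[drop],
       filter_counts = counts, report = report)
}
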