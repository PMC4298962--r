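# Internal pairwise local-alignment search (desk-scale stand-in for external
# BLAST-style tools).  Two routes share one interface:
#   * exact Smith-Waterman (Biostrings::pairwiseAlignment) below a size
#     cutoff, and
#   * k-mer seeded, ungapped X-drop-free extension (best-scoring run on the
#     seed diagonal) above it.
# The generator plants substitutions only, so the ungapped route loses no
# alignments on simulated data; real indel-containing inputs should come in
# as external tabular hits instead.
#
# E-values follow a Karlin-Altschul form E = K m n exp(-lambda S) with fixed
# parameters per mode (nucleotide: +1/-2 scoring, lambda = 1.33, K = 0.621;
# protein: BLOSUM62, lambda = 0.267, K = 0.041), calibrated so that the
# filter cascade's published cutoffs are meaningful at toy scale.  External
# BLAST tables remain drop-in compatible via read_hits_tabular().

NT_MATCH <- 1
NT_MISMATCH <- -2
NT_LAMBDA <- 1.33
NT_K <- 0.621
AA_LAMBDA <- 0.267
AA_K <- 0.041

.blosum62 <- function() {
  # lazy data() load from Biostrings, cached in the package namespace env
  if (is.null(.align_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$B62 <- e$BLOSUM62
  }
  .align_cache$B62
}
.align_cache <- new.env(parent = emptyenv())

nt_evalue <- function(score, m, n) NT_K * m * n * exp(-NT_LAMBDA * score)
aa_evalue <- function(score, m, n) AA_K * m * n * exp(-AA_LAMBDA * score)
nt_bits <- function(score) (NT_LAMBDA * score - log(NT_K)) / log(2)
aa_bits <- function(score) (AA_LAMBDA * score - log(AA_K)) / log(2)

as_named_char <- function(x, what) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop(what, " must be a character vector or XStringSet")
  if (length(x) == 0) return(character(0))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(what, " must have unique names")
  toupper(x)
}

# best-scoring contiguous run of a numeric score vector (Kadane, vectorized);
# returns c(start, end, score) 1-based inclusive, or NULL if all <= 0
best_run <- function(scores) {
  cs <- cumsum(scores)
  pre <- cummin(c(0, cs[-length(cs)]))
  gains <- cs - pre
  e <- which.max(gains)
  if (gains[e] <= 0) return(NULL)
  b <- which.min(c(0, cs)[seq_len(e)])  # prefix min position before e
  c(b, e, gains[e])
}

# match patterns (equal-width, no N) against a set of subject strings using
# one matchPDict call on an N-separated concatenation.
# Returns data.frame(pat, subj, pos) with pos 1-based within the subject.
seed_match <- function(patterns, subjects, width) {
  stopifnot(length(patterns) > 0, length(subjects) > 0)
  sep <- strrep("N", width + 5L)
  lens <- nchar(subjects)
  # offset of each subject within the concatenation (0-based)
  offs <- cumsum(c(0L, utils::head(lens + nchar(sep), -1L)))
  big <- Biostrings::DNAString(paste(subjects, collapse = sep))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
  mi <- Biostrings::matchPDict(pd, big)
  counts <- S4Vectors::elementNROWS(mi)
  if (sum(counts) == 0)
    return(data.frame(pat = integer(0), subj = integer(0), pos = integer(0)))
  starts <- unlist(Biostrings::startIndex(mi), use.names = FALSE)
  pat <- rep(seq_along(patterns), counts)
  subj <- findInterval(starts, offs + 1L)
  pos <- starts - offs[subj]
  keep <- pos >= 1L & pos + width - 1L <= lens[subj]  # drop separator spans
  data.frame(pat = pat[keep], subj = subj[keep], pos = pos[keep])
}

# per-base nt scores for two equal-length strings; N never matches
nt_base_scores <- function(x, y) {
  xb <- charToRaw(x); yb <- charToRaw(y)
  match_ok <- xb == yb & xb != charToRaw("N")[1]
  ifelse(match_ok, NT_MATCH, NT_MISMATCH)
}

# ---------------------------------------------------------------------------

#' Local similarity search between two sequence sets
#'
#' Seed-and-extend local alignment emitting percent identity, percent
#' similarity (translated mode; BLOSUM62 positives), aligned length, an
#' e-value-like score, and 0-based half-open coordinates.  Below a
#' `sw_cutoff` problem size every query/subject pair is aligned with exact
#' Smith--Waterman on both strands; above it, alignments are found from
#' exact k-mer seeds extended ungapped along the diagonal.  Minus-strand
#' nucleotide hits report query coordinates on the forward query with
#' `strand = "-"`.
#'
#' @param queries named character vector or `DNAStringSet` (nucleotide reads)
#' @param subjects named character vector or `XStringSet`; nucleotide in
#'   `"nt"` mode, amino-acid (or CDS, translated in frame 1) in
#'   `"translated"` mode
#' @param mode `"nt"` for blastn-style, `"translated"` for blastx-style
#'   (all 6 reading frames of each query)
#' @param db_tag database label attached to the hits
#' @param method `"auto"` (default), `"seed"`, or `"sw"`; auto picks exact
#'   Smith--Waterman when `length(queries) * length(subjects) <= sw_cutoff`
#' @param seed_k seed length (nt mode: nucleotides; translated: residues)
#' @param seed_step spacing between seed start positions along each query
#' @param max_diags seed diagonals extended per query/subject/strand pair
#' @param min_aln_len minimum reported alignment length (nt or residues)
#' @param max_evalue hits above this e-value are dropped
#' @param sw_cutoff pair-count threshold for the exact route under
#'   `method = "auto"`
#' @return alignment-hit data.frame (see [read_hits_tabular()] for columns)
#' @export
internal_search <- function(queries, subjects, mode = c("nt", "translated"),
                            db_tag = "dataset_ext",
                            method = c("auto", "seed", "sw"),
                            seed_k = if (match.arg(mode) == "nt") 18L else 6L,
                            seed_step = if (match.arg(mode) == "nt") 24L else 8L,
                            max_diags = 4L, min_aln_len = 20L,
                            max_evalue = 10, sw_cutoff = 400L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  queries <- as_named_char(queries, "queries")
  if (length(queries) == 0) return(empty_hits())
  if (any(grepl("[^ACGTN]", queries)))
    stop("queries contain characters outside the DNA alphabet (ACGTN)")
  if (method == "auto")
    method <- if (length(queries) * length(subjects) <= sw_cutoff) "sw" else "seed"
  if (mode == "nt") {
    subjects <- as_named_char(subjects, "subjects")
    if (any(grepl("[^ACGTN]", subjects)))
      stop("subjects contain characters outside the DNA alphabet (ACGTN)")
    hits <- if (method == "sw") sw_search_nt(queries, subjects)
            else seed_search_nt(queries, subjects, seed_k, seed_step,
                                max_diags, min_aln_len)
  } else {
    if (methods::is(subjects, "DNAStringSet") ||
        (is.character(subjects) && all(grepl("^[ACGTN]+$", toupper(subjects))))) {
      subjects <- as_named_char(subjects, "subjects")
      subjects <- vapply(subjects, function(s) translate_frame(s, 0L), character(1))
    } else {
      subjects <- as_named_char(subjects, "subjects")
    }
    hits <- if (method == "sw") sw_search_tr(queries, subjects)
            else seed_search_tr(queries, subjects, seed_k, seed_step,
                                max_diags, min_aln_len)
  }
  if (nrow(hits) == 0) return(empty_hits())
  hits <- hits[hits$aln_len >= min_aln_len & hits$evalue <= max_evalue, ,
               drop = FALSE]
  hits$db_tag <- db_tag
  rownames(hits) <- NULL
  hits
}

# translate one frame (0-based offset) of a nucleotide string to protein
translate_frame <- function(seq, frame) {
  n <- nchar(seq)
  usable <- n - frame
  usable <- usable - usable %% 3L
  if (usable < 3L) return("")
  s <- substr(seq, frame + 1L, frame + usable)
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X")))
}

# --- exact Smith-Waterman routes -------------------------------------------

sw_search_nt <- function(queries, subjects) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = NT_MATCH, mismatch = NT_MISMATCH, baseOnly = FALSE)
  qset <- Biostrings::DNAStringSet(queries)
  rcset <- Biostrings::reverseComplement(qset)
  n_db <- sum(nchar(subjects))
  out <- list()
  for (j in seq_along(subjects)) {
    sseq <- Biostrings::DNAString(subjects[[j]])
    for (strand in c("+", "-")) {
      pset <- if (strand == "+") qset else rcset
      pa <- Biostrings::pairwiseAlignment(
        pset, sseq, type = "local", substitutionMatrix = submat,
        gapOpening = 4, gapExtension = 2)
      sc <- Biostrings::score(pa)
      keep <- which(sc > 0)
      if (!length(keep)) next
      alen <- Biostrings::nchar(pa)[keep]
      nmat <- Biostrings::nmatch(pa)[keep]
      prng <- Biostrings::pattern(pa)
      qs <- IRanges::start(prng)[keep]; qe <- IRanges::end(prng)[keep]
      srng <- Biostrings::subject(pa)
      ss <- IRanges::start(srng)[keep]; se <- IRanges::end(srng)[keep]
      qlen <- nchar(queries)[keep]
      if (strand == "-") {  # map back to forward-query coordinates
        tmp <- qlen - qe
        qe <- qlen - qs + 1L
        qs <- tmp + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(queries)[keep], subject_id = names(subjects)[j],
        pct_identity = 100 * nmat / alen, pct_similarity = NA_real_,
        aln_len = alen,
        evalue = nt_evalue(sc[keep], nchar(queries)[keep], n_db),
        bit_score = nt_bits(sc[keep]),
        q_start = qs - 1L, q_end = qe,
        s_start = ss - 1L, s_end = se,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

sw_search_tr <- function(queries, subjects) {
  b62 <- .blosum62()
  n_db <- sum(nchar(subjects))
  out <- list()
  for (i in seq_along(queries)) {
    qseq <- queries[[i]]
    qlen <- nchar(qseq)
    frames <- query_frames(qseq)
    for (f in seq_along(frames)) {
      aa <- frames[[f]]$aa
      if (nchar(aa) < 5) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(aa, length(subjects))),
        Biostrings::AAStringSet(subjects),
        type = "local", substitutionMatrix = b62,
        gapOpening = 10, gapExtension = 2)
      sc <- Biostrings::score(pa)
      keep <- which(sc > 0)
      if (!length(keep)) next
      pat_al <- as.character(Biostrings::alignedPattern(pa)[keep])
      sub_al <- as.character(Biostrings::alignedSubject(pa)[keep])
      stats <- aa_pair_stats(pat_al, sub_al, b62)
      prng <- Biostrings::pattern(pa)
      qs_aa <- IRanges::start(prng)[keep]; qe_aa <- IRanges::end(prng)[keep]
      srng <- Biostrings::subject(pa)
      ntc <- aa_to_nt_coords(qs_aa, qe_aa, frames[[f]]$offset,
                             frames[[f]]$strand, qlen)
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(queries)[i], subject_id = names(subjects)[keep],
        pct_identity = stats$identity, pct_similarity = stats$similarity,
        aln_len = stats$len,
        evalue = aa_evalue(sc[keep], nchar(aa), n_db),
        bit_score = aa_bits(sc[keep]),
        q_start = ntc$start, q_end = ntc$end,
        s_start = IRanges::start(srng)[keep] - 1L,
        s_end = IRanges::end(srng)[keep],
        strand = frames[[f]]$strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  # one HSP per (query, subject): keep the lowest e-value frame
  res <- res[order(res$query_id, res$subject_id, res$evalue,
                   -res$aln_len), , drop = FALSE]
  res[!duplicated(res[, c("query_id", "subject_id")]), , drop = FALSE]
}

# aligned-string statistics for protein alignments (may contain gaps from
# the SW route; gap columns count toward length, never toward positives)
aa_pair_stats <- function(pat_al, sub_al, b62) {
  n <- length(pat_al)
  identity <- similarity <- numeric(n)
  len <- integer(n)
  rn <- rownames(b62)
  for (i in seq_len(n)) {
    p <- strsplit(pat_al[i], "", fixed = TRUE)[[1]]
    s <- strsplit(sub_al[i], "", fixed = TRUE)[[1]]
    len[i] <- length(p)
    no_gap <- p != "-" & s != "-"
    pi <- match(p[no_gap], rn); si <- match(s[no_gap], rn)
    ok <- !is.na(pi) & !is.na(si)
    pos <- sum(b62[cbind(pi[ok], si[ok])] > 0)
    identity[i] <- 100 * sum(p[no_gap] == s[no_gap]) / len[i]
    similarity[i] <- 100 * pos / len[i]
  }
  list(identity = identity, similarity = similarity, len = len)
}

# the six reading frames of a nucleotide query
query_frames <- function(qseq) {
  rc <- revcomp(qseq)
  out <- list()
  for (f in 0:2) {
    out[[length(out) + 1L]] <- list(aa = translate_frame(qseq, f),
                                    offset = f, strand = "+")
    out[[length(out) + 1L]] <- list(aa = translate_frame(rc, f),
                                    offset = f, strand = "-")
  }
  out
}

# aa alignment range -> 0-based half-open nt range on the forward query
aa_to_nt_coords <- function(qs_aa, qe_aa, offset, strand, qlen) {
  start_nt <- offset + 3L * (qs_aa - 1L)    # 0-based on the oriented strand
  end_nt <- offset + 3L * qe_aa
  if (strand == "-") {
    tmp <- qlen - end_nt
    end_nt <- qlen - start_nt
    start_nt <- tmp
  }
  list(start = start_nt, end = end_nt)
}

# --- seeded routes ---------------------------------------------------------

# seed start positions along one sequence of length n
seed_positions <- function(n, k, step) {
  if (n < k) return(integer(0))
  unique(c(seq(1L, n - k + 1L, by = step), n - k + 1L))
}

seed_search_nt <- function(queries, subjects, seed_k, seed_step,
                           max_diags, min_aln_len) {
  qlens <- nchar(queries)
  n_db <- sum(nchar(subjects))
  # enumerate seeds on both strands of every query (vectorized)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(queries))))
  oriented <- character(2L * length(queries))
  oriented[2L * seq_along(queries) - 1L] <- unname(queries)
  oriented[2L * seq_along(queries)] <- rcs
  pos_list <- lapply(qlens, seed_positions, k = seed_k, step = seed_step)
  nseeds <- lengths(pos_list)
  qidx <- rep(seq_along(queries), nseeds)
  qpos <- unlist(pos_list, use.names = FALSE)
  if (!length(qpos)) return(empty_hits())
  seeds <- data.frame(
    q = c(qidx, qidx),
    strand = rep(1:2, each = length(qidx)),
    qpos = c(qpos, qpos),
    pat = c(substring(unname(queries)[qidx], qpos, qpos + seed_k - 1L),
            substring(rcs[qidx], qpos, qpos + seed_k - 1L)),
    stringsAsFactors = FALSE)
  seeds <- seeds[!grepl("N", seeds$pat, fixed = TRUE), , drop = FALSE]
  if (!nrow(seeds)) return(empty_hits())
  m <- seed_match(seeds$pat, subjects, seed_k)
  if (nrow(m) == 0) return(empty_hits())
  q <- seeds$q[m$pat]; strand <- seeds$strand[m$pat]
  diag <- m$pos - seeds$qpos[m$pat]
  key <- paste(q, strand, m$subj, diag)
  # seed support per diagonal; keep the top max_diags per (q, strand, subj)
  agg <- data.frame(q = q, strand = strand, subj = m$subj, diag = diag,
                    key = key, stringsAsFactors = FALSE)
  agg <- agg[!duplicated(agg$key), , drop = FALSE]
  support <- as.integer(table(key)[agg$key])
  grp <- paste(agg$q, agg$strand, agg$subj)
  ord <- order(grp, -support, agg$diag)
  agg <- agg[ord, , drop = FALSE]
  grp <- grp[ord]
  rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  agg <- agg[rank_in_grp <= max_diags, , drop = FALSE]

  slens <- nchar(subjects)
  out_rows <- vector("list", nrow(agg))
  for (r in seq_len(nrow(agg))) {
    qi <- agg$q[r]; st <- agg$strand[r]; sj <- agg$subj[r]; d <- agg$diag[r]
    qlen <- qlens[qi]; slen <- slens[sj]
    q_lo <- max(1L, 1L - d); q_hi <- min(qlen, slen - d)
    if (q_hi - q_lo + 1L < min_aln_len) next
    qsub <- substr(oriented[2L * qi - (st == 1L)], q_lo, q_hi)
    ssub <- substr(subjects[[sj]], q_lo + d, q_hi + d)
    scores <- nt_base_scores(qsub, ssub)
    run <- best_run(scores)
    if (is.null(run)) next
    alen <- run[2] - run[1] + 1L
    if (alen < min_aln_len) next
    nmat <- sum(scores[run[1]:run[2]] == NT_MATCH)
    # run coords on the oriented query, then map to forward coordinates
    oqs <- q_lo + run[1] - 1L; oqe <- q_lo + run[2] - 1L
    if (st == 1L) { fqs <- oqs; fqe <- oqe }
    else { fqs <- qlen - oqe + 1L; fqe <- qlen - oqs + 1L }
    out_rows[[r]] <- data.frame(
      query_id = names(queries)[qi], subject_id = names(subjects)[sj],
      pct_identity = 100 * nmat / alen, pct_similarity = NA_real_,
      aln_len = alen, evalue = nt_evalue(run[3], qlen, n_db),
      bit_score = nt_bits(run[3]),
      q_start = fqs - 1L, q_end = fqe,
      s_start = oqs + d - 1L, s_end = oqe + d,
      strand = c("+", "-")[st], stringsAsFactors = FALSE)
  }
  out_rows <- out_rows[!vapply(out_rows, is.null, logical(1))]
  if (!length(out_rows)) return(empty_hits())
  res <- do.call(rbind, out_rows)
  # collapse duplicate HSPs found from overlapping diagonals
  res[!duplicated(res[, c("query_id", "subject_id", "q_start", "q_end",
                          "s_start", "s_end")]), , drop = FALSE]
}

seed_search_tr <- function(queries, subjects, seed_k, seed_step,
                           max_diags, min_aln_len) {
  b62 <- .blosum62()
  rn <- rownames(b62)
  n_db <- sum(nchar(subjects))
  # subject residue-index vectors and a k-mer -> (subject, pos) index
  subj_idx <- lapply(subjects, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], rn))
  idx_tab <- list()
  for (j in seq_along(subjects)) {
    n <- nchar(subjects[[j]])
    if (n < seed_k) next
    pos <- seq_len(n - seed_k + 1L)
    idx_tab[[length(idx_tab) + 1L]] <- data.frame(
      key = substring(subjects[[j]], pos, pos + seed_k - 1L),
      subj = j, pos = pos, stringsAsFactors = FALSE)
  }
  if (!length(idx_tab)) return(empty_hits())
  idx <- do.call(rbind, idx_tab)
  idx <- idx[!grepl("X", idx$key, fixed = TRUE), , drop = FALSE]

  out_rows <- list()
  for (i in seq_along(queries)) {
    qseq <- queries[[i]]
    qlen <- nchar(qseq)
    for (fr in query_frames(qseq)) {
      aa <- fr$aa
      n <- nchar(aa)
      if (n < seed_k) next
      pos <- seed_positions(n, seed_k, seed_step)
      keys <- substring(aa, pos, pos + seed_k - 1L)
      hit <- which(keys %in% idx$key)
      if (!length(hit)) next
      mrows <- idx[idx$key %in% keys[hit], , drop = FALSE]
      mrows$qpos <- pos[hit][match(mrows$key, keys[hit])]
      mrows$diag <- mrows$pos - mrows$qpos
      dk <- paste(mrows$subj, mrows$diag)
      supp <- table(dk)
      uniq <- mrows[!duplicated(dk), , drop = FALSE]
      uniq$supp <- as.integer(supp[paste(uniq$subj, uniq$diag)])
      uniq <- uniq[order(uniq$subj, -uniq$supp, uniq$diag), , drop = FALSE]
      rk <- stats::ave(seq_len(nrow(uniq)), uniq$subj, FUN = seq_along)
      uniq <- uniq[rk <= max_diags, , drop = FALSE]
      q_res <- match(strsplit(aa, "", fixed = TRUE)[[1]], rn)
      for (r in seq_len(nrow(uniq))) {
        sj <- uniq$subj[r]; d <- uniq$diag[r]
        slen <- nchar(subjects[[sj]])
        q_lo <- max(1L, 1L - d); q_hi <- min(n, slen - d)
        if (q_hi - q_lo + 1L < min_aln_len) next
        qi_v <- q_res[q_lo:q_hi]; si_v <- subj_idx[[sj]][(q_lo + d):(q_hi + d)]
        ok <- !is.na(qi_v) & !is.na(si_v)
        scores <- rep(-4, length(qi_v))
        scores[ok] <- b62[cbind(qi_v[ok], si_v[ok])]
        run <- best_run(scores)
        if (is.null(run)) next
        alen <- run[2] - run[1] + 1L
        if (alen < min_aln_len) next
        seg <- run[1]:run[2]
        pos_cnt <- sum(scores[seg] > 0)
        id_cnt <- sum(qi_v[seg] == si_v[seg], na.rm = TRUE)
        ntc <- aa_to_nt_coords(q_lo + run[1] - 1L, q_lo + run[2] - 1L,
                               fr$offset, fr$strand, qlen)
        out_rows[[length(out_rows) + 1L]] <- data.frame(
          query_id = names(queries)[i], subject_id = names(subjects)[sj],
          pct_identity = 100 * id_cnt / alen,
          pct_similarity = 100 * pos_cnt / alen,
          aln_len = alen, evalue = aa_evalue(run[3], n, n_db),
          bit_score = aa_bits(run[3]),
          q_start = ntc$start, q_end = ntc$end,
          s_start = q_lo + d + run[1] - 2L, s_end = q_lo + d + run[2] - 1L,
          strand = fr$strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out_rows)) return(empty_hits())
  res <- do.call(rbind, out_rows)
  res <- res[order(res$query_id, res$subject_id, res$evalue,
                   -res$aln_len), , drop = FALSE]
  res[!duplicated(res[, c("query_id", "subject_id")]), , drop = FALSE]
}
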