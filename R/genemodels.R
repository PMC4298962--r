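# Reference-guided gene coding-sequence models.
#
# Non-repetitive reads are laid onto the CDS of the reference gene they
# were assigned to (one database per read, precedence genome A > B > C >
# UniGene > UniProt), stacked into contigs at >= 40 nt overlap, condensed
# into one model per reference with gaps filled by runs of 'n', and
# classified by transcript coverage (high >= 60%, low 20-60%, eliminated
# < 20%).

DB_PRECEDENCE <- c("genomeA", "genomeB", "genomeC", "unigene", "uniprot")

#' Map assigned reads onto their reference CDS
#'
#' Groups read alignments by reference subject, chains reads whose
#' reference intervals overlap by at least `min_overlap` nt into contigs,
#' and calls a majority-vote consensus per contig in reference coordinates
#' (ties go to the earliest-starting read).  Reads aligned on the minus
#' strand contribute their reverse complement.
#'
#' @param reads read set (data.frame with `read_id`, `sequence`)
#' @param assignments assignment table (query/subject coordinates and
#'   strand, from the homology cascade); one database per read is kept
#'   following `DB_PRECEDENCE`
#' @param min_overlap minimum reference-interval overlap to chain reads
#' @param min_contig minimum contig length (nt)
#' @return named list (by `db:subject`) of contig tables
#'   (`start, end, consensus, n_reads`, reference coordinates, 0-based
#'   half-open)
#' @export
map_reads_to_reference <- function(reads, assignments, min_overlap = 40L,
                                   min_contig = 40L) {
  reads <- as_read_frame(reads)
  a <- assignments
  a <- a[order(match(a$db_tag, DB_PRECEDENCE), a$evalue), , drop = FALSE]
  a <- a[!duplicated(a$query_id), , drop = FALSE]   # precedence per read
  seqs <- stats::setNames(reads$sequence, reads$read_id)
  a <- a[a$query_id %in% names(seqs), , drop = FALSE]
  out <- list()
  for (key in unique(paste(a$db_tag, a$subject_id, sep = ":"))) {
    h <- a[paste(a$db_tag, a$subject_id, sep = ":") == key, , drop = FALSE]
    seg <- character(nrow(h))
    ok <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      s <- substr(seqs[[h$query_id[i]]], h$q_start[i] + 1L, h$q_end[i])
      if (h$strand[i] == "-") s <- revcomp(s)
      ok[i] <- nchar(s) == h$s_end[i] - h$s_start[i]  # ungapped placements
      seg[i] <- s
    }
    h <- h[ok, , drop = FALSE]; seg <- seg[ok]
    if (!nrow(h)) next
    od <- order(h$s_start, h$s_end, h$query_id)
    h <- h[od, , drop = FALSE]; seg <- seg[od]
    # chain into contigs at >= min_overlap reference overlap
    contig_id <- cumsum(c(1L, as.integer(
      h$s_start[-1] > cummax(h$s_end[-nrow(h)]) - min_overlap)))
    ctg <- lapply(split(seq_len(nrow(h)), contig_id), function(idx) {
      cs <- min(h$s_start[idx]); ce <- max(h$s_end[idx])
      span <- ce - cs
      votes <- matrix(NA_character_, nrow = length(idx), ncol = span)
      for (k in seq_along(idx)) {
        i <- idx[k]
        cols <- (h$s_start[i] - cs + 1L):(h$s_end[i] - cs)
        votes[k, cols] <- strsplit(seg[i], "", fixed = TRUE)[[1]]
      }
      cons <- apply(votes, 2, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return("n")
        tab <- table(col)
        win <- names(tab)[tab == max(tab)]
        if (length(win) == 1) win else col[col %in% win][1]  # earliest read
      })
      data.frame(start = cs, end = ce,
                 consensus = paste(cons, collapse = ""),
                 n_reads = length(idx), stringsAsFactors = FALSE)
    })
    ctg <- do.call(rbind, ctg)
    ctg <- ctg[ctg$end - ctg$start >= min_contig, , drop = FALSE]
    if (nrow(ctg)) out[[key]] <- ctg
  }
  out
}

#' Condense contigs into a single gene model
#'
#' Contigs are ordered by reference coordinate; coordinate gaps are filled
#' with runs of `'n'` of the gap length (floor one `'n'`), and overlapping
#' contigs are merged (the overlap is trimmed from the later contig; if
#' the overlapping consensus disagrees below `min_overlap_identity`
#' percent the model is flagged ambiguous but still merged).
#'
#' @param contigs contig table from [map_reads_to_reference()] (one
#'   reference)
#' @param min_overlap_identity consensus agreement threshold in overlaps
#' @return list: `sequence`, `ambiguous`, `n_gap_bases`, `n_contigs`
#' @export
merge_contigs <- function(contigs, min_overlap_identity = 95) {
  stopifnot(nrow(contigs) >= 1)
  contigs <- contigs[order(contigs$start, contigs$end), , drop = FALSE]
  seqp <- contigs$consensus[1]
  cur_end <- contigs$end[1]
  ambiguous <- FALSE
  n_gap <- 0L
  if (nrow(contigs) > 1) {
    for (i in 2:nrow(contigs)) {
      gap <- contigs$start[i] - cur_end
      if (gap > 0) {
        seqp <- paste0(seqp, strrep("n", gap), contigs$consensus[i])
        n_gap <- n_gap + gap
      } else if (gap == 0) {
        seqp <- paste0(seqp, strrep("n", 1L), contigs$consensus[i])
        n_gap <- n_gap + 1L
      } else {
        ov <- -gap
        tail_prev <- substr(seqp, nchar(seqp) - ov + 1L, nchar(seqp))
        head_next <- substr(contigs$consensus[i], 1L, ov)
        idov <- 100 * mean(charToRaw(tail_prev) == charToRaw(head_next))
        if (idov < min_overlap_identity) ambiguous <- TRUE
        seqp <- paste0(seqp, substr(contigs$consensus[i], ov + 1L,
                                    nchar(contigs$consensus[i])))
      }
      cur_end <- max(cur_end, contigs$end[i])
    }
  }
  list(sequence = seqp, ambiguous = ambiguous, n_gap_bases = n_gap,
       n_contigs = nrow(contigs))
}

#' Build gene models for every assigned reference
#'
#' @param reads read set
#' @param assignments deduplicated assignment table
#' @param min_overlap,min_contig assembly parameters
#' @return data.frame of class `gene_models`: `model_id, reference_id,
#'   db_tag, source_class, sequence, n_contigs, n_gap_bases, ambiguous`
#' @export
build_gene_models <- function(reads, assignments, min_overlap = 40L,
                              min_contig = 40L) {
  ctgs <- map_reads_to_reference(reads, assignments, min_overlap,
                                 min_contig)
  if (!length(ctgs))
    return(data.frame(model_id = character(0), reference_id = character(0),
                      db_tag = character(0), source_class = character(0),
                      sequence = character(0), n_contigs = integer(0),
                      n_gap_bases = integer(0), ambiguous = logical(0)))
  rows <- lapply(names(ctgs), function(key) {
    db <- sub(":.*", "", key)
    refid <- sub("^[^:]*:", "", key)
    m <- merge_contigs(ctgs[[key]])
    data.frame(model_id = sprintf("MDL_%s_%s", sub("^genome", "", db),
                                  refid),
               reference_id = refid, db_tag = db,
               source_class = if (db %in% c("unigene", "uniprot"))
                 "non_conserved" else "conserved",
               sequence = m$sequence, n_contigs = m$n_contigs,
               n_gap_bases = m$n_gap_bases, ambiguous = m$ambiguous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Classify gene models by transcript coverage
#'
#' Transcripts are matched to the models at `min_identity` percent
#' identity; per model, coverage is the percentage of non-`n` bases
#' overlapped by at least one transcript hit.  Models partition into
#' high (>= 60%), low (20-60%) and eliminated (< 20%); the 60% boundary
#' belongs to the high class and 20% to the low class.
#'
#' @param models a [build_gene_models()] result
#' @param transcripts named character vector / `DNAStringSet` of
#'   transcript sequences (or a precomputed hit table via `hits`)
#' @param min_identity transcript match threshold
#' @param hits optional hit table (query = transcript, subject = model)
#' @param ... passed to [internal_search()]
#' @return `models` with added `transcript_coverage` (percent) and
#'   `confidence` columns
#' @export
classify_confidence <- function(models, transcripts = NULL,
                                min_identity = 95, hits = NULL, ...) {
  if (is.null(hits)) {
    if (is.null(transcripts) || length(transcripts) == 0) {
      hits <- empty_hits()
    } else {
      hits <- internal_search(transcripts,
                              stats::setNames(models$sequence,
                                              models$model_id),
                              mode = "nt", db_tag = "transcript", ...)
    }
  }
  hits <- hits[hits$pct_identity >= min_identity, , drop = FALSE]
  cov <- numeric(nrow(models))
  for (i in seq_len(nrow(models))) {
    sq <- models$sequence[i]
    non_n <- which(strsplit(sq, "", fixed = TRUE)[[1]] != "n")
    if (!length(non_n)) { cov[i] <- 0; next }
    h <- hits[hits$subject_id == models$model_id[i], , drop = FALSE]
    if (!nrow(h)) { cov[i] <- 0; next }
    iv <- merge_intervals(data.frame(start = h$s_start, end = h$s_end))
    covered <- logical(nchar(sq))
    for (r in seq_len(nrow(iv)))
      covered[(iv$start[r] + 1L):iv$end[r]] <- TRUE
    cov[i] <- 100 * sum(covered[non_n]) / length(non_n)
  }
  models$transcript_coverage <- cov
  models$confidence <- ifelse(cov >= 60, "high",
                              ifelse(cov >= 20, "low", "eliminated"))
  models
}

#' Best-reciprocal matching of two gene-model sets
#'
#' Reciprocal best nucleotide matches at `min_identity` percent identity
#' and `max_evalue`; equal-e-value ties break in favour of the subject
#' whose location label matches the query's (the homoeologous-location
#' rule), then lexicographically.  Matched identities are binned at 1%
#' resolution (`95` = 95.00-95.99) and a query-vs-subject location
#' concordance table is returned.
#'
#' @param models_q,models_s model tables (need `model_id`, `sequence`;
#'   optional `location`)
#' @param min_identity,max_evalue match thresholds
#' @param ... passed to [internal_search()]
#' @return list: `matches` (query, subject, identity, identity_bin,
#'   location_concordant), `identity_histogram`, `concordance`
#' @export
cross_dataset_match <- function(models_q, models_s, min_identity = 95,
                                max_evalue = 1e-20, ...) {
  qs <- stats::setNames(models_q$sequence, models_q$model_id)
  ss <- stats::setNames(models_s$sequence, models_s$model_id)
  loc_q <- if ("location" %in% names(models_q))
    stats::setNames(models_q$location, models_q$model_id) else NULL
  loc_s <- if ("location" %in% names(models_s))
    stats::setNames(models_s$location, models_s$model_id) else NULL
  filt <- function(h) h[h$pct_identity >= min_identity &
                          h$evalue <= max_evalue, , drop = FALSE]
  fwd <- filt(internal_search(qs, ss, mode = "nt", db_tag = "dataset_ext",
                              ...))
  rev <- filt(internal_search(ss, qs, mode = "nt", db_tag = "dataset_ext",
                              ...))
  best_with_tie <- function(h, loc_of_query, loc_of_subject) {
    if (!nrow(h)) return(h)
    conc <- if (!is.null(loc_of_query) && !is.null(loc_of_subject))
      as.integer(loc_of_subject[h$subject_id] == loc_of_query[h$query_id])
    else rep(0L, nrow(h))
    conc[is.na(conc)] <- 0L
    h <- h[order(h$query_id, h$evalue, -conc, h$subject_id), , drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  fb <- best_with_tie(fwd, loc_q, loc_s)
  rb <- best_with_tie(rev, loc_s, loc_q)
  rbest <- stats::setNames(rb$subject_id, rb$query_id)
  keep <- rbest[fb$subject_id] == fb$query_id
  keep[is.na(keep)] <- FALSE
  m <- fb[keep, , drop = FALSE]
  matches <- data.frame(query = m$query_id, subject = m$subject_id,
                        identity = m$pct_identity,
                        identity_bin = pmin(100, floor(m$pct_identity)),
                        stringsAsFactors = FALSE)
  if (!is.null(loc_q) && !is.null(loc_s))
    matches$location_concordant <-
      unname(loc_q[matches$query] == loc_s[matches$subject])
  hist <- table(factor(matches$identity_bin,
                       levels = seq(floor(min_identity), 100)))
  conc <- if (!is.null(loc_q) && !is.null(loc_s))
    table(query = loc_q[matches$query], subject = loc_s[matches$subject])
  else NULL
  list(matches = matches, identity_histogram = hist, concordance = conc)
}
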