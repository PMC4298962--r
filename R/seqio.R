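# Readers and writers for every format the pipeline touches.
#
# Internal coordinates are 0-based half-open; external tabular formats use
# the conventions native to each dialect (BLAST tabular and zipper TSV are
# 1-based inclusive, BED is 0-based half-open).  "NA" is the single
# missing-value token in all TSVs.

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] with defensive checks
#' that fail loudly (naming the offending line) on malformed input, and a
#' warning instead of an error for empty files.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]; empty set (with a warning) for an
#'   empty file
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  non_empty <- which(nzchar(trimws(lines)))
  if (length(non_empty) == 0) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  first <- non_empty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA at line ", first, ": expected '>' header")
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#'
#' @param records a [Biostrings::DNAStringSet] or named character vector
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("character records must be named")
    records <- Biostrings::DNAStringSet(records)
  }
  if (length(records) == 0) stop("no records to write")
  Biostrings::writeXStringSet(records, filepath = path, width = width)
  invisible(path)
}

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")

# canonical empty hit table (shared by readers and the internal aligner)
empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), pct_similarity = numeric(0),
             aln_len = integer(0), evalue = numeric(0),
             bit_score = numeric(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), db_tag = character(0))
}

#' Read a tabular alignment-hit file (BLAST outfmt-6 dialect)
#'
#' Accepts the standard 12 tab-separated columns, plus an optional 13th
#' "positives" column from which percent similarity is derived (protein
#' searches); without it `pct_similarity` is `NA` and filters requiring it
#' must recompute via the internal aligner.  Coordinates are normalized to
#' 0-based half-open on the plus strand; a subject range given in reverse
#' order marks a minus-strand hit (`strand = "-"`), not an error.
#'
#' @param path tab-separated hit file
#' @param db_tag database label attached to every hit (e.g. `"genomeA"`,
#'   `"unigene"`, `"organelle"`)
#' @return data.frame of alignment hits (possibly 0 rows)
#' @export
read_hits_tabular <- function(path, db_tag = "dataset_ext") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1)) == 0) return(empty_hits())
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", fill = FALSE)
  if (nrow(raw) == 0) return(empty_hits())
  if (ncol(raw) < 12)
    stop("expected >= 12 tab-separated columns, got ", ncol(raw))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & raw[[j]] != "NA")
    if (length(bad))
      stop("non-numeric value in column ", what, " at data row ", bad[1])
    v
  }
  pid <- num(3, "pct_identity"); alen <- num(4, "aln_len")
  qs <- num(7, "q_start"); qe <- num(8, "q_end")
  ss <- num(9, "s_start"); se <- num(10, "s_end")
  ev <- num(11, "evalue"); bs <- num(12, "bit_score")
  strand <- ifelse(ss <= se, "+", "-")
  s_lo <- pmin(ss, se); s_hi <- pmax(ss, se)
  sim <- rep(NA_real_, nrow(raw))
  if (ncol(raw) >= 13) {
    pos <- suppressWarnings(as.numeric(raw[[13]]))
    sim <- ifelse(is.na(pos), NA_real_, 100 * pos / alen)
  }
  data.frame(query_id = raw[[1]], subject_id = raw[[2]],
             pct_identity = pid, pct_similarity = sim,
             aln_len = as.integer(alen), evalue = ev, bit_score = bs,
             q_start = as.integer(qs) - 1L, q_end = as.integer(qe),
             s_start = as.integer(s_lo) - 1L, s_end = as.integer(s_hi),
             strand = strand, db_tag = db_tag,
             stringsAsFactors = FALSE)
}

#' Write alignment hits in the outfmt-6 dialect
#'
#' Inverse of [read_hits_tabular()]: coordinates go out 1-based inclusive,
#' minus-strand hits get reversed subject coordinates, and percent
#' similarity (when present) is emitted as a 13th "positives" column.
#'
#' @param hits hit data.frame as produced by the internal aligner or reader
#' @param path output file
#' @return `path`, invisibly
#' @export
write_hits_tabular <- function(hits, path) {
  ss <- ifelse(hits$strand == "-", hits$s_end, hits$s_start + 1L)
  se <- ifelse(hits$strand == "-", hits$s_start + 1L, hits$s_end)
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$pct_identity), hits$aln_len,
                    0L, 0L, hits$q_start + 1L, hits$q_end, ss, se,
                    format(hits$evalue, digits = 3, scientific = TRUE),
                    round(hits$bit_score, 1))
  if (!all(is.na(hits$pct_similarity)))
    out[[13]] <- as.integer(round(hits$pct_similarity * hits$aln_len / 100))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ZIPPER_COLUMNS <- c("index", "ref_gene", "ref_chrom", "ref_pos", "reads",
                    "bin", "map_position", "syntenic_flag")

#' Write a virtual gene order (zipper) table
#'
#' TSV with header columns `index, ref_gene, ref_chrom, ref_pos, reads, bin,
#' map_position, syntenic_flag`.  `reads` is a comma-joined read id list;
#' missing bins/map positions are written as `"NA"`.
#'
#' @param rows zipper data.frame (see [build_zipper()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_zipper <- function(rows, path) {
  if (is.unsorted(rows$index, strictly = TRUE))
    stop("zipper rows must be ordered by strictly increasing index")
  out <- data.frame(index = rows$index, ref_gene = rows$ref_gene,
                    ref_chrom = rows$ref_chrom, ref_pos = rows$ref_pos + 1L,
                    reads = vapply(rows$reads, function(r)
                      if (length(r)) paste(r, collapse = ",") else "NA",
                      character(1)),
                    bin = ifelse(is.na(rows$bin), "NA", rows$bin),
                    map_position = ifelse(is.na(rows$map_position), "NA",
                                          rows$map_position),
                    syntenic_flag = as.integer(rows$syntenic))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a zipper table written by [write_zipper()]
#' @param path TSV file
#' @return zipper data.frame with a list-column `reads`
#' @export
read_zipper <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!identical(names(tab), ZIPPER_COLUMNS))
    stop("unexpected zipper columns: ", paste(names(tab), collapse = ", "))
  out <- data.frame(index = tab$index, ref_gene = tab$ref_gene,
                    ref_chrom = tab$ref_chrom,
                    ref_pos = as.integer(tab$ref_pos) - 1L,
                    bin = as.character(tab$bin),
                    map_position = tab$map_position,
                    syntenic = tab$syntenic_flag == 1L,
                    stringsAsFactors = FALSE)
  out$reads <- lapply(tab$reads, function(r)
    if (is.na(r)) character(0) else strsplit(r, ",", fixed = TRUE)[[1]])
  out[, c("index", "ref_gene", "ref_chrom", "ref_pos", "reads", "bin",
          "map_position", "syntenic")]
}

#' Read/write plain BED3 interval files (0-based half-open)
#'
#' @param path BED file
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
  check_intervals(out, what = "BED")
  out
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); must be sorted within chromosome
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals, what = "BED")
  ord <- order(intervals$chrom, intervals$start)
  if (!identical(ord, seq_len(nrow(intervals))))
    stop("intervals must be sorted by (chrom, start) before writing BED")
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write/read a marker table
#'
#' TSV with columns `marker_id, kind, bin, map_position, sequence`.
#' @param markers marker data.frame
#' @param path TSV file
#' @export
write_markers <- function(markers, path) {
  out <- markers[, c("marker_id", "kind", "bin", "map_position", "sequence")]
  out$map_position <- ifelse(is.na(out$map_position), "NA", out$map_position)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Serialize / restore a simulation truth set as JSON
#' @param truth truth-set list from [simulate_survey()]
#' @param path JSON file
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
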