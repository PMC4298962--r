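# Closed-form survey statistics and the shared Fisher exact test utility.

#' Representation probability of a chromosome arm survey
#'
#' Probability that a given base of a flow-sorted chromosome arm is sampled
#' by at least one shotgun read, corrected for sorting purity:
#' \deqn{P = [1 - (1 - L/S)^N] \times \mathrm{purity}}
#' where `S` is the arm size in bp, `N` the number of reads and `L` the mean
#' read length in bp.  The power term is evaluated in log space
#' (`exp(N * log1p(-L/S))`) so that very small `L/S` with `N` in the millions
#' does not underflow.
#'
#' @param S arm size in bp (must exceed `L`)
#' @param N number of reads (>= 0)
#' @param L mean read length in bp (>= 1)
#' @param purity fraction of sorted DNA originating from the target arm,
#'   in \[0, 1\]
#' @return probability in \[0, purity\]
#' @examples
#' representation_probability(490e6, 2271366, 347.25, 0.855)  # ~0.684
#' @export
representation_probability <- function(S, N, L, purity = 1) {
  stopifnot(N >= 0, L >= 1, purity >= 0, purity <= 1)
  if (L >= S) stop("mean read length L must be smaller than arm size S")
  (1 - exp(N * log1p(-L / S))) * purity
}

#' Fold coverage of an arm by its survey reads
#'
#' @param total_read_len summed length of all reads, bp
#' @param S arm size, bp
#' @return `total_read_len / S` (dimensionless fold coverage)
#' @examples
#' coverage_fold(791e6, 490e6)  # 1.61
#' @export
coverage_fold <- function(total_read_len, S) {
  stopifnot(S > 0, total_read_len >= 0)
  total_read_len / S
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Computes the two-tailed p-value by summing hypergeometric point
#' probabilities no larger than that of the observed table (the same
#' definition used by `stats::fisher.test`, which serves as an independent
#' cross-check in the test suite).  Cells are
#' \preformatted{ a b
#'  c d }
#'
#' @param a,b,c,d non-negative integer cell counts
#' @return p-value in (0, 1]
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("degenerate margin; p = 1")
    return(1)
  }
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  # relative tolerance guards against ties lost to floating-point noise
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Arm-level survey statistics container
#'
#' Bundles the Table-1-style quantities for one chromosome arm and derives
#' coverage and representation probability from them.
#'
#' @param S arm size (bp); `N` read count; `L` mean read length (bp);
#'   `purity` sorting purity fraction
#' @param N,L,purity see above
#' @param total_read_len summed read length in bp; defaults to `N * L`
#' @return list of class `arm_survey_stats` with fields `S`, `N`, `L`,
#'   `purity`, `total_read_len`, `coverage_fold`, `representation_P`
#' @export
arm_survey_stats <- function(S, N, L, purity, total_read_len = N * L) {
  structure(list(
    S = S, N = N, L = L, purity = purity,
    total_read_len = total_read_len,
    coverage_fold = coverage_fold(total_read_len, S),
    representation_P = representation_probability(S, N, L, purity)
  ), class = "arm_survey_stats")
}

#' @export
print.arm_survey_stats <- function(x, ...) {
  cat(sprintf(
    "Arm survey: S=%.1f Mbp, N=%d reads, L=%.2f bp, purity=%.1f%%\n",
    x$S / 1e6, x$N, x$L, 100 * x$purity))
  cat(sprintf("  coverage %.2fx, representation probability %.3f\n",
              x$coverage_fold, x$representation_P))
  invisible(x)
}

#' tRNA gene density from an external prediction table
#'
#' Consumes a tabular tRNA prediction (e.g. tRNAscan-SE output reduced to
#' read id / isotype / anticodon / score) and reports per-isotype counts and
#' densities per surveyed megabase.  Prediction itself is delegated to
#' external tools; this function only does the density arithmetic.
#'
#' @param prediction_table data.frame with at least columns `read_id` and
#'   `isotype`; unknown/empty isotype tokens are counted under `"Other"`
#' @param surveyed_mb surveyed sequence length in Mb (> 0)
#' @param isotypes optional character vector of recognized isotype names;
#'   defaults to the standard 20 amino-acid isotypes
#' @return data.frame with columns `isotype`, `count`, `genes_per_mb`,
#'   ordered by decreasing count, plus a `"Total"` row
#' @export
trna_density <- function(prediction_table, surveyed_mb,
                         isotypes = c("Ala","Arg","Asn","Asp","Cys","Gln",
                                      "Glu","Gly","His","Ile","Leu","Lys",
                                      "Met","Phe","Pro","Ser","Thr","Trp",
                                      "Tyr","Val")) {
  stopifnot(surveyed_mb > 0)
  if (nrow(prediction_table) == 0) {
    return(data.frame(isotype = "Total", count = 0L, genes_per_mb = 0))
  }
  iso <- as.character(prediction_table$isotype)
  iso[!(iso %in% isotypes)] <- "Other"
  tab <- table(iso)
  out <- data.frame(isotype = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$isotype), , drop = FALSE]
  out <- rbind(out, data.frame(isotype = "Total", count = sum(out$count)))
  out$genes_per_mb <- out$count / surveyed_mb
  rownames(out) <- NULL
  out
}

#' Side-by-side tRNA density comparison between two arms or read sets
#'
#' @param pred_a,pred_b prediction tables (see [trna_density()])
#' @param mb_a,mb_b surveyed Mb for each set
#' @param labels names for the two sets
#' @return merged data.frame with per-isotype densities for both sets
#' @export
trna_density_comparison <- function(pred_a, pred_b, mb_a, mb_b,
                                    labels = c("set_a", "set_b")) {
  da <- trna_density(pred_a, mb_a)
  db <- trna_density(pred_b, mb_b)
  out <- merge(da[, c("isotype", "count", "genes_per_mb")],
               db[, c("isotype", "count", "genes_per_mb")],
               by = "isotype", all = TRUE, suffixes = paste0("_", labels))
  for (j in 2:5) out[[j]][is.na(out[[j]])] <- 0
  out[order(out$isotype != "Total",
            -(out[[3]] + out[[5]])), , drop = FALSE]
}

#' Assembly/filtering survey report (Table-2 style)
#'
#' Derives the percentage and length summaries of the repeat-filtering stage
#' from raw counts.  The estimated arm length is the sum of contig consensus
#' bases and the bases of reads that did not align into any contig; it
#' estimates arm size free of the collapse of repeats into deep contigs.
#'
#' All percentages use the documented denominators: read percentages over
#' `total_reads`, base percentages over `total_bases`.
#'
#' @param total_reads,total_bases totals over all survey reads
#' @param aligned_reads,aligned_bases reads (and their bases) assembled into
#'   contigs
#' @param singleton_reads reads left unassembled
#' @param n_contigs number of contigs longer than 100 bases
#' @param bases_in_contigs total contig consensus length
#' @param non_aligned_bases total bases of non-aligned (singleton) reads
#' @param deep_reads reads in contigs at or above the repeat depth threshold
#' @return list of class `survey_report` with raw counts, percentages
#'   (2 dp), and `estimated_arm_length_mb` (1 dp)
#' @export
survey_report <- function(total_reads, total_bases,
                          aligned_reads, aligned_bases,
                          singleton_reads, n_contigs,
                          bases_in_contigs, non_aligned_bases,
                          deep_reads) {
  pct <- function(x, denom) if (denom > 0) round(100 * x / denom, 2) else 0
  structure(list(
    total_reads = total_reads,
    total_bases = total_bases,
    aligned_reads = aligned_reads,
    aligned_reads_pct = pct(aligned_reads, total_reads),
    aligned_bases = aligned_bases,
    aligned_bases_pct = pct(aligned_bases, total_bases),
    singleton_reads = singleton_reads,
    n_contigs = n_contigs,
    bases_in_contigs = bases_in_contigs,
    non_aligned_bases = non_aligned_bases,
    estimated_arm_length = bases_in_contigs + non_aligned_bases,
    estimated_arm_length_mb = round((bases_in_contigs + non_aligned_bases) / 1e6, 1),
    deep_reads = deep_reads,
    deep_reads_pct = pct(deep_reads, total_reads)
  ), class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Survey assembly/filter report\n")
  cat(sprintf("  reads: %d total, %d aligned (%.2f%%), %d singletons\n",
              x$total_reads, x$aligned_reads, x$aligned_reads_pct,
              x$singleton_reads))
  cat(sprintf("  bases: %d total, %d aligned (%.2f%%)\n",
              x$total_bases, x$aligned_bases, x$aligned_bases_pct))
  cat(sprintf("  contigs >100 b: %d (%d bases); non-aligned bases: %d\n",
              x$n_contigs, x$bases_in_contigs, x$non_aligned_bases))
  cat(sprintf("  estimated arm length: %.1f MB\n", x$estimated_arm_length_mb))
  cat(sprintf("  deep-contig reads: %d (%.2f%%)\n",
              x$deep_reads, x$deep_reads_pct))
  invisible(x)
}
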