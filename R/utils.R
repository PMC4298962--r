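# Internal helpers shared across modules.
#
# Coordinate convention: every interval held in memory is 0-based, half-open
# [start, end).  Conversion to 1-based inclusive happens only in external
# tabular formats (seqio).

DNA_BASES <- c("A", "C", "G", "T")

#' Run an expression with a private RNG stream
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so simulation functions are deterministic without
#' clobbering the session stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stage-specific RNG seed from a user seed, kept inside the
# 32-bit integer range R requires
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483629)
}

# uniform random DNA of length n (single string)
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# point-mutate a sequence string at the given per-base rate (substitutions
# only; indels are not modelled anywhere in the generator)
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Validate an interval table
#'
#' Intervals are data.frames with integer columns `start` and `end`,
#' 0-based half-open.  Errors loudly on violations (negative length,
#' out-of-bounds) so malformed coordinates never propagate silently.
#' @keywords internal
check_intervals <- function(iv, len = NULL, what = "interval") {
  if (is.null(iv) || nrow(iv) == 0) return(invisible(TRUE))
  if (any(iv$end < iv$start))
    stop(what, ": end < start (half-open intervals must have end >= start)")
  if (any(iv$start < 0))
    stop(what, ": negative start coordinate")
  if (!is.null(len) && any(iv$end > len))
    stop(what, ": end beyond sequence length ", len)
  invisible(TRUE)
}

# merge overlapping/adjacent half-open intervals; returns sorted data.frame
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# total length covered by (possibly overlapping) intervals
intervals_covered <- function(iv) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0) 0L else sum(m$end - m$start)
}

# split n items as evenly as possible into k groups, returns group index 1..k
even_groups <- function(n, k) {
  if (k < 1) stop("k must be >= 1")
  rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
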