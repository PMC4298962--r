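# Virtual gene order ("genome zipper") construction and rearrangement
# analysis.
#
# Deletion bins provide the macro-order along the arm; synteny with the
# ordering reference genome provides the micro-order inside each bin.
# Blocks are called from sliding-window gene density supported by two or
# more reference species; rearrangements are read off the permutation
# between reference order and zipper order.

#' Sliding-window conserved-gene density
#'
#' Counts genes per window of `window` bp advanced by `step` bp along one
#' chromosome; genes are assigned to windows by their midpoint position.
#'
#' @param positions gene midpoint positions (bp, 0-based) on one chromosome
#' @param chrom_len chromosome length; defaults to `max(positions) + 1`
#' @param window,step window and step size in bp (`step <= window`)
#' @return data.frame `start, end, count` (0-based half-open windows)
#' @export
window_density <- function(positions, chrom_len = NULL, window = 500000,
                           step = 50000) {
  if (step > window) stop("step must not exceed window")
  if (length(positions) == 0 && is.null(chrom_len))
    return(data.frame(start = numeric(0), end = numeric(0),
                      count = integer(0)))
  L <- chrom_len %||% (max(positions) + 1)
  n_win <- max(1L, ceiling((L - window) / step) + 1L)
  starts <- (seq_len(n_win) - 1L) * step
  pos <- sort(positions)
  count <- findInterval(starts + window - 0.5, pos) -
    findInterval(starts - 0.5, pos)
  data.frame(start = starts, end = starts + window, count = count)
}

#' Per-species density tracks on the ordering reference's coordinates
#'
#' For each reference species, the track counts catalogued ortholog groups
#' whose ordering-reference (genome A) position falls in the window and
#' whose conservation profile includes that species — so all tracks share
#' one coordinate grid and block support can be intersected across species.
#'
#' @param catalogue a [build_gene_catalogue()] result with positions
#'   annotated
#' @param ref_pos genome A position table (`gene_id, chrom, start, end`)
#'   giving chromosome lengths
#' @param window,step see [window_density()]
#' @return named list (species `A`, `B`, `C`) of lists (per chromosome) of
#'   density frames
#' @export
density_tracks <- function(catalogue, ref_pos, window = 500000,
                           step = 50000) {
  g <- catalogue$genes
  g <- g[g$db_tag == "genomeA" & !is.na(g$position), , drop = FALSE]
  chrom_len <- tapply(ref_pos$end, ref_pos$chrom, max)
  chroms <- sort(unique(g$chrom))
  out <- list()
  for (sp in c("A", "B", "C")) {
    gs <- g[grepl(sp, g$profile), , drop = FALSE]
    out[[sp]] <- lapply(stats::setNames(chroms, chroms), function(ch)
      window_density(gs$position[gs$chrom == ch],
                     chrom_len = chrom_len[[ch]], window = window,
                     step = step))
  }
  out
}

#' Call syntenic blocks from multi-species density tracks
#'
#' A window qualifies when its gene density reaches `min_genes_per_mb`
#' (scaled to the window size) in at least `min_species` species' tracks;
#' overlapping or adjacent qualifying windows merge into maximal blocks.
#'
#' @param tracks output of [density_tracks()] (or any named list of
#'   per-chromosome density frames on a shared grid)
#' @param min_genes_per_mb density threshold in genes per Mb
#' @param min_species minimum supporting species per window
#' @param max_gap qualifying windows separated by no more than this many
#'   bp of sub-threshold sequence still merge into one block (local
#'   sampling dips should not split a contiguous conserved region)
#' @return data.frame `ref_chrom, start, end, n_windows, max_count`
#'   (0-based half-open block coordinates); zero rows when nothing
#'   qualifies
#' @export
call_syntenic_blocks <- function(tracks, min_genes_per_mb = 50,
                                 min_species = 2, max_gap = 500000) {
  chroms <- unique(unlist(lapply(tracks, names)))
  blocks <- list()
  for (ch in chroms) {
    per_sp <- lapply(tracks, function(t) t[[ch]])
    per_sp <- per_sp[!vapply(per_sp, is.null, logical(1))]
    if (!length(per_sp)) next
    grid <- per_sp[[1]][, c("start", "end")]
    thr <- min_genes_per_mb * (grid$end[1] - grid$start[1]) / 1e6
    n_pass <- Reduce(`+`, lapply(per_sp, function(t)
      as.integer(t$count >= thr)))
    ok <- which(n_pass >= min_species)
    if (!length(ok)) next
    iv <- merge_intervals(data.frame(start = grid$start[ok],
                                     end = grid$end[ok]))
    if (nrow(iv) > 1 && max_gap > 0) {       # bridge sub-max_gap dips
      bridged <- merge_intervals(data.frame(
        start = iv$start, end = pmin(iv$end + max_gap, max(iv$end))))
      bridged$end[nrow(bridged)] <- max(iv$end)
      for (r in seq_len(nrow(bridged)))
        bridged$end[r] <- max(iv$end[iv$start >= bridged$start[r] &
                                       iv$start < bridged$end[r] + 1])
      iv <- bridged
    }
    counts <- per_sp[[1]]$count
    for (r in seq_len(nrow(iv))) {
      inside <- ok[grid$start[ok] >= iv$start[r] & grid$end[ok] <= iv$end[r]]
      blocks[[length(blocks) + 1L]] <- data.frame(
        ref_chrom = ch, start = iv$start[r], end = iv$end[r],
        n_windows = length(inside),
        max_count = if (length(inside)) max(counts[inside]) else 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(data.frame(ref_chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      max_count = integer(0)))
  out <- do.call(rbind, blocks)
  out <- out[order(out$ref_chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor deletion-bin markers to catalogued genes
#'
#' A marker anchors the gene whose supporting read its sequence matches at
#' `min_identity` percent identity over at least `min_len` nt (markers are
#' same-species sequences, so near-identity is required).  Per gene,
#' conflicting marker bins resolve by majority, ties to the bin earliest in
#' `bin_order`.
#'
#' @param markers marker data.frame (`marker_id, kind, bin, map_position,
#'   sequence`)
#' @param reads read set searched against (typically the retained
#'   non-repetitive reads)
#' @param assignments read-gene assignment table (genome A rows are used)
#' @param bin_order character vector of bins in arm order
#' @param min_identity,min_len match thresholds
#' @param ... passed to [internal_search()]
#' @return data.frame `gene_id, bin, map_position, n_markers`
#' @export
anchor_markers <- function(markers, reads, assignments, bin_order,
                           min_identity = 95, min_len = 30, ...) {
  reads <- as_read_frame(reads)
  if (!all(markers$bin %in% bin_order))
    stop("marker bin absent from bin_order: ",
         paste(setdiff(markers$bin, bin_order), collapse = ", "))
  aA <- assignments[assignments$db_tag == "genomeA", , drop = FALSE]
  reads <- reads[reads$read_id %in% aA$query_id, , drop = FALSE]
  if (nrow(reads) == 0 || nrow(markers) == 0)
    return(data.frame(gene_id = character(0), bin = character(0),
                      map_position = numeric(0), n_markers = integer(0)))
  hits <- internal_search(
    stats::setNames(markers$sequence, markers$marker_id),
    stats::setNames(reads$sequence, reads$read_id),
    mode = "nt", db_tag = "marker", ...)
  hits <- hits[hits$pct_identity >= min_identity & hits$aln_len >= min_len, ,
               drop = FALSE]
  hits <- best_per_query(hits)
  if (nrow(hits) == 0)
    return(data.frame(gene_id = character(0), bin = character(0),
                      map_position = numeric(0), n_markers = integer(0)))
  mk <- markers[match(hits$query_id, markers$marker_id), , drop = FALSE]
  mk$gene_id <- aA$subject_id[match(hits$subject_id, aA$query_id)]
  mk <- mk[!is.na(mk$gene_id), , drop = FALSE]
  # majority bin per gene; ties to the earliest bin in bin_order
  out <- lapply(split(mk, mk$gene_id), function(d) {
    tab <- table(d$bin)
    winners <- names(tab)[tab == max(tab)]
    bin <- winners[order(match(winners, bin_order))][1]
    mp <- d$map_position[order(d$marker_id)]
    data.frame(gene_id = d$gene_id[1], bin = bin,
               map_position = if (any(!is.na(mp))) mp[!is.na(mp)][1]
                              else NA_real_,
               n_markers = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Chain ordering units bin by bin, choosing the order and orientation of
# each bin's units to minimize the summed |reference-position jump| at
# unit junctions over the whole chain (exact subset DP per bin up to 8
# units, greedy nearest-entry beyond).  Orientation 1 = reference order,
# 2 = reversed; reversal carries a small fixed penalty so symmetric cases
# resolve to reference order.  Junction distances are informative only up
# to `max_junction` bp — larger jumps are genuine discontinuities
# (rearrangement breakpoints) and cost the same either way, so reference
# orientation prevails there.  Cross-chromosome junctions cost a large
# constant, grouping same-chromosome units together.
chain_units <- function(units, unit_rank, max_junction = 1e5) {
  n <- length(units)
  if (n == 0) return(list(path = integer(0), orients = integer(0)))
  u_min <- vapply(units, function(u) min(u$genes$position), numeric(1))
  u_max <- vapply(units, function(u) max(u$genes$position), numeric(1))
  u_chrom <- vapply(units, function(u) u$chrom, character(1))
  entry_of <- function(i, o) if (o == 1L) u_min[i] else u_max[i]
  exit_of <- function(i, o) if (o == 1L) u_max[i] else u_min[i]
  BIG <- 1e9
  jump <- function(pc, pp, i, o) {
    base <- if (is.na(pc)) 0
            else if (pc != u_chrom[i]) BIG
            else min(abs(entry_of(i, o) - pp), max_junction)
    base + (o == 2L) * 0.5
  }
  frontier <- list(list(path = integer(0), orients = integer(0), cost = 0,
                        chrom = NA_character_, pos = NA_real_))
  for (r in sort(unique(unit_rank))) {
    us <- which(unit_rank == r)
    us <- us[order(u_chrom[us], u_min[us])]
    k <- length(us)
    if (k <= 8L) {
      nst <- 2L^k
      dp <- vector("list", nst)
      for (f in frontier) for (j in seq_len(k)) for (o in 1:2) {
        c1 <- f$cost + jump(f$chrom, f$pos, us[j], o)
        sub <- bitwShiftL(1L, j - 1L)
        key <- (j - 1L) * 2L + o
        cur <- if (is.null(dp[[sub + 1L]])) NULL else dp[[sub + 1L]][key][[1]]
        if (is.null(cur) || c1 < cur$cost - 1e-9)
          dp[[sub + 1L]][[key]] <- list(cost = c1,
                                        path = c(f$path, us[j]),
                                        orients = c(f$orients, o))
      }
      for (sub in seq_len(nst - 1L)) {
        cells <- dp[[sub + 1L]]
        if (is.null(cells)) next
        for (key in seq_along(cells)) {
          cell <- cells[[key]]
          if (is.null(cell)) next
          j <- (key - 1L) %/% 2L + 1L; o <- (key - 1L) %% 2L + 1L
          pc <- u_chrom[us[j]]; pp <- exit_of(us[j], o)
          for (j2 in seq_len(k)) {
            if (bitwAnd(sub, bitwShiftL(1L, j2 - 1L)) != 0L) next
            for (o2 in 1:2) {
              c2 <- cell$cost + jump(pc, pp, us[j2], o2)
              sub2 <- bitwOr(sub, bitwShiftL(1L, j2 - 1L))
              key2 <- (j2 - 1L) * 2L + o2
              cur <- if (is.null(dp[[sub2 + 1L]])) NULL
                     else dp[[sub2 + 1L]][key2][[1]]
              if (is.null(cur) || c2 < cur$cost - 1e-9)
                dp[[sub2 + 1L]][[key2]] <- list(
                  cost = c2, path = c(cell$path, us[j2]),
                  orients = c(cell$orients, o2))
            }
          }
        }
      }
      full <- dp[[nst]]
      frontier <- list()
      for (key in seq_along(full)) {
        cell <- full[[key]]
        if (is.null(cell)) next
        j <- (key - 1L) %/% 2L + 1L; o <- (key - 1L) %% 2L + 1L
        frontier[[length(frontier) + 1L]] <-
          list(path = cell$path, orients = cell$orients, cost = cell$cost,
               chrom = u_chrom[us[j]], pos = exit_of(us[j], o))
      }
    } else {
      # too many units for exact DP: greedy nearest-entry continuation
      f <- frontier[[which.min(vapply(frontier, `[[`, numeric(1), "cost"))]]
      pend <- us
      while (length(pend)) {
        best_c <- Inf; best_j <- pend[1]; best_o <- 1L
        for (j in pend) for (o in 1:2) {
          cj <- jump(f$chrom, f$pos, j, o)
          if (cj < best_c - 1e-9) { best_c <- cj; best_j <- j; best_o <- o }
        }
        f$path <- c(f$path, best_j)
        f$orients <- c(f$orients, best_o)
        f$cost <- f$cost + best_c
        f$chrom <- u_chrom[best_j]
        f$pos <- exit_of(best_j, best_o)
        pend <- setdiff(pend, best_j)
      }
      frontier <- list(f)
    }
  }
  frontier[[which.min(vapply(frontier, `[[`, numeric(1), "cost"))]]
}

#' Build the virtual gene order
#'
#' Syntenic genes (catalogued genome A genes inside syntenic blocks) are
#' grouped into (block, bin) units: each block's genes are sorted by
#' reference position, bins are taken from marker anchors (unanchored genes
#' inherit the nearest anchored neighbour's bin within the block), and
#' maximal constant-bin runs become ordering units.  Units are ordered by
#' deletion-bin rank (ties by reference adjacency); within a unit genes
#' follow reference order, reversed when the local bin trend across the
#' unit's reference-adjacent neighbours descends (a block co-linear in
#' reverse).  Unanchored blocks keep reference order and sort after
#' anchored units of their chromosome.  Non-syntenic conserved genes with a
#' marker anchor are appended with bin-only placement.
#'
#' @param catalogue a [build_gene_catalogue()] result (positions annotated)
#' @param ref_pos genome A position table
#' @param gene_anchors output of [anchor_markers()]
#' @param bin_order bins in arm order
#' @param blocks syntenic blocks; computed from the catalogue when `NULL`
#' @param window,step,min_genes_per_mb,min_species block-calling parameters
#' @param max_junction reference-distance scale (bp) beyond which a unit
#'   junction counts as a plain discontinuity when ordering units (see
#'   Details in the package vignette)
#' @return data.frame of class `zipper_frame` (columns `index, ref_gene,
#'   ref_chrom, ref_pos, reads, bin, map_position, syntenic`), with the
#'   block table in `attr(, "blocks")`
#' @export
build_zipper <- function(catalogue, ref_pos, gene_anchors, bin_order,
                         blocks = NULL, window = 500000, step = 50000,
                         min_genes_per_mb = 50, min_species = 2,
                         max_junction = 1e5) {
  if (!all(gene_anchors$bin %in% bin_order))
    stop("anchor bin absent from bin_order")
  if (is.null(blocks)) {
    tracks <- density_tracks(catalogue, ref_pos, window, step)
    blocks <- call_syntenic_blocks(tracks, min_genes_per_mb, min_species)
  }
  g <- catalogue$genes
  g <- g[g$db_tag == "genomeA" & !is.na(g$position), , drop = FALSE]
  g$block <- NA_integer_
  for (b in seq_len(nrow(blocks))) {
    hit <- g$chrom == blocks$ref_chrom[b] & g$position >= blocks$start[b] &
      g$position < blocks$end[b]
    g$block[hit] <- b
  }
  anchor_bin <- stats::setNames(gene_anchors$bin, gene_anchors$gene_id)
  anchor_map <- stats::setNames(gene_anchors$map_position,
                                gene_anchors$gene_id)
  bin_rank <- stats::setNames(seq_along(bin_order), bin_order)

  units <- list()
  syn <- g[!is.na(g$block), , drop = FALSE]
  for (b in unique(syn$block)) {
    gb <- syn[syn$block == b, , drop = FALSE]
    gb <- gb[order(gb$position, gb$gene_id), , drop = FALSE]
    bins <- unname(anchor_bin[gb$gene_id])
    anchored <- which(!is.na(bins))
    if (length(anchored)) {
      # every gene takes the majority bin of its 3 nearest anchors
      # (ref-index distance; ties to the nearest anchor), which both fills
      # unanchored genes and outvotes isolated discordant anchors (e.g. a
      # marker drawn from a duplicated copy elsewhere on the arm)
      raw <- bins
      for (i in seq_len(nrow(gb))) {
        nk <- anchored[order(abs(anchored - i), anchored)]
        nk <- nk[seq_len(min(3L, length(nk)))]
        tab <- table(raw[nk])
        win <- names(tab)[tab == max(tab)]
        bins[i] <- if (length(win) == 1) win else raw[nk[1]]
      }
    }
    run_id <- cumsum(c(1L, as.integer(bins[-1] != bins[-length(bins)] |
                                        (is.na(bins[-1]) !=
                                           is.na(bins[-length(bins)])))))
    if (all(is.na(bins))) run_id <- rep(1L, nrow(gb))
    for (u in unique(run_id)) {
      rows <- gb[run_id == u, , drop = FALSE]
      units[[length(units) + 1L]] <- list(
        block = b, chrom = rows$chrom[1], bin = bins[run_id == u][1],
        ref_start = min(rows$position), genes = rows,
        unit_index = u)
    }
  }
  # bin-major order; inside each bin the units' order AND orientation are
  # chosen jointly to minimize the total reference-coordinate jump along
  # the whole chain (deletion bins give macro-order only; co-linear
  # continuity supplies the micro-order, including reversed blocks whose
  # bins descend with reference position)
  rank_of <- function(u) {
    if (is.na(u$bin)) length(bin_order) + 1L else bin_rank[[u$bin]]
  }
  unit_rank <- vapply(units, rank_of, numeric(1))
  chain <- chain_units(units, unit_rank, max_junction)
  rows <- list()
  for (t in seq_along(chain$path)) {
    u <- units[[chain$path[t]]]
    gg <- u$genes
    if (chain$orients[t] == 2L) gg <- gg[rev(seq_len(nrow(gg))), ,
                                         drop = FALSE]
    gg$bin_out <- u$bin
    rows[[length(rows) + 1L]] <- gg
  }
  zip_syn <- if (length(rows)) do.call(rbind, rows) else g[0, , drop = FALSE]
  if (nrow(zip_syn)) zip_syn$syntenic <- TRUE

  # non-syntenic conserved genes: bin-only placement when a marker anchors
  nonsyn <- g[is.na(g$block), , drop = FALSE]
  nonsyn <- nonsyn[nonsyn$gene_id %in% names(anchor_bin), , drop = FALSE]
  if (nrow(nonsyn)) {
    nonsyn$bin_out <- unname(anchor_bin[nonsyn$gene_id])
    nonsyn <- nonsyn[order(bin_rank[nonsyn$bin_out], nonsyn$chrom,
                           nonsyn$position), , drop = FALSE]
    nonsyn$syntenic <- FALSE
  }
  zc <- rbind(zip_syn, nonsyn)
  if (nrow(zc) == 0)
    return(structure(data.frame(index = integer(0), ref_gene = character(0),
                                ref_chrom = character(0),
                                ref_pos = integer(0), bin = character(0),
                                map_position = numeric(0),
                                syntenic = logical(0)),
                     blocks = blocks, class = c("zipper_frame",
                                                "data.frame")))
  out <- data.frame(index = seq_len(nrow(zc)), ref_gene = zc$gene_id,
                    ref_chrom = zc$chrom, ref_pos = zc$position,
                    bin = zc$bin_out,
                    map_position = unname(anchor_map[zc$gene_id]),
                    syntenic = zc$syntenic, stringsAsFactors = FALSE)
  out$reads <- zc$supporting_reads
  out <- out[, c("index", "ref_gene", "ref_chrom", "ref_pos", "reads",
                 "bin", "map_position", "syntenic")]
  structure(out, blocks = blocks, class = c("zipper_frame", "data.frame"))
}

#' Decompose zipper-vs-reference order into co-linear segments
#'
#' Within each reference chromosome the syntenic zipper genes define a
#' permutation of their reference ranks; the permutation is decomposed
#' greedily into maximal runs of consecutive ranks (ascending `+` or
#' descending `-`).  Runs of at least `min_segment` genes are reported as
#' segments, shorter runs as small-scale translocations.  Consecutive
#' segments whose reference ranges are contiguous but appear in reversed
#' order form a reversal event (an inversion seen at deletion-bin
#' resolution when the segments themselves are `+`).
#'
#' @param zipper a [build_zipper()] result
#' @param min_segment minimum genes per reported segment
#' @param gap_tol rank slack allowed between chained segments (small-scale
#'   translocations excised from a region leave rank gaps at its joins)
#' @return list: `segments`, `all_runs`, `translocations`, `events`,
#'   `breakpoints`
#' @export
detect_rearrangements <- function(zipper, min_segment = 5L,
                                  gap_tol = min_segment) {
  z <- zipper[zipper$syntenic, , drop = FALSE]
  empty <- list(segments = data.frame(), all_runs = data.frame(),
                translocations = data.frame(), events = data.frame(),
                breakpoints = data.frame())
  if (nrow(z) < 2) return(empty)
  runs <- list()
  for (ch in unique(z$ref_chrom)) {
    zc <- z[z$ref_chrom == ch, , drop = FALSE]
    if (nrow(zc) < 1) next
    rk <- rank(zc$ref_pos, ties.method = "first")
    start <- 1L
    dir <- 0L
    for (i in seq_len(nrow(zc))) {
      if (i == nrow(zc)) { nxt <- NA_integer_ } else nxt <- rk[i + 1L]
      step <- if (is.na(nxt)) 0L else nxt - rk[i]
      extend <- !is.na(nxt) && abs(step) == 1L && (dir == 0L || step == dir)
      if (extend) {
        if (dir == 0L) dir <- step
      } else {
        runs[[length(runs) + 1L]] <- data.frame(
          ref_chrom = ch, zipper_from = zc$index[start],
          zipper_to = zc$index[i],
          rank_from = rk[start], rank_to = rk[i],
          n_genes = i - start + 1L,
          orientation = if (dir < 0) "-" else "+",
          first_gene = zc$ref_gene[start], last_gene = zc$ref_gene[i],
          stringsAsFactors = FALSE)
        start <- i + 1L
        dir <- 0L
      }
    }
  }
  all_runs <- do.call(rbind, runs)
  all_runs$run_id <- seq_len(nrow(all_runs))
  segs <- all_runs[all_runs$n_genes >= min_segment, , drop = FALSE]
  transloc <- all_runs[all_runs$n_genes < min_segment, , drop = FALSE]

  # re-join segments split by excised small translocations: consecutive
  # segments on one chromosome continuing in the same direction within
  # gap_tol ranks are one co-linear region
  if (nrow(segs) > 1) {
    keep <- rep(TRUE, nrow(segs))
    for (j in 2:nrow(segs)) {
      i <- max(which(keep[seq_len(j - 1L)]))
      same <- segs$ref_chrom[j] == segs$ref_chrom[i] &&
        segs$orientation[j] == segs$orientation[i]
      gap <- if (segs$orientation[j] == "+")
        segs$rank_from[j] - segs$rank_to[i] - 1L
      else segs$rank_to[i] - segs$rank_from[j] - 1L
      if (same && gap >= 0 && gap <= gap_tol) {
        segs$rank_to[i] <- segs$rank_to[j]
        segs$zipper_to[i] <- segs$zipper_to[j]
        segs$last_gene[i] <- segs$last_gene[j]
        segs$n_genes[i] <- segs$n_genes[i] + segs$n_genes[j]
        keep[j] <- FALSE
      }
    }
    segs <- segs[keep, , drop = FALSE]
  }

  # reversal events: maximal chains of zipper-consecutive segments whose
  # reference ranges are contiguous and strictly descending
  events <- list()
  if (nrow(segs)) {
    segs$seg_id <- seq_len(nrow(segs))
    i <- 1L
    while (i <= nrow(segs)) {
      j <- i
      while (j < nrow(segs) &&
             segs$ref_chrom[j + 1L] == segs$ref_chrom[j] &&
             abs(max(segs$rank_from[j + 1L], segs$rank_to[j + 1L]) + 1L -
                   min(segs$rank_from[j], segs$rank_to[j])) <= gap_tol)
        j <- j + 1L
      if (j > i || segs$orientation[i] == "-") {
        type <- if (j == i) "inversion" else "reversal"
        events[[length(events) + 1L]] <- data.frame(
          ref_chrom = segs$ref_chrom[i], type = type,
          n_segments = j - i + 1L,
          seg_first = segs$seg_id[i], seg_last = segs$seg_id[j],
          rank_min = min(segs$rank_from[i:j], segs$rank_to[i:j]),
          rank_max = max(segs$rank_from[i:j], segs$rank_to[i:j]),
          first_gene = segs$last_gene[j], last_gene = segs$first_gene[i],
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  events <- if (length(events)) do.call(rbind, events) else data.frame()

  # breakpoint intervals between zipper-adjacent segments
  bps <- list()
  if (nrow(segs) > 1) {
    for (k in seq_len(nrow(segs) - 1L)) {
      if (segs$ref_chrom[k] != segs$ref_chrom[k + 1L]) next
      bps[[length(bps) + 1L]] <- data.frame(
        ref_chrom = segs$ref_chrom[k],
        left_gene = segs$last_gene[k],
        right_gene = segs$first_gene[k + 1L], stringsAsFactors = FALSE)
    }
  }
  list(segments = segs, all_runs = all_runs, translocations = transloc,
       events = events,
       breakpoints = if (length(bps)) do.call(rbind, bps) else data.frame())
}

#' Per-bin syntenic/non-syntenic composition with Fisher tests
#'
#' @param gene_bins data.frame `gene_id, bin, syntenic` (every counted gene
#'   carries a bin)
#' @param bin_order bins in arm order
#' @param min_genes bins with fewer genes are flagged low-power
#' @return data.frame `bin, syntenic, non_syntenic, prop_syntenic, p_value,
#'   low_power` (two-tailed Fisher test of each bin against the rest)
#' @export
bin_synteny_stats <- function(gene_bins, bin_order, min_genes = 5L) {
  stopifnot(all(c("bin", "syntenic") %in% names(gene_bins)))
  if (any(is.na(gene_bins$bin))) stop("every counted gene needs a bin")
  tot_s <- sum(gene_bins$syntenic)
  tot_n <- sum(!gene_bins$syntenic)
  out <- lapply(bin_order, function(b) {
    inb <- gene_bins$bin == b
    s <- sum(gene_bins$syntenic[inb]); ns <- sum(!gene_bins$syntenic[inb])
    p <- if (s + ns == 0) NA_real_
         else fisher_two_tailed(s, ns, tot_s - s, tot_n - ns)
    data.frame(bin = b, syntenic = s, non_syntenic = ns,
               prop_syntenic = if (s + ns > 0) s / (s + ns) else NA_real_,
               p_value = p, low_power = (s + ns) < min_genes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Three-way zipper comparison
#'
#' @param zip1,zip2,zip3 zipper frames keyed on shared reference gene ids
#' @param labels names for the three zippers
#' @return list: `venn` (7 named counts of syntenic genes by sharing
#'   pattern), `links` (gene, position index in each zipper where present)
#' @export
compare_zippers <- function(zip1, zip2, zip3,
                            labels = c("z1", "z2", "z3")) {
  sets <- list(zip1, zip2, zip3)
  ids <- lapply(sets, function(z) unique(z$ref_gene[z$syntenic]))
  all_ids <- unique(unlist(ids))
  inz <- vapply(ids, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) inz <- matrix(inz, nrow = 1)
  pat <- apply(inz, 1, function(r) paste(which(r), collapse = ""))
  key <- c("123" = "all3", "12" = paste(labels[1], labels[2], sep = "&"),
           "13" = paste(labels[1], labels[3], sep = "&"),
           "23" = paste(labels[2], labels[3], sep = "&"),
           "1" = labels[1], "2" = labels[2], "3" = labels[3])
  venn <- stats::setNames(integer(length(key)), unname(key))
  tv <- table(pat)
  venn[unname(key[names(tv)])] <- as.integer(tv)
  pos <- lapply(sets, function(z) {
    zz <- z[z$syntenic, , drop = FALSE]
    stats::setNames(zz$index, zz$ref_gene)
  })
  links <- data.frame(gene = all_ids,
                      pos1 = unname(pos[[1]][all_ids]),
                      pos2 = unname(pos[[2]][all_ids]),
                      pos3 = unname(pos[[3]][all_ids]),
                      stringsAsFactors = FALSE)
  names(links)[2:4] <- paste0("pos_", labels)
  list(venn = venn, links = links)
}
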