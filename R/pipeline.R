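# End-to-end driver: repeat filtering -> homology cascade -> catalogue ->
# marker anchoring -> zipper -> rearrangement detection.

#' Run the survey pipeline on a simulation (or equivalent input bundle)
#'
#' @param sim an [simulate_survey()] result, or a list with the same
#'   `reads`, `references`, `repeat_library`, `markers`, `organelle` fields
#' @param mode similarity-search mode for the cascade (`"nt"` desk-scale,
#'   `"translated"` protein-database style)
#' @param depth_threshold deep-contig depth threshold
#' @param window,step,min_genes_per_mb,min_species block-calling parameters
#' @param min_segment segment size threshold for rearrangement calls
#' @param verbose log stage timings to stderr
#' @return list with every stage's output: `assembly`, `deep`, `mask`,
#'   `nonrep`, `cascade`, `catalogue`, `anchors`, `zipper`, `rearrangements`
#' @export
run_survey_pipeline <- function(sim, mode = c("nt", "translated"),
                                depth_threshold = 5, window = 500000,
                                step = 50000, min_genes_per_mb = 50,
                                min_species = 2, min_segment = 5L,
                                verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  el <- function(t) sprintf("%.1fs", as.numeric(Sys.time() - t, units = "secs"))

  t <- tic()
  assembly <- overlap_assemble(sim$reads)
  deep <- flag_deep_contig_reads(assembly, depth_threshold)
  say("assembly: %d contigs, %d deep reads [%s]",
      nrow(assembly$contigs), deep$n_deep_reads, el(t))

  t <- tic()
  mask <- library_mask(sim$reads, sim$repeat_library)
  nonrep <- nonrepetitive_summary(mask$reads, deep$read_ids,
                                  assembly = assembly)
  say("masking: %d reads retained of %d [%s]",
      nrow(nonrep$reads), nrow(sim$reads), el(t))

  t <- tic()
  cascade <- homology_cascade(nonrep$reads, sim$references, mode = mode,
                              organelle = sim$organelle)
  say("cascade: %d assignments [%s]", nrow(cascade$assignments), el(t))

  pos_list <- list(genomeA = sim$references$genomes$A$pos,
                   genomeB = sim$references$genomes$B$pos,
                   genomeC = sim$references$genomes$C$pos)
  catalogue <- build_gene_catalogue(cascade$assignments, pos_list)
  say("catalogue: %d entries", nrow(catalogue$genes))

  t <- tic()
  bin_order <- sim$truth$bins$bin
  anchors <- anchor_markers(sim$markers, nonrep$reads,
                            cascade$assignments, bin_order)
  zipper <- build_zipper(catalogue, sim$references$genomes$A$pos, anchors,
                         bin_order, window = window, step = step,
                         min_genes_per_mb = min_genes_per_mb,
                         min_species = min_species)
  rearr <- detect_rearrangements(zipper, min_segment = min_segment)
  say("zipper: %d rows (%d syntenic), %d segments [%s]",
      nrow(zipper), sum(zipper$syntenic), nrow(rearr$segments), el(t))

  list(assembly = assembly, deep = deep, mask = mask, nonrep = nonrep,
       cascade = cascade, catalogue = catalogue, anchors = anchors,
       zipper = zipper, rearrangements = rearr,
       blocks = attr(zipper, "blocks"))
}
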