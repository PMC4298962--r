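# Shared fixtures: small simulations are built once per test run and
# cached; random sequences come from fixed seeds so expectations are
# stable.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# small survey: quick, exercises every stage
small_config <- function(seed = 11) {
  sim_config(seed = seed, n_genes = 60, n_nonsyntenic = 10,
             n_wheat_specific = 4, n_fragment_genes = 3, n_duplicated = 4,
             n_bins = 4, n_repeat_families = 4, n_trna_genic = 6)
}

small_sim <- function() cached("small_sim", simulate_survey(small_config()))

# medium survey: enough genes for catalogue / zipper behaviour, with the
# deletion-bin resolution (bins per planted segment) the ordering needs
medium_config <- function(seed = 11) {
  sim_config(seed = seed, n_genes = 150, n_nonsyntenic = 20,
             n_wheat_specific = 8, n_fragment_genes = 4, n_duplicated = 8,
             n_bins = 10, n_repeat_families = 6)
}

medium_sim <- function() cached("medium_sim", simulate_survey(medium_config()))

medium_pipeline <- function() cached("medium_pipeline", {
  run_survey_pipeline(medium_sim(), min_genes_per_mb = 30)
})

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

mutate_str <- function(x, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
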