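---
title: "Chromosome-arm survey analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-arm survey analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armsurvey)
```

# The problem

Flow sorting lets a single chromosome arm of a huge polyploid genome
(bread wheat's is ~17 Gb and ~80% repetitive) be sequenced on its own at
modest cost. A low-coverage shotgun survey of a sorted arm cannot be
assembled into a reference sequence, but it can answer structural
questions: which genes sit on the arm, in what order, which regions are
collinear with sequenced model grasses, and where the arm has been
rearranged since the lineages diverged. `armsurvey` implements that
analysis as a set of composable stages, together with a synthetic-data
generator that plants known structure so each stage can be scored.

The pipeline stages, in order:

1. **Repeat identification** (`overlap_assemble()`,
   `flag_deep_contig_reads()`, `library_mask()`,
   `nonrepetitive_summary()`) — repetitive reads are found two ways:
   by similarity to a repeat library, and by membership in assembly
   contigs whose read depth is far above the survey coverage (collapsed
   copies of near-identical elements).
2. **Conserved-gene discovery** (`internal_search()`, the `filter_*`
   functions, `reciprocal_best()`, `dedup_artifacts()`,
   `build_gene_catalogue()`) — non-repetitive reads are compared with
   three model grass genomes and external sequence collections through a
   threshold cascade, reciprocal-best-hit selection and amplification
   artifact removal; gene-level evidence is tallied into a conservation
   Venn over ortholog groups.
3. **Virtual gene order** (`window_density()`, `call_syntenic_blocks()`,
   `anchor_markers()`, `build_zipper()`, `detect_rearrangements()`,
   `bin_synteny_stats()`, `compare_zippers()`) — the "genome zipper":
   syntenic genes are ordered by deletion-bin markers at macro scale and
   reference collinearity at micro scale; the permutation between
   reference and zipper order exposes inversions and segmental
   reversals.
4. **Non-syntenic gene validation** (`evenness_test()`,
   `find_nonsyntenic_conserved()`, `cross_genome_synteny()`,
   `classify_wheat_specific()`) — conserved genes outside all syntenic
   blocks are screened by read-coverage evenness; those whose orthologs
   are mutually syntenic among the three references are called putative
   lineage-specific translocations.
5. **Gene models** (`build_gene_models()`, `classify_confidence()`,
   `cross_dataset_match()`) — reference-guided consensus models with
   `'n'`-filled gaps, classified by transcript coverage.
6. **Survey statistics** (`representation_probability()`,
   `coverage_fold()`, `fisher_two_tailed()`, `trna_density()`,
   `survey_report()`).

# Survey statistics

For an arm of size $S$ sampled by $N$ reads of mean length $L$ at
sorting purity $p$, the probability that a given base is represented in
at least one read is

$$P = \left[1 - \left(1 - \frac{L}{S}\right)^{N}\right] \times p .$$

`representation_probability()` evaluates the power term in log space
(`exp(N * log1p(-L/S))`): at survey scale $L/S \approx 10^{-6}$ and $N$
is in the millions, where naive exponentiation loses precision. The
function is strictly increasing in $N$, $L$ and $p$ and bounded above by
$p$; the test suite checks it against a Monte-Carlo base-sampling
simulation.

`fisher_two_tailed()` computes the exact two-tailed Fisher p-value by
summing hypergeometric point probabilities no larger than the observed
table's (with a $1+10^{-7}$ relative tolerance against ties lost to
floating point). `stats::fisher.test` uses the same two-tailed
definition and serves as an independent cross-check in the tests, along
with a direct `choose()`-based enumeration.

# Repeat identification

Surveys at ~1.3–1.6× coverage cannot assemble multi-kilobase LTR
retrotransposons, but reads from different near-identical copies of one
element co-assemble. `overlap_assemble()` is a deterministic greedy
exact suffix–prefix layout (overlap and minimum contig length both 40 nt
by default): candidate overlaps are found from read-prefix seeds,
verified by exact string equality, and accepted longest-overlap-first
with ties broken by read id; contained reads are absorbed. The layout is
orientation-naive — reads from opposite strands of one template form two
contigs — which halves apparent depth but leaves the depth signal of
high-copy families intact. Contig depth is total aligned member bases
divided by contig length, and `flag_deep_contig_reads()` flags members
of contigs at depth ≥ 5 (at ~1.5× coverage, only collapsed repeats reach
that depth).

`library_mask()` finds repeats by similarity instead: 24-mer seeds from
both strands of each library consensus are located in the reads and
extended ungapped along their diagonal; the best-scoring run with at
least 80% identity over at least 50 nt is masked. The identity and
length floors are package defaults (the corresponding external maskers
leave them implicit); they give near-complete masking of element copies
with point divergence below ~10%. Up to four diagonals per
read/family/strand are extended, so an insertion inside a copy (such as
a captured tRNA) splits but does not lose the match. Masking never
alters read length.

`nonrepetitive_summary()` removes deep-contig reads and majority-masked
reads (> 50% masked) and hard-masks residual intervals to `N` in the
survivors, so downstream searches skip them (interval exclusion rather
than whole-read removal; both interpretations are defensible and the
choice is explicit here). The survey report derives the
assembly-summary quantities with documented denominators; the estimated
arm length is contig bases plus non-aligned read bases — an
underestimate exactly to the extent that repeats collapse, which is why
it is reported alongside, not instead of, the cytogenetic size.

# The similarity search and the filter cascade

`internal_search()` is a desk-scale local aligner with two routes behind
one interface: exact Smith–Waterman (via `Biostrings::pairwiseAlignment`)
when the problem is small, and k-mer seeded, ungapped best-run extension
above that. E-values follow a Karlin–Altschul form with fixed
parameters per mode (nucleotide +1/−2, λ = 1.33, K = 0.621; protein
BLOSUM62, λ = 0.267, K = 0.041), calibrated so that the cascade's
published thresholds are meaningful at package scale; externally
produced BLAST tabular files are drop-in replacements through
`read_hits_tabular()` (with an optional 13th "positives" column carrying
percent similarity). Percent amino-acid similarity is the BLOSUM62
positives fraction; the cited search tool's default matrix is BLOSUM62,
so that is the reference definition here.

The cascade thresholds are the published ones: organellar screen ≥ 95%
identity over ≥ 75% of the read; protein hits e ≤ 1e−6, ≥ 75%
similarity, ≥ 30 aa; nucleotide hits e ≤ 1e−30, ≥ 75% identity over
≥ 90 nt, raised to 95% identity for same-species collections; best hit
per read. Reciprocal-best selection keeps a (read, gene) pair when the
gene is the read's best hit in both search directions — the per-read
reading, which is the only one compatible with genes retaining two or
more supporting reads. In nucleotide mode both directions are searched
literally; in translated mode the reverse direction is obtained by
transposing the symmetric hit table.

Amplification (MDA) duplicates — byte-identical reads aligning to the
same subject at the same start and end — are collapsed to the
lexicographically smallest read id. The catalogue then applies the two
quality rules: genes supported by a single read are eliminated
(impurity fragments dilute over the whole rest of the genome, so a
contaminated gene is overwhelmingly unlikely to attract two independent
reads), and external-collection subjects with more than 50 reads are
dropped as probable repeats. Ortholog groups are connected components
of the subject–read graph across the three genome databases; the
conservation Venn is tallied over groups, so one gene conserved in all
three genomes counts once with profile `ABC`.

# The genome zipper

Deletion bins — cytogenetically defined intervals from deletion stocks —
give coarse physical order along the arm; collinearity with a sequenced
reference genome gives fine order. The construction here:

* **Blocks.** Gene density per species is computed on the ordering
  reference's coordinates in 500 kb windows advanced by 50 kb (genes
  assigned by midpoint); windows at ≥ 50 genes/Mb in at least two
  species merge into maximal blocks, bridging sub-window density dips
  (≤ 1 window by default) so sampling noise does not split one
  conserved region.
* **Anchors.** A deletion-bin marker anchors the catalogued gene whose
  supporting read it matches at ≥ 95% identity over ≥ 30 nt (markers
  are same-species sequences, matched against the wheat reads rather
  than the diverged reference CDS). Conflicting bins for one gene
  resolve by majority, and each gene takes the majority bin of its
  three nearest anchors along the block — one discordant marker (for
  instance from a duplicated copy elsewhere on the arm) is outvoted
  instead of dragging its neighbours into the wrong bin.
* **Units and chaining.** Each block's genes, sorted by reference
  position, split into maximal constant-bin runs ("units"). Units are
  ordered bin-major; within each bin their order and orientation are
  chosen jointly by an exact dynamic program (subset DP over up to 8
  units per bin, greedy beyond) minimizing the total
  reference-coordinate jump at unit junctions along the whole chain.
  Junction distances are informative only up to `max_junction`
  (100 kb by default): larger jumps are genuine discontinuities
  (breakpoints) and cost the same in either orientation, so reference
  orientation prevails there — the package never infers an inversion
  from a discontinuity alone, mirroring the fact that bin-resolution
  data cannot orient a segment interior without internal evidence.
  Reversal also carries a small fixed penalty, so exactly symmetric
  cases resolve to reference order.
* **Rearrangements.** Within each reference chromosome the syntenic
  zipper genes define a permutation of their reference ranks, which is
  decomposed greedily into maximal runs of consecutive ranks. Runs of
  at least 5 genes are segments (shorter runs are reported as
  small-scale translocations, echoing the distinction between "large
  regions" and single-gene moves); segments split only by excised small
  runs are re-joined. Consecutive segments whose reference ranges are
  contiguous but appear in reversed order form a reversal event — a
  three-segment event models a centromeric segmental reversal, a
  single reversed segment (or two swapped sub-segments at bin
  resolution) an inversion.

Genetic map positions travel on the zipper as annotation only; they are
never used to reorder, because their integration rules are not well
defined at bin resolution.

# Non-syntenic genes and lineage-specific translocations

Conserved genes (profile `ABC`, ≥ 2 reads) lying outside every syntenic
block are candidate translocations, but pseudogene fragments and
amplified gene pieces also produce such matches — with reads piled on
one end. The evenness rule makes the published screen explicit and
automatic: a gene covered by $n$ reads is divided into
$k = \min(n, 4)$ equal segments and is genuine only if every segment is
overlapped by at least one read. The published procedure prescribed 2
and 3 segments for 2- and 3-read genes and visual inspection beyond;
capping at $k = 4$ is the package's conservative automation of the
visual step. Note one consequence of the $k = \min(n,4)$ family: adding
a read can raise $k$ and flip a borderline gene, so monotonicity in
read count holds only at fixed $k$ — the test suite checks it there.

A genuine non-syntenic gene whose three reference orthologs are
mutually syntenic (checked with the same block machinery applied
pairwise between the references, at the same thresholds) implies the
move happened on the wheat lineage after it diverged from the
references' common ancestor: a wheat-specific rearrangement.

# Gene models

Reads are laid onto the CDS of the reference gene they were assigned to
(one database per read, precedence genome A > B > C > UniGene >
UniProt), chained into contigs at ≥ 40 nt reference overlap and
condensed per reference into one model, with coordinate gaps filled by
runs of `'n'` (floor one `'n'`) and overlap disagreements below 95%
flagged ambiguous. Consensus is a per-column majority with ties to the
earliest-starting read. Transcript coverage — the percentage of non-`n`
model bases overlapped by ≥ 95%-identity transcript matches — assigns
high (≥ 60%), low (20–60%) or eliminated (< 20%); the 60% boundary
belongs to the high class and 20% to the low class (the published
ranges overlap at the boundaries; this package resolves them upward).
`cross_dataset_match()` compares two model sets by reciprocal best
nucleotide matches at ≥ 95% identity and e ≤ 1e−20, breaking equal
e-value ties toward the subject whose location label matches the
query's arm (the homoeolog rule: wheat sub-genome copies can be ~99%
identical, so location is the only tiebreaker), and bins matched
identities at 1% resolution.

# The synthetic-data generator

`sim_config()` / `simulate_survey()` emulate the survey inputs with
full ground truth. The default configuration is the long-arm survey's
conditions: 1.61× coverage, 347.25 bp mean read length, 85.5% sorting
purity, 75% repeat content, ~2000 syntenic genes. Structure the
generator plants:

* three reference genomes derived from one ancestral gene set by
  independent point substitution (3%/lineage by default; wheat copies
  2%), with per-lineage gene losses following configurable conservation
  class proportions and 5% random relocations;
* a wheat-like arm carrying the syntenic genes of two reference
  regions, with one inversion (~12% of the first region, matching the
  published inversion's share of its region) and a three-segment order
  reversal of the second region planted by default;
* non-syntenic insertions biased toward the distal 10% of the arm
  (60% by default), drawn from reference regions where they are
  embedded sparsely (1:9) in a dense backdrop of reference-only genes —
  so the reference side is gene-dense and mutually syntenic while arm
  evidence there stays sparse, as for a real translocated gene; a
  subset is planted as 5′-only fragments (evenness-test negatives) and
  another as duplicated copies of syntenic genes;
* TE families tiled to the target repeat fraction as truncated,
  recently-amplified (identical by default) copies on both strands,
  some carrying a 75 bp tRNA-like token; a fraction of families is
  withheld from the emitted library so depth-based detection is
  exercised independently of masking;
* reads of truncated-normal length (minimum 50 bp) at uniform
  positions, with a $1-p$ impurity drawn from a contaminant source four
  arm-equivalents in size (impurities come from the whole rest of the
  genome; the single-read contaminant rule relies on that dilution),
  a small organellar read fraction, and an `artifact_rate` fraction of
  reads re-emitted as byte-identical MDA duplicates;
* deletion bins as equal arm intervals, markers as subsequences of the
  wheat gene copies tagged with their gene's bin, and transcripts
  covering each gene to a planted class (high 65–95%, low 30–52% of the
  CDS — bands kept clear of the 20/60% boundaries so planted classes
  are recoverable exactly under complete read tiling).

What the generator does **not** model, and what passing tests therefore
do not show: sequencing error (no homopolymer or substitution noise —
alignments on simulated data are near-exact, so identity thresholds are
exercised by divergence between genomes, not by noise); indels
(the internal aligner's seeded route is ungapped for the same reason);
MDA chimeras or coverage waviness beyond exact duplicates; real CDS
composition (sequences are uniform random, so translated-mode searches
see stop codons — the cascade is indifferent, but no ORF semantics
exist); recombination-map structure. Real-data gene counts are not
reproducible from synthetic data and are not targets; the planted-truth
tests score the machinery, not the biology.

Reference geometry defaults are chosen for realism of the gene-dense
syntenic regions of compact model grass genomes: 6 kb gene spacing
(~167 genes/Mb), so that at the ~55% catalogue recovery implied by
1.6× coverage the block threshold of 50 genes/Mb is met with margin.
Determinism: every `simulate_*` function seeds a private RNG stream
from `config$seed`, so identical configurations are byte-reproducible
and the session RNG is untouched.

# Problem sizes used in the shipped tests

The test suite runs three simulation scales, chosen so the full suite
completes in minutes: a small arm (60 genes) for per-stage smoke and
truth checks; a medium arm (150 genes, 10 bins) for catalogue and
zipper behaviour — at that scale each planted segment spans barely more
than one bin, so order-recovery bounds are looser there by design; and
one survey-scale run (the default ~2000-gene configuration, ~25,000
reads) shared by the acceptance tests for rearrangement recovery
(Kendall τ ≥ 0.95, exactly three reversed segments plus the inversion),
repeat detection (planted fraction within 5 points, sensitivity ≥ 0.9,
FDR ≤ 0.1) and the filter cascade. Gene-model class recovery uses a
small arm at 6× coverage, where CDS are tiled end to end and planted
transcript classes are measurable exactly.

# Known limitations

* The greedy assembler is exact-overlap and orientation-naive: real
  454 data with sequencing error would need an error-tolerant
  assembler; here the assembler's role is the depth signal, which
  survives both simplifications.
* Zipper orientation within a single bin without internal continuity
  evidence defaults to reference order; a genuinely inverted segment
  wholly inside one bin is therefore reported in reference orientation
  (the corresponding published analysis left the same case undecided).
* E-values of the internal aligner are calibrated, not BLAST-faithful;
  absolute e-values should not be compared between the internal and an
  external search, only used against the cascade's thresholds.
* `cross_genome_synteny()` reduces mutual synteny to block co-membership
  at the same density thresholds; micro-rearrangements between the
  references are invisible at that resolution.
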