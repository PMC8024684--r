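---
title: "Defining a phage group from metagenomic viral genomes and mapping its distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining a phage group from metagenomic viral genomes and mapping its distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

A newly isolated phage is often genetically distinct from every cultured
relative, with its only kin hiding among metagenomic viral genomes (MVGs)
assembled from environmental sequencing. `mvgkit` implements the standard
chain of analyses that turns such an isolate into a defined *phage group*
with a mapped ocean biogeography:

1. **Annotation.** ORFs are called on the (usually circular) genome and
   annotated by protein homology.
2. **Group membership.** Candidate MVG contigs are compared to the
   reference by orthologous gene content: a contig joins the group when it
   shares at least 40% of the reference's genes and is at least 25 kb
   long.
3. **Phylogeny and subgroups.** A marker-protein tree (the terminase
   large subunit, TerL, is the usual marker for tailed phages) and a
   whole-proteome distance tree resolve the group's internal structure;
   single-linkage cuts of the proteome distance define genus- and
   subfamily-level subgroups.
4. **Dereplication and read recruitment.** Near-identical genomes
   (>= 70% average nucleotide identity, ANI) are collapsed to their
   longest representative, and viromic reads are recruited to the panel
   (>= 50 bp reads, >= 70% identity, >= 90% read coverage). Abundance is
   reported as KPKG — recruited kilobases per kilobase of genome per
   gigabase of metagenome — and zeroed for genomes with breadth of
   coverage below 40%, the standard guard against spurious recruitment to
   a few conserved regions.

Every stage is exercised end to end against synthetic data with planted
truth, so the package needs no external downloads to validate itself.

## Coordinates, topology, containers

Coordinates are 0-based and half-open on the forward strand everywhere.
Circular genomes represent an origin-spanning interval by `end >
length(genome)`, normalized modulo the length; `extractSubseq()` is the
single place where this convention is materialized, and every other
module (ORF caller, recruitment breadth) goes through it or unwraps with
the same rule. `N` bases are legal input, are excluded from G+C, and
never match anything in nucleotide alignment.

Genomes travel in a `GenomeSet` (a `Biostrings::DNAStringSet` plus
topology and provenance, with validity checks), trees as `ape::phylo`,
and recruitment results as a `SummarizedExperiment` with assays `kpkg`,
`kpkg_raw`, `breadth` and `recruited_kb`.

## The alignment engine

The published analysis used BLASTP/BLASTn; `mvgkit` ships its own local
aligners so that results are deterministic and self-contained.

* `alignProteinLocal()` is exact full-matrix Smith–Waterman under
  BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $k$ costs
  $11 + k$). Ties among equal-scoring alignments break deterministically.
  The test suite checks it cell-for-cell against an independent dynamic
  programming oracle on hundreds of random pairs.
* `alignNtLocal()` is a BLAST-like heuristic: exact 11-mer seeds on both
  query strands, clustered by diagonal, each cluster extended by banded
  affine dynamic programming (match +2, mismatch −3, gap open 5, extend
  2). The band half-width (8) is ample for the substitution-only
  divergence the synthetic data plant; data with many indels would need a
  wider band.
* `allVsAllProteins()` adds a word prefilter: a pair is aligned only if
  the two sequences share at least `min_word_hits = 2` distinct exact
  words of `word_size = 4` letters (the two-hit idea). This is the one
  deliberate deviation from exhaustive search; both knobs are exposed,
  and `alignProteinLocal()` itself never seeds.

Identity is `identities / alignment columns` (gap columns included),
matching the `pident` convention the thresholds were written against.
E-values use the Karlin–Altschul form with fixed gapped-BLOSUM62
constants ($\lambda = 0.267$, $K = 0.041$); for nucleotide scores,
approximate constants ($\lambda = 0.625$, $K = 0.41$) are used. The
published thresholds (E ≤ 1e−3) are coarse, so this approximate
calibration is sufficient; the constants are arguments, not magic
numbers.

## Orthologous groups and membership

Protein hits filtered at E ≤ 1e−3 and identity ≥ 0.25 (the retrieval
thresholds; note the annotation step additionally requires ≥ 50% query
coverage, the retrieval step deliberately does not) become an undirected
graph weighted by $-\log_{10}\max(E, 10^{-180})$, averaging the two
directed E-values of each pair. Markov clustering (expansion 2, inflation
1.5, pruning at 1e−6, convergence tolerance 1e−8) partitions the graph;
self-loops are added at each node's maximum incident edge weight, the
canonical MCL regularization — without it, a strongly linked pair
oscillates under expansion and inflation tears it apart. Proteins without
hits become singletons, so the groups always partition the protein
universe.

`sharedGeneFraction()` counts the fraction of *reference* genes whose
orthogroup contains at least one contig gene. Two choices matter:

* The denominator is the reference's gene count, not the contig's —
  "shares 40% of the reference's genes" stays meaningful for truncated
  contigs. The other convention is available via `denominator =
  "contig"`.
* The reference contributes its *curated* annotation (for a deposited
  genome, its annotated CDS set; for synthetic data, the planted genes),
  while contigs are called ab initio. A six-frame caller over-reports
  overlapping minor-frame ORFs by design (all overlapping ORFs are kept,
  since orthogroups — not a non-overlapping gene map — consume them);
  re-calling the reference would inflate the denominator several-fold
  and silently re-scale the 40% rule.

Membership thresholds are inclusive: shared fraction ≥ 0.40 **and**
length ≥ 25,000 bp (N bases count toward length).

## ANI and dereplication

`computeANI()` is fragment-based: the query genome is cut into
consecutive 1,000-bp windows (trailing partial window dropped), each
window is aligned to the other genome, and windows whose best hit spans
at least 70% of the window count as aligned. ANI is the mean identity of
aligned windows, averaged over the two directions. With no named tool in
the original method description, this standard fragment recipe is the
declared choice; `frag_len` and the 70% qualification are arguments.
Note the consequence: ANI is an identity *conditional on alignment* —
two genomes sharing only one conserved region can still show high ANI
with few aligned fragments, which is why dereplication, not ANI alone,
decides redundancy.

`dereplicateGenomes()` single-links pairs with ANI ≥ 0.70 ("clustered at
70% identity" conventionally means transitive linkage in viromics) and
keeps the longest genome per cluster, ties to the lexicographically
smallest ID. The operation is idempotent.

## Phylogeny

The marker tree uses Poisson-corrected local-alignment distances
($-\ln(1-p)$, capped at 5, with the cap for unalignable pairs) and the
package's own Saitou–Nei neighbor joining (negative branch lengths
clamped to zero; Q-criterion ties broken by smallest label pair). The
published analysis used maximum likelihood; the conclusions drawn from
the tree here are topological (which genomes cluster apart), which
distance NJ recovers on planted data, so ML was not re-implemented.
`ape::nj` serves as an independent cross-check in the tests, never as the
implementation.

`bootstrapMarkerTree()` builds a progressive profile–profile alignment
(BLOSUM62, gaps 11/1) along a midpoint-rooted NJ guide tree, then
resamples alignment columns with replacement (seeded), rebuilding a tree
per replicate; supports are the percentage of replicates containing each
internal bipartition of the full-data tree. The default is 100
replicates — the published 1,000 is a config choice away and scales
linearly. Alignment trimming is deliberately omitted (the bootstrap
operates on the full alignment).

The whole-proteome distance mirrors genome-BLAST distance ideas: greedy
one-to-one best-hit pairing of the two proteomes, then
$d = 1 - 2\sum I / (N_a + N_b)$, where $\sum I$ is the summed identical
residues and $N_a, N_b$ the proteome sizes; $d$ is clamped to $[0, 1]$.
Genus- and subfamily-level cuts default to thresholds 0.6 and 0.9 on
this distance. These defaults are calibrated only in the sense that they
cleanly separate the planted subgroup structure of the synthetic
scenario (the distant genome sits at $d \gtrsim 0.8$ from the rest, the
close ones below ~0.6); on real data the reference-partition-fitting the
original OPTSIL workflow performs would be required, and the thresholds
are exposed for exactly that reason.

## Recruitment and KPKG

Reads shorter than 50 bp are discarded (inclusive threshold: a 50-bp
read stays). Each surviving read is assigned to at most one genome — the
highest-scoring qualifying hit, ties to the smallest genome ID — under
identity ≥ 0.70 and aligned-read-fraction ≥ 0.90. "Recruited
nucleotides" counts *aligned* read bases (`q_end − q_start`), the
closest literal reading; `count_full_read = TRUE` switches to full read
lengths. The metagenome size in the KPKG denominator is the dataset's
total bases *before* the length filter, since "per gigabase of
metagenome" describes the dataset. Breadth of coverage is the interval
union of subject hits over the genome length (wrap intervals unwrapped),
and KPKG is zeroed below 40% breadth while the raw value is kept in a
separate assay.

## What the synthetic data emulate — and what they do not

`makeReferenceGenome()` plants a circular ~35-kb genome with 55
forward-strand genes (lengths 300–1,500 nt rescaled to fit, ATG starts,
stop-free interiors, genetic code 11) at G+C 0.40 — the scale of a small
marine phage isolate. The stop-free codon distribution is solved
numerically so the realized G+C hits the target despite the exclusion of
the AT-rich stop codons. An in-frame `TAA` is planted immediately
upstream of each start so the maximal-ORF caller recovers every gene
exactly — a deliberate scaffold, not a property of real genomes.

`evolveGenome()` derives relatives at a planted nucleotide divergence
and gene retention. Two modeling choices deserve emphasis:

* Removed genes are **replaced** by random sequence of equal length by
  default, not excised. Real environmental relatives share a subset of
  the reference's genes yet remain full-sized genomes (26–35 kb carrying
  42–57 genes) because they carry *other* genes; literal deletion would
  shrink a 45%-retention genome below the 25-kb membership floor and
  make the planted scenario internally contradictory. `mode = "delete"`
  is available.
* Substitutions inside retained genes are frame-aware: a substitution
  that would create an in-frame stop is redirected to another base. The
  substitution *count* (hence planted divergence and the ANI oracle) is
  preserved, but retained genes stay intact ORFs. Without this, a gene
  at 25% divergence fragments into ~35-codon pieces and the gene-sharing
  signal the scenario is supposed to plant disintegrates. Start, stop
  and upstream-spacer codons are never substituted.

The default study scenario (`makeStudyScenario()`) is one reference plus
eleven relatives at divergence 0.05 with retentions 0.75–1.00 (subgroup
I; 42–55 retained genes) and one distant relative at divergence 0.25
retaining 45% of the genes (subgroup II) — a 12-genome panel whose
membership, 11+1 subgroup split and tree placement are all recoverable
ground truth. The marker gene (the longest planted gene, standing in for
the universally conserved TerL) is exempt from removal, mirroring the
fact that a packaging marker is present in every member of a real phage
group.

`simulateVirome()` draws fixed-length reads from panel genomes at planted
abundances (uniform positions honoring circularity, uniform strand, iid
substitution errors), plus a configurable fraction of fresh random
background. The recruitment grid scenario uses five unrelated genomes ×
three mixture viromes (3,000 reads of 100 bp, 1% error, 10% background,
minimum panel share 0.08 so every genome clears the breadth threshold)
plus one sparse virome planting sub-threshold breadth.

What the generator does **not** emulate: indels (substitution-only
evolution keeps the ANI and identity oracles exact; an indel mode would
need wider alignment bands), quality scores, chimeric reads, strand
bias, uneven coverage, gene gain from real foreign sequence, and
rearrangements. Passing tests therefore demonstrate correctness of the
computations under a clean substitution model, not robustness to every
artifact of real viromes.

## Numerical choices and degenerate inputs

* MCL iterates at most 200 times with tolerance 1e−8 and returns the
  current matrix if unconverged; components of the limit support are the
  clusters either way.
* All RNG flows through explicit seeds; child seeds derive
  deterministically from a master seed and stay below $2^{31}$.
* Membership and ANI threshold comparisons use a 1e−12 slack so
  fractions like 22/55 compare as intended against 0.40.
* An all-zero distance matrix yields a star tree with zero branch
  lengths; an unalignable protein pair gets the capped distance 5.0; a
  virome whose reads all fail the length filter contributes zero
  recruitment rather than an error.
* Problem sizes in the tests and the acceptance script — 35-kb genomes,
  a 12-genome panel, 3,000-read viromes, 100-replicate bootstraps and
  50-tree/200-pair oracle sweeps — were chosen as the smallest sizes at
  which every planted signal is comfortably above its recovery
  threshold.

## The pipeline surface

`runStage()` orchestrates `simulate → annotate → group → dereplicate →
tree → recruit → report` over a shared output directory; stages read
their predecessors' artifacts, so stagewise and `"all"` runs are
identical, and a YAML config (every threshold named above) plus a
written manifest (config snapshot, seed, package version, input
checksums) make runs reproducible. A thin command-line wrapper ships in
`inst/scripts/phage-pipeline.R`. The R functions are the primary
interface; the wrapper only maps arguments and exit codes (0 success, 1
usage/config, 2 data).

## Known limitations

* The aligners are simplified BLAST stand-ins: no sum statistics, no
  composition-based score adjustment, no translated searches. Absolute
  E-values are approximate; thresholded decisions are what the pipeline
  relies on.
* The genus/subfamily thresholds are scenario-calibrated defaults, not
  fitted taxonomy (see above).
* Fragment ANI with a seeded aligner can miss heavily diverged homology
  (seed probability decays as identity${}^{11}$), understating linkage
  near the 70% threshold for genomes right at that divergence.
* The six-frame ORF caller reports all maximal ORFs; it is not a gene
  finder, and gene counts from it are not comparable to curated
  annotations (which is why the reference uses its curated gene set).
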