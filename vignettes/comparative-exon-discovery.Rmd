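---
title: "Comparative discovery of unannotated exons from isoform alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative discovery of unannotated exons from isoform alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonscout)
```

## The problem

Eukaryotic genes are spliced: a gene's exons are conditionally combined into
alternative mRNA transcripts, so a single gene yields a family of related
protein isoforms. Because the space of conditions (tissue, developmental
stage, environment) that control splicing cannot be enumerated, the isoform
catalog of any one species is incomplete, and many genuinely coding exons are
missing from its annotation. Sequencing efforts in *other* species sample
different conditions, so an exon observed in mouse but never in rat is often
present — just unobserved — in the rat genome. exonscout finds such exons: it
compares protein isoforms across species and searches for the missing exon's
homolog exactly where the gene structure says it must be.

## The method

Input is a per-gene-family, splice-aware protein isoform MSA together with a
coordinate map: for every aligned residue, the genomic position of the middle
nucleotide of its codon. We denote the residue matrix $M$ (rows = isoforms,
columns = alignment columns, gaps as `-`) and the coordinate matrix $P$
(same shape, `NULL` exactly at gaps, strictly monotone along each row in
strand orientation). Such alignments are produced by splice-aware isoform
aligners; the file dialect read here is a simple aligned FASTA plus a
per-isoform list of codon-middle coordinates.

The pipeline has four steps.

1. **Collapse** (`collapse_isoforms`). All isoforms of species $k$ are
   collapsed into one *all-exon* row $C(k)$ with coordinates $Q(k)$: a column
   is non-gap wherever at least one isoform of $k$ has a residue. Usually all
   isoforms agree at a column; when they do not (a region can code in more
   than one frame across isoforms), a majority vote over (residue,
   coordinate) pairs decides, with ties going first to the isoform with the
   best annotation score (1–5, lower is stronger) and then to the earliest
   row. Conflicts are counted and retained for inspection.

2. **Exon blocks** (`derive_exon_blocks`). Adjacent codon middles are 3 nt
   apart within an exon, so a jump $|Q(k,j{+}1) - Q(k,j)| >$
   `max_codon_step` (default 6 nt) marks an intron. Boundaries from all
   species are unioned into one ordered list of column ranges $X$ tiling the
   alignment. The default of 6 tolerates one skipped codon produced by
   collapse artifacts while catching any real intron, which is dozens of
   nucleotides at minimum.

3. **Candidates and windows** (`find_missing_exons`,
   `compute_search_window`). A (species $k$, block $b..e$) pair where
   $C(k, b..e)$ is all gaps while another species has residues there is a
   missing-exon candidate. Each other species' block residues (gaps
   stripped) become a query peptide; queries shorter than 6 amino acids are
   discarded as unalignable. The homolog, if present, must lie between the
   flanking exons of $k$: the window is $L = Q(k, b{-}1)$ to
   $R = Q(k, e{+}1)$ on the forward strand (flanks swap on the minus strand
   so $L < R$ always). If the flanking column happens to be a gap in row
   $k$, the nearest mapped coordinate further out is used. When a species
   has no exon on one side at all, the window extends 25,000 nt
   (`window_pad`) from the existing flank; windows are clamped to
   chromosome bounds. Window endpoints are used inclusively — an overlap of
   one codon with a flanking exon is harmless to local alignment.

4. **Translated search and acceptance** (`seed_search`, `sw_align`,
   `accept_prediction`). The window sequence (reverse-complemented for
   minus-strand genes) is translated in all three forward frames and scanned
   for local alignments of each query peptide under BLOSUM62 with affine
   gaps (open 11, extend 1 — standard translated-search defaults). The
   internal backend extracts the best local hit, masks its nucleotide
   footprint in every frame, and repeats, yielding the highest-scoring
   mutually non-overlapping seeds; because windows are at most 25 kb this
   exhaustive scan is cheap and was preferred over a k-mer-seeded heuristic,
   which would add miss modes without saving measurable time. An optional
   external `tblastn` backend honors the same contract. Each seed is
   extended by 15 codons per side, re-aligned at the protein level by the
   package's Smith–Waterman kernel, and then extended ungapped to the full
   query wherever target residues exist: the exon's extent is defined by
   the query exon, so terminal mismatches of a diverged exon belong inside
   the alignment rather than being trimmed by the score optimum. The raw
   local score is kept as the alignment score. A hit is accepted when it
   covers at least 90% of the query (`min_coverage`), reaches 35% identity
   over gap-free columns (`min_identity`), and has positive score.

Accepted hits from different query species that overlap by at least one
nucleotide describe the same exon and are merged, reporting the best
supporting identity (`dedup_predictions`). Predictions are classified
against annotation tracks — `overlaps_gtf` before `overlaps_competing`
before `entirely_novel`, strand-agnostically and with 1 nt sufficing, a
deliberately conservative novelty call — and receive a transitive
annotation score: the best source annotation score among supports whose
alignment covers ≥85% of the predicted exon's residues. Finally
`divergence_deltas` situates each prediction against its gene: per-block
identities of the (target, best query) species pair, the unweighted mean
over blocks (exon-length weighting is a plausible alternative; unweighted
was chosen for simplicity and robustness to one long exon), and the nearest
upstream/downstream blocks.

## Identity definition

Percent identity is everywhere the share of *gap-free* alignment columns in
which both sequences carry the same amino acid; columns with a gap on
either side count toward neither numerator nor denominator. An alignment
with no gap-free column reports 0 flagged as undefined.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_coverage` | 0.90 | fraction | query residues that must be aligned for acceptance |
| `min_identity` | 35 | % | gap-free-column identity floor for acceptance |
| `window_pad` | 25000 | nt | one-sided window when a flanking exon is absent |
| `max_codon_step` | 6 | nt | coordinate jump that declares an exon boundary |
| `gap_open`, `gap_extend` | 11, 1 | score | affine gap penalties (BLOSUM62) |
| `seed_min_score` | 40 | raw score | seed floor; short queries use 0.9 × self-score if lower |
| `seed_margin` | 15 | codons | seed extension before realignment |

The seed floor of 40 comes from the extreme-value behavior of local
alignment scores: for a ~20-residue query against a ≤25 kb window the
expected number of random BLOSUM62 hits at score 40 is well below one, and
0 false seeds were observed over 100 random 4 kb windows. The
`0.9 × self-score` arm exists because a 6–10 aa query cannot reach 40 even
when perfect.

## What the simulator emulates — and what it does not

`generate_family` builds an ancestral multi-exon protein (by default 5
exons of 18–36 aa), derives each species' copy (species 1 is the
undiverged reference; the others are mutated to a target pairwise identity
by uniform random substitution, no indels), back-translates with random
codon choice, and embeds the exons with random 100–2000 nt GT..AG introns
and 2,500 nt flanks on a per-species toy chromosome, reverse-complemented
for minus-strand species. Intron lengths keep windows well under the 25 kb
fallback, which the flank policies exercise separately. Exons listed as
hidden are planted in the genome at a chosen identity but omitted from all
isoforms of that species; every family carries its ground truth. Each
species contributes two isoforms (the full visible set, score 1, and the
same minus its last exon, score 3) so collapsing is genuinely exercised.

The simulator is deterministic given its spec and seed. It does **not**
model indels within exons, rate-matrix substitution biases, paralogy,
trans-splicing, split codons at intron boundaries, or alignment error in
the input MSA — the MSA is constructed column-exact. Passing recovery tests
therefore demonstrate the pipeline's arithmetic and search machinery, not
robustness to upstream aligner mistakes: with real alignments, collapse
conflicts and ragged block edges will be more common, which is why
conflicts are logged and flank columns are scanned outward.

In the recovery experiments, hidden exons are placed only in non-reference
species: hiding in the reference would make query and planted copy diverge
independently from each other (≈ p² identity), which is a different — and
for the delta-centering study, wrong — evolutionary scenario than uniform
divergence along one lineage.

## Numerical and degenerate-input choices

* Ties in the majority vote: best annotation score, then first row —
  deterministic and favoring better-evidenced sequences.
* `percent_identity` with zero gap-free columns: 0 with an `undefined`
  attribute rather than `NaN`, so downstream sorting never sees missing
  values.
* Candidates whose target species has no mapped coordinate on either side
  are skipped with a logged reason; degenerate (empty) windows likewise.
* All internal coordinates are 1-based inclusive forward-strand; BED's
  0-based half-open convention is converted exactly at the writer/reader
  boundary, and the conversion is a bijection on integer intervals.
* Frameshifts within one exon are not modeled: each alignment lives in a
  single reading frame.
* Per-family failures in `run_pipeline` are caught, logged, and do not
  abort the run; outputs are a pure function of inputs and configuration
  (families are processed in sorted name order, so results are independent
  of scheduling and of `threads`).

## Validation studies and problem sizes

The test suite regenerates everything from code; no stored fixtures are
needed. The main studies, sized to run comfortably on one CPU: 50 planted
families at 60% identity and 25 at 100% (recovery and exactness), 200
random alignment instances against an independent local-alignment oracle,
60 randomized window configurations checked exactly, 100 random families
for collapse conservation/idempotence, 200 uniformly mutated families for
delta centering (mean within ±2 percentage points of zero), byte-level
determinism of a two-family pipeline run, and 10-family format round-trips.

## Known limitations

* A missing exon whose homolog lies *outside* the exon-bounded window
  (e.g., after genomic rearrangement) cannot be found by design.
* Exons shorter than 6 aa are never searched for, mirroring the query
  filter.
* The acceptance thresholds operationalize "high-quality full-length
  match"; they are configurable, and borderline real hits near 35%
  identity should be reviewed manually via the per-gene alignment files.
* Novelty classification is strand-agnostic and purely interval-based; it
  does not check reading-frame compatibility with the overlapping
  annotation.
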