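# exonscout

Comparative discovery of unannotated exons from protein isoform alignments.

## The problem

Alternative splicing means a gene's exons are combined conditionally into
many protein isoforms, and no single species' sequencing record observes
them all. An exon documented in mouse isoforms but never in rat is often
present — just unobserved — in the rat genome. exonscout identifies such
exons by cross-species comparison: it collapses each species' isoforms into
a single *all-exon* representation, spots exon blocks that one species lacks
entirely, and searches for the missing exon's homolog by translated
Smith–Waterman alignment inside the genomic interval bounded by that
species' neighboring exons. It is intended for genome annotators and
comparative genomicists working from splice-aware, genome-mapped isoform
MSAs.

## Method in brief

For a gene family, the input is the isoform residue matrix `M` and a
coordinate matrix `P` giving, for every aligned residue, the genomic
position of its codon's middle nucleotide. Per species *k* the rows are
collapsed into `C(k)`/`Q(k)` (majority vote at rare conflicting columns);
codon-coordinate jumps `|Q(k,j+1) − Q(k,j)| > 6` partition the columns into
exon blocks `X`. For each block `b..e` that is all-gap in species *k* but
populated in another species, the other species' block residues become
query peptides (≥ 6 aa), and the search window is

```
L = Q(k, b−1),   R = Q(k, e+1)
```

(flanks swapped on the minus strand; a missing flank extends the window by
25,000 nt; windows are clamped to chromosome bounds). Queries are aligned to
all three frames of the window under BLOSUM62 with affine gaps (open 11,
extend 1); the highest-scoring non-overlapping seeds are re-aligned at the
protein level and accepted when they cover ≥ 90% of the query at ≥ 35%
identity over gap-free columns. Overlapping hits from different query
species are merged keeping the best supporting identity, classified against
GTF CDS and competing-prediction BED tracks (`overlaps_gtf` >
`overlaps_competing` > `entirely_novel`), given transitive annotation
scores (best source score among supports covering ≥ 85% of the predicted
exon), and written out as per-species BED files, a ranked hit report, and
per-gene alignment renderings with the collapsed `C`/`Q` data.

A synthetic family generator (`generate_family`) with planted hidden exons
provides ground truth for end-to-end validation; no external data are
needed to build or test the package.

## Worked example

```r
library(exonscout)

# a 3-species family whose exon 3 is hidden from all isoforms of species 2,
# but planted in its genome at 60% amino-acid identity
spec <- family_spec(seed = 42,
                    hidden_exons = list(list(species = 2, exon = 3,
                                             identity = 60)))
fam <- generate_family(spec)
res <- process_family(fam$aln, fam$genomes)
p <- res$predictions[[1]]
```

This prints (via the snippets in `?process_family` / the vignette):

```
candidates: 1 | windows searched: 1 | predictions: 1
predicted exon: chr1:5327-5380(+) in sp2, block e3
identity 61.1% | aa length 18 | novelty entirely_novel
truth: 5327 - 5380  planted identity: 60

score 53  identity 61.1%  coverage 1.00  frame 0
target chr1:5327-5380(+)

query  LNSCFCRWTWCFGGDDEI
       |.||||||....|.||.|
target LLSCFCRWFNQWGCDDWI
```

The predicted interval is exactly the planted one; the measured 61.1%
equals the planted 60% at the granularity of an 18-residue exon
(11/18 matches). With no loaded annotation tracks the exon is
`entirely_novel`.

Directory-level runs use `run_pipeline()` (or the thin CLI wrapper in
`inst/cli/exonscout.R` with `run` and `simulate` subcommands), producing
`<species>.bed`, `Hits-by-Pct-ID.tsv`, and `Results-by-Gene/` under the
output directory.

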