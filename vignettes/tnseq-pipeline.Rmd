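---
title: "Insertion spectra, peaks, and barcoded lineages: the tnseqr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion spectra, peaks, and barcoded lineages: the tnseqr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The readout this package implements

Mariner-family transposons insert exclusively at TA dinucleotides. Junction
sequencing (Tn-Seq) reads across the transposon's inverted-repeat terminus
into the adjacent genomic DNA, so each read pair witnesses one insertion
event: the forward read carries the 30-nt terminus followed by genomic
sequence, and the reverse read starts with a random unique molecular
identifier (UMI) and reads back from the sheared fragment end. In the
random-barcode variant (RB-Tn-Seq) the forward read additionally carries a
20-nt random barcode between fixed flanking sequences; because the barcode
travels with the transposon, it identifies the founder lineage even after
the transposon remobilizes to a new locus.

`tnseqr` turns raw paired FASTQ files from either protocol into:

1. per-TA-site **insertion spectra** (deduplicated molecule counts),
2. **promoter orientation** calls per site,
3. **enriched peaks** against a local Poisson background,
4. gene-level **differential enrichment** between paired start/end samples,
5. barcode-defined **lineages** across time points, with founder
   identification, convergent-locus reports, and cross-contamination flags.

A synthetic-data generator produces the genome, the barcoded insertion
population, and the reads, so every stage is exercised and validated
without any external data.

# Stage-by-stage model and parameter choices

## Junction filtering and trimming

A pair is kept when its forward read contains the transposon terminus with
at most 2 substitutions (`match_terminus()`, Hamming distance over every
window, leftmost hit). Hamming rather than edit distance is used
throughout the package: the library chemistry modeled here produces
substitution errors, and substitution-only semantics make every matching
rule exactly checkable against a brute-force oracle.

Trimming is anchor-based by default — the forward read is cut immediately
after its terminus match, which is robust to the exact amplicon prefix
geometry. A fixed-offset mode (`trim_mode = "fixed"`) reproduces
positional trimming for libraries whose prefix length is known and
constant. The UMI is the first 8 (RB-Tn-Seq) or 9 (Tn-Seq) bases of the
reverse read and is appended to the read name after a `":"`; the
two defaults reflect an adapter carrying 8 random bases plus one
ligation-scar base consumed by the plain Tn-Seq extraction. Pairs with
mean Phred quality below 15 on either mate are dropped; the threshold is
deliberately permissive because quality degradation is not part of the
error model — the simulator exposes `low_quality_frac` purely to exercise
the filter.

## Barcode extraction and error-correction clustering

Barcodes are the sequence strictly between the two flanking sequences,
located by leftmost Hamming match with a *combined* budget of 4
substitutions across both flanks; only length-20 barcodes are kept.
Nearly identical barcodes are consolidated by greedy abundance-ranked
clustering (`cluster_barcodes()`): barcodes are visited by descending read
count (lexicographic tie-break) and join the first existing cluster whose
*center* is within Hamming distance 2, else found a new cluster. The
procedure is deterministic and conserves reads, which the tests assert.
When true barcodes are pairwise more than 2×d apart and errors perturb
each read by at most d, every read provably lands in its generating
cluster — this oracle property is part of the acceptance suite.

## Read placement and the insert bound

The built-in placer is an exact-seed + Hamming-extension mapper intended
for desk-scale genomes (up to a few Mb): up to three non-overlapping
20-mers of each read (and of its reverse complement) are looked up
exactly, candidates are extended by Hamming comparison with at most 3
mismatches per read, and only a *unique* best placement is accepted — ties
are dropped as ambiguous rather than assigned arbitrarily. Mates must
place on opposite strands in the proper orientation with an insert of at
most 1,000 nt. Multiple seeds matter at realistic error rates: with a
single seed, a 1% substitution rate leaves ~18% of reads with an error in
the seed and silently unmapped; three seeds reduce seed loss to under 1%.
Externally aligned SAM/BAM (any aligner) can be imported instead
(`import_sam()`), with the same pairing and insert rules applied.

## UMI deduplication

Reads collapse to molecules by (chromosome, fragment span, strand, UMI).
Within a coordinate group, UMIs at Hamming distance 1 merge under the
directional rule — an edge runs from UMI *a* to *b* when
`count(a) >= 2*count(b) - 1` — and each connected component keeps its
highest-count UMI and that UMI's earliest read id. The rule removes
PCR/sequencing UMI errors (low-count satellites of a high-count parent)
while keeping genuinely co-located distinct molecules apart.

One consequence is worth stating plainly: when two *true* molecules in
the same coordinate group happen to draw UMIs at Hamming distance 1 and
their PCR copy numbers are skewed, the rule merges them. With 8-nt UMIs,
six insertion sites, and 50,000 molecules, this affects roughly 0.1% of
molecules. It is a property of directional deduplication itself, not of
this implementation; the molecule count is therefore exact at small scale
and accurate to well within 1% at full scale.

## Insertion spectra and orientation

Junction positions snap to the nearest TA site within 2 nt (ties go
upstream); molecules with no TA within tolerance are reported in an
off-TA side table and excluded from the normalized spectrum. Fractions
are molecule counts over total mapped molecules, per sample. The
outward-facing promoter of an insertion points *against* the strand on
which its junction reads accumulate; with reads on both strands the
majority decides and the minority fraction is reported, with exact ties
flagged ambiguous.

## Peak calling

Fixed 200-nt windows slide at 100-nt steps. Each window's molecule pileup
is tested against `lambda_local = max(lambda_genome, lambda_5kb,
lambda_10kb)` — the genome-wide rate and the 5-kb/10-kb neighborhood
rates, scaled to the window width and floored at 1e-6. P-values come from
the upper-tail Poisson survival function, are Benjamini–Hochberg adjusted
across *all* tested windows, and windows passing `q <= 0.01` merge into
peaks (summit = highest-count position). The 200-nt window matches the
fragment scale; the 5/10-kb local backgrounds mirror the defaults of
standard coverage-based peak callers at desk scale. BH across windows is
intentionally conservative and self-contained. Off-TA molecules are
excluded from peak calling but reported.

## Differential enrichment

Molecules aggregate per gene by TA position within `[start, end]` (full
gene span; no 3'-tail trimming). Genes with a combined start+end count
below 128 are filtered. The test is an exact conditional
negative-binomial test: conditioned on a gene's total `t`, the two-sided
p-value sums the probabilities of all splits no more likely than the
observed one, under NB noise with means proportional to library sizes and
a common dispersion. Dispersion is estimated across genes by the method
of moments on counts scaled to a common library size — the *mean* of the
per-gene estimates `(var - mean) / mean^2`, floored at 0.01. The mean is
used rather than the median because each per-gene estimate has a single
degree of freedom and a heavily right-skewed distribution; the median is
biased low, which would make the test anticonservative (this is visible
in null simulations). As dispersion approaches 0 the test reduces to the
binomial exact test, which serves as the independent oracle in the test
suite. Library-size normalization (rather than raw totals) is used and
recorded; fold changes use a pseudocount of 0.5 per condition.

## Lineages, founders, convergence, contamination

Samples demultiplex into lineages by barcode cluster; per-lineage spectra
renormalize within each (lineage, time point) so pooled sequencing-depth
differences do not distort longitudinal comparisons. Founder sites hold
at least 50% of the earliest time point's molecules (several may qualify
at multicopy loci; none qualifying flags `ambiguous_founder`). Convergent
loci are 1-kb windows where at least 2 lineages each place at least 5% of
their end-point molecules — windowed rather than exact-position because
independent replicates hit nearby TA sites of the same locus. The 50%,
5%, and 1-kb values are package defaults exposed as configuration keys;
they are not sharp biological constants. Donor-site retention (founder
site persisting at end point) and the multisite signature (two or more
sites above 20% at end point) are reported alongside. A replicate is
flagged contaminated when at least 10 end-point molecules carry a barcode
outside its expected founder set; 10 molecules is the package default for
"more than sequencing noise", again a configuration key, and the source
replicate is named when the foreign barcode is another replicate's
founder.

# The synthetic-data generator

`simulate_genome()` draws an i.i.d. genome at a requested GC content
(default 0.5) and guarantees at least one TA site per 50 bp, resampling if
needed; genes are non-overlapping with random strands.
`simulate_population()` gives each founder one 20-nt barcode and draws
insertion positions uniformly over TA sites without replacement, with
within-founder abundances from a symmetric Dirichlet(1).
`simulate_reads()` draws molecules multinomially from the true
abundances, fragment lengths uniform on [200, 1000] nt, UMIs without
replacement within each insertion site (cross-site collisions can occur
by chance, as in a real library), emits `1 + Poisson(mean - 1)` PCR
copies per molecule, and applies i.i.d. substitution errors.

What the generator deliberately does **not** model: indels, adapter
read-through, quality-score decay along the read, GC-dependent coverage
bias, and chimeric fragments. Passing tests therefore demonstrate the
pipeline's correctness under substitution noise and PCR duplication —
the dominant error modes of the protocol — not robustness to structural
artifacts, which real libraries can contain.

The reference study design used by the validation suite is a 100-kb
genome, 3 founders × 2 insertions, and 50,000 molecules (250,000 read
pairs at PCR duplication 5); peak calibration uses 200 null simulations
of 5,000 molecules on 50 kb, and the enrichment operating characteristics
use 200 replicates of 500 genes at a depth of 100,000 molecules per
condition. These sizes make the whole suite run in a few minutes on one
CPU while keeping Monte-Carlo error small relative to the tested margins.

# Numerical and degenerate-input choices

* All internal coordinates are 1-based inclusive; BED converts at the
  boundary (`[10, 20)` becomes 11..20). Offsets returned by
  `match_terminus()` are 1-based for consistency.
* TA snapping ties (junction equidistant from two TA sites) go to the
  upstream site; nearest-gene ties go to the lexicographically smallest
  `gene_id`.
* An empty spectrum yields an empty peak list; an empty annotation is an
  error for nearest-gene annotation.
* `lambda_local` is floored at 1e-6 so fold enrichment is always finite.
* Clustering and deduplication are fully deterministic: ordering rules
  (count-descending, then lexicographic) are part of the contract, and
  re-running the pipeline with the same seed produces byte-identical
  tables.
* Circular genomes are supported for TA indexing (the end-to-start
  junction is checked); mapping treats the genome as linear, which is the
  default assumption throughout.

# A minimal end-to-end run

```{r demo}
library(tnseqr)

config <- list(
  mode = "rbtnseq", seed = 11, outdir = "demo_out", enrichment = TRUE,
  simulate = list(
    genome_length = 20000, n_genes = 6,
    n_founders = 2, insertions_per_founder = 2,
    n_molecules = 1200,
    samples = list(list(sample = "start", time_point = 0),
                   list(sample = "end", time_point = 1))
  )
)
res <- run_pipeline(config)

glance(res$spectra$start)
res$peaks$start
tidy(res$diff)
plot_lineage_traces(res$lineage)
```

# Known limitations

* The built-in placer is exact-seed based and desk-scale; for real
  bacterial genomes with repeats, map externally and use `import_sam()`.
* Dispersion is a single common estimate across genes; there is no
  per-gene shrinkage, so very heterogeneous dispersions will be averaged.
* Contamination detection distinguishes lineages only by barcode; it
  cannot separate a co-resident second insertion from a multicopy locus
  within one genome, and does not attempt phylogenetic inference over
  lineages.
* Multi-contig references are handled as independent contigs.
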