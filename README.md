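# tnseqr

Transposon insertion sequencing (Tn-Seq) and random-barcode lineage
tracking (RB-Tn-Seq) for mariner-family transposons, end to end in R: from
raw paired-end FASTQ to genome-wide insertion spectra, enriched-peak
calls, gene-level differential enrichment between time points, and
barcode-defined lineage reconstruction with cross-contamination
detection.

## Who this is for

Mariner/himar1 transposons insert exclusively at TA dinucleotides and can
remobilize, carrying an outward-facing promoter (and, in RB designs, a
20-nt random barcode) to new loci. Experimentalists following such
populations through selection need to know, per sample and per time
point: *where* the transposons sit, *how many independent molecules*
support each site, *which direction* the promoter faces, *which loci* are
significantly enriched, *which genes* gain insertions between start and
end point, and — when replicate lineages are pooled and sequenced
together — *which barcode lineage* each insertion belongs to and whether
wells cross-contaminated each other. `tnseqr` computes all of these, and
ships a synthetic-data generator that makes every stage testable without
touching external data.

## The statistics at the core

* **Molecule counting.** Reads collapse to molecules by (fragment span,
  strand, UMI), merging UMIs at Hamming distance 1 under the directional
  rule `count(a) >= 2·count(b) − 1`.
* **Peak calling.** For each 200-nt window with pileup `k`, the p-value
  is the Poisson upper tail `P(X >= k)` with `X ~ Pois(λ_local)`,
  `λ_local = max(λ_genome, λ_5kb, λ_10kb)`, Benjamini–Hochberg adjusted
  across all windows with peaks at `q ≤ 0.01`.
* **Differential enrichment.** Per gene, an exact conditional
  negative-binomial test: conditioned on the total count `t = x_start +
  x_end`, the two-sided p-value sums all splits of `t` no more likely
  than the observed one under NB noise with library-size-proportional
  means and a common method-of-moments dispersion (floored at 0.01). As
  dispersion → 0 this reduces to the binomial exact test, which the test
  suite uses as an independent oracle.
* **Barcode error correction.** Greedy abundance-ranked clustering at
  Hamming distance ≤ 2 to the cluster center; deterministic and
  read-conserving.

## A worked example

Simulate a pooled RB-Tn-Seq experiment (50-kb genome, 3 founder lineages
with 2 insertions each, 5,000 molecules per time point) and run the whole
pipeline:

```r
library(tnseqr)

config <- list(
  mode = "rbtnseq", seed = 7, outdir = "demo_out", enrichment = TRUE,
  simulate = list(
    genome_length = 50000, n_genes = 25,
    n_founders = 3, insertions_per_founder = 2,
    n_molecules = 5000,
    samples = list(list(sample = "start", time_point = 0),
                   list(sample = "end",   time_point = 1))
  )
)
res <- run_pipeline(config)

glance(res$spectra$start)
#> # A tibble: 1 × 4
#>   sample n_sites total_mapped n_off_ta_positions
#>   <chr>    <int>        <int>              <int>
#> 1 start        6         4998                  0
```

All 4,998 mapped molecules sit on exactly 6 TA sites — the 6 simulated
insertions, none off-target. Each one becomes a peak, annotated with its
nearest gene (distance 0 = inside the gene, negative = upstream):

```r
tibble::as_tibble(res$peaks$start)[, c(2:6, 8:10)]
#>   start   end summit pileup fold_enrichment        q nearest_gene distance
#> 1  1901  2200   2047    605           25    0        gene003             0
#> 2  7401  7700   7576   1602           25    0        gene007             0
#> 3 20601 20900  20718    664            9.75 0        gene013         -1171
#> 4 22001 22300  22198   1038           15.2  0        gene013             0
#> 5 24501 24800  24692   1003           12.3  0        gene015             0
#> 6 33801 34100  33916     86            4.30 3.46e-26 gene017          1112
```

No selection was simulated between the time points, and the differential
test correctly finds nothing (4 genes pass the combined-count filter of
128; all q ≈ 0.93):

```r
tidy(res$diff)
#>   gene_id count_start count_end log2_fold_change     p     q
#> 1 gene003         605       596          -0.0210 0.931 0.931
#> 2 gene007        1602      1561          -0.0368 0.862 0.931
#> 3 gene013        1038      1099           0.0829 0.700 0.931
#> 4 gene015        1003       985          -0.0255 0.908 0.931
```

Lineage demultiplexing recovers the three founder barcodes, each with its
dominant founder insertion site and the fraction of that lineage's
earliest-time-point molecules it holds:

```r
identify_founder(res$lineage)
#>   barcode              position fraction ambiguous_founder
#> 1 ATACCGCCCAAGGGGCCGTA    22198    0.632 FALSE
#> 2 CGAGTCTTATTGAAATCCGC     7576    0.949 FALSE
#> 3 GTGTGAGGTTCCATGGACAG    24692    0.602 FALSE
```

`autoplot()` works on spectra, peaks, and differential results;
`plot_lineage_traces()` draws per-lineage insertion spectra across time
points. A thin command-line wrapper lives at
`inst/scripts/tnseq-pipeline.R` (`--config config.yaml`, exit codes 0/2/3
for success/config error/data error).

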