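# rpkum

Mappability-aware pseudogene expression quantification and ceRNA screening
for short-read RNA-seq.

## Why

Pseudogenes are near-identical genomic copies of protein-coding genes. When
the expressed parent gene carries a couple of SNPs — or a read carries
base-call errors — reads from the parent can align *uniquely, but wrongly*
to the silent pseudogene. Naive unique-read counting then reports expression
for a locus that produced no RNA.

`rpkum` addresses this with three pieces:

1. **A discrete, mismatch-tolerant mappability track.** A genomic position
   is mappable at read length *k* and safety margin ε iff no other *k*-mer
   occurrence — at any other position, on either strand, or crossing any
   annotated splice junction (via *synthetic regions*) — lies within Hamming
   distance ε. With ε = 2, a read carrying up to two mismatches cannot be
   uniquely misplaced onto a mappable position. Defaults: *k* = 50, ε = 2.
2. **A read filter** that keeps only uniquely aligned reads starting at
   mappable positions (or spliced reads certified by a unique junction
   *k*-mer).
3. **RPKUM** — Reads Per Kilobase of Uniquely mappable transcript per
   Million reads:

   ```
   RPKUM = retained_reads × 10⁹ / (mappable_bases × total_reads)
   ```

   where `mappable_bases` replaces transcript length (so discarding reads
   over unmappable regions does not deflate expression; for fully mappable
   genes RPKUM = RPKM) and `total_reads` is the aligned library size before
   filtering. Genes with zero mappable bases are undefined (`NA`), and genes
   under 50 mappable bases are flagged unquantifiable.

Downstream, the package screens for **ceRNA** (competing endogenous RNA)
relationships: pseudo-3′ UTR annotation by local alignment against the
parent's 3′ UTR, canonical miRNA seed-site matching (8mer / 7mer-m8 /
7mer-A1 / 6mer), presence-filtered log-scale correlations with
permutation-based null models, BH correction, and
pseudogene–gene–miRNA triple identification.

A first-class synthetic-data module generates genomes with processed,
duplicated and unitary pseudogenes, subject SNPs, error-bearing reads with
exhaustive idealized alignments, and expression matrices with planted ceRNA
structure — every result in the test suite is reproduced from seeds, with
no stored fixtures.

## Worked example

The built-in `fig1a_scenario()` constructs the textbook failure mode: a
gene and its pseudogene differ at one base; the subject genome's gene
carries three clustered SNPs, one of which matches the pseudogene. Reads
covering all three SNPs align uniquely — and wrongly — to the pseudogene.

```r
library(rpkum)

fx <- fig1a_scenario(seed = 1)

# naive unique-read counting misattributes reads to the silent pseudogene
count_reads_naive(fx$records, fx$models)
#> GENE1  PSG1
#>     0    46

# the mappability track at the read length
track <- compute_mappability(fx$genome, k = 50, epsilon = 2)
track
#> MappabilityTrack k=50 epsilon=2: 1 chrom(s), 2441/2951 start positions mappable, 0 synthetic region(s)

# gene and pseudogene are everywhere within Hamming distance 1 of each
# other, so the whole locus is unmappable at epsilon = 2 and every
# misaligned read is discarded
filtered <- filter_reads(fx$records, track, fx$models, sample_id = "s1")
filtered
#> MappableReadSet 's1': 251 reads; retained 0, multi 205, unmappable 46, non-genic 0

base_counts <- lapply(fx$models, function(m)
  count_mappable_bases(build_consensus_model(m), track))
em <- build_expression_matrix(list(filtered), base_counts)
em$rpkum
#>       s1
#> GENE1  0
#> PSG1   0
```

The pseudogene's expression is exactly zero after filtering — and the
per-read ledger (`retained + multi + unmappable + nongenic`) always sums to
the total, so no read is silently lost.

How reliable is RPKUM when only a sliver of a gene is mappable?

```r
rpkum_robustness_simulation(n_genes = 1000, seed = 1)
#>     m spearman_rho
#> 1  50    0.9489523
#> 2 100    0.9746307
#> 3 500    0.9942844
```

Even with only 50 mappable bases per 1 kb gene, RPKUM rank-tracks true
expression at ρ ≈ 0.95, rising to ≈ 0.99 at 500 bases.

## Pipeline interface

Each stage is an exported function taking a config list (or JSON/YAML
path) and writing outputs plus a manifest (config echo + input MD5s):

```r
cmd_simulate(list(scenario = "genome", seed = 1, out_dir = "sim"))
cmd_mappability(list(genome = "sim/genome.fa", annotations = "sim/annotations.gtf",
                     k = 50, epsilon = 2, out_dir = "mapp"))
cmd_quantify(list(genome = "sim/genome.fa", annotations = "sim/annotations.gtf",
                  alignments = list(s1 = "sim/alignments.tsv"),
                  mappability_dir = "mapp", out_dir = "quant"))
cmd_cerna(list(pseudogene_matrix = "...", gene_matrix = "...",
               mirna_matrix = "...", pairs = "...", shared = "...",
               n_permutations = 5000, seed = 1, out_dir = "cerna"))
```

A command-line wrapper with the same four subcommands is installed at
`system.file("scripts", "rpkum-cli.R", package = "rpkum")`.

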