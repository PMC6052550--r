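# tandemasm

A de novo assembler for short sequencing reads that restores **tandem
repeats longer than the read and insert length** — the repeats every
conventional de Bruijn assembler collapses to one or two copies.

## The problem

A tandem repeat is an array of a motif of length *d* repeated *m* times
back to back (total length *n ≈ m·d*). When *n* exceeds the read length,
all copies collapse onto the same k-mers, and the assembly graph contains a
loop that a paired-end assembler can only bridge if the insert size exceeds
*n*. Long arrays (e.g. a 31-bp motif repeated 13 times = 403 bp, longer
than a 300-bp insert) are therefore emitted once or twice instead of
*m* times — unless the assembler uses **read depth** as a copy counter,
which is what this package does.

## The model

Edges of the de Bruijn graph of dimension *k* are observed k-mers weighted
by their count *w* in the reads. For *N* error-free reads of length *L*
sampled uniformly from a circular genome of length *G*, a unique k-mer has
expected weight *N(L−k+1)/G*, and a k-mer inside a tandem array of length
*n* has expectation inflated by *Δ/d*, where *Δ = n−k+1*; the weight is
Poisson-distributed. Multiplying by the normalization factor

    p = G / (N(L−k+1)),       w' = ⌊p·w + 0.5⌋

turns read-space counts into per-genome copy numbers. For coverage
*c = NL/G ≥ 100* the normalized repeat weight is approximately
Normal(*Δ/d*, √(*Δ/d*)), and the depth required to resolve a copy number
with confidence *q* is

    c = k/(L−k+1) · (2·Φ⁻¹((1+q)/2))² · Δ/d

(`required_coverage()`). In the normalized graph a tandem array appears as
a loop attached to the rest of the graph by exactly one in-edge and one
out-edge; the pipeline equalizes each loop branch to its median weight,
balances the branches so every loop vertex has in-weight = out-weight
(signed degree 0), and then generates contigs by a weight-consuming
traversal that re-enters the loop while its back edge has weight left —
spelling the motif out exactly *m* times.

Pipeline: `count_kmers → build_graph → clean (low-weight / tips / bubbles)
→ normalize_graph → resolve_all → generate_contigs`, wrapped by
`assemble()`.

## Worked example: the 4-mer toy graph

Three reads whose 4-mers form a graph with a 3-fold `GAC` loop
(`inst/extdata/worked_reads.fasta`):

```r
library(tandemasm)
rs  <- read_sequences(system.file("extdata", "worked_reads.fasta",
                                  package = "tandemasm"))
res <- assemble(rs, k = 4, single_strand = TRUE, normalize = FALSE,
                resolve_repeats = FALSE, clean = FALSE)
res$contigs
#> [1] "CCAT"          "TTTCCC"        "CATGGGAG"      "CATTAACCC"
#> [5] "CCCGACGACGACT"
```

`CAT` and `CCC` are ambiguous junctions (contigs end there);
`CCCGACGACGACT` spells the `GAC` motif three times because the loop edges
carried weights 3/2/2 and the traversal preferred the loop-back edge until
its weight was consumed.

## Worked example: restoring a 1500-bp array from 100-bp reads

```r
ref   <- make_reference(repeat_spec(300, 5), spacer_length = 1000,
                        circular = TRUE, seed = 7)       # 3500-bp genome
reads <- simulate_reads(ref, read_sim_params(read_length = 100,
           coverage = 150, insert_mean = 250, insert_std = 25,
           substitution_rate = 0.01, seed = 7))
res   <- assemble(reads$mate1, reads$mate2, k = 55,
                  genome_size = nchar(ref$sequence))
res
#> assembly: 5 contig(s), N50 = 3554 bp, longest = 3554 bp
res$loop_report[1, c("body_len", "back_len", "body_post", "back_post")]
#>   body_len back_len body_post back_post
#> 1      246       54         5         4
score_assembly(res, ref)$per_array
#>   motif_length expected recovered
#> 1          300        5         5
```

The 300-bp motif is restored 5 times from 100-bp single reads although the
array (1500 bp) is six times the insert size: the balanced loop carries
body weight 5 and back weight 4. (The extra small contigs are residual
error fragments on the opposite strand.)

## Coverage planning

```r
required_coverage_table(0.95, k = 55, L = 100, n_values = c(200, 500),
                        d_values = 100)
#>     n   d coverage
#> 1 200 100    26.82
#> 2 500 100    81.94
```

## Command line

```sh
Rscript inst/scripts/tandemasm simulate-ref --specs 300:5 --spacer 1000 \
    --circular --seed 7 --out ref.fasta --truth-out truth.tsv
Rscript inst/scripts/tandemasm simulate-reads --ref ref.fasta --circular \
    --coverage 150 --seed 7 --out1 r1.fastq --out2 r2.fastq
Rscript inst/scripts/tandemasm assemble --reads r1.fastq --reads2 r2.fastq \
    --k 55 --genome-size 3500 --out contigs.fasta
Rscript inst/scripts/tandemasm evaluate-repeats --contigs contigs.fasta \
    --truth truth.tsv
Rscript inst/scripts/tandemasm required-coverage --q 0.95 --k 55 \
    --read-length 100 --repeat-length 200,500 --motif-length 100
```

All flags can also be given in a `key = value` config file (`--config`);
explicit flags win.

## Limitations

- Unitig mode only: no paired-end scaffolding or gap filling.
- Exact-match repeat evaluation (no fuzzy motif detection).
- Interspersed repeat families (same motif recurring elsewhere in the
  genome) violate the loop degree pattern and are left unresolved.
- The copy-number model needs high, uniform coverage (warns below 100×).

See `vignettes/tandem-repeat-assembly.Rmd` for the methods account.
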