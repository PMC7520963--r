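# plastaudit

Quantitative evaluation of chloroplast (plastid) genome assemblies.

Chloroplast genomes are circular molecules of roughly 120–160 kbp with a
quadripartite architecture: two identical, oppositely oriented inverted
repeats (IRa, IRb) separating a large (LSC) and a small (SSC)
single-copy region. Short-read assemblers fail on them in recurring
ways — fragmented output, unresolved or duplicated repeats, flipped SSC,
arbitrary start point — and `plastaudit` exists to measure those
failures. It is aimed at anyone benchmarking organelle assemblers or
quality-checking a freshly assembled plastome.

## The score

An assembly is aligned against its reference in both directions and
scored on a 0–100 scale, each of four terms contributing up to 25
points:

```
score = 25 · ( cov_ref + cov_qry + min(cov_qry/cov_ref, cov_ref/cov_qry) + 1/n_contigs )
```

* `cov_ref` — completeness: fraction of reference bases covered by the
  assembly;
* `cov_qry` — correctness: fraction of assembly bases covered by the
  reference;
* the ratio term — repeat resolution: penalises size mismatch, e.g. a
  surplus genome copy;
* `1/n_contigs` — continuity: full marks only for a single contig.

Coverage counts **primary alignments only** (minimap2's `tp:A:P` tag, or
the built-in exact aligner's per-base assignment), which is what lets
the ratio term see duplications. With a reference, success is a score
≥ 99. Without one, success means a single contig of ≥ 130 kbp carrying
an inverted repeat of ≥ 17 kbp; `select_cutoffs()` reproduces the
F1-maximising grid search behind those constants.

The package also ships a synthetic quadripartite plastome generator
with controlled failure-mode variants, a perfect paired-read simulator
(sliding windows, genome:chloroplast mixture ratios, exact
subsampling), inverted-repeat / structure detection, and canonical
rotation of circular assemblies.

## Worked example

```r
library(plastaudit)

p <- make_plastome(seed = 1)     # 80 kb LSC + 20 kb IRa + 15 kb SSC + 20 kb IRb
tidy(find_ir(p$genome))
#> # A tibble: 4 × 4
#>   region  start    end length
#>   <chr>   <dbl>  <dbl>  <dbl>
#> 1 lsc         0  80000  80000
#> 2 ira     80000 100000  20000
#> 3 ssc    100000 115000  15000
#> 4 irb    115000 135000  20000

# an assembly with an unresolved duplication, scored against the reference
dup <- make_variant(p$genome, "tandem_duplicate")
score_assembly(dup, p$genome)
#> Assembly score: 75.00 / 100
#>   completeness (cov_ref):    1.0000
#>   correctness  (cov_qry):    0.5000
#>   repeat resolution:         0.5000
#>   continuity (1/1 contigs):  1.0000

# an SSC flip is a valid presentation of the same molecule: full score
flip <- make_variant(p$genome, "flip_ssc", structure = p$structure)
score_assembly(flip, p$genome)$score
#> [1] 100

classify_novel_mode(p$genome)   # reference-free success check
#> # A tibble: 1 × 6
#>   mode  success reasons    n_contigs total_len ir_len
#>   <chr> <lgl>   <list>         <int>     <int>  <dbl>
#> 1 novel TRUE    <chr [0]>          1    135000  20000
```

The duplication keeps the reference fully covered (`cov_ref = 1`) but
only half the assembly is covered by the reference under primary-only
counting (`cov_qry = 0.5`), so both the correctness and the repeat
term drop and the score lands at 75.00. The flipped-SSC variant aligns
completely in both directions and loses nothing.

A command-line wrapper over the same functions is installed at
`inst/cli/plastaudit` (subcommands `synth`, `simulate`, `score`,
`structure`, `rotate`, `classify`, `calibrate`, `consistency`).

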