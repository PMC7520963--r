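---
title: "Evaluating chloroplast genome assemblies with plastaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating chloroplast genome assemblies with plastaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastaudit)
```

## The problem

Chloroplast genomes (plastomes) are small circular molecules, typically
120--160 kbp, with a characteristic quadripartite architecture: two
identical but oppositely oriented inverted repeats (IRa, IRb), anywhere
from roughly 10 to 76 kbp long, separate a large (LSC) and a small (SSC)
single-copy region. The IRs are longer than short sequencing reads, so
short-read assemblers routinely fail on plastomes in characteristic
ways: they emit several contigs, collapse or duplicate the repeat,
flip the SSC, or start the circle at an arbitrary position. Judging
whether an assembly is "good" therefore needs more than an N50.

`plastaudit` packages a complete evaluation workflow: a composite 0--100
score against a reference, structure detection and canonical rotation
for circular assemblies, success classification with and without a
reference, and a perfect-read simulator plus a synthetic plastome
generator so that every part of the pipeline can be exercised and tested
without any external data.

## The composite score

An assembly is compared with its reference through pairwise alignment in
both directions. Four terms, each worth up to 25 points, enter the
score:

$$
\mathrm{score} \;=\; \frac{100}{4}\left(
\mathrm{cov}_{ref} + \mathrm{cov}_{qry} +
\min\!\left\{\frac{\mathrm{cov}_{qry}}{\mathrm{cov}_{ref}},
             \frac{\mathrm{cov}_{ref}}{\mathrm{cov}_{qry}}\right\}
+ \frac{1}{n_{contigs}}\right)
$$

* **Completeness** ($\mathrm{cov}_{ref}$): the fraction of reference
  bases covered when the assembly is mapped onto the reference.
* **Correctness** ($\mathrm{cov}_{qry}$): the fraction of assembly bases
  covered when the reference is mapped onto the assembly.
* **Repeat resolution**: the smaller of the two coverage ratios. It
  penalises size mismatch between assembly and reference -- an assembly
  that carries the genome twice has $\mathrm{cov}_{qry} = 0.5$ and loses
  repeat-resolution points.
* **Continuity**: $1/n_{contigs}$; only a single-contig assembly gets
  the full quarter.

A score of 100 therefore requires a single contig that covers, and is
covered by, the reference completely. When either coverage is zero the
repeat term is defined as zero rather than raising an error, so a failed
mapping still yields a finite (low) score and batch summaries stay
computable.

Scores are reported to two decimals; full precision is kept internally.

### Coverage semantics

Both coverage fractions are interval unions of *primary* alignments
only. This is deliberate: if secondary alignments counted, an assembly
containing two copies of the genome would still have
$\mathrm{cov}_{qry} = 1$ and the repeat term could never see the surplus.
With an external aligner (minimap2 writes PAF), primariness is taken from
the `tp:A:` tag. The built-in aligner (`exact_anchor_align()`) assigns
each query base to at most one alignment block itself: maximal exact
match blocks on both strands are seeded from shared k-mers, collapsed per
diagonal, grouped into colinear chains (same strand and diagonal), and
chains are selected greedily by total matched length, trimming each block
to the query intervals not yet claimed. Trimming an exact match is
coordinate-safe on both sides, so primary records never overlap on the
query.

The built-in aligner does no gapped extension. It is complete for
assemblies that are exact rotations, fragments, rearrangements,
duplications, strand flips or SSC flips of the reference -- which is
exactly the space the synthetic test bed generates -- and it is *not* a
general-purpose aligner for diverged real sequences. For real data,
supply minimap2 PAF files for the two directions instead
(`score_assembly(..., aln_ref = parse_paf(...), aln_qry = parse_paf(...))`).

The reference is treated as linear during coverage: an assembly opened
at a different origin aligns as two blocks whose union still covers
everything, so rotation costs no points, as it should not for a circular
molecule.

## Structure detection and canonical rotation

`find_ir()` looks for the maximal pair of disjoint blocks on the circle
such that one is the reverse complement of the other. The search seeds
k-mer matches (default k = 31) between the doubled sequence and its
doubled reverse complement, so blocks spanning the origin are found and
the result is independent of where the circle was opened. Equal-length
candidates are tied broken by smallest start coordinate, making the
result deterministic. The IR model is exact-match: the synthetic test
bed plants exact repeats, and degraded real repeats are out of scope for
the default mode.

The single-copy gaps between the two repeat copies become LSC (the
longer gap) and SSC (the shorter); IRa is defined as the copy
immediately following the LSC. `canonicalize()` then rewrites the
molecule as `LSC + IRa + SSC + IRb` starting at the first LSC base.
Because a circular sequence has no intrinsic strand and the SSC
orientation is itself a biologically valid degree of freedom, four
equivalent presentations remain; the lexicographically smallest is
chosen. There is no community-standard definition of "the" canonical
plastome orientation, so lexicographic choice is our deterministic
stand-in; it guarantees that rotations, global reverse complements and
SSC flips of the same molecule all canonicalize to the identical string,
and that the function is idempotent.

```{r structure-example, eval = FALSE}
p <- make_plastome(seed = 1) # 80 kb LSC + 20 kb IRs + 15 kb SSC
tidy(find_ir(p$genome))
canonicalize(p$genome)
```

## Success classification

With a reference, success is a score of at least 99 (inclusive). Without
one, an assembly counts as successful when it is a single contig of at
least 130 kbp carrying an inverted repeat of at least 17 kbp; both
thresholds are inclusive, and the contig is treated as circular for the
IR scan. `select_cutoffs()` reproduces the calibration procedure behind
those two constants: given per-assembly features labelled with a truth
flag, it grid-searches all (length, IR) cutoff pairs and returns the
F1-maximising pair. The default grids span 100--160 kbp in 1 kbp steps
and 10--30 kbp in 0.5 kbp steps, bracketing reported plastome and IR
sizes; ties break towards the smaller cutoffs so the least restrictive
optimum is preferred. The grid search consumes precomputed features
(`n_contigs`, `total_len`, `ir_len`) rather than raw FASTA, so IR
detection runs once per assembly, not once per grid point.

## The synthetic test bed

`make_plastome()` generates the study conditions for every synthetic
check: a circular `LSC + IRa + SSC + IRb` sequence whose planted repeat
is provably the unique answer. Three measures guarantee that:

* single-copy DNA is uniform random, rejection-sampled so that no
  incidental inverted repeat of 32 bp or more exists anywhere outside
  the planted pair (any repeat that long must share a 32-mer with the
  reverse-complement k-mer set, which is how the screen detects it);
* the bases flanking the IR copies are adjusted so the planted pair
  cannot be extended by chance;
* the default region sizes (80 kb LSC, 20 kb IRs, 15 kb SSC; 135 kb
  total) sit comfortably above both reference-free cutoffs, so boundary
  tests perturb downward from a known-good fixture.

`make_variant()` derives the failure modes real assemblers show:
rotation and reverse complement (score 100 -- valid presentations),
SSC flip (score 100 -- biologically valid), fragmentation (continuity
loss), tandem duplication (repeat-resolution loss, score 75), and
region deletion (completeness loss proportional to the deleted
fraction).

What the generator does **not** emulate: real gene content, GC skew,
codon structure, sequencing error, heteroplasmy, or diverged repeats.
Passing tests demonstrate that the scoring, detection and
canonicalization machinery is correct on exact structural variants; they
do not certify aligner behaviour on biologically diverged sequences --
that is what the external-PAF route is for.

## The read simulator

`simulate_component()` emits perfect, error-free read pairs:
fragments of `fragment_len` (default `2 * read_len`, so the mates tile
the fragment exactly) are placed at evenly spaced starts, the forward
read is the fragment's first `read_len` bases and the reverse read the
reverse complement of its last `read_len`. The number of fragments is
`round(coverage * n / (2 * read_len))`; when it exceeds the number of
distinct start positions, full passes at step 1 are made and the
remainder is spread evenly. This even-spacing schedule was chosen over a
fixed integer step because it realizes the requested coverage within one
fragment's worth of bases for *every* coverage value and for linear as
well as circular sequences (a fixed step loses a fragment-length's worth
of starts at each linear edge and drifts whenever the step rounds).
Plastid sequences are circular, so windows wrap the origin; nuclear and
mitochondrial components are linear by default.

`simulate_mixture()` mixes components at a genome:chloroplast coverage
ratio `(g, c)`: nuclear at `30g`, mitochondrial at `300g`, plastid at
`30c`, reflecting a fixed background sequenced at 30x genome / 300x
mitochondrion with varying plastid enrichment (the standard series is
`0:1`, `1:10`, `1:100`, `1:1000`; `1:100` implies 3000x plastid). The
ratio could alternatively be read as a read-count ratio; the coverage
reading is the default because the background coverages are stated as
fixed while only enrichment varies, and arbitrary numeric ratios are
accepted for anything else. Qualities are constant Phred 40: the reads
are perfect by construction, and no error model is in scope. Read names
encode `component:fragment_start:pass`, so downstream evaluation can
compute per-origin coverage by counting, without any alignment
(`realized_coverage()`).

All randomness (mixture shuffling, subsampling) is driven by explicit
seeds; a fixed spec and seed reproduces FASTQ output byte for byte.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (PAF's native
  convention); region tables and structure maps use the same convention.
* Sequences are normalised on ingest: uppercase, `U` to `T`, other
  IUPAC ambiguity codes to `N` with a warning (the alignment and IR
  machinery assume a 5-letter alphabet).
* FASTQ pairing is positional: record *i* of `forward.fq` mates record
  *i* of `reverse.fq`; `/1`/`/2` suffixes are ignored.
* The consistency comparison treats two scores within 0.01 (one
  reporting unit, inclusive) as identical.
* Degenerate inputs: zero coverage in the score's repeat term gives 0;
  precision/recall with empty denominators give 0; `find_ir()` returns
  `NULL` (not an error) when no repeat reaches the cutoff.

## Problem sizes used in the test suite

The package's own tests run the full pipeline at the study's stated
sizes where that is the point of the check -- a 135 kb plastome scored
against itself, a 200 kb / 50 kb / 135 kb mixture at ratio 1:10, a
2,000,000-pair subsample, and reference-free boundary cases at exactly
130,000 bp and 17,000 bp -- and scale down to 1--15 kb fixtures for
property sweeps (IR detection vs brute force, per-base coverage oracles,
canonicalization group invariance), where hundreds of cases matter more
than size.

## Limitations

* The exact-match IR model will underestimate repeats that have diverged
  between their two copies; a tolerance mode would need gapped anchors.
* The built-in aligner is not a substitute for minimap2 on real,
  diverged assemblies; it exists so the pipeline is self-contained and
  exactly analysable on synthetic inputs.
* Gene-anchored orientation (placing particular genes at conventional
  positions) requires annotation and is out of scope; canonical
  orientation here is purely sequence-defined.
* `|LSC| = |SSC|` ties in region labelling are resolved arbitrarily but
  deterministically; real plastomes do not hit this case.
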