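# polishr

Repeat-aware short-read polishing of long-read bacterial genome
assemblies, in R.

## The problem

Long-read-only assemblies of bacterial genomes are structurally complete
but usually retain hundreds of small-scale errors, mostly
homopolymer-length indels. Short reads can fix these, but conventional
polishers consume *best-hit* alignments: each read is placed at the
single location where it aligns best. When one copy of a genomic repeat
contains an error and another copy does not, reads systematically prefer
the error-free copy, the erroneous copy is starved of coverage, and the
error survives polishing.

polishr consumes alignments made in **all-alignments-per-read** mode
(e.g. `bwa mem -a`) instead. Every read contributes evidence at *every*
location it fits, so errors inside repeats stay covered.

## The algorithm

For each assembly position the package builds a pileup of read
**pieces** — the read content a covering alignment attributes to that
position: one base (match or substitution), an empty piece (the read
says this base is deleted), or a base plus following inserted bases.
Two details matter:

* **Homopolymer end trimming.** An alignment that ends inside a
  homopolymer run cannot attest the run's full length, so each
  alignment's end is trimmed: the terminal run of identical read bases,
  plus one more base (always ≥ 2 bases).
* **Fractional depth.** A read with *k* alignments adds 1/*k* to the
  depth of each covered position, approximating conventional best-hit
  depth, while piece **counts stay raw integers** — inside a collapsed
  repeat the counts carry full-strength evidence from every copy.

A position with fractional depth *d* is changed only under a
conservative rule. With

```
T_valid   = max(min_depth, fraction_valid * d)     (defaults: 5, 0.5)
T_invalid = fraction_invalid * d                   (default: 0.2)
```

a piece is *valid* when its count > `T_valid` and *invalid* when its
count < `T_invalid` (both strict). The base is replaced only when
exactly one valid piece exists, it differs from the current base, and
every other observed piece is invalid. Counts between the thresholds
(the "dead zone") block any change, which is why the polisher almost
never introduces errors.

The package also ships a self-contained fixture simulator — random
genomes with planted exact repeats, calibrated error injection
(substitutions, homopolymer indels and other indels at 0.01% per class
by default), error-free read tiling, and an exhaustive edit-distance
aligner that writes SAM in all-per-read or best-only mode — plus
reference-based assessment: global-alignment error counts, identity and
Phred Q-scores (`Q = -10 log10(1 - identity)`), read-based repeat
annotation, and polishing confusion matrices (TP/TN/FP/FN per genome
position).

## Worked example

Simulate a 20 kbp genome with a two-copy 1 kbp repeat, plant seven
errors in it, tile the clean genome with error-free 150 bp reads at
40×, align them exhaustively in all-per-read mode, and polish:

```r
library(polishr)

g     <- make_genome(20000, repeat_length = 1000, repeat_copies = 2, seed = 5)
inj   <- inject_errors(g$assembly, error_profile(seed = 7),
                       counts = c(sub = 3, hp_ins = 1, hp_del = 1,
                                  other_ins = 1, other_del = 1))
reads <- simulate_reads(g$assembly, 150, depth = 40, seed = 11)
aln   <- exhaustive_align(reads, inj$assembly, max_edits = 5,
                          mode = "all", seed = 3)
sam <- tempfile(fileext = ".sam")
write_sam(aln, inj$assembly, sam)

res <- polish_round(inj$assembly, sam)
#> chromosome: 3 substitution(s), 2 insertion(s), 2 deletion(s)
res$changes
#>        contig   pos    old    new depth count        class
#> 1: chromosome  1034      A     AC    36    35    insertion
#> 2: chromosome  3382      C           44    44     deletion
#> 3: chromosome  4571      T      G    34    34 substitution
#> 4: chromosome  7582      G      A    31    31 substitution
#> 5: chromosome  9891      T           43    43     deletion
#> 6: chromosome 14325      A     AC    45    45    insertion
#> 7: chromosome 15974      C      G    44    44 substitution
```

Each row is one applied edit in pre-polish coordinates: at position
3382 the reads unanimously (count 44 of depth 44) indicate that the
assembly base `C` is an insertion error, so it is deleted; at 1034 they
indicate a missing base, restored as the piece `AC`. Assessing the
polished sequence against the truth, and classifying the polisher's
effect per position:

```r
assess(res$assembly, g$assembly)
#> errors: 0  identity: 1.000000  Q-inf (capped)
#>   by type: 0 substitution, 0 insertion, 0 deletion
confusion(g$assembly, inj$assembly, res$assembly)
#> TP 7 (fixed)  TN 19993 (kept correct)  FP 0 (introduced)  FN 0 (missed)
```

All seven planted errors were fixed and none introduced.

Command-line wrappers over the same functions live in `inst/cli/`
(`polish.R` for one polishing round, `eval.R` for
assess/repeats/confusion); multiple polishing rounds are performed by
realigning reads to each round's output and re-running.

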