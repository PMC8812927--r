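---
title: "Methods: repeat-aware short-read polishing and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware short-read polishing and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polishr)
```

## The polishing model

polishr corrects small-scale errors (substitutions and short indels,
overwhelmingly homopolymer-length indels) in a haploid bacterial
assembly using short-read alignments produced in
all-alignments-per-read mode. Its premise: best-hit alignment starves
erroneous repeat copies of coverage, because an error-free copy of the
same repeat always wins the placement. When every alignment of every
read is reported instead, the erroneous copy stays covered, and the
reads covering it — whichever copy they were actually sequenced from —
agree on the correct base wherever the repeat copies are identical in
the true genome.

### Pileup construction

Each alignment is expanded into per-position *pieces*: `M`/`=`/`X`
CIGAR ops yield one base per reference position, `I` appends its bases
to the piece of the preceding reference position, `D` yields empty
pieces, and clips contribute nothing. Two conventions are worth
stating:

* An insertion before the first reference-consuming op is discarded.
  The alternative — attaching it to the previous assembly position,
  outside the alignment — would attribute read content to a position
  the aligner never claimed to cover; alignments produced by the
  built-in simulator never emit such CIGARs, so the choice only matters
  for imported SAM.
* `=`/`X` are folded into `M`; the pileup re-derives agreement from the
  sequences themselves. The `N` op (intron skip) is rejected: it has no
  meaning for short reads on bacterial assemblies.

**End trimming.** An alignment that stops inside a homopolymer run
cannot attest the run's true length: a read ending in `...GAA` aligned
over `GAAA` is consistent with runs of length 2, 3 or 4. Each
alignment therefore drops its terminal run of identical bases plus one
more base (at least 2 bases, up to the whole alignment). Positions are
dropped from the first one whose piece uses any trimmed read base, so
trailing deletion pieces adjacent to the trimmed region fall too —
otherwise a deletion signal would survive that the trimmed bases can no
longer support. The trim is computed on the clip-stripped sequence in
alignment (reference-forward) orientation, because it is the
*alignment's* end that is ambiguous, not the sequencing read's.

The default trims only the alignment end (`trim_mode = "end_only"`).
The homopolymer-ambiguity argument applies symmetrically at the
alignment start, so `"both_ends"` is available as a documented option;
the default follows the established single-end behaviour, and on the
package's own fixtures the two modes give identical polishing results
(error-free reads at moderate depth leave ample interior evidence).

**Counts versus depth.** A read aligned to *k* locations contributes a
full integer count of 1 to each piece it stacks at each location, but
only 1/*k* units of read depth. This asymmetry is load-bearing. Depth
must approximate conventional best-hit depth, or the thresholds below
would double inside two-copy repeats and nothing would pass them.
Counts must stay raw, or evidence inside repeats would be halved and
the valid threshold would become unreachable exactly where the
all-per-read strategy is supposed to help. Whether counts should also
be down-weighted is genuinely open; raw counts are what makes the
repeat-repair mechanism work, and the zero-introduction guarantee does
not depend on the choice.

### The change rule

At a position with fractional depth $d$, with defaults in parentheses:

$$T_\mathrm{valid} = \max(\texttt{min\_depth},\ \texttt{fraction\_valid}\cdot d)
\qquad (5,\ 0.5)$$
$$T_\mathrm{invalid} = \texttt{fraction\_invalid}\cdot d \qquad (0.2)$$

A piece is *valid* iff its count strictly exceeds $T_\mathrm{valid}$,
*invalid* iff strictly below $T_\mathrm{invalid}$. The base is replaced
iff exactly one valid piece exists, it differs from the current base,
and every other observed piece is invalid. Both comparisons are strict,
so ties land in the dead zone between the thresholds and block the
change: conservatism is built into the boundary cases, which the test
suite probes exhaustively at depths 5, 8, 10 and 20. `min_depth` (units:
read-depth; default 5) exists so that a handful of reads can never force
a change at low coverage; `fraction_valid` and `fraction_invalid` are
fractions of local depth, constrained to
$0 < \texttt{fraction\_invalid} \le \texttt{fraction\_valid} \le 1$.

Positions with zero depth have no pieces, cannot satisfy the rule, and
keep their base. One invocation performs one polishing round; repeated
rounds require realignment to the new output, and on fixtures with
unambiguous evidence the second round makes zero changes (verified in
the acceptance tests).

### Degenerate inputs

Reads whose every record lacks a sequence are dropped and tallied,
never fatal. Secondary records with `*` sequences inherit a same-group
sequence, reverse-complemented when strands differ; a filled sequence
inconsistent with the record's CIGAR drops that record. An empty SAM
produces zero changes and a warning. Supplementary (chimeric) records
are excluded by default — split alignments complicate piece extraction
and are rare in short reads — with a flag to include them. Ambiguity
codes in input FASTA are replaced by seeded random bases at load, so
downstream arithmetic sees a strict A/C/G/T alphabet and runs are
reproducible.

## What the simulator emulates, and what it does not

The fixture generator exists so that every claim above is testable
without downloads or external binaries.

* `make_genome()` draws i.i.d. uniform sequence and plants
  character-identical copies of one segment at non-overlapping recorded
  positions. Real bacterial genomes have compositional bias, tandem and
  nested repeats, and mobile elements at varying identity; planted
  exact repeats isolate the one property the polisher exploits —
  cross-copy alignability.
* `inject_errors()` plants the four error classes at 0.01% per class by
  default, the rate used to degrade assemblies to roughly Q30. Per-class
  totals are drawn Binomial(L, rate) genome-wide and placed uniformly on
  the class's eligible sites (homopolymer runs of ≥ 2 for homopolymer
  classes, non-run positions for other indels), rather than by
  per-position coin flips on eligible sites only — the latter would
  silently scale each class's realised rate by the fraction of eligible
  positions (~44% for homopolymer context in random sequence). Planted
  positions are kept ≥ 2 bp apart so each error is an independent,
  unambiguous column. Real long-read assemblies instead cluster errors
  in long homopolymers and low-complexity regions.
* `simulate_reads()` tiles error-free, fixed-length reads uniformly.
  Real short reads carry sequencing errors, quality gradients, coverage
  bias and adapter artefacts; none of these are modelled, because the
  repeat-starvation phenomenon and the change rule do not require read
  errors. A passing test suite therefore demonstrates algorithmic
  correctness on clean evidence, not robustness to real library
  artefacts (the `max_errors` NM filter is the hook for noisy data).
* `exhaustive_align()` reports *every* end-to-end placement within an
  edit budget (default ≤ 5). Candidates come from pigeonhole k-mer
  seeding — an alignment with ≤ e edits leaves at least one of e+1
  non-overlapping k-mers exact, with k = min(31, ⌊L/(e+1)⌋) — and are
  verified by an infix dynamic program over a ±e-padded window, which
  also collapses overlapping placements at one locus to the single best
  (mimicking the one-hit-per-locus behaviour of real aligners). In
  `"all"` mode the lowest-distance hit becomes primary (ties broken by
  a seeded RNG, as real aligners break them randomly) and the rest
  secondary with `*` sequences; `"best_only"` keeps the primary alone.
  Unlike a production aligner it does no clipping or affine gaps and
  has a hard edit cap — appropriate for fixtures, not for real reads.

## Assessment conventions

`global_align()` is a unit-cost Needleman–Wunsch with an expanding band:
a banded pass with half-width B is exact whenever its reported distance
is ≤ B (the optimal path then fits in the band), so the band doubles
from 32 until that holds. Traceback tie-breaks prefer match >
substitution > deletion > insertion, giving deterministic column labels.
The error count is the number of non-match columns; identity is matches
over alignment length; `Q = -10·log10(1 - identity)`, with identity 1
printed as Q-inf and reported numerically at a configurable cap
(default 90).

Repeat annotation is operational: deep error-free reads (150 bp, 300×
by default) are aligned in all-per-read mode, and every position
covered by a read with ≥ 2 alignments is marked, then merged into
intervals. The edit budget (default 2) sets how diverged two repeat
copies may be and still count as one repeat.

The confusion matrix projects the unpolished and polished sequences
onto reference coordinates via pairwise global alignment and classifies
each reference position (fixed / kept-correct / introduced / missed).
Indel columns need a position convention: insertions attach to their
left-anchoring reference base (clamped to position 0), deletions to the
deleted base. A whole-genome three-way multiple alignment would remove
the need for projection but would add an external dependency; on
substitution-only inputs the two agree exactly (tp + fn equals the
unpolished error count, asserted over randomised toys), and the
left-anchor convention is pinned by hand-computed indel cases.

## Numerical and scale choices

Depth accumulates 1/k in double precision; the conservation identity
(total depth = Σ retained positions / k) is asserted to 1e-9. Piece
counts are exact integers. The acceptance checks run at sizes chosen to
exercise every mechanism while keeping the whole suite in minutes on
one core: a 100 kbp genome at 50× for zero-introduction, a 50 kbp
genome with a 2 kbp two-copy repeat and twelve planted errors for
repeat repair and convergence, 1 Mbp genomes for injector calibration
(per-class counts within 4σ of the Binomial mean of 100), and ≤ 5 kbp
fixtures for brute-force pileup cross-checks. Bacterial chromosomes are
40–100× larger than these fixtures; nothing in the implementation is
quadratic in genome length except the global aligner's band width in
the number of *errors*, so the scale-up is routine.

## Known limitations

* `inject_errors()` handles one contig at a time (plasmid-bearing
  fixtures need per-contig calls).
* SAM text only — no BAM/CRAM, no sorted/indexed access; bacterial-scale
  whole-contig arrays make streaming unnecessary.
* No base-quality weighting and no mate-pair concordance checks;
  pairing information is carried but unused by the change rule.
* Haploid assumption throughout: a heterozygous site would present two
  strong pieces and (correctly, for bacteria) fall in the dead zone.
* The exhaustive aligner is for fixture construction and oracle duty;
  real data should be aligned with a production aligner in
  all-alignments-per-read mode and imported as SAM.
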