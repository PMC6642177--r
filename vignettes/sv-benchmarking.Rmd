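---
title: "Benchmarking structural variant callers with svbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking structural variant callers with svbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbench)
```

## The problem

Structural variant (SV) callers disagree wildly, and deciding whether a
reported deletion, insertion, inversion, duplication or translocation is
"the same event" as a truth-set entry is itself a modelling decision. Two
callers describing one biological rearrangement rarely report identical
coordinates: paired-end evidence localises a junction only to within the
library fragment size, and micro-homology at the junction makes the exact
breakpoint position genuinely ambiguous — any placement within the
homologous run produces the same alternate sequence. svbench implements a
breakpoint-level benchmarking methodology built around these two sources of
uncertainty, together with a simulator that produces genomes with known
truth sets so the whole pipeline can be exercised and validated without any
external data.

## The matching model

Every VCF record is first reduced to one or more *breakpoints*: ordered
pairs of *breakends*. A breakend has a contig, a 1-based position, an
orientation (which side of the junction retains reference sequence) and a
closed ambiguity interval `[lo, hi]` covering the positions the caller
considers equivalent (populated from `CIPOS`/`CIEND` and homology-length
annotations, a point interval otherwise). A symbolic `<INV>` record
contributes its two constituent breakpoints, which are matched
independently; `BND` mate pairs are joined into a single breakpoint using
the VCF 4.2 bracket semantics.

A call matches a truth entry when

* both breakends lie within **200 bp** of the true positions — measured as
  the minimum distance between ambiguity intervals, so any position within
  the interval may satisfy the window — and
* the event sizes differ by at most **25%**, and
* breakend orientations agree (switchable off for callers that do not
  report orientation).

All bounds are inclusive; both thresholds are exposed as parameters of
`match_config()` with these defaults. The window absorbs positional error
of paired-end callers; the size tolerance prevents an unrelated small event
from matching a large one at a nearby locus (a 400 bp deletion call is
never matched with a 50 bp deletion — true under every denominator
convention, which is why the convention itself matters little; we default
to the symmetric `max(size_call, size_truth)` and expose the alternatives).

Matching is *coverage*-based and many-to-many: no one-to-one assignment is
computed. A call is a true positive if it matches at least one truth entry;
recall counts truth *components* — truth entries that mutually match (the
two haplotypes of a homozygous variant, or duplicates from merged truth
sets) are collapsed into connected components of the overlap graph, and the
component count is the recall denominator (`effective_truth_total()`).
Because calls are counted on one side and components on the other, the
evaluation is deliberately **not commutative**: swapping calls and truth
can change both precision and recall. The overlap graph is not transitive
(A may match B and B match C while A misses C), which is why connected
components, not cliques, are the duplicate-collapsing unit; this is our
reading of "adjusting the total", and it is the only choice that is
order-independent.

Calls with FILTER `PASS` or `.` form the PASS-only subset; all evaluations
are run on both the full and PASS-only call sets. Baseline filters remove
events under 50 bp (inclusive lower boundary: a 50 bp event is kept,
following the filter's phrasing "under 50 bp" literally) and, optionally,
inter-chromosomal calls.

## The simulator

`plan_simple_events()` places 500 events of each of 36 ladder sizes — 1 bp
to 65,536 bp, dense through the indel boundary and geometric above — for a
default total of 18,000 events per dataset, each dataset holding
heterozygous events of a single type. Events are separated by at least
2500 bp from each other and from any run of ambiguous `N` bases, so that no
two events interact within the matching window and no breakpoint is placed
in unalignable sequence. A ~133 Mb reference (the scale of a mid-sized
human chromosome) comfortably hosts the default load; the placement refuses
(with a capacity diagnostic, never silent truncation) when the reference is
too small. Positions are drawn by a left-to-right scan that spreads the
free slack uniformly across inter-event gaps; sizes are shuffled across
slots. Both choices are ours — only the ordering and the separation
constraint are inherent to the design.

`plan_translocations()` cuts the reference into consecutive 2500 bp
fragments and concatenates a seeded random sample of 10,000 of them;
every junction between non-originally-adjacent fragments is a truth
breakpoint. Fragments keep their original orientation (a design choice;
inverted-fragment joins would exercise the same matching code).

`apply_events()` realises the plan and emits the rearranged haplotype plus
a truth VCF; length-conservation identities (`len(alt) = len(ref) - ΣDEL +
ΣINS + ΣDUP`, inversions neutral) are asserted in the test suite, and
`parse_vcf(write_vcf(truth))` reproduces the truth set exactly.
`sample_read_pairs()` draws error-free FR read pairs with fragment length
uniform within ±10% of the target — we interpret the ±10% as a uniform
band; an empirical simulator would use a learned error and insert-size
model, and no sequencing errors are introduced, so read-level outputs here
exercise formats and coverage accounting, not aligner robustness.

`perturb_callset()` turns a truth set into a pseudo-caller with known error
structure: per-call breakend offsets and a size rescaling drawn *jointly*
so that, at `pos_noise = 200` and `size_noise = 0.25`, every emitted call
still satisfies all three inclusive matching bounds (this is what makes
"precision = recall = 1 under maximal in-tolerance noise" a sharp test
rather than a statistical one); decoy calls are placed at least
`2 × window + pos_noise` from every truth breakend so they can never match,
and their count is drawn negative-binomially so the decoy fraction equals
`fp_rate` in expectation with binomial-scale fluctuation.

What the simulator does **not** emulate: sequencing error, alignment
artefacts, repeat-mediated systematic false calls, overlapping or
homozygous events, and inter-chromosomal rearrangements. Passing the
package's tests therefore demonstrates correctness of the *evaluation
machinery*, not caller performance on real genomes.

## Context stratification

Breakends are annotated by RepeatMasker top-level class with everything
beyond DNA/LINE/SINE/LTR/Low_complexity collapsed into `Other`;
`Simple_repeat` breakends, and breakends in a tandem-repeats-finder region
that RepeatMasker does not cover, are labelled `Simple/Tandem`. When
several RepeatMasker intervals overlap one breakend we apply the precedence
`Simple_repeat > Low_complexity > named classes > Other` (the choice is
ours; for width-1 breakend lookups overlap length cannot break ties). BED
inputs are 0-based half-open and converted at the boundary; all internal
coordinates are 1-based inclusive.

Small-variant proximity counts SNV/indel positions within 50 bp (inclusive)
of the *nominal* position of either breakend — ambiguity intervals are
deliberately ignored here, and a variant near both breakends of a short
event counts once per breakend. Blacklist filtering removes calls with
either breakend within 200 bp of a blacklisted interval; high-confidence
filtering keeps calls with both breakends inside the region set. For size
stratification, true positives use the truth-set length and false positives
the caller-reported length, so callers that mis-report lengths are not
flattered.

## Ensembles

For an ensemble of `m` callers with support threshold `n`, every call that
does not overlap at least `n` ensemble callers is removed (a call counts
its own caller, so `n = 1` is the union and `n = m` the intersection);
surviving calls are labelled TP/FP by truth overlap and the totals divided
by `m`. The division compensates for multiple counting of shared calls
without requiring a deduplication step, which would be ill-defined under
non-transitive overlap chains. Caller-caller overlap is used symmetrically
(either matching direction counts); truth matching keeps its asymmetric
direction. Recall uses unique truth-component coverage by surviving calls
rather than divided totals — divided recall would not be a coverage
fraction. `enumerate_ensembles()` evaluates every subset × threshold
combination, for all calls and PASS-only.

## Quality diagnostics

`pr_curve()` ranks calls by quality score — or supporting read count as a
proxy when no quality is reported — and re-evaluates precision/recall at
every distinct threshold. `quality_bins()` separates calls into 100
equal-width bins over the observed score range (log10 read count for the
count key; zero counts excluded with a logged count; edge ties to the lower
bin) and attaches an exact Clopper–Pearson 95% interval to each bin's
precision; bins with 10 or fewer calls are flagged as unstable. Binning is
per caller, over that caller's own score range, since score scales are not
comparable across callers. The Clopper–Pearson endpoints are the standard
beta quantiles, checked in the test suite against an independent inversion
of the binomial tail probabilities and for empirical coverage (the interval
is conservative, so coverage exceeds the nominal 95%).

## Numerical and scale choices

The test suite and examples run on references of 80 kb–9 Mb for everything
except the two full-scale planning checks (18,000 events and 10,000
fragments on a 133 Mb reference), keeping a complete run around a minute on
one core. The indexed matcher generates candidate pairs with an interval
overlap query on window-expanded first breakends and then applies the full
predicate, and is tested to be exactly equivalent to all-pairs evaluation.
All randomness flows through explicit integer seeds; identical seeds give
byte-identical FASTA/VCF/FASTQ/TSV outputs. Degenerate inputs are defined
rather than accidental: empty call sets give precision 0 and valid zeroed
reports, an empty truth set gives `NA` recall with a warning, zero-size
pairs match only each other, and unpaired `BND` mates are excluded from
matching with a warning and a logged count (the conversion of single
breakends is otherwise undefined).

## Known limitations

Single-sample VCFs only (first sample used); genotype concordance,
reciprocal-overlap CNV matching and multi-allelic records are out of scope.
An isolated inversion breakpoint (one of the pair missing) is written as a
BND mate pair, so it re-parses as a translocation breakend rather than an
inversion; sets produced by the parser or simulator always carry both
breakpoints and round-trip exactly. Event size for translocation breakends
is reported (|pos2 − pos1| intra-chromosomally) but ignored in matching
unless explicitly enabled.
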