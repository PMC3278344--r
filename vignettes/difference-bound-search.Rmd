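---
title: "Difference-bound FM-index alignment: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference-bound FM-index alignment: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmalign)
```

## The index

The reference is the concatenation of its contigs, packed at 2 bits per
base (A=0, C=1, G=2, T=3), followed by a single sentinel that sorts before
A. Ambiguous IUPAC bases cannot be represented in a 2-bit alphabet; they
are deterministically replaced with A and their positions recorded in an
ambiguity mask, so coordinate resolution can flag any placement that
overlaps a masked region. Using one sentinel for the whole genome (rather
than one per contig) keeps the suffix sort simple; the price is that a
match may straddle a contig junction, and such placements are filtered
during coordinate translation instead.

The suffix array is built by a plain comparison sort of all suffixes.
That is O(n log n) comparisons with expected O(log n) work each on random
DNA — entirely adequate at the scales this package targets (up to a few
megabases); linear-time construction is a non-goal. From the suffix array
we take the BWT, cumulative counts `C`, an occurrence checkpoint table at a
configurable stride (default 64 bases), and suffix-array samples at a
configurable row stride (default 8). Those defaults balance memory against
the length of the scan/LF-walk each query pays; both are configurable, and
a property test asserts that answers are identical across strides 1, 32
and 128. Between checkpoints, occurrences are counted on 2-bit-packed
64-bit words with popcount — the standard rank trick, and the single most
important constant-factor choice in the package: the inexact search
executes two rank queries per tree edge.

Both a forward and a reverse-text index are kept (file roles `.bwt/.sa`
and `.rbwt/.rsa`, plus `.pac` and the `.ann` annotation). The reverse
index exists for one purpose: the per-position lower bound described next.

## The search

A *difference* is one mismatch, one gap open, or one gap extension; an
alignment may carry at most `z` of them. Backward search consumes the read
3'→5'; at each node the branch set is the exact extension, the three
substitutions, an insertion (read base consumed, interval unchanged) and
four deletions (reference base consumed, read position unchanged).
Children are expanded in ascending added-penalty order — exact first, then
mismatch (default penalty 3), then gap extension (4), then gap open (11),
ties broken A<C<G<T with insertions before deletions — and the traversal
descends depth-first, returning to a node to take its next-best child, so
the memory in use is one branch of the tree: at most `m + 1`
query-consuming nodes for a read of length `m` (deletion steps extend the
current node rather than adding a frame, matching the way a gap is one
labelled node in the search-tree picture).

Two prunes bound the tree:

* **Prefix lower bound.** `d(i)` is the minimum number of differences any
  occurrence of the read prefix ending at `i` must carry, computed by a
  single left-to-right walk on the reverse-text index that restarts and
  increments whenever the interval empties. A node with `n_diff + d(i−1)`
  above the budget cannot lead to a reportable alignment. `d` is a true
  lower bound (each restart witnesses at least one unavoidable
  difference), non-decreasing by construction.
* **Suboptimal collapse.** Once a full alignment with `best` differences
  exists, the budget drops to `min(z, best + 1)`: one stratum above the
  optimum is reported (so mapping quality can see suboptimal evidence),
  never more, and never beyond `z`. With suboptimal reporting off the
  budget drops to `best`.

The same rules drive the breadth-first reference implementation — a
priority queue ordered by accumulated penalty, FIFO within ties — which
must produce the identical hit set while reporting its peak frontier size.
Its role is purely evidential: the paired property tests assert hit-set
equality and the memory ordering (branch store vs frontier) on randomized
suites. A third, index-free route — a vectorised dynamic program over the
raw reference text (`brute_force_hits`) — recomputes, for every start
position, the minimal difference count of any alignment under the same
operation model, and anchors the central oracle-equivalence tests. It is
restricted to at most one gap open per alignment (the package default;
start-position recovery in the DP relies on the single-gap invariant) and
errors loudly beyond that.

### Gap conventions

Gap opens and extensions are budgeted separately (defaults: 1 open, 6
extensions) and each counts as one difference; the penalties
(mismatch 3 / open 11 / extend 4) are declared conventions in the BWA
lineage, pinned for reproducibility rather than extracted from any
measurement. Gaps are disallowed within 5 bases of either read end
(configurable, at least 1): terminal indels are not distinguishable from
soft boundary effects at these read lengths, and requiring at least one
anchor base on each side removes an end-state ambiguity from both the
search and the oracle. Adjacent insertion/deletion switches within one gap
are not allowed (a gap has a single type); a read `N` matches nothing and
always costs a mismatch. The multi-gap case (`max_gap_opens > 1`) is
supported by the search itself but not by the oracle, and is outside the
tested envelope.

### Automatic difference budget

With `max_diff = "auto"`, `z` is the smallest value for which the
probability of more than `z` errors on the read, under a binomial model
with a 0.04 per-base rate, falls below 1%. For 70 bp reads this gives
`z = 7`. A budget that generous makes a naive full-budget search explore
large spurious subtrees, so the production path escalates: the search runs
at increasing budgets starting from the read's own whole-prefix lower
bound `d(m−1)`, and the first budget admitting any full alignment pins
`best`; one further bounded run collects the reporting stratum
`min(z, best + 1)`. Escalation changes no output — every stratum the
reporting rule would keep is still searched — it only avoids strata the
rule would discard, and the multiphase-vs-single-pass equivalence suite
runs over both paths.

## The multi-phase scheduler

Reads longer than the seed length (default 32 bp) are fragmented; the
3'-most fragment is searched first and the short remainder, if any, last.
Partial hits pause at fragment boundaries in a ranked stack — ordering key
(difference count, penalty, query position), deterministic ties — and the
best-ranked entry resumes first. Gap state is carried across boundaries so
a gap may span two fragments; without that, the multi-phase result would
not equal the single-pass search, which is the module's central tested
property. `run_phase()` is a pure function from (stack, reads) to (stack,
completed hits): the host/device split of the original architecture is
modelled as explicit state so the stack discipline — no entry above `z`,
none above `min(z, best + 1)` once a full alignment exists — is directly
inspectable by tests.

## Coordinates, mapping quality, SAM

Internally everything is 0-based half-open; SAM emission converts to
1-based. Suffix-array rows resolve to linear positions through the sampled
SA by LF-walking; placements crossing contig junctions are dropped, and
placements over ambiguity-masked reference are flagged. The reference span
of a hit is `m − inserted + deleted` bases, which is why hits record the
gap composition and not only the counts of opens/extends.

Mapping quality is a declared deterministic convention (the evaluation
protocol needs a Phred-scale confidence, not a calibrated probability): 0
if the best stratum holds more than one placement; 37 for a unique
placement with no suboptimal hits; otherwise `max(0, 23 − 8·(subopt − 1))`,
minus 3 if the suboptimal gap is zero. It is monotone non-increasing in
the suboptimal count, and the value 23 for "unique best, one suboptimal"
keeps such reads above the protocol's threshold of 10 while two or more
suboptimal placements push them below it at ≥ 3.

For gapped hits the search records operation counts, not paths, so the
CIGAR re-places the single gap on the known reference span at the boundary
minimising mismatches (leftmost on ties). The `NM` tag reports the hit's
difference count. Paired-end emission picks the opposite-strand,
head-to-head combination minimising the combined difference count subject
to the insert-size window — inferred as mean ± 4 sd from up to 10,000
unique candidate pairs, falling back to [0, 2000] when fewer than 20 are
available, and overridable by argument.

## The simulator and what passing tests mean

The simulator emulates whole-genome shotgun resequencing the way wgsim
does: an i.i.d. random genome at a requested GC content (0.46 in the
protocol, a typical eukaryotic value); a haplotype carrying SNPs and short
indels (mutation rate 0.001, indel fraction 0.1, geometric indel lengths —
declared defaults, chosen as ordinary resequencing values since only the
sequencing error rate of 0.02 is externally fixed); pairs sampled
uniformly with normal insert sizes (500 ± 50 bp) truncated at the read
length, mate 2 reverse-complemented, per-base errors injected at 0.02, and
constant `I` qualities because the aligner is quality-blind. Truth —
contig, both mates' reference-projected leftmost positions, strands — is
encoded losslessly in the read name, and the evaluator scores percent
confidently mapped (mapq ≥ 10 over all reads) and percent of confident
mappings wrong (off by more than 5 bp, a tolerance absorbing indel wobble,
or wrong contig/strand).

What an i.i.d. genome does **not** contain is repeat structure: real
genomes have segmental duplications and low-complexity tracts that create
genuinely ambiguous placements, so the near-zero error rates and ~100%
unique mapping achieved here say that the machinery is correct, not that
real-genome accuracy would look like this. The protocol's comparative
claims — error rate at the threshold, and the near-indifference of the
mapped fraction to disabling gap opening (indels are rare at these rates,
and a read straddling one either gaps or fails cleanly) — are the
properties the acceptance suite asserts, at sizes (100 kb genome, 10,000
pairs of 70 bp) chosen so the full pipeline runs comfortably on one CPU.

## Numerical and degenerate-input choices

Empty query: the fold over an empty read is the full interval, reported as
a zero-difference hit. Reads shorter than `2 × no_indel_end` simply admit
no gaps. Ties everywhere (child order, stack ranking, primary-hit choice,
CIGAR gap placement) are broken by fixed deterministic keys, which is what
makes the whole pipeline byte-reproducible under a fixed seed — asserted
end-to-end, including index save/load and the binary hit-file round trip.
BFS frontiers are capped (error past 10^6 stored nodes by default): the
frontier explosion is the documented reason the production search is
depth-first. Index and hit files carry magic bytes and a format version;
hit files also carry a fingerprint of the index they were computed
against, and SAM conversion refuses a mismatched pair.

## Known limitations

Quality-aware scoring, Smith–Waterman rescue of one mate, color-space
reads, and BAM output are out of scope. The mapping-quality formula is a
pinned convention, not calibrated on real data. The oracle (and hence the
tested envelope) covers at most one gap open per alignment. Suffix-array
construction is quadratic on adversarial inputs such as a single-letter
genome; on random or real DNA at package scale it is not a bottleneck.
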