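---
title: "Assessing barcoded plasmid libraries: models and methods in bclut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing barcoded plasmid libraries: models and methods in bclut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bclut)
```

## The problem

Pooled screening experiments built on barcoded plasmid libraries stand or
fall on one mapping: each degenerate DNA barcode must point to exactly one
genomic fragment. Once that look-up table is trusted, cheap barcode-only
sequencing of downstream samples can be interpreted in terms of fragments.
But the table is built from sequencing data that is itself corrupted by
synthesis truncations, base-calling errors, PCR template switching
(read-level chimeras) and, with some cloning strategies, plasmid-level
heterodimer formation. `bclut` implements the assessment workflow for such
libraries: it recovers barcode–fragment links from paired-end reads,
quantifies their ambiguity with a per-barcode **purity** statistic, and
validates barcode error-correction (clustering) against that statistic. A
full synthetic-data stack provides ground-truthed inputs so every stage can
be tested against a known answer.

## The purity parameter

For one barcode observed in $n \ge 2$ reads, each read contributes an
aligned genomic range (start, end, strand). Identical ranges are counted,
and the most frequent identical range is the **consensus** (ties broken
deterministically: highest count, then smallest ref, start, end, strand).
Every read whose start *and* end both lie within ±`tol_bp` (default 20 bp)
of the consensus, on the same strand, is counted as concordant, and

$$\mathrm{purity} \;=\; \frac{\text{concordant reads}}{\text{total reads for the barcode}} \in (0, 1].$$

Purity 1 means every read of that barcode tells the same story; values
toward 0 mean the barcode points at multiple fragments — the signature of
chimeras or of falsely merged barcodes. Barcodes seen in a single read
(**singlets**) have undefined purity; they are tallied and reported but
excluded from purity distributions. The ±20 bp box absorbs small alignment
wobble (indels, soft ends) without letting genuinely different fragments
collapse; both endpoints are checked independently, and strand is part of
fragment identity because insertion orientation distinguishes otherwise
identical intervals.

Two failure modes separate cleanly under this statistic, and the simulator
reproduces the dissociation: plasmid-level heterodimers re-pair a barcode
with a wrong fragment *before* amplification, so all its reads agree with
each other (purity stays 1) while the table silently lies — only a
truth-aware comparison reveals it; read-level template switching scatters a
barcode's reads across fragments and collapses purity directly.

## Barcode design and its analytics

The default design cycles the IUPAC codes V, H, D, B (each "anything but
one base") five times: 20 positions, three choices each, $3^{20} \approx
3.5\times 10^9$ sequences, and — because each code excludes a different
base every fourth position — no conforming sequence can contain a
homopolymer longer than three. `design_diversity()` computes the product
exactly; `max_homopolymer_run()` proves the bound by exact search over the
pattern's position alphabets rather than by sampling. Observed barcodes are
accepted when 18–22 nt long, reflecting the synthesis-truncation spectrum
of column-made degenerate oligos. Generation is uniform within each
position's alphabet; an optional per-base weight table lets users emulate
the G/T synthesis skew seen in real logos, but the default stays uniform
because that skew is an artefact of synthesis chemistry, not part of the
design. Uniqueness inside one simulated library is enforced by rejection
sampling, mirroring single-use barcoding.

## The dUTP/UDG fragmentation model

Fragment pools are generated by a two-parameter abstraction of
dUTP-PCR/UDG fragmentation: a T position of the template incorporates
uracil with probability $p = f r / (f r + 1 - f)$, where $f$ is the dUTP
fraction in the reaction and $r$ the polymerase's relative incorporation
efficiency (default 1); every incorporated uracil is excised and the
backbone cleaved. Cuts are independent across positions, a single-strand
model: nick pairing across strands is deliberately out of scope. The cut
convention removes the cleaved base, so per replicate
$\sum \text{fragment lengths} + \#\text{cuts} = L$ holds exactly — the
conservation law the tests assert. The expected mean fragment length is
$(L - p\,n_T)\,/\,(p\,n_T + 1 - e_0)$ with $n_T$ the number of T positions
and $e_0$ the expected number of empty intervals (adjacent or terminal
cuts), approaching the geometric spacing $1/(p f_T)$ on long templates.
Fragments under `min_fragment_len` (default 50 bp, the bead-cleanup cut)
are discarded. The default $f = 0.10$ matches the fraction used in the
protocol the model emulates.

## The read simulator as the test harness

`build_library()` assigns unique barcodes, uniformly sampled fragments and
uniform orientation; `simulate_reads()` then draws Poisson(`mean_depth`)
read pairs per clone (default 10), adds spurious singleton reads at
`singlet_inflation` per clone (each a one-substitution variant of its
clone's barcode, emulating the error-borne singlet excess), applies
per-base substitution/indel errors (defaults $10^{-3}$ / $10^{-4}$ /
$10^{-4}$, a well-behaved short-read run), and switches the barcode of a
read pair to another clone's with probability `chimera_rate`. Emulsion PCR
is represented solely as a low chimera rate. Correct bases carry phred 37,
error bases phred 12, so phred filtration has something real to act on.
Every read carries a truth tag, which makes two oracle checks possible:
with all noise off, the pipeline must reproduce the truth table exactly
(for clones with at least two reads), and at any chimera rate the pipeline
purity must equal purity recomputed directly from the tags.

What the simulator does **not** emulate: cycle-resolved PCR kinetics and
amplification bias, platform-specific error spectra (flow-space indels,
quality-by-cycle decay), micelle occupancy statistics, and real flank
sequences (the bundled flanks are synthetic constants). Passing tests
therefore demonstrate correctness of the analysis under the stated
generative model, not robustness to every artefact of a particular
instrument.

## Extraction and alignment choices

Flank matching is a substitution-only leftmost Hamming scan (default 1
mismatch per flank); flanks are short and indel-tolerant matching buys
little at these error rates. Phred filtration inside the barcode uses the
per-base **minimum** (the strictest reading); failures are recorded per
read with a reason, never dropped silently. Fragment reads are trimmed of
backbone read-through and kept regardless of length.

The aligner is a self-contained seed-and-extend: 15-mer exact seeds on both
strands, candidate diagonals merged within a band (8 nt), affine-gap
semiglobal extension (match +1, mismatch −1, gap open −2, gap extend −1).
A fragment maps only if its best score clears
$\lceil \mathrm{len}(1 - 3\cdot\texttt{max\_mismatch\_rate})\rceil$ *and*
no second location or strand ties it — the unique-valid-alignment filter.
Ranges are 0-based half-open internally; 1-based only at the GRanges
export. Read 2 is modelled as covering the whole fragment (the
merged-mates view), so alignment end points are directly comparable with
the truth.

## Clustering: sphere versus message passing

Both algorithms consume (sequence, count) tallies, canonically sorted
(count descending, then lexicographic) so results are independent of input
order, and both share one Levenshtein kernel: a banded unit-cost DP with a
cap, plus admissible length and base-composition prefilters for the
all-pairs neighbour scan (practical to roughly $2\times10^4$ distinct
sequences).

**Sphere**: walking down the sorted list, a sequence becomes a centroid
unless a formed centroid of strictly greater count lies within `max_dist`;
the nearest such centroid claims it, and a sequence equidistant from two
formed centroids is discarded as ambiguous at the point of clustering.

**Message passing**: each sequence points at its nearest
strictly-higher-count neighbour within `max_dist`; parent pointers resolve
transitively (parents always have higher counts, so they resolve first),
parentless sequences become centroids, and a sequence whose equally-near
candidate parents resolve to *different* centroids is discarded, along
with anything beneath it. An optional count-ratio gate
(`min_ratio`, default 1 = off) additionally requires a parent to have at
least `min_ratio` times the child's count. We evaluated defaulting the
gate to 5: at 10× depth it strands the error halos of shallowly sequenced
clones (a clone seen 3–4 times cannot absorb even a singleton halo),
inflating cluster counts far above the true clone number, so the gate
ships off and is left to the user for deep datasets.

Validation is deliberately algorithm-agnostic: relabel every read by its
centroid, rerun the reduce, and read the purity distribution. False merges
of truly distinct barcodes show up as purity loss; correct absorption of
error halos leaves purity untouched. On the package's validation scenario
(5 000 clones, 10× depth, error rates inflating raw unique barcodes about
three-fold) message passing at distance 3 recovers the clone count within
a few percent with mean purity above 0.99, while sphere clustering at
distance 4 shows a clear purity drop relative to distance 0 — the
directional contrast the two algorithms are known for. Equivalence with
any particular external clustering binary is not claimed.

One structural asymmetry is worth knowing: the message-passing cluster
count is provably non-increasing in `max_dist` (a larger radius can only
give a sequence more candidate parents), but the greedy sphere count is
not — a larger radius can let the top centroid claim a mid-count sequence
that was itself a centroid at the smaller radius, freeing that sequence's
satellites to become centroids of their own. The test suite pins a
twelve-sequence counterexample whose sphere counts run 12, 7, 4, 5 over
radii 0–3.

## Numerical and degenerate-input conventions

* Consensus ties: highest count, then lexicographic (ref, start, end,
  strand) — deterministic and documented, since the choice is arbitrary.
* Singleton groups raise an error in `consensus_and_purity()`; the batch
  reduce sets them aside instead.
* Empty inputs: empty pair sets produce empty grouped tables; an empty
  look-up table is an error only where a distribution is requested.
* Equal-count sequences never claim each other in either clustering
  algorithm; at `max_dist = 0` both reduce to identity clustering.
* All stochastic stages accept explicit seeds, and a pipeline run with the
  same inputs and seed is reproducible element for element.

## Problem sizes used in validation

The shipped tests run entirely on synthetic data at desk scale, chosen to
exercise the statistics without heroic runtimes: single-operation tests at
tens to hundreds of cases; oracle-equivalence sweeps at 1 000 clones × 10×
depth over five seeds and chimera rates {0, 0.3, 0.9}; the clustering
recovery scenario at 5 000 clones (≈50 000 read pairs, ≈15 000 raw unique
barcodes); fragmentation calibration at 10 000 replicates of a 2 kb
template. The clone-count scale of a real NextSeq run (10⁷ raw barcodes)
is outside the all-pairs neighbour scan's envelope by design.

## Known limitations

* The fragmentation model is single-stranded and memoryless; real UDG/NaOH
  chemistry shows local sequence context effects it does not capture.
* The aligner is built for short references (plasmid inserts, amplicons);
  it is not a genome-scale mapper, and its uniqueness filter is a
  contract, not a reproduction of any external aligner's internals.
* The message-passing formulation is a faithful, testable reading of
  count-flow clustering with tie discarding; published implementations
  differ in internals (tries, propagated counts) and may disagree on edge
  cases.
* Purity validates linkage, not abundance: amplification bias that
  preserves linkage is invisible to it.
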