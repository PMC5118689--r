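# bclut — barcode–fragment look-up tables and purity QC for barcoded plasmid libraries

Pooled screens built on barcoded plasmid libraries depend on one mapping:
every degenerate DNA barcode must point to exactly one genomic fragment.
`bclut` builds and stress-tests that mapping from paired-end sequencing of
the plasmid library itself. It is aimed at people constructing
fragment-scanning or vector-barcoding libraries who need to know, before a
screen, whether their barcodes are unambiguous — and at anyone who wants a
ground-truthed sandbox for barcode error-correction methods.

## What it computes

**The purity parameter.** For a barcode observed in $n \ge 2$ reads, each
read contributes an aligned genomic range (start, end, strand). The most
frequent identical range is the consensus (deterministic tie-break), reads
whose start *and* end lie within ±20 bp of it on the same strand count as
concordant, and

$$\mathrm{purity} = \frac{\text{concordant reads}}{\text{total reads}} \in (0,1].$$

Purity 1 = unambiguous linkage; low purity = the barcode points at several
fragments (template-switching chimeras, or falsely merged barcodes).
Single-read barcodes are reported but excluded (purity undefined).

Around this sit the supporting stages, all self-contained:

* **barcode model** — the `(VHDB)x5` cycling design: exactly $3^{20}$
  sequences, homopolymers provably capped at 3, 18–22 nt acceptance window;
* **extraction** — flank matching with mismatch tolerance, length and
  per-base phred filtration, every failure counted by reason;
* **alignment** — seed-and-extend with affine gaps and a strict
  unique-best-hit filter, 0-based half-open ranges;
* **reduce** — group by barcode, split singlets, consensus + purity → the
  look-up table (TSV + JSON metadata, GRanges export);
* **clustering** — sphere and message-passing clustering over a capped
  banded Levenshtein kernel, with tie discarding, validated by the purity
  readout;
* **simulator** — dUTP/UDG fragmentation size model, library constructor,
  paired-read simulator with Poisson depth, singlet inflation,
  substitution/indel errors, read-level chimeras and plasmid-level
  heterodimers, emitting per-read ground truth.

## Worked example

Simulate a 500-clone library on a 600 bp reference with 10× depth and a 5%
chimera rate, then assess it:

```r
library(bclut)
set.seed(7)
ref  <- paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")
pool <- do.call(rbind, lapply(1:40, function(i)
  fragment_template(ref, fragmentation_config(0.10))))
truth <- build_library(pool, 500, barcode_spec())
sim   <- simulate_reads(truth, ref,
                        read_sim_config(mean_depth = 10, chimera_rate = 0.05, seed = 8))
res   <- run_pipeline(sim$reads, ref)
res
#> bclut pipeline run
#>   reads in:        4929
#>   barcode pass:    4902
#>   aligned:         4927
#>   joined pairs:    4900
#>   singlets:        105
#>   multi barcodes:  500
#>   mean purity:     0.9519

report(res$table, truth = truth, reference_length = nchar(ref))
#> library report: 500 multi-read barcodes
#>   orientation: 251 (+) / 249 (-), binomial p = 0.964
#>   mean purity: 0.9519
#>   links: 500 correct, 0 chimeric, 0 novel, 0 lost

head(as.data.frame(res$table[, c("barcode","start","end","strand","total_count","purity")]), 3)
#>                barcode start end strand total_count    purity
#> 1 AAACACAGGTTTGTTGAAAT    28  87      +           8 0.8750000
#> 2 AAACACGCAAGCCAACCCGC   242 332      +           9 1.0000000
#> 3 AAACACGCGTGGGATCAATT   274 329      +          11 0.9090909
```

Reading it: all 500 clones are recovered and correctly linked; the mean
purity of 0.95 reflects the injected 5% read-level chimerism (each
switched read lands in some other barcode's group and dilutes it); the
singlet excess comes from the simulator's error-borne singleton reads; and
orientation is balanced, as unbiased ligation should be. With
`chimera_rate = 0` the same pipeline returns purity 1.0 for every barcode.

Barcode error-correction is validated the same way:

```r
counts <- barcode_tally(res$pairs$barcode)
cl <- message_passing_cluster(counts, max_dist = 3)
validate_clustering(cl, res$pairs)$purity
```

A thin command-line front end (`simulate`, `run`, `cluster` subcommands)
is installed at `inst/scripts/bclut.R`.

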