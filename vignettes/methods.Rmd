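---
title: "Mitogenome architecture, rearrangement inference, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome architecture, rearrangement inference, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
```

## The model

An animal mitogenome is represented at two levels.

1. **Annotation** (`mito_annotation`): a circular genome of known length
   carrying records `(gene, start, end, strand)` with 1-based inclusive
   coordinates. A record whose `end < start` wraps the origin; its length is
   `genome_length - start + 1 + end`. The gene vocabulary is fixed at
   38 symbols — 13 protein-coding genes, 22 tRNAs (with the standard
   `trnL1/trnL2` and `trnS1/trnS2` split), two rRNAs, and the control
   region — and common aliases (`COI`, `16S`, `D-loop`, anticodon suffixes,
   ...) are normalized on input. `validate_annotation()` cross-checks stated
   lengths, codon fields and coordinate sanity, and reports issues rather
   than failing, because published tables do contain internal
   inconsistencies (one of the bundled fixtures carries a stated tRNA length
   that disagrees with its own coordinates; the validator flags it).

2. **Signed circular gene order** (`gene_order`): the sequence of the 38
   symbols with orientations, read off the genome strand. Two orders are the
   same arrangement if they differ only by rotation or reflection;
   `canonicalize()` anchors at `cox1` oriented forward so that equality,
   hashing, and distances are well defined.

## Composition and codon statistics

Skews are the usual strand-asymmetry statistics `AT = (A-T)/(A+T)` and
`GC = (G-C)/(G+C)`, returned as `NA` when a denominator is zero. Partition
statistics slice the genome strand by default; minus-strand genes therefore
show flipped skews unless `strand_aware = TRUE` reverse-complements them
first. Both conventions appear in the literature, so the choice is explicit
rather than implicit.

Codon work uses the invertebrate mitochondrial code: 62 sense codons, stops
TAA/TAG only, `ATA = Met`, `AGA/AGG = Ser` (making Ser an 8-codon family).
RSCU is `count * family_size / family_total`, so family sums equal family
size whenever the family is observed at all — an invariant the tests check
on random usage tables. Terminal codons are classified strand-correctly
from the sequence, including the truncated stops `T--` and `TA-` completed
by polyadenylation; internal stop triplets are skipped with a warning
rather than silently counted or fatally rejected.

## Rearrangement mechanisms

Three event types act on signed circular orders:

- **Inversion** of a contiguous span: reverse it and flip every sign.
- **Translocation** of a contiguous span to a new position (`after = some
  gene outside the span`).
- **TDRL** (tandem duplication–random loss): the span is duplicated
  head-to-tail and one redundant copy of each gene is lost. The product
  keeps original signs and consists of the copy-1 survivors in span order
  followed by the copy-2 survivors in span order — an interleaving
  ("riffle") of two complementary subsequences.

Scenarios (`new_scenario`) bundle a source order with an event list;
`verify_scenario()` replays them and pinpoints the first step whose
precondition fails or whose product differs.

### Inference

`infer_scenarios(src, dst, max_events, kinds)` returns every minimum-cost
scenario, by iterative deepening. The design choice that makes this fast is
that the *final* step is never enumerated: for each candidate penultimate
order, single-event reachability to the target is decided analytically.
Precomputed target contexts (the signed integer vector, its sorted multiset,
and its adjacency-key set, for the target and its reflection) let each probe
run in about a millisecond. The TDRL case rests on a characterization proved
by the test suite against brute force: a span permutation is a single-TDRL
product iff the signs are unchanged and the permutation's source-index
sequence has at most one descent. A length-`l` span therefore has exactly
`2^l - l` single-TDRL products.

Two mechanistically different events can produce the same order — every
translocation is also expressible as a TDRL. Scenarios are deduplicated by
their event list *and* their intermediate-order sequence, so each
mechanistic explanation is reported once.

**Limits.** With all three mechanisms and spans up to 6 genes on a
38-symbol order there are ~7,100 distinct single events. Depth-2 exhaustive
search (enumerate one event, solve the last analytically) completes in
seconds; full depth-3 search squares the enumeration and is not practical
without restricting `kinds` or the span range. `max_events = 2` covers the
intended use: scoring simulated histories of one or two events and finding
parsimonious explanations for closely related arrangements.

## The simulator

`simulation_config()` defaults are the study conditions, not free dials: a
~17 kb circular genome; base composition A 35.5 / T 38.1 / G 9.0 / C 17.5 %
(renormalized, so rounded percentages are accepted as-is); tRNAs of
60–75 bp, rRNAs of 800–1,400 bp, PCG lengths near typical brachyuran values
and always multiples of 3; spacers of 0–25 bp with occasional overlaps up
to 47 bp — matching the largest overlap seen in the bundled genomes — and
never upstream of a PCG, whose start codon must survive; event kinds
weighted TDRL 0.5 / translocation 0.3 / inversion 0.2 with spans of 2–6
genes. The control region absorbs layout slack so the genome hits its
length target exactly. Every PCG receives an `ATN` start and a `TAA`/`TAG`
stop written on its coding strand, so simulated genomes validate cleanly by
construction.

Two deliberate simplifications:

- Sequence is i.i.d. from the target composition. PCG interiors therefore
  contain in-frame stop triplets, which `codon_usage()` flags; composition
  statistics are exact in expectation, codon statistics are not meant to be
  realistic. `simulate_cds()` exists separately for codon-level work.
- `mirror_minus` (off by default) fills minus-strand gene regions with the
  complement-mirrored composition. On, it mimics the strand-specific
  mutational asymmetry real genomes show; off, the whole-genome composition
  tracks the target exactly, which is what the composition-recovery checks
  need.

All randomness flows from `cfg$seed` (history), `seed + 1` (genome layout
and sequence), `seed + 2` (coding sequence), so identical configs reproduce
byte-identical output — the report layer's tests rely on this.

## What the package does not do

No phylogenetics (no tree building, dating, or selection tests), no *de
novo* annotation from raw sequence, no plotting. Gene orders are compared
combinatorially; no attempt is made to weight events by mechanistic
plausibility beyond parsimony.
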