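---
title: "Combinatorial inline indexing for amplicon libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial inline indexing for amplicon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplitag)
```

## The problem

Amplicon sequencing on Illumina instruments faces two structural
problems.  First, cost: a sequencing run is cheap per read but
expensive per run, so it only pays off when many samples share it —
which requires each sample to carry identifying indexes.  Second, base
diversity: amplicons from one primer pair are near-identical over
their first cycles, and four-colour Illumina basecalling degrades when
one detection channel goes dark at a cycle.

The approach implemented here solves both with *indexed fusion
primers*: locus-specific PCR primers carrying, at their 5' end, a
partial adapter tail (the TruSeq or Nextera Read 1/Read 2
sequencing-primer site) and an inline tag — a 0–3 nt *heterogeneity
spacer* (lowercase by convention) plus a 5-nt *index* (uppercase).
Eight forward-tagged and twelve reverse-tagged primers amplify the 96
wells of a plate with 8 × 12 distinct tag combinations; products can
then be pooled and converted to full-length libraries in one
limited-cycle PCR with outer i5/i7-indexed universal primers.  The
result is a quadruple-indexed library: sample identity is the tuple
(inner forward, inner reverse, i5, i7), and

```{r capacity}
multiplex_capacity(8, 12)             # one plate, inner tags only
multiplex_capacity(8, 12, 384, 384)   # with a full outer-primer set
```

## The tag design and its guarantees

The packaged default set (`default_index_set()`) carries 20 tags
organised in five *tetrads* (groups of four).  Three properties hold
by construction and are machine-checked by `validate_index_set()`:

1. **Error correction.** Every pair of 5-nt indexes is at Levenshtein
   distance ≥ 3, so no single sequencing error can convert one tag
   into (or within distance 1 of) another.
2. **Cycle staggering.** Within each tetrad the spacer lengths are
   0, 1, 2, 3 nt, so full sequences have lengths 5–8 and the
   downstream locus primer is read out of phase across the pool.
   Note the limit: a mononucleotide run of ≥ 5 bp in the target
   defeats a 0–3 nt stagger; `design_index_set()` accepts other
   spacer ranges (e.g. `spacer_lengths = 4:7`) for such loci, at the
   price of sequenced bases.
3. **Channel balance.** On MiSeq/HiSeq (≤ 2500) optics A and C are
   imaged in the red channel, G and T in the green.  At each of the
   five leading positions shared by a whole tetrad, the four full
   sequences carry exactly two red and two green bases.  Two-channel
   instruments (NextSeq/NovaSeq) use a different encoding and are
   deliberately not modelled.

```{r validate}
validate_index_set(default_index_set())
```

`design_index_set()` searches for fresh sets under the same
constraints with a greedy randomised construction: per tetrad it draws
a channel pattern and a spacer-length permutation, then samples
members one at a time, resampling any member whose index falls within
`min_edit` of an already-accepted index (forward and reverse pooled —
conservative, since it also protects against orientation mix-ups).
The search is deterministic given `seed` and fails loudly, naming the
constraint, when the budget is exhausted (as it must for
`min_edit = 6` on 5-nt indexes, where the maximum possible distance
is 5).

Two choices here were genuinely open.  The published distance claim
does not say whether it covers indexes alone or spacer + index; we
validate on the 5-nt indexes (the stricter reading of "indexes") and
expose `on = "full_sequence"` as well.  And balance is evaluated on
5'-aligned full sequences at positions 1–5 only, because beyond the
shortest member a tetrad's sequences run out at different cycles.

## Fusion-primer assembly

`build_fusion_primer()` is a pure concatenation — tail, then lowercase
spacer + uppercase index, then locus primer, no linkers — and
`build_primer_panel()` emits the standard panel for one primer pair: 2
non-indexed + 20 indexed primers (22 rows), or 44 with
`flipped = TRUE`, where forward and reverse locus primers swap Read 1
and Read 2 tails to mitigate Read 2 quality bias (tags stay with the
locus primer).  IUPAC degeneracy codes pass through untouched.  Primer
names follow `<locus>_<chemistry>_<R1|R2>_<tag|NoTag>[_flip]`; the
upstream material does not fix a naming scheme, so this one was chosen
to be unique, sortable, and order-sheet friendly.  No thermodynamic QC
(hairpins, dimers, Tm) is performed anywhere — validate primers before
ordering.

## Demultiplexing

`run_demux()` assigns each pair by matching forward tags against the
Read 1 prefix and reverse tags against the Read 2 prefix.  Matching is
**Hamming, not Levenshtein**: each candidate is compared at its own
full-sequence length, and the unique candidate within `max_dist`
(default 1) wins.  Indels in the first 5–8 cycles are rare, and across
a deliberately length-staggered set an indel-tolerant matcher would
have to decide which length to realign to — ill-posed.  Ties at the
minimum qualifying distance, including ties between candidates of
different lengths, are refused as ambiguous rather than guessed.  This
tie-break has a measurable consequence: with one substitution placed
in every tag, a few percent of reads tie between their own damaged tag
and a longer candidate whose extra positions happen to match the locus
primer, and land in `unassigned_ambiguous`.  Misassignment, however,
is structurally impossible at `max_dist = 1` given the distance-3
guarantee, and the test suite asserts exactly that split.

Pairs whose two tags both match but whose combination is not on the
sample sheet are counted and written out as
`unexpected_combination` — the observable signature of *tag jumping*
(chimera formation between pooled molecules).  The full observed
tag-pair matrix is always reported so jump rates can be quantified
from deliberately unused combinations.  Nothing is silently dropped;
the suite checks read conservation (inputs = sum over all output
categories) under randomised fuzz input.

Trimming removes spacer + index (and optionally the locus primer,
IUPAC-aware with ≤ 2 mismatches by default) from sequence and quality
in lockstep; Phred+33 is assumed.  Outer i5/i7 demultiplexing is
assumed done upstream; an optional mode cross-checks `i5=`/`i7=`
header comments against the sheet.

## Pooling arithmetic

`plan_pool()` converts (mean length bp, ng/µL, desired reads) per
sub-pool into volumes: molarity is `ng/µL × 10⁶ / (bp × 660)` with the
conventional 660 g·mol⁻¹·bp⁻¹ dsDNA mass (configurable; the upstream
spreadsheet's constant is not published), volumes are proportional to
`target_reads / molarity`, and the largest (or a chosen reference)
volume is pinned to `cap_volume` (default 10 µL).  Volumes are
reported to 0.1 µL and anything positive below 0.5 µL warns — below
typical pipettable accuracy.  The model is molarity-aware but
clustering-efficiency-naive; the `efficiency` argument is an identity
hook for platform-specific corrections.

## Cost and PCR-count planning

`total_cost()` implements a three-term model over five library-prep
strategies: a one-time indexed-universal-primer buy-in ($500), a
per-method oligo buy-in, a fixed per-sample cost, and — for methods
that pool before the second PCR — a variable cost per pooled
second-round reaction.  Treating the variable cost as per-pool is an
interpretation, justified because it reproduces both the published
minimum-PCR row (192/193/97/192/97 at 96 samples, one pool) and the
under-$2-per-library figure at 18 plates.  Prices are January-2019
vendor list prices shipped as a data file (`method_cost_params()`),
not constants — reprice by pointing at your own CSV.

```{r cost}
total_cost(5, 18 * 96, 18)
```

## The read simulator and what passing tests mean

`simulate_reads()` renders the full library construct — tag, concrete
IUPAC realisation of the locus primer, insert, then read-through into
the opposite primer, tag, and adapter tail — and emits paired FASTQ
plus a truth table (sample, embedded tags, 0-based insert coordinates
and error positions).  Read 2 begins with the reverse spacer + index
read 5'→3' on the bottom strand, mirroring how the primer is built;
this strand convention is asserted in the tests but should be spot-
checked against real data by users with unusual setups.  The error
model is substitution-only at a constant per-base rate with flat Q37
quality, and tag jumps can be injected by swapping Read-2 tags at a
given rate.

That is exactly the model the Hamming matcher assumes, which bounds
what green tests demonstrate: they verify the combinatorial and
error-correcting logic (round trips recover 100% of error-free reads
across all 96 combinations; single-substitution damage is never
misassigned), not robustness to indels, quality-correlated errors,
adapter artefacts, or PCR chimeras beyond simple tag swaps.  Problem
sizes in the routine suite are 96 samples × 50 pairs for the
round-trip check and a few hundred fuzz reads elsewhere — small by
design, since every property asserted is scale-free.

## Limitations

* Two-channel (NextSeq/NovaSeq) colour balance is not modelled.
* No primer thermodynamics or secondary-structure QC.
* No quality filtering, pair merging, or chimera removal — downstream
  tools own those steps.
* The cost table models only the published buy-in/fixed/variable
  segment; full vendor line items are out of scope.
* Unique molecular identifiers (N-base inline indexes) are not
  implemented.
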