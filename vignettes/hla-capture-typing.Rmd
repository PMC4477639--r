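---
title: "HLA typing from capture sequencing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLA typing from capture sequencing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacaller)
```

## The problem

The classical HLA loci (A, B, C, DRB1, DQA1, DQB1, DPA1, DPB1) are the most
polymorphic genes in the human genome: thousands of alleles per locus,
most differing from their nearest neighbour by only a handful of
nucleotides. Typing them from shotgun sequencing therefore fails in both
directions at once — reads cross-map between alleles and between loci, and
small allelic differences are easily lost in alignment mismatch tolerance.
`hlacaller` implements an amplicon-free strategy: enrich whole HLA genes
(including flanks) from genomic DNA with tiled RNA capture baits, sequence
100 bp paired ends, map reads against the complete cDNA allele collection
*allowing perfect matches only*, and call each locus by exhaustively
scoring every candidate allele pair.

## Read mapping model

A read placement on an allele cDNA is admissible only if the matched read
substring equals the cDNA substring exactly. The single exception is
*boundary truncation*: because genomic fragments cross exon/intron
junctions and gene flanks, a read prefix or suffix of at least
`min_trunc_len` (default 70 bp) may match provided the alignment
terminates exactly at a cDNA end or an annotated internal exon boundary on
the truncated side. Reads are mapped on both strands; reads containing N
never match; multi-mapping is expected and kept, because the
allele-specific evidence used by the caller is defined over the full
multi-map set. Mate pairing is never required for a mapping to count — it
is scored (as `mppr`, below), not enforced.

The index anchors candidates on the first 16 bases of the (oriented) read
through a k-mer position table and verifies every candidate by direct
substring comparison, so results are exact; the test suite checks them
against an independent exhaustive-enumeration oracle built on
`Biostrings` matching.

### Start-point reduction and the ideal profile

Duplicate fragments inflate depth without adding evidence, so per allele
all mappings sharing a placement — start, matched length and strand — are
collapsed to one ("single start-point" coverage). The dedup key includes
the matched length: two reads may legitimately start at the same cDNA
position with different boundary-truncation lengths, and those are
distinct fragments, not duplicates.

`ideal_profile()` gives the coverage expected when every admissible
placement occurs exactly once per strand: a flat interior plateau of
`2 * read_len` and ramps at the cDNA ends shaped by the truncation rule
(position 0 is reachable by one full-length and thirty truncated windows
per strand). It is the normalisation reference for the coverage statistic
and the red background of coverage plots. Internal exon boundaries admit
extra truncated placements not counted in the ideal, so the observed/ideal
ratio is capped at 1.

## Candidate filtering

Per locus, an allele survives pre-filtering only if

* **full coverage** — every cDNA position has reduced coverage ≥ 1. A
  single uncovered base rejects the allele: under perfect matching, a
  true allele's positions are all reachable, while an allele that differs
  anywhere from the sample's true alleles necessarily shows a gap around
  the differing positions.
* **central reads** — the ratio of kept mappings lying fully inside
  `[read_len/2, cdna_len - read_len/2)` to all other kept mappings must
  not drop below 0.2 (exactly 0.2 passes). Alleles supported only by
  boundary pile-ups — the signature of cross-mapping artifacts — fail.
  The central window is defined by `read_len/2` margins so that a
  uniformly covered allele is ratio-stable and the 0.2 threshold is
  meaningful; cDNAs shorter than `read_len` have no central window and
  cannot pass, which is irrelevant for the ≥ 500 bp classical transcripts.

Rejected alleles are reported, not discarded silently: the `failed` QC
table lists them with the count of zero-coverage positions (ascending, so
near-misses come first), the `undercovered` table lists the top 50 alleles
by uncovered bases, and in low-coverage samples (best observed/ideal
coverage below 0.5) an explicit `review` table asks for manual
verification of low-error rejections. `force_include` / `force_exclude`
in `run_config()` mirror the manual include/exclude interaction.

## Pair scoring

All unordered candidate pairs, homozygous included, are scored on five
parameters:

* `asm` — reads mapping exclusively to one allele of the pair;
* `req = min(asm_a, asm_b) / max(asm_a, asm_b)` — balance of that
  exclusive evidence (0/0 counts as 0);
* `msl` — mean cDNA length of the pair;
* `mppr` — fraction of mapped read instances on the pair whose mate maps
  the same allele;
* `auc` — mean observed/ideal coverage of the pair, capped at 1.

Each parameter is scaled by its maximum over the locus's pairs, and pairs
ranked by the weighted harmonic mean

$$H = \frac{\left(\sum_k 1/w_k\right)\prod_k P_k}{\sum_k (1/w_k) P_k},
\qquad w = \{0.5, 1, 0.1, 0.1, 1\},$$

equivalently `24*asm*req*msl*mppr*auc / (2*asm + req + 10*msl + 10*mppr +
auc)`. H is 1 iff every scaled parameter is 1, 0 as soon as any parameter
is 0, and strictly increasing in each parameter — so a pair must be
simultaneously strong on all axes, with coverage and evidence balance
weighted hardest.

```{r}
harmonic_score(rep(1, 5))
harmonic_score(c(1, 0.9, 1, 1, 0))   # any zero annihilates
```

### Homozygous pairs

The two alleles of a homozygous pair have no reads exclusive to one of
them, which would zero `asm` and make homozygotes uncallable whenever more
than one candidate survives. We therefore measure a homozygous pair's
exclusivity against the union of *all other candidate alleles* of the
locus, count it once, and set `req = 1` (perfectly balanced by
definition). Counting it once — rather than doubling it like the
heterozygous `asm_a + asm_b` — is what keeps the comparison honest: for a
true heterozygote a/b, the spurious homozygous candidate (a,a) carries
half the exclusive evidence of (a,b) and loses; for a true homozygote the
mixed pairs (a,x) die on `req = 0` and (a,a) wins. Doubling instead makes
(a,a) tie with (a,b) for heterozygous truths, with `req` then tipping the
score towards the false homozygote; we verified this failure mode in
simulation before fixing the definition.

### Scaling choice and a degenerate case

Scaling is divide-by-max rather than min–max: min–max would force the
worst pair's parameter to 0 and annihilate its score merely for ranking
last. A parameter whose maximum over the locus is 0 scales to 0 for every
pair, making all scores 0; ranking then falls back to deterministic
name order and the tie set is reported as alternatives. This arises only
in degenerate geometries (e.g. exons so short that no mate pair ever
co-maps, zeroing `mppr` locus-wide) and never under the capture design
this package models.

### Alternatives and flags

Alternatives are the pairs genuinely indistinguishable from the best call:
identical per-allele read support sets, plus exact score ties. No epsilon
window is used — a tolerance window would inflate ambiguity counts
arbitrarily. Flags: `low_coverage` (best pair's raw auc < 0.5, manual
review advised), `low_read_count` (fewer than 7 million reads — 3.5
million pairs — in the sample; warning only), `no_call` (no candidate
survived filtering).

### Erroneous reference alleles

When the best-scoring allele is itself wrong in the database — the classic
case being two alleles separated only by two nucleotides 32 and 34 bases
upstream of an exon 3′ end — the giveaway is the *shape* of the coverage
collapse: every position from the first differing base to the boundary is
unreachable by any admissible read from the true allele, so the profile
shows a zero-coverage segment abutting the boundary while the rest of the
exon is covered. `discriminate_boundary_variant()` reports exactly these
per-exon gap segments; `make_erroneous_reference_fixture()` reconstructs
the scenario synthetically. Boundary abutment is judged with a 3 bp
tolerance: a junction-crossing read whose first intron base coincidentally
equals the next cDNA base extends its perfect match a base or two across
the boundary (probability $4^{-k}$ for $k$ extra bases), so an
exact-abutment rule would intermittently miss real gaps.

## Bait design

The capture panel starts as a non-overlapping 120 bp tiling of the
genomic reference haplotypes; a trailing window shorter than the bait
length is covered by one extra bait anchored at the 3′ end (the
alternative — leaving tails unbaited — would violate the design's
completeness goal). Each gDNA of the allele collection, then each
stand-alone exon of the cDNA collection, is scanned in input order against
the current panel (ungapped Hamming placement, both strands, up to 5
mismatches — capture tolerates mismatches, not gaps); any uncovered run of
at least one bait length is tiled from that sequence's own bases and the
new baits appended. The procedure guarantees by construction that no input
retains a fillable gap, the reported panel size counts distinct bait
sequences, and identical inputs in identical order give byte-identical
panels. Exons shorter than a bait that are not already contained (within
the mismatch budget) in an existing bait are recorded as warnings rather
than silently skipped.

The mismatch scan is implemented as an exact pigeonhole seed-and-verify:
a 120-mer within 5 mismatches of a bait must contain one of the bait's 6
disjoint 20-mer chunks exactly, so exact chunk hits (one multi-pattern
pass per target) followed by direct Hamming verification reproduce the
full per-offset scan at a fraction of the cost. Unit tests compare it
against a naive per-offset character-comparison oracle.

## Benchmark panel selection

`select_diverse_panel()` reduces a large reference collection to a small
panel still carrying every distinct allele: per restart, samples are drawn
uniformly without replacement and kept only if they contribute an unseen
allele, stopping at full coverage; the smallest pool over all restarts
wins (ties to the first found). Restart `r` uses `seed + r - 1`, making
runs reproducible at any restart count. On small instances the pool
matches brute-force minimum set covers; at scale it is a cheap randomised
approximation, which is all the sample-logistics use case requires.

## The synthetic data generator

Because real IMGT collections and benchmark cell lines cannot ship with a
package, every stage is exercised against a synthetic model designed to
reproduce the *hard* features of the real problem:

* per locus, a random founder cDNA partitioned into exons (default 3
  exons of 140–260 bp), from which each allele derives by exactly 5
  substitutions at random positions — so alleles are pairwise distinct
  but highly similar, and reads cross-map pervasively;
* genomic constructs per allele — exons separated by random introns
  (150–300 bp, never shorter than a read) and bracketed by 300 bp flanks,
  shared across the alleles of a locus as in a real gene — so
  boundary-truncated reads arise at realistic rates;
* error-free or substitution-noised 100 bp paired reads from uniform
  150–300 bp fragments, with a per-read truth table recording the cDNA
  placement each mate must produce under the mapping rules.

The fragment count per allele copy is derived from the target unique
start-point depth by inverting the start-occupancy saturation
`depth/2 = read_len * (1 - e^{-n/U})`, with 15% headroom for collisions.
At the default depth of 50 the observed/ideal coverage ratio is ~0.25 —
deliberately far from saturation, so the `low_coverage` flag fires on
simulated samples; the flag is advisory and the calls themselves are
tested to be correct.

What the generator does **not** model: capture efficiency bias, PCR
duplicates (start-point reduction is still exercised, by fragment-start
collisions), indel sequencing errors (the mapper is perfect-match; indels
only lose reads), quality scores, and real IMGT nomenclature quirks
(partial sequences, chimeric entries are supported only as explicit
exclusion lists). Passing the simulated benchmarks therefore demonstrates
the correctness of the algorithmic chain, not performance on degraded or
contaminated libraries.

## Problem sizes and numerical choices

The shipped benchmarks use 8 loci × 20 alleles at ~600 bp cDNA — compact
enough to run a few hundred full calling rounds in minutes while keeping
every structural difficulty (near-identical alleles, multi-mapping,
boundary truncation, homozygotes). The recovery benchmark draws 100
random genotypes per locus with replacement (so ~5% homozygotes) at depth
50 and requires the true pair at rank 1. Determinism everywhere comes
from a single master seed with arithmetic derivation of child seeds;
ranking ties break lexicographically by allele name; all coordinates are
0-based half-open throughout.

## Limitations

Novel alleles absent from the reference cannot be called — at best they
surface as boundary-shaped coverage anomalies on their nearest neighbour.
Loci are called independently; no cross-locus phasing. The caller's
absolute `auc` threshold presumes the ideal-profile normalisation above;
a different duplicate-removal policy would need a matching ideal.
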