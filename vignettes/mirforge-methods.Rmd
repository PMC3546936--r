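---
title: "mirforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer would want written down.
All empirical statements here are computed by the test suite or the
acceptance script; nothing is asserted that the code does not check.

## The analysis in one paragraph

A size-selected (16–30 nt) small-RNA library from pooled fish tissues is
collapsed into unique tags with copy counts, screened against an
rRNA/tRNA/snoRNA/snRNA reference, and mapped to a genome (and, where the
species lacks one, EST/GSS contigs). Tags matching a known-mature
catalogue within one substitution are conserved miRNAs; the rest are
candidate novel miRNAs if a window around their locus folds into a
stem-loop with at least 18 base pairs that confines the tag to one arm.
Calls are then characterized: isomiR decomposition (end shifts, internal
substitutions, 3′ non-template additions), dominant Drosha/Dicer cleavage
sites, miRNA:miRNA\* duplexes with 2-nt 3′ overhangs, seed-conservation
profiles, `2^−ΔCt` tissue expression with two-way hierarchical
clustering, and antisense target prediction.

## Folding: base-pair maximization, not thermodynamics

The hairpin criterion in this workflow is stated in *paired bases* — a
stem-loop with 18 or more base pairs — which a Nussinov-style
maximization tests directly. `predict_structure()` therefore maximizes
the number of AU/GC/GU pairs with a minimum loop of 3, and among
max-pair structures prefers the best weighted pair score
`E = −(3·GC + 2·AU + 1·GU)`; both objectives are folded into one integer
DP (`1000·pairs + weight`, exact while `3n/2 < 1000`, guarded at
n ≤ 600). Remaining ties are resolved by a fixed traceback (prefer the
3′ base unpaired, then the 5′-most partner), so results are
deterministic. The same weighted score stands behind `fold_energy()` and
the target `duplex_score()`; a thermodynamic engine could be slotted
behind either contract without touching callers. The default acceptance
threshold `energy_threshold = −25` corresponds to roughly ten GC-average
pairs and is deliberately permissive: the pair-count and arm criteria do
the discriminating. GU wobbles count toward the 18 pairs (configurable
in spirit; the pair table is one function).

An independent memoized recursion (decomposing on the left end, written
in the test helpers) recomputes optimal pair counts for every sequence
up to 60 nt; the test suite and acceptance checks require exact
agreement, and also verify that each reported structure is well-formed,
achieves the reported count, and respects the loop minimum.

**Tag-in-one-arm.** On real windows, maximization produces a few spurious
pairs beyond the planted stem, so demanding that *every* tag partner lie
on one side rejects genuine hairpins. The implemented rule is a majority
rule: at least 12 tag bases must pair to one side, with at most 3 tag
bases pairing the other way or within the tag. Planted stems give 18–21
consistent pairs, comfortably inside; a tag folded inside a random
window pairs in mixed directions and fails.

## Mapping and annotation

The mapping rule is substitution-only (no indels), with at most one
mismatch inside the tag's first 18 bases and one overall, both strands,
all loci reported (cap 10 per tag, flagged beyond). 18 nt covers most of
a 21–23 nt tag; the seed length and both tolerances are arguments.
Candidate search is delegated to `Biostrings::matchPattern`; the seed
bookkeeping (mismatch positions mapped back to tag coordinates on the
minus strand) is the package's. An exhaustive all-window scan in the
test helpers re-derives the rule position by position; `map_tags()` must
match it exactly at 200 tags × 50 kb. Coordinates are 1-based inclusive
on the forward strand, round-tripping losslessly through the
`ref:start.end:strand` table format (the parser also accepts the
published tables' unicode colon/minus and stray spaces); BED export is
0-based half-open.

The ncRNA screen is the same machinery with the tag as a substring of
the reference (≤ 1 substitution, either strand). Class ties break by the
fixed priority rRNA > tRNA > snoRNA > snRNA > other, for reproducibility.

## Novel calling and the strand question

A hairpin's reverse complement is also a hairpin, and a mature-arm read
maps antisense onto its own star arm. Grouping leftover-tag loci by
strand therefore duplicates every precursor region; `call_novel()`
groups loci per reference *ignoring strand* (gap ≤ 40 nt, which merges
the two arms across a 9–14 nt loop) and lets the most abundant tag's
locus pick the excised strand. Windows containing a catalogue mature
(≤ 1 substitution, either orientation) are precursors of conserved
miRNAs — their opposite-arm tags are miRNA\* candidates, not novel calls —
and are screened out when a catalogue is supplied. Excision uses two
asymmetric windows, tag − 10 … tag + 70 and the mirror image; 70 nt
covers published precursor spans (≈ 45–85 nt).

## isomiR decomposition

Each tag is aligned ungapped at every start within ± 5 nt of the
reference mature 5′ end. For each start, the maximal trailing run of
mismatches (≤ 3 nt) is the non-template tail candidate; remaining
mismatches are internal substitutions; the start minimizing internal
substitutions wins (ties: shorter tail, then smaller |5′ offset|). A
trailing mismatch followed by matching bases is a substitution, never a
tail. Tails longer than 3 nt are indistinguishable from mis-mapping at
these read lengths and are not modelled. The decomposition is exactly
invertible (templated span + substitutions + tail reproduces the tag),
and the suite round-trips every simulated record. Substitution spectra
are reported both read-weighted (the convention behind published
percentages) and tag-weighted, since the weighting is rarely stated.
Cleavage sites are read-weighted modes of the end offsets, ties broken
toward the reference end (offset 0, then smaller |offset|, then the
5′-extended side).

Conservation profiles use pairwise global alignment of each sequence to
a designated reference (match +1, mismatch −1, linear gap −2, via
`Biostrings::pairwiseAlignment`) instead of a multiple alignment:
deterministic, and sufficient for per-column identity and seed-identity
claims.

## Expression

`2^−ΔCt` is computed per reaction and averaged over replicates (the
alternative, exponentiating the mean ΔCt, is an option); adding any
constant to all Ct values cancels exactly. The clustering default —
1 − Pearson correlation of log₂ values, average linkage — follows the
defaults of the heatmap software this kind of study uses; the study
itself states neither, so both distance and linkage are arguments.
Rows are sorted by label before agglomeration, making the merges
invariant to input order; constant rows (undefined correlation) get unit
distance with a warning. Tissue specificity is the fraction of a
miRNA's total expression in its top tissue, flagged at ≥ 0.5.

## The synthetic study

The generator's defaults are the study conditions the rest of the
package is tested under: 5 novel + 3 catalogue precursors planted on
3 chromosomes (≈ 12 kb), 10,000 reads, 10% ncRNA contamination, 3%
unmappable background, star fraction 0.15, per-read substitution
probability 0.05, 3′-tail probability 0.10 with base weights
A 0.45 / U 0.41 / C 0.14 / G 0 (the A > U > C ordering and magnitudes
follow the published 3′-addition counts for the most abundant miRNA),
end-shift distribution 80% canonical with ± 1 at 8% and ± 2 at 2%, and
arm lengths 20–23 nt matching the published 21–23 nt length mode.
Precursors are built to spec: the star arm is the reverse complement of
the mature's first L−2 bases plus two free bases, giving an 18–21 bp
stem and 2-nt 3′ overhangs at both duplex ends. Catalogue members of
the same family are sequence relatives — identical seed, two
substitutions in the 3′ half — so family aggregation and seed
conservation operate on real structure. Ten tissues are profiled in
triplicate; the first profiled miRNA carries a planted stomach effect of
5 Ct (32-fold), the designed tissue-specific case.

Two deliberate design choices keep ground truth exact:

* **Edits are per-read i.i.d.**, so realized rates are binomial and the
  3-SE recovery checks are well-calibrated; copy counts emerge from
  sampling reads from precursors with geometric expression weights
  (long-tailed, so singletons exist for the min-copies filter), and the
  uniform background supplies guaranteed singletons.
* **Tails are non-templated by construction**: the five bases following
  each arm's 3′ end are set to the zero-weight tail base, so a planted
  tail can never be read as templated extension — except when the tail
  sits on a 3′-*trimmed* end, where it faces arm sequence; that inherent
  ambiguity affects ≈ 0.3% of reads, the classifier returns the other
  minimal decomposition, and the recovery tests' tolerances absorb it.
  Planted substitutions are internal (positions 3 … len−3) so they never
  masquerade as tails or shifts.

What the generator does **not** emulate: realistic base-call error
profiles and quality scores (constant quality is written), PCR
duplication, expression-dependent ligation bias, genomic repeats, or
multi-isoform precursors. Passing tests therefore demonstrate that the
*rules* are implemented exactly and recover planted structure under
clean conditions — not that the pipeline is robust to instrument
artifacts.

## Problem sizes and determinism

The suite and the acceptance script run at desk scale by design: 10,000
reads, ≈ 12 kb genome, 50 kb mapping-oracle references, ≤ 60 nt folding
oracles. These sizes make every oracle comparison exact and exhaustive
while the whole suite stays in the minutes range. All randomness flows
from a single integer seed (stage seeds are derived as seed + 1,
seed + 2), and equal seeds give byte-identical outputs, which the suite
asserts.

## Known limitations

* The folding model has no stacking, bulge or dangling-end energetics;
  18 required pairs plus the arm rule, not the energy threshold, carry
  the specificity.
* Substitution-only mapping cannot place tags over indels or splice
  junctions.
* "Low-quality read" filtering is undefined in this protocol and is off
  by default (a mean-quality threshold can be added upstream of
  trimming without touching the accounting contract).
* The published spectra (e.g. substitution-class percentages) depend on
  the undeposited reads; the pipeline reproduces the computations and
  verifies them on synthetic truth instead.
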