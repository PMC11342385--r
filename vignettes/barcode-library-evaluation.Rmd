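---
title: "Evaluating species discrimination in a barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating species discrimination in a barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA barcoding identifies a specimen by matching a short sequence against a
reference library of labelled sequences. This works only when every species
in the library is separated from every other by more sequence variation than
occurs within species. Short markers used in environmental-DNA metabarcoding
— such as the hypervariable ~170 bp "MiFish" window of the mitochondrial 12S
rRNA gene — amplify more reliably than longer fragments but carry fewer
variable sites, so before trusting them one must audit the reference library
itself: which species are discriminable, which collapse together, and which
sit close enough to a neighbour that identifications deserve caution.

`barcodeval` implements that audit as a reproducible pipeline: pairwise
distances, neighbour-joining (NJ) trees, a deterministic
Match/Split/Merge/Mixture classification of every species, a distance-based
caution threshold, in-silico excision of a nested subregion by primer
matching, and a sequence-evolution simulator that generates whole reference
libraries with known ground truth so every stage can be validated without
any external data.

## The evaluation procedure

### Distances

Every pair of sequences is globally aligned (Needleman–Wunsch with affine
gaps, implemented in C++; ties in the traceback prefer the diagonal move so
results are deterministic). Columns holding a gap or an ambiguity code in
either sequence are excluded per pair (*pairwise deletion*). From the
remaining $L$ columns we count the proportions of purine transitions $P_1$
(A$\leftrightarrow$G), pyrimidine transitions $P_2$ (C$\leftrightarrow$T)
and transversions $Q$, plus base frequencies pooled over both sequences.

Two distances are derived in one pass:

* the uncorrected **p-distance** $p = P_1 + P_2 + Q$, used for thresholding
  (its raw integer mismatch count is kept as the authoritative substitution
  count);
* the **Tamura–Nei (TN93)** distance,
  $$d = -\tfrac{2 g_A g_G}{g_R}\ln\!\Big(1-\tfrac{g_R P_1}{2 g_A g_G}-\tfrac{Q}{2 g_R}\Big)
        -\tfrac{2 g_T g_C}{g_Y}\ln\!\Big(1-\tfrac{g_Y P_2}{2 g_T g_C}-\tfrac{Q}{2 g_Y}\Big)
        -2\Big(g_R g_Y-\tfrac{g_A g_G g_Y}{g_R}-\tfrac{g_T g_C g_R}{g_Y}\Big)\ln\!\Big(1-\tfrac{Q}{2 g_R g_Y}\Big),$$
  used for tree building. When a logarithm's argument is non-positive
  (saturation) the entry is flagged undefined; tree building then refuses it
  or the caller falls back to p-distance, with a warning.

With equal base frequencies and $P_1 = P_2$ the TN93 expression reduces to
the Kimura two-parameter distance — the package's tests verify that limit
algebraically, and verify $d \ge p$ wherever $d$ is defined.

### Trees and clusters

The NJ tree is built from the TN93 matrix with `ape`'s classic Saitou–Nei
implementation. Negative branch-length estimates (a known artifact of the
least-squares formulas) are clamped to zero with the deficit added to the
sibling branch, so downstream path-based logic never sees negative lengths.
Identical sequences are retained as separate leaves. Bootstrap supports
(column resampling of a progressive multiple alignment, recomputing
distances and NJ per pseudoreplicate, counting bipartition recovery on the
reference tree) are available but deliberately optional: supports describe
confidence in edges and do not enter the classification.

### Categories, the single-specimen rule, and the threshold

The published category scheme scores each species by how its sequences fall
into operational taxonomic units (OTUs) of the tree. Where the original
procedure judged OTUs by eye, `barcodeval` fixes a deterministic rule: two
leaves belong to one OTU iff (a) their distance is at most
`identity_epsilon` (default 0 — exact haplotype sharing), or (b) they form a
clade with no heterospecific leaf inside (computed unrooted-safely by
rooting at a heterospecific leaf). For a species with $k$ maximal pure
clusters:

| category | condition |
|---|---|
| Match   | $k = 1$ and no haplotype shared with another species |
| Split   | $k \ge 2$, nothing shared |
| Merge   | $k = 1$, haplotype shared |
| Mixture | $k \ge 2$ and shared |

Split, Merge and Mixture are failures. A single-specimen species cannot be
judged by clustering; it fails only when its sequence is carried by another
species, and is otherwise judged by distance alone. A species that passes
gets **caution** rather than success when its nearest heterospecific
distance is positive but does not exceed the threshold (default 0.01
substitutions/site, p-distance); a distance of exactly 0.01 is a caution —
success strictly requires exceeding the threshold. Raising the threshold can
therefore only move species from success toward caution, never the reverse
(a monotonicity the tests exercise).

The 0.01 default reflects the empirical regime of mitochondrial 12S in
closely related fish: most multi-sequence species vary by less than 0.01
within species, so a heterospecific neighbour inside that band is within the
noise floor of intraspecific variation.

### Curation screen

Reference libraries accumulate mislabelled and chimeric deposits. The screen
flags — never removes — sequences whose nearest conspecific exceeds
`max_conspecific_dist` (default 0.05) or whose nearest neighbour belongs to
a different genus while conspecifics exist. Exclusion is a human decision
recorded in the metadata table; the default threshold deliberately sits well
above typical intraspecific variation so that genuine deep splits (which do
occur, up to ~0.026 in this marker) are surfaced for review rather than
silently dropped.

### Subregion excision

The shorter marker is excised from the longer fragment in silico: each
primer is matched against the sequence as an IUPAC-degenerate pattern (a
primer symbol matches a target base when the base is in the symbol's set),
the best hit being the offset with fewest mismatches, ties to the smallest
start. The reverse primer, given antisense 5'→3', is reverse-complemented
before matching. The excised region runs *between* the primer sites
(primers excluded), consistent with reported subregion lengths being
insert-only. Up to `max_mismatch` mismatches (default 3 for ~20-mers) absorb
natural variation in the conserved flanks. Fragments lacking a primer site
can fall back to `anchor_trim()`, which aligns the fragment to a trusted
subregion exemplar and takes the spanned interval, requiring 80% coverage.

The MiFish inner primer sequences themselves are configuration: users
reproduce a real excision by supplying the published primer pair of their
marker. The simulator plants its own synthetic primer pair.

## The simulator

`sim_barcode_library()` generates a library whose statistical structure
matches what the evaluation assumes, with every planted feature recorded as
ground truth:

* a pure-birth (Yule) species tree rescaled so the mean tip-pair path equals
  twice `interspecific_depth` (default 0.05 substitutions/site); genus
  blocks are carved from the tree's own clade structure (average-linkage
  clusters at half the mean path), so per-genus summaries are exercised and
  congeners are genuinely related;
* sequences evolve along the tree under TN93 (defaults: frequencies
  A 0.32, C 0.26, G 0.19, T 0.23; transition/transversion factors 4:4:1;
  matrix normalized to one expected substitution per site per unit length).
  TN93 is chosen as the generating model precisely so the TN93 estimator is
  matched — enabling parameter-recovery tests (mean estimates at true
  divergences 0.01–0.15 are required to sit within 10% relative bias);
* one hypervariable core (length drawn once per run from 166–199 nt) evolves
  1.5× faster. The factor is set from the empirical contrast between the two
  markers: intraspecific variation is proportionally similar in the short
  window and the full fragment (≈0.004 mean p-distance in both), while
  congeneric divergence in the window runs modestly higher (maxima ≈0.25
  versus ≈0.18), so a mild acceleration — not an order of magnitude — is
  what "hypervariable" means at this scale. Together with the intraspecific
  depth of 0.002 this keeps the mean conspecific difference near 3
  substitutions per 750 nt and most multi-sequence species below the 0.01
  threshold, the regime the defaults are required to emulate; the two
  flanking primer sites are invariant by default
  (`primer_rate_multiplier = 0`), mimicking conserved rRNA stems and keeping
  excision testable independently of alignment quality. A stress switch lets
  primer sites mutate;
* each individual evolves an extra branch of `intraspecific_depth` (default
  0.002) from its species tip — a star genealogy per species, which is
  sufficient for the properties tested and deliberately simpler than a
  coalescent;
* sequence counts per species: singletons with probability 0.647, otherwise
  $2 + \mathrm{Poisson}(1.85)$ capped at 20. With 150 species this yields
  roughly 300 sequences, about two thirds of species represented once — the
  composition of the reference collections this package targets;
* events: *introgression* replaces chosen recipient individuals' sequences
  with copies of one donor haplotype (modelling a recent mitochondrial
  sweep, so introgressed sequences are identical to the donor's — which is
  what makes the expected category well-defined); *identical injections*
  copy a haplotype verbatim across a species pair. The default `"auto"`
  event set plants two partial congeneric introgressions plus one identical
  injection between congeneric singletons, mirroring the handful of
  known introgressed and unresolved pairs in real damselfish libraries, so
  a default 150-species run carries six expected failures (~96% expected
  discriminability).

Ground truth records an expected category per species. For event
participants whose tree-side outcome genuinely depends on where NJ places
zero-length branches, the truth stores the admissible set (`"Merge|Mixture"`)
and recovery is scored by membership.

What the simulator does **not** model — and hence what passing tests do not
show about real data: within-species coalescent structure, rate variation
beyond the three site classes, sequencing error, alignment ambiguity from
length-variable loops (lengths are constant per run; the 725–773 nt spread
of real deposits comes from trimming decisions the generator does not
imitate), numts, and taxonomic error other than the planted events. Real
libraries should additionally pass through `curation_screen()` and human
review.

## Numerical choices

* Alignment scores: match 2, mismatch −1, gap open 12, gap extension 1 (a
  gap run of length $L$ costs $12 + L$). The gap opening is deliberately
  heavy relative to the mismatch penalty: with these values, replacing a run
  of consecutive mismatches by a pair of compensating gaps only pays off
  beyond 24 mismatches, so divergent blocks are not spuriously excised from
  the compared sites. Any scheme with `match > -mismatch` and non-negative
  gap penalties is accepted; the exhaustive-search oracle in the tests is
  scheme-agnostic.
* IUPAC handling: in alignment, symbols match when their sets intersect; in
  distance computation, non-ACGT symbols are excluded with the column
  (pairwise deletion); in primer matching, the target base must lie inside
  the primer symbol's set.
* Substitution counts are kept as raw integers (the proportion × $L$
  rounding is only a consistency check); percentages are reported to one
  decimal.
* Ties: alignment traceback prefers diagonal, then the gap consuming the
  first sequence; primer hits prefer the smallest start; NJ tie-breaking is
  delegated to `ape`'s deterministic implementation.
* Degenerate inputs: empty sequences, pairs with no comparable sites, trees
  under 3 leaves, species absent from the tree, and undefined TN93 entries
  all raise informative errors rather than propagating silently.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale: oracle checks use sequences of length ≤ 8 and trees of ≤ 10
leaves (exhaustive enumeration), recovery checks use 20–30 species across
20 seeds, and the headline runs use the default 150-species /
183-species configurations — a few minutes of compute in total on one core.

## Known limitations

* The OTU rule is a formalization; a human reading a tree may merge
  near-identical clusters that the rule (at `identity_epsilon = 0`) keeps
  apart. Raising `identity_epsilon` approximates more permissive readings.
* TN93 saturation produces undefined distances; the package surfaces them
  rather than guessing. For deeply diverged libraries a different marker or
  model is the right fix.
* The progressive MSA is adequate for the near-identical, rarely indelled
  sequences this marker produces; it is not a general-purpose aligner.
* Bootstrap supports annotate the reference tree's bipartitions only; no
  consensus tree is built.
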