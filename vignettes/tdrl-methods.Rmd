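---
title: "Methods: enumerating equivalent TDRL rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumerating equivalent TDRL rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrlkit)
```

## The model and its assumptions

`tdrlkit` analyses unichromosomal circular genomes — typically animal
mitochondrial genomes — under the tandem duplication random loss (TDRL)
rearrangement. The model makes three assumptions, all standard for
mitochondrial gene-order analysis:

* no gene is duplicated in the observed genomes and genes do not overlap,
  so a genome is a permutation of `n` distinct labels;
* the genome is circular, so a gene order is a *rotation class* `π°` with
  `n` linear representatives `π_p`, one per start gene `p`;
* gene orientation is ignored: a TDRL duplicates and deletes but never
  inverts, so strand signs carry no information about the event (the
  parser strips them with a notice).

A TDRL is the triple `(F, S, p)`: duplication starts at origin `p`,
`F`-genes survive in the first copy of the duplicated intermediate,
`S`-genes in the second. Its action on `π°` rearranges `π_p` into the
`F`-genes followed by the `S`-genes, each sub-sequence keeping its
relative order. The two labelings `(F, S, p)` and `(S, F, p)` produce the
same circular result; both are enumerated and reported, because the
*biological* interpretation (which copy decayed) differs.

All positions are 1-based and the origin is a gene label, not a numeric
position; this keeps triples stable when an order is re-rotated or genes
are renamed.

## Distances

For a fixed pair of linearizations, the minimum number of unit-cost
whole-genome TDRLs that sorts one into the other is `⌈log₂ k⌉`, where `k`
counts the maximal value-consecutive increasing substrings of the
relabeled permutation (`relabel_by_target()` then
`increasing_substring_count()`): one TDRL can at best halve `k`. Because
an unfavourable linearization can overestimate the true circular
distance, `circular_tdrl_distance()` minimizes the linear distance over
all `n × n` representative pairs. The distance is directed; pairs with
`d(a,b) ≠ d(b,a)` exist (the worked length-8 example is one).

The min-over-rotations definition is validated empirically rather than
proven here: `bfs_distance_oracle()` performs exact breadth-first search
over rotation classes by applying all `n·2ⁿ` triples per state. The test
suite checks agreement for *every* ordered pair of classes at `n = 5`
(24 × 24 pairs via per-source BFS distance tables) and for 90 seeded
constructed pairs at `n = 6, 7` plus 10 arbitrary seeded pairs checked by
full search. These sizes keep the exhaustive checks exact while the whole
suite runs in well under a minute of BFS time; the formula-based distance
itself is polynomial and handles the 38-marker case instantly.

## Enumerating equivalent TDRLs

For a pair at distance one, `enumerate_tdrls()` uses a descent scan
instead of the `2ⁿ` subset search: for each origin `p`, each of the `n`
target linearizations is mapped into the position space of `π_p`; a
linearization contributes a triple exactly when that position sequence
has a single descent, and the cut at the descent determines `F` and `S`
uniquely. This is `O(n²)` triples tested with `O(n)` work each, feasible
at mitochondrial scale, and it reproduces the theoretical count of `2n`
triples (two per origin, mutual F/S swaps). Completeness is tested by set
equality against `brute_force_enumerate()`, which applies all `n·2ⁿ`
triples, for every test pair with `n ≤ 8`.

Equal orders are a special case: every triple fixing the order is an
identity map, and there are `2n²` of them — per origin, the `n + 1`
prefix cuts of `π_p` and their swaps, minus the two triples shared
between the families. These are enumerated directly and brute-force
verified for `n ≤ 8`.

Output order is deterministic (origins along the source's canonical
rotation; the labeling with the origin in `S` — the "direct" labeling —
before its swap), so TSV and SVG outputs are byte-reproducible, which the
tests assert literally.

## Minimal partial-duplication windows

Every whole-genome triple is equivalent to a partial duplication that
copies only the contiguous window of `π_p` from the first `S`-gene to the
last `F`-gene; genes before the window are untouched `F`-members, genes
after it untouched `S`-members. `minimal_partial()` applies this rule;
an exhaustive oracle (`window_size_oracle()`, simulating every contiguous
window) confirms minimality on all enumerated triples at `n ≤ 8`. Two
boundary decisions:

* The rule is defined per *labeled* triple, and the two labelings of an
  origin generally give different windows. Matrix renderings display the
  smaller-window labeling (ties: smaller `|F|`, then lexicographically
  smaller `F`); per-origin duplication cost is the smaller of the two,
  and `minimum_duplication_set()` selects the origins attaining the
  global minimum.
* Identity maps rearrange nothing, and the window rule is only meaningful
  for proper rearrangements: an identity triple whose `F` is a circular
  *suffix* of `π_p` would formally receive a full-genome window. The
  enumeration never produces identity triples in the distance-one case,
  and the window-oracle property is therefore quantified over
  non-identity triples.

`partial_to_whole()` implements the reverse correspondence (`F = S′`,
`S = N ∪ F′`, origin = the gene following the window) and is tested to
reproduce the original action.

## Constraint filters

Two user-suppliable constraint types restrict the enumeration:

* **Conserved groups** — a set `G` passes a triple iff `G ⊆ F` or
  `G ⊆ S`, i.e. the whole group is lost from one copy and therefore kept
  contiguous. Singletons pass trivially; adding groups can only shrink
  the passing set (tested as a monotonicity property).
* **Intergenic pairs** — an intergenic region between adjacent genes `x`
  and `y` of the derived genome is explainable as a duplication remnant
  iff some gene `z` has a lost copy between `x` and `y`. With positions
  taken in `π_p`: if `x` and `y` survive in different copies, any gene
  strictly between them qualifies; if they survive in the same copy, a
  gene of the opposite set must lie strictly between them. *Betweenness
  is evaluated on the unordered positional interval of the single
  representative `π_p`.* A plausible alternative — measuring arcs on the
  `2n`-element duplicated intermediate itself — is rejected because it
  contradicts the same-copy case analysis that makes the two formulations
  agree on worked instances; the `π_p` interval reading is the one under
  which both filters are invariant under F/S relabeling (tested).
  When `x` and `y` are not adjacent in the target the filter still
  evaluates but warns, since the framed region then contains genes.

Both filters are reported per triple and per constraint (with a witness
gene `z` for intergenic passes) rather than silently dropping rows, so a
user can distinguish "fails one group" from "fails all".

## Synthetic data

The seeded generators back the property tests and are pure functions of
their parameters and seed:

* `random_circular_order(n, seed)` draws a uniform rotation class (a
  uniform permutation induces one); uniformity over the `(n-1)!` classes
  is tested at `n = 4` with 10⁴ draws against a ±3-standard-error band.
* `random_d1_pair(n, seed)` applies a random non-identity triple (each
  gene assigned to `F` with probability ½, origin uniform; identity maps
  rejected and redrawn) to a random order. By construction the directed
  distance is exactly one — the resulting class differs and one event
  suffices — which the BFS oracle re-verifies for `n ≤ 7`. An `identity`
  flag produces the distance-zero case deliberately.

These fixtures emulate the *combinatorial* situation the enumerator
faces — every possible bipartition and origin at realistic mitochondrial
`n` — but not real data's failure modes: annotation disagreements
(missing or extra genes between genomes), duplicated genes, or pairs
more than one event apart. Passing tests therefore certify the
combinatorics, not the upstream annotation; `project_shared()` exists
precisely for the first failure mode and errors/warnings are tested for
the rest.

## The mitochondrial case study

The bundled 38-marker example (`inst/extdata/psocoptera_pair.fa`)
contrasts the ancestral Pancrustacea mitochondrial gene order (as in
*Prionoglaris stygia*; 37 genes plus the control region) with the
rearranged order shared by the Trogiomorpha barklice *Lepidopsocidae sp.*
and *Dorypteryx domestica*. The derived record is **reconstructed, not
downloaded**: `reconstruct_targets()` exhaustively searches all
block-respecting single-TDRL images of the ancestral order (15 blocks:
six known conserved segments plus nine singleton markers; every block
rotation × every bipartition of blocks) for images whose maximal
conserved segments are *exactly* the six known shared segments. Block
granularity is sufficient: a cut inside a conserved block would separate
its genes in the image. The search returns a **unique** rotation class,
and two quantities that played no role in the search corroborate it — the
enumeration of the pair gives an origin-`cox2` TDRL duplicating 34 of 38
markers and a global minimum of 29, matching the published analysis of
these genomes. A test regenerates the bundled record from the segment
file and asserts uniqueness.

```{r case-study, eval = FALSE}
orders <- read_gene_orders(system.file("extdata", "psocoptera_pair.fa",
                                       package = "tdrlkit"))
enum <- enumerate_tdrls(orders[[1]], orders[[2]])
glance(enum)                       # 76 = 2n equivalent TDRLs
min(minimum_duplication_set(enum)$window_size)   # 29 duplicated markers
```

## Degenerate inputs, tie-breaks, defaults

* Canonical stored rotation: starts at the smallest label (numeric order
  when all labels are unsigned integers, C-locale otherwise) — gives
  deterministic equality, ordering and rendering.
* Empty `F` or `S` is representable (required for the `2n²` identity
  count) but `partial_to_whole()` and matrix rendering reject the
  degenerate cases with explicit errors.
* `enumerate_tdrls()` refuses pairs at distance ≥ 2 with both directed
  distances in the message (CLI exit code 2); mismatched gene sets are a
  hard error naming the difference (exit code 3), with
  `project_shared()` as the opt-in remedy.
* Oracle guards: BFS at `n ≤ 8`, brute-force enumeration at `n ≤ 10`,
  reconstruction at ≤ 16 blocks — beyond these the exponential cost is
  no longer worth exactness and the polynomial paths are the answer.

## Known limitations

* Only the unit-cost model is implemented: distances count events, not
  duplicated genes; cost-weighted TDRL variants and multi-event scenario
  enumeration (distance ≥ 2) are out of scope — the enumeration applies
  exactly to the distance-one case.
* Loss is treated as fully random; models coupling loss to gene
  orientation or transcript structure are not implemented, though
  conserved groups can encode transcript-level hypotheses as
  constraints.
* Inversions, transpositions-as-such and DCJ are not modelled; conserved
  segments are same-direction only, which is the correct reading for
  TDRL-only histories.
* Sequence-level remnant detection inside intergenic regions (profile or
  covariance model searches) is outside the package; the intergenic
  filter identifies *candidate* TDRLs whose losses could leave a remnant,
  not the remnant itself.
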