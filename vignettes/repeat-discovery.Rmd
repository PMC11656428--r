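---
title: "De novo repeat discovery with repeatscan: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo repeat discovery with repeatscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscan)
```

## The detection model

`repeatscan` finds repeated sequence de novo, without a repeat library,
multiple alignment, or suffix structures.  The model is seed-and-extend over
exact k-mers:

1. **Seeding.**  Every N-free window of length *k* is indexed.  Two loci
   sharing a k-mer seed a *direct* repeat candidate; a locus whose k-mer
   equals the reverse complement of another locus' k-mer seeds an *inverted*
   candidate.  Seeds must be identical — sensitivity to diverged copies comes
   from the density of windows, not from inexact matching.  Inverted seed
   windows may self-overlap by at most ⌊k/2⌋ positions, which admits
   hairpins and palindromes while excluding the degenerate self-match.
2. **Extension.**  Each seed is extended in both directions as an *ungapped*
   segment pair (substitutions only, no indels — the method stays
   alignment-free).  Scoring is +1 per match, −2 per mismatch; a direction
   stops when the running score falls `xdrop` (default 10) below its running
   maximum, or at a sequence end or an N, and the endpoint is the position of
   the running maximum.  At +1/−2, sequence below ~2/3 identity cannot grow
   the score, which matches the 60% homology floor: a reported pair must
   reach `homology_floor` identity (default 0.60) over its full extent.
3. **Blocks.**  Both intervals of every surviving pair are projected onto the
   genome; intervals that overlap or touch are unioned (`merge_gap = 0` is
   the conservative reading of "adjacent"); merged blocks shorter than
   `min_length` are discarded.  Two independent length filters exist because
   they act at different stages: `initial_length` (default 50) removes short
   segment *pairs* before merging, `min_length` (default 100) removes short
   merged *blocks*.
4. **Clustering.**  Homology between blocks is evidenced two ways: a
   surviving segment pair whose sides land in different blocks (identity ≥
   the floor by construction), and the shared-k-mer similarity
   `|K(x) ∩ K(y ∪ rc(y))| / min(|K(x)|, |K(y)|)`.  The `min` denominator is
   deliberate: a short element embedded in a longer one scores high, so
   nested and overlapping blocks read as homologous.  The pair-derived edges
   matter for diverged families — two copies at 10–20% pairwise divergence
   share far fewer than 60% of their exact 12-mers, yet are connected by the
   very segment pair that discovered them.  *Quick* mode takes connected
   components (single linkage; fast, but mixed repeat types can co-cluster on
   large genomes).  *Profile* mode emits one cluster per homology
   relationship: blocks are visited in genomic order as sources, each source
   claims its not-yet-covered edges, and overlapping clusters are never
   merged, so one block may appear in several clusters.  When a source has
   homologs in both orientations the forward and inverted members form two
   linked clusters sharing a `Group` id.  Every quick cluster is a union of
   profile clusters over the same edges (refinement).
5. **Reporting.**  A cluster needs two members, or one member when the block
   is internally tandem; other singleton blocks are masked but not reported
   as clusters.

## Tandem and low-complexity structure

Microsatellites and other short-period arrays are found by direct
periodicity analysis rather than seeding: for each period *p* in
1..`max_unit` (default 10) the sequence is compared against itself shifted by
*p* in one vector pass.  Runs of lag-*p* matches are chained across short
substitution scars; the longest pure run of a chain is the *core*, the
consensus motif is read from the core, and the boundaries grow by a
maximal-scoring-segment rule in which a mismatch costs `f/(1−f)` for purity
floor *f* (default 0.8) — a segment of purity exactly *f* scores zero, so the
annotation cannot drift into random flank but crosses the scars of an
imperfect array.  Annotation purity is the fraction of positions matching the
cyclic extrapolation of the consensus motif; `detect_periodicity()`, the
windowed primitive, instead reports the autocorrelation identity
`A(p) = matches/(len − p)`, which is the natural statistic at that level.
Motifs are reported in canonical form (lexicographically smallest rotation);
a motif that is itself periodic (e.g. "AA") is rejected in favour of its
true period.  Arrays must hold at least four copies (eight bases for
homopolymers): chance two-copy matches of unit ≥ 4 occur every few hundred
bases in random DNA and would swamp the annotation.

Unit lengths 2–6 are microsatellites; units 5–10 that match a configurable
telomere motif list (default TTAGGG, TTTAGGG, TTAGG, plus rotations and
reverse complements) are telomeric; longer-unit tandem structure is
classified at the cluster level: a cluster is a `tandem_array` when two or
more same-orientation members are consecutive with a gap at most half the
median member length (a relative limit — absolute gaps are meaningless across
scales), and `higher_order` when such a tandem's members contain two or more
internal sub-repeat intervals ("repeat within repeat").

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kmer` | 12 | seed length; floor 5; 18+ recommended above 10 Mb (a warning, not an error) |
| `initial_length` | 50 | minimum aligned length of a segment pair (bases) |
| `min_length` | 100 | minimum merged block length (bases) |
| `homology_floor` | 0.60 | minimum identity of a pair / similarity of a cluster edge |
| `xdrop` | 10 | extension stop: score drop below the running maximum |
| `occurrence_cap` | 1000 | k-mer multiplicity above which pair enumeration is withheld (low-complexity k-mers go to the tandem scanner instead of generating quadratic seed pairs) |
| `purity_floor` | 0.8 | minimum purity of a tandem annotation |
| `quick` | TRUE | quick vs profile clustering |

Smaller `kmer` raises sensitivity to diverged copies (a copy pair at
pairwise identity *s* yields exact seeds at rate ~*s*^k per offset) at the
cost of quadratically more chance seeds.

## Numerical and tie-break choices

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based inclusive happens only in the GFF writer, so there is a single
  conversion point.
* IUPAC ambiguity codes other than N become N; N never seeds, never matches,
  and stops extension.
* The X-drop endpoint is the *first* position attaining the running maximum:
  score ties resolve to the shorter extension.
* For forward pairs the two intervals may touch but not cross; when the gap
  between the copies limits the total extension (tandem-like settings) the
  left direction is extended first.  Inverted extension stops before the two
  intervals would cross their common centre.
* An interior seed on the same (anti-)diagonal as an already-accepted pair
  with identity 1.0 is skipped: a fully exact cover forces the identical
  walk, so the shortcut is exact (and is exercised against a naive oracle in
  the tests).
* Sequences shorter than k give an empty report, not an error, so directory
  batches survive tiny contigs.
* Cluster representatives are the longest member (leftmost on ties); member
  orientations propagate from the representative along homology edges.

## The synthetic benchmark generator

`generate_genome()` plants repeat families with known ground truth in
uniform i.i.d. A/C/G/T background.  Divergence is substitution-only, applied
independently per copy from the ancestral unit at rate *d*, so two copies
match at a position with probability `(1−d)² + d²/3` — the closed form is
itself a test.  Planted elements keep at least `min_gap` background between
them (default 300 bp) so that distinct copies do not merge into one block.
The desk-scale benchmark used by the tests and by `scripts/acceptance.R` is a
200 kb genome with five dispersed families (copy numbers 3/2/6/4/2, unit
lengths 0.6–1.5 kb, mixed orientations) whose *pairwise* copy divergences are
0, 0.05, 0.10, 0.20 and 0.10 — each copy is mutated at half the pairwise
rate, so the most diverged family sits at pairwise identity ≈ 0.81, above
the 0.60 floor.  These sizes keep a full run under a minute while leaving
hundreds of seed offsets per copy pair even at the highest divergence.

What the generator does *not* emulate: indels (the extension model is
ungapped by design), realistic transposon sequence models, GC bias,
insertion-age structure, and N runs in the background.  Passing the planted
benchmarks therefore demonstrates the machinery — seeding density, extension
stops, merging, clustering — under the stated substitution model, not
performance on real genomes with indel-diverged families, where ungapped
extension will fragment copies at indel positions.

## Known limitations

* Substitution-only: an indel between two copies ends the ungapped extension
  there; the copy is then covered by several shorter pairs or missed if the
  fragments fall under `initial_length`.
* At pairwise divergence near 0.20 with `kmer = 12`, clustered mutations
  occasionally leave a stretch with no exact seed on any partner copy while
  X-drop stops on both sides; the copy then fragments into two or three
  blocks.  This is inherent to exact seeding and is visible as a few percent
  recall/precision fluctuation across generator seeds.
* Quick mode can merge distinct families that share a mosaic block (the
  classic single-linkage failure); profile mode is the safe choice for
  structure analysis, and copy-number-based splitting of mixed clusters is
  future work.
* Cross-record repeats in a multi-FASTA are not searched; each record is
  analysed on its own.
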