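---
title: "Writhe of all sub-chains: method, parameters, and design notes"
author: "writhescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Writhe of all sub-chains: method, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(writhescan)
```

## The quantity being computed

A protein chain is represented by the piecewise-linear curve through its
alpha-carbon atoms, traversed N-to-C.  The writhe of a space curve is the
average, over all viewing directions, of the signed number of crossings
seen in projection, with a crossing counted positive when the two
traversal directions follow the right-hand rule.  It is a real-valued,
dimensionless descriptor, invariant under rotations and translations,
and it is the lowest-order member of the family of Gauss-integral fold
descriptors.

For a polygonal curve the writhe decomposes exactly into contributions
of segment pairs.  The contribution `w(i, j)` of segments `i` and `j` is
the signed solid angle swept by the direction vector between a point
running along segment `i` and one running along segment `j`, divided by
`4 * pi`.  `writhescan` counts every unordered pair once, so

* the writhe of a sub-chain spanning segments `a..b` is
  `W(a, b) = sum of w(i, j) over a <= i < j <= b`, and
* the *mutual writhe* of two disjoint sub-chains `A` and `B` is the
  cross sum `M(A, B) = sum of w(i, j) over i in A, j in B`.

With this normalisation the mutual writhe of two closed polygons is
exactly their integer linking number, which is what makes it a motif
detector: two almost-closed loops that interlink once (a "1-link") have
mutual writhe near +-1, and a short segment poking through an
almost-closed loop contributes a large fraction of a full solid angle.
An alternative convention, common in the polymer literature, counts
ordered pairs (twice the value used here); under that convention the
cross term of two Hopf-linked rings would be +-2.  The one-count
convention is used because the method's calibration — loops interlinking
once should score +-1 — is stated on the linking-number scale.

## The all-sub-chain recursion

The package's central data structure is the writhe table: `W(a, b)` for
*every* `0 <= a <= b <= S - 1`, where `S` is the segment count.  It is
filled by inclusion-exclusion,

```
W(a, b) = W(a, b - 1) + W(a + 1, b) - W(a + 1, b - 1) + w(a, b),
```

which costs exactly `S * (S - 1) / 2` evaluations of `w` — the count is
instrumented and exposed as `n_pair_evals`.  The recursion runs in
compiled code; a chain of 1,000 residues needs a dense table of about
8 MB and well under a second.

The payoff is that the mutual writhe of *any* interval pair is four
table look-ups:

```
M(A, B) = W(A1, B2) - W(A1, B1 - 1) - W(A2 + 1, B2) + W(A2 + 1, B1 - 1).
```

Look-ups whose first index exceeds their last (empty sub-chains, which
arise when the intervals are adjacent or touch the trace ends) are
defined as 0; this makes the identity total.  The identity is verified
in the test suite against `gauss_integral_oracle()`, an independent
R-level brute-force double sum.

```{r recursion-demo}
tr <- make_random_walk(n_points = 40, seed = 1)
tab <- build_writhe_table(tr)
c(four_lookups = mutual_writhe(tab, interval(0, 9), interval(20, 29)),
  brute_force  = gauss_integral_oracle(tr, c(0, 9), c(20, 29)))
```

## Numerical evaluation of the segment-pair term

`w(i, j)` is evaluated as the area of the spherical quadrilateral
spanned by the four unit vectors connecting the endpoints of segment `i`
to those of segment `j`, split into two spherical triangles, each
computed with the atan2-of-scalar-triple-product (van
Oosterom–Strackee) formula.  This form was chosen over the classical
sum-of-arcsines expression for a numerical reason: near coplanar
geometry the arcsine arguments approach +-1, where `asin` loses half
the working precision (errors of order `sqrt(eps) ~ 1e-8`).  Synthetic
fixtures built from exact planar arcs expose this immediately once
rotated; the atan2 form keeps rigid-motion invariance at the 1e-13
level.  Remaining guards: segments sharing an endpoint return exactly 0
(consecutive trace segments never contribute), and connecting
directions shorter than 1e-12 are treated as degenerate with
contribution 0.  Both the compiled and the reference R implementation
are validated against adaptive 2D quadrature of the Gauss integrand.

## Reading structures

`parse_pdb()` keeps `ATOM` records with atom name `CA` and alternate
location `' '` or `'A'` (the standard single-conformer convention),
excludes HETATM records, and takes the first model unless
`model_policy = "all"`.  Chains are split at chain breaks, defined as a
consecutive Ca-Ca distance above 4.5 Angstrom — wide enough for trans
(~3.8 A) and cis (~3.0 A) peptide bonds while flagging genuine gaps.
Residues keep file order; all downstream indices are 0-based positions
along the resulting trace, *not* PDB residue numbers.  These are
documented defaults for situations the method itself leaves open, not
reconstructions of any particular tool's behaviour.

A note on printed interval ranges: segment intervals are half-open in
neither sense — they are inclusive segment index pairs — but report
files print *vertex* ranges, so a 30-segment window starting at segment
0 prints as `(0,30)`.  Abutting windows therefore share one vertex but
no segment, and are still disjoint for the searches.

## The searches

**Restricted search.**  A closed loop is a sub-chain of 6 to 30
segments whose terminal alpha-carbons are at most 7 Angstrom apart (all
three values are exposed as parameters).  `link_search()` scores every
disjoint loop pair by mutual writhe; values near +-1 indicate 1-links.
`poke_search()` pairs every loop with every sub-chain of exactly 10
segments (`poke_segments`), keeping the 10 most negative and 10 most
positive records — pokedness is graded, not binary, so the output is a
ranking rather than a yes/no call.

**Unrestricted search.**  `unrestricted_search()` enumerates *all*
disjoint ordered pairs of fixed-length windows (default 30 segments) at
stride 1 and keeps the `keep = 10` lowest and highest mutual-writhe
pairs.  Since each pair costs four look-ups, exhaustive enumeration is
cheap, and no stride is applied here.  This search needs no definition
of a loop, which is exactly its point: knots, pseudo-knots and
multi-winds surface as extreme values without being asked for.

**rar0 scan.**  `structure_extremes()` slides windows at a stride
(`step = 2` by default, trading 4x fewer pairs for a negligible chance
of missing an extreme by more than a window shift) and keeps the single
most positive and most negative pair per structure.
`build_background()` collects these over a structure set;
`rar0_scan()` then attaches to each query the plain empirical
exceedance frequency — the fraction of background structures at least
as extreme, separately per tail, with no smoothing, so probability 0 is
a legal result for a query beyond the whole background.  The two tails
are ranked independently because the empirical writhe distributions of
real structure sets are skewed.  The published table semantics
(per-structure extreme pair plus one-sided probability) is the default
score; a threshold-content score (summed mutual writhe of all stepped
pairs beyond `threshold = 1.0`, per sign) is available via
`score = "content"`.

## The synthetic generators

The generators exist so that every module can be exercised against
known topology without any database access:

* `make_hopf_rings()` — two *closed* polygons with linking number
  exactly +-1 (or 0 when separated); pins the normalisation.
* `make_hopf_link_chain()` — one connected trace: tail, near-closed
  ring, linker, second near-closed ring threaded through the first,
  tail.  Ring closure gap 2 Angstrom; with a 24-segment ring the
  ring-pair mutual writhe is ~0.93, inside the 1-link band.  The entry
  tail leaves perpendicular to both ring planes — a tail running along
  a ring's axis would itself thread the ring and contaminate the
  cross term, which is a useful reminder of what the statistic
  measures.
* `make_pierced_loop()` — a poke: planar near-closed ring plus a
  10-segment rod crossing the ring plane at a tunable offset.
* `make_planar_zigzag()` — exact zeros everywhere (coplanarity).
* `make_helix()` — writhe accumulating smoothly with length.
* `make_random_walk()` — the background model: a self-avoiding walk
  with 3.8 Angstrom steps, consecutive-step direction cosines drawn
  uniformly from [-0.26, 0.866] (virtual bond angles of roughly
  75-150 degrees) and a 4.0 Angstrom excluded-volume radius.  Excluded
  volume matters: an unconstrained isotropic walk collapses into
  unphysically dense coils whose window pairs reach mutual writhe
  beyond +-2, out-entangling a genuine 1-link; with the self-avoidance
  of real chains the extremes stay well below +-1, which is the regime
  real structure sets show.

What the generators do *not* emulate: secondary structure statistics,
sequence-dependent geometry, or the length distribution of real chains.
Passing tests on them demonstrates the correctness of the computations
and the calibration of the statistic on known topology — not that the
background distribution matches any particular experimental structure
set.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
curves: 200 walks of 15-60 points for the oracle sweep, traces of up to
401 points for the complexity checks (where the instrumented pair count
is asserted exactly and the 400-vs-100-segment runtime ratio is
required to sit in [12, 20] around the quadratic prediction of 16), and
a 1,000-walk background of 64-point coils for the scan check with one
planted Hopf-link query, which must rank first with exceedance
probability 0.  Every random quantity is derived from an explicit seed;
generators save and restore the caller's RNG state.

## Limitations

* The writhe of *open* sub-chains is a real number, not a topological
  invariant; near-closed is a matter of degree, and the loop definition
  (6-30 segments, 7 Angstrom) is an operational choice that can miss
  borderline loops — the unrestricted search exists to be free of it.
* No knot classification is attempted (no closure randomisation, no
  knot polynomials); knotted conformations appear only as extreme
  mutual-writhe window pairs.
* Only order-1 Gauss integrals are computed; higher-order invariants
  and the dictionary-based scan flavours built on them are out of
  scope.
* Reproducing published per-structure values for named PDB entries
  requires those coordinate files; the package ships none and performs
  no downloads, so such comparisons are left to the user
  (`parse_pdb()` + `structure_extremes()` at window 30, step 2 is the
  whole recipe).
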