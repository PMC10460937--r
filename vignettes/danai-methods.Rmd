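---
title: "Counting micro-interaction motifs in molecular liquids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting micro-interaction motifs in molecular liquids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danai)
```

## The problem

Condensed-phase MD trajectories of small halogenated molecules such as
1,1,1,2-tetrafluoroethane (HFA-134a, the pressurized propellant of metered
dose inhalers) contain a dense, disordered network of weak induced-dipole
contacts.  `danai` reduces that network to something countable: per frame it
builds an *interaction map* — a graph whose nodes are the chemically tagged
carbon centers of each molecule and whose edges are intermolecular contacts
— and then counts small topological motifs in that graph, each named by a
DANAI statement (DL_ANALYSER Notation for Atomic Interactions).  The counts
become time series whose means, deviations and mode–mode Pearson
correlations summarize the liquid's local structure.

The model system has two carbon centers per molecule, labelled in DL_F
style: `C180` (monohaloalkane carbon, the CH2F group) and `C182`
(trihaloalkane carbon, the CF3 group).

## The interaction map

Two centers are in contact when they belong to **different molecules** and
their **minimum-image distance** is at most the cutoff.

* **Cutoff, 5 Å by default.**  Small enough that no third molecule can
  straddle the pair; it is the operational definition of an induced-dipole
  contact, not a fitted parameter.  The boundary is *inclusive*
  (`d <= cutoff`); strictness is not observable on real-valued data but the
  choice is fixed and tested.
* **"Non-bonded" = different molecule.**  In a two-center molecule the only
  intramolecular carbon pair is the covalently bonded one, so molecule-level
  exclusion is exact for this chemistry and safer in general.
* **Periodicity.**  Cubic and orthorhombic cells wrap per axis; triclinic
  cells wrap fractional coordinates and scan the 27 surrounding images.
  Both are exact only below half the smallest cell width, so
  `build_contact_graph()` refuses larger cutoffs rather than silently
  producing ambiguous neighbors.
* **Neighbor search.**  All-pairs up to 500 centers, cell-list binning
  beyond; the two paths are required (and tested) to agree exactly, so the
  accelerator can never change a result.

## The DANAI grammar and its canonical forms

The parser implements the published reading rules: `[L|R|J][order]` header,
`:` for a contact, ring closure by repeating the opening species, branches
in brackets with the colon side selecting the attachment (`(X:)` binds to
the following backbone species, `(:X)` to the preceding one), uppercase for
isolation, lowercase for "may have further contacts".  Nested brackets are
rejected; mixed-case statements are accepted even though the built-in table
never uses them, because the rules define case per species.

One abstract motif has several textual readings (a chain read backwards, a
ring opened elsewhere).  `canonicalize_danai()` collapses them:

* element order ranks species by **descending numeric code**, then uppercase
  before lowercase — the published statements write `c182` before `c180`
  (`[L2]c182:c180`), which rules out plain ascending lexicographic order;
* linear chains take the smaller of the two reading directions;
* rings open at the **majority species** and place minority species as
  early as possible after the opening; this reproduces the published
  mixed rings `[R3]c182:c180:c182:c182` and `[R3]c180:c182:c180:c180`
  exactly, where a naive minimal-rotation rule does not;
* junction backbones take the minimal orientation with branches sorted.

All 20 built-in statements are canonical fixed points under these rules;
this is asserted in the test suite, which also checks idempotence and
rewriting-invariance on randomly generated statements.

## Counting semantics

Counting is a **subgraph census**: an instance is a set of nodes plus a
role assignment, counted once up to the pattern's automorphisms, with all
pattern edges present.  Extra edges among the instance's nodes are *not*
excluded for lowercase species — a triangle therefore also contains three
chains and three pairs.  This convention (rather than classifying connected
components) is what makes the published magnitudes coherent: the counts of
chains and junctions follow the `sum(choose(degree, k))` arithmetic that
`closed_form_count()` implements.

Case semantics are configurable through `semantics_config()`:

* **Uppercase** requires the node's degree to equal its role degree — i.e.
  no contact beyond those drawn.  The judging degree defaults to the *full*
  graph (`case_scope = "global"`, matching the stated "no additional
  interaction with any other species"); `"macro"` restricts it to the
  pattern's macro-class subgraph.
* **Lowercase** imposes nothing by default (`lowercase_mode = "superset"`,
  from the permissive "may interact"), so every uppercase instance is also
  counted by its lowercase twin; `"exclusive"` instead demands at least one
  extra contact.  Both conventions are implemented because the published
  tables alone cannot discriminate them; the defaults are the superset
  reading.

Macro-class restriction of motif edges is enforced through species matching:
an edge between a `C182` and a `C180` node *is* an `ID_180_182` edge, so
requiring the pattern's species on each endpoint is equivalent to an edge
lookup in the macro subgraph.  This equivalence matters for the mixed rings,
whose closing `182–182` edge belongs to a different macro class than the
ring's own grouping.

The supported family is `L2`, `L3`, `R3` and the star junctions `J4`, `J5`
— exactly the shapes of the built-in table; anything else is refused
rather than miscounted.

## The oracle

`brute_force_count()` is a second, independent implementation used as
ground truth in tests: exhaustive depth-first enumeration of ordered
node-to-position assignments checking every constraint literally, with the
automorphism group computed by enumerating position permutations.  It shares
no counting code with the fast path and refuses graphs above 200 nodes.
The acceptance suite cross-validates the two on 50 seeded random
mixed-species graphs under both lowercase conventions.

## Statistics

For each mode `i`, the mean count `mu_i` is the arithmetic mean over all
frames and the deviation is the **population** standard deviation (divide
by N; the source tables do not state a divisor, the difference is ~0.04% at
N ≈ 1250, and `"N-1"` is available).  The correlation

    C_{x-y} = <dCx dCy> / sqrt(<dCx^2> <dCy^2>),   dCi = Ci - mu_i

is Pearson's coefficient — the normalizing denominator is adopted because
the published diagonal is exactly 1.000.  A constant series has an
*undefined* correlation, reported as `NA` (written `undefined` in the CSV),
never silently 0.  Report rounding follows the published tables: 3 decimals
for means and correlations, 6 for deviations; the per-frame counts CSV is
exact.

## What the synthetic generator does (and does not) emulate

`generate_liquid()` draws the stated world of the study system: 1000
two-center dimer molecules (one `C180` + one `C182` site, bond length
1.5 Å, a typical C–C bond) in a periodic cubic box of edge 53 Å, random
positions and orientations, rejection-sampled to a 2.0 Å intermolecular
clash distance — a conventional hard-core separation for heavy-atom sites;
frames are stamped at the 4 ps write-out cadence of the source simulations.
Frames are **independent redraws, not dynamics**: the generator validates
counting and summary statistics, not relaxation or transport.  Its contact
counts are somewhat higher than the equilibrated liquid's (random packing
has no repulsive structure beyond the hard core), so a green pipeline test
establishes correctness of the census machinery — not agreement with the
published per-mode averages, which require the deposited trajectories.
Correlation behavior is therefore tested on constructed series, not on
liquid frames.

`plant_pattern()` builds frames whose interaction map is *exactly* one
motif: motif edges at `0.96 x cutoff`, non-adjacent motif sites beyond the
cutoff by construction (collinear chains, equilateral triangles, 120°
planar or tetrahedral star leaves), and each molecule's second site parked
on a ring at `2.5 x cutoff` from the motif centroid.  The parked companions
are deliberately unphysical (far from their bonded partner): for a star hub
no direction at a realistic 1.5 Å bond length clears the cutoff to all
leaves, and the fixture's purpose is an exactly known census, not geometry.
A rigid random rotation (seeded) avoids axis-aligned special cases.

## Numerical and degenerate-input choices

* Eager frame reading: at the scales this package targets (thousands of
  sites, tens to hundreds of frames) memory residency is trivial; the
  trajectory contract is forward sequential access either way.
* HISTORY parsing accepts 2–5 header integers, `levcfg` 0–2 (skipping
  velocity/force lines), `imcon` 1–3; everything else is a located parse
  error, and truncated frames, inconsistent atom counts, or an atom count
  not divisible by the configured molecule size are structural errors, not
  warnings.
* An empty XYZ file is a structural error, not an empty trajectory.
* A frame with no tagged atoms yields an empty center list with a warning,
  not an error — an all-zero census row is meaningful.
* Embedding counts are divided by the automorphism order only after an
  exact divisibility check; a remainder would indicate a counting bug and
  aborts.

## Known limitations

* Only the L2/L3/R3/J4/J5 star family is counted; longer chains, larger
  rings, and non-star junctions parse but are refused by the counter.
* Macro classes are defined for at most two distinct species codes per
  pattern.
* The generator's liquids are structureless beyond the clash distance; do
  not read physical meaning into their absolute mode counts.
* Hydrogen-bond-style criteria (angles, energies) are out of scope; the
  contact criterion is purely geometric.
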