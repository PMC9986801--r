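---
title: "Methods: real-space model processing, trimming, morphing and the iterative cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-space model processing, trimming, morphing and the iterative cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itermodel)
```

# Scope and model of the problem

`itermodel` implements the bespoke real-space stages of an iterative,
prediction-driven crystallographic structure determination cycle: a
predicted model is trimmed by confidence, placed, morphed onto the
current working model, refined and rebuilt by external engines, and
trimmed against the current density map; the loop repeats until the
model stops changing. The crystallographic engines themselves —
structure prediction, molecular replacement, reciprocal-space
refinement, density modification and rebuilding — are deliberately
outside the package: they appear as a four-function engine interface
(`predict`, `mr`, `refine`, `rebuild`), and the shipped
`mock_engines()` exercise every orchestration code path against a known
synthetic truth. Everything the package computes itself is real-space:
Gaussian-atom model maps, masked Pearson correlations, confidence
processing, trimming, morphing, and model comparison.

# Confidence processing of predicted models

Predicted models carry a per-residue confidence score (pLDDT, 0-100) in
the B-factor field. Three operations consume it:

* **Trimming** removes residues with pLDDT strictly below
  `plddt_cutoff` (default 70, the conventional boundary of moderate
  confidence). Scores on the 0-1 scale are detected (`max <= 1`) and
  rescaled.
* **ADP conversion** maps confidence to an estimated coordinate error
  `d = 1.5 * exp(4 * (0.7 - lDDT))` Angstrom (lDDT fractional) and then
  to an isotropic displacement parameter `B = (8 * pi^2 / 3) * d^2`.
  At the trim boundary (pLDDT 70) this gives d = 1.5 A and B of about
  59 A^2; the conversion is strictly decreasing. This closed form is
  the published error-versus-lDDT fit used by the established
  processing tools; the package adopts it because the trim boundary and
  the conversion then agree with each other.
* **Domain splitting** partitions residues into spatially compact
  groups: a CA contact graph at `contact_distance` (default 8 A),
  counting only contacts at sequence separation of at least 3 so that
  an extended linker cannot glue two domains together, followed by
  connected components; components smaller than `min_domain_residues`
  (default 10) are merged into the spatially nearest component. The
  established tools use the predicted aligned error matrix for this
  step; that matrix is not available to this pipeline, so the package
  uses the purely geometric criterion above, which reproduces the
  intended behaviour on compact-globule fixtures and is deterministic.
  Trimming is applied before splitting (the order in the original
  tooling is not documented; the choice is configurable by composing
  the exported functions in either order).

# Model-derived density and map-model correlation

Model maps use a single Gaussian per atom: integrated weight equal to
the element electron count, variance
`sigma^2 = (b_iso + B_res) / (8 * pi^2)` with a resolution-dependent
blur `B_res = 79 * (resolution / 3)^2` A^2. A single Gaussian (rather
than multi-Gaussian form factors) is adequate at the 2-4 A regime the
procedure targets and keeps every downstream quantity analytically
checkable; the tests verify the rendered profile against the closed
form. Grids must satisfy `spacing < resolution / 2`; the default grid
is the model extent plus a 5 A pad.

Per-residue correlation (`local_cc`) is the Pearson correlation between
the experimental and the model map over grid points within
`mask_radius` (default 2.5 A, the midpoint of the optimization grid
below) of any atom of the residue. Residues with fewer than 10 masked
points are flagged and scored 0; both numbers are exposed as
parameters because the originating procedure does not state them.

Global correlation (`global_cc`) uses the union-of-spheres mask over
all atoms, with mean subtraction inside the mask only. With
`optimize = TRUE` it reproduces the mask-radius / side-chain-B
optimization used when scoring rebuilt models: a grid search over mask
radii {1.5, 2, 2.5, 3} A and per-atom-beyond-CA B increments
{0, 10, 20, 40} A^2, returning the maximized correlation. The
optimized value can never be lower than the unoptimized one, and the
tests construct a displaced-side-chain fixture for which a positive
increment genuinely helps.

Per-residue tracks are smoothed with a centered moving average
(`smooth_track`) that shrinks symmetrically near segment ends and never
crosses a chain break. A break is declared when the chain id changes,
the residue numbering jumps, or consecutive CA atoms are more than
4.2 A apart. For even window widths the centered window uses the
nearest smaller odd width; with the default window of ten residues the
effective window is nine centered residues.

# Three-step trimming against a map

`trim_to_map` composes, exactly and in order:

1. **Cutoff-based removal.** Smoothed local correlation below the
   top-half cutoff (mean of the highest half of the values minus
   `cc_sd_ratio` = 3 standard deviations) marks a residue for removal;
   for predicted models the smoothed pLDDT must *also* be below its own
   cutoff (the conjunction is configurable to a disjunction). "Highest
   half" is the top `ceiling(n/2)` values after a descending sort, with
   the sample standard deviation (ddof 1, zero when fewer than two
   values); neither convention is stated by the originating procedure,
   so the package fixes them deterministically and documents them here.
2. **End trimming.** Segments are rebuilt from the survivors; from each
   end inward, residues whose raw *and* smoothed correlations sit below
   a higher cutoff (`cc_sd_ratio_end` = 2) are stripped; segments
   shorter than the smoothing window (`minimum_domain_length` = 10,
   one parameter serving both roles) are deleted. The end-cutoff
   statistics are recomputed over the surviving residues rather than
   reused from step 1 (the alternative is not distinguishable from the
   original description; recomputation is the more conservative
   reading).
3. **Weak-segment removal.** With `m` the mean of the top half of the
   per-segment mean correlations, segments below
   `max(0.64 * m, m - 0.3)` are dropped — the printed constants being
   `reasonable_cc_ratio^2` and `2 * reasonable_cc_diff`.

All "below cutoff" comparisons are strict, matching the strict
`pLDDT < 70` convention, but applied with a numerical tolerance of
1e-9: without it, a model scored against its own map (correlation 1
everywhere up to floating-point noise, standard deviation ~1e-16)
would be trimmed by machine rounding, which the contract explicitly
forbids. The tolerance is far below any physically meaningful
correlation difference.

An independent straight-line re-implementation of the three steps lives
in the test helpers and is compared against `trim_to_map` on 100 seeded
fixtures; the only shared component is the per-residue correlation
profile, so the trimming logic itself is dual-routed.

# Anchor-based morphing

`superpose_and_morph` deforms a full-length prediction onto a working
model in two stages.

**Anchor detection** must find parts of the moving model that match the
target *after a part-local superposition* — a domain that is rigidly
displaced in the prediction still matches its density-placed
counterpart locally even though no global superposition aligns both
domains at once. Each paired residue is therefore scored under a
least-squares fit of its surrounding sequence window, and runs are then
grown outward from the best-fitting seeds, a neighbor joining only
while it fits the rigid transform of the whole run so far (the run is
refit as it grows). This prevents runs from creeping across a
displaced-domain boundary: the many residues already in the run pin the
fit, and the first residue of the displaced domain fails the
`match_distance` test (default 3 A, consistent with the match window
used for model assessment; `min_anchor` defaults to 5 residues).
Residues shaved from a run's ends remain available to seed later
anchors, which is how the displaced domain acquires its own anchor.

**Deformation.** Residues inside an anchor move rigidly by that
anchor's transform. Residues between two anchors of the same chain move
by `x' = (1 - s) T_L(x) + s T_R(x)`, where `s` is the smoothstep
`3t^2 - 2t^3` of the fractional sequence position across the gap: the
blend is continuous with zero slope at the anchor borders, so anchors
stay exactly rigid while the gap deforms smoothly. Residues outside the
anchor span follow the nearest anchor; chains without anchors fall back
to an exponential sequence-distance blend (decay 10 residues). All
atoms of a residue share the residue-level blend. The maximum
difference between neighboring residues' displacement vectors is
reported as `max_local_distortion`, since large distortions signal a
geometrically implausible morph.

One geometric caveat is inherent rather than an implementation choice:
when two anchors are relocated relative to each other by more than the
gap residues can absorb (for example a stretched 4-residue linker
between domains), some linker bond must stretch, so the "no new chain
breaks" property holds everywhere except immediately adjacent to
pre-existing breaks. The tests encode exactly that property.

# Model comparison metrics

`kabsch` is the standard SVD superposition with the determinant sign
correction. `compare_models` pairs residues by identical (chain,
residue number, insertion code) — with an optional nearest-CA fallback
within 5 A for renumbered models — and reports the r.m.s.d. over
pairs, *completeness* (percent of reference CA atoms within 2.0 A of
any comparison CA) and *coverage* (percent of reference residues
paired). `symmetry_expand_best` evaluates every supplied symmetry
operator image of the mobile model, including origin shifts on a
half-cell grid along the axes each operator allows, and returns the
image with the highest completeness (ties broken by lower r.m.s.d.).
Operators come from triplet strings ("-x,y+1/2,-z") or explicit
matrices; deriving them from a space-group symbol is out of scope, as
is a continuous origin-shift search. Fractional operators assume
orthogonal cells, which covers every fixture this package generates.

`assess_prediction` reproduces the prediction-quality protocol:
superpose, drop residues below pLDDT 70, then drop residues whose
paired CA distance smoothed over ten residues exceeds 3 A, and report
the r.m.s.d. of the survivors plus coverage of the deposited model.
The cap applies to the smoothed distances, so an isolated one-residue
spike inside accurate surroundings survives.

# The iterative cycle

`run_cycles` executes: predict (cycle 1 without, later cycles with the
previous kept model as template), confidence-process, place by MR
(cycle 1 only), morph the full-length prediction onto the placed or
previous model, refine, rebuild, score, and trim to the map. Morphing
precedes refinement in every cycle (the original ordering for later
cycles is ambiguous; this is the configuration point most easily
changed by recomposing the exported stages). A rebuilt candidate
replaces the incumbent only if its free R decreases strictly — models
are not necessarily improved by rebuilding — and the loop stops after
at least `min_cycles` = 3 cycles once the CA r.m.s.d. between
successive models falls strictly below
`cycle_rmsd_to_resolution_ratio` (default 0.25) times the resolution,
scaling the convergence tolerance with the expected coordinate error.

The mock engines make the loop testable without any crystallographic
machinery. The mock predictor returns
`alpha * template + (1 - alpha) * truth` plus seeded noise and writes a
pLDDT track anti-correlated with the true local error; the mock MR
engine superposes onto the truth frame; the mock refiner scores a
*proxy* free R as `0.2 + 0.4 * (1 - global_cc)` clipped to
[0.2, 0.6] — the real free R needs reciprocal-space machinery, but the
keep-if-better logic only needs a deterministic, monotone quality
score; the mock rebuilder nudges atoms a bounded step toward the local
density centroid. Everything is deterministic given the configured
seed.

# The synthetic world

Fixtures are generated, never shipped. The stated world is:

* **Truth models**: ideal poly-alanine helices (rise 1.5 A, 100
  degrees/residue), optionally as two or three domains stacked end to
  end 24 A apart, each rotated 60 degrees about the stacking axis and
  joined by stretched 4-residue linkers. The large gap guarantees the
  domains are genuinely separate in an 8 A contact graph — with
  side-by-side domains a linker can pass within contact range of both
  and falsely bridge them. Side chains are a single CB; side-chain
  realism is unnecessary for every contract except the side-chain-B
  optimization, which uses displaced-CB fixtures.
* **Predictions**: sequence-smooth coordinate noise (natural cubic
  spline through knots every ~8 residues, normalized to `core_rmsd`,
  default 1.2 A — the error regime typical of usable predictions),
  plus a *rigid* displacement of the last domain (`region_rot` = 20
  degrees about its centroid and a `region_rmsd` = 4 A translation).
  Smooth noise keeps bonded geometry intact, as in real predictions;
  early fully-independent-per-atom noise variants fragmented the chain
  into spurious segments and made every downstream contract
  meaningless. The rigid region emulates a prediction that is locally
  accurate but wrongly placed — which is what morphing and trimming
  are designed to detect. Simulated pLDDT is
  `90 - 15 * smoothed local CA error`, clipped to [20, 98], hence
  anti-correlated with the true error (Spearman correlation below
  -0.5 on the default fixtures).
* **Maps**: the Gaussian-atom map of the truth at grid spacing
  `resolution / 3`, plus optional seeded Gaussian noise scaled to the
  peak density.

What a green test does *not* establish: the fixtures contain no
solvent, no anisotropy, no reciprocal-space error structure, no
sequence diversity and no genuinely wrong topology, so passing the
suite demonstrates the correctness of the algorithms, not the success
rate of the full procedure on real crystallographic data — the
headline statistics of the original study (success on most of a
215-structure PDB test set) require the real engines at scale and are
explicitly out of desk-scale reach.

# Numerical choices and degenerate inputs

* Strict below-cutoff tests carry a 1e-9 tolerance (see trimming).
* `top_half_cutoff` of fewer than two values uses sd = 0, so a single
  segment or constant track is never self-trimmed.
* Kabsch refuses fewer than 3 pairs and collinear/coincident geometry.
* Models entirely (or more than 20 percent) outside a map raise a
  coverage error rather than returning correlations of the padding.
* PDB output is refused beyond 99999 atoms or multi-character chain
  ids, with the instruction to use mmCIF.
* Multi-model files: only the first model is read. Alternate
  conformations other than blank/'A' are dropped, as are HETATM
  records (with a logged count) — the procedure operates on the
  protein component only.
* All randomness flows from explicit integer seeds; trajectories and
  fixtures are bit-for-bit reproducible.

# Known limitations

* Orthogonal cells only in symmetry mapping; no space-group derivation.
* Single-Gaussian atoms, no anisotropic ADPs, no occupancy-weighted
  multi-conformer handling beyond dropping alternates.
* Sequence alignment is out of scope: model correspondence relies on
  consistent chain ids and residue numbers (with a nearest-CA fallback
  for rigid renumbering).
* The morph blend is a contract of this package, not a claim about the
  original tool's interpolation scheme, which is undocumented.
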