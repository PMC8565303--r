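---
title: "Models and conventions: nucleosome wrap, fiber packing and digestion kinetics"
author: "chromfiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions: nucleosome wrap, fiber packing and digestion kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfiber)
```

This vignette is the package's own account of the science it implements:
what each quantity means, which conventions were chosen where several are
defensible, and what the synthetic-data tests do and do not demonstrate
about real data.

## The nucleosome as a measured object

A nucleosome core particle wraps about 147 bp of DNA in roughly 1.65
left-handed superhelical turns around the histone octamer.  The package's
unit of analysis is the **base-pair path**: the ordered centers of the
base pairs of the nucleosomal (and linker) duplex, indexed relative to the
**dyad** (the pseudo-two-fold base pair, index 0).  Superhelical location
is the standard bookkeeping along the wrap:

$$\mathrm{SHL}(i) = i / 10$$

one unit per double-helical turn, at the conventional 10 bp per turn.  A
full 147-bp core spans SHL −7.3 to +7.3.  Base pairs are formed
geometrically — mutually nearest opposite-strand C1′ atoms within 12 Å —
never by residue numbering, because deposited models renumber DNA
inconsistently.  The 12 Å cutoff is generous for a C1′–C1′ separation
(~10.5 Å in B-DNA) while excluding cross-pairing with neighboring steps.

**Wrap accounting.**  Against a reference wrap (147 bp by default, the
canonical core), the resolved base pairs are counted and each terminus'
deficit reported as an SHL interval.  A nucleosome wrapping 136 bp with
all 11 missing base pairs at one terminus has a deficit spanning SHL
6.3–7.3 on that side.  We count *modeled base pairs*: whether a deposited
entry's "wrapped" figure refers to ordered density or modeled residues is
an upstream question the package cannot decide.  The disc-face labels
follow the observation-driven convention that **DF1 carries the larger
terminal deficit** (the flexible side); ties go to the positive-index
terminus.

**The dyad register.**  With `dyad = "auto"` the dyad is the midpoint of
the longest contiguous resolved span (the lower-middle base pair when the
span length is even — erroring on even spans would make "auto" useless on
real models, which resolve even spans routinely).  Auto-location is a
heuristic: it is correct for symmetric or one-sided-truncated paths and
wrong for asymmetric truncation, which is why every entry point accepts an
explicit `c(chain, resno)` dyad and the synthetic duplex writer encodes
the register in strand-1 residue numbers (dyad at resno 74).  Exact
reproduction of a known register should always pass the explicit dyad.

## The nucleosome reference frame

Each nucleosome gets a rigid frame: disc **center**, disc **normal**,
**dyad direction** (center → dyad bp, in the disc plane), handedness −1
(left-handed wrap).  Two estimator choices matter and are deliberate:

* **Normal = superhelix axis, not a least-squares plane.**  The wrap has
  pitch: axial position is linear in wrap angle, which couples in-plane
  and axial coordinates and tilts a raw PCA plane of the bp centers by
  several degrees.  Instead we use the second differences of consecutive
  base-pair centers: for a uniformly sampled helix these vectors are
  exactly radial (the linear pitch term cancels), so the axis is the null
  direction — the smallest right-singular vector — of the second-difference
  matrix.  This is exact on ideal geometry and rigid-motion equivariant by
  construction.  Collinear paths leave no radial signal and raise a
  degeneracy error.
* **Center = circle-fit center, not the bp centroid.**  The centroid of a
  1.65-turn arc sits several Å off-axis and moves when termini disorder.
  The center of the best-fit circle (Kåsa fit, linear least squares) of
  the core base pairs in the disc plane is the actual disc axis point and
  is insensitive to terminal truncation because only |SHL| ≤ 5 base pairs
  enter the fit.

The normal's sign is fixed by handedness: it is oriented so the wrap runs
clockwise when viewed down the normal (left-handed about it).

## Di-nucleosome packing parameters

In a two-start zigzag fiber the **di-nucleosome is the repeating unit**:
nucleosomes (1,2), (3,4), … in DNA order.  Four parameters describe
packing; all are invariant under global rigid motions, and β and γ are
additionally scale-invariant:

| parameter | definition | units |
|---|---|---|
| *x* | center-to-center distance of the two nucleosomes in a unit | nm |
| *β* | angle between consecutive units' intra-unit direction vectors, projected perpendicular to the fiber axis | degrees, [0, 180) |
| *d* | magnitude of the consecutive-unit center displacement projected on the fiber axis | Å |
| *γ* | entry/exit linker opening relative to the fully wrapped reference | degrees, ≥ 0 |

The **fiber axis** is the first principal direction of the unit centers,
oriented first → last unit (which also fixes the sign convention under
which *d* is reported as a magnitude).  With only two units this reduces
to the normalized center difference.

**Why β uses the intra-unit direction.**  "Rotation between consecutive
units about the axis" does not by itself say which unit feature carries
the rotation.  We use the member-1 → member-2 direction projected
perpendicular to the axis because it is the unique choice that is exact
under the builder's screw construction: the builder rotates that direction
by precisely β per unit step, so builder → estimator is an identity in the
noise-free case (the round-trip property every release is tested against).
A unit whose intra-unit direction is parallel to the axis has no
perpendicular projection and raises a degeneracy error rather than
returning an arbitrary angle.

**The γ convention.**  γ is measured between the *entering* and *exiting*
linker directions of a nucleosome — each a least-squares line through ≥ 4
linker bp centers, oriented away from the nucleosome — **minus the same
angle for a canonical fully wrapped core with straight tangential
linkers** (≈ 55.1° for the default superhelix constants), clipped at 0.
A fully wrapped nucleosome with straight linkers therefore scores γ = 0,
and γ grows as the entry/exit DNA opens.  The raw absolute angle is also
returned for users preferring an unreferenced convention.  Terminal
nucleosomes have only one linker and contribute no γ sample, so an
n-nucleosome fiber yields n − 2 γ values, n/2 x values and n/2 − 1
(β, d) pairs.  Means and SDs use the n − 1 denominator.

## The idealized fiber builder

`build_fiber` places di-nucleosome units by a screw operation (rotate β
about the axis, shift d along it), the two unit members x apart with disc
normals along the fiber axis — odd ordinals forming one stack, even the
other, the two-start topology.  Linkers are straight base-pair paths at
3.4 Å rise: the linker between nucleosomes i and i+1 is stored as two
half-segments leaving/entering the flanking nucleosomes along directions
opened symmetrically by γ about the fully wrapped baseline.  This makes
the builder and estimator exact inverses, which is the calibration that
fixes both conventions.  A physically continuous linker would tie γ to
(x, β, d) and the repeat length; the package treats γ as an independent
packing descriptor, as the fiber figures it quantifies do.

Parameter ranges producing clashes (non-neighboring disc centers < 60 Å)
warn but still build: near-contact stacking is a real regime, and the
caller decides what to do with it.

**Dimensions.**  Fiber length and width model each nucleosome as a disc of
11 nm diameter × 5.5 nm thickness (canonical core dimensions) in its
frame: length is the envelope extent along the axis, width the maximal
extent over perpendicular directions (sampled at 0.5° steps — the
envelope is smooth, so this is exact to well below reporting precision).
Absolute published fiber lengths depend on an envelope convention that is
rarely stated; the package documents its own and guarantees only
*orderings* between parameter sets (the H2A.Z-parameter 24-mer is shorter
than the H2A-parameter one, in line with reported 80 vs 86 nm under the
authors' convention).

## Digestion kinetics

Restriction-enzyme accessibility assays quantify end-DNA flexibility: the
fraction digested y(t) follows the increasing exponential

$$y = C + A\,(1 - e^{-kt}), \qquad k > 0,$$

with C the baseline, A the amplitude and k (min⁻¹) the rate constant that
carries the biology.  The fit is bounded nonlinear least squares
(Levenberg–Marquardt via minpack.lm) with a fully deterministic
initialization: C₀ = min(y), A₀ = max(y) − min(y), k₀ log-linearized from
the first two informative points, then a fixed five-point multiplicative
grid on k₀; the lowest-RSS solution wins.  This replaces interactive
spreadsheet solving with a reproducible rule.  Flat time courses raise an
identifiability error rather than returning an arbitrary k.  Two exact
equivariances are tested: scaling t by c scales k̂ by 1/c, and adding δ
to y shifts Ĉ by δ leaving Â, k̂ unchanged.

Group comparison follows the two-stage recipe: an F test for equality of
variances at 0.05 chooses between the pooled and Welch two-sample t test
on the per-replicate rate constants, each non-control condition against
the control (first) group, significance at P ≤ 0.05.  The two-stage
procedure's operating characteristics are checked by simulation: its
type-I error at n = 5 per group stays near the nominal 0.05 (asserted
within [0.03, 0.07] over 1000 simulations).  If both groups are
numerically constant the t statistic is reported as 0 (equal means) or
unbounded (unequal) instead of erroring.  Fold changes are ratios of group
mean rate constants with first-order SEM propagation:
se = fold·√((SEM_t/mean_t)² + (SEM_c/mean_c)²).  "Initial rate"
comparisons are governed by k when A is comparable across conditions,
which the assay design (same substrate, same enzyme) makes reasonable.

## The 601 constructs

The three construct sequences (167-bp repeat, 208-bp repeat, NsiI-modified
208-bp repeat — the modification is a single A→G creating ATGCAT) are
embedded verbatim and length-checked (167/208/208) by
`validate_fixture_lengths()`.  Coordinates are 1-based inclusive.  The
positioned 147-bp core register is configuration, not inference: the
default anchors the core at the conserved `CTGGAGA` start of the shared
601 region, which puts the HinfI site 5 bp inside one core edge of the
208-mer and the introduced NsiI site 5 bp inside the other — the "edge"
regime (≤ 10 bp inside a core end) where terminus flexibility controls
cleavage.  Whether such distances should be measured from the 147-bp core
edge or from the positioned particle's entry/exit is ambiguous in general;
the core interval is therefore always overridable.  Scanning is IUPAC-
aware via Biostrings; both HinfI and NsiI motifs are their own reverse
complements, so top-strand scanning is complete for them, while
non-palindromic custom motifs are scanned on both strands.

## What the synthetic generator does and does not emulate

The generator produces: ideal left-handed superhelical bp paths (41.9 Å
radius, 25.9 Å pitch, 1.65 turns — canonical core geometry; only relative
geometry matters downstream) with optional terminal truncation; two-start
fibers identical to the builder's output with seeded Gaussian jitter on
centers (Å), orientations (degrees, about a uniform random axis) and
linker bp (Å); and exponential time courses with seeded Gaussian noise
clipped to [0, 1.1].  All generators are deterministic functions of their
seed and leave the global RNG state untouched.

It does **not** emulate: sequence-dependent DNA mechanics, histone-DNA
contact heterogeneity, bent linkers (the tetra-nucleosome crystal regime),
partial unwrapping coupled to fiber packing, cryo-EM map noise or
classification heterogeneity, or gel-quantification artifacts beyond
additive Gaussian noise.  Passing the synthetic suites therefore
demonstrates estimator *correctness* (exact inversion on clean geometry,
unbiasedness under isotropic noise) — not robustness to the structured
errors of real reconstructions, which always warrant inspection.

## Problem sizes and numerical choices

Test and acceptance workloads are sized for interactive runs: 12- to
24-nucleosome fibers, 100-replicate jitter studies (2 Å / 2°), 200-fit
noise recovery, 1000-replicate test-calibration simulations at n = 5 per
group.  Key tolerances: orthonormality of frame axes to 1e−8; noise-free
round-trips asserted at 1e−6; rigid-motion invariance at 1e−6 over 100
random motions; PDB coordinates round-trip at the format's 3-decimal
precision.  Angles are computed with atan2 of the cross/dot decomposition
(stable near 0° and 180°), β ∈ [0, 180) with exact-180 wrapping to 0, and
γ clipped below at 0 (closures tighter than the reference are reported as
0, with the raw angle available).

## Known limitations

* Frames recovered *from structure files* carry no linker geometry, so γ
  is only available for in-memory built/generated models or when linkers
  are supplied; file-based fiber analysis reports x, β, d.
* The chain-relabeling pool for decorated fibers is 62 single-character
  chain ids; very large decorated models (copies × template chains > 62)
  are refused rather than silently aliased.
* Auto dyad location assumes near-symmetric resolution; asymmetric
  truncation requires the explicit register.
* The two-start topology is hard-coded in the builder; solenoid or
  heteromorphic topologies are out of scope.
* mmCIF output is a minimal canonical atom_site loop — sufficient for
  coordinate exchange, not a general mmCIF feature writer.
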