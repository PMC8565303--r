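# chromfiber

Quantitative chromatin structural analysis around the histone variant
H2A.Z, for structural biologists and chromatin biochemists who want the
numbers behind "the H2A.Z nucleosome wraps less DNA and packs into a more
twisted, more compact fiber":

* **Nucleosome wrap accounting** — extract the DNA duplex from a PDB/mmCIF
  model, assign the nucleosome reference frame and superhelical locations
  (SHL = bp offset from the dyad / 10), and count wrapped vs missing
  terminal base pairs against the canonical 147-bp core (e.g. a nucleosome
  that compacts only 136 bp is missing 11 bp spanning SHL 6.3–7.3 on one
  disc face).
* **Fiber packing geometry** — decompose an ordered fiber into
  di-nucleosome units and measure the two-start packing parameters:
  intra-unit center distance *x* (nm), inter-unit rotation *β* (degrees)
  and axial shift *d* (Å) about/along the fiber axis, and the DNA
  entry/exit angle *γ* (degrees) of each nucleosome relative to the fully
  wrapped straight-linker reference.
* **Fiber building** — construct idealized two-start zigzag fibers from
  (*x*, *β*, *d*, *γ*) by a screw operation (unit *i*+1 = unit *i* rotated
  *β* and shifted *d* along the axis), decorate frames with a template
  nucleosome, and measure overall length/width from an 11 × 5.5 nm disc
  envelope.
* **Restriction accessibility kinetics** — fit digestion time courses to
  the saturating exponential *y* = *C* + *A*(1 − e^(−*kt*)), *k* > 0,
  compare rate constants between nucleosome types (F-test-gated t test)
  and report fold changes with propagated uncertainty.
* **601 construct maps** — the 167-bp and 208-bp Widom 601 repeats (and
  the NsiI-modified 208-mer) are embedded; IUPAC motif scanning (HinfI
  GANTC, NsiI ATGCAT, or custom) with distance-to-core-edge annotation.
* **Synthetic data** — deterministic generators for ideal superhelical
  DNA paths, jittered fibers and noisy time courses, so every estimator is
  validated against known ground truth.

## Worked example

Build a 24 × 167-bp fiber from the H2A.Z parameter set, recover its
parameters, and compare its dimensions with the canonical-H2A fiber:

```r
library(chromfiber)

m <- build_fiber(fiber_build_spec(n = 24, x = 14.9, beta = 19.7,
                                  d = 59.5, gamma = 27.5))
summarize_parameters(m$frames, m$linkers)
#> <fiber_parameters>
#>   x     mean   14.900 nm  (sd 0.000, n = 12)
#>   beta  mean   19.700 deg  (sd 0.000, n = 11)
#>   d     mean   59.500 A  (sd 0.000, n = 11)
#>   gamma mean   27.500 deg  (sd 0.000, n = 22)

round(measure_dimensions(m), 1)
#> length_nm  width_nm
#>      71.0      25.9

ma <- build_fiber(fiber_build_spec(n = 24, x = 14.3, beta = 12,
                                   d = 61, gamma = 9.7))
round(measure_dimensions(ma), 1)
#> length_nm  width_nm
#>      72.6      25.3
```

The estimator returns exactly the construction parameters (builder and
estimator are exact inverses for noise-free fibers), and the H2A.Z-
parameter fiber comes out shorter than the H2A one — the compaction
ordering the parameters imply.  Absolute lengths depend on the stated
disc-envelope convention; only the ordering is meaningful.

Map the HinfI site on the 208-bp construct and fit synthetic digestion
kinetics with a true 2.31-fold rate difference:

```r
s <- widom_601_constructs("601_208")
site_accessibility_context(scan_sites(s, "HinfI"), s)
#>   enzyme motif start end strand dist_to_core class
#> 1  HinfI GANTC    37  41      +           -5  edge

ctrl <- lapply(1:5, function(i) fit_exponential(
  make_timecourse(0.05, 0.85, 0.02, noise_sd = 0.02, seed = 100 + i)))
hz <- lapply(1:5, function(i) fit_exponential(
  make_timecourse(0.05, 0.85, 0.0462, noise_sd = 0.02, seed = 200 + i)))
rr <- relative_rate(hz, ctrl)
sprintf("fold = %.2f +/- %.2f", rr$fold, rr$se)
#> "fold = 2.29 +/- 0.11"
```

The site sits 5 bp inside the positioned core edge ("edge" class — the
situation in which end-DNA flexibility controls digestion), and the fitted
fold change recovers the simulated ratio within its propagated standard
error.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","chromfiber.R",package="chromfiber"))')" \
  build-fiber --n 24 --nrl 167 --x 14.9 --beta 19.7 --d 59.5 --gamma 27.5 --out out/
```

Subcommands: `analyze-nucleosome`, `analyze-fiber`, `build-fiber`,
`fit-kinetics`, `scan-sites`, `simulate`.  Every run writes a
`*_config.json` recording its configuration and seed.

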