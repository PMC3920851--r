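# hipwear

Measures polyethylene liner wear in total hip arthroplasty (THA) from CT.

In a THA the femoral head articulates inside a polyethylene liner seated in
a hemispherical metal acetabular cup. The liner is invisible in CT, but as
it wears the head center migrates toward the cup center — so wear can be
inferred from the **cup-head separation**, the Euclidean distance between
the centers of spheres fitted to the two metal components. Clinically
meaningful wear is a few tenths of a millimetre, below the voxel size, so
the pipeline is built for sub-voxel accuracy and comes with a synthetic
phantom generator that validates the whole chain against exact ground
truth. It is aimed at researchers in orthopaedic imaging and implant
metrology who want a reproducible, scriptable measurement chain rather than
interactive tooling.

## Method

Given a CT volume, an intensity threshold for implant metal, and seven
operator landmarks (three cup-rim points, an apical dome-hole point, an
offset point along the cup axis, and two spherical landmarks bracketing the
head and the head-stem junction):

1. **Surface extraction** — rays are cast inward over Fibonacci-spiral
   directions (hemisphere for the cup, full sphere for the head), sampling
   intensity by trilinear interpolation. A surface point is the threshold
   crossing confirmed by `min_run_length` consecutive above-threshold
   samples; cup rays are range-limited to 60% of the starting radius (the
   rim-plane-to-apex distance) and head rays that intersect the
   stem-junction sphere are discarded.
2. **Robust sphere fitting** — 80,000 random four-point subsets (pairwise
   ≥ 2 mm) give closed-form circumspheres; a 1000-bin radius histogram
   initialises the radius, two pruning passes (±2 mm, then ±2 × slice
   thickness) remove points that keep producing off-radius circumspheres,
   and geometric least squares `min Σ(|pᵢ − c| − r)²` over the survivors
   gives the final center **c** and radius r.
3. **Wear analysis** — separation per scan against a reference, OLS of
   measured on expected displacement (the 45° line), summary statistics
   with 99% CIs, and the ISO 5725 repeatability coefficient 2.77·s_r.

## Worked example

Simulate one full-size phantom scan (54.2 mm cup, 22.1 mm head, 0.2 mm
voxels, realistic blur and noise) and measure it:

```r
library(hipwear)

spec <- phantom_spec(rng_seed = 1)          # head at the reference position
ph   <- generate_phantom(spec)
lm   <- auto_landmarks(ph$truth, spec)      # stands in for the operator
m    <- measure_implant(ph$volume, lm,
                        extraction = extraction_config(threshold = 1500),
                        fitting    = fit_config(rng_seed = 1),
                        scan_id    = "demo")
m
#> <implant_measurement> scan demo
#>   cup diameter 54.194 mm, head diameter 22.095 mm
#>   cup-head separation 0.0008 mm
glance(m$cup_fit)
#> # A tibble: 1 x 6
#>   radius diameter initial_radius n_initial_points n_valid_points rms_residual
#>    <dbl>    <dbl>          <dbl>            <int>          <int>        <dbl>
#> 1   27.1     54.2           27.0             3806           3806       0.0200
```

The true diameters are 54.2 and 22.1 mm and the true separation is 0 — the
fitted values are within hundredths of a millimetre despite 5% noise. A
whole displacement study (here the built-in 14-scan micrometer design) runs
with one call and plots measured against expected separation with
`autoplot()`:

```r
study <- run_phantom_study(displacements = table1_displacements(),
                           spec = phantom_spec(rng_seed = 7),
                           fitting = fit_config(rng_seed = 7))
max(abs(study$wear$difference))   # worst separation error over 14 scans, mm
#> [1] 0.0024
autoplot(study)                   # 45-degree line with a +/-0.1 mm band
```

The same chain is scriptable from a shell via `inst/cli/hipwear`
(`simulate`, `extract`, `fit`, `measure`, `analyze` subcommands) for
volumes on disk (NIfTI or NRRD) with landmark CSVs.

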