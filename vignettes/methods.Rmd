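---
title: "Measuring implant wear from CT: model, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant wear from CT: model, algorithms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipwear)
```

## The measurement problem

In a total hip arthroplasty, the femoral head articulates inside a
polyethylene liner held by a hemispherical metal acetabular shell. As the
liner wears, the head center migrates toward the cup center. Both components
are metal and essentially spherical, so each can be located in a CT volume
by fitting a sphere to its thresholded surface; the Euclidean distance
between the two fitted centers — the *cup-head separation* — then proxies
liner wear without any knowledge of the liner itself, which is invisible in
CT. Clinically relevant wear totals a few tenths of a millimetre to a few
millimetres, so the separation must be measured to roughly a tenth of a
millimetre: well below the voxel size. Everything in this package exists to
make that sub-voxel measurement reliable and to quantify how reliable it is.

hipwear implements the whole chain: seven operator landmarks and an
intensity threshold constrain a ray-cast search for candidate surface
points; a robust randomised sphere fit turns each point cloud into a center
and radius; and the wear analysis compares measured separations with known
displacements, with regression, summary statistics and a repeatability
coefficient. A synthetic phantom generator supplies CT-like volumes with
exact ground truth so the chain can be validated end to end.

## The seven-landmark protocol

Three landmarks on the cup rim define the rim plane; one point sits in the
apical dome hole (the instrumentation hole at the shell's pole); one point
is shifted 5–10 mm outward along the cup axis. Two further landmarks are
spheres: one surrounding the head-stem junction, one enclosing the whole
head. The landmarks only *limit the search* — they never enter the final
estimate directly, which is why sub-millimetre landmark accuracy is not
required of the operator (the jitter test below makes this quantitative).

## Surface extraction

The cup search works outside-in. The apical point's distance to the rim
plane is the *starting radius* (for a hemispherical shell whose rim plane
passes through its center this is exactly the outer radius). Rays start at
1.2 times the starting radius from the estimated center (the apex projected
onto the rim plane) and step inward at half the smallest voxel spacing,
reading intensity by trilinear interpolation. Directions follow a Fibonacci
spiral over the hemisphere on the apex side of the rim plane: uniform,
deterministic coverage. A surface point requires `min_run_length` (default
3) consecutive samples above threshold, so isolated bright voxels cannot
produce a crossing; the reported position is the linear interpolation of the
threshold crossing immediately before that run. We interpolate the crossing
rather than report the first above-threshold sample because the raw rule
quantises depth to the step size and biases every radius inward by half a
step (~0.05 mm at default settings) — an avoidable systematic error of the
same order as the quantity being measured.

Two range rules keep the search on the intended surface. Travel is capped at
60% of the starting radius, so a ray that slips through an unused screw hole
stops before reaching the head or the far side of the shell. And rays whose
hit would land within `rim_margin_mm` (default 1 mm) of the rim plane are
skipped: at the rim the hemispherical shell is cut off and meets the liner,
and partial-volume blur of that cut drags threshold crossings several tenths
of a millimetre inward. Dome-hole-edge rays are *not* filtered: they land on
the hole's cylindrical wall, inside the sphere, and removing them is the job
of the robust fitting stage — exactly the point-count reduction the fitting
procedure is designed to produce.

The head search casts rays inward from the head-enclosing landmark sphere,
with the same run rule. Heads need not be solid metal, so only the first
crossing is used. Rays whose path intersects the stem-junction sphere are
discarded, which keeps the search off the stem; rays that already start
inside metal are discarded too (they cannot be searching "from outside").
Fewer than 500 surviving points triggers a warning, the symptom of an
undersized or misplaced enclosing landmark.

With 4,000 ray directions per surface the cup typically yields ~3,500–4,000
points and the head ~3,000–3,500, comfortably inside the intended
2,000–16,000 band.

## Robust sphere fitting

Candidate points contain structured outliers (hole edges, residual stem or
rim contamination), so a plain least-squares fit is not trustworthy. The
fitting stage is a randomised consensus procedure:

1. **Sampling.** 80,000 random four-point subsets of the valid points, each
   pair at least 2 mm apart (tight quadruples make degenerate
   circumspheres). Each quadruple has a unique circumsphere, computed in
   closed form; quadruples whose tetrahedron volume falls below
   10⁻⁶ mm³ are discarded as coplanar.
2. **Initialisation.** The circumsphere radii are histogrammed into 1,000
   uniform bins spanning 0–100 mm (0.1 mm per bin, covering every plausible
   implant radius); the fullest bin gives the initial radius, ties broken
   toward the larger radius (hole-edge contamination biases small). The
   initial center is the component-wise median of the in-bin circumsphere
   centers — the histogram step is described in the source procedure, the
   median center is this package's choice (robust and deterministic).
3. **Pruning, twice.** A fresh seeded pass of quadruples is drawn; every
   quadruple whose circumsphere radius deviates from the initial radius by
   more than the tolerance (coarse: 2 mm; fine: twice the slice thickness,
   0.4 mm at 0.2 mm slices) increments an *offending count* for its four
   members. A point is removed when the offending fraction of its
   participations exceeds `offending_fraction` (default 0.7). The historical
   rule removed points whose absolute count exceeded 1,600; that constant is
   retained as an option (`offending_mode = "absolute"`) but cannot work at
   arbitrary sampling densities — with 80,000 quadruples over 15,000 points
   a point participates ~21 times on average, so no absolute count near
   1,600 is reachable. The relative rule is scale-free: a quadruple offends
   if *any* member is an outlier, so at contamination c an inlier's
   offending fraction concentrates near 1 − (1 − c)³ (≈ 0.49 at c = 20%)
   while a gross outlier's is near 1; 0.7 separates the two for
   contamination up to roughly 25%, and was fixed from this analysis, not
   fitted. Points sampled fewer than `min_participation = 8` times are never
   pruned — too little evidence. Pruning is monotone by construction: the
   valid set only shrinks.
4. **Final estimate.** Geometric least squares on the surviving points:
   Gauss-Newton on residuals |p − c| − r, initialised by the algebraic
   (Coope) linear fit. On outlier-free data nothing is pruned and the
   robust fit coincides with plain least squares to numerical precision,
   which is one of the package's invariant tests.

The fine tolerance of twice the slice thickness ties the consensus band to
scan resolution; at the default 0.2 mm voxels it is 0.4 mm.

## Wear analysis

The separation is the distance between the two fitted centers; the expected
separation is the norm of the micrometer displacement triple applied
relative to the zero-displacement reference scan. Agreement is summarised
three ways: ordinary least squares of measured on expected (a perfect chain
gives the 45° line), summary statistics of the differences (mean, median,
SD, coefficient of variation, and a t-based 99% confidence interval), and —
for paired repeated measurements — the repeatability coefficient
2.77·s_r, where s_r = √(Σdᵢ²/2n) is the within-pair standard deviation (ISO
5725 convention; 2.77 = 1.96·√2, the 95% bound on the absolute difference
of two future repeats). The constant 2.77 is this package's reading of the
standard repeatability literature; sources that report only a final
coefficient rarely print the constant. Differences are reported as measured
minus expected.

## The synthetic phantom

The generator emulates the physical validation rig: a hemispherical metal
shell (outer diameter 54.2 mm, shell 4 mm, apical dome hole 8 mm, optional
unused screw holes), a solid 22.1 mm head whose center coincides with the
cup center at reference, and a cylindrical stem (radius 6 mm) running from
the head down the cup axis. The sub-voxel head displacements of the 14-scan
micrometer design (`table1_displacements()`) move only the head — the rig's
micrometer mechanics are not described in detail anywhere, so a rigid head
translation is the simplest faithful model. Voxels inside metal get
intensity 3,000 against a background of 0 (arbitrary units; electron-density
thresholds are scanner-specific, so units are not Hounsfield), the volume is
blurred with a Gaussian PSF (σ = 0.2 mm) as a partial-volume surrogate, and
white Gaussian noise (SD 150 = 5% of metal) is added. The default threshold
midway between the two intensities is where a blurred step edge crosses its
true boundary, making the extraction stage approximately unbiased by
construction. An optional band-limited radial roughness of the outer shell
(amplitude 0.3 mm in tests, default 0) emulates a trabecular coating.

Grid and spacing default to 288×288×244 voxels at 0.2 mm — about the
smallest grid that contains the implant with a blur margin (a 256³ grid at
0.2 mm spans only 51.2 mm, less than the cup's 54.2 mm diameter). Scan *i*
of a series uses seed `base + i`, so noise realisations are independent but
reproducible; everything downstream of a seed is deterministic, and the
full pipeline reproduces bit for bit.

What the phantom does *not* emulate: beam hardening, metal streak
artefacts, scatter, patient motion, scanner-specific reconstruction kernels
and nonuniform backgrounds (bone, soft tissue). Passing the synthetic suite
therefore demonstrates the geometric and statistical correctness of the
chain at clinical noise levels, not robustness to every clinical artefact.

## Validation at study scale

The acceptance suite regenerates the 14-scan series at full scale (0.2 mm
voxels, default blur and noise, fixed seed) and checks, in one run:
every |measured − expected| separation within 0.1 mm; cup-diameter SD
across scans ≤ 0.05 mm and head ≤ 0.07 mm; regression slope within
[0.9, 1.1] and |intercept| ≤ 0.05 mm. In this implementation the maximum
separation error on that series is a few hundredths of a millimetre, with
diameter SDs near 0.01 mm. A landmark-jitter test perturbs all seven
landmarks by ±1 mm on a full-size phantom and requires the separation to
move by less than 0.05 mm — the protocol's core robustness claim, since the
landmarks only gate the search. Unit suites use a 20 mm down-scaled phantom
(128×128×112 voxels) so they run in seconds; the full-size series is
reserved for the acceptance run, which takes a few minutes on one CPU.

`scripts/acceptance.R` reruns the full-scale study from scratch against the
installed package and writes the headline number (maximum absolute
separation error over the 14 scans) as JSON.

## Numerical choices and degenerate inputs

* Coplanarity: quadruples with tetrahedron volume < 10⁻⁶ mm³ are rejected;
  plane fits require triangle area above 10⁻⁹ mm²; the final least squares
  refuses point sets whose smallest singular value of the centered cloud is
  below 10⁻⁹ of the largest.
* The circumsphere solver is Cramer's rule on the 3×3 chordal system —
  exact, vectorised over tens of thousands of quadruples.
* Histogram ties break toward the larger radius; all other ties cannot
  occur with continuous data.
* Quadruple sampling is batch rejection sampling with a bound of 50× the
  requested count; clouds tighter than the 2 mm pair separation fail with
  an explicit insufficient-points error rather than looping.
* Volumes must carry voxel spacing; a file without spatial metadata is a
  format error, never assumed isotropic 1 mm. All geometry is computed in
  world millimetres, so anisotropic spacing (e.g. 0.35×0.35×0.6 mm clinical
  protocols) needs no special casing.
* The starting radius uses the apical point by default; the offset point is
  accepted as an alternative (`radius_landmark = "cup_offset"`), since
  operator protocols differ on which of the two drives the calculation.

## Known limitations

* The wear proxy is center-to-center distance; multiple wear tracts, liner
  deformation or a head not seated in the deepest wear path are outside the
  model.
* Only hemispherical uncemented cups are addressed; elliptical or dysplasia
  cups violate the sphere model.
* The absolute offending-count mode reproduces the historical rule only at
  its original sampling density; the relative mode is the supported
  default.
* NIfTI spatial metadata is single precision by format; NRRD round-trips
  exactly.
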