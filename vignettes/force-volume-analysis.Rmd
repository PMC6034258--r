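---
title: "Force-volume analysis with fcvolume: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-volume analysis with fcvolume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcvolume)
```

## The measurement and the model

A force curve records the cantilever deflection signal $D$ (volts) against
the piezo stage displacement $z$ as an AFM tip approaches and indents a
sample.  A force-volume map is a grid of such curves.  Three calibration
constants connect the raw signals to physics: the Z-stage sensitivity
(nm per raw Z unit), the cantilever elastic constant $K_C$ (N/m), and the
detector sensitivity $S$ (V/nm), measured as the approach slope on an
incompressible surface.  Deflection becomes force through

$$F = D \, K_C / S \quad \text{(nN)},$$

and files that already store forces pass through with $K_C = S = 1$.

The mechanical content of the contact region is extracted in two ways.
*Contact stiffness* is simply the least-squares slope of $F$ versus $z$
over a window of the contact line; it saturates at $K_C$ on rigid samples
and requires no contact model, which makes it the robust choice for hard
specimens.  *Young's modulus* requires separating sample deformation from
cantilever bending: the bending is $d = F / K_C$ (identically $D / S$), so
the indentation depth is $\delta = (z - z_{cp}) - d$, with $z_{cp}$ the
contact-point position.  For a conical or four-sided pyramidal tip the
Sneddon/Bilodeau contact solution is

$$F = C_0 \frac{2 E \delta^2}{\pi (1-\nu^2) \tan\alpha},$$

linear in $\delta^2$.  The package fits $F = B\delta^2 + c$ by ordinary
least squares and inverts the prefactor:

$$E = \frac{\pi B (1-\nu^2)\tan\alpha}{2 C_0},$$

which for $\nu = \tfrac12$ reduces to the familiar
$E = 3\pi B \tan\alpha / (8 C_0)$.  The general-$\nu$ form is implemented
(rather than the $\nu = \tfrac12$ special case alone) because the Poisson
ratio is a user parameter; silently ignoring a non-default $\nu$ would be
worse than the extra algebra.  With $B$ in nN/nm$^2$ the modulus comes out
in GPa exactly ($1\ \text{nN/nm}^2 = 1$ GPa), so the kPa/MPa/GPa options
are exact powers of ten.

Model assumptions worth keeping in mind: linear elasticity, a homogeneous
isotropic half-space, no adhesion in the contact region, a sharp cone or
pyramid (no tip rounding), and indentation small relative to sample
thickness.  Spherical tips, adhesion models and bottom-effect corrections
are out of scope.

## The parameters that matter

* **`zeroline_window`** (percent of the curve, default 0–70 %): the stretch
  fitted linearly as the zero-force baseline.  0 % is the sample farthest
  from the surface, 100 % the maximum load.  It must lie inside the
  non-contact part; on the synthetic scenes below, whose contact region
  occupies the second half of the approach, the analyses use 0–40 %.
* **`cp_method`** and **`n_smooth`**: the contact-point routine and its
  moving-average window (samples; even values widen to the next odd).  The
  smoothed-derivative routine tolerates noise best; the smoothed-minimum
  routine is for low-noise curves with an adhesive dip; the two-line
  intersection suits hard samples whose contact line is straight.  On
  curves with a true contact kink every routine lands within about
  `n_smooth` sample spacings of it, which is the CP (and hence topography)
  resolution.  Smoothing should scale with the noise-to-signal ratio of
  the force *derivative*: the validation runs use `n_smooth = 3` on
  noiseless curves, 51 at 2 % force noise on 2 nN loads, and 101 on the
  higher-load tomography curves — choices made with the `run_optimizer()`
  preview, which exists precisely to tune these knobs on four curves
  before a batch run.
* **`contact_window`** (percent of the whole curve, default 90–100 %): the
  contact-line fit range of the intersection routine.
* **`fit_window`** (percent of maximum depth, default 0–100 %): the depth
  range fitted for the modulus.  This is a *depth* fraction, not a sample
  fraction, so tomography windows such as 0–35 / 40–75 / 80–100 % select
  true penetration ranges even though samples are not uniform in $\delta$.
* **`fv_tip()`**: shape (`pyramid4`, $C_0 = 1.46$; `cone`, $C_0 = 1$, both
  overridable), half-angle $\alpha$ (degrees) and $\nu$.  Defaults
  (pyramid, $\alpha = 23.5°$, $\nu = 0.5$) are typical of silicon-nitride
  probes on soft biological samples.

Progressive file numbering is 1-based (file 33 is the 33rd curve); grid
coordinates everywhere else are 0-based.  In serpentine ("raster") scans,
odd 1-based rows run left to right and even rows right to left, so the
column index of even rows is mirrored when progressive indices are decoded.

## Numerical choices

* Percent-to-index mapping uses `floor(p/100 * (N-1))`, inclusive on both
  ends; windows must map to at least 2 samples.
* The derivative is a two-point central difference (one-sided at the
  ends).  "Zero" on the smoothed derivative means a sign change between
  consecutive samples or $|d| \le 10^{-12} \max|d|$.
* Both scan-back routines start at the last *fully* smoothed sample
  ($N - \lfloor n_{smooth}/2 \rfloor$): the moving average truncates its
  window at the array edges, so the trailing samples are nearly raw and a
  scan started literally at maximum load would trigger on their noise.
* Plateaus (in the turnaround split and the minimum scan) resolve to the
  sample nearest maximum load, consistent with scanning from that end.
* Samples with $\delta < 0$ (noise around contact) are dropped rather than
  clamped to zero, because clamping piles points onto the origin of the
  $F$–$\delta^2$ fit and biases the slope; the count is logged on the
  indentation object.
* The modulus fit keeps a free intercept: residual contact-point error
  displaces the curve along $F$, and a free intercept absorbs it instead
  of leaking it into the slope.  The intercept is reported for diagnostics.
* Degenerate inputs fail loudly per pixel and quietly per map: a rigid
  pixel (all-zero depth), a curve with no derivative zero, or an unreadable
  file each raise a classed error, which the batch routines convert to a
  `NaN` cell plus a summary count, so partially acquired maps still
  process.
* Negative fitted slopes report a negative modulus with a warning —
  a visible diagnostic, never a silent clip.
* Exported matrices carry X positions in the first row and Y positions in
  the first column; the header corner, which no convention defines, is
  written as `0`.  Output decimals use `.`; inputs accept `,` as well.
  Missing cells are written as `nan`.

## What the synthetic generator emulates — and what it does not

`synthetic_scene()` inverts the same contact model the analysis fits: at
every stage position past contact the cantilever deflection solves the
force balance $K_C d = F_{tip}(z - z_{cp} - d)$ (by bisection, which also
covers the piecewise two-layer depth profile used for tomography tests).
The emitted files reproduce the input dialect exactly: raw Z in stage
units, deflection in volts via $S$, a linear baseline offset and tilt, an
optional mirrored withdraw half, both naming modes, both scan orders, and
seeded Gaussian force noise whose stream depends only on the scene seed
and pixel position (so acquisition order cannot change a pixel's data).
Scene defaults are the constants of a typical soft-sample acquisition:
$K_C = 0.164$ N/m, $S = 0.025$ V/nm, pyramidal tip with
$\alpha = 23.5°$, $\nu = 0.5$, 2 nN maximum load, 2000 approach samples
per curve with the non-contact run equal to the contact travel.

Because generator and analysis share the same contact model, closure tests
validate the *implementation* — calibration, baseline, contact point,
depth arithmetic, fitting, grid bookkeeping — not the model's adequacy for
real materials.  Passing them says nothing about adhesion, viscoelastic
rate dependence, substrate effects, tip wear or piezo creep, none of which
the generator simulates.  The bilayer scene likewise uses an ad-hoc
piecewise stiffness purely as a monotonicity oracle for tomography
ordering, not as a quantitative layered-contact solution.

Validation problem sizes: the end-to-end closure runs a 20 × 20 two-region
scene (10 vs 50 kPa, 200 nm step), noiseless and at 2 % force noise;
contact-point oracle equivalence uses 100 noisy curves; tomography
ordering uses 20 seeded bilayer curves; equivariance checks use 4–6 pixel
per side maps.  These sizes make the whole suite run in about a minute
while leaving every per-pixel tolerance meaningful.

## Known limitations

* Only cone/pyramid contact: no spheres, no adhesion (JKR/DMT), no
  viscoelasticity, no bottom-effect correction.
* The contact-point routines are local heuristics; on very noisy curves
  their placement error grows with the smoothing needed to stabilise them
  (roughly half the smoothing window), which propagates into topography
  and, more weakly, into the modulus.  The two-line intersection routine
  is systematically shallow on curved (Hertzian) contacts — for a
  quadratic contact a chord over depths $[d_1, d_2]$ crosses zero at
  $d_1 d_2/(d_1+d_2)$ inside the contact — so it should be reserved for
  hard samples.
* The stiffness map's slope depends on the fit window for nonlinear
  contacts; it is a ranking tool, not a calibrated modulus.
* Vendor binary formats (.nid, JPK, Bruker) are out of scope; curves must
  be exported to per-pixel two-column text first.

## A minimal run

```{r example, eval = FALSE}
scene <- scene_two_region(8, 8, seed = 1)
data_dir <- tempfile()
generate_map(scene, data_dir)

config <- fv_config(
  acquisition = scene_acquisition(scene),
  analysis = fv_analysis(
    zeroline_window = c(0, 40),
    cp_method = "derivative_smooth", n_smooth = 3,
    tip = fv_tip("pyramid4", 23.5, nu = 0.5)
  )
)

out <- tempfile()
maps <- run_multicurve(config, data_dir, out_dir = out)
tomo <- lapply(
  list(c(0, 35), c(40, 75), c(80, 100)),
  function(w) run_multindentation(config, out, window = w, out_dir = out)
)
autoplot(maps$preliminary_e)
```
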