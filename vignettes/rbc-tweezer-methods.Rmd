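---
title: "Methods: optical-tweezer elasticity analysis of sickle-cell RBC cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical-tweezer elasticity analysis of sickle-cell RBC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbctweezer)
```

# The measurement this package models

In a laser-tweezer stretching experiment, a red blood cell (RBC) is held in
a focused, linearly polarised Gaussian beam while a piezo stage moves the
surrounding fluid at constant speed. The viscous drag displaces the cell
from the trap centre until the optical restoring force balances the drag;
comparing the cell's outline in the free, trapped, and dragged (stretched)
states quantifies its deformability. This package implements the full
analysis chain for two-cohort comparisons — sickle-cell trait (HbAS) versus
sickle-cell anemia (HbSS) RBCs — together with a synthetic-cohort generator
so the chain can be exercised and validated end to end without microscope
data.

# Trapping-force model

The cell is modelled as a thin dielectric cylinder (radius $\rho$,
thickness $t \ll \rho$) lying with its flat face parallel to the beam axis
and displaced by $r_t$ from the trap centre along the polarisation axis.
Because the cell is optically denser than the medium (index ratio
$m = n_{\mathrm{cell}} / n_1 > 1$), the beam polarises it, and the gradient
of the Gaussian intensity over its rim produces a restoring force. The
intensity at rim angle $\phi$ is

$$I(\phi) = \frac{2P}{\pi w_0^2}
  \exp\!\left[-\frac{2\big((r_t+\rho\cos\phi)^2 +
  \rho^2\sin^2\phi\big)}{w_0^2}\right],$$

with $P$ the power at the trap and $w_0$ the beam waist. Integrating over
the cylinder wall gives the closed-form magnitude

$$|F| = \frac{16\,n_1 P \rho^2}{c\,w_0^2}
  \left|\frac{m^2-1}{m^2+1}\right|
  e^{-2(\rho^2+r_t^2)/w_0^2}\; I_0\!\left(\frac{4 r_t \rho}{w_0^2}\right),$$

where $I_0$ is the modified Bessel function of the first kind, order zero.
The azimuthal integral of $\exp(-a\cos\phi)$ over a full period is
$2\pi I_0(a)$, which is why the dimensionless *offset parameter*
$a = 4 r_t \rho / w_0^2$ controls the correction; at $a = 0$ the factor is
exactly 1 and the small-offset approximation (`trap_force_small_offset()`)
is recovered. `trap_force_small_offset()` logs a warning once $a > 0.1$,
where dropping the correction is no longer justified.

Three routes to the same number are exposed deliberately:

* `trap_force_exact()` — the closed form above;
* `trap_force_small_offset()` — the $I_0 \to 1$ approximation, with the
  offset parameter recorded in the result;
* `trap_force_numeric()` — an independent two-dimensional quadrature of
  the intensity over the cylinder wall (trapezoid rule in the periodic
  azimuth, Gauss–Legendre across the thickness) with the same prefactor
  convention.

The quadrature is the oracle: the test suite checks closed form against
quadrature to better than 1% over randomised configurations with
$a \le 2$, and in practice the two agree to machine precision because the
trapezoid rule is spectrally accurate on periodic integrands. The
azimuthal resolution doubles until the result is stable to $10^{-6}$
relative (cap 4096 nodes). The Bessel term overflows double precision near
$a \approx 709$; `trap_force_exact()` refuses with a range error naming
the argument well before that.

Forces are reported as a magnitude plus a direction sign along the
polarisation (drag) axis, $-1$ meaning restoring (toward the trap centre),
which is the physical case for $m > 1$. At $m = 1$ (index matched) the
dielectric contrast $(m^2-1)/(m^2+1)$ vanishes and all three routes return
exactly zero.

Two modelling caveats are intrinsic rather than numerical. First, the
closed form keeps the isotropic (monopole) projection of the
dipole-sheet force on the displaced cell, which is nonzero at $r_t = 0$;
the pure transverse-gradient component would instead carry an $I_1(a)$
factor and vanish at the centre. The package follows the closed form
throughout — the two differ only in how the angular projection of the
surface normal is resolved, the quadrature is defined with the same
convention, and all cohort-level calibration is anchored to drag, not to a
forward force prediction. Second, the default optical constants
(`n_medium = 1.334`, `index_ratio = 1.05`) are conventional literature
values for serum and RBCs, not measurements; they are plainly labelled
configuration values.

# Drag model and calibration

No drag formula is uniquely determined for a disc-shaped cell near a slide
wall, so the package uses Stokes sphere drag with one dimensionless knob:

$$F_d = k_s \cdot 6\pi \eta r v,$$

with $\eta$ the dynamic viscosity (default $10^{-3}$ Pa·s, water at room
temperature), $r$ the cell radius, $v$ the stage speed, and the shape
factor $k_s$ (default 1) absorbing disc geometry and wall proximity.
`calibrate_shape_factor()` fits the single scalar $k_s$ by least squares
to any set of (force, speed) pairs — e.g. the seven per-subgroup mean drag
forces of a stretching experiment — so the drag model can be anchored to
data rather than to the idealised sphere. This one-scalar absorption is
standard practice in trapped-particle force calibration; Faxén-type wall
corrections and unsteady drag are deliberately out of scope.

# Image-based morphometry

The interactive image-analysis step of the original protocol is replaced
by a deterministic pipeline: `render_cell()` draws an elliptical cell with
a one-pixel anti-aliased edge and Gaussian pixel noise (a stand-in for a
single-cell micrograph); `segment_cell()` thresholds by between-class
variance maximisation (Otsu), keeps the largest connected component, and
fills holes (via EBImage); `measure_geometry()` takes the area from the
pixel count and the semi-axes from the second central moments of the mask
(semi-axis $= 2\sqrt{\lambda}$ for each eigenvalue $\lambda$ of the pixel
covariance, with a $1/12\,\mathrm{px}^2$ term for the pixels' own extent,
which also makes a single-pixel mask well defined). Moment-based axes were
chosen over boundary fitting for noise robustness; the test suite verifies
the render–segment–measure round trip against analytic ellipses to 2%
across radii 2–8 µm and axis ratios 1–2, and orientation recovery to 2°.

Because "diameter" is ambiguous for an ellipse, all three radii are
reported; cohort diameter summaries default to $2 r_{\mathrm{equiv}}$ with
$r_{\mathrm{equiv}} = \sqrt{A/\pi}$. The default pixel size, 0.05 µm/px,
is the 100× oil-immersion regime. The renderer draws a flat-top ellipse:
it does not emulate the biconcave (donut) profile of a real RBC, phase
contrast, or debris, so passing imaging tests demonstrate correctness of
the measurement operators, not segmentation robustness on real
micrographs.

# Elasticity metrics

Per cell, with $R$ a reference radius (free or stretched) and $R_T$ the
trapped radius, and likewise for areas:

$$\%DR = 100\,\frac{R - R_T}{R}, \qquad
  \%DA = 100\,\frac{A - A_T}{A}, \qquad
  k = \frac{\Delta F}{\Delta R},$$

plus the axis ratio $r_{\max}/r_{\min}$ of each state. Percent differences
are signed, exactly as defined. Stiffness uses
$\Delta R = r_{\max,\mathrm{stretched}} - r_{\max,\mathrm{trapped}}$ — the
stretch acts along the longitudinal (drag) axis — and, by default,
$\Delta F = F_{\mathrm{drag}} - F_{\mathrm{trap}}$, the change in applied
force between the trapped equilibrium and the dragged state. Because the
published definition of the force change is not precise enough to
adjudicate, `stiffness_force = "drag"` switches to $\Delta F =
F_{\mathrm{drag}}$ alone; the default is the net convention. With forces
in pN and radii in µm the ratio is in µN/m with no unit conversion.
Records without a stretched state yield the free-vs-trapped metrics with
stiffness absent, not an error.

# Sort-and-delete trimming

The published scatter figures were drawn after manually deleting extremes:
sort by one metric, delete a stated number of minima and maxima, repeat.
`trim_step()`/`apply_recipe()` encode each such sequence as explicit data,
with ties broken by cell id so the removal set is independent of input
order, and an audit log listing every removed cell per step. The two
built-in recipes reproduce the published counts (11 of 49 cells for the
HbSS sequence, 10 of 49 for HbAS). Where the published prose was ambiguous
about a count, the literal reading encoded in `builtin_trim_recipes()` is
the package's interpretation, and recipes are fully overridable. Trimming
operates cohort-wide on the per-cell metric table (not per subgroup),
matching the figure-level usage. No statistical outlier test is offered
here by design: the point is to reproduce the manual procedure exactly.

# Cohort statistics

`summarize_cohort()` reports n, sample mean, sample SD ($n-1$), min and
max. `two_sample_ttest()` wraps the standard two-sample t test in both
variants used for the published comparison — pooled variance
($\mathrm{df} = n_a + n_b - 2$) and Welch — always two-sided, which is the
conventional reading when sidedness is unstated. Two degenerate
conventions are made explicit rather than left to error: identical
constant samples give $p = 1$, constant samples with different means give
$p = 0$. `compare_cohorts()` runs both variants per metric and flags
significance at 0.05 and 0.01 only when *both* variants agree, the
conservative reading of "significant under both assumptions".

# The synthetic-cohort generator

The generator defines the study conditions; it is the package's substitute
for the unpublished per-cell raw data. Two modes mirror the two
measurement campaigns, which are numerically inconsistent as one
population (mean diameters 4.02/6.60 µm versus mean radii 4.67/5.24 µm)
and are therefore modelled as two distinct datasets:

**Morphology mode** draws free-cell diameters from a truncated normal
(> 1 µm) at the published mean/SD (SCT 4.02 ± 0.60 µm, SCA 6.60 ± 0.90 µm)
and axis ratios from a normal clipped at $\ge 1$, and optionally renders
each cell to an image for the segmentation pipeline.

**Elasticity mode** builds each record in the order the physics dictates:

1. free $r_{\max}$ from a truncated normal on the published range with the
   published mean (HbAS 4.67 µm on [3.84, 5.38]; HbSS 5.24 µm on
   [4.45, 6.12]); spread defaults to a quarter of the range width;
2. a trapped state compressed by a drawn percentage (defaults 12% HbAS,
   8% HbSS, SD 2.5);
3. a trap force drawn about the published cohort mean (0.26 / 0.33 pN,
   CV 0.25), truncated above at 95% of the cell's drag force so every
   record is physically consistent (drag exceeds trap);
4. a drag force from Stokes drag at the cell's subgroup stage speed;
5. a latent stiffness about the published cohort mean (1.08 / 4.47 µN/m,
   CV 0.25, truncated positive), and a stretched state that inverts the
   stiffness definition:
   $r_{\max,\mathrm{stretched}} = r_{\max,\mathrm{trapped}} +
   (F_d - F_t)/k$;
6. elliptical areas per state, and multiplicative measurement noise on the
   recorded (not latent) values.

The seven subgroup stage speeds are not published (a single 45 µm/s
appears); they are back-solved through the Stokes model at the cohort mean
radius from the published seven-subgroup drag profile (1.48, 1.26, 1.10,
0.853, 0.635, 4.31, 3.23 pN) rescaled so its mean equals the published
cohort mean drag (1.20 / 1.27 pN). The rescaling resolves an internal
inconsistency in the published numbers — the subgroup profile averages
1.84 pN, the cohort means do not — in favour of the cohort means, which
are the quantities the recovery analysis checks; the relative shape of the
profile (and hence the subgroup ordering) is preserved.

Several dispersion parameters have no published value and are package
defaults, chosen once as plausible for RBC optical-stretching data: force
and stiffness CVs of 0.25, axis ratio 1.05 ± 0.03, trap compression SD
2.5, measurement noise SD 1%. The compression *means* (12% vs 8%) are
likewise unpublished; they were set so the trait cohort deforms more, the
direction the published comparison reports, and are the only generator
defaults that encode a between-cohort difference beyond the printed
means. The default noise model (`noise_model = "scale"`) applies one
multiplier per cell shared across all geometry values — a per-cell
magnification/calibration error — which leaves percent differences
untouched and perturbs stiffness only at second order. The alternative
`"independent"` model perturbs each state separately and redraws any
multiplier that would invert the trapped/stretched ordering; it makes
per-cell stiffness noticeably noisier, which is the realistic but less
benign choice.

Everything is driven by R's Mersenne–Twister generator through a private,
restored RNG stream, so a (config, seed) pair reproduces a dataset
exactly, bit for bit, across runs and platforms.

What the generator does *not* emulate: biconcave geometry, sickled
morphologies, optical-force/shape feedback during stretching, per-subgroup
heterogeneity beyond the speed, and any correlation between cell size and
stiffness. Passing recovery tests therefore demonstrate that the analysis
chain inverts the generative model at the study's sample sizes — not that
it would be unbiased on real micrographs.

# Problem sizes and numerical choices

The validation suite uses the study's own sizes: 49-cell, 7-subgroup
elasticity cohorts and 200-cell morphology surveys, plus a 10 500-cell
scaled-up elasticity run to separate bias from sampling noise (recoveries
tighten to 2% there, versus 10% at n = 49). Truncated normals are drawn by
rejection (the truncation regions here keep acceptance high); a zero SD
collapses to the mean deterministically. Type-I calibration of the t tests
is checked under the null over 1000 replicate cohort pairs at n = 49 per
arm.

# The fitting interface

Following the classic R modelling idiom, the front door is a single
fitting-style function: `rbc_elasticity(records)` takes the per-cell
record table (one or two cohorts), computes all per-cell metrics, applies
optional trimming recipes, and returns a classed object with `print`,
`summary`, `coef` (cohort-mean matrix), `plot` (comparison figures) and
`simulate` (regenerate synthetic cohorts from the fitted means — a
parametric-bootstrap-style closure check) methods. The pipeline stages
remain available as plain functions for scripted use, and `read_records`/
`write_records`/`write_report`/`read_run_config` handle the CSV, JSON and
YAML interchange formats with laboratory units (µm, pN, µN/m, mW) at the
interface and SI internally.

# Known limitations

* The cylinder model ignores the biconcave profile; the thin-disc
  approximation enters only through the closed form's prefactor, but a
  thickness-resolved model would change the absolute force scale.
* Optical constants and beam waist are configuration inputs, not
  measurements; absolute force predictions inherit their uncertainty,
  which is why cohort-level force statistics are generator-configured
  rather than forward-predicted.
* The drag shape factor conflates disc geometry and wall proximity into
  one scalar; it is honest calibration, not hydrodynamics.
* Trimming recipes reproduce a manual procedure; they are not a defensible
  outlier policy for new data.
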