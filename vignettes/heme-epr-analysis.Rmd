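---
title: "EPR analysis of low-spin ferric hemes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPR analysis of low-spin ferric hemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeEPR)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and the choices made
where the methodology left room for them.

## 1. The one-hole crystal-field model

A low-spin Fe(III) ion (d⁵, S = 1/2) in a heme has its five d electrons in
the t₂g set; the single hole makes the g-tensor exquisitely sensitive to
the ligand field. In the Griffith–Taylor treatment the Kramers ground
doublet is an admixture of the three t₂g orbitals with real coefficients
`a` (d_yz), `b` (d_xz) and `c` (d_xy), and the principal g-values follow
from

$$g_z = 2[(a+b)^2 - c^2],\quad g_y = 2[(a+c)^2 - b^2],\quad
g_x = 2[a^2 - (b+c)^2].$$

`g_from_coefficients()` implements this forward map. Experimentally one
measures the g-values and inverts:

$$a = \frac{g_z+g_y}{D},\; b = \frac{g_z-g_x}{D},\; c = \frac{g_y-g_x}{D},
\qquad D = \sqrt{8(g_z+g_y-g_x)},$$

which `coefficients_from_g()` evaluates. The two maps are algebraically
exact inverses (the test suite asserts the round trip to 1e-12), because
$g_z+g_y-g_x = 2(a+b+c)^2$, so $D = 4(a+b+c)$.

The normalization $m^2 = a^2+b^2+c^2$ diagnoses the adequacy of the
pure-t₂g description: values below one indicate covalent delocalization
onto the ligands, values above one admixture of excited configurations.
`analyze_table()` flags $|m^2-1| > 0.02$ with an advisory note rather than
an error — the deviation is interpretive, not a computational failure.

The crystal-field splittings in units of the spin–orbit constant,

$$V/\xi = \frac{g_x}{g_z+g_y} + \frac{g_y}{g_z-g_x},\qquad
\Delta/\xi = \frac{g_x}{g_z+g_y} + \frac{g_z}{g_y-g_x} - \frac{V}{2\xi},$$

are Taylor's standard forms. Δ tracks the strength of the axial ligand
field (it separates d_xy from the d_xz/d_yz pair); V the rhombic splitting
within that pair, i.e. the asymmetry and orientation of the axial ligands.
ξ is an optional input (`crystal_field_ratios(g, xi = 400)`); the free-ion
value ≈400 cm⁻¹ is a common choice, but since covalency reduces ξ the
package reports ratios by default and converts only on request.

Inputs are canonically ordered $g_z \ge g_y \ge g_x$ on construction
(`gtensor()` warns when it reorders), because the formalism assumes the
proper axis assignment. Degenerate tensors with $g_y = g_x$ or
$g_z = g_x$ make a denominator vanish; these raise an error naming the
offending difference rather than returning infinities.

### Uncertainty propagation

Published tables give ± values on the g's without stating a propagation
rule. The package offers three (`propagate_uncertainties()`):

* `linear_sum` (default): $\sigma_f = \sum_i |\partial f/\partial g_i|\,\sigma_i$,
  a worst-case rule with analytic partial derivatives. For the
  resting-state tensor it gives σ(V/ξ) = 0.063, matching the ±0.06 a
  worst-case reading of the published table implies.
* `quadrature`: root-sum-square of the same terms; never exceeds
  `linear_sum` (Cauchy–Schwarz, asserted property-style in the tests).
* `monte_carlo`: sample standard deviations over independent Gaussian
  draws; requires an explicit seed so results are reproducible, and at
  least 1000 draws.

No single rule reproduces every published uncertainty column (the ±0.18 on
Δ/ξ, for instance, sits between the linear 0.12 and the quadrature 0.07
for any plausible reading); the choice is therefore exposed rather than
hidden.

## 2. Powder CW simulation

`simulate_cw()` computes a field-swept powder spectrum for an S = 1/2
centre from first principles:

* **Orientation average.** A deterministic Fibonacci spiral places
  `n_orientations` equal-area points on the hemisphere (uniform in
  cos θ). No random seed is involved, so spectra are bit-reproducible and
  self-convergence can be measured by doubling the grid: with 2000 points
  the change on doubling is below 0.5% RMS for the systems treated here.
* **Resonance condition.** Each orientation resonates at
  $B = h\nu / (g(\theta,\phi)\mu_B)$ with
  $g^2 = g_x^2 l_x^2 + g_y^2 l_y^2 + g_z^2 l_z^2$.
* **g-strain.** Frozen-solution conformational heterogeneity is modelled
  as independent Gaussian distributions on each principal g-value,
  mapped to a field-domain width to first order:
  $\sigma_B = (B/g)\sqrt{\sum_i (g_i l_i^2 \sigma_{g_i}/g)^2}$.
  The three strain values are interpreted as σ; a `strain_fwhm = TRUE`
  switch converts from FWHM conventions. Cross-correlations between the
  strain components are not supported.
* **Residual linewidth** `lw_mT` is a Gaussian FWHM added in quadrature in
  the field domain.
* **Intensity.** The 1/g frequency-to-field (Aasa–Vänngård) factor is
  applied; transition-moment (g₁-type) anisotropy is omitted — at X band
  for g ≈ 1.9–2.6 it is a percent-level correction to relative
  intensities and does not move the turning points.
* **Detection.** `first_derivative` mode returns the analytic derivative
  of the accumulated Gaussians. Field modulation is *not* convolved: at a
  1 mT modulation amplitude against ≥2 mT linewidths, pseudo-modulation
  broadening is negligible. The absorption integral is normalized to 1.

Each orientation's Gaussian is accumulated on its ±6σ field window only;
the truncated tail mass is below 1e-8 per line, far under the 1e-3
normalization tolerance the tests enforce.

## 3. Fitting CW spectra

`fit_gtensor()` recovers (g_z, g_y, g_x), the three strain components and
the linewidth by least squares against `simulate_cw()`:

* **Preprocessing** (`preprocess()`): a polynomial baseline (default
  order 1) anchored on the outer 10% of the sweep — where a bounded
  powder pattern is flat — followed by Savitzky–Golay smoothing
  (order 2, window 11 by default; the window must be odd and is
  configurable because the appropriate value depends on the point
  density).
* **Profiled nuisance parameters.** Overall amplitude and vertical offset
  enter linearly and are solved by linear least squares inside the
  objective, leaving a 7-dimensional nonlinear problem and making the fit
  exactly invariant to intensity scaling of the input.
* **Optimizer.** Deterministic Nelder–Mead over *offsets* from the
  user-supplied start, scaled per parameter (0.05 per g, 0.02 per strain,
  1 mT for the linewidth) so the initial simplex takes sensible steps for
  every coordinate; one restart from the incumbent follows the first run.
  This mirrors operator-guided practice: the start comes from the
  turning points (`detect_g_init()` maps the derivative extrema through
  the resonance condition), and a local search refines it. Box bounds are
  enforced as penalties; canonical g-ordering likewise.
* **Convergence and errors.** A budget-limited simplex near the noise
  floor keeps rearranging the broadening parameters long after the
  g-estimates are stable; `converged` therefore reports either the
  simplex tolerance being met or g-stability across the restart to
  5e-4. Non-convergence is reported in the result object, never thrown.
  Parameter uncertainties from the finite-difference Hessian at the
  optimum are advisory.

On synthetic spectra with 1% RMS noise (the generator's default emulating
the measured signal-to-noise), the median recovery error over ten seeds is
well inside ±0.005 for all three g-values — the precision with which such
g-values are typically quoted.

## 4. Proton HYSCORE analysis

For an I = 1/2 nucleus coupled to the S = 1/2 electron, with axial
hyperfine coupling (isotropic part `aiso`, dipolar part `T`) at polar
angle θ from the unique axis:

$$A(\theta) = a_{iso} + T(3\cos^2\theta - 1),\qquad
B(\theta) = 3T\sin\theta\cos\theta,$$
$$\nu_{\alpha,\beta} = \sqrt{(\nu_I \mp A/2)^2 + (B/2)^2}.$$

`ridge_curve()` sweeps θ over [0, π/2] and returns both the
(ν_α, ν_β) branch and its mirror, the (+,+)-quadrant correlation ridge of
a 4-pulse HYSCORE experiment. Two optional weights modulate it:

* **Blind spots**: the τ-dependent suppression
  $\sin^2(\pi\nu_\alpha\tau)\sin^2(\pi\nu_\beta\tau)$, applied when a τ is
  supplied (208 or 250 ns in the experiments emulated here). It moves
  intensity, never positions.
* **Orientation selection**: at an observer field on the g_z edge only
  molecules with the field near the g_z axis contribute, so θ is
  restricted near the Fe–H polar angle β (22° for the fitted water
  proton). A Gaussian acceptance window stands in for the full
  excitation-bandwidth calculation; its default width (15°) corresponds
  to the ~60 MHz bandwidth of a 16 ns π pulse.

The ridge arcs away from the antidiagonal ν₁+ν₂ = 2ν_I; its apex
displacement per coordinate is, to second order in the coupling,
9T²/(32ν_I). `ridge_apex_shift()` measures the displacement from the
ridge itself. The second-order formula is accurate to ~0.1% for
T/ν_I ≤ 0.1 but falls ~2% above the exact value at the water-proton
coupling (T/ν_I ≈ 0.43) — a property of the approximation, documented
rather than hidden; the unit tests pin the formula at weak coupling and
the exact measurement elsewhere.

`point_dipole_distance()` inverts
$T = (\mu_0/4\pi h)\, g_e\beta_e g_n\beta_n / r^3$; the prefactor
(79.06 MHz Å³ for ¹H with g_e = 2.0023) is evaluated from CODATA
constants at run time, never hardcoded. The free-electron g-value is the
conventional choice at this level of approximation; since r ∝ g_e^{1/3},
substituting the measured g_z = 2.44 would lengthen r by
(2.44/2.0023)^{1/3} ≈ 7%, a useful bound on the systematic error of the
convention.

Only ¹H ships in the nuclear-constants table. I = 1 nuclei (¹⁴N of the
heme and of bound imidazole) produce double-quantum correlation peaks
whose positions need the quadrupole tensor; without published parameters
to validate against, a ¹⁴N module would be decoration, so it is an
explicit non-goal and `larmor_frequency()` lists the supported nuclei in
its error message.

## 5. The 2D processing chain

`process_hyscore()` converts a time-domain map to a magnitude spectrum
with the standard sequence, each step fixed to one dialect:

1. polynomial baseline subtraction, order 3, rows first then columns
   (the common ESEEM practice; the order of the two passes is not
   prescribed anywhere authoritative, so it is fixed and documented);
2. separable Hamming apodization,
   $w_n = 0.54 - 0.46\cos(2\pi n/(N-1))$;
3. zero filling of each axis to `zerofill_factor` × the next power of
   two (default ×2 — "zero filled" without a factor is conventionally
   read as at least doubling);
4. 2D discrete Fourier transform (`stats::fft`), magnitude, and
   restriction to the (+,+) quadrant with frequency axes in MHz derived
   from the dwell times.

The chain is linear up to the magnitude stage (asserted to 1e-10 on the
complex output) and energy-conserving in the Parseval sense. A constant
(DC) map is annihilated by the baseline stage; non-uniform dwell or a
baseline order reaching the point count are structural errors.

## 6. Synthetic data: what it emulates and what it does not

The generator module produces every input the pipeline consumes, under a
mandatory seed:

* `make_cw()`: simulator output plus an optional linear ramp and white
  Gaussian noise, RMS specified relative to the peak intensity (default
  1%, the scale seen in the measured spectra this package emulates).
* `make_hyscore_trace()`: sums of exponentially decaying cosine products
  at specified correlated frequencies (default dwell 16 ns, 128×128
  points, τ 208 ns, matching the acquisition settings of the emulated
  experiments), DC offset, optional blind-spot factors, white noise.
  Frequencies beyond the Nyquist limit of the dwell raise an error naming
  the limit.
* `make_fixture_suite()`: a reproducible file set (BES3T in both byte
  orders, 2D real and complex variants, ASCII twins, the g-value table)
  with an MD5 manifest.

Deliberate simplifications: noise is white (no 1/f drift beyond the
ramp), HYSCORE amplitudes are heuristic constants rather than
density-matrix ESEEM intensities, and no instrumental artifacts (cavity
background, field offsets) are modelled. Consequently, passing recovery
tests demonstrate correctness of the analysis chain under the stated
statistical model — not robustness to every pathology of real
spectrometer output.

## 7. File formats

The BES3T subset implemented covers the layouts such CW and HYSCORE
datasets use: IKKF REAL/CPLX, IRFMT D (float64) and I (int32), BSEQ
BIG/LIT, linear X and Y axes. Values round-trip bit-exactly; the reader
refuses size mismatches rather than truncating, and detects (and rejects)
nonlinear companion-axis files. Gauss field axes are normalized to mT on
read so the package has a single internal field unit. Legacy ESP/WinEPR
formats are out of scope.

## 8. Problem sizes

Defaults were chosen as the smallest sizes at which the quantities of
interest are converged: 2000 orientations and 1024–2048 field points for
presentation-quality CW spectra (grid error <0.5% RMS); 400 orientations
inside fitting objectives (the profiled residual is insensitive to grid
noise well below the measurement noise); 128×128 HYSCORE traces zero
filled to 256×256 (0.24 MHz bins, comfortably finer than the ridge
features). All are arguments, not constants.
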