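---
title: "Injection-less conductance sizing: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injection-less conductance sizing: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condsize)
```

## The measurement and its model

A tetrapolar conductance guidewire carries four ring electrodes: the outer
pair drives a small alternating current (100–300 µA rms), the inner pair
senses the voltage drop. Inside a blood vessel the measured conductance
`G = 1/R` is the sum of three parallel pathways:

* the **lumen annulus** between the wire shaft (diameter $d_{GW}$) and the
  vessel wall, $G_b = \sigma_b \pi (d_b^2 - d_{GW}^2) / (4L)$;
* the **vessel wall annulus** of thickness $t_w = TR \cdot d_b$,
  $G_t = \sigma_t \pi d_b^2\, TR (1 + TR) / L$;
* the **surrounding medium** (perivascular tissue in vivo, a saline bath
  ex vivo), a kernel-weighted annular integral described below.

Both annulus terms are axial conductances of coaxial shells over the
sensing separation $L$, which presumes a cylindrical lumen and an axially
uniform excitation field across the sensing segment. The field is
acceptably uniform when the excitation separation $d$ is at least twice
the lumen diameter; `cylindricity_check()` warns (but does not refuse)
below that ratio. Electrode centre-to-centre separations include one
electrode width per gap; with the default 1 mm electrodes the "5-5-5"
peripheral wire has $L = 6$ mm, $d = 18$ mm and a 0.889 mm (0.035")
shaft, and the "2-2-2" coronary wire has $L = 3$ mm, $d = 9$ mm and a
0.3556 mm (0.014") shaft. The 1 mm width is the value that makes the
annulus model reproduce measured lumen and wall conductances of a
reference ex-vivo vessel to a few percent, and it is a configuration knob
(`guidewire(..., electrode_width_mm = )`).

The measurement problem is the inverse one: given `R`, recover $d_b$. With
no conducting surroundings the model inverts in closed form
(`invert_diameter_closed_form()`); the square root is forced by
dimensional analysis:

$$d_b = \sqrt{\frac{4L + \pi R \sigma_b d_{GW}^2}
                  {\pi R\,(\sigma_b + 4\sigma_t TR(1+TR))}}.$$

## Extracting R: the two-frequency series-RC model

The electrode–electrolyte interface behaves as a polarization capacitance
in series with the ohmic system resistance, so the magnitude measured at
angular frequency $\omega$ is $|Z|^2 = R^2 + 1/(\omega C)^2$. Magnitudes
at two frequencies determine $(R, C)$ by a linear solve in
$(R^2, 1/C^2)$; `fit_series_rc_multi()` generalizes this to a least-squares
fit over a whole spectrum and tabulates the per-pair estimates, which agree
to machine precision on clean series-RC data. Two contracts follow from
the circuit: $|Z|$ must not increase with frequency (violations raise an
error rather than returning a meaningless fit), and $R$ can never exceed
the smallest measured $|Z|$. On noisy spectra the unconstrained
least-squares optimum can sit slightly outside that region, so the fit is
projected back onto it (constrained least squares). A perfectly flat pair
is purely ohmic and reports `C = Inf` rather than failing.

The default working pair is 10 and 20 kHz: low enough that tissue
dispersion is mild, far enough apart that the polarization term (about
160 Ω at 10 kHz for the default 100 nF) separates the two magnitudes
clearly.

## Calibration

**Fluid conductivity.** In a rigid phantom (or the introducing catheter,
in vivo) there is no parallel pathway, so `phantom_conductivity()` inverts
the lumen-annulus formula exactly. The packaged
`saline_conductivity_table()` holds the effective ("ideal") conductivity
of 0.45% saline measured this way with the 5-5-5 wire in 1.75–8 mm
phantoms at 10–80 kHz. The apparent diameter dependence absorbs field
non-uniformity, which is why the package treats the table as an empirical
lookup rather than a material property. `conductivity_lookup()`
interpolates bilinearly in (log10 frequency, diameter) — dispersion is
closer to log-linear in frequency — and clamps at the table edges instead
of extrapolating, a deliberately conservative choice.

**Wall conductivity.** Ex vivo, with the vessel suspended so nothing
conducts outside the wall, the wall conductance is total minus lumen, and
`tissue_conductivity_from_exvivo()` inverts the wall-annulus formula. On
the packaged reference measurements (3.2 mm bovine carotid, TR = 0.79)
this gives 0.39–0.41 S/m across 10–80 kHz:

```{r tissue}
gw <- guidewire("5-5-5")
round(tissue_conductivity_from_exvivo(c(2.97e-3, 3.12e-3), 3.2e-3, 0.79, gw), 2)
```

Arterial wall conductivity is essentially flat in this band, so a single
assumed `sigma_t = 0.4` S/m is the package-wide default for sizing.

## The surrounding-medium (parallel-field) model

Current escaping the lumen samples the surroundings with a weight that
decays with radial distance from the lumen wall, because the excitation
field falls off away from the electrodes. The bath term is

$$G_{bath} = \frac{2\pi\sigma_{bath}}{L}
  \int_0^{t_{bath}} w(t_w + x)\,(r_{wo} + x)\,dx,$$

with $w(0) = 1$ at the lumen wall, non-increasing. Kernel families
(`field_kernel()`):

* `exponential` (default), $w(x) = e^{-x/s}$, scale $s$ fitted to a
  measured bath-thickness series by one-parameter least squares
  (`fit_kernel_scale()`); on the packaged ex-vivo series the fit gives
  $s \approx 6.9$ mm with an RMS misfit under 7% of the largest bath
  conductance;
* `dipole`, $w(x) = (1 + x/s)^{-3}$, the far-field decay of a source–sink
  electrode pair, as an alternative shape;
* `uniform`, $w \equiv 1$, the homogeneous-annulus limit used for exact
  degenerate checks.

The exact field expression for a finite tetrapolar probe in a three-layer
cylindrical medium is not available in closed form, so the kernel
interface isolates that uncertainty behind a one-parameter family while
enforcing the behaviors the data show: the bath conductance grows with
bath thickness, saturates (the kernel is integrable), and its fraction of
the total falls as the wall thickens.

One genuine limitation of any single-scale kernel deserves note. The
measured series still grows strongly 12–21 mm out, which forces a shallow
kernel ($s \gtrsim 5$ mm); such a kernel is nearly flat across the first
millimetres, so for a *very thin* bath shell the annular-area growth with
wall thickness can slightly outweigh the field decay, and the predicted
parallel fraction can rise by a few tenths of a percentage point between
small TR values at the thinnest shell. Everywhere else — and for the
thin-wall vs thick-wall ordering at every thickness — the fraction is
monotone decreasing in TR, as physical intuition demands. A kernel steep
enough to remove the thin-shell wiggle ($s \lesssim 3.4$ mm) is
incompatible with the measured far-field growth. Model-predicted fraction
*values* are therefore model-specific; only their orderings and
monotonicities should be compared across setups.

```{r fractions}
series <- exvivo_bath_series()
round(100 * bath_fraction_empirical(series), 2)
```

## The sizing algorithm

`estimate_diameter()` implements the iterative inversion:

1. fit the series-RC model on the working pair, giving `G = 1/R`;
2. for a candidate diameter `d`, look up $\sigma_b$ at the lower working
   frequency and `d`, and compute $G_b(d)$;
3. measurement-side parallel conductance: $G - G_b(d)$; model-side:
   $G_t(d) + G_{bath}(d)$;
4. bisect `d` on $[1.05\,d_{GW},\, d_{exc}/2]$ until the two agree.

The bracket is physical: the lumen cannot be smaller than the wire nor
larger than the cylindricity limit. Bisection was chosen over Newton for
guaranteed robustness — the mismatch is monotone on the bracket, and no
derivative of the kernel integral is needed. The bisection runs to bracket
collapse (relative width $10^{-6}$, at most 100 iterations) and the
classical 2% relative agreement of the two parallel-conductance estimates
is evaluated *at exit* as the convergence declaration. Stopping the
iteration the moment the mismatch first dips under 2% would leave a
quasi-random tolerance-sized quantization (up to ~1% in diameter even on
perfect data); running to collapse costs a handful of extra iterations and
removes that error entirely, while the reported `mismatch` keeps the 2%
criterion's meaning. The fluid conductivity is re-interpolated at every
candidate, so the returned `sigma_b_used` is self-consistent with the
returned diameter. Failure modes are explicit: a total conductance below
the lumen term everywhere is an infeasible measurement; a mismatch that
never changes sign on the bracket has no solution; both raise errors
rather than returning a boundary value.

Degenerate inputs behave sensibly: with no conducting surroundings the
algorithm reproduces the closed-form inversion; `TR = 0` removes the wall
term; a zero-conductivity bath contributes nothing.

**Sensitivity.** The wall parameters are assumptions in vivo, so
`sensitivity_analysis()` reports the signed percent diameter change when
the assumed wall thickness or wall conductivity is perturbed (default
+20%) with the measurement held fixed. Because the diameter scales as the
square root of the lumen conductance, parallel-pathway errors roughly
halve in the diameter: over TR 0.2–0.6 at $\sigma_b = 1.4$,
$\sigma_t = 0.4$ S/m the +20% thickness sensitivity runs 2.5–6.8% and the
+20% conductivity sensitivity 2.1–4.9%, both growing with TR since thicker
walls carry more of the current.

```{r sens}
round(sapply(c(0.2, 0.4, 0.6), function(tr)
  sensitivity_analysis(1.4, 0.4, tr, "t_w")), 2)
```

## The synthetic generator and what passing tests mean

`simulate_spectrum()` forward-composes the three-pathway model into a
system resistance, applies the series-RC polarization magnitude (default
`C_pol = 100 nF`, chosen to separate the 10/20 kHz magnitudes clearly),
and multiplies each voltage by $(1 + \epsilon_f)$,
$\epsilon_f \sim N(0, \mathrm{noise\_cv})$ independently per frequency —
the simplest proxy for instrument noise. With a fixed seed the output is
bit-identical across runs. `make_exvivo_battery()` builds validation sets
mirroring a realistic ex-vivo design: diameters evenly spanning
1.7–8 mm, TR spanning 0.16–0.9 (shuffled against diameter so the two are
not confounded), the coronary wire auto-selected below 4 mm, fluid
conductivity taken from the packaged saline table at 10 kHz, and no
conducting surroundings (a vessel suspended in air or de-ionized water).
An optional duplicate mode re-simulates each vessel with fresh noise for
repeatability analysis.

The generator emulates geometry, calibration self-consistency, electrode
polarization and multiplicative noise. It does **not** emulate electrode
contact artifacts, drift, mains interference, phase information,
Cole-type tissue dispersion, non-circular lumens, axial taper within the
sensing segment, or pulsatile motion. Closed-loop recovery therefore
demonstrates that the inversion is correct and noise-stable *under the
model's own physics*, not that the method is robust to everything a
catheter lab produces.

Noise propagation is strongly heteroscedastic across a battery: the
diameter error scales roughly with $d_b \cdot G/G_b$, so large
thick-walled vessels amplify voltage noise several-fold more than small
ones. Two practical consequences, both visible in validation runs: a
pooled SD understates the worst vessel, and in an 11-vessel set the
chance that *every* point falls within 2 pooled SDs is well below one for
many noise draws even when the method is working exactly as designed. At
1% voltage noise the 10/20 kHz magnitudes of a small high-resistance
vessel can occasionally invert order outright, which the series-RC fit
correctly rejects as a model violation rather than silently absorbing.

**Agreement statistics.** `bland_altman()` summarizes predicted-vs-measured
pairs by the mean and sample (n−1) standard deviation of the differences —
the SD of differences is the repeatability coefficient under the standard
convention — plus the fractions of points within 1 and 2 SD of the mean
difference (a flag switches the reference to zero), the 1.96 SD limits of
agreement, and an OLS line with $R^2$ (squared Pearson correlation).

## Numerical choices

* Bath integral: composite Simpson with 1000 fixed radial steps; doubling
  the step count changes the result by well under $10^{-6}$ relative, and
  the rule is exact for the linear integrand of the uniform kernel.
* Kernel-scale fit: `stats::optimize()` on the log of the scale over
  [0.01, 1000] mm; the log parameterization keeps the 1-D search
  well-conditioned across decades.
* Table interpolation: bilinear in (log10 f, d), exact at nodes, edge
  clamped.
* Two-frequency algebra: closed-form linear solve per pair; spectrum-wide
  fit via `stats::lm` on the transformed variables with projection onto
  the physical constraint set.
* Tie-breaks and degeneracies: flat spectra report `C = Inf`; zero wall
  (TR = 0) with positive wall conductance is rejected in calibration;
  relative parallel-conductance mismatch falls back to a total-conductance
  denominator when the model-side parallel term is zero.

Validation problem sizes, chosen to probe the full design space while
keeping each property check on the order of seconds: 100-point randomized
noiseless recovery grids, an 11-vessel battery at 1% noise, 50-replicate
noise ensembles for bias/scatter, and 40-replicate ensembles per noise
level for the scatter-vs-noise monotonicity check.

## Known limitations

* The surrounding-tissue conductivity and extent are inputs, not
  measurands; in vivo they can only be estimated, and the sensitivity
  analysis quantifies the induced diameter error (fat ~0.06 S/m vs muscle
  ~0.38 S/m is the realistic extreme range).
* The kernel family is phenomenological; its scale absorbs the unknown
  field geometry and should be refitted when the guidewire, bath
  conductivity or vessel size class changes materially.
* The conductivity table is specific to the fluid, temperature and
  guidewire used to produce it; blood at body temperature needs its own
  table.
* Phase is discarded; constant-phase-element or Cole models of the
  interface are out of scope.
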