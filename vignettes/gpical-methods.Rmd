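---
title: "Methods: green-pixel-intensity calibration for chlorophyll estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: green-pixel-intensity calibration for chlorophyll estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpical)
```

## The measurement model

A culture of a green microalga photographed against a white background
appears greener the more chlorophyll it contains. `gpical` quantifies that
color as the green pixel intensity of an 8-bit RGB pixel,

$$\mathrm{GPI} = \frac{G}{R+G+B},$$

a dimensionless ratio in $(0, 1]$. Two properties make this ratio a usable
instrument response. First, it is invariant under a common multiplicative
change of all three channels, so a shadow that darkens part of the vessel
(the flask lid casts one) does not move the reading; the package still
stratifies its culture pixels across the shadowed and lit regions, as the
manual protocol does, so that any residual non-multiplicative shading is
averaged rather than ignored. Second, every achromatic pixel gives exactly
$1/3$, so white-background readings cluster tightly and the background
subtraction below is well conditioned.

One photograph yields a background-corrected reading

$$\mathrm{GPI}_{\mathrm{sample}} = \overline{\mathrm{GPI}}_{\mathrm{culture}}
 - \overline{\mathrm{GPI}}_{\mathrm{background}},$$

with 3 culture pixels and 6 background pixels (3 left, 3 right of the
vessel). Each sample is photographed three times; a media-only baseline
flask is photographed the same way each sampling day, and the final
response is

$$\mathrm{GPI}_{\mathrm{final}} =
  \overline{\mathrm{GPI}}_{\mathrm{sample}} -
  \overline{\mathrm{GPI}}_{\mathrm{baseline}}.$$

Baseline subtraction zeroes the assay: blanks read approximately 0, and
negative readings are deliberately retained (never floored) so the blank
distribution used for the limit of blank is unbiased.

The reference axis comes from conventional solvent extraction (80% acetone /
20% methanol) with absorbances at 663.6 and 646.6 nm, each corrected by the
750 nm turbidity reading. The extinction-coefficient set used gives, per ml
of original culture,

$$\begin{aligned}
\text{chl } a &= (12.25\,E_{663.6} - 2.55\,E_{646.6})\,v_e/v_c,\\
\text{chl } b &= (20.31\,E_{646.6} - 4.91\,E_{663.6})\,v_e/v_c,\\
\text{chl } a{+}b &= (17.76\,E_{646.6} + 7.34\,E_{663.6})\,v_e/v_c.
\end{aligned}$$

The total-pigment coefficients are exactly the sums of the individual ones
($12.25-4.91 = 7.34$, $20.31-2.55 = 17.76$), so `chl_total == chl_a + chl_b`
is an algebraic identity the implementation preserves to machine precision
and the tests assert. The printed single-volume form of these equations
corresponds to an extract volume $v_e$ of 1 ml; the package parameterizes
$v_e$ explicitly (default 1 ml) because the ratio, not the culture volume
alone, is what the spectrophotometer sees. Because the $2\times 2$
coefficient matrix has determinant $236.277 \ne 0$, the equations invert
uniquely; `absorbance_from_chlorophyll()` uses that inverse to manufacture
synthetic spectrophotometry records with known ground truth.

## Calibration and its validation

The standard curve is an ordinary least-squares fit of
$\mathrm{GPI}_{\mathrm{final}}$ on chlorophyll concentration, restricted to
the response's linear interval. No weighting or robust loss is used: the
response noise is approximately constant on the GPI scale across the
interval, and OLS keeps every downstream quantity (standard errors,
confidence bands, ANCOVA F-tests) in its textbook form.

**Linear-interval detection.** Colorimetric responses saturate: past a
breakpoint concentration the curve bends toward a plateau. Points are
sorted by concentration and the highest one removed repeatedly, refitting
and recomputing $R^2$, for as long as removal improves it; the first prefix
(at least 3 points) whose $R^2$ further removal fails to improve is
retained. The stopping rule matters. Taking instead the global maximum of
$R^2$ over all prefixes looks equivalent but is not: once the retained range
is noise-limited, shrinking it further shrinks the concentration spread, and
a short, nearly collinear prefix will beat the full linear range's $R^2$
purely by chance (with a handful of points the probability is large, not
small). In simulation at the package's nominal noise, the global-maximum
rule discards most of the genuine linear interval in roughly a third of
runs, while the stepwise rule recovers the breakpoint to within one
concentration grid step in the large majority of runs — the acceptance suite
quantifies this. Exact ties stop the walk, keeping the wider interval. A
secondary, subjective criterion sometimes used in manual practice
("noticeably increased scatter" beyond the linear range) is intentionally
not encoded as a rule.

**Confidence band.** The pointwise $1-\alpha$ band for the mean response is
the classical $\hat y(x) \pm t_{1-\alpha/2,\,n-2}\, s\sqrt{1/n +
(x-\bar x)^2/SS_x}$; at $\bar x$ the half-width reduces to
$t\,s/\sqrt{n}$, and it grows monotonically with $|x - \bar x|$ — both are
tested.

**Limits of blank and detection.** The CLSI-style convention is used:
$\mathrm{LoB} = \bar b + 1.645\,s_b$ over blank replicates, and
$\mathrm{LoD}(\mathrm{GPI}) = \mathrm{LoB} + 1.645\,s_{\mathrm{low}}$ over
replicate readings of a low-concentration sample, converted to
concentration through the calibration line as
$(\mathrm{LoD}_{\mathrm{GPI}} - \text{intercept})/\text{slope}$ and floored
at 0. The same conversion is applied to the LoB, which preserves
$\mathrm{LoD}_c \ge \mathrm{LoB}_c \ge 0$ whenever the slope is positive.
Which replicates count as "low concentration" is a genuinely open choice;
by default the package uses the triplicate photograph readings of the
lowest-concentration non-blank point retained in the linear interval, and
the argument is exposed for laboratories that run dedicated low-level
replicates. The LoD is also the lower limit of the linear interval: below
it the assay cannot distinguish a sample from a blank.

**Precision.** Each calibration point carries three per-photograph
readings. Every replicate is back-predicted to a concentration through the
fitted line and the percent relative standard deviation
($100\,s/\bar x$) of the three predictions computed; the unweighted mean
over points at or above the LoD is reported. Computing %RSD on
back-predicted concentrations rather than raw GPI expresses precision in
assay units; the restriction to the quantifiable range matters because the
ratio diverges as the true concentration approaches zero, which is a
property of the estimand, not of the assay. This basis (concentration vs
GPI) is ambiguous in manual practice; the choice is recorded here and in
the function documentation.

**Inverse prediction.** Concentration is read off as
$(\mathrm{GPI} - \text{intercept})/\text{slope}$, an exact inverse of the
fitted line (tested to $10^{-9}$). Estimates below the LoD are flagged
`below_LoD`; readings above the linear interval's GPI ceiling are flagged
`dilute_sample` — the response is saturating there, so the sample should be
diluted and re-photographed. Point estimates are always reported alongside
the flag.

## Comparing calibrations across conditions

Whether one standard curve can serve under an altered condition (reduced
sample volume, raised pH, bacterial contamination) is decided by an
ANCOVA-style general linear model on the pooled points,

$$\mathrm{GPI} \sim \text{group} + \text{chl} + \text{group:chl},$$

F-testing the interaction (slopes) first and, only when slopes are
compatible at $\alpha$, dropping the interaction and F-testing the group
term (intercepts). Testing intercepts of lines with different slopes is not
meaningful, so the second test is withheld in that case. Both F-statistics
equal the nested-model residual-sum-of-squares formula, which the tests
verify against an oracle built directly from normal equations. Comparisons
are restricted to the control curve's linear interval by excluding points
whose GPI exceeds its upper limit from both groups before fitting; the
cutoff is an explicit argument (`gpi_max`) rather than an implicit
recomputation, so that simulation studies of the test's size are not
confounded with interval re-detection. Residual normality is summarized
(moment skewness and kurtosis) but never gated on, mirroring the visual
Q-Q-plot practice such analyses use.

**Interference errors.** The practical cost of reusing the control curve is
tabulated at the control curve's maximum measurable concentration and at
half of it: the concentration is mapped through the control line to a GPI,
that GPI inverted through the condition's own line to the "actual"
concentration a sample with that reading would have, and the signed error
$100\,(c_{\mathrm{control}} - c_{\mathrm{actual}})/c_{\mathrm{actual}}$
reported. With equal slopes and a shifted intercept the error shrinks as
concentration grows (a zero error, not a span error), which the tests
assert; the table is antisymmetric under exchanging the two curves only
when both intercepts vanish.

**Sensitivity power analysis.** For planned comparisons,
`detectable_slope_difference()` solves for the smallest $|\Delta|$ such
that the two-tailed $t$-test of slope equality, with
$\mathrm{SE}(\Delta) = s\sqrt{1/SS_{x,1} + 1/SS_{x,2}}$ on $n_1+n_2-4$
degrees of freedom, reaches the requested power. Power is evaluated with
the noncentral $t$ distribution and inverted by bisection to a relative
tolerance of $10^{-10}$ (power is strictly increasing in $|\Delta|$, so
bisection cannot stall; failure to bracket raises a numerical error with
diagnostics). In the large-sample limit $\Delta/\mathrm{SE} \to
z_{1-\alpha/2} + z_{\mathrm{power}}$ ($\approx 2.802$ at $\alpha = 0.05$,
power 0.80), which the tests check to 1%.

## The synthetic generators

Because the package must be testable without laboratory data, it ships two
seeded generators whose defaults encode the nominal study conditions: a
control-like slope of 0.00694 GPI per ug/ml, a near-zero intercept,
linearity up to 16 ug/ml, triplicate photographs, and additive Gaussian GPI
noise with SD 0.002 per photograph — a level that yields mid-curve replicate
precision of roughly 5 %RSD, the scale a careful manual protocol attains.

**Assay-level generator.** `simulate_calibration_dataset()` draws
per-photograph readings around a mean response that is linear to the
breakpoint and approaches a plateau exponentially beyond it, with the rate
fixed by $C^1$ continuity (the curve leaves the breakpoint at the linear
slope, matching the observed "steady reduction of the gradient" rather than
a kink). The plateau default (0.12 GPI) was set by an explicit
fixture-design power argument: for the generator to be able to validate
breakpoint detection at all, the systematic departure of the first clearly
excluded grid concentration must exceed about 4 standard deviations of a
triplicate-mean reading; gentler plateaus make the breakpoint statistically
invisible at the default noise, and a fixture that cannot reveal its own
breakpoint tests nothing. The resulting ceiling is consistent with the
response range the physical assay shows (fitted response $\approx 0.112$ at
the breakpoint, observed readings up to $\approx 0.125$). The exponential
form itself is a fixture choice, recorded in the configuration.

**Pixel-level renderer.** `render_flask_image()` builds a synthetic
photograph: a near-white background, a culture rectangle whose color is the
background attenuated channel-wise by Beer–Lambert factors
$e^{-\varepsilon_{ch}\,c}$, a lid-shadow strip that multiplies all channels
by a common factor (leaving GPI unchanged, as in the physical protocol),
and Gaussian pixel noise clipped to 8 bits. The green extinction
coefficient is constrained to be the smallest, so GPI rises with pigment.
Ground truth (the pre-quantization culture GPI) is recorded alongside each
image, and a matching annotation is emitted, so the whole image pipeline
can be scored end to end.

What the generators do *not* emulate — and hence what passing tests cannot
show about real photographs: lens vignetting and white-balance drift,
specular highlights on the flask, heteroscedastic scatter above the
breakpoint, the yellowing of nitrogen-starved (lipid-accumulating) cultures,
and turbidity from heavy bacterial contamination. Altered conditions are
exercised only as slope/intercept perturbations of the assay model; the
package's statistics quantify their consequences but no forward model of
their physics is attempted. Real deployments must build their standard
curve with their own organism, vessel, camera and lighting.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based (row, column); annotation rectangles are
  half-open `[row0, col0, row1, col1)`. Regions must be disjoint and inside
  the image; empty regions and out-of-bounds rectangles are distinct,
  named errors.
* Images deeper than 8 bits are rescaled to 8-bit on read; alpha channels
  are composited over white (the background is white paper); grayscale
  images are expanded to three channels. Only PNG is read and written.
* A black pixel ($R+G+B=0$) makes GPI undefined; the error names the pixel
  coordinate.
* Pixel sampling allocates 2 of the 3 culture pixels to the larger of the
  shadowed/lit regions (ties favor the shadowed one) and draws without
  replacement whenever the region is large enough. All randomness flows
  through an explicit seed, and library code restores the caller's RNG
  state.
* Fits require at least 3 points and non-degenerate concentrations;
  slope $\le 0$ invalidates a curve for inversion, LoD conversion and
  interference tables (named errors rather than silent nonsense).
* Absorbances above 1.00 warn (outside the recommended working range —
  dilute the extract) but do not block; negative corrected absorbances warn
  and proceed, since near-blank extracts legitimately produce them.
* Validation problem sizes are chosen to give stable statistics at
  interactive cost: 25-concentration calibrations over 0.1–25 ug/ml for
  parameter recovery (100 seeds), 5,000 replicate pairs for the size of the
  slope test, and 25 rendered triplicates for the image pipeline.

## Known limitations

* The linear-interval rule assumes saturation from above: it only ever
  trims the highest concentrations. Responses nonlinear at the low end are
  handled by the LoD, not by point removal.
* LoB/LoD use the 1.645 normal-quantile convention; heavy-tailed blank
  distributions would need the nonparametric percentile variant, which is
  not implemented.
* `compare_curves()` handles exactly two groups; multi-day or multi-batch
  designs are supported only as repeated pairwise calls, without any
  multiplicity correction across pigments or comparisons.
* No weighted, robust, or four-parameter-logistic calibration; laboratories
  whose response noise grows with concentration will find the OLS bands
  optimistic at the top of the interval.
* The renderer is deliberately minimal; it validates the sampling and
  correction arithmetic, not camera physics.
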