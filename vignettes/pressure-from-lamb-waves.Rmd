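---
title: "Estimating compartment pressure from Lamb-wave dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating compartment pressure from Lamb-wave dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lambpress)
```

## The problem

Hollow organs that sustain fluid pressure — the bladder above all — are
usually assessed invasively, with catheter-mounted transducers. Elastography
can measure something else non-invasively: the phase velocity of guided
(Lamb-type) waves travelling along the organ wall, excited by acoustic
radiation force and tracked with ultrafast ultrasound. `lambpress` implements
a mechanical analysis that connects the two quantities directly, so that
pressure can be estimated from a measured dispersion curve, the fill volume,
and a wall-thickness measurement, without a per-organ calibration.

The chain has three links: (i) pressure-vessel mechanics gives the static
wall stress produced by a given pressure at a given inflation; (ii)
acoustoelasticity gives the incremental moduli — the effective stiffnesses
felt by a small-amplitude wave — in terms of that pre-stress; (iii) a
fluid-loaded plate dispersion relation turns those moduli into a predicted
phase-velocity curve. Inverting the composed map recovers pressure.

## Model and assumptions

**Kinematics.** The compartment is a thin-walled incompressible sphere
inflated from a reference (taut but unpressurized) volume $V_0$ to $V$. The
wall is in equibiaxial tension with principal stretches
$\lambda_1 = (V/V_0)^{1/3}$ in plane (both directions; $\lambda_3 =
\lambda_1$) and $\lambda_2 = (V_0/V)^{2/3}$ through the thickness, so
$\lambda_1^2 \lambda_2 = 1$ and the deformed half-thickness is
$h = \lambda_2 h_0$.

**Constitutive model.** The wall follows the Demiray–Fung exponential energy
$$W = \frac{\mu_0}{2b}\left(e^{b(I_1 - 3)} - 1\right), \qquad
I_1 = 2\lambda_1^2 + \lambda_2^2,$$
with initial shear modulus $\mu_0$ and a dimensionless strain-stiffening
exponent $b$. The principal stress difference (the incompressibility
multiplier cancels) is
$t_1 - t_2 = (\lambda_1^2 - \lambda_2^2)\,\mu_0 e^{b(I_1-3)}$.

**Pressure–stress link.** Treating the stress as homogeneous across the wall
(the thin-wall assumption) gives $P = (t_1 - t_2)\,4h/r$, the first-order
form of the thick-wall relation $P = 2(t_1 - t_2)\ln(b_{\text{out}}/a)$;
the two differ by under 1% for $b_{\text{out}}/a = 1.01$ and under 2% up to
1.04, which brackets the geometries of interest.

**Acoustoelastic moduli.** Linearizing the equations of motion about the
deformed state yields moduli $\alpha$, $\gamma$, $2\beta$ for waves in the
(propagation, thickness) plane. Differentiating the *constrained* energy
$\tilde W(\lambda_1, \lambda_2) = W(\lambda_1, \lambda_2,
1/(\lambda_1\lambda_2))$ gives, after the removable
$\lambda_1 = \lambda_2$ singularities are cancelled analytically,
$$\alpha = \lambda_1^2\,\mu_0 e^{b(I_1-3)}, \quad
  \gamma = \lambda_2^2\,\mu_0 e^{b(I_1-3)}, \quad
  2\beta = \mu_0 e^{b(I_1-3)}\left[2b(\lambda_1^2-\lambda_2^2)^2 +
  \lambda_1^2 + \lambda_2^2\right].$$
All three tend to $(\mu_0, \mu_0, 2\mu_0)$ at $\lambda_1 \to 1$, recovering
the classical unstressed incompressible factorization. Published closed
forms for $2\beta$ circulate in two variants that disagree by a factor of two
in the $b$ term and have mutually inconsistent classical limits ($4\mu_0$
vs $2\mu_0$); this package *defines* $2\beta$ by differentiation of the
energy (validated against a finite-difference oracle in the test suite) and
exposes the two published variants behind `beta_variant = "eq17"` / `"eq19"`
for reproduction studies. Substituting the thin-wall law makes every modulus
proportional to $P r / (4h)$ — the dispersion relation therefore depends on
$P$, the volumes, $h_0$ and $b$, but **not** on $\mu_0$. That is what makes
calibration-free pressure estimation possible, and it also means the
stressed equation degenerates at exactly $P = 0$ (all moduli vanish);
`quadratic_wave_roots()` raises a targeted error there and the unstressed
classical form is available through `incremental_moduli()` at
$\lambda_1 = 1$.

**Dispersion relation.** For the antisymmetric branch of a pre-stressed
incompressible plate of half-thickness $h$ with fluid on both faces (the
organ sits in a water bath and is filled with water):
$$\Theta = \gamma s_1 (1+s_2^2)^2 \tanh(s_1 k h)
 - \gamma s_2 (1+s_1^2)^2 \tanh(s_2 k h)
 + \rho_F c^2 \frac{s_1^2 - s_2^2}{\xi} = 0,$$
where $s_{1,2}^2$ solve $\gamma s^4 - (2\beta - \rho c^2)s^2 +
(\alpha - \rho c^2) = 0$, $k = 2\pi f/c$, and $\xi$ involves the fluid sound
speed $c_p$. Two typographic ambiguities in the printed source equation are
resolved by physical requirements and kept configurable:
$\xi = \sqrt{1 - c^2/c_p^2}$ (`xi_convention = "sqrt"`; the `linear` reading
is available) because the square root matches the standard leaky-plate
structure, and the fluid term divides by $\xi$ (`fluid_term = "ratio"`)
because the term must vanish as $\rho_F \to 0$ and diverge at the leaky
cutoff $c \to c_p$. Complex $s^2$ roots are ordered by real part (then
imaginary part) and principal square roots are used throughout, which makes
$\Theta$ single-valued; where both roots are real $\Theta$ is real, and
where they form a conjugate pair $\Theta$ is purely imaginary.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `b_stiff` | 5 | — | assumed strain stiffening; soft-tissue literature value, not organ-specific |
| `h0` | 2.75e-3 | m | undeformed half-thickness (5.5 mm wall), sets $V_0$ inference and $kh$ |
| `f_min`, `f_max` | 150, 500 | Hz | fitting band, matching in vivo usable bandwidth |
| `P_init` | 100 | mmHg | simplex start |
| `rho_solid`, `rho_fluid` | 1000 | kg/m³ | wall and fluid densities (1 g/ml) |
| `cp` | 1480 | m/s | fluid sound speed |

Because $b$ and $h_0$ are assumed rather than measured,
`sensitivity_analysis()` re-fits over a grid of both; changing the assumed
$h_0$ also rescales the inferred $V_0 \propto h_0^{-3/2}$, since $V_0$ is
obtained from the same thickness measurements.

## Numerical choices

- **Forward solver**: bracketed scan (1 m/s grid over 0.2–15 m/s by default)
  of the sign of $\mathrm{Re}\,\Theta + \mathrm{Im}\,\Theta$ — a single
  indicator valid in both the real and conjugate root regimes — refined by
  bisection to ~1e-12 m/s, with candidates verified against the normalized
  residual ($|\Theta| / \sum |\text{terms}| < 10^{-8}$) so that poles of the
  tangent terms are never mistaken for roots. Frequency sweeps seed each root
  with its neighbour for branch continuity.
- **Inversion**: the objective is literally
  $\sum_i \Theta_i(P)\overline{\Theta_i(P)}$ on the measured $(f_i, c_i)$
  pairs restricted to the closed fitting band. The search variable is P in
  mmHg (scale 10–100) under a deterministic 1-D Nelder–Mead simplex
  (reflection/expansion/contraction, convergence at 1e-3 mmHg simplex size
  and 1e-10 relative objective change, 500-iteration cap); nonnegativity is
  a quadratic penalty below a 1e-3 mmHg floor rather than a hard bound. The
  objective grows steeply as $P \to 0^+$ (the moduli collapse), so the floor
  is never binding in practice.
- **Moduli at $\lambda_1 = \lambda_2$**: the $0/0$ forms are replaced by
  their analytic cancellations; no limits are taken numerically.
- **k-space estimation**: Tukey(0.1) windows on both axes, 4× zero padding,
  one-sided frequency and two-sided wavenumber, per-direction peak picking
  with quadratic sub-bin interpolation, directions merged by median when
  both carry a genuine wave (weaker-direction peak at least 25% of the
  stronger; a leakage peak in an empty half-plane would otherwise corrupt the
  median), and per-frequency SNR gating (row peak over row median, threshold
  2) following the exclusion rule used for low-quality acquisitions.
- **Replicate alignment**: curves from repeated acquisitions are aligned on
  the nearest frequency bin and reduced by the per-frequency median;
  frequencies present in at most half the acquisitions are dropped.
- **Variance components**: ANOVA method-of-moments on the crossed
  subject × method × repeat design, negative moment estimates truncated at
  zero with the raw values retained in the result; the percentile bootstrap
  resamples subjects, the independent units. `estimator = "lmer"` swaps in
  REML components from lme4. The REML confidence-interval machinery of the
  original mixed-model analysis is deliberately out of scope; the bootstrap
  is the package's own design choice for interval estimation.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure the pipeline assumes:
single-mode dispersive propagation (a coherent broadband pulse, flat
spectrum across the excitation band with raised-cosine rolloff outside it),
optional counter-propagating waves radiating from a mid-aperture push,
additive pixel noise, multiplicative outlier pixels standing in for
bubble-type artifacts, replicate acquisitions with identical positioning,
IQ speckle with the exact autocorrelation phase encoding, and
filling protocols driven by the package's own forward mechanics (reference
volume 150 ml, 2.75 mm half-thickness, $\mu_0 = 3$ kPa, $b = 5$, fills
170–280 ml — pressures of roughly 1–45 mmHg, the physiological range).

They do **not** emulate: beamforming and speckle decorrelation, mode mixing
(S0 and higher modes), viscoelastic attenuation and dispersion, non-spherical
geometry, wall-stress inhomogeneity (thick walls), anisotropy, fluid flow, or
active contraction. Passing the synthetic end-to-end tests therefore
demonstrates correctness of the processing and inversion chain under the
model's own assumptions — not robustness of the method on real organs, where
those neglected factors set the error floor. Consistent with that, the
generator's velocity-noise and outlier defaults (0.1 m/s, 2%) produce
synthetic-study agreement statistics far tighter than any physical
experiment would show.

## Problem sizes used in tests and the acceptance script

Dispersion tests use 15-frequency curves (150–500 Hz in 25 Hz steps);
round-trip recovery covers pressures 5–60 mmHg × inflations
$V/V_0 \in \{1.2, 1.5, 2.0\}$. Wavefield studies use 40 mm × 64 ms records
(0.3 mm, 0.25 ms sampling; about 134 positions × 257 frames), five replicate
acquisitions, and five generator seeds. The synthetic study behind the
acceptance report uses six compartments with initial shear moduli spanning
2–8 kPa (emulating soft through cross-linked walls) × twelve fills × five
replicates, with 500 bootstrap draws for the concordance interval. These
sizes were chosen so every statistic is estimated with comfortable
Monte-Carlo margin while the whole suite stays interactive.

## Known limitations

- The thin-wall, homogeneous-stress assumption couples to the wave model; at
  large $h/r$ both fail together, and only a numerical thick-wall wave
  solver would quantify the error.
- $b$ and $h_0$ are assumed constants; the sensitivity grid quantifies, but
  does not remove, their influence.
- The repeated-measures concordance estimate is noisy by construction on
  small designs: $\sigma^2_{mn}$ has only $(M-1)(R-1)$ degrees of freedom,
  and the subject component has $S - 1$, so even at 50 subjects the CCC
  estimate carries a sampling sd near 0.08. Tests therefore check
  Monte-Carlo means over replicate designs rather than single draws.
- The wavenumber resolution bounds phase-velocity accuracy from below:
  the relative error scales with $c/(f \cdot L_{\text{padded}})$, so faster
  waves (higher pressures) are estimated with proportionally larger error —
  visible in the end-to-end tests as a half-bin error bound that grows
  toward low frequency and high speed.
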