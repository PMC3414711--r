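---
title: "Hydration equilibrium thermochemistry: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration equilibrium thermochemistry: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydratherm)
```

# The measurement model

A pulsed ion-beam high-pressure mass spectrometer injects cationized
nucleobase ions into a reaction chamber holding ~10 mbar of N~2~ with a
known water partial pressure *P* (0.02–0.20 mbar). Ions drift for on the
order of a millisecond, hydrate, and — if the cell kinetics are fast
relative to the residence time — leave at equilibrium. A multichannel
scaler (1 µs dwell) accumulates an arrival-time distribution (ATD) per
mass over several thousand injection pulses; the ATD peak area is the ion
intensity.

For the hydration step (n−1, n) the dimensionless equilibrium constant is

$$K_{n-1,n} = \frac{I_n \, P_0}{I_{n-1} \, P}, \qquad P_0 = 1000\ \mathrm{mbar},$$

and the van't Hoff relation $\ln K = -\Delta H^\circ_n/(RT) +
\Delta S^\circ_n/R$ turns a temperature series of K into the step's
standard enthalpy and entropy, with
$\Delta G^\circ_n = \Delta H^\circ_n - T\Delta S^\circ_n$ evaluated at
298 K for reporting. Association quantities are stored with their
thermodynamic (negative) sign; tables print the negated values, as is
conventional for clustering thermochemistry.

# The synthetic-data generator: what it emulates

`simulate_atds()` realises the stated world of the experiment:

* **Kinetics.** A birth–death master equation over hydration states
  0..`max_n`. Forward pseudo-first-order rates are free simulator
  parameters (default 0.01 µs⁻¹): the experiment only asserts that
  equilibrium is reached, never the rates, so the default is chosen to
  put the relaxation time (≈40–100 µs for ratios of order one) well
  inside the ~1 ms residence window. Reverse rates follow from detailed
  balance against $r_n = K_n P / P_0$, so the stationary state reproduces
  the thermodynamic ratios *exactly* — that identity, not a tuned
  approximation, is what the detailed-balance tests check at 1e-10.
* **Arrival-time shape.** The 90 µs injection boxcar convolved with a
  single Gaussian spread (default σ = 30 µs) centred on the mean drift
  time (default 700 µs within a 1 ms repetition window). Real drift
  peaks carry diffusion tails and mobility differences between hydrates;
  none of that matters downstream because only peak *areas* enter the
  analysis, so the shape model is deliberately minimal.
* **Counting statistics.** Expected counts per channel are
  `n_pulses × population × profile`; observed counts are independent
  Poisson draws. Real detectors add dead-time and afterpulsing effects
  that are out of scope.
* **K-series shortcut.** `simulate_k_series()` skips the ATD layer and
  perturbs the exact van't Hoff line with multiplicative log-normal noise
  (σ of ln K equal to the stated relative noise), setting the σ_K column
  consistently. This is the stated world for the Monte-Carlo calibration
  of the fit.

A green simulator test therefore establishes that the *analysis chain* is
correct and correctly calibrated against Poisson statistics — not that
the instrument model captures real drift physics.

Since the reference work does not state how many (T, K) points per van't
Hoff line were measured, the simulator defaults to 8 points evenly spaced
in temperature across 350–550 K; that is an assumption, not a read-off
from the published plots.

# Reduction choices

* **Baseline.** Constant, estimated from the 50 channels preceding the
  integration window (configurable). Background is never described in the
  source experiment; a constant is the minimal model, and the baseline
  estimate's variance is propagated into the area σ.
* **Integration window.** Default is mode ± 3σ̂ with σ̂ a count-weighted
  moment estimate (`find_peak_window()`), overridable per record.
* **Equilibrium test.** The overlapping peak region is cut into n bins
  (default 8); per-bin product/reactant ratios carry Poisson errors
  $\sigma_r = r\sqrt{1/N_p + 1/N_r}$; a weighted line of ratio vs
  residence time is fitted and the system passes when
  $|{\rm slope}| \le 2\,\sigma_{\rm slope}$. The 2σ criterion
  operationalises "constant within the error limits"; bins with fewer
  than 10 reactant counts are dropped because the Poisson ratio error
  model degenerates below that. On truly equilibrated synthetic data the
  false-positive rate of this rule is ≈5 % and is required to stay ≤10 %.

# Fitting choices

* **Weights.** $w_i = 1/\sigma^2(\ln K_i)$ with
  $\sigma(\ln K) = \sigma_K/K$ (first order). A `weights = "uniform"`
  switch exists because the original report does not say whether its
  weights were statistical.
* **Covariance convention.** With statistical weights, parameter σ's use
  the *unscaled* weighted normal-equations covariance (input σ's taken at
  face value) and the reduced χ² is reported for optional inflation. With
  uniform weights no absolute error scale exists, so the covariance is
  scaled by the reduced χ² (ordinary least-squares errors); this also
  makes the noiseless limit report exact zeros.
* **Conditioning.** The regressor is 1/T, centred about its weighted mean
  internally and un-centred afterwards. 1/T spans a narrow range far from
  zero, so an uncentred intercept (the entropy) is numerically degraded;
  centring removes that without changing the estimates.
* **Report temperature.** 298.15 K exactly (thermodynamic standard
  convention). At one-decimal table precision the difference from 298 K
  is ≤0.015 kJ/mol for these entropies; the seven self-consistent
  reference rows reproduce identically either way.
* **Display rounding.** Half-even at one decimal, with the tie decided on
  the decimal representation (so 29.95 prints 30.0); uncertainties print
  as the last-digit integer in parentheses.

# Tautomer-mixture analysis

The binding-energy-versus-MIA correlation is fitted by *unweighted* OLS:
the MIA values are quantum-chemical numbers without stated uncertainties,
so statistical weighting has nothing to stand on (a weighted variant is
available when binding σ's are supplied). First- and second-water data
are fitted separately per cation; nothing in the source indicates a joint
fit, and separate fits make no joint-slope assumption.

The mixture inversion is deliberately *not* a point estimate: one
observable (the effective MIA from the correlation line) cannot determine
≥2 mole fractions, so `mixture_feasible_set()` enumerates the simplex on
a grid (default step 0.02) and returns every fraction vector whose
weighted MIA falls inside the tolerance band. An empty set is a valid
answer. The bundled cytosine fixture maps the neutral tautomer fractions
(0.22, 0.44, 0.26, 0.08) onto the complexes 2d, 2e, 2f, 2g in that
order; the source material labels the fourth fraction inconsistently
(2c in one place, 2g in another), which does not change the weighted sum
because the fraction-to-MIA pairing is identical.

# Numerical notes

* Matrix exponentials for the master equation use the detailed-balance
  symmetrization $S = D^{-1/2} Q D^{1/2}$ (D the stationary diagonal),
  which is symmetric for birth–death generators, followed by an exact
  symmetric eigendecomposition. The test suite cross-checks it against a
  brute-force RK4 integration of $\dot p = Qp$.
* Stationary states come from an SVD null-space solve; the closed-form
  product over the step ratios serves as the independent oracle.
* Degenerate inputs fail loudly: all-equal temperatures (singular design),
  non-positive K, reactant intensity 0, windows outside the time axis,
  fraction vectors off the simplex, |slope| < 1e-6 in the correlation
  inversion.
* All randomness flows through one integer seed; pipeline stages derive
  per-stage seeds by a stable string hash, so a report is a pure function
  of (config, seed). Configuration is JSON (round-trip tested); no TOML
  reader is available in the supported dependency set.

# Known limitations

* The ATD model omits diffusion broadening differences between hydrates,
  mobility-dependent drift times, and detector dead-time.
* The van't Hoff model assumes ΔC°p = 0 over the fitted range; no
  Clarke–Glew or curved fits.
* Sub-ambient equilibration (needed for higher hydration steps) is not
  modelled, mirroring the experimental constraint.
* The published K(T) point sets are not available, so the original van't
  Hoff lines cannot be reproduced point-for-point; the pipeline is
  instead validated by exact noiseless recovery, Monte-Carlo calibration,
  and the printed-table identities it does reproduce.
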