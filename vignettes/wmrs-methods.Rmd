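---
title: "Wavelength-modulated Raman spectroscopy: model, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength-modulated Raman spectroscopy: model, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmrs)
```

## The measurement model

A single-cell Raman spectrum rides on an autofluorescence background that
is typically an order of magnitude more intense than the Raman bands.
Wavelength modulation exploits an asymmetry between the two: a Raman band
sits at a fixed energy *difference* from the excitation, while the
fluorescence emission profile is essentially fixed in absolute wavelength.
If spectra are tabulated on a Raman-shift axis computed relative to a
nominal excitation $\lambda_0$, a band at true shift $\nu$ appears, under
excitation $\lambda$, at

$$\nu_{\mathrm{app}} = \nu + 10^7\left(\frac{1}{\lambda_0} -
\frac{1}{\lambda}\right)\ \mathrm{cm}^{-1},$$

so the Raman features translate across modulation steps (about
8 cm$^{-1}$ per 0.5 nm at 785 nm, `peak_shift()`) while the background
column stays constant. Five steps spanning a total modulation of 1 nm,
centred on 785 nm, are the default acquisition; the analysis window is
600–1800 cm$^{-1}$ on 1200 bins. The steps are taken equally spaced and
centred on $\lambda_0$ — the simplest symmetric choice; a stepped (rather
than continuous) modulation waveform is assumed throughout.

Each step spectrum is first divided by its own total intensity (a plain
sum over the uniform grid; a trapezoidal rule would differ only by a
constant factor), which cancels laser-power fluctuations and any global
gain. The five normalised spectra are then treated as observations over
the bins; after per-bin mean centring, the static background vanishes and
the first principal axis — the unit-norm loading vector over bins — is the
*modulated Raman spectrum*. It resembles the derivative of the
conventional spectrum, and conventional peak positions appear as its zero
crossings. This orientation of the PCA (steps as observations, bins as
variables, no variable scaling) is the only one that yields a
spectrum-length loading.

Because a principal axis is defined only up to sign, the loading is
oriented so that its inner product with the bin-wise finite difference of
the mean spectrum is non-negative, with ties broken by making the
largest-magnitude element positive. A stack whose steps are identical
after centring has no modulated component and raises an error rather than
returning zeros, which would silently poison every downstream PCA.

Numerically the extraction uses the eigendecomposition of the
$S \times S$ Gram matrix of the centred stack ($S$ = number of steps),
which is exact, cheap and well-conditioned for the handful of steps
involved; the test suite checks agreement with a direct singular value
decomposition of the centred matrix to better than $10^{-8}$.

## The simulator

`generate_stack()` produces, for each step $s$ with displacement
$\delta_s$,

$$I_s(\nu) = g\,\Big[\,b_d\,B(\nu) + \sum_k a_k j_k\,
L(\nu;\,c_k + \delta_s,\,w_k)\,\Big] + \varepsilon,$$

with $L$ a Lorentzian of HWHM $w$ (the standard Raman line shape; default
8 cm$^{-1}$), $B$ a smooth strictly positive background (default a broad
Gaussian, centre 1300 cm$^{-1}$, width 700 cm$^{-1}$, at 10× the Raman
amplitude), $j_k$ a per-cell log-normal amplitude jitter with unit mean
and CV `amplitude_cv` (default 0.10), donor factors $b_d$ (background,
×0.7–1.3 across the default three donors) and $g$ (gain, ×0.8–1.2), and
i.i.d. additive Gaussian noise $\varepsilon$ (default SD 0.05 in the raw
units in which a nominal band has unit amplitude). Bands displaced past
the window edge are truncated, as on a real detector. Poisson statistics,
cosmic rays, etaloning and calibration drift are deliberately out of
scope: the generator exists to exercise the analysis, not to emulate a
camera.

The default three-class fixture places class-specific bands at positions
where human lymphocyte subsets are known to differ (A: 645, 800, 1007,
1097 cm$^{-1}$; B: 1259, 1345, 1378 cm$^{-1}$; C: 621, 671, 725,
1129 cm$^{-1}$) at half the amplitude of a shared backbone (1305, 1450,
1585, 1660 cm$^{-1}$). Sixty cells per class from three donors,
round-robin assigned, mirror a realistic study size. All draws derive
from a user seed (one derived seed per cell), so datasets are
reproducible byte for byte.

What passing tests on these simulations do **not** show: robustness to
non-Gaussian noise, wavenumber miscalibration between cells, background
shapes that vary *within* a modulation stack, or real biological
within-class heterogeneity beyond log-normal band jitter. Results on real
spectra depend on those factors; the simulator establishes correctness of
the algorithmic chain, not instrument-grade validation.

## Band statistics

`compare_groups()` computes, per bin, the two-sample Student $t$ with
pooled variance on $n_A + n_B - 2$ degrees of freedom (the named
parametric test; Welch's form is available via `welch = TRUE`). No
multiple-testing correction is applied — reproducing the convention of
controlling the ~1000 correlated bin tests with the stringent fixed
threshold $p < 10^{-7}$ instead. Bins with zero within-group variance get
$t = 0, p = 1$ when the means agree. `significant_regions()` collapses
the mask into maximal runs, dropping runs shorter than `min_run = 3`
bins: isolated significant bins are rarely interpretable as bands, and
the parameter is exposed.

Because modulated spectra have unit norm, adding a band to one class
slightly rescales all *shared* bands; the significance map is therefore a
statement about the normalised representation, and a large class-specific
band can induce weak secondary differences at shared positions. The
calibration tests use small differing bands where this coupling is
negligible.

## Classification

Modulated spectra are reduced by mean-centred PCA (`fit_pca()`, backed by
`stats::prcomp`); seven components are the default because they capture
the major variance of modulated immune-cell spectra while discarding
bin-level noise. LOOCV refits the PCA on every fold — the honest design,
since the held-out cell must not influence the basis — and classifies the
projected spectrum by its Euclidean-nearest training score with $k = 1$,
the simplest reading of "nearest neighbour". No score whitening is
applied before distances. Equidistant neighbours resolve to the smallest
`cell_id` for determinism. A shared-basis approximation
(`refit = FALSE`) is provided for exploration but is not the default.
Classes with a single member are rejected: their fold has no same-class
neighbour by construction.

Pairwise sensitivity/specificity are computed from dedicated two-class
LOOCV runs (`pairwise_metrics()`), with the first-listed class treated as
positive; both the positive-class convention and a collapse of an
existing multi-class confusion matrix (`collapse_pairwise()`) are exposed
because either convention is defensible and published tables do not
always disambiguate them.

## Numerical and design notes

- Zero crossings are located by linear interpolation between adjacent
  bins of opposite sign; candidates are retained only if the maximum
  absolute amplitude within ±20 cm$^{-1}$ exceeds `min_amplitude`
  (default 3× the median absolute amplitude), suppressing noise-driven
  crossings near zero amplitude.
- The degrees-of-freedom and variance computations in `compare_groups()`
  are vectorised over bins; single-bin results are cross-checked against
  `stats::t.test` in the tests.
- Problem sizes in the test suite are chosen to keep the default run
  brief: unit tests use 80–300-bin axes and up to ~40 cells, while the
  end-to-end checks run the full 1200-bin, 60-cells-per-class, three-donor
  configuration (and 20 replicate null datasets of 60 + 60 cells).
- `run_pipeline()` derives every stochastic input from the config seed,
  labels stage failures with the stage name, and writes all intermediates
  (modulated spectra, scores, confusion matrix, metrics, JSON summary) so
  every reported number can be recomputed from stored artefacts.

## Known limitations

The simulator's background is static across steps by construction, so
background suppression here is an upper bound on what drifting
backgrounds allow. Real acquisition may also produce step spacings that
are not perfectly equal, which the extraction tolerates (the PCA does not
assume equal spacing) but the simulator does not emulate. Finally, with
unit-norm spectra the classifier operates on relative band patterns only;
absolute intensity differences between classes are invisible by design.
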