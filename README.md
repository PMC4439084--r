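# wmrs

Label-free identification of single cells from their Raman spectra is
usually frustrated by cellular autofluorescence, which can be an order of
magnitude brighter than the Raman signal. Wavelength-modulated Raman
spectroscopy (WMRS) defeats this by recording several spectra of the same
cell at slightly different excitation wavelengths (here five steps
spanning Δλ = 1 nm around 785 nm): on a Raman-shift axis fixed relative to
the nominal excitation, Raman bands translate with the excitation while
the broad fluorescence background stays static. The first principal
component across the modulation steps is then a *modulated Raman
spectrum* — a derivative-like trace with the background suppressed, whose
zero crossings mark the conventional Raman peak positions.

`wmrs` is an R package for analysts of single-cell Raman cytometry data
(e.g. immune-cell subsets such as CD4⁺/CD8⁺ T cells and CD56⁺ NK cells).
It provides:

- a **simulator** of modulation stacks with the physical structure WMRS
  assumes (translating Lorentzian bands, static background, donor-level
  nuisance variation, additive noise), so the whole method can be
  exercised without an instrument;
- **extraction**: total-intensity normalisation, per-cell modulation PCA
  (`extract_modulated_spectrum()`), and zero-crossing peak calls;
- **band statistics**: per-wavenumber pooled-variance Student *t* maps
  between two cell subsets (`compare_groups()`, default threshold
  p < 10⁻⁷) and contiguous significant regions;
- **classification**: PCA score reduction (7 components by default) and
  leave-one-out cross-validated 1-nearest-neighbour classification with
  the PCA refitted in every fold, summarised as confusion matrices and
  pairwise sensitivity/specificity;
- plain-text **I/O** (CSV spectra matrix + manifest, a single-file JSON
  bundle, a minimal JCAMP-DX reader) and a one-call `run_pipeline()`
  driven by a YAML config.

## The core quantities

For one cell with normalised step spectra `x_1 … x_S` (rows over bins),
the modulated spectrum is the unit-norm first principal axis `v` of the
mean-centred stack; conventional peaks lie where `v` crosses zero. Groups
are compared per bin with the pooled two-sample statistic
`t = (x̄_A − x̄_B) / (s_p √(1/n_A + 1/n_B))` on `n_A + n_B − 2` degrees of
freedom. Cells are classified by projecting the held-out modulated
spectrum onto the principal components of the remaining cells and taking
the class of the Euclidean-nearest training score (k = 1), aggregated as
sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) per class pair.

## Worked example

```r
library(wmrs)
rep <- run_pipeline(list(
  simulate = list(n_cells_per_class = 12, n_donors = 3),
  acquisition = list(n_bins = 600),
  seed = 7, n_components = 5))
rep
#> WMRS pipeline report: 36 cells, seed 7
#>   LOOCV accuracy (5 PCs): 1.000
#>   A vs B: 14 significant bands at p < 1e-07
#>   A vs C: 13 significant bands at p < 1e-07
#>   B vs C: 14 significant bands at p < 1e-07
#>   A vs B: sensitivity 1.000, specificity 1.000
#>   A vs C: sensitivity 1.000, specificity 1.000
#>   B vs C: sensitivity 1.000, specificity 1.000
```

The three synthetic classes differ in small sets of band intensities
(class A at 645/800/1007/1097 cm⁻¹, B at 1259/1345/1378 cm⁻¹, C at
621/671/725/1129 cm⁻¹) over a shared backbone and a 10× fluorescence
background; the report shows that after modulation PCA the subsets are
fully separated and each pairwise comparison finds significant bands at
the differing positions. Zero-crossing peak calls land on the simulated
band centres:

```r
st <- generate_stack(default_cell_classes(noise_sigma = 0)$A,
                     acq = acquisition_config(n_bins = 600), seed = 1)
head(find_zero_crossings(extract_modulated_spectrum(st))$position)
#> [1]  645.0009  799.9907 1007.0190 1096.9864 1304.9969 1450.0027
```

A published reference confusion matrix for a three-way CD4/CD8/CD56
discrimination (638 cells) ships as a plain-text fixture:

```r
matrix_summaries(reference_confusion())$total_cells
#> [1] 638
```

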