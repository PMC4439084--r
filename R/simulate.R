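#' A single Raman band
#'
#' Bands are modelled as Lorentzian lines, the natural line shape for
#' homogeneously broadened Raman transitions.
#'
#' @param center Band position, cm^-1.
#' @param width Half-width at half-maximum, cm^-1.
#' @param amplitude Peak intensity, arbitrary units.
#' @return Object of class `raman_peak`.
#' @export
raman_peak <- function(center, width = 8, amplitude = 1) {
  stopifnot(is.numeric(center), is.numeric(width), is.numeric(amplitude))
  if (width <= 0) stop("`width` must be > 0")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  structure(list(center = as.numeric(center), width = as.numeric(width),
                 amplitude = as.numeric(amplitude)),
            class = "raman_peak")
}

lorentzian <- function(x, center, width, amplitude) {
  amplitude * width^2 / ((x - center)^2 + width^2)
}

#' Smooth autofluorescence background model
#'
#' The background emulates broad cellular autofluorescence: a smooth,
#' strictly positive curve an order of magnitude more intense than the Raman
#' bands, static across modulation steps. Two families are supported: a
#' single broad Gaussian (`coefficients = c(center, sigma)` in cm^-1) and a
#' polynomial in the rescaled axis `(x - mid) / halfspan` (coefficients in
#' increasing degree). `scale` multiplies the shape and sets the
#' background-to-Raman intensity ratio.
#'
#' @param kind `"gaussian"` or `"polynomial"`.
#' @param coefficients Family parameters (see Details).
#' @param scale Overall background intensity relative to a unit-amplitude
#'   Raman band.
#' @return Object of class `background_model`.
#' @export
background_model <- function(kind = c("gaussian", "polynomial"),
                             coefficients = c(1300, 700), scale = 10) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(coefficients), is.numeric(scale), scale >= 0)
  if (kind == "gaussian") {
    if (length(coefficients) != 2L || coefficients[2] <= 0)
      stop("gaussian background needs coefficients c(center, sigma), sigma > 0")
    # sigma must stay broad relative to Raman lines; enforced at evaluation
  }
  structure(list(kind = kind, coefficients = as.numeric(coefficients),
                 scale = as.numeric(scale)),
            class = "background_model")
}

#' Evaluate a background model on a Raman-shift axis
#'
#' @param bg A [background_model()].
#' @param axis Raman-shift vector, cm^-1.
#' @return Vector of background intensities; errors if the model is not
#'   strictly positive over the axis (a zero or negative background would
#'   break total-intensity normalisation downstream).
#' @export
eval_background <- function(bg, axis) {
  stopifnot(inherits(bg, "background_model"), is.numeric(axis))
  shape <- switch(bg$kind,
    gaussian = {
      exp(-0.5 * ((axis - bg$coefficients[1]) / bg$coefficients[2])^2)
    },
    polynomial = {
      mid <- (max(axis) + min(axis)) / 2
      halfspan <- (max(axis) - min(axis)) / 2
      u <- (axis - mid) / max(halfspan, .Machine$double.eps)
      drop(outer(u, seq_along(bg$coefficients) - 1, `^`) %*% bg$coefficients)
    })
  out <- bg$scale * shape
  if (bg$scale > 0 && any(out <= 0))
    stop("background model is not strictly positive over the axis")
  out
}

#' Spectral model of one cell class
#'
#' A class is a set of Raman bands over a shared background, with two
#' nuisance terms: per-cell log-normal jitter of every band amplitude
#' (coefficient of variation `amplitude_cv`) and additive Gaussian read
#' noise of standard deviation `noise_sigma` (in the raw intensity units in
#' which a nominal Raman band has unit amplitude).
#'
#' @param name Class label.
#' @param peaks List of [raman_peak()].
#' @param background A [background_model()].
#' @param amplitude_cv Per-cell multiplicative amplitude variability (CV).
#' @param noise_sigma Additive noise standard deviation.
#' @return Object of class `cell_class_model`.
#' @export
cell_class_model <- function(name, peaks, background = background_model(),
                             amplitude_cv = 0.1, noise_sigma = 0.05) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  stopifnot(is.list(peaks), inherits(background, "background_model"))
  if (!all(vapply(peaks, inherits, logical(1), "raman_peak")))
    stop("`peaks` must be a list of raman_peak objects")
  if (amplitude_cv < 0) stop("`amplitude_cv` must be >= 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(name = name, peaks = peaks, background = background,
                 amplitude_cv = amplitude_cv, noise_sigma = noise_sigma),
            class = "cell_class_model")
}

#' Donor-level nuisance effects
#'
#' Cells from different donors share class chemistry but differ in overall
#' autofluorescence level and collection efficiency; both are modelled as
#' multiplicative factors.
#'
#' @param donor_id Donor label.
#' @param background_scale_mult Multiplier on the background scale.
#' @param global_gain Multiplier on all intensities.
#' @return Object of class `donor_effect`.
#' @export
donor_effect <- function(donor_id, background_scale_mult = 1,
                         global_gain = 1) {
  if (!is.character(donor_id) || !nzchar(donor_id))
    stop("`donor_id` must be a non-empty string")
  if (background_scale_mult <= 0 || global_gain <= 0)
    stop("donor multipliers must be > 0")
  structure(list(donor_id = donor_id,
                 background_scale_mult = as.numeric(background_scale_mult),
                 global_gain = as.numeric(global_gain)),
            class = "donor_effect")
}

#' Default three-class immune-cell fixtures
#'
#' Three synthetic cell classes built from band positions at which human
#' lymphocyte subsets are known to differ (tyrosine 645, O-P-O 800/1097,
#' phenylalanine 1007 for class A; amide III 1259, polynucleotide 1345,
#' thymine/adenine/guanine 1378 for class B; phenylalanine 621, cysteine
#' 671, adenine 725, lipid C-C 1129 for class C), on a shared backbone of
#' common cellular bands (1305, 1450, 1585, 1660 cm^-1).
#'
#' @param noise_sigma,amplitude_cv,background_scale Passed to every class.
#' @param emphasis Amplitude of the class-specific bands (backbone bands
#'   have amplitude 1).
#' @return Named list of three [cell_class_model()] objects A, B, C.
#' @export
default_cell_classes <- function(noise_sigma = 0.05, amplitude_cv = 0.1,
                                 background_scale = 10, emphasis = 0.5) {
  backbone <- c(1305, 1450, 1585, 1660)
  bands <- list(A = c(645, 800, 1007, 1097),
                B = c(1259, 1345, 1378),
                C = c(621, 671, 725, 1129))
  bg <- background_model(scale = background_scale)
  mk <- function(nm) {
    pk <- c(lapply(backbone, raman_peak, width = 8, amplitude = 1),
            lapply(bands[[nm]], raman_peak, width = 8, amplitude = emphasis))
    cell_class_model(nm, pk, background = bg,
                     amplitude_cv = amplitude_cv, noise_sigma = noise_sigma)
  }
  stats::setNames(lapply(names(bands), mk), names(bands))
}

#' Default donor panel
#'
#' @param n Number of donors (1-3 use fixed multipliers spanning a
#'   plausible inter-donor range: background x0.7-1.3, gain x0.8-1.2;
#'   more donors interpolate).
#' @return List of [donor_effect()] objects.
#' @export
default_donors <- function(n = 3) {
  stopifnot(n >= 1)
  bg <- if (n == 1) 1 else seq(0.7, 1.3, length.out = n)
  gn <- if (n == 1) 1 else seq(0.8, 1.2, length.out = n)
  lapply(seq_len(n), function(i)
    donor_effect(sprintf("donor%d", i), bg[i], gn[i]))
}

#' Simulate one cell's modulation stack
#'
#' For each modulation step the Raman bands are displaced by
#' [peak_shift()] while the background stays fixed, then donor gain and
#' additive noise are applied:
#' `gain * (bg_mult * background + sum of shifted Lorentzians) + noise`.
#' Amplitude jitter is drawn once per cell per band from a log-normal with
#' unit mean and coefficient of variation `amplitude_cv`. Bands displaced
#' beyond the axis window are truncated, as a real detector would.
#'
#' @param model A [cell_class_model()].
#' @param donor A [donor_effect()].
#' @param acq An [acquisition_config()].
#' @param seed Integer seed; the stack is a deterministic function of its
#'   arguments and the seed.
#' @param cell_id Label carried through the pipeline.
#' @return Object of class `modulation_stack`: labels, `axis`,
#'   `excitations`, and an `n_steps x n_bins` intensity matrix.
#' @export
generate_stack <- function(model, donor = donor_effect("donor1"),
                           acq = acquisition_config(), seed = NULL,
                           cell_id = "cell1") {
  stopifnot(inherits(model, "cell_class_model"),
            inherits(donor, "donor_effect"),
            inherits(acq, "acquisition_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  axis <- raman_axis(acq)
  exc <- excitation_grid(acq)
  np <- length(model$peaks)
  jitter <- if (np > 0 && model$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + model$amplitude_cv^2))
    stats::rlnorm(np, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, np)
  bg <- donor$background_scale_mult * eval_background(model$background, axis)
  intens <- matrix(0, nrow = acq$n_steps, ncol = acq$n_bins)
  for (s in seq_len(acq$n_steps)) {
    shift <- peak_shift(exc[s], acq$lambda0)
    row <- bg
    for (k in seq_len(np)) {
      p <- model$peaks[[k]]
      row <- row + lorentzian(axis, p$center + shift, p$width,
                              p$amplitude * jitter[k])
    }
    intens[s, ] <- donor$global_gain * row
  }
  if (model$noise_sigma > 0)
    intens <- intens + stats::rnorm(length(intens), sd = model$noise_sigma)
  structure(
    list(cell_id = cell_id, class_label = model$name,
         donor_id = donor$donor_id, axis = axis, intensities = intens,
         excitations = exc, acq = acq),
    class = "modulation_stack")
}

#' @export
print.modulation_stack <- function(x, ...) {
  cat(sprintf(
    "Modulation stack %s (class %s, %s): %d steps x %d bins, %g-%g cm^-1\n",
    x$cell_id, x$class_label, x$donor_id, nrow(x$intensities),
    ncol(x$intensities), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Simulate a labelled dataset of modulation stacks
#'
#' Generates `n_cells_per_class` cells for every class model, assigning
#' cells to donors round-robin within each class. Cell ids are unique and
#' the whole dataset is a deterministic function of `seed` (each cell draws
#' from its own derived seed).
#'
#' @param models List of [cell_class_model()] (distinct names).
#' @param n_cells_per_class Cells per class, >= 1.
#' @param donors List of [donor_effect()] (at least one).
#' @param acq An [acquisition_config()].
#' @param seed Integer master seed.
#' @return Object of class `wmrs_dataset`: a list of `modulation_stack`
#'   objects with the acquisition stored as an attribute.
#' @export
generate_dataset <- function(models, n_cells_per_class = 60,
                             donors = default_donors(3),
                             acq = acquisition_config(), seed = 1) {
  if (!is.list(models) || length(models) == 0)
    stop("`models` must be a non-empty list of cell_class_model objects")
  if (!all(vapply(models, inherits, logical(1), "cell_class_model")))
    stop("`models` must be a non-empty list of cell_class_model objects")
  if (n_cells_per_class < 1) stop("`n_cells_per_class` must be >= 1")
  if (!is.list(donors) || length(donors) == 0)
    stop("at least one donor is required")
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("class model names must be distinct")
  stacks <- vector("list", length(models) * n_cells_per_class)
  idx <- 0L
  for (ci in seq_along(models)) {
    for (j in seq_len(n_cells_per_class)) {
      idx <- idx + 1L
      donor <- donors[[(j - 1L) %% length(donors) + 1L]]
      stacks[[idx]] <- generate_stack(
        models[[ci]], donor, acq,
        seed = (as.integer(seed) + idx) %% .Machine$integer.max,
        cell_id = sprintf("%s_c%03d", nm[ci], j))
    }
  }
  structure(stacks, class = "wmrs_dataset", acq = acq, seed = seed)
}

#' @export
print.wmrs_dataset <- function(x, ...) {
  cls <- table(vapply(x, `[[`, character(1), "class_label"))
  cat(sprintf("WMRS dataset: %d cells (%s)\n", length(x),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}
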