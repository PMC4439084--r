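#' Acquisition geometry for a wavelength-modulated Raman measurement
#'
#' Describes how the modulation stack of a single cell is acquired: the
#' nominal excitation wavelength, the number of modulation steps, the total
#' excitation modulation range, and the Raman-shift axis on which every
#' spectrum is tabulated. The axis is fixed relative to `lambda0`, so Raman
#' bands appear to translate across modulation steps while any
#' autofluorescence background stays put -- the asymmetry the whole method
#' exploits.
#'
#' @param lambda0 Nominal excitation wavelength in nm.
#' @param n_steps Number of modulation steps (spectra per cell).
#' @param delta_lambda_total Total excitation modulation range in nm
#'   (max minus min excitation).
#' @param axis_min,axis_max Raman-shift analysis window bounds in cm^-1.
#' @param n_bins Number of points on the Raman-shift axis.
#'
#' @return An object of class `acquisition_config`.
#' @examples
#' acq <- acquisition_config()
#' raman_axis(acq)[1:3]
#' excitation_grid(acq)
#' @export
acquisition_config <- function(lambda0 = 785, n_steps = 5,
                               delta_lambda_total = 1.0,
                               axis_min = 600, axis_max = 1800,
                               n_bins = 1200) {
  stopifnot(is.numeric(lambda0), length(lambda0) == 1L, lambda0 > 0)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2)
    stop("`n_steps` must be >= 2")
  if (!is.numeric(delta_lambda_total) || delta_lambda_total <= 0)
    stop("`delta_lambda_total` must be > 0")
  if (!(axis_min < axis_max))
    stop("`axis_min` must be < `axis_max`")
  if (!is.numeric(n_bins) || n_bins < 2)
    stop("`n_bins` must be >= 2")
  structure(
    list(lambda0 = as.numeric(lambda0),
         n_steps = as.integer(n_steps),
         delta_lambda_total = as.numeric(delta_lambda_total),
         axis_min = as.numeric(axis_min),
         axis_max = as.numeric(axis_max),
         n_bins = as.integer(n_bins)),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "WMRS acquisition: %d steps over %g nm at %g nm; axis %g-%g cm^-1 (%d bins)\n",
    x$n_steps, x$delta_lambda_total, x$lambda0, x$axis_min, x$axis_max,
    x$n_bins))
  invisible(x)
}

#' Raman-shift axis of an acquisition
#'
#' @param acq An [acquisition_config()].
#' @return Numeric vector of `n_bins` equally spaced Raman shifts (cm^-1).
#' @export
raman_axis <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  seq(acq$axis_min, acq$axis_max, length.out = acq$n_bins)
}

#' Excitation wavelengths of the modulation steps
#'
#' The steps are equally spaced and centred on the nominal wavelength, so
#' that the extremes span exactly `delta_lambda_total`.
#'
#' @param acq An [acquisition_config()].
#' @return Numeric vector of `n_steps` wavelengths in nm, strictly
#'   increasing, with `max - min == delta_lambda_total`.
#' @examples
#' excitation_grid(acquisition_config(785, 5, 1.0))
#' @export
excitation_grid <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  half <- acq$delta_lambda_total / 2
  seq(acq$lambda0 - half, acq$lambda0 + half, length.out = acq$n_steps)
}

#' Apparent displacement of Raman bands on a fixed axis
#'
#' Spectra are tabulated on a Raman-shift axis computed relative to the
#' nominal excitation `lambda0`. When the true excitation is `lambda_exc`,
#' a band at fixed true Raman shift appears displaced by
#' `1e7 * (1/lambda0 - 1/lambda_exc)` cm^-1 on that axis; the
#' autofluorescence background, which is tied to emission wavelength rather
#' than to the excitation, is not displaced.
#'
#' @param lambda_exc Actual excitation wavelength, nm.
#' @param lambda0 Nominal excitation wavelength defining the axis, nm.
#' @return Displacement in cm^-1 (positive when `lambda_exc > lambda0`).
#' @examples
#' peak_shift(785, 785)  # 0
#' peak_shift(786, 785)  # ~ +16.2 cm^-1
#' @export
peak_shift <- function(lambda_exc, lambda0) {
  if (any(!is.finite(lambda_exc)) || any(lambda_exc <= 0))
    stop("`lambda_exc` must be positive")
  if (any(!is.finite(lambda0)) || any(lambda0 <= 0))
    stop("`lambda0` must be positive")
  1e7 * (1 / lambda0 - 1 / lambda_exc)
}
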