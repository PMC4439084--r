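#' Total-intensity normalisation of a modulation stack
#'
#' Each of the per-step spectra is divided by its own summed intensity, so
#' every row integrates to one. This compensates for laser power
#' fluctuations between modulation steps; any global gain (e.g. donor or
#' instrument throughput) cancels exactly.
#'
#' @param stack A `modulation_stack`.
#' @return The stack with every row of `intensities` summing to 1.
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "modulation_stack"))
  tot <- rowSums(stack$intensities)
  bad <- which(!(tot > 0))
  if (length(bad))
    stop(sprintf("non-positive total intensity at modulation step %s of cell '%s'",
                 paste(bad, collapse = ", "), stack$cell_id))
  stack$intensities <- stack$intensities / tot
  stack
}

#' Extract the modulated Raman spectrum of one cell
#'
#' The modulation steps are treated as observations over the spectral bins.
#' After per-bin mean centring across steps, the first principal axis (the
#' unit-norm loading vector over bins) is the modulated Raman spectrum: the
#' static autofluorescence background cancels in the centring, while the
#' translating Raman bands produce derivative-like signatures whose zero
#' crossings sit at the conventional peak positions.
#'
#' Computation uses the eigendecomposition of the small `n_steps x n_steps`
#' Gram matrix of the centred stack, which is exact and cheap for the few
#' modulation steps involved. The inherent sign ambiguity of a principal
#' axis is fixed so that the loading's inner product with the bin-wise
#' finite difference of the mean spectrum is non-negative (tie broken by
#' making the largest-magnitude element positive).
#'
#' @param stack A `modulation_stack`.
#' @param normalize Apply [normalize_stack()] first (default `TRUE`).
#' @return Object of class `modulated_spectrum` with fields `cell_id`,
#'   `class_label`, `donor_id`, `axis`, unit-norm `values`, and
#'   `explained_variance_ratio`.
#' @export
extract_modulated_spectrum <- function(stack, normalize = TRUE) {
  stopifnot(inherits(stack, "modulation_stack"))
  if (normalize) stack <- normalize_stack(stack)
  x <- stack$intensities
  m <- colMeans(x)
  xc <- sweep(x, 2L, m)
  g <- tcrossprod(xc)            # n_steps x n_steps
  eg <- eigen(g, symmetric = TRUE)
  total <- sum(pmax(eg$values, 0))
  if (total <= 1e-18 * max(1, sum(x^2)))
    stop(sprintf("no modulated component: all steps of cell '%s' are identical after centring",
                 stack$cell_id))
  v <- drop(crossprod(xc, eg$vectors[, 1L])) / sqrt(eg$values[1L])
  v <- v / sqrt(sum(v^2))        # guard against rounding in the Gram route
  s <- sum(v[-length(v)] * diff(m))
  if (s < 0) {
    v <- -v
  } else if (s == 0 && v[which.max(abs(v))] < 0) {
    v <- -v
  }
  structure(
    list(cell_id = stack$cell_id, class_label = stack$class_label,
         donor_id = stack$donor_id, axis = stack$axis, values = v,
         explained_variance_ratio = eg$values[1L] / total),
    class = "modulated_spectrum")
}

#' @export
print.modulated_spectrum <- function(x, ...) {
  cat(sprintf(
    "Modulated Raman spectrum %s (class %s, %s): %d bins, EVR %.3f\n",
    x$cell_id, x$class_label, x$donor_id, length(x$values),
    x$explained_variance_ratio))
  invisible(x)
}

#' @export
plot.modulated_spectrum <- function(x, ...) {
  graphics::plot(x$axis, x$values, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Modulated amplitude", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Extract modulated spectra for a whole dataset
#'
#' @param dataset A `wmrs_dataset` (list of modulation stacks).
#' @param normalize Passed to [extract_modulated_spectrum()].
#' @return Object of class `wmrs_spectra`: list of `modulated_spectrum`.
#' @export
extract_dataset <- function(dataset, normalize = TRUE) {
  stopifnot(is.list(dataset))
  structure(lapply(dataset, extract_modulated_spectrum, normalize = normalize),
            class = "wmrs_spectra")
}

#' @export
print.wmrs_spectra <- function(x, ...) {
  cat(sprintf("%d modulated Raman spectra, %d bins each\n", length(x),
              if (length(x)) length(x[[1]]$values) else 0L))
  invisible(x)
}

#' Locate Raman peaks at the zero crossings of a modulated spectrum
#'
#' Every sign change between adjacent bins yields a candidate position at
#' the linearly interpolated root. Candidates are retained only when the
#' maximum absolute modulated amplitude within `window` cm^-1 of the root
#' exceeds `min_amplitude`, which suppresses noise-driven crossings near
#' zero amplitude.
#'
#' @param modspec A `modulated_spectrum`.
#' @param min_amplitude Retention threshold; default is 3x the median
#'   absolute modulated amplitude.
#' @param window Half-width of the amplitude window, cm^-1 (default 20).
#' @return A data frame of class `peak_calls` with columns `position`
#'   (cm^-1), `slope_sign` (+1 downward-to-upward, -1 upward-to-downward)
#'   and `local_amplitude`, sorted by position. May have zero rows.
#' @export
find_zero_crossings <- function(modspec, min_amplitude = NULL, window = 20) {
  stopifnot(inherits(modspec, "modulated_spectrum"))
  v <- modspec$values
  ax <- modspec$axis
  if (is.null(min_amplitude)) min_amplitude <- 3 * stats::median(abs(v))
  if (min_amplitude < 0) stop("`min_amplitude` must be >= 0")
  i <- which(v[-length(v)] * v[-1L] < 0)
  if (!length(i)) {
    out <- data.frame(position = numeric(0), slope_sign = numeric(0),
                      local_amplitude = numeric(0))
    class(out) <- c("peak_calls", "data.frame")
    return(out)
  }
  pos <- ax[i] + v[i] * (ax[i + 1L] - ax[i]) / (v[i] - v[i + 1L])
  amp <- vapply(pos, function(p) max(abs(v[abs(ax - p) <= window])),
                numeric(1))
  keep <- amp > min_amplitude
  out <- data.frame(position = pos[keep],
                    slope_sign = sign(v[i + 1L] - v[i])[keep],
                    local_amplitude = amp[keep])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_calls", "data.frame")
  out
}
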