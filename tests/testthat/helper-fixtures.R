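# Shared fixture builders; everything is generated in code.

small_acq <- function(n_bins = 300, ...) {
  acquisition_config(n_bins = n_bins, ...)
}

# a modulated_spectrum with arbitrary values, for unit tests that bypass
# the extractor
new_modspec <- function(values, axis = seq_along(values),
                        cell_id = "cell1", class_label = "A",
                        donor_id = "donor1") {
  structure(list(cell_id = cell_id, class_label = class_label,
                 donor_id = donor_id, axis = axis, values = values,
                 explained_variance_ratio = 1),
            class = "modulated_spectrum")
}

# single-class model with chosen peaks and nuisance levels
peak_model <- function(centers, name = "A", amplitude = 1, width = 8,
                       background_scale = 0, noise_sigma = 0,
                       amplitude_cv = 0) {
  cell_class_model(
    name,
    lapply(centers, raman_peak, width = width, amplitude = amplitude),
    background = background_model(scale = background_scale),
    amplitude_cv = amplitude_cv, noise_sigma = noise_sigma)
}

# spectra with iid standard normal "values": null fixtures for the t-test
noise_spectra <- function(n, n_bins, prefix = "a", class_label = "A") {
  lapply(seq_len(n), function(i)
    new_modspec(rnorm(n_bins), axis = seq_len(n_bins),
                cell_id = sprintf("%s%03d", prefix, i),
                class_label = class_label))
}

# naive LOOCV 1-NN: per-fold svd PCA and explicit loops, written
# independently of the package internals
brute_force_loocv <- function(spectra, n_components) {
  n <- length(spectra)
  labs <- vapply(spectra, `[[`, character(1), "class_label")
  ids <- vapply(spectra, `[[`, character(1), "cell_id")
  x <- do.call(rbind, lapply(spectra, `[[`, "values"))
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ctr <- colMeans(xtr)
    xc <- sweep(xtr, 2, ctr)
    v <- svd(xc)$v[, seq_len(n_components), drop = FALSE]
    str_scores <- xc %*% v
    q <- drop((x[i, ] - ctr) %*% v)
    d2 <- numeric(n - 1)
    for (j in seq_len(n - 1))
      d2[j] <- sum((str_scores[j, ] - q)^2)
    cand <- which(d2 == min(d2))
    if (length(cand) > 1) cand <- cand[order(ids[-i][cand])][1]
    pred[i] <- labs[-i][cand]
  }
  pred
}
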