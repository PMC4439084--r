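spectra_matrix <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  ax <- spectra[[1L]]$axis
  for (s in spectra)
    if (length(s$axis) != length(ax) || any(s$axis != ax))
      stop("spectra do not share a common axis")
  list(axis = ax,
       x = do.call(rbind, lapply(spectra, `[[`, "values")),
       cell_id = vapply(spectra, `[[`, character(1), "cell_id"),
       class_label = vapply(spectra, `[[`, character(1), "class_label"))
}

#' Per-wavenumber two-sample comparison of two cell subsets
#'
#' At every spectral bin, the modulated amplitudes of group A are compared
#' with those of group B by a two-sample Student t test with pooled
#' variance (`nA + nB - 2` degrees of freedom; `welch = TRUE` switches to
#' the Welch unequal-variance form). No multiple-testing correction is
#' applied: the stringent default threshold of `alpha = 1e-7` is itself the
#' control for the ~1000 correlated bins tested.
#'
#' Bins with zero within-group variance get `t = 0, p = 1` when the group
#' means agree and infinite `t`, `p = 0` when they differ.
#'
#' @param group_a,group_b Lists of `modulated_spectrum` (>= 2 each, shared
#'   axis).
#' @param alpha Per-bin significance threshold.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return Object of class `significance_map`: `axis`, `t_values`
#'   (positive where A exceeds B), `p_values`, `alpha`, logical `mask`
#'   (`p < alpha`), and the group sizes.
#' @export
compare_groups <- function(group_a, group_b, alpha = 1e-7, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 spectra")
  ma <- spectra_matrix(group_a)
  mb <- spectra_matrix(group_b)
  if (length(ma$axis) != length(mb$axis) || any(ma$axis != mb$axis))
    stop("the two groups do not share a common axis")
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]")
  na <- nrow(ma$x); nb <- nrow(mb$x)
  mean_a <- colMeans(ma$x); mean_b <- colMeans(mb$x)
  var_a <- colSums(sweep(ma$x, 2L, mean_a)^2) / (na - 1)
  var_b <- colSums(sweep(mb$x, 2L, mean_b)^2) / (nb - 1)
  d <- mean_a - mean_b
  if (welch) {
    se2 <- var_a / na + var_b / nb
    df <- se2^2 / (var_a^2 / (na^2 * (na - 1)) + var_b^2 / (nb^2 * (nb - 1)))
  } else {
    sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(d))
  }
  tv <- ifelse(se2 > 0, d / sqrt(se2),
               ifelse(d == 0, 0, sign(d) * Inf))
  df[!(se2 > 0)] <- na + nb - 2
  pv <- 2 * stats::pt(-abs(tv), df)
  structure(
    list(axis = ma$axis, t_values = tv, p_values = pv,
         alpha = alpha, mask = pv < alpha, df = df, n_a = na, n_b = nb),
    class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf(
    "Significance map: %d bins, %d significant at p < %g (n = %d vs %d)\n",
    length(x$axis), sum(x$mask), x$alpha, x$n_a, x$n_b))
  invisible(x)
}

#' @export
plot.significance_map <- function(x, ...) {
  lp <- -log10(pmax(x$p_values, .Machine$double.xmin))
  graphics::plot(x$axis, lp, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Contiguous significant wavenumber bands
#'
#' Collapses the per-bin significance mask into maximal runs of
#' consecutive significant bins, discarding runs shorter than `min_run`
#' (isolated significant bins are rarely interpretable as bands).
#'
#' @param sigmap A `significance_map`.
#' @param min_run Minimum run length in bins (default 3).
#' @return A data frame of class `band_regions` with columns `start`,
#'   `end` (cm^-1), `n_bins` and `min_p`; zero rows when nothing passes.
#' @export
significant_regions <- function(sigmap, min_run = 3) {
  stopifnot(inherits(sigmap, "significance_map"))
  if (min_run < 1) stop("`min_run` must be >= 1")
  r <- rle(as.logical(sigmap$mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  out <- data.frame(
    start = sigmap$axis[starts[keep]],
    end = sigmap$axis[ends[keep]],
    n_bins = r$lengths[keep],
    min_p = vapply(keep, function(k)
      min(sigmap$p_values[starts[k]:ends[k]]), numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("band_regions", "data.frame")
  out
}
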