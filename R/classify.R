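#' Principal-component model of a set of modulated spectra
#'
#' Mean-centred PCA over cells (no variable scaling), keeping the leading
#' `n_components` axes. Seven components are the default: in practice they
#' account for the major variance of modulated Raman spectra of immune
#' cells while discarding bin-level noise.
#'
#' @param spectra List of `modulated_spectrum` (>= 2, shared axis).
#' @param n_components Number of components, at most
#'   `min(n_samples - 1, n_bins)`.
#' @return Object of class `wmrs_pca`: `mean_spectrum`, `components`
#'   (`n_bins x n_components`, orthonormal columns), non-increasing
#'   `explained_variance_ratios`, the training `scores`
#'   (`n_samples x n_components`), `axis` and training labels.
#' @export
fit_pca <- function(spectra, n_components = 7) {
  m <- spectra_matrix(spectra)
  n <- nrow(m$x); p <- ncol(m$x)
  if (n < 2) stop("at least 2 spectra are required")
  kmax <- min(n - 1L, p)
  if (n_components < 1 || n_components > kmax)
    stop(sprintf("`n_components` must be in 1..%d for %d spectra of %d bins",
                 kmax, n, p))
  pc <- stats::prcomp(m$x, center = TRUE, scale. = FALSE)
  k <- as.integer(n_components)
  structure(
    list(mean_spectrum = pc$center,
         components = pc$rotation[, seq_len(k), drop = FALSE],
         explained_variance_ratios = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
         n_components = k,
         scores = pc$x[, seq_len(k), drop = FALSE],
         axis = m$axis, cell_id = m$cell_id, class_label = m$class_label),
    class = "wmrs_pca")
}

#' @export
print.wmrs_pca <- function(x, ...) {
  cat(sprintf("PCA of %d modulated spectra: %d components, EVR %s\n",
              length(x$cell_id), x$n_components,
              paste(sprintf("%.3f", x$explained_variance_ratios),
                    collapse = " ")))
  invisible(x)
}

#' Project a spectrum onto a fitted principal-component basis
#'
#' @param model A `wmrs_pca`.
#' @param spectrum A `modulated_spectrum` on the model's axis.
#' @return Numeric score vector of length `n_components` (inner products
#'   of the mean-subtracted spectrum with each component).
#' @export
project <- function(model, spectrum) {
  stopifnot(inherits(model, "wmrs_pca"),
            inherits(spectrum, "modulated_spectrum"))
  if (length(spectrum$axis) != length(model$axis) ||
      any(spectrum$axis != model$axis))
    stop("spectrum axis does not match the PCA model axis")
  drop(crossprod(model$components,
                 spectrum$values - model$mean_spectrum))
}

#' Construct a confusion matrix from actual and predicted labels
#'
#' @param actual,predicted Character vectors of equal length.
#' @param class_order Row/column order; defaults to first appearance in
#'   `actual`.
#' @return Object of class `confusion_matrix` with `class_order` and the
#'   integer `counts` matrix (rows = actual, columns = predicted).
#' @export
confusion_matrix <- function(actual, predicted,
                             class_order = unique(actual)) {
  stopifnot(length(actual) == length(predicted))
  lv <- union(class_order, unique(c(actual, predicted)))
  counts <- table(factor(actual, levels = lv),
                  factor(predicted, levels = lv))
  counts <- matrix(as.integer(counts), nrow = length(lv),
                   dimnames = list(actual = lv, predicted = lv))
  structure(list(class_order = lv, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted):\n")
  print(x$counts)
  invisible(x)
}

nn_predict <- function(scores, labels, cell_ids, query) {
  d2 <- colSums((t(scores) - query)^2)
  cand <- which(d2 == min(d2))
  if (length(cand) > 1L) cand <- cand[order(cell_ids[cand])][1L]
  labels[cand]
}

#' Leave-one-out nearest-neighbour classification of modulated spectra
#'
#' For every cell, the principal components are determined from the whole
#' dataset without that cell; the held-out spectrum is then projected into
#' that space and assigned the class of its Euclidean-nearest training
#' score vector (k = 1; the held-out cell is never its own neighbour).
#' Equidistant neighbours are resolved in favour of the smallest `cell_id`
#' so the procedure is deterministic. `refit = FALSE` gives a fast
#' approximation sharing one PCA across folds; the per-fold refit is the
#' default and the validated design.
#'
#' @param spectra List of labelled `modulated_spectrum`; >= 2 classes and
#'   >= 2 cells per class (a singleton class has no same-class neighbour
#'   in its own fold, making its recall structurally zero).
#' @param n_components Dimensionality of the classification space.
#' @param refit Refit the PCA in every fold (default `TRUE`).
#' @return Object of class `wmrs_loocv`: `predictions` (data frame with
#'   `cell_id`, `actual`, `predicted`) and `confusion` (a
#'   [confusion_matrix()]).
#' @export
loocv_classify <- function(spectra, n_components = 7, refit = TRUE) {
  m <- spectra_matrix(spectra)
  n <- length(spectra)
  tab <- table(m$class_label)
  if (length(tab) < 2) stop("at least 2 classes are required")
  if (any(tab < 2))
    stop(sprintf("class '%s' has a single member; LOOCV needs >= 2 cells per class",
                 names(tab)[which(tab < 2)[1L]]))
  if (n_components > n - 2L)
    stop(sprintf("`n_components` must be <= %d so every fold of %d cells can be fitted",
                 n - 2L, n))
  predicted <- character(n)
  if (refit) {
    for (i in seq_len(n)) {
      fold <- fit_pca(spectra[-i], n_components)
      q <- project(fold, spectra[[i]])
      predicted[i] <- nn_predict(fold$scores, fold$class_label,
                                 fold$cell_id, q)
    }
  } else {
    full <- fit_pca(spectra, n_components)
    for (i in seq_len(n))
      predicted[i] <- nn_predict(full$scores[-i, , drop = FALSE],
                                 full$class_label[-i], full$cell_id[-i],
                                 full$scores[i, ])
  }
  structure(
    list(predictions = data.frame(cell_id = m$cell_id,
                                  actual = m$class_label,
                                  predicted = predicted),
         confusion = confusion_matrix(m$class_label, predicted,
                                      unique(m$class_label)),
         n_components = as.integer(n_components), refit = refit),
    class = "wmrs_loocv")
}

#' @export
print.wmrs_loocv <- function(x, ...) {
  s <- matrix_summaries(x$confusion)
  cat(sprintf("LOOCV 1-NN on %d components: accuracy %.3f over %d cells\n",
              x$n_components, s$overall_accuracy, s$total_cells))
  print(x$confusion)
  invisible(x)
}

#' Pairwise sensitivity and specificity from a dedicated two-class LOOCV
#'
#' Runs [loocv_classify()] on a two-class dataset and summarises it with
#' the first-listed class as positive: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). Which class counts as positive is a
#' convention, so it is exposed as a parameter. To derive pairwise metrics
#' from an existing multi-class run instead, see [collapse_pairwise()].
#'
#' @param spectra Labelled `modulated_spectrum` list containing exactly
#'   two classes.
#' @param n_components Passed to [loocv_classify()].
#' @param positive Positive-class label; default the first class by
#'   appearance order.
#' @param refit Passed to [loocv_classify()].
#' @return Object of class `pairwise_metrics` with the two labels,
#'   `sensitivity`, `specificity`, counts and the underlying confusion
#'   matrix.
#' @export
pairwise_metrics <- function(spectra, n_components = 7, positive = NULL,
                             refit = TRUE) {
  labs <- unique(vapply(spectra, `[[`, character(1), "class_label"))
  if (length(labs) != 2)
    stop(sprintf("exactly 2 classes are required, got %d", length(labs)))
  if (is.null(positive)) positive <- labs[1L]
  if (!positive %in% labs) stop("`positive` is not one of the two classes")
  res <- loocv_classify(spectra, n_components, refit = refit)
  out <- collapse_pairwise(res$confusion, positive = positive,
                           negative = setdiff(labs, positive))
  out$loocv <- res
  out
}

#' Pairwise metrics by collapsing a (possibly multi-class) confusion matrix
#'
#' Restricts to cells whose actual class is `positive` or `negative`;
#' a positive cell predicted as anything but `positive` counts as a false
#' negative, and a negative cell predicted as `positive` counts as a false
#' positive.
#'
#' @param cm A [confusion_matrix()].
#' @param positive,negative Class labels present in `cm`.
#' @return Object of class `pairwise_metrics`.
#' @export
collapse_pairwise <- function(cm, positive, negative) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!all(c(positive, negative) %in% cm$class_order))
    stop("both classes must be present in the confusion matrix")
  tp <- cm$counts[positive, positive]
  fn <- sum(cm$counts[positive, ]) - tp
  fp <- cm$counts[negative, positive]
  tn <- sum(cm$counts[negative, ]) - fp
  structure(
    list(positive_class = positive, negative_class = negative,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         n_positive = tp + fn, n_negative = tn + fp,
         counts = c(TP = tp, FN = fn, FP = fp, TN = tn)),
    class = "pairwise_metrics")
}

#' @export
print.pairwise_metrics <- function(x, ...) {
  cat(sprintf(
    "%s (positive, n=%d) vs %s (n=%d): sensitivity %.3f, specificity %.3f\n",
    x$positive_class, x$n_positive, x$negative_class, x$n_negative,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Summaries of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return List with `total_cells`, `overall_accuracy` (trace over total)
#'   and named `per_class_recall` (diagonal over row sums; `NaN` for a
#'   class with no cells).
#' @export
matrix_summaries <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0) stop("confusion matrix has zero total count")
  list(total_cells = total,
       overall_accuracy = sum(diag(cm$counts)) / total,
       per_class_recall = diag(cm$counts) / rowSums(cm$counts))
}
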