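test_that("PCA of modulated spectra matches an independent SVD oracle", {
  set.seed(11)
  sp <- noise_spectra(20, 50)
  fit <- fit_pca(sp, 5)
  x <- do.call(rbind, lapply(sp, `[[`, "values"))
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  for (k in 1:5) {
    v <- sv$v[, k]
    if (sum(v * fit$components[, k]) < 0) v <- -v
    expect_lt(max(abs(fit$components[, k] - v)), 1e-8)
    sc <- xc %*% v
    expect_lt(max(abs(fit$scores[, k] - sc)), 1e-8)
  }
  expect_equal(fit$explained_variance_ratios,
               (sv$d^2 / sum(sv$d^2))[1:5], tolerance = 1e-10)
  expect_equal(crossprod(fit$components), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance_ratios) <= 1e-12))
})

test_that("two spectra define a single axis along their difference", {
  a <- new_modspec(c(1, 0, 0, 0), cell_id = "a")
  b <- new_modspec(c(0, 1, 0, 0), cell_id = "b")
  fit <- fit_pca(list(a, b), 1)
  d <- (a$values - b$values) / sqrt(2)
  expect_equal(abs(sum(fit$components[, 1] * d)), 1, tolerance = 1e-10)
  expect_error(fit_pca(list(a, b), 2), "n_components")
})

test_that("projection is consistent with fit-time scores", {
  set.seed(12)
  sp <- noise_spectra(10, 30)
  fit <- fit_pca(sp, 3)
  expect_equal(project(fit, new_modspec(fit$mean_spectrum,
                                        axis = fit$axis)),
               rep(0, 3), tolerance = 1e-10, ignore_attr = TRUE)
  for (i in c(1, 5, 10))
    expect_equal(project(fit, sp[[i]]), fit$scores[i, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  wrong <- new_modspec(rnorm(30), axis = seq(2, 31))
  expect_error(project(fit, wrong), "axis")
})

test_that("noise-free identical classmates classify perfectly", {
  acq <- small_acq(150)
  ma <- peak_model(c(800, 1007), name = "A")
  mb <- peak_model(c(1345, 1450), name = "B")
  ds <- generate_dataset(list(ma, mb), 5, default_donors(1), acq, seed = 1)
  sp <- extract_dataset(ds)
  res <- loocv_classify(sp, 1)
  expect_true(all(res$predictions$actual == res$predictions$predicted))
  expect_equal(diag(res$confusion$counts), c(A = 5, B = 5))
})

test_that("LOOCV agrees exactly with a brute-force per-fold oracle", {
  acq <- small_acq(80)
  models <- default_cell_classes(noise_sigma = 0.1)[1:2]
  ds <- generate_dataset(models, 4, default_donors(2), acq, seed = 31)
  sp <- extract_dataset(ds)
  res <- loocv_classify(sp, 2)
  expect_identical(res$predictions$predicted, brute_force_loocv(sp, 2))
  expect_equal(rowSums(res$confusion$counts),
               c(A = 4, B = 4))
})

test_that("the fast shared-PCA mode stays close to the per-fold refit", {
  acq <- small_acq(120)
  ds <- generate_dataset(default_cell_classes(noise_sigma = 0.05), 6,
                         default_donors(2), acq, seed = 5)
  sp <- extract_dataset(ds)
  slow <- loocv_classify(sp, 4, refit = TRUE)
  fast <- loocv_classify(sp, 4, refit = FALSE)
  agree <- mean(slow$predictions$predicted == fast$predictions$predicted)
  expect_gt(agree, 0.8)
})

test_that("degenerate class structures are rejected", {
  sp <- noise_spectra(4, 20)
  expect_error(loocv_classify(sp, 2), "2 classes")
  sp2 <- c(noise_spectra(3, 20, "a", "A"),
           noise_spectra(1, 20, "b", "B"))
  expect_error(loocv_classify(sp2, 1), "single member")
})

test_that("pairwise metrics follow the positive-class convention", {
  acq <- small_acq(150)
  ma <- peak_model(c(800, 1007), name = "A", noise_sigma = 0.01)
  mb <- peak_model(c(1345, 1450), name = "B", noise_sigma = 0.01)
  ds <- generate_dataset(list(ma, mb), 4, default_donors(1), acq, seed = 2)
  sp <- extract_dataset(ds)
  pm <- pairwise_metrics(sp, 2)
  expect_identical(pm$positive_class, "A")
  expect_equal(pm$sensitivity, 1)
  expect_equal(pm$specificity, 1)
  expect_error(pairwise_metrics(noise_spectra(4, 10), 2), "exactly 2")

  # definition arithmetic on fixed counts: TP 9, FN 1, FP 2, TN 8
  actual <- c(rep("pos", 10), rep("neg", 10))
  predicted <- c(rep("pos", 9), "neg", rep("pos", 2), rep("neg", 8))
  cm <- confusion_matrix(actual, predicted, c("pos", "neg"))
  got <- collapse_pairwise(cm, "pos", "neg")
  expect_equal(got$sensitivity, 0.9)
  expect_equal(got$specificity, 0.8)
  expect_identical(got$counts, c(TP = 9L, FN = 1L, FP = 2L, TN = 8L))
})

test_that("confusion-matrix summaries reduce to counts, trace and recalls", {
  cm <- reference_confusion()
  s <- matrix_summaries(cm)
  expect_identical(s$total_cells, 638L)
  # hand arithmetic on the printed cells
  expect_equal(s$overall_accuracy, (135 + 149 + 148) / 638)
  expect_equal(unname(s$per_class_recall),
               c(135 / 231, 149 / 231, 148 / 176))

  ident <- confusion_matrix(rep(c("x", "y"), each = 10),
                            rep(c("x", "y"), each = 10))
  expect_equal(matrix_summaries(ident)$overall_accuracy, 1)
  empty <- confusion_matrix(character(0), character(0), c("x", "y"))
  expect_error(matrix_summaries(empty), "zero total")
})

test_that("accuracy does not decrease with between-class effect size", {
  acq <- small_acq(200)
  accs <- sapply(c(0.15, 0.4, 0.8), function(eff) {
    mean(sapply(1:5, function(s) {
      models <- default_cell_classes(noise_sigma = 0.3, emphasis = eff)
      ds <- generate_dataset(models[1:2], 8, default_donors(2), acq,
                             seed = 100 * s)
      res <- loocv_classify(extract_dataset(ds), 4)
      matrix_summaries(res$confusion)$overall_accuracy
    }))
  })
  viol <- sum(diff(accs) < -0.02)
  expect_lte(viol, 1)
})

test_that("label permutation collapses a separable problem to chance", {
  acq <- small_acq(300)
  ds <- generate_dataset(default_cell_classes(), 15, default_donors(3),
                         acq, seed = 6)
  sp <- extract_dataset(ds)
  res <- loocv_classify(sp, 5)
  expect_gt(matrix_summaries(res$confusion)$overall_accuracy, 0.9)
  set.seed(60)
  labs <- vapply(sp, `[[`, character(1), "class_label")
  perm <- sample(labs)
  spp <- Map(function(s, l) { s$class_label <- l; s }, sp, perm)
  resp <- loocv_classify(spp, 5)
  acc <- matrix_summaries(resp$confusion)$overall_accuracy
  expect_lt(abs(acc - 1 / 3), 0.18)
})

test_that("donor nuisance effects cost little class accuracy", {
  acq <- small_acq(300)
  with_donors <- generate_dataset(default_cell_classes(), 12,
                                  default_donors(3), acq, seed = 9)
  no_donors <- generate_dataset(default_cell_classes(), 12,
                                default_donors(1), acq, seed = 9)
  acc <- function(ds)
    matrix_summaries(loocv_classify(extract_dataset(ds),
                                    5)$confusion)$overall_accuracy
  expect_gt(acc(with_donors), acc(no_donors) - 0.10)
})
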