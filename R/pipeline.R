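#' Reference confusion matrix for the CD4/CD8/CD56 discrimination
#'
#' The published confusion matrix of a three-way LOOCV discrimination of
#' CD4+ T cells, CD8+ T cells and CD56+ NK cells by WMRS (638 cells from
#' three donors), shipped as a plain-text fixture. Useful as a worked
#' example for [matrix_summaries()] and [collapse_pairwise()].
#'
#' @return A [confusion_matrix()] with classes CD4, CD8, CD56.
#' @examples
#' matrix_summaries(reference_confusion())$total_cells
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion_cd4_cd8_cd56.csv",
                      package = "wmrs", mustWork = TRUE)
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  counts <- as.matrix(tab)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(actual = rownames(tab),
                           predicted = colnames(tab))
  structure(list(class_order = rownames(tab), counts = counts),
            class = "confusion_matrix")
}

default_pipeline_config <- function() {
  list(
    simulate = list(n_cells_per_class = 60, n_donors = 3,
                    noise_sigma = 0.05, amplitude_cv = 0.1,
                    background_scale = 10, emphasis = 0.5),
    seed = 1,
    n_components = 7,
    alpha = 1e-7,
    min_run = 3,
    compare = "all_pairs",
    refit = TRUE)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(config$input)) cfg$simulate <- NULL
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full WMRS analysis pipeline
#'
#' Executes simulate (or load) -> normalise -> modulated-spectrum
#' extraction -> pairwise band comparison -> PCA/LOOCV classification ->
#' pairwise metrics, and optionally writes every intermediate artefact to
#' an output directory. The run is fully reproducible from the
#' configuration and seed.
#'
#' The configuration is a named list (or a YAML file with the same keys):
#' either a `simulate` block (`n_cells_per_class`, `n_donors`,
#' `noise_sigma`, `amplitude_cv`, `background_scale`, `emphasis`) or an
#' `input` block (`spectra`, `manifest` paths); plus `seed`,
#' `n_components`, `alpha`, `min_run`, `compare` (`"all_pairs"`, `"none"`,
#' or a list of label pairs) and `refit`.
#'
#' @param config Named list or YAML path; missing entries take defaults.
#' @param out_dir Optional directory for artefacts (modulated spectra
#'   table, PCA scores, confusion matrix, metrics, report JSON).
#' @return Object of class `wmrs_report`: the configuration used, the
#'   significance maps and band regions per comparison, the PCA
#'   explained-variance table, the LOOCV result and the pairwise metrics.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_pipeline_config(config)
  acq <- do.call(acquisition_config, cfg$acquisition %||% list())

  dataset <- if (!is.null(cfg$input)) {
    pipeline_stage("read", read_dataset(cfg$input$spectra,
                                        cfg$input$manifest))
  } else {
    pipeline_stage("simulate", {
      sim <- cfg$simulate
      models <- default_cell_classes(noise_sigma = sim$noise_sigma,
                                     amplitude_cv = sim$amplitude_cv,
                                     background_scale = sim$background_scale,
                                     emphasis = sim$emphasis)
      generate_dataset(models, sim$n_cells_per_class,
                       default_donors(sim$n_donors), acq, seed = cfg$seed)
    })
  }

  spectra <- pipeline_stage("extract", extract_dataset(dataset))
  labels <- vapply(spectra, `[[`, character(1), "class_label")
  classes <- unique(labels)

  pairs <- if (identical(cfg$compare, "all_pairs")) {
    if (length(classes) >= 2) utils::combn(classes, 2, simplify = FALSE)
    else list()
  } else if (identical(cfg$compare, "none")) list() else cfg$compare
  comparisons <- lapply(pairs, function(pr) {
    pipeline_stage(sprintf("compare %s vs %s", pr[1], pr[2]), {
      sm <- compare_groups(spectra[labels == pr[1]],
                           spectra[labels == pr[2]], alpha = cfg$alpha)
      list(pair = pr, significance = sm,
           regions = significant_regions(sm, cfg$min_run))
    })
  })

  pca <- pipeline_stage("pca", fit_pca(spectra, cfg$n_components))
  loocv <- pipeline_stage("classify",
                          loocv_classify(spectra, cfg$n_components,
                                         refit = cfg$refit))
  metrics <- lapply(pairs, function(pr) {
    pipeline_stage(sprintf("metrics %s vs %s", pr[1], pr[2]),
                   pairwise_metrics(spectra[labels %in% pr],
                                    cfg$n_components, positive = pr[1],
                                    refit = cfg$refit))
  })

  report <- structure(
    list(config = cfg, acquisition = acq, n_cells = length(dataset),
         comparisons = comparisons, pca = pca, loocv = loocv,
         pairwise = metrics),
    class = "wmrs_report")
  if (!is.null(out_dir)) write_report(report, spectra, out_dir)
  report
}

write_report <- function(report, spectra, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mm <- spectra_matrix(spectra)
  mod <- data.table::as.data.table(mm$x)
  data.table::setnames(mod, sprintf("wn_%.15g", mm$axis))
  mod <- cbind(data.table::data.table(cell_id = mm$cell_id,
                                      class_label = mm$class_label), mod)
  data.table::fwrite(mod, file.path(out_dir, "modulated_spectra.csv"))
  sc <- data.table::data.table(cell_id = report$pca$cell_id,
                               class_label = report$pca$class_label)
  sc <- cbind(sc, data.table::as.data.table(report$pca$scores))
  data.table::fwrite(sc, file.path(out_dir, "pca_scores.csv"))
  utils::write.csv(report$loocv$confusion$counts,
                   file.path(out_dir, "confusion_matrix.csv"))
  met <- do.call(rbind, lapply(report$pairwise, function(m)
    data.frame(positive = m$positive_class, negative = m$negative_class,
               sensitivity = m$sensitivity, specificity = m$specificity,
               n_positive = m$n_positive, n_negative = m$n_negative)))
  if (!is.null(met))
    utils::write.csv(met, file.path(out_dir, "pairwise_metrics.csv"),
                     row.names = FALSE)
  summ <- matrix_summaries(report$loocv$confusion)
  jsonlite::write_json(
    list(seed = report$config$seed,
         n_components = report$config$n_components,
         n_cells = report$n_cells,
         overall_accuracy = summ$overall_accuracy,
         per_class_recall = as.list(summ$per_class_recall),
         explained_variance_ratios = report$pca$explained_variance_ratios,
         significant_regions = lapply(report$comparisons, function(cc)
           list(pair = cc$pair, regions = cc$regions))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.wmrs_report <- function(x, ...) {
  summ <- matrix_summaries(x$loocv$confusion)
  cat(sprintf("WMRS pipeline report: %d cells, seed %s\n", x$n_cells,
              format(x$config$seed)))
  cat(sprintf("  LOOCV accuracy (%d PCs): %.3f\n",
              x$config$n_components, summ$overall_accuracy))
  for (cc in x$comparisons)
    cat(sprintf("  %s vs %s: %d significant bands at p < %g\n",
                cc$pair[1], cc$pair[2], nrow(cc$regions), x$config$alpha))
  for (m in x$pairwise)
    cat(sprintf("  %s vs %s: sensitivity %.3f, specificity %.3f\n",
                m$positive_class, m$negative_class, m$sensitivity,
                m$specificity))
  invisible(x)
}
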