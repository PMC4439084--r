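dataset_manifest <- function(dataset) {
  rows <- lapply(seq_along(dataset), function(i) {
    st <- dataset[[i]]
    n <- nrow(st$intensities)
    data.frame(cell_id = st$cell_id, class_label = st$class_label,
               donor_id = st$donor_id, step_index = seq_len(n),
               excitation_nm = st$excitations,
               spectrum_row_index = NA_integer_)
  })
  man <- do.call(rbind, rows)
  man$spectrum_row_index <- seq_len(nrow(man))
  man
}

#' Write a dataset as a spectra matrix plus manifest
#'
#' The spectra file is a wide CSV whose columns are the axis values (header
#' `wn_<shift>`), one row per (cell, modulation step). The manifest CSV
#' maps every row back to its cell, class, donor, step and excitation
#' wavelength. A small JSON sidecar (`<manifest>.meta.json`) records the
#' acquisition geometry.
#'
#' @param dataset A `wmrs_dataset`.
#' @param spectra_path,manifest_path Output CSV paths.
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, spectra_path, manifest_path) {
  stopifnot(inherits(dataset, "wmrs_dataset"), length(dataset) >= 1)
  axis <- dataset[[1L]]$axis
  mat <- do.call(rbind, lapply(dataset, `[[`, "intensities"))
  colnames(mat) <- sprintf("wn_%.15g", axis)
  data.table::fwrite(data.table::as.data.table(mat), spectra_path)
  man <- dataset_manifest(dataset)
  data.table::fwrite(man, manifest_path)
  acq <- attr(dataset, "acq")
  jsonlite::write_json(unclass(acq), paste0(manifest_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read a dataset from a spectra matrix plus manifest
#'
#' Validates the manifest against the stack invariants: every cell must
#' have exactly `n_steps` rows, row indices must be unique and in range,
#' and labels non-empty; violations raise an error naming the offending
#' cell. The axis is taken from the spectra header; acquisition metadata
#' is read from `<manifest>.meta.json` when present and reconstructed from
#' the data otherwise.
#'
#' @param spectra_path,manifest_path CSV paths as written by
#'   [write_dataset()].
#' @return A `wmrs_dataset`.
#' @export
read_dataset <- function(spectra_path, manifest_path) {
  mat <- as.matrix(data.table::fread(spectra_path))
  man <- as.data.frame(data.table::fread(manifest_path,
                                         colClasses = list(character = c(
                                           "cell_id", "class_label",
                                           "donor_id"))))
  if (nrow(man) == 0) stop("no cells: the manifest is empty")
  need <- c("cell_id", "class_label", "donor_id", "step_index",
            "excitation_nm", "spectrum_row_index")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(setdiff(need, names(man)), collapse = ", ")))
  if (any(!nzchar(man$cell_id)) || any(!nzchar(man$class_label)))
    stop("manifest labels must be non-empty")
  if (anyDuplicated(man[c("cell_id", "step_index")]))
    stop("duplicate (cell_id, step_index) pair in manifest")
  if (any(man$spectrum_row_index < 1 | man$spectrum_row_index > nrow(mat)))
    stop("manifest spectrum_row_index out of range")
  if (anyDuplicated(man$spectrum_row_index))
    stop("duplicate spectrum_row_index in manifest")
  axis <- as.numeric(sub("^wn_", "", colnames(mat)))
  if (any(is.na(axis)) || any(diff(axis) <= 0))
    stop("spectra header does not define a strictly increasing axis")

  meta_path <- paste0(manifest_path, ".meta.json")
  steps_per_cell <- table(man$cell_id)
  n_steps <- as.integer(steps_per_cell[1L])
  bad <- names(steps_per_cell)[steps_per_cell != n_steps]
  if (length(bad))
    stop(sprintf("cell '%s' has %d step rows; expected %d like the others",
                 bad[1L], as.integer(steps_per_cell[bad[1L]]), n_steps))
  acq <- if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    acquisition_config(m$lambda0, m$n_steps, m$delta_lambda_total,
                       m$axis_min, m$axis_max, m$n_bins)
  } else {
    exc <- sort(unique(man$excitation_nm))
    acquisition_config(stats::median(exc), n_steps,
                       max(exc) - min(exc), min(axis), max(axis),
                       length(axis))
  }
  if (acq$n_steps != n_steps)
    stop(sprintf("manifest has %d steps per cell but metadata declares %d",
                 n_steps, acq$n_steps))

  ids <- unique(man$cell_id)
  stacks <- lapply(ids, function(id) {
    sub <- man[man$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$step_index), , drop = FALSE]
    if (!identical(as.integer(sub$step_index), seq_len(n_steps)))
      stop(sprintf("cell '%s' has step indices %s; expected 1..%d", id,
                   paste(sub$step_index, collapse = ","), n_steps))
    structure(
      list(cell_id = id, class_label = sub$class_label[1L],
           donor_id = sub$donor_id[1L], axis = axis,
           intensities = mat[sub$spectrum_row_index, , drop = FALSE],
           excitations = sub$excitation_nm, acq = acq),
      class = "modulation_stack")
  })
  structure(stacks, class = "wmrs_dataset", acq = acq)
}

#' Write a dataset as a single self-describing bundle
#'
#' One JSON file holding the acquisition metadata, the manifest and the
#' intensity matrix, for lossless round-tripping of small datasets.
#'
#' @param dataset A `wmrs_dataset`.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_bundle <- function(dataset, path) {
  stopifnot(inherits(dataset, "wmrs_dataset"), length(dataset) >= 1)
  obj <- list(
    format = "wmrs-bundle-v1",
    acquisition = unclass(attr(dataset, "acq")),
    axis = dataset[[1L]]$axis,
    manifest = dataset_manifest(dataset),
    intensities = do.call(rbind, lapply(dataset, `[[`, "intensities")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param path Bundle path.
#' @return A `wmrs_dataset`.
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wmrs-bundle-v1"))
    stop("not a wmrs bundle")
  a <- obj$acquisition
  acq <- acquisition_config(a$lambda0, a$n_steps, a$delta_lambda_total,
                            a$axis_min, a$axis_max, a$n_bins)
  man <- obj$manifest
  mat <- obj$intensities
  axis <- obj$axis
  ids <- unique(man$cell_id)
  stacks <- lapply(ids, function(id) {
    sub <- man[man$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$step_index), , drop = FALSE]
    structure(
      list(cell_id = id, class_label = sub$class_label[1L],
           donor_id = sub$donor_id[1L], axis = axis,
           intensities = mat[sub$spectrum_row_index, , drop = FALSE],
           excitations = sub$excitation_nm, acq = acq),
      class = "modulation_stack")
  })
  structure(stacks, class = "wmrs_dataset", acq = acq)
}

#' Minimal JCAMP-DX reader for single spectra
#'
#' Reads fixed-format JCAMP-DX files with numeric (AFFN) `##XYDATA=
#' (X++(Y..Y))` tables, the common interchange layout for vibrational
#' spectra. Applies `##XFACTOR`/`##YFACTOR` and checks `##NPOINTS`.
#' Compressed ordinate encodings (PAC/SQZ/DIF) are not supported.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return List with `x`, `y` and a named `metadata` character vector of
#'   the header labels.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^##", lines)
  meta <- list()
  data_start <- NA_integer_
  for (i in hdr) {
    kv <- sub("^##", "", lines[i])
    key <- toupper(trimws(sub("=.*$", "", kv)))
    val <- trimws(sub("^[^=]*=", "", kv))
    if (key == "XYDATA") { data_start <- i; break }
    meta[[key]] <- val
  }
  if (is.na(data_start)) stop("no ##XYDATA block found")
  end <- grep("^##END", lines)
  end <- end[end > data_start][1L]
  if (is.na(end)) end <- length(lines) + 1L
  body <- lines[seq(data_start + 1L, end - 1L)]
  body <- body[nzchar(trimws(body))]
  xf <- as.numeric(meta[["XFACTOR"]] %||% "1")
  yf <- as.numeric(meta[["YFACTOR"]] %||% "1")
  x <- numeric(0); y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (any(is.na(vals)))
      stop("non-numeric ordinate encoding; only AFFN XYDATA is supported")
    if (length(vals) < 2) next
    x <- c(x, vals[1L])
    y <- c(y, vals[-1L])
  }
  np <- length(y)
  if (!is.null(meta[["NPOINTS"]]) &&
      as.integer(meta[["NPOINTS"]]) != np)
    stop(sprintf("NPOINTS declares %s points but %d were read",
                 meta[["NPOINTS"]], np))
  # line-start abscissae anchor equally spaced ordinates
  firstx <- as.numeric(meta[["FIRSTX"]] %||% as.character(x[1L] * xf))
  lastx <- as.numeric(meta[["LASTX"]] %||% NA)
  xs <- if (!is.na(lastx) && np > 1) seq(firstx, lastx, length.out = np)
        else firstx + (seq_len(np) - 1L) *
          as.numeric(meta[["DELTAX"]] %||% "1")
  list(x = xs, y = y * yf, metadata = unlist(meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
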