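#' Reading and writing pipeline artifacts
#'
#' CSV is the canonical interchange format for signals, feature tables and
#' accuracy grids; densities and run manifests travel as JSON. Signals are
#' stored channels-by-samples with the electrode label in the first column.
#'
#' @name cli_io
NULL

#' Read / write a multichannel signal epoch
#'
#' @param path CSV path. Layout: first column `channel` (electrode label),
#'   remaining columns samples.
#' @param format Only `"csv"` is supported; requesting `"edf"` raises an
#'   informative error.
#' @param fs Sampling rate to attach (Hz).
#' @param n_channels Expected channel count; checked when given.
#' @return Channels-by-samples numeric matrix with channel row names and an
#'   `fs` attribute.
#' @export
read_signals <- function(path, format = c("csv", "edf"), fs = NULL,
                         n_channels = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF input is not supported by this build; export the recording ",
         "to CSV (channels x samples, electrode label in the first column)",
         call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ch <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[, -1], is.numeric, logical(1)))[1]
    stop("non-numeric sample column '", names(df)[-1][bad], "' in ", path,
         call. = FALSE)
  }
  rownames(mat) <- ch
  if (!is.null(n_channels) && nrow(mat) != n_channels) {
    stop("channel count mismatch: file has ", nrow(mat), ", expected ",
         n_channels, call. = FALSE)
  }
  if (!is.null(fs)) attr(mat, "fs") <- fs
  mat
}

#' @rdname read_signals
#' @param x Channels-by-samples matrix.
#' @export
write_signals <- function(x, path) {
  stopifnot(is.matrix(x))
  ch <- rownames(x)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(x)))
  xm <- x
  dimnames(xm) <- list(NULL, paste0("t", seq_len(ncol(x))))
  df <- dplyr::bind_cols(tibble::tibble(channel = ch), tibble::as_tibble(xm))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read / write a feature (or any tabular) dataset
#'
#' `read_table()` validates that every column except recognized identifier
#' columns (`subject`, `sample`, `label`, `classifier`, `class`, `operator`,
#' `family`, `band`) parses as numeric, and reports the offending row and
#' column otherwise; round-tripping through `write_table()` preserves values
#' to full double precision.
#'
#' @param path CSV path.
#' @param x Data frame.
#' @return A tibble.
#' @export
read_table <- function(path) {
  id_cols <- c("subject", "sample", "label", "classifier", "class",
               "operator", "family", "band")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in setdiff(names(df), id_cols)) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed) & !is.na(col))[1]
      stop("non-numeric value '", col[bad], "' at row ", bad, ", column '",
           nm, "' of ", path, call. = FALSE)
    }
  }
  df
}

#' @rdname read_table
#' @export
write_table <- function(x, path) {
  readr::write_csv(dplyr::as_tibble(x), path)
  invisible(path)
}

#' Load an experiment configuration from YAML or JSON
#'
#' The file mirrors [fusion_config()] fields; the `operator_grid` entry may
#' be a list of `{operator, family, alpha}` records. Missing fields take
#' the package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [fusion_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw),
                        c("holdout_fraction", "n_repetitions", "cv_folds",
                          "classifiers", "h0", "cd3_ratio", "seed"))]
  if (!is.null(raw$operator_grid)) {
    og <- dplyr::bind_rows(lapply(raw$operator_grid, function(row) {
      tibble::tibble(operator = row$operator,
                     family = if (is.null(row$family)) NA_character_
                              else as.character(row$family),
                     alpha = if (is.null(row$alpha)) NA_real_
                             else as.numeric(row$alpha))
    }))
    args$operator_grid <- og
  }
  do.call(fusion_config, args)
}

#' Write a reproducibility manifest
#'
#' Records the seed, a content hash of the configuration, and software
#' versions, so any run can be reproduced bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config Configuration object (any list).
#' @param seed The seed the run used.
#' @param extra Optional named list merged into the manifest.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    seed = seed,
    config_hash = rlang::hash(config),
    config = unclass(config),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("choqfuse")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
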