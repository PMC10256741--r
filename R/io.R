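#' Write a set of result tables with a manifest
#'
#' Writes each named table as a TSV file (`<name>.tsv`) under `out_dir` and
#' a `manifest.json` listing every file, its row count and a hash of the
#' run configuration. Re-running with identical inputs reproduces
#' byte-identical files.
#'
#' @param tables Named list of data frames; must be nonempty.
#' @param out_dir Output directory, created if needed.
#' @param config Optional list describing the run configuration; its hash
#'   is recorded in the manifest.
#' @return The manifest as a list, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == "")) {
    stop_langlat("'tables' must be a nonempty named list of data frames",
                 "langlat_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_langlat(paste0("cannot create output directory: ", out_dir),
                 "langlat_io_error")
  }
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    if (!is.data.frame(tbl)) {
      stop_langlat(paste0("table '", nm, "' is not a data frame"),
                   "langlat_io_error")
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
    files <- c(files, basename(path))
    rows <- c(rows, nrow(tbl))
  }
  manifest <- list(
    files = files,
    rows = as.list(setNames(rows, files)),
    config_hash = rlang::hash(config),
    created = "langlat"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write one subject scan as a TSV (region_id first column)
#' @param mat region x time matrix with rownames = region ids
#' @param path output file
#' @keywords internal
write_timeseries <- function(mat, path) {
  tbl <- tibble::as_tibble(mat, .name_repair = ~ paste0("t", seq_along(.x)))
  tbl <- dplyr::bind_cols(tibble::tibble(region_id = as.integer(rownames(mat))), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read one subject scan TSV back into a region x time matrix
#' @param path TSV written by [write_timeseries()]
#' @keywords internal
read_timeseries <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- as.character(tbl$region_id)
  colnames(mat) <- NULL
  mat
}
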