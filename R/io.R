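# Plain-text / PNG interchange for datasets and metric tables.

#' Write / read an image dataset as PNG files with a JSON sidecar
#'
#' Pixel values are mapped from `[-1, 1]` to the 8-bit PNG range (the
#' inverse mapping is applied on reading, so round-trips are exact to 1/255
#' quantisation). Labels and shape/texture classes go to `labels.json`.
#'
#' @param dataset dataset tibble with a `pixels` list-column.
#' @param dir output directory (created if needed).
#' @return the directory (writing) / the dataset tibble (reading).
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset[setdiff(names(dataset), "pixels")]
  meta$file <- sprintf("img_%05d.png", seq_len(nrow(dataset)))
  for (i in seq_len(nrow(dataset))) {
    png::writePNG((dataset$pixels[[i]] + 1) / 2, file.path(dir, meta$file[i]))
  }
  jsonlite::write_json(meta, file.path(dir, "labels.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  meta <- as_tibble(jsonlite::read_json(file.path(dir, "labels.json"),
                                        simplifyVector = TRUE))
  pixels <- lapply(meta$file, function(f)
    png::readPNG(file.path(dir, f)) * 2 - 1)
  meta$file <- NULL
  meta$pixels <- pixels
  meta
}

#' Write per-unit metric records as CSV with JSON metadata
#'
#' @param records tibble from [rf_metrics()].
#' @param path CSV path; a `.json` sidecar records the computation
#'   parameters.
#' @param meta named list of parameters to record.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(records, path, meta = list()) {
  utils::write.csv(records, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
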