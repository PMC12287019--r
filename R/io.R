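## File I/O: 8-/16-bit grayscale PNG and TIFF images, 0/255 masks,
## JSON configurations, and the published benchmark table.

#' Read a grayscale image
#'
#' Accepts 8- or 16-bit grayscale PNG or TIFF; 16-bit values are linearly
#' rescaled to `[0, 255]`. Colour images are rejected (a grayscale image
#' stored with identical R/G/B channels is accepted).
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return integer gray matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("package 'tiff' required for TIFF input", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3 &&
        (max(abs(a[, , 1] - a[, , 2])) > 0 || max(abs(a[, , 1] - a[, , 3])) > 0)) {
      stop("colour images are not supported; provide a grayscale image", call. = FALSE)
    }
    a <- a[, , 1]
  }
  as_gray(round_half_up(a * 255))
}

#' Write a gray image as 8-bit PNG
#' @param img integer gray matrix in `[0, 255]`.
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(as_gray(img) / 255, path)
  invisible(path)
}

#' Write a binary mask as 0/255 8-bit PNG
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1.0, path)
  invisible(path)
}

#' Published benchmark metric tables
#'
#' Per-split accuracy, precision, recall and F-measure reported for KNN
#' (k = 3, 5, 7, 9, 11) and a linear SVM on a 63-patient / 315-vertebra
#' clinical lumbar dataset, at train:test splits 30:70 through 80:20.
#' Shipped so the statistical comparison tools ([compare_classifiers()],
#' [results_table()]) can be exercised and cross-checked against published
#' numbers without access to the clinical images.
#'
#' @return data.frame with columns `classifier`, `param`, `split`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
reference_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "vbseg", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Write / read a pipeline configuration as JSON
#'
#' Configurations round-trip losslessly: every parameter is a scalar or
#' small vector.
#'
#' @param config list (e.g. from [pipeline_config()]).
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}
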