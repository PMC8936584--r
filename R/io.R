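# Readers and writers: PNG images and masks, metric tables, run manifests.

#' Write a grayscale image as PNG
#'
#' @param image `[H,W]` matrix with values in \[0,1\].
#' @param path Output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a grayscale image PNG
#'
#' Multi-channel PNGs are converted to grayscale by channel averaging.
#'
#' @param path PNG file.
#' @return `[H,W]` matrix in \[0,1\].
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    nc <- min(dim(x)[3], 3L)       # drop alpha
    x <- apply(x[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  x
}

#' Write an integer label mask as an indexed (8-bit grayscale) PNG
#'
#' Labels are stored one per gray level (label k -> intensity k/255), which
#' round-trips exactly for up to 255 regions.
#'
#' @param mask Integer label matrix with values in `0..255`.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  if (any(mask < 0) || any(mask > 255)) stop("write_mask_png: labels must be 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png]
#'
#' @param path PNG file.
#' @return Integer label matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  m
}

#' Write per-sample region metrics as CSV
#'
#' Columns: sample_id, region, iou, dice.
#'
#' @param report An `eval_report` from [evaluate_model] (or a compatible
#'   data.frame).
#' @param path Output CSV.
#' @export
write_metrics_csv <- function(report, path) {
  df <- if (inherits(report, "eval_report")) report$per_sample else report
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the JSON metrics summary
#'
#' Mean IoU/Dice over the named cardiac regions; background is excluded from
#' all means.
#'
#' @param report An `eval_report`.
#' @param path Output JSON.
#' @param labels Optional named label vector for region names.
#' @export
write_metrics_json <- function(report, path, labels = NULL) {
  per <- report$per_region
  if (!is.null(labels))
    per$name <- names(labels)[match(per$region, labels)]
  jsonlite::write_json(
    list(mean_iou = report$mean_iou, mean_dice = report$mean_dice,
         background_excluded = TRUE, per_region = per),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the merged configuration, its hash, the seed and the package
#' version so a run can be reproduced byte-for-byte.
#'
#' @param config Configuration list.
#' @param seed Integer seed of the run.
#' @param path Output JSON.
#' @export
write_run_manifest <- function(config, seed, path) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = config, seed = seed,
         config_hash = unname(tools::md5sum(textConnection_write(cfg_json))),
         package = "echoseg",
         version = as.character(utils::packageVersion("echoseg"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

textConnection_write <- function(text) {
  f <- tempfile()
  writeLines(as.character(text), f)
  f
}
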