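#' Image, mask and table input/output
#'
#' PNG and TIFF images are exchanged as `H x W x 3` arrays in `[0, 1]`
#' (8- or 16-bit integer files are scaled on read). Segmentation masks are
#' stored as PNG with raw levels 0 = stroma and 1 = epithelium; a visual
#' export renders epithelium in red over black stroma. Labels travel in a
#' single provenance-bearing CSV with schema
#' `sample_id,path,grade,fold,transform_tag,source_id`.
#'
#' @name histoswt-io
NULL

#' Read an RGB image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `H x W x 3` array in `[0, 1]` (grayscale replicated, alpha
#'   dropped).
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  .check_rgb(img, arg = path)
  img
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  .check_rgb(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read a two-class segmentation mask
#'
#' Accepts PNG files whose raw levels are 0 (stroma) and 1 (epithelium),
#' or any grayscale PNG which is thresholded at one half.
#'
#' @param path PNG file path.
#' @return Integer matrix with 1 = stroma, 2 = epithelium.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  raw <- round(img * 255)
  if (all(raw %in% c(0, 1))) {
    matrix(as.integer(raw) + 1L, nrow(img))
  } else {
    matrix(ifelse(img >= 0.5, 2L, 1L), nrow(img))
  }
}

#' Write a two-class segmentation mask
#'
#' @param mask Integer matrix with 1 = stroma, 2 = epithelium.
#' @param path Output PNG path.
#' @param visual If `TRUE`, render epithelium red over black stroma
#'   instead of raw 0/1 levels.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path, visual = FALSE) {
  stopifnot(is.matrix(mask), all(mask %in% c(1L, 2L)))
  if (visual) {
    img <- array(0, c(dim(mask), 3L))
    img[, , 1] <- as.numeric(mask == 2L)
    png::writePNG(img, path)
  } else {
    png::writePNG(matrix((mask - 1L) / 255, nrow(mask)), path)
  }
  invisible(path)
}

#' Export subband planes for inspection
#'
#' Writes the twelve coefficient planes (4 subbands x 3 channels) as a
#' multi-page TIFF, each plane min-max normalized to `[0, 1]`, together
#' with a JSON sidecar recording the original value ranges.
#'
#' @param bands An `"swt_subbands"` object.
#' @param path Output `.tiff` path; the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_subbands_tiff <- function(bands, path) {
  stopifnot(inherits(bands, "swt_subbands"))
  pages <- list()
  ranges <- list()
  for (nm in c("ll", "lh", "hl", "hh")) {
    for (ch in 1:3) {
      m <- bands[[nm]][, , ch]
      rng <- range(m)
      den <- if (rng[2] - rng[1] < 1e-15) 1 else rng[2] - rng[1]
      pages[[length(pages) + 1L]] <- (m - rng[1]) / den
      ranges[[sprintf("%s_ch%d", nm, ch)]] <- rng
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(wavelet = bands$wavelet, level = bands$level,
                            ranges = ranges),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the labels CSV
#'
#' @param df Data frame with columns `sample_id`, `path`, `grade`, `fold`,
#'   `transform_tag`, `source_id` (missing ones are filled with `NA` /
#'   defaults).
#' @param path CSV file path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_labels_csv <- function(df, path) {
  cols <- c("sample_id", "path", "grade", "fold", "transform_tag", "source_id")
  for (cl in setdiff(cols, names(df))) {
    df[[cl]] <- if (cl == "transform_tag") "original"
                else if (cl == "source_id") df$sample_id
                else NA
  }
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "grade")
  if (!all(need %in% names(df))) {
    stop("labels CSV must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a fold-assignment manifest
#'
#' @param folds A `"fold_assignment"`.
#' @param path JSON file path.
#' @return The assignment (read) or `path` invisibly (write).
#' @export
write_fold_manifest <- function(folds, path) {
  stopifnot(inherits(folds, "fold_assignment"))
  jsonlite::write_json(list(k = folds$k, seed = folds$seed,
                            fold = as.list(folds$fold)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_manifest
#' @export
read_fold_manifest <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(k = as.integer(obj$k),
                 fold = stats::setNames(as.integer(unlist(obj$fold)),
                                        names(obj$fold)),
                 seed = as.integer(obj$seed)),
            class = "fold_assignment")
}

#' Hash a file's bytes
#'
#' Same rolling hash as [image_hash()], applied to raw file content; used
#' in run manifests for replay verification.
#'
#' @param path File path.
#' @return Integer hash.
#' @export
file_hash <- function(path) {
  v <- as.integer(readBin(path, "raw", file.info(path)$size))
  p <- 2147483647
  hsh <- 0
  for (x in v) hsh <- (hsh * 31 + x) %% p
  as.integer(hsh)
}
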