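#' Geometric training-set augmentation
#'
#' The seven rigid transforms applied to every training image (never to
#' test images): 90/180/270 degree anticlockwise rotations, horizontal
#' flip, horizontal flip + 90 degree rotation, vertical flip, and vertical
#' flip + 90 degree rotation. Each is a bijection on the pixel grid, so
#' intensity histograms are preserved exactly.
#'
#' Conventions: "horizontal flip" mirrors left-right (across the vertical
#' axis), "vertical flip" mirrors top-bottom; in the combined transforms
#' the flip is applied first, then the anticlockwise rotation.
#'
#' @name augmentation
NULL

.TRANSFORM_TAGS <- c("rot90", "rot180", "rot270", "hflip",
                     "hflip_rot90", "vflip", "vflip_rot90")

# anticlockwise rotation by 90 degrees of an H x W x C array (square input)
.rot90acw <- function(x) {
  out <- aperm(x, c(2L, 1L, 3L))
  out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
}

.hflip <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
.vflip <- function(x) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]

#' Apply one named geometric transform
#'
#' @param image `H x W x 3` array (square).
#' @param tag One of `"rot90"`, `"rot180"`, `"rot270"`, `"hflip"`,
#'   `"hflip_rot90"`, `"vflip"`, `"vflip_rot90"`, or `"original"`.
#' @return Transformed array of the same shape.
#' @export
apply_transform <- function(image, tag) {
  switch(tag,
    original    = image,
    rot90       = .rot90acw(image),
    rot180      = .rot90acw(.rot90acw(image)),
    rot270      = .rot90acw(.rot90acw(.rot90acw(image))),
    hflip       = .hflip(image),
    hflip_rot90 = .rot90acw(.hflip(image)),
    vflip       = .vflip(image),
    vflip_rot90 = .rot90acw(.vflip(image)),
    stop("unknown transform tag: ", tag, call. = FALSE)
  )
}

#' The seven-transform augmentation of one image
#'
#' Returns the seven transformed copies in a fixed canonical order so
#' augmented datasets are byte-for-byte reproducible. Rotations preserve
#' shape only for square images, so non-square input is an error (labels
#' and masks must stay aligned).
#'
#' @param image Square `H x W x 3` array in `[0, 1]`.
#' @param source_id Identifier of the original image, carried on every
#'   augmented sample for leakage auditing.
#' @return List of 7 samples, each a list with `pixels`, `source_id` and
#'   `transform_tag` (in the order rot90, rot180, rot270, hflip,
#'   hflip_rot90, vflip, vflip_rot90).
#' @examples
#' img <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
#' length(augment_seven(img))  # 7
#' @export
augment_seven <- function(image, source_id = "img") {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(image)
  if (d[1] != d[2]) {
    stop("augmentation requires a square image (got ", d[1], " x ", d[2], ")",
         call. = FALSE)
  }
  lapply(.TRANSFORM_TAGS, function(tag) {
    list(pixels = apply_transform(image, tag),
         source_id = source_id, transform_tag = tag)
  })
}
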