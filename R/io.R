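#' Construct a registered multimodal image pair
#'
#' Bundles a fluorescein angiography frame and a color fundus photograph of
#' the same eye. The two rasters must be spatially registered upstream and
#' therefore share a pixel grid; only the dimensions can be checked here.
#'
#' @param angiography numeric matrix `[row, col]` with values in \[0, 1\].
#' @param color_fundus numeric `H x W x 3` array with values in \[0, 1\].
#' @param pixel_size_note optional free-text acquisition metadata.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(angiography, color_fundus, pixel_size_note = NULL) {
  if (!is.matrix(angiography) || !is.numeric(angiography))
    stop("`angiography` must be a numeric matrix")
  if (!(is.array(color_fundus) && length(dim(color_fundus)) == 3 &&
        dim(color_fundus)[3] == 3))
    stop("`color_fundus` must be an H x W x 3 array")
  if (!all(dim(angiography) == dim(color_fundus)[1:2]))
    stop("registration error: angiography and color fundus dimensions differ")
  rng <- range(angiography, color_fundus)
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]")
  structure(
    list(angiography = angiography, color_fundus = color_fundus,
         pixel_size_note = pixel_size_note),
    class = "image_pair"
  )
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d px (angiography + RGB fundus)\n",
              nrow(x$angiography), ncol(x$angiography)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' The clinician's box around the suspected leakage area. Coordinates are
#' 0-based and half-open: the box covers rows `[r0, r1)` and columns
#' `[c0, c1)` so its height is `r1 - r0` and width `c1 - c0`.
#'
#' @param r0,c0 top-left corner (0-based).
#' @param r1,c1 exclusive bottom-right corner.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(r0, c0, r1, c1) {
  v <- c(r0 = r0, c0 = c0, r1 = r1, c1 = c1)
  if (any(v != round(v))) stop("box coordinates must be integers")
  if (!(r0 >= 0 && c0 >= 0 && r1 > r0 && c1 > c0))
    stop("invalid box: need 0 <= r0 < r1 and 0 <= c0 < c1")
  vi <- as.integer(round(v))
  structure(list(r0 = vi[1], c0 = vi[2], r1 = vi[3], c1 = vi[4]),
            class = "roi_box")
}

box_height <- function(box) box$r1 - box$r0
box_width <- function(box) box$c1 - box$c0

validate_box <- function(box, shape, patch_size = NULL) {
  stopifnot(inherits(box, "roi_box"))
  if (box$r1 > shape[1] || box$c1 > shape[2])
    stop("box out of bounds for a ", shape[1], " x ", shape[2], " image")
  if (!is.null(patch_size) &&
      (box_height(box) < patch_size || box_width(box) < patch_size))
    stop("box smaller than the decomposition patch size (", patch_size, " px)")
  invisible(box)
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows [%d, %d) x cols [%d, %d)  (%d x %d px)\n",
              x$r0, x$r1, x$c0, x$c1, box_height(x), box_width(x)))
  invisible(x)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  )
  img
}

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] >= 3) return(img[, , 2])  # green channel
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  if (length(d) == 3 && d[3] == 2) return(img[, , 1])  # gray + alpha
  stop("cannot interpret raster with dim ", paste(d, collapse = "x"))
}

#' Load a registered angiography / color-fundus pair from disk
#'
#' PNG and TIFF rasters are supported; intensities are rescaled to \[0, 1\]
#' by the readers. An RGB angiography image is reduced to its green channel
#' (the standard high-contrast channel in fundus work); grayscale passes
#' through. The fundus image must be RGB (an alpha channel is dropped).
#'
#' @param angio_path path to the angiography image.
#' @param fundus_path path to the color fundus image.
#' @return an [image_pair()].
#' @export
load_image_pair <- function(angio_path, fundus_path) {
  angio <- to_gray(read_raster(angio_path))
  fundus <- read_raster(fundus_path)
  if (is.matrix(fundus) || dim(fundus)[3] < 3)
    stop("fundus image must be RGB")
  fundus <- fundus[, , 1:3, drop = FALSE]
  if (!all(dim(angio) == dim(fundus)[1:2]))
    stop("registration error: angiography is ",
         paste(dim(angio), collapse = "x"), " but fundus is ",
         paste(dim(fundus)[1:2], collapse = "x"))
  image_pair(clamp01(angio), clamp01(fundus))
}

#' Write a binary mask as a lossless 0/255 PNG
#'
#' @param mask binary matrix (values 0/1 or logical).
#' @param path output path (`.png`).
#' @export
save_mask <- function(mask, path) {
  if (is.logical(mask)) mask <- as_binary(mask * 1)
  if (!is_binary_matrix(mask))
    stop("`mask` must be binary (0/1)")
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a binary mask written by [save_mask()]
#'
#' @param path PNG path.
#' @return binary 0/1 matrix.
#' @export
load_mask <- function(path) {
  m <- to_gray(read_raster(path))
  as_binary((m > 0.5) * 1)
}
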