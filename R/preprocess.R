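#' Crop the ROI from both modalities at identical coordinates
#'
#' The box drawn on the angiography is transferred unchanged to the
#' registered fundus image, so the two blocks cover the same retinal area.
#'
#' @param pair an [image_pair()].
#' @param box an [roi_box()] (0-based, half-open).
#' @return list with `angio_block` (matrix) and `fundus_block`
#'   (`h x w x 3` array), plus the `box`.
#' @export
extract_roi <- function(pair, box) {
  stopifnot(inherits(pair, "image_pair"))
  validate_box(box, dim(pair$angiography))
  rows <- (box$r0 + 1):box$r1
  cols <- (box$c0 + 1):box$c1
  list(
    angio_block = pair$angiography[rows, cols, drop = FALSE],
    fundus_block = pair$color_fundus[rows, cols, , drop = FALSE],
    box = box
  )
}

# CLAHE wrapper: EBImage requires dimensions divisible by the tile counts,
# so replicate-pad on the bottom/right and crop back.
clahe_padded <- function(x, tiles, clip) {
  nr <- nrow(x); nc <- ncol(x)
  tr <- min(tiles[1], max(1, nr %/% 8))
  tc <- min(tiles[2], max(1, nc %/% 8))
  pr <- (tr - nr %% tr) %% tr
  pc <- (tc - nc %% tc) %% tc
  xp <- x[c(seq_len(nr), rep(nr, pr)), c(seq_len(nc), rep(nc, pc)),
          drop = FALSE]
  out <- EBImage::imageData(
    EBImage::clahe(EBImage::Image(xp), nx = tr, ny = tc, limit = clip)
  )
  matrix(out, nrow(xp), ncol(xp))[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Preprocess the fundus ROI: green channel + CLAHE
#'
#' Vessels have their best contrast against the retinal background in the
#' green channel of a color fundus photograph; contrast-limited adaptive
#' histogram equalization then evens out illumination before vessel
#' filtering.
#'
#' @param fundus_block `h x w x 3` RGB array.
#' @param clahe_clip relative clip limit (default 2, the common fundus
#'   setting).
#' @param clahe_tiles tile grid `(rows, cols)`; tiles are reduced
#'   automatically for very small blocks.
#' @return the enhanced green-channel block, values in \[0, 1\].
#' @export
preprocess_fundus <- function(fundus_block, clahe_clip = 2,
                              clahe_tiles = c(8, 8)) {
  if (!(is.array(fundus_block) && length(dim(fundus_block)) == 3 &&
        dim(fundus_block)[3] == 3))
    stop("`fundus_block` must be an RGB (3-channel) block")
  g <- fundus_block[, , 2]
  if (diff(range(g)) < .Machine$double.eps) return(g)  # flat field: no-op
  clamp01(clahe_padded(g, clahe_tiles, clahe_clip))
}
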