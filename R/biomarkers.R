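#' Binarize the sparse map into a candidate-leakage mask
#'
#' Rule `"adaptive"` (default): threshold at `mean + 2 sd` of the strictly
#' positive sparse values, so only responses well above the bulk of the
#' surviving sparse energy are kept; with fewer than two positive entries
#' the mask is empty. Rule `"nonzero"`: any strictly positive entry.
#'
#' @param S_map non-negative sparse map from [decompose_block()].
#' @param rule `"adaptive"` or `"nonzero"`.
#' @return binary matrix.
#' @export
binarize_sparse_map <- function(S_map, rule = c("adaptive", "nonzero")) {
  rule <- match.arg(rule)
  if (any(S_map < 0))
    stop("`S_map` must be non-negative (clip the sparse map at 0)")
  pos <- S_map[S_map > 0]
  if (rule == "nonzero") return(as_binary((S_map > 0) * 1))
  if (length(pos) < 2) return(matrix(0, nrow(S_map), ncol(S_map)))
  thr <- mean(pos) + 2 * sd(pos)
  as_binary((S_map > thr) * 1)
}

region_table <- function(lab, min_area, max_regions) {
  k <- max(lab)
  if (k == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = k)
  regs <- list()
  for (i in seq_len(k)) {
    if (areas[i] < min_area) next
    idx <- which(lab == i, arr.ind = TRUE)
    centroid <- colMeans(idx) - 1  # 0-based
    regs[[length(regs) + 1]] <- list(
      area_px = areas[i], centroid = unname(centroid), raw_label = i
    )
  }
  if (!length(regs)) return(list())
  ord <- order(
    -vapply(regs, `[[`, numeric(1), "area_px"),
    vapply(regs, function(r) r$centroid[1], numeric(1)),
    vapply(regs, function(r) r$centroid[2], numeric(1))
  )
  regs <- regs[ord]
  if (is.finite(max_regions) && length(regs) > max_regions)
    regs <- regs[seq_len(max_regions)]
  regs
}

#' Extract sorted connected leakage regions from a binary mask
#'
#' 8-connected labeling, removal of components below `min_area`, sorting by
#' area (descending, ties broken top-most then left-most centroid), and an
#' optional cap on the number of regions. Region `d` of the result is the
#' d-th biomarker block; the union of all retained regions is the
#' biomarker mask `S_P`.
#'
#' @param mask binary matrix (ROI frame).
#' @param min_area minimum region area in px (default 5).
#' @param max_regions keep at most this many regions (default all).
#' @return object of class `biomarker_set`: `regions` (list of `label`,
#'   `mask_roi`, `area_px`, `centroid`, `seed` — seed filled later),
#'   `S_P` (binary union mask), `box` / `full_mask` (attached by
#'   [restore_to_full_frame()]).
#' @export
extract_regions <- function(mask, min_area = 5, max_regions = Inf) {
  if (!is_binary_matrix(as_binary(mask * 1)))
    stop("`mask` must be binary")
  mask <- as_binary((mask > 0) * 1)
  lab <- label8(mask)
  regs <- region_table(lab, min_area, max_regions)
  regions <- vector("list", length(regs))
  S_P <- matrix(0, nrow(mask), ncol(mask))
  for (d in seq_along(regs)) {
    m <- (lab == regs[[d]]$raw_label) * 1
    dim(m) <- dim(mask)
    S_P <- pmax(S_P, m)
    regions[[d]] <- list(
      label = d,
      mask_roi = as_binary(m),
      area_px = regs[[d]]$area_px,
      centroid = regs[[d]]$centroid,
      seed = NULL
    )
  }
  structure(list(regions = regions, S_P = as_binary(S_P),
                 box = NULL, full_mask = NULL),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> %d region(s), %d positive px in ROI\n",
              length(x$regions), sum(x$S_P)))
  for (r in x$regions)
    cat(sprintf("  #%d area=%d centroid=(%.1f, %.1f)\n",
                r$label, r$area_px, r$centroid[1], r$centroid[2]))
  invisible(x)
}

#' Restore ROI-frame biomarkers to full-image coordinates
#'
#' Places the biomarker mask at the box position in a full-size zero
#' raster and offsets centroids and seeds by `(r0, c0)`, undoing the ROI
#' cropping so the result can be overlaid on the original images.
#'
#' @param set a [extract_regions()] result (with `S_P` in ROI frame).
#' @param box the [roi_box()] used for cropping.
#' @param image_shape `(H, W)` of the full image.
#' @return the set with `box`, `full_mask`, and per-region `centroid_full`
#'   / `seed_full` fields added.
#' @export
restore_to_full_frame <- function(set, box, image_shape) {
  stopifnot(inherits(set, "biomarker_set"))
  validate_box(box, image_shape)
  if (box_height(box) != nrow(set$S_P) || box_width(box) != ncol(set$S_P))
    stop("box does not match the ROI mask shape")
  full <- matrix(0, image_shape[1], image_shape[2])
  full[(box$r0 + 1):box$r1, (box$c0 + 1):box$c1] <- set$S_P
  set$box <- box
  set$full_mask <- as_binary(full)
  off <- c(box$r0, box$c0)
  set$regions <- lapply(set$regions, function(r) {
    r$centroid_full <- r$centroid + off
    if (!is.null(r$seed)) r$seed_full <- r$seed + off
    r
  })
  set
}
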