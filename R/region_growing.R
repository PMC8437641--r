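#' Seed point of a biomarker region
#'
#' The seed of region `d` is the argmax of the sparse map restricted to the
#' region's mask — the most salient pixel of the decomposition response —
#' with ties broken by smallest row, then smallest column. The seed value
#' handed to region growing is the *angiography* intensity at that
#' position, since growing operates on the raw angiography block.
#'
#' @param region one element of `biomarker_set$regions`.
#' @param S_map sparse map (ROI frame).
#' @param angio_block angiography ROI block.
#' @return list (class `seed_point`): `position` (0-based `(row, col)`),
#'   `source_label`, `seed_value`.
#' @export
extract_seed <- function(region, S_map, angio_block) {
  mask <- region$mask_roi
  if (sum(mask) == 0) stop("empty region has no seed")
  vals <- ifelse(mask > 0, S_map, -Inf)
  best <- max(vals)
  idx <- which(vals == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  structure(list(
    position = unname(idx) - 1,
    source_label = region$label,
    seed_value = angio_block[idx[1], idx[2]]
  ), class = "seed_point")
}

#' Grow a region from a seed on the angiography block
#'
#' Breadth-first growth over 8-neighbors starting at the seed: a pixel `p`
#' is admitted iff `|I(p) - seed_value| <= T`. The admission test compares
#' to the fixed seed intensity (not a running mean), so the result is
#' order-independent and monotone in `T`. Growth stops when no admissible
#' neighbor remains; the result is the 8-connected set of admitted pixels
#' containing the seed.
#'
#' @param angio_block angiography ROI block, values in \[0, 1\].
#' @param seed a [extract_seed()] result (its `seed_value` is used), or a
#'   0-based `(row, col)` pair (value then read from the block).
#' @param threshold admission threshold `T` in (0, 1).
#' @return object of class `grown_region`: `R_pd` (binary matrix), `d`
#'   (source label or `NA`), `T_used`, `seed`.
#' @export
region_grow <- function(angio_block, seed, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  if (inherits(seed, "seed_point")) {
    pos <- seed$position + 1
    sv <- seed$seed_value
    d <- seed$source_label
  } else {
    pos <- as.integer(seed) + 1L
    if (any(pos < 1) || pos[1] > nrow(angio_block) || pos[2] > ncol(angio_block))
      stop("seed outside the block")
    sv <- angio_block[pos[1], pos[2]]
    d <- NA_integer_
  }
  if (pos[1] < 1 || pos[1] > nrow(angio_block) ||
      pos[2] < 1 || pos[2] > ncol(angio_block))
    stop("seed outside the block")
  admissible <- abs(angio_block - sv) <= threshold
  region <- matrix(FALSE, nrow(angio_block), ncol(angio_block))
  frontier <- matrix(FALSE, nrow(angio_block), ncol(angio_block))
  if (admissible[pos[1], pos[2]]) {
    region[pos[1], pos[2]] <- TRUE
    frontier[pos[1], pos[2]] <- TRUE
    while (any(frontier)) {
      nb <- matrix(FALSE, nrow(region), ncol(region))
      for (i in seq_len(nrow(NEIGH8)))
        nb <- nb | shift_mat(frontier, NEIGH8[i, 1], NEIGH8[i, 2],
                             fill = FALSE)
      frontier <- nb & admissible & !region
      region <- region | frontier
    }
  }
  structure(list(R_pd = as_binary(region * 1), d = d,
                 T_used = threshold, seed = if (inherits(seed, "seed_point"))
                   seed$position else as.integer(seed)),
            class = "grown_region")
}

#' Fuse decomposition and region-growing masks
#'
#' The fused biomarker mask is the pixelwise union of every decomposition
#' region mask and every grown region (sums re-binarized). Fusion can only
#' add pixels to the decomposition mask, which is the mechanism that
#' counteracts its undersegmentation.
#'
#' @param set a `biomarker_set` (its `S_P` supplies the decomposition
#'   regions).
#' @param grown list of [region_grow()] results.
#' @return binary fused mask `F_S` (ROI frame).
#' @export
fuse_masks <- function(set, grown) {
  F_S <- set$S_P
  for (g in grown) {
    if (!all(dim(g$R_pd) == dim(F_S)))
      stop("grown mask shape differs from the ROI mask")
    F_S <- pmax(F_S, g$R_pd)
  }
  as_binary(F_S)
}
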