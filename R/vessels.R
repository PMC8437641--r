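#' Truncated Laplacian of Gaussian kernel
#'
#' Weights follow the LoG formula
#' \deqn{LoG(r,c) = -\frac{1}{\pi\sigma^4}
#'   \Big(1 - \frac{r^2+c^2}{2\sigma^2}\Big)
#'   e^{-\frac{r^2+c^2}{2\sigma^2}}}
#' on the integer grid \eqn{(r,c) \in [-k,k] \times [-l,l]}. With the
#' defaults (`sigma = 3`, `k = l = 3`) this is the 7x7 kernel used for
#' retinal vessel detection: vessels a few pixels wide produce strong
#' responses, dark vessels with positive sign and bright ones negative.
#'
#' @param sigma Gaussian standard deviation (> 0), pixels.
#' @param k,l half-sizes of the truncated support.
#' @return object of class `log_kernel` with fields `weights`
#'   (`(2k+1) x (2l+1)` matrix), `sigma`, `k`, `l`.
#' @export
build_log_kernel <- function(sigma = 3, k = 3, l = 3) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (k < 0 || l < 0) stop("half-sizes must be non-negative")
  r <- -k:k
  c <- -l:l
  rho2 <- outer(r^2, c^2, "+")
  w <- -(1 / (pi * sigma^4)) * (1 - rho2 / (2 * sigma^2)) *
    exp(-rho2 / (2 * sigma^2))
  structure(list(weights = w, sigma = sigma, k = as.integer(k),
                 l = as.integer(l)), class = "log_kernel")
}

#' Spatially filter a block with a LoG kernel
#'
#' Cross-correlation \eqn{G(x,y) = \sum_r \sum_c LoG(r,c)\, I(x+r, y+c)}
#' with reflect padding at the borders (avoids the artificial edge
#' responses a zero or circular border would feed into the binarization).
#'
#' @param block numeric matrix, at least as large as the kernel.
#' @param kernel a [build_log_kernel()] result.
#' @return response matrix of the same shape as `block`.
#' @export
log_filter <- function(block, kernel) {
  stopifnot(inherits(kernel, "log_kernel"))
  k <- kernel$k; l <- kernel$l
  if (nrow(block) < 2 * k + 1 || ncol(block) < 2 * l + 1)
    stop("block smaller than the kernel")
  padded <- pad_reflect(block, k, l)
  out <- matrix(0, nrow(block), ncol(block))
  nr <- nrow(block); nc <- ncol(block)
  for (dr in -k:k) {
    for (dc in -l:l) {
      out <- out + kernel$weights[dr + k + 1, dc + l + 1] *
        padded[(1 + k + dr):(nr + k + dr), (1 + l + dc):(nc + l + dc)]
    }
  }
  out
}

#' Binarize a vessel-filter response into a vessel mask
#'
#' The response is rescaled to \[0, 1\] and thresholded by Otsu's method;
#' 8-connected components smaller than `min_area` are removed (fragments of
#' that size are noise, not vessels). A flat response yields an empty mask.
#'
#' The truncated 7x7 LoG kernel has a markedly negative weight sum, so its
#' response carries a `-c * I(x)` baseline on top of the second-derivative
#' line term: dark vessels on a fundus green channel end up in the *upper*
#' tail of the signed response, bright vessels (angiography) in the lower
#' tail. `polarity` selects which tail is thresholded: `"dark"` (default,
#' fundus), `"bright"`, or `"abs"` (response magnitude, appropriate only
#' for kernels with a near-zero sum).
#'
#' @param response LoG response matrix.
#' @param min_area minimum component area (px) kept, default 30.
#' @param polarity `"dark"`, `"bright"` or `"abs"`; see Details.
#' @return object of class `vessel_mask` with fields `mask` (binary
#'   matrix) and `min_area_used`.
#' @export
vessel_mask_from_response <- function(response, min_area = 30,
                                      polarity = c("dark", "bright", "abs")) {
  polarity <- match.arg(polarity)
  if (!all(is.finite(response))) stop("response must be finite")
  a <- switch(polarity, dark = response, bright = -response,
              abs = abs(response))
  rng <- range(a)
  if (diff(rng) < .Machine$double.eps) {
    mask <- matrix(0, nrow(response), ncol(response))
  } else {
    a <- (a - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(a), range = c(0, 1))
    # Otsu assumes a bimodal histogram; on a block containing few vessel
    # pixels the between-class split lands inside the background texture
    # and floods the mask, so it is floored by a robust outlier bound
    thr <- max(thr, stats::median(a) + 3 * stats::mad(a))
    mask <- (a > thr) * 1
    lab <- label8(mask)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], nbins = max(lab))
      keep <- which(areas >= min_area)
      mask <- (lab %in% keep) * 1
      dim(mask) <- dim(response)
    }
  }
  structure(list(mask = as_binary(mask), min_area_used = as.integer(min_area)),
            class = "vessel_mask")
}

#' Inpaint the vessel mask out of the angiography block
#'
#' The (dilated) vessel pixels are replaced by values propagated from the
#' surrounding background: an onion-peel pass assigns each masked pixel the
#' mean of its already-known 8-neighbors, from the mask boundary inward,
#' followed by a few Jacobi smoothing sweeps restricted to the mask so the
#' fill is close to harmonic. Pixels outside the dilated mask are returned
#' bit-exactly unchanged.
#'
#' @param angio_block angiography ROI block (the raw observation).
#' @param vessels a [vessel_mask_from_response()] result, or a binary
#'   matrix.
#' @param dilate_radius dilation radius (px) applied to the mask before
#'   filling, to cover partial-volume vessel borders. Default 2.
#' @param smooth_iter Jacobi sweeps after the propagation pass.
#' @return list (class `inpainted_block`) with `G_P` (the inpainted block)
#'   and `mask_used` (the dilated mask actually filled).
#' @export
inpaint_vessels <- function(angio_block, vessels, dilate_radius = 2,
                            smooth_iter = 25) {
  mask <- if (inherits(vessels, "vessel_mask")) vessels$mask else vessels
  if (!all(dim(mask) == dim(angio_block)))
    stop("mask and block shapes differ")
  if (dilate_radius > 0 && any(mask > 0)) {
    brush <- EBImage::makeBrush(2 * dilate_radius + 1, "disc")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush))
    mask <- matrix(as.numeric(mask > 0), nrow(angio_block), ncol(angio_block))
  }
  if (all(mask > 0)) stop("vessel mask covers the whole block")
  gp <- angio_block
  if (any(mask > 0)) {
    known <- mask == 0
    vals <- gp
    vals[!known] <- 0
    # onion peel: repeatedly assign boundary pixels the mean of known
    # 8-neighbors
    while (!all(known)) {
      ksum <- matrix(0, nrow(gp), ncol(gp))
      kcnt <- matrix(0, nrow(gp), ncol(gp))
      for (i in seq_len(nrow(NEIGH8))) {
        ksum <- ksum + shift_mat(vals * known, NEIGH8[i, 1], NEIGH8[i, 2])
        kcnt <- kcnt + shift_mat(known * 1, NEIGH8[i, 1], NEIGH8[i, 2])
      }
      newly <- !known & kcnt > 0
      if (!any(newly)) break  # isolated region (cannot happen with finite mask)
      vals[newly] <- ksum[newly] / kcnt[newly]
      known <- known | newly
    }
    # Jacobi sweeps toward a harmonic fill, masked pixels only
    inside <- mask > 0
    for (it in seq_len(smooth_iter)) {
      nsum <- matrix(0, nrow(gp), ncol(gp))
      for (i in seq_len(nrow(NEIGH8)))
        nsum <- nsum + shift_mat(vals, NEIGH8[i, 1], NEIGH8[i, 2], fill = NA)
      ncnt <- matrix(8, nrow(gp), ncol(gp))
      # border pixels have fewer neighbors; recompute their counts
      ncnt[1, ] <- ncnt[nrow(gp), ] <- 5
      ncnt[, 1] <- ncnt[, ncol(gp)] <- 5
      ncnt[c(1, nrow(gp)), c(1, ncol(gp))] <- 3
      nmean <- nsum / ncnt
      vals[inside] <- ifelse(is.na(nmean[inside]), vals[inside], nmean[inside])
    }
    gp[inside] <- clamp01(vals[inside])
  }
  structure(list(G_P = gp, mask_used = as_binary(mask)),
            class = "inpainted_block")
}
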