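#' Specification of a synthetic multimodal fundus phantom
#'
#' Describes the simulated eye: a smooth low-rank background, a handful of
#' curvilinear vessels (bright in angiography, dark in the fundus green
#' channel), and compact Gaussian leakage blobs present only in
#' angiography, plus i.i.d. Gaussian sensor noise. Blob centers are kept in
#' a central "macular" disc — CSCR leakage sits near the macula — and away
#' from vessels so the half-maximum ground truth is unambiguous.
#'
#' @param height,width phantom dimensions in pixels.
#' @param n_vessels number of vessel strokes.
#' @param vessel_width_px length-2 range of stroke widths (px).
#' @param vessel_contrast intensity offset of vessels (+ in angiography,
#'   - in the fundus green channel).
#' @param n_blobs number of leakage blobs; a length-2 range draws uniformly.
#' @param blob_sigma_px length-2 range of blob Gaussian sigmas (px).
#' @param blob_peak_contrast peak intensity of each blob above background.
#' @param background_level mean background intensity of the angiography.
#' @param background_smoothness amplitude of the smooth background
#'   variation (each of the separable profiles varies by about this much).
#' @param n_background_profiles number of separable (rank-one) profiles
#'   summed into the background; bounds its numerical rank.
#' @param macula_radius_px radius of the disc (centred mid-image) holding
#'   the blob centers; keeps the clinician's ROI compact.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param rng_seed integer seed; the phantom is a deterministic function of
#'   this object's fields.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 512, width = 512,
                         n_vessels = 6,
                         vessel_width_px = c(3, 7),
                         vessel_contrast = 0.30,
                         n_blobs = c(2, 4),
                         blob_sigma_px = c(6, 12),
                         blob_peak_contrast = 0.45,
                         background_level = 0.35,
                         background_smoothness = 0.04,
                         n_background_profiles = 3,
                         macula_radius_px = 70,
                         noise_sigma = 0.02,
                         rng_seed = 1L) {
  if (height < 64 || width < 64) stop("phantom must be at least 64 x 64")
  if (any(n_blobs < 0) || n_vessels < 0)
    stop("vessel and blob counts must be >= 0")
  if (blob_peak_contrast <= 0 || blob_peak_contrast > 1)
    stop("`blob_peak_contrast` must lie in (0, 1]")
  if (max(n_blobs) > 0 &&
      macula_radius_px + 3 * max(blob_sigma_px) > min(height, width) / 2)
    stop("blobs do not fit inside the image with a 3-sigma margin")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_vessels = as.integer(n_vessels),
    vessel_width_px = vessel_width_px, vessel_contrast = vessel_contrast,
    n_blobs = as.integer(n_blobs), blob_sigma_px = blob_sigma_px,
    blob_peak_contrast = blob_peak_contrast,
    background_level = background_level,
    background_smoothness = background_smoothness,
    n_background_profiles = as.integer(n_background_profiles),
    macula_radius_px = macula_radius_px,
    noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

# smooth 1-D profile: low-order random cosine mixture on [0, 1]
smooth_profile <- function(n, amplitude) {
  t <- seq(0, 1, length.out = n)
  w <- rnorm(3) / (1:3)
  w <- w / max(sum(abs(w)), 1e-12)
  phi <- runif(3, 0, 2 * pi)
  amplitude * (w[1] * cos(pi * t + phi[1]) +
               w[2] * cos(2 * pi * t + phi[2]) +
               w[3] * cos(3 * pi * t + phi[3]))
}

# render one random smooth vessel stroke; returns list(field, mask)
render_vessel <- function(h, w, width_px) {
  # random walk in heading from a random border point through the image
  side <- sample(4, 1)
  pos <- switch(side,
    c(1, runif(1, 1, w)),
    c(h, runif(1, 1, w)),
    c(runif(1, 1, h), 1),
    c(runif(1, 1, h), w)
  )
  ang <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.5, 0.5)
  n_steps <- round(1.4 * max(h, w))
  pts <- matrix(NA_real_, n_steps, 2)
  for (i in seq_len(n_steps)) {
    pts[i, ] <- pos
    ang <- ang + rnorm(1, 0, 0.06)
    pos <- pos + c(sin(ang), cos(ang))
    if (pos[1] < -width_px || pos[1] > h + width_px ||
        pos[2] < -width_px || pos[2] > w + width_px) {
      pts <- pts[seq_len(i), , drop = FALSE]
      break
    }
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  mask <- matrix(0, h, w)
  half <- width_px / 2
  rad <- ceiling(half)
  for (i in seq_len(nrow(pts))) {
    r0 <- max(1, floor(pts[i, 1] - rad)); r1 <- min(h, ceiling(pts[i, 1] + rad))
    c0 <- max(1, floor(pts[i, 2] - rad)); c1 <- min(w, ceiling(pts[i, 2] + rad))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pts[i, 1])^2, (cc - pts[i, 2])^2, "+")
    sub <- mask[rr, cc]
    sub[d2 <= half^2] <- 1
    mask[rr, cc] <- sub
  }
  # soften the stroke profile slightly so edges are not a hard step
  field <- gaussian_blur(mask, sigma = 0.8)
  field <- field / max(field, 1e-12)
  list(field = field, mask = mask)
}

# separable Gaussian blur (reflect-padded)
gaussian_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  xp <- pad_reflect(x, r, r)
  # rows then columns, valid part
  xr <- apply(xp, 2, function(col) as.vector(stats::filter(col, g, sides = 2)))
  xr <- xr[(r + 1):(nrow(xp) - r), , drop = FALSE]
  xc <- t(apply(xr, 1, function(row) as.vector(stats::filter(row, g, sides = 2))))
  xc[, (r + 1):(ncol(xp) - r), drop = FALSE]
}

#' Generate a registered synthetic angiography / fundus pair
#'
#' The angiography is `background + vessels + blobs + noise`; the fundus
#' green channel carries the same vessels dark on its own smooth background
#' (leakage is a fluorescein phenomenon and appears only in angiography).
#' The ground-truth blob mask is the half-maximum support of the noiseless
#' blob field. Deterministic given `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `pair` (an [image_pair()]) and `truth`
#'   (class `phantom_truth`: `blob_mask`, `blob_centers` (0-based rows/cols),
#'   `blob_sigmas`, `vessel_mask`, and the noiseless `background` field).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, {
    h <- spec$height; w <- spec$width

    # low-rank background: sum of separable smooth profiles
    bg <- matrix(0, h, w)
    for (i in seq_len(spec$n_background_profiles)) {
      base <- if (i == 1) spec$background_level else 0
      u <- base + smooth_profile(h, spec$background_smoothness)
      v <- 1 + smooth_profile(w, spec$background_smoothness)
      bg <- bg + outer(u, v)
    }

    # vessels
    vessel_field <- matrix(0, h, w)
    vessel_mask <- matrix(0, h, w)
    for (i in seq_len(spec$n_vessels)) {
      width_px <- runif(1, spec$vessel_width_px[1], spec$vessel_width_px[2])
      vs <- render_vessel(h, w, width_px)
      vessel_field <- pmax(vessel_field, vs$field)
      vessel_mask <- pmax(vessel_mask, vs$mask)
    }

    # leakage blobs: centers in the macular disc, clear of vessels
    n_blobs <- if (length(spec$n_blobs) > 1)
      sample(seq(spec$n_blobs[1], spec$n_blobs[2]), 1) else spec$n_blobs
    ctr <- c(h, w) / 2
    centers <- matrix(NA_real_, 0, 2)
    sigmas <- numeric(0)
    attempts <- 0
    while (nrow(centers) < n_blobs && attempts < 2000) {
      attempts <- attempts + 1
      sg <- runif(1, spec$blob_sigma_px[1], spec$blob_sigma_px[2])
      u <- runif(1); th <- runif(1, 0, 2 * pi)
      rr <- spec$macula_radius_px * sqrt(u)
      cand <- ctr + rr * c(sin(th), cos(th))
      # separation from other blobs and clearance from vessels
      relax <- max(0, attempts - 1000) / 1000  # degrade gracefully if crowded
      sep_ok <- nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >
              (1 - relax / 2) * 2.2 * (sigmas + sg))
      clear <- (2 - relax) * sg
      rs <- max(1, floor(cand[1] - clear)):min(h, ceiling(cand[1] + clear))
      cs <- max(1, floor(cand[2] - clear)):min(w, ceiling(cand[2] + clear))
      ves_ok <- sum(vessel_mask[rs, cs]) == 0
      if (sep_ok && ves_ok) {
        centers <- rbind(centers, cand)
        sigmas <- c(sigmas, sg)
      }
    }
    if (nrow(centers) < n_blobs)
      stop("could not place ", n_blobs, " blobs; spec too crowded")

    blob_field <- matrix(0, h, w)
    blob_mask <- matrix(0, h, w)
    rows <- seq_len(h); cols <- seq_len(w)
    for (i in seq_len(nrow(centers))) {
      d2 <- outer((rows - centers[i, 1])^2, (cols - centers[i, 2])^2, "+")
      bump <- spec$blob_peak_contrast * exp(-d2 / (2 * sigmas[i]^2))
      blob_field <- blob_field + bump
      blob_mask[bump > spec$blob_peak_contrast / 2] <- 1
    }

    angio_clean <- bg + spec$vessel_contrast * vessel_field + blob_field
    fundus_g_clean <- bg + 0.10 - spec$vessel_contrast * vessel_field

    noise_a <- matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    noise_f <- matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    angio <- clamp01(angio_clean + noise_a)
    fundus_g <- clamp01(fundus_g_clean + noise_f)
    fundus <- array(0, c(h, w, 3))
    fundus[, , 1] <- clamp01(fundus_g + 0.25)   # red-dominant, as in practice
    fundus[, , 2] <- fundus_g
    fundus[, , 3] <- clamp01(0.5 * fundus_g)

    truth <- structure(list(
      blob_mask = as_binary(blob_mask),
      blob_centers = centers - 1,              # 0-based
      blob_sigmas = sigmas,
      vessel_mask = as_binary(vessel_mask),
      background = bg,
      n_blobs = nrow(centers)
    ), class = "phantom_truth")

    list(pair = image_pair(angio, fundus, "synthetic phantom"), truth = truth)
  })
}

#' Generate a batch of phantoms with consecutive seeds
#'
#' @param n batch size (>= 1).
#' @param spec base [phantom_spec()]; phantom `i` uses seed
#'   `spec$rng_seed + i - 1`.
#' @return list of `n` results of [generate_phantom()].
#' @export
phantom_batch <- function(n, spec) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(i) {
    s <- spec
    s$rng_seed <- spec$rng_seed + i
    generate_phantom(s)
  })
}

#' Emulate the clinician's ROI box around the phantom leakage area
#'
#' Takes the bounding box of the true blob mask, pads it, and enforces a
#' minimum side length so the box is valid for the patch decomposition —
#' the synthetic counterpart of the manual box-selection step.
#'
#' @param truth a `phantom_truth`.
#' @param shape `(H, W)` of the phantom.
#' @param margin padding around the blob bounding box (px).
#' @param min_side minimum box side (px); must be >= the patch size.
#' @return an [roi_box()].
#' @export
phantom_roi_box <- function(truth, shape, margin = 30, min_side = 100) {
  idx <- which(truth$blob_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {  # no blobs: central box
    r0 <- floor((shape[1] - min_side) / 2); c0 <- floor((shape[2] - min_side) / 2)
    return(roi_box(r0, c0, r0 + min_side, c0 + min_side))
  }
  r0 <- max(0, min(idx[, 1]) - 1 - margin)
  c0 <- max(0, min(idx[, 2]) - 1 - margin)
  r1 <- min(shape[1], max(idx[, 1]) + margin)
  c1 <- min(shape[2], max(idx[, 2]) + margin)
  # grow to the minimum side, keeping inside the image
  grow <- function(a0, a1, lim) {
    need <- min_side - (a1 - a0)
    if (need > 0) {
      a0 <- max(0, a0 - ceiling(need / 2))
      a1 <- min(lim, a0 + max(min_side, a1 - a0))
      a0 <- max(0, a1 - max(min_side, a1 - a0))
    }
    c(a0, a1)
  }
  r <- grow(r0, r1, shape[1]); cc <- grow(c0, c1, shape[2])
  roi_box(r[1], cc[1], r[2], cc[2])
}

#' Write a phantom to disk (PNG pair + truth masks + JSON sidecar)
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  png::writePNG(phantom$pair$angiography, p("angio.png"))
  png::writePNG(phantom$pair$color_fundus, p("fundus.png"))
  save_mask(phantom$truth$blob_mask, p("truth_blobs.png"))
  save_mask(phantom$truth$vessel_mask, p("truth_vessels.png"))
  sidecar <- list(
    blob_centers = unname(apply(phantom$truth$blob_centers, 1, as.numeric,
                                simplify = FALSE)),
    blob_sigmas = phantom$truth$blob_sigmas,
    n_blobs = phantom$truth$n_blobs
  )
  jsonlite::write_json(sidecar, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(vapply(c("angio.png", "fundus.png", "truth_blobs.png",
                     "truth_vessels.png", "truth.json"), p, character(1)))
}
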