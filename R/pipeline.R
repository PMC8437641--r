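VARIANTS <- c("LR", "LRM", "LRM_to_R", "LRM_plus_R")

normalize_variant <- function(variant) {
  v <- gsub("[+]", "_plus_", variant)
  v <- gsub("->|→", "_to_", v)
  v <- gsub("__", "_", toupper(v))
  v <- sub("^LRM_PLUS_R$", "LRM_plus_R", v)
  v <- sub("^LRM_TO_R$", "LRM_to_R", v)
  if (!v %in% VARIANTS)
    stop("unknown variant: ", variant,
         " (use LR, LRM, LRM_to_R or LRM_plus_R)")
  v
}

# shared stages: ROI -> (vessel inpainting) -> decomposition -> regions
lrsd_stage <- function(pair, box, config, multimodal) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  validate_box(box, dim(pair$angiography), config$patch_size)
  roi <- extract_roi(pair, box)
  I_a <- roi$angio_block
  timings["roi"] <- tic() - t0

  vessel_mask <- NULL
  if (multimodal) {
    t0 <- tic()
    I_c <- preprocess_fundus(roi$fundus_block, config$clahe_clip,
                             config$clahe_tiles)
    kern <- build_log_kernel(config$log_sigma, config$log_half_size,
                             config$log_half_size)
    resp <- log_filter(I_c, kern)
    vm <- vessel_mask_from_response(resp, config$vessel_min_area)
    vessel_mask <- vm$mask
    inp <- inpaint_vessels(I_a, vm, config$vessel_dilate_radius)
    G_P <- inp$G_P
    timings["vessel_inpainting"] <- tic() - t0
  } else {
    G_P <- I_a
  }

  t0 <- tic()
  dec <- decompose_block(G_P, config)
  timings["lrsd"] <- tic() - t0

  t0 <- tic()
  bin <- binarize_sparse_map(dec$S_map, config$sparse_binarize_rule)
  bset <- extract_regions(bin, config$region_min_area, config$max_regions)
  timings["regions"] <- tic() - t0

  list(I_a = I_a, G_P = G_P, vessel_mask = vessel_mask, S_map = dec$S_map,
       L_map = dec$L_map, solver = dec$result, noise_sd = dec$noise_sd,
       bset = bset, timings = timings, box = box,
       image_shape = dim(pair$angiography))
}

finish_variant <- function(ctx, config, variant, threshold) {
  grown <- list()
  n_failed <- 0L
  if (variant %in% c("LRM_to_R", "LRM_plus_R")) {
    cap <- config$max_growth_fraction * length(ctx$I_a)
    for (r in ctx$bset$regions) {
      seed <- extract_seed(r, ctx$S_map, ctx$I_a)
      g <- region_grow(ctx$I_a, seed, threshold)
      # a leakage blob never fills the clinician's box: a growth this large
      # means the admission band reached the background, i.e. the growth
      # failed, and it must not overwrite the baseline segmentation
      if (sum(g$R_pd) > cap) {
        n_failed <- n_failed + 1L
        next
      }
      grown[[length(grown) + 1]] <- g
    }
  }
  final_mask <- switch(variant,
    LR = ,
    LRM = ctx$bset$S_P,
    LRM_to_R = {
      m <- matrix(0, nrow(ctx$I_a), ncol(ctx$I_a))
      for (g in grown) m <- pmax(m, g$R_pd)
      as_binary(m)
    },
    LRM_plus_R = fuse_masks(ctx$bset, grown)
  )
  if (variant %in% c("LR", "LRM")) {
    set <- ctx$bset
  } else {
    set <- extract_regions(final_mask, config$region_min_area,
                           config$max_regions)
  }
  # attach seeds to regions (the argmax of the sparse map inside each)
  set$regions <- lapply(set$regions, function(r) {
    if (sum(r$mask_roi * (ctx$S_map > 0)) > 0) {
      sp <- extract_seed(r, ctx$S_map, ctx$I_a)
      r$seed <- sp$position
    } else {
      r$seed <- r$centroid  # grown-only region without sparse support
    }
    r
  })
  set <- restore_to_full_frame(set, ctx$box, ctx$image_shape)
  list(set = set, grown = grown, final_mask = final_mask,
       n_failed_growths = n_failed)
}

#' Run the full segmentation pipeline on an image pair
#'
#' Dispatches the four ablation variants:
#' \describe{
#'   \item{`LR`}{decomposition of the raw angiography ROI (no vessel
#'     inpainting, the fundus image is unused).}
#'   \item{`LRM`}{the multimodal baseline: vessel inpainting, then
#'     decomposition.}
#'   \item{`LRM_to_R`}{region growing seeded by the baseline; the grown
#'     regions alone form the mask.}
#'   \item{`LRM_plus_R`}{the joint framework: union of the baseline and
#'     grown masks.}
#' }
#'
#' @param pair an [image_pair()].
#' @param box an [roi_box()]; both sides must reach the patch size.
#' @param config a [run_config()].
#' @param variant one of `"LR"`, `"LRM"`, `"LRM_to_R"`, `"LRM_plus_R"`
#'   (aliases `"lrm+r"`, `"lrm->r"` accepted).
#' @return list (class `cscr_run`) with `biomarkers` (a full-frame
#'   `biomarker_set`), `report` (provenance: config, variant, timings,
#'   solver diagnostics, region table) and `maps` (`S_map`, `L_map`,
#'   `G_P`, `vessel_mask`, ROI-frame `final_mask`).
#' @export
run_pipeline <- function(pair, box, config = run_config(),
                         variant = "LRM_plus_R") {
  variant <- normalize_variant(variant)
  ctx <- lrsd_stage(pair, box, config, multimodal = variant != "LR")
  fin <- finish_variant(ctx, config, variant, config$threshold)
  report <- build_report(ctx, fin, config, variant)
  structure(list(
    biomarkers = fin$set,
    report = report,
    maps = list(S_map = ctx$S_map, L_map = ctx$L_map, G_P = ctx$G_P,
                vessel_mask = ctx$vessel_mask, final_mask = fin$final_mask)
  ), class = "cscr_run")
}

#' @export
print.cscr_run <- function(x, ...) {
  cat(sprintf("<cscr_run> variant=%s, %d region(s)\n",
              x$report$variant, length(x$biomarkers$regions)))
  print(x$biomarkers)
  invisible(x)
}

build_report <- function(ctx, fin, config, variant, threshold = NULL) {
  regions <- lapply(fin$set$regions, function(r) {
    idx <- which(r$mask_roi > 0, arr.ind = TRUE)
    list(label = r$label, area_px = r$area_px,
         centroid = round(r$centroid, 2),
         seed = if (!is.null(r$seed)) round(r$seed, 2),
         bbox_full = c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]),
                       max(idx[, 2])) - 1 +
           c(ctx$box$r0, ctx$box$c0, ctx$box$r0, ctx$box$c0))
  })
  cfg <- unclass(config)
  cfg$max_regions <- if (is.finite(cfg$max_regions))
    cfg$max_regions else "all"
  list(
    tool = "cscrseg",
    variant = variant,
    threshold = threshold %||% config$threshold,
    box = unclass(ctx$box)[c("r0", "c0", "r1", "c1")],
    config = cfg,
    noise_sd_estimate = signif(ctx$noise_sd, 6),
    solver = list(iterations = ctx$solver$iterations,
                  converged = ctx$solver$converged,
                  lambda = signif(ctx$solver$lambda_used, 6),
                  mu = signif(ctx$solver$mu_used, 6),
                  rank_L = ctx$solver$rank_L,
                  nnz_S = ctx$solver$nnz_S),
    timings_sec = as.list(round(ctx$timings, 3)),
    n_failed_growths = fin$n_failed_growths,
    n_regions = length(fin$set$regions),
    regions = regions
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a pipeline report as JSON
#'
#' @param report the `report` element of a [run_pipeline()] result.
#' @param path JSON path.
#' @return `save_report` the path, invisibly; `load_report` the report
#'   list.
#' @export
save_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_report
#' @export
load_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' Run region growing and fusion over a threshold grid
#'
#' The decomposition stages are computed once and shared; only the
#' growing/fusion stage is repeated per threshold, mirroring how the
#' threshold sweep of the ablation experiments is organised.
#'
#' @param pair an [image_pair()].
#' @param box an [roi_box()].
#' @param config a [run_config()] (its `threshold` field is ignored).
#' @param T_grid numeric vector of thresholds in (0, 1); must be
#'   non-empty.
#' @param variant `"LRM_to_R"` or `"LRM_plus_R"`.
#' @return named list (one element per threshold, names `"T0.10"` etc.) of
#'   full-frame `biomarker_set`s, with the shared stage context in
#'   attribute `"context"`.
#' @export
run_threshold_grid <- function(pair, box, config = run_config(),
                               T_grid = threshold_grid(),
                               variant = "LRM_plus_R") {
  if (length(T_grid) == 0) stop("empty threshold grid")
  variant <- normalize_variant(variant)
  if (!variant %in% c("LRM_to_R", "LRM_plus_R"))
    stop("the threshold grid applies to the region-growing variants only")
  ctx <- lrsd_stage(pair, box, config, multimodal = TRUE)
  out <- lapply(T_grid, function(Tv) {
    fin <- finish_variant(ctx, config, variant, Tv)
    fin$set
  })
  names(out) <- sprintf("T%.2f", T_grid)
  attr(out, "context") <- ctx
  out
}
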