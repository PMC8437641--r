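#' Pixelwise confusion counts between a predicted and a true mask
#'
#' @param pred,truth binary matrices of identical shape (full frame or ROI
#'   frame, as long as both agree).
#' @param scope `"full"` counts every pixel; `"roi"` restricts the count to
#'   the footprint of `box` (both masks must then be full-frame). Counting
#'   over the ROI avoids the huge true-negative inflation a full frame
#'   produces.
#' @param box required when `scope = "roi"`: the [roi_box()].
#' @return object of class `confusion_counts`: `TP`, `FN`, `TN`, `FP`,
#'   `n_pixels`, `scope`.
#' @export
confusion <- function(pred, truth, scope = c("roi", "full"), box = NULL) {
  scope <- match.arg(scope)
  if (!all(dim(pred) == dim(truth)))
    stop("mask shapes differ")
  if (!is_binary_matrix(as_binary(pred * 1)) ||
      !is_binary_matrix(as_binary(truth * 1)))
    stop("masks must be binary")
  if (scope == "roi") {
    if (is.null(box)) stop("`box` is required for scope = \"roi\"")
    validate_box(box, dim(pred))
    rows <- (box$r0 + 1):box$r1
    cols <- (box$c0 + 1):box$c1
    pred <- pred[rows, cols, drop = FALSE]
    truth <- truth[rows, cols, drop = FALSE]
  }
  p <- pred > 0
  t <- truth > 0
  structure(list(
    TP = sum(p & t), FN = sum(!p & t), TN = sum(!p & !t), FP = sum(p & !t),
    n_pixels = length(p), scope = scope
  ), class = "confusion_counts")
}

#' Segmentation indicators from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, F1 `2TP/(2TP+FN+FP)`, accuracy
#' `(TP+TN)/(TP+FN+TN+FP)`, specificity `TN/(TN+FP)`. A zero denominator
#' yields `NA` (the undefined marker), never an error; such values are
#' excluded from batch averages.
#'
#' @param counts a [confusion()] result.
#' @return object of class `metric_report` with the four indicators in
#'   \[0, 1\] (or `NA`).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, structure(list(
    sensitivity = safe_div(TP, TP + FN),
    f1_score = safe_div(2 * TP, 2 * TP + FN + FP),
    accuracy = safe_div(TP + TN, TP + FN + TN + FP),
    specificity = safe_div(TN, TN + FP)
  ), class = "metric_report"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "sensitivity=%.4f  F1=%.4f  accuracy=%.4f  specificity=%.4f\n",
    x$sensitivity, x$f1_score, x$accuracy, x$specificity))
  invisible(x)
}

#' Score one pipeline run against a phantom ground truth
#'
#' @param run a [run_pipeline()] result (or a full-frame `biomarker_set`).
#' @param truth a `phantom_truth` (its `blob_mask` is the reference).
#' @param scope,box see [confusion()]; defaults to the run's own box.
#' @return a [metrics()] report.
#' @export
score_run <- function(run, truth, scope = "roi", box = NULL) {
  set <- if (inherits(run, "cscr_run")) run$biomarkers else run
  if (is.null(set$full_mask)) stop("biomarker set has no full-frame mask")
  box <- box %||% set$box
  metrics(confusion(set$full_mask, truth$blob_mask, scope = scope, box = box))
}

#' Ablation study over phantoms, variants and the threshold grid
#'
#' Runs all four variants on each phantom. The decomposition stages of
#' `LRM`, `LRM_to_R` and `LRM_plus_R` are shared, and `LR`/`LRM` do not
#' depend on the threshold, so their rows are constant across `T_grid`.
#'
#' @param phantoms list of [generate_phantom()] results (a
#'   [phantom_batch()]).
#' @param T_grid thresholds for the region-growing variants.
#' @param config a [run_config()].
#' @param scope metric scope, `"roi"` (default) or `"full"`.
#' @param margin,min_side forwarded to [phantom_roi_box()].
#' @return list with `per_image` (data frame: phantom, variant, threshold,
#'   four indicators) and `summary` (mean over phantoms per variant x
#'   threshold; `NA` metrics are excluded, with the exclusion count in
#'   `n_undefined`).
#' @export
ablation_study <- function(phantoms, T_grid = threshold_grid(),
                           config = run_config(), scope = "roi",
                           margin = 30, min_side = 100) {
  stopifnot(length(phantoms) >= 1, length(T_grid) >= 1)
  rows <- list()
  add_row <- function(i, variant, Tv, rep) {
    rows[[length(rows) + 1]] <<- data.frame(
      phantom = i, variant = variant, threshold = Tv,
      sensitivity = rep$sensitivity, f1_score = rep$f1_score,
      accuracy = rep$accuracy, specificity = rep$specificity
    )
  }
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    box <- phantom_roi_box(ph$truth, dim(ph$pair$angiography),
                           margin = margin, min_side = min_side)
    score_mask <- function(final_mask) {
      bs <- extract_regions(final_mask, config$region_min_area,
                            config$max_regions)
      bs <- restore_to_full_frame(bs, box, dim(ph$pair$angiography))
      metrics(confusion(bs$full_mask, ph$truth$blob_mask,
                        scope = scope, box = box))
    }
    ctx_lr <- lrsd_stage(ph$pair, box, config, multimodal = FALSE)
    ctx_lrm <- lrsd_stage(ph$pair, box, config, multimodal = TRUE)
    rep_lr <- score_mask(ctx_lr$bset$S_P)
    rep_lrm <- score_mask(ctx_lrm$bset$S_P)
    for (Tv in T_grid) {
      add_row(i, "LR", Tv, rep_lr)
      add_row(i, "LRM", Tv, rep_lrm)
      for (variant in c("LRM_to_R", "LRM_plus_R")) {
        fin <- finish_variant(ctx_lrm, config, variant, Tv)
        add_row(i, variant, Tv, score_mask(fin$final_mask))
      }
    }
  }
  per_image <- do.call(rbind, rows)
  per_image$variant <- factor(per_image$variant, levels = VARIANTS)
  metric_cols <- c("sensitivity", "f1_score", "accuracy", "specificity")
  groups <- split(per_image,
                  list(per_image$variant, per_image$threshold), drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    out <- data.frame(variant = g$variant[1], threshold = g$threshold[1])
    for (mc in metric_cols) out[[mc]] <- mean(g[[mc]], na.rm = TRUE)
    out$n_images <- nrow(g)
    out$n_undefined <- sum(!stats::complete.cases(g[metric_cols]))
    out
  }))
  summary <- summary[order(summary$variant, summary$threshold), ]
  rownames(summary) <- NULL
  list(per_image = per_image, summary = summary)
}
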