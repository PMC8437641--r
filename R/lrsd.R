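#' Build the patch-image matrix of a block
#'
#' Columns are row-major vectorizations of `patch_size x patch_size`
#' sliding windows. Origins run over rows and columns `0, stride,
#' 2*stride, ...`; when the last regular origin does not reach
#' `dim - patch_size`, one extra origin is clamped there so every pixel is
#' covered. Columns are ordered row-major over origins. Stacking patches
#' raises the rank deficiency of the smooth background and the relative
#' sparsity of compact targets, which is what makes the low-rank + sparse
#' split effective on small lesions.
#'
#' @param block numeric matrix, both sides >= `patch_size`.
#' @param patch_size patch side (default 50).
#' @param stride sliding step (default 10).
#' @return object of class `patch_image`: `matrix`
#'   (`patch_size^2 x n_patches`), `origins` (0-based two-column matrix),
#'   `patch_size`, `stride`, `source_shape`.
#' @export
build_patch_image <- function(block, patch_size = 50, stride = 10) {
  h <- nrow(block); w <- ncol(block)
  if (h < patch_size || w < patch_size)
    stop("block smaller than the patch size")
  origins_1d <- function(dim) {
    o <- seq(0L, dim - patch_size, by = stride)
    if (o[length(o)] != dim - patch_size) o <- c(o, dim - patch_size)
    as.integer(o)
  }
  ro <- origins_1d(h)
  co <- origins_1d(w)
  origins <- cbind(
    row = rep(ro, each = length(co)),
    col = rep(co, times = length(ro))
  )
  n <- nrow(origins)
  # row-major vectorization of each patch
  m <- matrix(0, patch_size^2, n)
  for (j in seq_len(n)) {
    p <- block[origins[j, 1] + seq_len(patch_size),
               origins[j, 2] + seq_len(patch_size), drop = FALSE]
    m[, j] <- as.vector(t(p))
  }
  structure(list(matrix = m, origins = origins,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 source_shape = c(h, w)),
            class = "patch_image")
}

# linear pixel indices (column-major in the source block) addressed by each
# patch-matrix entry
patch_pixel_index <- function(meta) {
  ps <- meta$patch_size
  h <- meta$source_shape[1]
  # row-major within-patch offsets
  within_r <- rep(seq_len(ps) - 1L, each = ps)
  within_c <- rep(seq_len(ps) - 1L, times = ps)
  idx <- matrix(0L, ps^2, nrow(meta$origins))
  for (j in seq_len(nrow(meta$origins))) {
    rr <- meta$origins[j, 1] + within_r + 1L
    cc <- meta$origins[j, 2] + within_c + 1L
    idx[, j] <- rr + (cc - 1L) * h
  }
  idx
}

#' Fold a patch-image matrix back to a block
#'
#' Each pixel is covered by several overlapping patches; its value is the
#' median (default) or mean of all covering entries. The median keeps a
#' pixel's reconstruction unchanged when a minority of covering patches
#' disagree, the usual robustness argument in patch-image target detection.
#'
#' @param matrix patch-image matrix (same shape as `meta$matrix`).
#' @param meta a [build_patch_image()] result carrying the geometry.
#' @param aggregate `"median"` or `"mean"`.
#' @return matrix of shape `meta$source_shape`.
#' @export
reconstruct_from_patch_image <- function(matrix, meta,
                                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(meta, "patch_image"))
  if (!all(dim(matrix) == dim(meta$matrix)))
    stop("matrix shape does not match the patch geometry")
  idx <- as.vector(patch_pixel_index(meta))
  vals <- as.vector(matrix)
  n_px <- prod(meta$source_shape)
  cnt <- tabulate(idx, nbins = n_px)
  if (aggregate == "mean") {
    sums <- as.vector(rowsum(vals, idx, reorder = TRUE))
    out <- sums / cnt
  } else {
    # per-pixel median without splitting: sort by (pixel, value), then take
    # the middle element(s) of each pixel's contiguous run
    o <- order(idx, vals)
    sv <- vals[o]
    end <- cumsum(cnt)
    start <- end - cnt + 1L
    out <- (sv[start + (cnt - 1L) %/% 2L] + sv[start + cnt %/% 2L]) / 2
  }
  base::matrix(out, meta$source_shape[1], meta$source_shape[2])
}

#' Elementwise soft-thresholding (l1 proximal operator)
#'
#' `sign(x) * pmax(|x| - tau, 0)`.
#'
#' @param x numeric array.
#' @param tau threshold (>= 0).
#' @return array of the same shape.
#' @export
soft_threshold <- function(x, tau) {
  if (tau < 0) stop("`tau` must be >= 0")
  sign(x) * pmax(abs(x) - tau, 0)
}

# economy singular triplet machinery: for tall (or wide) matrices the
# Gram-matrix eigendecomposition is much cheaper than LAPACK's full SVD and
# accurate to ~1e-13 on the singular values retained after thresholding.
svt_internal <- function(X, tau) {
  p <- nrow(X); q <- ncol(X)
  if (min(p, q) <= 64 || max(p, q) / min(p, q) < 2) {
    s <- svd(X)
    keep <- s$d > tau
    if (!any(keep)) {
      return(list(Y = matrix(0, p, q), nuclear = 0, rank = 0L,
                  sv = pmax(s$d - tau, 0)))
    }
    d2 <- s$d[keep] - tau
    Y <- s$u[, keep, drop = FALSE] %*% (d2 * t(s$v[, keep, drop = FALSE]))
    return(list(Y = Y, nuclear = sum(d2), rank = sum(keep),
                sv = pmax(s$d - tau, 0)))
  }
  tall <- p >= q
  A <- if (tall) X else t(X)
  e <- eigen(crossprod(A), symmetric = TRUE)
  sv <- sqrt(pmax(e$values, 0))
  keep <- sv > tau
  if (!any(keep)) {
    return(list(Y = matrix(0, p, q), nuclear = 0, rank = 0L,
                sv = pmax(sv - tau, 0)))
  }
  V <- e$vectors[, keep, drop = FALSE]
  f <- (sv[keep] - tau) / sv[keep]
  Y <- A %*% (V %*% (f * t(V)))
  if (!tall) Y <- t(Y)
  list(Y = Y, nuclear = sum(sv[keep] - tau), rank = sum(keep),
       sv = pmax(sv - tau, 0))
}

#' Singular value thresholding (nuclear-norm proximal operator)
#'
#' Computes `U * max(S - tau, 0) * t(V)` for the SVD `X = U S t(V)`.
#'
#' @param X numeric matrix.
#' @param tau threshold (>= 0).
#' @return matrix of the same shape.
#' @export
singular_value_threshold <- function(X, tau) {
  if (tau < 0) stop("`tau` must be >= 0")
  svt_internal(X, tau)$Y
}

spectral_norm <- function(X) {
  A <- if (nrow(X) >= ncol(X)) X else t(X)
  sqrt(max(0, eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values[1]))
}

#' Stable low-rank + sparse decomposition by accelerated proximal gradient
#'
#' Minimizes
#' \deqn{\|L\|_* + \lambda \|S\|_1 + \frac{1}{2\mu}\|M - L - S\|_F^2}
#' over `(L, S)`, the convex relaxation of splitting an observation into
#' low-rank background `L`, sparse targets `S` and dense noise
#' `N = M - L - S`. The smooth term has Lipschitz gradient `2/mu`, so each
#' iteration takes a singular-value-threshold step on `L` and a
#' soft-threshold step on `S` at an extrapolated (Nesterov momentum) point.
#' A monotone safeguard keeps the accepted objective non-increasing once
#' `mu` is fixed. In `"auto"` mode `mu` follows the usual continuation
#' schedule: start at `0.1 * ||M||_2` and shrink by 0.9 per iteration down
#' to `mu_floor`.
#'
#' @param M observation matrix (e.g. a patch image).
#' @param lambda_weight sparsity weight; `"auto"` is `1 / sqrt(max(p, q))`.
#' @param mu noise weight; `"auto"` enables continuation, a number fixes it
#'   (no continuation).
#' @param mu_floor continuation floor; `"auto"` uses `1e-4 * ||M||_2`.
#'   Larger floors suppress more of a dense noise component into `N`; see
#'   [decompose_block()] for the noise-scaled choice used on images.
#' @param tol stop when the relative change of `(L, S)` falls below this
#'   (and `mu` has reached its floor).
#' @param max_iter iteration cap.
#' @return object of class `lrsd_result`: `L`, `S`, `N`, `lambda_used`,
#'   `mu_used`, `iterations`, `converged`, `objective_trace`, `burn_in`
#'   (first iteration at the final `mu`; the trace is non-increasing from
#'   there on), `rank_L`, `nnz_S`.
#' @export
apg_decompose <- function(M, lambda_weight = "auto", mu = "auto",
                          mu_floor = "auto", tol = 1e-6, max_iter = 500) {
  if (!all(is.finite(M))) stop("`M` must be finite")
  if (tol <= 0) stop("`tol` must be positive")
  p <- nrow(M); q <- ncol(M)
  lambda <- if (identical(lambda_weight, "auto")) 1 / sqrt(max(p, q))
            else lambda_weight
  norm2 <- spectral_norm(M)
  if (norm2 == 0) {
    Z <- matrix(0, p, q)
    return(structure(list(L = Z, S = Z, N = Z, lambda_used = lambda,
                          mu_used = if (is.numeric(mu)) mu else 0,
                          iterations = 0L, converged = TRUE,
                          objective_trace = numeric(0), burn_in = 0L,
                          rank_L = 0L, nnz_S = 0L),
                     class = "lrsd_result"))
  }
  continuation <- identical(mu, "auto")
  mu_f <- if (continuation) {
    if (identical(mu_floor, "auto")) 1e-4 * norm2 else mu_floor
  } else mu
  mu_k <- if (continuation) max(0.1 * norm2, mu_f) else mu

  # monotone FISTA (accepted iterate never increases the objective once mu
  # is fixed; extrapolation still runs through the candidate, so progress
  # does not stall on rejection)
  Z <- matrix(0, p, q)
  xL <- xLp <- Z; xS <- xSp <- Z     # accepted iterates
  yL <- yS <- Z                       # extrapolation point
  zL <- zS <- Z                       # prox candidates
  t_k <- 1
  obj_prev <- Inf
  trace <- numeric(0)
  burn_in <- if (continuation && mu_k > mu_f) NA_integer_ else 1L
  prev_at_floor <- !continuation || mu_k <= mu_f * (1 + 1e-12)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    R <- M - yL - yS
    sv <- svt_internal(yL + 0.5 * R, mu_k / 2)
    zL_new <- sv$Y
    zS_new <- soft_threshold(yS + 0.5 * R, lambda * mu_k / 2)
    obj_z <- sv$nuclear + lambda * sum(abs(zS_new)) +
      sum((M - zL_new - zS_new)^2) / (2 * mu_k)
    at_floor <- mu_k <= mu_f * (1 + 1e-12)
    delta_z <- sqrt(sum((zL_new - zL)^2) + sum((zS_new - zS)^2))
    base <- max(1, sqrt(sum(zL^2) + sum(zS^2)))
    zL <- zL_new; zS <- zS_new
    # monotone acceptance: comparison is only meaningful between
    # iterations evaluated at the same (floor) mu
    xLp <- xL; xSp <- xS
    if (at_floor && prev_at_floor && obj_z > obj_prev) {
      obj_acc <- obj_prev                    # keep previous accepted x
    } else {
      xL <- zL; xS <- zS; obj_acc <- obj_z
    }
    if (at_floor && is.na(burn_in)) burn_in <- iter
    trace <- c(trace, obj_acc)
    obj_prev <- obj_acc
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    yL <- xL + (t_k / t_new) * (zL - xL) + ((t_k - 1) / t_new) * (xL - xLp)
    yS <- xS + (t_k / t_new) * (zS - xS) + ((t_k - 1) / t_new) * (xS - xSp)
    t_k <- t_new
    if (at_floor && prev_at_floor && delta_z / base < tol) {
      converged <- TRUE
      break
    }
    prev_at_floor <- at_floor
    if (continuation) mu_k <- max(0.9 * mu_k, mu_f)
  }
  L <- xL; S <- xS
  N <- M - L - S
  structure(list(L = L, S = S, N = N, lambda_used = lambda, mu_used = mu_k,
                 iterations = iter, converged = converged,
                 objective_trace = trace,
                 burn_in = if (is.na(burn_in)) iter else burn_in,
                 rank_L = qr(L)$rank, nnz_S = sum(S != 0)),
            class = "lrsd_result")
}

#' @export
print.lrsd_result <- function(x, ...) {
  cat(sprintf(
    "<lrsd_result> %d x %d | rank(L)=%d nnz(S)=%d | %d iters (%s), lambda=%.4g mu=%.4g\n",
    nrow(x$L), ncol(x$L), x$rank_L, x$nnz_S, x$iterations,
    if (x$converged) "converged" else "max_iter", x$lambda_used, x$mu_used))
  invisible(x)
}

# Immerkaer fast noise-variance estimate: the 3x3 Laplacian-difference
# operator annihilates locally planar structure, leaving ~ noise only.
estimate_noise_sd <- function(block) {
  if (nrow(block) < 3 || ncol(block) < 3) return(0)
  D <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  nr <- nrow(block); nc <- ncol(block)
  acc <- matrix(0, nr - 2, nc - 2)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + D[dr + 1, dc + 1] *
      block[(1 + dr):(nr - 2 + dr), (1 + dc):(nc - 2 + dc)]
  }
  sqrt(pi / 2) * mean(abs(acc)) / 6
}

#' Decompose an ROI block into low-rank and sparse maps
#'
#' Full composition of the decomposition stage: build the patch image,
#' solve the stable decomposition with [apg_decompose()], and fold `L` and
#' `S` back to image frame. The sparse map is clipped at 0 from below:
#' CSCR leakage is hyperfluorescent, so only positive sparse responses are
#' targets. In `"auto"` mode the continuation floor of `mu` is scaled to
#' the image noise level (estimated by the Immerkaer operator) so that the
#' effective per-iteration soft threshold `lambda * mu / 2` sits at about
#' 2 noise standard deviations — dense noise then lands in `N`, not `S`,
#' while the faint margins of genuine targets still survive in `S`.
#'
#' @param G_P the (inpainted) angiography block.
#' @param config a [run_config()].
#' @return list with `L_map`, `S_map` (matrices, `S_map >= 0`), `result`
#'   (the [apg_decompose()] output), `patch_image` (geometry), and
#'   `noise_sd` (the estimate used).
#' @export
decompose_block <- function(G_P, config = run_config()) {
  pm <- build_patch_image(G_P, config$patch_size, config$stride)
  lambda <- if (identical(config$lambda_weight, "auto"))
    1 / sqrt(max(dim(pm$matrix))) else config$lambda_weight
  sigma_hat <- estimate_noise_sd(G_P)
  mu_floor <- if (identical(config$mu_weight, "auto")) {
    max(2 * 2 * sigma_hat / lambda, 1e-4 * spectral_norm(pm$matrix))
  } else "auto"
  res <- apg_decompose(
    pm$matrix,
    lambda_weight = lambda,
    mu = if (identical(config$mu_weight, "auto")) "auto" else config$mu_weight,
    mu_floor = mu_floor,
    tol = config$apg_tolerance,
    max_iter = config$apg_max_iter
  )
  L_map <- reconstruct_from_patch_image(res$L, pm, config$aggregate)
  S_map <- reconstruct_from_patch_image(res$S, pm, config$aggregate)
  S_map <- pmax(S_map, 0)
  list(L_map = L_map, S_map = S_map, result = res, patch_image = pm,
       noise_sd = sigma_hat)
}
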