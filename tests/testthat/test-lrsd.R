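test_that("patch-image origins enumerate the sliding grid with boundary clamping", {
  set.seed(1)
  X <- matrix(runif(100 * 100), 100, 100)
  pm <- build_patch_image(X, 50, 10)
  expect_equal(nrow(pm$origins), 36)          # ((100-50)/10 + 1)^2
  expect_equal(dim(pm$matrix), c(2500, 36))
  # first column is the row-major vectorized top-left patch
  expect_equal(pm$matrix[, 1], as.vector(t(X[1:50, 1:50])))

  # 105-row block: origins 0,10,...,50 plus the clamped 55
  X2 <- matrix(runif(105 * 50), 105, 50)
  pm2 <- build_patch_image(X2, 50, 10)
  expect_equal(unique(pm2$origins[, 1]), c(0L, 10L, 20L, 30L, 40L, 50L, 55L))
  expect_equal(unique(pm2$origins[, 2]), 0L)

  # exactly one patch for a patch-sized block
  X3 <- matrix(runif(2500), 50, 50)
  pm3 <- build_patch_image(X3, 50, 10)
  expect_equal(ncol(pm3$matrix), 1)
  expect_equal(pm3$matrix[, 1], as.vector(t(X3)))
  expect_error(build_patch_image(matrix(0, 40, 60), 50, 10), "smaller")
})

test_that("reconstruction inverts patching exactly and the median resists outliers", {
  set.seed(2)
  shapes <- list(c(50, 50), c(60, 60), c(73, 61), c(105, 55), c(50, 92))
  for (sh in shapes) {
    X <- matrix(runif(prod(sh)), sh[1], sh[2])
    pm <- build_patch_image(X, 50, 10)
    expect_identical(reconstruct_from_patch_image(pm$matrix, pm), X)
    expect_identical(reconstruct_from_patch_image(pm$matrix, pm, "mean"), X)
  }

  X <- matrix(runif(70 * 70), 70, 70)
  pm <- build_patch_image(X, 50, 10)
  expect_equal(reconstruct_from_patch_image(matrix(0, nrow(pm$matrix),
                                                   ncol(pm$matrix)), pm),
               matrix(0, 70, 70))

  # perturb one covering patch at a pixel covered by >= 3 patches: the
  # median reconstruction there must not move
  idx <- cscrseg:::patch_pixel_index(pm)
  px <- 35 + (35 - 1) * 70  # center pixel, column-major linear index
  covering <- which(idx == px, arr.ind = TRUE)
  expect_gte(nrow(covering), 3)
  pert <- pm$matrix
  pert[covering[1, 1], covering[1, 2]] <- pert[covering[1, 1], covering[1, 2]] + 1
  rec <- reconstruct_from_patch_image(pert, pm)
  expect_equal(rec[35, 35], X[35, 35])
  # direct median over the covering multiset agrees
  vals <- pert[idx == px]
  expect_equal(rec[35, 35], median(vals))
})

test_that("soft thresholding and singular value thresholding follow their formulas", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-3, 0.2, 5), 0), c(-3, 0.2, 5))
  expect_equal(soft_threshold(c(-2, 2), 0.5), c(-1.5, 1.5))
  expect_error(soft_threshold(1, -1), ">= 0")

  D <- diag(c(5, 2, 0.5))
  expect_equal(singular_value_threshold(D, 1), diag(c(4, 1, 0)),
               tolerance = 1e-8)
  set.seed(3)
  X <- matrix(rnorm(120), 12, 10)
  expect_equal(singular_value_threshold(X, 0), X, tolerance = 1e-8)
  expect_equal(singular_value_threshold(X, 2 * svd(X)$d[1]),
               matrix(0, 12, 10))
  # tall-matrix (Gram) path agrees with the direct small-matrix path
  T1 <- matrix(rnorm(400 * 30), 400, 30)
  s <- svd(T1)
  direct <- s$u %*% (pmax(s$d - 1, 0) * t(s$v))
  expect_equal(singular_value_threshold(T1, 1), direct, tolerance = 1e-8)
})

test_that("the APG solver recovers a planted low-rank + sparse split", {
  expect_identical(apg_decompose(matrix(0, 30, 20))$L, matrix(0, 30, 20))

  set.seed(0)
  u <- rnorm(400); u <- u / sqrt(sum(u^2))
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  L0 <- outer(u, v)
  S0 <- matrix(0, 400, 30)
  S0[sample(400 * 30, 600)] <- 1
  res <- apg_decompose(L0 + S0, tol = 1e-7, max_iter = 500)
  expect_lte(sqrt(sum((res$L - L0)^2)) / sqrt(sum(L0^2)), 0.05)
  expect_lte(sqrt(sum((res$S - S0)^2)) / sqrt(sum(S0^2)), 0.05)
  expect_true(res$converged)

  # consistency: L + S + N == M exactly by construction of N
  M <- L0 + S0
  expect_equal(res$L + res$S + res$N, M, tolerance = 1e-12)
  expect_error(apg_decompose(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("the objective trace is non-increasing after burn-in on assorted inputs", {
  set.seed(6)
  for (k in 1:4) {
    M <- matrix(rnorm(600), 30, 20) + 2 * outer(rnorm(30), rnorm(20))
    res <- apg_decompose(M, tol = 1e-8, max_iter = 400)
    tr <- res$objective_trace
    post <- tr[res$burn_in:length(tr)]
    expect_true(all(diff(post) <= 1e-9 * max(abs(post))))
  }
})

test_that("increasing lambda never increases the sparse support", {
  set.seed(7)
  M <- matrix(rnorm(800), 40, 20) + outer(rnorm(40), rnorm(20))
  nnz <- vapply(c(0.05, 0.1, 0.2, 0.4), function(lam) {
    apg_decompose(M, lambda_weight = lam, mu = 0.5, tol = 1e-7,
                  max_iter = 800)$nnz_S
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("accelerated and unaccelerated solvers reach the same optimum", {
  set.seed(42)
  for (k in 1:3) {
    M <- matrix(rnorm(400), 20, 20) + outer(rnorm(20), rnorm(20))
    lambda <- 1 / sqrt(20)
    o <- ista_lrsd(M, lambda, mu = 0.5)
    a <- apg_decompose(M, lambda, mu = 0.5, tol = 1e-9, max_iter = 4000)
    relerr <- sqrt(sum((a$L - o$L)^2)) / max(sqrt(sum(o$L^2)), 1e-12)
    expect_lt(relerr, 1e-3)
  }
})

test_that("decompose_block localizes a blob and reproduces a clean background", {
  # separable noise-free background, no blobs: L_map reproduces it
  set.seed(9)
  bg <- outer(0.4 + 0.05 * sin(seq(0, 3, length.out = 70)),
              1 + 0.1 * cos(seq(0, 2, length.out = 70)))
  cfg <- run_config(patch_size = 30, stride = 10)
  dec0 <- decompose_block(bg, cfg)
  expect_lte(sqrt(sum((dec0$L_map - bg)^2)) / sqrt(sum(bg^2)), 0.05)

  # background + one Gaussian blob: the sparse map peaks at the blob
  rows <- seq_len(70)
  d2 <- outer((rows - 30)^2, (rows - 42)^2, "+")
  blob <- 0.45 * exp(-d2 / (2 * 6^2))
  noisy <- clamp_ref(bg + blob + matrix(rnorm(4900, 0, 0.02), 70, 70))
  dec <- decompose_block(noisy, cfg)
  expect_true(all(dec$S_map >= 0))
  am <- which(dec$S_map == max(dec$S_map), arr.ind = TRUE)[1, ]
  expect_lte(sqrt((am[1] - 30)^2 + (am[2] - 42)^2), 3)

  # patch-domain consistency at the solver solution
  r <- dec$result
  relres <- sqrt(sum((dec$patch_image$matrix - r$L - r$S - r$N)^2)) /
    sqrt(sum(dec$patch_image$matrix^2))
  expect_lt(relres, 10 * cfg$apg_tolerance)
})
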