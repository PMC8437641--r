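test_that("LoG kernel matches the closed form, its symmetries and zero set", {
  k <- build_log_kernel(sigma = 3, k = 3, l = 3)
  expect_equal(dim(k$weights), c(7, 7))
  # center value -1/(pi sigma^4) = -1/(81 pi)
  expect_equal(k$weights[4, 4], -1 / (81 * pi), tolerance = 1e-12)
  # direct evaluation at every grid point
  for (r in -3:3) for (cc in -3:3) {
    expected <- -(1 / (pi * 81)) * (1 - (r^2 + cc^2) / 18) *
      exp(-(r^2 + cc^2) / 18)
    expect_equal(k$weights[r + 4, cc + 4], expected, tolerance = 1e-14)
  }
  # 4-fold symmetry
  expect_equal(k$weights, k$weights[7:1, ])
  expect_equal(k$weights, t(k$weights))
  # zero where r^2 + c^2 = 2 sigma^2 (sigma = 1: r^2+c^2 = 2)
  k1 <- build_log_kernel(sigma = 1, k = 2, l = 2)
  expect_equal(k1$weights[3 + 1, 3 + 1], 0, tolerance = 1e-12)  # (1,1)
  expect_error(build_log_kernel(sigma = 0), "positive")
})

test_that("LoG filtering is the stated correlation: impulse, constant, linear", {
  kern <- build_log_kernel(3, 3, 3)
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- 1
  resp <- log_filter(imp, kern)
  # impulse response reproduces the (symmetric) kernel around the center
  expect_equal(resp[5:11, 5:11], kern$weights, tolerance = 1e-12)

  cst <- matrix(0.7, 20, 20)
  resp_c <- log_filter(cst, kern)
  expect_equal(resp_c[10, 10], 0.7 * sum(kern$weights), tolerance = 1e-12)

  set.seed(5)
  X <- matrix(runif(400), 20, 20)
  Y <- matrix(runif(400), 20, 20)
  expect_equal(log_filter(2 * X + 3 * Y, kern),
               2 * log_filter(X, kern) + 3 * log_filter(Y, kern),
               tolerance = 1e-10)
  expect_error(log_filter(matrix(0, 5, 5), kern), "smaller")
})

test_that("truncated kernel sum is small against the center weight but nonzero", {
  kern <- build_log_kernel(3, 3, 3)
  s <- sum(kern$weights)
  # the 7x7 support truncates the positive outer ring: the sum is negative
  # and an order of magnitude larger than |center|, which is why the signed
  # response (not its magnitude) separates dark vessels
  expect_lt(s, 0)
  expect_lt(abs(s), 25 * abs(kern$weights[4, 4]))
  # a wide kernel approaches zero-sum
  kw <- build_log_kernel(3, 12, 12)
  expect_lt(abs(sum(kw$weights)), abs(s) / 50)
})

test_that("vessel masks are binarized with small components removed", {
  # constant response -> empty mask, not an error
  vm <- vessel_mask_from_response(matrix(0.3, 40, 40))
  expect_equal(sum(vm$mask), 0)

  # two bright components, areas 10 and 100: only the large one survives
  resp <- matrix(0, 60, 60)
  resp[5:6, 5:9] <- 1        # 10 px
  resp[30:39, 30:39] <- 1    # 100 px
  vm2 <- vessel_mask_from_response(resp, min_area = 30)
  expect_equal(sum(vm2$mask), 100)
  expect_equal(sum(vm2$mask[30:39, 30:39]), 100)
  expect_error(vessel_mask_from_response(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("the LoG stage recovers most of a phantom vessel stroke", {
  ph <- cached("ph_small_21", generate_phantom(small_phantom_spec(21)))
  g <- ph$pair$color_fundus[, , 2]
  block <- array(0, c(dim(g), 3))
  block[, , 2] <- g
  ic <- preprocess_fundus(block)
  resp <- log_filter(ic, build_log_kernel())
  vm <- vessel_mask_from_response(resp, min_area = 30)
  truth <- ph$truth$vessel_mask
  expect_gte(sum(vm$mask * truth) / sum(truth), 0.7)
})

test_that("inpainting obeys its contract", {
  set.seed(8)
  block <- matrix(runif(50 * 50, 0.2, 0.8), 50, 50)

  # empty mask: exact identity
  out <- inpaint_vessels(block, matrix(0, 50, 50))
  expect_identical(out$G_P, block)

  # constant block: fill is the same constant
  cst <- matrix(0.5, 50, 50)
  mask <- matrix(0, 50, 50)
  mask[20:30, 20:30] <- 1
  out2 <- inpaint_vessels(cst, mask, dilate_radius = 0)
  expect_equal(out2$G_P, cst, tolerance = 1e-12)

  # single masked pixel: value within the range of its 8 neighbors
  m1 <- matrix(0, 50, 50)
  m1[25, 25] <- 1
  out3 <- inpaint_vessels(block, m1, dilate_radius = 0)
  nb <- block[24:26, 24:26][-5]
  expect_gte(out3$G_P[25, 25], min(nb))
  expect_lte(out3$G_P[25, 25], max(nb))

  # pixels outside the dilated mask are untouched bit-exactly
  out4 <- inpaint_vessels(block, m1, dilate_radius = 2)
  outside <- out4$mask_used == 0
  expect_identical(out4$G_P[outside], block[outside])

  expect_error(inpaint_vessels(block, matrix(1, 50, 50)), "whole block")
  expect_error(inpaint_vessels(block, matrix(0, 10, 10)), "shapes")
})

test_that("inpainting suppresses bright vessels in the angiography block", {
  ph <- cached("ph_small_21", generate_phantom(small_phantom_spec(21)))
  angio <- ph$pair$angiography
  vm <- list(mask = ph$truth$vessel_mask)
  class(vm) <- "vessel_mask"
  out <- inpaint_vessels(angio, vm, dilate_radius = 2)
  v <- ph$truth$vessel_mask > 0
  expect_lt(max(out$G_P[v]), max(angio[v]))
  expect_lt(mean(out$G_P[v]), mean(angio[v]))
})
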