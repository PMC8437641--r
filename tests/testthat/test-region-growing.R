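test_that("seed extraction takes the sparse-map argmax with deterministic ties", {
  S <- matrix(0, 10, 10)
  mask <- matrix(0, 10, 10)
  mask[3:7, 3:7] <- 1
  S[4, 5] <- 0.9
  region <- list(label = 1, mask_roi = mask)
  angio <- matrix(seq(0, 1, length.out = 100), 10, 10)
  sp <- extract_seed(region, S, angio)
  expect_equal(sp$position, c(3, 4))          # 0-based
  expect_equal(sp$seed_value, angio[4, 5])

  # two equal maxima: smallest row, then smallest column
  S2 <- matrix(0, 10, 10)
  S2[3, 8 + 0] <- 0.5; S2[6, 2] <- 0.5
  mask2 <- matrix(1, 10, 10)
  sp2 <- extract_seed(list(label = 1, mask_roi = mask2), S2, angio)
  expect_equal(sp2$position, c(2, 7))

  expect_error(extract_seed(list(label = 1, mask_roi = matrix(0, 5, 5)),
                            matrix(0, 5, 5), matrix(0, 5, 5)), "empty")
})

test_that("region growing floods plateaus and respects the admission band", {
  cst <- matrix(0.5, 15, 15)
  g <- region_grow(cst, c(7, 7), 0.1)
  expect_equal(sum(g$R_pd), 225)

  # isolated 3x3 plateau of 1 on zero background, T = 0.1
  blk <- matrix(0, 20, 20)
  blk[9:11, 9:11] <- 1
  g2 <- region_grow(blk, c(9, 9), 0.1)
  expect_equal(sum(g2$R_pd), 9)
  expect_equal(sum(g2$R_pd[9:11, 9:11]), 9)

  # grown region always contains its seed
  expect_equal(g2$R_pd[10, 10], 1)
  expect_error(region_grow(blk, c(25, 3), 0.1), "outside")
  expect_error(region_grow(blk, c(3, 3), 1.2), "threshold")
})

test_that("region growing equals the exhaustive flood-fill oracle", {
  set.seed(13)
  for (i in 1:10) {
    blk <- matrix(runif(400), 20, 20)
    seed0 <- c(sample(20, 1) - 1, sample(20, 1) - 1)
    for (Tv in c(0.10, 0.14, 0.18)) {
      g <- region_grow(blk, seed0, Tv)
      oracle <- flood_fill_oracle(blk, seed0 + 1, Tv)
      expect_identical(g$R_pd, oracle)
    }
  }
})

test_that("grown regions are monotone in the threshold", {
  set.seed(14)
  blk <- matrix(runif(900, 0.2, 0.8), 30, 30)
  seed0 <- c(14, 14)
  prev <- matrix(0, 30, 30)
  for (Tv in c(0.10, 0.12, 0.14, 0.16, 0.18)) {
    g <- region_grow(blk, seed0, Tv)
    expect_true(all(g$R_pd >= prev))
    prev <- g$R_pd
  }
})

test_that("fusion is the union and can only add pixels", {
  S_P <- matrix(0, 20, 20)
  S_P[3:6, 3:6] <- 1
  bs <- extract_regions(S_P, min_area = 5)

  # empty grown list: fusion returns the decomposition mask
  expect_identical(fuse_masks(bs, list()), bs$S_P)

  # disjoint masks: areas add
  g1 <- structure(list(R_pd = matrix(0, 20, 20)), class = "grown_region")
  g1$R_pd[12:14, 12:16] <- 1
  fused <- fuse_masks(bs, list(g1))
  expect_equal(sum(fused), 16 + 15)
  expect_true(all(fused >= bs$S_P))

  # superset grown region: fusion equals the grown mask
  g2 <- structure(list(R_pd = matrix(0, 20, 20)), class = "grown_region")
  g2$R_pd[2:8, 2:8] <- 1
  expect_identical(fuse_masks(bs, list(g2)), g2$R_pd)

  g3 <- structure(list(R_pd = matrix(0, 5, 5)), class = "grown_region")
  expect_error(fuse_masks(bs, list(g3)), "shape")
})

test_that("the threshold grid shares the decomposition and matches single runs", {
  ph <- cached("ph_small_21", generate_phantom(small_phantom_spec(21)))
  box <- phantom_roi_box(ph$truth, dim(ph$pair$angiography))
  cfg <- run_config(threshold = 0.18)

  grid <- cached("grid_small_21",
                 run_threshold_grid(ph$pair, box, cfg,
                                    T_grid = c(0.10, 0.14, 0.18),
                                    variant = "LRM_plus_R"))
  single <- run_pipeline(ph$pair, box, cfg, "LRM_plus_R")
  expect_identical(grid[["T0.18"]]$full_mask, single$biomarkers$full_mask)

  # fused masks are monotone in T (seed-relative admission)
  expect_true(all(grid[["T0.14"]]$full_mask >= grid[["T0.10"]]$full_mask))
  expect_true(all(grid[["T0.18"]]$full_mask >= grid[["T0.14"]]$full_mask))

  expect_error(run_threshold_grid(ph$pair, box, cfg, numeric(0)), "empty")
  expect_error(run_threshold_grid(ph$pair, box, cfg, 0.18, variant = "LR"),
               "region-growing")
})
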