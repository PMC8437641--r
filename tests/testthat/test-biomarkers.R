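test_that("sparse-map binarization rules behave as specified", {
  z <- matrix(0, 20, 20)
  expect_equal(sum(binarize_sparse_map(z)), 0)
  expect_equal(sum(binarize_sparse_map(z, "nonzero")), 0)

  plateau <- matrix(0, 20, 20)
  plateau[5:8, 5:8] <- 1
  expect_identical(binarize_sparse_map(plateau, "nonzero"), plateau)

  # adaptive rule on a Gaussian bump: a connected set containing the argmax
  d2 <- outer((1:40 - 20)^2, (1:40 - 25)^2, "+")
  bump <- exp(-d2 / (2 * 4^2))
  m <- binarize_sparse_map(bump, "adaptive")
  expect_equal(m[20, 25], 1)
  expect_equal(count_components_oracle(m), 1)
  # direct evaluation of the rule
  pos <- bump[bump > 0]
  expect_identical(m, (bump > mean(pos) + 2 * sd(pos)) * 1)

  expect_error(binarize_sparse_map(matrix(-1, 3, 3)), "non-negative")
})

test_that("region extraction labels, filters, sorts and caps", {
  m <- matrix(0, 40, 40)
  m[2:5, 2:4] <- 1          # area 12
  m[20:27, 20:24] <- 1      # area 40
  m[35, 35] <- 1            # area 1 (dropped at min_area 5)
  bs <- extract_regions(m, min_area = 5)
  expect_equal(length(bs$regions), 2)
  expect_equal(vapply(bs$regions, `[[`, numeric(1), "area_px"), c(40, 12))
  expect_equal(bs$regions[[1]]$label, 1)
  expect_equal(sum(bs$S_P), 52)

  # area-3 component dropped
  m2 <- matrix(0, 10, 10)
  m2[2:4, 2] <- 1
  expect_equal(length(extract_regions(m2, min_area = 5)$regions), 0)

  # max_regions keeps the largest
  m3 <- matrix(0, 80, 60)
  sizes <- c(6, 8, 10, 12, 14, 16)
  for (i in seq_along(sizes)) m3[seq_len(sizes[i]), i * 5] <- 1
  bs3 <- extract_regions(m3, min_area = 5, max_regions = 3)
  expect_equal(vapply(bs3$regions, `[[`, numeric(1), "area_px"),
               c(16, 14, 12))

  # each region is one 8-connected component; diagonal pixels join
  m4 <- matrix(0, 10, 10)
  m4[2, 2] <- 1; m4[3, 3] <- 1; m4[4, 4] <- 1; m4[5, 5] <- 1; m4[6, 6] <- 1
  bs4 <- extract_regions(m4, min_area = 5)
  expect_equal(length(bs4$regions), 1)
  expect_equal(bs4$regions[[1]]$area_px, 5)

  expect_error(extract_regions(matrix(0.3, 5, 5)), "binary")
})

test_that("re-extracting regions from the union mask is idempotent", {
  set.seed(12)
  m <- matrix(rbinom(900, 1, 0.1), 30, 30) * 1
  bs <- extract_regions(m, min_area = 5)
  bs2 <- extract_regions(bs$S_P, min_area = 5)
  expect_identical(bs$S_P, bs2$S_P)
  expect_equal(vapply(bs$regions, `[[`, numeric(1), "area_px"),
               vapply(bs2$regions, `[[`, numeric(1), "area_px"))
})

test_that("full-frame restoration translates masks and coordinates", {
  m <- matrix(0, 30, 30)
  m[6:10, 6:10] <- 1
  bs <- extract_regions(m, min_area = 5)

  # box at the origin: plain zero-padding
  bs0 <- restore_to_full_frame(bs, roi_box(0, 0, 30, 30), c(80, 80))
  expect_equal(bs0$full_mask[1:30, 1:30], bs$S_P)
  expect_equal(sum(bs0$full_mask), sum(bs$S_P))

  # offset box: centroid shifts by (r0, c0)
  bs1 <- restore_to_full_frame(bs, roi_box(40, 25, 70, 55), c(100, 100))
  expect_equal(sum(bs1$full_mask), sum(bs$S_P))
  expect_equal(bs1$regions[[1]]$centroid_full,
               bs1$regions[[1]]$centroid + c(40, 25))
  expect_equal(sum(bs1$full_mask[41:70, 26:55]), sum(bs$S_P))
  expect_equal(sum(bs1$full_mask) - sum(bs1$full_mask[41:70, 26:55]), 0)

  # empty set: all-zero full mask
  empty <- extract_regions(matrix(0, 30, 30))
  bs2 <- restore_to_full_frame(empty, roi_box(0, 0, 30, 30), c(50, 50))
  expect_equal(sum(bs2$full_mask), 0)

  expect_error(restore_to_full_frame(bs, roi_box(0, 0, 20, 30), c(50, 50)),
               "shape")
})
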