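test_that("a single three-cell vertex is found within 2 px", {
  fs <- field_spec(128, 128, 3)
  tess <- tessellation_from_points(rbind(c(30, 30), c(90, 35), c(60, 100)),
                                   fs)
  img <- render_border_channel(tess, render_params(noise_sd = 0))
  det <- geometric_detector(img)
  expect_equal(nrow(det), 1)
  d <- sqrt((det$x - tess$vertices$x)^2 + (det$y - tess$vertices$y)^2)
  expect_lt(d, 2)
})

test_that("a blank image yields an empty junction set", {
  expect_equal(nrow(geometric_detector(matrix(0, 64, 64))), 0)
  expect_equal(nrow(geometric_detector(matrix(0.5, 64, 64))), 0)
})

test_that("noiseless dense monolayers are detected with high recall and precision", {
  tess <- generate_tessellation(field_spec(512, 512, 100, rng_seed = 21))
  img <- render_border_channel(tess, render_params(noise_sd = 0))
  det <- geometric_detector(img)
  m <- match_junctions(det, tess$vertices, radius = 3)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("greedy matching pairs each truth junction at most once", {
  det <- junction_set(c(10, 11, 50), c(10, 10, 50))
  tru <- junction_set(c(10.4, 50), c(10, 50))
  m <- match_junctions(det, tru, radius = 3)
  expect_equal(m$n_matched, 2)
  expect_equal(sort(m$pairs[, 2]), c(1, 2))
  # the nearer detection (index 1) takes the shared truth junction
  expect_true(all(m$pairs[m$pairs[, 2] == 1, 1] == 1))
})

test_that("watershed splitting separates well-separated and merged bumps", {
  g <- function(cx, cy) {
    d2 <- outer((0:63 - cy)^2, (0:63 - cx)^2, "+")
    exp(-d2 / (2 * 2.5^2))
  }
  # two well-separated bumps
  m1 <- pmin(g(16, 16) + g(48, 48), 1)
  r1 <- binarize_and_split(m1, 0.5)
  expect_equal(nrow(r1$junctions), 2)
  ord <- order(r1$junctions$x)
  expect_lt(max(abs(r1$junctions$x[ord] - c(16, 48))), 1.01)
  # single bump
  expect_equal(nrow(binarize_and_split(g(32, 32), 0.5)$junctions), 1)
  # 8-shaped merged pair, centres 8 px apart, split into two regions
  m2 <- pmin(g(28, 32) + g(36, 32), 1)
  fg <- m2 > 0.5
  expect_equal(max(tjperm:::cpp_label8(fg)), 1)  # genuinely merged
  r2 <- binarize_and_split(m2, 0.5)
  expect_equal(nrow(r2$junctions), 2)
  ord <- order(r2$junctions$x)
  expect_lt(abs(r2$junctions$x[ord][1] - 28), 2)
  expect_lt(abs(r2$junctions$x[ord][2] - 36), 2)
  # uniform-size map: one radius-3 disk per centroid
  expect_equal(max(tjperm:::cpp_label8(r2$binary_map > 0)), 2)
  expect_true(sum(r2$binary_map) <= 2 * 29 && sum(r2$binary_map) > 40)
})

test_that("empty probability maps give empty junction sets", {
  r <- binarize_and_split(matrix(0.1, 32, 32), 0.5)
  expect_equal(nrow(r$junctions), 0)
  expect_true(all(r$binary_map == 0))
})

test_that("end-to-end geometric detection is 90-degree rotation invariant", {
  sim <- fixture_sim()
  det <- geometric_detector(sim$border)
  det_r <- geometric_detector(rot90m(sim$border))
  # rot90m maps (x, y) -> (H-1-y, x); invert: x = y', y = H-1-x'
  back <- junction_set(det_r$y, 255 - det_r$x)
  m <- match_junctions(back, det, radius = 1)
  expect_equal(m$n_matched, nrow(det))
  expect_equal(nrow(back), nrow(det))
})
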