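test_that("constant images yield an empty adaptive-threshold foreground", {
  expect_false(any(adaptive_threshold(matrix(0.3, 64, 64))))
  expect_false(any(adaptive_threshold(matrix(0, 64, 64))))
})

test_that("a single bright pixel on zero background is foreground", {
  img <- matrix(0, 64, 64); img[32, 32] <- 0.9
  fg <- adaptive_threshold(img, threshold_params(sensitivity = 0.9))
  expect_true(fg[32, 32])
})

test_that("thresholding covers spot half-max support and spares background", {
  # analytic spot field: background 0.1, three spots peak 0.8, sigma 2
  img <- matrix(0.1, 256, 256)
  ctr <- rbind(c(60, 60), c(150, 90), c(90, 200))
  for (i in 1:3) {
    d2 <- outer((0:255 - ctr[i, 2])^2, (0:255 - ctr[i, 1])^2, "+")
    img <- img + 0.7 * exp(-d2 / (2 * 2^2))
  }
  fg <- adaptive_threshold(img)
  halfmax <- matrix(FALSE, 256, 256)
  for (i in 1:3) {
    d2 <- outer((0:255 - ctr[i, 2])^2, (0:255 - ctr[i, 1])^2, "+")
    halfmax <- halfmax | d2 <= 2 * 2^2 * log(2)
  }
  expect_gte(sum(fg & halfmax) / sum(halfmax), 0.9)
  bgpix <- !halfmax
  expect_lt(sum(fg & bgpix) / sum(bgpix), 0.01)
})

test_that("total accumulation sums original pixel values over the foreground", {
  img <- matrix(1, 10, 10)
  expect_equal(total_accumulation(img, matrix(TRUE, 10, 10)), 100)
  expect_equal(total_accumulation(img, matrix(FALSE, 10, 10)), 0)
  set.seed(3)
  img2 <- matrix(runif(100), 10, 10)
  fg <- img2 > 0.5
  expect_equal(total_accumulation(img2, fg), sum(img2[img2 > 0.5]))
})

test_that("spot labelling is 8-connected with per-spot intensities", {
  img <- matrix(0, 16, 16)
  fg <- matrix(FALSE, 16, 16)
  fg[2:3, 2:3] <- TRUE; img[2:3, 2:3] <- 0.5       # 4-px blob
  fg[10:11, 10:11] <- TRUE; img[10:11, 10:11] <- 0.25
  sp <- label_spots(fg, img)
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$n_pixels, c(4, 4))
  expect_setequal(round(sp$integrated_intensity, 6), c(2, 1))
  # diagonal touch merges under 8-connectivity
  fg2 <- matrix(FALSE, 8, 8); fg2[2, 2] <- TRUE; fg2[3, 3] <- TRUE
  expect_equal(nrow(label_spots(fg2, matrix(1, 8, 8))), 1)
  # empty foreground
  expect_equal(nrow(label_spots(matrix(FALSE, 8, 8), matrix(1, 8, 8))), 0)
})

test_that("generated spots are recovered with matching ground-truth integrals", {
  fs <- field_spec(512, 512, 90, rng_seed = 14)
  tess <- generate_tessellation(fs)
  tp <- tracer_params(permeable_fraction = 0.35, background_noise_sd = 0)
  tr <- render_tracer_channel(tess, tp, rng_seed = 15)
  fg <- adaptive_threshold(tr$image)
  sp <- label_spots(fg, tr$image, min_spot_px = 5)
  truth_sp <- tr$truth$spots
  expect_equal(nrow(sp), nrow(truth_sp))
  # each detected spot centroid sits on a generated spot
  for (i in seq_len(nrow(sp))) {
    d <- sqrt((truth_sp$x - sp$x[i])^2 + (truth_sp$y - sp$y[i])^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("the 2-px association rule flags junctions and assigns spots once", {
  jn <- junction_set(c(10, 20), c(10, 10))
  mkspots <- function(px_list, img_dim = c(32, 32)) {
    fg <- matrix(FALSE, img_dim[1], img_dim[2])
    img <- matrix(0, img_dim[1], img_dim[2])
    for (p in px_list) { fg[p[2] + 1, p[1] + 1] <- TRUE
                         img[p[2] + 1, p[1] + 1] <- 1 }
    label_spots(fg, img)
  }
  # pixel at (11, 11): distance sqrt(2) <= 2 -> permeable
  a <- associate(jn, mkspots(list(c(11, 11))))
  expect_true(a$permeable[1]); expect_false(a$permeable[2])
  expect_equal(a$assignment, 1L)
  # pixel at (13, 10): distance 3 from junction 1, 7 from junction 2
  b <- associate(jn, mkspots(list(c(13, 10))))
  expect_false(any(b$permeable))
  expect_true(is.na(b$assignment))
  # one spot within 2 px of both junctions, nearer junction 1:
  # both flagged, spot assigned to junction 1 only
  jn2 <- junction_set(c(10, 14), c(10, 10))
  sp2 <- mkspots(list(c(11, 10), c(12, 10), c(13, 10)))
  c2 <- associate(jn2, sp2)
  expect_true(all(c2$permeable))
  expect_equal(c2$assignment, 1L)
})

test_that("report arithmetic and degenerate cases follow the invariants", {
  jn <- junction_set(seq_len(100), rep(1, 100))
  flags <- rep(c(TRUE, FALSE), c(38, 62))
  sp <- structure(data.frame(label = 1L, x = 1, y = 1, n_pixels = 4L,
                             integrated_intensity = 10),
                  class = c("spot_set", "data.frame"))
  attr(sp, "pixels") <- list(cbind(x = 1, y = 1))
  img <- matrix(0.5, 8, 8); fg <- matrix(FALSE, 8, 8); fg[2, 2] <- TRUE
  rep1 <- compute_report(jn, sp, flags, 1L, img, fg)
  expect_equal(rep1$fraction_permeable, 0.38)
  expect_equal(rep1$n_permeable, 38)
  expect_equal(rep1$mean_per_permeable, 10 / 38)
  # all spots assigned and foreground = spot support -> tj_fraction 1
  img2 <- matrix(0, 8, 8); img2[2, 2] <- 0.5
  fg2 <- img2 > 0
  sp2 <- label_spots(fg2, img2)
  rep2 <- compute_report(jn, sp2, flags, 1L, img2, fg2)
  expect_equal(rep2$tj_fraction, 1)
  expect_lte(rep2$tj_accumulation, rep2$total_accumulation)
  # no junctions -> image rejected
  expect_error(compute_report(junction_set(), sp, logical(), 1L, img, fg),
               "unanalysable")
  # zero permeable -> undefined mean per permeable
  rep3 <- compute_report(jn, sp2, rep(FALSE, 100), NA_integer_, img2, fg2)
  expect_true(is.na(rep3$mean_per_permeable))
  expect_equal(rep3$tj_fraction, 0)
})

test_that("preset images are quantified close to generator truth", {
  fs <- field_spec(512, 512, 100, rng_seed = 33)
  tess <- generate_tessellation(fs)
  tr <- render_tracer_channel(tess, condition_preset("untreated"),
                              rng_seed = 34)
  q <- quantify_image(tr$image, tr$truth$junctions)
  expect_lt(abs(q$report$fraction_permeable -
                tr$truth$n_permeable / nrow(tess$vertices)), 0.05)
  expect_lt(abs(q$report$tj_fraction - tr$truth$realised_share), 0.05)
})

test_that("reports are deterministic and 90-degree rotation invariant", {
  sim <- fixture_sim()
  q1 <- quantify_image(sim$tracer, sim$truth$junctions)
  q2 <- quantify_image(sim$tracer, sim$truth$junctions)
  expect_identical(q1$report, q2$report)
  # rotate tracer and junction set together
  jn <- sim$truth$junctions
  jn_r <- junction_set(255 - jn$y, jn$x, permeable = jn$permeable)
  q3 <- quantify_image(rot90m(sim$tracer), jn_r)
  expect_equal(q1$report$n_permeable, q3$report$n_permeable)
  expect_equal(q1$report$total_accumulation, q3$report$total_accumulation)
  expect_equal(q1$report$tj_accumulation, q3$report$tj_accumulation)
  expect_equal(q1$report$fraction_permeable, q3$report$fraction_permeable)
})
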