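test_that("zero permeable fraction yields a flat background channel", {
  tess <- fixture_sim()$tess
  tp <- tracer_params(permeable_fraction = 0, n_offjunction_spots = 0,
                      background_noise_sd = 0)
  tr <- render_tracer_channel(tess, tp, rng_seed = 1)
  expect_true(all(tr$image == tp$background_level))
  expect_equal(tr$truth$n_permeable, 0)
  expect_equal(sum(tr$truth$junctions$permeable), 0)
})

test_that("all-junction signal gives a realised share of exactly one", {
  tess <- fixture_sim()$tess
  tp <- tracer_params(permeable_fraction = 1, n_offjunction_spots = 0)
  tr <- render_tracer_channel(tess, tp, rng_seed = 2)
  expect_equal(tr$truth$realised_share, 1)
  expect_equal(tr$truth$n_permeable, nrow(tess$vertices))
})

test_that("realised signal share tracks the set-point and the analytic oracle", {
  fs <- field_spec(512, 512, 100, rng_seed = 8)
  tess <- generate_tessellation(fs)
  expect_gte(nrow(tess$vertices), 100)
  tp <- tracer_params(permeable_fraction = 0.5, tj_signal_share = 0.5,
                      background_noise_sd = 0)
  tr <- render_tracer_channel(tess, tp, rng_seed = 3)
  expect_lt(abs(tr$truth$realised_share - 0.5), 0.05)
  # oracle: spot integrals summed directly from amplitudes and sigmas
  # (interior spots only; spots near the field edge are clipped)
  sp <- tr$truth$spots
  interior <- sp$x > 8 & sp$x < 503 & sp$y > 8 & sp$y < 503
  analytic <- sp$amplitude * 2 * pi * sp$sigma^2
  expect_lt(max(abs(sp$integral[interior] - analytic[interior]) /
                analytic[interior]), 0.02)
  # and the noiseless image is background + sum of spots
  expect_equal(sum(tr$image - tp$background_level), sum(sp$integral),
               tolerance = 1e-3)
})

test_that("realised permeable count is exactly round(fraction x n)", {
  tess <- fixture_sim()$tess
  n <- nrow(tess$vertices)
  for (pf in c(0.2, 0.381, 0.73)) {
    tr <- render_tracer_channel(tess, tracer_params(permeable_fraction = pf),
                                rng_seed = 4)
    expect_identical(tr$truth$n_permeable, round(pf * n))
  }
})

test_that("sub-unit expected permeable count warns and yields none", {
  fs <- field_spec(256, 256, 3)
  tess <- tessellation_from_points(rbind(c(60, 60), c(180, 70), c(120, 200)),
                                   fs)
  expect_warning(
    tr <- render_tracer_channel(tess,
                                tracer_params(permeable_fraction = 0.1),
                                rng_seed = 5),
    "zero permeable")
  expect_equal(tr$truth$n_permeable, 0)
})

test_that("off-junction spots keep their distance from junctions", {
  tess <- fixture_sim()$tess
  tr <- render_tracer_channel(tess,
                              tracer_params(tj_signal_share = 0.6),
                              rng_seed = 6)
  sp <- tr$truth$spots
  off <- sp[is.na(sp$junction), ]
  jn <- tr$truth$junctions
  for (i in seq_len(nrow(off)))
    expect_gt(min(sqrt((jn$x - off$x[i])^2 + (jn$y - off$y[i])^2)), 5)
  # junction spots stay within the 2-px association radius by construction
  onj <- sp[!is.na(sp$junction), ]
  d <- sqrt((jn$x[onj$junction] - onj$x)^2 + (jn$y[onj$junction] - onj$y)^2)
  expect_true(all(d <= 1 + 1e-9))
})

test_that("condition presets encode the measured set-points", {
  expect_equal(condition_preset("untreated")$permeable_fraction, 0.381)
  expect_equal(condition_preset("s1p")$permeable_fraction, 0.203)
  th <- condition_preset("thrombin")
  expect_equal(th$permeable_fraction, 0.473)
  expect_equal(th$spot_amplitude_mean /
                 condition_preset("untreated")$spot_amplitude_mean, 1.25)
  expect_equal(condition_preset("multidirectional")$permeable_fraction, 0.407)
  un <- condition_preset("uniaxial")
  expect_equal(un$permeable_fraction, 0.289)
  expect_equal(un$spot_amplitude_mean /
                 condition_preset("multidirectional")$spot_amplitude_mean,
               0.69)
  expect_true(all(condition_presets()$tj_signal_share >= 0.80 &
                  condition_presets()$tj_signal_share <= 0.87))
  expect_error(condition_preset("vegf"), "untreated")
})

test_that("free diffusion radius follows sqrt(4 D t)", {
  expect_equal(free_diffusion_radius(1, 1), 2)
  expect_equal(free_diffusion_radius(0.25, 1), 1)
  # 66-kDa-protein-like diffusivity of 42 um^2/s for 12 min
  expect_equal(free_diffusion_radius(42, 720), 347.8, tolerance = 1e-3)
  expect_error(free_diffusion_radius(0, 1), "positive")
  expect_error(free_diffusion_radius(1, -2), "positive")
})
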