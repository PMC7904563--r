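# Independent pure-R oracles and small shared fixtures.

# Brute-force Voronoi-vertex oracle: enumerate all seed triples, keep
# circumcentres whose circumcircle contains no other seed, merge centres
# closer than `merge_radius` (greedy single linkage), count those inside
# the field. Deliberately coded independently of the package's C++ path.
oracle_vertex_count <- function(seeds, width, height, merge_radius = 2) {
  n <- nrow(seeds)
  trip <- t(utils::combn(n, 3))
  centres <- matrix(NA_real_, 0, 2)
  for (t in seq_len(nrow(trip))) {
    a <- seeds[trip[t, 1], ]; b <- seeds[trip[t, 2], ]; c <- seeds[trip[t, 3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    others <- seeds[-trip[t, ], , drop = FALSE]
    if (nrow(others) > 0 &&
        any((others[, 1] - ux)^2 + (others[, 2] - uy)^2 < r2 - 1e-9)) next
    centres <- rbind(centres, c(ux, uy))
  }
  if (nrow(centres) == 0) return(0L)
  # greedy merge
  used <- rep(FALSE, nrow(centres))
  merged <- matrix(NA_real_, 0, 2)
  for (i in seq_len(nrow(centres))) {
    if (used[i]) next
    grp <- i
    repeat {
      dd <- sqrt((centres[, 1] - mean(centres[grp, 1]))^2 +
                 (centres[, 2] - mean(centres[grp, 2]))^2)
      add <- which(!used & dd <= merge_radius)
      add <- setdiff(add, grp)
      if (length(add) == 0) break
      grp <- c(grp, add)
      used[grp] <- TRUE
    }
    used[grp] <- TRUE
    merged <- rbind(merged, c(mean(centres[grp, 1]), mean(centres[grp, 2])))
  }
  sum(merged[, 1] >= 0 & merged[, 1] <= width - 1 &
      merged[, 2] >= 0 & merged[, 2] <= height - 1)
}

# closed-form pooled-variance two-sample t statistic and p value
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# rotate an image matrix by 90 degrees (counter-clockwise in matrix terms)
rot90m <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# one modest shared tessellation + channels, built once per test run
fixture_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulate_monolayer(field_spec(256, 256, 40, rng_seed = 42))
    sim
  }
})

# a briefly trained small segmenter, built once per test run (~30 s)
fixture_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      td <- make_training_data(n_fields = 2,
                               field = field_spec(256, 256, 40),
                               tile_px = 128, seed = 301)
      cfg <- segmenter_config(input_size_px = 64, n_channels = 6,
                              n_levels = 3, batch_size = 6,
                              learning_rate = 2e-3, rng_seed = 3,
                              n_updates = 120, eval_interval = 20)
      r <- train_segmenter(td$pairs[seq(1, length(td$pairs), by = 2)],
                           td$pairs[c(2, 4)], cfg)
      m <<- restore_checkpoint(r$model, r$state)
    }
    m
  }
})
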