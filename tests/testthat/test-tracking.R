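test_that("well-separated slow particles yield full-length tracks without swaps", {
  frames <- lapply(0:9, function(t) {
    data.frame(id = c("a", "b"),
               x_um = c(1 + 0.1 * t, 8 - 0.1 * t),
               y_um = c(1, 8))
  })
  tr <- link_tracks(frames, max_disp = 1)
  expect_equal(length(unique(tr$track_id)), 2L)
  expect_true(all(table(tr$track_id) == 10))
  # no identity swaps: each track carries a single particle id
  swaps <- tapply(tr$particle_id, tr$track_id, function(x) length(unique(x)))
  expect_true(all(swaps == 1))
})

test_that("a jump beyond max_disp terminates the track and starts a new one", {
  frames <- list(data.frame(id = "a", x_um = 1, y_um = 1),
                 data.frame(id = "a", x_um = 1.2, y_um = 1),
                 data.frame(id = "a", x_um = 5, y_um = 5))
  tr <- link_tracks(frames, max_disp = 1)
  expect_equal(length(unique(tr$track_id)), 2L)
  lens <- sort(as.integer(table(tr$track_id)))
  expect_equal(lens, c(1L, 2L))
})

test_that("a single frame yields one 1-point track per particle and linking conserves particles", {
  f1 <- data.frame(id = sprintf("p%d", 1:5), x_um = runif(5, 0, 5),
                   y_um = runif(5, 0, 5))
  tr <- link_tracks(list(f1), max_disp = 1)
  expect_equal(nrow(tr), 5L)
  expect_equal(length(unique(tr$track_id)), 5L)

  set.seed(42)
  frames <- lapply(1:6, function(t)
    data.frame(id = sprintf("p%02d", 1:12),
               x_um = runif(12, 0, 10), y_um = runif(12, 0, 10)))
  tr <- link_tracks(frames, max_disp = 1.5)
  # every particle of every frame belongs to exactly one track point
  expect_equal(nrow(tr), 6L * 12L)
  expect_false(any(duplicated(tr[, c("frame", "particle_id")])))
})

test_that("frame-to-frame assignment equals exhaustive minimal-cost matching", {
  set.seed(7)
  for (rep in 1:25) {
    np <- sample(2:8, 1); nc <- sample(2:8, 1)
    prev <- data.frame(id = sprintf("a%d", seq_len(np)),
                       x_um = runif(np, 0, 4), y_um = runif(np, 0, 4))
    cur <- data.frame(id = sprintf("b%d", seq_len(nc)),
                      x_um = runif(nc, 0, 4), y_um = runif(nc, 0, 4))
    max_disp <- runif(1, 0.5, 2)
    got <- granulytics:::link_frame_pair(prev, cur, max_disp)
    oracle <- brute_force_link(prev, cur, max_disp)
    d2 <- (prev$x_um[got[, 1]] - cur$x_um[got[, 2]])^2 +
      (prev$y_um[got[, 1]] - cur$y_um[got[, 2]])^2
    cost_got <- sum(d2) + max_disp^2 *
      ((np - nrow(got)) + (nc - nrow(got)))
    expect_equal(cost_got, oracle$cost, tolerance = 1e-9)
  }
})

test_that("track metrics match analytic values on straight and closed paths", {
  straight <- data.frame(track_id = "s", t_s = 0:9 * 0.2,
                         x_um = 0:9 * 0.06, y_um = 0)
  m <- track_metrics(straight, min_length = 2)
  expect_equal(m$velocity_um_s, 0.3, tolerance = 1e-12)
  expect_equal(m$linearity, 1, tolerance = 1e-12)
  expect_equal(m$net_displacement_um, 0.54, tolerance = 1e-12)

  theta <- seq(0, 2 * pi, length.out = 21)
  loop <- data.frame(track_id = "l", t_s = seq_along(theta) * 0.2,
                     x_um = cos(theta), y_um = sin(theta))
  m2 <- track_metrics(loop, min_length = 2)
  expect_equal(m2$net_displacement_um, 0, tolerance = 1e-9)
  expect_equal(m2$linearity, 0, tolerance = 1e-9)
  expect_true(m2$net_displacement_um <= m2$path_length_um)
})

test_that("metrics are invariant under rigid rotation and translation", {
  set.seed(1)
  tr <- data.frame(track_id = "r", t_s = 1:20 * 0.2,
                   x_um = cumsum(rnorm(20, 0.05, 0.02)),
                   y_um = cumsum(rnorm(20, 0, 0.02)))
  m0 <- track_metrics(tr, min_length = 2)
  th <- 0.83
  tr2 <- tr
  tr2$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 3.2
  tr2$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 1.1
  m1 <- track_metrics(tr2, min_length = 2)
  for (col in c("velocity_um_s", "linearity", "net_displacement_um",
                "path_length_um"))
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
})

test_that("linearity of long Brownian tracks decays toward zero", {
  set.seed(5)
  mets <- replicate(40, {
    n <- 600
    tr <- data.frame(track_id = "b", t_s = seq_len(n) * 0.2,
                     x_um = cumsum(rnorm(n, 0, 0.05)),
                     y_um = cumsum(rnorm(n, 0, 0.05)))
    track_metrics(tr, min_length = 2)$linearity
  })
  expect_true(all(mets >= 0 & mets <= 1))
  expect_lt(mean(mets), 0.2)
})

test_that("equal-area regions count particles correctly", {
  field <- list(xlim = c(0, 10), ylim = c(0, 8))
  # uniform occupancy: each of 4 regions holds ~25%
  set.seed(9)
  pts <- data.frame(x_um = runif(4000, 0, 10), y_um = runif(4000, 0, 8))
  occ <- region_occupancy(pts, field, cortex = "ymax")
  props <- occ$counts / sum(occ$counts)
  expect_true(all(abs(props - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000) + 0.01))
  expect_equal(sum(occ$counts), 4000)

  # all particles exactly on the cortex edge fall in region 4
  edge <- data.frame(x_um = 1:5, y_um = 8)
  occ2 <- region_occupancy(edge, field, cortex = "ymax")
  expect_equal(unname(occ2$counts[1, ]), c(0, 0, 0, 5))

  # boundary points go to the band nearer the cortex
  bnd <- data.frame(x_um = 1, y_um = 8 - 2)  # exactly one band width away
  occ3 <- region_occupancy(bnd, field, cortex = "ymax")
  expect_equal(unname(occ3$counts[1, ]), c(0, 0, 0, 1))

  expect_error(region_occupancy(pts, list(xlim = c(0, 0), ylim = c(0, 8))),
               "degenerate")
  expect_error(region_occupancy(data.frame(x_um = 11, y_um = 1), field),
               "inside the field")
})

test_that("directed population beats confined on velocity, linearity and displacement", {
  cfg <- motion_config(n_frames = 600, n_particles = 60,
                       directed_fraction = 0.5, seed = 21)
  mv <- render_movie(cfg)
  tr <- link_tracks(mv$frames, max_disp = 1.0,
                    frame_interval_s = cfg$frame_interval_s)
  m <- track_metrics(tr, min_length = 5)
  # map tracks to populations via the observed particle ids (stable here)
  first_pt <- tr[!duplicated(tr$track_id), ]
  truth1 <- mv$truth[!duplicated(mv$truth$track_id), ]
  model <- truth1$model[match(first_pt$particle_id, truth1$track_id)]
  names(model) <- first_pt$track_id
  m$model <- model[m$track_id]
  dirm <- m[m$model == "directed", ]
  conf <- m[m$model == "confined", ]
  expect_gt(nrow(dirm), 5); expect_gt(nrow(conf), 5)
  for (col in c("velocity_um_s", "linearity", "net_displacement_um")) {
    tt <- t.test(dirm[[col]], conf[[col]], alternative = "greater",
                 var.equal = TRUE)
    expect_lt(tt$p.value, 0.01)
  }
  # confined displacement is far below directed over the movie
  expect_lt(mean(conf$net_displacement_um),
            0.2 * mean(dirm$net_displacement_um))
})

test_that("directed and confined kinematics are exact without noise", {
  cfg <- motion_config(n_frames = 10, n_particles = 1,
                       directed_fraction = 1, speed_um_s = 0.5,
                       directed_jitter_sd_um = 0, loc_noise_sd_um = 0,
                       nuclei = cbind(x = 100, y = 100),
                       field_um = c(x = 200, y = 200), seed = 2)
  mv <- render_movie(cfg)
  tt <- mv$truth
  net <- sqrt((tt$x_um[10] - tt$x_um[1])^2 + (tt$y_um[10] - tt$y_um[1])^2)
  expect_equal(net, 0.9, tolerance = 1e-9)

  cfg2 <- motion_config(n_frames = 50, n_particles = 1,
                        directed_fraction = 0, jitter_sd_um = 0,
                        loc_noise_sd_um = 0, seed = 3)
  mv2 <- render_movie(cfg2)
  expect_equal(max(abs(diff(mv2$truth$x_um))), 0, tolerance = 1e-12)
})
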