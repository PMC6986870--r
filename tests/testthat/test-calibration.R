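fake_particles <- function(intensities, stage = "nc2", embryo = "e1") {
  n <- length(intensities)
  data.frame(id = sprintf("p%03d", seq_len(n)), channel = "oskar",
             z_um = runif(n, 1, 3), y_um = runif(n, 0, 8),
             x_um = runif(n, 0, 8), intensity = intensities,
             peak = intensities / 10, background = 0.5, saturated = FALSE,
             stage = stage, embryo = embryo, stringsAsFactors = FALSE)
}

test_that("internal calibration assigns counts from the unlocalized mean", {
  set.seed(1)
  unloc <- fake_particles(rnorm(30, 400, 40))
  cal <- calibrate(unloc, "oskar")
  I <- mean(unloc$intensity)
  expect_equal(cal$photons_per_transcript, I / 2)
  # a localized particle of intensity exactly I carries 2 transcripts
  loc <- assign_transcript_counts(fake_particles(c(I, 5 * I)), cal)
  expect_equal(loc$count, c(2, 10), tolerance = 1e-12)
  # nanos standards carry 1 transcript
  cal_n <- calibrate(unloc, "nanos")
  expect_equal(cal_n$photons_per_transcript, I)
})

test_that("calibration errors are informative", {
  expect_error(calibrate(fake_particles(rep(100, 5)), "oskar"),
               "minimum")
  expect_error(calibrate(fake_particles(rep(0, 25)), "oskar"), "zero mean")
  expect_error(calibrate(fake_particles(rep(100, 25)), "gcl"), "assumed")
  mixed <- rbind(fake_particles(rep(100, 15), embryo = "e1"),
                 fake_particles(rep(100, 15), embryo = "e2"))
  expect_error(calibrate(mixed, "oskar"), "per-image")
})

test_that("counts are invariant to global intensity rescaling of a stack", {
  set.seed(2)
  unloc <- fake_particles(rnorm(25, 350, 30))
  loc <- fake_particles(runif(40, 500, 5000))
  counts1 <- assign_transcript_counts(loc, calibrate(unloc, "oskar"))$count
  unloc2 <- unloc; unloc2$intensity <- unloc2$intensity * 7.3
  loc2 <- loc; loc2$intensity <- loc2$intensity * 7.3
  counts2 <- assign_transcript_counts(loc2, calibrate(unloc2, "oskar"))$count
  expect_equal(counts1, counts2, tolerance = 1e-12)
})

test_that("calibration on synthetic stacks recovers the configured unit intensity", {
  cfg <- scene_config(field_um = c(x = 10, y = 10, z = 5.1), n_founder = 15,
                      n_germ = 0, n_unloc_oskar = 50, n_unloc_nanos = 0,
                      seed = 3)
  ratios <- vapply(1:4, function(e) {
    sim <- render_stack(cfg, "nc2", embryo = paste0("e", e), seed = 3)
    det <- detect_particles(sim$stack, "oskar")
    unloc <- det[det$y_um < 10 - cfg$band_depth_um, ]
    cal <- calibrate(unloc, "oskar")
    cal$photons_per_transcript /
      (cfg$unit_intensity * sim$truth$embryo_effect)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("size distributions bin correctly and follow the generator", {
  p <- fake_particles(rep(1, 50)); p$count <- rep(5, 50)
  sd1 <- size_distribution(p, bins = c(1, 10, 100))
  expect_equal(sd1$proportions, c(1, 0))
  expect_error(size_distribution(p[0, ]), "no particles")

  # detected early-stage founder-granule counts match the configured
  # log-uniform by a two-sample KS test at alpha = 0.01
  cfg <- scene_config(field_um = c(x = 12, y = 12, z = 5.1), n_founder = 30,
                      n_germ = 0, n_unloc_oskar = 50, n_unloc_nanos = 0,
                      seed = 4)
  counts <- unlist(lapply(1:3, function(e) {
    sim <- render_stack(cfg, "nc2", embryo = paste0("e", e), seed = 4)
    det <- detect_particles(sim$stack, "oskar")
    unloc <- det[det$y_um < 12 - cfg$band_depth_um, ]
    gp <- det[det$y_um >= 12 - cfg$band_depth_um, ]
    gp <- assign_transcript_counts(gp, calibrate(unloc, "oskar"))
    # granule-matched detections only: the band also holds unlocalized
    # low-copy particles, which belong to a different distribution
    osk <- sim$truth$particles
    osk <- osk[osk$population == "granule" & osk$species == "oskar", ]
    dd <- granulytics:::cross_dist(cbind(gp$z_um, gp$y_um, gp$x_um),
                                   cbind(osk$z_um, osk$y_um, osk$x_um))
    gp$count[apply(dd, 1, min) < 0.2]
  }))
  ref <- exp(runif(5000, log(3), log(200)))
  ks <- suppressWarnings(ks.test(counts, ref))
  expect_gt(ks$p.value, 0.01)

  # programmed shrinking gives monotonically decreasing mean counts
  cfg2 <- scene_config(field_um = c(x = 10, y = 10, z = 5.1),
                       n_founder = 40, n_germ = 0, n_unloc_oskar = 40,
                       n_unloc_nanos = 0, seed = 5)
  means <- vapply(c("nc8", "nc10", "nc12"), function(st) {
    mean(unlist(lapply(1:3, function(e) {
      tr <- render_stack(cfg2, st, embryo = paste0("e", e),
                         seed = 5)$truth$particles
      tr$count[tr$population == "granule" & tr$species == "oskar"]
    })))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("transcript-count recovery: relative RMSE below 15% for resolvable particles with >= 5 transcripts", {
  cfg <- scene_config(field_um = c(x = 14, y = 14, z = 5.1), n_founder = 20,
                      n_germ = 0, n_unloc_oskar = 60, n_unloc_nanos = 0,
                      seed = 11)
  rels <- c()
  for (e in 1:8) {
    sim <- render_stack(cfg, "nc2", embryo = paste0("e", e), seed = 11)
    det <- detect_particles(sim$stack, "oskar")
    band_lo <- 14 - cfg$band_depth_um
    cal <- calibrate(det[det$y_um < band_lo, ], "oskar")
    gp <- assign_transcript_counts(det[det$y_um >= band_lo, ], cal)
    tr <- sim$truth$particles
    osk <- tr[tr$population == "granule", ]
    allosk <- tr[tr$channel == "oskar", ]
    dd <- granulytics:::cross_dist(cbind(gp$z_um, gp$y_um, gp$x_um),
                                   cbind(osk$z_um, osk$y_um, osk$x_um))
    nn2 <- apply(granulytics:::cross_dist(
      cbind(osk$z_um, osk$y_um, osk$x_um),
      cbind(allosk$z_um, allosk$y_um, allosk$x_um)), 1,
      function(r) sort(r)[2])
    mi <- apply(dd, 1, which.min); mv <- apply(dd, 1, min)
    # resolvable: no other particle inside the measurement aperture reach
    ok <- mv < 0.2 & osk$count[mi] >= 5 & nn2[mi] > 1.0
    rels <- c(rels, (gp$count[ok] - osk$count[mi][ok]) / osk$count[mi][ok])
  }
  expect_gt(length(rels), 30)
  expect_lt(sqrt(mean(rels^2)), 0.15)
})

test_that("abundance time courses normalize, test and difference correctly", {
  m <- data.frame(stage = rep(c("early", "late"), each = 2),
                  embryo = c("a", "b", "c", "d"),
                  total = c(100, 100, 2, 2))
  tc <- abundance_timecourse(m, baseline = "early")
  expect_equal(percent_decrease(tc, "early", "late"), 98)
  expect_equal(tc$norm_mean[tc$stage == "early"], 1)

  flat <- data.frame(stage = rep(c("s1", "s2", "s3"), each = 3),
                     embryo = rep(letters[1:3], 3), total = 7)
  tcf <- abundance_timecourse(flat, baseline = "s1")
  expect_true(all(tcf$norm_mean == 1))
  expect_true(all(tcf$p_value[tcf$stage != "s1"] > 0.99))

  # pooled-variance Student's t-test equals the closed-form oracle
  x <- c(10, 11, 9); y <- c(5, 6, 4)
  m2 <- data.frame(stage = rep(c("b", "s"), each = 3),
                   embryo = letters[1:6], total = c(x, y))
  tc2 <- abundance_timecourse(m2, baseline = "b")
  oracle <- pooled_t_oracle(y, x)
  expect_equal(tc2$p_value[tc2$stage == "s"], oracle$p, tolerance = 1e-12)
  expect_error(abundance_timecourse(m2, baseline = "zz"), "baseline")
})

test_that("5':3' ratios are 1 for intact particles and scale with degradation", {
  set.seed(6)
  mk <- function(stage, intact, n = 60) {
    p <- fake_particles(runif(n, 1000, 8000), stage = stage,
                        embryo = sample(paste0("e", 1:6), n, replace = TRUE))
    p$intensity_5p <- p$intensity * intact * rnorm(n, 1, 0.05)
    p$count <- p$intensity / 300
    p
  }
  early <- mk("nc3-4", 1)
  late <- mk("nc7-8", 0.5)
  rr <- ratio_5to3(rbind(early, late), reference_stage = "nc3-4")
  gm <- rr$group_means
  expect_equal(mean(gm$ratio[gm$stage == "nc3-4"]), 1, tolerance = 0.05)
  expect_equal(mean(gm$ratio[gm$stage == "nc7-8"]), 0.5, tolerance = 0.05)
  # decrease significant for both size classes
  expect_true(all(rr$tests$p_value < 0.001))
  expect_equal(sort(unique(rr$tests$size_class)), c("larger", "smaller"))

  # particles with nonpositive 3' intensity are excluded and counted
  bad <- mk("nc7-8", 0.5, n = 5); bad$intensity <- 0
  rr2 <- ratio_5to3(rbind(early, late, bad), reference_stage = "nc3-4")
  expect_equal(rr2$excluded_n, 5L)
})

test_that("end-to-end dual-probe measurement recovers the programmed 5' loss", {
  cfg <- scene_config(field_um = c(x = 10, y = 10, z = 5.1), n_founder = 25,
                      n_germ = 0, n_unloc_oskar = 0, n_unloc_nanos = 0,
                      channels = c("oskar_5p", "oskar_3p"), seed = 7)
  ratios <- function(stage) {
    unlist(lapply(1:3, function(e) {
      sim <- render_stack(cfg, stage, embryo = paste0("e", e), seed = 7)
      det3 <- detect_particles(sim$stack, "oskar_3p")
      det3 <- det3[det3$y_um >= 10 - cfg$band_depth_um, ]
      i5 <- measure_at(sim$stack, "oskar_5p", det3)
      i5 / det3$intensity
    }))
  }
  r_early <- ratios("nc2")   # intact fraction 1
  r_late <- ratios("nc8")    # intact fraction 0.5
  expect_equal(mean(r_early), 1, tolerance = 0.08)
  expect_equal(mean(r_late) / mean(r_early), 0.5, tolerance = 0.08)
})
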