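small_cfg <- function(...) {
  scene_config(field_um = c(x = 8, y = 8, z = 5.1), n_founder = 15,
               n_germ = 10, n_unloc_oskar = 25, n_unloc_nanos = 20,
               seed = 2, ...)
}

test_that("identical config and seed give bit-identical stacks and truth", {
  cfg <- small_cfg()
  a <- render_stack(cfg, "nc2", embryo = "e1", seed = 13)
  b <- render_stack(cfg, "nc2", embryo = "e1", seed = 13)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$particles, b$truth$particles)
  # different embryo label gives an independent substream
  c <- render_stack(cfg, "nc2", embryo = "e2", seed = 13)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("rendering conserves photons: spot sums equal amplitudes", {
  # one centered granule of 20 transcripts, zero noise, zero background
  cfg <- scene_config(field_um = c(x = 6, y = 6, z = 5.1), n_founder = 1,
                      n_germ = 0, n_unloc_oskar = 0, n_unloc_nanos = 0,
                      background = 0, seed = 3)
  spots <- data.frame(z = 2.55, y = 3, x = 3, amplitude = 20 * 200)
  a <- granulytics:::render_spots(spots, scene_dims(cfg),
                                  c(z = 0.34, y = 0.072, x = 0.072),
                                  cfg$psf_sigma_um)
  expect_equal(sum(a), 20 * 200, tolerance = 1e-4)

  # population-level: noise-free rendered sum minus background equals the
  # summed true amplitudes within discretization/edge tolerance
  cfg2 <- small_cfg()
  sim <- render_stack(cfg2, "nc2", embryo = "e1", seed = 5, noise = FALSE)
  tr <- sim$truth$particles
  for (ch in c("oskar", "nanos")) {
    arr <- sim$stack$data[[ch]]
    expect_equal(sum(arr) - cfg2$background * length(arr),
                 sum(tr$amplitude[tr$channel == ch]),
                 tolerance = 0.02)
  }
  # with noise the same holds within 3 sd of the total Poisson count
  simn <- render_stack(cfg2, "nc2", embryo = "e1", seed = 5, noise = TRUE)
  arr <- simn$stack$data$oskar
  total <- sum(tr$amplitude[tr$channel == "oskar"]) +
    cfg2$background * length(arr)
  expect_lt(abs(sum(arr) - total), 3 * sqrt(total) + 0.02 * total)
})

test_that("ground-truth totals equal per-particle sums and follow stage decay", {
  cfg <- small_cfg()
  sim <- render_stack(cfg, "nc5", embryo = "e1", seed = 4)
  tr <- sim$truth$particles
  tot <- sim$truth$totals
  for (i in seq_len(nrow(tot))) {
    expect_equal(tot$true_transcripts[i],
                 sum(tr$count[tr$channel == tot$channel[i] &
                                tr$population == tot$population[i]],
                     na.rm = TRUE))
  }
  # late/early ratio of true localized totals matches the configured
  # decay multiplier (averaged over embryos to beat the embryo effect)
  loc_total <- function(stage, e) {
    p <- render_stack(cfg, stage, embryo = paste0("e", e),
                      seed = 11)$truth$particles
    sum(p$count[p$population == "granule" & p$species == "oskar"])
  }
  early <- mean(vapply(1:6, function(e) loc_total("nc2", e), numeric(1)))
  late <- mean(vapply(1:6, function(e) loc_total("nc9", e), numeric(1)))
  mult <- cfg$stages$total_mult[cfg$stages$stage == "nc9"]
  expect_equal(late / early, mult, tolerance = 0.12)
})

test_that("programmed colocalization fractions are assigned exactly in the truth", {
  cfg <- scenario_config("staufen-nc8", seed = 6, n_founder = 60,
                         field_um = c(x = 12, y = 12, z = 5.1))
  sim <- render_stack(cfg, "nc8", embryo = "e1", seed = 6)
  tr <- sim$truth$particles
  sites_osk <- tr$site_id[tr$channel == "oskar" & !is.na(tr$site_id)]
  sites_dcp <- tr$site_id[tr$channel == "dcp1" & !is.na(tr$site_id)]
  sites_sta <- tr$site_id[tr$channel == "staufen" & !is.na(tr$site_id)]
  expect_equal(length(sites_osk), round(0.9 * 60))
  expect_equal(length(sites_dcp), round(0.35 * 60))
  expect_equal(length(sites_sta), 60)
  # DCP1 assignment is independent of oskar occupancy by construction:
  # fraction of staufen+oskar sites with DCP1 equals the programmed value
  both <- intersect(sites_sta, sites_osk)
  expect_equal(mean(both %in% sites_dcp), 0.35, tolerance = 0.08)

  # boundary cases: fraction 0 and fraction 1
  tab <- cfg$stages; tab$dcp1_coloc <- 0
  cfg0 <- scenario_config("staufen-nc8", seed = 6, n_founder = 40,
                          field_um = c(x = 12, y = 12, z = 5.1),
                          stages = tab)
  tr0 <- render_stack(cfg0, "nc8", embryo = "e1", seed = 6)$truth$particles
  expect_equal(sum(tr0$channel == "dcp1" & !is.na(tr0$site_id)), 0)
  tab$dcp1_coloc <- 1
  cfg1 <- scenario_config("staufen-nc8", seed = 6, n_founder = 40,
                          field_um = c(x = 12, y = 12, z = 5.1),
                          stages = tab)
  tr1 <- render_stack(cfg1, "nc8", embryo = "e1", seed = 6)$truth$particles
  expect_equal(sum(tr1$channel == "dcp1" & !is.na(tr1$site_id)), 40)
})

test_that("dual-probe channels scale the 5' amplitude by the intact fraction", {
  cfg <- scene_config(field_um = c(x = 8, y = 8, z = 5.1), n_founder = 10,
                      n_germ = 0, n_unloc_oskar = 0, n_unloc_nanos = 0,
                      channels = c("oskar_5p", "oskar_3p"),
                      background = 0, seed = 8)
  cfg$stages$five_prime_intact[cfg$stages$stage == "nc7"] <- 0.5
  sim <- render_stack(cfg, "nc7", embryo = "e1", seed = 8, noise = FALSE)
  s5 <- sum(sim$stack$data$oskar_5p)
  s3 <- sum(sim$stack$data$oskar_3p)
  expect_equal(s5 / s3, 0.5, tolerance = 0.01)
})

test_that("overcrowded scenes trigger the resolvability warning", {
  cfg <- scene_config(field_um = c(x = 4, y = 4, z = 5.1), n_founder = 600,
                      n_germ = 0, n_unloc_oskar = 0, n_unloc_nanos = 0,
                      band_depth_um = 1, seed = 9)
  expect_warning(render_stack(cfg, "nc2", embryo = "e1", seed = 9),
                 "nearest-neighbor")
})

test_that("scene configuration rejects invalid parameters", {
  expect_error(scene_config(pixel_um = -1), "pixel_um")
  expect_error(scene_config(psf_sigma_um = c(lateral = 0, axial = 0.3)),
               "PSF")
  expect_error(scene_config(localized_fraction = 1.4), "\\[0, 1\\]")
  expect_error(scene_config(band_depth_um = 50), "band depth")
  expect_error(render_stack(small_cfg(), "nc99"), "not present")
  expect_error(motion_config(n_frames = 1), "2 frames")
})
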