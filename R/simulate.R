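# Synthetic scene rendering: ground-truth particle placement and Gaussian
# PSF rendering with Poisson/Gaussian noise.

# Exact-count random subset: assigns a programmed fraction exactly
# (round(frac * n) members), not by per-element Bernoulli draws, so
# configured colocalization fractions are recovered exactly in the truth.
pick_exact <- function(n, frac) {
  k <- round(frac * n)
  sel <- logical(n)
  if (k > 0) sel[sample.int(n, k)] <- TRUE
  sel
}

runif_box <- function(n, lo, hi) runif(n, lo, hi)

loguniform_mean <- function(d) (d$max - d$min) / log(d$max / d$min)

# Discrete log-uniform transcript counts (support >= min >= 1).
draw_counts <- function(n, d) {
  pmax(d$min, round(exp(runif(n, log(d$min), log(d$max)))))
}

#' Render one synthetic stage as an image stack with ground truth
#'
#' Realizes a [scene_config()] at one stage: places founder-granule and
#' germ-granule sites in the cortical germ-plasm band, unlocalized
#' calibration particles in the bulk, and protein-channel particles at
#' partner sites for the configured (exactly assigned) fractions; then
#' renders every requested channel as a sum of anisotropic 3D Gaussian
#' spots integrated over voxels, adds the background, and applies
#' Poisson shot noise plus optional Gaussian read noise.
#'
#' Spot amplitudes are proportional to transcript count times
#' `unit_intensity` (mRNA channels) or drawn lognormally around
#' `protein_intensity` (protein channels). In dual-probe mode (channels
#' `oskar_5p`/`oskar_3p`) the 5' amplitude of each particle is scaled by
#' its 5'-intact fraction for the stage. A per-embryo lognormal staining
#' effect multiplies all amplitudes; granule transcript counts are
#' normalized so that each stage's true localized total follows the
#' configured stage trajectory times that embryo effect.
#'
#' @param config a [scene_config()].
#' @param stage stage label; must appear in `config$stages$stage`.
#' @param embryo embryo identifier (also seeds the substream).
#' @param seed master seed; defaults to the seed stored in `config`.
#' @param noise logical; `FALSE` renders the noise-free expectation
#'   (signal plus constant background).
#' @return a list with elements `stack` (an [image_stack()]) and `truth`
#'   (list of `particles` — one row per emitted spot with true centroid,
#'   transcript count, 5'-intact fraction and partner site id — and
#'   `totals`, per-channel true transcript/intensity totals by region).
#' @export
render_stack <- function(config, stage, embryo = "e1", seed = config$seed,
                         noise = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  row <- config$stages[config$stages$stage == stage, ]
  if (nrow(row) != 1L)
    stop(sprintf("stage '%s' not present in the scene's stage table", stage))
  set.seed(substream_seed(seed, "stack", stage, embryo))
  emb <- stats::rlnorm(1, -config$embryo_sdlog^2 / 2, config$embryo_sdlog)

  fx <- config$field_um[["x"]]; fy <- config$field_um[["y"]]
  fz <- config$field_um[["z"]]
  m <- config$margin_um
  # axial placement margin: keeps the 3-sigma axial measurement aperture
  # (~1.05 um for a 350 nm axial PSF) inside the field, so per-particle
  # capture is position-independent and cancels exactly in calibration
  mz <- min(1.2, fz / 3)
  band_lo <- fy - config$band_depth_um

  particles <- list()
  sp_f <- config$founder_species
  sp_g <- config$germ_species

  ## --- founder-granule sites -------------------------------------------
  n_pres <- round(row$site_frac * config$n_founder)
  site <- NULL
  if (n_pres > 0) {
    site <- data.frame(
      site_id = sprintf("f%03d", seq_len(n_pres)),
      x = runif_box(n_pres, m, fx - m),
      y = runif_box(n_pres, band_lo, fy - m),
      z = runif_box(n_pres, mz, fz - mz))
    site$has_oskar <- pick_exact(n_pres, row$oskar_given_site)
    site$has_staufen <- pick_exact(n_pres, row$staufen_given_site)
    site$has_dcp1 <- pick_exact(n_pres, row$dcp1_coloc)
    site$has_me31b <- site$has_pacman <- FALSE
    idx_d <- which(site$has_dcp1); idx_n <- which(!site$has_dcp1)
    site$has_me31b[idx_d] <- pick_exact(length(idx_d), config$me31b_given_dcp1)
    site$has_me31b[idx_n] <- pick_exact(length(idx_n), config$me31b_base)
    site$has_pacman[idx_d] <- pick_exact(length(idx_d), config$pacman_given_dcp1)
    site$has_pacman[idx_n] <- pick_exact(length(idx_n), config$pacman_base)
  }
  n_osk <- if (is.null(site)) 0L else sum(site$has_oskar)
  osk_counts <- numeric(0)
  if (n_osk > 0) {
    raw <- draw_counts(n_osk, config$founder_counts)
    target <- config$n_founder * loguniform_mean(config$founder_counts) *
      row$total_mult * emb
    osk_counts <- raw * target / sum(raw)
    osk <- site[site$has_oskar, ]
    particles$osk <- data.frame(
      id = paste0(sp_f, "_", osk$site_id), channel = sp_f, species = sp_f,
      site_id = osk$site_id, population = "granule",
      z_um = osk$z, y_um = osk$y, x_um = osk$x,
      count = osk_counts, intact5 = row$five_prime_intact,
      amplitude = osk_counts * config$unit_intensity,
      stringsAsFactors = FALSE)
  }

  ## --- germ-granule sites ----------------------------------------------
  if (config$n_germ > 0) {
    ng <- config$n_germ
    raw <- draw_counts(ng, config$germ_counts)
    target <- ng * loguniform_mean(config$germ_counts) * row$nanos_mult * emb
    gcounts <- raw * target / sum(raw)
    particles$germ <- data.frame(
      id = sprintf("%s_g%03d", sp_g, seq_len(ng)), channel = sp_g,
      species = sp_g, site_id = sprintf("g%03d", seq_len(ng)),
      population = "granule",
      z_um = runif_box(ng, mz, fz - mz),
      y_um = runif_box(ng, band_lo, fy - m),
      x_um = runif_box(ng, m, fx - m),
      count = gcounts, intact5 = 1,
      amplitude = gcounts * config$unit_intensity,
      stringsAsFactors = FALSE)
  }

  ## --- unlocalized calibration particles -------------------------------
  loc_total <- sum(osk_counts)
  if (!is.null(config$localized_fraction) && loc_total > 0) {
    f <- config$localized_fraction
    # divide out the embryo effect: unlocalized amplitudes are rescaled by
    # it below, so the localized share stays exactly f per embryo
    n_unloc <- round(loc_total / emb * (1 / f - 1) /
                       config$unloc_oskar_count)
  } else {
    n_unloc <- round(config$n_unloc_oskar * row$bulk_mult)
  }
  if (n_unloc > 0) {
    particles$unloc_f <- data.frame(
      id = sprintf("%s_u%04d", sp_f, seq_len(n_unloc)), channel = sp_f,
      species = sp_f, site_id = NA_character_, population = "unlocalized",
      z_um = runif_box(n_unloc, mz, fz - mz),
      y_um = runif_box(n_unloc, 0, fy),   # no y margin: uniform across both
                                          # compartment ROIs
      x_um = runif_box(n_unloc, m, fx - m),
      count = config$unloc_oskar_count, intact5 = 1,
      amplitude = config$unloc_oskar_count * config$unit_intensity * emb,
      stringsAsFactors = FALSE)
  }
  if (config$n_unloc_nanos > 0) {
    nu <- config$n_unloc_nanos
    particles$unloc_g <- data.frame(
      id = sprintf("%s_u%04d", sp_g, seq_len(nu)), channel = sp_g,
      species = sp_g, site_id = NA_character_, population = "unlocalized",
      z_um = runif_box(nu, mz, fz - mz),
      y_um = runif_box(nu, 0, fy),
      x_um = runif_box(nu, m, fx - m),
      count = config$unloc_nanos_count, intact5 = 1,
      amplitude = config$unloc_nanos_count * config$unit_intensity * emb,
      stringsAsFactors = FALSE)
  }

  ## --- protein channels -------------------------------------------------
  protein_spots <- function(chan, at_sites, size_mult = 1) {
    rows <- NULL
    if (!is.null(site) && any(at_sites)) {
      s <- site[at_sites, ]
      np <- nrow(s)
      rows <- data.frame(
        id = paste0(chan, "_", s$site_id), channel = chan, species = chan,
        site_id = s$site_id, population = "protein-site",
        z_um = s$z + rnorm(np, 0, config$partner_offset_sd_um),
        y_um = s$y + rnorm(np, 0, config$partner_offset_sd_um),
        x_um = s$x + rnorm(np, 0, config$partner_offset_sd_um),
        count = NA_real_, intact5 = NA_real_,
        amplitude = config$protein_intensity * size_mult * emb *
          stats::rlnorm(np, -config$protein_intensity_sdlog^2 / 2,
                        config$protein_intensity_sdlog),
        stringsAsFactors = FALSE)
    }
    nf <- config$free_protein[[chan]] %||% 0
    if (nf > 0) {
      free <- data.frame(
        id = sprintf("%s_free%03d", chan, seq_len(nf)), channel = chan,
        species = chan, site_id = NA_character_, population = "protein-free",
        z_um = runif_box(nf, mz, fz - mz),
        y_um = runif_box(nf, m, fy - m),
        x_um = runif_box(nf, m, fx - m),
        count = NA_real_, intact5 = NA_real_,
        amplitude = config$protein_intensity * size_mult * emb *
          stats::rlnorm(nf, -config$protein_intensity_sdlog^2 / 2,
                        config$protein_intensity_sdlog),
        stringsAsFactors = FALSE)
      rows <- rbind(rows, free)
    }
    rows
  }
  if ("dcp1" %in% config$channels && !is.null(site))
    particles$dcp1 <- protein_spots("dcp1", site$has_dcp1)
  if ("me31b" %in% config$channels && !is.null(site))
    particles$me31b <- protein_spots("me31b", site$has_me31b)
  if ("pacman" %in% config$channels && !is.null(site))
    particles$pacman <- protein_spots("pacman", site$has_pacman)
  if ("staufen" %in% config$channels && !is.null(site))
    particles$staufen <- protein_spots("staufen", site$has_staufen,
                                       size_mult = row$staufen_size_mult)

  truth <- do.call(rbind, particles)
  if (is.null(truth)) stop("scene is empty: no particles to render")
  rownames(truth) <- NULL
  truth$stage <- stage
  truth$embryo <- embryo
  truth$region <- ifelse(truth$y_um >= band_lo, "germ plasm",
                         "bulk cytoplasm")

  ## --- dual-probe channels share the mRNA truth -------------------------
  render_sets <- list()
  for (chan in config$channels) {
    if (chan %in% c("oskar_5p", "oskar_3p")) {
      sub <- truth[truth$species == sp_f, ]
      amp <- sub$amplitude
      if (chan == "oskar_5p") amp <- amp * sub$intact5
      render_sets[[chan]] <- data.frame(z = sub$z_um, y = sub$y_um,
                                        x = sub$x_um, amplitude = amp)
    } else {
      sub <- truth[truth$channel == chan, ]
      render_sets[[chan]] <- data.frame(z = sub$z_um, y = sub$y_um,
                                        x = sub$x_um, amplitude = sub$amplitude)
    }
  }

  ## density guard: expected nearest-neighbor spacing in the band
  n_band <- sum(truth$region == "germ plasm")  # position-based
  if (n_band > 1) {
    vol_band <- fx * config$band_depth_um * fz
    enn <- 0.554 * (n_band / vol_band)^(-1 / 3)
    if (enn < 2 * config$psf_sigma_um[["lateral"]])
      warning(sprintf(paste0("expected nearest-neighbor spacing %.0f nm < 2",
                             " lateral PSF sigma; detection guarantees void"),
                      1000 * enn))
  }

  dims <- scene_dims(config)
  spacing <- c(z = config$z_step_um, y = config$pixel_um, x = config$pixel_um)
  arrays <- lapply(render_sets, function(spots) {
    a <- render_spots(spots, dims, spacing, config$psf_sigma_um)
    add_noise(a, config$background, config$read_noise_sd, noise)
  })
  stack <- image_stack(arrays, spacing, stage = stage, embryo = embryo)

  totals <- stats::aggregate(count ~ channel + population,
                             data = truth[!is.na(truth$count), ], FUN = sum)
  names(totals)[names(totals) == "count"] <- "true_transcripts"
  list(stack = stack,
       truth = list(particles = truth, totals = totals,
                    embryo_effect = emb, stage = stage, embryo = embryo))
}

# Sum-of-Gaussians rendering. Each spot deposits amplitude * the product of
# per-axis Gaussian masses integrated over voxel extents (pnorm
# differences), so the voxel sum of a spot fully inside the field equals
# its amplitude exactly.
render_spots <- function(spots, dims, spacing, psf_sigma_um, cut = 4) {
  a <- array(0, dim = dims[c("nz", "ny", "nx")])
  if (is.null(spots) || nrow(spots) == 0) return(a)
  sig <- c(z = psf_sigma_um[["axial"]], y = psf_sigma_um[["lateral"]],
           x = psf_sigma_um[["lateral"]])
  n <- c(z = dims[["nz"]], y = dims[["ny"]], x = dims[["nx"]])
  for (i in seq_len(nrow(spots))) {
    w <- list()
    idx <- list()
    for (ax in c("z", "y", "x")) {
      mu <- spots[[ax]][i]; s <- sig[[ax]]; d <- spacing[[ax]]
      lo <- max(0L, floor((mu - cut * s) / d))
      hi <- min(n[[ax]] - 1L, ceiling((mu + cut * s) / d))
      if (hi < lo) { w <- NULL; break }
      k <- lo:hi
      w[[ax]] <- stats::pnorm((k + 1) * d, mu, s) - stats::pnorm(k * d, mu, s)
      idx[[ax]] <- k + 1L
    }
    if (is.null(w)) next
    block <- spots$amplitude[i] * (w$z %o% w$y %o% w$x)
    a[idx$z, idx$y, idx$x] <- a[idx$z, idx$y, idx$x] + block
  }
  a
}

add_noise <- function(a, background, read_noise_sd, noise) {
  lam <- a + background
  if (!noise) return(lam)
  out <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  if (read_noise_sd > 0)
    out <- pmax(0, out + stats::rnorm(length(out), 0, read_noise_sd))
  out
}

#' Simulate a granule-motility movie with ground-truth tracks
#'
#' Propagates a directed population (constant speed toward the nearest
#' nucleus target, plus small jitter) and a confined population (tethered
#' Ornstein-Uhlenbeck-like jitter around a fixed point) over the configured
#' frames, and returns both the true trajectories and per-frame observed
#' particle tables with localization noise.
#'
#' @param config a [motion_config()].
#' @param seed master seed; defaults to the seed in `config`.
#' @return a list with `truth` (data.frame: track_id, model, frame, t_s,
#'   x_um, y_um, speed_um_s), `frames` (list of per-frame observed particle
#'   data.frames with x_um, y_um), `nuclei` (target points) and `config`.
#' @export
render_movie <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "motion_config"))
  set.seed(substream_seed(seed, "movie"))
  fx <- config$field_um[["x"]]; fy <- config$field_um[["y"]]
  dt <- config$frame_interval_s
  nf <- config$n_frames
  np <- config$n_particles
  n_dir <- round(config$directed_fraction * np)
  model <- rep(c("directed", "confined"), c(n_dir, np - n_dir))
  nuclei <- config$nuclei
  if (is.null(nuclei))
    # default: the nucleus row sits just beyond the cortex-side edge, so
    # directed granules stream across the field for the whole movie (and
    # may leave the observed frames) instead of parking mid-field
    nuclei <- cbind(x = runif(config$n_nuclei, 0.2 * fx, 0.8 * fx),
                    y = fy + 2)
  nuclei <- matrix(as.numeric(nuclei), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  pos <- cbind(x = runif(np, 0, fx), y = runif(np, 0, fy))
  tether <- pos
  decay <- exp(-config$tether_rate_s * dt)

  xs <- matrix(NA_real_, nf, np)
  ys <- matrix(NA_real_, nf, np)
  xs[1, ] <- pos[, 1]; ys[1, ] <- pos[, 2]
  for (t in 2:nf) {
    if (n_dir > 0) {
      d <- cross_dist(pos[seq_len(n_dir), , drop = FALSE], nuclei)
      tgt <- nuclei[max.col(-d), , drop = FALSE]
      vec <- tgt - pos[seq_len(n_dir), , drop = FALSE]
      len <- sqrt(rowSums(vec^2))
      step <- pmin(config$speed_um_s * dt, len)
      dirn <- vec / pmax(len, 1e-12)
      pos[seq_len(n_dir), ] <- pos[seq_len(n_dir), ] + dirn * step +
        matrix(rnorm(2 * n_dir, 0, config$directed_jitter_sd_um), n_dir, 2)
    }
    if (np > n_dir) {
      ic <- (n_dir + 1):np
      pos[ic, ] <- tether[ic, ] + (pos[ic, ] - tether[ic, ]) * decay +
        matrix(rnorm(2 * length(ic), 0, config$jitter_sd_um), length(ic), 2)
    }
    xs[t, ] <- pos[, 1]; ys[t, ] <- pos[, 2]
  }

  truth <- data.frame(
    track_id = rep(sprintf("t%03d", seq_len(np)), each = nf),
    model = rep(model, each = nf),
    frame = rep(seq_len(nf), np),
    t_s = rep((seq_len(nf) - 1) * dt, np),
    x_um = as.vector(xs), y_um = as.vector(ys),
    speed_um_s = rep(ifelse(model == "directed", config$speed_um_s, 0),
                     each = nf),
    stringsAsFactors = FALSE)

  frames <- lapply(seq_len(nf), function(t) {
    f <- data.frame(id = sprintf("t%03d", seq_len(np)),
                    x_um = xs[t, ] + rnorm(np, 0, config$loc_noise_sd_um),
                    y_um = ys[t, ] + rnorm(np, 0, config$loc_noise_sd_um),
                    stringsAsFactors = FALSE)
    # particles outside the imaged field are not observed in that frame
    f[f$x_um >= 0 & f$x_um <= fx & f$y_um >= 0 & f$y_um <= fy, ,
      drop = FALSE]
  })
  list(truth = truth, frames = frames, nuclei = nuclei, config = config)
}
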