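#' Configuration of a synthetic germ-plasm imaging scene
#'
#' Defines the geometry, optics, granule populations and noise model of a
#' simulated posterior-pole confocal field. The defaults emulate smFISH
#' imaging of the early *Drosophila* embryo: a cortical germ-plasm band
#' densely populated with founder granules (multi-copy *oskar* RNPs) and
#' germ granules (*nanos* RNPs), sparse unlocalized single/low-copy
#' particles in the bulk cytoplasm that serve as internal single-molecule
#' calibration standards, and protein channels (DCP1, Me31B, Pacman,
#' Staufen) whose particles are placed at granule sites for configured,
#' stage-dependent fractions.
#'
#' Geometry and optics follow standard confocal acquisition of this system:
#' 72 x 72 nm pixels, 340 nm z-step, and an anisotropic Gaussian PSF
#' (sigma 110 nm lateral, 350 nm axial). Granule transcript-count
#' distributions are log-uniform (founder granules 3-200 transcripts, germ
#' granules 2-40); unlocalized *oskar* and *nanos* particles carry 2 and 1
#' transcripts respectively. Detectors are modeled in photon-counting mode:
#' Poisson shot noise on signal plus background, zero read noise unless
#' `read_noise_sd` is set.
#'
#' @param field_um named vector `c(x=, y=, z=)`, field size in micrometres.
#' @param pixel_um lateral pixel size (dx = dy), micrometres.
#' @param z_step_um axial step, micrometres.
#' @param band_depth_um depth of the germ-plasm band measured from the
#'   cortex edge (the maximal-y edge of the field), micrometres.
#' @param n_founder number of founder-granule sites at the reference stage.
#' @param n_germ number of germ-granule sites.
#' @param n_unloc_oskar,n_unloc_nanos unlocalized particle counts at the
#'   reference stage (scaled per stage by `bulk_mult`).
#' @param founder_counts,germ_counts transcript-count distributions, lists
#'   `list(min=, max=)` interpreted as log-uniform.
#' @param unloc_oskar_count,unloc_nanos_count transcripts per unlocalized
#'   particle (2 and 1 for *oskar* and *nanos*).
#' @param unit_intensity photons emitted per transcript per channel.
#' @param protein_intensity mean photons per protein-channel particle.
#' @param protein_intensity_sdlog lognormal spread of protein spot
#'   brightness.
#' @param psf_sigma_um named vector `c(lateral=, axial=)`, micrometres.
#' @param background expected background photons per voxel.
#' @param read_noise_sd Gaussian read noise sd (photons); 0 in
#'   photon-counting mode.
#' @param partner_offset_sd_um isotropic registration offset (sd per axis)
#'   between a protein spot and its partner granule centroid.
#' @param free_protein named vector of unpartnered protein particles per
#'   channel, placed uniformly at random.
#' @param embryo_sdlog lognormal sd of the per-embryo staining/collection
#'   effect applied to all true totals.
#' @param me31b_given_dcp1,pacman_given_dcp1 conditional partnering
#'   probabilities of Me31B/Pacman at DCP1-positive founder sites.
#' @param me31b_base,pacman_base partnering probabilities at DCP1-negative
#'   founder sites.
#' @param localized_fraction if non-`NULL`, fraction of total *oskar*
#'   transcripts in the field residing in founder granules; the unlocalized
#'   particle number is derived to satisfy it (overrides `n_unloc_oskar`).
#' @param channels channels to render, subset of `oskar`, `nanos`, `dcp1`,
#'   `me31b`, `pacman`, `staufen`, `oskar_5p`, `oskar_3p`.
#' @param stages stage table, a data.frame as produced by
#'   [stage_table_wildtype()]; one row per stage label.
#' @param margin_um granule placement margin from the field faces (avoids
#'   PSF truncation at the boundary).
#' @param seed master RNG seed.
#' @return an object of class `scene_config`.
#' @seealso [scenario_config()] for the named study scenarios,
#'   [render_stack()] to realize a stage.
#' @export
scene_config <- function(field_um = c(x = 12, y = 12, z = 5.1),
                         pixel_um = 0.072,
                         z_step_um = 0.34,
                         band_depth_um = 3,
                         n_founder = 50,
                         n_germ = 50,
                         n_unloc_oskar = 60,
                         n_unloc_nanos = 60,
                         founder_counts = list(min = 3, max = 200),
                         germ_counts = list(min = 2, max = 40),
                         unloc_oskar_count = 2,
                         unloc_nanos_count = 1,
                         unit_intensity = 200,
                         protein_intensity = 300,
                         protein_intensity_sdlog = 0.25,
                         psf_sigma_um = c(lateral = 0.110, axial = 0.350),
                         background = 0.5,
                         read_noise_sd = 0,
                         partner_offset_sd_um = 0.08,
                         free_protein = c(dcp1 = 20, me31b = 20, pacman = 20,
                                          staufen = 10),
                         embryo_sdlog = 0.08,
                         me31b_given_dcp1 = 0.77,
                         pacman_given_dcp1 = 0.49,
                         me31b_base = 0.10,
                         pacman_base = 0.05,
                         localized_fraction = NULL,
                         channels = c("oskar", "nanos"),
                         stages = stage_table_wildtype(),
                         founder_species = "oskar",
                         germ_species = "nanos",
                         margin_um = 0.4,
                         seed = 1L) {
  stopifnot_scalar(pixel_um, "pixel_um", positive = TRUE)
  stopifnot_scalar(z_step_um, "z_step_um", positive = TRUE)
  stopifnot_scalar(band_depth_um, "band_depth_um", positive = TRUE)
  if (any(field_um <= 0)) stop("field_um must be positive on all axes")
  if (any(psf_sigma_um <= 0)) stop("PSF sigmas must be > 0")
  if (band_depth_um >= field_um[["y"]])
    stop("germ-plasm band depth must be smaller than the field")
  for (nm in c("n_founder", "n_germ", "n_unloc_oskar", "n_unloc_nanos"))
    if (get(nm) < 0) stop(sprintf("'%s' must be >= 0", nm))
  if (!is.null(localized_fraction))
    check_fraction(localized_fraction, "localized_fraction")
  check_fraction(c(me31b_given_dcp1, pacman_given_dcp1, me31b_base,
                   pacman_base), "partnering probabilities")
  frac_cols <- intersect(c("site_frac", "oskar_given_site",
                           "staufen_given_site", "dcp1_coloc", "pacman_coloc",
                           "five_prime_intact"), names(stages))
  for (cc in frac_cols) check_fraction(stages[[cc]], cc)
  cfg <- list(field_um = field_um, pixel_um = pixel_um, z_step_um = z_step_um,
              band_depth_um = band_depth_um, n_founder = n_founder,
              n_germ = n_germ, n_unloc_oskar = n_unloc_oskar,
              n_unloc_nanos = n_unloc_nanos, founder_counts = founder_counts,
              germ_counts = germ_counts,
              unloc_oskar_count = unloc_oskar_count,
              unloc_nanos_count = unloc_nanos_count,
              unit_intensity = unit_intensity,
              protein_intensity = protein_intensity,
              protein_intensity_sdlog = protein_intensity_sdlog,
              psf_sigma_um = psf_sigma_um, background = background,
              read_noise_sd = read_noise_sd,
              partner_offset_sd_um = partner_offset_sd_um,
              free_protein = free_protein, embryo_sdlog = embryo_sdlog,
              me31b_given_dcp1 = me31b_given_dcp1,
              pacman_given_dcp1 = pacman_given_dcp1,
              me31b_base = me31b_base, pacman_base = pacman_base,
              localized_fraction = localized_fraction, channels = channels,
              stages = stages, founder_species = founder_species,
              germ_species = germ_species, margin_um = margin_um,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  dims <- scene_dims(x)
  cat("<scene_config>\n")
  cat(sprintf("  field: %.1f x %.1f x %.1f um (%d x %d x %d voxels at %g/%g um)\n",
              x$field_um[["x"]], x$field_um[["y"]], x$field_um[["z"]],
              dims[["nx"]], dims[["ny"]], dims[["nz"]],
              x$pixel_um, x$z_step_um))
  cat(sprintf("  germ-plasm band: %.1f um; founder sites: %d; germ sites: %d\n",
              x$band_depth_um, x$n_founder, x$n_germ))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  stages: %s\n", paste(x$stages$stage, collapse = ", ")))
  invisible(x)
}

scene_dims <- function(config) {
  c(nz = max(2L, as.integer(round(config$field_um[["z"]] / config$z_step_um))),
    ny = as.integer(round(config$field_um[["y"]] / config$pixel_um)),
    nx = as.integer(round(config$field_um[["x"]] / config$pixel_um)))
}

#' Wild-type stage table (nuclear cycles 2-12)
#'
#' Per-stage parameters of the default wild-type scenario, encoding the
#' measured chronology of compartmentalized *oskar* degradation: DCP1
#' recruitment to founder granules rising from nc5 with Pacman delayed to
#' nc7; total germ-plasm *oskar* declining from nc7 (98% lost from the
#' pre- to the post-pole-cell-formation window); mean founder-granule size
#' declining from nc9; Staufen particle intensity declining from nc11;
#' unlocalized (bulk) *oskar* stable until a late decline, first reaching
#' significance at nc12; *nanos* flat throughout; and 5' probe signal lost
#' relative to 3' as degradation proceeds.
#'
#' Columns: `stage`; `total_mult` (true localized *oskar* total relative to
#' nc2); `size_mult` (granule transcript-count scale); `site_frac`
#' (fraction of founder sites still present; the product
#' `site_frac * oskar_given_site/0.9 * size_mult` equals `total_mult`);
#' `oskar_given_site`, `staufen_given_site` (occupancy of surviving sites);
#' `dcp1_coloc` (fraction of surviving founder sites carrying DCP1; Me31B
#' and Pacman attach conditionally on DCP1 through the scene-level
#' `me31b_given_dcp1`/`pacman_given_dcp1` probabilities, which delays the
#' Pacman marginal relative to DCP1); `staufen_size_mult`; `bulk_mult`
#' (unlocalized *oskar*); `nanos_mult`; `five_prime_intact`.
#'
#' @return a data.frame with one row per nuclear cycle nc2-nc12.
#' @export
stage_table_wildtype <- function() {
  stage <- paste0("nc", 2:12)
  total_mult <- c(1, 1, 1, 1, 0.90, 0.72, 0.55, 0.32, 0.12, 0.03, 0.01)
  size_mult  <- c(1, 1, 1, 1, 1,    1,    1,    0.55, 0.40, 0.30, 0.25)
  oskar_given_site <- c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.8, 0.65, 0.5)
  site_frac <- total_mult / (size_mult * oskar_given_site / 0.9)
  data.frame(
    stage = stage,
    total_mult = total_mult,
    size_mult = size_mult,
    site_frac = pmin(1, site_frac),
    oskar_given_site = oskar_given_site,
    staufen_given_site = c(0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95,
                           0.85, 0.80, 0.75),
    dcp1_coloc = c(0.02, 0.02, 0.02, 0.12, 0.20, 0.28, 0.35, 0.42, 0.48,
                   0.52, 0.55),
    staufen_size_mult = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0.60, 0.40),
    bulk_mult = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.60),
    nanos_mult = 1,
    five_prime_intact = c(1, 1, 1, 1, 0.85, 0.60, 0.50, 0.40, 0.40, 0.40,
                          0.40),
    stringsAsFactors = FALSE
  )
}

#' Stage table over collection windows
#'
#' Three stage windows used when embryos are staged by time after egg
#' laying rather than by nuclear cycle: before (nc2-5), during (nc6-10)
#' and after (nc11-12) pole cell formation. The localized totals encode a
#' 98% decrease of germ-plasm *oskar* from the pre- to the post-window.
#'
#' @return a data.frame in the [stage_table_wildtype()] layout.
#' @export
stage_table_windows <- function() {
  tab <- stage_table_wildtype()[c(1, 5, 10), ]
  tab$stage <- c("nc2-5", "nc6-10", "nc11-12")
  tab$total_mult <- c(1, 0.45, 0.02)
  tab$size_mult <- c(1, 0.9, 0.5)
  tab$oskar_given_site <- c(0.9, 0.9, 0.7)
  tab$site_frac <- tab$total_mult /
    (tab$size_mult * tab$oskar_given_site / 0.9)
  tab$staufen_given_site <- c(0.95, 0.95, 0.8)
  tab$dcp1_coloc <- c(0.02, 0.3, 0.5)
  tab$staufen_size_mult <- c(1, 1, 0.5)
  tab$bulk_mult <- c(1, 1, 0.7)
  tab$five_prime_intact <- c(1, 0.6, 0.4)
  rownames(tab) <- NULL
  tab
}

#' Named scenario configurations
#'
#' Returns a [scene_config()] parameterized for one of the study
#' scenarios. Genotype scenarios are generator parameterizations only; no
#' mechanistic model is implied.
#'
#' \describe{
#' \item{`wild-type`}{full nc2-nc12 stage table, *oskar* + *nanos* +
#'   DCP1 + Staufen channels.}
#' \item{`wild-type-windows`}{three collection windows encoding the 98%
#'   pre- to post-pole-cell-formation loss of germ-plasm *oskar*.}
#' \item{`tagged-reporter`}{two reporter mRNAs detected through a common
#'   tag: `og` (founder-granule-targeted, 90% loss across the windows) and
#'   `odgn` (germ-granule-targeted, flat).}
#' \item{`triple-dcp1`}{nc7 field with *oskar*, DCP1, Me31B and Pacman;
#'   Me31B and Pacman partner DCP1-positive founder sites with
#'   probabilities 0.77 and 0.49.}
#' \item{`staufen-nc8`}{nc8 field with Staufen, *oskar* and DCP1; DCP1
#'   occupies 35% of founder sites and 90% of surviving sites retain
#'   *oskar*.}
#' \item{`whole-embryo-early`}{early-stage field holding 18% of total
#'   *oskar* signal in the germ plasm, imaged without detectable dark
#'   counts, for localized-share measurement.}
#' \item{`decay-null`}{degradation-deficient genotype mimic: stage decay
#'   multipliers pinned at 1 and DCP1 partnering at chance.}
#' \item{`rescue`}{decay restored; identical stage table to `wild-type`.}
#' }
#'
#' @param name scenario name (see Details).
#' @param seed master seed stored in the configuration.
#' @param ... overrides passed on to [scene_config()].
#' @return a `scene_config`.
#' @export
scenario_config <- function(name = c("wild-type", "wild-type-windows",
                                     "tagged-reporter", "triple-dcp1",
                                     "staufen-nc8", "whole-embryo-early",
                                     "decay-null", "rescue"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    "wild-type" = list(channels = c("oskar", "nanos", "dcp1", "staufen"),
                       stages = stage_table_wildtype()),
    "rescue" = list(channels = c("oskar", "nanos", "dcp1", "staufen"),
                    stages = stage_table_wildtype()),
    "wild-type-windows" = list(channels = c("oskar", "nanos"),
                               stages = stage_table_windows()),
    "tagged-reporter" = {
      tab <- stage_table_windows()
      tab$total_mult <- c(1, 0.51, 0.10)
      tab$size_mult <- c(1, 0.85, 0.5)
      tab$site_frac <- tab$total_mult /
        (tab$size_mult * tab$oskar_given_site / 0.9)
      list(channels = c("og", "odgn"), stages = tab,
           founder_species = "og", germ_species = "odgn")
    },
    "triple-dcp1" = {
      tab <- stage_table_wildtype()[stage_table_wildtype()$stage == "nc7", ]
      tab$site_frac <- 1
      tab$size_mult <- 1
      tab$total_mult <- 0.9    # keeps per-granule sizes at full scale
      tab$dcp1_coloc <- 0.35
      list(channels = c("oskar", "dcp1", "me31b", "pacman"), stages = tab,
           n_founder = 90, n_germ = 0,
           field_um = c(x = 20, y = 20, z = 5.1))
    },
    "staufen-nc8" = {
      tab <- stage_table_wildtype()[stage_table_wildtype()$stage == "nc8", ]
      tab$site_frac <- 1
      tab$size_mult <- 1
      tab$total_mult <- 0.9
      tab$dcp1_coloc <- 0.35
      tab$oskar_given_site <- 0.90
      tab$staufen_given_site <- 1
      list(channels = c("oskar", "dcp1", "staufen"), stages = tab,
           n_founder = 55, n_germ = 0,
           field_um = c(x = 26, y = 26, z = 6.8))
    },
    "whole-embryo-early" = {
      tab <- stage_table_wildtype()[1, ]
      list(channels = "oskar", stages = tab, n_founder = 30, n_germ = 0,
           localized_fraction = 0.18, background = 0, read_noise_sd = 0,
           field_um = c(x = 16, y = 16, z = 5.1))
    },
    "decay-null" = {
      tab <- stage_table_wildtype()
      tab$total_mult <- 1
      tab$size_mult <- 1
      tab$site_frac <- 1
      tab$oskar_given_site <- 0.9
      tab$dcp1_coloc <- 0.02
      tab$staufen_size_mult <- 1
      tab$five_prime_intact <- 1
      list(channels = c("oskar", "nanos", "dcp1", "staufen"), stages = tab)
    })
  args$seed <- seed
  overrides <- list(...)
  args[names(overrides)] <- overrides
  cfg <- do.call(scene_config, args)
  attr(cfg, "scenario") <- name
  cfg
}

#' Configuration of a synthetic granule-motility movie
#'
#' Two-dimensional time-lapse of a mixed granule population: a directed
#' population moving toward nucleus positions (germ-granule-like motility)
#' and a confined population tethered in place (founder-granule-like).
#' Defaults follow spinning-disc acquisition of this system: 5 frames per
#' second for 600 frames.
#'
#' @param frame_interval_s seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param field_um named vector `c(x=, y=)`.
#' @param n_particles particles per population draw.
#' @param directed_fraction fraction of particles in the directed
#'   population; the rest are confined. Must sum to <= 1 with any other
#'   populations.
#' @param speed_um_s directed speed toward the nearest nucleus.
#' @param n_nuclei number of nucleus target points.
#' @param tether_rate_s confinement relaxation rate (per second) pulling a
#'   confined particle back to its tether point.
#' @param jitter_sd_um per-frame positional jitter sd of confined
#'   particles.
#' @param directed_jitter_sd_um per-frame jitter added to directed motion.
#' @param loc_noise_sd_um localization error sd applied to observed (not
#'   true) positions.
#' @param seed master seed.
#' @return an object of class `motion_config`.
#' @export
motion_config <- function(frame_interval_s = 0.2,
                          n_frames = 600L,
                          field_um = c(x = 20, y = 20),
                          n_particles = 80L,
                          directed_fraction = 0.5,
                          speed_um_s = 0.30,
                          n_nuclei = 3L,
                          tether_rate_s = 5,
                          jitter_sd_um = 0.03,
                          directed_jitter_sd_um = 0.01,
                          loc_noise_sd_um = 0.02,
                          nuclei = NULL,
                          seed = 1L) {
  stopifnot_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (n_frames < 2) stop("a movie needs at least 2 frames")
  check_fraction(directed_fraction, "directed_fraction")
  cfg <- list(frame_interval_s = frame_interval_s,
              n_frames = as.integer(n_frames), field_um = field_um,
              n_particles = as.integer(n_particles),
              directed_fraction = directed_fraction,
              speed_um_s = speed_um_s, n_nuclei = as.integer(n_nuclei),
              tether_rate_s = tether_rate_s, jitter_sd_um = jitter_sd_um,
              directed_jitter_sd_um = directed_jitter_sd_um,
              loc_noise_sd_um = loc_noise_sd_um, nuclei = nuclei,
              seed = as.integer(seed))
  class(cfg) <- "motion_config"
  cfg
}
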