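# Internal single-molecule intensity calibration and derived statistics.
#
# Unlocalized particles in the bulk cytoplasm carry a known average
# transcript load (nanos: 1, oskar: 2), so their mean intensity fixes the
# photons-per-transcript scale of each image. Calibration is strictly
# per-stack: it internally normalizes every image, making transcript
# counts invariant to global intensity rescaling and allowing direct
# comparison across embryos and experiments.

ASSUMED_TRANSCRIPTS <- c(nanos = 1, oskar = 2)

# Two-sample t-test p-value that tolerates degenerate (constant) samples:
# identical constant groups are maximally compatible (p = 1); constant
# groups with different means are incompatible (p = 0).
safe_t_p <- function(x, y, welch = FALSE) {
  if (stats::sd(c(x, y)) == 0) return(1)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  tryCatch(stats::t.test(x, y, var.equal = !welch)$p.value,
           error = function(e) NA_real_)
}

#' Calibrate photons-per-transcript from unlocalized particles
#'
#' @param unlocalized data.frame of particles (from [detect_particles()])
#'   drawn from the bulk-cytoplasm region of a single stack.
#' @param species species label; `"nanos"` and `"oskar"` carry assumed
#'   average loads of 1 and 2 transcripts per unlocalized particle. Other
#'   labels require `assumed_transcripts`.
#' @param assumed_transcripts override for the assumed average transcripts
#'   per unlocalized particle.
#' @param min_n minimum number of calibration particles (default 20).
#' @return an object of class `calibration_result`: species, mean
#'   unlocalized intensity, assumed transcripts, `photons_per_transcript`,
#'   `n`, and the stack identifier.
#' @export
calibrate <- function(unlocalized, species, assumed_transcripts = NULL,
                      min_n = 20) {
  if (is.null(assumed_transcripts)) {
    if (!species %in% names(ASSUMED_TRANSCRIPTS))
      stop(sprintf("no assumed transcript load for species '%s'; %s",
                   species, "supply assumed_transcripts"))
    assumed_transcripts <- ASSUMED_TRANSCRIPTS[[species]]
  }
  stack_id <- unique(paste(unlocalized$embryo, unlocalized$stage))
  if (length(stack_id) > 1)
    stop("calibration is strictly per-image; particles span several stacks")
  n <- nrow(unlocalized)
  if (n < min_n)
    stop(sprintf("only %d calibration particles in stack '%s' (minimum %d)",
                 n, stack_id, min_n))
  mean_int <- mean(unlocalized$intensity)
  if (!is.finite(mean_int) || mean_int <= 0)
    stop(sprintf("zero mean unlocalized intensity in stack '%s'", stack_id))
  structure(list(species = species, mean_unlocalized = mean_int,
                 assumed_transcripts = assumed_transcripts,
                 photons_per_transcript = mean_int / assumed_transcripts,
                 n = n, stack_id = stack_id),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration> %s: %.1f photons/transcript (%d unlocalized particles, %s)\n",
    x$species, x$photons_per_transcript, x$n, x$stack_id))
  invisible(x)
}

#' Assign transcript counts to particles via a calibration
#'
#' @param particles particle data.frame from the same stack as the
#'   calibration.
#' @param calibration a [calibrate()] result.
#' @param bins transcript-count bin edges used for the `size_bin` column.
#' @return the particle frame with `count` (continuous, >= 0) and
#'   `size_bin` columns appended.
#' @export
assign_transcript_counts <- function(particles, calibration,
                                     bins = size_bins_default()) {
  particles$count <- particles$intensity / calibration$photons_per_transcript
  particles$size_bin <- cut(particles$count, breaks = bins, right = FALSE,
                            include.lowest = FALSE)
  particles
}

#' Default transcript-count bin edges
#'
#' Bins used for granule size distributions and size-binned
#' colocalization; edges are configurable everywhere they are consumed.
#' @return numeric vector of edges.
#' @export
size_bins_default <- function() c(1, 2, 5, 10, 50, Inf)

#' Granule size distribution
#'
#' Per-bin proportions of transcripts-per-particle, plus the mean
#' transcripts per particle with its standard error across embryos (the
#' per-embryo mean is the statistical unit for the mean; per-particle
#' pooling is used for the distribution itself).
#'
#' @param particles calibrated particles (single species).
#' @param bins bin edges.
#' @return a list of class `size_distribution`: `bins`, `proportions`
#'   (sums to 1), `n_particles`, `n_embryos`, `mean_count`,
#'   `sem_count` (across embryos).
#' @export
size_distribution <- function(particles, bins = size_bins_default()) {
  if (nrow(particles) == 0) stop("no particles to bin")
  if ("species" %in% names(particles) &&
      length(unique(particles$species)) > 1)
    stop("size distributions are per species")
  cb <- cut(particles$count, breaks = bins, right = FALSE)
  tab <- table(cb)
  per_embryo <- tapply(particles$count, particles$embryo, mean)
  structure(list(bins = bins, proportions = as.numeric(tab) / sum(tab),
                 bin_labels = names(tab), n_particles = nrow(particles),
                 n_embryos = length(per_embryo),
                 mean_count = mean(per_embryo),
                 sem_count = stats::sd(per_embryo) /
                   sqrt(length(per_embryo))),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d particles, %d embryos, mean %.1f +/- %.1f transcripts\n",
              x$n_particles, x$n_embryos, x$mean_count,
              ifelse(is.na(x$sem_count), 0, x$sem_count)))
  print(stats::setNames(round(x$proportions, 3), x$bin_labels))
  invisible(x)
}

#' Stage-resolved abundance time course with baseline-normalized means
#'
#' Normalizes per-embryo totals to the baseline-stage mean and tests each
#' stage against baseline with a two-sided two-sample Student's t-test
#' (pooled variance by default, mirroring the figure conventions of this
#' analysis; per-comparison alpha, no multiple-testing correction; Welch
#' available via `welch = TRUE`).
#'
#' @param measurements data.frame with columns `stage`, `embryo`, `total`.
#' @param baseline baseline stage label.
#' @param stage_order optional stage ordering; defaults to order of first
#'   appearance.
#' @param spread `"sd"` or `"sem"` for the reported spread.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return an object of class `timecourse`: a data.frame (`stage`, `n`,
#'   `mean_total`, `norm_mean` relative to baseline, `spread`, `p_value`
#'   vs baseline) with the baseline row's `norm_mean` exactly 1.
#' @export
abundance_timecourse <- function(measurements, baseline,
                                 stage_order = NULL, spread = c("sd", "sem"),
                                 welch = FALSE) {
  spread <- match.arg(spread)
  if (!baseline %in% measurements$stage)
    stop(sprintf("baseline stage '%s' has no data", baseline))
  stage_order <- stage_order %||% unique(measurements$stage)
  base <- measurements$total[measurements$stage == baseline]
  if (length(base) < 2)
    stop("need >= 2 embryos at the baseline stage")
  rows <- lapply(stage_order, function(st) {
    v <- measurements$total[measurements$stage == st]
    p <- if (st == baseline) 1 else safe_t_p(v, base, welch)
    sp <- if (spread == "sd") stats::sd(v) else
      stats::sd(v) / sqrt(length(v))
    data.frame(stage = st, n = length(v), mean_total = mean(v),
               norm_mean = mean(v) / mean(base), spread = sp / mean(base),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  attr(out, "spread") <- spread
  class(out) <- c("timecourse", "data.frame")
  out
}

#' Percent decrease between two stages of a time course
#'
#' `100 * (1 - late/early)` on the stage means.
#'
#' @param tc a [abundance_timecourse()] result.
#' @param early,late stage labels.
#' @return percent decrease (negative values mean an increase).
#' @export
percent_decrease <- function(tc, early, late) {
  e <- tc$mean_total[tc$stage == early]
  l <- tc$mean_total[tc$stage == late]
  if (length(e) != 1 || length(l) != 1) stop("stage not found in time course")
  100 * (1 - l / e)
}

#' Per-particle 5':3' transcript-integrity ratios
#'
#' For particles detected in the 3' probe channel with the 5' intensity
#' measured at the same centroid (see [measure_at()]; independent 5'
#' detection would drop degraded particles and bias ratios upward),
#' computes per-particle 5'/3' intensity ratios rescaled so the
#' early-reference group mean is 1, and compares stages within size
#' classes by Student's t-test on per-embryo means.
#'
#' @param particles data.frame with `intensity` (3' channel),
#'   `intensity_5p`, `count` (calibrated), `stage`, `embryo`.
#' @param reference_stage stage whose mean ratio defines 1.
#' @param size_cut transcript count separating smaller from larger
#'   particles.
#' @param welch use Welch's t-test.
#' @return a list of class `ratio53_result`: `particles` (with `ratio`
#'   and `size_class`), `excluded_n` (3' intensity <= 0), `group_means`
#'   (stage x size class), `tests` (stage vs reference within size class).
#' @export
ratio_5to3 <- function(particles, reference_stage, size_cut = 10,
                       welch = FALSE) {
  excl <- particles$intensity <= 0
  p <- particles[!excl, , drop = FALSE]
  p$ratio_raw <- p$intensity_5p / p$intensity
  ref <- p$ratio_raw[p$stage == reference_stage]
  if (length(ref) == 0) stop("reference stage absent")
  p$ratio <- p$ratio_raw / mean(ref)
  p$size_class <- ifelse(p$count >= size_cut, "larger", "smaller")
  gm <- stats::aggregate(ratio ~ stage + size_class, data = p, FUN = mean)
  per_embryo <- stats::aggregate(ratio ~ stage + size_class + embryo,
                                 data = p, FUN = mean)
  tests <- list()
  for (sc in unique(per_embryo$size_class)) {
    base <- per_embryo$ratio[per_embryo$size_class == sc &
                               per_embryo$stage == reference_stage]
    for (st in setdiff(unique(per_embryo$stage), reference_stage)) {
      v <- per_embryo$ratio[per_embryo$size_class == sc &
                              per_embryo$stage == st]
      if (length(v) >= 2 && length(base) >= 2) {
        tt <- stats::t.test(v, base, var.equal = !welch)
        tests[[paste(sc, st)]] <- data.frame(
          size_class = sc, stage = st, mean_ratio = mean(v),
          p_value = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(particles = p, excluded_n = sum(excl), group_means = gm,
                 tests = do.call(rbind, tests),
                 reference_stage = reference_stage, size_cut = size_cut),
            class = "ratio53_result")
}
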