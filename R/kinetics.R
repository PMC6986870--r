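# Stage-resolved comparative analyses: onset ordering of degradation
# events, germ plasm vs bulk timing, and scenario orchestration.

#' Onset analysis of stage-resolved statistics
#'
#' For each named statistic (a data.frame of per-embryo values by stage),
#' finds the earliest stage whose two-sided Student's t-test against the
#' baseline stage is significant at `alpha` and whose direction of change
#' matches the overall trend direction (the sign of the change at the last
#' stage); isolated significant blips in the opposite direction are not
#' onsets. Statistics with no significant stage report onset `"none"`.
#'
#' @param timecourses named list of data.frames with columns `stage`,
#'   `embryo`, `value`.
#' @param baseline baseline stage label.
#' @param alpha per-comparison significance level (no multiple-testing
#'   correction, mirroring the per-stage figure conventions).
#' @param stage_order stage ordering; defaults to order of appearance in
#'   the first statistic.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return an object of class `onset_report`: data.frame (`statistic`,
#'   `onset`, `onset_index`, `direction`, `p_at_onset`) ordered by onset
#'   stage, plus the per-stage p-value matrix in `attr(, "p_values")`.
#' @export
onset_analysis <- function(timecourses, baseline, alpha = 0.05,
                           stage_order = NULL, welch = FALSE) {
  stopifnot(length(names(timecourses)) == length(timecourses))
  stage_order <- stage_order %||% unique(timecourses[[1]]$stage)
  pmat <- matrix(NA_real_, length(timecourses), length(stage_order),
                 dimnames = list(names(timecourses), stage_order))
  rows <- lapply(names(timecourses), function(nm) {
    tc <- timecourses[[nm]]
    if (!baseline %in% tc$stage)
      stop(sprintf("statistic '%s' has no baseline data", nm))
    base <- tc$value[tc$stage == baseline]
    dirs <- ps <- stats::setNames(rep(NA_real_, length(stage_order)),
                                  stage_order)
    for (st in setdiff(stage_order, baseline)) {
      v <- tc$value[tc$stage == st]
      if (length(v) < 2 || length(base) < 2) next
      ps[st] <- safe_t_p(v, base, welch)
      dirs[st] <- sign(mean(v) - mean(base))
    }
    pmat[nm, ] <<- ps
    trend <- dirs[max(which(!is.na(dirs)))]
    sig <- which(!is.na(ps) & ps <= alpha & dirs == trend)
    if (length(sig) == 0)
      data.frame(statistic = nm, onset = "none", onset_index = NA_integer_,
                 direction = NA_real_, p_at_onset = NA_real_,
                 stringsAsFactors = FALSE)
    else {
      i <- min(sig)
      data.frame(statistic = nm, onset = stage_order[i], onset_index = i,
                 direction = dirs[i], p_at_onset = ps[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_index), ]
  rownames(out) <- NULL
  attr(out, "p_values") <- pmat
  attr(out, "baseline") <- baseline
  attr(out, "alpha") <- alpha
  class(out) <- c("onset_report", "data.frame")
  out
}

#' Compare degradation onset between compartments
#'
#' Onset of the first significant change in the germ plasm versus the
#' bulk cytoplasm, plus the onset gap in stages (positive when the germ
#' plasm changes first).
#'
#' @param germ_plasm,bulk data.frames with `stage`, `embryo`, `value`
#'   sharing the stage axis.
#' @param baseline baseline stage.
#' @param alpha significance level.
#' @param ... passed to [onset_analysis()].
#' @return list: `onsets` (an `onset_report`), `gap_stages` (bulk onset
#'   index minus germ-plasm onset index; `NA` if either onset is
#'   `"none"`).
#' @export
compare_compartments <- function(germ_plasm, bulk, baseline, alpha = 0.05,
                                 ...) {
  rep <- onset_analysis(list(germ_plasm = germ_plasm, bulk = bulk),
                        baseline, alpha, ...)
  gi <- rep$onset_index[rep$statistic == "germ_plasm"]
  bi <- rep$onset_index[rep$statistic == "bulk"]
  list(onsets = rep, gap_stages = bi - gi)
}

#' Run a full synthetic scenario through the pipeline
#'
#' Executes generate -> detect -> calibrate -> colocalize -> kinetics for
#' every stage and pseudo-embryo of a scenario and assembles the report
#' bundle: per-embryo measurement tables, baseline-normalized time
#' courses, onset report, and (when the scenario carries the relevant
#' channels) conditional colocalization fractions. Bit-reproducible for a
#' given `(config, seed)`.
#'
#' @param config a [scene_config()], typically from [scenario_config()].
#' @param seed master seed (overrides the seed in `config`).
#' @param n_embryos pseudo-embryos per stage.
#' @param stages stages to run (default: all in the config).
#' @param detect run particle detection (needed for size/colocalization
#'   measures; projection and ROI measures work without it).
#' @param alpha significance level for the onset report.
#' @param threshold_um colocalization distance threshold. The default
#'   (0.40 um) matches the error budget of two independently registered
#'   channels: 80 nm per-axis registration offset per channel plus
#'   centroid localization error, dominated by the coarse axial sampling.
#' @param granule_min_count founder-granule definition for the
#'   mean-particle-size statistic: particles below this calibrated
#'   transcript count (unlocalized mRNAs lying inside the band) are not
#'   granules and are excluded from the size time course.
#' @param out_dir if non-`NULL`, tables are exported there as CSV plus a
#'   JSON summary (see [export_tables()]).
#' @param params detection settings.
#' @return a list of class `scenario_report`.
#' @export
run_scenario <- function(config, seed = config$seed, n_embryos = 5,
                         stages = config$stages$stage, detect = TRUE,
                         alpha = 0.05, threshold_um = 0.40,
                         granule_min_count = 3,
                         out_dir = NULL, params = detection_params()) {
  sp_f <- config$founder_species
  band_lo <- config$field_um[["y"]] - config$band_depth_um
  has <- function(ch) ch %in% config$channels
  meas <- list()
  cond <- list()
  particles_all <- list()
  add <- function(lst, nm, stage, embryo, value) {
    lst[[length(lst) + 1L]] <- data.frame(statistic = nm, stage = stage,
                                          embryo = embryo, value = value,
                                          stringsAsFactors = FALSE)
    lst
  }
  for (st in stages) {
    for (e in seq_len(n_embryos)) {
      emb <- sprintf("e%02d", e)
      sim <- render_stack(config, st, embryo = emb, seed = seed)
      stk <- sim$stack
      ext <- stack_extent(stk)
      # total localized signal: sum projection restricted to the band
      tot <- measure_projection_intensity(stk, sp_f,
                                          roi_y = c(band_lo, ext[["y"]]))
      meas <- add(meas, "total_intensity", st, emb, tot$total)
      if (has(config$germ_species)) {
        totg <- measure_projection_intensity(stk, config$germ_species,
                                             roi_y = c(band_lo, ext[["y"]]))
        meas <- add(meas, "germ_species_total", st, emb, totg$total)
      }
      # per-volume densities for compartment comparison
      meas <- add(meas, "gp_density", st, emb,
                  measure_roi_density(stk, sp_f,
                                      roi = list(y = c(band_lo,
                                                       ext[["y"]]))))
      meas <- add(meas, "bulk_density", st, emb,
                  measure_roi_density(stk, sp_f,
                                      roi = list(y = c(0, band_lo - 0.5))))
      if (!detect) next
      det <- detect_particles(stk, sp_f, params)
      gp <- det[det$y_um >= band_lo, , drop = FALSE]
      unloc <- det[det$y_um < band_lo, , drop = FALSE]
      if (nrow(unloc) >= 20 && nrow(gp) > 0) {
        cal <- calibrate(unloc, "oskar")
        gp <- assign_transcript_counts(gp, cal)
        gran <- gp$count[gp$count >= granule_min_count]
        if (length(gran) > 0)
          meas <- add(meas, "mean_particle_size", st, emb, mean(gran))
        particles_all[[paste(st, emb)]] <- gp
      }
      if (has("dcp1")) {
        det_d <- detect_particles(stk, "dcp1", params)
        cc <- colocalize(gp, det_d, threshold_um, n_control = 0)
        meas <- add(meas, "dcp1_coloc", st, emb, cc$fraction_ref)
        if (has("me31b")) {
          det_m <- detect_particles(stk, "me31b", params)
          cond[[length(cond) + 1L]] <- data.frame(
            stage = st, embryo = emb, query = "me31b",
            fraction = conditional_coloc(gp, det_d, det_m,
                                         threshold_um)$fraction_ref,
            stringsAsFactors = FALSE)
        }
        if (has("pacman")) {
          det_p <- detect_particles(stk, "pacman", params)
          cc_p <- colocalize(gp, det_p, threshold_um, n_control = 0)
          meas <- add(meas, "pacman_coloc", st, emb, cc_p$fraction_ref)
          cond[[length(cond) + 1L]] <- data.frame(
            stage = st, embryo = emb, query = "pacman",
            fraction = conditional_coloc(gp, det_d, det_p,
                                         threshold_um)$fraction_ref,
            stringsAsFactors = FALSE)
        }
        if (has("staufen")) {
          det_s <- detect_particles(stk, "staufen", params)
          det_s <- det_s[det_s$y_um >= band_lo, , drop = FALSE]
          meas <- add(meas, "staufen_mean_intensity", st, emb,
                      mean(det_s$intensity))
          cc_so <- colocalize(det_s, det[, , drop = FALSE], threshold_um,
                              n_control = 0)
          meas <- add(meas, "staufen_oskar_coloc", st, emb,
                      cc_so$fraction_ref)
        }
      } else if (has("staufen")) {
        det_s <- detect_particles(stk, "staufen", params)
        det_s <- det_s[det_s$y_um >= band_lo, , drop = FALSE]
        meas <- add(meas, "staufen_mean_intensity", st, emb,
                    mean(det_s$intensity))
      }
    }
  }
  meas <- do.call(rbind, meas)
  cond <- if (length(cond)) do.call(rbind, cond) else NULL
  baseline <- stages[1]
  tc_list <- split(meas[, c("stage", "embryo", "value")], meas$statistic)
  tc_list <- lapply(tc_list, function(d) { rownames(d) <- NULL; d })
  tc_total <- abundance_timecourse(
    data.frame(stage = meas$stage[meas$statistic == "total_intensity"],
               embryo = meas$embryo[meas$statistic == "total_intensity"],
               total = meas$value[meas$statistic == "total_intensity"]),
    baseline = baseline, stage_order = stages)
  onset_stats <- intersect(c("dcp1_coloc", "total_intensity",
                             "mean_particle_size", "staufen_mean_intensity",
                             "pacman_coloc", "staufen_oskar_coloc"),
                           names(tc_list))
  onsets <- if (length(onset_stats) >= 1 && length(stages) >= 3)
    onset_analysis(tc_list[onset_stats], baseline, alpha,
                   stage_order = stages) else NULL
  bundle <- list(scenario = attr(config, "scenario") %||% "custom",
                 seed = seed, stages = stages, n_embryos = n_embryos,
                 measurements = meas, conditional = cond,
                 timecourse_total = tc_total, timecourses = tc_list,
                 onsets = onsets, alpha = alpha,
                 threshold_um = threshold_um,
                 particles = particles_all)
  class(bundle) <- "scenario_report"
  if (!is.null(out_dir)) export_scenario_report(bundle, out_dir)
  bundle
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> '%s', seed %d: %d stages x %d embryos\n",
              x$scenario, x$seed, length(x$stages), x$n_embryos))
  cat("normalized total-intensity time course:\n")
  print(as.data.frame(x$timecourse_total)[, c("stage", "norm_mean",
                                              "p_value")])
  if (!is.null(x$onsets)) {
    cat(sprintf("onsets (alpha = %g, baseline %s):\n", x$alpha,
                attr(x$onsets, "baseline")))
    print(as.data.frame(x$onsets))
  }
  invisible(x)
}

#' Deterministic digest of a report bundle
#'
#' MD5 of the serialized bundle; identical `(scenario, seed)` runs give
#' identical hashes.
#'
#' @param report any R object.
#' @return character MD5 digest.
#' @export
report_hash <- function(report) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(report, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
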