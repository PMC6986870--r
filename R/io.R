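# File formats and run configuration.
#
# Images are written as multi-page 32-bit float TIFF (page order CZYX for
# stacks, TYX for movies) with an XML sidecar (<file>.xml) declaring axis
# order, voxel spacing in micrometres, channel labels, acquisition
# metadata and the intensity scale used to fit photon counts into the
# float range. Tables are CSV with a schema-version comment line;
# physical columns carry unit suffixes (_um, _s).

TABLE_SCHEMA <- "granulytics table schema 1.0"

stack_meta_xml <- function(axes, spacing_um, channels, scale, stage = NA,
                           embryo = NA, region = NA, frame_interval_s = NA) {
  paste0(
    "<granulytics-image version=\"1.0\">",
    sprintf("<axes>%s</axes>", axes),
    sprintf("<spacing z=\"%.17g\" y=\"%.17g\" x=\"%.17g\"/>",
            spacing_um[["z"]] %||% NA, spacing_um[["y"]] %||% NA,
            spacing_um[["x"]] %||% NA),
    sprintf("<channels>%s</channels>", paste(channels, collapse = ",")),
    sprintf("<scale>%.17g</scale>", scale),
    sprintf("<stage>%s</stage>", stage),
    sprintf("<embryo>%s</embryo>", embryo),
    sprintf("<region>%s</region>", region),
    sprintf("<frameInterval>%.17g</frameInterval>", frame_interval_s),
    "</granulytics-image>")
}

parse_meta_xml <- function(path) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_first(doc, "spacing")
  getnum <- function(x) suppressWarnings(as.numeric(x))
  list(axes = xml2::xml_text(xml2::xml_find_first(doc, "axes")),
       spacing_um = c(z = getnum(xml2::xml_attr(sp, "z")),
                      y = getnum(xml2::xml_attr(sp, "y")),
                      x = getnum(xml2::xml_attr(sp, "x"))),
       channels = strsplit(xml2::xml_text(
         xml2::xml_find_first(doc, "channels")), ",")[[1]],
       scale = getnum(xml2::xml_text(xml2::xml_find_first(doc, "scale"))),
       stage = xml2::xml_text(xml2::xml_find_first(doc, "stage")),
       embryo = xml2::xml_text(xml2::xml_find_first(doc, "embryo")),
       region = xml2::xml_text(xml2::xml_find_first(doc, "region")),
       frame_interval_s = getnum(xml2::xml_text(
         xml2::xml_find_first(doc, "frameInterval"))))
}

#' Write an image stack (or movie) to multi-page float TIFF
#'
#' Page order is CZYX for stacks (channels outer, z inner). A 2D movie
#' (list of matrices) is written as TYX. Intensities are rescaled into
#' `[0, 1]` for 32-bit float storage; the scale factor, axis order, voxel
#' spacing and channel labels go into an XML sidecar at `<path>.xml`.
#'
#' @param stack an [image_stack()], or a list of 2D matrices (frames) for
#'   a movie.
#' @param path output TIFF path.
#' @param frame_interval_s stored for movies.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, frame_interval_s = NA) {
  if (inherits(stack, "image_stack")) {
    pages <- list()
    for (ch in names(stack$data)) {
      a <- stack$data[[ch]]
      for (z in seq_len(dim(a)[1])) pages[[length(pages) + 1L]] <- a[z, , ]
    }
    scale <- max(1, max(vapply(pages, max, numeric(1))))
    meta <- stack_meta_xml("CZYX", stack$spacing_um, names(stack$data),
                           scale, stack$stage, stack$embryo, stack$region)
  } else if (is.list(stack) && is.matrix(stack[[1]])) {
    pages <- stack
    scale <- max(1, max(vapply(pages, max, numeric(1))))
    meta <- stack_meta_xml("TYX", c(z = NA, y = NA, x = NA), "movie",
                           scale, frame_interval_s = frame_interval_s)
  } else stop("unsupported image object")
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  writeLines(meta, paste0(path, ".xml"))
  invisible(path)
}

#' Read an image stack or movie written by [write_stack()]
#'
#' Resolves axis order, voxel spacing and channel labels from the XML
#' sidecar; `spacing_um` overrides (or supplies, with a message) the
#' spacing. A stack lacking spacing metadata without an override is an
#' error, never a silent default. TYX files are returned as a `movie`
#' list of frames with the time axis recognized.
#'
#' @param path TIFF path.
#' @param spacing_um optional named override `c(z=, y=, x=)`.
#' @return an [image_stack()], or for movies a list of class `movie`
#'   with `frames` and `frame_interval_s`.
#' @export
read_stack <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".xml")
  meta <- if (file.exists(meta_path)) parse_meta_xml(meta_path) else NULL
  axes <- meta$axes %||% "CZYX"
  scale <- meta$scale %||% 1
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # tolerate grayscale-as-RGB
    p * scale
  })
  if (identical(axes, "TYX")) {
    return(structure(list(frames = pages,
                          frame_interval_s = meta$frame_interval_s),
                     class = "movie"))
  }
  if (!identical(axes, "CZYX"))
    stop(sprintf("ambiguous or unsupported axis order '%s'", axes))
  channels <- meta$channels %||% "channel1"
  nz <- length(pages) / length(channels)
  if (nz != round(nz)) stop("page count is not a multiple of channel count")
  sp <- spacing_um
  if (is.null(sp)) {
    sp <- meta$spacing_um
    if (is.null(sp) || any(is.na(sp)))
      stop("stack has no voxel spacing metadata; supply spacing_um")
  } else {
    message(sprintf("using spacing override (z=%g, y=%g, x=%g um)",
                    sp[["z"]], sp[["y"]], sp[["x"]]))
  }
  data <- list()
  for (i in seq_along(channels)) {
    zs <- pages[((i - 1) * nz + 1):(i * nz)]
    a <- array(0, c(nz, nrow(zs[[1]]), ncol(zs[[1]])))
    for (z in seq_len(nz)) a[z, , ] <- zs[[z]]
    data[[channels[i]]] <- a
  }
  image_stack(data, sp, stage = meta$stage %||% NA_character_,
              embryo = meta$embryo %||% NA_character_,
              region = meta$region %||% "whole field")
}

#' Export result tables as schema-versioned CSV
#'
#' One file per table, first line a `#`-prefixed schema-version comment,
#' reproducible column order, one row per record. Existing files are an
#' error unless `overwrite = TRUE`.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param overwrite allow clobbering existing files.
#' @return character vector of paths, invisibly.
#' @export
export_tables <- function(tables, dir, overwrite = FALSE) {
  stopifnot(length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p) && !overwrite)
      stop(sprintf("'%s' exists; use overwrite = TRUE", p))
    con <- file(p, "w")
    writeLines(paste0("# ", TABLE_SCHEMA), con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a table written by [export_tables()]
#' @param path CSV path.
#' @return data.frame.
#' @export
import_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#"))
    stop("missing schema-version header line")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

export_scenario_report <- function(bundle, dir, overwrite = FALSE) {
  tabs <- list(measurements = bundle$measurements,
               timecourse_total = as.data.frame(bundle$timecourse_total))
  if (!is.null(bundle$conditional)) tabs$conditional <- bundle$conditional
  if (!is.null(bundle$onsets)) tabs$onsets <- as.data.frame(bundle$onsets)
  export_tables(tabs, dir, overwrite = overwrite)
  summary <- list(scenario = bundle$scenario, seed = bundle$seed,
                  stages = bundle$stages, n_embryos = bundle$n_embryos,
                  alpha = bundle$alpha, threshold_um = bundle$threshold_um,
                  normalized_totals = stats::setNames(
                    bundle$timecourse_total$norm_mean,
                    bundle$timecourse_total$stage),
                  p_values = stats::setNames(
                    bundle$timecourse_total$p_value,
                    bundle$timecourse_total$stage))
  if (!is.null(bundle$onsets))
    summary$onsets <- stats::setNames(bundle$onsets$onset,
                                      bundle$onsets$statistic)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

RUN_CONFIG_KEYS <- c("scenario", "seed", "out_dir", "n_embryos", "stages",
                     "detection", "colocalization", "tracking", "statistics",
                     "log_level")

#' Read and validate a run configuration (YAML or JSON)
#'
#' Schema-validated before any computation; unknown keys are rejected.
#' Recognized blocks: `scenario`, `seed`, `out_dir`, `n_embryos`,
#' `stages`, `detection` (`threshold_sd`), `colocalization`
#' (`threshold_um`), `tracking` (`max_disp_um`, `min_track_length`),
#' `statistics` (`alpha`, `welch`), `log_level`.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON"))
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  if (!is.null(cfg$seed)) stopifnot_scalar(cfg$seed, "seed")
  if (!is.null(cfg$n_embryos))
    stopifnot_scalar(cfg$n_embryos, "n_embryos", positive = TRUE)
  if (!is.null(cfg$colocalization$threshold_um))
    stopifnot_scalar(cfg$colocalization$threshold_um, "threshold_um",
                     positive = TRUE)
  if (!is.null(cfg$statistics$alpha))
    check_fraction(cfg$statistics$alpha, "alpha")
  class(cfg) <- "run_config"
  cfg
}
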