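#' Multi-channel 3D image stack with physical metadata
#'
#' The central image container: one 3D voxel array per channel (photon
#' counts, dimension order z, y, x), voxel spacing in micrometres, and
#' acquisition metadata. Voxel indices are 0-based in all physical
#' coordinate conversions; the physical coordinate of voxel `i` along an
#' axis with spacing `d` is the voxel center `(i + 0.5) * d`, so the field
#' spans `[0, n * d]` micrometres.
#'
#' @param data named list of 3D numeric arrays (z, y, x), one per channel;
#'   all the same dimension. A single array is accepted and wrapped.
#' @param spacing_um named vector `c(z=, y=, x=)` of voxel spacing.
#' @param stage stage label (nuclear cycle or collection window).
#' @param embryo embryo identifier.
#' @param region region tag: `"germ plasm"`, `"bulk cytoplasm"` or
#'   `"whole field"`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, spacing_um, stage = NA_character_,
                        embryo = NA_character_, region = "whole field") {
  if (is.array(data)) data <- list(channel1 = data)
  if (is.null(names(data)) || anyDuplicated(names(data)))
    stop("channel labels must be present and unique")
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array (z, y, x)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share dimensions")
  if (any(vapply(data, function(a) any(a < 0), TRUE)))
    stop("voxel values must be non-negative")
  spacing_um <- spacing_um[c("z", "y", "x")]
  if (any(is.na(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be positive and named (z, y, x)")
  structure(list(data = data, spacing_um = spacing_um, stage = stage,
                 embryo = embryo, region = region),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              length(x$data), paste(names(x$data), collapse = ", "),
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3f x %.3f x %.3f um; stage: %s; embryo: %s; region: %s\n",
              x$spacing_um[["z"]], x$spacing_um[["y"]], x$spacing_um[["x"]],
              x$stage, x$embryo, x$region))
  invisible(x)
}

#' Physical extent of a stack
#' @param stack an [image_stack()].
#' @return named vector `c(z=, y=, x=)` of field size in micrometres.
#' @export
stack_extent <- function(stack) {
  stats::setNames(dim(stack$data[[1]]) * stack$spacing_um, c("z", "y", "x"))
}

channel_array <- function(stack, channel) {
  if (!channel %in% names(stack$data))
    stop(sprintf("channel '%s' not present in stack (has: %s)", channel,
                 paste(names(stack$data), collapse = ", ")))
  stack$data[[channel]]
}
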