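# Diffraction-limited particle detection in 3D stacks.
#
# Operator: Laplacian-of-Gaussian band-pass at the PSF scale, local maxima
# in the 26-neighborhood, threshold in robust-sd-above-background units.
# Integrated intensities are background-subtracted sums over an anisotropic
# 3-sigma ellipsoid aperture; the same aperture feeds the intensity-weighted
# sub-voxel centroid.

#' Detection settings
#'
#' @param threshold_sd peak threshold in robust standard deviations of the
#'   band-pass response above zero (the response of flat background).
#' @param psf_sigma_um PSF sigmas, named `c(lateral=, axial=)`; sets the
#'   band-pass scale, the 3-sigma measurement aperture and the merge
#'   radius.
#' @param merge_radius_um maxima closer than this are reported as one
#'   particle (brightest kept); default 2 lateral sigma.
#' @param min_intensity_sd integrated-intensity significance cut: a
#'   particle must integrate to more than this many standard deviations
#'   of the expected Poisson background fluctuation over the aperture
#'   (suppresses isolated noise peaks that pass the response threshold
#'   but carry no appreciable photons).
#' @param saturation voxel value at or above which a particle is flagged
#'   saturated (never dropped).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(threshold_sd = 5,
                             psf_sigma_um = c(lateral = 0.110, axial = 0.350),
                             merge_radius_um = 2 * psf_sigma_um[["lateral"]],
                             min_intensity_sd = 5,
                             saturation = Inf) {
  structure(list(threshold_sd = threshold_sd, psf_sigma_um = psf_sigma_um,
                 merge_radius_um = merge_radius_um,
                 min_intensity_sd = min_intensity_sd, saturation = saturation),
            class = "detection_params")
}

# Shift a 3D array by whole voxels with edge replication.
shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
  ix <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
  a[iz, iy, ix, drop = FALSE]
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = max(sigma_vox, 1e-6))
  k / sum(k)
}

# Separable Gaussian smoothing via shifted-array accumulation (edge
# replication). sigma_vox is c(z, y, x) in voxel units.
smooth3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    k <- gauss_kernel(sigma_vox[ax])
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      acc <- acc + k[j] * switch(ax,
                                 shift3(a, off, 0L, 0L),
                                 shift3(a, 0L, off, 0L),
                                 shift3(a, 0L, 0L, off))
    }
    a <- acc
  }
  a
}

# Negative Laplacian of the smoothed image, scale-normalized per axis so a
# PSF-sized blob gives a strong positive peak regardless of anisotropy.
log_response <- function(a, sigma_vox) {
  s <- smooth3(a, sigma_vox)
  resp <- array(0, dim(a))
  for (ax in 1:3) {
    sv <- max(sigma_vox[ax], 0.5)
    lap <- 2 * s - switch(ax,
                          shift3(s, 1L, 0L, 0L) + shift3(s, -1L, 0L, 0L),
                          shift3(s, 0L, 1L, 0L) + shift3(s, 0L, -1L, 0L),
                          shift3(s, 0L, 0L, 1L) + shift3(s, 0L, 0L, -1L))
    resp <- resp + sv^2 * lap
  }
  resp
}

local_maxima3 <- function(a) {
  keep <- array(TRUE, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    keep <- keep & (a > shift3(a, dz, dy, dx) |
                      (a == shift3(a, dz, dy, dx) &
                         later_in_scan(dim(a), dz, dy, dx)))
  }
  keep
}

# Deterministic tie-break for equal neighboring maxima: the voxel earlier
# in lexicographic (z, y, x) scan order wins. Returns an array that is TRUE
# where the neighbor at offset (dz,dy,dx) comes later in scan order.
later_in_scan <- function(d, dz, dy, dx) {
  # offset ordering by (dx, dy, dz) lexicographic sign
  later <- (dx > 0) || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0)
  array(later, d)
}

ellipsoid_offsets <- function(spacing_um, psf_sigma_um, r_sigma = 3) {
  rz <- ceiling(r_sigma * psf_sigma_um[["axial"]] / spacing_um[["z"]])
  ry <- ceiling(r_sigma * psf_sigma_um[["lateral"]] / spacing_um[["y"]])
  rx <- ceiling(r_sigma * psf_sigma_um[["lateral"]] / spacing_um[["x"]])
  g <- expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx)
  u <- (g$dz * spacing_um[["z"]] / psf_sigma_um[["axial"]])^2 +
    (g$dy * spacing_um[["y"]] / psf_sigma_um[["lateral"]])^2 +
    (g$dx * spacing_um[["x"]] / psf_sigma_um[["lateral"]])^2
  g[u <= r_sigma^2, ]
}

#' Detect diffraction-limited particles in one channel of a 3D stack
#'
#' Finds local maxima of a Laplacian-of-Gaussian band-pass response at the
#' PSF scale, thresholds them in robust-sd units, merges maxima closer
#' than the merge radius, and measures each particle: sub-voxel centroid
#' (intensity-weighted center of mass over a 3-sigma anisotropic
#' ellipsoid), background-subtracted integrated intensity over the same
#' aperture, peak intensity, and a saturation flag. Background is the
#' median of the channel outside the dilated spot masks, re-estimated per
#' stack.
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param params a [detection_params()].
#' @return a data.frame with one row per particle: `id`, `channel`,
#'   `z_um`, `y_um`, `x_um` (voxel-center physical coordinates),
#'   `intensity` (integrated, background-subtracted photons), `peak`,
#'   `background` (per-voxel estimate), `saturated`, `stage`, `embryo`.
#'   Empty channel yields a zero-row frame.
#' @export
detect_particles <- function(stack, channel, params = detection_params()) {
  a <- channel_array(stack, channel)
  sp <- stack$spacing_um
  empty <- data.frame(id = character(0), channel = character(0),
                      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      intensity = numeric(0), peak = numeric(0),
                      background = numeric(0), saturated = logical(0),
                      stage = character(0), embryo = character(0),
                      stringsAsFactors = FALSE)
  if (all(a == 0)) return(empty)
  sigma_vox <- c(params$psf_sigma_um[["axial"]] / sp[["z"]],
                 params$psf_sigma_um[["lateral"]] / sp[["y"]],
                 params$psf_sigma_um[["lateral"]] / sp[["x"]])
  resp <- log_response(a, sigma_vox)
  noise_sd <- max(stats::mad(resp), 1e-9)
  thr <- params$threshold_sd * noise_sd
  cand <- which(local_maxima3(resp) & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  # order candidates by decreasing response; lexicographic voxel order
  # breaks exact ties deterministically
  rvals <- resp[cand]
  ord <- order(-rvals, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]

  # merge maxima closer than the merge radius (keep the stronger)
  pos_um <- cbind((cand[, 1] - 0.5) * sp[["z"]],
                  (cand[, 2] - 0.5) * sp[["y"]],
                  (cand[, 3] - 0.5) * sp[["x"]])
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d <- sqrt(colSums((t(pos_um[j, , drop = FALSE]) - pos_um[i, ])^2))
      keep[j][d < params$merge_radius_um] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  off <- ellipsoid_offsets(sp, params$psf_sigma_um)
  # centroids use a tighter aperture than intensities: 1.5 sigma holds the
  # bulk of the PSF mass but is far less sensitive to the skirts of
  # axially close neighbors, which would otherwise drag the center of mass
  off_c <- ellipsoid_offsets(sp, params$psf_sigma_um, r_sigma = 1.5)
  d <- dim(a)
  # background: median outside the dilated union of spot apertures
  mask <- array(FALSE, d)
  for (i in seq_len(nrow(cand))) {
    iz <- cand[i, 1] + off$dz; iy <- cand[i, 2] + off$dy
    ix <- cand[i, 3] + off$dx
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    mask[cbind(iz[ok], iy[ok], ix[ok])] <- TRUE
  }
  # mean, not median: at photon-counting backgrounds (< 1 count/voxel) the
  # integer-valued median is badly biased, while spot tails beyond the
  # dilated apertures contribute negligibly to the mean
  bg <- if (all(mask)) mean(a) else mean(a[!mask])

  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ctr <- cand[i, ]
    # two passes: the second re-centers the aperture on the first-pass
    # centroid, which removes the aperture mis-centering of dim particles
    # whose response argmax jitters by a voxel (coarsest along z)
    w <- 0
    for (pass in 1:2) {
      izc <- ctr[1] + off_c$dz; iyc <- ctr[2] + off_c$dy
      ixc <- ctr[3] + off_c$dx
      okc <- izc >= 1 & izc <= d[1] & iyc >= 1 & iyc <= d[2] &
        ixc >= 1 & ixc <= d[3]
      voxc <- cbind(izc[okc], iyc[okc], ixc[okc])
      w <- pmax(a[voxc] - bg, 0)
      if (sum(w) <= 0) break
      zc <- sum(w * (voxc[, 1] - 0.5)) / sum(w) * sp[["z"]]
      yc <- sum(w * (voxc[, 2] - 0.5)) / sum(w) * sp[["y"]]
      xc <- sum(w * (voxc[, 3] - 0.5)) / sum(w) * sp[["x"]]
      ctr <- c(round(zc / sp[["z"]] + 0.5), round(yc / sp[["y"]] + 0.5),
               round(xc / sp[["x"]] + 0.5))
    }
    if (sum(w) <= 0) next
    iz <- ctr[1] + off$dz; iy <- ctr[2] + off$dy; ix <- ctr[3] + off$dx
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    vox <- cbind(iz[ok], iy[ok], ix[ok])
    vals <- a[vox] - bg
    out[[i]] <- data.frame(
      id = NA_character_, channel = channel, z_um = zc, y_um = yc, x_um = xc,
      intensity = sum(vals), peak = max(a[vox]), background = bg,
      saturated = any(a[vox] >= params$saturation),
      stage = stack$stage, embryo = stack$embryo, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  min_int <- params$min_intensity_sd * sqrt(nrow(off) * bg)
  out <- out[out$intensity > max(0, min_int), , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$id <- sprintf("%s_%04d", channel, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Measure intensity at fixed positions
#'
#' Integrates background-subtracted intensity over the standard 3-sigma
#' aperture centered at given physical coordinates, without detecting.
#' Used for dual-probe measurements where the second channel is quantified
#' at the centroids detected in the first.
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param centroids data.frame with `z_um`, `y_um`, `x_um`.
#' @param params a [detection_params()] (sets the aperture).
#' @return numeric vector of integrated intensities (photons).
#' @export
measure_at <- function(stack, channel, centroids,
                       params = detection_params()) {
  a <- channel_array(stack, channel)
  sp <- stack$spacing_um
  d <- dim(a)
  off <- ellipsoid_offsets(sp, params$psf_sigma_um)
  mask <- array(FALSE, d)
  for (i in seq_len(nrow(centroids))) {
    iz <- round(centroids$z_um[i] / sp[["z"]] + 0.5) + off$dz
    iy <- round(centroids$y_um[i] / sp[["y"]] + 0.5) + off$dy
    ix <- round(centroids$x_um[i] / sp[["x"]] + 0.5) + off$dx
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    mask[cbind(iz[ok], iy[ok], ix[ok])] <- TRUE
  }
  bg <- if (all(mask)) mean(a) else mean(a[!mask])
  vapply(seq_len(nrow(centroids)), function(i) {
    iz <- round(centroids$z_um[i] / sp[["z"]] + 0.5) + off$dz
    iy <- round(centroids$y_um[i] / sp[["y"]] + 0.5) + off$dy
    ix <- round(centroids$x_um[i] / sp[["x"]] + 0.5) + off$dx
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    sum(a[cbind(iz[ok], iy[ok], ix[ok])] - bg)
  }, numeric(1))
}

# Triangle threshold on a numeric vector: the histogram point farthest
# from the line joining the histogram peak to the far tail end.
triangle_threshold <- function(v, nbins = 256) {
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  ipk <- which.max(cnt)
  itail <- max(which(cnt > 0))
  if (itail <= ipk) return(max(v))
  x1 <- ipk; y1 <- cnt[ipk]; x2 <- itail; y2 <- cnt[itail]
  ii <- ipk:itail
  # distance from (ii, cnt[ii]) to the peak-tail line
  num <- abs((y2 - y1) * ii - (x2 - x1) * cnt[ii] + x2 * y1 - y2 * x1)
  ib <- ii[which.max(num)]
  mids[ib]
}

#' Total intensity of the localized signal in a sum projection
#'
#' Sum-projects one channel along z, builds a foreground mask with an
#' automatic threshold (triangle by default, which keeps the dim tail of
#' the localized signal inside the mask; Otsu and a fixed value are
#' selectable), and returns the integrated, background-subtracted density
#' within the mask. An all-background image yields a zero-area mask and
#' zero intensity.
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param method `"triangle"`, `"otsu"` or `"fixed"`.
#' @param fixed threshold value when `method = "fixed"`.
#' @param background_subtract subtract the per-pixel background (median of
#'   the projection outside the mask) times the mask area.
#' @param roi_y optional `c(lo, hi)` in micrometres restricting the
#'   projection to a y-band (e.g. the germ-plasm band) before thresholding.
#' @return a list: `total` (photons), `area_um2`, `threshold`, `mask`
#'   (logical matrix).
#' @export
measure_projection_intensity <- function(stack, channel,
                                         method = c("triangle", "otsu",
                                                    "fixed"),
                                         fixed = NULL,
                                         background_subtract = TRUE,
                                         roi_y = NULL) {
  method <- match.arg(method)
  a <- channel_array(stack, channel)
  sp <- stack$spacing_um
  proj <- apply(a, c(2, 3), sum)
  if (!is.null(roi_y)) {
    iy <- which((seq_len(nrow(proj)) - 0.5) * sp[["y"]] >= roi_y[1] &
                  (seq_len(nrow(proj)) - 0.5) * sp[["y"]] <= roi_y[2])
    proj <- proj[iy, , drop = FALSE]
  }
  if (all(proj == 0))
    return(list(total = 0, area_um2 = 0, threshold = 0,
                mask = matrix(FALSE, nrow(proj), ncol(proj))))
  thr <- switch(method,
                triangle = triangle_threshold(as.vector(proj)),
                otsu = {
                  rng <- range(proj)
                  EBImage::otsu(matrix((proj - rng[1]) /
                                         max(rng[2] - rng[1], 1e-12),
                                       nrow(proj)), levels = 256) *
                    (rng[2] - rng[1]) + rng[1]
                },
                fixed = {
                  if (is.null(fixed)) stop("method 'fixed' needs a value")
                  fixed
                })
  mask <- proj > thr
  if (!any(mask))
    return(list(total = 0, area_um2 = 0, threshold = thr, mask = mask))
  bg <- if (background_subtract && !all(mask)) stats::median(proj[!mask])
        else 0
  total <- sum(proj[mask] - bg)
  list(total = total, area_um2 = sum(mask) * sp[["y"]] * sp[["x"]],
       threshold = thr, mask = mask)
}

#' Mean intensity per unit volume in a box ROI
#'
#' Integrated density of a rectangular ROI over a z-slab, divided by the
#' physical volume, for per-volume compartment comparisons (germ plasm vs
#' bulk cytoplasm).
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param roi list with `x`, `y` (and optionally `z`) elements, each
#'   `c(lo, hi)` in micrometres; omitted axes span the stack.
#' @return intensity density, photons per cubic micrometre.
#' @export
measure_roi_density <- function(stack, channel, roi = list()) {
  a <- channel_array(stack, channel)
  sp <- stack$spacing_um
  d <- dim(a)
  sel <- function(ax, n, lim) {
    ctr <- (seq_len(n) - 0.5) * sp[[ax]]
    if (is.null(lim)) seq_len(n) else {
      if (lim[1] >= lim[2]) stop("zero-volume ROI")
      i <- which(ctr >= lim[1] & ctr <= lim[2])
      if (length(i) == 0) stop("ROI outside stack bounds")
      i
    }
  }
  iz <- sel("z", d[1], roi$z); iy <- sel("y", d[2], roi$y)
  ix <- sel("x", d[3], roi$x)
  vol <- length(iz) * length(iy) * length(ix) * prod(sp)
  sum(a[iz, iy, ix]) / vol
}

#' Share of a channel's signal localized to the germ-plasm band
#'
#' Background- and bulk-corrected estimate of the fraction of total signal
#' residing in the cortical band: the band's density excess over the bulk
#' density times the band volume, divided by the total field signal.
#' Requires imaging without dark counts (photon-counting background 0), as
#' in the whole-embryo scenario.
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param band_depth_um germ-plasm band depth from the cortex (maximal-y)
#'   edge.
#' @param buffer_um ROI margin added beyond the band (captures PSF leak)
#'   and excluded from the bulk ROI.
#' @return fraction in `[0, 1]`.
#' @export
measure_localized_share <- function(stack, channel, band_depth_um = 2,
                                    buffer_um = 0.35) {
  ext <- stack_extent(stack)
  band_lo <- ext[["y"]] - band_depth_um - buffer_um
  d_gp <- measure_roi_density(stack, channel,
                              roi = list(y = c(band_lo, ext[["y"]])))
  d_bulk <- measure_roi_density(stack, channel,
                                roi = list(y = c(0, band_lo - 1)))
  v_gp <- (ext[["y"]] - band_lo) * ext[["x"]] * ext[["z"]]
  total <- measure_roi_density(stack, channel) * prod(ext)
  max(0, (d_gp - d_bulk) * v_gp) / total
}
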