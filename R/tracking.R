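# Frame-to-frame particle linking and motility statistics.
#
# The linker replaces a proprietary autoregressive tracker with a
# published, reproducible alternative: minimal-cost bipartite assignment
# (Hungarian/shortest-augmenting-path) between consecutive frames, gated
# at max_disp, with birth/death dummies so the objective is "maximize
# gated links, then minimize total squared displacement". No gap closing.

# Shortest-augmenting-path assignment for an n x m cost matrix (n <= m).
# Returns, for each row, the assigned column. O(n^2 m).
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

# Optimal gated link between two point sets. Returns a two-column matrix
# (prev index, cur index). Decomposes the gating graph into connected
# components and solves each with birth/death-augmented assignment;
# penalty per unmatched particle is max_disp^2, so any gated link is
# preferred and the solution minimizes total squared displacement among
# maximum-cardinality gated matchings.
link_frame_pair <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  if (np == 0 || nc == 0) return(cbind(integer(0), integer(0)))
  d <- cross_dist(cbind(prev$x_um, prev$y_um), cbind(cur$x_um, cur$y_um))
  allowed <- d <= max_disp
  if (!any(allowed)) return(cbind(integer(0), integer(0)))
  # connected components over the bipartite gating graph
  comp_p <- integer(np); comp_c <- integer(nc); ncomp <- 0L
  for (s in seq_len(np)) {
    if (comp_p[s] != 0 || !any(allowed[s, ])) next
    ncomp <- ncomp + 1L
    qp <- s
    while (length(qp) > 0) {
      newly_c <- setdiff(which(colSums(allowed[qp, , drop = FALSE]) > 0),
                         which(comp_c != 0))
      comp_p[qp] <- ncomp
      comp_c[newly_c] <- ncomp
      qp <- setdiff(which(rowSums(allowed[, newly_c, drop = FALSE]) > 0),
                    which(comp_p != 0))
    }
  }
  BIG <- max_disp^2 * 1e6 + 1
  pen <- max_disp^2
  links <- list()
  for (k in seq_len(ncomp)) {
    ip <- which(comp_p == k); ic <- which(comp_c == k)
    r <- length(ip); cl <- length(ic)
    if (r == 1 && cl == 1) { links[[k]] <- cbind(ip, ic); next }
    sz <- r + cl
    cost <- matrix(BIG, sz, sz)
    sub <- d[ip, ic, drop = FALSE]^2
    sub[!allowed[ip, ic, drop = FALSE]] <- BIG
    cost[seq_len(r), seq_len(cl)] <- sub
    for (i in seq_len(r)) cost[i, cl + i] <- pen          # death of prev i
    for (j in seq_len(cl)) cost[r + j, j] <- pen          # birth of cur j
    cost[(r + 1):sz, (cl + 1):sz] <- 0
    a <- hungarian(cost)
    got <- which(seq_len(sz) <= r & a <= cl)
    got <- got[sub[cbind(got, a[got])] < BIG]
    links[[k]] <- cbind(ip[got], ic[a[got]])
  }
  do.call(rbind, links)
}

#' Link per-frame particle tables into tracks
#'
#' Greedy frame-to-frame linking with globally optimal per-frame
#' assignment: consecutive frames are matched one-to-one by minimal total
#' squared displacement subject to a per-link distance gate; unmatched
#' particles start new tracks; a particle jumping farther than `max_disp`
#' terminates its track and begins a new one. No gap closing. Particles
#' within each frame are processed in id order, so the result does not
#' depend on row order.
#'
#' @param frames time-ordered list of data.frames with `x_um`, `y_um` and
#'   optionally `id`.
#' @param max_disp maximum link displacement per frame, micrometres.
#' @param frame_interval_s seconds between frames (fills the `t_s`
#'   column).
#' @return a data.frame of class `tracks`: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `particle_id`. Every input particle belongs to
#'   exactly one track; a single frame yields one 1-point track per
#'   particle.
#' @export
link_tracks <- function(frames, max_disp = 1.0, frame_interval_s = 0.2) {
  if (max_disp <= 0) stop("max_disp must be > 0")
  frames <- lapply(frames, function(f) {
    if (is.null(f$id)) f$id <- sprintf("p%05d", seq_len(nrow(f)))
    f[order(f$id), , drop = FALSE]
  })
  nf <- length(frames)
  next_track <- 1L
  rows <- vector("list", nf)
  frame_rows <- function(tracks, frame, f) {
    data.frame(track_id = sprintf("trk%05d", tracks), frame = frame,
               t_s = (frame - 1) * frame_interval_s,
               x_um = f$x_um, y_um = f$y_um, particle_id = f$id,
               stringsAsFactors = FALSE)
  }
  cur_tracks <- seq_len(nrow(frames[[1]]))
  next_track <- nrow(frames[[1]]) + 1L
  rows[[1]] <- frame_rows(cur_tracks, 1L, frames[[1]])
  if (nf >= 2) {
    for (t in 2:nf) {
      prev <- frames[[t - 1]]; cur <- frames[[t]]
      lk <- link_frame_pair(prev, cur, max_disp)
      new_tracks <- integer(nrow(cur))
      if (nrow(lk) > 0) new_tracks[lk[, 2]] <- cur_tracks[lk[, 1]]
      fresh <- which(new_tracks == 0L)
      if (length(fresh) > 0) {
        new_tracks[fresh] <- next_track + seq_along(fresh) - 1L
        next_track <- next_track + length(fresh)
      }
      rows[[t]] <- frame_rows(new_tracks, t, cur)
      cur_tracks <- new_tracks
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("tracks", "data.frame")
  out
}

#' Per-track motility metrics
#'
#' Average velocity (path length / duration), net displacement
#' (straight-line start-to-end distance), linearity (net displacement /
#' path length, in `[0, 1]`; 1 for straight directed motion, toward 0 for
#' confined or random motion) and duration. Tracks shorter than
#' `min_length` points are excluded from population statistics by default
#' (noise suppression; the threshold is reported in the output attributes).
#'
#' @param tracks a [link_tracks()] result or any data.frame with
#'   `track_id`, `t_s`, `x_um`, `y_um`.
#' @param min_length minimum points per track.
#' @return data.frame: `track_id`, `n_points`, `duration_s`,
#'   `path_length_um`, `net_displacement_um`, `velocity_um_s`,
#'   `linearity`.
#' @export
track_metrics <- function(tracks, min_length = 5) {
  split_tracks <- split(tracks, tracks$track_id)
  out <- lapply(split_tracks, function(tr) {
    if (nrow(tr) < max(2, min_length)) return(NULL)
    tr <- tr[order(tr$t_s), ]
    if (any(diff(tr$t_s) <= 0)) stop("timestamps must be strictly increasing")
    dur <- tr$t_s[nrow(tr)] - tr$t_s[1]
    if (dur <= 0) stop("zero-duration track")
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    path <- sum(steps)
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                  (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    data.frame(track_id = tr$track_id[1], n_points = nrow(tr),
               duration_s = dur, path_length_um = path,
               net_displacement_um = net,
               velocity_um_s = path / dur,
               linearity = if (path > 0) net / path else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = character(0), n_points = integer(0),
                      duration_s = numeric(0), path_length_um = numeric(0),
                      net_displacement_um = numeric(0),
                      velocity_um_s = numeric(0), linearity = numeric(0))
  rownames(out) <- NULL
  attr(out, "min_length") <- min_length
  out
}

#' Particle counts in equal-area bands by distance from the cortex
#'
#' Partitions a rectangular field into `n_regions` bands of equal area by
#' distance from the cortex edge, with region `n_regions` nearest the
#' cortex; particles exactly on a boundary are assigned to the band nearer
#' the cortex. Counts are reported per species.
#'
#' @param particles data.frame with `x_um`, `y_um` and optionally
#'   `species`.
#' @param field list with `xlim`, `ylim` (micrometres).
#' @param cortex which field edge is the cortex: `"ymax"`, `"ymin"`,
#'   `"xmax"` or `"xmin"`.
#' @param n_regions number of equal-area bands.
#' @return a list of class `region_occupancy`: `counts` (species x
#'   region matrix, region columns ordered 1 = farthest to
#'   `n_regions` = nearest cortex), `region_area_um2`, `n_regions`.
#' @export
region_occupancy <- function(particles, field,
                             cortex = c("ymax", "ymin", "xmax", "xmin"),
                             n_regions = 4) {
  cortex <- match.arg(cortex)
  if (diff(field$xlim) <= 0 || diff(field$ylim) <= 0)
    stop("degenerate field")
  if (any(particles$x_um < field$xlim[1] - 1e-9) ||
      any(particles$x_um > field$xlim[2] + 1e-9) ||
      any(particles$y_um < field$ylim[1] - 1e-9) ||
      any(particles$y_um > field$ylim[2] + 1e-9))
    stop("all particles must lie inside the field")
  dist <- switch(cortex,
                 ymax = field$ylim[2] - particles$y_um,
                 ymin = particles$y_um - field$ylim[1],
                 xmax = field$xlim[2] - particles$x_um,
                 xmin = particles$x_um - field$xlim[1])
  extent <- if (startsWith(cortex, "y")) diff(field$ylim) else
    diff(field$xlim)
  w <- extent / n_regions
  band <- pmax(1L, as.integer(ceiling(dist / w)))       # 1 = nearest cortex
  band <- pmin(band, n_regions)
  region <- n_regions + 1L - band                        # n_regions = nearest
  species <- if (is.null(particles$species)) rep("all", nrow(particles))
             else particles$species
  counts <- table(factor(species),
                  factor(region, levels = seq_len(n_regions)))
  other <- if (startsWith(cortex, "y")) diff(field$xlim) else
    diff(field$ylim)
  structure(list(counts = unclass(counts), region_area_um2 = w * other,
                 n_regions = n_regions, cortex = cortex),
            class = "region_occupancy")
}
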