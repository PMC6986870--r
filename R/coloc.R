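# Pairwise, conditional and size-binned colocalization between particle
# sets, using one-to-one mutual-nearest-neighbor matching of 3D centroids.
#
# Criterion: a reference particle is colocalized iff its mutual-nearest
# query particle lies within the distance threshold (default 250 nm, about
# twice the lateral PSF sigma; every reported fraction carries its
# threshold). Matching is one-to-one by construction; ties are broken by
# smaller distance, then lexicographic id. A randomized control (query
# positions re-drawn uniformly within the reference bounding region) is
# computed alongside every fraction so chance colocalization can be
# subtracted.

coords3 <- function(p) cbind(p$z_um, p$y_um, p$x_um)

# Mutual-nearest-neighbor matched pairs within a threshold.
mnn_pairs <- function(reference, query, threshold_um) {
  nr <- nrow(reference); nq <- nrow(query)
  if (nr == 0 || nq == 0)
    return(data.frame(ref = integer(0), query = integer(0),
                      dist_um = numeric(0)))
  d <- cross_dist(coords3(reference), coords3(query))
  # deterministic tie-break: among equal minima prefer the smaller index,
  # i.e. lexicographically earlier id order as supplied
  nn_q <- apply(d, 1, which.min)
  nn_r <- apply(d, 2, which.min)
  ref_idx <- which(nn_r[nn_q] == seq_len(nr))
  qry_idx <- nn_q[ref_idx]
  dd <- d[cbind(ref_idx, qry_idx)]
  ok <- dd <= threshold_um
  data.frame(ref = ref_idx[ok], query = qry_idx[ok], dist_um = dd[ok])
}

#' Colocalization between two particle sets
#'
#' Matches reference and query particles one-to-one by mutual nearest
#' neighbors within a 3D distance threshold and returns the directional
#' colocalized fractions both ways, the matched-pair list, and a
#' chance-colocalization estimate from randomized query positions.
#'
#' @param reference,query particle data.frames (from [detect_particles()]
#'   or ground-truth tables) with `z_um`, `y_um`, `x_um` and optionally
#'   `id`, `stage`, `embryo`.
#' @param threshold_um centroid distance threshold in micrometres.
#' @param n_control number of randomized-control replicates (0 disables).
#' @param control_seed seed for the randomized control.
#' @return an object of class `coloc_result`: `n_ref`, `n_query`,
#'   `n_matched`, `fraction_ref` (fraction of reference with a partner),
#'   `fraction_query`, `pairs` (row indices and ids), `chance_fraction`
#'   (mean over control replicates), `threshold_um`.
#' @export
colocalize <- function(reference, query, threshold_um = 0.25,
                       n_control = 10, control_seed = 1L) {
  if (nrow(query) == 0) {
    warning("empty query set; colocalized fraction is 0")
    return(structure(list(n_ref = nrow(reference), n_query = 0L,
                          n_matched = 0L, fraction_ref = 0,
                          fraction_query = NA_real_,
                          pairs = data.frame(), chance_fraction = 0,
                          threshold_um = threshold_um),
                     class = "coloc_result"))
  }
  if (!is.null(reference$embryo) && !is.null(query$embryo)) {
    se <- unique(c(reference$embryo, query$embryo))
    if (length(stats::na.omit(se)) > 1)
      stop("reference and query must come from the same stack")
  }
  pairs <- mnn_pairs(reference, query, threshold_um)
  if (!is.null(reference$id)) pairs$ref_id <- reference$id[pairs$ref]
  if (!is.null(query$id)) pairs$query_id <- query$id[pairs$query]
  chance <- NA_real_
  if (n_control > 0 && nrow(reference) > 0) {
    lo <- apply(coords3(query), 2, min); hi <- apply(coords3(query), 2, max)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(control_seed)
    cf <- vapply(seq_len(n_control), function(i) {
      q2 <- data.frame(z_um = runif(nrow(query), lo[1], hi[1]),
                       y_um = runif(nrow(query), lo[2], hi[2]),
                       x_um = runif(nrow(query), lo[3], hi[3]))
      nrow(mnn_pairs(reference, q2, threshold_um)) / nrow(reference)
    }, numeric(1))
    chance <- mean(cf)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(n_ref = nrow(reference), n_query = nrow(query),
                 n_matched = nrow(pairs),
                 fraction_ref = nrow(pairs) / max(1, nrow(reference)),
                 fraction_query = nrow(pairs) / max(1, nrow(query)),
                 pairs = pairs, chance_fraction = chance,
                 threshold_um = threshold_um),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc> %d/%d reference colocalized (%.1f%%) at %.0f nm; chance %.1f%%\n",
    x$n_matched, x$n_ref, 100 * x$fraction_ref, 1000 * x$threshold_um,
    ifelse(is.na(x$chance_fraction), NA, 100 * x$chance_fraction)))
  invisible(x)
}

#' Conditional (triple-channel) colocalization
#'
#' Restricts the reference set to particles colocalized with the
#' conditioning set, then measures the fraction of that subset also
#' colocalized with the query set (e.g. the proportion of *oskar*
#' particles carrying DCP1 that also carry Me31B).
#'
#' @param reference,cond,query particle data.frames from the same stack.
#' @param threshold_um distance threshold.
#' @param ... passed to [colocalize()].
#' @return a `coloc_result` with extra fields `n_conditioned` (size of
#'   the restricted set) and `undefined` (`TRUE` when the restricted set
#'   is empty, in which case the fraction is `NA`).
#' @export
conditional_coloc <- function(reference, cond, query, threshold_um = 0.25,
                              ...) {
  first <- colocalize(reference, cond, threshold_um, n_control = 0)
  sub <- reference[first$pairs$ref, , drop = FALSE]
  if (nrow(sub) == 0) {
    res <- structure(list(n_ref = 0L, n_query = nrow(query), n_matched = 0L,
                          fraction_ref = NA_real_, fraction_query = NA_real_,
                          pairs = data.frame(), chance_fraction = NA_real_,
                          threshold_um = threshold_um, n_conditioned = 0L,
                          undefined = TRUE),
                     class = "coloc_result")
    return(res)
  }
  res <- colocalize(sub, query, threshold_um, ...)
  res$n_conditioned <- nrow(sub)
  res$undefined <- FALSE
  res
}

#' Colocalized fraction by granule size class
#'
#' Splits calibrated reference particles into transcript-count bins and
#' reports the colocalized fraction per bin together with the
#' bin-occupancy distribution. Empty bins yield `NA` fractions, not zero.
#'
#' @param reference calibrated particles (with `count`).
#' @param query particle data.frame.
#' @param threshold_um distance threshold.
#' @param bins transcript-count bin edges.
#' @return data.frame: `bin`, `n`, `occupancy` (sums to 1 over non-empty
#'   input), `n_coloc`, `fraction`.
#' @export
coloc_by_size <- function(reference, query, threshold_um = 0.25,
                          bins = size_bins_default()) {
  if (!"count" %in% names(reference))
    stop("reference particles must be calibrated (have 'count')")
  cc <- colocalize(reference, query, threshold_um, n_control = 0)
  matched <- logical(nrow(reference))
  matched[cc$pairs$ref] <- TRUE
  bin <- cut(reference$count, breaks = bins, right = FALSE)
  lev <- levels(bin)
  out <- do.call(rbind, lapply(lev, function(b) {
    i <- which(bin == b)
    data.frame(bin = b, n = length(i),
               occupancy = length(i) / nrow(reference),
               n_coloc = sum(matched[i]),
               fraction = if (length(i) == 0) NA_real_ else
                 sum(matched[i]) / length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expected chance colocalization of a Poisson query field
#'
#' Closed-form probability that at least one uniformly random query
#' particle falls within the 3D threshold of a reference particle:
#' `1 - exp(-rho * 4/3 * pi * r^3)` for query density `rho`.
#'
#' @param density_per_um3 query particle density.
#' @param threshold_um distance threshold.
#' @return probability in `[0, 1]`.
#' @export
chance_coloc_poisson <- function(density_per_um3, threshold_um = 0.25) {
  1 - exp(-density_per_um3 * 4 / 3 * pi * threshold_um^3)
}
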