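# Independent oracles used across tests. These deliberately re-derive
# results by brute force or closed form, sharing no code with the
# implementation paths they check.

# Pooled-variance two-sample t-test from the textbook formulas.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Mutual-nearest-neighbor matching recomputed directly from the full
# distance matrix.
mnn_oracle <- function(ref, qry, threshold) {
  d <- as.matrix(dist(rbind(as.matrix(ref), as.matrix(qry))))
  d <- d[seq_len(nrow(ref)), nrow(ref) + seq_len(nrow(qry)), drop = FALSE]
  pairs <- NULL
  for (i in seq_len(nrow(ref))) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i && d[i, j] <= threshold)
      pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

# Exhaustive minimal-cost gated matching between two small point sets:
# objective = sum of squared link distances + max_disp^2 per unmatched
# particle on either side. Enumerates every injective partial matching.
brute_force_link <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  d2 <- outer(seq_len(np), seq_len(nc), function(i, j)
    (prev$x_um[i] - cur$x_um[j])^2 + (prev$y_um[i] - cur$y_um[j])^2)
  gate <- d2 <= max_disp^2
  pen <- max_disp^2
  best <- list(cost = Inf, links = NULL)
  recurse <- function(i, used, links, cost) {
    if (cost >= best$cost) return()
    if (i > np) {
      total <- cost + pen * (np - nrow0(links)) + pen * (nc - nrow0(links))
      if (total < best$cost) best <<- list(cost = total, links = links)
      return()
    }
    recurse(i + 1, used, links, cost)                       # i unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && gate[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, rbind(links, c(i, j)), cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  nrow0 <- function(x) if (is.null(x)) 0L else nrow(x)
  recurse(1L, logical(nc), NULL, 0)
  best
}

# Small noise-free stack with spots on a well-separated grid.
grid_scene <- function(n_spots = 10, amplitude = 2000, background = 0.5,
                       noise = FALSE, nz = 12, spacing_um = 1.5) {
  pos <- expand.grid(x = seq(1, by = spacing_um, length.out = 4),
                     y = seq(1, by = spacing_um, length.out = 4))
  pos <- pos[seq_len(n_spots), ]
  spots <- data.frame(z = rep(c(1.5, 2.5), length.out = n_spots),
                      y = pos$y, x = pos$x,
                      amplitude = amplitude)
  dims <- c(nz = nz,
            ny = as.integer(ceiling((max(pos$y) + 1.5) / 0.072)),
            nx = as.integer(ceiling((max(pos$x) + 1.5) / 0.072)))
  sp <- c(z = 0.34, y = 0.072, x = 0.072)
  a <- granulytics:::render_spots(spots, dims, sp,
                                  c(lateral = 0.110, axial = 0.350))
  a <- granulytics:::add_noise(a, background, 0, noise)
  list(stack = image_stack(list(spots = a), sp, stage = "s", embryo = "e"),
       spots = spots)
}
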