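# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementations.

# Tile/crop origins for one axis: advance by stride, clamp the final origin.
oracle_axis_origins <- function(n, patch, stride) {
  o <- integer(0)
  pos <- 0
  while (TRUE) {
    o <- c(o, min(pos, n - patch))
    if (pos >= n - patch) break
    pos <- pos + stride
  }
  unique(o)
}

oracle_tile_plan <- function(h, w, patch, overlap) {
  stride <- max(1, round(patch * (1 - overlap)))
  or <- oracle_axis_origins(h, patch, stride)
  oc <- oracle_axis_origins(w, patch, stride)
  cbind(row = rep(or, each = length(oc)), col = rep(oc, times = length(or)))
}

# 8-connected component labelling by BFS on a 0/1 matrix.
oracle_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  cur <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (m[r0, c0] == 1 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          rr <- p[1] + offs$dr[k]; cc <- p[2] + offs$dc[k]
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
              m[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# All-pairs longest shortest path (geodesic diameter, in pixel count) of an
# 8-connected pixel set, by BFS from every pixel.
oracle_geodesic_diameter <- function(px) {
  n <- nrow(px)
  adj <- lapply(seq_len(n), function(i) {
    which(abs(px[, 1] - px[i, 1]) <= 1 & abs(px[, 2] - px[i, 2]) <= 1 &
            !(px[, 1] == px[i, 1] & px[, 2] == px[i, 2]))
  })
  best <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
    best <- max(best, max(dist, na.rm = TRUE))
  }
  best + 1L  # path length in pixels
}

# Exhaustive minimum-cost one-to-one assignment over all permutations.
oracle_min_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; bestp <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; bestp <- p }
  }
  list(cost = best, assignment = bestp)
}

# Vessel-to-ring assignment via dense rasterized bands: walk down each
# vessel's column counting boundary bands crossed above the vessel.
oracle_assign_by_bands <- function(boundaries, vessels, height) {
  rows_at <- function(p, col) {
    pts <- p$points
    if (nrow(pts) == 1) return(pts[1, 1])
    approx(pts[, 2], pts[, 1], xout = col, rule = 2)$y
  }
  vapply(seq_len(nrow(vessels)), function(i) {
    col <- vessels$col[i]
    sum(vapply(boundaries, function(b) rows_at(b, col), numeric(1)) <
          vessels$row[i])
  }, numeric(1))
}

# Tiny network configuration used across tests (fast on one CPU).
tiny_net_config <- function(image_size = 64)
  unetr_config(image_size = image_size, embed_dim_K = 16,
               n_transformer_layers = 4, n_heads = 2, mlp_hidden_dim = 32,
               decoder_base_channels = 2)

# Small synthetic scene for fast generator tests.
small_synth_config <- function(seed = 1, n_boundaries = 2, ...)
  synth_config(height_px = 330, width_px = 96, n_boundaries = n_boundaries,
               mean_ring_width_px = 100, ring_width_cv = 0.15,
               boundary_waviness_px = 3, fiber_band_halfwidth_px = 2,
               vessels_per_ring_mean = 20, vessel_radius_range_px = c(2, 4),
               noise_sd = 4, seed = seed, ...)

# A binary mask with a handful of random filled rectangles and discs.
random_blob_mask <- function(H = 40, W = 40, n = 4) {
  m <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    if (runif(1) < 0.5) {
      r <- sort(sample(H, 2)); c <- sort(sample(W, 2))
      m[r[1]:r[2], c[1]:c[2]] <- 1L
    } else {
      cr <- sample(H, 1); cc <- sample(W, 1); rad <- sample(2:6, 1)
      for (rr in max(1, cr - rad):min(H, cr + rad))
        for (ccc in max(1, cc - rad):min(W, cc + rad))
          if ((rr - cr)^2 + (ccc - cc)^2 <= rad^2) m[rr, ccc] <- 1L
    }
  }
  m
}

# Exhaustive-order DSE oracle: try every removal order of end branches
# whose weight is below the threshold, re-deriving the graph each time.
oracle_dse_all_orders <- function(skel, mask, dt, thr) {
  finals <- list()
  recurse <- function(sk) {
    g <- ringseg:::decompose_skeleton(sk, mask, dt)
    cand <- which(vapply(g$branches, function(b)
      b$end_free && !b$is_cycle && length(b$removable) > 0, logical(1)))
    if (length(cand)) {
      w <- vapply(cand, function(i) branch_reconstruction_weight(g, i),
                  numeric(1))
      cand <- cand[w < thr]
    }
    if (length(cand) == 0) {
      finals[[length(finals) + 1]] <<- sort(which(sk == 1L))
      return()
    }
    for (i in cand) {
      sk2 <- sk
      sk2[g$pixels[g$branches[[i]]$removable, , drop = FALSE]] <- 0L
      recurse(sk2)
    }
  }
  recurse(skel)
  unique(finals)
}
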