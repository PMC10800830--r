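# Synthetic microsection generator.
#
# Emulates the statistical structure the segmentation pipeline assumes in
# transverse beech core images: a tall core with roughly transverse ring
# boundaries (bands of narrow, dark fibers) separating rings populated by
# bright vessel lumina whose diameter shrinks from the start to the end of
# each ring (semi-ring-porous pattern). Not a histological simulation:
# parenchyma rays, staining gradients and stitching artifacts are absent.

#' Configuration for the synthetic microsection generator
#'
#' Defaults emulate the imaging conditions of 40x beech microsection scans:
#' 1.63 um/px, rings about 1110 um (~680 px) wide, and on average 120
#' vessels per ring. The default canvas is a 2048 x 512 (tall x wide) core
#' strip, a desk-scale stand-in for full cores of ~24000 x 1500 px.
#'
#' @param height_px,width_px canvas size in pixels (rows x cols).
#' @param n_boundaries number of ring boundaries (>= 0). `n` boundaries
#'   delimit `n + 1` rings (the first and last ring touch the image edge).
#' @param mean_ring_width_px mean spacing between consecutive boundaries.
#' @param ring_width_cv coefficient of variation of ring widths, in `[0,1)`.
#' @param boundary_waviness_px maximum vertical amplitude of the smooth
#'   undulation applied to each boundary.
#' @param fiber_band_halfwidth_px half-width of the dark fiber band drawn
#'   around each boundary path.
#' @param vessels_per_ring_mean Poisson mean of the vessel count per ring.
#' @param vessel_radius_range_px `(min, max)` expected vessel radius; the
#'   expectation decreases linearly from max at the ring start (top) to min
#'   at the ring end, with multiplicative lognormal noise.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (8-bit intensity units).
#' @param mask_stroke_px stroke width (odd) used to rasterize the
#'   ground-truth mask from the boundary polylines.
#' @param resolution_um_per_px physical resolution.
#' @param seed RNG seed; identical configs reproduce bit-identical samples.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(height_px = 2048, width_px = 512, n_boundaries = 2,
                         mean_ring_width_px = 680, ring_width_cv = 0.2,
                         boundary_waviness_px = 6, fiber_band_halfwidth_px = 4,
                         vessels_per_ring_mean = 120,
                         vessel_radius_range_px = c(4, 11), noise_sd = 6,
                         mask_stroke_px = 3, resolution_um_per_px = 1.63,
                         seed = 1) {
  stop_if_not(is_count(height_px) && is_count(width_px),
              "height_px and width_px must be positive integers")
  stop_if_not(is_count(n_boundaries, positive = FALSE),
              "n_boundaries must be a non-negative integer")
  stop_if_not(is_scalar(mean_ring_width_px) && mean_ring_width_px > 0,
              "mean_ring_width_px must be positive")
  stop_if_not(is_scalar(ring_width_cv) && ring_width_cv >= 0 &&
                ring_width_cv < 1, "ring_width_cv must lie in [0, 1)")
  stop_if_not(is_scalar(boundary_waviness_px) && boundary_waviness_px >= 0,
              "boundary_waviness_px must be non-negative")
  stop_if_not(is_count(fiber_band_halfwidth_px),
              "fiber_band_halfwidth_px must be a positive integer")
  stop_if_not(is_scalar(vessels_per_ring_mean) && vessels_per_ring_mean > 0,
              "vessels_per_ring_mean must be positive")
  stop_if_not(length(vessel_radius_range_px) == 2 &&
                all(vessel_radius_range_px > 0) &&
                vessel_radius_range_px[1] <= vessel_radius_range_px[2],
              "vessel_radius_range_px must be (min, max) with min <= max")
  stop_if_not(is_count(mask_stroke_px) && mask_stroke_px %% 2 == 1,
              "mask_stroke_px must be a positive odd integer")
  stop_if_not(is_scalar(noise_sd) && noise_sd >= 0,
              "noise_sd must be non-negative")
  stop_if_not(n_boundaries * mean_ring_width_px <= height_px,
              paste("infeasible config: %d boundaries x %g px mean ring width",
                    "do not fit in %d rows"),
              n_boundaries, mean_ring_width_px, height_px)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 n_boundaries = as.integer(n_boundaries),
                 mean_ring_width_px = mean_ring_width_px,
                 ring_width_cv = ring_width_cv,
                 boundary_waviness_px = boundary_waviness_px,
                 fiber_band_halfwidth_px = as.integer(fiber_band_halfwidth_px),
                 vessels_per_ring_mean = vessels_per_ring_mean,
                 vessel_radius_range_px = as.numeric(vessel_radius_range_px),
                 noise_sd = noise_sd,
                 mask_stroke_px = as.integer(mask_stroke_px),
                 resolution_um_per_px = resolution_um_per_px,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Integer Bresenham segment between two 0-based points, inclusive.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

#' Rasterize boundary polylines into a binary mask
#'
#' Draws the line segments connecting consecutive path points (Bresenham)
#' and dilates the stroke to `stroke_px` width (Chebyshev/square
#' structuring element), so every mask pixel lies within `stroke_px / 2`
#' (Chebyshev) of a polyline segment.
#'
#' @param paths list of [boundary_path()] objects (0-based coordinates).
#' @param shape integer `(rows, cols)` of the target mask.
#' @param stroke_px positive odd stroke width.
#' @return A [binary_mask()].
#' @export
rasterize_boundaries <- function(paths, shape, stroke_px = 3) {
  stop_if_not(is_count(stroke_px) && stroke_px %% 2 == 1,
              "stroke_px must be a positive odd integer")
  H <- shape[1]; W <- shape[2]
  m <- matrix(0L, H, W)
  h <- (stroke_px - 1L) %/% 2L
  for (i in seq_along(paths)) {
    p <- paths[[i]]$points
    pr <- round(p[, 1]); pc <- round(p[, 2])
    if (any(pr < 0 | pr > H - 1 | pc < 0 | pc > W - 1))
      stop("boundary path ", i, " has points outside the ", H, " x ", W,
           " image", call. = FALSE)
    segs <- if (nrow(p) == 1) list(cbind(pr, pc)) else
      lapply(seq_len(nrow(p) - 1), function(j)
        bresenham(pr[j], pc[j], pr[j + 1], pc[j + 1]))
    px <- unique(do.call(rbind, segs))
    for (dr in -h:h) for (dc in -h:h) {
      r <- px[, 1] + dr + 1L; c <- px[, 2] + dc + 1L
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      m[cbind(r[ok], c[ok])] <- 1L
    }
  }
  binary_mask(m)
}

# Smooth, zero-mean undulation of length W with max amplitude `amp`.
make_wave <- function(W, amp) {
  if (amp <= 0 || W < 3) return(numeric(W))
  w <- cumsum(rnorm(W))
  k <- min(2L * (W %/% 10L) + 1L, 61L)
  if (k >= 3) {
    ker <- rep(1 / k, k)
    w <- as.numeric(stats::filter(w, ker, sides = 2, circular = TRUE))
  }
  w <- w - mean(w)
  mx <- max(abs(w))
  if (mx > 0) w <- w * (amp / mx)
  w
}

#' Generate an annotated synthetic microsection
#'
#' Produces an image, its ring-boundary paths (sorted by increasing mean
#' row), a vessel table carrying each vessel's generative ring index, and
#' the ground-truth boundary mask. Vessels are kept clear of the fiber
#' bands by a margin of band half-width plus vessel radius, so their ring
#' membership is unambiguous; boundary undulations are resampled (bounded
#' retries) if they would cross.
#'
#' @param config a [synth_config()].
#' @param sample_id identifier stored in the image.
#' @return An `annotated_sample` list with elements `image`, `boundaries`,
#'   `vessels`, `mask`.
#' @export
generate_sample <- function(config, sample_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_sample_impl(config, sample_id))
}

generate_sample_impl <- function(cfg, sample_id) {
  H <- cfg$height_px; W <- cfg$width_px; n <- cfg$n_boundaries
  hw <- cfg$fiber_band_halfwidth_px
  margin <- hw + ceiling(cfg$boundary_waviness_px) + 2

  # --- boundary layout: base rows + smooth undulation, non-crossing ------
  rows_at <- NULL  # n x W matrix of per-column boundary rows
  if (n > 0) {
    ok <- FALSE
    for (try in 1:50) {
      t0 <- runif(1, 0.25, 0.9) * cfg$mean_ring_width_px
      w <- rnorm(n - 1, cfg$mean_ring_width_px,
                 cfg$ring_width_cv * cfg$mean_ring_width_px)
      w <- clamp(w, 0.35 * cfg$mean_ring_width_px,
                 1.8 * cfg$mean_ring_width_px)
      base <- t0 + c(0, cumsum(w))
      if (base[1] < margin || base[n] > H - 1 - margin) next
      rows_at <- t(vapply(seq_len(n), function(j)
        base[j] + make_wave(W, cfg$boundary_waviness_px), numeric(W)))
      gaps <- if (n > 1) apply(rows_at[-1, , drop = FALSE] -
                                 rows_at[-n, , drop = FALSE], 1, min) else Inf
      if (all(gaps >= 2 * hw + 6) && min(rows_at) >= margin &&
          max(rows_at) <= H - 1 - margin) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible config: could not lay out ", n,
                  " non-crossing boundaries in ", H, " rows", call. = FALSE)
  }

  # --- base tissue ------------------------------------------------------
  bg <- c(205, 190, 175)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]

  # --- fiber bands ------------------------------------------------------
  band_col <- c(120, 92, 88)
  if (n > 0) {
    for (j in seq_len(n)) {
      for (cc in seq_len(W)) {
        r0 <- max(1, floor(rows_at[j, cc] - hw) + 1)
        r1 <- min(H, ceiling(rows_at[j, cc] + hw) + 1)
        img[r0:r1, cc, ] <- rep(band_col, each = r1 - r0 + 1)
        # 1-px soft edge
        if (r0 - 1 >= 1) img[r0 - 1, cc, ] <- (band_col + bg) / 2
        if (r1 + 1 <= H) img[r1 + 1, cc, ] <- (band_col + bg) / 2
      }
    }
  }

  # --- vessels ----------------------------------------------------------
  rmin <- cfg$vessel_radius_range_px[1]; rmax <- cfg$vessel_radius_range_px[2]
  lumen_col <- c(240, 235, 228); wall_col <- c(150, 112, 100)
  vs <- list(); vid <- 0L
  for (ring in 0:n) {
    count <- rpois(1, cfg$vessels_per_ring_mean)
    if (count == 0) next
    for (v in seq_len(count)) {
      cc <- runif(1, 0, W - 1)
      up <- if (ring == 0) 0 else rows_at[ring, floor(cc) + 1]
      dn <- if (ring == n) H - 1 else rows_at[ring + 1, floor(cc) + 1]
      frac <- runif(1)
      rad <- (rmax - (rmax - rmin) * frac) * exp(rnorm(1, 0, 0.15))
      rad <- clamp(rad, 1, rmax * 1.3)
      a <- rad * runif(1, 0.85, 1.15)   # row semi-axis
      b <- rad * runif(1, 0.85, 1.15)   # col semi-axis
      mu <- if (ring == 0) a + 2 else hw + a + 3   # margin above
      md <- if (ring == n) a + 2 else hw + a + 3   # margin below
      if (up + mu >= dn - md) {         # narrow ring: shrink to fit
        amax <- (dn - up - 2 * hw - 8) / 2
        if (amax < 1) next              # degenerate sliver, skip vessel
        a <- b <- min(a, amax); rad <- a
        mu <- if (ring == 0) a + 2 else hw + a + 3
        md <- if (ring == n) a + 2 else hw + a + 3
      }
      rr <- up + mu + frac * (dn - md - (up + mu))
      vid <- vid + 1L
      vs[[vid]] <- c(rr, cc, ring, a, b)
      # draw ellipse with a thin darker wall
      rA <- max(1, floor(rr - a - 1.5) + 1); rB <- min(H, ceiling(rr + a + 1.5) + 1)
      cA <- max(1, floor(cc - b - 1.5) + 1); cB <- min(W, ceiling(cc + b + 1.5) + 1)
      rg <- rA:rB; cg <- cA:cB
      d2in <- outer(((rg - 1) - rr)^2 / a^2, ((cg - 1) - cc)^2 / b^2, "+")
      d2out <- outer(((rg - 1) - rr)^2 / (a + 1.5)^2,
                     ((cg - 1) - cc)^2 / (b + 1.5)^2, "+")
      for (ch in 1:3) {
        sl <- img[rg, cg, ch]
        sl[d2out <= 1] <- wall_col[ch]
        sl[d2in <= 1] <- lumen_col[ch]
        img[rg, cg, ch] <- sl
      }
    }
  }
  vessels <- if (vid == 0)
    data.frame(vessel_id = character(), row = numeric(), col = numeric(),
               ring_index = integer(), lumen_area_um2 = numeric())
  else {
    m <- do.call(rbind, vs)
    data.frame(vessel_id = sprintf("v%04d", seq_len(vid)),
               row = m[, 1], col = m[, 2], ring_index = as.integer(m[, 3]),
               lumen_area_um2 = pi * m[, 4] * m[, 5] *
                 cfg$resolution_um_per_px^2)
  }

  # --- noise ------------------------------------------------------------
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
  img <- round(clamp(img, 0, 255))

  boundaries <- if (n > 0)
    lapply(seq_len(n), function(j)
      boundary_path(cbind(row = round(rows_at[j, ]), col = 0:(W - 1)),
                    source = "synthetic"))
  else list()
  mask <- rasterize_boundaries(boundaries, c(H, W), cfg$mask_stroke_px)

  structure(list(
    image = microsection_image(img, cfg$resolution_um_per_px, sample_id),
    boundaries = boundaries,
    vessels = vessel_table(vessels),
    mask = mask),
    class = "annotated_sample")
}

#' @export
print.annotated_sample <- function(x, ...) {
  cat(sprintf("<annotated_sample '%s': %d x %d px, %d boundaries, %d vessels>\n",
              x$image$sample_id, dim(x$image)[1], dim(x$image)[2],
              length(x$boundaries), nrow(x$vessels)))
  invisible(x)
}

#' Write an annotated sample to disk
#'
#' Writes the image (PNG or TIFF plus YAML sidecar), the boundary CSV, the
#' vessel CSV, and optionally the generating configuration as YAML.
#'
#' @param sample an `annotated_sample` from [generate_sample()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @param config optional [synth_config()] to record alongside.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sample <- function(sample, dir, format = c("png", "tiff"),
                         config = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sample$image$sample_id
  ext <- if (format == "png") "png" else "tif"
  files <- c(image = file.path(dir, paste0(id, ".", ext)),
             boundaries = file.path(dir, paste0(id, "_boundaries.csv")),
             vessels = file.path(dir, paste0(id, "_vessels.csv")))
  write_microsection(sample$image, files[["image"]])
  write_boundaries(sample$boundaries, files[["boundaries"]])
  write_vessels(sample$vessels, files[["vessels"]])
  if (!is.null(config)) {
    f <- file.path(dir, paste0(id, "_config.yaml"))
    yaml::write_yaml(unclass(config), f)
    files <- c(files, config = f)
  }
  invisible(files)
}
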