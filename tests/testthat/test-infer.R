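# Overlap-tile planning, dihedral TTA, and whole-image prediction.

test_that("tile plans advance by the overlap-derived stride and clamp", {
  expect_equal(tile_plan(256, 256, 256, 0.9),
               cbind(row = 0L, col = 0L), ignore_attr = TRUE)
  # 256 x 307, overlap 0.9 -> stride 26, col origins 0, 26, 51 (clamped)
  plan <- tile_plan(256, 307, 256, 0.9)
  expect_equal(unique(plan[, "col"]), c(0L, 26L, 51L))
  expect_equal(unique(plan[, "row"]), 0L)
  expect_error(tile_plan(100, 300, 256, 0.9), "smaller")
})

test_that("tile plans match the brute-force enumeration and cover all", {
  set.seed(1)
  for (i in 1:6) {
    H <- sample(256:420, 1); W <- sample(256:420, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.9), 1)
    plan <- tile_plan(H, W, 256, ov)
    expect_equal(plan, oracle_tile_plan(H, W, 256, ov), ignore_attr = TRUE)
    expect_false(any(duplicated(plan)))
    cover <- matrix(0L, H, W)
    for (j in seq_len(nrow(plan)))
      cover[plan[j, 1] + 1:256, plan[j, 2] + 1:256] <- 1L
    expect_true(all(cover == 1L))
  }
})

test_that("the dihedral orbit has 8 exact, invertible members", {
  set.seed(2)
  x <- matrix(runif(49), 7, 7)  # generic asymmetric patch
  orb <- dihedral_orbit(x)
  expect_length(orb, 8)
  # pairwise distinct for a generic input
  for (a in 1:7) for (b in (a + 1):8)
    expect_false(identical(orb[[a]], orb[[b]]))
  # group inverse: inverse_dihedral(orbit[k], k) == x for all k
  for (k in 0:7)
    expect_identical(inverse_dihedral(orb[[k + 1]], k), x)
  # fully symmetric (constant) patch: 8 identical copies
  const <- matrix(0.3, 6, 6)
  expect_true(all(vapply(dihedral_orbit(const),
                         function(m) identical(m, const), logical(1))))
  expect_error(dihedral_orbit(matrix(0, 3, 4)), "square")
})

test_that("dihedral transforms act per channel on 3-channel arrays", {
  set.seed(3)
  a <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  orb <- dihedral_orbit(a)
  for (k in 0:7) {
    expect_identical(inverse_dihedral(orb[[k + 1]], k), a)
    for (ch in 1:3)
      expect_identical(orb[[k + 1]][, , ch], dihedral_orbit(a[, , ch])[[k + 1]])
  }
})

test_that("TTA prediction equals the explicit orbit-align-max oracle", {
  net <- build_unetr(tiny_net_config(64), seed = 4)
  set.seed(5)
  patch <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  got <- tta_predict(net, patch, tta = TRUE)
  # explicit oracle: transform, predict one by one, invert, pixelwise max
  maps <- lapply(0:7, function(k) {
    tp <- dihedral_orbit(patch)[[k + 1]]
    pred <- ringseg:::predict_patches(net, list(tp))[[1]]
    inverse_dihedral(pred, k)
  })
  oracle <- Reduce(pmax, maps)
  expect_equal(got, oracle, tolerance = 1e-12)
  # disabled TTA is a plain forward pass
  expect_equal(tta_predict(net, patch, tta = FALSE),
               ringseg:::predict_patches(net, list(patch))[[1]])
})

test_that("whole-image prediction normalizes, thresholds and is monotone", {
  net <- build_unetr(tiny_net_config(64), seed = 6)
  set.seed(7)
  img <- array(sample(0:255, 100 * 80 * 3, TRUE), dim = c(100, 80, 3))
  cfg <- inference_config(patch_size = 64, overlap_fraction = 0.5,
                          tta_enabled = FALSE, threshold = 0.2)
  out <- predict_image(net, img, cfg)
  expect_equal(dim(out$prob), c(100, 80))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_equal(range(out$prob), c(0, 1))  # min-max normalized
  # mask pixels are exactly those with normalized probability > threshold
  expect_equal(unclass(out$mask), (unclass(out$prob) > 0.2) * 1L,
               ignore_attr = TRUE)
  # raising the threshold never adds pixels
  hi <- predict_image(net, img,
                      inference_config(patch_size = 64,
                                       overlap_fraction = 0.5,
                                       tta_enabled = FALSE, threshold = 0.6))
  expect_true(all(unclass(hi$mask) <= unclass(out$mask)))
})

test_that("a constant-output network yields an empty mask", {
  net <- build_unetr(tiny_net_config(64), seed = 8)
  net$params$dec$head$W[] <- 0
  net$params$dec$head$b <- -1
  img <- array(120, dim = c(64, 64, 3))
  out <- predict_image(net, img, inference_config(patch_size = 64,
                                                  tta_enabled = FALSE))
  expect_true(all(out$prob == 0))  # constant map normalizes to zero
  expect_equal(sum(out$mask), 0)
})

test_that("the aggregated map is invariant to tile order (max rule)", {
  net <- build_unetr(tiny_net_config(64), seed = 9)
  set.seed(10)
  img <- array(sample(0:255, 90 * 70 * 3, TRUE), dim = c(90, 70, 3))
  cfg <- inference_config(patch_size = 64, overlap_fraction = 0.3,
                          tta_enabled = FALSE)
  # manual recomputation over the (reversed) tile list
  plan <- tile_plan(90, 70, 64, 0.3)
  xn <- img / 255
  agg <- matrix(-Inf, 90, 70)
  for (j in rev(seq_len(nrow(plan)))) {
    r <- plan[j, 1]; c <- plan[j, 2]
    tile <- xn[(r + 1):(r + 64), (c + 1):(c + 64), , drop = FALSE]
    pred <- ringseg:::predict_patches(net, list(tile))[[1]]
    agg[(r + 1):(r + 64), (c + 1):(c + 64)] <-
      pmax(agg[(r + 1):(r + 64), (c + 1):(c + 64)], pred)
  }
  rng <- range(agg)
  prob <- (agg - rng[1]) / (rng[2] - rng[1])
  out <- predict_image(net, img, cfg)
  expect_equal(unclass(out$prob), prob, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("undersized images are reflection-padded and cropped back", {
  net <- build_unetr(tiny_net_config(64), seed = 11)
  img <- array(sample(0:255, 40 * 30 * 3, TRUE), dim = c(40, 30, 3))
  out <- predict_image(net, img, inference_config(patch_size = 64,
                                                  tta_enabled = FALSE))
  expect_equal(dim(out$prob), c(40, 30))
  expect_equal(dim(unclass(out$mask)), c(40, 30))
})
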