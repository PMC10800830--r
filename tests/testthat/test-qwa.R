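# Four-criterion QWA evaluation: pixel agreement, boundary matching and
# spacing, vessel assignment/mismatch, expert-label summaries.

hline <- function(row, cols = 0:49, source = "manual")
  boundary_path(cbind(row = rep(row, length(cols)), col = cols), source)

test_that("pixel agreement reproduces confusion arithmetic", {
  a <- binary_mask(matrix(0L, 8, 8)); b <- a
  expect_equal(pixel_agreement(a, b), c(precision = 1, recall = 1,
                                        F1 = 1, IoU = 1))
  m <- matrix(0L, 8, 8); m[4, ] <- 1L
  expect_equal(pixel_agreement(binary_mask(m), binary_mask(m))[["F1"]], 1)
  # two complete parallel 1-px lines offset by one row: 0% match
  m2 <- matrix(0L, 8, 8); m2[5, ] <- 1L
  res <- pixel_agreement(binary_mask(m), binary_mask(m2))
  expect_equal(res[["F1"]], 0)
  expect_equal(res[["IoU"]], 0)
  expect_error(pixel_agreement(binary_mask(m), binary_mask(matrix(0L, 4, 4))),
               "differ")
})

test_that("pixel agreement matches per-pixel brute force on random masks", {
  set.seed(1)
  for (i in 1:10) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    got <- pixel_agreement(binary_mask(a), binary_mask(b))
    tp <- 0; fp <- 0; fn <- 0
    for (r in 1:8) for (c in 1:8) {
      if (a[r, c] == 1 && b[r, c] == 1) tp <- tp + 1
      if (a[r, c] == 0 && b[r, c] == 1) fp <- fp + 1
      if (a[r, c] == 1 && b[r, c] == 0) fn <- fn + 1
    }
    if (tp + fp + fn == 0) next
    expect_equal(got[["IoU"]], tp / (tp + fp + fn))
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r_ <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(got[["precision"]], p)
    expect_equal(got[["recall"]], r_)
  }
})

test_that("the Hungarian solver matches brute-force assignment", {
  set.seed(2)
  for (n in c(3, 4, 5)) for (i in 1:4) {
    cost <- matrix(runif(n * n, 0, 10), n, n)
    asg <- ringseg:::hungarian_assign(cost)
    expect_equal(sort(asg), seq_len(n))  # a permutation
    expect_equal(sum(cost[cbind(seq_len(n), asg)]),
                 oracle_min_assignment(cost)$cost, tolerance = 1e-9)
  }
})

test_that("identical boundary lists match one-to-one at distance zero", {
  paths <- lapply(c(10, 40, 90), hline)
  ms <- match_boundaries(paths, paths)
  expect_length(ms, 3)
  expect_true(all(vapply(ms, function(r) r$type == "matched", logical(1))))
  expect_true(all(vapply(ms, center_distance, numeric(1)) == 0))
})

test_that("unmatched boundaries become one-sided records", {
  manual <- lapply(c(10, 40), hline)
  predicted <- lapply(c(10.5, 40.5, 200), hline, source = "model")
  ms <- match_boundaries(manual, predicted, gate_px = 15)
  types <- vapply(ms, `[[`, character(1), "type")
  expect_equal(sum(types == "matched"), 2)
  expect_equal(sum(types == "predicted_only"), 1)
  ms2 <- match_boundaries(predicted, manual, gate_px = 15)
  expect_equal(sum(vapply(ms2, `[[`, character(1), "type") == "manual_only"),
               1)
  expect_error(center_distance(ms[[which(types == "predicted_only")]]),
               "matched")
})

test_that("gated matching minimizes total distance like brute force", {
  set.seed(3)
  for (i in 1:6) {
    rows_m <- sort(runif(4, 0, 100))
    rows_p <- sort(runif(4, 0, 100))
    manual <- lapply(rows_m, hline)
    predicted <- lapply(rows_p, hline, source = "model")
    ms <- match_boundaries(manual, predicted, gate_px = Inf)
    got <- sum(vapply(ms, function(r)
      if (r$type == "matched") r$center_distance_px else 0, numeric(1)))
    cost <- outer(rows_m, rows_p, function(a, b) abs(a - b))
    expect_equal(got, oracle_min_assignment(cost)$cost, tolerance = 1e-9)
  }
})

test_that("spacing converts pixels to micrometres by the resolution", {
  a <- hline(20); b <- hline(30, source = "model")
  ms <- match_boundaries(list(a), list(b), gate_px = Inf)
  expect_equal(center_distance(ms[[1]]), 10)
  expect_equal(px_to_um(10), 16.3)
  # 35.85 px at 1.63 um/px -> 58.43 um after truncating to two decimals
  expect_equal(trunc_dec(px_to_um(35.85), 2), 58.43)
})

test_that("vessels are assigned by strict side counts with extension", {
  vessels <- vessel_table(data.frame(
    vessel_id = c("a", "b", "c", "d"),
    row = c(5, 25, 60, 25), col = c(10, 10, 10, 200)))
  bounds <- lapply(c(15, 45), hline)
  idx <- assign_vessels(bounds, vessels)
  expect_equal(idx, c(0L, 1L, 2L, 1L))  # col 200 uses horizontal extension
  expect_equal(assign_vessels(list(), vessels), rep(0L, 4))
  # crossing boundaries are rejected
  x1 <- boundary_path(cbind(row = c(10, 50), col = c(0, 49)))
  x2 <- boundary_path(cbind(row = c(50, 10), col = c(0, 49)))
  expect_error(assign_vessels(list(x1, x2), vessels), "cross")
})

test_that("vessel assignment matches the rasterized-band oracle", {
  set.seed(4)
  for (i in 1:6) {
    s <- generate_sample(small_synth_config(seed = 40 + i))
    got <- assign_vessels(s$boundaries, s$vessels)
    want <- oracle_assign_by_bands(s$boundaries, s$vessels, 330)
    expect_equal(got, as.integer(want))
    # conservation: every vessel in exactly one ring
    expect_equal(sum(tabulate(got + 1L, nbins = 3)), nrow(s$vessels))
  }
})

test_that("vessel mismatch counts vessels between the two delineations", {
  vessels <- vessel_table(data.frame(vessel_id = c("a", "b"),
                                     row = c(22, 60), col = c(5, 5)))
  pair0 <- match_boundaries(list(hline(20)), list(hline(20, source = "model")),
                            gate_px = Inf)[[1]]
  expect_equal(vessel_mismatch(pair0, vessels), 0)
  # predicted shifted 5 rows below the manual, one vessel in the gap
  pair <- match_boundaries(list(hline(20)), list(hline(25, source = "model")),
                           gate_px = Inf)[[1]]
  expect_equal(vessel_mismatch(pair, vessels), 1)
  # symmetry under swapping manual and predicted
  swapped <- match_boundaries(list(hline(25)), list(hline(20, source = "model")),
                              gate_px = Inf)[[1]]
  expect_equal(vessel_mismatch(swapped, vessels), 1)
})

test_that("random mismatch counts agree with a per-vessel side test", {
  set.seed(5)
  for (i in 1:6) {
    cols <- 0:49
    rm_ <- 25 + 4 * sin(cols / 7)
    rp <- 25 + 4 * cos(cols / 9) + runif(1, -6, 6)
    manual <- boundary_path(cbind(row = rm_, col = cols))
    pred <- boundary_path(cbind(row = rp, col = cols), source = "model")
    vessels <- vessel_table(data.frame(
      vessel_id = sprintf("v%d", 1:30),
      row = runif(30, 10, 40), col = runif(30, 0, 49)))
    pair <- match_boundaries(list(manual), list(pred), gate_px = Inf)[[1]]
    got <- vessel_mismatch(pair, vessels)
    want <- sum(vapply(seq_len(30), function(j) {
      rmj <- approx(cols, rm_, vessels$col[j], rule = 2)$y
      rpj <- approx(cols, rp, vessels$col[j], rule = 2)$y
      (vessels$row[j] > rmj) != (vessels$row[j] > rpj)
    }, logical(1)))
    expect_equal(got, want)
  }
})

test_that("zero-distance identity: equal delineations agree everywhere", {
  s <- generate_sample(small_synth_config(seed = 77))
  ev <- evaluate_segmentation(s$boundaries, s$boundaries, s$vessels)
  expect_equal(ev$n_matched, length(s$boundaries))
  expect_true(all(ev$per_ring$center_distance_px == 0))
  expect_true(all(ev$per_ring$vessel_mismatch == 0))
  expect_equal(pixel_agreement(s$mask, s$mask)[["F1"]], 1)
})

test_that("a known vertical shift is recovered by the spacing metric", {
  s <- generate_sample(small_synth_config(seed = 78))
  delta <- 7
  shifted <- lapply(s$boundaries, function(b)
    boundary_path(cbind(row = b$points[, 1] + delta, col = b$points[, 2]),
                  source = "model"))
  ev <- evaluate_segmentation(s$boundaries, shifted, s$vessels)
  expect_equal(ev$n_matched, length(s$boundaries))
  expect_lt(abs(mean(ev$per_ring$center_distance_px) - delta), 0.5)
})

test_that("agreement summaries reproduce the tabulated arithmetic", {
  mk <- function(label, n) replicate(n, eval_record(
    match_boundaries(list(hline(10)), list(hline(11, source = "model")),
                     gate_px = Inf)[[1]],
    expert_label = label, vessel_mismatch = 1), simplify = FALSE)
  records <- c(mk("manual", 108), mk("similar", 619), mk("model", 601))
  s <- summarize_agreement(records, total_rings = 1329)
  expect_equal(s$by_label$pct, c(8.12, 46.57, 45.22))
  expect_equal(s$equal_or_better_pct, 91.79)
  expect_equal(round(s$by_label$pct[1], 1), 8.1)
  expect_equal(sum(s$by_label$n), 1328)
  # single model record: 100 / 0 / 0
  one <- summarize_agreement(mk("model", 1), total_rings = 1)
  expect_equal(one$by_label$pct, c(0, 0, 100))
  # unlabeled records are an error
  expect_error(summarize_agreement(c(mk("model", 1), list(eval_record(
    match_boundaries(list(hline(10)), list(hline(11, source = "model")),
                     gate_px = Inf)[[1]]))), 2), "unlabeled|required")
})

test_that("numeric trinomial codes map onto the label set", {
  pair <- match_boundaries(list(hline(10)), list(hline(11, source = "model")),
                           gate_px = Inf)[[1]]
  expect_equal(eval_record(pair, 0)$expert_label, "manual")
  expect_equal(eval_record(pair, 1)$expert_label, "similar")
  expect_equal(eval_record(pair, 2)$expert_label, "model")
  expect_error(eval_record(pair, "better"), "expert_label")
})

test_that("mean mismatch against mean vessels per ring is a percentage", {
  expect_lt(relative_vessel_divergence(1.18, 120), 1)
  expect_equal(relative_vessel_divergence(1.2, 120), 1)
})
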