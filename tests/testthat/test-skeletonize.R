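# Skeletonization, DSE pruning, and boundary-path extraction.

test_that("an empty mask gives an empty skeleton", {
  g <- skeletonize_mask(binary_mask(matrix(0L, 10, 10)))
  expect_equal(nrow(g$pixels), 0)
  expect_length(g$branches, 0)
  expect_length(extract_boundary_paths(g, 1), 0)
})

test_that("a thick horizontal bar thins to a single chain", {
  m <- matrix(0L, 40, 80)
  m[15:19, 5:75] <- 1L
  g <- skeletonize_mask(binary_mask(m))
  expect_length(g$branches, 1)
  expect_equal(sum(g$degree == 1L), 2)  # two endpoints
  expect_equal(sum(g$degree >= 3L), 0)  # no junctions
  # skeleton is a subset of the mask foreground
  expect_true(all(m[g$pixels] == 1L))
})

no_2x2_block <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  !any(skel[-H, -W] & skel[-1, -W] & skel[-H, -1] & skel[-1, -1])
}

test_that("skeletons are 1-px wide and preserve component count", {
  set.seed(1)
  for (i in 1:15) {
    m <- random_blob_mask(40, 40, n = sample(2:5, 1))
    g <- skeletonize_mask(binary_mask(m))
    expect_true(no_2x2_block(g$skel))
    # topology: component counts agree with the BFS oracle
    expect_equal(max(oracle_components(g$skel)), max(oracle_components(m)))
  }
})

test_that("branch weights follow the disk-reconstruction definition", {
  # single-branch skeleton: weight equals the total reconstructed area
  m <- matrix(0L, 20, 30)
  m[9:11, 4:26] <- 1L
  g <- skeletonize_mask(binary_mask(m))
  expect_length(g$branches, 1)
  w <- branch_reconstruction_weight(g, 1)
  full <- ringseg:::paint_disks(g, seq_len(nrow(g$pixels)))
  expect_equal(w, sum(full > 0))
  expect_error(branch_reconstruction_weight(g, 5), "no branch")
})

test_that("branch weights match a brute-force two-reconstruction oracle", {
  # T-shaped object: trunk plus a stub; check every end branch
  m <- matrix(0L, 25, 30)
  m[12:14, 3:27] <- 1L
  m[3:12, 14:16] <- 1L
  g <- skeletonize_mask(binary_mask(m))
  ends <- which(vapply(g$branches, function(b)
    b$end_free && length(b$removable) > 0, logical(1)))
  expect_gt(length(ends), 1)
  for (i in ends) {
    rem <- g$branches[[i]]$removable
    others <- setdiff(seq_len(nrow(g$pixels)), rem)
    bc <- ringseg:::paint_disks(g, rem)
    oc <- ringseg:::paint_disks(g, others)
    expect_equal(branch_reconstruction_weight(g, i),
                 sum(bc > 0 & oc == 0))
  }
})

test_that("pruning removes a small spur and keeps the trunk", {
  m <- matrix(0L, 30, 120)
  m[14:16, 3:115] <- 1L     # long trunk
  m[9:13, 60] <- 1L         # 5-px spur
  g <- skeletonize_mask(binary_mask(m))
  expect_gt(length(g$branches), 1)
  pruned <- dse_prune(g, prune_config(100))
  expect_length(pruned$branches, 1)
  expect_equal(sum(pruned$degree >= 3L), 0)
  # trunk intact: still spans the full column range
  expect_gte(diff(range(pruned$pixels[, 2])), 105)
  # prune is idempotent and a fixed point when nothing is under threshold
  again <- dse_prune(pruned, prune_config(100))
  expect_equal(again$pixels, pruned$pixels)
  expect_true(no_2x2_block(pruned$skel))
})

test_that("pruning is monotone in the area threshold", {
  set.seed(2)
  m <- random_blob_mask(40, 60, 4)
  m[20, ] <- 1L  # connecting line so something survives
  g <- skeletonize_mask(binary_mask(m))
  sizes <- vapply(c(5, 30, 100, 400), function(thr)
    nrow(dse_prune(g, prune_config(thr))$pixels), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("greedy DSE agrees with exhaustive-order search on toy shapes", {
  shapes <- list()
  m1 <- matrix(0L, 22, 26)           # cross: 4 end branches
  m1[10:12, 3:23] <- 1L
  m1[4:18, 12:14] <- 1L
  shapes[[1]] <- m1
  m2 <- matrix(0L, 20, 28)           # trunk with two stubs
  m2[9:11, 2:26] <- 1L
  m2[4:9, 8] <- 1L
  m2[11:17, 19] <- 1L
  shapes[[2]] <- m2
  for (m in shapes) {
    g <- skeletonize_mask(binary_mask(m))
    for (thr in c(15, 60)) {
      got <- sort(which(dse_prune(g, prune_config(thr))$skel == 1L))
      allowed <- oracle_dse_all_orders(g$skel, g$source_mask, g$dt, thr)
      expect_true(any(vapply(allowed, identical, logical(1), y = got)))
    }
  }
})

test_that("path extraction projects the longest geodesic per component", {
  # straight 200-px chain
  m <- matrix(0L, 10, 210)
  m[5, 6:205] <- 1L
  g <- skeletonize_mask(binary_mask(m))
  paths <- extract_boundary_paths(g, 50)
  expect_length(paths, 1)
  expect_equal(nrow(paths[[1]]$points), 200)
  expect_equal(paths[[1]]$source, "model")
  expect_true(all(paths[[1]]$points[, 1] == 4))  # 0-based row
  # short components are discarded
  expect_length(extract_boundary_paths(g, 500), 0)
})

test_that("longest geodesic matches the all-pairs BFS oracle", {
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(0L, 20, 20)
    # random tree-ish scribble
    r <- 10; c <- 2
    m[r, c] <- 1L
    for (s in 1:40) {
      dr <- sample(-1:1, 1); dc <- sample(0:1, 1)
      r <- min(19, max(2, r + dr)); c <- min(19, max(2, c + dc))
      m[r, c] <- 1L
    }
    g <- skeletonize_mask(binary_mask(m))
    if (nrow(g$pixels) < 3) next
    comp <- oracle_components(g$skel)
    for (k in seq_len(max(comp))) {
      px <- which(comp == k, arr.ind = TRUE)
      if (nrow(px) < 3 || nrow(px) > 100) next
      paths <- extract_boundary_paths(g, 1)
      # geodesic length of the extracted path for this component
      diam <- oracle_geodesic_diameter(px)
      lens <- vapply(paths, function(p) nrow(p$points), numeric(1))
      # the projected path can merge same-column pixels; compare against
      # the unprojected diameter via the component's pixel count bound
      expect_true(any(lens <= diam + 1))
    }
  }
})

test_that("ground-truth masks round-trip to their boundary paths", {
  s <- generate_sample(small_synth_config(seed = 31))
  g <- dse_prune(skeletonize_mask(s$mask), prune_config(30))
  paths <- extract_boundary_paths(g, 40)
  expect_length(paths, length(s$boundaries))
  for (i in seq_along(paths)) {
    truth <- s$boundaries[[i]]$points
    got <- paths[[i]]$points
    shared <- intersect(truth[, 2], got[, 2])
    dtr <- abs(truth[match(shared, truth[, 2]), 1] -
                 got[match(shared, got[, 2]), 1])
    expect_lt(mean(dtr), 2)
  }
})
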