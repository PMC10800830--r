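# Reduce a binary boundary prediction to 1-px-wide ring-boundary paths:
# Zhang-Suen thinning, Discrete Skeleton Evolution (DSE) pruning of spur
# branches by their shape-reconstruction contribution, and extraction of
# the longest geodesic path per component.

OFFS8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Zhang-Suen two-subiteration thinning, vectorized over the whole matrix.
zhang_suen <- function(m) {
  H <- nrow(m); W <- ncol(m)
  M <- matrix(0L, H + 2, W + 2)
  M[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(dr, dc) M[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
      P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
      Bn <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      sq <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- 0L
      for (i in 1:8) A <- A + (sq[[i]] == 0L & sq[[i + 1]] == 1L)
      if (sub == 1) {
        c1 <- P2 * P4 * P6 == 0L; c2 <- P4 * P6 * P8 == 0L
      } else {
        c1 <- P2 * P4 * P8 == 0L; c2 <- P2 * P6 * P8 == 0L
      }
      core <- M[2:(H + 1), 2:(W + 1)]
      del <- core == 1L & Bn >= 2L & Bn <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        core[del] <- 0L
        M[2:(H + 1), 2:(W + 1)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M[2:(H + 1), 2:(W + 1)]
}

# local 0->1 crossing number around (r, c), order N,NE,E,SE,S,SW,W,NW,N
crossing_number <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  val <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > H || cc < 1 || cc > W) 0L else m[rr, cc]
  }
  seqv <- c(val(-1, 0), val(-1, 1), val(0, 1), val(1, 1), val(1, 0),
            val(1, -1), val(0, -1), val(-1, -1))
  sum(seqv == 0L & c(seqv[-1], seqv[1]) == 1L)
}

# remove one simple pixel from every remaining 2x2 foreground block
break_2x2_blocks <- function(m) {
  H <- nrow(m); W <- ncol(m)
  repeat {
    bl <- which(m[-H, -W] == 1L & m[-1, -W] == 1L &
                  m[-H, -1] == 1L & m[-1, -1] == 1L, arr.ind = TRUE)
    if (nrow(bl) == 0) break
    progress <- FALSE
    for (i in seq_len(nrow(bl))) {
      r <- bl[i, 1]; c <- bl[i, 2]
      cand <- rbind(c(r + 1, c + 1), c(r + 1, c), c(r, c + 1), c(r, c))
      for (j in 1:4) {
        rr <- cand[j, 1]; cc <- cand[j, 2]
        if (m[rr, cc] == 1L && crossing_number(m, rr, cc) == 1L) {
          m[rr, cc] <- 0L
          progress <- TRUE
          break
        }
      }
    }
    if (!progress) break
  }
  m
}

# Decompose a thinned pixel set into endpoints/junctions and maximal
# branches. Pixels are stored as an n x 2 matrix of 1-based (row, col).
decompose_skeleton <- function(skel, source_mask, dt) {
  H <- nrow(skel); W <- ncol(skel)
  px <- which(skel == 1L, arr.ind = TRUE)
  n <- nrow(px)
  map <- matrix(0L, H, W)
  if (n > 0) map[px] <- seq_len(n)
  at <- function(r, c)
    r >= 1 && r <= H && c >= 1 && c <= W && map[r, c] > 0L
  nbrs <- vector("list", n)
  deg <- integer(n)
  for (i in seq_len(n)) {
    r <- px[i, 1]; c <- px[i, 2]
    ids <- integer(0)
    for (k in 1:8) {
      dr <- OFFS8[k, 1]; dc <- OFFS8[k, 2]
      if (!at(r + dr, c + dc)) next
      # a diagonal link bridged by an orthogonal skeleton pixel is
      # redundant (8-connected staircases otherwise read as junctions)
      if (dr != 0L && dc != 0L &&
          (at(r + dr, c) || at(r, c + dc))) next
      ids <- c(ids, map[r + dr, c + dc])
    }
    nbrs[[i]] <- ids
    deg[i] <- length(ids)
  }
  is_node <- deg != 2L
  branches <- list()
  consumed <- logical(n)
  add_branch <- function(ids, is_cycle) {
    free_ends <- ids[deg[ids] == 1L]
    removable <- ids[!is_node[ids] | deg[ids] <= 1L]
    branches[[length(branches) + 1]] <<- list(
      px = ids, removable = removable, is_cycle = is_cycle,
      end_free = length(free_ends) > 0 || length(ids) == 1)
  }
  seen_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (u in which(is_node)) {
    if (deg[u] == 0L) { add_branch(u, FALSE); next }
    for (v in nbrs[[u]]) {
      if (is_node[v]) {
        k <- edge_key(u, v)
        if (!is.null(seen_edge[[k]])) next
        seen_edge[[k]] <- TRUE
        add_branch(c(u, v), FALSE)
      } else if (!consumed[v]) {
        path <- c(u, v)
        consumed[v] <- TRUE
        prev <- u; cur <- v
        repeat {
          nxt <- setdiff(nbrs[[cur]], prev)
          if (length(nxt) == 0) break           # dead end inside chain
          nxt <- nxt[1]
          path <- c(path, nxt)
          if (is_node[nxt]) break
          consumed[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        add_branch(path, FALSE)
      }
    }
  }
  # remaining unconsumed degree-2 pixels form pure cycles
  for (i in seq_len(n)) {
    if (is_node[i] || consumed[i]) next
    path <- i
    consumed[i] <- TRUE
    prev <- i; cur <- nbrs[[i]][1]
    while (!is.null(cur) && cur != i) {
      path <- c(path, cur)
      consumed[cur] <- TRUE
      nxt <- setdiff(nbrs[[cur]], prev)
      prev <- cur
      cur <- if (length(nxt) > 0) nxt[1] else NULL
    }
    add_branch(path, TRUE)
  }
  structure(list(pixels = px, map = map, degree = deg, nbrs = nbrs,
                 branches = branches, source_mask = source_mask, dt = dt,
                 dim = c(H, W), skel = skel),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph: %d pixels, %d branches, %d endpoints, %d junctions>\n",
              nrow(x$pixels), length(x$branches), sum(x$degree == 1L),
              sum(x$degree >= 3L)))
  invisible(x)
}

#' Skeletonize a binary boundary mask
#'
#' Thins the mask to a 1-px-wide, topology-preserving skeleton (Zhang-Suen
#' two-subiteration thinning, 8-connectivity) and decomposes it into
#' endpoints, junctions and maximal branches. The source mask and its
#' Euclidean distance transform are kept on the graph: DSE pruning needs
#' them for the maximal-disk reconstruction.
#'
#' @param mask a [binary_mask()].
#' @return A `skeleton_graph`.
#' @export
# 8-connected component labels of a 0/1 matrix (BFS flood fill)
label_components8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  px <- which(m == 1L, arr.ind = TRUE)
  n <- nrow(px)
  map <- matrix(0L, H, W)
  if (n > 0) map[px] <- seq_len(n)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      r <- px[u, 1]; c <- px[u, 2]
      rr <- r + OFFS8[, 1]; cc <- c + OFFS8[, 2]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      ids <- map[cbind(rr[ok], cc[ok])]
      for (v in ids[ids > 0L]) if (lab[v] == 0L) {
        lab[v] <- cur
        queue <- c(queue, v)
      }
    }
  }
  list(px = px, lab = lab, n = cur)
}

skeletonize_mask <- function(mask) {
  m <- unclass(mask)
  storage.mode(m) <- "integer"
  skel <- break_2x2_blocks(zhang_suen(m))
  dt <- if (any(m == 1L))
    as.matrix(EBImage::distmap(m, metric = "euclidean"))
  else matrix(0, nrow(m), ncol(m))
  # parallel thinning can erase very small components (a 2x2 block
  # deletes in one pass); restore one representative pixel per lost
  # component so the skeleton keeps the mask's topology
  if (any(m == 1L)) {
    comp <- label_components8(m)
    alive <- unique(comp$lab[skel[comp$px] == 1L])
    for (k in setdiff(seq_len(comp$n), alive)) {
      ids <- which(comp$lab == k)
      pick <- ids[which.max(dt[comp$px[ids, , drop = FALSE]])]
      skel[comp$px[pick, 1], comp$px[pick, 2]] <- 1L
    }
  }
  decompose_skeleton(skel, mask, dt)
}

# paint the union of maximal disks centred on `ids` into an integer count
# map (each disk adds 1 where it covers)
paint_disks <- function(graph, ids, base = NULL) {
  H <- graph$dim[1]; W <- graph$dim[2]
  cnt <- if (is.null(base)) matrix(0L, H, W) else base
  for (i in ids) {
    r <- graph$pixels[i, 1]; c <- graph$pixels[i, 2]
    rad <- max(graph$dt[r, c], 1)
    ir <- ceiling(rad)
    rr <- max(1, r - ir):min(H, r + ir)
    cc <- max(1, c - ir):min(W, c + ir)
    disk <- outer((rr - r)^2, (cc - c)^2, "+") <= rad^2 + 1e-9
    cnt[rr, cc] <- cnt[rr, cc] + disk
  }
  cnt
}

#' Reconstruction weight of a skeleton branch
#'
#' The DSE relevance of a branch: the number of source-mask foreground
#' pixels covered by the union of maximal disks (radius = distance
#' transform) centred on the branch's removable pixels but not covered by
#' the disks of the remaining skeleton. Fully redundant branches weigh 0;
#' a skeleton's only branch weighs its entire reconstructed area.
#'
#' @param graph a `skeleton_graph`.
#' @param branch branch index in `graph$branches`.
#' @return non-negative reconstruction weight in pixels.
#' @export
branch_reconstruction_weight <- function(graph, branch) {
  stopifnot(inherits(graph, "skeleton_graph"))
  stop_if_not(branch >= 1 && branch <= length(graph$branches),
              "no branch %s in graph", as.character(branch))
  br <- graph$branches[[branch]]
  rem <- br$removable
  if (length(rem) == 0) return(0)
  others <- setdiff(seq_len(nrow(graph$pixels)), rem)
  bc <- paint_disks(graph, rem)
  oc <- if (length(others) > 0) paint_disks(graph, others)
        else matrix(0L, graph$dim[1], graph$dim[2])
  sum(bc > 0 & oc == 0L)
}

#' Pruning configuration for Discrete Skeleton Evolution
#'
#' @param min_branch_area_px end-branches whose reconstruction weight is
#'   below this area are pruned (default 100).
#' @param mode `"reconstruction"` ranks branches by DSE reconstruction
#'   weight; `"length"` by raw pixel count.
#' @return A validated `prune_config` list.
#' @export
prune_config <- function(min_branch_area_px = 100,
                         mode = c("reconstruction", "length")) {
  mode <- match.arg(mode)
  stop_if_not(is_scalar(min_branch_area_px) && min_branch_area_px > 0,
              "min_branch_area_px must be positive")
  structure(list(min_branch_area_px = min_branch_area_px, mode = mode),
            class = "prune_config")
}

#' Prune spur branches by Discrete Skeleton Evolution
#'
#' Iteratively removes the end-branch with the smallest reconstruction
#' weight while that weight is below `min_branch_area_px`, re-deriving the
#' node classification and weights after every removal. Ties are broken by
#' branch length, then by lexicographically first pixel. Components that
#' are pure cycles are left untouched; the output skeleton is a subset of
#' the input.
#'
#' @param graph a `skeleton_graph` from [skeletonize_mask()].
#' @param cfg a [prune_config()].
#' @return The pruned `skeleton_graph`.
#' @export
component_membership <- function(g) {
  n <- nrow(g$pixels)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in g$nbrs[[u]]) if (comp[v] == 0L) {
        comp[v] <- cur
        queue <- c(queue, v)
      }
    }
  }
  comp
}

dse_prune <- function(graph, cfg = prune_config()) {
  stopifnot(inherits(graph, "skeleton_graph"), inherits(cfg, "prune_config"))
  skel <- graph$skel
  g <- graph
  if (nrow(g$pixels) == 0) return(g)
  # coverage count over all current skeleton pixels' disks; a branch's
  # weight is the area its own disks cover exclusively, i.e. where the
  # total count equals the branch's own count
  total <- paint_disks(g, seq_len(nrow(g$pixels)))
  # fast path: an acyclic component whose whole reconstruction area is
  # below the threshold loses all its branches under DSE no matter the
  # removal order, so such components are removed at component granularity
  # (in increasing weight order, keeping the coverage map exact)
  if (cfg$mode == "reconstruction") {
    comp <- component_membership(g)
    removed <- FALSE
    info <- lapply(seq_len(max(comp)), function(k) {
      ids <- which(comp == k)
      acyclic <- sum(g$degree[ids]) / 2 == length(ids) - 1
      if (!acyclic) return(NULL)
      cmap <- paint_disks(g, ids)
      list(ids = ids, cmap = cmap, w = sum(cmap > 0L & total == cmap))
    })
    info <- Filter(Negate(is.null), info)
    for (ci in order(vapply(info, `[[`, numeric(1), "w"))) {
      cm <- info[[ci]]
      w <- sum(cm$cmap > 0L & total == cm$cmap)
      if (w < cfg$min_branch_area_px) {
        skel[g$pixels[cm$ids, , drop = FALSE]] <- 0L
        total <- total - cm$cmap
        removed <- TRUE
      }
    }
    if (removed) g <- decompose_skeleton(skel, graph$source_mask, graph$dt)
  }
  repeat {
    cand <- which(vapply(g$branches, function(b)
      b$end_free && !b$is_cycle && length(b$removable) > 0, logical(1)))
    if (length(cand) == 0) break
    bmaps <- lapply(cand, function(i)
      paint_disks(g, g$branches[[i]]$removable))
    w <- vapply(seq_along(cand), function(k) {
      if (cfg$mode == "length") length(g$branches[[cand[k]]]$removable)
      else sum(bmaps[[k]] > 0L & total == bmaps[[k]])
    }, numeric(1))
    under <- w < cfg$min_branch_area_px
    if (!any(under)) break
    cand <- cand[under]; bmaps <- bmaps[under]; w <- w[under]
    len <- vapply(cand, function(i) length(g$branches[[i]]$px), numeric(1))
    first_px <- t(vapply(cand, function(i) {
      p <- g$pixels[g$branches[[i]]$px, , drop = FALSE]
      p[order(p[, 1], p[, 2])[1], ]
    }, numeric(2)))
    k <- order(w, len, first_px[, 1], first_px[, 2])[1]
    rm_ids <- g$branches[[cand[k]]]$removable
    skel[g$pixels[rm_ids, , drop = FALSE]] <- 0L
    total <- total - bmaps[[k]]
    g <- decompose_skeleton(skel, graph$source_mask, graph$dt)
  }
  g
}

#' Extract ring-boundary paths from a pruned skeleton
#'
#' For each connected component the longest geodesic pixel path (graph
#' diameter under 8-connectivity) is taken; paths shorter than
#' `min_path_len_px` pixels are discarded. Each surviving path is projected
#' to function-of-column form (per-column mean row) and the list is
#' returned sorted by mean row, with source `"model"`.
#'
#' @param graph a `skeleton_graph`.
#' @param min_path_len_px minimum geodesic length in pixels (default 50).
#' @return list of [boundary_path()] objects.
#' @export
extract_boundary_paths <- function(graph, min_path_len_px = 50) {
  stopifnot(inherits(graph, "skeleton_graph"))
  n <- nrow(graph$pixels)
  if (n == 0) return(list())
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- graph$nbrs[[i]]
    js <- js[js > i]
    if (length(js) == 0) NULL else cbind(i, js)
  }))
  ig <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(0L, 0, 2) else edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  out <- list()
  for (k in unique(comp)) {
    vs <- which(comp == k)
    if (length(vs) < min_path_len_px) next
    sub <- igraph::induced_subgraph(ig, vs)
    dia <- as.integer(igraph::get_diameter(sub))
    ids <- vs[dia]
    if (length(ids) < min_path_len_px) next
    pts <- graph$pixels[ids, , drop = FALSE]
    rows <- tapply(pts[, 1], pts[, 2], mean)
    cols <- as.numeric(names(rows))
    ord <- order(cols)
    out[[length(out) + 1]] <- boundary_path(
      cbind(row = as.numeric(rows)[ord] - 1, col = cols[ord] - 1),
      source = "model")
  }
  if (length(out) > 1) {
    mr <- vapply(out, function(p) mean(p$points[, 1]), numeric(1))
    out <- out[order(mr)]
  }
  out
}
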