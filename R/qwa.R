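# Four-criterion evaluation of ring-boundary delineations for QWA:
# (1) pixel-level coincidence, (2) spacing of per-boundary mean positions,
# (3) vessel-to-ring mismatch, (4) expert-label agreement summaries.

#' Pixel-level agreement between two binary masks
#'
#' Standard confusion metrics treating `a` as the reference. Two parallel
#' complete 1-px lines offset by one row share no pixels and score F1 = 0 -
#' the motivation for the complementary boundary-level criteria.
#'
#' @param a reference [binary_mask()].
#' @param b comparison [binary_mask()] of the same shape.
#' @return named numeric: `precision`, `recall`, `F1`, `IoU`. Two empty
#'   masks agree perfectly (all metrics 1).
#' @export
pixel_agreement <- function(a, b) {
  stop_if_not(all(dim(a) == dim(b)), "mask shapes differ")
  av <- as.integer(a); bv <- as.integer(b)
  tp <- sum(av == 1L & bv == 1L)
  fp <- sum(av == 0L & bv == 1L)
  fn <- sum(av == 1L & bv == 0L)
  if (tp + fp + fn == 0)
    return(c(precision = 1, recall = 1, F1 = 1, IoU = 1))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, F1 = f1,
    IoU = tp / (tp + fp + fn))
}

#' Convert a pixel distance to micrometres
#'
#' @param d_px distance in pixels.
#' @param resolution_um_per_px physical resolution (default 1.63).
#' @return distance in micrometres.
#' @export
#' @examples
#' px_to_um(35.85)  # 58.4355, printed as 58.43 after truncation
px_to_um <- function(d_px, resolution_um_per_px = 1.63) {
  stop_if_not(is_scalar(resolution_um_per_px) && resolution_um_per_px > 0,
              "resolution must be positive")
  d_px * resolution_um_per_px
}

# O(n^3) Hungarian algorithm on a square cost matrix; returns, for each
# row, the assigned column.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- 1e18
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

#' Match manual and predicted boundaries one-to-one
#'
#' Optimal one-to-one assignment (Hungarian algorithm) minimizing the total
#' distance between per-boundary mean positions, among pairs closer than
#' `gate_px`; matching as many pairs as the gate allows. Unassigned manual
#' boundaries become `manual_only` records (rings the model failed to
#' detect), unassigned predicted ones `predicted_only` (boundaries absent
#' from the manual delineation).
#'
#' @param manual,predicted lists of [boundary_path()] objects from the
#'   same image.
#' @param gate_px maximum mean-position distance for a valid pair; default
#'   half the median manual ring width (`Inf` when fewer than two manual
#'   boundaries exist).
#' @param distance `"euclidean"` distance between mean positions, or
#'   `"row"` for the absolute row (growth-axis) difference.
#' @return list of `boundary_match` records with fields `type`
#'   (`matched` / `manual_only` / `predicted_only`), `manual`, `predicted`,
#'   `manual_index`, `predicted_index`, `center_distance_px`.
#' @export
match_boundaries <- function(manual, predicted, gate_px = NULL,
                             distance = c("euclidean", "row")) {
  distance <- match.arg(distance)
  nm <- length(manual); np <- length(predicted)
  mpos <- lapply(manual, boundary_mean_position)
  ppos <- lapply(predicted, boundary_mean_position)
  if (is.null(gate_px)) {
    rows <- sort(vapply(mpos, `[`, numeric(1), 1))
    gate_px <- if (length(rows) >= 2) 0.5 * median(diff(rows)) else Inf
  }
  BIG <- 1e12; UNMATCHED <- 1e6
  d <- function(a, b) {
    if (distance == "row") abs(a[1] - b[1])
    else sqrt(sum((a - b)^2))
  }
  rec <- function(type, mi = NA, pi = NA, dist = NA_real_) {
    structure(list(type = type,
                   manual = if (is.na(mi)) NULL else manual[[mi]],
                   predicted = if (is.na(pi)) NULL else predicted[[pi]],
                   manual_index = mi, predicted_index = pi,
                   center_distance_px = dist), class = "boundary_match")
  }
  if (nm + np == 0) return(list())
  n <- nm + np
  cost <- matrix(0, n, n)
  if (nm > 0 && np > 0)
    for (i in seq_len(nm)) for (j in seq_len(np)) {
      dij <- d(mpos[[i]], ppos[[j]])
      cost[i, j] <- if (dij <= gate_px) dij else BIG
    }
  if (nm > 0) cost[seq_len(nm), np + seq_len(nm)] <- UNMATCHED
  if (np > 0) cost[nm + seq_len(np), seq_len(np)] <- UNMATCHED
  asg <- hungarian_assign(cost)
  out <- list()
  for (i in seq_len(nm)) {
    j <- asg[i]
    if (j <= np && cost[i, j] < BIG)
      out[[length(out) + 1]] <- rec("matched", i, j, cost[i, j])
    else out[[length(out) + 1]] <- rec("manual_only", mi = i)
  }
  matched_pred <- vapply(out, function(r)
    if (r$type == "matched") r$predicted_index else NA_integer_, integer(1))
  for (j in setdiff(seq_len(np), matched_pred))
    out[[length(out) + 1]] <- rec("predicted_only", pi = j)
  out
}

#' Distance between the mean positions of a matched pair
#'
#' @param pair a matched `boundary_match` record.
#' @return distance in pixels between the two boundary mean positions.
#' @export
center_distance <- function(pair) {
  stopifnot(inherits(pair, "boundary_match"))
  stop_if_not(pair$type == "matched",
              "center_distance needs a matched pair, got '%s'", pair$type)
  pair$center_distance_px
}

# crossing check on a column grid shared by all boundaries
check_non_crossing <- function(boundaries, cols) {
  if (length(boundaries) < 2) return(invisible(TRUE))
  rows <- vapply(boundaries, boundary_row_at, numeric(length(cols)),
                 cols = cols)
  rows <- matrix(rows, nrow = length(cols))
  for (k in seq_len(ncol(rows) - 1))
    if (any(rows[, k] >= rows[, k + 1]))
      stop("boundaries ", k, " and ", k + 1, " cross; vessel assignment ",
           "requires non-crossing boundaries", call. = FALSE)
  invisible(TRUE)
}

#' Assign vessels to rings
#'
#' A vessel's ring index is the number of boundaries whose interpolated
#' row at the vessel's column lies strictly above (less than) the vessel's
#' row; boundaries not spanning that column are extended horizontally from
#' their nearest endpoint. Indices run from 0 (above the first boundary)
#' to `length(boundaries)`.
#'
#' @param boundaries list of non-crossing [boundary_path()] objects,
#'   sorted by mean row (sorted internally if not).
#' @param vessels a [vessel_table()] (or data frame with `row`, `col`).
#' @return integer vector of ring indices, one per vessel.
#' @export
assign_vessels <- function(boundaries, vessels) {
  if (length(boundaries) == 0) return(rep(0L, nrow(vessels)))
  mr <- vapply(boundaries, function(p) mean(p$points[, 1]), numeric(1))
  boundaries <- boundaries[order(mr)]
  span <- range(unlist(lapply(boundaries, function(p) p$points[, 2])),
                vessels$col)
  grid <- sort(unique(c(seq(span[1], span[2], length.out = 256),
                        vessels$col)))
  check_non_crossing(boundaries, grid)
  idx <- rep(0L, nrow(vessels))
  for (b in boundaries) {
    rb <- boundary_row_at(b, vessels$col)
    idx <- idx + as.integer(rb < vessels$row)
  }
  idx
}

#' Vessels assigned differently by two delineations of one boundary
#'
#' Counts the vessels whose side (above/below, by interpolated row at the
#' vessel's column) differs between the manual and the predicted version
#' of a matched boundary - the vessels lying between the two delineations.
#'
#' @param pair a matched `boundary_match` record.
#' @param vessels a [vessel_table()] (or data frame with `row`, `col`).
#' @return non-negative integer mismatch count.
#' @export
vessel_mismatch <- function(pair, vessels) {
  stopifnot(inherits(pair, "boundary_match"))
  stop_if_not(pair$type == "matched",
              "vessel_mismatch needs a matched pair, got '%s'", pair$type)
  if (nrow(vessels) == 0) return(0L)
  rm_ <- boundary_row_at(pair$manual, vessels$col)
  rp <- boundary_row_at(pair$predicted, vessels$col)
  sum((vessels$row > rm_) != (vessels$row > rp))
}

#' Relative vessel divergence
#'
#' A mean per-ring vessel mismatch expressed as a percentage of the mean
#' vessel count per ring; about one mismatched vessel against 120 vessels
#' per ring is a divergence below 1%.
#'
#' @param mean_mismatch mean vessels mismatched per ring.
#' @param vessels_per_ring mean vessels per ring.
#' @return percentage (0--100 scale).
#' @export
relative_vessel_divergence <- function(mean_mismatch, vessels_per_ring) {
  stop_if_not(vessels_per_ring > 0, "vessels_per_ring must be positive")
  100 * mean_mismatch / vessels_per_ring
}

TRINOMIAL <- c("manual", "similar", "model")

#' Per-ring evaluation record
#'
#' Couples a [match_boundaries()] record with the expert's trinomial
#' judgement of which delineation is better: `"manual"` (0), `"similar"`
#' (1) or `"model"` (2).
#'
#' @param match a `boundary_match` record.
#' @param expert_label label or code in `0:2`; `NA` allowed for unlabeled.
#' @param center_distance_px,vessel_mismatch optional precomputed metrics
#'   (taken from `match` / left `NA` otherwise).
#' @return An `eval_record` list.
#' @export
eval_record <- function(match, expert_label = NA,
                        center_distance_px = NULL, vessel_mismatch = NA) {
  stopifnot(inherits(match, "boundary_match"))
  if (!is.na(expert_label) && !is.character(expert_label))
    expert_label <- TRINOMIAL[as.integer(expert_label) + 1L]
  stop_if_not(is.na(expert_label) || expert_label %in% TRINOMIAL,
              "expert_label must be one of %s (or 0/1/2)",
              paste(TRINOMIAL, collapse = "/"))
  structure(list(match = match,
                 expert_label = expert_label,
                 center_distance_px = if (is.null(center_distance_px))
                   match$center_distance_px else center_distance_px,
                 vessel_mismatch = vessel_mismatch),
            class = "eval_record")
}

#' Summarize expert agreement over evaluated rings
#'
#' Reproduces the arithmetic of per-label agreement tables: for each
#' trinomial label the ring count, its percentage of `total_rings`
#' (truncated at two decimals), and mean with standard error
#' (`sd / sqrt(n)`) of the center distance and the vessel mismatch; plus
#' the "equal or better" percentage (`similar` + `model`).
#'
#' @param records list of labelled [eval_record()]s for matched rings
#'   (unlabeled matched records are an error).
#' @param total_rings total ring count the percentages refer to (>= number
#'   of records).
#' @param n_manual_only,n_predicted_only counts of unmatched boundaries to
#'   carry into the summary.
#' @return An `agreement_summary`: data frame `by_label` plus totals.
#' @export
summarize_agreement <- function(records, total_rings,
                                n_manual_only = 0, n_predicted_only = 0) {
  stop_if_not(is_count(total_rings), "total_rings must be a positive integer")
  stop_if_not(total_rings >= length(records),
              "total_rings (%d) smaller than the number of records (%d)",
              total_rings, length(records))
  labels <- vapply(records, function(r) {
    stopifnot(inherits(r, "eval_record"))
    if (is.na(r$expert_label))
      stop("unlabeled record; expert labels are required", call. = FALSE)
    r$expert_label
  }, character(1))
  dist <- vapply(records, function(r)
    if (is.null(r$center_distance_px)) NA_real_ else
      as.numeric(r$center_distance_px), numeric(1))
  mm <- vapply(records, function(r) as.numeric(r$vessel_mismatch),
               numeric(1))
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  by_label <- do.call(rbind, lapply(TRINOMIAL, function(lb) {
    sel <- labels == lb
    data.frame(label = lb, n = sum(sel),
               pct = trunc_dec(100 * sum(sel) / total_rings, 2),
               mean_center_distance_px = mn(dist[sel]),
               se_center_distance_px = se(dist[sel]),
               mean_vessel_mismatch = mn(mm[sel]),
               se_vessel_mismatch = se(mm[sel]))
  }))
  structure(list(
    by_label = by_label,
    total_rings = as.integer(total_rings),
    n_records = length(records),
    n_manual_only = as.integer(n_manual_only),
    n_predicted_only = as.integer(n_predicted_only),
    equal_or_better_pct = trunc_dec(
      100 * sum(labels %in% c("similar", "model")) / total_rings, 2)),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement over %d rings (%d labelled records):\n",
              x$total_rings, x$n_records))
  print(x$by_label, row.names = FALSE)
  cat(sprintf("equal-or-better: %.2f%%; manual-only %d, predicted-only %d\n",
              x$equal_or_better_pct, x$n_manual_only, x$n_predicted_only))
  invisible(x)
}

#' Evaluate a predicted delineation against the manual reference
#'
#' Runs the boundary-level criteria for one image: one-to-one matching of
#' boundaries, mean-position spacing in pixels and micrometres, and the
#' per-boundary vessel mismatch. Expert labels, when available, can be fed
#' to [summarize_agreement()] afterwards.
#'
#' @param manual,predicted lists of [boundary_path()] objects.
#' @param vessels optional [vessel_table()] for the mismatch criterion.
#' @param resolution_um_per_px physical resolution for the um conversion.
#' @param gate_px,distance forwarded to [match_boundaries()].
#' @return `list(matches, per_ring, n_matched, n_manual_only,
#'   n_predicted_only)`, where `per_ring` is a data frame with one row per
#'   matched boundary.
#' @export
evaluate_segmentation <- function(manual, predicted, vessels = NULL,
                                  resolution_um_per_px = 1.63,
                                  gate_px = NULL,
                                  distance = c("euclidean", "row")) {
  matches <- match_boundaries(manual, predicted, gate_px = gate_px,
                              distance = distance)
  matched <- Filter(function(r) r$type == "matched", matches)
  per_ring <- do.call(rbind, lapply(matched, function(r) {
    vm <- if (is.null(vessels) || nrow(vessels) == 0) NA_integer_
          else vessel_mismatch(r, vessels)
    data.frame(manual_index = r$manual_index,
               predicted_index = r$predicted_index,
               center_distance_px = r$center_distance_px,
               center_distance_um = px_to_um(r$center_distance_px,
                                             resolution_um_per_px),
               vessel_mismatch = vm)
  }))
  if (is.null(per_ring))
    per_ring <- data.frame(manual_index = integer(),
                           predicted_index = integer(),
                           center_distance_px = numeric(),
                           center_distance_um = numeric(),
                           vessel_mismatch = integer())
  list(matches = matches, per_ring = per_ring,
       n_matched = length(matched),
       n_manual_only = sum(vapply(matches, function(r)
         r$type == "manual_only", logical(1))),
       n_predicted_only = sum(vapply(matches, function(r)
         r$type == "predicted_only", logical(1))))
}
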