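# Domain types and file I/O for microsection images and their annotations.
#
# Coordinate convention: 0-based (row, col), row 0 at the top of the image.
# Cores are tall (height >> width) and the growth axis is the row axis, so
# ring boundaries run roughly along columns and a boundary is stored in
# function-of-column form (strictly increasing col).

#' Microsection image
#'
#' An RGB pixel grid with a physical resolution. Pixels are 8-bit
#' intensities (0--255) stored as an `H x W x 3` integer array.
#'
#' @param pixels `H x W x 3` numeric array with values in 0--255.
#' @param resolution_um_per_px physical resolution in micrometres per pixel
#'   (default 1.63, the scale of 40x microsection scans).
#' @param sample_id character identifier.
#' @return An object of class `microsection_image`.
#' @export
microsection_image <- function(pixels, resolution_um_per_px = 1.63,
                               sample_id = "sample") {
  d <- dim(pixels)
  stop_if_not(length(d) == 3 && d[3] == 3,
              "pixels must be an H x W x 3 array, got dims [%s]",
              paste(d, collapse = ", "))
  stop_if_not(d[1] >= 1 && d[2] >= 1, "image must have H >= 1 and W >= 1")
  stop_if_not(is_scalar(resolution_um_per_px) && resolution_um_per_px > 0,
              "resolution_um_per_px must be a positive number")
  stop_if_not(all(pixels >= 0 & pixels <= 255),
              "pixel values must lie in [0, 255]")
  structure(list(pixels = round(pixels),
                 resolution_um_per_px = resolution_um_per_px,
                 sample_id = as.character(sample_id)),
            class = "microsection_image")
}

#' @export
dim.microsection_image <- function(x) dim(x$pixels)

#' @export
print.microsection_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<microsection_image '%s': %d x %d px, %.2f um/px>\n",
              x$sample_id, d[1], d[2], x$resolution_um_per_px))
  invisible(x)
}

#' Ring-boundary path
#'
#' An ordered pixel path for one ring boundary in function-of-column form:
#' columns strictly increasing, one (row, col) pair per stored point.
#'
#' @param points two-column numeric matrix `(row, col)`, 0-based, with
#'   strictly increasing col.
#' @param source one of `"manual"`, `"model"`, `"synthetic"`.
#' @return An object of class `boundary_path`.
#' @export
boundary_path <- function(points, source = c("manual", "model", "synthetic")) {
  source <- match.arg(source)
  points <- as.matrix(points)
  stop_if_not(ncol(points) == 2 && nrow(points) >= 1,
              "a boundary path needs an n x 2 matrix with n >= 1 points")
  stop_if_not(all(is.finite(points)), "boundary points must be finite")
  stop_if_not(nrow(points) == 1 || all(diff(points[, 2]) > 0),
              "boundary path columns must be strictly increasing")
  dimnames(points) <- list(NULL, c("row", "col"))
  structure(list(points = points, source = source), class = "boundary_path")
}

#' @export
print.boundary_path <- function(x, ...) {
  cat(sprintf("<boundary_path (%s): %d points, cols %g..%g, mean row %.1f>\n",
              x$source, nrow(x$points), x$points[1, 2],
              x$points[nrow(x$points), 2], mean(x$points[, 1])))
  invisible(x)
}

#' Vessel table
#'
#' Validates a data frame of vessel records: one row per vessel with real
#' valued center `(row, col)`, optional non-negative `lumen_area_um2` and
#' optional integer `ring_index`.
#'
#' @param df data frame with columns `vessel_id`, `row`, `col` and
#'   optionally `lumen_area_um2`, `ring_index`.
#' @return The validated data frame (class `vessel_table` prepended).
#' @export
vessel_table <- function(df) {
  need <- c("vessel_id", "row", "col")
  stop_if_not(all(need %in% names(df)),
              "vessel table must have columns %s", paste(need, collapse = ", "))
  stop_if_not(all(is.finite(df$row)) && all(is.finite(df$col)),
              "vessel centers must be finite numbers")
  if ("lumen_area_um2" %in% names(df)) {
    bad <- !is.na(df$lumen_area_um2) & df$lumen_area_um2 < 0
    stop_if_not(!any(bad), "negative lumen area for vessel(s) %s",
                paste(df$vessel_id[bad], collapse = ", "))
  }
  df$vessel_id <- as.character(df$vessel_id)
  class(df) <- unique(c("vessel_table", class(df)))
  df
}

#' Binary ring-boundary mask
#'
#' @param m integer/logical matrix; 1 marks ring-boundary pixels.
#' @return 0/1 integer matrix of class `binary_mask`.
#' @export
binary_mask <- function(m) {
  m <- as.matrix(m)
  stop_if_not(all(m %in% c(0, 1)), "mask values must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("binary_mask", class(m))
  m
}

#' Per-pixel ring-boundary probability map
#'
#' @param m numeric matrix with values in `[0, 1]`.
#' @return matrix of class `probability_map`.
#' @export
probability_map <- function(m) {
  m <- as.matrix(m)
  stop_if_not(all(is.finite(m)) && all(m >= 0 & m <= 1),
              "probability values must lie in [0, 1]")
  class(m) <- c("probability_map", class(m))
  m
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".yaml")

#' Read a microsection image from TIFF or PNG
#'
#' 16-bit inputs are rescaled to 8-bit. The physical resolution is taken
#' from the `resolution_um_per_px` argument if given, else from a YAML
#' sidecar (`<image>.yaml`) if present, else the 1.63 um/px default.
#'
#' @param path file path to an RGB TIFF or PNG image.
#' @param resolution_um_per_px optional resolution override.
#' @return A [microsection_image()].
#' @export
read_microsection <- function(path, resolution_um_per_px = NULL) {
  stop_if_not(file.exists(path), "image file not found: %s", path)
  ext <- tolower(sub(".*\\.", "", path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (need TIFF or PNG)",
         call. = FALSE))
  if (length(dim(px)) == 2)
    stop("image is not RGB: single-channel layout in ", path, call. = FALSE)
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3] != 3)
    stop("image is not RGB: ", dim(px)[3], " channels in ", path,
         call. = FALSE)
  # readers return [0,1] floats for any bit depth; 65535 -> 1 -> 255
  px <- round(px * 255)
  res <- resolution_um_per_px
  if (is.null(res)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- yaml::read_yaml(sc)
      if (!is.null(meta$resolution_um_per_px))
        res <- as.numeric(meta$resolution_um_per_px)
    }
  }
  if (is.null(res)) res <- 1.63
  microsection_image(px, res, sub("\\.[A-Za-z]+$", "", basename(path)))
}

#' Write a microsection image (plus YAML sidecar) to TIFF or PNG
#'
#' @param image a [microsection_image()].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_microsection <- function(image, path) {
  stopifnot(inherits(image, "microsection_image"))
  px <- image$pixels / 255
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'", call. = FALSE))
  yaml::write_yaml(list(sample_id = image$sample_id,
                        resolution_um_per_px = image$resolution_um_per_px),
                   sidecar_path(path))
  invisible(path)
}

#' Read ring-boundary paths from CSV
#'
#' Expects columns `boundary_id, point_index, row, col`. Points are sorted
#' by `point_index` within each boundary; malformed rows are rejected, not
#' coerced.
#'
#' @param path CSV file path.
#' @return list of [boundary_path()] objects, ordered by first appearance
#'   of their `boundary_id`.
#' @param source path source tag to attach (default `"manual"`).
#' @export
read_boundaries <- function(path, source = "manual") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("boundary_id", "point_index", "row", "col")
  stop_if_not(all(need %in% names(df)),
              "boundary CSV must have columns %s", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(list())
  for (col in c("point_index", "row", "col"))
    stop_if_not(is.numeric(df[[col]]) && all(is.finite(df[[col]])),
                "non-numeric values in boundary CSV column '%s'", col)
  key <- paste(df$boundary_id, df$point_index)
  stop_if_not(!anyDuplicated(key),
              "duplicated (boundary_id, point_index) in %s", path)
  ids <- unique(df$boundary_id)
  lapply(ids, function(id) {
    sub <- df[df$boundary_id == id, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    boundary_path(cbind(row = sub$row, col = sub$col), source = source)
  })
}

#' Write ring-boundary paths to CSV
#'
#' @param paths list of [boundary_path()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(paths, path) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    stopifnot(inherits(p, "boundary_path"))
    data.frame(boundary_id = sprintf("b%03d", i - 1),
               point_index = seq_len(nrow(p$points)) - 1L,
               row = p$points[, 1], col = p$points[, 2])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(boundary_id = character(), point_index = integer(),
                     row = numeric(), col = numeric())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vessel table from CSV
#'
#' Expects columns `vessel_id, row, col` and optionally `lumen_area_um2`,
#' `ring_index`. Rows are returned in file order.
#'
#' @param path CSV file path.
#' @return A [vessel_table()] data frame.
#' @export
read_vessels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "row", "col")
  stop_if_not(all(need %in% names(df)),
              "vessel CSV must have columns %s", paste(need, collapse = ", "))
  num_cols <- intersect(c("row", "col", "lumen_area_um2", "ring_index"),
                        names(df))
  if (nrow(df) == 0) {
    df$vessel_id <- as.character(df$vessel_id)
    for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
    return(vessel_table(df))
  }
  for (col in num_cols)
    stop_if_not(is.numeric(df[[col]]),
                "non-numeric values in vessel CSV column '%s'", col)
  vessel_table(df)
}

#' Write a vessel table to CSV
#'
#' @param vessels a [vessel_table()] data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vessels <- function(vessels, path) {
  write.csv(as.data.frame(unclass(vessels)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# Interpolated row of a boundary at arbitrary (possibly fractional) columns.
# Columns outside the path's span extend horizontally from the nearest
# endpoint (approx rule = 2).
boundary_row_at <- function(path, cols) {
  p <- path$points
  if (nrow(p) == 1) return(rep(p[1, 1], length(cols)))
  approx(p[, 2], p[, 1], xout = cols, rule = 2)$y
}

# Mean (row, col) of a path's stored points.
#' Mean position of a boundary path
#'
#' The arithmetic mean of the path's pixel coordinates; the per-ring
#' location statistic whose spacing between two delineations of the same
#' ring measures their disagreement.
#'
#' @param path a [boundary_path()].
#' @return named numeric `c(row, col)`.
#' @export
boundary_mean_position <- function(path) {
  stopifnot(inherits(path, "boundary_path"))
  c(row = mean(path$points[, 1]), col = mean(path$points[, 2]))
}
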