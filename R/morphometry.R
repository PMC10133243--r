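#' The 27-feature morphometry registry
#'
#' Ordered registry of the per-cell descriptors extracted from a labelled
#' nuclear mask and its paired grayscale intensity image: a 14-feature shape
#' block (regionprops-style measurements, lengths in µm and areas in µm²) and
#' a 13-feature staining block (statistics of the intensity values under the
#' mask, on the 0-255 scale). The registry is data-driven: passing a
#' reordered or subset registry to [extract_features()] changes the output
#' accordingly, and a hash of the registry travels with every feature table.
#'
#' @return A tibble with columns `name`, `block` (`shape`/`intensity`) and
#'   `kind` (`length`, `area`, `dimensionless`, `count`, `intensity`), 27
#'   rows.
#' @export
feature_registry <- function() {
  tibble(
    name = c("area", "convex_area", "filled_area", "perimeter",
             "equivalent_diameter", "major_axis_length", "minor_axis_length",
             "eccentricity", "orientation", "solidity", "extent",
             "euler_number", "circularity", "aspect_ratio",
             "int_mean", "int_median", "int_min", "int_max", "int_sd",
             "int_mad", "int_range", "int_q25", "int_q75", "int_iqr",
             "int_skewness", "int_kurtosis", "int_entropy"),
    block = rep(c("shape", "intensity"), c(14, 13)),
    kind = c("area", "area", "area", "length", "length", "length", "length",
             "dimensionless", "dimensionless", "dimensionless",
             "dimensionless", "count", "dimensionless", "dimensionless",
             rep("intensity", 13))
  )
}

registry_hash <- function(registry) rlang::hash(registry$name)

#' Extract per-cell morphometric and staining features
#'
#' Computes the [feature_registry()] descriptors for every labelled region of
#' a nuclear mask. Lengths are scaled by `scale` (µm/px) and areas by
#' `scale^2`; intensity statistics are taken over the masked pixels of the
#' paired grayscale image. Moments use the regionprops convention of adding
#' 1/12 px² to the second central moments (the variance of a unit pixel), so
#' one-pixel-wide regions keep eccentricity < 1. Labels with fewer than 3
#' pixels are skipped with a warning (their moments are undefined for axis
#' estimation).
#'
#' @param mask Integer matrix; 0 = background, k > 0 = pixels of cell k.
#'   Rows are y (downwards), columns are x.
#' @param intensity Numeric matrix, same shape, grayscale values in
#'   \[0, 255\].
#' @param scale Micrometres per pixel.
#' @param registry Feature registry (name order defines column order).
#' @param species_code,cls_lookup Optional species tag and a named vector
#'   mapping label -> class carried into the output.
#' @return Tibble with `cell_id` (the label, as character), `species_code`,
#'   `cls`, centroid `x`, `y` (µm), then one column per registry feature;
#'   attribute `registry_hash`.
#' @export
extract_features <- function(mask, intensity, scale = 1,
                             registry = feature_registry(),
                             species_code = NA_character_,
                             cls_lookup = NULL) {
  stopifnot(is.matrix(mask), is.matrix(intensity))
  if (!all(dim(mask) == dim(intensity))) {
    abort("`mask` and `intensity` must have the same dimensions.")
  }
  if (!is.finite(scale) || scale <= 0) abort("`scale` must be > 0.")
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labs) == 0) abort("Mask contains no labelled pixels.")
  idx_by_lab <- split(which(mask > 0), as.integer(mask[mask > 0]))
  nr <- nrow(mask)

  rows <- purrr::map(labs, function(lb) {
    idx <- idx_by_lab[[as.character(lb)]]
    if (length(idx) < 3) return(NULL)
    rr <- ((idx - 1L) %% nr) + 1L   # row = y
    cc <- ((idx - 1L) %/% nr) + 1L  # col = x
    vals <- intensity[idx]
    f <- region_features(rr, cc, vals, scale)
    c(list(cell_id = as.character(lb)), f)
  })
  skipped <- labs[purrr::map_lgl(rows, is.null)]
  if (length(skipped) > 0) {
    warn(paste0("Skipped label(s) with < 3 pixels: ",
                paste(skipped, collapse = ", "), "."))
  }
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("No label had >= 3 pixels.")
  out <- purrr::map_dfr(rows, as_tibble)
  out$species_code <- species_code
  out$cls <- if (is.null(cls_lookup)) NA_character_ else
    unname(cls_lookup[out$cell_id])
  out <- out[, c("cell_id", "species_code", "cls", "x", "y", registry$name)]
  attr(out, "registry_hash") <- registry_hash(registry)
  attr(out, "microns_per_pixel") <- scale
  out
}

# All 27 descriptors for one region. rr/cc are pixel row/col indices, vals the
# intensity values at those pixels.
region_features <- function(rr, cc, vals, scale) {
  n <- length(rr)
  # pixel centres: x = col - 0.5, y = row - 0.5
  xs <- cc - 0.5
  ys <- rr - 0.5
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  # second central moments with the 1/12 px^2 pixel-extent correction
  uxx <- mean(dx^2) + 1 / 12
  uyy <- mean(dy^2) + 1 / 12
  uxy <- mean(dx * dy)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  lam1 <- (uxx + uyy + common) / 2
  lam2 <- (uxx + uyy - common) / 2
  major <- 4 * sqrt(lam1)
  minor <- 4 * sqrt(max(lam2, 0))
  ecc <- sqrt(max(0, 1 - lam2 / lam1))
  # angle of the major axis, degrees in (-90, 90]; positive = counter-
  # clockwise with y pointing up (so the sign of uxy is flipped for the
  # image's y-down convention)
  orientation <- if (common == 0) 0 else
    0.5 * atan2(-2 * uxy, uxx - uyy) * 180 / pi

  crop <- crop_mask(rr, cc)
  per_px <- border_perimeter(crop)
  topo <- fill_and_euler(crop)

  hull_px <- convex_pixel_count(xs, ys)
  bbox_area <- (max(rr) - min(rr) + 1) * (max(cc) - min(cc) + 1)

  area <- n * scale^2
  perim <- per_px * scale
  q <- unname(quantile(vals, c(0.25, 0.5, 0.75)))
  list(
    x = cx * scale, y = cy * scale,
    area = area,
    convex_area = hull_px * scale^2,
    filled_area = topo$filled * scale^2,
    perimeter = perim,
    equivalent_diameter = sqrt(4 * area / pi),
    major_axis_length = major * scale,
    minor_axis_length = minor * scale,
    eccentricity = ecc,
    orientation = orientation,
    solidity = n / hull_px,
    extent = n / bbox_area,
    euler_number = topo$euler,
    circularity = 4 * pi * area / perim^2,
    aspect_ratio = major / max(minor, .Machine$double.eps),
    int_mean = mean(vals),
    int_median = q[2],
    int_min = min(vals),
    int_max = max(vals),
    int_sd = sd(vals),
    int_mad = median(abs(vals - q[2])),
    int_range = max(vals) - min(vals),
    int_q25 = q[1],
    int_q75 = q[3],
    int_iqr = q[3] - q[1],
    int_skewness = if (sd(vals) > 0) e1071::skewness(vals) else 0,
    int_kurtosis = if (sd(vals) > 0) e1071::kurtosis(vals) else 0,
    int_entropy = shannon_entropy_256(vals)
  )
}

crop_mask <- function(rr, cc) {
  r0 <- min(rr); c0 <- min(cc)
  m <- matrix(FALSE, max(rr) - r0 + 1L, max(cc) - c0 + 1L)
  m[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
  m
}

pad_mask <- function(m, pad = 1L) {
  out <- matrix(FALSE, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  out[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
  out
}

# Weighted border-pixel perimeter approximation. Border pixels (those losing
# a 4-neighbour under erosion) are classified by a 3x3 neighbourhood code
# (corners 10, edges 2, centre 1) and weighted: isolated edge configurations
# count 1, diagonal steps sqrt(2), mixed corners (1 + sqrt(2))/2.
border_perimeter <- function(m) {
  p <- pad_mask(m)
  nr <- nrow(p); nc <- ncol(p)
  ctr <- p[2:(nr - 1), 2:(nc - 1)]
  up <- p[1:(nr - 2), 2:(nc - 1)]; down <- p[3:nr, 2:(nc - 1)]
  left <- p[2:(nr - 1), 1:(nc - 2)]; right <- p[2:(nr - 1), 3:nc]
  eroded <- ctr & up & down & left & right
  b <- matrix(0L, nr, nc)
  b[2:(nr - 1), 2:(nc - 1)] <- as.integer(ctr & !eroded)
  bu <- b[1:(nr - 2), 2:(nc - 1)]; bd <- b[3:nr, 2:(nc - 1)]
  bl <- b[2:(nr - 1), 1:(nc - 2)]; br <- b[2:(nr - 1), 3:nc]
  bul <- b[1:(nr - 2), 1:(nc - 2)]; bur <- b[1:(nr - 2), 3:nc]
  bdl <- b[3:nr, 1:(nc - 2)]; bdr <- b[3:nr, 3:nc]
  code <- 10L * (bul + bur + bdl + bdr) + 2L * (bu + bd + bl + br) +
    b[2:(nr - 1), 2:(nc - 1)]
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(w[code[b[2:(nr - 1), 2:(nc - 1)] == 1L] + 1])
}

# Filled area (holes included) and Euler number (components minus holes) via
# EBImage hole filling / connected-component labelling on the padded crop.
fill_and_euler <- function(m) {
  p <- pad_mask(m)
  filled <- EBImage::fillHull(EBImage::Image(p * 1)) > 0.5
  holes <- filled & !p
  n_holes <- max(EBImage::bwlabel(EBImage::Image(holes * 1)))
  n_comp <- max(EBImage::bwlabel(EBImage::Image(p * 1)))
  list(filled = sum(filled), euler = as.integer(n_comp - n_holes))
}

# Number of pixel centres on or inside the convex hull of the region's pixel
# centres, counted by a scanline over integer+0.5 rows. Degenerate (collinear)
# regions fall back to the pixel count itself.
convex_pixel_count <- function(xs, ys) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) < 3) return(length(xs))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (abs(polygon_area(hx, hy)) < 1e-9) return(length(xs))
  eps <- 1e-9
  total <- 0L
  for (y in seq(min(ys), max(ys), by = 1)) {
    xr <- scanline_range(hx, hy, y, eps)
    if (is.null(xr)) next
    lo <- ceiling(xr[1] - 0.5 - eps) + 0.5
    hi <- floor(xr[2] - 0.5 + eps) + 0.5
    if (hi >= lo) total <- total + as.integer(round(hi - lo)) + 1L
  }
  max(total, length(xs))
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

scanline_range <- function(hx, hy, y, eps) {
  n <- length(hx)
  j <- c(n, seq_len(n - 1))
  xs <- c()
  for (k in seq_len(n)) {
    y1 <- hy[j[k]]; y2 <- hy[k]; x1 <- hx[j[k]]; x2 <- hx[k]
    if (abs(y1 - y2) < eps) {
      if (abs(y - y1) < eps) xs <- c(xs, x1, x2)
    } else if ((y >= min(y1, y2) - eps) && (y <= max(y1, y2) + eps)) {
      t <- (y - y1) / (y2 - y1)
      xs <- c(xs, x1 + t * (x2 - x1))
    }
  }
  if (length(xs) == 0) return(NULL)
  c(min(xs), max(xs))
}

shannon_entropy_256 <- function(vals) {
  b <- pmin(pmax(floor(vals), 0), 255)
  p <- tabulate(b + 1L, nbins = 256L)
  p <- p[p > 0] / length(b)
  -sum(p * log2(p))
}

#' Match annotations to detected cell centroids
#'
#' Greedy one-to-one assignment by ascending distance: annotation-centroid
#' pairs within `max_dist` are sorted by distance and accepted while both
#' members are unused. The default threshold is 1.824 µm (4 px at the 20X
#' working resolution of 0.456 µm/px).
#'
#' @param annotations Data frame with `cell_id`, `x`, `y` (µm).
#' @param centroids Data frame with `cell_id`, `x`, `y` (µm) of detected
#'   cells, e.g. from [extract_features()].
#' @param max_dist Matching threshold in micrometres.
#' @return Tibble with one row per annotation: `annotation_id`, `matched_id`
#'   (`NA` when unmatched) and `distance`.
#' @export
map_annotations_to_cells <- function(annotations, centroids,
                                     max_dist = 1.824) {
  if (!is.finite(max_dist) || max_dist <= 0) abort("`max_dist` must be > 0.")
  na <- nrow(annotations); nc <- nrow(centroids)
  if (na == 0) abort("No annotations supplied.")
  d <- outer(annotations$x, centroids$x, "-")^2 +
    outer(annotations$y, centroids$y, "-")^2
  d <- sqrt(d)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  matched <- rep(NA_integer_, na)
  dist_out <- rep(NA_real_, na)
  if (nrow(cand) > 0) {
    ord <- order(d[cand])
    used_c <- logical(nc)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (is.na(matched[i]) && !used_c[j]) {
        matched[i] <- j
        dist_out[i] <- d[i, j]
        used_c[j] <- TRUE
      }
    }
  }
  tibble(
    annotation_id = annotations$cell_id,
    matched_id = ifelse(is.na(matched), NA_character_,
                        centroids$cell_id[matched]),
    distance = dist_out
  )
}

#' Read and write label / intensity images
#'
#' Label masks are stored as single-channel 16-bit images (0 = background,
#' k > 0 = cell k); intensity images as 8-bit grayscale. PNG and TIFF are
#' supported, chosen by file extension.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_label_image()` / `read_intensity_image()` return an integer
#'   matrix (rows = y, columns = x); the writers return `path` invisibly.
#' @export
read_label_image <- function(path) {
  img <- read_gray(path)
  m <- round(img * 65535)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_image
#' @export
read_intensity_image <- function(path) {
  img <- read_gray(path)
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' @param mask Integer label matrix (values < 65536). Written as 16-bit TIFF
#'   (PNG writing is 8-bit only in R and cannot hold label values > 255).
#' @rdname read_label_image
#' @export
write_label_image <- function(mask, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("tif", "tiff")) {
    abort("Label masks are written as 16-bit TIFF; use a .tif/.tiff path.")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @param img Integer intensity matrix (values 0-255).
#' @rdname read_label_image
#' @export
write_intensity_image <- function(img, path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(img / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(img / 255, path, bits.per.sample = 8L),
    abort("Unsupported image extension (use png/tif/tiff).")
  )
  invisible(path)
}

read_gray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort("Unsupported image extension (use png/tif/tiff).")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
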