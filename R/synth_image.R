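#' Class-conditional nuclear morphology profile
#'
#' Distributional parameters from which synthetic nuclei are drawn, per cell
#' class: nuclear area (log-normal, median in µm² and log-scale dispersion),
#' aspect ratio (>= 1), boundary irregularity in \[0, 1\] (amplitude of a
#' low-frequency radial perturbation of the ellipse outline) and mean
#' hematoxylin-scale stain intensity in \[0, 255\] with its spread. Defaults
#' emulate the qualitative structure of H&E nuclei: lymphocytes small, round
#' and dark; cancer nuclei large, pleomorphic and intermediate; stromal
#' nuclei elongated and pale.
#'
#' @param profile Optional tibble overriding the defaults (same columns).
#' @return Tibble with one row per class: `cls`, `area_median`,
#'   `area_dispersion`, `aspect_mean`, `aspect_sd`, `irregularity`,
#'   `intensity_mean`, `intensity_sd`.
#' @export
morphology_profile <- function(profile = NULL) {
  if (!is.null(profile)) {
    stopifnot(all(c("cls", "area_median", "area_dispersion", "aspect_mean",
                    "aspect_sd", "irregularity", "intensity_mean",
                    "intensity_sd") %in% names(profile)))
    stopifnot(all(profile$area_dispersion > 0),
              all(profile$cls %in% CORE_CLASSES),
              all(profile$aspect_mean >= 1),
              all(profile$irregularity >= 0 & profile$irregularity <= 1))
    return(as_tibble(profile))
  }
  tibble(
    cls = c("cancer", "lymphocyte", "stromal"),
    area_median = c(110, 35, 55),
    area_dispersion = c(0.35, 0.20, 0.30),
    aspect_mean = c(1.5, 1.1, 2.6),
    aspect_sd = c(0.25, 0.08, 0.50),
    irregularity = c(0.15, 0.03, 0.08),
    intensity_mean = c(140, 90, 150),
    intensity_sd = c(20, 12, 18)
  )
}

#' Generate a labelled nuclear image with ground truth
#'
#' Draws non-overlapping synthetic nuclei (ellipses with a low-frequency
#' radial perturbation) on a blank canvas and rasterises them into a 16-bit
#' label mask plus a paired 8-bit grayscale intensity image. Cell size,
#' elongation, boundary irregularity and staining are drawn from the
#' class-conditional [morphology_profile()]. The truth table records each
#' cell's rasterised centroid and class.
#'
#' @param profile A [morphology_profile()].
#' @param n_per_class Named integer vector, e.g.
#'   `c(cancer = 50, lymphocyte = 50, stromal = 50)`.
#' @param canvas Canvas width/height in µm, length-2 vector.
#' @param scale Micrometres per pixel of the raster.
#' @param seed RNG seed; the generator is fully seed-deterministic.
#' @param max_tries Placement attempts per cell before giving up.
#' @return List with `mask` (integer label matrix), `intensity` (integer
#'   matrix, 0-255), `truth` (tibble: `cell_id`, `x`, `y` in µm, `cls`,
#'   `source = "annotation"`) and `spec` (the generating parameters).
#' @export
gen_cell_image <- function(profile = morphology_profile(),
                           n_per_class = c(cancer = 50, lymphocyte = 50,
                                           stromal = 50),
                           canvas = c(250, 250), scale = 0.456,
                           seed = 1L, max_tries = 80L) {
  stopifnot(all(names(n_per_class) %in% profile$cls),
            all(n_per_class >= 0), length(canvas) == 2, all(canvas > 0))
  with_seed_if(seed, {
    w_px <- ceiling(canvas[1] / scale)
    h_px <- ceiling(canvas[2] / scale)
    mask <- matrix(0L, h_px, w_px)
    intensity <- matrix(as.integer(round(pmin(pmax(rnorm(h_px * w_px, 225, 8), 0), 255))),
                        h_px, w_px)
    classes <- rep(names(n_per_class), n_per_class)
    classes <- sample(classes)  # interleave placement order
    truth <- vector("list", length(classes))
    lab <- 0L
    n_rejected <- 0L
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      pr <- profile[profile$cls == cl, ]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cell <- draw_nucleus(pr, scale)
        # candidate centre, keeping the whole bounding radius on canvas
        rmax <- cell$rmax_px
        if (2 * rmax + 2 >= min(h_px, w_px)) next
        cx <- runif(1, rmax + 1, w_px - rmax - 1)
        cy <- runif(1, rmax + 1, h_px - rmax - 1)
        px <- rasterise_nucleus(cell, cx, cy, h_px, w_px)
        if (length(px) < 3 || any(mask[px] != 0L)) {
          n_rejected <- n_rejected + 1L
          next
        }
        lab <- lab + 1L
        mask[px] <- lab
        intensity[px] <- as.integer(round(pmin(pmax(
          rnorm(length(px), pr$intensity_mean, pr$intensity_sd), 0), 255)))
        rr <- ((px - 1L) %% h_px) + 1L
        cc <- ((px - 1L) %/% h_px) + 1L
        truth[[ci]] <- tibble(cell_id = sprintf("c%05d", lab),
                              x = mean(cc - 0.5) * scale,
                              y = mean(rr - 0.5) * scale,
                              cls = cl, source = "annotation")
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(paste0("Could not place cell ", ci, " of ", length(classes),
                     " after ", max_tries, " attempts (", n_rejected,
                     " rejections so far); increase the canvas size or ",
                     "reduce cell counts."))
      }
    }
    truth <- dplyr::bind_rows(truth)
    list(mask = mask, intensity = intensity, truth = truth,
         spec = list(profile = profile, n_per_class = n_per_class,
                     canvas = canvas, scale = scale, seed = seed,
                     n_rejected = n_rejected))
  })
}

# Sample one nucleus: semi-axes from area/aspect draws, a random orientation
# and 2nd-4th harmonic radial perturbation amplitudes scaled by the class
# irregularity.
draw_nucleus <- function(pr, scale) {
  area <- rlnorm(1, log(pr$area_median), pr$area_dispersion)
  ar <- max(1, rnorm(1, pr$aspect_mean, pr$aspect_sd))
  a_um <- sqrt(area * ar / pi)
  b_um <- a_um / ar
  phi <- runif(1, 0, pi)
  kh <- 2:4
  amp <- rnorm(3, 0, pr$irregularity / 2)
  pha <- runif(3, 0, 2 * pi)
  a_px <- a_um / scale
  b_px <- b_um / scale
  rmax_px <- a_px * (1 + sum(abs(amp))) + 1
  list(a = a_px, b = b_px, phi = phi, kh = kh, amp = amp, pha = pha,
       rmax_px = rmax_px)
}

rasterise_nucleus <- function(cell, cx, cy, h_px, w_px) {
  r <- ceiling(cell$rmax_px)
  cols <- max(1L, floor(cx - r)):min(w_px, ceiling(cx + r))
  rows <- max(1L, floor(cy - r)):min(h_px, ceiling(cy + r))
  g <- expand.grid(row = rows, col = cols)
  u <- (g$col - 0.5) - cx
  v <- (g$row - 0.5) - cy
  # rotate into the ellipse frame
  ur <- u * cos(cell$phi) + v * sin(cell$phi)
  vr <- -u * sin(cell$phi) + v * cos(cell$phi)
  rho <- sqrt((ur / cell$a)^2 + (vr / cell$b)^2)
  theta <- atan2(vr, ur)
  mod <- 1 + Reduce(`+`, lapply(seq_along(cell$kh), function(i) {
    cell$amp[i] * cos(cell$kh[i] * theta + cell$pha[i])
  }))
  inside <- rho <= pmax(mod, 0.2)
  (g$col[inside] - 1L) * h_px + g$row[inside]
}
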