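## Puncta morphometry: projection, rolling-ball background subtraction,
## median filtering, fractional-max threshold masks, connected-component
## counting, density and per-punctum intensity.

#' Maximum-intensity projection with background correction
#'
#' Projects a z-stack to a maximum-intensity image, subtracts a rolling-ball
#' background (grayscale opening with a ball structuring element of the
#' stated physical radius), and returns both the 3 x 3 median-filtered and
#' the unfiltered corrected projection. Masks are built from the filtered
#' image; per-punctum intensities must be measured on the unfiltered one.
#'
#' @param stack numeric matrix (single plane) or 3-D array (y, x, z).
#' @param pixel_size pixel edge (nm).
#' @param ball_radius_um rolling-ball radius (micrometers, default 1).
#' @param median_px median filter window (odd, default 3; 0 disables).
#' @param ball_aspect intensity units per pixel of ball height (the ball is
#'   a sphere in (x, y, intensity) space after this scaling; default 1).
#' @return a list with `filtered` and `unfiltered` corrected projections
#'   and `background`.
#' @export
preprocess_projection <- function(stack, pixel_size, ball_radius_um = 1,
                                  median_px = 3L, ball_aspect = 1) {
  check_that(is_scalar_num(pixel_size) && pixel_size > 0,
             "pixel_size must be > 0")
  proj <- if (length(dim(stack)) == 3L) apply(stack, c(1, 2), max)
          else as.matrix(stack)
  r_px <- ball_radius_um * 1000 / pixel_size
  check_that(r_px >= 1, "ball radius below one pixel")
  bg <- rolling_ball_background(proj, r_px, ball_aspect)
  corrected <- proj - bg
  filtered <- if (median_px >= 3L) median_filter(corrected, median_px)
              else corrected
  list(filtered = filtered, unfiltered = corrected, background = bg)
}

# Grayscale opening with a ball structuring element: background estimate.
# b(u) = aspect * (sqrt(r^2 - |u|^2) - r) <= 0, peak 0 at the center.
rolling_ball_background <- function(img, r_px, ball_aspect = 1) {
  r <- ceiling(r_px)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- off$dr^2 + off$dc^2
  off <- off[d2 <= r_px^2, ]
  h <- ball_aspect * (sqrt(r_px^2 - off$dr^2 - off$dc^2) - r_px)
  er <- shift_reduce(img, off$dr, off$dc, -h, pmin, Inf)
  shift_reduce(er, -off$dr, -off$dc, h, pmax, -Inf)
}

# reduce(img shifted by (dr, dc) + add) over all offsets; `fill` pads
# outside the image so border pixels use only available support.
shift_reduce <- function(img, dr, dc, add, reduce, fill) {
  ny <- nrow(img); nx <- ncol(img)
  acc <- matrix(fill, ny, nx)
  for (k in seq_along(dr)) {
    sr <- dr[k]; sc <- dc[k]
    if (abs(sr) >= ny || abs(sc) >= nx) next
    r_dst <- max(1L, 1L - sr):min(ny, ny - sr)
    c_dst <- max(1L, 1L - sc):min(nx, nx - sc)
    acc[r_dst, c_dst] <- reduce(acc[r_dst, c_dst],
                                img[r_dst + sr, c_dst + sc] + add[k])
  }
  acc
}

# 3x3 (or k x k) median filter with replicate padding.
median_filter <- function(img, k = 3L) {
  k <- as.integer(k)
  check_that(k %% 2L == 1L && k >= 3L, "median window must be odd and >= 3")
  ny <- nrow(img); nx <- ncol(img)
  half <- k %/% 2L
  pad <- img[pmin(pmax(seq_len(ny + 2L * half) - half, 1L), ny),
             pmin(pmax(seq_len(nx + 2L * half) - half, 1L), nx)]
  stackv <- vapply(seq_len(k * k), function(i) {
    dr <- (i - 1L) %% k
    dc <- (i - 1L) %/% k
    as.numeric(pad[dr + seq_len(ny), dc + seq_len(nx)])
  }, numeric(ny * nx))
  matrix(apply(stackv, 1, median), ny, nx)
}

#' Fractional-of-maximum threshold mask
#'
#' Pixels at or above `fraction` of the image maximum. An all-zero image
#' yields an empty mask with a warning (not an error).
#'
#' @param image numeric matrix.
#' @param fraction threshold fraction in (0, 1]; the analysis chain uses
#'   0.15 or 0.35.
#' @return logical matrix.
#' @export
threshold_mask <- function(image, fraction) {
  check_that(is_scalar_num(fraction) && fraction > 0 && fraction <= 1,
             "fraction must be in (0, 1]")
  mx <- max(image)
  if (mx <= 0) {
    warning("image maximum is not positive: empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image >= fraction * mx
}

#' Label connected components (8-connectivity)
#'
#' @param mask logical matrix.
#' @param min_size minimum component size in pixels (default 0: no filter).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, min_size = 0L) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0L) {
      px <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((px - 1L) %% ny) + 1L
      c <- ((px - 1L) %/% ny) + 1L
      for (dc in -1:1) {
        cc <- c + dc
        if (cc < 1L || cc > nx) next
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > ny) next
          nb <- (cc - 1L) * ny + rr
          if (mask[nb] && labels[nb] == 0L) {
            labels[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  if (min_size > 0L && cur > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = cur)
    keep <- which(sizes >= min_size)
    remap <- integer(cur)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}

#' Count puncta and measure morphometry
#'
#' Counts 8-connected components of the puncta mask, measures the marker
#' mask area, their ratio (density), and the mean intensity of each punctum
#' on the background-corrected unfiltered projection.
#'
#' @param puncta_mask logical matrix (e.g. the Brp 15%-of-max mask).
#' @param corrected_unfiltered background-corrected unfiltered projection
#'   on which intensities are measured.
#' @param area_mask logical matrix whose area normalizes the count (e.g.
#'   the HRP mask); an empty mask gives `NA` density with a warning.
#' @param pixel_size pixel edge (nm).
#' @param min_size minimum punctum size in pixels (default 0).
#' @return an object of class `morphometry`: `object_count`,
#'   `mask_area_um2`, `density_per_um2`, `object_intensity` (per-punctum
#'   means), `mean_intensity`, `labels`.
#' @export
count_and_measure <- function(puncta_mask, corrected_unfiltered, area_mask,
                              pixel_size, min_size = 0L) {
  check_that(all(dim(puncta_mask) == dim(corrected_unfiltered)) &&
               all(dim(puncta_mask) == dim(area_mask)),
             "masks and image must share shape")
  check_that(is_scalar_num(pixel_size) && pixel_size > 0,
             "pixel_size must be > 0")
  labels <- label_components(puncta_mask, min_size)
  count <- max(labels)
  px_um2 <- (pixel_size / 1000)^2
  area <- sum(area_mask) * px_um2
  if (area == 0) warning("empty area mask: density undefined")
  density <- if (area > 0) count / area else NA_real_
  obj_int <- if (count > 0)
    as.numeric(tapply(corrected_unfiltered[labels > 0L],
                      labels[labels > 0L], mean))
  else numeric(0)
  structure(list(object_count = count, mask_area_um2 = area,
                 density_per_um2 = density, object_intensity = obj_int,
                 mean_intensity = if (count > 0) mean(obj_int) else NA_real_,
                 labels = labels),
            class = "morphometry")
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf(
    "morphometry: %d puncta, area %.3f um^2, density %.3f /um^2, mean intensity %.3f\n",
    x$object_count, x$mask_area_um2, x$density_per_um2, x$mean_intensity))
  invisible(x)
}
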