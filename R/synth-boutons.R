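## Synthetic two-channel puncta geometries inside bouton polygons, and a
## Gaussian-PSF renderer for two-channel images.

#' Parameters for two-channel bouton point simulation
#'
#' Settings for [simulate_boutons()]. Reference points are placed uniformly
#' inside the bouton polygon. Each target point is, with probability
#' `coupling_fraction`, tethered to a uniformly chosen reference point plus
#' an isotropic Gaussian displacement of SD `coupling_sigma` (re-drawn until
#' it falls inside the polygon); otherwise it is itself uniform in the
#' polygon (complete spatial randomness).
#'
#' @param polygon n x 2 matrix of bouton boundary vertices (nm); defaults to
#'   [bouton_polygon()].
#' @param n_ref,n_target point counts for the reference and target channel.
#' @param coupling_fraction fraction of target points tethered to a
#'   reference point.
#' @param coupling_sigma tether displacement SD (nm).
#' @param seed integer RNG seed or NULL.
#' @return an object of class `bouton_sim_params`.
#' @export
bouton_sim_params <- function(polygon = bouton_polygon(),
                              n_ref = 12L, n_target = 15L,
                              coupling_fraction = 0, coupling_sigma = 50,
                              seed = NULL) {
  polygon <- as_polygon_matrix(polygon)
  check_that(polygon_area(polygon) > 0, "polygon must have positive area")
  check_that(is_scalar_num(n_ref) && n_ref >= 0, "n_ref must be >= 0")
  check_that(is_scalar_num(n_target) && n_target >= 0, "n_target must be >= 0")
  check_that(is_scalar_num(coupling_fraction) && coupling_fraction >= 0 &&
               coupling_fraction <= 1, "coupling_fraction must be in [0, 1]")
  check_that(is_scalar_num(coupling_sigma) && coupling_sigma >= 0,
             "coupling_sigma must be >= 0")
  structure(list(polygon = polygon, n_ref = as.integer(n_ref),
                 n_target = as.integer(n_target),
                 coupling_fraction = coupling_fraction,
                 coupling_sigma = coupling_sigma, seed = seed),
            class = "bouton_sim_params")
}

#' Irregular bouton boundary polygon
#'
#' A closed, simple polygon approximating a synaptic bouton outline: a
#' circle of the given radius with smooth radial modulation. Guaranteed
#' simple because the radius stays positive for `wobble < 1`.
#'
#' @param radius mean radius (nm); boutons are of order 1 micron across.
#' @param wobble relative amplitude of the radial modulation, in [0, 1).
#' @param n_vertices number of boundary vertices.
#' @param phase rotation of the modulation (radians).
#' @return an n x 2 matrix of vertices (nm).
#' @export
bouton_polygon <- function(radius = 1000, wobble = 0.25, n_vertices = 48L,
                           phase = 0) {
  check_that(is_scalar_num(radius) && radius > 0, "radius must be > 0")
  check_that(is_scalar_num(wobble) && wobble >= 0 && wobble < 1,
             "wobble must be in [0, 1)")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- radius * (1 + wobble * (0.6 * sin(3 * th + phase) +
                                 0.4 * cos(2 * th - phase)))
  cbind(r * cos(th), r * sin(th))
}

# Vectorized point-in-polygon (strict interior test is not needed at the
# precision of these simulations).
points_in_polygon <- function(pts, polygon) {
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(rbind(polygon, polygon[1L, , drop = FALSE]), pts)
}

#' Uniform random points inside a polygon
#'
#' Rejection sampling from the bounding box of a simple polygon.
#'
#' @param polygon n x 2 vertex matrix.
#' @param n number of points.
#' @param seed integer RNG seed or NULL (NULL draws from the current
#'   stream, which is what [mc_nnd_test()] relies on internally).
#' @return an n x 2 matrix of coordinates.
#' @export
sample_uniform_in_polygon <- function(polygon, n, seed = NULL) {
  polygon <- as_polygon_matrix(polygon)
  check_that(polygon_area(polygon) > 0, "polygon must have positive area")
  check_that(is_scalar_num(n) && n >= 0, "n must be >= 0")
  n <- as.integer(n)
  with_seed(seed, {
    out <- matrix(numeric(0), ncol = 2)
    if (n == 0L) return(out)
    xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
    ## acceptance rate = polygon area / bbox area; draw in batches
    batch <- max(2L * n, 32L)
    while (nrow(out) < n) {
      cand <- cbind(runif(batch, xr[1], xr[2]), runif(batch, yr[1], yr[2]))
      out <- rbind(out, cand[points_in_polygon(cand, polygon), , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Simulate coupled or CSR two-channel puncta in a bouton
#'
#' @param params a [bouton_sim_params()] object.
#' @return a list with `geometry` (class `bouton_geometry`: `polygon`,
#'   `reference`, `target` coordinate matrices in nm) and `truth`, holding
#'   the per-target-point `coupled` flags.
#' @export
simulate_boutons <- function(params) {
  stopifnot(inherits(params, "bouton_sim_params"))
  p <- params
  with_seed(p$seed, {
    ref <- sample_uniform_in_polygon(p$polygon, p$n_ref)
    coupled <- runif(p$n_target) < p$coupling_fraction
    if (p$n_ref == 0L) coupled[] <- FALSE
    tgt <- matrix(NA_real_, nrow = p$n_target, ncol = 2)
    n_free <- sum(!coupled)
    if (n_free > 0)
      tgt[!coupled, ] <- sample_uniform_in_polygon(p$polygon, n_free)
    for (i in which(coupled)) {
      anchor <- ref[sample.int(p$n_ref, 1L), ]
      repeat {
        cand <- anchor + rnorm(2, 0, p$coupling_sigma)
        if (points_in_polygon(matrix(cand, ncol = 2), p$polygon)) break
      }
      tgt[i, ] <- cand
    }
    geometry <- structure(list(polygon = p$polygon, reference = ref,
                               target = tgt),
                          class = "bouton_geometry")
    list(geometry = geometry, truth = data.frame(coupled = coupled),
         params = p)
  })
}

#' Render a bouton geometry as a two-channel image
#'
#' Each point becomes a 2-D Gaussian of SD `psf_sigma`, rasterized on a grid
#' of `pixel_size` nm pixels covering the polygon bounding box (padded by
#' 3 PSF widths), with additive Gaussian noise per channel.
#'
#' @param geometry a `bouton_geometry` from [simulate_boutons()].
#' @param psf_sigma PSF standard deviation (nm).
#' @param pixel_size pixel edge (nm, default 20).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param amplitude peak intensity of a single rendered point.
#' @param seed integer RNG seed or NULL.
#' @return an object of class `puncta_image`: list with `reference` and
#'   `target` intensity matrices (rows = y, columns = x), `pixel_size` (nm)
#'   and `origin`, the nm coordinates of the outer corner of pixel (1, 1).
#' @export
render_puncta_image <- function(geometry, psf_sigma = 30, pixel_size = 20,
                                noise_sd = 0, amplitude = 100, seed = NULL) {
  stopifnot(inherits(geometry, "bouton_geometry"))
  check_that(is_scalar_num(psf_sigma) && psf_sigma > 0, "psf_sigma must be > 0")
  check_that(is_scalar_num(pixel_size) && pixel_size > 0,
             "pixel_size must be > 0")
  check_that(is_scalar_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  pad <- 3 * psf_sigma
  xr <- range(geometry$polygon[, 1]) + c(-pad, pad)
  yr <- range(geometry$polygon[, 2]) + c(-pad, pad)
  nx <- max(1L, as.integer(ceiling(diff(xr) / pixel_size)))
  ny <- max(1L, as.integer(ceiling(diff(yr) / pixel_size)))
  origin <- c(xr[1], yr[1])
  xc <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  yc <- origin[2] + (seq_len(ny) - 0.5) * pixel_size
  render_channel <- function(pts) {
    img <- matrix(0, nrow = ny, ncol = nx)
    if (nrow(pts) > 0)
      for (i in seq_len(nrow(pts))) {
        gx <- exp(-(xc - pts[i, 1])^2 / (2 * psf_sigma^2))
        gy <- exp(-(yc - pts[i, 2])^2 / (2 * psf_sigma^2))
        img <- img + amplitude * outer(gy, gx)
      }
    img
  }
  with_seed(seed, {
    ref <- render_channel(geometry$reference)
    tgt <- render_channel(geometry$target)
    if (noise_sd > 0) {
      ref <- ref + rnorm(length(ref), 0, noise_sd)
      tgt <- tgt + rnorm(length(tgt), 0, noise_sd)
    }
    structure(list(reference = ref, target = tgt, pixel_size = pixel_size,
                   origin = origin),
              class = "puncta_image")
  })
}
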