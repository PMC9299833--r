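## Two-channel puncta proximity analysis: prominence-based maxima,
## nearest-neighbor distances, Monte-Carlo uniform-in-polygon null, and a
## block-scramble Pearson correlation null.

#' Punctum maxima of a single-channel image
#'
#' Finds one peak per punctum: local maxima (8-neighborhood) whose
#' prominence — the drop from the peak to the highest saddle connecting it
#' to a brighter region — exceeds `noise_tolerance`. This emulates a
#' "Find Maxima"-style operator: peaks closer in height than the tolerance
#' to their surrounding saddle are merged into their brighter neighbor.
#'
#' @param image numeric matrix (rows = y, columns = x), or a
#'   `puncta_image` channel extracted by the caller.
#' @param noise_tolerance minimum prominence (intensity units).
#' @param pixel_size pixel edge in nm (default 1, i.e. pixel units).
#' @param origin nm coordinates of the outer corner of pixel (1, 1).
#' @return a matrix of punctum coordinates (x, y) in nm (pixel centers).
#' @export
find_maxima <- function(image, noise_tolerance = 0, pixel_size = 1,
                        origin = c(0, 0)) {
  check_that(is.matrix(image) && is.numeric(image), "image must be a 2-D numeric matrix")
  ny <- nrow(image); nx <- ncol(image)
  ord <- order(image, decreasing = TRUE)
  ## union-find over pixels; every component remembers its peak height
  parent <- integer(ny * nx)        # 0 = not yet flooded
  peak_val <- numeric(ny * nx)
  peak_idx <- integer(ny * nx)
  is_max <- logical(ny * nx)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (idx in ord) {
    v <- image[idx]
    r <- ((idx - 1L) %% ny) + 1L
    c <- ((idx - 1L) %/% ny) + 1L
    roots <- integer(0)
    for (dc in -1:1) {
      cc <- c + dc
      if (cc < 1L || cc > nx) next
      for (dr in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr
        if (rr < 1L || rr > ny) next
        nb <- (cc - 1L) * ny + rr
        if (parent[nb] != 0L) roots <- c(roots, find_root(nb))
      }
    }
    roots <- unique(roots)
    if (length(roots) == 0L) {
      parent[idx] <- idx
      peak_val[idx] <- v
      peak_idx[idx] <- idx
    } else {
      ## attach to the highest-peak neighboring component; other components
      ## meeting here die at saddle height v
      best <- roots[which.max(peak_val[roots])]
      parent[idx] <- best
      for (rt in roots) {
        if (rt == best) next
        if (peak_val[rt] - v > noise_tolerance) is_max[peak_idx[rt]] <- TRUE
        parent[rt] <- best
      }
    }
  }
  ## surviving components: their peaks are maxima (infinite prominence
  ## relative to the image floor)
  alive <- which(parent == seq_along(parent))
  for (rt in alive) if (parent[rt] == rt) is_max[peak_idx[rt]] <- TRUE
  hits <- which(is_max)
  r <- ((hits - 1L) %% ny) + 1L
  c <- ((hits - 1L) %/% ny) + 1L
  cbind(x = origin[1] + (c - 0.5) * pixel_size,
        y = origin[2] + (r - 0.5) * pixel_size)
}

#' Punctum maxima of both channels of a rendered image
#'
#' @param img a `puncta_image` from [render_puncta_image()].
#' @param noise_tolerance minimum prominence (intensity units).
#' @return list with `reference` and `target` coordinate matrices (nm).
#' @export
find_maxima_channels <- function(img, noise_tolerance = 0) {
  stopifnot(inherits(img, "puncta_image"))
  list(reference = find_maxima(img$reference, noise_tolerance,
                               img$pixel_size, img$origin),
       target = find_maxima(img$target, noise_tolerance,
                            img$pixel_size, img$origin))
}

#' Nearest-neighbor distances from reference to target points
#'
#' @param reference,target coordinate matrices (n x 2); `target` must be
#'   nonempty.
#' @return numeric vector: for each reference point, the Euclidean distance
#'   to its nearest target point.
#' @export
nnd_set <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  check_that(nrow(target) >= 1, "empty target set: NND undefined")
  if (nrow(reference) == 0L) return(numeric(0))
  d2 <- outer(reference[, 1], target[, 1], "-")^2 +
    outer(reference[, 2], target[, 2], "-")^2
  ## row minima via max.col (C-level), much faster than apply() here
  sqrt(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))])
}

#' Monte-Carlo nearest-neighbor-distance colocalization test
#'
#' For every bouton, computes the mean observed reference-to-target NND,
#' then re-places both channels' points uniformly inside the bouton polygon
#' (keeping the point counts) `n_rand` times and averages the randomized
#' mean NND over repetitions. The global p value is a two-sided Student's
#' t-test of per-bouton observed vs randomized means (unpaired by default,
#' matching the original analysis; a paired test is available).
#'
#' @param boutons list of `bouton_geometry` objects (see
#'   [simulate_boutons()]).
#' @param n_rand randomizations per bouton (default 100; 1 mirrors a
#'   single-draw null).
#' @param seed integer RNG seed or NULL.
#' @param paired logical; use a paired t-test across boutons.
#' @return an object of class `nnd_test`: data frame `boutons`
#'   (`bouton`, `mean_obs_nnd`, `mean_rand_nnd`, `n_ref`, `n_target`),
#'   `p`, `t`, `n_rand`, `paired`. Boutons with an empty channel are
#'   excluded with a warning.
#' @export
mc_nnd_test <- function(boutons, n_rand = 100L, seed = NULL, paired = FALSE) {
  check_that(is.list(boutons) && length(boutons) >= 2,
             "need a list of >= 2 boutons")
  check_that(is_scalar_num(n_rand) && n_rand >= 1, "n_rand must be >= 1")
  keep <- vapply(boutons, function(b)
    nrow(b$reference) > 0 && nrow(b$target) > 0, logical(1))
  if (!all(keep)) warning(sum(!keep), " bouton(s) with an empty channel excluded")
  boutons <- boutons[keep]
  check_that(length(boutons) >= 2, "fewer than 2 usable boutons")
  with_seed(seed, {
    rows <- lapply(seq_along(boutons), function(i) {
      b <- boutons[[i]]
      n_ref <- nrow(b$reference); n_tgt <- nrow(b$target)
      obs <- mean(nnd_set(b$reference, b$target))
      ## both channels re-placed uniformly with the same counts; all
      ## repetitions drawn in one batch for speed
      per_rep <- n_ref + n_tgt
      pts <- sample_uniform_in_polygon(b$polygon, n_rand * per_rep)
      rand_means <- vapply(seq_len(n_rand), function(r) {
        blk <- pts[((r - 1L) * per_rep + 1L):(r * per_rep), , drop = FALSE]
        mean(nnd_set(blk[seq_len(n_ref), , drop = FALSE],
                     blk[(n_ref + 1L):per_rep, , drop = FALSE]))
      }, numeric(1))
      data.frame(bouton = i, mean_obs_nnd = obs,
                 mean_rand_nnd = mean(rand_means),
                 n_ref = n_ref, n_target = n_tgt)
    })
    tab <- do.call(rbind, rows)
    tt <- t.test(tab$mean_obs_nnd, tab$mean_rand_nnd,
                 var.equal = TRUE, paired = paired)
    structure(list(boutons = tab, p = tt$p.value,
                   t = unname(tt$statistic), n_rand = as.integer(n_rand),
                   paired = paired),
              class = "nnd_test")
  })
}

#' @export
print.nnd_test <- function(x, ...) {
  cat(sprintf(
    "MC NND test: %d boutons, mean obs %.1f vs rand %.1f nm, %s t-test p = %.4g (n_rand = %d)\n",
    nrow(x$boutons), mean(x$boutons$mean_obs_nnd),
    mean(x$boutons$mean_rand_nnd),
    if (x$paired) "paired" else "unpaired", x$p, x$n_rand))
  invisible(x)
}

#' Block-scramble Pearson correlation test
#'
#' Computes the Pearson correlation of two images over a mask, then builds
#' a null distribution by rearranging PSF-sized blocks of the first image
#' `n_scramble` times and recomputing the correlation (a simplified
#' Costes-style randomization). The p value is the fraction of null
#' correlations at least as large as the observed one, with the +1
#' correction so the smallest attainable p is 1/(n_scramble + 1).
#'
#' @param imageA,imageB numeric matrices of identical shape.
#' @param mask logical matrix of the same shape, or NULL for the whole
#'   image.
#' @param block_px block edge in pixels (of order the PSF size).
#' @param n_scramble number of randomizations (default 100).
#' @param seed integer RNG seed or NULL.
#' @return an object of class `costes_test`: `r_obs`, `p`, `null_r`
#'   (numeric vector), `block_px`, `n_scramble`.
#' @export
costes_test <- function(imageA, imageB, mask = NULL, block_px = 5L,
                        n_scramble = 100L, seed = NULL) {
  check_that(is.matrix(imageA) && is.matrix(imageB) &&
               all(dim(imageA) == dim(imageB)),
             "images must be matrices of identical shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(imageA), ncol(imageA))
  check_that(all(dim(mask) == dim(imageA)), "mask shape mismatch")
  check_that(is_scalar_num(block_px) && block_px >= 1, "block_px must be >= 1")
  block_px <- as.integer(block_px)
  a <- imageA[mask]; b <- imageB[mask]
  check_that(sd(a) > 0 && sd(b) > 0,
             "constant channel within mask: correlation undefined")
  ## blocks of the full grid; the null needs >= 2 blocks intersecting the mask
  ny <- nrow(imageA); nx <- ncol(imageA)
  bi <- (row(imageA) - 1L) %/% block_px
  bj <- (col(imageA) - 1L) %/% block_px
  block_id <- bi + bj * (max(bi) + 1L)
  check_that(length(unique(block_id[mask])) >= 2,
             "block covers the whole mask: degenerate null")
  r_obs <- cor(a, b)
  blocks <- sort(unique(as.integer(block_id)))
  idx_by_block <- split(seq_along(imageA), factor(block_id, levels = blocks))
  sizes <- lengths(idx_by_block)
  with_seed(seed, {
    null_r <- vapply(seq_len(n_scramble), function(s) {
      scrA <- imageA
      ## permute equal-size blocks among themselves (edge remainders among
      ## their own size class), preserving within-block pixel order
      for (sz in unique(sizes)) {
        grp <- which(sizes == sz)
        if (length(grp) < 2) next
        perm <- sample(grp)
        scrA[unlist(idx_by_block[grp], use.names = FALSE)] <-
          imageA[unlist(idx_by_block[perm], use.names = FALSE)]
      }
      cor(scrA[mask], b)
    }, numeric(1))
    structure(list(r_obs = r_obs, p = (1 + sum(null_r >= r_obs)) /
                     (n_scramble + 1),
                   null_r = null_r, block_px = block_px,
                   n_scramble = as.integer(n_scramble)),
              class = "costes_test")
  })
}

#' @export
print.costes_test <- function(x, ...) {
  cat(sprintf(
    "block-scramble correlation: r = %.3f, p = %.4g (null mean %.3f, %d scrambles, block %d px)\n",
    x$r_obs, x$p, mean(x$null_r), x$n_scramble, x$block_px))
  invisible(x)
}
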