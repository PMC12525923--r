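# Synthetic stomatal micrograph generator.
#
# Real fields are micrographs of a cereal leaf surface at ~550x magnification:
# rows of roughly parallel, elongated stomatal complexes (two guard cells
# flanking a central pore) over a textured epidermal background. The generator
# emulates the geometry that matters to the downstream mask-to-trait pipeline:
# elongated two-lobed stomata with an interior pore, non-overlapping, fully
# inside the frame, with exact per-object ground truth (center, axes, angle).

#' Specification of a synthetic stomatal field
#'
#' Defines the geometry and appearance of one generated micrograph. Defaults
#' emulate a 1600 x 1200 px field of view holding roughly 19-23 stomata with
#' long axes around 120 px and short axes around 67 px, the scale typical of
#' wheat leaves at 550x magnification.
#'
#' @param image_height,image_width field size in pixels.
#' @param n_stomata integer count or inclusive `c(min, max)` range of objects
#'   per field.
#' @param long_axis_range inclusive range (px) of the stomatal long axis.
#' @param short_axis_range inclusive range (px) of the stomatal short axis.
#' @param pore_fraction pore ellipse axes as a fraction of the stoma axes,
#'   in (0, 1).
#' @param orientation_deg common row orientation of the field (degrees,
#'   measured from the image x-axis).
#' @param orientation_jitter_deg half-width of the uniform per-object jitter
#'   about `orientation_deg`.
#' @param background_level,stoma_level,pore_level mean 8-bit intensities of the
#'   three regions.
#' @param noise_sd amplitude (intensity units) of the background texture noise.
#' @param noise_smooth Gaussian smoothing sigma (px) of the texture noise.
#' @param illumination_gradient amplitude (intensity units) of a smooth
#'   corner-to-corner illumination ramp.
#' @param margin minimum distance (px) from any object to the frame edge.
#' @param seed optional default seed used when [generate_sample()] is called
#'   without one.
#' @return an object of class `stoma_field_spec`.
#' @seealso [generate_sample()]
#' @export
stoma_field_spec <- function(image_height = 1200L, image_width = 1600L,
                             n_stomata = c(19L, 23L),
                             long_axis_range = c(100, 140),
                             short_axis_range = c(55, 80),
                             pore_fraction = 0.4,
                             orientation_deg = 0,
                             orientation_jitter_deg = 8,
                             background_level = 150,
                             stoma_level = 190,
                             pore_level = 70,
                             noise_sd = 8,
                             noise_smooth = 4,
                             illumination_gradient = 12,
                             margin = 4,
                             seed = NULL) {
  if (length(n_stomata) == 1L) n_stomata <- rep(n_stomata, 2L)
  if (length(long_axis_range) == 1L) long_axis_range <- rep(long_axis_range, 2L)
  if (length(short_axis_range) == 1L) short_axis_range <- rep(short_axis_range, 2L)
  assert_that(image_height >= 16 && image_width >= 16, "field dimensions too small")
  assert_that(all(long_axis_range > 0) && all(short_axis_range > 0),
              "axis ranges must be positive")
  assert_that(diff(long_axis_range) >= 0 && diff(short_axis_range) >= 0,
              "axis ranges must be non-decreasing (min, max)")
  assert_that(short_axis_range[1] <= long_axis_range[2],
              "short_axis_range must overlap below long_axis_range (short <= long per object)")
  assert_that(pore_fraction > 0 && pore_fraction < 1, "pore_fraction must lie in (0,1)")
  assert_that(all(n_stomata >= 0) && n_stomata[1] <= n_stomata[2],
              "n_stomata must be a non-negative count or (min, max) range")
  spec <- list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_stomata = as.integer(n_stomata),
    long_axis_range = as.numeric(long_axis_range),
    short_axis_range = as.numeric(short_axis_range),
    pore_fraction = pore_fraction,
    orientation_deg = orientation_deg,
    orientation_jitter_deg = orientation_jitter_deg,
    background_level = background_level, stoma_level = stoma_level,
    pore_level = pore_level,
    noise_sd = noise_sd, noise_smooth = noise_smooth,
    illumination_gradient = illumination_gradient,
    margin = margin, seed = seed
  )
  class(spec) <- "stoma_field_spec"
  spec
}

# Membership test of pixels in one two-lobed stoma. Returns a list of logical
# vectors (stoma support incl. pore; pore) for local coordinates dx, dy
# relative to the object's center. The stoma support is the union of two
# tangent elliptical guard-cell lobes and the pore ellipse, so the overall
# extent along the object axes is exactly long_axis x short_axis.
stoma_membership <- function(dx, dy, long_axis, short_axis, angle_deg, pore_fraction) {
  th <- angle_deg * pi / 180
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  a <- long_axis / 2
  b <- short_axis / 2
  lobe1 <- (u / a)^2 + ((v - b / 2) / (b / 2))^2 <= 1
  lobe2 <- (u / a)^2 + ((v + b / 2) / (b / 2))^2 <= 1
  pore <- (u / (pore_fraction * a))^2 + (v / (pore_fraction * b))^2 <= 1
  list(stoma = lobe1 | lobe2 | pore, pore = pore, u = u, v = v)
}

#' Generate one synthetic micrograph with exact ground truth
#'
#' Draws object parameters from the field specification, places stomata by
#' rejection sampling until they are pairwise non-overlapping and fully inside
#' the frame, rasterizes the three-class mask (0 background, 1 stoma,
#' 2 pore), and renders a matching RGB intensity image with textured
#' background, illumination gradient and per-pixel noise. The same
#' `(spec, seed)` pair always returns a bit-identical sample.
#'
#' @param spec a [stoma_field_spec()].
#' @param seed integer seed controlling all randomness of this sample.
#' @return an object of class `stoma_sample`: a list with `image`
#'   (H x W x 3 integer array, 0-255), `mask` (H x W integer matrix with
#'   labels 0/1/2) and `objects` (data.frame with columns `center_x`,
#'   `center_y`, `long_axis`, `short_axis`, `angle_deg`).
#' @export
generate_sample <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "stoma_field_spec"))
  assert_that(!is.null(seed), "generate_sample() needs a seed (argument or spec$seed)")
  with_seed(seed, {
    H <- spec$image_height; W <- spec$image_width
    n <- if (spec$n_stomata[1] == spec$n_stomata[2]) spec$n_stomata[1] else
      sample(spec$n_stomata[1]:spec$n_stomata[2], 1L)

    objects <- place_objects(spec, n)
    mask <- matrix(0L, H, W)
    seam <- matrix(FALSE, H, W)
    if (n > 0) {
      for (i in seq_len(n)) {
        ob <- objects[i, ]
        a <- sqrt((ob$long_axis / 2)^2 + (ob$short_axis / 4)^2)
        r0 <- max(1L, floor(ob$center_y - a - 2)); r1 <- min(H, ceiling(ob$center_y + a + 2))
        c0 <- max(1L, floor(ob$center_x - a - 2)); c1 <- min(W, ceiling(ob$center_x + a + 2))
        rows <- r0:r1; cols <- c0:c1
        dy <- matrix(rows - ob$center_y, length(rows), length(cols))
        dx <- matrix(cols - ob$center_x, length(rows), length(cols), byrow = TRUE)
        mem <- stoma_membership(dx, dy, ob$long_axis, ob$short_axis,
                                ob$angle_deg, spec$pore_fraction)
        sub <- mask[rows, cols]
        sub[mem$stoma] <- 1L
        sub[mem$pore] <- 2L
        mask[rows, cols] <- sub
        sseam <- seam[rows, cols]
        sseam[mem$stoma & !mem$pore & abs(mem$v) < 1.2] <- TRUE
        seam[rows, cols] <- sseam
      }
    }

    image <- render_image(spec, mask, seam, objects)
    structure(list(image = image, mask = mask, objects = objects),
              class = "stoma_sample")
  })
}

# Rejection-sampling placement: centers drawn uniformly inside the admissible
# frame, accepted when the bounding circles of all placed objects stay
# disjoint with a 2 px gap. The two-lobed shape reaches its circumradius
# sqrt((L/2)^2 + (S/4)^2) at the lobe tips (u = +/- L/2, v = +/- S/4), which
# exceeds L/2; the placement radius accounts for that. Errors out when the
# spec is too dense to satisfy within the attempt budget.
place_objects <- function(spec, n) {
  H <- spec$image_height; W <- spec$image_width
  out <- data.frame(center_x = numeric(0), center_y = numeric(0),
                    long_axis = numeric(0), short_axis = numeric(0),
                    angle_deg = numeric(0))
  if (n == 0) return(out)
  max_attempts <- 1000L * n
  attempts <- 0L
  cx <- cy <- rad <- numeric(n)
  L <- S <- A <- numeric(n)
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(paste0("could not place %d non-overlapping stomata in a %d x %d field ",
                          "after %d attempts; the field specification is too dense"),
                   n, W, H, max_attempts), call. = FALSE)
    }
    l <- stats::runif(1, spec$long_axis_range[1], spec$long_axis_range[2])
    s <- stats::runif(1, spec$short_axis_range[1], min(spec$short_axis_range[2], l))
    ang <- spec$orientation_deg +
      stats::runif(1, -spec$orientation_jitter_deg, spec$orientation_jitter_deg)
    r <- sqrt((l / 2)^2 + (s / 4)^2)
    lo_x <- r + spec$margin; hi_x <- W - r - spec$margin
    lo_y <- r + spec$margin; hi_y <- H - r - spec$margin
    if (lo_x >= hi_x || lo_y >= hi_y) {
      stop("objects are too large for the field at the requested margin", call. = FALSE)
    }
    x <- stats::runif(1, lo_x, hi_x)
    y <- stats::runif(1, lo_y, hi_y)
    ok <- placed == 0L ||
      all(sqrt((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2) >
            rad[seq_len(placed)] + r + 2)
    if (ok) {
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y; rad[placed] <- r
      L[placed] <- l; S[placed] <- s; A[placed] <- ang
    }
  }
  data.frame(center_x = cx, center_y = cy, long_axis = L, short_axis = S,
             angle_deg = A)
}

# Render an RGB intensity image matching a rasterized mask. Consumes RNG.
render_image <- function(spec, mask, seam, objects) {
  H <- nrow(mask); W <- ncol(mask)
  ramp <- outer(seq(-0.5, 0.5, length.out = H), seq(-0.5, 0.5, length.out = W), "+")
  base <- spec$background_level + spec$illumination_gradient * ramp
  if (spec$noise_sd > 0) {
    tex <- matrix(stats::rnorm(H * W), H, W)
    if (spec$noise_smooth > 0) tex <- EBImage::gblur(tex, sigma = spec$noise_smooth)
    tex <- tex / max(stats::sd(tex), 1e-12) * spec$noise_sd
    base <- base + tex
  }
  lvl <- matrix(0, H, W)
  lvl[mask == 1L] <- spec$stoma_level - spec$background_level
  lvl[mask == 2L] <- spec$pore_level - spec$background_level
  # per-object brightness jitter so stomata are not perfectly uniform
  if (nrow(objects) > 0) {
    jit <- stats::rnorm(nrow(objects), 0, 4)
    # apply the i-th jitter inside the i-th object's bounding circle
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      a <- ob$long_axis / 2
      r0 <- max(1L, floor(ob$center_y - a)); r1 <- min(H, ceiling(ob$center_y + a))
      c0 <- max(1L, floor(ob$center_x - a)); c1 <- min(W, ceiling(ob$center_x + a))
      sub <- lvl[r0:r1, c0:c1]
      sel <- mask[r0:r1, c0:c1] > 0L
      sub[sel] <- sub[sel] + jit[i]
      lvl[r0:r1, c0:c1] <- sub
    }
  }
  lvl[seam] <- lvl[seam] - 18  # guard-cell junction shading
  base <- base + lvl
  if (spec$noise_sd > 0) base <- base + matrix(stats::rnorm(H * W, 0, spec$noise_sd / 2), H, W)
  gains <- c(0.93, 1.0, 0.88)  # leaf tissue renders greenish
  img <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(round(clamp(base * gains[ch], 0, 255)))
  img
}

#' Print method for synthetic samples
#' @param x a `stoma_sample`.
#' @param ... unused.
#' @export
print.stoma_sample <- function(x, ...) {
  cat(sprintf("stoma_sample: %d x %d px, %d objects, classes {%s}\n",
              nrow(x$mask), ncol(x$mask), nrow(x$objects),
              paste(sort(unique(as.vector(x$mask))), collapse = ",")))
  invisible(x)
}

#' Augmentation specification
#'
#' Parameters of the stochastic geometric + photometric augmentation applied
#' identically to an image and its mask: random rotation, isotropic scaling,
#' horizontal/vertical flips, smooth elastic deformation, and additive image
#' noise. `expansion_factor` is the number of variants each source sample
#' contributes to an expanded dataset (the original counts as variant 1), so
#' the default of 10 turns 1,260 sources into 12,600 samples.
#'
#' @param rotation_range_deg rotations drawn uniformly in `+/-` this range.
#' @param scale_range inclusive multiplicative scale range.
#' @param elastic_sigma displacement amplitude (px) of the elastic field;
#'   0 disables deformation.
#' @param elastic_grid spacing (px) of the coarse displacement grid.
#' @param flip_h_prob,flip_v_prob flip probabilities.
#' @param noise_sigma additive Gaussian intensity noise on the image only.
#' @param expansion_factor variants per source sample (>= 1).
#' @param seed optional default seed.
#' @return an object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_range_deg = 15, scale_range = c(0.9, 1.1),
                         elastic_sigma = 2, elastic_grid = 64,
                         flip_h_prob = 0.5, flip_v_prob = 0.5,
                         noise_sigma = 4, expansion_factor = 10L, seed = NULL) {
  assert_that(expansion_factor >= 1, "expansion_factor must be >= 1")
  assert_that(all(scale_range > 0), "scale_range must be positive")
  if (length(scale_range) == 1L) scale_range <- rep(scale_range, 2L)
  structure(list(rotation_range_deg = rotation_range_deg,
                 scale_range = as.numeric(scale_range),
                 elastic_sigma = elastic_sigma, elastic_grid = elastic_grid,
                 flip_h_prob = flip_h_prob, flip_v_prob = flip_v_prob,
                 noise_sigma = noise_sigma,
                 expansion_factor = as.integer(expansion_factor), seed = seed),
            class = "augment_spec")
}

# Inverse-map warp shared by image (bilinear) and mask (nearest neighbour).
# theta/scale define the forward affine about the image center; dx, dy are
# forward elastic displacement fields sampled on the output grid. The source
# location of output pixel p is center + R(-theta)/scale (p - center) - D(p).
warp_coords <- function(H, W, theta_deg, scale, dx = NULL, dy = NULL) {
  th <- theta_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  src_c <- (cos(th) * c + sin(th) * r) / scale + cx
  src_r <- (-sin(th) * c + cos(th) * r) / scale + cy
  if (!is.null(dx)) { src_c <- src_c - dx; src_r <- src_r - dy }
  list(r = src_r, c = src_c)
}

warp_mask_nn <- function(mask, coords) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- round(coords$r); ci <- round(coords$c)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- matrix(0L, H, W)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  out
}

warp_channel_bilinear <- function(ch, coords, fill) {
  H <- nrow(ch); W <- ncol(ch)
  r <- coords$r; c <- coords$c
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  r0 <- clamp(floor(r), 1, H); c0 <- clamp(floor(c), 1, W)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- clamp(r - r0, 0, 1); fc <- clamp(c - c0, 0, 1)
  at <- function(ri, ci) matrix(ch[ri + (ci - 1) * H], H, W)
  v <- (1 - fr) * (1 - fc) * at(r0, c0) +
       (1 - fr) * fc       * at(r0, c1) +
       fr       * (1 - fc) * at(r1, c0) +
       fr       * fc       * at(r1, c1)
  out <- matrix(fill, H, W)
  out[ok] <- v[ok]
  out
}

#' Apply one random augmentation to a sample
#'
#' Draws rotation, scale, flips and an elastic displacement field from
#' `aug` under `seed` and applies the identical geometry to image and mask.
#' The mask is resampled with nearest-neighbour interpolation (labels stay in
#' \{0, 1, 2\}); the image with bilinear interpolation. Regions exposed by the
#' transform are filled with background: label 0 in the mask, the mean
#' background intensity in the image. Additive noise is applied to the image
#' only. Output dimensions equal input dimensions.
#'
#' @param sample a `stoma_sample` (or any list with `image` and `mask`).
#' @param aug an [augment_spec()].
#' @param seed integer seed for this draw.
#' @return a `stoma_sample` with transformed `image` and `mask`; the affine
#'   part of the transform is also applied to the `objects` table (elastic
#'   deformation, when enabled, perturbs objects beyond what the table
#'   records).
#' @export
augment_sample <- function(sample, aug, seed = aug$seed) {
  stopifnot(inherits(aug, "augment_spec"))
  assert_that(!is.null(seed), "augment_sample() needs a seed")
  assert_that(all(sample$mask %in% 0:2), "input mask labels must lie in {0,1,2}")
  with_seed(seed, {
    H <- nrow(sample$mask); W <- ncol(sample$mask)
    theta <- stats::runif(1, -aug$rotation_range_deg, aug$rotation_range_deg)
    scale <- stats::runif(1, aug$scale_range[1], aug$scale_range[2])
    fh <- stats::runif(1) < aug$flip_h_prob
    fv <- stats::runif(1) < aug$flip_v_prob

    img <- sample$image
    mask <- sample$mask
    objects <- sample$objects
    if (fh) {  # exact column reversal
      img <- img[, W:1, , drop = FALSE]; mask <- mask[, W:1, drop = FALSE]
      if (!is.null(objects) && nrow(objects)) {
        objects$center_x <- W + 1 - objects$center_x
        objects$angle_deg <- -objects$angle_deg
      }
    }
    if (fv) {
      img <- img[H:1, , , drop = FALSE]; mask <- mask[H:1, , drop = FALSE]
      if (!is.null(objects) && nrow(objects)) {
        objects$center_y <- H + 1 - objects$center_y
        objects$angle_deg <- -objects$angle_deg
      }
    }

    dx <- dy <- NULL
    if (aug$elastic_sigma > 0) {
      gh <- max(2L, ceiling(H / aug$elastic_grid) + 1L)
      gw <- max(2L, ceiling(W / aug$elastic_grid) + 1L)
      gx <- matrix(stats::rnorm(gh * gw, 0, aug$elastic_sigma), gh, gw)
      gy <- matrix(stats::rnorm(gh * gw, 0, aug$elastic_sigma), gh, gw)
      dx <- EBImage::resize(gx, w = H, h = W)  # EBImage uses (w=rows, h=cols) of the matrix
      dy <- EBImage::resize(gy, w = H, h = W)
    }

    coords <- warp_coords(H, W, theta, scale, dx, dy)
    new_mask <- warp_mask_nn(mask, coords)
    if (!all(new_mask %in% 0:2)) {
      stop("mask resampling produced labels outside {0,1,2}", call. = FALSE)
    }
    fill <- vapply(1:3, function(ch) {
      v <- img[, , ch][mask == 0L]
      if (length(v)) mean(v) else mean(img[, , ch])
    }, numeric(1))
    new_img <- array(0, dim = dim(img))
    for (ch in 1:3) {
      w <- warp_channel_bilinear(img[, , ch], coords, fill[ch])
      if (aug$noise_sigma > 0) w <- w + stats::rnorm(length(w), 0, aug$noise_sigma)
      new_img[, , ch] <- as.integer(round(clamp(w, 0, 255)))
    }
    storage.mode(new_img) <- "integer"

    if (!is.null(objects) && nrow(objects)) {
      th <- theta * pi / 180
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      ox <- objects$center_x - cx; oy <- objects$center_y - cy
      objects$center_x <- cx + scale * (cos(th) * ox - sin(th) * oy)
      objects$center_y <- cy + scale * (sin(th) * ox + cos(th) * oy)
      objects$long_axis <- objects$long_axis * scale
      objects$short_axis <- objects$short_axis * scale
      objects$angle_deg <- objects$angle_deg + theta
    }
    structure(list(image = new_img, mask = new_mask, objects = objects),
              class = "stoma_sample")
  })
}

#' Expand a list of samples by augmentation
#'
#' Produces `expansion_factor` variants per source sample; variant 1 is the
#' untouched original, the rest are independent [augment_sample()] draws.
#' Source identity is retained so that dataset splits can be grouped by
#' source (see [split_dataset()]).
#'
#' @param samples list of `stoma_sample` objects.
#' @param aug an [augment_spec()].
#' @param seed integer master seed; each variant derives its own stream.
#' @return list of samples, each carrying attributes `source_id` and
#'   `variant`.
#' @export
augment_dataset <- function(samples, aug, seed) {
  stopifnot(inherits(aug, "augment_spec"))
  out <- vector("list", length(samples) * aug$expansion_factor)
  k <- 0L
  for (i in seq_along(samples)) {
    for (v in seq_len(aug$expansion_factor)) {
      k <- k + 1L
      s <- if (v == 1L) samples[[i]] else
        augment_sample(samples[[i]], aug, seed = derive_seed(seed, k))
      attr(s, "source_id") <- i
      attr(s, "variant") <- v
      out[[k]] <- s
    }
  }
  out
}
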