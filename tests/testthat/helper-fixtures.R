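# Fixtures are generated in code; no binary files ship with the package.

# Small dense field with fixed axes, used for parameter-recovery checks.
fixture_field_spec <- function(n = 5L, long = 120, short = 66,
                               H = 400L, W = 520L, jitter = 0) {
  stoma_field_spec(image_height = H, image_width = W, n_stomata = n,
                   long_axis_range = c(long, long),
                   short_axis_range = c(short, short),
                   orientation_jitter_deg = jitter)
}

# High-contrast, low-noise 128 px fields small enough for CPU training.
easy_train_spec <- function() {
  stoma_field_spec(image_height = 128L, image_width = 128L, n_stomata = c(2L, 3L),
                   long_axis_range = c(36, 44), short_axis_range = c(20, 26),
                   pore_fraction = 0.45, orientation_jitter_deg = 20,
                   background_level = 150, stoma_level = 210, pore_level = 40,
                   noise_sd = 4, noise_smooth = 2, illumination_gradient = 8,
                   margin = 2)
}

# Independent ellipse rasterization oracle: pixel centers inside the exact
# ellipse inequality, used to cross-check generator geometry.
oracle_ellipse_mask <- function(H, W, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Brute-force nearest-neighbour warp oracle (independent of the package's
# vectorized warp): per-pixel loop over the output grid.
oracle_warp_nn <- function(mask, theta_deg, scale) {
  H <- nrow(mask); W <- ncol(mask)
  th <- theta_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      sc <- (cos(th) * (c - cx) + sin(th) * (r - cy)) / scale + cx
      sr <- (-sin(th) * (c - cx) + cos(th) * (r - cy)) / scale + cy
      ri <- round(sr); ci <- round(sc)
      if (ri >= 1 && ri <= H && ci >= 1 && ci <= W) out[r, c] <- mask[ri, ci]
    }
  }
  out
}

# Brute-force minimum-area enclosing rectangle over a 0.1 degree angle grid.
oracle_min_rect <- function(points, step_deg = 0.1) {
  x <- points[, 2]; y <- points[, 1]
  best <- NULL
  for (ang in seq(0, 90 - step_deg, by = step_deg)) {
    th <- ang * pi / 180
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    du <- diff(range(u)) + 1
    dv <- diff(range(v)) + 1
    if (is.null(best) || du * dv < best$area) {
      best <- list(area = du * dv, side_a = max(du, dv), side_b = min(du, dv))
    }
  }
  best
}

# Rasterize a rotated filled ellipse / rectangle for geometry tests.
raster_shape <- function(shape = c("ellipse", "rect"), a, b, angle_deg,
                         H = 160L, W = 160L) {
  shape <- match.arg(shape)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- angle_deg * pi / 180
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- if (shape == "ellipse") (u / a)^2 + (v / b)^2 <= 1
            else abs(u) <= a & abs(v) <= b
  m <- matrix(0L, H, W)
  m[inside] <- 1L
  m
}
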