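test_that("connected components are 8-connected and size-filtered", {
  m <- matrix(0L, 8, 8)
  m[2, 2] <- 1L; m[3, 3] <- 1L       # diagonal touch: one component
  obs <- extract_stoma_objects(m, min_size = 1)
  expect_length(obs, 1L)
  expect_identical(obs[[1]]$size, 2L)

  m2 <- matrix(0L, 20, 20)
  m2[2:4, 2:5] <- 1L                  # 12 px
  m2[10:11, 10:14] <- 1L              # 10 px speck
  expect_length(extract_stoma_objects(m2, min_size = 11), 1L)
  expect_length(extract_stoma_objects(m2, min_size = 1), 2L)

  expect_error(extract_stoma_objects(matrix(7L, 2, 2)), "\\{0,1,2\\}")
})

test_that("three separated ellipses yield three unflagged objects; border
           contact sets the flag", {
  s <- generate_sample(fixture_field_spec(n = 3L), seed = 31)
  obs <- extract_stoma_objects(s$mask)
  expect_length(obs, 3L)
  expect_false(any(vapply(obs, function(o) o$border_flag, logical(1))))

  edge <- matrix(0L, 30, 30)
  edge[1:5, 10:20] <- 1L
  oe <- extract_stoma_objects(edge, min_size = 1)
  expect_true(oe[[1]]$border_flag)
})

test_that("contours are closed boundaries consistent with an edge operator", {
  s <- generate_sample(fixture_field_spec(n = 2L, jitter = 20), seed = 32)
  obs <- extract_stoma_objects(s$mask)
  bin <- s$mask > 0L
  for (ob in obs) {
    # every contour pixel belongs to the component and touches background
    expect_true(all(bin[ob$contour]))
    # oracle edge set: foreground pixels with a 4-neighbour outside
    H <- nrow(bin); W <- ncol(bin)
    pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- bin
    edge <- bin & !(pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
                      pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)])
    on_edge <- edge[ob$contour]
    expect_true(all(on_edge))
    # and the trace covers that component's full edge set
    comp <- matrix(FALSE, H, W); comp[ob$pixels] <- TRUE
    expect_identical(sum(edge & comp), nrow(unique(ob$contour)))
  }
})

test_that("min_area_rect recovers axis-aligned rectangles and single pixels", {
  pts <- which(raster_shape("rect", a = 9.5, b = 3.5, angle_deg = 0) == 1L,
               arr.ind = TRUE)
  r <- min_area_rect(pts)
  expect_lt(abs(r$side_a - 20), 1)
  expect_lt(abs(r$side_b - 8), 1)
  expect_lt(abs(r$angle_deg - 0) %% 180, 1)

  single <- min_area_rect(matrix(c(5, 7), 1, 2))
  expect_equal(single$side_a, 1)
  expect_equal(single$side_b, 1)

  seg <- min_area_rect(cbind(5:10, 5:10))  # collinear diagonal
  expect_equal(seg$side_b, 1)
  expect_equal(seg$side_a, sqrt(50) + 1)
})

test_that("rotating calipers agrees with a 0.1-degree brute-force search", {
  set.seed(33)
  for (i in 1:12) {
    shape <- sample(c("ellipse", "rect"), 1)
    a <- runif(1, 15, 40); b <- runif(1, 6, a * 0.7)
    ang <- runif(1, 0, 180)
    m <- raster_shape(shape, a, b, ang, H = 120L, W = 120L)
    pts <- which(m == 1L, arr.ind = TRUE)
    fast <- min_area_rect(pts)
    slow <- oracle_min_rect(pts)
    expect_lt(abs(fast$side_a - slow$side_a), 2)
    expect_lt(abs(fast$side_b - slow$side_b), 2)
    expect_lte(fast$side_a * fast$side_b, slow$area + 1e-6)
  }
})

test_that("clean generated masks recover count, axes and exact pixel areas", {
  spec <- fixture_field_spec(n = 6L, long = 120, short = 66, H = 600L, W = 800L,
                             jitter = 10)
  s <- generate_sample(spec, seed = 34)
  tr <- mask_to_traits(s$mask)
  expect_identical(tr$stoma_count, 6L)
  expect_lt(abs(mean(tr$records$length_px) - 120), 2)
  expect_lt(abs(mean(tr$records$width_px) - 66), 2)
  # area at pixel_area = 1 equals the component pixel count exactly
  obs <- extract_stoma_objects(s$mask)
  expect_identical(tr$records$area, vapply(obs, function(o) as.numeric(o$size), numeric(1)))
  expect_true(all(tr$records$length_px >= tr$records$width_px))
  # ellipse-like sanity band: area <= length*width <= (4/pi)*area * margin
  lw <- tr$records$length_px * tr$records$width_px
  expect_true(all(tr$records$area <= lw))
  expect_true(all(lw <= (4 / pi) * tr$records$area * 1.1))

  scaled <- measure_traits(obs, pixel_area = 2.5)
  expect_equal(scaled$records$area, tr$records$area * 2.5)
  expect_error(measure_traits(obs, pixel_area = 0), "positive")
})

test_that("traits are pixel-exact under 90-degree rotation of the scene", {
  spec <- stoma_field_spec(image_height = 320, image_width = 320, n_stomata = 3,
                           long_axis_range = c(80, 80), short_axis_range = c(44, 44),
                           orientation_jitter_deg = 30)
  s <- generate_sample(spec, seed = 35)
  t0 <- mask_to_traits(s$mask)
  rot <- matrix(t(s$mask)[, nrow(s$mask):1], 320, 320)  # exact 90-degree rotation
  t90 <- mask_to_traits(rot)
  expect_identical(t90$stoma_count, t0$stoma_count)
  expect_equal(sort(t90$records$area), sort(t0$records$area))
  expect_equal(sort(t90$records$length_px), sort(t0$records$length_px), tolerance = 1e-9)
  expect_equal(sort(t90$records$width_px), sort(t0$records$width_px), tolerance = 1e-9)
})

test_that("traits are stable within tolerance under arbitrary scene rotation", {
  spec <- stoma_field_spec(image_height = 320, image_width = 320, n_stomata = 3,
                           long_axis_range = c(80, 80), short_axis_range = c(44, 44),
                           margin = 60)
  s <- generate_sample(spec, seed = 36)
  t0 <- mask_to_traits(s$mask)
  aug <- augment_spec(rotation_range_deg = 40, scale_range = 1, elastic_sigma = 0,
                      flip_h_prob = 0, flip_v_prob = 0, noise_sigma = 0)
  a <- augment_sample(s, aug, seed = 37)
  t1 <- mask_to_traits(a$mask)
  expect_identical(t1$stoma_count, t0$stoma_count)
  expect_lt(max(abs(sort(t1$records$length_px) - sort(t0$records$length_px))), 2)
  expect_lt(max(abs(sort(t1$records$width_px) - sort(t0$records$width_px))), 2)
  expect_lt(max(abs(sort(t1$records$area) / sort(t0$records$area) - 1)), 0.04)
})

test_that("empty masks and pore-only policies behave as documented", {
  tr <- mask_to_traits(matrix(0L, 50, 50))
  expect_identical(tr$stoma_count, 0L)
  expect_identical(nrow(tr$records), 0L)

  s <- generate_sample(fixture_field_spec(n = 3L), seed = 38)
  pores <- mask_to_traits(s$mask, class_policy = "pore_only", min_size = 10)
  expect_identical(pores$stoma_count, 3L)
  full <- mask_to_traits(s$mask)
  expect_true(all(pores$records$area < full$records$area))
})
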