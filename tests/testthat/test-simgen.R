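test_that("generation is deterministic and respects the requested object count", {
  spec <- fixture_field_spec(n = 5L)
  s1 <- generate_sample(spec, seed = 11)
  s2 <- generate_sample(spec, seed = 11)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$objects, s2$objects)
  s3 <- generate_sample(spec, seed = 12)
  expect_false(identical(s1$mask, s3$mask))

  expect_equal(nrow(s1$objects), 5L)
  obs <- extract_stoma_objects(s1$mask, min_size = 1)
  expect_length(obs, 5L)
  expect_identical(dim(s1$mask), dim(s1$image)[1:2])
  expect_true(all(s1$mask %in% 0:2))
})

test_that("pore pixels are nested inside their stoma's ellipse", {
  spec <- fixture_field_spec(n = 4L, jitter = 15)
  s <- generate_sample(spec, seed = 3)
  pore <- which(s$mask == 2L, arr.ind = TRUE)
  expect_gt(nrow(pore), 0)
  inside_any <- rep(FALSE, nrow(pore))
  for (i in seq_len(nrow(s$objects))) {
    ob <- s$objects[i, ]
    th <- ob$angle_deg * pi / 180
    dx <- pore[, 2] - ob$center_x; dy <- pore[, 1] - ob$center_y
    u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
    inside_any <- inside_any |
      (u / (ob$long_axis / 2))^2 + (v / (ob$short_axis / 2))^2 <= 1 + 1e-9
  }
  expect_true(all(inside_any))
})

test_that("rasterized extent matches the analytic ellipse oracle within 2 px", {
  spec <- fixture_field_spec(n = 3L, long = 120, short = 66)
  s <- generate_sample(spec, seed = 7)
  for (i in seq_len(nrow(s$objects))) {
    ob <- s$objects[i, ]
    oracle <- oracle_ellipse_mask(spec$image_height, spec$image_width,
                                  ob$center_x, ob$center_y,
                                  ob$long_axis / 2, ob$short_axis / 2, ob$angle_deg)
    opix <- which(oracle, arr.ind = TRUE)
    orect <- min_area_rect(opix)
    expect_lt(abs(orect$side_a - 120), 2)
    expect_lt(abs(orect$side_b - 66), 2)
    # the generated two-lobed object spans the same enclosing rectangle
    obs <- extract_stoma_objects(s$mask, min_size = 1)
    sizes <- vapply(obs, function(o) o$size, numeric(1))
    # match this object by centroid proximity
    cent <- t(vapply(obs, function(o) colMeans(o$pixels), numeric(2)))
    j <- which.min((cent[, 2] - ob$center_x)^2 + (cent[, 1] - ob$center_y)^2)
    rect <- min_area_rect(obs[[j]]$contour)
    expect_lt(abs(rect$side_a - orect$side_a), 2)
    expect_lt(abs(rect$side_b - orect$side_b), 2)
  }
})

test_that("an over-dense field specification fails with a clear error", {
  spec <- stoma_field_spec(image_height = 200, image_width = 200, n_stomata = 30,
                           long_axis_range = c(90, 90), short_axis_range = c(50, 50))
  expect_error(generate_sample(spec, seed = 1), "too dense|too large")
})

test_that("forced horizontal flips are an exact involution", {
  s <- generate_sample(fixture_field_spec(n = 3L), seed = 21)
  aug <- augment_spec(rotation_range_deg = 0, scale_range = 1, elastic_sigma = 0,
                      flip_h_prob = 1, flip_v_prob = 0, noise_sigma = 0)
  twice <- augment_sample(augment_sample(s, aug, seed = 1), aug, seed = 2)
  expect_identical(twice$mask, s$mask)
  expect_equal(unclass(twice$image), unclass(s$image))
})

test_that("90-degree rotation of a square sample preserves class counts exactly", {
  spec <- stoma_field_spec(image_height = 256, image_width = 256, n_stomata = 2,
                           long_axis_range = c(60, 60), short_axis_range = c(34, 34))
  s <- generate_sample(spec, seed = 5)
  rot <- stomatools:::warp_mask_nn(s$mask, stomatools:::warp_coords(256, 256, 90, 1))
  expect_identical(table(factor(rot, 0:2)), table(factor(s$mask, 0:2)))
})

test_that("the vectorized warp agrees with a brute-force nearest-neighbour oracle", {
  spec <- stoma_field_spec(image_height = 96, image_width = 96, n_stomata = 2,
                           long_axis_range = c(28, 28), short_axis_range = c(16, 16),
                           margin = 2)
  s <- generate_sample(spec, seed = 13)
  for (case in list(c(17, 0.9), c(-33, 1.05), c(61, 1.0))) {
    fast <- stomatools:::warp_mask_nn(
      s$mask, stomatools:::warp_coords(96, 96, case[1], case[2]))
    slow <- oracle_warp_nn(s$mask, case[1], case[2])
    expect_identical(fast, slow)
  }
})

test_that("rotation+scale keeps foreground count near count * scale^2 when in frame", {
  spec <- stoma_field_spec(image_height = 200, image_width = 200, n_stomata = 2,
                           long_axis_range = c(40, 40), short_axis_range = c(22, 22),
                           margin = 30)
  s <- generate_sample(spec, seed = 2)
  aug <- augment_spec(rotation_range_deg = 25, scale_range = c(0.9, 0.9),
                      elastic_sigma = 0, flip_h_prob = 0, flip_v_prob = 0,
                      noise_sigma = 0)
  a <- augment_sample(s, aug, seed = 4)
  fg0 <- sum(s$mask > 0); fg1 <- sum(a$mask > 0)
  expect_lt(abs(fg1 - fg0 * 0.81) / (fg0 * 0.81), 0.05)
  expect_true(all(a$mask %in% 0:2))
  expect_identical(dim(a$mask), dim(s$mask))
})

test_that("augmentation with identical seeds is reproducible and label-safe", {
  s <- generate_sample(easy_train_spec(), seed = 8)
  aug <- augment_spec()
  a1 <- augment_sample(s, aug, seed = 99)
  a2 <- augment_sample(s, aug, seed = 99)
  expect_identical(a1$mask, a2$mask)
  expect_equal(unclass(a1$image), unclass(a2$image))
  expect_true(all(a1$mask %in% 0:2))
})

test_that("dataset expansion keeps the original as variant 1 and tags sources", {
  samples <- lapply(1:3, function(i) generate_sample(easy_train_spec(), seed = i))
  aug <- augment_spec(expansion_factor = 4L)
  ds <- augment_dataset(samples, aug, seed = 5)
  expect_length(ds, 12L)
  expect_identical(ds[[1]]$mask, samples[[1]]$mask)
  expect_identical(attr(ds[[5]], "source_id"), 2L)
  expect_identical(attr(ds[[5]], "variant"), 1L)
  srcs <- vapply(ds, function(s) attr(s, "source_id"), integer(1))
  expect_identical(srcs, rep(1:3, each = 4L))
})
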