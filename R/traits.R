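# Mask-to-trait pipeline: a 3-class label mask is binarized, split into
# 8-connected stomatal objects, and each object is measured — length and
# width as the sides of the minimum-area enclosing rectangle of its boundary,
# area as pixel count times the physical area of one pixel, and the stomatal
# count as the number of retained objects.

# 8-connected labeling: EBImage::bwlabel provides 4-connected components;
# diagonal-only adjacencies are then merged with a union-find over the label
# graph, which yields exact 8-connectivity.
label_components_8 <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  n <- max(lab)
  if (n <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]    # down-left diagonal pairs
  s1 <- a1 > 0 & b1 > 0 & a1 != b1
  s2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Moore-neighbour boundary trace of one component (given as a logical
# sub-window); returns ordered (row, col) boundary coordinates.
trace_boundary <- function(sub) {
  pix <- which(sub, arr.ind = TRUE)
  if (nrow(pix) == 1L) return(pix)
  # clockwise Moore neighbourhood starting west
  off <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  H <- nrow(sub); W <- ncol(sub)
  inside <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && sub[r, c]
  start <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE][1, ]
  path <- list(start)
  cur <- start
  back <- 1L  # came from the west
  max_steps <- 8L * nrow(pix) + 8L
  for (step in seq_len(max_steps)) {
    found <- FALSE
    for (d in seq_len(8L)) {
      k <- (back - 1L + d - 1L) %% 8L + 1L
      r <- cur[1] + off[k, 1]; c <- cur[2] + off[k, 2]
      if (inside(r, c)) {
        # next backtrack: the neighbour scanned just before k, seen from (r,c)
        prevk <- (k - 2L) %% 8L + 1L
        pr <- cur[1] + off[prevk, 1]; pc <- cur[2] + off[prevk, 2]
        drc <- c(pr - r, pc - c)
        back <- which(off[, 1] == drc[1] & off[, 2] == drc[2])
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster fully scanned
    if (cur[1] == start[1] && cur[2] == start[2]) break
    path[[length(path) + 1L]] <- cur
  }
  out <- do.call(rbind, path)
  colnames(out) <- c("row", "col")
  out
}

#' Extract stomatal objects from a label mask
#'
#' Binarizes the mask according to `class_policy` (by default the stomatal
#' region is the union of the stoma and pore classes, since the pore lies
#' inside the stoma), labels 8-connected components, discards components
#' smaller than `min_size` pixels, traces each retained component's outer
#' boundary, and flags components touching the image border.
#'
#' @param mask H x W integer matrix with labels in \{0, 1, 2\}.
#' @param min_size minimum component area (px^2) retained.
#' @param class_policy `"stoma_union_pore"` (default), `"stoma_only"` or
#'   `"pore_only"`.
#' @return list of objects, each a list with `pixels` (n x 2 row/col
#'   matrix), `contour` (ordered boundary row/col matrix), `size` (pixel
#'   count) and `border_flag`.
#' @export
extract_stoma_objects <- function(mask, min_size = 50,
                                  class_policy = c("stoma_union_pore",
                                                   "stoma_only", "pore_only")) {
  class_policy <- match.arg(class_policy)
  if (!all(mask %in% 0:2)) {
    stop("mask labels must lie in {0,1,2}", call. = FALSE)
  }
  bin <- switch(class_policy,
                stoma_union_pore = mask == 1L | mask == 2L,
                stoma_only = mask == 1L,
                pore_only = mask == 2L)
  storage.mode(bin) <- "integer"
  lab <- label_components_8(bin)
  n <- max(lab)
  if (n == 0) return(list())
  H <- nrow(mask); W <- ncol(mask)
  out <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    pix <- which(lab == i, arr.ind = TRUE)
    colnames(pix) <- c("row", "col")
    if (nrow(pix) < min_size) next
    r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
    c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- TRUE
    contour <- trace_boundary(sub)
    contour[, 1] <- contour[, 1] + r0 - 1L
    contour[, 2] <- contour[, 2] + c0 - 1L
    keep[i] <- TRUE
    out[[i]] <- list(pixels = pix, contour = contour, size = nrow(pix),
                     border_flag = r0 == 1L || r1 == H || c0 == 1L || c1 == W)
  }
  out[keep]
}

#' Minimum-area enclosing rectangle of a point set
#'
#' Rotating calipers over the convex hull: the minimal rectangle has one side
#' collinear with a hull edge, so the exact optimum is found by scanning hull
#' edges. Points are pixel centers; reported side lengths are the coordinate
#' extents plus one pixel (a single pixel is a 1 x 1 rectangle).
#'
#' @param points n x 2 matrix of (row, col) pixel coordinates, n >= 1.
#' @return list with `center` (x = col, y = row), `side_a` >= `side_b`
#'   (px) and `angle_deg`, the direction of the long side measured from the
#'   image x-axis.
#' @export
min_area_rect <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 1L)
  x <- points[, 2]; y <- points[, 1]
  if (nrow(points) == 1L) {
    return(list(center = c(x = unname(x[1]), y = unname(y[1])),
                side_a = 1, side_b = 1, angle_deg = 0))
  }
  hi <- grDevices::chull(x, y)
  hx <- x[hi]; hy <- y[hi]
  m <- length(hi)
  if (m < 3L) {  # collinear point set
    i <- which.max((hx - hx[1])^2 + (hy - hy[1])^2)
    len <- sqrt((hx[i] - hx[1])^2 + (hy[i] - hy[1])^2)
    ang <- atan2(hy[i] - hy[1], hx[i] - hx[1]) * 180 / pi
    return(list(center = c(x = mean(range(hx)), y = mean(range(hy))),
                side_a = len + 1, side_b = 1,
                angle_deg = ((ang + 90) %% 180) - 90))
  }
  best <- NULL
  for (e in seq_len(m)) {
    j <- if (e == m) 1L else e + 1L
    th <- atan2(hy[j] - hy[e], hx[j] - hx[e])
    u <- hx * cos(th) + hy * sin(th)
    v <- -hx * sin(th) + hy * cos(th)
    du <- diff(range(u)) + 1
    dv <- diff(range(v)) + 1
    if (is.null(best) || du * dv < best$area) {
      cu <- mean(range(u)); cv <- mean(range(v))
      best <- list(area = du * dv, du = du, dv = dv, th = th,
                   cx = cu * cos(th) - cv * sin(th),
                   cy = cu * sin(th) + cv * cos(th))
    }
  }
  if (best$du >= best$dv) {
    side_a <- best$du; side_b <- best$dv; ang <- best$th * 180 / pi
  } else {
    side_a <- best$dv; side_b <- best$du; ang <- best$th * 180 / pi + 90
  }
  list(center = c(x = best$cx, y = best$cy),
       side_a = side_a, side_b = side_b,
       angle_deg = ((ang + 90) %% 180) - 90)
}

#' Measure per-stoma traits
#'
#' For each object: length and width are the long and short sides of the
#' minimum-area enclosing rectangle of its boundary; area is the component
#' pixel count multiplied by `pixel_area`. The stomatal count is the number
#' of objects.
#'
#' @param objects list from [extract_stoma_objects()].
#' @param pixel_area physical area represented by one pixel (default 1, so
#'   areas are in px^2).
#' @param sample_id,surface optional identifiers carried into the result.
#' @return an object of class `image_traits`: list with `sample_id`,
#'   `surface`, `stoma_count`, `records` (data.frame: object_id, length_px,
#'   width_px, area, border_flag) and `means`.
#' @export
measure_traits <- function(objects, pixel_area = 1, sample_id = NA_character_,
                           surface = NA_character_) {
  assert_that(pixel_area > 0, "pixel_area must be positive")
  recs <- lapply(seq_along(objects), function(i) {
    ob <- objects[[i]]
    rect <- min_area_rect(ob$contour)
    data.frame(object_id = i,
               length_px = rect$side_a, width_px = rect$side_b,
               area = ob$size * pixel_area,
               border_flag = ob$border_flag)
  })
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(object_id = integer(0), length_px = numeric(0),
               width_px = numeric(0), area = numeric(0),
               border_flag = logical(0))
  structure(list(sample_id = sample_id, surface = surface,
                 stoma_count = nrow(records), records = records,
                 means = list(length_px = mean(records$length_px),
                              width_px = mean(records$width_px),
                              area = mean(records$area))),
            class = "image_traits")
}

#' Mask to traits in one call
#'
#' @param mask H x W label matrix in \{0, 1, 2\}.
#' @param min_size,class_policy passed to [extract_stoma_objects()].
#' @param pixel_area,sample_id,surface passed to [measure_traits()].
#' @return an `image_traits` object.
#' @export
mask_to_traits <- function(mask, min_size = 50, class_policy = "stoma_union_pore",
                           pixel_area = 1, sample_id = NA_character_,
                           surface = NA_character_) {
  measure_traits(extract_stoma_objects(mask, min_size, class_policy),
                 pixel_area, sample_id, surface)
}

#' @export
print.image_traits <- function(x, ...) {
  cat(sprintf("image_traits: %d stomata; mean length %.1f, width %.1f, area %.1f\n",
              x$stoma_count, x$means$length_px, x$means$width_px, x$means$area))
  invisible(x)
}
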