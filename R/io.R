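# Dataset bookkeeping: deterministic 7:2:1 splits with largest-remainder
# apportionment, TSV manifests, label-mask and image PNG I/O, trait CSVs.

#' Largest-remainder apportionment
#'
#' Splits `n` items into integer partition sizes proportional to `ratios`:
#' floors of the exact quotas, with remaining items assigned by descending
#' fractional remainder (ties resolved toward the earlier partition).
#'
#' @param n total count.
#' @param ratios positive numeric vector.
#' @return integer vector of sizes summing to `n`.
#' @export
largest_remainder <- function(n, ratios) {
  assert_that(all(ratios > 0), "ratios must be positive")
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)  # stable: ties keep earlier partition
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a dataset into train / test / validation partitions
#'
#' Sizes follow largest-remainder apportionment of the (normalized) ratios;
#' assignment is a seeded permutation. When `groups` is supplied (e.g. the
#' source image of each augmented variant), whole groups are assigned to one
#' partition so augmented siblings never straddle partitions; ungrouped
#' splitting (the default when `groups` is NULL) reproduces exact
#' sample-level counts.
#'
#' @param n number of samples (>= number of partitions).
#' @param ratios positive ratios, default `c(7, 2, 1)` for train:test:val.
#' @param seed integer seed.
#' @param groups optional vector of group identifiers, length `n`.
#' @return an object of class `split_assignment`: list with `assignment`
#'   (factor with levels train/test/val), `sizes`, `ratios`, `seed`.
#' @export
split_dataset <- function(n, ratios = c(7, 2, 1), seed = 0L, groups = NULL) {
  assert_that(length(ratios) == 3L, "ratios must have three entries (train, test, val)")
  assert_that(all(ratios > 0), "ratios must be positive")
  assert_that(n >= 3L, "need at least as many samples as partitions")
  levels <- c("train", "test", "val")
  if (is.null(groups)) {
    sizes <- largest_remainder(n, ratios)
    perm <- with_seed(seed, sample.int(n))
    lab <- rep(levels, times = sizes)
    assignment <- factor(character(n), levels = levels)
    assignment[perm] <- factor(lab, levels = levels)
  } else {
    assert_that(length(groups) == n, "groups must have length n")
    gids <- unique(groups)
    ng <- length(gids)
    assert_that(ng >= 3L, "need at least three groups for a grouped split")
    gsizes <- largest_remainder(ng, ratios)
    perm <- with_seed(seed, sample.int(ng))
    glab <- rep(levels, times = gsizes)
    gassign <- character(ng)
    gassign[perm] <- glab
    assignment <- factor(gassign[match(groups, gids)], levels = levels)
    sizes <- as.integer(table(assignment)[levels])
  }
  structure(list(assignment = assignment,
                 sizes = stats::setNames(as.integer(table(assignment)[levels]), levels),
                 ratios = ratios, seed = seed, grouped = !is.null(groups)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment (%s): train %d / test %d / val %d\n",
              if (x$grouped) "grouped" else "ungrouped",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  invisible(x)
}

#' Read and write label masks
#'
#' Masks are single-channel 8-bit PNG files whose pixel values are the raw
#' class labels \{0, 1, 2\}; the write/read round-trip is bit-exact. Reading
#' validates the label range and rejects multi-channel images.
#'
#' @param mask H x W integer matrix with labels in \{0, 1, 2\}.
#' @param path PNG file path.
#' @return `read_mask` returns the integer label matrix; `write_mask`
#'   returns `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% 0:2)) stop("mask labels must lie in {0,1,2}", call. = FALSE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) != 2L) {
    stop("mask file is not a single-channel image", call. = FALSE)
  }
  m <- round(raw * 255)
  if (!all(m %in% 0:2)) {
    stop(sprintf("mask %s contains labels outside {0,1,2}", path), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read and write RGB intensity images
#'
#' @param image H x W x 3 array with values 0-255.
#' @param path PNG file path.
#' @return `read_image` returns an integer H x W x 3 array.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  img <- round(raw[, , 1:3, drop = FALSE] * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write a synthetic sample to disk
#'
#' Writes `<stem>.png` (image), `<stem>_mask.png` (labels) and
#' `<stem>.json` (the ground-truth object list) under `dir`.
#'
#' @param sample a `stoma_sample`.
#' @param dir output directory (created if missing).
#' @param stem file name stem, canonically
#'   `<variety>_<surface>_<replicate>[_augK]`.
#' @return named character vector of the three paths.
#' @export
write_sample <- function(sample, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ip <- file.path(dir, paste0(stem, ".png"))
  mp <- file.path(dir, paste0(stem, "_mask.png"))
  jp <- file.path(dir, paste0(stem, ".json"))
  write_image(sample$image, ip)
  write_mask(sample$mask, mp)
  jsonlite::write_json(sample$objects, jp, digits = NA)
  c(image = ip, mask = mp, objects = jp)
}

#' Read a sample written by [write_sample()]
#'
#' @param dir directory.
#' @param stem file name stem.
#' @return a `stoma_sample`.
#' @export
read_sample <- function(dir, stem) {
  structure(list(image = read_image(file.path(dir, paste0(stem, ".png"))),
                 mask = read_mask(file.path(dir, paste0(stem, "_mask.png"))),
                 objects = jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                                               simplifyVector = TRUE)),
            class = "stoma_sample")
}

#' Dataset manifests
#'
#' A manifest is a TSV with columns sample_id, image_path, mask_path,
#' variety, surface, replicate, split. Image/mask pairs are matched by file
#' name stem. `read_manifest` optionally validates that every referenced
#' path exists.
#'
#' @param manifest data.frame with the columns above.
#' @param path TSV file path.
#' @param check_paths validate referenced files on read.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "image_path", "mask_path", "variety", "surface",
            "replicate", "split")
  assert_that(all(need %in% names(manifest)), "manifest is missing required columns")
  assert_that(!anyDuplicated(manifest$sample_id), "sample_id must be unique")
  utils::write.table(manifest[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(m$sample_id), "sample_id must be unique")
  stems <- function(p) sub("(_mask)?\\.[a-zA-Z]+$", "", basename(p))
  bad <- stems(m$image_path) != stems(m$mask_path)
  if (any(bad)) {
    stop(sprintf("image/mask stem mismatch for sample(s): %s",
                 paste(utils::head(m$sample_id[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  if (check_paths) {
    missing <- !file.exists(m$image_path) | !file.exists(m$mask_path)
    if (any(missing)) {
      stop(sprintf("manifest references missing files for: %s",
                   paste(utils::head(m$sample_id[missing], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  m
}

#' Write per-object and per-image trait tables
#'
#' The detail CSV holds one row per detected object (sample_id, surface,
#' object_id, length_px, width_px, area_px2, border_flag); the summary CSV
#' one row per image (sample_id, surface, stoma_count and trait means). An
#' empty trait list yields header-only files.
#'
#' @param traits list of `image_traits`.
#' @param path detail CSV path.
#' @param summary_path summary CSV path (default: `_summary.csv` sibling).
#' @return invisible list of the two data.frames written.
#' @export
write_traits_csv <- function(traits, path,
                             summary_path = sub("\\.csv$", "_summary.csv", path)) {
  detail <- do.call(rbind, c(list(
    data.frame(sample_id = character(0), surface = character(0),
               object_id = integer(0), length_px = numeric(0),
               width_px = numeric(0), area_px2 = numeric(0),
               border_flag = logical(0))),
    lapply(traits, function(tr) {
      if (tr$stoma_count == 0) return(NULL)
      data.frame(sample_id = tr$sample_id, surface = tr$surface,
                 object_id = tr$records$object_id,
                 length_px = tr$records$length_px,
                 width_px = tr$records$width_px,
                 area_px2 = tr$records$area,
                 border_flag = tr$records$border_flag)
    })))
  summary <- do.call(rbind, c(list(
    data.frame(sample_id = character(0), surface = character(0),
               stoma_count = integer(0), mean_length_px = numeric(0),
               mean_width_px = numeric(0), mean_area_px2 = numeric(0))),
    lapply(traits, function(tr) {
      data.frame(sample_id = tr$sample_id, surface = tr$surface,
                 stoma_count = tr$stoma_count,
                 mean_length_px = tr$means$length_px,
                 mean_width_px = tr$means$width_px,
                 mean_area_px2 = tr$means$area)
    })))
  utils::write.csv(detail, path, row.names = FALSE)
  utils::write.csv(summary, summary_path, row.names = FALSE)
  invisible(list(detail = detail, summary = summary))
}
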