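# Hierarchical-transformer semantic segmentation model.
#
# Architecture: overlapping patch embedding (7x7 conv, stride 4, pad 3), four
# transformer stages at 1/4, 1/8, 1/16, 1/32 of the input resolution with
# spatial-reduction self-attention and Mix-FFN blocks (3x3 depthwise conv
# between the two linear layers), in the mix-transformer (MiT) convention.
# A cross-layer feature pyramid attention block refines the four-level
# pyramid via channel attention (CCA) and spatial attention (CSA) over
# spatially aligned tokens, with residual redistribution, before an all-MLP
# decoder projects every level to a common width, upsamples to the 1/4 grid,
# fuses parallel MLP branches, and emits an (H, W, K) logit tensor.

#' Model configuration
#'
#' All architecture hyperparameters. Two presets are provided: `"paper"`, the
#' full-scale configuration (stage channels 64/128/320/512, depth 2 per
#' stage, 256 decoder channels), and `"tiny"`, a desk-scale configuration
#' (channels 16/32/64/128, depth 1, 64 decoder channels) used for tests and
#' CPU training.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param num_classes K, the number of segmentation classes (default 3:
#'   background, stoma, pore).
#' @param stage_channels,stage_depths,sr_ratios,mlp_ratio,decoder_channels
#'   optional overrides of the preset values. `sr_ratios` are the per-stage
#'   spatial-reduction factors of the self-attention keys/values.
#' @param patch_kernel,patch_stride,patch_padding stem embedding convolution
#'   geometry (7 / 4 / 3).
#' @return an object of class `seg_config`.
#' @export
model_config <- function(preset = c("tiny", "paper"), num_classes = 3L,
                         stage_channels = NULL, stage_depths = NULL,
                         sr_ratios = NULL, mlp_ratio = NULL,
                         decoder_channels = NULL,
                         patch_kernel = 7L, patch_stride = 4L, patch_padding = 3L) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(stage_channels = c(64L, 128L, 320L, 512L), stage_depths = rep(2L, 4),
         mlp_ratio = 4L, decoder_channels = 256L)
  } else {
    list(stage_channels = c(16L, 32L, 64L, 128L), stage_depths = rep(1L, 4),
         mlp_ratio = 2L, decoder_channels = 64L)
  }
  cfg <- list(
    preset = preset,
    num_classes = as.integer(num_classes),
    stage_channels = as.integer(stage_channels %||% def$stage_channels),
    stage_depths = as.integer(stage_depths %||% def$stage_depths),
    sr_ratios = as.integer(sr_ratios %||% c(8L, 4L, 2L, 1L)),
    mlp_ratio = as.integer(mlp_ratio %||% def$mlp_ratio),
    decoder_channels = as.integer(decoder_channels %||% def$decoder_channels),
    patch_kernel = as.integer(patch_kernel),
    patch_stride = as.integer(patch_stride),
    patch_padding = as.integer(patch_padding),
    stage_downsample = c(4L, 8L, 16L, 32L)
  )
  assert_that(length(cfg$stage_channels) == 4L, "exactly four stages required")
  assert_that(length(cfg$stage_depths) == 4L && all(cfg$stage_depths >= 1L),
              "stage_depths must be four positive integers")
  assert_that(cfg$num_classes >= 2L, "num_classes must be >= 2")
  assert_that(cfg$decoder_channels > 0L, "decoder_channels must be positive")
  cfg$cfpt_channels <- min(cfg$stage_channels)
  class(cfg) <- "seg_config"
  cfg
}

trunc_normal <- function(n, sd = 0.02) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

new_param <- function(params, name, nr, nc, init = c("tn", "zero", "one")) {
  init <- match.arg(init)
  v <- switch(init,
              tn = matrix(trunc_normal(nr * nc), nr, nc),
              zero = matrix(0, nr, nc),
              one = matrix(1, nr, nc))
  params[[name]] <- v
  params
}

#' Build a model with freshly initialized weights
#'
#' Projection weights are truncated-normal (sd 0.02, clipped at two standard
#' deviations), biases zero, layer-norm gains one. Initialization is fully
#' determined by `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `seg_model`: list with `config` and the named
#'   parameter list `params`.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "seg_config"))
  with_seed(seed, {
    p <- list()
    ch <- config$stage_channels
    k <- config$patch_kernel
    # stem: overlapping patch embedding from 3 input channels
    p <- new_param(p, "pe.W", k * k * 3L, ch[1])
    p <- new_param(p, "pe.b", 1L, ch[1], "zero")
    p <- new_param(p, "pe.ln.g", 1L, ch[1], "one")
    p <- new_param(p, "pe.ln.b", 1L, ch[1], "zero")
    for (s in 1:4) {
      C <- ch[s]
      if (s > 1) {  # overlapping 3x3/stride-2 merge between stages
        p <- new_param(p, sprintf("mg%d.W", s), 9L * ch[s - 1], C)
        p <- new_param(p, sprintf("mg%d.b", s), 1L, C, "zero")
        p <- new_param(p, sprintf("mg%d.ln.g", s), 1L, C, "one")
        p <- new_param(p, sprintf("mg%d.ln.b", s), 1L, C, "zero")
      }
      for (d in seq_len(config$stage_depths[s])) {
        pre <- sprintf("st%d.b%d.", s, d)
        for (nm in c("ln1", "ln2")) {
          p <- new_param(p, paste0(pre, nm, ".g"), 1L, C, "one")
          p <- new_param(p, paste0(pre, nm, ".b"), 1L, C, "zero")
        }
        for (nm in c("Wq", "Wk", "Wv", "Wo")) p <- new_param(p, paste0(pre, "attn.", nm), C, C)
        for (nm in c("bq", "bk", "bv", "bo")) p <- new_param(p, paste0(pre, "attn.", nm), 1L, C, "zero")
        if (config$sr_ratios[s] > 1L) {
          p <- new_param(p, paste0(pre, "sr.W"), C, C)
          p <- new_param(p, paste0(pre, "sr.b"), 1L, C, "zero")
          p <- new_param(p, paste0(pre, "sr.ln.g"), 1L, C, "one")
          p <- new_param(p, paste0(pre, "sr.ln.b"), 1L, C, "zero")
        }
        Ch <- C * config$mlp_ratio
        p <- new_param(p, paste0(pre, "ffn.W1"), C, Ch)
        p <- new_param(p, paste0(pre, "ffn.b1"), 1L, Ch, "zero")
        p <- new_param(p, paste0(pre, "ffn.dw.W"), 9L, Ch)
        p <- new_param(p, paste0(pre, "ffn.dw.b"), 1L, Ch, "zero")
        p <- new_param(p, paste0(pre, "ffn.W2"), Ch, C)
        p <- new_param(p, paste0(pre, "ffn.b2"), 1L, C, "zero")
      }
      p <- new_param(p, sprintf("st%d.ln.g", s), 1L, C, "one")
      p <- new_param(p, sprintf("st%d.ln.b", s), 1L, C, "zero")
    }
    # cross-layer feature pyramid attention
    Cc <- config$cfpt_channels
    for (i in 1:4) {
      p <- new_param(p, sprintf("cfpt.lat%d.W", i), ch[i], Cc)
      p <- new_param(p, sprintf("cfpt.lat%d.b", i), 1L, Cc, "zero")
      p <- new_param(p, sprintf("cfpt.out%d.W", i), Cc, ch[i])
      p <- new_param(p, sprintf("cfpt.out%d.b", i), 1L, ch[i], "zero")
    }
    p <- new_param(p, "cfpt.ln.g", 1L, 4L * Cc, "one")
    p <- new_param(p, "cfpt.ln.b", 1L, 4L * Cc, "zero")
    for (nm in c("Wq", "Wk", "Wv")) p <- new_param(p, paste0("cfpt.csa.", nm), 4L * Cc, 4L * Cc)
    p <- new_param(p, "cfpt.comb.Wc", 4L * Cc, 4L * Cc)
    p <- new_param(p, "cfpt.comb.Ws", 4L * Cc, 4L * Cc)
    p <- new_param(p, "cfpt.comb.b", 1L, 4L * Cc, "zero")
    # all-MLP decoder
    D <- config$decoder_channels
    for (i in 1:4) {
      p <- new_param(p, sprintf("dec.proj%d.W", i), ch[i], D)
      p <- new_param(p, sprintf("dec.proj%d.b", i), 1L, D, "zero")
    }
    for (j in 1:2) {
      p <- new_param(p, sprintf("dec.br%d.W", j), 4L * D, D)
      p <- new_param(p, sprintf("dec.br%d.b", j), 1L, D, "zero")
    }
    p <- new_param(p, "dec.fuse.W", 2L * D, D)
    p <- new_param(p, "dec.fuse.b", 1L, D, "zero")
    p <- new_param(p, "dec.cls.W", D, config$num_classes)
    p <- new_param(p, "dec.cls.b", 1L, config$num_classes, "zero")
    structure(list(config = config, params = p), class = "seg_model")
  })
}

#' Overwrite parameters matching a regular expression (test hook)
#'
#' @param model a `seg_model`.
#' @param pattern regular expression over parameter names.
#' @param value scalar the matching parameters are filled with.
#' @return the modified model.
#' @export
model_set_params <- function(model, pattern, value) {
  sel <- grep(pattern, names(model$params))
  for (i in sel) model$params[[i]][] <- value
  model
}

# Register all parameters as tape inputs; returns an environment mapping
# parameter name -> node id.
reg_params <- function(tape, model) {
  ids <- new.env(parent = emptyenv())
  nms <- names(model$params)
  for (i in seq_along(nms)) assign(nms[i], tp_input(tape, model$params[[i]]), envir = ids)
  ids
}

pid <- function(ids, name) get(name, envir = ids, inherits = FALSE)

tp_linear <- function(tape, x, ids, name) {
  tp_add(tape, tp_mm(tape, x, pid(ids, paste0(name, ".W"))), pid(ids, paste0(name, ".b")))
}

tp_ln <- function(tape, x, ids, name) {
  tp_layernorm(tape, x, pid(ids, paste0(name, ".g")), pid(ids, paste0(name, ".b")))
}

stage_forward <- function(tape, ids, x, h, w, s, cfg, B = 1L) {
  C <- cfg$stage_channels[s]
  sr <- cfg$sr_ratios[s]
  for (d in seq_len(cfg$stage_depths[s])) {
    pre <- sprintf("st%d.b%d.", s, d)
    # spatial-reduction self-attention
    xn <- tp_ln(tape, x, ids, paste0(pre, "ln1"))
    q <- tp_add(tape, tp_mm(tape, xn, pid(ids, paste0(pre, "attn.Wq"))),
                pid(ids, paste0(pre, "attn.bq")))
    kvsrc <- xn
    if (sr > 1L && h %% sr == 0L && w %% sr == 0L) {
      red <- tp_spmm(tape, avgpool_matrix_b(h, w, sr, B), xn)
      red <- tp_add(tape, tp_mm(tape, red, pid(ids, paste0(pre, "sr.W"))),
                    pid(ids, paste0(pre, "sr.b")))
      kvsrc <- tp_ln(tape, red, ids, paste0(pre, "sr.ln"))
    }
    kk <- tp_add(tape, tp_mm(tape, kvsrc, pid(ids, paste0(pre, "attn.Wk"))),
                 pid(ids, paste0(pre, "attn.bk")))
    vv <- tp_add(tape, tp_mm(tape, kvsrc, pid(ids, paste0(pre, "attn.Wv"))),
                 pid(ids, paste0(pre, "attn.bv")))
    att <- tp_block_attention(tape, q, kk, vv, B, 1 / sqrt(C))
    att <- tp_add(tape, tp_mm(tape, att, pid(ids, paste0(pre, "attn.Wo"))),
                  pid(ids, paste0(pre, "attn.bo")))
    x <- tp_add(tape, x, att)
    # Mix-FFN: linear -> depthwise 3x3 on the (h, w) grid -> GELU -> linear
    xn2 <- tp_ln(tape, x, ids, paste0(pre, "ln2"))
    hid <- tp_add(tape, tp_mm(tape, xn2, pid(ids, paste0(pre, "ffn.W1"))),
                  pid(ids, paste0(pre, "ffn.b1")))
    hid <- tp_dwconv(tape, hid, pid(ids, paste0(pre, "ffn.dw.W")),
                     pid(ids, paste0(pre, "ffn.dw.b")), im2col_idx_b(h, w, 3L, 1L, 1L, B))
    hid <- tp_gelu(tape, hid)
    out <- tp_add(tape, tp_mm(tape, hid, pid(ids, paste0(pre, "ffn.W2"))),
                  pid(ids, paste0(pre, "ffn.b2")))
    x <- tp_add(tape, x, out)
  }
  tp_ln(tape, x, ids, sprintf("st%d.ln", s))
}

# Full encoder on the tape: image matrix (N x 3, normalized) -> list of four
# levels, each list(id, h, w).
encoder_tape <- function(tape, ids, img_mat, H, W, cfg, B = 1L) {
  idx <- im2col_idx_b(H, W, cfg$patch_kernel, cfg$patch_stride, cfg$patch_padding, B)
  x <- tp_im2col(tape, img_mat, idx)
  x <- tp_add(tape, tp_mm(tape, x, pid(ids, "pe.W")), pid(ids, "pe.b"))
  x <- tp_ln(tape, x, ids, "pe.ln")
  h <- attr(idx, "h_out"); w <- attr(idx, "w_out")
  pyr <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1) {
      midx <- im2col_idx_b(h, w, 3L, 2L, 1L, B)
      x <- tp_im2col(tape, x, midx)
      x <- tp_add(tape, tp_mm(tape, x, pid(ids, sprintf("mg%d.W", s))),
                  pid(ids, sprintf("mg%d.b", s)))
      x <- tp_ln(tape, x, ids, sprintf("mg%d.ln", s))
      h <- attr(midx, "h_out"); w <- attr(midx, "w_out")
    }
    x <- stage_forward(tape, ids, x, h, w, s, cfg, B)
    pyr[[s]] <- list(id = x, h = h, w = w)
  }
  pyr
}

# Cross-layer feature pyramid attention on the tape. Levels are channel-
# aligned by lateral 1x1 projections, spatially aligned to the 1/16 grid
# (channel reconstruction: average pooling down, bilinear up), refined by
# channel attention (tokens = channels, Gram-matrix attention) and spatial
# attention (tokens = positions, learned q/k/v), combined, redistributed to
# the original grids and added residually through per-level output
# projections. Zeroing the output projections makes the block an identity.
cfpt_tape <- function(tape, ids, pyr, cfg, B = 1L) {
  Cc <- cfg$cfpt_channels
  h3 <- pyr[[3]]$h; w3 <- pyr[[3]]$w
  aligned <- vector("list", 4L)
  for (i in 1:4) {
    lat <- tp_linear(tape, pyr[[i]]$id, ids, sprintf("cfpt.lat%d", i))
    hi <- pyr[[i]]$h; wi <- pyr[[i]]$w
    if (hi > h3) {
      lat <- tp_spmm(tape, avgpool_matrix_b(hi, wi, hi %/% h3, B), lat)
    } else if (hi < h3) {
      lat <- tp_spmm(tape, bilinear_matrix_b(hi, wi, h3, w3, B), lat)
    }
    aligned[[i]] <- lat
  }
  X <- tp_cbind(tape, unlist(aligned))
  Xn <- tp_ln(tape, X, ids, "cfpt.ln")
  N3 <- h3 * w3
  # CCA: channel tokens attend over the joint spatial support (Gram-matrix
  # attention; the tokens are the 4*Cc aligned channels of one instance)
  Xt <- tp_block_transpose(tape, Xn, B)
  Yc <- tp_block_transpose(tape, tp_block_attention(tape, Xt, Xt, Xt, B, 1 / sqrt(N3)), B)
  # CSA: spatial tokens attend with learned projections
  q <- tp_mm(tape, Xn, pid(ids, "cfpt.csa.Wq"))
  k <- tp_mm(tape, Xn, pid(ids, "cfpt.csa.Wk"))
  v <- tp_mm(tape, Xn, pid(ids, "cfpt.csa.Wv"))
  Ys <- tp_block_attention(tape, q, k, v, B, 1 / sqrt(4 * Cc))
  Z <- tp_add(tape, tp_add(tape, tp_mm(tape, Yc, pid(ids, "cfpt.comb.Wc")),
                           tp_mm(tape, Ys, pid(ids, "cfpt.comb.Ws"))),
              pid(ids, "cfpt.comb.b"))
  out <- vector("list", 4L)
  for (i in 1:4) {
    blk <- tp_slice_cols(tape, Z, (i - 1L) * Cc + 1L, i * Cc)
    hi <- pyr[[i]]$h; wi <- pyr[[i]]$w
    if (hi > h3) {
      blk <- tp_spmm(tape, bilinear_matrix_b(h3, w3, hi, wi, B), blk)
    } else if (hi < h3) {
      blk <- tp_spmm(tape, avgpool_matrix_b(h3, w3, h3 %/% hi, B), blk)
    }
    delta <- tp_linear(tape, blk, ids, sprintf("cfpt.out%d", i))
    out[[i]] <- list(id = tp_add(tape, pyr[[i]]$id, delta), h = hi, w = wi)
  }
  out
}

# All-MLP decoder on the tape; returns logits over the full H x W grid.
decoder_tape <- function(tape, ids, pyr, cfg, H, W, B = 1L) {
  D <- cfg$decoder_channels
  h1 <- pyr[[1]]$h; w1 <- pyr[[1]]$w
  proj <- vector("list", 4L)
  for (i in 1:4) {
    p <- tp_linear(tape, pyr[[i]]$id, ids, sprintf("dec.proj%d", i))
    if (pyr[[i]]$h < h1) {
      p <- tp_spmm(tape, bilinear_matrix_b(pyr[[i]]$h, pyr[[i]]$w, h1, w1, B), p)
    }
    proj[[i]] <- p
  }
  cat4 <- tp_cbind(tape, unlist(proj))
  branches <- lapply(1:2, function(j) {
    tp_gelu(tape, tp_linear(tape, cat4, ids, sprintf("dec.br%d", j)))
  })
  fused <- tp_gelu(tape, tp_linear(tape, tp_cbind(tape, unlist(branches)), ids, "dec.fuse"))
  logits <- tp_linear(tape, fused, ids, "dec.cls")
  tp_spmm(tape, bilinear_matrix_b(h1, w1, H, W, B), logits)
}

# Normalize an 8-bit image array to the [-1, 1] range the encoder expects and
# flatten to an (H*W x 3) matrix in column-major pixel order.
normalize_image <- function(image) {
  d <- dim(image)
  assert_that(length(d) == 3L && d[3] == 3L, "image must be an H x W x 3 array")
  matrix(as.numeric(image) / 127.5 - 1, d[1] * d[2], 3L)
}

check_divisible <- function(H, W) {
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop(sprintf("input size %d x %d is not divisible by 32; pad or crop first", H, W),
         call. = FALSE)
  }
}

pyramid_from_tape <- function(tape, pyr, cfg) {
  maps <- lapply(seq_along(pyr), function(i) {
    m <- tp_val(tape, pyr[[i]]$id)
    array(m, dim = c(pyr[[i]]$h, pyr[[i]]$w, ncol(m)))
  })
  class(maps) <- "feature_pyramid"
  maps
}

pyramid_to_tape <- function(tape, pyramid) {
  lapply(pyramid, function(a) {
    d <- dim(a)
    list(id = tp_input(tape, matrix(a, d[1] * d[2], d[3])), h = d[1], w = d[2])
  })
}

validate_pyramid <- function(pyramid, cfg = NULL) {
  assert_that(length(pyramid) == 4L, "feature pyramid must have exactly four levels")
  for (i in 1:4) assert_that(length(dim(pyramid[[i]])) == 3L,
                             "each pyramid level must be an h x w x C array")
  for (i in 2:4) {
    assert_that(dim(pyramid[[i - 1]])[1] == 2L * dim(pyramid[[i]])[1] &&
                  dim(pyramid[[i - 1]])[2] == 2L * dim(pyramid[[i]])[2],
                "pyramid spatial sizes must halve between consecutive levels")
  }
  if (!is.null(cfg)) {
    for (i in 1:4) {
      if (dim(pyramid[[i]])[3] != cfg$stage_channels[i]) {
        stop(sprintf("pyramid level %d has %d channels, config expects %d",
                     i, dim(pyramid[[i]])[3], cfg$stage_channels[i]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Encoder forward pass
#'
#' Runs the overlapping patch embedding and the four transformer stages,
#' returning the feature pyramid at 1/4, 1/8, 1/16 and 1/32 of the input
#' resolution with the configured channel counts. Input height and width must
#' be divisible by 32. Intensities (0-255) are normalized internally to
#' \[-1, 1\].
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 intensity array.
#' @return a `feature_pyramid`: list of four h x w x C arrays.
#' @export
encoder_forward <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  d <- dim(image)
  check_divisible(d[1], d[2])
  tape <- tape_new()
  ids <- reg_params(tape, model)
  pyr <- encoder_tape(tape, ids, tp_input(tape, normalize_image(image)),
                      d[1], d[2], model$config)
  pyramid_from_tape(tape, pyr, model$config)
}

#' Cross-layer feature pyramid attention forward pass
#'
#' Refines a four-level pyramid by cross-layer channel and spatial attention
#' over tokens aligned on the 1/16 grid; shapes are preserved level by level
#' (the block is residual).
#'
#' @param model a `seg_model`.
#' @param pyramid a four-level `feature_pyramid`.
#' @return a `feature_pyramid` with identical shapes.
#' @export
cfpt_forward <- function(model, pyramid) {
  stopifnot(inherits(model, "seg_model"))
  validate_pyramid(pyramid, model$config)
  tape <- tape_new()
  ids <- reg_params(tape, model)
  out <- cfpt_tape(tape, ids, pyramid_to_tape(tape, pyramid), model$config)
  pyramid_from_tape(tape, out, model$config)
}

#' All-MLP decoder forward pass
#'
#' Projects each pyramid level to the decoder width, upsamples to the 1/4
#' grid, concatenates, runs parallel MLP branches and a fusion layer, and
#' emits per-pixel class scores at full input resolution.
#'
#' @param model a `seg_model`.
#' @param pyramid a four-level `feature_pyramid`.
#' @return an H x W x K numeric array of logits (class `logit_map`).
#' @export
decoder_forward <- function(model, pyramid) {
  stopifnot(inherits(model, "seg_model"))
  validate_pyramid(pyramid, model$config)
  tape <- tape_new()
  ids <- reg_params(tape, model)
  pyr <- pyramid_to_tape(tape, pyramid)
  H <- pyr[[1]]$h * 4L; W <- pyr[[1]]$w * 4L
  lg <- decoder_tape(tape, ids, pyr, model$config, H, W)
  out <- array(tp_val(tape, lg), dim = c(H, W, model$config$num_classes))
  class(out) <- c("logit_map", class(out))
  out
}

#' Full segmentation forward pass
#'
#' Encoder, cross-layer pyramid attention and decoder composed on one graph.
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 intensity array, sides divisible by 32.
#' @return an H x W x K `logit_map`.
#' @export
model_forward <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  d <- dim(image)
  check_divisible(d[1], d[2])
  tape <- tape_new()
  ids <- reg_params(tape, model)
  pyr <- encoder_tape(tape, ids, tp_input(tape, normalize_image(image)),
                      d[1], d[2], model$config)
  pyr <- cfpt_tape(tape, ids, pyr, model$config)
  lg <- decoder_tape(tape, ids, pyr, model$config, d[1], d[2])
  out <- array(tp_val(tape, lg), dim = c(d[1], d[2], model$config$num_classes))
  class(out) <- c("logit_map", class(out))
  out
}

#' Read out a label mask from per-pixel class scores
#'
#' Per-pixel argmax; ties are broken toward the lowest class index.
#'
#' @param logits H x W x K array of finite class scores.
#' @return H x W integer matrix of labels 0..K-1.
#' @export
predict_mask <- function(logits) {
  d <- dim(logits)
  assert_that(length(d) == 3L, "logits must be an H x W x K array")
  if (anyNA(logits) || any(is.nan(logits))) stop("logits contain NaN", call. = FALSE)
  m <- matrix(logits, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Segment an image
#'
#' Convenience wrapper: forward pass plus argmax readout.
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 intensity array.
#' @return H x W integer label mask.
#' @export
segment_image <- function(model, image) predict_mask(model_forward(model, image))

#' Save / load model checkpoints
#'
#' Checkpoints embed the configuration alongside the weights.
#'
#' @param model a `seg_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "seg_model"))
  m
}
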