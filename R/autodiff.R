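# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Values are plain R matrices; a tape records, per node, its value, parent
# node ids and a backward closure mapping the upstream gradient to gradients
# for each parent. Feature maps are stored as (tokens x channels) matrices in
# R's column-major pixel order (index = row + (col-1) * H); spatial metadata
# travels alongside in the model code, not in the tape. Matrix products hit
# BLAS, so this is fast enough for the desk-scale presets the package trains.

tape_new <- function(hint = 1024L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", hint)
  tp$parents <- vector("list", hint)
  tp$bw <- vector("list", hint)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, val, parents = integer(0), bw = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$vals)) {
    length(tape$vals) <- 2L * n
    length(tape$parents) <- 2L * n
    length(tape$bw) <- 2L * n
  }
  tape$n <- n
  tape$vals[[n]] <- val
  tape$parents[[n]] <- as.integer(parents)
  tape$bw[[n]] <- bw
  n
}

tp_input <- function(tape, val) tp_node(tape, val)

tp_val <- function(tape, id) {
  force(id)
  tape$vals[[id]]
}

# Reverse sweep from `root`; returns a list of gradients indexed by node id
# (NULL where the node does not influence the root).
tp_backward <- function(tape, root, seed_grad = NULL) {
  grads <- vector("list", tape$n)
  rv <- tape$vals[[root]]
  grads[[root]] <- seed_grad %||% array(1, dim = dim(rv) %||% length(rv))
  for (i in seq.int(root, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bwf <- tape$bw[[i]]
    if (is.null(bwf)) next
    pg <- bwf(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      id <- ps[j]
      grads[[id]] <- if (is.null(grads[[id]])) pg[[j]] else grads[[id]] + pg[[j]]
    }
  }
  grads
}

# --- elementary ops ---------------------------------------------------------

tp_mm <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  tp_node(tape, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

# a + b; b may be a 1 x C bias row broadcast over the rows of a.
tp_add <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  if (nrow(B) == 1L && nrow(A) > 1L) {
    val <- A + matrix(B, nrow(A), ncol(A), byrow = TRUE)
    tp_node(tape, val, c(a, b),
            function(g) list(g, matrix(colSums(g), 1L)))
  } else {
    tp_node(tape, A + B, c(a, b), function(g) list(g, g))
  }
}

tp_scale <- function(tape, a, k) {
  force(a)
  A <- tape$vals[[a]]
  tp_node(tape, A * k, a, function(g) list(g * k))
}

tp_mul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  tp_node(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_gelu <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  Phi <- stats::pnorm(A)
  tp_node(tape, A * Phi, a,
          function(g) list(g * (Phi + A * stats::dnorm(A))))
}

tp_relu <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  tp_node(tape, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tp_transpose <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  tp_node(tape, t(A), a, function(g) list(t(g)))
}

tp_cbind <- function(tape, ids) {
  ids <- as.integer(ids)
  vals <- lapply(ids, function(i) tape$vals[[i]])
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  tp_node(tape, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

tp_slice_cols <- function(tape, a, from, to) {
  force(a)
  A <- tape$vals[[a]]
  tp_node(tape, A[, from:to, drop = FALSE], a, function(g) {
    gx <- matrix(0, nrow(A), ncol(A))
    gx[, from:to] <- g
    list(gx)
  })
}

tp_mean <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  tp_node(tape, matrix(mean(A), 1L, 1L), a,
          function(g) list(array(g[1] / length(A), dim = dim(A))))
}

# Row-wise layer normalization with learnable 1 x C gain/offset.
tp_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  force(x); force(gamma); force(beta)
  X <- tape$vals[[x]]; G <- tape$vals[[gamma]]; B <- tape$vals[[beta]]
  N <- nrow(X); C <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  Gm <- matrix(G, N, C, byrow = TRUE)
  val <- xhat * Gm + matrix(B, N, C, byrow = TRUE)
  tp_node(tape, val, c(x, gamma, beta), function(g) {
    dxhat <- g * Gm
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * xhat)
    dx <- (inv / C) * (C * dxhat - t1 - xhat * t2)
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

tp_softmax_rows <- function(tape, x) {
  force(x)
  X <- tape$vals[[x]]
  m <- apply(X, 1L, max)
  e <- exp(X - m)
  P <- e / rowSums(e)
  tp_node(tape, P, x, function(g) list(P * (g - rowSums(g * P))))
}

# Multiply by a constant sparse matrix (bilinear resampling, pooling).
tp_spmm <- function(tape, M, x) {
  force(x)
  X <- tape$vals[[x]]
  tp_node(tape, as.matrix(M %*% X), x,
          function(g) list(as.matrix(Matrix::crossprod(M, g))))
}

# Patch extraction (im2col). `idx` is an N_out x (kh*kw) matrix of row indices
# into x (0 marks zero padding); output column block j holds x[idx[, j], ].
tp_im2col <- function(tape, x, idx) {
  force(x)
  X <- tape$vals[[x]]
  C <- ncol(X); K <- ncol(idx); N <- nrow(idx)
  val <- matrix(0, N, K * C)
  for (j in seq_len(K)) {
    sel <- idx[, j] > 0L
    blk <- matrix(0, N, C)
    blk[sel, ] <- X[idx[sel, j], , drop = FALSE]
    val[, ((j - 1L) * C + 1L):(j * C)] <- blk
  }
  tp_node(tape, val, x, function(g) {
    gx <- matrix(0, nrow(X), C)
    for (j in seq_len(K)) {
      sel <- idx[, j] > 0L
      if (!any(sel)) next
      gj <- g[sel, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      rs <- rowsum(gj, idx[sel, j])
      tgt <- as.integer(rownames(rs))
      gx[tgt, ] <- gx[tgt, , drop = FALSE] + rs
    }
    list(gx)
  })
}

# Depthwise 3x3 convolution: w is a 9 x C kernel matrix, b a 1 x C bias,
# idx the 3x3 im2col index matrix for the map's (h, w) grid.
tp_dwconv <- function(tape, x, w, b, idx) {
  force(x); force(w); force(b)
  X <- tape$vals[[x]]; W <- tape$vals[[w]]; B <- tape$vals[[b]]
  N <- nrow(idx); C <- ncol(X); K <- ncol(idx)
  val <- matrix(B, N, C, byrow = TRUE)
  gathered <- vector("list", K)
  for (j in seq_len(K)) {
    sel <- idx[, j] > 0L
    blk <- matrix(0, N, C)
    blk[sel, ] <- X[idx[sel, j], , drop = FALSE]
    gathered[[j]] <- blk
    val <- val + blk * matrix(W[j, ], N, C, byrow = TRUE)
  }
  tp_node(tape, val, c(x, w, b), function(g) {
    gx <- matrix(0, nrow(X), C)
    gw <- matrix(0, K, C)
    for (j in seq_len(K)) {
      gw[j, ] <- colSums(g * gathered[[j]])
      sel <- idx[, j] > 0L
      if (!any(sel)) next
      gj <- g[sel, , drop = FALSE] * matrix(W[j, ], sum(sel), C, byrow = TRUE)
      rs <- rowsum(gj, idx[sel, j])
      tgt <- as.integer(rownames(rs))
      gx[tgt, ] <- gx[tgt, , drop = FALSE] + rs
    }
    list(gx, gw, matrix(colSums(g), 1L))
  })
}

# Batch-stacked block transpose: x holds B row-blocks of equal height; each
# block is transposed independently, so (B*N x C) becomes (B*C x N).
tp_block_transpose <- function(tape, x, B) {
  force(x)
  X <- tape$vals[[x]]
  N <- nrow(X) %/% B
  val <- do.call(rbind, lapply(seq_len(B), function(b) {
    t(X[((b - 1L) * N + 1L):(b * N), , drop = FALSE])
  }))
  C <- ncol(X)
  tp_node(tape, val, x, function(g) {
    list(do.call(rbind, lapply(seq_len(B), function(b) {
      t(g[((b - 1L) * C + 1L):(b * C), , drop = FALSE])
    })))
  })
}

# Scaled-dot-product attention over B stacked instances: q is (B*N x C),
# k and v are (B*M x C); attention is computed block-diagonally so instances
# never attend across the batch.
tp_block_attention <- function(tape, q, k, v, B, scale) {
  force(q); force(k); force(v)
  Q <- tape$vals[[q]]; K <- tape$vals[[k]]; V <- tape$vals[[v]]
  N <- nrow(Q) %/% B; M <- nrow(K) %/% B
  A <- vector("list", B)
  out <- matrix(0, nrow(Q), ncol(V))
  for (b in seq_len(B)) {
    qi <- ((b - 1L) * N + 1L):(b * N)
    ki <- ((b - 1L) * M + 1L):(b * M)
    S <- tcrossprod(Q[qi, , drop = FALSE], K[ki, , drop = FALSE]) * scale
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    A[[b]] <- E / rowSums(E)
    out[qi, ] <- A[[b]] %*% V[ki, , drop = FALSE]
  }
  tp_node(tape, out, c(q, k, v), function(g) {
    gq <- matrix(0, nrow(Q), ncol(Q))
    gk <- matrix(0, nrow(K), ncol(K))
    gv <- matrix(0, nrow(V), ncol(V))
    for (b in seq_len(B)) {
      qi <- ((b - 1L) * N + 1L):(b * N)
      ki <- ((b - 1L) * M + 1L):(b * M)
      gb <- g[qi, , drop = FALSE]
      Ab <- A[[b]]
      dA <- tcrossprod(gb, V[ki, , drop = FALSE])
      dS <- Ab * (dA - rowSums(dA * Ab))
      gq[qi, ] <- dS %*% K[ki, , drop = FALSE] * scale
      gk[ki, ] <- crossprod(dS, Q[qi, , drop = FALSE]) * scale
      gv[ki, ] <- crossprod(Ab, gb)
    }
    list(gq, gk, gv)
  })
}

# Fused hybrid segmentation loss: w_ce * weighted cross-entropy +
# w_dice * (1 - mean soft Dice). `labels` is an integer vector in 0..K-1
# aligned with the rows of the logit matrix. The analytic gradient w.r.t. the
# logits is exercised against finite differences in the test suite.
tp_hybrid_loss_node <- function(tape, logits, labels, w_ce = 1, w_dice = 1,
                                class_weights = NULL) {
  force(logits)
  Z <- tape$vals[[logits]]
  N <- nrow(Z); K <- ncol(Z)
  if (any(labels < 0L | labels >= K)) {
    stop(sprintf("mask contains labels outside 0..%d; class count mismatch", K - 1L),
         call. = FALSE)
  }
  cw <- class_weights %||% rep(1, K)
  m <- apply(Z, 1L, max)
  e <- exp(Z - m)
  se <- rowSums(e)
  P <- e / se
  logp <- Z - m - log(se)
  yi <- cbind(seq_len(N), labels + 1L)
  Y <- matrix(0, N, K); Y[yi] <- 1
  wi <- cw[labels + 1L]
  sw <- sum(wi)
  ce <- -sum(wi * logp[yi]) / sw

  epsd <- 1e-7
  I <- colSums(P * Y); S <- colSums(P); G <- colSums(Y)
  Dc <- (2 * I + epsd) / (S + G + epsd)
  dice <- 1 - mean(Dc)

  total <- w_ce * ce + w_dice * dice
  val <- matrix(total, 1L, 1L)
  attr(val, "ce") <- ce
  attr(val, "dice") <- dice
  tp_node(tape, val, logits, function(g) {
    dce_dz <- (P - Y) * (wi / sw)
    denom <- (S + G + epsd)
    ddice_dp <- -(1 / K) * (2 * Y * matrix(denom, N, K, byrow = TRUE) -
                              matrix(2 * I + epsd, N, K, byrow = TRUE)) /
      matrix(denom^2, N, K, byrow = TRUE)
    ddice_dz <- P * (ddice_dp - rowSums(ddice_dp * P))
    list((w_ce * dce_dz + w_dice * ddice_dz) * g[1])
  })
}

# --- cached index/sparse-matrix builders ------------------------------------

.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .op_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .op_cache)
  }
  get(key, envir = .op_cache, inherits = FALSE)
}

# Row-index matrix for im2col over an h x w grid stored column-major.
im2col_idx <- function(h, w, k, stride, pad) {
  key <- paste("i2c", h, w, k, stride, pad, sep = "_")
  cache_get(key, function() {
    h_out <- (h + 2L * pad - k) %/% stride + 1L
    w_out <- (w + 2L * pad - k) %/% stride + 1L
    ro <- rep(seq_len(h_out), times = w_out)
    co <- rep(seq_len(w_out), each = h_out)
    idx <- matrix(0L, h_out * w_out, k * k)
    j <- 0L
    for (kc in seq_len(k)) {
      for (kr in seq_len(k)) {
        j <- j + 1L
        ir <- (ro - 1L) * stride - pad + kr
        ic <- (co - 1L) * stride - pad + kc
        ok <- ir >= 1L & ir <= h & ic >= 1L & ic <= w
        col <- integer(h_out * w_out)
        col[ok] <- ir[ok] + (ic[ok] - 1L) * h
        idx[, j] <- col
      }
    }
    attr(idx, "h_out") <- h_out
    attr(idx, "w_out") <- w_out
    idx
  })
}

# Sparse bilinear resampling matrix (align_corners = FALSE convention) from an
# h_in x w_in grid to h_out x w_out, both column-major.
bilinear_matrix <- function(h_in, w_in, h_out, w_out) {
  key <- paste("bil", h_in, w_in, h_out, w_out, sep = "_")
  cache_get(key, function() {
    src_axis <- function(n_out, n_in) {
      s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
      s <- clamp(s, 1, n_in)
      i0 <- pmin(floor(s), n_in - ifelse(n_in > 1, 1, 0))
      i0 <- pmax(i0, 1)
      f <- s - i0
      if (n_in == 1) f <- f * 0
      list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, n_in)), f = f)
    }
    ra <- src_axis(h_out, h_in)
    ca <- src_axis(w_out, w_in)
    ro <- rep(seq_len(h_out), times = w_out)
    co <- rep(seq_len(w_out), each = h_out)
    out_id <- ro + (co - 1L) * h_out
    r0 <- ra$i0[ro]; r1 <- ra$i1[ro]; fr <- ra$f[ro]
    c0 <- ca$i0[co]; c1 <- ca$i1[co]; fc <- ca$f[co]
    i <- rep(out_id, 4L)
    j <- c(r0 + (c0 - 1L) * h_in, r0 + (c1 - 1L) * h_in,
           r1 + (c0 - 1L) * h_in, r1 + (c1 - 1L) * h_in)
    x <- c((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
    Matrix::sparseMatrix(i = i, j = j, x = x,
                         dims = c(h_out * w_out, h_in * w_in))
  })
}

# Sparse average pooling by an integer factor over an h x w grid.
avgpool_matrix <- function(h, w, f) {
  key <- paste("avg", h, w, f, sep = "_")
  cache_get(key, function() {
    stopifnot(h %% f == 0L, w %% f == 0L)
    ho <- h %/% f; wo <- w %/% f
    ri <- rep(seq_len(h), times = w)
    ci <- rep(seq_len(w), each = h)
    out_r <- (ri - 1L) %/% f + 1L
    out_c <- (ci - 1L) %/% f + 1L
    Matrix::sparseMatrix(i = out_r + (out_c - 1L) * ho,
                         j = ri + (ci - 1L) * h,
                         x = rep(1 / (f * f), h * w),
                         dims = c(ho * wo, h * w))
  })
}

# Batched variants: B copies of the single-instance structure, stacked
# row-wise / block-diagonally, so one tape op serves a whole minibatch.
im2col_idx_b <- function(h, w, k, stride, pad, B) {
  if (B == 1L) return(im2col_idx(h, w, k, stride, pad))
  key <- paste("i2cb", h, w, k, stride, pad, B, sep = "_")
  cache_get(key, function() {
    idx <- im2col_idx(h, w, k, stride, pad)
    n_in <- h * w
    out <- do.call(rbind, lapply(seq_len(B), function(b) {
      o <- idx + (b - 1L) * n_in
      o[idx == 0L] <- 0L
      o
    }))
    attr(out, "h_out") <- attr(idx, "h_out")
    attr(out, "w_out") <- attr(idx, "w_out")
    out
  })
}

avgpool_matrix_b <- function(h, w, f, B) {
  if (B == 1L) return(avgpool_matrix(h, w, f))
  key <- paste("avgb", h, w, f, B, sep = "_")
  cache_get(key, function() {
    Matrix::bdiag(rep(list(avgpool_matrix(h, w, f)), B))
  })
}

bilinear_matrix_b <- function(h_in, w_in, h_out, w_out, B) {
  if (B == 1L) return(bilinear_matrix(h_in, w_in, h_out, w_out))
  key <- paste("bilb", h_in, w_in, h_out, w_out, B, sep = "_")
  cache_get(key, function() {
    Matrix::bdiag(rep(list(bilinear_matrix(h_in, w_in, h_out, w_out)), B))
  })
}

# Finite-difference gradient of a scalar-valued function of one matrix, used
# by the test suite as the independent oracle for backward passes.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
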