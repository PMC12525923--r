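# The tape's analytic gradients are validated against central finite
# differences — the independent oracle for every backward pass the training
# loop relies on.

tp <- stomatools:::tape_new
tin <- stomatools:::tp_input
tval <- stomatools:::tp_val
tback <- stomatools:::tp_backward
ngrad <- stomatools:::numeric_grad

test_that("composite linear/layernorm/gelu gradients match finite differences", {
  set.seed(41)
  X <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(12), 3, 4)
  gam <- matrix(runif(4, 0.5, 1.5), 1)
  bet <- matrix(rnorm(4), 1)
  f <- function(Xv) {
    t <- tp(); x <- tin(t, Xv); w <- tin(t, W)
    g <- tin(t, gam); b <- tin(t, bet)
    y <- stomatools:::tp_layernorm(t, stomatools:::tp_gelu(t, stomatools:::tp_mm(t, x, w)), g, b)
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y)))[1]
  }
  t <- tp(); x <- tin(t, X); w <- tin(t, W); g <- tin(t, gam); b <- tin(t, bet)
  y <- stomatools:::tp_layernorm(t, stomatools:::tp_gelu(t, stomatools:::tp_mm(t, x, w)), g, b)
  loss <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y))
  gr <- tback(t, loss)
  expect_lt(max(abs(gr[[x]] - ngrad(f, X))), 1e-6)
})

test_that("im2col, depthwise conv and sparse resampling gradients are exact", {
  set.seed(42)
  X <- matrix(rnorm(24), 12, 2)
  idx <- stomatools:::im2col_idx(4L, 3L, 3L, 1L, 1L)
  Wd <- matrix(rnorm(18), 9, 2); bd <- matrix(rnorm(2), 1)
  M <- stomatools:::bilinear_matrix(4L, 3L, 8L, 6L)

  fim <- function(Xv) {
    t <- tp(); x <- tin(t, Xv)
    p <- stomatools:::tp_im2col(t, x, idx)
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, p, p)))[1]
  }
  t <- tp(); x <- tin(t, X)
  p <- stomatools:::tp_im2col(t, x, idx)
  l <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, p, p))
  expect_lt(max(abs(tback(t, l)[[x]] - ngrad(fim, X))), 1e-6)

  fdw <- function(Wv) {
    t <- tp(); x <- tin(t, X); w <- tin(t, Wv); b <- tin(t, bd)
    y <- stomatools:::tp_dwconv(t, x, w, b, idx)
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y)))[1]
  }
  t <- tp(); x <- tin(t, X); w <- tin(t, Wd); b <- tin(t, bd)
  y <- stomatools:::tp_dwconv(t, x, w, b, idx)
  l <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y))
  gr <- tback(t, l)
  expect_lt(max(abs(gr[[w]] - ngrad(fdw, Wd))), 1e-6)

  fsp <- function(Xv) {
    t <- tp(); x <- tin(t, Xv)
    y <- stomatools:::tp_spmm(t, M, x)
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y)))[1]
  }
  t <- tp(); x <- tin(t, X)
  y <- stomatools:::tp_spmm(t, M, x)
  l <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, y, y))
  expect_lt(max(abs(tback(t, l)[[x]] - ngrad(fsp, X))), 1e-6)
})

test_that("block attention gradients match finite differences for all inputs", {
  set.seed(43)
  B <- 2L; N <- 4L; M <- 3L; C <- 3L
  Q <- matrix(rnorm(B * N * C), B * N, C)
  K <- matrix(rnorm(B * M * C), B * M, C)
  V <- matrix(rnorm(B * M * C), B * M, C)
  loss_of <- function(Qv, Kv, Vv) {
    t <- tp(); q <- tin(t, Qv); k <- tin(t, Kv); v <- tin(t, Vv)
    o <- stomatools:::tp_block_attention(t, q, k, v, B, 1 / sqrt(C))
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, o, o)))[1]
  }
  t <- tp(); q <- tin(t, Q); k <- tin(t, K); v <- tin(t, V)
  o <- stomatools:::tp_block_attention(t, q, k, v, B, 1 / sqrt(C))
  l <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, o, o))
  gr <- tback(t, l)
  expect_lt(max(abs(gr[[q]] - ngrad(function(x) loss_of(x, K, V), Q))), 1e-6)
  expect_lt(max(abs(gr[[k]] - ngrad(function(x) loss_of(Q, x, V), K))), 1e-6)
  expect_lt(max(abs(gr[[v]] - ngrad(function(x) loss_of(Q, K, x), V))), 1e-6)
})

test_that("the fused hybrid loss gradient matches finite differences", {
  set.seed(44)
  Z <- matrix(rnorm(15), 5, 3)
  lab <- c(0L, 1L, 2L, 1L, 0L)
  cw <- c(1, 2, 3)
  f <- function(Zv) {
    t <- tp(); z <- tin(t, Zv)
    tval(t, stomatools:::tp_hybrid_loss_node(t, z, lab, 0.7, 1.3, cw))[1]
  }
  t <- tp(); z <- tin(t, Z)
  l <- stomatools:::tp_hybrid_loss_node(t, z, lab, 0.7, 1.3, cw)
  expect_lt(max(abs(tback(t, l)[[z]] - ngrad(f, Z))), 1e-6)
})

test_that("shared q/k/v parents accumulate gradients correctly", {
  set.seed(45)
  X <- matrix(rnorm(12), 4, 3)
  f <- function(Xv) {
    t <- tp(); x <- tin(t, Xv)
    o <- stomatools:::tp_block_attention(t, x, x, x, 1L, 1 / sqrt(3))
    tval(t, stomatools:::tp_mean(t, stomatools:::tp_mul(t, o, o)))[1]
  }
  t <- tp(); x <- tin(t, X)
  o <- stomatools:::tp_block_attention(t, x, x, x, 1L, 1 / sqrt(3))
  l <- stomatools:::tp_mean(t, stomatools:::tp_mul(t, o, o))
  expect_lt(max(abs(tback(t, l)[[x]] - ngrad(f, X))), 1e-6)
})
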