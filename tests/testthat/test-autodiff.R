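# The autodiff engine underlies every network module: check each
# operation's analytic gradient against central finite differences and
# the convolution forward pass against a naive seven-loop oracle.

ns <- asNamespace("ifpn3d")

test_that("convolution matches a naive loop oracle and differentiates", {
  set.seed(11)
  x <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2, 1))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  naive <- array(0, c(3, 3, 2, 3, 1))
  for (co in 1:3) for (z in 1:2) for (y in 1:3) for (xx in 1:3) {
    s <- b[co]
    for (ci in 1:2) for (kz in 1:3) for (ky in 1:3) for (kx in 1:3) {
      xi <- xx + kx - 2; yi <- y + ky - 2; zi <- z + kz - 2
      if (xi >= 1 && xi <= 3 && yi >= 1 && yi <= 3 && zi >= 1 && zi <= 2)
        s <- s + x[xi, yi, zi, ci, 1] * w[kx, ky, kz, ci, co]
    }
    naive[xx, y, z, co, 1] <- s
  }
  got <- ns$agValue(ns$ag_conv3d(ns$agLeaf(x), ns$agLeaf(w), ns$agLeaf(b)))
  expect_equal(got, naive, tolerance = 1e-12)

  # gradients (strided, grouped, dilated cases)
  xs <- array(rnorm(4 * 4 * 2 * 4 * 2), c(4, 4, 2, 4, 2))
  cases <- list(
    list(w = c(3, 3, 3, 2, 6), stride = c(1, 1, 1), dil = c(1, 1, 1), g = 2L),
    list(w = c(3, 3, 3, 4, 4), stride = c(2, 2, 1), dil = c(1, 1, 1), g = 1L),
    list(w = c(3, 3, 3, 4, 4), stride = c(1, 1, 1), dil = c(2, 2, 1), g = 1L),
    list(w = c(1, 1, 1, 4, 6), stride = c(1, 1, 1), dil = c(1, 1, 1), g = 1L)
  )
  for (cs in cases) {
    set.seed(7)
    wv <- array(rnorm(prod(cs$w)) * 0.3, cs$w)
    bv <- rnorm(cs$w[5]) * 0.1
    build_x <- function(xn) ns$ag_sum(ns$ag_powc(
      ns$ag_conv3d(xn, ns$agLeaf(wv), ns$agLeaf(bv),
                   stride = cs$stride, dil = cs$dil, groups = cs$g), 2))
    build_w <- function(wn) ns$ag_sum(ns$ag_powc(
      ns$ag_conv3d(ns$agLeaf(xs), wn, ns$agLeaf(bv),
                   stride = cs$stride, dil = cs$dil, groups = cs$g), 2))
    fx <- function(xv) ns$agValue(build_x(ns$agLeaf(xv)))
    fw <- function(wv2) ns$agValue(build_w(ns$agLeaf(wv2)))
    expect_lt(relErr(tapeGrad(build_x, xs), numGrad(fx, xs)), 1e-6)
    expect_lt(relErr(tapeGrad(build_w, wv), numGrad(fw, wv)), 1e-6)
  }
})

test_that("normalization, activation and pooling gradients match finite differences", {
  x <- randTensor(c(4, 4, 2, 4, 2), seed = 21)
  gm <- rnorm(4); bt <- rnorm(4); al <- runif(4, 0.1, 0.4)
  builders <- list(
    gn = function(xn) ns$ag_sum(ns$ag_powc(
      ns$ag_groupnorm(xn, ns$agLeaf(gm), ns$agLeaf(bt), 2L), 2)),
    prelu = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_prelu(xn, ns$agLeaf(al)), 2)),
    sigmoid = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_sigmoid(xn), 2)),
    softmax = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_softmax_ch(xn), 3)),
    maxpool = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_maxpool(xn, 2L), 2)),
    up_lin = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_upsample(xn, 2L, "linear"), 2)),
    up_nn = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_upsample(xn, 2L, "nearest"), 2)),
    gap = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_gap(xn), 2)),
    gmp = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_gmp(xn), 2)),
    chmean = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_chmean(xn), 2)),
    chmax = function(xn) ns$ag_sum(ns$ag_powc(ns$ag_chmax(xn), 2)),
    concat_slice = function(xn) ns$ag_sum(ns$ag_powc(
      ns$ag_slice_ch(ns$ag_concat(list(xn, ns$ag_scale(xn, 2))), 6L), 2))
  )
  for (nm in names(builders)) {
    b <- builders[[nm]]
    f <- function(xv) ns$agValue(b(ns$agLeaf(xv)))
    expect_lt(relErr(tapeGrad(b, x), numGrad(f, x)), 1e-6)
  }
  # GN parameter gradients
  bg <- function(gn) ns$ag_sum(ns$ag_powc(
    ns$ag_groupnorm(ns$agLeaf(x), gn, ns$agLeaf(bt), 2L), 2))
  fg <- function(gv) ns$agValue(bg(ns$agLeaf(gv)))
  expect_lt(relErr(tapeGrad(bg, gm), numGrad(fg, gm)), 1e-6)
})

test_that("broadcast multiply reduces gradients over expanded axes", {
  x <- randTensor(c(3, 3, 2, 4, 2), seed = 31)
  gate_c <- randTensor(c(1, 1, 1, 4, 2), seed = 32)   # channel gate
  gate_s <- randTensor(c(3, 3, 2, 1, 2), seed = 33)   # spatial gate
  for (gate in list(gate_c, gate_s)) {
    bx <- function(xn) ns$ag_sum(ns$ag_powc(ns$ag_mul(xn, ns$agLeaf(gate)), 2))
    fx <- function(xv) ns$agValue(bx(ns$agLeaf(xv)))
    expect_lt(relErr(tapeGrad(bx, x), numGrad(fx, x)), 1e-6)
    bgt <- function(gn) ns$ag_sum(ns$ag_powc(ns$ag_mul(ns$agLeaf(x), gn), 2))
    fgt <- function(gv) ns$agValue(bgt(ns$agLeaf(gv)))
    expect_lt(relErr(tapeGrad(bgt, gate), numGrad(fgt, gate)), 1e-6)
  }
})

test_that("a value used twice accumulates both gradient paths", {
  x <- randTensor(c(2, 2, 1, 2, 1), seed = 41)
  b <- function(xn) ns$ag_sum(ns$ag_mul(xn, ns$ag_sigmoid(xn)))
  f <- function(xv) ns$agValue(b(ns$agLeaf(xv)))
  expect_lt(relErr(tapeGrad(b, x), numGrad(f, x)), 1e-6)
})

test_that("forward passes are deterministic given fixed parameters", {
  m <- tinyModel(seed = 5L)
  v <- randVol(16, 16, 3, seed = 6)
  p1 <- ifpnForward(m, v)$prob
  p2 <- ifpnForward(m, v)$prob
  expect_identical(p1, p2)
})
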