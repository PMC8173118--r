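# Hybrid Jaccard/focal loss analytics: hand-derivable values, ranges,
# monotonicity, loop oracles and finite-difference gradients.

ns <- asNamespace("ifpn3d")

test_that("Jaccard loss reproduces hand-computed values", {
  expect_equal(jaccardLoss(c(0.5, 0.5), c(1, 0)), 0.5, tolerance = 1e-6)
  q <- c(1, 1, 0, 1)
  expect_lt(jaccardLoss(q, q), 1e-6)                 # perfect prediction
  expect_equal(jaccardLoss(rep(0, 4), q), 1, tolerance = 1e-6)  # total miss
})

test_that("focal loss reproduces hand-computed single-voxel values", {
  # q=1, p=0.5: -0.2 * 0.5 * ln(0.5)
  expect_equal(focalLoss(0.5, 1), 0.2 * 0.5 * log(2), tolerance = 1e-6)
  expect_equal(focalLoss(0.5, 1), 0.06931, tolerance = 1e-4)
  # q=0, p=0.5: -0.8 * 0.5 * ln(0.5)
  expect_equal(focalLoss(0.5, 0), 0.8 * 0.5 * log(2), tolerance = 1e-6)
  expect_equal(focalLoss(0.5, 0), 0.27726, tolerance = 1e-4)
  expect_lt(focalLoss(1 - 1e-9, 1), 1e-6)            # confident and correct
})

test_that("signal and SDS losses are the stated weighted sums", {
  set.seed(31)
  p <- runif(8); q <- as.numeric(runif(8) < 0.5)
  cfg <- lossConfig()
  expect_equal(signalLoss(p, q, cfg),
               jaccardLoss(p, q, cfg$eps) + 0.1 * focalLoss(p, q, cfg),
               tolerance = 1e-12)
  cfg0 <- lossConfig(eta_f = 0)
  expect_equal(signalLoss(p, q, cfg0), jaccardLoss(p, q, cfg0$eps),
               tolerance = 1e-12)
  # unit stage losses sum to 0.8 + 0.9 + 1.0 = 2.7: check with stage
  # predictions constructed to give a known common signal loss
  ls <- signalLoss(p, q, cfg)
  preds <- list(p_s2 = p, p_s3 = p, p_f = p)
  expect_equal(sdsLoss(preds, q, cfg), 2.7 * ls, tolerance = 1e-12)
  # and the generic weighted sum 0.8*a + 0.9*b + 1.0*c
  a <- runif(8); b <- runif(8); co <- runif(8)
  got <- sdsLoss(list(p_s2 = a, p_s3 = b, p_f = co), q, cfg)
  expect_equal(got, 0.8 * signalLoss(a, q, cfg) + 0.9 * signalLoss(b, q, cfg) +
                 1.0 * signalLoss(co, q, cfg), tolerance = 1e-12)
  # perfect predictions: loss ~ 0
  expect_lt(sdsLoss(list(p_s2 = q, p_s3 = q, p_f = q), q, cfg), 1e-3)
  # disabling the auxiliary stages recovers single-output training
  cfg_nosds <- lossConfig(stage_weights = c(w2 = 0, w3 = 0, wf = 1))
  expect_equal(sdsLoss(list(p_s2 = a, p_s3 = b, p_f = co), q, cfg_nosds),
               signalLoss(co, q, cfg_nosds), tolerance = 1e-12)
})

test_that("losses stay in range and reject malformed inputs", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    p <- runif(n)
    q <- as.numeric(runif(n) < runif(1))
    j <- jaccardLoss(p, q)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_gte(focalLoss(p, q), 0)
    expect_gte(sdsLoss(list(p_s2 = p, p_s3 = p, p_f = p), q), 0)
  }
  expect_error(jaccardLoss(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(focalLoss(c(0.5), c(0.5)), "binary")
})

test_that("Jaccard loss decreases strictly as the hit probability rises", {
  q <- c(1, rep(0, 7))
  ps <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(ps, function(pv) jaccardLoss(c(pv, rep(0, 7)), q), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("vectorized losses match naive per-voxel loops", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    p <- runif(n)
    q <- as.numeric(runif(n) < 0.4)
    expect_equal(jaccardLoss(p, q), loopJaccard(p, q), tolerance = 1e-6)
    expect_equal(focalLoss(p, q), loopFocal(p, q), tolerance = 1e-6)
  }
})

test_that("loss gradients match central finite differences", {
  set.seed(34)
  p <- array(runif(8, 0.05, 0.95), c(2, 2, 2, 1, 1))
  q <- array(as.numeric(runif(8) < 0.5), c(2, 2, 2, 1, 1))
  if (sum(q) == 0) q[1] <- 1
  cfg <- lossConfig()
  builders <- list(
    function(pn) ns$asNode(jaccardLoss(pn, q)),
    function(pn) ns$asNode(focalLoss(pn, q, cfg)),
    function(pn) ns$asNode(signalLoss(pn, q, cfg))
  )
  fns <- list(function(pv) jaccardLoss(pv, q),
              function(pv) focalLoss(pv, q, cfg),
              function(pv) signalLoss(pv, q, cfg))
  for (k in seq_along(builders)) {
    g <- tapeGrad(builders[[k]], p)
    gn <- numGrad(fns[[k]], p)
    expect_lt(relErr(g, gn), 1e-4)
  }
  # SDS through three maps
  p3 <- list(p_s2 = p, p_s3 = p + 0.01, p_f = p - 0.01)
  bsds <- function(pn) ns$asNode(sdsLoss(list(p_s2 = pn, p_s3 = ns$agLeaf(p3$p_s3),
                                              p_f = ns$agLeaf(p3$p_f)), q, cfg))
  fsds <- function(pv) sdsLoss(list(p_s2 = pv, p_s3 = p3$p_s3, p_f = p3$p_f), q, cfg)
  expect_lt(relErr(tapeGrad(bsds, p), numGrad(fsds, p)), 1e-4)
})
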