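# Evaluation metrics against brute-force set counts and an O(N^2)
# all-pairs surface-distance oracle.

test_that("overlap metrics reproduce the worked example and edge cases", {
  # |pred| = 4, |gt| = 8, overlap = 2
  gt <- array(0, c(6, 6, 2)); gt[1:4, 1:2, 1] <- 1          # 8 voxels
  pred <- array(0, c(6, 6, 2))
  pred[1:2, 1, 1] <- 1                                       # 2 overlapping
  pred[5:6, 6, 2] <- 1                                       # 2 disjoint
  ov <- overlapMetrics(pred, gt)
  expect_equal(unname(ov), c(100 * 4 / 12, 20, 50, 25), tolerance = 1e-9)

  m <- randomMask(c(5, 5, 3), seed = 1, p = 0.3)
  expect_equal(unname(overlapMetrics(m, m)), rep(100, 4))
  a <- array(0, c(4, 4, 2)); a[1, 1, 1] <- 1
  b <- array(0, c(4, 4, 2)); b[4, 4, 2] <- 1
  expect_equal(unname(overlapMetrics(a, b)), rep(0, 4))
  # conventions: both empty -> 100; empty prediction -> precision 0
  e <- array(0, c(4, 4, 2))
  expect_equal(unname(overlapMetrics(e, e)), rep(100, 4))
  expect_equal(unname(overlapMetrics(e, b)), rep(0, 4))
})

test_that("surface voxels follow the 6-neighbourhood definition", {
  m <- array(0, c(5, 5, 5))
  m[3, 3, 3] <- 1
  expect_identical(nrow(surfaceVoxels(m)), 1L)      # single voxel is its surface
  cube <- array(0, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surfaceVoxels(cube)), 26L)  # 27 minus the centre
  expect_identical(nrow(surfaceVoxels(array(0, c(3, 3, 3)))), 0L)
  # mask touching the grid border is surface there
  slab <- array(1, c(3, 3, 1))
  expect_identical(nrow(surfaceVoxels(slab)), 9L)
  # every voxel adjacent to an interior cavity is surface
  hollow <- array(0, c(7, 7, 7))
  hollow[2:6, 2:6, 2:6] <- 1
  hollow[4, 4, 4] <- 0
  sv <- surfaceVoxels(hollow)
  keys <- apply(sv, 1, paste, collapse = ",")
  for (nb in list(c(3, 4, 4), c(5, 4, 4), c(4, 3, 4), c(4, 5, 4),
                  c(4, 4, 3), c(4, 4, 5)))
    expect_true(paste(nb, collapse = ",") %in% keys)
})

test_that("surface distances match hand geometry and handle empties", {
  m <- randomMask(c(6, 6, 3), seed = 2, p = 0.3)
  expect_equal(unname(surfaceMetrics(m, m)), c(0, 0))
  a <- array(0, c(9, 5, 3)); a[2, 3, 2] <- 1
  b <- array(0, c(9, 5, 3)); b[5, 3, 2] <- 1       # 3 voxels apart on x
  expect_equal(unname(surfaceMetrics(a, b)), c(3, 3))
  e <- array(0, c(9, 5, 3))
  expect_warning(sm <- surfaceMetrics(e, a), "undefined")
  expect_true(all(is.na(sm)))
})

test_that("surface metrics equal the all-pairs brute-force oracle", {
  for (s in 1:12) {
    d <- c(sample(6:10, 1), sample(6:10, 1), sample(3:6, 1))
    pred <- randomMask(d, seed = 300 + s, p = runif(1, 0.1, 0.5))
    gt <- randomMask(d, seed = 600 + s, p = runif(1, 0.1, 0.5))
    got <- surfaceMetrics(pred, gt)
    want <- bruteSurfaceMetrics(pred, gt)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("metric symmetries and translation invariance hold", {
  for (s in 1:5) {
    d <- c(8, 8, 4)
    a <- randomMask(d, seed = 40 + s, p = 0.3)
    b <- randomMask(d, seed = 50 + s, p = 0.3)
    oab <- overlapMetrics(a, b); oba <- overlapMetrics(b, a)
    expect_equal(oab[["dice_pct"]], oba[["dice_pct"]])
    expect_equal(oab[["ji_pct"]], oba[["ji_pct"]])
    expect_equal(oab[["pre_pct"]], oba[["recall_pct"]])  # Pre(a,b) = Recall(b,a)
    sab <- surfaceMetrics(a, b); sba <- surfaceMetrics(b, a)
    expect_equal(sab, sba)
    expect_true(oab[["ji_pct"]] <= oab[["dice_pct"]] + 1e-12)
    # shift both masks by (1,2,1) inside a larger grid
    big <- function(m, off) {
      out <- array(0, d + c(3, 3, 2))
      out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- m
      out
    }
    s0 <- surfaceMetrics(big(a, c(0, 0, 0)), big(b, c(0, 0, 0)))
    s1 <- surfaceMetrics(big(a, c(1, 2, 1)), big(b, c(1, 2, 1)))
    expect_equal(s0, s1, tolerance = 1e-12)
    o0 <- overlapMetrics(big(a, c(1, 2, 1)), big(b, c(1, 2, 1)))
    expect_equal(o0, overlapMetrics(a, b))
  }
})

test_that("95HD never exceeds the largest pooled distance", {
  for (s in 1:5) {
    a <- randomMask(c(8, 8, 4), seed = 70 + s, p = 0.2)
    b <- randomMask(c(8, 8, 4), seed = 80 + s, p = 0.2)
    sv_a <- surfaceVoxels(a); sv_b <- surfaceVoxels(b)
    brute <- bruteSurfaceMetrics(a, b)
    got <- surfaceMetrics(a, b)
    expect_lte(got[["hd95_vox"]], max(brute) + 1e-12)
    expect_lte(got[["hd95_vox"]],
               max(c(stats::dist(rbind(sv_a, sv_b)))) + 1e-12)
  }
})

test_that("pair reports assemble and aggregate with mean and sample SD", {
  m <- randomMask(c(8, 8, 4), seed = 90, p = 0.3)
  r <- evaluatePair(m, m, id = "self")
  expect_s4_class(r, "MetricsReport")
  df <- as.data.frame(r)
  expect_equal(unlist(df[, 2:5], use.names = FALSE), rep(100, 4))
  expect_equal(unlist(df[, 6:7], use.names = FALSE), c(0, 0))

  # two volumes with Dice 60 and 64 -> 62 +/- 2.83
  fake <- function(dice) methods::new("MetricsReport", id = "x",
                                      dice_pct = dice, ji_pct = 50, pre_pct = 50,
                                      recall_pct = 50, asd_vox = 1, hd95_vox = 2,
                                      defined = TRUE)
  tab <- aggregateReports(list(fake(60), fake(64)))
  expect_equal(tab$dice_pct[tab$id == "Mean"], 62)
  expect_equal(tab$dice_pct[tab$id == "SD"], sd(c(60, 64)), tolerance = 1e-12)
  expect_equal(round(tab$dice_pct[tab$id == "SD"], 2), 2.83)
})
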