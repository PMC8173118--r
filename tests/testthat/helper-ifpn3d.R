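# Shared fixtures and independent oracles, all built in code.

# Extra-small backbone used for fast structural/property tests; the
# full desk-scale profile is exercised in the acceptance tests.
tinyCfg <- function() {
  cfg <- deskConfig()
  cfg$backbone$base_width <- 8L
  cfg$backbone$cardinality <- 2L
  cfg$backbone$se_ratio <- 4L
  cfg$backbone$cbam_ratio <- 4L
  cfg$backbone$pyramid_channels <- 16L
  cfg$backbone$fusion_hidden <- 4L
  cfg$backbone$gn_groups <- 4L
  cfg$train$patch_size <- c(16L, 16L, 4L)
  cfg$train$epochs <- 2L
  cfg
}

.model_cache <- new.env(parent = emptyenv())

tinyModel <- function(seed = 1L, ablation = "none") {
  key <- paste0("m", seed, "_", ablation)
  if (is.null(.model_cache[[key]])) {
    cfg <- tinyCfg()
    cfg$ablation <- ablation
    .model_cache[[key]] <- ifpnModel(cfg, seed = seed)
  }
  .model_cache[[key]]
}

randVol <- function(x = 16L, y = 16L, z = 4L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(x * y * z), dim = c(x, y, z))
}

randTensor <- function(d, seed = 1L, sd = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(d), 0, sd), dim = d)
}

# central finite-difference gradient of a scalar function of an array
numGrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = ifpn3d:::dimOf(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# tape gradient of a scalar-node builder with respect to input x
tapeGrad <- function(build, x) {
  xn <- ifpn3d:::agParam(x)
  ifpn3d:::agBackward(build(xn))
  xn$grad
}

relErr <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

# O(N^2) all-pairs surface-distance oracle, pure R
bruteSurfaceMetrics <- function(pred, gt) {
  sp <- surfaceVoxels(pred)
  sg <- surfaceVoxels(gt)
  d2 <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2 +
             (a[i, 3] - b[j, 3])^2)
    })
  }
  dPG <- apply(d2(sp, sg), 1, min)
  dGP <- apply(d2(sg, sp), 1, min)
  pooled <- c(dPG, dGP)
  c(asd = mean(pooled),
    hd95 = unname(stats::quantile(pooled, 0.95, type = 7)))
}

randomMask <- function(d, seed, p = 0.5) {
  set.seed(seed)
  # blobby random mask: threshold smoothed noise so surfaces are
  # non-trivial; fall back to a single voxel if empty
  m <- array(as.numeric(stats::runif(prod(d)) < p), dim = d)
  if (sum(m) == 0) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- 1
  m
}

# naive triple-loop fusion oracle for the per-voxel convex combination
naiveFuse <- function(weights, resized) {
  d <- dim(resized[[1]])
  out <- array(0, dim = d)
  for (n in seq_len(d[5])) for (c in seq_len(d[4]))
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      s <- 0
      for (m in 1:3)
        s <- s + weights[[m]][x, y, z, 1, n] * resized[[m]][x, y, z, c, n]
      out[x, y, z, c, n] <- s
    }
  out
}

# naive per-voxel loop implementations of the losses
loopJaccard <- function(p, q, eps = 1e-7) {
  sqp <- 0; sp2 <- 0; sq2 <- 0
  for (i in seq_along(p)) {
    sqp <- sqp + q[i] * p[i]
    sp2 <- sp2 + p[i]^2
    sq2 <- sq2 + q[i]^2
  }
  1 - sqp / (sq2 + sp2 - sqp + eps)
}

loopFocal <- function(p, q, alpha = 0.2, gamma = 1, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s + alpha * q[i] * (1 - pi)^gamma * log(pi) +
      (1 - alpha) * (1 - q[i]) * pi^gamma * log(1 - pi)
  }
  -s / length(p)
}
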