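# The segmentation network.
#
# Volumes are 3-D arrays with dim = (x, y, z): x/y are the in-plane
# axes (each divisible by 8), z indexes slices (never down-sampled, the
# slice axis is anisotropic in CT).  Internally the network works on
# 5-D tensors (x, y, z, channel, batch).
#
# Encoder: stem conv + three SE-ResNeXt stages, each halving the
# in-plane resolution by stride (2,2) with stride 1 on slices, followed
# by a dilated bridge stage at unchanged resolution.  A top-down
# pathway with 1x1x1 lateral projections yields three pyramid levels
# x1 (1/4 in-plane), x2 and x3 (both 1/8).  Each level is then fused
# across levels by ASFF, refined per level (SLFR) and across levels
# (MLFR), and read out as a full-resolution probability map, with two
# auxiliary deeply supervised heads during training.

asInputTensor <- function(vol) {
  if (isNode(vol)) return(vol)
  d <- dimOf(vol)
  if (length(d) == 3L) dim(vol) <- c(d, 1L, 1L)
  else if (length(d) != 5L) stop("volume must be a 3-D or 5-D array")
  d <- dim(vol)
  if (!all(is.finite(vol))) stop("input volume contains non-finite values")
  if (d[1] %% 8L || d[2] %% 8L)
    stop("in-plane dimensions must be divisible by 8 (got ",
         d[1], " x ", d[2], ")")
  if (d[3] < 1L) stop("need at least one slice")
  agLeaf(vol)
}

buildBackboneModule <- function(ctx, bb) {
  family <- match.arg(bb$family, c("se_resnext", "resnext", "resnet"))
  w <- bb$base_width * c(1L, 2L, 4L, 4L)
  gng <- bb$gn_groups
  stage <- function(name, cin, cout, stride, dil = c(1L, 1L, 1L)) {
    blocks <- lapply(seq_len(bb$blocks), function(i) {
      resBlock(ctx, paste0(name, ".b", i),
               if (i == 1L) cin else cout, cout, bb$cardinality,
               stride = if (i == 1L) stride else c(1L, 1L, 1L),
               dil = dil, se_ratio = bb$se_ratio, gn_groups = gng,
               family = family)
    })
    function(x) Reduce(function(h, blk) blk(h), blocks, x)
  }
  stem <- cgpLayer(ctx, "stem", 1L, w[1], k = c(3L, 3L, 3L), gn_groups = gng)
  l0 <- stage("layer0", w[1], w[1], c(2L, 2L, 1L))
  l1 <- stage("layer1", w[1], w[2], c(2L, 2L, 1L))
  l2 <- stage("layer2", w[2], w[3], c(2L, 2L, 1L))
  dl <- as.integer(bb$dilation)
  l3 <- stage("layer3", w[3], w[4], c(1L, 1L, 1L), dil = c(dl, dl, 1L))
  function(x) {
    f0 <- l0(stem(x))
    f1 <- l1(f0)
    f2 <- l2(f1)
    f3 <- l3(f2)
    list(layer0 = f0, layer1 = f1, layer2 = f2, layer3 = f3)
  }
}

buildPyramidModule <- function(ctx, bb) {
  cp <- bb$pyramid_channels
  w <- bb$base_width * c(1L, 2L, 4L, 4L)
  lat1 <- convLayer(ctx, "lat1", w[2], cp)
  lat2 <- convLayer(ctx, "lat2", w[3], cp)
  lat3 <- convLayer(ctx, "lat3", w[4], cp)
  function(layers) {
    x3 <- lat3(layers$layer3)
    x2 <- ag_add(lat2(layers$layer2), x3)           # same resolution: identity resize
    x1 <- ag_add(lat1(layers$layer1), ag_upsample(x2, f = 2L, mode = "nearest"))
    list(x1 = x1, x2 = x2, x3 = x3)
  }
}

# deterministic, parameter-free resize between pyramid levels (in-plane
# scales 1/4, 1/8, 1/8): trilinear up-sampling coarse->fine, max-pool
# fine->coarse, identity for equal resolutions; slices untouched
resizeNode <- function(x, from, to) {
  scales <- c(4L, 8L, 8L)
  if (scales[from] == scales[to]) return(x)
  f <- scales[to] %/% scales[from]
  if (f > 1L) ag_maxpool(x, f) else ag_upsample(x, scales[from] %/% scales[to],
                                                mode = "linear")
}

buildAsffModule <- function(ctx, bb, level) {
  cp <- bb$pyramid_channels
  hid <- bb$fusion_hidden
  branch <- lapply(1:3, function(m) {
    pre <- cgpLayer(ctx, sprintf("asff%d.w%d", level, m), cp, hid,
                    gn_groups = bb$gn_groups)
    out <- convLayer(ctx, sprintf("asff%d.w%d.logit", level, m), hid, 1L)
    function(y) out(pre(y))
  })
  function(pyr) {
    resized <- lapply(1:3, function(m) resizeNode(pyr[[m]], m, level))
    logits <- ag_concat(lapply(1:3, function(m) branch[[m]](resized[[m]])))
    wmaps <- ag_softmax_ch(logits)
    weights <- lapply(1:3, function(m) ag_slice_ch(wmaps, m))
    fused <- fuseNode(weights, resized)
    list(resized = resized, weights = weights, fused = fused)
  }
}

# Eq.-style per-voxel convex combination, broadcast across channels
fuseNode <- function(weights, resized) {
  acc <- ag_mul(weights[[1]], resized[[1]])
  for (m in 2:3) acc <- ag_add(acc, ag_mul(weights[[m]], resized[[m]]))
  acc
}

buildSlfrModule <- function(ctx, bb, level) {
  cp <- bb$pyramid_channels
  nm <- sprintf("slfr%d", level)
  c1 <- cgpLayer(ctx, paste0(nm, ".c1"), 2L * cp, cp, gn_groups = bb$gn_groups)
  c2 <- cgpLayer(ctx, paste0(nm, ".c2"), cp, cp, k = c(3L, 3L, 3L),
                 gn_groups = bb$gn_groups)
  c3 <- cgpLayer(ctx, paste0(nm, ".c3"), cp, cp, k = c(3L, 3L, 3L),
                 gn_groups = bb$gn_groups)
  att <- cbamLayer(ctx, paste0(nm, ".cbam"), cp, ratio = bb$cbam_ratio,
                   spatial_kernel = bb$cbam_kernel)
  function(x_l, yhat_l) {
    skip <- c1(ag_concat(list(x_l, yhat_l)))
    ag_add(att(c3(c2(skip))), skip)
  }
}

buildMlfrModule <- function(ctx, bb) {
  cp <- bb$pyramid_channels
  c1 <- cgpLayer(ctx, "mlfr.c1", 3L * cp, cp, gn_groups = bb$gn_groups)
  c2 <- cgpLayer(ctx, "mlfr.c2", cp, cp, k = c(3L, 3L, 3L),
                 gn_groups = bb$gn_groups)
  c3 <- cgpLayer(ctx, "mlfr.c3", cp, cp, k = c(3L, 3L, 3L),
                 gn_groups = bb$gn_groups)
  se <- seLayer(ctx, "mlfr.se", cp, {
    r <- bb$se_ratio
    while (cp %% r) r <- r - 1L
    r
  })
  head <- convLayer(ctx, "mlfr.head", cp, 1L)
  function(refined) {
    up <- list(refined[[1]],
               ag_upsample(refined[[2]], 2L, mode = "linear"),
               ag_upsample(refined[[3]], 2L, mode = "linear"))
    trunk <- se(c3(c2(c1(ag_concat(up)))))
    prob <- ag_sigmoid(ag_upsample(head(trunk), 4L, mode = "linear"))
    list(trunk = trunk, prob = prob)
  }
}

#' Build the segmentation model
#'
#' Constructs the full network (encoder pyramid, adaptive spatial
#' feature fusion, single- and multi-level refinement, deeply
#' supervised heads) with freshly initialized parameters.  With
#' `cfg$ablation = "plain_pyramid"` the fusion and refinement stages
#' are dropped and plain prediction heads are attached to the pyramid
#' levels.
#'
#' @param cfg configuration list, see [deskConfig()].
#' @param seed integer seed for parameter initialization; fixed seed
#'   gives bit-identical parameters and therefore bit-identical forward
#'   passes.
#' @return an `IFPNModel` object.
#' @export
#' @examples
#' cfg <- deskConfig()
#' cfg$backbone$base_width <- 8L   # extra small for the example
#' cfg$backbone$pyramid_channels <- 16L
#' m <- ifpnModel(cfg, seed = 1)
#' out <- ifpnForward(m, array(rnorm(16 * 16 * 2), c(16, 16, 2)))
#' range(out$prob)
ifpnModel <- function(cfg = deskConfig(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctx <- newParamCtx()
  bb <- cfg$backbone
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$ctx <- ctx
  m$backbone <- buildBackboneModule(ctx, bb)
  m$pyramid <- buildPyramidModule(ctx, bb)
  plain <- identical(cfg$ablation, "plain_pyramid")
  if (!plain) {
    m$asff <- lapply(1:3, function(l) buildAsffModule(ctx, bb, l))
    m$slfr <- lapply(1:3, function(l) buildSlfrModule(ctx, bb, l))
    m$mlfr <- buildMlfrModule(ctx, bb)
    cp <- bb$pyramid_channels
    h2 <- convLayer(ctx, "head.s2", cp, 1L)
    h3 <- convLayer(ctx, "head.s3", cp, 1L)
    m$head_s2 <- function(refined) {
      at1 <- list(refined[[1]],
                  ag_upsample(refined[[2]], 2L, mode = "linear"),
                  ag_upsample(refined[[3]], 2L, mode = "linear"))
      avg <- ag_scale(ag_add(ag_add(at1[[1]], at1[[2]]), at1[[3]]), 1 / 3)
      ag_sigmoid(ag_upsample(h2(avg), 4L, mode = "linear"))
    }
    m$head_s3 <- function(trunk) {
      ag_sigmoid(ag_upsample(h3(trunk), 4L, mode = "linear"))
    }
  } else {
    cp <- bb$pyramid_channels
    hf <- convLayer(ctx, "plain.head", cp, 1L)
    h2 <- convLayer(ctx, "plain.s2", cp, 1L)
    h3 <- convLayer(ctx, "plain.s3", cp, 1L)
    m$plain_heads <- list(
      f = function(pyr) ag_sigmoid(ag_upsample(hf(pyr$x1), 4L, mode = "linear")),
      s2 = function(pyr) ag_sigmoid(ag_upsample(h2(pyr$x2), 8L, mode = "linear")),
      s3 = function(pyr) ag_sigmoid(ag_upsample(h3(pyr$x3), 8L, mode = "linear"))
    )
  }
  m$forwardNodes <- function(x, training = FALSE) {
    layers <- m$backbone(x)
    pyr <- m$pyramid(layers)
    if (plain) {
      out <- list(layers = layers, pyramid = pyr,
                  prob = m$plain_heads$f(pyr))
      if (training) {
        out$p_s2 <- m$plain_heads$s2(pyr)
        out$p_s3 <- m$plain_heads$s3(pyr)
      }
      return(out)
    }
    fus <- lapply(1:3, function(l) m$asff[[l]](pyr))
    refined <- lapply(1:3, function(l) m$slfr[[l]](pyr[[l]], fus[[l]]$fused))
    ml <- m$mlfr(refined)
    out <- list(layers = layers, pyramid = pyr, fusion = fus,
                refined = refined, trunk = ml$trunk, prob = ml$prob)
    if (training) {
      out$p_s2 <- m$head_s2(refined)
      out$p_s3 <- m$head_s3(ml$trunk)
    }
    out
  }
  class(m) <- c("IFPNModel", "environment")
  m
}

#' @export
print.IFPNModel <- function(x, ...) {
  np <- sum(vapply(x$ctx$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("IFPNModel: %d parameter tensors, %s parameters, family %s%s\n",
              length(x$ctx$params), format(np, big.mark = ","),
              x$cfg$backbone$family,
              if (identical(x$cfg$ablation, "plain_pyramid"))
                " (plain-pyramid ablation)" else ""))
  invisible(x)
}

modelParams <- function(model) model$ctx$params

#' Run the model on a volume
#'
#' @param model an [ifpnModel()] object.
#' @param vol a 3-D volume (x, y, z) with in-plane dims divisible by 8,
#'   or a 5-D tensor (x, y, z, 1, batch).
#' @param training if `TRUE`, also return the two auxiliary deeply
#'   supervised probability maps `p_s2` and `p_s3`; inference returns
#'   the final map only.
#' @return a list with `prob` (the full-resolution probability map, same
#'   grid as the input) and, in training mode, `p_s2` and `p_s3`.
#' @export
ifpnForward <- function(model, vol, training = FALSE) {
  x <- asInputTensor(vol)
  out <- model$forwardNodes(x, training = training)
  res <- list(prob = agValue(out$prob))
  if (training) {
    res$p_s2 <- agValue(out$p_s2)
    res$p_s3 <- agValue(out$p_s3)
  }
  res
}

#' Extract multi-scale encoder features
#'
#' Runs the stem + three strided SE-ResNeXt stages and the dilated
#' bridge.  In-plane resolutions are 1/2, 1/4, 1/8 and 1/8 of the input
#' for layers 0-3; the slice axis is never down-sampled.
#'
#' @inheritParams ifpnForward
#' @return a list of four feature arrays `layer0` .. `layer3`.
#' @export
extractBaseFeatures <- function(model, vol) {
  lapply(model$backbone(asInputTensor(vol)), agValue)
}

#' Merge encoder layers into the feature pyramid
#'
#' Top-down pathway with 1x1x1 lateral projections: each level is the
#' lateral projection of its encoder layer plus the next-higher level,
#' up-sampled in-plane (nearest-neighbour) where resolutions differ and
#' added identically where they coincide (levels 2 and 3 share their
#' resolution because of the dilated bridge).
#'
#' @param model an [ifpnModel()] object.
#' @param layers output of [extractBaseFeatures()].
#' @return a list of three arrays `x1`, `x2`, `x3` with a common channel
#'   count.
#' @export
buildPyramid <- function(model, layers) {
  layers <- lapply(layers, asNode)
  lapply(model$pyramid(layers), agValue)
}

#' Resize a pyramid level to another level's resolution
#'
#' Parameter-free resize used by the fusion stage: trilinear
#' interpolation when going coarse to fine, in-plane max-pooling when
#' going fine to coarse, an identity copy when the two levels share a
#' resolution.  Slices are never resampled.
#'
#' @param x feature array at level `from`.
#' @param from,to source and target level in 1..3 (in-plane scales 1/4,
#'   1/8, 1/8).
#' @return the resized array.
#' @export
resizeToLevel <- function(x, from, to) {
  stopifnot(from %in% 1:3, to %in% 1:3)
  agValue(resizeNode(asNode(x), from, to))
}

#' Per-voxel fusion weights for one target level
#'
#' Each resized level passes through its own small convolutional branch
#' (1x1x1 conv, group norm, PReLU, 1x1x1 logit); the three logit maps
#' are concatenated on the channel axis and softmax-normalized per
#' voxel, so the three weights are in \[0, 1\] and sum to one
#' everywhere.
#'
#' @param model an [ifpnModel()] object (not built with the
#'   plain-pyramid ablation).
#' @param resized list of three feature arrays at the target level's
#'   dimensions, ordered by source level.
#' @param level target level in 1..3.
#' @return a list of three single-channel weight arrays.
#' @export
computeFusionWeights <- function(model, resized, level) {
  if (is.null(model$asff)) stop("model was built without the fusion stage")
  env <- environment(model$asff[[level]])
  branch <- env$branch
  logits <- ag_concat(lapply(1:3, function(m) branch[[m]](asNode(resized[[m]]))))
  wmaps <- ag_softmax_ch(logits)
  lapply(1:3, function(m) agValue(ag_slice_ch(wmaps, m)))
}

#' Adaptive fusion of three resized levels
#'
#' The per-voxel convex combination `sum_m w_m * y_m`, with the
#' single-channel weight maps broadcast across feature channels.  This
#' is parameter-free given the weights.
#'
#' @param weights list of three single-channel weight arrays (per-voxel,
#'   softmax-normalized).
#' @param resized list of three feature arrays at matching dimensions.
#' @return the fused feature array.
#' @export
fuseFeatures <- function(weights, resized) {
  agValue(fuseNode(lapply(weights, asNode), lapply(resized, asNode)))
}

#' Single-level feature refinement
#'
#' Concatenates the pyramid feature with its fused counterpart,
#' projects with a 1x1x1 conv (the residual skip), refines with two
#' 3x3x3 conv/GN/PReLU layers and CBAM attention, and adds the skip.
#'
#' @param model an [ifpnModel()] object.
#' @param level level in 1..3.
#' @param x_l pyramid feature at `level`.
#' @param yhat_l fused feature at `level`.
#' @return refined feature array, same dims and channels as `x_l`.
#' @export
slfrRefine <- function(model, level, x_l, yhat_l) {
  if (is.null(model$slfr)) stop("model was built without the refinement stage")
  agValue(model$slfr[[level]](asNode(x_l), asNode(yhat_l)))
}

#' Multi-level feature refinement and prediction
#'
#' Up-samples the refined level-2 and level-3 features to level-1
#' resolution, concatenates all three, refines (1x1x1 then two 3x3x3
#' conv/GN/PReLU layers), recalibrates channels with an SE block, and
#' reads out a full-resolution probability map through a 1x1x1 head,
#' a 4x in-plane trilinear up-sampling and a sigmoid.
#'
#' @param model an [ifpnModel()] object.
#' @param refined list of three refined feature arrays.
#' @return list with `trunk` (pre-head feature at level-1 dims) and
#'   `prob` (probability map at input resolution).
#' @export
mlfrPredict <- function(model, refined) {
  if (is.null(model$mlfr)) stop("model was built without the refinement stage")
  out <- model$mlfr(lapply(refined, asNode))
  list(trunk = agValue(out$trunk), prob = agValue(out$prob))
}

#' Standalone CBAM attention module
#'
#' Sequential channel-then-spatial attention: a shared two-layer
#' bottleneck over globally average- and max-pooled channel vectors
#' gives a sigmoid channel gate; channel-wise mean and max maps pass
#' through a conv to give a sigmoid spatial gate.  Output is the input
#' modulated by both gates, so its magnitude never exceeds the input's.
#'
#' @param channels number of input channels.
#' @param ratio bottleneck reduction ratio for the channel gate.
#' @param spatial_kernel in-plane kernel size of the spatial-gate conv.
#' @param seed parameter initialization seed.
#' @return a function mapping a feature array (x, y, z, C, N) to its
#'   attended version.
#' @export
#' @examples
#' att <- cbamModule(8, seed = 1)
#' f <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8, 1))
#' g <- att(f)
#' all(abs(g) <= abs(f) + 1e-12)
cbamModule <- function(channels, ratio = 16L, spatial_kernel = 7L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctx <- newParamCtx()
  lay <- cbamLayer(ctx, "cbam", channels, ratio = ratio,
                   spatial_kernel = spatial_kernel)
  function(x) agValue(lay(asNode(x)))
}

#' Standalone squeeze-and-excitation module
#'
#' Global average pool per channel (squeeze), two-layer bottleneck with
#' reduction `ratio` and sigmoid (excitation), per-channel rescale.
#'
#' @param channels number of channels; must be divisible by `ratio`.
#' @param ratio bottleneck reduction ratio.
#' @param seed parameter initialization seed.
#' @return a function mapping a feature array to its recalibrated
#'   version.
#' @export
seModule <- function(channels, ratio = 16L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctx <- newParamCtx()
  lay <- seLayer(ctx, "se", channels, ratio)
  function(x) agValue(lay(asNode(x)))
}
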