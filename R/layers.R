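# Layer constructors.  A "context" environment collects named parameter
# nodes as layers are built; each constructor returns a forward closure.
# Weight init is Kaiming-normal (fan-in), biases and GN shifts zero,
# GN scales one, PReLU slopes 0.25.

newParamCtx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx
}

addParam <- function(ctx, name, value) {
  if (!is.null(ctx$params[[name]])) stop("duplicate parameter name: ", name)
  p <- agParam(value, name)
  ctx$params[[name]] <- p
  p
}

heWeights <- function(k, cin_g, cout, fan_in) {
  array(stats::rnorm(prod(k) * cin_g * cout, 0, sqrt(2 / fan_in)),
        dim = c(k, cin_g, cout))
}

convLayer <- function(ctx, name, cin, cout, k = c(1L, 1L, 1L),
                      stride = c(1L, 1L, 1L), dil = c(1L, 1L, 1L),
                      groups = 1L, bias = TRUE) {
  if (cin %% groups || cout %% groups) stop("channels not divisible by groups")
  cin_g <- cin %/% groups
  fan_in <- prod(k) * cin_g
  w <- addParam(ctx, paste0(name, ".w"), heWeights(k, cin_g, cout, fan_in))
  b <- if (bias) addParam(ctx, paste0(name, ".b"), numeric(cout)) else NULL
  function(x) ag_conv3d(x, w, b, stride = stride, dil = dil, groups = groups)
}

gnLayer <- function(ctx, name, ch, groups = 8L, eps = 1e-5) {
  g <- min(groups, ch)
  while (ch %% g) g <- g - 1L   # largest feasible group count <= requested
  gamma <- addParam(ctx, paste0(name, ".g"), rep(1, ch))
  beta <- addParam(ctx, paste0(name, ".b"), numeric(ch))
  function(x) ag_groupnorm(x, gamma, beta, groups = g, eps = eps)
}

preluLayer <- function(ctx, name, ch, init = 0.25) {
  alpha <- addParam(ctx, paste0(name, ".a"), rep(init, ch))
  function(x) ag_prelu(x, alpha)
}

# conv -> GN -> PReLU
cgpLayer <- function(ctx, name, cin, cout, k = c(1L, 1L, 1L),
                     stride = c(1L, 1L, 1L), dil = c(1L, 1L, 1L),
                     groups = 1L, gn_groups = 8L) {
  cv <- convLayer(ctx, paste0(name, ".conv"), cin, cout, k, stride, dil, groups)
  gn <- gnLayer(ctx, paste0(name, ".gn"), cout, gn_groups)
  pr <- preluLayer(ctx, paste0(name, ".prelu"), cout)
  function(x) pr(gn(cv(x)))
}

# PReLU (not ReLU) in the bottleneck: the excitation path must stay on
# a live gradient path even when the bottleneck is very narrow, where
# dead ReLU units are likely at initialization.
seLayer <- function(ctx, name, ch, ratio) {
  if (ch %% ratio) stop("SE ratio must divide the channel count")
  mid <- ch %/% ratio
  fc1 <- convLayer(ctx, paste0(name, ".fc1"), ch, mid)
  act <- preluLayer(ctx, paste0(name, ".act"), mid)
  fc2 <- convLayer(ctx, paste0(name, ".fc2"), mid, ch)
  function(x) {
    s <- ag_gap(x)                        # squeeze
    e <- ag_sigmoid(fc2(act(fc1(s))))     # excitation, per-channel in (0,1)
    ag_mul(x, e)
  }
}

# CBAM: channel attention (shared bottleneck over avg- and max-pooled
# channel vectors), then spatial attention (conv over channel-wise
# avg/max maps); both gates sigmoid.
cbamLayer <- function(ctx, name, ch, ratio = 16L, spatial_kernel = 7L) {
  r <- ratio
  while (ch %% r) r <- r - 1L
  mid <- max(1L, ch %/% r)
  fc1 <- convLayer(ctx, paste0(name, ".ca.fc1"), ch, mid)
  act <- preluLayer(ctx, paste0(name, ".ca.act"), mid)
  fc2 <- convLayer(ctx, paste0(name, ".ca.fc2"), mid, ch)
  sk <- as.integer(spatial_kernel)
  sconv <- convLayer(ctx, paste0(name, ".sa.conv"), 2L, 1L,
                     k = c(sk, sk, 3L))
  function(x) {
    ca <- ag_sigmoid(ag_add(fc2(act(fc1(ag_gap(x)))),
                            fc2(act(fc1(ag_gmp(x))))))
    x <- ag_mul(x, ca)
    sa <- ag_sigmoid(sconv(ag_concat(list(ag_chmean(x), ag_chmax(x)))))
    ag_mul(x, sa)
  }
}

# SE-ResNeXt bottleneck block: 1x1x1 reduce, grouped 3x3x3 (carries the
# stride/dilation), 1x1x1 expand, optional SE, projection shortcut when
# the shape changes, PReLU on the sum.
resBlock <- function(ctx, name, cin, cout, cardinality, stride = c(1L, 1L, 1L),
                     dil = c(1L, 1L, 1L), se_ratio = 16L, gn_groups = 8L,
                     family = c("se_resnext", "resnext", "resnet")) {
  family <- match.arg(family)
  mid <- max(cout %/% 2L, 1L)
  groups <- if (family == "resnet") 1L else cardinality
  while (mid %% groups) groups <- groups - 1L
  c1 <- cgpLayer(ctx, paste0(name, ".c1"), cin, mid, gn_groups = gn_groups)
  c2 <- cgpLayer(ctx, paste0(name, ".c2"), mid, mid, k = c(3L, 3L, 3L),
                 stride = stride, dil = dil, groups = groups,
                 gn_groups = gn_groups)
  c3 <- convLayer(ctx, paste0(name, ".c3"), mid, cout)
  gn3 <- gnLayer(ctx, paste0(name, ".gn3"), cout, gn_groups)
  se <- if (family == "se_resnext") {
    r <- se_ratio
    while (cout %% r) r <- r - 1L
    seLayer(ctx, paste0(name, ".se"), cout, r)
  } else NULL
  needs_proj <- (cin != cout) || any(stride != 1L)
  proj <- if (needs_proj) {
    pc <- convLayer(ctx, paste0(name, ".proj"), cin, cout, stride = stride,
                    bias = FALSE)
    pg <- gnLayer(ctx, paste0(name, ".projgn"), cout, gn_groups)
    function(x) pg(pc(x))
  } else identity
  act <- preluLayer(ctx, paste0(name, ".out"), cout)
  function(x) {
    h <- gn3(c3(c2(c1(x))))
    if (!is.null(se)) h <- se(h)
    act(ag_add(h, proj(x)))
  }
}
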