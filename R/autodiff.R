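# Reverse-mode automatic differentiation on 5-D tensors.
#
# Tensors are plain R arrays with dim = (X, Y, Z, C, N): X/Y in-plane,
# Z slices (the anisotropic axis), C channels, N batch.  A graph node is
# an environment carrying the forward value, the parent nodes, and a
# closure that maps the node's gradient to its parents' gradients.
# Node ids increase in creation order, so reverse id order is a valid
# topological order for backpropagation.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

agNode <- function(value, parents = list(), bfun = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$bfun <- bfun
  nd$grad <- NULL
  nd$is_param <- FALSE
  nd$requires <- FALSE
  for (p in parents) if (p$requires) { nd$requires <- TRUE; break }
  .ag$id <- .ag$id + 1L
  nd$id <- .ag$id
  class(nd) <- "agNode"
  nd
}

agLeaf <- function(value) agNode(value)

agParam <- function(value, name = "") {
  nd <- agNode(value)
  nd$is_param <- TRUE
  nd$requires <- TRUE
  nd$name <- name
  nd
}

isNode <- function(x) inherits(x, "agNode")
asNode <- function(x) if (isNode(x)) x else agLeaf(x)

#' Extract the numeric value of an autodiff node
#'
#' Plain arrays pass through unchanged, so code can be written once for
#' both tape-tracked and untracked inputs.
#'
#' @param x an autodiff node or a numeric array.
#' @return the underlying numeric value.
#' @keywords internal
agValue <- function(x) if (isNode(x)) x$value else x

zerosLike <- function(v) {
  z <- v
  z[] <- 0
  z
}

# Backpropagate from a scalar-valued node; fills $grad on every
# reachable node (accumulating over multiple uses).
agBackward <- function(out) {
  stopifnot(isNode(out), length(out$value) == 1L)
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(out)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (isTRUE(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  for (nd in nodes) nd$grad <- NULL
  out$grad <- 1
  for (nd in nodes) {
    if (is.null(nd$bfun) || is.null(nd$grad)) next
    gs <- nd$bfun(nd$grad)
    for (i in seq_along(gs)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

dimOf <- function(v) if (is.null(dim(v))) length(v) else dim(v)

# ---- broadcasting helpers (dims equal or 1) --------------------------------

bcExpand <- function(v, to) {
  d <- dimOf(v)
  if (length(d) != length(to)) stop("rank mismatch in broadcast")
  if (all(d == to)) return(v)
  for (ax in seq_along(to)) {
    if (d[ax] == to[ax]) next
    if (d[ax] != 1L) stop("broadcast needs size-1 axis")
    pre <- prod(d[seq_len(ax - 1L)])
    post <- prod(d[-seq_len(ax)])
    m <- matrix(v, nrow = pre)
    m <- m[, rep(seq_len(post), each = to[ax]), drop = FALSE]
    d[ax] <- to[ax]
    v <- array(m, dim = d)
  }
  v
}

# Sum g over the axes on which `to` has size 1, back to shape `to`.
bcReduce <- function(g, to) {
  d <- dimOf(g)
  if (all(d == to)) return(g)
  for (ax in rev(seq_along(to))) {
    dg <- dimOf(g)
    if (to[ax] == dg[ax]) next
    pre <- prod(dg[seq_len(ax - 1L)])
    post <- prod(dg[-seq_len(ax)])
    a3 <- array(g, dim = c(pre, dg[ax], post))
    s <- array(0, dim = c(pre, 1L, post))
    for (j in seq_len(dg[ax])) s <- s + a3[, j, , drop = FALSE]
    dg[ax] <- 1L
    g <- array(s, dim = dg)
  }
  g
}

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_scale <- function(a, k) {
  a <- asNode(a)
  agNode(a$value * k, list(a), function(g) list(g * k))
}

ag_addc <- function(a, k) {
  a <- asNode(a)
  agNode(a$value + k, list(a), function(g) list(g))
}

# broadcasting multiply (each axis: equal sizes or one side 1)
ag_mul <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  da <- dimOf(a$value); db <- dimOf(b$value)
  if (identical(da, db)) {
    av <- a$value; bv <- b$value
    return(agNode(av * bv, list(a, b), function(g) list(g * bv, g * av)))
  }
  to <- pmax(da, db)
  ae <- bcExpand(a$value, to)
  be <- bcExpand(b$value, to)
  agNode(ae * be, list(a, b), function(g) {
    list(bcReduce(g * be, da), bcReduce(g * ae, db))
  })
}

ag_div <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  av <- a$value; bv <- b$value
  agNode(av / bv, list(a, b),
         function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_powc <- function(a, p) {
  a <- asNode(a)
  av <- a$value
  agNode(av^p, list(a), function(g) {
    if (p == 1) list(g) else list(g * p * av^(p - 1))
  })
}

ag_log <- function(a) {
  a <- asNode(a)
  av <- a$value
  agNode(log(av), list(a), function(g) list(g / av))
}

ag_clamp <- function(a, lo, hi) {
  a <- asNode(a)
  av <- a$value
  inside <- (av >= lo) & (av <= hi)
  agNode(pmin(pmax(av, lo), hi), list(a), function(g) list(g * inside))
}

ag_sigmoid <- function(a) {
  a <- asNode(a)
  y <- 1 / (1 + exp(-a$value))
  agNode(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_relu <- function(a) {
  a <- asNode(a)
  pos <- a$value > 0
  agNode(a$value * pos, list(a), function(g) list(g * pos))
}

ag_sum <- function(a) {
  a <- asNode(a)
  d <- dimOf(a$value)
  agNode(sum(a$value), list(a), function(g) list(array(g, dim = d)))
}

ag_mean <- function(a) {
  a <- asNode(a)
  d <- dimOf(a$value)
  n <- length(a$value)
  agNode(mean(a$value), list(a), function(g) list(array(g / n, dim = d)))
}

# ---- shape ops -------------------------------------------------------------

# concatenate along the channel axis (axis 4)
ag_concat <- function(xs) {
  xs <- lapply(xs, asNode)
  ds <- lapply(xs, function(x) dimOf(x$value))
  chans <- vapply(ds, `[`, numeric(1), 4L)
  d0 <- ds[[1]]
  dout <- d0
  dout[4] <- sum(chans)
  S <- prod(d0[1:3])
  N <- d0[5]
  Ctot <- as.integer(sum(chans))
  out <- array(0, dim = dout)
  om <- array(out, dim = c(S, Ctot, N))
  at <- 0L
  for (i in seq_along(xs)) {
    ci <- as.integer(chans[i])
    om[, at + seq_len(ci), ] <- array(xs[[i]]$value, dim = c(S, ci, N))
    at <- at + ci
  }
  offs <- cumsum(c(0L, chans))
  agNode(array(om, dim = dout), xs, function(g) {
    gm <- array(g, dim = c(S, Ctot, N))
    lapply(seq_along(xs), function(i) {
      ci <- as.integer(chans[i])
      array(gm[, offs[i] + seq_len(ci), , drop = FALSE], dim = ds[[i]])
    })
  })
}

# take channel `idx` (1-based), keeping a singleton channel axis
ag_slice_ch <- function(a, idx) {
  a <- asNode(a)
  d <- dimOf(a$value)
  S <- prod(d[1:3]); N <- d[5]
  am <- array(a$value, dim = c(S, d[4], N))
  dout <- d; dout[4] <- 1L
  agNode(array(am[, idx, , drop = FALSE], dim = dout), list(a), function(g) {
    gm <- array(0, dim = c(S, d[4], N))
    gm[, idx, ] <- array(g, dim = c(S, 1L, N))
    list(array(gm, dim = d))
  })
}

# softmax across the channel axis
ag_softmax_ch <- function(a) {
  a <- asNode(a)
  d <- dimOf(a$value)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- array(a$value, dim = c(S, C, N))
  mx <- m[, 1, , drop = FALSE]
  for (j in seq_len(C)[-1]) mx <- pmax(mx, m[, j, , drop = FALSE])
  e <- exp(m - bcExpand(mx, c(S, C, N)))
  tot <- array(0, dim = c(S, 1L, N))
  for (j in seq_len(C)) tot <- tot + e[, j, , drop = FALSE]
  y <- e / bcExpand(tot, c(S, C, N))
  agNode(array(y, dim = d), list(a), function(g) {
    gm <- array(g, dim = c(S, C, N))
    dot <- array(0, dim = c(S, 1L, N))
    for (j in seq_len(C)) dot <- dot + gm[, j, , drop = FALSE] * y[, j, , drop = FALSE]
    gx <- y * (gm - bcExpand(dot, c(S, C, N)))
    list(array(gx, dim = d))
  })
}

# ---- normalization / activations with parameters ---------------------------

# group normalization over (spatial x channels-in-group), per batch item
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- asNode(x); gamma <- asNode(gamma); beta <- asNode(beta)
  d <- dimOf(x$value)
  if (d[4] %% groups) stop("channels not divisible by GN groups")
  y <- gn_fwd_cpp(x$value, gamma$value, beta$value, as.integer(groups), eps)
  agNode(y, list(x, gamma, beta), function(g) {
    if (is.null(dim(g))) dim(g) <- d
    r <- gn_bwd_cpp(x$value, gamma$value, g, as.integer(groups), eps)
    list(r$gx, r$ggamma, r$gbeta)
  })
}

# PReLU with one learnable slope per channel
ag_prelu <- function(x, alpha) {
  x <- asNode(x); alpha <- asNode(alpha)
  d <- dimOf(x$value)
  y <- prelu_fwd_cpp(x$value, alpha$value)
  agNode(y, list(x, alpha), function(g) {
    if (is.null(dim(g))) dim(g) <- d
    r <- prelu_bwd_cpp(x$value, alpha$value, g)
    list(r$gx, r$galpha)
  })
}

# ---- pooling / resampling --------------------------------------------------

ag_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), dil = c(1L, 1L, 1L),
                      pad = NULL, groups = 1L) {
  x <- asNode(x); w <- asNode(w)
  has_b <- !is.null(b)
  if (has_b) b <- asNode(b)
  k <- dimOf(w$value)[1:3]
  if (is.null(pad)) pad <- as.integer(((k - 1) * dil) %/% 2)
  y <- conv3d_fwd_cpp(x$value, w$value,
                      if (has_b) b$value else numeric(0),
                      as.integer(stride), as.integer(dil),
                      as.integer(pad), as.integer(groups))
  parents <- if (has_b) list(x, w, b) else list(x, w)
  agNode(y, parents, function(g) {
    gr <- conv3d_bwd_cpp(x$value, w$value, g, as.integer(stride),
                         as.integer(dil), as.integer(pad),
                         as.integer(groups), has_b, x$requires)
    gx <- if (x$requires) gr$gx else NULL
    if (has_b) list(gx, gr$gw, gr$gb) else list(gx, gr$gw)
  })
}

ag_maxpool <- function(x, k) {
  x <- asNode(x)
  r <- maxpool_inplane_fwd_cpp(x$value, as.integer(k))
  xd <- dimOf(x$value)
  agNode(r$out, list(x), function(g) {
    list(maxpool_inplane_bwd_cpp(g, r$argmax, as.integer(xd)))
  })
}

ag_upsample <- function(x, f, mode = c("nearest", "linear")) {
  mode <- match.arg(mode)
  x <- asNode(x)
  mi <- if (mode == "nearest") 0L else 1L
  xd <- dimOf(x$value)
  y <- upsample_inplane_fwd_cpp(x$value, as.integer(f), mi)
  agNode(y, list(x), function(g) {
    list(upsample_inplane_bwd_cpp(g, as.integer(xd), as.integer(f), mi))
  })
}

# global average pool over spatial axes -> (1,1,1,C,N)
ag_gap <- function(x) {
  x <- asNode(x)
  d <- dimOf(x$value)
  S <- prod(d[1:3])
  m <- colMeans(matrix(x$value, nrow = S))          # length C*N
  dout <- c(1L, 1L, 1L, d[4], d[5])
  agNode(array(m, dim = dout), list(x), function(g) {
    gexp <- rep(as.vector(g) / S, each = S)
    list(array(gexp, dim = d))
  })
}

# global max pool over spatial axes -> (1,1,1,C,N)
ag_gmp <- function(x) {
  x <- asNode(x)
  d <- dimOf(x$value)
  S <- prod(d[1:3])
  m <- matrix(x$value, nrow = S)
  idx <- max.col(t(m), ties.method = "first")       # argmax per column
  mx <- m[cbind(idx, seq_len(ncol(m)))]
  dout <- c(1L, 1L, 1L, d[4], d[5])
  agNode(array(mx, dim = dout), list(x), function(g) {
    gm <- matrix(0, nrow = S, ncol = ncol(m))
    gm[cbind(idx, seq_len(ncol(m)))] <- as.vector(g)
    list(array(gm, dim = d))
  })
}

# mean over the channel axis -> (X,Y,Z,1,N)
ag_chmean <- function(x) {
  x <- asNode(x)
  d <- dimOf(x$value)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  a3 <- array(x$value, dim = c(S, C, N))
  s <- array(0, dim = c(S, 1L, N))
  for (j in seq_len(C)) s <- s + a3[, j, , drop = FALSE]
  dout <- d; dout[4] <- 1L
  agNode(array(s / C, dim = dout), list(x), function(g) {
    ge <- bcExpand(array(g, dim = c(S, 1L, N)), c(S, C, N)) / C
    list(array(ge, dim = d))
  })
}

# max over the channel axis -> (X,Y,Z,1,N)
ag_chmax <- function(x) {
  x <- asNode(x)
  d <- dimOf(x$value)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  a3 <- array(x$value, dim = c(S, C, N))
  best <- a3[, 1, , drop = FALSE]
  arg <- array(1L, dim = c(S, 1L, N))
  for (j in seq_len(C)[-1]) {
    upd <- a3[, j, , drop = FALSE] > best
    best[upd] <- a3[, j, , drop = FALSE][upd]
    arg[upd] <- j
  }
  dout <- d; dout[4] <- 1L
  agNode(array(best, dim = dout), list(x), function(g) {
    gx <- array(0, dim = c(S, C, N))
    gm <- array(g, dim = c(S, 1L, N))
    for (j in seq_len(C)) {
      sel <- arg == j
      slab <- gx[, j, , drop = FALSE]
      slab[sel] <- gm[sel]
      gx[, j, ] <- slab
    }
    list(array(gx, dim = d))
  })
}
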