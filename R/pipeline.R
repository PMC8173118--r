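# Training, inference and run evaluation.

#' Cross-validation folds
#'
#' Seeded shuffle followed by a contiguous partition into `k` folds of
#' near-equal size (differing by at most one case).
#'
#' @param n_cases number of cases.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return a list of `k` elements, each `list(train=, val=)` index
#'   vectors; folds are disjoint and cover `1:n_cases`.
#' @export
makeFolds <- function(n_cases, k = 5L, seed = 1L) {
  if (n_cases < k) stop("need at least as many cases as folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n_cases)
  sizes <- rep(n_cases %/% k, k)
  extra <- n_cases %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = sort(setdiff(seq_len(n_cases), val)), val = val)
  })
}

adamInit <- function(params) {
  lapply(params, function(p) list(m = zerosLike(p$value), v = zerosLike(p$value)))
}

adamStep <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    state[[nm]] <- st
  }
  state
}

# reduce-on-plateau: multiply lr by `factor` after `patience` epochs
# without an improvement of at least `min_delta`
plateauScheduler <- function(lr, patience = 10L, factor = 0.1,
                             min_delta = 1e-4) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$bad <- 0L
  env$lr <- lr
  function(monitored) {
    if (monitored < env$best - min_delta) {
      env$best <- monitored
      env$bad <- 0L
    } else {
      env$bad <- env$bad + 1L
      if (env$bad >= patience) {
        env$lr <- env$lr * factor
        env$bad <- 0L
      }
    }
    env$lr
  }
}

samplePatchCenter <- function(pair, patch_size, tumor_bias) {
  d <- dim(pair@image)
  if (all(d == patch_size)) return(NULL)
  fg <- which(pair@mask == 1, arr.ind = TRUE)
  if (nrow(fg) > 0 && stats::runif(1) < tumor_bias) {
    fg[sample.int(nrow(fg), 1L), ]
  } else {
    vapply(1:3, function(ax) sample.int(d[ax], 1L), numeric(1))
  }
}

batchTensor <- function(pairs, patch_size, tumor_bias) {
  n <- length(pairs)
  xs <- array(0, dim = c(patch_size, 1L, n))
  qs <- array(0, dim = c(patch_size, 1L, n))
  for (i in seq_len(n)) {
    pr <- pairs[[i]]
    if (!all(dim(pr@image) == patch_size)) {
      pr <- extractPatch(pr, patch_size,
                         center = samplePatchCenter(pr, patch_size, tumor_bias))
    }
    xs[, , , 1L, i] <- pr@image
    qs[, , , 1L, i] <- pr@mask
  }
  if (!all(is.finite(xs)))
    stop("non-finite values in training batch")
  list(x = xs, q = qs)
}

#' Train the segmentation model
#'
#' Adam with reduce-on-plateau scheduling on the stage-wise deeply
#' supervised hybrid loss.  One epoch visits every training case once
#' (in a seeded random order), cutting a patch per case when the volume
#' is larger than `patch_size` (tumor-biased centre sampling).  The
#' whole run is driven by `cfg$train$seed`, so a fixed config
#' reproduces the history bit-identically on CPU.
#'
#' @param pairs list of [VolumePair-class] training cases (intensities
#'   already normalized, e.g. by [normalizeIntensity()]).
#' @param cfg configuration, see [deskConfig()].
#' @param val_pairs optional validation cases; when given, validation
#'   loss drives the plateau scheduler and validation Dice selects the
#'   retained best parameters.
#' @param epochs number of epochs; defaults to `cfg$train$epochs`.
#' @param model optionally continue training an existing model.
#' @return a list with `model` (final parameters), `best` (parameter
#'   snapshot with the best monitored Dice), and `history` (one row per
#'   epoch: epoch, lr, train_loss, val_loss, val_dice).
#' @export
trainModel <- function(pairs, cfg = deskConfig(), val_pairs = NULL,
                       epochs = NULL, model = NULL) {
  tr <- cfg$train
  if (is.null(epochs)) epochs <- tr$epochs
  if (is.null(model)) model <- ifpnModel(cfg, seed = tr$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tr$seed + 1L)
  params <- modelParams(model)
  state <- adamInit(params)
  sched <- plateauScheduler(tr$learning_rate, tr$patience, tr$factor,
                            tr$min_delta)
  lr <- tr$learning_rate
  lcfg <- cfg$loss
  ps <- as.integer(tr$patch_size)
  hist <- vector("list", epochs)
  best <- list(dice = -Inf, params = NULL)
  t_adam <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(pairs))
    losses <- c()
    dices <- c()
    for (bs in split(ord, ceiling(seq_along(ord) / tr$batch_size))) {
      b <- batchTensor(pairs[bs], ps, tr$tumor_bias)
      out <- model$forwardNodes(agLeaf(b$x), training = TRUE)
      loss <- sdsLoss(list(p_s2 = out$p_s2, p_s3 = out$p_s3, p_f = out$prob),
                      b$q, lcfg)
      lv <- agValue(loss)
      if (!is.finite(lv))
        stop("non-finite training loss at epoch ", ep,
             " (lr = ", lr, "); aborting")
      agBackward(loss)
      t_adam <- t_adam + 1L
      state <- adamStep(params, state, lr, t_adam)
      losses <- c(losses, lv)
      pm <- agValue(out$prob)
      ov <- overlapMetrics(array(as.numeric(pm >= 0.5), dim = dim(b$q)), b$q)
      dices <- c(dices, ov[["dice_pct"]] / 100)
    }
    train_loss <- mean(losses)
    if (is.null(val_pairs)) {
      # no held-out set: monitor the training batches themselves
      val_loss <- train_loss
      val_dice <- mean(dices)
    } else {
      vl <- c(); vd <- c()
      for (pr in val_pairs) {
        b <- batchTensor(list(pr), ps, 1)
        out <- model$forwardNodes(agLeaf(b$x), training = TRUE)
        l <- agValue(sdsLoss(list(p_s2 = out$p_s2, p_s3 = out$p_s3,
                                  p_f = out$prob), b$q, lcfg))
        pm <- agValue(out$prob)
        ov <- overlapMetrics(array(as.numeric(pm >= 0.5), dim = dim(b$q)), b$q)
        vl <- c(vl, l)
        vd <- c(vd, ov[["dice_pct"]] / 100)
      }
      val_loss <- mean(vl)
      val_dice <- mean(vd)
    }
    if (val_dice > best$dice) {
      best <- list(dice = val_dice,
                   params = lapply(params, function(p) p$value))
    }
    lr <- sched(val_loss)
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, train_loss = train_loss,
                             val_loss = val_loss, val_dice = val_dice)
  }
  list(model = model, best = best, history = do.call(rbind, hist))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is the configuration plus a named list of parameter
#' arrays; loading rebuilds the model and overwrites its parameters,
#' so a save/load round trip predicts bit-identically.
#'
#' @param model an [ifpnModel()] object.
#' @param path file path (RDS).
#' @return `path` invisibly (save); the restored model (load).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg,
               params = lapply(modelParams(model), function(p) p$value)),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- ifpnModel(ck$cfg, seed = 0L)
  params <- modelParams(model)
  stopifnot(identical(sort(names(params)), sort(names(ck$params))))
  for (nm in names(params)) params[[nm]]$value <- ck$params[[nm]]
  model
}

#' Restore the best parameters from a training run
#'
#' @param model an [ifpnModel()] object.
#' @param snapshot the `best$params` element of a [trainModel()] result.
#' @return the model, with parameters replaced, invisibly.
#' @export
restoreParams <- function(model, snapshot) {
  params <- modelParams(model)
  for (nm in names(snapshot)) params[[nm]]$value <- snapshot[[nm]]
  invisible(model)
}

#' Sliding-window inference
#'
#' Tiles the volume with `patch_size` windows at 50% overlap, averages
#' the overlapping probabilities uniformly, and thresholds at 0.5.
#' Volumes smaller than the patch are zero-padded (and the output
#' cropped back).
#'
#' @param model an [ifpnModel()] object (trained).
#' @param vol 3-D volume, normalized as in training.
#' @param patch_size window dims; defaults to the model config's patch
#'   size.
#' @return list with `prob` (probability map, input grid) and `mask`
#'   (binary array).
#' @export
predictVolume <- function(model, vol, patch_size = NULL) {
  if (is.null(patch_size)) patch_size <- model$cfg$train$patch_size
  ps <- as.integer(patch_size)
  d0 <- dim(vol)
  d <- pmax(d0, ps)
  if (!all(d == d0)) {
    padded <- array(0, dim = d)
    padded[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- vol
    vol <- padded
  }
  starts <- function(n, p) {
    if (n == p) return(0L)
    s <- seq(0L, n - p, by = max(1L, p %/% 2L))
    unique(c(s, n - p))
  }
  sx <- starts(d[1], ps[1]); sy <- starts(d[2], ps[2]); sz <- starts(d[3], ps[3])
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    win <- vol[ox + seq_len(ps[1]), oy + seq_len(ps[2]), oz + seq_len(ps[3]),
               drop = FALSE]
    pr <- ifpnForward(model, array(win, dim = ps))$prob
    acc[ox + seq_len(ps[1]), oy + seq_len(ps[2]), oz + seq_len(ps[3])] <-
      acc[ox + seq_len(ps[1]), oy + seq_len(ps[2]), oz + seq_len(ps[3])] +
      array(pr, dim = ps)
    cnt[ox + seq_len(ps[1]), oy + seq_len(ps[2]), oz + seq_len(ps[3])] <-
      cnt[ox + seq_len(ps[1]), oy + seq_len(ps[2]), oz + seq_len(ps[3])] + 1
  }
  prob <- acc / cnt
  prob <- prob[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(prob) <- d0
  list(prob = prob, mask = array(as.numeric(prob >= 0.5), dim = d0))
}

#' Evaluate a directory of predictions against ground truth
#'
#' Matches NIfTI files by name between the two directories, computes
#' the six-metric report per volume, and writes a CSV with one row per
#' volume plus Mean and SD rows.  Unmatched files are skipped with a
#' warning; an empty intersection is an error.
#'
#' @param pred_dir,gt_dir directories of binary-mask NIfTI files.
#' @param out_csv optional output CSV path.
#' @return the report `data.frame`, invisibly if `out_csv` is given.
#' @export
evaluateRun <- function(pred_dir, gt_dir, out_csv = NULL) {
  pf <- list.files(pred_dir, pattern = "\\.nii(\\.gz)?$")
  gf <- list.files(gt_dir, pattern = "\\.nii(\\.gz)?$")
  common <- intersect(pf, gf)
  skipped <- union(setdiff(pf, gf), setdiff(gf, pf))
  if (length(skipped))
    warning("skipping unmatched files: ", paste(skipped, collapse = ", "))
  if (length(common) == 0L)
    stop("no matching prediction/ground-truth files")
  reports <- lapply(common, function(fn) {
    pred <- RNifti::readNifti(file.path(pred_dir, fn))
    gt <- RNifti::readNifti(file.path(gt_dir, fn))
    evaluatePair(array(as.numeric(pred >= 0.5), dim = dim(pred)),
                 array(as.numeric(gt >= 0.5), dim = dim(gt)),
                 id = sub("\\.nii(\\.gz)?$", "", fn))
  })
  tab <- aggregateReports(reports)
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
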