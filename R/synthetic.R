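# Synthetic phantoms and the preprocessing/augmentation pipeline.
#
# The phantoms emulate the awkward properties of abdominal tumor CT:
# a low-contrast ellipsoidal lesion whose boundary is blurred into the
# background, a slowly varying intensity-inhomogeneity field, Gaussian
# noise, and strongly anisotropic voxels (thick slices).  The mask is
# the crisp (unblurred) ellipsoid indicator, so the image boundary is
# genuinely ambiguous relative to the label.

#' Phantom specification
#'
#' Defaults produce a low-contrast lesion: contrast 40 intensity units
#' over a background of 60, noise SD 15 (contrast-to-noise ~2.7),
#' boundary blur 1.5 voxels in-plane, inhomogeneity amplitude 20, and
#' 5x thicker slices than in-plane spacing.
#'
#' @param grid volume dimensions `(x, y, z)`; x and y should be
#'   divisible by 8 for the network.
#' @param semiaxes ellipsoid semi-axes in voxels `(x, y, z)`.
#' @param center ellipsoid centre in voxels; `NULL` places it at the
#'   grid centre, jittered by up to 10% of the grid per axis.
#' @param background,contrast background level and tumor offset
#'   (Hounsfield-like units).
#' @param blur_sigma in-plane Gaussian blur SD (voxels) applied to the
#'   lesion indicator before it enters the image; the slice-axis SD is
#'   `blur_sigma / spacing_ratio`.
#' @param noise_sd additive Gaussian noise SD.
#' @param inhomogeneity amplitude of the low-frequency bias field.
#' @param spacing_ratio slice thickness over in-plane spacing.
#' @param seed RNG seed; phantoms are bit-reproducible given the spec.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(grid = c(64L, 64L, 8L), semiaxes = c(12, 12, 3),
                        center = NULL, background = 60, contrast = 40,
                        blur_sigma = 1.5, noise_sd = 15, inhomogeneity = 20,
                        spacing_ratio = 5, seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 1), length(semiaxes) == 3L,
            all(semiaxes > 0), noise_sd >= 0, blur_sigma >= 0,
            spacing_ratio > 0)
  if (any(2 * semiaxes >= grid))
    stop("ellipsoid does not fit inside the grid")
  structure(list(grid = as.integer(grid), semiaxes = semiaxes,
                 center = center, background = background,
                 contrast = contrast, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, inhomogeneity = inhomogeneity,
                 spacing_ratio = spacing_ratio, seed = as.integer(seed)),
            class = "PhantomSpec")
}

gauss1dKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable blur along one axis with zero padding
blurAxis <- function(vol, sigma, axis) {
  k <- gauss1dKernel(sigma)
  if (length(k) == 1L) return(vol)
  d <- dim(vol)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    A[i, j[ok]] <- k[ok]
  }
  applyAxis(vol, axis, function(m) A %*% m)
}

# apply f (a matrix->matrix map along rows) over one axis of a 3-D array
applyAxis <- function(vol, axis, f) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[axis])
  m2 <- f(m)
  out <- array(m2, dim = c(nrow(m2), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

gaussBlur3d <- function(vol, sigma) {
  for (ax in 1:3) vol <- blurAxis(vol, sigma[ax], ax)
  vol
}

#' Generate a phantom volume/mask pair
#'
#' image = background + bias field + contrast * blurred ellipsoid
#' indicator + Gaussian noise; mask = crisp ellipsoid indicator.
#' Deterministic given the spec (which includes the seed).
#'
#' @param spec a [phantomSpec()].
#' @return a [VolumePair-class]; `spacing` is
#'   `(1, 1, spacing_ratio)` mm and `meta` carries the spec.
#' @export
#' @examples
#' pair <- generatePhantom(phantomSpec(seed = 7))
#' pair
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  d <- spec$grid
  center <- spec$center
  if (is.null(center)) {
    center <- (d + 1) / 2 + stats::runif(3, -0.1, 0.1) * d
  }
  if (any(center - spec$semiaxes < 1) || any(center + spec$semiaxes > d))
    stop("ellipsoid does not fit inside the grid at this centre")
  cx <- seq_len(d[1]); cy <- seq_len(d[2]); cz <- seq_len(d[3])
  ex <- ((cx - center[1]) / spec$semiaxes[1])^2
  ey <- ((cy - center[2]) / spec$semiaxes[2])^2
  ez <- ((cz - center[3]) / spec$semiaxes[3])^2
  q <- outer(outer(ex, ey, `+`), ez, `+`)
  mask <- array(as.numeric(q <= 1), dim = d)

  ind <- mask
  if (spec$blur_sigma > 0) {
    sig <- c(spec$blur_sigma, spec$blur_sigma,
             spec$blur_sigma / spec$spacing_ratio)
    ind <- gaussBlur3d(ind, sig)
  }
  img <- spec$background + spec$contrast * ind
  if (spec$inhomogeneity > 0) {
    # three random low-frequency cosine modes
    bias <- array(0, dim = d)
    for (k in 1:3) {
      f <- stats::runif(3, 0.3, 1.2)           # cycles per extent
      ph <- stats::runif(3, 0, 2 * pi)
      bx <- cos(2 * pi * f[1] * cx / d[1] + ph[1])
      by <- cos(2 * pi * f[2] * cy / d[2] + ph[2])
      bz <- cos(2 * pi * f[3] * cz / d[3] + ph[3])
      bias <- bias + outer(outer(bx, by), bz)
    }
    img <- img + spec$inhomogeneity * bias / 3
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }
  volumePair(img, mask, spacing = c(1, 1, spec$spacing_ratio),
             meta = list(spec = spec))
}

#' Percentile intensity normalization
#'
#' Clips the volume to the 0.5th and 99.5th percentile of its
#' foreground (nonzero) voxels — an automatic level/window — then
#' standardizes to zero mean and unit variance over the clipped volume.
#' A constant (or empty-foreground) volume maps to all zeros.
#'
#' @param vol 3-D numeric array.
#' @param probs clipping percentiles.
#' @return normalized array, same shape.
#' @export
normalizeIntensity <- function(vol, probs = c(0.005, 0.995)) {
  fg <- vol[vol != 0]
  if (length(fg) == 0L) return(array(0, dim = dimOf(vol)))
  lim <- stats::quantile(fg, probs, names = FALSE, type = 7)
  v <- pmin(pmax(vol, lim[1]), lim[2])
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(array(0, dim = dimOf(vol)))
  array((v - mean(v)) / s, dim = dimOf(vol))
}

splineInterpMatrix <- function(n_src, src_pos, tgt_pos, method = "natural") {
  A <- matrix(0, length(tgt_pos), n_src)
  for (i in seq_len(n_src)) {
    e <- numeric(n_src)
    e[i] <- 1
    A[, i] <- if (n_src >= 4)
      stats::splinefun(src_pos, e, method = method)(tgt_pos)
    else
      stats::approxfun(src_pos, e, rule = 2)(tgt_pos)
  }
  A
}

#' Resample a volume (and mask) to a target spacing
#'
#' The image is interpolated with a third-order (cubic) spline,
#' separably per axis; the mask with nearest-neighbour so it stays
#' strictly binary.  The output grid is `round(extent / target)` per
#' axis.
#'
#' @param vol 3-D image array.
#' @param mask optional 3-D binary array on the same grid.
#' @param spacing current voxel spacing `(dx, dy, dz)`.
#' @param target target voxel spacing.
#' @return a list with `image`, `mask` (or `NULL`) and `spacing`.
#' @export
resampleVolume <- function(vol, mask = NULL, spacing, target) {
  if (any(spacing <= 0) || any(target <= 0))
    stop("spacings must be positive")
  d <- dim(vol)
  extent <- d * spacing
  nd <- pmax(1L, as.integer(round(extent / target)))
  img <- vol
  msk <- mask
  for (ax in 1:3) {
    if (nd[ax] == d[ax] && isTRUE(all.equal(spacing[ax], target[ax]))) next
    src <- (seq_len(d[ax]) - 0.5) * spacing[ax]
    tgt <- (seq_len(nd[ax]) - 0.5) * target[ax]
    A <- splineInterpMatrix(d[ax], src, tgt)
    img <- applyAxis(img, ax, function(m) A %*% m)
    if (!is.null(msk)) {
      nn <- vapply(tgt, function(t) which.min(abs(src - t)), integer(1))
      msk <- applyAxis(msk, ax, function(m) m[nn, , drop = FALSE])
    }
  }
  list(image = img, mask = msk, spacing = target)
}

#' Extract a fixed-size patch
#'
#' Crops a `patch_size` window centred on `center`, zero-padding image
#' and mask where the window overruns the volume.
#'
#' @param pair a [VolumePair-class].
#' @param patch_size patch dims `(x, y, z)`; in-plane dims should be
#'   divisible by 8.
#' @param center patch centre in voxels; defaults to the volume centre.
#' @return a [VolumePair-class] of dims `patch_size`.
#' @export
extractPatch <- function(pair, patch_size = c(64L, 64L, 8L), center = NULL) {
  d <- dim(pair@image)
  ps <- as.integer(patch_size)
  if (is.null(center)) center <- (d + 1) / 2
  start <- round(center - ps / 2)
  img <- array(0, dim = ps)
  msk <- array(0, dim = ps)
  src_lo <- pmax(1, start + 1)
  src_hi <- pmin(d, start + ps)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start
    dst_hi <- src_hi - start
    img[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      pair@image[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    msk[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      pair@mask[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  volumePair(img, msk, spacing = pair@spacing,
             meta = c(pair@meta, list(patch_start = start)))
}

rot90InPlane <- function(a, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    a <- aperm(a, c(2, 1, 3))
    a <- a[dim(a)[1]:1, , , drop = FALSE]
  }
  a
}

#' Random flip / rotation / translation augmentation
#'
#' In-plane flips (p = 0.5 per axis), an in-plane rotation by a random
#' multiple of 90 degrees (so masks stay exact), and an integer
#' translation of up to +/- `max_shift` of the grid per axis
#' (zero-filled).  Image and mask receive the identical transform.
#'
#' @param pair a [VolumePair-class].
#' @param seed RNG seed; same seed, same augmentation.
#' @param max_shift maximum translation as a fraction of each dim.
#' @return the augmented [VolumePair-class].
#' @export
augmentPair <- function(pair, seed, max_shift = 0.1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  img <- pair@image
  msk <- pair@mask
  d <- dim(img)
  for (ax in 1:2) {
    if (stats::runif(1) < 0.5) {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- rev(idx[[ax]])
      img <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
      msk <- do.call(`[`, c(list(msk), idx, list(drop = FALSE)))
    }
  }
  if (d[1] == d[2]) {
    k <- sample(0:3, 1)
    img <- rot90InPlane(img, k)
    msk <- rot90InPlane(msk, k)
  }
  shift <- vapply(1:3, function(ax)
    sample(seq(-floor(max_shift * d[ax]), floor(max_shift * d[ax])), 1),
    numeric(1))
  translate <- function(a) {
    out <- array(0, dim = d)
    src_lo <- pmax(1, 1 - shift)
    src_hi <- pmin(d, d - shift)
    dst_lo <- src_lo + shift
    dst_hi <- src_hi + shift
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    out
  }
  volumePair(translate(img), translate(msk), spacing = pair@spacing,
             meta = c(pair@meta, list(augment_seed = seed)))
}

#' Write a volume pair as NIfTI
#'
#' @param pair a [VolumePair-class].
#' @param image_path,mask_path output `.nii`/`.nii.gz` paths; spacing is
#'   recorded in the header.
#' @return `image_path`, invisibly.
#' @export
writePairNifti <- function(pair, image_path, mask_path) {
  img <- RNifti::asNifti(pair@image)
  RNifti::pixdim(img) <- pair@spacing
  msk <- RNifti::asNifti(pair@mask)
  RNifti::pixdim(msk) <- pair@spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(image_path)
}

#' Read a volume pair from NIfTI files
#'
#' @param image_path,mask_path `.nii`/`.nii.gz` paths.
#' @return a [VolumePair-class].
#' @export
readPairNifti <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)
  volumePair(array(as.numeric(img), dim = dim(img)),
             array(as.numeric(msk >= 0.5), dim = dim(msk)),
             spacing = sp[1:3])
}
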