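# Evaluation panel: overlap metrics (Dice, Jaccard index, precision,
# recall, reported in percent) and surface-distance metrics (average
# symmetric surface distance and 95th-percentile Hausdorff distance,
# in voxel units on the isotropic grid).

checkMaskPair <- function(pred, gt) {
  if (!identical(dimOf(pred), dimOf(gt)))
    stop("masks must share one grid")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be strictly binary")
  invisible(NULL)
}

#' Voxel-overlap metrics
#'
#' Counts true/false positives and negatives voxel-wise and reports
#' Dice = 2TP/(2TP+FP+FN), Jaccard index = TP/(TP+FP+FN), precision =
#' TP/(TP+FP) and recall = TP/(TP+FN), each in percent.  When both
#' masks are empty all four are 100 by convention; otherwise a ratio
#' with an empty denominator (e.g. precision of an empty prediction)
#' is 0.
#'
#' @param pred,gt binary masks on the same grid (any shape).
#' @return named numeric vector `c(dice_pct, ji_pct, pre_pct,
#'   recall_pct)`.
#' @export
#' @examples
#' g <- array(0, c(4, 4, 1)); g[1:2, 1:4, 1] <- 1
#' p <- array(0, c(4, 4, 1)); p[1:2, 1:2, 1] <- 1
#' overlapMetrics(p, g)
overlapMetrics <- function(pred, gt) {
  checkMaskPair(pred, gt)
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  if (tp + fp + fn == 0) {  # both empty
    return(c(dice_pct = 100, ji_pct = 100, pre_pct = 100, recall_pct = 100))
  }
  rat <- function(num, den) if (den == 0) 0 else num / den
  c(dice_pct = 100 * rat(2 * tp, 2 * tp + fp + fn),
    ji_pct = 100 * rat(tp, tp + fp + fn),
    pre_pct = 100 * rat(tp, tp + fp),
    recall_pct = 100 * rat(tp, tp + fn))
}

#' Surface voxels of a binary mask
#'
#' Foreground voxels with at least one background voxel in their
#' 6-neighbourhood; the grid boundary counts as background, so a mask
#' touching the border is surface there.
#'
#' @param mask 3-D binary array.
#' @return integer matrix with one row per surface voxel and columns
#'   `x`, `y`, `z` (1-based); zero rows for an empty mask.
#' @export
surfaceVoxels <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3-D array")
  m <- mask == 1
  shift_bg <- function(ax, by) {
    # TRUE where the neighbour in direction (ax, by) is background/border
    out <- array(TRUE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (n < 1) return(out)
    if (by == 1) { idx_dst[[ax]] <- seq_len(n - 1); idx_src[[ax]] <- 2:n }
    else { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- seq_len(n - 1) }
    if (n > 1)
      out <- do.call(`[<-`, c(list(out), idx_dst, list(!do.call(`[`, c(list(m), idx_src)))))
    out
  }
  border <- array(FALSE, d)
  for (ax in 1:3) for (by in c(-1, 1)) border <- border | shift_bg(ax, by)
  surf <- m & border
  coords <- which(surf, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Surface-distance metrics
#'
#' Distances from every surface voxel of one mask to the nearest
#' surface voxel of the other (Euclidean, in voxels; exact distance
#' transform).  The two directed distance sets are pooled; ASD is their
#' mean and 95HD the 95th percentile (linear interpolation).
#'
#' @param pred,gt binary masks on the same 3-D grid.
#' @return named numeric vector `c(asd_vox, hd95_vox)`; both `NA` (with
#'   a warning) if either mask is empty, since a surface distance is
#'   then undefined.
#' @export
surfaceMetrics <- function(pred, gt) {
  checkMaskPair(pred, gt)
  sp <- surfaceVoxels(pred)
  sg <- surfaceVoxels(gt)
  if (nrow(sp) == 0L || nrow(sg) == 0L) {
    warning("surface distances undefined for an empty mask")
    return(c(asd_vox = NA_real_, hd95_vox = NA_real_))
  }
  d <- dim(pred)
  at <- function(coords, field) field[coords]  # matrix-indexed lookup
  dt_g <- edt3d_cpp(asSurfaceField(sg, d), as.integer(d))
  dt_p <- edt3d_cpp(asSurfaceField(sp, d), as.integer(d))
  pooled <- c(at(sp, dt_g), at(sg, dt_p))
  c(asd_vox = mean(pooled),
    hd95_vox = unname(stats::quantile(pooled, 0.95, type = 7)))
}

asSurfaceField <- function(coords, d) {
  f <- array(FALSE, d)
  f[coords] <- TRUE
  f
}

#' Full metric report for one volume pair
#'
#' @param pred,gt binary masks on the same 3-D grid.
#' @param id volume identifier carried into the report.
#' @return a [MetricsReport-class] object with the four overlap metrics
#'   (percent) and the two surface metrics (voxels).
#' @export
#' @examples
#' m <- array(0, c(8, 8, 4)); m[3:6, 3:6, 2:3] <- 1
#' evaluatePair(m, m)
evaluatePair <- function(pred, gt, id = "volume") {
  ov <- overlapMetrics(pred, gt)
  sm <- suppressWarnings(surfaceMetrics(pred, gt))
  methods::new("MetricsReport",
               id = as.character(id),
               dice_pct = unname(ov[["dice_pct"]]),
               ji_pct = unname(ov[["ji_pct"]]),
               pre_pct = unname(ov[["pre_pct"]]),
               recall_pct = unname(ov[["recall_pct"]]),
               asd_vox = unname(sm[["asd_vox"]]),
               hd95_vox = unname(sm[["hd95_vox"]]),
               defined = !anyNA(sm))
}

#' Aggregate per-volume reports into a summary table
#'
#' One row per volume plus `Mean` and `SD` rows (sample standard
#' deviation, n-1 denominator), matching the Mean +/- SD convention of
#' segmentation papers.  Volumes with undefined surface distances
#' (empty masks) contribute `NA` there and are dropped from the
#' surface-metric mean/SD.
#'
#' @param reports a list of [MetricsReport-class] objects.
#' @return a `data.frame` with columns `id`, `dice_pct`, `ji_pct`,
#'   `pre_pct`, `recall_pct`, `asd_vox`, `hd95_vox`.
#' @export
aggregateReports <- function(reports) {
  rows <- do.call(rbind, lapply(reports, as.data.frame))
  num <- rows[, -1, drop = FALSE]
  mean_row <- data.frame(id = "Mean", t(colMeans(num, na.rm = TRUE)))
  sd_row <- data.frame(id = "SD", t(apply(num, 2, stats::sd, na.rm = TRUE)))
  names(mean_row) <- names(rows)
  names(sd_row) <- names(rows)
  rbind(rows, mean_row, sd_row)
}
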