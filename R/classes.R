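# S4 containers for the data objects that travel between modules.

#' Volume/mask pair
#'
#' A grayscale volume with its binary segmentation mask on the same
#' grid, plus the physical voxel spacing `(dx, dy, dz)` in mm (the
#' slice axis z is typically the coarse one in CT) and free-form
#' metadata (e.g. the phantom spec and seed that generated it).
#'
#' @slot image 3-D numeric array (x, y, z).
#' @slot mask 3-D binary array on the same grid.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot meta list of metadata.
#' @export
setClass("VolumePair",
         representation(image = "array", mask = "array",
                        spacing = "numeric", meta = "list"),
         prototype(spacing = c(1, 1, 1), meta = list()))

setValidity("VolumePair", function(object) {
  if (length(dim(object@image)) != 3L) return("image must be 3-D")
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask grids differ")
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  TRUE
})

#' Construct a VolumePair
#'
#' @param image 3-D numeric array.
#' @param mask 3-D binary array on the same grid.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param meta metadata list.
#' @return a [VolumePair-class] object.
#' @export
volumePair <- function(image, mask, spacing = c(1, 1, 1), meta = list()) {
  methods::new("VolumePair", image = image, mask = mask,
               spacing = as.numeric(spacing), meta = meta)
}

#' @describeIn VolumePair-class image accessor
#' @param object,x a `VolumePair`.
#' @export
setGeneric("volumeImage", function(x) standardGeneric("volumeImage"))

#' @rdname VolumePair-class
#' @export
setMethod("volumeImage", "VolumePair", function(x) x@image)

#' @rdname VolumePair-class
#' @export
setGeneric("volumeMask", function(x) standardGeneric("volumeMask"))

#' @rdname VolumePair-class
#' @export
setMethod("volumeMask", "VolumePair", function(x) x@mask)

#' @rdname VolumePair-class
#' @export
setGeneric("volumeSpacing", function(x) standardGeneric("volumeSpacing"))

#' @rdname VolumePair-class
#' @export
setMethod("volumeSpacing", "VolumePair", function(x) x@spacing)

setMethod("show", "VolumePair", function(object) {
  d <- dim(object@image)
  cat(sprintf("VolumePair %d x %d x %d, spacing %s mm, %d foreground voxels\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              sum(object@mask)))
})

#' Per-volume metric report
#'
#' Overlap metrics in percent and surface distances in voxels for one
#' predicted/ground-truth mask pair.  `defined` is FALSE when surface
#' distances are undefined (an empty mask), in which case they are
#' `NA`.
#'
#' @slot id volume identifier.
#' @slot dice_pct,ji_pct,pre_pct,recall_pct overlap metrics in percent.
#' @slot asd_vox,hd95_vox surface distances in voxels.
#' @slot defined logical, surface distances defined.
#' @export
setClass("MetricsReport",
         representation(id = "character", dice_pct = "numeric",
                        ji_pct = "numeric", pre_pct = "numeric",
                        recall_pct = "numeric", asd_vox = "numeric",
                        hd95_vox = "numeric", defined = "logical"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport [%s] Dice %.1f%%  JI %.1f%%  Pre %.1f%%  ",
                     "Recall %.1f%%  ASD %s  95HD %s\n"),
              object@id, object@dice_pct, object@ji_pct, object@pre_pct,
              object@recall_pct,
              if (object@defined) sprintf("%.2f vox", object@asd_vox) else "undef",
              if (object@defined) sprintf("%.2f vox", object@hd95_vox) else "undef"))
})

#' @describeIn MetricsReport-class one-row data.frame, the CSV row format
#' @param x a `MetricsReport`.
#' @param row.names,optional,... ignored, present for generic
#'   consistency.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(id = x@id, dice_pct = x@dice_pct, ji_pct = x@ji_pct,
             pre_pct = x@pre_pct, recall_pct = x@recall_pct,
             asd_vox = x@asd_vox, hd95_vox = x@hd95_vox,
             stringsAsFactors = FALSE)
}
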