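#' Desk-scale configuration
#'
#' A configuration sized so the whole network trains in minutes on a
#' single CPU core: 8 x 64 x 64 patches, base width 16, 32 pyramid
#' channels, one residual block per encoder layer.  All keys can be
#' overridden via [readConfig()] or by editing the returned list.
#'
#' @return a nested list with `backbone`, `loss`, `train` and `ablation`
#'   entries.
#' @seealso [fullConfig()] for the GPU-sized profile.
#' @export
#' @examples
#' cfg <- deskConfig()
#' cfg$backbone$pyramid_channels
deskConfig <- function() {
  list(
    backbone = list(
      family = "se_resnext",
      base_width = 16L,
      blocks = 1L,
      cardinality = 4L,
      se_ratio = 8L,
      pyramid_channels = 32L,
      gn_groups = 8L,
      dilation = 2L,
      fusion_hidden = 8L,
      cbam_ratio = 8L,
      cbam_kernel = 7L
    ),
    loss = lossConfig(),
    train = list(
      batch_size = 2L,
      learning_rate = 0.003,
      epochs = 20L,
      patch_size = c(64L, 64L, 8L),   # (x, y, slices)
      folds = 5L,
      seed = 1L,
      patience = 10L,
      factor = 0.1,
      min_delta = 1e-4,
      tumor_bias = 0.5
    ),
    ablation = "none"
  )
}

#' Full-scale configuration
#'
#' The training profile used for real multi-center CT volumes: 24 x 256
#' x 256 patches, batch size 2, learning rate 0.003, 500 epochs, Adam
#' with reduce-on-plateau.  This profile is GPU-sized; on a CPU use
#' [deskConfig()].
#'
#' @return a nested configuration list, same shape as [deskConfig()].
#' @export
fullConfig <- function() {
  cfg <- deskConfig()
  cfg$backbone$base_width <- 64L
  cfg$backbone$cardinality <- 32L
  cfg$backbone$se_ratio <- 16L
  cfg$backbone$pyramid_channels <- 128L
  cfg$backbone$fusion_hidden <- 16L
  cfg$backbone$cbam_ratio <- 16L
  cfg$train$patch_size <- c(256L, 256L, 24L)
  cfg$train$epochs <- 500L
  cfg
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a training configuration from a YAML file
#'
#' Keys present in the file override the desk-scale defaults; anything
#' omitted keeps its default, so a config file only needs the keys that
#' differ.
#'
#' @param path path to a YAML file.
#' @param base default configuration to merge into.
#' @return a configuration list.
#' @export
readConfig <- function(path, base = deskConfig()) {
  mergeConfig(base, yaml::read_yaml(path))
}

#' Write a configuration to a YAML file
#'
#' @param cfg a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
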