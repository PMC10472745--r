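# Synthetic ex vivo fluorescence image stacks with known artifact, tissue
# and hyperfluorescent-blob masks.

#' Configuration for a synthetic ex vivo stack
#'
#' Emulates a stack of aligned ex vivo pCLE frames from one biopsy specimen:
#' acquisition-artifact pixels are constant across frames (temporal SD 0),
#' tissue pixels are i.i.d. Gaussian per frame, and hyperfluorescent blobs
#' (drug binding) are brighter discs whose locations are fixed across the
#' stack while their intensities fluctuate like tissue.
#'
#' @param n_images number of frames (>= 2; per-pixel SD is undefined below 2).
#' @param image_size integer (H, W) in pixels.
#' @param artifact_fraction fraction of pixels that are constant artifacts.
#' @param tissue_mean,tissue_sd Gaussian tissue intensity parameters
#'   (intensities live in \[0, 1\]; `tissue_sd` > 0).
#' @param blob_fraction target fraction of pixels covered by blobs.
#' @param blob_mean mean blob intensity.
#' @param blob_radius blob disc radius in pixels.
#' @param seed integer seed.
#' @return object of class `stack_config`.
#' @export
stack_config <- function(n_images = 10L, image_size = c(64L, 64L),
                         artifact_fraction = 0.05, tissue_mean = 0.3,
                         tissue_sd = 0.05, blob_fraction = 0,
                         blob_mean = 0.6, blob_radius = 4L, seed = 1L) {
  stopifnot(n_images >= 2L, length(image_size) == 2L, all(image_size > 0),
            artifact_fraction >= 0, blob_fraction >= 0,
            artifact_fraction + blob_fraction <= 1,
            tissue_sd > 0, blob_radius >= 1)
  structure(as.list(environment()), class = "stack_config")
}

#' Generate a synthetic ex vivo stack with truth masks
#'
#' @param config a [stack_config()].
#' @return list with `stack` (an [exvivo_stack()]) and `truth`: logical
#'   `artifact`, `blob` and `tissue` masks (H x W).
#' @export
generate_exvivo_stack <- function(config) {
  stopifnot(inherits(config, "stack_config"))
  withr::with_seed(config$seed, {
    h <- config$image_size[1L]; w <- config$image_size[2L]
    npix <- h * w
    artifact <- matrix(FALSE, h, w)
    n_art <- round(config$artifact_fraction * npix)
    if (n_art > 0) artifact[sample.int(npix, n_art)] <- TRUE

    blob <- matrix(FALSE, h, w)
    target_blob <- round(config$blob_fraction * npix)
    guard <- 0L
    while (sum(blob & !artifact) < target_blob && guard < 10000L) {
      guard <- guard + 1L
      bc <- c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1))
      cols <- matrix(rep(0:(w - 1L), each = h), h, w)
      rows <- matrix(rep(0:(h - 1L), w), h, w)
      blob <- blob | ((cols - bc[1L])^2 + (rows - bc[2L])^2 <= config$blob_radius^2)
    }
    blob <- blob & !artifact
    tissue <- !artifact & !blob

    art_values <- matrix(stats::runif(npix, 0.1, 0.9), h, w)
    images <- lapply(seq_len(config$n_images), function(k) {
      img <- matrix(stats::rnorm(npix, config$tissue_mean, config$tissue_sd), h, w)
      img[blob] <- stats::rnorm(sum(blob), config$blob_mean, config$tissue_sd)
      img[artifact] <- art_values[artifact]
      pmin(pmax(img, 0), 1)
    })
    list(stack = exvivo_stack(images, specimen_id = sprintf("synthetic-seed%d", config$seed)),
         truth = list(artifact = artifact, blob = blob, tissue = tissue))
  })
}
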