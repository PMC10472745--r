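# Ex vivo fluorescent drug-binding quantification: temporal-variance
# artifact masking, dual mu/sigma intensity thresholds, and per-image /
# per-specimen hyperfluorescent area and intensity readouts.
#
# Pipeline per specimen: (1) discard every pixel whose intensity SD across
# the stacked frames falls below theta_sigma (near-constant pixels are
# acquisition artifacts); (2) pool the remaining pixels of all frames and
# estimate mu_fluo and sigma_fluo; (3) threshold each frame at the
# conservative cut theta_con = mu + 2*sigma and the relaxed cut
# theta_rel = mu, reading out area and mean intensity above each.

#' Ex vivo image stack container
#'
#' @param images list of >= 2 same-size numeric matrices with intensities
#'   normalized to \[0, 1\].
#' @param specimen_id identifier.
#' @param drug one of `"infliximab"`, `"vedolizumab"`, `"isotype"`, or `NA`.
#' @return object of class `exvivo_stack`.
#' @export
exvivo_stack <- function(images, specimen_id = "specimen", drug = NA_character_) {
  stopifnot(is.list(images))
  if (length(images) < 2L) stop("stack needs >= 2 images (per-pixel SD undefined)")
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all images in a stack must have the same shape")
  }
  rng <- range(unlist(lapply(images, range)))
  if (rng[1L] < 0 || rng[2L] > 1) {
    stop("stack intensities must be normalized to [0, 1]")
  }
  if (!is.na(drug) && !drug %in% c("infliximab", "vedolizumab", "isotype")) {
    stop("unknown drug label: ", drug)
  }
  structure(list(images = images, specimen_id = specimen_id, drug = drug),
            class = "exvivo_stack")
}

#' Load an ex vivo stack from a multi-page TIFF, normalizing to \[0, 1\]
#'
#' @param path multi-page TIFF file.
#' @param specimen_id,drug metadata passed to [exvivo_stack()].
#' @export
read_exvivo_stack <- function(path, specimen_id = basename(path),
                              drug = NA_character_) {
  exvivo_stack(read_stack(path), specimen_id = specimen_id, drug = drug)
}

#' Temporal-variance artifact mask
#'
#' Marks as discarded every pixel whose intensity SD across the stack's
#' frames is smaller than `theta_sigma`: near-zero temporal variation
#' indicates an acquisition artifact rather than tissue. The SD is the
#' sample SD (N-1 denominator).
#'
#' @param stack an [exvivo_stack()].
#' @param theta_sigma SD threshold (default 0.01 on the \[0, 1\] scale).
#' @return logical H x W matrix, `TRUE` = discarded (artifact).
#' @export
artifact_mask <- function(stack, theta_sigma = 0.01) {
  stopifnot(inherits(stack, "exvivo_stack"))
  n <- length(stack$images)
  s1 <- Reduce(`+`, stack$images)
  s2 <- Reduce(`+`, lapply(stack$images, function(m) m^2))
  v <- pmax((s2 - s1^2 / n) / (n - 1), 0)  # pmax first arg keeps the dim
  sqrt(v) < theta_sigma
}

#' Estimate the dual intensity thresholds for a specimen
#'
#' Pools the retained (non-artifact) pixels of all the specimen's frames,
#' estimates their mean `mu_fluo` and sample SD `sigma_fluo`, and derives
#' the conservative threshold `theta_con = mu + 2*sigma` (fewer pixels
#' selected) and the relaxed threshold `theta_rel = mu`.
#'
#' @param stack an [exvivo_stack()].
#' @param mask logical discard mask from [artifact_mask()].
#' @param theta_sigma recorded alongside the estimates.
#' @return object of class `exvivo_thresholds` with fields `theta_sigma`,
#'   `mu_fluo`, `sigma_fluo`, `theta_con`, `theta_rel`.
#' @export
estimate_thresholds <- function(stack, mask, theta_sigma = 0.01) {
  stopifnot(inherits(stack, "exvivo_stack"), is.logical(mask))
  keep <- !mask
  if (!any(keep)) stop("no analyzable tissue: all pixels discarded as artifact")
  vals <- unlist(lapply(stack$images, function(m) m[keep]))
  mu <- mean(vals)
  sdv <- if (length(vals) > 1L) stats::sd(vals) else 0
  structure(list(theta_sigma = theta_sigma, mu_fluo = mu, sigma_fluo = sdv,
                 theta_con = mu + 2 * sdv, theta_rel = mu),
            class = "exvivo_thresholds")
}

#' @export
print.exvivo_thresholds <- function(x, ...) {
  cat(sprintf("<exvivo_thresholds mu=%.4f sd=%.4f con=%.4f rel=%.4f>\n",
              x$mu_fluo, x$sigma_fluo, x$theta_con, x$theta_rel))
  invisible(x)
}

#' Quantify one image against the specimen thresholds
#'
#' Selection is strict (`> threshold`); ties at the threshold are excluded.
#' "Area" is reported both as retained-pixel count and as a fraction of
#' retained pixels. When no pixel exceeds a threshold the area is 0 and the
#' mean-above is missing (`NA`), never 0.
#'
#' @param image numeric matrix from the thresholds' stack.
#' @param thresholds an `exvivo_thresholds`.
#' @param mask logical discard mask.
#' @return one-row data frame: `area_con`, `frac_con`, `intensity_con`,
#'   `area_rel`, `frac_rel`, `intensity_rel`, `mean_intensity` (whole-image
#'   mean over retained pixels).
#' @export
quantify_image <- function(image, thresholds, mask) {
  stopifnot(inherits(thresholds, "exvivo_thresholds"))
  keep <- !mask
  vals <- image[keep]
  n_keep <- length(vals)
  if (!n_keep) stop("no retained pixels in image")
  one <- function(th) {
    sel <- vals > th
    list(area = sum(sel),
         frac = sum(sel) / n_keep,
         intensity = if (any(sel)) mean(vals[sel]) else NA_real_)
  }
  con <- one(thresholds$theta_con)
  rel <- one(thresholds$theta_rel)
  data.frame(area_con = con$area, frac_con = con$frac, intensity_con = con$intensity,
             area_rel = rel$area, frac_rel = rel$frac, intensity_rel = rel$intensity,
             mean_intensity = mean(vals))
}

#' Run the full ex vivo quantification for one specimen stack
#'
#' @param stack an [exvivo_stack()].
#' @param theta_sigma temporal SD artifact threshold (default 0.01).
#' @return list with `thresholds`, `mask`, `per_image` (data frame, one row
#'   per frame) and `specimen` (the [aggregate_specimen()] summary).
#' @export
quantify_stack <- function(stack, theta_sigma = 0.01) {
  mask <- artifact_mask(stack, theta_sigma)
  th <- estimate_thresholds(stack, mask, theta_sigma)
  per_image <- do.call(rbind, lapply(stack$images, quantify_image,
                                     thresholds = th, mask = mask))
  per_image <- cbind(specimen_id = stack$specimen_id,
                     image = seq_len(nrow(per_image)), per_image)
  list(thresholds = th, mask = mask, per_image = per_image,
       specimen = aggregate_specimen(per_image))
}

#' Aggregate per-image readouts to the specimen summary
#'
#' Mean and max across the specimen's images of: hyperfluorescent area and
#' mean intensity above the conservative ("high") and relaxed ("low")
#' thresholds, plus the whole-image mean intensity.
#'
#' @param per_image data frame from [quantify_stack()] (or rbind of
#'   [quantify_image()] rows with a `specimen_id` column).
#' @return one-row data frame of `mean_`/`max_` summaries.
#' @export
aggregate_specimen <- function(per_image) {
  stopifnot(nrow(per_image) >= 1L)
  if ("specimen_id" %in% names(per_image) &&
      length(unique(per_image$specimen_id)) > 1L) {
    stop("per-image rows mix specimens")
  }
  cols <- c("frac_con", "intensity_con", "frac_rel", "intensity_rel", "mean_intensity")
  out <- list(specimen_id = if ("specimen_id" %in% names(per_image))
    per_image$specimen_id[1L] else NA_character_,
    n_images = nrow(per_image))
  for (cl in cols) {
    v <- per_image[[cl]]
    v <- v[!is.na(v)]
    out[[paste0("mean_", cl)]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0("max_", cl)]] <- if (length(v)) max(v) else NA_real_
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
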