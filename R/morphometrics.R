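# In vivo pCLE morphometry: vessel tortuosity, crypt shape, wall thickness,
# intercrypt distance, and pericryptic fluorescein leakage (FLCM), plus
# per-patient aggregation.

#' Vessel tortuosity (arc-chord ratio)
#'
#' The standard distance-factor tortuosity index: total centerline arc length
#' divided by the straight-line distance between its endpoints. 1 for a
#' straight vessel, increasing with winding; invariant to rigid motion and
#' uniform scaling, hence also to pixel size.
#'
#' @param centerline n x 2 matrix (n >= 2) of centerline coordinates.
#' @return dimensionless ratio >= 1.
#' @export
vessel_tortuosity <- function(centerline) {
  if (inherits(centerline, "vessel_annotation")) centerline <- centerline$centerline
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 vertices")
  chord <- sqrt(sum((centerline[nrow(centerline), ] - centerline[1L, ])^2))
  if (chord < 1e-9) stop("tortuosity undefined for closed curve")
  polyline_length(centerline) / chord
}

#' Crypt shape descriptors: area, eccentricity, equivalent diameter
#'
#' Area by the shoelace formula scaled to um^2; eccentricity from the
#' polygon's second central moments (best-fit ellipse-of-inertia,
#' e = sqrt(1 - (b/a)^2)); diameter as the equivalent circular diameter
#' 2*sqrt(area/pi).
#'
#' @param outer simple closed polygon (n x 2, pixel coordinates) or a
#'   [crypt_annotation()].
#' @param pixel_size micrometres per pixel.
#' @param diameter_method `"equivalent"` (default; unambiguous for
#'   non-elliptical outlines) or `"feret"` (maximum vertex-to-vertex
#'   caliper distance).
#' @return named numeric: `area` (um^2), `eccentricity`, `diameter` (um).
#' @export
crypt_shape <- function(outer, pixel_size = 1,
                        diameter_method = c("equivalent", "feret")) {
  diameter_method <- match.arg(diameter_method)
  if (inherits(outer, "crypt_annotation")) outer <- outer$outer
  outer <- as_polygon(outer)
  a_px <- polygon_area(outer)
  if (a_px <= 0) stop("degenerate (zero-area) crypt polygon")
  area <- a_px * pixel_size^2
  diam <- if (diameter_method == "equivalent") 2 * sqrt(area / pi)
  else max(stats::dist(outer)) * pixel_size
  c(area = area,
    eccentricity = polygon_eccentricity(outer),
    diameter = diam)
}

#' Crypt wall thickness by radial rays
#'
#' Mean, over `n_rays` equally spaced directions from the shared centroid,
#' of the distance from the inner (lumen) boundary crossing to the outer
#' boundary crossing. Rays that fail to cross both boundaries are excluded
#' with a warning.
#'
#' @param outer,inner closed polygons (pixel coordinates), inner strictly
#'   inside outer; or a [crypt_annotation()] as `outer` with `inner` missing.
#' @param pixel_size micrometres per pixel.
#' @param n_rays number of rays (default 72).
#' @return mean wall thickness in um, or `NA` when no inner outline exists.
#' @export
wall_thickness <- function(outer, inner = NULL, pixel_size = 1, n_rays = 72L) {
  if (inherits(outer, "crypt_annotation")) {
    inner <- outer$inner
    outer <- outer$outer
  }
  if (is.null(inner)) return(NA_real_)
  outer <- as_polygon(outer); inner <- as_polygon(inner)
  cen <- polygon_centroid(outer)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  gaps <- vapply(ang, function(th) {
    dir <- c(cos(th), sin(th))
    t_out <- ray_polygon_distance(cen, dir, outer)
    t_in <- ray_polygon_distance(cen, dir, inner)
    if (is.na(t_out) || is.na(t_in)) return(NA_real_)
    t_out - t_in
  }, numeric(1L))
  if (anyNA(gaps)) {
    warning(sprintf("%d of %d rays had no boundary crossing; excluded",
                    sum(is.na(gaps)), n_rays))
    gaps <- gaps[!is.na(gaps)]
    if (!length(gaps)) stop("no ray crossed both boundaries")
  }
  mean(gaps) * pixel_size
}

#' Intercrypt distance (nearest-neighbour boundary gap)
#'
#' For each crypt, the minimum over all other crypts of the minimum
#' boundary-to-boundary distance, i.e. the stromal gap to the nearest
#' neighbouring crypt (0 when outlines touch). Outlines are treated as
#' densely sampled, so the gap is the minimum vertex-to-vertex distance.
#'
#' @param crypts list of [crypt_annotation()] objects or of outer polygons.
#' @param pixel_size micrometres per pixel.
#' @param mode `"boundary"` (default; stromal gap between outlines) or
#'   `"center"` (centroid-to-centroid distance).
#' @return numeric vector of per-crypt ICD in um, or `NULL` (feature
#'   missing) when fewer than 2 crypts are present.
#' @export
intercrypt_distance <- function(crypts, pixel_size = 1,
                                mode = c("boundary", "center")) {
  mode <- match.arg(mode)
  polys <- lapply(crypts, function(cr) {
    if (inherits(cr, "crypt_annotation")) cr$outer else as_polygon(cr)
  })
  n <- length(polys)
  if (n < 2L) return(NULL)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (mode == "boundary") {
        min_vertex_distance(polys[[i]], polys[[j]])
      } else {
        sqrt(sum((polygon_centroid(polys[[i]]) - polygon_centroid(polys[[j]]))^2))
      }
    }
  }
  apply(d, 1L, min) * pixel_size
}

#' Pericryptic and background fluorescein leakage (FLCM)
#'
#' Quantifies fluorescein leakage through the colonic mucosa as mean
#' intensity in a pericryptic annulus of width `annulus_width` around each
#' crypt's outer boundary (excluding pixels inside any crypt), and as the
#' mean intensity "elsewhere": outside every crypt and every annulus.
#'
#' @param scene a [mosaic_scene()] with an intensity image.
#' @param annulus_width annulus width in um (default 10).
#' @return list with `pericrypt` (named per-crypt mean intensities) and
#'   `elsewhere` (scalar mean, `NA` with a warning when the annuli cover the
#'   whole non-crypt area).
#' @export
flcm <- function(scene, annulus_width = 10) {
  stopifnot(inherits(scene, "mosaic_scene"), annulus_width > 0)
  if (is.null(scene$image)) stop("scene has no intensity image")
  img <- scene$image
  dim_hw <- dim(img)
  masks <- pericrypt_masks(scene$crypts, dim_hw, annulus_width, scene$pixel_size)
  peri <- vapply(seq_along(scene$crypts), function(i) {
    m <- masks$annuli[[i]]
    if (!any(m)) NA_real_ else mean(img[m])
  }, numeric(1L))
  names(peri) <- vapply(scene$crypts, function(cr) cr$crypt_id, character(1L))
  outside <- !masks$any_crypt & !masks$any_annulus
  if (!any(outside)) {
    warning("pericryptic annuli cover the entire non-crypt area; 'elsewhere' missing")
    elsewhere <- NA_real_
  } else {
    elsewhere <- mean(img[outside])
  }
  list(pericrypt = peri, elsewhere = elsewhere)
}

# Shared rasterization of crypt interiors and pericryptic annuli.
# Returns per-crypt annulus masks (dilation of the outer outline by the
# annulus width, minus the union of all crypt interiors) plus union masks.
pericrypt_masks <- function(crypts, dim_hw, annulus_width, pixel_size) {
  radius_px <- max(1L, round(annulus_width / pixel_size))
  crypt_masks <- lapply(crypts, function(cr) polygon_mask(cr$outer, dim_hw))
  any_crypt <- Reduce(`|`, crypt_masks, matrix(FALSE, dim_hw[1L], dim_hw[2L]))
  annuli <- lapply(crypt_masks, function(m) dilate_mask(m, radius_px) & !any_crypt)
  any_annulus <- Reduce(`|`, annuli, matrix(FALSE, dim_hw[1L], dim_hw[2L]))
  list(crypt_masks = crypt_masks, annuli = annuli,
       any_crypt = any_crypt, any_annulus = any_annulus)
}

#' Measure the full morphometric panel for one scene
#'
#' @param scene a [mosaic_scene()].
#' @param annulus_width FLCM annulus width in um.
#' @param n_rays rays for wall thickness.
#' @return a `morphometric_record`: list with `mosaic_id`, per-vessel
#'   `tortuosity`, per-crypt `area`, `eccentricity`, `diameter`,
#'   `wall_thickness`, `icd` (all um-scaled) and `flcm_pericrypt` /
#'   `flcm_elsewhere` (intensity units; `NULL` when the scene has no image).
#' @export
measure_scene <- function(scene, annulus_width = 10, n_rays = 72L) {
  stopifnot(inherits(scene, "mosaic_scene"))
  ps <- scene$pixel_size
  tort <- vapply(scene$vessels, vessel_tortuosity, numeric(1L))
  shapes <- lapply(scene$crypts, crypt_shape, pixel_size = ps)
  wt <- vapply(scene$crypts, function(cr) {
    wall_thickness(cr, pixel_size = ps, n_rays = n_rays)
  }, numeric(1L))
  icd <- intercrypt_distance(scene$crypts, pixel_size = ps)
  fl <- if (!is.null(scene$image) && length(scene$crypts)) {
    flcm(scene, annulus_width = annulus_width)
  } else list(pericrypt = NULL, elsewhere = NULL)
  structure(list(
    mosaic_id = scene$mosaic_id,
    patient_id = scene$patient_id,
    timepoint = scene$timepoint,
    tortuosity = tort,
    area = vapply(shapes, `[[`, numeric(1L), "area"),
    eccentricity = vapply(shapes, `[[`, numeric(1L), "eccentricity"),
    diameter = vapply(shapes, `[[`, numeric(1L), "diameter"),
    wall_thickness = wt,
    icd = icd,
    flcm_pericrypt = fl$pericrypt,
    flcm_elsewhere = fl$elsewhere
  ), class = "morphometric_record")
}

#' Aggregate per-mosaic morphometric records to one patient feature row
#'
#' Pools the per-structure values across all the patient's mosaics at one
#' timepoint and takes the summary each feature is reported with:
#' mean vessel tortuosity, maximal crypt area, mean crypt eccentricity,
#' maximal crypt diameter, mean ICD, mean WT, maximal pericryptic FLCM and
#' mean FLCM elsewhere. Features with no measured structures are `NA`
#' (missing), never zero.
#'
#' @param records list of records from [measure_scene()], all belonging to
#'   one patient-timepoint.
#' @param pooling `"structures"` (default) pools individual structures
#'   across mosaics before summarizing, which is robust to mosaics with few
#'   structures; `"mosaic_means"` first averages within each mosaic and
#'   then summarizes the per-mosaic values.
#' @return one-row data frame with columns `patient_id`, `timepoint`,
#'   `mean_vessel_tortuosity`, `max_crypt_area`, `mean_crypt_eccentricity`,
#'   `max_crypt_diameter`, `mean_icd`, `mean_wt`, `max_flcm_pericrypt`,
#'   `mean_flcm_elsewhere`.
#' @export
aggregate_patient <- function(records, pooling = c("structures", "mosaic_means")) {
  pooling <- match.arg(pooling)
  stopifnot(length(records) >= 1L)
  pids <- unique(vapply(records, `[[`, character(1L), "patient_id"))
  tps <- unique(vapply(records, `[[`, character(1L), "timepoint"))
  if (length(pids) > 1L || length(tps) > 1L) {
    stop("records mix patients or timepoints: ",
         paste(pids, collapse = ","), " / ", paste(tps, collapse = ","))
  }
  pool <- function(field) {
    if (pooling == "structures") {
      v <- unlist(lapply(records, `[[`, field))
    } else {
      v <- vapply(records, function(r) {
        x <- r[[field]]
        if (length(x) && any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
      }, numeric(1L))
    }
    v[!is.na(v)]
  }
  agg <- function(v, f) if (length(v)) f(v) else NA_real_
  data.frame(
    patient_id = pids, timepoint = tps,
    mean_vessel_tortuosity = agg(pool("tortuosity"), mean),
    max_crypt_area = agg(pool("area"), max),
    mean_crypt_eccentricity = agg(pool("eccentricity"), mean),
    max_crypt_diameter = agg(pool("diameter"), max),
    mean_icd = agg(pool("icd"), mean),
    mean_wt = agg(pool("wall_thickness"), mean),
    max_flcm_pericrypt = agg(pool("flcm_pericrypt"), max),
    mean_flcm_elsewhere = agg(pool("flcm_elsewhere"), mean),
    stringsAsFactors = FALSE)
}
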