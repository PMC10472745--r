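# Data model for annotated pCLE mosaics: scenes, crypt/vessel annotations,
# and clinical score tables.
#
# Coordinate convention (also written into every annotation file):
# 0-based pixel coordinates, origin at the top-left pixel center,
# x = column, y = row. All geometry is stored and processed in pixel
# units; conversion to micrometres happens exactly once, at measurement
# time, through `pixel_size` (um/px).

#' Crypt annotation
#'
#' A crypt is outlined by a closed outer polygon and, when the lumen is
#' visible, an inner polygon strictly inside the outer one. The inner
#' outline is required for wall-thickness measurement; crypts without it
#' simply yield a missing wall thickness.
#'
#' @param outer n x 2 numeric matrix of (x, y) pixel coordinates.
#' @param inner optional n x 2 matrix (lumen outline), or `NULL`.
#' @param crypt_id identifier string.
#' @return object of class `crypt_annotation`.
#' @export
crypt_annotation <- function(outer, inner = NULL, crypt_id = "crypt") {
  outer <- as_polygon(outer)
  outer <- orient_ccw(outer)
  if (polygon_self_intersects(outer)) {
    stop(sprintf("crypt '%s': outer polygon is self-intersecting", crypt_id))
  }
  if (!is.null(inner)) {
    inner <- orient_ccw(as_polygon(inner))
    if (polygon_self_intersects(inner)) {
      stop(sprintf("crypt '%s': inner polygon is self-intersecting", crypt_id))
    }
    if (!all(points_in_polygon(inner, outer))) {
      stop(sprintf("crypt '%s': inner outline not strictly inside outer", crypt_id))
    }
  }
  structure(list(outer = outer, inner = inner, crypt_id = as.character(crypt_id)),
            class = "crypt_annotation")
}

#' Vessel annotation
#'
#' @param centerline n x 2 numeric matrix (n >= 2) of (x, y) pixel
#'   coordinates along the vessel centerline.
#' @param vessel_id identifier string.
#' @return object of class `vessel_annotation`.
#' @export
vessel_annotation <- function(centerline, vessel_id = "vessel") {
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "double"
  if (ncol(centerline) != 2L || nrow(centerline) < 2L) {
    stop("centerline must be an n x 2 matrix with n >= 2")
  }
  d <- diff(centerline)
  if (any(rowSums(d^2) == 0)) {
    stop(sprintf("vessel '%s': consecutive centerline vertices coincide", vessel_id))
  }
  structure(list(centerline = centerline, vessel_id = as.character(vessel_id)),
            class = "vessel_annotation")
}

#' Annotated pCLE mosaic scene
#'
#' Bundles one mosaic intensity image with its crypt and vessel annotations
#' and acquisition metadata.
#'
#' @param image numeric matrix (rows = y, cols = x) of intensities, or `NULL`
#'   when only geometry is of interest.
#' @param crypts list of [crypt_annotation()] objects.
#' @param vessels list of [vessel_annotation()] objects.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param patient_id,timepoint,mosaic_id metadata; `timepoint` must be
#'   `"pre"` or `"post"`.
#' @return object of class `mosaic_scene`.
#' @export
mosaic_scene <- function(image = NULL, crypts = list(), vessels = list(),
                         pixel_size = 1, patient_id = NA_character_,
                         timepoint = "pre", mosaic_id = NA_character_) {
  stopifnot(pixel_size > 0)
  if (!timepoint %in% c("pre", "post")) stop("timepoint must be 'pre' or 'post'")
  if (!is.null(image)) {
    image <- as.matrix(image)
    h <- nrow(image); w <- ncol(image)
    for (cr in crypts) {
      for (poly in list(cr$outer, cr$inner)) {
        if (is.null(poly)) next
        if (any(poly[, 1L] < -0.5 | poly[, 1L] > w - 0.5 |
                poly[, 2L] < -0.5 | poly[, 2L] > h - 0.5)) {
          stop(sprintf("crypt '%s': vertex outside image bounds", cr$crypt_id))
        }
      }
    }
    for (v in vessels) {
      cl <- v$centerline
      if (any(cl[, 1L] < -0.5 | cl[, 1L] > w - 0.5 |
              cl[, 2L] < -0.5 | cl[, 2L] > h - 0.5)) {
        stop(sprintf("vessel '%s': vertex outside image bounds", v$vessel_id))
      }
    }
  }
  structure(list(image = image, crypts = crypts, vessels = vessels,
                 pixel_size = pixel_size, patient_id = patient_id,
                 timepoint = timepoint, mosaic_id = mosaic_id),
            class = "mosaic_scene")
}

#' @export
print.mosaic_scene <- function(x, ...) {
  cat(sprintf("<mosaic_scene %s/%s/%s: %s, %d crypts, %d vessels, %.3g um/px>\n",
              x$patient_id, x$timepoint, x$mosaic_id,
              if (is.null(x$image)) "no image" else
                paste(dim(x$image), collapse = "x"),
              length(x$crypts), length(x$vessels), x$pixel_size))
  invisible(x)
}

# Normalize vertex order to counterclockwise in the mathematical sense
# (signed shoelace area > 0).
orient_ccw <- function(poly) {
  if (polygon_area(poly, signed = TRUE) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# ---------------------------------------------------------------------------
# Scene file IO: 16-bit (or 8-bit) grayscale TIFF/PNG image plus a sidecar
# GeoJSON FeatureCollection. Crypt outlines are Polygon features with
# properties {role: "outer"|"inner", crypt_id}; vessels are LineString
# features with {vessel_id}. Scene metadata travels in a top-level
# "metadata" member.

#' Write a scene to an image file and a GeoJSON annotation file
#'
#' The image is written as grayscale TIFF (default 16-bit) or PNG; intensities
#' are stored as `image / (2^bit_depth - 1)`, so integer-valued images in
#' `[0, 2^bit_depth - 1]` round-trip exactly.
#'
#' @param scene a [mosaic_scene()].
#' @param image_path output path ending in `.tif`/`.tiff` or `.png`.
#' @param annotation_path output GeoJSON path.
#' @param bit_depth 8 or 16.
#' @return invisibly, the two paths.
#' @export
write_scene <- function(scene, image_path, annotation_path, bit_depth = 16L) {
  stopifnot(inherits(scene, "mosaic_scene"), bit_depth %in% c(8L, 16L))
  if (is.null(scene$image)) stop("scene has no image to write")
  maxv <- 2^bit_depth - 1
  img <- pmin(pmax(scene$image / maxv, 0), 1)
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, image_path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    png::writePNG(img, image_path)
  } else stop("unsupported image extension: ", ext)

  poly_coords <- function(poly) {
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
  }
  feats <- list()
  for (cr in scene$crypts) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = poly_coords(cr$outer)),
      properties = list(role = "outer", crypt_id = cr$crypt_id))
    if (!is.null(cr$inner)) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon", coordinates = poly_coords(cr$inner)),
        properties = list(role = "inner", crypt_id = cr$crypt_id))
    }
  }
  for (v in scene$vessels) {
    cl <- v$centerline
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(cl)), function(i) cl[i, ])),
      properties = list(vessel_id = v$vessel_id))
  }
  doc <- list(
    type = "FeatureCollection",
    metadata = list(pixel_size = scene$pixel_size, patient_id = scene$patient_id,
                    timepoint = scene$timepoint, mosaic_id = scene$mosaic_id,
                    coordinates = "0-based, origin top-left, x=column, y=row"),
    features = feats)
  jsonlite::write_json(doc, annotation_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(image_path, annotation_path))
}

#' Read a scene from an image file and its GeoJSON annotations
#'
#' Intensities are returned on the integer scale of the stored bit depth
#' (0..255 for 8-bit, 0..65535 for 16-bit), so the same scene saved at
#' different depths yields identical geometry and proportionally scaled
#' intensities.
#'
#' @param image_path TIFF or PNG grayscale image.
#' @param annotation_path GeoJSON FeatureCollection written by [write_scene()]
#'   or following the same dialect.
#' @return a [mosaic_scene()].
#' @export
read_scene <- function(image_path, annotation_path) {
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(image_path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    raw <- png::readPNG(image_path, info = TRUE)
    info <- attr(raw, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    img <- raw
  } else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img <- round(img * (2^bits - 1))

  doc <- jsonlite::read_json(annotation_path)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("annotation file is not a GeoJSON FeatureCollection")
  }
  md <- doc$metadata
  outers <- list(); inners <- list(); vessels <- list()
  for (f in doc$features) {
    props <- f$properties
    geom <- f$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1L]], function(p) unlist(p)))
      if (is.null(props$crypt_id)) stop("Polygon feature without crypt_id")
      role <- props$role
      if (identical(role, "outer")) outers[[props$crypt_id]] <- ring
      else if (identical(role, "inner")) inners[[props$crypt_id]] <- ring
      else stop(sprintf("crypt '%s': unknown polygon role '%s'", props$crypt_id, role))
    } else if (identical(geom$type, "LineString")) {
      cl <- do.call(rbind, lapply(geom$coordinates, function(p) unlist(p)))
      vid <- if (is.null(props$vessel_id)) sprintf("V%d", length(vessels) + 1L) else props$vessel_id
      vessels[[length(vessels) + 1L]] <- vessel_annotation(cl, vid)
    } else stop("unsupported geometry type: ", geom$type)
  }
  orphans <- setdiff(names(inners), names(outers))
  if (length(orphans)) {
    stop("inner outline(s) without matching outer crypt_id: ",
         paste(orphans, collapse = ", "))
  }
  crypts <- lapply(names(outers), function(id) {
    crypt_annotation(outers[[id]], inners[[id]], crypt_id = id)
  })
  mosaic_scene(image = img, crypts = crypts, vessels = vessels,
               pixel_size = if (is.null(md$pixel_size)) 1 else md$pixel_size,
               patient_id = if (is.null(md$patient_id)) NA_character_ else md$patient_id,
               timepoint = if (is.null(md$timepoint)) "pre" else md$timepoint,
               mosaic_id = if (is.null(md$mosaic_id)) NA_character_ else md$mosaic_id)
}

# ---------------------------------------------------------------------------
# Clinical score tables

#' Read a clinical endoscopic score table
#'
#' Expected CSV header: `patient_id,disease,timepoint,Mayo,UCEIS,PICaSSO,SES_CD`.
#' UC rows carry the Mayo (0-3), UCEIS (0-8) and PICaSSO (>= 0) indices;
#' CD rows carry SES_CD (>= 0). Scores not applicable to the disease may be
#' left empty.
#'
#' @param csv_path path to the CSV file.
#' @return data frame with one validated row per patient-timepoint, columns
#'   as in the header above plus no extras.
#' @export
read_clinical_table <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  required <- c("patient_id", "disease", "timepoint", "Mayo", "UCEIS", "PICaSSO", "SES_CD")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  for (sc in c("Mayo", "UCEIS", "PICaSSO", "SES_CD")) df[[sc]] <- as.integer(df[[sc]])
  validate_clinical(df)
  df
}

#' Write a clinical score table
#' @param scores data frame as returned by [read_clinical_table()].
#' @param csv_path output path.
#' @export
write_clinical_table <- function(scores, csv_path) {
  validate_clinical(scores)
  utils::write.csv(scores, csv_path, row.names = FALSE, na = "")
  invisible(csv_path)
}

validate_clinical <- function(df) {
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    who <- sprintf("row %d (patient %s, %s)", i, row$patient_id, row$timepoint)
    if (!row$disease %in% c("UC", "CD")) {
      stop(who, ": unknown disease code '", row$disease, "'")
    }
    if (!row$timepoint %in% c("pre", "post")) {
      stop(who, ": timepoint must be 'pre' or 'post'")
    }
    if (row$disease == "UC") {
      if (is.na(row$Mayo) && is.na(row$UCEIS) && is.na(row$PICaSSO)) {
        stop(who, ": UC row carries none of Mayo/UCEIS/PICaSSO")
      }
      if (!is.na(row$Mayo) && (row$Mayo < 0 || row$Mayo > 3)) {
        stop(who, ": Mayo endoscopic score must be in 0..3")
      }
      if (!is.na(row$UCEIS) && (row$UCEIS < 0 || row$UCEIS > 8)) {
        stop(who, ": UCEIS must be in 0..8")
      }
      if (!is.na(row$PICaSSO) && row$PICaSSO < 0) {
        stop(who, ": PICaSSO must be >= 0")
      }
    } else {
      if (is.na(row$SES_CD)) stop(who, ": CD row missing SES_CD")
      if (row$SES_CD < 0) stop(who, ": SES-CD must be >= 0")
    }
  }
  invisible(df)
}

# ---------------------------------------------------------------------------
# Expression matrices: TSV, genes as rows, first column gene_id.

#' Read a gene x sample expression matrix from TSV
#'
#' @param tsv_path tab-separated file; first column `gene_id`, remaining
#'   columns one per sample, values on the TPM scale (>= 0).
#' @return numeric matrix with gene_id rownames and sample colnames.
#' @export
read_expression <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression values must be non-negative (TPM scale)")
  m
}

#' Write a gene x sample expression matrix to TSV
#' @param mat numeric matrix with rownames (gene ids) and colnames (samples).
#' @param tsv_path output path.
#' @export
write_expression <- function(mat, tsv_path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tsv_path)
}

# ---------------------------------------------------------------------------
# Image stacks: multi-page TIFF, intensities in [0, 1].

#' Write an image stack as multi-page TIFF
#' @param images list of same-size numeric matrices with values in \[0, 1\].
#' @param path output `.tif` path.
#' @param bit_depth bits per sample (default 16).
#' @export
write_stack <- function(images, path, bit_depth = 16L) {
  stopifnot(is.list(images), length(images) >= 1L)
  tiff::writeTIFF(images, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF image stack
#' @param path `.tif` path.
#' @return list of numeric matrices with values in \[0, 1\].
#' @export
read_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) if (length(dim(m)) == 3L) m[, , 1L] else m)
}
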