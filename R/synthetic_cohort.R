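# Synthetic responder/nonresponder cohorts: per-patient imaging features
# drawn from class-conditional normal distributions, with consistent
# endoscopic scores and (optionally) full annotated scenes per mosaic.

#' Default class-conditional feature distributions
#'
#' Means and SDs for responder vs nonresponder patients for the in vivo
#' pCLE feature panel, chosen as plausible magnitudes for colonic mucosa
#' (areas in um^2, distances in um, tortuosity dimensionless, FLCM in
#' image intensity units). Responders trend toward smaller, rounder,
#' less leaky architecture.
#'
#' @return data frame with columns `feature`, `mean_responder`,
#'   `mean_nonresponder`, `sd`.
#' @export
default_cohort_features <- function() {
  data.frame(
    feature = c("mean_vessel_tortuosity", "max_crypt_area",
                "mean_crypt_eccentricity", "max_crypt_diameter",
                "mean_icd", "mean_wt", "max_flcm_pericrypt",
                "mean_flcm_elsewhere"),
    mean_responder    = c(1.15, 4000, 0.55, 75, 28, 9, 14000, 11500),
    mean_nonresponder = c(1.40, 5500, 0.68, 90, 36, 12, 19000, 12500),
    sd                = c(0.10, 700, 0.06, 8, 4, 1.5, 2200, 900),
    stringsAsFactors = FALSE)
}

#' Configuration for a synthetic patient cohort
#'
#' @param n_responders,n_nonresponders patients per class (each >= 2).
#' @param features data frame as [default_cohort_features()]: one row per
#'   feature with class means and a common SD (> 0).
#' @param mosaics_per_patient mosaics analysed per patient (default 10,
#'   the study protocol's count).
#' @param disease `"UC"` or `"CD"`; controls which endoscopic scores the
#'   consistency table carries.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_responders = 20L, n_nonresponders = 9L,
                          features = default_cohort_features(),
                          mosaics_per_patient = 10L, disease = "UC",
                          seed = 1L) {
  stopifnot(n_responders >= 2L, n_nonresponders >= 2L,
            all(features$sd > 0), mosaics_per_patient >= 1L,
            disease %in% c("UC", "CD"))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Per-patient features are drawn from the class-conditional normals in
#' `config$features`. A clinical score table consistent with each patient's
#' generating class is produced so the endoscopic labeling rules can be
#' exercised end to end: responders receive post-treatment scores in the
#' remission band, nonresponders in the nonresponse band.
#'
#' @param config a [cohort_config()].
#' @param generate_scenes if `TRUE`, also generate `mosaics_per_patient`
#'   annotated scenes per patient whose crypt sizes and vessel tortuosity
#'   track the patient's drawn features (slow; off by default).
#' @return list with `features` (data frame, one row per patient), `labels`
#'   (named 0/1 vector, 1 = responder), `clinical` (score table with pre and
#'   post rows), and optionally `scenes`.
#' @export
generate_cohort <- function(config, generate_scenes = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_responders + config$n_nonresponders
    cls <- rep(c(1L, 0L), c(config$n_responders, config$n_nonresponders))
    ids <- sprintf("P%03d", seq_len(n))
    feat <- config$features
    tab <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(feat))) {
      mu <- ifelse(cls == 1L, feat$mean_responder[i], feat$mean_nonresponder[i])
      tab[[feat$feature[i]]] <- stats::rnorm(n, mu, feat$sd[i])
    }
    labels <- stats::setNames(cls, ids)

    clinical <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (config$disease == "UC") {
        pre <- data.frame(patient_id = ids[i], disease = "UC", timepoint = "pre",
                          Mayo = sample(2:3, 1L), UCEIS = sample(5:8, 1L),
                          PICaSSO = sample(9:15, 1L), SES_CD = NA_integer_)
        post <- pre; post$timepoint <- "post"
        if (cls[i] == 1L) {
          post$Mayo <- sample(0:1, 1L); post$UCEIS <- sample(0:1, 1L)
          post$PICaSSO <- sample(0:3, 1L)
        } else {
          post$Mayo <- 3L; post$UCEIS <- sample(7:8, 1L); post$PICaSSO <- sample(8:15, 1L)
        }
        rbind(pre, post)
      } else {
        pre_score <- sample(7:15, 1L)
        post_score <- if (cls[i] == 1L) floor(pre_score * stats::runif(1, 0.1, 0.5))
                      else ceiling(pre_score * stats::runif(1, 0.76, 1.0))
        rbind(data.frame(patient_id = ids[i], disease = "CD", timepoint = "pre",
                         Mayo = NA_integer_, UCEIS = NA_integer_,
                         PICaSSO = NA_integer_, SES_CD = pre_score),
              data.frame(patient_id = ids[i], disease = "CD", timepoint = "post",
                         Mayo = NA_integer_, UCEIS = NA_integer_,
                         PICaSSO = NA_integer_, SES_CD = post_score))
      }
    }))

    scenes <- NULL
    if (generate_scenes) {
      scenes <- lapply(seq_len(n), function(i) {
        lapply(seq_len(config$mosaics_per_patient), function(m) {
          cfg <- scene_config(
            n_crypts = 5L,
            crypt_area_log_mean = log(max(tab$max_crypt_area[i], 500) * 0.6),
            vessel_tortuosity_target = max(tab$mean_vessel_tortuosity[i], 1.01),
            seed = config$seed * 10000L + i * 100L + m)
          out <- generate_mosaic_scene(cfg)
          out$scene$patient_id <- ids[i]
          out$scene$mosaic_id <- sprintf("M%02d", m)
          out$scene
        })
      })
      names(scenes) <- ids
    }
    list(features = tab, labels = labels, clinical = clinical, scenes = scenes)
  })
}
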