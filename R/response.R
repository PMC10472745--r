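# Response labeling from endoscopic indices, paired pre/post testing, and
# leave-one-out cross-validated univariate logistic prediction.

#' Label treatment response from endoscopic scores
#'
#' UC (scores at the post-treatment endoscopy): endoscopic remission
#' (responder) requires Mayo <= 1 AND UCEIS <= 1 AND PICaSSO <= 3;
#' nonresponse is Mayo = 3 OR UCEIS >= 7 OR PICaSSO >= 8; everything else is
#' partial response. The published partial and nonresponse bands overlap
#' (PICaSSO 8 sits in both; UCEIS 5-6 sits in neither), so categories are
#' assigned with precedence remission > nonresponse > partial and the
#' unassigned middle band falls to partial.
#'
#' CD: remission is an SES-CD reduction >= 50\% (post <= 0.5 * pre,
#' boundary inclusive); nonresponse is post > 75\% of pre; partial
#' otherwise (post exactly 75\% of pre is partial).
#'
#' @param scores_pre,scores_post one-row data frames (or lists) with the
#'   fields of a clinical score row: `Mayo`, `UCEIS`, `PICaSSO`, `SES_CD`.
#' @param disease `"UC"` or `"CD"`.
#' @param policy binary-label policy for partial responders:
#'   `"partial_as_responder"` (default, the primary analysis) or
#'   `"partial_as_nonresponder"` (sensitivity analysis).
#' @return list with `category` (`"responder"`, `"partial"`,
#'   `"nonresponder"`), `label` (1 = responder under the policy), `policy`,
#'   and `inputs` (the scores used, retained for audit).
#' @export
label_response <- function(scores_pre, scores_post, disease,
                           policy = c("partial_as_responder",
                                      "partial_as_nonresponder")) {
  policy <- match.arg(policy)
  stopifnot(disease %in% c("UC", "CD"))
  if (disease == "UC") {
    needed <- c("Mayo", "UCEIS", "PICaSSO")
    vals <- lapply(needed, function(f) scores_post[[f]])
    miss <- needed[vapply(vals, function(v) is.null(v) || is.na(v), logical(1L))]
    if (length(miss)) {
      stop("missing required post-treatment UC score(s): ",
           paste(miss, collapse = ", "))
    }
    category <- uc_category(scores_post$Mayo, scores_post$UCEIS, scores_post$PICaSSO)
    inputs <- list(post = scores_post[needed])
  } else {
    pre <- scores_pre$SES_CD; post <- scores_post$SES_CD
    if (is.null(pre) || is.na(pre)) stop("missing required score: pre-treatment SES_CD")
    if (is.null(post) || is.na(post)) stop("missing required score: post-treatment SES_CD")
    if (pre <= 0) stop("pre-treatment SES-CD must be > 0 to assess reduction")
    category <- if (post <= 0.5 * pre) "responder"
    else if (post > 0.75 * pre) "nonresponder"
    else "partial"
    inputs <- list(pre = pre, post = post, ratio = post / pre)
  }
  label <- switch(category,
                  responder = 1L,
                  nonresponder = 0L,
                  partial = if (policy == "partial_as_responder") 1L else 0L)
  list(category = category, label = label, policy = policy, inputs = inputs)
}

uc_category <- function(mayo, uceis, picasso) {
  if (mayo <= 1 && uceis <= 1 && picasso <= 3) "responder"
  else if (mayo == 3 || uceis >= 7 || picasso >= 8) "nonresponder"
  else "partial"
}

#' Paired pre/post change test (Wilcoxon signed rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired differences: exact for
#' n <= 25 informative pairs (no ties among the nonzero differences),
#' normal approximation with continuity correction otherwise. Zero
#' differences are dropped (the signed-rank convention); when every
#' difference is zero the test is vacuous and p = 1 is returned with a
#' warning. A paired t-test is available via `method` for users preferring
#' the parametric variant.
#'
#' @param pre,post paired numeric vectors.
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @return list with `statistic` (V, or t), `p_value`, `n_informative`.
#' @export
paired_change_test <- function(pre, post, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[!is.na(d)]
  if (method == "ttest") {
    if (stats::sd(d) == 0) {
      warning("all paired differences are equal; t-test is vacuous")
      return(list(statistic = NA_real_, p_value = 1, n_informative = length(d)))
    }
    ht <- stats::t.test(d, mu = 0)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n_informative = length(d)))
  }
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero; test is vacuous")
    return(list(statistic = 0, p_value = 1, n_informative = 0L))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_informative = length(nz))
}

#' AUROC (Mann-Whitney form)
#'
#' P(score of a random positive > score of a random negative) + 1/2 P(tie),
#' which equals the trapezoidal area under the ROC curve.
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (1 = positive), same length.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Confusion-matrix metrics
#'
#' Standard 2x2 definitions. Ratios with a zero denominator (e.g. NPV when
#' nothing is predicted negative) are reported as `NA`, never 0.
#'
#' @param predicted,labels binary vectors (1 = positive) of equal length.
#' @return named numeric: `accuracy`, `ppv`, `npv`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(predicted, labels) {
  if (length(predicted) != length(labels)) stop("length mismatch")
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  stopifnot(all(predicted %in% 0:1), all(labels %in% 0:1))
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (tp + tn) / length(labels),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp))
}

#' Leave-one-out cross-validated univariate logistic prediction
#'
#' For each patient i, a univariate logistic regression
#' (intercept + feature) is fitted on the other n-1 patients and the
#' held-out probability for i is recorded. The AUROC is computed over the n
#' held-out probabilities; the probability cutoff is then chosen to
#' maximize Youden's J (sensitivity + specificity - 1) on those held-out
#' probabilities (max-accuracy selection available via `cutoff_rule`), and
#' accuracy/PPV/NPV follow from the resulting confusion matrix.
#'
#' Training folds with complete separation (common at small n) fall back to
#' a lightly ridge-penalized fit (penalty `ridge` on the slope), flagged in
#' the report; folds with a single class are an error.
#'
#' @param feature numeric per-patient values.
#' @param labels binary labels (1 = responder).
#' @param feature_name name recorded in the report.
#' @param cutoff_rule `"youden"` (default) or `"accuracy"`.
#' @param ridge ridge penalty used by the separation fallback.
#' @return object of class `classifier_report`: list with `feature`,
#'   `auroc`, `accuracy`, `ppv`, `npv`, `sensitivity`, `specificity`,
#'   `cutoff`, `probabilities` (held-out, per patient), `n`,
#'   `n_separation_fallbacks`.
#' @export
loocv_logistic <- function(feature, labels, feature_name = "feature",
                           cutoff_rule = c("youden", "accuracy"),
                           ridge = 1e-4) {
  cutoff_rule <- match.arg(cutoff_rule)
  stopifnot(length(feature) == length(labels))
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 6L) stop("need at least 6 patients for LOOCV")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  probs <- numeric(n)
  fallbacks <- 0L
  for (i in seq_len(n)) {
    x <- feature[-i]; y <- labels[-i]
    if (length(unique(y)) < 2L) stop("training fold ", i, " has a single class")
    fit <- fit_univariate_logistic(x, y, ridge = ridge)
    if (fit$fallback) fallbacks <- fallbacks + 1L
    eta <- fit$coef[1L] + fit$coef[2L] * feature[i]
    probs[i] <- stats::plogis(eta)
  }
  auroc <- roc_auc(probs, labels)
  cutoff <- choose_cutoff(probs, labels, cutoff_rule)
  cm <- confusion_metrics(as.integer(probs > cutoff), labels)
  structure(list(feature = feature_name, auroc = auroc,
                 accuracy = cm[["accuracy"]], ppv = cm[["ppv"]],
                 npv = cm[["npv"]], sensitivity = cm[["sensitivity"]],
                 specificity = cm[["specificity"]], cutoff = cutoff,
                 probabilities = probs, n = n,
                 n_separation_fallbacks = fallbacks),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report %s: n=%d AUROC=%.3f acc=%.3f PPV=%.3f NPV=%.3f cutoff=%.3f%s>\n",
    x$feature, x$n, x$auroc, x$accuracy, x$ppv, x$npv, x$cutoff,
    if (x$n_separation_fallbacks > 0)
      sprintf(" [%d ridge fallback folds]", x$n_separation_fallbacks) else ""))
  invisible(x)
}

# Plain ML fit via glm; on complete/quasi-separation (fitted probabilities
# pinned at 0/1 or non-convergence) refit with a small ridge penalty on the
# slope so the LOOCV probability stays defined.
fit_univariate_logistic <- function(x, y, ridge = 1e-4) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete/quasi-separation shows up as a (near-)perfect fit: the ML
  # estimate diverges and glm stops at an arbitrary large slope
  separated <- warned || !fit$converged || fit$deviance < 1e-6
  if (!separated) {
    return(list(coef = unname(fit$coefficients), fallback = FALSE))
  }
  list(coef = ridge_logistic(x, y, lambda = ridge), fallback = TRUE)
}

# Newton-Raphson for logistic regression with an L2 penalty on the slope
# (intercept unpenalized).
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100L) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  P <- diag(c(0, lambda))
  for (k in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(X, y - p)) - P %*% beta
    H <- crossprod(X * wt, X) + P
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  unname(beta)
}

choose_cutoff <- function(probs, labels, rule) {
  cand <- sort(unique(probs))
  if (length(cand) > 1L) {
    cand <- (cand[-1L] + cand[-length(cand)]) / 2  # midpoints between observed probs
  }
  cand <- c(cand, 0.5)
  score <- vapply(cand, function(ct) {
    cm <- confusion_metrics(as.integer(probs > ct), labels)
    if (rule == "youden") {
      s <- cm[["sensitivity"]] + cm[["specificity"]] - 1
      if (is.na(s)) -Inf else s
    } else cm[["accuracy"]]
  }, numeric(1L))
  cand[which.max(score)]
}

#' Evaluate every feature of a patient table as a univariate predictor
#'
#' Convenience wrapper producing one report row per feature (and optionally
#' per disease subgroup), matching the AUROC / accuracy / PPV / NPV
#' reporting layout of the study.
#'
#' @param features data frame with `patient_id` plus numeric feature columns.
#' @param labels named binary vector (names = patient ids).
#' @param subgroup optional factor/character vector per patient (e.g.
#'   disease); when given, each level is evaluated separately.
#' @return data frame with columns `feature`, `subgroup`, `n`, `auroc`,
#'   `accuracy`, `ppv`, `npv`, `cutoff`.
#' @export
evaluate_features <- function(features, labels, subgroup = NULL) {
  stopifnot("patient_id" %in% names(features))
  y <- labels[features$patient_id]
  if (anyNA(y)) stop("labels missing for some patients")
  numcols <- names(features)[vapply(features, is.numeric, logical(1L))]
  groups <- if (is.null(subgroup)) list(all = seq_len(nrow(features)))
  else split(seq_len(nrow(features)), subgroup)
  out <- NULL
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    for (fc in numcols) {
      rep <- loocv_logistic(features[[fc]][idx], y[idx], feature_name = fc)
      out <- rbind(out, data.frame(
        feature = fc, subgroup = gname, n = rep$n, auroc = rep$auroc,
        accuracy = rep$accuracy, ppv = rep$ppv, npv = rep$npv,
        cutoff = rep$cutoff, stringsAsFactors = FALSE))
    }
  }
  out
}
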