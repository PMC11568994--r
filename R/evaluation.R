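# Registration evaluation: control-point error, the registration-score
# curve and its AUC, per-category aggregation, and the variable-top-keypoint
# registration score (VTKRS).

#' Mean control-point error of a registration
#'
#' The mean Euclidean distance between the mapped fixed control points and
#' their moving counterparts.  A transform that sends any control point to
#' infinity yields the failed-registration sentinel `Inf`.
#'
#' @param h 3x3 homography (fixed -> moving).
#' @param cps data.frame with columns `x_fixed`, `y_fixed`, `x_moving`,
#'   `y_moving`; at least 1 row.
#' @return mean error in pixels (possibly `Inf`).
#' @export
control_point_error <- function(h, cps) {
  stopifnot(nrow(cps) >= 1)
  p <- apply_homography(h, cbind(cps$x_fixed, cps$y_fixed))
  if (any(!is.finite(p))) return(Inf)
  mean(sqrt((p[, 1] - cps$x_moving)^2 + (p[, 2] - cps$y_moving)^2))
}

#' Registration score curve and AUC
#'
#' A pair is a successful registration at threshold t if its control-point
#' error is <= t; sweeping t over the integer grid 1..25 px gives the
#' success-ratio curve, summarized by its AUC (the mean of the 25 ratios).
#' Failed registrations enter as error `Inf`, penalizing every threshold.
#'
#' @param errors numeric vector of per-pair control-point errors (px).
#' @param thresholds integer threshold grid (default 1:25).
#' @return a `score_curve`: list with `thresholds`, `success_ratio`, `auc`.
#' @export
registration_score <- function(errors, thresholds = 1:25) {
  stopifnot(length(errors) >= 1)
  ratio <- vapply(thresholds, function(t) mean(errors <= t), 0)
  structure(list(thresholds = thresholds, success_ratio = ratio,
                 auc = mean(ratio)),
            class = "score_curve")
}

#' @export
print.score_curve <- function(x, ...) {
  cat(sprintf("<score_curve: AUC %.3f over thresholds %g..%g>\n",
              x$auc, min(x$thresholds), max(x$thresholds)))
  invisible(x)
}

#' Aggregate registration scores by fixture category
#'
#' Computes the registration-score AUC per category, their unweighted mean
#' (`avg`) and a weighted mean (`w_avg`) with the per-category pair counts
#' as weights (the counts of the evaluated pairs by default).  Categories
#' with no pairs are excluded from the averages with a warning.
#'
#' @param per_pair_errors numeric vector of per-pair errors.
#' @param categories character vector (one of "A", "P", "S" per pair).
#' @param weights named weights for `w_avg`; default = pair counts.
#' @return a `category_summary`: list with `auc` (named by category),
#'   `avg`, `w_avg`, `weights`.
#' @export
aggregate_by_category <- function(per_pair_errors, categories,
                                  weights = NULL) {
  stopifnot(length(per_pair_errors) == length(categories))
  cats <- c("A", "P", "S")
  auc <- setNames(rep(NA_real_, 3), cats)
  for (cl in cats) {
    sel <- categories == cl
    if (any(sel)) auc[cl] <- registration_score(per_pair_errors[sel])$auc
  }
  if (anyNA(auc)) {
    warning(sprintf("empty category(ies) excluded from averages: %s",
                    paste(cats[is.na(auc)], collapse = ", ")))
  }
  if (is.null(weights)) {
    weights <- setNames(vapply(cats, function(cl) sum(categories == cl), 0),
                        cats)
  }
  ok <- !is.na(auc) & weights[cats] > 0
  structure(list(auc = auc,
                 avg = mean(auc[!is.na(auc)]),
                 w_avg = sum(auc[ok] * weights[cats][ok]) /
                   sum(weights[cats][ok]),
                 weights = weights),
            class = "category_summary")
}

#' Variable Top Keypoint Registration Score (VTKRS)
#'
#' Evaluates registration quality as a function of the number of keypoint
#' matches used.  Matches are computed once per pair and ranked per class by
#' descriptor similarity (descending); for each n in `n_range` only the top
#' n matches per class are kept (a class with fewer matches contributes all
#' it has), the homography is re-estimated with exhaustive RANSAC (all
#' C(M, 4) minimal samples) and the control-point error recomputed.  Each n
#' yields a registration-score AUC over the pairs; the VTKRS AUC is the mean
#' of these values over `n_range`.  A pair with fewer than 4 kept matches at
#' some n counts as failed at that n.
#'
#' @param match_sets list of `match_set`s, one per pair.
#' @param control_points list of control-point data.frames, one per pair.
#' @param n_range integer vector of per-class match budgets (default 3:25).
#' @param inlier_threshold RANSAC inlier threshold, px.
#' @return a `score_curve` over n: list with `n`, `auc_per_n`, `auc`, and
#'   `errors` (pairs x n matrix of control-point errors).
#' @export
vtkrs_from_matches <- function(match_sets, control_points, n_range = 3:25,
                               inlier_threshold = 5) {
  stopifnot(length(match_sets) == length(control_points))
  errs <- matrix(Inf, length(match_sets), length(n_range))
  for (p in seq_along(match_sets)) {
    m <- match_sets[[p]]
    ord <- order(-m$similarity)
    m <- m[ord, , drop = FALSE]
    for (ni in seq_along(n_range)) {
      n <- n_range[ni]
      keep <- unlist(lapply(KEYPOINT_CLASSES, function(cl) {
        head(which(m$class == cl), n)
      }))
      mk <- m[sort(keep), , drop = FALSE]
      if (nrow(mk) < 4) next
      est <- tryCatch(
        estimate_homography(mk, ransac_config(
          inlier_threshold = inlier_threshold, exhaustive = TRUE)),
        fundusreg_insufficient_matches = function(e) NULL)
      if (!is.null(est)) {
        errs[p, ni] <- control_point_error(est$h, control_points[[p]])
      }
    }
  }
  auc_per_n <- vapply(seq_along(n_range), function(ni) {
    registration_score(errs[, ni])$auc
  }, 0)
  structure(list(n = n_range, auc_per_n = auc_per_n, auc = mean(auc_per_n),
                 errors = errs),
            class = c("vtkrs_curve", "score_curve"))
}

#' @rdname vtkrs_from_matches
#' @param pairs list of `registration_pair` fixtures.
#' @param detector,descriptor trained models.
#' @param threshold,window detector extraction parameters.
#' @export
vtkrs <- function(pairs, detector, descriptor, n_range = 3:25,
                  inlier_threshold = 5, threshold = 0.35, window = 7) {
  ms <- lapply(pairs, function(pr) {
    kf <- detect(detector, pr$fixed, threshold, window)
    km <- detect(detector, pr$moving, threshold, window)
    df <- sample_descriptors(describe(descriptor, pr$fixed), kf)
    dm <- sample_descriptors(describe(descriptor, pr$moving), km)
    mutual_match(df, dm, resolution = dim(pr$fixed)[1:2])
  })
  cps <- lapply(pairs, `[[`, "control_points")
  vtkrs_from_matches(ms, cps, n_range, inlier_threshold)
}
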