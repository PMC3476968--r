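# Threshold-selection-factor calibration: exhaustive grid search on
# training recordings and the leave-one-out cross-validation harness.

#' Default threshold-selection-factor grids
#'
#' The grids bracket the published exemplar settings -- (4, 25) for the
#' time-domain estimator and (0.5, 3.5) for the frequency-domain one --
#' by roughly an order of magnitude on each side, and contain both points
#' exactly.
#'
#' @param method `"tda"` or `"fda"`.
#' @return data.frame with columns `tsf1`, `tsf2`, ordered by `tsf1` then
#'   `tsf2` (the tie-break order).
#' @export
default_grid <- function(method = c("tda", "fda")) {
  method <- match.arg(method)
  g <- if (method == "tda")
    expand.grid(tsf2 = seq(5, 50, by = 5), tsf1 = 1:10)
  else
    expand.grid(tsf2 = seq(0.5, 5, by = 0.5), tsf1 = seq(0, 2, by = 0.25))
  g <- g[, c("tsf1", "tsf2")]
  g[order(g$tsf1, g$tsf2), , drop = FALSE]
}

#' Classify a feature set at given threshold-selection factors
#'
#' @param features a feature list from [recording_features()].
#' @param method `"tda"` or `"fda"`.
#' @param tsf1,tsf2 threshold-selection factors.
#' @return a `binary_hypnogram` of per-epoch estimates.
#' @export
predict_from_features <- function(features, method = c("tda", "fda"),
                                  tsf1, tsf2) {
  method <- match.arg(method)
  if (method == "tda") {
    thr <- adaptive_threshold(features$z, tsf1, tsf2)
    classify_tda(hemg_count(features$y, thr))
  } else {
    classify_fda(features$tp, tsf1, tsf2)$prediction
  }
}

cohort_items <- function(x) {
  if (inherits(x, "emg_cohort")) x$items else x
}

#' Ensure each cohort item carries per-epoch features
#'
#' Computes [recording_features()] for items that only hold a raw
#' recording and (by default) drops the raw signal afterwards, keeping the
#' cohort small in memory; aligns each reference hypnogram to the
#' recording's whole epochs.
#'
#' @param cohort an `emg_cohort` or plain list of items.
#' @param drop_signals remove raw recordings after feature extraction.
#' @param ... passed to [recording_features()].
#' @return the cohort with `features` present on every item.
#' @export
cohort_features <- function(cohort, drop_signals = TRUE, ...) {
  items <- cohort_items(cohort)
  items <- lapply(items, function(it) {
    if (is.null(it$features)) {
      if (is.null(it$recording))
        stop("item ", it$subject_id, " has neither features nor a recording")
      al <- align_epochs(it$recording, it$binary)
      it$features <- recording_features(al$recording, ...)
      it$binary <- al$hypnogram
      if (drop_signals) it$recording <- NULL
    }
    it
  })
  if (inherits(cohort, "emg_cohort")) { cohort$items <- items; cohort }
  else items
}

objective_value <- function(stats, objective) {
  switch(objective, kappa = stats$kappa, accuracy = stats$accuracy,
         f = stats$f_measure)
}

#' Grid search of threshold-selection factors on training recordings
#'
#' Evaluates every grid point on every training recording and returns the
#' point maximizing the mean objective (Cohen's kappa by default: with
#' ~97% sleep prevalence, accuracy is dominated by the majority class and
#' is not an informative training signal). Ties break deterministically
#' toward smaller `tsf1`, then smaller `tsf2`. Recordings on which the
#' objective is undefined (single-class reference) are dropped from the
#' mean; if no recording yields a defined objective at any grid point,
#' calibration fails with an error.
#'
#' @param train an `emg_cohort` or list of items, each with `features`
#'   and a `binary` reference (see [cohort_features()]).
#' @param method `"tda"` or `"fda"`.
#' @param grid data.frame of `tsf1`, `tsf2` candidates.
#' @param objective `"kappa"`, `"accuracy"` or `"f"`.
#' @return list with `tsf1`, `tsf2`, `objective` (the achieved mean) and
#'   `table` (the full grid with each point's mean objective).
#' @export
grid_search <- function(train, method = c("tda", "fda"),
                        grid = default_grid(method),
                        objective = c("kappa", "accuracy", "f")) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  items <- cohort_items(train)
  if (length(items) == 0L) stop("empty training set")
  if (nrow(grid) == 0L) stop("empty parameter grid")
  for (it in items)
    if (is.null(it$features) || is.null(it$binary))
      stop("training items need `features` and `binary`; run cohort_features()")
  grid <- grid[order(grid$tsf1, grid$tsf2), , drop = FALSE]
  score_one <- function(it, tsf1, tsf2) {
    pred <- predict_from_features(it$features, method, tsf1, tsf2)
    st <- suppressWarnings(agreement(pred, it$binary))
    objective_value(st, objective)
  }
  means <- vapply(seq_len(nrow(grid)), function(g) {
    vals <- vapply(items, score_one, numeric(1L),
                   tsf1 = grid$tsf1[g], tsf2 = grid$tsf2[g])
    mean(vals, na.rm = TRUE)           # NaN if all are NA
  }, numeric(1L))
  if (all(is.nan(means) | is.na(means)))
    stop("calibration failed: the objective is undefined on every training recording")
  best <- which.max(means)             # first maximum = smallest tsf1, tsf2
  list(tsf1 = grid$tsf1[best], tsf2 = grid$tsf2[best],
       objective = means[best],
       table = cbind(grid, objective = means))
}

#' Leave-one-out cross-validation of a sleep/wake estimator
#'
#' For each subject, selects the threshold-selection factors by grid
#' search on all other subjects and scores the held-out subject with the
#' selected factors, mirroring a leave-one-subject-out validation design.
#'
#' @param cohort an `emg_cohort` (features are computed on the fly if
#'   missing).
#' @param method `"tda"` or `"fda"`.
#' @param grid data.frame of `tsf1`, `tsf2` candidates.
#' @param objective training objective, see [grid_search()].
#' @return an object of class `loocv_result`: list with `folds` (each
#'   holding `held_out_id`, `tsf1`, `tsf2`, `train_objective`, `stats`,
#'   `se`), `table` (per-fold statistics as a data.frame) and `summary`
#'   (mean/sample-SD aggregation of the statistic columns).
#' @export
loocv <- function(cohort, method = c("tda", "fda"),
                  grid = default_grid(method),
                  objective = c("kappa", "accuracy", "f")) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  items <- cohort_items(cohort_features(cohort))
  if (length(items) < 2L)
    stop("leave-one-out needs at least 2 subjects")
  folds <- lapply(seq_along(items), function(i) {
    sel <- tryCatch(
      grid_search(items[-i], method, grid, objective),
      error = function(e) stop("fold ", items[[i]]$subject_id, ": ",
                               conditionMessage(e), call. = FALSE))
    pred <- predict_from_features(items[[i]]$features, method,
                                  sel$tsf1, sel$tsf2)
    st <- suppressWarnings(agreement(pred, items[[i]]$binary))
    se <- sleep_efficiency_compare(items[[i]]$binary, pred)
    list(held_out_id = items[[i]]$subject_id, tsf1 = sel$tsf1,
         tsf2 = sel$tsf2, train_objective = sel$objective,
         stats = st, se = se)
  })
  tab <- do.call(rbind, lapply(folds, function(f) {
    cbind(data.frame(subject = f$held_out_id, method = toupper(method),
                     tsf1 = f$tsf1, tsf2 = f$tsf2,
                     stringsAsFactors = FALSE),
          as.data.frame(f$stats)[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy", "kappa", "f_measure")],
          data.frame(se_ref = f$se$se_ref, se_est = f$se$se_est,
                     se_abs_diff = f$se$abs_diff,
                     se_rel_diff = f$se$rel_diff))
  }))
  structure(list(folds = folds, table = tab,
                 summary = aggregate_stats(
                   tab[!(names(tab) %in% c("tsf1", "tsf2"))], na.rm = TRUE),
                 method = method),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, digits = 3L, ...) {
  cat(sprintf("<loocv_result> %s, %d folds\n", toupper(x$method),
              length(x$folds)))
  tab <- x$table
  tab[] <- lapply(tab, function(c) if (is.numeric(c)) round(c, digits) else c)
  print(tab, row.names = FALSE)
  cat("mean (SD):\n")
  print(round(x$summary, digits))
  invisible(x)
}
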