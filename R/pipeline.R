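# End-to-end scoring and cohort evaluation: wiring I/O, features, the two
# estimators and the agreement report together.

#' Score a recording epoch by epoch
#'
#' Runs one or both estimators over a recording and, when a reference
#' hypnogram is supplied, attaches the full epoch-by-epoch agreement
#' report and the sleep-efficiency comparison.
#'
#' @param rec an `emg_recording`.
#' @param ref optional reference `hypnogram` or `binary_hypnogram`
#'   (aligned with [align_epochs()]; a one-epoch length mismatch is
#'   truncated with a warning).
#' @param method `"both"`, `"tda"` or `"fda"`.
#' @param tda_tsf1,tda_tsf2 time-domain threshold-selection factors.
#' @param fda_tsf1,fda_tsf2 frequency-domain threshold-selection factors.
#' @param combine channel combination rule, see [score_tda()].
#' @param band,mains_band,window spectral options, see
#'   [epoch_total_power()].
#' @param remove_dc see [second_energy()].
#' @return an object of class `sleep_score`: list with `table` (one row
#'   per epoch: index, per-method state, reference state if given, and the
#'   feature values), `reports` (per-method `agreement_stats`, when a
#'   reference is present), `se` (per-method sleep-efficiency comparison,
#'   or the estimated efficiency alone without a reference) and `params`.
#' @export
score_recording <- function(rec, ref = NULL, method = c("both", "tda", "fda"),
                            tda_tsf1 = 4, tda_tsf2 = 25,
                            fda_tsf1 = 0.5, fda_tsf2 = 3.5,
                            combine = "sum", band = c(10, 75),
                            mains_band = c(55, 65), window = "none",
                            remove_dc = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.null(ref)) {
    al <- align_epochs(rec, ref)
    rec <- al$recording
    ref <- binarize(al$hypnogram)
  }
  want_fda <- method %in% c("both", "fda")
  feats <- recording_features(rec, with_tp = want_fda, band = band,
                              mains_band = mains_band, window = window,
                              remove_dc = remove_dc)
  tab <- data.frame(epoch = seq_len(feats$n_epochs), z = feats$z)
  reports <- list()
  se <- list()
  params <- list()
  if (method %in% c("both", "tda")) {
    td <- score_tda(feats, tda_tsf1, tda_tsf2, combine = combine)
    tab$hemg <- td$counts
    tab$tda_state <- td$prediction$states
    params$tda <- list(tsf1 = tda_tsf1, tsf2 = tda_tsf2,
                       mean_hemg = td$mean_hemg)
    if (!is.null(ref)) {
      reports$tda <- agreement(td$prediction, ref)
      se$tda <- sleep_efficiency_compare(ref, td$prediction)
    } else {
      se$tda <- list(se_est = sleep_efficiency(td$prediction))
    }
  }
  if (want_fda) {
    fd <- score_fda(feats, fda_tsf1, fda_tsf2, combine = combine)
    tab$tp <- feats$tp
    tab$fda_state <- fd$prediction$states
    params$fda <- list(tsf1 = fda_tsf1, tsf2 = fda_tsf2,
                       threshold = fd$threshold)
    if (!is.null(ref)) {
      reports$fda <- agreement(fd$prediction, ref)
      se$fda <- sleep_efficiency_compare(ref, fd$prediction)
    } else {
      se$fda <- list(se_est = sleep_efficiency(fd$prediction))
    }
  }
  if (!is.null(ref)) tab$reference_state <- ref$states
  structure(list(table = tab, reports = reports, se = se, params = params,
                 subject_id = rec$subject_id, method = method),
            class = "sleep_score")
}

#' @export
print.sleep_score <- function(x, ...) {
  cat(sprintf("<sleep_score> %s: %d epochs, method %s\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              nrow(x$table), x$method))
  for (m in names(x$se)) {
    if (!is.null(x$reports[[m]])) {
      st <- x$reports[[m]]
      cat(sprintf(
        "  %s: SE est %.1f%% (ref %.1f%%); sens %.3f spec %.3f kappa %.3f\n",
        toupper(m), x$se[[m]]$se_est, x$se[[m]]$se_ref,
        st$sensitivity, st$specificity, st$kappa))
    } else {
      cat(sprintf("  %s: SE est %.1f%%\n", toupper(m), x$se[[m]]$se_est))
    }
  }
  invisible(x)
}

#' Write the per-epoch scored table as CSV
#'
#' @param score a `sleep_score`.
#' @param path file to write.
#' @export
write_score <- function(score, path) {
  stopifnot(inherits(score, "sleep_score"))
  write.csv(score$table, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate an estimator over a cohort
#'
#' Either cross-validates the threshold-selection factors
#' (`params = "auto"`, leave-one-subject-out as in [loocv()]) or applies
#' fixed factors to every subject, and reports the per-subject statistic
#' rows plus their mean/sample-SD aggregation.
#'
#' @param cohort an `emg_cohort`.
#' @param method `"tda"` or `"fda"`.
#' @param params `"auto"` or a list/vector with `tsf1` and `tsf2`.
#' @param grid,objective calibration options, see [grid_search()].
#' @return list with `table` (per-subject rows) and `summary` (mean/SD),
#'   as produced by [loocv()] when `params = "auto"`.
#' @export
evaluate_cohort <- function(cohort, method = c("tda", "fda"),
                            params = "auto", grid = default_grid(method),
                            objective = "kappa") {
  method <- match.arg(method)
  if (identical(params, "auto")) {
    res <- loocv(cohort, method, grid, objective)
    return(list(table = res$table, summary = res$summary, folds = res$folds))
  }
  params <- as.list(params)
  items <- cohort_items(cohort_features(cohort))
  rows <- lapply(items, function(it) {
    pred <- predict_from_features(it$features, method,
                                  params$tsf1, params$tsf2)
    st <- suppressWarnings(agreement(pred, it$binary))
    se <- sleep_efficiency_compare(it$binary, pred)
    cbind(data.frame(subject = it$subject_id, method = toupper(method),
                     tsf1 = params$tsf1, tsf2 = params$tsf2,
                     stringsAsFactors = FALSE),
          as.data.frame(st)[c("sensitivity", "specificity", "ppv", "npv",
                              "accuracy", "kappa", "f_measure")],
          data.frame(se_ref = se$se_ref, se_est = se$se_est,
                     se_abs_diff = se$abs_diff, se_rel_diff = se$rel_diff))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = aggregate_stats(
         tab[!(names(tab) %in% c("tsf1", "tsf2"))], na.rm = TRUE))
}
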