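#' End-to-end CMD analysis of a cohort
#'
#' Runs the full analysis on a simulated (or otherwise assembled) cohort:
#' preprocesses every recording, extracts block-averaged imagery/rest feature
#' vectors for the four motor ROIs, trains per-ROI RBF-SVMs on the healthy
#' controls with GA hyperparameter search, predicts every patient, designates
#' the reporting ROI (the ROI with the highest patient-level sensitivity
#' against the behavioral MCS+ reference), and derives the confusion summary,
#' the CMD list and the prognosis comparisons.
#'
#' @param cohort A `fnirs_cohort` from [simulate_cohort()], or any list of
#'   elements with `profile` and `recording`.
#' @param combos Feature combinations to search (default: all 120; pass a
#'   single combination for desk-scale runs).
#' @param rois Candidate ROIs.
#' @param ga A [ga_config()].
#' @param config A [preprocess_config()].
#' @param rule Response decision rule, see [decide_response()].
#' @return A `cmd_analysis` list: `models`, `predictions` (all ROIs),
#'   `reporting_roi`, `records` (patients, reporting ROI), `confusion`,
#'   `cmd_ids`, `prognosis`, `train_features`, `patient_features`.
#' @export
cmd_analysis <- function(cohort, combos = enumerate_combos(),
                         rois = motor_rois(), ga = ga_config(),
                         config = preprocess_config(),
                         rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  roi_map <- build_roi_map()
  feats <- lapply(cohort, function(s) {
    hb <- preprocess_chain(s$recording, config)$hb
    subject_features(hb, roi_map, rois)
  })
  meta <- cohort_metadata(cohort)
  is_hc <- meta$diagnosis == "HC"
  train_features <- do.call(rbind, feats[is_hc])
  patient_features <- do.call(rbind, feats[!is_hc])
  if (is.null(train_features) || is.null(patient_features)) {
    stop("cohort must contain both HC and patients", call. = FALSE)
  }
  models <- select_model(train_features, combos, rois, ga)
  predictions <- predict_cohort(models, patient_features, rule = rule)
  pmeta <- meta[!is_hc, , drop = FALSE]

  # reporting ROI: highest sensitivity against the behavioral reference
  sens <- vapply(names(models), function(roi) {
    pr <- predictions[predictions$roi == roi, , drop = FALSE]
    m <- merge(pr, pmeta, by = "subject_id")
    pos <- m$diagnosis == "MCS+"
    if (!any(pos)) return(NA_real_)
    mean(m$response[pos])
  }, numeric(1))
  reporting_roi <- names(models)[which.max(sens)]

  pr <- predictions[predictions$roi == reporting_roi, , drop = FALSE]
  m <- merge(pr, pmeta, by = "subject_id")
  records <- subject_records(m$subject_id, m$diagnosis, m$response, m$gose_6mo)
  structure(
    list(
      models = models, predictions = predictions,
      reporting_roi = reporting_roi, sensitivity_by_roi = sens,
      records = records,
      confusion = confusion_summary(records),
      cmd_ids = identify_cmd(records),
      prognosis = prognosis_analysis(records),
      train_features = train_features, patient_features = patient_features
    ),
    class = "cmd_analysis"
  )
}

#' @export
print.cmd_analysis <- function(x, ...) {
  cat("CMD analysis - reporting ROI:", x$reporting_roi, "\n")
  print(x$confusion)
  cat(sprintf("  CMD patients identified: %d (%s)\n", length(x$cmd_ids),
              paste(x$cmd_ids, collapse = ", ")))
  print(x$prognosis)
  invisible(x)
}
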