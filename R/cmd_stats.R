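#' Build per-subject records for CMD analysis
#'
#' Joins the classifier's response decisions with the behavioral metadata and
#' assigns each patient a CMD status: a VS/UWS or MCS- patient with an fNIRS
#' response is a CMD case; a behaviorally unresponsive patient without one is
#' true DOC; MCS+ patients are split by response.
#'
#' @param subject_id,diagnosis,fnirs_response,gose_6mo Equal-length vectors
#'   (diagnosis in `"VS/UWS"`, `"MCS-"`, `"MCS+"`; GOS-E integer 1..8 or NA).
#' @return Data frame of class `subject_records` with an added `cmd_status`
#'   column (`CMD`, `true_DOC`, `MCS+_responder`, `MCS+_nonresponder`).
#' @export
subject_records <- function(subject_id, diagnosis, fnirs_response,
                            gose_6mo = NA) {
  stopifnot(all(diagnosis %in% c("VS/UWS", "MCS-", "MCS+")))
  ref_negative <- diagnosis %in% c("VS/UWS", "MCS-")
  cmd_status <- ifelse(
    ref_negative,
    ifelse(fnirs_response, "CMD", "true_DOC"),
    ifelse(fnirs_response, "MCS+_responder", "MCS+_nonresponder")
  )
  out <- data.frame(
    subject_id = as.character(subject_id), diagnosis = diagnosis,
    fnirs_response = as.logical(fnirs_response),
    gose_6mo = as.integer(rep_len(gose_6mo, length(subject_id))),
    cmd_status = cmd_status, stringsAsFactors = FALSE
  )
  class(out) <- c("subject_records", "data.frame")
  out
}

#' Diagnostic confusion summary against the behavioral reference
#'
#' The behavioral diagnosis is the reference standard for command-following:
#' MCS+ is reference-positive, VS/UWS and MCS- reference-negative. The fNIRS
#' response is the test standard. Rates are reported as percentages (rounded
#' to one decimal for display; unrounded values retained).
#'
#' @param records A `subject_records` data frame (or counts via
#'   [confusion_from_counts()]).
#' @return A `confusion_summary`: list with counts `TP`, `FN`, `TN`, `FP` and
#'   rates `TPR`, `FNR`, `TNR`, `FPR` (percent, unrounded) plus a `rounded`
#'   vector at one decimal.
#' @export
confusion_summary <- function(records) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  pos <- records$diagnosis == "MCS+"
  confusion_from_counts(
    TP = sum(pos & records$fnirs_response),
    FN = sum(pos & !records$fnirs_response),
    TN = sum(!pos & !records$fnirs_response),
    FP = sum(!pos & records$fnirs_response)
  )
}

#' Confusion summary from raw counts
#' @param TP,FN,TN,FP Non-negative integer counts.
#' @return See [confusion_summary()].
#' @export
confusion_from_counts <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  rates <- c(
    TPR = 100 * TP / (TP + FN), FNR = 100 * FN / (TP + FN),
    TNR = 100 * TN / (TN + FP), FPR = 100 * FP / (TN + FP)
  )
  structure(
    list(TP = TP, FN = FN, TN = TN, FP = FP,
         TPR = rates[["TPR"]], FNR = rates[["FNR"]],
         TNR = rates[["TNR"]], FPR = rates[["FPR"]],
         rounded = round(rates, 1)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Command-following detection vs behavioral reference\n",
           "  TPR (sensitivity) %.1f%% (%d/%d)   FNR %.1f%%\n",
           "  TNR (specificity) %.1f%% (%d/%d)   FPR %.1f%%\n"),
    x$rounded["TPR"], x$TP, x$TP + x$FN, x$rounded["FNR"],
    x$rounded["TNR"], x$TN, x$TN + x$FP, x$rounded["FPR"]
  ))
  invisible(x)
}

#' Identify CMD patients
#'
#' CMD (cognitive motor dissociation) patients are the false positives of the
#' behavioral reference: VS/UWS or MCS- patients showing an fNIRS response.
#'
#' @param records A `subject_records` data frame.
#' @return Character vector of CMD subject ids (sorted), with the true-DOC
#'   ids attached as attribute `true_doc`.
#' @export
identify_cmd <- function(records) {
  cmd <- sort(records$subject_id[records$cmd_status == "CMD"])
  structure(cmd, true_doc = sort(
    records$subject_id[records$cmd_status == "true_DOC"]
  ))
}

#' Dichotomize a GOS-E score
#'
#' Favorable outcome is upper severe disability or better (GOS-E 4-8);
#' unfavorable is GOS-E 3 or less. Missing scores (lost to follow-up) map to
#' `NA` and are excluded from prognosis tables with a message.
#'
#' @param score Integer vector of GOS-E scores (1..8) or NA.
#' @return Character vector `"favorable"` / `"unfavorable"` / NA.
#' @export
dichotomize_gose <- function(score) {
  bad <- !is.na(score) & (score < 1 | score > 8)
  if (any(bad)) {
    stop("GOS-E score out of range 1..8: ",
         paste(score[bad], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(score))) {
    message(sum(is.na(score)), " subject(s) lost to follow-up (missing GOS-E)")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score >= 4, "favorable", "unfavorable"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration over the feasible cell range:
#' with all margins fixed, p is the sum of hypergeometric point probabilities
#' of every table whose point probability does not exceed that of the
#' observed table (point-probability rule, the convention of mainstream
#' statistical software; relative tolerance 1e-7 absorbs floating-point
#' ties). A table with any zero margin is degenerate and returns p = 1.
#'
#' @param table 2x2 matrix (or 4-vector, row-major) of non-negative integer
#'   counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 4, 1, 31), 2, byrow = TRUE))  # ~0.014
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4 || any(x < 0) || any(x != round(x))) {
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  }
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    message("degenerate 2x2 table (zero margin): p = 1")
    return(1.0)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni-adjusted significance threshold
#' @param family_alpha Family-wise alpha.
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The adjusted per-comparison threshold (unrounded; conventionally
#'   reported to 4 decimals, e.g. 0.05/3 -> 0.0167).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1", call. = FALSE)
  family_alpha / n_comparisons
}

# favorable/unfavorable counts for a subset of records (followed-up only)
outcome_counts <- function(records) {
  g <- records[!is.na(records$gose_6mo), , drop = FALSE]
  out <- suppressMessages(dichotomize_gose(g$gose_6mo))
  c(favorable = sum(out == "favorable"), unfavorable = sum(out == "unfavorable"))
}

#' Prognosis comparison between CMD and true-DOC groups
#'
#' Dichotomizes 6-month GOS-E outcomes and compares favorable/unfavorable
#' proportions with the exact test: CMD vs all true DOC, plus the three
#' pairwise comparisons among true VS/UWS, true MCS- and CMD, the latter
#' against a Bonferroni-adjusted threshold of `family_alpha / 3`. Subjects
#' lost to follow-up are excluded from these tables only.
#'
#' @param records A `subject_records` data frame.
#' @param family_alpha Family-wise alpha for the pairwise family.
#' @return A `prognosis_report`: list with `tables` (named list of 2x2
#'   matrices), `p_values`, `bonferroni_threshold`, `groups` (outcome counts
#'   per group). Comparisons with an empty group are skipped with a warning.
#' @export
prognosis_analysis <- function(records, family_alpha = 0.05) {
  is_cmd <- records$cmd_status == "CMD"
  is_true_doc <- records$cmd_status == "true_DOC"
  groups <- list(
    CMD = outcome_counts(records[is_cmd, , drop = FALSE]),
    true_DOC = outcome_counts(records[is_true_doc, , drop = FALSE]),
    true_VS_UWS = outcome_counts(
      records[is_true_doc & records$diagnosis == "VS/UWS", , drop = FALSE]),
    true_MCS_minus = outcome_counts(
      records[is_true_doc & records$diagnosis == "MCS-", , drop = FALSE])
  )
  comparisons <- list(
    CMD_vs_true_DOC = c("CMD", "true_DOC"),
    true_VS_UWS_vs_CMD = c("true_VS_UWS", "CMD"),
    true_VS_UWS_vs_true_MCS_minus = c("true_VS_UWS", "true_MCS_minus"),
    true_MCS_minus_vs_CMD = c("true_MCS_minus", "CMD")
  )
  tables <- list()
  p_values <- c()
  for (nm in names(comparisons)) {
    g1 <- groups[[comparisons[[nm]][1]]]
    g2 <- groups[[comparisons[[nm]][2]]]
    if (sum(g1) == 0 || sum(g2) == 0) {
      warning("comparison ", nm, " skipped: a group has no followed-up members",
              call. = FALSE)
      next
    }
    tab <- rbind(g1, g2)
    rownames(tab) <- comparisons[[nm]]
    tables[[nm]] <- tab
    p_values[nm] <- fisher_exact_2x2(tab)
  }
  structure(
    list(tables = tables, p_values = p_values,
         bonferroni_threshold = bonferroni_alpha(family_alpha, 3),
         groups = groups),
    class = "prognosis_report"
  )
}

#' @export
print.prognosis_report <- function(x, ...) {
  cat("Prognosis (favorable = GOS-E >= 4, followed-up subjects only)\n")
  for (nm in names(x$p_values)) {
    tab <- x$tables[[nm]]
    cat(sprintf("  %s: %d/%d vs %d/%d, P = %.3f\n", nm,
                tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ]),
                round(x$p_values[[nm]], 3)))
  }
  cat(sprintf("  Bonferroni threshold for pairwise family: P < %.4f\n",
              round(x$bonferroni_threshold, 4)))
  invisible(x)
}
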