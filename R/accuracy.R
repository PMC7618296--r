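#' Read a test accuracy table
#'
#' Loads a delimited table of diagnostic test accuracy (sensitivity and
#' specificity with 95% confidence bounds) by test and age group. The bundled
#' default holds the accuracy of the CA125 35 U/mL cut-off and of the Ovatools
#' risk model at the 1% and 3% risk thresholds, stratified by age (under 50 /
#' 50 and over), together with the age-invariant pelvic ultrasound (USS)
#' accuracy used in UK ovarian-cancer pathway evaluations.
#'
#' @param path Path to a CSV with columns `test_id`, `age_group`,
#'   `threshold_label`, `sensitivity`, `sens_low`, `sens_high`,
#'   `specificity`, `spec_low`, `spec_high`. Defaults to the bundled table.
#' @return A data frame of class `accuracy_table`.
#' @export
read_accuracy_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "test_accuracy.csv", package = "ovatriage")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("accuracy table not found: ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("test_id", "age_group", "threshold_label",
                "sensitivity", "specificity")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("accuracy table lacks columns: ", paste(missing, collapse = ", "))
  }
  prob_cols <- intersect(
    c("sensitivity", "sens_low", "sens_high",
      "specificity", "spec_low", "spec_high"),
    names(tab)
  )
  for (cl in prob_cols) {
    v <- tab[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("accuracy column out of [0,1]: ", cl)
    }
  }
  if (all(c("sens_low", "sens_high") %in% names(tab))) {
    bad <- !is.na(tab$sens_low) &
      (tab$sens_low > tab$sensitivity | tab$sensitivity > tab$sens_high)
    if (any(bad)) stop("sensitivity outside its CI in accuracy table")
  }
  if (all(c("spec_low", "spec_high") %in% names(tab))) {
    bad <- !is.na(tab$spec_low) &
      (tab$spec_low > tab$specificity | tab$specificity > tab$spec_high)
    if (any(bad)) stop("specificity outside its CI in accuracy table")
  }
  class(tab) <- c("accuracy_table", class(tab))
  tab
}

#' Look up test accuracy
#'
#' Returns the stored sensitivity/specificity (and CIs) of a test for an age
#' group at a threshold. USS accuracy is age-invariant: the `ALL` row is
#' returned whatever age group is requested. The age-adjusted CA125 threshold
#' test (`AGE_ADJ_CA125`) is, by default, accuracy-matched to Ovatools at the
#' corresponding risk level, so it resolves to the `OVATOOLS` rows unless the
#' table carries explicit `AGE_ADJ_CA125` rows (an override table may be
#' supplied when threshold-specific accuracy is available).
#'
#' @param test_id One of `"CA125_35"`, `"OVATOOLS"`, `"AGE_ADJ_CA125"`, `"USS"`.
#' @param age_group `"UNDER50"`, `"GE50"` or `"ALL"`.
#' @param threshold_label Threshold label as stored, e.g. `"35 U/mL"`, `"1%"`,
#'   `"3%"`. May be omitted when the test has a single row for the age group.
#' @param table An `accuracy_table`; defaults to the bundled one.
#' @return A one-row list with `sensitivity`, `specificity` and CI bounds.
#' @export
get_accuracy <- function(test_id, age_group, threshold_label = NULL,
                         table = read_accuracy_table()) {
  lookup_id <- test_id
  if (identical(test_id, "AGE_ADJ_CA125") &&
      !any(table$test_id == "AGE_ADJ_CA125")) {
    lookup_id <- "OVATOOLS"
  }
  rows <- table[table$test_id == lookup_id, , drop = FALSE]
  if (identical(lookup_id, "USS")) {
    rows <- rows[rows$age_group == "ALL", , drop = FALSE]
  } else {
    rows <- rows[rows$age_group == age_group, , drop = FALSE]
  }
  if (!is.null(threshold_label) && nrow(rows) > 1) {
    rows <- rows[rows$threshold_label == threshold_label, , drop = FALSE]
  } else if (!is.null(threshold_label) && nrow(rows) == 1 &&
             !identical(lookup_id, "USS") &&
             !identical(rows$threshold_label, threshold_label)) {
    rows <- rows[rows$threshold_label == threshold_label, , drop = FALSE]
  }
  if (nrow(rows) != 1) {
    stop(sprintf(
      "no accuracy entry for (%s, %s, %s)",
      test_id, age_group,
      if (is.null(threshold_label)) "<default>" else threshold_label
    ))
  }
  as.list(rows[1, , drop = FALSE])
}

#' Fit a binormal ROC curve through Ovatools operating points
#'
#' The accuracy of the Ovatools risk score is printed at two risk thresholds
#' per age group. To sweep intermediate thresholds the package fits the
#' standard binormal ROC form, TPR = pnorm(a + b * qnorm(FPR)), through the
#' anchor operating points, and indexes the operating point by the log risk
#' threshold: qnorm(FPR) is linearly interpolated (and extrapolated) against
#' log(risk threshold) through the anchors. With exactly two anchors both
#' relations are determined exactly.
#'
#' @param anchors Data frame with columns `risk` (risk threshold, fraction),
#'   `sensitivity`, `specificity`; at least two rows with distinct FPR.
#' @param age_group Optional label carried on the curve.
#' @return An object of class `roc_curve` with elements `a`, `b`, `anchors`.
#' @export
build_binormal_roc <- function(anchors, age_group = NULL) {
  stopifnot(is.data.frame(anchors),
            all(c("risk", "sensitivity", "specificity") %in% names(anchors)))
  if (nrow(anchors) < 2) stop("need at least two anchor operating points")
  fpr <- 1 - anchors$specificity
  tpr <- anchors$sensitivity
  if (any(fpr <= 0 | fpr >= 1 | tpr <= 0 | tpr >= 1)) {
    stop("degenerate anchor: FPR and TPR must lie strictly in (0, 1)")
  }
  if (anyDuplicated(signif(fpr, 12))) {
    stop("degenerate anchor: anchors share the same FPR")
  }
  if (any(anchors$risk <= 0)) stop("risk thresholds must be positive")
  zf <- stats::qnorm(fpr)
  zt <- stats::qnorm(tpr)
  lr <- log(anchors$risk)
  if (nrow(anchors) == 2) {
    b <- (zt[1] - zt[2]) / (zf[1] - zf[2])
    a <- zt[1] - b * zf[1]
    # zf vs log-risk line
    s <- (zf[2] - zf[1]) / (lr[2] - lr[1])
    i <- zf[1] - s * lr[1]
  } else {
    fit <- stats::lm.fit(cbind(1, zf), zt)
    a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
    fit2 <- stats::lm.fit(cbind(1, lr), zf)
    i <- unname(fit2$coefficients[1]); s <- unname(fit2$coefficients[2])
  }
  if (b <= 0) stop("anchors imply a non-increasing ROC (b <= 0)")
  structure(
    list(a = a, b = b, risk_slope = s, risk_intercept = i,
         anchors = anchors, age_group = age_group),
    class = "roc_curve"
  )
}

#' Interpolate Ovatools accuracy at an arbitrary risk threshold
#'
#' Evaluates a fitted binormal ROC curve at a risk threshold. Thresholds
#' outside the calibrated sweep range (0.6%-4%) are extrapolated with a
#' warning. At an anchor threshold the anchor's operating point is returned
#' exactly.
#'
#' @param curve A `roc_curve` from [build_binormal_roc()].
#' @param risk_threshold Risk threshold(s), fractions in (0, 1].
#' @return Data frame with `risk`, `sensitivity`, `specificity`.
#' @export
roc_interpolate <- function(curve, risk_threshold) {
  stopifnot(inherits(curve, "roc_curve"))
  if (any(risk_threshold <= 0)) stop("invalid risk threshold: must be > 0")
  if (any(risk_threshold < 0.006 | risk_threshold > 0.04)) {
    warning("risk threshold outside the calibrated sweep range [0.006, 0.04]; extrapolating")
  }
  zf <- curve$risk_intercept + curve$risk_slope * log(risk_threshold)
  fpr <- stats::pnorm(zf)
  tpr <- stats::pnorm(curve$a + curve$b * zf)
  data.frame(risk = risk_threshold, sensitivity = tpr, specificity = 1 - fpr)
}

#' Default Ovatools ROC curve for an age group
#'
#' Convenience wrapper: builds the binormal curve through the two printed
#' Ovatools operating points (1% and 3% risk) for the requested age group.
#'
#' @inheritParams get_accuracy
#' @export
ovatools_roc <- function(age_group, table = read_accuracy_table()) {
  a1 <- get_accuracy("OVATOOLS", age_group, "1%", table)
  a3 <- get_accuracy("OVATOOLS", age_group, "3%", table)
  anchors <- data.frame(
    risk = c(0.01, 0.03),
    sensitivity = c(a1$sensitivity, a3$sensitivity),
    specificity = c(a1$specificity, a3$specificity)
  )
  build_binormal_roc(anchors, age_group = age_group)
}
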