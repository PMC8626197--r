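#' Round half away from zero
#'
#' Display rounding for error percentages; R's `round()` rounds half to
#' even, which is the wrong convention for printed error tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # the 1e-9 guard keeps values that are exactly .5 at full precision from
  # slipping below the threshold through floating-point representation
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Relative error between nominal and predicted values
#'
#' `100 * |predicted - nominal| / nominal`, in percent. Full precision is
#' returned; round with [round_half_up()] (one decimal) for display.
#' Scale-invariant: multiplying both values by the same positive factor
#' leaves the error unchanged.
#'
#' @param nominal Nominal (actual) values; must be nonzero.
#' @param predicted Predicted values.
#' @return Percent relative error(s), vectorized.
#' @examples
#' round_half_up(relative_error(3.1, 3.16)) # 1.9
#' @export
relative_error <- function(nominal, predicted) {
  if (any(nominal == 0)) {
    stop("relative error undefined for nominal value 0", call. = FALSE)
  }
  100 * abs(predicted - nominal) / abs(nominal)
}

#' Mean relative error over rows of an error table
#'
#' Arithmetic mean of per-row relative errors, at full precision; the
#' display convention is one decimal, half up.
#'
#' @param errors Numeric vector of per-row percent errors (e.g. from
#'   [relative_error()]).
#' @return Mean percent error.
#' @export
mean_error <- function(errors) {
  if (length(errors) == 0) stop("no rows supplied", call. = FALSE)
  mean(errors)
}

#' Per-row and mean relative-error table
#'
#' @param nominal,predicted Paired value vectors.
#' @return Data frame with `serial`, `nominal`, `predicted`, `error_pct`
#'   (display-rounded to one decimal), plus attribute `mean_error_pct`.
#' @export
error_table <- function(nominal, predicted) {
  stopifnot(length(nominal) == length(predicted), length(nominal) > 0)
  err <- relative_error(nominal, predicted)
  out <- data.frame(
    serial = seq_along(nominal),
    nominal = nominal,
    predicted = predicted,
    error_pct = round_half_up(err, 1)
  )
  attr(out, "mean_error_pct") <- round_half_up(mean_error(err), 1)
  out
}

#' Bundled nominal-vs-predicted comprehensive physiological values
#'
#' A ten-row benchmark of comprehensive physiological characteristic values
#' (unitless scalars summarizing a patient's vitals): the nominal value, the
#' value predicted from clustered detection data, and the error percentage
#' as originally reported. Row 3's reported error (6.5) differs from the
#' recomputed one (6.9); the table preserves the reported figure, and the
#' recomputation is left to [relative_error()].
#'
#' @return Data frame with columns `serial`, `nominal`, `predicted`,
#'   `reported_error_pct`.
#' @export
comprehensive_values <- function() {
  path <- system.file("extdata", "comprehensive_values.csv",
                      package = "vitalclust", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Nearest-centroid stand-in predictor of the comprehensive value
#'
#' The original predictive model binding feature-extraction data to the
#' diagnosis conclusion is not specified anywhere; this package supplies a
#' clearly-labelled stand-in that predicts the comprehensive scalar as the
#' mean first-coordinate value of the largest retained cluster.
#'
#' @param screen A `vc_screen` from [remove_anomalies()].
#' @param points The screened `vc_points` or matrix.
#' @return A single predicted value.
#' @export
centroid_predict <- function(screen, points) {
  stopifnot(inherits(screen, "vc_screen"))
  x <- if (inherits(points, "vc_points")) points$coords else
    as_point_matrix(points)
  if (length(screen$clusters) == 0) {
    stop("no retained clusters to predict from", call. = FALSE)
  }
  main <- screen$clusters[[which.max(lengths(screen$clusters))]]
  mean(x[main, 1])
}

#' Precision and recall of anomaly flagging against ground truth
#'
#' Scores flagged ids against the `ANOMALY` class of a truth table. When
#' nothing is flagged and no anomalies exist, precision is reported as 1
#' (nothing wrong was asserted); flagging nothing while anomalies exist
#' gives recall 0.
#'
#' @param truth Data frame with `record_id` and `label` (cluster index or
#'   `"ANOMALY"`), e.g. from [generate()].
#' @param flagged Character vector of record ids flagged as anomalous.
#' @return A `detection_score`: list with `precision`, `recall`,
#'   `n_true_anomalies`, `n_flagged`.
#' @export
score_detection <- function(truth, flagged) {
  stopifnot(is.data.frame(truth), all(c("record_id", "label") %in%
                                        names(truth)))
  unknown <- setdiff(flagged, truth$record_id)
  if (length(unknown) > 0) {
    stop("flagged ids not in truth: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  anomalies <- truth$record_id[truth$label == "ANOMALY"]
  tp <- length(intersect(flagged, anomalies))
  precision <- if (length(flagged) == 0) {
    if (length(anomalies) == 0) 1 else 0
  } else {
    tp / length(flagged)
  }
  recall <- if (length(anomalies) == 0) 1 else tp / length(anomalies)
  structure(
    list(precision = precision, recall = recall,
         n_true_anomalies = length(anomalies), n_flagged = length(flagged)),
    class = "detection_score"
  )
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf(
    "detection_score: precision %.3f, recall %.3f (%d true, %d flagged)\n",
    x$precision, x$recall, x$n_true_anomalies, x$n_flagged
  ))
  invisible(x)
}
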