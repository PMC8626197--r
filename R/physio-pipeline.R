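#' Default clinical reference ranges
#'
#' Adult resting reference ranges used to judge deviations of retained
#' clusters: systolic 90--140 mmHg (target 120), diastolic 60--90 mmHg
#' (target 80), temperature 36.1--37.2 degC (target 36.8), pulse 60--100
#' beats/min (target 72).
#'
#' @return Data frame with columns `vital`, `low`, `high`, `target`.
#' @export
default_reference_ranges <- function() {
  data.frame(
    vital = c("systolic", "diastolic", "temperature", "pulse"),
    low = c(90, 60, 36.1, 60),
    high = c(140, 90, 37.2, 100),
    target = c(120, 80, 36.8, 72),
    stringsAsFactors = FALSE
  )
}

# ISO-8601 with either "T" or space separator; POSIXct in UTC
parse_iso_times <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  tryCatch(
    suppressWarnings(as.POSIXct(x, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%d"))),
    error = function(e) as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  )
}

validate_ranges <- function(ranges) {
  need <- c("vital", "low", "high", "target")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges))) {
    stop("ranges must be a data frame with columns vital, low, high, target",
         call. = FALSE)
  }
  bad <- ranges$low >= ranges$high | ranges$target < ranges$low |
    ranges$target > ranges$high
  if (any(bad)) {
    stop("invalid reference range for: ",
         paste(ranges$vital[bad], collapse = ", "), call. = FALSE)
  }
  ranges
}

#' Turn vital-sign records into feature-space points
#'
#' Each record becomes one data point whose coordinates are the selected
#' vital values in the declared order; coordinate values equal the measured
#' body data (raw units) unless `standardize` z-scores each vital.
#' Acquisition time is carried along as metadata and never enters the
#' distance. Records with a missing or non-finite selected vital are
#' rejected with a logged reason, not silently dropped.
#'
#' @param records Data frame of vital records (columns `subject_id`, `time`,
#'   and the vitals; an optional `record_id` column supplies point ids).
#' @param vitals Character vector of vital columns to use, in order.
#' @param standardize Z-score each coordinate column. A constant column has
#'   no z-score and raises an error.
#' @return A `vc_points` object: list with `coords` (matrix, row names =
#'   record ids), `time` (POSIXct), `rejected` (data frame of id + reason).
#' @export
featurize <- function(records,
                      vitals = c("systolic", "diastolic", "temperature",
                                 "pulse"),
                      standardize = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(vitals, names(records))
  if (length(missing_cols) > 0) {
    stop("selected vitals absent from records: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if ("record_id" %in% names(records)) {
    as.character(records$record_id)
  } else {
    as.character(seq_len(nrow(records)))
  }

  m <- as.matrix(records[, vitals, drop = FALSE])
  storage.mode(m) <- "double"
  ok <- apply(m, 1, function(r) all(is.finite(r)) && all(r > 0))
  rejected <- data.frame(
    record_id = ids[!ok],
    reason = rep("missing or non-finite vital", sum(!ok)),
    stringsAsFactors = FALSE
  )
  if (nrow(rejected) > 0) {
    message("featurize: rejected ", nrow(rejected), " record(s)")
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) stop("no valid records after featurization", call. = FALSE)
  rownames(m) <- ids[ok]

  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) {
      stop("cannot standardize zero-variance vital(s): ",
           paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "),
           call. = FALSE)
    }
    m <- scale(m)[, , drop = FALSE]
    rownames(m) <- ids[ok]
  }

  tm <- if ("time" %in% names(records)) {
    parse_iso_times(records$time[ok])
  } else {
    NULL
  }
  structure(
    list(coords = m, time = tm, rejected = rejected),
    class = "vc_points"
  )
}

#' @export
print.vc_points <- function(x, ...) {
  cat(sprintf("vc_points: %d points x %d vitals (%s); %d rejected\n",
              nrow(x$coords), ncol(x$coords),
              paste(colnames(x$coords), collapse = ", "), nrow(x$rejected)))
  invisible(x)
}

#' Eliminate anomalous readings by density clustering
#'
#' Clusters the points (plain [dbscan()], or the partitioned scheme when a
#' partitioning config is given) and returns the dense clusters as the
#' useful data; noise points are the isolated readings regarded as abnormal
#' and eliminated from further analysis.
#'
#' @param points A `vc_points` object or point matrix.
#' @param params [dbscan_params()].
#' @param partitioning Optional list with `n_partitions`, `overlap_width`
#'   and optionally per-partition `eps`; `NULL` (or `n_partitions = 1`)
#'   selects the unpartitioned path.
#' @param trace_file Optional merge-trace path, passed to [merge_all()].
#' @return A `vc_screen` object: list with `clusters` (named list of id
#'   vectors), `anomalies` (noise ids), and `result` (the `vc_clustering`).
#'   If every point is noise the retained set is empty, with a warning.
#' @export
remove_anomalies <- function(points, params, partitioning = NULL,
                             trace_file = NULL) {
  x <- if (inherits(points, "vc_points")) points$coords else points
  x <- as_point_matrix(x)
  if (is.null(partitioning) || partitioning$n_partitions <= 1) {
    result <- dbscan(x, params)
  } else {
    eps_i <- if (!is.null(partitioning$eps)) partitioning$eps else params$eps
    parts <- partition_data(x, partitioning$n_partitions,
                            overlap_width = partitioning$overlap_width %||% 0,
                            eps = eps_i, cuts = partitioning$cuts)
    result <- merge_all(x, parts, params$min_pts, trace_file = trace_file)
  }
  clusters <- cluster_members(result)
  anomalies <- noise_ids(result)
  if (length(clusters) == 0) {
    warning("all points were classified as noise; no clusters retained",
            call. = FALSE)
  }
  structure(
    list(clusters = clusters, anomalies = anomalies, result = result),
    class = "vc_screen"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vc_screen <- function(x, ...) {
  cat(sprintf("vc_screen: %d cluster(s) retained, %d anomalies flagged\n",
              length(x$clusters), length(x$anomalies)))
  invisible(x)
}

#' Compare retained clusters against reference ranges
#'
#' The representative of the patient's dominant physiological state is the
#' per-vital mean of the largest retained cluster. Its signed deviation from
#' each reference target and an in-range flag against [low, high] form the
#' deviation report that drives diagnosis.
#'
#' @param screen A `vc_screen` from [remove_anomalies()].
#' @param points The `vc_points` (or matrix) that was screened.
#' @param ranges Reference ranges (see [default_reference_ranges()]); must
#'   cover every featurized vital.
#' @return A `vc_deviation_report`: list with `vitals` (data frame of
#'   `vital`, `representative`, `deviation`, `in_range`), `n_retained`,
#'   `n_anomalies`.
#' @export
deviation_report <- function(screen, points, ranges =
                               default_reference_ranges()) {
  stopifnot(inherits(screen, "vc_screen"))
  ranges <- validate_ranges(ranges)
  x <- if (inherits(points, "vc_points")) points$coords else
    as_point_matrix(points)
  if (length(screen$clusters) == 0) {
    stop("no retained clusters: review eps/min_pts before diagnosing",
         call. = FALSE)
  }
  uncovered <- setdiff(colnames(x), ranges$vital)
  if (length(uncovered) > 0) {
    stop("no reference range for vital(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  sizes <- lengths(screen$clusters)
  main <- screen$clusters[[which.max(sizes)]] # first largest on ties
  rep_vals <- colMeans(x[main, , drop = FALSE])

  idx <- match(colnames(x), ranges$vital)
  vit <- data.frame(
    vital = colnames(x),
    representative = unname(rep_vals),
    deviation = unname(rep_vals) - ranges$target[idx],
    in_range = unname(rep_vals) >= ranges$low[idx] &
      unname(rep_vals) <= ranges$high[idx],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      vitals = vit,
      n_retained = sum(sizes),
      n_anomalies = length(screen$anomalies),
      insufficient = FALSE
    ),
    class = "vc_deviation_report"
  )
}

#' @export
print.vc_deviation_report <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("vc_deviation_report: insufficient data in window (",
        x$n_records, " record(s))\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("vc_deviation_report: %d retained, %d anomalies\n",
              x$n_retained, x$n_anomalies))
  for (i in seq_len(nrow(x$vitals))) {
    r <- x$vitals[i, ]
    cat(sprintf("  %-12s %8.2f  deviation %+7.2f  %s\n", r$vital,
                r$representative, r$deviation,
                if (r$in_range) "in range" else "OUT OF RANGE"))
  }
  invisible(x)
}

#' Severity profile controlling parameter adaptation and windowing
#'
#' For severe patients the clustering is tightened (more measurements, a
#' larger MinPts, a reduced radius) so the current physiological state is
#' estimated more strictly; for chronic patients the observation period is
#' extended and split into several time windows analysed separately.
#'
#' @param level `"NORMAL"`, `"SEVERE"` or `"CHRONIC"`.
#' @param n_windows Number of consecutive analysis windows (> 1 for
#'   CHRONIC).
#' @param window_length Window length in seconds; `NULL` divides the record
#'   span evenly.
#' @param minpts_scale Multiplier for MinPts under SEVERE; > 1.
#' @param eps_scale Multiplier for eps under SEVERE; in (0, 1).
#' @return A `severity_profile` object.
#' @export
severity_profile <- function(level = c("NORMAL", "SEVERE", "CHRONIC"),
                             n_windows = 1, window_length = NULL,
                             minpts_scale = 1.5, eps_scale = 0.8) {
  level <- match.arg(level)
  if (level == "SEVERE" && (minpts_scale <= 1 || eps_scale >= 1 ||
                            eps_scale <= 0)) {
    stop("SEVERE requires minpts_scale > 1 and eps_scale in (0, 1)",
         call. = FALSE)
  }
  if (level == "CHRONIC" && n_windows <= 1) {
    stop("CHRONIC requires n_windows > 1", call. = FALSE)
  }
  structure(
    list(level = level, n_windows = as.integer(n_windows),
         window_length = window_length, minpts_scale = minpts_scale,
         eps_scale = eps_scale),
    class = "severity_profile"
  )
}

#' Adapt clustering parameters to the patient's condition
#'
#' SEVERE increases MinPts (`ceiling(min_pts * minpts_scale)`) and reduces
#' the radius (`eps * eps_scale`); NORMAL leaves the parameters untouched;
#' CHRONIC changes only the windowing, not the parameters.
#'
#' @param base [dbscan_params()].
#' @param profile [severity_profile()].
#' @return Adapted [dbscan_params()].
#' @export
adapt_parameters <- function(base, profile) {
  stopifnot(inherits(base, "dbscan_params"),
            inherits(profile, "severity_profile"))
  if (profile$level != "SEVERE") return(base)
  mp <- as.integer(ceiling(base$min_pts * profile$minpts_scale))
  if (mp < 1) stop("adapted min_pts would fall below 1", call. = FALSE)
  dbscan_params(base$eps * profile$eps_scale, mp)
}

#' One unwindowed pass: featurize, screen, report
#'
#' @inheritParams featurize
#' @inheritParams remove_anomalies
#' @inheritParams deviation_report
#' @return A `vc_deviation_report`.
#' @export
vital_pipeline <- function(records, params,
                           ranges = default_reference_ranges(),
                           vitals = c("systolic", "diastolic", "temperature",
                                      "pulse"),
                           standardize = FALSE, partitioning = NULL) {
  pts <- featurize(records, vitals = vitals, standardize = standardize)
  screen <- remove_anomalies(pts, params, partitioning = partitioning)
  deviation_report(screen, pts, ranges)
}

insufficient_report <- function(n_records) {
  structure(
    list(vitals = NULL, n_retained = 0L, n_anomalies = 0L,
         n_records = n_records, insufficient = TRUE),
    class = "vc_deviation_report"
  )
}

#' Analyse a record stream over consecutive time windows
#'
#' Splits the records into `n_windows` contiguous, equal-length,
#' non-overlapping windows (length `window_length` seconds from the first
#' timestamp, or the record span divided evenly when `NULL`), runs the
#' anomaly-elimination and deviation pipeline in each, and returns the
#' reports chronologically. Running the algorithm over multiple periods
#' tracks a chronic patient's state over a long time. A window with fewer
#' than `min_pts` records is flagged insufficient rather than failing.
#'
#' @inheritParams vital_pipeline
#' @param profile [severity_profile()]; its level also adapts the
#'   parameters via [adapt_parameters()].
#' @return List of `vc_deviation_report`, one per window, each carrying
#'   `window`, `window_start`, `window_end` fields.
#' @export
windowed_analysis <- function(records, profile, params,
                              ranges = default_reference_ranges(),
                              vitals = c("systolic", "diastolic",
                                         "temperature", "pulse"),
                              standardize = FALSE, partitioning = NULL) {
  stopifnot(inherits(profile, "severity_profile"))
  params <- adapt_parameters(params, profile)
  times <- parse_iso_times(records$time)
  if (any(is.na(times))) stop("unparseable timestamps", call. = FALSE)
  t0 <- min(times)
  nw <- profile$n_windows
  len <- profile$window_length %||%
    (as.numeric(difftime(max(times), t0, units = "secs")) / nw)
  breaks <- t0 + seq(0, by = len, length.out = nw + 1)
  idx <- findInterval(times, breaks, rightmost.closed = TRUE)
  outside <- idx < 1 | idx > nw
  if (any(outside)) {
    message("windowed_analysis: ", sum(outside),
            " record(s) fall outside the analysis windows")
  }

  lapply(seq_len(nw), function(w) {
    sub <- records[idx == w, , drop = FALSE]
    rep <- if (nrow(sub) < params$min_pts) {
      insufficient_report(nrow(sub))
    } else {
      vital_pipeline(sub, params, ranges = ranges, vitals = vitals,
                     standardize = standardize, partitioning = partitioning)
    }
    rep$window <- w
    rep$window_start <- breaks[w]
    rep$window_end <- breaks[w + 1]
    rep
  })
}

#' Derive findings from a deviation report
#'
#' Emits one finding per out-of-range vital: which vital, whether its
#' representative lies above or below the reference range, and the
#' magnitude of its deviation from the target. All vitals in range gives an
#' empty finding list.
#'
#' @param report A `vc_deviation_report`.
#' @param ranges The reference ranges the report was built against.
#' @return Data frame with columns `vital`, `direction`, `magnitude`
#'   (zero rows when nothing is out of range).
#' @export
diagnose <- function(report, ranges = default_reference_ranges()) {
  stopifnot(inherits(report, "vc_deviation_report"))
  ranges <- validate_ranges(ranges)
  empty <- data.frame(vital = character(0), direction = character(0),
                      magnitude = numeric(0), stringsAsFactors = FALSE)
  if (isTRUE(report$insufficient) || is.null(report$vitals)) return(empty)
  v <- report$vitals
  out <- v[!v$in_range, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  idx <- match(out$vital, ranges$vital)
  data.frame(
    vital = out$vital,
    direction = ifelse(out$representative > ranges$high[idx], "above",
                       "below"),
    magnitude = abs(out$deviation),
    stringsAsFactors = FALSE
  )
}
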