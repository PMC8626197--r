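#' Specification for a synthetic vital-sign dataset
#'
#' Describes dense Gaussian clusters of normal vitals plus sparse isolated
#' anomalous readings, the structure the screening pipeline is built for.
#' The default preset is one cluster of 60 records around typical adult
#' resting vitals — systolic 120 +/- 8 mmHg, diastolic 80 +/- 6 mmHg,
#' temperature 36.8 +/- 0.3 degC, pulse 72 +/- 6 beats/min — with three
#' anomalies placed at least 40 feature-space units from every cluster mean.
#'
#' @param clusters List of clusters, each a list with `mean` (named vector
#'   over the four vitals), `sd` (per-vital spread, > 0), `count` (> 0).
#' @param anomaly_count Number of injected anomalous readings, >= 0.
#' @param anomaly_offset Minimum Euclidean distance (raw feature units) of
#'   every anomaly from every cluster mean; > 0.
#' @param time_span Acquisition period in seconds; timestamps are uniform
#'   over it.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(clusters = NULL, anomaly_count = 3,
                           anomaly_offset = 40, time_span = 86400,
                           seed = 1) {
  if (is.null(clusters)) {
    clusters <- list(list(
      mean = c(systolic = 120, diastolic = 80, temperature = 36.8,
               pulse = 72),
      sd = c(systolic = 8, diastolic = 6, temperature = 0.3, pulse = 6),
      count = 60
    ))
  }
  for (cl in clusters) {
    stopifnot(cl$count > 0, all(cl$sd > 0), length(cl$mean) == length(cl$sd))
  }
  stopifnot(anomaly_count >= 0, anomaly_offset > 0, time_span > 0)
  structure(
    list(clusters = clusters, anomaly_count = as.integer(anomaly_count),
         anomaly_offset = anomaly_offset, time_span = time_span,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

draw_anomaly <- function(means, offset, sds, max_tries = 1000) {
  d <- length(sds)
  for (i in seq_len(max_tries)) {
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    cand <- means[[sample.int(length(means), 1)]] +
      dir * stats::runif(1, offset, 2 * offset)
    far <- all(vapply(means, function(m) sqrt(sum((cand - m)^2)) >= offset,
                      logical(1)))
    if (far && all(cand > 0)) return(cand)
  }
  stop("could not place an anomaly >= anomaly_offset from all cluster means",
       call. = FALSE)
}

#' Generate a labelled synthetic vital-sign dataset
#'
#' Draws each cluster's vitals from independent normal distributions around
#' the cluster mean, places anomalies at least `anomaly_offset` from every
#' cluster mean (verified at generation), and assigns timestamps uniformly
#' over the time span, sorted so acquisition time is monotone along the
#' record order. Identical seeds give identical datasets.
#'
#' @param spec A [generator_spec()].
#' @return A `vc_dataset`: list with `records` (data frame `record_id`,
#'   `subject_id`, `time`, one column per vital) and `truth` (data frame
#'   `record_id`, `label`, where `label` is a cluster index or
#'   `"ANOMALY"`).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  vitals <- names(spec$clusters[[1]]$mean)

  rows <- list()
  labels <- character(0)
  for (k in seq_along(spec$clusters)) {
    cl <- spec$clusters[[k]]
    m <- sapply(seq_along(cl$mean), function(j) {
      stats::rnorm(cl$count, cl$mean[j], cl$sd[j])
    })
    m <- matrix(m, nrow = cl$count)
    rows[[length(rows) + 1]] <- m
    labels <- c(labels, rep(as.character(k), cl$count))
  }
  means <- lapply(spec$clusters, `[[`, "mean")
  sds <- spec$clusters[[1]]$sd
  if (spec$anomaly_count > 0) {
    an <- t(vapply(seq_len(spec$anomaly_count), function(i) {
      draw_anomaly(means, spec$anomaly_offset, sds)
    }, numeric(length(vitals))))
    rows[[length(rows) + 1]] <- an
    labels <- c(labels, rep("ANOMALY", spec$anomaly_count))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- vitals
  n <- nrow(m)

  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  times <- t0 + sort(stats::runif(n, 0, spec$time_span))
  ids <- sprintf("r%04d", seq_len(n))

  records <- data.frame(
    record_id = ids, subject_id = "S1",
    time = format(times, "%Y-%m-%dT%H:%M:%S"),
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(m))
  truth <- data.frame(record_id = ids, label = labels,
                      stringsAsFactors = FALSE)

  # generation-time check of the ground-truth separation guarantee
  for (i in which(labels == "ANOMALY")) {
    stopifnot(all(vapply(means, function(mu) sqrt(sum((m[i, ] - mu)^2)) >=
                           spec$anomaly_offset, logical(1))))
  }
  structure(list(records = records, truth = truth), class = "vc_dataset")
}

#' @export
print.vc_dataset <- function(x, ...) {
  cat(sprintf("vc_dataset: %d records (%d anomalies)\n",
              nrow(x$records), sum(x$truth$label == "ANOMALY")))
  invisible(x)
}

#' Generate a dataset with a sparse cluster straddling a partition cut
#'
#' Adds to [generate()] one tight, sparse cluster centred (in the first
#' vital, the partitioning coordinate) exactly on `cut_coordinate`, with its
#' members alternating between the two sides of the cut. A balanced split of
#' `straddle_count` members leaves at most `ceiling(count/2)` per side, so
#' with MinPts above that the cluster dissolves into per-partition noise and
#' can only be recovered by pooled noise re-clustering.
#'
#' @param spec A [generator_spec()].
#' @param cut_coordinate First-vital value of the partition cut the sparse
#'   cluster must straddle.
#' @param straddle_count Members of the straddling cluster (default 6).
#' @param straddle_mean Named mean vector of the straddling cluster; its
#'   first entry is overridden by `cut_coordinate`. Defaults to the first
#'   cluster's mean shifted to the cut.
#' @param straddle_sd Per-vital spread of the straddling cluster (tight by
#'   default so the cluster is internally dense).
#' @return A `vc_dataset`; the straddling cluster gets its own truth label
#'   (one past the last spec cluster index).
#' @export
generate_partitioned <- function(spec, cut_coordinate, straddle_count = 6,
                                 straddle_mean = NULL, straddle_sd = NULL) {
  stopifnot(inherits(spec, "generator_spec"),
            straddle_count == 0 || straddle_count >= 2)
  base <- generate(spec)
  if (straddle_count == 0) return(base)
  vitals <- names(spec$clusters[[1]]$mean)
  if (is.null(straddle_mean)) {
    straddle_mean <- spec$clusters[[1]]$mean
    straddle_mean[1] <- cut_coordinate
  }
  if (is.null(straddle_sd)) {
    straddle_sd <- stats::setNames(rep(1, length(vitals)), vitals)
    straddle_sd["temperature"] <- 0.1
  }

  # alternate sides of the cut for a balanced split; first coordinate is
  # offset by |N(0, sd)| with the sign forced
  side <- rep(c(1, -1), length.out = straddle_count)
  first <- cut_coordinate + side * abs(stats::rnorm(straddle_count,
                                                    0, straddle_sd[1]))
  others <- sapply(seq_along(vitals)[-1], function(j) {
    stats::rnorm(straddle_count, straddle_mean[j], straddle_sd[j])
  })
  m <- cbind(first, matrix(others, nrow = straddle_count))
  colnames(m) <- vitals

  new_label <- as.character(length(spec$clusters) + 1L)
  n0 <- nrow(base$records)
  ids <- sprintf("r%04d", n0 + seq_len(straddle_count))
  t_last <- max(as.POSIXct(base$records$time, tz = "UTC"))
  times <- t_last + seq_len(straddle_count)

  add <- data.frame(
    record_id = ids, subject_id = "S1",
    time = format(times, "%Y-%m-%dT%H:%M:%S"),
    stringsAsFactors = FALSE
  )
  add <- cbind(add, as.data.frame(m))
  base$records <- rbind(base$records, add)
  base$truth <- rbind(base$truth,
                      data.frame(record_id = ids, label = new_label,
                                 stringsAsFactors = FALSE))
  base
}
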