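# Shared fixture builders and independent oracles for the test suite.

# Gaussian blob of n points around `center` (matrix rows are points)
blob <- function(n, center, sd = 0.1) {
  d <- length(center)
  m <- matrix(stats::rnorm(n * d, mean = rep(center, each = n), sd = sd),
              nrow = n)
  m
}

# Stack point matrices and assign ids "1".."n"
stack_points <- function(...) {
  m <- do.call(rbind, list(...))
  rownames(m) <- as.character(seq_len(nrow(m)))
  m
}

# Canonical labeling: clusters renumbered by first occurrence, noise -> 0.
# Two labelings equal up to relabeling iff their canonical forms are equal.
canon_labels <- function(labels) {
  out <- integer(length(labels))
  nxt <- 0L
  seen <- integer(0)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == 0L || l == -1L) next
    key <- as.character(l)
    if (is.na(seen[key])) {
      nxt <- nxt + 1L
      seen[key] <- nxt
    }
    out[i] <- seen[[key]]
  }
  out
}

# Brute-force mean of all cross distances between two id sets
brute_cross_mean <- function(e_a, e_b, x) {
  tot <- 0
  for (p in e_a) for (q in e_b) {
    tot <- tot + sqrt(sum((x[p, ] - x[q, ])^2))
  }
  tot / (length(e_a) * length(e_b))
}

# Independent reference DBSCAN (scikit-learn), run once over a batch of
# small instances; returns one data.frame(id, core, label) per instance.
run_reference_dbscan <- function(instances) {
  rows <- lapply(seq_along(instances), function(k) {
    inst <- instances[[k]]
    x <- inst$x
    d <- ncol(x)
    pad <- matrix(NA_real_, nrow(x), 4 - d)
    data.frame(instance = k, id = seq_len(nrow(x)), eps = inst$eps,
               min_pts = inst$min_pts,
               x1 = x[, 1],
               x2 = if (d >= 2) x[, 2] else NA_real_,
               x3 = if (d >= 3) x[, 3] else NA_real_,
               x4 = if (d >= 4) x[, 4] else NA_real_)
  })
  inp <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, rows), inp, row.names = FALSE)
  script <- system.file("oracle", "dbscan_oracle.py", package = "vitalclust")
  status <- system2("python", c(script, inp, out))
  stopifnot(status == 0)
  res <- utils::read.csv(out)
  lapply(seq_along(instances), function(k) res[res$instance == k, ])
}

# Small labelled vital-sign frame for pipeline tests
toy_records <- function(n = 10, systolic = 120) {
  data.frame(
    record_id = sprintf("t%02d", seq_len(n)),
    subject_id = "S1",
    time = format(as.POSIXct("2026-01-01", tz = "UTC") + seq_len(n) * 60,
                  "%Y-%m-%dT%H:%M:%S"),
    systolic = systolic + seq_len(n) * 0.01,
    diastolic = 80, temperature = 36.8, pulse = 72,
    stringsAsFactors = FALSE
  )
}
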