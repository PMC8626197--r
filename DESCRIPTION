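Package: vitalclust
Title: Partitioned Density-Based Clustering and Anomaly Screening for Vital-Sign Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Density-based clustering (DBSCAN) implemented from scratch for
    timestamped physiological records (blood pressure, body temperature,
    pulse), together with a partitioned variant that clusters axis-aligned
    data slabs locally and merges the local clusters across partition
    boundaries: a four-case rule for points clustered twice in an overlap
    zone, a mean boundary-distance criterion for clusters in adjacent
    non-overlapping partitions, absorption of boundary noise points into
    neighbouring classes, and re-clustering of residual noise so that a
    sparse cluster split by a cut is recovered as one class. On top of the
    clustering sits a vital-sign pipeline: featurization of records, anomaly
    elimination, comparison of retained clusters against clinical reference
    ranges, severity-dependent parameter adaptation, multi-window analysis,
    and relative-error evaluation utilities. Includes a seeded synthetic
    vital-sign generator with ground-truth labels and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
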