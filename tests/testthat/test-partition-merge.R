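test_that("a single partition spans everything with empty overlaps", {
  set.seed(21)
  x <- stack_points(matrix(rnorm(30), ncol = 3))
  parts <- partition_data(x, 1, overlap_width = 0, eps = 1)
  expect_length(parts, 1)
  expect_setequal(parts[[1]]$member_ids, rownames(x))
  expect_length(parts[[1]]$overlap_left, 0)
  expect_length(parts[[1]]$overlap_right, 0)
})

test_that("two disjoint partitions split a line of points at the median", {
  x <- stack_points(matrix(1:10, ncol = 1))
  parts <- partition_data(x, 2, overlap_width = 0, eps = 1)
  expect_setequal(parts[[1]]$member_ids, as.character(1:5))
  expect_setequal(parts[[2]]$member_ids, as.character(6:10))
  expect_equal(parts[[1]]$cut_right, 5.5)

  # overlap as wide as the data range puts interior points in both slabs
  wide <- partition_data(x, 2, overlap_width = 9, eps = 1)
  expect_setequal(intersect(wide[[1]]$member_ids, wide[[2]]$member_ids),
                  as.character(1:10))
  expect_error(partition_data(x, 11, 0, 1), "exceeds")
})

test_that("explicit cuts override quantile placement", {
  x <- stack_points(matrix(c(1, 2, 3, 100), ncol = 1))
  parts <- partition_data(x, 2, overlap_width = 0, eps = 1, cuts = 50)
  expect_setequal(parts[[1]]$member_ids, as.character(1:3))
  expect_setequal(parts[[2]]$member_ids, "4")
  expect_error(partition_data(x, 3, 0, 1, cuts = 50), "length")
})

test_that("clustering the whole dataset as one partition equals plain dbscan", {
  set.seed(22)
  x <- stack_points(blob(15, c(0, 0)), blob(15, c(4, 4)), c(20, 20))
  parts <- partition_data(x, 1, 0, eps = 1)
  lr <- cluster_partition(parts[[1]], x, min_pts = 4)
  plain <- dbscan(x, dbscan_params(1, 4))
  expect_equal(lr$result$labels, plain$labels)
  expect_setequal(lr$noise, noise_ids(plain))
})

test_that("local clusters on both sides of an overlapped cut share points", {
  set.seed(23)
  # dense blob centred on the cut, overlap wide enough to cover it
  x <- stack_points(blob(30, c(0, 0), sd = 0.3), blob(10, c(8, 0), sd = 0.2))
  parts <- partition_data(x, 2, overlap_width = 1.5, eps = 0.8, cuts = 0)
  la <- cluster_partition(parts[[1]], x, min_pts = 3)
  lb <- cluster_partition(parts[[2]], x, min_pts = 3)
  shared <- intersect(parts[[1]]$overlap_right, parts[[2]]$overlap_left)
  expect_gt(length(shared), 0)
  in_a <- unlist(lapply(la$clusters, `[[`, "members"))
  in_b <- unlist(lapply(lb$clusters, `[[`, "members"))
  expect_true(any(shared %in% in_a) && any(shared %in% in_b))
  # the far blob lives wholly right of the cut: no left-partition cluster
  far <- as.character(31:40)
  expect_false(any(far %in% parts[[1]]$member_ids))
})

test_that("the four overlap-zone cases give the stated verdicts", {
  A <- vitalclust:::local_cluster(1, 1, members = c("p", "a"),
                                  core_members = "a", boundary_set = "p")
  B <- vitalclust:::local_cluster(2, 1, members = c("p", "b"),
                                  core_members = "b", boundary_set = "p")
  cases <- list(
    list(ra = "CORE", rb = "BORDER", verdict = "MERGE"),
    list(ra = "BORDER", rb = "CORE", verdict = "MERGE"),
    list(ra = "CORE", rb = "CORE", verdict = "MERGE"),
    list(ra = "CORE", rb = "NOISE", verdict = "MERGE"),
    list(ra = "BORDER", rb = "BORDER", verdict = "ASSIGN_EITHER"),
    list(ra = "BORDER", rb = "NOISE", verdict = "ASSIGN_TO_ONE"),
    list(ra = "NOISE", rb = "BORDER", verdict = "ASSIGN_TO_ONE"),
    list(ra = "NOISE", rb = "NOISE", verdict = "NOISE")
  )
  for (cs in cases) {
    dec <- merge_overlap(if (cs$ra == "NOISE") NULL else A,
                         if (cs$rb == "NOISE") NULL else B,
                         "p", cs$ra, cs$rb)
    expect_equal(dec$verdict, cs$verdict)
    if (cs$verdict == "ASSIGN_TO_ONE") {
      expect_equal(dec$target$partition_id,
                   if (cs$ra != "NOISE") 1 else 2)
    }
  }
  expect_error(merge_overlap(NULL, B, "p", "BORDER", "NOISE"), "required")
  expect_error(merge_overlap(A, B, "zz", "BORDER", "BORDER"), "member")
})

test_that("the boundary merge statistic is the mean of all cross distances", {
  x <- stack_points(rbind(c(0, 0), c(3, 4), c(1, 0), c(0, 1)))
  one <- boundary_merge_test("1", "2", 6, 7, x)
  expect_equal(one$statistic, 5)
  expect_equal(one$verdict, "MERGE") # 5 <= min(6, 7)
  expect_equal(boundary_merge_test("1", "2", 4, 7, x)$verdict, "NOISE")
  expect_error(boundary_merge_test(character(0), "2", 1, 1, x), "non-empty")

  set.seed(24)
  for (i in 1:20) {
    y <- stack_points(matrix(rnorm(60), ncol = 3))
    e_a <- sample(rownames(y), sample(1:10, 1))
    e_b <- sample(setdiff(rownames(y), e_a), sample(1:10, 1))
    got <- boundary_merge_test(e_a, e_b, 1, 2, y)
    want <- brute_cross_mean(e_a, e_b, y)
    expect_equal(got$statistic, want, tolerance = 1e-12)
    # symmetry and the min/max pairwise bounds
    expect_equal(boundary_merge_test(e_b, e_a, 1, 2, y)$statistic,
                 got$statistic, tolerance = 1e-12)
    pair <- outer(e_a, e_b, Vectorize(function(p, q) {
      sqrt(sum((y[p, ] - y[q, ])^2))
    }))
    expect_gte(got$statistic, min(pair) - 1e-12)
    expect_lte(got$statistic, max(pair) + 1e-12)
  }
})

test_that("noise absorption uses the mean distance to the boundary set", {
  x <- stack_points(rbind(c(0, 0), c(0, 0), c(9, 0), c(0, 8)))
  expect_equal(absorb_noise("1", "2", 1, x)$verdict, "ASSIGN_TO_ONE")
  # every member farther than eps_next: the mean exceeds eps_next too
  far <- absorb_noise("1", c("3", "4"), 2, x)
  expect_equal(far$verdict, "NOISE")
  expect_error(absorb_noise("1", character(0), 1, x), "non-empty")

  set.seed(25)
  for (i in 1:20) {
    y <- stack_points(matrix(rnorm(40), ncol = 2))
    p <- sample(rownames(y), 1)
    e_c <- sample(setdiff(rownames(y), p), sample(1:10, 1))
    got <- absorb_noise(p, e_c, 0.5, y)$statistic
    want <- mean(vapply(e_c, function(q) sqrt(sum((y[p, ] - y[q, ])^2)),
                        numeric(1)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pooled residual noise recovers split sparse clusters", {
  expect_equal(recluster_noise(character(0), matrix(1), dbscan_params(1, 2)),
               list(clusters = list(), noise = character(0)))

  set.seed(26)
  # a tight 6-point cluster plus one far outlier, all arriving as noise
  x <- stack_points(blob(6, c(0, 0), sd = 0.05), c(30, 30))
  rec <- recluster_noise(rownames(x), x, dbscan_params(0.5, 4))
  expect_length(rec$clusters, 1)
  expect_setequal(rec$clusters[[1]]$members, as.character(1:6))
  expect_equal(rec$noise, "7")
})

test_that("merge_all with one partition reproduces dbscan exactly", {
  set.seed(27)
  for (i in 1:8) {
    x <- stack_points(matrix(rnorm(100), ncol = 2))
    eps <- runif(1, 0.4, 1)
    mp <- sample(2:5, 1)
    parts <- partition_data(x, 1, 0, eps = eps)
    got <- merge_all(x, parts, mp)
    want <- dbscan(x, dbscan_params(eps, mp))
    expect_equal(got$labels, want$labels)
    expect_equal(got$roles, want$roles)
  }
})

test_that("a blob whose core points straddle an overlapped cut is one class", {
  set.seed(28)
  x <- stack_points(blob(40, c(0, 0), sd = 0.4), blob(12, c(10, 0), sd = 0.2))
  parts <- partition_data(x, 2, overlap_width = 1, eps = 0.8, cuts = 0)
  g <- merge_all(x, parts, 4)
  main <- as.character(1:40)
  expect_equal(length(unique(g$labels[main])), 1)
  expect_true(all(g$labels[main] > 0))
  # consistency with plain dbscan up to relabeling
  plain <- dbscan(x, dbscan_params(0.8, 4))
  expect_equal(canon_labels(unname(g$labels)),
               canon_labels(unname(plain$labels)))
})

test_that("disjoint far-apart blobs in separate partitions stay separate", {
  set.seed(29)
  x <- stack_points(blob(15, c(0, 0)), blob(15, c(100, 0)))
  parts <- partition_data(x, 2, overlap_width = 0, eps = 1)
  g <- merge_all(x, parts, 4)
  expect_equal(max(g$labels), 2)
  expect_equal(length(unique(g$labels[as.character(1:15)])), 1)
  expect_equal(length(unique(g$labels[as.character(16:30)])), 1)
  expect_length(noise_ids(g), 0)
})

test_that("adjacent boundary-hugging clusters merge through the mean test", {
  # two tight clumps nudged against the cut from both sides; the mean
  # cross distance is below eps so they must fuse into one class
  x <- stack_points(
    cbind(c(-0.3, -0.2, -0.25, -0.15), c(0, 0.1, -0.1, 0)),
    cbind(c(0.3, 0.2, 0.25, 0.15), c(0, 0.1, -0.1, 0))
  )
  parts <- partition_data(x, 2, overlap_width = 0, eps = 0.6, cuts = 0)
  trace_file <- tempfile(fileext = ".tsv")
  g <- merge_all(x, parts, 3, trace_file = trace_file)
  expect_equal(max(g$labels), 1)
  expect_true(all(g$labels == 1))
  tr <- utils::read.delim(trace_file)
  expect_true(any(tr$phase == "boundary" & tr$verdict == "MERGE"))
  expect_true(all(tr$statistic[tr$verdict == "MERGE"] <=
                    tr$threshold[tr$verdict == "MERGE"]))
})

test_that("boundary noise points are absorbed into the neighboring class", {
  # cluster right of the cut; a lone point left of the cut is local noise
  # but lies within eps of the cluster's boundary set
  x <- stack_points(
    c(-0.2, 0),
    cbind(c(0.3, 0.35, 0.4, 0.45), c(0, 0.05, -0.05, 0))
  )
  parts <- partition_data(x, 2, overlap_width = 0, eps = 0.9, cuts = 0)
  g <- merge_all(x, parts, 3)
  expect_true(g$labels["1"] > 0)
  expect_equal(unname(g$labels["1"]), unname(g$labels["2"]))
  expect_equal(unname(g$roles["1"]), "BORDER")
})
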