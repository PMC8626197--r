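#' Slice a dataset into ordered partitions along the first coordinate
#'
#' Partitions are axis-aligned slabs `D_1 .. D_n` ordered by the first
#' feature coordinate, with cut positions at equal-frequency quantile
#' midpoints so every slab holds roughly the same number of points. When
#' `overlap_width > 0`, consecutive slabs additionally share exactly the
#' points whose first coordinate lies within `overlap_width` of the cut;
#' those points are clustered twice and drive the four-case overlap merge.
#' With `overlap_width = 0` the slabs are disjoint and merging falls back to
#' the mean boundary-distance criterion.
#'
#' @param x Point matrix or data frame (rows = points, row names = ids).
#' @param n_partitions Number of slabs, >= 1 and <= number of points.
#' @param overlap_width Half-width of the shared band around each cut, >= 0.
#' @param eps Per-partition neighborhood radius `Eps_i`; a single value is
#'   recycled, or a vector of length `n_partitions`.
#' @param cuts Optional explicit cut positions (ascending, length
#'   `n_partitions - 1`) overriding the quantile-midpoint placement, for
#'   callers that know the data distribution.
#' @return List of `vc_partition` objects, each with fields `id`, `eps`,
#'   `member_ids`, `cut_left`, `cut_right`, `overlap_left`, `overlap_right`.
#' @export
partition_data <- function(x, n_partitions, overlap_width = 0, eps,
                           cuts = NULL) {
  x <- as_point_matrix(x)
  n <- nrow(x)
  n_partitions <- as.integer(n_partitions)
  if (n_partitions < 1) stop("n_partitions must be >= 1", call. = FALSE)
  if (n_partitions > n) {
    stop("n_partitions (", n_partitions, ") exceeds number of points (", n,
         ")", call. = FALSE)
  }
  if (overlap_width < 0) stop("overlap_width must be >= 0", call. = FALSE)
  eps <- as.numeric(eps)
  if (length(eps) == 1) eps <- rep(eps, n_partitions)
  if (length(eps) != n_partitions || any(!is.finite(eps)) || any(eps <= 0)) {
    stop("eps must be one value or n_partitions values, all > 0",
         call. = FALSE)
  }

  v <- x[, 1]
  ids <- rownames(x)
  if (is.null(cuts)) {
    # cut k sits midway between the order statistics that split the sorted
    # first coordinate into equal-count blocks
    sv <- sort(v)
    cuts <- numeric(0)
    if (n_partitions > 1) {
      idx <- round(seq_len(n_partitions - 1) * n / n_partitions)
      idx <- pmin(pmax(idx, 1L), n - 1L)
      cuts <- unname((sv[idx] + sv[idx + 1L]) / 2)
    }
  } else {
    cuts <- as.numeric(cuts)
    if (length(cuts) != n_partitions - 1 || is.unsorted(cuts)) {
      stop("cuts must be ascending and of length n_partitions - 1",
           call. = FALSE)
    }
  }
  base_idx <- vapply(v, function(val) sum(val > cuts), numeric(1)) + 1L

  overlaps <- lapply(seq_along(cuts), function(k) {
    if (overlap_width > 0) ids[abs(v - cuts[k]) <= overlap_width]
    else character(0)
  })

  lapply(seq_len(n_partitions), function(i) {
    left <- if (i > 1) overlaps[[i - 1]] else character(0)
    right <- if (i < n_partitions) overlaps[[i]] else character(0)
    members <- unique(c(ids[base_idx == i], left, right))
    # preserve input row order for determinism
    members <- ids[ids %in% members]
    structure(
      list(
        id = i,
        eps = eps[i],
        member_ids = members,
        cut_left = if (i > 1) cuts[i - 1] else -Inf,
        cut_right = if (i < n_partitions) cuts[i] else Inf,
        overlap_left = left,
        overlap_right = right
      ),
      class = "vc_partition"
    )
  })
}

#' @export
print.vc_partition <- function(x, ...) {
  cat(sprintf(
    "vc_partition %d: %d points, eps = %g, slab (%g, %g]\n",
    x$id, length(x$member_ids), x$eps, x$cut_left, x$cut_right
  ))
  invisible(x)
}

local_cluster <- function(partition_id, cluster_id, members, core_members,
                          boundary_set) {
  structure(
    list(
      partition_id = partition_id, cluster_id = cluster_id,
      members = members, core_members = core_members,
      boundary_set = boundary_set
    ),
    class = "vc_local_cluster"
  )
}

merge_decision <- function(verdict, target = NULL, statistic = NA_real_) {
  stopifnot(verdict %in% c("MERGE", "ASSIGN_EITHER", "ASSIGN_TO_ONE", "NOISE"))
  structure(
    list(verdict = verdict, target = target, statistic = statistic),
    class = "vc_merge_decision"
  )
}

#' Cluster a single partition locally
#'
#' Runs [dbscan()] on the partition's members with the partition-local
#' radius `Eps_i`, and saves for every local cluster its boundary-object
#' set: the members lying within `Eps_i` of a (finite) partition cut plane.
#' These saved sets feed the cross-partition merge tests.
#'
#' @param partition A `vc_partition` from [partition_data()].
#' @param x The full point matrix.
#' @param min_pts Global minimum neighborhood population.
#' @return A `vc_local_result`: list with `partition_id`, `clusters` (list of
#'   `vc_local_cluster`), `noise` (ids), and `result` (the raw
#'   `vc_clustering` over the partition members).
#' @export
cluster_partition <- function(partition, x, min_pts) {
  stopifnot(inherits(partition, "vc_partition"))
  x <- as_point_matrix(x)
  sub <- x[partition$member_ids, , drop = FALSE]
  res <- dbscan(sub, dbscan_params(partition$eps, min_pts))

  near_cut <- function(ids) {
    v <- x[ids, 1]
    d <- pmin(abs(v - partition$cut_left), abs(v - partition$cut_right))
    ids[d <= partition$eps]
  }

  clusters <- lapply(cluster_members(res), function(members) {
    local_cluster(
      partition_id = partition$id,
      cluster_id = unname(res$labels[members[1]]),
      members = members,
      core_members = members[res$roles[members] == "CORE"],
      boundary_set = near_cut(members)
    )
  })
  structure(
    list(
      partition_id = partition$id,
      clusters = unname(clusters),
      noise = noise_ids(res),
      result = res
    ),
    class = "vc_local_result"
  )
}

#' Four-case merge rule for a point clustered twice in an overlap zone
#'
#' A point `p` in the overlap band between adjacent partitions has been
#' clustered once in each. The verdict follows four cases: if `p` is a core
#' object of class A or class B (or both), the two classes merge into one
#' cluster; if `p` is a border point in both, it may be assigned to either
#' class (no merge), resolved here deterministically to the class with the
#' lower `(partition_id, cluster_id)`; if `p` belongs to one class and is
#' noise in the other, it belongs to that class; if it is noise in both, it
#' is a noise point of the whole partition.
#'
#' @param A,B `vc_local_cluster` objects from the two partitions (`NULL`
#'   allowed when the corresponding role is `"NOISE"`).
#' @param p Point id clustered in both partitions' overlap zone.
#' @param role_in_A,role_in_B Role of `p` in each local clustering.
#' @return A `vc_merge_decision` with verdict `MERGE`, `ASSIGN_EITHER`,
#'   `ASSIGN_TO_ONE` (with `target`), or `NOISE`.
#' @export
merge_overlap <- function(A, B, p, role_in_A, role_in_B) {
  roles <- c("CORE", "BORDER", "NOISE")
  if (!(role_in_A %in% roles) || !(role_in_B %in% roles)) {
    stop("roles must be CORE, BORDER or NOISE", call. = FALSE)
  }
  chk <- function(cl, role, side) {
    if (role != "NOISE") {
      if (is.null(cl)) {
        stop("cluster ", side, " required when p is not noise there",
             call. = FALSE)
      }
      if (!(p %in% cl$members)) {
        stop("p is not a member of cluster ", side, call. = FALSE)
      }
    }
  }
  chk(A, role_in_A, "A")
  chk(B, role_in_B, "B")

  if (role_in_A == "CORE" || role_in_B == "CORE") {
    return(merge_decision("MERGE"))
  }
  if (role_in_A == "BORDER" && role_in_B == "BORDER") {
    return(merge_decision("ASSIGN_EITHER"))
  }
  if (role_in_A == "NOISE" && role_in_B == "NOISE") {
    return(merge_decision("NOISE"))
  }
  merge_decision("ASSIGN_TO_ONE",
                 target = if (role_in_A != "NOISE") A else B)
}

#' Mean boundary-distance merge test for clusters in adjacent partitions
#'
#' For classes in consecutive non-overlapping partitions no point is
#' clustered twice, so merging uses the saved boundary-object sets: the mean
#' of all cross distances between the two sets,
#' \eqn{\bar{d} = \sum_i \sum_j Dist(p_i, q_j) / (|E_A| \cdot |E_B|)},
#' and the classes merge iff \eqn{\bar{d} \le \min(Eps_i, Eps_j)}.
#'
#' @param e_a,e_b Non-empty boundary-object id sets of the two classes.
#' @param eps_i,eps_j The two partitions' radii.
#' @param x The full point matrix.
#' @return A `vc_merge_decision`: verdict `MERGE` when the mean is within
#'   the threshold, else `NOISE` (no action); `statistic` holds the mean.
#' @export
boundary_merge_test <- function(e_a, e_b, eps_i, eps_j, x) {
  if (length(e_a) == 0 || length(e_b) == 0) {
    stop("boundary object sets must be non-empty", call. = FALSE)
  }
  x <- as_point_matrix(x)
  da <- x[e_a, , drop = FALSE]
  db <- x[e_b, , drop = FALSE]
  cross <- outer(seq_len(nrow(da)), seq_len(nrow(db)),
                 Vectorize(function(i, j) sqrt(sum((da[i, ] - db[j, ])^2))))
  stat <- sum(cross) / (length(e_a) * length(e_b))
  thr <- min(eps_i, eps_j)
  merge_decision(if (stat <= thr) "MERGE" else "NOISE", statistic = stat)
}

#' Absorption test for a boundary noise point
#'
#' A noise point near the boundary of one partition may really be a border
#' point of a class in the next partition. It is absorbed into class C when
#' its mean distance to C's saved boundary set,
#' \eqn{\bar{d} = \sum_j Dist(p, q_j) / |E_C|}, is at most the neighboring
#' partition's radius.
#'
#' @param p Id of the noise point.
#' @param e_c Non-empty boundary-object id set of the candidate class C.
#' @param eps_next Radius of the partition holding C.
#' @param x The full point matrix.
#' @return A `vc_merge_decision`: `ASSIGN_TO_ONE` (target `e_c`'s class is
#'   resolved by the caller) when absorbed, else `NOISE`; `statistic` holds
#'   the mean distance.
#' @export
absorb_noise <- function(p, e_c, eps_next, x) {
  if (length(e_c) == 0) {
    stop("boundary object set E_C must be non-empty", call. = FALSE)
  }
  x <- as_point_matrix(x)
  q <- x[e_c, , drop = FALSE]
  stat <- mean(sqrt(rowSums((q - matrix(x[p, ], nrow(q), ncol(q),
                                        byrow = TRUE))^2)))
  merge_decision(if (stat <= eps_next) "ASSIGN_TO_ONE" else "NOISE",
                 statistic = stat)
}

#' Re-cluster residual noise points
#'
#' A sparse cluster split across a cut can leave fewer than `min_pts` points
#' per side, so both halves come out as local noise. Pooling all residual
#' noise and clustering it again (radius = the smallest partition radius)
#' recovers such a cluster as a new class; whatever still fails the density
#' test stays noise.
#'
#' @param noise_ids Ids of points still labelled noise after merging.
#' @param x The full point matrix.
#' @param params [dbscan_params()] for the pooled run.
#' @return List with `clusters` (list of `vc_local_cluster`, `partition_id
#'   = NA`) and `noise` (ids that remain noise). Empty input gives empty
#'   output.
#' @export
recluster_noise <- function(noise_ids, x, params) {
  if (length(noise_ids) == 0) {
    return(list(clusters = list(), noise = character(0)))
  }
  x <- as_point_matrix(x)
  res <- dbscan(x[noise_ids, , drop = FALSE], params)
  clusters <- lapply(cluster_members(res), function(members) {
    local_cluster(
      partition_id = NA_integer_,
      cluster_id = unname(res$labels[members[1]]),
      members = members,
      core_members = members[res$roles[members] == "CORE"],
      boundary_set = character(0)
    )
  })
  list(clusters = unname(clusters), noise = noise_ids(res))
}

# -- union-find over local-cluster keys --------------------------------------

uf_new <- function(keys) {
  env <- new.env(parent = emptyenv())
  env$parent <- stats::setNames(keys, keys)
  env
}

uf_find <- function(uf, k) {
  while (uf$parent[[k]] != k) {
    uf$parent[[k]] <- uf$parent[[uf$parent[[k]]]]
    k <- uf$parent[[k]]
  }
  k
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a)
  rb <- uf_find(uf, b)
  if (ra != rb) {
    # deterministic: smaller key string becomes the root
    if (ra < rb) uf$parent[[rb]] <- ra else uf$parent[[ra]] <- rb
  }
  invisible(uf)
}

cluster_key <- function(pid, cid) sprintf("P%06d.C%06d", pid, cid)

#' Merge locally clustered partitions into one global clustering
#'
#' Orchestrates the full partitioned scheme: per-partition clustering (done
#' by the caller or on demand), the four-case rule for every point in an
#' overlap zone, the mean boundary-distance merge for adjacent
#' non-overlapping partitions, absorption of boundary noise points, and
#' finally re-clustering of the pooled residual noise (radius
#' `min_i Eps_i`, global `min_pts`) so that split sparse clusters surface as
#' new classes. Merges are realized through a union-find over local
#' clusters; the result is deterministic given the inputs. With a single
#' partition the output equals plain [dbscan()] exactly.
#'
#' @param x The full point matrix or data frame.
#' @param partitions List of `vc_partition` from [partition_data()].
#' @param min_pts Global minimum neighborhood population.
#' @param local_results Optional list of `vc_local_result` (computed via
#'   [cluster_partition()] when omitted).
#' @param trace_file Optional path; when given, every cross-partition merge
#'   test is appended as a tab-separated row (pair, statistic, threshold,
#'   verdict) for auditability.
#' @return A global `vc_clustering` over all points, with cluster ids dense
#'   `1..k` ordered by each class's earliest core point in input order.
#' @export
merge_all <- function(x, partitions, min_pts, local_results = NULL,
                      trace_file = NULL) {
  x <- as_point_matrix(x)
  ids <- rownames(x)
  if (is.null(local_results)) {
    local_results <- lapply(partitions, cluster_partition, x = x,
                            min_pts = min_pts)
  }
  covered <- unique(unlist(lapply(partitions, `[[`, "member_ids")))
  if (!setequal(covered, ids)) {
    stop("inconsistent local results: partitions do not cover all points",
         call. = FALSE)
  }

  trace <- if (!is.null(trace_file)) {
    con <- file(trace_file, open = "wt")
    writeLines("phase\tleft\tright\tstatistic\tthreshold\tverdict", con)
    on.exit(close(con), add = TRUE)
    function(phase, left, right, stat, thr, verdict) {
      writeLines(sprintf("%s\t%s\t%s\t%.10g\t%.10g\t%s",
                         phase, left, right, stat, thr, verdict), con)
    }
  } else {
    function(...) invisible(NULL)
  }

  # bookkeeping: per point, which local clusters contain it; per local
  # cluster, its key, members and cores
  all_clusters <- list()
  for (lr in local_results) {
    for (cl in lr$clusters) {
      all_clusters[[cluster_key(cl$partition_id, cl$cluster_id)]] <- cl
    }
  }
  keys <- names(all_clusters)
  uf <- if (length(keys) > 0) uf_new(keys) else NULL

  membership <- stats::setNames(vector("list", length(ids)), ids)
  for (k in keys) {
    for (m in all_clusters[[k]]$members) {
      membership[[m]] <- c(membership[[m]], k)
    }
  }

  find_cluster <- function(lr, p) {
    for (cl in lr$clusters) if (p %in% cl$members) return(cl)
    NULL
  }

  override <- character(0)   # point id -> forced key
  absorb_cand <- list()      # point id -> list(key =, stat =)

  n_parts <- length(partitions)
  if (n_parts > 1) {
    for (i in seq_len(n_parts - 1)) {
      pa <- partitions[[i]]
      pb <- partitions[[i + 1]]
      la <- local_results[[i]]
      lb <- local_results[[i + 1]]
      shared <- intersect(pa$overlap_right, pb$overlap_left)

      if (length(shared) > 0) {
        # overlap path: every shared point was clustered twice
        for (p in shared) {
          ca <- find_cluster(la, p)
          cb <- find_cluster(lb, p)
          ra <- unname(la$result$roles[p])
          rb <- unname(lb$result$roles[p])
          dec <- merge_overlap(ca, cb, p, ra, rb)
          if (dec$verdict == "MERGE") {
            ka <- cluster_key(ca$partition_id, ca$cluster_id)
            kb <- cluster_key(cb$partition_id, cb$cluster_id)
            uf_union(uf, ka, kb)
            trace("overlap", ka, kb, NA_real_, NA_real_, "MERGE")
          } else if (dec$verdict == "ASSIGN_EITHER") {
            ka <- cluster_key(ca$partition_id, ca$cluster_id)
            kb <- cluster_key(cb$partition_id, cb$cluster_id)
            override[p] <- min(ka, kb)
          }
          # ASSIGN_TO_ONE: p is already a member of exactly that cluster;
          # NOISE: handled by the residual pool
        }
      } else {
        # disjoint path: mean boundary-distance merge over saved sets
        cut <- pa$cut_right
        near <- function(mids, eps) {
          mids[abs(x[mids, 1] - cut) <= eps]
        }
        for (ca in la$clusters) {
          e_a <- near(ca$members, pa$eps)
          if (length(e_a) == 0) next
          for (cb in lb$clusters) {
            e_b <- near(cb$members, pb$eps)
            if (length(e_b) == 0) next
            dec <- boundary_merge_test(e_a, e_b, pa$eps, pb$eps, x)
            ka <- cluster_key(ca$partition_id, ca$cluster_id)
            kb <- cluster_key(cb$partition_id, cb$cluster_id)
            trace("boundary", ka, kb, dec$statistic, min(pa$eps, pb$eps),
                  dec$verdict)
            if (dec$verdict == "MERGE") uf_union(uf, ka, kb)
          }
        }
        # noise absorption, applied in both directions across the cut
        absorb_dir <- function(l_noise, eps_noise, l_cl, p_cl) {
          np <- l_noise$noise[abs(x[l_noise$noise, 1] - cut) <= eps_noise]
          for (p in np) {
            for (cc in l_cl$clusters) {
              e_c <- near(cc$members, p_cl$eps)
              if (length(e_c) == 0) next
              dec <- absorb_noise(p, e_c, p_cl$eps, x)
              kc <- cluster_key(cc$partition_id, cc$cluster_id)
              trace("absorb", p, kc, dec$statistic, p_cl$eps, dec$verdict)
              if (dec$verdict == "ASSIGN_TO_ONE") {
                absorb_cand[[p]] <<- c(
                  absorb_cand[[p]],
                  list(list(key = kc, stat = dec$statistic))
                )
              }
            }
          }
        }
        absorb_dir(la, pa$eps, lb, pb)
        absorb_dir(lb, pb$eps, la, pa)
      }
    }
  }

  # resolve absorption candidates: smallest mean distance wins, key breaks ties
  for (p in names(absorb_cand)) {
    if (!is.null(membership[[p]])) next # clustered elsewhere after all
    cand <- absorb_cand[[p]]
    stats_ <- vapply(cand, `[[`, numeric(1), "stat")
    keys_ <- vapply(cand, `[[`, character(1), "key")
    ord <- order(stats_, keys_)
    membership[[p]] <- keys_[ord[1]]
  }

  # assign each point to the root of its (possibly overridden) local cluster
  point_root <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (p in ids) {
    ks <- membership[[p]]
    if (is.null(ks)) next
    if (p %in% names(override)) ks <- override[[p]]
    roots <- unique(vapply(ks, function(k) uf_find(uf, k), character(1)))
    point_root[p] <- min(roots)
  }

  core_in_local <- unique(unlist(lapply(all_clusters, `[[`, "core_members")))

  # pool whatever is still unassigned and try to recover split sparse clusters
  pool <- ids[is.na(point_root)]
  min_eps <- min(vapply(partitions, `[[`, numeric(1), "eps"))
  rec <- recluster_noise(pool, x, dbscan_params(min_eps, min_pts))
  rec_root <- character(0)
  for (cl in rec$clusters) {
    key <- sprintf("R.C%06d", cl$cluster_id)
    point_root[cl$members] <- key
    rec_root <- c(rec_root, key)
    core_in_local <- union(core_in_local, cl$core_members)
  }

  # dense global ids ordered by each class's earliest core point
  assigned <- !is.na(point_root)
  labels <- stats::setNames(integer(length(ids)), ids)
  roots <- unique(point_root[assigned])
  if (length(roots) > 0) {
    first_core <- vapply(roots, function(r) {
      members <- ids[assigned & point_root == r]
      cores <- intersect(ids, intersect(members, core_in_local))
      min(match(cores, ids))
    }, numeric(1))
    roots <- roots[order(first_core)]
    for (g in seq_along(roots)) {
      labels[assigned & point_root == roots[g]] <- g
    }
  }

  roles <- ifelse(ids %in% core_in_local, "CORE",
                  ifelse(labels > 0L, "BORDER", "NOISE"))
  names(roles) <- ids
  params <- dbscan_params(min_eps, min_pts)
  structure(
    list(ids = ids, labels = labels, roles = roles, params = params),
    class = "vc_clustering"
  )
}
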