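# KMeans++ clustering of binary gene profiles with equal-distance
# multi-assignment: a gene whose profile is exactly equidistant from
# several centroids belongs to all of them, treating each cluster as an
# open interactive unit.

#' Matching distance between binary vectors
#'
#' Number of positions where two equal-length binary vectors differ
#' (simple-matching / Hamming distance).
#'
#' @param u,v Binary vectors of equal length.
#' @return Nonnegative integer count.
#' @export
matching_distance <- function(u, v) {
  if (length(u) != length(v))
    gfn_stop("gfn_dimension_error", "vectors differ in length (%d vs %d)",
             length(u), length(v))
  sum(u != v)
}

# Squared Euclidean distances from every row of `data` to every centroid
# row; the workhorse for assignment against fractional centroids.
sq_dist_to_centroids <- function(data, centroids) {
  d2 <- outer(rowSums(data^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(data)), rowSums(centroids^2)) -
    2 * tcrossprod(data, centroids)
  d2[d2 < 0] <- 0
  d2
}

#' KMeans++ seeding
#'
#' Chooses `k` initial centroids from the data rows: the first uniformly
#' at random, each subsequent one with probability proportional to the
#' squared matching distance to the nearest centroid already chosen. Rows
#' coincident with a chosen centroid therefore have zero selection weight.
#' Fully deterministic given `seed`.
#'
#' @param data Binary gene-by-site matrix (rows are points).
#' @param k Number of centroids; must not exceed the number of distinct rows.
#' @param seed RNG seed (required).
#' @return k-by-sites numeric matrix of centroids (rows of `data`), with
#'   attribute `chosen` giving the selected row indices.
#' @export
kmeanspp_seed <- function(data, k, seed) {
  n_distinct <- nrow(unique(data))
  if (k > n_distinct)
    gfn_stop("gfn_parameter_error",
             "k = %d exceeds the %d distinct rows", k, n_distinct)
  set.seed(seed)
  n <- nrow(data)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  min_d <- apply(data, 1, matching_distance, v = data[chosen[1], ])
  if (k > 1) for (j in 2:k) {
    w <- min_d^2
    chosen[j] <- sample.int(n, 1, prob = w)
    d_new <- apply(data, 1, matching_distance, v = data[chosen[j], ])
    min_d <- pmin(min_d, d_new)
  }
  cent <- data[chosen, , drop = FALSE] * 1.0
  rownames(cent) <- sprintf("c%02d", seq_len(k))
  attr(cent, "chosen") <- chosen
  cent
}

new_cluster_assignment <- function(membership, centroids, objective = NA_real_,
                                   iterations = NA_integer_) {
  structure(list(membership = membership, centroids = centroids,
                 objective = objective, iterations = iterations),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(unlist(x$membership))
  cat("Cluster assignment:", length(x$membership), "genes,",
      nrow(x$centroids), "clusters\n")
  cat("sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "),
      "\n")
  multi <- sum(lengths(x$membership) > 1)
  cat(multi, "gene(s) with multi-cluster membership; objective =",
      format(x$objective), "\n")
  invisible(x)
}

#' Primary (single) labels of a cluster assignment
#'
#' For genes in several clusters, returns the first owning label; used for
#' partition-level comparisons such as the adjusted Rand index.
#'
#' @param assignment A `cluster_assignment`.
#' @return Named character vector of single labels.
#' @export
primary_labels <- function(assignment) {
  vapply(assignment$membership, function(x) x[1], character(1))
}

#' Lloyd iterations with tie multi-assignment
#'
#' Alternates (a) assignment of every row to all centroids at minimal
#' squared Euclidean distance (ties within `tol` give multi-membership;
#' with binary centroids ties are exact integer equalities) and
#' (b) centroid update as the coordinate-wise mean of member rows, where a
#' multi-member row counts with full weight in every owning cluster.
#' Stops when memberships are unchanged or after `max_iter` rounds. The
#' objective (sum over rows of the minimal squared distance) is checked to
#' be non-increasing every iteration. A cluster that empties is re-seeded
#' from the row farthest from its nearest centroid.
#'
#' @param data Binary gene-by-site matrix.
#' @param centroids Initial centroids, e.g. from [kmeanspp_seed()].
#' @param max_iter Iteration cap (default 100).
#' @param tol Absolute tie tolerance on squared distances (default 1e-9).
#' @return A `cluster_assignment` with membership list, final centroids,
#'   converged objective and iteration count.
#' @export
kmeans_iterate <- function(data, centroids, max_iter = 100, tol = 1e-9) {
  if (max_iter < 1) gfn_stop("gfn_parameter_error", "max_iter must be >= 1")
  k <- nrow(centroids)
  labels <- rownames(centroids)
  if (is.null(labels)) labels <- sprintf("c%02d", seq_len(k))
  data <- data * 1.0
  prev_member <- NULL
  obj_prev <- Inf
  member <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(data, centroids)
    min_d2 <- apply(d2, 1, min)
    obj <- sum(min_d2)
    if (obj > obj_prev + 1e-8)
      warning("objective increased; stopping at previous assignment")
    member <- lapply(seq_len(nrow(data)), function(i)
      labels[which(d2[i, ] <= min_d2[i] + tol)])
    names(member) <- rownames(data)
    # re-seed empty clusters from the worst-fit row
    owned <- unique(unlist(member))
    empty <- setdiff(labels, owned)
    for (e in empty) {
      far <- which.max(min_d2)
      centroids[e, ] <- data[far, ]
      member[[far]] <- e
      min_d2[far] <- 0
    }
    if (!is.null(prev_member) && identical(member, prev_member)) {
      obj_prev <- obj
      break
    }
    # centroid update: full weight per owning cluster
    for (j in seq_len(k)) {
      owners <- vapply(member, function(m) labels[j] %in% m, logical(1))
      if (any(owners))
        centroids[j, ] <- colMeans(data[owners, , drop = FALSE])
    }
    prev_member <- member
    obj_prev <- obj
  }
  new_cluster_assignment(member, centroids, objective = obj_prev,
                         iterations = it)
}

#' Consensus profile centroids of an existing grouping
#'
#' Computes the coordinate-wise mean profile of each group of a named
#' assignment (e.g. network modules), ordered by decreasing group size and
#' relabeled `c01`, `c02`, ... The result is a valid centroid matrix for
#' [kmeans_iterate()], letting an independently derived grouping serve as
#' an informed initialization for the clustering stage. Genes labeled
#' `"unassigned"` are ignored.
#'
#' @param assignment Named character vector of group labels.
#' @param data Binary gene-by-site matrix covering the assigned genes.
#' @return Numeric group-by-site centroid matrix.
#' @export
consensus_profiles <- function(assignment, data) {
  groups <- setdiff(unique(assignment), "unassigned")
  if (length(groups) == 0)
    gfn_stop("gfn_parameter_error", "no assigned groups")
  missing <- setdiff(names(assignment), rownames(data))
  if (length(missing) > 0)
    gfn_stop("gfn_validation_error", "%d assigned genes not in data",
             length(missing))
  sizes <- table(assignment[assignment != "unassigned"])
  groups <- names(sort(sizes, decreasing = TRUE))
  cent <- do.call(rbind, lapply(groups, function(g)
    colMeans(data[names(assignment)[assignment == g], , drop = FALSE])))
  rownames(cent) <- sprintf("c%02d", seq_along(groups))
  cent
}

#' Clustering with restarts and a stability score
#'
#' Runs KMeans++ seeding plus Lloyd iterations from `n_restarts`
#' independent seeds, returns the run with the lowest objective as the
#' consensus, and reports the mean pairwise adjusted Rand index between
#' the runs' primary partitions as a stability score in \[-1, 1\].
#' An optional informed initialization (e.g. [consensus_profiles()] of
#' detected network modules) is run alongside the random restarts and
#' competes for the consensus on the same objective: random KMeans++
#' restarts can converge to poorer local optima than a start informed by
#' the co-occurrence structure.
#'
#' @param data Binary gene-by-site matrix.
#' @param k Number of clusters.
#' @param n_restarts Number of restarts (>= 2), default 10.
#' @param seeds Optional explicit seed vector (length `n_restarts`);
#'   defaults to `seed + 0:(n_restarts-1)`.
#' @param seed Base seed used when `seeds` is not given.
#' @param max_iter,tol Passed to [kmeans_iterate()].
#' @param init_centroids Optional `k`-by-site centroid matrix used as one
#'   additional, non-random restart.
#' @return List with `assignment` (best `cluster_assignment`), `stability`
#'   (mean pairwise ARI) and `objectives` (per run).
#' @export
cluster_stability <- function(data, k, n_restarts = 10, seeds = NULL,
                              seed = 1, max_iter = 100, tol = 1e-9,
                              init_centroids = NULL) {
  if (n_restarts < 2)
    gfn_stop("gfn_parameter_error", "n_restarts must be >= 2")
  if (is.null(seeds)) seeds <- seed + seq_len(n_restarts) - 1
  if (length(seeds) != n_restarts)
    gfn_stop("gfn_parameter_error", "need one seed per restart")
  runs <- lapply(seeds, function(s) {
    cent <- kmeanspp_seed(data, k, seed = s)
    kmeans_iterate(data, cent, max_iter = max_iter, tol = tol)
  })
  if (!is.null(init_centroids)) {
    if (nrow(init_centroids) != k)
      gfn_stop("gfn_parameter_error",
               "init_centroids must have exactly k = %d rows", k)
    runs <- c(runs, list(kmeans_iterate(data, init_centroids,
                                        max_iter = max_iter, tol = tol)))
  }
  objs <- vapply(runs, function(r) r$objective, numeric(1))
  labels <- lapply(runs, primary_labels)
  pairs <- utils::combn(length(runs), 2)
  aris <- apply(pairs, 2, function(p)
    mclust::adjustedRandIndex(labels[[p[1]]], labels[[p[2]]]))
  list(assignment = runs[[which.min(objs)]],
       stability = mean(aris),
       objectives = objs)
}
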