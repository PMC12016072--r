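check_square_dist <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square", call. = FALSE)
}

# Smallest and second-smallest distance to the current medoids, plus the
# nearest medoid (lowest index on ties). Like any single-swap k-medoids
# search, the SWAP phase terminates in a local optimum of the total-cost
# landscape; on dissimilarities with recoverable cluster structure this
# coincides with the global optimum, on unstructured dissimilarities it
# need not.
nearest_two <- function(D, medoids) {
  Dm <- D[, medoids, drop = FALSE]
  ncol1 <- max.col(-Dm, ties.method = "first")
  d1 <- Dm[cbind(seq_len(nrow(Dm)), ncol1)]
  Dm[cbind(seq_len(nrow(Dm)), ncol1)] <- Inf
  d2 <- Dm[cbind(seq_len(nrow(Dm)), max.col(-Dm, ties.method = "first"))]
  list(nearest = medoids[ncol1], d1 = d1, d2 = d2)
}

#' Partitioning around medoids on a precomputed dissimilarity matrix
#'
#' Classic deterministic PAM. The BUILD phase seeds medoids greedily (first
#' medoid minimizes the total distance to all points; each subsequent medoid
#' maximizes the cost reduction). The SWAP phase repeatedly applies the
#' single best improving (medoid, non-medoid) exchange until no swap strictly
#' reduces the total cost. All ties are broken toward the lowest index, so
#' results are reproducible across platforms. Each point is assigned to its
#' minimum-distance medoid (lowest medoid index on ties); medoids are
#' assigned to themselves.
#'
#' @param m square symmetric dissimilarity matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @return object of class `"pam_result"`: list with `k`, `medoids` (indices,
#'   ascending), `medoid_ids` (labels if the matrix has dimnames),
#'   `assignment` (integer cluster per point, clusters ordered by medoid
#'   index), and `total_cost`.
#' @export
pam_cluster <- function(m, k) {
  check_square_dist(m)
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 2L || k >= n)
    stop(sprintf("k must satisfy 2 <= k < n (got k = %d, n = %d)", k, n),
         call. = FALSE)

  ## BUILD
  medoids <- which.min(rowSums(m))
  dnear <- m[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    red <- colSums(pmax(dnear - m[, cand, drop = FALSE], 0))
    new <- cand[which.max(red)]
    medoids <- c(medoids, new)
    dnear <- pmin(dnear, m[, new])
  }
  medoids <- sort(medoids)
  build_cost <- sum(nearest_two(m, medoids)$d1)

  ## SWAP: best-improvement exchanges until no strict decrease
  eps <- 1e-12
  repeat {
    nt <- nearest_two(m, medoids)
    current <- sum(nt$d1)
    best <- list(cost = current, out = NA_integer_, inn = NA_integer_)
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in medoids) {
      base <- ifelse(nt$nearest == mi, nt$d2, nt$d1)
      costs <- colSums(pmin(m[, nonmed, drop = FALSE], base))
      j <- which.min(costs)
      if (costs[j] < best$cost - eps) {
        best <- list(cost = costs[j], out = mi, inn = nonmed[j])
      }
    }
    if (is.na(best$out)) break
    medoids <- sort(c(setdiff(medoids, best$out), best$inn))
  }

  Dm <- m[, medoids, drop = FALSE]
  assignment <- max.col(-Dm, ties.method = "first")
  assignment[medoids] <- seq_along(medoids)
  total_cost <- sum(Dm[cbind(seq_len(n), assignment)])
  structure(list(k = k, medoids = medoids,
                 medoid_ids = rownames(m)[medoids],
                 assignment = assignment, total_cost = total_cost,
                 build_cost = build_cost),
            class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, total cost = %.4f\n", x$k, x$total_cost))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Average silhouette width
#'
#' For each point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the
#' mean distance to its own cluster (excluding itself) and `b(i)` the minimum
#' over other clusters of the mean distance to that cluster. Members of
#' singleton clusters have `s(i) = 0`. Returns the mean over all points;
#' values lie in `[-1, 1]`, higher is better.
#'
#' @param m square symmetric dissimilarity matrix.
#' @param assignment integer cluster labels.
#' @return numeric scalar.
#' @export
average_silhouette_width <- function(m, assignment) {
  check_square_dist(m)
  k <- length(unique(assignment))
  if (k < 2L) stop("silhouette requires at least 2 clusters", call. = FALSE)
  lev <- sort(unique(assignment))
  Z <- outer(assignment, lev, "==") * 1
  nk <- colSums(Z)
  S <- m %*% Z                                    # point x cluster distance sums
  own <- match(assignment, lev)
  a <- S[cbind(seq_along(assignment), own)] / (nk[own] - 1)
  Sb <- sweep(S, 2, nk, "/")
  Sb[cbind(seq_along(assignment), own)] <- Inf
  b <- apply(Sb, 1, min)
  s <- (b - a) / pmax(a, b)
  s[nk[own] == 1] <- 0                             # singleton convention
  s[!is.finite(s)] <- 0                            # a = b = 0
  mean(s)
}

#' Point-biserial correlation of a clustering
#'
#' Pearson correlation, over all unordered point pairs, between the pairwise
#' distance and the indicator of the pair lying in different clusters.
#' Higher is better.
#'
#' @inheritParams average_silhouette_width
#' @return numeric scalar, or `NA` with a warning when either vector has zero
#'   variance.
#' @export
point_biserial <- function(m, assignment) {
  check_square_dist(m)
  if (length(unique(assignment)) < 2L)
    stop("point-biserial correlation requires at least 2 clusters", call. = FALSE)
  lt <- lower.tri(m)
  d <- m[lt]
  diff_cluster <- (outer(assignment, assignment, "!=") * 1)[lt]
  if (sd(d) == 0 || sd(diff_cluster) == 0) {
    warning("point-biserial correlation undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  cor(d, diff_cluster)
}

#' Hubert's C index
#'
#' `C = (S_w - S_min) / (S_max - S_min)` where `S_w` is the sum of
#' within-cluster pairwise distances over the `N_w` within-cluster pairs and
#' `S_min` / `S_max` are the sums of the `N_w` smallest / largest
#' off-diagonal distances. Lies in `[0, 1]`; lower is better.
#'
#' @inheritParams average_silhouette_width
#' @return numeric scalar, or `NA` with a warning when all pair distances are
#'   equal.
#' @export
huberts_c <- function(m, assignment) {
  check_square_dist(m)
  if (length(unique(assignment)) < 2L)
    stop("Hubert's C requires at least 2 clusters", call. = FALSE)
  lt <- lower.tri(m)
  d <- m[lt]
  same <- (outer(assignment, assignment, "==") * 1)[lt] == 1
  nw <- sum(same)
  if (nw < 1L) stop("no within-cluster pairs", call. = FALSE)
  sw <- sum(d[same])
  ds <- sort(d)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
  if (smax == smin) {
    warning("Hubert's C undefined: all pair distances equal", call. = FALSE)
    return(NA_real_)
  }
  (sw - smin) / (smax - smin)
}

#' Cluster-count selection by quality indices
#'
#' Runs [pam_cluster()] for every `k` in `k_min..k_max` and evaluates the
#' average silhouette width, point-biserial correlation and Hubert's C index
#' on each solution. The recommended `k` maximizes ASW (ties toward the
#' smaller `k`); the full index table is retained so the profile can also be
#' inspected visually.
#'
#' @param m pooled dissimilarity matrix.
#' @param k_min,k_max candidate range (defaults 2..10).
#' @return object of class `"quality_profile"`: list with `profile`
#'   (data.frame `k`, `asw`, `point_biserial`, `huberts_c`), `recommended_k`
#'   and `clusterings` (list of `pam_result` keyed by `k`).
#' @export
select_k <- function(m, k_min = 2L, k_max = 10L) {
  check_square_dist(m)
  if (k_max >= nrow(m)) stop("k_max must be smaller than n", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  clusterings <- vector("list", length(ks))
  names(clusterings) <- ks
  profile <- data.frame(k = ks, asw = NA_real_, point_biserial = NA_real_,
                        huberts_c = NA_real_)
  for (i in seq_along(ks)) {
    fit <- pam_cluster(m, ks[i])
    clusterings[[i]] <- fit
    profile$asw[i] <- average_silhouette_width(m, fit$assignment)
    profile$point_biserial[i] <- suppressWarnings(point_biserial(m, fit$assignment))
    profile$huberts_c[i] <- suppressWarnings(huberts_c(m, fit$assignment))
  }
  structure(list(profile = profile,
                 recommended_k = ks[which.max(profile$asw)],
                 clusterings = clusterings),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  print(x$profile, row.names = FALSE)
  cat(sprintf("recommended k (max ASW): %d\n", x$recommended_k))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same points;
#' 1 for identical partitions, approximately 0 for random agreement. Used
#' here for parameter-recovery checks against planted ground truth.
#'
#' @param x,y two label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- choose2(length(x))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
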