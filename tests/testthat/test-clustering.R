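test_that("PAM recovers planted structure and matches exhaustive search", {
  # two tight pairs far apart
  m <- matrix(c(0, 1, 10, 10,
                1, 0, 10, 10,
                10, 10, 0, 1,
                10, 10, 1, 0), 4, byrow = TRUE)
  fit <- pam_cluster(m, 2)
  expect_identical(fit$assignment[1], fit$assignment[2])
  expect_identical(fit$assignment[3], fit$assignment[4])
  expect_false(fit$assignment[1] == fit$assignment[3])
  expect_identical(fit$total_cost, bf_pam_cost(m, 2))

  # k = n is rejected; k = n - 1 leaves a single paired point
  expect_error(pam_cluster(m, 4), "k must satisfy")
  fit3 <- pam_cluster(m, 3)
  expect_identical(fit3$total_cost, bf_pam_cost(m, 3))
  expect_identical(fit3$total_cost, 1)
})

test_that("PAM equals exhaustive medoid search on clusterable instances", {
  set.seed(201)
  for (i in 1:100) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    m <- planted_dist_matrix(n, k)
    fit <- pam_cluster(m, k)
    expect_equal(fit$total_cost, bf_pam_cost(m, k))
    # assignment bookkeeping: medoids belong to themselves, cost consistent
    expect_identical(fit$assignment[fit$medoids], seq_len(k))
    expect_equal(fit$total_cost,
                 sum(m[cbind(seq_len(n), fit$medoids[fit$assignment])]))
  }
})

test_that("on unstructured dissimilarities PAM reaches a swap-local optimum", {
  # single-exchange k-medoids search guarantees local, not global, optimality;
  # check the guarantees it does make, bracketed by BUILD cost and the
  # exhaustive optimum
  set.seed(208)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    m <- random_dist_matrix(n)
    fit <- pam_cluster(m, k)
    expect_lte(fit$total_cost, fit$build_cost)
    expect_gte(fit$total_cost, bf_pam_cost(m, k) - 1e-9)
    expect_true(is_swap_local_optimum(m, fit$medoids, fit$total_cost))
  }
})

test_that("PAM partitions agree with the reference implementation on planted blobs", {
  set.seed(209)
  for (i in 1:25) {
    n <- sample(8:12, 1)
    k <- sample(2:3, 1)
    m <- planted_dist_matrix(n, k)
    fit <- pam_cluster(m, k)
    ref <- cluster::pam(stats::as.dist(m), k)
    expect_identical(adjusted_rand_index(fit$assignment, ref$clustering), 1)
  }
})

test_that("PAM tie-breaking on a degenerate all-zero matrix is deterministic", {
  m <- matrix(0, 5, 5)
  fit <- pam_cluster(m, 2)
  expect_identical(fit$medoids, c(1L, 2L))
  expect_identical(fit$total_cost, 0)
  expect_identical(fit$assignment, c(1L, 2L, 1L, 1L, 1L))
})

test_that("silhouette matches the direct formula and the reference implementation", {
  # ideal separation: zero within, positive between
  m <- matrix(5, 6, 6); m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0; diag(m) <- 0
  cl <- c(1, 1, 1, 2, 2, 2)
  expect_identical(average_silhouette_width(m, cl), 1)

  # pathological assignment gives negative ASW
  expect_lt(average_silhouette_width(m, c(1, 1, 2, 2, 1, 2)), 0)

  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    m <- random_dist_matrix(n)
    cl <- as.integer(factor(sample(1:3, n, replace = TRUE)))
    if (length(unique(cl)) < 2) next
    expect_equal(average_silhouette_width(m, cl), bf_asw(m, cl))
    ref <- mean(cluster::silhouette(cl, dmatrix = m)[, "sil_width"])
    expect_equal(average_silhouette_width(m, cl), ref)
  }
  expect_error(average_silhouette_width(m, rep(1, nrow(m))), "2 clusters")
})

test_that("point-biserial correlation matches direct pair recomputation", {
  # constant within < constant between -> perfect two-valued correlation
  m <- matrix(4, 6, 6); m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  cl <- c(1, 1, 1, 2, 2, 2)
  expect_equal(point_biserial(m, cl), 1)

  const <- matrix(1, 5, 5); diag(const) <- 0
  expect_warning(pb <- point_biserial(const, c(1, 2, 1, 2, 1)), "zero variance")
  expect_true(is.na(pb))

  set.seed(203)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    m <- random_dist_matrix(n)
    cl <- sample(1:2, n, replace = TRUE)
    if (length(unique(cl)) < 2) next
    expect_equal(point_biserial(m, cl), bf_point_biserial(m, cl))
  }
})

test_that("Hubert's C attains its bounds and matches sorted-pair recomputation", {
  # within-pairs are exactly the globally smallest distances -> C = 0
  m <- matrix(4, 6, 6); m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  cl <- c(1, 1, 1, 2, 2, 2)
  expect_identical(huberts_c(m, cl), 0)
  # within-pairs are exactly the largest -> C = 1
  worst <- c(1, 2, 2, 1, 1, 2)
  m2 <- matrix(1, 6, 6); diag(m2) <- 0
  m2[1, 4] <- m2[4, 1] <- 9; m2[1, 5] <- m2[5, 1] <- 9; m2[4, 5] <- m2[5, 4] <- 9
  m2[2, 3] <- m2[3, 2] <- 9; m2[2, 6] <- m2[6, 2] <- 9; m2[3, 6] <- m2[6, 3] <- 9
  expect_identical(huberts_c(m2, worst), 1)

  set.seed(204)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    m <- random_dist_matrix(n)
    cl <- sample(1:2, n, replace = TRUE)
    if (length(unique(cl)) < 2) next
    expect_equal(huberts_c(m, cl), bf_huberts_c(m, cl))
  }

  const <- matrix(1, 4, 4); diag(const) <- 0
  expect_warning(hc <- huberts_c(const, c(1, 1, 2, 2)), "undefined")
  expect_true(is.na(hc))
})

test_that("indices are invariant to label permutation and distance scaling", {
  set.seed(205)
  m <- random_dist_matrix(8)
  cl <- c(1, 2, 1, 3, 2, 3, 1, 2)
  perm <- c(3, 1, 3, 2, 1, 2, 3, 1)  # relabeled clusters
  for (f in list(average_silhouette_width, point_biserial, huberts_c)) {
    expect_equal(f(m, cl), f(m, perm))
    expect_equal(f(m, cl), f(m * 7, cl))
  }
})

test_that("select_k scans the k range and recommends by maximum ASW", {
  set.seed(206)
  # three well-separated blobs
  centers <- c(0, 50, 100)
  x <- centers[rep(1:3, each = 8)] + runif(24)
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(paste0("P", 1:24), paste0("P", 1:24))
  prof <- select_k(m, 2, 6)
  expect_identical(prof$recommended_k, 3L)
  expect_identical(nrow(prof$profile), 5L)
  expect_true(all(prof$profile$asw >= -1 & prof$profile$asw <= 1))
  expect_true(all(prof$profile$huberts_c >= 0 & prof$profile$huberts_c <= 1,
                  na.rm = TRUE))

  one <- select_k(m, 2, 2)
  expect_identical(nrow(one$profile), 1L)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(207)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
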