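# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration / direct textbook formulas) and share no
# code with the package internals.

# all subsequences of x, encoded as strings; includes the empty subsequence
all_subsequences <- function(x) {
  n <- length(x)
  out <- character(2^n)
  for (mask in 0:(2^n - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    out[mask + 1] <- paste(x[sel], collapse = "\x01")
  }
  unique(out)
}

# brute-force LCS length by enumerating common subsequences
bf_lcs_length <- function(x, y) {
  common <- intersect(all_subsequences(x), all_subsequences(y))
  lens <- vapply(common, function(s) {
    if (!nzchar(s)) 0L else length(strsplit(s, "\x01", fixed = TRUE)[[1]])
  }, integer(1))
  max(lens)
}

# exhaustive k-medoids: minimum total cost over all candidate medoid sets
bf_pam_cost <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(m[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# direct per-point silhouette formula
bf_asw <- function(m, cl) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(m[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(m[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# direct Pearson correlation over unordered pairs
bf_point_biserial <- function(m, cl) {
  n <- nrow(m)
  d <- c(); ind <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, m[i, j]); ind <- c(ind, as.numeric(cl[i] != cl[j]))
  }
  stats::cor(d, ind)
}

# direct sorted-pair Hubert's C
bf_huberts_c <- function(m, cl) {
  n <- nrow(m)
  d <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, m[i, j]); within <- c(within, cl[i] == cl[j])
  }
  nw <- sum(within)
  sw <- sum(d[within])
  ds <- sort(d)
  (sw - sum(ds[1:nw])) / (sum(rev(ds)[1:nw]) - sum(ds[1:nw]))
}

# symmetric random distance matrix with zero diagonal (unstructured, and in
# general non-metric -- an adversarial input for local-search clustering)
random_dist_matrix <- function(n, max_val = 10) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- sample.int(max_val, n * (n - 1) / 2, replace = TRUE)
  m + t(m)
}

# random instance with recoverable planted structure: k tight, well-separated
# blobs on a line (each nonempty), Euclidean distances
planted_dist_matrix <- function(n, k) {
  centers <- seq(0, by = 50, length.out = k)
  g <- sort(c(seq_len(k), sample.int(k, n - k, replace = TRUE)))
  as.matrix(dist(centers[g] + runif(n, -2, 2)))
}

# TRUE iff no single (medoid, non-medoid) exchange strictly reduces the cost
is_swap_local_optimum <- function(m, medoids, total_cost) {
  n <- nrow(m)
  for (out in medoids) for (inn in setdiff(seq_len(n), medoids)) {
    s <- c(setdiff(medoids, out), inn)
    if (sum(apply(m[, s, drop = FALSE], 1, min)) < total_cost - 1e-9) return(FALSE)
  }
  TRUE
}

# minimal event-table row builder
ev_row <- function(patient_id, date, code, quantity = NA_real_,
                   setting = "outpatient") {
  data.frame(patient_id = patient_id, date = date, event_code = code,
             quantity = quantity, setting = setting, stringsAsFactors = FALSE)
}

dx_row <- function(patient_id, date, setting) {
  data.frame(patient_id = patient_id, date = date, setting = setting,
             code = "E10", stringsAsFactors = FALSE)
}
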