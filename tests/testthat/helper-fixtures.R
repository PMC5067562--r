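# Fixture builders and independent oracles used across the suite.

# Wrap a 0/1 matrix as a binarized response table.
binary_table <- function(x, group = "ASC", cohort = "discovery") {
  if (is.null(colnames(x))) colnames(x) <- sprintf("item_%02d", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(nrow(x))),
      group = group, cohort = cohort
    ),
    tibble::as_tibble(x)
  )
}

# Wide-format coded response table from a character matrix of 1/0/T codes.
coded_table <- function(codes, group = "ASC", cohort = "discovery") {
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("item_%02d", seq_len(ncol(codes)))
  }
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(nrow(codes))),
      group = group, cohort = cohort
    ),
    tibble::as_tibble(codes)
  )
}

random_coded_table <- function(n, m, timeout_prob = 0.1) {
  codes <- matrix(
    sample(c("1", "0", "T"), n * m, replace = TRUE,
           prob = c(0.6, 1 - 0.6 - timeout_prob, timeout_prob)),
    nrow = n
  )
  coded_table(codes)
}

# Symmetric random dissimilarity in [0, 1] with zero diagonal.
random_dissimilarity <- function(n) {
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Block-structured dissimilarity: low within planted blocks, high between.
planted_block_dissimilarity <- function(sizes, within = 0.1, between = 0.9,
                                        jitter = 0.02) {
  lab <- rep(seq_along(sizes), times = sizes)
  n <- length(lab)
  d <- matrix(between, n, n)
  for (b in seq_along(sizes)) d[lab == b, lab == b] <- within
  noise <- matrix(runif(n * n, 0, jitter), n, n)
  d <- d + (noise + t(noise)) / 2
  diag(d) <- 0
  list(d = d, labels = lab)
}

# --- independent oracles -----------------------------------------------------

# Triple-loop evaluation of the unsigned topological overlap.
tom_oracle <- function(d) {
  n <- nrow(d)
  a <- 1 - d
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ell <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) ell <- ell + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (ell + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# Step-by-step greedy Lance-Williams Ward recurrence (non-squared form):
# merge the globally closest pair, update by the weighted recurrence.
ward_oracle <- function(d) {
  n <- nrow(d)
  sizes <- rep(1, n)
  id <- -(seq_len(n))
  members <- lapply(seq_len(n), identity)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  D <- d
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    best_h <- Inf
    bi <- bj <- NA
    act <- which(alive)
    for (ai in seq_along(act)) {
      for (aj in seq_along(act)) {
        if (aj <= ai) next
        i <- act[ai]; j <- act[aj]
        if (D[i, j] < best_h) {
          best_h <- D[i, j]; bi <- i; bj <- j
        }
      }
    }
    merges[step, ] <- sort(c(id[bi], id[bj]))
    heights[step] <- best_h
    for (k in act) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <-
        ((sizes[bi] + sizes[k]) * D[bi, k] +
           (sizes[bj] + sizes[k]) * D[bj, k] -
           sizes[k] * D[bi, bj]) / (sizes[bi] + sizes[bj] + sizes[k])
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    alive[bj] <- FALSE
    members[[bi]] <- sort(c(members[[bi]], members[[bj]]))
    merged_sets[[step]] <- members[[bi]]
    id[bi] <- step
  }
  list(merges = merges, heights = heights, merged_sets = merged_sets)
}

# Leaf sets merged at each step of an hclust tree, for order comparison.
hclust_merged_sets <- function(tree) {
  n <- nrow(tree$merge) + 1
  sets <- vector("list", n - 1)
  for (j in seq_len(n - 1)) {
    grab <- function(ch) if (ch < 0) -ch else sets[[ch]]
    sets[[j]] <- sort(c(grab(tree$merge[j, 1]), grab(tree$merge[j, 2])))
  }
  sets
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  k_max <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i / m * q) k_max <- i
  }
  if (k_max > 0) flags[ord[seq_len(k_max)]] <- TRUE
  flags
}
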