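# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately use naive
# enumeration, not the package's code paths.

# all 13 unique 3-D directions, duplicated for explicit double loops
oracle_directions <- function() {
  d <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  d <- d[!(d$x == 0 & d$y == 0 & d$z == 0), ]
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  as.matrix(d[keep, ])
}

# exhaustive symmetric co-occurrence counts: matrix levels x levels
oracle_glcm_counts <- function(lev, mask, d = 1) {
  dims <- dim(lev)
  n_lev <- max(lev[mask != 0])
  counts <- matrix(0, n_lev, n_lev)
  dirs <- oracle_directions()
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ] * d
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
        if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2] ||
            k2 < 1 || k2 > dims[3]) next
        if (mask[i, j, k] == 0 || mask[i2, j2, k2] == 0) next
        a <- lev[i, j, k]; b <- lev[i2, j2, k2]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
  }
  counts
}

# naive run enumeration: data frame (level, len) per maximal run, all dirs
oracle_runs <- function(lev, mask) {
  dims <- dim(lev)
  dirs <- oracle_directions()
  out <- list()
  inside <- function(p) all(p >= 1) && all(p <= dims)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        p <- c(i, j, k)
        if (mask[i, j, k] == 0) next
        prev <- p - off
        # run start: predecessor outside grid, off-mask, or different level
        starts <- !inside(prev) || mask[prev[1], prev[2], prev[3]] == 0 ||
          lev[prev[1], prev[2], prev[3]] != lev[i, j, k]
        if (!starts) next
        len <- 1
        q <- p + off
        while (inside(q) && mask[q[1], q[2], q[3]] != 0 &&
               lev[q[1], q[2], q[3]] == lev[i, j, k]) {
          len <- len + 1
          q <- q + off
        }
        out[[length(out) + 1]] <- c(lev[i, j, k], len)
      }
  }
  m <- do.call(rbind, out)
  data.frame(level = m[, 1], len = m[, 2])
}

# recursive flood fill of 26-connected iso-level zones
oracle_zones <- function(lev, mask) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (mask[i, j, k] == 0 || seen[i, j, k]) next
      target <- lev[i, j, k]
      stack <- list(c(i, j, k))
      seen[i, j, k] <- TRUE
      size <- 0
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1
        for (r in seq_len(nrow(offs))) {
          q <- p + offs[r, ]
          if (any(q < 1) || any(q > dims)) next
          if (seen[q[1], q[2], q[3]] || mask[q[1], q[2], q[3]] == 0) next
          if (lev[q[1], q[2], q[3]] != target) next
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
      zones[[length(zones) + 1]] <- c(target, size)
    }
  m <- do.call(rbind, zones)
  data.frame(level = m[, 1], size = m[, 2])
}

# explicit pair-enumeration Harrell c-index (same pair convention:
# orderable iff the strictly earlier time is an event; risk ties count 1/2)
oracle_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(time[i] < time[j] && event[i] == 1)) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (r in seq(n, 1)) {
    val <- min(prev, p[o[r]] * n / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# hypergeometric upper tail by explicit enumeration of the pmf
oracle_hyper_p <- function(k, K, N, m) {
  # P(X >= k) where X = |DE  within a set of size m|, K DE among N
  kk <- max(0, m + K - N):min(m, K)
  pmf <- choose(K, kk) * choose(N - K, m - kk) / choose(N, m)
  sum(pmf[kk >= k])
}

# plain diagonal-covariance nearest-centroid classification with priors
oracle_nearest_centroid <- function(train, labels, test, s0) {
  cls <- sort(unique(labels))
  n <- ncol(train)
  cent <- sapply(cls, function(k) rowMeans(train[, labels == k, drop = FALSE]))
  ss <- 0
  for (k in cls) {
    xk <- train[, labels == k, drop = FALSE]
    ss <- ss + rowSums((xk - cent[, k])^2)
  }
  s <- sqrt(ss / (n - length(cls)))
  priors <- as.numeric(table(labels)[cls]) / n
  apply(test, 2, function(x) {
    sc <- sapply(seq_along(cls), function(i) {
      sum((x - cent[, i])^2 / (s + s0)^2) - 2 * log(priors[i])
    })
    cls[which.min(sc)]
  })
}

# average-linkage merge heights by explicit group-mean distances
oracle_average_link_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  heights <- c()
  while (length(groups) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      dd <- mean(D[groups[[a]], groups[[b]]])
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    heights <- c(heights, bd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# small deterministic tumor-slice set for deep-radiomics tests
make_slices <- function(n, seed = 1, grid = c(32, 32, 8),
                        specs = default_phenotypes()) {
  set.seed(seed)
  pick <- sample(seq_len(nrow(specs)), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    st <- simulate_tumor_study(specs[pick[i], ], grid, c(2, 2, 6),
      seed = seed * 1000 + i)
    sl <- extract_center_slice(st$channels$ce, st$mask)
    sl / max(max(sl), 1e-9)
  })
}
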