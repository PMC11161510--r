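make_disc <- function(values, dims) {
  arr <- array(as.integer(values), dims)
  attr(arr, "n_levels") <- max(arr)
  arr
}

test_that("first-order features match hand computations", {
  # constant region: degenerate histogram
  disc <- make_disc(rep(1, 8), c(2, 2, 2))
  m <- array(1L, c(2, 2, 2))
  f <- first_order_features(disc, m)
  expect_equal(unname(f["fo_variance"]), 0)
  expect_equal(unname(f["fo_entropy"]), 0)
  expect_equal(unname(f["fo_energy"]), 1)
  expect_equal(unname(f["fo_skewness"]), 0)

  # two levels with counts 3 and 1: entropy by hand
  disc2 <- make_disc(c(1, 1, 1, 2), c(4, 1, 1))
  m2 <- array(1L, c(4, 1, 1))
  f2 <- first_order_features(disc2, m2)
  expect_equal(unname(f2["fo_entropy"]),
    -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-10)
  expect_equal(unname(f2["fo_energy"]), 0.75^2 + 0.25^2)
  expect_equal(unname(f2["fo_levels"]), 2)

  # symmetric two-point histogram has zero skewness
  disc3 <- make_disc(c(1, 2, 1, 2), c(4, 1, 1))
  expect_equal(unname(first_order_features(disc3, m2)["fo_skewness"]), 0)

  expect_error(first_order_features(disc, array(0L, c(2, 2, 2))),
    class = "sarcomix_invalid_argument")
})

test_that("GLCM features on a checkerboard equal the pair-count oracle", {
  cb <- make_disc(rep(c(1, 2), 8), c(4, 4, 1))
  m <- array(1L, c(4, 4, 1))
  counts <- oracle_glcm_counts(cb, m, d = 1)
  p <- counts / sum(counts)
  ij <- which(p > 0, arr.ind = TRUE)
  pv <- p[ij]
  oracle_contrast <- sum((ij[, 1] - ij[, 2])^2 * pv)
  oracle_energy <- sum(pv^2)
  f <- glcm_features(cb, m, distances = 1)
  expect_equal(unname(f["glcm_contrast_d1"]), oracle_contrast)
  expect_equal(unname(f["glcm_energy_d1"]), oracle_energy)

  # constant region: neutral values
  cst <- make_disc(rep(1, 16), c(4, 4, 1))
  fc <- glcm_features(cst, m, distances = 1)
  expect_equal(unname(fc["glcm_contrast_d1"]), 0)
  expect_equal(unname(fc["glcm_energy_d1"]), 1)
  expect_equal(unname(fc["glcm_entropy_d1"]), 0)
})

test_that("GLCM correlation of a linear gradient matches the pair-set definition", {
  # oracle: Pearson correlation computed directly on the symmetric pair set
  pair_corr <- function(n) {
    a <- c(1:(n - 1), 2:n)
    b <- c(2:n, 1:(n - 1))
    cor(a, b)
  }
  for (n in c(8, 32)) {
    grad <- make_disc(rep(seq_len(n), n), c(n, n, 1))
    m <- array(1L, c(n, n, 1))
    f <- glcm_features(grad, m, distances = 1,
      directions = rbind(c(1, 0, 0)))
    expect_equal(unname(f["glcm_correlation_d1"]), pair_corr(n),
      tolerance = 1e-9)
  }
  # and it approaches 1 as the gradient lengthens
  expect_gt(pair_corr(32), 0.99)
})

test_that("GLRLM features match hand enumeration and closed forms", {
  # single row [1,1,1,2], one direction
  row <- make_disc(c(1, 1, 1, 2), c(4, 1, 1))
  m <- array(1L, c(4, 1, 1))
  f <- glrlm_features(row, m, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(f["glrlm_rp"]), 2 / 4)
  # runs: (1, len 3), (2, len 1); SRE = (1/9 + 1)/2
  expect_equal(unname(f["glrlm_sre"]), (1 / 9 + 1) / 2)
  expect_equal(unname(f["glrlm_lre"]), (9 + 1) / 2)

  # constant 1-D region of n voxels, single direction
  n <- 7
  cst <- make_disc(rep(1, n), c(n, 1, 1))
  mc <- array(1L, c(n, 1, 1))
  fc <- glrlm_features(cst, mc, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(fc["glrlm_lre"]), n^2)
  expect_equal(unname(fc["glrlm_rp"]), 1 / n)

  # all runs length 1 (alternating): SRE = 1, RP = 1
  alt <- make_disc(rep(c(1, 2), 4), c(8, 1, 1))
  ma <- array(1L, c(8, 1, 1))
  fa <- glrlm_features(alt, ma, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(fa["glrlm_sre"]), 1)
  expect_equal(unname(fa["glrlm_rp"]), 1)
})

test_that("GLCM and GLRLM equal brute-force oracles on all 512 two-level 3x3x1 images", {
  m <- array(1L, c(3, 3, 1))
  for (code in 0:511) {
    bits <- as.integer(intToBits(code))[1:9]
    lev <- make_disc(bits + 1L, c(3, 3, 1))

    counts <- oracle_glcm_counts(lev, m, 1)
    g <- sarcomix:::glcm_matrix(lev, m, 1)
    full <- matrix(0, max(lev), max(lev))
    full[cbind(g$i, g$j)] <- g$p
    expect_equal(full, counts / sum(counts))

    runs <- oracle_runs(lev, m)
    rlm <- sarcomix:::glrlm_matrix(lev, m)
    oracle_tab <- as.data.frame(table(runs$level, runs$len),
      stringsAsFactors = FALSE)
    oracle_tab <- oracle_tab[oracle_tab$Freq > 0, ]
    got <- rlm[order(rlm$level, rlm$len), ]
    oracle_tab <- oracle_tab[order(as.integer(oracle_tab$Var1),
      as.integer(oracle_tab$Var2)), ]
    expect_equal(got$level, as.integer(oracle_tab$Var1))
    expect_equal(got$len, as.integer(oracle_tab$Var2))
    expect_equal(got$n, oracle_tab$Freq)
  }
})

test_that("GLZLM zones equal the flood-fill oracle on random volumes", {
  set.seed(42)
  for (trial in 1:20) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(2:3, 1))
    lev <- make_disc(sample(1:3, prod(dims), replace = TRUE), dims)
    m <- array(rbinom(prod(dims), 1, 0.8), dims)
    if (sum(m) == 0) next
    oz <- oracle_zones(lev, m)
    lab <- sarcomix:::label_zones(unclass(lev), m != 0)
    got_sizes <- sort(as.numeric(table(lab[m != 0])))
    expect_equal(got_sizes, sort(oz$size))
    expect_equal(length(got_sizes), nrow(oz))
  }

  # single uniform zone of n voxels: zone percentage 1/n
  n <- 12
  cst <- make_disc(rep(1, n), c(n, 1, 1))
  mc <- array(1L, c(n, 1, 1))
  expect_equal(unname(glzlm_features(cst, mc)["glzlm_rp"]), 1 / n)

  # isolated single-voxel zones: zone percentage 1
  iso <- make_disc(rep(c(1, 2), 5), c(10, 1, 1))
  mi <- array(1L, c(10, 1, 1))
  expect_equal(unname(glzlm_features(iso, mi)["glzlm_rp"]), 1)
})

test_that("NGLDM behaves correctly on flat and alternating inputs", {
  cst <- make_disc(rep(2, 27), c(3, 3, 3))
  m <- array(1L, c(3, 3, 3))
  f <- ngldm_features(cst, m)
  expect_equal(unname(f["ngldm_contrast"]), 0)
  expect_equal(unname(f["ngldm_coarseness"]), 1e6)

  # 1-D alternating strip: brute-force neighborhood differences
  n <- 6
  strip <- make_disc(rep(c(1, 2), 3), c(n, 1, 1))
  ms <- array(1L, c(n, 1, 1))
  # oracle: per voxel, mean |level - mean(neighbors)|
  lev <- as.vector(strip)
  s_i <- sapply(seq_len(n), function(i) {
    nb <- lev[setdiff(max(1, i - 1):min(n, i + 1), i)]
    abs(lev[i] - mean(nb))
  })
  gl <- c(1, 2)
  ni <- c(sum(lev == 1), sum(lev == 2))
  pi_ <- ni / n
  si <- c(sum(s_i[lev == 1]), sum(s_i[lev == 2]))
  oracle_contrast <- (sum(outer(pi_, pi_) * outer(gl, gl, `-`)^2) / 2) *
    (sum(si) / n)
  f2 <- ngldm_features(strip, ms)
  expect_equal(unname(f2["ngldm_contrast"]), oracle_contrast)
})

test_that("shape features match arithmetic and approach sphere limits", {
  m1 <- array(0L, c(3, 3, 3)); m1[2, 2, 2] <- 1L
  f <- shape_features(m1, c(1, 1, 4))
  expect_equal(unname(f["shape_volume_ml"]), 0.004)
  expect_equal(unname(f["shape_voxels"]), 1)

  cube <- array(1L, c(3, 3, 3))
  expect_equal(unname(shape_features(cube, c(1, 1, 1))["shape_voxels"]), 27)

  # large digitized ball: sphericity approaches 1 from below
  r <- 20
  n <- 2 * r + 3
  ax <- (seq_len(n) - (n + 1) / 2)^2
  d2 <- outer(outer(ax, ax, `+`), ax, `+`)
  ball <- array(as.integer(d2 <= r^2), c(n, n, n))
  sph <- unname(shape_features(ball, c(1, 1, 1))["shape_sphericity"])
  expect_gt(sph, 0.9)
  expect_lt(sph, 1.05)

  expect_error(shape_features(array(0L, c(2, 2, 2))),
    class = "sarcomix_invalid_argument")
})

test_that("texture features are affine-invariant and the per-sequence count is 59", {
  set.seed(77)
  mask <- array(0L, c(8, 8, 4)); mask[2:7, 2:7, 2:3] <- 1L
  v <- array(runif(8 * 8 * 4, 5, 50), c(8, 8, 4))
  ref <- texture_features(discretize(v, mask, 16), mask)
  expect_length(ref, 59)
  expect_true(all(is.finite(ref)))
  for (i in 1:50) {
    a <- runif(1, 0.2, 8); b <- runif(1, -20, 20)
    got <- texture_features(discretize(a * v + b, mask, 16), mask)
    expect_equal(got, ref)
  }
})

test_that("ICC recovers planted variance ratios and handles edge cases", {
  # identical repeats
  x <- cbind(1:10, 1:10)
  expect_equal(icc(x), 1)

  # zero total variance is undefined
  expect_true(is.na(icc(matrix(5, 4, 2))))

  # independent noise: ICC near 0
  set.seed(8)
  noise <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc(noise)), 0.1)

  # planted subject variance 9, error variance 1: ICC ~ 0.9
  subj <- rnorm(500, 0, 3)
  reps <- cbind(subj + rnorm(500), subj + rnorm(500))
  expect_equal(icc(reps), 0.9, tolerance = 0.05)
})

test_that("the ICC filter keeps exactly the features at or above threshold", {
  feats <- tibble::tibble(id = c("a", "b"), f1 = c(1, 2), f2 = c(3, 4),
    f3 = c(5, 6))
  rep <- tibble::tibble(feature = c("f1", "f2", "f3"),
    icc = c(0.95, 0.90, 0.89), n = 30)
  kept <- filter_robust_features(feats, rep, 0.90)
  expect_equal(setdiff(names(kept), "id"), c("f1", "f2"))

  all_kept <- filter_robust_features(feats, rep, 0)
  expect_equal(setdiff(names(all_kept), "id"), c("f1", "f2", "f3"))

  expect_error(filter_robust_features(feats, rep, 1 + 1e-9),
    class = "sarcomix_invalid_argument")
})
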