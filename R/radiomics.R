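#' Handcrafted radiomics features
#'
#' Formula-defined texture and shape statistics computed on discretized
#' tumor volumes: 13 first-order histogram features, 21 co-occurrence (GLCM)
#' features (7 at each of the neighbor distances 1, 2 and 4), 11 run-length
#' (GLRLM) features, 3 neighborhood gray-level difference (NGLDM) features,
#' and 11 zone-length (GLZLM) features — 59 texture features per sequence —
#' plus 4 shape features from the contrast-enhanced mask. Texture matrices
#' aggregate the 13 unique 3-D directions; all features are invariant to
#' positive affine intensity transforms applied before discretization.
#'
#' @name radiomics
NULL

# the 13 unique 3-D direction offsets (first non-zero component positive)
gl_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# paired in-mask voxel levels along `dir` at step `d`: list(a, b) level vectors
dir_pairs <- function(lev, m, dir, d = 1) {
  dd <- dim(lev)
  off <- dir * d
  rng <- lapply(1:3, function(a) {
    lo <- max(1, 1 - off[a]); hi <- min(dd[a], dd[a] - off[a])
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(rng, is.null, logical(1)))) {
    return(list(a = integer(0), b = integer(0)))
  }
  src <- list(rng[[1]], rng[[2]], rng[[3]])
  dst <- list(rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3])
  ma <- m[src[[1]], src[[2]], src[[3]], drop = FALSE]
  mb <- m[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- ma & mb
  list(
    a = lev[src[[1]], src[[2]], src[[3]], drop = FALSE][ok],
    b = lev[dst[[1]], dst[[2]], dst[[3]], drop = FALSE][ok]
  )
}

check_disc <- function(disc, mask) {
  m <- check_mask(disc, mask)
  if (any(disc[m] < 1) || any(disc[m] != round(disc[m]))) {
    stop_invalid("`disc` must hold integer gray levels >= 1 (see discretize()).")
  }
  m
}

#' First-order histogram features
#'
#' The 13 first-order statistics of the in-mask gray-level histogram: mean,
#' standard deviation, variance (population moments), skewness, kurtosis
#' (both 0 for a degenerate histogram), minimum, maximum, median, 10th and
#' 90th percentiles, energy (sum of squared level probabilities), entropy
#' (base-2, in bits), and the number of occupied gray levels.
#'
#' @param disc Integer gray-level volume from [discretize()].
#' @param mask Binary array, non-empty.
#' @return Named numeric vector of 13 features prefixed `fo_`.
#' @export
first_order_features <- function(disc, mask) {
  m <- check_disc(disc, mask)
  x <- as.numeric(disc[m])
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- as.numeric(table(x)) / n
  c(
    fo_mean = mu, fo_sd = sqrt(m2), fo_variance = m2,
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_min = min(x), fo_max = max(x), fo_median = median(x),
    fo_p10 = unname(quantile(x, 0.10)), fo_p90 = unname(quantile(x, 0.90)),
    fo_energy = sum(p^2),
    fo_entropy = -sum(p * log2(p)),
    fo_levels = length(p)
  )
}

# accumulate the symmetric, normalized GLCM at distance d over `directions`
glcm_matrix <- function(disc, mask, d = 1, directions = gl_directions()) {
  m <- check_disc(disc, mask)
  lev <- unclass(disc)
  n_lev <- max(lev[m])
  counts <- numeric(n_lev * n_lev)
  for (r in seq_len(nrow(directions))) {
    pr <- dir_pairs(lev, m, directions[r, ], d)
    if (length(pr$a) == 0) next
    code <- c((pr$a - 1) * n_lev + pr$b, (pr$b - 1) * n_lev + pr$a)
    tb <- tabulate(code, nbins = n_lev * n_lev)
    counts <- counts + tb
  }
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  list(
    i = (which(counts > 0) - 1) %/% n_lev + 1,
    j = (which(counts > 0) - 1) %% n_lev + 1,
    p = counts[counts > 0] / tot
  )
}

glcm_features_one <- function(g) {
  if (is.null(g)) {
    return(c(homogeneity = 1, energy = 1, contrast = 0, correlation = 0,
             entropy = 0, dissimilarity = 0, idm = 1))
  }
  i <- g$i; j <- g$j; p <- g$p
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  corr <- if (var_i > 0 && var_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  } else 0
  c(
    homogeneity = sum(p / (1 + abs(i - j))),
    energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    entropy = -sum(p * log2(p)),
    dissimilarity = sum(abs(i - j) * p),
    idm = sum(p / (1 + (i - j)^2))
  )
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Builds the symmetric, overall-normalized co-occurrence matrix aggregated
#' over the 13 unique 3-D directions (only voxel pairs fully inside the
#' mask) at each neighbor distance, and emits 7 features per distance:
#' homogeneity, energy, contrast, correlation, entropy, dissimilarity, and
#' inverse difference moment. Degenerate matrices (no valid pair) yield the
#' documented neutral values of a constant image.
#'
#' @inheritParams first_order_features
#' @param distances Integer neighbor distances (default `c(1, 2, 4)`).
#' @param directions Matrix of direction offsets (rows), default all 13.
#' @return Named numeric vector of `7 * length(distances)` features.
#' @export
glcm_features <- function(disc, mask, distances = c(1, 2, 4),
                          directions = gl_directions()) {
  out <- lapply(distances, function(d) {
    f <- glcm_features_one(glcm_matrix(disc, mask, d, directions))
    setNames(f, sprintf("glcm_%s_d%d", names(f), d))
  })
  unlist(out)
}

# per-shape, per-direction traversal orders are reused across volumes
.traversal_cache <- new.env(parent = emptyenv())

# voxel visiting order along all lines of one direction, plus the
# line-start indicator in that order
direction_traversal <- function(d, dir) {
  key_str <- paste(c(d, dir), collapse = "_")
  hit <- .traversal_cache[[key_str]]
  if (!is.null(hit)) return(hit)
  co <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
    k = seq_len(d[3])))
  t_pos <- as.numeric(co %*% dir)
  norm2 <- sum(dir^2)
  keym <- co * norm2 - outer(t_pos, dir)
  key <- keym[, 1] + keym[, 2] * (4 * max(d) * norm2) +
    keym[, 3] * (4 * max(d) * norm2)^2
  ord <- order(key, t_pos)
  kv <- key[ord]
  out <- list(ord = ord, newline = c(TRUE, kv[-1] != kv[-length(kv)]))
  .traversal_cache[[key_str]] <- out
  out
}

# run-length matrix over all directions: data frame (level, len, n)
glrlm_matrix <- function(disc, mask, directions = gl_directions()) {
  m <- check_disc(disc, mask)
  lev <- unclass(disc)
  lev[!m] <- NA_integer_
  d <- dim(lev)
  lv <- as.vector(lev)
  lev_all <- integer(0); len_all <- integer(0)
  for (r in seq_len(nrow(directions))) {
    tr <- direction_traversal(d, directions[r, ])
    vv <- lv[tr$ord]
    n <- length(vv)
    brk <- tr$newline | is.na(vv) |
      c(TRUE, is.na(vv[-n])) | c(TRUE, vv[-1] != vv[-n])
    brk[is.na(brk)] <- TRUE
    rid <- cumsum(brk)
    keep <- !is.na(vv)
    if (!any(keep)) next
    rk <- rid[keep]
    lens <- tabulate(rk)
    run_ids <- which(lens > 0)
    lev_all <- c(lev_all, vv[keep][!duplicated(rk)])
    len_all <- c(len_all, lens[run_ids])
  }
  if (length(lev_all) == 0) return(NULL)
  code <- paste(lev_all, len_all)
  first <- !duplicated(code)
  agg <- data.frame(
    level = lev_all[first], len = len_all[first],
    n = as.numeric(table(factor(code, levels = code[first])))
  )
  attr(agg, "n_vox") <- sum(m)
  attr(agg, "n_dir") <- nrow(directions)
  agg
}

# the 11 standard run/zone-length features given (level, size, count) triples
rl_features <- function(level, size, n, n_runs, n_sites) {
  g2 <- level^2; l2 <- size^2
  c(
    sre = sum(n / l2) / n_runs,
    lre = sum(n * l2) / n_runs,
    gln = sum(tapply(n, level, sum)^2) / n_runs,
    rln = sum(tapply(n, size, sum)^2) / n_runs,
    rp = n_runs / n_sites,
    lgre = sum(n / g2) / n_runs,
    hgre = sum(n * g2) / n_runs,
    srlge = sum(n / (g2 * l2)) / n_runs,
    srhge = sum(n * g2 / l2) / n_runs,
    lrlge = sum(n * l2 / g2) / n_runs,
    lrhge = sum(n * g2 * l2) / n_runs
  )
}

#' Gray-level run-length (GLRLM) features
#'
#' Maximal runs of equal gray level along each of the 13 directions (runs
#' break at mask boundaries) are pooled into one run-length matrix; the 11
#' standard features are computed from it. Run percentage uses the total
#' number of voxel sites over all directions, so a single-direction run of a
#' constant n-voxel line gives `rp = 1/n`.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 features prefixed `glrlm_`.
#' @export
glrlm_features <- function(disc, mask, directions = gl_directions()) {
  rlm <- glrlm_matrix(disc, mask, directions)
  if (is.null(rlm)) {
    return(setNames(rep(0, 11), paste0("glrlm_", c(
      "sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
      "lrlge", "lrhge"
    ))))
  }
  f <- rl_features(rlm$level, rlm$len, rlm$n, sum(rlm$n),
    attr(rlm, "n_vox") * attr(rlm, "n_dir"))
  setNames(f, paste0("glrlm_", names(f)))
}

#' Neighborhood gray-level difference (NGLDM) features
#'
#' Coarseness, contrast, and busyness from the mean absolute difference
#' between each in-mask voxel's level and the mean level of its in-mask
#' 26-neighborhood. Coarseness of a perfectly flat region is capped at
#' `1e6` (the reciprocal-epsilon convention) rather than dividing by zero.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector: `ngldm_coarseness`, `ngldm_contrast`,
#'   `ngldm_busyness`.
#' @export
ngldm_features <- function(disc, mask) {
  m <- check_disc(disc, mask)
  lev <- unclass(disc)
  d <- dim(lev)
  nb_sum <- array(0, d); nb_cnt <- array(0, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rng <- lapply(1:3, function(a) {
      lo <- max(1, 1 - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) NULL else lo:hi
    })
    if (any(vapply(rng, is.null, logical(1)))) next
    s1 <- rng[[1]]; s2 <- rng[[2]]; s3 <- rng[[3]]
    d1 <- s1 + off[1]; d2 <- s2 + off[2]; d3 <- s3 + off[3]
    valid <- m[d1, d2, d3, drop = FALSE]
    nb_sum[s1, s2, s3] <- nb_sum[s1, s2, s3] +
      lev[d1, d2, d3, drop = FALSE] * valid
    nb_cnt[s1, s2, s3] <- nb_cnt[s1, s2, s3] + valid
  }
  use <- m & nb_cnt > 0
  li <- lev[use]
  diffs <- abs(li - nb_sum[use] / nb_cnt[use])
  n_tot <- sum(use)
  gl <- sort(unique(li))
  ni <- as.numeric(table(factor(li, levels = gl)))
  si <- as.numeric(tapply(diffs, factor(li, levels = gl), sum))
  si[is.na(si)] <- 0
  pi <- ni / n_tot
  denom <- sum(pi * si)
  coarseness <- if (denom < 1e-6) 1e6 else 1 / denom
  ngp <- length(gl)
  contrast <- if (ngp > 1) {
    (sum(outer(pi, pi) * outer(gl, gl, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(si) / n_tot)
  } else 0
  ipij <- gl * pi
  bus_den <- sum(abs(outer(ipij, ipij, `-`)))
  busyness <- if (bus_den > 0) sum(pi * si) / bus_den else 0
  c(ngldm_coarseness = coarseness, ngldm_contrast = contrast,
    ngldm_busyness = busyness)
}

# 26-connected iso-level zone labeling: same-level adjacencies over the 13
# half-directions form an undirected graph whose connected components are
# the zones (components via igraph; an independent flood-fill oracle
# validates this in the tests)
label_zones <- function(lev, m) {
  d <- dim(lev)
  idx <- which(m)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  I <- array(seq_len(prod(d)), d)
  lv <- as.vector(lev)
  mv <- as.vector(m)
  edges <- list()
  dirs <- gl_directions()
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    rng <- lapply(1:3, function(a) {
      lo <- max(1, 1 - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) NULL else lo:hi
    })
    if (any(vapply(rng, is.null, logical(1)))) next
    src <- as.vector(I[rng[[1]], rng[[2]], rng[[3]]])
    dst <- as.vector(I[rng[[1]] + off[1], rng[[2]] + off[2],
      rng[[3]] + off[3]])
    ok <- mv[src] & mv[dst] & lv[src] == lv[dst]
    if (any(ok)) edges[[r]] <- cbind(pos[src[ok]], pos[dst[ok]])
  }
  el <- do.call(rbind, edges)
  membership <- if (is.null(el)) {
    seq_along(idx)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    igraph::components(g)$membership
  }
  lab <- array(NA_real_, d)
  lab[idx] <- membership
  lab
}

#' Gray-level zone-length (GLZLM) features
#'
#' 26-connected zones of identical gray level inside the mask form the zone
#' matrix; the same 11 formulas as [glrlm_features()] apply with run length
#' replaced by zone size, and zone percentage = zones / in-mask voxels.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector of 11 features prefixed `glzlm_`.
#' @export
glzlm_features <- function(disc, mask) {
  m <- check_disc(disc, mask)
  lev <- unclass(disc)
  lab <- label_zones(lev, m)
  zl <- lab[m]
  sizes <- table(zl)
  zlev <- lev[m][match(as.numeric(names(sizes)), zl)]
  zs <- as.numeric(sizes)
  n_zones <- length(zs)
  f <- rl_features(zlev, zs, rep(1, n_zones), n_zones, sum(m))
  setNames(f, paste0("glzlm_", names(f)))
}

#' Shape features of a tumor mask
#'
#' Volume (mL), voxel count, sphericity, and compactness. Surface area is
#' obtained by counting exposed voxel faces on the grid (each weighted by
#' its physical face area) and multiplying by 2/3 — axis-aligned face
#' counting overestimates a smooth surface by exactly 3/2 in the
#' fine-resolution limit, so the corrected estimate makes a large digitized
#' ball converge to sphericity 1. Sphericity is
#' `pi^(1/3) * (6 V)^(2/3) / A` and compacity is the dimensionless
#' surface-to-volume compactness `V / (sqrt(pi) * A^(3/2))`.
#'
#' @param mask Binary array, non-empty.
#' @param spacing Voxel spacing in mm.
#' @return Named numeric vector: `shape_volume_ml`, `shape_voxels`,
#'   `shape_sphericity`, `shape_compacity`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- mask != 0
  if (!any(m)) stop_invalid("mask has no foreground voxel.")
  check_positive(spacing, "spacing")
  d <- dim(m)
  face_area <- c(
    spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2]
  )
  area <- 0
  for (a in 1:3) {
    pad_dim <- d; pad_dim[a] <- d[a] + 2
    padded <- array(FALSE, pad_dim)
    idx <- lapply(1:3, function(b) if (b == a) 1 + seq_len(d[a]) else seq_len(d[b]))
    padded[idx[[1]], idx[[2]], idx[[3]]] <- m
    lo <- lapply(1:3, function(b) if (b == a) seq_len(pad_dim[a] - 1) else seq_len(d[b]))
    hi <- lapply(1:3, function(b) if (b == a) 1 + seq_len(pad_dim[a] - 1) else seq_len(d[b]))
    faces <- sum(padded[lo[[1]], lo[[2]], lo[[3]]] != padded[hi[[1]], hi[[2]], hi[[3]]])
    area <- area + faces * face_area[a]
  }
  area <- area * 2 / 3 # digital-surface correction (see details)
  vox_vol <- prod(spacing)
  v_mm3 <- sum(m) * vox_vol
  c(
    shape_volume_ml = v_mm3 / 1000,
    shape_voxels = sum(m),
    shape_sphericity = pi^(1 / 3) * (6 * v_mm3)^(2 / 3) / area,
    shape_compacity = v_mm3 / (sqrt(pi) * area^1.5)
  )
}

#' All 59 texture features of one discretized volume
#'
#' The computation is restricted to the bounding box of the mask (plus a
#' one-voxel margin), which leaves every feature unchanged — pairs, runs,
#' neighborhoods and zones never cross the mask boundary — while skipping
#' background voxels.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector of 59 features.
#' @export
texture_features <- function(disc, mask) {
  m <- check_disc(disc, mask)
  bb <- lapply(1:3, function(a) {
    pr <- range(which(apply(m, a, any)))
    max(1, pr[1] - 1):min(dim(m)[a], pr[2] + 1)
  })
  dc <- unclass(disc)[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  attr(dc, "n_levels") <- attr(disc, "n_levels")
  mc <- m[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  c(
    first_order_features(dc, mc),
    glcm_features(dc, mc),
    glrlm_features(dc, mc),
    ngldm_features(dc, mc),
    glzlm_features(dc, mc)
  )
}

#' Extract the radiomics feature matrix of a cohort
#'
#' Harmonizes each channel of each study ([harmonize_volume()]), discretizes
#' in-mask intensities into 256 gray levels, computes the 59 texture
#' features per sequence plus the 4 shape features from the
#' contrast-enhanced mask, and returns one row per subject.
#'
#' @param cohort A `synthetic_cohort`, or a named list of studies as
#'   produced by [simulate_tumor_study()].
#' @param n_levels Gray levels for discretization.
#' @param target Harmonization target spacing.
#' @return A tibble: `id` plus `3 * 59 + 4 = 181` named feature columns
#'   (`<sequence>_<family>_<feature>`).
#' @export
extract_radiomics <- function(cohort, n_levels = 256, target = c(1, 1, 4)) {
  studies <- if (inherits(cohort, "synthetic_cohort")) cohort$studies else cohort
  rows <- purrr::imap(studies, function(st, id) {
    feats <- purrr::imap(st$channels, function(vol, ch) {
      h <- harmonize_volume(vol, st$mask, target = target)
      disc <- discretize(h$volume, h$mask, n_levels = n_levels)
      f <- texture_features(disc, h$mask)
      setNames(f, paste0(ch, "_", names(f)))
    })
    hce <- harmonize_volume(st$channels$ce, st$mask, target = target)
    shp <- shape_features(hce$mask, spacing(hce$volume))
    tibble::as_tibble_row(c(
      id = id, as.list(unlist(unname(feats))), as.list(shp)
    ))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, dplyr::across(-"id", as.numeric))
}

#' Intraclass correlation coefficient (two-way, absolute agreement, single)
#'
#' The ICC variant for test-retest reproducibility with the rater treated as
#' a systematic factor: two-way model, absolute agreement, single
#' measurement, from the standard mean-square decomposition. Returns `NA`
#' when the total variance is zero (undefined; treated as failing any
#' reproducibility threshold).
#'
#' @param x Numeric matrix, subjects in rows, exactly 2 repeat measurements
#'   in columns; at least 3 subjects.
#' @return ICC estimate in `(-Inf, 1]`, or `NA`.
#' @export
icc <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_invalid("exactly 2 repeats are required.")
  n <- nrow(x)
  if (n < 3) stop_invalid("at least 3 subjects are required.")
  k <- 2
  if (var(as.vector(x)) == 0) return(NA_real_)
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Per-feature ICC report from two repeat feature matrices
#'
#' @param m1,m2 Tibbles or matrices with identical feature columns (an `id`
#'   column, if present, is dropped); rows are the same subjects.
#' @return A tibble: `feature`, `icc`, `n`.
#' @export
icc_report <- function(m1, m2) {
  drop_id <- function(m) {
    if (is.data.frame(m) && "id" %in% names(m)) m <- m[setdiff(names(m), "id")]
    as.matrix(m)
  }
  a <- drop_id(m1); b <- drop_id(m2)
  if (!identical(colnames(a), colnames(b)) || nrow(a) != nrow(b)) {
    stop_invalid("repeat matrices must share features and subjects.")
  }
  tibble(
    feature = colnames(a),
    icc = vapply(seq_len(ncol(a)), function(j) icc(cbind(a[, j], b[, j])),
      numeric(1)),
    n = nrow(a)
  )
}

#' Keep only reproducible features
#'
#' Retains the feature columns whose ICC meets the threshold (boundary
#' inclusive; the conventional robustness cut is ICC >= 0.90). Undefined
#' ICCs fail the filter. Column order is preserved.
#'
#' @param features Feature tibble (an `id` column is carried through).
#' @param report Output of [icc_report()] covering every feature column.
#' @param threshold Minimum ICC (default 0.90).
#' @return Filtered feature tibble.
#' @export
filter_robust_features <- function(features, report, threshold = 0.90) {
  cols <- setdiff(names(features), "id")
  missing <- setdiff(cols, report$feature)
  if (length(missing) > 0) {
    stop_invalid(sprintf("report lacks ICC for: %s",
      paste(utils::head(missing, 3), collapse = ", ")))
  }
  iccs <- setNames(report$icc, report$feature)[cols]
  keep <- cols[!is.na(iccs) & iccs >= threshold]
  if (length(keep) == 0) stop_invalid("no feature survives the ICC filter.")
  features[c(intersect(names(features), "id"), keep)]
}
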