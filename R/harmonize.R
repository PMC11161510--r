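#' MRI intensity harmonization
#'
#' Conventional MRI has no standardized intensity units, so volumes acquired
#' on different systems are post-processed through a fixed chain before any
#' feature extraction: resampling to a common voxel size, removal of the
#' smooth multiplicative bias field caused by B1 inhomogeneity, histogram
#' matching to a cohort reference, and rescaling of the intensity range.
#' [harmonize_volume()] applies the chain in that order; the individual steps
#' are exported for testing and custom pipelines.
#'
#' @name harmonization
NULL

# trilinear interpolation of `vol` at fractional voxel indices (n x 3 matrix)
interp_trilinear <- function(vol, idx) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  i0 <- floor(idx)
  fr <- idx - i0
  gather <- function(ox, oy, oz) {
    ii <- cl(i0[, 1] + ox, d[1])
    jj <- cl(i0[, 2] + oy, d[2])
    kk <- cl(i0[, 3] + oz, d[3])
    vol[cbind(ii, jj, kk)]
  }
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- gather(0, 0, 0) * (1 - fx) + gather(1, 0, 0) * fx
  c10 <- gather(0, 1, 0) * (1 - fx) + gather(1, 1, 0) * fx
  c01 <- gather(0, 0, 1) * (1 - fx) + gather(1, 0, 1) * fx
  c11 <- gather(0, 1, 1) * (1 - fx) + gather(1, 1, 1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a volume to a target voxel spacing
#'
#' Linear interpolation in physical space. Voxel centers are placed on a
#' regular grid at the target spacing starting at the volume origin, so the
#' physical extent is preserved to within one voxel. The default target is
#' the common clinical resolution of 1 x 1 x 4 mm.
#'
#' @param vol An [image_volume()].
#' @param target Numeric length-3, target spacing in mm (> 0).
#' @return An [image_volume()] at the target spacing.
#' @export
resample_to_spacing <- function(vol, target = c(1, 1, 4)) {
  check_positive(target, "target")
  if (length(vol) == 0) stop_invalid("empty volume.")
  sp <- spacing(vol)
  d <- dim(vol)
  if (isTRUE(all.equal(sp, as.numeric(target)))) return(vol)
  extent <- (d - 1) * sp
  nd <- pmax(floor(extent / target) + 1, 1)
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * target[a] / sp[a] + 1)
  idx <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  out <- array(interp_trilinear(unclass(vol), idx), dim = nd)
  image_volume(out, spacing = as.numeric(target), origin = origin(vol))
}

# nearest-neighbour resampling for binary masks (linear + 0.5 threshold)
resample_mask <- function(mask, spacing_in, target = c(1, 1, 4)) {
  vol <- image_volume(array(as.numeric(mask != 0), dim(mask)), spacing_in)
  res <- resample_to_spacing(vol, target)
  array(as.integer(unclass(res) >= 0.5), dim(res))
}

#' Correct a smooth multiplicative bias field
#'
#' Estimates the low-frequency multiplicative intensity modulation (the
#' "bias field" of surface-coil MRI) by fitting a low-order polynomial in the
#' spatial coordinates to the log-intensities inside the mask, then divides
#' the field out over the whole volume. The mean intensity inside the mask is
#' preserved exactly. Non-positive inputs are shifted positive before the log
#' fit and shifted back.
#'
#' @param vol An [image_volume()].
#' @param mask Binary array on the same grid, non-empty.
#' @param order Total polynomial degree of the field model (default 2).
#' @return Bias-corrected [image_volume()].
#' @export
correct_bias_field <- function(vol, mask, order = 2) {
  m <- check_mask(vol, mask)
  v <- unclass(vol)
  shift <- 0
  vmin <- min(v[m])
  if (vmin <= 0) shift <- 1 - vmin
  v <- v + shift
  d <- dim(v)
  ax <- lapply(1:3, function(a) {
    if (d[a] == 1) rep(0, d[a]) else seq(-1, 1, length.out = d[a])
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  pows <- expand.grid(px = 0:order, py = 0:order, pz = 0:order)
  pows <- pows[rowSums(pows) <= order & rowSums(pows) > 0, , drop = FALSE]
  X <- vapply(seq_len(nrow(pows)), function(i) {
    g$x^pows$px[i] * g$y^pows$py[i] * g$z^pows$pz[i]
  }, numeric(nrow(g)))
  logv <- log(v[m])
  fit <- stats::lm.fit(cbind(1, X[as.vector(m), , drop = FALSE]), logv)
  field <- drop(cbind(1, X) %*% fit$coefficients)
  field <- field - mean(field[as.vector(m)])
  corrected <- v / exp(array(field, dim = d))
  corrected <- corrected * (mean(v[m]) / mean(corrected[m])) - shift
  as_image_volume(corrected, vol)
}

#' Match an intensity histogram to a reference volume
#'
#' Quantile-mapping histogram matching: the empirical quantiles of the input
#' at `n_match` probability points are mapped onto the corresponding
#' reference quantiles by monotone piecewise-linear interpolation.
#'
#' @param vol,reference [image_volume()] objects (non-empty).
#' @param n_match Number of quantile match points (default 64).
#' @return Matched [image_volume()].
#' @export
match_histogram <- function(vol, reference, n_match = 64) {
  if (length(vol) == 0 || length(reference) == 0) stop_invalid("empty volume.")
  rv <- as.vector(unclass(reference))
  v <- as.vector(unclass(vol))
  if (diff(range(rv)) == 0) {
    return(as_image_volume(array(rv[1], dim(vol)), vol))
  }
  if (diff(range(v)) == 0) {
    return(as_image_volume(array(median(rv), dim(vol)), vol))
  }
  probs <- seq(0, 1, length.out = n_match)
  qs <- quantile(v, probs, names = FALSE, type = 7)
  qr <- quantile(rv, probs, names = FALSE, type = 7)
  keep <- !duplicated(qs)
  mapped <- approx(qs[keep], qr[keep], xout = v, rule = 2, ties = "ordered")$y
  as_image_volume(array(mapped, dim(vol)), vol)
}

#' Rescale intensities to a fixed range
#'
#' Affine map of the observed `[min, max]` onto `[lo, hi]`; the defaults give
#' the conventional post-harmonization range of -10,000 to +10,000. A
#' constant volume maps to `lo` everywhere (documented convention).
#'
#' @param vol An [image_volume()].
#' @param lo,hi Output range bounds (`hi > lo`).
#' @return Rescaled [image_volume()].
#' @export
rescale_range <- function(vol, lo = -10000, hi = 10000) {
  if (hi <= lo) stop_invalid("`hi` must exceed `lo`.")
  v <- unclass(vol)
  rng <- range(v)
  if (diff(rng) == 0) {
    return(as_image_volume(array(lo, dim(vol)), vol))
  }
  as_image_volume((v - rng[1]) / diff(rng) * (hi - lo) + lo, vol)
}

#' Discretize in-mask intensities into gray levels
#'
#' Min-max binning of the in-mask intensity range into `n_levels` integer
#' levels `1..n_levels` (256 by default, the conventional choice for texture
#' analysis). The binning is invariant to positive affine transforms of the
#' input. A constant in-mask region maps to level 1.
#'
#' @param vol An [image_volume()] or numeric array.
#' @param mask Binary array, non-empty.
#' @param n_levels Number of gray levels (default 256).
#' @return Integer array of levels with attribute `n_levels`.
#' @export
discretize <- function(vol, mask, n_levels = 256) {
  m <- check_mask(vol, mask)
  v <- unclass(vol)
  rng <- range(v[m])
  if (diff(rng) == 0) {
    out <- array(1L, dim(v))
  } else {
    lev <- floor((v - rng[1]) / diff(rng) * n_levels) + 1
    out <- array(as.integer(pmin(pmax(lev, 1), n_levels)), dim(v))
  }
  attr(out, "n_levels") <- as.integer(n_levels)
  out
}

#' Extract the background-zeroed center slice of a tumor
#'
#' Selects the slice at the midpoint of the mask extent along the third
#' (through-plane) axis — the floor of the mean of the first and last
#' mask-bearing slice indices — and zeroes every out-of-mask pixel, yielding
#' the representative 2-D tumor image used by the deep-radiomics branch.
#'
#' @param vol An [image_volume()] or 3-D array.
#' @param mask Binary array, non-empty.
#' @return A 2-D matrix with attribute `slice_index`.
#' @export
extract_center_slice <- function(vol, mask) {
  m <- check_mask(vol, mask)
  zs <- which(apply(m, 3, any))
  k <- floor((zs[1] + zs[length(zs)]) / 2)
  sl <- unclass(vol)[, , k]
  sl[!m[, , k]] <- 0
  attr(sl, "slice_index") <- k
  sl
}

#' Apply the full harmonization chain
#'
#' Resample to the target spacing, correct the bias field, optionally match
#' the histogram to a reference volume, and rescale to `[-10000, 10000]`;
#' the mask is propagated onto the resampled grid.
#'
#' @param vol An [image_volume()].
#' @param mask Binary array on the input grid.
#' @param reference Optional reference [image_volume()] for histogram
#'   matching (already harmonized up to the matching step); `NULL` skips it.
#' @param target Target spacing in mm.
#' @param order Bias-field polynomial order.
#' @return A list with elements `volume` (harmonized [image_volume()]) and
#'   `mask` (resampled binary array).
#' @export
harmonize_volume <- function(vol, mask, reference = NULL,
                             target = c(1, 1, 4), order = 2) {
  res <- resample_to_spacing(vol, target)
  m2 <- resample_mask(mask, spacing(vol), target)
  if (!any(m2 != 0)) m2 <- array(as.integer(unclass(resample_to_spacing(
    image_volume(array(as.numeric(mask != 0), dim(mask)), spacing(vol)), target
  )) > 0), dim(res))
  out <- correct_bias_field(res, m2, order = order)
  if (!is.null(reference)) out <- match_histogram(out, reference)
  list(volume = rescale_range(out), mask = m2)
}
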