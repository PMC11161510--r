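#' Gridded image volume with physical spacing
#'
#' A minimal 3-D image container: a numeric array carrying voxel spacing (mm)
#' and the physical origin of voxel `(1, 1, 1)`. All harmonization and
#' radiomics operations consume and return `image_volume` objects (or plain
#' arrays where intensities have been discretized).
#'
#' @param values Numeric 3-D array of signal intensities.
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @param origin Numeric length-3 vector, physical coordinates of the first
#'   voxel center. Defaults to the origin.
#'
#' @return An `image_volume`: the array with `spacing` and `origin` attributes.
#' @export
#' @examples
#' vol <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(2, 2, 4))
#' spacing(vol)
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop_invalid("`values` must be a 3-D array.")
  }
  if (any(!is.finite(values))) stop_invalid("`values` must be finite.")
  check_positive(spacing, "spacing")
  structure(values,
    spacing = as.numeric(spacing), origin = as.numeric(origin),
    class = c("image_volume", "array")
  )
}

#' @rdname image_volume
#' @param x An `image_volume`.
#' @export
spacing <- function(x) attr(x, "spacing") %||% c(1, 1, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

origin <- function(x) attr(x, "origin") %||% c(0, 0, 0)

# Rebuild an image_volume around a plain array, inheriting geometry from `like`.
as_image_volume <- function(values, like, spacing = NULL, origin = NULL) {
  image_volume(values,
    spacing = spacing %||% spacing(like),
    origin = origin %||% origin(like)
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], paste(signif(spacing(x), 4), collapse = " x "),
    min(x), max(x)
  ))
  invisible(x)
}

# Binary mask checks -----------------------------------------------------

check_mask <- function(vol, mask, require_nonempty = TRUE) {
  if (!identical(dim(vol), dim(mask))) {
    stop_invalid("mask and volume must share the same grid.")
  }
  m <- mask != 0
  if (require_nonempty && !any(m)) stop_invalid("mask has no foreground voxel.")
  m
}
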