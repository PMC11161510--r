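#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd var median quantile rnorm runif rexp rbinom rnbinom
#'   rlnorm na.omit setNames approx cor pchisq phyper p.adjust
NULL

# Run expr with a local RNG stream seeded at `seed`, restoring the caller's
# RNG state afterwards so generators are pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    images = 101L, survival = 211L, expression = 307L, cohort = 401L,
    cae = 503L, cluster = 601L, folds = 701L, bootstrap = 809L
  )
  off <- offsets[[stage]]
  if (is.null(off)) off <- sum(utf8ToInt(stage))
  (as.integer(seed) * 7919L + off) %% 214748329L
}

stop_invalid <- function(msg) abort(msg, class = "sarcomix_invalid_argument")

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (bad) {
    stop_invalid(sprintf(
      "`%s` must be %s.", name, if (strict) "strictly positive" else "non-negative"
    ))
  }
  invisible(x)
}
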