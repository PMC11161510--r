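#' Resampling-based consensus clustering
#'
#' Stability-based clustering of a feature matrix: the cohort is repeatedly
#' subsampled (each resample retains a random 60% of subjects by default,
#' i.e. 40% are left out), each subsample is partitioned by agglomerative
#' average-linkage clustering under the Pearson distance, and the proportion
#' of co-sampled resamples in which two subjects co-cluster forms the
#' consensus matrix. Final labels come from clustering the consensus matrix
#' itself; the number of clusters is chosen by the delta-area criterion on
#' the consensus CDF unless fixed. Fitted models store the feature scaling
#' and cluster centroids so new observations can be assigned by nearest
#' Pearson-distance centroid.
#'
#' @name consensus
NULL

#' Center and scale a feature matrix
#'
#' Columns are centered to mean 0 and scaled to unit standard deviation
#' (population convention by default, matching the arithmetic `[1, 2, 3] ->
#' [-1.2247, 0, 1.2247]`; sample convention available). Zero-variance
#' columns are dropped with a warning.
#'
#' @param x Numeric matrix or feature tibble (an `id` column, if present, is
#'   used for row names and dropped); at least 2 rows.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Scaled matrix with attributes `center` and `scale`.
#' @export
center_scale <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.data.frame(x)) {
    rn <- if ("id" %in% names(x)) x$id else NULL
    x <- as.matrix(x[setdiff(names(x), "id")])
    if (!is.null(rn)) rownames(x) <- rn
  }
  if (nrow(x) < 2) stop_invalid("at least 2 subjects are required.")
  ctr <- colMeans(x)
  n <- nrow(x)
  sds <- sqrt(colSums(sweep(x, 2, ctr)^2) /
    (if (sd_type == "population") n else n - 1))
  bad <- sds == 0 | !is.finite(sds)
  if (all(bad)) stop_invalid("all columns are degenerate.")
  if (any(bad)) {
    warn(sprintf("dropping %d zero-variance column(s).", sum(bad)))
  }
  out <- sweep(sweep(x[, !bad, drop = FALSE], 2, ctr[!bad]), 2, sds[!bad], `/`)
  attr(out, "center") <- ctr[!bad]
  attr(out, "scale") <- sds[!bad]
  out
}

#' Pearson distance between observation vectors
#'
#' `1 - cor(x, y)`, in `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length >= 2, non-constant.
#' @return The Pearson distance.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("vectors must have equal length >= 2.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_invalid("Pearson distance is undefined for constant vectors.")
  }
  1 - cor(x, y)
}

# full pairwise Pearson distance between rows
pearson_dist_matrix <- function(x) {
  if (any(apply(x, 1, sd) == 0)) {
    stop_invalid("Pearson distance is undefined for constant rows.")
  }
  d <- 1 - cor(t(x))
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Cut an average-linkage tree into k clusters
#'
#' Agglomerative hierarchical clustering (average linkage) of a distance
#' matrix, cut into `k` groups. Merge ties follow the deterministic order of
#' [stats::hclust()].
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Integer cluster labels.
#' @export
hierarchical_cluster <- function(d, k) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n) stop_invalid("`k` cannot exceed the number of observations.")
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

# area under the empirical CDF of the upper-triangle consensus entries
consensus_cdf_area <- function(cons) {
  v <- sort(cons[upper.tri(cons)])
  if (length(v) == 0) return(0)
  xs <- c(0, v, 1)
  cdf <- c(0, seq_along(v) / length(v), 1)
  sum(diff(xs) * cdf[-length(cdf)])
}

# proportion of ambiguously clustered pairs (consensus strictly between the
# clear co-cluster / separate-cluster bands)
consensus_pac <- function(cons, lower = 0.1, upper = 0.9) {
  v <- cons[upper.tri(cons)]
  if (length(v) == 0) return(0)
  mean(v > lower & v < upper)
}

#' Consensus clustering with automatic model-order selection
#'
#' @param x Feature matrix or tibble (subjects in rows); scaled internally
#'   via [center_scale()].
#' @param k_range Candidate cluster numbers (default `2:5`).
#' @param B Number of resamples (the reference protocol uses 10,000;
#'   smaller values are adequate at desk scale).
#' @param holdout Fraction of subjects left out per resample (default 0.40,
#'   i.e. 60% retained).
#' @param seed Integer seed.
#' @param k_fixed Optional fixed `k`, bypassing selection.
#' @param pac_threshold Maximum tolerated proportion of ambiguously
#'   clustered pairs (consensus entries strictly inside `(0.1, 0.9)`); the
#'   largest `k` within tolerance is selected. At a clean partition every
#'   pair is either always or never co-clustered, so the proportion is 0
#'   for every `k` up to the true cluster number and rises sharply beyond
#'   it, where tight groups are split arbitrarily. If no candidate is
#'   within tolerance the `k` minimizing the proportion is used. The
#'   consensus-CDF areas underlying the classical delta-area display are
#'   kept in `settings$areas` for inspection.
#' @param scale Logical; set `FALSE` if `x` is already scaled.
#' @return A `consensus_model`: consensus matrix, selected `k`, size-ordered
#'   labels (`A` = largest cluster), centroids on the scaled features,
#'   scaling parameters, and settings.
#' @export
consensus_cluster <- function(x, k_range = 2:5, B = 1000, holdout = 0.40,
                              seed = 1, k_fixed = NULL,
                              pac_threshold = 0.02, scale = TRUE) {
  xs <- if (scale) center_scale(x) else as.matrix(x)
  n <- nrow(xs)
  if (n < 10) stop_invalid("at least 10 subjects are required.")
  if (B < 1) stop_invalid("`B` must be >= 1.")
  k_range <- sort(unique(pmin(k_range, n)))
  n_keep <- max(2, floor((1 - holdout) * n))
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sort(sample.int(n, n_keep))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      d <- pearson_dist_matrix(xs[idx, , drop = FALSE])
      tree <- stats::hclust(d, method = "average")
      for (k in k_range) {
        if (k > n_keep) next
        lab <- stats::cutree(tree, k = k)
        for (g in seq_len(k)) {
          gi <- idx[lab == g]
          co_clustered[[as.character(k)]][gi, gi] <-
            co_clustered[[as.character(k)]][gi, gi] + 1
        }
      }
    }
  })
  never <- co_sampled == 0
  consensus_of <- function(k) {
    cc <- co_clustered[[as.character(k)]]
    cons <- cc / pmax(co_sampled, 1)
    if (any(never[upper.tri(never)])) cons[never] <- 0.5
    diag(cons) <- 1
    cons
  }
  if (any(never[upper.tri(never)])) {
    warn("some pairs were never co-sampled; consensus imputed at 0.5.")
  }
  cons_all <- lapply(k_range, consensus_of)
  names(cons_all) <- as.character(k_range)
  areas <- vapply(cons_all, consensus_cdf_area, numeric(1))
  pacs <- vapply(cons_all, consensus_pac, numeric(1))
  if (!is.null(k_fixed)) {
    if (!k_fixed %in% k_range) stop_invalid("`k_fixed` must lie in `k_range`.")
    k_sel <- k_fixed
  } else {
    ok <- which(pacs <= pac_threshold)
    k_sel <- if (length(ok) > 0) k_range[max(ok)] else k_range[which.min(pacs)]
  }
  cons <- cons_all[[as.character(k_sel)]]
  labels <- hierarchical_cluster(stats::as.dist(1 - cons), k_sel)
  model <- structure(
    list(
      consensus = cons, k = k_sel, labels = labels,
      centroids = NULL,
      scaling = list(center = attr(xs, "center"), scale = attr(xs, "scale")),
      features = colnames(xs),
      settings = list(
        B = B, holdout = holdout, k_range = k_range, seed = seed,
        areas = setNames(areas, k_range), pac = setNames(pacs, k_range),
        pac_threshold = pac_threshold
      ),
      ids = rownames(xs)
    ),
    class = "consensus_model"
  )
  model <- label_clusters_by_size(model)
  model$centroids <- do.call(rbind, lapply(
    sort(unique(model$labels)),
    function(g) colMeans(xs[model$labels == g, , drop = FALSE])
  ))
  rownames(model$centroids) <- sort(unique(model$labels))
  model
}

#' Rename clusters by decreasing size
#'
#' Clusters are relabeled `A`, `B`, `C`, ... with `A` the most numerous
#' group; ties keep the original label order.
#'
#' @param model A `consensus_model` (or any object with a `labels` field).
#' @return The model with letter labels.
#' @export
label_clusters_by_size <- function(model) {
  lab <- model$labels
  sizes <- table(lab)
  ord <- names(sizes)[order(-as.numeric(sizes), seq_along(sizes))]
  new <- setNames(LETTERS[seq_along(ord)], ord)
  model$labels <- unname(new[as.character(lab)])
  names(model$labels) <- model$ids
  model
}

#' Assign new observations to consensus clusters by nearest centroid
#'
#' Each new observation is scaled with the model's stored scaling parameters
#' and assigned the label of the cluster centroid at minimal Pearson
#' distance; exact ties go to the lexicographically first label.
#'
#' @param model A fitted `consensus_model`.
#' @param new_obs Numeric matrix/tibble of new observations (columns must
#'   cover the model's features).
#' @return Character vector of cluster labels.
#' @export
assign_by_centroid <- function(model, new_obs) {
  if (is.data.frame(new_obs)) {
    new_obs <- as.matrix(new_obs[setdiff(names(new_obs), "id")])
  }
  if (is.null(dim(new_obs))) new_obs <- matrix(new_obs, nrow = 1)
  p <- ncol(model$centroids)
  if (!is.null(model$features) && !is.null(colnames(new_obs))) {
    if (!all(model$features %in% colnames(new_obs))) {
      stop_invalid("new observations lack model features.")
    }
    new_obs <- new_obs[, model$features, drop = FALSE]
  } else if (ncol(new_obs) != p) {
    stop_invalid("feature count mismatch.")
  }
  xs <- sweep(sweep(new_obs, 2, model$scaling$center), 2,
    model$scaling$scale, `/`)
  labs <- rownames(model$centroids)
  apply(xs, 1, function(v) {
    d <- vapply(labs, function(g) pearson_distance(v, model$centroids[g, ]),
      numeric(1))
    labs[order(d, labs)][1]
  })
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf(
    "<consensus_model> k = %d, n = %d, B = %d (holdout %.0f%%)\n",
    x$k, length(x$labels), x$settings$B, 100 * x$settings$holdout
  ))
  print(table(x$labels))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.consensus_model <- function(x, ...) {
  tibble(
    id = x$ids %||% as.character(seq_along(x$labels)),
    cluster = unname(x$labels)
  )
}

#' @export
glance.consensus_model <- function(x, ...) {
  tibble(
    k = x$k, n = length(x$labels), B = x$settings$B,
    holdout = x$settings$holdout,
    mean_consensus = mean(x$consensus[upper.tri(x$consensus)])
  )
}

#' Consensus-matrix heatmap
#'
#' @param object A `consensus_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.consensus_model <- function(object, ...) {
  ord <- order(object$labels)
  m <- object$consensus[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(nrow(m)))
  df$consensus <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
      limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Consensus matrix (k = %d)", object$k)
    )
}

#' @export
autoplot
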