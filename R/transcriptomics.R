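#' Transcriptomics: normalization, differential expression, enrichment,
#' and discriminant signatures
#'
#' Batch correction (empirical-Bayes location/scale adjustment), voom
#' normalization of counts to log2-CPM with precision weights, per-gene
#' Welch t-test differential expression gated at fold change 2 with
#' Benjamini-Hochberg adjustment, hypergeometric over-representation
#' enrichment of genesets, and a nearest-shrunken-centroid discriminant
#' classifier.
#'
#' @name transcriptomics
NULL

#' Empirical-Bayes batch correction of log-scale expression
#'
#' Parametric location/scale batch adjustment (ComBat). A single batch is
#' the identity; batches with fewer than 2 samples are rejected because
#' their scale cannot be estimated.
#'
#' @param x Numeric matrix, genes x samples, log scale.
#' @param batches Batch label per sample.
#' @return Corrected matrix of the same shape.
#' @export
combat_correct <- function(x, batches) {
  x <- as.matrix(x)
  batches <- as.character(batches)
  if (length(batches) != ncol(x)) stop_invalid("`batches` misaligned.")
  tb <- table(batches)
  if (length(tb) == 1) return(x)
  if (any(tb < 2)) stop_invalid("every batch needs >= 2 samples.")
  if (!requireNamespace("sva", quietly = TRUE)) {
    stop_invalid("the sva package is required for multi-batch correction.")
  }
  keep <- apply(x, 1, function(r) stats::var(r) > 0)
  out <- x
  corrected <- suppressMessages(
    sva::ComBat(dat = x[keep, , drop = FALSE], batch = factor(batches))
  )
  out[keep, ] <- corrected
  out
}

#' Voom normalization of counts
#'
#' Log2 counts-per-million with a 0.5 offset and inverse-variance precision
#' weights from the fitted mean-variance trend, via limma's voom under a
#' group-means design.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param groups Optional group label per sample (defaults to a single
#'   group / intercept design).
#' @return A list: `logcpm` (genes x samples), `weights` (same shape,
#'   strictly positive), `voom` (the underlying EList).
#' @export
voom_normalize <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_invalid("counts must be non-negative.")
  if (any(colSums(counts) == 0)) stop_invalid("library sizes must be > 0.")
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop_invalid("the limma package is required.")
  }
  design <- if (is.null(groups)) {
    matrix(1, ncol(counts), 1)
  } else {
    stats::model.matrix(~ 0 + factor(as.character(groups)))
  }
  v <- limma::voom(counts, design = design)
  list(logcpm = v$E, weights = v$weights, voom = v)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Differential expression by per-gene Welch t-test
#'
#' Per-gene Welch t-test on log2 expression between two groups; a gene is
#' called up/down only when its BH-adjusted p-value passes `alpha` AND its
#' absolute fold change reaches `fc_threshold` (the conventional gate is
#' fold change 2). Degenerate per-gene variances are floored and flagged.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale.
#' @param groups Binary group label per sample (>= 2 samples per group).
#' @param fc_threshold Fold-change gate on the linear scale (default 2).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return A `dge_result` tibble: `gene`, `log2_fc`, `t`, `p_value`,
#'   `p_adjusted`, `call` (`up`/`down`/`ns`), `neg_log10_padj`,
#'   `variance_floored`.
#' @export
dge_ttest <- function(expr, groups, fc_threshold = 2, alpha = 0.05) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop_invalid("exactly 2 groups are required.")
  i1 <- groups == lv[1]; i2 <- groups == lv[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop_invalid("each group needs >= 2 samples.")
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1, var)
  v2 <- apply(expr[, i2, drop = FALSE], 1, var)
  floor_v <- 1e-8
  floored <- v1 < floor_v | v2 < floor_v
  v1 <- pmax(v1, floor_v); v2 <- pmax(v2, floor_v)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  padj <- bh_adjust(p)
  lfc <- m1 - m2
  sig <- padj < alpha & abs(lfc) >= log2(fc_threshold)
  out <- tibble(
    gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    log2_fc = lfc, t = tstat, p_value = p, p_adjusted = padj,
    call = ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down")),
    neg_log10_padj = -log10(pmax(padj, 1e-300)),
    variance_floored = floored
  )
  class(out) <- c("dge_result", class(out))
  attr(out, "groups") <- lv
  out
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `dge_result` from [dge_ttest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dge_result <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(.data$log2_fc, .data$neg_log10_padj, color = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
      color = NULL)
}

#' Hypergeometric over-representation enrichment
#'
#' For each geneset, the over-representation p-value of the differentially
#' expressed genes among the set members within the universe, adjusted
#' across sets by Benjamini-Hochberg. The activation status is the
#' proportion of the set's DE genes called up-regulated. Sets with no
#' member in the universe are skipped.
#'
#' @param de_genes Character vector of DE gene ids (subset of `universe`).
#' @param universe Character vector of all tested gene ids.
#' @param genesets Named list of character vectors.
#' @param direction_calls Optional named vector (`up`/`down`) over
#'   `de_genes` for the activation proportion.
#' @return A tibble: `geneset`, `n_set`, `n_overlap`, `p_value`,
#'   `p_adjusted`, `prop_up`.
#' @export
geneset_enrichment <- function(de_genes, universe, genesets,
                               direction_calls = NULL) {
  if (!all(de_genes %in% universe)) {
    stop_invalid("`de_genes` must be a subset of `universe`.")
  }
  N <- length(universe); K <- length(de_genes)
  rows <- purrr::imap(genesets, function(members, nm) {
    set_u <- intersect(members, universe)
    if (length(set_u) == 0) return(NULL)
    ov <- intersect(set_u, de_genes)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, length(set_u), lower.tail = FALSE)
    prop_up <- if (!is.null(direction_calls) && k > 0) {
      mean(direction_calls[ov] == "up")
    } else NA_real_
    tibble(geneset = nm, n_set = length(set_u), n_overlap = k,
      p_value = p, prop_up = prop_up)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_adjusted <- bh_adjust(out$p_value)
  dplyr::arrange(out[, c("geneset", "n_set", "n_overlap", "p_value",
    "p_adjusted", "prop_up")], .data$p_value)
}

#' Read a GMT geneset file
#'
#' @param path Path to a tab-separated GMT file (name, description,
#'   members...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    setNames(list(parts[-(1:2)]), parts[1])
  })
  do.call(c, out)
}

# Nearest shrunken centroids -------------------------------------------

#' Train a nearest-shrunken-centroid classifier
#'
#' The standardized class-vs-overall centroid differences
#' `d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0))` are soft-thresholded at
#' `delta` and the shrunken class centroids rebuilt from the surviving
#' components; classification minimizes the standardized discriminant score
#' with a log-prior term. `delta` is selected by cross-validation with the
#' one-standard-error rule; the genes with any surviving component form the
#' discriminant signature. At `delta = 0` the classifier reduces to plain
#' diagonal-covariance nearest-centroid classification.
#'
#' @param expr Numeric matrix, genes x samples, log scale.
#' @param labels Class label per sample (>= 2 classes, each >= 2 samples).
#' @param delta_grid Candidate shrinkage amounts; defaults to 30 values
#'   spanning 0 to the largest |d_kj|.
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return A `pam_model`: centroids, shrunken differences, `s` and `s0`,
#'   priors, chosen `delta`, CV error curve, signature gene ids.
#' @export
pam_train <- function(expr, labels, delta_grid = NULL, cv_folds = 5,
                      seed = 1) {
  expr <- as.matrix(expr)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop_invalid(">= 2 classes are required.")
  if (any(table(labels) < 2)) stop_invalid("every class needs >= 2 samples.")
  fitted <- pam_fit(expr, labels)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(fitted$d)) * 0.999, length.out = 30)
  }
  folds <- make_folds(as.integer(factor(labels)), cv_folds, seed)
  errs <- matrix(NA_real_, cv_folds, length(delta_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < length(cls)) next
    fit_f <- pam_fit(expr[, tr, drop = FALSE], labels[tr])
    for (j in seq_along(delta_grid)) {
      pred <- pam_predict_fit(fit_f, expr[, !tr, drop = FALSE],
        delta_grid[j])
      errs[f, j] <- mean(pred != labels[!tr])
    }
  }
  cv_err <- colMeans(errs, na.rm = TRUE)
  cv_se <- apply(errs, 2, function(e) sd(e, na.rm = TRUE) /
    sqrt(sum(!is.na(e))))
  best <- which.min(cv_err)
  within_1se <- which(cv_err <= cv_err[best] + cv_se[best])
  delta <- max(delta_grid[within_1se])
  dprime <- soft_threshold(fitted$d, delta)
  signature <- rownames(expr)[rowSums(abs(dprime) > 0) > 0]
  if (length(signature) == 0) {
    warn("chosen delta eliminates every gene; predictions fall back to priors.")
  }
  structure(c(fitted, list(
    delta = delta, delta_grid = delta_grid, cv_error = cv_err,
    cv_se = cv_se, signature = signature
  )), class = "pam_model")
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

# raw NSC statistics on a training matrix
pam_fit <- function(expr, labels) {
  cls <- sort(unique(labels))
  n <- ncol(expr)
  nk <- table(labels)[cls]
  overall <- rowMeans(expr)
  cent <- vapply(cls, function(k) rowMeans(expr[, labels == k, drop = FALSE]),
    numeric(nrow(expr)))
  # pooled within-class standard deviation
  ss <- Reduce(`+`, lapply(cls, function(k) {
    xk <- expr[, labels == k, drop = FALSE]
    rowSums((xk - cent[, k])^2)
  }))
  s <- sqrt(ss / (n - length(cls)))
  s0 <- median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- vapply(seq_along(cls), function(i) {
    (cent[, i] - overall) / (mk[i] * (s + s0))
  }, numeric(nrow(expr)))
  colnames(d) <- cls
  list(classes = cls, overall = overall, centroids = cent, s = s, s0 = s0,
    mk = setNames(mk, cls), priors = as.numeric(nk) / n, d = d,
    genes = rownames(expr))
}

pam_predict_fit <- function(fit, newdata, delta) {
  dprime <- soft_threshold(fit$d, delta)
  shrunken <- fit$overall +
    sweep(dprime, 2, fit$mk, `*`) * (fit$s + fit$s0)
  newdata <- as.matrix(newdata)
  scores <- vapply(seq_along(fit$classes), function(i) {
    colSums((newdata - shrunken[, i])^2 / (fit$s + fit$s0)^2) -
      2 * log(fit$priors[i])
  }, numeric(ncol(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[apply(scores, 1, which.min)]
}

#' Predict classes with a trained nearest-shrunken-centroid model
#'
#' @param model A `pam_model`.
#' @param newdata Numeric matrix, genes x samples, same gene order as
#'   training.
#' @param delta Optional shrinkage override (defaults to the CV-chosen
#'   value).
#' @return Character vector of predicted class labels.
#' @export
pam_predict <- function(model, newdata, delta = NULL) {
  delta <- delta %||% model$delta
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != length(model$overall)) {
    stop_invalid("gene dimension mismatch.")
  }
  if (all(soft_threshold(model$d, delta) == 0)) {
    # empty signature: fall back to the prior-majority class
    return(rep(model$classes[which.max(model$priors)], ncol(newdata)))
  }
  pam_predict_fit(model, newdata, delta)
}

#' @export
print.pam_model <- function(x, ...) {
  cat(sprintf(
    "<pam_model> %d classes, delta = %.3f, signature = %d gene(s)\n",
    length(x$classes), x$delta, length(x$signature)
  ))
  invisible(x)
}
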