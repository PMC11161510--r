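#' Survival and association statistics
#'
#' Kaplan-Meier estimation, log-rank tests, Cox proportional-hazards
#' regression (uni- and multivariable, with backward selection minimizing
#' the AIC), Harrell's concordance index with 5-fold cross-validation and
#' bootstrap model comparison, contingency-table and rank tests, the
#' nomogram-probability grouping, the 2-of-3 semantic radiophenotype rule,
#' and the combined radiomic-transcriptomic group construction. Standard
#' estimators delegate to the survival package; the concordance machinery is
#' implemented here with the explicit pair conventions documented below.
#'
#' @name survival-stats
NULL

check_records <- function(data) {
  if (!all(c("time", "event") %in% names(data))) {
    stop_invalid("`data` needs `time` and `event` columns.")
  }
  if (any(!is.finite(data$time)) || any(data$time <= 0)) {
    stop_invalid("`time` must be finite and > 0.")
  }
  if (!all(data$event %in% c(0, 1))) stop_invalid("`event` must be 0/1.")
  invisible(data)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood standard errors. A dataset with no
#' events yields the constant curve S(t) = 1.
#'
#' @param data Data frame with `time` (months) and `event` (0/1).
#' @return A `km_estimate`: tibble of steps (`time`, `n_risk`, `n_event`,
#'   `surv`, `std_err`) with the fitted [survival::survfit] object attached.
#' @export
km_estimate <- function(data) {
  check_records(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  steps <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv,
    # Greenwood standard error on the survival scale; 0 once S(t) = 0
    std_err = ifelse(fit$surv > 0, fit$std.err * fit$surv, 0)
  )
  structure(list(steps = steps, fit = fit, n = nrow(data)),
    class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d event times\n", x$n,
    sum(x$steps$n_event > 0)))
  invisible(x)
}

#' Survival probability at arbitrary times
#'
#' Right-continuous step lookup on a [km_estimate()].
#'
#' @param km A `km_estimate`.
#' @param t Numeric vector of times.
#' @return S(t) values.
#' @export
km_prob <- function(km, t) {
  st <- km$steps[km$steps$n_event > 0, ]
  if (nrow(st) == 0) return(rep(1, length(t)))
  f <- stats::stepfun(st$time, c(1, st$surv), right = FALSE)
  f(t)
}

#' @export
tidy.km_estimate <- function(x, ...) x$steps

#' Kaplan-Meier curve plot
#' @param object A `km_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, surv = 1),
    object$steps[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability")
}

#' Log-rank test between groups
#'
#' @param data Data frame with `time`, `event`.
#' @param groups Group label per row (>= 2 non-empty groups).
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, groups) {
  check_records(data)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop_invalid("need >= 2 groups.")
  d <- dplyr::mutate(data, .group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group, data = d)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
    p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling and Wald 95% confidence
#' intervals. Rows with missing covariates are dropped (complete-case) and
#' counted.
#'
#' @param data Data frame with `time`, `event`, and covariate columns.
#' @param covariates Character vector of covariate names.
#' @return A `cox_fit`: coefficient tibble (`term`, `estimate`, `std_error`,
#'   `hr`, `conf_low`, `conf_high`, `p_value`), log-likelihood, AIC, `n`,
#'   dropped-row count, convergence flag.
#' @export
cox_fit <- function(data, covariates) {
  check_records(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    stop_invalid(sprintf("missing covariate column(s): %s",
      paste(miss, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[covariates])
  d <- data[cc, , drop = FALSE]
  for (v in covariates) {
    vals <- d[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      stop_invalid(sprintf("covariate `%s` is constant (degenerate design).", v))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  s <- summary(fit)
  coefs <- tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    std_error = s$coefficients[, "se(coef)"],
    hr = s$coefficients[, "exp(coef)"],
    conf_low = s$conf.int[, "lower .95"],
    conf_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  structure(list(
    coefficients = coefs,
    loglik = fit$loglik[length(fit$loglik)],
    aic = stats::AIC(fit),
    n = nrow(d), n_dropped = sum(!cc),
    converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
    covariates = covariates, fit = fit, data = d
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (%d dropped), AIC = %.2f\n",
    x$n, x$n_dropped, x$aic))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_dropped = x$n_dropped, loglik = x$loglik, aic = x$aic,
    converged = x$converged)
}

#' Backward covariate elimination minimizing the AIC
#'
#' Starting from the full Cox model, repeatedly removes the covariate whose
#' removal most decreases the AIC, until no removal decreases it. The final
#' AIC is therefore never above the full-model AIC.
#'
#' @inheritParams cox_fit
#' @return A `cox_fit` with an extra `trace` tibble (`step`, `removed`,
#'   `aic`).
#' @export
stepwise_backward_aic <- function(data, covariates) {
  current <- covariates
  fit <- cox_fit(data, current)
  trace <- tibble(step = 0L, removed = NA_character_, aic = fit$aic)
  step <- 0L
  while (length(current) > 1) {
    cand <- purrr::map_dbl(current, function(v) {
      cox_fit(data, setdiff(current, v))$aic
    })
    if (min(cand) >= fit$aic) break
    drop_v <- current[which.min(cand)]
    current <- setdiff(current, drop_v)
    fit <- cox_fit(data, current)
    step <- step + 1L
    trace <- dplyr::bind_rows(trace,
      tibble(step = step, removed = drop_v, aic = fit$aic))
  }
  fit$trace <- trace
  fit
}

#' Harrell's concordance index
#'
#' The proportion of orderable pairs in which the subject with the higher
#' risk score fails first. A pair is orderable when the earlier time is an
#' event and the times differ; tied risk scores count 1/2.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param data Data frame with `time`, `event` aligned to `risk`.
#' @return A tibble: `cindex`, `concordant`, `discordant`, `tied_risk`,
#'   `usable_pairs`.
#' @export
harrell_cindex <- function(risk, data) {
  check_records(data)
  if (length(risk) != nrow(data)) stop_invalid("`risk` misaligned with data.")
  t <- data$time; e <- data$event
  n <- length(t)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    # orderable: strictly earlier time with an event
    ei <- t[i] < t[j] & e[i] == 1
    ej <- t[j] < t[i] & e[j] == 1
    di <- risk[i] - risk[j]
    conc <- conc + sum(ei & di > 0) + sum(ej & di < 0)
    disc <- disc + sum(ei & di < 0) + sum(ej & di > 0)
    tied <- tied + sum((ei | ej) & di == 0)
  }
  usable <- conc + disc + tied
  if (usable == 0) stop_invalid("no orderable pair under censoring.")
  tibble(
    cindex = (conc + tied / 2) / usable, concordant = conc,
    discordant = disc, tied_risk = tied, usable_pairs = usable
  )
}

# event-stratified fold assignment
make_folds <- function(event, folds, seed) {
  with_seed(seed, {
    f <- integer(length(event))
    for (lv in unique(event)) {
      idx <- which(event == lv)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
}

#' Cross-validated concordance of a Cox model
#'
#' Event-stratified k-fold cross-validation: the model is fit on the
#' training folds, held-out subjects are scored by their linear predictor,
#' and the concordance is computed on the held-out fold only. Folds without
#' any orderable pair are skipped with a warning.
#'
#' @inheritParams cox_fit
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble: `cindex` (mean over folds), `conf_low`, `conf_high`
#'   (percentile 95% interval across folds), `n_folds`, and the per-fold
#'   values in a list column `fold_values`.
#' @export
cv_cindex <- function(data, covariates, folds = 5, seed = 1) {
  check_records(data)
  if (sum(data$event) < folds) stop_invalid("need at least `folds` events.")
  fold_id <- make_folds(data$event, folds, seed)
  vals <- c()
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    fit <- try(cox_fit(train, covariates), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warn(sprintf("fold %d skipped (degenerate training data).", f))
      next
    }
    lp <- predict_cox(fit, test)
    ci <- try(harrell_cindex(lp, test)$cindex, silent = TRUE)
    if (inherits(ci, "try-error")) {
      warn(sprintf("fold %d skipped (no orderable pair).", f))
      next
    }
    vals <- c(vals, ci)
  }
  if (length(vals) == 0) stop_invalid("no usable fold.")
  tibble(
    cindex = mean(vals),
    conf_low = unname(quantile(vals, 0.025)),
    conf_high = unname(quantile(vals, 0.975)),
    n_folds = length(vals), fold_values = list(vals)
  )
}

# linear predictor of a cox_fit on new data (handles new factor rows via
# model frame reconstruction)
predict_cox <- function(fit, newdata) {
  unname(stats::predict(fit$fit, newdata = newdata, type = "lp"))
}

#' Bootstrap comparison of two models' cross-validated concordance
#'
#' For each bootstrap replicate, subjects are resampled with replacement and
#' both models' cross-validated concordance indices are recomputed; the
#' two-sided p-value is the doubled smaller tail proportion of the
#' difference distribution around zero (percentile convention). Degenerate
#' replicates (too few events or constant covariates) are redrawn and
#' counted.
#'
#' @inheritParams cox_fit
#' @param covariates_a,covariates_b Covariate sets of the two models.
#' @param B Bootstrap replicates (the reference protocol uses 1000).
#' @param folds CV folds per replicate.
#' @param seed Integer seed.
#' @return A tibble: `diff` (mean of A - B), `conf_low`, `conf_high`,
#'   `p_value`, `n_redrawn`, with the replicate differences in `boot_diffs`.
#' @export
bootstrap_cindex_diff <- function(data, covariates_a, covariates_b,
                                  B = 1000, folds = 5, seed = 1) {
  check_records(data)
  n <- nrow(data)
  diffs <- numeric(B)
  redrawn <- 0
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        d <- data[idx, , drop = FALSE]
        sub_seed <- sample.int(2^30, 1)
        ca <- try(cv_cindex(d, covariates_a, folds, seed = sub_seed)$cindex,
          silent = TRUE)
        cb <- try(cv_cindex(d, covariates_b, folds, seed = sub_seed)$cindex,
          silent = TRUE)
        if (!inherits(ca, "try-error") && !inherits(cb, "try-error")) {
          diffs[b] <- ca - cb
          break
        }
        redrawn <- redrawn + 1
        if (redrawn > 50 * B) stop_invalid("too many degenerate replicates.")
      }
    }
  })
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  tibble(
    diff = mean(diffs),
    conf_low = unname(quantile(diffs, 0.025)),
    conf_high = unname(quantile(diffs, 0.975)),
    p_value = p, n_redrawn = redrawn, boot_diffs = list(diffs)
  )
}

#' Chi-square test of a contingency table
#'
#' Pearson chi-square with expected counts from the margins; the Yates
#' continuity correction is applied to 2x2 tables only (and can be turned
#' off). This is the convention under which the reference cross-tabulations
#' of cluster memberships reproduce to 4 decimals.
#'
#' @param table Integer matrix of counts, >= 2 rows and columns, no zero
#'   margin.
#' @param yates_2x2 Apply the continuity correction to 2x2 tables.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, yates_2x2 = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop_invalid("table must be >= 2x2.")
  if (any(table < 0) || sum(table) == 0) stop_invalid("invalid counts.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_invalid("zero margin.")
  }
  correct <- yates_2x2 && nrow(table) == 2 && ncol(table) == 2
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value)
}

#' Rank tests of group location
#'
#' Mann-Whitney U (normal approximation with tie correction) for two
#' groups; Kruskal-Wallis for three or more.
#'
#' @param values Numeric vector.
#' @param groups Group label per value; every group non-empty.
#' @return A tibble: `method`, `statistic`, `p_value`.
#' @export
rank_tests <- function(values, groups) {
  groups <- as.character(groups)
  split_v <- split(values, groups)
  if (length(split_v) < 2 || any(lengths(split_v) == 0)) {
    stop_invalid("need >= 2 non-empty groups.")
  }
  if (length(split_v) == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(split_v[[1]], split_v[[2]], exact = FALSE)
    )
    tibble(method = "mann_whitney", statistic = unname(ht$statistic),
      p_value = ht$p.value)
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    tibble(method = "kruskal_wallis", statistic = unname(ht$statistic),
      p_value = ht$p.value)
  }
}

#' Nomogram survival-probability grouping
#'
#' Categorizes the predicted 10-year overall-survival probability into
#' `low` (<= 0.51), `intermediate` (> 0.51 and <= 0.66) and `high`
#' (> 0.66).
#'
#' @param pr_os Probabilities in `[0, 1]`.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
sarculator_grouping <- function(pr_os) {
  check_probability(pr_os, "pr_os")
  cut(pr_os, breaks = c(-Inf, 0.51, 0.66, Inf),
    labels = c("low", "intermediate", "high"))
}

#' Semantic radiophenotype rule
#'
#' `high risk` when at least 2 of the 3 semantic radiological features
#' (marked T2 heterogeneity, necrosis, peritumoral enhancement) are present,
#' `low risk` otherwise.
#'
#' @param heterogeneity,necrosis,rim Logical vectors (recycled to a common
#'   length is not allowed; must match).
#' @return Factor with levels `low_risk`, `high_risk`.
#' @export
semantic_radiophenotype <- function(heterogeneity, necrosis, rim) {
  if (length(unique(c(length(heterogeneity), length(necrosis),
    length(rim)))) != 1) {
    stop_invalid("flag vectors must have equal length.")
  }
  total <- as.integer(heterogeneity) + as.integer(necrosis) + as.integer(rim)
  factor(ifelse(total >= 2, "high_risk", "low_risk"),
    levels = c("low_risk", "high_risk"))
}

#' Combine a radiomics grouping with a transcriptomics grouping
#'
#' Builds the 4-level hybrid label `<radiomics>x<rna>` and the binarized
#' indicator that pools everything against the double-`A` (worst) group.
#' Subjects with a missing label are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param radiomics_label,rna_label Character vectors of cluster labels
#'   (`A` = most numerous group per [label_clusters_by_size()]).
#' @param worst Label of the worse-prognosis cluster in each grouping
#'   (default `"A"`).
#' @return A tibble: `radiomics`, `rna`, `hybrid`, `binary` (factor
#'   `Others` / `AxA`).
#' @export
combine_groups <- function(radiomics_label, rna_label, worst = "A") {
  if (length(radiomics_label) != length(rna_label)) {
    stop_invalid("label vectors must align.")
  }
  keep <- !is.na(radiomics_label) & !is.na(rna_label)
  out <- tibble(
    radiomics = as.character(radiomics_label[keep]),
    rna = as.character(rna_label[keep])
  )
  out$hybrid <- paste0(out$radiomics, "x", out$rna)
  out$binary <- factor(
    ifelse(out$radiomics == worst & out$rna == worst, "AxA", "Others"),
    levels = c("Others", "AxA")
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}
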