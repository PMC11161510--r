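toy_records <- function(time, event, ...) {
  tibble::tibble(time = time, event = event, ...)
}

test_that("Kaplan-Meier matches the hand product-limit and KM properties", {
  km <- km_estimate(toy_records(c(1, 2, 3), c(1, 1, 0)))
  expect_equal(km_prob(km, 2), (2 / 3) * (1 / 2))
  expect_equal(km_prob(km, 0.5), 1)

  # all censored: flat survival
  km2 <- km_estimate(toy_records(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(km_prob(km2, c(1, 5, 20)) == 1))

  # non-increasing right-continuous step function in [0, 1]
  set.seed(1)
  km3 <- km_estimate(toy_records(rexp(50, 0.1), rbinom(50, 1, 0.7)))
  s <- km_prob(km3, sort(runif(100, 0, 30)))
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
  # Greenwood standard errors are non-negative
  expect_true(all(km3$steps$std_err >= 0))
})

test_that("log-rank behaves at the null and under planted hazard ratios", {
  d <- toy_records(rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  same <- logrank_test(d, rep(c("x", "y"), each = 4))
  expect_lt(same$statistic, 1e-10)
  expect_equal(same$p_value, 1)

  # planted HR = 3: essentially always detected at n = 300/arm
  hits <- vapply(1:30, function(s) {
    sv <- simulate_survival(rep(c("a", "b"), each = 300),
      baseline_rate = 0.02, log_hazards = c(a = 0, b = log(3)),
      censor_rate = 0.01, seed = s)
    logrank_test(sv, sv$group)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(logrank_test(d, rep("only", 8)),
    class = "sarcomix_invalid_argument")
})

test_that("log-rank statistic agrees with a permutation null on toy data", {
  set.seed(7)
  sv <- simulate_survival(rep(c("a", "b"), each = 30), baseline_rate = 0.05,
    log_hazards = c(a = 0, b = 0), censor_rate = 0.02, seed = 3)
  obs <- logrank_test(sv, sv$group)$statistic
  perm <- vapply(1:400, function(i) {
    logrank_test(sv, sample(sv$group))$statistic
  }, numeric(1))
  # under the null the observed statistic is an unexceptional draw
  p_perm <- mean(perm >= obs)
  p_chisq <- pchisq(obs, 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_chisq), 0.1)
})

test_that("Cox regression recovers planted effects and flags degeneracy", {
  sv <- simulate_survival(rep(c("a", "b"), each = 1000),
    baseline_rate = 0.02, log_hazards = c(a = 0, b = log(2)),
    censor_rate = 0.005, seed = 21)
  fit <- cox_fit(sv, "group")
  expect_equal(fit$coefficients$estimate, log(2), tolerance = 0.15)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$estimate))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * nrow(fit$coefficients))

  # constant covariate is a degenerate design
  expect_error(cox_fit(dplyr::mutate(sv, z = 1), "z"),
    class = "sarcomix_invalid_argument")

  # complete-case handling counts dropped rows
  sv2 <- dplyr::mutate(sv, x = rnorm(dplyr::n()))
  sv2$x[1:10] <- NA
  fit2 <- cox_fit(sv2, "x")
  expect_equal(fit2$n_dropped, 10)
  expect_equal(fit2$n, nrow(sv2) - 10)
})

test_that("null-covariate Cox rejection is calibrated near 5%", {
  rejections <- vapply(1:200, function(s) {
    sv <- simulate_survival(rep("a", 120), baseline_rate = 0.03,
      censor_rate = 0.01, seed = s)
    set.seed(s + 5000)
    sv$x <- rnorm(120)
    fit <- cox_fit(sv, "x")
    fit$coefficients$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("backward-AIC elimination drops noise and keeps signal", {
  keep_rate <- vapply(1:40, function(s) {
    sv <- simulate_survival(rep(c("a", "b"), each = 250),
      baseline_rate = 0.03, log_hazards = c(a = 0, b = log(2.5)),
      censor_rate = 0.01, seed = s)
    set.seed(s + 900)
    sv$noise <- rnorm(500)
    fit <- stepwise_backward_aic(sv, c("group", "noise"))
    c(kept_signal = "group" %in% fit$covariates,
      dropped_noise = !"noise" %in% fit$covariates)
  }, logical(2))
  # AIC removes a null covariate exactly when its LRT chi-square is < 2,
  # which happens with probability P(chisq_1 < 2) ~ 0.843 under the null
  expect_equal(mean(keep_rate["dropped_noise", ]), pchisq(2, 1),
    tolerance = 0.15)
  expect_gte(mean(keep_rate["kept_signal", ]), 0.95)

  # the trace never ends above the full-model AIC
  sv <- simulate_survival(rep(c("a", "b"), each = 100),
    baseline_rate = 0.03, log_hazards = c(a = 0, b = 1),
    censor_rate = 0.01, seed = 1)
  set.seed(2); sv$z1 <- rnorm(200); sv$z2 <- rnorm(200)
  fit <- stepwise_backward_aic(sv, c("group", "z1", "z2"))
  expect_lte(fit$aic, fit$trace$aic[1])

  # an already-minimal model is returned unchanged
  fit1 <- stepwise_backward_aic(sv, "group")
  expect_equal(fit1$covariates, "group")
})

test_that("Harrell c-index equals the pair-enumeration oracle", {
  # perfect ranking
  d <- toy_records(c(5, 3, 9, 1), c(1, 1, 1, 1))
  expect_equal(harrell_cindex(-d$time, d)$cindex, 1)

  set.seed(33)
  for (trial in 1:200) {
    n <- sample(3:6, 1)
    d <- toy_records(sample(1:8, n, replace = TRUE),
      rbinom(n, 1, 0.7))
    risk <- sample(1:4, n, replace = TRUE)
    if (sum(d$event) == 0) next
    got <- try(harrell_cindex(risk, d), silent = TRUE)
    ora <- try(oracle_cindex(risk, d$time, d$event), silent = TRUE)
    if (inherits(ora, "try-error") || !is.finite(ora)) {
      expect_s3_class(got, "try-error")
    } else {
      expect_equal(got$cindex, ora)
    }
  }
})

test_that("random risk scores give a c-index of one half", {
  set.seed(44)
  d <- toy_records(rexp(150, 0.05), rbinom(150, 1, 0.8))
  cs <- vapply(1:100, function(i) {
    harrell_cindex(sample(150), d)$cindex
  }, numeric(1))
  expect_equal(mean(cs), 0.5, tolerance = 0.03)
})

test_that("cross-validated c-index separates signal from noise", {
  signal <- vapply(1:12, function(s) {
    sv <- simulate_survival(rep(c("a", "b", "c"), each = 80),
      baseline_rate = 0.02,
      log_hazards = c(a = 0, b = 1, c = 2), censor_rate = 0.008, seed = s)
    cv_cindex(sv, "group", folds = 5, seed = s)$cindex
  }, numeric(1))
  expect_gte(mean(signal > 0.65), 0.9)

  null_c <- vapply(1:12, function(s) {
    sv <- simulate_survival(rep("a", 150), baseline_rate = 0.02,
      censor_rate = 0.008, seed = 100 + s)
    set.seed(s)
    sv$x <- rnorm(150)
    cv_cindex(sv, "x", folds = 5, seed = s)$cindex
  }, numeric(1))
  expect_gt(mean(null_c), 0.45)
  expect_lt(mean(null_c), 0.55)

  # determinism
  sv <- simulate_survival(rep(c("a", "b"), each = 60), baseline_rate = 0.02,
    log_hazards = c(a = 0, b = 1), censor_rate = 0.01, seed = 5)
  expect_identical(cv_cindex(sv, "group", seed = 9),
    cv_cindex(sv, "group", seed = 9))
})

test_that("bootstrap c-index comparison is honest at the null and powered", {
  sv <- simulate_survival(rep(c("a", "b"), each = 100), baseline_rate = 0.03,
    log_hazards = c(a = 0, b = 1.2), censor_rate = 0.01, seed = 2)
  same <- bootstrap_cindex_diff(sv, "group", "group", B = 20, seed = 3)
  expect_gte(same$p_value, 0.9)
  expect_equal(same$diff, mean(same$boot_diffs[[1]]), tolerance = 1e-12)

  # informative vs noise model
  wins <- vapply(1:8, function(s) {
    sv <- simulate_survival(rep(c("a", "b"), each = 200),
      baseline_rate = 0.03, log_hazards = c(a = 0, b = 1.5),
      censor_rate = 0.01, seed = s)
    set.seed(s + 70)
    sv$noise <- rnorm(400)
    bootstrap_cindex_diff(sv, "group", "noise", B = 40,
      seed = s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("chi-square tests reproduce reference cross-tabulation p-values", {
  # 3x2 grouping-vs-grouping table: plain Pearson
  t1 <- matrix(c(14, 24, 18, 20, 9, 25), nrow = 3, byrow = TRUE)
  expect_equal(chi_square_test(t1)$p_value, 0.1867, tolerance = 5e-5)

  # 2x2 tables with Yates continuity correction
  t2 <- matrix(c(24, 39, 17, 30), nrow = 2, byrow = TRUE)
  expect_equal(chi_square_test(t2)$p_value, 0.9942, tolerance = 5e-5)

  t3 <- matrix(c(25, 40, 16, 29), nrow = 2, byrow = TRUE)
  expect_equal(chi_square_test(t3)$p_value, 0.9129, tolerance = 5e-5)

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
    class = "sarcomix_invalid_argument")
})

test_that("rank tests match the exhaustive U-statistic and detect shifts", {
  set.seed(55)
  for (trial in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    got <- rank_tests(c(x, y), rep(c("a", "b"), c(n1, n2)))
    # exhaustive pairwise-comparison count (ties count 1/2)
    u <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(unname(got$statistic), u)
  }

  # identical groups: p at the null center
  same <- rank_tests(rep(1:6, 2), rep(c("a", "b"), each = 6))
  expect_gt(same$p_value, 0.9)

  # planted 2-sd shift, n = 50/arm
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    rank_tests(c(rnorm(50), rnorm(50, 2)),
      rep(c("a", "b"), each = 50))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # three groups route to Kruskal-Wallis
  kw <- rank_tests(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_equal(kw$method, "kruskal_wallis")
})

test_that("nomogram grouping respects its boundaries", {
  expect_equal(as.character(sarculator_grouping(c(0.51, 0.66, 0.67, 0.2, 0.9))),
    c("low", "intermediate", "high", "low", "high"))
  expect_error(sarculator_grouping(1.2), class = "sarcomix_invalid_argument")
})

test_that("the semantic radiophenotype follows the 2-of-3 rule", {
  expect_equal(
    as.character(semantic_radiophenotype(
      c(TRUE, TRUE, FALSE, FALSE, TRUE),
      c(TRUE, FALSE, FALSE, FALSE, TRUE),
      c(FALSE, FALSE, FALSE, TRUE, TRUE))),
    c("high_risk", "low_risk", "low_risk", "low_risk", "high_risk")
  )
})

test_that("group combination builds the hybrid and pooled binary variable", {
  out <- combine_groups(c("A", "B", "B", "A"), c("A", "A", "B", NA))
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(as.character(out$binary), c("AxA", "Others", "Others"))
  expect_equal(out$hybrid, c("AxA", "BxA", "BxB"))
})
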