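# small configurations keep these tests fast; the network code is identical
# at every scale
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_size = 32, channels = c(4, 8, 16), latent_dim = 16,
      epochs = 12, batch_size = 16, learning_rate = 3e-3, cv_repeats = 1,
      final_refit = FALSE, seed = 1),
    list(...)
  )
  do.call(cae_config, args)
}

test_that("augmentation is deterministic, shape-preserving, and clipped", {
  img <- matrix(runif(32 * 32), 32, 32)
  a1 <- augment_image(img, seed = 5)
  a2 <- augment_image(img, seed = 5)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))

  # flips are exact index reversals: applying the same flip twice = identity
  f1 <- augment_image(img, params = list(flip_h = TRUE))
  f2 <- augment_image(f1, params = list(flip_h = TRUE))
  expect_equal(f2, img, ignore_attr = TRUE)
  fv <- augment_image(augment_image(img, params = list(flip_v = TRUE)),
    params = list(flip_v = TRUE))
  expect_equal(fv, img, ignore_attr = TRUE)

  # a genuinely transformed image differs
  rot <- augment_image(img, params = list(angle = 15))
  expect_gt(mean(abs(rot - img)), 0)
})

test_that("training is deterministic, loss decreases, and the CAE/HSCAE paths coincide at lambda 0", {
  slices <- make_slices(30, seed = 3)
  m1 <- cae_train(slices, config = small_cfg())
  m2 <- cae_train(slices, config = small_cfg())
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net$params$We1, m2$net$params$We1)

  # smoothed (5-epoch) training loss is non-increasing
  sm <- stats::filter(m1$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-6))

  # lambda = 0 with a survival table supplied changes nothing: the
  # prognostic branch is inert, so CAE and HSCAE share one code path
  surv <- simulate_survival(rep("a", 30), 0.02, censor_rate = 0.01, seed = 2)
  m3 <- cae_train(slices, survival = surv, config = small_cfg())
  expect_identical(m1$history$loss, m3$history$loss)
})

test_that("held-out reconstruction error becomes small with training", {
  # quick 32x32 convergence check; the full-scale sub-1% reconstruction
  # contract is exercised in the acceptance suite at 64x64
  slices <- make_slices(80, seed = 11)
  cfg <- cae_config(input_size = 32, channels = c(8, 16, 32),
    latent_dim = 64, epochs = 40, batch_size = 16, learning_rate = 3e-3,
    cv_repeats = 1, final_refit = FALSE, seed = 4)
  m <- cae_train(slices, config = cfg)
  expect_lt(m$holdout$mse[1], 0.02)
})

test_that("reconstruction reports obey their arithmetic contracts", {
  slices <- make_slices(12, seed = 7)
  m <- cae_train(slices, config = small_cfg(epochs = 3))
  rep <- reconstruction_mse(m, slices)
  expect_equal(rep$mse, mean(rep$per_subject$mse), tolerance = 1e-12)
  expect_true(all(rep$per_subject$mse >= 0))

  # identical inputs produce identical per-image errors and latents
  twin <- c(slices[1], slices[1])
  rep2 <- reconstruction_mse(m, twin)
  expect_equal(rep2$per_subject$mse[1], rep2$per_subject$mse[2])
  L <- extract_latent(m, twin)
  expect_equal(L[1, ], L[2, ])
})

test_that("latent extraction has the configured width and requires training", {
  cfg <- cae_config()
  expect_equal(cfg$latent_dim, 1024)
  slices <- make_slices(10, seed = 2)
  m <- cae_train(slices, config = small_cfg(epochs = 2))
  L <- extract_latent(m, slices)
  expect_identical(dim(L), c(10L, 16L))
  expect_true(all(is.finite(L)))

  m$trained <- FALSE
  expect_error(extract_latent(m, slices), class = "sarcomix_invalid_state")
})

test_that("the prognostic loss steers latents toward survival signal", {
  # two phenotype groups with very different images and hazards
  specs <- dplyr::bind_rows(
    phenotype_spec("big", prop = 0.5, size_mm_mean = 130, size_mm_sd = 10,
      texture_contrast = 0.3, necrosis_prob = 1, heterogeneity_prob = 1,
      log_hazard = 1.5),
    phenotype_spec("small", prop = 0.5, size_mm_mean = 50, size_mm_sd = 10,
      texture_contrast = 0, necrosis_prob = 0, heterogeneity_prob = 0,
      log_hazard = 0)
  )
  set.seed(5)
  grp <- sample(c("big", "small"), 60, replace = TRUE)
  slices <- lapply(seq_along(grp), function(i) {
    st <- simulate_tumor_study(specs[specs$group_id == grp[i], ],
      c(32, 32, 8), c(2, 2, 6), seed = 500 + i)
    sl <- extract_center_slice(st$channels$ce, st$mask)
    sl / max(max(sl), 1e-9)
  })
  surv <- simulate_survival(grp, 0.02,
    c(big = 1.5, small = 0), censor_rate = 0.005, seed = 6)

  wins <- vapply(1:10, function(s) {
    m <- cae_train(slices, survival = surv,
      config = small_cfg(lambda_prognostic = 1, epochs = 10, seed = s))
    risk <- drop(extract_latent(m, slices) %*% m$net$params$Wrisk)
    harrell_cindex(risk, surv)$cindex > 0.5
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("class activation maps are rectified, input-sized, and tumor-focused", {
  # two-group cohort with a real survival signal so the risk head learns
  specs <- dplyr::bind_rows(
    phenotype_spec("big", prop = 0.5, size_mm_mean = 120, size_mm_sd = 10,
      texture_contrast = 0.3, necrosis_prob = 1, heterogeneity_prob = 1,
      log_hazard = 1.5),
    phenotype_spec("small", prop = 0.5, size_mm_mean = 45, size_mm_sd = 8,
      texture_contrast = 0, necrosis_prob = 0, heterogeneity_prob = 0,
      log_hazard = 0)
  )
  set.seed(19)
  grp <- rep(c("big", "small"), each = 25)[sample(50)]
  slices <- lapply(seq_along(grp), function(i) {
    st <- simulate_tumor_study(specs[specs$group_id == grp[i], ],
      c(32, 32, 8), c(2, 2, 6), seed = 300 + i)
    sl <- extract_center_slice(st$channels$ce, st$mask)
    sl / max(max(sl), 1e-9)
  })
  surv <- simulate_survival(grp, 0.02, c(big = 1.5, small = 0),
    censor_rate = 0.005, seed = 3)
  # two blocks keep the activation grid at 8x8 so the map can localize
  m <- cae_train(slices, survival = surv,
    config = small_cfg(lambda_prognostic = 1, epochs = 12,
      channels = c(8, 16)))

  cam <- class_activation_map(m, slices[[1]])
  expect_identical(dim(cam), c(32L, 32L))
  expect_true(all(cam >= 0))

  # the prognostic phenotype lives inside the tumor, so most of the map
  # mass should fall on tumor rather than background pixels
  fracs <- vapply(which(grp == "big")[1:20], function(i) {
    cam_i <- class_activation_map(m, slices[[i]])
    msk <- slices[[i]] > 0
    if (sum(cam_i) == 0) return(NA_real_)
    sum(cam_i[msk]) / sum(cam_i)
  }, numeric(1))
  expect_gte(mean(fracs, na.rm = TRUE), 0.6)

  # lambda = 0 models cannot produce activation maps
  m0 <- cae_train(slices, config = small_cfg(epochs = 2))
  expect_error(class_activation_map(m0, slices[[1]]),
    class = "sarcomix_unsupported_operation")
})

test_that("HSCAE latents cluster at least as prognostically as CAE latents", {
  specs <- dplyr::bind_rows(
    phenotype_spec("hi", prop = 0.5, size_mm_mean = 120, size_mm_sd = 15,
      texture_contrast = 0.3, necrosis_prob = 0.9, heterogeneity_prob = 0.9,
      log_hazard = 1.5),
    phenotype_spec("lo", prop = 0.5, size_mm_mean = 50, size_mm_sd = 10,
      texture_contrast = 0.03, necrosis_prob = 0.05,
      heterogeneity_prob = 0.1, log_hazard = 0)
  )
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    grp <- rep(c("hi", "lo"), each = 25)[sample(50)]
    slices <- lapply(seq_along(grp), function(i) {
      st <- simulate_tumor_study(specs[specs$group_id == grp[i], ],
        c(32, 32, 8), c(2, 2, 6), seed = s * 777 + i)
      sl <- extract_center_slice(st$channels$ce, st$mask)
      sl / max(max(sl), 1e-9)
    })
    surv <- simulate_survival(grp, 0.02, c(hi = 1.5, lo = 0),
      censor_rate = 0.005, seed = s)
    cluster_ari <- function(lambda) {
      m <- cae_train(slices, survival = if (lambda > 0) surv else NULL,
        config = small_cfg(lambda_prognostic = lambda, epochs = 8, seed = s))
      L <- extract_latent(m, slices)
      cm <- consensus_cluster(L, k_range = 2, B = 60, seed = s, k_fixed = 2)
      ari(cm$labels, grp)
    }
    cluster_ari(1) - cluster_ari(0)
  }, numeric(1))
  # on average the prognostic loss does not hurt group recovery
  expect_gte(mean(aris), 0)
})
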