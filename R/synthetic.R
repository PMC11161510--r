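#' Planted imaging/expression phenotype specification
#'
#' Describes one cohort subgroup: its tumor size distribution, texture
#' contrast, the probabilities of the three prognostic radiological features
#' (intra-tumoral heterogeneity, a necrotic core, a peritumoral enhancing
#' rim), its multiplicative effect on the metastatic-relapse hazard, the
#' transcriptomic group it maps to, and the center of its nomogram-predicted
#' 10-year overall-survival probability (Pr-OS).
#'
#' @param group_id Character label of the imaging group.
#' @param prop Cohort proportion of the group (proportions must sum to 1
#'   across the specs passed to [simulate_cohort()]).
#' @param size_mm_mean,size_mm_sd Tumor diameter distribution in mm
#'   (`size_mm_mean > 0`, `size_mm_sd >= 0`).
#' @param texture_contrast Non-negative scale of the high-frequency in-tumor
#'   intensity variation; 0 gives a flat tumor (up to the bias field).
#' @param necrosis_prob,peritumoral_rim_prob,heterogeneity_prob Probabilities
#'   of the planted radiological features.
#' @param log_hazard Additive log-hazard of the group on event times.
#' @param expr_group_id Character label of the transcriptomic group this
#'   imaging group maps to by default (overridable via `mixing`).
#' @param pr_os_mean Mean Pr-OS probability for the group.
#' @return A one-row tibble of class `phenotype_spec`.
#' @export
phenotype_spec <- function(group_id, prop = 1, size_mm_mean = 80,
                           size_mm_sd = 20, texture_contrast = 0.1,
                           necrosis_prob = 0.2, peritumoral_rim_prob = 0.2,
                           heterogeneity_prob = 0.3, log_hazard = 0,
                           expr_group_id = "A", pr_os_mean = 0.6) {
  check_positive(size_mm_mean, "size_mm_mean")
  check_positive(size_mm_sd, "size_mm_sd", strict = FALSE)
  check_positive(texture_contrast, "texture_contrast", strict = FALSE)
  check_probability(necrosis_prob, "necrosis_prob")
  check_probability(peritumoral_rim_prob, "peritumoral_rim_prob")
  check_probability(heterogeneity_prob, "heterogeneity_prob")
  check_probability(pr_os_mean, "pr_os_mean")
  out <- tibble(
    group_id = as.character(group_id), prop = prop,
    size_mm_mean = size_mm_mean, size_mm_sd = size_mm_sd,
    texture_contrast = texture_contrast, necrosis_prob = necrosis_prob,
    peritumoral_rim_prob = peritumoral_rim_prob,
    heterogeneity_prob = heterogeneity_prob, log_hazard = log_hazard,
    expr_group_id = as.character(expr_group_id), pr_os_mean = pr_os_mean
  )
  class(out) <- c("phenotype_spec", class(out))
  out
}

# default three-group cohort structure: a large/necrotic high-risk group, an
# intermediate group, and a small/homogeneous low-risk group, mirroring
# high/intermediate/low-risk sarcoma presentations.
#' Default three-group phenotype table
#' @return A `phenotype_spec` tibble with three rows.
#' @export
default_phenotypes <- function() {
  dplyr::bind_rows(
    phenotype_spec("G1", prop = 0.4, size_mm_mean = 120, size_mm_sd = 30,
      texture_contrast = 0.25, necrosis_prob = 0.7, peritumoral_rim_prob = 0.6,
      heterogeneity_prob = 0.8, log_hazard = 1.0, expr_group_id = "E1",
      pr_os_mean = 0.45),
    phenotype_spec("G2", prop = 0.35, size_mm_mean = 85, size_mm_sd = 25,
      texture_contrast = 0.12, necrosis_prob = 0.3, peritumoral_rim_prob = 0.3,
      heterogeneity_prob = 0.4, log_hazard = 0.4, expr_group_id = "E1",
      pr_os_mean = 0.6),
    phenotype_spec("G3", prop = 0.25, size_mm_mean = 55, size_mm_sd = 15,
      texture_contrast = 0.04, necrosis_prob = 0.1, peritumoral_rim_prob = 0.1,
      heterogeneity_prob = 0.15, log_hazard = 0, expr_group_id = "E2",
      pr_os_mean = 0.75)
  )
}

# separable Gaussian smoothing of a 3-D array (reflected edges)
smooth_gaussian <- function(x, sigma) {
  if (all(sigma <= 0)) return(x)
  d <- dim(x)
  for (a in 1:3) {
    s <- sigma[min(a, length(sigma))]
    if (s <= 0 || d[a] == 1) next
    r <- max(1, ceiling(2.5 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    perm <- c(a, setdiff(1:3, a))
    xp <- aperm(x, perm)
    dm <- dim(xp)
    m <- matrix(xp, nrow = dm[1])
    n <- dm[1]
    acc <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1
      idx <- pmin(pmax(seq_len(n) + off, 1), n)
      acc <- acc + k[j] * m[idx, , drop = FALSE]
    }
    x <- aperm(array(acc, dm), order(perm))
  }
  x
}

#' Simulate one multi-channel tumor study
#'
#' Generates a 3-channel (T1-like, T2-like, contrast-enhanced-like) volume
#' with an ellipsoidal tumor whose diameter is drawn from the phenotype
#' specification. Channel intensities are a base tissue level modulated by a
#' smooth multiplicative bias field plus Gaussian-filtered noise scaled by
#' `texture_contrast`; with the phenotype's probabilities the tumor gains a
#' central low-enhancement "necrotic" core, an enhancing rim extending beyond
#' the mask, and coarse intra-tumoral heterogeneity patches. Output is a pure
#' function of `(spec, grid, seed)`.
#'
#' @param spec A one-row [phenotype_spec()].
#' @param grid_dim Integer length-3 array dimensions (> 0).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @return A list: `channels` (named list of three [image_volume()]s `t1`,
#'   `t2`, `ce`), `mask` (binary array), and `features` (logical flags
#'   `necrosis`, `rim`, `heterogeneity` actually planted) plus
#'   `diameter_mm`.
#' @export
simulate_tumor_study <- function(spec, grid_dim = c(64, 64, 16),
                                 spacing = c(1, 1, 4), seed = 1) {
  if (any(grid_dim <= 0)) stop_invalid("grid dimensions must be positive.")
  check_positive(spacing, "spacing")
  if (spec$size_mm_sd < 0) stop_invalid("size sd must be >= 0.")
  with_seed(seed, {
    d <- as.integer(grid_dim)
    diam <- max(spec$size_mm_mean / 4, rnorm(1, spec$size_mm_mean, spec$size_mm_sd))
    # ellipsoid radii in voxels, capped so the mask stays strictly inside
    radii <- pmin((diam / 2) / spacing, (d - 3) / 2)
    radii <- pmax(radii, 1)
    ctr <- (d + 1) / 2
    ax <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / radii[a])^2)
    r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    mask <- array(as.integer(r2 <= 1), d)
    necro <- runif(1) < spec$necrosis_prob
    rim <- runif(1) < spec$peritumoral_rim_prob
    hetero <- runif(1) < spec$heterogeneity_prob
    core <- r2 <= 0.15
    shell <- r2 > 1 & r2 <= 1.45
    base <- c(t1 = 0.35, t2 = 0.55, ce = 0.6)
    channels <- lapply(names(base), function(ch) {
      b <- base[[ch]]
      vol <- array(0.08, d) # dim background tissue
      vol[mask == 1] <- b
      if (hetero) {
        patches <- smooth_gaussian(array(rnorm(prod(d)), d), sigma = c(4, 4, 1.5))
        patches <- patches / max(stats::sd(patches), 1e-12)
        vol[mask == 1] <- vol[mask == 1] * (1 + 0.35 * patches[mask == 1])
      }
      if (necro) {
        # fluid-like core: bright on T2, dark on CE
        vol[core] <- if (ch == "t2") b * 1.5 else if (ch == "ce") b * 0.25 else b * 0.7
      }
      if (rim && ch == "ce") vol[shell] <- pmax(vol[shell], b * 0.85)
      if (spec$texture_contrast > 0) {
        tex <- smooth_gaussian(array(rnorm(prod(d)), d), sigma = c(1, 1, 0.5))
        vol <- vol * (1 + spec$texture_contrast * tex)
      }
      # smooth multiplicative bias field
      cf <- rnorm(3, 0, 0.1)
      g <- lapply(1:3, function(a) seq(-1, 1, length.out = d[a]))
      field <- outer(outer(cf[1] * g[[1]], cf[2] * g[[2]], `+`), cf[3] * g[[3]], `+`)
      vol <- vol * exp(field)
      image_volume(pmax(vol, 0), spacing = spacing)
    })
    names(channels) <- names(base)
    list(
      channels = channels, mask = mask,
      features = c(necrosis = necro, rim = rim, heterogeneity = hetero),
      diameter_mm = diam
    )
  })
}

#' Simulate exponential survival with independent censoring
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(log_hazard[group])`; censoring times are independent
#' exponential with rate `censor_rate`. The observed time is the minimum and
#' the event indicator marks whether the event preceded censoring.
#'
#' @param groups Character/factor vector of group labels per subject.
#' @param baseline_rate Baseline event rate per month (> 0).
#' @param log_hazards Named numeric vector mapping each group to its
#'   log-hazard.
#' @param censor_rate Censoring rate per month (> 0).
#' @param seed Integer seed.
#' @return A tibble: `id`, `group`, `time` (months), `event` (0/1).
#' @export
simulate_survival <- function(groups, baseline_rate = 0.01,
                              log_hazards = c(), censor_rate = 0.005,
                              seed = 1) {
  check_positive(baseline_rate, "baseline_rate")
  check_positive(censor_rate, "censor_rate")
  groups <- as.character(groups)
  miss <- setdiff(unique(groups), names(log_hazards))
  if (length(log_hazards) > 0 && length(miss) > 0) {
    stop_invalid(sprintf("unknown group label(s): %s", paste(miss, collapse = ", ")))
  }
  lh <- if (length(log_hazards) == 0) setNames(rep(0, length(unique(groups))), unique(groups)) else log_hazards
  with_seed(seed, {
    n <- length(groups)
    rate <- baseline_rate * exp(unname(lh[groups]))
    t_event <- rexp(n, rate)
    t_cens <- rexp(n, censor_rate)
    tibble(
      id = sprintf("S%03d", seq_len(n)), group = groups,
      time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens)
    )
  })
}

#' Simulate negative-binomial expression counts with planted signal
#'
#' Gene-wise baseline abundances are log-normal, dispersions are drawn
#' log-normally around `dispersion`, and the first `n_de` genes are shifted
#' by `log2_fc` between the first expression group and the others (half up,
#' half down). Batches act multiplicatively on location (log-normal per gene
#' per batch) and on dispersion. Library sizes are uniform in
#' `libsize_range`.
#'
#' @param n_genes,n_de Total and differentially expressed gene counts
#'   (`n_de <= n_genes`).
#' @param log2_fc Planted log2 fold change (the conventional planted effect
#'   is 1, i.e. fold change 2).
#' @param groups Character vector of expression-group labels per sample.
#' @param batches Optional character vector of batch labels (default: one
#'   batch).
#' @param libsize_range Length-2 range of library sizes.
#' @param dispersion Median negative-binomial dispersion (> 0).
#' @param batch_sd Log-normal sd of the per-gene batch location effect.
#' @param seed Integer seed.
#' @return A list: `counts` (genes x samples integer matrix), `truth`
#'   (tibble with `gene`, `is_de`, `direction`), `batches`, `groups`.
#' @export
simulate_expression <- function(n_genes = 2000, n_de = 100, log2_fc = 1,
                                groups, batches = NULL,
                                libsize_range = c(5e5, 1.5e6),
                                dispersion = 0.1, batch_sd = 0.3, seed = 1) {
  if (n_de > n_genes) stop_invalid("`n_de` must not exceed `n_genes`.")
  check_positive(dispersion, "dispersion")
  check_positive(libsize_range, "libsize_range")
  if (n_genes < 1) stop_invalid("`n_genes` must be positive.")
  groups <- as.character(groups)
  n <- length(groups)
  if (is.null(batches)) batches <- rep("batch1", n)
  batches <- as.character(batches)
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 4, sdlog = 1.5)
    disp <- rlnorm(n_genes, meanlog = log(dispersion), sdlog = 0.5)
    lg <- sort(unique(groups))
    de_dir <- rep(0, n_genes)
    if (n_de > 0) {
      n_up <- ceiling(n_de / 2)
      de_dir[seq_len(n_de)] <- c(rep(1, n_up), rep(-1, n_de - n_up))
    }
    # group effect: first group shifted relative to the rest
    in_g1 <- groups == lg[1]
    lfc <- outer(de_dir * log2_fc, as.numeric(in_g1))
    ub <- sort(unique(batches))
    bfac <- matrix(1, n_genes, n)
    if (length(ub) > 1) {
      for (b in ub[-1]) {
        eff <- rlnorm(n_genes, 0, batch_sd)
        bfac[, batches == b] <- eff
      }
    }
    libs <- runif(n, libsize_range[1], libsize_range[2])
    rel <- base / sum(base)
    mu <- (rel %o% libs) * 2^lfc * bfac
    counts <- matrix(
      rnbinom(n_genes * n, mu = as.vector(mu), size = rep(1 / disp, n)),
      n_genes, n
    )
    rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
    colnames(counts) <- sprintf("S%03d", seq_len(n))
    list(
      counts = counts,
      truth = tibble(
        gene = rownames(counts), is_de = de_dir != 0,
        direction = c("down", "ns", "up")[de_dir + 2]
      ),
      batches = batches, groups = groups
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws an imaging group per subject from the spec proportions, a
#' transcriptomic group via the `mixing` matrix (rows = imaging groups,
#' columns = expression groups; rows sum to 1), images and masks per subject,
#' clinical covariates (age, size, grade, histotype category, Pr-OS,
#' chemo/radio/margins, the three semantic radiological flags), survival
#' times, and expression counts. The mixing matrix makes the degree of
#' dependence between the imaging and transcriptomic groupings an explicit
#' parameter.
#'
#' @param n Number of subjects (>= 0).
#' @param specs A [phenotype_spec()] tibble; `prop` must sum to 1.
#' @param mixing Optional numeric matrix, rows named by imaging group and
#'   columns by expression group; defaults to the deterministic map given by
#'   `expr_group_id`.
#' @param grid_dim,spacing Image grid.
#' @param baseline_rate,censor_rate Survival rates per month.
#' @param expr_log_hazards Optional named log-hazards of the expression
#'   groups, added to the imaging-group log-hazard.
#' @param n_genes,n_de,log2_fc,dispersion Expression parameters.
#' @param n_batches Number of expression batches.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `synthetic_cohort` list: `studies`, `clinical`, `survival`,
#'   `counts`, `truth`.
#' @export
simulate_cohort <- function(n, specs = default_phenotypes(), mixing = NULL,
                            grid_dim = c(64, 64, 16), spacing = c(1, 1, 4),
                            baseline_rate = 0.015, censor_rate = 0.008,
                            expr_log_hazards = NULL,
                            n_genes = 1000, n_de = 80, log2_fc = 1,
                            dispersion = 0.1, n_batches = 2, seed = 1) {
  if (n < 0) stop_invalid("`n` must be >= 0.")
  if (abs(sum(specs$prop) - 1) > 1e-9) {
    stop_invalid("phenotype proportions must sum to 1.")
  }
  gids <- specs$group_id
  egids <- sort(unique(specs$expr_group_id))
  if (is.null(mixing)) {
    mixing <- matrix(0, length(gids), length(egids),
      dimnames = list(gids, egids)
    )
    for (i in seq_along(gids)) mixing[i, specs$expr_group_id[i]] <- 1
  }
  if (any(abs(rowSums(mixing) - 1) > 1e-9)) {
    stop_invalid("mixing rows must sum to 1.")
  }
  empty <- function() {
    list(
      studies = list(),
      clinical = tibble(
        id = character(), imaging_group = character(),
        expr_group = character(), age = numeric(), size_mm = numeric(),
        grade = character(), histotype = character(), pr_os = numeric(),
        chemo = integer(), radio = integer(), margins = character(),
        flag_heterogeneity = logical(), flag_necrosis = logical(),
        flag_rim = logical()
      ),
      survival = tibble(
        id = character(), group = character(),
        time = numeric(), event = integer()
      ),
      counts = matrix(integer(), 0, 0), truth = tibble(),
      de_truth = tibble()
    )
  }
  if (n == 0) {
    out <- empty()
    class(out) <- "synthetic_cohort"
    return(out)
  }
  histotypes <- c(
    "MRC_LPS", "DD_LPS", "leiomyosarcoma", "myxofibrosarcoma",
    "synovial", "UPS", "other"
  )
  with_seed(derive_seed(seed, "cohort"), {
    g_idx <- sample(seq_along(gids), n, replace = TRUE, prob = specs$prop)
    img_grp <- gids[g_idx]
    expr_grp <- vapply(g_idx, function(i) {
      sample(colnames(mixing), 1, prob = mixing[gids[i], ])
    }, character(1))
    study_seeds <- sample.int(2^30, n)
    pr_os <- stats::rbeta(n, specs$pr_os_mean[g_idx] * 25,
      (1 - specs$pr_os_mean[g_idx]) * 25)
    age <- round(rnorm(n, 62, 13))
    grade <- vapply(g_idx, function(i) {
      p3 <- min(0.25 + 0.4 * specs$log_hazard[i], 0.9)
      sample(c("I", "II", "III"), 1,
        prob = c((1 - p3) * 0.4, (1 - p3) * 0.6, p3))
    }, character(1))
    histo <- sample(histotypes, n, replace = TRUE,
      prob = c(0.09, 0.11, 0.1, 0.06, 0.07, 0.32, 0.25))
    chemo <- rbinom(n, 1, 0.35)
    radio <- rbinom(n, 1, 0.7)
    margins <- sample(c("R0", "R1_R2"), n, replace = TRUE, prob = c(0.8, 0.2))
    batches <- sample(sprintf("batch%d", seq_len(max(1, n_batches))), n,
      replace = TRUE)
  })
  studies <- lapply(seq_len(n), function(i) {
    simulate_tumor_study(specs[g_idx[i], ], grid_dim, spacing,
      seed = study_seeds[i])
  })
  flags <- t(vapply(studies, function(s) s$features, logical(3)))
  surv <- simulate_survival(
    img_grp,
    baseline_rate = baseline_rate,
    log_hazards = setNames(specs$log_hazard, gids),
    censor_rate = censor_rate, seed = derive_seed(seed, "survival")
  )
  if (!is.null(expr_log_hazards)) {
    # add the expression-group hazard on top: regenerate with combined rates
    combo <- setNames(
      specs$log_hazard[g_idx] + unname(expr_log_hazards[expr_grp]),
      sprintf("s%d", seq_len(n))
    )
    surv <- simulate_survival(sprintf("s%d", seq_len(n)),
      baseline_rate = baseline_rate, log_hazards = combo,
      censor_rate = censor_rate, seed = derive_seed(seed, "survival")
    )
    surv$group <- img_grp
  }
  expr <- simulate_expression(
    n_genes = n_genes, n_de = n_de, log2_fc = log2_fc, groups = expr_grp,
    batches = batches, dispersion = dispersion,
    seed = derive_seed(seed, "expression")
  )
  ids <- sprintf("S%03d", seq_len(n))
  surv$id <- ids
  clinical <- tibble(
    id = ids, imaging_group = img_grp, expr_group = expr_grp,
    age = age, size_mm = vapply(studies, `[[`, numeric(1), "diameter_mm"),
    grade = grade, histotype = histo, pr_os = pr_os,
    chemo = chemo, radio = radio, margins = margins,
    flag_heterogeneity = flags[, "heterogeneity"],
    flag_necrosis = flags[, "necrosis"], flag_rim = flags[, "rim"],
    batch = batches
  )
  out <- list(
    studies = setNames(studies, ids), clinical = clinical, survival = surv,
    counts = expr$counts,
    truth = tibble(id = ids, imaging_group = img_grp, expr_group = expr_grp),
    de_truth = expr$truth
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d genes x %d samples\n",
    nrow(x$clinical), nrow(x$counts), ncol(x$counts)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes NIfTI image/mask pairs (requires the RNifti package), the clinical
#' and survival tables, counts, and planted truth as plain-text files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (requireNamespace("RNifti", quietly = TRUE)) {
    for (id in names(cohort$studies)) {
      st <- cohort$studies[[id]]
      for (ch in names(st$channels)) {
        p <- file.path(dir, sprintf("%s_%s.nii.gz", id, ch))
        RNifti::writeNifti(
          RNifti::asNifti(unclass(st$channels[[ch]]),
            pixdim = spacing(st$channels[[ch]])), p)
        paths <- c(paths, p)
      }
      p <- file.path(dir, sprintf("%s_mask.nii.gz", id))
      RNifti::writeNifti(RNifti::asNifti(st$mask), p)
      paths <- c(paths, p)
    }
  } else {
    warn("RNifti not installed; skipping NIfTI export.")
  }
  cl <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, cl, row.names = FALSE)
  sv <- file.path(dir, "survival.csv")
  utils::write.csv(cohort$survival, sv, row.names = FALSE)
  ct <- file.path(dir, "counts.tsv")
  utils::write.table(cohort$counts, ct, sep = "\t", quote = FALSE)
  tr <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$truth, tr, row.names = FALSE)
  invisible(c(paths, cl, sv, ct, tr))
}
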