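#' End-to-end analysis pipeline
#'
#' Orchestrates the full multi-omic analysis on a cohort: harmonization and
#' handcrafted-radiomics extraction, deep-radiomics training and latent
#' extraction, consensus clustering of each feature space, association
#' testing between groupings, survival modeling (Kaplan-Meier, Cox,
#' cross-validated concordance of single and combined groupings), and
#' differential expression with enrichment between the combined worst-
#' prognosis group and the rest. Every stage is seeded from a single master
#' seed and logged in a run manifest.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()], or a
#'   compatible list (`studies`, `clinical`, `survival`, `counts`).
#' @param config Named list of per-stage settings; see
#'   [pipeline_config()] for defaults.
#' @return A `pipeline_result` list: per-stage outputs plus a `manifest`
#'   tibble (stage, seconds, output hash, warnings).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  seed <- cfg$seed
  manifest <- tibble(stage = character(), seconds = numeric(),
    hash = character(), n_warnings = integer())
  results <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    warns <- 0
    out <- withCallingHandlers(fun(), warning = function(w) {
      warns <<- warns + 1
      invokeRestart("muffleWarning")
    })
    manifest <<- dplyr::bind_rows(manifest, tibble(
      stage = name, seconds = proc.time()[["elapsed"]] - t0,
      hash = rlang::hash(out), n_warnings = warns
    ))
    results[[name]] <<- out
    out
  }

  hrf <- run_stage("handcrafted_radiomics", function() {
    extract_radiomics(cohort, n_levels = cfg$n_levels)
  })
  hrf_model <- run_stage("hrf_clustering", function() {
    consensus_cluster(hrf, k_range = cfg$k_range, B = cfg$B,
      seed = derive_seed(seed, "cluster"))
  })
  slices <- lapply(cohort$studies, function(st) {
    extract_center_slice(st$channels$ce, st$mask)
  })
  surv <- cohort$survival
  cae_cfg <- function(lambda) {
    do.call(cae_config, utils::modifyList(cfg$cae,
      list(lambda_prognostic = lambda, seed = derive_seed(seed, "cae"))))
  }
  cae <- run_stage("cae_training", function() {
    cae_train(slices, config = cae_cfg(0))
  })
  hscae <- run_stage("hscae_training", function() {
    cae_train(slices, survival = surv, config = cae_cfg(cfg$lambda_prognostic))
  })
  drf_models <- run_stage("drf_clustering", function() {
    lapply(list(cae = cae, hscae = hscae), function(m) {
      L <- extract_latent(m, slices)
      rownames(L) <- names(cohort$studies)
      consensus_cluster(L, k_range = cfg$k_range, B = cfg$B,
        seed = derive_seed(seed, "cluster"))
    })
  })
  rna_model <- run_stage("rna_clustering", function() {
    v <- voom_normalize(cohort$counts)
    e <- combat_correct(v$logcpm, cohort$clinical$batch)
    consensus_cluster(t(e), k_range = cfg$k_range, B = cfg$B,
      seed = derive_seed(seed, "cluster"))
  })
  groupings <- tibble(
    id = cohort$clinical$id,
    hrf = unname(hrf_model$labels),
    cae = unname(drf_models$cae$labels),
    hscae = unname(drf_models$hscae$labels),
    rna = unname(rna_model$labels)
  )
  run_stage("associations", function() {
    pairs <- utils::combn(c("hrf", "cae", "hscae", "rna"), 2,
      simplify = FALSE)
    dplyr::bind_rows(lapply(pairs, function(pr) {
      tab <- table(groupings[[pr[1]]], groupings[[pr[2]]])
      dplyr::mutate(chi_square_test(tab),
        grouping_a = pr[1], grouping_b = pr[2], .before = 1)
    }))
  })
  surv_data <- dplyr::inner_join(surv, groupings, by = "id")
  run_stage("survival_models", function() {
    combo <- combine_groups(surv_data$hscae, surv_data$rna)
    d <- dplyr::mutate(surv_data, combined = combo$binary)
    list(
      km = lapply(split(d, d$hscae), km_estimate),
      logrank = logrank_test(d, d$hscae),
      cox_hscae = cox_fit(d, "hscae"),
      cv = list(
        hscae = cv_cindex(d, "hscae", seed = derive_seed(seed, "folds")),
        rna = cv_cindex(d, "rna", seed = derive_seed(seed, "folds")),
        combined = cv_cindex(d, c("hscae", "rna"),
          seed = derive_seed(seed, "folds"))
      )
    )
  })
  run_stage("dge", function() {
    combo <- combine_groups(groupings$hscae, groupings$rna)
    v <- voom_normalize(cohort$counts)
    e <- combat_correct(v$logcpm, cohort$clinical$batch)
    dge <- dge_ttest(e, combo$binary)
    de <- dge$gene[dge$call != "ns"]
    enr <- if (length(de) > 0 && !is.null(cfg$genesets)) {
      geneset_enrichment(de, dge$gene, cfg$genesets,
        setNames(dge$call, dge$gene)[de])
    } else NULL
    list(dge = dge, enrichment = enr)
  })
  results$groupings <- groupings
  results$manifest <- manifest
  class(results) <- "pipeline_result"
  results
}

#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param k_range,B Consensus-clustering settings.
#' @param n_levels Gray levels for discretization.
#' @param cae Partial [cae_config()] override list for the deep branch.
#' @param lambda_prognostic Prognostic-loss weight of the half-supervised
#'   model.
#' @param genesets Optional named list of genesets for enrichment.
#' @return Named list of settings.
#' @export
pipeline_config <- function(seed = 1, k_range = 2:4, B = 200,
                            n_levels = 64,
                            cae = list(epochs = 10, channels = c(4, 8, 16),
                              latent_dim = 32, input_size = 32,
                              cv_repeats = 1, final_refit = FALSE),
                            lambda_prognostic = 0.5, genesets = NULL) {
  list(seed = seed, k_range = k_range, B = B, n_levels = n_levels,
    cae = cae, lambda_prognostic = lambda_prognostic, genesets = genesets)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(as.data.frame(x$manifest), digits = 3)
  invisible(x)
}

#' Render a plain-text pipeline report
#'
#' Summarizes cluster sizes (labeled A >= B >= ...), the association tests,
#' the concordance comparison, and the differential-expression counts of a
#' completed run. Stages absent from the result are marked "not run".
#'
#' @param result A `pipeline_result`.
#' @return Character vector of report lines (invisibly printed with
#'   `cat()` when interactive).
#' @export
pipeline_report <- function(result) {
  lines <- c("== Multi-omic pipeline report ==", "")
  if (!is.null(result$groupings)) {
    for (g in c("hrf", "cae", "hscae", "rna")) {
      tb <- table(result$groupings[[g]])
      lines <- c(lines, sprintf("%-6s clusters: %s", g,
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
    }
  } else {
    lines <- c(lines, "clustering: not run")
  }
  lines <- c(lines, "")
  if (!is.null(result$associations)) {
    a <- result$associations
    lines <- c(lines, "association tests (chi-square):",
      sprintf("  %s x %s: chi2 = %.3f, p = %.4f",
        a$grouping_a, a$grouping_b, a$statistic, a$p_value))
  } else {
    lines <- c(lines, "associations: not run")
  }
  lines <- c(lines, "")
  if (!is.null(result$survival_models)) {
    cv <- result$survival_models$cv
    lines <- c(lines, "cross-validated concordance:",
      sprintf("  %-9s c-index = %.3f [%.3f, %.3f]",
        names(cv),
        vapply(cv, function(z) z$cindex, numeric(1)),
        vapply(cv, function(z) z$conf_low, numeric(1)),
        vapply(cv, function(z) z$conf_high, numeric(1))))
  } else {
    lines <- c(lines, "survival models: not run")
  }
  lines <- c(lines, "")
  if (!is.null(result$dge)) {
    calls <- table(result$dge$dge$call)
    lines <- c(lines, sprintf(
      "differential expression: %d up, %d down, %d ns",
      calls["up"] %|na|% 0, calls["down"] %|na|% 0, calls["ns"] %|na|% 0))
  } else {
    lines <- c(lines, "differential expression: not run")
  }
  invisible(lines)
}

`%|na|%` <- function(a, b) if (is.na(a) || is.null(a)) b else a
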