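sim_lmm_data <- function(seed = 1, beta = 1, sd_study = 0.3, sd_resid = 0.3,
                         n_studies = 12, per = 4) {
  simulate_size_response(n_studies = n_studies, networks_per_study = per,
                         beta = beta, sd_study = sd_study,
                         sd_resid = sd_resid, seed = seed)
}

test_that("fit_lmm reports likelihood, AIC and the AICc correction", {
  df <- sim_lmm_data()
  fit <- fit_lmm(df, y ~ log_m + (1 | study_id), "ML")
  expect_s3_class(fit, "quantweb_lmm")
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)
  expect_gt(fit$AICc, fit$AIC)
  expect_equal(fit$AICc - fit$AIC,
               2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1))
  expect_lt(abs(mean(residuals(fit))), 1e-6)
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "log_m") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$method, "ML")
})

test_that("a constant response gives a zero slope and zero residuals", {
  df <- sim_lmm_data()
  df$y <- 2.5
  fit <- fit_lmm(df, y ~ log_m + (1 | study_id), "ML")
  expect_equal(unname(lme4::fixef(fit$fit)["log_m"]), 0, tolerance = 1e-8)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
})

test_that("likelihood-ratio tests follow the chi-square contract", {
  df <- sim_lmm_data(seed = 2, beta = 0)
  full <- fit_lmm(df, y ~ log_m + (1 | study_id), "ML")
  reduced <- fit_lmm(df, y ~ 1 + (1 | study_id), "ML")
  out <- lrt(full, reduced)
  expect_gte(out$chisq, 0)
  expect_equal(out$df, 1L)
  expect_equal(out$p, pchisq(out$chisq, 1, lower.tail = FALSE))
  # same model twice: chisq clipped at 0, p = 1
  self <- suppressWarnings(lrt(full, full))
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)
  # REML fits are refused
  fr <- fit_lmm(df, y ~ log_m + (1 | study_id), "REML")
  expect_error(lrt(fr, reduced), class = "quantweb_refusal_error")
})

test_that("marginal residuals retain the study effects, conditional do not", {
  df <- sim_lmm_data(seed = 3, sd_study = 1)
  fit <- fit_lmm(df, y ~ log_m + (1 | study_id), "REML")
  rc <- residuals(fit, type = "conditional")
  rm_ <- residuals(fit, type = "marginal")
  expect_gt(sd(rm_), sd(rc))
})

test_that("random-structure selection applies the parsimony rule", {
  # no slope heterogeneity: the simpler intercept model must win
  df <- sim_lmm_data(seed = 4, sd_study = 0.4)
  sel <- select_random_structure(df, "y", "log_m")
  expect_equal(sel$structure, "intercept")
  # strong per-study slope variation: the slope model must win by > 1 AIC
  df2 <- withr::with_seed(9, {
    d <- sim_lmm_data(seed = 9, beta = 1, sd_study = 0.2, n_studies = 15)
    slopes <- rnorm(15, 0, 0.8)
    d$y <- d$y + slopes[as.integer(factor(d$study_id))] * d$log_m
    d
  })
  sel2 <- select_random_structure(df2, "y", "log_m")
  expect_equal(sel2$structure, "slope")
  expect_gt(sel2$delta, 1)
})

test_that("backward simplification respects marginality and keeps real effects", {
  df <- withr::with_seed(31, {
    n <- 150
    tibble::tibble(
      study_id = rep(sprintf("S%02d", 1:15), each = 10),
      x1 = rnorm(n), x2 = rnorm(n),
      residual = 2 * x1 * x2 + rnorm(n, 0, 0.5) +
        rep(rnorm(15, 0, 0.3), each = 10))
  })
  sim <- backward_simplify(df, "residual", c("x1", "x2", "x1:x2"))
  expect_true("x1:x2" %in% sim$terms)
  expect_true(all(c("x1", "x2") %in% sim$terms))  # parents kept
  expect_equal(sim$fit$method, "REML")

  # pure-noise predictors are stripped to the intercept-only model
  df$residual <- withr::with_seed(32, rnorm(nrow(df)) +
                                    rep(rnorm(15, 0, 0.3), each = 10))
  sim0 <- backward_simplify(df, "residual", c("x1", "x2", "x1:x2"))
  expect_length(sim0$terms, 0)
  expect_true(all(sim0$path$p[sim0$path$dropped] >= 0.05))
})

test_that("stage-1 regressions recover strong size effects and leave nulls", {
  df <- sim_lmm_data(seed = 6, beta = 0.3, n_studies = 15, per = 5)
  metrics <- tibble::tibble(
    study_id = df$study_id, network_id = df$network_id, m = df$m,
    generality = exp(df$y),
    h2prime = withr::with_seed(8, runif(nrow(df), 0.4, 0.6)))
  rep1 <- stage1_size_regressions(metrics)
  g <- rep1[rep1$metric == "generality", ]
  expect_lt(g$p, 0.05)
  expect_equal(g$direction, "increase")
  h <- rep1[rep1$metric == "h2prime", ]
  expect_gt(h$p, 0.05)
})

test_that("single-study inputs fall back to fixed-effect regressions", {
  df <- sim_lmm_data(seed = 7, beta = 0.5, n_studies = 1, per = 12)
  metrics <- tibble::tibble(study_id = df$study_id, network_id = df$network_id,
                            m = df$m, generality = exp(df$y))
  expect_warning(rep1 <- stage1_size_regressions(metrics), "single study")
  expect_equal(rep1$random_structure, "none")
  expect_lt(rep1$p, 0.05)
})

test_that("stage-2 subsampling regressions recover the sampling signs", {
  nets <- purrr::map(1:4, function(i) {
    withr::with_seed(50 + i, {
      net <- generate_network(20, 15, 400, 0.5, config = generator_config(),
                              network_id = paste0("n", i),
                              study_id = if (i <= 2) "s1" else "s2")
    })
  })
  coll <- quantweb_collection(nets)
  rar <- collection_rarefaction(coll, reps = 25, seed = 3, grid_points = 8)
  rep2 <- stage2_subsample_regressions(rar)
  gen <- rep2[rep2$metric == "generality", ]
  expect_lt(gen$p, 0.05)
  expect_equal(gen$direction, "increase")
  con <- rep2[rep2$metric == "connectance", ]
  expect_lt(con$p, 0.05)
  expect_equal(con$direction, "decrease")
  h2 <- rep2[rep2$metric == "h2prime", ]
  expect_lt(abs(h2$slope), 0.05)
})

test_that("stage-4 Delta regressions detect coupling and refuse constants", {
  df <- withr::with_seed(41, {
    tibble::tibble(
      study_id = rep(sprintf("S%02d", 1:12), each = 4),
      network_id = sprintf("n%02d", 1:48),
      m = exp(runif(48, 3, 7)),
      delta = runif(48, 20, 90))
  })
  df$generality <- withr::with_seed(42, exp(0.02 * df$delta + rnorm(48, 0, 0.2)))
  df$connectance <- withr::with_seed(43, runif(48, 0.2, 0.4))
  rep4 <- stage4_delta_regressions(df)
  g <- rep4[rep4$metric == "generality", ]
  expect_lt(g$p, 0.05)
  expect_equal(g$direction, "increase")
  expect_equal(g$random_structure, "slope")
  expect_gt(rep4$p[rep4$metric == "connectance"], 0.05)
  df$delta <- 50
  expect_error(stage4_delta_regressions(df),
               class = "quantweb_not_applicable_error")
})

test_that("stage 5 reduces null and degenerate inputs to the intercept", {
  df <- withr::with_seed(51, {
    tibble::tibble(
      study_id = rep(sprintf("S%02d", 1:12), each = 4),
      network_id = sprintf("n%02d", 1:48),
      latitude = rep(runif(12, -30, 70), each = 4),
      guild = rep(sample(c("aphids", "gallers", "leaf miners"), 12, TRUE),
                  each = 4),
      delta = runif(48, 20, 90),
      m = exp(runif(48, 3, 7)))
  })
  # a constant metric: residuals are all zero, model collapses
  df$h2prime <- 0.5
  rep5 <- suppressWarnings(stage5_residual_analysis(df))
  expect_equal(rep5$retained, "")
  expect_false(rep5$latitude_retained)

  # single-level guild: guild terms dropped with a warning
  df$guild <- "aphids"
  df$h2prime <- withr::with_seed(52, runif(48, 0.3, 0.7))
  expect_warning(rep5b <- stage5_residual_analysis(df), "single level")
  expect_false(rep5b$guild_retained)
})
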