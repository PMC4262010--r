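# Mixed-model machinery for the five analysis stages: AIC/AICc-based
# choice of the random structure, likelihood-ratio tests of fixed
# effects (always on ML fits), backward simplification respecting
# marginality, and a REML refit of the minimum adequate model.

metric_names <- c("connectance", "generality", "h2prime",
                  "linkage_density", "modularity", "vulnerability")

#' Fit a linear mixed model (or plain linear model)
#'
#' Thin wrapper around [lme4::lmer()] (or [stats::lm()] when the
#' formula has no random terms) that records the estimation method,
#' log-likelihood, AIC and small-sample AICc
#' (`AIC + 2k(k+1)/(n-k-1)`), and flags singular or non-converged fits
#' instead of dropping them.
#'
#' @param data A data frame.
#' @param formula Model formula, with random terms in `lme4` syntax.
#' @param method `"ML"` (required for likelihood-ratio tests of fixed
#'   effects) or `"REML"` (used only for the final reported model).
#' @return An object of class `quantweb_lmm`.
#' @export
fit_lmm <- function(data, formula, method = c("ML", "REML")) {
  method <- match.arg(method)
  has_re <- length(lme4::findbars(formula)) > 0
  msgs <- character(0)
  conv <- TRUE
  sing <- FALSE
  if (has_re) {
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = data, REML = method == "REML",
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        conv <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    sing <- lme4::isSingular(fit)
  } else {
    fit <- stats::lm(formula, data = data)
  }
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  aic <- -2 * as.numeric(ll) + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(fit = fit, formula = formula, method = method,
                 logLik = as.numeric(ll), k = k, n = n,
                 AIC = aic, AICc = aicc,
                 singular = sing, converged = conv, messages = msgs,
                 has_re = has_re),
            class = "quantweb_lmm")
}

#' @export
print.quantweb_lmm <- function(x, ...) {
  cat(sprintf("<quantweb_lmm> %s fit: %s\n  logLik %.3f, AIC %.2f, AICc %.2f, k = %d, n = %d%s%s\n",
              x$method, deparse(x$formula), x$logLik, x$AIC, x$AICc, x$k, x$n,
              if (x$singular) " [singular]" else "",
              if (!x$converged) " [convergence flagged]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.quantweb_lmm <- function(x, ...) {
  cf <- if (x$has_re) {
    summary(x$fit)$coefficients
  } else {
    summary(x$fit)$coefficients[, 1:3, drop = FALSE]
  }
  tibble(term = rownames(cf), estimate = cf[, 1],
         std.error = cf[, 2], statistic = cf[, 3])
}

#' @export
glance.quantweb_lmm <- function(x, ...) {
  tibble(logLik = x$logLik, AIC = x$AIC, AICc = x$AICc, df = x$k,
         nobs = x$n, method = x$method, singular = x$singular,
         converged = x$converged)
}

#' @export
residuals.quantweb_lmm <- function(object,
                                   type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (!object$has_re || type == "conditional") {
    return(unname(residuals(object$fit)))
  }
  y <- model.response(model.frame(object$fit))
  unname(y - predict(object$fit, re.form = NA))
}

fixef_slope <- function(fit, term) {
  cf <- if (fit$has_re) lme4::fixef(fit$fit) else coef(fit$fit)
  unname(cf[term])
}

#' Likelihood-ratio test of nested mixed models
#'
#' `chisq = 2 (logLik_full - logLik_reduced)` (clipped at zero), with
#' degrees of freedom equal to the difference in parameter counts and a
#' chi-square upper-tail p-value. Both fits must be ML: REML
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param full,reduced `quantweb_lmm` fits, `reduced` nested in `full`.
#' @return A one-row tibble with `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "quantweb_lmm"), inherits(reduced, "quantweb_lmm"))
  if (full$method != "ML" || reduced$method != "ML") {
    abort("likelihood-ratio tests of fixed effects require ML fits",
          class = c("quantweb_refusal_error", "quantweb_error"))
  }
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$k - reduced$k
  if (df < 1) {
    warn("models do not differ in parameter count; using df = 1")
    df <- 1L
  }
  tibble(chisq = chisq, df = as.integer(df),
         p = pchisq(chisq, df, lower.tail = FALSE))
}

random_part <- function(structure = c("intercept", "slope"), group,
                        slope_var = NULL) {
  structure <- match.arg(structure)
  if (structure == "intercept") {
    sprintf("(1 | %s)", group)
  } else {
    sprintf("(1 + %s | %s)", slope_var, group)
  }
}

#' Choose between random-intercept and random-intercept-plus-slope
#'
#' Fits both candidate random structures by ML and keeps the more
#' complex one only when it improves the information criterion by more
#' than 1; otherwise the simpler model is preferred (parsimony rule).
#' If one candidate fails to fit, the other is returned with a warning.
#'
#' @param data A data frame.
#' @param response,fixed Response name and character vector of fixed
#'   terms (may be empty for an intercept-only fixed part).
#' @param group Grouping expression, e.g. `"study_id"` or
#'   `"study_id/network_id"`.
#' @param slope_var Variable getting the random slope.
#' @param criterion `"AIC"` or `"AICc"`.
#' @return A list with `structure` (`"intercept"` or `"slope"`), the
#'   chosen ML `fit`, both candidate fits, and the criterion
#'   difference `delta` (intercept minus slope).
#' @export
select_random_structure <- function(data, response, fixed, group = "study_id",
                                    slope_var = "log_m",
                                    criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  fml <- function(re) {
    as.formula(paste(response, "~",
                     paste(c(if (length(fixed)) fixed else "1", re),
                           collapse = " + ")))
  }
  f_int <- tryCatch(fit_lmm(data, fml(random_part("intercept", group)), "ML"),
                    error = function(e) e)
  f_slp <- tryCatch(fit_lmm(data, fml(random_part("slope", group, slope_var)),
                            "ML"),
                    error = function(e) e)
  if (inherits(f_int, "error") && inherits(f_slp, "error")) {
    abort("both candidate random structures failed to fit",
          class = c("quantweb_fit_error", "quantweb_error"))
  }
  if (inherits(f_slp, "error")) {
    warn("random-slope candidate failed; using random intercept")
    return(list(structure = "intercept", fit = f_int, fits = list(intercept = f_int),
                delta = NA_real_))
  }
  if (inherits(f_int, "error")) {
    warn("random-intercept candidate failed; using random slope")
    return(list(structure = "slope", fit = f_slp, fits = list(slope = f_slp),
                delta = NA_real_))
  }
  delta <- f_int[[criterion]] - f_slp[[criterion]]
  choose_slope <- is.finite(delta) && delta > 1
  list(structure = if (choose_slope) "slope" else "intercept",
       fit = if (choose_slope) f_slp else f_int,
       fits = list(intercept = f_int, slope = f_slp),
       delta = delta)
}

#' Backward simplification to the minimum adequate model
#'
#' Starting from the maximal fixed-effect structure, repeatedly drops
#' the least significant droppable term (interactions before the main
#' effects they contain, so marginality is respected) whose
#' likelihood-ratio p-value is at or above `p_cut`, refitting by ML at
#' each step. The surviving model is refitted with REML for reporting.
#'
#' @param data A data frame.
#' @param response Response variable name.
#' @param fixed Character vector of fixed-effect terms (use `:` for
#'   interactions).
#' @param random Random part as a string, e.g. `"(1 | study_id)"`, or
#'   `NULL` for a fixed-effects model.
#' @param p_cut Retention threshold for fixed effects.
#' @return A list with `terms` (retained fixed terms), `fit` (REML
#'   refit), `fit_ml`, and `path` (a tibble logging every test: term,
#'   chisq, df, p, dropped).
#' @export
backward_simplify <- function(data, response, fixed, random = "(1 | study_id)",
                              p_cut = 0.05) {
  fml <- function(fx) {
    as.formula(paste(response, "~",
                     paste(c(if (length(fx)) fx else "1", random),
                           collapse = " + ")))
  }
  current <- fixed
  path <- list()
  full <- fit_lmm(data, fml(current), "ML")
  step <- 0L
  while (length(current) > 0) {
    droppable <- drop.scope(reformulate(current))
    if (length(droppable) == 0) break
    tests <- purrr::map(droppable, function(tm) {
      reduced <- fit_lmm(data, fml(setdiff(current, tm)), "ML")
      cbind(tibble(term = tm), lrt(full, reduced))
    })
    tests <- purrr::list_rbind(tests)
    # a degenerate fit (e.g. zero-variance response) gives no evidence
    # for any term: treat its p as 1 so the term drops
    tests$p[!is.finite(tests$p)] <- 1
    worst <- which.max(tests$p)
    step <- step + 1L
    drop_it <- tests$p[worst] >= p_cut
    path[[step]] <- dplyr::mutate(tests,
                                  step = step,
                                  dropped = dplyr::row_number() == worst & drop_it)
    if (!drop_it) break
    current <- setdiff(current, tests$term[worst])
    full <- fit_lmm(data, fml(current), "ML")
  }
  list(terms = current,
       fit = fit_lmm(data, fml(current), "REML"),
       fit_ml = full,
       path = if (length(path)) purrr::list_rbind(path) else
         tibble(term = character(0), chisq = double(0), df = integer(0),
                p = double(0), step = integer(0), dropped = logical(0)))
}

# per-stage response transforms: which metrics are log-transformed
stage_logged <- function(stage, metric) {
  switch(as.character(stage),
         "1" = metric != "h2prime",
         "2" = !metric %in% c("h2prime", "modularity"),
         "3" = !metric %in% c("h2prime", "modularity"),
         "4" = !metric %in% c("h2prime", "connectance"),
         "5" = metric != "h2prime",
         stop_validation("unknown stage"))
}

transform_response <- function(x, logged, metric) {
  if (!logged) return(x)
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warn(sprintf("%d non-positive %s value(s) dropped before log transform",
                 sum(bad), metric))
    x[bad] <- NA_real_
  }
  log(x)
}

report_row <- function(stage, metric, n, structure, test, slope,
                       singular = FALSE) {
  tibble(stage = stage, metric = metric, n = as.integer(n),
         random_structure = structure, chisq = test$chisq,
         df = test$df, p = test$p, slope = slope,
         direction = ifelse(is.na(slope), NA_character_,
                            ifelse(slope > 0, "increase", "decrease")),
         singular = singular)
}

# shared engine for the single-predictor stages (1, 3, 4)
single_predictor_stage <- function(metrics, stage, predictor, criterion,
                                   structure_rule = NULL) {
  present <- intersect(metric_names, names(metrics))
  fits <- list()
  rows <- purrr::map(present, function(metric) {
    logged <- stage_logged(stage, metric)
    df <- tibble(y = transform_response(metrics[[metric]], logged, metric),
                 x = metrics[[predictor]],
                 study_id = metrics$study_id)
    if (predictor == "m") df$x <- log(df$x)
    df <- df[stats::complete.cases(df), ]
    if (nrow(df) < 3 || all(is.na(df$y))) return(NULL)
    if (length(unique(df$x)) < 2) {
      stop_not_applicable(sprintf(
        "predictor is constant; stage-%s regression for %s is undefined",
        stage, metric))
    }
    if (length(unique(df$study_id)) < 2) {
      warn(sprintf("single study: fixed-effects-only regression for %s", metric))
      full <- fit_lmm(df, y ~ x, "ML")
      reduced <- fit_lmm(df, y ~ 1, "ML")
      fits[[metric]] <<- full
      return(report_row(stage, metric, nrow(df), "none", lrt(full, reduced),
                        fixef_slope(full, "x")))
    }
    structure <- if (is.null(structure_rule)) {
      select_random_structure(df, "y", "x", group = "study_id",
                              slope_var = "x", criterion = criterion)$structure
    } else {
      structure_rule(metric)
    }
    re <- random_part(structure, "study_id", "x")
    full <- fit_lmm(df, as.formula(paste("y ~ x +", re)), "ML")
    reduced <- fit_lmm(df, as.formula(paste("y ~ 1 +", re)), "ML")
    fits[[metric]] <<- full
    report_row(stage, metric, nrow(df), structure, lrt(full, reduced),
               fixef_slope(full, "x"), full$singular)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "fits") <- fits
  out
}

#' Stage 1: network metrics against matrix size
#'
#' Regresses each (transformed) metric on `log(m)` across the original
#' networks, with study as the random-effect group. The random
#' structure (intercept vs intercept + slope) is chosen by AIC with the
#' parsimony rule; the p-value comes from a likelihood-ratio test of
#' the `log(m)` fixed effect. All metrics are log-transformed except
#' H2'.
#'
#' @param metrics A metric table from [network_metrics()] (columns
#'   `study_id`, `m` and the metric columns).
#' @return A report tibble with one row per metric: `chisq`, `df`, `p`,
#'   chosen `random_structure`, fitted `slope` and its `direction`.
#'   Full-model fits are kept in the `fits` attribute.
#' @export
stage1_size_regressions <- function(metrics) {
  single_predictor_stage(metrics, 1L, "m", "AIC")
}

#' Stage 2: metrics against size within subsampled networks
#'
#' Uses rarefaction output (replicate means per subsampled size):
#' `log(mean metric)` (untransformed for modularity and H2') against
#' `log(size)`, with network nested within study as random intercepts;
#' modularity additionally gets a random slope. The likelihood-ratio
#' test concerns the fixed `log(size)` effect.
#'
#' @param rarefaction A `quantweb_rarefaction` tibble
#'   (from [collection_rarefaction()]).
#' @return A report tibble as in [stage1_size_regressions()].
#' @export
stage2_subsample_regressions <- function(rarefaction) {
  present <- intersect(metric_names, unique(rarefaction$metric))
  if (length(unique(rarefaction$network_id)) < 2) {
    stop_validation("stage 2 needs rarefaction curves for at least 2 networks")
  }
  rows <- purrr::map(present, function(metric) {
    sub <- rarefaction[rarefaction$metric == metric, ]
    logged <- stage_logged(2L, metric)
    df <- tibble(y = transform_response(sub$mean, logged, metric),
                 x = log(sub$size),
                 study_id = sub$study_id, network_id = sub$network_id)
    df <- df[stats::complete.cases(df), ]
    if (nrow(df) < 4) return(NULL)
    group <- if (length(unique(df$study_id)) < 2) "network_id" else
      "study_id/network_id"
    structure <- if (metric == "modularity") "slope" else "intercept"
    re <- random_part(structure, group, "x")
    full <- fit_lmm(df, as.formula(paste("y ~ x +", re)), "ML")
    reduced <- fit_lmm(df, as.formula(paste("y ~ 1 +", re)), "ML")
    report_row(2L, metric, nrow(df), structure, lrt(full, reduced),
               fixef_slope(full, "x"), full$singular)
  })
  purrr::list_rbind(rows)
}

#' Stage 3: standardised metrics against original size
#'
#' After subsampling every network to a common size, regresses each
#' standardised metric on the logarithm of the *original* matrix size
#' (random structure chosen by small-sample AICc). Under pure sampling
#' effects the expectation is a null result for every metric.
#'
#' @param standardised Output of [standardise_collection()].
#' @return A report tibble as in [stage1_size_regressions()].
#' @export
stage3_standardised_regressions <- function(standardised) {
  metrics <- dplyr::rename(standardised, m = "m_original")
  single_predictor_stage(metrics, 3L, "m", "AICc")
}

#' Stage 4: metrics against host taxonomic diversity
#'
#' Regresses each metric (untransformed connectance and H2',
#' log-transformed otherwise) on the taxonomic diversity index Delta,
#' with a random intercept by study (random intercept + slope for
#' generality). A constant Delta across networks makes the regression
#' undefined and raises an error.
#'
#' @param metrics A metric table carrying a `delta` column (join the
#'   output of [collection_delta()]).
#' @return A report tibble as in [stage1_size_regressions()].
#' @export
stage4_delta_regressions <- function(metrics) {
  if (!"delta" %in% names(metrics)) {
    stop_validation("metrics table needs a `delta` column (see collection_delta)")
  }
  if (length(unique(round(metrics$delta, 10))) < 2) {
    stop_not_applicable("Delta is constant across networks; regression undefined")
  }
  single_predictor_stage(metrics, 4L, "delta", "AIC",
                         structure_rule = function(metric) {
                           if (metric == "generality") "slope" else "intercept"
                         })
}

#' Size-corrected residuals of a network metric
#'
#' The stage-1 recipe (transformed metric against `log(m)` with the
#' AIC-chosen random structure) refitted with the requested method; the
#' residuals are the size-corrected metric values used as responses in
#' the latitude/guild analysis. Conditional residuals (default)
#' subtract the study-level random effects; marginal residuals only
#' subtract the fixed-effect prediction.
#'
#' @inheritParams stage1_size_regressions
#' @param metric Metric column name.
#' @param method `"REML"` (default) or `"ML"` for the residual-producing
#'   fit.
#' @param type `"conditional"` or `"marginal"`.
#' @return A tibble `network_id`, `study_id`, `residual` for the rows
#'   where the metric is defined.
#' @export
size_residuals <- function(metrics, metric, method = "REML",
                           type = c("conditional", "marginal")) {
  type <- match.arg(type)
  logged <- stage_logged(5L, metric)
  df <- tibble(network_id = metrics$network_id, study_id = metrics$study_id,
               y = transform_response(metrics[[metric]], logged, metric),
               x = log(metrics$m))
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop_validation("too few defined values for residuals")
  if (length(unique(df$study_id)) < 2) {
    fit <- fit_lmm(df, y ~ x, method)
    res <- residuals(fit)
  } else {
    structure <- select_random_structure(df, "y", "x", group = "study_id",
                                         slope_var = "x",
                                         criterion = "AIC")$structure
    re <- random_part(structure, "study_id", "x")
    fit <- fit_lmm(df, as.formula(paste("y ~ x +", re)), method)
    res <- residuals(fit, type = type)
  }
  tibble(network_id = df$network_id, study_id = df$study_id, residual = res)
}

#' Stage 5: latitude and guild effects on size-corrected metrics
#'
#' For each metric, takes the residuals from the metric-vs-size
#' regression and models them as a function of host guild, absolute
#' latitude, Delta and all two-way interactions, with a random
#' intercept by study, then backward-simplifies to the minimum adequate
#' model (interactions drop before their main effects; retention
#' threshold `p_cut`). The report says which terms survive — in
#' particular whether any latitude or guild term is retained.
#'
#' Residuals default to *marginal* (fixed-effect prediction only):
#' latitude and guild are constant within a study, so conditional
#' residuals — which subtract the fitted study intercepts — would
#' absorb exactly the between-study variation these covariates could
#' explain, leaving the test with almost no power.
#'
#' @param metrics Metric table with `latitude`, `guild` and `delta`
#'   columns (join [collection_delta()] output first).
#' @param p_cut Retention threshold.
#' @param residual_method,residual_type Passed to [size_residuals()].
#' @return A tibble with one row per metric: retained terms,
#'   `latitude_retained`, `guild_retained`, `delta_retained`, and the
#'   simplification path in a list-column.
#' @export
stage5_residual_analysis <- function(metrics, p_cut = 0.05,
                                     residual_method = "REML",
                                     residual_type = "marginal") {
  need <- c("latitude", "guild", "delta", "m", "study_id", "network_id")
  if (!all(need %in% names(metrics))) {
    stop_validation(sprintf("metrics table needs columns %s",
                            paste(need, collapse = ", ")))
  }
  present <- intersect(metric_names, names(metrics))
  rows <- purrr::map(present, function(metric) {
    res <- tryCatch(size_residuals(metrics, metric, method = residual_method,
                                   type = residual_type),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    df <- dplyr::inner_join(res,
                            dplyr::select(metrics, "network_id", "latitude",
                                          "guild", "delta"),
                            by = "network_id")
    df$abs_lat <- abs(df$latitude)
    df$guild <- factor(df$guild)
    mains <- c("guild", "abs_lat", "delta")
    if (length(levels(df$guild)) < 2) {
      warn(sprintf("guild has a single level; guild terms dropped for %s",
                   metric))
      mains <- setdiff(mains, "guild")
    }
    if (length(unique(round(df$delta, 10))) < 2) {
      mains <- setdiff(mains, "delta")
    }
    fixed <- c(mains, if (length(mains) > 1) utils::combn(mains, 2, paste,
                                                          collapse = ":"))
    random <- if (length(unique(df$study_id)) > 1) "(1 | study_id)" else NULL
    sim <- backward_simplify(df, "residual", fixed, random = random,
                             p_cut = p_cut)
    tibble(stage = 5L, metric = metric, n = nrow(df),
           retained = paste(sim$terms, collapse = " + "),
           latitude_retained = any(grepl("abs_lat", sim$terms)),
           guild_retained = any(grepl("guild", sim$terms)),
           delta_retained = any(grepl("delta", sim$terms)),
           path = list(sim$path))
  })
  purrr::list_rbind(rows)
}
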