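#' @importFrom stats as.formula binomial coef glm lm pgamma qnorm rbinom
#'   rgamma rnorm runif sd vcov setNames
NULL

# Treatment coding with the referent levels pulse / strong / 4 mm, so every
# reported effect reads as "changing pulse to thrill", "strong to weak",
# "4 mm to 6 mm".
model_frame <- function(metric_table) {
  need <- c("participant_id", "vibration_type", "vibration_intensity",
            "skin_thickness_mm")
  miss <- setdiff(need, names(metric_table))
  if (length(miss)) {
    palp_error(paste0("metric table missing column(s): ",
                      paste(miss, collapse = ", ")), "palp_format_error")
  }
  data.frame(
    participant_id = factor(metric_table$participant_id),
    type_thrill = as.numeric(metric_table$vibration_type == "thrill"),
    intensity_weak = as.numeric(metric_table$vibration_intensity == "weak"),
    thickness_6mm = as.numeric(metric_table$skin_thickness_mm == 6)
  )
}

factor_terms <- c(vibration_type = "type_thrill",
                  vibration_intensity = "intensity_weak",
                  skin_thickness = "thickness_6mm")

wald_ci <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  cbind(ci_low = est - z * se, ci_high = est + z * se)
}

#' Fit the per-metric linear mixed model
#'
#' A random-intercept-per-participant linear model of one metric on the
#' three haptic factors (indicator coded, referents pulse / strong / 4 mm),
#' fitted by REML. Each participant gets their own baseline; the three fixed
#' effects are the mean shifts from changing one factor level. Inference is
#' by Wald normal 95% confidence intervals; a factor is flagged significant
#' when its interval excludes 0 (alpha = 0.05).
#'
#' @param metric_table data.frame with one row per trial: `participant_id`,
#'   `vibration_type`, `vibration_intensity`, `skin_thickness_mm`, and the
#'   metric column.
#' @param metric_name name of the metric column to model
#'   (e.g. `"duration_s"`).
#' @return an object of class `lmm_fit`: list with `metric_name`,
#'   `fixed_effects` (data.frame: factor, estimate, se, ci_low, ci_high,
#'   significant), `intercept`, `participant_intercept_variance`,
#'   `residual_variance`, `n_obs`, `n_participants`, `converged`.
#' @export
fit_metric_lmm <- function(metric_table, metric_name) {
  if (!metric_name %in% names(metric_table)) {
    palp_error(paste0("no metric column ", metric_name), "palp_domain_error")
  }
  d <- model_frame(metric_table)
  d$y <- as.numeric(metric_table[[metric_name]])
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$participant_id)) < 2L) {
    palp_error("need at least 2 participants", "palp_domain_error")
  }
  if (sd(d$y) == 0) {
    palp_error(paste0(metric_name, " is constant: degenerate fit"),
               "palp_degenerate_fit")
  }
  fit <- tryCatch(
    lme4::lmer(y ~ type_thrill + intensity_weak + thickness_6mm +
                 (1 | participant_id),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) {
      palp_error(paste0("LMM for ", metric_name, " failed to converge: ",
                        conditionMessage(e)), "palp_fit_failure")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  terms <- unname(factor_terms)
  ci <- wald_ci(b[terms], se[terms])
  fe <- data.frame(factor = names(factor_terms),
                   estimate = unname(b[terms]),
                   se = unname(se[terms]),
                   ci_low = unname(ci[, 1L]),
                   ci_high = unname(ci[, 2L]),
                   stringsAsFactors = FALSE)
  fe$significant <- fe$ci_low > 0 | fe$ci_high < 0
  structure(
    list(metric_name = metric_name,
         fixed_effects = fe,
         intercept = unname(b[["(Intercept)"]]),
         participant_intercept_variance =
           vc$vcov[vc$grp == "participant_id"][1L],
         residual_variance = vc$vcov[vc$grp == "Residual"][1L],
         n_obs = nrow(d),
         n_participants = nlevels(droplevels(d$participant_id)),
         converged = length(fit@optinfo$conv$lme4$messages %||% character()) == 0L),
    class = "lmm_fit"
  )
}

#' Fit the logistic GLMM for binary accuracy
#'
#' Models the probability that a trial's final location estimate falls
#' within 30 mm of the target. The linear predictor has a participant
#' random intercept plus the three haptic-factor indicators; the inverse
#' logit maps it to a probability. The marginal likelihood is integrated by
#' adaptive Gauss-Hermite quadrature (`nAGQ` nodes, default 15). Effects are
#' reported on the log-odds scale and as odds ratios exp(coefficient) with
#' exponentiated Wald intervals.
#'
#' @param metric_table data.frame with `accurate_binary` plus the id and
#'   factor columns.
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes (>= 1).
#' @return an object of class `glmm_fit`: list with `fixed_effects`
#'   (factor, log_odds, se, ci_low, ci_high, or, or_ci_low, or_ci_high,
#'   significant), `intercept`, `random_intercept_variance`, `n_obs`,
#'   `n_participants`, `converged`, and `fitted` (linear predictors eta and
#'   probabilities pi for the modeled rows).
#' @export
fit_accuracy_glmm <- function(metric_table, nagq = 15L) {
  if (!"accurate_binary" %in% names(metric_table)) {
    palp_error("metric table has no accurate_binary column", "palp_format_error")
  }
  d <- model_frame(metric_table)
  d$y <- as.numeric(as.logical(metric_table$accurate_binary))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$participant_id)) < 2L) {
    palp_error("need at least 2 participants", "palp_domain_error")
  }
  for (nm in names(factor_terms)) {
    tab <- table(d[[factor_terms[[nm]]]], d$y)
    if (any(tab == 0) && nrow(tab) == 2L) {
      if (any(rowSums(tab > 0) == 1L)) {
        palp_error(paste0("complete separation on factor ", nm),
                   "palp_separation_error")
      }
    }
  }
  fit <- tryCatch(
    lme4::glmer(y ~ type_thrill + intensity_weak + thickness_6mm +
                  (1 | participant_id),
                data = d, family = binomial(), nAGQ = as.integer(nagq),
                control = lme4::glmerControl(check.conv.singular = "ignore")),
    error = function(e) {
      palp_error(paste0("accuracy GLMM failed to converge: ",
                        conditionMessage(e)), "palp_fit_failure")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  terms <- unname(factor_terms)
  ci <- wald_ci(b[terms], se[terms])
  fe <- data.frame(factor = names(factor_terms),
                   log_odds = unname(b[terms]),
                   se = unname(se[terms]),
                   ci_low = unname(ci[, 1L]),
                   ci_high = unname(ci[, 2L]),
                   stringsAsFactors = FALSE)
  fe$or <- exp(fe$log_odds)
  fe$or_ci_low <- exp(fe$ci_low)
  fe$or_ci_high <- exp(fe$ci_high)
  fe$significant <- fe$ci_low > 0 | fe$ci_high < 0
  eta <- as.numeric(lme4::getME(fit, "X") %*% b) +
    as.numeric(lme4::getME(fit, "Z") %*% lme4::getME(fit, "b"))
  structure(
    list(fixed_effects = fe,
         intercept = unname(b[["(Intercept)"]]),
         random_intercept_variance = vc$vcov[vc$grp == "participant_id"][1L],
         n_obs = nrow(d),
         n_participants = nlevels(droplevels(d$participant_id)),
         converged = length(fit@optinfo$conv$lme4$messages %||% character()) == 0L,
         fitted = data.frame(eta = eta, pi = 1 / (1 + exp(-eta)))),
    class = "glmm_fit"
  )
}

#' Odds ratio for one haptic factor
#'
#' The multiplicative change in the odds of an accurate (within 30 mm)
#' estimate when the factor moves off its referent level: exp of the fitted
#' log-odds coefficient, with exponentiated confidence bounds. An odds
#' ratio above 1 means the change increases the probability of being
#' accurate.
#'
#' @param glmm_fit a [fit_accuracy_glmm()] result.
#' @param factor one of `"vibration_type"`, `"vibration_intensity"`,
#'   `"skin_thickness"`.
#' @return named numeric `c(estimate, ci_low, ci_high)`.
#' @export
odds_ratio <- function(glmm_fit, factor) {
  fe <- glmm_fit$fixed_effects
  row <- fe[fe$factor == factor, ]
  if (nrow(row) != 1L) {
    palp_error(paste0("unknown factor: ", factor), "palp_domain_error")
  }
  c(estimate = row$or, ci_low = row$or_ci_low, ci_high = row$or_ci_high)
}

continuous_metrics <- c("duration_s", "tpl_mm", "rcm_pct", "error_rate")

#' Analyze a full palpation study
#'
#' Fits the accuracy GLMM plus one LMM per continuous metric (duration,
#' TPL, RCM, error rate) and collects estimates, 95% confidence intervals
#' and alpha = 0.05 significance flags for all three haptic factors. No
#' multiple-testing correction is applied across metrics. Per-metric fit
#' failures are recorded without aborting the other fits.
#'
#' @param metric_table the full per-trial metric table.
#' @param nagq quadrature nodes for the GLMM.
#' @return an object of class `study_analysis`: list with `accuracy` (a
#'   `glmm_fit` or a failure record), `metrics` (named list of `lmm_fit` or
#'   failure records), `n_obs`, `n_participants`.
#' @export
analyze_study <- function(metric_table, nagq = 15L) {
  acc <- tryCatch(fit_accuracy_glmm(metric_table, nagq = nagq),
                  palp_error = function(e) {
                    list(failed = TRUE, message = conditionMessage(e))
                  })
  fits <- lapply(continuous_metrics, function(m) {
    tryCatch(fit_metric_lmm(metric_table, m),
             palp_error = function(e) {
               list(failed = TRUE, message = conditionMessage(e))
             })
  })
  names(fits) <- continuous_metrics
  structure(
    list(accuracy = acc, metrics = fits,
         n_obs = nrow(metric_table),
         n_participants = length(unique(metric_table$participant_id))),
    class = "study_analysis"
  )
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("<study_analysis> %d trials, %d participants\n",
              x$n_obs, x$n_participants))
  cat(format_analysis_table(x), sep = "\n")
  invisible(x)
}

# Human-readable factor-by-metric table in the referent-change phrasing.
format_analysis_table <- function(analysis) {
  lab <- c(vibration_type = "pulse->thrill",
           vibration_intensity = "strong->weak",
           skin_thickness = "4mm->6mm")
  out <- sprintf("%-28s %-15s %10s  %-22s", "metric", "factor change",
                 "estimate", "95% CI")
  star <- function(s) ifelse(s, " *", "")
  if (!isTRUE(analysis$accuracy$failed)) {
    fe <- analysis$accuracy$fixed_effects
    for (i in seq_len(nrow(fe))) {
      out <- c(out, sprintf("%-28s %-15s %10.3f  (%.3f, %.3f)%s",
                            "accuracy (odds ratio)", lab[[fe$factor[i]]],
                            fe$or[i], fe$or_ci_low[i], fe$or_ci_high[i],
                            star(fe$significant[i])))
    }
  } else {
    out <- c(out, paste0("accuracy: FIT FAILED - ", analysis$accuracy$message))
  }
  for (m in names(analysis$metrics)) {
    f <- analysis$metrics[[m]]
    if (isTRUE(f$failed)) {
      out <- c(out, sprintf("%s: FIT FAILED - %s", m, f$message))
      next
    }
    fe <- f$fixed_effects
    for (i in seq_len(nrow(fe))) {
      out <- c(out, sprintf("%-28s %-15s %10.3f  (%.3f, %.3f)%s",
                            paste0(m, " (mean shift)"), lab[[fe$factor[i]]],
                            fe$estimate[i], fe$ci_low[i], fe$ci_high[i],
                            star(fe$significant[i])))
    }
  }
  out
}

#' Serialize a study analysis to the results JSON schema
#'
#' Schema: `{metrics: {<metric>: {<factor>: {estimate, se, ci_low, ci_high,
#' significant}}, ...}, accuracy: {<factor>: {log_odds, or, or_ci_low,
#' or_ci_high, significant}}, variances, n}`.
#'
#' @param analysis a [analyze_study()] result.
#' @param path optional output path; when given, the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
analysis_to_json <- function(analysis, path = NULL) {
  fe_block <- function(fe, cols) {
    out <- lapply(seq_len(nrow(fe)), function(i) as.list(fe[i, cols]))
    names(out) <- fe$factor
    out
  }
  variances <- list()
  metrics <- list()
  for (m in names(analysis$metrics)) {
    f <- analysis$metrics[[m]]
    if (isTRUE(f$failed)) {
      metrics[[m]] <- list(failed = TRUE, message = f$message)
    } else {
      metrics[[m]] <- fe_block(f$fixed_effects,
                               c("estimate", "se", "ci_low", "ci_high",
                                 "significant"))
      variances[[m]] <- list(
        participant_intercept = f$participant_intercept_variance,
        residual = f$residual_variance)
    }
  }
  acc <- analysis$accuracy
  accuracy <- if (isTRUE(acc$failed)) {
    list(failed = TRUE, message = acc$message)
  } else {
    variances$accuracy <- list(random_intercept = acc$random_intercept_variance)
    fe_block(acc$fixed_effects,
             c("log_odds", "se", "or", "or_ci_low", "or_ci_high",
               "significant"))
  }
  obj <- list(metrics = metrics, accuracy = accuracy, variances = variances,
              n = list(obs = analysis$n_obs,
                       participants = analysis$n_participants))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a results JSON file back into a list
#'
#' @param path path to a file written by [analysis_to_json()].
#' @return the parsed list.
#' @export
read_analysis_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
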