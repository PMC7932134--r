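#' Build a randomized full-factorial study design
#'
#' Each participant receives the full 2 x 2 x 2 cross of vibration type,
#' vibration intensity and skin thickness at each of 4 target locations
#' drawn without replacement from the 8 simulator positions, giving 32
#' trials per participant presented in randomized order. Deterministic
#' given the seed.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `trial_id`, `participant_id`,
#'   `vibration_type`, `vibration_intensity`, `skin_thickness_mm`,
#'   `location_index`, `target_x_mm`, `target_y_mm`, one row per trial.
#' @export
#' @examples
#' d <- build_design(12, seed = 1)
#' nrow(d)  # 384
build_design <- function(n_participants, seed = 1L) {
  if (length(n_participants) != 1L || is.na(n_participants) ||
      n_participants < 1L || n_participants != as.integer(n_participants)) {
    palp_error("n_participants must be a positive integer", "palp_domain_error")
  }
  n_participants <- as.integer(n_participants)
  with_seed(seed, {
    per <- lapply(seq_len(n_participants), function(j) {
      locs <- sample(8L, 4L)
      g <- expand.grid(vibration_type = c("pulse", "thrill"),
                       vibration_intensity = c("strong", "weak"),
                       skin_thickness_mm = c(4, 6),
                       location_index = locs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      g <- g[sample(nrow(g)), , drop = FALSE]
      g$participant_id <- sprintf("P%02d", j)
      g
    })
    d <- do.call(rbind, per)
  })
  d$trial_id <- sprintf("%s_T%02d", d$participant_id,
                        stats::ave(seq_len(nrow(d)), d$participant_id,
                                   FUN = seq_along))
  tp <- t(vapply(d$location_index, target_position, numeric(2L)))
  d$target_x_mm <- tp[, 1L]
  d$target_y_mm <- tp[, 2L]
  rownames(d) <- NULL
  d[c("trial_id", "participant_id", "vibration_type", "vibration_intensity",
      "skin_thickness_mm", "location_index", "target_x_mm", "target_y_mm")]
}

design_indicators <- function(design) {
  cbind(vibration_type = as.numeric(design$vibration_type == "thrill"),
        vibration_intensity = as.numeric(design$vibration_intensity == "weak"),
        skin_thickness = as.numeric(design$skin_thickness_mm == 6))
}

#' Simulate a per-trial metric table from the generative models
#'
#' Draws every metric directly from the models the analysis stage fits:
#' continuous metrics from the random-intercept linear model (participant
#' intercepts normal around the baseline, indicator-coded factor effects,
#' normal residual, clipped to the metric's valid range); continuous
#' accuracy from a gamma distribution whose mean depends on condition with
#' fixed shape; and the binary within-30 mm outcome from the logistic
#' random-intercept model. Deterministic given the seed.
#'
#' @param design a [build_design()] table.
#' @param params a [default_generator_params()] list.
#' @param seed integer seed.
#' @return the design with metric columns appended (`accuracy_mm`,
#'   `accuracy_band`, `accurate_binary`, `duration_s`, `tpl_mm`,
#'   `rcm_pct`, `error_rate`).
#' @export
simulate_metric_table <- function(design, params = default_generator_params(),
                                  seed = 1L) {
  validate_generator_params(params)
  ind <- design_indicators(design)
  pid <- factor(design$participant_id)
  nP <- nlevels(pid)
  n <- nrow(design)
  out <- design
  with_seed(seed, {
    for (m in names(params$metrics)) {
      p <- params$metrics[[m]]
      b_j <- rnorm(nP, 0, p$participant_sd)
      y <- p$baseline + b_j[as.integer(pid)] +
        as.numeric(ind %*% p$effects[colnames(ind)]) +
        rnorm(n, 0, p$residual_sd)
      out[[m]] <- pmin(pmax(y, p$lower), p$upper)
    }
    a <- params$accuracy
    mu <- a$mean_referent_mm + as.numeric(ind %*% a$mean_effects_mm[colnames(ind)])
    if (any(mu <= 0)) {
      palp_error("accuracy condition means must be positive", "palp_domain_error")
    }
    out$accuracy_mm <- rgamma(n, shape = a$gamma_shape,
                              scale = mu / a$gamma_shape)
    u_j <- rnorm(nP, 0, a$binary_participant_sd)
    eta <- a$binary_intercept + u_j[as.integer(pid)] +
      as.numeric(ind %*% a$binary_effects[colnames(ind)])
    out$accurate_binary <- rbinom(n, 1L, 1 / (1 + exp(-eta))) == 1L
  })
  out$accuracy_band <- as.character(classify_accuracy(out$accuracy_mm))
  out[c(names(design), "accuracy_mm", "accuracy_band", "accurate_binary",
        "duration_s", "tpl_mm", "rcm_pct", "error_rate")]
}

#' Simulate one fingertip trajectory trial
#'
#' A mechanistic stand-in for palpation behavior: the index fingertip
#' starts on an annulus about the workspace center (away from the target)
#' and performs a biased random walk whose in-plane velocity is
#' `gain * unit-vector-toward-noisy-target-estimate + isotropic noise`,
#' with a small sinusoidal z bobbing. The gain is scaled down for pulse
#' type, weak intensity and 6 mm skin, and multiplied by
#' `participant_skill`. The trial succeeds once the fingertip dwells
#' continuously inside the capture radius, and otherwise stops at timeout.
#' The middle fingertip tracks the index at a fixed in-plane offset.
#'
#' @param condition a [haptic_condition()].
#' @param target numeric `c(x, y)` mm; defaults to the condition's canonical
#'   [target_position()].
#' @param participant_skill multiplicative gain factor (1 = nominal).
#' @param params a [default_generator_params()] list.
#' @param seed integer seed.
#' @param trial_id,participant_id identifiers for the resulting trial.
#' @return a [palp_trial()].
#' @export
simulate_trajectory <- function(condition,
                                target = target_position(condition$location_index),
                                participant_skill = 1,
                                params = default_generator_params(),
                                seed = 1L,
                                trial_id = "sim_trial",
                                participant_id = "sim") {
  validate_generator_params(params)
  if (!inherits(condition, "haptic_condition")) {
    palp_error("condition must be a haptic_condition", "palp_domain_error")
  }
  tr <- params$trajectory
  gain <- tr$base_gain_mm_s * participant_skill
  if (condition$vibration_type == "pulse") gain <- gain * tr$gain_multiplier[["pulse"]]
  if (condition$vibration_intensity == "weak") gain <- gain * tr$gain_multiplier[["weak"]]
  if (condition$skin_thickness_mm == 6) gain <- gain * tr$gain_multiplier[["skin6mm"]]
  dt <- 1 / tr$frame_rate_hz
  n_max <- ceiling(tr$timeout_s / dt) + 1L
  dwell_frames <- max(1L, ceiling(tr$dwell_s / dt))
  tx <- target[[1L]]; ty <- target[[2L]]
  with_seed(seed, {
    # rejection-sample a start on the annulus, away from the target
    repeat {
      r <- sqrt(runif(1L, tr$start_annulus_mm[["inner"]]^2,
                      tr$start_annulus_mm[["outer"]]^2))
      th <- runif(1L, 0, 2 * pi)
      sx <- r * cos(th); sy <- r * sin(th)
      if (sqrt((sx - tx)^2 + (sy - ty)^2) >= tr$start_min_target_dist_mm) break
    }
    noise <- matrix(rnorm(2L * n_max, 0, tr$noise_sd_mm_s), n_max, 2L)
    est_noise <- matrix(rnorm(2L * n_max, 0, tr$estimate_noise_sd_mm), n_max, 2L)
    zn <- rnorm(n_max, 0, tr$z_noise_sd_mm)
    x <- numeric(n_max); y <- numeric(n_max)
    x[1L] <- sx; y[1L] <- sy
    inside <- 0L
    n_used <- n_max
    for (i in seq_len(n_max - 1L)) {
      ex <- tx + est_noise[i, 1L] - x[i]
      ey <- ty + est_noise[i, 2L] - y[i]
      ed <- sqrt(ex^2 + ey^2)
      if (ed > 0) { ux <- ex / ed; uy <- ey / ed } else { ux <- 0; uy <- 0 }
      x[i + 1L] <- x[i] + (gain * ux + noise[i, 1L]) * dt
      y[i + 1L] <- y[i] + (gain * uy + noise[i, 2L]) * dt
      d_true <- sqrt((x[i + 1L] - tx)^2 + (y[i + 1L] - ty)^2)
      inside <- if (d_true <= tr$capture_radius_mm) inside + 1L else 0L
      if (inside >= dwell_frames) { n_used <- i + 1L; break }
    }
    t_s <- (seq_len(n_used) - 1L) * dt
    z <- tr$z_rest_mm + tr$z_bob_amp_mm * sin(2 * pi * tr$z_bob_hz * t_s) +
      zn[seq_len(n_used)]
    frames <- data.frame(
      t_s = t_s,
      ix = x[seq_len(n_used)], iy = y[seq_len(n_used)], iz = z,
      mx = x[seq_len(n_used)] + tr$middle_offset_mm[[1L]],
      my = y[seq_len(n_used)] + tr$middle_offset_mm[[2L]],
      mz = z)
  })
  palp_trial(trial_id, participant_id, condition, c(tx, ty), frames)
}

#' Simulate a complete palpation study
#'
#' At `"metric"` fidelity the study is a design plus a directly drawn
#' metric table. At `"trajectory"` fidelity every trial is a simulated
#' fingertip trajectory and the metric table is derived from the
#' trajectories through the metrics engine, never drawn directly.
#' Per-trial sub-seeds are derived by counter from the study seed, so each
#' trial is individually reproducible.
#'
#' @param n_participants number of participants.
#' @param params a [default_generator_params()] list.
#' @param seed integer seed.
#' @param fidelity `"metric"` or `"trajectory"`.
#' @return list of class `palp_study`: `design`, `metric_table`,
#'   `fidelity`, `params`, `seed`, and (trajectory fidelity only) `trials`,
#'   a list of [palp_trial()] objects.
#' @export
simulate_study <- function(n_participants, params = default_generator_params(),
                           seed = 1L, fidelity = c("metric", "trajectory")) {
  fidelity <- match.arg(fidelity)
  validate_generator_params(params)
  design <- build_design(n_participants, seed = derive_seed(seed, 0L))
  if (fidelity == "metric") {
    tab <- simulate_metric_table(design, params, seed = derive_seed(seed, 1L))
    return(structure(list(design = design, metric_table = tab,
                          fidelity = fidelity, params = params, seed = seed),
                     class = "palp_study"))
  }
  pid <- factor(design$participant_id)
  skills <- with_seed(derive_seed(seed, 2L),
                      exp(rnorm(nlevels(pid), 0, params$trajectory$skill_sd_log)))
  trials <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    cond <- haptic_condition(row$vibration_type, row$vibration_intensity,
                             row$skin_thickness_mm, row$location_index)
    simulate_trajectory(cond,
                        target = c(row$target_x_mm, row$target_y_mm),
                        participant_skill = skills[as.integer(pid)[i]],
                        params = params,
                        seed = derive_seed(seed, 10L + i),
                        trial_id = row$trial_id,
                        participant_id = row$participant_id)
  })
  tab <- suppressWarnings(metrics_table(trials))
  tab <- merge(design, tab[setdiff(names(tab),
                                   c("participant_id", "vibration_type",
                                     "vibration_intensity", "skin_thickness_mm",
                                     "location_index"))],
               by = "trial_id", sort = FALSE)
  structure(list(design = design, metric_table = tab, trials = trials,
                 fidelity = fidelity, params = params, seed = seed),
            class = "palp_study")
}

#' Write a study bundle to disk
#'
#' Layout: `manifest.json` (array of trial records), `metrics.csv`, a
#' `params.json` copy of the generator constants, and, at trajectory
#' fidelity, `trials/<trial_id>.csv` frame files.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param force overwrite a non-empty directory.
#' @return invisibly, `dir`.
#' @export
write_study_bundle <- function(study, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !force) {
    palp_error(paste0("directory not empty (use force): ", dir), "palp_io_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- study$design
  if (!is.null(study$trials)) {
    dir.create(file.path(dir, "trials"), showWarnings = FALSE)
    manifest$frame_file <- file.path("trials", paste0(manifest$trial_id, ".csv"))
    for (tr in study$trials) {
      write_trial(tr, file.path(dir, "trials", paste0(tr$trial_id, ".csv")))
    }
  } else {
    manifest$frame_file <- NA_character_
  }
  writeLines(jsonlite::toJSON(manifest, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(dir, "manifest.json"))
  utils::write.csv(study$metric_table, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  write_generator_params(study$params, file.path(dir, "params.json"))
  invisible(dir)
}

#' Read the trials of a study bundle
#'
#' @param dir bundle directory containing `manifest.json` and `trials/`.
#' @return list with `manifest` (data.frame) and `trials` (list of
#'   [palp_trial()]); trials that fail validation are reported in
#'   `failures` and skipped.
#' @export
read_study_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    palp_error(paste0("no manifest.json in ", dir), "palp_io_error")
  }
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  trials <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[i, ])
    res <- tryCatch(read_trial(file.path(dir, entry$frame_file), entry),
                    palp_error = function(e) e)
    if (inherits(res, "palp_trial")) {
      trials[[entry$trial_id]] <- res
    } else {
      failures[[entry$trial_id]] <- conditionMessage(res)
    }
  }
  list(manifest = manifest, trials = trials, failures = failures)
}

#' Parameter-recovery study over simulated replicates
#'
#' Repeatedly simulates a metric-level study and refits the full analysis,
#' then summarizes, for every fixed effect of every model, the mean
#' estimate, bias against the generating value, empirical SD, Monte-Carlo
#' standard error of the mean, and 95% CI coverage. Per-replicate fit
#' failures are recorded, not fatal.
#'
#' @param replicates number of replicates (>= 2).
#' @param params generator parameters (also the recovery truth).
#' @param seed integer base seed; replicate r uses sub-seed `seed + r - 1`
#'   for design and draws.
#' @param n_participants participants per replicate.
#' @param nagq GLMM quadrature nodes.
#' @return list of class `recovery_report`: `summary` (data.frame with one
#'   row per model x factor), `or_summary` (odds-ratio scale for the
#'   accuracy model), `n_failed`, `replicates`.
#' @export
recovery_study <- function(replicates, params = default_generator_params(),
                           seed = 1L, n_participants = 12L, nagq = 15L) {
  if (length(replicates) != 1L || is.na(replicates) || replicates < 2L) {
    palp_error("replicates must be >= 2", "palp_domain_error")
  }
  validate_generator_params(params)
  factor_names <- names(factor_terms)
  est <- list(); cover <- list()
  or_est <- matrix(NA_real_, replicates, 3L,
                   dimnames = list(NULL, factor_names))
  log_odds_est <- or_est
  or_cover <- or_est
  for (m in c(names(params$metrics))) {
    est[[m]] <- matrix(NA_real_, replicates, 3L,
                       dimnames = list(NULL, factor_names))
    cover[[m]] <- est[[m]]
  }
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    rs <- as.integer(seed) + r - 1L
    design <- build_design(n_participants, seed = rs)
    tab <- simulate_metric_table(design, params, seed = derive_seed(rs, 1L))
    an <- analyze_study(tab, nagq = nagq)
    any_fail <- FALSE
    for (m in names(params$metrics)) {
      f <- an$metrics[[m]]
      if (isTRUE(f$failed)) { any_fail <- TRUE; next }
      truth <- params$metrics[[m]]$effects
      fe <- f$fixed_effects
      est[[m]][r, fe$factor] <- fe$estimate
      cover[[m]][r, fe$factor] <-
        as.numeric(fe$ci_low <= truth[fe$factor] &
                     truth[fe$factor] <= fe$ci_high)
    }
    if (!isTRUE(an$accuracy$failed)) {
      fe <- an$accuracy$fixed_effects
      log_odds_est[r, fe$factor] <- fe$log_odds
      or_est[r, fe$factor] <- fe$or
      truth <- params$accuracy$binary_effects
      or_cover[r, fe$factor] <-
        as.numeric(fe$ci_low <= truth[fe$factor] &
                     truth[fe$factor] <= fe$ci_high)
    } else any_fail <- TRUE
    if (any_fail) n_failed <- n_failed + 1L
  }
  summarize <- function(mat, truth, cov) {
    do.call(rbind, lapply(colnames(mat), function(fc) {
      x <- mat[, fc]
      ok <- is.finite(x)
      data.frame(factor = fc, truth = unname(truth[fc]),
                 mean_estimate = mean(x[ok]),
                 bias = mean(x[ok]) - unname(truth[fc]),
                 empirical_sd = sd(x[ok]),
                 mc_se = sd(x[ok]) / sqrt(sum(ok)),
                 coverage = mean(cov[ok, fc]),
                 n_fits = sum(ok),
                 stringsAsFactors = FALSE)
    }))
  }
  summary <- do.call(rbind, lapply(names(params$metrics), function(m) {
    s <- summarize(est[[m]], params$metrics[[m]]$effects, cover[[m]])
    cbind(data.frame(model = m, stringsAsFactors = FALSE), s)
  }))
  s_lo <- summarize(log_odds_est, params$accuracy$binary_effects, or_cover)
  summary <- rbind(summary,
                   cbind(data.frame(model = "accuracy_log_odds",
                                    stringsAsFactors = FALSE), s_lo))
  or_summary <- summarize(or_est, exp(params$accuracy$binary_effects), or_cover)
  rownames(summary) <- NULL
  rownames(or_summary) <- NULL
  structure(list(summary = summary, or_summary = or_summary,
                 n_failed = n_failed, replicates = replicates,
                 n_participants = n_participants, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates, %d participants, %d failed\n",
              x$replicates, x$n_participants, x$n_failed))
  print(x$summary, digits = 4)
  cat("accuracy model, odds-ratio scale:\n")
  print(x$or_summary, digits = 4)
  invisible(x)
}
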