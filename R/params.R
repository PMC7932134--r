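#' Default generator parameters for synthetic palpation studies
#'
#' All constants of the two generative models, in one inspectable list.
#'
#' Metric-level model: each continuous metric is
#' `baseline (referent cell: pulse / strong / 4 mm) + participant intercept
#' (normal, SD `participant_sd`) + factor effects (indicator coded) +
#' normal residual`, clipped to its valid range. The factor effects default
#' to the published mean shifts (duration -6.20 / +10.36 / +6.20 s; TPL
#' -221.9 / +501.9 / +491.4 mm; RCM 0 / -1.08 / -1.17 points; error rate
#' all 0). Baselines and variance components are not published and are
#' explicit package choices (see the methods vignette).
#'
#' Accuracy: continuous accuracy is gamma with fixed shape (default 2) and
#' condition-dependent mean, additive around 23.2 mm with marginal means
#' strong 22.5 / weak 23.9 and 4 mm 21.8 / 6 mm 24.6. The binary
#' within-30 mm outcome follows a logistic model with participant random
#' intercept; the vibration-type log-odds defaults to log(1.61).
#'
#' Trajectory-level model: a biased random walk at `frame_rate_hz` whose
#' in-plane velocity is `gain * unit-vector-toward-noisy-target-estimate +
#' noise`; the gain shrinks multiplicatively for pulse type, weak intensity
#' and 6 mm skin, so harder conditions take longer, travel farther and
#' track the target less well. A trial ends after `dwell_s` continuously
#' inside `capture_radius_mm` of the target, or at `timeout_s`.
#'
#' @return a named list of class `generator_params`.
#' @export
#' @examples
#' p <- default_generator_params()
#' p$metrics$duration_s$effects
default_generator_params <- function() {
  structure(list(
    metrics = list(
      duration_s = list(baseline = 25,
                        effects = c(vibration_type = -6.20,
                                    vibration_intensity = 10.36,
                                    skin_thickness = 6.20),
                        participant_sd = 4, residual_sd = 8,
                        lower = 0.001, upper = Inf),
      tpl_mm = list(baseline = 1200,
                    effects = c(vibration_type = -221.9,
                                vibration_intensity = 501.9,
                                skin_thickness = 491.4),
                    participant_sd = 150, residual_sd = 450,
                    lower = 0.001, upper = Inf),
      rcm_pct = list(baseline = 52,
                     effects = c(vibration_type = 0,
                                 vibration_intensity = -1.08,
                                 skin_thickness = -1.17),
                     participant_sd = 1.5, residual_sd = 2.6,
                     lower = 0, upper = 100),
      error_rate = list(baseline = 0.28,
                        effects = c(vibration_type = 0,
                                    vibration_intensity = 0,
                                    skin_thickness = 0),
                        participant_sd = 0.05, residual_sd = 0.12,
                        lower = 0, upper = 1)
    ),
    accuracy = list(
      gamma_shape = 2,
      # referent-cell mean and additive level shifts: 23.2 overall,
      # strong 22.5 / weak 23.9, 4 mm 21.8 / 6 mm 24.6 marginal means
      mean_referent_mm = 21.1,
      mean_effects_mm = c(vibration_type = 0,
                          vibration_intensity = 1.4,
                          skin_thickness = 2.8),
      binary_intercept = 0.975,
      binary_effects = c(vibration_type = log(1.61),
                         vibration_intensity = log(0.8),
                         skin_thickness = log(0.8)),
      binary_participant_sd = 0.5
    ),
    trajectory = list(
      frame_rate_hz = 60,
      base_gain_mm_s = 14,
      gain_multiplier = c(pulse = 0.75, weak = 0.65, skin6mm = 0.7),
      noise_sd_mm_s = 30,
      estimate_noise_sd_mm = 15,
      capture_radius_mm = 8,
      dwell_s = 0.5,
      timeout_s = 90,
      start_annulus_mm = c(inner = 30, outer = 80),
      start_min_target_dist_mm = 30,
      z_rest_mm = 2, z_bob_amp_mm = 1.5, z_bob_hz = 1.2, z_noise_sd_mm = 0.2,
      middle_offset_mm = c(20, 0),
      skill_sd_log = 0.2
    )
  ), class = "generator_params")
}

validate_generator_params <- function(params) {
  if (!is.list(params)) {
    palp_error("params must be a generator_params list", "palp_domain_error")
  }
  for (m in names(params$metrics)) {
    p <- params$metrics[[m]]
    if (p$participant_sd < 0 || p$residual_sd < 0) {
      palp_error(paste0(m, ": SDs must be >= 0"), "palp_domain_error")
    }
  }
  a <- params$accuracy
  if (a$gamma_shape <= 0) {
    palp_error("gamma_shape must be > 0", "palp_domain_error")
  }
  if (a$binary_participant_sd < 0) {
    palp_error("binary_participant_sd must be >= 0", "palp_domain_error")
  }
  tr <- params$trajectory
  for (nm in c("frame_rate_hz", "base_gain_mm_s", "capture_radius_mm",
               "dwell_s", "timeout_s")) {
    if (tr[[nm]] <= 0) {
      palp_error(paste0("trajectory$", nm, " must be > 0"), "palp_domain_error")
    }
  }
  if (tr$noise_sd_mm_s < 0 || tr$estimate_noise_sd_mm < 0) {
    palp_error("trajectory noise SDs must be >= 0", "palp_domain_error")
  }
  invisible(params)
}

#' Read or write generator parameters as JSON
#'
#' Round-trips [default_generator_params()]-shaped lists through a plain
#' JSON config file so a study bundle records the exact constants that
#' produced it.
#'
#' @param path file path.
#' @return `read_generator_params()` returns a `generator_params` list.
#' @export
read_generator_params <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p <- default_generator_params()
  for (sec in intersect(names(raw), names(p))) {
    for (k in intersect(names(raw[[sec]]), names(p[[sec]]))) {
      v <- raw[[sec]][[k]]
      if (is.list(p[[sec]][[k]]) && is.list(v)) {
        for (kk in intersect(names(v), names(p[[sec]][[k]]))) {
          tmpl <- p[[sec]][[k]][[kk]]
          vv <- v[[kk]]
          if (!is.null(names(tmpl))) vv <- setNames(unlist(vv), names(tmpl))
          p[[sec]][[k]][[kk]] <- vv
        }
      } else {
        if (!is.null(names(p[[sec]][[k]]))) v <- setNames(unlist(v), names(p[[sec]][[k]]))
        p[[sec]][[k]] <- v
      }
    }
  }
  validate_generator_params(p)
}

#' @rdname read_generator_params
#' @param params a `generator_params` list.
#' @export
write_generator_params <- function(params, path) {
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
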