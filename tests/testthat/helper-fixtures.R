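# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

ref_condition <- function(location_index = 1L) {
  haptic_condition("pulse", "strong", 4, location_index)
}

# Trial from bare index-fingertip coordinates; middle finger rides at a
# +20 mm x offset unless given explicitly.
make_trial <- function(t, ix, iy, iz = rep(0, length(t)),
                       mx = ix + 20, my = iy, mz = iz,
                       target = c(0, 0), condition = ref_condition(),
                       trial_id = "T1", participant_id = "P1") {
  palp_trial(trial_id, participant_id, condition, target,
             data.frame(t_s = t, ix = ix, iy = iy, iz = iz,
                        mx = mx, my = my, mz = mz))
}

# Random valid trial: sorted distinct timestamps, bounded smooth-ish jitter.
random_trial <- function(seed, n_frames = NULL) {
  set.seed(seed)
  n <- n_frames %||% sample(5:40, 1L)
  t <- cumsum(runif(n, 0.005, 0.1))
  base <- matrix(rnorm(3L * n, 0, 15), n, 3L)
  make_trial(t,
             ix = base[, 1L], iy = base[, 2L], iz = abs(base[, 3L]) / 3,
             target = c(runif(1, -40, 40), runif(1, -40, 40)),
             condition = haptic_condition(
               sample(c("pulse", "thrill"), 1L),
               sample(c("strong", "weak"), 1L),
               sample(c(4, 6), 1L),
               sample(8L, 1L)),
             trial_id = sprintf("T%03d", seed),
             participant_id = sprintf("P%02d", 1L + seed %% 7L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# In-plane rotation of a whole trial (both fingertips) and its target about
# the z axis, preserving z.
rotate_trial <- function(trial, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  fr <- trial$frames
  ip <- cbind(fr$ix, fr$iy) %*% t(R)
  mp <- cbind(fr$mx, fr$my) %*% t(R)
  tg <- as.numeric(R %*% trial$target)
  palp_trial(trial$trial_id, trial$participant_id, trial$condition, tg,
             data.frame(t_s = fr$t_s, ix = ip[, 1L], iy = ip[, 2L], iz = fr$iz,
                        mx = mp[, 1L], my = mp[, 2L], mz = fr$mz))
}

translate_trial <- function(trial, dx, dy) {
  fr <- trial$frames
  palp_trial(trial$trial_id, trial$participant_id, trial$condition,
             trial$target + c(dx, dy),
             data.frame(t_s = fr$t_s, ix = fr$ix + dx, iy = fr$iy + dy,
                        iz = fr$iz, mx = fr$mx + dx, my = fr$my + dy,
                        mz = fr$mz))
}

reverse_trial <- function(trial) {
  fr <- trial$frames[rev(seq_len(nrow(trial$frames))), ]
  fr$t_s <- max(trial$frames$t_s) - fr$t_s
  palp_trial(trial$trial_id, trial$participant_id, trial$condition,
             trial$target, fr)
}

# Small metric table drawn at defaults, cached per session for model tests.
small_metric_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- build_design(12, seed = 42)
      cache <<- simulate_metric_table(d, seed = 43)
    }
    cache
  }
})
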