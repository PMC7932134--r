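test_that("estimate_velocity is exact on linear and quadratic motion", {
  # uniform motion x = 5 t
  t <- seq(0, 2, by = 0.1)
  tr <- make_trial(t, ix = 5 * t, iy = rep(0, length(t)))
  v <- estimate_velocity(tr, "index")
  expect_equal(v[, "vx"], rep(5, length(t)), tolerance = 1e-12)
  expect_equal(v[, "vy"], rep(0, length(t)), tolerance = 1e-12)

  # stationary
  tr0 <- make_trial(t, ix = rep(3, length(t)), iy = rep(-2, length(t)))
  expect_true(all(estimate_velocity(tr0, "index") == 0))

  # x = t^2: central differences are exact for quadratics on a uniform grid
  tr2 <- make_trial(t, ix = t^2, iy = rep(0, length(t)))
  v2 <- estimate_velocity(tr2, "index")
  interior <- 2:(length(t) - 1)
  expect_equal(v2[interior, "vx"], 2 * t[interior], tolerance = 1e-10)

  # middle finger has its own series
  trm <- make_trial(t, ix = rep(0, length(t)), iy = rep(0, length(t)),
                    mx = 5 * t, my = rep(1, length(t)))
  expect_equal(estimate_velocity(trm, "middle")[, "vx"], rep(5, length(t)),
               tolerance = 1e-12)
})

test_that("duration is the first-to-last time span, translation invariant", {
  tr <- make_trial(c(0, 4, 12.5), ix = c(0, 1, 2), iy = c(0, 0, 0))
  expect_equal(compute_duration(tr), 12.5)
  fr <- tr$frames; fr$t_s <- fr$t_s + 100
  tr2 <- palp_trial("t", "p", ref_condition(), tr$target, fr)
  expect_equal(compute_duration(tr2), 12.5)
})

test_that("TPL sums segment lengths and dominates net displacement", {
  tr <- make_trial(c(0, 1), ix = c(0, 3), iy = c(0, 4))
  expect_equal(compute_tpl(tr), 5)
  # out and back: A -> B -> A
  trb <- make_trial(c(0, 1, 2), ix = c(0, 3, 0), iy = c(0, 4, 0))
  expect_equal(compute_tpl(trb), 10)
  # triangle inequality on random paths
  for (s in 1:25) {
    tr <- random_trial(s, n_frames = 100)
    fr <- tr$frames
    net <- sqrt((fr$ix[100] - fr$ix[1])^2 + (fr$iy[100] - fr$iy[1])^2 +
                  (fr$iz[100] - fr$iz[1])^2)
    expect_gte(compute_tpl(tr), net)
  }
  # concatenation: TPL(a + b) = TPL(a) + TPL(b) + connecting segment
  a <- random_trial(1, n_frames = 20)
  b <- random_trial(2, n_frames = 20)
  fb <- b$frames; fb$t_s <- fb$t_s + max(a$frames$t_s) + 0.01
  joined <- palp_trial("j", "p", a$condition, a$target, rbind(a$frames, fb))
  conn <- sqrt(sum((unlist(fb[1, c("ix", "iy", "iz")]) -
                      unlist(a$frames[20, c("ix", "iy", "iz")]))^2))
  expect_equal(compute_tpl(joined), compute_tpl(a) + compute_tpl(b) + conn,
               tolerance = 1e-9)
})

test_that("accuracy takes the in-plane min over fingers at the final frame", {
  # index ends on the target
  tr <- make_trial(c(0, 1), ix = c(30, 0), iy = c(0, 0), target = c(0, 0))
  expect_equal(compute_accuracy(tr), 0)
  # index 12 mm off, middle 7 mm off -> 7
  tr2 <- make_trial(c(0, 1), ix = c(30, 12), iy = c(0, 0),
                    mx = c(50, 7), my = c(0, 0), target = c(0, 0))
  expect_equal(compute_accuracy(tr2), 7)
  # z displacement does not count
  tr3 <- make_trial(c(0, 1), ix = c(30, 0), iy = c(0, 0), iz = c(0, 25),
                    mx = c(60, 60), my = c(0, 0), target = c(0, 0))
  expect_equal(compute_accuracy(tr3), 0)
})

test_that("accuracy bands use closed inner boundaries", {
  b <- classify_accuracy(c(0, 10, 10.0001, 23.2, 30, 30.0001, 100))
  expect_equal(as.character(b),
               c("accurate", "accurate", "marginal", "marginal", "marginal",
                 "error", "error"))
  expect_error(classify_accuracy(-1), class = "palp_domain_error")
})

test_that("project_velocity is the signed approach speed", {
  expect_equal(project_velocity(c(10, 0), c(-5, 0), c(0, 0)), 5)
  expect_equal(project_velocity(c(10, 0), c(0, 7), c(0, 0)), 0)
  expect_equal(project_velocity(c(10, 0), c(3, 0), c(0, 0)), -3)
  expect_error(project_velocity(c(0, 0), c(1, 0), c(0, 0)),
               class = "palp_undefined_direction")

  # equivalence: -d/dt distance(t) == projected velocity, on an analytic path
  pos_fun <- function(t) c(30 * cos(t) + 5 * t, 20 * sin(t))
  vel_fun <- function(t) c(-30 * sin(t) + 5, 20 * cos(t))
  target <- c(4, -3)
  for (t in seq(0.2, 3, by = 0.4)) {
    h <- 1e-6
    dist <- function(tt) sqrt(sum((pos_fun(tt) - target)^2))
    ddist <- (dist(t + h) - dist(t - h)) / (2 * h)
    expect_equal(project_velocity(pos_fun(t), vel_fun(t), target), -ddist,
                 tolerance = 1e-6)
  }
})

test_that("RCM matches its definition and brute-force recount", {
  # straight run onto the target
  t <- seq(0, 1, by = 0.02)
  tr <- make_trial(t, ix = 50 * (1 - t), iy = rep(0, length(t)),
                   target = c(0, 0))
  expect_equal(compute_rcm(tr), 100)
  # straight run away
  tra <- make_trial(t, ix = 10 + 50 * t, iy = rep(0, length(t)),
                    target = c(0, 0))
  expect_equal(compute_rcm(tra), 0)

  # naive frame-by-frame recount on random trials
  naive_rcm <- function(trial, eps = 1) {
    v <- estimate_velocity(trial, "index")
    n_mov <- 0L; n_cor <- 0L
    for (i in seq_len(nrow(trial$frames))) {
      p <- c(trial$frames$ix[i], trial$frames$iy[i], trial$frames$iz[i])
      speed <- sqrt(sum(v[i, ]^2))
      d <- sqrt(sum((p[1:2] - trial$target)^2))
      if (speed >= eps && d > 0) {
        n_mov <- n_mov + 1L
        if (project_velocity(p, v[i, ], trial$target) > 0) n_cor <- n_cor + 1L
      }
    }
    if (n_mov == 0L) return(NA_real_)
    100 * n_cor / n_mov
  }
  for (s in c(3, 11, 29)) {
    tr <- random_trial(s, n_frames = 50)
    expect_identical(compute_rcm(tr), naive_rcm(tr))
  }
})

test_that("error rate matches manual counts and supports both denominators", {
  t <- seq(0, 1, by = 0.1)  # 11 frames, all moving at 100 mm/s
  x <- seq(100, 0, by = -10)
  tr <- make_trial(t, ix = x, iy = rep(0, 11), target = c(0, 0))
  # frames with distance > 30: x in {100,...,40} -> 7; the final frame sits
  # exactly on the target, so it is excluded from the movement denominator
  # (10) but kept by the all-frames denominator (11)
  expect_equal(compute_error_rate(tr), 7 / 10)
  expect_equal(compute_error_rate(tr, denominator = "all"), 7 / 11)

  inside <- make_trial(c(0, 0.5, 1), ix = c(10, 5, 0), iy = c(0, 0, 0),
                       target = c(0, 0))
  expect_equal(compute_error_rate(inside), 0)
  outside <- make_trial(c(0, 0.5, 1), ix = c(90, 80, 70), iy = c(0, 0, 0),
                        target = c(0, 0))
  expect_equal(compute_error_rate(outside), 1)

  naive_er <- function(trial, eps = 1) {
    v <- estimate_velocity(trial, "index")
    keep <- sqrt(rowSums(v^2)) >= eps &
      sqrt((trial$frames$ix - trial$target[1])^2 +
             (trial$frames$iy - trial$target[2])^2) > 0
    d <- sqrt((trial$frames$ix - trial$target[1])^2 +
                (trial$frames$iy - trial$target[2])^2)
    sum(d[keep] > 30) / sum(keep)
  }
  for (s in c(5, 17)) {
    tr <- random_trial(s, n_frames = 50)
    expect_identical(compute_error_rate(tr), naive_er(tr))
  }
})

test_that("undefined frame-ratio metrics come back as NA with a classed warning", {
  t <- seq(0, 1, by = 0.1)
  still <- make_trial(t, ix = rep(5, 11), iy = rep(5, 11), target = c(0, 0))
  expect_warning(r <- compute_rcm(still), class = "palp_undefined_metric")
  expect_true(is.na(r))
  expect_warning(e <- compute_error_rate(still), class = "palp_undefined_metric")
  expect_true(is.na(e))
  m <- suppressWarnings(compute_metrics(still))
  expect_true(is.na(m$rcm_pct) && is.na(m$error_rate))
  expect_false(is.na(m$accuracy_mm))
})

test_that("all five metrics are invariant to rigid in-plane motions", {
  for (s in c(2, 9, 21)) {
    tr <- random_trial(s, n_frames = 60)
    m0 <- suppressWarnings(compute_metrics(tr))
    for (variant in list(rotate_trial(tr, 1.1),
                         translate_trial(tr, 13.5, -8.2),
                         translate_trial(rotate_trial(tr, -2.4), 4, 4))) {
      m1 <- suppressWarnings(compute_metrics(variant))
      for (f in c("accuracy_mm", "duration_s", "tpl_mm", "rcm_pct",
                  "error_rate")) {
        expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9)
      }
      expect_identical(m1$accuracy_band, m0$accuracy_band)
    }
  }
})

test_that("time reversal maps RCM to 100 - RCM when no projection is zero", {
  for (s in c(4, 13, 31)) {
    tr <- random_trial(s, n_frames = 40)
    v <- estimate_velocity(tr, "index")
    k_moving <- sqrt(rowSums(v^2)) >= 1
    vp <- vapply(seq_len(nrow(v)), function(i) {
      project_velocity(c(tr$frames$ix[i], tr$frames$iy[i]), v[i, ], tr$target)
    }, numeric(1))
    # reversal negates every estimated velocity only up to the one-sided end
    # stencils; restrict the claim to trials whose moving-frame projections
    # are bounded away from zero
    if (any(abs(vp[k_moving]) < 1e-6)) next
    expect_equal(compute_rcm(reverse_trial(tr)), 100 - compute_rcm(tr),
                 tolerance = 1e-9)
  }
})

test_that("compute_metrics keeps band, binary and field consistency", {
  for (s in 1:40) {
    tr <- random_trial(s)
    m <- suppressWarnings(compute_metrics(tr))
    expect_identical(m$accuracy_band,
                     as.character(classify_accuracy(m$accuracy_mm)))
    expect_identical(m$accurate_binary, m$accuracy_mm <= 30)
    expect_gte(m$accuracy_mm, 0)
    expect_gt(m$duration_s, 0)
    fr <- tr$frames; n <- nrow(fr)
    net <- sqrt((fr$ix[n] - fr$ix[1])^2 + (fr$iy[n] - fr$iy[1])^2 +
                  (fr$iz[n] - fr$iz[1])^2)
    expect_gte(m$tpl_mm, net - 1e-9)
    if (!is.na(m$rcm_pct)) {
      expect_gte(m$rcm_pct, 0); expect_lte(m$rcm_pct, 100)
    }
    if (!is.na(m$error_rate)) {
      expect_gte(m$error_rate, 0); expect_lte(m$error_rate, 1)
    }
  }
})

test_that("a wandering path can end on target: accuracy 0, TPL large", {
  t <- seq(0, 2, by = 0.05)
  tr <- make_trial(t, ix = 40 * sin(7 * t) * (2 - t) / 2,
                   iy = 40 * cos(5 * t) * (2 - t) / 2 - 40 * cos(10),
                   target = c(0, -40 * cos(10)))
  m <- compute_metrics(tr)
  expect_lt(m$accuracy_mm, 1)
  expect_gt(m$tpl_mm, 3 * sqrt(sum((unlist(tr$frames[1, c("ix", "iy")]) -
                                      tr$target)^2)))
})
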