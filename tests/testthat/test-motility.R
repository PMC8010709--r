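test_that("a clean staircase is recovered exactly", {
  tr <- make_staircase(n_steps = 10, size = 1.0, dwell = 1.0)
  sd_series <- detect_steps(tr)
  expect_length(sd_series$step_sizes, 10)
  expect_equal(sd_series$step_sizes, rep(1.0, 10), tolerance = 1e-9)
  expect_equal(sd_series$dwell_times, rep(1.0, 9), tolerance = 1e-6)
})

test_that("detected steps conserve the net plateau displacement", {
  tr <- gen_motility_trace(trace_gen_config(duration = 30, seed = 9))
  s <- detect_steps(tr)
  net <- s$plateau_levels[length(s$plateau_levels)] - s$plateau_levels[1]
  expect_equal(sum(s$step_sizes), net, tolerance = 1e-9)
})

test_that("noisy 1-nm staircases are recovered with high recall", {
  hits <- 0L; total <- 0L; errs <- c()
  for (s in 1:5) {
    tr <- gen_motility_trace(trace_gen_config(
      duration = 60, step_sizes = data.frame(size_nm = 1, weight = 1),
      back_step_prob = 0.35, noise_sd = 0.3, sample_rate = 1000, seed = s))
    truth <- attr(tr, "truth")
    det <- detect_steps(tr)
    m <- match_steps(truth$step_times, det$step_times)
    hits <- hits + m[1]; total <- total + m[2]
    for (i in seq_along(det$step_times)) {
      j <- which.min(abs(truth$step_times - det$step_times[i]))
      if (abs(truth$step_times[j] - det$step_times[i]) <= 0.15)
        errs <- c(errs, abs(det$step_sizes[i] - truth$step_sizes[j]))
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(mean(errs), 0.1)
})

test_that("flat noise produces almost no false steps", {
  fp <- vapply(1:5, function(s) {
    tr <- gen_motility_trace(trace_gen_config(
      duration = 100, dwell_mean = 1e9, noise_sd = 0.3, sample_rate = 1000,
      seed = s))
    length(detect_steps(tr)$step_times)
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("step-size mixture fits recover their generating distribution", {
  set.seed(21)
  # single forward Gaussian at 1 nm: fundamental recovered, 2x weight ~ 0
  x1 <- rnorm(500, 1, 0.15)
  f1 <- fit_step_sizes(x1)
  expect_equal(f1$forward$mean1, 1.0, tolerance = 0.05)
  expect_lt(f1$forward$weight2, 0.1)
  expect_equal(f1$reverse_fraction, 0)
  # 80/20 mixture of 1 and 2 nm at n = 1000
  n2 <- rbinom(1, 1000, 0.2)
  x2 <- c(rnorm(1000 - n2, 1, 0.12), rnorm(n2, 2, 0.12))
  f2 <- fit_step_sizes(x2)
  expect_equal(f2$forward$weight2, n2 / 1000, tolerance = 0.05)
  expect_equal(f2$forward$mean1, 1.0, tolerance = 0.05)
  # sign split is pure counting
  x3 <- c(rnorm(650, 1, 0.1), -rnorm(350, 1, 0.1))
  expect_equal(fit_step_sizes(x3)$reverse_fraction, 0.35)
  expect_error(fit_step_sizes(rnorm(5, 1)), "at least 20")
})

test_that("dwell-time MLE is consistent and censoring-aware", {
  set.seed(31)
  x <- rexp(1e4, 1 / 0.75)
  f <- fit_dwell_times(x)
  expect_equal(f$tau, 0.75, tolerance = 0.03)
  expect_equal(f$se, f$tau / sqrt(1e4), tolerance = 1e-9)
  # identical dwells: MLE is the sample mean
  expect_equal(fit_dwell_times(rep(0.4, 50))$tau, 0.4)
  # right censoring at 1.5 s: censored MLE unbiased, naive mean biased low
  xc <- pmin(x, 1.5)
  fc <- fit_dwell_times(xc, censor_limit = 1.5)
  expect_lt(abs(fc$tau - 0.75), 3 * fc$se)
  expect_lt(mean(xc), 0.75 - 3 * sd(xc) / sqrt(length(xc)))
  expect_gt(fc$n_censored, 0)
  expect_error(fit_dwell_times(rexp(5, 1)), "at least 10")
})

test_that("dead-time correction removes missed-event bias", {
  # observed interval mean is tau * exp(c / tau) when dwells < c merge
  set.seed(41)
  tau <- 0.75; cc <- 0.05
  d <- rexp(4e4, 1 / tau)
  obs <- c(); acc <- 0
  for (v in d) {
    if (v < cc) { acc <- acc + v } else { obs <- c(obs, v + acc); acc <- 0 }
  }
  # oracle check of the inflation formula itself
  expect_equal(mean(obs), tau * exp(cc / tau), tolerance = 0.02)
  f <- fit_dwell_times(obs, dead_time = cc)
  expect_lt(abs(f$tau - tau), 3 * f$se)
})

test_that("trace velocity is the regression slope", {
  tt <- seq(0, 100, by = 0.05)
  tr <- motility_trace(tt, 0.25 * tt)
  expect_equal(trace_velocity(tr)$v, 0.25, tolerance = 1e-12)
  st <- make_staircase(n_steps = 20, size = 1, dwell = 1)
  v <- trace_velocity(st)$v
  net <- st$position[length(st$position)] - st$position[1]
  expect_equal(v, net / (max(st$time) - min(st$time)), tolerance = 0.2)
})

test_that("commitment classification follows the 10-s motility rule", {
  # long monotone staircase: committed
  tr <- gen_motility_trace(trace_gen_config(
    duration = 600, sample_rate = 100, back_step_prob = 0, noise_sd = 0.3,
    seed = 2))
  lab <- classify_commitment(tr)
  expect_identical(lab$state, "committed")
  expect_gte(lab$motile_duration, 10)
  # 100-nm excursions returning to baseline before motility: unstable
  tr_u <- gen_motility_trace(trace_gen_config(
    duration = 120, sample_rate = 100, spike_amplitude = 100, noise_sd = 0.3,
    back_step_prob = 0, seed = 3))
  lab_u <- classify_commitment(tr_u)
  expect_identical(lab_u$state, "unstable")
  expect_gte(lab_u$max_excursion, 50)
  # flat noise: no binding
  tr_0 <- gen_motility_trace(trace_gen_config(
    duration = 60, sample_rate = 100, dwell_mean = 1e9, noise_sd = 0.3,
    seed = 4))
  expect_identical(classify_commitment(tr_0)$state, "no_binding")
})

test_that("commitment classification ignores constant offsets", {
  tr <- gen_motility_trace(trace_gen_config(
    duration = 120, sample_rate = 100, back_step_prob = 0, noise_sd = 0.3,
    seed = 6))
  shifted <- motility_trace(tr$time, tr$position + 500, tr$sample_rate)
  expect_identical(classify_commitment(tr)$state,
                   classify_commitment(shifted)$state)
})

test_that("instability fractions reproduce the printed percentages", {
  mk <- function(state) structure(list(state = state, motile_duration = 0,
                                       max_excursion = 0),
                                  class = "commitment_label")
  lab17 <- c(replicate(2, mk("unstable"), simplify = FALSE),
             replicate(15, mk("committed"), simplify = FALSE))
  expect_equal(round(instability_summary(lab17)$fraction_unstable * 100), 12)
  lab13 <- c(replicate(3, mk("unstable"), simplify = FALSE),
             replicate(10, mk("committed"), simplify = FALSE))
  expect_equal(round(instability_summary(lab13)$fraction_unstable * 100), 23)
  lab0 <- replicate(5, mk("committed"), simplify = FALSE)
  expect_equal(instability_summary(lab0)$fraction_unstable, 0)
  expect_error(instability_summary(list()), "empty")
})
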