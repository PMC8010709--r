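test_that("generators are pure functions of their seed", {
  c1 <- trace_gen_config(duration = 5, seed = 42)
  expect_identical(gen_motility_trace(c1)$position,
                   gen_motility_trace(c1)$position)
  r1 <- rupture_gen_config(n_events = 50, seed = 42)
  expect_identical(gen_rupture_events(r1)$lifetime,
                   gen_rupture_events(r1)$lifetime)
  x1 <- gen_xrd_pattern(data.frame(two_theta = 20, height = 10, fwhm = 1),
                        noise_sd = 0.2, seed = 42)
  x2 <- gen_xrd_pattern(data.frame(two_theta = 20, height = 10, fwhm = 1),
                        noise_sd = 0.2, seed = 42)
  expect_identical(x1$intensity, x2$intensity)
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(gen_motility_trace(c1))
  expect_identical(.Random.seed, before)
})

test_that("trace generator config is validated", {
  expect_error(trace_gen_config(dwell_mean = 0), "dwell_mean")
  expect_error(trace_gen_config(sample_rate = -1), "sample_rate")
  expect_error(trace_gen_config(back_step_prob = 1.2), "back_step_prob")
  expect_error(trace_gen_config(
    step_sizes = data.frame(size_nm = 1, weight = 0.7)), "sum to 1")
})

test_that("noise-free forward staircase moves at the renewal rate", {
  cfg <- trace_gen_config(dwell_mean = 0.5,
                          step_sizes = data.frame(size_nm = 1, weight = 1),
                          back_step_prob = 0, noise_sd = 0, sample_rate = 100,
                          duration = 400, seed = 3)
  tr <- gen_motility_trace(cfg)
  v <- trace_velocity(tr)$v
  # renewal mean rate 1 step / 0.5 s = 2 nm/s; MC SE of the mean rate over
  # ~800 steps is ~ 2/sqrt(800)
  expect_lt(abs(v - 2), 3 * 2 / sqrt(400 / 0.5))
})

test_that("back-stepping scales the expected net velocity", {
  # E[v] = (1 - 2 p_back) * E[step] / dwell_mean = (1 - 0.7) * 1 / 0.75
  v_true <- (1 - 2 * 0.35) * 1 / 0.75
  vs <- vapply(1:6, function(s) {
    cfg <- trace_gen_config(dwell_mean = 0.75,
                            step_sizes = data.frame(size_nm = 1, weight = 1),
                            back_step_prob = 0.35, noise_sd = 0,
                            sample_rate = 100, duration = 300, seed = s)
    trace_velocity(gen_motility_trace(cfg))$v
  }, numeric(1))
  se <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - v_true), 3 * se)
})

test_that("rupture lifetimes follow the Bell mean at fixed force", {
  cfg <- rupture_gen_config(modes = data.frame(tau0 = 2, x_dagger = 0.4,
                                               weight = 1),
                            force_sampler = function(n) rep(0, n),
                            n_events = 2000, seed = 11)
  ev <- gen_rupture_events(cfg)
  expect_true(all(ev$lifetime > 0))
  expect_lt(abs(mean(ev$lifetime) - 2), 3 * 2 / sqrt(2000))
})

test_that("zero barrier distance makes lifetimes force independent", {
  ps <- vapply(1:40, function(s) {
    ev <- gen_rupture_events(rupture_gen_config(
      modes = data.frame(tau0 = 1.5, x_dagger = 0, weight = 1),
      n_events = 400, seed = s))
    lo <- ev$lifetime[ev$force < 10]
    hi <- ev$lifetime[ev$force >= 10]
    suppressWarnings(stats::wilcox.test(lo, hi)$p.value)
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("rupture config rejects invalid inputs", {
  expect_error(rupture_gen_config(n_events = 0), "n_events")
  expect_error(rupture_gen_config(
    modes = data.frame(tau0 = 1, x_dagger = 0, weight = 0.5)), "sum to 1")
  expect_error(rupture_gen_config(
    modes = data.frame(tau0 = -1, x_dagger = 0, weight = 1)), "tau0")
})

test_that("isotherm generator reproduces the model exactly without noise", {
  cfg <- isotherm_gen_config(params = c(n_max = 4.34, K_d = 8.69),
                             free_grid = c(0, 8.69), noise_sd = 0, seed = 1)
  d <- gen_isotherm(cfg)
  expect_equal(d$bound[d$free == 0], 0)
  expect_equal(d$bound[d$free == 8.69], 2.17, tolerance = 1e-12)
})

test_that("replicate means converge to the noiseless isotherm (CLT)", {
  cfg <- isotherm_gen_config(params = c(n_max = 4.34, K_d = 8.69),
                             free_grid = 50, noise_sd = 0.1,
                             replicates = 200, seed = 5)
  d <- gen_isotherm(cfg)
  truth <- eval_isotherm("one_site", c(n_max = 4.34, K_d = 8.69), 50)
  expect_lt(abs(mean(d$bound) - truth), 3 * 0.1 / sqrt(200))
  expect_true(all(d$bound >= 0))
})

test_that("FRAP curve anchors: baseline, asymptote, half-life", {
  tgrid <- seq(0, 120, by = 0.1)
  cv <- gen_frap_curve(k_off = 0.1, F_M = 0.6, baseline = 0.2, noise_sd = 0,
                       t_grid = tgrid)
  expect_equal(cv$value[1], 0.2)
  expect_equal(cv$value[length(cv$value)], 0.8, tolerance = 1e-4)
  # half recovery at ln(2)/k_off = 6.93 s
  t_half <- tgrid[which.min(abs(cv$value - (0.2 + 0.3)))]
  expect_equal(t_half, log(2) / 0.1, tolerance = 0.05)
  expect_error(gen_frap_curve(k_off = -1, F_M = 0.5), "k_off")
  expect_error(gen_frap_curve(0.1, 0.5, noise_sd = -1), "noise_sd")
})

test_that("QCM-D sensorgram has the stated steady state and rinse decay", {
  kon <- 0.05; koff <- 0.005; A <- 1e12
  sg <- gen_qcmd_sensorgram(kon, koff, A, phase_times = c(0, 400, 1000),
                            dt = 0.5, noise_sd = 0, seed = 2)
  gam <- attr(sg, "coverage")
  tt <- sg$time
  gamma_eq <- A * kon / (kon + koff)
  expect_equal(max(gam), gamma_eq, tolerance = 1e-6)
  # rinse phase is a pure exponential at rate k_off
  rin <- tt >= 400
  slope <- coef(lm(log(gam[rin]) ~ tt[rin]))[2]
  expect_equal(unname(slope), -koff, tolerance = 1e-8)
  # adsorption relaxation rate equals k_on* + k_off
  ads <- tt < 400
  z <- log(1 - gam[ads][-1] / gamma_eq)
  slope_a <- coef(lm(z ~ tt[ads][-1]))[2]
  expect_equal(unname(slope_a), -(kon + koff), tolerance = 1e-6)
  expect_error(gen_qcmd_sensorgram(kon, koff, A,
                                   phase_times = c(0, 1000, 400)),
               "increasing")
})

test_that("XRD generator peaks land on the grid and round-trip their width", {
  pk <- data.frame(two_theta = 23.0, height = 100, fwhm = 0.9)
  pat <- gen_xrd_pattern(pk, amorphous = c(18, 0, 5), noise_sd = 0)
  expect_equal(pat$two_theta[which.max(pat$intensity)], 23.0,
               tolerance = 0.021)
  fw <- peak_fwhm(pat, 23.0)
  expect_equal(fw$fwhm, 0.9, tolerance = 0.009)
  expect_error(gen_xrd_pattern(data.frame(two_theta = 50, height = 1,
                                          fwhm = 1)),
               "outside the grid")
})

test_that("derive_seed gives stable distinct streams", {
  expect_identical(derive_seed(1, "motility"), derive_seed(1, "motility"))
  expect_false(derive_seed(1, "motility") == derive_seed(1, "rupture"))
  expect_false(derive_seed(1, "motility") == derive_seed(2, "motility"))
  s <- derive_seed(2147483646, "x")
  expect_true(s >= 1 && s <= 2147483645)
})

test_that("CSV round trips preserve the documented columns", {
  tmp <- tempfile(fileext = ".csv")
  d <- adsorption_data(c(1, 2, 5), c(0.3, 0.5, 0.9))
  write_adsorption_csv(d, tmp)
  expect_identical(names(read.csv(tmp)), c("free_uM", "bound_umol_g"))
  expect_equal(read_adsorption_csv(tmp)$bound, d$bound)
  ev <- rupture_events(c(1, 2), c(0.5, 1.5))
  write_rupture_csv(ev, tmp)
  expect_equal(read_rupture_csv(tmp)$force, ev$force)
  tr <- make_staircase(3, sample_rate = 50)
  write_trace_csv(tr, tmp)
  expect_equal(read_trace_csv(tmp)$position, tr$position)
  unlink(tmp)
})
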