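test_that("FRAP fits round-trip the generator", {
  cv <- gen_frap_curve(k_off = 0.1, F_M = 0.6, baseline = 0.2, noise_sd = 0,
                       t_grid = seq(0, 60, by = 0.5))
  f <- fit_frap(cv)
  expect_true(f$converged && f$identifiable)
  expect_lt(abs(f$k_off - 0.1) / 0.1, 1e-6)
  expect_lt(abs(f$F_M - 0.6) / 0.6, 1e-6)
  expect_lt(abs(f$baseline - 0.2) / 0.2, 1e-6)
})

test_that("FRAP fits tolerate 1% noise", {
  rel <- vapply(1:10, function(s) {
    cv <- gen_frap_curve(0.1, 0.6, 0.2, noise_sd = 0.01,
                         t_grid = seq(0, 60, by = 0.5), seed = s)
    f <- fit_frap(cv)
    abs(f$k_off - 0.1) / 0.1
  }, numeric(1))
  expect_lt(mean(rel), 0.05)
})

test_that("a non-recovering curve flags k_off as non-identifiable", {
  flat <- kinetic_curve(seq(0, 60, 0.5), rep(0.2, 121), "frap")
  f <- fit_frap(flat)
  expect_false(f$identifiable)
  expect_error(fit_frap(kinetic_curve(1:5, rep(0.2, 5), "frap")),
               "at least 10")
})

test_that("k_off fold change is a guarded ratio", {
  a <- fit_frap(gen_frap_curve(0.05, 0.6, 0.2, 0, seq(0, 200, 1)))
  b <- fit_frap(gen_frap_curve(0.095, 0.6, 0.2, 0, seq(0, 120, 0.5)))
  expect_equal(frap_fold_change(a, a), 1.0, tolerance = 1e-9)
  expect_equal(frap_fold_change(a, b), 1.9, tolerance = 1e-4)
  bad <- structure(list(converged = FALSE), class = "frap_fit")
  expect_error(frap_fold_change(a, bad), "converged")
})

test_that("Sauerbrey conversion is the linear textbook relation", {
  expect_equal(sauerbrey_mass(-30, 3), 177)
  expect_equal(sauerbrey_mass(0, 3), 0)
  expect_equal(sauerbrey_mass(-10, 5), 2 * sauerbrey_mass(-5, 5))
  expect_lt(sauerbrey_mass(12, 3), 0) # desorption sign convention
  expect_error(sauerbrey_mass(-30, 2), "odd")
  expect_error(sauerbrey_mass(-30, 0), "odd")
})

test_that("mass-to-molecule conversion is Avogadro arithmetic", {
  # 100 ng of a 50-kDa protein
  expect_equal(mass_to_molecules(100, 1, 50000), 1.204e12,
               tolerance = 1e-3)
  expect_equal(mass_to_molecules(0, 1, 50000), 0)
  expect_equal(mass_to_molecules(100, 1, 100000),
               mass_to_molecules(100, 1, 50000) / 2)
  expect_error(mass_to_molecules(100, 1, 0), "molar_mass")
})

test_that("QCM-D joint fits recover study-magnitude rate constants", {
  phases <- c(0, 60, 800)
  sg <- gen_qcmd_sensorgram(0.13, 4.6e-3, 1e12, phase_times = phases,
                            dt = 0.5, noise_sd = 0)
  f <- fit_qcmd(sg, phases, molar_mass = 77000)
  expect_true(f$separable && f$converged)
  expect_lt(abs(f$k_on_star - 0.13) / 0.13, 0.01)
  expect_lt(abs(f$k_off - 4.6e-3) / 4.6e-3, 0.01)
  expect_lt(abs(f$A - 1e12) / 1e12, 0.01)
  # internal consistency: Gamma_eq / A identity for the fitted parameters
  gamma_eq_true <- 1e12 * 0.13 / (0.13 + 4.6e-3)
  expect_equal(gamma_eq_true / f$A, f$k_on_star / (f$k_on_star + f$k_off),
               tolerance = 1e-3)
})

test_that("adsorption-only data are flagged non-separable", {
  phases <- c(0, 600, 601)
  sg <- gen_qcmd_sensorgram(0.05, 0.005, 1e12, phase_times = c(0, 600, 602),
                            dt = 1, noise_sd = 0)
  keep <- sg$time < 600
  ads <- kinetic_curve(sg$time[keep], sg$value[keep], "qcmd", overtone = 3)
  f <- fit_qcmd(ads, c(0, 600, 600), molar_mass = 77000)
  expect_false(f$separable)
  # only the relaxation sum is identifiable, and it is recovered
  expect_equal(f$relaxation_rate, 0.055, tolerance = 1e-4)
})

test_that("the rinse phase alone gives k_off exactly", {
  sg <- gen_qcmd_sensorgram(0.05, 0.005, 1e12, phase_times = c(0, 300, 1500),
                            dt = 1, noise_sd = 0)
  rin <- sg$time >= 300
  gam <- attr(sg, "coverage")[rin]
  slope <- -coef(lm(log(gam) ~ sg$time[rin]))[[2]]
  expect_equal(slope, 0.005, tolerance = 1e-10)
})
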