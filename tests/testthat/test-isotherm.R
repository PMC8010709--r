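test_that("isotherm models evaluate to their closed forms", {
  expect_equal(eval_isotherm("one_site", c(n_max = 4.34, K_d = 8.69), 8.69),
               2.17)
  expect_equal(eval_isotherm("langmuir_freundlich",
                             c(n_max = 4.80, K_d = 6.90, m = 0.77), 6.90),
               2.40)
  for (spec in list(list("one_site", c(n_max = 2, K_d = 5)),
                    list("two_site", c(n_max_1 = 2, K_d_1 = 10,
                                       n_max_2 = 0.5, K_d_2 = 0.2)),
                    list("langmuir_freundlich",
                         c(n_max = 2, K_d = 5, m = 0.7))))
    expect_equal(eval_isotherm(spec[[1]], spec[[2]], 0), 0)
  expect_error(eval_isotherm("one_site", c(n_max = 2, K_d = 5), -1),
               "non-negative")
  expect_error(eval_isotherm("bogus", c(n_max = 2, K_d = 5), 1), "unknown")
  expect_error(eval_isotherm("langmuir_freundlich",
                             c(n_max = 2, K_d = 5, m = 3), 1), "m must lie")
})

test_that("isotherms are monotone and saturate at total n_max", {
  F <- c(0, 10^seq(-3, 5, length.out = 60))
  cases <- list(
    list("one_site", c(n_max = 4.34, K_d = 8.69), 4.34),
    list("two_site", c(n_max_1 = 4.14, K_d_1 = 13.68,
                       n_max_2 = 0.42, K_d_2 = 0.13), 4.56),
    list("langmuir_freundlich", c(n_max = 4.80, K_d = 6.90, m = 0.77), 4.80))
  for (cs in cases) {
    B <- eval_isotherm(cs[[1]], cs[[2]], F)
    expect_true(all(diff(B) >= -1e-12))
    expect_true(all(B < cs[[3]]))
    expect_equal(B[length(B)], cs[[3]], tolerance = 0.02)
  }
})

test_that("noiseless data are refit to the generating parameters", {
  for (cs in list(
    list("one_site", c(n_max = 3.32, K_d = 10.55)),
    list("two_site", c(n_max_1 = 4.14, K_d_1 = 13.68,
                       n_max_2 = 0.42, K_d_2 = 0.13)),
    list("langmuir_freundlich", c(n_max = 4.80, K_d = 6.90, m = 0.77)))) {
    d <- gen_isotherm(isotherm_gen_config(model_id = cs[[1]],
                                          params = cs[[2]], noise_sd = 0))
    f <- fit_isotherm(d, cs[[1]])
    expect_true(f$converged)
    expect_lt(max(abs(f$params[names(cs[[2]])] - cs[[2]]) / cs[[2]]), 1e-4)
  }
})

test_that("the nested two-site model never fits worse than one-site", {
  d <- gen_isotherm(isotherm_gen_config(params = c(n_max = 4.34, K_d = 8.69),
                                        noise_sd = 0.1, seed = 7))
  f1 <- fit_isotherm(d, "one_site")
  f2 <- fit_isotherm(d, "two_site")
  expect_lte(f2$rmse, f1$rmse * (1 + 1e-4))
})

test_that("degenerate datasets are rejected as non-identifiable", {
  expect_error(fit_isotherm(adsorption_data(1:10, rep(0, 10)), "one_site"),
               "identifiable")
  expect_error(fit_isotherm(adsorption_data(1:10, rep(2, 10)), "one_site"),
               "identifiable")
  expect_error(fit_isotherm(adsorption_data(1:3, c(0.1, 0.2, 0.3)),
                            "two_site"), "at least")
})

test_that("noisy fits cover the truth at the reported standard errors", {
  truth <- c(n_max = 4.34, K_d = 8.69)
  ok <- vapply(1:30, function(s) {
    d <- gen_isotherm(isotherm_gen_config(params = truth, noise_sd = 0.1,
                                          seed = s))
    f <- fit_isotherm(d, "one_site")
    f$converged &&
      all(abs(f$params[names(truth)] - truth) <= 3 * f$std_errors[names(truth)])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("partition coefficient matches the low-concentration Langmuir slope", {
  d <- gen_isotherm(isotherm_gen_config(
    params = ref_one_site$cellulose_I,
    free_grid = seq(0.02, 0.3, length.out = 10), noise_sd = 0))
  pc <- partition_coefficient(d, 0.3)
  expect_equal(pc$slope, 4.34 / 8.69, tolerance = 0.03)
  # printed one-site parameters imply a lower slope on cellulose III
  expect_gt(4.34 / 8.69, 3.32 / 10.55)
  expect_error(partition_coefficient(d, 0.01), "at least 3")
})

test_that("truncation reproduces the saturation-range artifact", {
  d <- gen_isotherm(isotherm_gen_config(params = c(n_max = 10, K_d = 10),
                                        free_grid = exp(seq(log(0.1), log(30),
                                                            length.out = 25)),
                                        noise_sd = 0.05, seed = 3))
  fits <- truncate_and_fit(d, c(15, 3), "one_site")
  expect_named(fits, c("full", "15", "3"))
  # cutoff above max(F) returns the full fit
  same <- truncate_and_fit(d, 1000, "one_site")
  expect_equal(same[["1000"]]$params, same$full$params)
  # information loss inflates the K_d standard error
  expect_gt(fits[["3"]]$std_errors["K_d"], fits$full$std_errors["K_d"])
  expect_error(truncate_and_fit(d, 0.001, "one_site"), "excludes all")
})

test_that("apparent n_max shrinks as the dataset is truncated harder", {
  # emulates the published truncation analysis on a CBM1-like dataset
  d <- gen_isotherm(isotherm_gen_config(
    params = c(n_max_1 = 4.14, K_d_1 = 13.68, n_max_2 = 0.42, K_d_2 = 0.13),
    model_id = "two_site", noise_sd = 0.1, seed = 11))
  fits <- truncate_and_fit(d, c(50, 15), "one_site")
  n_full <- fits$full$params["n_max"]
  n_50 <- fits[["50"]]$params["n_max"]
  n_15 <- fits[["15"]]$params["n_max"]
  expect_true(n_full > n_50 && n_50 > n_15)
})

test_that("Scatchard diagnostics separate one-site from two-site binding", {
  F <- exp(seq(log(0.05), log(250), length.out = 40))
  d1 <- adsorption_data(F, eval_isotherm("one_site",
                                         c(n_max = 4.34, K_d = 8.69), F))
  s1 <- scatchard_diagnostic(d1)
  expect_identical(s1$curvature_sign, 0L)
  d2 <- adsorption_data(F, eval_isotherm("two_site",
    c(n_max_1 = 4.14, K_d_1 = 13.68, n_max_2 = 0.42, K_d_2 = 0.13), F))
  s2 <- scatchard_diagnostic(d2)
  expect_identical(s2$curvature_sign, 1L)
  d0 <- adsorption_data(c(0, F), c(0, d1$bound))
  expect_warning(scatchard_diagnostic(d0), "F = 0")
})

test_that("affinity fold changes reproduce the printed ratios", {
  f1a <- fake_iso_fit("one_site", ref_one_site$cellulose_I)
  f1b <- fake_iso_fit("one_site", ref_one_site$cellulose_III)
  expect_equal(affinity_fold_change(f1a, f1b), 10.55 / 8.69, tolerance = 1e-12)
  expect_equal(round(affinity_fold_change(f1a, f1b), 1), 1.2)
  f2a <- fake_iso_fit("two_site", c(n_max_1 = 4.14, K_d_1 = 13.68,
                                    n_max_2 = 0.42, K_d_2 = 0.13))
  f2b <- fake_iso_fit("two_site", c(n_max_1 = 2.81, K_d_1 = 25.06,
                                    n_max_2 = 0.75, K_d_2 = 0.92))
  expect_equal(affinity_fold_change(f2a, f2b, "high_affinity"), 0.92 / 0.13)
  expect_equal(round(affinity_fold_change(f2a, f2b, "high_affinity")), 7)
  expect_equal(affinity_fold_change(f1a, f1a), 1.0)
  expect_error(affinity_fold_change(f1a, f2a), "different models")
})
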