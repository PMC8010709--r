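`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' Returns the full default run configuration for the synthetic cellulose I
#' vs cellulose III comparison: one section per stage, with the default
#' thresholds surfaced (10 s commitment threshold, 50 nm excursion
#' threshold, 2.5 pN force bins, QCM-D overtone 3). Per-substrate generator
#' parameters default to the study-system reference constants
#' ([cbm1_binding_params()], [single_molecule_reference()],
#' [qcmd_reference()]).
#'
#' @param master_seed integer master seed; every stage derives its own
#'   stream via [derive_seed()].
#' @param stages character vector of stages to run, a subset of
#'   `c("isotherm", "motility", "rupture", "kinetics", "buffon", "xrd")`.
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 1,
                               stages = c("isotherm", "motility", "rupture",
                                          "kinetics", "buffon", "xrd")) {
  sm <- single_molecule_reference()
  qr <- qcmd_reference()
  cfg <- list(
    master_seed = master_seed,
    stages = stages,
    isotherm = list(
      model = "one_site",
      noise_sd = 0.1,
      replicates = 2,
      truncation_cutoffs = c(50, 15),
      partition_max_free = 0.5,
      params = list(
        cellulose_I = list(n_max = 4.34, K_d = 8.69),
        cellulose_III = list(n_max = 3.32, K_d = 10.55))),
    motility = list(
      n_traces = 12, duration = 60, noise_sd = 0.3, sample_rate = 1000,
      min_dwell = 0.02, penalty = 10,
      commit_threshold = 10, excursion_threshold = 50,
      params = list(
        cellulose_I = list(dwell_mean = sm$dwell_tau_s[["cellulose_I"]],
                           back_step_prob = sm$reverse_fraction[["cellulose_I"]],
                           unstable_fraction = 2 / 17),
        cellulose_III = list(dwell_mean = sm$dwell_tau_s[["cellulose_III"]],
                             back_step_prob = sm$reverse_fraction[["cellulose_III"]],
                             unstable_fraction = 3 / 13))),
    rupture = list(
      n_events = 500, bin_width = 2.5, kBT = 4.114,
      params = list(
        cellulose_I = list(tau0 = 2.0, x_dagger = 0.4),
        cellulose_III = list(tau0 = 1.6, x_dagger = 0.4))),
    kinetics = list(
      overtone = 3, sauerbrey_c = 17.7, molar_mass = 77000, area = 0.2,
      frap = list(
        cellulose_I = list(k_off = 0.05, F_M = 0.6),
        cellulose_III = list(k_off = 0.095, F_M = 0.6)),
      qcmd = list(
        cellulose_I = list(k_on_star = qr$k_on_star[1], k_off = qr$k_off[1],
                           A = 1e12),
        cellulose_III = list(k_on_star = qr$k_on_star[2], k_off = qr$k_off[2],
                             A = 0.7e12))),
    buffon = list(ratio_wildtype = 0.9, ratio_mutant = 0.6, n_trials = 1e5),
    xrd = list(noise_sd = 0.3, fwhm = 0.9, segal_amorphous = c(
      cellulose_I = 18.0, cellulose_III = 16.0)))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a declarative document with one section per stage; any keys
#' present override the defaults of [default_run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(
    master_seed = if (!is.null(user$master_seed)) user$master_seed else 1)
  cfg <- modifyList(cfg, user)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic cellulose I vs III comparison pipeline
#'
#' Executes the requested stages for both substrates with all randomness
#' derived from the master seed, then tabulates the derived deltas
#' (velocity reduction, commitment reduction, K_d and k_off fold changes,
#' mean-lifetime difference). Rerunning with the same configuration
#' reproduces the report exactly.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @return object of class `comparison_report`: list with one element per
#'   stage (each a per-substrate list), `deltas` (see [derived_deltas()]),
#'   and `log` (stage parameters).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (is.null(config$master_seed)) stop("config must set master_seed")
  subs <- c("cellulose_I", "cellulose_III")
  report <- list(stages = list(), log = list(
    master_seed = config$master_seed, stages = config$stages))

  for (stage in config$stages) {
    if (is.null(config[[stage]]))
      stop("missing configuration for stage: ", stage)
    report$stages[[stage]] <- switch(stage,
      isotherm = wb_isotherm(config, subs),
      motility = wb_motility(config, subs),
      rupture = wb_rupture(config, subs),
      kinetics = wb_kinetics(config, subs),
      buffon = wb_buffon(config),
      xrd = wb_xrd(config),
      stop("unknown stage: ", stage))
  }
  report$deltas <- derived_deltas(report)
  class(report) <- "comparison_report"
  report
}

wb_isotherm <- function(config, subs) {
  sc <- config$isotherm
  out <- list()
  for (s in subs) {
    gen <- isotherm_gen_config(
      model_id = sc$model, params = unlist(sc$params[[s]]),
      noise_sd = sc$noise_sd, replicates = sc$replicates,
      seed = derive_seed(config$master_seed, paste0("isotherm_", s)))
    dat <- gen_isotherm(gen)
    fit <- fit_isotherm(dat, sc$model)
    out[[s]] <- list(
      fit = fit,
      partition = partition_coefficient(dat, sc$partition_max_free),
      truncation = truncate_and_fit(dat, sc$truncation_cutoffs, sc$model),
      scatchard = scatchard_diagnostic(dat))
  }
  out
}

wb_motility <- function(config, subs) {
  sc <- config$motility
  out <- list()
  for (s in subs) {
    p <- sc$params[[s]]
    steps_all <- numeric(0); dwells_all <- numeric(0)
    vels <- numeric(sc$n_traces); labels <- vector("list", sc$n_traces)
    n_unstable <- round((p$unstable_fraction %||% 0) * sc$n_traces)
    for (i in seq_len(sc$n_traces)) {
      tr <- gen_motility_trace(trace_gen_config(
        dwell_mean = p$dwell_mean, back_step_prob = p$back_step_prob,
        noise_sd = sc$noise_sd, sample_rate = sc$sample_rate,
        duration = sc$duration,
        spike_amplitude = if (i <= n_unstable) 100 else 0,
        seed = derive_seed(config$master_seed,
                           paste0("motility_", s, "_", i))))
      sd_series <- detect_steps(tr, sc$min_dwell, sc$penalty)
      steps_all <- c(steps_all, sd_series$step_sizes)
      dwells_all <- c(dwells_all, sd_series$dwell_times)
      vels[i] <- trace_velocity(tr)$v
      labels[[i]] <- classify_commitment(tr, sc$commit_threshold,
                                         sc$excursion_threshold)
    }
    out[[s]] <- list(
      velocity = list(v = mean(vels), se = sd(vels) / sqrt(length(vels))),
      steps = if (length(steps_all) >= 20) fit_step_sizes(steps_all) else NULL,
      dwells = if (length(dwells_all) >= 10) fit_dwell_times(dwells_all) else NULL,
      commitment = instability_summary(labels))
  }
  out
}

wb_rupture <- function(config, subs) {
  sc <- config$rupture
  out <- list()
  for (s in subs) {
    p <- sc$params[[s]]
    ev <- gen_rupture_events(rupture_gen_config(
      modes = data.frame(tau0 = p$tau0, x_dagger = p$x_dagger, weight = 1),
      kBT = sc$kBT, n_events = sc$n_events,
      seed = derive_seed(config$master_seed, paste0("rupture_", s))))
    bins <- bin_events(ev, sc$bin_width)
    out[[s]] <- list(summary = summarize_lifetime(ev), bins = bins,
                     bell = fit_bell_slip(bins, sc$kBT))
  }
  out
}

wb_kinetics <- function(config, subs) {
  sc <- config$kinetics
  out <- list()
  for (s in subs) {
    fp <- sc$frap[[s]]
    frap <- fit_frap(gen_frap_curve(
      k_off = fp$k_off, F_M = fp$F_M, noise_sd = 0.01,
      t_grid = seq(0, 5 / fp$k_off, length.out = 200),
      seed = derive_seed(config$master_seed, paste0("frap_", s))))
    qp <- sc$qcmd[[s]]
    phases <- c(0, 5 / (qp$k_on_star + qp$k_off), 5 / (qp$k_on_star + qp$k_off) +
                  3 / qp$k_off)
    sg <- gen_qcmd_sensorgram(
      qp$k_on_star, qp$k_off, qp$A, phase_times = phases,
      overtone = sc$overtone, molar_mass = sc$molar_mass, area = sc$area,
      sauerbrey_c = sc$sauerbrey_c, dt = diff(range(phases)) / 600,
      seed = derive_seed(config$master_seed, paste0("qcmd_", s)))
    qcmd <- fit_qcmd(sg, phases, molar_mass = sc$molar_mass, area = sc$area,
                     sauerbrey_c = sc$sauerbrey_c)
    out[[s]] <- list(frap = frap, qcmd = qcmd)
  }
  out
}

wb_buffon <- function(config) {
  sc <- config$buffon
  compare_constructs(sc$ratio_wildtype, sc$ratio_mutant, d = 1,
                     n_trials = sc$n_trials,
                     seed = derive_seed(config$master_seed, "buffon"))
}

wb_xrd <- function(config) {
  sc <- config$xrd
  ref <- xrd_reference_peaks()
  out <- list()
  for (s in names(ref)) {
    pk <- data.frame(two_theta = ref[[s]], height = c(40, 30, 100),
                     fwhm = sc$fwhm)
    pat <- gen_xrd_pattern(pk, amorphous = c(sc$segal_amorphous[[s]], 7.5, 6),
                           noise_sd = sc$noise_sd, allomorph = s,
                           seed = derive_seed(config$master_seed,
                                              paste0("xrd_", s)))
    main <- ref[[s]][3]
    out[[s]] <- list(
      peaks = locate_peaks(pat, ref[[s]], window = 0.5),
      cri = segal_cri(pat, main, sc$segal_amorphous[[s]]),
      size_nm = scherrer_size(main, peak_fwhm(pat, main)$fwhm))
  }
  out
}

#' Derived cellulose I vs III deltas from a pipeline report
#'
#' Velocity reduction is `(v_I - v_III) / v_I * 100`. Commitment reduction is
#' the relative change in the unstable-binding fraction,
#' `(f_III - f_I) / f_III * 100` — the arithmetic under which instability
#' fractions of 12% and 23% give a 48% reduction in commitment. K_d and
#' k_off fold changes are III/I ratios; the mean-lifetime difference is in
#' seconds.
#'
#' @param report a [run_pipeline()] result (or its `stages` list).
#' @return named list of deltas for the stages present.
#' @export
derived_deltas <- function(report) {
  st <- if (!is.null(report$stages)) report$stages else report
  subs <- c("cellulose_I", "cellulose_III")
  out <- list()
  if (!is.null(st$motility)) {
    for (s in subs) if (is.null(st$motility[[s]]))
      stop("motility stage missing substrate ", s)
    v <- unname(vapply(subs, function(s) st$motility[[s]]$velocity$v,
                       numeric(1)))
    out$velocity_reduction_pct <- (v[1] - v[2]) / v[1] * 100
    f <- unname(vapply(subs,
                       function(s) st$motility[[s]]$commitment$fraction_unstable,
                       numeric(1)))
    out$commitment_reduction_pct <-
      if (f[2] > 0) (f[2] - f[1]) / f[2] * 100 else NA_real_
  }
  if (!is.null(st$isotherm)) {
    out$kd_fold_change <- affinity_fold_change(
      st$isotherm$cellulose_I$fit, st$isotherm$cellulose_III$fit)
    pr <- unname(vapply(subs, function(s) st$isotherm[[s]]$partition$slope,
                        numeric(1)))
    out$partition_ratio_I_over_III <- pr[1] / pr[2]
  }
  if (!is.null(st$rupture)) {
    out$mean_lifetime_diff_s <- st$rupture$cellulose_I$summary$mean -
      st$rupture$cellulose_III$summary$mean
  }
  if (!is.null(st$kinetics)) {
    out$frap_koff_fold <- frap_fold_change(st$kinetics$cellulose_I$frap,
                                           st$kinetics$cellulose_III$frap)
    q <- st$kinetics
    if (q$cellulose_I$qcmd$separable && q$cellulose_III$qcmd$separable)
      out$qcmd_koff_fold <- q$cellulose_III$qcmd$k_off / q$cellulose_I$qcmd$k_off
  }
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Cellulose I vs cellulose III comparison report\n")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  cat("  master seed:", x$log$master_seed, "\n")
  for (nm in names(x$deltas))
    cat(sprintf("  %-28s %.4g\n", nm, x$deltas[[nm]]))
  invisible(x)
}

#' Write a comparison report to JSON
#'
#' Serializes the derived deltas and per-stage scalar summaries to a
#' machine-readable JSON file.
#'
#' @param report a [run_pipeline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  slim <- list(master_seed = report$log$master_seed,
               stages = names(report$stages),
               deltas = report$deltas)
  if (!is.null(report$stages$isotherm)) {
    slim$isotherm <- lapply(report$stages$isotherm, function(s)
      list(params = as.list(s$fit$params), rmse = s$fit$rmse,
           partition_slope = s$partition$slope))
  }
  if (!is.null(report$stages$rupture)) {
    slim$rupture <- lapply(report$stages$rupture, function(s)
      list(mean = s$summary$mean, sem = s$summary$sem, n = s$summary$n,
           tau0 = s$bell$tau0, x_dagger = s$bell$x_dagger))
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
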