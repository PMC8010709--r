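#' Configuration for the processive-motility trace generator
#'
#' @param dwell_mean mean dwell between catalytic steps, s (> 0).
#' @param step_sizes data frame with columns `size_nm`, `weight` giving the
#'   step-size mixture (weights must sum to 1). Default: fundamental ~1 nm
#'   cellobiose step with a minor 2x component.
#' @param back_step_prob probability a step is a reverse (negative) step.
#' @param noise_sd Gaussian position noise SD, nm.
#' @param sample_rate sampling rate, Hz.
#' @param duration trace duration, s.
#' @param detach_rate detachment rate, s^-1 (0 = never detaches); after
#'   detachment the staircase freezes at its last level.
#' @param spike_amplitude amplitude of pre-commitment unstable-binding
#'   excursions, nm (0 = committed trace, staircase starts immediately).
#' @param n_spikes number of pre-commitment excursions when
#'   `spike_amplitude > 0`.
#' @param unstable_duration length of the pre-commitment window, s.
#' @param seed integer seed.
#' @return validated config of class `trace_gen_config`.
#' @export
trace_gen_config <- function(dwell_mean = 0.75,
                             step_sizes = data.frame(size_nm = c(1, 2),
                                                     weight = c(0.8, 0.2)),
                             back_step_prob = 0.35, noise_sd = 0.3,
                             sample_rate = 1000, duration = 60,
                             detach_rate = 0, spike_amplitude = 0,
                             n_spikes = 3, unstable_duration = 20,
                             seed = 1) {
  if (dwell_mean <= 0) stop("dwell_mean must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (back_step_prob < 0 || back_step_prob > 1)
    stop("back_step_prob must lie in [0, 1]")
  if (abs(sum(step_sizes$weight) - 1) > 1e-9)
    stop("step-size weights must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (detach_rate < 0) stop("detach_rate must be non-negative")
  structure(as.list(environment()), class = "trace_gen_config")
}

#' Generate a synthetic processive-motility bead trace
#'
#' Renewal-process staircase: exponential dwells with mean `dwell_mean`, step
#' displacements drawn from the weighted size mixture with the sign flipped to
#' negative with probability `back_step_prob`, plus additive Gaussian position
#' noise. When `spike_amplitude > 0` the staircase is preceded by an unstable
#' pre-commitment window with transient excursions that return to baseline,
#' emulating repeated surface desorption before processive motion starts.
#' The expected net velocity of the committed staircase is
#' `(1 - 2 * back_step_prob) * E[step] / dwell_mean`.
#'
#' @param config a [trace_gen_config()].
#' @return [motility_trace] with attribute `truth`: list of true `step_times`,
#'   `step_sizes`, `dwell_times` and `motility_start`.
#' @export
gen_motility_trace <- function(config) {
  stopifnot(inherits(config, "trace_gen_config"))
  cfg <- config
  with_seed(cfg$seed, {
    t_grid <- seq(0, cfg$duration, by = 1 / cfg$sample_rate)
    pos <- numeric(length(t_grid))

    t0 <- 0
    if (cfg$spike_amplitude > 0 && cfg$n_spikes > 0) {
      t0 <- min(cfg$unstable_duration, cfg$duration / 2)
      width <- 0.5
      starts <- sort(runif(cfg$n_spikes, 0, max(t0 - width, 0.1)))
      for (s in starts) {
        idx <- t_grid >= s & t_grid < s + width
        pos[idx] <- cfg$spike_amplitude
      }
    }

    t_end <- cfg$duration
    if (cfg$detach_rate > 0)
      t_end <- min(t_end, t0 + rexp(1, cfg$detach_rate))

    # draw step times until past the attachment window
    step_times <- numeric(0)
    tt <- t0
    repeat {
      tt <- tt + rexp(1, 1 / cfg$dwell_mean)
      if (tt >= t_end) break
      step_times <- c(step_times, tt)
    }
    n_steps <- length(step_times)
    sizes <- numeric(0)
    if (n_steps > 0) {
      sizes <- sample(cfg$step_sizes$size_nm, n_steps, replace = TRUE,
                      prob = cfg$step_sizes$weight)
      sgn <- ifelse(runif(n_steps) < cfg$back_step_prob, -1, 1)
      sizes <- sizes * sgn
      level_at <- stats::stepfun(step_times, c(0, cumsum(sizes)))
      stair <- level_at(t_grid)
      stair[t_grid < t0] <- 0
      pos <- pos + stair
    }

    if (cfg$noise_sd > 0) pos <- pos + rnorm(length(pos), 0, cfg$noise_sd)

    tr <- motility_trace(t_grid, pos, cfg$sample_rate)
    attr(tr, "truth") <- list(step_times = step_times, step_sizes = sizes,
                              dwell_times = if (n_steps > 1) diff(step_times)
                                            else numeric(0),
                              motility_start = t0, detach_time = t_end)
    tr
  })
}

#' Configuration for the bond-rupture event generator
#'
#' @param modes data frame with columns `tau0` (zero-force lifetime, s),
#'   `x_dagger` (distance to the transition state, nm) and `weight`; weights
#'   must sum to 1 (tolerance 1e-9). One row = classic unimodal slip bond.
#' @param force_sampler either a function `n -> forces (pN)` or a list
#'   `list(dist = "uniform", min, max)`. Default uniform on [0, 20] pN.
#' @param kBT thermal energy, pN nm (4.114 at 298 K).
#' @param n_events number of rupture events (>= 1).
#' @param seed integer seed.
#' @return validated config of class `rupture_gen_config`.
#' @export
rupture_gen_config <- function(modes = data.frame(tau0 = 2, x_dagger = 0.4,
                                                  weight = 1),
                               force_sampler = list(dist = "uniform",
                                                    min = 0, max = 20),
                               kBT = 4.114, n_events = 500, seed = 1) {
  if (abs(sum(modes$weight) - 1) > 1e-9) stop("mode weights must sum to 1")
  if (any(modes$tau0 <= 0)) stop("tau0 must be positive")
  if (any(modes$x_dagger < 0)) stop("x_dagger must be non-negative")
  if (n_events < 1) stop("n_events must be at least 1")
  if (kBT <= 0) stop("kBT must be positive")
  structure(as.list(environment()), class = "rupture_gen_config")
}

#' Generate synthetic single-bond rupture events
#'
#' Per event: a binding mode is drawn by weight, a clamp force from the force
#' sampler, and the bond lifetime from an exponential distribution with mean
#' `tau0 * exp(-F * x_dagger / kBT)` (Bell slip bond). Multi-row `modes`
#' produce the multimodal force-lifetime behavior seen when several binding
#' orientations coexist.
#'
#' @param config a [rupture_gen_config()].
#' @return [rupture_events] with attribute `truth` (mode index per event).
#' @export
gen_rupture_events <- function(config) {
  stopifnot(inherits(config, "rupture_gen_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_events
    mode <- sample.int(nrow(cfg$modes), n, replace = TRUE,
                       prob = cfg$modes$weight)
    force <- if (is.function(cfg$force_sampler)) cfg$force_sampler(n)
             else runif(n, cfg$force_sampler$min, cfg$force_sampler$max)
    if (any(force < 0)) stop("force sampler produced negative forces")
    mean_life <- cfg$modes$tau0[mode] *
      exp(-force * cfg$modes$x_dagger[mode] / cfg$kBT)
    lifetime <- rexp(n, rate = 1 / mean_life)
    ev <- rupture_events(force, lifetime)
    attr(ev, "truth") <- list(mode = mode)
    ev
  })
}

#' Configuration for the adsorption-isotherm generator
#'
#' @param model_id adsorption model, see [eval_isotherm()].
#' @param params named parameters for the model.
#' @param free_grid free-concentration grid, uM (>= 0). Default: 20-point
#'   log-spaced dilution series 0.05-250 uM, the working range of the
#'   pull-down assays.
#' @param noise_sd additive Gaussian noise SD on bound values, umol/g.
#' @param replicates replicate measurements per grid point.
#' @param seed integer seed.
#' @return validated config of class `isotherm_gen_config`.
#' @export
isotherm_gen_config <- function(model_id = "one_site",
                                params = c(n_max = 4.34, K_d = 8.69),
                                free_grid = exp(seq(log(0.05), log(250),
                                                    length.out = 20)),
                                noise_sd = 0.1, replicates = 1, seed = 1) {
  model_id <- normalize_model_id(model_id)
  check_iso_params(model_id, as.list(params))
  if (any(free_grid < 0)) stop("free_grid values must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (replicates < 1) stop("replicates must be at least 1")
  structure(as.list(environment()), class = "isotherm_gen_config")
}

#' Generate a synthetic adsorption dataset
#'
#' `bound = model(free) + Gaussian noise`, truncated at zero (a depletion
#' assay cannot report negative bound protein); replicates are stacked.
#'
#' @param config an [isotherm_gen_config()].
#' @return [adsorption_data].
#' @export
gen_isotherm <- function(config) {
  stopifnot(inherits(config, "isotherm_gen_config"))
  cfg <- config
  with_seed(cfg$seed, {
    F <- rep(cfg$free_grid, times = cfg$replicates)
    B <- eval_isotherm(cfg$model_id, cfg$params, F)
    if (cfg$noise_sd > 0) B <- B + rnorm(length(B), 0, cfg$noise_sd)
    adsorption_data(F, pmax(B, 0))
  })
}

#' Generate a synthetic FRAP recovery curve
#'
#' Reaction-dominated (binding-dominated) recovery:
#' `intensity(t) = baseline + F_M * (1 - exp(-k_off * t))`, plus Gaussian
#' noise. `F_M` is the reversibly bound (mobile) fraction; the recovery rate
#' is the desorption rate constant `k_off`.
#'
#' @param k_off desorption rate constant, s^-1 (> 0).
#' @param F_M mobile fraction in [0, 1].
#' @param baseline normalized post-bleach intensity at t = 0.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param t_grid time grid starting at the bleach, s.
#' @param seed integer seed.
#' @return [kinetic_curve] of kind `"frap"`.
#' @export
gen_frap_curve <- function(k_off, F_M, baseline = 0.2, noise_sd = 0,
                           t_grid = seq(0, 60, by = 0.5), seed = 1) {
  if (k_off <= 0) stop("k_off must be positive")
  if (F_M < 0 || F_M > 1) stop("F_M must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    y <- baseline + F_M * (1 - exp(-k_off * t_grid))
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    kinetic_curve(t_grid, y, "frap")
  })
}

#' Generate a synthetic QCM-D sensorgram
#'
#' Langmuir adsorption kinetics in molecule-coverage space, converted to a
#' frequency shift by the inverse Sauerbrey relation at the given overtone.
#' During the adsorption phase
#' `Gamma(t) = Gamma_eq * (1 - exp(-(k_on_star + k_off) t))` with
#' `Gamma_eq = A * k_on_star / (k_on_star + k_off)`; after the rinse starts,
#' coverage decays as `Gamma(t) = Gamma_rinse * exp(-k_off (t - t_rinse))`.
#'
#' @param k_on_star pseudo-adsorption rate constant, s^-1 (true on-rate times
#'   free protein concentration).
#' @param k_off desorption rate constant, s^-1.
#' @param A bound molecules at full saturation.
#' @param phase_times numeric `c(start, rinse_start, end)`, s, increasing.
#' @param overtone odd overtone number (default 3).
#' @param noise_sd Gaussian noise SD on Delta-f, Hz.
#' @param molar_mass molar mass of the protein construct, g/mol.
#' @param area sensor area, cm^2.
#' @param sauerbrey_c Sauerbrey mass-sensitivity constant, ng cm^-2 Hz^-1.
#' @param dt sampling interval, s.
#' @param seed integer seed.
#' @return [kinetic_curve] of kind `"qcmd"` (value = Delta-f, Hz), with
#'   attribute `coverage` (bound molecules at each time).
#' @export
gen_qcmd_sensorgram <- function(k_on_star, k_off, A,
                                phase_times = c(0, 600, 1200), overtone = 3,
                                noise_sd = 0, molar_mass = 77000, area = 0.2,
                                sauerbrey_c = 17.7, dt = 1, seed = 1) {
  if (k_on_star <= 0 || k_off <= 0) stop("rate constants must be positive")
  if (A <= 0) stop("A must be positive")
  if (length(phase_times) != 3 || any(diff(phase_times) <= 0))
    stop("phase_times must be increasing c(start, rinse_start, end)")
  if (overtone <= 0 || overtone %% 2 == 0) stop("overtone must be odd positive")
  with_seed(seed, {
    tt <- seq(phase_times[1], phase_times[3], by = dt)
    krel <- k_on_star + k_off
    gamma_eq <- A * k_on_star / krel
    gamma <- numeric(length(tt))
    ads <- tt < phase_times[2]
    gamma[ads] <- gamma_eq * (1 - exp(-krel * (tt[ads] - phase_times[1])))
    gamma_rinse <- gamma_eq * (1 - exp(-krel * (phase_times[2] - phase_times[1])))
    gamma[!ads] <- gamma_rinse * exp(-k_off * (tt[!ads] - phase_times[2]))
    # molecules -> areal mass (ng/cm^2) -> Delta-f (inverse Sauerbrey)
    mass_ng_cm2 <- gamma * molar_mass / 6.02214076e23 * 1e9 / area
    delta_f <- -overtone * mass_ng_cm2 / sauerbrey_c
    if (noise_sd > 0) delta_f <- delta_f + rnorm(length(delta_f), 0, noise_sd)
    out <- kinetic_curve(tt, delta_f, "qcmd", overtone = overtone)
    attr(out, "coverage") <- gamma
    attr(out, "phase_times") <- phase_times
    out
  })
}

#' Generate a synthetic powder XRD pattern
#'
#' Sum of Gaussian crystalline peaks plus one broad amorphous Gaussian and
#' optional noise, on a 2-theta grid.
#'
#' @param peaks data frame with columns `two_theta`, `height`, `fwhm`
#'   (degrees).
#' @param amorphous numeric `c(two_theta, height, width)` for the broad
#'   amorphous halo (width = Gaussian SD in degrees).
#' @param noise_sd Gaussian noise SD, intensity units.
#' @param grid increasing 2-theta grid, degrees.
#' @param allomorph label passed to [xrd_pattern()].
#' @param seed integer seed.
#' @return [xrd_pattern].
#' @export
gen_xrd_pattern <- function(peaks, amorphous = c(18, 5, 5), noise_sd = 0,
                            grid = seq(8, 32, by = 0.02),
                            allomorph = "unknown", seed = 1) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(peaks$height < 0) || amorphous[2] < 0) stop("heights must be >= 0")
  if (any(peaks$two_theta < min(grid) | peaks$two_theta > max(grid)))
    stop("peak positions fall outside the grid")
  with_seed(seed, {
    y <- numeric(length(grid))
    for (i in seq_len(nrow(peaks))) {
      s <- peaks$fwhm[i] / (2 * sqrt(2 * log(2)))
      y <- y + peaks$height[i] * exp(-(grid - peaks$two_theta[i])^2 / (2 * s^2))
    }
    y <- y + amorphous[2] * exp(-(grid - amorphous[1])^2 / (2 * amorphous[3]^2))
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    xrd_pattern(grid, pmax(y, 0), allomorph)
  })
}
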