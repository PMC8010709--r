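#' Detect steps in a motility trace by penalized change-point insertion
#'
#' Fits a piecewise-constant staircase by greedy binary change-point
#' insertion: at each round the split giving the largest residual
#' sum-of-squares reduction is accepted if the gain exceeds a BIC-like
#' threshold `penalty * sigma^2 * log(n)`, where `sigma` is a robust noise
#' estimate from the median absolute deviation of first differences
#' (`mad(diff(x)) / sqrt(2)`). Plateaus shorter than `min_dwell` are then
#' merged into their neighbours, removing whichever bounding change-point
#' costs the least RSS.
#'
#' @param trace a [motility_trace].
#' @param min_dwell minimum resolvable plateau duration (detector dead time),
#'   s. Default `NULL` uses 20 samples (`20 / sample_rate`), the shortest
#'   plateau whose mean is well separated from sub-nanometer noise at typical
#'   trap SNR.
#' @param penalty dimensionless penalty multiplier for the per-split
#'   acceptance threshold.
#' @return object of class `step_dwell_series`: list with `step_times` (s),
#'   `step_sizes` (signed nm), `dwell_times` (intervals between consecutive
#'   accepted steps, s; first/last partial plateaus excluded),
#'   `plateau_levels` (nm), `plateau_starts` (s), `sigma` (noise estimate).
#' @export
detect_steps <- function(trace, min_dwell = NULL, penalty = 10) {
  stopifnot(inherits(trace, "motility_trace"))
  if (is.null(min_dwell)) min_dwell <- 20 / trace$sample_rate
  x <- trace$position
  n <- length(x)
  if (n < 2 * max(min_dwell * trace$sample_rate, 1))
    stop("trace too short for the requested min_dwell")

  sigma <- mad(diff(x)) / sqrt(2)
  if (sigma == 0) sigma <- 1e-12 # noiseless traces: any real step is accepted
  thresh <- penalty * sigma^2 * log(n)
  min_len <- max(1L, as.integer(round(min_dwell * trace$sample_rate)))

  bounds <- cp_greedy(x, integer(0), thresh, min_len)
  # single-split insertion cannot see short zero-net excursions (a step up
  # followed immediately by a step down); carve those out explicitly and
  # re-segment until stable
  repeat {
    nb <- cp_bumps(x, bounds, 2 * thresh, min_len)
    if (length(nb) == length(bounds)) break
    bounds <- cp_greedy(x, nb, thresh, min_len)
  }
  bounds <- cp_merge_short(x, bounds, min_len)
  bounds <- cp_prune(x, bounds, thresh)

  # plateau means and step series
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  levels <- vapply(seq_along(starts),
                   function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  step_sizes <- diff(levels)
  step_times <- trace$time[bounds]
  dwell_times <- if (length(step_times) > 1) diff(step_times) else numeric(0)

  structure(list(step_times = step_times, step_sizes = step_sizes,
                 dwell_times = dwell_times, plateau_levels = levels,
                 plateau_starts = trace$time[starts], sigma = sigma,
                 min_dwell = min_dwell),
            class = "step_dwell_series")
}

#' @export
print.step_dwell_series <- function(x, ...) {
  cat(sprintf("Step/dwell series: %d steps, mean |step| %.3g nm, mean dwell %.3g s\n",
              length(x$step_sizes),
              if (length(x$step_sizes)) mean(abs(x$step_sizes)) else NA,
              if (length(x$dwell_times)) mean(x$dwell_times) else NA))
  invisible(x)
}

# Best single split of x[l..r] (global cumulative sums S, S0 = S[l-1]).
# Returns c(gain, k): split after index k maximizes the RSS reduction
#   (A^2/n1 + B^2/n2 - (A+B)^2/n), with min segment length constraint.
cp_best_split <- function(S, l, r, min_len) {
  n <- r - l + 1L
  if (n < 2L * min_len) return(c(-Inf, NA))
  ks <- (l + min_len - 1L):(r - min_len)
  S0 <- if (l > 1L) S[l - 1L] else 0
  tot <- S[r] - S0
  A <- S[ks] - S0
  n1 <- ks - l + 1L
  gain <- A^2 / n1 + (tot - A)^2 / (n - n1) - tot^2 / n
  i <- which.max(gain)
  c(gain[i], ks[i])
}

# Greedy penalized binary segmentation starting from existing change points;
# returns sorted change-point indices (boundary = last index of left plateau).
cp_greedy <- function(x, bounds, thresh, min_len) {
  n <- length(x)
  S <- cumsum(x)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  segs <- lapply(seq_along(starts), function(i) c(starts[i], ends[i]))
  cand <- lapply(segs, function(sg) cp_best_split(S, sg[1], sg[2], min_len))
  repeat {
    gains <- vapply(cand, `[`, numeric(1), 1L)
    i <- which.max(gains)
    if (!length(gains) || gains[i] <= thresh) break
    k <- as.integer(cand[[i]][2])
    l <- segs[[i]][1]; r <- segs[[i]][2]
    bounds <- c(bounds, k)
    segs[[i]] <- c(l, k)
    cand[[i]] <- cp_best_split(S, l, k, min_len)
    segs[[length(segs) + 1L]] <- c(k + 1L, r)
    cand[[length(cand) + 1L]] <- cp_best_split(S, k + 1L, r, min_len)
  }
  sort(bounds)
}

# Merge plateaus shorter than min_len by deleting the bounding change-point
# whose removal increases the RSS least.
cp_merge_short <- function(x, bounds, min_len) {
  S <- cumsum(x)
  n <- length(x)
  seg_cost <- function(l, r) {
    S0 <- if (l > 1L) S[l - 1L] else 0
    tot <- S[r] - S0
    -tot^2 / (r - l + 1L) # RSS up to a constant sum(x^2)
  }
  repeat {
    if (!length(bounds)) return(bounds)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    lens <- ends - starts + 1L
    short <- which(lens < min_len)
    if (!length(short)) return(bounds)
    i <- short[which.min(lens[short])] # shortest plateau first
    # candidate boundary removals: left boundary (i-1th cp) or right (ith cp)
    cand <- integer(0)
    if (i > 1L) cand <- c(cand, i - 1L)
    if (i <= length(bounds)) cand <- c(cand, i)
    cost <- vapply(cand, function(j) {
      l <- starts[j]; r <- ends[j + 1L]
      seg_cost(l, r) - seg_cost(starts[j], ends[j]) -
        seg_cost(starts[j + 1L], ends[j + 1L])
    }, numeric(1))
    bounds <- bounds[-cand[which.min(cost)]]
  }
}

# Scan each segment for the best short "bump" (interval whose mean departs
# from the rest of the segment); insert its two boundaries when the RSS gain
# exceeds the two-split threshold. One bump per segment per pass.
cp_bumps <- function(x, bounds, thresh2, min_len) {
  n <- length(x)
  S <- c(0, cumsum(x))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  new_b <- integer(0)
  for (i in seq_along(starts)) {
    l <- starts[i]; r <- ends[i]
    ns <- r - l + 1L
    if (ns < 3L * min_len) next
    tot <- S[r + 1L] - S[l]
    widths <- unique(pmax(min_len,
      as.integer(round(min_len * c(1, 2, 4, 8, 16)))))
    widths <- widths[widths <= ns - 2L * min_len]
    best_gain <- -Inf; best <- NULL
    for (w in widths) {
      # bump must keep min_len samples on both flanks
      is <- (l + min_len):(r - min_len - w + 1L)
      if (!length(is) || is[1] > is[length(is)]) next
      B <- S[is + w] - S[is]
      gain <- B^2 / w + (tot - B)^2 / (ns - w) - tot^2 / ns
      j <- which.max(gain)
      if (gain[j] > best_gain) {
        best_gain <- gain[j]
        best <- c(is[j] - 1L, is[j] + w - 1L)
      }
    }
    if (!is.null(best) && best_gain > thresh2) new_b <- c(new_b, best)
  }
  sort(unique(c(bounds, new_b)))
}

# Backward elimination: drop any change-point whose removal costs less RSS
# than the acceptance threshold (e.g. near-zero steps left by merging).
cp_prune <- function(x, bounds, thresh) {
  S <- cumsum(x)
  n <- length(x)
  seg_cost <- function(l, r) {
    S0 <- if (l > 1L) S[l - 1L] else 0
    -(S[r] - S0)^2 / (r - l + 1L)
  }
  repeat {
    if (!length(bounds)) return(bounds)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    cost <- vapply(seq_along(bounds), function(j) {
      seg_cost(starts[j], ends[j + 1L]) - seg_cost(starts[j], ends[j]) -
        seg_cost(starts[j + 1L], ends[j + 1L])
    }, numeric(1))
    j <- which.min(cost)
    if (cost[j] >= thresh) return(bounds)
    bounds <- bounds[-j]
  }
}

#' Fit the step-size distribution as sign-resolved Gaussian mixtures
#'
#' For each sign, the absolute step sizes are fit by a two-component Gaussian
#' mixture whose second mean is constrained to twice the first, reflecting
#' the fundamental (~1 nm, one cellobiose) and 2x-fundamental steps of a
#' processive exocellulase. Fitting is by constrained EM. The reverse-step
#' fraction is the share of negative steps.
#'
#' @param steps numeric vector of signed step sizes, nm (>= 20 values).
#' @return list with `forward` and `reverse` mixture fits (each: `mean1`,
#'   `mean2 = 2*mean1`, `sd1`, `sd2`, `weight2`, `n`; `NULL` if that sign has
#'   fewer than 5 steps), and `reverse_fraction`.
#' @export
fit_step_sizes <- function(steps) {
  steps <- steps[is.finite(steps) & steps != 0]
  if (length(steps) < 20) stop("need at least 20 steps")
  fit_one <- function(v) {
    if (length(v) < 5) return(NULL)
    em_gauss_x2(v)
  }
  list(forward = fit_one(abs(steps[steps > 0])),
       reverse = fit_one(abs(steps[steps < 0])),
       reverse_fraction = mean(steps < 0))
}

# EM for a two-component Gaussian mixture with mean2 constrained to 2*mean1.
em_gauss_x2 <- function(x, max_iter = 500, tol = 1e-8) {
  mu <- median(x); s1 <- s2 <- max(sd(x), 1e-3); w2 <- 0.2
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- (1 - w2) * dnorm(x, mu, s1)
    d2 <- w2 * dnorm(x, 2 * mu, s2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    # constrained M-step: minimize sum r1 (x-mu)^2/s1^2 + r2 (x-2mu)^2/s2^2
    mu <- sum(r1 * x / s1^2 + 2 * r2 * x / s2^2) /
      sum(r1 / s1^2 + 4 * r2 / s2^2)
    s1 <- sqrt(max(sum(r1 * (x - mu)^2) / max(sum(r1), 1e-9), 1e-6))
    s2 <- sqrt(max(sum(r2 * (x - 2 * mu)^2) / max(sum(r2), 1e-9), 1e-6))
    w2 <- mean(r2)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mean1 = mu, mean2 = 2 * mu, sd1 = s1, sd2 = s2,
       weight2 = w2, n = length(x), loglik = ll)
}

#' Fit the dwell-time constant
#'
#' Maximum-likelihood single-exponential fit of dwell times; with a right-
#' censoring limit, dwells at or above the limit are treated as censored and
#' the standard censored-exponential MLE
#' `tau = total observed time / number of uncensored dwells` is used. A
#' histogram least-squares mode is available for parity with binned
#' exponential-decay fits of dwell-time distributions.
#'
#' When dwells come from a step detector with dead time `c` (steps closer
#' than `c` merge, so short dwells are absorbed into their neighbours), the
#' observed mean is inflated to `tau * exp(c / tau)` (Wald's identity for the
#' geometric number of true dwells per observed interval). Supplying
#' `dead_time` applies this missed-event correction by inverting that
#' relation; its standard error follows by the delta method.
#'
#' @param dwells positive dwell times, s (>= 10 values).
#' @param censor_limit optional right-censoring limit, s.
#' @param dead_time optional detector dead time, s (e.g. the `min_dwell` used
#'   in [detect_steps()]); applies the missed-event correction.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param breaks histogram breaks for `method = "histogram"`.
#' @return list with `tau` (s), `se`, `n`, `n_censored`, `method`.
#' @export
fit_dwell_times <- function(dwells, censor_limit = NULL, dead_time = NULL,
                            method = c("mle", "histogram"), breaks = 30) {
  method <- match.arg(method)
  dwells <- dwells[is.finite(dwells)]
  if (length(dwells) == 0) stop("no dwell times supplied")
  if (any(dwells <= 0)) stop("dwell times must be positive")
  if (length(dwells) < 10) stop("need at least 10 dwell times")
  n <- length(dwells)

  if (method == "histogram") {
    h <- graphics::hist(dwells, breaks = breaks, plot = FALSE)
    mids <- h$mids[h$counts > 0]; cts <- h$counts[h$counts > 0]
    fit <- minpack.lm::nlsLM(cts ~ a * exp(-mids / tau),
                             start = list(a = max(cts), tau = mean(dwells)),
                             lower = c(1e-9, 1e-9))
    cf <- summary(fit)$coefficients
    return(list(tau = unname(coef(fit)["tau"]), se = unname(cf["tau", 2]),
                n = n, n_censored = 0L, method = method))
  }

  if (!is.null(censor_limit)) {
    cens <- dwells >= censor_limit
    obs <- pmin(dwells, censor_limit)
    d <- sum(!cens)
    if (d == 0) stop("all dwells censored: tau not identifiable")
    tau <- sum(obs) / d
    list(tau = tau, se = tau / sqrt(d), n = n, n_censored = sum(cens),
         method = "mle_censored")
  } else if (!is.null(dead_time) && dead_time > 0) {
    m <- mean(dwells)
    # invert E[D] = tau * exp(c / tau); monotone increasing in tau
    f <- function(tau) tau * exp(dead_time / tau) - m
    if (m <= dead_time * exp(1))
      stop("mean dwell too close to the dead time: tau not identifiable")
    # E[D] = tau * exp(c/tau) is increasing only for tau > c; root is unique
    # on [c, m]
    tau <- stats::uniroot(f, lower = dead_time, upper = m, tol = 1e-10)$root
    # delta method: dE/dtau = exp(c/tau) (1 - c/tau)
    dEdtau <- exp(dead_time / tau) * (1 - dead_time / tau)
    se_m <- sd(dwells) / sqrt(n)
    list(tau = tau, se = se_m / abs(dEdtau), n = n, n_censored = 0L,
         method = "mle_dead_time")
  } else {
    tau <- mean(dwells)
    list(tau = tau, se = tau / sqrt(n), n = n, n_censored = 0L,
         method = method)
  }
}

#' Average processive velocity of a trace
#'
#' Least-squares slope of position versus time, which is less sensitive to
#' terminal detachment than an endpoint difference.
#'
#' @param trace a [motility_trace].
#' @return list with `v` (nm/s) and `se`.
#' @export
trace_velocity <- function(trace) {
  stopifnot(inherits(trace, "motility_trace"))
  if (diff(range(trace$time)) <= 0) stop("trace has zero duration")
  fit <- lm(position ~ time, data = list(position = trace$position,
                                         time = trace$time))
  cf <- suppressWarnings(summary(fit))$coefficients
  list(v = unname(cf["time", 1]), se = unname(cf["time", 2]))
}

#' Classify initial binding commitment of a trace
#'
#' A trace is `committed` when the enzyme-cellulose bond survives and the
#' enzyme sustains processive motility for at least `motile_threshold`
#' seconds; `unstable` when large excursions (at least `excursion_threshold`
#' from baseline) that return to baseline precede, or replace, motility,
#' indicating repeated desorption before processive motion; `no_binding`
#' otherwise. The classification is invariant to constant position offsets.
#'
#' @param trace a [motility_trace].
#' @param motile_threshold minimum sustained motility duration, s.
#' @param excursion_threshold minimum excursion amplitude, nm.
#' @param min_displacement minimum net displacement to count as motility, nm.
#' @return object of class `commitment_label`: list with `state`,
#'   `motile_duration` (s), `max_excursion` (nm).
#' @export
classify_commitment <- function(trace, motile_threshold = 10,
                                excursion_threshold = 50,
                                min_displacement = 5) {
  stopifnot(inherits(trace, "motility_trace"))
  x <- trace$position
  tt <- trace$time
  n <- length(x)
  # baseline from the first second (or first 5% of samples)
  nb <- max(10L, min(n, as.integer(trace$sample_rate)))
  base <- median(x[seq_len(nb)])
  dev <- x - base
  noise <- mad(diff(x)) / sqrt(2)
  band <- max(3 * noise, 1)

  # smooth on ~0.25 s scale for motility detection
  w <- max(1L, as.integer(trace$sample_rate * 0.25))
  sm <- if (w > 1 && n > 2 * w) {
    stats::filter(dev, rep(1 / w, w), sides = 2)
  } else dev
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- dev[is.na(sm)]

  net <- sm[n] - 0
  motile <- abs(net) >= min_displacement
  onset_idx <- NA_integer_
  if (motile) {
    # last time the smoothed position was still within the baseline band
    at_base <- which(abs(sm) <= band)
    onset_idx <- if (length(at_base)) max(at_base) else 1L
  }
  motile_duration <- if (motile) tt[n] - tt[onset_idx] else 0

  # excursions before motility onset (or anywhere if no motility) that
  # exceed the threshold and later return to baseline
  scan_end <- if (motile) onset_idx else n
  pre <- abs(dev[seq_len(scan_end)])
  max_exc <- if (length(pre)) max(pre) else 0
  spike <- FALSE
  if (max_exc >= excursion_threshold) {
    i_exc <- which(pre >= excursion_threshold)
    # returned to baseline after the last big excursion?
    after <- abs(dev[max(i_exc):scan_end])
    spike <- any(after <= band)
  }

  state <- if (spike) "unstable"
           else if (motile && motile_duration >= motile_threshold) "committed"
           else if (motile) "unstable" # bound and moved, but did not sustain
           else "no_binding"
  structure(list(state = state, motile_duration = motile_duration,
                 max_excursion = max_exc), class = "commitment_label")
}

#' @export
print.commitment_label <- function(x, ...) {
  cat(sprintf("Commitment: %s (motile %.1f s, max excursion %.1f nm)\n",
              x$state, x$motile_duration, x$max_excursion))
  invisible(x)
}

#' Fraction of unstable-binding traces
#'
#' Fraction of `unstable` classifications among traces that showed any
#' binding (`committed` or `unstable`); pure `no_binding` traces are
#' excluded from the denominator.
#'
#' @param labels list of [classify_commitment()] results.
#' @return list with `fraction_unstable`, `n_binding`, `n_total`.
#' @export
instability_summary <- function(labels) {
  if (!length(labels)) stop("empty label list")
  states <- vapply(labels, function(l) l$state, character(1))
  binding <- states != "no_binding"
  n <- sum(binding)
  list(fraction_unstable = if (n) sum(states == "unstable") / n else NA_real_,
       n_binding = n, n_total = length(states))
}
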