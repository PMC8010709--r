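#' Fit a reaction-dominated FRAP recovery curve
#'
#' Nonlinear fit of `intensity(t) = baseline + F_M * (1 - exp(-k_off * t))`,
#' the binding-dominated recovery model that ignores diffusion: the recovery
#' rate is the desorption rate constant `k_off` and the amplitude `F_M` the
#' reversibly bound (mobile) fraction. A curve with no recovery (fitted
#' `F_M` indistinguishable from 0) leaves `k_off` non-identifiable and is
#' flagged rather than errored.
#'
#' @param curve a [kinetic_curve] of kind `"frap"` with time starting at the
#'   bleach (>= 10 samples).
#' @return object of class `frap_fit`: list with `k_off` (s^-1), `F_M`,
#'   `baseline`, `std_errors` (named), `converged`, `identifiable`, `rmse`.
#' @export
fit_frap <- function(curve) {
  stopifnot(inherits(curve, "kinetic_curve"))
  tt <- curve$time; y <- curve$value
  if (length(tt) < 10) stop("need at least 10 post-bleach samples")
  span <- max(y) - min(y)
  start <- list(baseline = min(y), F_M = max(span, 1e-3),
                k_off = 1 / max(diff(range(tt)) / 5, 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ baseline + F_M * (1 - exp(-k_off * tt)),
                      start = start,
                      lower = c(-Inf, 0, 1e-9), upper = c(Inf, 1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k_off = NA_real_, F_M = NA_real_,
                          baseline = NA_real_, std_errors = NULL,
                          converged = FALSE, identifiable = FALSE,
                          rmse = NA_real_), class = "frap_fit"))
  }
  cf <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  fm <- unname(cf["F_M"]); fm_se <- unname(ses["F_M"])
  identifiable <- is.finite(fm) &&
    (fm > 1e-3) && (!is.finite(fm_se) || fm > 2 * fm_se)
  structure(list(k_off = unname(cf["k_off"]), F_M = fm,
                 baseline = unname(cf["baseline"]),
                 std_errors = ses, converged = TRUE,
                 identifiable = identifiable,
                 rmse = sqrt(mean(resid(fit)^2))),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) { cat("FRAP fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf("FRAP fit: k_off = %.4g s^-1, F_M = %.3g, baseline = %.3g%s\n",
              x$k_off, x$F_M, x$baseline,
              if (!x$identifiable) " [k_off non-identifiable: no recovery]" else ""))
  invisible(x)
}

#' Desorption-rate fold change between two FRAP fits
#'
#' @param fit_a,fit_b converged [fit_frap()] results.
#' @return `k_off(b) / k_off(a)`.
#' @export
frap_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "frap_fit"), inherits(fit_b, "frap_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged")
  if (!fit_a$identifiable || !fit_b$identifiable)
    stop("k_off not identifiable in at least one fit")
  fit_b$k_off / fit_a$k_off
}

#' Sauerbrey areal mass from a frequency shift
#'
#' `Delta_m = -C * Delta_f / n` for a rigid adsorbed film at overtone `n`.
#' Negative frequency shifts correspond to mass uptake; a positive shift
#' yields negative mass (net desorption relative to the reference).
#'
#' @param delta_f frequency shift, Hz (can be a vector).
#' @param overtone odd positive overtone number.
#' @param C mass-sensitivity constant, ng cm^-2 Hz^-1 (17.7 for a 5 MHz
#'   sensor).
#' @return areal mass, ng/cm^2.
#' @examples
#' sauerbrey_mass(-30, 3) # 177 ng/cm^2
#' @export
sauerbrey_mass <- function(delta_f, overtone = 3, C = 17.7) {
  if (overtone <= 0 || overtone %% 2 == 0)
    stop("overtone must be odd and positive")
  -C * delta_f / overtone
}

#' Convert areal mass to a molecule count
#'
#' `count = mass * N_A / molar_mass` over the given sensor area.
#'
#' @param areal_mass areal mass, ng/cm^2.
#' @param area sensor area, cm^2.
#' @param molar_mass molar mass, g/mol (> 0).
#' @return number of bound molecules.
#' @export
mass_to_molecules <- function(areal_mass, area, molar_mass) {
  if (molar_mass <= 0) stop("molar_mass must be positive")
  if (area <= 0) stop("area must be positive")
  areal_mass * 1e-9 * area * 6.02214076e23 / molar_mass
}

#' Fit Langmuir kinetics to a QCM-D sensorgram
#'
#' Joint fit of the adsorption and rinse phases in molecule-coverage space.
#' The frequency shift is first converted to bound molecules via
#' [sauerbrey_mass()] and [mass_to_molecules()]; then
#' `Gamma(t) = Gamma_eq (1 - exp(-(k_on_star + k_off) t))` during adsorption,
#' with `Gamma_eq = A k_on_star / (k_on_star + k_off)`, and exponential decay
#' at rate `k_off` after the rinse. Without a rinse phase only the relaxation
#' sum `k_on_star + k_off` is identifiable and the fit is flagged
#' non-separable.
#'
#' @param sensorgram a [kinetic_curve] of kind `"qcmd"`.
#' @param phase_boundaries numeric `c(start, rinse_start, end)`, s. If
#'   `rinse_start >= end` the data are treated as adsorption-only.
#' @param molar_mass molar mass of the construct, g/mol (required).
#' @param area sensor area, cm^2.
#' @param sauerbrey_c Sauerbrey constant, ng cm^-2 Hz^-1.
#' @return object of class `qcmd_fit`: list with `k_on_star`, `k_off` (s^-1),
#'   `A` (molecules), `std_errors`, `separable`, `converged`, `rmse`
#'   (molecules).
#' @export
fit_qcmd <- function(sensorgram, phase_boundaries, molar_mass, area = 0.2,
                     sauerbrey_c = 17.7) {
  stopifnot(inherits(sensorgram, "kinetic_curve"))
  if (sensorgram$kind != "qcmd") stop("expected a QCM-D sensorgram")
  if (length(phase_boundaries) != 3) stop("phase_boundaries must be c(start, rinse_start, end)")
  t0 <- phase_boundaries[1]; t1 <- phase_boundaries[2]; t2 <- phase_boundaries[3]
  if (t1 <= t0) stop("rinse_start must follow the adsorption start")
  ov <- if (is.na(sensorgram$overtone)) 3 else sensorgram$overtone
  tt <- sensorgram$time
  gamma <- mass_to_molecules(sauerbrey_mass(sensorgram$value, ov, sauerbrey_c),
                             area, molar_mass)
  has_rinse <- t1 < t2 && any(tt >= t1)

  if (!has_rinse) {
    # adsorption-only: fit Gamma_eq (1 - exp(-krel t)); krel = k_on* + k_off
    fit <- minpack.lm::nlsLM(gamma ~ geq * (1 - exp(-krel * (tt - t0))),
                             start = list(geq = max(gamma), krel = 1 /
                                            max((t1 - t0) / 5, 1e-6)),
                             lower = c(1e-12, 1e-12))
    cf <- coef(fit)
    return(structure(list(k_on_star = NA_real_, k_off = NA_real_,
                          A = NA_real_,
                          relaxation_rate = unname(cf["krel"]),
                          gamma_eq = unname(cf["geq"]),
                          std_errors = summary(fit)$coefficients[, 2],
                          separable = FALSE, converged = TRUE,
                          rmse = sqrt(mean(resid(fit)^2))),
                     class = "qcmd_fit"))
  }

  ads <- tt < t1
  model <- function(p, tt) {
    krel <- p[1] + p[2]
    geq <- p[3] * p[1] / krel
    g <- numeric(length(tt))
    g[ads] <- geq * (1 - exp(-krel * (tt[ads] - t0)))
    g_r <- geq * (1 - exp(-krel * (t1 - t0)))
    g[!ads] <- g_r * exp(-p[2] * (tt[!ads] - t1))
    g
  }
  residfun <- function(p) gamma - model(p, tt)
  k0 <- 1 / max((t1 - t0) / 5, 1e-6)
  start <- c(k0, k0 / 10, max(gamma) * 1.2)
  out <- minpack.lm::nls.lm(par = start, fn = residfun,
                            lower = c(1e-12, 1e-12, 1e-12),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- out$par
  # covariance from the Jacobian at the optimum
  ses <- tryCatch({
    s2 <- sum(out$fvec^2) / (length(gamma) - 3)
    sqrt(diag(s2 * solve(out$hessian)))
  }, error = function(e) rep(NA_real_, 3))
  structure(list(k_on_star = p[1], k_off = p[2], A = p[3],
                 std_errors = setNames(ses, c("k_on_star", "k_off", "A")),
                 separable = TRUE, converged = out$info %in% 1:4,
                 rmse = sqrt(mean(out$fvec^2))),
            class = "qcmd_fit")
}

#' @export
print.qcmd_fit <- function(x, ...) {
  if (!x$separable) {
    cat(sprintf("QCM-D fit (adsorption only, non-separable): k_on*+k_off = %.4g s^-1\n",
                x$relaxation_rate))
  } else {
    cat(sprintf("QCM-D fit: k_on* = %.4g s^-1, k_off = %.4g s^-1, A = %.4g molecules\n",
                x$k_on_star, x$k_off, x$A))
  }
  invisible(x)
}
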