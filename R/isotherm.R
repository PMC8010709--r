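#' Evaluate an adsorption isotherm model
#'
#' The three adsorption models used for CBM-cellulose pull-down data:
#' \describe{
#'   \item{one_site}{`B = n_max * F / (K_d + F)`}
#'   \item{two_site}{`B = n_max_1 * F / (K_d_1 + F) + n_max_2 * F / (K_d_2 + F)`}
#'   \item{langmuir_freundlich}{`B = n_max * F^m / (K_d^m + F^m)`, so that
#'     `F = K_d` gives half-saturation and `K_d` keeps concentration units}
#' }
#'
#' @param model_id one of `"one_site"`, `"two_site"`,
#'   `"langmuir_freundlich"` (alias `"lf"`).
#' @param params named list/vector of parameters: `n_max`, `K_d` (one-site);
#'   `n_max_1`, `K_d_1`, `n_max_2`, `K_d_2` (two-site); `n_max`, `K_d`, `m`
#'   (Langmuir-Freundlich).
#' @param F free protein concentration(s), uM, >= 0.
#' @return bound protein, umol/g cellulose, same length as `F`.
#' @examples
#' eval_isotherm("one_site", c(n_max = 4.34, K_d = 8.69), 8.69) # 2.17
#' @export
eval_isotherm <- function(model_id, params, F) {
  model_id <- normalize_model_id(model_id)
  if (any(F < 0)) stop("free concentration must be non-negative")
  p <- as.list(params)
  check_iso_params(model_id, p)
  switch(model_id,
    one_site = p$n_max * F / (p$K_d + F),
    two_site = p$n_max_1 * F / (p$K_d_1 + F) + p$n_max_2 * F / (p$K_d_2 + F),
    langmuir_freundlich = {
      # F = 0 handled explicitly so 0^m never produces NaN for small m
      B <- numeric(length(F))
      pos <- F > 0
      B[pos] <- p$n_max * F[pos]^p$m / (p$K_d^p$m + F[pos]^p$m)
      B
    })
}

normalize_model_id <- function(model_id) {
  id <- switch(as.character(model_id),
               one_site = "one_site", two_site = "two_site",
               lf = "langmuir_freundlich",
               langmuir_freundlich = "langmuir_freundlich",
               stop("unknown model_id: ", model_id))
  id
}

iso_param_names <- function(model_id) {
  switch(model_id,
         one_site = c("n_max", "K_d"),
         two_site = c("n_max_1", "K_d_1", "n_max_2", "K_d_2"),
         langmuir_freundlich = c("n_max", "K_d", "m"))
}

check_iso_params <- function(model_id, p) {
  need <- iso_param_names(model_id)
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing isotherm parameters: ",
                         paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (any(!is.finite(vals)) || any(vals[grep("^n_max|^K_d", need)] <= 0))
    stop("n_max and K_d parameters must be positive and finite")
  if ("m" %in% need && (p$m <= 0 || p$m > 2))
    stop("Freundlich power m must lie in (0, 2]")
  invisible(TRUE)
}

#' Fit an adsorption isotherm by nonlinear least squares
#'
#' Unweighted nonlinear regression of bound vs free protein with multi-start
#' initialisation: `K_d` starts are log-spaced across the observed free range
#' and the best-RMSE converged fit is kept. Parameter standard errors come
#' from the Jacobian-based covariance at the optimum. Two-site fits are
#' reported with sites ordered `K_d_1 >= K_d_2` (low-affinity site first).
#'
#' @param dataset an [adsorption_data] object.
#' @param model_id model identifier, see [eval_isotherm()].
#' @param init optional named list of starting values (replaces multi-start).
#' @param n_starts number of log-spaced `K_d` starting values.
#' @return object of class `isotherm_fit`: list with `model_id`, `params`
#'   (named vector), `std_errors`, `rmse`, `converged`, `n_points`, and the
#'   underlying `nls` fit.
#' @export
fit_isotherm <- function(dataset, model_id, init = NULL, n_starts = 8) {
  stopifnot(inherits(dataset, "adsorption_data"))
  model_id <- normalize_model_id(model_id)
  pnames <- iso_param_names(model_id)
  F <- dataset$free; B <- dataset$bound
  n <- length(F)
  if (n < 2 * length(pnames))
    stop("need at least ", 2 * length(pnames), " points to fit ", model_id)
  if (all(B == 0)) stop("all bound values are zero: model not identifiable")
  if (sd(B) == 0) stop("constant bound values: model not identifiable")

  starts <- if (!is.null(init)) list(as.list(init)) else
    iso_start_grid(model_id, F, B, n_starts)
  lower <- setNames(rep(1e-8, length(pnames)), pnames)
  upper <- setNames(rep(Inf, length(pnames)), pnames)
  if ("m" %in% pnames) upper["m"] <- 2

  form <- switch(model_id,
    one_site = B ~ n_max * F / (K_d + F),
    two_site = B ~ n_max_1 * F / (K_d_1 + F) + n_max_2 * F / (K_d_2 + F),
    langmuir_freundlich = B ~ n_max * ifelse(F > 0, F^m / (K_d^m + F^m), 0))
  dat <- data.frame(F = F, B = B)

  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st[pnames],
                        lower = lower[pnames], upper = upper[pnames],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }

  if (is.null(best)) {
    return(structure(list(model_id = model_id,
                          params = setNames(rep(NA_real_, length(pnames)), pnames),
                          std_errors = NULL, rmse = NA_real_,
                          converged = FALSE, n_points = n, fit = NULL),
                     class = "isotherm_fit"))
  }

  params <- coef(best)
  ses <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, length(params)),
                                               names(params)))
  if (model_id == "two_site" && params["K_d_1"] < params["K_d_2"]) {
    swap <- c("n_max_2", "K_d_2", "n_max_1", "K_d_1")
    params <- setNames(params[swap], pnames)
    ses <- setNames(ses[swap], pnames)
  }
  structure(list(model_id = model_id, params = params[pnames],
                 std_errors = ses[pnames],
                 rmse = sqrt(mean(resid(best)^2)),
                 converged = TRUE, n_points = n, fit = best),
            class = "isotherm_fit")
}

iso_start_grid <- function(model_id, F, B, n_starts) {
  fpos <- F[F > 0]
  kd_grid <- exp(seq(log(max(min(fpos) / 2, 1e-3)), log(max(fpos) * 2),
                     length.out = n_starts))
  nmax0 <- max(B) * 1.1
  lapply(kd_grid, function(kd) switch(model_id,
    one_site = list(n_max = nmax0, K_d = kd),
    two_site = list(n_max_1 = 0.8 * nmax0, K_d_1 = kd,
                    n_max_2 = 0.2 * nmax0, K_d_2 = kd / 20),
    langmuir_freundlich = list(n_max = nmax0, K_d = kd, m = 0.8)))
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Isotherm fit [%s], n=%d, converged=%s, RMSE=%.4g umol/g\n",
              x$model_id, x$n_points, x$converged, x$rmse))
  if (x$converged) {
    tab <- data.frame(estimate = x$params, se = x$std_errors)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Partition coefficient from the initial linear region of a binding curve
#'
#' The partition coefficient is the slope (through the origin) of bound vs
#' free protein restricted to the low-concentration linear region
#' `F <= max_free`. For one-site Langmuir data it converges to `n_max / K_d`
#' as `max_free -> 0`.
#'
#' @param dataset an [adsorption_data] object.
#' @param max_free upper free-concentration bound of the linear region, uM.
#' @return list with `slope` (L/g), `se`, `n_points`, `max_free`.
#' @export
partition_coefficient <- function(dataset, max_free) {
  stopifnot(inherits(dataset, "adsorption_data"), max_free > 0)
  keep <- dataset$free <= max_free
  if (sum(keep) < 3)
    stop("need at least 3 points with free <= ", max_free, " uM")
  F <- dataset$free[keep]; B <- dataset$bound[keep]
  fit <- lm(B ~ F + 0)
  list(slope = unname(coef(fit)[1]),
       se = unname(summary(fit)$coefficients[1, 2]),
       n_points = sum(keep), max_free = max_free)
}

#' Truncation-sensitivity analysis of isotherm fits
#'
#' Refits the model after discarding points above each free-concentration
#' cutoff, alongside the full-data fit. On datasets that do not reach full
#' saturation, truncation systematically shrinks the apparent `n_max` and
#' inflates parameter standard errors.
#'
#' @param dataset an [adsorption_data] object.
#' @param cutoffs positive free-concentration cutoffs, uM.
#' @param model_id model identifier, see [eval_isotherm()].
#' @param ... passed to [fit_isotherm()].
#' @return named list of `isotherm_fit` objects: `"full"` plus one per cutoff.
#' @export
truncate_and_fit <- function(dataset, cutoffs, model_id, ...) {
  stopifnot(all(cutoffs > 0))
  out <- list(full = fit_isotherm(dataset, model_id, ...))
  for (ct in cutoffs) {
    keep <- dataset$free <= ct
    if (!any(keep)) stop("cutoff ", ct, " uM excludes all points")
    sub <- adsorption_data(dataset$free[keep], dataset$bound[keep],
                           dataset$protein, dataset$substrate)
    out[[sprintf("%g", ct)]] <- fit_isotherm(sub, model_id, ...)
  }
  out
}

#' Scatchard curvature diagnostic
#'
#' Transforms the dataset to Scatchard coordinates (`B/F` vs `B`) and fits a
#' quadratic. A one-site Langmuir isotherm is exactly linear in these
#' coordinates; concave-up curvature (positive quadratic coefficient) is the
#' classic signature of multiple non-equivalent or overlapping binding-site
#' classes. Points with `F = 0` are excluded with a warning.
#'
#' @param dataset an [adsorption_data] object.
#' @return list with `points` (data frame `B`, `B_over_F`), `curvature`
#'   (quadratic coefficient), `curvature_se`, `curvature_sign` (-1, 0, +1;
#'   0 when |coef| < 2 SE).
#' @export
scatchard_diagnostic <- function(dataset) {
  stopifnot(inherits(dataset, "adsorption_data"))
  keep <- dataset$free > 0
  if (any(!keep)) warning(sum(!keep), " points with F = 0 excluded from Scatchard plot")
  F <- dataset$free[keep]; B <- dataset$bound[keep]
  if (length(F) < 4) stop("need at least 4 points with F > 0")
  y <- B / F
  fit <- lm(y ~ B + I(B^2))
  # noiseless input gives a numerically perfect fit; that is fine here
  cf <- suppressWarnings(summary(fit))$coefficients
  curv <- cf["I(B^2)", "Estimate"]; se <- cf["I(B^2)", "Std. Error"]
  # numerically-zero curvature (exactly linear Scatchard) counts as flat
  tol0 <- 1e-8 * max(abs(y)) / max(abs(B))^2
  sign_out <- if (abs(curv) < tol0 || (is.finite(se) && abs(curv) < 2 * se))
    0L else as.integer(sign(curv))
  list(points = data.frame(B = B, B_over_F = y),
       curvature = curv, curvature_se = se, curvature_sign = sign_out)
}

#' Affinity fold change between two isotherm fits
#'
#' Ratio `K_d(b) / K_d(a)` for the selected site: a value above 1 means
#' substrate/fit `b` binds more weakly.
#'
#' @param fit_a,fit_b `isotherm_fit` objects with the same `model_id`.
#' @param site for two-site fits: `"low_affinity"` (site 1, large `K_d`) or
#'   `"high_affinity"` (site 2); ignored otherwise.
#' @return numeric fold change.
#' @export
affinity_fold_change <- function(fit_a, fit_b,
                                 site = c("high_affinity", "low_affinity")) {
  site <- match.arg(site)
  stopifnot(inherits(fit_a, "isotherm_fit"), inherits(fit_b, "isotherm_fit"))
  if (fit_a$model_id != fit_b$model_id)
    stop("fits use different models: ", fit_a$model_id, " vs ", fit_b$model_id)
  key <- if (fit_a$model_id == "two_site") {
    if (site == "high_affinity") "K_d_2" else "K_d_1"
  } else "K_d"
  unname(fit_b$params[key] / fit_a$params[key])
}
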