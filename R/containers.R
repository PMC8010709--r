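#' Construct a bead-position motility trace
#'
#' A uniformly sampled bead-displacement time series from an optical-tweezer
#' motility assay. `position` is the bead displacement from the trap center
#' (nm).
#'
#' @param time numeric vector, seconds, uniform grid.
#' @param position numeric vector, nm, same length as `time`.
#' @param sample_rate sampling rate in Hz; inferred from `time` if `NULL`.
#' @param label optional character label (substrate, construct).
#' @return an object of class `motility_trace` with elements `time`,
#'   `position`, `sample_rate`, `label`.
#' @export
motility_trace <- function(time, position, sample_rate = NULL, label = "") {
  stopifnot(length(time) == length(position), length(time) >= 2)
  if (!all(is.finite(time)) || !all(is.finite(position)))
    stop("trace must contain finite values only")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1e-12)))
    stop("time grid must be uniform")
  if (is.null(sample_rate)) sample_rate <- 1 / dt[1]
  structure(list(time = as.numeric(time), position = as.numeric(position),
                 sample_rate = sample_rate, label = label),
            class = "motility_trace")
}

#' @export
print.motility_trace <- function(x, ...) {
  cat(sprintf("Motility trace%s: %d samples at %g Hz, %.3g s, net %.2f nm\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$time), x$sample_rate,
              x$time[length(x$time)] - x$time[1],
              x$position[length(x$position)] - x$position[1]))
  invisible(x)
}

#' Construct an adsorption dataset
#'
#' Paired (free, bound) observations from a solid-depletion (pull-down)
#' protein-polysaccharide binding assay.
#'
#' @param free free protein concentration, uM.
#' @param bound bound protein, umol per g cellulose.
#' @param protein,substrate optional labels.
#' @return object of class `adsorption_data`.
#' @export
adsorption_data <- function(free, bound, protein = "", substrate = "") {
  stopifnot(length(free) == length(bound))
  if (any(free < 0) || any(bound < 0))
    stop("free and bound concentrations must be non-negative")
  if (!all(is.finite(free)) || !all(is.finite(bound)))
    stop("free and bound must be finite")
  structure(list(free = as.numeric(free), bound = as.numeric(bound),
                 protein = protein, substrate = substrate),
            class = "adsorption_data")
}

#' @export
print.adsorption_data <- function(x, ...) {
  cat(sprintf("Adsorption dataset %s/%s: %d points, free %.3g-%.3g uM\n",
              x$protein, x$substrate, length(x$free),
              min(x$free), max(x$free)))
  invisible(x)
}

#' Construct a rupture event set
#'
#' Single CBM-cellulose bond rupture observations: the force loaded across the
#' bond at rupture and the total bond lifetime.
#'
#' @param force rupture force, pN (>= 0).
#' @param lifetime bond lifetime, s (> 0).
#' @param substrate,construct optional labels.
#' @return object of class `rupture_events`.
#' @export
rupture_events <- function(force, lifetime, substrate = "", construct = "") {
  stopifnot(length(force) == length(lifetime))
  if (any(force < 0)) stop("forces must be non-negative")
  if (any(lifetime <= 0)) stop("lifetimes must be positive")
  structure(list(force = as.numeric(force), lifetime = as.numeric(lifetime),
                 substrate = substrate, construct = construct),
            class = "rupture_events")
}

#' @export
print.rupture_events <- function(x, ...) {
  cat(sprintf("Rupture events %s/%s: n=%d, force %.2f-%.2f pN, mean lifetime %.3g s\n",
              x$substrate, x$construct, length(x$force),
              min(x$force), max(x$force), mean(x$lifetime)))
  invisible(x)
}

#' Construct a kinetic curve (FRAP or QCM-D)
#'
#' @param time time, s.
#' @param value normalized fluorescence intensity (FRAP) or frequency shift
#'   Delta-f in Hz (QCM-D).
#' @param kind `"frap"` or `"qcmd"`.
#' @param overtone odd overtone number for QCM-D curves.
#' @param label optional label.
#' @return object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(time, value, kind = c("frap", "qcmd"),
                          overtone = NA_integer_, label = "") {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(value))
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 kind = kind, overtone = overtone, label = label),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("%s curve%s: %d samples over %.3g s\n",
              toupper(x$kind),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$time), max(x$time) - min(x$time)))
  invisible(x)
}

#' Construct a powder XRD pattern
#'
#' @param two_theta Bragg angle 2-theta grid, degrees, strictly increasing.
#' @param intensity intensities, arbitrary units, >= 0 and finite.
#' @param allomorph `"cellulose_I"`, `"cellulose_III"` or `"unknown"`.
#' @return object of class `xrd_pattern`.
#' @export
xrd_pattern <- function(two_theta, intensity,
                        allomorph = c("unknown", "cellulose_I", "cellulose_III")) {
  allomorph <- match.arg(allomorph)
  stopifnot(length(two_theta) == length(intensity))
  if (any(diff(two_theta) <= 0)) stop("two_theta grid must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(two_theta = as.numeric(two_theta),
                 intensity = as.numeric(intensity), allomorph = allomorph),
            class = "xrd_pattern")
}

#' @export
print.xrd_pattern <- function(x, ...) {
  cat(sprintf("XRD pattern (%s): %d points, 2theta %.1f-%.1f deg\n",
              x$allomorph, length(x$two_theta),
              min(x$two_theta), max(x$two_theta)))
  invisible(x)
}

#' Read/write helpers for the standard CSV layouts
#'
#' Columns follow the documented headers: `time_s, position_nm` (traces),
#' `force_pN, lifetime_s` (rupture events), `free_uM, bound_umol_g`
#' (adsorption), `time_s, intensity` (FRAP), `time_s, delta_f_Hz` (QCM-D),
#' `two_theta_deg, intensity` (XRD).
#'
#' @param x object to write.
#' @param path CSV path.
#' @return `read_*` return the corresponding object; `write_*` return `path`
#'   invisibly.
#' @name binding_io
NULL

#' @rdname binding_io
#' @export
write_trace_csv <- function(x, path) {
  write.csv(data.frame(time_s = x$time, position_nm = x$position),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  motility_trace(d$time_s, d$position_nm)
}

#' @rdname binding_io
#' @export
write_adsorption_csv <- function(x, path) {
  write.csv(data.frame(free_uM = x$free, bound_umol_g = x$bound),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_adsorption_csv <- function(path) {
  d <- read.csv(path)
  adsorption_data(d$free_uM, d$bound_umol_g)
}

#' @rdname binding_io
#' @export
write_rupture_csv <- function(x, path) {
  write.csv(data.frame(force_pN = x$force, lifetime_s = x$lifetime),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_rupture_csv <- function(path) {
  d <- read.csv(path)
  rupture_events(d$force_pN, d$lifetime_s)
}

#' @rdname binding_io
#' @export
write_kinetic_csv <- function(x, path) {
  col <- if (x$kind == "qcmd") "delta_f_Hz" else "intensity"
  d <- setNames(data.frame(x$time, x$value), c("time_s", col))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_kinetic_csv <- function(path) {
  d <- read.csv(path)
  if ("delta_f_Hz" %in% names(d)) kinetic_curve(d$time_s, d$delta_f_Hz, "qcmd")
  else kinetic_curve(d$time_s, d$intensity, "frap")
}

#' @rdname binding_io
#' @export
write_xrd_csv <- function(x, path) {
  write.csv(data.frame(two_theta_deg = x$two_theta, intensity = x$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_xrd_csv <- function(path) {
  d <- read.csv(path)
  xrd_pattern(d$two_theta_deg, d$intensity)
}
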