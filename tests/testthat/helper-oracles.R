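# Shared fixtures and independent oracles, built in code.

# One-to-one greedy matching of detected to true step times within `tol`
# seconds; returns c(n_matched, n_true).
match_steps <- function(true_times, detected_times, tol = 0.15) {
  if (!length(true_times)) return(c(0L, 0L))
  used <- rep(FALSE, length(detected_times))
  hits <- 0L
  for (tt in true_times) {
    d <- abs(detected_times - tt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  c(hits, length(true_times))
}

# Noiseless deterministic staircase trace: n_steps steps of `size` nm
# separated by `dwell` s plateaus.
make_staircase <- function(n_steps = 10, size = 1.0, dwell = 1.0,
                           sample_rate = 200, pad = 2) {
  duration <- pad + n_steps * dwell + pad
  tt <- seq(0, duration, by = 1 / sample_rate)
  step_times <- pad + dwell * (seq_len(n_steps) - 1)
  pos <- size * findInterval(tt, step_times)
  motility_trace(tt, pos, sample_rate)
}

# Study-system one-site reference parameters used across tests.
ref_one_site <- list(
  cellulose_I = c(n_max = 4.34, K_d = 8.69),
  cellulose_III = c(n_max = 3.32, K_d = 10.55))

# Build an isotherm_fit object from known parameters (for fold-change
# arithmetic on printed values).
fake_iso_fit <- function(model_id, params) {
  structure(list(model_id = model_id, params = unlist(params),
                 std_errors = NULL, rmse = 0, converged = TRUE,
                 n_points = NA_integer_, fit = NULL),
            class = "isotherm_fit")
}
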