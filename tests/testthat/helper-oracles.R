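# Independent dense-step reference integrator: forward-Euler voltage update,
# exact exponential conductance decay, same arrival binning semantics as the
# package core (decay, then jumps, then the voltage step). No spiking.
# Deliberately written against the equations, not the package internals.
fe_reference <- function(spec, trains, dt_ms = 0.001) {
  horizon <- train_horizon(trains)
  n_steps <- ceiling(horizon / dt_ms)
  n_groups <- length(spec$groups)
  tau_s <- vapply(spec$groups, `[[`, numeric(1), "tau_s_ms")
  E_s <- vapply(spec$groups, `[[`, numeric(1), "E_s_mV")
  amp <- spec$drive_scale * vapply(spec$groups, `[[`, numeric(1), "g_max_pS")
  additive <- vapply(spec$groups, function(g)
    g$jump_mode == "additive_unbounded", logical(1))
  m <- spec$membrane

  arr_step <- floor(trains$time_ms / dt_ms) + 1
  arr_group <- as.integer(spec$mapping[trains$source_id])
  ord <- order(arr_step, trains$source_id)
  arr_step <- arr_step[ord]
  arr_group <- arr_group[ord]

  g <- numeric(n_groups)
  decay <- exp(-dt_ms / tau_s)
  v <- m$v_rest_mV
  v_peak <- -Inf
  a <- 1
  for (k in seq_len(n_steps)) {
    g <- g * decay
    while (a <= length(arr_step) && arr_step[a] == k) {
      j <- arr_group[a]
      g[j] <- if (additive[j]) g[j] + amp[j] else amp[j]
      a <- a + 1
    }
    drive <- m$R_MOhm * 1e-6 * sum(g * (E_s - v))
    v <- v + dt_ms / m$tau_ms * (-(v - m$v_rest_mV) + drive)
    if (v > v_peak) v_peak <- v
  }
  v_peak
}

# the four task patterns of the 4-input compact feature binding problem,
# in truth-table row order
cfbp_patterns <- function() c("0011", "1100", "0101", "1010")

# all 2^(2^n) complete truth tables over n inputs
all_full_tables <- function(n) {
  pats <- apply(as.matrix(expand.grid(rep(list(0:1), n))), 1,
                paste, collapse = "")
  lapply(seq_len(2^(2^n)) - 1, function(k) {
    bits <- as.integer(intToBits(k))[seq_along(pats)]
    boolean_table(pats, bits)
  })
}
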