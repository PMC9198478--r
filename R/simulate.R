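#' Advance grouped synaptic conductances by one time step
#'
#' Each group first decays by the exact factor `exp(-dt/tau_s)`, then every
#' arriving spike is applied: `"set_to_max"` groups jump to their ceiling
#' `drive_scale * g_max_pS` (so they can never exceed it), while
#' `"additive_unbounded"` groups gain `drive_scale * g_max_pS` per spike.
#'
#' @param state Numeric vector of per-group conductances (pS), one per group.
#' @param dt_ms Time step (ms), > 0.
#' @param arrivals Named integer vector of spike counts; names are input
#'   source ids (must exist in `spec$mapping`). May be empty.
#' @param spec A [neuron_spec()].
#'
#' @return Numeric vector of updated per-group conductances (pS).
#' @export
#' @examples
#' spec <- sif_neuron()
#' update_conductances(c(100, 0), dt_ms = 1, arrivals = integer(), spec)
#' update_conductances(c(36.79, 0), 1, c(`1` = 1), spec)  # jumps back to 100
update_conductances <- function(state, dt_ms, arrivals, spec) {
  stopifnot(inherits(spec, "neuron_spec"), dt_ms > 0,
            length(state) == length(spec$groups))
  if (any(state < 0)) {
    abort("negative conductance state", class = "satif_error_state")
  }
  for (j in seq_along(state)) {
    state[j] <- state[j] * exp(-dt_ms / spec$groups[[j]]$tau_s_ms)
  }
  if (length(arrivals) > 0) {
    src <- names(arrivals)
    unknown <- setdiff(src, names(spec$mapping))
    if (length(unknown) > 0) {
      abort(paste0("unknown input source id(s): ",
                   paste(unknown, collapse = ", ")),
            class = "satif_error_mapping")
    }
    # ascending source order for reproducibility under simultaneity
    for (s in src[order(src)]) {
      j <- spec$mapping[[s]]
      grp <- spec$groups[[j]]
      amp <- spec$drive_scale * grp$g_max_pS
      if (grp$jump_mode == "additive_unbounded") {
        state[j] <- state[j] + arrivals[[s]] * amp
      } else {
        state[j] <- amp
      }
    }
  }
  state
}

#' Advance the membrane voltage by one time step
#'
#' Integrates \eqn{\tau \, dv/dt = -(v - v_{rest}) + R\, g_{tot}\,(E_s - v)}
#' over `dt_ms` with the total conductance held constant, using the exact
#' solution of the resulting affine ODE (exponential Euler). With
#' `g_total_pS = 0` the voltage relaxes towards rest; with constant drive and
#' `dt_ms` large it converges to the fixed point
#' \eqn{(v_{rest} + R g E_s)/(1 + R g)}.
#'
#' @param v_mV Current membrane voltage (mV).
#' @param g_total_pS Total synaptic conductance (pS), held constant over the
#'   step.
#' @param dt_ms Time step (ms), > 0.
#' @param membrane A [membrane_params()] object.
#' @param E_s_mV Synaptic reversal potential (mV).
#'
#' @return The voltage after one step (mV).
#' @export
#' @examples
#' step_voltage(-60, 0, dt_ms = 20, membrane_params())  # relaxes toward -65
step_voltage <- function(v_mV, g_total_pS, dt_ms, membrane, E_s_mV = 0) {
  stopifnot(inherits(membrane, "membrane_params"), dt_ms > 0)
  rg <- membrane$R_MOhm * g_total_pS * 1e-6  # MOhm * pS, dimensionless
  A <- 1 + rg
  v_inf <- (membrane$v_rest_mV + rg * E_s_mV) / A
  v_inf + (v_mV - v_inf) * exp(-A * dt_ms / membrane$tau_ms)
}

#' Simulate a neuron driven by input spike trains
#'
#' Time-stepped composition of [update_conductances()] and [step_voltage()]
#' (both applied in exact/exponential-Euler form, the conductance frozen over
#' each step). Whenever the voltage reaches the threshold at a step boundary
#' a somatic spike is recorded and the voltage is reset; conductances are
#' *not* reset at somatic spikes. Input spikes are binned onto the step grid
#' (a spike at time `t` acts during the step ending at
#' `(floor(t/dt)+1)*dt`).
#'
#' @param spec A [neuron_spec()].
#' @param trains A [spike_trains()] object; source ids must appear in
#'   `spec$mapping`.
#' @param dt_ms Integration step (ms); must satisfy
#'   `dt_ms <= min(tau_s_ms)/5` so the fastest synaptic decay is resolved.
#' @param spiking If `FALSE`, the threshold/reset rule is disabled and the
#'   free subthreshold (or suprathreshold) voltage is returned — used by
#'   [calibrate()] to measure peak depolarisations.
#'
#' @return An object of class `sif_sim`: a list with `dt_ms`, `time_ms`,
#'   `voltage_mV`, `conductance_pS` (matrix, one column per group),
#'   `spike_times_ms`, `horizon_ms` and the `spec` used. See [tidy.sif_sim()]
#'   and [glance.sif_sim()].
#' @export
#' @examples
#' spec <- sif_neuron()
#' trains <- generate_single_spike_trains("1010", t0_ms = 10, horizon_ms = 50)
#' sim <- run_simulation(spec, trains)
#' glance(sim)
run_simulation <- function(spec, trains, dt_ms = 0.1, spiking = TRUE) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(trains, "spike_trains"))
  tau_s <- vapply(spec$groups, `[[`, numeric(1), "tau_s_ms")
  if (dt_ms <= 0 || dt_ms > min(tau_s) / 5) {
    abort(sprintf("dt_ms must be in (0, min(tau_s)/5] = (0, %g] ms", min(tau_s) / 5),
          class = "satif_error_resolution")
  }
  horizon <- train_horizon(trains)
  n_steps <- as.integer(ceiling(horizon / dt_ms))
  if (n_steps < 1) {
    abort("empty horizon", class = "satif_error_empty")
  }
  unknown <- setdiff(unique(trains$source_id), names(spec$mapping))
  if (length(unknown) > 0) {
    abort(paste0("unknown input source id(s): ", paste(unknown, collapse = ", ")),
          class = "satif_error_mapping")
  }

  # bin arrivals, ordered by (step, source id) for deterministic application
  if (nrow(trains) > 0) {
    ord <- order(floor(trains$time_ms / dt_ms), trains$source_id)
    arr_step <- as.integer(floor(trains$time_ms / dt_ms) + 1)[ord]
    arr_group <- as.integer(spec$mapping[trains$source_id])[ord]
  } else {
    arr_step <- integer(0)
    arr_group <- integer(0)
  }

  m <- spec$membrane
  core <- .sif_run_core(
    n_steps = n_steps, dt = dt_ms,
    tau = m$tau_ms, v_rest = m$v_rest_mV, R = m$R_MOhm,
    v_threshold = m$v_threshold_mV, v_reset = m$v_reset_mV,
    E_s = vapply(spec$groups, `[[`, numeric(1), "E_s_mV"),
    tau_s = tau_s,
    g_jump = spec$drive_scale *
      vapply(spec$groups, `[[`, numeric(1), "g_max_pS"),
    additive = vapply(spec$groups, function(g)
      g$jump_mode == "additive_unbounded", logical(1)),
    arr_step = arr_step, arr_group = arr_group,
    spiking = spiking
  )
  colnames(core$conductance_pS) <- paste0("g", seq_along(spec$groups))
  structure(
    list(dt_ms = dt_ms, time_ms = seq_len(n_steps) * dt_ms,
         voltage_mV = core$voltage_mV,
         conductance_pS = core$conductance_pS,
         spike_times_ms = core$spike_times_ms,
         horizon_ms = horizon, spec = spec, spiking = spiking),
    class = "sif_sim"
  )
}

#' @export
print.sif_sim <- function(x, ...) {
  cat(sprintf(
    "<sif_sim: %g ms at dt %g ms, %d somatic spike(s), peak V %.4f mV, peak total g %.2f pS>\n",
    x$horizon_ms, x$dt_ms, length(x$spike_times_ms), max(x$voltage_mV),
    max(rowSums(x$conductance_pS))))
  invisible(x)
}

#' Tidy a simulation result into a per-sample tibble
#'
#' @param x A `sif_sim` object.
#' @param ... Unused.
#' @return A tibble with `time_ms`, `voltage_mV` and one `g<j>_pS` column per
#'   conductance group.
#' @export
tidy.sif_sim <- function(x, ...) {
  g <- tibble::as_tibble(x$conductance_pS)
  names(g) <- paste0(names(g), "_pS")
  dplyr::bind_cols(
    tibble::tibble(time_ms = x$time_ms, voltage_mV = x$voltage_mV), g)
}

#' One-row summary of a simulation result
#'
#' @param x A `sif_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: spike count, mean somatic rate (Hz), peak
#'   voltage (mV), peak total and per-group peak conductance (pS).
#' @export
glance.sif_sim <- function(x, ...) {
  tibble::tibble(
    n_spikes = length(x$spike_times_ms),
    mean_rate_hz = length(x$spike_times_ms) / x$horizon_ms * 1000,
    peak_voltage_mV = max(x$voltage_mV),
    peak_total_g_pS = max(rowSums(x$conductance_pS)),
    peak_group_g_pS = max(x$conductance_pS)
  )
}

#' Plot a simulation: voltage trace over grouped conductances
#'
#' @param object A `sif_sim` object.
#' @param ... Unused.
#' @return A ggplot object (voltage and conductance panels stacked).
#' @export
autoplot.sif_sim <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(-"time_ms", names_to = "trace", values_to = "value") |>
    dplyr::mutate(panel = ifelse(.data$trace == "voltage_mV",
                                 "voltage (mV)", "conductance (pS)"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$spike_times_ms,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
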