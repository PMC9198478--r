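#' Configuration of a truth-table stimulation protocol
#'
#' One episode is simulated per truth-table row. In `"spike"` mode a row is
#' delivered as simultaneous single spikes on its active inputs
#' ([generate_single_spike_trains()]); in `"rate"` mode each active input
#' fires a Poisson train ([generate_poisson_trains()]) at `active_rate_hz`
#' with within-episode synchrony `sync`. Episodes are simulated
#' independently (full state reset between episodes) when
#' `inter_episode_reset` is `TRUE`.
#'
#' @param table A [boolean_table()] to be realised.
#' @param mode `"spike"` or `"rate"`.
#' @param active_rate_hz Rate of active inputs in rate mode (Hz), > 0.
#' @param episode_ms Episode duration (ms).
#' @param t0_ms Spike time of spike-mode episodes (ms).
#' @param sync Within-episode input synchrony in rate mode, in `[0, 1]`.
#' @param inter_episode_reset Reset neuron state between episodes.
#' @param seed Base RNG seed for rate-mode episodes.
#' @param dt_ms Integration step (ms).
#'
#' @return A list of class `protocol_config`.
#' @export
#' @examples
#' protocol_config(make_cfbp(2), mode = "spike")
protocol_config <- function(table, mode = c("spike", "rate"),
                            active_rate_hz = 50, episode_ms = 500,
                            t0_ms = 10, sync = 1,
                            inter_episode_reset = TRUE, seed = 1L,
                            dt_ms = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "boolean_table"), episode_ms > 0)
  if (mode == "rate" && active_rate_hz <= 0) {
    abort("active_rate_hz must be > 0 in rate mode",
          class = "satif_error_invalid_config")
  }
  structure(
    list(table = table, mode = mode, active_rate_hz = active_rate_hz,
         episode_ms = episode_ms, t0_ms = t0_ms, sync = sync,
         inter_episode_reset = inter_episode_reset, seed = as.integer(seed),
         dt_ms = dt_ms),
    class = "protocol_config"
  )
}

# trains for one table row; all rate-mode episodes of a repetition share
# `seed`, and generate_poisson_trains draws every source's train regardless
# of the pattern, so a source's drive is pattern-independent at fixed seed.
episode_trains <- function(pattern, config, seed = config$seed) {
  if (config$mode == "spike") {
    generate_single_spike_trains(pattern, t0_ms = config$t0_ms,
                                 horizon_ms = config$episode_ms)
  } else {
    generate_poisson_trains(pattern, rate_hz = config$active_rate_hz,
                            duration_ms = config$episode_ms,
                            seed = seed, sync = config$sync)
  }
}

#' Calibrate drive scale and threshold for a truth-table protocol
#'
#' With spiking disabled, measures the peak depolarisation of every episode
#' and places the spike threshold at the midpoint between the largest
#' output-0 peak and the smallest output-1 peak. If the midpoint sits less
#' than `min_headroom_mV` above rest, `drive_scale` is raised by factors of
#' 10 (conductance ratios between episodes are preserved by saturation) and
#' the episodes re-measured. Deterministic in spike mode; rate mode uses
#' fixed-seed episodes (`config$seed`).
#'
#' If the two output classes do not separate in peak voltage — e.g. for a
#' LIF, whose episodes are exactly identical — a `not-calibratable` result is
#' returned rather than an error: that is a scientific outcome.
#'
#' @param spec A [neuron_spec()].
#' @param config A [protocol_config()]; the table must contain both output
#'   classes.
#' @param min_headroom_mV Required midpoint elevation above rest (mV).
#' @param max_scale Give up once `drive_scale` would exceed this.
#'
#' @return An object of class `sif_calibration`: list with `calibratable`,
#'   `drive_scale`, `v_threshold_mV`, `margin_mV` (half the class gap),
#'   `peaks` (per-episode tibble) and `reason` when not calibratable.
#' @export
#' @examples
#' calibrate(sif_neuron(), protocol_config(make_cfbp(2), mode = "spike"))
calibrate <- function(spec, config, min_headroom_mV = 0.5, max_scale = 1e6) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(config, "protocol_config"))
  tbl <- config$table
  not_cal <- function(reason, peaks = NULL, scale = spec$drive_scale) {
    structure(list(calibratable = FALSE, drive_scale = scale,
                   v_threshold_mV = NA_real_, margin_mV = NA_real_,
                   peaks = peaks, reason = reason),
              class = "sif_calibration")
  }
  if (length(unique(tbl$output)) < 2) {
    return(not_cal("table has a single output class; midpoint undefined"))
  }
  v_rest <- spec$membrane$v_rest_mV
  scale <- spec$drive_scale
  repeat {
    spec_s <- spec
    spec_s$drive_scale <- scale
    peaks <- purrr::map_dbl(tbl$pattern, function(p) {
      sim <- run_simulation(spec_s, episode_trains(p, config),
                            dt_ms = config$dt_ms, spiking = FALSE)
      max(sim$voltage_mV)
    })
    peak_tbl <- tibble::tibble(pattern = tbl$pattern, output = tbl$output,
                               peak_voltage_mV = peaks)
    max0 <- max(peaks[tbl$output == 0])
    min1 <- min(peaks[tbl$output == 1])
    if (min1 <= max0) {
      return(not_cal(sprintf(
        "no peak-voltage gap between output classes (max0 = %.6f, min1 = %.6f mV)",
        max0, min1), peak_tbl, scale))
    }
    mid <- (max0 + min1) / 2
    if (mid - v_rest >= min_headroom_mV) {
      return(structure(
        list(calibratable = TRUE, drive_scale = scale, v_threshold_mV = mid,
             margin_mV = (min1 - max0) / 2, peaks = peak_tbl, reason = NULL),
        class = "sif_calibration"))
    }
    scale <- scale * 10
    if (scale > max_scale) {
      return(not_cal("drive_scale ceiling reached before spiking regime",
                     peak_tbl, scale))
    }
  }
}

#' @export
print.sif_calibration <- function(x, ...) {
  if (x$calibratable) {
    cat(sprintf(
      "<sif_calibration: drive_scale %g, v_threshold %.4f mV, margin %.4f mV>\n",
      x$drive_scale, x$v_threshold_mV, x$margin_mV))
  } else {
    cat(sprintf("<sif_calibration: NOT calibratable — %s>\n", x$reason))
  }
  invisible(x)
}

# spec with calibration applied
apply_calibration <- function(spec, calibration) {
  spec$drive_scale <- calibration$drive_scale
  spec$membrane$v_threshold_mV <- calibration$v_threshold_mV
  spec
}

#' Run the stimulation-episode protocol
#'
#' Simulates one independent episode per table row (in table order, spiking
#' enabled, calibration applied) and reads out each episode as a Boolean:
#' output 1 iff at least one somatic spike was fired.
#'
#' @param spec A [neuron_spec()].
#' @param config A [protocol_config()].
#' @param calibration A calibratable [calibrate()] result.
#' @param seed Seed for rate-mode episodes (defaults to `config$seed`).
#'
#' @return An object of class `sif_protocol`; its `episodes` element is a
#'   tibble with `pattern`, `expected`, `n_spikes`, `peak_voltage_mV`,
#'   `mean_rate_hz` and the decided `output`. [tidy()] returns the episode
#'   tibble, [glance()] a one-row verdict summary.
#' @export
#' @examples
#' spec <- sif_neuron()
#' config <- protocol_config(make_cfbp(2), mode = "spike")
#' run_protocol(spec, config, calibrate(spec, config))
run_protocol <- function(spec, config, calibration, seed = config$seed) {
  stopifnot(inherits(calibration, "sif_calibration"))
  if (!calibration$calibratable) {
    abort("cannot run protocol from a not-calibratable calibration",
          class = "satif_error_calibration")
  }
  spec_c <- apply_calibration(spec, calibration)
  tbl <- config$table
  episodes <- purrr::map2_dfr(tbl$pattern, tbl$output, function(p, exp_out) {
    sim <- run_simulation(spec_c, episode_trains(p, config, seed = seed),
                          dt_ms = config$dt_ms, spiking = TRUE)
    g <- glance(sim)
    tibble::tibble(pattern = p, expected = exp_out, n_spikes = g$n_spikes,
                   peak_voltage_mV = g$peak_voltage_mV,
                   mean_rate_hz = g$mean_rate_hz,
                   output = as.integer(g$n_spikes >= 1))
  })
  structure(list(episodes = episodes, config = config,
                 calibration = calibration, spec = spec_c, seed = seed),
            class = "sif_protocol")
}

#' @export
print.sif_protocol <- function(x, ...) {
  cat(sprintf("<sif_protocol: %s mode, %d episode(s)>\n",
              x$config$mode, nrow(x$episodes)))
  print(x$episodes)
  invisible(x)
}

#' @rdname run_protocol
#' @param x A `sif_protocol` object.
#' @param ... Unused.
#' @export
tidy.sif_protocol <- function(x, ...) x$episodes

#' @rdname run_protocol
#' @export
glance.sif_protocol <- function(x, ...) {
  tibble::tibble(mode = x$config$mode, n_episodes = nrow(x$episodes),
                 matches_table = all(x$episodes$output == x$episodes$expected),
                 drive_scale = x$calibration$drive_scale,
                 v_threshold_mV = x$calibration$v_threshold_mV)
}

#' Does a neuron model implement a partial truth table?
#'
#' Calibrates the model for the table ([calibrate()]), then runs the episode
#' protocol ([run_protocol()]) and compares decided against required
#' outputs. In spike mode the check is deterministic and runs once; in rate
#' mode it is repeated over `n_seeds` consecutive seeds and the verdict is
#' `TRUE` only if *every* repetition reproduces the whole table (the
#' agreement fraction is reported alongside). A model that cannot be
#' calibrated — no peak-voltage gap between the output classes, as for a
#' LIF — returns `FALSE` with the reason.
#'
#' @param spec A [neuron_spec()].
#' @param config A [protocol_config()].
#' @param n_seeds Rate-mode repetitions (default 20).
#'
#' @return An object of class `sif_implementation`: list with `implements`,
#'   `reason`, `agreement` (fraction of repetitions matching the table),
#'   `episodes` (readouts of the first repetition), `calibration`.
#' @export
#' @examples
#' implements_table(sif_neuron(), protocol_config(make_cfbp(2), mode = "spike"))
implements_table <- function(spec, config, n_seeds = 20L) {
  calibration <- calibrate(spec, config)
  if (!calibration$calibratable) {
    return(structure(
      list(implements = FALSE,
           reason = paste0("not calibratable: ", calibration$reason),
           agreement = NA_real_, episodes = NULL, calibration = calibration),
      class = "sif_implementation"))
  }
  seeds <- if (config$mode == "spike") config$seed else
    config$seed + seq_len(n_seeds) - 1L
  runs <- purrr::map(seeds, function(s)
    run_protocol(spec, config, calibration, seed = s))
  match_all <- purrr::map_lgl(runs, function(r)
    all(r$episodes$output == r$episodes$expected))
  structure(
    list(implements = all(match_all), reason = NULL,
         agreement = mean(match_all), episodes = runs[[1]]$episodes,
         calibration = calibration),
    class = "sif_implementation")
}

#' @export
print.sif_implementation <- function(x, ...) {
  if (x$implements) {
    cat(sprintf("<sif_implementation: TRUE (agreement %.0f%%)>\n",
                100 * x$agreement))
  } else {
    cat(sprintf("<sif_implementation: FALSE%s>\n",
                if (!is.null(x$reason)) paste0(" — ", x$reason) else
                  sprintf(" (agreement %.0f%%)", 100 * x$agreement)))
  }
  if (!is.null(x$episodes)) print(x$episodes)
  invisible(x)
}

#' @rdname implements_table
#' @param x A `sif_implementation` object.
#' @param ... Unused.
#' @export
glance.sif_implementation <- function(x, ...) {
  tibble::tibble(implements = x$implements, agreement = x$agreement,
                 calibratable = x$calibration$calibratable,
                 drive_scale = x$calibration$drive_scale,
                 v_threshold_mV = x$calibration$v_threshold_mV,
                 reason = x$reason %||% NA_character_)
}

#' Plot per-episode protocol readouts
#'
#' @param object A `sif_protocol` object.
#' @param ... Unused.
#' @return A ggplot bar chart of spike counts per episode, coloured by the
#'   required output.
#' @export
autoplot.sif_protocol <- function(object, ...) {
  d <- object$episodes |>
    dplyr::mutate(pattern = factor(.data$pattern, levels = .data$pattern),
                  expected = factor(.data$expected))
  ggplot2::ggplot(d, ggplot2::aes(.data$pattern, .data$n_spikes,
                                  fill = .data$expected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "input pattern", y = "somatic spikes",
                  fill = "required output") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
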