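#' Build a set of input spike trains
#'
#' A `spike_trains` object is a tibble with columns `source_id` (character)
#' and `time_ms` (double), carrying the episode horizon as an attribute.
#' Times must lie in `[0, horizon_ms)` and are kept strictly sorted within
#' each source.
#'
#' @param trains A data frame with columns `source_id` and `time_ms`, or a
#'   named list of numeric spike-time vectors (names are source ids).
#' @param horizon_ms Total simulated duration (ms), > 0.
#'
#' @return A tibble of class `spike_trains`.
#' @export
#' @examples
#' spike_trains(list(`1` = c(5, 12), `3` = 5), horizon_ms = 50)
spike_trains <- function(trains, horizon_ms) {
  if (is.list(trains) && !is.data.frame(trains)) {
    trains <- purrr::imap_dfr(trains, function(t, id) {
      tibble::tibble(source_id = as.character(id), time_ms = as.double(t))
    })
    if (nrow(trains) == 0) {
      trains <- tibble::tibble(source_id = character(), time_ms = double())
    }
  }
  stopifnot(is.data.frame(trains),
            all(c("source_id", "time_ms") %in% names(trains)))
  stopifnot(is.numeric(horizon_ms), horizon_ms > 0)
  out <- tibble::as_tibble(trains) |>
    dplyr::transmute(source_id = as.character(.data$source_id),
                     time_ms = as.double(.data$time_ms)) |>
    dplyr::arrange(.data$source_id, .data$time_ms)
  if (nrow(out) > 0) {
    if (any(out$time_ms < 0 | out$time_ms >= horizon_ms)) {
      abort("spike times must lie in [0, horizon_ms)",
            class = "satif_error_invalid_trains")
    }
    dup <- out |>
      dplyr::group_by(.data$source_id) |>
      dplyr::summarise(ok = !anyDuplicated(.data$time_ms), .groups = "drop")
    if (!all(dup$ok)) {
      abort("spike times must be strictly sorted within each source",
            class = "satif_error_invalid_trains")
    }
  }
  structure(out, horizon_ms = horizon_ms,
            class = c("spike_trains", class(out)))
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains: %d spike(s) on %d source(s), horizon %g ms>\n",
              nrow(x), dplyr::n_distinct(x$source_id), attr(x, "horizon_ms")))
  NextMethod()
}

#' Episode horizon of a spike-train set
#' @param trains A `spike_trains` object.
#' @return The horizon in ms.
#' @export
train_horizon <- function(trains) attr(trains, "horizon_ms")

#' Poisson spike trains for a stimulation episode
#'
#' Encodes an input pattern as 50 Hz (by default) Poisson spike trains on the
#' active sources; inactive sources receive no spikes. Trains are built from
#' a multiple-interaction-process construction: one "mother" homogeneous
#' Poisson train of rate `rate_hz / sync` is drawn and each source keeps each
#' mother event independently with probability `sync`, so every source's
#' marginal rate is `rate_hz` while `sync` sets the within-episode event
#' synchrony across sources. `sync = 1` (default) makes all active inputs of
#' an episode fire the same event times — the rate-coded reading of a
#' truth-table row as repeated joint activation; `sync = 0` draws fully
#' independent streams.
#'
#' A train is drawn for *every* source and discarded for inactive ones, so a
#' given source receives the same train under any pattern at a fixed seed.
#'
#' @param pattern Binary vector (0/1) over sources `1..n`, or a bit-string
#'   such as `"1010"`.
#' @param rate_hz Marginal firing rate per active source (Hz), >= 0.
#' @param duration_ms Episode duration (ms), > 0.
#' @param seed Integer RNG seed; identical seeds give identical trains.
#' @param sync Within-episode synchrony in `[0, 1]`; see Details.
#'
#' @return A [spike_trains()] object with `horizon_ms = duration_ms`.
#' @export
#' @examples
#' generate_poisson_trains("1010", rate_hz = 50, duration_ms = 500, seed = 1)
generate_poisson_trains <- function(pattern, rate_hz = 50, duration_ms = 500,
                                    seed = 1L, sync = 1) {
  pattern <- parse_pattern(pattern)
  stopifnot(rate_hz >= 0, duration_ms > 0, sync >= 0, sync <= 1)
  n <- length(pattern)
  trains <- withr::with_seed(as.integer(seed), {
    if (sync == 0) {
      lapply(seq_len(n), function(s) {
        k <- rpois(1, rate_hz * duration_ms / 1000)
        sort(runif(k, 0, duration_ms))
      })
    } else {
      k <- rpois(1, rate_hz / sync * duration_ms / 1000)
      mother <- sort(runif(k, 0, duration_ms))
      lapply(seq_len(n), function(s) {
        if (sync == 1) mother else mother[rbinom(length(mother), 1, sync) == 1]
      })
    }
  })
  names(trains) <- as.character(seq_len(n))
  trains[pattern == 0] <- list(numeric(0))
  spike_trains(trains, horizon_ms = duration_ms)
}

#' Simultaneous single-spike trains for a stimulation episode
#'
#' Encodes an input pattern as exactly one spike at `t0_ms` on every active
#' source, simultaneous across sources — the spike-coded reading of a
#' truth-table row.
#'
#' @param pattern Binary vector or bit-string over sources `1..n`.
#' @param t0_ms Spike time (ms), inside `[0, horizon_ms)`.
#' @param horizon_ms Episode duration (ms).
#'
#' @return A [spike_trains()] object.
#' @export
#' @examples
#' generate_single_spike_trains("1010", t0_ms = 10, horizon_ms = 50)
generate_single_spike_trains <- function(pattern, t0_ms = 10,
                                         horizon_ms = 500) {
  pattern <- parse_pattern(pattern)
  if (t0_ms < 0 || t0_ms >= horizon_ms) {
    abort("t0_ms must lie within the episode",
          class = "satif_error_invalid_trains")
  }
  trains <- lapply(pattern, function(b) if (b == 1) t0_ms else numeric(0))
  names(trains) <- as.character(seq_along(pattern))
  spike_trains(trains, horizon_ms = horizon_ms)
}

# "1010" -> c(1,0,1,0); numeric vectors validated and passed through
parse_pattern <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1) {
    pattern <- as.integer(strsplit(pattern, "")[[1]])
  }
  if (!is.numeric(pattern) || length(pattern) == 0 ||
      !all(pattern %in% c(0, 1))) {
    abort("pattern must be a 0/1 vector or bit-string",
          class = "satif_error_invalid_pattern")
  }
  as.integer(pattern)
}
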