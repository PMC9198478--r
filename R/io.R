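#' Read and write spike trains as delimited text
#'
#' The on-disk format is a two-column CSV with a header line:
#' `source_id,time_ms`, times in ms from episode start.
#'
#' @param trains A [spike_trains()] object.
#' @param path File path.
#' @param horizon_ms Episode horizon for the object read back; if `NULL`,
#'   the smallest integer ms strictly greater than the last spike is used.
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns a [spike_trains()] object.
#' @export
write_spike_trains <- function(trains, path) {
  stopifnot(inherits(trains, "spike_trains"))
  # 17 significant digits so a write/read cycle is lossless for doubles
  df <- data.frame(source_id = trains$source_id,
                   time_ms = sprintf("%.17g", trains$time_ms))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, horizon_ms = NULL) {
  df <- tryCatch(
    suppressWarnings(
      utils::read.csv(path, colClasses = c(source_id = "character",
                                           time_ms = "numeric"))),
    error = function(e) abort(
      sprintf("cannot parse spike trains from '%s': %s", path, conditionMessage(e)),
      class = "satif_error_parse"))
  if (!all(c("source_id", "time_ms") %in% names(df))) {
    abort(sprintf("'%s': expected header 'source_id,time_ms'", path),
          class = "satif_error_parse")
  }
  if (is.null(horizon_ms)) {
    horizon_ms <- if (nrow(df) == 0) 1 else floor(max(df$time_ms)) + 1
  }
  spike_trains(df, horizon_ms = horizon_ms)
}

#' Read and write partial truth tables as delimited text
#'
#' CSV with header `pattern,output`; patterns are bit-strings (kept as text
#' so leading zeros survive).
#'
#' @param table A [boolean_table()].
#' @param path File path.
#' @return `write_boolean_table()` returns `path` invisibly;
#'   `read_boolean_table()` returns a [boolean_table()].
#' @export
write_boolean_table <- function(table, path) {
  stopifnot(inherits(table, "boolean_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boolean_table
#' @export
read_boolean_table <- function(path) {
  df <- tryCatch(
    suppressWarnings(
      utils::read.csv(path, colClasses = c(pattern = "character",
                                           output = "integer"))),
    error = function(e) abort(
      sprintf("cannot parse truth table from '%s': %s", path, conditionMessage(e)),
      class = "satif_error_parse"))
  if (!all(c("pattern", "output") %in% names(df))) {
    abort(sprintf("'%s': expected header 'pattern,output'", path),
          class = "satif_error_parse")
  }
  boolean_table(df$pattern, df$output)
}

#' Read and write simulation results as structured text
#'
#' JSON serialisation of a [run_simulation()] result at full double
#' precision, so a write/read cycle reproduces the traces bit-exactly.
#'
#' @param sim A `sif_sim` object.
#' @param path File path.
#' @return `write_sim_result()` returns `path` invisibly;
#'   `read_sim_result()` returns a `sif_sim` object (without the originating
#'   `neuron_spec`).
#' @export
write_sim_result <- function(sim, path) {
  stopifnot(inherits(sim, "sif_sim"))
  payload <- list(
    dt_ms = sim$dt_ms, horizon_ms = sim$horizon_ms, spiking = sim$spiking,
    voltage_mV = sim$voltage_mV,
    conductance_pS = as.list(as.data.frame(sim$conductance_pS)),
    spike_times_ms = sim$spike_times_ms)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sim_result
#' @export
read_sim_result <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(cbind, payload$conductance_pS)
  if (is.null(g)) g <- matrix(numeric(0), 0, 0)
  n_steps <- length(payload$voltage_mV)
  structure(
    list(dt_ms = payload$dt_ms, time_ms = seq_len(n_steps) * payload$dt_ms,
         voltage_mV = as.numeric(payload$voltage_mV),
         conductance_pS = g,
         spike_times_ms = as.numeric(payload$spike_times_ms),
         horizon_ms = payload$horizon_ms, spec = NULL,
         spiking = payload$spiking),
    class = "sif_sim"
  )
}

#' Read and write separability certificates
#'
#' JSON report carrying the verdict, the method, the witness (if separable)
#' and the pairing-certificate rows (if one was found).
#'
#' @param certificate A `separability_certificate`.
#' @param path File path.
#' @param pairing Optional result of [check_pairing_contradiction()] to
#'   embed in the report.
#' @return `write_certificate()` returns `path` invisibly;
#'   `read_certificate()` returns the report as a list.
#' @export
write_certificate <- function(certificate, path, pairing = NULL) {
  stopifnot(inherits(certificate, "separability_certificate"))
  payload <- list(
    separable = certificate$separable, method = certificate$method,
    n_inputs = certificate$n_inputs,
    weights = certificate$weights, theta = certificate$theta)
  if (!is.null(pairing)) {
    payload$pairing_contradiction <- isTRUE(as.logical(pairing))
    if (isTRUE(as.logical(pairing))) {
      payload$pairing_rows <- as.data.frame(attr(pairing, "pairing"))
    }
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_certificate
#' @export
read_certificate <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a neuron + protocol configuration document
#'
#' One YAML document describes a run: a `neuron` block (membrane, groups,
#' mapping, drive_scale), a global `dt_ms`, and an optional `protocol` block
#' (mode, table file or inline rows, rate, durations, seed). Keys carry unit
#' suffixes (`_ms`, `_mV`, `_MOhm`, `_pS`, `_hz`) to prevent silent unit
#' drift. A `table` entry naming a file is resolved relative to the config
#' file's directory.
#'
#' @param path Path to the YAML config.
#' @return A list with elements `spec` ([neuron_spec()]), `dt_ms`, and
#'   `protocol` (a [protocol_config()] or `NULL`).
#' @export
read_neuron_config <- function(path) {
  doc <- tryCatch(suppressWarnings(yaml::read_yaml(path)),
                  error = function(e) abort(
                    sprintf("cannot parse config '%s': %s", path,
                            conditionMessage(e)),
                    class = "satif_error_parse"))
  if (!is.list(doc) || is.null(doc$neuron)) {
    abort(sprintf("'%s': missing 'neuron' block", path),
          class = "satif_error_parse")
  }
  nb <- doc$neuron
  membrane <- do.call(membrane_params, nb$membrane %||% list())
  groups <- lapply(nb$groups %||% list(list()), function(g)
    do.call(synapse_group, g))
  mapping <- unlist(nb$mapping)
  spec <- neuron_spec(membrane, groups, mapping,
                      drive_scale = nb$drive_scale %||% 1)
  dt_ms <- doc$dt_ms %||% 0.1
  protocol <- NULL
  if (!is.null(doc$protocol)) {
    pb <- doc$protocol
    if (is.null(pb$table)) {
      abort(sprintf("'%s': protocol block needs a 'table'", path),
            class = "satif_error_parse")
    }
    table <- if (is.character(pb$table)) {
      tp <- pb$table
      if (!file.exists(tp)) tp <- file.path(dirname(path), pb$table)
      if (!file.exists(tp)) {
        abort(sprintf("'%s': table file '%s' not found", path, pb$table),
              class = "satif_error_parse")
      }
      read_boolean_table(tp)
    } else {
      boolean_table(vapply(pb$table, `[[`, character(1), "pattern"),
                    vapply(pb$table, `[[`, integer(1), "output"))
    }
    protocol <- protocol_config(
      table, mode = pb$mode %||% "spike",
      active_rate_hz = pb$active_rate_hz %||% 50,
      episode_ms = pb$episode_ms %||% 500,
      t0_ms = pb$t0_ms %||% 10, sync = pb$sync %||% 1,
      inter_episode_reset = pb$inter_episode_reset %||% TRUE,
      seed = pb$seed %||% 1L, dt_ms = dt_ms)
  }
  list(spec = spec, dt_ms = dt_ms, protocol = protocol)
}

# YAML-serialisable snapshot of a neuron_spec
spec_to_config <- function(spec, dt_ms = 0.1, protocol = NULL) {
  out <- list(
    neuron = list(
      membrane = unclass(spec$membrane),
      groups = lapply(spec$groups, unclass),
      mapping = as.list(spec$mapping),
      drive_scale = spec$drive_scale),
    dt_ms = dt_ms)
  if (!is.null(protocol)) out$protocol <- protocol
  out
}

#' Generate the bundled plain-text fixtures
#'
#' Writes the standard task battery into `dir`: the 4-input compact
#' feature-binding table and its 6-input extension, AND and XOR tables,
#' default SIF and LIF configuration documents (the SIF config carries a
#' spike-mode protocol block), single-spike train files for all four
#' 4-input task patterns, and a seeded rate-mode protocol manifest.
#' Regeneration is byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the rate-mode manifest.
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }

  write_boolean_table(make_cfbp(2), put(file.path(dir, "cfbp_m2.csv")))
  write_boolean_table(make_cfbp(3), put(file.path(dir, "cfbp_m3.csv")))
  write_boolean_table(boolean_table(c("00", "01", "10", "11"), c(0, 0, 0, 1)),
                      put(file.path(dir, "and.csv")))
  write_boolean_table(make_xor(), put(file.path(dir, "xor.csv")))

  sif <- sif_neuron()
  cfg <- spec_to_config(sif, dt_ms = 0.1,
                        protocol = list(mode = "spike", table = "cfbp_m2.csv",
                                        episode_ms = 500, t0_ms = 10,
                                        seed = as.integer(seed)))
  yaml::write_yaml(cfg, put(file.path(dir, "sif_config.yaml")))
  yaml::write_yaml(spec_to_config(make_lif(sif), dt_ms = 0.1,
                                  protocol = list(mode = "spike",
                                                  table = "cfbp_m2.csv",
                                                  episode_ms = 500, t0_ms = 10,
                                                  seed = as.integer(seed))),
                   put(file.path(dir, "lif_config.yaml")))

  for (p in make_cfbp(2)$pattern) {
    write_spike_trains(
      generate_single_spike_trains(p, t0_ms = 10, horizon_ms = 500),
      put(file.path(dir, paste0("trains_", p, ".csv"))))
  }

  jsonlite::write_json(
    list(command = "protocol",
         args = c("protocol", "--config", "sif_rate_config.yaml",
                  "--out", "rate_report.json"),
         mode = "rate", seed = as.integer(seed), sync = 1,
         active_rate_hz = 50, episode_ms = 500,
         package = "satif", version = as.character(utils::packageVersion("satif"))),
    put(file.path(dir, "rate_manifest.json")),
    digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(
    spec_to_config(sif, dt_ms = 0.1,
                   protocol = list(mode = "rate", table = "cfbp_m2.csv",
                                   active_rate_hz = 50, episode_ms = 500,
                                   sync = 1, seed = as.integer(seed))),
    put(file.path(dir, "sif_rate_config.yaml")))

  invisible(paths)
}
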