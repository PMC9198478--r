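#' Membrane parameters of a leaky integrate-and-fire compartment
#'
#' The membrane obeys \eqn{\tau \, dv/dt = -(v - v_{rest}) + R I_s(t)} with a
#' spike-and-reset rule: whenever \eqn{v} reaches `v_threshold_mV` a somatic
#' spike is recorded and the voltage is set back to `v_reset_mV`. Defaults are
#' a compact, granule-cell-like cell: \eqn{\tau} = 20 ms, rest at -65 mV,
#' input resistance 20 MOhm, threshold -62 mV, reset -65 mV.
#'
#' @param tau_ms Membrane time constant (ms), > 0.
#' @param v_rest_mV Resting (leak reversal) potential (mV).
#' @param R_MOhm Input resistance (MOhm), > 0.
#' @param v_threshold_mV Spike threshold (mV), must exceed `v_rest_mV`.
#' @param v_reset_mV Post-spike reset potential (mV), at most `v_rest_mV`.
#'
#' @return An object of class `membrane_params`.
#' @export
#' @examples
#' membrane_params()
membrane_params <- function(tau_ms = 20, v_rest_mV = -65, R_MOhm = 20,
                            v_threshold_mV = -62, v_reset_mV = -65) {
  if (!is.numeric(tau_ms) || tau_ms <= 0 || !is.numeric(R_MOhm) || R_MOhm <= 0) {
    abort("tau_ms and R_MOhm must be positive",
          class = "satif_error_invalid_spec")
  }
  if (!(v_reset_mV <= v_rest_mV && v_rest_mV < v_threshold_mV)) {
    abort("membrane parameters must satisfy v_reset <= v_rest < v_threshold",
          class = "satif_error_invalid_spec")
  }
  structure(
    list(tau_ms = tau_ms, v_rest_mV = v_rest_mV, R_MOhm = R_MOhm,
         v_threshold_mV = v_threshold_mV, v_reset_mV = v_reset_mV),
    class = "membrane_params"
  )
}

#' Parameters of one synaptic conductance group
#'
#' A conductance group pools the synaptic drive of all input sources mapped
#' to it into a single conductance variable \eqn{g(t)} that decays
#' exponentially with time constant `tau_s_ms`. Two jump semantics are
#' supported on spike arrival:
#'
#' * `"set_to_max"` — the saturating semantics: \eqn{g} jumps instantaneously
#'   to its ceiling `g_max_pS` (times the neuron's `drive_scale`) and can
#'   never exceed it. This models a locally bounded conductance per unit of
#'   membrane surface.
#' * `"additive_unbounded"` — the classical linear semantics: every spike
#'   increments \eqn{g} by `g_max_pS` (times `drive_scale`) with no bound, so
#'   total drive depends only on the number of incoming spikes.
#'
#' @param E_s_mV Synaptic reversal potential (mV); default 0 (excitatory).
#' @param tau_s_ms Synaptic decay time constant (ms), > 0; default 1.
#' @param g_max_pS Conductance ceiling / per-spike increment (pS), > 0;
#'   default 100.
#' @param jump_mode `"set_to_max"` (saturating) or `"additive_unbounded"`.
#'
#' @return An object of class `synapse_group`.
#' @export
#' @examples
#' synapse_group()
#' synapse_group(jump_mode = "additive_unbounded")
synapse_group <- function(E_s_mV = 0, tau_s_ms = 1, g_max_pS = 100,
                          jump_mode = c("set_to_max", "additive_unbounded")) {
  jump_mode <- match.arg(jump_mode)
  stopifnot(is.numeric(tau_s_ms), tau_s_ms > 0, is.numeric(g_max_pS), g_max_pS > 0)
  structure(
    list(E_s_mV = E_s_mV, tau_s_ms = tau_s_ms, g_max_pS = g_max_pS,
         jump_mode = jump_mode),
    class = "synapse_group"
  )
}

#' Define a neuron as membrane + grouped synaptic conductances
#'
#' A `neuron_spec` combines membrane parameters, an ordered list of
#' conductance groups, and a mapping from input-source ids to group indices.
#' A *SIF* (saturating integrate-and-fire) has two or more `"set_to_max"`
#' groups; a *LIF* gathers all sources into a single
#' `"additive_unbounded"` group.
#'
#' `drive_scale` is a dimensionless multiplier (>= 1) applied to every
#' group's `g_max_pS`; it is used by [calibrate()] to bring responses into
#' the spiking regime while preserving conductance ratios. All conductance
#' book-keeping is reported in scaled pS.
#'
#' @param membrane A [membrane_params()] object.
#' @param groups List of [synapse_group()] objects (ordered; group 1, 2, ...).
#' @param mapping Named integer vector: names are input-source ids, values
#'   are group indices. Every source maps to exactly one group.
#' @param drive_scale Dimensionless multiplier >= 1 applied to all `g_max_pS`.
#'
#' @return An object of class `neuron_spec`.
#' @seealso [sif_neuron()] for the standard 4-input 2-group cell,
#'   [make_lif()] for the matched linear control.
#' @export
#' @examples
#' neuron_spec(
#'   membrane_params(),
#'   groups = list(synapse_group(), synapse_group()),
#'   mapping = c(`1` = 1, `2` = 1, `3` = 2, `4` = 2)
#' )
neuron_spec <- function(membrane, groups, mapping, drive_scale = 1) {
  stopifnot(inherits(membrane, "membrane_params"), is.list(groups),
            length(groups) >= 1)
  if (!all(vapply(groups, inherits, logical(1), "synapse_group"))) {
    abort("all groups must be synapse_group objects",
          class = "satif_error_invalid_spec")
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("mapping must be a named vector (source id -> group index)",
          class = "satif_error_invalid_spec")
  }
  mapping <- stats::setNames(as.integer(mapping), names(mapping))
  if (anyDuplicated(names(mapping))) {
    abort("every input source must map to exactly one group",
          class = "satif_error_invalid_spec")
  }
  if (any(mapping < 1L) || any(mapping > length(groups))) {
    abort("mapping refers to a group index that does not exist",
          class = "satif_error_invalid_spec")
  }
  if (!is.numeric(drive_scale) || drive_scale < 1) {
    abort("drive_scale must be a number >= 1",
          class = "satif_error_invalid_spec")
  }
  structure(
    list(membrane = membrane, groups = groups, mapping = mapping,
         drive_scale = drive_scale),
    class = "neuron_spec"
  )
}

#' Convenience constructor for the standard SIF cell
#'
#' Builds the reference saturating neuron: `n_inputs` sources split into
#' `n_groups` contiguous, equally sized saturating conductance groups.
#' The default (4 inputs, 2 groups) maps sources 1,2 to group 1 and sources
#' 3,4 to group 2 with a 100 pS ceiling per group.
#'
#' @param n_inputs Number of input sources (divisible by `n_groups`).
#' @param n_groups Number of saturating conductance groups.
#' @param membrane,drive_scale Passed to [neuron_spec()].
#' @param ... Passed to [synapse_group()] (e.g. `g_max_pS`, `tau_s_ms`).
#'
#' @return A `neuron_spec`.
#' @export
#' @examples
#' sif_neuron()                 # 4 inputs, 2 saturating points
#' sif_neuron(n_groups = 1)     # a single saturating point
sif_neuron <- function(n_inputs = 4, n_groups = 2,
                       membrane = membrane_params(), drive_scale = 1, ...) {
  stopifnot(n_inputs %% n_groups == 0)
  per <- n_inputs / n_groups
  mapping <- stats::setNames(rep(seq_len(n_groups), each = per),
                             as.character(seq_len(n_inputs)))
  neuron_spec(membrane,
              groups = replicate(n_groups, synapse_group(...), simplify = FALSE),
              mapping = mapping, drive_scale = drive_scale)
}

#' Collapse a grouped neuron into its matched LIF control
#'
#' Pools all input sources into a single unbounded additive conductance with
#' the same membrane parameters and the same per-spike increment
#' (`drive_scale * g_max_pS` of the first group), so total drive depends only
#' on the number of incoming spikes — the linear integration of the classical
#' LIF. Idempotent on a spec that is already a LIF.
#'
#' @param spec A `neuron_spec`.
#' @return A `neuron_spec` with one `"additive_unbounded"` group.
#' @export
#' @examples
#' make_lif(sif_neuron())
make_lif <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  if (is_lif(spec)) return(spec)
  g1 <- spec$groups[[1]]
  lif_group <- synapse_group(E_s_mV = g1$E_s_mV, tau_s_ms = g1$tau_s_ms,
                             g_max_pS = g1$g_max_pS,
                             jump_mode = "additive_unbounded")
  mapping <- stats::setNames(rep(1L, length(spec$mapping)), names(spec$mapping))
  neuron_spec(spec$membrane, groups = list(lif_group), mapping = mapping,
              drive_scale = spec$drive_scale)
}

#' @rdname make_lif
#' @export
is_lif <- function(spec) {
  length(spec$groups) == 1L &&
    spec$groups[[1]]$jump_mode == "additive_unbounded"
}

#' @rdname make_lif
#' @export
is_sif <- function(spec) {
  length(spec$groups) >= 2L &&
    all(vapply(spec$groups, function(g) g$jump_mode == "set_to_max", logical(1)))
}

#' @export
print.neuron_spec <- function(x, ...) {
  kind <- if (is_lif(x)) "LIF" else if (is_sif(x)) "SIF" else "neuron"
  cat(sprintf("<neuron_spec: %s, %d input(s) -> %d conductance group(s), drive_scale %g>\n",
              kind, length(x$mapping), length(x$groups), x$drive_scale))
  m <- x$membrane
  cat(sprintf("  membrane: tau %g ms, rest %g mV, R %g MOhm, threshold %g mV, reset %g mV\n",
              m$tau_ms, m$v_rest_mV, m$R_MOhm, m$v_threshold_mV, m$v_reset_mV))
  for (j in seq_along(x$groups)) {
    g <- x$groups[[j]]
    srcs <- names(x$mapping)[x$mapping == j]
    cat(sprintf("  group %d [%s]: E_s %g mV, tau_s %g ms, g_max %g pS <- sources {%s}\n",
                j, g$jump_mode, g$E_s_mV, g$tau_s_ms, g$g_max_pS,
                paste(srcs, collapse = ",")))
  }
  invisible(x)
}
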