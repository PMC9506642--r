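## Simulation configuration, engine packing, and trace utilities.

#' Simulation configuration
#'
#' Fixed-step implicit (backward Euler) integration; gates are advanced by
#' exact exponential updates at the start-of-step voltage.  A settle phase
#' of `settle` ms runs before t = 0 with all stimuli silent so the model
#' relaxes to its resting state (gates are additionally initialized to
#' their steady state at `v_init`).
#'
#' @param dt time step (ms)
#' @param t_stop end of the recorded epoch (ms)
#' @param settle settle-phase duration before t = 0 (ms)
#' @param v_init initial voltage (mV); `NULL` = model's `v_init`
#' @param record_stride record every `record_stride`-th step
#' @param spike_thresh somatic spike detection threshold (mV)
#' @param spike_refrac minimum inter-spike separation (ms)
#' @param seed RNG seed recorded with results (the integrator itself is
#'   deterministic)
#' @return object of class `sim_config`
#' @export
sim_config <- function(dt = 0.025, t_stop = 500, settle = 500,
                       v_init = NULL, record_stride = 1L,
                       spike_thresh = 0, spike_refrac = 1, seed = 1L) {
  stopifnot(dt > 0, t_stop > 0, settle >= 0, record_stride >= 1)
  structure(list(dt = dt, t_stop = t_stop, settle = settle,
                 v_init = v_init, record_stride = as.integer(record_stride),
                 spike_thresh = spike_thresh, spike_refrac = spike_refrac,
                 seed = seed),
            class = "sim_config")
}

## voltage grid for the gate lookup tables
.VGRID <- list(v0 = -150, step = 0.05, n = 5201)   # -150 .. +110 mV

## pack one mechanism into engine form: gate tables are built by calling the
## R rate functions on the grid, so the engine shares the tested kinetics
.pack_mech <- function(mech, graph, dt) {
  v <- .VGRID$v0 + .VGRID$step * (seq_len(.VGRID$n) - 1)
  base <- mech$params
  base$v_shift <- 0; base$tau_scale <- 1   # shifts live in per-comp dv
  gates <- lapply(gate_defs(base), function(g) {
    r <- g$rates(v)
    list(exponent = as.integer(g$exponent), inf = r$inf,
         edt = exp(-dt / r$tau), tau = r$tau)
  })
  ## params-level modulation folds into the per-compartment fields
  dv <- mech$dv + mech$params$v_shift
  tau_scale <- mech$tau_scale * mech$params$tau_scale
  list(gbar_uS = mech$density * graph$area_cm2 * 1e6,
       erev = if (mech$is_ca) NA_real_ else as.numeric(mech$e_rev),
       is_ca = mech$is_ca, shift_tau = mech$shift_tau,
       dv = dv, tau_scale = tau_scale, gates = gates)
}

.pack_stimuli <- function(stimuli, model) {
  graph <- model$graph
  comp_of <- function(site) {
    if (is.numeric(site)) return(as.integer(site))       # compartment row
    site_compartment(graph, site)
  }
  pulses <- matrix(numeric(0), 0, 4)
  alphas <- matrix(numeric(0), 0, 5)
  expsyn <- list(); nmda <- list()
  for (s in stimuli) {
    ci <- comp_of(s$site) - 1L
    if (inherits(s, "square_pulse")) {
      pulses <- rbind(pulses, c(ci, s$onset, s$duration, s$amplitude))
    } else if (inherits(s, "alpha_synapse")) {
      alphas <- rbind(alphas, c(ci, s$onset, s$tau, s$g_max * 1e-3, s$e_rev))
    } else if (inherits(s, "nmda_synapse")) {
      nmda[[length(nmda) + 1L]] <- list(
        comp = ci, tau_x = s$tau_x, tau_s = s$tau_s, alpha_s = s$alpha_s,
        mg = s$mg, gmax_uS = s$g_max * 1e-3, erev = s$e_rev,
        times = s$spike_times)
    } else if (inherits(s, "exp_synapse")) {
      expsyn[[length(expsyn) + 1L]] <- list(
        comp = ci, tau_s = s$tau_s, gmax_uS = s$g_max * 1e-3, erev = s$e_rev,
        times = s$spike_times)
    } else stop("unknown stimulus type: ", paste(class(s), collapse = "/"))
  }
  list(pulses = pulses, alphas = alphas, expsyn = expsyn, nmda = nmda)
}

#' Run a simulation
#'
#' @param model a [cmodel()]
#' @param stimuli list of stimulus objects ([square_pulse()],
#'   [alpha_synapse()], [exp_synapse()], [nmda_synapse()]), possibly from
#'   [realize_population()]
#' @param cfg a [sim_config()]
#' @param probes compartments to record voltage at: site refs, compartment
#'   rows, or path distances (apical); the soma is always recorded first
#' @param ca_probes compartments to record `[Ca]` at (same addressing)
#' @param gate_probes data.frame/list with `mech`, `gate`, `comp` to record
#'   gating variables
#' @param replay optional list of replay clamps, each
#'   `list(mech =, gate =, comp =, t =, values =)`; the named gate is forced
#'   to the (linearly interpolated) trace instead of integrating its ODE
#' @return object of class `sim_result`: `t`, `v` (matrix, one column per
#'   probe), `spikes` (somatic spike times, ms), `vmax` (per-compartment
#'   peak voltage after t = 0), `ca`, `gates`, and the probe map
#' @export
run_sim <- function(model, stimuli = list(), cfg = sim_config(),
                    probes = list(), ca_probes = list(),
                    gate_probes = NULL, replay = NULL) {
  stopifnot(inherits(model, "cmodel"), inherits(cfg, "sim_config"))
  graph <- model$graph
  n <- nrow(graph)
  resolve <- function(x) {
    if (inherits(x, "site_ref")) site_compartment(graph, x)
    else if (is.numeric(x) && x == as.integer(x) && x >= 1 && x <= n) as.integer(x)
    else if (is.numeric(x)) site_compartment(graph, x, "apical")
    else stop("cannot resolve probe")
  }
  probe_comps <- unique(c(1L, vapply(probes, resolve, integer(1))))
  ca_comps <- vapply(ca_probes, resolve, integer(1))
  v_init <- if (is.null(cfg$v_init)) model$v_init else cfg$v_init

  mechs <- lapply(model$mechs, .pack_mech, graph = graph, dt = cfg$dt)
  gamma <- ca_gamma(model$ca_pool, graph$area_cm2)
  r_gas <- 8.31446261815324; faraday <- 96485.33212
  packed <- list(
    ncomp = n, parent = as.integer(graph$parent - 1L),
    cap_nF = model$cm * graph$area_cm2 * 1e3,
    gax_uS = graph$g_axial_uS,
    gleak_uS = model$g_pas * graph$area_cm2 * 1e6,
    eleak = model$e_pas,
    vgrid = .VGRID, mechs = unname(mechs),
    ca = list(gamma = gamma, tau_decay = model$ca_pool$tau_decay,
              ca_rest = model$ca_pool$ca_rest, ca_out = model$ca_pool$ca_out,
              rt2f_mV = 1e3 * r_gas * model$ca_pool$temp_k / (2 * faraday)))

  nsteps <- round(cfg$t_stop / cfg$dt)
  gp <- if (is.null(gate_probes)) {
    matrix(integer(0), 0, 3)
  } else {
    do.call(rbind, lapply(gate_probes, function(g)
      c(match(g$mech, names(model$mechs)) - 1L, g$gate - 1L,
        resolve(g$comp) - 1L)))
  }
  rp <- if (is.null(replay)) list() else lapply(replay, function(r) {
    tgrid <- seq(0, cfg$t_stop, by = cfg$dt)
    vals <- approx(r$t, r$values, xout = tgrid, rule = 2)$y
    if (max(r$t) < cfg$t_stop - 1e-9)
      stop("replay trace does not cover [0, t_stop]")
    list(mech = match(r$mech, names(model$mechs)) - 1L,
         gate = as.integer(r$gate - 1L),
         comp = if (is.null(r$comp) || is.na(r$comp)) -1L
                else resolve(r$comp) - 1L,
         values = vals)
  })
  ccfg <- list(dt = cfg$dt, t_stop = cfg$t_stop, settle = cfg$settle,
               v_init = v_init, record_stride = cfg$record_stride,
               probes = probe_comps - 1L, ca_probes = ca_comps - 1L,
               gate_probes = gp, spike_comp = 0L,
               spike_thresh = cfg$spike_thresh,
               spike_refrac = cfg$spike_refrac, replay = rp)
  storage.mode(ccfg$gate_probes) <- "integer"
  out <- .engine_run(packed, .pack_stimuli(stimuli, model), ccfg)
  structure(list(t = out$t, v = out$v, ca = out$ca, gates = out$gates,
                 spikes = out$spikes, vmax = out$vmax, v_end = out$v_end,
                 cai_end = out$cai_end, gate_states = out$gate_states,
                 probe_comps = probe_comps, ca_comps = ca_comps,
                 cfg = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d samples, %d probes, %d spikes\n",
              length(x$t), ncol(x$v), length(x$spikes)))
  invisible(x)
}

#' Detect somatic spikes in a voltage trace
#'
#' Upward crossings of `threshold` within `window`, with a minimum
#' inter-event separation.
#'
#' @param trace voltage samples (mV)
#' @param times sample times (ms); defaults to the sample index
#' @param window closed time window `c(t0, t1)` (ms)
#' @param threshold detection threshold (mV)
#' @param refractory minimum separation between events (ms)
#' @return spike times (ms), strictly increasing
#' @export
detect_spikes <- function(trace, times = seq_along(trace) - 1,
                          window = range(times), threshold = 0,
                          refractory = 1) {
  up <- which(trace[-1] >= threshold & trace[-length(trace)] < threshold) + 1L
  tt <- times[up]
  tt <- tt[tt >= window[1] & tt <= window[2]]
  out <- numeric(0)
  last <- -Inf
  for (t in tt) {
    if (t - last >= refractory) { out <- c(out, t); last <- t }
  }
  out
}

#' Capture a gating-variable time course
#'
#' Runs the simulation and returns the named gate's trace at a compartment,
#' in the form [run_sim()]'s `replay` argument accepts.
#'
#' @inheritParams run_sim
#' @param mech mechanism name
#' @param gate gate index within the mechanism (1-based)
#' @param comp compartment (site ref, row index or apical distance)
#' @return list with `mech`, `gate`, `comp`, `t`, `values` plus the full
#'   `sim_result` as attribute `"result"`
#' @export
capture_gating <- function(model, stimuli, cfg, mech, gate = 1, comp = 1) {
  if (is.null(model$mechs[[mech]]))
    stop("no mechanism '", mech, "' in the model")
  res <- run_sim(model, stimuli, cfg,
                 gate_probes = list(list(mech = mech, gate = gate,
                                         comp = comp)))
  structure(list(mech = mech, gate = gate, comp = comp,
                 t = res$t, values = res$gates[, 1]),
            result = res)
}

#' Run with a gating variable clamped to a recorded trace
#'
#' @inheritParams run_sim
#' @param trace a capture from [capture_gating()] (or a compatible list)
#' @return a `sim_result`
#' @export
run_with_replay <- function(model, stimuli, cfg, trace, probes = list()) {
  if (is.null(model$mechs[[trace$mech]]))
    stop("no mechanism '", trace$mech, "' in the model")
  run_sim(model, stimuli, cfg, probes = probes, replay = list(trace))
}
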