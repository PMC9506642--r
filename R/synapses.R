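## Stimuli and synapse models.  Conductances in nS, currents in nA,
## times in ms, voltages in mV.

#' Square current pulse
#'
#' @param site a [site_ref()] (or compartment index for single-compartment
#'   use)
#' @param onset start time (ms)
#' @param duration pulse length (ms); the pulse is on for
#'   `t in [onset, onset + duration)`
#' @param amplitude current (nA)
#' @return object of class `square_pulse`
#' @export
square_pulse <- function(site, onset, duration, amplitude) {
  stopifnot(duration > 0)
  structure(list(site = site, onset = onset, duration = duration,
                 amplitude = amplitude),
            class = c("square_pulse", "stimulus"))
}

#' @rdname square_pulse
#' @param t time (ms), vectorized
#' @param p a `square_pulse`
#' @return injected current (nA)
#' @export
pulse_current <- function(t, p) {
  ifelse(t >= p$onset & t < p$onset + p$duration, p$amplitude, 0)
}

#' Alpha-shaped conductance synapse
#'
#' Peak-normalized alpha waveform: `g(t) = g_max * u * exp(1 - u)` with
#' `u = (t - onset)/tau`, peaking at `g_max` at `t = onset + tau`.
#'
#' @param site a [site_ref()]
#' @param onset activation time (ms)
#' @param tau time constant (ms)
#' @param g_max peak conductance (nS)
#' @param e_rev reversal potential (mV)
#' @return object of class `alpha_synapse`
#' @export
alpha_synapse <- function(site, onset, tau = 5, g_max = 1, e_rev = 0) {
  stopifnot(tau > 0, g_max >= 0)
  structure(list(site = site, onset = onset, tau = tau, g_max = g_max,
                 e_rev = e_rev),
            class = c("alpha_synapse", "stimulus"))
}

#' @rdname alpha_synapse
#' @param t time (ms), vectorized
#' @param p an `alpha_synapse`
#' @return conductance (nS)
#' @export
alpha_conductance <- function(t, p) {
  u <- (t - p$onset) / p$tau
  ifelse(u >= 0, p$g_max * u * exp(1 - u), 0)
}

#' Single-exponential synapse (AMPA or GABA-A)
#'
#' Gating variable `s` jumps by 1 at each presynaptic spike and decays
#' exponentially (`ds/dt = -s/tau_s + sum_k delta(t - t_k)`); the current is
#' `I = g_max * s * (E_rev - V)`.
#'
#' @param site a [site_ref()]
#' @param spike_times presynaptic spike times (ms)
#' @param tau_s decay time constant (ms); AMPA default 2
#' @param g_max conductance scale (nS)
#' @param e_rev reversal potential (mV); 0 for AMPA, -80 for GABA-A
#' @return object of class `exp_synapse`
#' @export
exp_synapse <- function(site, spike_times, tau_s = 2, g_max = 1, e_rev = 0) {
  stopifnot(tau_s > 0, g_max >= 0)
  structure(list(site = site, spike_times = sort(spike_times), tau_s = tau_s,
                 g_max = g_max, e_rev = e_rev, s = 0),
            class = c("exp_synapse", "stimulus"))
}

#' @rdname exp_synapse
#' @param s state at the start of the step
#' @param dt step (ms)
#' @param n_spikes number of spikes arriving during the step (each
#'   increments `s` by 1 after the decay)
#' @param tau_s decay time constant (ms)
#' @return updated state
#' @export
exp_syn_update <- function(s, dt, n_spikes = 0, tau_s = 2) {
  stopifnot(dt > 0)
  s * exp(-dt / tau_s) + n_spikes
}

#' @rdname exp_synapse
#' @param v membrane potential (mV)
#' @param g_max conductance scale (nS)
#' @param e_rev reversal potential (mV)
#' @return synaptic current (nA)
#' @export
exp_syn_current <- function(s, v, g_max = 1, e_rev = 0) {
  g_max * s * (e_rev - v) * 1e-3    # nS * mV = pA -> nA
}

#' Two-state NMDA synapse with magnesium block
#'
#' Fast driver variable `x` (spike-incremented, decaying with `tau_x`)
#' feeds a saturating slow variable `s`:
#' `ds/dt = -s/tau_s + alpha_s * x * (1 - s)`.  The conductance is
#' `g_max * s * B(V)` with the magnesium block
#' `B(V) = 1/(1 + Mg * exp(-0.062 V)/3.57)`.
#'
#' @param site a [site_ref()]
#' @param spike_times presynaptic spike times (ms)
#' @param tau_x rise time constant (ms)
#' @param tau_s decay time constant (ms)
#' @param alpha_s activation rate (kHz = 1/ms)
#' @param mg extracellular magnesium concentration (mM)
#' @param g_max conductance scale (nS)
#' @param e_rev reversal potential (mV)
#' @return object of class `nmda_synapse`
#' @export
nmda_synapse <- function(site, spike_times, tau_x = 2, tau_s = 100,
                         alpha_s = 2, mg = 1, g_max = 1, e_rev = 0) {
  stopifnot(tau_x > 0, tau_s > 0, alpha_s > 0, mg >= 0, g_max >= 0)
  structure(list(site = site, spike_times = sort(spike_times),
                 tau_x = tau_x, tau_s = tau_s, alpha_s = alpha_s, mg = mg,
                 g_max = g_max, e_rev = e_rev, s = 0, x = 0),
            class = c("nmda_synapse", "stimulus"))
}

#' Magnesium-block factor of the NMDA receptor
#'
#' @param v membrane potential (mV), vectorized
#' @param mg magnesium concentration (mM)
#' @return unblocked fraction in (0, 1]
#' @export
nmda_block <- function(v, mg = 1) {
  1 / (1 + mg * exp(-0.062 * v) / 3.57)
}

#' Advance the NMDA state variables one step
#'
#' `x` is advanced exactly (exponential decay plus unit spike increments);
#' `s` is advanced by exact integration of the locally linear equation
#' `ds/dt = a - b s` with `a = alpha_s * xbar`,
#' `b = 1/tau_s + alpha_s * xbar`, where `xbar` is the exact average of `x`
#' over the step.  `s` stays in `[0, 1]`.
#'
#' @param s,x states at the start of the step
#' @param dt step (ms); should be small relative to `tau_x`
#' @param n_spikes spikes arriving during the step
#' @param p an [nmda_synapse()] (used for its time constants)
#' @return list with updated `s` and `x`
#' @export
nmda_update <- function(s, x, dt, n_spikes = 0, p = nmda_synapse(1, numeric(0))) {
  stopifnot(dt > 0)
  decay <- exp(-dt / p$tau_x)
  xbar <- x * p$tau_x * (1 - decay) / dt       # exact average of decaying x
  a <- p$alpha_s * xbar
  b <- 1 / p$tau_s + a
  s_ss <- a / b
  s_new <- s_ss + (s - s_ss) * exp(-b * dt)
  list(s = min(1, max(0, s_new)), x = x * decay + n_spikes)
}

#' Seeded synapse population
#'
#' `n` synapses placed uniformly per unit dendritic length on the sections
#' of `region` whose path distance lies in the closed interval
#' `[x1, x2]`.  Glutamatergic populations are AMPA+NMDA pairs sharing site
#' and conductance (`g_ampa = g_nmda = g_max`); GABAergic populations are
#' single exponential synapses with activation times drawn uniformly from
#' `time_window` (glutamatergic synapses all fire at `time`).
#'
#' @param n number of synapses (>= 1)
#' @param region `"apical"` or `"basal"`
#' @param interval closed path-distance interval `[x1, x2]` (um)
#' @param g_max per-synapse conductance (nS)
#' @param kind `"glut"` (AMPA+NMDA) or `"gaba"`
#' @param time activation time for simultaneous synapses (ms)
#' @param time_window GABA timing window `c(lo, hi)` (ms); default
#'   `time + c(-25, 25)`
#' @param tau_s exponential decay constant (ms) for the AMPA/GABA component
#' @param seed RNG seed for placement (and GABA times)
#' @return object of class `synapse_population`
#' @export
synapse_population <- function(n, region = "apical", interval = c(200, 1300),
                               g_max = 0.01, kind = c("glut", "gaba"),
                               time = 2000, time_window = NULL, tau_s = 2,
                               seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, length(interval) == 2, interval[1] <= interval[2],
            g_max >= 0)
  if (is.null(time_window)) time_window <- time + c(-25, 25)
  structure(list(n = as.integer(n), region = region, interval = interval,
                 g_max = g_max, kind = kind, time = time,
                 time_window = time_window, tau_s = tau_s, seed = seed),
            class = "synapse_population")
}

#' Place a synapse population on a morphology
#'
#' Sites are drawn uniformly per unit length across the eligible dendritic
#' length (deterministic given the seed).  Returns the placed synapse
#' objects plus a placement table.
#'
#' @param pop a [synapse_population()]
#' @param tree a [section_tree()]
#' @return list with `synapses` (list of stimulus objects) and `placement`
#'   (data.frame: section, frac, dist, g_max, time)
#' @export
realize_population <- function(pop, tree) {
  stopifnot(inherits(pop, "synapse_population"), inherits(tree, "section_tree"))
  lo <- pop$interval[1]; hi <- pop$interval[2]
  secs <- which(tree$region == pop$region &
                tree$dist0 + tree$length >= lo &
                tree$dist0 <= hi)
  if (length(secs) == 0)
    stop("empty selector: no '", pop$region, "' dendrite in [",
         lo, ", ", hi, "] um")
  a <- pmax(tree$dist0[secs], lo)
  b <- pmin(tree$dist0[secs] + tree$length[secs], hi)
  len <- b - a
  ok <- len > 0
  if (!any(ok)) stop("empty selector: zero eligible dendritic length")
  secs <- secs[ok]; a <- a[ok]; b <- b[ok]; len <- len[ok]
  placed <- withr_seed(pop$seed, {
    u <- runif(pop$n) * sum(len)
    cum <- cumsum(len)
    k <- findInterval(u, c(0, head(cum, -1) + 1e-12)) # section index per draw
    k[k < 1] <- 1L
    d <- a[k] + (u - c(0, head(cum, -1))[k])          # distance per draw
    times <- if (pop$kind == "gaba")
      runif(pop$n, pop$time_window[1], pop$time_window[2])
    else rep(pop$time, pop$n)
    list(k = k, d = d, times = times)
  })
  sec_rows <- secs[placed$k]
  frac <- (placed$d - tree$dist0[sec_rows]) / tree$length[sec_rows]
  placement <- data.frame(section = tree$id[sec_rows], frac = frac,
                          dist = placed$d, g_max = pop$g_max,
                          time = placed$times)
  syns <- vector("list", 0)
  for (i in seq_len(pop$n)) {
    s <- site_ref(placement$section[i], min(1, max(0, placement$frac[i])),
                  placement$dist[i])
    if (pop$kind == "glut") {
      syns[[length(syns) + 1L]] <-
        exp_synapse(s, placement$time[i], tau_s = pop$tau_s,
                    g_max = pop$g_max, e_rev = 0)
      syns[[length(syns) + 1L]] <-
        nmda_synapse(s, placement$time[i], g_max = pop$g_max, e_rev = 0)
    } else {
      syns[[length(syns) + 1L]] <-
        exp_synapse(s, placement$time[i], tau_s = pop$tau_s,
                    g_max = pop$g_max, e_rev = -80)
    }
  }
  list(synapses = syns, placement = placement)
}

## evaluate expr with a local RNG seed, restoring the global RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
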