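## Channel kinetics, conductance profiles, neuromodulation and calcium
## handling.  Voltages in mV, times in ms, densities in S/cm^2,
## concentrations in mM, temperatures as stated per function.

#' Ih channel kinetics, Hay-model variant
#'
#' Rate-based HCN kinetics: `alpha = (V - v_off_a) /
#' (tau_a * (exp((V - v_off_a)/v_slo_a) - 1))` (with the removable
#' singularity at `V = v_off_a` evaluated analytically as
#' `v_slo_a / tau_a`), `beta = exp((V - v_off_b)/v_slo_b) / tau_b`,
#' `h_inf = alpha/(alpha+beta)`, `tau = 1/(alpha+beta)`.  The gate opens
#' with hyperpolarization (h_inf decreasing in V); the current is
#' `g_h * h * (E_h - V)`.
#'
#' @param v_off_a,v_slo_a,tau_a alpha-rate offset (mV), slope (mV) and
#'   reciprocal rate scale (ms)
#' @param v_off_b,v_slo_b,tau_b beta-rate parameters
#' @param e_h reversal potential (mV)
#' @param v_shift voltage shift applied by neuromodulation (mV); the gating
#'   curves move by `+v_shift` along the voltage axis
#' @param tau_scale multiplicative factor on the time constant
#' @param shift_tau logical: does `v_shift` also move the time-constant
#'   curve (default) or only the steady state?
#' @return parameter object of class `ih_hay_params`
#' @export
ih_hay_params <- function(v_off_a = -154.9, v_slo_a = 11.9, tau_a = 155.521,
                          v_off_b = 0.0, v_slo_b = 33.1, tau_b = 5.18135,
                          e_h = -45, v_shift = 0, tau_scale = 1,
                          shift_tau = TRUE) {
  stopifnot(v_slo_a > 0, v_slo_b > 0, tau_a > 0, tau_b > 0, tau_scale > 0)
  structure(list(v_off_a = v_off_a, v_slo_a = v_slo_a, tau_a = tau_a,
                 v_off_b = v_off_b, v_slo_b = v_slo_b, tau_b = tau_b,
                 e_h = e_h, v_shift = v_shift, tau_scale = tau_scale,
                 shift_tau = shift_tau),
            class = c("ih_hay_params", "mech_params"))
}

#' Ih channel kinetics, Almog-model variant
#'
#' Sigmoidal steady state `h_inf = 1/(1+exp((V - v_off)/v_slo))` and a
#' two-exponential rate for the time constant,
#' `tau = 1 / (t_adj * (exp((v_off_t1 - V)/v_slo_t1)/t0 +
#' exp(-(v_off_t2 - V)/v_slo_t2)/t1))` with the temperature factor
#' `t_adj = q10^((T-22)/10)` (warming shortens the time constant).
#'
#' @param v_off,v_slo half-activation voltage and slope (mV)
#' @param t0,t1 reciprocal rate scales (ms)
#' @param v_off_t1,v_off_t2,v_slo_t1,v_slo_t2 time-constant voltage params
#' @param q10,temp_c temperature sensitivity and temperature (deg C)
#' @param e_h reversal potential (mV)
#' @inheritParams ih_hay_params
#' @return parameter object of class `ih_almog_params`
#' @export
ih_almog_params <- function(v_off = -91, v_slo = 6,
                            t0 = 2542.5883549, t1 = 11.40250855,
                            v_off_t1 = 0, v_off_t2 = 0,
                            v_slo_t1 = 40.1606426, v_slo_t2 = 16.1290323,
                            q10 = 2.3, temp_c = 34, e_h = -33,
                            v_shift = 0, tau_scale = 1, shift_tau = TRUE) {
  stopifnot(v_slo > 0, t0 > 0, t1 > 0, tau_scale > 0)
  structure(list(v_off = v_off, v_slo = v_slo, t0 = t0, t1 = t1,
                 v_off_t1 = v_off_t1, v_off_t2 = v_off_t2,
                 v_slo_t1 = v_slo_t1, v_slo_t2 = v_slo_t2,
                 q10 = q10, temp_c = temp_c, e_h = e_h,
                 v_shift = v_shift, tau_scale = tau_scale,
                 shift_tau = shift_tau),
            class = c("ih_almog_params", "mech_params"))
}

#' Low-voltage-activated (T-type) calcium channel kinetics
#'
#' Activation gate `m` (exponent 2) and inactivation gate `h` (exponent 1):
#' `m_inf = 1/(1+exp((v_off_m - V)/v_slo_m))` (increasing in V),
#' `h_inf = 1/(1+exp((V - v_off_h)/v_slo_h))` (decreasing in V), time
#' constants `tau = (tau_min + tau_diff/(1+exp(-(V - v_off_t)/v_slo_t))) /
#' t_adj` with the sign conventions that make tau_m grow and tau_h grow with
#' depolarization around their half points.  The current is
#' `g * m^2 * h * (E_Ca - V)` with a dynamic calcium reversal.
#'
#' @param v_off_m,v_slo_m,v_off_m_t,v_slo_m_t activation parameters (mV)
#' @param v_off_h,v_slo_h,v_off_h_t,v_slo_h_t inactivation parameters (mV)
#' @param tau_m_min,tau_m_diff,tau_h_min,tau_h_diff time constants (ms)
#' @param q10,temp_c temperature adjustment (reference 21 deg C)
#' @return parameter object of class `calva_params`
#' @export
calva_params <- function(v_off_m = -40, v_slo_m = 6.0,
                         v_off_m_t = -35, v_slo_m_t = 5.0,
                         v_off_h = -90, v_slo_h = 6.4,
                         v_off_h_t = -50, v_slo_h_t = 7.0,
                         tau_m_min = 5, tau_m_diff = 20,
                         tau_h_min = 20, tau_h_diff = 50,
                         q10 = 2.3, temp_c = 34) {
  stopifnot(v_slo_m > 0, v_slo_h > 0, v_slo_m_t > 0, v_slo_h_t > 0)
  structure(list(v_off_m = v_off_m, v_slo_m = v_slo_m,
                 v_off_m_t = v_off_m_t, v_slo_m_t = v_slo_m_t,
                 v_off_h = v_off_h, v_slo_h = v_slo_h,
                 v_off_h_t = v_off_h_t, v_slo_h_t = v_slo_h_t,
                 tau_m_min = tau_m_min, tau_m_diff = tau_m_diff,
                 tau_h_min = tau_h_min, tau_h_diff = tau_h_diff,
                 q10 = q10, temp_c = temp_c,
                 v_shift = 0, tau_scale = 1, shift_tau = TRUE),
            class = c("calva_params", "mech_params"))
}

#' Generic gate parameterization (plug-in channels)
#'
#' Sigmoidal steady state with signed slope (negative `vslo` gives an
#' inactivating gate) and a sigmoid-bump time constant,
#' `tau = (tau_min + tau_diff/(1+exp(-(V - tau_voff)/tau_vslo))) / t_adj`.
#' Channels whose published kinetics are not built in (fast Na+, delayed
#' rectifier K+, etc.) are expressed through lists of these gates.
#'
#' @param voff,vslo steady-state half voltage and signed slope (mV)
#' @param tau_min,tau_diff,tau_voff,tau_vslo time-constant form
#' @param exponent gate exponent in the open-probability product
#' @param t_adj temperature factor dividing the time constant
#' @return a `generic_gate` list
#' @export
generic_gate <- function(voff, vslo, tau_min, tau_diff = 0,
                         tau_voff = 0, tau_vslo = 10, exponent = 1,
                         t_adj = 1) {
  stopifnot(vslo != 0, tau_min > 0 || tau_diff > 0, exponent >= 1)
  structure(list(voff = voff, vslo = vslo, tau_min = tau_min,
                 tau_diff = tau_diff, tau_voff = tau_voff,
                 tau_vslo = tau_vslo, exponent = exponent, t_adj = t_adj),
            class = "generic_gate")
}

#' Generic multi-gate channel (plug-in mechanism)
#'
#' @param gates list of [generic_gate()]
#' @param e_rev fixed reversal potential (mV), or the string `"ca"` for a
#'   dynamic calcium Nernst reversal
#' @return parameter object of class `generic_channel_params`
#' @export
generic_channel_params <- function(gates, e_rev) {
  stopifnot(length(gates) >= 1,
            all(vapply(gates, inherits, logical(1), "generic_gate")))
  structure(list(gates = gates, e_rev = e_rev,
                 v_shift = 0, tau_scale = 1, shift_tau = TRUE),
            class = c("generic_channel_params", "mech_params"))
}

## ---- rate evaluation -----------------------------------------------------

.hay_alpha <- function(v, p) {
  u <- v - p$v_off_a
  a <- ifelse(abs(u) < 1e-7,
              p$v_slo_a / p$tau_a,
              u / (p$tau_a * (exp(u / p$v_slo_a) - 1)))
  a
}

#' Steady state and time constant of the Hay Ih gate
#'
#' @param v membrane potential (mV), vectorized
#' @param p [ih_hay_params()]
#' @return list with `h_inf` and `tau` (ms)
#' @export
ih_hay_rates <- function(v, p = ih_hay_params()) {
  vi <- v - p$v_shift
  vt <- if (p$shift_tau) vi else v
  a <- .hay_alpha(vi, p)
  b <- exp((vi - p$v_off_b) / p$v_slo_b) / p$tau_b
  at <- .hay_alpha(vt, p)
  bt <- exp((vt - p$v_off_b) / p$v_slo_b) / p$tau_b
  list(h_inf = a / (a + b), tau = p$tau_scale / (at + bt))
}

#' Steady state and time constant of the Almog Ih gate
#'
#' @param v membrane potential (mV), vectorized
#' @param p [ih_almog_params()]
#' @return list with `h_inf` and `tau` (ms)
#' @export
ih_almog_rates <- function(v, p = ih_almog_params()) {
  vi <- v - p$v_shift
  vt <- if (p$shift_tau) vi else v
  t_adj <- p$q10^((p$temp_c - 22) / 10)
  h_inf <- 1 / (1 + exp((vi - p$v_off) / p$v_slo))
  rate <- exp((p$v_off_t1 - vt) / p$v_slo_t1) / p$t0 +
          exp(-(p$v_off_t2 - vt) / p$v_slo_t2) / p$t1
  list(h_inf = h_inf, tau = p$tau_scale / (t_adj * rate))
}

#' Steady states and time constants of the T-type calcium gates
#'
#' @param v membrane potential (mV), vectorized
#' @param p [calva_params()]
#' @return list with `m_inf`, `tau_m`, `h_inf`, `tau_h`
#' @export
calva_rates <- function(v, p = calva_params()) {
  vi <- v - p$v_shift
  vt <- if (p$shift_tau) vi else v
  t_adj <- p$q10^((p$temp_c - 21) / 10)
  m_inf <- 1 / (1 + exp((p$v_off_m - vi) / p$v_slo_m))
  h_inf <- 1 / (1 + exp((vi - p$v_off_h) / p$v_slo_h))
  tau_m <- (p$tau_m_min + p$tau_m_diff /
              (1 + exp(-(vt - p$v_off_m_t) / p$v_slo_m_t))) / t_adj
  tau_h <- (p$tau_h_min + p$tau_h_diff /
              (1 + exp(-(vt - p$v_off_h_t) / p$v_slo_h_t))) / t_adj
  list(m_inf = m_inf, tau_m = p$tau_scale * tau_m,
       h_inf = h_inf, tau_h = p$tau_scale * tau_h)
}

#' @rdname generic_gate
#' @param v membrane potential (mV), vectorized
#' @param g a `generic_gate`
#' @return list with `inf` and `tau`
#' @export
generic_gate_rates <- function(v, g) {
  inf <- 1 / (1 + exp((g$voff - v) / g$vslo))
  tau <- (g$tau_min + g$tau_diff /
            (1 + exp(-(v - g$tau_voff) / g$tau_vslo))) / g$t_adj
  list(inf = inf, tau = rep_len(tau, length(v)))
}

## gate table interface used by the engine: list of gates, each a function of
## voltage returning inf and tau, plus exponent and name
gate_defs <- function(p) UseMethod("gate_defs")

#' @export
gate_defs.ih_hay_params <- function(p) {
  list(list(name = "h", exponent = 1,
            rates = function(v) {
              r <- ih_hay_rates(v, p); list(inf = r$h_inf, tau = r$tau)
            }))
}

#' @export
gate_defs.ih_almog_params <- function(p) {
  list(list(name = "h", exponent = 1,
            rates = function(v) {
              r <- ih_almog_rates(v, p); list(inf = r$h_inf, tau = r$tau)
            }))
}

#' @export
gate_defs.calva_params <- function(p) {
  list(list(name = "m", exponent = 2,
            rates = function(v) {
              r <- calva_rates(v, p); list(inf = r$m_inf, tau = r$tau_m)
            }),
       list(name = "h", exponent = 1,
            rates = function(v) {
              r <- calva_rates(v, p); list(inf = r$h_inf, tau = r$tau_h)
            }))
}

#' @export
gate_defs.generic_channel_params <- function(p) {
  lapply(seq_along(p$gates), function(i) {
    g <- p$gates[[i]]
    list(name = paste0("g", i), exponent = g$exponent,
         rates = function(v) {
           vi <- v - p$v_shift
           vt <- if (p$shift_tau) vi else v
           inf <- generic_gate_rates(vi, g)$inf
           tau <- generic_gate_rates(vt, g)$tau * p$tau_scale
           list(inf = inf, tau = tau)
         })
  })
}

#' Neuromodulation specification for Ih channels
#'
#' Models cAMP-mediated neuromodulation as a shift of the channel's voltage
#' dependence: every voltage argument of the gating functions is replaced by
#' `V - dv` so the curves move by `+dv` along the voltage axis
#' (cAMP-enhancing modulation: positive `dv`; cAMP-inhibiting: negative).
#' Time constants are additionally multiplied by `tau_scale`.
#'
#' @param dv half-activation voltage shift (mV)
#' @param tau_scale multiplicative factor on time constants (> 0)
#' @param region region label the modulation applies to (model-level use)
#' @param interval path-distance interval `[x1, x2]` (um, closed) within the
#'   region; `NULL` = whole region
#' @param target target mechanism name (only Ih variants are supported)
#' @param shift_tau should the voltage shift also move the time-constant
#'   curve (`TRUE`, default) or only the steady state?
#' @return object of class `neuromod_spec`
#' @export
neuromod_spec <- function(dv = 0, tau_scale = 1, region = NULL,
                          interval = NULL, target = "ih",
                          shift_tau = TRUE) {
  stopifnot(tau_scale > 0)
  structure(list(dv = dv, tau_scale = tau_scale, region = region,
                 interval = interval, target = target,
                 shift_tau = shift_tau),
            class = "neuromod_spec")
}

#' Apply neuromodulation
#'
#' For parameter objects, returns shifted parameters; for compartmental
#' models (see [make_scenario()]), applies the shift to the targeted
#' mechanism within the spec's region/interval selector.
#'
#' @param x an Ih parameter object or a `cmodel`
#' @param spec a [neuromod_spec()]
#' @return modified copy of `x`
#' @export
apply_neuromod <- function(x, spec) UseMethod("apply_neuromod")

.check_ih_target <- function(x) {
  if (!inherits(x, c("ih_hay_params", "ih_almog_params")))
    stop("unsupported modulation target: only Ih mechanisms can be ",
         "neuromodulated")
}

#' @export
apply_neuromod.mech_params <- function(x, spec) {
  .check_ih_target(x)
  x$v_shift <- x$v_shift + spec$dv
  x$tau_scale <- x$tau_scale * spec$tau_scale
  x$shift_tau <- spec$shift_tau
  x
}

#' Conductance-density profile along the morphology
#'
#' Describes how a channel's maximal conductance density (S/cm^2) varies
#' with path distance within one region, with an optional hot-zone override.
#'
#' @param region region label the profile applies to
#' @param form `"constant"`, `"linear"`, `"exp"`, `"piecewise"` or `"table"`
#' @param base density at distance 0 (S/cm^2)
#' @param slope linear form: density = base + slope * dist
#' @param lambda exponential form: density = base * exp(dist / lambda)
#' @param breaks,values piecewise/table forms: distances (um) and densities;
#'   `piecewise` interpolates linearly, `table` is a right-continuous step
#' @param hot_zone optional list with `interval = c(x1, x2)` um (closed) and
#'   either `multiplier` or `absolute` (S/cm^2)
#' @return object of class `conductance_profile`
#' @export
conductance_profile <- function(region, form = "constant", base = 0,
                                slope = 0, lambda = Inf,
                                breaks = NULL, values = NULL,
                                hot_zone = NULL) {
  form <- match.arg(form, c("constant", "linear", "exp", "piecewise", "table"))
  if (form %in% c("piecewise", "table") &&
      (is.null(breaks) || is.null(values)))
    stop("piecewise/table profiles need breaks and values")
  if (!is.null(hot_zone)) {
    stopifnot(length(hot_zone$interval) == 2,
              hot_zone$interval[1] <= hot_zone$interval[2])
    if (is.null(hot_zone$multiplier) && is.null(hot_zone$absolute))
      stop("hot_zone needs a multiplier or an absolute density")
  }
  structure(list(region = region, form = form, base = base, slope = slope,
                 lambda = lambda, breaks = breaks, values = values,
                 hot_zone = hot_zone, scale = 1, scale_interval = NULL),
            class = "conductance_profile")
}

#' Evaluate a conductance profile
#'
#' @param profile a [conductance_profile()]
#' @param dist path distances (um), vectorized
#' @return densities (S/cm^2)
#' @export
profile_density <- function(profile, dist) {
  g <- switch(profile$form,
    constant  = rep_len(profile$base, length(dist)),
    linear    = profile$base + profile$slope * dist,
    exp       = profile$base * exp(dist / profile$lambda),
    piecewise = approx(profile$breaks, profile$values, xout = dist,
                       rule = 2)$y,
    table     = profile$values[pmax(1, findInterval(dist, profile$breaks))])
  hz <- profile$hot_zone
  if (!is.null(hz)) {
    inz <- dist >= hz$interval[1] & dist <= hz$interval[2]   # closed interval
    if (!is.null(hz$absolute)) g[inz] <- hz$absolute
    else g[inz] <- g[inz] * hz$multiplier
  }
  if (profile$scale != 1) {
    sel <- if (is.null(profile$scale_interval)) rep(TRUE, length(dist))
           else dist >= profile$scale_interval[1] &
                dist <= profile$scale_interval[2]
    g[sel] <- g[sel] * profile$scale
  }
  pmax(g, 0)
}

#' Block or over-express a conductance
#'
#' Multiplies densities by `factor` within the selector: `0` is a full
#' block, `2` is a +100 percent over-expression, `1` is the identity.
#'
#' @param x a [conductance_profile()] or a `cmodel`
#' @param factor non-negative multiplier
#' @param interval optional closed path-distance interval `[x1,x2]` (um)
#'   restricting the operation; `NULL` = everywhere
#' @param ... passed to methods
#' @return modified copy of `x`
#' @export
block <- function(x, factor, interval = NULL, ...) UseMethod("block")

#' @export
block.conductance_profile <- function(x, factor, interval = NULL, ...) {
  stopifnot(factor >= 0)
  if (is.null(interval) && x$scale == 1) {
    x$scale <- factor
  } else if (is.null(interval)) {
    x$scale <- x$scale * factor
  } else {
    if (!is.null(x$scale_interval))
      stop("only one interval-restricted block per profile is supported; ",
           "apply to the model instead")
    x$scale <- factor
    x$scale_interval <- interval
  }
  x
}

#' Install, replace or remove a calcium-channel hot zone
#'
#' @param profile a [conductance_profile()]
#' @param interval closed distance interval `[x1,x2]` (um)
#' @param multiplier density multiplier inside the zone (e.g. 100 for the
#'   LVA channel), or
#' @param absolute absolute density inside the zone (S/cm^2), or
#' @param remove if `TRUE` the zone density is set back to the surrounding
#'   baseline (profile becomes hot-zone free)
#' @return modified profile
#' @export
hot_zone <- function(profile, interval = NULL, multiplier = NULL,
                     absolute = NULL, remove = FALSE) {
  stopifnot(inherits(profile, "conductance_profile"))
  if (remove) { profile$hot_zone <- NULL; return(profile) }
  stopifnot(length(interval) == 2, interval[1] <= interval[2])
  if (is.null(multiplier) && is.null(absolute))
    stop("hot_zone needs a multiplier or an absolute density")
  profile$hot_zone <- list(interval = interval, multiplier = multiplier,
                           absolute = absolute)
  profile
}

#' Calcium pool parameters
#'
#' A single-shell first-order pool: `d[Ca]/dt = -gamma * I_Ca -
#' ([Ca]-[Ca]_rest)/tau_decay`, where `I_Ca` is the (negative-inward)
#' calcium current in nA and `gamma = 1e-6/(2*F*depth*area)` converts nA to
#' mM/ms for a shell of the given depth under the membrane.
#'
#' @param depth_um shell depth (um)
#' @param tau_decay decay time constant toward rest (ms)
#' @param ca_rest resting concentration (mM)
#' @param ca_out extracellular concentration (mM)
#' @param temp_k temperature (K)
#' @return object of class `ca_pool_params`
#' @export
ca_pool_params <- function(depth_um = 0.1, tau_decay = 80,
                           ca_rest = 1e-4, ca_out = 2, temp_k = 307.15) {
  stopifnot(depth_um > 0, tau_decay > 0, ca_rest > 0, ca_out > 0, temp_k > 0)
  structure(list(depth_um = depth_um, tau_decay = tau_decay,
                 ca_rest = ca_rest, ca_out = ca_out, temp_k = temp_k),
            class = "ca_pool_params")
}

## mM per (nA * ms) for a compartment of membrane area `area_cm2`
ca_gamma <- function(p, area_cm2) {
  faraday <- 96485.33212
  1e-6 / (2 * faraday * (p$depth_um * 1e-4) * area_cm2)
}

#' Calcium Nernst reversal potential
#'
#' `E_Ca = (R*T)/(2*F) * ln([Ca]_o/[Ca]_i)` in mV.
#'
#' @param ca_i intracellular concentration (mM)
#' @param ca_o extracellular concentration (mM)
#' @param temp_k temperature (K)
#' @return reversal potential (mV)
#' @export
nernst_eca <- function(ca_i, ca_o = 2, temp_k = 307.15) {
  if (any(ca_i <= 0) || any(ca_o <= 0))
    stop("concentrations must be positive")
  r_gas <- 8.31446261815324; faraday <- 96485.33212
  1e3 * r_gas * temp_k / (2 * faraday) * log(ca_o / ca_i)
}

#' Advance the calcium pool one step (exact exponential update)
#'
#' Solves `d[Ca]/dt = -gamma*I_Ca - ([Ca]-rest)/tau` exactly over `dt` for a
#' constant current (inward, negative `I_Ca` raises the concentration).
#'
#' @param ca current concentration (mM)
#' @param i_ca calcium current (nA; inward negative)
#' @param p [ca_pool_params()]
#' @param dt step (ms)
#' @param area_cm2 compartment membrane area (cm^2)
#' @return new concentration (mM)
#' @export
ca_pool_step <- function(ca, i_ca, p, dt, area_cm2 = 1e-6) {
  stopifnot(dt > 0)
  g <- ca_gamma(p, area_cm2)
  ca_ss <- p$ca_rest - g * i_ca * p$tau_decay   # fixed point
  ca_ss + (ca - ca_ss) * exp(-dt / p$tau_decay)
}
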