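## Compartmental model container: discretized morphology + realized
## mechanism densities.  The object is plain data; the integrator consumes
## a packed version of it (see run_sim).

#' Assemble a compartmental model
#'
#' Attaches membrane passive properties and a set of channel mechanisms to
#' a discretized morphology.  Each mechanism is realized as a per-compartment
#' density vector (S/cm^2) from its [conductance_profile()]s, so that later
#' operators ([block()], [apply_neuromod()], [hot_zone()]) act on concrete
#' numbers.
#'
#' @param graph a [discretize()] result
#' @param cm specific membrane capacitance (uF/cm^2)
#' @param g_pas leak density (S/cm^2), scalar or per-compartment
#' @param e_pas leak reversal (mV)
#' @param v_init initial/holding voltage for steady-state initialization (mV)
#' @param ca_pool a [ca_pool_params()]
#' @return object of class `cmodel`; add mechanisms with [add_mechanism()]
#' @export
cmodel <- function(graph, cm = 1, g_pas = 3e-5, e_pas = -90,
                   v_init = -75, ca_pool = ca_pool_params()) {
  stopifnot(inherits(graph, "compartment_graph"))
  n <- nrow(graph)
  structure(list(graph = graph, cm = cm,
                 g_pas = rep_len(g_pas, n), e_pas = e_pas,
                 v_init = v_init, ca_pool = ca_pool,
                 mechs = list()),
            class = "cmodel")
}

#' @export
print.cmodel <- function(x, ...) {
  cat("<cmodel> ", nrow(x$graph), " compartments, mechanisms: ",
      paste(names(x$mechs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Add a channel mechanism to a model
#'
#' @param model a [cmodel()]
#' @param name mechanism name (unique within the model)
#' @param params a `mech_params` object ([ih_hay_params()],
#'   [ih_almog_params()], [calva_params()], [generic_channel_params()])
#' @param profiles list of [conductance_profile()] (one per region the
#'   mechanism lives in), or a single profile
#' @param density alternative to `profiles`: per-compartment density vector
#'   (S/cm^2)
#' @param e_rev reversal potential override (mV); `"ca"` marks a calcium
#'   current with dynamic Nernst reversal
#' @return the model with the mechanism realized
#' @export
add_mechanism <- function(model, name, params, profiles = NULL,
                          density = NULL, e_rev = NULL) {
  stopifnot(inherits(model, "cmodel"), inherits(params, "mech_params"))
  n <- nrow(model$graph)
  if (is.null(density)) {
    if (inherits(profiles, "conductance_profile")) profiles <- list(profiles)
    density <- rep(0, n)
    for (pr in profiles) {
      sel <- model$graph$region == pr$region
      density[sel] <- profile_density(pr, model$graph$dist[sel])
    }
  } else density <- rep_len(density, n)
  if (any(density < 0)) stop("densities must be >= 0")
  if (is.null(e_rev)) {
    e_rev <- if (inherits(params, "calva_params")) "ca"
             else if (!is.null(params$e_h)) params$e_h
             else if (!is.null(params$e_rev)) params$e_rev
             else stop("mechanism '", name, "' needs a reversal potential")
  }
  model$mechs[[name]] <- list(
    name = name, params = params, density = density,
    e_rev = e_rev, is_ca = identical(e_rev, "ca"),
    dv = rep(0, n), tau_scale = rep(1, n),
    shift_tau = isTRUE(params$shift_tau),
    profiles = profiles)
  model
}

## selector: compartments matched by region and/or closed distance interval
.select_comps <- function(graph, region = NULL, interval = NULL) {
  sel <- rep(TRUE, nrow(graph))
  if (!is.null(region)) {
    if (identical(region, "dend") || identical(region, "dendrites"))
      sel <- sel & graph$region %in% c("basal", "apical")
    else sel <- sel & graph$region %in% region
  }
  if (!is.null(interval))
    sel <- sel & graph$dist >= interval[1] & graph$dist <= interval[2]
  sel
}

#' @describeIn block Scale a mechanism's realized density on a model.
#' @param mechanism mechanism name in `model$mechs`
#' @param region optional region selector (`"soma"`, `"basal"`, `"apical"`,
#'   `"dend"` for both dendritic regions)
#' @export
block.cmodel <- function(x, factor, interval = NULL, mechanism = "ih",
                         region = NULL, ...) {
  stopifnot(factor >= 0)
  if (is.null(x$mechs[[mechanism]]))
    stop("no mechanism '", mechanism, "' in the model")
  sel <- .select_comps(x$graph, region, interval)
  x$mechs[[mechanism]]$density[sel] <- x$mechs[[mechanism]]$density[sel] * factor
  x
}

#' @export
apply_neuromod.cmodel <- function(x, spec) {
  target <- spec$target
  if (is.null(x$mechs[[target]]))
    stop("no mechanism '", target, "' in the model")
  .check_ih_target(x$mechs[[target]]$params)
  sel <- .select_comps(x$graph, spec$region, spec$interval)
  x$mechs[[target]]$dv[sel] <- x$mechs[[target]]$dv[sel] + spec$dv
  x$mechs[[target]]$tau_scale[sel] <-
    x$mechs[[target]]$tau_scale[sel] * spec$tau_scale
  x$mechs[[target]]$shift_tau <- spec$shift_tau
  x
}

#' Densities along the morphology at fixed resolution
#'
#' Reports every mechanism's density at `by`-um steps of path distance
#' (apical axis), for manifests and scenario inspection.
#'
#' @param model a [cmodel()]
#' @param by resolution (um)
#' @return data.frame: `dist`, one column per mechanism (S/cm^2)
#' @export
density_manifest <- function(model, by = 10) {
  g <- model$graph
  dmax <- max(g$dist)
  dists <- seq(0, dmax, by = by)
  ## nearest compartment on the main apical path (largest-diameter choice)
  out <- data.frame(dist = dists)
  for (nm in names(model$mechs)) {
    dens <- vapply(dists, function(d) {
      cand <- which(abs(g$dist - d) <= max(by, max(g$length)) / 2 + 1e-9 &
                    (g$region == "apical" | g$region == "soma"))
      if (length(cand) == 0) return(NA_real_)
      i <- cand[which.min(abs(g$dist[cand] - d))]
      model$mechs[[nm]]$density[i]
    }, numeric(1))
    out[[nm]] <- dens
  }
  out
}
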