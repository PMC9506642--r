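## Experiment protocols: f-I curves, bisection threshold search, distance
## sweeps, distributed-synapse grids with nonparametric statistics, combined
## basal/apical stimulation and split proximal/distal neuromodulation.

#' f-I curve and area under the curve
#'
#' Somatic square-pulse current from `onset` to the end of the simulation
#' for each amplitude; firing frequency is the somatic spike count inside
#' `window` divided by the window length; AUC is the trapezoid integral of
#' frequency over amplitude.
#'
#' @param model a [cmodel()]
#' @param amplitudes injected currents (nA), sorted increasing
#' @param cfg a [sim_config()]; `t_stop` should cover the window
#' @param onset pulse start (ms)
#' @param window spike-counting window (ms)
#' @return object of class `fi_curve`: data.frame (`amplitude`, `frequency`)
#'   with attribute `auc` (nA*Hz)
#' @export
fi_curve <- function(model, amplitudes,
                     cfg = sim_config(t_stop = 16000, settle = 500),
                     onset = 200, window = c(500, min(16000, cfg$t_stop))) {
  stopifnot(!is.unsorted(amplitudes, strictly = TRUE))
  freq <- vapply(amplitudes, function(a) {
    st <- square_pulse(1L, onset, cfg$t_stop - onset, a)
    res <- run_sim(model, list(st), cfg)
    sp <- res$spikes
    sum(sp >= window[1] & sp <= window[2]) / (diff(window) / 1000)
  }, numeric(1))
  out <- data.frame(amplitude = amplitudes, frequency = freq)
  attr(out, "auc") <- fi_auc(amplitudes, freq)
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' @rdname fi_curve
#' @param frequencies firing frequencies (Hz)
#' @return `fi_auc`: trapezoid area (nA*Hz)
#' @export
fi_auc <- function(amplitudes, frequencies) {
  stopifnot(length(amplitudes) == length(frequencies))
  if (length(amplitudes) < 2) return(0)
  sum(diff(amplitudes) * (head(frequencies, -1) + tail(frequencies, -1)) / 2)
}

#' Bisection threshold search
#'
#' Finds the minimal stimulus scalar eliciting a somatic action potential.
#' The bracket is grown by doubling from `seed_value` until the predicate
#' reports a spike (or `cap` is reached, in which case the result is
#' flagged `no_ap` rather than raised); if the seed itself already spikes
#' the lower edge is halved down.  Bisection then narrows the bracket until
#' its relative width is below `tol`; the midpoint is returned.
#'
#' @param predicate function of one scalar returning `TRUE`/`FALSE` (spike /
#'   no spike) or a list with elements `spike` and optionally `peak` (local
#'   peak voltage, mV)
#' @param seed_value starting scalar (e.g. 0.1 nA, or 1e-3 nS per synapse)
#' @param cap upper bound for the doubling phase
#' @param tol relative bracket width at convergence
#' @param floor_value lower bound for the downward phase
#' @return object of class `threshold_result`: `threshold`, `no_ap`,
#'   `converged`, `peak_v` (at the last spiking evaluation), `bracket`,
#'   `history` (evaluated scalars and outcomes)
#' @export
find_threshold <- function(predicate, seed_value = 0.1, cap = 300,
                           tol = 0.01, floor_value = seed_value * 1e-6) {
  hist_x <- numeric(0); hist_s <- logical(0)
  peak_v <- NA_real_
  eval1 <- function(x) {
    r <- predicate(x)
    if (is.list(r)) {
      if (isTRUE(r$spike) && !is.null(r$peak)) peak_v <<- r$peak
      r <- isTRUE(r$spike)
    }
    hist_x <<- c(hist_x, x); hist_s <<- c(hist_s, r)
    r
  }
  ## doubling phase
  x <- seed_value
  while (!eval1(x)) {
    if (x >= cap)
      return(structure(list(threshold = NA_real_, no_ap = TRUE,
                            converged = FALSE, peak_v = NA_real_,
                            bracket = c(x, Inf),
                            history = data.frame(x = hist_x, spike = hist_s)),
                       class = "threshold_result"))
    x <- min(cap, x * 2)
  }
  hi <- x
  ## find a non-spiking lower edge
  lo <- hi / 2
  while (lo > floor_value && eval1(lo)) { hi <- lo; lo <- lo / 2 }
  if (lo <= floor_value && hist_s[length(hist_s)]) lo <- 0
  ## bisection
  while ((hi - lo) > tol * hi) {
    mid <- (hi + lo) / 2
    if (eval1(mid)) hi <- mid else lo <- mid
  }
  structure(list(threshold = (hi + lo) / 2, no_ap = FALSE, converged = TRUE,
                 peak_v = peak_v, bracket = c(lo, hi),
                 history = data.frame(x = hist_x, spike = hist_s)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_ap) cat("<threshold> no AP up to cap\n")
  else cat(sprintf("<threshold> %.6g (bracket [%.6g, %.6g], %d evals)\n",
                   x$threshold, x$bracket[1], x$bracket[2], nrow(x$history)))
  invisible(x)
}

## spike predicate for a model + stimulus factory
.spike_predicate <- function(model, make_stimuli, cfg, window = NULL,
                             peak_comp = NULL) {
  function(x) {
    res <- run_sim(model, make_stimuli(x), cfg)
    sp <- res$spikes
    if (!is.null(window)) sp <- sp[sp >= window[1] & sp <= window[2]]
    list(spike = length(sp) > 0,
         peak = if (is.null(peak_comp)) NA_real_ else res$vmax[peak_comp])
  }
}

#' Threshold of a single-site stimulus
#'
#' @param model a [cmodel()]
#' @param site a [site_ref()] (or apical path distance, um)
#' @param kind `"pulse"` (short square current, scalar = amplitude in nA) or
#'   `"alpha"` (alpha conductance, scalar = peak conductance in nS)
#' @param cfg a [sim_config()]
#' @param onset stimulus onset (ms)
#' @param duration pulse duration (ms); the protocol default is 0.2 ms,
#'   use 2 ms for the long-pulse preset
#' @param tau alpha time constant (ms); 5 ms by default, 3 ms for the
#'   conductance-threshold preset
#' @param seed_value,cap,tol bisection controls (see [find_threshold()])
#' @return a [find_threshold()] result; `peak_v` is the local peak voltage
#'   at the stimulated compartment
#' @export
site_threshold <- function(model, site, kind = c("pulse", "alpha"),
                           cfg = sim_config(t_stop = 150, settle = 500),
                           onset = 10, duration = 0.2, tau = 5,
                           seed_value = NULL, cap = NULL, tol = 0.01) {
  kind <- match.arg(kind)
  if (is.numeric(site)) site <- select_site(scenario_tree(model), "apical", site)
  comp <- site_compartment(model$graph, site)
  if (is.null(seed_value)) seed_value <- if (kind == "pulse") 0.1 else 1e-3
  if (is.null(cap)) cap <- if (kind == "pulse") 300 else 1e3
  make_stim <- if (kind == "pulse")
    function(x) list(square_pulse(site, onset, duration, x))
  else
    function(x) list(alpha_synapse(site, onset, tau = tau, g_max = x,
                                   e_rev = 0))
  find_threshold(.spike_predicate(model, make_stim, cfg, peak_comp = comp),
                 seed_value = seed_value, cap = cap, tol = tol)
}

#' Threshold versus stimulus distance for several model variants
#'
#' For each distance the stimulus site is the thickest section at that
#' distance ([select_site()]); each variant's threshold is found by
#' bisection.  Local peak voltages above 100 mV are flagged as
#' unphysiological.
#'
#' @param variants named list of [cmodel()] (e.g. control / Ih-blocked)
#' @param distances stimulus distances (um)
#' @param kind,cfg,onset,duration,tau,tol see [site_threshold()]
#' @param region stimulated region
#' @return data.frame: `distance`, `variant`, `threshold`, `no_ap`,
#'   `peak_v`, `unphysiological`
#' @export
distance_sweep <- function(variants, distances = seq(50, 1000, by = 50),
                           kind = c("pulse", "alpha"),
                           cfg = sim_config(t_stop = 150, settle = 500),
                           onset = 10, duration = 0.2, tau = 5, tol = 0.01,
                           region = "apical") {
  kind <- match.arg(kind)
  stopifnot(is.list(variants), !is.null(names(variants)))
  tree <- scenario_tree(variants[[1]])
  rows <- list()
  for (d in distances) {
    site <- select_site(tree, region, d)
    for (nm in names(variants)) {
      th <- site_threshold(variants[[nm]], site, kind = kind, cfg = cfg,
                           onset = onset, duration = duration, tau = tau,
                           tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        distance = d, variant = nm, threshold = th$threshold,
        no_ap = th$no_ap, peak_v = th$peak_v,
        unphysiological = !is.na(th$peak_v) && th$peak_v > 100)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties.  For `min(n, m) <= 8` and no
#' ties the two-sided p-value is computed by exhaustive enumeration of all
#' `choose(n+m, n)` rank assignments (`p = P(|U - nm/2| >= |u - nm/2|)`);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.  Identical samples give p = 1.
#'
#' @param a,b numeric samples
#' @return list with `U` (statistic of sample `a`), `p` (two-sided) and
#'   `method`
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && min(n, m) <= 8) {
    ## exact enumeration over rank assignments
    combs <- utils::combn(n + m, n)
    us <- colSums(matrix(combs, nrow = n)) - n * (n + 1) / 2
    dev <- abs(us - n * m / 2)
    p <- mean(dev >= abs(u - n * m / 2) - 1e-12)
    return(list(U = u, p = min(1, p), method = "exact"))
  }
  ## normal approximation with tie and continuity corrections
  tab <- table(r)
  tie_term <- sum(tab^3 - tab)
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_term / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "degenerate"))
  z <- (abs(u - n * m / 2) - 0.5) / sqrt(sigma2)
  z <- max(0, z)
  list(U = u, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Cells of the upper-triangular distance grid
#'
#' All pairs `(x1, x2)` with `x1 < x2` from the grid edges; the number of
#' rows is the Bonferroni correction factor of the grid experiment (66 for
#' the standard 200-1300 um grid in 100 um steps).
#'
#' @param x_vals grid edges (um)
#' @return data.frame with columns `x1`, `x2`
#' @export
grid_cells <- function(x_vals = seq(200, 1300, by = 100)) {
  cells <- expand.grid(x1 = x_vals, x2 = x_vals)
  cells <- cells[cells$x1 < cells$x2, ]
  rownames(cells) <- NULL
  cells
}

#' Distributed-synapse grid experiment
#'
#' For every cell `(x1, x2)` of the upper-triangular distance grid, `n_samp`
#' seeded placements of a glutamatergic population are made (the same
#' placement is reused across variants), the per-synapse threshold
#' conductance is found for each variant, and the two variants are compared
#' per cell with a Mann-Whitney U test, Bonferroni-corrected by the number
#' of tested cells.
#'
#' @param variants named list of exactly two [cmodel()]s (reference first)
#' @param x_vals grid edges (um), e.g. `seq(200, 1300, by = 100)`
#' @param n_syn synapses per population
#' @param n_samp placements per cell (>= 2)
#' @param seed base seed; repeat `r` uses `seed + r`
#' @param cfg a [sim_config()]
#' @param time activation time of the glutamatergic synapses (ms)
#' @param alpha significance level before correction
#' @param cap per-synapse conductance cap (nS)
#' @param tol bisection tolerance
#' @param region stimulated region
#' @param extra_stimuli optional function(repeat_seed) returning stimuli
#'   co-active in every run (used for basal drive)
#' @param cells optional data.frame (`x1`, `x2`) restricting the grid
#' @return object of class `grid_result`: data.frame per cell with median
#'   thresholds, `ratio` (variant2/variant1 of medians), `U`, `p`,
#'   `significant` (after Bonferroni), `no_ap`; attributes `m` (number of
#'   tested cells) and `samples`
#' @export
grid_experiment <- function(variants, x_vals = seq(200, 1300, by = 100),
                            n_syn = 200, n_samp = 5, seed = 1,
                            cfg = sim_config(t_stop = 250, settle = 500),
                            time = 50, alpha = 0.05, cap = 1, tol = 0.01,
                            region = "apical", extra_stimuli = NULL,
                            cells = NULL) {
  stopifnot(length(variants) == 2, !is.null(names(variants)), n_samp >= 2)
  tree <- scenario_tree(variants[[1]])
  if (is.null(cells)) cells <- grid_cells(x_vals)
  m_tests <- nrow(cells)
  nm <- names(variants)
  rows <- list(); samples <- list()
  for (ci in seq_len(nrow(cells))) {
    x1 <- cells$x1[ci]; x2 <- cells$x2[ci]
    th <- matrix(NA_real_, n_samp, 2, dimnames = list(NULL, nm))
    for (r in seq_len(n_samp)) {
      pop <- synapse_population(n_syn, region = region,
                                interval = c(x1, x2), g_max = 1,
                                kind = "glut", time = time,
                                seed = seed + r)
      placed <- realize_population(pop, tree)
      extra <- if (is.null(extra_stimuli)) list()
               else extra_stimuli(seed + r)
      for (vi in 1:2) {
        model <- variants[[vi]]
        make_stim <- function(g) {
          syns <- lapply(placed$synapses, function(s) { s$g_max <- g; s })
          c(syns, extra)
        }
        res <- find_threshold(
          .spike_predicate(model, make_stim, cfg,
                           window = c(time - 25, cfg$t_stop)),
          seed_value = 1e-3, cap = cap, tol = tol)
        th[r, vi] <- res$threshold
      }
    }
    ok <- stats::complete.cases(th)
    no_ap <- !any(ok)
    if (no_ap) {
      rows[[ci]] <- data.frame(x1 = x1, x2 = x2, median1 = NA, median2 = NA,
                               ratio = NA, U = NA, p = NA,
                               significant = FALSE, no_ap = TRUE)
    } else {
      a <- th[ok, 1]; b <- th[ok, 2]
      mw <- mann_whitney_u(a, b)
      rows[[ci]] <- data.frame(
        x1 = x1, x2 = x2, median1 = median(a), median2 = median(b),
        ratio = median(b) / median(a), U = mw$U, p = mw$p,
        significant = mw$p < alpha / m_tests, no_ap = FALSE)
    }
    samples[[ci]] <- th
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m_tests
  attr(out, "alpha") <- alpha
  attr(out, "samples") <- samples
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Grid experiment with concurrent basal-dendrite drive
#'
#' Adds a basal stimulus to every run of [grid_experiment()]:
#' glutamatergic (`n = 2000` scaled via `n_basal`, conductance 80 percent of
#' the control basal threshold conductance) or GABAergic (`n = 500` scaled,
#' 0.2 nS, activation times uniform in a +/- 25 ms window around the apical
#' activation time, re-drawn per repeat from the repeat seed).
#'
#' @inheritParams grid_experiment
#' @param basal `"glut"`, `"gaba"` or `"none"`
#' @param n_basal number of basal synapses
#' @param basal_g basal per-synapse conductance (nS); for `basal = "glut"`,
#'   `NULL` means 80 percent of the control whole-basal threshold
#' @return a `grid_result` (see [grid_experiment()])
#' @export
combined_basal_apical <- function(variants, basal = c("glut", "gaba", "none"),
                                  x_vals = seq(200, 1300, by = 100),
                                  n_syn = 200, n_basal = 100, n_samp = 5,
                                  seed = 1,
                                  cfg = sim_config(t_stop = 250, settle = 500),
                                  time = 50, basal_g = NULL, cap = 1,
                                  tol = 0.01, cells = NULL) {
  basal <- match.arg(basal)
  tree <- scenario_tree(variants[[1]])
  basal_max <- max(tree$dist0[tree$region == "basal"] +
                   tree$length[tree$region == "basal"])
  if (basal == "glut" && is.null(basal_g)) {
    ## 80% of the control threshold for a whole-basal population
    pop <- synapse_population(n_basal, region = "basal",
                              interval = c(0, basal_max), g_max = 1,
                              kind = "glut", time = time, seed = seed)
    placed <- realize_population(pop, tree)
    res <- find_threshold(
      .spike_predicate(variants[[1]],
                       function(g) lapply(placed$synapses,
                                          function(s) { s$g_max <- g; s }),
                       cfg, window = c(time - 25, cfg$t_stop)),
      seed_value = 1e-3, cap = cap, tol = tol)
    if (res$no_ap) stop("basal drive calibration failed: no AP up to cap")
    basal_g <- 0.8 * res$threshold
  }
  if (basal == "gaba" && is.null(basal_g)) basal_g <- 0.2
  extra <- switch(basal,
    none = NULL,
    glut = function(rep_seed) {
      pop <- synapse_population(n_basal, region = "basal",
                                interval = c(0, basal_max), g_max = basal_g,
                                kind = "glut", time = time,
                                seed = rep_seed * 7919L)
      realize_population(pop, tree)$synapses
    },
    gaba = function(rep_seed) {
      pop <- synapse_population(n_basal, region = "basal",
                                interval = c(0, basal_max), g_max = basal_g,
                                kind = "gaba", time = time,
                                time_window = time + c(-25, 25),
                                seed = rep_seed * 7919L)
      realize_population(pop, tree)$synapses
    })
  grid_experiment(variants, x_vals = x_vals, n_syn = n_syn, n_samp = n_samp,
                  seed = seed, cfg = cfg, time = time, cap = cap, tol = tol,
                  extra_stimuli = extra, cells = cells)
}

#' Split proximal/distal neuromodulation experiment
#'
#' Applies one half-activation shift to the proximal apical dendrite
#' (`[0, boundary]` um) and another to the distal part
#' (`(boundary, tip]`), then measures thresholds along the dendrite.
#'
#' @param model control [cmodel()]
#' @param dv_prox,dv_dist half-activation voltage shifts (mV)
#' @param boundary proximal/distal split (um)
#' @param distances stimulus distances for the sweep (um)
#' @param kind,cfg,duration,tau,tol see [distance_sweep()]
#' @param include list of variants to run: subset of
#'   `c("control", "prox", "prox_dist")`
#' @return [distance_sweep()] table over the requested variants
#' @export
split_neuromod_experiment <- function(model, dv_prox, dv_dist,
                                      boundary = 500,
                                      distances = seq(100, 1000, by = 100),
                                      kind = "pulse",
                                      cfg = sim_config(t_stop = 150,
                                                       settle = 500),
                                      duration = 0.2, tau = 5, tol = 0.01,
                                      include = c("control", "prox",
                                                  "prox_dist")) {
  tree <- scenario_tree(model)
  apical_max <- max(tree$dist0[tree$region == "apical"] +
                    tree$length[tree$region == "apical"])
  stopifnot(boundary > 0, boundary < apical_max)
  prox <- apply_neuromod(model, neuromod_spec(dv = dv_prox, region = "apical",
                                              interval = c(0, boundary)))
  prox_dist <- apply_neuromod(prox,
                              neuromod_spec(dv = dv_dist, region = "apical",
                                            interval = c(boundary + 1e-9,
                                                         apical_max)))
  variants <- list(control = model, prox = prox, prox_dist = prox_dist)
  distance_sweep(variants[include], distances = distances, kind = kind,
                 cfg = cfg, duration = duration, tau = tau, tol = tol)
}
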