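## Stylized thick-tufted pyramidal morphologies and ready-made model
## scenarios, so every protocol runs at desk scale without reconstructed
## morphologies.

#' Parameters of the stylized ball-and-tuft morphology
#'
#' A spherical soma, a long tapering apical trunk carrying a terminal tuft,
#' and a star of basal dendrites.  Defaults emulate a thick-tufted layer V
#' pyramidal cell: apical trunk 1300 um (so the largest protocol distance,
#' 1300 um, lies on the trunk), tuft extending beyond it.
#'
#' @param soma_diam soma diameter (um)
#' @param trunk_len apical trunk length (um)
#' @param trunk_diam_p,trunk_diam_d proximal/distal trunk diameters (um)
#' @param trunk_seg number of trunk sections (taper is resolved per section)
#' @param tuft_n,tuft_len,tuft_diam tuft branch count, length, diameter
#' @param basal_n,basal_len,basal_diam basal branch count, length, diameter
#' @param oblique_n,oblique_len,oblique_diam oblique branches leaving the
#'   mid trunk
#' @param seed seed for the (purely cosmetic) 3D layout
#' @return object of class `ball_and_tuft_params`
#' @export
ball_and_tuft_params <- function(soma_diam = 23, trunk_len = 1300,
                                 trunk_diam_p = 4, trunk_diam_d = 1.2,
                                 trunk_seg = 13,
                                 tuft_n = 2, tuft_len = 300, tuft_diam = 1.0,
                                 basal_n = 5, basal_len = 250,
                                 basal_diam = 1.0,
                                 oblique_n = 2, oblique_len = 150,
                                 oblique_diam = 1.0, seed = 1) {
  stopifnot(soma_diam > 0, trunk_len > 0, trunk_seg >= 1,
            trunk_diam_p > 0, trunk_diam_d > 0)
  structure(as.list(environment()), class = "ball_and_tuft_params")
}

#' Generate a stylized ball-and-tuft morphology
#'
#' Deterministic given the seed: identical parameters write identical SWC
#' bytes.
#'
#' @param p a [ball_and_tuft_params()]
#' @return a [section_tree()] whose apical path distances cover
#'   `[0, trunk_len + tuft_len]` um
#' @export
make_ball_and_tuft <- function(p = ball_and_tuft_params()) {
  stopifnot(inherits(p, "ball_and_tuft_params"))
  secs <- list(data.frame(id = 1L, parent = NA_integer_, parent_frac = 1,
                          region = "soma", length = p$soma_diam,
                          diam_p = p$soma_diam, diam_d = p$soma_diam))
  nid <- 2L
  ## apical trunk: tapered chain
  f <- seq(0, 1, length.out = p$trunk_seg + 1)
  dia <- p$trunk_diam_p + f * (p$trunk_diam_d - p$trunk_diam_p)
  parent <- 1L
  trunk_ids <- integer(p$trunk_seg)
  for (i in seq_len(p$trunk_seg)) {
    secs[[length(secs) + 1L]] <- data.frame(
      id = nid, parent = parent, parent_frac = 1, region = "apical",
      length = p$trunk_len / p$trunk_seg,
      diam_p = dia[i], diam_d = dia[i + 1])
    trunk_ids[i] <- nid; parent <- nid; nid <- nid + 1L
  }
  ## tuft branches from the trunk tip
  for (i in seq_len(p$tuft_n)) {
    secs[[length(secs) + 1L]] <- data.frame(
      id = nid, parent = trunk_ids[p$trunk_seg], parent_frac = 1,
      region = "apical", length = p$tuft_len,
      diam_p = p$tuft_diam, diam_d = p$tuft_diam * 0.8)
    nid <- nid + 1L
  }
  ## obliques from the mid trunk
  if (p$oblique_n > 0) {
    mid <- trunk_ids[max(1L, floor(p$trunk_seg / 3))]
    for (i in seq_len(p$oblique_n)) {
      secs[[length(secs) + 1L]] <- data.frame(
        id = nid, parent = mid, parent_frac = 1, region = "apical",
        length = p$oblique_len, diam_p = p$oblique_diam,
        diam_d = p$oblique_diam * 0.8)
      nid <- nid + 1L
    }
  }
  ## basal star
  for (i in seq_len(p$basal_n)) {
    secs[[length(secs) + 1L]] <- data.frame(
      id = nid, parent = 1L, parent_frac = 1, region = "basal",
      length = p$basal_len, diam_p = p$basal_diam,
      diam_d = p$basal_diam * 0.7)
    nid <- nid + 1L
  }
  section_tree(do.call(rbind, secs))
}

#' Scenario specification for the reduced model
#'
#' The reduced mechanism set carries the leak/Ih/T-type-calcium interplay
#' that drives distance-dependent shunting: leak everywhere, Ih everywhere
#' with an exponentially growing apical profile, T-type (LVA) calcium
#' channels on the apical dendrite with an optional hot zone, a calcium
#' pool, and a generic sodium/potassium spike mechanism at the soma.
#'
#' @param morph a [ball_and_tuft_params()] or a ready [section_tree()]
#' @param ih `"hay"` or `"almog"` Ih kinetics
#' @param ih_base somatic/basal Ih density (S/cm^2)
#' @param ih_lambda length constant of the exponential apical Ih growth (um)
#' @param calva_base apical LVA density outside the hot zone (S/cm^2);
#'   the published removal baseline is 187e-6
#' @param hot_zone logical: include the calcium hot zone
#' @param hot_zone_style `"multiplier"` (x100 over base inside the zone) or
#'   `"absolute"` (fixed density inside, `calva_base` outside)
#' @param hot_zone_interval closed distance interval (um); 685-885 for the
#'   multiplier style, 585-985 for the absolute style
#' @param hot_zone_mult multiplier for the multiplier style
#' @param hot_zone_abs absolute density (S/cm^2) for the absolute style
#' @param g_pas,e_pas,cm,ra passive properties
#' @param spine_factor multiplier on the apical leak density compensating
#'   for unmodelled dendritic spines
#' @param gna,gk somatic spike-mechanism densities (S/cm^2)
#' @param max_seg_len discretization policy (um)
#' @param v_init initial voltage (mV)
#' @param neuromod optional list of [neuromod_spec()] applied after assembly
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(morph = ball_and_tuft_params(),
                          ih = c("hay", "almog"),
                          ih_base = 2e-4, ih_lambda = 400,
                          calva_base = 187e-6,
                          hot_zone = TRUE,
                          hot_zone_style = c("multiplier", "absolute"),
                          hot_zone_interval = NULL,
                          hot_zone_mult = 100, hot_zone_abs = 0.3,
                          g_pas = 3.38e-5, e_pas = -85, cm = 1, ra = 100,
                          spine_factor = 2,
                          gna = 2.0, gk = 0.6,
                          max_seg_len = 20, v_init = -75,
                          neuromod = NULL) {
  ih <- match.arg(ih)
  hot_zone_style <- match.arg(hot_zone_style)
  if (is.null(hot_zone_interval))
    hot_zone_interval <- if (hot_zone_style == "multiplier") c(685, 885)
                         else c(585, 985)
  structure(as.list(environment()), class = "scenario_spec")
}

#' Assemble a compartmental model from a scenario
#'
#' @param spec a [scenario_spec()]
#' @return a [cmodel()] carrying mechanisms `leak` (implicit), `ih`,
#'   `calva` (if apical LVA density > 0), `na`, `kdr`
#' @export
make_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  tree <- if (inherits(spec$morph, "section_tree")) spec$morph
          else make_ball_and_tuft(spec$morph)
  apical_max <- max(tree$dist0[tree$region == "apical"] +
                    tree$length[tree$region == "apical"])
  if (spec$hot_zone && spec$hot_zone_interval[2] > apical_max)
    stop("config error: hot-zone interval [",
         spec$hot_zone_interval[1], ", ", spec$hot_zone_interval[2],
         "] um exceeds the apical extent (", round(apical_max), " um)")
  graph <- discretize(tree, max_len = spec$max_seg_len, ra = spec$ra)
  ## spine correction: apical membrane leak scaled up for unmodelled spines
  g_pas <- rep(spec$g_pas, nrow(graph))
  g_pas[graph$region == "apical"] <- spec$g_pas * spec$spine_factor
  m <- cmodel(graph, cm = spec$cm, g_pas = g_pas, e_pas = spec$e_pas,
              v_init = spec$v_init)

  ih_params <- if (spec$ih == "hay") ih_hay_params() else ih_almog_params()
  ih_profiles <- list(
    conductance_profile("soma", "constant", base = spec$ih_base),
    conductance_profile("basal", "constant", base = spec$ih_base),
    conductance_profile("apical", "exp", base = spec$ih_base,
                        lambda = spec$ih_lambda))
  m <- add_mechanism(m, "ih", ih_params, profiles = ih_profiles)

  if (spec$calva_base > 0 || spec$hot_zone) {
    hz <- if (!spec$hot_zone) NULL
          else if (spec$hot_zone_style == "multiplier")
            list(interval = spec$hot_zone_interval,
                 multiplier = spec$hot_zone_mult)
          else list(interval = spec$hot_zone_interval,
                    absolute = spec$hot_zone_abs)
    calva_profile <- conductance_profile("apical", "constant",
                                         base = spec$calva_base,
                                         hot_zone = hz)
    m <- add_mechanism(m, "calva", calva_params(), profiles = calva_profile)
  }

  ## generic somatic spike mechanism: two-gate Na, one-gate K
  na <- generic_channel_params(
    gates = list(generic_gate(voff = -33, vslo = 6.5, tau_min = 0.08,
                              exponent = 3),
                 generic_gate(voff = -52, vslo = -7.5, tau_min = 0.4,
                              tau_diff = 6, tau_voff = -60, tau_vslo = 8,
                              exponent = 1)),
    e_rev = 50)
  kdr <- generic_channel_params(
    gates = list(generic_gate(voff = -35, vslo = 9, tau_min = 0.8,
                              tau_diff = 4, tau_voff = -50, tau_vslo = 15,
                              exponent = 4)),
    e_rev = -85)
  soma_sel <- as.numeric(graph$region == "soma")
  m <- add_mechanism(m, "na", na, density = spec$gna * soma_sel)
  m <- add_mechanism(m, "kdr", kdr, density = spec$gk * soma_sel)

  if (!is.null(spec$neuromod))
    for (nm in spec$neuromod) m <- apply_neuromod(m, nm)
  attr(m, "tree") <- tree
  attr(m, "spec") <- spec
  m
}

#' @rdname make_scenario
#' @param model a model built by `make_scenario`
#' @export
scenario_tree <- function(model) attr(model, "tree")
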