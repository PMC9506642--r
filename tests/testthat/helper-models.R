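## Shared fixtures, built in code.  Models are cached per test run because
## scenario assembly is cheap but not free.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

## default reduced hot-zone scenario (the stated world)
hz_model <- function() cached("hz", make_scenario(scenario_spec()))

## same scenario with the hot zone removed
nohz_model <- function() cached("nohz",
  make_scenario(scenario_spec(hot_zone = FALSE)))

ih_blocked <- function(m) block(m, 0, mechanism = "ih")

## one iso-potential compartment with distal-apical densities, for the
## gating-replay experiments
one_comp_model <- function(gh = 1.5e-3, glva = 0.0187) {
  tree <- section_tree(data.frame(id = 1L, parent = NA, parent_frac = 1,
                                  region = "soma", length = 20,
                                  diam_p = 20, diam_d = 20))
  m <- cmodel(discretize(tree), g_pas = 6.76e-5, e_pas = -85, v_init = -75)
  m <- add_mechanism(m, "ih", ih_hay_params(), density = gh)
  m <- add_mechanism(m, "calva", calva_params(), density = glva)
  m
}

## passive single compartment (sphere), closed-form RC reference
rc_model <- function(g_pas = 1e-4, e_pas = -70, diam = 20) {
  tree <- section_tree(data.frame(id = 1L, parent = NA, parent_frac = 1,
                                  region = "soma", length = diam,
                                  diam_p = diam, diam_d = diam))
  cmodel(discretize(tree), g_pas = g_pas, e_pas = e_pas, v_init = e_pas)
}

## passive unbranched cable on a tiny soma, for cable-theory checks
cable_model <- function(diam = 2, len = 800, max_len = 10, g_pas = 1e-4,
                        ra = 100) {
  tree <- section_tree(rbind(
    data.frame(id = 1L, parent = NA, parent_frac = 1, region = "soma",
               length = 0.5, diam_p = 0.5, diam_d = 0.5),
    data.frame(id = 2L, parent = 1L, parent_frac = 1, region = "apical",
               length = len, diam_p = diam, diam_d = diam)))
  cmodel(discretize(tree, max_len = max_len, ra = ra),
         g_pas = g_pas, e_pas = -70, v_init = -70)
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("|%s - %s| <= %g",
                              paste(signif(actual, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","),
                              tol))
}
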