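# Shared fixtures, built once per test run. Small templates keep the
# simulation-heavy tests fast; the full-size template is only built inside
# the acceptance suite.

micro_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- build_dome_template(n_target = 90, seed = 42)
    tpl
  }
})

# ~300-cell template used by the screening/sensitivity suites
small_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- build_dome_template(n_target = 300, seed = 7)
    tpl
  }
})

# a fast-converging config for unit tests (baseline converges in ~220 h)
fast_config <- function(...) sim_config(...)

expect_layers_partition <- function(tpl) {
  expect_equal(sum(table(tpl$cells$layer)), nrow(tpl$cells))
  expect_false(any(is.na(tpl$cells$layer)))
}
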