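# Parameter exploration: one-at-a-time grid and QMC random search.

test_that("the default OAT grid enumerates exactly 481 unique parameter sets", {
  g <- grid_oat(baseline_params())
  expect_equal(nrow(g), 481)
  pcols <- samcascade:::PARAM_NAMES
  expect_equal(nrow(unique(g[, pcols])), 481)
  # the all-baseline set appears exactly once
  base <- unclass(baseline_params())
  is_base <- apply(g[, pcols], 1, function(r) all(abs(r - base) < 1e-12))
  expect_equal(sum(is_base), 1L)
  # multipliers span 40% to 200% at 2% steps
  expect_equal(range(g$multiplier), c(0.40, 2.00))
  expect_equal(sort(unique(round(diff(sort(unique(g$multiplier))), 10))), 0.02)
})

test_that("OAT grid counts follow |keys| * ((hi-lo)/step) + 1, checked by brute force", {
  g1 <- grid_oat(baseline_params(), keys = "k_mirp")
  expect_equal(nrow(g1), 81)
  # brute-force enumeration with deduplication for 3 keys
  keys <- c("k_mirp", "k_hrp", "D_mir171")
  g3 <- grid_oat(baseline_params(), keys = keys)
  mult <- seq(0.40, 2.00, by = 0.02)
  brute <- unique(do.call(rbind, lapply(keys, function(k) {
    do.call(rbind, lapply(mult, function(f) {
      p <- unclass(baseline_params()); p[k] <- p[k] * f
      as.data.frame(as.list(p))
    }))
  })))
  expect_equal(nrow(g3), nrow(brute))
  expect_equal(nrow(g3), 3 * 80 + 1)
  # degenerate grid: only the baseline
  expect_equal(nrow(grid_oat(baseline_params(), lo_frac = 1, hi_frac = 1,
                             step_frac = 0.02)), 1)
  # a step that does not tile the interval is rejected
  expect_error(grid_oat(baseline_params(), step_frac = 0.03), "tile")
})

test_that("QMC draws stay in bounds, are seed-reproducible, and log-uniform", {
  sp <- search_space()
  d <- random_search_qmc(sp, n = 4096, seed = 5)
  expect_equal(nrow(d), 4096)
  for (k in samcascade:::SEARCH_KEYS) {
    b <- sp$bounds[[k]]
    expect_true(all(d[[k]] >= b[1] & d[[k]] <= b[2]))
    # empirical log-uniformity: two-sided KS not rejected at alpha = 0.01
    ks <- suppressWarnings(
      stats::ks.test(log(d[[k]]), "punif", log(b[1]), log(b[2])))
    expect_gt(ks$p.value, 0.01)
  }
  expect_identical(random_search_qmc(sp, n = 100, seed = 5)[, -1],
                   d[1:100, -1])
  expect_false(identical(random_search_qmc(sp, n = 100, seed = 6),
                         random_search_qmc(sp, n = 100, seed = 5)))
  one <- random_search_qmc(sp, n = 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_error(search_space(list(k_mirp = c(1, 0.1))), "six search keys|bounds")
  expect_error(search_space(list(k_mirp = c(1, 0.1), k_mirn = c(0.1, 1),
                                 k_hrp = c(0.1, 1), k_hrnm = c(0.1, 1),
                                 k_hrnh = c(0.1, 1), D_mir171 = c(0.001, 0.1))),
               "low < high")
})

test_that("screening a zero ML1p field yields no hits for any parameter set", {
  tpl <- micro_template()
  zero <- samcascade:::new_ml1p(rep(0, nrow(tpl$cells)), "null")
  sets <- random_search_qmc(search_space(), n = 12, seed = 2)
  sc <- screen(sets, tpl, zero)
  expect_equal(nrow(sc), 12)
  expect_false(any(sc$passed))
  expect_true(all(sc$converged))
})

test_that("screen is a pure map over its input sets", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  sets <- random_search_qmc(search_space(), n = 8, seed = 3)
  sc <- screen(sets, tpl, wt)
  # permuting the input permutes the records identically
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  sc2 <- screen(sets[perm, ], tpl, wt)
  expect_equal(sc2$set_id, sc$set_id[perm])
  expect_equal(sc2$total_hamr, sc$total_hamr[perm])
  expect_equal(sc2$passed, sc$passed[perm])
  # re-screening single sets reproduces their verdicts bit-identically
  for (r in c(2, 6)) {
    again <- screen(sets[r, ], tpl, wt)
    expect_identical(again$total_hamr, sc$total_hamr[r])
    expect_identical(again$passed, sc$passed[r])
  }
  # the screening baseline itself passes its own criteria
  basescreen <- screen(data.frame(set_id = 1,
                                  as.list(unclass(baseline_params()))),
                       small_template(), make_ml1p_wildtype(small_template()))
  expect_true(basescreen$passed)
})

test_that("per-set failures are recorded without aborting the sweep", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  sets <- data.frame(set_id = 1:2,
                     k_mirp = c(0.5, 0.5), k_mirn = c(0.1, -1))
  sc <- screen(sets, tpl, wt)
  expect_equal(nrow(sc), 2)
  expect_true(is.na(sc$error[1]))
  expect_match(sc$error[2], "finite")
  expect_false(sc$passed[2])
})
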