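# Cascade model: Laplacian, derivatives, Euler integration, closed-form
# oracle, and the model's structural properties.

test_that("discrete Laplacian matches hand evaluation and conserves mass", {
  # two neighbouring cells with values (0, 2) -> (2, -2)
  two <- structure(list(
    cells = data.frame(id = 1:2, x = c(0, 1.5), y = 0, z = 0, radius = 1,
                       volume = 4 / 3 * pi, shell = c(0L, 1L)),
    edges = cbind(i = 1L, j = 2L), metadata = list()), class = "sam_template")
  expect_equal(discrete_laplacian(c(0, 2), two), c(2, -2))
  tpl <- micro_template()
  n <- nrow(tpl$cells)
  # Laplacian of a constant is zero everywhere
  expect_equal(discrete_laplacian(rep(3.7, n), tpl), rep(0, n))
  # outputs sum to zero on any field (no-flux conservation; symmetric
  # pair contributions cancel up to summation rounding)
  for (s in 1:5) {
    f <- samcascade:::with_local_seed(s, runif(n, 0, 10))
    expect_lt(abs(sum(discrete_laplacian(f, tpl))), 1e-11)
  }
  expect_error(discrete_laplacian(rep(1, n - 1), tpl), "length")
})

test_that("derivatives at the zero state reduce to the production terms", {
  tpl <- micro_template()
  n <- nrow(tpl$cells)
  p <- baseline_params()
  m <- numeric(n); m[5] <- 1  # ML1p in one cell only
  d <- derivatives(matrix(0, n, 5), m, p, tpl)
  expect_equal(unname(d[5, "mir171"]), unname(p["k_mirp"]))
  expect_equal(unname(d[, "ham_mrna"]), rep(unname(p["k_hrp"]), n))
  expect_equal(unname(d[5, "gfp_mrna"]), unname(p["k_grp"]))
  expect_equal(d[, "ham_protein"], rep(0, n))
  expect_equal(d[, "gfp_protein"], rep(0, n))
  expect_equal(d[-5, "mir171"], rep(0, n - 1))
})

test_that("derivatives vanish at the closed-form fixed point when ML1p = 0", {
  tpl <- micro_template()
  n <- nrow(tpl$cells)
  p <- baseline_params()
  ss <- single_cell_steady_state(0, p)
  state <- matrix(rep(ss, each = n), n, 5, dimnames = list(NULL, colnames(ss)))
  d <- derivatives(state, rep(0, n), p, tpl)
  expect_lt(max(abs(d)), 1e-12)
})

test_that("with D = 0 each cell is decoupled from the rest", {
  tpl <- micro_template()
  n <- nrow(tpl$cells)
  p <- update_params(baseline_params(), D_mir171 = 0)
  state <- matrix(samcascade:::with_local_seed(1, runif(5 * n)), n, 5)
  m <- rep(0.5, n)
  d1 <- derivatives(state, m, p, tpl)
  state2 <- state
  state2[2, ] <- state2[2, ] + 1  # perturb a different cell
  d2 <- derivatives(state2, m, p, tpl)
  expect_equal(d1[1, ], d2[1, ])
})

test_that("one Euler step from zero gives [miR171] = dt * k_mirp * ML1p exactly", {
  tpl <- micro_template()
  p <- baseline_params()
  wt <- make_ml1p_wildtype(tpl)
  sim <- simulate_cascade(wt, p, tpl, sim_config(dt = 0.01, t_max = 0.01))
  expect_identical(sim$state[, "mir171"], 0.01 * p[["k_mirp"]] * wt$values)
  expect_identical(sim$state[, "ham_mrna"],
                   rep(0.01 * p[["k_hrp"]], nrow(tpl$cells)))
})

test_that("ML1p = 0 everywhere converges to the analytic no-input steady state", {
  tpl <- micro_template()
  p <- baseline_params()
  zero <- samcascade:::new_ml1p(rep(0, nrow(tpl$cells)), "null")
  sim <- simulate_cascade(zero, p, tpl)
  expect_true(sim$converged)
  expect_equal(max(abs(sim$state[, "mir171"])), 0)
  expect_lt(max(abs(sim$state[, "ham_mrna"] - p[["k_hrp"]] / p[["k_hrnh"]])), 1e-6)
  expect_lt(max(abs(sim$state[, "ham_protein"] -
                      p[["k_hpp"]] / p[["k_hpn"]] * p[["k_hrp"]] / p[["k_hrnh"]])), 1e-6)
  expect_equal(max(abs(sim$state[, c("gfp_mrna", "gfp_protein")])), 0)
})

test_that("with D = 0 every cell's steady state matches the single-cell closed form to 1e-8", {
  tpl <- micro_template()
  p <- update_params(baseline_params(), D_mir171 = 0)
  f <- make_ml1p_ectopic(tpl, 1.2, 0.3)
  # tight derivative tolerance so the state error (~ tol / slowest rate)
  # stays below the 1e-8 oracle bound
  sim <- simulate_cascade(f, p, tpl, sim_config(steady_tol = 1e-10))
  expect_true(sim$converged)
  for (v in sort(unique(f$values))) {
    ss <- single_cell_steady_state(v, p)
    idx <- which(f$values == v)
    expect_lt(max(abs(sweep(sim$state[idx, , drop = FALSE], 2, ss))), 1e-8)
  }
})

test_that("single-cell closed form matches hand arithmetic and limits", {
  p0 <- baseline_params()
  expect_equal(single_cell_steady_state(0, p0)[["mir171"]], 0)
  expect_equal(single_cell_steady_state(0, p0)[["ham_mrna"]],
               p0[["k_hrp"]] / p0[["k_hrnh"]])
  # all six key rates at 0.5, M = 1: miR171* = 1, HAMr* = 0.5/(0.5+0.5) = 0.5
  p <- update_params(p0, k_mirp = 0.5, k_mirn = 0.5, D_mir171 = 0.5,
                     k_hrp = 0.5, k_hrnm = 0.5, k_hrnh = 0.5)
  ss <- single_cell_steady_state(1, p)
  expect_equal(ss[["mir171"]], 1)
  expect_equal(ss[["ham_mrna"]], 0.5)
  # HAMr* decreases monotonically toward 0 as M grows
  hr <- vapply(c(0, 1, 10, 100, 1e4),
               function(M) single_cell_steady_state(M, p0)[["ham_mrna"]],
               numeric(1))
  expect_true(all(diff(hr) < 0))
  expect_lt(hr[5], 1e-3)
})

test_that("steady state is a fixed point: doubling t_max leaves it unchanged", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  cfg <- sim_config(t_max = 1000)
  a <- simulate_cascade(wt, baseline_params(), tpl, cfg)
  expect_true(a$converged)
  b <- simulate_cascade(wt, baseline_params(), tpl, sim_config(t_max = 2000))
  expect_lt(max(abs(a$state - b$state)), cfg$steady_tol)
})

test_that("no species goes negative from the zero initial state", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  sim <- simulate_cascade(wt, baseline_params(), tpl,
                          sim_config(t_max = 50, record_every = 100L))
  expect_true(all(sim$state >= 0))
  expect_true(all(vapply(sim$trajectory, function(s) all(s >= 0), logical(1))))
})

test_that("steady-state [HAMr] is exactly proportional to k_hrp", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  p1 <- baseline_params()
  p2 <- update_params(p1, k_hrp = 3 * p1[["k_hrp"]])
  cfg <- sim_config(t_max = 400)
  a <- simulate_cascade(wt, p1, tpl, cfg, early_stop = FALSE)
  b <- simulate_cascade(wt, p2, tpl, cfg, early_stop = FALSE)
  # miR171 field independent of k_hrp; HAMr scales linearly
  expect_identical(a$state[, "mir171"], b$state[, "mir171"])
  expect_equal(b$state[, "ham_mrna"], 3 * a$state[, "ham_mrna"],
               tolerance = 1e-12)
})

test_that("GFP reporter parameters do not influence the native cascade", {
  tpl <- micro_template()
  f <- make_ml1p_ectopic(tpl, 1.1, 0.4)
  cfg <- sim_config(t_max = 300)
  a <- simulate_cascade(f, baseline_params(), tpl, cfg, early_stop = FALSE)
  b <- simulate_cascade(f, update_params(baseline_params(), k_grp = 0, k_gpp = 0),
                        tpl, cfg, early_stop = FALSE)
  expect_identical(a$state[, c("mir171", "ham_mrna", "ham_protein")],
                   b$state[, c("mir171", "ham_mrna", "ham_protein")])
  expect_equal(max(abs(b$state[, c("gfp_mrna", "gfp_protein")])), 0)
})

test_that("pointwise-increasing the ML1p field never increases steady-state [HAMr]", {
  tpl <- micro_template()
  n <- nrow(tpl$cells)
  p <- baseline_params()
  for (s in 1:5) {
    pair <- samcascade:::with_local_seed(s, {
      lo <- runif(n, 0, 1.2)
      list(lo = lo, hi = lo + runif(n, 0, 0.8))
    })
    a <- simulate_cascade(samcascade:::new_ml1p(pair$lo, "lo"), p, tpl)
    b <- simulate_cascade(samcascade:::new_ml1p(pair$hi, "hi"), p, tpl)
    expect_true(all(b$state[, "ham_mrna"] <= a$state[, "ham_mrna"] + 1e-10))
  }
})

test_that("halving the step changes steady-state total [HAMr] by < 0.1%", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  a <- simulate_cascade(wt, baseline_params(), tpl, sim_config(dt = 0.01))
  b <- simulate_cascade(wt, baseline_params(), tpl, sim_config(dt = 0.005))
  expect_lt(abs(total_ham_mrna(a) - total_ham_mrna(b)) / total_ham_mrna(a),
            0.001)
})

test_that("the stability guard refuses unstable steps and divergence is caught", {
  tpl <- micro_template()
  wt <- make_ml1p_wildtype(tpl)
  # dt = 0.01 with a loss rate >= 100/h trips the guard
  bad <- update_params(baseline_params(), k_gpn = 150)
  expect_error(simulate_cascade(wt, bad, tpl), "unstable")
  expect_warning(
    sim <- simulate_cascade(wt, bad, tpl, sim_config(t_max = 2),
                            allow_unstable = TRUE),
    "unstable")
  # a genuinely exploding configuration aborts with a divergence error
  worse <- update_params(baseline_params(), k_gpn = 250, k_gpp = 1)
  expect_error(
    suppressWarnings(simulate_cascade(wt, worse, tpl, allow_unstable = TRUE)),
    "diverged")
})

test_that("parameter validation rejects malformed sets", {
  expect_error(cascade_params(k_mirn = 0), "strictly positive")
  expect_error(cascade_params(k_mirp = -1), ">= 0")
  expect_error(update_params(baseline_params(), nope = 1), "unknown parameter")
})
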