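#' Rate constants of the cascade model
#'
#' Constructs the validated set of 12 rate constants of the five-equation
#' reaction-diffusion model. Per cell, with `M = [ML1p]`:
#'
#' \deqn{d[miR171]/dt = k_{mirp} M - k_{mirn} [miR171] + D_{mir171} \Delta[miR171]}
#' \deqn{d[HAMr]/dt = k_{hrp} - k_{hrnm} [HAMr][miR171] - k_{hrnh} [HAMr]}
#' \deqn{d[HAMp]/dt = k_{hpp} [HAMr] - k_{hpn} [HAMp]}
#' \deqn{d[GFPr]/dt = k_{grp} M - k_{grn} [GFPr]}
#' \deqn{d[GFPp]/dt = k_{gpp} [GFPr] - k_{gpn} [GFPp]}
#'
#' where \eqn{\Delta} is the discrete graph Laplacian over neighbouring
#' cells. The GFP pair is a transcriptional reporter of the `MIR171`
#' promoter and feeds back on nothing.
#'
#' The defaults are the package's documented baseline: a parameter set
#' inside the search ranges (rates in \[0.1, 1\] per hour, diffusion in
#' \[0.001, 0.1\] area a.u. per hour) that produces the apical-low /
#' basal-high HAM mRNA gradient under wild-type input. It is a package
#' choice, not a published reference set.
#'
#' @param k_mirp miR171 production rate per unit ML1p (a.u./h per a.u.).
#' @param k_mirn miR171 degradation rate (1/h, > 0).
#' @param D_mir171 rescaled (by cell size) diffusion constant of miR171
#'   (area a.u./h).
#' @param k_hrp HAM mRNA production rate, uniform across the SAM (a.u./h).
#' @param k_hrnm miR171-dependent HAM mRNA degradation rate (1/(a.u. h)).
#' @param k_hrnh miR171-independent HAM mRNA degradation rate (1/h, > 0).
#' @param k_hpp,k_hpn HAM protein production (1/h) and degradation (1/h, > 0).
#' @param k_grp,k_grn GFP mRNA production per unit ML1p and degradation
#'   (degradation > 0).
#' @param k_gpp,k_gpn GFP protein production and degradation (degradation > 0).
#' @return named numeric vector of class `cascade_params`.
#' @export
cascade_params <- function(k_mirp = 0.5, k_mirn = 0.1, D_mir171 = 0.01,
                           k_hrp = 0.5, k_hrnm = 0.8, k_hrnh = 0.1,
                           k_hpp = 0.5, k_hpn = 0.5,
                           k_grp = 0.5, k_grn = 0.5,
                           k_gpp = 0.5, k_gpn = 0.5) {
  p <- c(k_mirp = k_mirp, k_mirn = k_mirn, D_mir171 = D_mir171,
         k_hrp = k_hrp, k_hrnm = k_hrnm, k_hrnh = k_hrnh,
         k_hpp = k_hpp, k_hpn = k_hpn,
         k_grp = k_grp, k_grn = k_grn, k_gpp = k_gpp, k_gpn = k_gpn)
  validate_params(p)
  structure(p, class = "cascade_params")
}

validate_params <- function(p) {
  if (!all(PARAM_NAMES %in% names(p))) {
    stop("missing parameters: ", paste(setdiff(PARAM_NAMES, names(p)), collapse = ", "))
  }
  if (any(!is.finite(p)) || any(p < 0)) stop("all rate constants must be finite and >= 0")
  degr <- c("k_mirn", "k_hrnh", "k_hpn", "k_grn", "k_gpn")
  if (any(p[degr] <= 0)) stop("degradation rates must be strictly positive")
  invisible(p)
}

#' The package's documented baseline parameter set
#'
#' Alias for `cascade_params()` with all defaults; see that help page for
#' how the baseline was chosen and what it is not.
#' @export
baseline_params <- function() cascade_params()

#' Modify a parameter set
#' @param params a `cascade_params` vector.
#' @param ... named replacements, e.g. `k_mirp = 0.2`.
#' @export
update_params <- function(params, ...) {
  repl <- unlist(list(...))
  bad <- setdiff(names(repl), PARAM_NAMES)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  validate_params(params)
  structure(params, class = "cascade_params")
}

#' Discrete graph Laplacian on the cell template
#'
#' For cell i, returns the sum over neighbouring cells n of
#' `field[n] - field[i]`. Boundary cells use only their existing
#' neighbours, which is exactly the no-flux boundary condition: the
#' outputs sum to zero on every template.
#'
#' @param field numeric vector, one value per cell.
#' @param template a `sam_template`.
#' @return numeric vector of the same length.
#' @export
discrete_laplacian <- function(field, template) {
  n <- nrow(template$cells)
  if (length(field) != n) stop("field length does not match the cell count")
  e1 <- template$edges[, 1]
  e2 <- template$edges[, 2]
  lap <- numeric(n)
  d <- field[e2] - field[e1]
  acc <- rowsum(c(d, -d), group = c(e1, e2))
  lap[as.integer(rownames(acc))] <- acc[, 1]
  lap
}

#' Time derivatives of the five species
#'
#' Reference (pure R) evaluation of the model right-hand side; the
#' compiled integration kernel is cross-checked against this function.
#'
#' @param state numeric matrix, cells x 5, columns `mir171`, `ham_mrna`,
#'   `ham_protein`, `gfp_mrna`, `gfp_protein`.
#' @param ml1p an `ml1p_field` (or numeric vector of per-cell ML1p).
#' @param params a `cascade_params` vector.
#' @param template a `sam_template`.
#' @return matrix of the same shape: d(state)/dt in a.u./h.
#' @export
derivatives <- function(state, ml1p, params, template) {
  n <- nrow(template$cells)
  m <- if (inherits(ml1p, "ml1p_field")) ml1p$values else ml1p
  if (length(m) != n || nrow(state) != n) stop("state/ml1p length does not match the cell count")
  validate_params(params)
  p <- as.list(params)
  mir <- state[, 1]; hr <- state[, 2]; hp <- state[, 3]
  gr <- state[, 4]; gp <- state[, 5]
  out <- cbind(
    mir171      = p$k_mirp * m - p$k_mirn * mir +
                  p$D_mir171 * discrete_laplacian(mir, template),
    ham_mrna    = p$k_hrp - p$k_hrnm * hr * mir - p$k_hrnh * hr,
    ham_protein = p$k_hpp * hr - p$k_hpn * hp,
    gfp_mrna    = p$k_grp * m - p$k_grn * gr,
    gfp_protein = p$k_gpp * gr - p$k_gpn * gp)
  out
}

#' Simulation configuration
#'
#' @param dt fixed Euler time step in hours (default 0.01 h).
#' @param t_max hard cap on simulated time (h).
#' @param steady_tol steady-state tolerance: converged when every cell's
#'   every species changes more slowly than this (a.u./h).
#' @param record_every record a state snapshot every this many steps
#'   (0 = final state only).
#' @param ceiling divergence guard: any concentration above this aborts.
#' @param check_every test convergence/divergence every this many steps;
#'   a converged result always satisfies the tolerance at its final state.
#' @export
sim_config <- function(dt = 0.01, t_max = 2000, steady_tol = 1e-8,
                       record_every = 0L, ceiling = 1e6, check_every = 10L) {
  stopifnot(dt > 0, steady_tol >= 0, t_max >= dt, ceiling > 0, check_every >= 1)
  structure(list(dt = dt, t_max = t_max, steady_tol = steady_tol,
                 record_every = as.integer(record_every), ceiling = ceiling,
                 check_every = as.integer(check_every)),
            class = "sim_config")
}

#' Integrate the cascade to steady state with explicit forward Euler
#'
#' Advances the all-zero initial state with fixed steps
#' `x <- x + dt * dx/dt` until the steady-state tolerance is met or
#' `t_max` is reached. Deterministic. A stability guard refuses parameter
#' sets whose fastest per-cell loss rate makes the explicit step unstable
#' (`dt * rate >= 1`), unless `allow_unstable = TRUE`.
#'
#' @param ml1p an `ml1p_field`.
#' @param params a `cascade_params` vector.
#' @param template a `sam_template`.
#' @param config a `sim_config`.
#' @param rescale_diffusion `"none"` (the default: one uniform rescaled
#'   diffusion constant, exactly as the model equation is written) or
#'   `"pair_volume"` (per-edge weight inversely proportional to the mean
#'   volume of the cell pair, normalized by the template mean volume).
#' @param early_stop stop as soon as the tolerance is met (default). With
#'   `FALSE` the integration runs exactly to `t_max`, which keeps the step
#'   count identical across runs that are compared pointwise (used by the
#'   sensitivity analysis).
#' @param allow_unstable override the stability guard (a warning is still
#'   emitted).
#' @return object of class `cascade_sim`: list with `state` (cells x 5
#'   matrix), `converged`, `t_final`, `steps`, `max_deriv`, optional
#'   `trajectory`, and `provenance` (parameters, config, template
#'   fingerprint, input label).
#' @export
simulate_cascade <- function(ml1p, params, template, config = sim_config(),
                             rescale_diffusion = c("none", "pair_volume"),
                             early_stop = TRUE, allow_unstable = FALSE) {
  stopifnot(inherits(template, "sam_template"), inherits(config, "sim_config"))
  rescale_diffusion <- match.arg(rescale_diffusion)
  m <- if (inherits(ml1p, "ml1p_field")) ml1p$values else ml1p
  label <- if (inherits(ml1p, "ml1p_field")) ml1p$label else "custom"
  n <- nrow(template$cells)
  if (length(m) != n) stop("ml1p length does not match the cell count")
  validate_params(params)

  e1 <- template$edges[, 1]; e2 <- template$edges[, 2]
  w <- rep(1, length(e1))
  if (rescale_diffusion == "pair_volume") {
    v <- template$cells$volume
    w <- mean(v) / ((v[e1] + v[e2]) / 2)
  }

  # explicit-Euler stability guard on the fastest linear loss rate
  deg <- tabulate(c(e1, e2), n)
  mir_max <- params[["k_mirp"]] * max(m) / params[["k_mirn"]]
  loss <- max(params[["k_mirn"]] + params[["D_mir171"]] * max(deg) * max(w),
              params[["k_hrnh"]] + params[["k_hrnm"]] * mir_max,
              params[["k_hpn"]], params[["k_grn"]], params[["k_gpn"]])
  if (config$dt * loss >= 1) {
    msg <- sprintf(paste0("explicit Euler step dt = %g is unstable for these ",
                          "parameters (fastest loss rate ~ %.3g/h)"),
                   config$dt, loss)
    if (allow_unstable) warning(msg) else
      stop(msg, "; reduce dt or set allow_unstable = TRUE")
  }

  out <- .euler_kernel(as.numeric(m), as.numeric(params[PARAM_NAMES]),
                       as.integer(e1) - 1L, as.integer(e2) - 1L, w,
                       config$dt, config$t_max, config$steady_tol,
                       config$ceiling, early_stop, config$record_every,
                       config$check_every)
  state <- out$state
  dimnames(state) <- list(NULL, SPECIES)
  traj <- NULL
  if (config$record_every > 0L && length(out$trajectory)) {
    traj <- lapply(out$trajectory, function(s) { dimnames(s) <- list(NULL, SPECIES); s })
    names(traj) <- format(out$trajectory_times)
  }
  structure(list(state = state,
                 converged = isTRUE(out$converged),
                 t_final = out$t_final,
                 steps = out$steps,
                 max_deriv = out$max_deriv,
                 trajectory = traj,
                 provenance = list(params = unclass(params),
                                   config = unclass(config),
                                   template_fingerprint = object_fingerprint(template$cells),
                                   ml1p_label = label,
                                   ml1p_fingerprint = object_fingerprint(m),
                                   rescale_diffusion = rescale_diffusion)),
            class = "cascade_sim")
}

#' @export
print.cascade_sim <- function(x, ...) {
  cat("cascade simulation (", nrow(x$state), " cells): ",
      if (x$converged) "converged" else "NOT converged",
      " at t = ", format(x$t_final), " h (", format(x$steps), " steps, max |d/dt| = ",
      format(x$max_deriv, digits = 3), " a.u./h)\n", sep = "")
  cat("  input:", x$provenance$ml1p_label, "\n")
  invisible(x)
}

#' Closed-form single-cell steady state
#'
#' Analytic fixed point of the five equations for an isolated cell (no
#' diffusion) with constant input `M = [ML1p]`:
#' `miR171* = k_mirp M / k_mirn`,
#' `HAMr* = k_hrp / (k_hrnm miR171* + k_hrnh)`,
#' `HAMp* = k_hpp HAMr* / k_hpn`,
#' `GFPr* = k_grp M / k_grn`, `GFPp* = k_gpp GFPr* / k_gpn`.
#'
#' Serves as the analytic oracle for the integrator (with `D_mir171 = 0`
#' every cell must match this).
#'
#' @param ml1p_value scalar ML1p (a.u.).
#' @param params a `cascade_params` vector.
#' @return named numeric vector of the five steady concentrations.
#' @export
single_cell_steady_state <- function(ml1p_value, params) {
  validate_params(params)
  stopifnot(ml1p_value >= 0)
  p <- as.list(params)
  mir <- p$k_mirp * ml1p_value / p$k_mirn
  hr <- p$k_hrp / (p$k_hrnm * mir + p$k_hrnh)
  hp <- p$k_hpp * hr / p$k_hpn
  gr <- p$k_grp * ml1p_value / p$k_grn
  gp <- p$k_gpp * gr / p$k_gpn
  c(mir171 = mir, ham_mrna = hr, ham_protein = hp,
    gfp_mrna = gr, gfp_protein = gp)
}

#' Per-layer mean concentration of one species
#'
#' @param x a `cascade_sim` or a cells x 5 state matrix.
#' @param template a `sam_template` with layers assigned.
#' @param species one of `"mir171"`, `"ham_mrna"`, `"ham_protein"`,
#'   `"gfp_mrna"`, `"gfp_protein"`.
#' @return named numeric vector `c(L1 = , L2 = , CORPUS = )`.
#' @export
layer_means <- function(x, template, species = "ham_mrna") {
  state <- if (inherits(x, "cascade_sim")) x$state else x
  species <- match.arg(species, SPECIES)
  layer <- template$cells$layer
  if (is.null(layer)) stop("template has no layer labels")
  counts <- table(layer)
  if (any(counts == 0)) {
    stop("empty layer(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  vapply(levels(layer),
         function(l) mean(state[layer == l, species]),
         numeric(1))
}

#' Total steady-state HAM mRNA over the template
#' @inheritParams layer_means
#' @export
total_ham_mrna <- function(x) {
  state <- if (inherits(x, "cascade_sim")) x$state else x
  sum(state[, "ham_mrna"])
}

#' Read / write parameter sets as CSV
#'
#' One row per set, one column per rate constant, plus `set_id`.
#' @param params a `cascade_params` or data.frame of parameter rows.
#' @param path CSV path.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "cascade_params")) {
    params <- as.data.frame(as.list(unclass(params)))
    params <- cbind(set_id = 1L, params)
  }
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 1L && all(PARAM_NAMES %in% names(d))) {
    p <- unlist(d[1, PARAM_NAMES])
    return(structure(p, class = "cascade_params"))
  }
  d
}
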