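#' Search space for the six key rate constants
#'
#' Default bounds follow the unbiased random search: the five reaction
#' rates (`k_mirp`, `k_mirn`, `k_hrp`, `k_hrnm`, `k_hrnh`) in
#' \[0.1, 1\] and the rescaled miR171 diffusion constant `D_mir171` in
#' \[0.001, 0.1\] area a.u./h, sampled uniformly on the log scale. The
#' 100-fold production/degradation balance of a dynamically stable SAM is
#' encoded in these bounds.
#'
#' @param bounds named list mapping each of the six keys to `c(low, high)`
#'   with `0 < low < high`.
#' @param scale `"log"` (default) or `"linear"` sampling scale.
#' @export
search_space <- function(bounds = NULL, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (is.null(bounds)) {
    bounds <- list(k_mirp = c(0.1, 1), k_mirn = c(0.1, 1),
                   k_hrp = c(0.1, 1), k_hrnm = c(0.1, 1),
                   k_hrnh = c(0.1, 1), D_mir171 = c(0.001, 0.1))
  }
  if (!setequal(names(bounds), SEARCH_KEYS)) {
    stop("bounds must cover exactly the six search keys: ",
         paste(SEARCH_KEYS, collapse = ", "))
  }
  for (k in SEARCH_KEYS) {
    b <- bounds[[k]]
    if (length(b) != 2 || !(b[1] > 0) || !(b[2] > b[1])) {
      stop("invalid bounds for ", k, ": need 0 < low < high")
    }
  }
  structure(list(bounds = bounds[SEARCH_KEYS], scale = scale),
            class = "search_space")
}

#' One-at-a-time multiplier grid around a baseline
#'
#' For each key, generates one variant per multiplier in
#' `seq(lo_frac, hi_frac, by = step_frac)` with all other parameters held
#' at baseline; the all-baseline set appears exactly once. The defaults
#' (40% to 200% of the baseline at 2% intervals over the six key
#' parameters) enumerate 6 x 80 + 1 = 481 unique parameter sets.
#'
#' @param baseline a `cascade_params` vector.
#' @param lo_frac,hi_frac multiplier range with `lo_frac <= 1 <= hi_frac`.
#' @param step_frac multiplier step; must tile the interval exactly.
#' @param keys parameters to vary (default: the six search keys).
#' @return data.frame with `set_id`, `key`, `multiplier`, and the 12
#'   parameter columns; ordered baseline first, then by key (in `keys`
#'   order) and ascending multiplier.
#' @export
grid_oat <- function(baseline = baseline_params(), lo_frac = 0.40,
                     hi_frac = 2.00, step_frac = 0.02, keys = SEARCH_KEYS) {
  validate_params(baseline)
  stopifnot(lo_frac <= 1, hi_frac >= 1, step_frac > 0,
            all(keys %in% PARAM_NAMES))
  span <- hi_frac - lo_frac
  nstep <- round(span / step_frac)
  if (abs(nstep * step_frac - span) > 1e-9) {
    stop("step_frac does not tile the multiplier interval")
  }
  mult <- lo_frac + step_frac * (0:nstep)
  rows <- list(data.frame(key = "baseline", multiplier = 1,
                          as.list(unclass(baseline))))
  for (k in keys) {
    for (f in mult) {
      if (abs(f - 1) < 1e-9) next  # baseline already included once
      p <- unclass(baseline)
      p[k] <- p[k] * f
      rows[[length(rows) + 1L]] <- data.frame(key = k, multiplier = f,
                                              as.list(p))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(set_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Radical-inverse (van der Corput) digits of idx in the given base,
# vectorized over idx.
radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

# Randomized (random-shift) Halton points in the unit cube.
qmc_unit_points <- function(n, dim, seed) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19)[seq_len(dim)]
  shift <- with_local_seed(seed, stats::runif(dim))
  u <- vapply(seq_len(dim),
              function(j) (radical_inverse(seq_len(n), bases[j]) + shift[j]) %% 1,
              numeric(n))
  matrix(u, nrow = n)
}

#' Quasi-Monte-Carlo random search draws
#'
#' Samples `n` six-parameter sets from a seeded randomized low-discrepancy
#' (random-shift Halton) sequence in the unit cube, mapped to the search
#' bounds log-uniformly (`x = low * (high/low)^u`) or linearly per the
#' space's scale. Deterministic given the seed.
#'
#' @param space a `search_space`.
#' @param n number of parameter sets (default 20000, the reference search
#'   size).
#' @param seed integer seed for the randomization shift.
#' @return data.frame with `set_id` and one column per search key; every
#'   draw lies within its bounds.
#' @export
random_search_qmc <- function(space = search_space(), n = 20000, seed = 1L) {
  stopifnot(inherits(space, "search_space"), n >= 1)
  u <- qmc_unit_points(n, length(space$bounds), seed)
  out <- data.frame(set_id = seq_len(n))
  for (j in seq_along(space$bounds)) {
    b <- space$bounds[[j]]
    out[[names(space$bounds)[j]]] <-
      if (space$scale == "log") b[1] * (b[2] / b[1])^u[, j]
      else b[1] + u[, j] * (b[2] - b[1])
  }
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Screen parameter sets through simulation and classification
#'
#' Runs one wild-type-input simulation per parameter set and classifies
#' the steady state with the gradient criteria. Parameters absent from
#' `sets` are filled from `baseline`. Per-set failures (divergence,
#' non-convergence) are recorded in the output, never abort the sweep;
#' unconverged sets count as non-hits.
#'
#' @param sets data.frame of parameter sets (any subset of the 12 rate
#'   columns, e.g. from [grid_oat()] or [random_search_qmc()]).
#' @param template a `sam_template`.
#' @param ml1p an `ml1p_field` (typically wild type).
#' @param criteria a `gradient_criteria`.
#' @param config a `sim_config`.
#' @param baseline fills unvaried parameters.
#' @param verbose print a progress line every 500 sets.
#' @return data.frame with one row per set: `set_id`, the 12 parameter
#'   values, `converged`, `passed`, layer means of HAM mRNA, the
#'   L1/corpus ratio, `total_hamr`, and `error` (NA when clean).
#' @export
screen <- function(sets, template, ml1p, criteria = gradient_criteria(),
                   config = sim_config(), baseline = baseline_params(),
                   verbose = FALSE) {
  stopifnot(is.data.frame(sets), nrow(sets) >= 1)
  pcols <- intersect(names(sets), PARAM_NAMES)
  if (!length(pcols)) stop("sets contains no recognized parameter columns")
  ids <- if ("set_id" %in% names(sets)) sets$set_id else seq_len(nrow(sets))
  recs <- vector("list", nrow(sets))
  for (r in seq_len(nrow(sets))) {
    p <- unclass(baseline)
    p[pcols] <- as.numeric(sets[r, pcols])
    rec <- c(list(set_id = ids[r]), as.list(p),
             list(converged = FALSE, passed = FALSE,
                  hamr_L1 = NA_real_, hamr_L2 = NA_real_,
                  hamr_CORPUS = NA_real_, l1_corpus_ratio = NA_real_,
                  total_hamr = NA_real_, error = NA_character_))
    res <- tryCatch({
      sim <- simulate_cascade(ml1p, structure(p, class = "cascade_params"),
                              template, config)
      rec$converged <- sim$converged
      if (sim$converged) {
        v <- classify_wt_gradient(sim, template, criteria)
        rec$passed <- v$passed
        lm <- v$metrics$hamr_layer_means
        rec$hamr_L1 <- lm[["L1"]]; rec$hamr_L2 <- lm[["L2"]]
        rec$hamr_CORPUS <- lm[["CORPUS"]]
        rec$l1_corpus_ratio <- v$metrics$l1_corpus_ratio
        rec$total_hamr <- total_ham_mrna(sim)
      }
      rec
    }, error = function(e) { rec$error <- conditionMessage(e); rec })
    recs[[r]] <- as.data.frame(res, stringsAsFactors = FALSE)
    if (verbose && r %% 500 == 0) {
      message(sprintf("screen: %d/%d sets, %d hits so far", r, nrow(sets),
                      sum(vapply(recs[seq_len(r)], function(x) x$passed, logical(1)))))
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
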