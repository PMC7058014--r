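#' Wild-type in-silico experiment
#'
#' Simulates the wild-type ML1p input (1 a.u. in L1, 0 elsewhere) with the
#' given parameters, classifies the steady state for the apical-basal HAM
#' mRNA gradient, and optionally writes the per-cell result, a manifest,
#' and a VTK view to `out_dir`.
#'
#' @param params a `cascade_params` vector.
#' @param template a `sam_template`.
#' @param criteria a `gradient_criteria`.
#' @param config a `sim_config`.
#' @param out_dir optional output directory (created if missing).
#' @return list with `result` (`cascade_sim`) and `verdict`
#'   (`pattern_verdict`).
#' @export
run_wt_experiment <- function(params = baseline_params(), template,
                              criteria = gradient_criteria(),
                              config = sim_config(), out_dir = NULL) {
  ml1p <- make_ml1p_wildtype(template)
  res <- simulate_cascade(ml1p, params, template, config)
  verdict <- classify_wt_gradient(res, template, criteria)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(res, template, file.path(out_dir, "wt_result.csv"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   scenario = "wt", params = params, config = config,
                   criteria = criteria, template = template,
                   verdict = verdict)
  }
  list(result = res, verdict = verdict)
}

#' Ectopic-activation in-silico experiment
#'
#' Runs matched wild-type and ectopic-activation simulations (identical
#' parameters and template; the input field is the only difference),
#' reports the per-layer GFP reporter increase and the HAM mRNA
#' suppression verdict.
#'
#' @inheritParams run_wt_experiment
#' @param l1_value,deep_value ectopic ML1p levels (defaults 1.1 / 0.4 a.u.).
#' @param reduction_threshold per-layer threshold for
#'   [classify_suppression()].
#' @return list with `wt`, `ectopic` (`cascade_sim`), `suppression`
#'   (`pattern_verdict`), `gfp_layer_means` (wild type vs ectopic), and
#'   `hamr_reduced_all_layers` (strict per-layer reduction flag).
#' @export
run_ectopic_experiment <- function(params = baseline_params(), template,
                                   l1_value = 1.1, deep_value = 0.4,
                                   reduction_threshold = 0.5,
                                   config = sim_config(), out_dir = NULL) {
  wt <- simulate_cascade(make_ml1p_wildtype(template), params, template, config)
  ect <- simulate_cascade(make_ml1p_ectopic(template, l1_value, deep_value),
                          params, template, config)
  supp <- classify_suppression(ect, wt, template, reduction_threshold)
  gfp <- rbind(wild_type = layer_means(wt, template, "gfp_protein"),
               ectopic = layer_means(ect, template, "gfp_protein"))
  strict <- all(layer_means(ect, template, "ham_mrna") <
                  layer_means(wt, template, "ham_mrna"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(wt, template, file.path(out_dir, "wt_result.csv"))
    write_result_csv(ect, template, file.path(out_dir, "ectopic_result.csv"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   scenario = "ectopic", params = params, config = config,
                   criteria = list(l1_value = l1_value, deep_value = deep_value,
                                   reduction_threshold = reduction_threshold),
                   template = template, verdict = supp)
  }
  list(wt = wt, ectopic = ect, suppression = supp,
       gfp_layer_means = gfp, hamr_reduced_all_layers = strict)
}

#' Robustness panel over the 75 perturbed ML1p inputs
#'
#' Simulates all 75 perturbation patterns from [sample_ml1p_patterns()]
#' plus the matched wild-type run and summarizes, per pattern, the
#' per-layer HAM mRNA ratios to wild type, whether every layer is
#' strictly reduced, and whether the corpus drops below
#' `reduction_threshold` of its wild-type level.
#'
#' @inheritParams run_wt_experiment
#' @param seed seed for the random pattern draws.
#' @param reduction_threshold corpus "dramatic reduction" threshold.
#' @return data.frame with one row per pattern: `label`, `family`,
#'   `converged`, `ratio_L1`, `ratio_L2`, `ratio_CORPUS`,
#'   `reduced_all_layers`, `corpus_suppressed`.
#' @export
run_perturbation_panel <- function(params = baseline_params(), template,
                                   seed = 1L, reduction_threshold = 0.5,
                                   config = sim_config()) {
  patterns <- sample_ml1p_patterns(template, seed)
  fam <- attr(patterns, "family")
  wt <- simulate_cascade(make_ml1p_wildtype(template), params, template, config)
  if (!wt$converged) stop("wild-type reference simulation did not converge")
  hw <- layer_means(wt, template, "ham_mrna")
  rows <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    sim <- simulate_cascade(patterns[[i]], params, template, config)
    hp <- layer_means(sim, template, "ham_mrna")
    ratio <- hp / hw
    rows[[i]] <- data.frame(label = patterns[[i]]$label, family = fam[i],
                            converged = sim$converged,
                            ratio_L1 = ratio[["L1"]], ratio_L2 = ratio[["L2"]],
                            ratio_CORPUS = ratio[["CORPUS"]],
                            reduced_all_layers = sim$converged && all(ratio < 1),
                            corpus_suppressed = sim$converged &&
                              ratio[["CORPUS"]] < reduction_threshold)
  }
  out <- do.call(rbind, rows)
  attr(out, "wt_layer_means") <- hw
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write a per-cell simulation result as CSV
#'
#' Columns: `id`, `layer`, and the five species concentrations.
#' @param result a `cascade_sim`.
#' @param template the matching `sam_template`.
#' @param path CSV path.
#' @export
write_result_csv <- function(result, template, path) {
  stopifnot(inherits(result, "cascade_sim"))
  d <- data.frame(id = template$cells$id, layer = template$cells$layer,
                  result$state)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export a simulation result as a legacy-VTK point cloud
#'
#' Writes an ASCII legacy VTK polydata file with one point per cell and
#' the five species (plus the sphere radius) as point scalars, for 3D
#' rendering of the simulated SAM. With `half_clip = TRUE` only the
#' half-dome with `y <= 0` is written, exposing the inner layers the way
#' half-SAM views do.
#'
#' @param result a converged `cascade_sim`.
#' @param template the matching `sam_template`.
#' @param path output `.vtk` path.
#' @param half_clip clip to one side of the dome axis plane.
#' @export
export_vtk <- function(result, template, path, half_clip = FALSE) {
  stopifnot(inherits(result, "cascade_sim"))
  if (!result$converged) stop("refusing to export an unconverged simulation")
  keep <- if (half_clip) template$cells$y <= 0 else rep(TRUE, nrow(template$cells))
  cells <- template$cells[keep, ]
  state <- result$state[keep, , drop = FALSE]
  np <- nrow(cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "samcascade steady-state point cloud (display bounds: 0-2 a.u.)",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", np)), con)
  writeLines(sprintf("%.8g %.8g %.8g", cells$x, cells$y, cells$z), con)
  writeLines(sprintf("POINT_DATA %d", np), con)
  for (sp in c(SPECIES, "radius")) {
    v <- if (sp == "radius") cells$radius else state[, sp]
    writeLines(c(sprintf("SCALARS %s float 1", sp), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.8g", v), con)
  }
  invisible(path)
}

# JSON manifest capturing every effective setting of a run.
write_manifest <- function(path, scenario, params, config, criteria,
                           template, verdict = NULL) {
  jsonlite::write_json(
    list(package = "samcascade",
         version = as.character(utils::packageVersion("samcascade")),
         scenario = scenario,
         params = as.list(unclass(params)),
         config = unclass(config),
         criteria = unclass(criteria),
         template = template$metadata,
         template_fingerprint = object_fingerprint(template$cells),
         verdict = if (!is.null(verdict)) list(passed = verdict$passed)),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
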