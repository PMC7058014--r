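#' Criteria for the wild-type HAM mRNA gradient
#'
#' Quantitative operationalization of the qualitative wild-type readout:
#' an apical-low / basal-high gradient of HAM mRNA with the reporter
#' confined to the epidermis. All thresholds are explicit, configurable,
#' and recorded in every verdict.
#'
#' @param l1_ratio_max maximum allowed (L1 mean)/(corpus mean) of
#'   steady-state HAM mRNA (default 0.2: at least a five-fold
#'   apical-basal drop).
#' @param require_monotone require strictly increasing layer means
#'   L1 < L2 < corpus (default TRUE).
#' @param corpus_floor minimum corpus mean HAM mRNA in a.u. (default 0.1;
#'   rules out global shutdown masquerading as a gradient).
#' @param gfp_l1_only require the GFP reporter protein to be epidermis-
#'   restricted: corpus mean below `gfp_corpus_frac` of the L1 mean.
#' @param gfp_corpus_frac fraction for the GFP restriction (default 0.05).
#' @export
gradient_criteria <- function(l1_ratio_max = 0.2, require_monotone = TRUE,
                              corpus_floor = 0.1, gfp_l1_only = TRUE,
                              gfp_corpus_frac = 0.05) {
  stopifnot(l1_ratio_max > 0, l1_ratio_max < 1, corpus_floor > 0,
            gfp_corpus_frac > 0)
  structure(list(l1_ratio_max = l1_ratio_max,
                 require_monotone = require_monotone,
                 corpus_floor = corpus_floor,
                 gfp_l1_only = gfp_l1_only,
                 gfp_corpus_frac = gfp_corpus_frac),
            class = "gradient_criteria")
}

new_verdict <- function(passed, metrics, criteria) {
  structure(list(passed = isTRUE(passed), metrics = metrics,
                 criteria_used = criteria),
            class = "pattern_verdict")
}

#' @export
print.pattern_verdict <- function(x, ...) {
  cat("pattern verdict:", if (x$passed) "PASS" else "FAIL", "\n")
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify a wild-type simulation for the apical-basal HAM mRNA gradient
#'
#' Applies the enabled sub-criteria of [gradient_criteria()] to the
#' steady-state HAM mRNA (and GFP protein) layer means. Refuses
#' unconverged simulations.
#'
#' @param result a converged `cascade_sim`.
#' @param template the `sam_template` used for the simulation.
#' @param criteria a `gradient_criteria` object.
#' @return a `pattern_verdict` whose `passed` flag is a pure function of
#'   the computed metrics and the criteria.
#' @export
classify_wt_gradient <- function(result, template, criteria = gradient_criteria()) {
  stopifnot(inherits(result, "cascade_sim"), inherits(criteria, "gradient_criteria"))
  if (!result$converged) stop("refusing to classify an unconverged simulation")
  hamr <- layer_means(result, template, "ham_mrna")
  gfpp <- layer_means(result, template, "gfp_protein")
  ratio <- hamr[["L1"]] / hamr[["CORPUS"]]
  metrics <- list(hamr_layer_means = hamr,
                  gfpp_layer_means = gfpp,
                  l1_corpus_ratio = ratio)
  ok <- is.finite(ratio) && ratio < criteria$l1_ratio_max
  if (criteria$require_monotone) {
    ok <- ok && hamr[["L1"]] < hamr[["L2"]] && hamr[["L2"]] < hamr[["CORPUS"]]
  }
  ok <- ok && hamr[["CORPUS"]] > criteria$corpus_floor
  if (criteria$gfp_l1_only) {
    ok <- ok && is.finite(gfpp[["L1"]]) && gfpp[["L1"]] > 0 &&
      gfpp[["CORPUS"]] < criteria$gfp_corpus_frac * gfpp[["L1"]]
  }
  new_verdict(ok, metrics, criteria)
}

#' Classify suppression of HAM mRNA under a perturbed ML1p input
#'
#' Compares a perturbed (e.g. ectopic-activation) simulation against its
#' matched wild-type run with identical parameters and template. The
#' verdict passes iff in every layer the perturbed mean steady-state HAM
#' mRNA is below `reduction_threshold` times the wild-type mean; the
#' default 0.5 encodes "dramatic reduction" as a more-than-50% drop.
#'
#' @param perturbed,wildtype converged `cascade_sim` objects that share
#'   template and parameters (enforced via provenance fingerprints).
#' @param template the shared `sam_template`.
#' @param reduction_threshold per-layer ratio bound in (0, 1\]; use 1 for
#'   plain strict reduction.
#' @return a `pattern_verdict` with per-layer ratios in its metrics.
#' @export
classify_suppression <- function(perturbed, wildtype, template,
                                 reduction_threshold = 0.5) {
  stopifnot(inherits(perturbed, "cascade_sim"), inherits(wildtype, "cascade_sim"),
            reduction_threshold > 0, reduction_threshold <= 1)
  if (!perturbed$converged || !wildtype$converged) {
    stop("refusing to classify unconverged simulations")
  }
  if (!identical(perturbed$provenance$template_fingerprint,
                 wildtype$provenance$template_fingerprint)) {
    stop("perturbed and wild-type runs used different templates")
  }
  if (!identical(perturbed$provenance$params, wildtype$provenance$params)) {
    stop("perturbed and wild-type runs used different parameters")
  }
  hp <- layer_means(perturbed, template, "ham_mrna")
  hw <- layer_means(wildtype, template, "ham_mrna")
  ratio <- hp / hw
  metrics <- list(hamr_perturbed = hp, hamr_wildtype = hw,
                  layer_ratios = ratio)
  new_verdict(all(ratio < reduction_threshold), metrics,
              list(reduction_threshold = reduction_threshold))
}
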