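#' ML1p input fields
#'
#' The model input is the per-cell concentration of functional ATML1/PDF2
#' protein, `[ML1p]` (a.u.). In the wild type it is 1 a.u. in the L1
#' (epidermal) layer and 0 a.u. everywhere else; ectopic-activation
#' scenarios raise it in the deeper layers as well.
#'
#' @param template a `sam_template` with layers assigned.
#' @return an object of class `ml1p_field`: list with `values` (numeric,
#'   one per cell) and `label`.
#' @export
make_ml1p_wildtype <- function(template) {
  stopifnot(inherits(template, "sam_template"), !is.null(template$cells$layer))
  new_ml1p(as.numeric(template$cells$layer == "L1"), "wild_type")
}

#' Ectopic-activation ML1p field
#'
#' Sets `[ML1p]` to `l1_value` in the epidermis and `deep_value` in the L2
#' and corpus. The reference ectopic scenario (ATML1 over-activation) uses
#' 1.1 a.u. in the L1 and 0.4 a.u. in the deeper layers.
#'
#' @inheritParams make_ml1p_wildtype
#' @param l1_value ML1p in the L1 layer (a.u., >= 0).
#' @param deep_value ML1p in L2 and corpus (a.u., >= 0).
#' @export
make_ml1p_ectopic <- function(template, l1_value = 1.1, deep_value = 0.4) {
  stopifnot(inherits(template, "sam_template"), !is.null(template$cells$layer),
            l1_value >= 0, deep_value >= 0)
  v <- ifelse(template$cells$layer == "L1", l1_value, deep_value)
  new_ml1p(as.numeric(v), sprintf("ectopic_%g_%g", l1_value, deep_value))
}

new_ml1p <- function(values, label) {
  stopifnot(all(values >= 0), all(is.finite(values)))
  structure(list(values = values, label = label), class = "ml1p_field")
}

#' @export
print.ml1p_field <- function(x, ...) {
  cat("ML1p field '", x$label, "': ", length(x$values), " cells, range [",
      format(min(x$values)), ", ", format(max(x$values)), "] a.u.\n", sep = "")
  invisible(x)
}

#' Sample the 75 perturbed ML1p input patterns
#'
#' Reproduces the robustness panel of ectopic-activation inputs: three
#' families of 25 patterns each (24 uniform-random draws plus one fixed
#' member), 75 in total.
#'
#' * Family A ("in-situ range"): L1 value in \[1.05, 1.5\], deep-layer value
#'   in \[0.3, 0.6\]; fixed member (1.3, 0.5).
#' * Family B ("deep-high range"): L1 in \[1.05, 1.5\], deep in
#'   \[0.6, 2.0\]; fixed member (1.1, 0.7).
#' * Family C ("uniform"): a single value in \[1.05, 1.5\] applied to every
#'   layer; fixed member 1.1 everywhere.
#'
#' Draws are made in the fixed family order A, B, C from one seeded stream,
#' so the full collection is reproducible from the seed.
#'
#' @inheritParams make_ml1p_wildtype
#' @param seed integer seed for the random draws.
#' @return list of 75 `ml1p_field` objects; each carries attributes-free
#'   labels of the form `"A_r07"`, `"B_fixed"`, ... and the list has a
#'   `family` attribute (character vector of length 75).
#' @export
sample_ml1p_patterns <- function(template, seed = 1L) {
  stopifnot(inherits(template, "sam_template"), !is.null(template$cells$layer))
  draws <- with_local_seed(seed, {
    list(A = cbind(stats::runif(24, 1.05, 1.5), stats::runif(24, 0.3, 0.6)),
         B = cbind(stats::runif(24, 1.05, 1.5), stats::runif(24, 0.6, 2.0)),
         C = stats::runif(24, 1.05, 1.5))
  })
  fields <- list()
  fam <- character(0)
  for (i in 1:24) {
    f <- make_ml1p_ectopic(template, draws$A[i, 1], draws$A[i, 2])
    f$label <- sprintf("A_r%02d", i)
    fields <- c(fields, list(f)); fam <- c(fam, "A")
  }
  f <- make_ml1p_ectopic(template, 1.3, 0.5); f$label <- "A_fixed"
  fields <- c(fields, list(f)); fam <- c(fam, "A")
  for (i in 1:24) {
    f <- make_ml1p_ectopic(template, draws$B[i, 1], draws$B[i, 2])
    f$label <- sprintf("B_r%02d", i)
    fields <- c(fields, list(f)); fam <- c(fam, "B")
  }
  f <- make_ml1p_ectopic(template, 1.1, 0.7); f$label <- "B_fixed"
  fields <- c(fields, list(f)); fam <- c(fam, "B")
  for (i in 1:24) {
    f <- make_ml1p_ectopic(template, draws$C[i], draws$C[i])
    f$label <- sprintf("C_r%02d", i)
    fields <- c(fields, list(f)); fam <- c(fam, "C")
  }
  f <- make_ml1p_ectopic(template, 1.1, 1.1); f$label <- "C_fixed"
  fields <- c(fields, list(f)); fam <- c(fam, "C")
  attr(fields, "family") <- fam
  attr(fields, "seed") <- as.integer(seed)
  fields
}

#' Write / read an ML1p field as CSV
#'
#' Columns: `id`, `ml1p`, `label`.
#' @param field an `ml1p_field`.
#' @param path CSV file path.
#' @export
write_ml1p <- function(field, path) {
  stopifnot(inherits(field, "ml1p_field"))
  utils::write.csv(data.frame(id = seq_along(field$values),
                              ml1p = field$values,
                              label = field$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ml1p
#' @export
read_ml1p <- function(path) {
  d <- utils::read.csv(path)
  new_ml1p(d$ml1p[order(d$id)], as.character(d$label[1]))
}
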