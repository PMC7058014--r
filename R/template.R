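#' Build a dome-shaped multicellular SAM template from overlapping spheres
#'
#' Generates a synthetic 3D cell packing that mimics the shoot apical
#' meristem: a spherical-cap dome filled with concentric shells of
#' near-uniform spheres. Cells overlap their neighbours; the neighbourhood
#' graph is derived from sphere overlaps and realizes a no-flux boundary
#' implicitly (boundary cells simply have fewer neighbours). The outermost
#' shell is the L1 (epidermis), the next shell the L2, and all deeper
#' shells the corpus.
#'
#' The construction places shells at radii `R, R - d, R - 2d, ...` from the
#' dome's centre of curvature, where the shell spacing `d` is solved so that
#' the near-uniform surface density `1/d^2` integrates to `n_target` cells;
#' cells are then apportioned to shells proportionally to cap area so the
#' requested count is met exactly. Within a shell, cells sit on a
#' golden-angle (Fibonacci) spiral over the spherical cap, with a small
#' seeded jitter on positions and radii to avoid degenerate symmetry.
#'
#' @param n_target requested number of cells (>= 10). The default 1216
#'   matches the template size used throughout the package's reference
#'   simulations.
#' @param radius_of_curvature dome radius of curvature (length a.u.).
#' @param height dome height (length a.u.); must not exceed
#'   `radius_of_curvature`. The default equal to the radius gives a
#'   hemispherical dome.
#' @param overlap_factor neighbourhood criterion: cells i, j are neighbours
#'   iff `dist(i, j) < overlap_factor * (radius_i + radius_j)`. The default
#'   1 is strict sphere overlap.
#' @param cell_radius_factor sphere radius as a fraction of the shell
#'   spacing `d`; the default 0.65 guarantees overlap of adjacent cells
#'   within and across shells.
#' @param jitter_frac positional jitter amplitude as a fraction of `d`.
#' @param radius_jitter_frac relative jitter on sphere radii.
#' @param seed integer seed; templates are bit-identical for equal seeds.
#' @return An object of class `sam_template`: a list with `cells` (a
#'   data.frame with columns id, x, y, z, radius, volume, shell, layer),
#'   `edges` (two-column integer matrix of unordered neighbour pairs,
#'   i < j), and `metadata` (generation parameters including the seed).
#' @examples
#' tpl <- build_dome_template(n_target = 120, seed = 1)
#' table(tpl$cells$layer)
#' @export
build_dome_template <- function(n_target = 1216,
                                radius_of_curvature = 1,
                                height = radius_of_curvature,
                                overlap_factor = 1,
                                cell_radius_factor = 0.65,
                                jitter_frac = 0.04,
                                radius_jitter_frac = 0.03,
                                seed = 1L) {
  if (n_target < 10) stop("n_target must be at least 10")
  R <- radius_of_curvature
  h <- height
  if (h <= 0 || R <= 0) stop("dome dimensions must be positive")
  if (h > R + 1e-12) stop("dome height must not exceed the radius of curvature")
  z0 <- R - h  # base plane

  shell_radii <- function(d) {
    r <- seq(R, by = -d, length.out = floor(R / d) + 1L)
    r[r > z0 + 1e-12 & r > 1e-12]
  }
  cap_area <- function(r) 2 * pi * r * (r - z0)
  density_count <- function(d) sum(cap_area(shell_radii(d))) / d^2

  # solve the shell spacing by bisection; count decreases with d
  lo <- h / 400
  hi <- h * 0.999
  if (density_count(hi) > n_target) {
    stop("geometrically impossible configuration: shell spacing would exceed the dome height")
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (density_count(mid) > n_target) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2

  radii <- shell_radii(d)
  if (length(radii) < 2L) {
    stop("geometrically impossible configuration: fewer than two shells fit the dome")
  }

  # apportion exactly n_target cells over shells, proportional to cap area
  w <- cap_area(radii)
  raw <- n_target * w / sum(w)
  n_k <- floor(raw)
  rem <- n_target - sum(n_k)
  if (rem > 0) {
    order_frac <- order(raw - n_k, decreasing = TRUE)
    n_k[order_frac[seq_len(rem)]] <- n_k[order_frac[seq_len(rem)]] + 1L
  }
  keep <- n_k > 0L
  radii <- radii[keep]
  n_k <- n_k[keep]
  if (length(radii) < 2L) {
    stop("geometrically impossible configuration: cell budget fills fewer than two shells")
  }

  golden <- pi * (3 - sqrt(5))
  pts <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    nk <- n_k[k]
    rk <- radii[k]
    zz <- z0 + (rk - z0) * (seq_len(nk) - 0.5) / nk
    phi <- 0.7 * (k - 1) + golden * (seq_len(nk) - 1)
    rho <- sqrt(pmax(rk^2 - zz^2, 0))
    pts[[k]] <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = zz,
                      shell = k - 1)
  }
  pts <- do.call(rbind, pts)
  n <- nrow(pts)

  r_cell <- cell_radius_factor * d
  jit <- with_local_seed(seed, {
    list(pos = matrix(stats::runif(3 * n, -1, 1), ncol = 3) * jitter_frac * d,
         rad = 1 + stats::runif(n, -1, 1) * radius_jitter_frac)
  })
  cells <- data.frame(
    id = seq_len(n),
    x = pts[, "x"] + jit$pos[, 1],
    y = pts[, "y"] + jit$pos[, 2],
    z = pts[, "z"] + jit$pos[, 3],
    radius = r_cell * jit$rad,
    shell = as.integer(pts[, "shell"])
  )
  cells$volume <- 4 / 3 * pi * cells$radius^3

  tpl <- structure(
    list(cells = cells, edges = NULL,
         metadata = list(n_target = n_target,
                         radius_of_curvature = R, height = h,
                         shell_spacing = d,
                         overlap_factor = overlap_factor,
                         cell_radius_factor = cell_radius_factor,
                         jitter_frac = jitter_frac,
                         radius_jitter_frac = radius_jitter_frac,
                         seed = as.integer(seed))),
    class = "sam_template")
  tpl$edges <- find_neighbors(tpl$cells, overlap_factor = overlap_factor)
  tpl <- assign_layers(tpl)
  if (!graph_is_connected(n, tpl$edges)) {
    stop("generated template is disconnected; increase cell_radius_factor or overlap_factor")
  }
  tpl
}

#' Identify neighbouring cells by sphere overlap
#'
#' Two cells are neighbours iff the distance between their centres is
#' strictly smaller than `overlap_factor` times the sum of their radii.
#' The relation is symmetric and irreflexive; pairs are returned once with
#' i < j.
#'
#' @param cells a `sam_template` or a data.frame with columns x, y, z,
#'   radius.
#' @param overlap_factor positive multiplier on the radius sum.
#' @return two-column integer matrix of neighbour pairs (columns i, j).
#' @export
find_neighbors <- function(cells, overlap_factor = 1) {
  if (inherits(cells, "sam_template")) cells <- cells$cells
  stopifnot(overlap_factor > 0, all(cells$radius > 0))
  n <- nrow(cells)
  D <- as.matrix(stats::dist(cbind(cells$x, cells$y, cells$z)))
  if (n > 1 && min(D[upper.tri(D)]) < 1e-12) {
    stop("two cell centers coincide")
  }
  thresh <- overlap_factor * outer(cells$radius, cells$radius, "+")
  hit <- which(upper.tri(D) & D < thresh, arr.ind = TRUE)
  edges <- cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Assign layer labels (L1, L2, CORPUS) from the shell structure
#'
#' The generator knows its concentric shells, so layer labels follow the
#' shell index directly: outermost shell is the epidermis (L1), the next
#' shell the sub-epidermis (L2), and all deeper shells the corpus.
#'
#' @param template a `sam_template` whose cells carry a `shell` column.
#' @return the template with a `layer` factor column (levels L1, L2,
#'   CORPUS) on its cells.
#' @export
assign_layers <- function(template) {
  stopifnot(inherits(template, "sam_template"))
  shell <- template$cells$shell
  if (length(unique(shell)) < 2L) {
    stop("layer assignment needs at least two geometric shells")
  }
  lab <- ifelse(shell == 0L, "L1", ifelse(shell == 1L, "L2", "CORPUS"))
  template$cells$layer <- factor(lab, levels = c("L1", "L2", "CORPUS"))
  template
}

#' @export
print.sam_template <- function(x, ...) {
  cat("SAM template:", nrow(x$cells), "cells,", nrow(x$edges), "neighbour pairs\n")
  cat("  shells:", length(unique(x$cells$shell)),
      " layers:", paste(sprintf("%s=%d", levels(x$cells$layer),
                                tabulate(x$cells$layer, 3L)), collapse = ", "), "\n")
  cat("  dome: radius of curvature", format(x$metadata$radius_of_curvature),
      "a.u., height", format(x$metadata$height), "a.u., seed",
      x$metadata$seed, "\n")
  invisible(x)
}

#' Write / read a template
#'
#' `write_template` serializes a template either as a pair of CSV files
#' (`<stem>_cells.csv`, `<stem>_edges.csv`) or, when `path` ends in
#' `.json`, as a single JSON bundle including the generation metadata.
#' `read_template` reverses either form.
#'
#' @param template a `sam_template`.
#' @param path output path: a `.json` file or a stem for the CSV pair.
#' @return `write_template` returns `path` invisibly; `read_template`
#'   returns a `sam_template`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "sam_template"))
  cells <- template$cells[, c("id", "x", "y", "z", "radius", "volume", "shell", "layer")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(cells = cells,
           edges = as.data.frame(template$edges),
           metadata = template$metadata),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(cells, paste0(path, "_cells.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(template$edges), paste0(path, "_edges.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  if (grepl("\\.json$", path)) {
    b <- jsonlite::read_json(path, simplifyVector = TRUE)
    cells <- as.data.frame(b$cells)
    edges <- as.matrix(b$edges)
    meta <- b$metadata
  } else {
    cells <- utils::read.csv(paste0(path, "_cells.csv"))
    edges <- as.matrix(utils::read.csv(paste0(path, "_edges.csv")))
    meta <- list()
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- list(NULL, c("i", "j"))
  cells$shell <- as.integer(cells$shell)
  cells$layer <- factor(cells$layer, levels = c("L1", "L2", "CORPUS"))
  structure(list(cells = cells, edges = edges, metadata = meta),
            class = "sam_template")
}
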