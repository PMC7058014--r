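# Internal helpers shared across the package.

SPECIES <- c("mir171", "ham_mrna", "ham_protein", "gfp_mrna", "gfp_protein")

PARAM_NAMES <- c("k_mirp", "k_mirn", "D_mir171",
                 "k_hrp", "k_hrnm", "k_hrnh",
                 "k_hpp", "k_hpn",
                 "k_grp", "k_grn", "k_gpp", "k_gpn")

# the six rate constants explored by both parameter searches
SEARCH_KEYS <- c("k_mirp", "k_mirn", "k_hrp", "k_hrnm", "k_hrnh", "D_mir171")

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Cheap deterministic fingerprint of an R object, used to pair simulation
# results with the template/parameters that produced them.
object_fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (R version stamps) so equal content
  # fingerprints equally across sessions
  bytes <- bytes[-seq_len(14)]
  w <- (seq_along(bytes) - 1L) %% 251L + 1L
  sprintf("%d-%d-%.0f-%.0f", length(bytes), sum(bytes),
          sum(as.numeric(bytes) * w), sum(as.numeric(bytes) * w * w))
}

# Breadth-first connectivity check on an undirected edge list (1-based ids).
graph_is_connected <- function(n, edges) {
  if (n <= 1L) return(TRUE)
  if (nrow(edges) == 0L) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
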