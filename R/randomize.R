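#' Degree-preserving rewiring of one layer
#'
#' Generates a randomized version of a layer by random pairwise edge swaps
#' that exactly preserve every node's in- and out-degree (the degree sequence
#' for undirected edges). Directed and undirected edges are rewired within
#' their own class against a shared occupancy set, so each edge keeps its
#' directedness and no self-loops or duplicate edges are ever created. The
#' swap budget is `Q` attempts per edge of each class; rejected attempts are
#' not retried, so swap-poor graphs (e.g. a star) pass through unchanged.
#' The signed-fill convention is re-applied to the rewired edge list.
#'
#' @param layer A `mux_layer`.
#' @param Q Attempted swaps per edge (default 10).
#' @param seed Integer seed; the same layer, `Q` and seed always give the
#'   identical result.
#' @return A rewired `mux_layer` with the same label, node space, edge count
#'   and degree sequences.
#' @export
rewire_layer <- function(layer, Q = 10, seed = 1L) {
  stopifnot(inherits(layer, "mux_layer"))
  if (Q <= 0) stop("Q must be positive", call. = FALSE)
  e <- layer$edges
  if (nrow(e) < 2L) return(layer)
  em <- cbind(e$from, e$to)
  new_e <- withr::with_seed(seed, {
    rewire_edgelist(em, e$directed, as.integer(Q), layer$n)
  })
  new_layer(layer$label, new_e[, 1], new_e[, 2], e$directed, layer$n)
}

#' Build a randomized null ensemble for every layer
#'
#' Randomizes each of the network's layers independently (breaking any
#' degree correlation between layers) `n_instances` times with
#' [rewire_layer()], using per-(layer, instance) child seeds derived
#' deterministically from `master_seed`. The stored instances are reused by
#' all downstream null computations via the deterministic allocation rule of
#' [allocate_instances()], so results are reproducible end to end.
#'
#' @param net A `mux_net`.
#' @param n_instances Randomized instances per layer.
#' @param Q Attempted swaps per edge (see [rewire_layer()]).
#' @param master_seed Integer master seed.
#' @return A `mux_ensemble`: list with `instances` (named list: layer label
#'   -> list of rewired layers), `n_instances`, `Q`, `master_seed`.
#' @export
build_ensemble <- function(net, n_instances = 100, Q = 10, master_seed = 42L) {
  stopifnot(inherits(net, "mux_net"), n_instances >= 1)
  labs <- names(net$layers)
  seeds <- withr::with_seed(master_seed, {
    matrix(sample.int(2147483646L, length(labs) * n_instances),
           nrow = length(labs), dimnames = list(labs, NULL))
  })
  instances <- lapply(labs, function(lb) {
    lapply(seq_len(n_instances), function(k) {
      rewire_layer(net$layers[[lb]], Q = Q, seed = seeds[lb, k])
    })
  })
  names(instances) <- labs
  structure(
    list(instances = instances, n_instances = n_instances, Q = Q,
         master_seed = master_seed),
    class = "mux_ensemble"
  )
}

#' @export
print.mux_ensemble <- function(x, ...) {
  cat("<mux_ensemble> ", length(x$instances), " layers x ", x$n_instances,
      " instances (Q = ", x$Q, ", master_seed = ", x$master_seed, ")\n",
      sep = "")
  invisible(x)
}

#' Deterministically allocate ensemble instance pairs to null draws
#'
#' Maps null draw `k` to a pair of instance indices `(i_k, j_k)` — e.g. a
#' signaling-layer instance and a regulatory-layer instance — using a stable
#' hash of the context key as an offset into the `n^2` grid of instance
#' pairings. Draws within one context are collision-free; different contexts
#' may overlap but are each internally duplicate-free, and the allocation is
#' identical across runs and platforms.
#'
#' @param ensemble A `mux_ensemble` (or any list with an `n_instances`
#'   element).
#' @param layer_pair Character vector naming the two layers being paired;
#'   part of the hashed context.
#' @param n_rand Number of draws; must not exceed `n_instances^2`.
#' @param context_key String identifying the computation (e.g. the subset
#'   id), hashed into the starting offset.
#' @return Tibble with columns `k`, `i`, `j` (1-based instance indices).
#' @export
allocate_instances <- function(ensemble, layer_pair, n_rand,
                               context_key = "") {
  n <- ensemble$n_instances
  if (n_rand > n^2) {
    stop("n_rand exceeds the ", n^2, " unique instance pairings", call. = FALSE)
  }
  h <- stable_hash(paste(c(layer_pair, context_key), collapse = "|"))
  t <- (h + seq_len(n_rand) - 1) %% (n^2)
  tibble::tibble(
    k = seq_len(n_rand),
    i = as.integer(t %% n) + 1L,
    j = as.integer(t %/% n) + 1L
  )
}
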