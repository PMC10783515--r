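# Multilink types ------------------------------------------------------------

#' Encode / decode a multilink type as a unique integer
#'
#' A multilink is the pair `(S, R)` of signaling and regulatory edge states on
#' one node pair: `S` in `[0, 11]` indexes the signaling interaction type
#' (0 = no signaling edge) and `R` in `{-1, 0, 1}` records the regulatory
#' edge and its direction relative to the signaling edge. The hash
#' `3 * S + R + 1` maps the 36 types injectively onto `[0, 35]`, which keeps
#' tallying over large sparse tensors cheap.
#'
#' @param S Integer in `[0, 11]`.
#' @param R Integer in `{-1, 0, 1}`.
#' @return `encode_multilink()` returns the integer code;
#'   `decode_multilink()` returns a list with elements `S` and `R`.
#' @export
encode_multilink <- function(S, R) {
  if (any(S < 0 | S > 11) || any(!R %in% c(-1L, 0L, 1L))) {
    stop("multilink type out of range: S must be in [0, 11], R in {-1, 0, 1}",
         call. = FALSE)
  }
  as.integer(3L * S + R + 1L)
}

#' @rdname encode_multilink
#' @param code Integer code in `[0, 35]`.
#' @export
decode_multilink <- function(code) {
  if (any(code < 0 | code > 35)) {
    stop("multilink code out of range [0, 35]", call. = FALSE)
  }
  list(S = as.integer(code %/% 3L), R = as.integer(code %% 3L - 1L))
}

# Scope objects ---------------------------------------------------------------

# A scope confines counting to a set of ordered matrix positions:
#   type "all":     every off-diagonal position;
#   type "between": positions (a, b) and (b, a) for a in set A, b in set B;
#   type "keys":    an explicit set of ordered pair keys (with transposes).
scope_all <- function() list(type = "all")

scope_between <- function(a_idx, b_idx, n) {
  a <- logical(n); a[a_idx] <- TRUE
  b <- logical(n); b[b_idx] <- TRUE
  list(type = "between", a = a, b = b,
       total_unordered = sum(a) * sum(b))
}

scope_keys <- function(pairs, n) {
  # pairs: two-column matrix/data frame of ordered (from, to) index pairs
  pairs <- as.matrix(pairs)
  keys <- pair_key(pairs[, 1], pairs[, 2], n)
  list(type = "keys", keys = unique(keys),
       total_unordered = length(unique(upair_key(pairs[, 1], pairs[, 2], n))))
}

scope_keep <- function(scope, from, to, n) {
  if (!length(from)) return(logical(0))
  switch(scope$type,
    all = rep(TRUE, length(from)),
    between = (scope$a[from] & scope$b[to]) | (scope$b[from] & scope$a[to]),
    keys = (pair_key(from, to, n) %in% scope$keys) |
           (pair_key(to, from, n) %in% scope$keys),
    stop("unknown scope type")
  )
}

scope_total_unordered <- function(scope, n) {
  switch(scope$type,
    all = n * (n - 1) / 2,
    scope$total_unordered
  )
}

as_scope <- function(restrict_pairs, n) {
  if (is.null(restrict_pairs)) scope_all() else scope_keys(restrict_pairs, n)
}

# Counting core ---------------------------------------------------------------

# Join a signaling layer's canonical edges with the regulatory matrix entries
# at both orientations of each edge. bf = B[from, to], bb = B[to, from].
layer_overlap <- function(layer, B) {
  e <- layer$edges
  if (!nrow(e)) {
    return(tibble::tibble(from = integer(), to = integer(),
                          directed = logical(), bf = numeric(), bb = numeric()))
  }
  tibble::tibble(
    from = e$from, to = e$to, directed = e$directed,
    bf = B[cbind(e$from, e$to)], bb = B[cbind(e$to, e$from)]
  )
}

# Tally (S, R) multilinks from an overlap table, applying the collapse and
# double-counting conventions:
#  * a directed signaling edge contributes one count, to (S, sign) for a
#    directed regulatory edge, to (S, 0) when no regulatory edge coincides,
#    and to both (S, 1) and (S, -1) when the regulatory fill is symmetric;
#  * an undirected signaling edge contributes one count to each of (S, 1)
#    and (S, -1) when any regulatory edge coincides (the two equivalent
#    representations), and a single count to (S, 0) otherwise.
count_from_overlap <- function(ov, keep = NULL) {
  if (!is.null(keep)) ov <- ov[keep, , drop = FALSE]
  d <- ov$directed; bf <- ov$bf; bb <- ov$bb
  plus  <- sum(d & bf > 0) + sum(!d & (bf != 0 | bb != 0))
  minus <- sum(d & bf < 0) + sum(d & bf > 0 & bb > 0) +
           sum(!d & (bf != 0 | bb != 0))
  zero  <- sum(bf == 0 & bb == 0)
  c(`-1` = minus, `0` = zero, `1` = plus)
}

#' Count multilinks of one signaling layer against the regulatory layer
#'
#' Counts the `(S, R)` multilink types whose signaling component lies on
#' `S_layer`, for `R` in `{-1, 0, 1}`, applying the equivalence collapse and
#' the double-count correction for undirected signaling edges (see
#' [encode_multilink()] for the type space). Counting may be confined to a
#' set of ordered matrix positions, which is how pathway-pair subsets are
#' profiled.
#'
#' @param S_layer A signaling layer of a `mux_net` (e.g.
#'   `net$layers$activation`).
#' @param R_layer The regulatory layer (or its signed sparse matrix).
#' @param s Integer layer index reported in the `S` column.
#' @param restrict_pairs Optional two-column matrix of ordered (from, to)
#'   node index pairs confining the count.
#' @return Tibble with columns `S`, `R`, `count`.
#' @export
count_multilinks <- function(S_layer, R_layer, s = NA_integer_,
                             restrict_pairs = NULL) {
  B <- if (inherits(R_layer, "mux_layer")) R_layer$matrix else R_layer
  if (S_layer$n != nrow(B) || nrow(B) != ncol(B)) {
    stop("layer shape mismatch", call. = FALSE)
  }
  scope <- as_scope(restrict_pairs, S_layer$n)
  ov <- layer_overlap(S_layer, B)
  keep <- scope_keep(scope, ov$from, ov$to, S_layer$n)
  cnt <- count_from_overlap(ov, keep)
  tibble::tibble(S = as.integer(s), R = c(-1L, 0L, 1L),
                 count = as.numeric(cnt[c("-1", "0", "1")]))
}

# Regulatory records vs collapsed-signaling occupancy. occ marks records
# whose node pair carries any KEGGPPI edge.
zero_overlap <- function(keggppi, grn_layer) {
  g <- grn_layer$edges
  K <- keggppi$matrix
  occ <- if (nrow(g)) {
    K[cbind(g$from, g$to)] != 0 | K[cbind(g$to, g$from)] != 0
  } else {
    logical(0)
  }
  list(g = tibble::tibble(from = g$from, to = g$to, occ = occ),
       k = keggppi$edges[, c("from", "to")])
}

count_zero_from_overlap <- function(zov, scope, n) {
  gkeep <- scope_keep(scope, zov$g$from, zov$g$to, n)
  c01 <- sum(gkeep & !zov$g$occ)
  k_in <- sum(scope_keep(scope, zov$k$from, zov$k$to, n))
  c00 <- scope_total_unordered(scope, n) - k_in - c01
  c(`0` = c00, `1` = c01)
}

#' Count zero-signaling multilinks
#'
#' Counts the `(0, R)` multilink types — node pairs carrying a regulatory
#' edge but no signaling edge on the collapsed `KEGGPPI` layer — so that
#' regulatory edges coinciding with any signaling edge are not multiply
#' counted across the interaction-specific layers. A lone regulatory edge is
#' direction-less relative to an absent signaling edge, so `(0, 1)` and
#' `(0, -1)` are indistinguishable and tallied once as the canonical
#' `(0, 1)`. The `(0, 0)` count (pairs with neither edge) is obtained
#' arithmetically from the index-space size and the occupied pairs, never by
#' enumerating the dense complement.
#'
#' @param keggppi The collapsed signaling layer (`net$layers$KEGGPPI`).
#' @param R_layer The regulatory layer (`net$layers$GRN`).
#' @inheritParams count_multilinks
#' @return Tibble with columns `S` (0), `R` (0 and 1) and `count`.
#' @export
count_zero_signaling <- function(keggppi, R_layer, restrict_pairs = NULL) {
  if (keggppi$n != R_layer$n) stop("layer shape mismatch", call. = FALSE)
  scope <- as_scope(restrict_pairs, keggppi$n)
  cnt <- count_zero_from_overlap(zero_overlap(keggppi, R_layer), scope, keggppi$n)
  tibble::tibble(S = 0L, R = c(0L, 1L),
                 count = as.numeric(cnt[c("0", "1")]))
}

# Ensemble statistics ----------------------------------------------------------

#' z-score and empirical p-value of a multilink count against a null sample
#'
#' `z = (c_a - mean(c_r)) / sd(c_r)`. The empirical p-value is the fraction
#' of null instances at least as extreme as the observed count, with the tail
#' selected by the sign of `z`: `p = #(c_r >= c_a) / N_rand` when `z > 0` and
#' `p = #(c_r <= c_a) / N_rand` when `z < 0`. When `z = 0` exactly, `p = 1`
#' and the count is never significant. When the null sample is degenerate
#' (`sd = 0`) the z-score is undefined — flagged via `sigma_zero`, with
#' `z = +/-Inf` carrying the sign of `c_a - mean(c_r)` (or `NA` when
#' `c_a` equals every null count, in which case `p = 1`). No floor at
#' `1/N_rand` is applied; a raw fraction of 0 is possible.
#'
#' @param c_a Observed (actual) count.
#' @param c_r Numeric vector of null-ensemble counts.
#' @param n_rand Number of null instances; must equal `length(c_r)`.
#' @return List with `z`, `p_emp`, `sigma_zero`, `null_mean`, `null_sd`.
#' @export
multilink_stats <- function(c_a, c_r, n_rand = length(c_r)) {
  if (n_rand < 1L) stop("n_rand must be >= 1", call. = FALSE)
  if (length(c_r) != n_rand) {
    stop("length(c_r) must equal n_rand", call. = FALSE)
  }
  m <- mean(c_r)
  s <- if (n_rand > 1L) stats::sd(c_r) else 0
  sigma_zero <- !is.finite(s) || s == 0
  z <- if (!sigma_zero) {
    (c_a - m) / s
  } else if (c_a == m) {
    NA_real_
  } else {
    sign(c_a - m) * Inf
  }
  p <- if (is.na(z) || z == 0) {
    1
  } else if (z > 0) {
    sum(c_r >= c_a) / n_rand
  } else {
    sum(c_r <= c_a) / n_rand
  }
  list(z = z, p_emp = p, sigma_zero = sigma_zero,
       null_mean = m, null_sd = if (is.finite(s)) s else 0)
}

# Profile engine ---------------------------------------------------------------

ov_cached <- function(cache, key, builder) {
  if (is.null(cache)) return(builder())
  if (is.null(cache[[key]])) cache[[key]] <- builder()
  cache[[key]]
}

# Core routine shared by profile_subset() and the crosstalk driver. Computes
# actual and null counts for the 35 canonical multilink tallies (11 signaling
# layers x 3 R states, plus (0,0) and (0,1)) on one scope, then per-type
# z / p statistics. `null_scopes`, when given, supplies a per-draw scope
# (index by null draw k) — used by the shortest-path method, whose candidate
# positions are re-derived on each randomized instance.
compute_profile <- function(net, ensemble, scope = scope_all(),
                            subset_id = "whole-network", n_rand = 100,
                            alpha = 0.05, null_scopes = NULL, cache = NULL) {
  labels <- layer_labels()
  n <- net$n
  B0 <- net$layers$GRN$matrix

  actual <- numeric(0); Svec <- integer(0); Rvec <- integer(0)
  for (s in 1:11) {
    ov <- layer_overlap(net$layers[[labels[s]]], B0)
    cnt <- count_from_overlap(ov, scope_keep(scope, ov$from, ov$to, n))
    actual <- c(actual, cnt[c("-1", "0", "1")])
    Svec <- c(Svec, rep(s, 3L)); Rvec <- c(Rvec, c(-1L, 0L, 1L))
  }
  z0 <- count_zero_from_overlap(zero_overlap(net$layers$KEGGPPI, net$layers$GRN),
                                scope, n)
  actual <- c(actual, z0[c("0", "1")])
  Svec <- c(Svec, 0L, 0L); Rvec <- c(Rvec, 0L, 1L)
  n_types <- length(actual)

  alloc <- allocate_instances(ensemble, c("signaling", "GRN"), n_rand,
                              context_key = subset_id)
  nulls <- matrix(0, nrow = n_types, ncol = n_rand)
  for (k in seq_len(n_rand)) {
    i <- alloc$i[k]; j <- alloc$j[k]
    sc <- if (is.null(null_scopes)) scope else null_scopes[[k]]
    Bj <- ensemble$instances$GRN[[j]]$matrix
    row <- 1L
    for (s in 1:11) {
      ov <- ov_cached(cache, paste0(labels[s], ":", i, ":", j), function() {
        layer_overlap(ensemble$instances[[labels[s]]][[i]], Bj)
      })
      cnt <- count_from_overlap(ov, scope_keep(sc, ov$from, ov$to, n))
      nulls[row:(row + 2L), k] <- cnt[c("-1", "0", "1")]
      row <- row + 3L
    }
    zov <- ov_cached(cache, paste0("zero:", i, ":", j), function() {
      zero_overlap(ensemble$instances$KEGGPPI[[i]], ensemble$instances$GRN[[j]])
    })
    cz <- count_zero_from_overlap(zov, sc, n)
    nulls[row:(row + 1L), k] <- cz[c("0", "1")]
  }

  stats_list <- lapply(seq_len(n_types), function(t) {
    multilink_stats(actual[t], nulls[t, ], n_rand)
  })
  out <- tibble::tibble(
    subset_id = subset_id,
    layer = c(rep(labels, each = 3L), "KEGGPPI", "KEGGPPI"),
    S = Svec, R = Rvec,
    count = as.numeric(actual),
    null_mean = vapply(stats_list, `[[`, 0, "null_mean"),
    null_sd = vapply(stats_list, `[[`, 0, "null_sd"),
    z = vapply(stats_list, `[[`, 0, "z"),
    p_emp = vapply(stats_list, `[[`, 0, "p_emp"),
    sigma_zero = vapply(stats_list, `[[`, TRUE, "sigma_zero")
  )
  out$significant <- out$R != 0L & !is.na(out$z) & out$z > 0 &
    out$p_emp <= alpha
  class(out) <- c("mux_profile", class(out))
  attr(out, "n_rand") <- n_rand
  attr(out, "alpha") <- alpha
  out
}

#' Multilink profile of an edge subset
#'
#' Computes actual and null multilink counts, z-scores and empirical
#' p-values for every canonical multilink type over a subset of the
#' multilayer network's matrix positions: the whole network by default, or a
#' restricted position set (as used for pathway pairs). Null counts are
#' drawn deterministically from the precomputed randomized ensemble, one
#' coherent randomized multilayer per draw.
#'
#' @param net A `mux_net` from [build_multilayer()] or [gen_multilayer()].
#' @param ensemble A `mux_ensemble` from [build_ensemble()].
#' @param restrict_pairs Optional two-column matrix of ordered node-index
#'   pairs confining the profile.
#' @param subset_id Label for the subset; also seeds the deterministic
#'   allocation of ensemble instances.
#' @param n_rand Number of null draws (default 100).
#' @param alpha Significance level for flagging over-represented types.
#' @return A `mux_profile` tibble with one row per canonical multilink tally:
#'   `subset_id`, `layer`, `S`, `R`, `count`, `null_mean`, `null_sd`, `z`,
#'   `p_emp`, `sigma_zero`, `significant`.
#' @export
profile_subset <- function(net, ensemble, restrict_pairs = NULL,
                           subset_id = "whole-network", n_rand = 100,
                           alpha = 0.05) {
  compute_profile(net, ensemble, scope = as_scope(restrict_pairs, net$n),
                  subset_id = subset_id, n_rand = n_rand, alpha = alpha)
}

#' Export a multilink profile as TSV
#'
#' @param profile A `mux_profile`.
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}
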