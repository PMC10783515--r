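# Pair subsets ---------------------------------------------------------------

#' Mutually exclusive and common genes of a pathway pair
#'
#' @param pathway_a,pathway_b Pathway ids present in `membership`.
#' @param membership Named list mapping pathway id to gene ids.
#' @return List with `exA` (genes only in A), `exB` (genes only in B) and
#'   `common` (shared genes).
#' @export
exclusive_nodes <- function(pathway_a, pathway_b, membership) {
  if (!pathway_a %in% names(membership)) {
    stop("unknown pathway id '", pathway_a, "'", call. = FALSE)
  }
  if (!pathway_b %in% names(membership)) {
    stop("unknown pathway id '", pathway_b, "'", call. = FALSE)
  }
  a <- membership[[pathway_a]]
  b <- membership[[pathway_b]]
  list(exA = setdiff(a, b), exB = setdiff(b, a), common = intersect(a, b))
}

#' Candidate positions for direct between-pathway crosstalk
#'
#' All ordered matrix positions `(a, b)` with `a` exclusive to pathway A and
#' `b` exclusive to pathway B, plus their transposes, so both orientations of
#' direct edges are visible to the signed counting. Within-pathway positions
#' and positions touching genes common to both pathways are excluded by
#' construction.
#'
#' @param net A `mux_net`.
#' @param exA,exB Character vectors of mutually exclusive gene ids.
#' @return Two-column integer matrix of ordered (from, to) node indices;
#'   zero rows when either exclusive set is empty.
#' @export
between_positions <- function(net, exA, exB) {
  ia <- match(intersect(exA, net$genes), net$genes)
  ib <- match(intersect(exB, net$genes), net$genes)
  if (!length(ia) || !length(ib)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  g <- expand.grid(from = ia, to = ib)
  m <- rbind(as.matrix(g), as.matrix(g)[, 2:1, drop = FALSE])
  colnames(m) <- c("from", "to")
  m
}

# Directed igraph view of a layer (undirected edges become arc pairs).
graph_from_layer <- function(layer) {
  e <- layer$edges
  und <- !e$directed
  el <- rbind(cbind(e$from, e$to), cbind(e$to[und], e$from[und]))
  g <- igraph::make_empty_graph(n = layer$n, directed = TRUE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  g
}

# Shortest-path candidate positions on a given collapsed signaling layer.
# Paths are searched on a restricted view of the graph in which only
# intermediary candidates (nodes outside both pathways) can appear as
# internal nodes: source-side exclusive vertices cannot be entered and
# target-side exclusive vertices cannot be left, so every returned path is
# an intermediary shortest path by construction. Returns the ordered
# position matrix (path edges plus transposes) and the intermediary nodes.
shortest_scope_on_layer <- function(layer, ia, ib, ab_idx, sp_threshold,
                                    graph = NULL) {
  empty <- list(positions = matrix(integer(0), ncol = 2L),
                intermediaries = integer(0))
  if (!length(ia) || !length(ib)) return(empty)
  g <- graph %||% graph_from_layer(layer)
  keep_v <- sort(unique(c(setdiff(seq_len(layer$n), ab_idx), ia, ib)))
  h <- igraph::induced_subgraph(g, keep_v)
  inv <- integer(layer$n); inv[keep_v] <- seq_along(keep_v)
  ia2 <- inv[ia]; ib2 <- inv[ib]
  el <- igraph::as_edgelist(h, names = FALSE)
  if (nrow(el)) {
    h <- igraph::delete_edges(h, which(el[, 2] %in% ia2 | el[, 1] %in% ib2))
  }
  pos <- list(); inter <- integer(0)
  for (a in ia2) {
    vp <- suppressWarnings(
      igraph::shortest_paths(h, from = a, to = ib2, mode = "out",
                             output = "vpath")$vpath
    )
    for (p in vp) {
      v <- as.integer(p)
      if (length(v) < 2L) next
      internal <- v[-c(1L, length(v))]
      if (!is.null(sp_threshold) && length(internal) > sp_threshold) next
      vo <- keep_v[v]
      pos[[length(pos) + 1L]] <- cbind(vo[-length(vo)], vo[-1L])
      inter <- c(inter, keep_v[internal])
    }
  }
  if (!length(pos)) return(empty)
  m <- unique(do.call(rbind, pos))
  m <- unique(rbind(m, m[, 2:1, drop = FALSE]))
  colnames(m) <- c("from", "to")
  list(positions = m, intermediaries = sort(unique(inter)))
}

#' Candidate positions for shortest-path-mediated crosstalk
#'
#' Computes shortest directed paths on the collapsed `KEGGPPI` layer from
#' each gene exclusive to pathway A to each gene exclusive to pathway B,
#' discards any path with an internal node belonging to either pathway
#' (keeping only "intermediary" nodes), optionally caps the number of
#' intermediary nodes per path (`sp_threshold = 1` keeps only `a -> x -> b`
#' paths; `NULL` places no cap), and aggregates the edges of all retained
#' paths (with transposes) into one candidate position set.
#'
#' @inheritParams between_positions
#' @param nodes_a,nodes_b Full gene sets of pathways A and B (used to define
#'   intermediary nodes).
#' @param sp_threshold Maximum intermediary nodes per path, or `NULL` for no
#'   threshold.
#' @return List with `positions` (ordered index pair matrix) and
#'   `intermediaries` (character vector of gene ids).
#' @export
shortest_positions <- function(net, exA, exB, nodes_a, nodes_b,
                               sp_threshold = NULL) {
  ia <- match(intersect(exA, net$genes), net$genes)
  ib <- match(intersect(exB, net$genes), net$genes)
  ab_idx <- match(intersect(union(nodes_a, nodes_b), net$genes), net$genes)
  res <- shortest_scope_on_layer(net$layers$KEGGPPI, ia, ib, ab_idx,
                                 sp_threshold)
  res$intermediaries <- net$genes[res$intermediaries]
  res
}

# Scoring ----------------------------------------------------------------------

#' Composite crosstalk score
#'
#' `score = 1000 * n_sig - log10(p_best + 0.001) * z_best`, encoding the
#' three-key ranking (most significant multilink types first, then lowest
#' empirical p-value, then highest z-score) in a single number. When the
#' best type's null standard deviation is zero the z-score is undefined and
#' the z factor is dropped: `score = 1000 * n_sig - log10(p_best + 0.001)`.
#'
#' @param n_sig Number of significantly over-represented multilink types.
#' @param p_best Best (lowest) empirical p-value over `(S, +/-1)` types.
#' @param z_best Best (highest finite) z-score over `(S, +/-1)` types.
#' @param sigma_zero Whether the best type's null standard deviation is zero.
#' @return Numeric score.
#' @export
crosstalk_score <- function(n_sig, p_best, z_best, sigma_zero = FALSE) {
  if (sigma_zero) {
    1000 * n_sig - log10(p_best + 0.001)
  } else {
    1000 * n_sig - log10(p_best + 0.001) * z_best
  }
}

# Reduce a profile to the pair-level assessment. exclude_S supports the
# leave-one-layer-out analysis; include_zero toggles pure-regulatory (0, 1)
# multilinks as crosstalk proxies.
summarize_assessment <- function(prof, alpha = 0.05, include_zero = TRUE,
                                 exclude_S = integer(0)) {
  cand <- prof$R != 0L & !(prof$S %in% exclude_S)
  if (!include_zero) cand <- cand & prof$S != 0L
  n_sig <- sum(cand & prof$significant)
  cc <- which(cand & prof$count > 0)
  if (!length(cc)) {
    return(list(detected = FALSE, n_sig = 0L, p_best = NA_real_,
                z_best = NA_real_, sigma_zero = NA, score = NA_real_,
                sig_types = prof[integer(0), c("S", "R")]))
  }
  p_best <- min(prof$p_emp[cc])
  zv <- prof$z[cc]
  z_best <- if (any(is.finite(zv))) max(zv[is.finite(zv)]) else NA_real_
  zkey <- zv
  zkey[!is.finite(zkey) | is.na(zkey)] <- -Inf
  best <- cc[order(prof$p_emp[cc], -zkey)][1L]
  sigma_zero <- prof$null_sd[best] == 0
  list(
    detected = TRUE, n_sig = as.integer(n_sig), p_best = p_best,
    z_best = z_best, sigma_zero = sigma_zero,
    score = crosstalk_score(n_sig, p_best, z_best, sigma_zero),
    sig_types = prof[cand & prof$significant, c("S", "R")]
  )
}

# Concrete edge positions realizing each significant multilink type.
mediators_for <- function(net, scope, sig_types) {
  if (!nrow(sig_types)) {
    return(tibble::tibble(source = character(), target = character(),
                          S = integer(), R = integer()))
  }
  labels <- layer_labels()
  B0 <- net$layers$GRN$matrix
  out <- list()
  for (r in seq_len(nrow(sig_types))) {
    s <- sig_types$S[r]; rr <- sig_types$R[r]
    if (s == 0L) {
      zov <- zero_overlap(net$layers$KEGGPPI, net$layers$GRN)
      keep <- scope_keep(scope, zov$g$from, zov$g$to, net$n) & !zov$g$occ
      sel <- zov$g[keep, , drop = FALSE]
      out[[r]] <- tibble::tibble(source = net$genes[sel$from],
                                 target = net$genes[sel$to], S = 0L, R = rr)
    } else {
      ov <- layer_overlap(net$layers[[labels[s]]], B0)
      keep <- scope_keep(scope, ov$from, ov$to, net$n)
      hit <- if (rr == 1L) {
        (ov$directed & ov$bf > 0) | (!ov$directed & (ov$bf != 0 | ov$bb != 0))
      } else {
        (ov$directed & (ov$bf < 0 | (ov$bf > 0 & ov$bb > 0))) |
          (!ov$directed & (ov$bf != 0 | ov$bb != 0))
      }
      sel <- ov[keep & hit, , drop = FALSE]
      out[[r]] <- tibble::tibble(source = net$genes[sel$from],
                                 target = net$genes[sel$to], S = s, R = rr)
    }
  }
  dplyr::bind_rows(out)
}

# Inference driver --------------------------------------------------------------

#' Infer crosstalk for ordered pathway pairs
#'
#' For every ordered pathway pair, derives the candidate edge positions
#' (direct between-pathway positions, or edges on intermediary shortest
#' paths), profiles all multilink types on those positions against the
#' randomized ensemble, and summarizes each pair by its number of
#' significantly over-represented `(S, +/-1)` multilink types
#' (`p_emp <= alpha`, `z > 0`), best p-value, best z-score and composite
#' score (see [crosstalk_score()]). Pairs with no `(S, +/-1)` multilink on
#' their candidate positions are reported as undetected. For the shortest
#' method, candidate positions are re-derived on each randomized collapsed
#' layer instance, so the null experiences the same operations as the data.
#'
#' @param net A `mux_net`.
#' @param ensemble A `mux_ensemble` built from `net`.
#' @param method `"between"` (direct edges) or `"shortest"` (intermediary
#'   shortest paths).
#' @param sp_threshold Maximum intermediary nodes per path (shortest method
#'   only); `NULL` for no threshold.
#' @param pairs Tibble with columns `pathway_a`, `pathway_b`; default all
#'   ordered pairs of `net$membership`.
#' @param n_rand Null draws per pair (default 100).
#' @param alpha Significance level (default 0.05).
#' @param include_zero Count pure-regulatory `(0, 1)` multilinks as crosstalk
#'   proxies (default `TRUE`).
#' @return A ranked `mux_crosstalk` tibble: one row per ordered pair with
#'   columns `pathway_a`, `pathway_b`, `method`, `sp`, `detected`, `n_sig`,
#'   `p_best`, `z_best`, `sigma_zero`, `score`, `rank`, plus list columns
#'   `sig_types`, `mediators` and `profile`.
#' @export
infer_crosstalk <- function(net, ensemble, method = c("between", "shortest"),
                            sp_threshold = NULL, pairs = NULL, n_rand = 100,
                            alpha = 0.05, include_zero = TRUE) {
  method <- match.arg(method)
  if (is.null(pairs)) {
    ids <- names(net$membership)
    pairs <- tidyr::expand_grid(pathway_a = ids, pathway_b = ids)
    pairs <- dplyr::filter(pairs, .data$pathway_a != .data$pathway_b)
  }
  cache <- new.env(parent = emptyenv())
  # shortest-method caches, keyed by ensemble instance index
  inst_graphs <- new.env(parent = emptyenv())

  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pa <- pairs$pathway_a[r]; pb <- pairs$pathway_b[r]
    ex <- exclusive_nodes(pa, pb, net$membership)
    subset_id <- paste0(method, ":", pa, "->", pb)
    ia <- match(intersect(ex$exA, net$genes), net$genes)
    ib <- match(intersect(ex$exB, net$genes), net$genes)

    undetected <- tibble::tibble(
      pathway_a = pa, pathway_b = pb, method = method,
      sp = if (is.null(sp_threshold)) NA_integer_ else as.integer(sp_threshold),
      detected = FALSE, n_sig = 0L, p_best = NA_real_, z_best = NA_real_,
      sigma_zero = NA, score = NA_real_,
      sig_types = list(tibble::tibble(S = integer(), R = integer())),
      mediators = list(tibble::tibble(source = character(),
                                      target = character(),
                                      S = integer(), R = integer())),
      profile = list(NULL)
    )
    if (!length(ia) || !length(ib)) { rows[[r]] <- undetected; next }

    null_scopes <- NULL
    if (method == "between") {
      scope <- scope_between(ia, ib, net$n)
    } else {
      ab_idx <- match(
        intersect(union(net$membership[[pa]], net$membership[[pb]]), net$genes),
        net$genes
      )
      sres <- shortest_scope_on_layer(net$layers$KEGGPPI, ia, ib, ab_idx,
                                      sp_threshold)
      if (!nrow(sres$positions)) { rows[[r]] <- undetected; next }
      scope <- scope_keys(sres$positions, net$n)
      alloc <- allocate_instances(ensemble, c("signaling", "GRN"), n_rand,
                                  context_key = subset_id)
      inst_scopes <- list()
      null_scopes <- lapply(seq_len(n_rand), function(k) {
        i <- alloc$i[k]
        key <- as.character(i)
        if (is.null(inst_scopes[[key]])) {
          gkey <- paste0("g", i)
          if (is.null(inst_graphs[[gkey]])) {
            inst_graphs[[gkey]] <-
              graph_from_layer(ensemble$instances$KEGGPPI[[i]])
          }
          sk <- shortest_scope_on_layer(
            ensemble$instances$KEGGPPI[[i]], ia, ib, ab_idx, sp_threshold,
            graph = inst_graphs[[gkey]]
          )
          inst_scopes[[key]] <<- if (nrow(sk$positions)) {
            scope_keys(sk$positions, net$n)
          } else {
            scope_keys(matrix(integer(0), ncol = 2L), net$n)
          }
        }
        inst_scopes[[key]]
      })
    }

    prof <- compute_profile(net, ensemble, scope = scope,
                            subset_id = subset_id, n_rand = n_rand,
                            alpha = alpha, null_scopes = null_scopes,
                            cache = cache)
    s <- summarize_assessment(prof, alpha = alpha, include_zero = include_zero)
    rows[[r]] <- tibble::tibble(
      pathway_a = pa, pathway_b = pb, method = method,
      sp = if (is.null(sp_threshold)) NA_integer_ else as.integer(sp_threshold),
      detected = s$detected, n_sig = s$n_sig, p_best = s$p_best,
      z_best = s$z_best, sigma_zero = s$sigma_zero, score = s$score,
      sig_types = list(s$sig_types),
      mediators = list(mediators_for(net, scope, s$sig_types)),
      profile = list(prof)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mux_crosstalk", class(out))
  rank_pairs(out)
}

#' Rank assessed pathway pairs
#'
#' Detected pairs are sorted by score descending (the score encodes the
#' number-of-significant-types / best-p / best-z priority order), with exact
#' ties broken lexicographically by `(pathway_a, pathway_b)` for
#' determinism. Undetected pairs follow, unranked (`rank = NA`).
#'
#' @param results A `mux_crosstalk` tibble.
#' @return The same tibble, sorted, with a `rank` column.
#' @export
rank_pairs <- function(results) {
  if (!nrow(results)) stop("no results to rank", call. = FALSE)
  det <- dplyr::arrange(
    dplyr::filter(results, .data$detected),
    dplyr::desc(.data$score), .data$pathway_a, .data$pathway_b
  )
  und <- dplyr::arrange(
    dplyr::filter(results, !.data$detected),
    .data$pathway_a, .data$pathway_b
  )
  det$rank <- seq_len(nrow(det))
  und$rank <- rep(NA_integer_, nrow(und))
  out <- dplyr::bind_rows(det, und)
  class(out) <- unique(c("mux_crosstalk", class(out)))
  out
}

#' Re-rank pairs ignoring one signaling layer
#'
#' Leave-one-layer-out sensitivity analysis: recomputes each pair's number of
#' significant types, best statistics and score while ignoring multilink
#' types whose signaling component equals the left-out layer, then re-ranks.
#' The PPI layer cannot be left out: its edges are folded into every
#' interaction-specific layer and carry the connectivity the shortest-path
#' method relies on.
#'
#' @param results A `mux_crosstalk` tibble carrying per-pair profiles.
#' @param left_out_layer Layer label (e.g. `"inhibition"`) or signaling index
#'   in `[1, 11]`, not the PPI layer.
#' @param alpha,include_zero As in [infer_crosstalk()].
#' @return A re-ranked `mux_crosstalk` tibble.
#' @export
leave_one_layer_out <- function(results, left_out_layer, alpha = 0.05,
                                include_zero = TRUE) {
  labels <- layer_labels()
  s_out <- if (is.character(left_out_layer)) {
    match(left_out_layer, labels)
  } else {
    as.integer(left_out_layer)
  }
  if (is.na(s_out) || s_out < 1L || s_out > 11L) {
    stop("left_out_layer must be one of the 11 signaling layers", call. = FALSE)
  }
  if (labels[s_out] == "ppi") {
    stop("the PPI layer cannot be left out: it connects the signaling ",
         "pathways and underlies every interaction-specific layer",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(results)), function(r) {
    row <- results[r, ]
    prof <- row$profile[[1]]
    if (is.null(prof)) return(row)
    s <- summarize_assessment(prof, alpha = alpha,
                              include_zero = include_zero,
                              exclude_S = s_out)
    # a pair whose only evidence sat on the left-out layer drops out of the
    # deterministic ranking
    if (s$detected && s$n_sig == 0L &&
        nrow(dplyr::filter(row$sig_types[[1]], .data$S != s_out)) == 0L &&
        nrow(row$sig_types[[1]]) > 0L) {
      s$detected <- any(prof$count[prof$R != 0L & prof$S != s_out] > 0)
    }
    row$detected <- s$detected
    row$n_sig <- s$n_sig
    row$p_best <- s$p_best
    row$z_best <- s$z_best
    row$sigma_zero <- s$sigma_zero
    row$score <- s$score
    row$sig_types <- list(s$sig_types)
    row
  })
  rank_pairs(dplyr::bind_rows(rows))
}

#' @export
print.mux_crosstalk <- function(x, ...) {
  cat("<mux_crosstalk> ", nrow(x), " ordered pathway pairs (",
      sum(x$detected), " detected), method = ", x$method[1], "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a crosstalk result table
#'
#' @param x A `mux_crosstalk`.
#' @param ... Unused.
#' @return Tibble without the list columns, one row per ordered pair.
#' @export
tidy.mux_crosstalk <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$sig_types <- vapply(x$sig_types, function(t) {
    paste(sprintf("(%d,%d)", t$S, t$R), collapse = ";")
  }, character(1))
  out[, setdiff(names(out), c("mediators", "profile"))]
}

#' @rdname tidy.mux_crosstalk
#' @return `glance()` returns a one-row summary: pairs assessed, detected,
#'   significant, and the top-ranked pair.
#' @export
glance.mux_crosstalk <- function(x, ...) {
  top <- dplyr::filter(x, !is.na(.data$rank) & .data$rank == 1L)
  tibble::tibble(
    n_pairs = nrow(x),
    n_detected = sum(x$detected),
    n_crosstalking = sum(x$n_sig > 0),
    top_pair = if (nrow(top)) {
      paste0(top$pathway_a[1], "->", top$pathway_b[1])
    } else {
      NA_character_
    }
  )
}

#' Export crosstalk results and mediator edges as TSV
#'
#' @param results A `mux_crosstalk`.
#' @param path Output TSV path for the per-pair table.
#' @param mediators_path Optional TSV path for the mediator edge list
#'   (columns `source`, `target`, `S`, `R`, `pair`), suitable for network
#'   tools such as Cytoscape.
#' @export
write_crosstalk_tsv <- function(results, path, mediators_path = NULL) {
  readr::write_tsv(tidy(results), path)
  if (!is.null(mediators_path)) {
    med <- dplyr::bind_rows(lapply(seq_len(nrow(results)), function(r) {
      m <- results$mediators[[r]]
      if (!nrow(m)) return(NULL)
      m$pair <- paste0(results$pathway_a[r], "->", results$pathway_b[r])
      m
    }))
    if (is.null(med) || !nrow(med)) {
      med <- tibble::tibble(source = character(), target = character(),
                            S = integer(), R = integer(), pair = character())
    }
    readr::write_tsv(med, mediators_path)
  }
  invisible(path)
}
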