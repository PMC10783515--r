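# Baseline crosstalk rankings used in the benchmark.

# Expand an unordered-pair table to both orderings (overlap tests are
# symmetric, so the same value serves both directions and all methods rank
# the same ordered-pair universe).
expand_ordered <- function(unordered) {
  swapped <- unordered
  swapped$pathway_a <- unordered$pathway_b
  swapped$pathway_b <- unordered$pathway_a
  dplyr::bind_rows(unordered, swapped)
}

rank_by <- function(tbl, ...) {
  det <- dplyr::arrange(dplyr::filter(tbl, .data$detected), ...)
  und <- dplyr::arrange(dplyr::filter(tbl, !.data$detected),
                        .data$pathway_a, .data$pathway_b)
  det$rank <- seq_len(nrow(det))
  und$rank <- rep(NA_integer_, nrow(und))
  dplyr::bind_rows(det, und)
}

#' Rank pathway pairs by gene-set overlap
#'
#' Two-tailed Fisher exact test on the 2x2 table (shared genes, A-only,
#' B-only, neither) over the gene universe, Benjamini-Hochberg adjusted
#' across all pairs and ranked by ascending FDR. Pairs with zero overlap are
#' flagged undetected.
#'
#' @param membership Named list mapping pathway id to gene ids.
#' @param universe_genes Gene universe; defaults to the union of all pathway
#'   gene sets.
#' @return Tibble with one row per ordered pair: `pathway_a`, `pathway_b`,
#'   `overlap`, `p`, `fdr`, `detected`, `rank`.
#' @export
node_overlap_rank <- function(membership, universe_genes = NULL) {
  universe <- unique(universe_genes %||% unlist(membership, use.names = FALSE))
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  ids <- names(membership)
  un <- t(utils::combn(ids, 2L))
  u <- length(universe)
  res <- lapply(seq_len(nrow(un)), function(r) {
    a <- intersect(membership[[un[r, 1]]], universe)
    b <- intersect(membership[[un[r, 2]]], universe)
    k <- length(intersect(a, b))
    p <- stats::fisher.test(matrix(
      c(k, length(a) - k, length(b) - k, u - length(a) - length(b) + k), 2L
    ))$p.value
    tibble::tibble(pathway_a = un[r, 1], pathway_b = un[r, 2],
                   overlap = k, p = p)
  })
  tbl <- dplyr::bind_rows(res)
  tbl$fdr <- stats::p.adjust(tbl$p, method = "BH")
  tbl$detected <- tbl$overlap > 0L
  rank_by(expand_ordered(tbl), .data$fdr, .data$p,
          .data$pathway_a, .data$pathway_b)
}

#' Rank pathway pairs by edge overlap
#'
#' As [node_overlap_rank()], with edges as the overlapping items. Each
#' pathway's edge set comes from the signaling multigraph (unique ordered
#' positions; undirected records occupy both orientations), and the universe
#' is the `N * (N - 1)` ordered positions over the union gene set
#' (`ordered = FALSE` halves this to unordered pairs).
#'
#' @param multigraph A `signaling_multigraph` with pathway-annotated edges.
#' @param ordered Count positions as ordered pairs (default) or unordered.
#' @return Tibble as in [node_overlap_rank()].
#' @export
edge_overlap_rank <- function(multigraph, ordered = TRUE) {
  stopifnot(inherits(multigraph, "signaling_multigraph"))
  e <- dplyr::filter(multigraph$edges, !is.na(.data$pathway))
  genes <- sort(unique(c(e$source, e$target)))
  n <- length(genes)
  m_universe <- if (ordered) n * (n - 1) else n * (n - 1) / 2
  edge_ids <- function(rows) {
    if (ordered) {
      und <- !rows$directed
      unique(c(paste(rows$source, rows$target),
               paste(rows$target[und], rows$source[und])))
    } else {
      unique(paste(pmin(rows$source, rows$target),
                   pmax(rows$source, rows$target)))
    }
  }
  sets <- lapply(split(e, e$pathway), edge_ids)
  ids <- names(sets)
  un <- t(utils::combn(ids, 2L))
  res <- lapply(seq_len(nrow(un)), function(r) {
    a <- sets[[un[r, 1]]]; b <- sets[[un[r, 2]]]
    k <- length(intersect(a, b))
    p <- stats::fisher.test(matrix(
      c(k, length(a) - k, length(b) - k,
        m_universe - length(a) - length(b) + k), 2L
    ))$p.value
    tibble::tibble(pathway_a = un[r, 1], pathway_b = un[r, 2],
                   overlap = k, p = p)
  })
  tbl <- dplyr::bind_rows(res)
  tbl$fdr <- stats::p.adjust(tbl$p, method = "BH")
  tbl$detected <- tbl$overlap > 0L
  rank_by(expand_ordered(tbl), .data$fdr, .data$p,
          .data$pathway_a, .data$pathway_b)
}

#' Rank pathway pairs by direct inter-pathway edge counts
#'
#' Counts the edges of the collapsed signaling layer between the mutually
#' exclusive gene sets of each pair and compares the count to the same
#' quantity on degree-preserving randomized instances of that layer
#' (z-score and empirical p-value as in [multilink_stats()]). Pairs are
#' ranked by ascending p, then descending z.
#'
#' @param net A `mux_net`.
#' @param ensemble A `mux_ensemble` built from `net`.
#' @param n_rand Null draws per pair.
#' @return Tibble with one row per ordered pair: `pathway_a`, `pathway_b`,
#'   `n_direct`, `z`, `p_emp`, `detected`, `rank`.
#' @export
direct_edge_rank <- function(net, ensemble, n_rand = 100) {
  ids <- names(net$membership)
  un <- t(utils::combn(ids, 2L))
  count_between <- function(layer, scope) {
    e <- layer$edges
    sum(scope_keep(scope, e$from, e$to, net$n))
  }
  res <- lapply(seq_len(nrow(un)), function(r) {
    ex <- exclusive_nodes(un[r, 1], un[r, 2], net$membership)
    ia <- match(intersect(ex$exA, net$genes), net$genes)
    ib <- match(intersect(ex$exB, net$genes), net$genes)
    if (!length(ia) || !length(ib)) {
      return(tibble::tibble(pathway_a = un[r, 1], pathway_b = un[r, 2],
                            n_direct = NA_integer_, z = NA_real_,
                            p_emp = NA_real_, detected = FALSE))
    }
    scope <- scope_between(ia, ib, net$n)
    c_a <- count_between(net$layers$KEGGPPI, scope)
    alloc <- allocate_instances(ensemble, c("KEGGPPI", "KEGGPPI"), n_rand,
                                paste0("direct:", un[r, 1], "->", un[r, 2]))
    c_r <- vapply(alloc$i, function(i) {
      count_between(ensemble$instances$KEGGPPI[[i]], scope)
    }, numeric(1))
    st <- multilink_stats(c_a, c_r, n_rand)
    detected <- c_a > 0
    tibble::tibble(pathway_a = un[r, 1], pathway_b = un[r, 2],
                   n_direct = as.integer(c_a),
                   z = st$z, p_emp = st$p_emp, detected = detected)
  })
  tbl <- expand_ordered(dplyr::bind_rows(res))
  zkey <- tbl$z
  zkey[is.na(zkey)] <- -Inf
  tbl$.zkey <- -zkey
  out <- rank_by(tbl, .data$p_emp, .data$.zkey,
                 .data$pathway_a, .data$pathway_b)
  out$.zkey <- NULL
  out
}

#' K shortest loopless paths between two nodes
#'
#' Yen's algorithm (via igraph) with a deterministic ordering: paths sorted
#' by length, ties broken lexicographically by node sequence. Fewer than `K`
#' paths are returned when fewer exist.
#'
#' @param graph An igraph object.
#' @param source,target Vertex ids.
#' @param K Maximum number of paths (`>= 1`).
#' @return List of integer vertex vectors, possibly empty.
#' @export
yen_k_shortest <- function(graph, source, target, K) {
  stopifnot(K >= 1)
  nv <- igraph::vcount(graph)
  if (source < 1 || source > nv || target < 1 || target > nv) {
    stop("source or target vertex absent from graph", call. = FALSE)
  }
  # fetch enough paths to cover every tie at the K-th length, so the
  # deterministic (length, lexicographic) order is independent of the
  # library's internal tie-breaking
  k_fetch <- K
  repeat {
    res <- suppressWarnings(
      igraph::k_shortest_paths(graph, from = source, to = target, k = k_fetch)
    )
    paths <- lapply(res$vpaths, as.integer)
    if (length(paths) < k_fetch) break
    len <- vapply(paths, length, integer(1))
    if (len[length(len)] > len[K]) break
    k_fetch <- k_fetch * 2L
  }
  if (!length(paths)) return(list())
  key <- vapply(paths, function(p) {
    paste(sprintf("%06d", c(length(p), p)), collapse = "/")
  }, character(1))
  paths <- paths[order(key)]
  utils::head(paths, K)
}

#' Rank pathway pairs by a receptor-to-TF shortest-path statistic
#'
#' For each ordered pair (A, B), extracts the `K` shortest paths on the
#' collapsed signaling layer from every receptor of pathway A to every
#' transcription factor of pathway B and applies a crosstalk statistic
#' `chi_fn` to the path set; z-scores and empirical p-values come from
#' recomputing the statistic on randomized layer instances. Pairs lacking
#' receptors, TFs or connecting paths are undetected. The statistic is a
#' plug-in: the default simply counts the paths, a deliberately simple
#' stand-in users can replace with any statistic over the path set.
#'
#' @param net A `mux_net`.
#' @param ensemble A `mux_ensemble` built from `net`.
#' @param receptors,tfs Character vectors of receptor and TF gene ids.
#' @param K Paths per receptor-TF pair.
#' @param chi_fn Function taking a list of paths (integer vertex vectors)
#'   and returning a single number. Required; `chi_path_count` is the
#'   shipped default.
#' @param n_rand Null draws per pair.
#' @return Tibble with one row per ordered pair: `pathway_a`, `pathway_b`,
#'   `chi`, `z`, `p_emp`, `detected`, `rank`.
#' @export
chi_rank <- function(net, ensemble, receptors, tfs, K = 10,
                     chi_fn = chi_path_count, n_rand = 100) {
  if (is.null(chi_fn)) {
    stop("supply a chi_fn statistic over the K-shortest-path set ",
         "(e.g. chi_path_count)", call. = FALSE)
  }
  ids <- names(net$membership)
  pairs <- tidyr::expand_grid(pathway_a = ids, pathway_b = ids)
  pairs <- dplyr::filter(pairs, .data$pathway_a != .data$pathway_b)

  paths_stat <- function(graph, rec_idx, tf_idx) {
    paths <- list()
    for (a in rec_idx) {
      for (b in tf_idx) {
        paths <- c(paths, yen_k_shortest(graph, a, b, K))
      }
    }
    list(chi = if (length(paths)) chi_fn(paths) else NA_real_,
         n = length(paths))
  }

  g0 <- graph_from_layer(net$layers$KEGGPPI)
  inst_graphs <- lapply(ensemble$instances$KEGGPPI, graph_from_layer)

  res <- lapply(seq_len(nrow(pairs)), function(r) {
    pa <- pairs$pathway_a[r]; pb <- pairs$pathway_b[r]
    rec <- match(intersect(intersect(receptors, net$membership[[pa]]),
                           net$genes), net$genes)
    tfi <- match(intersect(intersect(tfs, net$membership[[pb]]),
                           net$genes), net$genes)
    base <- tibble::tibble(pathway_a = pa, pathway_b = pb, chi = NA_real_,
                           z = NA_real_, p_emp = NA_real_, detected = FALSE)
    if (!length(rec) || !length(tfi)) return(base)
    obs <- paths_stat(g0, rec, tfi)
    if (!obs$n) return(base)
    alloc <- allocate_instances(ensemble, c("KEGGPPI", "KEGGPPI"), n_rand,
                                paste0("chi:", pa, "->", pb))
    c_r <- vapply(alloc$i, function(i) {
      v <- paths_stat(inst_graphs[[i]], rec, tfi)$chi
      if (is.na(v)) 0 else v
    }, numeric(1))
    st <- multilink_stats(obs$chi, c_r, n_rand)
    tibble::tibble(pathway_a = pa, pathway_b = pb, chi = obs$chi,
                   z = st$z, p_emp = st$p_emp, detected = TRUE)
  })
  tbl <- dplyr::bind_rows(res)
  zkey <- tbl$z
  zkey[is.na(zkey)] <- -Inf
  tbl$.zkey <- -zkey
  out <- rank_by(tbl, .data$p_emp, .data$.zkey,
                 .data$pathway_a, .data$pathway_b)
  out$.zkey <- NULL
  out
}

#' @rdname chi_rank
#' @param paths List of paths.
#' @export
chi_path_count <- function(paths) length(paths)
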