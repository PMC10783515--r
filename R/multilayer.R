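# Layer objects -------------------------------------------------------------

# A layer stores its canonical edge list (integer node indices) and the signed
# sparse adjacency derived from it. Canonical form keeps at most one record
# per unordered node pair: a directed record with its orientation, or an
# undirected record with from < to. Reciprocal directed edges of the same
# type collapse to the undirected representation (+1 at both positions), the
# only form the signed {-1, 0, +1} fill can carry.
canonicalize_edges <- function(from, to, directed, n) {
  if (!length(from)) {
    return(tibble::tibble(from = integer(), to = integer(), directed = logical()))
  }
  from <- as.integer(from); to <- as.integer(to)
  keep <- from != to
  from <- from[keep]; to <- to[keep]; directed <- directed[keep]
  ukey <- upair_key(from, to, n)

  und_keys <- ukey[!directed]
  dkey_fwd <- pair_key(from[directed], to[directed], n)
  dkey_rev <- pair_key(to[directed], from[directed], n)
  recip <- dkey_fwd %in% dkey_rev
  sym_keys <- unique(c(und_keys, ukey[directed][recip]))

  # undirected part: one from<to record per symmetric unordered key
  sym_sel <- !duplicated(ukey) & (ukey %in% sym_keys)
  lo <- pmin(from[sym_sel], to[sym_sel])
  hi <- pmax(from[sym_sel], to[sym_sel])
  und <- tibble::tibble(from = lo, to = hi, directed = FALSE)
  # directed part: deduplicated single-orientation records
  dir_sel <- directed & !(ukey %in% sym_keys)
  dup <- duplicated(pair_key(from, to, n)) # ordered duplicates
  dir_sel <- dir_sel & !dup
  dir <- tibble::tibble(from = from[dir_sel], to = to[dir_sel], directed = TRUE)

  dplyr::arrange(dplyr::bind_rows(und, dir), .data$from, .data$to)
}

# Signed sparse adjacency: directed i->j gives (i,j)=+1, (j,i)=-1; undirected
# gives +1 at both symmetric positions. Entry magnitudes never exceed 1.
edges_to_matrix <- function(edges, n) {
  if (!nrow(edges)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  i <- c(edges$from, edges$to)
  j <- c(edges$to, edges$from)
  x <- c(rep(1, nrow(edges)), ifelse(edges$directed, -1, 1))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

new_layer <- function(label, from, to, directed, n) {
  edges <- canonicalize_edges(from, to, directed, n)
  structure(
    list(label = label, edges = edges, n = n,
         matrix = edges_to_matrix(edges, n)),
    class = "mux_layer"
  )
}

#' @export
print.mux_layer <- function(x, ...) {
  cat("<mux_layer> ", x$label, ": ", nrow(x$edges), " edges (",
      sum(x$edges$directed), " directed) over ", x$n, " nodes\n", sep = "")
  invisible(x)
}

# Multilayer network ---------------------------------------------------------

#' Build the signaling-regulatory multilayer network
#'
#' Assembles the default 13-layer multiplex network over the shared gene
#' universe of the refined signaling multigraph: 11 interaction-specific
#' signaling layers (each holding its own type's edges plus every PPI edge,
#' which widens the rewiring space of the null model), one collapsed
#' `KEGGPPI` layer holding every signaling/PPI edge exactly once with no type
#' distinction, and one regulatory (`GRN`) layer restricted to the signaling
#' gene universe (regulatory-only genes are pruned).
#'
#' @param signaling A refined `signaling_multigraph` (see
#'   [refine_signaling()]).
#' @param grn_edges Tibble with columns `tf`, `target` (directed regulatory
#'   edges), e.g. from [read_grn_tsv()].
#' @param membership Optional named list mapping pathway id to gene ids; if
#'   `NULL`, derived from the pathway annotations on the signaling edges.
#' @param type_index Named integer vector mapping interaction type to a
#'   signaling layer index in `[1, 11]`; see [default_type_index()].
#' @return A `mux_net`: list with `genes` (character vector defining the
#'   index space), `n`, `layers` (named list of 13 layer objects), and
#'   `membership`.
#' @export
build_multilayer <- function(signaling, grn_edges, membership = NULL,
                             type_index = default_type_index()) {
  stopifnot(inherits(signaling, "signaling_multigraph"))
  grn_edges <- tibble::as_tibble(grn_edges)
  if (!all(c("tf", "target") %in% names(grn_edges))) {
    stop("grn_edges must have columns tf, target", call. = FALSE)
  }

  edges <- signaling$edges
  unknown <- setdiff(unique(edges$type), names(type_index))
  if (length(unknown)) {
    stop("interaction type(s) not in type_index: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  genes <- sort(unique(c(signaling$nodes$node_id, edges$source, edges$target)))
  n <- length(genes)
  idx <- stats::setNames(seq_len(n), genes)

  grn <- dplyr::filter(grn_edges, .data$tf %in% genes, .data$target %in% genes,
                       .data$tf != .data$target)
  # a nonempty regulatory input must overlap the signaling gene universe; an
  # explicitly empty input builds an empty regulatory layer
  if (!nrow(grn) && nrow(grn_edges)) {
    stop("empty regulatory layer", call. = FALSE)
  }

  s_of <- unname(type_index[edges$type])
  ef <- idx[edges$source]; et <- idx[edges$target]
  is_ppi <- edges$type == "ppi"

  labels <- layer_labels()
  layers <- vector("list", 13L)
  names(layers) <- c(labels, "KEGGPPI", "GRN")
  for (s in 1:11) {
    sel <- s_of == s | is_ppi
    layers[[labels[s]]] <- new_layer(labels[s], ef[sel], et[sel],
                                     edges$directed[sel], n)
  }
  layers[["KEGGPPI"]] <- new_layer("KEGGPPI", ef, et, edges$directed, n)
  layers[["GRN"]] <- new_layer("GRN", idx[grn$tf], idx[grn$target],
                               rep(TRUE, nrow(grn)), n)

  if (is.null(membership)) {
    ann <- dplyr::filter(edges, !is.na(.data$pathway))
    membership <- lapply(
      split(seq_len(nrow(ann)), ann$pathway),
      function(i) sort(unique(c(ann$source[i], ann$target[i])))
    )
  }
  membership <- lapply(membership, function(g) intersect(g, genes))

  structure(
    list(genes = genes, n = n, layers = layers, membership = membership,
         type_index = type_index),
    class = "mux_net"
  )
}

#' @export
print.mux_net <- function(x, ...) {
  cat("<mux_net> ", x$n, " genes, ", length(x$layers), " layers, ",
      length(x$membership), " pathways\n", sep = "")
  for (l in x$layers) {
    cat("  ", format(l$label, width = 20), nrow(l$edges), " edges\n", sep = "")
  }
  invisible(x)
}

#' @rdname build_multilayer
#' @param x,object A `mux_net`.
#' @param ... Unused.
#' @return `glance()` returns a one-row tibble with the gene count, layer
#'   count, pathway count and total unique edge count.
#' @export
glance.mux_net <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n,
    n_layers = length(x$layers),
    n_pathways = length(x$membership),
    n_signaling_edges = nrow(x$layers$KEGGPPI$edges),
    n_regulatory_edges = nrow(x$layers$GRN$edges)
  )
}

#' Per-layer edge summary of a multilayer network
#'
#' @param x A `mux_net`.
#' @param ... Unused.
#' @return Tibble with one row per layer: `layer`, `S` (signaling index, NA
#'   for the collapsed and regulatory layers), `n_edges`, `n_directed`.
#' @export
tidy.mux_net <- function(x, ...) {
  tibble::tibble(
    layer = names(x$layers),
    S = c(1:11, NA_integer_, NA_integer_),
    n_edges = vapply(x$layers, function(l) nrow(l$edges), integer(1)),
    n_directed = vapply(x$layers, function(l) sum(l$edges$directed), integer(1))
  )
}
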