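#' Merge pathway graphs into a signaling multigraph
#'
#' Aggregates parsed pathway graphs into one directed heterogeneous
#' multigraph. Every edge record keeps its interaction type and pathway of
#' origin, so the same ordered node pair may carry several parallel records
#' (possibly with conflicting types across pathways, e.g. inhibitory in one
#' pathway and activating in another).
#'
#' @param pathway_graphs List of `pathway_graph` objects from [parse_kgml()].
#' @return A `signaling_multigraph`: list with `nodes` (tibble `node_id`,
#'   `node_kind`) and `edges` (tibble `source`, `target`, `type`, `directed`,
#'   `pathway`), plus a `multiplicity` element reporting the number and
#'   fraction of unordered node pairs carried by more than one pathway and
#'   those with conflicting types across pathways.
#' @export
merge_pathways <- function(pathway_graphs) {
  if (!length(pathway_graphs)) {
    stop("merge_pathways() needs at least one pathway graph", call. = FALSE)
  }
  nodes <- dplyr::distinct(
    dplyr::bind_rows(lapply(pathway_graphs, `[[`, "nodes")),
    .data$node_id, .keep_all = TRUE
  )
  edges <- dplyr::bind_rows(lapply(pathway_graphs, `[[`, "edges"))

  pair_id <- paste(pmin(edges$source, edges$target),
                   pmax(edges$source, edges$target), sep = "\r")
  by_pair <- split(seq_len(nrow(edges)), pair_id)
  n_pathways_per_pair <- vapply(
    by_pair, function(i) length(unique(edges$pathway[i])), integer(1)
  )
  n_types_per_pair <- vapply(
    by_pair, function(i) length(unique(edges$type[i])), integer(1)
  )
  shared <- n_pathways_per_pair > 1L
  conflicting <- shared & n_types_per_pair > 1L
  multiplicity <- list(
    n_pairs = length(by_pair),
    n_shared_pairs = sum(shared),
    frac_shared_pairs = mean(shared),
    n_conflicting_pairs = sum(conflicting),
    frac_conflicting_pairs = mean(conflicting)
  )

  structure(
    list(nodes = nodes, edges = edges, multiplicity = multiplicity),
    class = "signaling_multigraph"
  )
}

#' @export
print.signaling_multigraph <- function(x, ...) {
  cat("<signaling_multigraph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edge records, ", length(unique(stats::na.omit(x$edges$pathway))),
      " pathways\n", sep = "")
  invisible(x)
}

#' Refine the signaling multigraph and fold in the PPI scaffold
#'
#' Applies the quality-control and merging rules that produce the final
#' signaling layer: (a) non-gene nodes (compound, map, ortholog) and their
#' edges are removed, (b) records of unknown type are removed, (c) self-loops
#' are removed from both the pathway and PPI parts, (d) gene-expression
#' relation records (`expression`, `repression`) are removed to avoid
#' redundancy with the regulatory layer, and (e) PPI edges are added as
#' undirected `ppi` records only for unordered node pairs not already covered
#' by any pathway record — a known signaling interaction supersedes the PPI
#' edge. The resulting node universe is the union of pathway genes and PPI
#' genes. The operation is idempotent.
#'
#' @param multigraph A `signaling_multigraph` from [merge_pathways()].
#' @param ppi_edges Tibble/data frame with columns `gene_a`, `gene_b`
#'   (undirected PPI edge list), e.g. from [read_ppi_tsv()].
#' @return A refined `signaling_multigraph` whose nodes are all genes.
#' @export
refine_signaling <- function(multigraph, ppi_edges) {
  stopifnot(inherits(multigraph, "signaling_multigraph"))
  ppi_edges <- tibble::as_tibble(ppi_edges)
  if (!all(c("gene_a", "gene_b") %in% names(ppi_edges))) {
    stop("ppi_edges must have columns gene_a, gene_b", call. = FALSE)
  }

  gene_ids <- multigraph$nodes$node_id[multigraph$nodes$node_kind == "gene"]
  edges <- multigraph$edges
  edges <- dplyr::filter(
    edges,
    .data$source %in% gene_ids, .data$target %in% gene_ids,
    .data$type != "unknown",
    !(.data$type %in% c("expression", "repression")),
    .data$source != .data$target
  )

  ppi <- dplyr::filter(ppi_edges, .data$gene_a != .data$gene_b)
  ppi_pair <- paste(pmin(ppi$gene_a, ppi$gene_b),
                    pmax(ppi$gene_a, ppi$gene_b), sep = "\r")
  keep <- !duplicated(ppi_pair)
  ppi <- ppi[keep, , drop = FALSE]
  ppi_pair <- ppi_pair[keep]

  covered <- unique(paste(pmin(edges$source, edges$target),
                          pmax(edges$source, edges$target), sep = "\r"))
  add <- !(ppi_pair %in% covered)
  ppi_records <- tibble::tibble(
    source = pmin(ppi$gene_a[add], ppi$gene_b[add]),
    target = pmax(ppi$gene_a[add], ppi$gene_b[add]),
    type = "ppi", directed = FALSE, pathway = NA_character_
  )

  all_edges <- dplyr::bind_rows(edges, ppi_records)
  node_ids <- sort(unique(c(gene_ids[gene_ids %in% c(edges$source, edges$target)],
                            ppi$gene_a, ppi$gene_b,
                            all_edges$source, all_edges$target)))
  nodes <- tibble::tibble(node_id = node_ids, node_kind = "gene")

  structure(
    list(nodes = nodes, edges = all_edges, multiplicity = multigraph$multiplicity),
    class = "signaling_multigraph"
  )
}

#' Read an undirected PPI edge list from TSV
#'
#' Expects two columns (`gene_a`, `gene_b`), with an optional third `weight`
#' column supporting confidence-score cutoffs (STRING-style).
#'
#' @param path TSV file path.
#' @param min_weight If the file has a `weight` column, keep only edges with
#'   `weight >= min_weight`.
#' @return Tibble with columns `gene_a`, `gene_b` (and `weight` if present).
#' @export
read_ppi_tsv <- function(path, min_weight = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1:2] <- c("gene_a", "gene_b")
  x$gene_a <- as.character(x$gene_a)
  x$gene_b <- as.character(x$gene_b)
  if (!is.null(min_weight) && "weight" %in% names(x)) {
    x <- dplyr::filter(x, .data$weight >= min_weight)
  }
  x
}

#' Read a directed TF -> target regulatory edge list from TSV
#'
#' Expects two columns (`tf`, `target`), with an optional third `weight`
#' column supporting motif-p / enrichment-score style cutoffs.
#'
#' @inheritParams read_ppi_tsv
#' @return Tibble with columns `tf`, `target` (and `weight` if present).
#' @export
read_grn_tsv <- function(path, min_weight = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1:2] <- c("tf", "target")
  x$tf <- as.character(x$tf)
  x$target <- as.character(x$target)
  if (!is.null(min_weight) && "weight" %in% names(x)) {
    x <- dplyr::filter(x, .data$weight >= min_weight)
  }
  x
}

#' Read pathway membership from a GMT file
#'
#' @param path GMT file path (tab-separated: set name, description, genes...).
#' @return Named list mapping pathway id to a character vector of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    list(name = f[[1]], genes = unique(f[-(1:2)]))
  })
  stats::setNames(lapply(out, `[[`, "genes"), vapply(out, `[[`, "", "name"))
}

#' Write pathway membership to a GMT file
#'
#' @param membership Named list mapping pathway id to gene ids.
#' @param path Output file path.
#' @export
write_gmt <- function(membership, path) {
  lines <- vapply(names(membership), function(nm) {
    paste(c(nm, nm, membership[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export / import a signaling multigraph as a TSV edge table
#'
#' The table has columns `source`, `target`, `type`, `directed`, `pathway`;
#' writing then reading reproduces the multigraph exactly.
#'
#' @param multigraph A `signaling_multigraph`.
#' @param path Output TSV path.
#' @export
write_multigraph_tsv <- function(multigraph, path) {
  stopifnot(inherits(multigraph, "signaling_multigraph"))
  readr::write_tsv(multigraph$edges, path)
  invisible(path)
}

#' @rdname write_multigraph_tsv
#' @return `read_multigraph_tsv()` returns a `signaling_multigraph` (all
#'   nodes typed gene; multiplicity statistics recomputed).
#' @export
read_multigraph_tsv <- function(path) {
  edges <- readr::read_tsv(
    path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      type = readr::col_character(), directed = readr::col_logical(),
      pathway = readr::col_character()
    )
  )
  nodes <- tibble::tibble(
    node_id = sort(unique(c(edges$source, edges$target))), node_kind = "gene"
  )
  g <- structure(list(nodes = nodes, edges = edges, multiplicity = NULL),
                 class = "signaling_multigraph")
  g$multiplicity <- merge_pathways(list(list(nodes = nodes, edges = edges)))$multiplicity
  g
}
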