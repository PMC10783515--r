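#' Parse a KGML pathway document into a pathway graph
#'
#' Reads a KEGG Markup Language (KGML) document and builds a directed pathway
#' graph of KEGG entries (nodes) and relations (edges). Group entries
#' (protein complexes drawn as one box) are disaggregated into their member
#' genes and represented as complete graphs of undirected `within_group`
#' edges; relations that reference a group entry are expanded to every member.
#' Non-gene entries (compound, map, ortholog) are retained as typed nodes at
#' this stage and removed later by [refine_signaling()].
#'
#' Relations with several subtype children yield one edge record per subtype;
#' relations with no subtype are kept with type `"unknown"` so that downstream
#' refinement can drop them. Subtypes `binding/association` and `dissociation`
#' are undirected; all other subtypes keep the `entry1 -> entry2` direction.
#'
#' @param kgml Path to a KGML file, a KGML string, or an `xml2` document.
#' @return A `pathway_graph`: list with `pathway_id`, `nodes` (tibble with
#'   columns `node_id`, `node_kind`) and `edges` (tibble with columns
#'   `source`, `target`, `type`, `directed`, `pathway`).
#' @export
#' @examples
#' doc <- gen_kgml_fixture(
#'   pathway_id = "path1",
#'   entries = tibble::tibble(
#'     id = c("1", "2"), name = c("gA", "gB"), type = "gene",
#'     components = list(character(), character())
#'   ),
#'   relations = tibble::tibble(
#'     entry1 = "1", entry2 = "2", type = "PPrel", subtypes = list("activation")
#'   )
#' )
#' parse_kgml(doc)$edges
parse_kgml <- function(kgml) {
  doc <- tryCatch(
    {
      if (inherits(kgml, "xml_document")) {
        kgml
      } else if (is.character(kgml) && length(kgml) == 1L &&
                   !grepl("<", kgml, fixed = TRUE)) {
        xml2::read_xml(kgml)
      } else {
        xml2::read_xml(paste(kgml, collapse = "\n"))
      }
    },
    error = function(e) stop("malformed KGML XML: ", conditionMessage(e), call. = FALSE)
  )

  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(xml2::xml_name(root)) || xml2::xml_name(root) != "pathway") {
    stop("malformed KGML XML: missing <pathway> root element", call. = FALSE)
  }
  pathway_id <- xml2::xml_attr(root, "name")
  if (is.na(pathway_id)) pathway_id <- "pathway"

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  # Entries may carry several identifiers in `name`; the first token is used
  # as the node id. Identifiers are opaque strings, no conversion is done.
  entry_name <- vapply(
    strsplit(xml2::xml_attr(entries, "name"), "\\s+"),
    function(x) if (length(x)) x[[1]] else NA_character_, character(1)
  )

  is_group <- entry_type == "group"
  group_members <- stats::setNames(vector("list", sum(is_group)), entry_id[is_group])
  for (gid in entry_id[is_group]) {
    comp <- xml2::xml_find_all(
      entries[entry_id == gid][[1]], "./component"
    )
    group_members[[gid]] <- xml2::xml_attr(comp, "id")
  }

  # Map an entry id to the node ids it stands for (group -> member genes).
  id_to_nodes <- function(id) {
    if (id %in% names(group_members)) {
      members <- group_members[[id]]
      unname(vapply(members, id_to_nodes_single, character(1)))
    } else {
      id_to_nodes_single(id)
    }
  }
  id_to_nodes_single <- function(id) {
    hit <- which(entry_id == id)
    if (!length(hit)) {
      stop("relation references undeclared entry id '", id, "'", call. = FALSE)
    }
    entry_name[hit[1]]
  }

  nodes <- tibble::tibble(
    node_id = entry_name[!is_group],
    node_kind = entry_type[!is_group]
  )
  nodes <- dplyr::distinct(
    dplyr::filter(nodes, .data$node_kind %in% c("gene", "compound", "map", "ortholog")),
    .data$node_id, .keep_all = TRUE
  )

  undirected <- undirected_relation_types()
  edge_rows <- list()

  # Group disaggregation: complete graph of within_group edges per group.
  for (gid in names(group_members)) {
    members <- unique(unname(vapply(group_members[[gid]], id_to_nodes_single, character(1))))
    if (length(members) >= 2L) {
      cmb <- utils::combn(sort(members), 2L)
      edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
        source = cmb[1L, ], target = cmb[2L, ],
        type = "within_group", directed = FALSE
      )
    }
  }

  relations <- xml2::xml_find_all(doc, "/pathway/relation")
  vocab <- kegg_relation_types()
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    rel_type <- xml2::xml_attr(rel, "type")
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    src <- id_to_nodes(e1)
    dst <- id_to_nodes(e2)
    if (!length(subtypes)) {
      types <- "unknown"
    } else {
      # PCrel/compound-mediated relations are typed "compound"; subtype names
      # outside the closed vocabulary become "unknown" (dropped downstream).
      types <- unname(vapply(subtypes, function(s) {
        if (identical(rel_type, "PCrel") || identical(s, "compound")) {
          "compound"
        } else if (s %in% vocab) s else "unknown"
      }, character(1)))
    }
    grid <- expand.grid(source = src, target = dst,
                        type = types, stringsAsFactors = FALSE)
    edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
      source = grid$source, target = grid$target, type = grid$type,
      directed = !(grid$type %in% undirected) & grid$type != "unknown"
    )
  }

  edges <- if (length(edge_rows)) {
    dplyr::bind_rows(edge_rows)
  } else {
    tibble::tibble(source = character(), target = character(),
                   type = character(), directed = logical())
  }
  # Quality control at parse time: no self-loops.
  edges <- dplyr::filter(edges, .data$source != .data$target)
  edges$pathway <- rep(pathway_id, nrow(edges))

  # Every edge endpoint must be a declared node (groups already expanded).
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$node_id)
  if (length(missing)) {
    stop("edge endpoints not declared as entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  structure(
    list(pathway_id = pathway_id, nodes = nodes, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edge records\n", sep = "")
  invisible(x)
}
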