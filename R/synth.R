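# Synthetic multilayer networks with known structure, so the whole inference
# pipeline is testable without any external download.

#' Specification for a synthetic multilayer network
#'
#' The defaults emulate the statistical shape of the real inputs at desk
#' scale: a sparse directed typed signaling multigraph organized in a few
#' connected pathways with partial gene sharing, a denser undirected PPI
#' scaffold over the whole gene universe, and a directed bipartite TF ->
#' target regulatory layer over a 10% TF subset. Signaling densities are
#' kept well under 0.1, matching the sparsity of curated pathway maps.
#'
#' @param n_genes Gene universe size.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Min/max genes per pathway.
#' @param type_densities Named per-type edge densities inside each pathway
#'   (fraction of ordered gene pairs).
#' @param ppi_density Undirected PPI edge probability per unordered pair.
#' @param grn_density TF -> target edge probability per ordered (TF, gene)
#'   pair.
#' @param overlap_fraction Fraction of a pathway's genes shared with the
#'   previous pathway.
#' @param tf_fraction Fraction of genes designated TFs.
#' @param seed Integer seed; fully determines the generated network.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_genes = 200, n_pathways = 5,
                       pathway_size_range = c(20, 30),
                       type_densities = c(
                         "activation" = 0.015,
                         "binding/association" = 0.010,
                         "inhibition" = 0.008,
                         "phosphorylation" = 0.008,
                         "compound" = 0.003,
                         "dephosphorylation" = 0.003,
                         "dissociation" = 0.003,
                         "indirect effect" = 0.003,
                         "state change" = 0.003,
                         "ubiquitination" = 0.003
                       ),
                       ppi_density = 0.01, grn_density = 0.01,
                       overlap_fraction = 0.1, tf_fraction = 0.1,
                       seed = 1L) {
  stopifnot(
    all(type_densities >= 0), all(type_densities <= 1),
    ppi_density >= 0, ppi_density <= 1, grn_density >= 0, grn_density <= 1,
    pathway_size_range[1] >= 2, n_pathways >= 1
  )
  structure(
    list(n_genes = n_genes, n_pathways = n_pathways,
         pathway_size_range = pathway_size_range,
         type_densities = type_densities, ppi_density = ppi_density,
         grn_density = grn_density, overlap_fraction = overlap_fraction,
         tf_fraction = tf_fraction, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic multilayer network
#'
#' Pathways are random recursive trees (guaranteeing connectedness) over
#' partially overlapping gene sets, decorated with extra typed arcs at the
#' requested per-type densities; the PPI layer is an undirected G(n, p); the
#' regulatory layer is a directed bipartite TF -> target sample. The
#' pathway graphs go through the real construction pipeline
#' ([merge_pathways()], [refine_signaling()], [build_multilayer()]), so a
#' generated object satisfies every structural invariant of a built network.
#'
#' @param spec A `synth_spec`.
#' @return A `mux_synth` list: `spec`, `pathway_graphs`, `ppi`, `grn`,
#'   `membership`, `multigraph` (refined) and `net` (the `mux_net`).
#' @export
gen_multilayer <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with(spec, {
    mean_size <- mean(pathway_size_range)
    pos_per_pathway <- mean_size * (mean_size - 1)
    for (tn in names(type_densities)) {
      d <- type_densities[[tn]]
      if (d > 0 && d * pos_per_pathway * n_pathways < 1) {
        stop("infeasible spec: density for '", tn,
             "' cannot place a single edge", call. = FALSE)
      }
    }
    if (ppi_density > 0 && ppi_density * n_genes * (n_genes - 1) / 2 < 1) {
      stop("infeasible spec: ppi_density cannot place a single edge",
           call. = FALSE)
    }
    n_tf <- max(1L, ceiling(tf_fraction * n_genes))
    if (grn_density > 0 && grn_density * n_tf * (n_genes - 1) < 1) {
      stop("infeasible spec: grn_density cannot place a single edge",
           call. = FALSE)
    }
    NULL
  })

  withr::with_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    undirected <- undirected_relation_types()
    tnames <- names(spec$type_densities)
    tweights <- spec$type_densities
    if (all(tweights == 0)) tweights <- rep(1, length(tweights))

    # pathway gene sets: chained sharing with the previous pathway
    membership <- list()
    pool <- genes
    prev <- character(0)
    for (p in seq_len(spec$n_pathways)) {
      size <- sample(seq(spec$pathway_size_range[1],
                         spec$pathway_size_range[2]), 1L)
      n_shared <- if (length(prev)) min(ceiling(spec$overlap_fraction * size),
                                        length(prev)) else 0L
      shared <- if (n_shared) sample(prev, n_shared) else character(0)
      avail <- setdiff(pool, shared)
      if (length(avail) < size - n_shared) {
        stop("infeasible spec: gene universe too small for the requested ",
             "pathways", call. = FALSE)
      }
      fresh <- sample(avail, size - n_shared)
      memb <- c(shared, fresh)
      membership[[sprintf("pw%02d", p)]] <- sort(memb)
      pool <- setdiff(pool, fresh)
      prev <- memb
    }

    pathway_graphs <- lapply(names(membership), function(pid) {
      gs <- sample(membership[[pid]])
      k <- length(gs)
      # random recursive tree for connectedness
      parents <- vapply(2:k, function(i) gs[sample.int(i - 1L, 1L)],
                        character(1))
      tree_types <- sample(tnames, k - 1L, replace = TRUE, prob = tweights)
      edges <- tibble::tibble(source = parents, target = gs[-1L],
                              type = tree_types)
      # extra typed arcs at the requested densities
      grid <- expand.grid(source = gs, target = gs,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$source != grid$target, ]
      extra <- lapply(tnames, function(tn) {
        sel <- stats::runif(nrow(grid)) < spec$type_densities[[tn]]
        if (!any(sel)) return(NULL)
        tibble::tibble(source = grid$source[sel], target = grid$target[sel],
                       type = tn)
      })
      edges <- dplyr::distinct(
        dplyr::bind_rows(c(list(edges), extra)),
        .data$source, .data$target, .data$type
      )
      edges$directed <- !(edges$type %in% undirected)
      edges$pathway <- pid
      structure(
        list(pathway_id = pid,
             nodes = tibble::tibble(node_id = sort(gs), node_kind = "gene"),
             edges = edges),
        class = "pathway_graph"
      )
    })

    # PPI: undirected G(n, p) over the whole gene universe
    up <- which(upper.tri(matrix(0, spec$n_genes, spec$n_genes)),
                arr.ind = TRUE)
    sel <- stats::runif(nrow(up)) < spec$ppi_density
    ppi <- tibble::tibble(gene_a = genes[up[sel, 1]],
                          gene_b = genes[up[sel, 2]])

    # GRN: directed bipartite TF -> target sample
    n_tf <- max(1L, ceiling(spec$tf_fraction * spec$n_genes))
    tfs <- genes[seq_len(n_tf)]
    gg <- expand.grid(tf = tfs, target = genes, stringsAsFactors = FALSE)
    gg <- gg[gg$tf != gg$target, ]
    sel <- stats::runif(nrow(gg)) < spec$grn_density
    grn <- tibble::tibble(tf = gg$tf[sel], target = gg$target[sel])

    assemble_synth(spec, pathway_graphs, ppi, grn, membership, tfs)
  })
}

# Rebuild a mux_synth through the real construction pipeline.
assemble_synth <- function(spec, pathway_graphs, ppi, grn, membership, tfs,
                           extra_edges = NULL) {
  mg <- merge_pathways(pathway_graphs)
  if (!is.null(extra_edges) && nrow(extra_edges)) {
    new_nodes <- setdiff(unique(c(extra_edges$source, extra_edges$target)),
                         mg$nodes$node_id)
    mg$nodes <- dplyr::bind_rows(
      mg$nodes, tibble::tibble(node_id = new_nodes, node_kind = "gene")
    )
    mg$edges <- dplyr::bind_rows(mg$edges, extra_edges)
  }
  refined <- refine_signaling(mg, ppi)
  net <- build_multilayer(refined, grn, membership = membership)
  structure(
    list(spec = spec, pathway_graphs = pathway_graphs, ppi = ppi, grn = grn,
         membership = membership, tfs = tfs, extra_edges = extra_edges,
         multigraph = refined, net = net),
    class = "mux_synth"
  )
}

#' @export
print.mux_synth <- function(x, ...) {
  cat("<mux_synth> seed ", x$spec$seed, "\n", sep = "")
  print(x$net)
  invisible(x)
}

#' Plant a crosstalking pathway pair into a synthetic network
#'
#' Between mode adds `n_planted` coincident signaling/regulatory edge pairs
#' realizing the requested multilink type `(S, R)` on node pairs `(a, b)`
#' with `a` exclusive to pathway A and `b` exclusive to pathway B (and to no
#' other pathway, keeping the planting local to this pair); positions
#' already carrying any signaling or regulatory edge are avoided so the
#' subset count increases by exactly `n_planted`. Shortest mode routes the
#' signal through fresh intermediary genes `x` with signaling edges
#' `a -> x -> b` and regulatory edges realizing `(S, R)` on those positions.
#' The network is rebuilt through the standard pipeline and the pair is
#' returned as the positive truth label.
#'
#' @param synth A `mux_synth` from [gen_multilayer()].
#' @param pair Character vector `c(pathway_a, pathway_b)`.
#' @param mode `"between"` or `"shortest"`.
#' @param n_planted Number of planted multilinks (`>= 1`).
#' @param multilink_type Integer vector `c(S, R)` with `S` in `[1, 11]`,
#'   `R` in `{-1, 1}`.
#' @param seed Seed for position sampling.
#' @return A list with `synth` (rebuilt `mux_synth`) and `label` (one-row
#'   positive label tibble).
#' @export
plant_crosstalk <- function(synth, pair, mode = c("between", "shortest"),
                            n_planted = 10, multilink_type = c(9L, 1L),
                            seed = 1L) {
  stopifnot(inherits(synth, "mux_synth"), n_planted >= 1)
  mode <- match.arg(mode)
  s_type <- multilink_type[1]; r_dir <- multilink_type[2]
  stopifnot(s_type %in% 1:11, r_dir %in% c(-1L, 1L))
  type_name <- names(default_type_index())[
    match(s_type, default_type_index())
  ]
  undirected <- type_name %in% undirected_relation_types()

  memb <- synth$membership
  others <- function(p) unique(unlist(memb[setdiff(names(memb), p)]))
  only_a <- setdiff(memb[[pair[1]]], others(pair[1]))
  only_b <- setdiff(memb[[pair[2]]], others(pair[2]))
  if (!length(only_a) || !length(only_b)) {
    stop("insufficient exclusive nodes to plant crosstalk", call. = FALSE)
  }

  # occupied unordered gene pairs (any signaling or regulatory edge)
  occ <- unique(c(
    paste(pmin(synth$multigraph$edges$source, synth$multigraph$edges$target),
          pmax(synth$multigraph$edges$source, synth$multigraph$edges$target)),
    paste(pmin(synth$grn$tf, synth$grn$target),
          pmax(synth$grn$tf, synth$grn$target))
  ))

  withr::with_seed(seed, {
    if (mode == "between") {
      grid <- expand.grid(a = only_a, b = only_b, stringsAsFactors = FALSE)
      grid <- grid[!(paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b))
                     %in% occ), ]
      if (nrow(grid) < n_planted) {
        stop("insufficient free positions to plant crosstalk", call. = FALSE)
      }
      sel <- grid[sample.int(nrow(grid), n_planted), ]
      sig <- tibble::tibble(source = sel$a, target = sel$b,
                            type = type_name, directed = !undirected,
                            pathway = NA_character_)
      grn_add <- if (r_dir == 1L) {
        tibble::tibble(tf = sel$a, target = sel$b)
      } else {
        tibble::tibble(tf = sel$b, target = sel$a)
      }
    } else {
      a <- sample(only_a, n_planted, replace = TRUE)
      b <- sample(only_b, n_planted, replace = TRUE)
      x <- sprintf("x%04d", seq_len(n_planted))
      sig <- tibble::tibble(
        source = c(a, x), target = c(x, b),
        type = type_name, directed = !undirected, pathway = NA_character_
      )
      grn_add <- if (r_dir == 1L) {
        tibble::tibble(tf = c(a, x), target = c(x, b))
      } else {
        tibble::tibble(tf = c(x, b), target = c(a, x))
      }
    }

    extra <- dplyr::bind_rows(synth$extra_edges, sig)
    out <- assemble_synth(synth$spec, synth$pathway_graphs, synth$ppi,
                          dplyr::bind_rows(synth$grn, grn_add),
                          synth$membership, synth$tfs, extra_edges = extra)
    list(synth = out,
         label = tibble::tibble(pathway_a = pair[1], pathway_b = pair[2],
                                label = 1L))
  })
}

#' Emit a KGML document for a specified toy pathway
#'
#' Produces KGML text parseable by [parse_kgml()] that round-trips to the
#' specified graph: entries (optionally group entries with components) and
#' typed relations. Output is byte-stable for a fixed input.
#'
#' @param pathway_id Pathway name attribute.
#' @param entries Tibble with columns `id`, `name`, `type` and a
#'   `components` list column (entry ids for group entries, empty
#'   otherwise).
#' @param relations Tibble with columns `entry1`, `entry2`, `type` (KGML
#'   relation class, e.g. `PPrel`) and a `subtypes` list column of subtype
#'   names (empty for a subtype-less relation).
#' @return KGML document as a single character string.
#' @export
gen_kgml_fixture <- function(pathway_id, entries, relations) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="%s" org="syn" number="0">', esc(pathway_id))
  )
  for (i in seq_len(nrow(entries))) {
    comps <- entries$components[[i]]
    if (length(comps)) {
      lines <- c(
        lines,
        sprintf('  <entry id="%s" name="%s" type="%s">',
                entries$id[i], esc(entries$name[i]), entries$type[i]),
        sprintf('    <component id="%s"/>', comps),
        "  </entry>"
      )
    } else {
      lines <- c(lines, sprintf('  <entry id="%s" name="%s" type="%s"/>',
                                entries$id[i], esc(entries$name[i]),
                                entries$type[i]))
    }
  }
  if (!is.null(relations) && nrow(relations)) {
    for (i in seq_len(nrow(relations))) {
      subs <- relations$subtypes[[i]]
      if (length(subs)) {
        lines <- c(
          lines,
          sprintf('  <relation entry1="%s" entry2="%s" type="%s">',
                  relations$entry1[i], relations$entry2[i],
                  relations$type[i]),
          sprintf('    <subtype name="%s" value=""/>', esc(subs)),
          "  </relation>"
        )
      } else {
        lines <- c(lines,
                   sprintf('  <relation entry1="%s" entry2="%s" type="%s"/>',
                           relations$entry1[i], relations$entry2[i],
                           relations$type[i]))
      }
    }
  }
  paste(c(lines, "</pathway>", ""), collapse = "\n")
}

#' Generate benchmark labels over all ordered pathway pairs
#'
#' @param pathways Character vector of pathway ids.
#' @param positives Optional tibble (`pathway_a`, `pathway_b`) of
#'   crosstalking ordered pairs; all other ordered pairs are negatives.
#' @return Tibble with columns `pathway_a`, `pathway_b`, `label` covering
#'   all `n * (n - 1)` ordered pairs.
#' @export
gen_labels <- function(pathways, positives = NULL) {
  universe <- tidyr::expand_grid(pathway_a = pathways, pathway_b = pathways)
  universe <- dplyr::filter(universe, .data$pathway_a != .data$pathway_b)
  universe$label <- 0L
  if (!is.null(positives) && nrow(positives)) {
    pid <- paste(positives$pathway_a, positives$pathway_b, sep = "\r")
    if (anyDuplicated(pid)) {
      stop("duplicate positive pairs", call. = FALSE)
    }
    bad <- !(pid %in% paste(universe$pathway_a, universe$pathway_b,
                            sep = "\r"))
    if (any(bad)) stop("positive pair outside the universe", call. = FALSE)
    universe$label[paste(universe$pathway_a, universe$pathway_b,
                         sep = "\r") %in% pid] <- 1L
  }
  universe
}

#' Write a complete no-download input bundle for the command-line interface
#'
#' Produces a KGML directory, `ppi.tsv`, `grn.tsv`, `membership.gmt`,
#' `labels.tsv`, `receptors.txt` and `tfs.txt` from a synthetic network.
#' Receptors are a toy designation (the two lexicographically first genes of
#' each pathway).
#'
#' @param synth A `mux_synth`.
#' @param dir Output directory (created if needed).
#' @param labels Optional labels tibble; defaults to all-negative labels.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(synth, dir, labels = NULL) {
  dir.create(file.path(dir, "kgml"), recursive = TRUE, showWarnings = FALSE)
  rel_class <- function(type) {
    ifelse(type == "compound", "PCrel",
           ifelse(type %in% c("expression", "repression"), "GErel", "PPrel"))
  }
  for (pg in synth$pathway_graphs) {
    gs <- sort(pg$nodes$node_id)
    ids <- stats::setNames(as.character(seq_along(gs)), gs)
    entries <- tibble::tibble(
      id = unname(ids), name = gs, type = "gene",
      components = lapply(gs, function(.) character(0))
    )
    relations <- tibble::tibble(
      entry1 = unname(ids[pg$edges$source]),
      entry2 = unname(ids[pg$edges$target]),
      type = rel_class(pg$edges$type),
      subtypes = as.list(pg$edges$type)
    )
    writeLines(gen_kgml_fixture(pg$pathway_id, entries, relations),
               file.path(dir, "kgml", paste0(pg$pathway_id, ".xml")))
  }
  readr::write_tsv(synth$ppi, file.path(dir, "ppi.tsv"))
  readr::write_tsv(synth$grn, file.path(dir, "grn.tsv"))
  write_gmt(synth$membership, file.path(dir, "membership.gmt"))
  labels <- labels %||% gen_labels(names(synth$membership))
  write_labels_tsv(labels, file.path(dir, "labels.tsv"))
  receptors <- unique(unlist(lapply(synth$membership, function(g) {
    utils::head(sort(g), 2L)
  })))
  writeLines(receptors, file.path(dir, "receptors.txt"))
  writeLines(synth$tfs, file.path(dir, "tfs.txt"))
  invisible(dir)
}
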