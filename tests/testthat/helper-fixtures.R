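# Shared fixture builders. Everything is generated in code; no files.

# Build a layer directly from an edge table (1-based integer indices).
make_layer <- function(n, from, to, directed, label = "test") {
  crossmux:::new_layer(label, from, to, directed, n)
}

# Random mixed directed/undirected layer for property tests.
random_layer <- function(n, m, frac_directed = 0.7, seed = 1, label = "rand") {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2L))
    pick <- sample.int(nrow(pairs), min(m, nrow(pairs)))
    flip <- stats::runif(length(pick)) < 0.5
    from <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
    to <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
    make_layer(n, from, to,
               directed = stats::runif(length(pick)) < frac_directed,
               label = label)
  })
}

# Minimal KGML fixture helpers -------------------------------------------------

kgml_entries <- function(ids, names, types = "gene", components = NULL) {
  tibble::tibble(
    id = ids, name = names,
    type = rep(types, length.out = length(ids)),
    components = components %||% lapply(ids, function(.) character(0))
  )
}

kgml_relations <- function(entry1, entry2, type = "PPrel", subtypes) {
  tibble::tibble(entry1 = entry1, entry2 = entry2,
                 type = rep(type, length.out = length(entry1)),
                 subtypes = subtypes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built multigraph over named genes, for netbuild/crosstalk tests.
make_multigraph <- function(edges) {
  nodes <- tibble::tibble(
    node_id = sort(unique(c(edges$source, edges$target))), node_kind = "gene"
  )
  structure(list(nodes = nodes, edges = edges, multiplicity = NULL),
            class = "signaling_multigraph")
}

edge_row <- function(source, target, type, directed = TRUE, pathway = "pwA") {
  tibble::tibble(source = source, target = target, type = type,
                 directed = directed, pathway = pathway)
}

# Synthetic spec scaled for small test networks: denser per-type signaling
# so every requested layer stays feasible at toy pathway sizes.
small_spec <- function(n_genes, n_pathways, pathway_size_range, seed,
                       ppi_density = 0.02, grn_density = 0.02, ...) {
  synth_spec(
    n_genes = n_genes, n_pathways = n_pathways,
    pathway_size_range = pathway_size_range,
    type_densities = c("activation" = 0.06, "binding/association" = 0.04,
                       "inhibition" = 0.04, "phosphorylation" = 0.03),
    ppi_density = ppi_density, grn_density = grn_density, seed = seed, ...
  )
}

# A small deterministic multilayer network with two pathways joined through
# known edges; used by crosstalk unit tests.
toy_net <- function() {
  edges <- dplyr::bind_rows(
    edge_row("a1", "a2", "activation", pathway = "A"),
    edge_row("a2", "a3", "phosphorylation", pathway = "A"),
    edge_row("b1", "b2", "inhibition", pathway = "B"),
    edge_row("b2", "b3", "activation", pathway = "B"),
    edge_row("c1", "a1", "activation", pathway = "A"),
    edge_row("c1", "b1", "activation", pathway = "B")
  )
  mg <- make_multigraph(edges)
  ppi <- tibble::tibble(gene_a = c("a1", "a3", "x1"),
                        gene_b = c("b1", "x1", "b3"))
  refined <- refine_signaling(mg, ppi)
  grn <- tibble::tibble(tf = c("a1", "a3", "b2"),
                        target = c("b1", "x1", "a2"))
  build_multilayer(refined, grn,
                   membership = list(A = c("a1", "a2", "a3", "c1"),
                                     B = c("b1", "b2", "b3", "c1")))
}

# Dense-matrix oracle for multilink counts on one signaling layer: reads the
# two signed adjacency matrices position by position and applies the
# counting conventions independently of the edge-list implementation.
oracle_counts <- function(A, B) {
  n <- nrow(A)
  cnt <- c(`-1` = 0, `0` = 0, `1` = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aij <- A[i, j]; aji <- A[j, i]
      if (aij == 0 && aji == 0) next
      if (aij == 1 && aji == 1) {
        if (B[i, j] == 0 && B[j, i] == 0) {
          cnt["0"] <- cnt["0"] + 1
        } else {
          cnt["1"] <- cnt["1"] + 1
          cnt["-1"] <- cnt["-1"] + 1
        }
      } else {
        if (aij == 1) { bf <- B[i, j]; bb <- B[j, i] }
        else          { bf <- B[j, i]; bb <- B[i, j] }
        if (bf == 0 && bb == 0) cnt["0"] <- cnt["0"] + 1
        else if (bf > 0 && bb > 0) {
          cnt["1"] <- cnt["1"] + 1
          cnt["-1"] <- cnt["-1"] + 1
        } else if (bf > 0) cnt["1"] <- cnt["1"] + 1
        else cnt["-1"] <- cnt["-1"] + 1
      }
    }
  }
  cnt
}

# Matching oracle for the zero-signaling layer.
oracle_zero_counts <- function(K, B) {
  n <- nrow(K)
  c01 <- 0; occupied <- 0; grn_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k_on <- K[i, j] != 0 || K[j, i] != 0
      b_on <- B[i, j] != 0 || B[j, i] != 0
      if (b_on && !k_on) c01 <- c01 + 1
      if (k_on || b_on) occupied <- occupied + 1
    }
  }
  c(`0` = n * (n - 1) / 2 - occupied, `1` = c01)
}
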