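test_that("generation is a pure function of the spec seed", {
  s1 <- gen_multilayer(small_spec(n_genes = 60, n_pathways = 3,
                                  pathway_size_range = c(8, 12), seed = 31L))
  s2 <- gen_multilayer(small_spec(n_genes = 60, n_pathways = 3,
                                  pathway_size_range = c(8, 12), seed = 31L))
  expect_identical(as.data.frame(s1$multigraph$edges),
                   as.data.frame(s2$multigraph$edges))
  expect_identical(as.data.frame(s1$grn), as.data.frame(s2$grn))
  expect_identical(s1$membership, s2$membership)
  s3 <- gen_multilayer(small_spec(n_genes = 60, n_pathways = 3,
                                  pathway_size_range = c(8, 12), seed = 32L))
  expect_false(identical(as.data.frame(s1$ppi), as.data.frame(s3$ppi)))
})

test_that("requested layer densities are recovered within binomial bounds", {
  spec <- synth_spec(seed = 77L)
  syn <- gen_multilayer(spec)
  n <- spec$n_genes
  n_ppi_pos <- n * (n - 1) / 2
  expect_lt(abs(nrow(syn$ppi) - spec$ppi_density * n_ppi_pos),
            3 * sqrt(n_ppi_pos * spec$ppi_density * (1 - spec$ppi_density)))
  n_tf <- ceiling(spec$tf_fraction * n)
  n_grn_pos <- n_tf * (n - 1)
  expect_lt(abs(nrow(syn$grn) - spec$grn_density * n_grn_pos),
            3 * sqrt(n_grn_pos * spec$grn_density * (1 - spec$grn_density)))
})

test_that("an empty regulatory request empties the coincidence counts", {
  spec <- small_spec(n_genes = 60, n_pathways = 3,
                     pathway_size_range = c(8, 12), grn_density = 0,
                     seed = 41L)
  syn <- gen_multilayer(spec)
  expect_equal(nrow(syn$grn), 0L)
  expect_equal(nrow(syn$net$layers$GRN$edges), 0L)
  # with no regulatory edges, every (S, +/-1) tally over the whole network
  # is zero
  for (s in 1:11) {
    lab <- crossmux:::layer_labels()[s]
    cnt <- count_multilinks(syn$net$layers[[lab]], syn$net$layers$GRN, s = s)
    expect_equal(cnt$count[cnt$R != 0], c(0, 0))
  }
  z <- count_zero_signaling(syn$net$layers$KEGGPPI, syn$net$layers$GRN)
  expect_equal(z$count[z$R == 1], 0)
})

test_that("infeasible density requests error out", {
  expect_error(
    gen_multilayer(small_spec(n_genes = 20, n_pathways = 2,
                              pathway_size_range = c(4, 5),
                              ppi_density = 1e-6, seed = 1L)),
    "infeasible"
  )
})

test_that("generated networks satisfy the multiplex structural invariants", {
  for (seed in c(3L, 19L)) {
    syn <- gen_multilayer(small_spec(n_genes = 80, n_pathways = 4,
                                     pathway_size_range = c(10, 15),
                                     seed = seed))
    net <- syn$net
    expect_length(net$layers, 13L)
    for (l in net$layers) {
      expect_equal(dim(l$matrix), c(net$n, net$n))
      expect_true(all(abs(l$matrix@x) <= 1))
      expect_true(all(l$edges$from != l$edges$to))
      keys <- crossmux:::upair_key(l$edges$from, l$edges$to, net$n)
      expect_false(any(duplicated(keys)))
    }
    expect_true(all(unlist(net$membership) %in% net$genes))
    expect_true(all(net$layers$GRN$edges$from <= net$n))
  }
})

test_that("planting adds exactly the requested multilinks, locally", {
  syn <- gen_multilayer(synth_spec(seed = 61L))
  net0 <- syn$net
  ex <- exclusive_nodes("pw01", "pw03", net0$membership)
  pos0 <- between_positions(net0, ex$exA, ex$exB)
  before <- count_multilinks(net0$layers$ppi, net0$layers$GRN, s = 9,
                             restrict_pairs = pos0)

  pl <- plant_crosstalk(syn, c("pw01", "pw03"), mode = "between",
                        n_planted = 5, multilink_type = c(9L, 1L), seed = 8L)
  net1 <- pl$synth$net
  expect_equal(pl$label$label, 1L)
  pos1 <- between_positions(net1, ex$exA, ex$exB)
  after <- count_multilinks(net1$layers$ppi, net1$layers$GRN, s = 9,
                            restrict_pairs = pos1)
  # undirected planted edges with aligned regulation raise both (9, 1) and
  # (9, -1) tallies by exactly n_planted
  expect_equal(after$count[after$R == 1] - before$count[before$R == 1], 5)
  expect_equal(after$count[after$R == -1] - before$count[before$R == -1], 5)

  # all other pairs' between-subsets are untouched
  ids <- names(net0$membership)
  for (a in ids) for (b in setdiff(ids, a)) {
    if (a %in% c("pw01", "pw03") && b %in% c("pw01", "pw03")) next
    exo <- exclusive_nodes(a, b, net0$membership)
    p0 <- between_positions(net0, exo$exA, exo$exB)
    p1 <- between_positions(net1, exo$exA, exo$exB)
    c0 <- count_multilinks(net0$layers$ppi, net0$layers$GRN, s = 9,
                           restrict_pairs = p0)
    c1 <- count_multilinks(net1$layers$ppi, net1$layers$GRN, s = 9,
                           restrict_pairs = p1)
    expect_equal(c0$count, c1$count, info = paste(a, b))
  }
})

test_that("shortest-mode planting routes through fresh intermediaries", {
  syn <- gen_multilayer(synth_spec(seed = 71L))
  pl <- plant_crosstalk(syn, c("pw02", "pw05"), mode = "shortest",
                        n_planted = 6, multilink_type = c(1L, 1L), seed = 9L)
  net <- pl$synth$net
  fresh <- grep("^x", net$genes, value = TRUE)
  expect_length(fresh, 6L)
  # the planted intermediaries belong to no pathway
  expect_false(any(fresh %in% unlist(net$membership)))
  ex <- exclusive_nodes("pw02", "pw05", net$membership)
  sp <- shortest_positions(net, ex$exA, ex$exB, net$membership$pw02,
                           net$membership$pw05, sp_threshold = 1)
  expect_true(all(fresh %in% sp$intermediaries))
})

test_that("label universes have the expected ordered-pair counts", {
  expect_equal(nrow(gen_labels(sprintf("p%02d", 1:25))), 600L)
  expect_equal(nrow(gen_labels(sprintf("p%02d", 1:60))), 3540L)
  l3 <- gen_labels(c("a", "b", "c"),
                   positives = tibble::tibble(pathway_a = "a",
                                              pathway_b = "b"))
  expect_equal(nrow(l3), 6L)
  expect_equal(sum(l3$label), 1L)
  expect_error(
    gen_labels(c("a", "b"),
               positives = tibble::tibble(pathway_a = c("a", "a"),
                                          pathway_b = c("b", "b"))),
    "duplicate"
  )
})

test_that("unplanted networks keep the false-positive rate near the nominal level", {
  # loose type-I sanity bound on the per-(pair, type) positive rate
  rates <- vapply(1:5, function(seed) {
    syn <- gen_multilayer(small_spec(n_genes = 100, n_pathways = 3,
                                     pathway_size_range = c(12, 18),
                                     seed = 300L + seed))
    ens <- build_ensemble(syn$net, n_instances = 10, Q = 10,
                          master_seed = 300L + seed)
    res <- infer_crosstalk(syn$net, ens, method = "between", n_rand = 100)
    profs <- res$profile[!vapply(res$profile, is.null, TRUE)]
    n_tests <- sum(vapply(profs, function(p) sum(p$R != 0), numeric(1)))
    n_pos <- sum(vapply(profs, function(p) sum(p$significant), numeric(1)))
    if (n_tests == 0) 0 else n_pos / n_tests
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("fixture bundles are complete and readable by the import functions", {
  syn <- gen_multilayer(small_spec(n_genes = 40, n_pathways = 3,
                                   pathway_size_range = c(6, 9), seed = 13L))
  d <- withr::local_tempdir()
  write_fixture_bundle(syn, d)
  expect_setequal(
    list.files(d),
    c("kgml", "ppi.tsv", "grn.tsv", "membership.gmt", "labels.tsv",
      "receptors.txt", "tfs.txt")
  )
  memb <- read_gmt(file.path(d, "membership.gmt"))
  expect_identical(lapply(memb, sort), lapply(syn$membership, sort))
  lab <- read_labels_tsv(file.path(d, "labels.tsv"))
  expect_equal(nrow(lab), 6L)
  ppi <- read_ppi_tsv(file.path(d, "ppi.tsv"))
  expect_equal(nrow(ppi), nrow(syn$ppi))
})
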