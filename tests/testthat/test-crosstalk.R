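fake_profile <- function(df) {
  out <- tibble::tibble(
    subset_id = "t", layer = "x",
    S = df$S, R = df$R, count = df$count,
    null_mean = df[["null_mean"]] %||% rep(0, nrow(df)),
    null_sd = df[["null_sd"]] %||% rep(1, nrow(df)),
    z = df$z, p_emp = df$p_emp,
    sigma_zero = (df[["null_sd"]] %||% rep(1, nrow(df))) == 0
  )
  out$significant <- out$R != 0 & !is.na(out$z) & out$z > 0 & out$p_emp <= 0.05
  out
}

test_that("exclusive node sets partition a pathway pair", {
  memb <- list(A = c("1", "2", "3"), B = c("3", "4"), C = c("9"))
  ex <- exclusive_nodes("A", "B", memb)
  expect_setequal(ex$exA, c("1", "2"))
  expect_setequal(ex$exB, "4")
  expect_setequal(ex$common, "3")
  expect_setequal(c(ex$exA, ex$exB, ex$common), union(memb$A, memb$B))

  same <- exclusive_nodes("A", "A", memb)
  expect_length(same$exA, 0)
  expect_length(same$exB, 0)
  disj <- exclusive_nodes("A", "C", memb)
  expect_length(disj$common, 0)
  expect_error(exclusive_nodes("A", "nope", memb), "unknown pathway")
})

test_that("between positions cover both orientations and exclude common genes", {
  net <- toy_net()
  pos <- between_positions(net, c("a1", "a2"), c("b1", "b2", "b3"))
  expect_equal(nrow(pos), 2 * 3 * 2)
  # transposed closure
  keys <- crossmux:::pair_key(pos[, 1], pos[, 2], net$n)
  tkeys <- crossmux:::pair_key(pos[, 2], pos[, 1], net$n)
  expect_setequal(keys, tkeys)
  # the common gene c1 appears in no position
  ic <- match("c1", net$genes)
  expect_false(any(pos == ic))
  # empty exclusive set gives zero positions
  expect_equal(nrow(between_positions(net, character(0), "b1")), 0L)
})

test_that("an edge through a common gene contributes nothing to the between profile", {
  # c1 belongs to both pathways and carries the only A-B connections
  edges <- dplyr::bind_rows(
    edge_row("a1", "c1", "activation", pathway = "A"),
    edge_row("c1", "b1", "activation", pathway = "B")
  )
  ref <- refine_signaling(make_multigraph(edges),
                          tibble::tibble(gene_a = character(),
                                         gene_b = character()))
  net <- build_multilayer(ref, tibble::tibble(tf = "a1", target = "c1"),
                          membership = list(A = c("a1", "c1"),
                                            B = c("b1", "c1")))
  ex <- exclusive_nodes("A", "B", net$membership)
  pos <- between_positions(net, ex$exA, ex$exB)
  cnt <- count_multilinks(net$layers$activation, net$layers$GRN, s = 1,
                          restrict_pairs = pos)
  expect_true(all(cnt$count == 0))
})

test_that("shortest-path subsets follow the intermediary-node and threshold rules", {
  edges <- dplyr::bind_rows(
    edge_row("a", "x", "activation", pathway = "A"),
    edge_row("x", "b", "activation", pathway = "B"),
    edge_row("a", "m", "activation", pathway = "A"),
    edge_row("m", "b", "activation", pathway = "B"),
    edge_row("a", "p", "activation", pathway = "A"),
    edge_row("p", "q", "activation", pathway = "A"),
    edge_row("q", "b2", "activation", pathway = "B")
  )
  ref <- refine_signaling(make_multigraph(edges),
                          tibble::tibble(gene_a = character(),
                                         gene_b = character()))
  net <- build_multilayer(
    ref, tibble::tibble(tf = "a", target = "x"),
    membership = list(A = "a", B = c("b", "m", "b2"))
  )
  gi <- function(g) match(g, net$genes)

  sp1 <- shortest_positions(net, "a", c("b", "b2"), "a", c("b", "m", "b2"),
                            sp_threshold = 1)
  # a->x->b retained (x intermediary); a->m->b discarded (m in pathway B);
  # a->p->q->b2 too long for sp = 1
  expect_setequal(sp1$intermediaries, "x")
  got <- paste(sp1$positions[, 1], sp1$positions[, 2])
  want <- c(paste(gi("a"), gi("x")), paste(gi("x"), gi("a")),
            paste(gi("x"), gi("b")), paste(gi("b"), gi("x")))
  expect_setequal(got, want)

  # sp = 2 admits the two-intermediary path
  sp2 <- shortest_positions(net, "a", c("b", "b2"), "a", c("b", "m", "b2"),
                            sp_threshold = 2)
  expect_setequal(sp2$intermediaries, c("x", "p", "q"))
  expect_true(all(got %in% paste(sp2$positions[, 1], sp2$positions[, 2])))
})

test_that("shortest-path subsets are monotone in the threshold", {
  syn <- gen_multilayer(small_spec(n_genes = 80, n_pathways = 3,
                                   pathway_size_range = c(10, 14),
                                   ppi_density = 0.03, seed = 11L))
  net <- syn$net
  ids <- names(net$membership)
  for (a in ids) for (b in setdiff(ids, a)) {
    ex <- exclusive_nodes(a, b, net$membership)
    key <- function(sp) {
      p <- shortest_positions(net, ex$exA, ex$exB, net$membership[[a]],
                              net$membership[[b]], sp_threshold = sp)$positions
      if (!nrow(p)) character(0) else paste(p[, 1], p[, 2])
    }
    k1 <- key(1); k2 <- key(2); kn <- key(NULL)
    expect_true(all(k1 %in% k2), info = paste(a, b))
    expect_true(all(k2 %in% kn), info = paste(a, b))
  }
})

test_that("the composite score reproduces hand-computed values", {
  expect_equal(crosstalk_score(2, 0.01, 3, sigma_zero = FALSE),
               2000 - log10(0.011) * 3, tolerance = 1e-12)
  expect_equal(crosstalk_score(2, 0.01, 3, sigma_zero = FALSE),
               2005.875822, tolerance = 1e-6)
  expect_equal(crosstalk_score(0, 0.001, NA_real_, sigma_zero = TRUE),
               -log10(0.002), tolerance = 1e-12)
  expect_equal(crosstalk_score(0, 0.001, NA_real_, sigma_zero = TRUE),
               2.698970, tolerance = 1e-6)
})

test_that("significance uses the boundary p <= 0.05 with z > 0", {
  prof <- fake_profile(tibble::tibble(
    S = c(1, 1, 2, 2), R = c(1, -1, 1, -1), count = c(3, 2, 4, 1),
    z = c(2.0, 1.5, -0.5, 2.5), p_emp = c(0.05, 0.06, 0.01, 0.051)
  ))
  s <- crossmux:::summarize_assessment(prof, alpha = 0.05)
  # only (1, 1) qualifies: p = 0.05 counts, p = 0.06/0.051 and z < 0 do not
  expect_equal(s$n_sig, 1L)
  expect_equal(s$p_best, 0.01)
  expect_equal(s$z_best, 2.5)
})

test_that("assessment takes extrema over (S, +/-1) types and honors sigma-zero", {
  prof <- fake_profile(tibble::tibble(
    S = c(3, 5), R = c(1, 1), count = c(4, 2),
    null_mean = c(0, 1), null_sd = c(0, 1),
    z = c(Inf, 2), p_emp = c(0.001, 0.2)
  ))
  s <- crossmux:::summarize_assessment(prof)
  # best type (lowest p) has a degenerate null -> sigma-zero score branch
  expect_true(s$sigma_zero)
  expect_equal(s$score, crosstalk_score(s$n_sig, 0.001, NA, TRUE))
  # the finite z maximum is still reported
  expect_equal(s$z_best, 2)

  none <- fake_profile(tibble::tibble(S = c(1, 0), R = c(1, 1),
                                      count = c(0, 0), z = c(NA, NA),
                                      p_emp = c(1, 1)))
  expect_false(crossmux:::summarize_assessment(none)$detected)
})

test_that("ranking is score-descending with deterministic ties, undetected last", {
  res <- tibble::tibble(
    pathway_a = c("P1", "P2", "P3", "P2", "P1"),
    pathway_b = c("P2", "P3", "P1", "P1", "P3"),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    score = c(2005.9, 3.1, 1001.2, 3.1, NA),
    n_sig = c(2L, 0L, 1L, 0L, 0L)
  )
  class(res) <- c("mux_crosstalk", class(res))
  ranked <- rank_pairs(res)
  expect_equal(paste(ranked$pathway_a, ranked$pathway_b)[1:4],
               c("P1 P2", "P3 P1", "P2 P1", "P2 P3"))
  expect_true(is.na(ranked$rank[5]))
  expect_equal(ranked$rank[1:4], 1:4)
})

test_that("higher n_sig dominates the score whenever |log-p * z| < 1000", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n1 <- sample(1:20, 1); n2 <- sample(0:(n1 - 1), 1)
      p1 <- runif(1); p2 <- runif(1)
      z1 <- runif(1, 0, 332); z2 <- runif(1, 0, 332)
      expect_gt(crosstalk_score(n1, p1, z1), crosstalk_score(n2, p2, z2))
    }
  })
})

test_that("end-to-end inference detects a planted pair and reports clean mediators", {
  syn <- gen_multilayer(synth_spec(seed = 101L))
  pl <- plant_crosstalk(syn, c("pw02", "pw04"), mode = "between",
                        n_planted = 10, multilink_type = c(9L, 1L),
                        seed = 101L)
  net <- pl$synth$net
  ens <- build_ensemble(net, n_instances = 10, Q = 10, master_seed = 101L)
  res <- infer_crosstalk(net, ens, method = "between", n_rand = 100)
  top <- res[res$rank == 1 & !is.na(res$rank), ]
  expect_equal(c(top$pathway_a, top$pathway_b), c("pw02", "pw04"))
  expect_gte(top$n_sig, 1L)

  # exclusion soundness: no mediator touches a gene common to the pair
  common <- exclusive_nodes("pw02", "pw04", net$membership)$common
  med <- top$mediators[[1]]
  expect_gt(nrow(med), 0)
  expect_false(any(med$source %in% common | med$target %in% common))
  # mediator positions lie between the exclusive sets
  ex <- exclusive_nodes("pw02", "pw04", net$membership)
  expect_true(all((med$source %in% ex$exA & med$target %in% ex$exB) |
                    (med$source %in% ex$exB & med$target %in% ex$exA)))
})

test_that("leave-one-layer-out removes evidence of the left-out layer only", {
  base <- tibble::tibble(
    pathway_a = c("A", "B"), pathway_b = c("B", "C"),
    method = "between", sp = NA_integer_,
    detected = TRUE, n_sig = c(1L, 2L),
    p_best = c(0.01, 0.01), z_best = c(3, 3),
    sigma_zero = FALSE, score = NA_real_
  )
  base$score <- crosstalk_score(base$n_sig, base$p_best, base$z_best)
  prof1 <- fake_profile(tibble::tibble(
    S = c(7, 1), R = c(-1, 1), count = c(3, 1),
    z = c(4, 0.2), p_emp = c(0.01, 0.5)
  ))
  prof2 <- fake_profile(tibble::tibble(
    S = c(1, 9), R = c(1, 1), count = c(3, 2),
    z = c(4, 3), p_emp = c(0.01, 0.02)
  ))
  base$sig_types <- list(prof1[prof1$significant, c("S", "R")],
                         prof2[prof2$significant, c("S", "R")])
  base$mediators <- list(NULL, NULL)
  base$profile <- list(prof1, prof2)
  class(base) <- c("mux_crosstalk", class(base))

  # leaving out inhibition (S = 7) silences the first pair's only evidence
  out <- leave_one_layer_out(base, "inhibition")
  a <- out[out$pathway_a == "A", ]
  expect_equal(a$n_sig, 0L)
  # leaving out activation drops the second pair from 2 to 1 significant type
  out2 <- leave_one_layer_out(base, "activation")
  b <- out2[out2$pathway_a == "B", ]
  expect_equal(b$n_sig, 1L)
  # a layer with no significant types anywhere changes nothing
  out3 <- leave_one_layer_out(base, "ubiquitination")
  expect_equal(out3$n_sig[order(out3$pathway_a)], c(1L, 2L))
  expect_error(leave_one_layer_out(base, "ppi"), "PPI layer")
})
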