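test_that("the multilink hash is injective over all 36 types and invertible", {
  grid <- expand.grid(S = 0:11, R = -1:1)
  codes <- encode_multilink(grid$S, grid$R)
  expect_length(unique(codes), 36L)
  dec <- decode_multilink(codes)
  expect_equal(dec$S, grid$S)
  expect_equal(dec$R, grid$R)
  expect_equal(unlist(decode_multilink(encode_multilink(9, -1))),
               c(S = 9, R = -1))
  expect_equal(unlist(decode_multilink(encode_multilink(0, 0))),
               c(S = 0, R = 0))
  expect_error(encode_multilink(12, 0), "out of range")
  expect_error(encode_multilink(3, 2), "out of range")
  expect_error(decode_multilink(36), "out of range")
})

test_that("directed and undirected coincidence patterns count per the conventions", {
  n <- 4
  grn_ab <- make_layer(n, 1, 2, TRUE, "GRN")
  grn_ba <- make_layer(n, 2, 1, TRUE, "GRN")

  # aligned directed pair -> (S, 1)
  act <- make_layer(n, 1, 2, TRUE, "activation")
  expect_equal(count_multilinks(act, grn_ab, s = 1)$count, c(0, 0, 1))
  # opposed directed pair -> (S, -1)
  expect_equal(count_multilinks(act, grn_ba, s = 1)$count, c(1, 0, 0))

  # undirected signaling edge with a regulatory edge: both orientations tally
  bind <- make_layer(n, 1, 2, FALSE, "binding")
  expect_equal(count_multilinks(bind, grn_ab, s = 2)$count, c(1, 0, 1))
  # undirected signaling edge alone: single (S, 0) count, not two
  empty_grn <- make_layer(n, integer(0), integer(0), logical(0), "GRN")
  expect_equal(count_multilinks(bind, empty_grn, s = 2)$count, c(0, 1, 0))

  expect_error(count_multilinks(act, make_layer(9, 1, 2, TRUE, "GRN")),
               "shape mismatch")
})

test_that("zero-signaling counts cover regulatory-only positions once", {
  n <- 4
  grn <- make_layer(n, c(1, 3), c(2, 4), c(TRUE, TRUE), "GRN")
  empty_k <- make_layer(n, integer(0), integer(0), logical(0), "KEGGPPI")
  z <- count_zero_signaling(empty_k, grn)
  expect_equal(z$count[z$R == 1], 2)
  expect_equal(z$count[z$R == 0], 4 * 3 / 2 - 2)

  # a position occupied on the collapsed layer is not a (0, 1) multilink
  k <- make_layer(n, 1, 2, FALSE, "KEGGPPI")
  z2 <- count_zero_signaling(k, grn)
  expect_equal(z2$count[z2$R == 1], 1)

  # spec toy: 2 regulatory-only edges, 1 unrelated undirected signaling edge
  k3 <- make_layer(4, 1, 4, FALSE, "KEGGPPI")
  grn3 <- make_layer(4, c(1, 3), c(2, 4), c(TRUE, TRUE), "GRN")
  z3 <- count_zero_signaling(k3, grn3)
  expect_equal(z3$count[z3$R == 1], 2)
})

test_that("hashed sparse counting equals the dense brute-force oracle", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      m_s <- sample.int(n * (n - 1) / 2, 1)
      m_r <- sample.int(max(1, n), 1)
    })
    S_layer <- random_layer(n, m_s, frac_directed = 0.6, seed = seed * 2 + 1)
    R_layer <- random_layer(n, m_r, frac_directed = 0.9, seed = seed * 2,
                            label = "GRN")
    got <- count_multilinks(S_layer, R_layer, s = 1)
    want <- oracle_counts(as.matrix(S_layer$matrix),
                          as.matrix(R_layer$matrix))
    expect_equal(got$count, unname(want[c("-1", "0", "1")]),
                 info = paste("seed", seed))
    gotz <- count_zero_signaling(S_layer, R_layer)
    wantz <- oracle_zero_counts(as.matrix(S_layer$matrix),
                                as.matrix(R_layer$matrix))
    expect_equal(gotz$count, unname(wantz[c("0", "1")]),
                 info = paste("zero seed", seed))
  }
})

test_that("restricted counting matches the oracle on the sliced positions", {
  for (seed in 1:20) {
    S_layer <- random_layer(8, 12, seed = seed + 500)
    R_layer <- random_layer(8, 6, frac_directed = 1, seed = seed + 900,
                            label = "GRN")
    a <- 1:3; b <- 5:8
    pairs <- rbind(as.matrix(expand.grid(a, b)),
                   as.matrix(expand.grid(b, a)))
    got <- count_multilinks(S_layer, R_layer, s = 1, restrict_pairs = pairs)
    A <- as.matrix(S_layer$matrix); B <- as.matrix(R_layer$matrix)
    mask <- matrix(FALSE, 8, 8)
    mask[pairs] <- TRUE
    A[!(mask | t(mask))] <- 0
    want <- oracle_counts(A, B)
    expect_equal(got$count, unname(want[c("-1", "0", "1")]),
                 info = paste("seed", seed))
  }
})

test_that("z and empirical p follow the tail-by-sign formulas", {
  # mean 10, sd 4 null sample; c_a = 20 gives z = 2.5
  c_r <- c(rep(6, 50), rep(14, 50))
  st <- multilink_stats(20, c_r, 100)
  expect_equal(st$z, (20 - 10) / sd(c_r))
  expect_equal(sd(c_r), sqrt(16 * 100 / 99))

  # exactly 3 of 100 null counts >= c_a with positive z -> p = 0.03
  c_r2 <- c(rep(0, 97), 10, 11, 12)
  st2 <- multilink_stats(10, c_r2, 100)
  expect_gt(st2$z, 0)
  expect_equal(st2$p_emp, 0.03)

  # degenerate null equal to the observation: undefined z, p = 1
  st3 <- multilink_stats(5, rep(5, 100), 100)
  expect_true(st3$sigma_zero)
  expect_true(is.na(st3$z))
  expect_equal(st3$p_emp, 1)

  # degenerate null away from the observation: signed infinite z, matching tail
  st4 <- multilink_stats(7, rep(2, 100), 100)
  expect_identical(st4$z, Inf)
  expect_equal(st4$p_emp, 0)

  expect_error(multilink_stats(1, numeric(0), 0), "n_rand")
})

test_that("z-scores are invariant under count rescaling and p is monotone in c_a", {
  withr::with_seed(33, c_r <- rpois(100, 8))
  z1 <- multilink_stats(15, c_r, 100)$z
  z2 <- multilink_stats(15 * 7, c_r * 7, 100)$z
  expect_equal(z1, z2)

  p_prev <- 1
  for (c_a in sort(unique(c_r[c_r > mean(c_r)]))) {
    p <- multilink_stats(c_a, c_r, 100)$p_emp
    expect_lte(p, p_prev)
    p_prev <- p
  }
})

test_that("profile counts conserve layer edge totals and undirected symmetry", {
  syn <- gen_multilayer(small_spec(n_genes = 80, n_pathways = 3,
                                   pathway_size_range = c(10, 14), seed = 6L))
  net <- syn$net
  ens <- build_ensemble(net, n_instances = 4, Q = 5, master_seed = 5L)
  prof <- profile_subset(net, ens, n_rand = 16)

  # conservation: sum_R counts(S, R) equals the layer's unique edge count
  for (s in 1:11) {
    lab <- crossmux:::layer_labels()[s]
    expect_equal(sum(prof$count[prof$S == s]),
                 nrow(net$layers[[lab]]$edges), info = lab)
  }
  # (0,1) plus regulatory edges overlapping the collapsed layer equals the
  # total unique regulatory positions
  grn_e <- net$layers$GRN$edges
  K <- net$layers$KEGGPPI$matrix
  on_k <- sum(K[cbind(grn_e$from, grn_e$to)] != 0 |
                K[cbind(grn_e$to, grn_e$from)] != 0)
  expect_equal(prof$count[prof$S == 0 & prof$R == 1] + on_k, nrow(grn_e))

  # a layer of only undirected edges has exactly equal (S, +1) and (S, -1)
  bind <- net$layers$binding_association
  und_only <- make_layer(net$n, bind$edges$from[!bind$edges$directed],
                         bind$edges$to[!bind$edges$directed],
                         rep(FALSE, sum(!bind$edges$directed)), "und")
  cnt <- count_multilinks(und_only, net$layers$GRN, s = 2)
  expect_equal(cnt$count[cnt$R == 1], cnt$count[cnt$R == -1])
})

test_that("a planted over-representation is flagged significant in the profile", {
  syn <- gen_multilayer(synth_spec(seed = 14L))
  pl <- plant_crosstalk(syn, c("pw01", "pw02"), mode = "between",
                        n_planted = 10, multilink_type = c(9L, 1L),
                        seed = 14L)
  net <- pl$synth$net
  ens <- build_ensemble(net, n_instances = 10, Q = 10, master_seed = 14L)
  ex <- exclusive_nodes("pw01", "pw02", net$membership)
  pos <- between_positions(net, ex$exA, ex$exB)
  prof <- profile_subset(net, ens, restrict_pairs = pos,
                         subset_id = "between:pw01->pw02", n_rand = 100)
  row <- prof[prof$S == 9 & prof$R == 1, ]
  expect_gte(row$count, 10)
  expect_true(row$z > 0)
  expect_lte(row$p_emp, 0.05)
  expect_true(row$significant)
})
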