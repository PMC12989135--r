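mini_graph <- function(n = 6L, seed = 2L) {
  set.seed(seed)
  side <- rep(c("ig", "ag"), length.out = n)
  edges <- cbind(seq_len(n - 1L), 2:n)
  g <- toy_graph(n, c(t(edges)), side = side,
                 coords = matrix(rnorm(n * 3, sd = 3), n, 3L))
  g
}

layer_params <- function(params, t = 1L) {
  nms <- names(params)[startsWith(names(params), paste0("l", t, "."))]
  out <- params[nms]
  names(out) <- sub(paste0("l", t, "."), "", nms, fixed = TRUE)
  out
}

test_that("zero-initialised coordinate MLP leaves coordinates unchanged", {
  g <- mini_graph()
  cfg <- small_encoder()
  p <- init_model_params(cfg, "classifier", seed = 1)
  H <- matrix(rnorm(g$n_nodes * cfg$hidden_dim), g$n_nodes)
  out <- egnn_layer(H, g$node_coords, g, layer_params(p))
  expect_equal(out$P, g$node_coords)
  expect_false(isTRUE(all.equal(out$H, H)))
})

test_that("EGNN layer is equivariant and its features invariant", {
  g <- mini_graph()
  cfg <- small_encoder()
  p <- init_model_params(cfg, "classifier", seed = 1)
  lp <- layer_params(p)
  lp$Wx2 <- matrix(rnorm(length(lp$Wx2), sd = 0.3), nrow(lp$Wx2))  # move coords
  H <- matrix(rnorm(g$n_nodes * cfg$hidden_dim), g$n_nodes)
  base <- egnn_layer(H, g$node_coords, g, lp)
  set.seed(8)
  for (k in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 20)
    P2 <- g$node_coords %*% t(R) + matrix(tr, g$n_nodes, 3, byrow = TRUE)
    out <- egnn_layer(H, P2, g, lp)
    expect_lt(max(abs(out$H - base$H)), 1e-5)
    expect_lt(max(abs(out$P - (base$P %*% t(R) +
                               matrix(tr, g$n_nodes, 3, byrow = TRUE)))), 1e-4)
  }
})

test_that("EGNN layer matches a hand-coded scalar oracle on a 2-node graph", {
  # hidden dim 1, edge dim 30; both MLP layers reduce to scalar chains
  cfg <- encoder_config(n_layers = 1L, hidden_dim = 1L, input_dim = 4L,
                        edge_dim = 30L, dropout = 0)
  g <- toy_graph(2L, c(1, 2), side = c("ig", "ag"),
                 coords = matrix(c(0, 0, 0, 1, 2, 2), 2, 3, byrow = TRUE))
  p <- init_model_params(cfg, "classifier", seed = 3)
  lp <- layer_params(p)
  lp$Wx2 <- matrix(0.2); lp$bx2 <- matrix(0.1)
  H <- matrix(c(0.3, -0.5), 2, 1)
  out <- egnn_layer(H, g$node_coords, g, lp)

  silu <- function(x) x / (1 + exp(-x))
  efeat <- g$edge_features[1, ]
  d2 <- sum((g$node_coords[1, ] - g$node_coords[2, ])^2)
  oracle_m <- function(hi, hj) {
    x <- c(hi, hj, d2 / 100, efeat)
    h1 <- silu(sum(x * lp$We1[, 1]) + lp$be1[1])
    silu(h1 * lp$We2[1, 1] + lp$be2[1])
  }
  m12 <- oracle_m(H[1], H[2]); m21 <- oracle_m(H[2], H[1])
  phix <- function(m) (silu(m * lp$Wx1[1, 1] + lp$bx1[1])) * lp$Wx2[1, 1] + lp$bx2[1]
  diff12 <- g$node_coords[1, ] - g$node_coords[2, ]
  p1 <- g$node_coords[1, ] + diff12 / (sqrt(d2) + 1) * phix(m12)
  p2 <- g$node_coords[2, ] - diff12 / (sqrt(d2) + 1) * phix(m21)
  phih <- function(h, m) {
    h1 <- silu(h * lp$Wh1[1, 1] + m * lp$Wh1[2, 1] + lp$bh1[1])
    h1 * lp$Wh2[1, 1] + lp$bh2[1]
  }
  expect_equal(out$H[, 1], c(phih(H[1], m12), phih(H[2], m21)), tolerance = 1e-12)
  expect_equal(out$P, rbind(p1, p2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GRU gate algebra: zero params halve, saturated z passes through", {
  h <- 4L; n <- 3L
  zero <- list(Wgi = matrix(0, 2 * h, 3 * h), bgi = matrix(0, 1, 3 * h),
               Wgh = matrix(0, h, 3 * h), bgh = matrix(0, 1, 3 * h))
  Ht <- matrix(rnorm(n * h), n)
  Hp <- matrix(rnorm(n * h), n)
  expect_equal(gru_gate(Ht, Hp, zero), 0.5 * Hp, tolerance = 1e-12)

  sat <- zero
  sat$bgi[1, (h + 1):(2 * h)] <- 50  # drive update gate z to 1
  expect_equal(gru_gate(Ht, Hp, sat), Hp, tolerance = 1e-9)
})

test_that("GRU gate matches hand-evaluated cell equations", {
  h <- 2L
  set.seed(5)
  lp <- list(Wgi = matrix(rnorm(4 * 3 * h, sd = 0.3), 4),
             bgi = matrix(rnorm(3 * h, sd = 0.1), 1),
             Wgh = matrix(rnorm(2 * 3 * h, sd = 0.3), 2),
             bgh = matrix(rnorm(3 * h, sd = 0.1), 1))
  Ht <- matrix(c(0.2, -0.4), 1)
  Hp <- matrix(c(0.7, 0.1), 1)
  out <- gru_gate(Ht, Hp, lp)

  sig <- function(x) 1 / (1 + exp(-x))
  x <- c(Ht[1, ], Hp[1, ])
  gi <- drop(x %*% lp$Wgi) + lp$bgi[1, ]
  gh <- drop(Hp[1, ] %*% lp$Wgh) + lp$bgh[1, ]
  r <- sig(gi[1:2] + gh[1:2])
  z <- sig(gi[3:4] + gh[3:4])
  nn <- tanh(gi[5:6] + r * gh[5:6])
  expect_equal(out[1, ], (1 - z) * nn + z * Hp[1, ], tolerance = 1e-12)
})

test_that("encode with an empty stack returns the projected inputs", {
  g <- mini_graph()
  cfg <- encoder_config(n_layers = 0L, hidden_dim = 16L, input_dim = 320L)
  p <- init_model_params(cfg, "classifier", seed = 2)
  enc <- encode(g, p)
  silu <- function(x) x / (1 + exp(-x))
  H0 <- silu(g$node_features %*% p$Win +
               matrix(p$bin, g$n_nodes, 16, byrow = TRUE))
  expect_equal(enc$H, H0, tolerance = 1e-12)
  expect_equal(enc$P, g$node_coords)
})

test_that("encode is deterministic and dx mismatches error", {
  g <- mini_graph()
  cfg <- small_encoder()
  p <- init_model_params(cfg, "classifier", seed = 7)
  e1 <- encode(g, p); e2 <- encode(g, p)
  expect_identical(e1, e2)
  bad <- g; bad$node_features <- bad$node_features[, 1:10]
  ns <- asNamespace("abpose")
  tape <- ns$tape_new()
  expect_error(ns$tape_forward_graph(tape, ns$params_to_tape(tape, p), bad, cfg),
               "input_dim")
})

test_that("pooling strategies select the documented node sets", {
  n <- 10L
  side <- c(rep("ig", 5), rep("ag", 5))
  # 3 interface nodes: inter edges 1-6 (cdr) and 2-6; CDR nodes 1 and 4
  g <- toy_graph(n, c(1, 6, 2, 6, 2, 3, 7, 8), side = side,
                 is_cdr = c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 6)))
  expect_equal(select_pool_set(g, "all_nodes"), 1:10)
  expect_equal(select_pool_set(g, "interface_only"), c(1L, 2L, 6L))
  expect_equal(select_pool_set(g, "without_interface"), c(3:5, 7:10))
  expect_equal(select_pool_set(g, "cdr_only"), c(1L, 4L))
  expect_equal(select_pool_set(g, "without_cdr"),
               setdiff(1:10, select_pool_set(g, "cdr_only")))
  expect_equal(select_pool_set(g, "cdr_epitope_only"), c(1L, 6L))
  expect_equal(select_pool_set(g, "without_cdr_epitope"), setdiff(1:10, c(1L, 6L)))

  g_nocdr <- toy_graph(4, c(1, 3), side = c("ig", "ig", "ag", "ag"))
  expect_error(select_pool_set(g_nocdr, "cdr_only"), "all_nodes")
})

test_that("weighted pooling is a gated sum, invariant to node order", {
  h <- 3L
  H <- matrix(c(1, 2, 3, -1, 0.5, 2, 0, 1, -2), 3, h, byrow = TRUE)
  params <- list(wp = matrix(0, h, 1), bp = matrix(0, 1, 1))
  expect_equal(pool_weighted(H[1, , drop = FALSE], 1L, params), 0.5 * H[1, ])

  set.seed(3)
  params2 <- list(wp = matrix(rnorm(h), h, 1), bp = matrix(0.2, 1, 1))
  g1 <- pool_weighted(H, 1:3, params2)
  g2 <- pool_weighted(H[c(3, 1, 2), ], 1:3, params2)
  expect_equal(g1, g2, tolerance = 1e-12)
  # hand computation
  w <- 1 / (1 + exp(-(H %*% params2$wp + 0.2)))
  expect_equal(g1, colSums(H * drop(w)), tolerance = 1e-12)
  expect_error(pool_weighted(H, integer(0), params2), "empty")
})

test_that("classifier head computes a softmax over two classes", {
  h <- 4L
  zero <- list(Wc1 = matrix(0, h, h), bc1 = matrix(0, 1, h),
               Wc2 = matrix(0, h, 2), bc2 = matrix(0, 1, 2))
  out <- classify_head(rnorm(h), zero)
  expect_equal(unname(out$probs), c(0.5, 0.5))

  set.seed(4)
  p <- list(Wc1 = matrix(rnorm(h * h, sd = 0.5), h),
            bc1 = matrix(rnorm(h, sd = 0.1), 1),
            Wc2 = matrix(rnorm(h * 2, sd = 0.5), h),
            bc2 = matrix(rnorm(2, sd = 0.1), 1))
  gv <- rnorm(h)
  out2 <- classify_head(gv, p)
  expect_equal(sum(out2$probs), 1, tolerance = 1e-7)
  silu <- function(x) x / (1 + exp(-x))
  hid <- silu(drop(gv %*% p$Wc1) + p$bc1[1, ])
  logits <- drop(hid %*% p$Wc2) + p$bc2[1, ]
  expect_equal(unname(out2$probs), exp(logits) / sum(exp(logits)),
               tolerance = 1e-12)
  # node-type head is a linear map on node features
  H <- matrix(rnorm(3 * h), 3)
  p$Wnt <- matrix(rnorm(h * 3, sd = 0.3), h)
  p$bnt <- matrix(0.1, 1, 3)
  out3 <- classify_head(gv, p, H = H)
  expect_equal(out3$node_type_logits,
               H %*% p$Wnt + matrix(0.1, 3, 3), tolerance = 1e-12)
})

test_that("scaled-tanh score head is bounded, monotone and exact", {
  params <- list(Wr = matrix(1, 1, 1), br = matrix(0, 1, 1))
  expect_equal(score_head(0, params), 0.5)
  expect_equal(score_head(2, params), 0.5 * (tanh(1) + 1), tolerance = 1e-12)
  expect_equal(round(score_head(2, params), 5), 0.88080)
  zs <- seq(-30, 30, by = 0.5)
  ys <- vapply(zs, score_head, numeric(1), params = params)
  expect_true(all(diff(ys) >= 0))
  expect_true(all(ys > 0 & ys < 1))
})

test_that("ensemble combination is a checked convex combination", {
  expect_equal(ensemble_combine(c(1, 0), c(0.7, 0.3)), 0.7)
  expect_equal(ensemble_combine(rep(0.42, 4), rep(0.25, 4)), 0.42)
  p <- c(0.2, 0.6, 0.9, 0.1)
  expect_equal(ensemble_combine(p, rep(0.25, 4)), mean(p))
  expect_error(ensemble_combine(c(1, 0), c(0.7, 0.2)), "sum to 1")
  expect_error(ensemble_combine(c(1, 0), c(1.2, -0.2)), "non-negative")
  expect_error(ensemble_combine(c(1, 0, 0), c(0.5, 0.5)), "length")
  # matrix form combines row-wise across models
  M <- rbind(c(1, 0.5), c(0, 0.5))
  expect_equal(ensemble_combine(M, c(0.7, 0.3)), c(0.7, 0.5))
})

test_that("graph-level outputs are invariant to rigid motion and permutation", {
  b <- small_bench()
  g <- b[[1]]$graph
  cfg <- small_encoder()
  ns <- asNamespace("abpose")
  p <- init_model_params(cfg, "both", seed = 10)
  fwd <- function(gg) {
    tape <- ns$tape_new()
    pn <- ns$params_to_tape(tape, p)
    out <- ns$tape_forward_graph(tape, pn, gg, cfg, head = "classifier")
    c(out$p_pos$val[1], ns$tape_score_head(tape, out$g, pn)$val[1])
  }
  base <- fwd(g)
  set.seed(12)
  for (k in 1:5) {
    gm <- rigid_transform_graph(g, random_rotation(), rnorm(3, sd = 30))
    expect_lt(max(abs(fwd(gm) - base)), 1e-5)
  }
  for (k in 1:3) {
    gp <- permute_graph(g, sample(g$n_nodes))
    expect_lt(max(abs(fwd(gp) - base)), 1e-6)
  }
})

test_that("inference is deterministic with dropout active only in training", {
  b <- small_bench()
  g <- b[[1]]$graph
  cfg <- small_encoder()  # dropout 0.1
  p <- init_model_params(cfg, "classifier", seed = 11)
  ns <- asNamespace("abpose")
  s1 <- ns$model_forward_scores(p, list(g), "classifier", cfg)
  s2 <- ns$model_forward_scores(p, list(g), "classifier", cfg)
  expect_identical(s1, s2)
  # training-mode forward consumes RNG for the dropout mask
  set.seed(1)
  tape <- ns$tape_new()
  t1 <- ns$tape_forward_graph(tape, ns$params_to_tape(tape, p), g, cfg,
                              head = "classifier", training = TRUE)$p_pos$val[1]
  set.seed(2)
  tape <- ns$tape_new()
  t2 <- ns$tape_forward_graph(tape, ns$params_to_tape(tape, p), g, cfg,
                              head = "classifier", training = TRUE)$p_pos$val[1]
  expect_false(identical(t1, t2))
})
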