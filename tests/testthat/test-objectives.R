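test_that("pearson correlation matches the longhand formula and sentinels", {
  expect_equal(pearson_corr(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  a <- c(0.2, 0.7, 0.4, 0.9)
  expect_equal(pearson_corr(a, -a + 3), -1)
  a <- c(1, 2, 3, 5); b <- c(2, 1, 4, 6)
  ac <- a - mean(a); bc <- b - mean(b)
  longhand <- sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  expect_equal(pearson_corr(a, b), longhand)
  expect_equal(pearson_corr(a, b), cor(a, b))
  expect_true(is.na(pearson_corr(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_corr(1, 2), "length")
})

test_that("listwise ranking loss attains its entropy bound and shift invariance", {
  y <- c(0.9, 0.2, 0.5, 0.05)
  ent <- function(v) { p <- exp(v) / sum(exp(v)); -sum(p * log(p)) }
  expect_equal(listwise_rank_loss(y, y), ent(y), tolerance = 1e-12)
  expect_equal(listwise_rank_loss(y, y + 3.7), listwise_rank_loss(y, y),
               tolerance = 1e-12)
  # any other prediction is no better than the bound
  set.seed(2)
  for (k in 1:20) {
    expect_gte(listwise_rank_loss(y, rnorm(4)), ent(y) - 1e-12)
  }
  # 2-item closed form evaluated longhand
  yt <- c(1, 0); yp <- c(0, 1)
  pt <- exp(yt) / sum(exp(yt))
  lp <- yp - log(sum(exp(yp)))
  expect_equal(listwise_rank_loss(yt, yp), -sum(pt * lp), tolerance = 1e-12)
  # groups: mean over per-group losses
  y2 <- c(0.9, 0.1, 0.8, 0.3)
  p2 <- c(0.7, 0.2, 0.4, 0.5)
  gl <- c("a", "a", "b", "b")
  expect_equal(listwise_rank_loss(y2, p2, gl),
               mean(c(listwise_rank_loss(y2[1:2], p2[1:2]),
                      listwise_rank_loss(y2[3:4], p2[3:4]))))
  expect_warning(listwise_rank_loss(c(1, 0, 1), c(1, 0, 1), c("a", "a", "b")),
                 "singleton")
  expect_error(listwise_rank_loss(c(1, 2), c(1, 2), c("a", "b")), "single item")
})

test_that("classifier loss composes its three terms with alpha and beta", {
  w <- loss_weights()  # alpha 1e-3, beta 2e-3
  # perfect graph predictions, uniform node predictions, constant dockq
  outputs <- list(p_pos = c(1, 0, 1),
                  node_type_probs = list(matrix(1 / 3, 2, 3),
                                         matrix(1 / 3, 4, 3),
                                         matrix(1 / 3, 3, 3)))
  batch <- list(y = c(1, 0, 1), node_types = list(c(1L, 2L), c(1L, 1L, 2L, 3L),
                                                  c(2L, 2L, 3L)),
                dockq = c(1, 1, 1))  # constant -> correlation skipped
  L <- classifier_loss(outputs, batch, w)
  expect_equal(L$l_gc, 0, tolerance = 1e-9)
  expect_equal(L$l_nc, log(3), tolerance = 1e-12)
  expect_equal(L$l_mdn, 0)
  expect_equal(L$total, w$alpha * log(3), tolerance = 1e-9)

  # rank-aligned probabilities: correlation term contributes exactly -beta
  outputs2 <- list(p_pos = c(0.9, 0.1, 0.6), node_type_probs = NULL)
  batch2 <- list(y = c(1, 0, 1), dockq = c(0.95, 0.05, 0.6))
  L2 <- classifier_loss(outputs2, batch2, w)
  expect_equal(L2$l_mdn, -pearson_corr(outputs2$p_pos, batch2$dockq))
  expect_lt(abs(L2$l_mdn + 1), 0.05)

  # 4-example batch: total equals the longhand sum
  p <- c(0.8, 0.3, 0.6, 0.1)
  y <- c(1, 0, 1, 0)
  dq <- c(0.9, 0.4, 0.85, 0.1)
  ntp <- list(matrix(c(0.7, 0.2, 0.1), 1, 3, byrow = TRUE),
              matrix(c(0.1, 0.8, 0.1), 1, 3, byrow = TRUE),
              matrix(c(0.3, 0.3, 0.4), 1, 3, byrow = TRUE),
              matrix(c(0.5, 0.25, 0.25), 1, 3, byrow = TRUE))
  ntt <- list(1L, 2L, 3L, 1L)
  L3 <- classifier_loss(list(p_pos = p, node_type_probs = ntp),
                        list(y = y, node_types = ntt, dockq = dq), w)
  gc_hand <- mean(-log(c(0.8, 0.7, 0.6, 0.9)))
  nc_hand <- mean(-log(c(0.7, 0.8, 0.4, 0.5)))
  mdn_hand <- -pearson_corr(p, dq)
  expect_equal(L3$total, gc_hand + 1e-3 * nc_hand + 2e-3 * mdn_hand,
               tolerance = 1e-12)
  expect_error(classifier_loss(list(p_pos = p), list(y = y)), "dockq")
})

test_that("regressor loss couples correlation and ranking terms", {
  y <- c(0.9, 0.2, 0.5, 0.05)
  ent <- function(v) { p <- exp(v) / sum(exp(v)); -sum(p * log(p)) }
  L <- regressor_loss(y, y)
  expect_equal(L$l_coeff, -1)
  expect_equal(L$l_rank, ent(y), tolerance = 1e-12)
  expect_equal(L$total, -1 + ent(y), tolerance = 1e-12)

  # affine increasing transform keeps the correlation at 1
  L2 <- regressor_loss(2.5 * y + 0.3, y)
  expect_equal(L2$l_coeff, -1, tolerance = 1e-12)

  # two groups, longhand
  yp <- c(0.7, 0.2, 0.4, 0.5); yt <- c(0.9, 0.1, 0.8, 0.3)
  gl <- c("a", "a", "b", "b")
  L3 <- regressor_loss(yp, yt, gl)
  expect_equal(L3$total,
               -pearson_corr(yt, yp) + listwise_rank_loss(yt, yp, gl),
               tolerance = 1e-12)
})

test_that("losses are invariant to example order within a batch", {
  set.seed(6)
  p <- runif(6); y <- rep(c(1L, 0L), 3); dq <- runif(6)
  perm <- sample(6)
  L1 <- classifier_loss(list(p_pos = p), list(y = y, dockq = dq))
  L2 <- classifier_loss(list(p_pos = p[perm]), list(y = y[perm], dockq = dq[perm]))
  expect_equal(L1$total, L2$total, tolerance = 1e-12)
  R1 <- regressor_loss(p, dq)
  R2 <- regressor_loss(p[perm], dq[perm])
  expect_equal(R1$total, R2$total, tolerance = 1e-12)
})

test_that("tape losses agree with the numeric implementations", {
  ns <- asNamespace("abpose")
  b <- small_bench()
  cfg <- small_encoder()
  p <- init_model_params(cfg, "both", seed = 21)
  idx <- c(1, 4, 7)
  graphs <- lapply(b[idx], `[[`, "graph")
  y <- vapply(b[idx], `[[`, integer(1), "label")
  dq <- vapply(b[idx], `[[`, numeric(1), "dockq")
  nts <- lapply(graphs, ns$node_type_ints)

  tape <- ns$tape_new()
  pn <- ns$params_to_tape(tape, p)
  outs <- lapply(graphs, function(g) {
    ns$tape_forward_graph(tape, pn, g, cfg, head = "classifier")
  })
  L <- ns$tape_classifier_loss(tape, outs, y, nts, dq, loss_weights())
  # numeric recomputation from the same forward values
  p_pos <- vapply(outs, function(o) o$p_pos$val[1], numeric(1))
  ntp <- lapply(outs, function(o) {
    z <- o$node_type_logits$val
    t(apply(z, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  })
  Lnum <- classifier_loss(list(p_pos = p_pos, node_type_probs = ntp),
                          list(y = y, node_types = nts, dockq = dq))
  expect_equal(L$total$val[1], Lnum$total, tolerance = 1e-10)

  tape2 <- ns$tape_new()
  pn2 <- ns$params_to_tape(tape2, p)
  yr <- lapply(graphs, function(g) {
    ns$tape_forward_graph(tape2, pn2, g, cfg, head = "regressor")$yr
  })
  R <- ns$tape_regressor_loss(tape2, yr, dq)
  yrv <- vapply(yr, function(o) o$val[1], numeric(1))
  Rnum <- regressor_loss(yrv, dq)
  expect_equal(R$total$val[1], Rnum$total, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a toy batch", {
  ns <- asNamespace("abpose")
  cfg <- encoder_config(n_layers = 1L, hidden_dim = 6L, input_dim = 320L,
                        edge_dim = 30L, dropout = 0)
  b <- small_bench()
  graphs <- lapply(b[c(2, 5, 9)], `[[`, "graph")
  y <- vapply(b[c(2, 5, 9)], `[[`, integer(1), "label")
  dq <- vapply(b[c(2, 5, 9)], `[[`, numeric(1), "dockq")
  nts <- lapply(graphs, ns$node_type_ints)
  p <- init_model_params(cfg, "both", seed = 31)

  loss_of <- function(pp, task) {
    tape <- ns$tape_new()
    pn <- ns$params_to_tape(tape, pp)
    if (task == "classifier") {
      outs <- lapply(graphs, function(g) {
        ns$tape_forward_graph(tape, pn, g, cfg, head = "classifier")
      })
      L <- ns$tape_classifier_loss(tape, outs, y, nts, dq, loss_weights())
    } else {
      yr <- lapply(graphs, function(g) {
        ns$tape_forward_graph(tape, pn, g, cfg, head = "regressor")$yr
      })
      L <- ns$tape_regressor_loss(tape, yr, dq)
    }
    list(tape = tape, pn = pn, L = L)
  }
  set.seed(41)
  for (task in c("classifier", "regressor")) {
    r <- loss_of(p, task)
    ns$tape_backward(r$tape, r$L$total)
    gr <- ns$tape_param_grads(r$pn)
    for (nm in sample(names(p), 10)) {
      k <- sample(length(p[[nm]]), 1)
      eps <- 1e-5
      p1 <- p; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] - eps
      fd <- (loss_of(p1, task)$L$total$val[1] -
               loss_of(p2, task)$L$total$val[1]) / (2 * eps)
      an <- gr[[nm]][k]
      denom <- max(abs(fd) + abs(an), 1e-4)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("minimising the regression loss drives the correlation to one", {
  # linearly scorable toy: y = sigmoid-ish function of a scalar feature
  set.seed(9)
  x <- seq(-2, 2, length.out = 12)
  y_true <- (x - min(x)) / diff(range(x))
  w <- 0.01; b <- 0  # scalar "model": y_pred = w*x + b
  lr <- 0.05
  for (it in 1:400) {
    eps <- 1e-5
    f <- function(w, b) regressor_loss(w * x + b, y_true)$total
    gw <- (f(w + eps, b) - f(w - eps, b)) / (2 * eps)
    gb <- (f(w, b + eps) - f(w, b - eps)) / (2 * eps)
    w <- w - lr * gw; b <- b - lr * gb
  }
  expect_gt(pearson_corr(y_true, w * x + b), 0.999)
})
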