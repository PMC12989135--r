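#' Encoder configuration
#'
#' Architecture hyper-parameters of the pose-scoring network: an input
#' projection, `n_layers` E(n)-equivariant message-passing layers each
#' followed by a GRU gate, a selective sigmoid-weighted pooling readout, and
#' task heads (two-layer softmax classifier, or scaled-tanh regressor).
#'
#' @param n_layers number of EGNN+GRU blocks (default 4).
#' @param hidden_dim hidden width h (default 64).
#' @param input_dim node feature width dx (default 320).
#' @param edge_dim edge feature width de (default 30 = 3 distances x 10 RBF
#'   scales).
#' @param dropout dropout fraction between the classifier MLP layers
#'   (default 0.1; training only).
#' @param pooling_strategy one of `"all_nodes"`, `"interface_only"`,
#'   `"cdr_epitope_only"`, `"cdr_only"`, `"without_interface"`,
#'   `"without_cdr_epitope"`, `"without_cdr"`.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 4L, hidden_dim = 64L, input_dim = 320L,
                           edge_dim = 30L, dropout = 0.1,
                           pooling_strategy = "all_nodes") {
  stopifnot(n_layers >= 0L, hidden_dim >= 1L, dropout >= 0, dropout < 1)
  pooling_strategy <- match.arg(pooling_strategy, POOLING_STRATEGIES)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 input_dim = as.integer(input_dim),
                 edge_dim = as.integer(edge_dim),
                 dropout = dropout,
                 pooling_strategy = pooling_strategy),
            class = "encoder_config")
}

POOLING_STRATEGIES <- c("all_nodes", "interface_only", "cdr_epitope_only",
                        "cdr_only", "without_interface",
                        "without_cdr_epitope", "without_cdr")

NODE_TYPE_LEVELS <- c("antigen", "heavy", "light")

## ---- parameters ----

uinit <- function(nr, nc, fan_in = nr) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -b, b), nr, nc)
}

#' Initialise model parameters
#'
#' Uniform fan-in initialisation throughout; the final layer of the
#' coordinate MLP is zero-initialised so coordinates start unchanged
#' (a standard stability choice for equivariant message passing).
#'
#' @param config an [encoder_config()].
#' @param task `"classifier"`, `"regressor"`, or `"both"` (attach both
#'   heads).
#' @param seed integer seed for the initial draw.
#' @return Named list of parameter matrices, class `abpose_params`, with the
#'   config attached as an attribute.
#' @export
init_model_params <- function(config = encoder_config(),
                              task = c("classifier", "regressor", "both"),
                              seed = 1L) {
  task <- match.arg(task)
  h <- config$hidden_dim; dx <- config$input_dim; de <- config$edge_dim
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  p <- list(Win = uinit(dx, h), bin = matrix(0, 1, h))
  for (t in seq_len(config$n_layers)) {
    pref <- paste0("l", t, ".")
    din <- 2L * h + 1L + de
    lp <- list(
      We1 = uinit(din, h), be1 = matrix(0, 1, h),
      We2 = uinit(h, h), be2 = matrix(0, 1, h),
      Wx1 = uinit(h, h), bx1 = matrix(0, 1, h),
      Wx2 = matrix(0, h, 1), bx2 = matrix(0, 1, 1),
      Wh1 = uinit(2L * h, h), bh1 = matrix(0, 1, h),
      Wh2 = uinit(h, h), bh2 = matrix(0, 1, h),
      # update-gate bias (+2) biases z toward the identity path at init,
      # countering depth-wise feature contraction (cf. LSTM forget bias)
      Wgi = uinit(2L * h, 3L * h),
      bgi = matrix(rep(c(0, 2, 0), each = h), 1, 3L * h),
      Wgh = uinit(h, 3L * h), bgh = matrix(0, 1, 3L * h)
    )
    names(lp) <- paste0(pref, names(lp))
    p <- c(p, lp)
  }
  p <- c(p, list(wp = uinit(h, 1), bp = matrix(0, 1, 1),
                 Wnt = uinit(h, 3), bnt = matrix(0, 1, 3)))
  if (task %in% c("classifier", "both")) {
    p <- c(p, list(Wc1 = uinit(h, h), bc1 = matrix(0, 1, h),
                   Wc2 = uinit(h, 2), bc2 = matrix(0, 1, 2)))
  }
  if (task %in% c("regressor", "both")) {
    p <- c(p, list(Wr = uinit(h, 1), br = matrix(0, 1, 1)))
  }
  structure(p, class = "abpose_params", config = config)
}

params_config <- function(params) attr(params, "config")

params_to_tape <- function(tape, params) {
  out <- lapply(names(params), function(nm) tp_param(tape, params[[nm]], nm))
  names(out) <- names(params)
  out
}

## ---- tape-level building blocks ----

# One EGNN layer on the tape. `lp` is the named sub-list of layer param
# nodes (unprefixed names), `dirs` the directed edge arrays.
tape_egnn_layer <- function(tape, H, P, lp, dirs, n_nodes) {
  src <- dirs$src; dst <- dirs$dst
  feat <- tp_const(tape, dirs$feat)
  Hi <- tp_rows(tape, H, src); Hj <- tp_rows(tape, H, dst)
  Pi <- tp_rows(tape, P, src); Pj <- tp_rows(tape, P, dst)
  diff <- tp_sub(tape, Pi, Pj)
  d2 <- tp_rowsums(tape, tp_mul(tape, diff, diff))
  # squared distance enters the edge MLP in units of the 10 A interface
  # cutoff (d^2/100), keeping it on the scale of the other inputs
  m_in <- tp_cbind(tape, Hi, Hj, tp_scale(tape, d2, 0.01), feat)
  m <- tp_linear(tape, tp_linear(tape, m_in, lp$We1, lp$be1, "silu"),
                 lp$We2, lp$be2, "silu")
  xs <- tp_linear(tape, tp_linear(tape, m, lp$Wx1, lp$bx1, "silu"),
                  lp$Wx2, lp$bx2, "none")
  # unit-normalised difference vectors (diff / (d + 1)) stabilise the
  # coordinate update without breaking equivariance
  ones_e <- tp_const(tape, matrix(1, length(src), 1L))
  inv_d <- tp_div(tape, ones_e, tp_add(tape, tp_sqrt(tape, d2), ones_e))
  wdiff <- tp_mul(tape, tp_mul(tape, diff, inv_d), xs)
  agg <- tp_scatter(tape, wdiff, src, n_nodes)
  deg <- tabulate(src, nbins = n_nodes)
  deginv <- tp_const(tape, matrix(ifelse(deg > 0L, 1 / pmax(deg, 1L), 0), ncol = 1))
  Pn <- tp_add(tape, P, tp_mul(tape, agg, deginv))
  msum <- tp_scatter(tape, m, src, n_nodes)
  h_in <- tp_cbind(tape, H, msum)
  Ht <- tp_linear(tape, tp_linear(tape, h_in, lp$Wh1, lp$bh1, "silu"),
                  lp$Wh2, lp$bh2, "none")
  list(H = Ht, P = Pn)
}

# GRU gate: input = [H_tilde | H_prev], hidden state = H_prev.
tape_gru_gate <- function(tape, Ht, Hprev, lp, h) {
  x <- tp_cbind(tape, Ht, Hprev)
  gi <- tp_linear(tape, x, lp$Wgi, lp$bgi, "none")
  gh <- tp_linear(tape, Hprev, lp$Wgh, lp$bgh, "none")
  i1 <- 1:h; i2 <- (h + 1L):(2L * h); i3 <- (2L * h + 1L):(3L * h)
  r <- tp_sigmoid(tape, tp_add(tape, tp_cols(tape, gi, i1), tp_cols(tape, gh, i1)))
  z <- tp_sigmoid(tape, tp_add(tape, tp_cols(tape, gi, i2), tp_cols(tape, gh, i2)))
  nn <- tp_tanh(tape, tp_add(tape, tp_cols(tape, gi, i3),
                             tp_mul(tape, r, tp_cols(tape, gh, i3))))
  ones <- tp_const(tape, matrix(1, nrow(z$val), ncol(z$val)))
  tp_add(tape, tp_mul(tape, nn, tp_sub(tape, ones, z)),
         tp_mul(tape, Hprev, z))
}

tape_encode <- function(tape, pn, g, config) {
  H <- tp_linear(tape, tp_const(tape, g$node_features), pn$Win, pn$bin, "silu")
  P <- tp_const(tape, g$node_coords)
  dirs <- graph_directed(g)
  h <- config$hidden_dim
  for (t in seq_len(config$n_layers)) {
    lp <- layer_nodes(pn, t)
    eg <- tape_egnn_layer(tape, H, P, lp, dirs, g$n_nodes)
    H <- tape_gru_gate(tape, eg$H, H, lp, h)
    P <- eg$P
  }
  list(H = H, P = P)
}

layer_nodes <- function(pn, t) {
  pref <- paste0("l", t, ".")
  nms <- names(pn)[startsWith(names(pn), pref)]
  out <- pn[nms]
  names(out) <- sub(pref, "", nms, fixed = TRUE)
  out
}

tape_pool <- function(tape, H, S, pn) {
  HS <- tp_rows(tape, H, S)
  w <- tp_linear(tape, HS, pn$wp, pn$bp, "sigmoid")
  tp_mm(tape, tp_t(tape, w), HS)
}

tape_classifier_head <- function(tape, gvec, pn, dropout = 0, training = FALSE) {
  hid <- tp_linear(tape, gvec, pn$Wc1, pn$bc1, "silu")
  if (training && dropout > 0) {
    keep <- (runif(ncol(hid$val)) >= dropout) / (1 - dropout)
    hid <- tp_mul(tape, hid, tp_const(tape, matrix(keep, 1L)))
  }
  logits <- tp_linear(tape, hid, pn$Wc2, pn$bc2, "none")
  logp <- tp_logsoftmax(tape, tp_t(tape, logits))  # 2x1: (neg, pos)
  p_pos <- tp_exp(tape, tp_rows(tape, logp, 2L))
  list(logp = logp, p_pos = p_pos)
}

tape_score_head <- function(tape, gvec, pn) {
  z <- tp_linear(tape, gvec, pn$Wr, pn$br, "none")
  th <- tp_tanh(tape, tp_scale(tape, z, 0.5))
  tp_scale(tape, tp_add(tape, th, tp_const(tape, matrix(1, 1, 1))), 0.5)
}

# Full forward pass for one graph on an existing tape.
tape_forward_graph <- function(tape, pn, g, config,
                               head = c("classifier", "regressor", "none"),
                               training = FALSE) {
  head <- match.arg(head)
  if (ncol(g$node_features) != config$input_dim) {
    stop("node feature width ", ncol(g$node_features),
         " does not match encoder input_dim ", config$input_dim)
  }
  enc <- tape_encode(tape, pn, g, config)
  S <- select_pool_set(g, config$pooling_strategy)
  gvec <- tape_pool(tape, enc$H, S, pn)
  nt <- tp_linear(tape, enc$H, pn$Wnt, pn$bnt, "none")
  out <- list(H = enc$H, P = enc$P, g = gvec, node_type_logits = nt)
  if (head == "classifier") {
    out <- c(out, tape_classifier_head(tape, gvec, pn, config$dropout, training))
  } else if (head == "regressor") {
    out$yr <- tape_score_head(tape, gvec, pn)
  }
  out
}

## ---- numeric (user-facing) operations ----

#' One E(n)-equivariant message-passing layer
#'
#' Per directed edge, a message `m_ij = phi_e(h_i, h_j, |p_i - p_j|^2,
#' e_ij)`; coordinates update by `p_i + (1/deg i) * sum_j (p_i - p_j) *
#' phi_x(m_ij)` and features by `phi_h(h_i, sum_j m_ij)`. The MLPs use SiLU
#' activations; messages aggregate by sum, coordinate updates are
#' degree-normalised. Scalar features are rigid-motion invariant and the
#' coordinate update equivariant.
#'
#' @param H `N x h` node feature matrix.
#' @param P `N x 3` node coordinates.
#' @param g the `abpose_graph` supplying edges and edge features.
#' @param params named list of layer parameters (`We1`..`bh2`), e.g. one
#'   layer's slice of [init_model_params()].
#' @return `list(H = updated features, P = updated coordinates)`.
#' @export
egnn_layer <- function(H, P, g, params) {
  if (any(!is.finite(H)) || any(!is.finite(P))) stop("non-finite inputs")
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  eg <- tape_egnn_layer(tape, tp_const(tape, H), tp_const(tape, P),
                        pn, graph_directed(g), nrow(H))
  list(H = eg$H$val, P = eg$P$val)
}

#' GRU gate over node features
#'
#' Standard GRU cell applied per node with input `[h_tilde | h_prev]`
#' (concatenation) and hidden state `h_prev`; output
#' `(1 - z) * n + z * h_prev`. Acts as a learnable gated residual between
#' message-passing layers.
#'
#' @param H_tilde `N x h` candidate features from the EGNN layer.
#' @param H_prev `N x h` previous features (the hidden state).
#' @param params named list with `Wgi`, `bgi`, `Wgh`, `bgh` (reset/update/
#'   candidate gates stacked column-wise).
#' @return `N x h` gated features.
#' @export
gru_gate <- function(H_tilde, H_prev, params) {
  stopifnot(identical(dim(H_tilde), dim(H_prev)))
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  tape_gru_gate(tape, tp_const(tape, H_tilde), tp_const(tape, H_prev),
                pn, ncol(H_prev))$val
}

#' Encode a pose graph
#'
#' SiLU input projection followed by `n_layers` EGNN+GRU blocks.
#'
#' @param g an `abpose_graph`.
#' @param params an `abpose_params` object.
#' @param config an [encoder_config()]; defaults to the one attached to
#'   `params`.
#' @return `list(H = N x h invariant features, P = N x 3 coordinates)`.
#' @export
encode <- function(g, params, config = params_config(params)) {
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  enc <- tape_encode(tape, pn, g, config)
  list(H = enc$H$val, P = enc$P$val)
}

#' Select the pooling node set
#'
#' @param g an `abpose_graph`.
#' @param strategy one of the seven pooling strategies (see
#'   [encoder_config()]).
#' @return Integer vector of node indices.
#' @export
select_pool_set <- function(g, strategy = "all_nodes") {
  strategy <- match.arg(strategy, POOLING_STRATEGIES)
  V <- seq_len(g$n_nodes)
  S <- switch(strategy,
    all_nodes = V,
    interface_only = which(g$is_interface),
    cdr_epitope_only = which(g$is_cdr_epitope),
    cdr_only = which(g$is_cdr),
    without_interface = which(!g$is_interface),
    without_cdr_epitope = which(!g$is_cdr_epitope),
    without_cdr = which(!g$is_cdr)
  )
  if (length(S) == 0L) {
    stop("pooling strategy '", strategy, "' selects no nodes; ",
         "use strategy 'all_nodes' instead")
  }
  S
}

#' Sigmoid-gated weighted-sum pooling
#'
#' `w_i = sigmoid(wp' h_i + bp)` for i in S; `g = sum_i w_i h_i` (a weighted
#' sum, not a mean), invariant to node order.
#'
#' @param H `N x h` node features.
#' @param S node index set.
#' @param params named list with `wp` (h x 1) and `bp` (1 x 1).
#' @return Length-h numeric vector.
#' @export
pool_weighted <- function(H, S, params) {
  if (length(S) == 0L) stop("empty pooling set")
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  drop(tape_pool(tape, tp_const(tape, H), S, pn)$val)
}

#' Classifier head
#'
#' Two-layer MLP with SiLU and softmax over (non-native, native-like);
#' optionally also returns node-type logits from the auxiliary linear node
#' head.
#'
#' @param gvec pooled graph embedding (length-h vector).
#' @param params named list with `Wc1`, `bc1`, `Wc2`, `bc2` (and `Wnt`,
#'   `bnt` when `H` is given).
#' @param H optional `N x h` node features for the node-type head.
#' @return `list(probs = c(p_neg, p_pos), node_type_logits = N x 3 or NULL)`.
#' @export
classify_head <- function(gvec, params, H = NULL) {
  if (any(!is.finite(gvec))) stop("non-finite graph embedding")
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  out <- tape_classifier_head(tape, tp_const(tape, matrix(gvec, 1L)), pn)
  probs <- drop(exp(out$logp$val))
  names(probs) <- c("p_neg", "p_pos")
  ntl <- NULL
  if (!is.null(H)) {
    ntl <- sweep(H %*% params$Wnt, 2L, params$bnt[1L, ], "+")
  }
  list(probs = probs, node_type_logits = ntl)
}

#' Regressor head (scaled tanh)
#'
#' `y_r = (tanh(0.5 z) + 1) / 2` with `z = Wr' g + br`; strictly increasing
#' in z and bounded in (0, 1).
#'
#' @param gvec pooled graph embedding (length-h vector).
#' @param params named list with `Wr` (h x 1) and `br` (1 x 1).
#' @return Scalar in (0, 1).
#' @export
score_head <- function(gvec, params) {
  if (any(!is.finite(gvec))) stop("non-finite graph embedding")
  z <- drop(matrix(gvec, 1L) %*% params$Wr + params$br[1L])
  0.5 * (tanh(0.5 * z) + 1)
}

#' Weighted ensemble of predictions
#'
#' `y* = sum_m w_m y_m` over M model/checkpoint predictions with
#' non-negative weights summing to one.
#'
#' @param preds numeric vector (or M x k matrix, combined row-wise) of
#'   per-model predictions.
#' @param weights non-negative weights of the same length M, summing to 1
#'   within 1e-8.
#' @return Combined prediction (scalar, or length-k vector for matrix
#'   input).
#' @export
ensemble_combine <- function(preds, weights) {
  M <- if (is.matrix(preds)) nrow(preds) else length(preds)
  if (length(weights) != M) stop("length mismatch between preds and weights")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (is.matrix(preds)) drop(crossprod(preds, weights)) else sum(preds * weights)
}

# Numeric forward for inference over a list of graphs with one parameter
# set; returns a data frame of scores.
model_forward_scores <- function(params, graphs,
                                 head = c("classifier", "regressor"),
                                 config = params_config(params)) {
  head <- match.arg(head)
  vapply(graphs, function(g) {
    tape <- tape_new()
    pn <- params_to_tape(tape, params)
    out <- tape_forward_graph(tape, pn, g, config, head = head, training = FALSE)
    if (head == "classifier") out$p_pos$val[1L] else out$yr$val[1L]
  }, numeric(1))
}
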