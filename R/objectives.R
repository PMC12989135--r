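#' Loss term weights
#'
#' Lagrange multipliers of the composite classification objective
#' `L = L_GC + alpha * L_NC + beta * L_MDN`.
#'
#' @param alpha weight of the node-type cross-entropy term (default 1e-3).
#' @param beta weight of the negative-Pearson DockQ-alignment term
#'   (default 2e-3).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1e-3, beta = 2e-3) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Sample Pearson correlation with an explicit undefined sentinel
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA_real_` (the documented
#'   "undefined" sentinel) when either vector is constant; callers skip the
#'   corresponding loss term.
#' @export
pearson_corr <- function(a, b) {
  if (length(a) < 2L || length(b) != length(a)) {
    stop("pearson_corr needs two vectors of equal length >= 2")
  }
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  ac <- a - mean(a); bc <- b - mean(b)
  sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
}

#' Listwise (top-one) ranking loss
#'
#' Per group, `L = -sum(softmax(y_true) * log softmax(y_pred))`; the mean
#' over groups is returned. Its minimum over `y_pred` (attained at
#' `y_pred = y_true + const`) is the entropy of `softmax(y_true)`, and it is
#' invariant to constant shifts of the predictions.
#'
#' @param y_true true relevance values (e.g. DockQ).
#' @param y_pred predicted scores.
#' @param groups grouping vector (one group per target complex); `NULL`
#'   treats the whole batch as one group.
#' @return Non-negative scalar.
#' @export
listwise_rank_loss <- function(y_true, y_pred, groups = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(groups)) groups <- rep(1L, length(y_true))
  idx <- split(seq_along(y_true), groups)
  sizes <- lengths(idx)
  if (all(sizes < 2L)) stop("all groups have a single item; ranking undefined")
  if (any(sizes < 2L)) warning("skipping ", sum(sizes < 2L), " singleton group(s)")
  ls <- vapply(idx[sizes >= 2L], function(ii) {
    pt <- softmax_vec(y_true[ii])
    -sum(pt * logsoftmax_vec(y_pred[ii]))
  }, numeric(1))
  mean(ls)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

logsoftmax_vec <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

#' Composite classification loss
#'
#' `L = L_GC + alpha * L_NC + beta * L_MDN`: graph-level binary
#' cross-entropy, auxiliary node-type cross-entropy (mean over graphs of the
#' per-graph node mean), and the negative Pearson correlation between the
#' predicted native-like probability and the ground-truth DockQ over the
#' minibatch. The correlation term is set to zero when undefined (constant
#' vectors).
#'
#' @param outputs list with `p_pos` (numeric vector of native-like
#'   probabilities, one per graph) and `node_type_probs` (list of `N_i x 3`
#'   per-node class probability matrices; may be `NULL` to drop `L_NC`).
#' @param batch list with `y` (0/1 labels), `node_types` (list of integer
#'   vectors, classes 1 = antigen, 2 = heavy, 3 = light), `dockq` (numeric
#'   DockQ labels, required).
#' @param weights a [loss_weights()].
#' @return `list(total, l_gc, l_nc, l_mdn)`.
#' @export
classifier_loss <- function(outputs, batch, weights = loss_weights()) {
  p <- outputs$p_pos
  y <- batch$y
  if (is.null(batch$dockq)) stop("dockq labels are required")
  eps <- 1e-12
  l_gc <- mean(-log(pmax(ifelse(y == 1, p, 1 - p), eps)))
  l_nc <- 0
  if (!is.null(outputs$node_type_probs)) {
    l_nc <- mean(mapply(function(pm, tt) {
      mean(-log(pmax(pm[cbind(seq_along(tt), tt)], eps)))
    }, outputs$node_type_probs, batch$node_types))
  }
  r <- if (length(p) >= 2L) pearson_corr(p, batch$dockq) else NA_real_
  l_mdn <- if (is.na(r)) 0 else -r
  total <- l_gc + weights$alpha * l_nc + weights$beta * l_mdn
  list(total = total, l_gc = l_gc, l_nc = l_nc, l_mdn = l_mdn)
}

#' Composite regression loss
#'
#' `L = L_coeff + L_rank` with `L_coeff = -corr(y_true, y_pred)` (skipped
#' when undefined) and `L_rank` the listwise ranking loss over groups.
#'
#' @param y_pred predicted DockQ-scale scores.
#' @param y_true true DockQ labels.
#' @param groups grouping vector for the ranking term (default: one group).
#' @return `list(total, l_coeff, l_rank)`.
#' @export
regressor_loss <- function(y_pred, y_true, groups = NULL) {
  if (length(y_pred) < 2L) stop("batch size >= 2 required")
  r <- pearson_corr(y_true, y_pred)
  l_coeff <- if (is.na(r)) 0 else -r
  l_rank <- listwise_rank_loss(y_true, y_pred, groups)
  list(total = l_coeff + l_rank, l_coeff = l_coeff, l_rank = l_rank)
}

## ---- tape versions (training) ----

# Pearson correlation node between a Bx1 tape node and a constant vector.
# Returns NULL when undefined so callers can drop the term.
tape_pearson <- function(tape, a, b_vec) {
  if (sd(b_vec) < 1e-12 || sd(a$val[, 1L]) < 1e-12) return(NULL)
  bc <- b_vec - mean(b_vec)
  ac <- tp_center(tape, a)
  num <- tp_sum(tape, tp_mul(tape, ac, tp_const(tape, matrix(bc, ncol = 1))))
  den <- tp_sqrt(tape, tp_scale(tape, tp_sum(tape, tp_mul(tape, ac, ac)),
                                sum(bc^2)))
  tp_div(tape, num, den)
}

# Composite classifier loss over a batch of per-graph forward outputs.
tape_classifier_loss <- function(tape, outs, y, node_types, dockq, weights) {
  B <- length(outs)
  gc_terms <- vector("list", B)
  nc_terms <- vector("list", B)
  pos_terms <- vector("list", B)
  for (b in seq_len(B)) {
    logp <- outs[[b]]$logp
    gc_terms[[b]] <- tp_scale(tape, tp_t(tape, tp_rows(tape, logp, y[b] + 1L)), -1)
    lsm <- tp_logsoftmax_rows(tape, outs[[b]]$node_type_logits)
    tt <- node_types[[b]]
    onehot <- matrix(0, length(tt), 3L)
    onehot[cbind(seq_along(tt), tt)] <- 1
    nc_terms[[b]] <- tp_scale(tape, tp_sum(tape, tp_mul(tape, lsm, tp_const(tape, onehot))),
                              -1 / length(tt))
    pos_terms[[b]] <- outs[[b]]$p_pos
  }
  l_gc <- tp_mean(tape, tp_rbind_list(tape, gc_terms))
  l_nc <- tp_mean(tape, tp_rbind_list(tape, nc_terms))
  total <- tp_add(tape, l_gc, tp_scale(tape, l_nc, weights$alpha))
  r <- if (B >= 2L) tape_pearson(tape, tp_rbind_list(tape, pos_terms), dockq) else NULL
  if (!is.null(r)) {
    total <- tp_add(tape, total, tp_scale(tape, r, -weights$beta))
  }
  list(total = total, l_gc = l_gc$val[1L], l_nc = l_nc$val[1L],
       l_mdn = if (is.null(r)) 0 else -r$val[1L])
}

# Composite regressor loss over per-graph scalar predictions.
tape_regressor_loss <- function(tape, yr_nodes, y_true, groups = NULL) {
  yhat <- tp_rbind_list(tape, yr_nodes)
  r <- tape_pearson(tape, yhat, y_true)
  if (is.null(groups)) groups <- rep(1L, length(y_true))
  idx <- split(seq_along(y_true), groups)
  idx <- idx[lengths(idx) >= 2L]
  if (length(idx) == 0L) {
    # minibatch drew one example per target: rank across the whole batch
    idx <- list(seq_along(y_true))
  }
  terms <- lapply(idx, function(ii) {
    pt <- softmax_vec(y_true[ii])
    lsm <- tp_logsoftmax(tape, tp_rows(tape, yhat, ii))
    tp_scale(tape, tp_sum(tape, tp_mul(tape, lsm, tp_const(tape, matrix(pt, ncol = 1)))), -1)
  })
  l_rank <- tp_mean(tape, tp_rbind_list(tape, lapply(terms, function(t) tp_t(tape, t))))
  total <- if (is.null(r)) l_rank else tp_add(tape, l_rank, tp_scale(tape, r, -1))
  list(total = total, l_coeff = if (is.null(r)) 0 else -r$val[1L],
       l_rank = l_rank$val[1L])
}
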