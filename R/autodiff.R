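# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). A node is an
# environment holding `val`, an accumulated `grad`, and a backward closure
# `bk` that pushes the node's gradient into its parents. `tape_backward()`
# walks nodes in reverse creation order, so the tape must be built in
# topological order (which any forward pass does naturally).
#
# The op set is exactly what the pose-scoring encoder, pooling, heads and
# losses need: matmul, broadcasted add/sub/mul, element-wise nonlinearities,
# row gather/scatter (for edge message passing), column binds/slices, and a
# handful of scalar reductions. All internal; not part of the public API.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, val, bk = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bk <- bk
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

tp_const <- function(tape, x) {
  tp_node(tape, as_mat(x))
}

tp_param <- function(tape, x, name) {
  nd <- tp_node(tape, as_mat(x))
  nd$param_name <- name
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

tp_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
}

#' @noRd
tape_backward <- function(tape, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bk)) nd$bk(nd)
  }
  invisible(NULL)
}

# Collect gradients of all named parameter nodes into a named list.
tape_param_grads <- function(pnodes) {
  lapply(pnodes, function(nd) {
    if (is.null(nd$grad)) array(0, dim(nd$val)) else nd$grad
  })
}

## ---- arithmetic ----

tp_mm <- function(tape, a, b) {
  tp_node(tape, a$val %*% b$val, bk = function(nd) {
    g <- nd$grad
    tp_accum(a, g %*% t(b$val))
    tp_accum(b, t(a$val) %*% g)
  })
}

# a + b where b may be: same shape, a 1xk row (bias broadcast over rows),
# or a 1x1 scalar.
tp_add <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  val <- if (identical(dim(av), dim(bv))) {
    av + bv
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    av + rep(bv[1L, ], each = nrow(av))
  } else if (length(bv) == 1L) {
    av + bv[1L]
  } else stop("tp_add: incompatible shapes")
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    tp_accum(a, g)
    if (identical(dim(av), dim(bv))) {
      tp_accum(b, g)
    } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
      tp_accum(b, matrix(colSums(g), 1L))
    } else {
      tp_accum(b, matrix(sum(g), 1L, 1L))
    }
  })
}

tp_sub <- function(tape, a, b) {
  stopifnot(identical(dim(a$val), dim(b$val)))
  tp_node(tape, a$val - b$val, bk = function(nd) {
    tp_accum(a, nd$grad)
    tp_accum(b, -nd$grad)
  })
}

# Element-wise product. b may be same-shape, an Nx1 column broadcast across
# the columns of a, or a 1x1 scalar.
tp_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  same <- identical(dim(av), dim(bv))
  colb <- !same && ncol(bv) == 1L && nrow(bv) == nrow(av)
  scal <- !same && !colb && length(bv) == 1L
  if (!same && !colb && !scal) stop("tp_mul: incompatible shapes")
  val <- if (same) av * bv else if (colb) av * bv[, 1L] else av * bv[1L]
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    if (same) {
      tp_accum(a, g * bv)
      tp_accum(b, g * av)
    } else if (colb) {
      tp_accum(a, g * bv[, 1L])
      tp_accum(b, matrix(rowSums(g * av), ncol = 1L))
    } else {
      tp_accum(a, g * bv[1L])
      tp_accum(b, matrix(sum(g * av), 1L, 1L))
    }
  })
}

tp_scale <- function(tape, a, k) {
  tp_node(tape, a$val * k, bk = function(nd) tp_accum(a, nd$grad * k))
}

tp_div <- function(tape, a, b) {
  bv <- b$val
  stopifnot(length(bv) == 1L || identical(dim(a$val), dim(bv)))
  val <- if (length(bv) == 1L) a$val / bv[1L] else a$val / bv
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    if (length(bv) == 1L) {
      tp_accum(a, g / bv[1L])
      tp_accum(b, matrix(-sum(g * a$val) / bv[1L]^2, 1L, 1L))
    } else {
      tp_accum(a, g / bv)
      tp_accum(b, -g * a$val / bv^2)
    }
  })
}

# Fused x %*% W + b with optional activation; one node instead of three.
tp_linear <- function(tape, x, W, b, act = c("none", "silu", "sigmoid", "tanh")) {
  act <- match.arg(act)
  z <- x$val %*% W$val
  z <- z + rep(b$val[1L, ], each = nrow(z))
  val <- switch(act,
    none = z,
    silu = z / (1 + exp(-z)),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z)
  )
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    gz <- switch(act,
      none = g,
      silu = { s <- 1 / (1 + exp(-z)); g * (s * (1 + z * (1 - s))) },
      sigmoid = g * val * (1 - val),
      tanh = g * (1 - val^2)
    )
    tp_accum(x, gz %*% t(W$val))
    tp_accum(W, crossprod(x$val, gz))
    tp_accum(b, matrix(colSums(gz), 1L))
  })
}

## ---- nonlinearities ----

tp_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  tp_node(tape, s, bk = function(nd) tp_accum(a, nd$grad * s * (1 - s)))
}

tp_tanh <- function(tape, a) {
  th <- tanh(a$val)
  tp_node(tape, th, bk = function(nd) tp_accum(a, nd$grad * (1 - th^2)))
}

tp_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  tp_node(tape, a$val * s, bk = function(nd) {
    tp_accum(a, nd$grad * (s * (1 + a$val * (1 - s))))
  })
}

tp_exp <- function(tape, a) {
  ev <- exp(a$val)
  tp_node(tape, ev, bk = function(nd) tp_accum(a, nd$grad * ev))
}

tp_log <- function(tape, a) {
  tp_node(tape, log(a$val), bk = function(nd) tp_accum(a, nd$grad / a$val))
}

tp_sqrt <- function(tape, a) {
  sv <- sqrt(a$val)
  tp_node(tape, sv, bk = function(nd) tp_accum(a, nd$grad * 0.5 / sv))
}

## ---- structure ops ----

tp_rows <- function(tape, a, idx) {
  tp_node(tape, a$val[idx, , drop = FALSE], bk = function(nd) {
    g <- nd$grad
    gm <- matrix(0, nrow(a$val), ncol(a$val))
    rs <- rowsum(g, group = idx)
    gm[as.integer(rownames(rs)), ] <- rs
    tp_accum(a, gm)
  })
}

# Scatter-add rows of a into n_out rows by index.
tp_scatter <- function(tape, a, idx, n_out) {
  fwd <- matrix(0, n_out, ncol(a$val))
  rs <- rowsum(a$val, group = idx)
  fwd[as.integer(rownames(rs)), ] <- rs
  tp_node(tape, fwd, bk = function(nd) {
    tp_accum(a, nd$grad[idx, , drop = FALSE])
  })
}

tp_cbind <- function(tape, ...) {
  parts <- list(...)
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  val <- do.call(cbind, lapply(parts, function(p) p$val))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    for (k in seq_along(parts)) {
      tp_accum(parts[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

tp_cols <- function(tape, a, idx) {
  tp_node(tape, a$val[, idx, drop = FALSE], bk = function(nd) {
    gm <- matrix(0, nrow(a$val), ncol(a$val))
    gm[, idx] <- nd$grad
    tp_accum(a, gm)
  })
}

# Stack a list of 1xk nodes into an Mxk matrix.
tp_rbind_list <- function(tape, parts) {
  val <- do.call(rbind, lapply(parts, function(p) p$val))
  tp_node(tape, val, bk = function(nd) {
    g <- nd$grad
    for (k in seq_along(parts)) {
      tp_accum(parts[[k]], g[k, , drop = FALSE])
    }
  })
}

tp_t <- function(tape, a) {
  tp_node(tape, t(a$val), bk = function(nd) tp_accum(a, t(nd$grad)))
}

## ---- reductions ----

tp_rowsums <- function(tape, a) {
  tp_node(tape, matrix(rowSums(a$val), ncol = 1L), bk = function(nd) {
    tp_accum(a, matrix(nd$grad[, 1L], nrow(a$val), ncol(a$val)))
  })
}

tp_sum <- function(tape, a) {
  tp_node(tape, matrix(sum(a$val), 1L, 1L), bk = function(nd) {
    tp_accum(a, matrix(nd$grad[1L], nrow(a$val), ncol(a$val)))
  })
}

tp_mean <- function(tape, a) {
  n <- length(a$val)
  tp_node(tape, matrix(mean(a$val), 1L, 1L), bk = function(nd) {
    tp_accum(a, matrix(nd$grad[1L] / n, nrow(a$val), ncol(a$val)))
  })
}

# x - mean(x) for a column vector; the workhorse of the Pearson term.
tp_center <- function(tape, a) {
  stopifnot(ncol(a$val) == 1L)
  tp_node(tape, a$val - mean(a$val), bk = function(nd) {
    tp_accum(a, nd$grad - mean(nd$grad))
  })
}

# log-softmax of a column vector (numerically stable).
tp_logsoftmax <- function(tape, a) {
  stopifnot(ncol(a$val) == 1L)
  m <- max(a$val)
  ls <- a$val - m - log(sum(exp(a$val - m)))
  tp_node(tape, ls, bk = function(nd) {
    g <- nd$grad
    tp_accum(a, g - exp(ls) * sum(g))
  })
}

# row-wise log-softmax of an Nxk matrix (node-type cross-entropy).
tp_logsoftmax_rows <- function(tape, a) {
  m <- apply(a$val, 1L, max)
  sh <- a$val - m
  ls <- sh - log(rowSums(exp(sh)))
  tp_node(tape, ls, bk = function(nd) {
    g <- nd$grad
    tp_accum(a, g - exp(ls) * rowSums(g))
  })
}
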