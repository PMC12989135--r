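#' Training configuration
#'
#' @param max_epochs maximum epochs (default 50).
#' @param lr_init initial learning rate (default 1e-4).
#' @param lr_min final learning rate of the cosine schedule (default 1e-5).
#' @param w_neg,w_pos weighted-random-sampler weights for negative and
#'   positive examples (defaults 0.8 and 0.2).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param batch_size graphs per minibatch (default 8).
#' @param n_ensemble number of best-validation checkpoints retained for
#'   ensembling (default 5).
#' @param clip_norm global gradient-norm clip (default 5).
#' @param seed RNG seed for sampling, dropout and initialisation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_epochs = 50L, lr_init = 1e-4, lr_min = 1e-5,
                            w_neg = 0.8, w_pos = 0.2, patience = 10L,
                            batch_size = 8L, n_ensemble = 5L, clip_norm = 5,
                            seed = 1L) {
  stopifnot(lr_min <= lr_init, patience >= 1L, batch_size >= 1L)
  structure(list(max_epochs = as.integer(max_epochs), lr_init = lr_init,
                 lr_min = lr_min, w_neg = w_neg, w_pos = w_pos,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 n_ensemble = as.integer(n_ensemble), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Class-balanced sampling weights
#'
#' Weight `w_neg` for negative and `w_pos` for positive examples, used for
#' sampling minibatches with replacement. A single-class label vector
#' triggers a warning and uniform weights.
#'
#' @param labels 0/1 label vector.
#' @param w_neg,w_pos class weights (defaults 0.8, 0.2).
#' @return Numeric per-example weight vector.
#' @export
sampler_weights <- function(labels, w_neg = 0.8, w_pos = 0.2) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L) {
    warning("single-class dataset; using uniform sampling weights")
    return(rep(1, length(labels)))
  }
  ifelse(labels == 0L, w_neg, w_pos)
}

#' Cosine-annealed learning rate
#'
#' Epoch 1 yields exactly `lr_init` and epoch `max_epochs` exactly
#' `lr_min`; monotone non-increasing in between.
#'
#' @param epoch 1-based epoch index.
#' @param max_epochs schedule horizon.
#' @param lr_init,lr_max initial rate (alias arguments; `lr_init` used).
#' @param lr_min final rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, max_epochs, lr_init = 1e-4, lr_min = 1e-5) {
  if (max_epochs <= 1L) return(lr_init)
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * (epoch - 1) / (max_epochs - 1)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

node_type_ints <- function(g) match(g$node_type_label, NODE_TYPE_LEVELS)

#' Initialise a regressor from a trained classifier
#'
#' Copies every encoder, pooling and auxiliary-head parameter from the
#' source classifier, discards the softmax classification head, and
#' attaches a freshly initialised scaled-tanh regression head. All
#' parameters remain trainable.
#'
#' @param classifier_params an `abpose_params` with a classifier head (or an
#'   `abpose_fit`, whose best checkpoint is used).
#' @param seed seed for the fresh head initialisation.
#' @return An `abpose_params` with a regressor head.
#' @export
init_from_classifier <- function(classifier_params, seed = 1L) {
  if (inherits(classifier_params, "abpose_fit")) {
    classifier_params <- classifier_params$params
  }
  cfg <- params_config(classifier_params)
  p <- classifier_params[setdiff(names(classifier_params),
                                 c("Wc1", "bc1", "Wc2", "bc2"))]
  h <- cfg$hidden_dim
  head <- with_seed(seed, list(Wr = uinit(h, 1), br = matrix(0, 1, 1)))
  structure(c(p, head), class = "abpose_params", config = cfg)
}

#' Train a pose classifier or regressor
#'
#' Adam optimisation with cosine-annealed learning rate, class-weighted
#' minibatch sampling with replacement, global gradient-norm clipping, and
#' early stopping on the validation metric (F1 at threshold 0.5 for the
#' classifier; Pearson r for the regressor). The best checkpoint and the
#' `n_ensemble` best-validation checkpoints are retained for ensembling.
#' With `init` given and `task = "regressor"`, training fine-tunes from the
#' classifier via [init_from_classifier()].
#'
#' @param task `"classifier"` or `"regressor"`.
#' @param data `list(train = ..., val = ...)` of labelled examples as
#'   produced by [build_benchmark()] / [split_by_cluster()].
#' @param config a [training_config()].
#' @param encoder an [encoder_config()].
#' @param init optional source checkpoint (`abpose_params` or `abpose_fit`)
#'   for classifier-to-regressor transfer.
#' @param weights a [loss_weights()] (classifier task only).
#' @param verbose print per-epoch progress.
#' @return An `abpose_fit`: best parameters, retained checkpoints, per-epoch
#'   history tibble, and the configs used.
#' @export
train <- function(task = c("classifier", "regressor"), data,
                  config = training_config(), encoder = encoder_config(),
                  init = NULL, weights = loss_weights(), verbose = FALSE) {
  task <- match.arg(task)
  tr <- data$train; va <- data$val
  if (length(tr) == 0L || length(va) == 0L) stop("train and val sets must be non-empty")
  y_tr <- vapply(tr, `[[`, integer(1), "label")
  y_va <- vapply(va, `[[`, integer(1), "label")
  dq_tr <- vapply(tr, `[[`, numeric(1), "dockq")
  dq_va <- vapply(va, `[[`, numeric(1), "dockq")
  if (anyNA(dq_tr)) stop("dockq labels are required for every training example")
  if (task == "classifier" && length(unique(y_va)) < 2L) {
    stop("validation set must contain both classes for the classifier task")
  }

  params <- if (!is.null(init)) {
    if (task != "regressor") stop("init transfer is defined for the regressor task")
    init_from_classifier(init, seed = config$seed)
  } else {
    init_model_params(encoder, task = task, seed = config$seed)
  }
  encoder <- params_config(params)
  sw <- suppressWarnings(sampler_weights(y_tr, config$w_neg, config$w_pos))
  nt_tr <- lapply(tr, function(ex) node_type_ints(ex$graph))
  groups_tr <- vapply(tr, function(ex) as.character(ex$group), character(1))

  state <- adam_init(params)
  history <- list()
  best_metric <- -Inf
  best_params <- params
  best_epoch <- 0L
  kept <- list()
  stall <- 0L

  with_seed(config$seed + 1L, {
    steps <- max(1L, ceiling(length(tr) / config$batch_size))
    for (epoch in seq_len(config$max_epochs)) {
      lr <- cosine_lr(epoch, config$max_epochs, config$lr_init, config$lr_min)
      ep_loss <- 0
      for (step in seq_len(steps)) {
        idx <- sample.int(length(tr), config$batch_size, replace = TRUE, prob = sw)
        tape <- tape_new()
        pn <- params_to_tape(tape, params)
        if (task == "classifier") {
          outs <- lapply(idx, function(i) {
            tape_forward_graph(tape, pn, tr[[i]]$graph, encoder,
                               head = "classifier", training = TRUE)
          })
          loss <- tape_classifier_loss(tape, outs, y_tr[idx], nt_tr[idx],
                                       dq_tr[idx], weights)
        } else {
          yr <- lapply(idx, function(i) {
            tape_forward_graph(tape, pn, tr[[i]]$graph, encoder,
                               head = "regressor", training = TRUE)$yr
          })
          loss <- tape_regressor_loss(tape, yr, dq_tr[idx], groups_tr[idx])
        }
        if (!is.finite(loss$total$val[1L])) {
          stop("non-finite loss at epoch ", epoch, ", step ", step)
        }
        ep_loss <- ep_loss + loss$total$val[1L]
        tape_backward(tape, loss$total)
        grads <- clip_gradients(tape_param_grads(pn), config$clip_norm)
        upd <- adam_update(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      val_scores <- model_forward_scores(params, lapply(va, `[[`, "graph"),
                                         head = if (task == "classifier") "classifier" else "regressor",
                                         config = encoder)
      val_metric <- if (task == "classifier") {
        classification_metrics(val_scores, y_va, threshold = 0.5)$f1
      } else {
        r <- pearson_corr(val_scores, dq_va)
        if (is.na(r)) 0 else r
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = ep_loss / steps,
        val_metric = val_metric
      )
      if (verbose) {
        message(sprintf("epoch %d lr %.2e loss %.4f val %.4f",
                        epoch, lr, ep_loss / steps, val_metric))
      }
      kept[[length(kept) + 1L]] <- list(params = params, epoch = epoch,
                                        val_metric = val_metric)
      if (length(kept) > 1L) {
        ord <- order(vapply(kept, `[[`, numeric(1), "val_metric"),
                     vapply(kept, function(k) k$epoch, integer(1)),
                     decreasing = TRUE)
        kept <- kept[ord[seq_len(min(length(kept), config$n_ensemble))]]
      }
      # strict improvement resets patience; ties still refresh the incumbent
      # (later epochs are preferred when the monitored metric is flat)
      if (val_metric > best_metric + 1e-12) stall <- 0L else stall <- stall + 1L
      if (val_metric >= best_metric) {
        best_metric <- val_metric
        best_params <- params
        best_epoch <- epoch
      }
      if (stall >= config$patience) break
    }
  })

  structure(list(
    task = task,
    params = best_params,
    best_epoch = best_epoch,
    best_metric = best_metric,
    checkpoints = kept,
    history = do.call(rbind, history),
    encoder = encoder,
    config = config
  ), class = "abpose_fit")
}

#' @export
print.abpose_fit <- function(x, ...) {
  cat("<abpose_fit> task=", x$task, ", best epoch ", x$best_epoch,
      " (val ", sprintf("%.4f", x$best_metric), "), ",
      nrow(x$history), " epochs run, ", length(x$checkpoints),
      " checkpoints kept\n", sep = "")
  invisible(x)
}

#' Score graphs with a fitted model
#'
#' Scores each graph with every retained checkpoint and combines them with
#' [ensemble_combine()] (uniform weights by default, mirroring
#' checkpoint-averaging ensembles).
#'
#' @param object an `abpose_fit`.
#' @param graphs list of `abpose_graph` objects (or a single graph).
#' @param ensemble use all retained checkpoints (default) or only the best.
#' @param weights optional ensemble weights (must sum to 1).
#' @param ... unused.
#' @return Numeric score vector (classifier probability or regressor
#'   score).
#' @export
predict.abpose_fit <- function(object, graphs, ensemble = TRUE,
                               weights = NULL, ...) {
  if (inherits(graphs, "abpose_graph")) graphs <- list(graphs)
  head <- if (object$task == "classifier") "classifier" else "regressor"
  plist <- if (ensemble) lapply(object$checkpoints, `[[`, "params") else list(object$params)
  if (is.null(weights)) weights <- rep(1 / length(plist), length(plist))
  mat <- vapply(plist, function(p) {
    model_forward_scores(p, graphs, head = head, config = object$encoder)
  }, numeric(length(graphs)))
  mat <- matrix(mat, nrow = length(graphs))
  vapply(seq_len(length(graphs)), function(i) ensemble_combine(mat[i, ], weights),
         numeric(1))
}
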