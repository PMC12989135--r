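#' Score candidate poses end to end
#'
#' For each input structure: parse, clean, assign roles, featurize, sample
#' the interface subgraph, encode, pool, and score with the classifier (and
#' optionally the regressor), ensembling across checkpoints. Per-structure
#' failures are recorded in-row and the run continues; the call errors only
#' if no structure succeeds.
#'
#' @param inputs character vector of PDB/mmCIF paths, or a list of
#'   `typed_complex` objects (each optionally named for the `id` column).
#' @param annotation chain annotation (data frame or file path; see
#'   [assign_roles()]); ignored for `typed_complex` inputs.
#' @param classifier an `abpose_fit` (classifier task).
#' @param regressor optional `abpose_fit` (regressor task).
#' @param ensemble_weights optional checkpoint ensemble weights.
#' @param threshold classifier decision threshold for `pred_label`
#'   (default 0.5).
#' @param feat_config a [featurization_config()].
#' @param samp_config a [sampling_config()].
#' @param embedder node-embedding backend.
#' @return Tibble with one row per input: `id`, `clf_score`, `reg_score`,
#'   `pred_label`, `subgraph_nodes`, `error`.
#' @export
predict_poses <- function(inputs, annotation = NULL, classifier,
                          regressor = NULL, ensemble_weights = NULL,
                          threshold = 0.5,
                          feat_config = featurization_config(),
                          samp_config = sampling_config(),
                          embedder = hashed_embedder()) {
  stopifnot(inherits(classifier, "abpose_fit"), classifier$task == "classifier")
  if (!is.null(regressor)) stopifnot(regressor$task == "regressor")
  items <- if (is.character(inputs)) as.list(inputs) else inputs
  ids <- names(items)
  if (is.null(ids)) {
    ids <- vapply(seq_along(items), function(i) {
      if (is.character(items[[i]])) basename(items[[i]]) else paste0("input_", i)
    }, character(1))
  }
  rows <- lapply(seq_along(items), function(i) {
    res <- tryCatch({
      x <- items[[i]]
      tc <- if (inherits(x, "typed_complex")) x else {
        if (is.null(annotation)) stop("annotation required for file inputs")
        assign_roles(clean_structure(parse_structure(x)), annotation)
      }
      g <- suppressWarnings(build_graph(tc, feat_config, embedder))
      gs <- if (!any(g$is_interface)) {
        induce_subgraph(g, seq_len(min(g$n_nodes, samp_config$node_cap)))
      } else {
        sample_subgraph(g, samp_config)
      }
      clf <- predict(classifier, gs, weights = ensemble_weights)
      reg <- if (is.null(regressor)) NA_real_ else
        predict(regressor, gs, weights = ensemble_weights)
      tibble::tibble(id = ids[i], clf_score = clf, reg_score = reg,
                     pred_label = as.integer(clf >= threshold),
                     subgraph_nodes = gs$n_nodes, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(id = ids[i], clf_score = NA_real_, reg_score = NA_real_,
                     pred_label = NA_integer_, subgraph_nodes = NA_integer_,
                     error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error))) stop("all inputs failed; first error: ", out$error[1])
  out
}

#' Evaluate a prediction run
#'
#' Joins a prediction table with true labels/DockQ by `id` and reports the
#' full metrics both at the F-beta-optimal classifier threshold and at the
#' fixed 0.5 threshold, plus the filter-then-rank precision@K table.
#'
#' @param predictions tibble from [predict_poses()] (columns `id`,
#'   `clf_score`, optionally `reg_score`).
#' @param truth data frame with columns `id`, `label`, and optionally
#'   `dockq`.
#' @param beta F-beta parameter for threshold selection (default 1).
#' @param K_list Top-K report sizes (default `c(10, 20, 50, 100)`).
#' @return List: `metrics_fbeta`, `metrics_fixed` (tibbles from
#'   [classification_metrics()]), `threshold_fbeta`, `topk` (tibble), and
#'   `unmatched_ids`.
#' @export
evaluate_run <- function(predictions, truth, beta = 1,
                         K_list = c(10L, 20L, 50L, 100L)) {
  stopifnot(all(c("id", "clf_score") %in% names(predictions)),
            all(c("id", "label") %in% names(truth)))
  m <- match(predictions$id, truth$id)
  unmatched <- predictions$id[is.na(m)]
  ok <- !is.na(m) & !is.na(predictions$clf_score)
  scores <- predictions$clf_score[ok]
  labels <- truth$label[m[ok]]
  if (length(unique(labels)) < 2L) {
    thr <- NA_real_
    mf <- classification_metrics(scores, labels, threshold = 0.5)
  } else {
    thr <- select_threshold_fbeta(scores, labels, beta = beta)
    mf <- classification_metrics(scores, labels, threshold = thr)
  }
  m05 <- classification_metrics(scores, labels, threshold = 0.5)
  reg <- predictions$reg_score[ok]
  if (all(is.na(reg))) reg <- scores
  topk <- topk_success(scores, reg, labels,
                       clf_threshold = if (is.na(thr)) 0.5 else thr,
                       K_list = K_list)
  list(metrics_fbeta = mf, metrics_fixed = m05,
       threshold_fbeta = thr, topk = topk, unmatched_ids = unmatched)
}
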