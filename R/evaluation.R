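BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Least-squares rigid superposition (Kabsch, via SVD). Returns the moving
# coordinates transformed onto the target frame.
kabsch_fit <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), nrow(moving) >= 3L)
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, fitted = sweep(A %*% t(R), 2L, ct, "+"))
}

rmsd_val <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# Heavy-atom coordinate table of a typed complex: one row per atom with
# residue key, side and atom name.
side_atom_table <- function(tc) {
  rows <- list()
  for (a in tc$annotations) {
    for (r in tc$structure$chains[[a$chain_id]]) {
      at <- r$atoms[!(r$atoms$element %in% c("H", "D")), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        key = paste0(a$chain_id, ":", r$seq_index),
        side = a$side, name = at$name,
        x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Cross-side residue contact pairs at `cutoff` Angstrom (any heavy-atom
# pair), returned as "igkey|agkey" strings.
contact_pairs <- function(at, cutoff) {
  ig <- at[at$side == "ig", , drop = FALSE]
  ag <- at[at$side == "ag", , drop = FALSE]
  d2 <- cross_dist2(as.matrix(ig[, c("x", "y", "z")]),
                    as.matrix(ag[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  unique(paste(ig$key[hit[, 1]], ag$key[hit[, 2]], sep = "|"))
}

#' DockQ quality of a model complex against its native structure
#'
#' Computes Fnat (fraction of native cross-side residue contacts, any
#' heavy-atom pair within 5 Angstrom, recovered in the model), LRMS (Ig-side
#' backbone RMSD after least-squares superposition of the antigen-side
#' backbones) and iRMS (backbone RMSD over the native interface residues,
#' 10-Angstrom definition, after superposition on those residues), combined
#' as `DockQ = (Fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3`.
#' Multi-chain sides are merged: the Ig side is treated as the ligand and
#' the antigen side as the receptor. Residues are matched between model and
#' native by chain id and author residue number.
#'
#' @param model,native `typed_complex` objects with corresponding chains.
#' @return A list of class `dockq_result`: `fnat`, `irms`, `lrms`, `dockq`.
#' @export
dockq <- function(model, native) {
  stopifnot(inherits(model, "typed_complex"), inherits(native, "typed_complex"))
  atm <- side_atom_table(model)
  atn <- side_atom_table(native)

  nat_contacts <- contact_pairs(atn, 5)
  if (length(nat_contacts) == 0L) stop("no native interface (no contacts within 5 A)")
  mod_contacts <- contact_pairs(atm, 5)
  fnat <- length(intersect(nat_contacts, mod_contacts)) / length(nat_contacts)

  # backbone atoms present in both structures, keyed by residue+atom name
  bbm <- atm[atm$name %in% BACKBONE_ATOMS, , drop = FALSE]
  bbn <- atn[atn$name %in% BACKBONE_ATOMS, , drop = FALSE]
  bbm$id <- paste(bbm$key, bbm$name)
  bbn$id <- paste(bbn$key, bbn$name)
  common <- intersect(bbm$id, bbn$id)
  if (length(common) < 6L) stop("chain correspondence unresolvable: too few shared backbone atoms")
  bbm <- bbm[match(common, bbm$id), , drop = FALSE]
  bbn <- bbn[match(common, bbn$id), , drop = FALSE]
  M <- as.matrix(bbm[, c("x", "y", "z")])
  N <- as.matrix(bbn[, c("x", "y", "z")])

  # LRMS: fit on receptor (ag) backbone, measure ligand (ig) backbone
  rec <- bbn$side == "ag"; lig <- !rec
  fit <- kabsch_fit(M[rec, , drop = FALSE], N[rec, , drop = FALSE])
  Mfit <- sweep(sweep(M, 2L, colMeans(M[rec, , drop = FALSE])) %*% t(fit$R),
                2L, colMeans(N[rec, , drop = FALSE]), "+")
  lrms <- rmsd_val(Mfit[lig, , drop = FALSE], N[lig, , drop = FALSE])

  # iRMS: native interface residues at 10 A, fit and measure on those
  iface_pairs <- contact_pairs(atn, 10)
  iface_keys <- unique(unlist(strsplit(iface_pairs, "|", fixed = TRUE)))
  ii <- bbn$key %in% iface_keys
  if (sum(ii) < 3L) stop("no native interface residues for iRMS")
  ifit <- kabsch_fit(M[ii, , drop = FALSE], N[ii, , drop = FALSE])
  irms <- rmsd_val(ifit$fitted, N[ii, , drop = FALSE])

  score <- (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
  structure(list(fnat = fnat, irms = irms, lrms = lrms, dockq = score),
            class = "dockq_result")
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf("<dockq_result> DockQ %.4f (Fnat %.3f, iRMS %.2f A, LRMS %.2f A)\n",
              x$dockq, x$fnat, x$irms, x$lrms))
  invisible(x)
}

#' Binary label from a DockQ score
#'
#' @param score DockQ score(s) in `[0, 1]`.
#' @param threshold positive threshold (default 0.8, boundary inclusive:
#'   a score of exactly 0.8 is positive).
#' @return Integer 0/1 vector.
#' @export
label_from_dockq <- function(score, threshold = 0.8) {
  if (any(score < 0 | score > 1 | !is.finite(score))) {
    stop("DockQ scores must lie in [0, 1]")
  }
  as.integer(score >= threshold)
}

#' Classification metrics report
#'
#' Precision, recall and F1 at the given threshold (predicted positive when
#' `score >= threshold`); AUC-ROC by the rank statistic (ties averaged);
#' AP as the step-wise area under the precision-recall curve (precision at
#' each recall change, no interpolation). With single-class labels, AUC and
#' AP are `NA` (undefined sentinel), never silently 0.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return One-row tibble: `precision`, `recall`, `f1`, `auc_roc`, `auc_pr`,
#'   `pearson_r`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    auc <- NA_real_; ap <- NA_real_
  } else {
    rk <- rank(scores)
    auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ap <- average_precision(scores, labels)
  }
  r <- if (length(scores) >= 2L && sd(scores) > 0 && sd(labels) > 0) {
    pearson_corr(scores, labels)
  } else NA_real_
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 auc_roc = auc, auc_pr = ap, pearson_r = r,
                 threshold = threshold)
}

# Step-sum AP over unique descending score thresholds (tie-safe).
average_precision <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  tp <- vapply(ths, function(t) sum(labels == 1 & scores >= t), numeric(1))
  np <- vapply(ths, function(t) sum(scores >= t), numeric(1))
  recall <- tp / npos
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' F-beta-optimal decision threshold
#'
#' Scans the observed scores as candidate thresholds and returns the one
#' maximising `F_beta = (1 + beta^2) P R / (beta^2 P + R)`; ties resolve to
#' the lowest threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @param beta F-beta parameter (default 1).
#' @return The selected threshold.
#' @export
select_threshold_fbeta <- function(scores, labels, beta = 1) {
  if (length(unique(labels)) < 2L) stop("both classes required")
  cand <- sort(unique(scores))
  fb <- vapply(cand, function(t) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    if (p == 0 && r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
  }, numeric(1))
  cand[which.max(fb)]  # which.max returns the first (lowest) on ties
}

#' Filter-then-rank Top-K precision
#'
#' Implements the candidate-selection protocol: examples with classifier
#' score below `clf_threshold` are filtered out; survivors are ranked by
#' regressor score (descending; ties by higher classifier score, then input
#' order); precision@K is the number of true positives among the top K
#' divided by K. When fewer than K survivors exist the denominator stays K
#' (missing slots count as failures) and the row is flagged truncated.
#'
#' @param clf_scores classifier probabilities.
#' @param reg_scores regressor scores used for ranking.
#' @param labels 0/1 true labels.
#' @param clf_threshold classifier filter threshold.
#' @param K_list K values to report (default `c(10, 20, 50, 100)`).
#' @return Tibble with columns `K`, `precision`, `n_survivors`, `truncated`.
#' @export
topk_success <- function(clf_scores, reg_scores, labels, clf_threshold = 0.5,
                         K_list = c(10L, 20L, 50L, 100L)) {
  stopifnot(length(clf_scores) == length(reg_scores),
            length(labels) == length(clf_scores), all(K_list >= 1L))
  keep <- which(clf_scores >= clf_threshold)
  ord <- keep[order(-reg_scores[keep], -clf_scores[keep], keep)]
  lab <- labels[ord]
  tibble::tibble(
    K = as.integer(K_list),
    precision = vapply(K_list, function(K) sum(head(lab, K) == 1) / K, numeric(1)),
    n_survivors = length(ord),
    truncated = length(ord) < K_list
  )
}
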