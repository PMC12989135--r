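#' Featurization configuration
#'
#' Controls construction of the residue-level pose graph: the intra-side and
#' inter-side contact cutoffs (on minimum heavy-atom distance), the Gaussian
#' RBF expansion of the three raw edge distances, and how residues are
#' reduced to atoms and a single node coordinate.
#'
#' @param tau_intra intra-side edge cutoff in Angstrom (default 3.5).
#' @param tau_inter inter-side (interface) edge cutoff in Angstrom (default 10).
#' @param n_scales number of RBF scales D (default 10); the edge feature is
#'   the concatenation of three D-length expansions (min-atom, Ca-Ca,
#'   centroid distance), so its length is `3 * n_scales`.
#' @param scale_range inclusive range of the log-spaced RBF length scales in
#'   Angstrom (default `c(0.25, 8)`).
#' @param atom_mode `"all_atom"` (heavy atoms) or `"ca_only"`.
#' @param node_coord which point represents a residue for the equivariant
#'   network: `"ca"` (default; centroid fallback) or `"centroid"`.
#' @param rbf_mode `"widths"` (default): scales are Gaussian length scales
#'   with zero centers, `exp(-d^2 / (2 s_k^2))`; `"centers"`: log-spaced
#'   centers with a shared width.
#' @param include_hydrogens retain hydrogen atoms in distance computations
#'   (default `FALSE`: heavy atoms only).
#' @param mass_weighted use mass-weighted centroids (default `FALSE`:
#'   unweighted mean of heavy-atom coordinates).
#' @return A list of class `featurization_config`.
#' @export
featurization_config <- function(tau_intra = 3.5, tau_inter = 10.0,
                                 n_scales = 10L, scale_range = c(0.25, 8),
                                 atom_mode = c("all_atom", "ca_only"),
                                 node_coord = c("ca", "centroid"),
                                 rbf_mode = c("widths", "centers"),
                                 include_hydrogens = FALSE,
                                 mass_weighted = FALSE) {
  atom_mode <- match.arg(atom_mode)
  node_coord <- match.arg(node_coord)
  rbf_mode <- match.arg(rbf_mode)
  stopifnot(tau_intra <= tau_inter, n_scales >= 1L,
            length(scale_range) == 2L, scale_range[1] > 0,
            scale_range[2] > scale_range[1])
  structure(list(tau_intra = tau_intra, tau_inter = tau_inter,
                 n_scales = as.integer(n_scales), scale_range = scale_range,
                 atom_mode = atom_mode, node_coord = node_coord,
                 rbf_mode = rbf_mode, include_hydrogens = include_hydrogens,
                 mass_weighted = mass_weighted),
            class = "featurization_config")
}

ATOM_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, SE = 78.971,
               P = 30.974, H = 1.008)

residue_atom_coords <- function(r, config) {
  a <- r$atoms
  keep <- if (config$include_hydrogens) rep(TRUE, nrow(a)) else !(a$element %in% c("H", "D"))
  if (config$atom_mode == "ca_only") keep <- keep & a$name == "CA"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("residue ", r$seq_index, " has no atoms under atom_mode=", config$atom_mode)
  }
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       name = a$name, element = a$element)
}

residue_centroid <- function(ac, mass_weighted = FALSE) {
  if (mass_weighted) {
    w <- ATOM_MASS[ac$element]
    w[is.na(w)] <- 12
    colSums(ac$xyz * w) / sum(w)
  } else {
    colMeans(ac$xyz)
  }
}

#' Three raw distances between two residues
#'
#' Computes the minimum atomic distance (over all atom pairs under the
#' configured atom mode), the Ca-Ca distance, and the centroid distance, all
#' in Angstrom. A residue lacking a Ca in all-atom mode falls back to its
#' centroid for the Ca distance, with a warning.
#'
#' @param r1,r2 residues (as stored in a [complex_structure()]).
#' @param config a [featurization_config()].
#' @return Named numeric vector `c(d_min, d_ca, d_com)`.
#' @export
residue_distances <- function(r1, r2, config = featurization_config()) {
  a1 <- residue_atom_coords(r1, config)
  a2 <- residue_atom_coords(r2, config)
  d_min <- sqrt(min(cross_dist2(a1$xyz, a2$xyz)))
  com1 <- residue_centroid(a1, config$mass_weighted)
  com2 <- residue_centroid(a2, config$mass_weighted)
  d_com <- sqrt(sum((com1 - com2)^2))
  ca1 <- a1$xyz[match("CA", a1$name), ]
  ca2 <- a2$xyz[match("CA", a2$name), ]
  if (anyNA(ca1)) { warning("residue ", r1$seq_index, " has no CA; using centroid"); ca1 <- com1 }
  if (anyNA(ca2)) { warning("residue ", r2$seq_index, " has no CA; using centroid"); ca2 <- com2 }
  d_ca <- sqrt(sum((ca1 - ca2)^2))
  c(d_min = d_min, d_ca = d_ca, d_com = d_com)
}

# squared distances between rows of two coordinate matrices
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

rbf_scales <- function(config) {
  exp(seq(log(config$scale_range[1]), log(config$scale_range[2]),
          length.out = config$n_scales))
}

#' Gaussian RBF expansion of a distance
#'
#' Default (`rbf_mode = "widths"`): component k is
#' `exp(-d^2 / (2 * s_k^2))` with `s_k` the D log-spaced length scales over
#' the inclusive `scale_range`. All components lie in (0, 1] and are
#' monotone non-increasing in d.
#'
#' @param d distance(s) in Angstrom, non-negative and finite.
#' @param config a [featurization_config()].
#' @return A matrix `length(d) x D` (a vector input of length one yields a
#'   1 x D matrix).
#' @export
rbf_expand <- function(d, config = featurization_config()) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  s <- rbf_scales(config)
  if (config$rbf_mode == "widths") {
    outer(d^2, 2 * s^2, function(d2, v) exp(-d2 / v))
  } else {
    sigma <- if (length(s) > 1L) exp(mean(diff(log(s)))) * min(s) else s
    outer(d, s, function(dd, ck) exp(-(dd - ck)^2 / (2 * sigma^2)))
  }
}

## ---- embedders ----

#' Built-in deterministic residue embedder
#'
#' A hash-seeded pseudo-random per-residue embedding: each residue's row
#' depends only on its one-letter code within a sliding window (default
#' window 1, i.e. the residue identity alone), generated by a fixed linear
#' congruential stream so the mapping is reproducible with no model download
#' and no global RNG interaction. Serves as the default stand-in node
#' embedding where a protein-language-model matrix is not supplied.
#'
#' @param dim embedding width (default 320, matching the deployed node
#'   feature width).
#' @param window odd window length in residues (default 1).
#' @return An embedder object usable with [embed_sequence()].
#' @export
hashed_embedder <- function(dim = 320L, window = 1L) {
  stopifnot(dim >= 1L, window >= 1L, window %% 2L == 1L)
  cache <- new.env(parent = emptyenv())
  structure(list(name = "hashed", dim = as.integer(dim),
                 window = as.integer(window), cache = cache),
            class = "abpose_embedder")
}

# Deterministic vector for a window string: polynomial hash -> LCG stream.
hashed_vector <- function(key, dim) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483647
  state <- if (h == 0) 1 else h
  out <- numeric(dim)
  for (k in seq_len(dim)) {
    state <- (state * 48271) %% 2147483647  # Lehmer MINSTD
    out[k] <- state / 2147483647 - 0.5
  }
  out * sqrt(12)  # unit variance per component
}

#' Embed a residue sequence
#'
#' @param letters character vector of one-letter residue codes (unknowns as
#'   `"X"`), or a single string.
#' @param backend an embedder, e.g. [hashed_embedder()], or a precomputed
#'   numeric matrix with one row per residue (a protein-language-model
#'   embedding supplied externally).
#' @return An `N x dim` numeric matrix.
#' @export
embed_sequence <- function(letters, backend = hashed_embedder()) {
  if (length(letters) == 1L && nchar(letters) > 1L) {
    letters <- strsplit(letters, "")[[1]]
  }
  n <- length(letters)
  if (n == 0L) stop("empty sequence")
  if (is.matrix(backend)) {
    if (nrow(backend) != n) stop("embedding matrix rows != sequence length")
    return(backend)
  }
  stopifnot(inherits(backend, "abpose_embedder"))
  w <- backend$window
  half <- (w - 1L) %/% 2L
  padded <- c(rep("-", half), letters, rep("-", half))
  out <- matrix(0, n, backend$dim)
  for (i in seq_len(n)) {
    key <- paste0(padded[i:(i + w - 1L)], collapse = "")
    v <- backend$cache[[key]]
    if (is.null(v)) {
      v <- hashed_vector(key, backend$dim)
      assign(key, v, envir = backend$cache)
    }
    out[i, ] <- v
  }
  out
}

## ---- graph construction ----

#' Build the residue-level pose graph
#'
#' One node per residue. Intra-side edges connect residue pairs on the same
#' side (Ig or Ag, which may span several chains) with minimum atomic
#' distance at or below `tau_intra`; inter-side edges connect opposite-side
#' pairs at or below `tau_inter` (boundaries inclusive). Edge features are
#' the concatenated RBF expansions of the minimum-atom, Ca-Ca and centroid
#' distances. Node coordinates are Ca positions (centroid fallback). Masks:
#' `is_cdr` from the chain annotations, `is_interface` for endpoints of
#' inter edges, `is_cdr_epitope` for endpoints of inter edges whose Ig
#' endpoint lies in a CDR.
#'
#' @param tc a `typed_complex` from [assign_roles()].
#' @param config a [featurization_config()].
#' @param embedder node-embedding backend for [embed_sequence()].
#' @return An object of class `abpose_graph`.
#' @export
build_graph <- function(tc, config = featurization_config(),
                        embedder = hashed_embedder()) {
  stopifnot(inherits(tc, "typed_complex"))
  rt <- residue_table(tc)
  n <- nrow(rt)
  if (!all(c("ig", "ag") %in% rt$side)) stop("both sides required to build a graph")

  res <- vector("list", n)
  k <- 0L
  for (a in tc$annotations) {
    for (r in tc$structure$chains[[a$chain_id]]) {
      k <- k + 1L
      res[[k]] <- r
    }
  }
  ac <- lapply(res, residue_atom_coords, config = config)
  cents <- t(vapply(ac, residue_centroid, numeric(3),
                    mass_weighted = config$mass_weighted))
  radii <- vapply(seq_len(n), function(i) {
    sqrt(max(rowSums(sweep(ac[[i]]$xyz, 2L, cents[i, ])^2)))
  }, numeric(1))
  cas <- t(vapply(seq_len(n), function(i) {
    j <- match("CA", ac[[i]]$name)
    if (is.na(j)) c(NA_real_, NA_real_, NA_real_) else ac[[i]]$xyz[j, ]
  }, numeric(3)))
  ca_missing <- is.na(cas[, 1])
  if (any(ca_missing)) cas[ca_missing, ] <- cents[ca_missing, ]

  same_side <- outer(rt$side, rt$side, "==")
  tau <- ifelse(same_side, config$tau_intra, config$tau_inter)
  cd <- sqrt(cross_dist2(cents, cents))
  cand <- which(upper.tri(cd) & (cd - outer(radii, radii, "+") <= tau), arr.ind = TRUE)

  ei <- integer(0); ej <- integer(0); dmin <- numeric(0)
  if (nrow(cand) > 0L) {
    dm <- vapply(seq_len(nrow(cand)), function(q) {
      i <- cand[q, 1]; j <- cand[q, 2]
      sqrt(min(cross_dist2(ac[[i]]$xyz, ac[[j]]$xyz)))
    }, numeric(1))
    keep <- dm <= tau[cand]
    ei <- cand[keep, 1]; ej <- cand[keep, 2]; dmin <- dm[keep]
  }
  kind <- ifelse(rt$side[ei] == rt$side[ej], "intra", "inter")
  dca <- sqrt(rowSums((cas[ei, , drop = FALSE] - cas[ej, , drop = FALSE])^2))
  dcom <- cd[cbind(ei, ej)]
  feats <- cbind(rbf_expand(dmin, config), rbf_expand(dca, config),
                 rbf_expand(dcom, config))

  is_interface <- rep(FALSE, n)
  inter_idx <- which(kind == "inter")
  is_interface[c(ei[inter_idx], ej[inter_idx])] <- TRUE
  is_cdr_epitope <- rep(FALSE, n)
  for (q in inter_idx) {
    ig_end <- if (rt$side[ei[q]] == "ig") ei[q] else ej[q]
    if (rt$is_cdr[ig_end]) is_cdr_epitope[c(ei[q], ej[q])] <- TRUE
  }

  seqs <- vapply(res, function(r) {
    s <- AA3_TO_1[r$name3]; if (is.na(s)) "X" else s
  }, character(1))
  Xv <- embed_sequence(seqs, embedder)

  node_coords <- if (config$node_coord == "ca") cas else cents

  g <- structure(list(
    n_nodes = n,
    node_features = Xv,
    node_coords = node_coords,
    edges = data.frame(i = ei, j = ej, kind = kind, d_min = dmin,
                       d_ca = dca, d_com = dcom, stringsAsFactors = FALSE),
    edge_features = feats,
    node_side = rt$side,
    node_type_label = rt$node_type,
    is_cdr = rt$is_cdr,
    is_interface = is_interface,
    is_cdr_epitope = is_cdr_epitope,
    residue_keys = rt$key,
    config = config
  ), class = "abpose_graph")
  if (length(inter_idx) == 0L) {
    attr(g, "no_interface") <- TRUE
    warning("graph has zero inter-side edges (no interface)")
  }
  g
}

#' @export
print.abpose_graph <- function(x, ...) {
  cat("<abpose_graph> ", x$n_nodes, " nodes, ",
      sum(x$edges$kind == "intra"), " intra / ",
      sum(x$edges$kind == "inter"), " inter edges, ",
      sum(x$is_interface), " interface nodes\n", sep = "")
  invisible(x)
}

# Directed edge arrays (both orientations) for message passing.
graph_directed <- function(g) {
  e <- g$edges
  list(src = c(e$i, e$j), dst = c(e$j, e$i),
       feat = rbind(g$edge_features, g$edge_features))
}
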