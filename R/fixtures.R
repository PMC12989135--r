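# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic benchmark configuration
#'
#' Study conditions for the desk-scale synthetic benchmark: toy two-chain
#' Ig-Ag complexes with a contact-rich interface, rigid/noise-perturbed
#' cognate decoys whose DockQ labels span (0, 1) on both sides of the 0.8
#' positive threshold, non-cognate pairings labelled 0, and antigen-family
#' cluster structure for leakage-free splits.
#'
#' @param n_complexes number of native complexes (default 100).
#' @param residues_per_chain integer pair `c(ig, ag)` (default 30, 30 - a
#'   paratope/epitope-sized neighbourhood).
#' @param decoys_per_complex number of cognate decoys per native (default 8).
#' @param perturbation_schedule data frame with columns `rot_deg`,
#'   `trans_ang`, `noise_ang`: rigid rotation (degrees, about the interface
#'   centroid), rigid translation and per-atom Gaussian noise (Angstrom)
#'   applied to the Ig side, one decoy per row.
#' @param n_clusters number of antigen generator families (default 10).
#' @param noncognate_per_complex foreign-Ig pairings per complex (default 1).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_complexes = 100L,
                           residues_per_chain = c(ig = 30L, ag = 30L),
                           decoys_per_complex = 8L,
                           perturbation_schedule = default_perturbation_schedule(),
                           n_clusters = 10L,
                           noncognate_per_complex = 1L) {
  stopifnot(n_complexes >= 1L, all(residues_per_chain >= 4L),
            decoys_per_complex >= 1L, n_clusters >= 1L,
            all(perturbation_schedule$rot_deg >= 0),
            all(perturbation_schedule$trans_ang >= 0),
            all(perturbation_schedule$noise_ang >= 0))
  structure(list(n_complexes = as.integer(n_complexes),
                 residues_per_chain = as.integer(residues_per_chain),
                 decoys_per_complex = as.integer(decoys_per_complex),
                 perturbation_schedule = perturbation_schedule,
                 n_clusters = as.integer(n_clusters),
                 noncognate_per_complex = as.integer(noncognate_per_complex)),
            class = "fixture_config")
}

#' @rdname fixture_config
#' @export
default_perturbation_schedule <- function() {
  data.frame(
    rot_deg   = c(1,    1.5,  2.5,  5,    8,   10,   10,   10),
    trans_ang = c(0.2,  0.35, 0.5,  6.0,  9.0, 14.0, 25.0, 40.0),
    noise_ang = c(0.02, 0.04, 0.05, 0.15, 0.2,  0.3,  0.4,  0.5)
  )
}

## ---- chain geometry ----

unit3 <- function(v) v / sqrt(sum(v^2))

# Smooth random 3D curve with ~3.8 A spacing.
random_curve <- function(n, step = 3.8, wobble = 0.35) {
  pts <- matrix(0, n, 3L)
  dir <- unit3(rnorm(3))
  for (k in 2:n) {
    dir <- unit3(dir + wobble * rnorm(3))
    pts[k, ] <- pts[k - 1L, ] + step * dir
  }
  pts
}

# Pseudo-residue chain: backbone N/CA/C/O plus one side-chain atom, laid
# along a smooth curve. Returns a list of residues.
make_chain_residues <- function(n, seq_letters) {
  ca <- random_curve(n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    tgt <- if (i < n) unit3(ca[i + 1L, ] - ca[i, ]) else unit3(ca[i, ] - ca[i - 1L, ])
    ref <- if (abs(tgt[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    nrm <- unit3(pracma_cross(tgt, ref))
    bin <- unit3(pracma_cross(tgt, nrm))
    coords <- rbind(
      N  = ca[i, ] - 1.46 * tgt + 0.35 * nrm,
      CA = ca[i, ],
      C  = ca[i, ] + 1.52 * tgt + 0.35 * nrm,
      O  = ca[i, ] + 1.52 * tgt + 0.35 * nrm + 1.23 * bin,
      CB = ca[i, ] + 1.53 * nrm
    )
    name3 <- names(AA3_TO_1)[match(seq_letters[i], AA3_TO_1)]
    res[[i]] <- new_residue(name3, as.character(i), data.frame(
      name = rownames(coords), element = c("N", "C", "C", "O", "C"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1, altloc = "", is_hetatm = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  res
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

chain_atom_matrix <- function(res) {
  do.call(rbind, lapply(res, function(r) as.matrix(r$atoms[, c("x", "y", "z")])))
}

rotation_matrix <- function(axis, angle_rad) {
  a <- unit3(axis)
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(a)
}

transform_residues <- function(res, R = diag(3), shift = c(0, 0, 0),
                               center = c(0, 0, 0), noise = 0) {
  lapply(res, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2L, center) %*% t(R), 2L, center + shift, "+")
    if (noise > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = noise), ncol = 3L)
    r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
    r
  })
}

# Count cross-chain residue contact pairs (any heavy-atom pair <= cutoff)
# and the global minimum atom distance.
cross_contacts <- function(res_a, res_b, cutoff = 5) {
  A <- chain_atom_matrix(res_a); B <- chain_atom_matrix(res_b)
  d2 <- cross_dist2(A, B)
  na <- nrow(A) / 5L; nb <- nrow(B) / 5L
  ra <- rep(seq_len(na), each = 5L); rb <- rep(seq_len(nb), each = 5L)
  hit <- d2 <= cutoff^2
  pairs <- unique(cbind(ra[row(d2)[hit]], rb[col(d2)[hit]]))
  list(n_contacts = nrow(pairs), min_dist = sqrt(min(d2)))
}

# Rigidly pose `ig` residues against `ag` residues: orient the Ig chain
# mid-segment toward an outward-facing antigen residue and slide it in
# until the contact quota is met without steric collapse.
pose_ig_on_ag <- function(ig, ag, min_contacts = 10L, max_tries = 40L,
                          d_scan = seq(8, 3, by = -0.25), min_clearance = 1.8,
                          contact_cutoff = 5) {
  ag_ca <- t(vapply(ag, function(r) {
    unlist(r$atoms[r$atoms$name == "CA", c("x", "y", "z")], use.names = FALSE)
  }, numeric(3)))
  n_ag <- nrow(ag_ca)
  ig_ca <- t(vapply(ig, function(r) {
    unlist(r$atoms[r$atoms$name == "CA", c("x", "y", "z")], use.names = FALSE)
  }, numeric(3)))
  ig_mid <- ig_ca[nrow(ig_ca) %/% 2L, ]
  ig_cen <- colMeans(ig_ca)
  anchors <- seq.int(max(1L, n_ag %/% 4L), min(n_ag, (3L * n_ag) %/% 4L))
  for (try in seq_len(max_tries)) {
    mid <- if (try == 1L) n_ag %/% 2L else sample(anchors, 1L)
    u <- unit3(ag_ca[mid, ] - colMeans(ag_ca) + 0.3 * rnorm(3))
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    cand0 <- transform_residues(ig, R = R, center = ig_cen)
    c_mid <- sweep(matrix(ig_mid, 1L), 2L, ig_cen) %*% t(R) + ig_cen
    for (d in d_scan) {
      target <- ag_ca[mid, ] + d * u
      cand <- transform_residues(cand0, shift = target - drop(c_mid))
      cc <- cross_contacts(cand, ag, cutoff = contact_cutoff)
      if (cc$min_dist < min_clearance) break  # slid too far in; next approach
      if (cc$n_contacts >= min_contacts) return(cand)
    }
  }
  stop("failed to pose Ig chain with >= ", min_contacts,
       " interface contacts after ", max_tries, " attempts")
}

## ---- generator operations ----

# Internal: antigen residues for a family (deterministic per family seed)
# plus a per-complex jitter that keeps the family recognisable.
family_antigen <- function(n_res, family_seed, jitter_seed, jitter = 0.15) {
  base <- with_seed(family_seed, {
    letters <- sample(unname(AA3_TO_1), n_res, replace = TRUE)
    list(res = make_chain_residues(n_res, letters), letters = letters)
  })
  with_seed(jitter_seed, transform_residues(base$res, noise = jitter))
}

#' Generate a synthetic native Ig-Ag complex
#'
#' Two pseudo-residue chains (backbone N/CA/C/O plus one side-chain atom
#' per residue) on smooth random curves, posed so that at least ten
#' cross-side residue pairs are in 5-Angstrom heavy-atom contact. Chain "H"
#' carries the Ig (nanobody) role, chain "A" the antigen; synthetic CDR
#' intervals cover the Ig residues within 8 Angstrom of the antigen.
#' Deterministic given `(config, seed, cluster)`.
#'
#' @param config a [fixture_config()].
#' @param seed integer seed.
#' @param cluster antigen family index in `1..n_clusters` (default derived
#'   from `seed`).
#' @return A `typed_complex`.
#' @export
make_native_complex <- function(config = fixture_config(), seed = 1L,
                                cluster = ((seed - 1L) %% config$n_clusters) + 1L) {
  n_ig <- config$residues_per_chain[1]
  n_ag <- config$residues_per_chain[2]
  ag <- family_antigen(n_ag, family_seed = 7000L + cluster,
                       jitter_seed = 900000L + seed)
  with_seed(100000L + seed, {
    ig_letters <- sample(unname(AA3_TO_1), n_ig, replace = TRUE)
    ig <- make_chain_residues(n_ig, ig_letters)
    ig <- pose_ig_on_ag(ig, ag, min_contacts = 12L)
    tc <- typed_from_chains(ig, ag, source_id = paste0("synth_", seed))
    attr(tc, "cluster") <- cluster
    tc
  })
}

# Assemble a typed complex from posed Ig and Ag residue lists; CDR
# intervals are the contiguous runs of Ig residues within 8 A of the
# antigen.
typed_from_chains <- function(ig, ag, source_id) {
  s <- complex_structure(list(H = ig, A = ag), source_id = source_id)
  A <- chain_atom_matrix(ig); B <- chain_atom_matrix(ag)
  d2 <- cross_dist2(A, B)
  near <- apply(matrix(sqrt(apply(d2, 1L, min)), nrow = 5L), 2L, min) <= 8
  runs <- rle(near)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(starts[runs$values], ends[runs$values])
  cdr_txt <- paste(apply(iv, 1L, function(x) paste0(x[1], "-", x[2])), collapse = ";")
  ann <- data.frame(chain_id = c("H", "A"), role = c("nanobody", "antigen"),
                    cdr_intervals = c(cdr_txt, ""), stringsAsFactors = FALSE)
  assign_roles(s, ann)
}

#' Generate graded decoys of a native complex
#'
#' Applies each row of the perturbation schedule to the Ig side - a rigid
#' rotation about the interface centroid, a rigid translation along a
#' random direction, and per-atom Gaussian noise - and labels every decoy
#' with [dockq()] against the native. The default schedule spans DockQ
#' values across (0, 1), including both sides of the 0.8 threshold.
#'
#' @param native a `typed_complex` from [make_native_complex()].
#' @param config a [fixture_config()].
#' @param seed integer seed.
#' @return List of `list(complex, dockq)` per schedule row.
#' @export
make_decoys <- function(native, config = fixture_config(), seed = 1L) {
  sched <- config$perturbation_schedule
  ig <- native$structure$chains$H
  ag <- native$structure$chains$A
  A <- chain_atom_matrix(ig); B <- chain_atom_matrix(ag)
  d2 <- cross_dist2(A, B)
  iface <- which(d2 <= 25, arr.ind = TRUE)
  center <- if (nrow(iface) > 0L) {
    colMeans(rbind(A[unique(iface[, 1]), , drop = FALSE],
                   B[unique(iface[, 2]), , drop = FALSE]))
  } else colMeans(rbind(A, B))
  # translations act mainly along the local dissociation axis (from the
  # antigen-side to the Ig-side interface atoms), as pulling the binder off
  # the epitope is what degrades the interface; a small random tangential
  # component varies the path
  away <- if (nrow(iface) > 0L) {
    unit3(colMeans(A[unique(iface[, 1]), , drop = FALSE]) -
          colMeans(B[unique(iface[, 2]), , drop = FALSE]))
  } else {
    unit3(colMeans(A) - colMeans(B))
  }
  with_seed(200000L + seed, {
    lapply(seq_len(nrow(sched)), function(k) {
      R <- rotation_matrix(rnorm(3), sched$rot_deg[k] * pi / 180)
      shift <- sched$trans_ang[k] * unit3(away + 0.25 * rnorm(3))
      ig2 <- transform_residues(ig, R = R, shift = shift, center = center,
                                noise = sched$noise_ang[k])
      dec <- typed_from_chains(ig2, ag,
                               source_id = paste0(native$structure$source_id, "_d", k))
      list(complex = dec, dockq = dockq(dec, native))
    })
  })
}

#' Build the labelled synthetic benchmark
#'
#' Emits natives (label 1, DockQ 1), cognate decoys (label from the 0.8
#' DockQ rule), and non-cognate pairings (an Ig chain from a complex in a
#' different antigen cluster posed loosely against the antigen; label 0,
#' DockQ 0). Every example carries its antigen-cluster id and a group id
#' (the target complex) for listwise ranking, plus the featurized and
#' interface-sampled pose graph.
#'
#' @param config a [fixture_config()].
#' @param seed integer seed.
#' @param feat_config a [featurization_config()].
#' @param samp_config a [sampling_config()].
#' @param embedder node-embedding backend.
#' @return List of class `abpose_benchmark`; see [benchmark_manifest()].
#' @export
build_benchmark <- function(config = fixture_config(), seed = 1L,
                            feat_config = featurization_config(),
                            samp_config = sampling_config(),
                            embedder = hashed_embedder()) {
  if (config$n_clusters > config$n_complexes) {
    stop("n_clusters cannot exceed n_complexes")
  }
  natives <- lapply(seq_len(config$n_complexes), function(i) {
    make_native_complex(config, seed = seed * 1000L + i)
  })
  clusters <- vapply(natives, function(x) attr(x, "cluster"), numeric(1))

  # Far-displaced decoys can lose the interface entirely; those graphs are
  # kept whole (capped) rather than interface-sampled, so the model still
  # sees the tell-tale absence of inter-side edges.
  featurize <- function(tc) {
    g <- suppressWarnings(build_graph(tc, feat_config, embedder))
    if (!any(g$is_interface)) {
      keep <- seq_len(min(g$n_nodes, samp_config$node_cap))
      return(induce_subgraph(g, keep))
    }
    sample_subgraph(g, samp_config)
  }
  examples <- list()
  push <- function(id, tc, label, dq, cluster, group, kind) {
    examples[[length(examples) + 1L]] <<- list(
      id = id, graph = featurize(tc), label = as.integer(label),
      dockq = dq, cluster = as.integer(cluster), group = group, kind = kind
    )
  }
  for (i in seq_len(config$n_complexes)) {
    nat <- natives[[i]]
    push(paste0("c", i, "_native"), nat, 1L, 1.0, clusters[i], i, "native")
    decs <- make_decoys(nat, config, seed = seed * 1000L + i)
    for (k in seq_along(decs)) {
      dq <- decs[[k]]$dockq$dockq
      push(paste0("c", i, "_decoy", k), decs[[k]]$complex,
           label_from_dockq(dq), dq, clusters[i], i, "decoy")
    }
    if (config$noncognate_per_complex > 0L) {
      others <- which(clusters != clusters[i])
      for (k in seq_len(config$noncognate_per_complex)) {
        if (length(others) == 0L) break
        j <- others[((i + k - 2L) %% length(others)) + 1L]
        nc <- with_seed(300000L + seed * 1000L + i * 10L + k, {
          # non-cognate pairs lack shape complementarity: posed loosely,
          # grazing the epitope rather than docking into it
          ig <- pose_ig_on_ag(natives[[j]]$structure$chains$H,
                              nat$structure$chains$A,
                              min_contacts = 2L, min_clearance = 5.0,
                              contact_cutoff = 8,
                              d_scan = seq(12, 8.5, by = -0.5))
          typed_from_chains(ig, nat$structure$chains$A,
                            source_id = paste0("synth_nc_", i, "_", k))
        })
        push(paste0("c", i, "_noncog", k), nc, 0L, 0.0, clusters[i], i, "noncognate")
      }
    }
  }
  structure(examples, class = "abpose_benchmark", seed = seed, config = config)
}

#' Benchmark manifest table
#'
#' @param bench an `abpose_benchmark` from [build_benchmark()].
#' @return Tibble with columns `id`, `kind`, `label`, `dockq`, `cluster`,
#'   `group`, `n_nodes`.
#' @export
benchmark_manifest <- function(bench) {
  tibble::tibble(
    id = vapply(bench, `[[`, character(1), "id"),
    kind = vapply(bench, `[[`, character(1), "kind"),
    label = vapply(bench, `[[`, integer(1), "label"),
    dockq = vapply(bench, `[[`, numeric(1), "dockq"),
    cluster = vapply(bench, `[[`, integer(1), "cluster"),
    group = vapply(bench, function(x) as.integer(x$group), integer(1)),
    n_nodes = vapply(bench, function(x) x$graph$n_nodes, integer(1))
  )
}

#' Cluster-aware train/validation/test split
#'
#' Whole antigen clusters are assigned to splits by a seeded randomised
#' greedy size-balancing toward the target ratios; no cluster straddles
#' splits. Deterministic given the seed.
#'
#' @param examples an `abpose_benchmark` (or any list of examples carrying
#'   `$cluster`).
#' @param ratios target example-count fractions (default `c(0.6, 0.2, 0.2)`).
#' @param seed integer seed for the cluster ordering.
#' @return `list(train, val, test)` of example lists.
#' @export
split_by_cluster <- function(examples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  clusters <- vapply(examples, function(x) as.integer(x$cluster), integer(1))
  ucl <- unique(clusters)
  if (length(ucl) < 3L) stop("need at least 3 clusters to split")
  sizes <- table(factor(clusters, levels = ucl))
  # largest clusters first (better bin balance); seeded shuffle breaks size
  # ties so the assignment is randomised but reproducible
  ord <- with_seed(seed, {
    shuf <- sample(seq_along(ucl))
    shuf[order(sizes[shuf], decreasing = TRUE)]
  })
  total <- length(examples)
  assigned <- setNames(numeric(3), c("train", "val", "test"))
  membership <- setNames(character(length(ucl)), as.character(ucl))
  for (k in ord) {
    deficit <- ratios * total - assigned
    pick <- names(assigned)[which.max(deficit)]
    membership[as.character(ucl[k])] <- pick
    assigned[pick] <- assigned[pick] + sizes[k]
  }
  split_of <- membership[as.character(clusters)]
  list(train = examples[split_of == "train"],
       val = examples[split_of == "val"],
       test = examples[split_of == "test"])
}
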