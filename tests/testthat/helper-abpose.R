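# Shared fixtures and oracles, all built in code at test time.

# A 2-chain toy PDB: chain H (3 residues, 15 atoms), chain A (3 residues,
# 15 atoms). Includes one residue with A/B altlocs, one HETATM water and
# one MSE when requested.
write_toy_pdb <- function(path, altloc = FALSE, hetatm = FALSE, mse = FALSE) {
  fmt <- function(serial, name, alt, resn, chain, resno, x, y, z, occ,
                  el, type = "ATOM") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, el)
  }
  lines <- character(0)
  serial <- 0L
  emit <- function(...) {
    serial <<- serial + 1L
    lines <<- c(lines, fmt(serial, ...))
  }
  atoms <- list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"), c("CB", "C"))
  resns <- c("ALA", "GLY", "LEU")
  for (ch in c("H", "A")) {
    off <- if (ch == "H") 0 else 20
    for (r in 1:3) {
      for (k in seq_along(atoms)) {
        a <- atoms[[k]]
        x <- off + r * 4; y <- k * 1.4; z <- if (ch == "H") 0 else 3
        if (altloc && ch == "H" && r == 2 && a[1] == "CB") {
          emit(a[1], "A", resns[r], ch, r, x, y, z, 0.6, a[2])
          emit(a[1], "B", resns[r], ch, r, x + 0.5, y, z, 0.4, a[2])
        } else {
          emit(a[1], "", resns[r], ch, r, x, y, z, 1.00, a[2])
        }
      }
    }
  }
  if (mse) {
    emit("SE", "", "MSE", "A", 9, 5, 5, 5, 1.0, "SE", type = "HETATM")
  }
  if (hetatm) {
    emit("O", "", "HOH", "A", 101, 9, 9, 9, 1.0, "O", type = "HETATM")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Minimal mmCIF encoding of the same (altloc-free) toy complex.
write_toy_cif <- function(path) {
  hdr <- c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- character(0)
  serial <- 0L
  atoms <- list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"), c("CB", "C"))
  resns <- c("ALA", "GLY", "LEU")
  for (ch in c("H", "A")) {
    off <- if (ch == "H") 0 else 20
    for (r in 1:3) {
      for (k in seq_along(atoms)) {
        a <- atoms[[k]]
        serial <- serial + 1L
        x <- off + r * 4; y <- k * 1.4; z <- if (ch == "H") 0 else 3
        rows <- c(rows, sprintf(
          "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
          serial, a[2], a[1], resns[r], ch, r, x, y, z, r, resns[r], ch, a[1]))
      }
    }
  }
  writeLines(c(hdr, rows), path)
  path
}

toy_annotation <- function() {
  data.frame(chain_id = c("H", "A"), role = c("ig_heavy", "antigen"),
             cdr_intervals = c("2-3", ""), stringsAsFactors = FALSE)
}

# Build a residue directly from an atom coordinate table.
make_residue <- function(name3, seq_index, coords, names = NULL,
                         elements = NULL) {
  coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  n <- nrow(coords)
  if (is.null(names)) names <- c("CA", paste0("C", seq_len(max(0, n - 1))))[1:n]
  if (is.null(elements)) elements <- rep("C", n)
  new_residue_ext(name3, seq_index, data.frame(
    name = names, element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, altloc = "", is_hetatm = FALSE, stringsAsFactors = FALSE))
}

new_residue_ext <- function(name3, seq_index, atoms) {
  list(name3 = name3, seq_index = seq_index, atoms = atoms)
}

# Assemble a typed complex from per-chain residue lists and roles.
make_typed <- function(chains, roles, cdr = NULL) {
  s <- complex_structure(chains, source_id = "test")
  ann <- data.frame(chain_id = names(chains), role = roles,
                    cdr_intervals = if (is.null(cdr)) "" else cdr,
                    stringsAsFactors = FALSE)
  assign_roles(s, ann)
}

# Construct an abpose_graph directly from parts (for sampler/network tests).
toy_graph <- function(n, edges, side = rep(c("ig", "ag"), length.out = n),
                      kind = NULL, coords = NULL, dx = 4L,
                      is_cdr = rep(FALSE, n)) {
  edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  if (is.null(kind)) {
    kind <- ifelse(side[edges[, 1]] == side[edges[, 2]], "intra", "inter")
  }
  if (is.null(coords)) coords <- matrix(seq_len(n * 3), n, 3L) * 1.0
  d <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                     coords[edges[, 2], , drop = FALSE])^2))
  cfg <- featurization_config()
  feats <- cbind(rbf_expand(d, cfg), rbf_expand(d, cfg), rbf_expand(d, cfg))
  is_interface <- rep(FALSE, n)
  inter <- which(kind == "inter")
  is_interface[c(edges[inter, 1], edges[inter, 2])] <- TRUE
  is_ce <- rep(FALSE, n)
  for (q in inter) {
    ige <- if (side[edges[q, 1]] == "ig") edges[q, 1] else edges[q, 2]
    if (is_cdr[ige]) is_ce[c(edges[q, 1], edges[q, 2])] <- TRUE
  }
  structure(list(
    n_nodes = n,
    node_features = matrix(stats::rnorm(n * 320), n, 320L),
    node_coords = coords,
    edges = data.frame(i = edges[, 1], j = edges[, 2], kind = kind,
                       d_min = d, d_ca = d, d_com = d,
                       stringsAsFactors = FALSE),
    edge_features = feats,
    node_side = side,
    node_type_label = ifelse(side == "ig", "heavy", "antigen"),
    is_cdr = is_cdr,
    is_interface = is_interface,
    is_cdr_epitope = is_ce,
    residue_keys = paste0("k", seq_len(n)),
    config = featurization_config()
  ), class = "abpose_graph")
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

rigid_transform_graph <- function(g, R, t) {
  g$node_coords <- g$node_coords %*% t(R) +
    matrix(t, g$n_nodes, 3L, byrow = TRUE)
  g
}

# Apply a node permutation to a graph (relabels edges and masks).
permute_graph <- function(g, perm) {
  inv <- order(perm)  # inv[old] = new position
  out <- g
  out$node_features <- g$node_features[perm, , drop = FALSE]
  out$node_coords <- g$node_coords[perm, , drop = FALSE]
  out$node_side <- g$node_side[perm]
  out$node_type_label <- g$node_type_label[perm]
  out$is_cdr <- g$is_cdr[perm]
  out$is_interface <- g$is_interface[perm]
  out$is_cdr_epitope <- g$is_cdr_epitope[perm]
  out$residue_keys <- g$residue_keys[perm]
  out$edges$i <- inv[g$edges$i]
  out$edges$j <- inv[g$edges$j]
  out
}

# Small shared synthetic benchmark, built once per test session.
small_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_benchmark(
        fixture_config(n_complexes = 12L, n_clusters = 4L,
                       residues_per_chain = c(16L, 16L)),
        seed = 3L)
    }
    cache
  }
})

small_encoder <- function() {
  encoder_config(n_layers = 2L, hidden_dim = 16L, input_dim = 320L,
                 edge_dim = 30L, dropout = 0.1)
}

# Independently coded DockQ reference: brute-force residue-pair contact
# loops and bio3d-based superpositions, sharing no code with the package
# implementation beyond the typed-complex container.
reference_dockq <- function(model, native) {
  flat <- function(tc) {
    out <- list()
    for (a in tc$annotations) {
      for (r in tc$structure$chains[[a$chain_id]]) {
        at <- r$atoms[!(r$atoms$element %in% c("H", "D")), , drop = FALSE]
        out[[paste0(a$chain_id, ":", r$seq_index)]] <-
          list(side = a$side, name = at$name,
               xyz = as.matrix(at[, c("x", "y", "z")]))
      }
    }
    out
  }
  fm <- flat(model); fn <- flat(native)
  keys_ig <- names(fn)[vapply(fn, function(r) r$side == "ig", logical(1))]
  keys_ag <- names(fn)[vapply(fn, function(r) r$side == "ag", logical(1))]
  pair_min <- function(f, ki, kj) {
    min(vapply(seq_len(nrow(f[[ki]]$xyz)), function(q) {
      min(sqrt(colSums((t(f[[kj]]$xyz) - f[[ki]]$xyz[q, ])^2)))
    }, numeric(1)))
  }
  contacts <- function(f, cutoff) {
    hits <- character(0)
    for (ki in keys_ig) for (kj in keys_ag) {
      if (!is.null(f[[ki]]) && !is.null(f[[kj]]) &&
          pair_min(f, ki, kj) <= cutoff) {
        hits <- c(hits, paste(ki, kj))
      }
    }
    hits
  }
  natc <- contacts(fn, 5)
  modc <- contacts(fm, 5)
  fnat <- length(intersect(natc, modc)) / length(natc)

  bb_xyz <- function(f, keys) {
    do.call(rbind, lapply(keys, function(k) {
      r <- f[[k]]
      sel <- match(c("N", "CA", "C", "O"), r$name)
      sel <- sel[!is.na(sel)]
      cbind(r$xyz[sel, , drop = FALSE], which = paste(k, r$name[sel]))
    }))
  }
  align_rmsd <- function(fit_keys, measure_keys) {
    Ma <- bb_xyz(fm, fit_keys); Na <- bb_xyz(fn, fit_keys)
    common <- intersect(Ma[, 4], Na[, 4])
    A <- matrix(as.numeric(Ma[match(common, Ma[, 4]), 1:3]), ncol = 3)
    B <- matrix(as.numeric(Na[match(common, Na[, 4]), 1:3]), ncol = 3)
    Mm <- bb_xyz(fm, measure_keys); Nm <- bb_xyz(fn, measure_keys)
    common2 <- intersect(Mm[, 4], Nm[, 4])
    Am <- matrix(as.numeric(Mm[match(common2, Mm[, 4]), 1:3]), ncol = 3)
    Bm <- matrix(as.numeric(Nm[match(common2, Nm[, 4]), 1:3]), ncol = 3)
    # superpose via bio3d on the fit set, then measure
    xyz_fixed <- as.numeric(t(B))
    xyz_mobile <- as.numeric(t(rbind(A, Am)))
    fitted <- bio3d::fit.xyz(fixed = xyz_fixed, mobile = xyz_mobile,
                             fixed.inds = seq_along(xyz_fixed),
                             mobile.inds = seq_len(length(as.numeric(t(A)))))
    moved <- matrix(fitted, ncol = 3, byrow = TRUE)
    Am2 <- moved[nrow(A) + seq_len(nrow(Am)), , drop = FALSE]
    sqrt(mean(rowSums((Am2 - Bm)^2)))
  }
  lrms <- align_rmsd(keys_ag, keys_ig)
  iface <- unique(unlist(strsplit(contacts(fn, 10), " ")))
  irms <- align_rmsd(iface, iface)
  dq <- (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
  list(fnat = fnat, irms = irms, lrms = lrms, dockq = dq)
}

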