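#' Interface subgraph sampling configuration
#'
#' @param k_hops number of breadth-first hops from the seed set (default 3).
#' @param node_cap maximum number of nodes in the sampled subgraph
#'   (default 600).
#' @param seed_mode `"interface"` (seeds are the unique endpoints of
#'   inter-side edges) or `"cdr"` (seeds are CDR residues).
#' @param edge_kinds which edge kinds hops may traverse (default both).
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(k_hops = 3L, node_cap = 600L,
                            seed_mode = c("interface", "cdr"),
                            edge_kinds = c("intra", "inter")) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(k_hops >= 0L, node_cap >= 1L,
            all(edge_kinds %in% c("intra", "inter")))
  structure(list(k_hops = as.integer(k_hops), node_cap = as.integer(node_cap),
                 seed_mode = seed_mode, edge_kinds = edge_kinds),
            class = "sampling_config")
}

#' Seed nodes for subgraph sampling
#'
#' @param g an `abpose_graph`.
#' @param seed_mode `"interface"` or `"cdr"`.
#' @return Sorted integer vector of seed node indices.
#' @export
seed_nodes <- function(g, seed_mode = c("interface", "cdr")) {
  seed_mode <- match.arg(seed_mode)
  s <- if (seed_mode == "interface") which(g$is_interface) else which(g$is_cdr)
  if (length(s) == 0L) stop("no seeds available in mode '", seed_mode, "'")
  sort(s)
}

#' Extract the k-hop interface subgraph
#'
#' Breadth-first expansion from the seed set, hop by hop, over the permitted
#' edge kinds. Expansion halts once adding a hop would exceed the node cap:
#' within the violating hop, nodes are admitted in ascending node-index
#' order until the cap is exactly reached. The induced subgraph (all edges
#' between retained nodes) is returned with masks, features and coordinates
#' re-indexed; `residue_keys` preserve the mapping back to the parent graph.
#'
#' @param g an `abpose_graph`.
#' @param config a [sampling_config()].
#' @return An `abpose_graph` over the retained nodes.
#' @export
sample_subgraph <- function(g, config = sampling_config()) {
  seeds <- seed_nodes(g, config$seed_mode)
  cap <- config$node_cap
  if (length(seeds) > cap) seeds <- seeds[seq_len(cap)]

  e <- g$edges[g$edges$kind %in% config$edge_kinds, , drop = FALSE]
  nbr <- split(c(e$j, e$i), c(e$i, e$j))

  keep <- seeds
  frontier <- seeds
  hops <- 0L
  while (hops < config$k_hops && length(keep) < cap && length(frontier) > 0L) {
    nxt <- unique(unlist(nbr[as.character(frontier)], use.names = FALSE))
    nxt <- sort(setdiff(nxt, keep))
    if (length(nxt) == 0L) break
    room <- cap - length(keep)
    if (length(nxt) > room) nxt <- nxt[seq_len(room)]
    keep <- c(keep, nxt)
    frontier <- nxt
    hops <- hops + 1L
  }
  keep <- sort(keep)
  induce_subgraph(g, keep)
}

# Induced subgraph on sorted node index vector `keep`.
induce_subgraph <- function(g, keep) {
  remap <- integer(g$n_nodes)
  remap[keep] <- seq_along(keep)
  e <- g$edges
  sel <- e$i %in% keep & e$j %in% keep
  e2 <- e[sel, , drop = FALSE]
  e2$i <- remap[e2$i]
  e2$j <- remap[e2$j]
  rownames(e2) <- NULL
  out <- g
  out$n_nodes <- length(keep)
  out$node_features <- g$node_features[keep, , drop = FALSE]
  out$node_coords <- g$node_coords[keep, , drop = FALSE]
  out$edges <- e2
  out$edge_features <- g$edge_features[sel, , drop = FALSE]
  out$node_side <- g$node_side[keep]
  out$node_type_label <- g$node_type_label[keep]
  out$is_cdr <- g$is_cdr[keep]
  out$is_interface <- g$is_interface[keep]
  out$is_cdr_epitope <- g$is_cdr_epitope[keep]
  out$residue_keys <- g$residue_keys[keep]
  out
}
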