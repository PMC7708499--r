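# Directed weighted multiplex networks: one layer per interaction type over a
# common node set, entries in [0, 1] (weighted mode), diagonal zero.

#' Build a 4-layer multiplex network for one group
#'
#' @param index_table A `dyad_index_table` (run [normalize_weighted()] first
#'   when `weight = "weighted"`).
#' @param group Group label to extract.
#' @param weight `"index"` (raw proportions) or `"weighted"`
#'   (layer-max-normalized values in `[0, 1]`).
#' @return A `multiplex` object: list with `nodes` (ordered id vector),
#'   `layers` (named list of N x N matrices, entry (i, j) = sender-i ->
#'   receiver-j weight) and `layer_names`.
#' @export
build_multiplex <- function(index_table, group, weight = c("index", "weighted")) {
  weight <- match.arg(weight)
  tab <- index_table[index_table$group == group, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for group ", group, call. = FALSE)
  if (weight == "weighted" && anyNA(tab$weighted)) {
    stop("weighted values missing; run normalize_weighted() first",
         call. = FALSE)
  }
  nodes <- sort(unique(c(tab$sender, tab$receiver)))
  n <- length(nodes)
  expected <- n * (n - 1L)
  layers <- lapply(.layer_names, function(l) {
    rows <- tab[tab$layer == l, , drop = FALSE]
    if (nrow(rows) != expected) {
      stop("layer ", l, " of group ", group, " has ", nrow(rows),
           " dyad rows; expected ", expected, call. = FALSE)
    }
    m <- matrix(0, n, n, dimnames = list(nodes, nodes))
    m[cbind(match(rows$sender, nodes), match(rows$receiver, nodes))] <-
      rows[[weight]]
    m
  })
  names(layers) <- .layer_names
  structure(list(nodes = nodes, layers = layers, layer_names = .layer_names),
            class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat("multiplex network:", length(x$nodes), "nodes,",
      length(x$layers), "layers\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  multiplex density:", round(multiplex_density(x), 3), "\n")
  invisible(x)
}

#' Layer and multiplex edge densities
#'
#' An edge is present when its directed weight is strictly positive. The
#' density of a layer is the present-edge fraction of the N(N-1) possible
#' directed edges; the multiplex density pools present edges over all layers
#' (N(N-1)L possible edges).
#'
#' @param layer An N x N adjacency matrix.
#' @return Proportion in `[0, 1]`.
#' @export
layer_density <- function(layer) {
  n <- nrow(layer)
  off <- layer[row(layer) != col(layer)]
  sum(off > 0) / (n * (n - 1L))
}

#' @rdname layer_density
#' @param net A `multiplex` object.
#' @export
multiplex_density <- function(net) {
  mean(vapply(net$layers, layer_density, numeric(1)))
}

#' Multiplex density from a present-edge count
#'
#' @param n_present Number of present directed edges over all layers.
#' @param n_nodes,n_layers Multiplex dimensions.
#' @return Proportion of the `n_nodes * (n_nodes - 1) * n_layers` possible
#'   edges that are present.
#' @export
multiplex_density_from_counts <- function(n_present, n_nodes, n_layers) {
  possible <- n_nodes * (n_nodes - 1L) * n_layers
  if (n_present < 0 || n_present > possible) {
    stop("present-edge count must lie in [0, ", possible, "]", call. = FALSE)
  }
  n_present / possible
}

#' Node strength
#'
#' Sum of in- and out-edge weights incident to each node of a directed
#' weighted layer.
#'
#' @param layer An N x N adjacency matrix.
#' @param node Optional node name or index; default: all nodes.
#' @return Named numeric vector (or scalar).
#' @export
strength <- function(layer, node = NULL) {
  s <- rowSums(layer) + colSums(layer)
  if (!is.null(node)) s[node] else s
}

#' Eigenvector centrality of one layer
#'
#' Leading eigenvector of the symmetrized adjacency `(A + t(A)) / 2`,
#' rescaled so the maximum score is 1. Accounts for edge weights and indirect
#' connections; suited to small, densely connected groups. An all-zero layer
#' yields all-zero scores with a warning.
#'
#' @param layer An N x N adjacency matrix.
#' @return Named numeric vector of scores in `[0, 1]` with max 1 (or all 0).
#' @export
eigenvector_centrality <- function(layer) {
  m <- (layer + t(layer)) / 2
  if (all(m == 0)) {
    warning("layer has no edges; eigenvector centrality undefined, ",
            "returning zeros", call. = FALSE)
    return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  }
  v <- abs(eigen(m, symmetric = TRUE)$vectors[, 1L])
  stats::setNames(v / max(v), rownames(m))
}

#' Aggregate multiplex layers
#'
#' Element-wise sum of a subset of layer adjacency matrices.
#'
#' @param net A `multiplex` object.
#' @param layers Layer names or indices (default: all).
#' @return A single N x N matrix.
#' @export
aggregate_layers <- function(net, layers = net$layer_names) {
  if (length(layers) == 0L) stop("layer subset must be nonempty", call. = FALSE)
  Reduce(`+`, net$layers[layers])
}

#' Eigenvector versatility of a multiplex network
#'
#' Multilayer analogue of eigenvector centrality: the leading eigenvector of
#' the NL x NL supra-adjacency matrix whose diagonal blocks are the
#' symmetrized layers and whose off-diagonal blocks couple each node's layer
#' replicas with a uniform (categorical) weight `omega`. Per-node scores sum
#' the replica entries and are rescaled to max 1.
#'
#' @param net A `multiplex` object with at least two layers.
#' @param omega Positive interlayer coupling weight.
#' @return Named numeric vector of scores in `[0, 1]` with max 1.
#' @export
eigenvector_versatility <- function(net, omega = 1) {
  if (omega <= 0) stop("interlayer coupling omega must be positive",
                       call. = FALSE)
  L <- length(net$layers)
  if (L < 2L) stop("versatility requires at least two layers", call. = FALSE)
  n <- length(net$nodes)
  supra <- matrix(0, n * L, n * L)
  for (a in seq_len(L)) {
    ia <- (a - 1L) * n + seq_len(n)
    supra[ia, ia] <- (net$layers[[a]] + t(net$layers[[a]])) / 2
    for (b in seq_len(L)) {
      if (a == b) next
      ib <- (b - 1L) * n + seq_len(n)
      supra[cbind(ia, ib)] <- omega
    }
  }
  v <- abs(eigen(supra, symmetric = TRUE)$vectors[, 1L])
  score <- rowSums(matrix(v, nrow = n, ncol = L))
  stats::setNames(score / max(score), net$nodes)
}

#' Edge overlap between layers
#'
#' Jaccard overlap of directed edge presence: shared present edges divided by
#' the union of present edges. The global overlap of a multiplex is the
#' fraction of edges present in every layer relative to those present in any
#' layer.
#'
#' @param layer_a,layer_b N x N adjacency matrices over the same node set.
#' @return Proportion in `[0, 1]`; 0 (with a warning) when both layers are
#'   empty.
#' @export
edge_overlap <- function(layer_a, layer_b) {
  off <- row(layer_a) != col(layer_a)
  a <- layer_a > 0 & off
  b <- layer_b > 0 & off
  union <- sum(a | b)
  if (union == 0L) {
    warning("both layers are empty; edge overlap defined as 0", call. = FALSE)
    return(0)
  }
  sum(a & b) / union
}

#' @rdname edge_overlap
#' @param net A `multiplex` object.
#' @export
global_edge_overlap <- function(net) {
  off <- row(net$layers[[1L]]) != col(net$layers[[1L]])
  pres <- lapply(net$layers, function(m) m > 0 & off)
  union <- sum(Reduce(`|`, pres))
  if (union == 0L) {
    warning("all layers are empty; global edge overlap defined as 0",
            call. = FALSE)
    return(0)
  }
  sum(Reduce(`&`, pres)) / union
}

#' Pairwise edge-overlap matrix
#'
#' @param net A `multiplex` object.
#' @return Symmetric L x L matrix of pairwise Jaccard edge overlaps.
#' @export
edge_overlap_matrix <- function(net) {
  L <- length(net$layers)
  m <- matrix(1, L, L, dimnames = list(names(net$layers), names(net$layers)))
  for (a in seq_len(L - 1L)) {
    for (b in seq(a + 1L, L)) {
      m[a, b] <- m[b, a] <- edge_overlap(net$layers[[a]], net$layers[[b]])
    }
  }
  m
}

#' Export multiplex layers as GraphML
#'
#' Writes one directed weighted GraphML file per layer.
#'
#' @param net A `multiplex` object.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_multiplex_graphml <- function(net, dir, prefix = "layer") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (l in names(net$layers)) {
    g <- igraph::graph_from_adjacency_matrix(net$layers[[l]], mode = "directed",
                                             weighted = TRUE)
    path <- file.path(dir, paste0(prefix, "_", l, ".graphml"))
    igraph::write_graph(g, path, format = "graphml")
    paths <- c(paths, path)
  }
  invisible(paths)
}
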