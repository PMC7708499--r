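# Spectral layer comparison: Von Neumann graph entropy, quantum
# Jensen-Shannon divergence and structural reducibility.
#
# Directed layers are symmetrized as (A + t(A)) / 2 for all spectral
# computations; the Laplacian-spectrum entropy requires a symmetric operator.
# Logarithms are base 2 throughout, so entropies are in bits.

# Trace-rescaled Laplacian ("density matrix") of a layer.
.density_matrix <- function(layer) {
  m <- (layer + t(layer)) / 2
  lap <- diag(rowSums(m)) - m
  tr <- sum(diag(lap))
  if (tr <= 0) stop("layer has zero total weight; entropy undefined",
                    call. = FALSE)
  lap / tr
}

# Shannon entropy (bits) of the eigenvalue spectrum of a unit-trace
# symmetric positive semi-definite operator.
.spectral_entropy <- function(rho) {
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) {
    stop("operator has substantially negative eigenvalues", call. = FALSE)
  }
  ev <- ev[ev > 0]
  -sum(ev * log2(ev))
}

#' Von Neumann entropy of a network layer
#'
#' Shannon entropy (base 2) of the symmetrized weighted graph Laplacian's
#' eigenvalues rescaled to sum to one, with `0 * log(0) := 0`. A spectral
#' complexity measure: 0 bits for a single-edge graph, `log2(n - 1)` bits for
#' the complete graph on `n` nodes, and invariant under multiplying all
#' weights by a positive constant.
#'
#' @param layer An N x N adjacency matrix with positive total weight.
#' @return Entropy in bits (>= 0).
#' @export
von_neumann_entropy <- function(layer) {
  .spectral_entropy(.density_matrix(layer))
}

#' Quantum Jensen-Shannon distance between two layers
#'
#' Square root of the quantum Jensen-Shannon divergence between the
#' trace-rescaled Laplacians of two layers:
#' `D = sqrt(h((rho_A + rho_B) / 2) - (h(rho_A) + h(rho_B)) / 2)`.
#' Symmetric, zero for identical structures, bounded by 1 (base-2
#' logarithms); layers whose nodes connect similarly score close to 0.
#'
#' @param layer_a,layer_b N x N adjacency matrices with positive total
#'   weight, over the same node set.
#' @return Distance in `[0, 1]`.
#' @export
quantum_jsd <- function(layer_a, layer_b) {
  rho_a <- .density_matrix(layer_a)
  rho_b <- .density_matrix(layer_b)
  d2 <- .spectral_entropy((rho_a + rho_b) / 2) -
    (.spectral_entropy(rho_a) + .spectral_entropy(rho_b)) / 2
  sqrt(max(d2, 0))
}

#' Pairwise quantum Jensen-Shannon distance matrix
#'
#' @param net A `multiplex` object.
#' @return Symmetric L x L distance matrix with zero diagonal.
#' @export
jsd_matrix <- function(net) {
  L <- length(net$layers)
  m <- matrix(0, L, L, dimnames = list(names(net$layers), names(net$layers)))
  for (a in seq_len(L - 1L)) {
    for (b in seq(a + 1L, L)) {
      m[a, b] <- m[b, a] <- quantum_jsd(net$layers[[a]], net$layers[[b]])
    }
  }
  m
}

#' Structural reducibility of a multiplex network
#'
#' Greedy layer aggregation guided by spectral similarity: the pairwise
#' quantum Jensen-Shannon distance matrix is clustered hierarchically (Ward
#' linkage), and at each of the L - 1 merge steps the two most similar
#' layer sets are aggregated by summation. After each step the relative
#' entropy `q = 1 - mean(h(layer)) / h(aggregate)` measures how
#' distinguishable the current layer set remains from the fully aggregated
#' network; the optimal representation is the layer count maximizing `q`.
#' By construction `q = 0` at full aggregation.
#'
#' @param net A `multiplex` object with L >= 2 layers, all with positive
#'   total weight.
#' @return A `reducibility` object: list with `jsd_matrix`, `merge_sequence`
#'   (data frame: step, merged pair, linkage height), `relative_entropy`
#'   (named vector indexed by layer count, L down to 1) and
#'   `optimal_n_layers`.
#' @export
reducibility <- function(net) {
  L <- length(net$layers)
  if (L < 2L) stop("reducibility requires at least two layers", call. = FALSE)
  jsd <- jsd_matrix(net)
  hc <- stats::hclust(stats::as.dist(jsd), method = "ward.D2")
  h_agg <- von_neumann_entropy(aggregate_layers(net))

  rel_entropy <- function(mats) {
    1 - mean(vapply(mats, von_neumann_entropy, numeric(1))) / h_agg
  }
  # replay the merge sequence, aggregating matrices by summation
  cluster_mats <- net$layers
  cluster_labs <- as.list(names(net$layers))
  merged <- vector("list", L - 1L)  # row i: product of hclust step i
  merged_labs <- vector("list", L - 1L)
  curve <- stats::setNames(numeric(L), as.character(L:1))
  curve[as.character(L)] <- rel_entropy(cluster_mats)
  steps <- data.frame(step = integer(), merged = character(),
                      height = numeric(), stringsAsFactors = FALSE)
  active <- seq_len(L)  # indices into cluster_mats still unmerged
  for (st in seq_len(L - 1L)) {
    pick <- function(code) {
      if (code < 0L) {
        list(mat = net$layers[[-code]], lab = names(net$layers)[-code],
             drop = -code)
      } else {
        list(mat = merged[[code]], lab = merged_labs[[code]], drop = NA)
      }
    }
    a <- pick(hc$merge[st, 1L]); b <- pick(hc$merge[st, 2L])
    merged[[st]] <- a$mat + b$mat
    merged_labs[[st]] <- paste(sort(c(a$lab, b$lab)), collapse = "+")
    # current layer set: original layers not yet merged + live merge products
    used <- unlist(lapply(seq_len(st), function(i) {
      codes <- hc$merge[i, ]
      -codes[codes < 0L]
    }))
    live_products <- setdiff(seq_len(st), hc$merge[seq_len(st), ][
      hc$merge[seq_len(st), ] > 0L])
    mats <- c(net$layers[setdiff(seq_len(L), used)], merged[live_products])
    curve[as.character(L - st)] <- rel_entropy(mats)
    steps <- rbind(steps, data.frame(
      step = st, merged = merged_labs[[st]], height = hc$height[st],
      stringsAsFactors = FALSE))
  }
  # parsimony tie-break: smallest layer count within tolerance of the max
  best <- curve >= max(curve) - 1e-9
  structure(list(jsd_matrix = jsd, merge_sequence = steps,
                 relative_entropy = curve,
                 optimal_n_layers = min(as.integer(names(curve)[best])),
                 hclust = hc),
            class = "reducibility")
}

#' @export
print.reducibility <- function(x, ...) {
  cat("structural reducibility:", nrow(x$merge_sequence), "merge steps\n")
  for (i in seq_len(nrow(x$merge_sequence))) {
    cat(sprintf("  step %d: %s (height %.4f)\n", x$merge_sequence$step[i],
                x$merge_sequence$merged[i], x$merge_sequence$height[i]))
  }
  cat("relative entropy by layer count:\n")
  print(round(x$relative_entropy, 4))
  cat("optimal number of layers:", x$optimal_n_layers, "\n")
  invisible(x)
}
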