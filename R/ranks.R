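# Per-ring centrality report: eigenvector scores and ranks for each layer,
# the aggregate and the multiplex (versatility) ring.

#' Centrality and versatility rank report
#'
#' Computes max-normalized eigenvector scores for every "ring" of a multiplex
#' network -- each layer, the fully aggregated network and the multiplex
#' (eigenvector versatility) -- together with dense ranks (ties share a rank)
#' and a ring ordering by similarity (Spearman rank correlation with the
#' versatility ring).
#'
#' @param net A `multiplex` object (N >= 2 nodes).
#' @param omega Interlayer coupling for the versatility ring.
#' @return A `centrality_report`: list with `scores` (N x R matrix), `ranks`
#'   (dense ranks, 1 = highest score), `strength` (per-layer node strength),
#'   `ring_cor` (Spearman correlation matrix between rings) and `ring_order`.
#' @export
rank_report <- function(net, omega = 1) {
  if (length(net$nodes) < 2L) stop("rank report requires at least two nodes",
                                   call. = FALSE)
  scores <- vapply(net$layers, eigenvector_centrality,
                   numeric(length(net$nodes)))
  agg <- aggregate_layers(net)
  scores <- cbind(scores, aggregate = eigenvector_centrality(agg),
                  multiplex = eigenvector_versatility(net, omega))
  dense_rank <- function(s) match(-s, sort(unique(-s)))
  ranks <- apply(scores, 2L, dense_rank)
  rownames(ranks) <- rownames(scores)
  ring_cor <- suppressWarnings(stats::cor(scores, method = "spearman"))
  ord <- order(-ring_cor[, "multiplex"])
  structure(list(scores = scores, ranks = ranks,
                 strength = vapply(net$layers, strength,
                                   numeric(length(net$nodes))),
                 ring_cor = ring_cor,
                 ring_order = colnames(scores)[ord]),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("centrality report (", nrow(x$scores), " nodes, ", ncol(x$scores),
      " rings)\n", sep = "")
  cat("ring order by similarity to the multiplex ring:\n  ",
      paste(x$ring_order, collapse = ", "), "\n", sep = "")
  cat("versatility ranks:\n")
  print(sort(x$ranks[, "multiplex"]))
  invisible(x)
}
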