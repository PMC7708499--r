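# The four mutually exclusive dyadic interaction indices.
#
# Per ordered within-group dyad (sender a, receiver b) and scan, at most one of
# the following is credited:
#   stationary_vicinity     beyond arm's reach but within 5 m, height-level
#                           difference at most 1, no interaction (symmetric)
#   affiliative             a directs affiliative behaviour at b (directed)
#   grooming                a grooms b (directed; mutual grooming credits both
#                           directions)
#   passive_close_proximity within arm's reach, no interaction (symmetric)
# Each index is the credited scan count divided by the number of scans the two
# individuals had access to each other.

.layer_names <- c("stationary_vicinity", "affiliative", "grooming",
                  "passive_close_proximity")

#' Planar Euclidean distance
#'
#' @param p,q Numeric length-2 vectors of planar coordinates in metres.
#' @return Distance in metres.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != 2L || length(q) != 2L || anyNA(p) || anyNA(q)) {
    stop("both positions must be complete (x, y) coordinates", call. = FALSE)
  }
  sqrt(sum((p - q)^2))
}

# Exclusive per-pair channel counts for one group. PCP = arm's reach union
# minus interacting scans; SV already excludes arm's reach and interaction.
.pair_counts <- function(arr) {
  ch <- .pair_channels(arr)
  list(sv = rowSums(ch$sv),
       pcp = rowSums(ch$arm & !ch$interact),
       channels = ch)
}

#' Count stationary-vicinity scans for one dyad
#'
#' Scans where the two individuals were beyond arm's reach but within 5 m of
#' each other, at most one height level apart, and not interacting. Requires
#' both individuals visible with mapped positions; scans lacking positions
#' never contribute.
#'
#' @param records Scan records.
#' @param a,b Individual ids.
#' @return Integer scan count (symmetric in `a`, `b`).
#' @export
count_stationary_vicinity <- function(records, a, b) {
  .pair_count_one(records, a, b, "sv")
}

#' Count passive-close-proximity scans for one dyad
#'
#' Scans where the dyad was within an arm's reach (union of the two
#' individuals' arms-reach annotations) without interacting.
#'
#' @inheritParams count_stationary_vicinity
#' @return Integer scan count (symmetric in `a`, `b`).
#' @export
count_passive_close_proximity <- function(records, a, b) {
  .pair_count_one(records, a, b, "pcp")
}

.pair_count_one <- function(records, a, b, what) {
  g <- unique(records$group[records$individual %in% c(a, b)])
  if (length(g) != 1L) stop("dyad must belong to a single group", call. = FALSE)
  arr <- .scan_arrays(records, g)
  i <- match(a, arr$ids); j <- match(b, arr$ids)
  p <- which(arr$pairs[, 1L] == min(i, j) & arr$pairs[, 2L] == max(i, j))
  ch <- .pair_channels(arr)
  if (what == "sv") sum(ch$sv[p, ]) else sum(ch$arm[p, ] & !ch$interact[p, ])
}

#' Count directed interaction scans
#'
#' Scans where `sender`'s recorded behavior is `class` with `receiver` as the
#' partner. Mutual grooming scans increment both directions.
#'
#' @param records Scan records.
#' @param sender,receiver Individual ids (distinct).
#' @param class `"affiliative"` or `"grooming"`.
#' @return Integer scan count.
#' @export
count_directed <- function(records, sender, receiver,
                           class = c("affiliative", "grooming")) {
  class <- match.arg(class)
  if (sender == receiver) stop("sender and receiver must differ", call. = FALSE)
  rows <- records$individual == sender & records$behavior == class &
    !is.na(records$partner) & records$partner == receiver
  sum(rows)
}

#' Compute the dyadic interaction index table
#'
#' Produces the long-format table of all four interaction indices for every
#' ordered within-group dyad: credited scan count, access denominator and the
#' index (count / denominator). Symmetric layers (stationary vicinity, passive
#' close proximity) carry identical values in both directions of a dyad.
#'
#' @param records Scan records (all groups).
#' @param roster Roster; defines the node set per group (individuals without
#'   records still appear, with zero counts).
#' @return Data frame with columns
#'   `group, sender, receiver, layer, count, denominator, index, weighted`
#'   (`weighted` is `NA` until [normalize_weighted()] is applied). A 7-individual
#'   group yields 42 ordered dyads x 4 layers = 168 rows.
#' @export
compute_indices <- function(records, roster) {
  out <- list()
  for (g in unique(roster$group)) {
    ids_g <- roster$id[roster$group == g]
    rec_g <- records[records$group == g, , drop = FALSE]
    extra <- setdiff(unique(rec_g$individual), ids_g)
    if (length(extra) > 0L) {
      stop("records of group ", g, " contain individuals absent from roster: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    n <- length(ids_g)
    if (n < 2L) next
    arr <- .scan_arrays(rec_g, g)
    # map roster ids onto array indices (individuals may lack records entirely)
    ord <- t(expand.grid(r = seq_len(n), s = seq_len(n))[, c("s", "r")])
    sender <- ids_g[ord[1L, ]]; receiver <- ids_g[ord[2L, ]]
    keep <- sender != receiver
    sender <- sender[keep]; receiver <- receiver[keep]

    cnt <- matrix(0L, nrow = length(sender), ncol = 4L,
                  dimnames = list(NULL, .layer_names))
    den <- integer(length(sender))
    if (arr$n >= 2L) {
      pc <- .pair_counts(arr)
      aff_cnt <- grm_cnt <- matrix(0L, arr$n, arr$n)
      for (i in seq_len(arr$n)) {
        pi <- arr$partner[i, ]
        ok <- !is.na(pi)
        if (!any(ok)) next
        tab_a <- table(factor(pi[ok & arr$beh[i, ] == "affiliative"],
                              levels = arr$ids))
        tab_g <- table(factor(pi[ok & arr$beh[i, ] == "grooming"],
                              levels = arr$ids))
        aff_cnt[i, ] <- as.integer(tab_a)
        grm_cnt[i, ] <- as.integer(tab_g)
      }
      acc <- arr$access %*% t(arr$access)  # both-access scan counts
      si <- match(sender, arr$ids); ri <- match(receiver, arr$ids)
      for (k in seq_along(sender)) {
        i <- si[k]; j <- ri[k]
        if (is.na(i) || is.na(j)) next
        p <- which(arr$pairs[, 1L] == min(i, j) & arr$pairs[, 2L] == max(i, j))
        cnt[k, "stationary_vicinity"] <- pc$sv[p]
        cnt[k, "passive_close_proximity"] <- pc$pcp[p]
        cnt[k, "affiliative"] <- aff_cnt[i, j]
        cnt[k, "grooming"] <- grm_cnt[i, j]
        den[k] <- acc[i, j]
      }
    }
    tab <- data.frame(
      group = g,
      sender = rep(sender, times = 4L),
      receiver = rep(receiver, times = 4L),
      layer = rep(.layer_names, each = length(sender)),
      count = as.integer(cnt[cbind(rep(seq_along(sender), 4L),
                                   rep(seq_len(4L), each = length(sender)))]),
      denominator = rep(den, times = 4L),
      stringsAsFactors = FALSE
    )
    out[[g]] <- tab
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  zero_den <- tab$denominator == 0L
  if (any(zero_den)) {
    dy <- unique(paste0(tab$sender[zero_den], "->", tab$receiver[zero_den]))
    warning("zero access denominator (index set to 0) for dyad(s): ",
            paste(dy, collapse = ", "), call. = FALSE)
  }
  tab$index <- ifelse(zero_den, 0, tab$count / tab$denominator)
  tab$weighted <- NA_real_
  tab$layer <- factor(tab$layer, levels = .layer_names)
  class(tab) <- c("dyad_index_table", "data.frame")
  tab
}

#' Normalize indices into weighted index values
#'
#' Divides each index by the maximum index observed for its layer across all
#' groups in the table, so every layer's weights span (0, 1] with the
#' layer-maximum dyad at exactly 1. This removes between-layer scaling effects
#' before multiplex analysis.
#'
#' @param index_table Table from [compute_indices()] (may contain several
#'   groups; the per-layer maximum is pooled across all of them).
#' @return The table with the `weighted` column filled. Idempotent: applying
#'   it to an already-normalized table leaves weights unchanged.
#' @export
normalize_weighted <- function(index_table) {
  tab <- index_table
  for (l in levels(tab$layer)) {
    rows <- tab$layer == l
    if (!any(rows)) next
    mx <- max(tab$index[rows])
    if (mx == 0) {
      warning("layer ", l, " has no positive index; weighted values set to 0",
              call. = FALSE)
      tab$weighted[rows] <- 0
    } else {
      tab$weighted[rows] <- tab$index[rows] / mx
    }
  }
  tab
}
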