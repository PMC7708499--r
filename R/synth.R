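# Synthetic scan-sampling generator.
#
# Generative model (per group, per two-minute scan):
#   1. Each present individual draws at most one outgoing directed behaviour
#      (affiliative or grooming towards one partner) from a categorical whose
#      per-dyad marginals equal the configured probabilities exactly. Rare
#      cross-direction class collisions (a->b affiliative while b->a grooming,
#      which would break per-dyad exclusivity) are resolved by a fair coin.
#   2. Every unordered dyad without a realized directed behaviour draws one of
#      {none, stationary vicinity, passive close proximity}; the conditional
#      probabilities are inflated so the unconditional marginals equal the
#      configured rates.
#   3. Positions and height levels are generated so that the dyadic counting
#      rules recover the sampled states exactly: individuals sit on enclosure
#      "sites" more than 5 m apart by default; stationary-vicinity components
#      are laid out on a 1.6 m cell grid with height levels chosen so that
#      non-interacting pairs inside a component are separated by distance or
#      by two or more height levels.
# Dyads are independent across scans; absence (no enclosure access) is drawn
# per individual and session.

#' Synthetic-data configuration
#'
#' @param n_groups Number of social groups.
#' @param group_size Individuals per group (>= 2).
#' @param n_sessions Observation sessions per group.
#' @param scans_per_session Scans per 20-minute session (2-minute interval).
#' @param base_rates Named per-scan, per-dyad state probabilities for
#'   `stationary_vicinity`, `passive_close_proximity` (symmetric states) and
#'   `affiliative`, `grooming` (each direction of a dyad separately).
#' @param effect_multipliers List of planted effects; each element is a list
#'   with fields `factor` (`"origin"`, `"phc_infant"` or `"sex"`), `combo`
#'   (e.g. `"with->with"`), `value` (positive multiplier) and optional `layer`
#'   (default: all layers).
#' @param p_absent Probability an individual lacks enclosure access for a
#'   whole session.
#' @param p_indoor Probability a scan finds an individual indoors (access but
#'   not visible). Zero by default so that index estimates are unbiased for
#'   the planted probabilities.
#' @param mode `"state"` (canonical minimal geometry) or `"spatial"`
#'   (randomized geometry within the constraint regions).
#' @param proportions Optional roster attribute proportions
#'   (`female`, `wild`, `phc_with`); when `NULL` and the default
#'   two-groups-of-seven shape is requested, the roster mirrors the published
#'   study composition.
#' @param seed Integer seed; every stochastic operation derives its stream
#'   from it (roster: seed, state sampling: seed + 1, geometry: seed + 2).
#' @return A `panmux_config` list.
#' @export
synth_config <- function(n_groups = 2L, group_size = 7L, n_sessions = 30L,
                         scans_per_session = 10L,
                         base_rates = c(stationary_vicinity = 0.08,
                                        passive_close_proximity = 0.04,
                                        affiliative = 0.015,
                                        grooming = 0.025),
                         effect_multipliers = list(),
                         p_absent = 0.05, p_indoor = 0,
                         mode = c("state", "spatial"),
                         proportions = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_groups >= 1L, scans_per_session >= 1L, n_sessions >= 1L,
            p_absent >= 0, p_absent <= 1, p_indoor >= 0, p_indoor <= 1)
  if (group_size < 2L) stop("group_size must be at least 2", call. = FALSE)
  missing_rates <- setdiff(.layer_names, names(base_rates))
  if (length(missing_rates) > 0L) {
    stop("base_rates must name all four states; missing: ",
         paste(missing_rates, collapse = ", "), call. = FALSE)
  }
  if (any(base_rates < 0 | base_rates > 1)) {
    stop("base_rates must lie in [0, 1]", call. = FALSE)
  }
  for (em in effect_multipliers) {
    stopifnot(is.list(em), em$factor %in% c("origin", "phc_infant", "sex"),
              is.numeric(em$value), em$value > 0)
  }
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 n_sessions = as.integer(n_sessions),
                 scans_per_session = as.integer(scans_per_session),
                 base_rates = base_rates[.layer_names],
                 effect_multipliers = effect_multipliers,
                 p_absent = p_absent, p_indoor = p_indoor, mode = mode,
                 proportions = proportions, seed = as.integer(seed)),
            class = "panmux_config")
}

# Attribute composition of the two published groups, recycled as the default
# roster template (columns: sex, origin, phc_infant).
.default_comps <- list(
  data.frame(sex = c("F", "F", "F", "M", "M", "M", "M"),
             origin = c("wild", "wild", "wild", "captive", "wild", "wild",
                        "captive"),
             phc_infant = c("with", "without", "without", "without", "without",
                            "with", "without"), stringsAsFactors = FALSE),
  data.frame(sex = c("F", "M", "M", "M", "M", "M", "F"),
             origin = c("wild", "captive", "captive", "captive", "captive",
                        "wild", "captive"),
             phc_infant = c("without", "with", "with", "with", "with", "with",
                            "with"), stringsAsFactors = FALSE)
)

#' Generate a synthetic biography roster
#'
#' With the default configuration (two groups of seven, no `proportions`),
#' the attribute composition mirrors the published study groups. Otherwise
#' attributes are drawn independently with the configured proportions.
#'
#' @param config A [synth_config()].
#' @return A roster `data.frame` (see [read_biographies()]).
#' @export
make_roster <- function(config) {
  stopifnot(inherits(config, "panmux_config"))
  if (config$group_size < 2L) stop("group_size must be at least 2",
                                   call. = FALSE)
  set.seed(config$seed)
  rows <- list()
  mirror <- is.null(config$proportions) && config$group_size == 7L
  for (g in seq_len(config$n_groups)) {
    gname <- paste0("Group", LETTERS[(g - 1L) %% 26L + 1L])
    ids <- sprintf("%s%02d", LETTERS[(g - 1L) %% 26L + 1L],
                   seq_len(config$group_size))
    if (mirror) {
      comp <- .default_comps[[(g - 1L) %% 2L + 1L]]
    } else {
      pr <- config$proportions
      if (is.null(pr)) pr <- list()
      p_f <- if (is.null(pr$female)) 5 / 14 else pr$female
      p_w <- if (is.null(pr$wild)) 7 / 14 else pr$wild
      p_p <- if (is.null(pr$phc_with)) 8 / 14 else pr$phc_with
      comp <- data.frame(
        sex = ifelse(stats::runif(config$group_size) < p_f, "F", "M"),
        origin = ifelse(stats::runif(config$group_size) < p_w, "wild",
                        "captive"),
        phc_infant = ifelse(stats::runif(config$group_size) < p_p, "with",
                            "without"),
        stringsAsFactors = FALSE)
    }
    rows[[g]] <- data.frame(
      id = ids, name = ids, sex = comp$sex, origin = comp$origin,
      phc_infant = comp$phc_infant,
      year_birth = 1990L, year_arrival = 2005L, group = gname,
      stringsAsFactors = FALSE)
  }
  .as_roster(do.call(rbind, rows))
}

.combo <- function(a, b) paste0(a, "->", b)

# Multiplier applying to state `layer` for sender attributes `sa` and
# receiver attributes `sb` (rows of the roster).
.dyad_multiplier <- function(config, layer, sa, sb) {
  m <- 1
  for (em in config$effect_multipliers) {
    if (!is.null(em$layer) && !layer %in% em$layer) next
    if (.combo(as.character(sa[[em$factor]]),
               as.character(sb[[em$factor]])) == em$combo) {
      m <- m * em$value
    }
  }
  m
}

#' Ground-truth dyadic state probabilities
#'
#' Expands the configured base rates and planted effect multipliers into the
#' per-ordered-dyad, per-state probability table that the generator samples
#' from. Symmetric states (stationary vicinity, passive close proximity) get
#' the same probability in both directions of a dyad (the mean of the two
#' directed values when an asymmetric multiplier is supplied). If a dyad's
#' implied per-scan state probabilities sum beyond 1 they are renormalized
#' proportionally, with a warning.
#'
#' @param roster Roster from [make_roster()] (or any roster).
#' @param config A [synth_config()].
#' @return A `panmux_truth` object: list with `probs` (data frame
#'   `group, sender, receiver, layer, p`), `roster` and `config`.
#' @export
dyad_state_probs <- function(roster, config) {
  stopifnot(inherits(config, "panmux_config"))
  out <- list()
  sym_layers <- c("stationary_vicinity", "passive_close_proximity")
  for (g in unique(roster$group)) {
    rg <- roster[roster$group == g, , drop = FALSE]
    n <- nrow(rg)
    grid <- expand.grid(r = seq_len(n), s = seq_len(n))
    grid <- grid[grid$r != grid$s, c("s", "r")]
    tabs <- lapply(.layer_names, function(l) {
      p <- vapply(seq_len(nrow(grid)), function(k) {
        config$base_rates[[l]] *
          .dyad_multiplier(config, l, rg[grid$s[k], ], rg[grid$r[k], ])
      }, numeric(1))
      data.frame(group = g, sender = rg$id[grid$s], receiver = rg$id[grid$r],
                 layer = l, p = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    # symmetrize the symmetric states
    key <- paste(pmin(tab$sender, tab$receiver),
                 pmax(tab$sender, tab$receiver), tab$layer)
    for (l in sym_layers) {
      rows <- tab$layer == l
      tab$p[rows] <- stats::ave(tab$p[rows], key[rows])
    }
    # cap: total per-scan state mass per unordered dyad must not exceed 1
    ukey <- paste(pmin(tab$sender, tab$receiver),
                  pmax(tab$sender, tab$receiver))
    capped <- character(0)
    for (uk in unique(ukey)) {
      rows <- ukey == uk
      # symmetric states count once per unordered dyad, directed states per
      # direction
      w <- ifelse(tab$layer[rows] %in% sym_layers, 0.5, 1)
      tot <- sum(tab$p[rows] * w)
      if (tot > 1) {
        capped <- c(capped, uk)
        tab$p[rows] <- tab$p[rows] / tot
      }
    }
    if (length(capped) > 0L) {
      warning(length(capped), " dyad(s) in group ", g, " had total state ",
              "probability > 1; renormalized proportionally (first: ",
              capped[1L], ")", call. = FALSE)
    }
    out[[g]] <- tab
  }
  probs <- do.call(rbind, out)
  rownames(probs) <- NULL
  structure(list(probs = probs, roster = roster, config = config),
            class = "panmux_truth")
}

# ---- geometric realization ----------------------------------------------

# Site centres: a 3x3 grid with 18 m spacing; cross-site distances exceed 5 m
# even when a stationary-vicinity component extends 11.5 m along the cell
# grid of its anchor site.
.site_coords <- function() {
  v <- c(1, 19, 37)
  as.matrix(expand.grid(x = v, y = v))
}

# Slot geometry for stationary-vicinity components: slots are (kx, ky, h)
# with kx, ky in 0..7 (1.6 m grid cells) and h in 0..4 (height levels).
# A stationary-vicinity pair sits within 2 cells (Euclidean distance at most
# 4.53 m + offsets < 5 m) and within one height level; a separated pair sits
# 4+ cells (at least 6.1 m after offsets) or 2+ height levels apart.
# Pairwise slot-compatibility tables are precomputed once per session.
.slot_cell <- 1.6
.slot_cache <- new.env(parent = emptyenv())

.slot_tables <- function() {
  if (!is.null(.slot_cache$slots)) return(.slot_cache)
  slots <- as.matrix(expand.grid(kx = 0:7, ky = 0:7, h = 0:4))
  slots <- slots[order(pmax(slots[, 1], slots[, 2]), slots[, 1] + slots[, 2],
                       slots[, 3]), , drop = FALSE]
  dk <- pmax(abs(outer(slots[, 1], slots[, 1], `-`)),
             abs(outer(slots[, 2], slots[, 2], `-`)))
  dh <- abs(outer(slots[, 3], slots[, 3], `-`))
  .slot_cache$slots <- slots
  .slot_cache$ok <- list(
    dk <= 2 & dh <= 1,      # 1: stationary-vicinity edge
    dk == 0 & dh == 0,      # 2: touch (same cell, same height)
    dk >= 4 | dh >= 2       # 3: must separate
  )
  .slot_cache
}

# Backtracking slot assignment for one component, with forward checking and
# minimum-remaining-values ordering. rel[i, j] codes the pair constraint
# (see .slot_tables; 0 = unconstrained). Returns a k x 3 matrix of
# (kx, ky, h) or NULL if infeasible.
.solve_slots <- function(rel, max_nodes = 20000L) {
  # constraint patterns recur across scans; memoize solutions (and failures)
  key <- paste(rel, collapse = "")
  hit <- .slot_cache$memo[[key]]
  if (!is.null(hit)) {
    return(if (is.matrix(hit)) hit else NULL)
  }
  res <- .solve_slots_search(rel, max_nodes)
  if (is.null(.slot_cache$memo)) .slot_cache$memo <- list()
  .slot_cache$memo[[key]] <- if (is.null(res)) NA else res
  res
}

.solve_slots_search <- function(rel, max_nodes) {
  k <- nrow(rel)
  st <- .slot_tables()
  ns <- nrow(st$slots)
  assign <- integer(k)
  cand <- matrix(TRUE, ns, k)  # feasible slots per member
  nodes <- 0L
  exhausted <- FALSE
  recurse <- function(done) {
    if (done == k) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > max_nodes) {
      # treated as infeasible by the caller, which repairs by demotion
      exhausted <<- TRUE
      return(FALSE)
    }
    open <- which(assign == 0L)
    counts <- colSums(cand[, open, drop = FALSE])
    if (any(counts == 0L)) return(FALSE)
    i <- open[which.min(counts)]
    saved <- cand
    for (s in which(cand[, i])) {
      assign[i] <<- s
      ok <- TRUE
      for (j in open) {
        if (j == i) next
        r <- rel[i, j]
        if (r > 0L) {
          cand[, j] <<- cand[, j] & st$ok[[r]][, s]
          if (!any(cand[, j])) { ok <- FALSE; break }
        }
      }
      if (ok && recurse(done + 1L)) return(TRUE)
      if (exhausted) return(FALSE)
      cand <<- saved
      assign[i] <<- 0L
    }
    FALSE
  }
  if (!recurse(0L)) return(NULL)
  st$slots[assign, , drop = FALSE]
}

# Place one group's individuals for every scan. sv / touch are P x S logical
# matrices over unordered pairs; returns x, y, h matrices (n x S) plus
# `demoted`, a (pair, scan) index matrix of stationary-vicinity states that
# had to be dropped to "none" because the sampled configuration was not
# geometrically realizable (per-dyad independence admits rare infeasible
# combinations; the repair is deterministic and counted).
.place_group <- function(n, S, pairs, sv, touch, visible, spatial, rng_jitter) {
  sites <- .site_coords()
  site_of <- ((seq_len(n) - 1L) %% nrow(sites)) + 1L
  x <- matrix(sites[site_of, 1L], n, S)
  y <- matrix(sites[site_of, 2L], n, S)
  h <- matrix(0L, n, S)
  P <- nrow(pairs)
  demoted <- list()
  if (P > 0L) {
    close_mat <- if (spatial) sv | touch else sv
    # scans solvable by the vectorized path: close pairs form a matching
    inc <- matrix(0L, n, P)
    inc[cbind(pairs[, 1L], seq_len(P))] <- 1L
    inc[cbind(pairs[, 2L], seq_len(P))] <- 1L
    deg <- inc %*% close_mat            # n x S close-degree
    easy <- colSums(deg > 1L) == 0L
    # vectorized: mover = higher-index member joins the lower's site
    if (any(easy)) {
      hits <- which(close_mat & rep(easy, each = P), arr.ind = TRUE)
      if (nrow(hits) > 0L) {
        p <- hits[, 1L]; s <- hits[, 2L]
        i <- pairs[p, 1L]; j <- pairs[p, 2L]
        is_sv <- sv[cbind(p, s)]
        dx <- ifelse(is_sv, 3, 0.5)
        x[cbind(j, s)] <- sites[site_of[i], 1L] + dx
        y[cbind(j, s)] <- sites[site_of[i], 2L]
      }
    }
    hard <- which(!easy & colSums(close_mat) > 0L)
    for (s in hard) {
      cp <- which(close_mat[, s])
      # union-find over close edges
      comp <- seq_len(n)
      find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
      for (p in cp) {
        ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
        if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), find, integer(1))
      for (root in unique(roots[duplicated(roots)])) {
        mem <- which(roots == root)
        k <- length(mem)
        rel <- matrix(0L, k, k)
        for (p in cp) {
          a <- match(pairs[p, 1L], mem); b <- match(pairs[p, 2L], mem)
          if (!is.na(a) && !is.na(b)) {
            rel[a, b] <- rel[b, a] <- if (sv[p, s]) 1L else 2L
          }
        }
        sep <- rel == 0L & upper.tri(rel)
        rel[sep] <- 3L
        rel <- pmax(rel, t(rel))
        if (!spatial) rel[rel == 2L] <- 0L  # touch pairs need no geometry
        slots <- .solve_slots(rel)
        if (is.null(slots) && spatial) {
          rel2 <- rel; rel2[rel2 == 2L] <- 0L
          slots <- .solve_slots(rel2)
          if (!is.null(slots)) rel <- rel2
        }
        # infeasible configurations (possible under per-dyad independence):
        # deterministically demote stationary-vicinity edges to "none" until
        # the component is realizable; a fully separated set always is
        while (is.null(slots)) {
          svdeg <- rowSums(rel == 1L)
          if (all(svdeg == 0L)) {
            stop("geometric placement infeasible for a fully separated ",
                 "component of size ", k, call. = FALSE)
          }
          edges <- which(rel == 1L & upper.tri(rel), arr.ind = TRUE)
          load <- svdeg[edges[, 1L]] + svdeg[edges[, 2L]]
          e <- edges[order(-load, edges[, 1L], edges[, 2L])[1L], ]
          rel[e[1L], e[2L]] <- rel[e[2L], e[1L]] <- 3L
          p_drop <- which((pairs[, 1L] == mem[e[1L]] &
                             pairs[, 2L] == mem[e[2L]]) |
                            (pairs[, 1L] == mem[e[2L]] &
                               pairs[, 2L] == mem[e[1L]]))
          demoted[[length(demoted) + 1L]] <- c(p_drop, s)
          sv[p_drop, s] <- FALSE
          slots <- .solve_slots(rel)
        }
        anchor <- site_of[min(mem)]
        off <- if (spatial) rng_jitter(k) else
          cbind(0.02 * seq_len(k), rep(0, k))
        x[cbind(mem, s)] <- sites[anchor, 1L] + .slot_cell * slots[, 1L] +
          off[, 1L]
        y[cbind(mem, s)] <- sites[anchor, 2L] + .slot_cell * slots[, 2L] +
          off[, 2L]
        h[cbind(mem, s)] <- slots[, 3L]
      }
    }
  }
  x[!visible] <- NA_real_
  y[!visible] <- NA_real_
  h[!visible] <- NA_integer_
  list(x = x, y = y, h = h,
       demoted = if (length(demoted)) do.call(rbind, demoted) else
         matrix(integer(), ncol = 2L))
}

# ---- scan simulation ------------------------------------------------------

#' Simulate scan-sampling records
#'
#' Draws latent dyadic interaction states from a ground-truth probability
#' table and emits scan records in the canonical format, including a
#' geometric realization of stationary vicinity (positions and height
#' levels). The generated table always passes [validate_exclusivity()], and
#' [compute_indices()] applied to it recovers the sampled states exactly.
#' The sampled latent index table is attached as attribute
#' `"latent_indices"` (see [latent_indices()]).
#'
#' @param truth A `panmux_truth` from [dyad_state_probs()].
#' @param config Configuration; defaults to the one stored in `truth`.
#' @return Scan records data frame (one row per individual per scan).
#' @export
simulate_scans <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "panmux_truth"))
  roster <- truth$roster
  spatial <- config$mode == "spatial"
  sessions <- config$n_sessions
  spc <- config$scans_per_session
  S <- sessions * spc
  groups <- unique(roster$group)

  set.seed(config$seed + 1L)
  per_group <- list()
  for (g in groups) {
    ids <- roster$id[roster$group == g]
    n <- length(ids)
    pr <- truth$probs[truth$probs$group == g, , drop = FALSE]
    p_of <- function(layer, a, b) {
      pr$p[pr$layer == layer & pr$sender == a & pr$receiver == b]
    }
    # presence: per individual per session
    present <- matrix(rep(stats::runif(n * sessions) >= config$p_absent,
                          each = 1L), n, sessions)
    present <- present[, rep(seq_len(sessions), each = spc), drop = FALSE]
    visible <- present
    if (config$p_indoor > 0) {
      visible <- present & matrix(stats::runif(n * S) >= config$p_indoor, n, S)
    }

    # step 1: outgoing directed behaviour per individual
    out_partner <- matrix(0L, n, S)
    out_class <- matrix(0L, n, S)  # 1 = affiliative, 2 = grooming
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      p_aff <- vapply(others, function(j) p_of("affiliative", ids[i], ids[j]),
                      numeric(1))
      p_grm <- vapply(others, function(j) p_of("grooming", ids[i], ids[j]),
                      numeric(1))
      tot <- sum(p_aff) + sum(p_grm)
      if (tot > 1) stop("outgoing directed-behaviour probability of ", ids[i],
                        " exceeds 1", call. = FALSE)
      draw <- sample.int(2L * length(others) + 1L, S, replace = TRUE,
                         prob = c(1 - tot, p_aff, p_grm))
      m <- length(others)
      is_aff <- draw >= 2L & draw <= m + 1L
      is_grm <- draw > m + 1L
      out_class[i, is_aff] <- 1L
      out_class[i, is_grm] <- 2L
      out_partner[i, is_aff] <- others[draw[is_aff] - 1L]
      out_partner[i, is_grm] <- others[draw[is_grm] - m - 1L]
    }
    # suppress draws towards / from non-present or invisible individuals
    ok_obs <- present & visible
    for (i in seq_len(n)) {
      tgt <- out_partner[i, ]
      sel <- which(tgt > 0L)
      bad <- sel[!ok_obs[i, sel] | !ok_obs[cbind(tgt[sel], sel)]]
      out_partner[i, bad] <- 0L
      out_class[i, bad] <- 0L
    }
    pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(), ncol = 2L)
    P <- nrow(pairs)
    # cross-direction class collisions: keep one side by fair coin
    for (p in seq_len(P)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      clash <- which(out_partner[i, ] == j & out_partner[j, ] == i &
                       out_class[i, ] != out_class[j, ])
      if (length(clash) > 0L) {
        drop_i <- stats::runif(length(clash)) < 0.5
        out_partner[i, clash[drop_i]] <- 0L
        out_class[i, clash[drop_i]] <- 0L
        out_partner[j, clash[!drop_i]] <- 0L
        out_class[j, clash[!drop_i]] <- 0L
      }
    }
    # step 2: symmetric pair states where no directed behaviour realized
    pairstate <- matrix(0L, P, S)  # 1 = SV, 2 = PCP
    for (p in seq_len(P)) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      pa <- p_of("affiliative", ids[i], ids[j]) +
        p_of("grooming", ids[i], ids[j])
      pb <- p_of("affiliative", ids[j], ids[i]) +
        p_of("grooming", ids[j], ids[i])
      nodir <- (1 - pa) * (1 - pb)
      p_sv <- p_of("stationary_vicinity", ids[i], ids[j]) / nodir
      p_pcp <- p_of("passive_close_proximity", ids[i], ids[j]) / nodir
      if (p_sv + p_pcp > 1) {
        stop("conditional symmetric-state probability exceeds 1 for dyad ",
             ids[i], "-", ids[j], call. = FALSE)
      }
      cand <- sample.int(3L, S, replace = TRUE,
                         prob = c(1 - p_sv - p_pcp, p_sv, p_pcp)) - 1L
      free <- ok_obs[i, ] & ok_obs[j, ] &
        !(out_partner[i, ] == j & out_class[i, ] > 0L) &
        !(out_partner[j, ] == i & out_class[j, ] > 0L)
      pairstate[p, free] <- cand[free]
    }
    per_group[[g]] <- list(ids = ids, n = n, present = present,
                           visible = visible, out_partner = out_partner,
                           out_class = out_class, pairs = pairs,
                           pairstate = pairstate)
  }

  # geometry (separate stream so state draws are placement-independent)
  set.seed(config$seed + 2L)
  rng_jitter <- function(k) {
    matrix(stats::runif(2L * k, -0.15, 0.15), ncol = 2L)
  }
  rows <- list()
  n_demoted <- 0L
  for (g in groups) {
    gd <- per_group[[g]]
    pl <- .place_group(gd$n, S, gd$pairs, gd$pairstate == 1L,
                       gd$pairstate == 2L | .directed_pair_mat(gd),
                       gd$visible, spatial, rng_jitter)
    if (nrow(pl$demoted) > 0L) {
      # geometric feasibility repair: these dyad-scans revert to "none"
      gd$pairstate[pl$demoted] <- 0L
      per_group[[g]] <- gd
    }
    n_demoted <- n_demoted + nrow(pl$demoted)
    # arms-reach strings from PCP pair states
    arms <- matrix("", gd$n, S)
    pcp_hits <- which(gd$pairstate == 2L, arr.ind = TRUE)
    if (nrow(pcp_hits) > 0L) {
      p <- pcp_hits[, 1L]; s <- pcp_hits[, 2L]
      i <- gd$pairs[p, 1L]; j <- gd$pairs[p, 2L]
      add <- data.frame(who = c(i, j), s = c(s, s),
                        other = c(gd$ids[j], gd$ids[i]))
      key <- paste(add$who, add$s)
      merged <- tapply(add$other, key, paste, collapse = ";")
      loc <- do.call(rbind, strsplit(names(merged), " "))
      arms[cbind(as.integer(loc[, 1L]), as.integer(loc[, 2L]))] <-
        as.character(merged)
    }
    beh <- matrix("none", gd$n, S)
    beh[gd$out_class == 1L] <- "affiliative"
    beh[gd$out_class == 2L] <- "grooming"
    partner <- matrix(NA_character_, gd$n, S)
    has_p <- gd$out_partner > 0L
    partner[has_p] <- gd$ids[gd$out_partner[has_p]]

    sess <- rep(sprintf("%s_S%03d", g, seq_len(sessions)), each = spc)
    scan_no <- rep(seq_len(spc), times = sessions)
    rec <- data.frame(
      group = g,
      session_id = rep(sess, each = gd$n),
      scan_index = rep(scan_no, each = gd$n),
      individual = rep(gd$ids, times = S),
      access = as.vector(gd$present),
      visible = as.vector(gd$visible),
      behavior = as.vector(beh),
      partner = as.vector(partner),
      arms_reach = as.vector(arms),
      pos_x = round(as.vector(pl$x), 3L),
      pos_y = round(as.vector(pl$y), 3L),
      height_level = as.vector(pl$h),
      stringsAsFactors = FALSE
    )
    rec[!rec$visible, c("behavior")] <- "none"
    rec$partner[!rec$visible] <- NA_character_
    rec$arms_reach[!rec$visible] <- ""
    rows[[g]] <- rec
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$session_id, records$scan_index,
                           records$individual), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "latent_indices") <- .latent_table(per_group, roster)
  attr(records, "n_demoted") <- n_demoted
  attr(records, "issues") <- data.frame(
    session_id = character(), scan_index = integer(), individual = character(),
    problem = character(), stringsAsFactors = FALSE)
  records
}

.directed_pair_mat <- function(gd) {
  P <- nrow(gd$pairs)
  m <- matrix(FALSE, P, ncol(gd$out_partner))
  for (p in seq_len(P)) {
    i <- gd$pairs[p, 1L]; j <- gd$pairs[p, 2L]
    m[p, ] <- (gd$out_partner[i, ] == j & gd$out_class[i, ] > 0L) |
      (gd$out_partner[j, ] == i & gd$out_class[j, ] > 0L)
  }
  m
}

# Index table computed from the latent states (identical in value to running
# compute_indices() on the emitted records; the equality is asserted by the
# test suite). Used as the fast path in simulation studies.
.latent_table <- function(per_group, roster) {
  out <- list()
  for (g in names(per_group)) {
    gd <- per_group[[g]]
    n <- gd$n
    acc <- gd$present %*% t(gd$present)
    grid <- expand.grid(r = seq_len(n), s = seq_len(n))
    grid <- grid[grid$r != grid$s, c("s", "r")]
    m <- nrow(grid)
    cnt <- matrix(0L, m, 4L, dimnames = list(NULL, .layer_names))
    den <- integer(m)
    pk <- paste(gd$pairs[, 1L], gd$pairs[, 2L])
    sv_cnt <- rowSums(gd$pairstate == 1L)
    pcp_cnt <- rowSums(gd$pairstate == 2L)
    for (k in seq_len(m)) {
      i <- grid$s[k]; j <- grid$r[k]
      p <- match(paste(min(i, j), max(i, j)), pk)
      cnt[k, "stationary_vicinity"] <- sv_cnt[p]
      cnt[k, "passive_close_proximity"] <- pcp_cnt[p]
      cnt[k, "affiliative"] <- sum(gd$out_partner[i, ] == j &
                                     gd$out_class[i, ] == 1L)
      cnt[k, "grooming"] <- sum(gd$out_partner[i, ] == j &
                                  gd$out_class[i, ] == 2L)
      den[k] <- acc[i, j]
    }
    out[[g]] <- data.frame(
      group = g, sender = rep(gd$ids[grid$s], 4L),
      receiver = rep(gd$ids[grid$r], 4L),
      layer = rep(.layer_names, each = m),
      count = as.integer(cnt), denominator = rep(den, 4L),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$index <- ifelse(tab$denominator == 0L, 0, tab$count / tab$denominator)
  tab$weighted <- NA_real_
  tab$layer <- factor(tab$layer, levels = .layer_names)
  class(tab) <- c("dyad_index_table", "data.frame")
  tab
}

#' Latent index table of a simulated scan set
#'
#' The dyadic index table tallied directly from the sampled latent states of
#' [simulate_scans()]. Value-identical to [compute_indices()] on the emitted
#' records; useful as a fast path in large simulation studies.
#'
#' @param records Records from [simulate_scans()].
#' @return A `dyad_index_table`.
#' @export
latent_indices <- function(records) {
  tab <- attr(records, "latent_indices")
  if (is.null(tab)) stop("records carry no latent index table", call. = FALSE)
  tab
}

#' Simulate scans with randomized spatial realization
#'
#' Convenience wrapper around [simulate_scans()] with `mode = "spatial"`:
#' positions are jittered within the geometric constraint regions
#' (stationary-vicinity dyads a few metres apart with height-level difference
#' at most 1, interacting dyads within arm's reach, unconnected dyads beyond
#' 5 m or two or more height levels apart). Given the same seed, the latent
#' states -- and therefore the computed indices -- are identical to state
#' mode.
#'
#' @inheritParams simulate_scans
#' @return Scan records data frame.
#' @export
simulate_spatial <- function(truth, config = truth$config) {
  config$mode <- "spatial"
  simulate_scans(truth, config)
}
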