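# Hand-built scan-record fixtures. One row per individual per scan, in the
# in-memory record layout produced by read_scans().

rec_row <- function(individual, group = "G1", session_id = "S1",
                    scan_index = 1L, access = TRUE, visible = TRUE,
                    behavior = "none", partner = NA_character_,
                    arms_reach = "", pos_x = NA_real_, pos_y = NA_real_,
                    height_level = NA_integer_) {
  data.frame(group = group, session_id = session_id,
             scan_index = as.integer(scan_index), individual = individual,
             access = access, visible = visible, behavior = behavior,
             partner = partner, arms_reach = arms_reach,
             pos_x = as.numeric(pos_x), pos_y = as.numeric(pos_y),
             height_level = as.integer(height_level),
             stringsAsFactors = FALSE)
}

bind_records <- function(...) {
  rec <- do.call(rbind, list(...))
  rec <- rec[order(rec$session_id, rec$scan_index, rec$individual), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# Two-individual fixture: one session, `n_scans` scans, per-scan geometry and
# interaction supplied as vectors (recycled).
two_ind_session <- function(n_scans, d = 10, dh = 0, a_beh = "none",
                            a_partner = NA, arms_a = "", arms_b = "",
                            a_access = TRUE, b_access = TRUE,
                            b_visible = TRUE) {
  d <- rep(d, length.out = n_scans)
  dh <- rep(dh, length.out = n_scans)
  a_beh <- rep(a_beh, length.out = n_scans)
  a_partner <- rep(a_partner, length.out = n_scans)
  arms_a <- rep(arms_a, length.out = n_scans)
  arms_b <- rep(arms_b, length.out = n_scans)
  a_access <- rep(a_access, length.out = n_scans)
  b_access <- rep(b_access, length.out = n_scans)
  b_visible <- rep(b_visible, length.out = n_scans)
  rows <- lapply(seq_len(n_scans), function(s) {
    rbind(
      rec_row("AAA", scan_index = s, access = a_access[s],
              behavior = a_beh[s], partner = a_partner[s],
              arms_reach = arms_a[s], pos_x = 0, pos_y = 0, height_level = 0),
      rec_row("BBB", scan_index = s, access = b_access[s],
              visible = b_visible[s],
              arms_reach = arms_b[s],
              pos_x = if (b_visible[s]) d[s] else NA,
              pos_y = if (b_visible[s]) 0 else NA,
              height_level = if (b_visible[s]) dh[s] else NA))
  })
  do.call(bind_records, rows)
}

two_ind_roster <- function() {
  panmux:::.as_roster(data.frame(
    id = c("AAA", "BBB"), name = c("Aa", "Bb"), sex = c("F", "M"),
    origin = c("wild", "captive"), phc_infant = c("with", "without"),
    year_birth = c(1990, 1992), year_arrival = c(2005, 2006),
    group = "G1", stringsAsFactors = FALSE))
}

# Random directed weighted layer on n nodes with positive total weight.
random_layer <- function(n, density = 0.5) {
  m <- matrix(stats::runif(n * n) * (stats::runif(n * n) < density), n, n)
  diag(m) <- 0
  if (all(m == 0)) m[1, 2] <- stats::runif(1)
  m
}

# Complete graph with unit weights.
complete_layer <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

# Small synthetic multiplex built from the generator (cached per session).
synth_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_sessions = 15, seed = 42)
      roster <- make_roster(cfg)
      idx <- normalize_weighted(
        compute_indices(simulate_scans(dyad_state_probs(roster, cfg)), roster))
      cache <<- build_multiplex(idx, "GroupA", weight = "weighted")
    }
    cache
  }
})
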