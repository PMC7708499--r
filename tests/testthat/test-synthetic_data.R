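test_that("roster generation mirrors the study composition and is seeded", {
  cfg <- synth_config(seed = 3)
  roster <- make_roster(cfg)
  expect_equal(nrow(roster), 14L)
  expect_equal(length(unique(roster$group)), 2L)
  expect_false(anyDuplicated(roster$id) > 0)
  # default composition mirrors the published marginals
  expect_equal(sum(roster$sex == "M"), 9L)
  expect_equal(sum(roster$origin == "wild"), 7L)
  expect_equal(sum(roster$phc_infant == "with"), 8L)

  expect_identical(make_roster(cfg), roster)  # determinism

  all_f <- make_roster(synth_config(group_size = 5,
                                    proportions = list(female = 1), seed = 3))
  expect_true(all(all_f$sex == "F"))
  expect_error(make_roster(synth_config(group_size = 1)), "at least 2")
})

test_that("ground-truth probabilities expand base rates and multipliers", {
  roster <- make_roster(synth_config(seed = 1))
  cfg <- synth_config(base_rates = c(stationary_vicinity = 0.08,
                                     passive_close_proximity = 0.04,
                                     affiliative = 0.015, grooming = 0.05),
                      seed = 1)
  truth <- dyad_state_probs(roster, cfg)
  # identity: no multipliers -> every dyad carries the base rate
  for (l in c("grooming", "stationary_vicinity")) {
    expect_true(all(truth$probs$p[truth$probs$layer == l] ==
                      cfg$base_rates[[l]]))
  }

  # planted multiplier doubles grooming for with->with dyads only
  cfg2 <- synth_config(base_rates = cfg$base_rates,
                       effect_multipliers = list(
                         list(factor = "phc_infant", combo = "with->with",
                              layer = "grooming", value = 2)), seed = 1)
  truth2 <- dyad_state_probs(roster, cfg2)
  pr <- truth2$probs[truth2$probs$layer == "grooming", ]
  phc <- stats::setNames(as.character(roster$phc_infant), roster$id)
  ww <- phc[pr$sender] == "with" & phc[pr$receiver] == "with"
  expect_true(all(pr$p[ww] == 0.10))
  expect_true(all(pr$p[!ww] == 0.05))

  # symmetric states carry identical probabilities in both directions
  sym <- truth2$probs[truth2$probs$layer == "stationary_vicinity", ]
  key <- paste(pmin(sym$sender, sym$receiver), pmax(sym$sender, sym$receiver))
  expect_true(all(tapply(sym$p, key, function(x) length(unique(x))) == 1L))

  # over-unit total mass is renormalized proportionally with a warning
  cfg3 <- synth_config(base_rates = c(stationary_vicinity = 0.7,
                                      passive_close_proximity = 0.5,
                                      affiliative = 0, grooming = 0), seed = 1)
  w <- capture_warnings(truth3 <- dyad_state_probs(roster, cfg3))
  expect_true(any(grepl("renormalized", w)))
  tot <- tapply(seq_len(nrow(truth3$probs)),
                paste(truth3$probs$group,
                      pmin(truth3$probs$sender, truth3$probs$receiver),
                      pmax(truth3$probs$sender, truth3$probs$receiver)),
                function(i) {
                  w <- ifelse(truth3$probs$layer[i] %in%
                                c("affiliative", "grooming"), 1, 0.5)
                  sum(truth3$probs$p[i] * w)
                })
  expect_true(all(tot <= 1 + 1e-12))
})

test_that("simulation honours zero rates, determinism and session blocking", {
  cfg <- synth_config(n_groups = 1, n_sessions = 3,
                      base_rates = c(stationary_vicinity = 0,
                                     passive_close_proximity = 0,
                                     affiliative = 0, grooming = 0),
                      p_absent = 0, seed = 9)
  roster <- make_roster(cfg)
  rec <- simulate_scans(dyad_state_probs(roster, cfg))
  expect_true(all(rec$behavior == "none"))
  expect_true(all(rec$arms_reach == ""))
  expect_true(all(latent_indices(rec)$count == 0L))
  net_idx <- compute_indices(rec, roster)
  expect_true(all(net_idx$count == 0L))
  expect_equal(length(unique(rec$session_id)), 3L)
  expect_equal(sort(unique(rec$scan_index)), 1:10)

  cfg2 <- synth_config(n_sessions = 4, seed = 11)
  roster2 <- make_roster(cfg2)
  truth2 <- dyad_state_probs(roster2, cfg2)
  expect_identical(simulate_scans(truth2), simulate_scans(truth2))
})

test_that("generated data always passes the exclusivity audit", {
  for (seed in c(2, 31, 77)) {
    cfg <- synth_config(n_sessions = 8, seed = seed)
    roster <- make_roster(cfg)
    rec <- simulate_scans(dyad_state_probs(roster, cfg))
    expect_equal(nrow(validate_exclusivity(rec)), 0L)
    rec_fresh <- rec
    attr(rec_fresh, "issues") <- NULL  # force revalidation from scratch
    expect_equal(nrow(scan_issues(rec_fresh)), 0L)
  }
})

test_that("a planted rate is recovered within binomial error", {
  # single dyad observed over 5000 access scans with grooming rate 0.2
  cfg <- synth_config(n_groups = 1, group_size = 2, n_sessions = 500,
                      base_rates = c(stationary_vicinity = 0.1,
                                     passive_close_proximity = 0.05,
                                     affiliative = 0.01, grooming = 0.2),
                      p_absent = 0, seed = 21)
  roster <- make_roster(cfg)
  rec <- simulate_scans(dyad_state_probs(roster, cfg))
  idx <- compute_indices(rec, roster)
  grm <- idx[idx$layer == "grooming", ]
  expect_equal(unique(grm$denominator), 5000L)
  se <- sqrt(0.2 * 0.8 / 5000)
  expect_true(all(abs(grm$index - 0.2) < 3 * se))
})

test_that("record and latent index routes agree exactly in both modes", {
  cfg <- synth_config(n_sessions = 12, seed = 13)
  roster <- make_roster(cfg)
  truth <- dyad_state_probs(roster, cfg)
  rec_state <- simulate_scans(truth)
  rec_spatial <- simulate_spatial(truth)

  idx_state <- compute_indices(rec_state, roster)
  idx_spatial <- compute_indices(rec_spatial, roster)
  lat <- latent_indices(rec_state)
  cols <- c("count", "denominator", "index")
  expect_equal(as.data.frame(idx_state)[cols], as.data.frame(lat)[cols])
  expect_equal(as.data.frame(idx_spatial)[cols], as.data.frame(lat)[cols])
  expect_equal(nrow(validate_exclusivity(rec_spatial)), 0L)
})

test_that("spatial mode places dyads inside their geometric regions", {
  cfg <- synth_config(n_groups = 1, n_sessions = 10, mode = "spatial",
                      seed = 17)
  roster <- make_roster(cfg)
  rec <- simulate_spatial(dyad_state_probs(roster, cfg))
  arr <- panmux:::.scan_arrays(rec, "GroupA")
  ch <- panmux:::.pair_channels(arr)
  for (p in seq_len(nrow(arr$pairs))) {
    i <- arr$pairs[p, 1L]; j <- arr$pairs[p, 2L]
    d <- sqrt((arr$x[i, ] - arr$x[j, ])^2 + (arr$y[i, ] - arr$y[j, ])^2)
    dh <- abs(arr$h[i, ] - arr$h[j, ])
    sv <- which(ch$sv[p, ])
    expect_true(all(d[sv] <= 5 & dh[sv] <= 1))
    # non-interacting, non-proximate pairs are separated in space or height
    none <- which(!ch$sv[p, ] & !ch$arm[p, ] & !ch$interact[p, ] &
                    arr$visible[i, ] & arr$visible[j, ])
    expect_true(all(d[none] > 5 | dh[none] >= 2))
  }
})
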