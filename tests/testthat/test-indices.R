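test_that("planar distance matches an independent formula", {
  expect_equal(euclidean_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  for (k in 1:100) {
    p <- stats::runif(2, -50, 50); q <- stats::runif(2, -50, 50)
    oracle <- as.numeric(stats::dist(rbind(p, q)))
    expect_equal(euclidean_distance(p, q), oracle, tolerance = 1e-12)
  }
  expect_error(euclidean_distance(c(0, NA), c(1, 1)), "complete")
})

test_that("stationary vicinity subtracts arm's reach, height and interaction", {
  # 10 scans within 5 m; 4 of them within arm's reach; 2 with height gap 2
  arms <- c(rep("BBB", 4), rep("", 6))
  dh <- c(rep(0, 4), 2, 2, rep(0, 4))
  rec <- two_ind_session(10, d = 3, dh = dh, arms_a = arms)
  expect_equal(count_stationary_vicinity(rec, "AAA", "BBB"), 4L)

  # brute-force recount over the fixture
  brute <- sum(vapply(1:10, function(s) {
    r <- rec[rec$scan_index == s, ]
    d <- euclidean_distance(c(r$pos_x[1], r$pos_y[1]),
                            c(r$pos_x[2], r$pos_y[2]))
    d <= 5 && abs(r$height_level[1] - r$height_level[2]) <= 1 &&
      !any(grepl("BBB", r$arms_reach[1])) && all(r$behavior == "none")
  }, logical(1)))
  expect_equal(count_stationary_vicinity(rec, "AAA", "BBB"), brute)

  # always beyond 5 m -> 0
  expect_equal(count_stationary_vicinity(two_ind_session(5, d = 6),
                                         "AAA", "BBB"), 0L)
  # interaction is exclusive: grooming at 1 m is not stationary vicinity
  rec <- two_ind_session(5, d = 1, a_beh = "grooming", a_partner = "BBB")
  expect_equal(count_stationary_vicinity(rec, "AAA", "BBB"), 0L)
})

test_that("passive close proximity uses the arms-reach union minus interaction", {
  rec <- two_ind_session(7, arms_a = "BBB")
  expect_equal(count_passive_close_proximity(rec, "AAA", "BBB"), 7L)

  # 2 of 7 arm's-reach scans carry grooming -> 5 (recount oracle)
  beh <- c("grooming", "grooming", rep("none", 5))
  rec <- two_ind_session(7, arms_a = c("", "", rep("BBB", 5)),
                         a_beh = beh,
                         a_partner = c("BBB", "BBB", rep(NA, 5)))
  rec$arms_reach[rec$individual == "BBB"] <- "AAA"  # asymmetric annotation
  expect_equal(count_passive_close_proximity(rec, "AAA", "BBB"), 5L)
  expect_equal(count_passive_close_proximity(rec, "BBB", "AAA"),
               count_passive_close_proximity(rec, "AAA", "BBB"))
})

test_that("directed counts follow the sender's behavior records", {
  beh <- c(rep("grooming", 20), rep("none", 80))
  rec <- two_ind_session(100, a_beh = beh,
                         a_partner = c(rep("BBB", 20), rep(NA, 80)))
  expect_equal(count_directed(rec, "AAA", "BBB", "grooming"), 20L)
  expect_equal(count_directed(rec, "BBB", "AAA", "grooming"), 0L)
  expect_equal(count_directed(rec, "AAA", "BBB", "affiliative"), 0L)

  # mutual grooming increments both directions
  rec <- bind_records(
    rec_row("AAA", behavior = "grooming", partner = "BBB"),
    rec_row("BBB", behavior = "grooming", partner = "AAA"))
  expect_equal(count_directed(rec, "AAA", "BBB", "grooming"), 1L)
  expect_equal(count_directed(rec, "BBB", "AAA", "grooming"), 1L)
  expect_error(count_directed(rec, "AAA", "AAA", "grooming"), "differ")
})

test_that("the index table has full dyad coverage and exact arithmetic", {
  cfg <- synth_config(n_groups = 1, n_sessions = 10, seed = 8)
  roster <- make_roster(cfg)
  rec <- simulate_scans(dyad_state_probs(roster, cfg))
  idx <- compute_indices(rec, roster)
  # 7 individuals -> 42 ordered dyads x 4 layers = 168 rows
  expect_equal(nrow(idx), 168L)
  expect_true(all(idx$count <= idx$denominator))
  expect_equal(idx$index, ifelse(idx$denominator == 0, 0,
                                 idx$count / idx$denominator))

  # symmetric layers are symmetric
  sym <- idx[idx$layer %in% c("stationary_vicinity",
                              "passive_close_proximity"), ]
  key <- paste(sym$layer, pmin(sym$sender, sym$receiver),
               pmax(sym$sender, sym$receiver))
  expect_true(all(tapply(sym$count, key,
                         function(x) length(unique(x))) == 1L))

  # per-dyad exclusivity: four layer counts never exceed the denominator
  tot <- tapply(idx$count, paste(idx$sender, idx$receiver), sum)
  den <- tapply(idx$denominator, paste(idx$sender, idx$receiver), max)
  expect_true(all(tot <= den))

  # an individual without any enclosure access yields a zero denominator
  rec0 <- two_ind_session(5, b_access = FALSE, b_visible = FALSE)
  expect_warning(idx0 <- compute_indices(rec0, two_ind_roster()),
                 "zero access denominator")
  expect_true(all(idx0$index == 0))
})

test_that("weighted normalization pools the per-layer maximum across groups", {
  tab <- data.frame(
    group = rep(c("A", "B"), each = 2),
    sender = c("a1", "a2", "b1", "b2"),
    receiver = c("a2", "a1", "b2", "b1"),
    layer = factor("grooming", levels = panmux:::.layer_names),
    count = c(2, 4, 8, 0), denominator = 10,
    index = c(0.2, 0.4, 0.8, 0), weighted = NA_real_,
    stringsAsFactors = FALSE)
  class(tab) <- c("dyad_index_table", "data.frame")
  out <- normalize_weighted(tab)
  # pooled max is 0.8 (group B), so group A's 0.4 maps to 0.5
  expect_equal(out$weighted, c(0.25, 0.5, 1, 0))
  # the layer-maximum dyad scores exactly 1
  expect_equal(max(out$weighted), 1)
  # idempotence
  again <- normalize_weighted(out)
  expect_equal(again$weighted, out$weighted)

  # all-zero layer -> zeros with a warning
  tab$index <- 0
  expect_warning(z <- normalize_weighted(tab), "no positive")
  expect_true(all(z$weighted == 0))
})
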