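test_that("biography roster parses, validates enums and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,sex,origin,phc_infant,year_birth,year_arrival,group",
               "BEA,Bea,F,wild,with,1985,2012,Bilinga",
               "NIC,Nico,M,captive,without,2001,2004,Bilinga"), f)
  roster <- read_biographies(f)
  expect_s3_class(roster, "panmux_roster")
  expect_equal(roster$id, c("BEA", "NIC"))
  expect_equal(as.character(roster$sex), c("F", "M"))
  expect_equal(as.character(roster$origin), c("wild", "captive"))
  expect_equal(as.character(roster$phc_infant), c("with", "without"))

  # header-only file -> empty roster
  writeLines("id,name,sex,origin,phc_infant,year_birth,year_arrival,group", f)
  expect_equal(nrow(read_biographies(f)), 0L)

  # duplicate id
  writeLines(c("id,name,sex,origin,phc_infant,year_birth,year_arrival,group",
               "BEA,Bea,F,wild,with,1985,2012,Bilinga",
               "BEA,Bea2,F,wild,with,1985,2012,Bilinga"), f)
  expect_error(read_biographies(f), "duplicate")

  # missing column named in the error
  writeLines(c("id,name,sex,origin,phc_infant,year_birth,year_arrival",
               "BEA,Bea,F,wild,with,1985,2012"), f)
  expect_error(read_biographies(f), "group")

  # unknown enum token
  writeLines(c("id,name,sex,origin,phc_infant,year_birth,year_arrival,group",
               "BEA,Bea,X,wild,with,1985,2012,Bilinga"), f)
  expect_error(read_biographies(f), "sex")
})

test_that("published roster has the documented shape", {
  roster <- mona_roster()
  expect_equal(nrow(roster), 14L)
  expect_equal(sort(unique(roster$group)), c("Bilinga", "Mutamba"))
  expect_equal(unname(table(roster$group)), array(c(7L, 7L)))
  expect_equal(sum(roster$sex == "M"), 9L)
  expect_equal(sum(roster$origin == "wild"), 7L)
})

test_that("scan CSV reading resolves ids, sorts, and collects issues", {
  roster <- two_ind_roster()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0("group,session_id,scan_index,individual,access,visible,",
                      "behavior,partner,arms_reach,pos_x,pos_y,height_level"),
               "G1,S1,1,BBB,1,1,,,,5,0,0",
               "G1,S1,1,AAA,1,1,grooming,BBB,,0,0,0"), f)
  rec <- read_scans(f, roster)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$individual, c("AAA", "BBB"))  # sorted within scan
  expect_equal(nrow(scan_issues(rec)), 0L)

  # grooming without partner is a record-level validation issue, not a crash
  writeLines(c(paste0("group,session_id,scan_index,individual,access,visible,",
                      "behavior,partner,arms_reach,pos_x,pos_y,height_level"),
               "G1,S1,1,AAA,1,1,grooming,,,0,0,0"), f)
  rec <- read_scans(f, roster)
  expect_true(any(grepl("without partner", scan_issues(rec)$problem)))

  # malformed position is collected, unknown id is fatal
  writeLines(c(paste0("group,session_id,scan_index,individual,access,visible,",
                      "behavior,partner,arms_reach,pos_x,pos_y,height_level"),
               "G1,S1,1,AAA,1,1,,,,oops,0,0"), f)
  expect_true(any(grepl("malformed position",
                        scan_issues(read_scans(f, roster))$problem)))
  writeLines(c(paste0("group,session_id,scan_index,individual,access,visible,",
                      "behavior,partner,arms_reach,pos_x,pos_y,height_level"),
               "G1,S1,1,ZZZ,1,1,,,,0,0,0"), f)
  expect_error(read_scans(f, roster), "unknown individual")
})

test_that("a simulated session round-trips through the CSV dialect", {
  cfg <- synth_config(n_groups = 1, n_sessions = 1, seed = 5)
  roster <- make_roster(cfg)
  rec <- simulate_scans(dyad_state_probs(roster, cfg))
  expect_equal(nrow(rec), 7L * 10L)  # 7 individuals x 10 scans

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_scans(rec, f1)
  back <- read_scans(f1, roster)
  expect_equal(nrow(scan_issues(back)), 0L)
  write_scans(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (col in setdiff(names(rec), NULL)) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
})

test_that("access denominator counts access, not visibility", {
  # both individuals with access at all 10 scans -> 10
  rec <- two_ind_session(10)
  expect_equal(access_denominator(rec, "AAA", "BBB"), 10L)

  # B indoors (access but invisible) for 4 scans still counts -> 10
  rec <- two_ind_session(10, b_visible = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(access_denominator(rec, "AAA", "BBB"), 10L)

  # B separated (no access) for 3 scans -> 7, matching a brute-force recount
  b_acc <- c(rep(TRUE, 7), rep(FALSE, 3))
  rec <- two_ind_session(10, b_access = b_acc,
                         b_visible = b_acc)
  expect_equal(access_denominator(rec, "AAA", "BBB"), 7L)
  brute <- sum(vapply(1:10, function(s) {
    r <- rec[rec$scan_index == s, ]
    all(r$access)
  }, logical(1)))
  expect_equal(access_denominator(rec, "AAA", "BBB"), brute)

  # symmetry and error cases
  expect_equal(access_denominator(rec, "BBB", "AAA"),
               access_denominator(rec, "AAA", "BBB"))
  expect_error(access_denominator(rec, "AAA", "AAA"), "distinct")
  rec2 <- bind_records(rec, rec_row("CCC", group = "G2"))
  expect_error(access_denominator(rec2, "AAA", "CCC"), "different groups")
})

test_that("exclusivity audit flags double-credited dyad-scans only", {
  # grooming with the receiver in the groomer's arms-reach set -> flagged
  bad <- bind_records(
    rec_row("AAA", behavior = "grooming", partner = "BBB",
            arms_reach = "BBB", pos_x = 0, pos_y = 0, height_level = 0),
    rec_row("BBB", pos_x = 0.5, pos_y = 0, height_level = 0))
  rep <- validate_exclusivity(bad)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$states, "grooming")
  expect_match(rep$states, "passive_close_proximity")

  # exclusivity is per dyad: grooming B while C is in arm's reach is fine
  ok <- bind_records(
    rec_row("AAA", behavior = "grooming", partner = "BBB", arms_reach = "CCC",
            pos_x = 0, pos_y = 0, height_level = 0),
    rec_row("BBB", pos_x = 0.5, pos_y = 0, height_level = 0),
    rec_row("CCC", arms_reach = "AAA", pos_x = 0.5, pos_y = 0.5,
            height_level = 0))
  expect_equal(nrow(validate_exclusivity(ok)), 0L)

  # empty record list -> empty report
  expect_equal(nrow(validate_exclusivity(bad[0L, ])), 0L)
})
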