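# Scan-sampling observation records.
#
# Canonical CSV dialect (header required, UTF-8, comma-separated):
#   group,session_id,scan_index,individual,access,visible,behavior,partner,
#   arms_reach,pos_x,pos_y,height_level
# booleans are 0/1, empty string means missing, arms_reach is a ';'-separated
# id list. One row per individual per two-minute scan; sessions comprise
# `scans_per_session` scans (10 by default: a 20-minute session scanned every
# two minutes, first scan at minute 2).

.scan_cols <- c("group", "session_id", "scan_index", "individual", "access",
                "visible", "behavior", "partner", "arms_reach", "pos_x",
                "pos_y", "height_level")
.behavior_levels <- c("none", "affiliative", "grooming", "other")

#' Read scan records
#'
#' Reads a scan-sampling log in the canonical CSV dialect and validates it
#' against a roster. Unknown individual or partner ids are a hard error;
#' record-level problems (malformed positions, invariant violations such as a
#' grooming record without a partner) are collected into a validation report
#' attached as attribute `"issues"` and retrievable with [scan_issues()].
#'
#' @param path Path to a scans CSV file.
#' @param roster Roster from [read_biographies()].
#' @return A `data.frame` of scan records sorted by
#'   `(session_id, scan_index, individual)`, with a validation report in
#'   `attr(, "issues")`.
#' @export
read_scans <- function(path, roster) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(.scan_cols, names(raw))
  if (length(missing) > 0L) {
    stop("scan file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .scan_cols]
  unknown <- setdiff(unique(raw$individual), roster$id)
  if (length(unknown) > 0L) {
    stop("scan file contains unknown individual id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  partners <- setdiff(unique(raw$partner), c("", roster$id))
  if (length(partners) > 0L) {
    stop("scan file contains unknown partner id(s): ",
         paste(partners, collapse = ", "), call. = FALSE)
  }
  arm_ids <- setdiff(unique(unlist(strsplit(raw$arms_reach, ";", fixed = TRUE))),
                     roster$id)
  if (length(arm_ids) > 0L) {
    stop("scan file contains unknown arms_reach id(s): ",
         paste(arm_ids, collapse = ", "), call. = FALSE)
  }

  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  rec <- data.frame(
    group = raw$group,
    session_id = raw$session_id,
    scan_index = as.integer(raw$scan_index),
    individual = raw$individual,
    access = raw$access == "1",
    visible = raw$visible == "1",
    behavior = ifelse(raw$behavior == "", "none", raw$behavior),
    partner = ifelse(raw$partner == "", NA_character_, raw$partner),
    arms_reach = raw$arms_reach,
    pos_x = num_or_na(raw$pos_x),
    pos_y = num_or_na(raw$pos_y),
    height_level = as.integer(ifelse(raw$height_level == "", NA,
                                     raw$height_level)),
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$session_id, rec$scan_index, rec$individual), ,
             drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "issues") <- .validate_records(rec, raw)
  rec
}

.validate_records <- function(rec, raw) {
  issue <- function(idx, problem) {
    if (!any(idx)) return(NULL)
    data.frame(session_id = rec$session_id[idx],
               scan_index = rec$scan_index[idx],
               individual = rec$individual[idx],
               problem = problem, stringsAsFactors = FALSE)
  }
  malformed_pos <- (!is.na(rec$pos_x) & is.na(rec$pos_y)) |
    (is.na(rec$pos_x) & !is.na(rec$pos_y))
  if (!missing(raw)) {
    raw <- raw[order(raw$session_id, as.integer(raw$scan_index),
                     raw$individual), , drop = FALSE]
    malformed_pos <- malformed_pos |
      (raw$pos_x != "" & is.na(rec$pos_x)) | (raw$pos_y != "" & is.na(rec$pos_y))
  }
  arms <- strsplit(rec$arms_reach, ";", fixed = TRUE)
  self_arm <- mapply(function(a, ind) ind %in% a, arms, rec$individual)
  issues <- rbind(
    issue(malformed_pos, "malformed position"),
    issue(!rec$behavior %in% .behavior_levels, "unknown behavior code"),
    issue(!is.na(rec$partner) & rec$partner == rec$individual,
          "individual recorded as its own partner"),
    issue(self_arm, "individual recorded in its own arms_reach set"),
    issue(!is.na(rec$height_level) &
            (rec$height_level < 0L | rec$height_level > 4L),
          "height_level outside 0-4"),
    issue(rec$behavior %in% c("affiliative", "grooming") & is.na(rec$partner),
          "directed behavior without partner"),
    issue(!rec$visible & (rec$behavior != "none" | !is.na(rec$partner) |
                            rec$arms_reach != "" | !is.na(rec$pos_x)),
          "invisible record carries observations")
  )
  if (is.null(issues)) {
    issues <- data.frame(session_id = character(), scan_index = integer(),
                         individual = character(), problem = character(),
                         stringsAsFactors = FALSE)
  }
  issues
}

#' Validation report of a scan table
#'
#' @param records Records as returned by [read_scans()] or [simulate_scans()].
#' @return Data frame of record-level validation issues (possibly empty).
#' @export
scan_issues <- function(records) {
  iss <- attr(records, "issues")
  if (is.null(iss)) iss <- .validate_records(records)
  iss
}

#' Write scan records
#'
#' Writes records back to the canonical CSV dialect (the inverse of
#' [read_scans()]): booleans as 0/1, missing values as empty strings.
#'
#' @param records Scan records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(records, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                     scientific = FALSE))
  out <- data.frame(
    group = records$group,
    session_id = records$session_id,
    scan_index = records$scan_index,
    individual = records$individual,
    access = as.integer(records$access),
    visible = as.integer(records$visible),
    behavior = ifelse(records$behavior == "none", "", records$behavior),
    partner = ifelse(is.na(records$partner), "", records$partner),
    arms_reach = records$arms_reach,
    pos_x = fmt_num(records$pos_x),
    pos_y = fmt_num(records$pos_y),
    height_level = ifelse(is.na(records$height_level), "",
                          records$height_level),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reshape one group's records into per-individual-by-scan matrices; the
# workhorse layout for all pairwise counting. Scans are ordered by
# (session_id, scan_index).
.scan_arrays <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  ids <- sort(unique(records$individual))
  n <- length(ids)
  key <- unique(records[, c("session_id", "scan_index")])
  key <- key[order(key$session_id, key$scan_index), , drop = FALSE]
  s_of <- match(paste(records$session_id, records$scan_index, sep = "\r"),
                paste(key$session_id, key$scan_index, sep = "\r"))
  i_of <- match(records$individual, ids)
  S <- nrow(key)
  mk <- function(init) matrix(init, nrow = n, ncol = S)
  idx <- cbind(i_of, s_of)
  access <- mk(FALSE); access[idx] <- records$access
  visible <- mk(FALSE); visible[idx] <- records$visible
  beh <- mk("none"); beh[idx] <- records$behavior
  partner <- mk(NA_character_); partner[idx] <- records$partner
  x <- mk(NA_real_); x[idx] <- records$pos_x
  y <- mk(NA_real_); y[idx] <- records$pos_y
  h <- mk(NA_integer_); h[idx] <- records$height_level

  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else
    matrix(integer(), ncol = 2L)
  # arms-reach union per unordered pair per scan
  arm <- matrix(FALSE, nrow = nrow(pairs), ncol = S)
  has_arm <- which(records$arms_reach != "")
  if (length(has_arm) > 0L && n >= 2L) {
    lst <- strsplit(records$arms_reach[has_arm], ";", fixed = TRUE)
    reps <- lengths(lst)
    a <- rep(i_of[has_arm], reps)
    b <- match(unlist(lst), ids)
    s <- rep(s_of[has_arm], reps)
    keep <- !is.na(b) & a != b
    lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
    p <- match(paste(lo, hi), paste(pairs[, 1L], pairs[, 2L]))
    arm[cbind(p, s[keep])] <- TRUE
  }
  list(ids = ids, n = n, key = key, S = S, access = access, visible = visible,
       beh = beh, partner = partner, x = x, y = y, h = h,
       pairs = pairs, arm = arm)
}

# Per-pair-per-scan raw channel matrices (P x S logical) for one group.
.pair_channels <- function(arr) {
  P <- nrow(arr$pairs)
  dir_mat <- function(class) {
    m <- matrix(FALSE, nrow = P, ncol = arr$S)
    for (p in seq_len(P)) {
      i <- arr$pairs[p, 1L]; j <- arr$pairs[p, 2L]
      m[p, ] <- (arr$beh[i, ] == class & !is.na(arr$partner[i, ]) &
                   arr$partner[i, ] == arr$ids[j]) |
        (arr$beh[j, ] == class & !is.na(arr$partner[j, ]) &
           arr$partner[j, ] == arr$ids[i])
    }
    m
  }
  aff <- dir_mat("affiliative")
  grm <- dir_mat("grooming")
  interact <- aff | grm
  sv <- matrix(FALSE, nrow = P, ncol = arr$S)
  for (p in seq_len(P)) {
    i <- arr$pairs[p, 1L]; j <- arr$pairs[p, 2L]
    d2 <- (arr$x[i, ] - arr$x[j, ])^2 + (arr$y[i, ] - arr$y[j, ])^2
    dh <- abs(arr$h[i, ] - arr$h[j, ])
    ok <- arr$visible[i, ] & arr$visible[j, ] & !is.na(d2) & !is.na(dh) &
      d2 <= 25 & dh <= 1L
    sv[p, ] <- ok & !arr$arm[p, ] & !interact[p, ]
  }
  list(aff = aff, grm = grm, arm = arr$arm, sv = sv, interact = interact)
}

#' Audit per-dyad exclusivity of the four interaction states
#'
#' The four interaction indices are mutually exclusive per dyad and scan: a
#' dyad cannot simultaneously be credited with stationary vicinity,
#' affiliative behaviour, allogrooming and/or passive close proximity. This
#' audit flags every (dyad, scan) whose raw annotation channels credit more
#' than one state -- e.g. a grooming record whose receiver is also listed in
#' the groomer's arms-reach set. Exclusivity is per dyad: interactions of the
#' two individuals with third parties are not conflicts.
#'
#' @param records Scan records.
#' @return Data frame with one row per offending (session, scan, dyad) and the
#'   states credited; zero rows when the table is clean.
#' @export
validate_exclusivity <- function(records) {
  empty <- data.frame(group = character(), session_id = character(),
                      scan_index = integer(), id_a = character(),
                      id_b = character(), states = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  out <- empty
  for (g in unique(records$group)) {
    arr <- .scan_arrays(records, g)
    if (arr$n < 2L) next
    ch <- .pair_channels(arr)
    credit <- ch$sv + ch$aff + ch$grm + ch$arm
    bad <- which(credit > 1L, arr.ind = TRUE)
    if (nrow(bad) == 0L) next
    states <- character(nrow(bad))
    labs <- c("stationary_vicinity", "affiliative", "grooming",
              "passive_close_proximity")
    for (k in seq_len(nrow(bad))) {
      p <- bad[k, 1L]; s <- bad[k, 2L]
      on <- c(ch$sv[p, s], ch$aff[p, s], ch$grm[p, s], ch$arm[p, s])
      states[k] <- paste(labs[on], collapse = "+")
    }
    out <- rbind(out, data.frame(
      group = g,
      session_id = arr$key$session_id[bad[, 2L]],
      scan_index = arr$key$scan_index[bad[, 2L]],
      id_a = arr$ids[arr$pairs[bad[, 1L], 1L]],
      id_b = arr$ids[arr$pairs[bad[, 1L], 2L]],
      states = states, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Dyadic access denominator
#'
#' Number of scans in which two individuals had access to each other, i.e.
#' both had access to the outdoor enclosure. Scans where one of the two was
#' indoors (access granted but not visible to the observer) count; scans where
#' one was separated (no access) do not. This is the denominator of all four
#' interaction indices.
#'
#' @param records Scan records.
#' @param a,b Individual ids (distinct, same group).
#' @return Integer scan count.
#' @export
access_denominator <- function(records, a, b) {
  if (a == b) stop("access denominator is defined for distinct individuals",
                   call. = FALSE)
  ga <- unique(records$group[records$individual == a])
  gb <- unique(records$group[records$individual == b])
  if (length(ga) != 1L || length(gb) != 1L) {
    stop("individual(s) not found in records: ",
         paste(c(a, b)[c(length(ga) != 1L, length(gb) != 1L)], collapse = ", "),
         call. = FALSE)
  }
  if (ga != gb) stop("individuals ", a, " and ", b,
                     " belong to different groups", call. = FALSE)
  arr <- .scan_arrays(records, ga)
  i <- match(a, arr$ids); j <- match(b, arr$ids)
  sum(arr$access[i, ] & arr$access[j, ])
}
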