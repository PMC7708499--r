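#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the biography roster. `origin` distinguishes
# wild-caught from captive-born individuals; `phc_infant` is the predominant
# housing condition during the first five years of life (with vs without
# conspecifics for more than 2.5 of those years).
.sex_levels <- c("F", "M")
.origin_levels <- c("wild", "captive")
.phc_levels <- c("with", "without")

.biography_cols <- c("id", "name", "sex", "origin", "phc_infant",
                     "year_birth", "year_arrival", "group")

#' Read a biography roster
#'
#' Reads the per-individual biography table (one row per chimpanzee) used to
#' resolve scan records and to build the dyadic model design. Enumerated
#' columns are validated against their controlled vocabularies.
#'
#' @param path Path to a CSV file with columns
#'   `id,name,sex,origin,phc_infant,year_birth,year_arrival,group`.
#' @return A `data.frame` with one row per individual; `sex`, `origin` and
#'   `phc_infant` are factors with levels `F/M`, `wild/captive` and
#'   `with/without` respectively.
#' @examples
#' roster <- read_biographies(system.file("extdata", "mona_biographies.csv",
#'                                        package = "panmux"))
#' table(roster$group)
#' @export
read_biographies <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(.biography_cols, names(raw))
  if (length(missing) > 0L) {
    stop("biography file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .biography_cols]
  if (nrow(raw) == 0L) {
    return(.as_roster(raw[0L, ]))
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    stop("duplicate individual id(s) in roster: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  .as_roster(raw)
}

.as_roster <- function(raw) {
  parse_enum <- function(x, levels, what) {
    bad <- setdiff(unique(x), levels)
    if (length(bad) > 0L) {
      stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "),
           "; expected one of ", paste(levels, collapse = "/"), call. = FALSE)
    }
    factor(x, levels = levels)
  }
  out <- data.frame(
    id = as.character(raw$id),
    name = as.character(raw$name),
    sex = parse_enum(raw$sex, .sex_levels, "sex"),
    origin = parse_enum(raw$origin, .origin_levels, "origin"),
    phc_infant = parse_enum(raw$phc_infant, .phc_levels, "phc_infant"),
    year_birth = as.integer(raw$year_birth),
    year_arrival = as.integer(raw$year_arrival),
    group = as.character(raw$group),
    stringsAsFactors = FALSE
  )
  bad_years <- !is.na(out$year_arrival) & !is.na(out$year_birth) &
    out$year_arrival < out$year_birth
  if (any(bad_years)) {
    stop("year_arrival precedes year_birth for: ",
         paste(out$id[bad_years], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("panmux_roster", "data.frame")
  out
}

#' Published study roster
#'
#' The biography table of the 14 former pet and entertainment chimpanzees of
#' the Fundacio MONA sanctuary (two social groups of seven individuals each),
#' as published with the study this package reimplements.
#'
#' @return A roster `data.frame` (see [read_biographies()]).
#' @export
mona_roster <- function() {
  read_biographies(system.file("extdata", "mona_biographies.csv",
                               package = "panmux", mustWork = TRUE))
}

#' Published per-group scan totals
#'
#' Total number of individual scan records collected per social group during
#' the observation period, as published. Used for observation-effort
#' accounting.
#'
#' @return Named numeric vector of per-group scan counts.
#' @seealso [scan_accounting()]
#' @export
mona_scan_totals <- function() {
  c(Bilinga = 32320, Mutamba = 35677)
}

#' Observation-effort accounting
#'
#' Sums per-group scan totals into an overall observation-effort count.
#'
#' @param per_group Named numeric vector of per-group scan counts.
#' @return A list with elements `per_group` and `total`.
#' @examples
#' scan_accounting(mona_scan_totals())$total
#' @export
scan_accounting <- function(per_group) {
  stopifnot(is.numeric(per_group), length(per_group) >= 1L)
  list(per_group = per_group, total = sum(per_group))
}
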