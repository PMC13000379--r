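#' Cleanse sex fields
#'
#' Removes records with missing sex and normalizes verbose sex codes
#' (`"men"` to `M`, `"women"` to `F`; case-insensitive `male`/`female`
#' variants likewise). Tokens outside the normalization map are dropped and
#' reported, never guessed. Idempotent on clean tables.
#'
#' @param table Date-standardized encounter table with a `sex` column.
#' @return `list(table, report)` with `report$dropped_missing_sex`,
#'   `report$dropped_unknown_sex` and `report$n_normalized`.
#' @export
cleanse <- function(table) {
  tab <- data.table::copy(data.table::as.data.table(table))
  if (!"sex" %in% names(tab)) stop("no 'sex' column", call. = FALSE)
  raw <- as.character(tab$sex)
  missing <- is.na(raw) | raw == ""
  map <- c(m = "M", male = "M", men = "M", f = "F", female = "F", women = "F")
  norm <- unname(map[tolower(raw)])
  unknown <- !missing & is.na(norm)
  keep <- !missing & !unknown
  out <- tab[keep]
  out[, sex := norm[keep]]
  list(table = out,
       report = list(dropped_missing_sex = sum(missing),
                     dropped_unknown_sex = sum(unknown),
                     unknown_tokens = utils::head(unique(raw[unknown]), 10L),
                     n_normalized = sum(keep & !(raw %in% c("M", "F")))))
}

#' Deduplicate encounter records
#'
#' At most one row survives per (patient, date, diagnosis code); the
#' retained row is the most recent — the last-loaded among rows sharing the
#' key, since load order is the only ordering left when dates tie.
#'
#' @param table Cleansed table with ISO dates.
#' @return Deduplicated `data.table`, original (positional) order preserved
#'   among retained rows.
#' @export
deduplicate <- function(table) {
  tab <- data.table::as.data.table(table)
  unique(tab, by = c("patient_id", "visit_date", "dx_code"), fromLast = TRUE)
}

#' Segment visits into care episodes
#'
#' Within each patient (sorted by date), a new episode starts whenever the
#' department differs from the previous event or the date gap exceeds
#' `gap_days`. Every event belongs to exactly one episode; episode summaries
#' report start/end dates, duration in days, event count and whether any
#' event carried a primary-diagnosis flag.
#'
#' @param table Deduplicated table.
#' @param gap_days Positive gap threshold in days (default 30; the boundary
#'   itself does not split — only gaps strictly greater).
#' @return An episode `data.table` (`episode_id`, `patient_id`,
#'   `department`, `start_date`, `end_date`, `duration_days`, `event_count`,
#'   `has_primary_dx`).
#' @export
segment_episodes <- function(table, gap_days = 30L) {
  if (gap_days <= 0) stop("gap_days must be positive", call. = FALSE)
  tab <- data.table::as.data.table(table)
  if (nrow(tab) == 0L) {
    return(data.table::data.table(
      episode_id = character(), patient_id = character(), department = character(),
      start_date = character(), end_date = character(), duration_days = integer(),
      event_count = integer(), has_primary_dx = logical()
    ))
  }
  ev <- tab[, list(patient_id, department, is_primary,
                   date = as.Date(visit_date))]
  data.table::setorder(ev, patient_id, date)
  ev[, gap__ := as.integer(date - data.table::shift(date)), by = patient_id]
  ev[, new_ep__ := is.na(gap__) | gap__ > gap_days |
       department != data.table::shift(department, fill = "\r"),
     by = patient_id]
  ev[, episode_id := paste0(patient_id, ":", cumsum(new_ep__)), by = patient_id]
  eps <- ev[, list(
    patient_id = patient_id[1L],
    department = department[1L],
    start_date = format(min(date), "%Y-%m-%d"),
    end_date = format(max(date), "%Y-%m-%d"),
    duration_days = as.integer(max(date) - min(date)),
    event_count = .N,
    has_primary_dx = any(is_primary)
  ), by = episode_id]
  eps[]
}

#' Trailing rolling-window features per event
#'
#' For each diagnosis event at date `d`, counts that patient's events with
#' dates in the inclusive trailing window `[d - (window_days - 1), d]`:
#' total diagnosis count and distinct-code diversity. The window contains
#' the event itself, so both values are at least 1.
#'
#' @param table Deduplicated table.
#' @param window_days Window length in calendar days (default 90).
#' @return The event table with `roll_dx_count` and `roll_code_diversity`
#'   columns appended (rows ordered by patient, date).
#' @export
rolling_features <- function(table, window_days = 90L) {
  if (window_days <= 0) stop("window_days must be positive", call. = FALSE)
  tab <- data.table::copy(data.table::as.data.table(table))
  if (nrow(tab) == 0L) {
    tab[, c("roll_dx_count", "roll_code_diversity") := list(integer(), integer())]
    return(tab)
  }
  tab[, row__ := .I]
  data.table::setorder(tab, patient_id, visit_date, row__)
  tab[, c("roll_dx_count", "roll_code_diversity") := {
    d <- as.integer(as.Date(visit_date))
    hi <- findInterval(d, d)
    lo <- findInterval(d - window_days, d) + 1L
    div <- vapply(seq_along(d), function(i) {
      length(unique(dx_code[lo[i]:hi[i]]))
    }, integer(1))
    list(hi - lo + 1L, div)
  }, by = patient_id]
  tab[, row__ := NULL]
  tab[]
}

#' Monthly cohort aggregates
#'
#' Calendar-month summaries of a deduplicated table: distinct patients,
#' distinct codes across the cohort, primary-diagnosis event counts, and
#' p50/p90 quantiles (linear interpolation between order statistics) of
#' per-patient event counts within the month. Months without events are
#' absent, never zero-filled.
#'
#' @param table Deduplicated table.
#' @param diversity `"cohort"` (default): distinct codes across the whole
#'   month; `"patient"`: mean per-patient distinct-code count.
#' @return `data.table(month, patient_count, distinct_code_count,
#'   primary_dx_count, p50, p90)`.
#' @export
monthly_aggregates <- function(table, diversity = c("cohort", "patient")) {
  diversity <- match.arg(diversity)
  tab <- data.table::as.data.table(table)
  if (nrow(tab) == 0L) {
    return(data.table::data.table(month = character(), patient_count = integer(),
                                  distinct_code_count = numeric(),
                                  primary_dx_count = integer(),
                                  p50 = numeric(), p90 = numeric()))
  }
  tab <- tab[, list(patient_id, dx_code, is_primary,
                    month = substr(visit_date, 1L, 7L))]
  out <- tab[, {
    per_pat <- .SD[, .N, by = patient_id]$N
    list(
      patient_count = data.table::uniqueN(patient_id),
      distinct_code_count = if (diversity == "cohort") {
        as.numeric(data.table::uniqueN(dx_code))
      } else {
        mean(.SD[, data.table::uniqueN(dx_code), by = patient_id]$V1)
      },
      primary_dx_count = sum(is_primary),
      p50 = unname(quantile(per_pat, 0.50, type = 7)),
      p90 = unname(quantile(per_pat, 0.90, type = 7))
    )
  }, by = month]
  data.table::setorder(out, month)
  out[]
}

#' Extract patient-level summaries for target conditions
#'
#' For each condition specification (exact code or prefix range), selects
#' the matching diagnosis events and summarizes per patient: first and last
#' matching date and event count.
#'
#' @param table Deduplicated table.
#' @param code_specs Named list/vector of specs, e.g.
#'   `c(hypertension = "I10.9", diabetes = "E10-E14", spine = "M48.06")`.
#' @return Named list of `data.table(patient_id, first_date, last_date,
#'   event_count)`, one per condition.
#' @export
extract_targets <- function(table, code_specs) {
  tab <- data.table::as.data.table(table)
  specs <- lapply(code_specs, code_spec)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, function(s) s$spec, character(1))
  }
  lapply(specs, function(s) {
    hit <- tab[match_codes(dx_code, s)]
    if (nrow(hit) == 0L) {
      return(data.table::data.table(patient_id = character(),
                                    first_date = character(),
                                    last_date = character(),
                                    event_count = integer()))
    }
    out <- hit[, list(first_date = min(visit_date), last_date = max(visit_date),
                      event_count = .N), by = patient_id]
    data.table::setorder(out, patient_id)
    out[]
  })
}
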