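#' Standardize raw date strings to ISO-8601
#'
#' Parses the whitelisted date dialects — `YYYY-MM-DD`, `YYYYMMDD`,
#' `DD/MM/YYYY`, `YYYY.MM.DD` — into `YYYY-MM-DD`. Anything outside the
#' whitelist (or calendar-invalid) is dropped and counted, never silently
#' coerced. Idempotent on its own output.
#'
#' @param table Encounter table with a raw string date column.
#' @param date_col Name of the date column (default `"visit_date"`).
#' @return `list(table = <standardized table>, report = list(n_in, n_out,
#'   dropped, dropped_values))`.
#' @export
standardize_dates <- function(table, date_col = "visit_date") {
  tab <- data.table::as.data.table(table)
  if (!date_col %in% names(tab)) stop("no column '", date_col, "'", call. = FALSE)
  raw <- as.character(tab[[date_col]])
  parsed <- rep(as.Date(NA), length(raw))
  pats <- list(
    c("^\\d{4}-\\d{2}-\\d{2}$", "%Y-%m-%d"),
    c("^\\d{8}$", "%Y%m%d"),
    c("^\\d{2}/\\d{2}/\\d{4}$", "%d/%m/%Y"),
    c("^\\d{4}\\.\\d{2}\\.\\d{2}$", "%Y.%m.%d")
  )
  for (p in pats) {
    sel <- grepl(p[1], raw) & is.na(parsed)
    if (any(sel)) parsed[sel] <- as.Date(raw[sel], format = p[2])
  }
  ok <- !is.na(parsed)
  out <- tab[ok]
  data.table::set(out, j = date_col, value = format(parsed[ok], "%Y-%m-%d"))
  list(
    table = out,
    report = list(n_in = nrow(tab), n_out = nrow(out),
                  dropped = sum(!ok),
                  dropped_values = utils::head(unique(raw[!ok]), 20L))
  )
}

#' Replace patient identifiers with random surrogate IDs
#'
#' Every original identifier is replaced by an opaque random token;
#' the mapping is bijective, reproducible for a fixed seed, and no surrogate
#' collides with any original identifier, so longitudinal linkage is
#' preserved while direct identity is severed.
#'
#' @param table Table with an identifier column.
#' @param seed Integer seed for surrogate generation.
#' @param id_col Identifier column name (default `"patient_id"`).
#' @return `list(table = <re-keyed table>, map = <surrogate_map>)` where the
#'   map is a `data.table(original_id, surrogate_id)` of class
#'   `surrogate_map`.
#' @export
assign_surrogates <- function(table, seed = 42L, id_col = "patient_id") {
  tab <- data.table::as.data.table(table)
  if (!id_col %in% names(tab)) stop("no column '", id_col, "'", call. = FALSE)
  originals <- unique(tab[[id_col]])
  map <- with_seed(seed, {
    alphabet <- c(LETTERS, 0:9)
    gen <- function(n) {
      vapply(seq_len(n), function(i) {
        paste0("S-", paste(sample(alphabet, 10L, replace = TRUE), collapse = ""))
      }, character(1))
    }
    surr <- gen(length(originals))
    # regenerate internal collisions (with each other or with originals)
    repeat {
      bad <- duplicated(surr) | surr %in% originals
      if (!any(bad)) break
      surr[bad] <- gen(sum(bad))
    }
    data.table::data.table(original_id = originals, surrogate_id = surr)
  })
  data.table::setattr(map, "class", c("surrogate_map", class(map)))
  data.table::setattr(map, "seed", as.integer(seed))
  out <- data.table::copy(tab)
  data.table::set(out, j = id_col,
                  value = map$surrogate_id[match(out[[id_col]], map$original_id)])
  list(table = out, map = map)
}

#' k-anonymity policy
#'
#' @param k Minimum equivalence-class size (>= 2; default 5).
#' @param quasi_identifiers Ordered quasi-identifier columns, default
#'   `c("age_band", "sex")` — the only demographics in the modelled schema.
#' @param age_band_widths Strictly widening generalization ladder in years.
#' @param suppress_residual Drop patients in residual classes still below
#'   `k` at the widest rung (default `TRUE`); otherwise residual classes are
#'   merged into a single `"*"` band per remaining quasi-identifier value.
#' @return An `anonymity_policy` object.
#' @export
anonymity_policy <- function(k = 5L,
                             quasi_identifiers = c("age_band", "sex"),
                             age_band_widths = c(5L, 10L, 20L),
                             suppress_residual = TRUE) {
  stopifnot(k >= 2, length(age_band_widths) >= 1)
  if (any(diff(age_band_widths) <= 0)) {
    stop("age_band_widths must be strictly widening", call. = FALSE)
  }
  structure(list(k = as.integer(k), quasi_identifiers = quasi_identifiers,
                 age_band_widths = as.integer(age_band_widths),
                 suppress_residual = isTRUE(suppress_residual)),
            class = "anonymity_policy")
}

age_to_band <- function(age, width) {
  lo <- (age %/% width) * width
  sprintf("[%d,%d)", lo, lo + width)
}

# Patient-level class sizes over the quasi-identifier columns.
patient_class_sizes <- function(tab, quasi, id_col = "patient_id") {
  pat <- unique(tab, by = id_col)
  pat[, list(n_patients = .N), by = quasi]
}

#' Generalize quasi-identifiers to k-anonymity
#'
#' Applies a global band-widening ladder to age (5 -> 10 -> 20-year bands by
#' default), stopping at the first rung where every patient-level
#' (age_band, sex) equivalence class holds at least `k` distinct patients.
#' Residual classes still below `k` at the widest rung are suppressed
#' (patients dropped, reported per class) or merged into a top `"*"` band.
#'
#' @param table Deidentified table with numeric `age` and `sex` columns.
#' @param policy An [anonymity_policy()].
#' @return `list(table, report)`; the table gains `age_band` and loses raw
#'   `age`; the report records the rung used, suppressed patients per class
#'   and rows removed.
#' @export
generalize_quasi_identifiers <- function(table, policy = anonymity_policy()) {
  stopifnot(inherits(policy, "anonymity_policy"))
  tab <- data.table::copy(data.table::as.data.table(table))
  if (!"age" %in% names(tab)) stop("table must carry a numeric 'age' column", call. = FALSE)
  if (!is.numeric(tab$age)) stop("'age' must be numeric", call. = FALSE)
  quasi <- policy$quasi_identifiers
  other <- setdiff(quasi, "age_band")
  if (!all(other %in% names(tab))) {
    stop("missing quasi-identifier columns: ",
         paste(setdiff(other, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    tab[, age_band := character()]
    tab[, age := NULL]
    return(list(table = tab,
                report = list(rung_width = policy$age_band_widths[1],
                              suppressed = data.table::data.table(),
                              n_rows_suppressed = 0L, n_patients_suppressed = 0L)))
  }

  chosen <- NULL
  for (w in policy$age_band_widths) {
    tab[, age_band := age_to_band(age, w)]
    sizes <- patient_class_sizes(tab, quasi)
    chosen <- w
    if (min(sizes$n_patients) >= policy$k) break
  }

  sizes <- patient_class_sizes(tab, quasi)
  small <- sizes[n_patients < policy$k]
  suppressed <- data.table::data.table()
  n_rows_suppressed <- 0L
  n_pat_suppressed <- 0L
  if (nrow(small) > 0L) {
    if (policy$suppress_residual) {
      bad <- tab[small, on = quasi, which = TRUE]
      bad_pat <- unique(tab$patient_id[bad])
      n_pat_suppressed <- length(bad_pat)
      n_rows_suppressed <- length(bad)
      suppressed <- small
      tab <- tab[!bad]
    } else {
      bad <- tab[small, on = quasi, which = TRUE]
      tab[bad, age_band := "*"]
      sizes2 <- patient_class_sizes(tab, quasi)
      still <- sizes2[n_patients < policy$k]
      suppressed <- still  # reported, not removable at the top band
    }
  }
  tab[, age := NULL]
  list(table = tab,
       report = list(rung_width = chosen, suppressed = suppressed,
                     n_rows_suppressed = n_rows_suppressed,
                     n_patients_suppressed = n_pat_suppressed))
}

#' Verify k-anonymity of a deidentified table
#'
#' Pure read-only certification: the exact minimum, over all quasi-identifier
#' equivalence classes, of the number of distinct patients in the class.
#' Evaluated at patient level — rows per patient never inflate class sizes.
#'
#' @param table Deidentified table.
#' @param quasi_identifiers Columns defining equivalence classes.
#' @param id_col Patient identifier column.
#' @return Integer minimum class size.
#' @export
verify_k_anonymity <- function(table, quasi_identifiers = c("age_band", "sex"),
                               id_col = "patient_id") {
  tab <- data.table::as.data.table(table)
  if (nrow(tab) == 0L) stop("k-anonymity is undefined on an empty table", call. = FALSE)
  if (!all(quasi_identifiers %in% names(tab))) {
    stop("missing quasi-identifier columns", call. = FALSE)
  }
  sizes <- patient_class_sizes(tab, quasi_identifiers, id_col)
  min(sizes$n_patients)
}
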