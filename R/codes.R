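#' Diagnosis-code specifications
#'
#' A code specification selects diagnosis events either by an exact ICD-10/
#' KCD-8 code (e.g. `"I10.9"`) or by a 3-character prefix range
#' (e.g. `"E10-E14"`, which matches any code whose first three characters lie
#' in `E10..E14`, so `"E11.9"` matches and `"E15"` does not).
#'
#' @param x A single string: an exact code, or a range `"Axx-Ayy"` with a
#'   shared letter and `xx <= yy`.
#' @return An object of class `code_spec`.
#' @examples
#' code_spec("I10.9")
#' code_spec("E10-E14")
#' @export
code_spec <- function(x) {
  if (inherits(x, "code_spec")) return(x)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", x)) {
    from <- substr(x, 1L, 3L)
    to <- substr(x, 5L, 7L)
    if (substr(from, 1L, 1L) != substr(to, 1L, 1L)) {
      stop("malformed range spec '", x, "': letters differ", call. = FALSE)
    }
    lo <- as.integer(substr(from, 2L, 3L))
    hi <- as.integer(substr(to, 2L, 3L))
    if (lo > hi) stop("malformed range spec '", x, "': lower bound above upper", call. = FALSE)
    prefixes <- sprintf("%s%02d", substr(from, 1L, 1L), lo:hi)
    structure(list(type = "prefix_range", spec = x, prefixes = prefixes),
              class = "code_spec")
  } else if (grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", x)) {
    structure(list(type = "exact", spec = x, code = x), class = "code_spec")
  } else {
    stop("malformed code spec '", x, "'", call. = FALSE)
  }
}

#' @export
print.code_spec <- function(x, ...) {
  cat("<code_spec>", x$spec, sprintf("(%s)\n", x$type))
  invisible(x)
}

#' Match diagnosis codes against a specification
#'
#' @param codes Character vector of diagnosis codes.
#' @param spec A [code_spec()] or a string coercible to one.
#' @return Logical vector, `TRUE` where the code matches.
#' @examples
#' match_codes(c("E11.9", "E15", "I10.9"), "E10-E14")
#' @export
match_codes <- function(codes, spec) {
  spec <- code_spec(spec)
  if (spec$type == "exact") {
    codes == spec$code
  } else {
    substr(codes, 1L, 3L) %in% spec$prefixes
  }
}

matches_any_spec <- function(codes, specs) {
  out <- rep(FALSE, length(codes))
  for (s in specs) out <- out | match_codes(codes, s)
  out
}

#' Default disease-label specifications
#'
#' The three modelled conditions: essential hypertension (exact `I10.9`),
#' diabetes mellitus (prefix range `E10-E14`) and lumbar spinal stenosis
#' (exact `M48.06`).
#'
#' @return Named list of [code_spec()] objects.
#' @export
default_label_specs <- function() {
  list(
    hypertension = code_spec("I10.9"),
    diabetes = code_spec("E10-E14"),
    spine = code_spec("M48.06")
  )
}

# Defining codes actually emitted by the generator for each label. The
# diabetes label is a prefix range, so several concrete codes are used.
label_defining_codes <- function() {
  list(
    hypertension = "I10.9",
    diabetes = c("E10.9", "E11.9", "E11.65", "E13.9", "E14.9"),
    spine = "M48.06"
  )
}

# Comorbid / symptom codes emitted at elevated rates by label carriers.
# None of these match any defining spec, so predictive signal survives
# defining-code exclusion.
label_comorbid_codes <- function() {
  list(
    hypertension = c("E78.5", "I25.10", "I48.91", "I50.9", "N18.3",
                     "R03.0", "I67.9", "H35.0"),
    diabetes = c("E66.9", "E78.2", "H36.0", "N08.3", "G63.2",
                 "L97.4", "I73.9", "R73.9"),
    spine = c("M54.5", "M51.2", "M47.81", "G57.1", "M25.5", "R26.2", "M62.8")
  )
}

# Small bundled background pool of common outpatient ICD-10 codes with
# Zipf-like base rates; deliberately excludes every defining code.
default_code_pool <- function() {
  codes <- c(
    "J06.9", "K29.7", "M54.5", "I20.9", "J30.4", "K21.9", "E78.5", "N39.0",
    "L30.9", "H10.9", "J45.9", "K59.0", "M17.9", "G43.9", "F41.9", "J02.9",
    "H66.9", "K02.9", "M79.1", "R51.9", "J20.9", "B34.9", "L50.9", "N30.0",
    "M25.5", "H52.1", "K25.9", "J32.9", "D64.9", "E03.9", "I49.9", "G47.0",
    "K76.0", "M48.9", "N18.9", "R10.4", "J40.9", "L20.9", "H25.9", "K80.2",
    "M75.1", "F32.9", "J03.9", "B35.3", "L70.0", "N76.0", "M51.2", "R42.9",
    "J31.0", "K30.9", "H40.9", "E66.9", "I25.10", "G40.9", "K52.9", "M47.81",
    "N20.0", "R05.9", "J18.9", "L40.9", "H81.1", "E05.9", "I48.91", "G57.1",
    "K63.5", "M62.8", "N40.9", "R06.0", "J44.9", "L23.9", "H61.2", "E07.9",
    "I50.9", "G62.9", "K57.3", "M79.7", "N94.6", "R00.2", "J33.9", "L29.9"
  )
  rate <- 1 / seq_along(codes)^0.7
  data.table::data.table(code = codes, base_rate = rate / sum(rate))
}

default_departments <- function() {
  c("IM", "FM", "OS", "NS", "CA", "EN", "RE", "GS", "UR", "EM")
}
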