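#' Configuration for the synthetic EHR generator
#'
#' Defines the study conditions under which raw encounter tables are
#' simulated: cohort size, calendar span, visit intensity, the diagnosis-code
#' pool, disease-label prevalences with pairwise comorbidity structure, and
#' the data-quality defect fractions injected afterwards.
#'
#' Disease labels are drawn from a log-linear (Ising-style) model over the
#' three binary conditions, with intercepts calibrated so the marginal
#' prevalences match `label_prevalences` exactly under the configured
#' pairwise `comorbidity_log_odds`. The spinal-stenosis target defaults to a
#' 0.50% prevalence; the hypertension and diabetes anchor prevalences (10%
#' and 8.5%) are package assumptions.
#'
#' @param n_patients Number of patients (0 allowed; yields an empty table).
#' @param start_date,end_date Calendar bounds of visit dates (ISO strings).
#' @param mean_visits_per_patient Mean encounter count per patient (> 0).
#' @param departments Character vector of department codes.
#' @param code_pool `data.frame(code, base_rate)` of background diagnosis
#'   codes; rates are normalised internally.
#' @param label_prevalences Named probabilities for
#'   `hypertension`, `diabetes`, `spine`; all strictly in (0, 1).
#' @param comorbidity_log_odds Named pairwise log-odds-ratios, names of the
#'   form `"hypertension:diabetes"`.
#' @param messiness Named list of defect fractions in \[0, 1\]:
#'   `missing_sex`, `verbose_sex`, `duplicate_rows`, `nonstandard_dates`.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return A `generator_config` object.
#' @examples
#' cfg <- generator_config(n_patients = 100, seed = 1)
#' @export
generator_config <- function(n_patients,
                             start_date = "2022-01-01",
                             end_date = "2024-12-31",
                             mean_visits_per_patient = 28,
                             departments = default_departments(),
                             code_pool = default_code_pool(),
                             label_prevalences = c(hypertension = 0.10,
                                                   diabetes = 0.085,
                                                   spine = 0.005),
                             comorbidity_log_odds = c("hypertension:diabetes" = 1.5,
                                                      "hypertension:spine" = 0.5,
                                                      "diabetes:spine" = 0.5),
                             messiness = list(missing_sex = 0.02,
                                              verbose_sex = 0.10,
                                              duplicate_rows = 0.01,
                                              nonstandard_dates = 0.25),
                             seed = 42L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 0, n_patients == floor(n_patients))
  start <- as.Date(start_date)
  end <- as.Date(end_date)
  if (is.na(start) || is.na(end)) stop("start_date/end_date must be valid dates", call. = FALSE)
  if (end < start) stop("end_date must be >= start_date", call. = FALSE)
  if (mean_visits_per_patient <= 0) stop("mean_visits_per_patient must be positive", call. = FALSE)
  lbl <- c("hypertension", "diabetes", "spine")
  if (!all(lbl %in% names(label_prevalences))) {
    stop("label_prevalences must name hypertension, diabetes and spine", call. = FALSE)
  }
  p <- label_prevalences[lbl]
  if (any(p <= 0 | p >= 1)) stop("label prevalences must lie strictly in (0, 1)", call. = FALSE)
  mfrac <- unlist(messiness)
  if (any(mfrac < 0 | mfrac > 1)) stop("messiness fractions must lie in [0, 1]", call. = FALSE)
  code_pool <- data.table::as.data.table(code_pool)
  stopifnot(all(c("code", "base_rate") %in% names(code_pool)), nrow(code_pool) > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    start_date = start, end_date = end,
    mean_visits_per_patient = mean_visits_per_patient,
    departments = departments,
    code_pool = code_pool,
    label_prevalences = p,
    comorbidity_log_odds = comorbidity_log_odds,
    messiness = as.list(mfrac),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_patients, "patients,",
      format(x$start_date), "to", format(x$end_date),
      sprintf("| prevalences: %s\n",
              paste(sprintf("%s=%.3f", names(x$label_prevalences),
                            x$label_prevalences), collapse = " ")))
  invisible(x)
}

# Pairwise interaction matrix from the named log-odds vector.
comorbidity_matrix <- function(log_odds) {
  lbl <- c("hypertension", "diabetes", "spine")
  B <- matrix(0, 3, 3, dimnames = list(lbl, lbl))
  for (nm in names(log_odds)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% lbl)) {
      stop("comorbidity_log_odds names must be 'label:label' pairs", call. = FALSE)
    }
    B[pair[1], pair[2]] <- log_odds[[nm]]
    B[pair[2], pair[1]] <- log_odds[[nm]]
  }
  B
}

# Calibrate log-linear intercepts so state marginals hit the target
# prevalences under pairwise interactions B. States are the 8 corners of
# {0,1}^3; probabilities are exact by enumeration.
calibrate_label_model <- function(prevalences, B) {
  S <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(S) <- names(prevalences)
  pairterm <- vapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    sum(B[upper.tri(B)] * (outer(s, s)[upper.tri(B)]))
  }, numeric(1))
  state_probs <- function(alpha) {
    u <- exp(drop(S %*% alpha) + pairterm)
    u / sum(u)
  }
  target <- as.numeric(prevalences)
  obj <- function(alpha) {
    pr <- state_probs(alpha)
    marg <- drop(crossprod(S, pr))
    sum((log(marg) - log(target))^2)
  }
  fit <- optim(qlogis(target), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  pr <- state_probs(fit$par)
  marg <- drop(crossprod(S, pr))
  if (max(abs(marg - target)) > 1e-6) {
    stop("label model calibration failed to match marginal prevalences", call. = FALSE)
  }
  list(states = S, probs = pr, alpha = fit$par)
}

raw_encounter_cols <- function() {
  c("patient_id", "age", "sex", "visit_date", "department", "dx_code",
    "is_primary", "visit_type", "rx_code", "provider_id", "note_len")
}

empty_raw_table <- function() {
  data.table::data.table(
    patient_id = character(), age = integer(), sex = character(),
    visit_date = character(), department = character(), dx_code = character(),
    is_primary = logical(), visit_type = character(), rx_code = character(),
    provider_id = character(), note_len = integer()
  )
}

#' Generate a synthetic raw encounter cohort
#'
#' Simulates a raw EHR encounter table: per-patient demographics, correlated
#' disease-label membership from the calibrated log-linear model, Poisson
#' visit counts, within-patient date-ordered visits across departments, and
#' diagnosis codes. Every label carrier emits at least one defining code for
#' that label plus comorbid codes at elevated rates; non-carriers never emit
#' defining codes, so patient-level empirical prevalence equals the sampled
#' label prevalence. Data-quality defects are injected afterwards via
#' [inject_messiness()] unless `messy = FALSE`.
#'
#' @param config A [generator_config()].
#' @param messy Inject the configured defect fractions (default `TRUE`).
#' @return A `data.table` with one row per diagnosis event (columns
#'   `patient_id`, `age`, `sex`, `visit_date`, `department`, `dx_code`,
#'   `is_primary`, `visit_type` plus filler columns). The clean table carries
#'   a `label_truth` attribute with the per-patient label matrix.
#' @examples
#' tab <- generate_cohort(generator_config(n_patients = 200, seed = 7))
#' @export
generate_cohort <- function(config, messy = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  if (n == 0L) return(empty_raw_table())

  clean <- with_seed(config$seed, {
    lbl <- names(config$label_prevalences)
    model <- calibrate_label_model(config$label_prevalences,
                                   comorbidity_matrix(config$comorbidity_log_odds))
    state <- sample.int(nrow(model$states), n, replace = TRUE, prob = model$probs)
    Y <- model$states[state, , drop = FALSE]
    rownames(Y) <- sprintf("PT%07d", seq_len(n))

    age <- sample(18:90, n, replace = TRUE, prob = dnorm(18:90, 58, 18))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    home <- sample(config$departments, n, replace = TRUE)

    n_labels <- rowSums(Y)
    nv <- pmax(1L, n_labels) + rpois(n, max(config$mean_visits_per_patient - 1, 0.1))
    pid <- rep(seq_len(n), nv)
    N <- length(pid)

    span <- as.integer(config$end_date - config$start_date)
    day <- sample(0:span, N, replace = TRUE)
    dt <- data.table::data.table(pid = pid, day = day)
    data.table::setorder(dt, pid, day)

    stay <- runif(N) < 0.7
    dept <- ifelse(stay, home[dt$pid],
                   config$departments[sample.int(length(config$departments), N, replace = TRUE)])

    pool <- config$code_pool
    dx <- sample(pool$code, N, replace = TRUE, prob = pool$base_rate / sum(pool$base_rate))

    defining <- label_defining_codes()
    comorbid <- label_comorbid_codes()
    specs <- default_label_specs()
    forced <- rep(FALSE, N)
    row_of_patient <- split(seq_len(N), dt$pid)
    for (j in seq_along(lbl)) {
      carriers <- which(Y[, j] == 1L)
      if (!length(carriers)) next
      crows <- which(Y[dt$pid, j] == 1L)
      # elevated comorbid emission, then stochastic defining emission
      hit <- crows[runif(length(crows)) < 0.30]
      if (length(hit)) dx[hit] <- sample(comorbid[[lbl[j]]], length(hit), replace = TRUE)
      hit <- crows[runif(length(crows)) < 0.20 & !forced[crows]]
      if (length(hit)) {
        dx[hit] <- sample(rep(defining[[lbl[j]]], 2L), length(hit), replace = TRUE)
        forced[hit] <- TRUE
      }
      # guarantee >= 1 defining event per carrier
      for (pc in carriers) {
        rows <- row_of_patient[[pc]]
        if (!any(match_codes(dx[rows], specs[[lbl[j]]]))) {
          free <- rows[!forced[rows]]
          pick <- if (length(free)) free[sample.int(length(free), 1L)] else rows[sample.int(length(rows), 1L)]
          dx[pick] <- sample(rep(defining[[lbl[j]]], 2L), 1L)
          forced[pick] <- TRUE
        }
      }
    }

    out <- data.table::data.table(
      patient_id = rownames(Y)[dt$pid],
      age = age[dt$pid],
      sex = sex[dt$pid],
      visit_date = format(config$start_date + dt$day, "%Y-%m-%d"),
      department = dept,
      dx_code = dx,
      is_primary = ifelse(forced, runif(N) < 0.6, runif(N) < 0.3),
      visit_type = sample(c("outpatient", "inpatient", "emergency"), N,
                          replace = TRUE, prob = c(0.80, 0.15, 0.05)),
      rx_code = sample(c("", sprintf("RX%03d", 1:40)), N, replace = TRUE),
      provider_id = sprintf("DR%03d", sample.int(120, N, replace = TRUE)),
      note_len = as.integer(rpois(N, 45))
    )
    data.table::setattr(out, "label_truth", Y)
    out
  })

  if (messy) inject_messiness(clean, config) else clean
}

#' Inject data-quality defects into a clean encounter table
#'
#' Applies the four defect classes the downstream cleaning pipeline is built
#' to remove, at the fractions in `config$messiness`: appended duplicate rows
#' (half exact copies, half with an altered `visit_type` so the dedup key
#' still collides), blanked sex fields, verbose sex strings (`"men"`,
#' `"women"`), and non-ISO date dialects (`YYYYMMDD`, `DD/MM/YYYY`,
#' `YYYY.MM.DD`). Injection is seeded (from `config$seed`) and each defect
#' class is logged with the affected row indices in the `defect_log`
#' attribute. Rows outside the seeded defect sets are untouched.
#'
#' @param table A clean raw encounter `data.table`.
#' @param config The [generator_config()] carrying `messiness` and `seed`.
#' @return The defected table (row count grows only by the duplicate
#'   fraction: `floor(f * nrow)` appended rows).
#' @export
inject_messiness <- function(table, config) {
  stopifnot(inherits(config, "generator_config"))
  m <- config$messiness
  if (any(unlist(m) > 1)) stop("messiness fractions must be <= 1", call. = FALSE)
  tab <- data.table::copy(data.table::as.data.table(table))
  if (nrow(tab) == 0L || all(unlist(m) == 0)) {
    data.table::setattr(tab, "defect_log",
                        data.table::data.table(class = character(), n_rows = integer()))
    return(tab)
  }
  with_seed(config$seed + 1L, {
    log <- list()

    n_dup <- floor(m$duplicate_rows * nrow(tab))
    if (n_dup > 0) {
      idx <- sample.int(nrow(tab), n_dup)
      dups <- tab[idx]
      partial <- seq_len(n_dup) <= n_dup %/% 2
      if (any(partial)) {
        dups[partial, visit_type := ifelse(visit_type == "outpatient",
                                           "inpatient", "outpatient")]
      }
      tab <- rbind(tab, dups)
    }
    log$duplicate_rows <- n_dup

    n_miss <- floor(m$missing_sex * nrow(tab))
    miss_idx <- if (n_miss > 0) sample.int(nrow(tab), n_miss) else integer()
    if (n_miss > 0) tab[miss_idx, sex := ""]
    log$missing_sex <- n_miss

    eligible <- setdiff(which(tab$sex %in% c("M", "F")), miss_idx)
    n_verb <- floor(m$verbose_sex * nrow(tab))
    verb_idx <- if (n_verb > 0) sample(eligible, min(n_verb, length(eligible))) else integer()
    if (length(verb_idx)) {
      tab[verb_idx, sex := ifelse(sex == "M", "men", "women")]
    }
    log$verbose_sex <- length(verb_idx)

    n_date <- floor(m$nonstandard_dates * nrow(tab))
    date_idx <- if (n_date > 0) sample.int(nrow(tab), n_date) else integer()
    if (length(date_idx)) {
      d <- as.Date(tab$visit_date[date_idx])
      dialect <- sample.int(3L, length(date_idx), replace = TRUE)
      reform <- character(length(date_idx))
      reform[dialect == 1L] <- format(d[dialect == 1L], "%Y%m%d")
      reform[dialect == 2L] <- format(d[dialect == 2L], "%d/%m/%Y")
      reform[dialect == 3L] <- format(d[dialect == 3L], "%Y.%m.%d")
      tab[date_idx, visit_date := reform]
    }
    log$nonstandard_dates <- length(date_idx)

    data.table::setattr(tab, "defect_log", data.table::data.table(
      class = names(log), n_rows = as.integer(unlist(log))
    ))
    data.table::setattr(tab, "defect_rows", list(
      duplicate_rows = if (n_dup > 0) idx else integer(),
      missing_sex = miss_idx, verbose_sex = verb_idx, nonstandard_dates = date_idx
    ))
    tab
  })
}

#' Patient-level empirical prevalence of a condition
#'
#' Fraction of distinct patients with at least one event matching the
#' label definition (exact code or prefix range).
#'
#' @param table An encounter table with `patient_id` and `dx_code`.
#' @param label_definition A [code_spec()] or string (e.g. `"M48.06"`).
#' @return Proportion in \[0, 1\].
#' @export
empirical_prevalence <- function(table, label_definition) {
  tab <- data.table::as.data.table(table)
  if (nrow(tab) == 0L) {
    stop("empirical_prevalence is undefined on an empty table", call. = FALSE)
  }
  spec <- code_spec(label_definition)
  carriers <- unique(tab$patient_id[match_codes(tab$dx_code, spec)])
  length(carriers) / data.table::uniqueN(tab$patient_id)
}
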