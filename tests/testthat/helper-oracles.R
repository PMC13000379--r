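# Independent brute-force oracles. Each is written as the most literal
# possible restatement of the operation's definition (explicit loops,
# pairwise comparisons, full enumerations) so it shares no code path with
# the implementation it checks.

# keep-last row per (patient, date, code), preserving positional order of
# the retained rows
brute_dedup <- function(df) {
  key <- paste(df$patient_id, df$visit_date, df$dx_code, sep = "\r")
  keep <- logical(nrow(df))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx[length(idx)]] <- TRUE
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^2) pairwise-date rolling window per patient
brute_rolling <- function(df, window_days = 90L) {
  d <- as.integer(as.Date(df$visit_date))
  cnt <- integer(nrow(df))
  div <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    in_win <- df$patient_id == df$patient_id[i] &
      d >= d[i] - (window_days - 1L) & d <= d[i]
    cnt[i] <- sum(in_win)
    div[i] <- length(unique(df$dx_code[in_win]))
  }
  data.frame(patient_id = df$patient_id, visit_date = df$visit_date,
             cnt = cnt, div = div)
}

# event-by-event episode walk per patient
brute_episodes <- function(df, gap_days = 30L) {
  out <- list()
  for (p in unique(df$patient_id)) {
    sub <- df[df$patient_id == p, , drop = FALSE]
    sub <- sub[order(as.Date(sub$visit_date)), , drop = FALSE]
    ep <- 1L
    ep_id <- integer(nrow(sub))
    ep_id[1] <- ep
    for (i in seq_len(nrow(sub))[-1]) {
      gap <- as.integer(as.Date(sub$visit_date[i]) - as.Date(sub$visit_date[i - 1]))
      if (gap > gap_days || sub$department[i] != sub$department[i - 1]) ep <- ep + 1L
      ep_id[i] <- ep
    }
    for (e in unique(ep_id)) {
      s <- sub[ep_id == e, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, department = s$department[1],
        start_date = min(s$visit_date), end_date = max(s$visit_date),
        duration_days = as.integer(as.Date(max(s$visit_date)) - as.Date(min(s$visit_date))),
        event_count = nrow(s), has_primary_dx = any(s$is_primary))
    }
  }
  do.call(rbind, out)
}

# concordant-pair fraction with half credit for ties
brute_auroc <- function(y, p) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# threshold-by-threshold precision/recall staircase
brute_auprc <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in ths) {
    pred <- p >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    recall <- tp / sum(y == 1)
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# cell/row loops for the multilabel metrics
brute_multilabel <- function(Y, P, threshold = 0.5) {
  pred <- (P >= threshold) * 1L
  wrong <- 0
  all_right <- 0
  jac <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    row_ok <- TRUE
    for (j in seq_len(ncol(Y))) {
      if (pred[i, j] != Y[i, j]) {
        wrong <- wrong + 1
        row_ok <- FALSE
      }
    }
    if (row_ok) all_right <- all_right + 1
    inter <- sum(pred[i, ] == 1 & Y[i, ] == 1)
    uni <- sum(pred[i, ] == 1 | Y[i, ] == 1)
    jac[i] <- if (uni == 0) 1 else inter / uni
  }
  list(hamming_loss = wrong / (nrow(Y) * ncol(Y)),
       subset_accuracy = all_right / nrow(Y),
       jaccard = mean(jac))
}

# full threshold enumeration for attack advantage / best accuracy
brute_attack <- function(scores, is_member) {
  ths <- c(sort(unique(scores)), Inf)
  adv <- -Inf
  best_acc <- -Inf
  for (t in ths) {
    pred <- scores >= t
    tpr <- sum(pred & is_member) / sum(is_member)
    fpr <- sum(pred & !is_member) / sum(!is_member)
    acc <- mean(pred == is_member)
    adv <- max(adv, tpr - fpr)
    best_acc <- max(best_acc, acc)
  }
  list(auc = brute_auroc(as.integer(is_member), scores),
       advantage = adv, best_accuracy = best_acc)
}

# small random event table for property tests
random_event_table <- function(n_rows, n_patients = 8L, n_codes = 6L,
                               n_days = 120L, n_depts = 3L) {
  data.frame(
    patient_id = sprintf("P%02d", sample.int(n_patients, n_rows, replace = TRUE)),
    visit_date = format(as.Date("2023-01-01") + sample.int(n_days, n_rows, replace = TRUE),
                        "%Y-%m-%d"),
    department = sprintf("D%d", sample.int(n_depts, n_rows, replace = TRUE)),
    dx_code = sprintf("C%02d.%d", sample.int(n_codes, n_rows, replace = TRUE),
                      sample.int(3, n_rows, replace = TRUE) - 1L),
    is_primary = runif(n_rows) < 0.3,
    sex = sample(c("M", "F"), n_rows, replace = TRUE),
    age = sample(20:80, n_rows, replace = TRUE),
    visit_type = sample(c("outpatient", "inpatient"), n_rows, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# drop auxiliary attributes (defect logs, label truth) before frame comparison
plain_frame <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  rownames(x) <- NULL
  x
}

small_generator <- function(n = 300L, seed = 1L, ...) {
  generator_config(n_patients = n, mean_visits_per_patient = 8, seed = seed, ...)
}
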