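EPS_PROB <- 1e-6

clamp_prob <- function(p) pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)

#' Per-record membership scores
#'
#' Scalar scores oriented so that larger means "more likely a training
#' member". With per-label predicted probabilities `p` and true labels `y`:
#' `confidence` is the mean of `max(p, 1 - p)`; `entropy` is the negated
#' mean binary entropy of `p`; `loss` (the Yeom attack) is the negated mean
#' per-label log loss against `y`.
#'
#' @param model A fitted `ovr_model` or `cc_ensemble`.
#' @param X Feature matrix for the audited records.
#' @param Y True label matrix (needed for the loss strategy).
#' @param strategy One of `"confidence"`, `"entropy"`, `"loss"`.
#' @return Numeric score vector, one per record.
#' @export
membership_scores <- function(model, X, Y = NULL,
                              strategy = c("confidence", "entropy", "loss")) {
  strategy <- match.arg(strategy)
  P <- predict_proba(model, X)
  if (any(P < 0 | P > 1)) stop("probabilities outside [0, 1]", call. = FALSE)
  P <- clamp_prob(P)
  switch(strategy,
    confidence = rowMeans(pmax(P, 1 - P)),
    entropy = rowMeans(P * log(P) + (1 - P) * log1p(-P)),
    loss = {
      if (is.null(Y)) stop("the loss strategy requires true labels", call. = FALSE)
      Y <- as.matrix(Y)
      stopifnot(all(dim(Y) == dim(P)))
      rowMeans(Y * log(P) + (1 - Y) * log1p(-P))
    }
  )
}

#' Attack metrics from membership scores
#'
#' AUC by the midrank statistic; advantage (max over thresholds of
#' TPR - FPR) and best accuracy by an exhaustive sweep over the observed
#' score values (predicting "member" when score >= threshold); gain as best
#' accuracy minus the baseline `max(majority prior, 0.5)`. The threshold
#' sweep is an upper bound — no separate calibration set is held out — and
#' is reported as such. The AUC CI comes from a seeded bootstrap over
#' records.
#'
#' @param scores Membership scores (larger = more member-like).
#' @param is_member Logical membership truth.
#' @param strategy Label recorded in the output row.
#' @param boot_reps Bootstrap replicates for the AUC CI (default 1000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return One-row `data.table(strategy, auc, ci_lower, ci_upper,
#'   advantage, best_accuracy, gain)`.
#' @export
attack_metrics <- function(scores, is_member, strategy = "attack",
                           boot_reps = 1000L, seed = 42L, conf = 0.95) {
  stopifnot(length(scores) == length(is_member))
  is_member <- as.logical(is_member)
  if (!any(is_member) || all(is_member)) {
    stop("need both member and non-member records", call. = FALSE)
  }
  y <- as.integer(is_member)
  auc <- auroc(y, scores)

  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  boundary <- c(ss[-length(ss)] != ss[-1], TRUE)
  tp <- cumsum(ys)[boundary]
  fp <- cumsum(1 - ys)[boundary]
  n1 <- sum(y)
  n0 <- sum(1 - y)
  tpr <- c(0, tp / n1)   # leading 0: threshold above every score
  fpr <- c(0, fp / n0)
  acc <- c(n0, tp + (n0 - fp)) / length(y)
  advantage <- max(tpr - fpr)
  best_accuracy <- max(acc)
  gain <- best_accuracy - max(n1, n0) / length(y)

  boots <- with_seed(seed, {
    n <- length(y)
    vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(y[idx]) %in% c(0L, n)) return(NA_real_)
      auroc(y[idx], scores[idx])
    }, numeric(1))
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE)
  data.table::data.table(strategy = strategy, auc = auc,
                         ci_lower = qs[1], ci_upper = qs[2],
                         advantage = advantage, best_accuracy = best_accuracy,
                         gain = gain)
}

# Build one audited pipeline target: generate a cohort, preprocess, split
# patients 50/50 into members / non-members at patient level, train the
# configured model on the members.
audit_target <- function(config, seed, id_prefix = "") {
  gen <- config$generator
  gen$seed <- as.integer(seed)
  raw <- generate_cohort(gen)
  if (nzchar(id_prefix)) {
    raw <- data.table::copy(raw)[, patient_id := paste0(id_prefix, patient_id)]
  }
  prep <- prepare_model_inputs(raw, config)
  ids <- rownames(prep$X)
  member <- with_seed(seed + 1L, {
    m <- rep(FALSE, length(ids))
    m[sample.int(length(ids), floor(length(ids) / 2))] <- TRUE
    m
  })
  model <- fit_pipeline_model(prep$X[member, , drop = FALSE],
                              prep$Y[member, , drop = FALSE], config)
  list(model = model, X = prep$X, Y = prep$Y, ids = ids, is_member = member)
}

#' Shadow membership-inference attack
#'
#' Trains `n_shadow` pipeline models on disjoint synthetic cohorts, scores
#' each shadow cohort's records under its own shadow model with known
#' membership, fits a logistic attack classifier on the
#' (confidence, entropy, loss) score vectors, and evaluates it on the
#' target model's records. Shadow cohorts overlapping the target's training
#' patients are refused.
#'
#' @param config A [pipeline_config()]; the generator defines the cohorts.
#' @param n_shadow Number of shadow models (>= 2; default 8).
#' @param seed Base seed; target and shadow cohorts derive disjoint seeds
#'   and id namespaces from it.
#' @param target Optional pre-built target (from the internal builder) so a
#'   full audit can share one target across strategies.
#' @return One-row attack-metric `data.table` (strategy `"shadow"`).
#' @export
shadow_attack <- function(config, n_shadow = 8L, seed = 42L, target = NULL) {
  if (n_shadow < 2L) stop("n_shadow must be >= 2", call. = FALSE)
  if (is.null(target)) target <- audit_target(config, seed)
  target_train_ids <- target$ids[target$is_member]

  score_vec <- function(model, X, Y) {
    cbind(confidence = membership_scores(model, X, Y, "confidence"),
          entropy = membership_scores(model, X, Y, "entropy"),
          loss = membership_scores(model, X, Y, "loss"))
  }

  pooled <- list()
  for (s in seq_len(n_shadow)) {
    sh <- audit_target(config, seed + 1000L * s, id_prefix = sprintf("SH%d.", s))
    if (length(intersect(sh$ids[sh$is_member], target_train_ids))) {
      stop("shadow cohort overlaps target training patients", call. = FALSE)
    }
    sv <- score_vec(sh$model, sh$X, sh$Y)
    pooled[[s]] <- data.frame(sv, member = as.integer(sh$is_member))
  }
  train <- do.call(rbind, pooled)
  att <- glm(member ~ confidence + entropy + loss, data = train,
             family = binomial())
  tv <- as.data.frame(score_vec(target$model, target$X, target$Y))
  p <- predict(att, newdata = tv, type = "response")
  attack_metrics(p, target$is_member, strategy = "shadow", seed = seed)
}

# Logit-transformed probability assigned to a record's true labels,
# averaged over labels and clamped away from 0/1.
lira_phi <- function(model, X, Y) {
  P <- clamp_prob(predict_proba(model, X))
  Y <- as.matrix(Y)
  p_true <- clamp_prob(rowMeans(Y * P + (1 - Y) * (1 - P)))
  qlogis(p_true)
}

#' Likelihood Ratio Attack (LiRA)
#'
#' Per record, fits Gaussians to the logit-confidence of the record under
#' shadow models that did ("in") and did not ("out") train on it, and
#' scores the target model's logit-confidence by the log likelihood ratio
#' in/out. When a record has fewer than 2 observations on either side, the
#' global standard deviation over all shadow observations substitutes for
#' the per-record one (flagged in the result attributes). The offline
#' variant uses only the out population (a standardized z score).
#'
#' @param target_model Fitted target model.
#' @param shadow_models List of fitted shadow models (>= 2).
#' @param shadow_membership Logical matrix, records x shadow models: was
#'   the record in that shadow model's training set.
#' @param X,Y Features and true labels of the audited records.
#' @param is_member Logical membership truth under the target model.
#' @param offline Use the out-only variant (default `FALSE`).
#' @param seed Bootstrap seed for the AUC CI.
#' @return One-row attack-metric `data.table` (strategy `"lira"` or
#'   `"lira_offline"`), with a `n_variance_fallback` attribute.
#' @export
lira_attack <- function(target_model, shadow_models, shadow_membership,
                        X, Y, is_member, offline = FALSE, seed = 42L) {
  if (length(shadow_models) < 2L) stop("need >= 2 shadow models", call. = FALSE)
  M <- as.matrix(shadow_membership)
  stopifnot(nrow(M) == nrow(X), ncol(M) == length(shadow_models))
  phi_t <- lira_phi(target_model, X, Y)
  phi_s <- vapply(shadow_models, function(m) lira_phi(m, X, Y),
                  numeric(nrow(X)))
  global_sd <- sd(as.vector(phi_s))
  if (!is.finite(global_sd) || global_sd == 0) global_sd <- 1
  global_mean <- mean(phi_s)

  n_fallback <- 0L
  score <- vapply(seq_len(nrow(X)), function(i) {
    ins <- phi_s[i, M[i, ]]
    outs <- phi_s[i, !M[i, ]]
    stat <- function(v) {
      if (length(v) < 2L || sd(v) == 0) {
        n_fallback <<- n_fallback + 1L
        c(if (length(v)) mean(v) else global_mean, global_sd)
      } else {
        c(mean(v), sd(v))
      }
    }
    o <- stat(outs)
    if (offline) {
      (phi_t[i] - o[1]) / o[2]
    } else {
      g <- stat(ins)
      dnorm(phi_t[i], g[1], g[2], log = TRUE) - dnorm(phi_t[i], o[1], o[2], log = TRUE)
    }
  }, numeric(1))
  res <- attack_metrics(score, is_member,
                        strategy = if (offline) "lira_offline" else "lira",
                        seed = seed)
  data.table::setattr(res, "n_variance_fallback", n_fallback)
  data.table::setattr(res, "scores", score)
  res
}

#' Full privacy audit of a pipeline-trained model
#'
#' Runs the requested membership-inference strategies against a single
#' target model trained end-to-end from the configured synthetic cohort
#' (generation, date standardization, cleansing, deduplication, feature
#' hashing with defining-code exclusion, patient-level 50/50
#' member/non-member split). Membership truth is assigned at patient level:
#' a patient's records never straddle the member and non-member pools.
#'
#' @param config A [pipeline_config()].
#' @param strategies Subset of `c("confidence", "entropy", "loss",
#'   "shadow", "lira")`; an empty vector yields an empty, schema-complete
#'   report.
#' @param seed Master seed for the audit.
#' @param n_shadow Shadow-model count for the shadow and LiRA strategies.
#' @return `data.table` with one row per strategy: `strategy`, `auc`,
#'   `ci_lower`, `ci_upper`, `advantage`, `best_accuracy`, `gain`.
#' @export
full_audit <- function(config = pipeline_config(),
                       strategies = c("confidence", "entropy", "loss"),
                       seed = 42L, n_shadow = 8L) {
  known <- c("confidence", "entropy", "loss", "shadow", "lira")
  if (length(setdiff(strategies, known))) {
    stop("unknown strategy: ", paste(setdiff(strategies, known), collapse = ", "),
         call. = FALSE)
  }
  empty <- data.table::data.table(strategy = character(), auc = numeric(),
                                  ci_lower = numeric(), ci_upper = numeric(),
                                  advantage = numeric(), best_accuracy = numeric(),
                                  gain = numeric())
  if (length(strategies) == 0L) return(empty)

  target <- audit_target(config, seed)
  rows <- list()
  for (s in intersect(strategies, c("confidence", "entropy", "loss"))) {
    sc <- membership_scores(target$model, target$X, target$Y, s)
    rows[[s]] <- attack_metrics(sc, target$is_member, strategy = s, seed = seed)
  }
  if ("shadow" %in% strategies) {
    rows$shadow <- shadow_attack(config, n_shadow = n_shadow, seed = seed,
                                 target = target)
  }
  if ("lira" %in% strategies) {
    # LiRA shadows: models trained on random patient-level halves of the
    # audited record set, so per-record in/out populations are known.
    n <- nrow(target$X)
    M <- matrix(FALSE, n, n_shadow)
    shadows <- vector("list", n_shadow)
    for (j in seq_len(n_shadow)) {
      half <- with_seed(seed + 2000L + j, sample.int(n, floor(n / 2)))
      M[half, j] <- TRUE
      shadows[[j]] <- fit_pipeline_model(target$X[half, , drop = FALSE],
                                         target$Y[half, , drop = FALSE], config)
    }
    rows$lira <- lira_attack(target$model, shadows, M, target$X, target$Y,
                             target$is_member, seed = seed)
  }
  out <- data.table::rbindlist(rows[intersect(strategies, names(rows))])
  out[]
}
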