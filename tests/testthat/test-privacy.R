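# a stub model that returns a fixed probability matrix lets the score
# formulas be checked by hand, independent of any learner
stub_model <- function(P) structure(list(P = P), class = "stub_model")
registerS3method("predict_proba", "stub_model",
                 function(object, X, ...) object$P[seq_len(nrow(X)), , drop = FALSE],
                 envir = asNamespace("clinpipe"))

test_that("membership score formulas match hand computation and orientation", {
  X <- matrix(0, 3, 2)  # placeholder features; the stub ignores them
  P <- rbind(c(0.999999, 0.000001), c(0.5, 0.5), c(0.9, 0.2))
  Y <- rbind(c(1, 0), c(1, 0), c(1, 0))
  m <- stub_model(P)

  conf <- membership_scores(m, X, strategy = "confidence")
  expect_equal(conf, rowMeans(pmax(P, 1 - P)), tolerance = 1e-6)
  expect_gt(conf[1], conf[3])          # confident record scores higher
  expect_equal(conf[2], 0.5)           # all-0.5 probabilities floor the score

  ent <- membership_scores(m, X, strategy = "entropy")
  expect_equal(which.min(ent), 2L)     # maximal entropy -> minimal score
  expect_equal(which.max(ent), 1L)

  loss <- membership_scores(m, X, Y, strategy = "loss")
  hand <- sapply(1:3, function(i) {
    mean(log(ifelse(Y[i, ] == 1, pmin(pmax(P[i, ], 1e-6), 1 - 1e-6),
                    1 - pmin(pmax(P[i, ], 1e-6), 1 - 1e-6))))
  })
  expect_equal(loss, hand, tolerance = 1e-9)
  expect_equal(which.max(loss), 1L)    # correct + confident -> maximal
  expect_error(membership_scores(m, X, strategy = "loss"), "true labels")
})

test_that("attack metrics sit at chance for exchangeable scores and at 1 when separated", {
  set.seed(20)
  scores <- rnorm(10000)
  member <- rep(c(TRUE, FALSE), 5000)
  res <- attack_metrics(scores, member, boot_reps = 50)
  expect_lt(abs(res$auc - 0.5), 0.02)
  expect_lt(res$advantage, 0.05)
  expect_gte(res$gain, 0)

  sep <- attack_metrics(c(rnorm(50, 10), rnorm(50, -10)),
                        rep(c(TRUE, FALSE), each = 50), boot_reps = 50)
  expect_equal(sep$auc, 1)
  expect_equal(sep$advantage, 1)
  expect_equal(sep$best_accuracy, 1)
  expect_equal(sep$gain, 0.5)
  expect_error(attack_metrics(scores, rep(TRUE, 10000)), "both member")
})

test_that("attack metrics equal brute-force threshold enumeration on toy sets", {
  for (s in 1:10) {
    set.seed(s)
    scores <- round(rnorm(30), 1)  # ties on purpose
    member <- rbinom(30, 1, 0.5) == 1
    if (all(member) || !any(member)) member[1:2] <- c(TRUE, FALSE)
    got <- attack_metrics(scores, member, boot_reps = 10)
    want <- brute_attack(scores, member)
    expect_equal(got$auc, want$auc)
    expect_equal(got$advantage, want$advantage)
    expect_equal(got$best_accuracy, want$best_accuracy)
    expect_equal(got$gain, want$best_accuracy - max(mean(member), 1 - mean(member)))
  }
})

test_that("LiRA scores follow the Gaussian likelihood-ratio by hand", {
  # 5 records, 4 shadow models with constructed logit-confidences; every
  # record has exactly 2 "in" and 2 "out" shadow observations
  X <- matrix(0, 5, 2)
  Y <- matrix(1L, 5, 2)
  mk <- function(p_true) stub_model(matrix(p_true, 5, 2))
  M <- cbind(c(TRUE, TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE, FALSE, FALSE),
             c(FALSE, FALSE, FALSE, TRUE, TRUE), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  shadows <- list(mk(c(0.9, 0.8, 0.9, 0.6, 0.5)), mk(c(0.8, 0.9, 0.8, 0.5, 0.6)),
                  mk(c(0.6, 0.5, 0.7, 0.9, 0.8)), mk(c(0.5, 0.6, 0.6, 0.8, 0.9)))
  target <- mk(c(0.9, 0.6, 0.9, 0.7, 0.6))
  is_member <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

  res <- lira_attack(target, shadows, M, X, Y, is_member)
  expect_equal(attr(res, "n_variance_fallback"), 0L)

  # hand recomputation: per-label-mean true-class probability is the
  # per-label probability here (all labels identical), logit-transformed
  phis <- sapply(shadows, function(s) qlogis(s$P[, 1]))
  phit <- qlogis(target$P[, 1])
  hand <- sapply(1:5, function(i) {
    ins <- phis[i, M[i, ]]
    outs <- phis[i, !M[i, ]]
    dnorm(phit[i], mean(ins), sd(ins), log = TRUE) -
      dnorm(phit[i], mean(outs), sd(outs), log = TRUE)
  })
  expect_equal(attr(res, "scores"), hand, tolerance = 1e-12)

  # orientation: in-mean far above out-mean gives a positive score
  expect_gt(attr(res, "scores")[1], 0)

  # identical in/out populations give a zero log-ratio for every record
  sym <- list(mk(rep(0.7, 5)), mk(rep(0.8, 5)), mk(rep(0.7, 5)), mk(rep(0.8, 5)))
  r0 <- lira_attack(mk(rep(0.75, 5)), sym, M, X, Y, is_member)
  expect_equal(attr(r0, "scores"), rep(0, 5), tolerance = 1e-12)
})

test_that("the full audit emits a schema-complete, strategy-per-row report", {
  expect_equal(nrow(full_audit(strategies = character())), 0L)
  expect_named(full_audit(strategies = character()),
               c("strategy", "auc", "ci_lower", "ci_upper", "advantage",
                 "best_accuracy", "gain"))
  expect_error(full_audit(strategies = "gradient"), "unknown strategy")

  gen <- generator_config(n_patients = 250, mean_visits_per_patient = 8,
    label_prevalences = c(hypertension = 0.3, diabetes = 0.25, spine = 0.1),
    seed = 5)
  cfg <- pipeline_config(generator = gen, strategy = "ovr",
                         model = model_config(nrounds = 20))
  res <- full_audit(cfg, c("confidence", "loss"), seed = 3)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$strategy, c("confidence", "loss"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
})

test_that("shadow attacks refuse contaminated cohorts and run end-to-end", {
  gen <- generator_config(n_patients = 200, mean_visits_per_patient = 8,
    label_prevalences = c(hypertension = 0.3, diabetes = 0.25, spine = 0.1),
    seed = 6)
  cfg <- pipeline_config(generator = gen, strategy = "ovr",
                         model = model_config(nrounds = 15))
  res <- shadow_attack(cfg, n_shadow = 2, seed = 8)
  expect_equal(res$strategy, "shadow")
  expect_true(is.finite(res$auc))
  expect_gte(res$gain, 0)
  expect_error(shadow_attack(cfg, n_shadow = 1), ">= 2")
})
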