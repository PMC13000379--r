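test_that("the pinned hash matches published FNV-1a reference values", {
  # reference vectors for 32-bit FNV-1a: empty string -> offset basis,
  # "a" -> 0xe40c292c, "foobar" -> 0xbf9cf968
  expect_equal(fnv1a32(""), 2166136261)
  expect_equal(fnv1a32("a"), 0xe40c292c)
  expect_equal(fnv1a32("foobar"), 0xbf9cf968)
  expect_equal(fnv1a32(c("a", "a")), rep(0xe40c292c, 2))
})

test_that("hash determinism holds across processes", {
  codes <- c("I10.9", "E11.65", "M48.06", "J06.9")
  here <- paste(fnv1a32(codes), collapse = ",")
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c("-e", shQuote(sprintf(
                   "cat(paste(clinpipe::fnv1a32(c(%s)), collapse=','))",
                   paste(sprintf("'%s'", codes), collapse = ",")))),
                 stdout = TRUE)
  expect_equal(tail(out, 1), here)
})

test_that("hashed matrices have exactly 2^18 columns and are reproducible", {
  sets <- list(p1 = c("J06.9", "K29.7", "J06.9"), p2 = "M54.5", p3 = character())
  X <- hash_features(sets)
  expect_equal(ncol(X), 262144L)
  expect_equal(nrow(X), 3L)
  expect_identical(rownames(X), c("p1", "p2", "p3"))
  expect_identical(X, hash_features(sets))
  # repeats accumulate: the duplicated code contributes magnitude 2
  expect_equal(max(abs(X[1, ])), 2)
  # empty multiset -> zero row
  expect_equal(sum(abs(X[3, ])), 0)
  expect_error(hash_features(sets, n_bits = 5), "\\[8, 30\\]")
  expect_error(hash_features(sets, n_bits = 31), "\\[8, 30\\]")
})

test_that("engineered index collisions with opposite signs cancel", {
  # search a candidate pool for two codes sharing a column index at 8 bits
  # but with opposite sign bits, then verify cancellation from the hashes
  pool <- sprintf("Z%02d.%d", rep(0:99, each = 10), 0:9)
  idx <- (fnv1a32(pool) %% 2^8) + 1
  sgn <- ifelse((fnv1a32(paste0(pool, "#s")) %/% 65536) %% 2 == 0, 1, -1)
  found <- NULL
  for (i in seq_along(pool)) {
    j <- which(idx == idx[i] & sgn == -sgn[i])
    if (length(j)) { found <- c(pool[i], pool[j[1]]); break }
  }
  expect_false(is.null(found))
  X <- hash_features(list(p = found), n_bits = 8)
  expect_equal(unname(X[1, idx[match(found[1], pool)]]), 0)
})

test_that("defining-code exclusion equals a brute-force filter and finds no leaks", {
  expect_equal(exclude_defining_codes(c("I10.9", "J45.0")), "J45.0")
  expect_equal(exclude_defining_codes(character()), character())
  set.seed(13)
  pool <- c(default_code_pool()$code, "I10.9", "E10.9", "E11.9", "E13.5", "M48.06")
  ms <- sample(pool, 200, replace = TRUE)
  oracle <- ms[!(ms == "I10.9" | ms == "M48.06" |
                   substr(ms, 1, 3) %in% c("E10", "E11", "E12", "E13", "E14"))]
  expect_equal(exclude_defining_codes(ms), oracle)

  # leakage audit over the feature pipeline's actual input surface
  tab <- generate_cohort(small_generator(n = 100, seed = 3), messy = FALSE)
  sets <- patient_code_multisets(tab)
  specs <- default_label_specs()
  leaks <- sum(vapply(sets, function(cc) {
    sum(match_codes(cc, specs$hypertension) | match_codes(cc, specs$diabetes) |
          match_codes(cc, specs$spine))
  }, numeric(1)))
  expect_equal(leaks, 0)
})

test_that("label matrix matches a hand-built truth table", {
  df <- data.frame(
    patient_id = c("a", "b", "b", "c", "d", "e"),
    dx_code = c("E13.5", "I10.9", "M48.06", "J06.9", "I10.0", "E15")
  )
  Y <- build_label_matrix(df)
  truth <- rbind(a = c(1L, 0L, 0L), b = c(0L, 1L, 1L), c = c(0L, 0L, 0L),
                 d = c(0L, 0L, 0L), e = c(0L, 0L, 0L))
  colnames(truth) <- c("diabetes", "hypertension", "spine")
  expect_equal(Y[, colnames(truth)], truth[rownames(Y), ])
})

test_that("patient splits honour fractions, partition patients, and reproduce", {
  ids <- sprintf("P%03d", 1:100)
  sp <- split_patients(ids)
  expect_equal(as.integer(table(sp)[c("train", "validation", "test")]),
               c(65L, 15L, 20L))
  expect_identical(sp, split_patients(ids))
  expect_false(identical(sp, split_patients(ids, seed = 43)))
  expect_true(all(!is.na(sp)))
  expect_identical(names(sp), ids)

  all_train <- split_patients(ids, fractions = c(train = 1, validation = 0, test = 0))
  expect_true(all(all_train == "train"))

  # counts stay within one of exact at awkward sizes
  for (n in c(7, 13, 101, 997)) {
    sp <- split_patients(sprintf("Q%04d", seq_len(n)))
    cnt <- table(sp)
    expect_true(all(abs(cnt - n * c(0.65, 0.15, 0.20)) <= 1))
    expect_equal(sum(cnt), n)
  }
  expect_error(split_patients(ids, fractions = c(train = 0.6, validation = 0.2, test = 0.1)),
               "sum to 1")
  expect_error(split_patients(c("A", "A")), "distinct")

  # patient-level property on row-expanded data: all rows of a patient
  # share the split
  rows <- sample(ids, 400, replace = TRUE)
  by_row <- sp[rows]
  expect_true(all(tapply(as.character(by_row), rows,
                         function(v) length(unique(v)) == 1)))
})

test_that("positive-class weights are the neg/pos count ratio", {
  expect_equal(unname(pos_weight(matrix(c(rep(0, 9), 1), ncol = 1))), 9)
  expect_equal(unname(pos_weight(matrix(c(rep(0, 5), rep(1, 5)), ncol = 1))), 1)
  set.seed(2)
  y <- rbinom(200, 1, 0.3)
  expect_equal(unname(pos_weight(matrix(y, ncol = 1))), sum(y == 0) / sum(y == 1))
  Y <- cbind(a = y, b = rep(0L, 200))
  expect_error(pos_weight(Y), "zero positives.*b")
})
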