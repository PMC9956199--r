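test_that("cohort generation matches the configuration", {
  cfg <- synthetic_config(100, class_balance = 0.5, seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 100)
  expect_equal(ncol(cohort), 7)  # id + 5 features + label
  expect_false(anyDuplicated(cohort$patient_id) > 0)
  feats <- as.matrix(cohort[, paste0("f", 1:5)])
  expect_true(all(is.finite(feats)))
  expect_true(all(feats >= 0 & feats <= 1))
  # label fraction within binomial sampling error of the configured balance
  expect_lt(abs(mean(cohort$label) - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("null effect size gives equal class-conditional means", {
  cfg <- synthetic_config(4000, effect_size = 0, seed = 3)
  raw <- generate_cohort(cfg, scale = FALSE)
  for (j in 1:2) {
    d <- mean(raw[raw$label == 1, paste0("f", j)]) -
      mean(raw[raw$label == 0, paste0("f", j)])
    se <- sqrt(1 / sum(raw$label == 1) + 1 / sum(raw$label == 0))
    expect_lt(abs(d), 4 * se)
  }
})

test_that("a separable cohort is learnable by a linear-classifier oracle", {
  cfg <- synthetic_config(2000, effect_size = 2.0, seed = 5)
  cohort <- generate_cohort(cfg)
  sp <- split_cohort(cohort, 0.8, seed = 6)
  fit <- suppressWarnings(
    glm(label ~ f1 + f2 + f3 + f4 + f5, binomial(), data = sp$train))
  pred <- as.integer(predict(fit, sp$test, type = "response") >= 0.5)
  expect_gte(mean(pred == sp$test$label), 0.90)
})

test_that("generation is seed-deterministic down to the CSV bytes", {
  cfg <- synthetic_config(150, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1)
  write_cohort(c2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("class separation matches the configured shift across seeds", {
  diffs <- vapply(1:50, function(s) {
    cfg <- synthetic_config(400, effect_size = 1.5, noise_sd = 2, seed = s)
    raw <- generate_cohort(cfg, scale = FALSE)
    mean(raw[raw$label == 1, "f1"]) - mean(raw[raw$label == 0, "f1"])
  }, numeric(1))
  se <- 2 * sqrt(1 / 200 + 1 / 200) / sqrt(50)  # noise_sd 2, ~200 per class
  expect_lt(abs(mean(diffs) - 1.5 * 2), 3 * se)
})

test_that("split is a stratified, seeded, exhaustive partition", {
  cfg <- synthetic_config(100, seed = 2)
  cohort <- generate_cohort(cfg)
  sp <- split_cohort(cohort, 0.8, seed = 7)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  cohort$patient_id)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(unique(sp$train$label), c(0, 1))
  expect_setequal(unique(sp$test$label), c(0, 1))
  # stratification keeps class fractions close
  expect_lt(abs(mean(sp$train$label) - mean(cohort$label)), 0.02)

  sp2 <- split_cohort(cohort, 0.8, seed = 7)
  expect_identical(sp, sp2)

  even <- split_cohort(cohort[1:10, ], 0.5, seed = 1)
  expect_equal(nrow(even$train), 5)
  expect_equal(nrow(even$test), 5)

  expect_error(split_cohort(cohort[1, ], 0.5), "at least 2")
  expect_error(split_cohort(cohort, 0.999), "empty")
})

test_that("CSV write/read roundtrips exactly and rejects malformed input", {
  cohort <- generate_cohort(synthetic_config(40, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_identical(read_cohort(path), cohort)

  # unscaled (full-precision doubles) roundtrip too
  raw <- generate_cohort(synthetic_config(40, seed = 7), scale = FALSE)
  write_cohort(raw, path)
  expect_identical(read_cohort(path), raw)

  writeLines("patient_id,f1,f2,label", path)
  expect_warning(empty <- read_cohort(path), "no records")
  expect_equal(nrow(empty), 0)

  writeLines(c("patient_id,f1,f2", "P1,0.5,0.5"), path)
  expect_error(read_cohort(path), "header")

  writeLines(c("patient_id,f1,f2,label", "P1,0.5,oops,1"), path)
  expect_error(read_cohort(path), "row 1")

  writeLines(c("patient_id,f1,f2,label", "P1,0.5,0.5,1", "P1,0.1,0.2,0"),
             path)
  expect_error(read_cohort(path), "duplicate")

  writeLines(c("patient_id,f1,f2,label", "P1,0.5,0.5,2"), path)
  expect_error(read_cohort(path), "label")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(0), "n_records")
  expect_error(synthetic_config(10, n_features = -1), "n_features")
  expect_error(synthetic_config(10, class_balance = 1), "class_balance")
  expect_error(synthetic_config(10, noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(10, informative = 9), "informative")
})
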