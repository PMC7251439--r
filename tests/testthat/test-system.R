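test_that("the cohort is split 80/20 within each class", {
  fit <- small_system()
  lab <- fit$label
  for (cls in stage_levels()) {
    n_cls <- sum(lab == cls)
    n_tr <- sum(lab[fit$split$train] == cls)
    expect_equal(n_tr, round(0.8 * n_cls))
  }
  expect_equal(sort(c(fit$split$train, fit$split$test)), seq_along(lab))
})

test_that("training is deterministic: same cohort and seed, identical archives", {
  co <- simulate_cohort(cohort_spec(
    n_per_class = c(benign = 30, I = 30, II = 30, III = 30, IV = 30), seed = 41))
  f1 <- suppressWarnings(em_system(co, em_config(seed = 5)))
  f2 <- suppressWarnings(em_system(co, em_config(seed = 5)))
  p1 <- tempfile(fileext = ".rds"); p2 <- tempfile(fileext = ".rds")
  save_em_system(f1, p1); save_em_system(f2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  probe <- simulate_cohort(cohort_spec(
    n_per_class = c(benign = 5, I = 5, II = 5, III = 5, IV = 5), seed = 43))
  expect_identical(predict(f1, probe), predict(f2, probe))
})

test_that("training requires every class", {
  co <- small_cohort()
  expect_error(em_system(co[co$label != "II", ], em_config()), "II")
  expect_error(em_system(co[, setdiff(names(co), "label")], em_config()), "label")
})

test_that("clean benign and stage-IV cases are routed correctly", {
  fit <- small_system()
  benign <- clean_profile(2.0)
  d_b <- predict(fit, benign)
  expect_equal(as.character(d_b$verdict), "benign")
  expect_true(is.na(d_b$em))
  expect_equal(d_b$treatment, "next_examination")

  late <- clean_profile(6.0)
  d_iv <- predict(fit, late)
  expect_equal(as.character(d_iv$verdict), "IV")
  expect_gt(d_iv$ln_em, 5.3)
  expect_match(d_iv$treatment, "chemotherapy")

  # deterministic diagnosis, alias interface included
  expect_identical(predict(fit, late), predict(fit, late))
  expect_identical(diagnose(fit, late), predict(fit, late))
})

test_that("lnEM maps to stages by half-open bins with a below-range flag", {
  s <- stage_from_lnem(c(3.0, 3.6, 5.4, 2.0, 4.499, 4.5))
  expect_equal(as.character(s$stage), c("I", "II", "IV", "I", "II", "III"))
  expect_equal(s$flag, c("", "", "", "below_stage_I_range", "", ""))
  expect_error(stage_from_lnem(NA_real_), "finite")
  expect_error(stage_from_lnem(3, thresholds = c(4, 3, 2, 1)))
})

test_that("treatment recommendation is a deterministic stage lookup", {
  r <- recommend_treatment(c("benign", "I", "II", "III", "IV"))
  expect_equal(r$modalities[1], "next_examination")
  expect_match(r$modalities[2], "excision")
  expect_match(r$modalities[4], "chemotherapy")
  expect_match(r$modalities[5], "chemotherapy")
  expect_match(r$modalities[5], "drug method")
  expect_true(all(r$advisory == "auxiliary suggestion, not a prescription"))
  expect_identical(recommend_treatment("II"), recommend_treatment("II"))
  expect_error(recommend_treatment("X"), "unknown stage")
})

test_that("treatment tracking follows the relative-EM-drop rule and audits", {
  fit <- small_system()
  before <- clean_profile(5.8)
  improved <- clean_profile(4.0)
  audit <- tempfile(fileext = ".csv")

  a1 <- assess_treatment(fit, before, improved, delta = 0.3,
                         patient_id = "P1", audit_file = audit)
  expect_gt(a1$relative_drop, 0.3)
  expect_equal(a1$verdict, "maintain")
  expect_false(a1$deteriorated)
  expect_equal(a1$relative_drop, (a1$em_before - a1$em_after) / a1$em_before)

  a2 <- assess_treatment(fit, before, before, delta = 0.3,
                         patient_id = "P1", audit_file = audit)
  expect_equal(a2$verdict, "change")  # unchanged EM: plan is changed

  a3 <- assess_treatment(fit, improved, before, delta = 0.3,
                         patient_id = "P1", audit_file = audit)
  expect_equal(a3$verdict, "change")
  expect_true(a3$deteriorated)

  # exactly one audit record per call
  log <- read.csv(audit)
  expect_equal(nrow(log), 3)
  expect_error(assess_treatment(fit, before, improved, delta = 1.5), "delta")
})

test_that("model-idiom accessors expose the meta-learner fit", {
  fit <- small_system()
  cf <- coef(fit)
  expect_length(cf, 37)
  expect_equal(names(cf)[1], "intercept")
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(length(r), length(f))
  tr_mal <- sum(fit$label[fit$split$train] != "benign")
  expect_equal(length(r), tr_mal)
  target <- as.numeric(fit$config$supervising_values[
    as.character(fit$label[fit$split$train[fit$label[fit$split$train] != "benign"]])])
  expect_equal(unname(f - r), target)
  expect_output(print(fit), "decision system")
  expect_output(print(summary(fit)), "5-class accuracy")
})
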