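test_that("cohorts are reproducible and have the requested composition", {
  sp <- cohort_spec(n_per_class = c(benign = 0, I = 10, II = 0, III = 0, IV = 10), seed = 3)
  co1 <- simulate_cohort(sp)
  co2 <- simulate_cohort(sp)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 20)
  expect_equal(sum(co1$label == "I"), 10)
  expect_equal(sum(co1$label == "IV"), 10)
  expect_error(simulate_cohort(cohort_spec(n_per_class = c(benign = 0))), "zero patients")
})

test_that("latent severities follow the stage-centered normal law", {
  # degenerate spread pins the latent at the stage center
  sp0 <- cohort_spec(severity_sd = 1e-12)
  set.seed(1)
  expect_equal(sample_latent_severity("II", sp0, n = 5), rep(4, 5), tolerance = 1e-9)
  expect_error(sample_latent_severity("X", sp0), "unknown stage")

  # Monte-Carlo mean of 1e4 draws at stage III within 3 standard errors of 5
  sp <- cohort_spec()
  set.seed(42)
  L <- sample_latent_severity("III", sp, n = 1e4)
  expect_lt(abs(mean(L) - 5), 3 * sp$severity_sd / sqrt(1e4))

  # covariate shifts move the latent upward
  set.seed(7)
  Lhf <- sample_latent_severity("II", sp, n = 1e4, high_fat = TRUE)
  expect_lt(abs(mean(Lhf) - (4 + sp$diet_shift)), 0.02)
})

test_that("the exponential growth law maps latent severity to markers", {
  sp <- cohort_spec(noise_sd = 1e-12)
  set.seed(1)
  # at the benign reference, positive-gain markers sit at their upper bound
  p_ref <- severity_to_profile(sp$severity_location[["benign"]], sp)
  expect_equal(p_ref$psa, 4.0, tolerance = 1e-6)
  expect_equal(p_ref$pap, 9.0, tolerance = 1e-6)
  # four latent units up: psa = 4 * exp(0.6 * 4) ~ 11x the upper bound
  p4 <- severity_to_profile(sp$severity_location[["benign"]] + 4, sp)
  expect_equal(p4$psa, 4.0 * exp(2.4), tolerance = 1e-6)
  # monotone in L; RBC declines mildly
  p3 <- severity_to_profile(3, sp); p6 <- severity_to_profile(6, sp)
  expect_gt(p6$psa, p3$psa)
  expect_lt(p6$rbc, p3$rbc)
})

test_that("benign markers stay near normal while stage IV runs far beyond", {
  sp <- cohort_spec(n_per_class = c(benign = 500, I = 0, II = 0, III = 0, IV = 500), seed = 9)
  co <- simulate_cohort(sp)
  upper <- normal_ranges()$psa[2]
  expect_lt(median(co$psa[co$label == "benign"]) / upper, 2)
  expect_gt(median(co$psa[co$label == "IV"]) / upper, 5)
})

test_that("mean PSA increases strictly across the class gradient", {
  sp <- cohort_spec(n_per_class = setNames(rep(500, 5), stage_levels()), seed = 13)
  co <- simulate_cohort(sp)
  m <- tapply(co$psa, co$label, mean)
  expect_true(all(diff(m[stage_levels()]) > 0))
})

test_that("latent severity is recoverable from log markers (R^2 > 0.8)", {
  co <- simulate_cohort(cohort_spec(n_per_class = setNames(rep(200, 5), stage_levels()),
                                    seed = 17))
  logX <- log(pmax(marker_matrix(co), 1e-9))
  fit <- lm(co$severity ~ logX)
  expect_gt(summary(fit)$r.squared, 0.8)
})

test_that("diet and inheritance shifts raise latent severity of carriers", {
  sp <- cohort_spec(n_per_class = setNames(rep(300, 5), stage_levels()),
                    p_high_fat = 0.5, p_family_history = 0.5, seed = 19)
  co <- simulate_cohort(sp)
  expect_gt(mean(co$severity[co$diet == "high_fat"]),
            mean(co$severity[co$diet == "normal"]))
  expect_gt(mean(co$severity[co$family_history == 1]),
            mean(co$severity[co$family_history == 0]))
})
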