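test_that("bias is the respondent-minus-frame difference in percentage points", {
  # differences of the trial's printed frame-characteristics percentages
  expect_equal(compute_bias(86.9, 81.9), 5.0)
  expect_equal(compute_bias(23.6, 30.4), -6.8)
  expect_equal(compute_bias(57.3, 57.3), 0)
  # antisymmetry
  expect_equal(compute_bias(40, 70), -compute_bias(70, 40))
  expect_error(compute_bias(101, 50), "\\[0, 100\\]")
})

test_that("bias_by_arm is exactly zero under full response and flags empty strata", {
  cohort <- simulate_cohort(trial_scenario(), seed = 4)
  full <- cohort$responses
  full$returned <- 1L
  full$self_combat <- cohort$latent$self_combat
  full$self_msa <- cohort$latent$self_msa
  b <- bias_by_arm(cohort$frame, cohort$assignment, full, "combat_admin")
  expect_true(all(b$bias_pp[b$stratum == "overall"] == 0))
  expect_false(any(b$undefined))
  # per-arm rows compare the arm subset against the whole block frame, so
  # under full response they equal the randomization imbalance exactly
  men <- merge(cohort$frame[cohort$frame$block == "men", ],
               cohort$assignment[, c("subject_id", "incentive")],
               by = "subject_id")
  expect_equal(
    b$bias_pp[b$block == "men" & b$stratum == "usd40"],
    100 * mean(men$combat_admin[men$incentive == "usd40"]) -
      100 * mean(men$combat_admin))
  # no respondents among usd20 men -> undefined, not silently zero
  part <- cohort$responses
  drop_ids <- cohort$assignment$subject_id[
    cohort$assignment$incentive == "usd20"]
  part$returned[part$subject_id %in% drop_ids] <- 0L
  expect_warning(
    bpart <- bias_by_arm(cohort$frame, cohort$assignment, part,
                         "combat_admin", block = "men"),
    "empty respondent stratum")
  expect_true(bpart$undefined[bpart$stratum == "usd20"])
  expect_true(is.na(bpart$bias_pp[bpart$stratum == "usd20"]))
})

test_that("bias under MCAR response shrinks with sample size", {
  spec <- frame_spec(n_per_block = 24000)
  fr <- generate_frame(spec, seed = 21)
  asg <- randomize_blocked(fr, seed = 22)
  lat <- simulate_self_reports(
    fr, outcome_model(y = c("(Intercept)" = 0)), seed = 23)
  resp <- simulate_response(
    fr, asg, lat, response_model(alpha = c("(Intercept)" = -0.3)), seed = 24)
  b <- bias_by_arm(fr, asg, resp, "combat_admin", block = "men")
  expect_true(all(abs(b$bias_pp) < 2))
})

test_that("ANOVA partition conserves sums of squares with and without pooling", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 240
    fac <- data.frame(a = sample(c("x", "y", "z"), n, TRUE),
                      b = sample(c("u", "v"), n, TRUE),
                      c = sample(c("p", "q"), n, TRUE))
    y <- rnorm(n) + 0.3 * (fac$a == "x") + 0.2 * (fac$b == "u") * (fac$a == "y")
    for (alpha in c(0.05, 2)) {  # pooled and keep-all fits
      part <- anova_eta2(y, fac, pool_alpha = alpha)
      expect_lt(abs(sum(part$terms$ss) + part$ss_error - part$ss_total) /
                  part$ss_total, 1e-8)
      expect_true(all(part$eta2_percent >= 0 & part$eta2_percent <= 100))
    }
  }
})

test_that("single-factor eta squared equals the squared point-biserial correlation", {
  set.seed(32)
  g <- sample(c("a", "b"), 80, TRUE)
  y <- rnorm(80) + 0.5 * (g == "a")
  part <- anova_eta2(y, data.frame(g = g))
  r2 <- cor(y, as.numeric(g == "a"))^2
  expect_lt(abs(part$eta2_percent[["g"]] / 100 - r2), 1e-10)
})

test_that("eta squared is zero for a constant correlate and invariant to affine recoding", {
  set.seed(33)
  fac <- data.frame(a = rep(c("x", "y", "z"), each = 20),
                    b = rep(c("u", "v"), 30))
  const <- anova_eta2(rep(0.25, 60), fac)
  expect_true(all(const$eta2_percent == 0))
  y <- rbinom(60, 1, 0.4) - 0.4
  p1 <- anova_eta2(y, fac)
  p2 <- anova_eta2(3 * y + 7, fac)
  expect_equal(p1$eta2_percent, p2$eta2_percent, tolerance = 1e-10)
})

test_that("null simulation: mean eta squared matches its expectation df/(n-1)", {
  set.seed(34)
  n <- 60
  g <- factor(rep(letters[1:3], each = n / 3))
  e2 <- replicate(400, {
    part <- anova_eta2(rnorm(n), data.frame(g = g))
    part$eta2_percent[["g"]] / 100
  })
  expect_lt(abs(mean(e2) - 2 / (n - 1)), 4 * sd(e2) / sqrt(length(e2)))
})

test_that("factorial_anova_eta2 names empty cells and pools interactions", {
  cohort <- simulate_cohort(trial_scenario(), seed = 6)
  part <- factorial_anova_eta2(cohort$frame, cohort$assignment,
                               cohort$responses, "combat_admin",
                               block = "men")
  expect_s3_class(part, "anova_partition")
  expect_named(part$eta2_percent, c("content", "source", "incentive"))
  # interactions that were pooled no longer appear as model terms
  expect_true(all(!part$pooled %in% part$terms$term))
  resp <- cohort$responses
  kill <- cohort$assignment$subject_id[
    cohort$assignment$cell == "combat:oef_list:usd20" &
      cohort$assignment$block == "men"]
  resp$returned[resp$subject_id %in% kill] <- 0L
  expect_error(
    factorial_anova_eta2(cohort$frame, cohort$assignment, resp,
                         "combat_admin", block = "men"),
    "combat:oef_list:usd20")
})

test_that("Cohen's h follows the arcsine formula and its bounds", {
  expect_equal(cohen_h(0.37, 0.37), 0)
  expect_equal(cohen_h(0, 1), pi)
  expect_equal(cohen_h(0.5, 0.62),
               abs(2 * asin(sqrt(0.5)) - 2 * asin(sqrt(0.62))))
  expect_equal(cohen_h(0.2, 0.6), cohen_h(0.6, 0.2))
  expect_error(cohen_h(-0.1, 0.5), "\\[0, 1\\]")
})
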