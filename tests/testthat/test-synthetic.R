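test_that("generated frames reproduce the configured prevalences", {
  spec <- frame_spec(n_per_block = 100000)
  fr <- generate_frame(spec, seed = 42)
  men <- fr[fr$block == "men", ]
  women <- fr[fr$block == "women", ]
  expect_equal(nrow(men), 100000L)
  expect_lt(abs(mean(men$combat_admin) - 0.671), 0.005)
  expect_lt(abs(mean(women$mst_admin) - 0.456), 0.005)
  expect_lt(abs(mean(men$any_benefits) - 0.819), 0.005)
  expect_identical(fr, generate_frame(spec, seed = 42))
})

test_that("degenerate prevalences and invalid specs are handled", {
  prev <- default_prevalences()
  prev$men["smi"] <- 0
  fr <- generate_frame(frame_spec(1000, prev), seed = 1)
  expect_true(all(fr$smi[fr$block == "men"] == 0))
  prev$men["smi"] <- 1.2
  expect_error(frame_spec(1000, prev), "\\[0, 1\\]")
})

test_that("copula dependence induces the requested association and rejects invalid laws", {
  covs <- frame_covariates()
  R <- diag(8)
  R[3, 7] <- R[7, 3] <- 0.6  # combat_admin with any_benefits
  dimnames(R) <- list(covs, covs)
  fr <- generate_frame(frame_spec(50000, dependence = R), seed = 5)
  men <- fr[fr$block == "men", ]
  expect_gt(cor(men$combat_admin, men$any_benefits), 0.2)
  bad <- matrix(0.99, 8, 8); diag(bad) <- 0.1
  expect_error(frame_spec(1000, dependence = bad), "positive definite")
})

test_that("latent self-reports follow the logistic outcome model", {
  fr <- generate_frame(frame_spec(50000), seed = 7)
  fr <- fr[fr$block == "men", ]
  om <- outcome_model(y = c("(Intercept)" = stats::qlogis(0.9)))
  lat <- simulate_self_reports(fr, om, seed = 8)
  expect_lt(abs(mean(lat$y) - 0.9), 0.005)
  # conditional prevalences match expit arithmetic
  om2 <- outcome_model(y = c("(Intercept)" = -0.6, combat_admin = 2.0))
  lat2 <- simulate_self_reports(fr, om2, seed = 9)
  p1 <- mean(lat2$y[fr$combat_admin == 1])
  p0 <- mean(lat2$y[fr$combat_admin == 0])
  expect_lt(abs(p1 - stats::plogis(1.4)), 0.01)
  expect_lt(abs(p0 - stats::plogis(-0.6)), 0.01)
  expect_identical(lat2, simulate_self_reports(fr, om2, seed = 9))
  expect_error(outcome_model(y = c(unknown_cov = 1)), "unknown coefficient")
})

test_that("response process masks self-reports and hits the target rate", {
  fr <- generate_frame(frame_spec(50000), seed = 10)
  fr <- fr[fr$block == "men", ]
  om <- outcome_model(y = c("(Intercept)" = 0.2, combat_admin = 1.0))
  lat <- simulate_self_reports(fr, om, seed = 11)
  rmod <- response_model(alpha = c("(Intercept)" = stats::qlogis(0.427)))
  resp <- simulate_response(fr, NULL, lat, rmod, seed = 12)
  expect_lt(abs(mean(resp$returned) - 0.427), 0.01)
  # masking conservation
  expect_equal(sum(resp$returned == 1) + sum(is.na(resp$y)), nrow(fr))
  expect_true(all(is.na(resp$y[resp$returned == 0])))
  expect_equal(resp$y[resp$returned == 1], lat$y[resp$returned == 1])
})

test_that("negative gamma suppresses the outcome among responders", {
  fr <- generate_frame(frame_spec(50000), seed = 13)
  fr <- fr[fr$block == "men", ]
  om <- outcome_model(y = c("(Intercept)" = 0))
  lat <- simulate_self_reports(fr, om, seed = 14)
  rmod <- response_model(alpha = c("(Intercept)" = 0), gamma = c(y = -1.5))
  resp <- simulate_response(fr, NULL, lat, rmod, seed = 15)
  expect_lt(mean(resp$y[resp$returned == 1]), mean(lat$y) - 0.05)
})

test_that("generated mechanisms are MCAR / MAR / MNAR as labelled", {
  fr <- generate_frame(frame_spec(50000), seed = 16)
  fr <- fr[fr$block == "men", ]
  om <- outcome_model(y = c("(Intercept)" = -0.5, combat_admin = 1.5,
                            any_benefits = 1.0))
  lat <- simulate_self_reports(fr, om, seed = 17)
  fit_p <- function(resp, formula_terms) {
    d <- data.frame(r = resp$returned, y = lat$y,
                    combat_admin = fr$combat_admin,
                    any_benefits = fr$any_benefits)
    g <- stats::glm(stats::reformulate(formula_terms, "r"), data = d,
                    family = stats::binomial())
    summary(g)$coefficients
  }
  # MCAR: nothing predicts response
  mcar <- simulate_response(fr, NULL, lat,
                            response_model(alpha = c("(Intercept)" = -0.3)),
                            seed = 18)
  co <- fit_p(mcar, c("combat_admin", "any_benefits", "y"))
  expect_true(all(co[-1, "Pr(>|z|)"] > 0.01))
  # MAR: covariate predicts response, y does not (given x)
  mar <- simulate_response(fr, NULL, lat,
    response_model(alpha = c("(Intercept)" = -0.3, combat_admin = 0.8)),
    seed = 19)
  co <- fit_p(mar, c("combat_admin", "any_benefits", "y"))
  expect_lt(co["combat_admin", "Pr(>|z|)"], 1e-6)
  expect_gt(co["y", "Pr(>|z|)"], 0.01)
  # MNAR: y predicts response given x
  mnar <- simulate_response(fr, NULL, lat,
    response_model(alpha = c("(Intercept)" = -0.3, combat_admin = 0.8),
                   gamma = c(y = -1.0)), seed = 20)
  co <- fit_p(mnar, c("combat_admin", "any_benefits", "y"))
  expect_lt(co["y", "Pr(>|z|)"], 1e-6)
})

test_that("the bundled trial-like scenario reproduces the trial's dimensions", {
  cohort <- simulate_cohort(trial_scenario(), seed = 2016)
  expect_equal(nrow(cohort$frame), 960L)
  expect_true(all(table(cohort$assignment$block, cohort$assignment$cell) == 40L))
  rr <- mean(cohort$responses$returned)
  expect_gt(rr, 0.3); expect_lt(rr, 0.55)
  expect_identical(cohort$responses,
                   simulate_cohort(trial_scenario(), seed = 2016)$responses)
})
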