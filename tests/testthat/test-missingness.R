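test_that("complete-case prevalence is the observed mean among responders", {
  resp <- data.frame(subject_id = sprintf("S%02d", 1:10),
                     returned = c(rep(1L, 6), rep(0L, 4)),
                     y = c(1L, 1L, 0L, 1L, 0L, 1L, rep(NA, 4)))
  expect_equal(prevalence_mcar(resp, "y"), 100 * 4 / 6)
  resp$y[resp$returned == 1] <- 1L
  expect_equal(prevalence_mcar(resp, "y"), 100)
  resp$returned <- 0L
  expect_error(prevalence_mcar(resp, "y"), "no responders")
})

test_that("mechanism summaries reproduce the reporting convention for variance and range", {
  # men's self-reported combat triplet
  s <- summarize_mechanisms(89.3, 85.3, 66.8)
  expect_equal(round(s$variance_across, 4), 0.0144)
  expect_equal(s$range_across, 22.5)
  # men's military sexual assault triplet
  s <- summarize_mechanisms(5.2, 5.6, 25.6)
  expect_equal(round(s$variance_across, 4), 0.0136)
  expect_equal(s$range_across, 20.4)
  # women's triplets: printed ranges
  expect_equal(summarize_mechanisms(64.2, 62.3, 55.6)$range_across, 8.6)
  expect_equal(summarize_mechanisms(50.1, 51.0, 49.8)$range_across, 1.2)
  # degenerate
  s <- summarize_mechanisms(40, 40, 40)
  expect_equal(s$variance_across, 0)
  expect_equal(s$range_across, 0)
  expect_error(summarize_mechanisms(101, 50, 50), "\\[0, 100\\]")
})

test_that("Rubin pooling identities hold exactly", {
  sim <- simulate_benchmark(mcar_benchmark_scenario(), seed = 61)
  sub <- sim$frame[1:5004, ]
  rsub <- sim$responses[1:5004, ]
  mi <- impute_mar(sub, rsub, "y", m = 7, seed = 62,
                   covariates = mcar_benchmark_scenario()$covariates)
  expect_equal(mi$prevalence_pct, mean(mi$per_imputation_pct))
  expect_equal(mi$total_var, mi$within_var + (1 + 1 / 7) * mi$between_var,
               tolerance = 1e-10)
  m1 <- impute_mar(sub, rsub, "y", m = 1, seed = 63,
                   covariates = mcar_benchmark_scenario()$covariates)
  expect_equal(m1$between_var, 0)
  expect_equal(m1$total_var, m1$within_var)
  expect_identical(mi$per_imputation_pct,
                   impute_mar(sub, rsub, "y", m = 7, seed = 62,
                              covariates = mcar_benchmark_scenario()$covariates
                              )$per_imputation_pct)
})

test_that("under MCAR the imputation estimate tracks the complete-case mean", {
  sc <- mcar_benchmark_scenario()
  sc$n <- 10008L
  sim <- simulate_benchmark(sc, seed = 64)
  cc <- prevalence_mcar(sim$responses, "y")
  mi <- impute_mar(sim$frame, sim$responses, "y", covariates = sc$covariates,
                   m = 25, seed = 65)
  mc_se <- sqrt(mi$total_var) * 100
  expect_lt(abs(mi$prevalence_pct - cc), 2 * mc_se)
})

test_that("EM with nothing missing reduces to the ordinary logistic fit", {
  sim <- simulate_benchmark(em_recovery_scenario(), seed = 66)
  resp <- sim$responses
  resp$returned <- 1L
  resp$y <- sim$latent$y
  covs <- em_recovery_scenario()$covariates
  fit <- fit_em_nonignorable(sim$frame, resp, "y", covariates = covs)
  g <- stats::glm(stats::reformulate(covs, "y"),
                  data = cbind(sim$frame, y = sim$latent$y),
                  family = stats::binomial())
  expect_equal(unname(fit$beta), unname(stats::coef(g)), tolerance = 1e-6)
  expect_equal(prevalence_mnar(fit, sim$frame, resp),
               100 * mean(sim$latent$y))
  expect_true(fit$converged)
})

test_that("EM ascends the observed-data likelihood and bounds its weights", {
  sc <- em_recovery_scenario()
  sc$n <- 2400L
  sim <- simulate_benchmark(sc, seed = 67)
  fit <- fit_em_nonignorable(sim$frame, sim$responses, "y",
                             covariates = sc$covariates)
  expect_true(all(diff(fit$loglik) >= -1e-10))
  expect_true(all(fit$w1 >= 0 & fit$w1 <= 1))
  expect_true(fit$converged)
  expect_equal(length(fit$w1), sum(sim$responses$returned == 0))
  # accelerated and textbook iterations reach the same stationary point
  plain <- fit_em_nonignorable(sim$frame, sim$responses, "y",
                               covariates = sc$covariates,
                               accelerate = FALSE, max_iter = 5000L)
  expect_true(all(diff(plain$loglik) >= -1e-10))
  expect_equal(c(fit$beta, fit$alpha, fit$gamma),
               c(plain$beta, plain$alpha, plain$gamma), tolerance = 5e-3)
})

test_that("the selection model corrects the complete-case bias it was built for", {
  sim <- simulate_benchmark(em_recovery_scenario(), seed = 68)
  truth <- 100 * mean(sim$latent$y)
  cc <- prevalence_mcar(sim$responses, "y")
  fit <- fit_em_nonignorable(sim$frame, sim$responses, "y",
                             covariates = em_recovery_scenario()$covariates)
  mnar <- prevalence_mnar(fit, sim$frame, sim$responses)
  # gamma < 0 makes responders under-report; complete case is biased low
  expect_lt(cc, truth - 2)
  expect_lt(abs(mnar - truth), abs(cc - truth))
  marg <- prevalence_mnar(fit, sim$frame, sim$responses, type = "marginal")
  expect_lt(abs(marg - mnar), 10)  # both in the same neighbourhood
})

test_that("mechanism_triplet assembles the three estimators coherently", {
  sc <- mcar_benchmark_scenario()
  sc$n <- 6000L
  sim <- simulate_benchmark(sc, seed = 69)
  trip <- mechanism_triplet(sim$frame, sim$responses, "y",
                            covariates = sc$covariates, m = 10, seed = 70)
  expect_s3_class(trip, "mechanism_triplet")
  s <- summarize_mechanisms(trip$est_mcar, trip$est_mar, trip$est_mnar)
  expect_equal(trip$variance_across, s$variance_across)
  expect_equal(trip$range_across, s$range_across)
  expect_gte(trip$range_across, 0)
})
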