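# Multiple imputation of a binary outcome missing for non-respondents,
# with Rubin pooling of the prevalence estimate (missing-at-random analysis).

#' Complete-case prevalence (MCAR analysis)
#'
#' The observed mean of the outcome among responders, as a percentage. This
#' is the estimate that is valid when missingness is completely at random.
#'
#' @param responses Response table with `returned` and the outcome column.
#' @param outcome Name of the binary self-report column.
#' @return Percentage in \[0, 100\].
#' @export
prevalence_mcar <- function(responses, outcome) {
  stopifnot(outcome %in% names(responses))
  yobs <- responses[[outcome]][responses$returned == 1L]
  if (!length(yobs)) stop("no responders: prevalence undefined", call. = FALSE)
  if (anyNA(yobs)) stop("outcome missing for a responder", call. = FALSE)
  100 * mean(yobs)
}

#' Multiple imputation of a missing binary outcome (MAR analysis)
#'
#' Fits a logistic regression of the outcome on frame-complete covariates
#' among responders, then for each of `m` imputations draws coefficients
#' from the fit's asymptotic normal approximation (posterior-draw step) and
#' imputes Bernoulli outcomes for every non-respondent. The prevalence over
#' the full frame is pooled across imputations by Rubin's rules, with the
#' per-imputation sampling variance taken as p(1 - p)/N on the proportion
#' scale.
#'
#' @param frame Sampling frame (covariates observed for everyone).
#' @param responses Response table.
#' @param outcome Binary self-report column to impute.
#' @param covariates Character vector of frame columns used as predictors.
#' @param assignment Optional arm assignment; when supplied the four arm
#'   dummies enter the imputation model.
#' @param m Number of imputations (default 25).
#' @param seed Integer seed.
#' @param draw `"normal"` (default) draws coefficients from the asymptotic
#'   normal; `"bootstrap"` refits the responders model on a bootstrap
#'   resample before each imputation.
#' @return Object of class `mi_result`: list with `m`, `prevalence_pct`
#'   (pooled), `per_imputation_pct`, `within_var`, `between_var`,
#'   `total_var` (Rubin decomposition, proportion scale), `se_pct`, `coef`
#'   (responders-model fit).
#' @export
impute_mar <- function(frame, responses, outcome, covariates = frame_covariates(),
                       assignment = NULL, m = 25L, seed, draw = c("normal", "bootstrap")) {
  draw <- match.arg(draw)
  stopifnot(m >= 1)
  d <- merge(frame, responses[, c("subject_id", "returned", outcome)],
             by = "subject_id")
  X <- design_matrix(d, assignment)
  X <- X[, c("(Intercept)", intersect(colnames(X), covariates),
             intersect(colnames(X), c("content_sexual_attention",
                                      "content_lifetime", "source_claims_list",
                                      "incentive_usd40"))), drop = FALSE]
  r <- d$returned == 1L
  yobs <- d[[outcome]][r]
  fit <- tryCatch(
    fit_weighted_logistic(X[r, , drop = FALSE], yobs),
    warning = function(wrn) {
      # separation fallback: ridge-penalized refit, logged via message
      message("responders model unstable (", conditionMessage(wrn),
              "); using ridge-penalized fit")
      fit_penalized_logistic(X[r, , drop = FALSE], yobs)
    })
  vc <- attr(fit, "vcov")
  N <- nrow(d)
  n_mis <- sum(!r)
  local_seed(seed, {
    prev <- numeric(m)
    wvar <- numeric(m)
    for (k in seq_len(m)) {
      b <- if (draw == "normal") {
        drop(fit + crossprod(chol(vc), stats::rnorm(length(fit))))
      } else {
        idx <- sample(which(r), sum(r), replace = TRUE)
        as.numeric(fit_weighted_logistic(X[idx, , drop = FALSE],
                                         d[[outcome]][idx], start = fit))
      }
      pmis <- stats::plogis(drop(X[!r, , drop = FALSE] %*% b))
      yimp <- stats::rbinom(n_mis, 1L, pmis)
      phat <- (sum(yobs) + sum(yimp)) / N
      prev[k] <- phat
      wvar[k] <- phat * (1 - phat) / N
    }
    pooled <- mean(prev)
    within <- mean(wvar)
    between <- if (m > 1) stats::var(prev) else 0
    total <- within + (1 + 1 / m) * between
    structure(list(m = m, prevalence_pct = 100 * pooled,
                   per_imputation_pct = 100 * prev, within_var = within,
                   between_var = between, total_var = total,
                   se_pct = 100 * sqrt(total), coef = fit),
              class = "mi_result")
  })
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Multiple imputation (m = %d): prevalence %.1f%% (SE %.1f pp)\n",
              x$m, x$prevalence_pct, x$se_pct))
  cat(sprintf("Rubin variances (proportion scale): within %.3g, between %.3g, total %.3g\n",
              x$within_var, x$between_var, x$total_var))
  invisible(x)
}

# Small ridge penalty keeps the fit finite under separation; used only as a
# logged fallback in the imputation model.
fit_penalized_logistic <- function(X, y, lambda = 1e-3) {
  p <- ncol(X)
  beta <- numeric(p)
  for (i in 1:200) {
    mu <- stats::plogis(drop(X %*% beta))
    v <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * v) + diag(lambda, p)
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  names(beta) <- colnames(X)
  structure(drop(beta), vcov = solve(H), converged = TRUE, separation = TRUE,
            iterations = i, loglik = weighted_logistic_loglik(X, y, rep(1, length(y)), beta))
}
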