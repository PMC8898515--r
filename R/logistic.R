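# Weighted logistic regression by Fisher scoring (IRLS). Shared numeric core
# for the multiple-imputation draws and the EM M-steps, which need fractional
# case weights and warm starts.

#' Weighted logistic regression
#'
#' Maximizes the weighted Bernoulli log-likelihood
#' sum_i w_i \[y_i log p_i + (1 - y_i) log(1 - p_i)\], p_i = plogis(x_i'b),
#' by iteratively reweighted least squares. Weights are arbitrary
#' nonnegative reals (so a row duplicated at weight 0.5 is equivalent to one
#' row at weight 1), and `y` may be fractional in \[0, 1\]. Deterministic for
#' fixed input.
#'
#' @param X Design matrix (include an intercept column yourself).
#' @param y Response in \[0, 1\].
#' @param w Nonnegative case weights, default all 1.
#' @param start Optional starting coefficients (warm start).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap; hitting it with coefficients still growing
#'   flags likely separation.
#' @return Named coefficient vector with attributes `vcov` (inverse Fisher
#'   information), `converged`, `separation`, `iterations`, `loglik`.
#' @export
fit_weighted_logistic <- function(X, y, w = rep(1, length(y)), start = NULL,
                                  tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  if (all(w == 0)) stop("all weights are zero", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  p <- ncol(X)
  keep <- w > 0
  Xk <- X[keep, , drop = FALSE]
  if (qr(Xk * sqrt(w[keep]))$rank < p) {
    stop("design matrix is collinear among positively weighted rows",
         call. = FALSE)
  }
  yk <- y[keep]
  wk <- w[keep]
  beta <- if (is.null(start)) numeric(p) else as.numeric(start)
  stopifnot(length(beta) == p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xk %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-10)
    W <- wk * v
    # normal equations: cheap and stable here (few columns, rank checked)
    XtW <- crossprod(Xk, Xk * W)
    new_beta <- tryCatch(
      drop(solve(XtW, crossprod(Xk, W * (eta + (yk - mu) / v)))),
      error = function(e) rep(NA_real_, p))
    if (anyNA(new_beta)) {
      stop("IRLS produced NA coefficients (collinear design?)", call. = FALSE)
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (max(abs(beta)) > 15) {
      separation <- TRUE
      warning("possible separation: coefficients large after ", max_iter,
              " iterations", call. = FALSE)
    } else {
      warning("IRLS did not converge in ", max_iter, " iterations",
              call. = FALSE)
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  ll <- weighted_logistic_loglik(X, y, w, beta)
  names(beta) <- colnames(X)
  structure(beta, vcov = vc, converged = converged, separation = separation,
            iterations = iter, loglik = ll)
}

# Weighted Bernoulli log-likelihood at coefficients `beta`, numerically
# safe at extreme linear predictors.
weighted_logistic_loglik <- function(X, y, w, beta) {
  eta <- drop(as.matrix(X) %*% beta)
  # log p = -log1p(exp(-eta)); log(1-p) = -log1p(exp(eta))
  sum(w * (y * -log1p(exp(-eta)) + (1 - y) * -log1p(exp(eta))))
}
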