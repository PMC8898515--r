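# Synthetic cohort generator: sampling frames with administrative correlates,
# latent self-reported outcomes, and response indicators under configurable
# MCAR / MAR / MNAR mechanisms.

#' Names of the administrative non-response correlates
#'
#' Eight binary flags available for every frame member: age under 30,
#' non-white race, administrative combat exposure, administrative military
#' sexual trauma (MST), serious mental illness, Charlson comorbidity index
#' above zero, receipt of any VA disability benefits, and PTSD-specific
#' disability benefits. Administrative MST is deliberately distinct from
#' self-reported military sexual assault: the flag also covers severe,
#' pervasive physical sexual harassment, so the generator links the two
#' through an outcome model rather than equating them.
#'
#' @return Character vector of length 8.
#' @export
frame_covariates <- function() {
  c("age_lt30", "nonwhite", "combat_admin", "mst_admin",
    "smi", "charlson_gt0", "any_benefits", "ptsd_benefits")
}

#' Default covariate prevalences by gender block
#'
#' Marginal prevalences of the eight administrative correlates in the two
#' gender blocks of the emulated trial (overall sampling-frame proportions).
#'
#' @return Named list with numeric vectors `men` and `women`, one probability
#'   per correlate.
#' @export
default_prevalences <- function() {
  list(
    men = c(age_lt30 = 0.304, nonwhite = 0.419, combat_admin = 0.671,
            mst_admin = 0.021, smi = 0.052, charlson_gt0 = 0.117,
            any_benefits = 0.819, ptsd_benefits = 0.563),
    women = c(age_lt30 = 0.323, nonwhite = 0.594, combat_admin = 0.413,
              mst_admin = 0.456, smi = 0.082, charlson_gt0 = 0.100,
              any_benefits = 0.773, ptsd_benefits = 0.452)
  )
}

#' Specify a synthetic sampling frame
#'
#' @param n_per_block Subjects per gender block (default 480, the trial's
#'   dimension).
#' @param covariate_prevalence Named list (`men`, `women`) of per-correlate
#'   probabilities; defaults to [default_prevalences()].
#' @param dependence Optional correlation matrix (one matrix, or a per-block
#'   list) for a Gaussian-copula threshold construction inducing pairwise
#'   association between the binary correlates; `NULL` (default) draws them
#'   as independent Bernoullis.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(n_per_block = 480L,
                       covariate_prevalence = default_prevalences(),
                       dependence = NULL) {
  stopifnot(is.numeric(n_per_block), n_per_block >= 1)
  covs <- frame_covariates()
  for (b in names(covariate_prevalence)) {
    p <- covariate_prevalence[[b]]
    if (!all(covs %in% names(p))) {
      stop("covariate_prevalence$", b, " must name all 8 correlates",
           call. = FALSE)
    }
    if (any(!is.finite(p[covs])) || any(p[covs] < 0) || any(p[covs] > 1)) {
      stop("covariate prevalences must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(dependence)) {
    deps <- if (is.list(dependence)) dependence else
      stats::setNames(rep(list(dependence), length(covariate_prevalence)),
                      names(covariate_prevalence))
    for (b in names(deps)) {
      R <- deps[[b]]
      if (!is.matrix(R) || nrow(R) != length(covs) || ncol(R) != length(covs)) {
        stop("dependence must be an 8x8 correlation matrix", call. = FALSE)
      }
      ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
      if (!ok) {
        stop("dependence matrix is not positive definite: ",
             "no valid joint law exists", call. = FALSE)
      }
    }
    dependence <- deps
  }
  structure(list(n_per_block = as.integer(n_per_block),
                 covariate_prevalence = covariate_prevalence,
                 dependence = dependence),
            class = "frame_spec")
}

#' Generate a synthetic sampling frame
#'
#' Draws `n_per_block` subjects per gender block with binary administrative
#' correlates at the prevalences of the spec. With a `dependence` matrix the
#' correlates are thresholded latent Gaussians (copula construction);
#' otherwise independent Bernoullis. Deterministic given the seed.
#'
#' @param spec A [frame_spec()].
#' @param seed Integer seed.
#' @return data.frame with `subject_id`, `block`, and one 0/1 column per
#'   correlate.
#' @export
generate_frame <- function(spec, seed) {
  stopifnot(inherits(spec, "frame_spec"))
  covs <- frame_covariates()
  local_seed(seed, {
    pieces <- lapply(names(spec$covariate_prevalence), function(b) {
      n <- spec$n_per_block
      p <- spec$covariate_prevalence[[b]][covs]
      if (is.null(spec$dependence)) {
        X <- vapply(covs, function(j) stats::rbinom(n, 1L, p[[j]]),
                    integer(n))
      } else {
        R <- spec$dependence[[b]]
        Z <- matrix(stats::rnorm(n * length(covs)), n) %*% chol(R)
        X <- vapply(seq_along(covs),
                    function(j) as.integer(Z[, j] < stats::qnorm(p[[j]])),
                    integer(n))
      }
      colnames(X) <- covs
      data.frame(subject_id = sprintf("%s_%06d", b, seq_len(n)),
                 block = b, X, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

#' Specify latent self-report outcome models
#'
#' One logistic model per outcome: logit P(y = 1 | x) = x'beta, where x is
#' the intercept plus any subset of the administrative correlates. Each beta
#' is a named coefficient vector (names drawn from `"(Intercept)"` and
#' [frame_covariates()]); a coefficient may also be a per-block named list to
#' let the outcome process differ between men and women.
#'
#' @param ... Named coefficient vectors (or per-block lists of them), one per
#'   outcome, e.g. `self_combat = c("(Intercept)" = -0.6, combat_admin = 2)`.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(...) {
  beta <- list(...)
  if (is.null(names(beta)) || any(names(beta) == "")) {
    stop("every outcome model must be named", call. = FALSE)
  }
  for (nm in names(beta)) {
    vecs <- if (is.list(beta[[nm]])) beta[[nm]] else list(beta[[nm]])
    for (v in vecs) {
      if (any(!is.finite(v))) stop("non-finite coefficient in outcome model '",
                                   nm, "'", call. = FALSE)
      check_coef_names(v, c("(Intercept)", frame_covariates()))
    }
  }
  structure(list(beta = beta), class = "outcome_model")
}

#' Specify a response (selection) model
#'
#' The probability of returning the survey is
#' logit P(r = 1 | x, y) = x'alpha + sum_k gamma_k y_k, where x can include
#' an intercept, administrative correlates, and study-arm dummies
#' (`content_sexual_attention`, `content_lifetime`, `source_claims_list`,
#' `incentive_usd40`; the omitted levels are the baselines), and y_k are the
#' latent self-report values. `gamma = 0` makes missingness ignorable (MAR);
#' an intercept-only alpha with `gamma = 0` is MCAR; any nonzero gamma is
#' MNAR by construction.
#'
#' @param alpha Named coefficient vector, or per-block named list of vectors.
#' @param gamma Named vector of coefficients on the latent outcomes (names
#'   matching the outcome model), or a per-block list. Default: no
#'   outcome dependence (ignorable missingness).
#' @return An object of class `response_model`.
#' @export
response_model <- function(alpha, gamma = numeric()) {
  arm_cols <- c("content_sexual_attention", "content_lifetime",
                "source_claims_list", "incentive_usd40")
  vecs <- if (is.list(alpha)) alpha else list(alpha)
  for (v in vecs) {
    if (any(!is.finite(v))) stop("non-finite coefficient in alpha", call. = FALSE)
    check_coef_names(v, c("(Intercept)", frame_covariates(), arm_cols))
  }
  gvecs <- if (is.list(gamma)) gamma else list(gamma)
  for (g in gvecs) {
    if (length(g) && any(!is.finite(g))) {
      stop("non-finite coefficient in gamma", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, gamma = gamma), class = "response_model")
}

check_coef_names <- function(v, allowed) {
  if (length(v) && (is.null(names(v)) || !all(names(v) %in% allowed))) {
    bad <- setdiff(names(v), allowed)
    stop("unknown coefficient name(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  invisible(v)
}

# Resolve a possibly per-block coefficient spec to the vector for one block.
coef_for_block <- function(coef, block) {
  if (is.list(coef)) {
    if (is.null(coef[[block]])) {
      stop("no coefficients specified for block '", block, "'", call. = FALSE)
    }
    coef[[block]]
  } else coef
}

# Design matrix with intercept + correlates (+ arm dummies when an
# assignment is supplied), rows aligned to `frame`.
design_matrix <- function(frame, assignment = NULL) {
  X <- cbind("(Intercept)" = 1, as.matrix(frame[, frame_covariates()]))
  if (!is.null(assignment)) {
    a <- assignment[match(frame$subject_id, assignment$subject_id), ]
    if (anyNA(a$subject_id)) {
      stop("assignment does not cover every frame subject", call. = FALSE)
    }
    X <- cbind(X,
      content_sexual_attention = as.numeric(a$content == "sexual_attention"),
      content_lifetime         = as.numeric(a$content == "lifetime"),
      source_claims_list       = as.numeric(a$source == "claims_list"),
      incentive_usd40          = as.numeric(a$incentive == "usd40"))
  }
  X
}

# x'beta for a named coefficient vector against a named-column matrix.
linear_predictor <- function(X, coef) {
  if (!length(coef)) return(numeric(nrow(X)))
  missing_cols <- setdiff(names(coef), colnames(X))
  if (length(missing_cols)) {
    stop("coefficient names not present in design: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  drop(X[, names(coef), drop = FALSE] %*% coef)
}

#' Simulate latent self-reported outcomes
#'
#' One Bernoulli draw per subject and outcome with probability
#' plogis(x'beta). Latent values exist for every frame member — responders
#' and non-respondents alike — so that estimator recovery can be scored
#' against ground truth.
#'
#' @param frame A sampling frame from [generate_frame()].
#' @param model An [outcome_model()].
#' @param seed Integer seed.
#' @return data.frame with `subject_id` and one 0/1 column per outcome.
#' @export
simulate_self_reports <- function(frame, model, seed) {
  stopifnot(inherits(model, "outcome_model"))
  X <- design_matrix(frame)
  local_seed(seed, {
    out <- data.frame(subject_id = frame$subject_id, stringsAsFactors = FALSE)
    for (nm in names(model$beta)) {
      eta <- numeric(nrow(frame))
      for (b in unique(frame$block)) {
        idx <- frame$block == b
        eta[idx] <- linear_predictor(X[idx, , drop = FALSE],
                                     coef_for_block(model$beta[[nm]], b))
      }
      out[[nm]] <- stats::rbinom(nrow(frame), 1L, stats::plogis(eta))
    }
    out
  })
}

#' Simulate the response process and mask self-reports
#'
#' Draws the returned-survey indicator from the selection model
#' P(r = 1 | x, y) = plogis(x'alpha + sum_k gamma_k y_k) and copies the
#' latent self-reports for responders only; non-respondents' self-reports
#' are `NA`.
#'
#' @param frame Sampling frame.
#' @param assignment Arm assignment from [randomize_blocked()], or `NULL`
#'   when alpha has no arm terms.
#' @param latent Latent outcome table from [simulate_self_reports()].
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @return data.frame `subject_id`, `returned` (0/1), and one column per
#'   outcome (`NA` where `returned == 0`).
#' @export
simulate_response <- function(frame, assignment, latent, model, seed) {
  stopifnot(inherits(model, "response_model"))
  lat <- latent[match(frame$subject_id, latent$subject_id), , drop = FALSE]
  X <- design_matrix(frame, assignment)
  outcomes <- setdiff(names(latent), "subject_id")
  eta <- numeric(nrow(frame))
  for (b in unique(frame$block)) {
    idx <- frame$block == b
    eta[idx] <- linear_predictor(X[idx, , drop = FALSE],
                                 coef_for_block(model$alpha, b))
    g <- coef_for_block(model$gamma, b)
    if (length(g)) {
      check_coef_names(g, outcomes)
      for (k in names(g)) eta[idx] <- eta[idx] + g[[k]] * lat[[k]][idx]
    }
  }
  local_seed(seed, {
    returned <- stats::rbinom(nrow(frame), 1L, stats::plogis(eta))
    out <- data.frame(subject_id = frame$subject_id, returned = returned,
                      stringsAsFactors = FALSE)
    for (k in outcomes) out[[k]] <- ifelse(returned == 1L, lat[[k]], NA_integer_)
    out
  })
}

#' Bundled trial-like simulation scenario
#'
#' A complete scenario emulating the study conditions: two gender blocks of
#' 480 subjects, twelve equal cells of 40 per block, administrative
#' correlates at the frame prevalences of [default_prevalences()], latent
#' self-reported combat and military sexual assault driven by their
#' administrative counterparts, and a nonignorable response process whose
#' marginal response rates match the trial (41.5% men, 44.0% women; claims
#' -list and $40 effects for men, $40 effect for women). Combat survivors
#' respond more and male assault survivors respond less, reproducing the
#' study's MNAR signature.
#'
#' @return A list with `frame_spec`, `outcome_model`, `response_model`, and
#'   `outcomes`, consumable by [simulate_cohort()] and [run_pipeline()].
#' @export
trial_scenario <- function() {
  list(
    frame_spec = frame_spec(),
    outcome_model = outcome_model(
      self_combat = c("(Intercept)" = stats::qlogis(0.35), combat_admin = 2.0),
      self_msa    = c("(Intercept)" = stats::qlogis(0.18), mst_admin = 3.0)
    ),
    response_model = response_model(
      alpha = list(
        men = c("(Intercept)" = -1.4442, age_lt30 = -0.40, any_benefits = 0.50,
                smi = 0.30, source_claims_list = 0.40, incentive_usd40 = 0.47,
                content_lifetime = -0.15),
        women = c("(Intercept)" = -0.8218, smi = 0.50, ptsd_benefits = 0.40,
                  combat_admin = 0.30, nonwhite = -0.30,
                  content_sexual_attention = 0.20, incentive_usd40 = 0.39)
      ),
      gamma = list(
        men = c(self_combat = 0.90, self_msa = -1.20),
        women = c(self_combat = 0.35, self_msa = -0.10)
      )
    ),
    outcomes = c("self_combat", "self_msa")
  )
}

#' Simulate a full cohort from a scenario
#'
#' Convenience wrapper running frame generation, blocked randomization,
#' latent outcome simulation, and the response process with sub-seeds derived
#' deterministically from one master seed.
#'
#' @param scenario A scenario list as returned by [trial_scenario()].
#' @param seed Master integer seed.
#' @return List with `frame`, `assignment`, `latent`, `responses`, and the
#'   `seeds` actually used for each stage.
#' @export
simulate_cohort <- function(scenario, seed) {
  seeds <- derive_seeds(seed, c("frame", "design", "outcomes", "response"))
  frame <- generate_frame(scenario$frame_spec, seeds[["frame"]])
  assignment <- randomize_blocked(frame, seed = seeds[["design"]])
  latent <- simulate_self_reports(frame, scenario$outcome_model,
                                  seeds[["outcomes"]])
  responses <- simulate_response(frame, assignment, latent,
                                 scenario$response_model, seeds[["response"]])
  list(frame = frame, assignment = assignment, latent = latent,
       responses = responses, seeds = seeds)
}

# Deterministic stage sub-seeds from one master seed, kept within 32-bit
# integer range.
derive_seeds <- function(seed, stages) {
  base <- as.integer(seed) %% 1000000000L
  stats::setNames(base + 1009L * seq_along(stages), stages)
}
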