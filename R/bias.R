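# Non-response bias metrics, the factorial variance partition (eta squared
# with interaction-df pooling), and Cohen's h.

#' Non-response bias in percentage points
#'
#' Bias is the prevalence of a characteristic among survey respondents minus
#' its prevalence in the full sampling frame. Negative values mean the
#' characteristic is under-represented in the respondent pool; positive,
#' over-represented; zero, no bias.
#'
#' @param respondent_pct,frame_pct Percentages in \[0, 100\] (vectorized).
#' @return Signed percentage points in \[-100, 100\].
#' @examples
#' compute_bias(86.9, 81.9) # +5.0
#' @export
compute_bias <- function(respondent_pct, frame_pct) {
  if (any(respondent_pct < 0 | respondent_pct > 100, na.rm = TRUE) ||
      any(frame_pct < 0 | frame_pct > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  respondent_pct - frame_pct
}

#' Per-correlate bias overall and by study-arm manipulation
#'
#' For one administrative correlate and gender block, computes the bias among
#' respondents assigned to each level of the three manipulations (7 strata:
#' 3 content + 2 source + 2 incentive) plus overall. The reference is always
#' the full block's frame prevalence, so a manipulation that recruits a
#' representative pool scores near zero.
#'
#' @param frame Sampling frame (must contain the correlate column, `block`).
#' @param assignment Arm assignment table.
#' @param responses Response table with `returned`.
#' @param correlate Name of the binary frame column to analyse.
#' @param block Gender block to analyse (default: every block present).
#' @return data.frame with `block`, `stratum`, `n_respondents`,
#'   `respondent_pct`, `frame_pct`, `bias_pp`, `undefined` (TRUE when a
#'   stratum has no respondents — its bias is `NA`, never silently 0).
#' @export
bias_by_arm <- function(frame, assignment, responses, correlate,
                        block = unique(frame$block)) {
  stopifnot(correlate %in% names(frame))
  d <- merge(merge(frame[, c("subject_id", "block", correlate)],
                   assignment[, c("subject_id", "content", "source",
                                  "incentive")], by = "subject_id"),
             responses[, c("subject_id", "returned")], by = "subject_id")
  lv <- factor_levels()
  out <- lapply(block, function(b) {
    db <- d[d$block == b, ]
    frame_pct <- 100 * mean(db[[correlate]])
    strata <- c(list(overall = rep(TRUE, nrow(db))),
                stats::setNames(lapply(lv$content, function(l) db$content == l),
                                lv$content),
                stats::setNames(lapply(lv$source, function(l) db$source == l),
                                lv$source),
                stats::setNames(lapply(lv$incentive,
                                       function(l) db$incentive == l),
                                lv$incentive))
    rows <- lapply(names(strata), function(s) {
      resp <- db[strata[[s]] & db$returned == 1L, ]
      n <- nrow(resp)
      rpct <- if (n > 0) 100 * mean(resp[[correlate]]) else NA_real_
      data.frame(block = b, stratum = s, n_respondents = n,
                 respondent_pct = rpct, frame_pct = frame_pct,
                 bias_pp = if (n > 0) compute_bias(rpct, frame_pct)
                           else NA_real_,
                 undefined = n == 0, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (any(out$undefined)) {
    warning("empty respondent stratum: bias undefined for ",
            paste(out$stratum[out$undefined], collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Factorial ANOVA variance partition with interaction-df pooling
#'
#' Fits an ANOVA of `y` on the supplied factors including all interactions,
#' then pools non-significant interactions into error, highest order first:
#' the top-order interaction is tested and dropped if p >= `pool_alpha`, then
#' each next-order interaction is tested in the reduced model and the
#' non-significant ones are dropped together. Eta squared for each factor is
#' 100 * SS_factor / SS_total, with sequential (type I) sums of squares in
#' the order the factors are given.
#'
#' @param y Numeric response vector.
#' @param factors data.frame of factors (columns in the canonical testing
#'   order).
#' @param pool_alpha Pooling threshold; interactions with p >= this are added
#'   to the error term. Default 0.05.
#' @return An object of class `anova_partition`: list with `terms` (term,
#'   df, ss, f, p), `ss_error`, `df_error`, `ss_total`, `eta2_percent`
#'   (named, main factors only), and `pooled` (dropped interaction terms).
#' @export
anova_eta2 <- function(y, factors, pool_alpha = 0.05) {
  stopifnot(is.numeric(y), is.data.frame(factors), nrow(factors) == length(y))
  fnames <- names(factors)
  dat <- data.frame(.y = y, lapply(factors, factor))
  ss_total <- sum((y - mean(y))^2)
  if (ss_total < 1e-12) {
    # degenerate: response constant across respondents; nothing to partition
    return(structure(list(
      terms = data.frame(term = fnames, df = NA_integer_, ss = 0,
                         f = NA_real_, p = NA_real_, stringsAsFactors = FALSE),
      ss_error = 0, df_error = length(y) - 1L, ss_total = 0,
      eta2_percent = stats::setNames(rep(0, length(fnames)), fnames),
      pooled = character()), class = "anova_partition"))
  }
  term_order <- function(t) length(strsplit(t, ":", fixed = TRUE)[[1]])
  all_int <- character()
  if (length(fnames) >= 2) {
    for (k in length(fnames):2) {
      all_int <- c(all_int,
                   apply(utils::combn(fnames, k), 2, paste, collapse = ":"))
    }
  }
  keep_int <- all_int
  pooled <- character()
  repeat {
    rhs <- paste(c(fnames, keep_int), collapse = " + ")
    fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = dat)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    if (!length(keep_int)) break
    top <- max(vapply(keep_int, term_order, integer(1)))
    cand <- keep_int[vapply(keep_int, term_order, integer(1)) == top]
    pvals <- tab[match(cand, terms), "Pr(>F)"]
    drop <- cand[is.na(pvals) | pvals >= pool_alpha]
    if (!length(drop)) break
    pooled <- c(pooled, drop)
    keep_int <- setdiff(keep_int, drop)
    lower <- keep_int[vapply(keep_int, term_order, integer(1)) < top]
    # if the whole top order is gone, continue testing the next order down;
    # otherwise the retained higher-order term protects its margins
    if (length(cand) == length(drop) && length(lower)) next
    # refit once more so the final table excludes the dropped terms
    rhs <- paste(c(fnames, keep_int), collapse = " + ")
    fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = dat)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    break
  }
  res_row <- terms == "Residuals"
  tt <- data.frame(term = terms[!res_row], df = tab[!res_row, "Df"],
                   ss = tab[!res_row, "Sum Sq"], f = tab[!res_row, "F value"],
                   p = tab[!res_row, "Pr(>F)"], stringsAsFactors = FALSE)
  eta2 <- stats::setNames(100 * tt$ss[match(fnames, tt$term)] / ss_total,
                          fnames)
  structure(list(terms = tt, ss_error = tab[res_row, "Sum Sq"],
                 df_error = tab[res_row, "Df"], ss_total = ss_total,
                 eta2_percent = eta2, pooled = pooled),
            class = "anova_partition")
}

#' @export
print.anova_partition <- function(x, ...) {
  cat("ANOVA variance partition (sequential SS)\n")
  print(x$terms, row.names = FALSE)
  cat(sprintf("Error: SS = %.4g on %d df; total SS = %.4g\n",
              x$ss_error, x$df_error, x$ss_total))
  if (length(x$pooled)) {
    cat("Pooled into error:", paste(x$pooled, collapse = ", "), "\n")
  }
  cat("eta^2 (%):",
      paste(sprintf("%s = %.1f", names(x$eta2_percent), x$eta2_percent),
            collapse = ", "), "\n")
  invisible(x)
}

#' Three-factor ANOVA of non-response bias for one correlate
#'
#' The unit of analysis is the respondent-level frame-centered indicator:
#' the binary correlate minus the block's frame prevalence, so that each
#' cell's mean equals its bias and the SS partition decomposes the variance
#' in bias across the content, source and incentive manipulations.
#' Interactions are pooled into error when non-significant (see
#' [anova_eta2()]).
#'
#' @inheritParams bias_by_arm
#' @param block Single gender block to analyse.
#' @param pool_alpha Interaction pooling threshold (default 0.05).
#' @return An `anova_partition` (see [anova_eta2()]).
#' @export
factorial_anova_eta2 <- function(frame, assignment, responses, correlate,
                                 block, pool_alpha = 0.05) {
  stopifnot(correlate %in% names(frame), length(block) == 1L)
  d <- merge(merge(frame[, c("subject_id", "block", correlate)],
                   assignment[, c("subject_id", "content", "source",
                                  "incentive", "cell")], by = "subject_id"),
             responses[, c("subject_id", "returned")], by = "subject_id")
  db <- d[d$block == block, ]
  if (!nrow(db)) stop("no subjects in block '", block, "'", call. = FALSE)
  frame_prev <- mean(db[[correlate]])
  resp <- db[db$returned == 1L, ]
  empty <- setdiff(build_design()$cell, unique(resp$cell))
  if (length(empty)) {
    stop("no respondents in cell(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  y <- resp[[correlate]] - frame_prev
  anova_eta2(y, resp[, c("content", "source", "incentive")],
             pool_alpha = pool_alpha)
}

#' Cohen's h effect size for two proportions
#'
#' \eqn{h = |2 \arcsin\sqrt{p_1} - 2 \arcsin\sqrt{p_2}|}. Around 0.2 is
#' conventionally small, 0.5 medium.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return Nonnegative effect size (at most pi).
#' @examples
#' cohen_h(0.5, 0.62)
#' @export
cohen_h <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
}
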