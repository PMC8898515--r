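# AAPOR RR1 response rates by arm and margin, with omnibus homogeneity tests.

#' AAPOR response rate 1
#'
#' Returned completed surveys divided by all units assigned to the condition,
#' as a percentage. Values are carried at full precision; round only when
#' rendering tables.
#'
#' @param returned Number of returned surveys (vectorized).
#' @param assigned Number of subjects assigned to the condition.
#' @return Percentage(s) in \[0, 100\].
#' @examples
#' response_rate_rr1(199, 480) # men overall, 41.5%
#' @export
response_rate_rr1 <- function(returned, assigned) {
  if (any(assigned <= 0)) {
    stop("undefined rate: assigned must be positive", call. = FALSE)
  }
  if (any(returned < 0) || any(returned > assigned)) {
    stop("returned must lie in [0, assigned]", call. = FALSE)
  }
  100 * returned / assigned
}

#' Omnibus chi-square test of response-rate homogeneity
#'
#' Pearson chi-square on the strata x (returned, not returned) contingency
#' table, df = strata - 1. No continuity correction by default (the `correct`
#' flag exposes it); no multiple-testing adjustment.
#'
#' @param counts data.frame with columns `returned` and `assigned` (one row
#'   per stratum), or a matrix with columns returned / not-returned.
#' @param correct Apply Yates continuity correction (2x2 only)? Default
#'   `FALSE`.
#' @return List with `statistic`, `df`, `p`.
#' @export
omnibus_chi_square <- function(counts, correct = FALSE) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("returned", "assigned") %in% names(counts)))
    tab <- cbind(returned = counts$returned,
                 not_returned = counts$assigned - counts$returned)
  } else {
    tab <- as.matrix(counts)
  }
  if (nrow(tab) < 2) stop("need at least two strata", call. = FALSE)
  if (any(rowSums(tab) <= 0)) {
    stop("every stratum must have assigned > 0", call. = FALSE)
  }
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Response rates by block and study-arm manipulation
#'
#' Builds the per-block response-rate table: overall, each level of the three
#' manipulations, and each of the 12 factorial cells, with the per-margin and
#' omnibus 12-cell Pearson chi-square p-values.
#'
#' @param assignment Arm assignment table.
#' @param responses Response table (needs `subject_id`, `returned`).
#' @param correct Continuity correction flag passed to
#'   [omnibus_chi_square()].
#' @return data.frame with columns `block`, `margin` (`overall`, `content`,
#'   `source`, `incentive`, or `cell`), `stratum`, `assigned`, `returned`,
#'   `rate_pct`, `p_margin` (repeated within margin; `NA` for overall).
#' @export
response_rate_table <- function(assignment, responses, correct = FALSE) {
  d <- merge(assignment, responses[, c("subject_id", "returned")],
             by = "subject_id")
  if (nrow(d) != nrow(assignment)) {
    stop("responses do not cover every assigned subject", call. = FALSE)
  }
  one_block <- function(db, block) {
    strata_of <- function(margin, values) {
      agg <- stats::aggregate(db$returned, by = list(stratum = values),
                              FUN = function(r) c(sum(r), length(r)))
      cnt <- data.frame(stratum = as.character(agg$stratum),
                        returned = agg$x[, 1], assigned = agg$x[, 2],
                        stringsAsFactors = FALSE)
      p <- if (nrow(cnt) > 1) omnibus_chi_square(cnt, correct = correct)$p
           else NA_real_
      data.frame(block = block, margin = margin, cnt,
                 rate_pct = response_rate_rr1(cnt$returned, cnt$assigned),
                 p_margin = p, stringsAsFactors = FALSE)
    }
    rbind(
      data.frame(block = block, margin = "overall", stratum = "overall",
                 returned = sum(db$returned), assigned = nrow(db),
                 rate_pct = response_rate_rr1(sum(db$returned), nrow(db)),
                 p_margin = NA_real_, stringsAsFactors = FALSE),
      strata_of("content", db$content),
      strata_of("source", db$source),
      strata_of("incentive", db$incentive),
      strata_of("cell", db$cell)
    )
  }
  out <- do.call(rbind, lapply(unique(d$block),
                               function(b) one_block(d[d$block == b, ], b)))
  rownames(out) <- NULL
  out
}
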