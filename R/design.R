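# Factor structure and blocked randomization for the 3x2x2 mailed-survey trial.

#' Factor levels of the 3x2x2 design
#'
#' The trial crossed three cover-letter manipulations: what invitees were told
#' about the survey's content (combat, unwanted sexual attention, or lifetime
#' and military experiences), how their name was said to have been obtained
#' (a roster of recent-era Veterans or a list of disability-benefit
#' applicants), and the promised post-paid incentive ($20 or $40).
#'
#' @return Named list of character vectors giving the levels of each factor,
#'   in canonical order.
#' @export
factor_levels <- function() {
  list(
    content   = c("combat", "sexual_attention", "lifetime"),
    source    = c("oef_list", "claims_list"),
    incentive = c("usd20", "usd40")
  )
}

#' Enumerate the 12 cells of the factorial design
#'
#' Returns every content x source x incentive combination exactly once, in
#' canonical order: content varies slowest, then source, then incentive
#' (row-major over `factor_levels()`).
#'
#' @return A data.frame with 12 rows and columns `content`, `source`,
#'   `incentive`, and `cell` (the stable string key, see [cell_key()]).
#' @examples
#' build_design()
#' @export
build_design <- function() {
  lv <- factor_levels()
  grid <- expand.grid(
    incentive = lv$incentive,
    source    = lv$source,
    content   = lv$content,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  out <- grid[, c("content", "source", "incentive")]
  out$cell <- cell_key(out$content, out$source, out$incentive)
  rownames(out) <- NULL
  out
}

#' Serialize factor levels to a stable cell key
#'
#' @param content,source,incentive Character vectors of factor levels
#'   (recycled to a common length).
#' @return Character vector of keys of the form
#'   `"combat:oef_list:usd20"`.
#' @seealso [parse_cell_key()]
#' @export
cell_key <- function(content, source, incentive) {
  lv <- factor_levels()
  stopifnot(all(content %in% lv$content), all(source %in% lv$source),
            all(incentive %in% lv$incentive))
  paste(content, source, incentive, sep = ":")
}

#' Parse a cell key back into factor levels
#'
#' @param key Character vector of keys produced by [cell_key()].
#' @return data.frame with columns `content`, `source`, `incentive`.
#' @export
parse_cell_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed cell key: expected 'content:source:incentive'", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(content = m[, 1], source = m[, 2], incentive = m[, 3],
                    stringsAsFactors = FALSE)
  lv <- factor_levels()
  if (!all(out$content %in% lv$content) || !all(out$source %in% lv$source) ||
      !all(out$incentive %in% lv$incentive)) {
    stop("cell key contains an unknown factor level", call. = FALSE)
  }
  out
}

#' Gender-blocked equal-cell randomization
#'
#' Within each gender block, subjects are shuffled with a seeded uniform
#' permutation and chunked into 12 consecutive equal-sized groups; group j is
#' assigned to the j-th cell of [build_design()] (canonical order). The same
#' seed always yields the same plan.
#'
#' @param subjects A sampling-frame data.frame with at least `subject_id` and
#'   `block` columns (blocks are typically `"men"` and `"women"`).
#' @param cells_per_block Number of cells each block is split into; must
#'   divide every block size exactly. Default 12, the full factorial.
#' @param seed Integer seed for the permutation.
#' @return data.frame with columns `subject_id`, `block`, `content`,
#'   `source`, `incentive`, `cell`, one row per subject.
#' @examples
#' frame <- data.frame(subject_id = sprintf("S%03d", 1:24),
#'                     block = rep(c("men", "women"), each = 12))
#' plan <- randomize_blocked(frame, seed = 1)
#' table(plan$block, plan$cell)
#' @export
randomize_blocked <- function(subjects, cells_per_block = 12L, seed) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "block") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in sampling frame", call. = FALSE)
  }
  design <- build_design()
  if (cells_per_block != nrow(design)) {
    stop("cells_per_block must equal the number of design cells (12)",
         call. = FALSE)
  }
  blocks <- unique(subjects$block)
  sizes <- table(subjects$block)
  bad <- names(sizes)[as.integer(sizes) %% cells_per_block != 0L]
  if (length(bad)) {
    stop("invalid design: block size not divisible by ", cells_per_block,
         " for block(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- local_seed(seed, {
    pieces <- lapply(blocks, function(b) {
      ids <- subjects$subject_id[subjects$block == b]
      ids <- ids[sample.int(length(ids))]
      g <- length(ids) %/% cells_per_block
      cell_idx <- rep(seq_len(cells_per_block), each = g)
      data.frame(subject_id = ids, block = b,
                 design[cell_idx, c("content", "source", "incentive", "cell")],
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
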