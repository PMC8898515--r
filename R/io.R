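# Delimited-text I/O for the three pipeline tables. Round-trips are lossless,
# including the missing-value sentinel for masked self-reports.

#' Read the frame / assignment / response tables
#'
#' Tab-delimited text with a header row. Missing self-reports are encoded by
#' an explicit sentinel (default `"NA"`); any other unparseable value is a
#' schema error naming the offending column. Binary columns must be 0/1.
#'
#' @param frame,assignment,responses File paths (any subset may be `NULL`).
#' @param sentinel Missing-value sentinel string.
#' @return Named list with the tables that were requested.
#' @export
read_tables <- function(frame = NULL, assignment = NULL, responses = NULL,
                        sentinel = "NA") {
  out <- list()
  if (!is.null(frame)) {
    out$frame <- read_checked(frame, sentinel,
      character_cols = c("subject_id", "block"),
      binary_cols = frame_covariates(), allow_na = character())
  }
  if (!is.null(assignment)) {
    a <- read_checked(assignment, sentinel,
      character_cols = c("subject_id", "block", "content", "source",
                         "incentive"),
      binary_cols = character(), allow_na = character())
    lv <- factor_levels()
    for (col in names(lv)) {
      bad <- setdiff(unique(a[[col]]), lv[[col]])
      if (length(bad)) {
        stop("schema error in column '", col, "': unknown level(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    if (!"cell" %in% names(a)) {
      a$cell <- cell_key(a$content, a$source, a$incentive)
    }
    out$assignment <- a
  }
  if (!is.null(responses)) {
    hdr <- names(utils::read.delim(responses, nrows = 1,
                                   check.names = FALSE))
    outcome_cols <- setdiff(hdr, c("subject_id", "returned"))
    resp <- read_checked(responses, sentinel,
      character_cols = "subject_id",
      binary_cols = c("returned", outcome_cols), allow_na = outcome_cols)
    mism <- outcome_cols[vapply(outcome_cols, function(k) {
      any(resp$returned == 0L & !is.na(resp[[k]])) ||
        any(resp$returned == 1L & is.na(resp[[k]]))
    }, logical(1))]
    if (length(mism)) {
      stop("schema error in column '", mism[1],
           "': self-reports must be observed exactly when returned = 1",
           call. = FALSE)
    }
    out$responses <- resp
  }
  out
}

read_checked <- function(path, sentinel, character_cols, binary_cols,
                         allow_na) {
  d <- utils::read.delim(path, colClasses = "character",
                         na.strings = sentinel, check.names = FALSE)
  need <- c(character_cols, binary_cols)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (col in character_cols) {
    if (anyNA(d[[col]])) {
      stop("schema error in column '", col, "': missing values not allowed",
           call. = FALSE)
    }
  }
  for (col in binary_cols) {
    v <- d[[col]]
    ok_na <- col %in% allow_na
    if (!ok_na && anyNA(v)) {
      stop("schema error in column '", col, "': missing values not allowed",
           call. = FALSE)
    }
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (any(bad)) {
      stop("schema error in column '", col, "': non-binary value '",
           v[bad][1], "'", call. = FALSE)
    }
    d[[col]] <- as.integer(v)
  }
  d
}

#' Write pipeline tables as delimited text
#'
#' Each element of `bundle` that is a data.frame is written to
#' `<dir>/<name>.tsv` (tab-delimited, header, sentinel for `NA`). The
#' write/read round trip through [read_tables()] is lossless.
#'
#' @param bundle Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @param sentinel Missing-value sentinel.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(bundle, dir, sentinel = "NA") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(bundle)) {
    if (!is.data.frame(bundle[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = sentinel)
    paths <- c(paths, p)
  }
  invisible(paths)
}
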