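# CSV readers/writers. Checklist files are wide 0/1 tables
# (drawing_id,a,...,q); rating files are wide drawings x raters integer
# tables. Malformed cells are reported with their row and column.

#' Read a checklist CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `drawing_id,a,b,...,q` and one row per drawing, item cells in `{0,1}`.
#'
#' @param path file path.
#' @return Checklist data frame (`drawing_id` plus 17 logical columns); an
#'   empty data frame (with a warning) if the file holds only the header.
#' @export
read_checklists <- function(path) {
  df <- read_csv_checked(path)
  need <- c("drawing_id", CDT_ITEMS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("checklist file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  if (nrow(df) == 0L) {
    warning("checklist file ", path, " contains a header but no rows")
    df[CDT_ITEMS] <- lapply(df[CDT_ITEMS], as.logical)
    return(df)
  }
  for (col in CDT_ITEMS) {
    v <- df[[col]]
    bad <- which(!(v %in% c("0", "1", 0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary cell in %s: row %d, column '%s' (value '%s')",
                   path, bad[1L], col, v[bad[1L]]), call. = FALSE)
    }
    df[[col]] <- as.integer(v) == 1L
  }
  df$drawing_id <- as.character(df$drawing_id)
  dup <- df$drawing_id[duplicated(df$drawing_id)]
  if (length(dup) > 0L) {
    stop("duplicate drawing_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a checklist CSV
#'
#' Items are written as `{0,1}`; [read_checklists()] inverts this losslessly.
#'
#' @param x checklist data frame.
#' @param path output file path.
#' @export
write_checklists <- function(x, path) {
  m <- checklist_matrix(x)
  out <- data.frame(drawing_id = checklist_ids(x, nrow(m)),
                    stringsAsFactors = FALSE)
  out[CDT_ITEMS] <- as.data.frame(m + 0L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide rating CSV into a rating matrix
#'
#' Header is `drawing_id,<rater_1>,...,<rater_k>`; cells are integer scores
#' 1-10, no missing values, at least two raters and two drawings.
#'
#' @param path file path.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path) {
  df <- read_csv_checked(path)
  if (!"drawing_id" %in% names(df)) {
    stop("rating file ", path, " has no drawing_id column", call. = FALSE)
  }
  raters <- setdiff(names(df), "drawing_id")
  if (length(raters) < 2L) {
    stop("rating file ", path, " needs >= 2 rater columns", call. = FALSE)
  }
  s <- matrix(NA_integer_, nrow(df), length(raters))
  for (j in seq_along(raters)) {
    v <- suppressWarnings(as.numeric(df[[raters[j]]]))
    bad <- which(is.na(v) | v != as.integer(v) | v < 1 | v > 10)
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid score in %s: row %d, column '%s' (value '%s'); scores must be integers 1-10",
        path, bad[1L], raters[j], df[[raters[j]]][bad[1L]]), call. = FALSE)
    }
    s[, j] <- as.integer(v)
  }
  rating_matrix(s, drawing_ids = as.character(df$drawing_id),
                rater_ids = raters)
}

#' Write a rating matrix as a wide CSV
#'
#' @param x a [rating_matrix()].
#' @param path output file path.
#' @export
write_ratings <- function(x, path) {
  stopifnot(inherits(x, "rating_matrix"))
  out <- data.frame(drawing_id = x$drawing_ids, stringsAsFactors = FALSE)
  out[x$rater_ids] <- as.data.frame(x$scores)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write score results to CSV
#'
#' @param x score data frame from [score_checklist()].
#' @param path output file path.
#' @param full also write description and flags columns (default writes
#'   `drawing_id,score,rule_id,band`).
#' @export
write_scores <- function(x, path, full = FALSE) {
  cols <- c("drawing_id", "score", "rule_id", "band")
  if (full) cols <- c(cols, "description", "flags")
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = full)
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  df
}
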