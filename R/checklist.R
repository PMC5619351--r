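#' @keywords internal
"_PACKAGE"

# The 17 binary checklist items, in scale order. `a` is treated as the most
# significant bit wherever profiles are indexed numerically.
CDT_ITEMS <- letters[1:17]

CDT_ITEM_LABELS <- c(
  a = "circle present",
  b = "12 numbers present",
  c = "numbers inside the clock limit",
  d = "numbers in correct ascending order",
  e = "numbers in correct spatial position",
  f = "straight vertical line 12-6 possible",
  g = "straight horizontal line 3-9 possible",
  h = "numbers not concentrated in one part",
  i = "two hands present",
  j = "hour hand present",
  k = "minute hand present",
  l = "minute hand proportionally larger",
  m = "a hand between 2 and 3",
  n = "a hand exactly on 9",
  o = "wrong use of hands (digital/circled)",
  p = "only vague evidence of a clock",
  q = "no attempt / not a clock"
)

#' Construct a checklist data frame
#'
#' A checklist records, for one clock drawing, which of the 17 binary feature
#' items (`a`--`q`) the examiner marked. This constructor builds a one-row
#' checklist from the set of marked item letters.
#'
#' @param marked character vector of item letters in `a`--`q` that are marked.
#' @param drawing_id identifier for the drawing.
#' @return A one-row data frame with a `drawing_id` column and 17 logical
#'   columns `a`..`q`.
#' @examples
#' checklist(setdiff(letters[1:14], "l"))  # perfect clock except hand size
#' @export
checklist <- function(marked = character(), drawing_id = "drawing_1") {
  marked <- as.character(marked)
  bad <- setdiff(marked, CDT_ITEMS)
  if (length(bad) > 0L) {
    stop("unknown checklist item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  row <- as.data.frame(as.list(stats::setNames(CDT_ITEMS %in% marked,
                                               CDT_ITEMS)))
  cbind(data.frame(drawing_id = as.character(drawing_id),
                   stringsAsFactors = FALSE), row)
}

# Coerce a checklist data frame (or bare item matrix) to an n x 17 logical
# matrix with columns a..q; errors name any missing or non-binary column.
checklist_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 17L) stop("item matrix must have 17 columns", call. = FALSE)
    m <- x
    colnames(m) <- CDT_ITEMS
  } else {
    if (!is.data.frame(x)) {
      stop("expected a checklist data frame or logical matrix", call. = FALSE)
    }
    missing_cols <- setdiff(CDT_ITEMS, names(x))
    if (length(missing_cols) > 0L) {
      stop("checklist is missing item column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(x[, CDT_ITEMS])
  }
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1))) {
      stop("checklist items must be logical or 0/1", call. = FALSE)
    }
    m <- m == 1
  }
  if (!is.logical(m)) stop("checklist items must be logical or 0/1",
                           call. = FALSE)
  if (anyNA(m)) stop("checklist contains missing item values", call. = FALSE)
  m
}

checklist_ids <- function(x, n) {
  if (is.data.frame(x) && "drawing_id" %in% names(x)) {
    as.character(x$drawing_id)
  } else {
    sprintf("profile_%06d", seq_len(n) - 1L)
  }
}

# Consistency rules: each row is (code, message, violating-rows predicate).
# The rules encode the logical closure of the item semantics; the scale itself
# never constrains item combinations, so by default they are warnings.
checklist_rules <- function(m) {
  list(
    Q_EXCLUSIVE = list(
      message = "q (no attempt) marked together with other items",
      bad = m[, "q"] & rowSums(m[, setdiff(CDT_ITEMS, "q"), drop = FALSE]) > 0
    ),
    P_MINIMAL = list(
      message = "p (vague clock only) marked together with items b-n",
      bad = m[, "p"] & rowSums(m[, letters[2:14], drop = FALSE]) > 0
    ),
    O_EXCLUSIVE = list(
      message = "o (wrong hand use) marked together with p or q",
      bad = m[, "o"] & (m[, "p"] | m[, "q"])
    ),
    TWO_HANDS = list(
      message = "i (two hands) marked but hour or minute hand unmarked",
      bad = m[, "i"] & !(m[, "j"] & m[, "k"])
    ),
    MINUTE_LARGER = list(
      message = "l (minute hand larger) marked but hour or minute hand unmarked",
      bad = m[, "l"] & !(m[, "j"] & m[, "k"])
    ),
    HAND_POSITION = list(
      message = "m or n (hand position) marked but no hand item i/j/k marked",
      bad = (m[, "m"] | m[, "n"]) & !(m[, "i"] | m[, "j"] | m[, "k"])
    )
  )
}

#' Validate checklist consistency
#'
#' Applies an implication rule set derived from the item semantics: a "no
#' attempt" drawing cannot also show features; a "vague clock" cannot carry
#' number/hand detail; hand-quality items require the hands they describe. In
#' `lenient` mode (the default elsewhere in the package) violations are
#' reported as warnings and scoring proceeds; in `strict` mode any violation
#' marks the row invalid.
#'
#' @param x checklist data frame (one or more rows) as built by [checklist()]
#'   or read by [read_checklists()].
#' @param mode `"strict"` or `"lenient"`.
#' @return An object of class `cdt_validation`: list with `valid` (logical per
#'   row), `violations` (data frame `row`, `drawing_id`, `rule`, `message`,
#'   `severity`) and `mode`.
#' @export
validate_checklist <- function(x, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  m <- checklist_matrix(x)
  ids <- checklist_ids(x, nrow(m))
  rules <- checklist_rules(m)
  viol <- do.call(rbind, lapply(names(rules), function(code) {
    bad <- which(rules[[code]]$bad)
    if (length(bad) == 0L) return(NULL)
    data.frame(row = bad, drawing_id = ids[bad], rule = code,
               message = rules[[code]]$message,
               severity = if (mode == "strict") "error" else "warning",
               stringsAsFactors = FALSE)
  }))
  if (is.null(viol)) {
    viol <- data.frame(row = integer(), drawing_id = character(),
                       rule = character(), message = character(),
                       severity = character(), stringsAsFactors = FALSE)
  }
  valid <- rep(TRUE, nrow(m))
  if (mode == "strict") valid[unique(viol$row)] <- FALSE
  structure(list(valid = valid, violations = viol, mode = mode),
            class = "cdt_validation")
}

#' @export
print.cdt_validation <- function(x, ...) {
  cat("Checklist validation (", x$mode, " mode): ",
      sum(x$valid), "/", length(x$valid), " rows valid\n", sep = "")
  if (nrow(x$violations) > 0L) {
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

# Strict-consistency mask for a bare item matrix (vectorised; used for
# preimage restriction over all 2^17 profiles).
strict_valid_mask <- function(m) {
  rules <- checklist_rules(m)
  ok <- !rules[[1L]]$bad
  for (r in rules[-1L]) ok <- ok & !r$bad
  ok
}

#' Enumerate every possible checklist profile
#'
#' Yields all \eqn{2^{17} = 131072} item combinations exactly once, in binary
#' counting order with item `a` as the most significant bit: row 1 is the
#' all-unmarked profile, row 131072 the all-marked one. Row `i` therefore
#' corresponds to profile index `i - 1`.
#'
#' @return A 131072 x 17 logical matrix with columns `a`..`q`.
#' @seealso [profile_index()], [profiles_from_index()]
#' @export
enumerate_profiles <- function() {
  n <- 2L^17L
  profiles_from_index(seq_len(n) - 1L)
}

#' Convert between profiles and profile indices
#'
#' A profile index is the integer in `0:131071` whose 17-bit binary expansion,
#' with item `a` as the most significant bit, gives the marked items.
#'
#' @param idx integer vector of profile indices in `0:131071`.
#' @return `profiles_from_index`: logical matrix with one row per index;
#'   `profile_index`: integer vector of indices.
#' @export
profiles_from_index <- function(idx) {
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 0L | idx > 131071L)) {
    stop("profile indices must lie in 0:131071", call. = FALSE)
  }
  m <- matrix(FALSE, length(idx), 17L, dimnames = list(NULL, CDT_ITEMS))
  for (j in seq_len(17L)) {
    m[, j] <- bitwAnd(idx, bitwShiftL(1L, 17L - j)) != 0L
  }
  m
}

#' @param x checklist data frame or logical item matrix.
#' @rdname profiles_from_index
#' @export
profile_index <- function(x) {
  m <- checklist_matrix(x)
  as.integer(m %*% 2L^(16:0))
}
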