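# Verbatim descriptions of the original 10-point Sunderland scale, indexed by
# score. 10-6: clock face generally intact; 5-1: not intact.
SUNDERLAND_DESCRIPTIONS <- c(
  "Either no attempt or an uninterpretable effort is made.",
  "Drawing reveals some evidence of instructions being received but only a vague representation of a clock.",
  "Numbers and clock face no longer obviously connected in drawing. Hands are not present.",
  "Further distortion of number sequence. Integrity of clock face is now gone (i.e., numbers missing or placed at outside of the boundaries of the clock face).",
  "Crowding of numbers at one end of the clock or reversal of numbers. Hands may still be present in some fashion.",
  "Inappropriate use of clock hands (i.e., use of digital display or circling of numbers despite repeated instructions).",
  "Placement of hands is significantly off course.",
  "More noticeable errors in placement of hour and minute hands.",
  "Slight errors in placement of hands.",
  "Hands are in correct position."
)

#' Band of a Sunderland score
#'
#' The 10-point scale splits into two bands: scores 10-6 mean the clock face
#' with circle and numbers is generally intact, scores 5-1 that it is not.
#'
#' @param score integer vector of scores in 1-10.
#' @return character vector, `"intact"` (score >= 6) or `"not_intact"`.
#' @export
band_of <- function(score) {
  score <- check_score_range(score)
  ifelse(score >= 6L, "intact", "not_intact")
}

#' Original Sunderland description for a score
#'
#' @param score integer vector of scores in 1-10.
#' @return character vector with the original scale's description of each
#'   score.
#' @export
sunderland_description <- function(score) {
  score <- check_score_range(score)
  SUNDERLAND_DESCRIPTIONS[score]
}

check_score_range <- function(score) {
  s <- suppressWarnings(as.integer(score))
  if (length(s) == 0L || anyNA(s) || any(s != score) || any(s < 1L | s > 10L)) {
    stop("scores must be integers in 1:10", call. = FALSE)
  }
  s
}

# Vectorised decision core. First-match rule order:
#   O (wrong hand use) -> 6;  P (vague clock) -> 2;  Q (no attempt) -> 1;
#   NO_HANDS (i,j,k all unmarked) -> 3;
#   NUMBERS_OUT (b and c both unmarked) -> 4;
#   REVERSED_OR_CONCENTRATED (d or h unmarked) -> 5;
#   otherwise HANDS_miss with miss = # unmarked of {l,m,n}, score = 10 - miss.
# The three initial points (o, p, q) precede everything; the lower band is
# checked severity-first (3, then 4, then 5) so the worst applicable deficit
# dominates when several apply.
score_items <- function(m) {
  n <- nrow(m)
  score <- integer(n)
  rule <- character(n)
  todo <- rep(TRUE, n)
  fire <- function(cond, s, r) {
    hit <- todo & cond
    score[hit] <<- s
    rule[hit] <<- r
    todo[hit] <<- FALSE
  }
  fire(m[, "o"], 6L, "O")
  fire(m[, "p"], 2L, "P")
  fire(m[, "q"], 1L, "Q")
  fire(!(m[, "i"] | m[, "j"] | m[, "k"]), 3L, "NO_HANDS")
  fire(!m[, "b"] & !m[, "c"], 4L, "NUMBERS_OUT")
  fire(!m[, "d"] | !m[, "h"], 5L, "REVERSED_OR_CONCENTRATED")
  miss <- 3L - (m[, "l"] + m[, "m"] + m[, "n"])
  score[todo] <- 10L - miss[todo]
  rule[todo] <- paste0("HANDS_", miss[todo])
  list(score = score, rule_id = rule)
}

#' Score checklists with the algorithmic decision procedure
#'
#' Maps each 17-item checklist to a Sunderland score 1-10 by first-match rule
#' evaluation. Three exclusion items are considered first: wrong use of hands
#' (`o`, score 6), only a vague clock (`p`, score 2), no attempt (`q`, score
#' 1). A drawing with no hand item marked scores 3; with numbers missing and
#' outside the boundary (`b` and `c` unmarked) 4; with numbers out of order or
#' concentrated (`d` or `h` unmarked) 5. Any other drawing is in the intact
#' band and scores 10 minus the number of unmarked hand-quality items among
#' `l`, `m`, `n`.
#'
#' Items `a`, `e`, `f`, `g` never enter the score; intact-band drawings with
#' any of them unmarked are flagged `nonstandard_face` so users can audit
#' face-imperfect profiles the rule set leaves in the upper band.
#'
#' @param x checklist data frame ([checklist()], [read_checklists()]) or bare
#'   logical item matrix ([enumerate_profiles()]).
#' @param validate `"lenient"` (default) records consistency violations as
#'   flags and scores anyway; `"strict"` errors if any row is inconsistent;
#'   `"none"` skips validation.
#' @return A data frame with one row per drawing: `drawing_id`, `score`,
#'   `rule_id` (which rule fired), `band`, `description` (original scale text)
#'   and `flags` (`;`-separated advisory notes, `""` if none).
#' @examples
#' score_checklist(checklist(letters[1:14]))             # perfect clock: 10
#' score_checklist(checklist(character()))               # blank sheet: 3
#' @export
score_checklist <- function(x, validate = c("lenient", "strict", "none")) {
  validate <- match.arg(validate)
  m <- checklist_matrix(x)
  ids <- checklist_ids(x, nrow(m))
  if (anyDuplicated(ids)) {
    stop("duplicate drawing_id values", call. = FALSE)
  }
  flags <- rep("", nrow(m))
  if (validate != "none") {
    rep_mode <- if (validate == "strict") "strict" else "lenient"
    v <- validate_checklist(m, mode = rep_mode)
    if (validate == "strict" && !all(v$valid)) {
      stop("inconsistent checklist row(s): ",
           paste(unique(v$violations$row), collapse = ", "),
           " (", paste(unique(v$violations$rule), collapse = ", "), ")",
           call. = FALSE)
    }
    if (nrow(v$violations) > 0L) {
      notes <- tapply(v$violations$rule, v$violations$row,
                      function(r) paste(sort(unique(r)), collapse = ";"))
      flags[as.integer(names(notes))] <- as.character(notes)
    }
  }
  res <- score_items(m)
  face_ok <- m[, "a"] & m[, "e"] & m[, "f"] & m[, "g"]
  odd_face <- res$score >= 6L & !face_ok
  flags[odd_face] <- ifelse(flags[odd_face] == "", "nonstandard_face",
                            paste(flags[odd_face], "nonstandard_face",
                                  sep = ";"))
  data.frame(drawing_id = ids,
             score = res$score,
             rule_id = res$rule_id,
             band = band_of(res$score),
             description = sunderland_description(res$score),
             flags = flags,
             stringsAsFactors = FALSE)
}

# per-session cache for the exhaustive score table and preimages
.cdt_cache <- new.env(parent = emptyenv())

all_profile_scores <- function() {
  if (is.null(.cdt_cache$scores)) {
    m <- enumerate_profiles()
    .cdt_cache$scores <- score_items(m)$score
    .cdt_cache$strict_valid <- strict_valid_mask(m)
  }
  .cdt_cache$scores
}

#' Preimage of each score under the decision algorithm
#'
#' Partitions all \eqn{2^{17}} checklist profiles by the score the algorithm
#' assigns them. Profiles are identified by profile index (see
#' [profile_index()]); [profiles_from_index()] recovers the checklists. With
#' `strict_only = TRUE` the preimages are restricted to profiles passing
#' strict consistency validation, the restriction used when sampling
#' clinically plausible synthetic drawings.
#'
#' @param strict_only restrict to strictly consistent profiles?
#' @return Named list `"1"`..`"10"` of integer vectors of profile indices;
#'   over the full profile space the sets are disjoint and their union is all
#'   of `0:131071`.
#' @export
preimage_table <- function(strict_only = FALSE) {
  scores <- all_profile_scores()
  keep <- if (strict_only) .cdt_cache$strict_valid else rep(TRUE, length(scores))
  idx <- seq_along(scores) - 1L
  lapply(stats::setNames(1:10, as.character(1:10)),
         function(s) idx[keep & scores == s])
}
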