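# Inter-rater agreement statistics for 1-10 ordinal CDT scores.
#
# Conventions: unweighted kappa builds its contingency table over the union of
# observed categories (the usual two-rater construction); weighted kappa uses
# the full fixed 1-10 scale so ordinal distances refer to the instrument, not
# to whichever categories happened to occur. A kappa whose chance agreement is
# exactly 1 (both raters constant on the same category) is undefined and
# returned as NaN with a warning, never silently 0 or 1.

check_pair <- function(x, y, min_n = 1L) {
  if (length(x) != length(y)) stop("score vectors differ in length",
                                   call. = FALSE)
  if (length(x) < min_n) stop("need at least ", min_n, " paired scores",
                              call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing scores not allowed", call. = FALSE)
  invisible(NULL)
}

#' Percent agreement between two raters
#'
#' @param x,y equal-length integer score vectors.
#' @return Percentage (0-100) of drawings on which the raters agree exactly.
#' @export
percent_agreement <- function(x, y) {
  check_pair(x, y, 1L)
  100 * mean(x == y)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, with
#' chance agreement from the product of the raters' marginal category
#' proportions over the union of observed categories.
#'
#' @param x,y equal-length score vectors.
#' @return Kappa in \eqn{[-1, 1]}, or `NaN` (with a warning) when chance
#'   agreement is 1 and kappa is undefined.
#' @export
cohen_kappa <- function(x, y) {
  check_pair(x, y, 2L)
  cats <- sort(unique(c(x, y)))
  po <- mean(x == y)
  pe <- sum(tabulate(match(x, cats), length(cats)) *
              tabulate(match(y, cats), length(cats))) / length(x)^2
  if (pe >= 1 - 1e-12) {
    warning("kappa undefined: chance agreement is 1 (both raters constant)")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Weighted kappa for two raters on the 1-10 scale
#'
#' \eqn{\kappa_w = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}} over the full
#' 10 x 10 table, with disagreement weights \eqn{w_{ij} = |i-j|/9} (linear)
#' or its square (quadratic). `O` is the observed cross-classification, `E`
#' the chance-expected table from the marginal products.
#'
#' @param x,y equal-length score vectors with values in 1-10.
#' @param scheme `"linear"` (default) or `"quadratic"` disagreement weights.
#' @return Weighted kappa, or `NaN` with a warning when undefined.
#' @export
weighted_kappa <- function(x, y, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  check_pair(x, y, 2L)
  x <- check_score_range(x)
  y <- check_score_range(y)
  C <- 10L
  O <- table(factor(x, levels = 1:C), factor(y, levels = 1:C))
  E <- outer(rowSums(O), colSums(O)) / length(x)
  w <- abs(outer(1:C, 1:C, "-")) / (C - 1L)
  if (scheme == "quadratic") w <- w^2
  denom <- sum(w * E)
  if (denom <= 1e-12) {
    warning("weighted kappa undefined: no chance-expected disagreement")
    return(NaN)
  }
  1 - sum(w * O) / denom
}

#' Fleiss' kappa for a multi-rater score matrix
#'
#' Multi-rater chance-corrected agreement: per-drawing pairwise agreement is
#' averaged over drawings and corrected by chance agreement from the pooled
#' category proportions.
#'
#' @param ratings a `rating_matrix` (see [rating_matrix()]) or an n x k
#'   integer matrix of scores in 1-10 (n drawings, k raters).
#' @return Fleiss' kappa, or `NaN` with a warning when every cell is one
#'   single category.
#' @export
fleiss_kappa <- function(ratings) {
  s <- rating_scores(ratings)
  n <- nrow(s)
  k <- ncol(s)
  counts <- t(apply(s, 1L, function(r) tabulate(r, 10L)))
  p_j <- colSums(counts) / (n * k)
  P_i <- (rowSums(counts^2) - k) / (k * (k - 1L))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (Pe >= 1 - 1e-12) {
    warning("Fleiss' kappa undefined: all ratings in a single category")
    return(NaN)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two raters' scores; the p-value comes
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees
#' of freedom.
#'
#' @param x,y equal-length numeric vectors (length >= 3, both non-constant).
#' @return List with elements `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y, 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for a constant score vector",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- length(x) - 2L
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p)
}

#' Construct a rating matrix
#'
#' Container for a complete drawings x raters matrix of integer scores 1-10,
#' the unit of analysis for inter-rater reliability.
#'
#' @param scores n x k integer matrix, n >= 2 drawings, k >= 2 raters.
#' @param drawing_ids,rater_ids optional identifiers (defaults generated).
#' @return Object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, drawing_ids = NULL, rater_ids = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("rating matrix needs >= 2 drawings and >= 2 raters", call. = FALSE)
  }
  if (anyNA(scores)) stop("rating matrix has missing cells", call. = FALSE)
  storage.mode(scores) <- "integer"
  if (any(scores < 1L | scores > 10L)) {
    stop("scores must lie in 1:10", call. = FALSE)
  }
  if (is.null(drawing_ids)) drawing_ids <- sprintf("D%03d", seq_len(nrow(scores)))
  if (is.null(rater_ids)) rater_ids <- sprintf("rater_%d", seq_len(ncol(scores)))
  dimnames(scores) <- list(NULL, NULL)
  structure(list(drawing_ids = as.character(drawing_ids),
                 rater_ids = as.character(rater_ids),
                 scores = scores),
            class = "rating_matrix")
}

rating_scores <- function(x) {
  if (inherits(x, "rating_matrix")) return(x$scores)
  rating_matrix(x)$scores
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("Rating matrix:", nrow(x$scores), "drawings x", ncol(x$scores),
      "raters\n")
  invisible(x)
}

#' Full inter-rater reliability report
#'
#' Computes, for every pair among the k raters, the Pearson correlation with
#' its two-sided p-value, percent agreement, Cohen's kappa and weighted kappa,
#' plus pooled statistics: Fleiss' kappa and the means of the pairwise
#' statistics. The pooled "combined" agreement is reported both ways (Fleiss
#' and mean pairwise Cohen) since multi-rater kappas differ between the two
#' constructions; undefined pairwise kappas are excluded from the means and
#' counted in `n_undefined`. Per-rater mean and standard deviation of scores
#' are included.
#'
#' @param ratings a [rating_matrix()] or n x k score matrix.
#' @param scheme weighting scheme for the weighted kappa.
#' @return Object of class `reliability_report`: list with `pairwise` (data
#'   frame of the k(k-1)/2 pairs), `pooled` (named list), `rater_summary`
#'   (data frame) and `meta`.
#' @export
reliability_report <- function(ratings, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  rm <- if (inherits(ratings, "rating_matrix")) ratings else
    rating_matrix(ratings)
  s <- rm$scores
  k <- ncol(s)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(pidx) {
    i <- pairs[1L, pidx]; j <- pairs[2L, pidx]
    x <- s[, i]; y <- s[, j]
    pr <- tryCatch(pearson_r(x, y), error = function(e) list(r = NA_real_,
                                                             p = NA_real_))
    data.frame(rater_i = rm$rater_ids[i], rater_j = rm$rater_ids[j],
               pearson_r = pr$r, pearson_p = pr$p,
               percent_agreement = percent_agreement(x, y),
               cohen_kappa = suppressWarnings(cohen_kappa(x, y)),
               weighted_kappa = suppressWarnings(weighted_kappa(x, y, scheme)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pooled <- list(
    fleiss_kappa = suppressWarnings(fleiss_kappa(rm)),
    mean_pairwise_cohen_kappa = mean(pw$cohen_kappa[is.finite(pw$cohen_kappa)]),
    mean_pairwise_weighted_kappa =
      mean(pw$weighted_kappa[is.finite(pw$weighted_kappa)]),
    mean_percent_agreement = mean(pw$percent_agreement),
    n_undefined = sum(!is.finite(pw$cohen_kappa)) +
      sum(!is.finite(pw$weighted_kappa))
  )
  rater_summary <- data.frame(rater_id = rm$rater_ids,
                              mean = colMeans(s),
                              sd = apply(s, 2L, stats::sd),
                              stringsAsFactors = FALSE)
  structure(list(pairwise = pw, pooled = pooled,
                 rater_summary = rater_summary,
                 meta = list(n = nrow(s), k = k, scheme = scheme)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Inter-rater reliability:", x$meta$n, "drawings,", x$meta$k,
      "raters (", x$meta$scheme, "weights )\n\nPairwise:\n")
  pw <- x$pairwise
  pw[] <- lapply(pw, function(col) if (is.numeric(col)) round(col, digits)
                 else col)
  print(pw, row.names = FALSE)
  cat("\nPooled:\n")
  for (nm in names(x$pooled)) {
    cat(sprintf("  %-30s %s\n", nm, format(round(x$pooled[[nm]], digits))))
  }
  invisible(x)
}
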