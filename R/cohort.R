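# Synthetic cohorts: a maximum-entropy score distribution calibrated to
# published summary statistics, inverted through the scoring algorithm by
# sampling checklists uniformly from each score's preimage.

#' Specify a synthetic cohort
#'
#' The defaults reproduce the study conditions of the source cohort: 100
#' community-dwelling cognitively normal elderly whose score distribution had
#' mean 5.22, standard deviation 2.02, a 53.5% point mass on score 5, and no
#' drawings scoring 1 or 7.
#'
#' @param n cohort size.
#' @param target_mean,target_sd moment constraints for the calibrated score
#'   distribution (`NULL` drops the constraint; `target_sd` requires
#'   `target_mean`).
#' @param point_masses named numeric vector of fixed probabilities, names are
#'   scores (e.g. `c("5" = 0.535)`).
#' @param excluded_scores integer scores forced to probability zero.
#' @param seed integer seed for sampling.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100L,
                        target_mean = 5.22,
                        target_sd = 2.02,
                        point_masses = c("5" = 0.535),
                        excluded_scores = c(1L, 7L),
                        seed = 1L) {
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  if (!is.null(target_sd) && is.null(target_mean)) {
    stop("target_sd requires target_mean", call. = FALSE)
  }
  if (!is.null(target_sd) && target_sd <= 0) {
    stop("target_sd must be > 0", call. = FALSE)
  }
  if (length(point_masses) > 0L) {
    if (is.null(names(point_masses)) ||
        !all(names(point_masses) %in% as.character(1:10))) {
      stop("point_masses must be named by scores 1-10", call. = FALSE)
    }
    if (any(point_masses < 0 | point_masses > 1) || sum(point_masses) > 1) {
      stop("infeasible point_masses: probabilities must lie in [0,1] and sum to <= 1",
           call. = FALSE)
    }
  }
  excluded_scores <- as.integer(excluded_scores)
  if (any(excluded_scores %in% as.integer(names(point_masses)))) {
    stop("a score cannot be both excluded and given a point mass",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), target_mean = target_mean,
                 target_sd = target_sd, point_masses = point_masses,
                 excluded_scores = excluded_scores, seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-sum-exp
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Calibrate the maximum-entropy score distribution
#'
#' Finds the probability vector over scores 1-10 with maximum Shannon entropy
#' subject to the spec's constraints: excluded scores get zero mass, point
#' masses are fixed, and (if given) the distribution mean and standard
#' deviation match the targets. The free probabilities form an exponential
#' family \eqn{p(s) \propto \exp(\lambda_1 s + \lambda_2 s^2)}; the two
#' multipliers are found by minimising the convex dual (BFGS, then Newton
#' polish) until the moments match to 1e-10.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `score_distribution`: numeric probability vector
#'   named `"1"`..`"10"`, with attributes `mean`, `sd`, `entropy` and
#'   `lambda`.
#' @export
calibrate_distribution <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  support <- setdiff(1:10, spec$excluded_scores)
  pm_scores <- as.integer(names(spec$point_masses))
  if (!all(pm_scores %in% support)) {
    stop("point mass placed on an excluded score", call. = FALSE)
  }
  free <- setdiff(support, pm_scores)
  pm <- as.numeric(spec$point_masses)
  m_free <- 1 - sum(pm)
  p <- stats::setNames(numeric(10L), as.character(1:10))
  p[as.character(pm_scores)] <- pm

  if (m_free < 1e-12) {
    # degenerate: the point masses are the whole distribution
    if (abs(m_free) > 1e-9) stop("infeasible: point masses exceed 1",
                                 call. = FALSE)
    return(finish_distribution(p, spec))
  }
  if (length(free) == 0L) {
    stop("infeasible: free mass remains but every score is fixed or excluded",
         call. = FALSE)
  }

  if (is.null(spec$target_mean)) {
    p[as.character(free)] <- m_free / length(free)
    return(finish_distribution(p, spec))
  }

  mu <- spec$target_mean
  mean_lo <- sum(pm * pm_scores) + m_free * min(free)
  mean_hi <- sum(pm * pm_scores) + m_free * max(free)
  if (mu < mean_lo - 1e-9 || mu > mean_hi + 1e-9) {
    stop(sprintf(
      "infeasible: target_mean %.4g outside achievable range [%.4g, %.4g]",
      mu, mean_lo, mean_hi), call. = FALSE)
  }
  mu_free <- (mu - sum(pm * pm_scores)) / m_free

  if (is.null(spec$target_sd)) {
    lam <- solve_tilt(free, mu_free, NULL)
  } else {
    mu2 <- spec$target_sd^2 + mu^2
    mu2_free <- (mu2 - sum(pm * pm_scores^2)) / m_free
    var_free <- mu2_free - mu_free^2
    var_max <- (max(free) - mu_free) * (mu_free - min(free))
    if (var_free <= 1e-9 || var_free >= var_max - 1e-9) {
      stop(sprintf(
        "infeasible: target_sd implies free-support variance %.4g outside (0, %.4g)",
        var_free, var_max), call. = FALSE)
    }
    lam <- solve_tilt(free, mu_free, var_free)
  }
  w <- exp(lam[1L] * (free - mu_free) + lam[2L] * (free - mu_free)^2)
  p[as.character(free)] <- m_free * w / sum(w)
  finish_distribution(p, spec)
}

# Solve for the tilting multipliers on centred features (s - mu, (s - mu)^2)
# with targets (0, v). One multiplier when v is NULL.
solve_tilt <- function(s, mu, v) {
  t1 <- s - mu
  t2 <- t1^2
  two <- !is.null(v)
  targ <- if (two) c(0, v) else 0
  dual <- function(l) {
    l2 <- if (two) l[2L] else 0
    lse(l[1L] * t1 + l2 * t2) - sum(l * targ)
  }
  grad <- function(l) {
    l2 <- if (two) l[2L] else 0
    lw <- l[1L] * t1 + l2 * t2
    q <- exp(lw - lse(lw))
    g1 <- sum(q * t1) - targ[1L]
    if (!two) return(g1)
    c(g1, sum(q * t2) - targ[2L])
  }
  l0 <- if (two) c(0, 0) else 0
  fit <- stats::optim(l0, dual, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  l <- fit$par
  # Newton polish: the dual Hessian is the covariance of the features
  for (iter in 1:50) {
    l2 <- if (two) l[2L] else 0
    lw <- l[1L] * t1 + l2 * t2
    q <- exp(lw - lse(lw))
    g <- grad(l)
    if (max(abs(g)) < 1e-12) break
    if (two) {
      feats <- cbind(t1, t2)
      mu_f <- colSums(q * feats)
      H <- crossprod(feats * sqrt(q)) - tcrossprod(mu_f)
      step <- tryCatch(solve(H, g), error = function(e) g)
    } else {
      H <- sum(q * t1^2) - sum(q * t1)^2
      step <- g / H
    }
    l <- l - step
  }
  if (max(abs(grad(l))) > 1e-8) {
    stop("calibration failed to match the moment constraints", call. = FALSE)
  }
  if (two) l else c(l, 0)
}

finish_distribution <- function(p, spec) {
  if (abs(sum(p) - 1) > 1e-9) {
    stop("calibration failed: probabilities do not sum to 1", call. = FALSE)
  }
  s <- 1:10
  mean_p <- sum(p * s)
  sd_p <- sqrt(max(0, sum(p * s^2) - mean_p^2))
  pos <- p > 0
  structure(p,
            mean = mean_p, sd = sd_p,
            entropy = -sum(p[pos] * log(p[pos])),
            lambda = attr(p, "lambda"),
            spec = spec,
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Score distribution (mean", round(attr(x, "mean"), 4),
      ", sd", round(attr(x, "sd"), 4),
      ", entropy", round(attr(x, "entropy"), 4), ")\n")
  print(round(unclass(x)[1:10], 4))
  invisible(x)
}

#' Sample a synthetic cohort of checklists by preimage inversion
#'
#' Draws `n` scores i.i.d. from a calibrated score distribution, then for each
#' score draws a checklist uniformly at random from that score's preimage
#' under the scoring algorithm. Rescoring the sampled checklists therefore
#' returns the drawn scores exactly. By default only strictly consistent
#' profiles are sampled, producing clinically plausible checklists.
#'
#' @param dist a `score_distribution` (or any 10-vector of probabilities).
#' @param n number of drawings.
#' @param seed integer seed.
#' @param strict_only sample only strictly consistent profiles?
#' @return Object of class `cdt_cohort`: list with `checklists` (data frame),
#'   `true_scores` (integer vector), `distribution`, `seed`, `strict_only`.
#' @export
sample_cohort <- function(dist, n, seed = 1L, strict_only = TRUE) {
  probs <- as.numeric(dist)[1:10]
  if (anyNA(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
    stop("dist must be a probability vector over scores 1-10", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  pre <- preimage_table(strict_only = strict_only)
  active <- which(probs > 0)
  empty <- active[vapply(active, function(s) length(pre[[s]]) == 0L, logical(1L))]
  if (length(empty) > 0L) {
    stop("empty restricted preimage for score(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  scores <- if (n == 0L) integer() else
    sample.int(10L, n, replace = TRUE, prob = probs)
  idx <- integer(n)
  for (s in active) {
    hit <- which(scores == s)
    if (length(hit) > 0L) {
      pool <- pre[[s]]
      idx[hit] <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
    }
  }
  m <- profiles_from_index(idx)
  checklists <- cbind(
    data.frame(drawing_id = sprintf("D%05d", seq_len(n)),
               stringsAsFactors = FALSE),
    as.data.frame(m))
  if (n == 0L) checklists <- checklists[0L, , drop = FALSE]
  structure(list(checklists = checklists, true_scores = scores,
                 distribution = probs, seed = seed,
                 strict_only = strict_only),
            class = "cdt_cohort")
}

#' @export
print.cdt_cohort <- function(x, ...) {
  cat("Synthetic CDT cohort:", length(x$true_scores), "drawings (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Simulate multiple raters by perturbing checklists
#'
#' Emulates a multi-examiner reliability design: each rater sees each drawing
#' through a noisy checklist in which every one of the 17 items is flipped
#' independently with probability `epsilon`, and the perturbed checklist is
#' rescored with the actual algorithm. `epsilon = 0` reproduces the true
#' scores exactly for every rater.
#'
#' @param cohort a `cdt_cohort` or checklist data frame.
#' @param k number of raters (>= 2).
#' @param epsilon per-item flip probability in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @return A [rating_matrix()] of rescored perturbed checklists.
#' @export
perturb_raters <- function(cohort, k = 6L, epsilon = 0.05, seed = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single probability in [0, 1]", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  cl <- if (inherits(cohort, "cdt_cohort")) cohort$checklists else cohort
  m <- checklist_matrix(cl)
  ids <- checklist_ids(cl, nrow(m))
  set.seed(seed)
  scores <- matrix(0L, nrow(m), k)
  for (r in seq_len(k)) {
    flips <- matrix(stats::runif(length(m)) < epsilon, nrow(m), 17L)
    pm <- xor(m, flips)
    colnames(pm) <- CDT_ITEMS
    scores[, r] <- score_items(pm)$score
  }
  rating_matrix(scores, drawing_ids = ids)
}

#' Attach a correlated discrete covariate to scores
#'
#' Generates a covariate (e.g. an MMSE-like score on 18-30) through a latent
#' bivariate Gaussian copula whose correlation is adjusted analytically for
#' the attenuation caused by discretising both margins, so the realised
#' Pearson correlation with the scores approaches `target_r` at large n. At
#' small n the realised correlation varies with sampling error.
#'
#' @param scores integer score vector (non-constant).
#' @param target_r desired Pearson correlation, `|target_r| < 1`.
#' @param marginal integer vector of covariate support values, sampled with a
#'   uniform marginal (default `18:30`).
#' @param seed integer seed.
#' @return Integer covariate vector of the same length as `scores`.
#' @export
attach_covariate <- function(scores, target_r, marginal = 18:30, seed = 1L) {
  if (!is.numeric(target_r) || length(target_r) != 1L || abs(target_r) >= 1) {
    stop("target_r must satisfy |target_r| < 1", call. = FALSE)
  }
  scores <- check_score_range(scores)
  if (length(unique(scores)) < 2L) {
    stop("scores are constant; correlation target is undefined", call. = FALSE)
  }
  marginal <- sort(unique(as.integer(marginal)))
  if (length(marginal) < 2L) stop("marginal needs >= 2 values", call. = FALSE)

  # attenuation of corr(discrete var, its latent normal) for a discretised
  # standard normal: E[S z] = sum_s s (phi(z_lo) - phi(z_hi))
  attenuation <- function(vals, probs) {
    cu <- cumsum(probs)
    zlo <- stats::qnorm(c(0, cu[-length(cu)]))
    zhi <- stats::qnorm(cu)
    esz <- sum(vals * (stats::dnorm(zlo) - stats::dnorm(zhi)))
    mu <- sum(vals * probs)
    sdv <- sqrt(sum(vals^2 * probs) - mu^2)
    esz / sdv
  }
  svals <- sort(unique(scores))
  sprob <- as.numeric(table(factor(scores, levels = svals))) / length(scores)
  a1 <- attenuation(svals, sprob)
  a2 <- attenuation(marginal, rep(1 / length(marginal), length(marginal)))
  rho <- target_r / (a1 * a2)
  if (abs(rho) > 0.999) {
    warning("latent correlation clipped to +/-0.999; realised r will fall short")
    rho <- sign(rho) * 0.999
  }

  set.seed(seed)
  n <- length(scores)
  # latent normal for the scores via randomised PIT (comonotone with score)
  cu <- cumsum(sprob)
  lo <- c(0, cu[-length(cu)])
  pos <- match(scores, svals)
  u <- lo[pos] + stats::runif(n) * sprob[pos]
  z1 <- stats::qnorm(u)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  L <- length(marginal)
  marginal[pmin(L, floor(stats::pnorm(z2) * L) + 1L)]
}

#' Summary statistics of a score vector
#'
#' @param scores non-empty integer score vector (values 1-10).
#' @return List with `n`, `mean`, `sd` (sample, n-1 denominator), `median`
#'   (midpoint convention for even n), `min`, `max` and `histogram` (named
#'   counts over 1-10).
#' @export
summarize_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  scores <- check_score_range(scores)
  list(n = length(scores),
       mean = mean(scores),
       sd = stats::sd(scores),
       median = stats::median(scores),
       min = min(scores),
       max = max(scores),
       histogram = stats::setNames(tabulate(scores, 10L), as.character(1:10)))
}
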