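# Independent oracles, coded deliberately differently from the package:
# a literal condition-list scorer, brute-force contingency-table agreement
# statistics, and a penalized simplex optimizer for max-ent calibration.

# Literal condition-list scorer: each rule is a (predicate, score) pair
# scanned top to bottom, transcribed directly from the scoring rubric.
oracle_rules <- list(
  list(function(v) v[["o"]], 6L),                          # wrong hand use
  list(function(v) v[["p"]], 2L),                          # vague clock only
  list(function(v) v[["q"]], 1L),                          # no attempt
  list(function(v) !v[["i"]] && !v[["j"]] && !v[["k"]], 3L),  # no hands
  list(function(v) !v[["b"]] && !v[["c"]], 4L),            # numbers missing/out
  list(function(v) !v[["d"]] || !v[["h"]], 5L),            # reversed/concentrated
  list(function(v) v[["l"]] && v[["m"]] && v[["n"]], 10L),
  list(function(v) sum(!c(v[["l"]], v[["m"]], v[["n"]])) == 1L, 9L),
  list(function(v) sum(!c(v[["l"]], v[["m"]], v[["n"]])) == 2L, 8L),
  list(function(v) TRUE, 7L)
)

oracle_score <- function(v) {
  for (rule in oracle_rules) {
    if (rule[[1L]](v)) return(rule[[2L]])
  }
  stop("unreachable")
}

oracle_score_all <- function(m) {
  vapply(seq_len(nrow(m)), function(r) oracle_score(m[r, ]), integer(1L))
}

# Brute-force Cohen kappa from an explicitly constructed contingency table.
oracle_cohen <- function(x, y) {
  cats <- sort(unique(c(x, y)))
  tab <- matrix(0, length(cats), length(cats))
  for (idx in seq_along(x)) {
    i <- which(cats == x[idx]); j <- which(cats == y[idx])
    tab[i, j] <- tab[i, j] + 1
  }
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- 0
  for (i in seq_along(cats)) {
    pe <- pe + (sum(tab[i, ]) / n) * (sum(tab[, i]) / n)
  }
  (po - pe) / (1 - pe)
}

# Brute-force weighted kappa over the full 1-10 table.
oracle_weighted <- function(x, y, power = 1) {
  O <- matrix(0, 10, 10)
  for (idx in seq_along(x)) O[x[idx], y[idx]] <- O[x[idx], y[idx]] + 1
  n <- length(x)
  num <- 0; den <- 0
  for (i in 1:10) for (j in 1:10) {
    w <- (abs(i - j) / 9)^power
    num <- num + w * O[i, j]
    den <- den + w * sum(O[i, ]) * sum(O[, j]) / n
  }
  1 - num / den
}

# Two-rater pooled-marginal kappa: observed exact agreement corrected by
# chance agreement from the average of the two raters' marginals.
oracle_pooled_two_rater <- function(x, y) {
  po <- mean(x == y)
  pe <- 0
  for (cat in 1:10) {
    pbar <- (mean(x == cat) + mean(y == cat)) / 2
    pe <- pe + pbar^2
  }
  (po - pe) / (1 - pe)
}

# Direct-covariance Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# Generic constrained max-ent oracle on the 10-point simplex: softmax
# parameterization, quadratic moment penalties with penalty continuation,
# entropy maximized by BFGS.
oracle_maxent <- function(target_mean, target_sd, point_masses,
                          excluded_scores) {
  s <- 1:10
  free <- setdiff(s, c(as.integer(names(point_masses)), excluded_scores))
  m_free <- 1 - sum(point_masses)
  make_p <- function(theta) {
    w <- exp(theta - max(theta))
    p <- numeric(10)
    p[free] <- m_free * w / sum(w)
    p[as.integer(names(point_masses))] <- point_masses
    p
  }
  theta <- numeric(length(free))
  for (pen in c(1e2, 1e4, 1e6, 1e8, 1e10)) {
    obj <- function(theta) {
      p <- make_p(theta)
      ent <- -sum(p[p > 0] * log(p[p > 0]))
      v <- c(sum(p * s) - target_mean,
             sum(p * s^2) - (target_sd^2 + target_mean^2))
      -ent + pen * sum(v^2)
    }
    theta <- stats::optim(theta, obj, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-15))$par
  }
  make_p(theta)
}

# Small convenience: a fully correct checklist (items a-n marked).
perfect_checklist <- function(drop = character(), id = "d1") {
  checklist(setdiff(letters[1:14], drop), drawing_id = id)
}
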