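study_spec <- cohort_spec()  # defaults encode the study's printed marginals

test_that("max-ent calibration with no constraints is uniform", {
  spec <- cohort_spec(target_mean = NULL, target_sd = NULL,
                      point_masses = numeric(), excluded_scores = integer())
  d <- calibrate_distribution(spec)
  expect_equal(as.numeric(d), rep(0.1, 10))
})

test_that("calibration to the study marginals satisfies every constraint", {
  d <- calibrate_distribution(study_spec)
  p <- as.numeric(d)
  s <- 1:10
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(p[5], 0.535)
  expect_equal(p[1], 0)
  expect_equal(p[7], 0)
  expect_equal(sum(p * s), 5.22, tolerance = 1e-6)
  expect_equal(sqrt(sum(p * s^2) - sum(p * s)^2), 2.02, tolerance = 1e-6)
})

test_that("calibrated distribution agrees with a generic simplex optimizer", {
  d <- calibrate_distribution(study_spec)
  ref <- oracle_maxent(5.22, 2.02, c("5" = 0.535), c(1L, 7L))
  expect_lt(max(abs(as.numeric(d) - ref)), 2e-3)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  # the dual solution cannot have lower entropy than the penalized oracle
  expect_gte(ent(as.numeric(d)), ent(ref) - 1e-5)
})

test_that("mean-only calibration hits its single moment", {
  spec <- cohort_spec(target_mean = 4, target_sd = NULL,
                      point_masses = numeric(), excluded_scores = integer())
  d <- calibrate_distribution(spec)
  expect_equal(sum(as.numeric(d) * (1:10)), 4, tolerance = 1e-8)
})

test_that("infeasible constraints are rejected with named reasons", {
  expect_error(calibrate_distribution(cohort_spec(target_mean = 11)),
               "target_mean")
  expect_error(calibrate_distribution(cohort_spec(target_sd = 9)),
               "target_sd")
  expect_error(cohort_spec(point_masses = c("5" = 0.7, "4" = 0.6)),
               "point_masses")
  expect_error(cohort_spec(point_masses = c("7" = 0.5),
                           excluded_scores = c(1L, 7L)),
               "excluded")
  expect_error(cohort_spec(target_sd = -1), "target_sd")
})

test_that("preimage sampling round-trips exactly through the scoring algorithm", {
  d <- calibrate_distribution(study_spec)
  co <- sample_cohort(d, 500, seed = 7)
  rescored <- score_checklist(co$checklists, validate = "none")$score
  expect_equal(rescored, co$true_scores)
  # strict-only sampling yields strictly consistent profiles
  v <- validate_checklist(co$checklists, mode = "strict")
  expect_true(all(v$valid))
  # reproducibility: same seed identical, different seed different
  co2 <- sample_cohort(d, 500, seed = 7)
  expect_identical(co$checklists, co2$checklists)
  co3 <- sample_cohort(d, 500, seed = 8)
  expect_false(identical(co$true_scores, co3$true_scores))
  # empty cohort
  co0 <- sample_cohort(d, 0, seed = 1)
  expect_equal(nrow(co0$checklists), 0L)
  expect_length(co0$true_scores, 0L)
})

test_that("sampled score distribution matches the calibrated one (chi-square GOF)", {
  d <- calibrate_distribution(study_spec)
  p <- as.numeric(d)
  pos <- which(p > 0)
  for (seed in 1:3) {
    co <- sample_cohort(d, 10000, seed = seed)
    counts <- tabulate(co$true_scores, 10L)
    expect_true(all(counts[-pos] == 0L))
    gof <- suppressWarnings(chisq.test(counts[pos], p = p[pos]))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("noise-free raters reproduce the true scores and perfect agreement", {
  d <- calibrate_distribution(study_spec)
  co <- sample_cohort(d, 60, seed = 3)
  rm <- perturb_raters(co, k = 6, epsilon = 0, seed = 5)
  expect_true(all(rm$scores == co$true_scores))
  rep0 <- reliability_report(rm)
  expect_equal(rep0$pooled$fleiss_kappa, 1)
  expect_equal(rep0$pooled$mean_percent_agreement, 100)
  expect_error(perturb_raters(co, k = 6, epsilon = 1.5), "epsilon")
  expect_error(perturb_raters(co, k = 1, epsilon = 0), "k must be")
})

test_that("pooled kappa decreases in expectation as rater noise grows", {
  d <- calibrate_distribution(study_spec)
  co <- sample_cohort(d, 30, seed = 13)
  eps <- c(0, 0.05, 0.2)
  kap <- sapply(1:10, function(seed) {
    sapply(eps, function(e) {
      fleiss_kappa(perturb_raters(co, k = 6, epsilon = e, seed = seed))
    })
  })
  means <- rowMeans(kap)
  expect_equal(means[1], 1)
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
  # exact reproducibility under a fixed seed
  a <- perturb_raters(co, k = 6, epsilon = 0.1, seed = 99)
  b <- perturb_raters(co, k = 6, epsilon = 0.1, seed = 99)
  expect_identical(a$scores, b$scores)
})

test_that("covariate generator realizes its target correlation at large n", {
  d <- calibrate_distribution(study_spec)
  co <- sample_cohort(d, 10000, seed = 17)
  x0 <- attach_covariate(co$true_scores, 0, seed = 1)
  expect_lt(abs(cor(co$true_scores, x0)), 0.05)
  expect_true(all(x0 %in% 18:30))
  for (seed in 1:3) {
    x <- attach_covariate(co$true_scores, 0.22, seed = seed)
    expect_lt(abs(cor(co$true_scores, x) - 0.22), 0.03)
  }
  expect_error(attach_covariate(co$true_scores, 1), "target_r")
  expect_error(attach_covariate(rep(5L, 10), 0.2), "constant")
})

test_that("score summaries use sample SD and midpoint medians", {
  s1 <- summarize_scores(c(5, 5, 5, 5))
  expect_equal(s1[c("mean", "sd", "median")], list(mean = 5, sd = 0,
                                                   median = 5))
  s2 <- summarize_scores(c(2, 10))
  expect_equal(s2$mean, 6)
  expect_equal(s2$min, 2)
  expect_equal(s2$max, 10)
  expect_equal(s2$median, 6)
  s3 <- summarize_scores(c(2, 4, 5, 5, 9))
  expect_equal(s3$median, 5)
  # direct-formula oracle: sqrt(sum((x - mean)^2)/(n - 1))
  expect_equal(s3$sd, sqrt(26 / 4))
  expect_equal(sum(s3$histogram), 5L)
  expect_equal(unname(s3$histogram[5]), 2L)
  expect_error(summarize_scores(integer()), "empty")
})
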