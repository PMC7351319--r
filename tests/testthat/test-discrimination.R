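test_that("rank-sum test reproduces the worked examples", {
  a <- c(5, 7, 7, 9)
  expect_gte(rank_sum_test(a, a), 0.99)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("AUC equals U/(n1 n2) on tie-free samples", {
  set.seed(41)
  for (i in 1:30) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    scores <- sample(seq_len(50), n1 + n0)   # tie-free
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    u <- sum(outer(scores[labels], scores[!labels], ">"))
    expect_equal(roc_auc(scores, labels), u / (n1 * n0))
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
  }
})

test_that("AUC worked examples and edge cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.3, 8), c(0, 1, 0, 1, 0, 1, 0, 1)), 0.5)
  und <- roc_auc(1:4, c(1, 1, 1, 1))
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(42)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), base)
  expect_equal(roc_auc(atan(scores) * 3 + 2, labels), base)
})

test_that("average precision reproduces the worked examples", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(3, 2, 1), c(1, 1, 0)), 1.0)
  expect_equal(average_precision(c(3, 2, 1), c(0, 0, 1)), 1 / 3)
  und <- average_precision(1:3, c(0, 0, 0))
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("AP equals prevalence in expectation for random scores", {
  set.seed(43)
  n <- 200; prev <- 0.3
  labels <- c(rep(TRUE, n * prev), rep(FALSE, n * (1 - prev)))
  aps <- replicate(400, average_precision(runif(n), labels))
  expect_lt(abs(mean(aps) - prev), 0.02)
})

test_that("Cohen's d follows its pooled-SD definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  set.seed(44)
  a <- rnorm(20000, 1, 1); b <- rnorm(20000, 0, 1)
  expect_lt(abs(abs(cohens_d(a, b)) - 1), 0.05)
  expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b))
  und <- cohens_d(rep(1, 5), rep(1, 5))
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("LDA recovers the analytic discriminant direction", {
  set.seed(45)
  # contrast only in feature 3, isotropic within-class covariance
  n <- 6000
  x <- matrix(rnorm(n * 6), n, 6)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x[labels, 3] <- x[labels, 3] + 1.5
  w <- fit_lda(x, labels)
  expect_gt(abs(w[3]), 0.95)
  expect_lt(max(abs(w[-3])), 0.05)
  # 2-feature anisotropic case: direction within 5 degrees of solve(S, dmu)
  n <- 2000
  sigma <- matrix(c(1, 0.6, 0.6, 1), 2)
  ch <- chol(sigma)
  x2 <- matrix(rnorm(n * 2), n, 2) %*% ch
  labels2 <- rep(c(TRUE, FALSE), each = n / 2)
  dmu <- c(1, 0.2)
  x2[labels2, ] <- x2[labels2, ] + rep(dmu, each = n / 2)
  w2 <- fit_lda(x2, labels2)
  ideal <- solve(sigma, dmu)
  cosang <- sum(w2 * ideal) / sqrt(sum(ideal^2))
  expect_gt(cosang, cos(5 * pi / 180))
})

test_that("duplicated feature columns take the ridge path", {
  set.seed(46)
  x <- matrix(rnorm(100), 50, 2)
  x <- cbind(x, x[, 1])
  labels <- rep(c(TRUE, FALSE), 25)
  expect_warning(w <- fit_lda(x, labels), "ridge")
  expect_true(all(is.finite(w)))
})

test_that("LDA scores are min-max scaled and order-preserving", {
  set.seed(47)
  x <- matrix(rnorm(200), 50, 4)
  w <- c(0.5, -0.3, 0.2, 0.1)
  s <- lda_scores(x, w)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_identical(order(s), order(as.numeric(x %*% w)))
  const <- lda_scores(matrix(1, 10, 4), w)
  expect_true(all(const == 0.5) && attr(const, "constant"))
})

test_that("LDA weights are scale-invariant up to feature rescaling", {
  set.seed(48)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x[labels, ] <- x[labels, ] + rep(c(0.8, 0.5, -0.4), each = n / 2)
  w1 <- fit_lda(x, labels)
  scales <- c(10, 0.2, 3)
  w2 <- fit_lda(sweep(x, 2, scales, "*"), labels)
  # projections must be proportional: same direction after rescaling
  p1 <- as.numeric(x %*% w1)
  p2 <- as.numeric(sweep(x, 2, scales, "*") %*% w2)
  expect_gt(abs(stats::cor(p1, p2)), 1 - 1e-9)
})

test_that("patient_report computes per-parameter stats and handles a missing class", {
  set.seed(49)
  n <- 60
  mk <- function(group, shift) {
    data.frame(
      lifetime_ch1 = rnorm(n, 4 - shift * 0.4, .2),
      lifetime_ch2 = rnorm(n, 3.3 + shift * 0.5, .2),
      lifetime_ch3 = rnorm(n, 2.8, .2),
      intratio_ch1 = rnorm(n, .45, .04), intratio_ch2 = rnorm(n, .33, .04),
      intratio_ch3 = rnorm(n, .22 + shift * 0.05, .04),
      group = group)
  }
  d <- rbind(mk("healthy", 0), mk("cancer", 1))
  d$analysis_ready <- TRUE
  for (p in flimpipe:::flim_parameters()) d[[paste0("mad_pass_", p)]] <- TRUE
  d$mad_pass_all <- TRUE
  rep1 <- patient_report(d, context = "in_vivo_pre", patient = 1)
  expect_identical(nrow(rep1), 7L)
  expect_lt(rep1$p_value[rep1$parameter == "lifetime_ch2"], 1e-3)
  expect_gt(rep1$auc_oriented[rep1$parameter == "lifetime_ch2"], 0.8)
  # raw AUC of the inverted parameter sits below 0.5
  expect_lt(rep1$auc[rep1$parameter == "lifetime_ch1"], 0.5)
  expect_gte(rep1$auc[rep1$parameter == "lda"],
             max(rep1$auc_oriented[rep1$parameter != "lda"]) - 0.05)
  # single-class scan is non-discriminable
  d2 <- d[d$group == "healthy", ]
  rep2 <- patient_report(d2, context = "tumor_bed", patient = 1)
  expect_true(attr(rep2, "non_discriminable"))
  expect_true(all(is.na(rep2$auc)))
  # serialization round-trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(rep1), f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$auc, rep1$auc, tolerance = 1e-12)
  expect_identical(back$parameter, rep1$parameter)
})

test_that("context effect sizes recover the imposed shift", {
  set.seed(50)
  n <- 3000
  mk <- function(ctx, shift) {
    data.frame(lifetime_ch1 = rnorm(n, 4 + shift, 0.3),
               lifetime_ch2 = rnorm(n, 3.3, .3), lifetime_ch3 = rnorm(n, 2.8, .3),
               intratio_ch1 = rnorm(n, .45, .05), intratio_ch2 = rnorm(n, .33, .05),
               intratio_ch3 = rnorm(n, .22, .05),
               group = "healthy", context = ctx)
  }
  m <- rbind(mk("in_vivo_pre", 0), mk("ex_vivo", 0.3))
  es <- context_effect_sizes(m)
  got <- es$cohens_d[es$parameter == "lifetime_ch1"]
  expect_lt(abs(got - 1), 0.08)
})
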