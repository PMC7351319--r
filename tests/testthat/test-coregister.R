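test_that("label assignment follows the 10-pixel rule", {
  map <- toy_map()
  # cancer rect x in [40, 80]: on-pixel, 9 px away, 11 px away
  pts <- data.frame(x = c(60, 89, 91, 5), y = c(100, 100, 100, 5))
  lab <- assign_labels(pts, map, radius = 10)
  expect_identical(lab$condition[1], "cancer")
  expect_identical(lab$condition[2], "cancer")   # 9 px from nearest pixel
  expect_true(is.na(lab$condition[3]))           # 11 px: unlabeled
  expect_true(lab$unlabeled[4])
  expect_identical(lab$group[1], "cancer")
})

test_that("label assignment matches the brute-force oracle", {
  map <- toy_map()
  set.seed(77)
  pts <- data.frame(x = runif(150, 1, 200), y = runif(150, 1, 200))
  lab <- assign_labels(pts, map, radius = 10)
  expect_identical(lab$condition, brute_assign(pts, map, radius = 10))
})

test_that("heterogeneity exclusion flags binary-disparate neighborhoods", {
  # cancer pixel at distance 5 and healthy pixel at distance 8
  map <- generate_annotation_map(
    list(list(condition = "cancer", x0 = 55, x1 = 55, y0 = 50, y1 = 50),
         list(condition = "healthy_epithelium", x0 = 42, x1 = 42,
              y0 = 50, y1 = 50)),
    width = 100, height = 100)
  pts <- assign_labels(data.frame(x = 50, y = 50), map, radius = 10)
  pts <- exclude_heterogeneous(pts, map, radius = 10)
  expect_true(pts$heterogeneity_excluded[1])
  # thin + thick epithelium both group healthy: retained
  map2 <- generate_annotation_map(
    list(list(condition = "thin_epithelium", x0 = 55, x1 = 55, y0 = 50,
              y1 = 50),
         list(condition = "thick_epithelium", x0 = 42, x1 = 42, y0 = 50,
              y1 = 50)),
    width = 100, height = 100)
  pts2 <- assign_labels(data.frame(x = 50, y = 50), map2, radius = 10)
  pts2 <- exclude_heterogeneous(pts2, map2, radius = 10)
  expect_false(pts2$heterogeneity_excluded[1])
  expect_identical(pts2$group[1], "healthy")
})

test_that("heterogeneity flags match an exhaustive scan on a toy map", {
  map <- toy_map()
  set.seed(78)
  pts <- data.frame(x = runif(120, 30, 180), y = runif(120, 30, 180))
  lab <- exclude_heterogeneous(assign_labels(pts, map, 10), map, 10)
  oracle <- brute_heterogeneous(pts, map, 10) & !lab$unlabeled
  expect_identical(lab$heterogeneity_excluded, oracle)
})

test_that("SNR filter requires the threshold on every channel", {
  pts <- data.frame(snr_ch1 = c(40, 40, 30, NA),
                    snr_ch2 = c(40, 25, 30, 40),
                    snr_ch3 = c(40, 40, 30, 40))
  out <- filter_snr(pts, 30)
  expect_identical(out$snr_pass, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("MAD filtering follows the raw-MAD definition", {
  vals <- c(2, 3, 3, 4, 5, 50)
  keep <- mad_filter(vals, k = 2.5)
  expect_identical(vals[!keep], 50)
  expect_true(all(mad_filter(rep(3.3, 8))))
  # symmetric values all within 2.5 MAD survive
  expect_true(all(mad_filter(c(-2, -1, 0, 1, 2), k = 2.5)))
})

test_that("the filter chain is permutation-invariant and idempotent", {
  map <- toy_map()
  set.seed(79)
  n <- 80
  pts <- data.frame(
    x = runif(n, 45, 155), y = runif(n, 45, 155),
    lifetime_ch1 = rnorm(n, 4, .2), lifetime_ch2 = rnorm(n, 3.3, .2),
    lifetime_ch3 = rnorm(n, 2.8, .2),
    intratio_ch1 = rnorm(n, .45, .04), intratio_ch2 = rnorm(n, .33, .04),
    intratio_ch3 = rnorm(n, .22, .04),
    snr_ch1 = rnorm(n, 40, 4), snr_ch2 = rnorm(n, 40, 4),
    snr_ch3 = rnorm(n, 40, 4), dropped = FALSE)
  chain <- function(d) {
    apply_filters(exclude_heterogeneous(assign_labels(d, map, 10), map, 10),
                  snr_db = 30, mad_k = 2.5)
  }
  out <- chain(pts)
  # permutation invariance
  perm <- sample(n)
  out_p <- chain(pts[perm, ])
  reord <- out_p[order(perm), ]
  rownames(reord) <- rownames(out)
  expect_equal(reord$analysis_ready, out$analysis_ready)
  expect_equal(reord$mad_pass_all, out$mad_pass_all)
  expect_equal(reord$condition, out$condition)
  # idempotence: re-running the chain on its own output changes no flags
  out2 <- chain(out[names(pts)])
  expect_identical(out2$analysis_ready, out$analysis_ready)
  expect_identical(out2$mad_pass_all, out$mad_pass_all)
  expect_identical(attr(out2, "filter_counts"), attr(out, "filter_counts"))
})

test_that("interior points of a clean scan overwhelmingly survive", {
  map <- toy_map()
  set.seed(80)
  n <- 100
  half <- n / 2
  pts <- data.frame(
    x = c(runif(half, 45, 75), runif(half, 125, 155)),
    y = runif(n, 45, 155),
    lifetime_ch1 = rnorm(n, 4, .2), lifetime_ch2 = rnorm(n, 3.3, .2),
    lifetime_ch3 = rnorm(n, 2.8, .2),
    intratio_ch1 = rnorm(n, .45, .04), intratio_ch2 = rnorm(n, .33, .04),
    intratio_ch3 = rnorm(n, .22, .04),
    snr_ch1 = rnorm(n, 45, 2), snr_ch2 = rnorm(n, 45, 2),
    snr_ch3 = rnorm(n, 45, 2), dropped = FALSE)
  out <- apply_filters(
    exclude_heterogeneous(assign_labels(pts, map, 10), map, 10))
  expect_gte(sum(out$analysis_ready) / n, 0.95)
})
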