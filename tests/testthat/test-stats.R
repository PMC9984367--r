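test_that("descriptive statistics compute the coefficient of variation", {
  # CV = 100 * SD / mean at the kernel-weight scale of the study
  d <- descriptive_stats(c(44.5 - 10.7, 44.5, 44.5 + 10.7), rep("cv", 3))
  expect_equal(d$mean, 44.5)
  expect_equal(d$sd, 10.7)
  expect_equal(d$cv, 100 * 10.7 / 44.5, tolerance = 1e-12)
  expect_equal(round(d$cv, 0), 24)

  const <- descriptive_stats(rep(5, 4), rep("x", 4))
  expect_equal(const$cv, 0)
  single <- descriptive_stats(3.2, "y")
  expect_true(is.na(single$sd) && is.na(single$cv))
})

test_that("ANOVA F matches a brute-force sum-of-squares computation", {
  set.seed(12)
  v <- c(rnorm(8, 0), rnorm(12, 1), rnorm(10, 3))
  g <- factor(rep(c("a", "b", "c"), c(8, 12, 10)))
  d <- anova_duncan(v, g)
  means <- tapply(v, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (means - mean(v))^2)
  ssw <- sum((v - means[g])^2)
  F_brute <- (ssb / 2) / (ssw / (30 - 3))
  expect_equal(d$F, F_brute, tolerance = 1e-10)
  expect_equal(d$MSE, ssw / 27, tolerance = 1e-10)
})

test_that("Duncan grouping separates well-separated means and merges equal ones", {
  set.seed(33)
  v <- c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 5))
  g <- rep(c("g1", "g2", "g3"), each = 30)
  d <- anova_duncan(v, g)
  lt <- setNames(d$groups$letters, d$groups$group)
  expect_equal(lt[["g1"]], lt[["g2"]])
  expect_false(lt[["g3"]] %in% c(lt[["g1"]], lt[["g2"]]))

  dup <- anova_duncan(c(v[1:30], v[1:30] + rnorm(30, 0, 1e-8)),
                      rep(c("x", "x2"), each = 30))
  expect_equal(length(unique(dup$groups$letters)), 1)
})

test_that("groups with different letters differ by more than the least range", {
  set.seed(44)
  v <- c(rnorm(15, 0), rnorm(15, 1.2), rnorm(15, 2.4), rnorm(15, 8))
  g <- rep(paste0("t", 1:4), each = 15)
  d <- anova_duncan(v, g)
  gr <- d$groups  # sorted ascending by mean
  nh <- 4 / sum(1 / gr$n)
  for (i in seq_len(nrow(gr) - 1)) for (j in (i + 1):nrow(gr)) {
    shared <- any(strsplit(gr$letters[i], "")[[1]] %in%
                  strsplit(gr$letters[j], "")[[1]])
    if (!shared) {
      span <- j - i + 1
      Rp <- qtukey((1 - 0.05)^(span - 1), span, d$df[2]) * sqrt(d$MSE / nh)
      expect_gt(gr$mean[j] - gr$mean[i], Rp)
    }
  }
})

test_that("Duncan test rejects degenerate designs", {
  expect_error(anova_duncan(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(anova_duncan(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 observations")
  expect_error(anova_duncan(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("Kruskal-Wallis matches hand-computed ranks on a small table", {
  # 3 groups x 5 observations, no ties
  v <- c(27, 2, 4, 18, 7,  9, 5, 11, 10, 26,  1, 8, 17, 16, 3)
  g <- rep(c("a", "b", "c"), each = 5)
  kw <- kruskal_wallis(v, g)
  r <- rank(v)
  Rj <- tapply(r, g, sum)
  H_hand <- 12 / (15 * 16) * sum(Rj^2 / 5) - 3 * 16
  expect_equal(kw$H, H_hand, tolerance = 1e-10)
  expect_equal(kw$p_value, 1 - pchisq(H_hand, 2), tolerance = 1e-12)

  same <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  set.seed(3)
  shifted <- kruskal_wallis(c(rnorm(20), rnorm(20, 5)),
                            rep(c("a", "b"), each = 20))
  expect_lt(shifted$p_value, 1e-6)
})

test_that("Pearson correlation has its closed-form limits and affine invariance", {
  x <- c(2, 4, 7, 1, 9)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  r0 <- pearson_cor(x, c(5, 3, 8, 2, 7))
  r_aff <- pearson_cor(3 * x + 2, c(5, 3, 8, 2, 7))
  expect_equal(r0$r, r_aff$r, tolerance = 1e-12)
  r_neg <- pearson_cor(-2 * x, c(5, 3, 8, 2, 7))
  expect_equal(r_neg$r, -r0$r, tolerance = 1e-12)
})

test_that("correlations across printed cultivar means match the study", {
  HI <- c(21.4, 71.2, 26.1, 21.4, 70.6)
  D <- c(2.49, 2.59, 2.45, 2.48, 2.58)
  expect_equal(pearson_cor(D, HI)$r, 0.952, tolerance = 0.001)
  Er <- c(57.1, 73.0, 47.2, 54.8, 69.5)
  expect_equal(pearson_cor(Er, HI)$r, 0.906, tolerance = 0.001)
})

test_that("the normality gate routes to the right test", {
  set.seed(55)
  normal <- compare_groups(c(rnorm(20), rnorm(20, 3)),
                           rep(c("a", "b"), each = 20))
  expect_equal(attr(normal, "test"), "anova_duncan")
  skewed <- compare_groups(c(rlnorm(20, sdlog = 2), rlnorm(20, 2, sdlog = 2)),
                           rep(c("a", "b"), each = 20))
  expect_equal(attr(skewed, "test"), "kruskal_wallis")
})
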