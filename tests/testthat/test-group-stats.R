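test_that("ROUT keeps homogeneous samples and removes a gross outlier", {
  base <- c(1.0, 1.1, 0.9, 1.05, 1.02)
  r <- rout_outliers(base)
  expect_length(r$removed, 0)
  r2 <- rout_outliers(c(base, 50))
  expect_equal(r2$removed, 50)
  expect_setequal(r2$kept, base)
  # verify against direct computation of the FDR boundary for the extreme
  x <- c(base, 50)
  res <- abs(x - median(x))
  rsdr <- unname(quantile(res, 0.6827, type = 7)) * 6 / 5
  p_extreme <- 2 * pt(-max(res) / rsdr, df = 5)
  expect_lt(p_extreme, 0.05 * 6 / 6)
  p_next <- 2 * pt(-sort(res, decreasing = TRUE)[2] / rsdr, df = 5)
  expect_gt(p_next, 0.05 * 5 / 6)
})

test_that("ROUT handles degenerate scale and small n", {
  r <- rout_outliers(rep(3.3, 6))
  expect_length(r$removed, 0)
  expect_warning(r2 <- rout_outliers(c(1, 2, 100)), "fewer than 4")
  expect_length(r2$removed, 0)
  # order independence
  set.seed(2)
  x <- c(rnorm(20), 25, -30)
  a <- rout_outliers(x)
  b <- rout_outliers(rev(x))
  expect_setequal(a$removed, b$removed)
})

test_that("Kruskal-Wallis H matches hand-computed ranks; ties degenerate", {
  kd <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  # ranks 1..9: H = 12/(9*10) * (36 + 225 + 576)/3 - 3*10 = 7.2
  expect_equal(kd$H, 7.2)
  expect_equal(kd$df, 2)
  all_tied <- kruskal_dunn(list(a = rep(1, 3), b = rep(1, 3), c = rep(1, 3)))
  expect_equal(all_tied$H, 0)
  expect_equal(all_tied$p_value, 1)
  expect_error(kruskal_dunn(list(a = 1:3, b = 1:3)), "at least 3 groups")
  expect_error(kruskal_dunn(list(a = 1:2, b = 1:3, c = 1:3)),
               "at least 3 values")
})

test_that("Dunn flags only pairs involving a strongly shifted group", {
  set.seed(11)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 8)
  kd <- kruskal_dunn(g)
  pw <- kd$pairwise
  expect_gt(pw$adjusted_p[pw$comparison == "a vs b"], 0.05)
  expect_lt(pw$adjusted_p[pw$comparison == "a vs c"], 0.05)
  expect_lt(pw$adjusted_p[pw$comparison == "b vs c"], 0.05)
})

test_that("group tests are invariant to label permutation", {
  set.seed(12)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  p1 <- kruskal_dunn(g)$p_value
  p2 <- kruskal_dunn(g[c("c", "a", "b")])$p_value
  expect_equal(p1, p2)
  m1 <- mann_whitney(g$a, g$b)$p_value
  m2 <- mann_whitney(g$b, g$a)$p_value
  expect_equal(m1, m2)
})

test_that("Mann-Whitney: exact small-sample enumeration and identity", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)   # 2 * (1/20), all 20 arrangements
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.99)
  expect_error(mann_whitney(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("GG epsilon: exact 1 for two levels, matches the formula oracle", {
  set.seed(13)
  d2 <- expand.grid(subject = 1:10, within = 1:2)
  d2$between <- rep(rep(c("A", "B"), each = 5), 2)
  d2$value <- rnorm(20)
  res2 <- rm_anova_gg(d2)
  expect_identical(res2$epsilon, 1)

  d3 <- expand.grid(subject = 1:8, within = 1:3)
  d3$between <- rep(rep(c("A", "B"), each = 4), 3)
  d3$value <- rnorm(24) + 0.5 * as.numeric(d3$within)
  res3 <- rm_anova_gg(d3)
  wide <- tapply(d3$value, list(d3$subject, d3$within), mean)
  grp <- rep(c("A", "B"), each = 4)
  expect_equal(res3$epsilon, oracle_gg_epsilon(wide, grp), tolerance = 1e-10)
  expect_gte(res3$epsilon, 0.5)   # lower bound 1/(k-1)
  expect_lte(res3$epsilon, 1)
})

test_that("GG-corrected mixed ANOVA agrees with car::Anova", {
  skip_if_not_installed("car")
  set.seed(14)
  n <- 12
  k <- 4
  wide <- matrix(rnorm(n * k), n, k)
  wide[, 2] <- wide[, 2] + wide[, 1] * 0.8      # break sphericity
  grp <- rep(c("A", "B", "C"), each = 4)
  long <- data.frame(
    subject = rep(seq_len(n), k),
    within = rep(seq_len(k), each = n),
    between = rep(grp, k),
    value = as.vector(wide)
  )
  mine <- rm_anova_gg(long)

  dfw <- data.frame(grp = factor(grp))
  mlm <- lm(wide ~ grp, data = dfw)
  av <- suppressWarnings(
    summary(car::Anova(mlm, idata = data.frame(level = factor(1:k)),
                       idesign = ~level),
            multivariate = FALSE)
  )
  gg <- av$pval.adjustments
  expect_equal(mine$epsilon, unname(gg["level", "GG eps"]), tolerance = 1e-8)
  expect_equal(mine$effects$p_gg[mine$effects$effect == "within"],
               unname(gg["level", "Pr(>F[GG])"]), tolerance = 1e-8)
  expect_equal(mine$effects$p_gg[mine$effects$effect == "between:within"],
               unname(gg["grp:level", "Pr(>F[GG])"]), tolerance = 1e-8)
})

test_that("incomplete subjects are excluded listwise with a warning", {
  set.seed(15)
  d <- expand.grid(subject = 1:6, within = 1:3)
  d$between <- rep(rep(c("A", "B"), each = 3), 3)
  d$value <- rnorm(18)
  d <- d[-1, ]                                    # subject 1 incomplete
  expect_warning(res <- rm_anova_gg(d), "listwise")
  expect_equal(res$effects$df2[res$effects$effect == "between"], 3)  # 5 - 2
})

test_that("one-phase association fit recovers noiseless parameters", {
  x <- rep(seq(20, 480, 20), 2)
  y <- 1 * (1 - exp(-0.01 * x))
  ft <- one_phase_f_test(x, y, rep(c("A", "B"), 24))
  expect_equal(unname(ft$shared[["plateau"]]), 1, tolerance = 1e-6)
  expect_equal(unname(ft$shared[["k"]]), 0.01, tolerance = 1e-6)
  expect_lt(ft$F, 1e-6)
  expect_error(one_phase_f_test(c(-1, x), c(0, y), rep("A", 49)),
               "non-negative")
})

test_that("one-phase F-test separates groups with different plateaus", {
  set.seed(16)
  x <- rep(seq(20, 480, 20), 2)
  gr <- rep(c("A", "B"), each = 24)
  rej <- replicate(100, {
    y <- ifelse(gr == "A", 1, 0.5) * (1 - exp(-0.01 * x)) +
      rnorm(48, 0, 0.08)
    one_phase_f_test(x, y, gr)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("line F-test through the origin distinguishes slopes", {
  set.seed(17)
  x <- rep(seq(20, 480, 20), 2)
  gr <- rep(c("A", "B"), each = 24)
  same <- line_f_test(x, 0.001 * x + rnorm(48, 0, 0.05), gr)
  expect_gt(same$p_value, 0.01)
  diff_ <- line_f_test(x, ifelse(gr == "A", 0.002, 0.001) * x +
                         rnorm(48, 0, 0.02), gr)
  expect_lt(diff_$p_value, 0.001)
})

test_that("larger group separation never raises the median p (monotone)", {
  set.seed(18)
  shifts <- c(0, 0.5, 1, 2, 4)
  med_p <- vapply(shifts, function(s) {
    median(replicate(60, {
      mann_whitney(rnorm(12), rnorm(12) + s)$p_value
    }))
  }, numeric(1))
  expect_true(all(diff(med_p) <= 1e-12))
})
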