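test_that("the ERC filter is strict on both count and sample fraction", {
  n <- 10L
  counts <- rbind(
    at10 = rep(10, n),              # exactly 10 everywhere: removed
    half11 = c(rep(11, 5), rep(0, 5)),  # >10 in exactly 50%: removed
    all11 = rep(11, n),             # kept
    most = c(rep(50, 6), rep(1, 4)))    # >10 in 60%: kept
  kept <- filter_genes(counts)
  expect_identical(rownames(kept), c("all11", "most"))
})

test_that("bh_fdr matches hand-worked and brute-force step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  grid <- seq(0, 1, by = 0.01)
  # exhaustive: all length-1 and length-2 grid lists
  for (p1 in grid) expect_equal(bh_fdr(p1), min(p1, 1))
  pairs <- expand.grid(a = grid, b = grid)
  got <- mapply(function(a, b) bh_fdr(c(a, b)), pairs$a, pairs$b)
  want <- mapply(function(a, b) oracle_bh(c(a, b)), pairs$a, pairs$b)
  expect_equal(got, want)
  # random longer lists, against both the oracle and stats::p.adjust
  set.seed(13)
  for (len in 3:8) {
    for (rep_i in 1:25) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_fdr(p), oracle_bh(p))
      expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"))
    }
  }
})

test_that("unadjusted correlation matches the textbook t-transform", {
  x <- 1:10
  expect_equal(corr_unadjusted(x, 2 * x)$r, 1)
  expect_equal(corr_unadjusted(x, -x + 7)$r, -1)

  set.seed(17)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  got <- corr_unadjusted(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(28 / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
  expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  z <- corr_unadjusted(rep(1, 5), rnorm(5))
  expect_true(is.na(z$r))
  expect_identical(z$flag, "zero_variance")
})

test_that("age adjustment removes group-level offsets exactly", {
  set.seed(19)
  g <- factor(rep(c("6m", "14m"), each = 10))
  x <- rnorm(20)
  y <- x + ifelse(g == "14m", 100, 0)  # pooled r far from 1
  got <- corr_age_adjusted(y, x, g)
  expect_equal(got$r, 1)
  expect_lt(cor(y, x), 1)
  expect_equal(got$df, 20 - 2 - 1)

  # single group reduces to the unadjusted r (df differs)
  g1 <- factor(rep("a", 20))
  expect_equal(corr_age_adjusted(y, x, g1)$r, cor(y, x))
  expect_warning(
    corr_age_adjusted(rnorm(11), rnorm(11),
                      factor(c(rep("a", 10), "b"))), "n < 2")
})

test_that("confounded associations vanish under age adjustment", {
  # expression and load both shift with age but are conditionally
  # independent: r_adjusted should center on 0
  set.seed(23)
  nrep <- 200
  g <- factor(rep(c("6m", "14m"), c(17, 20)))
  radj <- replicate(nrep, {
    load <- rnorm(37, ifelse(g == "14m", 8, 4), 1)
    expr <- rnorm(37, ifelse(g == "14m", 2, 0), 1)
    corr_age_adjusted(expr, load, g)$r
  })
  ci <- mean(radj) + c(-1, 1) * 1.96 * sd(radj) / sqrt(nrep)
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(abs(mean(radj)), 0.05)
})

test_that("gene classification follows the two-p-value rule", {
  cls <- classify_genes(c(0.01, 0.20, 0.01, 0.20),
                        c(0.20, 0.01, 0.01, 0.20))
  expect_identical(as.character(cls),
                   c("age_dependent", "age_independent", "both", "ns"))
})

test_that("the age-effect ANOVA reduces to known identities", {
  # two-group one-factor case: F equals the squared pooled-variance t
  set.seed(29)
  load <- c(rnorm(17, 5), rnorm(20, 6))
  age <- factor(rep(c("6m", "14m"), c(17, 20)))
  strain <- factor(rep("s1", 37))
  got <- age_effect_test(load, age, strain)
  tt <- t.test(load ~ age, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)

  # balanced two-factor design with identical responses in both age
  # groups: the age term explains nothing, F = 0 and p = 1
  strain2 <- factor(rep(rep(c("a", "b"), 5), 2))
  age2 <- factor(rep(c("6m", "14m"), each = 10))
  load2 <- rep(c(1, 5, 2, 7, 3, 6, 1, 8, 4, 9), 2)
  got2 <- age_effect_test(load2, age2, strain2)
  expect_lt(abs(got2$F), 1e-10)
  expect_gt(got2$p, 0.999)

  # age confounded with strain: flagged
  conf <- age_effect_test(rnorm(10), factor(rep(c("x", "y"), each = 5)),
                          factor(rep(c("s1", "s2"), each = 5)))
  expect_identical(conf$flag, "age_aliased")

  # matches car-style Type II on an unbalanced design via model comparison
  set.seed(31)
  n <- 24
  age3 <- factor(sample(c("6m", "14m"), n, replace = TRUE))
  strain3 <- factor(sample(paste0("s", 1:4), n, replace = TRUE))
  load3 <- rnorm(n) + as.numeric(age3) + 0.5 * as.numeric(strain3)
  got3 <- age_effect_test(load3, age3, strain3)
  a_full <- lm(load3 ~ age3 + strain3)
  a_red <- lm(load3 ~ strain3)
  av <- anova(a_red, a_full)
  expect_equal(got3$F, av$F[2], tolerance = 1e-10)
  expect_equal(got3$p, av$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("a strong age shift is detected with the study's group sizes", {
  set.seed(37)
  nrep <- 200
  hits <- replicate(nrep, {
    age <- factor(rep(c("6m", "14m"), c(17, 20)))
    strain <- factor(sample(paste0("s", 1:5), 37, replace = TRUE))
    load <- rnorm(37, sd = 1) + ifelse(age == "14m", 3, 0)
    age_effect_test(load, age, strain)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the paired signed-rank test matches exact enumeration", {
  expect_equal(method_difference_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_identical(method_difference_test(c(1, 2), c(1, 2))$flag, "all_zero")

  # n = 6, all shifts positive: two-sided exact p = 2/64
  x <- c(10, 11, 12, 13, 14, 15)
  y <- x + c(1, 2, 3, 4, 5, 6)
  got <- method_difference_test(x, y)
  expect_equal(got$p, 2 / 64)
  expect_identical(got$method, "exact")
  expect_equal(got$p, oracle_signrank_p(y - x))
  expect_equal(got$p, wilcox.test(y, x, paired = TRUE)$p.value)

  # random untied cases vs full sign enumeration and stats::wilcox.test
  set.seed(41)
  for (rep_i in 1:10) {
    d <- round(rnorm(7), 3)
    d <- d[d != 0]
    if (length(d) < 3 || any(duplicated(abs(d)))) next
    got <- method_difference_test(rep(0, length(d)), d)
    expect_equal(got$p, oracle_signrank_p(d))
    expect_equal(got$p, wilcox.test(d)$p.value)
  }

  # antisymmetric differences sit at the null center
  d <- c(-3, -2, -1, 1, 2, 3)
  got <- method_difference_test(rep(0, 6), d)
  mu <- 6 * 7 / 4
  expect_equal(got$statistic, mu)

  # ties fall back to the tie-corrected normal approximation
  tied <- method_difference_test(rep(0, 30), rep(c(1, -1, 2), 10))
  expect_identical(tied$method, "normal_tie_corrected")
  expect_true(tied$p >= 0 && tied$p <= 1)
})

test_that("region-level wrappers attach BH-adjusted q values", {
  set.seed(43)
  loads <- data.frame(
    region_id = rep(1:4, each = 12),
    load_pct = rnorm(48, 10),
    age_group = factor(rep(rep(c("6m", "14m"), each = 6), 4)),
    strain = factor(rep(rep(c("a", "b"), 6), 4)))
  res <- age_effect_by_region(loads)
  expect_equal(nrow(res), 4L)
  expect_equal(res$q, bh_fdr(res$p))

  lin <- data.frame(brain_id = rep(paste0("b", 1:8), 2),
                    region_id = rep(c(1L, 2L), each = 8),
                    load_pct = rnorm(16, 10))
  non <- lin; non$load_pct <- lin$load_pct + rnorm(16, 0.5, 0.2)
  mdr <- method_difference_by_region(lin, non)
  expect_equal(nrow(mdr), 2L)
  expect_equal(mdr$q, bh_fdr(mdr$p))
})
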