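test_that("larval datapoints are per-larva means", {
  expect_equal(larvalDatapoint(5), 5)
  expect_equal(larvalDatapoint(c(1, 3)), 2)
  dp <- larvalDatapoint(c(1, 3, 10, 20), c("a", "a", "b", "b"))
  expect_equal(unname(dp), c(2, 15))
})

test_that("between-larva variance of datapoints matches the nested model", {
  sigL <- 0.5; sigN <- 1; m <- 4
  vars <- vapply(1:300, function(s) {
    set.seed(s)
    larva <- rep(1:12, each = m)
    y <- rnorm(12, 0, sigL)[larva] + rnorm(12 * m, 0, sigN)
    var(larvalDatapoint(y, larva))
  }, numeric(1))
  expect_equal(mean(vars), sigL^2 + sigN^2 / m, tolerance = 0.05)
})

test_that("normality gate routes as expected", {
  # Normal samples: parametric route about 90% of the time (two groups)
  routes <- vapply(1:300, function(s) {
    set.seed(s)
    normalityGate(c(rnorm(20), rnorm(20)),
                  rep(c("a", "b"), each = 20))$route
  }, character(1))
  p <- mean(routes == "parametric")
  expect_gt(p, 0.85)
  expect_lt(p, 0.95)
  # strong lognormal group: nonparametric almost surely
  set.seed(77)
  g <- normalityGate(c(rnorm(50), exp(rnorm(50, sd = 1))),
                     rep(c("a", "b"), each = 50))
  expect_equal(g$route, "nonparametric")
  expect_error(normalityGate(c(1, 1, 1, 2, 3, 4),
                             rep(c("a", "b"), each = 3)), "zero variance")
  expect_error(normalityGate(c(1, 2, 5, 6), c("a", "a", "b", "b")),
               "at least 3")
})

test_that("identical samples give t = 0 and p = 1", {
  g <- c(1.2, 3.4, 2.2, 4.8)
  res <- twoGroupTest(g, g, route = "parametric")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(twoGroupTest(rep(2, 4), rep(2, 4), route = "parametric"),
               "degenerate")
})

test_that("summary-statistic t test reproduces the published bouton-count contrast", {
  res <- tTestFromSummary(24.6, 0.5, 18, 27.8, 1.0, 17)
  expect_equal(res$df, 33)
  # textbook-formula oracle, frozen: sp2 = (17*4.5 + 16*17)/33, t = -3.2/se
  se <- sqrt((17 * (0.5 * sqrt(18))^2 + 16 * (1.0 * sqrt(17))^2) / 33 *
               (1 / 18 + 1 / 17))
  expect_equal(res$statistic, -3.2 / se, tolerance = 1e-12)
  # the publication reports P = 0.0075 from unrounded raw data; the
  # rounded summaries land near it
  expect_lt(abs(res$p_value - 0.0075), 0.003)
  expect_lt(res$p_value, 0.05)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  res <- twoGroupTest(c(1, 2, 3), c(4, 5, 6), route = "nonparametric")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(mwExactP(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(88)
  for (rep in 1:6) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, 1)
    res <- twoGroupTest(x, y, route = "nonparametric")
    expect_equal(res$p_value, mwExactP(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation approaches the exact Mann-Whitney p", {
  set.seed(89)
  diffs <- vapply(1:10, function(i) {
    x <- rnorm(8); y <- rnorm(8, 0.8)
    pEx <- mwExactP(x, y)
    pAp <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))$p.value
    abs(pAp - pEx) / pEx
  }, numeric(1))
  expect_lt(median(diffs), 0.1)
})

test_that("swapping groups flips t but not p", {
  set.seed(90)
  x <- rnorm(10); y <- rnorm(10, 1)
  a <- twoGroupTest(x, y, route = "parametric")
  b <- twoGroupTest(y, x, route = "parametric")
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_gte(a$p_value, 0)
  expect_lte(a$p_value, 1)
})

test_that("mixed-design ANOVA reports the three design effects", {
  co <- simulateCohort(nLarvae = 6, frequencies = c(20, 50), seed = 2)
  res <- multiGroupTest(data.frame(value = co$max_dff,
                                   genotype = co$genotype,
                                   frequency = co$frequency,
                                   larva_id = co$larva_id))
  expect_setequal(res$effects$term,
                  c("genotype", "frequency", "genotype:frequency"))
  expect_lt(res$effects$p_value[res$effects$term == "genotype"], 0.05)
  expect_true(all(res$effects$p_value >= 0 & res$effects$p_value <= 1))
})

test_that("mixed-design genotype test holds its type-I error under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(s + 4000)
    d <- expand.grid(larva_id = 1:8, genotype = c("a", "b"),
                     frequency = c(10, 40))
    d$larva_id <- paste(d$genotype, d$larva_id)
    lv <- rnorm(16, 0, 0.5)
    names(lv) <- unique(d$larva_id)
    d$value <- lv[d$larva_id] + rnorm(nrow(d))
    res <- multiGroupTest(d)
    res$effects$p_value[res$effects$term == "genotype"]
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("a single frequency level reduces to the two-sample comparison", {
  set.seed(91)
  d <- data.frame(value = c(rnorm(8), rnorm(8, 1)),
                  genotype = rep(c("a", "b"), each = 8),
                  frequency = 50,
                  larva_id = paste0("L", 1:16))
  res <- multiGroupTest(d)
  tt <- twoGroupTest(d$value[d$genotype == "a"],
                     d$value[d$genotype == "b"], route = "parametric")
  expect_equal(res$effects$statistic[1], tt$statistic^2, tolerance = 1e-9)
  expect_equal(res$effects$p_value[1], tt$p_value, tolerance = 1e-9)
})

test_that("one-way nonparametric route runs Kruskal-Wallis", {
  set.seed(92)
  v <- c(rexp(10), rexp(10), rexp(10, 0.2))
  g <- rep(letters[1:3], each = 10)
  res <- multiGroupTest(values = v, groups = g, route = "nonparametric")
  expect_equal(res$test, "Kruskal-Wallis")
  expect_equal(res$effects$p_value,
               stats::kruskal.test(v, factor(g))$p.value)
})

test_that("Tukey with two groups equals the unadjusted comparison", {
  set.seed(93)
  x <- rnorm(9); y <- rnorm(9, 0.5)
  ph <- postHoc(c(x, y), rep(c("a", "b"), each = 9), method = "tukey")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("Dunnett compares each group to the control only", {
  set.seed(94)
  v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  g <- rep(c("WT", "m1", "m2"), each = 8)
  ph <- postHoc(v, g, method = "dunnett", controlLabel = "WT")
  expect_equal(nrow(ph), 2L)
  expect_true(all(grepl("WT", ph$comparison)))
  expect_error(postHoc(v, g, method = "dunnett"), "control")
})

test_that("Tukey familywise error stays at the nominal level under the null", {
  anyRej <- vapply(1:200, function(s) {
    set.seed(s + 6000)
    v <- rnorm(24)
    g <- rep(letters[1:3], each = 8)
    any(postHoc(v, g, method = "tukey")$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(anyRej), 0.08)
})
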