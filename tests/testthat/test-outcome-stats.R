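test_that("Spearman rho and exact p match enumeration-based references", {
  expect_equal(spearman_test(c(1, 2, 3), c(10, 20, 30))$estimate, 1.0)
  expect_equal(spearman_test(c(1, 2, 3), c(30, 20, 10))$estimate, -1.0)
  r <- spearman_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8)
  expect_equal(r$p.value, 1 / 3)  # 8 of 24 pairings reach |rho| >= 0.8
  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    mine <- spearman_test(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$estimate, unname(ref$estimate))
  }
  # large-n path agrees with the t approximation
  set.seed(32)
  x <- rnorm(20); y <- x + rnorm(20)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(spearman_test(x, y)$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  km <- km_estimate(c(5, 10, 15, 20), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.50, 0.25, 0))
  km2 <- km_estimate(c(5, 10, 15, 20), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(km2$survival[km2$time == 5], 0.75)
  expect_equal(km2$survival[km2$time == 15], 0.375)  # 0.75 * (1 - 1/2)
  expect_equal(km2$survival[km2$time == 20], 0)
  km3 <- km_estimate(c(5, 10), c(FALSE, FALSE))
  expect_equal(km3$survival, c(1, 1))
  expect_true(all(diff(km2$survival) <= 0))
  expect_error(km_estimate(c(0, 5), c(TRUE, TRUE)), "positive")
})

test_that("log-rank agrees with survdiff and behaves under symmetry", {
  time <- c(5, 8, 12, 20, 33, 40)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  sym <- logrank_test(rep(time, 2), rep(ev, 2), rep(c("A", "B"), each = 6))
  expect_equal(sym$chisq, 0)
  expect_equal(sym$p.value, 1)
  # group A fails first: O_A > E_A, chisq > 0
  t2 <- c(1, 2, 3, 10, 11, 12)
  g2 <- rep(c("A", "B"), each = 3)
  dir <- logrank_test(t2, rep(TRUE, 6), g2)
  expect_gt(dir$chisq, 0)
  expect_gt(dir$observed["A"], dir$expected["A"])
  skip_if_not_installed("survival")
  set.seed(41)
  for (i in 1:15) {
    n <- sample(10:40, 1)
    tt <- round(stats::rexp(n, 1 / 50)) + 1
    e <- stats::runif(n) < 0.7
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(e) < 1) next
    mine <- logrank_test(tt, e, g)
    ref <- survival::survdiff(survival::Surv(tt, e) ~ g)
    expect_equal(mine$chisq, unname(ref$chisq), tolerance = 1e-10)
  }
  expect_error(logrank_test(time, ev, rep("A", 6)), "2 groups")
  expect_error(logrank_test(time, rep(FALSE, 6), rep(c("A", "B"), 3)),
               "at least one event")
})

test_that("permutation log-rank p matches its sampled null distribution", {
  time <- c(5, 8, 12, 20, 33, 40, 7, 15, 22, 30, 44, 60)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
          TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  g <- rep(c("A", "B"), each = 6)
  pp <- logrank_test(time, ev, g, p_method = "permutation")
  expect_match(pp$p.method, "enumeration")
  expect_true(pp$p.value >= 0 && pp$p.value <= 1)
  # chisq statistic itself is unchanged by the p method
  expect_equal(pp$chisq, logrank_test(time, ev, g)$chisq)
})

test_that("Mantel-Haenszel hazard ratio respects symmetry and relabeling", {
  time <- rep(c(5, 8, 12, 20, 33, 40), 2)
  ev <- rep(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), 2)
  g <- rep(c("A", "B"), each = 6)
  expect_equal(mh_hazard_ratio(time, ev, g)$hr, 1.0)
  set.seed(42)
  t2 <- round(stats::rexp(40, 1 / 100)) + 1
  e2 <- stats::runif(40) < 0.8
  g2 <- factor(rep(c("hi", "lo"), 20), levels = c("hi", "lo"))
  h1 <- mh_hazard_ratio(t2, e2, g2)
  h2 <- mh_hazard_ratio(t2, e2, factor(g2, levels = c("lo", "hi")))
  expect_equal(h2$hr, 1 / h1$hr)
  expect_equal(sort(h2$ci), sort(1 / h1$ci))
  expect_true(h1$ci[1] <= h1$hr && h1$hr <= h1$ci[2])
  h3 <- mh_hazard_ratio(t2, e2, g2, method = "oe_ratio")
  expect_equal(sign(log(h3$hr)), sign(log(h1$hr)))
})

test_that("Mann-Whitney exact and approximate paths match references", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p.value, 0.1)  # 2 * 1/20 arrangements
  a <- c(3, 1, 4, 1, 5)
  same <- mann_whitney(a, a)
  expect_equal(same$U, length(a)^2 / 2)
  expect_equal(same$p.value, 1)
  # p decreases monotonically as the shift grows (exact path)
  ps <- sapply(c(0, 2, 5, 100), function(s)
    mann_whitney(c(1.1, 2.2, 3.3) + s, c(1.5, 2.7, 3.9))$p.value)
  expect_true(all(diff(ps) <= 1e-12))
  set.seed(51)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    v <- sample(1000, na + nb)
    mine <- mann_whitney(v[1:na], v[-(1:na)])
    ref <- stats::wilcox.test(v[1:na], v[-(1:na)], exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal approximation against wilcox.test
  set.seed(52)
  x <- sample(1:8, 20, replace = TRUE); y <- sample(3:10, 18, replace = TRUE)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mann_whitney(x, y)$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the hand rank formula and is rank-based", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 4.571, tolerance = 1e-3)
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p.value, 1)
  # invariance under a strictly monotone transform
  kw2 <- kruskal_wallis(lapply(g, function(v) exp(v) + 5))
  expect_equal(kw2$H, kw$H)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "3 groups")
})

test_that("cohort association recovers direction and survives degeneracy", {
  co <- simulate_cohort(sim_config(seed = 7))
  cv <- fit_cohort(co$viability, fit = FALSE)
  pr <- build_profiles(cv, co$clinical)
  as <- associate_cohort(pr$profiles, co$clinical)
  expect_gt(as$spearman$estimate, 0)
  expect_true(as$overall$logrank$p.value >= 0 && as$overall$logrank$p.value <= 1)
  expect_equal(as$n_total, 54)
  # all patients excluded -> structured empty report, no crash
  cl2 <- co$clinical
  cl2$excluded_reason <- "best supportive care without chemotherapy"
  empty <- associate_cohort(pr$profiles, cl2)
  expect_equal(empty$n_evaluable, 0)
  expect_null(empty$spearman)
  expect_match(empty$overall$note, "degenerate")
})
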