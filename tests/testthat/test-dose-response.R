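test_that("viability normalization maps vehicle mean to exactly 1", {
  tbl <- data.frame(organoid = "A", drug = "5-FU",
                    concentration_um = c(10, 1, 0, 0),
                    replicate = c(1, 1, 1, 2),
                    signal = c(5000, 10000, 9000, 11000))
  out <- normalize_viability(tbl)
  expect_equal(out$viability[1], 0.5)       # 5000 / mean(9000, 11000)
  expect_equal(out$viability[2], 1.0)       # equal to vehicle mean
  tbl$signal[1] <- 0
  expect_equal(normalize_viability(tbl)$viability[1], 0)
})

test_that("normalization errors name the offending group", {
  tbl <- data.frame(organoid = c("A", "B"), drug = "5-FU",
                    concentration_um = c(10, 0), replicate = 1,
                    signal = c(100, 200))
  expect_error(normalize_viability(tbl), "A")
  tbl0 <- data.frame(organoid = "A", drug = "5-FU",
                     concentration_um = c(10, 0), replicate = 1,
                     signal = c(100, 0))
  expect_error(normalize_viability(tbl0), "zero vehicle")
})

test_that("4PL fit recovers noiseless parameters on the 6-point grid", {
  d <- rep(dose_grid(), each = 3)
  v <- fourpl(d, top = 1, bottom = 0, hill = 1, ic50 = 0.1)
  f <- fit_curve(d, v)
  expect_false(f$ic50_censored)
  expect_lt(abs(f$ic50 / 0.1 - 1), 0.01)
  # midpoint identity: fitted curve passes through (IC50, 0.55) for
  # top 1 / bottom 0.1 data
  v2 <- fourpl(d, top = 1, bottom = 0.1, hill = 1, ic50 = 0.05)
  f2 <- fit_curve(d, v2)
  expect_equal(fourpl(f2$ic50, f2$top, f2$bottom, f2$hill, f2$ic50), 0.55,
               tolerance = 1e-3)
})

test_that("a non-responding curve reports a right-censored IC50", {
  d <- dose_grid()
  f <- fit_curve(d, rep(1, length(d)))
  expect_true(f$ic50_censored)
  expect_equal(f$ic50, max(d))
})

test_that("curve fitting enforces its preconditions", {
  expect_error(fit_curve(c(10, 1, 0.1), c(1, 0.5, 0.2)), "4 distinct")
  expect_error(fit_curve(dose_grid(), c(NA, 1, 1, 1, 1, 1)), "non-finite")
})

test_that("trapezoidal AUC matches hand values and a fine-grid oracle", {
  d <- dose_grid()  # 10 ... 1e-4 uM, 5 decades
  a <- compute_auc(d, rep(1, 6))
  expect_equal(a$auc_raw, 5.0)
  expect_equal(a$auc_span, 1.0)
  expect_equal(compute_auc(d, rep(0, 6))$auc_raw, 0)
  # linear in log10 c from 1 at 1e-4 uM down to 0 at 10 uM
  v_lin <- (log10(10) - log10(d)) / 5
  expect_equal(compute_auc(d, v_lin)$auc_span, 0.5)
  # random piecewise-linear inputs against an independent Riemann-sum oracle
  set.seed(77)
  for (i in 1:10) {
    v <- runif(6)
    expect_equal(compute_auc(d, v)$auc_raw, auc_riemann_oracle(d, v),
                 tolerance = 1e-9)
  }
  expect_error(compute_auc(10, 1), "2 distinct")
})

test_that("cohort AUC normalization preserves order and pins the max at 1", {
  x <- c(a = 0.2, b = 0.4, c = 0.8)
  expect_equal(normalize_auc_cohort(x), c(a = 0.25, b = 0.5, c = 1.0))
  expect_equal(unname(normalize_auc_cohort(c(z = 0.37))), 1.0)
  set.seed(4)
  y <- runif(20)
  expect_equal(order(normalize_auc_cohort(y)), order(y))
  ties <- c(0.5, 0.8, 0.8)
  expect_equal(normalize_auc_cohort(ties), c(0.625, 1, 1))
  expect_error(normalize_auc_cohort(c(0, 0)), "no measurable")
})

test_that("fit_cohort assembles per-drug normalized AUCs", {
  vb <- make_viability(list(
    A = list(`5-FU` = 0.05, oxaliplatin = 1),
    B = list(`5-FU` = 5, oxaliplatin = 0.2),
    C = list(`5-FU` = 0.5, oxaliplatin = 20)))
  cv <- fit_cohort(vb)
  expect_equal(nrow(cv), 6)
  for (dr in unique(cv$drug))
    expect_equal(max(cv$auc_norm[cv$drug == dr]), 1.0)
  # higher IC50 -> higher AUC within a drug (noiseless)
  fu <- cv[cv$drug == "5-FU", ]
  expect_equal(fu$organoid[order(fu$auc_span)], c("A", "C", "B"))
  # AUC exists without fitting
  cv2 <- fit_cohort(vb, fit = FALSE)
  expect_equal(cv2$auc_span, cv$auc_span)
  expect_true(all(is.na(cv2$ic50_um)))
})

test_that("noisy simulated curves keep AUC monotone in latent resistance", {
  co <- simulate_cohort(sim_config(n_organoids = 12, noise_cv = 0, seed = 2))
  cv <- fit_cohort(co$viability, fit = FALSE)
  for (d in colnames(co$rho)) {
    sub <- cv[cv$drug == d, ]
    rho <- co$rho[sub$organoid, d]
    expect_true(all(diff(sub$auc_span[order(rho)]) >= -1e-12))
  }
})
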