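test_that("identical config and seed give bit-identical cohorts", {
  a <- simulate_cohort(sim_config(n_organoids = 10, seed = 42))
  b <- simulate_cohort(sim_config(n_organoids = 10, seed = 42))
  expect_identical(a$viability, b$viability)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$genotype, b$genotype)
  expect_identical(a$rho, b$rho)
  d <- simulate_cohort(sim_config(n_organoids = 10, seed = 43))
  expect_false(identical(a$viability$signal, d$viability$signal))
})

test_that("noiseless viability hits the 4PL midpoint at the true IC50", {
  # one drug with degenerate IC50 range -> IC50 = 1 uM on the grid exactly
  cfg <- sim_config(n_organoids = 3, n_replicates = 2, noise_cv = 0,
                    drugs = data.frame(drug = "5-FU", lo = 0, hi = 0),
                    seed = 1)
  co <- simulate_cohort(cfg)
  at_ic50 <- co$viability$signal[co$viability$concentration_um == 1]
  expect_equal(at_ic50, rep(0.55, length(at_ic50)))  # (1 + 0.1) / 2
  vehicle <- co$viability$signal[co$viability$concentration_um == 0]
  expect_equal(vehicle, rep(1, length(vehicle)))
})

test_that("well counts follow organoids x drugs x (doses + vehicle) x replicates", {
  cfg <- sim_config(n_organoids = 2, n_replicates = 3,
                    drugs = data.frame(drug = "5-FU", lo = -1, hi = 1),
                    seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$viability), 2 * 1 * (6 + 1) * 3)
  full <- simulate_cohort(sim_config(n_organoids = 8, seed = 5))
  expect_equal(nrow(full$viability), 8 * 4 * 7 * 3)
})

test_that("ground-truth IC50 is monotone in latent resistance per drug", {
  co <- simulate_cohort(sim_config(seed = 11))
  for (d in colnames(co$rho)) {
    ord <- order(co$rho[, d])
    expect_true(all(diff(co$ic50_um[ord, d]) >= 0))
  }
  expect_true(all(co$rho >= 0 & co$rho <= 1))
})

test_that("hotspot and RNF43 genotypes shift the targeted drugs only", {
  cfg <- sim_config(n_organoids = 40, hotspot_prob = 0.5, seed = 21)
  co <- simulate_cohort(cfg)
  hs <- co$genotype$anti_egfr_resistant
  expect_true(any(hs) && any(!hs))
  expect_gt(mean(co$rho[hs, "cetuximab"]), mean(co$rho[!hs, "cetuximab"]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_organoids = 0), "positive")
  expect_error(sim_config(drugs = data.frame()), "non-empty")
  expect_error(sim_config(n_doses = 1))
  expect_error(sim_config(dilution_factor = 1))
  expect_error(sim_config(hotspot_prob = 1.5), "probabilities")
  expect_error(sim_config(drugs = data.frame(drug = "x", lo = 1, hi = 0)),
               "well-ordered")
})

test_that("cohorts round-trip losslessly through write_cohort/read_cohort", {
  co <- simulate_cohort(sim_config(n_organoids = 6, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$viability, co$viability)
  expect_equal(back$clinical, co$clinical)
  expect_equal(back$genotype, co$genotype)
  expect_equal(back$rho, co$rho)
  expect_equal(back$ic50_um, co$ic50_um)
})

test_that("an empty cohort writes valid headers with zero data rows", {
  empty <- list(
    viability = data.frame(organoid = character(0), drug = character(0),
                           concentration_um = numeric(0),
                           replicate = integer(0), signal = numeric(0)),
    clinical = data.frame(patient = character(0), regimen = character(0),
                          size_change = numeric(0), pfs_days = numeric(0),
                          event = logical(0)),
    genotype = data.frame(organoid = character(0)),
    rho = matrix(numeric(0), 0, 0), ic50_um = matrix(numeric(0), 0, 0))
  dir <- withr::local_tempdir()
  write_cohort(empty, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$viability), 0)
  expect_true(all(c("organoid", "drug", "concentration_um") %in%
                    names(back$viability)))
})

test_that("simulated screens carry class structure and RNF43 coupling", {
  scr <- simulate_screen(n_organoids = 5, seed = 8,
                         rnf43_flags = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_length(scr$auc, 2)
  expect_equal(dim(scr$auc[[1]]), c(5, 57))
  expect_identical(dimnames(scr$auc[[1]]), dimnames(scr$auc[[2]]))
  # same seed without the flag: only the PORCN-drug column of R001 moves
  scr0 <- simulate_screen(n_organoids = 5, seed = 8, rnf43_flags = rep(FALSE, 5))
  delta <- scr$rho - scr0$rho
  expect_true(all(delta[, colnames(delta) != "LGK974"] == 0))
  expect_true(all(delta[-1, "LGK974"] == 0))
  expect_lt(delta["R001", "LGK974"], 0)
  expect_true(all(scr$auc[[1]] >= 0))
})
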