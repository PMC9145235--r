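# EM-REML variance components, BLUP shrinkage and heritability.

test_that("a noise-free panel recovers the planted line-effect variance", {
  sim <- generate_phenotype_panel(
    panel_sim_spec(n_lines = 50, L = 2, R = 2, Vg = 1, Vgl = 0, Ve = 0),
    seed = 3)
  f <- fit_variance_components(sim$panel)
  expect_lt(abs(f$Vg - var(sim$truth$g)), 1e-6)
  expect_lte(f$Ve, 1e-8)
})

test_that("EM-REML matches lme4 on a two-environment panel", {
  skip_if_not_installed("lme4")
  sim <- generate_phenotype_panel(
    panel_sim_spec(n_lines = 80, env_sd = 1), seed = 7)
  f <- fit_variance_components(sim$panel)
  m <- lme4::lmer(value ~ env + (1 | line) + (1 | line:env),
                  data = sim$panel, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  v <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(f$Vg, unname(v["line"]), tolerance = 1e-4)
  expect_equal(f$Vgl, unname(v["line:env"]), tolerance = 1e-4)
  expect_equal(f$Ve, unname(v["Residual"]), tolerance = 1e-4)
  # BLUP deviations match lme4's conditional modes
  b <- blup(sim$panel, f)
  re <- lme4::ranef(m)$line
  expect_equal(b$blup - f$mu, re[b$line, 1], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("parameter recovery over simulated panels is nearly unbiased", {
  est <- sapply(1:40, function(s) {
    p <- generate_phenotype_panel(panel_sim_spec(), seed = 4000 + s)
    f <- fit_variance_components(p$panel)
    c(f$Vg, f$Vgl, f$Ve, heritability(f))
  })
  mn <- rowMeans(est)
  expect_lt(abs(mn[1] - 1), 0.1)
  expect_lt(abs(mn[2] - 0.2), 0.06)
  expect_lt(abs(mn[3] - 0.5), 0.05)
  expect_lt(abs(mn[4] - 0.8451), 0.05)
})

test_that("a pure-noise panel yields a near-zero Vg estimate", {
  vg <- sapply(1:15, function(s) {
    p <- generate_phenotype_panel(
      panel_sim_spec(n_lines = 100, L = 2, R = 2, Vg = 0, Vgl = 0, Ve = 1),
      seed = 300 + s)
    f <- suppressWarnings(fit_variance_components(p$panel, max_iter = 300))
    c(f$Vg, f$Ve)
  })
  expect_lte(median(vg[1, ]), 0.05 * median(vg[2, ]))
})

test_that("BLUP shrinks toward the grand mean", {
  sim <- generate_phenotype_panel(panel_sim_spec(n_lines = 60), seed = 9)
  f <- fit_variance_components(sim$panel)
  b <- blup(sim$panel, f)
  raw <- tapply(sim$panel$value, sim$panel$line, mean)
  expect_true(all(abs(b$blup - f$mu) <=
                    abs(raw[b$line] - mean(sim$panel$value)) + 1e-8))

  # complete shrinkage at Vg = 0
  f0 <- f; f0$Vg <- 0
  b0 <- blup(sim$panel, f0)
  expect_true(all(b0$blup == f0$mu))

  # no-shrinkage limit: Ve -> 0, Vgl = 0 reproduces raw line-mean deviations
  simnf <- generate_phenotype_panel(
    panel_sim_spec(n_lines = 30, L = 2, R = 2, Vg = 1, Vgl = 0, Ve = 1e-8),
    seed = 10)
  fnf <- suppressWarnings(fit_variance_components(simnf$panel,
                                                  include_interaction = FALSE))
  bnf <- blup(simnf$panel, fnf)
  rawnf <- tapply(simnf$panel$value, simnf$panel$line, mean)
  expect_equal(as.numeric(bnf$blup - fnf$mu),
               as.numeric(rawnf[bnf$line] - mean(simnf$panel$value)),
               tolerance = 1e-2)
})

test_that("pipeline is invariant to adding a constant to all observations", {
  sim <- generate_phenotype_panel(panel_sim_spec(n_lines = 40), seed = 11)
  f1 <- fit_variance_components(sim$panel, tol = 1e-12)
  shifted <- sim$panel
  shifted$value <- shifted$value + 1000
  f2 <- fit_variance_components(shifted, tol = 1e-12)
  expect_equal(f2$Vg, f1$Vg, tolerance = 1e-9)
  expect_equal(f2$Vgl, f1$Vgl, tolerance = 1e-9)
  expect_equal(f2$Ve, f1$Ve, tolerance = 1e-9)
  expect_equal(f2$mu, f1$mu + 1000, tolerance = 1e-6)
})

test_that("heritability follows the plug-in formula and its monotonicities", {
  expect_equal(heritability(list(Vg = 1, Vgl = 0.2, Ve = 0.5), 2, 3),
               1 / (1 + 0.1 + 0.5 / 6), tolerance = 1e-12)
  expect_equal(round(heritability(list(Vg = 1, Vgl = 0.2, Ve = 0.5), 2, 3), 4),
               0.8451)
  expect_equal(heritability(list(Vg = 2, Vgl = 0, Ve = 0), 2, 3), 1)
  expect_equal(heritability(list(Vg = 0, Vgl = 0, Ve = 1), 2, 3), 0)
  expect_error(heritability(list(Vg = 0, Vgl = 0, Ve = 0), 2, 3),
               "undefined")
  # monotone in each component and in L, R
  grid <- seq(0.1, 2, by = 0.38)
  h_vg <- sapply(grid, function(v) heritability(list(Vg = v, Vgl = 0.2, Ve = 0.5), 2, 3))
  h_vgl <- sapply(grid, function(v) heritability(list(Vg = 1, Vgl = v, Ve = 0.5), 2, 3))
  h_ve <- sapply(grid, function(v) heritability(list(Vg = 1, Vgl = 0.2, Ve = v), 2, 3))
  expect_true(all(diff(h_vg) > 0))
  expect_true(all(diff(h_vgl) < 0))
  expect_true(all(diff(h_ve) < 0))
  h_L <- sapply(1:5, function(L) heritability(list(Vg = 1, Vgl = 0.2, Ve = 0.5), L, 3))
  h_R <- sapply(1:5, function(R) heritability(list(Vg = 1, Vgl = 0.2, Ve = 0.5), 2, R))
  expect_true(all(diff(h_L) > 0))
  expect_true(all(diff(h_R) > 0))
})

test_that("single-environment panels report a structural zero interaction", {
  sim <- generate_phenotype_panel(
    panel_sim_spec(n_lines = 30, L = 1, R = 3, Vg = 1, Vgl = 0, Ve = 0.5),
    seed = 12)
  f <- fit_variance_components(sim$panel)
  expect_equal(f$Vgl, 0)
  expect_gt(f$Vg, 0)
})
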