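test_that("generator is seed-deterministic and matches its target moments", {
  panel <- trait_panel()
  scen <- sim_scenario(config = c(1, 0, 1, 0), sigma_h2 = panel$sigma_h2,
                       causal = 16000, n_variants = 5e4, n = panel$n,
                       rho_e = panel$rho_e, n_shared = panel$n_shared,
                       seed = 77)
  Z1 <- gen_zscores(scen)
  Z2 <- gen_zscores(scen)
  expect_identical(Z1, Z2)
  # moment check: sample covariance within 3 SE of Sigma_e + Sigma_g(c)
  sigma_e <- build_sigma_e(panel$rho_e, panel$n, panel$n_shared)
  sg <- build_sigma_g_z(panel$sigma_h2 / 16000, panel$n)
  target <- sigma_e + masked_sigma_g(sg, c(1, 0, 1, 0))
  emp <- crossprod(Z1) / nrow(Z1)
  M <- nrow(Z1)
  for (i in 1:4) for (k in 1:4) {
    se_ik <- sqrt((target[i, i] * target[k, k] + target[i, k]^2) / M)
    expect_lt(abs(emp[i, k] - target[i, k]), 3.5 * se_ik)
  }
})

test_that("null scenario draws have identity covariance", {
  scen <- sim_scenario(config = c(0, 0), sigma_h2 = diag(2) * 1e-4,
                       causal = 100, n_variants = 5e4, n = c(1e4, 1e4),
                       seed = 5)
  Z <- gen_zscores(scen)
  emp <- crossprod(Z) / nrow(Z)
  expect_lt(max(abs(emp - diag(2))), 3.5 * sqrt(2 / nrow(Z)))
})

test_that("correlated genetic effects show up among large-effect draws", {
  # two traits, 67% genetic correlation, no environmental correlation
  sg2 <- 4.9e-5
  sh2 <- matrix(c(sg2, 0.67 * sg2, 0.67 * sg2, sg2), 2, 2) * 25000
  scen <- sim_scenario(config = c(1, 1), sigma_h2 = sh2, causal = 1,
                       n_variants = 2e4, n = c(25000, 25000), seed = 13)
  Z <- gen_zscores(scen)
  big <- rowSums(abs(Z) > 2) > 0
  expect_gt(cor(Z[big, 1], Z[big, 2]), 0)
})

test_that("power tuning converges to targets across the operating range", {
  panel <- trait_panel()
  mdl <- cov_model(panel$n, panel$sigma_h2 / 1e6, rho_e = panel$rho_e,
                   n_shared = panel$n_shared)
  cal <- simulate_null(mdl, n = 1e5, r = 2, seed = 41, statistic = "pat")
  for (target in c(0.2, 0.5, 0.8)) {
    fit <- tune_power_scale(mdl, cal, alpha = 1e-4, target = target,
                            n_tune = 1e4, seed = 42)
    expect_lt(abs(fit$power - target), 0.015)
    expect_gt(fit$multiplier, 0)
  }
})

test_that("rejection-region experiment exposes the two geometries", {
  res <- rejection_region_experiment(n_points = 2e4, rho_g = 0, rho_e = 0,
                                     calib_n = 5e4, seed = 19)
  pts <- res$points
  # MI GWAS is an axis-aligned square: the decision is a pure function of
  # max(|s1|, |s2|) against the simulated threshold
  expect_equal(pts$migwas, pmax(abs(pts$s1), abs(pts$s2)) > res$z_mi)
  expect_equal(res$z_mi, mi_gwas_threshold_bonferroni(0.05, 2),
               tolerance = 0.03)
  # PAT with no correlation is a disc: decision depends only on the radius
  r2 <- pts$s1^2 + pts$s2^2
  expect_lt(max(r2[!pts$pat]), min(r2[pts$pat]) + 1e-6)
  # sign-flip and swap invariance of the PAT set (statistic is even and
  # exchangeable here)
  s_swap <- pat_statistic(cbind(pts$s2[1:100], -pts$s1[1:100]), res$model)
  s_orig <- pat_statistic(cbind(pts$s1[1:100], pts$s2[1:100]), res$model)
  expect_equal(s_swap, s_orig, tolerance = 1e-10)
  expect_true(all(names(res$counts) %in%
                    c("PAT only", "MI only", "both", "neither")))
})

test_that("power asymmetry flips between genetic and environmental correlation", {
  res_g <- rejection_region_experiment(n_points = 3e4, rho_g = 0.67,
                                       rho_e = 0, calib_n = 5e4, seed = 29)
  res_e <- rejection_region_experiment(n_points = 3e4, rho_g = 0,
                                       rho_e = 0.67, calib_n = 5e4, seed = 29)
  conc_power <- function(res) {
    pts <- res$points
    conc <- sign(pts$s1) == sign(pts$s2)
    r <- sqrt(pts$s1^2 + pts$s2^2)
    band <- r > 2.5 & r < 3.5          # matched radius band
    c(conc = mean(pts$pat[band & conc]), disc = mean(pts$pat[band & !conc]))
  }
  pg <- conc_power(res_g)
  pe <- conc_power(res_e)
  expect_gt(pg["conc"], pg["disc"])    # genetic correlation favors concordant
  expect_lt(pe["conc"], pe["disc"])    # environmental correlation reverses it
})

test_that("layered power experiment controls the null and orders methods", {
  panel <- trait_panel()
  out <- power_table_experiment(panel$n, panel$sigma_h2,
                                rho_e = panel$rho_e,
                                n_shared = panel$n_shared,
                                alpha = 1e-5, scale_factor = 0.01,
                                calib_n = 2e5, r = 2, seed = 55)
  tab <- out$table
  expect_equal(nrow(tab), 1 + 15 * 3)
  # null block: expected false positives alpha * n << 1
  expect_lte(tab$pat[1], 2)
  expect_lte(tab$migwas[1], 2)
  # power (rejection rate) grows as the causal count shrinks, i.e. as
  # per-variant effects grow
  rate <- tab$pat[-1] / tab$n_variants[-1]
  by_causal <- tapply(rate, tab$causal[-1], mean)
  by_causal <- by_causal[order(-as.numeric(names(by_causal)))]
  expect_true(all(diff(by_causal) >= 0))
  expect_gte(out$totals["pat"], out$totals["migwas"])
})
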