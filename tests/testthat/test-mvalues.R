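test_that("m-values reduce to the two-term posterior at T = 1", {
  v <- 60                                 # scaled genetic variance
  mdl <- cov_model(n = 1e4, sigma_g = matrix(v / 1e4, 1, 1))
  for (s in c(0, 1, 3, 6)) {
    l1 <- dnorm(s, sd = sqrt(1 + v), log = FALSE)
    l0 <- dnorm(s, sd = 1, log = FALSE)
    expect_equal(as.numeric(compute_mvalues(s, mdl, scale = 1)),
                 l1 / (l0 + l1), tolerance = 1e-12)
  }
  # at S = 0 a large genetic variance makes the alternative implausible
  expect_lt(as.numeric(compute_mvalues(0, mdl)), 0.5)
  # complement identity: the two configuration masses sum to one
  m <- as.numeric(compute_mvalues(2.5, mdl))
  expect_equal(m + (1 - m), 1)
})

test_that("exchangeable traits with equal z get equal m-values", {
  mdl <- toy_model2(n_sigma = 2, rho_g = 0.5, rho_e = 0.3)
  m <- compute_mvalues(c(3.2, 3.2), mdl, scale = 10)
  expect_equal(m[[1]], m[[2]], tolerance = 1e-12)
})

test_that("optimized path matches brute-force enumeration at T = 4", {
  panel <- trait_panel()
  mdl <- cov_model(panel$n, panel$sigma_h2 / 5e4, rho_e = panel$rho_e,
                   n_shared = panel$n_shared)
  set.seed(17)
  Z <- matrix(rnorm(40, sd = 3), 10, 4)
  got <- compute_mvalues(Z, mdl, scale = 3)
  for (i in 1:10) {
    want <- brute_mvalues(Z[i, ], mdl$sigma_e, mdl$sigma_g_z, scale = 3)
    expect_equal(as.numeric(got[i, ]), want, tolerance = 1e-10)
  }
  expect_true(all(got >= 0 & got <= 1))
})

test_that("m-values are equivariant under trait permutation", {
  panel <- trait_panel()
  mdl <- cov_model(panel$n, panel$sigma_h2 / 5e4, rho_e = panel$rho_e,
                   n_shared = panel$n_shared)
  S <- c(4.1, -2.0, 5.5, 0.3)
  p <- c(2, 4, 1, 3)
  mdl_p <- cov_model(panel$n[p], (panel$sigma_h2 / 5e4)[p, p],
                     rho_e = panel$rho_e[p, p],
                     n_shared = panel$n_shared[p, p])
  expect_equal(as.numeric(compute_mvalues(S[p], mdl_p, scale = 2)),
               as.numeric(compute_mvalues(S, mdl, scale = 2))[p],
               tolerance = 1e-10)
})

test_that("assignment uses a strict 0.9 threshold", {
  labs <- assign_mvalues(c(0.95, 0.5, 0.9, 0.90001))
  expect_equal(labs, c("associated", "ambiguous", "ambiguous", "associated"))
  m <- matrix(c(0.99, 0.1, 0.91, 0.89), 2, 2)
  expect_equal(dim(assign_mvalues(m)), dim(m))
})

test_that("m-values bound the false assignment rate conservatively", {
  mdl <- toy_model2(n_sigma = 1.5, rho_g = 0.2)
  set.seed(23)
  n_each <- 4000
  scale <- 40
  # half the variants have an effect in trait 1 only, half in neither
  sig_alt <- mdl$sigma_e + scale * masked_sigma_g(mdl$sigma_g_z, c(1, 0))
  Z <- rbind(matrix(rnorm(n_each * 2), n_each, 2) %*% chol(sig_alt),
             matrix(rnorm(n_each * 2), n_each, 2) %*% chol(mdl$sigma_e))
  truly_null_t1 <- rep(c(FALSE, TRUE), each = n_each)
  m <- compute_mvalues(Z, mdl, scale = scale)
  called <- m[, 1] > 0.9
  expect_gt(sum(called), 0)
  # among trait-1 assignments, the truly-null fraction stays below 1 - 0.9
  expect_lt(mean(truly_null_t1[called]), 0.1)
})

test_that("P-M plot regions follow the p/m cross-classification", {
  d <- pm_plot_data(p = c(1e-12, 1e-3, 1e-12, 0.5),
                    m = c(0.99, 0.2, 0.3, 0.95))
  expect_equal(d$region, c("B", "C", "A", "D"))
  expect_error(pm_plot_data(p = c(0, 0.5), m = c(0.5, 0.5)))
})

test_that("Q grid search samples one variant per window and recovers scale", {
  panel <- trait_panel()
  mdl <- cov_model(panel$n, panel$sigma_h2 / 1e6, rho_e = panel$rho_e,
                   n_shared = panel$n_shared)
  # two significant variants 30kb apart share a 100KB window: only one
  # enters the likelihood
  z2 <- matrix(c(6, 5, 5, 4, 4, 3, 6, 5), 2, 4)
  hits2 <- structure(list(
    trait_names = mdl$trait_names,
    variants = data.table::data.table(variant_id = c("a", "b"), chrom = "1",
                                      pos = c(150000L, 180000L),
                                      ref = "A", alt = "G"),
    z = z2, n = matrix(panel$n, 2, 4, byrow = TRUE),
    n_per_trait = panel$n), class = "multi_sumstats")
  cs <- estimate_q(hits2, mdl, M = 1e6, seed = 3)
  expect_equal(cs$k, 1)

  # parameter recovery sanity at one replicate (full sweep in acceptance):
  # draw hits from (M/Q*) Sigma_g + Sigma_e with M/Q* = 50
  M <- 1e6
  true_scale <- 50
  set.seed(31)
  k <- 80
  Zh <- matrix(rnorm(k * 4), k, 4) %*%
    chol(mdl$sigma_e + true_scale * mdl$sigma_g_z)
  hits <- structure(list(
    trait_names = mdl$trait_names,
    variants = data.table::data.table(
      variant_id = paste0("v", 1:k), chrom = "1",
      pos = as.integer(seq_len(k) * 200000L), ref = "A", alt = "G"),
    z = Zh, n = matrix(panel$n, k, 4, byrow = TRUE),
    n_per_trait = panel$n), class = "multi_sumstats")
  cs <- estimate_q(hits, mdl, M = M, seed = 5)
  expect_equal(cs$k, k)
  expect_gt(cs$scale, true_scale / 3)
  expect_lt(cs$scale, true_scale * 3)
  # the recorded grid maximum is the returned Q
  expect_equal(cs$grid$Q[which.max(cs$grid$loglik)], cs$Q)
  # errors: positions and hits are required
  no_pos <- hits
  no_pos$variants$pos <- NA_integer_
  expect_error(estimate_q(no_pos, mdl, M = M, seed = 1), "positional")
  empty <- hits
  empty$z <- hits$z[0, , drop = FALSE]
  expect_error(estimate_q(empty, mdl, M = M, seed = 1), "significant")
})
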