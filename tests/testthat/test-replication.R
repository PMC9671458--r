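test_that("greedy clumping keeps one lead per window", {
  # 0.4MB apart: the weaker of the two is suppressed
  leads <- clump(chrom = c("1", "1"), pos = c(1e6, 1.4e6),
                 score = c(0.99, 0.95))
  expect_equal(leads, 1L)
  # 1.5MB apart: both survive
  leads <- clump(chrom = c("1", "1"), pos = c(1e6, 2.5e6),
                 score = c(0.99, 0.95))
  expect_equal(sort(leads), c(1L, 2L))
  # different chromosomes never suppress each other
  leads <- clump(chrom = c("1", "2"), pos = c(1e6, 1e6),
                 score = c(0.99, 0.95))
  expect_equal(sort(leads), c(1L, 2L))
  # p-value rule: smallest wins
  leads <- clump(chrom = c("1", "1"), pos = c(1e6, 1.2e6),
                 score = c(1e-12, 1e-4), decreasing = FALSE)
  expect_equal(leads, 1L)
  # ties break to the smaller coordinate
  leads <- clump(chrom = c("1", "1"), pos = c(2e6, 1e6),
                 score = c(0.9, 0.9))
  expect_equal(leads[1], 2L)
})

test_that("greedy clumping matches the exhaustive oracle on random fixtures", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 100
    chrom <- sample(c("1", "2", "3"), n, replace = TRUE)
    pos <- sample.int(2e7, n)
    score <- round(runif(n), 3)          # rounded so ties actually occur
    got <- clump(chrom, pos, score)
    want <- brute_clump(chrom, pos, score)
    expect_equal(got, want)
    # no two leads on one chromosome within the window
    for (c_ in unique(chrom[got])) {
      p <- sort(pos[got][chrom[got] == c_])
      if (length(p) > 1) expect_true(all(diff(p) >= 5e5))
    }
  }
})

test_that("one-sided replication test follows the discovery direction", {
  r <- one_sided_replication_test(beta_disc = 0.1, beta_rep = 0,
                                  se_rep = 0.02, alpha_adjusted = 0.05)
  expect_equal(r$p_one_sided, 0.5)
  # concordant negative effects: p = 1 - Phi(3.9)
  r <- one_sided_replication_test(beta_disc = -0.2, beta_rep = -0.039,
                                  se_rep = 0.01, alpha_adjusted = 1e-4)
  expect_equal(r$p_one_sided, pnorm(3.9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p_one_sided, 4.8e-5, tolerance = 0.01)
  expect_true(r$replicated && r$same_direction)
  # discordant effect cannot replicate
  r <- one_sided_replication_test(beta_disc = 0.2, beta_rep = -0.05,
                                  se_rep = 0.01, alpha_adjusted = 0.05)
  expect_false(r$replicated)
  expect_false(r$same_direction)
  expect_error(one_sided_replication_test(0, 0.1, 0.01, 0.05), "direction")
  # replicated implies same_direction across a random batch
  set.seed(3)
  r <- one_sided_replication_test(rnorm(200), rnorm(200), runif(200, .01, .1),
                                  alpha_adjusted = 0.05)
  expect_true(all(!r$replicated | r$same_direction))
})

test_that("exact binomial concordance matches direct summation and prints", {
  expect_equal(concordance_binomial(1, 1), 0.5)
  for (n in c(5, 12, 30)) {
    for (k in c(0, floor(n / 2), n)) {
      expect_equal(concordance_binomial(k, n), brute_binom_tail(k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("replication power is the size at null and monotone otherwise", {
  a <- 1.22e-4
  expect_equal(replication_power(0, maf = 0.2, n_rep = 1e5,
                                 alpha_adjusted = a), a)
  p1 <- replication_power(0.02, 0.2, 1e5, a)
  p2 <- replication_power(0.04, 0.2, 1e5, a)
  p3 <- replication_power(0.04, 0.2, 4e5, a)
  expect_gt(p2, p1)
  expect_gt(p3, p2)
  # lambda exactly at the critical point: power one half
  lam <- qnorm(1 - a)
  beta <- lam / sqrt(2 * 0.2 * 0.8 * 1e5)
  expect_equal(replication_power(beta, 0.2, 1e5, a), 0.5)
})

test_that("observed replications track expected counts within deciles", {
  # fully synthetic replication cohort with known true effects
  set.seed(71)
  n_lead <- 2000
  maf <- runif(n_lead, 0.05, 0.5)
  n_rep <- 60000
  beta_true <- rnorm(n_lead, 0, 0.015)
  beta_true[beta_true == 0] <- 0.001
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_rep)
  beta_obs <- rnorm(n_lead, beta_true, se)
  alpha_adj <- 0.05 / n_lead
  tst <- one_sided_replication_test(beta_true, beta_obs, se, alpha_adj)
  pow <- replication_power(beta_true, maf, n_rep, alpha_adj)
  summ <- power_decile_summary(pow, tst$replicated, tst$same_direction)
  expect_true(all(summ$n_tested >= 1))
  dec <- pmin(floor(pow * 10), 9)
  for (i in seq_len(nrow(summ))) {
    d <- as.integer(sub("-.*", "", summ$decile[i])) / 10
    in_d <- dec == d
    exp_n <- summ$expected_replications[i]
    sd_n <- sqrt(sum(pow[in_d] * (1 - pow[in_d])))
    expect_lt(abs(summ$n_replicated[i] - exp_n), 3.5 * max(sd_n, 1.5))
  }
  # concordance p-values are valid probabilities, small in strong deciles
  expect_true(all(summ$concordance_p > 0 & summ$concordance_p <= 1))
})
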