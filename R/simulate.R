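#' Define a z-score simulation scenario
#'
#' A scenario fixes which traits carry a true effect (`config`), the
#' heritability covariance `sigma_h2` across traits, the effective number
#' of causal variants (`causal`, so the per-variant genetic covariance is
#' `sigma_h2 / causal`), the number of variants to draw, per-trait sample
#' sizes, the environmental structure and a seed.
#'
#' @param config length-T 0/1 vector of traits with a true effect.
#' @param sigma_h2 T x T heritability covariance matrix.
#' @param causal effective causal-variant count (>= 1) dividing `sigma_h2`.
#' @param n_variants number of variants to simulate.
#' @param n length-T per-trait sample sizes.
#' @param rho_e T x T environmental correlations; default identity.
#' @param n_shared T x T overlap counts; default no overlap.
#' @param seed integer seed.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(config, sigma_h2, causal, n_variants, n,
                         rho_e = NULL, n_shared = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  T <- length(n)
  stopifnot(length(config) == T, causal >= 1, n_variants >= 1)
  structure(list(config = as.numeric(config),
                 sigma_h2 = as.matrix(sigma_h2), causal = causal,
                 n_variants = as.integer(n_variants), n = as.numeric(n),
                 rho_e = if (is.null(rho_e)) diag(T) else as.matrix(rho_e),
                 n_shared = if (is.null(n_shared)) diag(n, T) else
                   as.matrix(n_shared),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate multi-trait z-scores under a scenario
#'
#' Rows are drawn i.i.d. from the marginal (posterior-predictive)
#' multivariate normal `N(0, Sigma_e + Sigma_g(c))` with
#' `Sigma_g(c)[i,k] = sqrt(n_i n_k) * sigma_h2[i,k] / causal` masked by the
#' scenario's configuration — distributionally identical to drawing
#' per-variant effect sizes and adding unit noise, but in one matrix
#' product. The null configuration draws from `N(0, Sigma_e)`.
#'
#' @param scenario a [sim_scenario()].
#' @return M x T z-score matrix.
#' @export
gen_zscores <- function(scenario) {
  T <- length(scenario$n)
  sigma_e <- build_sigma_e(scenario$rho_e, scenario$n, scenario$n_shared)
  sg_z <- build_sigma_g_z(scenario$sigma_h2 / scenario$causal, scenario$n)
  sigma <- sigma_e + masked_sigma_g(sg_z, scenario$config)
  ch <- chol(psd_repair(sigma, label = "scenario covariance"))
  set.seed(scenario$seed)
  matrix(stats::rnorm(scenario$n_variants * T), scenario$n_variants, T) %*% ch
}

#' Tune the genetic-effect scale to a target PAT power
#'
#' Given an analysis model and its PAT calibration, finds the multiplier on
#' the (configuration-masked) generative genetic covariance at which PAT's
#' rejection rate at `alpha` equals `target`. Uses common random numbers —
#' one fixed standard-normal draw reused across candidate multipliers, so
#' the estimated power is monotone in the multiplier — and a bisection on
#' the log scale.
#'
#' @param model a [cov_model()] (the analysis model).
#' @param calibration PAT calibration for `model`.
#' @param alpha significance level.
#' @param target target power in \[0.05, 0.95\].
#' @param config generative configuration; default all traits.
#' @param n_tune Monte-Carlo draws per evaluation; default 2e4.
#' @param seed integer seed.
#' @param tol convergence tolerance on power; default 0.01.
#' @return list with `multiplier` and the achieved `power`.
#' @export
tune_power_scale <- function(model, calibration, alpha, target,
                             config = rep(1, model$T), n_tune = 2e4, seed,
                             tol = 0.01) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(target >= 0.01, target <= 0.99)
  kappa <- critical_value(alpha, calibration)
  set.seed(as.integer(seed))
  U <- matrix(stats::rnorm(n_tune * model$T), n_tune, model$T)
  sg_c <- masked_sigma_g(model$sigma_g_z, config)
  if (all(sg_c == 0)) stop("configuration has no genetic effect to scale")
  power_at <- function(mult) {
    Z <- U %*% chol(model$sigma_e + mult * sg_c)
    mean(pat_statistic(Z, model) > kappa)
  }
  lo <- 1e-8
  hi <- 1
  it <- 0
  while (power_at(hi) < target && hi < 1e10) hi <- hi * 8
  mid <- sqrt(lo * hi)
  p <- power_at(mid)
  while (abs(p - target) > tol && it < 80) {
    if (p < target) lo <- mid else hi <- mid
    mid <- sqrt(lo * hi)
    p <- power_at(mid)
    it <- it + 1
  }
  list(multiplier = mid, power = p)
}

# internal: lay M variants on a synthetic genome, one every `spacing` bp
# across 22 chromosomes
synthetic_positions <- function(M, spacing = 3000, n_chrom = 22) {
  per <- ceiling(M / n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per)[seq_len(M)]
  pos <- rep(seq_len(per) * spacing, times = n_chrom)[seq_len(M)]
  data.table::data.table(chrom = chrom, pos = as.integer(pos))
}

# internal: wrap a z matrix with synthetic positions as multi_sumstats
as_multi_sumstats <- function(z, n, trait_names = colnames(z),
                              positions = NULL) {
  M <- nrow(z)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(z)))
  if (is.null(positions)) positions <- synthetic_positions(M)
  variants <- data.table::data.table(
    variant_id = paste0(positions$chrom, ":", positions$pos),
    chrom = positions$chrom, pos = positions$pos,
    ref = "A", alt = "G")
  structure(list(trait_names = trait_names, variants = variants,
                 z = `dimnames<-`(as.matrix(z), list(NULL, trait_names)),
                 n = matrix(n, M, length(n), byrow = TRUE),
                 n_per_trait = n),
            class = "multi_sumstats")
}

#' Rejection-region comparison of PAT and MI GWAS
#'
#' Simulates two-trait summary statistics under the alternative and labels
#' each point by which test rejects at `alpha`, exposing the geometry of
#' the two rejection regions: MI GWAS (max |z| over a simulated null
#' threshold) always rejects outside an axis-aligned square, while PAT's
#' region is an ellipse shaped by the environmental and genetic
#' correlations (a circle when both are zero).
#'
#' @param n_points number of simulated variants; default 1e5.
#' @param N per-trait sample size; default 25000.
#' @param sigma_g2 per-variant genetic variance; default 4.9e-5.
#' @param rho_g genetic correlation between the two traits.
#' @param rho_e environmental correlation between the two traits.
#' @param alpha significance level; default 0.05.
#' @param calib_n null-simulation draws for the thresholds; default 2e5.
#' @param seed integer seed.
#' @return list with `points` (data.table: s1, s2, pat, migwas, label),
#'   `counts` (table of labels), `kappa`, `z_mi`, and the `model`.
#' @export
rejection_region_experiment <- function(n_points = 1e5, N = 25000,
                                        sigma_g2 = 4.9e-5, rho_g = 0,
                                        rho_e = 0, alpha = 0.05,
                                        calib_n = 2e5, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  n <- c(N, N)
  sigma_g <- matrix(c(sigma_g2, rho_g * sigma_g2,
                      rho_g * sigma_g2, sigma_g2), 2, 2)
  re <- matrix(c(1, rho_e, rho_e, 1), 2, 2)
  n_shared <- matrix(c(N, N, N, N), 2, 2)  # same cohort measures both traits
  if (rho_e == 0) n_shared <- diag(n, 2)
  model <- cov_model(n, sigma_g, rho_e = re, n_shared = n_shared)
  cal_pat <- simulate_null(model, n = calib_n, r = 1, seed = seed + 1,
                           statistic = "pat")
  cal_mi <- simulate_null(model, n = calib_n, r = 1, seed = seed + 2,
                          statistic = "migwas")
  kappa <- critical_value(alpha, cal_pat)
  z_mi <- critical_value(alpha, cal_mi)
  scen <- sim_scenario(config = c(1, 1), sigma_h2 = sigma_g, causal = 1,
                       n_variants = n_points, n = n, rho_e = re,
                       n_shared = n_shared, seed = seed)
  Z <- gen_zscores(scen)
  pat_sig <- pat_statistic(Z, model) > kappa
  mi_sig <- row_max_abs(Z) > z_mi
  label <- ifelse(pat_sig & mi_sig, "both",
                  ifelse(pat_sig, "PAT only",
                         ifelse(mi_sig, "MI only", "neither")))
  pts <- data.table::data.table(s1 = Z[, 1], s2 = Z[, 2], pat = pat_sig,
                                migwas = mi_sig, label = label)
  list(points = pts, counts = table(label), kappa = kappa, z_mi = z_mi,
       model = model)
}

# the 15 non-empty subsets of the four traits, in a stable order
table1_configs <- function(T = 4) {
  cfg <- configurations(T)
  cfg <- cfg[rowSums(cfg) > 0, , drop = FALSE]
  cfg[order(-rowSums(cfg), apply(cfg, 1, function(r)
    sum(r * 2^(seq_along(r) - 1)))), , drop = FALSE]
}

#' Multi-configuration power experiment (omnibus and per-trait)
#'
#' Reproduces the layered simulation design used for the power comparison:
#' a large null block plus, for every non-empty configuration of the T
#' traits, three blocks of variants whose genetic covariance is
#' `sigma_h2 / causal` for causal = 40k, 24k, 16k (block sizes 5000, 3000,
#' 2000, all scaled by `scale_factor`; 10% of variants causal overall at
#' `scale_factor = 1` with the default 1.35M null block). The analysis
#' model is polygenic — `sigma_g = sigma_h2 / total_variants` — so the
#' test is deliberately misspecified relative to the sparse generative
#' model, as in real GWAS. Counts of PAT- and MI-GWAS-significant variants
#' are tallied per block; optionally m-values are computed for PAT hits
#' (after estimating Q on the hits) and true/false per-trait assignments
#' are tallied.
#'
#' @param n length-T per-trait sample sizes.
#' @param sigma_h2 T x T heritability covariance.
#' @param rho_e,n_shared environmental structure; defaults identity / none.
#' @param alpha significance level; default 5e-8.
#' @param scale_factor scales all block sizes; default 1 is the full
#'   1.5M-variant design. Use 0.1 for a quick run.
#' @param null_count null-block size before scaling; default 1,350,000.
#' @param counts per-causal-level block sizes before scaling.
#' @param causal_levels effective causal counts (effect sizes are
#'   `sigma_h2 / causal`, so power grows as causal shrinks).
#' @param calib_n,r importance-sampling calibration size and proposal scale.
#' @param seed integer seed.
#' @param with_mvalues also interpret PAT hits per trait? Default FALSE.
#' @param mvalue_threshold assignment threshold; default 0.9.
#' @return list with `table` (per-block counts), `totals`, thresholds, and
#'   when requested `mvalues` (per-trait true/false assignment counts and
#'   the false-assignment rate) .
#' @export
power_table_experiment <- function(n, sigma_h2, rho_e = NULL, n_shared = NULL,
                                   alpha = 5e-8, scale_factor = 1,
                                   null_count = 1350000,
                                   counts = c(5000, 3000, 2000),
                                   causal_levels = c(40000, 24000, 16000),
                                   calib_n = 1e6, r = 2, seed,
                                   with_mvalues = FALSE,
                                   mvalue_threshold = 0.9) {
  if (missing(seed)) stop("an explicit seed is required")
  T <- length(n)
  cfgs <- table1_configs(T)
  n_null <- round(null_count * scale_factor)
  block_sizes <- round(counts * scale_factor)
  total_variants <- n_null + nrow(cfgs) * sum(block_sizes)
  model <- cov_model(n, sigma_h2 / total_variants, rho_e = rho_e,
                     n_shared = n_shared)
  cal_pat <- simulate_null(model, n = calib_n, r = r, seed = seed + 1,
                           statistic = "pat")
  cal_mi <- simulate_null(model, n = calib_n, r = r, seed = seed + 2,
                          statistic = "migwas")
  kappa <- critical_value(alpha, cal_pat)
  z_mi <- critical_value(alpha, cal_mi)

  blocks <- list(list(config = rep(0, T), causal = NA_real_,
                      n_variants = n_null))
  for (i in seq_len(nrow(cfgs)))
    for (j in seq_along(causal_levels))
      blocks[[length(blocks) + 1]] <- list(config = cfgs[i, ],
                                           causal = causal_levels[j],
                                           n_variants = block_sizes[j])
  rows <- vector("list", length(blocks))
  Zs <- vector("list", length(blocks))
  truth <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bk <- blocks[[b]]
    scen <- sim_scenario(config = bk$config, sigma_h2 = sigma_h2,
                         causal = if (is.na(bk$causal)) 1 else bk$causal,
                         n_variants = bk$n_variants, n = n, rho_e = rho_e,
                         n_shared = n_shared, seed = seed + 100 + b)
    Z <- gen_zscores(scen)
    pat_sig <- pat_statistic(Z, model) > kappa
    mi_sig <- row_max_abs(Z) > z_mi
    rows[[b]] <- data.table::data.table(
      config = paste(bk$config, collapse = ""), causal = bk$causal,
      n_variants = bk$n_variants, pat = sum(pat_sig), migwas = sum(mi_sig))
    if (with_mvalues) {
      Zs[[b]] <- Z[pat_sig, , drop = FALSE]
      truth[[b]] <- matrix(rep(bk$config, each = sum(pat_sig)),
                           ncol = T)
    }
  }
  tab <- data.table::rbindlist(rows)
  out <- list(table = tab,
              totals = c(pat = sum(tab$pat[-1]), migwas = sum(tab$migwas[-1]),
                         pat_null = tab$pat[1], migwas_null = tab$migwas[1]),
              kappa = kappa, z_mi = z_mi, alpha = alpha, model = model,
              total_variants = total_variants)
  if (with_mvalues) {
    Zh <- do.call(rbind, Zs)
    th <- do.call(rbind, truth)
    if (nrow(Zh) > 0) {
      hits <- as_multi_sumstats(Zh, n, trait_names = model$trait_names)
      cs <- estimate_q(hits, model, M = total_variants, seed = seed + 7)
      m <- compute_mvalues(Zh, model, scale = cs$scale)
      assoc <- m > mvalue_threshold
      out$mvalues <- list(
        scaling = cs,
        per_trait = data.table::data.table(
          trait = model$trait_names,
          true_assigned = colSums(assoc & th == 1),
          false_assigned = colSums(assoc & th == 0),
          ambiguous = colSums(!assoc)),
        false_assignment_rate = sum(assoc & th == 0) / max(1, sum(assoc)))
    }
  }
  out
}

#' M-value interpretation accuracy under a tuned-power design
#'
#' Simulates `n_variants` variants whose true effect lies in the traits of
#' `config`, with the genetic scale tuned so PAT's power at `alpha` equals
#' `target_power`. PAT hits are interpreted per trait via Q estimation and
#' m-values, and the per-trait assignments are cross-tabulated against the
#' truth, split by whether the trait's |z| exceeds 3 (modest marginal
#' signal).
#'
#' @param model the analysis [cov_model()] (polygenic-scale sigma_g).
#' @param config length-T 0/1 generative configuration.
#' @param target_power PAT power to tune to; default 0.5.
#' @param n_variants number of simulated variants; default 1e6.
#' @param alpha significance level; default 5e-8.
#' @param calibration optional precomputed PAT calibration (else built
#'   with `calib_n` draws at r = 2).
#' @param calib_n calibration draws when `calibration` is NULL.
#' @param seed integer seed.
#' @param mvalue_threshold assignment threshold; default 0.9.
#' @return list with the contingency `summary` (per trait x |z| split:
#'   associated/ambiguous counts), `fn_rate` (truly-affected, |z| > 3,
#'   PAT-significant entries left ambiguous), `fp_rate` (assignments to
#'   unaffected traits over all assignments), the tuned `multiplier`,
#'   achieved tuning `power`, observed rejection rate, and `scaling`.
#' @export
mvalue_accuracy_experiment <- function(model, config, target_power = 0.5,
                                       n_variants = 1e6, alpha = 5e-8,
                                       calibration = NULL, calib_n = 1e6,
                                       seed, mvalue_threshold = 0.9) {
  if (missing(seed)) stop("an explicit seed is required")
  T <- model$T
  if (is.null(calibration))
    calibration <- simulate_null(model, n = calib_n, r = 2, seed = seed + 1,
                                 statistic = "pat")
  kappa <- critical_value(alpha, calibration)
  tune <- tune_power_scale(model, calibration, alpha, target_power,
                           config = config, seed = seed + 2)
  sg_c <- masked_sigma_g(model$sigma_g_z, config) * tune$multiplier
  ch <- chol(model$sigma_e + sg_c)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_variants * T), n_variants, T) %*% ch
  sig <- pat_statistic(Z, model) > kappa
  Zh <- Z[sig, , drop = FALSE]
  hits <- as_multi_sumstats(Zh, model$n, trait_names = model$trait_names)
  cs <- estimate_q(hits, model, M = n_variants, seed = seed + 3)
  m <- compute_mvalues(Zh, model, scale = cs$scale)
  assoc <- m > mvalue_threshold
  big <- abs(Zh) > 3
  truth <- matrix(as.logical(config), nrow(Zh), T, byrow = TRUE)
  summ <- data.table::data.table(
    trait = rep(model$trait_names, each = 2),
    z_split = rep(c("|z|>3", "|z|<=3"), T),
    associated = as.vector(rbind(colSums(assoc & big),
                                 colSums(assoc & !big))),
    ambiguous = as.vector(rbind(colSums(!assoc & big),
                                colSums(!assoc & !big))))
  fn_rate <- sum(!assoc & big & truth) / max(1, sum(big & truth))
  fp_rate <- sum(assoc & !truth) / max(1, sum(assoc))
  list(summary = summ, fn_rate = fn_rate, fp_rate = fp_rate,
       multiplier = tune$multiplier, power = tune$power,
       rejection_rate = mean(sig), scaling = cs, n_hits = nrow(Zh))
}
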